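# shared internal helpers

# run code with a locally seeded RNG, restoring global state afterwards
withSeed <- function(seed, code) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
        if (had) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed) %% .Machine$integer.max)
    force(code)
}

# sorted unique semicolon join / split
joinSemi <- function(x) paste(sort(unique(x[!is.na(x) & nzchar(x)])), collapse = ";")

splitSemi <- function(x) {
    if (length(x) == 0) return(character())
    unlist(strsplit(x, ";", fixed = TRUE), use.names = FALSE)
}

# case-fold and collapse internal whitespace; used for drug keys and indications
normalizeText <- function(x) {
    x <- tolower(trimws(x))
    gsub("[[:space:]]+", " ", x)
}

stopIfNot <- function(cond, ...) if (!isTRUE(cond)) stop(..., call. = FALSE)

# deterministic TSV writer shared by all pipeline outputs
writeTsv <- function(df, path) {
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = TRUE, fileEncoding = "UTF-8", eol = "\n")
    invisible(path)
}
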