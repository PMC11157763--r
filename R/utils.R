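# shared internal helpers

# min-max scale to [0,1]; a constant vector maps to all-zero (contributes no
# discrimination, avoids 0/0)
.minMax <- function(x) {
    r <- range(x, finite = TRUE)
    if (!is.finite(r[1]) || r[2] - r[1] == 0) return(rep(0, length(x)))
    (x - r[1]) / (r[2] - r[1])
}

# counts-per-million on a genes x units matrix, log2(CPM + 1)
.logCPM <- function(m) {
    libs <- colSums(m)
    libs[libs == 0] <- 1
    log2(sweep(as.matrix(m), 2, libs, "/") * 1e6 + 1)
}

.assertCount <- function(x, name, min = 1) {
    if (length(x) != 1 || !is.numeric(x) || is.na(x) || x != round(x) || x < min)
        stop(sprintf("'%s' must be a single integer >= %d", name, min), call. = FALSE)
    invisible(as.integer(x))
}

.assertPositive <- function(x, name) {
    if (length(x) != 1 || !is.numeric(x) || is.na(x) || x <= 0)
        stop(sprintf("'%s' must be a single positive number", name), call. = FALSE)
    invisible(x)
}

# deterministic ordering: descending by value, ties broken by lexicographic name
.orderDescTies <- function(values, names) order(-values, names, method = "radix")
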