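# Internal helpers shared across modules.

# Derive a stage-specific seed from the master seed so that each stochastic
# operation has its own reproducible stream. Kept below 2^31 - 1.
deriveSeed <- function(seed, tag) {
    stopifnot(is.numeric(seed), length(seed) == 1L, !is.na(seed))
    h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
    as.integer((abs(seed) * 69069 + h * 101 + 1) %% 2147483587)
}

# Run `expr` under a given seed without disturbing the caller's RNG state.
withSeed <- function(seed, expr) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        old <- get(".Random.seed", envir = globalenv())
        on.exit(assign(".Random.seed", old, envir = globalenv()))
    } else {
        on.exit(if (exists(".Random.seed", envir = globalenv(),
                           inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
    }
    set.seed(seed)
    expr
}

# Deterministic, locale-independent ordering (C collation).
orderRadix <- function(...) order(..., method = "radix")

.assertScalarNumber <- function(x, name, lo = -Inf, hi = Inf) {
    if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lo || x > hi)
        stop("'", name, "' must be a single number in [", lo, ", ", hi, "]",
             call. = FALSE)
    invisible(x)
}

# Zero-pad ids like snp00001 / gene001 so lexicographic order equals
# numeric order.
padIds <- function(prefix, n) {
    sprintf(paste0(prefix, "%0", max(3L, nchar(as.character(n))), "d"),
            seq_len(n))
}
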