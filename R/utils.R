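# internal helpers

# evaluate expr with a locally set RNG seed, restoring global state after
.withSeed <- function(seed, expr) {
    if (!is.null(seed)) {
        old <- if (exists(".Random.seed", envir = globalenv()))
            get(".Random.seed", envir = globalenv()) else NULL
        set.seed(as.integer(seed))
        on.exit({
            if (is.null(old))
                rm(".Random.seed", envir = globalenv())
            else
                assign(".Random.seed", old, envir = globalenv())
        })
    }
    force(expr)
}

.assertScalarNumber <- function(x, name, lower = -Inf, upper = Inf) {
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x) ||
        x < lower || x > upper)
        stop(name, " must be a single finite number in [", lower, ", ",
             upper, "]", call. = FALSE)
    invisible(x)
}
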