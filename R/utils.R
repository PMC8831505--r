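## Deterministic seed fan-out: one master seed yields independent,
## reproducible per-stage seeds. Lehmer-style multiplicative step keeps
## everything inside the 32-bit integer range set.seed() accepts.
.stageSeed <- function(seed, stage) {
    as.integer((as.numeric(seed) %% 2147483629 * 48271 + stage * 7919) %%
        2147483629)
}

## Evaluate `code` under a fixed seed, restoring the caller's RNG state.
## `seed = NULL` means: use (and advance) the current RNG stream.
.withSeed <- function(seed, code) {
    if (is.null(seed)) return(force(code))
    if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        stats::runif(1)
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
    force(code)
}

.assertScalarNumber <- function(x, name, lower = -Inf, upper = Inf) {
    if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lower || x > upper)
        stop(sprintf("'%s' must be a single number in [%s, %s]",
            name, format(lower), format(upper)), call. = FALSE)
    invisible(x)
}
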