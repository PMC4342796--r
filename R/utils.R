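# Internal helpers shared across modules.

# Run expr with a temporarily seeded RNG, restoring the caller's RNG state.
# Every stochastic operation in the package routes through this so that a
# fixed seed gives bit-identical results without clobbering the session RNG.
withSeed <- function(seed, expr) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = globalenv())
    on.exit({
        if (had) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(),
                        inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed))
    force(expr)
}

# Stable 31-bit hash of a string, mixed with a master seed: derives
# per-scenario / per-dataset seeds so that re-ordering scenarios cannot
# change any result.
deriveSeed <- function(master_seed, tag) {
    h <- 0
    for (cp in utf8ToInt(tag)) h <- (h * 31 + cp) %% 2147483647
    as.integer((as.numeric(master_seed) * 69069 + h + 1) %% 2147483647)
}

# Uniform integer draws via runif, independent of sample()'s algorithm
# version settings.
runifInt <- function(n, lo, hi) {
    lo + floor(stats::runif(n) * (hi - lo + 1))
}
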