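# Evaluate `code` under a temporary RNG state seeded with `seed`,
# restoring the caller's state afterwards. seed = NULL leaves the RNG alone.
.withSeed <- function(seed, code) {
  if (is.null(seed)) return(code)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    stats::runif(1)
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  code
}

# Deterministic child seeds below 2^31 derived from one master seed.
.childSeeds <- function(seed, n) {
  .withSeed(seed, sample.int(.Machine$integer.max, n))
}
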