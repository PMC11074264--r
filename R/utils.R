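# Internal helpers shared across modules.

# Run `expr` under a local Mersenne-Twister stream seeded with `seed`,
# restoring the caller's RNG state afterwards so package functions never
# perturb user-level reproducibility.
withLocalSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed), kind = "Mersenne-Twister", normal.kind = "Inversion")
  expr
}

stopIfNot <- function(cond, msg, call. = FALSE) {
  if (!isTRUE(cond)) stop(msg, call. = call.)
  invisible(TRUE)
}

# md5 of a canonical serialization; used for report provenance.
hashObject <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  con <- file(f, "wb")
  serialize(x, con, version = 2L)
  close(con)
  unname(tools::md5sum(f))
}

softplus <- function(x) {
  # overflow-safe log(1 + exp(x))
  ifelse(x > 30, x, log1p(exp(x)))
}

softplusInv <- function(y) {
  # inverse of softplus for y > 0
  ifelse(y > 30, y, log(expm1(y)))
}

sigmoid <- function(x) 1 / (1 + exp(-x))

matchDimension <- function(dimension) {
  match.arg(dimension, c("valence", "arousal"))
}
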