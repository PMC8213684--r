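# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv()),
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  force(code)
}

# Draw from a normal distribution truncated to [lower, upper] by
# reject-and-redraw, so no point mass accumulates at the bounds.
rnorm_trunc <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  if (sd == 0) {
    if (any(mean < lower | mean > upper))
      stop("degenerate truncated normal: mean outside bounds with sd = 0")
    return(rep(mean, length.out = n))
  }
  out <- stats::rnorm(n, mean, sd)
  bad <- which(out < lower | out > upper)
  while (length(bad) > 0L) {
    out[bad] <- stats::rnorm(length(bad), mean[
      if (length(mean) > 1L) bad else 1L], sd)
    bad <- which(out < lower | out > upper)
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Location parameter whose [lower, upper]-truncated normal has the target
# mean, so configured means are reproduced exactly in expectation.
trunc_adjusted_location <- function(target, sd, lower, upper) {
  if (sd == 0) return(target)
  tmean <- function(mu) {
    al <- (lower - mu) / sd
    be <- (upper - mu) / sd
    z <- stats::pnorm(be) - stats::pnorm(al)
    mu + sd * (stats::dnorm(al) - stats::dnorm(be)) / z
  }
  vapply(target, function(tg) {
    stats::uniroot(function(mu) tmean(mu) - tg,
                   interval = c(tg - 6 * sd, tg + 6 * sd),
                   tol = 1e-10)$root
  }, 0)
}
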