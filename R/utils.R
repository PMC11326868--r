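# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(code)
}

# Normal draws truncated below at `lower` (resampling; adequate for the
# mildly truncated amplitude/kinetic distributions used here).
rnorm_trunc <- function(n, mean, sd, lower = 0) {
  if (sd == 0) return(rep(mean, n))
  x <- rnorm(n, mean, sd)
  bad <- which(x <= lower)
  guard <- 0L
  while (length(bad) > 0 && guard < 100L) {
    x[bad] <- rnorm(length(bad), mean, sd)
    bad <- bad[x[bad] <= lower]
    guard <- guard + 1L
  }
  x[x <= lower] <- lower + abs(mean - lower) * 1e-3
  x
}

stop_field <- function(field, msg) {
  abort(sprintf("invalid `%s`: %s", field, msg), class = "mocsyn_validation_error")
}

check_field <- function(ok, field, msg) {
  if (!isTRUE(ok)) stop_field(field, msg)
  invisible(TRUE)
}
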