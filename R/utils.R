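#' @keywords internal
"_PACKAGE"

# Pressure unit conversion; 1 mmHg = 133.322 Pa.
MMHG_TO_PA <- 133.322

#' Evaluate an expression under a temporary RNG seed
#'
#' Runs `expr` with the global RNG seeded to `seed`, then restores the previous
#' RNG state so callers' random streams are unaffected.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# Truncated normal draws by rejection; sd = 0 degenerates to the mean
# (which must itself satisfy the bounds).
rtruncnorm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  mean <- rep_len(mean, n)
  sd <- rep_len(sd, n)
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x < lower | x > upper)
  it <- 0L
  while (length(bad) > 0L) {
    it <- it + 1L
    if (it > 1000L) stop("truncated-normal rejection failed to converge")
    x[bad] <- stats::rnorm(length(bad), mean[bad], sd[bad])
    bad <- bad[x[bad] < lower | x[bad] > upper]
  }
  deg <- sd == 0 & (mean < lower | mean > upper)
  if (any(deg)) stop("degenerate (sd = 0) draw outside truncation bounds")
  x
}

stop_if_not_positive <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x <= 0)) {
    stop(sprintf("`%s` must be positive and finite", name), call. = FALSE)
  }
  invisible(x)
}
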