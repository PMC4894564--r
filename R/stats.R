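# Cohort-level statistics: age x genotype linear models, the two-covariate
# rigidity model, Pearson correlations, paired comparisons and group
# summaries.

cohort_lm_terms <- function(fit) {
  s <- suppressWarnings(summary(fit))$coefficients
  data.frame(
    name = rownames(s),
    coefficient = s[, 1],
    se = s[, 2],
    p = s[, 4],
    row.names = NULL
  )
}

#' Age x genotype linear model for a per-eye property
#'
#' Ordinary least squares of a property on age and genotype group. With
#' `interaction = TRUE` the model includes the age:group interaction, from
#' which per-group intercepts and slopes are derived (these equal separate
#' per-group OLS fits exactly). The group main-effect p-value is always
#' reported from the additive model (group contrast with age as a covariate,
#' the published table layout).
#'
#' @param y Per-eye property values.
#' @param age Ages in months.
#' @param group Two-level factor or character (e.g. affected/normal).
#' @param interaction Include the age x group interaction (default `TRUE`).
#' @return A `cohort_lm` list: `terms` (coefficient table), `group_lines`
#'   (per-group intercept/slope, when interaction requested), `group_p`,
#'   `group_effect` (adjusted contrast, second level minus first), `r`
#'   (Pearson correlation of y with age, pooled), `n`, and the underlying
#'   `lm` fits.
#' @export
fit_age_genotype <- function(y, age, group, interaction = TRUE) {
  if (anyNA(y) || anyNA(age) || anyNA(group)) {
    stop("missing values in response or covariates", call. = FALSE)
  }
  group <- factor(group)
  if (nlevels(group) != 2) stop("group must have exactly two levels", call. = FALSE)
  if (interaction && any(table(group) < 3)) {
    stop("need at least 3 eyes per group for the interaction model", call. = FALSE)
  }
  dat <- data.frame(y = y, age = age, group = group)
  additive <- stats::lm(y ~ age + group, data = dat)
  fit <- if (interaction) stats::lm(y ~ age * group, data = dat) else additive
  if (fit$rank < length(stats::coef(fit))) {
    stop("rank-deficient design: covariates are confounded", call. = FALSE)
  }
  group_lines <- NULL
  if (interaction) {
    cf <- stats::coef(fit)
    lev <- levels(group)
    group_lines <- data.frame(
      group = lev,
      intercept = c(cf[1], cf[1] + cf[3]),
      slope = c(cf[2], cf[2] + cf[4]),
      row.names = NULL
    )
  }
  add_s <- suppressWarnings(summary(additive))$coefficients
  structure(
    list(
      terms = cohort_lm_terms(fit),
      group_lines = group_lines,
      group_p = add_s[3, 4],
      group_effect = add_s[3, 1],
      r = stats::cor(y, age),
      n = nrow(dat),
      lm = fit, lm_additive = additive
    ),
    class = "cohort_lm"
  )
}

#' Two-covariate model of normalized ocular rigidity on age and last IOP
#'
#' OLS of `k_norm ~ age + last_iop`, the affected-group model relating
#' normalized rigidity to age and the last measured IOP.
#'
#' @param k_norm Normalized ocular rigidity values.
#' @param age Ages in months.
#' @param last_iop Last measured IOP in mmHg.
#' @return A `cohort_lm` with `terms` in (intercept, age, last_iop) order.
#' @export
fit_rigidity_model <- function(k_norm, age, last_iop) {
  if (anyNA(k_norm) || anyNA(age) || anyNA(last_iop)) {
    stop("missing values in response or covariates", call. = FALSE)
  }
  dat <- data.frame(k_norm = k_norm, age = age, last_iop = last_iop)
  fit <- stats::lm(k_norm ~ age + last_iop, data = dat)
  if (fit$rank < 3) stop("rank-deficient design", call. = FALSE)
  structure(
    list(terms = cohort_lm_terms(fit), n = nrow(dat), lm = fit),
    class = "cohort_lm"
  )
}

#' Pearson correlation with a two-sided p-value
#'
#' @param x,y Finite numeric vectors of equal length (n >= 3).
#' @return A list with `r`, `p` (two-sided, from the t transform), `n`.
#' @export
pearson <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3) {
    stop("need paired vectors of length >= 3", call. = FALSE)
  }
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    stop("non-finite values", call. = FALSE)
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("undefined correlation: zero variance", call. = FALSE)
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Paired t-test between two repeated measurements
#'
#' @param a,b Equal-length paired vectors (n >= 2).
#' @return A list with `t`, `p`, `mean_difference` (a - b), `n`.
#' @export
paired_ttest <- function(a, b) {
  if (length(a) != length(b) || length(a) < 2) {
    stop("need equal-length paired vectors with n >= 2", call. = FALSE)
  }
  d <- a - b
  if (stats::sd(d) == 0) {
    # degenerate: all differences identical
    return(list(t = if (mean(d) == 0) 0 else Inf * sign(mean(d)),
                p = if (mean(d) == 0) 1 else 0,
                mean_difference = mean(d), n = length(a)))
  }
  tt <- stats::t.test(a, b, paired = TRUE)
  list(t = unname(tt$statistic), p = tt$p.value,
       mean_difference = unname(tt$estimate), n = length(a))
}

#' Per-group mean and SD summary of a cohort property
#'
#' @param data A data frame (e.g. a `cohort_table` or analyzer results).
#' @param property Column name to summarise.
#' @param group Column name of the grouping factor (default `"group"`).
#' @return A data frame with columns `group`, `n`, `mean`, `sd`.
#' @export
group_summary <- function(data, property, group = "group") {
  g <- factor(data[[group]])
  if (any(table(g) == 0)) stop("empty group", call. = FALSE)
  x <- data[[property]]
  if (is.null(x)) stop(sprintf("no column `%s`", property), call. = FALSE)
  out <- data.frame(
    group = levels(g),
    n = as.integer(table(g)),
    mean = as.numeric(tapply(x, g, mean)),
    sd = as.numeric(tapply(x, g, stats::sd)),
    row.names = NULL
  )
  out
}

#' Lifetime and interval-weighted IOP summaries
#'
#' `mean_iop` is the arithmetic mean of all readings; `weighted_iop` is the
#' mean over the last `window` months weighted by the interval between
#' consecutive readings (readings were not taken at regular intervals).
#'
#' @param age Ages (months) at which IOP was read, increasing.
#' @param iop IOP readings in mmHg.
#' @param window Look-back window in months (default 24).
#' @return A list with `mean_iop` and `weighted_iop`.
#' @export
iop_summaries <- function(age, iop, window = 24) {
  stopifnot(length(age) == length(iop), length(age) >= 1, !is.unsorted(age))
  mean_iop <- mean(iop)
  cutoff <- age[length(age)] - window
  idx <- which(age >= cutoff)
  weighted_iop <- if (length(idx) < 2) {
    iop[length(iop)]
  } else {
    a <- age[idx]
    v <- iop[idx]
    w <- diff(a)
    mid <- (v[-1] + v[-length(v)]) / 2
    sum(mid * w) / sum(w)
  }
  list(mean_iop = mean_iop, weighted_iop = weighted_iop)
}

#' @export
print.cohort_lm <- function(x, ...) {
  cat("Cohort linear model (n =", x$n, ")\n")
  print(x$terms, digits = 4)
  if (!is.null(x$group_lines)) {
    cat("Per-group lines:\n")
    print(x$group_lines, digits = 4)
  }
  if (!is.null(x$group_p)) {
    cat(sprintf("Group contrast (age-adjusted): %.4g, p = %.4g\n",
                x$group_effect, x$group_p))
  }
  invisible(x)
}

#' @export
coef.cohort_lm <- function(object, ...) {
  stats::setNames(object$terms$coefficient, object$terms$name)
}

#' @export
summary.cohort_lm <- function(object, ...) {
  summary(object$lm, ...)
}
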