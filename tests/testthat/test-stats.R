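test_that("noise-free cohorts are fit exactly by the age-genotype model", {
  lines <- reference_age_lines()
  set.seed(5)
  age <- runif(60, 5, 131)
  group <- rep(c("affected", "normal"), 30)
  y <- numeric(60)
  for (g in c("affected", "normal")) {
    l <- lines[lines$property == "E_star" & lines$group == g, ]
    y[group == g] <- l$intercept + l$slope * age[group == g]
  }
  fit <- fit_age_genotype(y, age, group)
  for (g in c("affected", "normal")) {
    l <- lines[lines$property == "E_star" & lines$group == g, ]
    gl <- fit$group_lines[fit$group_lines$group == g, ]
    expect_equal(gl$intercept, l$intercept, tolerance = 1e-10)
    expect_equal(gl$slope, l$slope, tolerance = 1e-10)
  }
})

test_that("interaction-model group lines equal separate per-group OLS fits", {
  set.seed(6)
  age <- runif(80, 5, 131)
  group <- sample(c("affected", "normal"), 80, replace = TRUE)
  y <- 2 + 0.05 * age + 0.4 * (group == "normal") + rnorm(80)
  fit <- fit_age_genotype(y, age, group)
  for (g in c("affected", "normal")) {
    sep <- coef(lm(y[group == g] ~ age[group == g]))
    gl <- fit$group_lines[fit$group_lines$group == g, ]
    expect_equal(gl$intercept, unname(sep[1]), tolerance = 1e-12)
    expect_equal(gl$slope, unname(sep[2]), tolerance = 1e-12)
  }
})

test_that("the rigidity plane is recovered exactly without noise and by sign with noise", {
  plane <- reference_rigidity_plane()
  set.seed(7)
  age <- runif(2000, 10, 130)
  iop <- runif(2000, 10, 80)
  k <- plane["intercept"] + plane["age"] * age + plane["last_iop"] * iop
  fit <- fit_rigidity_model(k, age, iop)
  expect_equal(unname(coef(fit)), unname(plane), tolerance = 1e-9)
  # with noise the IOP coefficient stays negative and within 2 SE
  k2 <- k + rnorm(2000, 0, 14)
  fit2 <- fit_rigidity_model(k2, age, iop)
  iop_row <- fit2$terms[fit2$terms$name == "last_iop", ]
  expect_lt(iop_row$coefficient, 0)
  expect_lt(abs(iop_row$coefficient - plane["last_iop"]), 2 * iop_row$se)
})

test_that("pearson matches its definition and nulls out for independent data", {
  x <- 1:20
  expect_equal(pearson(x, 2 * x)$r, 1)
  set.seed(8)
  null <- pearson(rnorm(10000), rnorm(10000))
  expect_lt(abs(null$r), 0.03)
  expect_error(pearson(rep(1, 10), 1:10), "zero variance")
  expect_error(pearson(1:2, 1:2), "3")
})

test_that("paired t-test handles identity and separated pairs", {
  a <- c(1, 2, 3, 4)
  res <- paired_ttest(a, a)
  expect_equal(res$t, 0)
  expect_equal(res$p, 1)
  # anterior thinner than posterior by an offset far above noise
  set.seed(9)
  post <- rnorm(20, 0.49, 0.02)
  ant <- post - 0.18 + rnorm(20, 0, 0.02)
  res2 <- paired_ttest(ant, post)
  expect_lt(res2$p, 0.001)
  expect_lt(res2$mean_difference, 0)
  expect_error(paired_ttest(1, 1), "n >= 2")
})

test_that("group summaries report per-group mean and SD", {
  d <- data.frame(group = rep(c("affected", "normal"), each = 4),
                  E_star = rep(5, 8))
  s <- group_summary(d, "E_star")
  expect_equal(s$mean, c(5, 5))
  expect_equal(s$sd, c(0, 0))
  expect_equal(s$n, c(4L, 4L))
  expect_error(group_summary(d, "nope"))
  # layout columns as in the published summary table
  co <- generate_cohort(15, 10, seed = 2)
  for (p in c("thickness_post", "E_star", "tan_delta", "AB", "B")) {
    expect_true(all(c("group", "n", "mean", "sd") %in%
                      names(group_summary(co, p))))
  }
})

test_that("IOP summaries weight by measurement interval over the window", {
  age <- c(10, 20, 30, 34, 36)
  iop <- c(15, 17, 25, 35, 45)
  s <- iop_summaries(age, iop, window = 24)
  expect_equal(s$mean_iop, mean(iop))
  # window cutoff 12: readings at 20, 30, 34, 36; trapezoid weights
  w <- c(10, 4, 2)
  mids <- c((17 + 25) / 2, (25 + 35) / 2, (35 + 45) / 2)
  expect_equal(s$weighted_iop, sum(mids * w) / sum(w))
  # single reading in window falls back to the last value
  expect_equal(iop_summaries(c(1, 50), c(12, 20), window = 10)$weighted_iop, 20)
})

test_that("degenerate designs produce informative errors", {
  expect_error(fit_age_genotype(1:6, 1:6, rep("a", 6)), "two levels")
  expect_error(fit_age_genotype(c(1, 2, NA), 1:3, c("a", "b", "a")), "missing")
  expect_error(fit_rigidity_model(1:5, 1:5, 1:5), "rank")
})
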