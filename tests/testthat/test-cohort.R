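test_that("zero residual noise puts every property exactly on its group line", {
  cfg <- zero_noise_config()
  co <- generate_cohort(40, 30, seed = 3, config = cfg)
  lines <- reference_age_lines()
  for (g in c("affected", "normal")) {
    rows <- co[co$group == g, ]
    for (prop in c("E_star", "tan_delta", "AB")) {
      l <- lines[lines$property == prop & lines$group == g, ]
      expect_equal(rows[[prop]], l$intercept + l$slope * rows$age,
                   tolerance = 1e-12)
    }
    # affected eye at 38.4 months sits at 3.574 + 0.05676 * 38.4 = 5.754 MPa
    if (g == "affected") {
      l <- lines[lines$property == "E_star" & lines$group == g, ]
      expect_equal(l$intercept + l$slope * 38.4, 5.754, tolerance = 1e-3)
    }
  }
  # B and thickness decline with age
  aff <- co[co$group == "affected", ]
  expect_lt(cor(aff$B, aff$age), -0.99)
  expect_lt(cor(aff$thickness_post, aff$age), -0.99)
})

test_that("cohort generation is deterministic for a fixed seed and config", {
  c1 <- generate_cohort(10, 5, seed = 123)
  c2 <- generate_cohort(10, 5, seed = 123)
  expect_identical(as.data.frame(c1), as.data.frame(c2))
  c3 <- generate_cohort(10, 5, seed = 124)
  expect_false(identical(c1$E_star, c3$E_star))
  # requested sizes honored
  expect_equal(sum(c1$group == "affected"), 10)
  expect_equal(sum(c1$group == "normal"), 5)
  expect_error(generate_cohort(0, 5), "at least 1")
})

test_that("generated truth satisfies its physical invariants", {
  co <- generate_cohort(300, 200, seed = 8)
  expect_true(all(co$E_star > 0))
  expect_true(all(co$tan_delta > 0 & co$tan_delta < 1))
  expect_true(all(co$A > 0 & co$B > 0))
  expect_equal(co$AB, co$A * co$B, tolerance = 1e-12)
  expect_true(all(co$K > 0))
  expect_true(all(co$Rc_15 <= 0))
  expect_true(all(co$age > 0 & co$last_iop > 0))
  expect_equal(co$v0, (pi / 6) * co$axial * co$nt * co$si, tolerance = 1e-12)
  expect_equal(co$k_norm, co$K * co$v0, tolerance = 1e-9)
})

test_that("IOP trajectories separate affected and normal groups", {
  # normal eyes stay within the normotensive band at any age
  h_norm <- generate_iop_history(list(group = "normal", age = 90), seed = 4)
  expect_true(all(h_norm$iop >= 8 & h_norm$iop <= 16))
  expect_equal(h_norm$last_iop, h_norm$iop[length(h_norm$iop)])
  # pre-onset affected eye sits near baseline (e.g. 5.6 months, ~16 mmHg)
  h_pre <- generate_iop_history(list(group = "affected", age = 5.6), seed = 4)
  expect_lt(abs(h_pre$last_iop - 16), 5)
  # affected last IOP rises with age across a large cohort
  co <- generate_cohort(2000, 2, seed = 9)
  aff <- co[co$group == "affected", ]
  expect_gt(cor(aff$age, aff$last_iop), 0.5)
  # and an old affected eye exceeds the normotensive band on average
  old <- aff[aff$age > 80, ]
  expect_gt(mean(old$last_iop), 30)
})

test_that("raw-record bundles are deterministic and close under zero noise", {
  co <- generate_cohort(3, 2, seed = 21)
  truth <- co[2, ]
  b1 <- render_raw_records(truth, seed = 6)
  b2 <- render_raw_records(truth, seed = 6)
  expect_identical(b1$infusion$iop, b2$infusion$iop)
  expect_identical(b1$ramp$stress, b2$ramp$stress)
  expect_identical(b1$dma[[1]]$stress, b2$dma[[1]]$stress)
  a <- analyze_bundle(b1, v0 = truth$v0)
  expect_equal(a$E_star, truth$E_star, tolerance = 1e-4)
  expect_equal(a$tan_delta, truth$tan_delta, tolerance = 1e-4)
  expect_equal(a$A, truth$A, tolerance = 1e-4)
  expect_equal(a$B, truth$B, tolerance = 1e-4)
  expect_equal(a$K, truth$K, tolerance = 1e-4)
  expect_equal(a$k_norm, truth$k_norm, tolerance = 1e-4)
})

test_that("the analyzer chain recovers the cohort E* mean under realistic noise", {
  co <- generate_cohort(200, 2, seed = 31)
  aff <- co[co$group == "affected", ]
  rec <- vapply(seq_len(nrow(aff)), function(i) {
    s <- simulate_dma(E_star = aff$E_star[i], delta = atan(aff$tan_delta[i]),
                      frequency = 1,
                      noise_sd = 0.02 * aff$E_star[i] * 0.0015,
                      seed = 500 + i)
    attr(s, "preload_N") <- 0.04
    viscoelastic_params(s)$E_star
  }, numeric(1))
  expect_lt(abs(mean(rec) - mean(aff$E_star)) / mean(aff$E_star), 0.02)
})

test_that("cohort slope estimates converge to the configured lines", {
  co <- generate_cohort(3000, 2000, seed = 17)
  fit <- fit_age_genotype(co$E_star, co$age, co$group)
  lines <- reference_age_lines()
  for (g in c("affected", "normal")) {
    truth_slope <- lines$slope[lines$property == "E_star" & lines$group == g]
    est <- fit$group_lines$slope[fit$group_lines$group == g]
    # within 2 SE of the single largest-variance coefficient
    se <- max(fit$terms$se[grepl("age", fit$terms$name)])
    expect_lt(abs(est - truth_slope), 2 * se + 1e-4)
  }
  # group contrast direction: affected E* lower at matched ages, so the
  # age-adjusted normal-minus-affected effect is positive
  expect_gt(fit$group_effect, 0)
})
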