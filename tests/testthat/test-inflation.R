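test_that("strain-tensor rotation matches the closed form and preserves trace", {
  # identity at zero orientation
  r0 <- to_tissue_strains(0.01, -0.004)
  expect_equal(r0$radial_strain, 0.01)
  expect_equal(r0$tangential_strain, -0.004)
  # quarter turn swaps the roles
  r90 <- to_tissue_strains(0.01, -0.004, orientation = pi / 2)
  expect_equal(r90$tangential_strain, 0.01, tolerance = 1e-12)
  expect_equal(r90$radial_strain, -0.004, tolerance = 1e-12)
  # 30 degrees, pure axial strain
  r30 <- to_tissue_strains(0.01, 0, orientation = pi / 6)
  expect_equal(r30$tangential_strain, 0.0025, tolerance = 1e-12)
  expect_equal(r30$radial_strain, 0.0075, tolerance = 1e-12)
  # trace preserved for random cases, including shear
  set.seed(4)
  for (i in 1:20) {
    ax <- runif(1, -0.02, 0.02)
    lat <- runif(1, -0.02, 0.02)
    sh <- runif(1, -0.01, 0.01)
    th <- runif(1, 0, pi)
    tis <- to_tissue_strains(ax, lat, sh, th)
    expect_equal(tis$tangential_strain + tis$radial_strain, ax + lat,
                 tolerance = 1e-14)
  }
  # zero-shear round trip: tissue-frame shear is (ax - lat) sin cos, and
  # rotating back with it recovers the beam-aligned strains
  for (i in 1:10) {
    ax <- runif(1, -0.02, 0.02)
    lat <- runif(1, -0.02, 0.02)
    th <- runif(1, 0, pi)
    tis <- to_tissue_strains(ax, lat, 0, th)
    sh_tis <- (ax - lat) * sin(th) * cos(th)
    back <- from_tissue_strains(tis$tangential_strain, tis$radial_strain,
                                shear = sh_tis, orientation = th)
    expect_equal(back$axial_strain, ax, tolerance = 1e-12)
    expect_equal(back$lateral_strain, lat, tolerance = 1e-12)
  }
})

test_that("the synthetic speckle pair is deterministic and flags sparse fields", {
  p1 <- simulate_speckle_pair(axial_strain = 0.01, lateral_strain = 0, seed = 9)
  p2 <- simulate_speckle_pair(axial_strain = 0.01, lateral_strain = 0, seed = 9)
  expect_identical(p1$pre, p2$pre)
  expect_identical(p1$post, p2$post)
  expect_true(p1$developed_speckle)
  sparse <- simulate_speckle_pair(axial_strain = 0, lateral_strain = 0,
                                  scatterer_density = 500, seed = 9)
  expect_false(sparse$developed_speckle)
  # zero strain: pre and post identical
  z <- simulate_speckle_pair(axial_strain = 0, lateral_strain = 0, seed = 9)
  expect_equal(z$pre, z$post, tolerance = 1e-12)
  expect_error(simulate_speckle_pair(axial_strain = 0.2, lateral_strain = 0),
               "small")
})

test_that("block matching recovers rigid shifts to sub-sample precision", {
  pair <- simulate_speckle_pair(axial_strain = 0, lateral_strain = 0, seed = 5)
  n <- nrow(pair$pre)
  # integer 3-sample axial shift
  p_int <- pair
  p_int$post <- rbind(matrix(0, 3, ncol(pair$pre)), pair$pre[1:(n - 3), ])
  f <- track_displacement(p_int)
  expect_true(all(f$valid))
  expect_equal(mean(f$axial_disp) / pair$dz_mm, 3, tolerance = 0.01)
  expect_gt(min(f$correlation), 0.99)
  # fractional 2.5-sample shift via band-limited resampling
  p_frac <- pair
  p_frac$post <- apply(pair$pre, 2, function(col) {
    approx(seq_len(n), col, xout = seq_len(n) + 2.5, rule = 2)$y
  })
  f2 <- track_displacement(p_frac, compand = FALSE)
  expect_equal(-mean(f2$axial_disp, na.rm = TRUE) / pair$dz_mm, 2.5,
               tolerance = 0.1)
})

test_that("decorrelated frames are flagged invalid rather than tracked", {
  pa <- simulate_speckle_pair(axial_strain = 0, lateral_strain = 0, seed = 7)
  pb <- simulate_speckle_pair(axial_strain = 0, lateral_strain = 0, seed = 8)
  pa$post <- pb$pre
  f <- track_displacement(pa)
  expect_lt(mean(f$valid), 0.5)
})

test_that("least-squares strain is exact for affine displacement fields", {
  f <- make_affine_field(0.01, -0.004)
  s <- ls_strain(f, strain_kernel = 5)
  expect_equal(max(abs(s$axial_strain - 0.01)), 0, tolerance = 1e-12)
  expect_equal(max(abs(s$lateral_strain + 0.004)), 0, tolerance = 1e-12)
  # zero displacement gives zero strain
  f0 <- make_affine_field(0, 0)
  s0 <- ls_strain(f0)
  expect_equal(max(abs(s0$axial_strain)), 0)
  # invalid nodes are excluded; isolated valid pairs yield NA
  f$valid[, 3] <- FALSE
  s2 <- ls_strain(f, strain_kernel = 5)
  expect_equal(median(s2$axial_strain[, 1], na.rm = TRUE), 0.01,
               tolerance = 1e-12)
})

test_that("wider strain kernels suppress displacement noise like 1/sqrt(k)", {
  set.seed(12)
  sd9 <- sd3 <- numeric(60)
  for (i in 1:60) {
    f <- make_affine_field(0.01, 0, n_z = 41, noise_sd = 1e-4)
    s9 <- ls_strain(f, strain_kernel = 9)
    # 3-node kernel as the near-finite-difference oracle
    s3 <- ls_strain(f, strain_kernel = 3)
    sd9[i] <- sd(s9$axial_strain[, 1], na.rm = TRUE)
    sd3[i] <- sd(s3$axial_strain[, 1], na.rm = TRUE)
  }
  ratio <- mean(sd9) / mean(sd3)
  # noise reduction of roughly sqrt(3/9), allowing edge effects
  expect_lt(ratio, 0.75)
})

test_that("tracking plus strain estimation recovers prescribed affine deformations", {
  cases <- list(c(0.01, -0.004), c(-0.006, 0.012), c(0.015, 0.005))
  for (i in seq_along(cases)) {
    pair <- simulate_speckle_pair(axial_strain = cases[[i]][1],
                                  lateral_strain = cases[[i]][2],
                                  seed = 20 + i)
    f <- track_displacement(pair)
    s <- ls_strain(f)
    expect_lt(abs(median(s$axial_strain, na.rm = TRUE) - cases[[i]][1]), 5e-4)
    expect_lt(abs(median(s$lateral_strain, na.rm = TRUE) - cases[[i]][2]), 5e-4)
  }
})

test_that("the default pressure schedule matches the inflation protocol", {
  sch <- inflation_schedule()
  expect_equal(sch[1], 5)
  expect_equal(sum(sch > 5 & sch <= 20), 30)  # 0.5 mmHg steps to 20
  expect_equal(sch[sch > 20 & sch <= 30], c(22.5, 25, 27.5, 30))
  expect_equal(tail(sch, 3), c(35, 40, 45))
  expect_true(15 %in% sch)
})

test_that("an inflation series closes on linear truth and preserves sign", {
  res <- inflation_series(list(tangential_15 = 0.01, radial_15 = -0.005),
                          schedule = seq(5, 15, by = 2.5), seed = 2)
  expect_false(res$tracking_failed)
  expect_lt(abs(res$tangential_15 - 0.01), 1.5e-3)
  expect_lt(abs(res$radial_15 - (-0.005)), 1.5e-3)
  expect_lt(res$radial_15, 0)  # compressive radial strain stays negative
  expect_true(all(res$invalid_fraction <= 0.2))
})
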