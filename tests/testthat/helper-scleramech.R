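# Shared fixtures built in code.

# A small displacement field object with a prescribed affine truth plus
# optional Gaussian noise, for exercising the strain estimator without RF
# synthesis.
make_affine_field <- function(eps_ax, eps_lat, n_z = 15, n_x = 11,
                              dz = 0.05, dx = 0.04, noise_sd = 0,
                              seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  z <- (seq_len(n_z) - 1) * dz
  x <- (seq_len(n_x) - 1) * dx
  u_ax <- outer(eps_ax * z, rep(1, n_x))
  u_lat <- outer(rep(1, n_z), eps_lat * x)
  if (noise_sd > 0) {
    u_ax <- u_ax + matrix(rnorm(n_z * n_x, 0, noise_sd), n_z, n_x)
    u_lat <- u_lat + matrix(rnorm(n_z * n_x, 0, noise_sd), n_z, n_x)
  }
  structure(
    list(z_mm = z, x_mm = x, axial_disp = u_ax, lateral_disp = u_lat,
         correlation = matrix(1, n_z, n_x),
         valid = matrix(TRUE, n_z, n_x)),
    class = "displacement_field"
  )
}

# Zero out every stochastic component of a cohort config so generated
# properties sit exactly on their group lines.
zero_noise_config <- function(config = default_cohort_config()) {
  for (g in c("affected", "normal")) {
    for (p in names(config$properties[[g]])) {
      config$properties[[g]][[p]][["sd"]] <- 0
    }
  }
  config$iop$baseline_affected_sd <- 0
  config$iop$rise_sd <- 0
  config$iop$normal_sd <- 0
  config$iop$max_extra_sd <- 0
  config$rigidity$affected_sd <- 0
  config$rigidity$normal_sd <- 0
  for (l in names(config$strain_links)) config$strain_links[[l]]$sigma <- 0
  config
}
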