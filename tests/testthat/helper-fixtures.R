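# shared fixtures built in code

# digitized ball mask of radius r (mm) on an isotropic grid
digitized_ball <- function(r, dims = c(48, 48, 48), spacing = 0.5,
                           center = dims * spacing / 2) {
  P <- aneumorph:::voxel_centers(dims, rep(spacing, 3))
  new_volume(array(as.integer(rowSums(sweep(P, 2, center)^2) <= r^2), dims),
             spacing)
}

# one rendered noise-free phantom with fixed geometry (R = 4, h = 6)
reference_phantom <- function(noise_sd = 0) {
  spec <- sample_phantom_spec(1, phantom_cohort_config(noise_sd = noise_sd),
                              seed = 101)
  spec$sphere_radius <- 4
  spec$cap_height <- 6
  spec$vessel_radius <- 2
  render_phantom(spec)
}

# small tabular coil cohort from analytic phantom morphometry
coil_cohort <- function(n = 153, seed = 3, noise_sd = 0.25) {
  spec <- sample_phantom_spec(n, seed = seed)
  tab <- analytic_morphometry(spec)
  tab$coil_mm <- assign_first_coil(tab, seed = seed + 1, noise_sd = noise_sd)
  tab
}

# independent ICC(2,1) oracle from aov() mean squares
icc_oracle <- function(x, y) {
  n <- length(x)
  d <- data.frame(y = c(x, y),
                  subj = factor(rep(seq_len(n), 2)),
                  rater = factor(rep(1:2, each = n)))
  ms <- summary(stats::aov(y ~ subj + rater, data = d))[[1]][["Mean Sq"]]
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  (msr - mse) / (msr + mse + 2 * (msc - mse) / n)
}
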