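# Shared fixture builders. Profiles and images are generated in code; no
# binary fixtures live on disk.

water <- list(drho = 1000, g = 9.81)

# Forward-model pendant profile for a known surface tension.
make_pendant_truth <- function(gamma, apex_radius, arc_factor = 3) {
  bond <- water$drho * water$g * apex_radius^2 / gamma
  integrate_drop_profile(bond, apex_radius,
                         arc_length_max = arc_factor * apex_radius)
}

# Seeded horizontal edge jitter (z stays exact: it comes from pixel rows).
jitter_profile_x <- function(profile, sigma, seed) {
  withr::with_seed(seed, {
    x <- profile$x + rnorm(length(profile$x), 0, sigma)
  })
  x[1] <- 0
  drop_profile(pmax(x, 0), profile$z, orientation = profile$orientation)
}

# Ramp-plateau trajectory sampled like the camera would.
make_ramp_trajectory <- function(h_max, t_start, t_end, total_hours = 24,
                                 interval_min = 2) {
  t <- seq(0, total_hours, by = interval_min / 60)
  h <- pmin(pmax(t - t_start, 0) * h_max / (t_end - t_start), h_max)
  tip_trajectory(t, h, frame_interval_min = interval_min)
}
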