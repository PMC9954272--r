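# fixture builders: hand-constructed trajectory logs

# linear interpolation path with n samples from `from` to `to` (inclusive)
straight_path <- function(from, to, n) {
  data.frame(x = seq(from[1], to[1], length.out = n),
             y = seq(from[2], to[2], length.out = n))
}

make_log <- function(samples, events = NULL, scene = default_scene(),
                     id = "fixture") {
  if (is.null(events))
    events <- data.frame(cube_id = character(), sample_index = integer())
  trajectory_log(id, scene, samples, events)
}

# a path with a given y-profile at constant x
y_path <- function(y, x = 1280) data.frame(x = rep(x, length(y)), y = y)

# random agent profile spanning the plausible knob ranges
random_profile <- function() {
  agent_profile(max_accel_px_s2 = runif(1, 300, 900),
                damping_per_s = runif(1, 1.2, 2.5),
                steering_noise_sd_rad = runif(1, 0.1, 0.9),
                replan_interval_s = 0.25,
                detour_prob = runif(1, 0, 0.15),
                dwell_above_s = runif(1, 0, 4))
}

# fast, precise profile for I/O round-trip fixtures
fast_profile <- function()
  agent_profile(max_accel_px_s2 = 1600, damping_per_s = 2.8,
                steering_noise_sd_rad = 0.25, detour_prob = 0)

# cohort with one planted informative marker (target AUC on the latent
# scale) plus independent null markers
make_selection_cohort <- function(seed, n = 200, informative_auc = 0.8,
                                  n_noise = 7) {
  sigma <- 0.3
  dmu <- qnorm(informative_auc) * sigma * sqrt(2)
  f <- exp(qnorm(0.75) * sigma)
  vars <- list(signal = spec_variable("lognormal",
                                      NC = c(1, 1 / f, f),
                                      MCI = exp(dmu) * c(1, 1 / f, f)))
  for (k in seq_len(n_noise))
    vars[[paste0("noise", k)]] <- spec_variable("lognormal",
                                                NC = c(1, 1 / f, f),
                                                MCI = c(1, 1 / f, f))
  sample_cohort(cohort_spec(vars, c(NC = n, MCI = n)), seed = seed)
}
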