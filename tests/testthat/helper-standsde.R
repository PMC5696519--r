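# Shared fixtures: the reference Scots pine configuration and small
# constructors used across the suite.

ref <- scots_pine_params()

# a second, deliberately different parameter set (faster height reversion,
# weaker cross-diffusion) for parameterised sweeps
alt_params <- function() {
  sde_params(alpha_d = 28, beta_d = 0.05, sigma11 = 1.2,
             alpha_h = 20, beta_h = 0.08, sigma22 = 0.5, sigma12 = 0.3)
}

# trees lying exactly on a stand's mean curve (noise-free inventory)
noise_free_stand <- function(params, init, phi, ages, plot_id = "s1") {
  m <- transition_mean(params, ages, phi, init)
  data.frame(plot_id = plot_id, tree_id = sprintf("t%02d", seq_along(ages)),
             age_years = ages, dbh_cm = m$mu_d, height_m = m$mu_h,
             stringsAsFactors = FALSE)
}

# numerical conditional moments of the joint density along a fixed-d slice
slice_moments_h <- function(d, t, params, init, effects = NULL) {
  st <- transition_state(params, t, effects, init)
  lo <- st$mu_h - 10 * sqrt(st$nu_h2); hi <- st$mu_h + 10 * sqrt(st$nu_h2)
  f0 <- stats::integrate(function(h) dtransition(d, h, t, params, effects, init),
                         lo, hi, rel.tol = 1e-10)$value
  f1 <- stats::integrate(function(h) h * dtransition(d, h, t, params, effects,
                                                     init),
                         lo, hi, rel.tol = 1e-10)$value
  m <- f1 / f0
  f2 <- stats::integrate(function(h) (h - m)^2 *
                           dtransition(d, h, t, params, effects, init),
                         lo, hi, rel.tol = 1e-10)$value
  list(m = m, w2 = f2 / f0)
}
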