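#' Mean of the diameter-height transition law
#'
#' Conditional mean of `(D(t), H(t))` given the initial state, for a stand
#' with asymptote shifts `effects`. Each trait follows the Vasicek mean
#' `a + (x0 - a) * exp(-beta * (t - t0))` with stand asymptote
#' `a = alpha + phi`, so the curve starts at the initial size and converges
#' monotonically to the asymptote.
#'
#' @param params An [sde_params] object.
#' @param t Stand age (years), `t >= init$t0`. Vectorised.
#' @param effects Stand random effects ([random_effects] or numeric pair);
#'   default the population-average stand `(0, 0)`.
#' @param init An [initial_state] object.
#' @return A list with numeric components `mu_d` (cm) and `mu_h` (m),
#'   each of length `length(t)`.
#' @examples
#' ref <- scots_pine_params()
#' transition_mean(ref$params, t = c(20, 65, 150), init = ref$init)
#' @export
transition_mean <- function(params, t, effects = NULL, init = initial_state()) {
  stopifnot(inherits(params, "sde_params"), inherits(init, "initial_state"))
  phi <- as_effects(effects)
  if (any(!is.finite(t)) || any(t < init$t0))
    stop_validation("age t must be finite and >= t0 = ", init$t0)
  tau <- t - init$t0
  ad <- params$alpha_d + phi[["phi_d"]]
  ah <- params$alpha_h + phi[["phi_h"]]
  list(mu_d = ad + (init$d0 - ad) * exp(-params$beta_d * tau),
       mu_h = ah + (init$h0 - ah) * exp(-params$beta_h * tau))
}

#' Covariance of the diameter-height transition law
#'
#' Closed-form covariance of `(D(t), H(t))` given the initial state:
#' `nu_d2 = sigma11 * (1 - exp(-2 beta_d tau)) / (2 beta_d)`,
#' `nu_h2` analogously with `sigma22`, `beta_h`, and cross-covariance
#' `nu_dh2 = sigma12 * (1 - exp(-(beta_d + beta_h) tau)) / (beta_d + beta_h)`,
#' with `tau = t - t0`. The covariance does not depend on the random
#' effects, which only shift the mean.
#'
#' @inheritParams transition_mean
#' @return A list with components `nu_d2` (cm^2), `nu_h2` (m^2),
#'   `nu_dh2` (cm*m), each of length `length(t)`.
#' @export
transition_cov <- function(params, t, init = initial_state()) {
  stopifnot(inherits(params, "sde_params"), inherits(init, "initial_state"))
  if (any(!is.finite(t)) || any(t < init$t0))
    stop_validation("age t must be finite and >= t0 = ", init$t0)
  tau <- t - init$t0
  bsum <- params$beta_d + params$beta_h
  list(nu_d2 = params$sigma11 * (1 - exp(-2 * params$beta_d * tau)) /
         (2 * params$beta_d),
       nu_h2 = params$sigma22 * (1 - exp(-2 * params$beta_h * tau)) /
         (2 * params$beta_h),
       nu_dh2 = params$sigma12 * (1 - exp(-bsum * tau)) / bsum)
}

#' Full Gaussian state of the transition law at an age
#'
#' Combines [transition_mean()] and [transition_cov()] into the bivariate
#' normal law `N2(mu(t), Sigma(t))` of diameter and height at age `t`.
#'
#' @inheritParams transition_mean
#' @return An object of class `transition_state`: list with `mu_d`, `mu_h`,
#'   `nu_d2`, `nu_h2`, `nu_dh2`, `t` (scalars).
#' @export
transition_state <- function(params, t, effects = NULL,
                             init = initial_state()) {
  if (length(t) != 1L) stop_validation("t must be a single age")
  m <- transition_mean(params, t, effects, init)
  v <- transition_cov(params, t, init)
  structure(list(mu_d = m$mu_d, mu_h = m$mu_h, nu_d2 = v$nu_d2,
                 nu_h2 = v$nu_h2, nu_dh2 = v$nu_dh2, t = t),
            class = "transition_state")
}

#' @export
print.transition_state <- function(x, ...) {
  cat(sprintf("Diameter-height law at age %g yr\n", x$t))
  cat(sprintf("  mean: d = %.3f cm, h = %.3f m\n", x$mu_d, x$mu_h))
  cat(sprintf("  var:  d = %.4f cm^2, h = %.4f m^2, cov = %.4f cm*m (cor %.3f)\n",
              x$nu_d2, x$nu_h2, x$nu_dh2,
              if (x$nu_d2 > 0 && x$nu_h2 > 0)
                x$nu_dh2 / sqrt(x$nu_d2 * x$nu_h2) else NA_real_))
  invisible(x)
}

#' Stationary (infinite-age) state of the diffusion
#'
#' Limit law as age grows without bound: mean
#' `(alpha_d + phi_d, alpha_h + phi_h)`, variances `sigma11 / (2 beta_d)`,
#' `sigma22 / (2 beta_h)` and covariance `sigma12 / (beta_d + beta_h)`.
#'
#' @inheritParams transition_mean
#' @return A `transition_state` with `t = Inf`.
#' @export
stationary_state <- function(params, effects = NULL) {
  stopifnot(inherits(params, "sde_params"))
  phi <- as_effects(effects)
  s <- list(mu_d = params$alpha_d + phi[["phi_d"]],
            mu_h = params$alpha_h + phi[["phi_h"]],
            nu_d2 = params$sigma11 / (2 * params$beta_d),
            nu_h2 = params$sigma22 / (2 * params$beta_h),
            nu_dh2 = params$sigma12 / (params$beta_d + params$beta_h),
            t = Inf)
  if (s$nu_d2 * s$nu_h2 - s$nu_dh2^2 <= 0)
    stop_validation("implied stationary covariance is not positive definite")
  structure(s, class = "transition_state")
}

#' Diameter-height correlation at an age
#'
#' `ro(t) = nu_dh2(t) / sqrt(nu_d2(t) * nu_h2(t))`; strictly inside
#' `(-1, 1)` for a positive-definite diffusion matrix.
#'
#' @inheritParams transition_mean
#' @return Correlation value(s) in `[-1, 1]`.
#' @export
transition_correlation <- function(params, t, init = initial_state()) {
  if (any(t <= init$t0))
    stop_validation("correlation requires t > t0 (zero variance at t0)")
  v <- transition_cov(params, t, init)
  v$nu_dh2 / sqrt(v$nu_d2 * v$nu_h2)
}

# internal: closed-form 2x2 inverse/determinant pieces of a state
state_inverse <- function(state) {
  det <- state$nu_d2 * state$nu_h2 - state$nu_dh2^2
  if (!is.finite(det) || det < 1e-300)
    stop_numerical("degenerate transition covariance (det = ", det, ")")
  list(det = det, i11 = state$nu_h2 / det, i22 = state$nu_d2 / det,
       i12 = -state$nu_dh2 / det)
}

#' Bivariate transition density of diameter and height
#'
#' Density of `(D(t), H(t))` given the initial state: the bivariate normal
#' `N2(mu(t), Sigma(t))` evaluated at `(d, h)`. Computed in log space with
#' the closed-form 2x2 inverse.
#'
#' @param d Diameter (cm). Vectorised (recycled against `h`).
#' @param h Height (m).
#' @inheritParams transition_mean
#' @param log Return the log density?
#' @return Density value(s).
#' @examples
#' ref <- scots_pine_params()
#' dtransition(25, 20, t = 60, params = ref$params, init = ref$init)
#' @export
dtransition <- function(d, h, t, params, effects = NULL,
                        init = initial_state(), log = FALSE) {
  if (length(t) != 1L) stop_validation("t must be a single age")
  if (t <= init$t0)
    stop_validation("transition law is degenerate at t <= t0")
  st <- transition_state(params, t, effects, init)
  inv <- state_inverse(st)
  r1 <- d - st$mu_d
  r2 <- h - st$mu_h
  omega <- inv$i11 * r1^2 + 2 * inv$i12 * r1 * r2 + inv$i22 * r2^2
  ll <- -log(2 * pi) - 0.5 * log(inv$det) - 0.5 * omega
  if (log) ll else exp(ll)
}

#' Conditional law of height given diameter (and vice versa)
#'
#' Univariate normal conditionals of the bivariate transition law.
#' `conditional_height(d, t, ...)` returns the law of `H(t) | D(t) = d`
#' with mean `mu_h + (nu_dh2 / nu_d2) * (d - mu_d)` and variance
#' `(1 - ro^2) * nu_h2`; the conditional variance does not depend on the
#' conditioning value. `conditional_diameter()` is the mirror image.
#'
#' @param d,h Conditioning diameter (cm) / height (m). Vectorised.
#' @inheritParams transition_mean
#' @return A list with components `m` (conditional mean, same length as the
#'   conditioning value) and `w2` (conditional variance, scalar).
#' @export
conditional_height <- function(d, t, params, effects = NULL,
                               init = initial_state()) {
  if (length(t) != 1L || t <= init$t0)
    stop_validation("conditional law requires a single age t > t0")
  st <- transition_state(params, t, effects, init)
  ro2 <- st$nu_dh2^2 / (st$nu_d2 * st$nu_h2)
  list(m = st$mu_h + (st$nu_dh2 / st$nu_d2) * (d - st$mu_d),
       w2 = (1 - ro2) * st$nu_h2)
}

#' @rdname conditional_height
#' @export
conditional_diameter <- function(h, t, params, effects = NULL,
                                 init = initial_state()) {
  if (length(t) != 1L || t <= init$t0)
    stop_validation("conditional law requires a single age t > t0")
  st <- transition_state(params, t, effects, init)
  ro2 <- st$nu_dh2^2 / (st$nu_d2 * st$nu_h2)
  list(m = st$mu_d + (st$nu_dh2 / st$nu_h2) * (h - st$mu_h),
       w2 = (1 - ro2) * st$nu_d2)
}
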