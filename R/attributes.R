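# Integral stand attributes over the bivariate diameter-height law:
# slenderness, stem-volume mean/SD/CV, assortment fractions and stand volume
# per ha. All expectations share one product Gauss-Legendre engine over the
# law truncated to the positive quadrant (power-law integrands are undefined
# for non-positive sizes); the truncated-away mass is reported as a
# diagnostic attribute.

#' Integrate a function against the bivariate diameter-height law
#'
#' Product Gauss-Legendre quadrature of `E[g(D, H)]` under a
#' [transition_state], over mean +/- 8 SD intersected (by default) with the
#' positive quadrant floored at `eps`. The node count doubles until the
#' estimate changes by less than `tol` in relative terms.
#'
#' @param g Function of two vectors `(d, h)` returning the integrand values.
#' @param state A [transition_state()] (or [stationary_state()]).
#' @param domain `"positive"` (default) or `"plane"` (no truncation).
#' @param eps Lower floor of the positive domain.
#' @param tol Relative convergence tolerance.
#' @param n_start,n_max Initial / maximal nodes per axis.
#' @return Scalar estimate, with attribute `"nodes"` (nodes per axis at
#'   convergence).
#' @export
integrate_bivariate <- function(g, state, domain = c("positive", "plane"),
                                eps = 1e-6, tol = 1e-6, n_start = 48,
                                n_max = 768) {
  domain <- match.arg(domain)
  stopifnot(inherits(state, "transition_state"))
  inv <- state_inverse(state)
  sd_d <- sqrt(state$nu_d2); sd_h <- sqrt(state$nu_h2)
  lo_d <- state$mu_d - 8 * sd_d; hi_d <- state$mu_d + 8 * sd_d
  lo_h <- state$mu_h - 8 * sd_h; hi_h <- state$mu_h + 8 * sd_h
  if (domain == "positive") {
    lo_d <- max(lo_d, eps); lo_h <- max(lo_h, eps)
  }
  if (lo_d >= hi_d || lo_h >= hi_h)
    stop_numerical("empty integration domain")
  # near an active positive-quadrant floor, add a log-spaced panel on
  # (eps, 1] so 1/size-type integrands (slenderness) are resolved
  axis_nodes <- function(n, lo, hi) {
    if (lo > 0 && lo <= eps * (1 + 1e-12) && hi > 1) {
      ql <- pracma::gaussLegendre(n, log(lo), 0)
      qr <- pracma::gaussLegendre(n, 1, hi)
      list(x = c(exp(ql$x), qr$x), w = c(ql$w * exp(ql$x), qr$w))
    } else {
      pracma::gaussLegendre(n, lo, hi)
    }
  }
  eval_n <- function(n) {
    qd <- axis_nodes(n, lo_d, hi_d)
    qh <- axis_nodes(n, lo_h, hi_h)
    d <- rep(qd$x, times = length(qh$x))
    h <- rep(qh$x, each = length(qd$x))
    w <- rep(qd$w, times = length(qh$x)) * rep(qh$w, each = length(qd$x))
    r1 <- d - state$mu_d; r2 <- h - state$mu_h
    f <- exp(-log(2 * pi) - 0.5 * log(inv$det) -
               0.5 * (inv$i11 * r1^2 + 2 * inv$i12 * r1 * r2 +
                        inv$i22 * r2^2))
    sum(w * g(d, h) * f)
  }
  n <- n_start
  est <- eval_n(n)
  repeat {
    n2 <- 2L * n
    est2 <- eval_n(n2)
    if (abs(est2 - est) <= tol * max(abs(est2), 1e-12)) {
      attr(est2, "nodes") <- n2
      return(est2)
    }
    if (n2 >= n_max)
      stop_numerical(sprintf(
        "bivariate quadrature did not converge (last two estimates %.10g, %.10g)",
        est, est2))
    est <- est2; n <- n2
  }
}

# law mass retained on the positive quadrant (diagnostic)
positive_mass <- function(state, eps = 1e-6) {
  as.numeric(assortment_fraction(state = state, d_min = eps, h_min = eps)) / 100
}

state_from_args <- function(t, params, effects, init, state) {
  if (!is.null(state)) return(state)
  if (is.null(t)) stop_validation("supply either a state or an age t")
  if (is.infinite(t)) stationary_state(params, effects)
  else transition_state(params, t, effects, init)
}

#' Mean slenderness ratio of a stand
#'
#' `E[H / D]` at age `t` under the bivariate law truncated to positive
#' sizes, the stand-level indicator of wind/snow damage risk (taller,
#' thinner trees are more vulnerable); decreases with stand age. If more
#' than 0.1% of the law's mass lies outside the positive quadrant (very
#' young stands, where the integrand's `1/d` singularity matters) the value
#' is flagged with a warning and attribute `"flagged"`.
#'
#' @param t Age (years), `> t0`; `Inf` for the stationary law.
#' @param params,effects,init Model configuration as in
#'   [transition_state()].
#' @param state Optionally a precomputed [transition_state()] (overrides
#'   `t`/`params`).
#' @param eps Positive-domain floor (cm / m).
#' @return Dimensionless mean slenderness (height m / diameter cm scaled by
#'   units as given).
#' @export
slenderness_ratio <- function(t = NULL, params = NULL, effects = NULL,
                              init = initial_state(), state = NULL,
                              eps = 1e-6) {
  st <- state_from_args(t, params, effects, init, state)
  mass <- positive_mass(st, eps)
  val <- integrate_bivariate(function(d, h) h / d, st, eps = eps) / mass
  if (1 - mass > 1e-3) {
    warning("slenderness at this age truncates ", signif(100 * (1 - mass), 3),
            "% of the law's mass; value flagged")
    attr(val, "flagged") <- TRUE
  }
  val
}

#' Mean stem volume of a stand
#'
#' `E[V(D, H)]` at age `t`: the stem-volume power equation integrated
#' against the bivariate diameter-height law (positive quadrant).
#'
#' @inheritParams slenderness_ratio
#' @param vol A [volume_params] object.
#' @return Mean stem volume (m^3).
#' @examples
#' ref <- scots_pine_params()
#' mean_stem_volume(t = 80, params = ref$params, init = ref$init,
#'                  vol = scots_pine_volume())
#' @export
mean_stem_volume <- function(t = NULL, params = NULL, effects = NULL,
                             init = initial_state(), vol, state = NULL) {
  stopifnot(inherits(vol, "volume_params"))
  st <- state_from_args(t, params, effects, init, state)
  integrate_bivariate(function(d, h) stem_volume(d, h, vol), st)
}

#' SD and coefficient of variation of stem volume
#'
#' `SD_V = sqrt(E[V^2] - E[V]^2)` and `CV = 100 * SD_V / E[V]` under the
#' bivariate law; the CV declines with age toward its stationary value.
#'
#' @inheritParams mean_stem_volume
#' @return A list with `sd` (m^3), `cv` (percent) and `mean` (m^3).
#' @export
volume_sd_cv <- function(t = NULL, params = NULL, effects = NULL,
                         init = initial_state(), vol, state = NULL) {
  stopifnot(inherits(vol, "volume_params"))
  st <- state_from_args(t, params, effects, init, state)
  m1 <- as.numeric(integrate_bivariate(function(d, h) stem_volume(d, h, vol),
                                       st))
  m2 <- as.numeric(integrate_bivariate(function(d, h)
    stem_volume(d, h, vol)^2, st))
  v <- m2 - m1^2
  if (v < 0) {
    if (abs(v) < 1e-10) {
      warning("negative stem-volume variance from quadrature noise; clamped to 0")
      v <- 0
    } else stop_numerical("negative stem-volume variance: ", v)
  }
  list(sd = sqrt(v), cv = 100 * sqrt(v) / m1, mean = m1)
}

#' Assortment fraction: share of trees exceeding size thresholds
#'
#' `100 * P(D > d_min, H > h_min)` under the bivariate law, the percentage
#' of a stand's trees reaching a merchantable size class. Computed from the
#' bivariate normal rectangle probability by integrating the Gaussian
#' conditional-slice decomposition with adaptive 1-D quadrature; with
#' `h_min = NULL` the threshold is on diameter alone (univariate normal
#' tail).
#'
#' @inheritParams slenderness_ratio
#' @param d_min Diameter threshold (cm); `-Inf` for none.
#' @param h_min Height threshold (m); `NULL` or `-Inf` for none.
#' @return Percentage in `[0, 100]`.
#' @examples
#' ref <- scots_pine_params()
#' assortment_fraction(t = 100, params = ref$params, init = ref$init,
#'                     d_min = 25, h_min = 20)
#' @export
assortment_fraction <- function(t = NULL, params = NULL, effects = NULL,
                                init = initial_state(), state = NULL,
                                d_min, h_min = NULL) {
  st <- state_from_args(t, params, effects, init, state)
  sd_d <- sqrt(st$nu_d2)
  if (is.null(h_min) || identical(h_min, -Inf))
    return(100 * stats::pnorm(d_min, st$mu_d, sd_d, lower.tail = FALSE))
  if (identical(d_min, -Inf))
    return(100 * stats::pnorm(h_min, st$mu_h, sqrt(st$nu_h2),
                              lower.tail = FALSE))
  ro <- st$nu_dh2 / sqrt(st$nu_d2 * st$nu_h2)
  w_h <- sqrt((1 - ro^2) * st$nu_h2)
  f <- function(d) {
    mh <- st$mu_h + (st$nu_dh2 / st$nu_d2) * (d - st$mu_d)
    stats::dnorm(d, st$mu_d, sd_d) *
      stats::pnorm(h_min, mh, w_h, lower.tail = FALSE)
  }
  val <- stats::integrate(f, max(d_min, st$mu_d - 10 * sd_d),
                          st$mu_d + 10 * sd_d,
                          rel.tol = 1e-10, abs.tol = 1e-12)
  100 * val$value
}

#' Stand volume per hectare
#'
#' `V_S(t) = mu_N(t) * E[V(D, H)]`: the mean trees-per-ha at age `t` times
#' the mean stem volume under the bivariate law at that age. Linear in the
#' volume scale coefficient.
#'
#' @inheritParams mean_stem_volume
#' @param params_N A [tree_count_params].
#' @param phi_N Stand effect on the density asymptote (default 0).
#' @return Stand volume (m^3/ha).
#' @export
stand_volume_per_ha <- function(t, params, effects = NULL,
                                init = initial_state(), vol, params_N,
                                phi_N = 0) {
  if (t > 200)
    stop_validation("stand volume is defined up to the anchor age 200")
  mN <- tree_count_mean_var(params_N, phi_N, t)$mean
  mN * as.numeric(mean_stem_volume(t, params, effects, init, vol))
}

#' Evaluate an attribute over an age grid
#'
#' @param ages Strictly increasing numeric age grid (years).
#' @param fun Function of a single age returning a scalar.
#' @param attribute Attribute name.
#' @param units Units label.
#' @return A data frame `age, value, attribute, units`.
#' @export
attribute_curve <- function(ages, fun, attribute, units) {
  if (is.unsorted(ages, strictly = TRUE))
    stop_validation("ages must be strictly increasing")
  data.frame(age = ages,
             value = vapply(ages, function(t) as.numeric(fun(t)), 0),
             attribute = attribute, units = units)
}
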