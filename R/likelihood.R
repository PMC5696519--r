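# Log-likelihoods for the four model variants: univariate (dbh or height) /
# bivariate, each with fixed or mixed (stand random) effects. Trees within a
# stand are conditionally independent given the stand effects; each tree
# contributes the Gaussian transition density from the initial state at t0 to
# its size at its measurement age.

#' Quadrature settings for the mixed-effects marginal likelihood
#'
#' The stand-level random effects are integrated out by adaptive
#' Gauss-Hermite quadrature centred and scaled at the per-stand posterior
#' mode. Because the transition mean is linear in the effects, the integrand
#' is exactly Gaussian in them, so the adaptive rule is exact for any node
#' count >= 1; `"laplace"` (one node at the mode) is the fast equivalent.
#'
#' @param method `"gauss-hermite"` (default) or `"laplace"`.
#' @param nodes Nodes per random-effect dimension (default 15).
#' @return An object of class `quad_spec`.
#' @export
quad_spec <- function(method = c("gauss-hermite", "laplace"), nodes = 15) {
  method <- match.arg(method)
  if (method == "laplace") nodes <- 1L
  if (nodes < 1) stop_validation("nodes must be >= 1")
  structure(list(method = method, nodes = as.integer(nodes)),
            class = "quad_spec")
}

# memoised Gauss-Hermite nodes/weights (weight exp(-z^2))
.gh_cache <- new.env(parent = emptyenv())
get_gh <- function(nodes) {
  key <- as.character(nodes)
  if (is.null(.gh_cache[[key]])) {
    if (nodes == 1L) .gh_cache[[key]] <- list(x = 0, w = sqrt(pi))
    else .gh_cache[[key]] <- pracma::gaussHermite(nodes)
  }
  .gh_cache[[key]]
}

log_sum_exp_rows <- function(m) {
  mx <- apply(m, 1L, max)
  mx + log(rowSums(exp(m - mx)))
}

# ---- per-tree precomputations ----------------------------------------------

# theta: plain list with alpha_d, beta_d, sigma11 (and _h / sigma22, sigma12
# as needed). Returns tree-level vectors for one trait.
prep_uni <- function(alpha, beta, sigma2rate, x0, tau) {
  k <- 1 - exp(-beta * tau)
  list(k = k,
       mu0 = alpha * k + x0 * (1 - k),
       v = sigma2rate * (1 - exp(-2 * beta * tau)) / (2 * beta))
}

prep_bi <- function(theta, init, age) {
  tau <- age - init$t0
  pd <- prep_uni(theta$alpha_d, theta$beta_d, theta$sigma11, init$d0, tau)
  ph <- prep_uni(theta$alpha_h, theta$beta_h, theta$sigma22, init$h0, tau)
  bsum <- theta$beta_d + theta$beta_h
  vdh <- theta$sigma12 * (1 - exp(-bsum * tau)) / bsum
  det <- pd$v * ph$v - vdh^2
  if (any(det <= 0)) return(NULL)
  list(kd = pd$k, kh = ph$k, mu0d = pd$mu0, mu0h = ph$mu0,
       i11 = ph$v / det, i22 = pd$v / det, i12 = -vdh / det,
       logdet = log(det))
}

check_ages <- function(age, init) {
  if (any(age <= init$t0))
    stop_data("all tree ages must exceed t0 = ", init$t0)
}

theta_from_params <- function(params) {
  stopifnot(inherits(params, "sde_params"))
  unclass(params)
}

# ---- fixed-effects log-likelihoods -----------------------------------------

#' Fixed-effects log-likelihood
#'
#' Sum over trees of the log transition density with the stand effects held
#' at a common value (zero for the population-average model). `model`
#' selects the bivariate density or the univariate marginal for one trait.
#'
#' @param params An [sde_params] object.
#' @param data A [forest_dataset].
#' @param init An [initial_state].
#' @param model `"bivariate"`, `"dbh"` or `"height"`.
#' @param effects Optional common effects (default zero).
#' @return Scalar log-likelihood.
#' @export
loglik_fixed <- function(params, data, init = initial_state(),
                         model = c("bivariate", "dbh", "height"),
                         effects = NULL) {
  model <- match.arg(model)
  stopifnot(inherits(data, "forest_dataset"))
  check_ages(data$age_years, init)
  phi <- as_effects(effects)
  theta <- theta_from_params(params)
  ll <- loglik_fixed_raw(theta, data, init, model, phi)
  if (!is.finite(ll)) stop_numerical("non-finite log-likelihood")
  ll
}

loglik_fixed_raw <- function(theta, data, init, model, phi = c(0, 0)) {
  age <- data$age_years
  tau <- age - init$t0
  if (model == "bivariate") {
    pp <- prep_bi(theta, init, age)
    if (is.null(pp)) return(-Inf)
    r1 <- data$dbh_cm - pp$mu0d - pp$kd * phi[[1]]
    r2 <- data$height_m - pp$mu0h - pp$kh * phi[[2]]
    sum(-log(2 * pi) - 0.5 * pp$logdet -
          0.5 * (pp$i11 * r1^2 + 2 * pp$i12 * r1 * r2 + pp$i22 * r2^2))
  } else if (model == "dbh") {
    p <- prep_uni(theta$alpha_d, theta$beta_d, theta$sigma11, init$d0, tau)
    r <- data$dbh_cm - p$mu0 - p$k * phi[[1]]
    sum(stats::dnorm(r, 0, sqrt(p$v), log = TRUE))
  } else {
    p <- prep_uni(theta$alpha_h, theta$beta_h, theta$sigma22, init$h0, tau)
    r <- data$height_m - p$mu0 - p$k * phi[[2]]
    sum(stats::dnorm(r, 0, sqrt(p$v), log = TRUE))
  }
}

# ---- mixed-effects marginal log-likelihoods --------------------------------

#' Mixed-effects marginal log-likelihood
#'
#' Per stand, the product of tree transition densities is integrated against
#' the Gaussian law of the stand effects,
#' `phi_d ~ N(0, sigma_d^2)`, `phi_h ~ N(0, sigma_h^2)` (one effect for a
#' univariate model), by adaptive Gauss-Hermite quadrature centred at the
#' per-stand mode; the total is the sum of the per-stand log integrals.
#' With both SDs zero this reduces exactly to [loglik_fixed()].
#'
#' @inheritParams loglik_fixed
#' @param re_vars An [re_variances] object.
#' @param quad A [quad_spec].
#' @return Scalar log-likelihood.
#' @export
loglik_mixed <- function(params, re_vars, data, init = initial_state(),
                         model = c("bivariate", "dbh", "height"),
                         quad = quad_spec()) {
  model <- match.arg(model)
  stopifnot(inherits(data, "forest_dataset"), inherits(re_vars, "re_variances"))
  check_ages(data$age_years, init)
  theta <- theta_from_params(params)
  ll <- loglik_mixed_raw(theta, c(re_vars$sigma_d, re_vars$sigma_h),
                         data, init, model, quad)
  if (!is.finite(ll)) stop_numerical("non-finite marginal log-likelihood")
  ll
}

loglik_mixed_raw <- function(theta, re_sd, data, init, model, quad) {
  if (model == "bivariate") {
    if (re_sd[1] <= 0 && re_sd[2] <= 0)
      return(loglik_fixed_raw(theta, data, init, model))
    re_sd <- pmax(re_sd, 1e-8)
    loglik_mixed_bi(theta, re_sd, data, init, quad)
  } else {
    sd1 <- if (model == "dbh") re_sd[1] else re_sd[2]
    if (sd1 <= 0) return(loglik_fixed_raw(theta, data, init, model))
    loglik_mixed_uni(theta, sd1, data, init, model, quad)
  }
}

loglik_mixed_bi <- function(theta, re_sd, data, init, quad) {
  pp <- prep_bi(theta, init, data$age_years)
  if (is.null(pp)) return(-Inf)
  si <- stand_index(data)
  M <- si$M; idx <- si$idx
  r1 <- data$dbh_cm - pp$mu0d
  r2 <- data$height_m - pp$mu0h
  base <- rowsum(-log(2 * pi) - 0.5 * pp$logdet, idx)[, 1L]

  # posterior mode and curvature of the (exactly Gaussian) stand integrand
  A11 <- rowsum(pp$kd^2 * pp$i11, idx)[, 1L] + 1 / re_sd[1]^2
  A22 <- rowsum(pp$kh^2 * pp$i22, idx)[, 1L] + 1 / re_sd[2]^2
  A12 <- rowsum(pp$kd * pp$kh * pp$i12, idx)[, 1L]
  b1 <- rowsum(pp$kd * (pp$i11 * r1 + pp$i12 * r2), idx)[, 1L]
  b2 <- rowsum(pp$kh * (pp$i12 * r1 + pp$i22 * r2), idx)[, 1L]
  detA <- A11 * A22 - A12^2
  if (any(detA <= 0)) return(-Inf)
  mode1 <- (A22 * b1 - A12 * b2) / detA
  mode2 <- (A11 * b2 - A12 * b1) / detA
  # Cholesky of the posterior covariance A^{-1}
  s1 <- A22 / detA; s2 <- A11 / detA; s12 <- -A12 / detA
  l11 <- sqrt(s1); l21 <- s12 / l11; l22sq <- s2 - l21^2
  if (any(l22sq <= 0)) return(-Inf)
  l22 <- sqrt(l22sq)

  gh <- get_gh(quad$nodes)
  lw <- log(gh$w) + gh$x^2
  n_nodes <- length(gh$x)
  lls <- matrix(0, M, n_nodes * n_nodes)
  col <- 0L
  for (a in seq_len(n_nodes)) {
    za <- gh$x[a]
    for (b in seq_len(n_nodes)) {
      zb <- gh$x[b]
      phi1 <- mode1 + sqrt(2) * l11 * za
      phi2 <- mode2 + sqrt(2) * (l21 * za + l22 * zb)
      rt1 <- r1 - pp$kd * phi1[idx]
      rt2 <- r2 - pp$kh * phi2[idx]
      q <- rowsum(pp$i11 * rt1^2 + 2 * pp$i12 * rt1 * rt2 + pp$i22 * rt2^2,
                  idx)[, 1L]
      col <- col + 1L
      lls[, col] <- lw[a] + lw[b] + base - 0.5 * q +
        stats::dnorm(phi1, 0, re_sd[1], log = TRUE) +
        stats::dnorm(phi2, 0, re_sd[2], log = TRUE)
    }
  }
  sum(log(2) + log(l11 * l22) + log_sum_exp_rows(lls))
}

loglik_mixed_uni <- function(theta, re_sd, data, init, model, quad) {
  tau <- data$age_years - init$t0
  if (model == "dbh") {
    p <- prep_uni(theta$alpha_d, theta$beta_d, theta$sigma11, init$d0, tau)
    x <- data$dbh_cm
  } else {
    p <- prep_uni(theta$alpha_h, theta$beta_h, theta$sigma22, init$h0, tau)
    x <- data$height_m
  }
  if (any(p$v <= 0)) return(-Inf)
  si <- stand_index(data)
  idx <- si$idx
  r <- x - p$mu0
  base <- rowsum(-0.5 * log(2 * pi * p$v), idx)[, 1L]
  A <- rowsum(p$k^2 / p$v, idx)[, 1L] + 1 / re_sd^2
  b <- rowsum(p$k * r / p$v, idx)[, 1L]
  mode <- b / A
  l <- sqrt(1 / A)
  gh <- get_gh(quad$nodes)
  lw <- log(gh$w) + gh$x^2
  lls <- matrix(0, si$M, length(gh$x))
  for (a in seq_along(gh$x)) {
    phi <- mode + sqrt(2) * l * gh$x[a]
    rt <- r - p$k * phi[idx]
    q <- rowsum(rt^2 / p$v, idx)[, 1L]
    lls[, a] <- lw[a] + base - 0.5 * q +
      stats::dnorm(phi, 0, re_sd, log = TRUE)
  }
  sum(0.5 * log(2) + log(l) + log_sum_exp_rows(lls))
}
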