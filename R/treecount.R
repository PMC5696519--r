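# Trees-per-ha dynamics: a univariate Vasicek diffusion for the stand
# density N(t), anchored at a known-age terminal condition N(200) = delta
# (the count at age 200 is a parameter, not a random quantity). Running the
# mean-reverting law backwards from the anchor gives, at age t <= 200,
# N(t) ~ Normal(mu_N(t), w_N^2(t)) with
#   mu_N(t)  = a + (delta - a) * exp(beta * (t - 200)),  a = alpha + phi_N,
#   w_N^2(t) = sigma^2 * (1 - exp(2 * beta * (t - 200))) / (2 * beta),
# so the variance vanishes exactly at the anchor age.

#' Parameters of the trees-per-ha model
#'
#' @param alpha Asymptotic count (trees/ha).
#' @param beta Mean-reversion rate (1/yr), positive.
#' @param sigma Diffusion rate (trees/ha * yr^-1/2), positive.
#' @param delta Anchor count at age 200 (trees/ha), non-negative.
#' @param sigma_N SD of the stand effect on the asymptote (trees/ha),
#'   non-negative.
#' @return An object of class `tree_count_params`.
#' @export
tree_count_params <- function(alpha, beta, sigma, delta, sigma_N = 0) {
  if (!all(is.finite(c(alpha, beta, sigma, delta, sigma_N))))
    stop_validation("tree-count parameters must be finite")
  if (beta <= 0 || sigma <= 0 || delta < 0 || sigma_N < 0)
    stop_validation("require beta > 0, sigma > 0, delta >= 0, sigma_N >= 0")
  structure(list(alpha = alpha, beta = beta, sigma = sigma, delta = delta,
                 sigma_N = sigma_N), class = "tree_count_params")
}

#' Reference trees-per-ha parameter scenarios for Scots pine
#'
#' The two fitted parameter scenarios of the stand-density model: the
#' fixed-effects scenario (`alpha = 41215.9217`, `beta = 8.84e-5`,
#' `sigma = 18.9385`, `delta = 10.0`) and the mixed-effects scenario
#' (`alpha = 2547.4181`, `beta = 0.0012`, `sigma = 5.8849`,
#' `delta = 94.7886`, `sigma_N = 1516.9969`). Though the scenarios differ
#' wildly in the asymptote, both imply about 372-373 trees/ha at age 100.
#'
#' @param scenario `"mixed"` (default) or `"fixed"`.
#' @return A [tree_count_params] object.
#' @export
scots_pine_tree_count <- function(scenario = c("mixed", "fixed")) {
  scenario <- match.arg(scenario)
  if (scenario == "mixed")
    tree_count_params(2547.4181, 0.0012, 5.8849, 94.7886, 1516.9969)
  else
    tree_count_params(41215.9217, 8.84e-5, 18.9385, 10.0)
}

#' Mean and variance of trees per ha at an age
#'
#' @param params_N A [tree_count_params] object.
#' @param phi_N Stand effect on the asymptote (default 0).
#' @param t Stand age (years), `t <= 200`. Vectorised.
#' @return A list with `mean` and `var` (trees/ha, (trees/ha)^2).
#' @examples
#' tree_count_mean_var(scots_pine_tree_count("mixed"), t = 100)
#' @export
tree_count_mean_var <- function(params_N, phi_N = 0, t) {
  stopifnot(inherits(params_N, "tree_count_params"))
  if (any(t > 200))
    stop_validation("tree-count law is defined for t <= 200 (anchor age)")
  a <- params_N$alpha + phi_N
  e <- exp(params_N$beta * (t - 200))
  # blend form is exact at the anchor (e = 1 gives delta bit-for-bit)
  list(mean = a * (1 - e) + params_N$delta * e,
       var = params_N$sigma^2 * (1 - e^2) / (2 * params_N$beta))
}

#' Simulate trees-per-ha counts
#'
#' Draws from the Gaussian law of `N(t)`; at the anchor age 200 every draw
#' equals `delta`.
#'
#' @inheritParams tree_count_mean_var
#' @param n Number of draws.
#' @param seed Optional integer seed.
#' @return Numeric vector of counts.
#' @export
simulate_tree_count <- function(params_N, phi_N = 0, t, n, seed = NULL) {
  if (length(t) != 1L) stop_validation("t must be a single age")
  mv <- tree_count_mean_var(params_N, phi_N, t)
  if (mv$var < 0) stop_validation("negative tree-count variance")
  if (!is.null(seed)) set.seed(seed)
  stats::rnorm(n, mv$mean, sqrt(mv$var))
}

#' Log-likelihood of plot-level tree counts
#'
#' Gaussian likelihood of observed trees-per-ha at given ages; the mixed
#' variant marginalises the stand effect `phi_N ~ N(0, sigma_N^2)` by 1-D
#' adaptive Gauss-Hermite quadrature per plot (`sigma_N = 0` reduces
#' exactly to the fixed-effects likelihood).
#'
#' @param params_N A [tree_count_params] (its `sigma_N` selects the
#'   variant).
#' @param counts Data frame with columns `age`, `trees_per_ha` and
#'   optionally `plot_id` (defaults to one plot per row).
#' @param quad A [quad_spec].
#' @return Scalar log-likelihood.
#' @export
loglik_tree_count <- function(params_N, counts, quad = quad_spec()) {
  stopifnot(inherits(params_N, "tree_count_params"))
  t <- counts$age
  y <- counts$trees_per_ha
  if (any(t > 200)) stop_validation("ages must be <= 200")
  p <- unclass(params_N)
  if (p$sigma_N <= 0)
    return(ll_tc_fixed(p, t, y))
  pid <- if (!is.null(counts$plot_id)) counts$plot_id else seq_along(t)
  idx <- match(pid, unique(pid))
  ll_tc_mixed(p, t, y, idx, quad)
}

ll_tc_fixed <- function(p, t, y, phi = 0) {
  e <- exp(p$beta * (t - 200))
  mu <- (p$alpha + phi) * (1 - e) + p$delta * e
  v <- p$sigma^2 * (1 - e^2) / (2 * p$beta)
  at_anchor <- v <= 0
  ll <- numeric(length(t))
  ll[at_anchor] <- ifelse(y[at_anchor] == p$delta, 0, -Inf)
  ll[!at_anchor] <- stats::dnorm(y[!at_anchor], mu[!at_anchor],
                                 sqrt(v[!at_anchor]), log = TRUE)
  sum(ll)
}

ll_tc_mixed <- function(p, t, y, idx, quad) {
  e <- exp(p$beta * (t - 200))
  k <- 1 - e
  mu0 <- p$alpha * k + p$delta * e
  v <- p$sigma^2 * (1 - e^2) / (2 * p$beta)
  if (any(v <= 0)) return(-Inf)  # anchor-age rows are fixed-variant territory
  M <- max(idx)
  r <- y - mu0
  base <- rowsum(-0.5 * log(2 * pi * v), idx)[, 1L]
  A <- rowsum(k^2 / v, idx)[, 1L] + 1 / p$sigma_N^2
  b <- rowsum(k * r / v, idx)[, 1L]
  mode <- b / A
  l <- sqrt(1 / A)
  gh <- get_gh(quad$nodes)
  lw <- log(gh$w) + gh$x^2
  lls <- matrix(0, M, length(gh$x))
  for (a in seq_along(gh$x)) {
    phi <- mode + sqrt(2) * l * gh$x[a]
    q <- rowsum((r - k * phi[idx])^2 / v, idx)[, 1L]
    lls[, a] <- lw[a] + base - 0.5 * q +
      stats::dnorm(phi, 0, p$sigma_N, log = TRUE)
  }
  sum(0.5 * log(2) + log(l) + log_sum_exp_rows(lls))
}

#' Fit the trees-per-ha model
#'
#' Maximum-likelihood fit of the stand-density diffusion to plot-level
#' counts. The fixed-effects variant profiles the diffusion rate `sigma`
#' out of the Gaussian likelihood; the mixed variant adds a stand effect
#' `phi_N ~ N(0, sigma_N^2)` marginalised by quadrature. Starts are built
#' from a grid of reversion rates with the linear-in-(alpha, delta) mean
#' solved by least squares.
#'
#' @param counts Data frame with `age`, `trees_per_ha`, optional `plot_id`.
#' @param effects `"fixed"` or `"mixed"`.
#' @param quad A [quad_spec].
#' @return An object of class `tree_count_fit`: `estimates`
#'   ([tree_count_params]), `loglik`, `aic` (`-2 loglik`), `converged`.
#' @export
fit_tree_count <- function(counts, effects = c("fixed", "mixed"),
                           quad = quad_spec()) {
  effects <- match.arg(effects)
  t <- counts$age
  y <- counts$trees_per_ha
  if (any(t >= 200))
    stop_data("fitting requires ages strictly below the anchor age 200")
  if (any(y < 0)) stop_data("counts must be non-negative")
  pid <- if (!is.null(counts$plot_id)) counts$plot_id else seq_along(t)
  idx <- match(pid, unique(pid))

  # least-squares (alpha, delta) given beta; mean is linear in both
  ls_mean <- function(beta) {
    e <- exp(beta * (t - 200))
    X <- cbind(1 - e, e)
    cf <- tryCatch(stats::lm.fit(X, y)$coefficients, error = function(e) NULL)
    if (is.null(cf) || any(!is.finite(cf))) return(NULL)
    c(alpha = cf[[1]], delta = max(cf[[2]], 1e-3))
  }

  if (effects == "fixed") {
    # profile likelihood over (alpha, log beta, log delta); sigma^2 closes
    negll <- function(par) {
      alpha <- par[1]; beta <- exp(par[2]); delta <- exp(par[3])
      e <- exp(beta * (t - 200))
      g <- (1 - e^2) / (2 * beta)
      if (any(g <= 0)) return(1e10)
      r <- y - (alpha * (1 - e) + delta * e)
      s2 <- max(mean(r^2 / g), 1e-200)
      n <- length(y)
      -(-0.5 * n * log(2 * pi * s2) - 0.5 * sum(log(g)) - 0.5 * n)
    }
    best <- NULL
    for (beta0 in c(1e-4, 5e-4, 1e-3, 5e-3, 0.02)) {
      ad <- ls_mean(beta0)
      if (is.null(ad)) next
      opt <- tryCatch(stats::nlminb(c(ad[["alpha"]], log(beta0),
                                      log(ad[["delta"]])), negll,
                                    control = list(iter.max = 500)),
                      error = function(e) NULL)
      if (!is.null(opt) && (is.null(best) || opt$objective < best$objective))
        best <- opt
    }
    if (is.null(best)) stop_numerical("tree-count fit failed from all starts")
    alpha <- best$par[1]; beta <- exp(best$par[2]); delta <- exp(best$par[3])
    e <- exp(beta * (t - 200))
    g <- (1 - e^2) / (2 * beta)
    r <- y - (alpha * (1 - e) + delta * e)
    sigma <- sqrt(max(mean(r^2 / g), 1e-200))
    est <- tree_count_params(alpha, beta, max(sigma, 1e-12), delta)
    ll <- -best$objective
    structure(list(estimates = est, loglik = ll, aic = -2 * ll,
                   converged = best$convergence == 0, effects = "fixed",
                   n_obs = length(y)), class = "tree_count_fit")
  } else {
    fx <- fit_tree_count(counts, "fixed", quad)
    f <- fx$estimates
    phihat <- rowsum((y - (f$alpha * (1 - exp(f$beta * (t - 200))) +
                             f$delta * exp(f$beta * (t - 200)))) /
                       pmax(1 - exp(f$beta * (t - 200)), 1e-6), idx)[, 1L] /
      tabulate(idx)
    sN0 <- max(stats::sd(phihat), 1)
    negll <- function(par) {
      p <- list(alpha = par[1], beta = exp(par[2]), sigma = exp(par[3]),
                delta = exp(par[4]), sigma_N = exp(par[5]))
      ll <- ll_tc_mixed(p, t, y, idx, quad)
      if (!is.finite(ll)) return(1e10)
      -ll
    }
    start <- c(f$alpha, log(f$beta), log(max(f$sigma, 1e-3)), log(f$delta),
               log(sN0))
    best <- tryCatch(stats::nlminb(start, negll,
                                   control = list(iter.max = 1000)),
                     error = function(e) NULL)
    if (is.null(best)) stop_numerical("mixed tree-count fit failed")
    est <- tree_count_params(best$par[1], exp(best$par[2]), exp(best$par[3]),
                             exp(best$par[4]), exp(best$par[5]))
    ll <- -best$objective
    structure(list(estimates = est, loglik = ll, aic = -2 * ll,
                   converged = best$convergence == 0, effects = "mixed",
                   n_obs = length(y)), class = "tree_count_fit")
  }
}

#' @export
print.tree_count_fit <- function(x, ...) {
  e <- x$estimates
  cat(sprintf("Trees-per-ha %s-effects fit (n = %d)\n", x$effects, x$n_obs))
  cat(sprintf("  alpha %.2f  beta %.5g  sigma %.4g  delta %.3f%s\n",
              e$alpha, e$beta, e$sigma, e$delta,
              if (e$sigma_N > 0) sprintf("  sigma_N %.2f", e$sigma_N) else ""))
  cat(sprintf("  loglik %.2f  converged: %s\n", x$loglik, x$converged))
  invisible(x)
}
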