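# Maximum-likelihood fitting of the four model variants. Optimisation runs on
# a transformed scale (log for rates and variance rates, atanh for the
# diffusion correlation) so the positivity / positive-definiteness
# constraints hold by construction; estimates are reported on the natural
# scale with delta-method standard errors from the observed information.

par_names <- function(model, effects) {
  base <- switch(model,
    dbh = c("alpha_d", "beta_d", "sigma11"),
    height = c("alpha_h", "beta_h", "sigma22"),
    bivariate = c("alpha_d", "beta_d", "sigma11", "alpha_h", "beta_h",
                  "sigma22", "sigma12"))
  if (effects == "mixed")
    base <- c(base, switch(model, dbh = "sigma_d", height = "sigma_h",
                           bivariate = c("sigma_d", "sigma_h")))
  base
}

# natural named vector -> transformed vector and back
nat_to_trans <- function(nat, model, effects) {
  tr <- nat
  for (nm in intersect(names(nat), c("beta_d", "beta_h", "sigma11", "sigma22",
                                     "sigma_d", "sigma_h")))
    tr[[nm]] <- log(nat[[nm]])
  if ("sigma12" %in% names(nat)) {
    rho <- nat[["sigma12"]] / sqrt(nat[["sigma11"]] * nat[["sigma22"]])
    tr[["sigma12"]] <- atanh(max(-0.99, min(0.99, rho)))
  }
  unname(tr)
}

trans_to_nat <- function(par, model, effects) {
  nms <- par_names(model, effects)
  nat <- stats::setNames(par, nms)
  for (nm in intersect(nms, c("beta_d", "beta_h", "sigma11", "sigma22",
                              "sigma_d", "sigma_h")))
    nat[[nm]] <- exp(nat[[nm]])
  if ("sigma12" %in% nms)
    nat[["sigma12"]] <- tanh(par[[which(nms == "sigma12")]]) *
      sqrt(nat[["sigma11"]] * nat[["sigma22"]])
  nat
}

nat_to_theta <- function(nat) {
  th <- as.list(nat)
  for (nm in c("alpha_d", "beta_d", "sigma11", "alpha_h", "beta_h",
               "sigma22", "sigma12"))
    if (is.null(th[[nm]])) th[[nm]] <- switch(nm, sigma12 = 0, 1)
  th
}

# moment-based univariate start for one trait given a reversion-rate guess
start_uni <- function(x, tau, x0, beta) {
  k <- 1 - exp(-beta * tau)
  alpha <- sum((x - x0 * (1 - k)) * k) / sum(k^2)
  r <- x - (alpha * k + x0 * (1 - k))
  g <- (1 - exp(-2 * beta * tau)) / (2 * beta)
  sigma <- max(mean(r^2 / g), 1e-6)
  c(alpha = alpha, beta = beta, sigma = sigma)
}

# crude per-stand effect estimates (mean-inversion) used for mixed starts
start_re_sd <- function(x, tau, x0, alpha, beta, idx) {
  k <- 1 - exp(-beta * tau)
  phi <- (x - alpha * k - x0 * (1 - k)) / k
  phihat <- rowsum(phi, idx)[, 1L] / tabulate(idx)
  max(stats::sd(phihat), 0.05)
}

#' Fit a diameter-height diffusion model by maximum likelihood
#'
#' Fits one of the four model variants: univariate (one trait) or bivariate,
#' with fixed or mixed (stand random) effects. Mixed variants maximise the
#' adaptive Gauss-Hermite marginal likelihood of [loglik_mixed()]. Moment-
#' based multi-starts over a grid of mean-reversion rates guard against
#' local optima; mixed fits warm-start from the corresponding fixed fit.
#'
#' @param data A [forest_dataset].
#' @param model `"bivariate"`, `"dbh"` or `"height"`.
#' @param effects `"fixed"` or `"mixed"`.
#' @param init An [initial_state].
#' @param start Optional named natural-scale start values (full parameter
#'   set for the variant).
#' @param quad A [quad_spec] for mixed variants.
#' @param se Compute standard errors from the observed information?
#' @return An object of class `sde_fit`: list with `estimates` (natural
#'   scale), `std_errors`, `loglik`, `aic` (`-2 loglik`, the model's
#'   comparison index), `aic_penalized` (`-2 loglik + 2k`), `converged`,
#'   `n_obs`, `n_stands`, `model`, `effects`.
#' @examples
#' fd <- simulate_forest(n_stands = 40, trees_per_stand = 5,
#'                       re_vars = re_variances(0, 0), seed = 7)
#' fit <- sde_fit(fd, model = "dbh", effects = "fixed")
#' fit
#' @export
sde_fit <- function(data, model = c("bivariate", "dbh", "height"),
                    effects = c("fixed", "mixed"), init = initial_state(),
                    start = NULL, quad = quad_spec(), se = TRUE) {
  model <- match.arg(model)
  effects <- match.arg(effects)
  stopifnot(inherits(data, "forest_dataset"))
  check_ages(data$age_years, init)
  si <- stand_index(data)
  if (effects == "mixed" && si$M < 2)
    stop_data("mixed-effects fit requires at least 2 stands")
  if (stats::var(data$age_years) == 0 &&
      stats::var(data$dbh_cm) == 0 && stats::var(data$height_m) == 0)
    stop_data("degenerate data: all ages and sizes identical")
  tau <- data$age_years - init$t0
  nms <- par_names(model, effects)

  negll <- function(par) {
    nat <- trans_to_nat(par, model, effects)
    theta <- nat_to_theta(nat)
    ll <- if (effects == "fixed") {
      loglik_fixed_raw(theta, data, init, model)
    } else {
      re_sd <- c(if ("sigma_d" %in% names(nat)) nat[["sigma_d"]] else 0,
                 if ("sigma_h" %in% names(nat)) nat[["sigma_h"]] else 0)
      loglik_mixed_raw(theta, re_sd, data, init, model, quad)
    }
    if (!is.finite(ll)) return(1e10)
    -ll
  }

  if (effects == "mixed" && is.null(start)) {
    # warm-start the marginal likelihood at the fixed-effects optimum with
    # moment-based random-effect SDs; the fixed fit absorbs between-stand
    # spread into the diffusion, so deflate those rates at the start
    ffit <- sde_fit(data, model, "fixed", init, se = FALSE)
    fe <- ffit$estimates
    nat <- fe
    if (model != "height") {
      nat[["sigma_d"]] <- start_re_sd(data$dbh_cm, tau, init$d0,
                                      fe[["alpha_d"]], fe[["beta_d"]], si$idx)
      nat[["sigma11"]] <- fe[["sigma11"]] * 0.6
    }
    if (model != "dbh") {
      nat[["sigma_h"]] <- start_re_sd(data$height_m, tau, init$h0,
                                      fe[["alpha_h"]], fe[["beta_h"]], si$idx)
      nat[["sigma22"]] <- fe[["sigma22"]] * 0.6
    }
    start <- nat[nms]
  }
  starts <- build_starts(data, model, effects, init, tau, si$idx, start, quad)
  best <- NULL
  for (s in starts) {
    opt <- tryCatch(
      stats::nlminb(s, negll,
                    control = list(iter.max = 1000, eval.max = 2000)),
      error = function(e) NULL)
    if (is.null(opt)) next
    if (is.null(best) || opt$objective < best$objective) best <- opt
  }
  if (is.null(best)) stop_numerical("all optimisation starts failed")

  nat <- trans_to_nat(best$par, model, effects)
  ll <- -best$objective
  k <- length(nms)
  se_nat <- NULL
  if (se) {
    H <- tryCatch(stats::optimHess(best$par, negll), error = function(e) NULL)
    if (!is.null(H) && all(is.finite(H)) &&
        all(eigen(H, symmetric = TRUE, only.values = TRUE)$values > 0)) {
      cov_t <- solve(H)
      J <- jacobian_nat(best$par, model, effects)
      cov_n <- J %*% cov_t %*% t(J)
      se_nat <- stats::setNames(sqrt(pmax(diag(cov_n), 0)), nms)
    }
  }
  structure(list(model = model, effects = effects,
                 estimates = nat, std_errors = se_nat,
                 loglik = ll, aic = -2 * ll, aic_penalized = -2 * ll + 2 * k,
                 converged = best$convergence == 0, n_obs = nrow(data),
                 n_stands = si$M, iterations = best$iterations,
                 init = init, quad = quad, message = best$message),
            class = "sde_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

build_starts <- function(data, model, effects, init, tau, idx, start, quad) {
  if (!is.null(start)) {
    nms <- par_names(model, effects)
    miss <- setdiff(nms, names(start))
    if (length(miss))
      stop_validation("start values missing: ", paste(miss, collapse = ", "))
    return(list(nat_to_trans(start[nms], model, effects)))
  }
  beta_grid <- c(0.01, 0.03, 0.08)
  if (model != "bivariate") {
    x <- if (model == "dbh") data$dbh_cm else data$height_m
    x0 <- if (model == "dbh") init$d0 else init$h0
    lapply(beta_grid, function(b) {
      s <- start_uni(x, tau, x0, b)
      nat <- stats::setNames(s, par_names(model, "fixed"))
      if (effects == "mixed") {
        re0 <- start_re_sd(x, tau, x0, s[["alpha"]], b, idx)
        nat <- c(nat, stats::setNames(re0,
                   if (model == "dbh") "sigma_d" else "sigma_h"))
        # between-stand spread sits in the fixed-fit diffusion; deflate it
        nat[[3L]] <- nat[[3L]] * 0.6
      }
      nat_to_trans(nat, model, effects)
    })
  } else {
    lapply(beta_grid, function(b) {
      sd_ <- start_uni(data$dbh_cm, tau, init$d0, b)
      sh_ <- start_uni(data$height_m, tau, init$h0, b * 1.2)
      kd <- 1 - exp(-b * tau); kh <- 1 - exp(-b * 1.2 * tau)
      rd <- data$dbh_cm - (sd_[["alpha"]] * kd + init$d0 * (1 - kd))
      rh <- data$height_m - (sh_[["alpha"]] * kh + init$h0 * (1 - kh))
      rho <- max(-0.9, min(0.9, stats::cor(rd, rh)))
      nat <- c(alpha_d = sd_[["alpha"]], beta_d = b, sigma11 = sd_[["sigma"]],
               alpha_h = sh_[["alpha"]], beta_h = b * 1.2,
               sigma22 = sh_[["sigma"]],
               sigma12 = rho * sqrt(sd_[["sigma"]] * sh_[["sigma"]]))
      if (effects == "mixed") {
        nat <- c(nat,
                 sigma_d = start_re_sd(data$dbh_cm, tau, init$d0,
                                       sd_[["alpha"]], b, idx),
                 sigma_h = start_re_sd(data$height_m, tau, init$h0,
                                       sh_[["alpha"]], b * 1.2, idx))
        nat[["sigma11"]] <- nat[["sigma11"]] * 0.6
        nat[["sigma22"]] <- nat[["sigma22"]] * 0.6
      }
      nat_to_trans(nat, model, effects)
    })
  }
}

# numerical Jacobian d(natural)/d(transformed), central differences
jacobian_nat <- function(par, model, effects, eps = 1e-5) {
  p <- length(par)
  J <- matrix(0, p, p)
  for (j in seq_len(p)) {
    up <- par; up[j] <- up[j] + eps
    dn <- par; dn[j] <- dn[j] - eps
    J[, j] <- (trans_to_nat(up, model, effects) -
                 trans_to_nat(dn, model, effects)) / (2 * eps)
  }
  J
}

#' @export
print.sde_fit <- function(x, ...) {
  cat(sprintf("%s %s-effects diffusion fit (%d trees, %d stands)\n",
              switch(x$model, bivariate = "Bivariate", dbh = "Univariate dbh",
                     height = "Univariate height"),
              x$effects, x$n_obs, x$n_stands))
  est <- x$estimates
  se <- x$std_errors
  for (nm in names(est))
    cat(sprintf("  %-8s %12.5f%s\n", nm, est[[nm]],
                if (!is.null(se)) sprintf("  (%.5f)", se[[nm]]) else ""))
  cat(sprintf("  loglik %.2f  AIC (-2LL) %.1f  converged: %s\n",
              x$loglik, x$aic, x$converged))
  invisible(x)
}

#' Model comparison index
#'
#' `-2 * loglik`, the comparison index used alongside the fits (smaller is
#' better); `penalized = TRUE` adds the conventional `2k` parameter-count
#' penalty.
#'
#' @param fit An `sde_fit` (or `tree_count_fit`) object.
#' @param penalized Add `2 * (number of parameters)`?
#' @return Scalar index.
#' @export
aic_index <- function(fit, penalized = FALSE) {
  if (penalized) fit$aic_penalized else fit$aic
}

#' Export a fit as a parameter file plus report
#'
#' Writes the fitted parameters in the flat JSON layout of [read_params()]
#' (unfitted components fall back to the supplied defaults) together with a
#' fit report (log-likelihood, comparison index, standard errors,
#' convergence).
#'
#' @param fit An `sde_fit`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_fit <- function(fit, path) {
  est <- as.list(fit$estimates)
  full <- list(alpha_d = est$alpha_d %||% NA, beta_d = est$beta_d %||% NA,
               alpha_h = est$alpha_h %||% NA, beta_h = est$beta_h %||% NA,
               sigma11 = est$sigma11 %||% NA, sigma12 = est$sigma12 %||% 0,
               sigma22 = est$sigma22 %||% NA,
               sigma_d = est$sigma_d %||% 0, sigma_h = est$sigma_h %||% 0,
               t0 = fit$init$t0, d0 = fit$init$d0, h0 = fit$init$h0)
  report <- list(model = fit$model, effects = fit$effects,
                 loglik = fit$loglik, aic = fit$aic,
                 aic_penalized = fit$aic_penalized,
                 std_errors = as.list(fit$std_errors),
                 converged = fit$converged, n_obs = fit$n_obs,
                 n_stands = fit$n_stands)
  jsonlite::write_json(c(full, list(fit_report = report)), path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
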