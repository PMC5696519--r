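#' Calibrate a stand's random effects from measured trees
#'
#' Predicts the asymptote shifts `(phi_d, phi_h)` of a new stand from a few
#' measured trees by inverting the mean curve per tree and averaging:
#' `phi_hat = (1/m) * sum_j (x_j - alpha - (x0 - alpha) * exp(-beta *
#' tau_j)) / (1 - exp(-beta * tau_j))` for each trait, with `tau_j` the
#' tree's age above `t0`. On noise-free trees this inversion is exact; it
#' applies no shrinkage toward zero for small tree counts.
#'
#' @param params An [sde_params] object (the fitted population parameters).
#' @param init An [initial_state].
#' @param trees Data frame with columns `age_years`, `dbh_cm`, `height_m`
#'   (one stand's trees); per-tree ages are used as given.
#' @return An object of class `calibrated_stand`: list with `phi_d` (cm),
#'   `phi_h` (m), `m_trees`.
#' @examples
#' ref <- scots_pine_params()
#' tr <- data.frame(age_years = c(60, 70), dbh_cm = c(30, 33),
#'                  height_m = c(24, 25))
#' calibrate_stand(ref$params, ref$init, tr)
#' @export
calibrate_stand <- function(params, init, trees) {
  stopifnot(inherits(params, "sde_params"), inherits(init, "initial_state"))
  if (is.null(trees) || nrow(trees) == 0L)
    stop_data("calibration requires at least one measured tree")
  tau <- trees$age_years - init$t0
  if (any(tau <= 0))
    stop_data("calibration requires all tree ages > t0 = ", init$t0,
              " (degenerate denominator otherwise)")
  inv <- function(x, alpha, beta, x0) {
    e <- exp(-beta * tau)
    mean((x - alpha - (x0 - alpha) * e) / (1 - e))
  }
  structure(list(
    phi_d = inv(trees$dbh_cm, params$alpha_d, params$beta_d, init$d0),
    phi_h = inv(trees$height_m, params$alpha_h, params$beta_h, init$h0),
    m_trees = nrow(trees)), class = "calibrated_stand")
}

#' @export
print.calibrated_stand <- function(x, ...) {
  cat(sprintf("Calibrated stand effects (m = %d trees): phi_d = %.3f cm, phi_h = %.3f m\n",
              x$m_trees, x$phi_d, x$phi_h))
  invisible(x)
}

#' Calibrate every stand of a dataset
#'
#' @inheritParams calibrate_stand
#' @param data A [forest_dataset].
#' @return Data frame with `plot_id`, `phi_d`, `phi_h`, `m_trees`.
#' @export
calibrate_all <- function(params, init, data) {
  stopifnot(inherits(data, "forest_dataset"))
  ids <- unique(data$plot_id)
  out <- lapply(ids, function(id) {
    cs <- calibrate_stand(params, init, data[data$plot_id == id, ])
    data.frame(plot_id = id, phi_d = cs$phi_d, phi_h = cs$phi_h,
               m_trees = cs$m_trees)
  })
  do.call(rbind, out)
}

#' Mean diameter / height predictors
#'
#' The eight mean predictors of tree size at age `t`, named by trait and
#' model level: `d1`/`h1` marginal fixed-effects means; `d2`/`h2` add the
#' calibrated stand effects; `d3`/`h3` condition on the other measured
#' trait through the fixed-effects bivariate law; `d4`/`h4` condition
#' through the mixed law (calibrated effects in both the mean and the
#' conditioning trend). At `effects = (0, 0)` the mixed predictors collapse
#' to their fixed counterparts, and conditioning at the mean of the other
#' trait collapses `h4` to `h2` (and `d4` to `d2`).
#'
#' @param variant One of `"d1", "h1", "d2", "h2", "d3", "h3", "d4", "h4"`.
#' @param params An [sde_params].
#' @param t Age (years); vectorised for the marginal variants.
#' @param effects Calibrated stand effects (required for variants 2 and 4).
#' @param init An [initial_state].
#' @param d,h Conditioning diameter (cm) for `h3`/`h4`, height (m) for
#'   `d3`/`d4`.
#' @return Predicted mean diameter (cm) or height (m).
#' @export
predict_mean <- function(variant, params, t, effects = NULL,
                         init = initial_state(), d = NULL, h = NULL) {
  variant <- match.arg(variant, c("d1", "h1", "d2", "h2", "d3", "h3",
                                  "d4", "h4"))
  lvl <- substr(variant, 2, 2)
  trait <- substr(variant, 1, 1)
  if (lvl %in% c("2", "4") && is.null(effects))
    stop_validation("variant ", variant, " requires calibrated stand effects")
  if (lvl %in% c("3", "4")) {
    if (trait == "d" && is.null(h))
      stop_validation("variant ", variant, " requires the conditioning height h")
    if (trait == "h" && is.null(d))
      stop_validation("variant ", variant, " requires the conditioning diameter d")
    if (any(t <= init$t0))
      stop_validation("conditional variants require t > t0")
  }
  if (inherits(effects, "calibrated_stand"))
    effects <- c(effects$phi_d, effects$phi_h)
  eff <- if (lvl %in% c("1", "3")) c(0, 0) else as_effects(effects)
  if (lvl %in% c("1", "2")) {
    m <- transition_mean(params, t, eff, init)
    return(if (trait == "d") m$mu_d else m$mu_h)
  }
  if (length(t) != 1L)
    stop_validation("conditional variants take a single age")
  if (trait == "d") conditional_diameter(h, t, params, eff, init)$m
  else conditional_height(d, t, params, eff, init)$m
}

#' Prediction-quality indexes
#'
#' Summary indexes of predicted vs observed values: mean bias
#' `B = mean(y - yhat)`, percentage bias `PB = mean((y - yhat)/y) * 100`,
#' absolute bias `AB = mean(|y - yhat|)` and its percentage form `PAB`,
#' adjusted root-mean-square error
#' `AE = sqrt(B^2 + sum((y - yhat - B)^2) / (n - 1))` and adjusted
#' coefficient of determination
#' `R2 = 1 - ((n - 1) / (n - p)) * sum((y - yhat)^2) / sum((y - ybar)^2)`,
#' where `p` is the number of model parameters (7 for the fixed-effects
#' model variants, 9 for the mixed ones).
#'
#' @param observed Observed values.
#' @param predicted Predicted values (same length).
#' @param p Number of model parameters used by `R2` (default 9).
#' @return An object of class `prediction_indexes`: list with `B`, `PB`,
#'   `AB`, `PAB`, `AE`, `R2`, `n`, `p`.
#' @examples
#' prediction_indexes(c(10, 20), c(11, 19), p = 0)
#' @export
prediction_indexes <- function(observed, predicted, p = 9) {
  n <- length(observed)
  if (length(predicted) != n)
    stop_data("observed and predicted lengths differ")
  if (n <= p) stop_data("need n > p observations")
  if (any(observed == 0))
    stop_data("zero observed value(s) at position(s) ",
              paste(which(observed == 0), collapse = ", "),
              "; percentage indexes undefined")
  e <- observed - predicted
  B <- mean(e)
  structure(list(
    B = B,
    PB = mean(e / observed) * 100,
    AB = mean(abs(e)),
    PAB = mean(abs(e / observed)) * 100,
    AE = sqrt(B^2 + sum((e - B)^2) / (n - 1)),
    R2 = 1 - (n - 1) / (n - p) * sum(e^2) / sum((observed - mean(observed))^2),
    n = n, p = p), class = "prediction_indexes")
}

#' @export
print.prediction_indexes <- function(x, ...) {
  cat(sprintf("Prediction indexes (n = %d, p = %d)\n", x$n, x$p))
  cat(sprintf("  B = %.4f (PB %.2f%%)  AB = %.4f (PAB %.2f%%)  AE = %.4f  R2 = %.4f\n",
              x$B, x$PB, x$AB, x$PAB, x$AE, x$R2))
  invisible(x)
}
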