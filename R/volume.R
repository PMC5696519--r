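#' Stem volume power equation
#'
#' Individual stem volume as a power function of diameter and height,
#' `V(d, h) = beta1 * d^beta2 * h^beta3` (m^3 for d in cm, h in m).
#'
#' @param beta1 Scale coefficient, positive.
#' @param beta2 Diameter exponent, positive.
#' @param beta3 Height exponent, positive.
#' @return An object of class `volume_params`.
#' @export
volume_params <- function(beta1, beta2, beta3) {
  if (!all(is.finite(c(beta1, beta2, beta3))) || beta1 <= 0 || beta2 <= 0 ||
      beta3 <= 0)
    stop_validation("volume coefficients must be finite and positive")
  structure(list(beta1 = beta1, beta2 = beta2, beta3 = beta3),
            class = "volume_params")
}

#' Reference stem-volume coefficients for Scots pine
#'
#' Weighted-least-squares estimates of the power volume equation for Scots
#' pine: `beta1 = 5.8e-5`, `beta2 = 1.8801`, `beta3 = 0.9723`.
#'
#' @return A [volume_params] object.
#' @export
scots_pine_volume <- function() volume_params(5.8e-5, 1.8801, 0.9723)

#' @rdname volume_params
#' @param d Diameter (cm); vectorised.
#' @param h Height (m); vectorised.
#' @param vol A `volume_params` object.
#' @return `stem_volume()` returns volumes in m^3.
#' @examples
#' stem_volume(27.24, 22.07, scots_pine_volume())
#' @export
stem_volume <- function(d, h, vol) {
  stopifnot(inherits(vol, "volume_params"))
  vol$beta1 * d^vol$beta2 * h^vol$beta3
}

#' Fit the stem volume power equation by weighted least squares
#'
#' Minimises `sum(w_i * (V_i - beta1 * d_i^beta2 * h_i^beta3)^2)`,
#' initialised from the log-linear OLS fit. The default weights
#' `w_i = d_i^-2` down-weight large stems, the classical variance model for
#' stem-volume data; weights are scale-invariant (doubling all weights
#' leaves the estimates unchanged).
#'
#' @param dbh Diameters (cm), positive.
#' @param height Heights (m), positive.
#' @param volume Stem volumes (m^3), positive.
#' @param weights Optional positive weights (default `dbh^-2`).
#' @return An object of class `volume_fit`: list with `estimates`
#'   ([volume_params]), `std_errors`, `converged`, `n_obs`.
#' @export
fit_volume_regression <- function(dbh, height, volume, weights = NULL) {
  n <- length(volume)
  if (n < 4) stop_data("volume regression needs at least 4 records")
  if (length(dbh) != n || length(height) != n)
    stop_data("dbh, height, volume must have equal lengths")
  if (any(dbh <= 0) || any(height <= 0) || any(volume <= 0))
    stop_data("volume regression requires positive dbh, height and volume")
  if (is.null(weights)) weights <- dbh^-2
  if (any(weights <= 0)) stop_data("weights must be positive")
  ols <- stats::lm(log(volume) ~ log(dbh) + log(height))
  st <- list(b1 = exp(stats::coef(ols)[[1]]), b2 = stats::coef(ols)[[2]],
             b3 = stats::coef(ols)[[3]])
  df <- data.frame(d = dbh, h = height, v = volume)
  nfit <- tryCatch(
    minpack.lm::nlsLM(v ~ b1 * d^b2 * h^b3, data = df, start = st,
                      weights = weights,
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) stop_numerical("volume regression failed: ",
                                       conditionMessage(e)))
  cf <- stats::coef(nfit)
  se <- tryCatch(summary(nfit)$coefficients[, "Std. Error"],
                 error = function(e) NULL)
  structure(list(estimates = volume_params(cf[["b1"]], cf[["b2"]], cf[["b3"]]),
                 std_errors = se, converged = nfit$convInfo$isConv,
                 n_obs = n),
            class = "volume_fit")
}

#' @export
print.volume_fit <- function(x, ...) {
  e <- x$estimates
  cat(sprintf(
    "Stem volume power fit (n = %d): V = %.4g * d^%.4f * h^%.4f\n",
    x$n_obs, e$beta1, e$beta2, e$beta3))
  invisible(x)
}
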