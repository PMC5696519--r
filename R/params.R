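#' Drift and diffusion parameters of the bivariate Vasicek diffusion
#'
#' Bundles the seven fixed-effect parameters of the bivariate mean-reverting
#' stochastic differential equation for diameter at breast height (dbh, cm)
#' and total height (m): the asymptotes `alpha_d`, `alpha_h`, the
#' mean-reversion rates `beta_d`, `beta_h` (1/yr) and the diffusion matrix
#' entries `sigma11` (cm^2/yr), `sigma22` (m^2/yr), `sigma12` (cm*m/yr).
#'
#' The diffusion matrix `B = [[sigma11, sigma12], [sigma12, sigma22]]` must be
#' positive definite; parameter sets with `sigma12^2 >= sigma11 * sigma22` are
#' rejected with a diagnostic rather than silently projected.
#'
#' @param alpha_d Asymptotic mean diameter (cm).
#' @param beta_d Diameter mean-reversion rate (1/yr), positive.
#' @param sigma11 Diameter diffusion variance rate (cm^2/yr), positive.
#' @param alpha_h Asymptotic mean height (m).
#' @param beta_h Height mean-reversion rate (1/yr), positive.
#' @param sigma22 Height diffusion variance rate (m^2/yr), positive.
#' @param sigma12 Cross diffusion rate (cm*m/yr); defaults to 0.
#' @return An object of class `sde_params` (named list).
#' @seealso [initial_state()], [re_variances()], [scots_pine_params()]
#' @examples
#' p <- sde_params(alpha_d = 35.9, beta_d = 0.029, sigma11 = 2.37,
#'                 alpha_h = 26.0, beta_h = 0.036, sigma22 = 0.36,
#'                 sigma12 = 0.63)
#' p
#' @export
sde_params <- function(alpha_d, beta_d, sigma11, alpha_h, beta_h, sigma22,
                       sigma12 = 0) {
  p <- list(alpha_d = alpha_d, beta_d = beta_d, sigma11 = sigma11,
            alpha_h = alpha_h, beta_h = beta_h, sigma22 = sigma22,
            sigma12 = sigma12)
  vals <- unlist(p)
  if (!all(is.finite(vals)))
    stop_validation("non-finite SDE parameter(s): ",
                    paste(names(p)[!is.finite(vals)], collapse = ", "))
  if (beta_d <= 0 || beta_h <= 0)
    stop_validation("mean-reversion rates beta_d, beta_h must be positive")
  if (sigma11 <= 0 || sigma22 <= 0)
    stop_validation("diffusion variance rates sigma11, sigma22 must be positive")
  disc <- sigma12^2 - sigma11 * sigma22
  if (disc >= 0)
    stop_validation(sprintf(
      "diffusion matrix not positive definite: sigma12^2 - sigma11*sigma22 = %g >= 0",
      disc))
  structure(p, class = "sde_params")
}

#' @export
print.sde_params <- function(x, ...) {
  cat("Bivariate Vasicek SDE parameters\n")
  cat(sprintf("  diameter: alpha = %.4f cm, beta = %.5f /yr, sigma11 = %.4f cm^2/yr\n",
              x$alpha_d, x$beta_d, x$sigma11))
  cat(sprintf("  height:   alpha = %.4f m,  beta = %.5f /yr, sigma22 = %.4f m^2/yr\n",
              x$alpha_h, x$beta_h, x$sigma22))
  cat(sprintf("  cross diffusion sigma12 = %.4f cm*m/yr\n", x$sigma12))
  invisible(x)
}

#' Initial condition of the diffusion
#'
#' Age and sizes at which every tree's trajectory starts. Trees are assumed
#' to reach breast height (1.30 m) at age `t0`, so the default is
#' `t0 = 5`, `d0 = 0` cm, `h0 = 1.3` m.
#'
#' @param t0 Initial age (years), non-negative.
#' @param d0 Initial diameter (cm), non-negative.
#' @param h0 Initial height (m), non-negative.
#' @return An object of class `initial_state`.
#' @export
initial_state <- function(t0 = 5, d0 = 0, h0 = 1.3) {
  if (!all(is.finite(c(t0, d0, h0))) || t0 < 0 || d0 < 0 || h0 < 0)
    stop_validation("initial state requires finite t0 >= 0, d0 >= 0, h0 >= 0")
  structure(list(t0 = t0, d0 = d0, h0 = h0), class = "initial_state")
}

#' Random-effect standard deviations
#'
#' Between-stand variability of the asymptotes: the stand-specific effects
#' `phi_d ~ N(0, sigma_d^2)` and `phi_h ~ N(0, sigma_h^2)` shift the
#' diameter and height asymptotes of a stand. Zero SDs reduce the model to
#' its fixed-effects form.
#'
#' @param sigma_d SD of the diameter asymptote effect (cm), non-negative.
#' @param sigma_h SD of the height asymptote effect (m), non-negative.
#' @return An object of class `re_variances`.
#' @export
re_variances <- function(sigma_d = 0, sigma_h = 0) {
  if (!all(is.finite(c(sigma_d, sigma_h))) || sigma_d < 0 || sigma_h < 0)
    stop_validation("random-effect SDs must be finite and non-negative")
  structure(list(sigma_d = sigma_d, sigma_h = sigma_h), class = "re_variances")
}

#' Stand-level random effects
#'
#' A single stand's shifts of the diameter and height asymptotes;
#' `(0, 0)` denotes the population-average stand.
#'
#' @param phi_d Diameter asymptote shift (cm).
#' @param phi_h Height asymptote shift (m).
#' @return An object of class `random_effects`.
#' @export
random_effects <- function(phi_d = 0, phi_h = 0) {
  if (!all(is.finite(c(phi_d, phi_h))))
    stop_validation("random effects must be finite")
  structure(list(phi_d = phi_d, phi_h = phi_h), class = "random_effects")
}

#' Reference parameter set for Scots pine stands
#'
#' The bivariate mixed-effects parameter estimates for Scots pine
#' (national-forest-inventory scale) used as the package's reference
#' conditions: drift/diffusion parameters, random-effect SDs
#' (`sigma_d = 5.9592` cm, `sigma_h = 3.6830` m) and the breast-height
#' initial condition. Used as the default configuration of the synthetic
#' inventory generator and throughout the examples.
#'
#' @return A list with components `params` ([sde_params]), `re_vars`
#'   ([re_variances]) and `init` ([initial_state]).
#' @examples
#' ref <- scots_pine_params()
#' transition_mean(ref$params, t = 65, init = ref$init)
#' @export
scots_pine_params <- function() {
  list(params = sde_params(alpha_d = 35.9030, beta_d = 0.0293, sigma11 = 2.3736,
                           alpha_h = 26.0039, beta_h = 0.0363, sigma22 = 0.3615,
                           sigma12 = 0.6334),
       re_vars = re_variances(sigma_d = 5.9592, sigma_h = 3.6830),
       init = initial_state(5, 0, 1.3))
}

# ---- condition helpers ------------------------------------------------------

stop_validation <- function(...) {
  stop(errorCondition(paste0(...), class = c("standsde_validation_error",
                                             "standsde_error")))
}

stop_numerical <- function(...) {
  stop(errorCondition(paste0(...), class = c("standsde_numerical_error",
                                             "standsde_error")))
}

stop_data <- function(...) {
  stop(errorCondition(paste0(...), class = c("standsde_data_error",
                                             "standsde_validation_error",
                                             "standsde_error")))
}

as_effects <- function(effects) {
  if (is.null(effects)) return(c(phi_d = 0, phi_h = 0))
  if (inherits(effects, "random_effects"))
    return(c(phi_d = effects$phi_d, phi_h = effects$phi_h))
  if (is.numeric(effects) && length(effects) == 2) {
    if (!all(is.finite(effects))) stop_validation("random effects must be finite")
    return(c(phi_d = effects[[1]], phi_h = effects[[2]]))
  }
  stop_validation("'effects' must be a random_effects object or a numeric pair")
}

# ---- JSON parameter files ---------------------------------------------------

#' Read / write model parameter files
#'
#' Flat JSON files carry the full model configuration with keys
#' `alpha_d, beta_d, alpha_h, beta_h, sigma11, sigma12, sigma22` plus the
#' optional random-effect SDs `sigma_d, sigma_h` (default 0) and the initial
#' condition `t0, d0, h0` (defaults 5, 0, 1.3).
#'
#' @param path File path.
#' @return `read_params()` returns a list with `params`, `re_vars`, `init`;
#'   `write_params()` returns `path` invisibly.
#' @export
read_params <- function(path) {
  if (!file.exists(path)) stop_data("parameter file not found: ", path)
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("alpha_d", "beta_d", "alpha_h", "beta_h",
            "sigma11", "sigma12", "sigma22")
  miss <- setdiff(need, names(j))
  if (length(miss))
    stop_data("parameter file missing key(s): ", paste(miss, collapse = ", "))
  grab <- function(key, default) if (is.null(j[[key]])) default else j[[key]]
  list(params = sde_params(j$alpha_d, j$beta_d, j$sigma11,
                           j$alpha_h, j$beta_h, j$sigma22, j$sigma12),
       re_vars = re_variances(grab("sigma_d", 0), grab("sigma_h", 0)),
       init = initial_state(grab("t0", 5), grab("d0", 0), grab("h0", 1.3)))
}

#' @rdname read_params
#' @param params An [sde_params] object.
#' @param re_vars An [re_variances] object.
#' @param init An [initial_state] object.
#' @export
write_params <- function(path, params, re_vars = re_variances(),
                         init = initial_state()) {
  x <- c(unclass(params), unclass(re_vars), unclass(init))
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
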