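#' Draw trees exactly from the transition law
#'
#' i.i.d. draws of `(dbh, height)` from the bivariate Gaussian transition
#' law at age `t` for a stand with the given effects. This is the exact
#' sampler (no discretisation error); see [euler_maruyama_paths()] for the
#' path-wise cross-check.
#'
#' @inheritParams transition_mean
#' @param n Number of trees to draw.
#' @param seed Optional integer seed for reproducibility.
#' @return A data frame with numeric columns `dbh_cm`, `height_m`.
#' @examples
#' ref <- scots_pine_params()
#' head(sample_transition(ref$params, t = 50, init = ref$init, n = 5, seed = 1))
#' @export
sample_transition <- function(params, t, effects = NULL,
                              init = initial_state(), n, seed = NULL) {
  if (length(t) != 1L || t <= init$t0)
    stop_validation("sampling requires a single age t > t0")
  if (n < 1) stop_validation("n must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  st <- transition_state(params, t, effects, init)
  draw_state(st, n)
}

# internal: n draws from a transition_state via its closed-form Cholesky
draw_state <- function(st, n) {
  l11 <- sqrt(st$nu_d2)
  l21 <- st$nu_dh2 / l11
  l22 <- sqrt(st$nu_h2 - l21^2)
  z1 <- stats::rnorm(n)
  z2 <- stats::rnorm(n)
  data.frame(dbh_cm = st$mu_d + l11 * z1,
             height_m = st$mu_h + l21 * z1 + l22 * z2)
}

#' Simulate a multi-stand forest inventory
#'
#' Generates a synthetic inventory from the mixed-effects diffusion: each
#' stand receives asymptote shifts `phi_d ~ N(0, sigma_d^2)`,
#' `phi_h ~ N(0, sigma_h^2)`, and its trees are independent draws from the
#' bivariate transition law at their ages given those effects. The defaults
#' emulate single-visit national-forest-inventory plots of Scots pine: one
#' shared measurement age per plot drawn uniformly over 17-221 years, 3-10
#' measured trees per plot, and the reference parameters of
#' [scots_pine_params()].
#'
#' Tree sizes are kept exactly as drawn from the Gaussian law (which admits
#' occasional non-positive values at young ages) unless
#' `truncate_positive = TRUE`, which redraws them; the untruncated default
#' keeps the closed-form moments exact.
#'
#' A single master seed deterministically spawns one substream per stand, so
#' the same seed reproduces the same dataset.
#'
#' @param n_stands Number of stands (plots), >= 1.
#' @param trees_per_stand Either a single count or a length-2 integer range
#'   `c(min, max)` from which each plot's tree count is drawn uniformly.
#' @param age_range Length-2 range of stand ages (years), within `(t0, Inf)`.
#' @param ages `"shared"` (one age per plot, the default) or `"per-tree"`.
#' @param params,re_vars,init Model configuration; defaults to
#'   [scots_pine_params()].
#' @param seed Integer master seed.
#' @param truncate_positive Redraw non-positive simulated sizes?
#' @return A [forest_dataset] whose `true_effects` attribute records the
#'   simulated stand effects.
#' @examples
#' fd <- simulate_forest(n_stands = 5, seed = 42)
#' fd
#' @export
simulate_forest <- function(n_stands,
                            trees_per_stand = c(3, 10),
                            age_range = c(17, 221),
                            ages = c("shared", "per-tree"),
                            params = NULL, re_vars = NULL, init = NULL,
                            seed = NULL,
                            truncate_positive = FALSE) {
  ages <- match.arg(ages)
  ref <- scots_pine_params()
  if (is.null(params)) params <- ref$params
  if (is.null(re_vars)) re_vars <- ref$re_vars
  if (is.null(init)) init <- ref$init
  stopifnot(inherits(params, "sde_params"), inherits(re_vars, "re_variances"),
            inherits(init, "initial_state"))
  if (!is.numeric(n_stands) || n_stands < 1)
    stop_validation("n_stands must be >= 1")
  if (length(trees_per_stand) == 1L)
    trees_per_stand <- rep(trees_per_stand, 2L)
  if (any(trees_per_stand < 1))
    stop_validation("trees_per_stand must be >= 1")
  if (length(age_range) != 2L || age_range[1] <= init$t0)
    stop_validation("age_range must lie within (t0, Inf)")

  if (!is.null(seed)) set.seed(seed)
  stand_seeds <- sample.int(.Machine$integer.max, n_stands)

  rows <- vector("list", n_stands)
  eff <- data.frame(plot_id = sprintf("stand_%04d", seq_len(n_stands)),
                    phi_d = NA_real_, phi_h = NA_real_)
  for (i in seq_len(n_stands)) {
    set.seed(stand_seeds[i])
    phi <- c(stats::rnorm(1, 0, re_vars$sigma_d),
             stats::rnorm(1, 0, re_vars$sigma_h))
    ni <- if (trees_per_stand[1] == trees_per_stand[2]) trees_per_stand[1]
          else sample(seq(trees_per_stand[1], trees_per_stand[2]), 1L)
    t_i <- if (ages == "shared")
             rep(stats::runif(1, age_range[1], age_range[2]), ni)
           else stats::runif(ni, age_range[1], age_range[2])
    d <- numeric(ni); h <- numeric(ni)
    for (t_u in unique(t_i)) {
      sel <- which(t_i == t_u)
      st <- transition_state(params, t_u, phi, init)
      xy <- draw_state(st, length(sel))
      if (truncate_positive) {
        bad <- xy$dbh_cm <= 0 | xy$height_m <= 0
        guard <- 0L
        while (any(bad) && guard < 1000L) {
          xy[bad, ] <- draw_state(st, sum(bad))
          bad <- xy$dbh_cm <= 0 | xy$height_m <= 0
          guard <- guard + 1L
        }
      }
      d[sel] <- xy$dbh_cm; h[sel] <- xy$height_m
    }
    eff$phi_d[i] <- phi[1]; eff$phi_h[i] <- phi[2]
    rows[[i]] <- data.frame(plot_id = eff$plot_id[i],
                            tree_id = sprintf("t%03d", seq_len(ni)),
                            age_years = t_i, dbh_cm = d, height_m = h,
                            stringsAsFactors = FALSE)
  }
  forest_dataset(do.call(rbind, rows), true_effects = eff)
}

#' Euler-Maruyama path simulation of the diffusion
#'
#' Simulates sample paths of the bivariate SDE
#' `dX = beta * (a - X) dt + B^(1/2) dW` on a regular grid of step `dt`
#' from `t0` to `t_end`, using the closed-form 2x2 matrix square root of the
#' diffusion matrix. Serves as an independent cross-check of the exact
#' transition law: terminal moments converge to [transition_mean()] /
#' [transition_cov()] as `dt` shrinks.
#'
#' @inheritParams transition_mean
#' @param t_end Terminal age (years), `> t0`.
#' @param dt Time step (years), positive.
#' @param n_paths Number of independent paths.
#' @param seed Optional integer seed.
#' @return A data frame with terminal `dbh_cm`, `height_m` per path.
#' @export
euler_maruyama_paths <- function(params, effects = NULL,
                                 init = initial_state(), t_end, dt = 0.01,
                                 n_paths, seed = NULL) {
  stopifnot(inherits(params, "sde_params"))
  if (dt <= 0) stop_validation("dt must be positive")
  if (t_end <= init$t0) stop_validation("t_end must exceed t0")
  if (!is.null(seed)) set.seed(seed)
  phi <- as_effects(effects)
  ad <- params$alpha_d + phi[["phi_d"]]
  ah <- params$alpha_h + phi[["phi_h"]]
  # symmetric square root of B = [[s11, s12], [s12, s22]]
  s <- sqrt(params$sigma11 * params$sigma22 - params$sigma12^2)
  tr <- params$sigma11 + params$sigma22
  u <- sqrt(tr + 2 * s)
  b11 <- (params$sigma11 + s) / u
  b22 <- (params$sigma22 + s) / u
  b12 <- params$sigma12 / u
  n_steps <- ceiling((t_end - init$t0) / dt)
  dt_last <- (t_end - init$t0) - (n_steps - 1) * dt
  d <- rep(init$d0, n_paths)
  h <- rep(init$h0, n_paths)
  for (k in seq_len(n_steps)) {
    step <- if (k == n_steps) dt_last else dt
    sq <- sqrt(step)
    z1 <- stats::rnorm(n_paths)
    z2 <- stats::rnorm(n_paths)
    d_new <- d + params$beta_d * (ad - d) * step + sq * (b11 * z1 + b12 * z2)
    h <- h + params$beta_h * (ah - h) * step + sq * (b12 * z1 + b22 * z2)
    d <- d_new
  }
  data.frame(dbh_cm = d, height_m = h)
}
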