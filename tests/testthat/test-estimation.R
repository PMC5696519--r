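# Likelihoods and fitting: fixed/mixed marginal likelihoods, the volume
# regression and the trees-per-ha model.

test_that("fixed-effects log-likelihood equals the brute-force per-tree sum", {
  fd <- simulate_forest(8, trees_per_stand = 4, seed = 13)
  ll <- loglik_fixed(ref$params, fd, ref$init, model = "bivariate")
  brute <- sum(vapply(seq_len(nrow(fd)), function(i)
    dtransition(fd$dbh_cm[i], fd$height_m[i], fd$age_years[i], ref$params,
                init = ref$init, log = TRUE), 0))
  expect_equal(ll, brute, tolerance = 1e-12)
  # additivity: duplicating every tree doubles the log-likelihood
  fd2 <- forest_dataset(rbind(as.data.frame(fd), as.data.frame(fd)))
  expect_equal(loglik_fixed(ref$params, fd2, ref$init), 2 * ll,
               tolerance = 1e-12)
  # a tree exactly at the mean contributes the log mode height
  st <- transition_state(ref$params, 70, init = ref$init)
  one <- forest_dataset(data.frame(plot_id = "a", tree_id = "t1",
                                   age_years = 70, dbh_cm = st$mu_d,
                                   height_m = st$mu_h))
  det <- st$nu_d2 * st$nu_h2 - st$nu_dh2^2
  expect_equal(loglik_fixed(ref$params, one, ref$init),
               -log(2 * pi * sqrt(det)), tolerance = 1e-12)
  expect_error(loglik_fixed(ref$params,
                            forest_dataset(data.frame(plot_id = "a",
                                                      tree_id = "t",
                                                      age_years = 3,
                                                      dbh_cm = 1,
                                                      height_m = 1)),
                            ref$init),
               class = "standsde_data_error")
})

test_that("marginal likelihood collapses to the fixed one without random effects", {
  fd <- simulate_forest(10, trees_per_stand = 5, seed = 17)
  expect_identical(loglik_mixed(ref$params, re_variances(0, 0), fd, ref$init),
                   loglik_fixed(ref$params, fd, ref$init))
  # and approaches it continuously as the SDs shrink
  lf <- loglik_fixed(ref$params, fd, ref$init)
  lm1 <- loglik_mixed(ref$params, re_variances(1e-4, 1e-4), fd, ref$init)
  expect_equal(lm1, lf, tolerance = 1e-6)
})

test_that("one-stand one-tree marginal likelihood matches the Gaussian convolution", {
  # with sigma12 = 0 the effect enters each trait's mean linearly with
  # factor k(t) = 1 - exp(-beta tau), so marginalising inflates the
  # variance by k(t)^2 sigma^2 per trait
  p0 <- sde_params(35, 0.03, 2.4, 26, 0.04, 0.36, sigma12 = 0)
  rv <- re_variances(4, 2)
  t <- 80; d <- 30; h <- 21
  fd <- forest_dataset(data.frame(plot_id = "s", tree_id = "t1",
                                  age_years = t, dbh_cm = d, height_m = h))
  tau <- t - ref$init$t0
  v <- transition_cov(p0, t, ref$init)
  m <- transition_mean(p0, t, init = ref$init)
  kd <- 1 - exp(-p0$beta_d * tau); kh <- 1 - exp(-p0$beta_h * tau)
  closed <- stats::dnorm(d, m$mu_d, sqrt(v$nu_d2 + kd^2 * rv$sigma_d^2),
                         log = TRUE) +
    stats::dnorm(h, m$mu_h, sqrt(v$nu_h2 + kh^2 * rv$sigma_h^2), log = TRUE)
  expect_equal(loglik_mixed(p0, rv, fd, ref$init), closed, tolerance = 1e-8)
})

test_that("Gauss-Hermite marginal likelihood is stable in the node count", {
  fd <- simulate_forest(10, trees_per_stand = 5, seed = 19)
  l15 <- loglik_mixed(ref$params, ref$re_vars, fd, ref$init,
                      quad = quad_spec(nodes = 15))
  l25 <- loglik_mixed(ref$params, ref$re_vars, fd, ref$init,
                      quad = quad_spec(nodes = 25))
  l1 <- loglik_mixed(ref$params, ref$re_vars, fd, ref$init,
                     quad = quad_spec("laplace"))
  expect_equal(l15, l25, tolerance = 1e-8)
  # the integrand is Gaussian in the effects, so Laplace is exact too
  expect_equal(l1, l15, tolerance = 1e-8)
})

test_that("profile MLE at a single observation age matches the closed form", {
  # all trees at one age: for a fixed reversion rate the likelihood is a
  # plain Gaussian in (alpha, sigma11) with closed-form maximisers
  set.seed(23)
  t <- 75; n <- 400; beta <- 0.03
  tau <- t - ref$init$t0
  k <- 1 - exp(-beta * tau)
  g <- (1 - exp(-2 * beta * tau)) / (2 * beta)
  x <- rnorm(n, 30, 5)
  alpha_hat <- (mean(x) - ref$init$d0 * (1 - k)) / k
  s_hat <- mean((x - mean(x))^2) / g
  fd <- forest_dataset(data.frame(plot_id = "s", tree_id = seq_len(n),
                                  age_years = t, dbh_cm = x, height_m = 20))
  llmax <- -0.5 * n * log(2 * pi * s_hat * g) - 0.5 * n
  mk <- function(alpha, s) sde_params(alpha, beta, s, 26, 0.04, 0.36)
  expect_equal(loglik_fixed(mk(alpha_hat, s_hat), fd, ref$init, "dbh"),
               llmax, tolerance = 1e-10)
  # any perturbation lowers the likelihood
  expect_lt(loglik_fixed(mk(alpha_hat + 0.5, s_hat), fd, ref$init, "dbh"), llmax)
  expect_lt(loglik_fixed(mk(alpha_hat, s_hat * 1.1), fd, ref$init, "dbh"), llmax)
})

test_that("fitting is order-invariant and stable under refitting", {
  fd <- simulate_forest(60, trees_per_stand = 4, re_vars = re_variances(0, 0),
                        seed = 29)
  fit <- sde_fit(fd, model = "dbh", effects = "fixed", se = FALSE)
  perm <- sample(nrow(fd))
  fd_perm <- forest_dataset(as.data.frame(fd)[perm, ])
  fit_perm <- sde_fit(fd_perm, model = "dbh", effects = "fixed", se = FALSE)
  expect_equal(fit$estimates, fit_perm$estimates, tolerance = 1e-6)
  refit <- sde_fit(fd, model = "dbh", effects = "fixed",
                   start = fit$estimates, se = FALSE)
  expect_gte(refit$loglik, fit$loglik - 1e-6)
})

test_that("standard errors shrink roughly as 1/sqrt(n)", {
  fd_small <- simulate_forest(100, trees_per_stand = 4,
                              re_vars = re_variances(0, 0), seed = 37)
  fd_big <- simulate_forest(400, trees_per_stand = 4,
                            re_vars = re_variances(0, 0), seed = 37)
  se_s <- sde_fit(fd_small, "dbh", "fixed")$std_errors[["alpha_d"]]
  se_b <- sde_fit(fd_big, "dbh", "fixed")$std_errors[["alpha_d"]]
  expect_equal(se_b / se_s, 0.5, tolerance = 0.35)
})

test_that("comparison index is minus twice the log-likelihood", {
  fd <- simulate_forest(10, trees_per_stand = 4, seed = 41)
  fit <- sde_fit(fd, "dbh", "fixed", se = FALSE)
  expect_equal(fit$aic, -2 * fit$loglik)
  expect_equal(aic_index(fit), fit$aic)
  expect_equal(aic_index(fit, penalized = TRUE), fit$aic + 2 * 3)
})

test_that("volume regression recovers exact coefficients and is weight-scale invariant", {
  vol <- scots_pine_volume()
  set.seed(43)
  d <- runif(60, 10, 50); h <- runif(60, 8, 32)
  v <- stem_volume(d, h, vol)
  fit <- fit_volume_regression(d, h, v)
  expect_equal(fit$estimates$beta1, vol$beta1, tolerance = 1e-6)
  expect_equal(fit$estimates$beta2, vol$beta2, tolerance = 1e-6)
  expect_equal(fit$estimates$beta3, vol$beta3, tolerance = 1e-6)
  # the reference coefficients give ~0.586 m^3 at the mean-sized stem
  expect_equal(stem_volume(27.24, 22.07, vol), 0.5865971, tolerance = 1e-6)
  vn <- v * exp(rnorm(60, 0, 0.03))
  f1 <- fit_volume_regression(d, h, vn, weights = d^-2)
  f2 <- fit_volume_regression(d, h, vn, weights = 2 * d^-2)
  expect_equal(unlist(f1$estimates), unlist(f2$estimates), tolerance = 1e-8)
  expect_error(fit_volume_regression(d[1:3], h[1:3], v[1:3]),
               class = "standsde_data_error")
  expect_error(fit_volume_regression(-d, h, v),
               class = "standsde_data_error")
})

test_that("tree-count model recovers noise-free parameters and nests its variants", {
  tc <- scots_pine_tree_count("mixed")
  ages <- seq(20, 180, by = 10)
  counts <- data.frame(age = ages,
                       trees_per_ha = tree_count_mean_var(tc, t = ages)$mean)
  fit <- fit_tree_count(counts, "fixed")
  expect_equal(fit$estimates$alpha, tc$alpha, tolerance = 1e-4)
  expect_equal(fit$estimates$beta, tc$beta, tolerance = 1e-4)
  expect_equal(fit$estimates$delta, tc$delta, tolerance = 1e-4)
  # sigma_N = 0 marginal likelihood is exactly the fixed one
  set.seed(47)
  counts$trees_per_ha <- counts$trees_per_ha + rnorm(nrow(counts), 0, 20)
  p_fixed <- tree_count_params(2500, 0.001, 20, 95, sigma_N = 0)
  p_tiny <- tree_count_params(2500, 0.001, 20, 95, sigma_N = 1e-6)
  l0 <- loglik_tree_count(p_fixed, counts)
  expect_equal(loglik_tree_count(p_tiny, counts), l0, tolerance = 1e-6)
  expect_error(tree_count_mean_var(tc, t = 210),
               class = "standsde_validation_error")
})

test_that("mixed tree-count fit recovers the stand-effect spread", {
  tc <- tree_count_params(1500, 0.005, 10, 100, sigma_N = 300)
  set.seed(53)
  rows <- lapply(1:60, function(i) {
    phi <- rnorm(1, 0, tc$sigma_N)
    ages <- sort(runif(4, 30, 190))
    mv <- tree_count_mean_var(tc, phi, ages)
    data.frame(plot_id = i, age = ages,
               trees_per_ha = pmax(rnorm(4, mv$mean, sqrt(mv$var)), 0))
  })
  counts <- do.call(rbind, rows)
  fit <- fit_tree_count(counts, "mixed")
  expect_equal(fit$estimates$sigma_N, tc$sigma_N, tolerance = 0.35)
  expect_equal(fit$estimates$alpha, tc$alpha, tolerance = 0.25)
})
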