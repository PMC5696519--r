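Package: standsde
Title: Bivariate Vasicek Diffusion Models of Tree Diameter and Height Growth
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Models the joint evolution of tree diameter at breast height and
    total height in a forest stand as a bivariate mean-reverting (Vasicek /
    Ornstein-Uhlenbeck) stochastic differential equation with stand-level
    random effects on the asymptotes. Provides the closed-form Gaussian
    transition law (mean, covariance, joint, conditional and stationary
    densities), exact and Euler-Maruyama simulators of multi-stand
    inventories, maximum-likelihood estimation of the four model variants
    (univariate/bivariate, fixed/mixed effects) with adaptive Gauss-Hermite
    marginalisation of the random effects, random-effect calibration for new
    stands, height-diameter mean predictors, and integral stand attributes:
    slenderness ratio, stem-volume mean/SD/CV via a power volume equation,
    assortment fractions, trees-per-ha dynamics and stand volume per ha.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    pracma,
    minpack.lm
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
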