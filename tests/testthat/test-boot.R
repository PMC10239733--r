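# Parametric bootstrap: response simulation, prediction ensembles, products,
# percentile intervals, habitat-difference curves.

test_that("simulated responses have the fitted mean and variance structure", {
  dat <- simulate_traits(small_scenario(), seed = 81)
  fit <- allom_fit(dat)
  # zero-variance fit: simulation returns X beta exactly
  fit0 <- allom_fit(dat, fixed_varcomp = c(order = 0, family = 0, genus = 0,
                                           resid = 0))
  s0 <- simulate(fit0, nsim = 2, seed = 1)
  eta <- unname(drop(fit0$design$X %*% coef(fit0)))
  expect_equal(unname(s0[, 1]), eta, tolerance = 1e-12)
  expect_equal(unname(s0[, 2]), eta, tolerance = 1e-12)
  # determinism
  expect_identical(simulate(fit, nsim = 3, seed = 9),
                   simulate(fit, nsim = 3, seed = 9))
  # residual variance recovered by Monte Carlo at sigma2 = 0.04
  fitv <- allom_fit(dat, fixed_varcomp = c(order = 0, family = 0, genus = 0,
                                           resid = 0.04))
  n_tot <- 1000
  sims <- simulate(fitv, nsim = ceiling(n_tot / nrow(dat)), seed = 2,
                   use_random = FALSE)
  devs <- as.vector(sims) - rep(drop(fitv$design$X %*% coef(fitv)), ncol(sims))
  tol <- 3 * 0.04 * sqrt(2 / (length(devs) - 1))
  expect_lt(abs(var(devs) - 0.04), tol)
})

test_that("bootstrap ensembles have the right shape and are reproducible", {
  dat <- simulate_traits(trait_scenario("VT"), seed = 82)
  fit <- allom_fit(dat)
  ens <- allom_boot(fit, n_boot = 100, seed = 5)
  expect_equal(dim(ens$samples), c(26L, 100L))
  expect_true(ens$includes_random_effects)
  ens2 <- allom_boot(fit, n_boot = 100, seed = 5)
  expect_identical(ens$samples, ens2$samples)
  # n_boot = 1, refit = FALSE, zero variances -> the fitted values
  fit0 <- allom_fit(dat, fixed_varcomp = c(order = 0, family = 0, genus = 0,
                                           resid = 0))
  e0 <- allom_boot(fit0, n_boot = 1, seed = 1, refit = FALSE)
  expect_equal(unname(e0$samples[, 1]),
               unname(drop(fit0$design$X %*% coef(fit0))), tolerance = 1e-12)
})

test_that("products add paired samples on the log scale, bit for bit", {
  t1 <- data.frame(species = c("a", "b", "c"))
  a <- allom_ensemble(matrix(rnorm(12), 3, dimnames = list(t1$species)),
                      targets = t1, quantity = "SV")
  b <- allom_ensemble(matrix(rnorm(12), 3, dimnames = list(t1$species)),
                      targets = t1, quantity = "fH")
  pr <- boot_product(a, b)
  expect_identical(pr$samples, a$samples + b$samples)
  expect_equal(pr$quantity, "CO")
  # a single cell: log10 SV = 2, log10 fH = 1.5 -> log10 CO = 3.5
  ca <- allom_ensemble(matrix(2, 1, 1), quantity = "SV")
  cb <- allom_ensemble(matrix(1.5, 1, 1), quantity = "fH")
  expect_equal(boot_product(ca, cb)$samples[1, 1], 3.5)
  expect_equal(10^3.5, 3162.278, tolerance = 1e-6)
  # identity element: an all-zero log ensemble
  zero <- allom_ensemble(matrix(0, 3, 4, dimnames = list(t1$species)),
                         targets = t1, quantity = "unit")
  expect_identical(boot_product(a, zero)$samples, a$samples)
  # species products use the intersection of species
  b2 <- allom_ensemble(matrix(rnorm(8), 2, dimnames = list(c("b", "c"))),
                       targets = data.frame(species = c("b", "c")),
                       quantity = "fH")
  pr2 <- boot_product(a, b2)
  expect_equal(pr2$targets$species, c("b", "c"))
  expect_error(boot_product(a, allom_ensemble(matrix(rnorm(9), 3))),
               "n_boot")
})

test_that("percentile intervals use the Hazen rule and back-transform", {
  ens <- allom_ensemble(matrix(1:100, 1), quantity = "demo", scale = "linear")
  ci <- boot_ci(ens, level = 0.90)
  expect_equal(c(ci$lo, ci$hi), c(5.5, 95.5))
  expect_equal(ci$estimate, mean(1:100))
  # level 0.95 on 100 replicates: 2.5th/97.5th empirical percentiles
  ci95 <- boot_ci(ens, level = 0.95)
  expect_equal(c(ci95$lo, ci95$hi),
               unname(quantile(1:100, c(0.025, 0.975), type = 5)))
  # constant ensembles collapse
  cst <- allom_ensemble(matrix(2, 2, 50), quantity = "c")
  cc <- boot_ci(cst)
  expect_equal(cc$lo, cc$hi)
  expect_equal(cc$estimate, c(100, 100))  # back-transformed from log10
  expect_warning(boot_ci(allom_ensemble(matrix(1:10, 1))), "replicates")
  expect_true(all(cc$lo <= cc$hi))
})

test_that("zero-variance no-refit population ensembles give zero-width intervals", {
  dat <- simulate_traits(small_scenario(), seed = 83)
  fit <- allom_fit(dat)
  nd <- data.frame(body_mass_kg = c(50, 500),
                   habitat = c("aquatic", "terrestrial"))
  ens <- allom_boot(fit, n_boot = 30, seed = 2, refit = FALSE, newdata = nd)
  expect_false(ens$includes_random_effects)
  ci <- boot_ci(ens)
  expect_equal(ci$lo, ci$hi)
  # refitting widens them
  ensr <- allom_boot(fit, n_boot = 30, seed = 2, refit = TRUE, newdata = nd)
  cir <- boot_ci(ensr)
  expect_true(all(cir$hi > cir$lo))
})

test_that("minute ventilation at 100 kg is the order of the classical reference", {
  ffr <- allom_fit(simulate_traits(trait_scenario("fR"), seed = 84))
  fvt <- allom_fit(simulate_traits(trait_scenario("VT"), seed = 85))
  nd <- data.frame(body_mass_kg = 100, habitat = "terrestrial")
  e1 <- allom_boot(ffr, n_boot = 60, seed = 1, newdata = nd)
  e2 <- allom_boot(fvt, n_boot = 60, seed = 2, newdata = nd)
  mv <- boot_ci(boot_product(e1, e2))$estimate
  stahl <- power_law(c(379, 0.80), 100)
  expect_gt(mv / stahl, 0.2)
  expect_lt(mv / stahl, 5)
})

test_that("habitat-difference curves are paired, deterministic and labelled", {
  fsv <- suppressWarnings(
    allom_fit(simulate_traits(trait_scenario("SV"), seed = 86)))
  ffh <- allom_fit(simulate_traits(trait_scenario("fH"), seed = 87))
  grid <- 10^seq(log10(40), log10(2500), length.out = 7)
  d1 <- habitat_difference(fsv, ffh, mass_grid = grid, n_boot = 60, seed = 9)
  d2 <- habitat_difference(fsv, ffh, mass_grid = grid, n_boot = 60, seed = 9)
  expect_identical(as.data.frame(d1), as.data.frame(d2))
  expect_equal(d1$mass_kg, grid)
  expect_true(all(d1$lo <= d1$hi))
  expect_match(d1$quantity[1], "^CO_difference")
  expect_error(habitat_difference(fsv, ffh, mass_grid = numeric(0)), "empty")
  expect_warning(
    habitat_difference(fsv, ffh, mass_grid = c(5, 100), n_boot = 25, seed = 1,
                       refit = FALSE),
    "extrapolation")
})

test_that("identical population lines give an identically zero difference", {
  # exact zero habitat coefficients and no refitting: aquatic and terrestrial
  # predictors coincide, so the difference is 0 with CI (0, 0)
  sc <- small_scenario(beta = c(2, 0.7, 0, 0),
                       varcomp = c(order = 0, family = 0, genus = 0, resid = 0))
  dat <- simulate_traits(sc, seed = 88)
  fit <- allom_fit(dat, fixed_varcomp = c(order = 0, family = 0, genus = 0,
                                          resid = 0))
  # exact zeros, not numerically-zero OLS estimates of the habitat terms
  fit$coefficients[3:4] <- 0
  d <- suppressWarnings(
    habitat_difference(fit, fit, mass_grid = c(20, 200, 2000), n_boot = 25,
                       seed = 3, refit = FALSE))
  expect_equal(d$estimate, c(0, 0, 0), tolerance = 1e-6)
  expect_equal(d$lo, c(0, 0, 0), tolerance = 1e-6)
  expect_equal(d$hi, c(0, 0, 0), tolerance = 1e-6)
  expect_true(all(d$spans_zero))
})
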