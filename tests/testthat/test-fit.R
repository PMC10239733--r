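# The REML fit: exactness limits, oracle equivalence, invariances,
# agreement with an independent mixed-model implementation.

test_that("with all variance components fixed at zero the fit is OLS", {
  dat <- simulate_traits(small_scenario(), seed = 41)
  tr <- log10_transform(dat)
  fit <- allom_fit(dat, fixed_varcomp = c(order = 0, family = 0, genus = 0,
                                          resid = 0))
  ols <- lm(log10_value ~ log10_mass * habitat, data = tr)
  expect_equal(unname(coef(fit)), unname(coef(ols)), tolerance = 1e-8)
})

test_that("noise-free data are recovered exactly", {
  beta <- c(2.04, 0.66, -0.55, 0.17)
  sc <- small_scenario(beta = beta,
                       varcomp = c(order = 0, family = 0, genus = 0, resid = 0))
  dat <- simulate_traits(sc, seed = 6)
  fit <- allom_fit(dat)
  expect_equal(unname(coef(fit)), beta, tolerance = 1e-7)
  expect_true(any(fit$boundary))   # variances shrink to the zero boundary
})

test_that("the REML criterion matches an independent dense oracle at the optimum", {
  for (seed in 1:5) {
    sc <- small_scenario()
    dat <- simulate_traits(sc, seed = 200 + seed)
    fit <- allom_fit(dat)
    d <- fit$design
    oracle <- reml_loglik_oracle(unname(fit$varcomp), d$X, d$y, d$K)
    expect_equal(fit$reml_loglik, oracle, tolerance = 1e-6)
  }
})

test_that("the optimum beats a coarse grid over variance components", {
  sc <- scenario_params(c(2, 0.7, -0.4, 0.1),
                        varcomp = c(order = 0.02, family = 0, genus = 0,
                                    resid = 0.01),
                        shape = list(aquatic = c(2, 2, 3, 4),
                                     terrestrial = c(2, 3, 3, 6)),
                        mass_range = list(aquatic = c(10, 5000),
                                          terrestrial = c(10, 4000)))
  dat <- simulate_traits(sc, seed = 3)
  fit <- allom_fit(dat, levels = "order")
  d <- fit$design
  crit_opt <- -2 * fit$reml_loglik
  grid <- expand.grid(lo = seq(-8, 1, by = 0.5), le = seq(-8, 1, by = 0.5))
  crit_grid <- mapply(function(lo, le)
    -2 * reml_loglik_oracle(c(exp(lo), exp(le)), d$X, d$y, d$K),
    grid$lo, grid$le)
  expect_lte(crit_opt, min(crit_grid) + 1e-6)
})

test_that("estimates agree with lme4 on the same model", {
  dat <- simulate_traits(trait_scenario("BMR"), seed = 42)
  fit <- allom_fit(dat)
  tr <- log10_transform(dat)
  m <- lme4::lmer(log10_value ~ log10_mass * habitat +
                    (1 | order/family/genus),
                  data = tr, REML = TRUE,
                  control = lme4::lmerControl(check.conv.singular = "ignore"))
  expect_equal(unname(coef(fit)), unname(lme4::fixef(m)), tolerance = 1e-4)
  expect_equal(unname(fit$se),
               unname(sqrt(diag(as.matrix(vcov(m))))), tolerance = 1e-4)
  vc <- as.data.frame(lme4::VarCorr(m))
  expect_equal(sort(unname(fit$varcomp)), sort(vc$vcov), tolerance = 1e-4)
})

test_that("the fit is invariant to row permutation and group relabeling", {
  dat <- simulate_traits(small_scenario(), seed = 51)
  fit <- allom_fit(dat)
  perm <- withr::with_seed(1, sample(nrow(dat)))
  dat_p <- structure(as.data.frame(dat)[perm, ],
                     class = c("trait_data", "data.frame"), trait = "BMR")
  fit_p <- allom_fit(dat_p)
  expect_equal(coef(fit), coef(fit_p), tolerance = 1e-8)
  expect_equal(fit$varcomp, fit_p$varcomp, tolerance = 1e-6)

  relab <- as.data.frame(dat)
  relab$order <- paste0("zz_", relab$order)
  relab$genus <- toupper(relab$genus)
  fit_r <- allom_fit(structure(relab, class = c("trait_data", "data.frame"),
                               trait = "BMR"))
  expect_equal(unname(coef(fit)), unname(coef(fit_r)), tolerance = 1e-8)
  expect_equal(unname(fit$varcomp), unname(fit_r$varcomp), tolerance = 1e-6)
})

test_that("aliased nesting levels are dropped by the incidence check", {
  # one species per genus: genus variance is aliased with the residual
  sc <- scenario_params(c(2, 0.7, -0.4, 0.1),
                        shape = list(aquatic = c(2, 3, 6, 6),
                                     terrestrial = c(3, 4, 10, 10)),
                        mass_range = list(aquatic = c(10, 5000),
                                          terrestrial = c(10, 4000)))
  dat <- simulate_traits(sc, seed = 12)
  expect_warning(fit <- allom_fit(dat), "genus.*aliased")
  expect_false("genus" %in% fit$levels_included)
  expect_true(all(c("order", "family") %in% fit$levels_included))
  expect_named(fit$varcomp, c("order", "family", "resid"))
})

test_that("degenerate designs are refused with rank-deficiency errors", {
  dat <- simulate_traits(small_scenario(), seed = 14)
  dat$body_mass_kg <- 100
  expect_error(allom_fit(dat), "slope is unestimable")
  expect_error(allom_fit(dat[1, , drop = FALSE]), "at least 2 species")
})

test_that("conditional modes and fitted values are coherent", {
  dat <- simulate_traits(small_scenario(), seed = 61)
  fit <- allom_fit(dat)
  expect_equal(length(fit$conditional_modes$order),
               length(unique(dat$order)))
  # species-level fitted = population fitted + summed modes
  fp <- fitted(fit, level = "population")
  fs <- fitted(fit, level = "species")
  d <- fit$design
  add <- rep(0, nrow(d$X))
  for (lv in names(fit$conditional_modes))
    add <- add + drop(d$Z[[lv]] %*% fit$conditional_modes[[lv]])
  expect_equal(unname(fs - fp), unname(add))
  expect_equal(unname(residuals(fit)), unname(d$y - fs))
  # covariance is symmetric PSD and se = sqrt(diag)
  ev <- eigen(vcov(fit), symmetric = TRUE, only.values = TRUE)$values
  expect_true(all(ev > -1e-12))
  expect_equal(fit$se, sqrt(diag(vcov(fit))))
})
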