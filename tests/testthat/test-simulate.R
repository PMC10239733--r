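# Synthetic-data generator: composition, determinism, generative structure.

test_that("built-in scenarios reproduce the published taxonomic compositions", {
  expected <- list(
    BMR = c(orders = 13, families = 32, genera = 55, species = 63, aquatic = 20),
    fR  = c(orders = 7,  families = 25, genera = 62, species = 76, aquatic = 26),
    fH  = c(orders = 7,  families = 19, genera = 25, species = 42, aquatic = 20),
    SV  = c(orders = 5,  families = 11, genera = 15, species = 15, aquatic = 4),
    VT  = c(orders = 6,  families = 14, genera = 23, species = 26, aquatic = 13))
  for (tr in names(expected)) {
    dat <- simulate_traits(trait_scenario(tr), seed = 100 + match(tr, names(expected)))
    e <- expected[[tr]]
    expect_equal(length(unique(dat$order)), unname(e["orders"]), info = tr)
    expect_equal(length(unique(dat$family)), unname(e["families"]), info = tr)
    expect_equal(length(unique(dat$genus)), unname(e["genera"]), info = tr)
    expect_equal(nrow(dat), unname(e["species"]), info = tr)
    expect_equal(sum(dat$habitat == "aquatic"), unname(e["aquatic"]), info = tr)
    # habitat is assigned at the order level
    expect_true(all(tapply(dat$habitat, dat$order,
                           function(h) length(unique(h))) == 1), info = tr)
    # masses respect the per-habitat ranges
    rng <- trait_scenario(tr)$mass_range
    for (h in c("aquatic", "terrestrial")) {
      mh <- dat$body_mass_kg[dat$habitat == h]
      expect_true(all(mh >= rng[[h]][1] & mh <= rng[[h]][2]), info = tr)
    }
  }
})

test_that("generation is deterministic given the seed, with sub-streams", {
  sc <- trait_scenario("BMR")
  a <- simulate_traits(sc, seed = 77)
  b <- simulate_traits(sc, seed = 77)
  expect_identical(as.data.frame(a), as.data.frame(b))
  c2 <- simulate_traits(sc, seed = 78)
  expect_false(identical(a$value, c2$value))
  tax1 <- generate_taxonomy(sc$shape, seed = 5)
  tax2 <- generate_taxonomy(sc$shape, seed = 5)
  expect_identical(tax1, tax2)
})

test_that("minimal and degenerate shapes behave", {
  one <- generate_taxonomy(list(terrestrial = c(1, 1, 1, 1)), seed = 1)
  expect_equal(nrow(one), 1L)
  expect_error(generate_taxonomy(list(terrestrial = c(0, 0, 0, 0))),
               "zero species")
  expect_error(generate_taxonomy(list(terrestrial = c(3, 2, 4, 8)), seed = 1),
               "weakly increasing")
})

test_that("the noise-free limit puts every species exactly on its habitat line", {
  beta <- c(2.04, 0.66, -0.55, 0.17)
  sc <- small_scenario(beta = beta,
                       varcomp = c(order = 0, family = 0, genus = 0, resid = 0))
  dat <- simulate_traits(sc, seed = 4)
  tr <- log10_transform(dat)
  eq <- habitat_equations(beta)
  pred <- eq[as.character(tr$habitat), "intercept"] +
    eq[as.character(tr$habitat), "slope"] * tr$log10_mass
  expect_equal(unname(tr$log10_value), unname(pred), tolerance = 1e-12)
})

test_that("residual draws have the stated variance (Monte Carlo)", {
  # 500 species in one order, no taxonomic variance, sigma2_resid = 0.04:
  # the sample variance of OLS residuals estimates 0.04 within 3 SE,
  # SE(var) ~ sigma2 * sqrt(2/(n-1))
  sc <- scenario_params(c(2, 0.7, 0, 0),
                        varcomp = c(order = 0, family = 0, genus = 0,
                                    resid = 0.04),
                        shape = list(terrestrial = c(1, 1, 1, 500)),
                        mass_range = list(terrestrial = c(10, 4000)))
  dat <- simulate_traits(sc, seed = 21)
  tr <- log10_transform(dat)
  res <- residuals(lm(log10_value ~ log10_mass, data = tr))
  tol <- 3 * 0.04 * sqrt(2 / 499)
  expect_lt(abs(var(res) - 0.04), tol)
})

test_that("simulated log10 values decompose exactly into the drawn components", {
  dat <- simulate_traits(small_scenario(), seed = 31)
  cmp <- attr(dat, "components")
  recon <- cmp$linear_predictor + cmp$order + cmp$family + cmp$genus + cmp$resid
  expect_identical(unname(recon), unname(cmp$log10_value))
  expect_equal(log10(dat$value), unname(cmp$log10_value), tolerance = 1e-12)
})

test_that("a single-habitat scenario flags habitat terms as unestimable", {
  sc <- scenario_params(c(2, 0.7, 0, 0),
                        shape = list(terrestrial = c(3, 4, 6, 12)),
                        mass_range = list(terrestrial = c(10, 4000)))
  dat <- simulate_traits(sc, seed = 8)
  expect_equal(sum(dat$habitat == "aquatic"), 0L)
  expect_warning(fit <- allom_fit(dat), "unestimable")
  expect_false(fit$habitat_estimable)
  expect_named(coef(fit), c("(Intercept)", "log10_mass"))
  expect_error(wald_tests(fit), "single habitat")
})

test_that("species-level habitat assignment scrambles habitat within orders", {
  sc <- trait_scenario("BMR", habitat_level = "species")
  dat <- simulate_traits(sc, seed = 13)
  expect_equal(sum(dat$habitat == "aquatic"), 20L)
  mixed <- tapply(dat$habitat, dat$order, function(h) length(unique(h)))
  expect_gt(sum(mixed > 1), 0)
})
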