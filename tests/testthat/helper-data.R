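# Shared fixtures, built in code at test time.

# A small, fast scenario for tests that only need a valid two-habitat
# hierarchy, not the full published composition.
small_scenario <- function(beta = c(2, 0.7, -0.5, 0.15),
                           varcomp = c(order = 0.01, family = 0.005,
                                       genus = 0.0025, resid = 0.01),
                           trait = "BMR") {
  scenario_params(beta, varcomp = varcomp,
                  shape = list(aquatic = c(2, 3, 4, 6),
                               terrestrial = c(3, 4, 6, 10)),
                  mass_range = list(aquatic = c(10, 5000),
                                    terrestrial = c(10, 4000)),
                  trait = trait)
}

# Write a trait_data table to a temporary CSV as a user file would look.
write_trait_csv <- function(dat, path = tempfile(fileext = ".csv")) {
  utils::write.csv(as.data.frame(dat), path, row.names = FALSE)
  path
}

# Independent dense REML oracle: restricted log-likelihood evaluated as the
# Gaussian log density of Q2'y, where Q2 is an orthonormal basis of the
# orthogonal complement of col(X). Distinct algebra from the package's
# profiled block-wise criterion.
reml_loglik_oracle <- function(s2, X, y, K) {
  n <- nrow(X); p <- ncol(X); m <- length(K)
  V <- diag(max(s2[m + 1], 1e-12), n)
  for (l in seq_len(m)) V <- V + s2[l] * K[[l]]
  Q2 <- qr.Q(qr(X), complete = TRUE)[, -(seq_len(p)), drop = FALSE]
  W <- crossprod(Q2, V %*% Q2)
  yq <- drop(crossprod(Q2, y))
  -0.5 * ((n - p) * log(2 * pi) +
            as.numeric(determinant(W, logarithm = TRUE)$modulus) +
            sum(yq * solve(W, yq)))
}
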