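# Type II Wald chi-square tests respecting marginality: each term is tested
# by a linear hypothesis on the full-model coefficients that is adjusted for
# every term not containing it and ignores the terms that contain it (so main
# effects are assessed without the interaction's contribution; the interaction
# is tested last). Degrees of freedom are Wald chi-square throughout.

#' Type II Wald chi-square tests for the model terms
#'
#' Tests the contribution of log10 body mass, habitat, and their interaction.
#' For a term with hypothesis matrix H the statistic is
#' \eqn{\chi^2 = (H\hat\beta)' (H C H')^{-1} (H\hat\beta)} with
#' \eqn{C = vcov(\hat\beta)} and df = rank(H); H is constructed under the
#' Type II marginality convention. For the single-df interaction this reduces
#' to \eqn{(\hat\beta_{int}/SE_{int})^2}.
#'
#' @param fit An `"allom_fit"` with both habitats present.
#' @return A `data.frame` with columns `term`, `chi2`, `df`, `p_value`.
#' @export
wald_tests <- function(fit) {
  stopifnot(inherits(fit, "allom_fit"))
  if (!fit$habitat_estimable)
    stop("habitat terms unestimable (single habitat); no Type II tests",
         call. = FALSE)
  beta <- fit$coefficients
  V <- fit$cov_beta
  p <- length(beta)
  trm <- stats::terms(~ log10_mass * habitat)
  labels <- attr(trm, "term.labels")          # log10_mass, habitat, interaction
  fac <- attr(trm, "factors")  # one-sided formula: rows are the variables
  assign <- c(0L, 1L, 2L, 3L)                 # columns of X -> term index

  out <- lapply(seq_along(labels), function(j) {
    rel <- type2_relatives(j, fac)
    L <- type2_hypothesis(j, rel, assign, V, p)
    Lb <- drop(L %*% beta)
    chi2 <- drop(crossprod(Lb, solve(L %*% V %*% t(L), Lb)))
    df <- nrow(L)
    data.frame(term = labels[j], chi2 = chi2, df = df,
               p_value = stats::pchisq(chi2, df, lower.tail = FALSE))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

# Higher-order relatives of term j: terms whose factor set strictly contains
# term j's factors.
type2_relatives <- function(j, fac) {
  which(vapply(seq_len(ncol(fac)), function(k) {
    k != j && all(fac[, j] <= fac[, k]) && any(fac[, k] > fac[, j])
  }, logical(1)))
}

# Type II hypothesis matrix for term j (rows act on the coefficient vector):
# the complement of the relatives' rows within span(relatives + term), taken
# orthogonal under the vcov inner product.
type2_hypothesis <- function(j, relatives, assign, V, p) {
  I_p <- diag(p)
  rows_rel <- which(assign %in% relatives)
  rows_term <- which(assign == j)
  h2 <- I_p[c(rows_rel, rows_term), , drop = FALSE]
  if (!length(rows_rel)) return(h2)
  # columns of t(h2) V-orthogonal to columns of t(h1)
  X1 <- t(I_p[rows_rel, , drop = FALSE])
  Z2 <- t(h2)
  xq <- qr(t(Z2) %*% V %*% X1)
  L <- t(Z2 %*% qr.Q(xq, complete = TRUE)[, -seq_len(xq$rank), drop = FALSE])
  L
}

#' Type II Wald chi-square table
#'
#' `anova()` on a single `"allom_fit"` returns the Type II Wald chi-square
#' tests of [wald_tests()]. Model comparison between fits is not supported.
#'
#' @param object An `"allom_fit"`.
#' @param ... Unused.
#' @export
anova.allom_fit <- function(object, ...) {
  if (length(list(...)))
    stop("model comparison between allom_fit objects is not supported",
         call. = FALSE)
  tab <- wald_tests(object)
  structure(tab, heading = "Type II Wald chi-square tests",
            class = c("anova_allom", class(tab)))
}
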