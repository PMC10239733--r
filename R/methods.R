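# S3 methods for "allom_fit".

#' @export
print.allom_fit <- function(x, digits = 4, ...) {
  cat("Allometric mixed model (REML), trait:", x$trait, "\n")
  cat("  ", x$n_species, "species;",
      if (x$habitat_estimable) "both habitats" else "single habitat", "\n")
  cat("  random levels:",
      if (length(x$levels_included)) paste(x$levels_included, collapse = " > ")
      else "none",
      if (length(x$levels_dropped))
        paste0(" (dropped: ", paste(x$levels_dropped, collapse = ", "), ")")
      else "", "\n")
  cat("Fixed effects:\n")
  print(round(x$coefficients, digits))
  cat("Variance components (log10 scale):\n")
  vc <- x$varcomp
  flag <- ifelse(x$boundary, " (boundary)", "")
  cat(paste0("  ", names(vc), " = ", signif(vc, digits), flag, collapse = "\n"),
      "\n")
  cat("REML log-likelihood:", round(x$reml_loglik, digits), "\n")
  if (!x$converged) cat("WARNING: optimiser did not report convergence\n")
  invisible(x)
}

#' Summarise an allometric mixed-model fit
#'
#' @param object An `"allom_fit"`.
#' @param level Confidence level for the Wald intervals (default 0.95).
#' @param ... Unused.
#' @return A `"summary.allom_fit"`: coefficient table (estimate, SE, Wald
#'   confidence limits, z and p), Type II Wald chi-square table, variance
#'   components, and per-habitat allometric equations.
#' @export
summary.allom_fit <- function(object, level = 0.95, ...) {
  ci <- confint(object, level = level)
  z <- object$coefficients / object$se
  tab <- cbind(Estimate = object$coefficients, `Std. Error` = object$se,
               lo = ci[, 1], hi = ci[, 2], `z value` = z,
               `Pr(>|z|)` = 2 * stats::pnorm(-abs(z)))
  colnames(tab)[3:4] <- sprintf("%s %g%%", c("lower", "upper"), 100 * level)
  structure(list(fit = object, coefficients = tab,
                 wald = if (object$habitat_estimable) wald_tests(object),
                 equations = if (object$habitat_estimable)
                   habitat_equations(object),
                 level = level),
            class = "summary.allom_fit")
}

#' @export
print.summary.allom_fit <- function(x, digits = 4, ...) {
  print(x$fit, digits = digits)
  cat("\nCoefficients:\n")
  stats::printCoefmat(x$coefficients, digits = digits,
                      P.values = TRUE, has.Pvalue = TRUE, cs.ind = 1:2)
  if (!is.null(x$wald)) {
    cat("\nType II Wald chi-square tests:\n")
    print(x$wald, digits = digits)
  }
  if (!is.null(x$equations)) {
    cat("\nPer-habitat equations, log10(", x$fit$trait,
        ") = intercept + slope * log10(Mb):\n", sep = "")
    print(round(x$equations, digits))
  }
  invisible(x)
}

#' @export
coef.allom_fit <- function(object, ...) object$coefficients

#' @export
vcov.allom_fit <- function(object, ...) object$cov_beta

#' Wald confidence intervals for the fixed effects
#'
#' Intervals are \eqn{\hat\beta_i \pm z_{(1+level)/2}\,SE_i}. A zero SE gives
#' the degenerate interval \eqn{(\hat\beta_i, \hat\beta_i)}.
#'
#' @param object An `"allom_fit"`.
#' @param parm Coefficients to include (names or indices; default all).
#' @param level Confidence level in (0, 1).
#' @param ... Unused.
#' @export
confint.allom_fit <- function(object, parm, level = 0.95, ...) {
  if (!(is.numeric(level) && length(level) == 1 && level > 0 && level < 1))
    stop("level must be in (0, 1)", call. = FALSE)
  zq <- stats::qnorm((1 + level) / 2)
  est <- object$coefficients
  ci <- cbind(est - zq * object$se, est + zq * object$se)
  dimnames(ci) <- list(names(est),
                       sprintf("%.1f %%", 100 * c((1 - level) / 2,
                                                  (1 + level) / 2)))
  if (!missing(parm)) ci <- ci[parm, , drop = FALSE]
  ci
}

#' @export
logLik.allom_fit <- function(object, ...) {
  structure(object$reml_loglik,
            df = length(object$coefficients) + length(object$varcomp),
            class = "logLik")
}

#' @export
fitted.allom_fit <- function(object, level = c("species", "population"), ...) {
  level <- match.arg(level)
  eta <- drop(object$design$X %*% object$coefficients)
  if (level == "species")
    for (lv in names(object$conditional_modes))
      eta <- eta + drop(object$design$Z[[lv]] %*% object$conditional_modes[[lv]])
  setNames(eta, object$design$data$species)
}

#' @export
residuals.allom_fit <- function(object, level = c("species", "population"),
                                ...) {
  object$design$y - fitted(object, level = match.arg(level))
}

#' Predict log10 trait values from an allometric fit
#'
#' @param object An `"allom_fit"`.
#' @param newdata Optional `data.frame` with `habitat` and either
#'   `body_mass_kg` or `log10_mass`. New data are predicted at population
#'   level (random effects zero). With `newdata = NULL`, predictions are for
#'   the fitted species.
#' @param level `"species"` (includes conditional random-effect modes; only
#'   for the fitted data) or `"population"`.
#' @param se.fit Also return standard errors of the population-level linear
#'   predictor, \eqn{\sqrt{diag(X_0 C X_0')}}.
#' @param ... Unused.
#' @return Numeric vector of log10-scale predictions, or a list with `fit`
#'   and `se.fit`.
#' @export
predict.allom_fit <- function(object, newdata = NULL,
                              level = c("species", "population"),
                              se.fit = FALSE, ...) {
  level <- match.arg(level)
  if (is.null(newdata)) {
    eta <- fitted(object, level = level)
    X0 <- object$design$X
  } else {
    if (level == "species")
      stop("species-level predictions require newdata = NULL; ",
           "new data are predicted at population level", call. = FALSE)
    X0 <- newdata_matrix(object, newdata)
    eta <- drop(X0 %*% object$coefficients)
  }
  if (!se.fit) return(eta)
  list(fit = eta, se.fit = sqrt(rowSums((X0 %*% object$cov_beta) * X0)))
}

# Fixed-effect design rows for new (mass, habitat) combinations.
newdata_matrix <- function(object, newdata) {
  lm10 <- if ("log10_mass" %in% names(newdata)) newdata$log10_mass
          else if ("body_mass_kg" %in% names(newdata)) {
            if (any(newdata$body_mass_kg <= 0))
              stop("body_mass_kg must be positive", call. = FALSE)
            log10(newdata$body_mass_kg)
          } else stop("newdata needs body_mass_kg or log10_mass", call. = FALSE)
  if (object$habitat_estimable) {
    hab <- factor(as.character(newdata$habitat),
                  levels = c("aquatic", "terrestrial"))
    if (anyNA(hab)) stop("habitat must be 'aquatic' or 'terrestrial'",
                         call. = FALSE)
    stats::model.matrix(~ log10_mass * habitat,
                        data = data.frame(log10_mass = lm10, habitat = hab))
  } else {
    stats::model.matrix(~ log10_mass, data = data.frame(log10_mass = lm10))
  }
}

#' Simulate responses from the fitted generative model
#'
#' Draws fresh nested random intercepts from the estimated variance components
#' and fresh residuals, added to the fixed-effect predictor \eqn{X\hat\beta}.
#' This is the inner step of the parametric bootstrap.
#'
#' @param object An `"allom_fit"`.
#' @param nsim Number of response vectors.
#' @param seed Optional integer seed.
#' @param use_random Draw group-level effects (default `TRUE`); if `FALSE`
#'   only residual noise is added.
#' @param ... Unused.
#' @return An n-by-`nsim` matrix of simulated log10 responses.
#' @export
simulate.allom_fit <- function(object, nsim = 1, seed = NULL,
                               use_random = TRUE, ...) {
  d <- object$design
  n <- nrow(d$X)
  eta <- drop(d$X %*% object$coefficients)
  with_seed(seed, {
    out <- matrix(eta, n, nsim)
    for (s in seq_len(nsim)) {
      if (use_random) {
        for (lv in names(d$Z)) {
          q <- ncol(d$Z[[lv]])
          u <- rnorm(q, 0, sqrt(object$varcomp[[lv]]))
          out[, s] <- out[, s] + drop(d$Z[[lv]] %*% u)
        }
      }
      out[, s] <- out[, s] + rnorm(n, 0, sqrt(object$varcomp[["resid"]]))
    }
    dimnames(out) <- list(d$data$species, paste0("sim_", seq_len(nsim)))
    out
  })
}

#' @export
plot.allom_fit <- function(x, ...) {
  d <- x$design$data
  cols <- c(aquatic = "#1f78b4", terrestrial = "#b2582a")
  plot(d$log10_mass, d$log10_value, col = cols[as.character(d$habitat)],
       pch = 19, xlab = expression(log[10] ~ "body mass (kg)"),
       ylab = bquote(log[10] ~ .(x$trait)), ...)
  if (x$habitat_estimable) {
    eq <- habitat_equations(x)
    for (h in rownames(eq))
      abline(eq[h, "intercept"], eq[h, "slope"], col = cols[h], lwd = 2,
             lty = if (h == "aquatic") 2 else 1)
    legend("topleft", legend = rownames(eq), col = cols[rownames(eq)],
           pch = 19, lty = c(2, 1), bty = "n")
  } else {
    abline(x$coefficients[1], x$coefficients[2], lwd = 2)
  }
  invisible(x)
}
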