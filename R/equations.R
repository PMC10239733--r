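# Per-habitat allometric equations and habitat contrasts derived from the
# fixed effects.

coef4 <- function(object) {
  if (inherits(object, "allom_fit")) {
    if (!object$habitat_estimable)
      stop("habitat terms unestimable in this fit", call. = FALSE)
    unname(object$coefficients)
  } else if (is.numeric(object) && length(object) == 4L) {
    unname(object)
  } else stop("expected an allom_fit or a length-4 coefficient vector",
              call. = FALSE)
}

#' Per-habitat allometric equations
#'
#' Composes the fitted fixed effects into one log10-scale line per habitat:
#' aquatic (reference) is \eqn{(\beta_0, \beta_m)}; terrestrial is
#' \eqn{(\beta_0 + \beta_h, \beta_m + \beta_i)}. On the natural scale the
#' line `intercept + slope * log10(Mb)` is the power law
#' \eqn{Y = 10^{intercept} M_b^{slope}}.
#'
#' @param object An `"allom_fit"` (both habitats estimable) or a length-4
#'   numeric vector `(beta0, beta_mass, beta_habitat, beta_interaction)`.
#' @return A 2x2 matrix with rows `aquatic`, `terrestrial` and columns
#'   `intercept`, `slope`.
#' @examples
#' habitat_equations(c(2.04, 0.66, -0.55, 0.17))  # terrestrial: 1.49, 0.83
#' @export
habitat_equations <- function(object) {
  b <- coef4(object)
  matrix(c(b[1], b[2], b[1] + b[3], b[2] + b[4]), 2, 2, byrow = TRUE,
         dimnames = list(c("aquatic", "terrestrial"),
                         c("intercept", "slope")))
}

#' Percent habitat difference at given body masses
#'
#' Signed percent difference of the aquatic population-level prediction
#' relative to the terrestrial one at mass m:
#' \eqn{100\,(10^{L_{aq}(m)} / 10^{L_{terr}(m)} - 1)}, where \eqn{L_h} is the
#' habitat's log10 linear predictor. Negative values mean the aquatic trait is
#' lower.
#'
#' @inheritParams habitat_equations
#' @param mass Body mass(es) in kg, positive; vectorised.
#' @return Numeric vector of signed percentages.
#' @examples
#' b <- c(2.04, 0.66, -0.55, 0.17)
#' round(percent_difference(b, c(10, 5000)))  # +140, -17
#' @export
percent_difference <- function(object, mass) {
  if (any(mass <= 0)) stop("mass must be positive", call. = FALSE)
  b <- coef4(object)
  lm10 <- log10(mass)
  # L_aq - L_terr = -(beta_hab + beta_int * log10 m)
  100 * (10^(-(b[3] + b[4] * lm10)) - 1)
}

#' Body mass at which the two habitats' predictions cross
#'
#' With a nonzero interaction the percent difference is monotone in mass and
#' crosses zero at a unique mass, \eqn{\log_{10} m^* = -\beta_h/\beta_i}.
#'
#' @inheritParams habitat_equations
#' @return Crossing mass in kg (`Inf`/`NaN` when the lines do not cross).
#' @export
crossover_mass <- function(object) {
  b <- coef4(object)
  if (b[4] == 0) {
    if (b[3] == 0) return(NaN)  # identical lines: equal everywhere
    return(Inf)                 # parallel lines: never equal
  }
  10^(-b[3] / b[4])
}
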