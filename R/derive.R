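# Derived physiological quantities and the literature reference power laws.

#' Literature reference allometric equations
#'
#' The classical power laws Y = c * Mb^n used as overlays for the five traits
#' and the two composed quantities. Coefficients are as published: Kleiber's
#' terrestrial BMR, Stahl's terrestrial heart rate, breathing frequency, tidal
#' volume, cardiac output and minute ventilation, Mortola & Limoges' aquatic
#' breathing frequency, and Fahlman's aquatic tidal volume. The terrestrial
#' stroke-volume entry is composed as cardiac output / heart rate,
#' (181/241) * Mb^(0.81 + 0.25), from the printed constituents.
#'
#' @return A `data.frame` with columns `name`, `trait`, `habitat`,
#'   `coefficient` (trait units at 1 kg), `exponent`, `units`, `source`;
#'   9 rows.
#' @export
reference_equations <- function() {
  data.frame(
    name = c("BMR terrestrial", "heart rate terrestrial",
             "stroke volume terrestrial", "breathing frequency terrestrial",
             "breathing frequency aquatic", "tidal volume terrestrial",
             "tidal volume aquatic", "cardiac output terrestrial",
             "minute ventilation terrestrial"),
    trait = c("BMR", "fH", "SV", "fR", "fR", "VT", "VT", "CO", "MV"),
    habitat = c("terrestrial", "terrestrial", "terrestrial", "terrestrial",
                "aquatic", "terrestrial", "aquatic", "terrestrial",
                "terrestrial"),
    coefficient = c(70, 241, 181 / 241, 53.5, 33, 7.69, 0.0372, 187, 379),
    exponent = c(0.75, -0.25, 1.06, -0.26, -0.42, 1.04, 0.92, 0.81, 0.80),
    units = c("kcal/day", "beats/min", "mL/beat", "breaths/min",
              "breaths/min", "mL/breath", "mL/breath", "mL/min", "mL/min"),
    source = c("Kleiber", "Stahl", "Stahl (CO/fH)", "Stahl",
               "Mortola & Limoges", "Stahl", "Fahlman", "Stahl", "Stahl"),
    stringsAsFactors = FALSE)
}

#' Evaluate a power law Y = c * Mb^n
#'
#' @param eq A one-row `data.frame` with `coefficient` and `exponent` columns
#'   (a row of [reference_equations()]), or a numeric vector `c(c, n)`.
#' @param mass Body mass(es) in kg, positive; vectorised.
#' @return Trait value(s) on the linear scale.
#' @examples
#' kleiber <- reference_equations()[1, ]
#' power_law(kleiber, 1)  # 70 kcal/day
#' @export
power_law <- function(eq, mass) {
  if (any(mass <= 0)) stop("mass must be positive", call. = FALSE)
  if (is.data.frame(eq)) {
    stopifnot(nrow(eq) == 1L)
    cc <- eq$coefficient; nn <- eq$exponent
  } else {
    stopifnot(is.numeric(eq), length(eq) == 2L)
    cc <- eq[1]; nn <- eq[2]
  }
  cc * mass^nn
}

#' Cardiac oxygen output
#'
#' Oxygen delivered per minute by the heart,
#' \deqn{\dot{C}O_{O_2} = f_H \cdot SV \cdot Hb \cdot 1.34 \cdot 0.01,}
#' where 1.34 mL O2 per g is the oxygen-loading capacity of hemoglobin and
#' 0.01 is the published unit constant, implemented exactly as printed. A
#' units audit (f_H in 1/min, SV in mL, Hb in g/dL = g per 100 mL) shows the
#' result is in mL O2/min under this constant; the source labels the quantity
#' L O2/min, which appears to be a typographical inconsistency, so outputs
#' here are labelled mL O2/min and no silent rescaling is applied. The
#' quantity is linear in each input.
#'
#' @param f_H Heart rate, beats/min.
#' @param SV Stroke volume, mL/beat.
#' @param Hb Hemoglobin concentration, g/dL.
#' @param o2_capacity O2 capacity of hemoglobin, mL O2 per g (default 1.34).
#' @param unit_factor Published unit constant (default 0.01).
#' @return Cardiac O2 output, mL O2/min.
#' @examples
#' cardiac_o2_output(60, 100, 10)  # 804
#' @export
cardiac_o2_output <- function(f_H, SV, Hb, o2_capacity = 1.34,
                              unit_factor = 0.01) {
  if (any(c(f_H, SV, Hb, o2_capacity, unit_factor) < 0))
    stop("inputs must be non-negative", call. = FALSE)
  f_H * SV * Hb * o2_capacity * unit_factor
}

#' Default respiratory dead-space fraction by habitat
#'
#' Aquatic mammals carry a larger relative dead space (7% of tidal volume)
#' than terrestrial mammals (3%).
#'
#' @param habitat `"aquatic"` or `"terrestrial"`.
#' @return Dead-space fraction (dimensionless).
#' @export
dead_space_fraction_default <- function(habitat) {
  vals <- c(aquatic = 0.07, terrestrial = 0.03)
  out <- vals[habitat]
  if (anyNA(out)) stop("habitat must be 'aquatic' or 'terrestrial'",
                       call. = FALSE)
  unname(out)
}

#' Alveolar ventilation
#'
#' Minute ventilation corrected for dead-space ventilation, using fractional
#' dead space of tidal volume (V_D = fraction * V_T):
#' \deqn{\dot{V}_A = V_T (1 - f_{DS}) f_R.}
#' With zero dead space this reduces to minute ventilation V_T * f_R. The
#' dead-space correction itself is the standard physiological definition and
#' is labelled exploratory in pipeline outputs.
#'
#' @param V_T Tidal volume, mL/breath.
#' @param f_R Breathing frequency, breaths/min.
#' @param dead_space_fraction Fraction of tidal volume that is dead space, in
#'   [0, 1); defaults via `habitat`.
#' @param habitat Optional habitat used to pick the default fraction
#'   (aquatic 0.07, terrestrial 0.03); ignored when `dead_space_fraction` is
#'   given.
#' @return Alveolar ventilation, mL/min.
#' @examples
#' alveolar_ventilation(1000, 10, 0.07)  # 9300
#' @export
alveolar_ventilation <- function(V_T, f_R, dead_space_fraction = NULL,
                                 habitat = NULL) {
  if (is.null(dead_space_fraction)) {
    if (is.null(habitat))
      stop("supply dead_space_fraction or habitat", call. = FALSE)
    dead_space_fraction <- dead_space_fraction_default(habitat)
  }
  if (any(dead_space_fraction < 0 | dead_space_fraction >= 1))
    stop("dead_space_fraction must be in [0, 1)", call. = FALSE)
  if (any(c(V_T, f_R) < 0)) stop("inputs must be non-negative", call. = FALSE)
  V_T * (1 - dead_space_fraction) * f_R
}
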