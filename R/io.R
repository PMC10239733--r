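# Species trait tables: import, validation, inclusion filters, log transform.

ALLOM_TRAITS <- c("BMR", "fR", "fH", "SV", "VT")

#' Units of the supported traits
#'
#' @return Named character vector mapping trait codes to measurement units:
#'   BMR (basal metabolic rate), fR (breathing frequency), fH (heart rate),
#'   SV (stroke volume), VT (tidal volume).
#' @export
trait_units <- function() {
  c(BMR = "kcal/day", fR = "breaths/min", fH = "beats/min",
    SV = "mL/beat", VT = "mL/breath")
}

#' Default body-mass inclusion bounds for a trait
#'
#' Species below 10 kg are excluded throughout (the mass of the smallest
#' aquatic mammal, so both habitats cover the same range); the upper bound is
#' 5318 kg for BMR and 6650 kg for the cardiorespiratory traits.
#'
#' @param trait One of `"BMR"`, `"fR"`, `"fH"`, `"SV"`, `"VT"`.
#' @return Numeric vector `c(min, max)` in kg.
#' @export
default_mass_bounds <- function(trait) {
  trait <- match_trait(trait)
  if (trait == "BMR") c(10, 5318) else c(10, 6650)
}

match_trait <- function(trait) {
  if (length(trait) != 1L || !trait %in% ALLOM_TRAITS)
    stop("unknown trait '", paste(trait, collapse = ","),
         "'; valid traits: ", paste(ALLOM_TRAITS, collapse = ", "),
         call. = FALSE)
  trait
}

REQUIRED_COLS <- c("order", "family", "genus", "species", "habitat",
                   "body_mass_kg", "trait", "value")
FLAG_COLS <- c("is_juvenile", "is_sedated")

#' Read and validate a species trait table
#'
#' Reads a comma-separated species table (UTF-8, header row required; one row
#' per species measurement) and keeps the rows for one trait. Columns:
#' `order, family, genus, species, habitat, body_mass_kg, trait, value` plus
#' optional logical flags `is_juvenile`, `is_sedated` (missing flags default to
#' `FALSE`). Validation rejects non-positive masses or trait values (the
#' log\eqn{_{10}} transform must be defined), habitats outside
#' \{aquatic, terrestrial\}, and taxonomies that are not hierarchical (a genus
#' must map to one family, a family to one order). Malformed rows are reported
#' by their row number in the file.
#'
#' @param path Path to a CSV file.
#' @param trait Trait to extract; one of `"BMR"`, `"fR"`, `"fH"`, `"SV"`,
#'   `"VT"`.
#' @return A `data.frame` of class `"trait_data"` with attributes `trait` and
#'   `provenance`. Duplicate species rows are retained here; they are
#'   aggregated by geometric mean in [log10_transform()].
#' @seealso [apply_inclusion_filters()], [log10_transform()]
#' @export
read_species_table <- function(path, trait) {
  trait <- match_trait(trait)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(REQUIRED_COLS, names(raw))
  if (length(missing_cols))
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  for (fc in FLAG_COLS) {
    if (!fc %in% names(raw)) raw[[fc]] <- FALSE
    raw[[fc]] <- as.logical(raw[[fc]]) & !is.na(as.logical(raw[[fc]]))
  }
  # file row numbers (header is row 1)
  raw$.row <- seq_len(nrow(raw)) + 1L
  dat <- raw[raw$trait == trait, , drop = FALSE]
  validate_trait_data(dat)
  rownames(dat) <- NULL
  out <- dat[, c(REQUIRED_COLS, FLAG_COLS), drop = FALSE]
  structure(out, class = c("trait_data", "data.frame"),
            trait = trait, provenance = path)
}

validate_trait_data <- function(dat) {
  rows <- dat$.row %||% seq_len(nrow(dat))
  bad <- function(cond, what) {
    idx <- which(cond)
    if (length(idx))
      stop("invalid ", what, " in row(s) ", paste(rows[idx], collapse = ", "),
           call. = FALSE)
  }
  if (nrow(dat) == 0L) return(invisible(TRUE))
  bad(!is.finite(dat$body_mass_kg) | dat$body_mass_kg <= 0,
      "body_mass_kg (must be positive)")
  bad(!is.finite(dat$value) | dat$value <= 0, "trait value (must be positive)")
  bad(!dat$habitat %in% c("aquatic", "terrestrial"),
      "habitat (must be 'aquatic' or 'terrestrial')")
  for (col in c("order", "family", "genus", "species"))
    bad(is.na(dat[[col]]) | !nzchar(dat[[col]]), paste0(col, " label"))
  # hierarchical taxonomy: each child label maps to exactly one parent
  check_nested <- function(child, parent, what) {
    tab <- unique(dat[, c(child, parent)])
    dup <- tab[[child]][duplicated(tab[[child]])]
    if (length(dup))
      stop("non-hierarchical taxonomy: ", what, " ",
           paste(unique(dup), collapse = ", "),
           " assigned to more than one ", parent, call. = FALSE)
  }
  check_nested("genus", "family", "genus")
  check_nested("family", "order", "family")
  invisible(TRUE)
}

#' Apply the study's inclusion filters
#'
#' Retains records with `mass_min <= body_mass_kg <= mass_max` and, when
#' `reduced = TRUE` (the reduced analysis set), drops records flagged as
#' juvenile or sedated. Each rule logs the number of records it removed via
#' `message()`. An empty result is a warning, not an error; the downstream fit
#' refuses empty designs itself.
#'
#' @param data A `"trait_data"` table from [read_species_table()] or
#'   [simulate_traits()].
#' @param mass_min,mass_max Body-mass bounds in kg; default
#'   [default_mass_bounds()] for the table's trait.
#' @param reduced Logical; drop juvenile/sedated records (default `TRUE`).
#' @return The filtered `"trait_data"` table (attributes preserved).
#' @export
apply_inclusion_filters <- function(data, mass_min = NULL, mass_max = NULL,
                                    reduced = TRUE) {
  trait <- attr(data, "trait") %||% "BMR"
  bounds <- default_mass_bounds(trait)
  mass_min <- mass_min %||% bounds[1]
  mass_max <- mass_max %||% bounds[2]
  if (!(mass_min < mass_max)) stop("mass_min must be < mass_max", call. = FALSE)

  drop_rule <- function(dat, keep, rule) {
    n_drop <- sum(!keep)
    if (n_drop > 0)
      message("dropped ", n_drop, " record(s): ", rule)
    dat[keep, , drop = FALSE]
  }
  out <- drop_rule(data, data$body_mass_kg >= mass_min,
                   sprintf("body mass below %g kg", mass_min))
  out <- drop_rule(out, out$body_mass_kg <= mass_max,
                   sprintf("body mass above %g kg", mass_max))
  if (isTRUE(reduced)) {
    out <- drop_rule(out, !out$is_juvenile, "juvenile")
    out <- drop_rule(out, !out$is_sedated, "sedated")
  }
  if (nrow(out) == 0L) warning("no records remain after filtering")
  rownames(out) <- NULL
  structure(out, class = c("trait_data", "data.frame"),
            trait = trait, provenance = attr(data, "provenance"))
}

#' Log-transform a trait table for model fitting
#'
#' Applies the base-10 logarithm to body mass and trait value, encodes habitat
#' as a factor with aquatic as the reference level (so the habitat coefficient
#' is the terrestrial offset), and aggregates duplicate species rows by the
#' geometric mean of mass and trait value (arithmetic mean on the
#' log\eqn{_{10}} scale), which preserves the log-scale model assumptions.
#' Flags of aggregated duplicates are combined with `any()`.
#'
#' @param data A `"trait_data"` table with positive masses and values.
#' @return A `data.frame` with columns `order, family, genus, species, habitat`
#'   (factor, levels aquatic then terrestrial), `log10_mass`, `log10_value`,
#'   carrying the `trait` attribute.
#' @export
log10_transform <- function(data) {
  validate_trait_data(data)
  trait <- attr(data, "trait")
  if (nrow(data) == 0L) {
    out <- data.frame(order = character(), family = character(),
                      genus = character(), species = character(),
                      habitat = factor(character(),
                                       levels = c("aquatic", "terrestrial")),
                      log10_mass = numeric(), log10_value = numeric())
    return(structure(out, trait = trait, class = c("allom_table", "data.frame")))
  }
  dat <- as.data.frame(data)
  dat$log10_mass <- log10(dat$body_mass_kg)
  dat$log10_value <- log10(dat$value)
  key <- paste(dat$species, dat$habitat, sep = "\r")
  if (anyDuplicated(key)) {
    n_dup <- nrow(dat) - length(unique(key))
    message("aggregated ", n_dup,
            " duplicate species record(s) by geometric mean")
    agg <- function(x, f) unsplit(lapply(split(x, key), f), key)
    dat$log10_mass <- agg(dat$log10_mass, function(v) rep(mean(v), length(v)))
    dat$log10_value <- agg(dat$log10_value, function(v) rep(mean(v), length(v)))
    for (fc in intersect(FLAG_COLS, names(dat)))
      dat[[fc]] <- agg(dat[[fc]], function(v) rep(any(v), length(v)))
    dat <- dat[!duplicated(key), , drop = FALSE]
  }
  out <- data.frame(order = dat$order, family = dat$family, genus = dat$genus,
                    species = dat$species,
                    habitat = factor(dat$habitat,
                                     levels = c("aquatic", "terrestrial")),
                    log10_mass = dat$log10_mass,
                    log10_value = dat$log10_value,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out, trait = trait, class = c("allom_table", "data.frame"))
}
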