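# Parametric bootstrap propagation: per-species (or mass-grid) prediction
# ensembles, paired products across traits (cardiac output, minute
# ventilation), percentile intervals and habitat-difference curves.

#' Construct a bootstrap ensemble from a sample matrix
#'
#' Low-level constructor, mainly for combining externally produced samples or
#' building small ensembles in examples and tests.
#'
#' @param samples Numeric matrix, one row per target, one column per bootstrap
#'   replicate.
#' @param targets `data.frame` describing the rows (e.g. species, or mass grid
#'   with habitat).
#' @param quantity Label of the quantity held (trait code, `"CO"`, `"MV"`,
#'   `"difference"`, ...).
#' @param scale `"log10"` (default; back-transformed by [boot_ci()]) or
#'   `"linear"`.
#' @param includes_random_effects Logical flag; `FALSE` for population-level
#'   ensembles.
#' @param seed Seed recorded for provenance.
#' @return An `"allom_ensemble"`.
#' @export
allom_ensemble <- function(samples, targets = NULL, quantity = "trait",
                           scale = c("log10", "linear"),
                           includes_random_effects = FALSE, seed = NULL) {
  samples <- as.matrix(samples)
  if (any(!is.finite(samples))) stop("ensemble has missing cells", call. = FALSE)
  if (ncol(samples) < 1L) stop("n_boot must be >= 1", call. = FALSE)
  if (is.null(targets))
    targets <- data.frame(target = rownames(samples) %||%
                            paste0("t", seq_len(nrow(samples))))
  stopifnot(nrow(targets) == nrow(samples))
  structure(list(samples = samples, targets = targets, quantity = quantity,
                 scale = match.arg(scale),
                 includes_random_effects = includes_random_effects,
                 seed = seed, n_boot = ncol(samples)),
            class = "allom_ensemble")
}

#' @export
print.allom_ensemble <- function(x, ...) {
  cat("Parametric bootstrap ensemble:", x$quantity, "\n")
  cat("  ", nrow(x$samples), "targets x", x$n_boot, "replicates (",
      x$scale, "scale )\n")
  cat("  random effects included:", x$includes_random_effects, "\n")
  invisible(x)
}

#' Parametric bootstrap prediction ensemble
#'
#' For each replicate a new response vector is simulated from the fitted model
#' (fresh random intercepts and residuals), the model is refitted
#' (`refit = TRUE`, the default, so parameter uncertainty is propagated), and
#' predictions are recorded: per fitted species including the replicate's
#' conditional random-effect modes when `newdata` is `NULL`, or at population
#' level (random effects zero) for the rows of `newdata`. With
#' `refit = FALSE` only random-effect and residual draws are propagated
#' (species-level samples are \eqn{X\hat\beta + Zu^*}; population-level
#' samples are degenerate), a fast mode for testing.
#'
#' Non-convergent replicates are redrawn, up to `max_redraw * n_boot` total
#' attempts; the redraw count is reported via `message()`.
#'
#' @param fit An `"allom_fit"`.
#' @param n_boot Number of bootstrap replicates (default 100).
#' @param seed Optional integer seed; identical seeds give identical
#'   ensembles.
#' @param refit Refit the model on each simulated response (default `TRUE`).
#' @param newdata Optional `data.frame` (`body_mass_kg` or `log10_mass`, plus
#'   `habitat`) for population-level ensembles.
#' @param max_redraw Redraw budget multiplier for non-convergent replicates.
#' @return An `"allom_ensemble"` of log10-scale predicted values, one column
#'   per replicate.
#' @export
allom_boot <- function(fit, n_boot = 100, seed = NULL, refit = TRUE,
                       newdata = NULL, max_redraw = 10) {
  stopifnot(inherits(fit, "allom_fit"), n_boot >= 1)
  d <- fit$design
  population <- !is.null(newdata)
  X0 <- if (population) newdata_matrix(fit, newdata) else d$X
  targets <- if (population) as.data.frame(newdata)
             else data.frame(species = d$data$species,
                             habitat = as.character(d$data$habitat),
                             body_mass_kg = 10^d$data$log10_mass)

  seed_pool <- with_seed(if (is.null(seed)) NULL else derive_seed(seed, "boot"),
                         sample.int(2147483646L, n_boot * max_redraw))
  samples <- matrix(NA_real_, nrow(X0), n_boot)
  pool_i <- 0L
  n_redrawn <- 0L
  for (b in seq_len(n_boot)) {
    repeat {
      pool_i <- pool_i + 1L
      if (pool_i > length(seed_pool))
        stop("bootstrap replicate redraw budget exhausted (",
             n_redrawn, " non-convergent replicates)", call. = FALSE)
      ysim <- simulate(fit, nsim = 1, seed = seed_pool[pool_i])[, 1]
      if (refit) {
        eng <- tryCatch(refit_response(fit, ysim), error = function(e) NULL)
        if (is.null(eng) || !eng$converged) { n_redrawn <- n_redrawn + 1L; next }
        pred <- drop(X0 %*% eng$beta)
        if (!population)
          for (lv in names(d$Z))
            pred <- pred + drop(d$Z[[lv]] %*% eng$modes[[lv]])
      } else {
        if (population) {
          pred <- drop(X0 %*% fit$coefficients)
        } else {
          # random-effect draws only: regenerate the group effects used in ysim
          pred <- drop(X0 %*% fit$coefficients)
          u <- with_seed(seed_pool[pool_i], {
            us <- list()
            for (lv in names(d$Z))
              us[[lv]] <- rnorm(ncol(d$Z[[lv]]), 0, sqrt(fit$varcomp[[lv]]))
            us
          })
          for (lv in names(d$Z)) pred <- pred + drop(d$Z[[lv]] %*% u[[lv]])
        }
      }
      samples[, b] <- pred
      break
    }
  }
  if (n_redrawn > 0)
    message(n_redrawn, " non-convergent bootstrap replicate(s) redrawn")
  rownames(samples) <- if (population) NULL else targets$species
  allom_ensemble(samples, targets = targets, quantity = fit$trait,
                 scale = "log10",
                 includes_random_effects = !population && refit ||
                   (!population && !refit),
                 seed = seed)
}

#' Multiply two paired bootstrap ensembles
#'
#' Combines two trait ensembles into their product quantity by adding paired
#' samples on the log10 scale (multiplication on the linear scale):
#' stroke volume x heart rate gives cardiac output (CO), tidal volume x
#' breathing frequency gives minute ventilation (MV). Replicates are paired by
#' index; the two ensembles' uncertainties are treated as independent, which
#' reflects that the traits are fitted on different species sets. Species
#' ensembles are combined on the intersection of their species; grid ensembles
#' must share the grid exactly.
#'
#' @param a,b `"allom_ensemble"` objects on the log10 scale with equal
#'   `n_boot`.
#' @param quantity Optional label; guessed from the inputs (`SV`x`fH` = CO,
#'   `VT`x`fR` = MV).
#' @return An `"allom_ensemble"` for the product quantity.
#' @export
boot_product <- function(a, b, quantity = NULL) {
  stopifnot(inherits(a, "allom_ensemble"), inherits(b, "allom_ensemble"))
  if (a$scale != "log10" || b$scale != "log10")
    stop("products are formed on the log10 scale", call. = FALSE)
  if (a$n_boot != b$n_boot)
    stop("ensembles have different n_boot (", a$n_boot, " vs ", b$n_boot, ")",
         call. = FALSE)
  if (!is.null(a$targets$species) && !is.null(b$targets$species)) {
    common <- intersect(a$targets$species, b$targets$species)
    if (!length(common))
      stop("no common species between the two ensembles", call. = FALSE)
    ia <- match(common, a$targets$species)
    ib <- match(common, b$targets$species)
    samples <- a$samples[ia, , drop = FALSE] + b$samples[ib, , drop = FALSE]
    targets <- a$targets[ia, , drop = FALSE]
  } else {
    if (nrow(a$samples) != nrow(b$samples) ||
        !isTRUE(all.equal(a$targets, b$targets, check.attributes = FALSE)))
      stop("ensemble targets do not match", call. = FALSE)
    samples <- a$samples + b$samples
    targets <- a$targets
  }
  if (is.null(quantity)) {
    pair <- c(a$quantity, b$quantity)
    quantity <- if (setequal(pair, c("SV", "fH"))) "CO"
                else if (setequal(pair, c("VT", "fR"))) "MV"
                else paste(a$quantity, b$quantity, sep = "*")
  }
  allom_ensemble(samples, targets = targets, quantity = quantity,
                 scale = "log10",
                 includes_random_effects = a$includes_random_effects ||
                   b$includes_random_effects,
                 seed = a$seed)
}

#' Percentile confidence intervals for a bootstrap ensemble
#'
#' Per target the point estimate is the ensemble mean and the bounds are the
#' empirical \eqn{(1 \pm level)/2} quantiles of the replicates (Hazen
#' linear-interpolation rule, fixed for reproducibility). Log10-scale
#' ensembles are back-transformed to the natural scale; linear-scale
#' ensembles (e.g. differences) are summarised as-is. Percentile bounds come
#' from the replicate distribution, so the plug-in estimate is not forced to
#' lie inside them, but `lo <= hi` always holds. Fewer than 20 replicates for
#' a 95% interval triggers a warning.
#'
#' @param x An `"allom_ensemble"`.
#' @param level Confidence level (default 0.95).
#' @return An `"allom_curve"` `data.frame`: target columns plus `estimate`,
#'   `lo`, `hi`, with attributes `level`, `n_boot`, `quantity`, `seed`.
#' @export
boot_ci <- function(x, level = 0.95) {
  stopifnot(inherits(x, "allom_ensemble"), level > 0, level < 1)
  if (x$n_boot < 20 && level >= 0.95)
    warning("only ", x$n_boot, " replicates for a ", 100 * level,
            "% percentile interval")
  probs <- c((1 - level) / 2, (1 + level) / 2)
  est <- rowMeans(x$samples)
  qs <- t(apply(x$samples, 1, hazen_quantile, probs = probs))
  if (x$scale == "log10") {
    est <- 10^est
    qs <- 10^qs
  }
  out <- cbind(x$targets,
               data.frame(estimate = est, lo = qs[, 1], hi = qs[, 2]))
  rownames(out) <- NULL
  structure(out, level = level, n_boot = x$n_boot, quantity = x$quantity,
            seed = x$seed, class = c("allom_curve", "data.frame"))
}

#' @export
print.allom_curve <- function(x, ...) {
  cat("Derived curve:", attr(x, "quantity"), " (level ",
      attr(x, "level"), ", n_boot ", attr(x, "n_boot"), ")\n", sep = "")
  print.data.frame(head(as.data.frame(x), 10), ...)
  if (nrow(x) > 10) cat("... ", nrow(x) - 10, " more rows\n")
  invisible(x)
}

#' @export
plot.allom_curve <- function(x, log_axes = TRUE, ...) {
  stopifnot("mass_kg" %in% names(x))
  lx <- log10(x$mass_kg)
  finite_pos <- function(v) all(v > 0)
  use_log_y <- log_axes && finite_pos(x$lo)
  ty <- function(v) if (use_log_y) log10(v) else v
  plot(lx, ty(x$estimate), type = "n",
       ylim = range(ty(x$lo), ty(x$hi)),
       xlab = expression(log[10] ~ "body mass (kg)"),
       ylab = paste0(if (use_log_y) "log10 " else "", attr(x, "quantity")),
       ...)
  polygon(c(lx, rev(lx)), c(ty(x$lo), rev(ty(x$hi))),
          col = adjustcolor("grey60", 0.4), border = NA)
  lines(lx, ty(x$estimate), lwd = 2)
  if (!use_log_y) abline(h = 0, lty = 3)
  invisible(x)
}

#' Habitat-difference curve for a (product) quantity
#'
#' Bootstraps the population-level prediction (all random effects zero) of a
#' quantity --- one trait, or the product of two traits such as CO = SV x fH
#' --- for hypothetical aquatic and terrestrial species over a body-mass grid,
#' and summarises the paired linear-scale difference (aquatic minus
#' terrestrial) with percentile confidence intervals. Each trait's replicates
#' use an independent RNG sub-stream derived from `seed`; within a trait the
#' same replicate fit drives both habitats, so the difference is paired.
#'
#' @param fit_a First trait fit.
#' @param fit_b Optional second trait fit for a product quantity.
#' @param mass_grid Body masses in kg (default 50 log-spaced points from 10 to
#'   6650). Masses outside the fitted mass range are flagged with a warning
#'   (extrapolation).
#' @param n_boot,seed,refit Passed to [allom_boot()].
#' @param level Confidence level (default 0.95).
#' @return An `"allom_curve"` with columns `quantity`, `mass_kg`, `estimate`,
#'   `lo`, `hi`, `spans_zero`.
#' @export
habitat_difference <- function(fit_a, fit_b = NULL, mass_grid = NULL,
                               n_boot = 100, seed = NULL, refit = TRUE,
                               level = 0.95) {
  stopifnot(inherits(fit_a, "allom_fit"))
  if (is.null(mass_grid))
    mass_grid <- 10^seq(log10(10), log10(6650), length.out = 50)
  if (!length(mass_grid)) stop("empty mass grid", call. = FALSE)
  fits <- c(list(fit_a), if (!is.null(fit_b)) list(fit_b))
  fitted_range <- range(unlist(lapply(fits, function(f)
    10^f$design$data$log10_mass)))
  if (any(mass_grid < fitted_range[1] | mass_grid > fitted_range[2]))
    warning("mass grid extends beyond the fitted mass range [",
            signif(fitted_range[1], 3), ", ", signif(fitted_range[2], 3),
            "] kg: extrapolation")

  grid_nd <- data.frame(
    body_mass_kg = rep(mass_grid, 2),
    habitat = rep(c("aquatic", "terrestrial"), each = length(mass_grid)))
  ens <- vector("list", length(fits))
  for (i in seq_along(fits)) {
    sub_seed <- if (is.null(seed)) NULL else derive_seed(seed, paste0("trait", i))
    ens[[i]] <- allom_boot(fits[[i]], n_boot = n_boot, seed = sub_seed,
                           refit = refit, newdata = grid_nd)
  }
  logq <- Reduce(`+`, lapply(ens, `[[`, "samples"))
  m <- length(mass_grid)
  diff_lin <- 10^logq[seq_len(m), , drop = FALSE] -
    10^logq[m + seq_len(m), , drop = FALSE]

  quantity <- if (is.null(fit_b)) fit_a$trait else {
    pair <- c(fit_a$trait, fit_b$trait)
    if (setequal(pair, c("SV", "fH"))) "CO"
    else if (setequal(pair, c("VT", "fR"))) "MV"
    else paste(sort(pair), collapse = "*")
  }
  dens <- allom_ensemble(diff_lin,
                         targets = data.frame(mass_kg = mass_grid),
                         quantity = paste0(quantity, " difference"),
                         scale = "linear", includes_random_effects = FALSE,
                         seed = seed)
  curve <- boot_ci(dens, level = level)
  curve$quantity <- paste0(quantity, "_difference_aquatic_minus_terrestrial")
  curve$spans_zero <- curve$lo <= 0 & curve$hi >= 0
  curve <- curve[, c("quantity", "mass_kg", "estimate", "lo", "hi",
                     "spans_zero")]
  structure(curve, level = level, n_boot = n_boot,
            quantity = attr(curve, "quantity") %||% quantity, seed = seed,
            class = c("allom_curve", "data.frame"))
}
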