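# REML fit of the allometric linear mixed model
#   log10(Y) ~ log10(Mb) * habitat + (1 | order/family/genus)
# Variance components are optimised on the log scale (simplex start, BFGS
# polish); the criterion itself is evaluated in compiled code (src/reml.cpp).

#' Build design matrices for the allometric mixed model
#'
#' Constructs the fixed-effect matrix (intercept, log10 mass, terrestrial
#' indicator, interaction; aquatic is the reference level) and the nested
#' grouping structure. A nesting level is dropped, with a warning, when it is
#' confounded: a level whose grouping partition coincides with the next finer
#' retained partition (or with the observations themselves) contributes no
#' identifiable variance --- e.g. one species per genus aliases the genus
#' variance with the residual. Levels with a single group are likewise dropped
#' (confounded with the intercept). With a single habitat present the habitat
#' and interaction columns are unestimable and the fixed design reduces to
#' (intercept, log10 mass), with a warning.
#'
#' @param data An `"allom_table"` from [log10_transform()] (raw `"trait_data"`
#'   is transformed automatically).
#' @param levels Nesting levels requested, outermost first.
#' @return A list with elements `X`, `y`, `Z` (list of indicator matrices),
#'   `K` (list of relationship matrices Z Z'), `groups`, `levels_included`,
#'   `levels_dropped`, `habitat_estimable`, `data`.
#' @keywords internal
build_design <- function(data, levels = c("order", "family", "genus")) {
  if (inherits(data, "trait_data") || !"log10_mass" %in% names(data))
    data <- log10_transform(data)
  # hierarchical row order makes V block diagonal by the coarsest retained
  # grouping, which the criterion evaluation exploits
  data <- data[order(data$order, data$family, data$genus, data$species), ,
               drop = FALSE]
  rownames(data) <- NULL
  n <- nrow(data)
  if (n < 2L) stop("need at least 2 species to fit", call. = FALSE)
  if (stats::sd(data$log10_mass) == 0)
    stop("rank-deficient fixed design: body mass identical across species; ",
         "the allometric slope is unestimable", call. = FALSE)

  habitats <- unique(as.character(data$habitat))
  habitat_estimable <- length(habitats) == 2L
  if (habitat_estimable) {
    X <- stats::model.matrix(~ log10_mass * habitat, data = data)
  } else {
    warning("single habitat (", habitats,
            "): habitat and interaction terms unestimable; ",
            "fitting intercept and slope only")
    X <- stats::model.matrix(~ log10_mass, data = data)
  }

  # nested grouping factors, coded within parent
  grp_all <- list()
  lab <- NULL
  for (lv in c("order", "family", "genus")) {
    lab <- if (is.null(lab)) as.character(data[[lv]])
           else paste(lab, data[[lv]], sep = "/")
    grp_all[[lv]] <- factor(lab)
  }
  grp_all <- grp_all[intersect(c("order", "family", "genus"), levels)]

  included <- character()
  dropped <- character()
  finer_k <- n  # partition size of the next finer retained structure
  for (lv in rev(names(grp_all))) {
    k <- nlevels(grp_all[[lv]])
    if (k >= finer_k) {
      dropped <- c(dropped, lv)
      warning("random level '", lv, "' aliased with finer structure ",
              "(", k, " groups for ", finer_k,
              " units); dropped from the model")
    } else if (k < 2L) {
      dropped <- c(dropped, lv)
      warning("random level '", lv, "' has a single group; dropped")
    } else {
      included <- c(lv, included)
      finer_k <- k
    }
  }
  groups <- grp_all[included]
  Z <- lapply(groups, function(f) {
    z <- stats::model.matrix(~ 0 + f)
    colnames(z) <- levels(f)
    z
  })
  K <- lapply(Z, tcrossprod)
  blocks <- if (length(groups)) {
    as.integer(rle(as.character(groups[[1]]))$lengths)
  } else rep(1L, n)

  list(X = X, y = data$log10_value, Z = Z, K = K, groups = groups,
       blocks = blocks,
       levels_included = included, levels_dropped = dropped,
       habitat_estimable = habitat_estimable, data = data)
}

# Dense REML engine. start: optional log variance components (levels then
# resid). fixed_varcomp: named full vector of variances to hold fixed (no
# optimisation). control: nm_maxit, bfgs (logical polish), reltol.
reml_engine <- function(X, y, K, blocks = NULL, start = NULL,
                        fixed_varcomp = NULL, control = list()) {
  ctl <- modifyList(list(nm_maxit = 500L, bfgs = TRUE, reltol = 1e-10), control)
  n <- nrow(X); p <- ncol(X); m <- length(K)
  if (n <= p) stop("fewer observations than fixed-effect parameters",
                   call. = FALSE)
  qx <- qr(X)
  if (qx$rank < p) stop("rank-deficient fixed design", call. = FALSE)
  logdet_xtx <- 2 * sum(log(abs(diag(qr.R(qx)))))
  if (is.null(blocks)) blocks <- n
  blocks <- as.integer(blocks)
  stopifnot(sum(blocks) == n)
  comp_names <- c(names(K), "resid")

  if (!is.null(fixed_varcomp)) {
    s2 <- fixed_varcomp[comp_names]
    if (anyNA(s2)) stop("fixed_varcomp must name: ",
                        paste(comp_names, collapse = ", "), call. = FALSE)
    sol <- reml_solution(s2, X, y, K, logdet_xtx)
    return(c(sol, list(varcomp = setNames(pmax(s2, 0), comp_names),
                       converged = TRUE, boundary = s2 <= 1e-10,
                       fevals = 0L, optimized = FALSE)))
  }

  # the criterion clamps log-variances internally, so no R-side boxing
  obj <- function(th) reml_nll(th, X, y, K, logdet_xtx, blocks)
  if (is.null(start)) {
    r0 <- qr.resid(qx, y)
    v0 <- max(sum(r0^2) / (n - p), 1e-8)
    start <- rep(log(v0 / (m + 1)), m + 1)
  }
  start <- unname(pmin(pmax(start, -50), 50))

  if (m + 1 > 1) {
    o1 <- stats::optim(start, obj, method = "Nelder-Mead",
                       control = list(maxit = ctl$nm_maxit,
                                      reltol = ctl$reltol))
  } else {
    o1 <- stats::optim(start, obj, method = "Brent", lower = -50, upper = 50)
  }
  best <- o1
  if (isTRUE(ctl$bfgs)) {
    o2 <- tryCatch(stats::optim(o1$par, obj, method = "BFGS",
                                control = list(maxit = 100L,
                                               reltol = ctl$reltol)),
                   error = function(e) NULL)
    if (!is.null(o2) && is.finite(o2$value) && o2$value <= best$value)
      best <- o2
  }
  converged <- best$convergence == 0 && best$value < 1e9
  if (!converged && best$value >= 1e9)
    stop("REML optimisation failed (non-finite criterion); best criterion ",
         format(best$value), call. = FALSE)

  s2 <- exp(pmin(pmax(best$par, -50), 50))
  boundary <- s2 < 1e-10
  s2[boundary] <- 0
  names(s2) <- comp_names
  sol <- reml_solution(s2, X, y, K, logdet_xtx)
  c(sol, list(varcomp = s2, converged = converged, boundary = boundary,
              theta = log(pmax(s2, 1e-12)),
              fevals = sum(o1$counts[1], if (isTRUE(ctl$bfgs)) best$counts[1] else 0,
                           na.rm = TRUE),
              optimized = TRUE))
}

# GLS solution, covariance, conditional modes and REML log-likelihood at a
# given set of variance components.
reml_solution <- function(s2, X, y, K, logdet_xtx) {
  n <- nrow(X); p <- ncol(X); m <- length(K)
  s2e <- max(s2[m + 1], 1e-12)
  V <- diag(s2e, n)
  for (l in seq_len(m)) if (s2[l] > 0) V <- V + s2[l] * K[[l]]
  ch <- chol(V)
  Vi <- chol2inv(ch)
  XtViX <- crossprod(X, Vi %*% X)
  cov_beta <- solve(XtViX)
  cov_beta <- (cov_beta + t(cov_beta)) / 2
  beta <- drop(cov_beta %*% crossprod(X, Vi %*% y))
  names(beta) <- colnames(X)
  dimnames(cov_beta) <- list(colnames(X), colnames(X))
  r <- y - drop(X %*% beta)
  Vir <- drop(Vi %*% r)
  nll2 <- (n - p) * log(2 * pi) + 2 * sum(log(diag(ch))) +
    as.numeric(determinant(XtViX, logarithm = TRUE)$modulus) -
    logdet_xtx + sum(r * Vir)
  list(beta = beta, cov_beta = cov_beta, se = sqrt(diag(cov_beta)),
       reml_loglik = -0.5 * nll2, resid_gls = r, Vir = Vir)
}

#' Fit the allometric linear mixed model by REML
#'
#' Fits \eqn{\log_{10} Y \sim \log_{10} M_b \times habitat} with nested random
#' intercepts for taxonomic order, family and genus (a proxy for phylogenetic
#' non-independence). Variance components are estimated by REML on the log
#' scale with a derivative-free simplex start and a quasi-Newton polish;
#' estimates below 1e-10 are mapped to exactly zero and flagged as boundary
#' fits. Fixed-effect covariance is \eqn{(X' V^{-1} X)^{-1}} at the optimum and
#' conditional modes (BLUPs) of the random intercepts are returned.
#'
#' @param data A `"trait_data"` table (filtered as desired) or an
#'   `"allom_table"` from [log10_transform()].
#' @param levels Nesting levels to request; levels that are confounded are
#'   dropped automatically (see [build_design()]).
#' @param fixed_varcomp Optional named vector of variances (`order`, `family`,
#'   `genus` as included, plus `resid`) to hold fixed instead of optimising;
#'   all-zero components give the ordinary least-squares solution.
#' @param start Optional starting values for the log variance components.
#' @param control List of optimiser settings: `nm_maxit` (simplex iterations,
#'   default 500), `bfgs` (logical, quasi-Newton polish, default `TRUE`),
#'   `reltol` (default 1e-10).
#' @param reml Use REML (default). `reml = FALSE` is intentionally unsupported
#'   and errors; SE-style inference here is REML-based.
#' @return An object of class `"allom_fit"`. Methods: `print`, `summary`,
#'   `coef`, `vcov`, `confint` (Wald), `anova` (Type II Wald chi-square),
#'   `predict`, `simulate`, `fitted`, `residuals`, `logLik`, `plot`.
#' @examples
#' sc <- trait_scenario("BMR")
#' dat <- simulate_traits(sc, seed = 1)
#' fit <- allom_fit(dat)
#' coef(fit)
#' habitat_equations(fit)
#' @export
allom_fit <- function(data, levels = c("order", "family", "genus"),
                      fixed_varcomp = NULL, start = NULL, control = list(),
                      reml = TRUE) {
  if (!isTRUE(reml))
    stop("only REML estimation is implemented", call. = FALSE)
  cl <- match.call()
  design <- build_design(data, levels = levels)
  eng <- reml_engine(design$X, design$y, design$K, blocks = design$blocks,
                     start = start, fixed_varcomp = fixed_varcomp,
                     control = control)
  modes <- cond_modes(eng, design)
  structure(list(call = cl,
                 trait = attr(design$data, "trait") %||% "trait",
                 coefficients = eng$beta,
                 cov_beta = eng$cov_beta,
                 se = eng$se,
                 varcomp = eng$varcomp,
                 reml_loglik = eng$reml_loglik,
                 conditional_modes = modes,
                 converged = eng$converged,
                 boundary = eng$boundary,
                 fevals = eng$fevals,
                 n_species = nrow(design$X),
                 levels_included = design$levels_included,
                 levels_dropped = design$levels_dropped,
                 habitat_estimable = design$habitat_estimable,
                 design = design),
            class = "allom_fit")
}

# Conditional modes u_l = s2_l Z_l' V^-1 (y - X beta) at the REML optimum.
cond_modes <- function(eng, design) {
  out <- list()
  for (lv in names(design$Z)) {
    u <- eng$varcomp[[lv]] * drop(crossprod(design$Z[[lv]], eng$Vir))
    names(u) <- colnames(design$Z[[lv]])
    out[[lv]] <- u
  }
  out
}

# Refit the same design with a new response (parametric bootstrap inner loop).
# Warm-started at the parent fit's variance components with a lighter simplex
# and no polish; falls back to cold settings if the warm fit fails.
refit_response <- function(fit, ynew, fast = TRUE) {
  d <- fit$design
  ctl <- if (fast) list(nm_maxit = 500L, bfgs = FALSE, reltol = 1e-8)
         else list()
  start <- if (!is.null(fit$varcomp)) log(pmax(fit$varcomp, 1e-8)) else NULL
  eng <- reml_engine(d$X, ynew, d$K, blocks = d$blocks, start = start,
                     control = ctl)
  eng$modes <- cond_modes(eng, d)
  eng
}
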