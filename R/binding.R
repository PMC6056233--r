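#' Construct a titration curve
#'
#' Fractional fluorescence as a function of ligand or metal concentration,
#' e.g. maltose dose-response of a donor-labeled maltose-binding protein or
#' Cu2+ binding to an engineered di-histidine site.
#'
#' @param concentrations Numeric vector of ligand concentrations in molar,
#'   non-negative, at least 3 distinct values.
#' @param F_values Fractional fluorescence at each concentration.
#' @param sems Optional standard errors (default 0).
#' @param ligand_label Free-text label.
#' @return An object of class `"titration_curve"`.
#' @export
titration_curve <- function(concentrations, F_values, sems = 0,
                            ligand_label = "") {
  concentrations <- as.numeric(concentrations)
  F_values <- as.numeric(F_values)
  sems <- rep_len(as.numeric(sems), length(concentrations))
  if (length(F_values) != length(concentrations))
    stop("concentrations and F_values must have equal length", call. = FALSE)
  if (any(concentrations < 0))
    stop("concentrations must be non-negative", call. = FALSE)
  if (length(unique(concentrations)) < 3L)
    stop("at least 3 distinct concentrations are required", call. = FALSE)
  if (any(sems < 0)) stop("sems must be non-negative", call. = FALSE)
  structure(list(concentrations = concentrations, F_values = F_values,
                 sems = sems, ligand_label = as.character(ligand_label)[1L]),
            class = "titration_curve")
}

#' Read a titration table (columns concentration_M, F, optionally sem)
#'
#' @param path CSV/TSV path.
#' @param ligand_label Label; defaults to the file name.
#' @return A [titration_curve()].
#' @export
read_titration <- function(path, ligand_label = basename(path)) {
  tab <- read_delim_sniff(path)
  if (!all(c("concentration_M", "F") %in% names(tab)))
    stop("titration file must have columns 'concentration_M' and 'F': ",
         path, call. = FALSE)
  titration_curve(tab$concentration_M, tab$F,
                  sems = if ("sem" %in% names(tab)) tab$sem else 0,
                  ligand_label = ligand_label)
}

#' Fit a single-site binding isotherm
#'
#' Least-squares fit of the rectangular hyperbola
#'
#' \deqn{F(L) = F_{start} + (F_{end} - F_{start})\,\frac{L}{L + K_d}}
#'
#' (Hill coefficient fixed at 1) to a titration curve, by
#' Levenberg-Marquardt. Initialization: F_start from the lowest-
#' concentration point, F_end from the highest, Kd from the concentration
#' nearest half amplitude. Both asymptotes float by default.
#'
#' @param curve A [titration_curve()].
#' @param weights `"none"` (default) for unweighted least squares or
#'   `"inverse_sem"` for weights 1/sem^2 (requires all sems > 0).
#' @param hill Optional free Hill coefficient; `NULL` (default) fixes it
#'   at 1, the single-site model.
#' @return An `"isotherm_fit"`: list with `Kd_app` (M), `F_start`, `F_end`,
#'   `hill` (if floated), `residual_rms`, `covariance`, `extrapolated`
#'   (TRUE when Kd_app falls outside the spanned nonzero-concentration
#'   range), and the underlying `nls` fit.
#' @seealso [saturation_check()]
#' @export
fit_isotherm <- function(curve, weights = c("none", "inverse_sem"),
                         hill = NULL) {
  stopifnot(inherits(curve, "titration_curve"))
  weights <- match.arg(weights)
  L <- curve$concentrations
  y <- curve$F_values
  if (stats::sd(y) == 0)
    stop("degenerate fit: titration response is flat", call. = FALSE)
  o <- order(L)
  f0 <- y[o][1L]; f1 <- y[o][length(y)]
  half <- (f0 + f1) / 2
  kd0 <- L[which.min(abs(y - half))]
  if (kd0 <= 0) kd0 <- stats::median(L[L > 0])
  w <- NULL
  if (weights == "inverse_sem") {
    if (any(curve$sems <= 0))
      stop("inverse_sem weighting requires all sems > 0", call. = FALSE)
    w <- 1 / curve$sems^2
  }
  dat <- data.frame(L = L, y = y)
  fit_args <- if (is.null(hill)) list(
    formula = y ~ F_start + (F_end - F_start) * L / (L + Kd),
    data = dat, start = list(F_start = f0, F_end = f1, Kd = kd0),
    lower = c(-Inf, -Inf, .Machine$double.xmin),
    control = minpack.lm::nls.lm.control(maxiter = 200))
  else list(
    formula = y ~ F_start + (F_end - F_start) * L^h / (L^h + Kd^h),
    data = dat, start = list(F_start = f0, F_end = f1, Kd = kd0, h = hill),
    lower = c(-Inf, -Inf, .Machine$double.xmin, 0.1),
    control = minpack.lm::nls.lm.control(maxiter = 200))
  if (!is.null(w)) fit_args$weights <- w
  fit <- tryCatch(
    do.call(minpack.lm::nlsLM, fit_args),
    error = function(e) stop("isotherm fit failed to converge: ",
                             conditionMessage(e), call. = FALSE))
  cf <- stats::coef(fit)
  nonzero <- L[L > 0]
  structure(list(
    Kd_app = unname(cf["Kd"]),
    F_start = unname(cf["F_start"]),
    F_end = unname(cf["F_end"]),
    hill = if (is.null(hill)) 1 else unname(cf["h"]),
    hill_floated = !is.null(hill),
    residual_rms = sqrt(mean(stats::resid(fit)^2)),
    covariance = tryCatch(stats::vcov(fit), error = function(e) NULL),
    extrapolated = cf["Kd"] < min(nonzero) || cf["Kd"] > max(nonzero),
    ligand_label = curve$ligand_label,
    fit = fit), class = "isotherm_fit")
}

#' @export
print.isotherm_fit <- function(x, ...) {
  cat(sprintf(
    "<isotherm fit%s: Kd_app = %.4g M, F %.3g -> %.3g, rms %.3g%s>\n",
    if (nzchar(x$ligand_label)) paste0(" [", x$ligand_label, "]") else "",
    x$Kd_app, x$F_start, x$F_end, x$residual_rms,
    if (x$extrapolated) ", Kd EXTRAPOLATED beyond data" else ""))
  invisible(x)
}

#' Fractional occupancy at a concentration
#'
#' L / (L + Kd_app) under the fitted single-site model: used, e.g., to
#' verify that a working metal concentration saturates its binding site.
#'
#' @param fit An [fit_isotherm()] result (or a bare Kd in molar).
#' @param concentration Ligand concentration in molar; vectorized.
#' @return Occupancy in `[0, 1)`.
#' @export
saturation_check <- function(fit, concentration) {
  kd <- if (inherits(fit, "isotherm_fit")) fit$Kd_app else as.numeric(fit)
  if (kd <= 0) stop("Kd must be > 0", call. = FALSE)
  if (any(concentration < 0))
    stop("concentration must be non-negative", call. = FALSE)
  concentration / (concentration + kd)
}
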