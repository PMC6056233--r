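#' FRET efficiency corrected for background energy transfer
#'
#' Quenching of the test construct reflects both site-specific FRET and
#' nonspecific transfer (e.g. solution quenching by free acceptor). Treating
#' the two as independent de-excitation pathways and referencing against a
#' control construct lacking the acceptor site gives
#'
#' \deqn{E = 1 - \frac{1}{1 + 1/F_{site} - 1/F_{nosite}}}
#'
#' where F_site and F_nosite are the fractional fluorescences of the test
#' and no-site-control constructs. With no background quenching
#' (F_nosite = 1) this reduces to E = 1 - F_site, agreeing exactly with the
#' ratio form of [efficiency_simplified()]; the two converge whenever
#' control quenching is small.
#'
#' @param F_site Fractional fluorescence of the test construct: a
#'   `"fractional_fluorescence"` from [fractional_fluorescence()] or a bare
#'   number (> 0).
#' @param F_no_site Fractional fluorescence of the no-acceptor-site control
#'   (> 0).
#' @return An `"efficiency_estimate"`: list with `E`, `sem` (NA until
#'   propagated, see [propagate_mc()]), `method = "corrected"`.
#' @export
efficiency_corrected <- function(F_site, F_no_site) {
  fs <- as_F(F_site); fn <- as_F(F_no_site)
  if (fs <= 0 || fn <= 0)
    stop("fractional fluorescences must be > 0", call. = FALSE)
  denom <- 1 + 1 / fs - 1 / fn
  if (denom <= 0)
    stop("inconsistent inputs: control quenched more than test ",
         "(1 + 1/F_site - 1/F_no_site <= 0)", call. = FALSE)
  efficiency_estimate(1 - 1 / denom, method = "corrected")
}

#' FRET efficiency by the simplified ratio formula
#'
#' \deqn{E = 1 - F_{site} / F_{nosite}}
#'
#' Accounts for nonspecific fluorescence loss (bleaching, protein loss) but
#' not for background energy transfer. When background quenching is small
#' (F_nosite near 1) the corrected and simplified values converge.
#'
#' @inheritParams efficiency_corrected
#' @return An `"efficiency_estimate"` with `method = "simplified"`.
#' @export
efficiency_simplified <- function(F_site, F_no_site) {
  fs <- as_F(F_site); fn <- as_F(F_no_site)
  if (fn <= 0)
    stop("F_no_site must be > 0", call. = FALSE)
  efficiency_estimate(1 - fs / fn, method = "simplified")
}

as_F <- function(x) {
  if (is.list(x) && !is.null(x$F)) x$F else as.numeric(x)[1L]
}
as_sem <- function(x) {
  if (is.list(x) && !is.null(x$sem)) x$sem else 0
}

efficiency_estimate <- function(E, method, sem = NA_real_, mc_cycles = 0L,
                                rejected = 0L) {
  structure(list(E = E, sem = sem, method = method,
                 mc_cycles = as.integer(mc_cycles),
                 rejected = as.integer(rejected)),
            class = "efficiency_estimate")
}

#' @export
print.efficiency_estimate <- function(x, ...) {
  cat(sprintf("<E = %.4f%s (%s%s)>\n", x$E,
              if (is.finite(x$sem)) sprintf(" +/- %.4f", x$sem) else "",
              x$method,
              if (x$mc_cycles > 0L)
                sprintf(", %d MC cycles", x$mc_cycles) else ""))
  invisible(x)
}

#' Monte-Carlo uncertainty propagation for FRET efficiency
#'
#' Propagates the means and standard errors of the two fractional
#' fluorescences through the chosen efficiency formula by resampling, in
#' the style of measurement-uncertainty resamplers: each cycle draws
#' F_site and F_no_site from independent normal distributions
#' (mean = measured F, sd = its SEM), evaluates the formula, and discards
#' draws for which it is undefined (non-positive F or non-positive
#' corrected-formula denominator). The rejection count is reported; more
#' than 50% rejections aborts, since the remaining draws would be badly
#' biased.
#'
#' @param F_site,F_no_site `"fractional_fluorescence"` objects (or lists
#'   with elements `F` and `sem`).
#' @param method `"corrected"` or `"simplified"`.
#' @param cycles Number of Monte-Carlo cycles (default 1e6).
#' @param seed Integer seed; the result is deterministic given the seed.
#' @return An `"efficiency_estimate"` with `E` = sample mean, `sem` =
#'   sample standard deviation of the accepted draws, plus the cycle and
#'   rejection counts. With both SEMs zero the deterministic value is
#'   returned with `sem = 0`.
#' @export
propagate_mc <- function(F_site, F_no_site,
                         method = c("corrected", "simplified"),
                         cycles = 1e6, seed = 1L) {
  method <- match.arg(method)
  fs <- as_F(F_site); ss <- as_sem(F_site)
  fn <- as_F(F_no_site); sn <- as_sem(F_no_site)
  if (cycles < 1) stop("cycles must be >= 1", call. = FALSE)
  if (ss < 0 || sn < 0) stop("SEMs must be non-negative", call. = FALSE)
  point <- if (method == "corrected") efficiency_corrected(fs, fn)
           else efficiency_simplified(fs, fn)
  if (ss == 0 && sn == 0)
    return(efficiency_estimate(point$E, method, sem = 0, mc_cycles = cycles))
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(as.integer(seed))
  draw_s <- stats::rnorm(cycles, fs, ss)
  draw_n <- stats::rnorm(cycles, fn, sn)
  ok <- draw_s > 0 & draw_n > 0
  e <- if (method == "corrected") {
    denom <- 1 + 1 / draw_s - 1 / draw_n
    ok <- ok & denom > 0
    1 - 1 / denom
  } else {
    1 - draw_s / draw_n
  }
  n_rej <- sum(!ok)
  if (n_rej > cycles / 2)
    stop("unstable propagation: ", n_rej, " of ", cycles,
         " draws rejected", call. = FALSE)
  if (n_rej > 0L)
    message("rejected ", n_rej, " of ", cycles, " invalid draws")
  e <- e[ok]
  efficiency_estimate(mean(e), method, sem = stats::sd(e),
                      mc_cycles = cycles, rejected = n_rej)
}

#' First-order (delta-method) SEM for the efficiency formulas
#'
#' Analytic counterpart of [propagate_mc()] for small input uncertainties;
#' useful as a cross-check of the resampler.
#'
#' @inheritParams propagate_mc
#' @return Standard error of E by linear error propagation.
#' @export
delta_method_sem <- function(F_site, F_no_site,
                             method = c("corrected", "simplified")) {
  method <- match.arg(method)
  fs <- as_F(F_site); ss <- as_sem(F_site)
  fn <- as_F(F_no_site); sn <- as_sem(F_no_site)
  if (method == "corrected") {
    denom <- 1 + 1 / fs - 1 / fn
    # dE/dF_site = -1/(fs^2 denom^2); dE/dF_no_site = 1/(fn^2 denom^2)
    sqrt((ss / (fs^2 * denom^2))^2 + (sn / (fn^2 * denom^2))^2)
  } else {
    sqrt((ss / fn)^2 + (fs * sn / fn^2)^2)
  }
}

# Save/restore .Random.seed so package internals do not perturb the
# caller's RNG stream.
.Random.seed_get <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.Random.seed_set <- function(seed) {
  if (is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", seed, envir = globalenv())
  }
}
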