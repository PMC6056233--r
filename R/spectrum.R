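#' Construct a spectrum
#'
#' A spectrum is a wavelength-indexed curve: either a donor emission spectrum
#' (arbitrary fluorescence units) or an acceptor absorption spectrum (molar
#' extinction, M^-1 cm^-1). All downstream photophysics (peak diagnostics,
#' the spectral overlap integral, R0) operates on this type.
#'
#' Negative emission values, which arise from instrument baseline noise, are
#' clipped to zero with a message reporting how many points were affected;
#' negative absorption values are rejected because a negative molar
#' extinction is unphysical.
#'
#' @param wavelengths_nm Numeric vector of wavelengths in nm, strictly
#'   increasing.
#' @param values Numeric vector of the same length: fluorescence intensity
#'   (emission) or molar extinction in M^-1 cm^-1 (absorption).
#' @param kind Either `"emission"` or `"absorption"`.
#' @param label Free-text label carried through reports.
#' @return An object of class `"spectrum"`: a list with elements
#'   `wavelengths_nm`, `values`, `kind`, `label`.
#' @examples
#' s <- spectrum(c(400, 450, 500), c(0, 1, 0.5), kind = "emission")
#' peak_wavelength(s)
#' @export
spectrum <- function(wavelengths_nm, values, kind = c("emission", "absorption"),
                     label = "") {
  kind <- match.arg(kind)
  wavelengths_nm <- as.numeric(wavelengths_nm)
  values <- as.numeric(values)
  if (length(wavelengths_nm) != length(values))
    stop("wavelengths and values must have equal length", call. = FALSE)
  if (length(wavelengths_nm) == 0L)
    stop("spectrum must contain at least one point", call. = FALSE)
  if (anyNA(wavelengths_nm) || anyNA(values) ||
      any(!is.finite(wavelengths_nm)) || any(!is.finite(values)))
    stop("spectrum contains non-finite values", call. = FALSE)
  if (is.unsorted(wavelengths_nm, strictly = TRUE)) {
    o <- order(wavelengths_nm)
    wavelengths_nm <- wavelengths_nm[o]
    values <- values[o]
    if (anyDuplicated(wavelengths_nm))
      stop("duplicate wavelengths in spectrum: ",
           paste(unique(wavelengths_nm[duplicated(wavelengths_nm)]),
                 collapse = ", "), call. = FALSE)
  }
  if (kind == "absorption" && any(values < 0))
    stop("negative absorption values are unphysical (first at ",
         wavelengths_nm[which(values < 0)[1L]], " nm)", call. = FALSE)
  if (kind == "emission" && any(values < 0)) {
    n_neg <- sum(values < 0)
    message("clipped ", n_neg, " negative emission value",
            if (n_neg > 1L) "s", " to zero (baseline noise)")
    values[values < 0] <- 0
  }
  structure(list(wavelengths_nm = wavelengths_nm, values = values,
                 kind = kind, label = as.character(label)[1L]),
            class = "spectrum")
}

#' @export
print.spectrum <- function(x, ...) {
  cat(sprintf("<spectrum: %s%s, %d points, %g-%g nm>\n", x$kind,
              if (nzchar(x$label)) paste0(" '", x$label, "'") else "",
              length(x$wavelengths_nm),
              min(x$wavelengths_nm), max(x$wavelengths_nm)))
  invisible(x)
}

#' Read a spectrum from a two-column delimited file
#'
#' Expects column 1 = wavelength (nm) and column 2 = value. The delimiter is
#' sniffed from comma vs. tab, a header row is detected and skipped, and
#' `#`-prefixed comment lines are ignored. Rows are sorted by wavelength;
#' duplicated wavelengths are an error.
#'
#' @param path Path to a CSV or TSV file.
#' @inheritParams spectrum
#' @return A [spectrum()] object.
#' @seealso [write_spectrum()]
#' @export
read_spectrum <- function(path, kind = c("emission", "absorption"),
                          label = basename(path)) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  lines <- lines[keep]
  line_no <- which(keep)
  if (length(lines) == 0L) stop("no data rows in ", path, call. = FALSE)
  sep <- if (sum(grepl("\t", lines)) >= sum(grepl(",", lines))) "\t" else ","
  fields <- strsplit(lines, sep, fixed = TRUE)
  start <- 1L
  first <- suppressWarnings(as.numeric(fields[[1L]][1:2]))
  if (anyNA(first)) start <- 2L  # header row
  if (start > length(fields)) stop("no data rows in ", path, call. = FALSE)
  wl <- val <- numeric(length(fields) - start + 1L)
  for (i in seq_along(wl)) {
    f <- fields[[start + i - 1L]]
    x <- suppressWarnings(as.numeric(f[1:2]))
    if (length(f) < 2L || anyNA(x))
      stop("malformed row at line ", line_no[start + i - 1L], " of ", path,
           ": '", lines[start + i - 1L], "'", call. = FALSE)
    wl[i] <- x[1L]; val[i] <- x[2L]
  }
  if (anyDuplicated(wl))
    stop("duplicate wavelength ", wl[duplicated(wl)][1L], " nm in ", path,
         call. = FALSE)
  spectrum(wl, val, kind = kind, label = label)
}

#' Write a spectrum to a delimited file
#'
#' Inverse of [read_spectrum()]; the round trip preserves values to full
#' numeric precision.
#'
#' @param s A [spectrum()] object.
#' @param path Output path.
#' @param sep Field delimiter, `","` (default) or `"\t"`.
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(s, path, sep = ",") {
  stopifnot(inherits(s, "spectrum"))
  header <- paste0("# ", s$kind, " spectrum: ", s$label)
  rows <- paste(format(s$wavelengths_nm, digits = 17, trim = TRUE),
                format(s$values, digits = 17, trim = TRUE), sep = sep)
  writeLines(c(header, paste("wavelength_nm", "value", sep = sep), rows), path)
  invisible(path)
}

#' Peak wavelength of a spectrum
#'
#' Wavelength of the maximum value; ties are broken toward the shortest
#' wavelength. Used for environment diagnostics of solvatochromic donors
#' such as L-Anap, whose emission peak shifts with local hydrophobicity
#' (494 nm in aqueous buffer, 475 nm in ethanol).
#'
#' @param s A [spectrum()] object.
#' @return Peak wavelength in nm.
#' @export
peak_wavelength <- function(s) {
  stopifnot(inherits(s, "spectrum"))
  if (all(s$values == 0))
    stop("degenerate spectrum: all values are zero", call. = FALSE)
  s$wavelengths_nm[which.max(s$values)]
}

#' Relative quantum yield from fluorescence-vs-absorbance slopes
#'
#' Computes the quantum yield of a fluorophore in a test condition relative
#' to a reference of known quantum yield, from the slopes of linear fits of
#' fluorescence intensity against absorbance and the refractive indices of
#' the two solvents:
#'
#' \deqn{Q_M = Q_{ref} \frac{slope_M}{slope_{ref}}
#'            \frac{\eta_M^2}{\eta_{ref}^2}}
#'
#' For L-Anap the customary reference is ethanol with Q = 0.48.
#'
#' @param slope Slope of fluorescence vs. absorbance for the test condition
#'   (must be > 0).
#' @param refractive_index Refractive index of the test solvent (>= 1).
#' @param ref_slope,ref_refractive_index Same quantities for the reference.
#' @param ref_quantum_yield Known quantum yield of the reference, in (0, 1].
#' @return The quantum yield of the test condition. Values above 1 trigger a
#'   warning (unphysical, usually an inconsistent reference) but are
#'   returned.
#' @examples
#' quantum_yield(slope = 0.5, refractive_index = 1.36,
#'               ref_slope = 1, ref_refractive_index = 1.36)
#' @export
quantum_yield <- function(slope, refractive_index,
                          ref_slope, ref_refractive_index,
                          ref_quantum_yield = 0.48) {
  if (!is.finite(ref_slope) || ref_slope == 0)
    stop("reference slope must be nonzero", call. = FALSE)
  if (slope <= 0 || ref_slope < 0)
    stop("slopes must be positive", call. = FALSE)
  if (refractive_index < 1 || ref_refractive_index < 1)
    stop("refractive indices must be >= 1", call. = FALSE)
  if (ref_quantum_yield <= 0 || ref_quantum_yield > 1)
    stop("reference quantum yield must lie in (0, 1]", call. = FALSE)
  q <- ref_quantum_yield * (slope / ref_slope) *
    (refractive_index^2 / ref_refractive_index^2)
  if (q > 1)
    warning("computed quantum yield ", signif(q, 4),
            " exceeds 1; check slopes and reference", call. = FALSE)
  q
}

#' Donor-acceptor spectral overlap integral
#'
#' The lambda^4-weighted overlap of the normalized donor emission with the
#' acceptor molar extinction, the J that enters the Forster radius:
#'
#' \deqn{J = \frac{\int F_D(\lambda)\,\varepsilon_A(\lambda)\,
#'   \lambda^4\,d\lambda}{\int F_D(\lambda)\,d\lambda}}
#'
#' Both spectra are linearly interpolated onto the union of their wavelength
#' grids and integrated by the trapezoid rule. The donor normalization
#' integral runs over the full donor support regardless of any integration
#' window, so J is invariant under rescaling of the donor spectrum and
#' linear in the acceptor extinction.
#'
#' @param donor_emission Emission [spectrum()] of the donor, F_D(lambda).
#' @param acceptor_absorption Absorption [spectrum()] of the acceptor,
#'   molar extinction in M^-1 cm^-1.
#' @param window Optional length-2 numeric, wavelength window (nm) over
#'   which the overlap numerator is integrated; defaults to the donor
#'   support.
#' @return J in M^-1 cm^-1 nm^4. Returns 0 with a warning if the spectra do
#'   not overlap in wavelength.
#' @seealso [compute_R0()]
#' @export
overlap_integral <- function(donor_emission, acceptor_absorption,
                             window = NULL) {
  stopifnot(inherits(donor_emission, "spectrum"),
            inherits(acceptor_absorption, "spectrum"))
  if (donor_emission$kind != "emission" ||
      acceptor_absorption$kind != "absorption")
    stop("expected an emission spectrum and an absorption spectrum",
         call. = FALSE)
  dw <- donor_emission$wavelengths_nm
  aw <- acceptor_absorption$wavelengths_nm
  lo <- max(min(dw), min(aw)); hi <- min(max(dw), max(aw))
  denom <- trapz(dw, donor_emission$values)
  if (denom <= 0)
    stop("degenerate donor spectrum: zero integrated emission", call. = FALSE)
  if (lo >= hi) {
    warning("donor and acceptor spectra do not overlap; J = 0", call. = FALSE)
    return(0)
  }
  if (!is.null(window)) {
    stopifnot(length(window) == 2L, window[1L] < window[2L])
    lo <- max(lo, window[1L]); hi <- min(hi, window[2L])
    if (lo >= hi) {
      warning("integration window excludes all overlap; J = 0", call. = FALSE)
      return(0)
    }
  }
  grid <- sort(unique(c(dw[dw >= lo & dw <= hi],
                        aw[aw >= lo & aw <= hi], lo, hi)))
  fd <- stats::approx(dw, donor_emission$values, xout = grid)$y
  ea <- stats::approx(aw, acceptor_absorption$values, xout = grid)$y
  trapz(grid, fd * ea * grid^4) / denom
}

# trapezoid rule on an irregular grid
trapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum((x[-1L] - x[-n]) * (y[-1L] + y[-n])) / 2
}
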