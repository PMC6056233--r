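#' Construct an annotated quenching time course
#'
#' A fluorescence time course (fluorometer cuvette or per-ROI means from
#' imaged membrane sheets) annotated with reagent-addition events: the
#' acceptor (Cu2+ or Cu2+-TETAC) and, optionally, a reversal reagent (DTT
#' or EDTA). The construct field distinguishes the labeled test protein
#' from the no-acceptor-site control and the no-protein background.
#'
#' @param times Strictly increasing numeric vector, seconds (or frame
#'   index).
#' @param fluorescence Numeric vector of the same length, arbitrary units.
#' @param events Data frame with columns `time` and `label`; labels are
#'   `"add_acceptor"`, `"add_reversal"` or `"other"`. Every event time must
#'   fall within the recorded time range.
#' @param construct One of `"test"`, `"no_site_control"`,
#'   `"no_protein_background"`.
#' @param condition One of `"apo"`, `"ligand"`.
#' @return An object of class `"quench_experiment"`.
#' @export
quench_experiment <- function(times, fluorescence, events,
                              construct = c("test", "no_site_control",
                                            "no_protein_background"),
                              condition = c("apo", "ligand")) {
  construct <- match.arg(construct)
  condition <- match.arg(condition)
  times <- as.numeric(times)
  fluorescence <- as.numeric(fluorescence)
  if (length(times) != length(fluorescence))
    stop("times and fluorescence must have equal length", call. = FALSE)
  if (is.unsorted(times, strictly = TRUE))
    stop("times must be strictly increasing", call. = FALSE)
  events <- as.data.frame(events)
  if (nrow(events) > 0L) {
    if (!all(c("time", "label") %in% names(events)))
      stop("events must have columns 'time' and 'label'", call. = FALSE)
    bad <- !events$label %in% c("add_acceptor", "add_reversal", "other")
    if (any(bad))
      stop("unknown event label: ", events$label[bad][1L], call. = FALSE)
    if (any(events$time < min(times)) || any(events$time > max(times)))
      stop("event time outside the recorded time range", call. = FALSE)
    events <- events[order(events$time), c("time", "label")]
  } else {
    events <- data.frame(time = numeric(0), label = character(0))
  }
  structure(list(times = times, fluorescence = fluorescence, events = events,
                 construct = construct, condition = condition),
            class = "quench_experiment")
}

#' @export
print.quench_experiment <- function(x, ...) {
  cat(sprintf("<quench_experiment: %s/%s, %d samples, events: %s>\n",
              x$construct, x$condition, length(x$times),
              if (nrow(x$events)) paste0(x$events$label, "@", x$events$time,
                                         collapse = ", ") else "none"))
  invisible(x)
}

#' Read a quench time course with its event annotations
#'
#' The trace file has columns `time` and `fluorescence` (CSV or TSV, header
#' required, `#` comments ignored); events come either from a sidecar table
#' with columns `time` and `label`, or from a data frame.
#'
#' @param path Trace file path.
#' @param events A data frame, or path to a sidecar delimited file, with
#'   columns `time` and `label`.
#' @inheritParams quench_experiment
#' @return A [quench_experiment()].
#' @export
read_quench_trace <- function(path, events, construct = "test",
                              condition = "apo") {
  tab <- read_delim_sniff(path)
  if (!all(c("time", "fluorescence") %in% names(tab)))
    stop("trace file must have columns 'time' and 'fluorescence': ", path,
         call. = FALSE)
  if (is.character(events)) events <- read_delim_sniff(events)
  quench_experiment(tab$time, tab$fluorescence, events,
                    construct = construct, condition = condition)
}

#' Write a quench time course (and events) to delimited files
#'
#' @param x A [quench_experiment()].
#' @param path Output trace path; the event sidecar is written to
#'   `events_path`.
#' @param events_path Path for the event table (default: `path` with an
#'   `_events` suffix before the extension).
#' @return `path`, invisibly.
#' @export
write_quench_trace <- function(x, path,
                               events_path = sub("(\\.[^.]+)?$", "_events\\1",
                                                 path)) {
  stopifnot(inherits(x, "quench_experiment"))
  utils::write.csv(data.frame(time = x$times, fluorescence = x$fluorescence),
                   path, row.names = FALSE, quote = FALSE)
  utils::write.csv(x$events, events_path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

read_delim_sniff <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  first <- readLines(path, n = 20L, warn = FALSE)
  first <- first[!grepl("^\\s*#", first)]
  sep <- if (sum(grepl("\t", first)) >= sum(grepl(",", first))) "\t" else ","
  utils::read.table(path, header = TRUE, sep = sep, comment.char = "#",
                    stringsAsFactors = FALSE)
}

#' Subtract an averaged no-protein background trace
#'
#' Fluorometer records contain signal that is not protein fluorescence
#' (buffer Raman, reagent absorbance changes). The convention is to run
#' several no-protein experiments with the same reagent additions, average
#' them, and subtract the average pointwise. Backgrounds recorded on a
#' different time base are linearly interpolated onto the trace's times;
#' they must span the full trace.
#'
#' @param trace A [quench_experiment()].
#' @param background_traces List of [quench_experiment()]s with
#'   `construct = "no_protein_background"`.
#' @return The background-subtracted trace; events are preserved.
#' @export
subtract_background <- function(trace, background_traces) {
  stopifnot(inherits(trace, "quench_experiment"))
  if (inherits(background_traces, "quench_experiment"))
    background_traces <- list(background_traces)
  if (length(background_traces) == 0L)
    stop("at least one background trace is required", call. = FALSE)
  bg <- vapply(background_traces, function(b) {
    stopifnot(inherits(b, "quench_experiment"))
    if (b$construct != "no_protein_background")
      stop("background traces must have construct 'no_protein_background'",
           call. = FALSE)
    y <- stats::approx(b$times, b$fluorescence, xout = trace$times)$y
    if (anyNA(y))
      stop("background trace does not span the trace's time range",
           call. = FALSE)
    y
  }, numeric(length(trace$times)))
  out <- trace
  out$fluorescence <- trace$fluorescence - rowMeans(as.matrix(bg))
  out
}

#' Fractional fluorescence around the acceptor addition
#'
#' F = (fluorescence with acceptor) / (fluorescence without acceptor),
#' estimated from plateau windows: the mean of the last `window_points`
#' samples before the acceptor addition (denominator) and the mean of the
#' last `window_points` samples of the quenched plateau, i.e. before the
#' next annotated event or the end of the trace (numerator). The SEM is
#' propagated from the two window standard errors by the first-order delta
#' method for a ratio.
#'
#' @param trace A [quench_experiment()] containing an `add_acceptor` event.
#' @param window_points Number of plateau samples averaged on each side
#'   (default 3).
#' @return A `"fractional_fluorescence"`: list with `F`, `sem`, `n`
#'   (= `window_points`), `construct`, `condition`.
#' @export
fractional_fluorescence <- function(trace, window_points = 3) {
  stopifnot(inherits(trace, "quench_experiment"))
  ev <- trace$events
  i_acc <- which(ev$label == "add_acceptor")
  if (length(i_acc) == 0L)
    stop("trace has no add_acceptor event", call. = FALSE)
  t_acc <- ev$time[i_acc[1L]]
  later <- ev$time[ev$time > t_acc]
  t_end <- if (length(later)) min(later) else Inf
  pre <- which(trace$times < t_acc)
  post <- which(trace$times >= t_acc & trace$times < t_end)
  if (length(pre) < window_points || length(post) < window_points)
    stop("fewer than ", window_points,
         " samples on one side of the acceptor addition", call. = FALSE)
  pre <- utils::tail(pre, window_points)
  post <- utils::tail(post, window_points)
  m0 <- mean(trace$fluorescence[pre])
  m1 <- mean(trace$fluorescence[post])
  if (m0 <= 0)
    stop("degenerate trace: pre-acceptor plateau mean is not positive",
         call. = FALSE)
  se0 <- stats::sd(trace$fluorescence[pre]) / sqrt(window_points)
  se1 <- stats::sd(trace$fluorescence[post]) / sqrt(window_points)
  f <- m1 / m0
  sem <- abs(f) * sqrt((se1 / m1)^2 + (se0 / m0)^2)
  if (!is.finite(sem)) sem <- 0
  structure(list(F = f, sem = sem, n = window_points,
                 construct = trace$construct, condition = trace$condition),
            class = "fractional_fluorescence")
}

#' @export
print.fractional_fluorescence <- function(x, ...) {
  cat(sprintf("<F = %.4f +/- %.4f (%s/%s, n = %d)>\n", x$F, x$sem,
              x$construct, x$condition, x$n))
  invisible(x)
}

#' Check reversal of quenching
#'
#' Cysteine-conjugated Cu2+-TETAC is released by DTT and metal bound to a
#' di-histidine site by EDTA; fluorescence should recover nearly completely,
#' which distinguishes site-specific quenching from fluorophore loss. Passes
#' when the post-reversal plateau reaches at least `tolerance` times the
#' pre-acceptor plateau.
#'
#' @param trace A [quench_experiment()] with an `add_reversal` event.
#' @param window_points Plateau samples averaged (default 3).
#' @param tolerance Minimum recovered fraction of the pre-acceptor level
#'   (default 0.9).
#' @return List with `reversed` (logical), `recovered_fraction`, and the
#'   two plateau means.
#' @export
reversal_check <- function(trace, window_points = 3, tolerance = 0.9) {
  stopifnot(inherits(trace, "quench_experiment"))
  ev <- trace$events
  i_rev <- which(ev$label == "add_reversal")
  if (length(i_rev) == 0L)
    stop("trace has no add_reversal event", call. = FALSE)
  i_acc <- which(ev$label == "add_acceptor")
  if (length(i_acc) == 0L)
    stop("trace has no add_acceptor event", call. = FALSE)
  t_acc <- ev$time[i_acc[1L]]
  t_rev <- ev$time[i_rev[1L]]
  pre <- utils::tail(which(trace$times < t_acc), window_points)
  later <- ev$time[ev$time > t_rev]
  t_end <- if (length(later)) min(later) else Inf
  post <- utils::tail(which(trace$times >= t_rev & trace$times < t_end),
                      window_points)
  if (length(pre) < window_points || length(post) < window_points)
    stop("insufficient samples around the reversal event", call. = FALSE)
  m_pre <- mean(trace$fluorescence[pre])
  m_post <- mean(trace$fluorescence[post])
  frac <- m_post / m_pre
  list(reversed = frac >= tolerance, recovered_fraction = frac,
       pre_acceptor_mean = m_pre, post_reversal_mean = m_post)
}
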