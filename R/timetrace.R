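# Confocal-style intensity trajectory analysis: photon binning, intensity
# autocorrelation (direct and multiple-tau estimators) and threshold-based
# on/off segmentation.

#' Bin a photon stream into an intensity trace
#'
#' counts[i] holds the photons with macrotime in
#' \code{[(i-1)*bin, i*bin)}; the total photon number is conserved.
#'
#' @param stream Photon stream data.frame (needs \code{macrotime_ns}) or a
#'   numeric vector of macrotimes in ns.
#' @param bin_time Bin width in seconds (default 1 ms).
#' @param duration Optional trace duration in s (default: last photon's
#'   bin).
#' @return Object of class \code{intensity_trace}: \code{counts} (integer),
#'   \code{bin_time} (s), \code{t0 = 0}.
#' @export
bin_photons <- function(stream, bin_time = 1e-3, duration = NULL) {
  stopifnot(bin_time > 0)
  t_ns <- if (is.data.frame(stream)) stream$macrotime_ns else stream
  if (length(t_ns) == 0L)
    return(structure(list(counts = integer(0), bin_time = bin_time, t0 = 0),
                     class = "intensity_trace"))
  bin_ns <- bin_time * 1e9
  idx <- floor(t_ns / bin_ns) + 1
  nbins <- if (is.null(duration)) max(idx) else ceiling(duration / bin_time)
  structure(list(counts = tabulate(idx[idx <= nbins], nbins = nbins),
                 bin_time = bin_time, t0 = 0),
            class = "intensity_trace")
}

#' Intensity autocorrelation of a binned trace (direct estimator)
#'
#' G(tau) = <I(t) I(t+tau)> / <I>^2 with the symmetric normalization
#' (separate means over the leading and trailing segments), evaluated at
#' integer-bin lags.  Suited to short traces and explicit lag grids.
#'
#' @param trace An \code{intensity_trace} (or integer vector of counts with
#'   \code{bin_time} supplied).
#' @param lags Lag times in seconds (rounded to whole bins; lag 0 excluded
#'   from shot-noise considerations is allowed but carries the shot-noise
#'   spike).
#' @param bin_time Bin width in s when \code{trace} is a bare vector.
#' @param normalization_lag If non-NULL, divide the curve by its value at
#'   this lag (linear interpolation on the lag grid; default NULL = raw G).
#' @return Object of class \code{correlation_curve}: data.frame-like list
#'   with \code{lags} (s), \code{G}, \code{normalization_lag}.
#' @export
autocorrelate_trace <- function(trace, lags, bin_time = NULL,
                                normalization_lag = NULL) {
  if (inherits(trace, "intensity_trace")) {
    x <- as.numeric(trace$counts); bt <- trace$bin_time
  } else {
    if (is.null(bin_time)) stop("autocorrelate_trace: bin_time required")
    x <- as.numeric(trace); bt <- bin_time
  }
  n <- length(x)
  if (n < 2L) stop("autocorrelate_trace: need >= 2 bins")
  if (mean(x) == 0) stop("autocorrelate_trace: zero mean intensity")
  klags <- unique(pmax(0L, as.integer(round(lags / bt))))
  klags <- klags[klags < n - 1L]
  G <- vapply(klags, function(k) {
    a <- x[seq_len(n - k)]
    b <- x[seq_len(n - k) + k]
    mean(a * b) / (mean(a) * mean(b))
  }, 0)
  .finish_curve(klags * bt, G, normalization_lag)
}

#' Multiple-tau intensity autocorrelation of a photon stream
#'
#' Multiple-tau estimator spanning microseconds to seconds: the photon
#' stream is binned at \code{base_bin}; after each octave of
#' \code{points_per_octave} lags the trace is coarsened by a factor of two.
#' Symmetric normalization is applied at every lag.
#'
#' @param stream Photon stream data.frame or numeric macrotimes (ns).
#' @param base_bin Finest bin width in seconds (default 10 us).
#' @param points_per_octave Lags per octave (default 8).
#' @param max_lag Largest lag in seconds (default 1).
#' @param normalization_lag If non-NULL, normalize the curve to its value at
#'   this lag (default 1 ms, the convention used for trajectory
#'   comparisons).
#' @return A \code{correlation_curve}.
#' @export
autocorrelate_photons <- function(stream, base_bin = 1e-5,
                                  points_per_octave = 8L, max_lag = 1,
                                  normalization_lag = 1e-3) {
  tr <- bin_photons(stream, base_bin)
  x <- as.numeric(tr$counts)
  if (length(x) < 2L) stop("autocorrelate_photons: need >= 2 events")
  if (mean(x) == 0) stop("autocorrelate_photons: zero mean intensity")
  bt <- base_bin
  lags_s <- numeric(0); G <- numeric(0)
  k_set <- seq_len(points_per_octave)
  repeat {
    n <- length(x)
    ks <- k_set[k_set < n - 1L]
    if (!length(ks)) break
    for (k in ks) {
      lag <- k * bt
      if (lag > max_lag) break
      if (lag %in% lags_s) next
      a <- x[seq_len(n - k)]
      b <- x[seq_len(n - k) + k]
      lags_s <- c(lags_s, lag)
      G <- c(G, mean(a * b) / (mean(a) * mean(b)))
    }
    if (max(ks) * bt > max_lag || n < 4L) break
    # coarsen by 2
    if (n %% 2L == 1L) x <- x[-n]
    x <- x[c(TRUE, FALSE)] + x[c(FALSE, TRUE)]
    bt <- bt * 2
    k_set <- seq.int(points_per_octave %/% 2L + 1L, points_per_octave)
  }
  ord <- order(lags_s)
  .finish_curve(lags_s[ord], G[ord], normalization_lag)
}

.finish_curve <- function(lags, G, normalization_lag) {
  out <- list(lags = lags, G = G, normalization_lag = normalization_lag)
  if (!is.null(normalization_lag)) {
    if (normalization_lag < min(lags) || normalization_lag > max(lags))
      stop("normalization_lag outside the lag range")
    g0 <- stats::approx(lags, G, xout = normalization_lag)$y
    out$G <- G / g0
  }
  structure(out, class = "correlation_curve")
}

#' Threshold segmentation of an intensity trace into on/off dwells
#'
#' Contiguous bins strictly above the threshold form on-dwells, the rest
#' off-dwells; dwells alternate and their durations sum to the trace
#' duration.  The default threshold is the background mean plus three
#' standard deviations, both estimated from the lowest decile of the
#' counts.
#'
#' @param trace An \code{intensity_trace}.
#' @param threshold Counts-per-bin threshold; NULL for the default rule.
#' @return List with \code{on_dwells}, \code{off_dwells} (s),
#'   \code{threshold}, and \code{on_mask} (logical per bin).
#' @export
segment_on_off <- function(trace, threshold = NULL) {
  x <- trace$counts
  if (length(x) == 0L) stop("segment_on_off: empty trace")
  if (is.null(threshold)) {
    low <- x[x <= stats::quantile(x, 0.1)]
    s <- stats::sd(low)
    threshold <- mean(low) + 3 * (if (is.finite(s)) s else 0)
  }
  on <- x > threshold
  r <- rle(on)
  dur <- r$lengths * trace$bin_time
  list(on_dwells = dur[r$values], off_dwells = dur[!r$values],
       threshold = threshold, on_mask = on)
}

#' @export
print.correlation_curve <- function(x, ...) {
  cat("Intensity autocorrelation:", length(x$lags), "lags from",
      signif(min(x$lags), 3), "to", signif(max(x$lags), 3), "s",
      if (!is.null(x$normalization_lag))
        paste0("(normalized at ", signif(x$normalization_lag, 3), " s)"),
      "\n")
  invisible(x)
}
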