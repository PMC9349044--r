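# Photoswitching fingerprint analysis of localization tables: photon
# filtering, track linking, on/off dwell statistics, cumulative
# localization curves and T80.

#' Filter localizations by photon count
#'
#' Keeps rows whose photon count is strictly greater than
#' \code{min_photons}, preserving order.  Conventional thresholds are 500
#' photons per frame for dSTORM and 6,000 for DNA-PAINT.
#'
#' @param table Localization data.frame with a \code{photons} column.
#' @param min_photons Threshold (strict >); 0 keeps everything.
#' @return The filtered data.frame.
#' @export
filter_localizations <- function(table, min_photons) {
  if (min_photons < 0) stop("filter_localizations: min_photons must be >= 0")
  table[table$photons > min_photons, , drop = FALSE]
}

#' Link localizations of immobile structures into tracks
#'
#' Greedy agglomerative spatial clustering on (x, y), ignoring time, suited
#' to immobile nanostructures: each localization (in frame order) joins the
#' nearest existing track whose running centroid lies within
#' \code{radius_nm}, otherwise it seeds a new track.  Ties are broken by
#' smallest distance, then lowest track id.  Localizations of the same
#' track falling in the same frame are merged with photons summed.
#'
#' @param table Localization data.frame (frame, x_nm, y_nm, photons).
#' @param radius_nm Tracking radius in nm (default 200).
#' @return A list of \code{track} objects, each with \code{track_id},
#'   \code{frames} (sorted, unique), \code{photons} (per frame, merged),
#'   \code{centroid} (nm), \code{n_locs} (rows before in-frame merging).
#' @export
link_tracks <- function(table, radius_nm = 200) {
  if (radius_nm <= 0) stop("link_tracks: radius_nm must be > 0")
  if (nrow(table) == 0L) return(list())
  tb <- table[order(table$frame), , drop = FALSE]
  n <- nrow(tb)
  # growing track store
  cap <- 64L
  cx <- numeric(cap); cy <- numeric(cap); cn <- integer(cap)
  ntr <- 0L
  assign_id <- integer(n)
  x <- tb$x_nm; y <- tb$y_nm
  r2 <- radius_nm^2
  for (i in seq_len(n)) {
    if (ntr > 0L) {
      d2 <- (cx[seq_len(ntr)] / cn[seq_len(ntr)] - x[i])^2 +
        (cy[seq_len(ntr)] / cn[seq_len(ntr)] - y[i])^2
      j <- which.min(d2)                       # ties: lowest id via which.min
      if (d2[j] <= r2) {
        assign_id[i] <- j
        cx[j] <- cx[j] + x[i]; cy[j] <- cy[j] + y[i]; cn[j] <- cn[j] + 1L
        next
      }
    }
    ntr <- ntr + 1L
    if (ntr > cap) {
      cap <- cap * 2L
      length(cx) <- cap; length(cy) <- cap; length(cn) <- cap
    }
    cx[ntr] <- x[i]; cy[ntr] <- y[i]; cn[ntr] <- 1L
    assign_id[i] <- ntr
  }
  lapply(seq_len(ntr), function(j) {
    sel <- assign_id == j
    fr <- tb$frame[sel]; ph <- tb$photons[sel]
    mf <- tapply(ph, fr, sum)                  # merge same-frame localizations
    frames <- as.integer(names(mf))
    structure(list(track_id = j,
                   frames = frames,
                   photons = as.numeric(mf),
                   centroid = c(x = cx[j] / cn[j], y = cy[j] / cn[j]),
                   n_locs = sum(sel)),
              class = "track")
  })
}

#' Photoswitching fingerprint statistics of one track
#'
#' On-times are the lengths of maximal runs of consecutive frames with a
#' localization; off-times are the gaps between runs, counted as
#' \code{start - end - 1} frames (frames with no localization strictly
#' between two events); the number of on-events is the number of runs.  A
#' single-frame blip is a valid on-event.  Intensity is the mean photon
#' count over on-frames, reported per millisecond.  T80 is the time (frame
#' number times frame time) at which the cumulative number of localizations
#' first reaches 80% of the track total.
#'
#' @param track A \code{track} from [link_tracks()].
#' @param frame_time Frame exposure time in seconds.
#' @return Object of class \code{fingerprint_summary}: \code{on_times},
#'   \code{off_times} (frames), \code{on_times_s}, \code{off_times_s},
#'   \code{n_on_events}, \code{mean_photons_per_ms}, \code{t80} (s),
#'   \code{total_localizations}.
#' @export
fingerprint_stats <- function(track, frame_time) {
  fr <- track$frames
  if (length(fr) == 0L) stop("fingerprint_stats: empty track")
  stopifnot(frame_time > 0)
  fr <- sort(unique(fr))
  brk <- which(diff(fr) > 1L)
  run_start <- fr[c(1L, brk + 1L)]
  run_end <- fr[c(brk, length(fr))]
  on_times <- run_end - run_start + 1L
  off_times <- if (length(run_start) > 1L)
    run_start[-1L] - run_end[-length(run_end)] - 1L else integer(0)
  total <- length(fr)
  t80_frame <- fr[which(seq_len(total) >= 0.8 * total)[1L]]
  structure(list(
    on_times = as.integer(on_times),
    off_times = as.integer(off_times),
    on_times_s = on_times * frame_time,
    off_times_s = off_times * frame_time,
    n_on_events = length(on_times),
    mean_photons_per_ms = mean(track$photons) / (frame_time * 1000),
    t80 = t80_frame * frame_time,
    total_localizations = total,
    track_id = track$track_id
  ), class = "fingerprint_summary")
}

#' Cumulative localization curve
#'
#' Per-frame cumulative number of localizations across a set of tracks, the
#' "cumulative localizations detected per frame as a function of time"
#' statistic: linear for homogeneous blinking, front-loaded (convex then
#' flat) for structures whose on-state is rapidly repopulated by energy
#' transfer.
#'
#' @param tracks List of \code{track} objects (or one track).
#' @param n_frames Total number of frames (must be > max frame).
#' @return Integer vector of length \code{n_frames}; non-decreasing, final
#'   value equals the total number of localized frames.
#' @export
cumulative_curve <- function(tracks, n_frames) {
  if (inherits(tracks, "track")) tracks <- list(tracks)
  frames <- unlist(lapply(tracks, `[[`, "frames"), use.names = FALSE)
  if (length(frames) && n_frames < max(frames) + 1L)
    stop("cumulative_curve: n_frames must be >= max frame + 1")
  counts <- tabulate(frames + 1L, nbins = n_frames)
  cumsum(counts)
}

#' T80 from a cumulative curve
#'
#' Time at which a cumulative localization curve first reaches 80% of its
#' final value (ceiling convention: the first frame at or above the 80%
#' mark, well-defined for small counts).
#'
#' @param curve Non-decreasing cumulative counts (from
#'   [cumulative_curve()]).
#' @param frame_time Frame time in seconds.
#' @return T80 in seconds (NA for an all-zero curve).
#' @export
t80_from_curve <- function(curve, frame_time) {
  total <- curve[length(curve)]
  if (total == 0) return(NA_real_)
  (which(curve >= 0.8 * total)[1L] - 1L) * frame_time
}

#' Aggregate fingerprint summaries into distribution tables
#'
#' Builds normalized histograms ("relative occurrence") of on-state
#' intensity, on-times, off-times and on-events across structures, plus the
#' median of each quantity.  Medians are the headline statistic.
#'
#' @param summaries List of \code{fingerprint_summary} objects.
#' @param breaks Optional named list of histogram break vectors (names among
#'   intensity, on_time, off_time, on_events).
#' @return List of class \code{fingerprint_aggregate} with
#'   \code{histograms} (data.frames mid/relative_occurrence summing to 1)
#'   and \code{medians} (named vector: intensity is photons/ms; on_time and
#'   off_time in seconds, pooled over all events; on_events per track).
#' @export
aggregate_fingerprints <- function(summaries, breaks = NULL) {
  if (length(summaries) < 1L) stop("aggregate_fingerprints: need >= 1 summary")
  vals <- list(
    intensity = vapply(summaries, `[[`, 0, "mean_photons_per_ms"),
    on_time = unlist(lapply(summaries, `[[`, "on_times_s"), use.names = FALSE),
    off_time = unlist(lapply(summaries, `[[`, "off_times_s"),
                      use.names = FALSE),
    on_events = vapply(summaries, `[[`, 0, "n_on_events")
  )
  hist1 <- function(v, br) {
    if (length(v) == 0L)
      return(data.frame(mid = numeric(0), relative_occurrence = numeric(0)))
    if (is.null(br)) br <- pretty(v, n = 30)
    if (length(unique(v)) == 1L) br <- c(v[1] - 0.5, v[1] + 0.5)
    h <- graphics::hist(v, breaks = br, plot = FALSE, include.lowest = TRUE)
    data.frame(mid = h$mids, relative_occurrence = h$counts / sum(h$counts))
  }
  hs <- lapply(names(vals), function(nm) hist1(vals[[nm]], breaks[[nm]]))
  names(hs) <- names(vals)
  structure(list(
    histograms = hs,
    medians = vapply(vals, function(v)
      if (length(v)) stats::median(v) else NA_real_, 0)
  ), class = "fingerprint_aggregate")
}

#' Fingerprint an entire localization table
#'
#' Convenience pipeline: photon filtering, track linking, per-track
#' fingerprint statistics and aggregation.
#'
#' @param table Localization data.frame.
#' @param frame_time Frame time in seconds.
#' @param min_photons Photon threshold (strict >; default 500, the dSTORM
#'   convention).
#' @param radius_nm Tracking radius (default 200 nm).
#' @param min_track_locs Discard tracks with fewer localizations than this
#'   (default 1 = keep all).
#' @return List with \code{tracks}, \code{summaries}, \code{aggregate}.
#' @export
fingerprint_table <- function(table, frame_time, min_photons = 500,
                              radius_nm = 200, min_track_locs = 1L) {
  tb <- filter_localizations(table, min_photons)
  tracks <- link_tracks(tb, radius_nm)
  tracks <- Filter(function(tr) length(tr$frames) >= min_track_locs, tracks)
  summaries <- lapply(tracks, fingerprint_stats, frame_time = frame_time)
  list(tracks = tracks, summaries = summaries,
       aggregate = if (length(summaries)) aggregate_fingerprints(summaries)
       else NULL)
}

#' @export
print.fingerprint_summary <- function(x, ...) {
  cat("Photoswitching fingerprint (track", x$track_id, ")\n")
  cat("  on-events:", x$n_on_events,
      "| median on-time:", stats::median(x$on_times), "frames",
      "| median off-time:",
      if (length(x$off_times)) stats::median(x$off_times) else NA, "frames\n")
  cat("  intensity:", signif(x$mean_photons_per_ms, 4), "photons/ms",
      "| T80:", signif(x$t80, 4), "s",
      "| localizations:", x$total_localizations, "\n")
  invisible(x)
}
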