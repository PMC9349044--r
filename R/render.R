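# Camera-frame rendering of simulated photon streams and composition of
# multi-structure synthetic datasets (dSTORM and DNA-PAINT imaging modes).

#' Geometry templates for synthetic structures
#'
#' Named templates emulating the experimental systems: DNA origami carrying
#' a single Cy5 ("origami_ref") or four Cy5 at the corners of a square with
#' 18/9/6/3 nm nearest-neighbour spacing, and membrane-receptor mimics
#' carrying 1 fluorophore ("receptor_monomer"), 2 at about 5 nm
#' ("receptor_dimer_5nm") or 4 at the corners of a square of side about
#' 7 nm ("receptor_tetramer_7nm").
#'
#' @param template Template name.
#' @return An [emitter_geometry()].
#' @export
template_geometry <- function(template) {
  sq <- function(d) rbind(c(0, 0), c(d, 0), c(d, d), c(0, d))
  geoms <- list(
    origami_ref = rbind(c(0, 0)),
    origami_18nm = sq(18),
    origami_9nm = sq(9),
    origami_6nm = sq(6),
    origami_3nm = sq(3),
    receptor_monomer = rbind(c(0, 0)),
    receptor_dimer_5nm = rbind(c(0, 0), c(5, 0)),
    receptor_tetramer_7nm = sq(7)
  )
  if (!template %in% names(geoms))
    stop("unknown template '", template, "'; valid templates: ",
         paste(names(geoms), collapse = ", "))
  emitter_geometry(geoms[[template]])
}

# Internal: single-linkage clustering of emitter positions at merge_radius.
.emitter_clusters <- function(positions, merge_radius) {
  n <- nrow(positions)
  if (n == 1L) return(1L)
  hc <- stats::hclust(stats::dist(positions), method = "single")
  stats::cutree(hc, h = merge_radius)
}

#' Render a simulated photon stream into a camera-frame localization table
#'
#' Photons are integrated into frames of \code{frame_time} seconds (a photon
#' at time t belongs to frame \code{floor(t / frame_time)}).  All photons
#' from emitters within \code{merge_radius} of each other form one candidate
#' spot per frame — a diffraction-limited camera cannot resolve sub-10-nm
#' separations, so closely spaced fluorophores always merge.  The spot
#' position is the photon-weighted true centroid plus Gaussian localization
#' jitter with sigma = \code{psf_sigma / sqrt(photons)} (simple model) or
#' the Mortensen formula (\code{precision_model = "mortensen"}).  Every spot
#' with at least one photon is emitted; photon thresholds belong to the
#' analysis stage ([filter_localizations()]).
#'
#' Background photons (emitter 0) are assigned to the nearest emitter
#' cluster within \code{merge_radius} of their uniform random position, and
#' discarded otherwise.
#'
#' @param result A \code{simulation_result} from [simulate_trajectory()], or
#'   a list with elements \code{photons} and \code{geometry}.
#' @param frame_time Frame exposure time in seconds.
#' @param psf_sigma PSF standard deviation in nm (default 160).
#' @param merge_radius Emitter merge radius in nm (default 200).
#' @param precision_model "simple" or "mortensen".
#' @param pixel_nm Camera pixel size in nm (Mortensen model; default 128).
#' @param bg_per_pixel Expected background photons per pixel per frame
#'   (Mortensen model; default 1).
#' @return data.frame with columns \code{frame} (0-based), \code{x_nm},
#'   \code{y_nm}, \code{photons}, \code{structure_id}; zero rows for an
#'   empty photon stream.
#' @export
render_frames <- function(result, frame_time, psf_sigma = 160,
                          merge_radius = 200, precision_model = c("simple",
                                                                  "mortensen"),
                          pixel_nm = 128, bg_per_pixel = 1) {
  precision_model <- match.arg(precision_model)
  if (frame_time <= 0) stop("render_frames: frame_time must be > 0")
  ph <- result$photons
  pos <- result$geometry$positions
  empty <- data.frame(frame = integer(0), x_nm = numeric(0),
                      y_nm = numeric(0), photons = integer(0),
                      structure_id = integer(0))
  if (is.null(ph) || nrow(ph) == 0L) return(empty)
  cl <- .emitter_clusters(pos, merge_radius)
  centroids <- cbind(tapply(pos[, 1], cl, mean), tapply(pos[, 2], cl, mean))

  emitter <- ph$emitter
  pcl <- integer(nrow(ph))
  sig <- emitter > 0L
  pcl[sig] <- cl[emitter[sig]]
  if (any(!sig)) {
    # background photons: uniform positions; keep those near a cluster
    box <- result$sim$background_box_nm %||% 500
    ctr <- colMeans(pos)
    nbg <- sum(!sig)
    bx <- stats::runif(nbg, ctr[1] - box, ctr[1] + box)
    by <- stats::runif(nbg, ctr[2] - box, ctr[2] + box)
    d2 <- outer(bx, centroids[, 1], "-")^2 + outer(by, centroids[, 2], "-")^2
    nearest <- max.col(-d2)
    ok <- d2[cbind(seq_len(nbg), nearest)] <= merge_radius^2
    pcl[!sig] <- ifelse(ok, nearest, NA_integer_)
  }
  keep <- !is.na(pcl)
  frame <- as.integer(floor(ph$macrotime_ns[keep] / (frame_time * 1e9)))
  dt <- data.table::data.table(frame = frame, clus = pcl[keep],
                               emitter = emitter[keep])
  px <- c(NA_real_, pos[, 1])[dt$emitter + 1L]   # NA for background
  py <- c(NA_real_, pos[, 2])[dt$emitter + 1L]
  data.table::set(dt, j = "ex", value = px)
  data.table::set(dt, j = "ey", value = py)
  agg <- dt[, list(photons = .N,
                   x0 = mean(ex, na.rm = TRUE),
                   y0 = mean(ey, na.rm = TRUE)),
            by = c("frame", "clus")]
  # pure-background spots: place at the cluster centroid
  nab <- is.nan(agg$x0)
  if (any(nab)) {
    agg$x0[nab] <- centroids[agg$clus[nab], 1]
    agg$y0[nab] <- centroids[agg$clus[nab], 2]
  }
  np <- agg$photons
  sigma_loc <- switch(precision_model,
    simple = psf_sigma / sqrt(np),
    mortensen = {
      sa2 <- psf_sigma^2 + pixel_nm^2 / 12
      sqrt(sa2 / np * (16 / 9 + 8 * pi * sa2 * bg_per_pixel /
                         (np * pixel_nm^2)))
    })
  data.frame(
    frame = agg$frame,
    x_nm = agg$x0 + stats::rnorm(nrow(agg), 0, sigma_loc),
    y_nm = agg$y0 + stats::rnorm(nrow(agg), 0, sigma_loc),
    photons = np,
    structure_id = agg$clus
  )[order(agg$frame), , drop = FALSE]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Imaging-mode defaults
#'
#' dSTORM mode: 5 ms exposure, 120,000 frames (600 s).  DNA-PAINT mode:
#' 100 ms exposure, 18,000 frames (1,800 s).
#'
#' @param mode "dstorm" or "paint".
#' @return List with \code{frame_time} (s), \code{n_frames},
#'   \code{min_photons} (the analysis photon threshold conventionally used
#'   with this mode: 500 for dSTORM, 6000 for DNA-PAINT).
#' @export
imaging_mode <- function(mode = c("dstorm", "paint")) {
  mode <- match.arg(mode)
  switch(mode,
         dstorm = list(mode = "dstorm", frame_time = 0.005,
                       n_frames = 120000L, min_photons = 500),
         paint = list(mode = "paint", frame_time = 0.1,
                      n_frames = 18000L, min_photons = 6000))
}

#' Generate a synthetic multi-structure SMLM dataset
#'
#' Places \code{n_structures} copies of a geometry template on a grid with
#' at least 1 micrometre spacing (no optical cross-talk), simulates each
#' structure's photoswitching independently, and renders camera frames.  In
#' dSTORM mode each structure is a coupled photoswitching system
#' ([simulate_trajectory()]); in DNA-PAINT mode each labelling site binds
#' imager strands as an independent telegraph process (Poisson arrivals,
#' exponential bright times, no energy transfer and no bleaching).
#'
#' @param template Geometry template name (see [template_geometry()]).
#' @param mode "dstorm" or "paint".
#' @param n_structures Number of structures (0 gives empty outputs and a
#'   valid manifest).
#' @param seed Integer seed; the run is deterministic given it.
#' @param rates A [rate_constants()] (dSTORM mode).
#' @param et_config An [energy_transfer_config()] (dSTORM mode).
#' @param sim A [sim_settings()].
#' @param n_frames Override the mode's number of frames (shorter runs for
#'   testing).
#' @param keep_photons Keep per-structure photon streams (memory-heavy for
#'   long acquisitions; default FALSE).
#' @param paint_binding_rate Imager binding rate per docking site (1/s;
#'   paint mode, default 0.005).
#' @param paint_bright_time Mean bound (bright) time in s (default 0.5).
#' @param paint_photon_rate Detected photon rate while bound (counts/s;
#'   default 8e4).
#' @param grid_spacing_nm Structure grid spacing (default 2000).
#' @return List of class \code{switchprint_dataset}: \code{localizations}
#'   (data.frame frame, x_nm, y_nm, photons, structure_id),
#'   \code{photon_streams} (list or NULL), \code{manifest} (ground truth:
#'   template, mode, geometry, rates, seed, per-structure offsets).
#' @export
generate_dataset <- function(template, mode = c("dstorm", "paint"),
                             n_structures, seed,
                             rates = rate_constants(),
                             et_config = energy_transfer_config(),
                             sim = sim_settings(),
                             n_frames = NULL, keep_photons = FALSE,
                             paint_binding_rate = 0.005,
                             paint_bright_time = 0.5,
                             paint_photon_rate = 8e4,
                             grid_spacing_nm = 2000) {
  mode <- match.arg(mode)
  if (n_structures < 0) stop("generate_dataset: n_structures must be >= 0")
  geom <- template_geometry(template)
  md <- imaging_mode(mode)
  if (!is.null(n_frames)) md$n_frames <- as.integer(n_frames)
  duration <- md$n_frames * md$frame_time
  ncol_grid <- max(1L, ceiling(sqrt(n_structures)))
  offsets <- cbind((seq_len(max(n_structures, 1L)) - 1L) %% ncol_grid,
                   (seq_len(max(n_structures, 1L)) - 1L) %/% ncol_grid) *
    grid_spacing_nm
  locs <- vector("list", n_structures)
  streams <- if (keep_photons) vector("list", n_structures) else NULL
  set.seed(seed)
  struct_seeds <- sample.int(.Machine$integer.max, max(n_structures, 1L))
  for (s in seq_len(n_structures)) {
    if (mode == "dstorm") {
      res <- simulate_trajectory(rates, geom, et_config, duration,
                                 seed = struct_seeds[s], sim = sim)
    } else {
      res <- .simulate_paint_structure(geom, duration, paint_binding_rate,
                                       paint_bright_time, paint_photon_rate,
                                       seed = struct_seeds[s], sim = sim)
    }
    lt <- render_frames(res, md$frame_time)
    if (nrow(lt)) {
      lt$x_nm <- lt$x_nm + offsets[s, 1]
      lt$y_nm <- lt$y_nm + offsets[s, 2]
      lt$structure_id <- s
    }
    locs[[s]] <- lt
    if (keep_photons) streams[[s]] <- res$photons
  }
  localizations <- if (n_structures > 0)
    do.call(rbind, locs) else render_frames(list(photons = NULL,
                                                 geometry = geom),
                                            md$frame_time)
  localizations <- localizations[order(localizations$frame), , drop = FALSE]
  rownames(localizations) <- NULL
  manifest <- list(template = template, mode = md$mode,
                   frame_time = md$frame_time, n_frames = md$n_frames,
                   n_structures = n_structures, seed = seed,
                   geometry_nm = geom$positions,
                   grid_offsets_nm = if (n_structures > 0)
                     offsets[seq_len(n_structures), , drop = FALSE]
                   else offsets[0, , drop = FALSE],
                   rates = unclass(rates),
                   energy_transfer = list(
                     r0_nm = as.list(et_config$r0),
                     enabled_pairs = et_config$enabled_pairs),
                   sim = unclass(sim))
  structure(list(localizations = localizations, photon_streams = streams,
                 manifest = manifest),
            class = "switchprint_dataset")
}

# Internal: DNA-PAINT structure — independent telegraph binding per site.
.simulate_paint_structure <- function(geom, duration, binding_rate,
                                      bright_time, photon_rate, seed, sim) {
  set.seed(seed)
  phs <- vector("list", geom$n)
  for (i in seq_len(geom$n)) {
    tg <- simulate_telegraph(duration, k_on = binding_rate,
                             k_off = 1 / bright_time,
                             photon_rate = photon_rate,
                             lifetime_ns = 2.8, sim = sim)
    p <- tg$photons
    p$emitter <- rep.int(i, nrow(p))
    phs[[i]] <- p
  }
  ph <- do.call(rbind, phs)
  nbg <- stats::rpois(1L, 2 * sim$background_rate * duration)
  if (nbg > 0L) {
    ph <- rbind(ph, data.frame(
      channel = stats::rbinom(nbg, 1L, 0.5),
      macrotime_ns = stats::runif(nbg, 0, duration * 1e9),
      microtime_ps = floor(stats::runif(nbg, 0, sim$pulse_period_ns) * 1000 /
                             sim$microtime_resolution_ps) *
        sim$microtime_resolution_ps,
      emitter = 0L))
  }
  ph <- ph[order(ph$macrotime_ns), , drop = FALSE]
  rownames(ph) <- NULL
  list(photons = ph, geometry = geom, sim = sim, duration = duration)
}
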