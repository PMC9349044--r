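# File formats: localization tables (CSV, with ThunderSTORM-style header
# aliases), columnar photon streams, dataset export and JSON run manifests.
# Conventions: coordinates in nm, frames 0-based, comma-separated UTF-8
# CSV with '.' decimal and a required header.

.loc_aliases <- c(
  "frame" = "frame",
  "x_nm" = "x_nm", "x [nm]" = "x_nm", "x" = "x_nm",
  "y_nm" = "y_nm", "y [nm]" = "y_nm", "y" = "y_nm",
  "photons" = "photons", "intensity [photon]" = "photons",
  "structure_id" = "structure_id"
)

#' Read a localization table
#'
#' Reads a CSV with columns \code{frame, x_nm, y_nm, photons} (optional
#' \code{structure_id}).  ThunderSTORM-style header aliases (\code{x [nm]},
#' \code{y [nm]}, \code{intensity [photon]}) are accepted.  Rows with
#' non-numeric or non-finite entries are reported with their line numbers.
#'
#' @param path CSV file path.
#' @return A validated data.frame (frame, x_nm, y_nm, photons, and
#'   structure_id if present).
#' @export
read_localizations <- function(path) {
  raw <- utils::read.csv(path, check.names = FALSE,
                         stringsAsFactors = FALSE)
  nm <- .loc_aliases[names(raw)]
  keep <- !is.na(nm)
  raw <- raw[keep]
  names(raw) <- nm[keep]
  for (col in c("frame", "x_nm", "y_nm", "photons"))
    if (!col %in% names(raw))
      stop("read_localizations: ", col, " column not found in '", path, "'")
  for (col in names(raw)) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(!is.finite(v))
    if (length(bad))
      stop("read_localizations: non-numeric or non-finite '", col,
           "' at data line(s) ", paste(utils::head(bad, 5), collapse = ", "),
           " of '", path, "'")
    raw[[col]] <- v
  }
  raw$frame <- as.integer(raw$frame)
  if (any(raw$frame < 0)) stop("read_localizations: negative frame index")
  if (any(raw$photons < 1)) stop("read_localizations: photons must be >= 1")
  raw
}

#' Write a localization table
#'
#' @param table Localization data.frame.
#' @param path Output CSV path (header
#'   \code{frame,x_nm,y_nm,photons,structure_id}).
#' @return \code{path}, invisibly.
#' @export
write_localizations <- function(table, path) {
  cols <- intersect(c("frame", "x_nm", "y_nm", "photons", "structure_id"),
                    names(table))
  utils::write.csv(table[cols], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a photon stream
#'
#' Columnar CSV with header \code{channel,macrotime_ns,microtime_ps}.
#' Macrotime monotonicity is validated; unsorted input is stably sorted
#' with a warning.
#'
#' @param path CSV file path.
#' @return Photon stream data.frame (possibly zero rows).
#' @export
read_photons <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("channel", "macrotime_ns", "microtime_ps")
  for (col in need)
    if (!col %in% names(df))
      stop("read_photons: ", col, " column not found in '", path, "'")
  if (nrow(df) == 0L) return(df[need])
  if (is.unsorted(df$macrotime_ns)) {
    warning("read_photons: macrotimes not monotone; sorting stably")
    df <- df[order(df$macrotime_ns), , drop = FALSE]
    rownames(df) <- NULL
  }
  if (!all(df$channel %in% c(0L, 1L)))
    stop("read_photons: channel must be 0 or 1")
  df
}

#' Write a photon stream
#'
#' @param stream Photon stream data.frame.
#' @param path Output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_photons <- function(stream, path) {
  utils::write.csv(stream[c("channel", "macrotime_ns", "microtime_ps")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a run manifest
#'
#' JSON manifest embedding the configuration snapshot, the seed and md5
#' checksums of the listed files, so every numeric output of a run is
#' reproducible from the manifest alone.
#'
#' @param config List of configuration values (must include the seed used).
#' @param files Character vector of output files to checksum.
#' @param path Output JSON path.
#' @return \code{path}, invisibly.
#' @export
write_manifest <- function(config, files = character(0), path) {
  checksums <- if (length(files))
    as.list(tools::md5sum(files)) else list()
  jsonlite::write_json(list(config = config, checksums = checksums,
                            written = format(Sys.time(), tz = "UTC")),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Export a synthetic dataset to disk
#'
#' Writes the localization table, any photon streams and a ground-truth
#' manifest of a [generate_dataset()] result into a directory.
#'
#' @param dataset A \code{switchprint_dataset}.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  loc_path <- file.path(dir, "localizations.csv")
  write_localizations(dataset$localizations, loc_path)
  files <- loc_path
  if (!is.null(dataset$photon_streams)) {
    for (s in seq_along(dataset$photon_streams)) {
      p <- file.path(dir, sprintf("photons_structure%03d.csv", s))
      write_photons(dataset$photon_streams[[s]], p)
      files <- c(files, p)
    }
  }
  man <- dataset$manifest
  man$geometry_nm <- unname(apply(man$geometry_nm, 1, as.list))
  man$grid_offsets_nm <- unname(apply(man$grid_offsets_nm, 1, as.list))
  write_manifest(man, files, file.path(dir, "manifest.json"))
  invisible(dir)
}
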