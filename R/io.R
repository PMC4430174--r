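#' Write / read a Stokes volume as multi-page TIFF plus JSON sidecar
#'
#' One 32-bit float TIFF file per Stokes channel (suffixes \code{_I.tif},
#' \code{_Q.tif}, \code{_U.tif}, \code{_V.tif}), one page per B-scan (page =
#' depth x A-scan image). TIFF storage here is constrained to [0,1], so each
#' channel is affinely mapped to [0,1] and the offset/scale pair is recorded
#' in the sidecar \code{<prefix>_geometry.json} together with the scan
#' geometry; the round trip is exact to float32 precision.
#'
#' @param volume A \code{stokes_volume}.
#' @param prefix Path prefix for the five files.
#' @return \code{prefix}, invisibly.
#' @export
write_stokes_volume <- function(volume, prefix) {
  if (!inherits(volume, "stokes_volume")) stop("volume must be a stokes_volume")
  chans <- c("I", "Q", "U", "V")
  scales <- list()
  for (ch in chans) {
    arr <- volume[[ch]]
    lo <- min(arr); hi <- max(arr)
    sc <- if (hi > lo) hi - lo else 1
    pages <- lapply(seq_len(dim(arr)[3]), function(b) (arr[, , b] - lo) / sc)
    tiff::writeTIFF(pages, paste0(prefix, "_", ch, ".tif"),
                    bits.per.sample = 32L, compression = "none", reduce = FALSE)
    scales[[ch]] <- list(offset = lo, scale = sc)
  }
  g <- volume$geometry
  side <- list(format = "psoct-stokes-v1",
               geometry = unclass(g), channel_scaling = scales)
  jsonlite::write_json(side, paste0(prefix, "_geometry.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(prefix)
}

#' @rdname write_stokes_volume
#' @export
read_stokes_volume <- function(prefix) {
  side_path <- paste0(prefix, "_geometry.json")
  if (!file.exists(side_path)) stop("missing geometry sidecar: ", side_path)
  side <- jsonlite::read_json(side_path, simplifyVector = TRUE)
  if (is.null(side$geometry) || is.null(side$channel_scaling))
    stop("geometry sidecar is malformed: ", side_path)
  g <- do.call(scan_geometry, as.list(side$geometry))
  chans <- c("I", "Q", "U", "V")
  out <- list()
  for (ch in chans) {
    f <- paste0(prefix, "_", ch, ".tif")
    if (!file.exists(f)) stop("missing Stokes channel file: ", f)
    pages <- tiff::readTIFF(f, all = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    if (length(pages) != g$n_bscans ||
        !identical(dim(pages[[1]]), c(g$n_depth, g$n_ascans)))
      stop(sprintf("geometry sidecar mismatch for channel %s: file is %d pages of %s, sidecar says %d x %d x %d",
                   ch, length(pages), paste(dim(pages[[1]]), collapse = "x"),
                   g$n_depth, g$n_ascans, g$n_bscans))
    sc <- side$channel_scaling[[ch]]
    arr <- array(0, dim = c(g$n_depth, g$n_ascans, g$n_bscans))
    for (b in seq_along(pages))
      arr[, , b] <- pages[[b]] * sc$scale + sc$offset
    out[[ch]] <- arr
  }
  stokes_volume(out$I, out$Q, out$U, out$V, g, check = FALSE)
}

#' Write / read a label or mask volume as single-channel multi-page TIFF
#'
#' Integer labels (e.g. the ground-truth label map, or a logical RPE mask)
#' are stored as 8-bit pages scaled by 1/255; the round trip is lossless for
#' labels up to 255.
#'
#' @param labels 3-D integer or logical array \code{[depth, ascan, bscan]}.
#' @param path Output TIFF path.
#' @export
write_label_volume <- function(labels, path) {
  arr <- labels * 1L
  if (max(arr) > 255L || min(arr) < 0L) stop("labels must lie in 0..255")
  pages <- lapply(seq_len(dim(arr)[3]), function(b) arr[, , b] / 255)
  tiff::writeTIFF(pages, path, bits.per.sample = 8L, compression = "none",
                  reduce = FALSE)
  invisible(path)
}

#' @rdname write_label_volume
#' @export
read_label_volume <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  arr <- array(0L, dim = c(dim(pages[[1]]), length(pages)))
  for (b in seq_along(pages)) arr[, , b] <- as.integer(round(pages[[b]] * 255))
  arr
}

#' Write / read an en-face map as CSV
#'
#' Plain rectangular CSV, rows = A-scans, columns = B-scans; used for
#' thickness and atrophy maps.
#'
#' @param m Matrix.
#' @param path CSV path.
#' @export
write_enface_csv <- function(m, path) {
  utils::write.table(m * 1, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname write_enface_csv
#' @export
read_enface_csv <- function(path) {
  as.matrix(utils::read.table(path, sep = ","))
}

#' Read manual evaluation-band overrides from YAML
#'
#' The file maps B-scan indices to \code{[upper, lower)} 0-based depth
#' bounds, e.g. \code{"5": [60, 100]}; the result feeds the \code{manual}
#' argument of [fit_evaluation_band()], making the semi-automated band
#' adjustment reproducible.
#'
#' @param path YAML path.
#' @return Named list of two-element numeric vectors.
#' @export
read_band_overrides <- function(path) {
  y <- yaml::read_yaml(path)
  lapply(y, function(v) as.numeric(unlist(v)))
}
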