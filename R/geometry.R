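#' Scan geometry of a raster OCT volume
#'
#' Describes the physical extent and sampling of a raster-scanned OCT volume:
#' the fast (A-scan) axis, the slow (B-scan) axis and the axial (depth)
#' direction. The default mirrors the acquisition protocol of the
#' polarization-sensitive prototype this package models: a 6.2 x 6.7 mm^2
#' scanning area sampled with 512 A-scans x 128 B-scans.
#'
#' Coordinate conventions used throughout the package: volumes are arrays of
#' dimension \code{c(n_depth, n_ascans, n_bscans)}; en-face maps are matrices
#' of dimension \code{c(n_ascans, n_bscans)}. The millimetre origin is the
#' scan corner, x runs along the fast axis, y along the slow axis, and depth
#' increases away from the vitreous.
#'
#' @param width_mm Fast-axis (A-scan direction) extent in mm.
#' @param height_mm Slow-axis (B-scan direction) extent in mm.
#' @param n_ascans A-scans per B-scan.
#' @param n_bscans B-scans per volume.
#' @param n_depth Axial samples per A-scan.
#' @param axial_step_um Axial sampling step in micrometres.
#' @return An object of class \code{scan_geometry}.
#' @examples
#' g <- scan_geometry()
#' pixel_area_mm2(g)
#' @export
scan_geometry <- function(width_mm = 6.2, height_mm = 6.7,
                          n_ascans = 512L, n_bscans = 128L,
                          n_depth = 256L, axial_step_um = 4.5) {
  g <- list(width_mm = as.numeric(width_mm), height_mm = as.numeric(height_mm),
            n_ascans = as.integer(n_ascans), n_bscans = as.integer(n_bscans),
            n_depth = as.integer(n_depth), axial_step_um = as.numeric(axial_step_um))
  vals <- unlist(g)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all scan_geometry fields must be finite and strictly positive")
  class(g) <- "scan_geometry"
  g
}

#' Downscaled test-profile geometry
#'
#' A coarser sampling of the same 6.2 x 6.7 mm^2 field (128 A-scans x
#' 64 B-scans x 128 depth samples) used for fast simulation studies. The
#' axial step is scaled so the physical depth range matches the full profile.
#'
#' @return A \code{scan_geometry}.
#' @export
scan_geometry_test <- function() {
  scan_geometry(n_ascans = 128L, n_bscans = 64L, n_depth = 128L,
                axial_step_um = 9.0)
}

#' En-face pixel area in mm^2
#'
#' The en-face grid is anisotropic: pixel side lengths are
#' \code{width_mm/n_ascans} along x and \code{height_mm/n_bscans} along y.
#' Areas are obtained by scaling pixel counts with this known pixel area;
#' no resampling to isotropic pixels is performed.
#'
#' @param geometry A \code{scan_geometry}.
#' @return Pixel area in mm^2.
#' @export
pixel_area_mm2 <- function(geometry) {
  ascan_pitch_mm(geometry) * bscan_pitch_mm(geometry)
}

#' @rdname pixel_area_mm2
#' @export
ascan_pitch_mm <- function(geometry) geometry$width_mm / geometry$n_ascans

#' @rdname pixel_area_mm2
#' @export
bscan_pitch_mm <- function(geometry) geometry$height_mm / geometry$n_bscans

#' @export
print.scan_geometry <- function(x, ...) {
  cat(sprintf("scan_geometry: %.2f x %.2f mm^2, %d A-scans x %d B-scans x %d depth (axial %.2f um)\n",
              x$width_mm, x$height_mm, x$n_ascans, x$n_bscans, x$n_depth,
              x$axial_step_um))
  invisible(x)
}

stopifnot_geometry <- function(geometry) {
  if (!inherits(geometry, "scan_geometry")) stop("expected a scan_geometry object")
  invisible(geometry)
}

# A-scan/B-scan pixel centres in mm (used for lesion rasterization)
ascan_centers_mm <- function(geometry) (seq_len(geometry$n_ascans) - 0.5) * ascan_pitch_mm(geometry)
bscan_centers_mm <- function(geometry) (seq_len(geometry$n_bscans) - 0.5) * bscan_pitch_mm(geometry)
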