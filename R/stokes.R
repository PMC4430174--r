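#' Stokes-vector OCT volume
#'
#' Container for a 4-channel polarization-sensitive OCT raster volume: the
#' per-voxel Stokes elements I, Q, U, V in arbitrary linear intensity units,
#' plus the scan geometry. Each channel is an array of dimension
#' \code{c(n_depth, n_ascans, n_bscans)}.
#'
#' Physicality: I must be non-negative everywhere and the polarized magnitude
#' \code{sqrt(Q^2+U^2+V^2)} must not exceed I (within a small numerical
#' tolerance).
#'
#' @param I,Q,U,V Numeric arrays of identical dimension
#'   \code{c(n_depth, n_ascans, n_bscans)}.
#' @param geometry A \code{scan_geometry} consistent with the array dims.
#' @param check Validate invariants (default \code{TRUE}).
#' @return An object of class \code{stokes_volume}.
#' @export
stokes_volume <- function(I, Q, U, V, geometry, check = TRUE) {
  stopifnot_geometry(geometry)
  dims <- dim(I)
  if (is.null(dims) || length(dims) != 3L)
    stop("Stokes channels must be 3-D arrays [depth, ascan, bscan]")
  for (ch in list(Q, U, V))
    if (!identical(dim(ch), dims)) stop("Stokes channel dimensions differ")
  expect <- c(geometry$n_depth, geometry$n_ascans, geometry$n_bscans)
  if (!identical(as.integer(dims), as.integer(expect)))
    stop(sprintf("volume dims [%s] inconsistent with geometry [%s]",
                 paste(dims, collapse = ","), paste(expect, collapse = ",")))
  if (check) {
    if (any(I < 0)) stop("I must be non-negative everywhere")
    pol <- sqrt(Q^2 + U^2 + V^2)
    if (any(pol > I * (1 + 1e-6) + 1e-9))
      stop("physicality violated: sqrt(Q^2+U^2+V^2) > I at some voxels")
  }
  structure(list(I = I, Q = Q, U = U, V = V, geometry = geometry),
            class = "stokes_volume")
}

#' @export
print.stokes_volume <- function(x, ...) {
  d <- dim(x$I)
  cat(sprintf("stokes_volume: %d depth x %d A-scans x %d B-scans\n", d[1], d[2], d[3]))
  print(x$geometry)
  invisible(x)
}

vol_dims <- function(volume) dim(volume$I)
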