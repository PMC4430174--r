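# One B-scan of a 3-D array as a matrix, robust to degenerate dimensions.
slice2d <- function(x, b) {
  m <- x[, , b, drop = FALSE]
  dim(m) <- dim(x)[1:2]
  m
}

# Truncated-window box sums via summed-area tables. Window extends
# half-widths hz/hx around each pixel and is truncated at the image edges
# (no padding with synthetic data).
box_sum <- function(m, hz, hx) {
  nr <- nrow(m); nc <- ncol(m)
  cs <- apply(m, 2L, cumsum)                 # cumulative down rows
  if (is.null(dim(cs))) cs <- matrix(cs, nr, nc)
  cs2 <- t(apply(cs, 1L, cumsum))            # then across columns
  if (is.null(dim(cs2))) cs2 <- matrix(cs2, nr, nc)
  S <- matrix(0, nr + 1L, nc + 1L)
  S[2:(nr + 1L), 2:(nc + 1L)] <- cs2
  r1 <- pmax(seq_len(nr) - hz, 1L); r2 <- pmin(seq_len(nr) + hz, nr)
  c1 <- pmax(seq_len(nc) - hx, 1L); c2 <- pmin(seq_len(nc) + hx, nc)
  S[r2 + 1L, c2 + 1L, drop = FALSE] -
    S[r1, c2 + 1L, drop = FALSE] -
    S[r2 + 1L, c1, drop = FALSE] +
    S[r1, c1, drop = FALSE]
}

#' Degree of polarization uniformity (DOPU) by windowed Stokes averaging
#'
#' At each voxel the Stokes elements Q, U, V are first normalized by the
#' per-pixel intensity I, then each normalized component is averaged over a
#' rectangular evaluation window lying within the B-scan (no averaging across
#' B-scans). DOPU is the Euclidean norm of the averaged vector, clamped to
#' [0,1]. In polarization-preserving or birefringent tissue DOPU is
#' approximately 1; a depolarizing layer scrambles the per-pixel polarization
#' states so their window average shrinks and DOPU drops below 1.
#'
#' Pixels with zero intensity contribute nothing to the window average; a
#' voxel whose entire window has zero intensity is marked invalid (DOPU
#' \code{NA}) and is never classified. Windows are truncated at B-scan edges.
#'
#' @param volume A \code{stokes_volume}.
#' @param window_z_px,window_x_px Odd window sizes (axial, lateral) in
#'   pixels. Defaults 3 x 5: the axial extent is kept below the nominal
#'   band thickness so the segmented band is not axially dilated by the
#'   window, which would distort thickness-ratio lesion rules; see the
#'   methods vignette.
#' @return A \code{dopu_volume}: \code{dopu} array in [0,1] (NA = invalid),
#'   \code{valid} logical array, the window descriptor and geometry.
#' @examples
#' g <- scan_geometry(width_mm = 1, height_mm = 1, n_ascans = 9,
#'                    n_bscans = 1, n_depth = 9, axial_step_um = 4.5)
#' one <- array(1, c(9, 9, 1)); zero <- array(0, c(9, 9, 1))
#' v <- stokes_volume(one, one, zero, zero, g)
#' d <- compute_dopu(v, 9, 9)
#' d$dopu[5, 5, 1]  # exactly 1: uniform fully polarized window
#' @export
compute_dopu <- function(volume, window_z_px = 3L, window_x_px = 5L) {
  if (!inherits(volume, "stokes_volume")) stop("volume must be a stokes_volume")
  wz <- as.integer(window_z_px); wx <- as.integer(window_x_px)
  if (wz < 1L || wx < 1L || wz %% 2L == 0L || wx %% 2L == 0L)
    stop("window sizes must be odd and >= 1")
  d <- vol_dims(volume)
  if (wz > d[1] || wx > d[2])
    stop(sprintf("window %dx%d larger than B-scan extent %dx%d", wz, wx, d[1], d[2]))
  hz <- (wz - 1L) %/% 2L; hx <- (wx - 1L) %/% 2L
  dopu <- array(NA_real_, d)
  valid <- array(FALSE, d)
  for (b in seq_len(d[3])) {
    Ib <- slice2d(volume$I, b)
    ok <- Ib > 0
    inv <- 1 / Ib; inv[!ok] <- 0
    q <- slice2d(volume$Q, b) * inv
    u <- slice2d(volume$U, b) * inv
    v <- slice2d(volume$V, b) * inv
    cnt <- box_sum(ok * 1, hz, hx)
    good <- cnt > 0
    safe <- ifelse(good, cnt, 1)
    mq <- box_sum(q, hz, hx) / safe
    mu <- box_sum(u, hz, hx) / safe
    mv <- box_sum(v, hz, hx) / safe
    dp <- pmin(1, pmax(0, sqrt(mq^2 + mu^2 + mv^2)))
    dp[!good] <- NA_real_
    dopu[, , b] <- dp
    valid[, , b] <- good
  }
  structure(list(dopu = dopu, valid = valid,
                 window = c(z = wz, x = wx), geometry = volume$geometry),
            class = "dopu_volume")
}

#' Intensity floor for RPE classification
#'
#' DOPU is meaningless at noise-level intensity, so classification is gated
#' by an intensity floor: the mean plus two standard deviations of the
#' background signal, estimated from the top (vitreous) 10\% of the depth
#' range of every B-scan.
#'
#' @param volume A \code{stokes_volume}.
#' @return The floor, in the volume's intensity units.
#' @export
estimate_intensity_floor <- function(volume) {
  d <- vol_dims(volume)
  top <- seq_len(max(1L, as.integer(ceiling(0.1 * d[1]))))
  bg <- volume$I[top, , , drop = FALSE]
  mean(bg) + 2 * stats::sd(as.vector(bg))
}

#' Segment the depolarizing RPE by DOPU thresholding
#'
#' A voxel is classified as depolarizing RPE exactly when it is valid, its
#' intensity reaches the floor, and its DOPU is strictly below the threshold
#' (default 0.8, matching the printed inequality DOPU < 0.8). The operation
#' is pointwise and idempotent.
#'
#' @param dopu A \code{dopu_volume}.
#' @param intensity The \code{stokes_volume} providing I.
#' @param dopu_threshold Strict upper DOPU bound, in (0, 1].
#' @param intensity_floor Minimum I; \code{NULL} (default) estimates it with
#'   [estimate_intensity_floor()].
#' @return An \code{rpe_mask}: logical array plus provenance (threshold,
#'   floor, window).
#' @export
segment_rpe <- function(dopu, intensity, dopu_threshold = 0.8,
                        intensity_floor = NULL) {
  if (!inherits(dopu, "dopu_volume")) stop("dopu must be a dopu_volume")
  if (!inherits(intensity, "stokes_volume")) stop("intensity must be a stokes_volume")
  if (!identical(dim(dopu$dopu), dim(intensity$I)))
    stop("dopu and intensity dimensions do not match")
  if (!(dopu_threshold > 0 && dopu_threshold <= 1))
    stop("dopu_threshold must lie in (0, 1]")
  if (is.null(intensity_floor))
    intensity_floor <- estimate_intensity_floor(intensity)
  mask <- dopu$valid & intensity$I >= intensity_floor &
    !is.na(dopu$dopu) & dopu$dopu < dopu_threshold
  mask[is.na(mask)] <- FALSE
  structure(list(mask = mask, dopu_threshold = dopu_threshold,
                 intensity_floor = intensity_floor, window = dopu$window,
                 geometry = dopu$geometry),
            class = "rpe_mask")
}

#' Overlay of the segmented RPE on a grayscale B-scan
#'
#' Pure rendering: the intensity B-scan is mapped to grayscale and mask
#' pixels are painted into a distinct color channel (red by default).
#'
#' @param intensity A \code{stokes_volume}.
#' @param mask An \code{rpe_mask} with matching dimensions.
#' @param bscan B-scan index.
#' @return A numeric array \code{[depth, ascan, 3]} (RGB in [0,1]).
#' @export
make_overlay <- function(intensity, mask, bscan = 1L) {
  if (!identical(dim(intensity$I), dim(mask$mask)))
    stop("intensity and mask dimensions do not match")
  Ib <- intensity$I[, , bscan]
  rng <- range(Ib)
  gray <- if (diff(rng) > 0) (Ib - rng[1]) / diff(rng) else Ib * 0
  m <- mask$mask[, , bscan]
  rgb <- array(gray, dim = c(dim(Ib), 3L))
  r <- rgb[, , 1]; gch <- rgb[, , 2]; bch <- rgb[, , 3]
  r[m] <- 1; gch[m] <- 0; bch[m] <- 0
  rgb[, , 1] <- r; rgb[, , 2] <- gch; rgb[, , 3] <- bch
  rgb
}
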