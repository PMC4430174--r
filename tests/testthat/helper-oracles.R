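# Shared fixtures and independent brute-force oracles.

# Small geometry for fast phantom tests (same pixel pitches as the test
# profile, quarter field).
tiny_geometry <- function() {
  scan_geometry(width_mm = 3.1, height_mm = 3.35, n_ascans = 64L,
                n_bscans = 32L, n_depth = 64L, axial_step_um = 9)
}

# Stokes volume in which every voxel carries the same state.
uniform_volume <- function(i = 1, q = 1, u = 0, v = 0, nd = 9L, na = 9L,
                           nb = 1L) {
  g <- scan_geometry(width_mm = na * 0.05, height_mm = nb * 0.1,
                     n_ascans = na, n_bscans = nb, n_depth = nd,
                     axial_step_um = 4.5)
  mk <- function(x) array(x, dim = c(nd, na, nb))
  stokes_volume(mk(i), mk(q), mk(u), mk(v), g)
}

# Build a stokes_volume from explicit per-channel arrays with a matching
# geometry (dims [depth, ascan, bscan]).
volume_from_arrays <- function(I, Q, U, V) {
  d <- dim(I)
  g <- scan_geometry(width_mm = d[2] * 0.05, height_mm = d[3] * 0.1,
                     n_ascans = d[2], n_bscans = d[3], n_depth = d[1],
                     axial_step_um = 4.5)
  stokes_volume(I, Q, U, V, g, check = FALSE)
}

# Wrap a logical 3-D array as an rpe_mask (bypassing DOPU) for unit tests of
# downstream stages.
mask_from_array <- function(m, geometry = NULL) {
  d <- dim(m)
  if (is.null(geometry))
    geometry <- scan_geometry(width_mm = d[2] * 0.05, height_mm = d[3] * 0.1,
                              n_ascans = d[2], n_bscans = d[3], n_depth = d[1],
                              axial_step_um = 4.5)
  structure(list(mask = m, dopu_threshold = 0.8, intensity_floor = 0,
                 window = c(z = 1L, x = 1L), geometry = geometry),
            class = "rpe_mask")
}

# Wrap an en-face count matrix as a thickness_map.
tmap_from_matrix <- function(counts, geometry = NULL) {
  d <- dim(counts)
  if (is.null(geometry))
    geometry <- scan_geometry(width_mm = d[1] * 0.05, height_mm = d[2] * 0.1,
                              n_ascans = d[1], n_bscans = d[2], n_depth = 64L,
                              axial_step_um = 9)
  structure(list(counts = counts, band = NULL, geometry = geometry),
            class = "thickness_map")
}

amap_from_matrix <- function(atrophic, geometry = NULL) {
  tm <- tmap_from_matrix((!atrophic) * 5L, geometry)
  structure(list(atrophic = atrophic,
                 params = list(atrophy_count_max = 0L, smooth_radius_px = 0L),
                 geometry = tm$geometry),
            class = "atrophy_map")
}

# Uniform flat depolarizing band wrapped as an rpe_mask.
flat_band_mask <- function(nd = 64L, na = 40L, nb = 8L, depth0 = 30L,
                           thick = 5L) {
  m <- array(FALSE, c(nd, na, nb))
  m[(depth0 + 1L):(depth0 + thick), , ] <- TRUE
  mask_from_array(m)
}

# Thickness row with gaps of given widths separated by residual runs.
row_with_gaps <- function(n, gap_widths, residual_width = 20L, nominal = 5L,
                          lead = 30L) {
  row <- rep(nominal, n)
  pos <- lead
  for (w in gap_widths) {
    row[pos:(pos + w - 1L)] <- 0L
    pos <- pos + w + residual_width
  }
  row
}

# --- independent oracles -----------------------------------------------------

# Explicit-loop DOPU on one B-scan (matrices [depth, ascan]); truncated
# windows, per-pixel normalization, exclusion of zero-intensity pixels.
loop_dopu <- function(I, Q, U, V, wz, wx) {
  nd <- nrow(I); na <- ncol(I)
  hz <- (wz - 1) %/% 2; hx <- (wx - 1) %/% 2
  out <- matrix(NA_real_, nd, na)
  for (z in seq_len(nd)) for (x in seq_len(na)) {
    zz <- max(1, z - hz):min(nd, z + hz)
    xx <- max(1, x - hx):min(na, x + hx)
    qs <- us <- vs <- c()
    for (z2 in zz) for (x2 in xx) {
      if (I[z2, x2] > 0) {
        qs <- c(qs, Q[z2, x2] / I[z2, x2])
        us <- c(us, U[z2, x2] / I[z2, x2])
        vs <- c(vs, V[z2, x2] / I[z2, x2])
      }
    }
    if (length(qs))
      out[z, x] <- min(1, max(0, sqrt(mean(qs)^2 + mean(us)^2 + mean(vs)^2)))
  }
  out
}

# Queue-based flood fill labelling (8- or 4-connectivity), independent of the
# union-find implementation in the package.
flood_fill_label <- function(mask, connectivity = 8L) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  nxt <- 0L
  offs <- if (connectivity == 8L)
    cbind(c(-1, -1, -1, 0, 0, 1, 1, 1), c(-1, 0, 1, -1, 1, -1, 0, 1))
  else cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
  for (r in seq_len(nr)) for (cc in seq_len(nc)) {
    if (mask[r, cc] && lab[r, cc] == 0L) {
      nxt <- nxt + 1L
      queue <- list(c(r, cc))
      lab[r, cc] <- nxt
      while (length(queue)) {
        p <- queue[[1]]; queue <- queue[-1]
        for (k in seq_len(nrow(offs))) {
          r2 <- p[1] + offs[k, 1]; c2 <- p[2] + offs[k, 2]
          if (r2 >= 1 && r2 <= nr && c2 >= 1 && c2 <= nc &&
              mask[r2, c2] && lab[r2, c2] == 0L) {
            lab[r2, c2] <- nxt
            queue[[length(queue) + 1]] <- c(r2, c2)
          }
        }
      }
    }
  }
  lab
}

# Two labelings describe the same partition?
same_partition <- function(a, b) {
  if (!identical(a > 0, b > 0)) return(FALSE)
  idx <- which(a > 0)
  if (!length(idx)) return(TRUE)
  length(unique(paste(a[idx], b[idx]))) == length(unique(a[idx])) &&
    length(unique(a[idx])) == length(unique(b[idx]))
}

# Monte-Carlo mean of || mean of n uniformly random unit vectors ||.
mc_mean_resultant <- function(n, reps = 10000L, seed = 99L) {
  set.seed(seed)
  vals <- replicate(reps, {
    z <- runif(n, -1, 1); phi <- runif(n, 0, 2 * pi)
    rxy <- sqrt(pmax(0, 1 - z^2))
    sqrt(mean(z)^2 + mean(rxy * cos(phi))^2 + mean(rxy * sin(phi))^2)
  })
  c(mean = mean(vals), sd = sd(vals))
}

month24_cohort_path <- function() {
  system.file("extdata", "cohort_month24.yaml", package = "psoct")
}
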