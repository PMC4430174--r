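#' Lesion specifications for the synthetic phantom
#'
#' Constructors for the lesion taxonomy the phantom can plant into the
#' depolarizing RPE band. All positions are in millimetres from the scan
#' corner (x along the fast/A-scan axis, y along the slow/B-scan axis);
#' axial quantities are in pixels.
#'
#' \describe{
#'   \item{ga_patch}{circular region of complete RPE loss intended to be
#'     quantifiable as geographic atrophy; its analytic area is
#'     \code{pi * radius_mm^2}.}
#'   \item{focal_atrophy}{small circular RPE defect, intended to stay below
#'     the GA area floor of the quantification algorithm.}
#'   \item{gap_series}{a row of \code{n_gaps} rectangular RPE gaps with
#'     intact depolarizing residuals between them, spanning a few adjacent
#'     B-scans; the footprint of RPE porosity.}
#'   \item{thinning}{rectangular region where the band thickness is scaled by
#'     \code{thickness_multiplier < 1}.}
#'   \item{thickening}{rectangular region scaled by
#'     \code{thickness_multiplier > 1}; the footprint of accumulation of
#'     depolarizing material at the RPE level.}
#'   \item{ectopic_focus}{a small cube of depolarizing voxels offset axially
#'     from the band; negative \code{depth_offset_px} places it in the outer
#'     retina (vitread of the band, i.e. an ectopic depolarizing focus),
#'     positive offsets place it in the choroid (used to exercise the
#'     evaluation-band exclusion).}
#' }
#'
#' @param center_x_mm,center_y_mm En-face centre.
#' @param radius_mm Disc radius (mm).
#' @param area_mm2 Alternative to \code{radius_mm}: analytic disc area.
#' @param start_x_mm Left edge of the first gap of a series.
#' @param n_gaps Number of gaps in a series.
#' @param gap_width_mm,spacing_mm Width of each gap and of the intact
#'   residual between consecutive gaps.
#' @param n_bscans_extent Number of adjacent B-scans covered by the lesion.
#' @param width_mm,height_mm Rectangle extents for thinning/thickening.
#' @param thickness_multiplier Band thickness scale factor.
#' @param depth_offset_px Axial offset of the focus centre from the nominal
#'   RPE depth (negative = towards the vitreous).
#' @param size_px Edge length of the cubic focus, in pixels.
#' @return A list of class \code{lesion_spec}.
#' @name lesion_specs
NULL

new_lesion <- function(kind, ...) {
  structure(c(list(kind = kind), list(...)), class = "lesion_spec")
}

#' @rdname lesion_specs
#' @export
lesion_ga_patch <- function(center_x_mm, center_y_mm, radius_mm = NULL,
                            area_mm2 = NULL) {
  if (is.null(radius_mm)) {
    if (is.null(area_mm2)) stop("give radius_mm or area_mm2")
    radius_mm <- sqrt(area_mm2 / pi)
  }
  new_lesion("ga_patch", center_x_mm = center_x_mm, center_y_mm = center_y_mm,
             radius_mm = radius_mm)
}

#' @rdname lesion_specs
#' @export
lesion_focal_atrophy <- function(center_x_mm, center_y_mm, radius_mm) {
  new_lesion("focal_atrophy", center_x_mm = center_x_mm,
             center_y_mm = center_y_mm, radius_mm = radius_mm)
}

#' @rdname lesion_specs
#' @export
lesion_gap_series <- function(start_x_mm, center_y_mm, n_gaps = 4L,
                              gap_width_mm = 0.53, spacing_mm = 0.39,
                              n_bscans_extent = 2L) {
  new_lesion("gap_series", start_x_mm = start_x_mm, center_y_mm = center_y_mm,
             n_gaps = as.integer(n_gaps), gap_width_mm = gap_width_mm,
             spacing_mm = spacing_mm, n_bscans_extent = as.integer(n_bscans_extent))
}

#' @rdname lesion_specs
#' @export
lesion_thinning <- function(center_x_mm, center_y_mm, width_mm, height_mm,
                            thickness_multiplier = 0.2) {
  new_lesion("thinning", center_x_mm = center_x_mm, center_y_mm = center_y_mm,
             width_mm = width_mm, height_mm = height_mm,
             thickness_multiplier = thickness_multiplier)
}

#' @rdname lesion_specs
#' @export
lesion_thickening <- function(center_x_mm, center_y_mm, width_mm, height_mm,
                              thickness_multiplier = 3) {
  new_lesion("thickening", center_x_mm = center_x_mm, center_y_mm = center_y_mm,
             width_mm = width_mm, height_mm = height_mm,
             thickness_multiplier = thickness_multiplier)
}

#' @rdname lesion_specs
#' @export
lesion_ectopic_focus <- function(center_x_mm, center_y_mm,
                                 depth_offset_px = -30L, size_px = 3L) {
  new_lesion("ectopic_focus", center_x_mm = center_x_mm,
             center_y_mm = center_y_mm, depth_offset_px = as.integer(depth_offset_px),
             size_px = as.integer(size_px))
}

#' Phantom specification
#'
#' Defines a synthetic polarization-sensitive OCT volume: a layered eye model
#' (vitreous / neurosensory retina / depolarizing RPE band / choroid) with a
#' list of planted lesions. Non-RPE voxels carry a common, fully polarized
#' Stokes state; RPE (and ectopic-focus) voxels carry per-voxel polarization
#' directions randomized with magnitude \code{depol_strength}.
#'
#' @param geometry A \code{scan_geometry} (default: full acquisition profile).
#' @param rpe_depth_px Axial index (0-based) of the top of the nominal RPE
#'   band; default 62.5\% of the depth range.
#' @param rpe_thickness_px Nominal band thickness in pixels; default scales
#'   with the axial sampling (10 px at 256 depth samples, 5 px at 128).
#' @param depol_strength In [0,1]: 0 leaves RPE voxels fully polarized along
#'   the common state, 1 randomizes their polarization direction uniformly on
#'   the Poincare sphere (geodesic interpolation in between).
#' @param noise_sd Standard deviation of additive Gaussian noise applied to
#'   the polarization channels Q,U,V, which are then rescaled where needed so
#'   the polarized magnitude never exceeds I. The vitreous is signal-free
#'   (I = 0) by default, so its voxels are invalid for DOPU rather than
#'   noise-dominated.
#' @param lesions List of \code{lesion_spec} objects.
#' @param intensities Named list of zone reflectivities (arbitrary linear
#'   units): vitreous, retina, rpe, choroid.
#' @return An object of class \code{phantom_spec}.
#' @export
phantom_spec <- function(geometry = scan_geometry(),
                         rpe_depth_px = NULL, rpe_thickness_px = NULL,
                         depol_strength = 1.0, noise_sd = 0.05,
                         lesions = list(),
                         intensities = list(vitreous = 0, retina = 1.0,
                                            rpe = 1.2, choroid = 0.8)) {
  stopifnot_geometry(geometry)
  if (is.null(rpe_depth_px)) rpe_depth_px <- round(0.625 * geometry$n_depth)
  if (is.null(rpe_thickness_px)) rpe_thickness_px <- max(3L, geometry$n_depth %/% 25L)
  rpe_depth_px <- as.integer(rpe_depth_px)
  rpe_thickness_px <- as.integer(rpe_thickness_px)
  if (rpe_depth_px < 0L || rpe_thickness_px < 1L)
    stop("rpe_depth_px must be >= 0 and rpe_thickness_px >= 1")
  if (rpe_depth_px + rpe_thickness_px >= geometry$n_depth)
    stop("rpe_depth_px + rpe_thickness_px must be < n_depth")
  if (depol_strength < 0 || depol_strength > 1)
    stop("depol_strength must lie in [0,1]")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (length(lesions) && !all(vapply(lesions, inherits, TRUE, "lesion_spec")))
    stop("lesions must be lesion_spec objects")
  spec <- list(geometry = geometry, rpe_depth_px = rpe_depth_px,
               rpe_thickness_px = rpe_thickness_px,
               depol_strength = depol_strength, noise_sd = noise_sd,
               lesions = lesions, intensities = intensities)
  class(spec) <- "phantom_spec"
  validate_lesion_footprints(spec)
  spec
}

lesion_bbox_mm <- function(l) {
  switch(l$kind,
    ga_patch = ,
    focal_atrophy = c(l$center_x_mm - l$radius_mm, l$center_x_mm + l$radius_mm,
                      l$center_y_mm - l$radius_mm, l$center_y_mm + l$radius_mm),
    gap_series = {
      span <- l$n_gaps * l$gap_width_mm + (l$n_gaps - 1L) * l$spacing_mm
      c(l$start_x_mm, l$start_x_mm + span, l$center_y_mm, l$center_y_mm)
    },
    thinning = ,
    thickening = c(l$center_x_mm - l$width_mm / 2, l$center_x_mm + l$width_mm / 2,
                   l$center_y_mm - l$height_mm / 2, l$center_y_mm + l$height_mm / 2),
    ectopic_focus = c(l$center_x_mm, l$center_x_mm, l$center_y_mm, l$center_y_mm),
    stop("unknown lesion kind: ", l$kind))
}

validate_lesion_footprints <- function(spec) {
  g <- spec$geometry
  for (i in seq_along(spec$lesions)) {
    l <- spec$lesions[[i]]
    bb <- lesion_bbox_mm(l)
    if (bb[1] < 0 || bb[2] > g$width_mm || bb[3] < 0 || bb[4] > g$height_mm)
      stop(sprintf("lesion %d (%s) footprint [%.2f,%.2f]x[%.2f,%.2f] mm outside scan area %.2f x %.2f mm",
                   i, l$kind, bb[1], bb[2], bb[3], bb[4], g$width_mm, g$height_mm))
    if (l$kind == "ectopic_focus") {
      d <- spec$rpe_depth_px + l$depth_offset_px
      if (d - l$size_px %/% 2 < 0L || d + l$size_px %/% 2 >= g$n_depth)
        stop(sprintf("lesion %d (ectopic_focus) axial extent outside volume", i))
    }
  }
  invisible(spec)
}

# En-face footprint (logical matrix [n_ascans, n_bscans]) of one lesion.
lesion_footprint <- function(l, geometry) {
  x <- ascan_centers_mm(geometry)
  y <- bscan_centers_mm(geometry)
  fp <- matrix(FALSE, geometry$n_ascans, geometry$n_bscans)
  if (l$kind %in% c("ga_patch", "focal_atrophy")) {
    dx2 <- (x - l$center_x_mm)^2
    dy2 <- (y - l$center_y_mm)^2
    fp <- outer(dx2, dy2, `+`) <= l$radius_mm^2
  } else if (l$kind == "gap_series") {
    pitch <- bscan_pitch_mm(geometry)
    rows <- which(y >= l$center_y_mm - 1e-9 &
                  y < l$center_y_mm + l$n_bscans_extent * pitch - 1e-9)
    rows <- rows[seq_len(min(length(rows), l$n_bscans_extent))]
    for (gidx in seq_len(l$n_gaps)) {
      x0 <- l$start_x_mm + (gidx - 1L) * (l$gap_width_mm + l$spacing_mm)
      cols <- x >= x0 & x < x0 + l$gap_width_mm
      fp[cols, rows] <- TRUE
    }
  } else if (l$kind %in% c("thinning", "thickening")) {
    cols <- abs(x - l$center_x_mm) <= l$width_mm / 2
    rows <- abs(y - l$center_y_mm) <= l$height_mm / 2
    fp[cols, rows] <- TRUE
  } else if (l$kind == "ectopic_focus") {
    h <- l$size_px %/% 2L
    ix <- which.min(abs(x - l$center_x_mm))
    iy <- which.min(abs(y - l$center_y_mm))
    fp[pmax(1L, ix - h):pmin(geometry$n_ascans, ix + h),
       pmax(1L, iy - h):pmin(geometry$n_bscans, iy + h)] <- TRUE
  }
  fp
}

lesion_true_area_mm2 <- function(l, geometry) {
  switch(l$kind,
    ga_patch = ,
    focal_atrophy = pi * l$radius_mm^2,
    gap_series = l$n_gaps * l$gap_width_mm *
      (l$n_bscans_extent * bscan_pitch_mm(geometry)),
    thinning = ,
    thickening = l$width_mm * l$height_mm,
    ectopic_focus = NA_real_)
}

lesion_center_mm <- function(l) {
  if (l$kind == "gap_series") {
    span <- l$n_gaps * l$gap_width_mm + (l$n_gaps - 1L) * l$spacing_mm
    c(l$start_x_mm + span / 2, l$center_y_mm)
  } else c(l$center_x_mm, l$center_y_mm)
}

# Mapping from planted lesion kinds to the lesion-type grades they should
# elicit. A gap series is, by construction, also a set of focal (sub-GA-floor)
# atrophic defects, so it sets the focal-atrophy expectation too.
kind_to_grade <- function(kind, depth_offset_px = NULL) {
  switch(kind,
    ga_patch = "ga",
    focal_atrophy = "focal_atrophy",
    gap_series = c("porosity", "focal_atrophy"),
    thinning = "thinning",
    thickening = "accumulation_rpe_level",
    ectopic_focus = if (!is.null(depth_offset_px) && depth_offset_px < 0)
      "ectopic_material" else character(0))
}

grade_types <- function() {
  c("porosity", "focal_atrophy", "thinning", "accumulation_rpe_level",
    "ectopic_material", "ga")
}

#' Generate a synthetic polarization-sensitive OCT volume
#'
#' Builds the ground-truth depolarizing-tissue label map from the phantom
#' specification (independent of seed and noise level), then synthesizes the
#' four Stokes channels: polarization-preserving voxels share a common fully
#' polarized state \code{(Q,U,V)/I = (1,0,0)}; depolarizing voxels (RPE band
#' and ectopic foci) have their polarization direction moved along the
#' great-circle towards an independently drawn uniformly random direction on
#' the Poincare sphere, with interpolation weight \code{depol_strength}.
#' Gaussian noise of SD \code{noise_sd} is added to all four channels, I is
#' clipped to be positive, and Q,U,V are rescaled where their norm would
#' exceed I, so every voxel is physical.
#'
#' Identical \code{(spec, seed)} pairs give bit-identical volumes.
#'
#' @param spec A \code{phantom_spec}.
#' @param seed Integer seed for the noise and depolarization draws.
#' @return A list with elements \code{volume} (a \code{stokes_volume}) and
#'   \code{truth} (class \code{phantom_truth}): the label array (0 = none,
#'   1 = RPE band, 2 = ectopic/sub-band focus), a \code{lesions} data frame
#'   (id, kind, true area in mm^2, centre), per-lesion en-face footprints,
#'   the planted band thickness map, and expected lesion grades (eye level
#'   and per B-scan).
#' @export
generate_phantom <- function(spec, seed = 1L) {
  if (!inherits(spec, "phantom_spec")) stop("spec must be a phantom_spec")
  truth <- phantom_ground_truth(spec)
  g <- spec$geometry
  nd <- g$n_depth; na <- g$n_ascans; nb <- g$n_bscans
  label <- truth$label
  depth_idx0 <- array(rep(seq_len(nd) - 1L, na * nb), dim = c(nd, na, nb))

  ## ---- volume synthesis ----
  set.seed(as.integer(seed))
  ints <- spec$intensities
  retina_top <- max(1L, as.integer(round(0.6 * spec$rpe_depth_px)))
  I <- array(ints$retina, dim = c(nd, na, nb))
  I[depth_idx0 < retina_top] <- ints$vitreous
  I[depth_idx0 >= spec$rpe_depth_px + spec$rpe_thickness_px] <- ints$choroid
  I[label > 0L] <- ints$rpe
  rm(depth_idx0)

  # direction field: common state (1,0,0); depolarizing voxels slerped
  dq <- array(1, dim = c(nd, na, nb))
  du <- array(0, dim = c(nd, na, nb))
  dv <- array(0, dim = c(nd, na, nb))
  # The random-direction field is drawn for every voxel (and used only where
  # the tissue depolarizes), so the draws consumed at any voxel do not depend
  # on which lesions are planted: ground-truth edits never shift the noise or
  # depolarization realization elsewhere in the volume.
  nvox <- length(I)
  zfield <- stats::runif(nvox, -1, 1)       # uniform on the sphere
  phifield <- stats::runif(nvox, 0, 2 * pi)
  dep <- which(label > 0L)
  if (length(dep) && spec$depol_strength > 0) {
    z <- zfield[dep]
    phi <- phifield[dep]
    rxy <- sqrt(pmax(0, 1 - z^2))
    rx <- z; ry <- rxy * cos(phi); rz <- rxy * sin(phi)
    t <- spec$depol_strength
    # slerp from e=(1,0,0) to r: angle between them is acos(rx)
    om <- acos(pmin(1, pmax(-1, rx)))
    s <- sin(om)
    w_e <- ifelse(s < 1e-12, 1 - t, sin((1 - t) * om) / pmax(s, 1e-12))
    w_r <- ifelse(s < 1e-12, t, sin(t * om) / pmax(s, 1e-12))
    qq <- w_e + w_r * rx; uu <- w_r * ry; vv <- w_r * rz
    nrm <- sqrt(qq^2 + uu^2 + vv^2)
    dq[dep] <- qq / nrm; du[dep] <- uu / nrm; dv[dep] <- vv / nrm
  }
  Q <- I * dq; U <- I * du; V <- I * dv
  rm(dq, du, dv, zfield, phifield)

  if (spec$noise_sd > 0) {
    # additive Gaussian noise on the polarization channels only, then
    # renormalized so the polarized magnitude never exceeds I (physicality)
    Q <- Q + stats::rnorm(nvox, 0, spec$noise_sd)
    U <- U + stats::rnorm(nvox, 0, spec$noise_sd)
    V <- V + stats::rnorm(nvox, 0, spec$noise_sd)
    pol <- sqrt(Q^2 + U^2 + V^2)
    over <- pol > I
    if (any(over)) {
      sc <- I[over] / pmax(pol[over], 1e-12)
      Q[over] <- Q[over] * sc; U[over] <- U[over] * sc; V[over] <- V[over] * sc
    }
    dim(Q) <- dim(U) <- dim(V) <- c(nd, na, nb)
  }

  list(volume = stokes_volume(I, Q, U, V, g, check = FALSE), truth = truth)
}

#' Ground truth of a phantom, without synthesizing the volume
#'
#' The ground truth depends only on the phantom specification: it is
#' invariant to the seed and to the noise level.
#'
#' @param spec A \code{phantom_spec}.
#' @return A \code{phantom_truth} object (see [generate_phantom()]).
#' @export
phantom_ground_truth <- function(spec) {
  if (!inherits(spec, "phantom_spec")) stop("spec must be a phantom_spec")
  validate_lesion_footprints(spec)
  g <- spec$geometry
  nd <- g$n_depth; na <- g$n_ascans; nb <- g$n_bscans
  thick <- matrix(spec$rpe_thickness_px, na, nb)  # planted band thickness/A-line
  for (l in spec$lesions) {
    fp <- lesion_footprint(l, g)
    if (l$kind %in% c("ga_patch", "focal_atrophy", "gap_series")) {
      thick[fp] <- 0L
    } else if (l$kind %in% c("thinning", "thickening")) {
      t_new <- max(1L, as.integer(round(l$thickness_multiplier * spec$rpe_thickness_px)))
      thick[fp] <- t_new
    }
  }
  depth_idx0 <- array(rep(seq_len(nd) - 1L, na * nb), dim = c(nd, na, nb))
  thick_arr <- aperm(array(thick, dim = c(na, nb, nd)), c(3L, 1L, 2L))
  label <- array(0L, dim = c(nd, na, nb))
  label[depth_idx0 >= spec$rpe_depth_px &
        depth_idx0 < spec$rpe_depth_px + thick_arr] <- 1L
  rm(thick_arr)

  lesion_rows <- list(); footprints <- list()
  for (i in seq_along(spec$lesions)) {
    l <- spec$lesions[[i]]
    fp <- lesion_footprint(l, g)
    footprints[[i]] <- fp
    ctr <- lesion_center_mm(l)
    lesion_rows[[i]] <- data.frame(
      lesion_id = i, kind = l$kind,
      area_mm2 = lesion_true_area_mm2(l, g),
      center_x_mm = ctr[1], center_y_mm = ctr[2],
      n_pixels = sum(fp), stringsAsFactors = FALSE)
    if (l$kind == "ectopic_focus") {
      h <- l$size_px %/% 2L
      dctr <- spec$rpe_depth_px + l$depth_offset_px  # 0-based
      dz <- (dctr - h):(dctr + h) + 1L
      idx <- which(fp, arr.ind = TRUE)
      for (k in seq_len(nrow(idx)))
        label[dz, idx[k, 1], idx[k, 2]] <- 2L
    }
  }
  lesions_df <- if (length(lesion_rows)) do.call(rbind, lesion_rows) else
    data.frame(lesion_id = integer(), kind = character(), area_mm2 = numeric(),
               center_x_mm = numeric(), center_y_mm = numeric(),
               n_pixels = integer(), stringsAsFactors = FALSE)

  ## expected grades
  types <- grade_types()
  eye_expected <- stats::setNames(rep(FALSE, length(types)), types)
  bscan_expected <- matrix(FALSE, nb, length(types), dimnames = list(NULL, types))
  for (i in seq_along(spec$lesions)) {
    l <- spec$lesions[[i]]
    tg <- kind_to_grade(l$kind, l$depth_offset_px)
    if (!length(tg)) next
    eye_expected[tg] <- TRUE
    rows <- which(colSums(footprints[[i]]) > 0)  # B-scans touched
    for (ty in setdiff(tg, "ga")) bscan_expected[rows, ty] <- TRUE
  }

  structure(list(
    label = label, lesions = lesions_df, footprints = footprints,
    band_thickness = thick, rpe_depth_px = spec$rpe_depth_px,
    rpe_thickness_px = spec$rpe_thickness_px,
    expected_eye = eye_expected, expected_bscan = bscan_expected,
    geometry = g), class = "phantom_truth")
}

#' @export
print.phantom_truth <- function(x, ...) {
  cat(sprintf("phantom_truth: %d planted lesions, band %d px at depth %d\n",
              nrow(x$lesions), x$rpe_thickness_px, x$rpe_depth_px))
  if (nrow(x$lesions)) print(x$lesions[, c("lesion_id", "kind", "area_mm2")])
  invisible(x)
}
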