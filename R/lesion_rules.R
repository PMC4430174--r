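#' Parameters of the rule-based lesion classifier
#'
#' Thresholds anchored to the grading definitions: porosity is a series of
#' RPE gaps (at least \code{porosity_min_gaps} gaps with at least
#' \code{porosity_min_residuals} interleaved depolarizing residuals) whose
#' cumulative width reaches 20\% of the B-scan; thinning is a contiguous run
#' thinner than half the normal band over at least 10\% of the B-scan;
#' accumulation is a run at least twice as thick as normal RPE. The plumbing
#' minima (\code{min_gap_px}, \code{min_thick_px}, \code{min_sep_px},
#' \code{min_focus_voxels}) suppress single-pixel noise.
#'
#' @param atrophy_count_max A-line count at or below which the A-line is a
#'   gap (0: a gap is the complete absence of depolarizing pixels).
#' @param min_gap_px Minimum gap run length in A-lines.
#' @param porosity_min_gaps,porosity_min_residuals Series definition.
#' @param porosity_width_frac Fraction of the B-scan width the gaps must
#'   cover (default 0.2).
#' @param porosity_width_mode \code{"cumulative"} (default) or
#'   \code{"contiguous"}: how gap width is accumulated against the 20\% rule.
#' @param thinning_ratio Thin means count < \code{thinning_ratio} x normal
#'   (strict), with count > \code{atrophy_count_max} (zero is a gap, not
#'   thinning).
#' @param thinning_width_frac Fraction of the B-scan a thin run must span
#'   (default 0.1).
#' @param thinning_width_mode \code{"contiguous"} (default) or
#'   \code{"cumulative"}.
#' @param accumulation_ratio Thick means count >= ratio x normal (default 2).
#' @param min_thick_px Minimum thick-run length in A-lines.
#' @param min_sep_px Minimum axial separation (pixels) between an ectopic
#'   focus and the band's upper bound.
#' @param min_focus_voxels Minimum voxel count of an ectopic focus.
#' @param ga_dilate_ascans,ga_dilate_bscans Dilation (in pixels) applied to
#'   detected GA-lesion footprints when deciding whether a gap belongs to a
#'   quantified GA lesion rather than focal atrophy.
#' @return A list of class \code{rule_params}.
#' @export
rule_params <- function(atrophy_count_max = 0L, min_gap_px = 3L,
                        porosity_min_gaps = 3L, porosity_min_residuals = 2L,
                        porosity_width_frac = 0.2,
                        porosity_width_mode = c("cumulative", "contiguous"),
                        thinning_ratio = 0.5, thinning_width_frac = 0.1,
                        thinning_width_mode = c("contiguous", "cumulative"),
                        accumulation_ratio = 2, min_thick_px = 5L,
                        min_sep_px = 5L, min_focus_voxels = 3L,
                        ga_dilate_ascans = 3L, ga_dilate_bscans = 2L) {
  structure(list(
    atrophy_count_max = atrophy_count_max, min_gap_px = as.integer(min_gap_px),
    porosity_min_gaps = as.integer(porosity_min_gaps),
    porosity_min_residuals = as.integer(porosity_min_residuals),
    porosity_width_frac = porosity_width_frac,
    porosity_width_mode = match.arg(porosity_width_mode),
    thinning_ratio = thinning_ratio, thinning_width_frac = thinning_width_frac,
    thinning_width_mode = match.arg(thinning_width_mode),
    accumulation_ratio = accumulation_ratio,
    min_thick_px = as.integer(min_thick_px),
    min_sep_px = as.integer(min_sep_px),
    min_focus_voxels = as.integer(min_focus_voxels),
    ga_dilate_ascans = as.integer(ga_dilate_ascans),
    ga_dilate_bscans = as.integer(ga_dilate_bscans)),
    class = "rule_params")
}

# TRUE-runs of a logical vector as a data frame (start, end, length).
true_runs <- function(x) {
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(start = starts[keep], end = ends[keep], length = r$lengths[keep])
}

#' Normal RPE segmentation-band thickness
#'
#' The reference thickness against which the thinning and accumulation rules
#' are evaluated: the median of non-zero depolarizing-pixel counts over
#' en-face cells outside the lesion exclusion mask, i.e. the band thickness
#' in regions outside the AMD lesion.
#'
#' @param tmap A \code{thickness_map}.
#' @param lesion_exclusion_mask Optional logical matrix of cells to exclude
#'   (recommended: the dilated union of the atrophy map and thick runs).
#' @param min_cell_frac Minimum fraction of cells that must remain after
#'   exclusion (default 0.05).
#' @return A \code{normal_rpe_thickness}: \code{value} (pixels) plus the
#'   estimation-region descriptor.
#' @export
estimate_normal_thickness <- function(tmap, lesion_exclusion_mask = NULL,
                                      min_cell_frac = 0.05) {
  if (!inherits(tmap, "thickness_map")) stop("tmap must be a thickness_map")
  counts <- tmap$counts
  keep <- if (is.null(lesion_exclusion_mask)) rep(TRUE, length(counts))
    else {
      if (!identical(dim(lesion_exclusion_mask), dim(counts)))
        stop("exclusion mask dimensions do not match the thickness map")
      !as.vector(lesion_exclusion_mask)
    }
  if (sum(keep) < min_cell_frac * length(counts))
    stop("fewer than the required fraction of cells available after exclusion")
  vals <- counts[keep]
  nz <- vals[vals > 0]
  if (!length(nz)) stop("no non-zero thickness cells: cannot estimate normal band thickness")
  structure(list(value = stats::median(nz), n_cells = length(nz),
                 region = if (is.null(lesion_exclusion_mask)) "all cells"
                          else "cells outside exclusion mask"),
            class = "normal_rpe_thickness")
}

#' Grade one B-scan for RPE lesion types
#'
#' Applies the run-length rules to the thickness-map row of one B-scan:
#' \itemize{
#' \item gap: a run of at least \code{min_gap_px} consecutive A-lines whose
#'   count is at most \code{atrophy_count_max};
#' \item porosity: a series of gaps (>= 3 gaps with >= 2 interleaved
#'   depolarizing residual runs) with cumulative width at least 20\% of the
#'   B-scan;
#' \item focal atrophy: a gap whose en-face pixels do not belong to any
#'   quantified GA lesion (they form a sub-threshold component, or were
#'   removed by smoothing) - isolated atrophy not quantifiable as advanced
#'   GA;
#' \item thinning: a contiguous run with 0 < count < half the normal band
#'   thickness spanning at least 10\% of the B-scan;
#' \item accumulation: a contiguous run with count at least twice the normal
#'   thickness spanning at least \code{min_thick_px} A-lines.
#' }
#'
#' @param row Integer vector: the thickness-map row of one B-scan (one count
#'   per A-line).
#' @param normal A \code{normal_rpe_thickness} (or a positive number).
#' @param params A \code{rule_params}.
#' @param ga_lesion_cols Optional logical vector flagging the A-lines of this
#'   B-scan covered by a detected (>= floor) GA lesion, after dilation;
#'   gaps overlapping it are attributed to GA, not focal atrophy. \code{NULL}
#'   treats no A-line as GA-covered.
#' @return A list of class \code{lesion_grade_bscan} with the four booleans
#'   and the run evidence each was derived from.
#' @export
grade_bscan <- function(row, normal, params = rule_params(),
                        ga_lesion_cols = NULL) {
  n <- length(row)
  if (n == 0L) stop("zero-length thickness row")
  nv <- if (inherits(normal, "normal_rpe_thickness")) normal$value else as.numeric(normal)
  if (!is.finite(nv) || nv <= 0) stop("normal band thickness must be > 0")
  acm <- params$atrophy_count_max
  eps <- 1e-9

  gap_all <- true_runs(row <= acm)
  gaps <- gap_all[gap_all$length >= params$min_gap_px, , drop = FALSE]
  residuals <- data.frame(start = integer(), end = integer(), length = integer())
  porosity <- FALSE
  cum_gap <- if (nrow(gaps)) sum(gaps$length) else 0L
  if (nrow(gaps) >= 1L) {
    res_all <- true_runs(row > acm)
    residuals <- res_all[res_all$start > min(gaps$start) &
                         res_all$end < max(gaps$end), , drop = FALSE]
    width <- if (params$porosity_width_mode == "cumulative") cum_gap
             else max(gaps$length)
    porosity <- nrow(gaps) >= params$porosity_min_gaps &&
      nrow(residuals) >= params$porosity_min_residuals &&
      width + eps >= params$porosity_width_frac * n
  }

  focal <- FALSE
  if (nrow(gaps)) {
    if (is.null(ga_lesion_cols)) ga_lesion_cols <- rep(FALSE, n)
    for (i in seq_len(nrow(gaps)))
      if (!any(ga_lesion_cols[gaps$start[i]:gaps$end[i]])) { focal <- TRUE; break }
  }

  thin_all <- true_runs(row > acm & row < params$thinning_ratio * nv)
  thin_req <- params$thinning_width_frac * n
  thinning <- if (params$thinning_width_mode == "contiguous")
    nrow(thin_all) > 0 && max(thin_all$length) + eps >= thin_req
  else sum(thin_all$length) + eps >= thin_req && nrow(thin_all) > 0

  thick_all <- true_runs(row >= params$accumulation_ratio * nv)
  thick_runs <- thick_all[thick_all$length >= params$min_thick_px, , drop = FALSE]
  accumulation <- nrow(thick_runs) > 0

  structure(list(porosity = porosity, focal_atrophy = focal,
                 thinning = thinning, accumulation_rpe_level = accumulation,
                 evidence = list(gaps = gaps, residuals = residuals,
                                 cum_gap_width = cum_gap,
                                 thin_runs = thin_all, thick_runs = thick_runs,
                                 normal = nv, n_ascans = n)),
            class = "lesion_grade_bscan")
}

#' Detect ectopic depolarizing foci in the outer retina
#'
#' Finds 26-connected components of depolarizing voxels whose entire extent
#' lies at least \code{min_sep_px} pixels above (vitread of) the evaluation
#' band's upper bound and which share no connected path with tissue at or
#' below that line - depolarizing structures in outer retinal layers that
#' are discontinuous from the RPE. Components smaller than
#' \code{min_focus_voxels} are discarded.
#'
#' @param mask An \code{rpe_mask}.
#' @param band An \code{evaluation_band}.
#' @param params A \code{rule_params}.
#' @return Data frame (focus_id, n_voxels, centroid_depth_px, ascan, bscan
#'   ranges); zero rows when no focus exists.
#' @export
detect_ectopic_foci <- function(mask, band, params = rule_params()) {
  if (!inherits(mask, "rpe_mask")) stop("mask must be an rpe_mask")
  if (!inherits(band, "evaluation_band")) stop("band must be an evaluation_band")
  m <- mask$mask
  d <- dim(m)
  nd <- d[1]; na <- d[2]; nb <- d[3]
  # cut line per A-line: depths strictly above it are candidate foci voxels
  cut <- band$upper - params$min_sep_px          # 0-based bound
  depth0 <- seq_len(nd) - 1L
  above <- array(FALSE, d)
  for (b in seq_len(nb))
    above[, , b] <- outer(depth0, cut[, b], `<=`)
  A <- m & above
  B <- m & !above
  idx <- which(A)
  empty <- data.frame(focus_id = integer(), n_voxels = integer(),
                      centroid_depth_px = numeric(), centroid_ascan = numeric(),
                      centroid_bscan = numeric())
  if (!length(idx)) return(empty)
  node <- array(0L, d)
  node[idx] <- seq_along(idx)
  zi <- ((idx - 1L) %% nd) + 1L
  ai <- (((idx - 1L) %/% nd) %% na) + 1L
  bi <- ((idx - 1L) %/% (nd * na)) + 1L
  offs <- as.matrix(expand.grid(dz = -1:1, da = -1:1, db = -1:1))
  offs <- offs[!(offs[, 1] == 0 & offs[, 2] == 0 & offs[, 3] == 0), , drop = FALSE]
  edges <- list()
  touches_B <- rep(FALSE, length(idx))
  for (k in seq_len(nrow(offs))) {
    z2 <- zi + offs[k, 1]; a2 <- ai + offs[k, 2]; b2 <- bi + offs[k, 3]
    okn <- z2 >= 1L & z2 <= nd & a2 >= 1L & a2 <= na & b2 >= 1L & b2 <= nb
    if (!any(okn)) next
    lin1 <- (b2[okn] - 1L) * nd * na + (a2[okn] - 1L) * nd + z2[okn]
    touches_B[which(okn)[B[lin1]]] <- TRUE
    nbn <- node[lin1]
    hit <- nbn > 0L
    if (any(hit))
      edges[[length(edges) + 1L]] <- cbind(node[idx[okn]][hit], nbn[hit])
  }
  edges <- if (length(edges)) do.call(rbind, edges) else matrix(0L, 0L, 2L)
  comp <- uf_components(length(idx), edges)
  bad <- unique(comp[touches_B])
  sizes <- tabulate(comp)
  keep_comp <- setdiff(which(sizes >= params$min_focus_voxels), bad)
  if (!length(keep_comp)) return(empty)
  out <- lapply(seq_along(keep_comp), function(i) {
    sel <- comp == keep_comp[i]
    data.frame(focus_id = i, n_voxels = sum(sel),
               centroid_depth_px = mean(zi[sel]) - 1,
               centroid_ascan = mean(ai[sel]),
               centroid_bscan = mean(bi[sel]))
  })
  do.call(rbind, out)
}

#' Grade a whole volume
#'
#' Convenience wrapper: estimates the normal band thickness, grades every
#' B-scan (supplying each row with the dilated footprints of detected GA
#' lesions so gaps are attributed correctly), and detects ectopic foci.
#'
#' @param tmap A \code{thickness_map}.
#' @param ga A \code{ga_lesion_set} for the same volume.
#' @param mask The \code{rpe_mask}.
#' @param band The \code{evaluation_band}.
#' @param params A \code{rule_params}.
#' @return List with \code{normal}, \code{grades} (one
#'   \code{lesion_grade_bscan} per B-scan) and \code{foci}.
#' @export
grade_volume <- function(tmap, ga, mask, band, params = rule_params()) {
  normal <- estimate_normal_thickness(tmap)
  les <- ga$lesion_label > 0L
  les_dil <- box_sum(les * 1, params$ga_dilate_ascans, params$ga_dilate_bscans) > 0
  nb <- ncol(tmap$counts)
  grades <- vector("list", nb)
  for (b in seq_len(nb))
    grades[[b]] <- grade_bscan(tmap$counts[, b], normal, params,
                               ga_lesion_cols = les_dil[, b])
  foci <- detect_ectopic_foci(mask, band, params)
  list(normal = normal, grades = grades, foci = foci)
}

#' Score an eye-visit record from volume-level outputs
#'
#' Each lesion type scores 1 when any graded B-scan is positive (ectopic
#' material: any detected focus; GA: non-empty lesion set). The GA area is
#' the lesion-set total.
#'
#' @param ga A \code{ga_lesion_set}.
#' @param grades List with one \code{lesion_grade_bscan} per B-scan (no
#'   missing entries).
#' @param foci Data frame from [detect_ectopic_foci()].
#' @param eye_id,visit_month Record identity.
#' @param crt_um,bcva_letters Stored clinical covariates.
#' @return One-row data frame (an eye-visit record): 0/1 presence per lesion
#'   type, \code{ga_area_mm2}, CRT and BCVA.
#' @export
score_eye_visit <- function(ga, grades, foci, eye_id = NA, visit_month = NA,
                            crt_um = NA_real_, bcva_letters = NA_real_) {
  if (!length(grades) || any(vapply(grades, is.null, TRUE)))
    stop("missing B-scan grades: every B-scan must be graded")
  anyof <- function(field) as.integer(any(vapply(grades, function(g) isTRUE(g[[field]]), TRUE)))
  data.frame(eye_id = eye_id, visit_month = visit_month,
             porosity = anyof("porosity"),
             focal_atrophy = anyof("focal_atrophy"),
             thinning = anyof("thinning"),
             accumulation_rpe_level = anyof("accumulation_rpe_level"),
             ectopic_material = as.integer(nrow(foci) > 0),
             ga = as.integer(nrow(ga$lesions) > 0),
             ga_area_mm2 = ga$total_area_mm2,
             crt_um = crt_um, bcva_letters = bcva_letters)
}
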