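# ---- connected components (union-find) -------------------------------------

# Union-find over n nodes given an edge list (2-column integer matrix).
# Returns compacted component ids (1..K) per node.
uf_components <- function(n, edges) {
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  if (length(edges)) {
    for (k in seq_len(nrow(edges))) {
      ra <- find(edges[k, 1]); rb <- find(edges[k, 2])
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, sort(unique(roots)))
}

#' Label connected components of an en-face binary map
#'
#' 8-connectivity (edge- and corner-adjacent pixels belong to the same
#' patch) by default, the standard choice for blob detection; 4-connectivity
#' is available for comparison.
#'
#' @param mask Logical matrix \code{[n_ascans, n_bscans]}.
#' @param connectivity 8 (default) or 4.
#' @return Integer matrix of the same shape: 0 = background, 1..K component
#'   labels.
#' @export
label_components <- function(mask, connectivity = 8L) {
  if (!is.matrix(mask)) stop("mask must be a matrix")
  if (!connectivity %in% c(4L, 8L)) stop("connectivity must be 4 or 8")
  nr <- nrow(mask); nc <- ncol(mask)
  idx <- which(mask)
  out <- matrix(0L, nr, nc)
  if (!length(idx)) return(out)
  node <- matrix(0L, nr, nc)
  node[idx] <- seq_along(idx)
  offs <- list(c(1L, 0L), c(0L, 1L))
  if (connectivity == 8L) offs <- c(offs, list(c(1L, 1L), c(-1L, 1L)))
  edges <- list()
  ai <- ((idx - 1L) %% nr) + 1L   # row (a-scan)
  bi <- ((idx - 1L) %/% nr) + 1L  # col (b-scan)
  for (o in offs) {
    a2 <- ai + o[1]; b2 <- bi + o[2]
    okn <- a2 >= 1L & a2 <= nr & b2 >= 1L & b2 <= nc
    if (!any(okn)) next
    nb <- node[cbind(a2[okn], b2[okn])]
    hit <- nb > 0L
    if (any(hit))
      edges[[length(edges) + 1L]] <- cbind(node[idx[okn]][hit], nb[hit])
  }
  edges <- if (length(edges)) do.call(rbind, edges) else matrix(0L, 0L, 2L)
  comp <- uf_components(length(idx), edges)
  out[idx] <- comp
  out
}

# ---- evaluation band --------------------------------------------------------

#' Fit the evaluation band around the segmented RPE/Bruch complex
#'
#' For every A-line the band is centred on the depth centroid of the
#' depolarizing mask: \code{[centroid - margin_up, centroid + margin_down)}
#' (0-based depth indices, half-open). Centroids are smoothed along the
#' A-scan axis with a running median; A-lines without any depolarizing pixel
#' (holes, e.g. inside atrophic patches) are filled by linear interpolation
#' from flanking A-lines. The band restricts the per-A-line counting of
#' depolarizing pixels so that depolarizing signals below the RPE/Bruch
#' membrane complex (choroid) are excluded.
#'
#' Manual per-B-scan overrides replace the fitted bounds for the listed
#' B-scans, making the semi-automated band adjustment reproducible.
#'
#' @param mask An \code{rpe_mask}.
#' @param margin_up_px,margin_down_px Band half-heights in pixels above and
#'   below the centroid.
#' @param manual Named list: names are B-scan indices, values \code{c(upper,
#'   lower)} 0-based depth bounds applied to every A-line of that B-scan.
#' @param median_window Running-median window along the A-scan axis (odd).
#' @return An \code{evaluation_band}: \code{upper}/\code{lower} matrices
#'   \code{[n_ascans, n_bscans]} (0-based, half-open) and per-B-scan source
#'   labels ("auto"/"manual").
#' @export
fit_evaluation_band <- function(mask, margin_up_px = 10L, margin_down_px = 10L,
                                manual = NULL, median_window = 31L) {
  if (!inherits(mask, "rpe_mask")) stop("mask must be an rpe_mask")
  m <- mask$mask
  d <- dim(m)
  nd <- d[1]; na <- d[2]; nb <- d[3]
  if (!any(m) && is.null(manual))
    stop("mask contains no depolarizing pixels and no manual overrides supplied")
  depth0 <- seq_len(nd) - 1L
  upper <- matrix(NA_real_, na, nb)
  lower <- matrix(NA_real_, na, nb)
  source <- rep("auto", nb)
  k <- min(median_window, if (na %% 2L == 1L) na else na - 1L)
  if (k %% 2L == 0L) k <- k - 1L
  all_centroids <- matrix(NA_real_, na, nb)
  for (b in seq_len(nb)) {
    mb <- m[, , b]
    w <- colSums(mb)
    cen <- colSums(mb * depth0) / ifelse(w > 0, w, NA)
    all_centroids[, b] <- cen
  }
  global_med <- stats::median(all_centroids, na.rm = TRUE)
  for (b in seq_len(nb)) {
    cen <- all_centroids[, b]
    if (all(is.na(cen))) {
      cen <- rep(global_med, na)   # fully empty B-scan: volume-wide fallback
    } else if (anyNA(cen)) {
      xs <- seq_len(na)
      cen <- stats::approx(xs[!is.na(cen)], cen[!is.na(cen)], xout = xs,
                           rule = 2)$y
    }
    cen <- if (k >= 3L && na >= k) as.numeric(stats::runmed(cen, k)) else cen
    upper[, b] <- pmax(0, round(cen) - margin_up_px)
    lower[, b] <- pmin(nd, round(cen) + margin_down_px)
  }
  if (!is.null(manual)) {
    for (nm in names(manual)) {
      b <- as.integer(nm)
      if (is.na(b) || b < 1L || b > nb)
        stop("manual override refers to B-scan outside the volume: ", nm)
      ov <- manual[[nm]]
      if (length(ov) != 2L || !(ov[1] >= 0 && ov[1] < ov[2] && ov[2] <= nd))
        stop("manual override must satisfy 0 <= upper < lower <= n_depth")
      upper[, b] <- ov[1]; lower[, b] <- ov[2]
      source[b] <- "manual"
    }
  }
  structure(list(upper = upper, lower = lower, source = source,
                 margins = c(up = margin_up_px, down = margin_down_px),
                 n_depth = nd),
            class = "evaluation_band")
}

# ---- thickness map ----------------------------------------------------------

#' En-face thickness map of depolarizing tissue
#'
#' For each A-line, counts the depolarizing (mask-true) voxels with depth in
#' the half-open evaluation band \code{[upper, lower)}. The resulting en-face
#' grid is the thickness map of depolarizing tissue; atrophic RPE shows up
#' as zero counts.
#'
#' @param mask An \code{rpe_mask}.
#' @param band An \code{evaluation_band} fitted on a volume of the same
#'   dimensions.
#' @return A \code{thickness_map}: integer \code{counts} matrix
#'   \code{[n_ascans, n_bscans]} plus geometry.
#' @export
depolarizing_thickness_map <- function(mask, band) {
  if (!inherits(mask, "rpe_mask")) stop("mask must be an rpe_mask")
  if (!inherits(band, "evaluation_band")) stop("band must be an evaluation_band")
  d <- dim(mask$mask)
  if (!identical(dim(band$upper), c(d[2], d[3])) || band$n_depth != d[1])
    stop("band dimensions do not match the mask")
  nd <- d[1]; na <- d[2]; nb <- d[3]
  depth0 <- seq_len(nd) - 1L
  counts <- matrix(0L, na, nb)
  for (b in seq_len(nb)) {
    inband <- outer(depth0, band$upper[, b], `>=`) &
              outer(depth0, band$lower[, b], `<`)
    counts[, b] <- as.integer(colSums(mask$mask[, , b] & inband))
  }
  structure(list(counts = counts, band = band, geometry = mask$geometry),
            class = "thickness_map")
}

# ---- binarize and smooth ----------------------------------------------------

#' Binarize and smooth the thickness map into an atrophy map
#'
#' A cell is atrophic when its depolarizing-pixel count is at most
#' \code{atrophy_count_max} (default 0: atrophy is the absence of
#' depolarizing RPE). The binary map is then smoothed by a 3x3 median filter
#' followed by morphological closing and opening with a disc of radius
#' \code{smooth_radius_px}; radius 0 skips all smoothing.
#'
#' @param tmap A \code{thickness_map}.
#' @param atrophy_count_max Maximum count still considered atrophic.
#' @param smooth_radius_px Disc radius in en-face pixels.
#' @return An \code{atrophy_map}: logical \code{atrophic} matrix with the
#'   parameters recorded.
#' @export
binarize_and_smooth <- function(tmap, atrophy_count_max = 0L,
                                smooth_radius_px = 1L) {
  if (!inherits(tmap, "thickness_map")) stop("tmap must be a thickness_map")
  if (atrophy_count_max < 0L) stop("atrophy_count_max must be >= 0")
  atro <- tmap$counts <= atrophy_count_max
  if (smooth_radius_px > 0L) {
    # binary 3x3 median = majority of the zero-padded 3x3 neighbourhood
    s <- box_sum(atro * 1, 1L, 1L)
    atro <- s >= 5
    kern <- EBImage::makeBrush(2L * as.integer(smooth_radius_px) + 1L, "disc")
    x <- EBImage::opening(EBImage::closing(atro * 1, kern), kern)
    atro <- as.matrix(EBImage::imageData(x)) > 0.5
  }
  structure(list(atrophic = atro,
                 params = list(atrophy_count_max = atrophy_count_max,
                               smooth_radius_px = smooth_radius_px),
                 geometry = tmap$geometry),
            class = "atrophy_map")
}

# ---- lesion detection -------------------------------------------------------

#' Detect geographic-atrophy lesions in an atrophy map
#'
#' Finds 8-connected patches of atrophic pixels and converts pixel counts to
#' areas by scaling with the known en-face pixel area. Patches reaching
#' \code{min_area_mm2} (default 0.1 mm^2, the minimal GA area detectable by
#' the algorithm) form the GA lesion list; smaller patches are retained in a
#' sub-threshold list, which the focal-atrophy classifier consumes. Lesions
#' are sorted by area (descending), ties broken by the top-left-most pixel in
#' scan order.
#'
#' @param amap An \code{atrophy_map}.
#' @param geometry The volume's \code{scan_geometry}.
#' @param min_area_mm2 GA area floor in mm^2.
#' @return A \code{ga_lesion_set}: data frames \code{lesions} and
#'   \code{sub_threshold} (lesion_id, n_pixels, area_mm2, centroid), label
#'   matrices for both, and \code{total_area_mm2} (sum of GA lesion areas).
#' @export
detect_ga_lesions <- function(amap, geometry, min_area_mm2 = 0.1) {
  if (!inherits(amap, "atrophy_map")) stop("amap must be an atrophy_map")
  stopifnot_geometry(geometry)
  if (min_area_mm2 < 0) stop("min_area_mm2 must be >= 0")
  pa <- pixel_area_mm2(geometry)
  lab <- label_components(amap$atrophic, 8L)
  nlab <- max(lab)
  xs <- ascan_centers_mm(geometry); ys <- bscan_centers_mm(geometry)
  rows <- list()
  for (id in seq_len(nlab)) {
    idx <- which(lab == id)
    a <- ((idx - 1L) %% nrow(lab)) + 1L
    b <- ((idx - 1L) %/% nrow(lab)) + 1L
    first <- min((b - 1L) * nrow(lab) + a)   # scan order: B-scan, then A-scan
    rows[[id]] <- data.frame(component = id, n_pixels = length(idx),
                             area_mm2 = length(idx) * pa,
                             centroid_x_mm = mean(xs[a]),
                             centroid_y_mm = mean(ys[b]),
                             first_pixel = first)
  }
  comp <- if (nlab) do.call(rbind, rows) else
    data.frame(component = integer(), n_pixels = integer(),
               area_mm2 = numeric(), centroid_x_mm = numeric(),
               centroid_y_mm = numeric(), first_pixel = integer())
  ord <- order(-comp$area_mm2, comp$first_pixel)
  comp <- comp[ord, , drop = FALSE]
  is_ga <- comp$area_mm2 >= min_area_mm2
  relabel <- function(df, old_lab) {
    out <- matrix(0L, nrow(lab), ncol(lab))
    for (i in seq_len(nrow(df))) out[lab == df$component[i]] <- i
    out
  }
  lesions <- comp[is_ga, , drop = FALSE]
  subth <- comp[!is_ga, , drop = FALSE]
  if (nrow(lesions)) lesions$lesion_id <- seq_len(nrow(lesions))
  else lesions$lesion_id <- integer(0)
  if (nrow(subth)) subth$lesion_id <- seq_len(nrow(subth))
  else subth$lesion_id <- integer(0)
  keep <- c("lesion_id", "n_pixels", "area_mm2", "centroid_x_mm", "centroid_y_mm")
  structure(list(
    lesions = lesions[, keep, drop = FALSE],
    sub_threshold = subth[, keep, drop = FALSE],
    lesion_label = relabel(lesions, lab),
    sub_threshold_label = relabel(subth, lab),
    min_area_mm2 = min_area_mm2,
    total_area_mm2 = sum(lesions$area_mm2),
    pixel_area_mm2 = pa),
    class = "ga_lesion_set")
}

#' @export
print.ga_lesion_set <- function(x, ...) {
  cat(sprintf("ga_lesion_set: %d lesion(s) >= %.2f mm^2 (total %.3f mm^2), %d sub-threshold component(s)\n",
              nrow(x$lesions), x$min_area_mm2, x$total_area_mm2,
              nrow(x$sub_threshold)))
  if (nrow(x$lesions)) print(x$lesions)
  invisible(x)
}
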