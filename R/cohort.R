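#' Synthetic cohort specification
#'
#' A cohort is a set of eyes imaged at a schedule of visits. Each eye carries
#' a lesion manifest; a manifest entry becomes active at its
#' \code{onset_month} and stays present at every later visit (lesions are
#' applied cumulatively), plus per-visit central retinal thickness (CRT, um)
#' and best-corrected visual acuity (BCVA, ETDRS letters) trajectories.
#'
#' @param eyes List of eye descriptions; each a list with \code{eye_id},
#'   numeric vectors \code{crt_um} and \code{bcva_letters} aligned with
#'   \code{visits_months}, and \code{lesions}: a list of manifest entries
#'   (a \code{lesion_spec} plus an \code{onset_month} attribute, or a plain
#'   list with \code{kind}, \code{onset_month} and the constructor arguments).
#' @param visits_months Strictly increasing visit schedule in months.
#' @param geometry \code{scan_geometry} for all volumes.
#' @param phantom Named list of \code{phantom_spec} arguments shared by all
#'   eyes (e.g. \code{rpe_depth_px}, \code{depol_strength}, \code{noise_sd}).
#' @param seed Base seed; per-eye, per-visit seeds are derived from it.
#' @param name Optional cohort label.
#' @return An object of class \code{cohort_spec}.
#' @export
cohort_spec <- function(eyes, visits_months, geometry = scan_geometry_test(),
                        phantom = list(), seed = 1L, name = "cohort") {
  if (!length(eyes)) stop("cohort must contain at least one eye")
  if (!length(visits_months)) stop("empty visit schedule")
  if (length(visits_months) > 1 && any(diff(visits_months) <= 0))
    stop("visits_months must be strictly increasing")
  stopifnot_geometry(geometry)
  spec <- list(eyes = eyes, visits_months = as.numeric(visits_months),
               geometry = geometry, phantom = phantom,
               seed = as.integer(seed), name = name)
  class(spec) <- "cohort_spec"
  spec
}

manifest_to_lesion <- function(m) {
  if (inherits(m, "lesion_spec")) return(m)
  args <- m[setdiff(names(m), c("kind", "onset_month"))]
  ctor <- switch(m$kind,
    ga_patch = lesion_ga_patch, focal_atrophy = lesion_focal_atrophy,
    gap_series = lesion_gap_series, thinning = lesion_thinning,
    thickening = lesion_thickening, ectopic_focus = lesion_ectopic_focus,
    stop("unknown lesion kind in manifest: ", m$kind))
  do.call(ctor, args)
}

manifest_onset <- function(m) {
  on <- if (inherits(m, "lesion_spec")) attr(m, "onset_month") else m$onset_month
  if (is.null(on)) -Inf else as.numeric(on)
}

#' Read a cohort specification from YAML
#'
#' The YAML encodes the fields of [cohort_spec()]; \code{geometry} may be
#' given either as \code{profile: full} / \code{profile: test} or as explicit
#' \code{scan_geometry} fields.
#'
#' @param path Path to a YAML file.
#' @return A \code{cohort_spec}.
#' @export
read_cohort_spec <- function(path) {
  y <- yaml::read_yaml(path)
  geom <- y$geometry
  geometry <- if (is.null(geom)) scan_geometry_test()
    else if (!is.null(geom$profile)) {
      switch(geom$profile, full = scan_geometry(), test = scan_geometry_test(),
             stop("unknown geometry profile: ", geom$profile))
    } else do.call(scan_geometry, geom)
  cohort_spec(eyes = y$eyes, visits_months = y$visits_months,
              geometry = geometry, phantom = if (is.null(y$phantom)) list() else y$phantom,
              seed = if (is.null(y$seed)) 1L else y$seed,
              name = if (is.null(y$name)) "cohort" else y$name)
}

# Phantom spec for one eye at one visit (manifests applied cumulatively).
eye_visit_phantom_spec <- function(cohort, eye_index, visit_month) {
  eye <- cohort$eyes[[eye_index]]
  active <- Filter(function(m) manifest_onset(m) <= visit_month,
                   if (is.null(eye$lesions)) list() else eye$lesions)
  lesions <- lapply(active, manifest_to_lesion)
  do.call(phantom_spec,
          c(list(geometry = cohort$geometry, lesions = lesions), cohort$phantom))
}

eye_visit_seed <- function(base_seed, eye_index, visit_index) {
  as.integer((as.double(base_seed) * 97 + eye_index * 7919 + visit_index * 104729) %%
             2147483647)
}

#' Generate a synthetic cohort
#'
#' Produces one record per eye per visit. Each record carries the eye id,
#' visit month, CRT and BCVA values, the ground truth, and (optionally) the
#' simulated Stokes volume. Fully deterministic under a fixed seed.
#'
#' @param cohort A \code{cohort_spec}.
#' @param seed Base seed; defaults to the cohort's own seed.
#' @param with_volumes If \code{FALSE}, volumes are omitted (each record then
#'   carries its \code{phantom_spec} and derived seed so the volume can be
#'   regenerated on demand, which keeps memory flat when streaming large
#'   cohorts).
#' @return List of records (class \code{eye_visit_sim} each).
#' @export
generate_cohort <- function(cohort, seed = NULL, with_volumes = TRUE) {
  if (!inherits(cohort, "cohort_spec")) stop("cohort must be a cohort_spec")
  if (is.null(seed)) seed <- cohort$seed
  records <- list()
  k <- 0L
  for (vi in seq_along(cohort$visits_months)) {
    month <- cohort$visits_months[vi]
    for (ei in seq_along(cohort$eyes)) {
      eye <- cohort$eyes[[ei]]
      spec <- eye_visit_phantom_spec(cohort, ei, month)
      rseed <- eye_visit_seed(seed, ei, vi)
      rec <- list(eye_id = if (is.null(eye$eye_id)) ei else eye$eye_id,
                  visit_month = month,
                  crt_um = if (is.null(eye$crt_um)) NA_real_ else
                    as.numeric(eye$crt_um)[min(vi, length(eye$crt_um))],
                  bcva_letters = if (is.null(eye$bcva_letters)) NA_real_ else
                    as.numeric(eye$bcva_letters)[min(vi, length(eye$bcva_letters))],
                  phantom = spec, seed = rseed)
      if (with_volumes) {
        sim <- generate_phantom(spec, rseed)
        rec$volume <- sim$volume
        rec$truth <- sim$truth
      } else {
        rec$truth <- phantom_ground_truth(spec)
      }
      class(rec) <- "eye_visit_sim"
      k <- k + 1L
      records[[k]] <- rec
    }
  }
  records
}

#' Filter eye-visit records by the retinal-thickening inclusion criterion
#'
#' Retains exactly the records whose central retinal thickness is strictly
#' greater than the threshold (inclusion required retinal thickening
#' > 250 um). Records with missing CRT are excluded, flagged in the
#' \code{"excluded"} attribute of the result, and reported via a warning.
#' Input order is preserved.
#'
#' @param records Either a list of records carrying \code{crt_um}, or a data
#'   frame with a \code{crt_um} column (as produced by [score_eye_visit()]).
#' @param crt_threshold_um Threshold in micrometres (default 250).
#' @return The retained records, same container type as the input.
#' @examples
#' recs <- data.frame(eye_id = 1:3, crt_um = c(450.9, 250, 251))
#' eligibility_filter(recs)$eye_id  # 1 and 3
#' @export
eligibility_filter <- function(records, crt_threshold_um = 250) {
  crt <- if (is.data.frame(records)) records$crt_um
    else vapply(records, function(r) {
      v <- r$crt_um
      if (is.null(v)) NA_real_ else as.numeric(v)
    }, numeric(1))
  if (is.null(crt)) stop("records carry no crt_um field")
  missing_idx <- which(is.na(crt))
  if (length(missing_idx))
    warning(sprintf("excluding %d record(s) with missing CRT (positions: %s)",
                    length(missing_idx), paste(missing_idx, collapse = ", ")))
  keep <- !is.na(crt) & crt > crt_threshold_um
  out <- if (is.data.frame(records)) records[keep, , drop = FALSE]
    else records[keep]
  attr(out, "excluded") <- which(!keep)
  out
}
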