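#' Per-visit lesion-type prevalence
#'
#' For every visit and lesion type: the number of affected eyes, the number
#' of graded eyes and the percentage of affected eyes.
#'
#' @param records Data frame of eye-visit records (rows from
#'   [score_eye_visit()], or any data frame with \code{visit_month} and 0/1
#'   lesion-type columns).
#' @param types Lesion-type columns to tabulate; defaults to the six graded
#'   types present in the records.
#' @return Data frame (class \code{prevalence_table}): visit_month, type,
#'   n_affected, n_total, percent.
#' @examples
#' r <- data.frame(visit_month = 24, ga = c(rep(1, 20), rep(0, 11)))
#' prevalence(r)  # 20 of 31 -> 64.5%
#' @export
prevalence <- function(records, types = NULL) {
  if (!is.data.frame(records)) records <- do.call(rbind, records)
  if (is.null(types))
    types <- intersect(c("porosity", "focal_atrophy", "thinning",
                         "accumulation_rpe_level", "ectopic_material", "ga"),
                       names(records))
  if (!length(types)) stop("no lesion-type columns found")
  visits <- sort(unique(records$visit_month))
  out <- list()
  for (v in visits) {
    sub <- records[records$visit_month == v, , drop = FALSE]
    if (!nrow(sub)) stop("visit without records")
    for (ty in types) {
      aff <- sum(sub[[ty]] > 0, na.rm = TRUE)
      out[[length(out) + 1L]] <- data.frame(
        visit_month = v, type = ty, n_affected = aff, n_total = nrow(sub),
        percent = 100 * aff / nrow(sub))
    }
  }
  structure(do.call(rbind, out), class = c("prevalence_table", "data.frame"))
}

#' Per-visit GA-area summary over eyes with detected GA
#'
#' Mean, SD and range of the GA area, computed only over records in which GA
#' was detected (\code{ga_area_mm2 > 0}); visits without any detected GA are
#' reported as absent (\code{n = 0}, NA summaries), not as zero area.
#'
#' @param records Data frame with \code{visit_month} and \code{ga_area_mm2}.
#' @return Data frame: visit_month, n, mean_mm2, sd_mm2, min_mm2, max_mm2.
#' @export
ga_area_summary <- function(records) {
  if (!is.data.frame(records)) records <- do.call(rbind, records)
  visits <- sort(unique(records$visit_month))
  out <- lapply(visits, function(v) {
    a <- records$ga_area_mm2[records$visit_month == v]
    a <- a[!is.na(a) & a > 0]
    if (!length(a))
      data.frame(visit_month = v, n = 0L, mean_mm2 = NA_real_,
                 sd_mm2 = NA_real_, min_mm2 = NA_real_, max_mm2 = NA_real_)
    else
      data.frame(visit_month = v, n = length(a), mean_mm2 = mean(a),
                 sd_mm2 = if (length(a) > 1) stats::sd(a) else 0,
                 min_mm2 = min(a), max_mm2 = max(a))
  })
  do.call(rbind, out)
}

#' Paired-sample t test
#'
#' Classical paired t on the within-eye differences, two-sided p from the t
#' distribution with n-1 degrees of freedom. Degenerate inputs are handled
#' explicitly: identical vectors give t = 0, p = 1; a constant non-zero
#' difference (zero variance, non-zero mean) is an error rather than an
#' arbitrarily extreme statistic.
#'
#' @param x,y Paired numeric vectors (same eyes, two time points), length
#'   >= 2.
#' @return List: t, df, p (two-sided), mean_difference.
#' @examples
#' paired_t(c(5, 6, 7), c(4, 4, 4))  # differences 1,2,3: t = 2*sqrt(3)
#' @export
paired_t <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length (paired by eye)")
  if (length(x) < 2L) stop("need at least 2 pairs")
  d <- x - y
  if (stats::sd(d) == 0) {
    if (mean(d) == 0)
      return(list(t = 0, df = length(d) - 1L, p = 1, mean_difference = 0,
                  degenerate = TRUE))
    stop("zero-variance non-zero difference: paired t statistic is undefined")
  }
  ht <- stats::t.test(x, y, paired = TRUE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value, mean_difference = unname(ht$estimate),
       degenerate = FALSE)
}

#' Cohen's kappa for two binary graders, with 95\% confidence interval
#'
#' kappa = (p_o - p_e) / (1 - p_e) from the 2x2 agreement table, with the
#' large-sample (Fleiss-type) standard error and a normal-approximation 95\%
#' CI clipped to [-1, 1]. When both graders assign a single identical
#' category throughout, agreement is perfect but chance agreement is
#' undefined; kappa is returned as 1 with a degeneracy flag.
#'
#' @param g1,g2 Equal-length 0/1 vectors.
#' @param conf_level Confidence level (default 0.95).
#' @return List of class \code{agreement_result}: kappa, kappa_ci_low,
#'   kappa_ci_high, se, percent_agreement, degenerate.
#' @examples
#' g1 <- rep(c(1, 1, 0, 0), c(10, 5, 5, 10))
#' g2 <- rep(c(1, 0, 1, 0), c(10, 5, 5, 10))
#' cohen_kappa(g1, g2)$kappa  # 1/3
#' @export
cohen_kappa <- function(g1, g2, conf_level = 0.95) {
  if (length(g1) != length(g2)) stop("grader vectors must have equal length")
  if (!length(g1)) stop("empty grader vectors")
  g1 <- as.integer(g1 > 0); g2 <- as.integer(g2 > 0)
  n <- length(g1)
  tab <- matrix(0, 2, 2)
  for (i in 0:1) for (j in 0:1) tab[i + 1, j + 1] <- sum(g1 == i & g2 == j)
  p <- tab / n
  po <- sum(diag(p))
  pe <- sum(rowSums(p) * colSums(p))
  degenerate <- isTRUE(all.equal(pe, 1))
  if (degenerate) {
    kap <- if (po == 1) 1 else 0
    return(structure(list(kappa = kap, kappa_ci_low = kap, kappa_ci_high = kap,
                          se = 0, percent_agreement = 100 * po,
                          degenerate = TRUE), class = "agreement_result"))
  }
  kap <- (po - pe) / (1 - pe)
  # Fleiss, Cohen & Everitt large-sample variance of kappa-hat
  ri <- rowSums(p); ci <- colSums(p)
  t1 <- sum(vapply(1:2, function(i) p[i, i] * (1 - (ri[i] + ci[i]) * (1 - kap))^2,
                   numeric(1)))
  t2 <- (1 - kap)^2 * sum(vapply(1:2, function(i) sum(vapply(1:2, function(j)
    if (i == j) 0 else p[i, j] * (ci[i] + ri[j])^2, numeric(1))), numeric(1)))
  t3 <- (kap - pe * (1 - kap))^2
  var_k <- (t1 + t2 - t3) / (n * (1 - pe)^2)
  se <- sqrt(max(0, var_k))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  structure(list(kappa = kap,
                 kappa_ci_low = max(-1, kap - z * se),
                 kappa_ci_high = min(1, kap + z * se),
                 se = se, percent_agreement = 100 * po,
                 degenerate = FALSE),
            class = "agreement_result")
}

#' @export
print.agreement_result <- function(x, ...) {
  cat(sprintf("kappa = %.3f (95%% CI %.3f to %.3f), agreement %.1f%%%s\n",
              x$kappa, x$kappa_ci_low, x$kappa_ci_high, x$percent_agreement,
              if (x$degenerate) " [degenerate: single category]" else ""))
  invisible(x)
}

#' Percent agreement between two graders
#'
#' @param g1,g2 Equal-length vectors.
#' @return 100 x (matches / n).
#' @export
percent_agreement <- function(g1, g2) {
  if (length(g1) != length(g2)) stop("grader vectors must have equal length")
  if (!length(g1)) stop("empty grader vectors")
  100 * mean(g1 == g2)
}

#' Spearman rank correlation
#'
#' Pearson correlation of mid-ranks (average ranks on ties), as used to
#' compare semi-automatically quantified GA areas between observers.
#'
#' @param x,y Equal-length numeric vectors, length >= 3.
#' @return Spearman's r.
#' @export
spearman_r <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3L) stop("need at least 3 observations")
  stats::cor(x, y, method = "spearman")
}
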