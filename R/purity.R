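# Tumour purity estimation from VAFs, and the three-feature exclusion
# rule for post-treatment samples.

#' Estimate tumour purity from retained variant allele fractions
#'
#' Each variant's VAF is inverted to the purity it would imply were the
#' mutation clonal and present on one copy:
#' `p = 2 v / (1 + 2 v - v * cn)` (which reduces to `2 v` for diploid
#' loci). The clonal cluster then shows up as the upper mode of the
#' kernel density of these candidate purities; subclonal mutations
#' produce lower modes, which are ignored provided the upper mode has at
#' least `mode_height` of the maximum density.
#'
#' @param vaf Numeric vector of tumour VAFs of retained somatic variants.
#' @param total_cn Local total copy numbers (default 2, scalar recycled).
#' @param min_variants Below this many variants the estimate is refused
#'   and `NA` returned with a warning (default 20).
#' @param mode_height Minimum relative density height for a mode to be
#'   eligible (default 0.25).
#' @param bw Kernel bandwidth on the candidate-purity scale (default
#'   0.04; a fixed moderate bandwidth keeps the clonal mode separate
#'   from subclonal mass, which plug-in bandwidths tend to smear).
#' @return Purity estimate in (0, 1], or `NA_real_`.
#' @export
estimate_purity <- function(vaf, total_cn = 2, min_variants = 20L,
                            mode_height = 0.25, bw = 0.04) {
  keep <- !is.na(vaf) & vaf > 0
  vaf <- vaf[keep]
  total_cn <- rep_len(total_cn, length(keep))[keep]
  if (length(vaf) < min_variants) {
    warning("fewer than ", min_variants,
            " variants: purity not estimable")
    return(NA_real_)
  }
  cand <- 2 * vaf / (1 + 2 * vaf - vaf * total_cn)
  cand <- pmin(pmax(cand, 1e-3), 1.2)
  if (stats::sd(cand) < 1e-9) {
    return(min(1, cand[1L]))
  }
  d <- stats::density(cand, bw = bw, n = 512L, from = 0, to = 1.2)
  y <- d$y
  peaks <- which(diff(sign(diff(y))) == -2) + 1L
  if (!length(peaks)) peaks <- which.max(y)
  eligible <- peaks[y[peaks] >= mode_height * max(y[peaks])]
  mode_x <- d$x[max(eligible)]
  # refine with the local median of the clonal cluster around the mode;
  # the raw mode sits left of the cluster center because the VAF->purity
  # inversion is convex for copy number > 2
  local <- cand[abs(cand - mode_x) <= 3 * bw]
  if (length(local)) mode_x <- stats::median(local)
  min(1, mode_x)
}

#' Assess the post-treatment exclusion rule
#'
#' Post-treatment samples are excluded when at least `k_required` of
#' three features fire: a large purity drop
#' (`purity_post < drop_fraction * purity_pre`), low histological tumour
#' content (`< histology_min`, strict, so exactly 20% does not fire), and
#' a low post-treatment mutation burden
#' (`post_burden < burden_drop * pre_burden`).
#'
#' @param patient Patient identifier.
#' @param purity_pre,purity_post Purity estimates (`NA` allowed; a
#'   missing estimate cannot fire the purity feature).
#' @param histology_content_post Histological tumour content in `[0, 1]`,
#'   or `NA`.
#' @param pre_burden,post_burden Retained mutation counts.
#' @param drop_fraction,histology_min,burden_drop Feature thresholds
#'   (defaults 0.5, 0.20, 0.2).
#' @param k_required How many features must fire to exclude (default 2).
#' @return List of class `qc_decision`: `patient`, the inputs, `reasons`
#'   (character subset of `purity_drop`, `low_histology`, `low_burden`)
#'   and `excluded`.
#' @export
assess_exclusion <- function(patient, purity_pre, purity_post,
                             histology_content_post,
                             pre_burden, post_burden,
                             drop_fraction = 0.5, histology_min = 0.20,
                             burden_drop = 0.2, k_required = 2L) {
  reasons <- character(0)
  if (!is.na(purity_pre) && !is.na(purity_post) &&
      purity_post < drop_fraction * purity_pre) {
    reasons <- c(reasons, "purity_drop")
  }
  if (!is.na(histology_content_post) &&
      histology_content_post < histology_min) {
    reasons <- c(reasons, "low_histology")
  }
  if (post_burden < burden_drop * pre_burden) {
    reasons <- c(reasons, "low_burden")
  }
  structure(list(patient = patient, purity_pre = purity_pre,
                 purity_post = purity_post,
                 histology_content_post = histology_content_post,
                 pre_burden = pre_burden, post_burden = post_burden,
                 reasons = reasons,
                 excluded = length(reasons) >= k_required),
            class = "qc_decision")
}
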