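# Empirical somatic-variant filtering with paired-sample relaxation.
#
# Seven rules are evaluated independently per tumour sample and recorded
# as audit flags; a variant passes for a sample iff no flag is raised.
# For paired pre/post analysis the minimum-alt-reads and minimum-VAF rules
# (R3, R4) are relaxed so that only one member of the pair must pass them.

#' Somatic filter thresholds
#'
#' @param min_normal_depth Minimum normal read depth (default 10; fewer
#'   reads fails the variant).
#' @param min_tumour_depth Minimum tumour read depth (default 8).
#' @param max_normal_vaf Normal VAF at or above this fails (default 0.03).
#' @param min_alt_reads Fewer than this many alt reads fails (default 4).
#' @param min_tumour_vaf_ff Fresh-frozen tumour VAF at or below this fails
#'   (default 0.02; the boundary itself fails).
#' @param min_tumour_vaf_ffpe FFPE minimum tumour VAF (default 0.05; the
#'   boundary itself passes, being a stated minimum).
#' @param max_population_freq Population allele frequency at or above this
#'   fails (default 0.01).
#' @param min_mappability Mappability below this fails (default 0.8).
#' @return List of class `filter_params`.
#' @export
filter_params <- function(min_normal_depth = 10L, min_tumour_depth = 8L,
                          max_normal_vaf = 0.03, min_alt_reads = 4L,
                          min_tumour_vaf_ff = 0.02,
                          min_tumour_vaf_ffpe = 0.05,
                          max_population_freq = 0.01,
                          min_mappability = 0.8) {
  structure(as.list(environment()), class = "filter_params")
}

FILTER_RULES <- c("R1_depth", "R2_normal_vaf", "R3_min_alt", "R4_min_vaf",
                  "R5_popfreq", "R6_pon", "R7_mappability")

#' Apply the empirical somatic filter rules
#'
#' Evaluates, per tumour sample (`pre` and `post`), the seven rules:
#' R1 insufficient depth (normal depth below `min_normal_depth` OR tumour
#' depth below `min_tumour_depth`); R2 normal VAF at/above
#' `max_normal_vaf`; R3 fewer than `min_alt_reads` alt reads; R4 tumour
#' VAF at/below the preservation-specific minimum; R5 population
#' frequency at/above `max_population_freq`; R6 panel-of-normals hit;
#' R7 segmental-duplication region or mappability below
#' `min_mappability`. Evaluation is pure: flags depend only on the input.
#'
#' @param variants Variant table from [read_variants()].
#' @param params A [filter_params()].
#' @param preservation `"ff"` or `"ffpe"` (selects the R4 threshold and
#'   boundary semantics).
#' @return The table with logical columns `pre_<rule>`, `post_<rule>`, and
#'   `pre_pass` / `post_pass`.
#' @export
apply_somatic_filters <- function(variants, params = filter_params(),
                                  preservation = c("ff", "ffpe")) {
  preservation <- match.arg(preservation)
  df <- variants
  if (is.null(df$pre_vaf)) df <- add_vafs(df)
  shared_flags <- function() {
    cbind(
      R2_normal_vaf = df$normal_vaf >= params$max_normal_vaf,
      R5_popfreq = df$popfreq >= params$max_population_freq,
      R6_pon = df$pon,
      R7_mappability = df$segdup | df$mappability < params$min_mappability)
  }
  vaf_fails <- function(vaf) {
    if (preservation == "ff") vaf <= params$min_tumour_vaf_ff
    else vaf < params$min_tumour_vaf_ffpe
  }
  for (s in c("pre", "post")) {
    flags <- cbind(
      R1_depth = df$normal_depth < params$min_normal_depth |
        df[[paste0(s, "_depth")]] < params$min_tumour_depth,
      shared_flags(),
      R3_min_alt = df[[paste0(s, "_alt")]] < params$min_alt_reads,
      R4_min_vaf = vaf_fails(df[[paste0(s, "_vaf")]]))
    flags <- flags[, FILTER_RULES, drop = FALSE]
    colnames(flags) <- paste0(s, "_", FILTER_RULES)
    df <- cbind(df, flags)
    df[[paste0(s, "_pass")]] <- rowSums(flags) == 0L
  }
  df
}

#' Retain variants under the paired-sample relaxation
#'
#' A variant is retained for the pre/post pair iff both samples are clean
#' on R1, R2, R5, R6 and R7 and at least one of the two samples is clean
#' on both R3 (minimum alt reads) and R4 (minimum VAF). The retained set
#' is therefore a superset of requiring both samples to pass everything.
#'
#' @param flagged Output of [apply_somatic_filters()] (must contain the
#'   per-rule flag columns).
#' @return The table with a logical `retained` column.
#' @export
apply_pair_relaxation <- function(flagged) {
  need <- c(paste0("pre_", FILTER_RULES), paste0("post_", FILTER_RULES))
  if (!all(need %in% names(flagged))) {
    stop("run apply_somatic_filters() before apply_pair_relaxation()")
  }
  strict <- c("R1_depth", "R2_normal_vaf", "R5_popfreq", "R6_pon",
              "R7_mappability")
  relaxed <- c("R3_min_alt", "R4_min_vaf")
  strict_ok <- rowSums(flagged[paste0("pre_", strict)]) == 0L &
    rowSums(flagged[paste0("post_", strict)]) == 0L
  pre_ok <- rowSums(flagged[paste0("pre_", relaxed)]) == 0L
  post_ok <- rowSums(flagged[paste0("post_", relaxed)]) == 0L
  flagged$retained <- strict_ok & (pre_ok | post_ok)
  flagged
}

#' Filter a paired variant table end to end
#'
#' Convenience wrapper: [apply_somatic_filters()] followed by
#' [apply_pair_relaxation()], returning only retained variants.
#'
#' @inheritParams apply_somatic_filters
#' @return The retained subset, with flag columns.
#' @export
filter_variants <- function(variants, params = filter_params(),
                            preservation = "ff") {
  flagged <- apply_pair_relaxation(
    apply_somatic_filters(variants, params, preservation))
  flagged[flagged$retained, , drop = FALSE]
}
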