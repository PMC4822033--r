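# Cohort-level clinical coding, association statistics and summary tables.

#' Binary pathological response from the Mandard grade
#'
#' Mandard tumour-regression grades 2-3 define responders, grades 4-5
#' non-responders (grade 1, complete response, also maps to responder;
#' such patients have no analysable post-treatment tumour).
#'
#' @param grade Integer grade(s) in 1..5.
#' @return Logical: `TRUE` for responders. Vectorised.
#' @export
response_from_mandard <- function(grade) {
  if (any(is.na(grade)) || any(grade < 1L | grade > 5L)) {
    stop("Mandard grade must be in 1..5")
  }
  grade <= 3L
}

#' Exact test of evolution category against response
#'
#' Freeman-Halton (Fisher's exact) test on the 2x3 response-by-category
#' table, two-sided by probability ordering over all tables with the
#' observed margins.
#'
#' @param counts 2x3 matrix of nonnegative integers (rows: responder,
#'   non-responder; columns: stable, polyclonal, bottleneck).
#' @return List: `p_value`, `table`.
#' @export
evolution_response_test <- function(counts) {
  counts <- as.matrix(counts)
  stopifnot(nrow(counts) == 2L)
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0)) {
    stop("not computable: a table margin is zero")
  }
  list(p_value = stats::fisher.test(counts)$p.value, table = counts)
}

#' Paired test of mutation burden change after therapy
#'
#' Wilcoxon signed-rank test of post- versus pre-treatment burdens
#' (exact for n <= 25 without zero-differences or ties), plus the two
#' medians.
#'
#' @param pre_burdens,post_burdens Paired positive counts, `n >= 5`.
#' @return List: `p_value`, `median_pre`, `median_post`, `n`.
#' @export
burden_change_test <- function(pre_burdens, post_burdens) {
  stopifnot(length(pre_burdens) == length(post_burdens))
  n <- length(pre_burdens)
  if (n < 5L) stop("not computable: fewer than 5 pairs")
  d <- post_burdens - pre_burdens
  p <- if (all(d == 0)) 1 else {
    suppressWarnings(
      stats::wilcox.test(post_burdens, pre_burdens, paired = TRUE,
                         exact = n <= 25L && !any(d == 0) &&
                           !anyDuplicated(abs(d[d != 0]))))$p.value
  }
  list(p_value = p, median_pre = stats::median(pre_burdens),
       median_post = stats::median(post_burdens), n = n)
}

#' T>A fraction versus response
#'
#' Two-sample Wilcoxon rank-sum test of the pre-treatment T>A mutation
#' fraction between responders and non-responders, with group medians
#' and the odds ratio from the 2x2 of response against being above the
#' cohort median (Haldane-Anscombe 0.5 correction when a cell is zero).
#'
#' @param ta_fractions Per-patient pre-treatment T>A proportions.
#' @param responder Logical response per patient.
#' @return List: `p_value`, `median_responder`, `median_non_responder`,
#'   `odds_ratio`, `haldane_corrected`.
#' @export
ta_response_test <- function(ta_fractions, responder) {
  stopifnot(length(ta_fractions) == length(responder))
  if (!any(responder) || !any(!responder)) {
    stop("not computable: a response group is empty")
  }
  x <- ta_fractions[responder]; y <- ta_fractions[!responder]
  p <- suppressWarnings(stats::wilcox.test(x, y))$p.value
  med <- stats::median(ta_fractions)
  above <- ta_fractions > med
  tab <- table(factor(responder, c(TRUE, FALSE)),
               factor(above, c(TRUE, FALSE)))
  corrected <- any(tab == 0)
  if (corrected) tab <- tab + 0.5
  or <- (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
  list(p_value = p, median_responder = stats::median(x),
       median_non_responder = stats::median(y), odds_ratio = or,
       haldane_corrected = corrected)
}

#' Correlation of patient age with the C>T mutation fraction
#'
#' Spearman rank correlation by default (robust on the skewed fraction
#' scale); Pearson available by flag.
#'
#' @param ages Patient ages (years).
#' @param ct_fractions Pre-treatment C>T proportions.
#' @param method `"spearman"` (default) or `"pearson"`.
#' @return List: `estimate`, `p_value`, `method`.
#' @export
age_ct_correlation <- function(ages, ct_fractions,
                               method = c("spearman", "pearson")) {
  method <- match.arg(method)
  stopifnot(length(ages) == length(ct_fractions))
  if (length(ages) < 5L) stop("not computable: fewer than 5 pairs")
  if (stats::sd(ages) == 0 || stats::sd(ct_fractions) == 0) {
    stop("not computable: constant vector")
  }
  ct <- suppressWarnings(stats::cor.test(ages, ct_fractions, method = method))
  list(estimate = unname(ct$estimate), p_value = ct$p.value, method = method)
}

#' Signature change versus response
#'
#' Two-sided Fisher's exact test on the 2x2 of predominant-signature
#' change against response.
#'
#' @param change Logical per patient (`NA` dropped with its patient).
#' @param responder Logical per patient.
#' @return List: `p_value`, `table`.
#' @export
signature_change_response_test <- function(change, responder) {
  keep <- !is.na(change) & !is.na(responder)
  change <- change[keep]; responder <- responder[keep]
  tab <- table(factor(responder, c(TRUE, FALSE)),
               factor(change, c(TRUE, FALSE)))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("not computable: degenerate margin")
  }
  list(p_value = stats::fisher.test(tab)$p.value, table = tab)
}

#' Assemble the cohort summary report
#'
#' Produces the per-patient master table (response, evolution category,
#' burdens, spectra and signature labels, shared-SCNA fraction, per-gene
#' driver trajectories), the cohort association statistics, a listing of
#' post-treatment-only driver SNVs and a log of all thresholds used. A
#' Benjamini-Hochberg column accompanies the nominal p-values for
#' transparency; claims rest on the nominal values.
#'
#' @param per_patient Data frame with one row per patient: `case`,
#'   `responder`, `category`, `burden_pre`, `burden_post`,
#'   `ta_fraction_pre`, `ct_fraction_pre`, `age`, `vaf_cv`,
#'   `signature_pre`, `signature_post`, `scna_shared` (NA allowed).
#' @param driver_trajectories Optional data frame `case`, `gene`,
#'   `trajectory`, `post_vaf` for driver mutations.
#' @param focal_events Optional annotation table of focal copy number
#'   events (`case`, `gene`, `direction`, `sample`); events with
#'   `sample == "post_only"` are listed in the report.
#' @param thresholds An [evolution_thresholds()] (logged).
#' @return List of class `cohort_report`: `per_patient`, `stats` (test
#'   name, p, BH-adjusted p, details), `post_only_drivers`,
#'   `post_only_focal_events`, `thresholds_log`.
#' @export
build_report <- function(per_patient, driver_trajectories = NULL,
                         focal_events = NULL,
                         thresholds = evolution_thresholds()) {
  pp <- per_patient
  analysable <- pp$category != "excluded"
  stats_rows <- list()
  addstat <- function(name, p, detail) {
    stats_rows[[length(stats_rows) + 1L]] <<-
      data.frame(test = name, p_value = p, detail = detail)
  }

  tab23 <- table(factor(pp$responder[analysable], c(TRUE, FALSE)),
                 factor(pp$category[analysable],
                        c("stable", "polyclonal", "bottleneck")))
  if (all(rowSums(tab23) > 0) && all(colSums(tab23) > 0)) {
    ev <- evolution_response_test(tab23)
    addstat("evolution_vs_response", ev$p_value,
            paste(as.vector(t(tab23)), collapse = ","))
  }
  bc <- burden_change_test(pp$burden_pre, pp$burden_post)
  addstat("burden_change", bc$p_value,
          sprintf("medians %g -> %g", bc$median_pre, bc$median_post))
  ta <- ta_response_test(pp$ta_fraction_pre, pp$responder)
  addstat("ta_vs_response", ta$p_value,
          sprintf("medians %.3f vs %.3f, OR %.2f", ta$median_responder,
                  ta$median_non_responder, ta$odds_ratio))
  ac <- age_ct_correlation(pp$age, pp$ct_fraction_pre)
  addstat("age_ct_correlation", ac$p_value,
          sprintf("rho %.3f", ac$estimate))
  chg <- signature_change(pp$signature_pre, pp$signature_post)
  chg[pp$category == "excluded"] <- NA
  sc <- tryCatch(signature_change_response_test(chg, pp$responder),
                 error = function(e) NULL)
  if (!is.null(sc)) {
    addstat("signature_change_vs_response", sc$p_value,
            paste(as.vector(sc$table), collapse = ","))
  }
  stats_df <- do.call(rbind, stats_rows)
  stats_df$p_bh <- stats::p.adjust(stats_df$p_value, "BH")

  post_only <- NULL
  if (!is.null(driver_trajectories)) {
    post_only <- driver_trajectories[
      driver_trajectories$trajectory == "post_only", , drop = FALSE]
  }
  post_focal <- NULL
  if (!is.null(focal_events)) {
    post_focal <- focal_events[focal_events$sample == "post_only", ,
                               drop = FALSE]
  }
  structure(list(per_patient = pp, stats = stats_df,
                 post_only_drivers = post_only,
                 post_only_focal_events = post_focal,
                 thresholds_log = unclass(thresholds)),
            class = "cohort_report")
}

#' Write a cohort report to TSV files
#'
#' @param report A `cohort_report`.
#' @param out_dir Output directory.
#' @return `out_dir`, invisibly.
#' @export
write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_tsv(report$per_patient, file.path(out_dir, "per_patient.tsv"))
  write_tsv(report$stats, file.path(out_dir, "cohort_stats.tsv"))
  if (!is.null(report$post_only_drivers)) {
    write_tsv(report$post_only_drivers,
              file.path(out_dir, "post_only_drivers.tsv"))
  }
  if (!is.null(report$post_only_focal_events)) {
    write_tsv(report$post_only_focal_events,
              file.path(out_dir, "post_only_focal_events.tsv"))
  }
  th <- report$thresholds_log
  writeLines(paste0(names(th), ": ", vapply(th, format, character(1))),
             file.path(out_dir, "thresholds.log"))
  invisible(out_dir)
}
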