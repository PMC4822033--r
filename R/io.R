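# Reading and writing cohort files.
#
# Per patient the writer emits a VCF 4.2 (three genotype columns NORMAL /
# PRE / POST with DP and AD FORMAT fields) plus a flat TSV mirror; the
# cohort gains a clinical TSV, an arm coordinate TSV, per-patient truth
# and SCNA tables. `read_variants()` accepts either format.

VARIANT_TSV_COLS <- c("chrom", "pos", "ref", "alt", "gene", "context96",
                      "total_cn",
                      "normal_depth", "normal_alt", "pre_depth", "pre_alt",
                      "post_depth", "post_alt",
                      "popfreq", "pon", "segdup", "mappability")

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

read_tsv <- function(path) {
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                    colClasses = NA, check.names = FALSE)
}

variant_vcf_lines <- function(variants) {
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=neoclone-synthetic-cohort",
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene symbol\">",
    "##INFO=<ID=CTX96,Number=1,Type=Integer,Description=\"Trinucleotide channel index 1-96\">",
    "##INFO=<ID=TCN,Number=1,Type=Integer,Description=\"Local total copy number in tumour\">",
    "##INFO=<ID=POPFREQ,Number=1,Type=Float,Description=\"Max population allele frequency\">",
    "##INFO=<ID=PON,Number=0,Type=Flag,Description=\"Seen in panel of normals\">",
    "##INFO=<ID=SEGDUP,Number=0,Type=Flag,Description=\"Segmental duplication region\">",
    "##INFO=<ID=MAPP,Number=1,Type=Float,Description=\"Mappability score\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Total read depth\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Ref and alt read depths\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "NORMAL", "PRE", "POST", sep = "\t"))
  if (!nrow(variants)) return(header)
  info <- paste0("GENE=", variants$gene, ";CTX96=", variants$context96,
                 ";TCN=", variants$total_cn,
                 ";POPFREQ=", format(variants$popfreq, trim = TRUE),
                 ifelse(variants$pon, ";PON", ""),
                 ifelse(variants$segdup, ";SEGDUP", ""),
                 ";MAPP=", format(variants$mappability, trim = TRUE))
  fmt <- function(dp, alt) paste0(dp, ":", dp - alt, ",", alt)
  body <- paste(variants$chrom, variants$pos, ".", variants$ref,
                variants$alt, ".", ".", info, "DP:AD",
                fmt(variants$normal_depth, variants$normal_alt),
                fmt(variants$pre_depth, variants$pre_alt),
                fmt(variants$post_depth, variants$post_alt), sep = "\t")
  c(header, body)
}

#' Write a simulated cohort to disk
#'
#' Emits, per patient, `case<N>.vcf` and `case<N>.variants.tsv` (identical
#' content), `case<N>.truth.tsv` and `case<N>.logr.tsv` (per-probe logR,
#' pre and post columns), plus cohort-level `clinical.tsv` (Case, Age,
#' Sex, T, N, PathR, Mandard, Histology), `arms.tsv` and
#' `arm_events_truth.tsv`.
#'
#' @param cohort A `sim_cohort` from [simulate_cohort()].
#' @param out_dir Output directory (created if missing).
#' @return `out_dir`, invisibly.
#' @export
write_cohort <- function(cohort, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  write_tsv(cohort$clinical, file.path(out_dir, "clinical.tsv"))
  write_tsv(cohort$arms, file.path(out_dir, "arms.tsv"))
  ev <- list()
  for (p in cohort$patients) {
    stem <- file.path(out_dir, paste0("case", p$case))
    writeLines(variant_vcf_lines(p$variants), paste0(stem, ".vcf"))
    write_tsv(p$variants, paste0(stem, ".variants.tsv"))
    tr <- p$truth
    tr$case <- p$case
    tr$scenario <- p$scenario
    tr$purity_pre <- p$purity_pre
    tr$purity_post <- p$purity_post
    write_tsv(tr, paste0(stem, ".truth.tsv"))
    if (!is.null(p$scna)) {
      ev[[length(ev) + 1L]] <- rbind(
        cbind(case = p$case, sample = "pre", p$scna$events_pre),
        cbind(case = p$case, sample = "post", p$scna$events_post))
    }
  }
  if (length(ev)) {
    write_tsv(do.call(rbind, ev), file.path(out_dir, "arm_events_truth.tsv"))
  }
  invisible(out_dir)
}

empty_variants <- function() {
  df <- data.frame(chrom = character(), pos = integer(), ref = character(),
                   alt = character(), gene = character(),
                   context96 = integer(), total_cn = integer(),
                   normal_depth = integer(), normal_alt = integer(),
                   pre_depth = integer(), pre_alt = integer(),
                   post_depth = integer(), post_alt = integer(),
                   popfreq = numeric(), pon = logical(), segdup = logical(),
                   mappability = numeric())
  add_vafs(df)
}

add_vafs <- function(df) {
  safe_div <- function(a, d) ifelse(d > 0, a / d, 0)
  df$normal_vaf <- safe_div(df$normal_alt, df$normal_depth)
  df$pre_vaf <- safe_div(df$pre_alt, df$pre_depth)
  df$post_vaf <- safe_div(df$post_alt, df$post_depth)
  df
}

info_field <- function(info, key, default = NA_character_) {
  pat <- paste0("(?:^|;)", key, "=([^;]*)")
  m <- regmatches(info, regexec(pat, info))
  vapply(m, function(x) if (length(x) == 2L) x[2L] else default, character(1))
}

info_flag <- function(info, key) {
  grepl(paste0("(?:^|;)", key, "(?:;|$)"), info)
}

#' Read a paired variant table
#'
#' Reads either the flat TSV schema (`chrom`, `pos`, `ref`, `alt`, `gene`,
#' `context96`, `{normal,pre,post}_{depth,alt}`, plus optional annotation
#' columns) or a VCF 4.2 with `DP`/`AD` FORMAT fields and NORMAL/PRE/POST
#' sample columns. Multi-allelic VCF rows are split into one record per
#' alternate allele; VAFs are computed per sample.
#'
#' @param path File path.
#' @param format `"tsv"` or `"vcf"`; guessed from the extension by default.
#' @return Data frame with one row per (site, alt allele) and per-sample
#'   `*_depth`, `*_alt`, `*_vaf` columns.
#' @export
read_variants <- function(path, format = c("auto", "tsv", "vcf")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.vcf(\\.gz)?$", path)) "vcf" else "tsv"
  }
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "tsv") {
    df <- read_tsv(path)
    need <- setdiff(c("chrom", "pos", "ref", "alt",
                      "normal_depth", "normal_alt", "pre_depth", "pre_alt",
                      "post_depth", "post_alt"), names(df))
    if (length(need)) {
      stop("variant TSV is missing required columns: ",
           paste(need, collapse = ", "))
    }
    if (!nrow(df)) return(empty_variants())
    for (col in c("gene", "context96", "total_cn", "popfreq", "pon",
                  "segdup", "mappability")) {
      if (is.null(df[[col]])) {
        df[[col]] <- switch(col, gene = NA_character_,
                            context96 = NA_integer_, total_cn = 2L,
                            popfreq = 0, pon = FALSE, segdup = FALSE,
                            mappability = 1)
      }
    }
    df$chrom <- as.character(df$chrom)
    bad <- which(df$normal_alt > df$normal_depth | df$pre_alt > df$pre_depth |
                   df$post_alt > df$post_depth | df$pos < 1)
    if (length(bad)) {
      stop("malformed variant row (alt > depth or pos < 1) at line ",
           bad[1L] + 1L)
    }
    return(add_vafs(df[VARIANT_TSV_COLS]))
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  if (!nrow(fix)) return(empty_variants())
  dp <- vcfR::extract.gt(v, "DP", as.numeric = TRUE)
  ad <- vcfR::extract.gt(v, "AD")
  samples <- colnames(dp)
  need <- setdiff(c("NORMAL", "PRE", "POST"), samples)
  if (length(need)) {
    stop("VCF is missing sample columns: ", paste(need, collapse = ", "))
  }
  rows <- list()
  for (i in seq_len(nrow(fix))) {
    alts <- strsplit(fix$ALT[i], ",", fixed = TRUE)[[1L]]
    info <- fix$INFO[i]
    for (a in seq_along(alts)) {
      rec <- data.frame(
        chrom = fix$CHROM[i], pos = as.integer(fix$POS[i]),
        ref = fix$REF[i], alt = alts[a],
        gene = info_field(info, "GENE"),
        context96 = as.integer(info_field(info, "CTX96")),
        total_cn = as.integer(info_field(info, "TCN", "2")),
        popfreq = as.numeric(info_field(info, "POPFREQ", "0")),
        pon = info_flag(info, "PON"),
        segdup = info_flag(info, "SEGDUP"),
        mappability = as.numeric(info_field(info, "MAPP", "1")))
      for (s in c("NORMAL", "PRE", "POST")) {
        adv <- as.integer(strsplit(ad[i, s], ",", fixed = TRUE)[[1L]])
        if (length(adv) != length(alts) + 1L) {
          stop("malformed AD field at VCF record ", i, " sample ", s)
        }
        pre <- tolower(ifelse(s == "NORMAL", "normal", s))
        rec[[paste0(pre, "_depth")]] <- as.integer(dp[i, s])
        rec[[paste0(pre, "_alt")]] <- adv[a + 1L]
      }
      rows[[length(rows) + 1L]] <- rec
    }
  }
  df <- do.call(rbind, rows)
  df <- df[VARIANT_TSV_COLS]
  add_vafs(df)
}

#' Read a cohort directory written by [write_cohort()]
#'
#' @param dir Cohort directory.
#' @return List with `clinical`, `arms`, and per-patient `variants`,
#'   `truth` and `arm events` tables keyed by case number.
#' @export
read_cohort <- function(dir) {
  clinical <- read_tsv(file.path(dir, "clinical.tsv"))
  arms <- read_tsv(file.path(dir, "arms.tsv"))
  cases <- clinical$Case
  variants <- lapply(cases, function(cs) {
    read_variants(file.path(dir, paste0("case", cs, ".variants.tsv")))
  })
  truth <- lapply(cases, function(cs) {
    read_tsv(file.path(dir, paste0("case", cs, ".truth.tsv")))
  })
  names(variants) <- names(truth) <- cases
  ev_path <- file.path(dir, "arm_events_truth.tsv")
  events <- if (file.exists(ev_path)) read_tsv(ev_path) else NULL
  list(clinical = clinical, arms = arms, variants = variants,
       truth = truth, arm_events = events)
}
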