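# -- 96-context conventions ---------------------------------------------------
# Substitutions are recorded on the pyrimidine strand. The 96 channels are
# ordered alphabetically by substitution class (C>A, C>G, C>T, T>A, T>C, T>G),
# then by 5' flanking base (A, C, G, T), then by 3' flanking base.

SUB_CLASSES <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
BASES <- c("A", "C", "G", "T")

.complement <- c(A = "T", C = "G", G = "C", T = "A")

#' Names of the 96 trinucleotide channels
#'
#' Channel `(k - 1) %/% 16 + 1` gives the substitution class,
#' the remainder encodes the 5' and 3' flanking bases. Names follow the
#' usual `"A[C>T]G"` convention.
#'
#' @return Character vector of length 96.
#' @export
channel_names <- function() {
  out <- character(96)
  k <- 1L
  for (cls in SUB_CLASSES) {
    for (fp in BASES) {
      for (tp in BASES) {
        out[k] <- paste0(fp, "[", cls, "]", tp)
        k <- k + 1L
      }
    }
  }
  out
}

#' Map a single-base substitution with flanking bases to its 96-channel index
#'
#' Purine-reference substitutions are reverse-complemented onto the
#' pyrimidine strand, so e.g. `G>A` in `C_T` context lands in the same
#' channel as `C>T` in `A_G` context.
#'
#' @param ref,alt Reference and alternate bases (single characters).
#' @param five_prime,three_prime Flanking bases on the same strand as `ref`.
#' @return Integer channel index in 1..96. Vectorised.
#' @export
context_channel <- function(ref, alt, five_prime, three_prime) {
  ref <- toupper(ref); alt <- toupper(alt)
  five_prime <- toupper(five_prime); three_prime <- toupper(three_prime)
  n <- max(length(ref), length(alt), length(five_prime), length(three_prime))
  ref <- rep_len(ref, n); alt <- rep_len(alt, n)
  five_prime <- rep_len(five_prime, n); three_prime <- rep_len(three_prime, n)
  ok <- ref %in% BASES & alt %in% BASES &
    five_prime %in% BASES & three_prime %in% BASES & ref != alt
  if (!all(ok)) {
    stop("invalid base or ref == alt in context_channel()")
  }
  flip <- ref %in% c("A", "G")
  if (any(flip)) {
    new_fp <- ifelse(flip, .complement[three_prime], five_prime)
    new_tp <- ifelse(flip, .complement[five_prime], three_prime)
    ref <- ifelse(flip, .complement[ref], ref)
    alt <- ifelse(flip, .complement[alt], alt)
    five_prime <- new_fp
    three_prime <- new_tp
  }
  cls <- match(paste0(ref, ">", alt), SUB_CLASSES)
  fp <- match(five_prime, BASES)
  tp <- match(three_prime, BASES)
  as.integer((cls - 1L) * 16L + (fp - 1L) * 4L + tp)
}

#' Tabulate a mutation spectrum
#'
#' Counts single-nucleotide variants over the 96 trinucleotide channels and
#' the collapsed 6 substitution classes. Records without a context channel
#' (e.g. indels) are skipped and reported in the `n_skipped` attribute.
#'
#' @param variants Data frame with a `context96` column of channel indices
#'   (1..96, `NA` for non-SNVs), or a bare vector of channel indices.
#' @return List of class `spectrum` with `counts96` (named length-96 vector),
#'   `counts6` (named length-6 vector) and attribute `n_skipped`.
#' @export
spectrum <- function(variants) {
  ch <- if (is.data.frame(variants)) variants$context96 else variants
  ch <- as.integer(ch)
  skipped <- sum(is.na(ch))
  ch <- ch[!is.na(ch)]
  if (length(ch) && (min(ch) < 1L || max(ch) > 96L)) {
    stop("context channel out of range 1..96")
  }
  counts96 <- tabulate(ch, nbins = 96L)
  names(counts96) <- channel_names()
  counts6 <- collapse6(counts96)
  structure(list(counts96 = counts96, counts6 = counts6),
            n_skipped = skipped, class = "spectrum")
}

#' Collapse a 96-channel vector onto the 6 substitution classes
#'
#' @param counts96 Numeric vector of length 96 in channel order.
#' @return Named numeric vector of length 6.
#' @export
collapse6 <- function(counts96) {
  stopifnot(length(counts96) == 96L)
  out <- vapply(seq_len(6L), function(i) {
    sum(counts96[((i - 1L) * 16L + 1L):(i * 16L)])
  }, numeric(1))
  names(out) <- SUB_CLASSES
  out
}

#' Test for a shift between two mutation spectra
#'
#' Compares two 6-class spectra with either a chi-square test (cohort-level,
#' en-masse comparisons) or Fisher's exact test on the 2x6 table
#' (per-patient comparisons). The exact test is evaluated by the network
#' algorithm when the table total is small, and by Monte-Carlo sampling with
#' a fixed seed above `exact_cap` cells total.
#'
#' @param group_a,group_b `spectrum` objects or length-6 count vectors.
#' @param method `"fisher"` (default) or `"chisq"`.
#' @param exact_cap Largest table total for which the exact test is used
#'   (default 200); larger tables use `1e5` Monte-Carlo draws.
#' @param seed Seed for the Monte-Carlo fallback.
#' @return Two-sided p-value.
#' @export
compare_spectra <- function(group_a, group_b, method = c("fisher", "chisq"),
                            exact_cap = 200L, seed = 1L) {
  method <- match.arg(method)
  a <- if (inherits(group_a, "spectrum")) group_a$counts6 else as.numeric(group_a)
  b <- if (inherits(group_b, "spectrum")) group_b$counts6 else as.numeric(group_b)
  stopifnot(length(a) == 6L, length(b) == 6L)
  if (sum(a) == 0 || sum(b) == 0) {
    stop("not computable: a group has zero total mutations")
  }
  tab <- rbind(a, b)
  keep <- colSums(tab) > 0
  tab <- tab[, keep, drop = FALSE]
  if (ncol(tab) < 2L) return(1)
  if (method == "chisq") {
    p <- suppressWarnings(stats::chisq.test(tab)$p.value)
  } else if (sum(tab) <= exact_cap) {
    p <- stats::fisher.test(tab, workspace = 2e7)$p.value
  } else {
    p <- withr_seed(seed, {
      stats::fisher.test(tab, simulate.p.value = TRUE, B = 1e5)$p.value
    })
  }
  min(1, p)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`.
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Planted mutational signatures used by the synthetic cohort generator
#'
#' Three 96-channel profiles emulating the signature structure seen in
#' oesophageal adenocarcinoma: an ageing-like signature dominated by C>T at
#' CpG dinucleotides with a minor NTT>NGT component, a smoking-like
#' signature dominated by C>A changes, and a third signature combining
#' T>C (especially NTT>NCT) with C>A changes.
#'
#' @return 96 x 3 column-stochastic matrix with columns
#'   `c("aging_CpG_CT", "CA_rich", "TC_CA_mixed")`.
#' @export
planted_signatures <- function() {
  nm <- channel_names()
  sig <- matrix(0, 96L, 3L,
                dimnames = list(nm, c("aging_CpG_CT", "CA_rich", "TC_CA_mixed")))

  cls_of <- rep(SUB_CLASSES, each = 16L)
  fp_of <- rep(rep(BASES, each = 4L), times = 6L)
  tp_of <- rep(BASES, times = 24L)

  # Signature 1: C>T at CpG (3' G) strongly weighted, other C>T weak,
  # plus a NTT>NGT shoulder (T>G with 3' T).
  w <- numeric(96)
  w[cls_of == "C>T" & tp_of == "G"] <- 10
  w[cls_of == "C>T" & tp_of != "G"] <- 1.2
  w[cls_of == "T>G" & tp_of == "T"] <- 2.5
  w[cls_of == "T>C"] <- w[cls_of == "T>C"] + 0.3
  sig[, 1L] <- w / sum(w)

  # Signature 2: C>A rich with mild 5' preference for A/C.
  w <- numeric(96)
  w[cls_of == "C>A"] <- 4
  w[cls_of == "C>A" & fp_of %in% c("A", "C")] <- 7
  w[cls_of == "C>G"] <- 0.4
  w[cls_of == "T>A"] <- 0.3
  sig[, 2L] <- w / sum(w)

  # Signature 3: T>C (especially NTT>NCT) together with C>A.
  w <- numeric(96)
  w[cls_of == "T>C" & tp_of == "T"] <- 8
  w[cls_of == "T>C" & tp_of != "T"] <- 2
  w[cls_of == "C>A"] <- 2.5
  w[cls_of == "T>G"] <- 0.2
  sig[, 3L] <- w / sum(w)

  sig
}
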