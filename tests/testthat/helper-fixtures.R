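# Shared fixtures: small variant tables built in code.

make_variant_row <- function(normal_depth = 60L, normal_alt = 0L,
                             pre_depth = 100L, pre_alt = 10L,
                             post_depth = 100L, post_alt = 10L,
                             popfreq = 0, pon = FALSE, segdup = FALSE,
                             mappability = 0.95, gene = NA_character_,
                             context96 = 1L, total_cn = 2L,
                             chrom = "1", pos = 1000L) {
  df <- data.frame(chrom = chrom, pos = pos, ref = "C", alt = "A",
                   gene = gene, context96 = context96, total_cn = total_cn,
                   normal_depth = normal_depth, normal_alt = normal_alt,
                   pre_depth = pre_depth, pre_alt = pre_alt,
                   post_depth = post_depth, post_alt = post_alt,
                   popfreq = popfreq, pon = pon, segdup = segdup,
                   mappability = mappability)
  neoclone:::add_vafs(df)
}

# Random variant records spanning all filter-threshold boundaries.
random_variant_table <- function(n, seed) {
  withr::with_seed(seed, {
    df <- data.frame(
      chrom = sample(as.character(1:22), n, TRUE),
      pos = sample.int(1e8, n, TRUE),
      ref = "C", alt = "T",
      gene = NA_character_,
      context96 = sample.int(96L, n, TRUE),
      total_cn = sample(2:4, n, TRUE),
      normal_depth = sample(0:40, n, TRUE),
      pre_depth = sample(0:150, n, TRUE),
      post_depth = sample(0:150, n, TRUE),
      popfreq = sample(c(0, 0.005, 0.01, 0.02, 0.3), n, TRUE),
      pon = sample(c(TRUE, FALSE), n, TRUE, prob = c(0.1, 0.9)),
      segdup = sample(c(TRUE, FALSE), n, TRUE, prob = c(0.1, 0.9)),
      mappability = sample(c(0.5, 0.79, 0.8, 0.81, 1), n, TRUE))
    df$normal_alt <- rbinom(n, df$normal_depth,
                            sample(c(0, 0.01, 0.03, 0.05, 0.5), n, TRUE))
    # mix exact boundary VAFs with random ones
    pre_vaf_target <- sample(c(0, 0.01, 0.02, 0.0201, 0.05, 0.1, 0.5), n, TRUE)
    post_vaf_target <- sample(c(0, 0.01, 0.02, 0.0201, 0.05, 0.1, 0.5), n, TRUE)
    df$pre_alt <- pmin(round(df$pre_depth * pre_vaf_target +
                               sample(0:4, n, TRUE)), df$pre_depth)
    df$post_alt <- pmin(round(df$post_depth * post_vaf_target +
                                sample(0:4, n, TRUE)), df$post_depth)
    neoclone:::add_vafs(df)
  })
}

# Independent brute-force evaluation of the filter + relaxation predicate,
# written directly from the rule statements (not via the package logic).
brute_force_retained <- function(df, params = filter_params(),
                                 preservation = "ff") {
  vapply(seq_len(nrow(df)), function(i) {
    r <- df[i, ]
    nv <- if (r$normal_depth > 0) r$normal_alt / r$normal_depth else 0
    sample_ok_strict <- function(dp) {
      !(r$normal_depth < params$min_normal_depth ||
          dp < params$min_tumour_depth) &&
        !(nv >= params$max_normal_vaf) &&
        !(r$popfreq >= params$max_population_freq) &&
        !r$pon &&
        !(r$segdup || r$mappability < params$min_mappability)
    }
    relaxed_ok <- function(alt, dp) {
      v <- if (dp > 0) alt / dp else 0
      vaf_ok <- if (preservation == "ff") {
        !(v <= params$min_tumour_vaf_ff)
      } else {
        !(v < params$min_tumour_vaf_ffpe)
      }
      !(alt < params$min_alt_reads) && vaf_ok
    }
    sample_ok_strict(r$pre_depth) && sample_ok_strict(r$post_depth) &&
      (relaxed_ok(r$pre_alt, r$pre_depth) ||
         relaxed_ok(r$post_alt, r$post_depth))
  }, logical(1))
}
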