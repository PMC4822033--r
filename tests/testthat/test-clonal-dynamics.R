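# CCFs, clustering, trajectories, sampling-loss and classification.

test_that("ccf_from_vaf inverts the expected-VAF model exactly", {
  expect_equal(as.numeric(ccf_from_vaf(0.5, 1, 2, 1)), 1.0)
  expect_equal(as.numeric(ccf_from_vaf(0.25, 0.5, 2, 1)), 1.0)
  expect_error(ccf_from_vaf(0.5, 0, 2), "purity")

  grid <- withr::with_seed(5, expand.grid(
    ccf = runif(6, 0.05, 1), purity = runif(4, 0.2, 1),
    cn = 1:4, mult = 1:2))
  grid <- grid[grid$mult <= grid$cn, ]
  v <- expected_vaf(grid$ccf, grid$purity, grid$cn, grid$mult)
  back <- ccf_from_vaf(v, grid$purity, grid$cn, grid$mult)
  expect_equal(as.numeric(back), grid$ccf, tolerance = 1e-12)

  clipped <- ccf_from_vaf(0.9, 0.5, 2, 1)
  expect_equal(as.numeric(clipped), 1.5)
  expect_equal(attr(clipped, "n_clipped"), 1L)
})

test_that("clustering inclusion rules and the hypermutator cap hold", {
  mk <- function(pre_depth, post_depth, pre_vaf, post_vaf, gene = NA) {
    data.frame(gene = gene, pre_depth = pre_depth, post_depth = post_depth,
               pre_vaf = pre_vaf, post_vaf = post_vaf,
               pre_alt = round(pre_vaf * pre_depth),
               post_alt = round(post_vaf * post_depth), total_cn = 2L)
  }
  shared_cov <- mk(59L, 61L, 0.2, 0.2)
  expect_equal(select_for_clustering(shared_cov)$inclusion_reason,
               "coverage60")
  rescue <- mk(30L, 30L, 0.20, 0.01)
  expect_equal(select_for_clustering(rescue)$inclusion_reason,
               "low_vaf_rescue")
  lowcov <- mk(30L, 30L, 0.2, 0.2)
  expect_equal(nrow(select_for_clustering(lowcov)), 0L)
  drv <- mk(30L, 30L, 0.2, 0.2, gene = "TP53")
  expect_equal(select_for_clustering(drv, drivers = "TP53")$inclusion_reason,
               "driver")

  big <- withr::with_seed(3, mk(rep(100L, 2000), rep(100L, 2000),
                                runif(2000, 0.1, 0.5),
                                runif(2000, 0.1, 0.5)))
  big$gene[1:3] <- "TP53"
  capped <- select_for_clustering(big, drivers = "TP53",
                                  subsample_cap = 500L, seed = 9)
  expect_equal(nrow(capped), 500L)
  expect_equal(sum(capped$gene == "TP53", na.rm = TRUE), 3L)
})

test_that("binomial-mixture clustering recovers planted clones", {
  deg <- data.frame(pre_depth = rep(100L, 30), post_depth = rep(100L, 30),
                    pre_alt = rep(25L, 30), post_alt = rep(25L, 30),
                    pre_vaf = 0.25, post_vaf = 0.25, total_cn = 2L)
  fit <- cluster_clones(deg, 0.5, 0.5, cluster_params(seed = 1))
  expect_equal(fit$K, 1L)
  expect_equal(fit$clusters$center_pre, 1.0, tolerance = 0.05)

  sim <- withr::with_seed(11, {
    truth <- rbind(
      data.frame(ccf_pre = 1.0, ccf_post = 1.0, n = 200),
      data.frame(ccf_pre = 0.6, ccf_post = 0.05, n = 200))
    do.call(rbind, lapply(seq_len(nrow(truth)), function(i) {
      n <- truth$n[i]
      vp <- expected_vaf(truth$ccf_pre[i], 0.6, 2)
      vq <- expected_vaf(truth$ccf_post[i], 0.6, 2)
      data.frame(clone = i,
                 pre_depth = 100L, post_depth = 100L,
                 pre_alt = rbinom(n, 100, vp), post_alt = rbinom(n, 100, vq),
                 total_cn = 2L)
    }))
  })
  sim$pre_vaf <- sim$pre_alt / sim$pre_depth
  sim$post_vaf <- sim$post_alt / sim$post_depth
  fit1 <- cluster_clones(sim, 0.6, 0.6, cluster_params(seed = 4))
  expect_equal(fit1$K, 2L)
  got <- fit1$clusters[order(fit1$clusters$center_pre, decreasing = TRUE), ]
  expect_lt(abs(got$center_pre[1] - 1.0), 0.1)
  expect_lt(abs(got$center_post[1] - 1.0), 0.1)
  expect_lt(abs(got$center_pre[2] - 0.6), 0.1)
  expect_lt(abs(got$center_post[2] - 0.05), 0.1)
  top_id <- fit1$clusters$cluster[which.max(fit1$clusters$center_post)]
  acc <- mean((fit1$assignment == top_id) == (sim$clone == 1))
  expect_gte(acc, 0.95)

  fit2 <- cluster_clones(sim, 0.6, 0.6, cluster_params(seed = 99))
  expect_equal(fit2$K, fit1$K)
  expect_identical(fit2$assignment, fit1$assignment)

  expect_error(cluster_clones(sim[1:3, ], 0.6, 0.6), "fewer than 5")
})

test_that("trajectory classification follows the detection floor", {
  expect_equal(classify_trajectory(0.30, 0.00), "pre_only")
  expect_equal(classify_trajectory(0.30, 0.25), "shared")
  expect_equal(classify_trajectory(0.00, 0.10), "post_only")
  expect_equal(classify_trajectory(c(0.3, 0, 0.01), c(0, 0.1, 0.01)),
               c("pre_only", "post_only", "shared"))
})

test_that("sampling-loss probability is the exact binomial tail", {
  expect_lt(sampling_loss_probability(0.5, 100, 4), 1e-20)
  expect_equal(sampling_loss_probability(0, 80, 4), 1.0)

  grid <- expand.grid(vaf = c(0.001, 0.01, 0.05, 0.2, 0.5, 0.9),
                      depth = c(1, 10, 75, 400), min_alt = c(1, 4, 10))
  oracle <- vapply(seq_len(nrow(grid)), function(i) {
    k <- seq_len(grid$min_alt[i]) - 1L
    sum(choose(grid$depth[i], k) * grid$vaf[i]^k *
          (1 - grid$vaf[i])^(grid$depth[i] - k))
  }, numeric(1))
  got <- sampling_loss_probability(grid$vaf, grid$depth, grid$min_alt)
  expect_equal(got, oracle, tolerance = 1e-12)

  # monotone decreasing in pre_vaf and in post_depth
  vafs <- seq(0.01, 0.5, by = 0.01)
  expect_true(all(diff(sampling_loss_probability(vafs, 80, 4)) <= 0))
  depths <- seq(10, 500, by = 10)
  expect_true(all(diff(sampling_loss_probability(0.1, depths, 4)) <= 0))
})

test_that("discordant same-gene driver sets mark polyclonality", {
  expect_equal(detect_polyclonality(
    rep("TP53", 3), c("pre_only", "shared", "shared")), 1L)
  expect_equal(detect_polyclonality(
    rep("TP53", 3), c("shared", "shared", "shared")), 0L)
  expect_equal(detect_polyclonality(
    rep("TP53", 2), c("pre_only", "shared")), 0L)
  expect_equal(detect_polyclonality(
    c(rep("TP53", 3), rep("NOTCH1", 3)),
    c("pre_only", "shared", "post_only", "pre_only", "pre_only", "shared")),
    2L)
})

test_that("VAF coefficient of variation is scale-free", {
  expect_equal(vaf_cv(c(0.2, 0.2, 0.2)), 0)
  expect_equal(vaf_cv(c(0.1, 0.3)), sd(c(0.1, 0.3)) / 0.2)
  expect_equal(vaf_cv(c(0.1, 0.3)), 0.7071068, tolerance = 1e-6)
  x <- withr::with_seed(2, runif(50))
  expect_equal(vaf_cv(x), vaf_cv(3 * x))
  expect_error(vaf_cv(0.5), "fewer than 2")
})

test_that("spatial concordance counts shared presence over the universe", {
  expect_equal(spatial_concordance(c("a", "b"), c("a", "b")), 1.0)
  expect_equal(spatial_concordance(c("a", "b"), c("c", "d")), 0.0)
  # 66 assessed sites, 55 concordant: 49 present in both, 6 absent from
  # both, 11 discordant
  uni <- paste0("s", 1:66)
  a <- uni[1:55]
  b <- c(uni[1:49], uni[56:60])
  expect_equal(spatial_concordance(a, b, universe = uni), 55 / 66)
  expect_equal(round(55 / 66, 3), 0.833)
  got <- spatial_concordance(
    data.frame(key = c("a", "b", "n1"), gene = c("X", "Y", "NOTCH1")),
    data.frame(key = c("a", "n2"), gene = c("X", "NOTCH1")),
    exclude_genes = "NOTCH1")
  expect_equal(got, 1 / 2)  # universe {a, b}; only "a" concordant
  expect_error(spatial_concordance(character(0), character(0)), "empty")
})

test_that("evolution categories follow the ordered decision rule", {
  th <- evolution_thresholds()
  base <- list(lost_high_vaf_fraction = 0, shared_count = 100,
               expanding_minor_clone = FALSE,
               discordant_same_gene_drivers = 0L, pre_burden = 300,
               post_burden = 280, hypermutator = FALSE,
               n_lost_high_unexplained = 0L, n_gained_high = 0L)
  expect_equal(classify_evolution(base, NULL, th)$category, "stable")

  bn <- modifyList(base, list(lost_high_vaf_fraction = 0.4,
                              expanding_minor_clone = TRUE))
  expect_equal(classify_evolution(bn, NULL, th)$category, "bottleneck")

  pc <- modifyList(base, list(discordant_same_gene_drivers = 1L))
  expect_equal(classify_evolution(pc, NULL, th)$category, "polyclonal")

  hyper <- modifyList(base, list(hypermutator = TRUE,
                                 n_lost_high_unexplained = 12L,
                                 n_gained_high = 30L))
  expect_equal(classify_evolution(hyper, NULL, th)$category, "polyclonal")

  qc_bad <- assess_exclusion("p", 0.7, 0.1, 0.1, 400, 30)
  expect_equal(classify_evolution(bn, qc_bad, th)$category, "excluded")

  # polyclonal outranks bottleneck; bottleneck needs all three features
  both <- modifyList(bn, list(discordant_same_gene_drivers = 2L))
  expect_equal(classify_evolution(both, NULL, th)$category, "polyclonal")
  partial <- modifyList(bn, list(shared_count = 5))
  expect_equal(classify_evolution(partial, NULL, th)$category, "stable")
})
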