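# Clone trees, bottlenecks, spectra draws and sequencing noise.

test_that("clone trees are rooted, consistent and deterministic", {
  expect_error(simulate_clone_tree(0), "n_clones")

  t1 <- simulate_clone_tree(1, seed = 3)
  expect_equal(nrow(t1), 1L)
  expect_equal(t1$fraction_pre, 1)
  expect_true(is.na(t1$parent_id))

  expect_identical(simulate_clone_tree(3, seed = 7),
                   simulate_clone_tree(3, seed = 7))

  tr <- simulate_clone_tree(5, seed = 1)
  expect_equal(tr$fraction_pre[1], 1)
  for (i in which(!is.na(tr$parent_id))) {
    expect_lte(tr$fraction_pre[i],
               tr$fraction_pre[tr$parent_id[i]] + 1e-9)
  }
  # children of one parent never exceed the parent's fraction jointly
  for (p in unique(stats::na.omit(tr$parent_id))) {
    kids <- tr$clone_id[!is.na(tr$parent_id) & tr$parent_id == p]
    expect_lte(sum(tr$fraction_pre[kids]), tr$fraction_pre[p] + 1e-9)
  }
})

test_that("bottlenecks renormalize surviving cell populations", {
  tr <- simulate_clone_tree(3, seed = 2)

  # survival identically 1 leaves the composition unchanged
  same <- apply_bottleneck(tr, rep(1, 3))
  expect_equal(same$fraction_post, same$fraction_pre, tolerance = 1e-12)

  # sibling pair: the survivor absorbs its sibling's share
  sib <- data.frame(clone_id = 1:3, parent_id = c(NA, 1L, 1L),
                    fraction_pre = c(1, 0.4, 0.4),
                    fraction_post = c(1, 0.4, 0.4), survival = 1)
  class(sib) <- c("clone_tree", "data.frame")
  out <- apply_bottleneck(sib, c(0, 1, 0))
  expect_equal(out$fraction_post, c(1, 1, 0), tolerance = 1e-12)

  # closed-form oracle for a chain with graded survival:
  # private cells (0.5, 0.2, 0.3) x survival (1, 0.1, 0.01),
  # renormalized, prevalence re-accumulated bottom-up.
  chain <- data.frame(clone_id = 1:3, parent_id = c(NA, 1L, 2L),
                      fraction_pre = c(1, 0.5, 0.3),
                      fraction_post = c(1, 0.5, 0.3), survival = 1)
  class(chain) <- c("clone_tree", "data.frame")
  cells <- c(0.5, 0.2, 0.3) * c(1, 0.1, 0.01)
  cells <- cells / sum(cells)
  oracle <- c(sum(cells), sum(cells[2:3]), cells[3])
  out <- apply_bottleneck(chain, c(1, 0.1, 0.01), extinction_threshold = 0)
  expect_equal(out$fraction_post, oracle, tolerance = 1e-12)

  expect_error(apply_bottleneck(chain, c(0, 0, 0)), "complete response")
  expect_error(apply_bottleneck(chain, c(-1, 1, 1)), ">= 0")
})

test_that("mutation channels follow the signature mixture", {
  S <- planted_signatures()

  expect_error(assign_mutation_spectra(10, c(0, 0, 0)), "weights")

  # law of large numbers: empirical spectrum near the pure signature
  ch <- assign_mutation_spectra(10000, c(1, 0, 0), seed = 4)
  emp <- tabulate(ch, 96) / 10000
  expect_lt(sum(abs(emp - S[, 1])) / 2, 0.05)

  expect_identical(assign_mutation_spectra(500, c(0.5, 0.5, 0), seed = 9),
                   assign_mutation_spectra(500, c(0.5, 0.5, 0), seed = 9))

  point <- matrix(0, 96, 1)
  point[42, 1] <- 1
  expect_true(all(assign_mutation_spectra(200, 1, signatures = point,
                                          seed = 1) == 42L))
})

test_that("expected VAF and sequencing noise follow the binomial model", {
  expect_equal(expected_vaf(1, 1, 2, 1), 0.5)
  expect_equal(expected_vaf(1, 0.5, 2, 1), 0.25)

  rc <- sequence_sample(rep(0.5, 10000), 100, seed = 6)
  se <- sqrt(0.5 * 0.5 / 100) / sqrt(10000)
  # extra depth variability is second-order; 3 s.e. on the mean VAF
  expect_lt(abs(mean(rc$alt / pmax(rc$depth, 1)) - 0.5), 3.5 * se)

  # chi-square goodness of fit of alt counts at fixed depth
  n <- 20000
  alt <- withr::with_seed(8, rbinom(n, 80, 0.2))
  sim <- sequence_sample(rep(0.2, n), 80, seed = 10)
  fixed <- sim$alt[sim$depth == 80]
  probs <- dbinom(0:80, 80, 0.2)
  bins <- c(0:30, 81)  # collapse the sparse tail
  obs <- tabulate(pmin(fixed, 30) + 1L, 31)
  expctd <- c(probs[1:30], sum(probs[31:81])) * length(fixed)
  keep <- expctd > 5
  stat <- sum((obs[keep] - expctd[keep])^2 / expctd[keep])
  expect_gt(stats::pchisq(stat, sum(keep) - 1, lower.tail = FALSE), 0.01)
})

test_that("cohorts are deterministic and internally consistent", {
  cfg <- sim_config(n_patients = 3, seed = 21, probes_per_arm = 12)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a, b)

  for (p in a$patients) {
    tr <- p$tree
    for (i in which(!is.na(tr$parent_id))) {
      expect_lte(tr$fraction_pre[i], tr$fraction_pre[tr$parent_id[i]] + 1e-9)
      expect_lte(tr$fraction_post[i], tr$fraction_post[tr$parent_id[i]] + 1e-9)
    }
    expect_equal(nrow(p$truth), nrow(p$variants))
  }
})

test_that("an empty cohort writes headers-only files", {
  dir <- withr::local_tempdir()
  co <- simulate_cohort(sim_config(n_patients = 0L, seed = 1))
  write_cohort(co, dir)
  clin <- neoclone:::read_tsv(file.path(dir, "clinical.tsv"))
  expect_equal(nrow(clin), 0L)
  expect_true(all(c("Case", "Mandard", "PathR") %in% names(clin)))
})

test_that("write_cohort emits the expected files and round-trips", {
  dir <- withr::local_tempdir()
  cfg <- sim_config(n_patients = 3, seed = 13, probes_per_arm = 12)
  co <- simulate_cohort(cfg)
  write_cohort(co, dir)

  expect_true(file.exists(file.path(dir, "clinical.tsv")))
  expect_length(list.files(dir, pattern = "\\.vcf$"), 3L)
  expect_length(list.files(dir, pattern = "^case[0-9]+\\.truth\\.tsv$"), 3L)

  v_tsv <- read_variants(file.path(dir, "case1.variants.tsv"))
  v_vcf <- read_variants(file.path(dir, "case1.vcf"))
  key <- function(d) d[order(d$chrom, d$pos, d$alt), ]
  expect_equal(key(v_tsv)$pre_alt, key(v_vcf)$pre_alt)
  expect_equal(key(v_tsv)$post_depth, key(v_vcf)$post_depth)
  expect_equal(key(v_tsv)$popfreq, key(v_vcf)$popfreq, tolerance = 1e-6)
  expect_equal(key(v_tsv)$pon, key(v_vcf)$pon)
  expect_equal(nrow(v_tsv), nrow(v_vcf))

  # survival == 1 leaves every pre-existing mutation's CCF unchanged, so
  # with equal depths and purities the expected VAFs are equal too
  stable <- Filter(function(p) p$scenario == "stable", co$patients)
  if (length(stable)) {
    tru <- stable[[1]]$truth
    pre_existing <- !tru$artifact & tru$ccf_pre > 0
    expect_equal(tru$ccf_pre[pre_existing], tru$ccf_post[pre_existing])
  }
})
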