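# Clinical coding and the cohort association battery.

table1_clinical <- function() {
  # the 30-patient clinical table shipped with the study design:
  # Mandard grades for cases 1..30
  mandard <- c(3, 3, 3, 3, 2, 2, 3, 2, 3, 3, 4, 5, 4, 4, 4, 4, 5, 5, 4, 3,
               4, 3, 3, 5, 4, 4, 3, 3, 5, 4)
  data.frame(Case = 1:30, Mandard = mandard)
}

test_that("Mandard grades map onto binary response", {
  expect_true(response_from_mandard(3))    # case 1
  expect_false(response_from_mandard(4))   # case 11
  expect_error(response_from_mandard(0), "1..5")
  expect_error(response_from_mandard(6), "1..5")

  cl <- table1_clinical()
  resp <- response_from_mandard(cl$Mandard)
  expect_equal(sum(resp), 15L)
  expect_equal(sum(!resp), 15L)
})

test_that("the 2x3 exact test reproduces known and enumerated p-values", {
  # responders 2/1/8 and non-responders 9/2/2 across
  # stable/polyclonal/bottleneck
  obs <- matrix(c(2, 1, 8, 9, 2, 2), nrow = 2, byrow = TRUE)
  res <- evolution_response_test(obs)
  expect_equal(round(res$p_value, 3), 0.013)

  flat <- matrix(3, nrow = 2, ncol = 3)
  expect_equal(evolution_response_test(flat)$p_value, 1.0)

  expect_error(evolution_response_test(matrix(c(0, 0, 0, 1, 2, 3), 2,
                                              byrow = TRUE)), "margin")

  # brute-force enumeration oracle on small tables
  enum_2x3 <- function(tab) {
    rs <- rowSums(tab); cs <- colSums(tab); n <- sum(tab)
    logp <- function(t) {
      sum(lchoose(cs, t)) - lchoose(n, rs[1])
    }
    p_obs <- logp(tab[1, ])
    total <- 0
    for (a in 0:min(rs[1], cs[1])) for (b in 0:min(rs[1] - a, cs[2])) {
      c3 <- rs[1] - a - b
      if (c3 < 0 || c3 > cs[3]) next
      lp <- logp(c(a, b, c3))
      if (lp <= p_obs + 1e-7) total <- total + exp(lp)
    }
    total
  }
  tabs <- withr::with_seed(13, lapply(1:8, function(i) {
    matrix(rpois(6, 2) + c(1, 0, 0, 0, 1, 0), nrow = 2)
  }))
  for (tab in tabs) {
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    expect_equal(evolution_response_test(tab)$p_value, enum_2x3(tab),
                 tolerance = 1e-9)
  }
})

test_that("paired burden test matches signed-rank enumeration", {
  pre <- c(300, 410, 250, 600, 180, 330, 520, 270)
  expect_equal(burden_change_test(pre, pre)$p_value, 1)

  res <- burden_change_test(rep(c(400, 300, 600, 500, 450), 4),
                            rep(c(200, 150, 300, 250, 225), 4))
  expect_lt(res$p_value, 0.01)
  expect_equal(res$median_pre, 450)
  expect_equal(res$median_post, 225)

  expect_error(burden_change_test(1:3, 4:6), "fewer than 5")

  # exact branch equals enumeration over all 2^n sign assignments
  post <- withr::with_seed(7, pre + sample(c(-60, -35, -20, 15, 25, 40,
                                             -75, 55)))
  d <- post - pre
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  n <- length(d)
  signs <- expand.grid(rep(list(c(0, 1)), n))
  w_all <- as.matrix(signs) %*% r
  p_enum <- mean(abs(w_all - n * (n + 1) / 4) >=
                   abs(w_obs - n * (n + 1) / 4) - 1e-9)
  expect_equal(burden_change_test(pre, post)$p_value, p_enum,
               tolerance = 1e-9)
})

test_that("T>A response test yields medians and odds ratios", {
  ta <- c(rep(0.08, 8), rep(0.04, 2), rep(0.08, 2), rep(0.04, 8))
  resp <- rep(c(TRUE, FALSE), each = 10)
  res <- ta_response_test(ta, resp)
  expect_equal(res$median_responder, 0.08)
  expect_equal(res$median_non_responder, 0.04)
  # 2x2 above/below cohort median: (8,2) vs (2,8)
  expect_equal(res$odds_ratio, 16)
  expect_false(res$haldane_corrected)

  sep <- ta_response_test(c(rep(0.9, 10), rep(0.1, 10)), resp)
  expect_true(sep$haldane_corrected)
  expect_true(is.finite(sep$odds_ratio))

  expect_error(ta_response_test(ta, rep(TRUE, 20)), "empty")
})

test_that("age correlation handles monotone and degenerate input", {
  ages <- c(40, 50, 60, 70, 80)
  expect_equal(age_ct_correlation(ages, c(0.1, 0.2, 0.3, 0.4, 0.5))$estimate,
               1)
  expect_equal(age_ct_correlation(ages, c(0.5, 0.4, 0.3, 0.2, 0.1))$estimate,
               -1)
  expect_error(age_ct_correlation(ages, rep(0.3, 5)), "constant")
  expect_error(age_ct_correlation(ages[1:3], c(0.1, 0.2, 0.3)), "fewer")
})

test_that("signature-change association is an exact 2x2 test", {
  chg <- rep(c(TRUE, FALSE), each = 8)
  resp <- rep(c(TRUE, FALSE), each = 8)
  res <- signature_change_response_test(chg, resp)
  # p equals the two-sided hypergeometric tail of the 8/0 0/8 table
  p_oracle <- 2 / choose(16, 8)
  expect_equal(res$p_value, p_oracle, tolerance = 1e-9)

  expect_equal(signature_change_response_test(
    c(TRUE, FALSE, TRUE, FALSE), c(TRUE, TRUE, FALSE, FALSE))$p_value, 1)

  expect_error(signature_change_response_test(rep(TRUE, 10),
                                              rep(c(TRUE, FALSE), 5)),
               "degenerate")
})

test_that("the assembled report is complete and deterministic", {
  build_pp <- function() {
    withr::with_seed(19, data.frame(
      case = 1:12,
      responder = rep(c(TRUE, FALSE), 6),
      category = sample(c("stable", "bottleneck", "polyclonal"), 12, TRUE),
      burden_pre = rpois(12, 350),
      burden_post = rpois(12, 250),
      ta_fraction_pre = runif(12, 0.02, 0.12),
      ct_fraction_pre = runif(12, 0.2, 0.5),
      age = sample(45:80, 12),
      vaf_cv = runif(12, 0.3, 0.9),
      signature_pre = "S1",
      signature_post = sample(c("S1", "S2"), 12, TRUE),
      scna_shared = runif(12)))
  }
  drv <- data.frame(case = c(1, 2), gene = c("TP53", "SMAD4"),
                    trajectory = c("post_only", "shared"),
                    post_vaf = c(0.3, 0.2))
  foc <- data.frame(case = c(3, 4), gene = c("ERBB2", "CCNE1"),
                    direction = "gain", sample = c("shared", "post_only"))
  rep1 <- build_report(build_pp(), drv, foc)
  rep2 <- build_report(build_pp(), drv, foc)
  expect_identical(rep1, rep2)
  expect_equal(nrow(rep1$per_patient), 12L)
  expect_true(all(rep1$stats$p_value >= 0 & rep1$stats$p_value <= 1))
  expect_true("p_bh" %in% names(rep1$stats))
  expect_equal(rep1$post_only_drivers$gene, "TP53")
  expect_equal(rep1$post_only_focal_events$gene, "CCNE1")

  dir <- withr::local_tempdir()
  write_report(rep1, dir)
  expect_true(file.exists(file.path(dir, "per_patient.tsv")))
  expect_true(file.exists(file.path(dir, "cohort_stats.tsv")))
  expect_true(file.exists(file.path(dir, "thresholds.log")))
})
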