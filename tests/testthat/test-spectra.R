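# 96-context channels, spectra, shift tests and NMF signatures.

test_that("context channels collapse strands onto 96 classes", {
  # C>T at ACG equals its reverse complement G>A at CGT
  expect_equal(context_channel("C", "T", "A", "G"),
               context_channel("G", "A", "C", "T"))

  # all 192 strand-specific contexts map onto 96 channels, each hit twice
  subs <- rbind(
    expand.grid(ref = c("C", "T"), alt = c("A", "C", "G", "T")),
    expand.grid(ref = c("A", "G"), alt = c("A", "C", "G", "T")))
  subs <- subs[as.character(subs$ref) != as.character(subs$alt), ]
  all_ch <- integer(0)
  for (i in seq_len(nrow(subs))) {
    for (fp in c("A", "C", "G", "T")) for (tp in c("A", "C", "G", "T")) {
      all_ch <- c(all_ch, context_channel(as.character(subs$ref[i]),
                                          as.character(subs$alt[i]), fp, tp))
    }
  }
  expect_length(all_ch, 192L)
  expect_equal(sort(unique(all_ch)), 1:96)
  expect_true(all(tabulate(all_ch, 96) == 2L))

  # T>G in an .TT context is an NTT>NGT channel
  ch <- context_channel("T", "G", "A", "T")
  expect_equal(channel_names()[ch], "A[T>G]T")

  expect_error(context_channel("C", "C", "A", "A"), "invalid")
  expect_error(context_channel("N", "T", "A", "A"), "invalid")
})

test_that("spectra tabulate channels and collapse to 6 classes", {
  z <- spectrum(integer(0))
  expect_equal(sum(z$counts96), 0)

  one_ct <- spectrum(context_channel("C", "T", "A", "A"))
  expect_equal(unname(one_ct$counts6["C>T"]), 1)
  expect_equal(sum(one_ct$counts6), 1)

  ch <- withr::with_seed(3, assign_mutation_spectra(5000, c(0, 1, 0)))
  sp <- spectrum(data.frame(context96 = c(ch, NA, NA)))
  expect_equal(attr(sp, "n_skipped"), 2L)
  expect_equal(sp$counts6, collapse6(sp$counts96))
  S <- planted_signatures()
  expect_lt(sum(abs(sp$counts96 / 5000 - S[, 2])) / 2, 0.05)
})

test_that("spectrum comparison matches an exact enumeration oracle", {
  expect_equal(compare_spectra(c(10, 5, 3, 2, 1, 0), c(10, 5, 3, 2, 1, 0)),
               1.0)
  expect_lt(compare_spectra(c(100, 0, 0, 0, 0, 0), c(0, 100, 0, 0, 0, 0)),
            1e-10)
  expect_error(compare_spectra(c(0, 0, 0, 0, 0, 0), c(1, 1, 1, 1, 1, 1)),
               "zero total")

  # full enumeration of 2xk tables with fixed margins; two-sided by
  # probability ordering of the conditional multivariate hypergeometric
  enum_fisher <- function(a, b) {
    k <- length(a)
    col_tot <- a + b
    n1 <- sum(a)
    tabs <- list(integer(0))
    for (j in seq_len(k)) {
      tabs <- do.call(c, lapply(tabs, function(t) {
        lapply(0:col_tot[j], function(x) c(t, x))
      }))
      tabs <- Filter(function(t) sum(t) <= n1, tabs)
    }
    tabs <- Filter(function(t) sum(t) == n1, tabs)
    logp <- vapply(tabs, function(t) {
      sum(lchoose(col_tot, t)) - lchoose(sum(col_tot), n1)
    }, numeric(1))
    p_obs <- sum(lchoose(col_tot, a)) - lchoose(sum(col_tot), n1)
    sum(exp(logp[logp <= p_obs + 1e-7]))
  }
  cases <- withr::with_seed(17, lapply(1:6, function(i) {
    list(a = as.integer(rmultinom(1, 8, rep(1, 6))),
         b = as.integer(rmultinom(1, 10, rep(1, 6))))
  }))
  for (cs in cases) {
    got <- compare_spectra(cs$a, cs$b, method = "fisher")
    want <- enum_fisher(cs$a, cs$b)
    expect_equal(got, want, tolerance = 1e-9)
  }
})

test_that("NMF recovers planted structure deterministically", {
  S <- planted_signatures()

  # rank-1 data factorises exactly
  profile <- S[, 1]
  V <- outer(c(100, 200, 400), profile)
  m1 <- fit_signatures(V, 1, seed = 2, restarts = 3)
  expect_lt(m1$reconstruction_error, 1e-6)
  expect_equal(as.numeric(m1$signatures[, 1]), unname(profile),
               tolerance = 1e-4)

  expect_error(fit_signatures(V, 5), "exceeds")

  counts <- withr::with_seed(23, {
    W <- t(vapply(1:12, function(i) {
      w <- rgamma(3, 1); w / sum(w)
    }, numeric(3)))
    t(vapply(1:12, function(i) {
      as.numeric(rmultinom(1, 3000, as.numeric(S %*% W[i, ])))
    }, numeric(96)))
  })
  m3a <- fit_signatures(counts, 3, seed = 7, restarts = 6)
  m3b <- fit_signatures(counts, 3, seed = 7, restarts = 6)
  expect_identical(m3a, m3b)

  # objective is monotone non-increasing over iterations
  expect_true(all(diff(m3a$error_trace) <= 1e-12))

  cs <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  match_sim <- apply(S, 2, function(s) max(apply(m3a$signatures, 2, cs, s)))
  expect_true(all(match_sim >= 0.90))

  # signatures are column-stochastic and exposures nonnegative
  expect_equal(unname(colSums(m3a$signatures)), rep(1, 3), tolerance = 1e-9)
  expect_true(all(m3a$exposures >= 0))
})

test_that("rank selection finds planted rank and degrades gracefully", {
  S <- planted_signatures()
  counts <- withr::with_seed(29, {
    W <- t(vapply(1:18, function(i) {
      w <- rgamma(3, 1); w / sum(w)
    }, numeric(3)))
    t(vapply(1:18, function(i) {
      as.numeric(rmultinom(1, 2500, as.numeric(S %*% W[i, ])))
    }, numeric(96)))
  })
  models <- lapply(2:6, function(r) {
    fit_signatures(counts, r, seed = 5, restarts = 6)
  })
  sel <- select_rank(models)
  expect_equal(sel$r, 3)

  # permuting sample order leaves the criterion unchanged
  perm <- withr::with_seed(1, sample(nrow(counts)))
  models_p <- lapply(2:6, function(r) {
    fit_signatures(counts[perm, ], r, seed = 5, restarts = 6)
  })
  sel_p <- select_rank(models_p)
  expect_equal(sel_p$r, sel$r)

  single <- withr::with_seed(31, t(vapply(1:8, function(i) {
    as.numeric(rmultinom(1, 2000, S[, 1]))
  }, numeric(96))))
  models1 <- lapply(2:5, function(r) {
    fit_signatures(single, r, seed = 3, restarts = 4)
  })
  expect_equal(select_rank(models1)$r, 2)
})

test_that("predominant signatures and changes are labelled correctly", {
  H <- matrix(c(0.7, 0.2, 0.1,
                0.1, 0.1, 0.8,
                0.2, 0.2, 0.2), nrow = 3)
  rownames(H) <- paste0("S", 1:3)
  model <- structure(list(r = 3, exposures = H), class = "signature_model")
  labs <- predominant_signature(model, totals = c(100, 100, 30))
  expect_equal(labs, c("S1", "S3", NA))

  # argmax ties break to the lowest signature index
  expect_equal(labs[3], NA_character_)
  tied <- predominant_signature(
    structure(list(exposures = H[, 3, drop = FALSE]),
              class = "signature_model"), totals = 100)
  expect_equal(tied, "S1")

  expect_true(signature_change("S3", "S1"))
  expect_false(signature_change("S1", "S1"))
  expect_false(signature_change(NA, "S1"))
})
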