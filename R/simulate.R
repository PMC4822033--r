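# Synthetic clonal-evolution cohort generator.
#
# Patients are simulated as rooted clone trees over cancer cells. Each
# clone's `fraction` is its cellular prevalence (fraction of cancer cells
# carrying the clone's mutations); nesting implies child <= parent.
# Chemotherapy multiplies each clone's *private* cell population by a
# survival factor, after which prevalences are renormalised, giving the
# post-treatment composition. Sequencing adds Poisson depth and binomial
# allele-count noise on the expected VAF implied by purity and local copy
# number.

maybe_seed <- function(seed, expr) {
  if (is.null(seed)) expr else withr_seed(seed, expr)
}

#' Synthetic cohort configuration
#'
#' Defaults emulate the cohort characteristics of a 30-patient paired
#' pre-/post-chemotherapy oesophageal adenocarcinoma study: median exome
#' depth ~75x, mean SNV burden 373, generally hypertriploid genomes,
#' ~18 arm-scale copy number events per cancer, a scenario mix matching
#' the observed 11 stable / 10 bottleneck / 3 polyclonal split, and
#' purities above histological review thresholds.
#'
#' @param n_patients Number of patients (default 30).
#' @param scenario_mix Named proportions over
#'   `c(stable, bottleneck, polyclonal)`; must sum to 1.
#' @param mean_burden Mean pre-treatment SNV burden (default 373).
#' @param burden_sdlog Log-sd of the lognormal burden draw (default 0.35).
#' @param depth_pre,depth_post Mean sequencing depths (default 75).
#' @param panel_depth Mean depth for deep-panel mode (default 1800).
#' @param normal_depth Mean depth of the matched normal (default 75).
#' @param purity_pre,purity_post Tumour purities in (0, 1].
#' @param ploidy Modal copy number (default 3, hypertriploid).
#' @param n_large_scna Arm-scale copy number events per cancer (default 18).
#' @param probes_per_arm Probes simulated per chromosome arm (default 200).
#' @param logr_noise_sd Per-probe logR noise sd (default 0.1).
#' @param scna_effect Absolute logR shift of a planted event (default 0.3).
#' @param hypermutator_factor Burden multiplier for polyclonal
#'   hypermutators (default 20).
#' @param post_only_mean Mean Poisson count of post-treatment-only
#'   mutations (default 30).
#' @param error_rate Sequencing error rate for the normal sample
#'   (default 1e-3).
#' @param extinction_threshold Clone prevalence below which a clone is
#'   considered extinct after treatment (default 1e-4, below any
#'   detectable VAF at the simulated depths).
#' @param artifact_mean Mean count of each planted artifact type
#'   (germline leak-through, panel-of-normals hits, segmental
#'   duplication and low-mappability sites) per patient (default 10).
#' @param seed Integer seed.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(n_patients = 30L,
                       scenario_mix = c(stable = 11 / 24, bottleneck = 10 / 24,
                                        polyclonal = 3 / 24),
                       mean_burden = 373, burden_sdlog = 0.35,
                       depth_pre = 75, depth_post = 75, panel_depth = 1800,
                       normal_depth = 75,
                       purity_pre = 0.65, purity_post = 0.6,
                       ploidy = 3L, n_large_scna = 18L,
                       probes_per_arm = 200L, logr_noise_sd = 0.1,
                       scna_effect = 0.3,
                       hypermutator_factor = 20,
                       post_only_mean = 30,
                       error_rate = 1e-3,
                       extinction_threshold = 1e-4,
                       artifact_mean = 10,
                       seed = 1L) {
  stopifnot(abs(sum(scenario_mix) - 1) < 1e-9,
            all(names(scenario_mix) %in% c("stable", "bottleneck", "polyclonal")),
            depth_pre >= 1, depth_post >= 1, normal_depth >= 1,
            purity_pre > 0, purity_pre <= 1, purity_post > 0, purity_post <= 1)
  structure(as.list(environment()), class = "sim_config")
}

# ---- clone trees ------------------------------------------------------------

#' Simulate a random rooted clone tree
#'
#' The root clone has prevalence 1 among cancer cells; each further clone
#' attaches to a uniformly chosen existing clone and takes a uniform share
#' of its parent's unallocated cell fraction, so the nesting constraint
#' (child prevalence <= parent prevalence) holds by construction.
#'
#' @param n_clones Number of clones, `>= 1`.
#' @param seed Integer seed, or `NULL` to use the current RNG stream.
#' @return Data frame of class `clone_tree` with columns `clone_id`,
#'   `parent_id` (`NA` for the root), `fraction_pre`, `fraction_post`
#'   (initially equal to `fraction_pre`) and `survival` (initially 1).
#' @export
simulate_clone_tree <- function(n_clones, seed = NULL) {
  if (n_clones < 1L) stop("n_clones must be >= 1")
  maybe_seed(seed, {
    tree <- data.frame(clone_id = seq_len(n_clones),
                       parent_id = NA_integer_,
                       fraction_pre = 0, fraction_post = 0, survival = 1)
    tree$fraction_pre[1L] <- 1
    if (n_clones > 1L) {
      for (i in 2L:n_clones) {
        parent <- if (i == 2L) 1L else sample.int(i - 1L, 1L)
        kids <- tree$clone_id[!is.na(tree$parent_id) & tree$parent_id == parent]
        avail <- tree$fraction_pre[parent] - sum(tree$fraction_pre[kids])
        tree$parent_id[i] <- parent
        tree$fraction_pre[i] <- stats::runif(1L, 0, max(avail, 0))
      }
    }
    tree$fraction_post <- tree$fraction_pre
    class(tree) <- c("clone_tree", "data.frame")
    tree
  })
}

subtree_members <- function(tree, clone) {
  out <- clone
  repeat {
    more <- tree$clone_id[!is.na(tree$parent_id) & tree$parent_id %in% out &
                            !(tree$clone_id %in% out)]
    if (!length(more)) break
    out <- c(out, more)
  }
  out
}

# Cellular prevalence -> private cell fraction (prevalence minus children).
cell_fractions <- function(tree, column = "fraction_pre") {
  prev <- tree[[column]]
  cf <- prev
  for (i in seq_len(nrow(tree))) {
    kids <- which(!is.na(tree$parent_id) & tree$parent_id == tree$clone_id[i])
    cf[i] <- prev[i] - sum(prev[kids])
  }
  pmax(cf, 0)
}

prevalence_from_cells <- function(tree, cells) {
  vapply(tree$clone_id, function(cl) {
    sum(cells[match(subtree_members(tree, cl), tree$clone_id)])
  }, numeric(1))
}

#' Apply a therapeutic bottleneck to a clone tree
#'
#' Multiplies each clone's private cell population by its survival factor,
#' renormalises so the surviving cancer cells again sum to 1, and zeroes
#' clones whose prevalence falls below the extinction threshold.
#'
#' @param tree A `clone_tree`.
#' @param survival_by_clone Numeric vector of nonnegative multipliers,
#'   one per clone (in `clone_id` order).
#' @param extinction_threshold Prevalence below which a clone is removed
#'   (default 1e-4).
#' @return The tree with `fraction_post` and `survival` filled in.
#' @export
apply_bottleneck <- function(tree, survival_by_clone,
                             extinction_threshold = 1e-4) {
  stopifnot(length(survival_by_clone) == nrow(tree))
  if (any(survival_by_clone < 0)) stop("survival multipliers must be >= 0")
  cells <- cell_fractions(tree, "fraction_pre")
  post <- cells * survival_by_clone
  if (sum(post) <= 0) {
    stop("complete response: no cancer cells survive treatment")
  }
  post <- post / sum(post)
  prev <- prevalence_from_cells(tree, post)
  dead <- prev < extinction_threshold
  if (any(dead)) {
    for (cl in tree$clone_id[dead]) {
      post[match(subtree_members(tree, cl), tree$clone_id)] <- 0
    }
    post <- post / sum(post)
    prev <- prevalence_from_cells(tree, post)
  }
  tree$fraction_post <- prev
  tree$survival <- survival_by_clone
  tree
}

# ---- mutation spectra -------------------------------------------------------

#' Draw 96-context channels for a set of mutations
#'
#' Channels are drawn from the mixture of planted signatures given by
#' `signature_weights`; the empirical spectrum converges to the mixture as
#' the number of mutations grows.
#'
#' @param n_mutations Number of channels to draw.
#' @param signature_weights Nonnegative mixture weights, one per column of
#'   `signatures`; not all zero.
#' @param signatures 96 x k column-stochastic matrix (defaults to
#'   [planted_signatures()]).
#' @param seed Integer seed or `NULL`.
#' @return Integer vector of channel indices in 1..96.
#' @export
assign_mutation_spectra <- function(n_mutations, signature_weights,
                                    signatures = planted_signatures(),
                                    seed = NULL) {
  if (any(signature_weights < 0) || sum(signature_weights) <= 0) {
    stop("signature weights must be nonnegative and not all zero")
  }
  stopifnot(nrow(signatures) == 96L,
            length(signature_weights) == ncol(signatures))
  p <- as.numeric(signatures %*% (signature_weights / sum(signature_weights)))
  maybe_seed(seed, {
    if (n_mutations == 0L) integer(0)
    else sample.int(96L, n_mutations, replace = TRUE, prob = p)
  })
}

# ---- sequencing noise -------------------------------------------------------

#' Expected VAF of a mutation given purity, CCF and copy number
#'
#' `vaf = purity * ccf * mutated_cn / (purity * total_cn + 2 (1 - purity))`
#'
#' @param ccf Cancer cell fraction in `[0, 1]`.
#' @param purity Tumour purity in `(0, 1]`.
#' @param total_cn Local total copy number in tumour cells.
#' @param mutated_cn Copies carrying the mutation (default 1).
#' @return Expected variant allele fraction. Vectorised.
#' @export
expected_vaf <- function(ccf, purity, total_cn, mutated_cn = 1) {
  purity * ccf * mutated_cn / (purity * total_cn + 2 * (1 - purity))
}

#' Simulate read counts for one sample
#'
#' Per-variant total depth is Poisson(`depth`); alt counts are binomial on
#' the expected VAF. For a normal sample pass the error rate as `vaf`.
#'
#' @param vaf Expected variant allele fractions.
#' @param depth Mean sequencing depth (`>= 1`).
#' @param seed Integer seed or `NULL`.
#' @return Data frame with columns `depth` and `alt`.
#' @export
sequence_sample <- function(vaf, depth, seed = NULL) {
  stopifnot(depth >= 1, all(vaf >= 0), all(vaf <= 1))
  maybe_seed(seed, {
    dp <- stats::rpois(length(vaf), depth)
    alt <- stats::rbinom(length(vaf), dp, vaf)
    data.frame(depth = dp, alt = alt)
  })
}

# ---- genome layout for SCNA simulation -------------------------------------

#' Synthetic chromosome-arm coordinate table
#'
#' A simplified 22-chromosome genome with two arms per chromosome, used by
#' the simulator and the arm-event caller. Arm lengths taper from
#' chromosome 1 downward.
#'
#' @return Data frame with columns `chrom`, `arm` (e.g. `"1p"`), `start`,
#'   `end` (1-based inclusive).
#' @export
synthetic_arm_table <- function() {
  chrom_mb <- round(seq(240, 50, length.out = 22L))
  out <- do.call(rbind, lapply(seq_len(22L), function(ch) {
    len <- chrom_mb[ch] * 1e6
    cen <- round(len * 0.4)
    data.frame(chrom = as.character(ch),
               arm = paste0(ch, c("p", "q")),
               start = c(1, cen + 1),
               end = c(cen, len))
  }))
  rownames(out) <- NULL
  out
}

#' Simulate a patient's arm-scale copy number events
#'
#' Plants `n_large_scna` arm events before treatment (2 for hyperdiploid
#' MSI-like genomes), keeps each after treatment with a patient-level
#' sharing probability, and adds a few treatment-emergent events.
#'
#' @param config A [sim_config()].
#' @param hyperdiploid Use the low-SCNA hyperdiploid profile.
#' @return List: `arms` (coordinate table), `events_pre`, `events_post`
#'   (data frames with `arm`, `direction`).
#' @export
simulate_scna_profile <- function(config, hyperdiploid = FALSE) {
  arms <- synthetic_arm_table()
  n_ev_pre <- if (hyperdiploid) 2L else config$n_large_scna
  idx_pre <- sample.int(nrow(arms), min(n_ev_pre, nrow(arms)))
  dir_pre <- sample(c("gain", "loss"), length(idx_pre), replace = TRUE)
  keep_prob <- stats::runif(1L, 0.2, 0.7)
  keep <- stats::runif(length(idx_pre)) < keep_prob
  n_new <- stats::rpois(1L, if (hyperdiploid) 1 else 6)
  free <- setdiff(seq_len(nrow(arms)), idx_pre)
  idx_new <- if (n_new > 0 && length(free)) {
    sample(free, min(n_new, length(free)))
  } else integer(0)
  dir_new <- sample(c("gain", "loss"), length(idx_new), replace = TRUE)
  events_pre <- data.frame(arm = arms$arm[idx_pre], direction = dir_pre)
  events_post <- rbind(
    data.frame(arm = arms$arm[idx_pre[keep]], direction = dir_pre[keep]),
    data.frame(arm = arms$arm[idx_new], direction = dir_new))
  list(arms = arms, events_pre = events_pre, events_post = events_post)
}

#' Simulate per-probe logR values with planted arm events
#'
#' Each arm carries `probes_per_arm` equally spaced probes; an arm with a
#' planted event has a contiguous stretch covering 60-100% of the arm
#' shifted by `scna_effect` (positive for gains), plus Gaussian noise.
#'
#' @param arms Arm coordinate table, e.g. [synthetic_arm_table()].
#' @param events Data frame with `arm`, `direction` columns.
#' @param config A [sim_config()] (probe count, effect size, noise sd).
#' @return Data frame with `chrom`, `pos`, `logr`.
#' @export
simulate_logr_probes <- function(arms, events, config) {
  do.call(rbind, lapply(seq_len(nrow(arms)), function(i) {
    n <- config$probes_per_arm
    pos <- round(seq(arms$start[i], arms$end[i], length.out = n))
    mu <- rep(0, n)
    ev <- events[events$arm == arms$arm[i], , drop = FALSE]
    if (nrow(ev)) {
      cover <- stats::runif(1L, 0.6, 1.0)
      span <- max(2L, round(n * cover))
      from <- sample.int(n - span + 1L, 1L)
      eff <- if (ev$direction[1L] == "gain") config$scna_effect else -config$scna_effect
      mu[from:(from + span - 1L)] <- eff
    }
    data.frame(chrom = arms$chrom[i], pos = pos,
               logr = mu + stats::rnorm(n, 0, config$logr_noise_sd))
  }))
}

# ---- per-patient simulation -------------------------------------------------

random_positions <- function(n) {
  chrom <- sample(as.character(1:22), n, replace = TRUE)
  pos <- sample.int(2e8, n, replace = TRUE)
  data.frame(chrom = chrom, pos = pos)
}

channel_to_alleles <- function(channel) {
  cls <- (channel - 1L) %/% 16L + 1L
  rest <- (channel - 1L) %% 16L
  fp <- BASES[rest %/% 4L + 1L]
  tp <- BASES[rest %% 4L + 1L]
  ref <- substr(SUB_CLASSES[cls], 1L, 1L)
  alt <- substr(SUB_CLASSES[cls], 3L, 3L)
  data.frame(ref = ref, alt = alt, five_prime = fp, three_prime = tp)
}

build_scenario_tree <- function(scenario) {
  if (scenario == "stable") {
    tree <- simulate_clone_tree(1L)
    surv <- 1
  } else if (scenario == "bottleneck") {
    n_extra <- sample.int(3L, 1L) - 1L  # 0..2 clones beyond the core trio
    n <- 3L + n_extra
    tree <- data.frame(clone_id = seq_len(n), parent_id = NA_integer_,
                       fraction_pre = 0, fraction_post = 0, survival = 1)
    tree$fraction_pre[1L] <- 1
    tree$parent_id[2L] <- 1L   # doomed dominant subclone
    tree$fraction_pre[2L] <- stats::runif(1L, 0.55, 0.8)
    tree$parent_id[3L] <- 1L   # surviving minor subclone
    tree$fraction_pre[3L] <- stats::runif(1L, 0.08, 0.18)
    if (n_extra > 0L) {
      for (i in seq_len(n_extra)) {
        id <- 3L + i
        parent <- sample(c(2L, 3L), 1L)
        kids <- which(!is.na(tree$parent_id) & tree$parent_id == parent)
        avail <- tree$fraction_pre[parent] - sum(tree$fraction_pre[kids])
        tree$parent_id[id] <- parent
        tree$fraction_pre[id] <- stats::runif(1L, 0, max(avail, 0) * 0.8)
      }
    }
    tree$fraction_post <- tree$fraction_pre
    class(tree) <- c("clone_tree", "data.frame")
    surv <- rep(0.002, n)
    surv[c(3L, which(!is.na(tree$parent_id) & tree$parent_id == 3L))] <- 1
  } else {  # polyclonal: two founder lineages under a mutation-free root
    tree <- data.frame(clone_id = 1:4, parent_id = c(NA, 1L, 1L, 2L),
                       fraction_pre = 0, fraction_post = 0, survival = 1)
    tree$fraction_pre[1L] <- 1
    tree$fraction_pre[2L] <- stats::runif(1L, 0.5, 0.65)  # founder A
    tree$fraction_pre[3L] <- 1 - tree$fraction_pre[2L] -
      stats::runif(1L, 0, 0.05)                            # founder B
    tree$fraction_pre[4L] <- tree$fraction_pre[2L] * stats::runif(1L, 0.3, 0.6)
    tree$fraction_post <- tree$fraction_pre
    class(tree) <- c("clone_tree", "data.frame")
    # founder A persists/expands, founder B shrinks but survives, the
    # subclone of A carrying the third same-gene driver is lost.
    surv <- c(0, 1, 0.25, 0)
  }
  list(tree = tree, survival = surv)
}

allocate_burden <- function(tree, scenario, total) {
  n <- nrow(tree)
  if (scenario == "bottleneck") {
    # the doomed dominant clone carries most private mutations, as in
    # observed bottlenecks where losses far outnumber retained mutations
    w <- numeric(n)
    w[1L] <- 1.2
    w[2L] <- stats::runif(1L, 1.2, 2.2)
    w[3L] <- stats::runif(1L, 0.3, 0.6)
    if (n > 3L) w[4:n] <- stats::runif(n - 3L, 0.2, 0.6)
  } else if (scenario == "polyclonal") {
    w <- c(0, 1, 0.8, 0.4)  # root of a polyclonal tumour carries nothing
  } else {
    w <- rep(1, n)
  }
  counts <- as.integer(stats::rmultinom(1L, total, w))
  pmax(counts, ifelse(w > 0, 1L, 0L))
}

simulate_patient <- function(case_id, scenario, config) {
  sc <- build_scenario_tree(scenario)
  tree <- apply_bottleneck(sc$tree, sc$survival,
                           config$extinction_threshold)
  hyper <- scenario == "polyclonal"

  burden <- max(50L, round(stats::rlnorm(1L, log(config$mean_burden),
                                         config$burden_sdlog)))
  if (hyper) burden <- burden * config$hypermutator_factor
  n_by_clone <- allocate_burden(tree, scenario, burden)

  # signature mixture: ageing-dominated pre-treatment, shifted for
  # mutations arising after therapy (less C>T, more C>A).
  w_aging <- stats::runif(1L, 0.55, 0.85)
  rest <- stats::runif(2L)
  w_pre <- c(w_aging, (1 - w_aging) * rest / sum(rest))
  shift <- stats::runif(1L, 0.3, 0.6)
  w_post <- c(w_pre[1L] * (1 - shift),
              w_pre[2L] + w_pre[1L] * shift, w_pre[3L])

  clone_id <- rep(tree$clone_id, n_by_clone)
  n_mut <- length(clone_id)
  ch <- assign_mutation_spectra(n_mut, w_pre)

  n_post_only <- stats::rpois(1L, config$post_only_mean *
                                if (hyper) config$hypermutator_factor else 1)
  if (n_post_only > 0L) {
    surviving <- tree$clone_id[tree$fraction_post > 0 &
                                 cell_fractions(tree, "fraction_post") > 0.05]
    if (!length(surviving)) surviving <- tree$clone_id[which.max(tree$fraction_post)]
    po_clone <- sample(rep(surviving, 2L), n_post_only, replace = TRUE)
    ch <- c(ch, assign_mutation_spectra(n_post_only, w_post))
  } else {
    po_clone <- integer(0)
  }

  ccf_pre <- c(tree$fraction_pre[clone_id], rep(0, n_post_only))
  ccf_post <- c(tree$fraction_post[clone_id],
                tree$fraction_post[po_clone] * stats::runif(n_post_only, 0.3, 1))
  clone_all <- c(clone_id, po_clone)
  n_all <- length(clone_all)

  cn_probs <- if (hyper) c(0.9, 0.08, 0.02) else c(0.25, 0.55, 0.2)
  total_cn <- sample(2:4, n_all, replace = TRUE, prob = cn_probs)

  loc <- random_positions(n_all)
  alle <- channel_to_alleles(ch)
  gene <- paste0("GENE", sample.int(500L, n_all, replace = TRUE))

  # driver annotation: most cancers carry a truncal TP53 driver; the
  # polyclonal scenario plants three same-gene drivers with discordant
  # post-treatment behaviour (lineage A rising, B persisting, subclone lost).
  driver_idx <- integer(0)
  if (scenario == "polyclonal") {
    driver_idx <- vapply(c(2L, 3L, 4L), function(cl) {
      which(clone_all == cl)[1L]
    }, integer(1))
    gene[driver_idx] <- "TP53"
  } else if (stats::runif(1L) < 0.77) {
    driver_idx <- which(clone_all == 1L)[1L]
    gene[driver_idx] <- "TP53"
  }

  vaf_pre <- expected_vaf(ccf_pre, config$purity_pre, total_cn)
  vaf_post <- expected_vaf(ccf_post, config$purity_post, total_cn)
  rc_n <- sequence_sample(rep(config$error_rate, n_all), config$normal_depth)
  rc_pre <- sequence_sample(pmin(vaf_pre, 1), config$depth_pre)
  rc_post <- sequence_sample(pmin(vaf_post, 1), config$depth_post)

  variants <- data.frame(
    chrom = loc$chrom, pos = loc$pos, ref = alle$ref, alt = alle$alt,
    gene = gene, context96 = ch, total_cn = total_cn,
    normal_depth = rc_n$depth, normal_alt = rc_n$alt,
    pre_depth = rc_pre$depth, pre_alt = rc_pre$alt,
    post_depth = rc_post$depth, post_alt = rc_post$alt,
    popfreq = 0, pon = FALSE, segdup = FALSE, mappability = 1)

  truth <- data.frame(
    chrom = loc$chrom, pos = loc$pos,
    clone_id = clone_all, ccf_pre = ccf_pre, ccf_post = ccf_post,
    context96 = ch, artifact = FALSE)

  art <- simulate_artifacts(config)
  if (nrow(art$variants)) {
    variants <- rbind(variants, art$variants)
    truth <- rbind(truth, art$truth)
  }

  list(case = case_id, scenario = scenario, tree = tree,
       variants = variants, truth = truth,
       purity_pre = config$purity_pre, purity_post = config$purity_post,
       signature_weights_pre = w_pre, signature_weights_post = w_post,
       msi = hyper)
}

simulate_artifacts <- function(config) {
  types <- c("popfreq", "pon", "segdup", "mappability")
  counts <- stats::rpois(4L, config$artifact_mean)
  n <- sum(counts)
  if (n == 0L) {
    return(list(variants = data.frame(), truth = data.frame()))
  }
  type <- rep(types, counts)
  loc <- random_positions(n)
  ch <- sample.int(96L, n, replace = TRUE)
  alle <- channel_to_alleles(ch)
  # germline leak-through sits at ~0.5 VAF everywhere; pipeline artefacts
  # show up as moderate-VAF calls flagged by the relevant annotation.
  is_germ <- type == "popfreq"
  vaf <- ifelse(is_germ, 0.5, stats::runif(n, 0.05, 0.3))
  rc_n <- sequence_sample(ifelse(is_germ, 0.5, config$error_rate),
                          config$normal_depth)
  rc_pre <- sequence_sample(vaf, config$depth_pre)
  rc_post <- sequence_sample(vaf, config$depth_post)
  variants <- data.frame(
    chrom = loc$chrom, pos = loc$pos, ref = alle$ref, alt = alle$alt,
    gene = paste0("GENE", sample.int(500L, n, replace = TRUE)),
    context96 = ch, total_cn = 2L,
    normal_depth = rc_n$depth, normal_alt = rc_n$alt,
    pre_depth = rc_pre$depth, pre_alt = rc_pre$alt,
    post_depth = rc_post$depth, post_alt = rc_post$alt,
    popfreq = ifelse(type == "popfreq", stats::runif(n, 0.01, 0.5), 0),
    pon = type == "pon", segdup = type == "segdup",
    mappability = ifelse(type == "mappability", stats::runif(n, 0, 0.79), 1))
  truth <- data.frame(chrom = loc$chrom, pos = loc$pos,
                      clone_id = NA_integer_, ccf_pre = NA_real_,
                      ccf_post = NA_real_, context96 = ch, artifact = TRUE)
  list(variants = variants, truth = truth)
}

simulate_clinical <- function(case_id, scenario) {
  p_resp <- switch(scenario, stable = 2 / 11, bottleneck = 8 / 10,
                   polyclonal = 1 / 3)
  responder <- stats::runif(1L) < p_resp
  mandard <- if (responder) sample(2:3, 1L) else sample(4:5, 1L)
  data.frame(Case = case_id,
             Age = pmin(85L, pmax(29L, round(stats::rnorm(1L, 65, 9)))),
             Sex = sample(c("Male", "Female"), 1L, prob = c(0.8, 0.2)),
             T = sample(1:4, 1L, prob = c(0.1, 0.3, 0.55, 0.05)),
             N = sample(0:3, 1L, prob = c(0.35, 0.5, 0.1, 0.05)),
             PathR = ifelse(responder, "Yes", "No"),
             Mandard = mandard,
             Histology = round(stats::runif(1L, 0.35, 0.8), 2))
}

#' Simulate a full synthetic cohort
#'
#' Draws per-patient clonal scenarios from the configured mix, simulates
#' clone trees, bottlenecks, mutation spectra, read counts, clinical
#' records and arm-scale copy number profiles, and keeps the generating
#' truth alongside.
#'
#' @param config A [sim_config()].
#' @return List of class `sim_cohort`: `patients` (list), `clinical`
#'   (data frame), `arms` (arm coordinate table), `config`.
#' @export
simulate_cohort <- function(config = sim_config()) {
  withr_seed(config$seed, {
    scen <- sample(names(config$scenario_mix), config$n_patients,
                   replace = TRUE, prob = config$scenario_mix)
    patients <- vector("list", config$n_patients)
    clinical <- vector("list", config$n_patients)
    for (i in seq_len(config$n_patients)) {
      p <- simulate_patient(i, scen[i], config)
      cl <- simulate_clinical(i, scen[i])
      scna <- simulate_scna_profile(config, hyperdiploid = p$msi)
      p$scna <- scna
      p$clinical <- cl
      patients[[i]] <- p
      clinical[[i]] <- cl
    }
    clin <- if (length(clinical)) {
      do.call(rbind, clinical)
    } else {
      simulate_clinical(1L, "stable")[0, ]
    }
    structure(list(patients = patients, clinical = clin,
                   arms = synthetic_arm_table(),
                   config = config),
              class = "sim_cohort")
  })
}
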