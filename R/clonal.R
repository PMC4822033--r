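# Copy-number-corrected cancer cell fractions, binomial-mixture clone
# clustering across the pre/post pair, and per-patient classification of
# clonal dynamics (stable / bottleneck / polyclonal / excluded).

#' Convert a VAF to a cancer cell fraction
#'
#' `CCF = vaf * (purity * total_cn + 2 (1 - purity)) / (purity * mutated_cn)`.
#' Values above 1.5 (possible under copy number mis-specification) are
#' clipped, with the count of clipped values attached as an attribute.
#'
#' @param vaf Variant allele fraction(s).
#' @param purity Tumour purity in (0, 1].
#' @param total_cn Local total copy number (`>= 1`).
#' @param mutated_cn Mutation multiplicity (`>= 1`, default 1).
#' @return CCF values in `[0, 1.5]` with attribute `n_clipped`.
#' @export
ccf_from_vaf <- function(vaf, purity, total_cn, mutated_cn = 1) {
  if (any(purity <= 0) || any(purity > 1)) {
    stop("purity must be in (0, 1]")
  }
  stopifnot(all(total_cn >= 1), all(mutated_cn >= 1))
  ccf <- vaf * (purity * total_cn + 2 * (1 - purity)) / (purity * mutated_cn)
  clipped <- sum(ccf > 1.5)
  structure(pmin(ccf, 1.5), n_clipped = clipped)
}

#' Select shared mutations for clone clustering
#'
#' Implements the inclusion rules used for paired clonal inference:
#' mutations detected in both samples with at least 60x coverage in one
#' of them (`coverage60`); shared positions whose allelic ratio falls
#' below 0.03 in just one of the samples (`low_vaf_rescue`); and
#' annotated driver mutations regardless of coverage (`driver`). When the
#' included set of a hypermutated cancer exceeds `subsample_cap`, it is
#' down-sampled uniformly at random to the cap, keeping all drivers.
#'
#' @param variants Retained variant table (with `pre_vaf`, `post_vaf`,
#'   `pre_depth`, `post_depth`, `gene` columns).
#' @param drivers Character vector of driver gene symbols.
#' @param min_coverage Coverage threshold (default 60).
#' @param detect_vaf Allelic-ratio detection boundary (default 0.03).
#' @param subsample_cap Hypermutator subsample size (default 500).
#' @param seed Seed for the subsample draw.
#' @return The table restricted to included mutations, with an
#'   `inclusion_reason` column.
#' @export
select_for_clustering <- function(variants, drivers = character(0),
                                  min_coverage = 60L, detect_vaf = 0.03,
                                  subsample_cap = 500L, seed = 1L) {
  det_pre <- variants$pre_vaf >= detect_vaf
  det_post <- variants$post_vaf >= detect_vaf
  cov60 <- pmax(variants$pre_depth, variants$post_depth) >= min_coverage
  coverage60 <- det_pre & det_post & cov60
  rescue <- xor(det_pre, det_post)
  driver <- !is.na(variants$gene) & variants$gene %in% drivers
  included <- coverage60 | rescue | driver
  reason <- rep(NA_character_, nrow(variants))
  reason[driver] <- "driver"
  reason[rescue] <- "low_vaf_rescue"
  reason[coverage60] <- "coverage60"
  out <- variants[included, , drop = FALSE]
  out$inclusion_reason <- reason[included]
  if (nrow(out) > subsample_cap) {
    keep_driver <- which(out$inclusion_reason == "driver" |
                           (!is.na(out$gene) & out$gene %in% drivers))
    pool <- setdiff(seq_len(nrow(out)), keep_driver)
    n_draw <- subsample_cap - length(keep_driver)
    drawn <- withr_seed(seed, sample(pool, max(n_draw, 0L)))
    out <- out[sort(c(keep_driver, drawn)), , drop = FALSE]
  }
  out
}

# ---- binomial-mixture EM ----------------------------------------------------

#' Clustering parameters for the binomial-mixture clone model
#'
#' @param max_clusters Largest number of clusters tried (default 8).
#' @param restarts Seeded initialisations per cluster count (default 20).
#' @param max_iterations EM iteration cap (default 500).
#' @param tolerance Relative log-likelihood convergence tolerance
#'   (default 1e-6).
#' @param subsample_cap Hypermutator subsample size (default 500).
#' @param min_cluster_size Smallest cluster considered when looking for
#'   an expanding minor clone (default 5).
#' @param seed Integer seed.
#' @return List of class `cluster_params`.
#' @export
cluster_params <- function(max_clusters = 8L, restarts = 20L,
                           max_iterations = 500L, tolerance = 1e-6,
                           subsample_cap = 500L, min_cluster_size = 5L,
                           seed = 1L) {
  stopifnot(max_clusters >= 1, restarts >= 1, max_iterations >= 1,
            tolerance > 0)
  structure(as.list(environment()), class = "cluster_params")
}

# One EM run at fixed K. `f_pre`/`f_post` map CCF to expected VAF per
# variant (purity and copy number absorbed); centers live on CCF scale.
# The log-likelihood omits the binomial coefficients (constant in the
# parameters); `const` restores the absolute value for BIC reporting.
em_binom_pair <- function(alt_pre, dp_pre, alt_post, dp_post,
                          f_pre, f_post, centers, max_iter, tol,
                          const = 0) {
  n <- length(alt_pre)
  K <- nrow(centers)
  w <- rep(1 / K, K)
  cap <- 0.999
  ref_pre <- dp_pre - alt_pre
  ref_post <- dp_post - alt_post
  ll <- matrix(0, n, K)
  loglik <- ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    for (k in seq_len(K)) {
      p1 <- pmin(pmax(f_pre * centers[k, 1L], 1e-6), cap)
      p2 <- pmin(pmax(f_post * centers[k, 2L], 1e-6), cap)
      ll[, k] <- log(w[k]) + alt_pre * log(p1) + ref_pre * log1p(-p1) +
        alt_post * log(p2) + ref_post * log1p(-p2)
    }
    mx <- ll[cbind(seq_len(n), max.col(ll, ties.method = "first"))]
    r <- exp(ll - mx)
    rs <- rowSums(r)
    loglik <- sum(mx + log(rs))
    r <- r / rs
    w <- pmax(colMeans(r), 1e-12)
    w <- w / sum(w)
    centers[, 1L] <- pmin(1.5, crossprod(r, alt_pre) /
                            pmax(crossprod(r, dp_pre * f_pre), 1e-12))
    centers[, 2L] <- pmin(1.5, crossprod(r, alt_post) /
                            pmax(crossprod(r, dp_post * f_post), 1e-12))
    if (is.finite(ll_old) && abs(loglik - ll_old) < tol * (abs(ll_old) + 1)) {
      break
    }
    ll_old <- loglik
  }
  assign <- max.col(ll, ties.method = "first")
  list(centers = centers, weights = w, loglik = loglik + const,
       assign = assign)
}

#' Cluster shared mutations into clones across the pre/post pair
#'
#' Fits a finite mixture of paired binomials to the (pre, post) alt-read
#' counts: each cluster has a joint (CCF_pre, CCF_post) center, and each
#' mutation's expected VAF is the center scaled by its purity/copy-number
#' factor. The number of clusters is chosen by BIC over
#' `1..max_clusters` (stopping early once BIC has worsened twice), with
#' `restarts` seeded initialisations per candidate. Deterministic given
#' the seed in `params`.
#'
#' @param records Included mutations from [select_for_clustering()].
#' @param purity_pre,purity_post Sample purities.
#' @param params A [cluster_params()].
#' @return List of class `clone_clusters`: `clusters` data frame
#'   (`cluster`, `center_pre`, `center_post`, `size`), `assignment`
#'   vector, `K`, `bic` table, `loglik`.
#' @export
cluster_clones <- function(records, purity_pre, purity_post,
                           params = cluster_params()) {
  n <- nrow(records)
  if (n < 5L) stop("not clusterable: fewer than 5 included mutations")
  f_pre <- expected_vaf(1, purity_pre, records$total_cn)
  f_post <- expected_vaf(1, purity_post, records$total_cn)
  ccf0 <- cbind(pmin(records$pre_vaf / f_pre, 1.5),
                pmin(records$post_vaf / f_post, 1.5))

  const <- sum(lchoose(records$pre_depth, records$pre_alt) +
                 lchoose(records$post_depth, records$post_alt))
  n_distinct <- nrow(unique(ccf0))

  withr_seed(params$seed, {
    best <- NULL
    bic_tab <- data.frame(K = integer(), bic = numeric())
    worse <- 0L
    for (K in seq_len(params$max_clusters)) {
      if (K > n) break
      best_k <- NULL
      for (rs in seq_len(params$restarts)) {
        init <- if (rs == 1L && K > 1L && n_distinct >= K) {
          km <- suppressWarnings(stats::kmeans(ccf0, centers = K,
                                               nstart = 1L, iter.max = 25L))
          km$centers
        } else if (K == 1L) {
          matrix(colMeans(ccf0), 1L, 2L)
        } else {
          ccf0[sample.int(n, K), , drop = FALSE] +
            matrix(stats::runif(2L * K, -0.02, 0.02), K, 2L)
        }
        init <- pmin(pmax(init, 0), 1.5)
        # short run per restart; the winner is polished to full tolerance
        fit <- em_binom_pair(records$pre_alt, records$pre_depth,
                             records$post_alt, records$post_depth,
                             f_pre, f_post, init,
                             max_iter = 40L, tol = 1e-4, const = const)
        if (is.null(best_k) || fit$loglik > best_k$loglik) best_k <- fit
      }
      best_k <- em_binom_pair(records$pre_alt, records$pre_depth,
                              records$post_alt, records$post_depth,
                              f_pre, f_post, best_k$centers,
                              max_iter = params$max_iterations,
                              tol = params$tolerance, const = const)
      bic <- -2 * best_k$loglik + (3 * K - 1) * log(n)
      bic_tab <- rbind(bic_tab, data.frame(K = K, bic = bic))
      if (is.null(best) || bic < best$bic) {
        best <- c(best_k, list(bic = bic, K = K))
        worse <- 0L
      } else {
        worse <- worse + 1L
        if (worse >= 2L) break
      }
    }
    sizes <- tabulate(best$assign, nbins = best$K)
    keep <- which(sizes > 0L)
    # canonical cluster order: decreasing pre-center, then post-center
    keep <- keep[order(-best$centers[keep, 1L], -best$centers[keep, 2L])]
    relabel <- match(best$assign, keep)
    clusters <- data.frame(cluster = seq_along(keep),
                           center_pre = best$centers[keep, 1L],
                           center_post = best$centers[keep, 2L],
                           size = sizes[keep])
    structure(list(clusters = clusters, assignment = relabel,
                   K = length(keep), bic = bic_tab, loglik = best$loglik),
              class = "clone_clusters")
  })
}

# ---- trajectories and sampling effects -------------------------------------

#' Classify a mutation's pre/post trajectory
#'
#' A mutation is detected in a sample when its VAF is at or above the
#' detection floor; `pre_only` means detected pre but not post (a loss),
#' `post_only` the reverse (a gain), `shared` otherwise.
#'
#' @param pre_vaf,post_vaf VAFs in `[0, 1]`. Vectorised.
#' @param detection_floor Detection VAF floor (default 0.02).
#' @return Character vector over `c("pre_only", "post_only", "shared")`.
#' @export
classify_trajectory <- function(pre_vaf, post_vaf, detection_floor = 0.02) {
  det_pre <- pre_vaf >= detection_floor
  det_post <- post_vaf >= detection_floor
  out <- rep("shared", length(det_pre))
  out[det_pre & !det_post] <- "pre_only"
  out[!det_pre & det_post] <- "post_only"
  out
}

#' Probability that a mutation loss is a read-sampling effect
#'
#' Returns `P(alt reads < min_alt | Binomial(post_depth, pre_vaf))`: the
#' probability the mutation would be missed in the post-treatment sample
#' purely by sampling if its underlying frequency were unchanged. A loss
#' is deemed not explainable by sampling when this probability falls
#' below `alpha` (applied by the caller; default 0.01 in the
#' classification pipeline). Monotone decreasing in `pre_vaf` and in
#' `post_depth`.
#'
#' @param pre_vaf Pre-treatment VAF(s).
#' @param post_depth Post-treatment read depth(s), `>= 1`.
#' @param min_alt Alt-read detection threshold (default 4).
#' @return Probabilities in `[0, 1]`. Vectorised.
#' @export
sampling_loss_probability <- function(pre_vaf, post_depth, min_alt = 4L) {
  stopifnot(all(post_depth >= 1))
  stats::pbinom(min_alt - 1L, post_depth, pre_vaf)
}

#' Count discordant same-gene driver mutation sets
#'
#' A gene contributes when one patient carries at least
#' `polyclonal_min_muts` distinct somatic mutations in it whose
#' trajectories are discordant: at least one lost (`pre_only`) and at
#' least one shared or gained. Multiple independent driver mutations in
#' one gene behaving discordantly are the hallmark of polyclonality.
#'
#' @param genes Gene symbol per driver mutation.
#' @param trajectories Trajectory per mutation (from
#'   [classify_trajectory()]).
#' @param polyclonal_min_muts Minimum distinct mutations per gene
#'   (default 3).
#' @return Integer count of discordant same-gene driver sets.
#' @export
detect_polyclonality <- function(genes, trajectories,
                                 polyclonal_min_muts = 3L) {
  keep <- !is.na(genes)
  genes <- genes[keep]; trajectories <- trajectories[keep]
  if (!length(genes)) return(0L)
  count <- 0L
  for (g in unique(genes)) {
    tr <- trajectories[genes == g]
    if (length(tr) >= polyclonal_min_muts &&
        any(tr == "pre_only") && any(tr %in% c("shared", "post_only"))) {
      count <- count + 1L
    }
  }
  count
}

#' Coefficient of variation of pre-treatment VAFs
#'
#' A simple scalar measure of genetic diversity: `sd(vaf) / mean(vaf)`.
#'
#' @param vaf At least two VAFs.
#' @return The coefficient of variation.
#' @export
vaf_cv <- function(vaf) {
  vaf <- vaf[!is.na(vaf)]
  if (length(vaf) < 2L) stop("not computable: fewer than 2 VAFs")
  stats::sd(vaf) / mean(vaf)
}

#' Concordance of mutation presence between two samples of one tumour
#'
#' Over a universe of assessed sites (by default the union of the two
#' mutation sets), the proportion of sites concordantly present in or
#' absent from both samples, after removing mutations in `exclude_genes`
#' (e.g. genes known to be frequently polyclonal).
#'
#' @param sample_a,sample_b Data frames with `key` (site identifier) and
#'   optional `gene` columns, or bare character vectors of keys.
#' @param exclude_genes Genes removed before assessment.
#' @param universe Optional character vector of assessed site keys.
#' @return Proportion concordant in `[0, 1]`.
#' @export
spatial_concordance <- function(sample_a, sample_b,
                                exclude_genes = character(0),
                                universe = NULL) {
  get_keys <- function(x) {
    if (is.data.frame(x)) {
      keep <- if (!is.null(x$gene)) !(x$gene %in% exclude_genes) else TRUE
      x$key[keep]
    } else x
  }
  a <- unique(get_keys(sample_a))
  b <- unique(get_keys(sample_b))
  if (is.null(universe)) universe <- union(a, b)
  universe <- unique(universe)
  if (!length(universe)) stop("not computable: empty assessed-site universe")
  conc <- sum((universe %in% a) == (universe %in% b))
  conc / length(universe)
}

# ---- per-patient classification --------------------------------------------

#' Thresholds for evolution classification
#'
#' Explicit, configurable stand-ins for the study's qualitative criteria:
#' "not at low VAFs" is a pre-VAF of at least `high_vaf`; a "non-trivial
#' number" of shared mutations is `min_shared`; an "uncommon clone" has
#' pre-CCF at most `minor_ccf_pre` and expands to post-CCF at least
#' `major_ccf_post`.
#'
#' @param high_vaf Pre-VAF boundary for a "high-VAF" mutation (0.10).
#' @param lost_fraction Minimum fraction of high-VAF mutations lost (and
#'   not explainable by sampling) for a bottleneck (0.25).
#' @param min_shared Minimum shared mutations for a bottleneck (20).
#' @param minor_ccf_pre,major_ccf_post Expanding-minor-clone bounds
#'   (0.3, 0.5). The pre-treatment bound is calibrated on the simulator:
#'   minor-clone pre-CCF estimates carry an upward bias from detection
#'   conditioning and purity estimation error, so the boundary sits
#'   above the nominal "uncommon" level while remaining far below
#'   clonal.
#' @param minor_ccf_min Minimum pre-treatment CCF for a clone to count
#'   as present (0.02): a cluster absent before therapy is a gained
#'   clone, not an expanding one.
#' @param sampling_alpha Sampling-loss probability below which a loss is
#'   not explainable by sampling (0.01).
#' @param detection_floor VAF detection floor (0.02).
#' @param polyclonal_min_muts Same-gene driver mutations required (3).
#' @param hypermutator_burden Pre-treatment burden above which a patient
#'   counts as hypermutated (2000).
#' @param hyper_min_lost,hyper_min_gained High-VAF losses and gains
#'   required for the hypermutator polyclonality route (5, 5).
#' @return List of class `evolution_thresholds`.
#' @export
evolution_thresholds <- function(high_vaf = 0.10, lost_fraction = 0.25,
                                 min_shared = 20L, minor_ccf_pre = 0.3,
                                 major_ccf_post = 0.5, minor_ccf_min = 0.02,
                                 sampling_alpha = 0.01,
                                 detection_floor = 0.02,
                                 polyclonal_min_muts = 3L,
                                 hypermutator_burden = 2000L,
                                 hyper_min_lost = 5L, hyper_min_gained = 5L) {
  structure(as.list(environment()), class = "evolution_thresholds")
}

#' Compute per-patient evolution metrics
#'
#' @param variants Retained paired variant table.
#' @param clusters A `clone_clusters` object or `NULL`.
#' @param drivers Driver gene symbols.
#' @param thresholds An [evolution_thresholds()].
#' @param min_cluster_size Smallest cluster eligible as the expanding
#'   minor clone (default 5).
#' @return List of metrics consumed by [classify_evolution()].
#' @export
evolution_metrics <- function(variants, clusters, drivers = character(0),
                              thresholds = evolution_thresholds(),
                              min_cluster_size = 5L) {
  tr <- classify_trajectory(variants$pre_vaf, variants$post_vaf,
                            thresholds$detection_floor)
  loss_p <- sampling_loss_probability(variants$pre_vaf, variants$post_depth)
  unexplained_loss <- tr == "pre_only" & loss_p < thresholds$sampling_alpha
  high <- variants$pre_vaf >= thresholds$high_vaf
  lost_high_vaf_fraction <- if (any(high)) {
    sum(unexplained_loss & high) / sum(high)
  } else 0
  is_driver <- !is.na(variants$gene) & variants$gene %in% drivers
  expanding <- FALSE
  if (!is.null(clusters)) {
    cl <- clusters$clusters
    expanding <- any(cl$size >= min_cluster_size &
                       cl$center_pre >= thresholds$minor_ccf_min &
                       cl$center_pre <= thresholds$minor_ccf_pre &
                       cl$center_post >= thresholds$major_ccf_post)
  }
  pre_burden <- sum(variants$pre_vaf >= thresholds$detection_floor)
  list(
    lost_high_vaf_fraction = lost_high_vaf_fraction,
    shared_count = sum(tr == "shared" &
                         variants$pre_vaf >= thresholds$detection_floor),
    expanding_minor_clone = expanding,
    discordant_same_gene_drivers = detect_polyclonality(
      ifelse(is_driver, variants$gene, NA_character_), tr,
      thresholds$polyclonal_min_muts),
    pre_burden = pre_burden,
    post_burden = sum(variants$post_vaf >= thresholds$detection_floor),
    hypermutator = pre_burden > thresholds$hypermutator_burden,
    n_lost_high_unexplained = sum(unexplained_loss & high),
    n_gained_high = sum(tr == "post_only" &
                          variants$post_vaf >= thresholds$high_vaf))
}

#' Classify a patient's clonal evolution
#'
#' Decision rule, applied in order: `excluded` when the QC decision
#' excludes the post-treatment sample; `polyclonal` when any discordant
#' same-gene driver set exists, or a hypermutated cancer loses and gains
#' mutations across the VAF spectrum; `bottleneck` when a substantial
#' fraction of high-VAF mutations is lost beyond sampling expectation,
#' a non-trivial number of mutations is shared, and an uncommon
#' pre-treatment clone expands to dominate the post-treatment sample;
#' `stable` otherwise.
#'
#' @param metrics From [evolution_metrics()].
#' @param qc A `qc_decision` (or `NULL` for a QC-passing patient).
#' @param thresholds An [evolution_thresholds()].
#' @return List of class `evolution_call`: `category`, `metrics`,
#'   `thresholds`.
#' @export
classify_evolution <- function(metrics, qc = NULL,
                               thresholds = evolution_thresholds()) {
  category <- if (!is.null(qc) && isTRUE(qc$excluded)) {
    "excluded"
  } else if (metrics$discordant_same_gene_drivers > 0L ||
             (metrics$hypermutator &&
              metrics$n_lost_high_unexplained >= thresholds$hyper_min_lost &&
              metrics$n_gained_high >= thresholds$hyper_min_gained)) {
    "polyclonal"
  } else if (metrics$lost_high_vaf_fraction >= thresholds$lost_fraction &&
             metrics$shared_count >= thresholds$min_shared &&
             metrics$expanding_minor_clone) {
    "bottleneck"
  } else {
    "stable"
  }
  structure(list(category = category, metrics = metrics,
                 thresholds = thresholds), class = "evolution_call")
}

#' Run the per-patient clonal-dynamics pipeline
#'
#' Filters the paired variant table, estimates purities, applies the QC
#' exclusion rule, selects and clusters shared mutations, computes the
#' evolution metrics and classifies the patient.
#'
#' @param variants Raw paired variant table (e.g. from
#'   [read_variants()]).
#' @param histology_content_post Histological tumour content of the
#'   post-treatment sample (`NA` if unknown).
#' @param drivers Driver gene symbols (defaults to the shipped list).
#' @param filter_p A [filter_params()].
#' @param cl_params A [cluster_params()].
#' @param thresholds An [evolution_thresholds()].
#' @param preservation Sample preservation, `"ff"` or `"ffpe"`.
#' @return List: `call` (`evolution_call`), `qc`, `clusters`,
#'   `purity_pre`, `purity_post`, `retained` variant table.
#' @export
classify_patient <- function(variants, histology_content_post = NA_real_,
                             drivers = driver_genes(),
                             filter_p = filter_params(),
                             cl_params = cluster_params(),
                             thresholds = evolution_thresholds(),
                             preservation = "ff") {
  retained <- filter_variants(variants, filter_p, preservation)
  det_pre <- retained$pre_vaf >= thresholds$detection_floor
  det_post <- retained$post_vaf >= thresholds$detection_floor
  purity_pre <- suppressWarnings(
    estimate_purity(retained$pre_vaf[det_pre], retained$total_cn[det_pre]))
  purity_post <- suppressWarnings(
    estimate_purity(retained$post_vaf[det_post],
                    retained$total_cn[det_post]))
  qc <- assess_exclusion("patient", purity_pre, purity_post,
                         histology_content_post,
                         pre_burden = sum(det_pre),
                         post_burden = sum(det_post))
  included <- select_for_clustering(retained, drivers,
                                    subsample_cap = cl_params$subsample_cap,
                                    seed = cl_params$seed)
  clusters <- if (nrow(included) >= 5L && !is.na(purity_pre) &&
                  !is.na(purity_post)) {
    cluster_clones(included, purity_pre, purity_post, cl_params)
  } else NULL
  metrics <- evolution_metrics(retained, clusters, drivers, thresholds,
                               cl_params$min_cluster_size)
  call <- classify_evolution(metrics, qc, thresholds)
  list(call = call, qc = qc, clusters = clusters,
       purity_pre = purity_pre, purity_post = purity_post,
       retained = retained)
}

#' Driver genes of oesophageal adenocarcinoma
#'
#' The shipped, user-replaceable driver list seeded from recurrently
#' mutated EAC genes.
#'
#' @param path Optional path to a one-symbol-per-line replacement file.
#' @return Character vector of gene symbols.
#' @export
driver_genes <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "eac_driver_genes.txt",
                        package = "neoclone")
  }
  readLines(path)
}
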