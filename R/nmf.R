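# Nonnegative matrix factorisation of mutation count matrices.
#
# The observed 96-channel counts V (channels x samples) are decomposed as
# V ~ W H with W >= 0 (96 x r signatures) and H >= 0 (r x samples
# exposures), by multiplicative updates minimising the Frobenius error.

#' Fit mutational signatures by NMF
#'
#' Decomposes a sample-by-96 count matrix into `r` nonnegative signatures
#' and per-sample exposures using Lee-Seung multiplicative updates under
#' the Frobenius objective. The best of `restarts` seeded random
#' initialisations is kept; signature columns are normalised to sum to 1
#' post hoc with exposures rescaled to compensate.
#'
#' @param count_matrix Numeric matrix, samples in rows, 96 channels in
#'   columns (a transposed channels-by-samples matrix is also accepted).
#' @param r Number of signatures, `>= 1` and at most the number of samples.
#' @param seed Integer seed; each restart derives its own stream from it.
#' @param restarts Number of random initialisations (default 10).
#' @param max_iter,tol Update loop limits (relative error change).
#' @return List of class `signature_model`: `r`, `signatures` (96 x r,
#'   column-stochastic), `exposures` (r x samples), `reconstruction_error`
#'   (relative Frobenius error), and `error_trace` of the winning restart.
#' @export
fit_signatures <- function(count_matrix, r, seed = 1L, restarts = 10L,
                           max_iter = 2000L, tol = 1e-9) {
  V <- as.matrix(count_matrix)
  if (ncol(V) != 96L && nrow(V) == 96L) V <- t(V)
  if (ncol(V) != 96L) stop("count_matrix must have 96 channels")
  keep <- rowSums(V) > 0
  if (r < 1L) stop("r must be >= 1")
  if (sum(keep) < r) stop("r exceeds the number of samples with mutations")
  V <- t(V)  # channels x samples
  n <- ncol(V)
  vnorm <- sqrt(sum(V^2))
  eps <- 1e-12

  best <- NULL
  for (rs in seq_len(restarts)) {
    res <- withr_seed(seed + 7919L * (rs - 1L), {
      W <- matrix(stats::runif(96L * r, 0.1, 1), 96L, r)
      H <- matrix(stats::runif(r * n, 0.1, 1), r, n)
      trace <- numeric(0)
      err_prev <- Inf
      for (it in seq_len(max_iter)) {
        H <- H * (crossprod(W, V) / (crossprod(W, W %*% H) + eps))
        W <- W * (V %*% t(H) / (W %*% tcrossprod(H) + eps))
        err <- sqrt(sum((V - W %*% H)^2)) / vnorm
        trace <- c(trace, err)
        if (is.finite(err_prev) && err_prev - err < tol * max(err_prev, 1e-30)) break
        err_prev <- err
      }
      list(W = W, H = H, err = err, trace = trace)
    })
    if (is.null(best) || res$err < best$err) best <- res
  }

  scale <- colSums(best$W)
  scale[scale == 0] <- 1
  W <- sweep(best$W, 2L, scale, "/")
  H <- sweep(best$H, 1L, scale, "*")
  colnames(W) <- rownames(H) <- paste0("S", seq_len(r))
  rownames(W) <- channel_names()
  structure(list(r = r, signatures = W, exposures = H,
                 reconstruction_error = best$err, error_trace = best$trace),
            class = "signature_model")
}

cosine_sim <- function(x, y) {
  nx <- sqrt(sum(x^2)); ny <- sqrt(sum(y^2))
  if (nx == 0 || ny == 0) return(0)
  sum(x * y) / (nx * ny)
}

min_pairwise_cosine_distance <- function(W) {
  r <- ncol(W)
  if (r < 2L) return(NA_real_)
  d <- Inf
  for (i in seq_len(r - 1L)) {
    for (j in (i + 1L):r) {
      d <- min(d, 1 - cosine_sim(W[, i], W[, j]))
    }
  }
  d
}

#' Choose the number of signatures by maximum differentiation
#'
#' Automates the "maximum differentiation between signatures" rule.
#' Admissible ranks are those whose reconstruction error sits near the
#' achievable floor (within `elbow_frac` of the error range across the
#' candidate ranks) — a rank below the elbow blends distinct processes
#' and cannot claim differentiated signatures. Among admissible ranks,
#' the one whose fitted signatures have the largest minimum pairwise
#' cosine distance is selected: adding a signature beyond the true rank
#' duplicates or splits an existing profile and collapses that minimum
#' distance. Ranks whose minimum distance falls below `distance_floor`
#' (effectively duplicated columns) are not eligible; if no rank is
#' eligible the data carry no evidence of multiple separated processes
#' and the smallest candidate rank is returned.
#'
#' @param models List of `signature_model` objects at increasing ranks
#'   (typically r = 2..8 on the same data).
#' @param elbow_frac Admissibility tolerance as a fraction of the error
#'   range (default 0.35: a blended under-fit sits at the top of the
#'   range, ratio near 1, so it stays excluded, while the true rank's
#'   small noise-absorption gap above the floor stays admissible).
#' @param distance_floor Minimum pairwise cosine distance below which a
#'   model's signatures count as degenerate (default 0.1).
#' @return List: `r` (selected rank), `criteria` data frame with per-rank
#'   reconstruction error and min pairwise cosine distance, and
#'   `admissible` ranks.
#' @export
select_rank <- function(models, elbow_frac = 0.35, distance_floor = 0.1) {
  if (length(models) < 2L) stop("need >= 2 fitted models")
  rs <- vapply(models, function(m) m$r, numeric(1))
  o <- order(rs)
  models <- models[o]; rs <- rs[o]
  err <- vapply(models, function(m) m$reconstruction_error, numeric(1))
  sep <- vapply(models, function(m) min_pairwise_cosine_distance(m$signatures),
                numeric(1))
  cutoff <- min(err) + elbow_frac * (max(err) - min(err))
  admissible <- rs[err <= cutoff]
  crit <- data.frame(r = rs, reconstruction_error = err,
                     min_pairwise_cosine_distance = sep,
                     admissible = rs %in% admissible)
  cand <- which(crit$admissible & crit$min_pairwise_cosine_distance >=
                  distance_floor)
  sel <- if (length(cand)) {
    cand[which.max(crit$min_pairwise_cosine_distance[cand])]
  } else 1L
  list(r = crit$r[sel], criteria = crit, admissible = admissible)
}

#' Predominant signature per sample
#'
#' Labels each sample with the signature carrying its largest exposure
#' share. Samples whose total mutation count is below `min_mutations` are
#' labelled `NA` (not assessable), mirroring the exclusion of low-burden
#' samples from signature assignment. Exposure ties break to the lowest
#' signature index.
#'
#' @param model A `signature_model`.
#' @param totals Optional per-sample mutation totals (defaults to column
#'   sums of the reconstructed exposures).
#' @param min_mutations Minimum burden for assessment (default 50).
#' @return Character vector of signature labels (`"S1"`, ...), `NA` where
#'   not assessable.
#' @export
predominant_signature <- function(model, totals = NULL, min_mutations = 50L) {
  H <- model$exposures
  if (is.null(totals)) totals <- colSums(H)
  lab <- rownames(H)[apply(H, 2L, which.max)]
  lab[totals < min_mutations] <- NA_character_
  lab
}

#' Did the predominant signature change between two samples?
#'
#' @param pre_label,post_label Labels from [predominant_signature()].
#' @return `TRUE` iff both are assessable and differ. Vectorised.
#' @export
signature_change <- function(pre_label, post_label) {
  !is.na(pre_label) & !is.na(post_label) & pre_label != post_label
}
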