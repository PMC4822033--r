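# Arm-scale somatic copy number analysis from logR values: MAD
# winsorization, penalized least-squares segmentation, threshold calls,
# arm events and pre/post sharing.

#' Winsorize logR values by the median absolute deviation
#'
#' Values beyond `median +- k * MAD` are clamped to the bound; the order
#' and length of the input are preserved. With fewer than 3 values the
#' input is returned unchanged with a warning.
#'
#' @param values Numeric logR values.
#' @param k MAD multiplier (default 2.5).
#' @return Winsorized values.
#' @export
winsorize_logr <- function(values, k = 2.5) {
  if (length(values) < 3L) {
    warning("fewer than 3 values: winsorization skipped")
    return(values)
  }
  med <- stats::median(values)
  mad <- stats::mad(values)
  if (mad == 0) return(values)
  pmin(pmax(values, med - k * mad), med + k * mad)
}

#' Segment logR values by penalized least squares
#'
#' Finds the piecewise-constant fit minimising
#' `sum((x - fit)^2) / sigma^2 + gamma * (number of breakpoints)` by
#' dynamic programming, exactly. The noise scale `sigma` is estimated
#' from the median absolute successive difference (divided by
#' `sqrt(2) * qnorm(3/4)`), so the penalty `gamma` applies on a
#' noise-standardised scale; `gamma = 1000` gives arm-scale segments at
#' typical array noise. Segmentation is per chromosome and deterministic.
#'
#' @param positions Integer positions, sorted increasing within
#'   chromosome.
#' @param logr logR value per position.
#' @param gamma Breakpoint penalty on the standardised scale
#'   (default 1000).
#' @param chrom Optional chromosome per position (segments never span
#'   chromosomes).
#' @param sigma Noise sd; estimated from the data when `NULL`.
#' @return Data frame of class `scna_segments`: `chrom`, `start`, `end`,
#'   `n_probes`, `logr` (segment mean).
#' @export
segment_logr <- function(positions, logr, gamma = 1000, chrom = NULL,
                         sigma = NULL) {
  stopifnot(length(positions) == length(logr))
  if (is.null(chrom)) chrom <- rep("1", length(positions))
  chrom <- as.character(chrom)
  out <- lapply(unique(chrom), function(ch) {
    idx <- which(chrom == ch)
    pos <- positions[idx]
    if (is.unsorted(pos, strictly = FALSE)) {
      stop("positions must be sorted within chromosome ", ch)
    }
    x <- logr[idx]
    s <- if (is.null(sigma)) estimate_logr_sigma(x) else sigma
    seg <- pcf_dp(x, gamma * s^2)
    data.frame(chrom = ch,
               start = pos[seg$start], end = pos[seg$end],
               n_probes = seg$end - seg$start + 1L, logr = seg$mean)
  })
  res <- do.call(rbind, out)
  class(res) <- c("scna_segments", "data.frame")
  res
}

estimate_logr_sigma <- function(x) {
  if (length(x) < 2L) return(1)
  d <- abs(diff(x))
  s <- stats::median(d) / (sqrt(2) * stats::qnorm(0.75))
  if (s <= 0) s <- max(stats::sd(x), 1e-6)
  s
}

# Exact optimal partition by dynamic programming. Cost of a candidate
# segment is its residual sum of squares (via prefix sums); each
# additional segment pays `penalty`.
pcf_dp <- function(x, penalty) {
  n <- length(x)
  cs <- c(0, cumsum(x))
  cs2 <- c(0, cumsum(x^2))
  sse <- function(i, j) {
    s <- cs[j + 1L] - cs[i]
    (cs2[j + 1L] - cs2[i]) - s^2 / (j - i + 1L)
  }
  F <- c(0, rep(Inf, n))  # F[j+1] = optimal cost of x[1..j]
  back <- integer(n)
  for (j in seq_len(n)) {
    i <- seq_len(j)
    s <- cs[j + 1L] - cs[i]
    costs <- (cs2[j + 1L] - cs2[i]) - s^2 / (j - i + 1L)
    tot <- F[i] + costs + penalty
    best <- which.min(tot)
    F[j + 1L] <- tot[best]
    back[j] <- best
  }
  ends <- integer(0)
  j <- n
  while (j > 0L) {
    ends <- c(j, ends)
    j <- back[j] - 1L
  }
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  means <- vapply(seq_along(starts), function(k) {
    mean(x[starts[k]:ends[k]])
  }, numeric(1))
  list(start = starts, end = ends, mean = means)
}

#' Call gains and losses on segments
#'
#' Gain when the segment mean exceeds `+threshold`, loss when below
#' `-threshold`; the boundary itself is neutral (strict inequalities).
#'
#' @param segments Data frame with a `logr` column.
#' @param threshold logR call threshold (default 0.15).
#' @return The segments with a `call` column in
#'   `c("gain", "loss", "neutral")`.
#' @export
call_segments <- function(segments, threshold = 0.15) {
  segments$call <- ifelse(segments$logr > threshold, "gain",
                          ifelse(segments$logr < -threshold, "loss",
                                 "neutral"))
  segments
}

#' Call copy number changes from absolute-copy-number segments
#'
#' Alternative input path for segment tables carrying absolute copy
#' number: a change is called where the segment copy number differs from
#' the genome-wide (probe-weighted) mean by more than `delta`.
#'
#' @param segments Data frame with `copy_number` and `n_probes` columns.
#' @param delta Call threshold on the absolute difference (default 1).
#' @return The segments with a `call` column.
#' @export
call_absolute_cn <- function(segments, delta = 1) {
  mu <- stats::weighted.mean(segments$copy_number, segments$n_probes)
  dev <- segments$copy_number - mu
  segments$call <- ifelse(dev > delta, "gain",
                          ifelse(dev < -delta, "loss", "neutral"))
  segments
}

#' Derive arm-scale events from called segments
#'
#' For each chromosome arm and direction, sums the length of
#' same-direction called segments overlapping the arm; an event is
#' emitted iff the covered fraction of the arm exceeds one half
#' ("large SCNA"). Segments outside every arm are ignored with a
#' warning.
#'
#' @param segments Called segments (`chrom`, `start`, `end`, `call`).
#' @param arm_table Arm coordinates (`chrom`, `arm`, `start`, `end`),
#'   e.g. [synthetic_arm_table()] or a cytoband-derived table.
#' @param min_fraction Covered-fraction threshold (default 0.5, strict).
#' @return Data frame of `ArmEvent`s: `arm`, `direction`,
#'   `covered_fraction`.
#' @export
arm_events <- function(segments, arm_table, min_fraction = 0.5) {
  seg <- segments[segments$call %in% c("gain", "loss"), , drop = FALSE]
  events <- list()
  covered_any <- rep(FALSE, nrow(seg))
  for (i in seq_len(nrow(arm_table))) {
    a <- arm_table[i, ]
    onchrom <- seg$chrom == a$chrom
    ov_start <- pmax(seg$start, a$start)
    ov_end <- pmin(seg$end, a$end)
    ov <- onchrom & ov_start <= ov_end
    covered_any <- covered_any | ov
    if (!any(ov)) next
    arm_len <- a$end - a$start + 1
    for (dir in c("gain", "loss")) {
      sel <- ov & seg$call == dir
      if (!any(sel)) next
      frac <- sum(ov_end[sel] - ov_start[sel] + 1) / arm_len
      if (frac > min_fraction) {
        events[[length(events) + 1L]] <-
          data.frame(arm = a$arm, direction = dir, covered_fraction = frac)
      }
    }
  }
  if (nrow(seg) && !all(covered_any)) {
    warning(sum(!covered_any), " called segment(s) outside every arm; ignored")
  }
  if (!length(events)) {
    return(data.frame(arm = character(), direction = character(),
                      covered_fraction = numeric()))
  }
  do.call(rbind, events)
}

#' Fraction of arm-scale events shared between two samples
#'
#' Sharing is defined on (arm, direction) identity:
#' `|intersection| / |union|`. Symmetric; undefined when both sets are
#' empty.
#'
#' @param events_pre,events_post Arm-event data frames from
#'   [arm_events()] (columns `arm`, `direction`).
#' @return Proportion in `[0, 1]`.
#' @export
shared_fraction <- function(events_pre, events_post) {
  key <- function(ev) {
    if (!nrow(ev)) character(0)
    else unique(paste(ev$arm, ev$direction, sep = ":"))
  }
  a <- key(events_pre); b <- key(events_post)
  u <- union(a, b)
  if (!length(u)) stop("not computable: both event sets are empty")
  length(intersect(a, b)) / length(u)
}
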