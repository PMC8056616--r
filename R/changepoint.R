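#' Segmentation configuration
#'
#' Tuning parameters of the exponential-likelihood binary-segmentation
#' changepoint detector used on per-base exon coverage.
#'
#' @param penalty_multiplier Positive real; a split is accepted only when its
#'   cost reduction exceeds `penalty_multiplier * log(n)` where n is the
#'   length of the full input vector. Default 3 (an MBIC-flavoured setting).
#' @param min_segment_length Minimum segment length in bases (>= 2); default
#'   20, which suppresses single-base artifacts in noisy coverage.
#' @param pseudocount Positive real added to every depth before likelihood
#'   evaluation; RNA-Seq coverage contains zeros, which an exponential
#'   likelihood cannot score. A constant shift preserves trough geometry.
#'   Default 1.
#' @param max_depth_of_recursion Maximum binary-segmentation recursion depth;
#'   default 10.
#' @param trough_drop_ratio Real in (0, 1); an interior segment qualifies as
#'   a trough only if its mean falls to at most this fraction of both
#'   flanking segment means. Default 0.2.
#' @return An object of class `segmentation_config`.
#' @export
segmentation_config <- function(penalty_multiplier = 3,
                                min_segment_length = 20L,
                                pseudocount = 1,
                                max_depth_of_recursion = 10L,
                                trough_drop_ratio = 0.2) {
  stopifnot(penalty_multiplier > 0,
            min_segment_length >= 2,
            pseudocount > 0,
            max_depth_of_recursion >= 1,
            trough_drop_ratio > 0, trough_drop_ratio < 1)
  structure(list(penalty_multiplier = penalty_multiplier,
                 min_segment_length = as.integer(min_segment_length),
                 pseudocount = pseudocount,
                 max_depth_of_recursion = as.integer(max_depth_of_recursion),
                 trough_drop_ratio = trough_drop_ratio),
            class = "segmentation_config")
}

#' Exponential segment cost
#'
#' Twice the negative exponential log-likelihood of a segment at its
#' maximum-likelihood rate, with the segmentation-invariant additive constant
#' 2n dropped: `C(x) = 2 n log(sum(x)/n)`. Permutation-invariant.
#'
#' @param x Vector of strictly positive reals (apply the pseudocount
#'   upstream).
#' @return Finite real cost.
#' @export
segment_cost <- function(x) {
  n <- length(x)
  if (n < 1L) stop("segment_cost: empty segment")
  if (any(x <= 0)) stop("segment_cost: all values must be > 0")
  2 * n * log(sum(x) / n)
}

#' Best single split of a segment
#'
#' Scans all admissible split points `tau` in `[min_seg, n - min_seg]` and
#' returns the one maximizing the cost reduction
#' `gain(tau) = C(x) - C(x[1..tau]) - C(x[tau+1..n])`. Ties are broken by
#' the smallest `tau`. The gain is reported signed; a negative maximum means
#' no split reduces the cost.
#'
#' @param x Vector of strictly positive reals.
#' @param min_seg Minimum length of each resulting part.
#' @return `list(tau, gain)`, or `NULL` when `length(x) < 2 * min_seg`
#'   ("too short": the caller treats this as no-split).
#' @export
best_split <- function(x, min_seg) {
  n <- length(x)
  if (n < 2L * min_seg) return(NULL)
  S <- sum(x)
  cs <- cumsum(x)
  taus <- seq.int(min_seg, n - min_seg)
  left <- cs[taus]
  gains <- 2 * n * log(S / n) -
    2 * taus * log(left / taus) -
    2 * (n - taus) * log((S - left) / (n - taus))
  i <- which.max(gains)
  list(tau = taus[i], gain = gains[i])
}

## best pair of changepoints (tau1, tau2) carving an interior window
## [tau1+1, tau2] out of the segment: the move that recovers a narrow trough
## between tall equal flanks, where no *single* split reduces the cost (the
## halves' means barely differ). Brute-force over admissible pairs,
## vectorized over tau2; ties break toward smallest (tau1, tau2).
best_double_split <- function(x, min_seg) {
  n <- length(x)
  if (n < 3L * min_seg) return(NULL)
  cs <- c(0, cumsum(x))
  seg_cost <- function(i, j) {              # cost of x[i..j], vectorized
    len <- j - i + 1
    2 * len * log((cs[j + 1L] - cs[i]) / len)
  }
  total <- seg_cost(1L, n)
  best <- list(tau1 = NA_integer_, tau2 = NA_integer_, gain = -Inf)
  for (t1 in seq.int(min_seg, n - 2L * min_seg)) {
    t2 <- seq.int(t1 + min_seg, n - min_seg)
    gains <- total - seg_cost(1L, t1) - seg_cost(t1 + 1L, t2) - seg_cost(t2 + 1L, n)
    i <- which.max(gains)
    if (gains[i] > best$gain) best <- list(tau1 = t1, tau2 = t2[i], gain = gains[i])
  }
  if (!is.finite(best$gain)) return(NULL)
  best
}

#' Binary segmentation of exon coverage
#'
#' Greedy binary segmentation under the exponential cost: the pseudocount is
#' added to every depth, then the segment whose best split yields the largest
#' gain is split first, recursively, as long as the gain exceeds the penalty
#' `beta = penalty_multiplier * log(n)` (n the full input length), each part
#' is at least `min_segment_length` long, and the recursion depth limit is
#' not hit. Deterministic: ties break toward the smallest changepoint.
#'
#' When no single split of any active segment passes the penalty, the step
#' falls back to proposing the best *pair* of changepoints carving an
#' interior window out of a segment (in the spirit of circular binary
#' segmentation), accepted when its joint gain exceeds `2 * beta`. A narrow
#' deep trough between two tall plateaus of equal height — precisely the
#' merged-gene signature — yields a near-zero single-split gain (either
#' half's mean is dominated by its flank) but a large joint gain, so the
#' paired proposal is what makes such troughs recoverable.
#'
#' @param x Non-negative numeric vector of per-base depths (1-based exon
#'   offsets).
#' @param config A [segmentation_config()].
#' @return An object of class `segmentation` with elements `changepoints`
#'   (sorted 1-based offsets; a changepoint at tau splits between positions
#'   tau and tau+1), `segment_bounds` (data.frame `start`,`end` partitioning
#'   `[1, n]`), `segment_means` (mean pseudocount-shifted depth per segment),
#'   `total_cost`, `penalty_used` and `n`.
#' @export
binary_segmentation <- function(x, config = segmentation_config()) {
  n <- length(x)
  if (n < 1L) stop("binary_segmentation: empty input")
  if (any(x < 0)) stop("binary_segmentation: negative depths")
  y <- as.numeric(x) + config$pseudocount
  beta <- config$penalty_multiplier * log(n)
  min_seg <- config$min_segment_length

  ## active segments with their precomputed single splits; paired proposals
  ## are computed lazily only when no single split passes the penalty
  new_seg <- function(start, end, depth) {
    list(start = start, end = end, depth = depth,
         split = best_split(y[start:end], min_seg), split2 = NULL)
  }
  segs <- list(new_seg(1L, n, 0L))
  cps <- integer(0)
  repeat {
    eligible <- vapply(segs, function(s) s$depth < config$max_depth_of_recursion,
                       logical(1))
    g1 <- vapply(segs, function(s) {
      if (is.null(s$split)) -Inf else s$split$gain
    }, numeric(1))
    g1[!eligible] <- -Inf
    if (length(g1) && max(g1) > beta) {
      i <- which.max(g1)
      s <- segs[[i]]
      cp <- s$start + s$split$tau - 1L
      cps <- c(cps, cp)
      segs <- c(segs[-i],
                list(new_seg(s$start, cp, s$depth + 1L),
                     new_seg(cp + 1L, s$end, s$depth + 1L)))
      next
    }
    for (i in seq_along(segs)) {
      if (eligible[i] && is.null(segs[[i]]$split2)) {
        s <- segs[[i]]
        d <- best_double_split(y[s$start:s$end], min_seg)
        segs[[i]]$split2 <- if (is.null(d)) list(gain = -Inf) else d
      }
    }
    g2 <- vapply(segs, function(s) {
      if (is.null(s$split2)) -Inf else s$split2$gain
    }, numeric(1))
    g2[!eligible] <- -Inf
    if (!length(g2) || max(g2) <= 2 * beta) break
    i <- which.max(g2)
    s <- segs[[i]]
    cp1 <- s$start + s$split2$tau1 - 1L
    cp2 <- s$start + s$split2$tau2 - 1L
    cps <- c(cps, cp1, cp2)
    segs <- c(segs[-i],
              list(new_seg(s$start, cp1, s$depth + 1L),
                   new_seg(cp1 + 1L, cp2, s$depth + 1L),
                   new_seg(cp2 + 1L, s$end, s$depth + 1L)))
  }

  cps <- sort(cps)
  bstart <- c(1L, cps + 1L)
  bend <- c(cps, n)
  means <- vapply(seq_along(bstart),
                  function(i) mean(y[bstart[i]:bend[i]]), numeric(1))
  total <- sum(vapply(seq_along(bstart),
                      function(i) segment_cost(y[bstart[i]:bend[i]]), numeric(1)))
  structure(list(changepoints = cps,
                 segment_bounds = data.frame(start = bstart, end = bend),
                 segment_means = means,
                 total_cost = total,
                 penalty_used = beta,
                 n = n),
            class = "segmentation")
}

#' @export
print.segmentation <- function(x, ...) {
  cat(sprintf("<segmentation> n=%d, %d changepoint(s)%s\n", x$n,
              length(x$changepoints),
              if (length(x$changepoints))
                paste0(" at ", paste(x$changepoints, collapse = ", ")) else ""))
  invisible(x)
}

#' Detect a qualified low-coverage trough within an exon
#'
#' Runs [binary_segmentation()] and, among interior segments (neither first
#' nor last), selects the one with the minimum mean. It is reported as a
#' trough only if its mean is at most `trough_drop_ratio` times the smaller
#' of the two adjacent segment means; a deep interior fall in coverage is the
#' signature of two merged gene models.
#'
#' @param x Non-negative per-base depths over one exon.
#' @param config A [segmentation_config()].
#' @return A `trough_call` (`left`, `right` 1-based offsets of the trough
#'   segment within the exon, plus `trough_mean`, `left_flank_mean`,
#'   `right_flank_mean` on the pseudocount-shifted scale), or `NULL` when the
#'   exon is too short (`< 3 * min_segment_length`), has fewer than three
#'   segments, or no interior segment passes the drop ratio.
#' @export
detect_trough <- function(x, config = segmentation_config()) {
  n <- length(x)
  if (n < 3L * config$min_segment_length) return(NULL)
  seg <- binary_segmentation(x, config)
  k <- nrow(seg$segment_bounds)
  if (k < 3L) return(NULL)
  interior <- 2:(k - 1L)
  i <- interior[which.min(seg$segment_means[interior])]
  tm <- seg$segment_means[i]
  lf <- seg$segment_means[i - 1L]
  rf <- seg$segment_means[i + 1L]
  if (tm > config$trough_drop_ratio * min(lf, rf)) return(NULL)
  structure(list(left = seg$segment_bounds$start[i],
                 right = seg$segment_bounds$end[i],
                 trough_mean = tm,
                 left_flank_mean = lf,
                 right_flank_mean = rf),
            class = "trough_call")
}

#' @export
print.trough_call <- function(x, ...) {
  cat(sprintf("<trough_call> offsets %d-%d, mean %.2f (flanks %.2f / %.2f)\n",
              x$left, x$right, x$trough_mean,
              x$left_flank_mean, x$right_flank_mean))
  invisible(x)
}
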