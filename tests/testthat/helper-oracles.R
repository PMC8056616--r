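# Independent oracles and small construction helpers shared across tests.
# The oracles deliberately use direct, unoptimized formulations so they share
# no code path with the implementation they check.

# exhaustive scan over every admissible split point, costs recomputed from
# the definition (2 n log(mean))
oracle_best_split <- function(x, min_seg) {
  n <- length(x)
  if (n < 2 * min_seg) return(NULL)
  cost <- function(v) 2 * length(v) * log(mean(v))
  best <- NULL
  for (tau in min_seg:(n - min_seg)) {
    g <- cost(x) - cost(x[1:tau]) - cost(x[(tau + 1):n])
    if (is.null(best) || g > best$gain) best <- list(tau = tau, gain = g)
  }
  best
}

# brute-force two-changepoint oracle: best (tau1, tau2) partition into three
# parts by full enumeration
oracle_two_changepoints <- function(x, min_seg) {
  n <- length(x)
  cost <- function(v) 2 * length(v) * log(mean(v))
  best <- NULL
  for (t1 in min_seg:(n - 2 * min_seg)) {
    for (t2 in (t1 + min_seg):(n - min_seg)) {
      g <- cost(x) - cost(x[1:t1]) - cost(x[(t1 + 1):t2]) - cost(x[(t2 + 1):n])
      if (is.null(best) || g > best$gain) best <- list(tau1 = t1, tau2 = t2, gain = g)
    }
  }
  best
}

# brute-force codon scan: enumerate every codon in all three frames
oracle_all_frame_stops <- function(seq, stops = c("TAA", "TAG", "TGA")) {
  n <- nchar(seq)
  if (n < 3) return(FALSE)
  for (f in 0:2) {
    found <- FALSE
    i <- 1 + f
    while (i + 2 <= n) {
      if (substr(seq, i, i + 2) %in% stops) { found <- TRUE; break }
      i <- i + 3
    }
    if (!found) return(FALSE)
  }
  TRUE
}

# brute-force pairwise-containment oracle for redundancy removal: restates
# the removal rules with direct interval/vector arithmetic
oracle_redundant_ids <- function(ann) {
  txs <- ann$transcripts
  ids <- names(txs)
  chain_of <- function(t) {
    ch <- derive_intron_chain(t)
    if (nrow(ch) == 0) character(0) else paste(ch[, 1], ch[, 2])
  }
  removed <- character(0)
  for (a in ids) {
    A <- txs[[a]]
    for (b in setdiff(ids, a)) {
      B <- txs[[b]]
      if (A$chrom != B$chrom || A$strand != B$strand) next
      sa <- c(tx_start(A), tx_end(A)); sb <- c(tx_start(B), tx_end(B))
      within <- sa[1] >= sb[1] && sa[2] <= sb[2]
      ca <- chain_of(A); cb <- chain_of(B)
      drop <- FALSE
      if (length(ca) > 0 && length(cb) > 0) {
        if (identical(ca, cb) && within) {
          la <- diff(sa); lb <- diff(sb)
          drop <- lb > la || (lb == la && b < a)
        } else if (within && length(ca) < length(cb)) {
          for (off in 0:(length(cb) - length(ca))) {
            if (identical(ca, cb[(off + 1):(off + length(ca))])) { drop <- TRUE; break }
          }
        }
      } else if (length(ca) == 0 && length(cb) > 0) {
        drop <- any(sa[1] >= B$exons[, "start"] & sa[2] <= B$exons[, "end"])
      } else if (length(ca) == 0 && length(cb) == 0) {
        if (within) drop <- if (all(sa == sb)) b < a else TRUE
      }
      if (drop) { removed <- c(removed, a); break }
    }
  }
  removed
}

# terse transcript constructor for fixtures built in code
mk_tx <- function(id, exons, strand = "+", chrom = "chr1", gene = NULL) {
  transcript_model(id, gene %||% paste0("g_", id), chrom, strand,
                   matrix(exons, ncol = 2, byrow = TRUE,
                          dimnames = list(NULL, c("start", "end"))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

mk_ann <- function(...) annotation(list(...))

# random annotation with mixed mono/multi transcripts for property tests
random_annotation <- function(n, prefix = "t") {
  txs <- lapply(seq_len(n), function(i) {
    k <- sample(1:3, 1)
    s <- sample(1:5000, 1)
    ex <- matrix(0L, k, 2)
    for (j in 1:k) {
      len <- sample(30:200, 1)
      ex[j, ] <- c(s, s + len)
      s <- s + len + sample(20:100, 1)
    }
    mk_tx(sprintf("%s%03d", prefix, i), as.vector(t(ex)),
          strand = sample(c("+", "-"), 1))
  })
  annotation(txs)
}
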