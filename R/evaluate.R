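#' Intron-chain match between two multi-exonic transcripts
#'
#' A multi-exonic transcript is "recognized" only when all of its intron
#' definitions agree with a reference transcript: same chromosome, same
#' strand, and identical ordered intron coordinate lists. End extents (UTR
#' lengths) play no part.
#'
#' @param pred,ref Multi-exonic [transcript_model]s.
#' @return Logical scalar.
#' @export
intron_chain_match <- function(pred, ref) {
  if (is_mono(pred) || is_mono(ref)) {
    stop("intron_chain_match: both transcripts must be multi-exonic ",
         "(use mono_overlap_match for mono-exonic transcripts)")
  }
  pred$chrom == ref$chrom && pred$strand == ref$strand &&
    identical(unname(derive_intron_chain(pred)), unname(derive_intron_chain(ref)))
}

#' Overlap match between two mono-exonic transcripts
#'
#' Mono-exonic transcripts have no introns to compare; they match when at
#' least `threshold` of the nucleotides overlap, with the symmetric
#' denominator `max(length(pred), length(ref))` so that a tiny prediction
#' inside a long reference does not count.
#'
#' @param pred,ref Mono-exonic [transcript_model]s.
#' @param threshold Minimum shared fraction; default 0.8.
#' @return Logical scalar; `FALSE` when chromosome or strand differ.
#' @export
mono_overlap_match <- function(pred, ref, threshold = 0.8) {
  if (!is_mono(pred) || !is_mono(ref)) {
    stop("mono_overlap_match: both transcripts must be mono-exonic")
  }
  if (pred$chrom != ref$chrom || pred$strand != ref$strand) return(FALSE)
  shared <- min(tx_end(pred), tx_end(ref)) - max(tx_start(pred), tx_start(ref)) + 1L
  if (shared <= 0L) return(FALSE)
  longest <- max(tx_end(pred) - tx_start(pred) + 1L, tx_end(ref) - tx_start(ref) + 1L)
  shared / longest >= threshold
}

## stranded exon GRanges of an annotation ('.' counted as '+')
ann_exon_granges <- function(ann) {
  et <- exon_table(ann)
  strand <- ifelse(et$strand == ".", "+", et$strand)
  GenomicRanges::GRanges(et$chrom, IRanges::IRanges(et$start, et$end),
                         strand = strand)
}

f1_score <- function(sn, sp) {
  if (sn + sp == 0) return(0)
  2 * sn * sp / (sn + sp)
}

## logical vector: for each transcript in `set`, is it matched by any
## transcript of `against`? (chain match for multi-exonic, >= threshold
## overlap for mono-exonic)
match_against <- function(set, against, mono_threshold = 0.8) {
  ag <- against$transcripts
  ag_multi_keys <- unique(unlist(lapply(ag, function(t) {
    if (is_mono(t)) NULL else paste(t$chrom, t$strand, chain_key(t))
  })))
  ag_mono <- ag[vapply(ag, is_mono, logical(1))]
  vapply(set$transcripts, function(t) {
    if (!is_mono(t)) {
      paste(t$chrom, t$strand, chain_key(t)) %in% ag_multi_keys
    } else {
      any(vapply(ag_mono, function(r) mono_overlap_match(t, r, mono_threshold),
                 logical(1)))
    }
  }, logical(1))
}

#' Compare a predicted annotation against a reference
#'
#' Computes TP/FP/FN, sensitivity (`100*TP/(TP+FN)`), specificity
#' (`100*TP/(TP+FP)`, i.e. precision) and their harmonic-mean F1 at five
#' levels, plus the per-transcript annotation edit distance:
#' \describe{
#'   \item{base}{stranded exonic positions, counted once per side however
#'     many isoforms cover them;}
#'   \item{exon}{exact (chrom, strand, start, end) matches over de-duplicated
#'     exon sets;}
#'   \item{intron}{likewise over de-duplicated intron sets;}
#'   \item{transcript}{a prediction is matched by [intron_chain_match()]
#'     (multi-exonic) or [mono_overlap_match()] (mono-exonic). A reference
#'     matched by several predictions counts once toward sensitivity; the
#'     stored `tp` is the matched-reference count (so `tp/(tp+fn)` is the
#'     sensitivity), `fp` the unmatched predictions over which specificity is
#'     computed;}
#'   \item{gene}{a gene is recognized when at least one of its transcripts
#'     is; sensitivity over reference genes, specificity over predicted
#'     genes.}
#' }
#'
#' @param pred,ref Non-empty [annotation]s on the same coordinate space.
#' @param mono_threshold Mono-exonic overlap threshold; default 0.8.
#' @return A `comparison_report`: `metrics` data.frame (level, tp, fp, fn,
#'   sensitivity, specificity, f1) and `aed` (named numeric, one value in
#'   \[0, 1\] per predicted transcript).
#' @export
compare_annotations <- function(pred, ref, mono_threshold = 0.8) {
  if (length(ref$transcripts) == 0L) {
    stop("empty reference annotation: sensitivity undefined")
  }
  if (length(pred$transcripts) == 0L) {
    stop("empty predicted annotation: specificity undefined")
  }

  row <- function(level, tp, fp, fn) {
    sn <- if (tp + fn > 0) 100 * tp / (tp + fn) else 0
    sp <- if (tp + fp > 0) 100 * tp / (tp + fp) else 0
    data.frame(level = level, tp = tp, fp = fp, fn = fn,
               sensitivity = sn, specificity = sp, f1 = f1_score(sn, sp),
               stringsAsFactors = FALSE)
  }

  ## base level
  pr <- GenomicRanges::reduce(ann_exon_granges(pred))
  rr <- GenomicRanges::reduce(ann_exon_granges(ref))
  tp_b <- sum(GenomicRanges::width(GenomicRanges::intersect(pr, rr)))
  base <- row("base", tp_b,
              sum(GenomicRanges::width(pr)) - tp_b,
              sum(GenomicRanges::width(rr)) - tp_b)

  ## exon / intron levels over de-duplicated feature sets
  feat_keys <- function(ann, what) {
    unique(unlist(lapply(ann$transcripts, function(t) {
      m <- if (what == "exon") t$exons else derive_intron_chain(t)
      if (nrow(m) == 0L) return(NULL)
      paste(t$chrom, t$strand, m[, "start"], m[, "end"])
    })))
  }
  lvl <- function(level) {
    p <- feat_keys(pred, level)
    r <- feat_keys(ref, level)
    tp <- length(intersect(p, r))
    row(level, tp, length(p) - tp, length(r) - tp)
  }
  exon <- lvl("exon")
  intron <- lvl("intron")

  ## transcript level
  pred_matched <- match_against(pred, ref, mono_threshold)
  ref_matched <- match_against(ref, pred, mono_threshold)
  tx <- row("transcript", sum(ref_matched), sum(!pred_matched), sum(!ref_matched))
  tx$specificity <- 100 * sum(pred_matched) / length(pred_matched)
  tx$f1 <- f1_score(tx$sensitivity, tx$specificity)

  ## gene level
  gene_hit <- function(matched, ann) {
    g <- annotation_genes(ann)
    vapply(g, function(tids) any(matched[tids]), logical(1))
  }
  pg <- gene_hit(pred_matched, pred)
  rg <- gene_hit(ref_matched, ref)
  gene <- row("gene", sum(rg), sum(!pg), sum(!rg))
  gene$specificity <- 100 * sum(pg) / length(pg)
  gene$f1 <- f1_score(gene$sensitivity, gene$specificity)

  aed <- vapply(pred$transcripts, function(t) compute_aed(t, ref), numeric(1))
  structure(list(metrics = rbind(base, exon, intron, tx, gene), aed = aed),
            class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat("<comparison_report>\n")
  m <- x$metrics
  m[, c("sensitivity", "specificity", "f1")] <-
    round(m[, c("sensitivity", "specificity", "f1")], 2)
  print(m, row.names = FALSE)
  cat(sprintf("AED: n=%d, mean=%.3f\n", length(x$aed), mean(x$aed)))
  invisible(x)
}

#' Annotation edit distance of one predicted transcript
#'
#' Over the reference transcripts on the same chromosome and strand sharing
#' at least one exonic base with the prediction, base-level sensitivity
#' (`shared / reference bases`) and specificity (`shared / predicted bases`)
#' are averaged into a congruence score, and `AED = 1 - max congruence`. 0
#' means complete agreement with some reference transcript; 1 means no
#' overlapping reference exists.
#'
#' @param pred A [transcript_model].
#' @param ref An [annotation].
#' @return Real in `[0, 1]`.
#' @export
compute_aed <- function(pred, ref) {
  pr <- IRanges::IRanges(pred$exons[, "start"], pred$exons[, "end"])
  pbases <- sum(IRanges::width(pr))
  best <- 0
  for (r in ref$transcripts) {
    if (r$chrom != pred$chrom || r$strand != pred$strand) next
    rr <- IRanges::IRanges(r$exons[, "start"], r$exons[, "end"])
    shared <- sum(IRanges::width(IRanges::intersect(pr, rr)))
    if (shared < 1L) next
    congruence <- (shared / sum(IRanges::width(rr)) + shared / pbases) / 2
    if (congruence > best) best <- congruence
  }
  1 - best
}

#' Write a comparison report
#'
#' @param report A `comparison_report`.
#' @param metrics_path Path for the 5-row level-metrics TSV.
#' @param aed_path Optional path for the per-transcript AED TSV.
#' @return Invisibly, `metrics_path`.
#' @export
write_comparison_report <- function(report, metrics_path, aed_path = NULL) {
  utils::write.table(report$metrics, metrics_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(aed_path)) {
    utils::write.table(
      data.frame(transcript_id = names(report$aed), aed = unname(report$aed)),
      aed_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(metrics_path)
}
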