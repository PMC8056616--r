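#' Polishing configuration
#'
#' @param segmentation A [segmentation_config()].
#' @param min_exons_for_internal Minimum exon count for a transcript to have
#'   an internal exon eligible for splitting (>= 3).
#' @param antisense_max_gap Maximum gap, in bases, between a terminal exon
#'   and an opposite-strand exon for the pair to count as an antisense
#'   overlap; default 0 (actual shared bases required).
#' @param stop_codons Codons treated as translation stops.
#' @return An object of class `polish_config`.
#' @export
polish_config <- function(segmentation = segmentation_config(),
                          min_exons_for_internal = 3L,
                          antisense_max_gap = 0L,
                          stop_codons = c("TAA", "TAG", "TGA")) {
  stopifnot(min_exons_for_internal >= 3, antisense_max_gap >= 0)
  structure(list(segmentation = segmentation,
                 min_exons_for_internal = as.integer(min_exons_for_internal),
                 antisense_max_gap = as.integer(antisense_max_gap),
                 stop_codons = toupper(stop_codons)),
            class = "polish_config")
}

#' Premature stop codons in all three reading frames
#'
#' An internal exon is a candidate for housing two merged genes only when no
#' reading frame can translate through it: every one of the three frame
#' offsets must contain at least one stop codon somewhere in the exon
#' sequence. Since the exon is internal, any stop is premature. Codons
#' containing `N` never match.
#'
#' @param seq Uppercase, transcript-strand-oriented nucleotide string (as
#'   returned by [exon_sequence()]).
#' @param stop_codons Codon set; default TAA/TAG/TGA.
#' @return `TRUE` iff each of the three frames contains a stop codon;
#'   `FALSE` for sequences shorter than 3 bases.
#' @export
has_premature_stops_all_frames <- function(seq, stop_codons = c("TAA", "TAG", "TGA")) {
  n <- nchar(seq)
  if (n < 3L) return(FALSE)
  for (f in 0:2) {
    starts <- seq.int(1L + f, n - 2L, by = 3L)
    if (length(starts) == 0L) return(FALSE)
    codons <- substring(seq, starts, starts + 2L)
    if (!any(codons %in% stop_codons)) return(FALSE)
  }
  TRUE
}

#' Select internal exons that may house a changepoint
#'
#' Internal exons (neither first nor last) whose strand-oriented sequence has
#' premature stop codons in all three frames are the only exons probed for
#' coverage troughs; restricting to them avoids splitting ordinary coding
#' exons.
#'
#' @param tx A [transcript_model].
#' @param genome A `DNAStringSet` covering the transcript.
#' @param config A [polish_config()].
#' @return Integer vector of candidate exon indices (1-based, genomic order;
#'   internal exons are the same set in transcription order). Empty for
#'   transcripts with fewer than three exons.
#' @export
select_candidate_exons <- function(tx, genome, config = polish_config()) {
  k <- n_exons(tx)
  if (k < config$min_exons_for_internal) return(integer(0))
  internal <- 2:(k - 1L)
  hits <- vapply(internal, function(i) {
    s <- exon_sequence(genome, tx$chrom, tx$exons[i, "start"], tx$exons[i, "end"],
                       tx$strand)
    has_premature_stops_all_frames(s, config$stop_codons)
  }, logical(1))
  internal[hits]
}

#' Split a transcript at a coverage trough inside an internal exon
#'
#' The exon is cut around the trough: the left child keeps the exons before
#' it plus the exon truncated to just before the trough, the right child the
#' exon truncated to just after the trough plus the following exons. Trough
#' bases belong to neither child (they model the inter-genic gap). Children
#' are two distinct genes: ids become `<parent>.split1` / `.split2` with gene
#' ids suffixed the same way. CDS-related attributes of the parent are not
#' propagated.
#'
#' @param tx A [transcript_model] with at least 3 exons.
#' @param exon_index Index of an internal exon (genomic order).
#' @param trough A `trough_call` with 1-based offsets within that exon.
#' @return `list(left, right)` of transcript models, or `NULL` when the
#'   trough touches the exon boundary (a trim scenario, not a split).
#' @export
split_transcript_at_trough <- function(tx, exon_index, trough) {
  k <- n_exons(tx)
  if (exon_index <= 1L || exon_index >= k) {
    stop("split_transcript_at_trough: exon_index must be internal")
  }
  s <- tx$exons[exon_index, "start"]
  e <- tx$exons[exon_index, "end"]
  exlen <- e - s + 1L
  if (trough$left <= 1L || trough$right >= exlen) return(NULL)
  left_frag <- c(start = s, end = s + trough$left - 2L)
  right_frag <- c(start = s + trough$right, end = e)
  attrs <- tx$attributes[!grepl("^(cds|CDS)", names(tx$attributes))]
  left <- transcript_model(paste0(tx$transcript_id, ".split1"),
                           paste0(tx$gene_id, ".split1"),
                           tx$chrom, tx$strand,
                           rbind(tx$exons[seq_len(exon_index - 1L), , drop = FALSE],
                                 left_frag),
                           attrs)
  right <- transcript_model(paste0(tx$transcript_id, ".split2"),
                            paste0(tx$gene_id, ".split2"),
                            tx$chrom, tx$strand,
                            rbind(right_frag,
                                  tx$exons[seq.int(exon_index + 1L, k), , drop = FALSE]),
                            attrs)
  list(left = left, right = right)
}

#' Find terminal exons overlapping antisense transcripts
#'
#' Reports every terminal (outermost left or right) exon that overlaps an
#' exon of a transcript on the opposite strand of the same chromosome, with
#' at least one shared base (or within `antisense_max_gap` bases). Such ends
#' typically over-extend up to the neighbour's nearest intron and are the
#' trimming targets. Unstranded (`.`) transcripts are never reported.
#'
#' @param ann An [annotation].
#' @param max_gap Maximum allowed gap in bases; default 0.
#' @return data.frame with columns `transcript_id`, `which_end`
#'   (`"left"`/`"right"`), `opposing_transcript_id`.
#' @export
find_antisense_end_overlaps <- function(ann, max_gap = 0L) {
  et <- exon_table(ann)
  empty <- data.frame(transcript_id = character(0), which_end = character(0),
                      opposing_transcript_id = character(0),
                      stringsAsFactors = FALSE)
  if (nrow(et) == 0L) return(empty)
  nex <- vapply(ann$transcripts, n_exons, integer(1))
  et$k <- nex[et$transcript_id]
  et$is_left <- et$exon_index == 1L
  et$is_right <- et$exon_index == et$k
  gr <- GenomicRanges::GRanges(et$chrom, IRanges::IRanges(et$start, et$end))
  mg <- if (max_gap <= 0L) -1L else as.integer(max_gap)  # 0 = require shared bases
  hits <- GenomicRanges::findOverlaps(gr, maxgap = mg, drop.self = TRUE,
                                      ignore.strand = TRUE)
  q <- S4Vectors::queryHits(hits)
  s <- S4Vectors::subjectHits(hits)
  keep <- (et$is_left[q] | et$is_right[q]) &
    et$strand[q] != et$strand[s] &
    et$strand[q] %in% c("+", "-") & et$strand[s] %in% c("+", "-") &
    et$transcript_id[q] != et$transcript_id[s]
  q <- q[keep]; s <- s[keep]
  if (length(q) == 0L) return(empty)
  ## a mono-exonic terminal exon is both ends; attribute the overlap to the
  ## end nearer the opposing exon
  which_end <- ifelse(
    et$is_left[q] & et$is_right[q],
    ifelse((et$start[s] + et$end[s]) >= (et$start[q] + et$end[q]), "right", "left"),
    ifelse(et$is_right[q], "right", "left"))
  out <- data.frame(transcript_id = et$transcript_id[q],
                    which_end = which_end,
                    opposing_transcript_id = et$transcript_id[s],
                    stringsAsFactors = FALSE)
  out <- unique(out)
  rownames(out) <- NULL
  out[order(out$transcript_id, out$which_end, out$opposing_transcript_id), ,
      drop = FALSE]
}

#' Trim an over-extended terminal exon using coverage changepoints
#'
#' The terminal exon's per-base coverage is segmented; walking from the outer
#' end inward, the outermost changepoint whose outer-side segment mean falls
#' to at most `trough_drop_ratio` times its inner-side neighbour's mean marks
#' the actual transcript end, and the bases outside it are removed. When no
#' changepoint qualifies (e.g. uniform coverage) the transcript is returned
#' unchanged. A trimmed transcript records its previous coordinates in a
#' `trimmed` attribute.
#'
#' @param tx A [transcript_model] (normally one implicated by
#'   [find_antisense_end_overlaps()]).
#' @param which_end `"left"` or `"right"` (genomic).
#' @param coverage A [coverage_track].
#' @param config A [polish_config()].
#' @return The (possibly) trimmed transcript model.
#' @export
trim_end_exon <- function(tx, which_end, coverage, config = polish_config()) {
  which_end <- match.arg(which_end, c("left", "right"))
  k <- n_exons(tx)
  i <- if (which_end == "left") 1L else k
  s <- tx$exons[i, "start"]
  e <- tx$exons[i, "end"]
  exlen <- e - s + 1L
  scfg <- config$segmentation
  if (exlen < 2L * scfg$min_segment_length) {
    tx$attributes[["trim_skipped"]] <- paste0(which_end, ":exon_too_short")
    return(tx)
  }
  x <- coverage_slice(coverage, tx$chrom, s, e)
  seg <- binary_segmentation(x, scfg)
  cps <- seg$changepoints
  if (length(cps) == 0L) return(tx)
  means <- seg$segment_means
  ratio <- scfg$trough_drop_ratio
  cut <- NULL
  if (which_end == "right") {
    for (j in rev(seq_along(cps))) {        # outermost changepoint first
      if (means[j + 1L] <= ratio * means[j]) { cut <- cps[j]; break }
    }
    if (is.null(cut)) return(tx)
    new_exon <- c(start = s, end = s + cut - 1L)
  } else {
    for (j in seq_along(cps)) {
      if (means[j] <= ratio * means[j + 1L]) { cut <- cps[j]; break }
    }
    if (is.null(cut)) return(tx)
    new_exon <- c(start = s + cut, end = e)
  }
  tx$exons[i, ] <- new_exon
  tx$attributes[["trimmed"]] <- sprintf("%s:%d-%d", tx$chrom, s, e)
  validate_transcript(tx)
  tx
}

#' Remove redundant transcripts
#'
#' A transcript is redundant when its exon-intron structure is a proper
#' subset of another transcript's on the same chromosome and strand:
#' \itemize{
#'   \item multi-exonic duplicates — identical intron chains with the span of
#'     one inside the span of the other; the longer span is kept, ties broken
#'     toward the lexicographically smaller transcript_id;
#'   \item multi-exonic sub-chains — an intron chain that is a proper
#'     contiguous subsequence of another's, with span contained;
#'   \item mono-exonic — an interval inside a single exon of another
#'     transcript, or inside another mono-exonic transcript's interval
#'     (equal intervals keep the smaller id).
#' }
#' Removal is decided against the original transcript set and then applied in
#' one step, so chains of containment resolve without cascade ambiguity, and
#' the operation is idempotent.
#'
#' @param ann An [annotation].
#' @return `list(annotation, removed_ids)`.
#' @export
remove_redundant_transcripts <- function(ann) {
  txs <- ann$transcripts
  n <- length(txs)
  if (n <= 1L) return(list(annotation = ann, removed_ids = character(0)))
  ids <- names(txs)
  chroms <- vapply(txs, function(t) t$chrom, character(1))
  strands <- vapply(txs, function(t) t$strand, character(1))
  keys <- paste(chroms, strands)
  removed <- logical(n)
  for (grp in split(seq_len(n), keys)) {
    if (length(grp) < 2L) next
    for (a in grp) {
      for (b in grp) {
        if (a == b) next
        if (dominates(txs[[b]], txs[[a]])) { removed[a] <- TRUE; break }
      }
    }
  }
  list(annotation = ann_drop(ann, ids[removed]),
       removed_ids = ids[removed])
}

## does B make A redundant? (same chrom/strand assumed)
dominates <- function(B, A) {
  span_a <- c(tx_start(A), tx_end(A))
  span_b <- c(tx_start(B), tx_end(B))
  within <- span_a[1] >= span_b[1] && span_a[2] <= span_b[2]
  mono_a <- is_mono(A)
  mono_b <- is_mono(B)
  if (!mono_a && !mono_b) {
    ka <- chain_key(A)
    kb <- chain_key(B)
    if (ka == kb && within) {
      la <- span_a[2] - span_a[1]
      lb <- span_b[2] - span_b[1]
      if (lb > la) return(TRUE)
      if (lb == la) return(B$transcript_id < A$transcript_id)
      return(FALSE)
    }
    if (within && is_contiguous_subchain(derive_intron_chain(A),
                                         derive_intron_chain(B))) {
      return(TRUE)
    }
    return(FALSE)
  }
  if (mono_a && !mono_b) {
    ex <- B$exons
    return(any(span_a[1] >= ex[, "start"] & span_a[2] <= ex[, "end"]))
  }
  if (mono_a && mono_b) {
    if (!within) return(FALSE)
    if (span_a[1] == span_b[1] && span_a[2] == span_b[2]) {
      return(B$transcript_id < A$transcript_id)
    }
    return(TRUE)
  }
  FALSE  # multi-exonic A is never dominated by a mono-exonic B
}

## is chain `a` a proper contiguous subsequence of chain `b`?
is_contiguous_subchain <- function(a, b) {
  na <- nrow(a); nb <- nrow(b)
  if (na == 0L || na >= nb) return(FALSE)
  arow <- paste(a[, 1], a[, 2])
  brow <- paste(b[, 1], b[, 2])
  for (off in 0:(nb - na)) {
    if (all(arow == brow[(off + 1):(off + na)])) return(TRUE)
  }
  FALSE
}

#' Polish an annotation against read coverage
#'
#' Applies the three structure-repair operators in a fixed order:
#' \enumerate{
#'   \item [remove_redundant_transcripts()];
#'   \item merged-gene splitting — for each transcript, internal exons
#'     passing the three-frame premature-stop screen are probed with
#'     [detect_trough()]; a transcript is split at most once per pass at the
#'     leftmost qualifying trough, and the two children re-enter the queue
#'     (so more than two merged genes resolve over successive passes);
#'   \item antisense end trimming — every terminal exon implicated by
#'     [find_antisense_end_overlaps()] is passed to [trim_end_exon()];
#'   \item [remove_redundant_transcripts()] again, since splitting and
#'     trimming can create duplicates of retained models.
#' }
#'
#' @param ann An [annotation].
#' @param coverage A [coverage_track] covering every chromosome of `ann`.
#' @param genome A `DNAStringSet` covering every chromosome of `ann`.
#' @param config A [polish_config()].
#' @return `list(annotation, report)` where `report` is a `polish_report`:
#'   counts (`n_redundant_removed`, `n_candidate_exons`, `n_troughs_found`,
#'   `n_transcripts_split`, `n_ends_trimmed`) plus a per-event `events`
#'   data.frame (kind, transcript_id, detail, before, after).
#' @export
polish_annotation <- function(ann, coverage, genome, config = polish_config()) {
  chroms <- unique(vapply(ann$transcripts, function(t) t$chrom, character(1)))
  missing <- setdiff(chroms, names(coverage$depth))
  if (length(missing)) {
    stop("coverage track missing chromosome(s): ", paste(missing, collapse = ", "))
  }
  events <- list()
  ev <- function(kind, tid, detail, before = NA_character_, after = NA_character_) {
    events[[length(events) + 1L]] <<- data.frame(
      kind = kind, transcript_id = tid, detail = detail,
      before = before, after = after, stringsAsFactors = FALSE)
  }

  ## pass 1: de-duplicate
  dd1 <- remove_redundant_transcripts(ann)
  ann <- dd1$annotation
  for (id in dd1$removed_ids) ev("redundant_removed", id, "pre-split")

  ## pass 2: split merged transcripts at coverage troughs
  n_cand <- 0L
  n_troughs <- 0L
  n_split <- 0L
  queue <- names(ann$transcripts)
  kept <- list()
  txs <- ann$transcripts
  while (length(queue)) {
    tid <- queue[[1L]]
    queue <- queue[-1L]
    tx <- txs[[tid]]
    cands <- select_candidate_exons(tx, genome, config)
    n_cand <- n_cand + length(cands)
    did_split <- FALSE
    for (i in cands) {
      x <- coverage_slice(coverage, tx$chrom, tx$exons[i, "start"], tx$exons[i, "end"])
      tc <- detect_trough(x, config$segmentation)
      if (is.null(tc)) next
      n_troughs <- n_troughs + 1L
      kids <- split_transcript_at_trough(tx, i, tc)
      if (is.null(kids)) next    # trough on the exon boundary: trim scenario
      n_split <- n_split + 1L
      trough_gen <- c(tx$exons[i, "start"] + tc$left - 1L,
                      tx$exons[i, "start"] + tc$right - 1L)
      ev("split", tid,
         sprintf("trough %s:%d-%d", tx$chrom, trough_gen[1], trough_gen[2]),
         before = sprintf("%s:%d-%d", tx$chrom, tx_start(tx), tx_end(tx)),
         after = paste0(kids$left$transcript_id, "+", kids$right$transcript_id))
      txs[[kids$left$transcript_id]] <- kids$left
      txs[[kids$right$transcript_id]] <- kids$right
      queue <- c(queue, kids$left$transcript_id, kids$right$transcript_id)
      did_split <- TRUE
      break
    }
    if (!did_split) kept[[tid]] <- tx
  }
  ann <- annotation(unname(kept))

  ## pass 3: trim antisense-overlapping terminal exons
  n_trim <- 0L
  ov <- find_antisense_end_overlaps(ann, config$antisense_max_gap)
  ov <- unique(ov[, c("transcript_id", "which_end")])
  for (r in seq_len(nrow(ov))) {
    tid <- ov$transcript_id[r]
    tx <- ann$transcripts[[tid]]
    before <- sprintf("%s:%d-%d", tx$chrom, tx_start(tx), tx_end(tx))
    tx2 <- trim_end_exon(tx, ov$which_end[r], coverage, config)
    if (!identical(unname(tx2$exons), unname(tx$exons))) {
      n_trim <- n_trim + 1L
      ev("trim", tid, paste0(ov$which_end[r], " end"), before = before,
         after = sprintf("%s:%d-%d", tx2$chrom, tx_start(tx2), tx_end(tx2)))
    }
    ann$transcripts[[tid]] <- tx2
  }

  ## pass 4: de-duplicate again
  dd2 <- remove_redundant_transcripts(ann)
  ann <- dd2$annotation
  for (id in dd2$removed_ids) ev("redundant_removed", id, "post-split")

  report <- structure(
    list(n_redundant_removed = length(dd1$removed_ids) + length(dd2$removed_ids),
         n_candidate_exons = n_cand,
         n_troughs_found = n_troughs,
         n_transcripts_split = n_split,
         n_ends_trimmed = n_trim,
         events = if (length(events)) do.call(rbind, events) else
           data.frame(kind = character(0), transcript_id = character(0),
                      detail = character(0), before = character(0),
                      after = character(0), stringsAsFactors = FALSE)),
    class = "polish_report")
  list(annotation = ann, report = report)
}

#' @export
print.polish_report <- function(x, ...) {
  cat(sprintf(paste0("<polish_report> %d redundant removed, %d candidate exon(s), ",
                     "%d trough(s), %d split(s), %d end(s) trimmed\n"),
              x$n_redundant_removed, x$n_candidate_exons, x$n_troughs_found,
              x$n_transcripts_split, x$n_ends_trimmed))
  invisible(x)
}

#' Write a polish report
#'
#' @param report A `polish_report`.
#' @param tsv_path Path for the per-event TSV (one event per row).
#' @param json_path Optional path for the JSON count summary.
#' @return Invisibly, `tsv_path`.
#' @export
write_polish_report <- function(report, tsv_path, json_path = NULL) {
  utils::write.table(report$events, tsv_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(json_path)) {
    jsonlite::write_json(
      report[c("n_redundant_removed", "n_candidate_exons", "n_troughs_found",
               "n_transcripts_split", "n_ends_trimmed")],
      json_path, auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(tsv_path)
}
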