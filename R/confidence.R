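#' Evidence flags for a gene
#'
#' @param expressed Assembled from RNA-Seq expression data.
#' @param predicted_ab_initio Present in the ab-initio gene prediction set.
#' @param protein_supported Has a hit to the supplied protein evidence.
#' @param in_repeat_region Overlaps annotated repeat regions (see
#'   [annotate_repeat_overlap()]).
#' @return An object of class `evidence_flags`.
#' @export
evidence_flags <- function(expressed = FALSE, predicted_ab_initio = FALSE,
                           protein_supported = FALSE, in_repeat_region = FALSE) {
  structure(list(expressed = isTRUE(expressed),
                 predicted_ab_initio = isTRUE(predicted_ab_initio),
                 protein_supported = isTRUE(protein_supported),
                 in_repeat_region = isTRUE(in_repeat_region)),
            class = "evidence_flags")
}

#' Assign a confidence class from evidence flags
#'
#' A gene located in repeat regions is always low confidence. Otherwise it is
#' high confidence when at least two of the three evidence types (expression,
#' ab-initio prediction, protein support) agree: genes with all three are
#' high confidence, while predictions with no expression or protein backing
#' are low confidence, and the remaining combinations are filled in
#' symmetrically by the same two-of-three rule.
#'
#' @param flags An [evidence_flags()] (or list with the same fields).
#' @param gene_id Optional gene id carried into the call.
#' @return A `confidence_call`: `gene_id`, `class` (`"high"`/`"low"`),
#'   `evidence_count` (0-3) and `repeat_flagged`.
#' @export
assign_confidence <- function(flags, gene_id = NA_character_) {
  count <- sum(flags$expressed, flags$predicted_ab_initio, flags$protein_supported)
  cls <- if (flags$in_repeat_region) "low" else if (count >= 2L) "high" else "low"
  structure(list(gene_id = gene_id, class = cls,
                 evidence_count = as.integer(count),
                 repeat_flagged = isTRUE(flags$in_repeat_region)),
            class = "confidence_call")
}

#' Flag genes overlapping repeat regions
#'
#' A gene is repeat-flagged when at least `threshold` of its exonic bases
#' (union over all of its transcripts) fall inside the supplied repeat
#' intervals; the boundary is inclusive (exactly `threshold` flags the
#' gene).
#'
#' @param ann An [annotation].
#' @param repeats A `GRanges` of repeat intervals (e.g. from [read_bed()]).
#' @param threshold Minimum covered fraction; default 0.5.
#' @return Named logical vector over gene ids.
#' @export
annotate_repeat_overlap <- function(ann, repeats, threshold = 0.5) {
  genes <- annotation_genes(ann)
  rep_red <- GenomicRanges::reduce(repeats)
  GenomicRanges::strand(rep_red) <- "*"
  vapply(genes, function(tids) {
    et <- exon_table(annotation(unname(ann$transcripts[tids])))
    gr <- GenomicRanges::reduce(
      GenomicRanges::GRanges(et$chrom, IRanges::IRanges(et$start, et$end)))
    total <- sum(GenomicRanges::width(gr))
    inside <- sum(GenomicRanges::width(GenomicRanges::intersect(gr, rep_red,
                                                                ignore.strand = TRUE)))
    inside / total >= threshold
  }, logical(1))
}

#' Score the genes of an annotation
#'
#' Combines per-transcript evidence id lists and a repeat interval set into
#' per-gene [assign_confidence()] calls. A gene carries an evidence type when
#' any of its transcripts appears in the corresponding id list.
#'
#' @param ann An [annotation].
#' @param expressed_ids,predicted_ids,protein_ids Character vectors of
#'   transcript ids (each may be empty).
#' @param repeats Optional `GRanges` of repeat intervals.
#' @param repeat_threshold Passed to [annotate_repeat_overlap()].
#' @return data.frame with one row per gene: gene_id, class, evidence_count,
#'   repeat_flagged, expressed, predicted_ab_initio, protein_supported.
#' @export
score_genes <- function(ann, expressed_ids = character(0),
                        predicted_ids = character(0),
                        protein_ids = character(0),
                        repeats = NULL, repeat_threshold = 0.5) {
  genes <- annotation_genes(ann)
  in_repeat <- if (!is.null(repeats)) {
    annotate_repeat_overlap(ann, repeats, repeat_threshold)
  } else {
    stats::setNames(rep(FALSE, length(genes)), names(genes))
  }
  rows <- lapply(names(genes), function(gid) {
    tids <- genes[[gid]]
    fl <- evidence_flags(expressed = any(tids %in% expressed_ids),
                         predicted_ab_initio = any(tids %in% predicted_ids),
                         protein_supported = any(tids %in% protein_ids),
                         in_repeat_region = in_repeat[[gid]])
    call <- assign_confidence(fl, gid)
    data.frame(gene_id = gid, class = call$class,
               evidence_count = call$evidence_count,
               repeat_flagged = call$repeat_flagged,
               expressed = fl$expressed,
               predicted_ab_initio = fl$predicted_ab_initio,
               protein_supported = fl$protein_supported,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Stamp confidence attributes onto an annotation
#'
#' Adds `confidence "high|low"; evidence_count "k";` attributes to every
#' transcript, for emission via [write_gtf()].
#'
#' @param ann An [annotation].
#' @param calls data.frame from [score_genes()].
#' @return The annotated [annotation].
#' @export
apply_confidence <- function(ann, calls) {
  cls <- stats::setNames(calls$class, calls$gene_id)
  cnt <- stats::setNames(calls$evidence_count, calls$gene_id)
  ann$transcripts <- lapply(ann$transcripts, function(t) {
    t$attributes[["confidence"]] <- cls[[t$gene_id]]
    t$attributes[["evidence_count"]] <- as.character(cnt[[t$gene_id]])
    t
  })
  ann
}

#' Tissue/condition association matrix
#'
#' For every transcript of the consolidated annotation and every
#' per-sample annotation, records whether the sample contains a matching
#' transcript ([intron_chain_match()] for multi-exonic transcripts,
#' [mono_overlap_match()] at `mono_threshold` for mono-exonic ones).
#'
#' @param consolidated An [annotation].
#' @param per_sample Non-empty named list of per-sample [annotation]s.
#' @param mono_threshold Mono-exonic overlap threshold; default 0.8.
#' @return Logical matrix: rows are transcript ids of `consolidated`,
#'   columns the sample labels.
#' @export
tissue_association <- function(consolidated, per_sample, mono_threshold = 0.8) {
  if (length(per_sample) == 0L) stop("per_sample must contain at least one annotation")
  if (is.null(names(per_sample)) || any(!nzchar(names(per_sample)))) {
    stop("per_sample annotations must be named by sample/condition label")
  }
  cols <- lapply(per_sample, function(s) {
    match_against(consolidated, s, mono_threshold)
  })
  m <- do.call(cbind, cols)
  rownames(m) <- names(consolidated$transcripts)
  colnames(m) <- names(per_sample)
  m
}

#' Write a tissue association matrix as TSV
#'
#' Rows are transcripts, columns sample labels, cells 0/1.
#'
#' @param mat Matrix from [tissue_association()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_tissue_matrix <- function(mat, path) {
  df <- data.frame(transcript_id = rownames(mat), mat * 1L,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
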