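#' Construct a transcript model
#'
#' A transcript model is the unit record that polishing, matching and scoring
#' operate on: an ordered set of exons on one strand of one chromosome,
#' belonging to one gene. All coordinates are 1-based and inclusive (the GTF
#' convention); this is the single internal coordinate convention of the
#' package, and 0-based formats (bedGraph, BED) are converted on read.
#'
#' @param transcript_id Character scalar, unique within an annotation.
#' @param gene_id Character scalar.
#' @param chrom Chromosome name, non-empty character scalar.
#' @param strand One of `"+"`, `"-"`, `"."`. The `"."` strand is treated as
#'   `"+"` for sequence extraction and is never eligible for antisense
#'   trimming.
#' @param exons Two-column matrix (or coercible data.frame) of exon
#'   `start`/`end` coordinates. Exons must be sorted by start, strictly
#'   non-overlapping and separated by at least one base.
#' @param attributes Named character vector of extra GTF attributes; preserved
#'   verbatim on write.
#'
#' @return An object of class `transcript_model`.
#' @export
transcript_model <- function(transcript_id, gene_id, chrom, strand, exons,
                             attributes = character()) {
  exons <- as.matrix(exons)
  storage.mode(exons) <- "integer"
  dimnames(exons) <- list(NULL, c("start", "end"))
  tx <- structure(
    list(transcript_id = as.character(transcript_id),
         gene_id = as.character(gene_id),
         chrom = as.character(chrom),
         strand = as.character(strand),
         exons = exons,
         attributes = attributes),
    class = "transcript_model")
  validate_transcript(tx)
  tx
}

validate_transcript <- function(tx) {
  if (!nzchar(tx$chrom)) stop("transcript '", tx$transcript_id, "': empty chromosome name")
  if (!tx$strand %in% c("+", "-", ".")) {
    stop("transcript '", tx$transcript_id, "': strand must be one of '+', '-', '.'")
  }
  ex <- tx$exons
  if (nrow(ex) < 1L) stop("transcript '", tx$transcript_id, "': no exons")
  if (any(ex[, "start"] < 1L)) {
    stop("transcript '", tx$transcript_id, "': exon start < 1")
  }
  if (any(ex[, "end"] < ex[, "start"])) {
    stop("transcript '", tx$transcript_id, "': exon with start > end")
  }
  if (nrow(ex) > 1L) {
    if (is.unsorted(ex[, "start"], strictly = TRUE)) {
      stop("transcript '", tx$transcript_id, "': exons not sorted by start")
    }
    gaps <- ex[-1L, "start"] - ex[-nrow(ex), "end"]
    if (any(gaps < 2L)) {
      stop("transcript '", tx$transcript_id,
           "': exons overlap or touch (need >= 1 intronic base between exons)")
    }
  }
  invisible(tx)
}

#' @export
print.transcript_model <- function(x, ...) {
  cat(sprintf("<transcript_model> %s (%s) %s:%d-%d(%s), %d exon(s)\n",
              x$transcript_id, x$gene_id, x$chrom,
              tx_start(x), tx_end(x), x$strand, nrow(x$exons)))
  invisible(x)
}

#' Transcript span accessors
#'
#' The span of a transcript is the interval from the start of its first exon
#' to the end of its last exon (introns included).
#'
#' @param tx A `transcript_model`.
#' @return Integer scalar coordinate.
#' @export
tx_start <- function(tx) unname(tx$exons[1L, "start"])

#' @rdname tx_start
#' @export
tx_end <- function(tx) unname(tx$exons[nrow(tx$exons), "end"])

#' @rdname tx_start
#' @export
n_exons <- function(tx) nrow(tx$exons)

is_mono <- function(tx) nrow(tx$exons) == 1L

#' Derive the intron chain of a transcript
#'
#' The intron chain is the ordered list of intron coordinate pairs implied by
#' consecutive exons: intron k runs from (exon k end + 1) to
#' (exon k+1 start - 1), 1-based inclusive. Two multi-exonic transcripts with
#' identical chains are structurally identical up to their end extents, which
#' is the matching unit used for transcript-level evaluation.
#'
#' @param tx A `transcript_model`.
#' @return Integer matrix with columns `start`, `end`; zero rows for a
#'   mono-exonic transcript.
#' @export
derive_intron_chain <- function(tx) {
  ex <- tx$exons
  k <- nrow(ex)
  if (k == 1L) {
    return(matrix(integer(0), ncol = 2L, dimnames = list(NULL, c("start", "end"))))
  }
  cbind(start = ex[-k, "end"] + 1L, end = ex[-1L, "start"] - 1L)
}

## canonical string key of a chain, "" for mono-exonic
chain_key <- function(tx) {
  ch <- derive_intron_chain(tx)
  if (nrow(ch) == 0L) return("")
  paste(paste0(ch[, "start"], "-", ch[, "end"]), collapse = ";")
}

exonic_bases <- function(tx) sum(tx$exons[, "end"] - tx$exons[, "start"] + 1L)

#' Construct an annotation
#'
#' An annotation is a collection of transcript models with unique
#' `transcript_id`s; the gene table (gene_id to transcript ids) is derived.
#'
#' @param transcripts List of `transcript_model` objects.
#' @return An object of class `annotation`.
#' @export
annotation <- function(transcripts = list()) {
  ids <- vapply(transcripts, function(t) t$transcript_id, character(1))
  if (anyDuplicated(ids)) {
    stop("duplicate transcript_id: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  names(transcripts) <- ids
  structure(list(transcripts = transcripts), class = "annotation")
}

#' @export
print.annotation <- function(x, ...) {
  cat(sprintf("<annotation> %d transcript(s), %d gene(s)\n",
              length(x$transcripts), length(annotation_genes(x))))
  invisible(x)
}

#' @export
length.annotation <- function(x) length(x$transcripts)

#' Gene table of an annotation
#'
#' @param ann An `annotation`.
#' @return Named list mapping gene_id to the character vector of its
#'   transcript ids.
#' @export
annotation_genes <- function(ann) {
  gids <- vapply(ann$transcripts, function(t) t$gene_id, character(1))
  tids <- names(ann$transcripts)
  split(tids, gids)
}

## stranded exon table across all transcripts of an annotation
exon_table <- function(ann) {
  if (length(ann$transcripts) == 0L) {
    return(data.frame(chrom = character(0), start = integer(0), end = integer(0),
                      strand = character(0), transcript_id = character(0),
                      gene_id = character(0), exon_index = integer(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, lapply(ann$transcripts, function(t) {
    data.frame(chrom = t$chrom, start = t$exons[, "start"], end = t$exons[, "end"],
               strand = t$strand, transcript_id = t$transcript_id,
               gene_id = t$gene_id, exon_index = seq_len(nrow(t$exons)),
               stringsAsFactors = FALSE, row.names = NULL)
  }))
}

## replace/insert transcripts; drop by id
ann_drop <- function(ann, ids) {
  annotation(unname(ann$transcripts[setdiff(names(ann$transcripts), ids)]))
}

ann_add <- function(ann, txs) {
  annotation(c(unname(ann$transcripts), txs))
}

## structural equality used by tests and round-trip checks
annotations_equal <- function(a, b) {
  if (!setequal(names(a$transcripts), names(b$transcripts))) return(FALSE)
  for (id in names(a$transcripts)) {
    ta <- a$transcripts[[id]]; tb <- b$transcripts[[id]]
    if (ta$gene_id != tb$gene_id || ta$chrom != tb$chrom ||
        ta$strand != tb$strand || !identical(unname(ta$exons), unname(tb$exons))) {
      return(FALSE)
    }
  }
  TRUE
}
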