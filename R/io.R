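#' Read a GTF annotation
#'
#' Exon features are grouped per `transcript_id` into [transcript_model]
#' records (exons sorted, invariants enforced). Non-exon features (CDS,
#' start/stop codons, ...) are retained verbatim in the returned object's
#' `other_features` table but play no part in polishing. Extra attributes on
#' exon lines are preserved per transcript.
#'
#' @param path Path to a tab-delimited 9-column GTF file with `gene_id` and
#'   `transcript_id` attributes. Coordinates are 1-based inclusive.
#' @return An [annotation]; its `other_features` element holds non-exon
#'   feature rows, if any.
#' @export
parse_gtf <- function(path) {
  if (!file.exists(path)) stop("GTF file does not exist: ", path)
  lines <- readLines(path, warn = FALSE)
  body <- which(!grepl("^\\s*#", lines) & nzchar(trimws(lines)))
  if (length(body) == 0L) {
    ann <- annotation(list())
    ann$other_features <- NULL
    return(ann)
  }
  fields <- strsplit(lines[body], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 9L)) {
    bad <- body[which(nf != 9L)[1L]]
    stop("malformed GTF line ", bad, ": expected 9 tab-delimited fields, got ",
         nf[which(nf != 9L)[1L]])
  }
  starts <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 4L)))
  ends <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 5L)))
  if (anyNA(starts) || anyNA(ends)) {
    bad <- body[which(is.na(starts) | is.na(ends))[1L]]
    stop("malformed GTF line ", bad, ": non-integer coordinates")
  }
  if (any(starts > ends)) {
    bad <- body[which(starts > ends)[1L]]
    stop("invalid GTF line ", bad, ": feature start > end")
  }

  gr <- rtracklayer::import(path, format = "gtf")
  meta <- S4Vectors::mcols(gr)
  if (is.null(meta$transcript_id) || is.null(meta$gene_id)) {
    stop("GTF lacks transcript_id/gene_id attributes: ", path)
  }
  is_exon <- as.character(meta$type) == "exon"
  other <- if (any(!is_exon)) as.data.frame(gr[!is_exon]) else NULL
  ex <- gr[is_exon]
  if (length(ex) == 0L) stop("GTF contains no exon features: ", path)
  exm <- S4Vectors::mcols(ex)

  reserved <- c("source", "type", "score", "phase", "gene_id", "transcript_id")
  extra_cols <- setdiff(colnames(exm), reserved)

  idx <- split(seq_along(ex), as.character(exm$transcript_id))
  txs <- lapply(names(idx), function(tid) {
    i <- idx[[tid]]
    gid <- unique(as.character(exm$gene_id[i]))
    if (length(gid) > 1L) {
      stop("transcript_id '", tid, "' assigned to multiple gene_ids: ",
           paste(gid, collapse = ", "))
    }
    chrom <- unique(as.character(GenomicRanges::seqnames(ex[i])))
    if (length(chrom) > 1L) {
      stop("transcript '", tid, "' has exons on multiple chromosomes")
    }
    strand <- unique(as.character(GenomicRanges::strand(ex[i])))
    if (length(strand) > 1L) stop("transcript '", tid, "' has exons on both strands")
    if (strand == "*") strand <- "."
    ord <- order(GenomicRanges::start(ex[i]))
    exons <- cbind(start = GenomicRanges::start(ex[i])[ord],
                   end = GenomicRanges::end(ex[i])[ord])
    attrs <- character(0)
    for (col in extra_cols) {
      v <- exm[[col]][i]
      v <- v[!is.na(v)]
      if (length(v)) attrs[[col]] <- as.character(v[[1L]])
    }
    transcript_model(tid, gid, chrom, strand, exons, attrs)
  })
  ann <- annotation(txs)
  ann$other_features <- other
  ann
}

#' Write an annotation as GTF
#'
#' Emits one `exon` feature line per exon, transcripts ordered by
#' (chromosome, span start), with attributes in the dialect
#' `gene_id "X"; transcript_id "Y";` followed by any preserved extra
#' attributes. `parse_gtf(write_gtf(a))` reproduces `a` field by field.
#'
#' @param ann An [annotation].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_gtf <- function(ann, path) {
  txs <- ann$transcripts
  lines <- character(0)
  if (length(txs)) {
    ord <- order(vapply(txs, function(t) t$chrom, character(1)),
                 vapply(txs, tx_start, integer(1)),
                 vapply(txs, function(t) t$transcript_id, character(1)))
    lines <- unlist(lapply(txs[ord], function(t) {
      attrs <- sprintf('gene_id "%s"; transcript_id "%s";', t$gene_id, t$transcript_id)
      if (length(t$attributes)) {
        extra <- paste(sprintf('%s "%s";', names(t$attributes), t$attributes),
                       collapse = " ")
        attrs <- paste(attrs, extra)
      }
      sprintf("%s\tannopolish\texon\t%d\t%d\t.\t%s\t.\t%s",
              t$chrom, t$exons[, "start"], t$exons[, "end"], t$strand, attrs)
    }), use.names = FALSE)
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' Read a genome FASTA
#'
#' @param path Multi-record, possibly line-wrapped FASTA file.
#' @return A [Biostrings::DNAStringSet] named by the first whitespace-
#'   delimited token of each header, sequences uppercased.
#' @export
read_genome <- function(path) {
  g <- Biostrings::readDNAStringSet(path)
  names(g) <- sub("\\s.*$", "", names(g))
  Biostrings::DNAStringSet(toupper(g))
}

#' Extract a strand-oriented exon sequence
#'
#' Returns the genomic substring for `+` (and `.`, treated as `+`) exons and
#' the reverse complement for `-` exons, always uppercase. `N` bases pass
#' through unchanged.
#'
#' @param genome A `DNAStringSet` as returned by [read_genome()].
#' @param chrom,start,end 1-based inclusive genomic interval.
#' @param strand `"+"`, `"-"` or `"."`.
#' @return Character scalar nucleotide sequence.
#' @export
exon_sequence <- function(genome, chrom, start, end, strand = "+") {
  if (!chrom %in% names(genome)) stop("chromosome not in genome: ", chrom)
  len <- length(genome[[chrom]])
  if (start < 1L || end > len || start > end) {
    stop(sprintf("interval %s:%d-%d outside chromosome bounds [1, %d]",
                 chrom, start, end, len))
  }
  s <- Biostrings::subseq(genome[[chrom]], start, end)
  if (identical(strand, "-")) s <- Biostrings::reverseComplement(s)
  as.character(s)
}

#' Per-base read-coverage track
#'
#' A coverage track stores one non-negative depth value per base per
#' chromosome (run-length encoded); index i is the depth at 1-based
#' position i. It is the signal that drives changepoint detection.
#'
#' @param depths Named list of non-negative numeric vectors, one per
#'   chromosome, position 1 first.
#' @return An object of class `coverage_track`.
#' @export
coverage_track <- function(depths) {
  if (is.null(names(depths)) || any(!nzchar(names(depths)))) {
    stop("coverage vectors must be named by chromosome")
  }
  rle <- methods::as(lapply(depths, function(v) {
    if (any(v < 0)) stop("negative depth in coverage track")
    S4Vectors::Rle(as.numeric(v))
  }), "SimpleRleList")
  structure(list(depth = rle), class = "coverage_track")
}

#' @export
print.coverage_track <- function(x, ...) {
  cat(sprintf("<coverage_track> %d chromosome(s): %s\n", length(x$depth),
              paste(sprintf("%s (%d bp)", names(x$depth),
                            lengths(x$depth)), collapse = ", ")))
  invisible(x)
}

#' Read per-base depth from a bedGraph file
#'
#' bedGraph records are 0-based half-open (as produced by
#' `bedtools genomecov -bga`-style depth exports) and are expanded to 1-based
#' per-base depth. Positions not covered by any record get depth 0;
#' overlapping records have their values summed, so total mass is conserved.
#'
#' @param path 4-column bedGraph file (chrom, start, end, value).
#' @param genome Optional `DNAStringSet`; when supplied, every chromosome of
#'   the genome is represented with a vector of exactly its length.
#' @return A [coverage_track].
#' @export
parse_bedgraph <- function(path, genome = NULL) {
  if (!file.exists(path)) stop("bedGraph file does not exist: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^(#|track|browser)", lines) & nzchar(trimws(lines))]
  sl <- if (!is.null(genome)) {
    stats::setNames(Biostrings::width(genome), names(genome))
  } else NULL
  if (length(lines) == 0L) {
    gr <- GenomicRanges::GRanges(seqlengths = sl)
    cov <- GenomicRanges::coverage(gr)
    return(structure(list(depth = cov), class = "coverage_track"))
  }
  rec <- utils::read.table(text = lines, header = FALSE,
                           col.names = c("chrom", "start", "end", "value"),
                           colClasses = c("character", "numeric", "numeric", "numeric"))
  if (any(rec$value < 0)) stop("bedGraph has negative coverage values")
  if (any(rec$end <= rec$start)) stop("bedGraph record with end <= start")
  gr <- GenomicRanges::GRanges(rec$chrom,
                               IRanges::IRanges(rec$start + 1L, rec$end))
  if (!is.null(sl)) {
    missing <- setdiff(as.character(GenomicRanges::seqnames(gr)), names(sl))
    if (length(missing)) {
      stop("bedGraph chromosome(s) absent from genome: ",
           paste(unique(missing), collapse = ", "))
    }
    GenomeInfoDb::seqlevels(gr) <- names(sl)
    GenomeInfoDb::seqlengths(gr) <- sl
  }
  cov <- GenomicRanges::coverage(gr, weight = rec$value)
  structure(list(depth = cov), class = "coverage_track")
}

#' Slice a coverage track
#'
#' @param track A [coverage_track].
#' @param chrom Chromosome name (must exist in the track).
#' @param start,end 1-based inclusive interval; positions beyond the stored
#'   vector are returned as depth 0.
#' @return Numeric vector of length `end - start + 1`.
#' @export
coverage_slice <- function(track, chrom, start, end) {
  if (!chrom %in% names(track$depth)) {
    stop("coverage track has no chromosome '", chrom, "'")
  }
  v <- track$depth[[chrom]]
  n <- length(v)
  out <- numeric(end - start + 1L)
  if (start <= n) {
    hi <- min(end, n)
    out[seq_len(hi - start + 1L)] <- as.numeric(S4Vectors::window(v, start, hi))
  }
  out
}

#' Write a coverage track as bedGraph
#'
#' Zero-depth runs are omitted; records are 0-based half-open.
#'
#' @param track A [coverage_track].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_bedgraph <- function(track, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (chrom in names(track$depth)) {
    v <- track$depth[[chrom]]
    ends <- cumsum(S4Vectors::runLength(v))
    starts <- ends - S4Vectors::runLength(v) + 1L
    vals <- S4Vectors::runValue(v)
    keep <- vals != 0
    if (any(keep)) {
      writeLines(sprintf("%s\t%d\t%d\t%s", chrom, starts[keep] - 1L,
                         ends[keep], format(vals[keep], trim = TRUE, scientific = FALSE)),
                 con)
    }
  }
  invisible(path)
}

#' Read repeat regions from a BED file
#'
#' @param path BED file (0-based half-open); converted to 1-based inclusive
#'   intervals on read.
#' @return A `GRanges` of repeat intervals.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("BED file does not exist: ", path)
  rtracklayer::import(path, format = "bed")
}

#' Write a genome FASTA
#'
#' @param genome A `DNAStringSet`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_genome <- function(genome, path) {
  Biostrings::writeXStringSet(genome, path, width = 70L)
  invisible(path)
}
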