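#' Simulate per-base exon coverage from plateau segments
#'
#' @param segments List of `c(length, mean_depth)` pairs (or a 2-column
#'   matrix), one per plateau.
#' @param noise `"none"` (constant blocks at the rounded means),
#'   `"exponential"` (each base drawn from an exponential with the segment
#'   mean, floored to an integer count) or `"poisson"`. The exponential model
#'   matches the changepoint detector's likelihood; Poisson exercises model
#'   misspecification.
#' @param seed Optional integer seed; the draw is deterministic under a
#'   fixed seed and leaves the caller's RNG state untouched.
#' @return Non-negative integer vector of per-base depths.
#' @export
simulate_exon_coverage <- function(segments, noise = c("none", "exponential", "poisson"),
                                   seed = NULL) {
  noise <- match.arg(noise)
  if (is.matrix(segments)) segments <- asplit(segments, 1)
  draw <- function() {
    unlist(lapply(segments, function(sg) {
      len <- as.integer(sg[[1]])
      mu <- as.numeric(sg[[2]])
      if (len < 1L) stop("segment length must be >= 1")
      if (mu <= 0) stop("segment mean must be > 0")
      switch(noise,
             none = rep(as.integer(round(mu)), len),
             exponential = as.integer(floor(stats::rexp(len, rate = 1 / mu))),
             poisson = stats::rpois(len, mu))
    }), use.names = FALSE)
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

## random A/C/G/T string of a given length (RNG state of the caller)
random_dna <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

## sequence guaranteed to carry stop codons in all three frames: tiled
## TAA-rich 12-mer, truncated to the requested length
stop_cassette <- function(len) {
  unit <- "TAAATAAATAAA"
  substr(strrep(unit, ceiling(len / nchar(unit))), 1L, len)
}

## assemble a chromosome coverage vector from (start, end, mean) blocks;
## anything not covered by a block stays 0
layout_coverage <- function(chrom_len, blocks, noise) {
  v <- integer(chrom_len)
  for (b in blocks) {
    v[b$start:b$end] <- simulate_exon_coverage(
      list(c(b$end - b$start + 1L, b$mean)), noise = noise)
  }
  v
}

merged_defaults <- function() {
  list(gap = 40L, exon_mean = 50, trough_mean = 2, intron_mean = 2,
       noise = "exponential", min_segment_length = 20L,
       exon_lengths = c(200L, 300L, 300L, 200L), intron_lengths = c(100L, 100L),
       pad = 200L, chrom = "chr1")
}

#' Simulate a merged-gene locus with known truth
#'
#' Emulates the assembly failure where reads from the facing end exons of two
#' closely spaced same-strand genes bleed across the short inter-genic gap,
#' so the assembler fuses the two gene models into one transcript whose
#' middle exon spans both end exons and the gap. The fused exon's genomic
#' sequence carries stop codons in all three frames (so the candidate screen
#' fires) and its coverage has a deep trough across the gap.
#'
#' @param seed Integer seed; all randomness (genome bases, coverage noise) is
#'   drawn under it.
#' @param params Named list overriding the defaults: `gap` (inter-gene gap,
#'   40), `exon_mean`/`trough_mean` (coverage plateaus, 50/2), `intron_mean`
#'   (2), `noise` (`"exponential"`), `exon_lengths` (200/300/300/200),
#'   `intron_lengths` (100/100), `pad`, `chrom`, `min_segment_length` (gap
#'   narrower than this is undetectable by construction and is an error).
#' @return List with `genome` (`DNAStringSet`), `annotation` (the corrupted
#'   merged input), `coverage` ([coverage_track]) and `truth` (list:
#'   `true_annotation`, `merged_annotation`, `events`, `seed`, `params`).
#' @export
simulate_merged_gene_fixture <- function(seed = 1L, params = list()) {
  p <- utils::modifyList(merged_defaults(), params)
  if (p$gap < p$min_segment_length) {
    stop("inter-gene gap (", p$gap, ") narrower than min_segment_length (",
         p$min_segment_length, "): trough undetectable by construction")
  }
  el <- p$exon_lengths; il <- p$intron_lengths
  a1 <- c(p$pad + 1L, p$pad + el[1])
  a2 <- c(a1[2] + il[1] + 1L, a1[2] + il[1] + el[2])
  b1 <- c(a2[2] + p$gap + 1L, a2[2] + p$gap + el[3])
  b2 <- c(b1[2] + il[2] + 1L, b1[2] + il[2] + el[4])
  chrom_len <- b2[2] + p$pad

  withr::with_seed(seed, {
    seq <- random_dna(chrom_len)
    fused <- c(a2[1], b1[2])
    substr(seq, fused[1], fused[2]) <- stop_cassette(fused[2] - fused[1] + 1L)
    genome <- Biostrings::DNAStringSet(stats::setNames(seq, p$chrom))

    blocks <- list(
      list(start = a1[1], end = a1[2], mean = p$exon_mean),
      list(start = a1[2] + 1L, end = a2[1] - 1L, mean = p$intron_mean),
      list(start = a2[1], end = a2[2], mean = p$exon_mean),
      list(start = a2[2] + 1L, end = b1[1] - 1L, mean = p$trough_mean),
      list(start = b1[1], end = b1[2], mean = p$exon_mean),
      list(start = b1[2] + 1L, end = b2[1] - 1L, mean = p$intron_mean),
      list(start = b2[1], end = b2[2], mean = p$exon_mean))
    cov <- coverage_track(stats::setNames(
      list(layout_coverage(chrom_len, blocks, p$noise)), p$chrom))
  })

  truth_ann <- annotation(list(
    transcript_model("txA", "geneA", p$chrom, "+", rbind(a1, a2)),
    transcript_model("txB", "geneB", p$chrom, "+", rbind(b1, b2))))
  merged_ann <- annotation(list(
    transcript_model("tx_merged", "gene_merged", p$chrom, "+",
                     rbind(a1, c(a2[1], b1[2]), b2))))

  list(genome = genome, annotation = merged_ann, coverage = cov,
       truth = list(true_annotation = truth_ann, merged_annotation = merged_ann,
                    events = list(list(kind = "merge",
                                       trough = c(a2[2] + 1L, b1[1] - 1L),
                                       left_true_end = a2[2],
                                       right_true_start = b1[1])),
                    seed = seed, params = p))
}

antisense_defaults <- function() {
  list(exon_mean = 50, low_mean = 2, intron_mean = 2, noise = "exponential",
       boundary_gap = 40L, pad = 200L, chrom = "chr1",
       plus_exon_lengths = c(200L, 200L), plus_intron_length = 100L,
       minus_exon_lengths = c(160L, 200L), minus_intron_length = 60L)
}

#' Simulate an antisense-overlap locus with known truth
#'
#' Two closely spaced genes on opposite strands: the corrupted input extends
#' the plus-strand gene's terminal exon across the neighbour, up to the far
#' edge of the neighbour's nearest intron. Coverage descends at the true
#' boundary and stays low across the over-extension (the regime in which the
#' extension is a coverage artifact rather than genuine expression, and the
#' descent marks the actual transcript end).
#'
#' @param seed Integer seed.
#' @param params Named list overriding `antisense_defaults()`-style fields
#'   (plateau means, lengths, `boundary_gap`, `noise`, `pad`, `chrom`).
#' @return Same shape as [simulate_merged_gene_fixture()]; the planted event
#'   records the extended transcript, the end involved, and the true end
#'   coordinate.
#' @export
simulate_antisense_fixture <- function(seed = 1L, params = list()) {
  p <- utils::modifyList(antisense_defaults(), params)
  pel <- p$plus_exon_lengths; mel <- p$minus_exon_lengths
  p1 <- c(p$pad + 1L, p$pad + pel[1])
  p2 <- c(p1[2] + p$plus_intron_length + 1L, p1[2] + p$plus_intron_length + pel[2])
  m1 <- c(p2[2] + p$boundary_gap + 1L, p2[2] + p$boundary_gap + mel[1])
  m2 <- c(m1[2] + p$minus_intron_length + 1L, m1[2] + p$minus_intron_length + mel[2])
  chrom_len <- m2[2] + p$pad
  ext_end <- m2[1] - 1L   # extension runs to the far edge of the neighbour's intron

  withr::with_seed(seed, {
    genome <- Biostrings::DNAStringSet(stats::setNames(random_dna(chrom_len), p$chrom))
    blocks <- list(
      list(start = p1[1], end = p1[2], mean = p$exon_mean),
      list(start = p1[2] + 1L, end = p2[1] - 1L, mean = p$intron_mean),
      list(start = p2[1], end = p2[2], mean = p$exon_mean),
      list(start = p2[2] + 1L, end = m2[2], mean = p$low_mean))
    cov <- coverage_track(stats::setNames(
      list(layout_coverage(chrom_len, blocks, p$noise)), p$chrom))
  })

  truth_ann <- annotation(list(
    transcript_model("txP", "geneP", p$chrom, "+", rbind(p1, p2)),
    transcript_model("txM", "geneM", p$chrom, "-", rbind(m1, m2))))
  merged_ann <- annotation(list(
    transcript_model("txP", "geneP", p$chrom, "+", rbind(p1, c(p2[1], ext_end))),
    transcript_model("txM", "geneM", p$chrom, "-", rbind(m1, m2))))

  list(genome = genome, annotation = merged_ann, coverage = cov,
       truth = list(true_annotation = truth_ann, merged_annotation = merged_ann,
                    events = list(list(kind = "antisense_overlap",
                                       transcript_id = "txP", which_end = "right",
                                       true_end = p2[2], extended_end = ext_end)),
                    seed = seed, params = p))
}

#' Simulate a combined locus set: merged genes, an antisense pair and
#' redundant transcripts
#'
#' One chromosome carrying the [simulate_merged_gene_fixture()] scenario, the
#' [simulate_antisense_fixture()] scenario and two planted redundant
#' transcripts (an exact duplicate of the merged transcript, and a
#' mono-exonic fragment inside an exon of the antisense gene). The full
#' polishing pipeline must de-duplicate, split and trim to recover the truth.
#'
#' @param seed Integer seed.
#' @param params Optional overrides forwarded to the two locus builders
#'   (shared fields: `noise`, `exon_mean`, `trough_mean`/`low_mean`).
#' @return Same shape as [simulate_merged_gene_fixture()].
#' @export
simulate_combined_fixture <- function(seed = 1L, params = list()) {
  mg <- simulate_merged_gene_fixture(seed, params)
  shift <- length(mg$coverage$depth[[1]])
  as_params <- params
  as_params$pad <- antisense_defaults()$pad + 0L
  as_fix <- simulate_antisense_fixture(seed + 1000L, as_params)
  chrom <- mg$truth$params$chrom

  shift_tx <- function(t, by) {
    t$exons[, "start"] <- t$exons[, "start"] + by
    t$exons[, "end"] <- t$exons[, "end"] + by
    validate_transcript(t)
    t
  }
  as_truth <- lapply(as_fix$truth$true_annotation$transcripts, shift_tx, by = shift)
  as_input <- lapply(as_fix$annotation$transcripts, shift_tx, by = shift)

  ## redundant transcript 1: exact duplicate of the merged transcript
  dup <- mg$annotation$transcripts[["tx_merged"]]
  dup$transcript_id <- "tx_merged_dup"
  dup$gene_id <- "gene_merged_dup"
  ## redundant transcript 2: mono-exonic fragment inside an exon of the
  ## antisense minus-strand gene
  m2 <- as_truth[["txM"]]$exons[2L, ]
  mono <- transcript_model("tx_mono_red", "gene_mono_red", chrom, "-",
                           rbind(c(m2["start"] + 40L, m2["end"] - 60L)))

  input <- annotation(c(unname(mg$annotation$transcripts), list(dup),
                        unname(as_input), list(mono)))
  truth_ann <- annotation(c(unname(mg$truth$true_annotation$transcripts),
                            unname(as_truth)))

  genome <- Biostrings::DNAStringSet(stats::setNames(
    paste0(as.character(mg$genome[[1]]), as.character(as_fix$genome[[1]])), chrom))
  cov <- coverage_track(stats::setNames(
    list(c(as.numeric(mg$coverage$depth[[1]]),
           as.numeric(as_fix$coverage$depth[[1]]))), chrom))

  ev <- c(mg$truth$events,
          lapply(as_fix$truth$events, function(e) {
            e$true_end <- e$true_end + shift
            e$extended_end <- e$extended_end + shift
            e
          }),
          list(list(kind = "duplicate", transcript_id = "tx_merged_dup"),
               list(kind = "duplicate", transcript_id = "tx_mono_red")))
  list(genome = genome, annotation = input, coverage = cov,
       truth = list(true_annotation = truth_ann, merged_annotation = input,
                    events = ev, seed = seed,
                    params = list(merged = mg$truth$params,
                                  antisense = as_fix$truth$params,
                                  antisense_shift = shift)))
}

pair_defaults <- function() {
  list(n_genes = 30L, drop_rate = 0, shift_rate = 0, truncate_rate = 0,
       spurious_rate = 0, chrom = "chr1", spacing = 1000L,
       exon_len_range = c(100L, 300L), intron_len_range = c(50L, 150L),
       max_exons = 4L)
}

#' Simulate a (prediction, reference) annotation pair with truth metrics
#'
#' Builds a reference of `n_genes` single-transcript genes (1 to `max_exons`
#' exons, random strands) and derives a prediction by applying independent
#' corruptions: dropping transcripts, shifting one intron boundary (breaks
#' the intron chain), truncating a terminal exon (chain preserved), and
#' adding spurious mono-exonic transcripts in intergenic space. The truth
#' report is computed inside the generator by
#' [naive_compare_annotations()], a direct position-set implementation of
#' the metrics that shares no code with [compare_annotations()].
#'
#' @param seed Integer seed.
#' @param params Named list overriding `n_genes`, `drop_rate`, `shift_rate`,
#'   `truncate_rate`, `spurious_rate` (all default 0) and the geometry
#'   fields.
#' @return `list(pred, ref, truth)` where `truth` is the naive
#'   `comparison_report`.
#' @export
simulate_annotation_pair <- function(seed = 1L, params = list()) {
  p <- utils::modifyList(pair_defaults(), params)
  withr::with_seed(seed, {
    pos <- 200L
    refs <- list()
    for (i in seq_len(p$n_genes)) {
      k <- sample.int(p$max_exons, 1L)
      strand <- sample(c("+", "-"), 1L)
      exons <- matrix(0L, k, 2L, dimnames = list(NULL, c("start", "end")))
      cur <- pos
      for (j in seq_len(k)) {
        len <- sample(seq(p$exon_len_range[1], p$exon_len_range[2]), 1L)
        exons[j, ] <- c(cur + 1L, cur + len)
        cur <- cur + len
        if (j < k) cur <- cur + sample(seq(p$intron_len_range[1], p$intron_len_range[2]), 1L)
      }
      refs[[i]] <- transcript_model(sprintf("ref_tx%03d", i), sprintf("ref_g%03d", i),
                                    p$chrom, strand, exons)
      pos <- cur + p$spacing
    }
    ref <- annotation(refs)

    preds <- list()
    for (t in refs) {
      if (stats::runif(1) < p$drop_rate) next
      q <- t
      q$transcript_id <- sub("^ref_", "pred_", q$transcript_id)
      q$gene_id <- sub("^ref_", "pred_", q$gene_id)
      if (n_exons(q) > 1L && stats::runif(1) < p$shift_rate) {
        j <- sample.int(n_exons(q) - 1L, 1L)
        q$exons[j, "end"] <- q$exons[j, "end"] + 4L   # shifts intron j's start
      }
      if (stats::runif(1) < p$truncate_rate) {
        k <- n_exons(q)
        len <- q$exons[k, "end"] - q$exons[k, "start"] + 1L
        q$exons[k, "end"] <- q$exons[k, "end"] - as.integer(floor(0.3 * len))
      }
      preds[[length(preds) + 1L]] <- q
    }
    n_spur <- stats::rbinom(1L, p$n_genes, p$spurious_rate)
    if (n_spur > 0L) {
      for (i in seq_len(n_spur)) {
        at <- pos + 500L * i
        preds[[length(preds) + 1L]] <- transcript_model(
          sprintf("spur_tx%03d", i), sprintf("spur_g%03d", i), p$chrom, "+",
          rbind(c(at, at + 199L)))
      }
    }
    pred <- annotation(preds)
  })
  list(pred = pred, ref = ref, truth = naive_compare_annotations(pred, ref))
}

#' Naive set-arithmetic evaluation oracle
#'
#' A direct, deliberately unoptimized implementation of the five-level
#' metrics and per-transcript AED, using literal per-position string sets
#' and double loops. It shares no code with [compare_annotations()] and
#' exists to validate it (and to supply generator truth for
#' [simulate_annotation_pair()]).
#'
#' @param pred,ref Non-empty [annotation]s.
#' @param mono_threshold Mono-exonic overlap threshold; default 0.8.
#' @return A `comparison_report` with the same fields as
#'   [compare_annotations()].
#' @export
naive_compare_annotations <- function(pred, ref, mono_threshold = 0.8) {
  stopifnot(length(pred$transcripts) > 0L, length(ref$transcripts) > 0L)
  pos_set <- function(ann) {
    unique(unlist(lapply(ann$transcripts, function(t) {
      st <- if (t$strand == ".") "+" else t$strand
      unlist(lapply(seq_len(nrow(t$exons)), function(i) {
        paste(t$chrom, st, seq(t$exons[i, "start"], t$exons[i, "end"]))
      }))
    })))
  }
  key_set <- function(ann, what) {
    unique(unlist(lapply(ann$transcripts, function(t) {
      m <- if (what == "exon") t$exons else derive_intron_chain(t)
      if (nrow(m) == 0L) return(NULL)
      paste(t$chrom, t$strand, m[, "start"], m[, "end"])
    })))
  }
  metric_row <- function(level, tp, fp, fn, sn = NULL, sp = NULL) {
    if (is.null(sn)) sn <- if (tp + fn > 0) 100 * tp / (tp + fn) else 0
    if (is.null(sp)) sp <- if (tp + fp > 0) 100 * tp / (tp + fp) else 0
    f1 <- if (sn + sp == 0) 0 else 2 * sn * sp / (sn + sp)
    data.frame(level = level, tp = tp, fp = fp, fn = fn, sensitivity = sn,
               specificity = sp, f1 = f1, stringsAsFactors = FALSE)
  }

  pp <- pos_set(pred); rp <- pos_set(ref)
  tpb <- length(intersect(pp, rp))
  rows <- metric_row("base", tpb, length(pp) - tpb, length(rp) - tpb)
  for (what in c("exon", "intron")) {
    pk <- key_set(pred, what); rk <- key_set(ref, what)
    tp <- length(intersect(pk, rk))
    rows <- rbind(rows, metric_row(what, tp, length(pk) - tp, length(rk) - tp))
  }

  one_match <- function(a, b) {
    if (a$chrom != b$chrom || a$strand != b$strand) return(FALSE)
    if (n_exons(a) > 1L && n_exons(b) > 1L) {
      return(identical(unname(derive_intron_chain(a)), unname(derive_intron_chain(b))))
    }
    if (n_exons(a) == 1L && n_exons(b) == 1L) {
      sh <- min(tx_end(a), tx_end(b)) - max(tx_start(a), tx_start(b)) + 1L
      if (sh <= 0L) return(FALSE)
      return(sh / max(tx_end(a) - tx_start(a) + 1L, tx_end(b) - tx_start(b) + 1L)
             >= mono_threshold)
    }
    FALSE
  }
  pm <- vapply(pred$transcripts, function(a) {
    any(vapply(ref$transcripts, function(b) one_match(a, b), logical(1)))
  }, logical(1))
  rm_ <- vapply(ref$transcripts, function(b) {
    any(vapply(pred$transcripts, function(a) one_match(a, b), logical(1)))
  }, logical(1))
  rows <- rbind(rows, metric_row("transcript", sum(rm_), sum(!pm), sum(!rm_),
                                 sn = 100 * sum(rm_) / length(rm_),
                                 sp = 100 * sum(pm) / length(pm)))
  pg <- tapply(pm, vapply(pred$transcripts, function(t) t$gene_id, character(1)), any)
  rg <- tapply(rm_, vapply(ref$transcripts, function(t) t$gene_id, character(1)), any)
  rows <- rbind(rows, metric_row("gene", sum(rg), sum(!pg), sum(!rg),
                                 sn = 100 * sum(rg) / length(rg),
                                 sp = 100 * sum(pg) / length(pg)))

  exon_pos <- function(t) {
    unlist(lapply(seq_len(nrow(t$exons)), function(i)
      seq(t$exons[i, "start"], t$exons[i, "end"])))
  }
  aed <- vapply(pred$transcripts, function(a) {
    ap <- exon_pos(a)
    best <- 0
    for (b in ref$transcripts) {
      if (b$chrom != a$chrom || b$strand != a$strand) next
      bp <- exon_pos(b)
      sh <- length(intersect(ap, bp))
      if (sh < 1L) next
      cg <- (sh / length(bp) + sh / length(ap)) / 2
      if (cg > best) best <- cg
    }
    1 - best
  }, numeric(1))
  structure(list(metrics = rows, aed = aed), class = "comparison_report")
}

#' Write a simulated fixture to disk
#'
#' Emits `genome.fa`, `input.gtf`, `truth.gtf`, `coverage.bedgraph` and
#' `truth.json` (planted events, seed, parameters) into a directory;
#' byte-identical output under identical seed and parameters.
#'
#' @param fix A fixture list from one of the `simulate_*_fixture()`
#'   generators.
#' @param dir Output directory (created if needed).
#' @return Invisibly, `dir`.
#' @export
write_fixture <- function(fix, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(fix$genome)) write_genome(fix$genome, file.path(dir, "genome.fa"))
  write_gtf(fix$annotation, file.path(dir, "input.gtf"))
  write_gtf(fix$truth$true_annotation, file.path(dir, "truth.gtf"))
  if (!is.null(fix$coverage)) {
    write_bedgraph(fix$coverage, file.path(dir, "coverage.bedgraph"))
  }
  jsonlite::write_json(list(seed = fix$truth$seed, events = fix$truth$events,
                            params = fix$truth$params),
                       file.path(dir, "truth.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(dir)
}
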