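test_that("three-frame premature-stop screen agrees with a brute-force codon scan", {
  expect_true(has_premature_stops_all_frames("TAAATAAATAAA"))
  expect_false(has_premature_stops_all_frames("AAAAAAAAA"))
  expect_false(has_premature_stops_all_frames("TA"))
  # N-containing codons never match
  expect_false(has_premature_stops_all_frames("TNATNATNATNA"))

  withr::with_seed(99, {
    for (i in 1:100) {
      s <- paste(sample(c("A", "C", "G", "T"), 300, replace = TRUE), collapse = "")
      expect_identical(has_premature_stops_all_frames(s), oracle_all_frame_stops(s))
    }
  })
})

test_that("candidate exons are internal exons failing all three frames", {
  stopseq <- "TAAATAAATAAA"
  genome <- Biostrings::DNAStringSet(c(chr1 = paste0(
    strrep("C", 100),                 # 1-100
    strrep("C", 50),                  # exon1 101-150 (clean)
    strrep("G", 50),                  # intron 151-200
    stopseq, strrep("C", 88),         # exon2 201-300 (stops all frames)
    strrep("G", 50),                  # intron 301-350
    strrep("C", 100))))               # exon3 351-450 (clean)
  tx <- mk_tx("t", c(101, 150, 201, 300, 351, 450))
  expect_equal(select_candidate_exons(tx, genome), 2L)

  # two-exon transcripts have no internal exon
  expect_equal(select_candidate_exons(mk_tx("t2", c(101, 150, 351, 450)), genome),
               integer(0))

  # a clean internal exon is not a candidate
  tx3 <- mk_tx("t3", c(101, 150, 241, 300, 351, 450))
  expect_equal(select_candidate_exons(tx3, genome), integer(0))

  # minus-strand sequences are reverse complemented before the screen: the
  # reverse complement of this cassette stops in all frames, the cassette
  # itself in none
  genome2 <- Biostrings::DNAStringSet(c(chr1 = paste0(
    strrep("C", 200), strrep("TTTATTTATTTA", 9), strrep("C", 200))))
  txm <- mk_tx("tm", c(101, 150, 201, 308, 351, 450), strand = "-")
  expect_equal(select_candidate_exons(txm, genome2), 2L)
  txp <- mk_tx("tp", c(101, 150, 201, 308, 351, 450), strand = "+")
  expect_equal(select_candidate_exons(txp, genome2), integer(0))
})

test_that("splitting at a trough partitions the exon and conserves bases", {
  tx <- mk_tx("p", c(501, 700, 1001, 1400, 1601, 1800), gene = "gp")
  trough <- structure(list(left = 121L, right = 160L, trough_mean = 3,
                           left_flank_mean = 50, right_flank_mean = 50),
                      class = "trough_call")
  kids <- split_transcript_at_trough(tx, 2L, trough)
  expect_equal(unname(kids$left$exons),
               unname(cbind(c(501L, 1001L), c(700L, 1120L))))
  expect_equal(unname(kids$right$exons),
               unname(cbind(c(1161L, 1601L), c(1400L, 1800L))))
  expect_equal(kids$left$transcript_id, "p.split1")
  expect_equal(kids$right$gene_id, "gp.split2")

  # base conservation: children's exonic bases = parent's minus trough width
  conserve <- function(t) sum(t$exons[, "end"] - t$exons[, "start"] + 1)
  expect_equal(conserve(kids$left) + conserve(kids$right),
               conserve(tx) - (160 - 121 + 1))

  # children's intron chains partition the parent's chain
  expect_equal(unname(derive_intron_chain(kids$left)),
               unname(derive_intron_chain(tx)[1, , drop = FALSE]))
  expect_equal(unname(derive_intron_chain(kids$right)),
               unname(derive_intron_chain(tx)[2, , drop = FALSE]))

  # a trough touching the exon boundary is a trim, not a split
  edge <- structure(list(left = 1L, right = 40L, trough_mean = 3,
                         left_flank_mean = 50, right_flank_mean = 50),
                    class = "trough_call")
  expect_null(split_transcript_at_trough(tx, 2L, edge))
  expect_error(split_transcript_at_trough(tx, 1L, trough), "internal")
})

test_that("antisense end overlaps are reported for opposite strands only", {
  plus <- mk_tx("P", c(100, 300, 500, 700), "+")
  minus <- mk_tx("M", c(650, 900, 1000, 1100), "-")
  same <- mk_tx("S", c(650, 900), "+")
  dot <- mk_tx("D", c(650, 900), ".")
  ov <- find_antisense_end_overlaps(mk_ann(plus, minus))
  expect_equal(nrow(ov), 2)  # both members of the pair are implicated
  expect_setequal(ov$transcript_id, c("P", "M"))
  expect_equal(ov$which_end[ov$transcript_id == "P"], "right")
  expect_equal(ov$which_end[ov$transcript_id == "M"], "left")

  # same-strand and unstranded overlaps are not reported
  expect_equal(nrow(find_antisense_end_overlaps(mk_ann(plus, same))), 0)
  expect_equal(nrow(find_antisense_end_overlaps(mk_ann(plus, dot))), 0)

  # internal-exon overlap on the opposing side still implicates the
  # terminal exon of the query
  ov2 <- find_antisense_end_overlaps(mk_ann(
    mk_tx("A", c(100, 300, 500, 700), "+"),
    mk_tx("B", c(600, 800, 900, 1000, 1100, 1200), "-")))
  expect_true("A" %in% ov2$transcript_id)

  # the generator's planted pair is recovered exactly
  af <- simulate_antisense_fixture(3, params = list(noise = "none"))
  ovf <- find_antisense_end_overlaps(af$annotation)
  expect_setequal(ovf$transcript_id, c("txP", "txM"))
  expect_equal(ovf$which_end[ovf$transcript_id == "txP"], "right")
})

test_that("end trimming cuts at the outermost qualifying changepoint", {
  tx <- mk_tx("P", c(100, 200, 301, 500), "+")
  cov <- coverage_track(list(chr1 = c(numeric(300),
                                      rep(40, 150), rep(4, 50))))
  out <- trim_end_exon(tx, "right", cov)
  expect_equal(unname(out$exons[2, ]), c(301L, 450L))
  expect_match(out$attributes[["trimmed"]], "chr1:301-500")

  # uniform coverage: unchanged
  cov2 <- coverage_track(list(chr1 = c(numeric(300), rep(40, 200))))
  expect_equal(trim_end_exon(tx, "right", cov2)$exons, tx$exons)

  # left-end trimming mirrors
  txl <- mk_tx("Q", c(101, 300, 401, 500), "+")
  covl <- coverage_track(list(chr1 = c(numeric(100), rep(4, 60), rep(40, 140))))
  outl <- trim_end_exon(txl, "left", covl)
  expect_equal(unname(outl$exons[1, ]), c(161L, 300L))

  # an exon shorter than two minimum segments is skipped, not modified
  short <- mk_tx("R", c(100, 130, 200, 300), "+")
  sk <- trim_end_exon(short, "left", cov2)
  expect_equal(sk$exons, short$exons)
  expect_match(sk$attributes[["trim_skipped"]], "left")
})

test_that("redundant transcripts are removed per containment rules, idempotently", {
  # 10-transcript set with 4 planted proper subsets
  base1 <- mk_tx("k01", c(100, 200, 301, 400, 501, 600))     # kept
  sub1 <- mk_tx("r01", c(150, 200, 301, 400, 501, 550))      # same chain, inside
  sub2 <- mk_tx("r02", c(320, 400, 501, 580))                # contiguous sub-chain
  base2 <- mk_tx("k02", c(1000, 1200), "-")                  # kept mono
  sub3 <- mk_tx("r03", c(1050, 1150), "-")                   # mono inside mono
  sub4 <- mk_tx("r04", c(105, 195))                          # mono inside an exon
  keep3 <- mk_tx("k03", c(2000, 2100, 2201, 2300), "-")      # kept, other strand
  keep4 <- mk_tx("k04", c(100, 200, 311, 400, 501, 600))     # chain differs by 10
  keep5 <- mk_tx("k05", c(5000, 5600))                       # kept mono
  keep6 <- mk_tx("k06", c(301, 400, 501, 700))               # sub-chain of k01 but span extends past it: kept
  ann <- mk_ann(base1, sub1, sub2, base2, sub3, sub4, keep3, keep4, keep5, keep6)
  res <- remove_redundant_transcripts(ann)
  expect_setequal(res$removed_ids, c("r01", "r02", "r03", "r04"))
  again <- remove_redundant_transcripts(res$annotation)
  expect_length(again$removed_ids, 0)

  # identical transcripts: smaller id kept
  dup <- mk_ann(mk_tx("b", c(1, 100, 201, 300)), mk_tx("a", c(1, 100, 201, 300)))
  res2 <- remove_redundant_transcripts(dup)
  expect_equal(res2$removed_ids, "b")

  # random annotations agree with the brute-force containment oracle
  withr::with_seed(77, {
    for (i in 1:25) {
      ra <- random_annotation(12)
      got <- remove_redundant_transcripts(ra)
      expect_setequal(got$removed_ids, oracle_redundant_ids(ra))
      # idempotent and pairwise non-redundant output
      expect_length(remove_redundant_transcripts(got$annotation)$removed_ids, 0)
    }
  })
})

test_that("polish pipeline is a fixed point on clean annotations", {
  genome <- Biostrings::DNAStringSet(c(chr1 = strrep("C", 2000)))
  cov <- coverage_track(list(chr1 = rep(20, 2000)))
  ann <- mk_ann(mk_tx("a", c(100, 300, 401, 600)),
                mk_tx("b", c(900, 1000, 1101, 1300), "-"))
  res <- polish_annotation(ann, cov, genome)
  expect_true(annopolish:::annotations_equal(res$annotation, ann))
  rep <- res$report
  expect_equal(rep$n_redundant_removed + rep$n_transcripts_split +
                 rep$n_ends_trimmed, 0)
  # strand and chromosome are never changed
  for (id in names(res$annotation$transcripts)) {
    expect_equal(res$annotation$transcripts[[id]]$strand,
                 ann$transcripts[[id]]$strand)
  }

  # missing coverage chromosome is a hard error naming it
  ann2 <- mk_ann(mk_tx("c", c(10, 50), chrom = "chrZ"))
  expect_error(polish_annotation(ann2, cov, genome), "chrZ")
})

test_that("polishing splits the merged-gene fixture at the planted gap", {
  fx <- simulate_merged_gene_fixture(11, params = list(noise = "none"))
  res <- polish_annotation(fx$annotation, fx$coverage, fx$genome)
  expect_equal(res$report$n_transcripts_split, 1)
  txs <- res$annotation$transcripts
  expect_length(txs, 2)
  ev <- fx$truth$events[[1]]
  # noise-free: exact boundaries
  expect_equal(tx_end(txs[["tx_merged.split1"]]), ev$left_true_end)
  expect_equal(tx_start(txs[["tx_merged.split2"]]), ev$right_true_start)
  # report invariants
  expect_lte(res$report$n_transcripts_split, res$report$n_troughs_found)
  expect_lte(res$report$n_troughs_found, res$report$n_candidate_exons)
})

test_that("polishing the combined fixture removes, splits and trims as planted", {
  fx <- simulate_combined_fixture(5, params = list(noise = "none"))
  res <- polish_annotation(fx$annotation, fx$coverage, fx$genome)
  expect_equal(res$report$n_redundant_removed, 2)
  expect_equal(res$report$n_transcripts_split, 1)
  expect_gte(res$report$n_ends_trimmed, 1)
  after <- compare_annotations(res$annotation, fx$truth$true_annotation)
  expect_equal(after$metrics$f1, rep(100, 5))
})
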