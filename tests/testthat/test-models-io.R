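test_that("transcript model invariants are enforced", {
  expect_error(mk_tx("a", c(10, 5)), "start > end")
  expect_error(mk_tx("a", c(1, 10, 10, 20)), "overlap or touch")
  expect_error(mk_tx("a", c(1, 10, 5, 20)), "overlap|sorted")
  expect_error(transcript_model("a", "g", "", "+", cbind(1, 10)), "empty chromosome")
  expect_error(annotation(list(mk_tx("a", c(1, 10)), mk_tx("a", c(20, 30)))),
               "duplicate transcript_id")
})

test_that("intron chains follow from consecutive exon gaps", {
  expect_equal(unname(derive_intron_chain(mk_tx("a", c(101, 200, 301, 400)))),
               cbind(201L, 300L), ignore_attr = TRUE)
  expect_equal(nrow(derive_intron_chain(mk_tx("a", c(5, 500)))), 0L)
  expect_equal(unname(derive_intron_chain(mk_tx("a", c(1, 10, 12, 20, 30, 40)))),
               unname(cbind(c(11L, 21L), c(11L, 29L))))
})

test_that("GTF round-trips through write and parse", {
  gtf <- tempfile(fileext = ".gtf")
  writeLines(c(
    'chr1\tsrc\texon\t101\t200\t.\t+\t.\tgene_id "g1"; transcript_id "t1";',
    'chr1\tsrc\texon\t301\t400\t.\t+\t.\tgene_id "g1"; transcript_id "t1";'),
    gtf)
  ann <- parse_gtf(gtf)
  expect_length(ann$transcripts, 1)
  tx <- ann$transcripts[["t1"]]
  expect_equal(n_exons(tx), 2)
  expect_equal(unname(derive_intron_chain(tx)), cbind(201L, 300L),
               ignore_attr = TRUE)

  out <- tempfile(fileext = ".gtf")
  write_gtf(ann, out)
  expect_true(annotations_equal <- local({
    re <- parse_gtf(out)
    isTRUE(all.equal(re$transcripts[["t1"]]$exons, tx$exons)) &&
      re$transcripts[["t1"]]$gene_id == "g1"
  }))

  # a richer annotation survives the round trip field by field
  ann2 <- mk_ann(mk_tx("tA", c(100, 200, 250, 300), "-"),
                 mk_tx("tB", c(50, 80), "+", chrom = "chr2"),
                 mk_tx("tC", c(500, 600, 700, 800, 900, 950), "+"))
  f <- tempfile(fileext = ".gtf")
  write_gtf(ann2, f)
  back <- parse_gtf(f)
  for (id in names(ann2$transcripts)) {
    expect_equal(back$transcripts[[id]]$exons, ann2$transcripts[[id]]$exons)
    expect_equal(back$transcripts[[id]]$strand, ann2$transcripts[[id]]$strand)
  }
  # one exon feature line per exon
  expect_length(readLines(f), 6L)

  # empty annotation writes an empty file
  ef <- tempfile(fileext = ".gtf")
  write_gtf(annotation(list()), ef)
  expect_length(readLines(ef), 0L)
})

test_that("GTF parse errors carry line numbers and transcript names", {
  f <- tempfile(fileext = ".gtf")
  writeLines(c(
    'chr1\tsrc\texon\t101\t200\t.\t+\t.\tgene_id "g1"; transcript_id "t1";',
    "chr1\tsrc\texon\t300"), f)
  expect_error(parse_gtf(f), "line 2")

  writeLines('chr1\tsrc\texon\t200\t101\t.\t+\t.\tgene_id "g"; transcript_id "t";', f)
  expect_error(parse_gtf(f), "start > end")

  writeLines(c(
    'chr1\tsrc\texon\t101\t200\t.\t+\t.\tgene_id "g"; transcript_id "t";',
    'chr1\tsrc\texon\t150\t250\t.\t+\t.\tgene_id "g"; transcript_id "t";'), f)
  expect_error(parse_gtf(f), "t")

  writeLines(c(
    'chr1\tsrc\texon\t101\t200\t.\t+\t.\tgene_id "g1"; transcript_id "t1";',
    'chr1\tsrc\texon\t301\t400\t.\t+\t.\tgene_id "g2"; transcript_id "t1";'), f)
  expect_error(parse_gtf(f), "multiple gene_ids")
})

test_that("parsing a generated fixture reproduces the generator's truth", {
  fx <- simulate_merged_gene_fixture(7, params = list(noise = "none"))
  d <- tempfile()
  write_fixture(fx, d)
  back <- parse_gtf(file.path(d, "truth.gtf"))
  expect_setequal(names(back$transcripts), names(fx$truth$true_annotation$transcripts))
  for (id in names(back$transcripts)) {
    expect_equal(back$transcripts[[id]]$exons,
                 fx$truth$true_annotation$transcripts[[id]]$exons)
  }
})

test_that("bedGraph expands 0-based half-open records to per-base depth", {
  f <- tempfile(fileext = ".bedgraph")
  writeLines("chr1\t0\t5\t7", f)
  cov <- parse_bedgraph(f)
  expect_equal(coverage_slice(cov, "chr1", 1, 5), rep(7, 5))
  expect_equal(coverage_slice(cov, "chr1", 6, 10), rep(0, 5))

  # overlapping records sum
  writeLines(c("chr1\t0\t10\t3", "chr1\t5\t15\t2"), f)
  cov <- parse_bedgraph(f)
  expect_equal(coverage_slice(cov, "chr1", 6, 6), 5)
  expect_equal(coverage_slice(cov, "chr1", 3, 3), 3)
  expect_equal(coverage_slice(cov, "chr1", 12, 12), 2)

  # mass conservation: sum of depths equals sum of value * width
  expect_equal(sum(coverage_slice(cov, "chr1", 1, 20)), 3 * 10 + 2 * 10)

  # empty file with a genome gives an all-zero track of genome length
  writeLines(character(0), f)
  genome <- Biostrings::DNAStringSet(c(chr1 = paste(rep("A", 100), collapse = "")))
  cov <- parse_bedgraph(f, genome)
  expect_equal(coverage_slice(cov, "chr1", 1, 100), rep(0, 100))

  writeLines("chr1\t5\t5\t1", f)
  expect_error(parse_bedgraph(f), "end <= start")
  writeLines("chr1\t0\t5\t-2", f)
  expect_error(parse_bedgraph(f), "negative")
})

test_that("exon sequences are strand oriented", {
  genome <- Biostrings::DNAStringSet(c(chr1 = "ATGTAA", chr2 = "ACGNNT"))
  expect_equal(exon_sequence(genome, "chr1", 1, 6, "+"), "ATGTAA")
  expect_equal(exon_sequence(genome, "chr1", 1, 6, "-"), "TTACAT")
  expect_equal(exon_sequence(genome, "chr1", 1, 6, "."), "ATGTAA")
  expect_equal(exon_sequence(genome, "chr2", 3, 5, "+"), "GNN")
  expect_error(exon_sequence(genome, "chr1", 2, 9, "+"), "chr1:2-9")
  expect_error(exon_sequence(genome, "chrX", 1, 2, "+"), "chrX")

  # reverse-complement identity on random sequence
  withr::with_seed(11, {
    s <- paste(sample(c("A", "C", "G", "T"), 60, replace = TRUE), collapse = "")
  })
  g2 <- Biostrings::DNAStringSet(c(c1 = s))
  fwd <- exon_sequence(g2, "c1", 10, 40, "+")
  rev <- exon_sequence(g2, "c1", 10, 40, "-")
  expect_equal(rev, as.character(Biostrings::reverseComplement(Biostrings::DNAString(fwd))))
})
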