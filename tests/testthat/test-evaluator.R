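test_that("intron-chain matching ignores end extents and is exact on introns", {
  a <- mk_tx("a", c(101, 200, 301, 400))
  b <- mk_tx("b", c(51, 200, 301, 480))    # same introns, longer UTRs
  c_ <- mk_tx("c", c(101, 200, 302, 400))  # intron shifted by one base
  d <- mk_tx("d", c(101, 200, 301, 400), "-")
  expect_true(intron_chain_match(a, a))
  expect_true(intron_chain_match(a, b))
  expect_false(intron_chain_match(a, c_))
  expect_false(intron_chain_match(a, d))
  expect_error(intron_chain_match(a, mk_tx("m", c(1, 500))), "mono")
})

test_that("mono-exonic matching uses shared over the longer length", {
  m <- function(id, s, e) mk_tx(id, c(s, e))
  expect_true(mono_overlap_match(m("a", 1, 100), m("b", 1, 100)))
  expect_true(mono_overlap_match(m("a", 1, 100), m("b", 21, 120)))   # 80/100
  expect_false(mono_overlap_match(m("a", 1, 100), m("b", 22, 121)))  # 79/100
  expect_false(mono_overlap_match(m("a", 1, 100), m("b", 61, 160)))
  # a tiny prediction inside a long reference does not count
  expect_false(mono_overlap_match(m("a", 1, 50), m("b", 1, 1000)))
  expect_error(mono_overlap_match(m("a", 1, 50), mk_tx("x", c(1, 10, 20, 30))),
               "mono")
})

test_that("identity comparison scores 100 at every level with AED 0", {
  ann <- mk_ann(mk_tx("a", c(101, 200, 301, 400), gene = "g1"),
                mk_tx("b", c(900, 1100), "-", gene = "g2"),
                mk_tx("c", c(2000, 2200, 2301, 2500, 2601, 2700), gene = "g3"))
  rep <- compare_annotations(ann, ann)
  expect_equal(rep$metrics$f1, rep(100, 5))
  expect_equal(rep$metrics$sensitivity, rep(100, 5))
  expect_equal(unname(rep$aed), rep(0, 3))
})

test_that("the hand toy reproduces the oracle-computed metric vector", {
  ref <- mk_ann(mk_tx("r", c(101, 200, 301, 400), gene = "gr"))
  pred <- mk_ann(mk_tx("p", c(101, 200, 301, 350), gene = "gp"))
  # frozen from the naive position-set oracle: shared bases 150 of 200
  # reference / 150 predicted; one of two exons exact each side; the single
  # intron identical; chains match
  rep <- compare_annotations(pred, ref)
  m <- rep$metrics
  expect_equal(m$sensitivity[m$level == "base"], 75)
  expect_equal(m$specificity[m$level == "base"], 100)
  expect_equal(m$sensitivity[m$level == "exon"], 50)
  expect_equal(m$specificity[m$level == "exon"], 50)
  expect_equal(m$sensitivity[m$level == "intron"], 100)
  expect_equal(m$specificity[m$level == "intron"], 100)
  expect_equal(m$sensitivity[m$level == "transcript"], 100)
  expect_equal(m$specificity[m$level == "transcript"], 100)
  expect_equal(m$sensitivity[m$level == "gene"], 100)
  # and the whole report equals the independent oracle
  want <- naive_compare_annotations(pred, ref)
  expect_equal(rep$metrics, want$metrics)
  expect_equal(rep$aed, want$aed)

  expect_error(compare_annotations(pred, annotation(list())), "reference")
  expect_error(compare_annotations(annotation(list()), ref), "predicted")
})

test_that("AED follows the best-congruence definition", {
  ref <- mk_ann(mk_tx("r", c(1, 200), gene = "gr"),
                mk_tx("r2", c(1000, 1100, 1201, 1300), gene = "gr2"))
  expect_equal(compute_aed(mk_tx("p", c(1, 200)), ref), 0)
  expect_equal(compute_aed(mk_tx("p", c(5000, 5100)), ref), 1)
  # pred 1-100 vs ref 1-200: SN 0.5, SP 1.0 -> AED 0.25
  expect_equal(compute_aed(mk_tx("p", c(1, 100)), ref), 0.25)
  # chain match with identical ends implies AED 0
  expect_equal(compute_aed(mk_tx("p", c(1000, 1100, 1201, 1300)), ref), 0)
})

test_that("swapping prediction and reference swaps sensitivity and specificity", {
  withr::with_seed(123, {
    for (i in 1:15) {
      a <- random_annotation(8, "a")
      b <- random_annotation(8, "b")
      ab <- compare_annotations(a, b)$metrics
      ba <- compare_annotations(b, a)$metrics
      expect_equal(ab$sensitivity, ba$specificity, tolerance = 1e-12)
      expect_equal(ab$specificity, ba$sensitivity, tolerance = 1e-12)
      # F1 is bounded by the geometric and arithmetic means of SN and SP
      gm <- sqrt(ab$sensitivity * ab$specificity)
      expect_true(all(ab$f1 <= gm + 1e-9))
      expect_true(all(gm <= (ab$sensitivity + ab$specificity) / 2 + 1e-9))
    }
  })
})

test_that("evaluator matches the naive oracle on corrupted annotation pairs", {
  for (s in 1:10) {
    pr <- simulate_annotation_pair(s, params = list(
      n_genes = 20, drop_rate = 0.2, shift_rate = 0.2,
      truncate_rate = 0.2, spurious_rate = 0.2))
    got <- compare_annotations(pr$pred, pr$ref)
    expect_equal(got$metrics, pr$truth$metrics)
    expect_equal(got$aed, pr$truth$aed)
  }
})
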