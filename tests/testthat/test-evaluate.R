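test_that("concordance is intersect over union as a percentage", {
  expect_equal(concordance(c("a", "b"), c("a", "b")), 100)
  expect_equal(concordance(c("a", "b"), c("c", "d")), 0)
  expect_equal(concordance(c("a", "b", "c"), c("b", "c", "d")), 50)
  expect_true(is.na(concordance(character(), character())))
  ## symmetric, bounded, 100 iff equal
  set.seed(77)
  for (rep in 1:10) {
    a <- sample(letters, sample(1:10, 1))
    b <- sample(letters, sample(1:10, 1))
    expect_equal(concordance(a, b), concordance(b, a))
    expect_gte(concordance(a, b), 0)
    expect_lte(concordance(a, b), 100)
    if (setequal(a, b)) expect_equal(concordance(a, b), 100)
    else expect_lt(concordance(a, b), 100)
  }
})

test_that("classification honours the AllSomatic-but-not-HC ignore rule", {
  ref_all <- c("v1", "v2", "v3", "v4")
  ref_hc <- c("v1", "v2")
  ## a test call in AllSomatic but not HC is ignored, not a false positive
  ec <- classifyCalls(c("v1", "v3", "v9"), ref_all, ref_hc)
  expect_equal(ec@tp, 1)
  expect_equal(ec@ignored, 1)
  expect_equal(ec@fp, 1)
  expect_equal(ec@fn, 1)
  ## exact HC recovery
  ec2 <- classifyCalls(ref_hc, ref_all, ref_hc)
  expect_equal(c(ec2@fp, ec2@fn), c(0, 0))
  expect_error(classifyCalls("x", "a", "b"), "subset")
})

test_that("classification equals brute-force set arithmetic on random sets", {
  set.seed(88)
  for (rep in 1:10) {
    univ <- paste0("v", 1:30)
    ref_all <- sample(univ, 15)
    ref_hc <- sample(ref_all, 8)
    test <- sample(univ, 12)
    ec <- classifyCalls(test, ref_all, ref_hc)
    expect_equal(ec@tp, sum(test %in% ref_hc))
    expect_equal(ec@fp, sum(!test %in% ref_all))
    expect_equal(ec@fn, sum(!ref_hc %in% test))
    expect_equal(ec@ignored, sum(test %in% ref_all & !test %in% ref_hc))
    ## conservation: every test call is tp, fp or ignored
    expect_equal(ec@tp + ec@fp + ec@ignored, length(test))
  }
})

test_that("precision, recall and F1 follow the standard formulas", {
  ec <- EvalCounts(tp = 9, fp = 1, fn = 3)
  expect_equal(ec@precision, 0.9)
  expect_equal(ec@recall, 0.75)
  expect_equal(ec@f1, 2 * 0.9 * 0.75 / (0.9 + 0.75))
  z <- EvalCounts(0, 0, 0)
  expect_true(all(is.na(c(z@precision, z@recall, z@f1))))
  perfect <- EvalCounts(tp = 5, fp = 0, fn = 0)
  expect_equal(c(perfect@precision, perfect@recall, perfect@f1), c(1, 1, 1))
  expect_equal(evalMetrics(precisionRecallF1(ec)), evalMetrics(ec))
})

test_that("base-level CNV comparison does interval arithmetic per category", {
  ref <- CNVSegments(chrom = c("chr1", "chr1"), start = c(50L, 300L),
                     end = c(150L, 400L), obs_log2 = c(-1, 0.5))
  test <- CNVSegments(chrom = "chr1", start = 0L, end = 100L, obs_log2 = -1)
  del <- cnvBaseCompare(test, ref, "DEL")
  expect_equal(c(del@tp, del@fp, del@fn), c(50, 50, 50))
  amp <- cnvBaseCompare(test, ref, "AMP")
  expect_equal(c(amp@tp, amp@fp, amp@fn), c(0, 0, 100))
  ## identical sets: no fp/fn, tp equals categorized bases
  same <- cnvBaseCompare(ref, ref, "DEL")
  expect_equal(c(same@tp, same@fp, same@fn), c(100, 0, 0))
  ## overlapping segments within one sample are rejected
  bad <- CNVSegments(chrom = c("chr1", "chr1"), start = c(0L, 50L),
                     end = c(100L, 150L), obs_log2 = c(-1, -1))
  expect_error(cnvBaseCompare(bad, ref, "DEL"), "overlap")
})

test_that("interval CNV comparison equals a dense per-base oracle", {
  set.seed(99)
  for (rep in 1:5) {
    contig <- 10000L
    mkseg <- function() {
      cuts <- sort(sample.int(contig - 1L, 6))
      bounds <- c(0L, cuts, contig)
      CNVSegments(chrom = "chr1", start = bounds[-8], end = bounds[-1],
                  obs_log2 = sample(c(-1, 0, 0.6), 7, TRUE))
    }
    test <- mkseg(); ref <- mkseg()
    paint <- function(seg, cat) {
      v <- logical(contig)
      s <- recordTable(seg)
      s <- s[s$category == cat, , drop = FALSE]
      for (i in seq_len(nrow(s))) v[(s$start[i] + 1):s$end[i]] <- TRUE
      v
    }
    for (cat in c("AMP", "DEL")) {
      got <- cnvBaseCompare(test, ref, cat)
      a <- paint(test, cat); b <- paint(ref, cat)
      expect_equal(got@tp, sum(a & b))
      expect_equal(got@fp, sum(a & !b))
      expect_equal(got@fn, sum(!a & b))
    }
  }
})

test_that("VAF-binned recall partitions the reference by left-closed bins", {
  ref <- paste0("v", 1:8)
  vaf <- c(0.05, 0.15, 0.15, 0.25, 0.45, 0.45, 0.8, 1.0)
  test <- ref[c(1, 2, 4, 5, 6, 7, 8)]  # miss v3 (bin [0.1,0.2))
  out <- recallByVafBin(test, ref, vaf,
                        bin_edges = c(0, 0.1, 0.2, 0.3, 0.5, 1))
  expect_equal(sum(out$n_ref), 8)
  expect_equal(out$recall[out$bin == "[0.1,0.2)"], 0.5)
  expect_true(all(out$recall[out$bin != "[0.1,0.2)"] == 1, na.rm = TRUE))
  ## a single [0,1] bin reproduces the overall recall
  one <- recallByVafBin(test, ref, vaf, bin_edges = c(0, 1))
  expect_equal(one$recall, 7 / 8)
  expect_error(recallByVafBin(test, ref, c(vaf[-8], 1.2), c(0, 1)),
               "VAF")
})

test_that("SV set membership uses the merge criteria, not exact keys", {
  ref <- mkSv(s1 = 10000L, s2 = 60000L)
  near <- mkSv(s1 = 10140L, s2 = 60160L, callers = "lumpy")
  far <- mkSv(s1 = 300000L, s2 = 400000L, callers = "lumpy")
  expect_true(svSeenIn(near, ref))
  expect_false(svSeenIn(far, ref))
  ec <- classifySvCalls(near, ref_all = ref, ref_hc = ref)
  expect_equal(c(ec@tp, ec@fp, ec@fn), c(1, 0, 0))
  ec2 <- classifySvCalls(far, ref_all = ref, ref_hc = ref)
  expect_equal(c(ec2@tp, ec2@fp, ec2@fn), c(0, 1, 1))
})
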