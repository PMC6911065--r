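test_that("pileup counts unique passing fragments", {
  ev <- mkEvidence(n_alt = 6, n_ref = 4)
  pc <- pileupCounts(ev)
  expect_equal(pc$alt_count, 6)
  expect_equal(pc$ref_count, 4)
  expect_equal(pc$depth, 10)
  expect_equal(pc$vaf, 0.6)
  expect_equal(pc$source, "PILEUP")
})

test_that("pileup deduplicates read pairs and drops discordant mates", {
  ## both mates ALT -> one fragment
  ev <- data.frame(fragment_id = c("f1", "f1", "f2"),
                   allele = c("ALT", "ALT", "REF"),
                   mq = 60, bq = 30, is_duplicate = FALSE,
                   is_supplementary = FALSE, is_qcfail = FALSE,
                   is_unmapped = FALSE)
  pc <- pileupCounts(ev)
  expect_equal(pc$alt_count, 1)
  expect_equal(pc$depth, 2)
  ## mates disagreeing on the allele are dropped entirely
  ev$allele <- c("ALT", "REF", "REF")
  pc2 <- pileupCounts(ev)
  expect_equal(pc2$alt_count, 0)
  expect_equal(pc2$depth, 1)  # the discordant fragment leaves the pileup
})

test_that("pileup enforces flag and quality exclusions at the threshold", {
  ev <- mkEvidence(n_alt = 3, n_ref = 3)
  ev$mq[1] <- 9    # just below
  ev$bq[2] <- 9
  ev$mq[3] <- 10   # at threshold: passes
  ev$is_duplicate[4] <- TRUE
  pc <- pileupCounts(ev)
  expect_equal(pc$alt_count, 1)
  expect_equal(pc$ref_count, 2)
  ## OTHER fragments add depth but no allele counts
  ev2 <- mkEvidence(n_alt = 2, n_ref = 2, n_other = 3)
  pc2 <- pileupCounts(ev2)
  expect_equal(pc2$depth, 7)
  expect_equal(pc2$vaf, 0.5)
})

test_that("pileup equals a brute-force fragment tally on random evidence", {
  set.seed(33)
  for (rep in 1:10) {
    n <- sample(10:60, 1)
    ev <- data.frame(
      fragment_id = paste0("f", sample(1:30, n, TRUE)),
      allele = sample(c("REF", "ALT", "OTHER"), n, TRUE, c(.5, .4, .1)),
      mq = sample(c(0, 9, 10, 60), n, TRUE),
      bq = sample(c(2, 9, 10, 30), n, TRUE),
      is_duplicate = runif(n) < .1, is_supplementary = runif(n) < .05,
      is_qcfail = runif(n) < .05, is_unmapped = runif(n) < .05)
    pc <- pileupCounts(ev)
    ## oracle: explicit per-fragment reasoning
    keep <- with(ev, !is_duplicate & !is_supplementary & !is_qcfail &
                   !is_unmapped & mq >= 10 & bq >= 10)
    fr <- split(ev$allele[keep], ev$fragment_id[keep])
    alleles <- unlist(lapply(fr, function(a)
      if (length(unique(a)) == 1L) a[1] else NULL))
    expect_equal(pc$alt_count, sum(alleles == "ALT"))
    expect_equal(pc$ref_count, sum(alleles == "REF"))
    expect_equal(pc$depth, length(alleles))
    ## monotonicity: raising thresholds never increases counts
    hi <- pileupCounts(ev, mq_min = 30, bq_min = 20)
    expect_lte(hi$alt_count, pc$alt_count)
    expect_lte(hi$ref_count, pc$ref_count)
    expect_lte(hi$depth, pc$depth)
  }
})

test_that("final counts use pileup for SNVs and short indels, callers for long", {
  pileup_t <- list(pileupCounts(mkEvidence(5, 15)))
  pileup_n <- list(pileupCounts(mkEvidence(0, 20)))
  cc <- data.frame(caller = c("mutect2", "lancet"),
                   t_ref = c(30, 28), t_alt = c(9, 11),
                   t_depth = c(40, 40), n_ref = c(20, 19),
                   n_alt = c(0, 0), n_depth = c(20, 19))
  ## 5 nt deletion -> pileup
  del5 <- mkVar(ref = "ATTTTT", alt = "A", callers = "mutect2",
                caller_counts = list(cc))
  names(pileup_t) <- names(pileup_n) <- recordKeys(del5)
  out <- selectFinalCounts(del5, pileup_t, pileup_n)
  expect_equal(recordTable(out)$t_source, "PILEUP")
  expect_equal(recordTable(out)$t_vaf, 0.25)
  ## 15 nt insertion called by mutect2+lancet -> mutect2 (strelka2 absent)
  ins15 <- mkVar(ref = "A", alt = paste0("A", strrep("T", 15)),
                 callers = list(c("mutect2", "lancet")),
                 caller_counts = list(cc))
  out2 <- selectFinalCounts(ins15, NULL, NULL)
  expect_equal(recordTable(out2)$t_source, "MUTECT2")
  expect_equal(recordTable(out2)$t_alt, 9)
  ## svaba-only 15 nt indel -> no final counts
  sv_only <- mkVar(ref = "A", alt = paste0("A", strrep("T", 15)),
                   callers = "svaba")
  out3 <- selectFinalCounts(sv_only, NULL, NULL)
  expect_equal(recordTable(out3)$t_source, "NONE")
  expect_true(is.na(recordTable(out3)$t_vaf))
})

test_that("count filters tag at the documented boundaries", {
  mk <- function(tv, nv, td = 100, nd = 100)
    mkVar(callers = "strelka2", t_vaf = tv, t_depth = td, t_source = "PILEUP",
          n_vaf = nv, n_depth = nd, n_source = "PILEUP")
  tag1 <- function(x) filterTags(applySomaticFilters(x))[[1]]
  expect_equal(tag1(mk(0.00005, 0)), "LOW_TUMOR_VAF")
  expect_equal(tag1(mk(0.0001, 0)), character())     # boundary passes
  expect_equal(tag1(mk(0.5, 0.25)), "HIGH_NORMAL_VAF")
  expect_equal(tag1(mk(0.5, 0.2)), character())      # boundary passes
  expect_equal(tag1(mk(0.10, 0.12)),
               c("HIGH_NORMAL_VAF"[FALSE], "NORMAL_GT_TUMOR"))
  expect_equal(tag1(mk(0.5, 0, td = 1)), "LOW_DEPTH")
  expect_equal(tag1(mk(0.5, 0, nd = 1)), "LOW_DEPTH")
  expect_equal(tag1(mk(0.5, 0, td = 2, nd = 2)), character())
})

test_that("records without counts stay AllSomatic with NO_COUNTS", {
  x <- mkVar(callers = "svaba", t_source = "NONE", n_source = "NONE")
  y <- applySomaticFilters(x)
  expect_equal(filterTags(y)[[1]], "NO_COUNTS")
  expect_true(isAllSomatic(y))
  ## re-running filters is idempotent
  expect_equal(recordTable(applySomaticFilters(y)), recordTable(y))
})

test_that("AllSomatic membership is a pure function of the tags", {
  x <- SmallVariants(chrom = rep("chr1", 3), pos = c(1L, 2L, 3L),
                     ref = "A", alt = "G", callers = "mutect2",
                     filters = list(character(), "PON",
                                    c("NO_COUNTS")))
  expect_equal(isAllSomatic(x), c(TRUE, FALSE, TRUE))
})
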