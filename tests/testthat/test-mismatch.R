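test_that("longest homopolymer runs; N breaks runs and is never counted", {
  r <- longestRuns("AAAT")
  expect_equal(r[1, ], c(A = 3L, C = 0L, G = 0L, T = 1L))
  expect_equal(unname(longestRuns("")[1, ]), rep(0L, 4))
  expect_equal(longestRuns("GGANGG")[1, "G"], c(G = 2L))
  expect_error(longestRuns("ACGX"), "non-ACGTN")
})

test_that("run-length distributions are normalized per base and read index", {
  d <- runLengthDistribution(c("AAAA", "AAAA"))
  a4 <- d[d$base == "A" & d$run_length == 4, ]
  expect_equal(a4$fraction, 1)
  sums <- tapply(d$fraction, d$base, sum)
  expect_true(all(abs(sums - 1) < 1e-12))
  ## inflated G runs shift the G distribution right (fixed seeds)
  ref <- c(chr1 = paste(rep("ACGT", 500), collapse = ""))
  plain <- simulateReads(ref, depth = 3, errorProfile(rate = 0),
                         read_length = 100, seed = 5)
  puffy <- simulateReads(ref, depth = 3,
                         errorProfile(rate = 0, g_run_extend = 0.25),
                         read_length = 100, seed = 5)
  mean_run <- function(reads) {
    d <- runLengthDistribution(reads$reads$seq)
    g <- d[d$base == "G", ]
    sum(g$run_length * g$fraction)
  }
  expect_gt(mean_run(puffy), mean_run(plain))
})

test_that("a read identical to the reference yields zero mismatches", {
  ref <- c(chr1 = "ACGTACGTACGTACGTACGT")
  reads <- data.frame(qname = "f1", read_index = "R1", chrom = "chr1",
                      pos = 3L, seq = substr(ref[[1]], 3, 14),
                      qual = strrep("?", 12),  # Q30
                      mapq = 60L, cigar = NA_character_,
                      is_reverse = FALSE, is_duplicate = FALSE,
                      is_supplementary = FALSE, is_qcfail = FALSE,
                      is_unmapped = FALSE)
  mc <- profileMismatches(reads, ref)
  expect_equal(sum(mc@counts), 0)
  ## both read ends lack a flank inside the alignment
  expect_equal(mc@eligible_bases, 10)
  expect_equal(mismatchRate(mc), 0)
})

test_that("mismatch channels follow read-strand orientation", {
  ## reference ...A G T...; read carries G>T at the middle position
  ref <- c(chr1 = "CCCCAGTCCCC")
  mkread <- function(rev) data.frame(
    qname = "f1", read_index = "R1", chrom = "chr1", pos = 4L,
    seq = "CATTC",  # ref CAGTC with G>T
    qual = strrep("?", 5), mapq = 60L, cigar = NA_character_,
    is_reverse = rev, is_duplicate = FALSE, is_supplementary = FALSE,
    is_qcfail = FALSE, is_unmapped = FALSE)
  fwd <- profileMismatches(mkread(FALSE), ref)
  expect_equal(sum(fwd@counts), 1)
  expect_equal(unname(fwd@counts["A[G>T]T"]), 1)
  ## same alignment flagged reverse: alleles and context reverse-complement
  rev <- profileMismatches(mkread(TRUE), ref)
  expect_equal(sum(rev@counts), 1)
  expect_equal(unname(rev@counts["A[C>A]T"]), 1)
})

test_that("flagged, low-quality and context-incomplete bases are excluded", {
  ref <- c(chr1 = "CCCCAGTCCCC")
  base <- data.frame(
    qname = "f1", read_index = "R1", chrom = "chr1", pos = 4L,
    seq = "CATTC", qual = strrep("?", 5), mapq = 60L,
    cigar = NA_character_, is_reverse = FALSE, is_duplicate = FALSE,
    is_supplementary = FALSE, is_qcfail = FALSE, is_unmapped = FALSE)
  for (flag in c("is_duplicate", "is_supplementary", "is_qcfail",
                 "is_unmapped")) {
    rd <- base; rd[[flag]] <- TRUE
    mc <- profileMismatches(rd, ref)
    expect_equal(mc@eligible_bases, 0)
    expect_equal(sum(mc@counts), 0)
  }
  low_mq <- base; low_mq$mapq <- 9L
  expect_equal(profileMismatches(low_mq, ref)@eligible_bases, 0)
  ## dropping base quality below 10 at the mismatch silences it
  low_bq <- base; low_bq$qual <- paste0(substr(low_bq$qual, 1, 2), ")",
                                        substr(low_bq$qual, 4, 5))
  mc2 <- profileMismatches(low_bq, ref)
  expect_equal(sum(mc2@counts), 0)
  expect_equal(mc2@eligible_bases, 2)
  ## raising bq_min never increases eligible bases or channel counts
  mc_lo <- profileMismatches(base, ref, bq_min = 10)
  mc_hi <- profileMismatches(base, ref, bq_min = 35)
  expect_lte(mc_hi@eligible_bases, mc_lo@eligible_bases)
  expect_true(all(mc_hi@counts <= mc_lo@counts))
})

test_that("indel-adjacent and soft-clipped bases never enter the tally", {
  ref <- c(chr1 = "AAACCCGGGTTTAAACCC")
  rd <- data.frame(
    qname = "f1", read_index = "R1", chrom = "chr1", pos = 2L,
    seq = "AACCTCGGG", qual = strrep("?", 9), mapq = 60L,
    cigar = "4M1I4M", is_reverse = FALSE, is_duplicate = FALSE,
    is_supplementary = FALSE, is_qcfail = FALSE, is_unmapped = FALSE)
  mc <- profileMismatches(rd, ref)
  ## two M blocks of 4: inner positions only, i.e. 2 per block
  expect_equal(mc@eligible_bases, 4)
  expect_equal(sum(mc@counts), 0)
})

test_that("collapse to six types conserves counts and reverse-complements", {
  mc <- MismatchCounts(counts = c("A[G>T]T" = 3, "A[C>A]G" = 2,
                                  "T[A>C]T" = 5),
                       eligible_bases = 1000)
  collapsed <- collapseToSix(mc)
  ## revcomp of A[G>T]T is A[C>A]T; pyrimidine channels unchanged
  expect_equal(unname(collapsed["A[C>A]T"]), 3)
  expect_equal(unname(collapsed["A[C>A]G"]), 2)
  ## revcomp of T[A>C]T is A[T>G]A
  expect_equal(unname(collapsed["A[T>G]A"]), 5)
  expect_equal(sum(collapsed), sum(mc@counts))
})

test_that("profiler recovers a simulated error profile", {
  set.seed(1)
  ref_seq <- paste(sample(c("A", "C", "G", "T"), 20000, TRUE),
                   collapse = "")
  ref <- c(chr1 = ref_seq)
  ## zero error rate -> zero mismatches
  clean <- simulateReads(ref, depth = 2, errorProfile(rate = 0),
                         read_length = 100, seed = 2)
  expect_equal(sum(profileMismatches(clean$reads, ref)@counts), 0)
  ## only C>A channels populated when the profile allows nothing else
  w <- setNames(numeric(192), mismatchChannels())
  w[grep(">", names(w), fixed = TRUE)[grepl("\\[C>A\\]", names(w))]] <- 1
  ca_only <- simulateReads(ref, depth = 4, errorProfile(rate = 0.01,
                                                        weights = w),
                           read_length = 100, seed = 3)
  mc <- profileMismatches(ca_only$reads, ref)
  hit <- names(mc@counts)[mc@counts > 0]
  expect_gt(sum(mc@counts), 0)
  expect_true(all(grepl("\\[C>A\\]", hit)))
  ## overall rate recovered within 3 binomial SEs
  rate <- 0.002
  sim <- simulateReads(ref, depth = 10, errorProfile(rate = rate),
                       read_length = 100, seed = 4)
  mc2 <- profileMismatches(sim$reads, ref)
  se <- sqrt(rate * (1 - rate) / mc2@eligible_bases)
  expect_lt(abs(mismatchRate(mc2) - rate), 3 * se)
})

test_that("downsampling keeps whole fragments at the target fraction", {
  reads <- data.frame(
    qname = rep(sprintf("f%05d", 1:5000), each = 2),
    read_index = rep(c("R1", "R2"), 5000),
    chrom = "chr1", pos = 1L, seq = strrep("A", 100),
    qual = strrep("?", 100), mapq = 60L, cigar = NA_character_,
    is_reverse = FALSE, is_duplicate = FALSE, is_supplementary = FALSE,
    is_qcfail = FALSE, is_unmapped = FALSE)
  genome <- 125000  # current depth = 8X
  half <- downsampleReads(reads, target_depth = 4, genome_size = genome,
                          seed = 9)
  ## mates stay together
  expect_true(all(table(half$qname) == 2))
  ## retained fragment count within 3 SE of the binomial expectation
  n_kept <- length(unique(half$qname))
  expect_lt(abs(n_kept - 2500), 3 * sqrt(5000 * 0.5 * 0.5))
  ## reproducible, and target above current errors out
  again <- downsampleReads(reads, 4, genome, seed = 9)
  expect_identical(half, again)
  expect_error(downsampleReads(reads, 16, genome), "exceeds")
})

test_that("SAM text imports into the aligned-read table", {
  path <- withr::local_tempfile(fileext = ".sam")
  writeLines(c(
    "@HD\tVN:1.6\tSO:coordinate",
    "@SQ\tSN:chr1\tLN:11",
    paste("f1", 0, "chr1", 4, 60, "5M", "*", 0, 0, "CATTC", "?????",
          sep = "\t"),
    paste("f2", 1040, "chr1", 4, 60, "5M", "*", 0, 0, "CAGTC", "?????",
          sep = "\t")), path)
  reads <- readAlignments(path)
  expect_equal(nrow(reads), 2)
  expect_true(reads$is_duplicate[2])   # flag 1024
  expect_equal(reads$read_index, c("R1", "R1"))
  mc <- profileMismatches(reads, c(chr1 = "CCCCAGTCCCC"))
  expect_equal(sum(mc@counts), 1)      # duplicate excluded
  expect_equal(unname(mc@counts["A[G>T]T"]), 1)
})
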