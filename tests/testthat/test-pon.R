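test_that("small PON keeps sites seen in at least two individuals", {
  pon <- buildSmallPon(list(
    ind1 = mkVar(pos = 100L),
    ind2 = SmallVariants(chrom = c("chr1", "chr1"), pos = c(100L, 300L),
                         ref = c("A", "C"), alt = c("G", "T")),
    ind3 = mkVar(pos = 500L, ref = "C", alt = "T")))
  expect_equal(pon@sites$pos, 100L)
  expect_equal(pon@sites$n_individuals, 2L)
  ## two alt alleles at one site in one individual count once
  pon2 <- buildSmallPon(list(
    ind1 = SmallVariants(chrom = c("chr1", "chr1"), pos = c(100L, 100L),
                         ref = c("A", "A"), alt = c("G", "T"))))
  expect_equal(nrow(pon2@sites), 0L)
  expect_equal(nrow(buildSmallPon(list())@sites), 0L)
})

test_that("small PON build equals brute-force counting on random inputs", {
  set.seed(21)
  for (rep in 1:5) {
    inds <- lapply(1:6, function(i) {
      n <- sample(5:15, 1)
      SmallVariants(chrom = "chr1", pos = sample(1:20, n, TRUE) * 10L,
                    ref = "A", alt = "G")
    })
    names(inds) <- paste0("ind", 1:6)
    pon <- buildSmallPon(inds, min_individuals = 2)
    counts <- table(unlist(lapply(inds, function(x)
      unique(recordTable(x)$pos))))
    expect_setequal(pon@sites$pos, as.integer(names(counts)[counts >= 2]))
  }
})

test_that("small PON tags by location, not allele, and is idempotent", {
  pon <- buildSmallPon(list(i1 = mkVar(pos = 100L, alt = "G"),
                            i2 = mkVar(pos = 100L, alt = "G")))
  ## different alt allele at the PON site is still tagged
  x <- SmallVariants(chrom = c("chr1", "chr1"), pos = c(100L, 200L),
                     ref = c("A", "A"), alt = c("T", "G"),
                     callers = "mutect2")
  y <- applySmallPon(x, pon)
  expect_equal(filterTags(y)[[1]], "PON")
  expect_equal(filterTags(y)[[2]], character())
  expect_equal(recordTable(applySmallPon(y, pon)), recordTable(y))
  expect_equal(nRecords(y), nRecords(x))  # tag-only, nothing removed
})

test_that("SV PON clusters same-type same-strand events within max distance", {
  ## two DELs 200 bp apart at both ends from two individuals -> one event
  pon <- buildSvPon(list(
    i1 = mkSv(s1 = 10000L, s2 = 50000L),
    i2 = mkSv(s1 = 10200L, s2 = 50200L)))
  expect_equal(nrow(pon@events), 1L)
  expect_equal(pon@events$n_individuals, 2L)
  ## same coordinates, different type stay separate
  pon2 <- buildSvPon(list(
    i1 = mkSv(s1 = 10000L, s2 = 50000L, svtype = "DEL"),
    i2 = mkSv(s1 = 10000L, s2 = 50000L, svtype = "DUP",
              strand1 = "-", strand2 = "+")))
  expect_equal(nrow(pon2@events), 2L)
  expect_true(all(pon2@events$n_individuals == 1L))
  ## no minimum size: a 50 bp DEL is retained
  pon3 <- buildSvPon(list(i1 = mkSv(s1 = 100L, s2 = 150L)))
  expect_equal(nrow(pon3@events), 1L)
})

test_that("SV PON application requires the individual-count threshold", {
  pon_hi <- buildSvPon(list(i1 = mkSv(), i2 = mkSv(s1 = 10100L, s2 = 60100L),
                            i3 = mkSv(s1 = 10050L, s2 = 60050L)))
  pon_lo <- buildSvPon(list(i1 = mkSv()))
  x <- mkSv(callers = "manta")
  expect_equal(filterTags(applySvPon(x, pon_hi))[[1]], "PON")
  expect_equal(filterTags(applySvPon(x, pon_lo))[[1]], character())
  ## nothing on that chromosome
  y <- mkSv(chrom1 = "chr9", chrom2 = "chr9", callers = "manta")
  expect_equal(filterTags(applySvPon(y, pon_hi))[[1]], character())
  ## idempotent
  z <- applySvPon(x, pon_hi)
  expect_equal(recordTable(applySvPon(z, pon_hi)), recordTable(z))
})

test_that("common-germline filter fires at MAF >= 1% in any database", {
  x <- SmallVariants(
    chrom = rep("chr1", 3), pos = c(100L, 200L, 300L),
    ref = "A", alt = "G", callers = "mutect2",
    pop_af = list(c(gnomad = 0.02),
                  c(gnomad = 0.005, kg = 0.009),
                  c(kg = 0.01)))
  y <- germlineAfFilter(x)
  expect_equal(filterTags(y)[[1]], "COMMON_GERMLINE")
  expect_equal(filterTags(y)[[2]], character())
  expect_equal(filterTags(y)[[3]], "COMMON_GERMLINE")  # boundary inclusive
  ## SVs tag against a germline catalog under the match criteria
  sv <- mkSv(callers = "manta")
  cat_ <- mkSv(s1 = 10100L, s2 = 60100L)
  tagged <- germlineAfFilter(sv, catalog = cat_)
  expect_equal(filterTags(tagged)[[1]], "COMMON_GERMLINE")
  expect_equal(filterTags(germlineAfFilter(sv, catalog = NULL))[[1]],
               character())
})

test_that("PON and germline tags commute and never drop records", {
  x <- SmallVariants(chrom = rep("chr1", 4), pos = c(100L, 200L, 300L, 400L),
                     ref = "A", alt = "G", callers = "mutect2",
                     pop_af = list(c(gnomad = 0.05),
                                   setNames(numeric(), character()),
                                   c(gnomad = 0.05),
                                   setNames(numeric(), character())))
  pon <- buildSmallPon(list(i1 = mkVar(pos = 200L), i2 = mkVar(pos = 200L),
                            i3 = mkVar(pos = 300L), i4 = mkVar(pos = 300L)))
  ab <- germlineAfFilter(applySmallPon(x, pon))
  ba <- applySmallPon(germlineAfFilter(x), pon)
  expect_equal(recordTable(ab), recordTable(ba))
  expect_equal(nRecords(ab), 4L)
  expect_equal(isAllSomatic(ab), c(FALSE, FALSE, FALSE, TRUE))
})
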