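test_that("MNV decomposition emits one SNV per altered base", {
  ## AC>GT at 100 -> A>G@100, C>T@101 with a shared origin
  x <- mkVar(pos = 100L, ref = "AC", alt = "GT", callers = "mutect2")
  d <- decomposeMnvs(x)
  v <- recordTable(d$variants)
  expect_equal(v$pos, c(100L, 101L))
  expect_equal(v$ref, c("A", "C"))
  expect_equal(v$alt, c("G", "T"))
  expect_equal(length(unique(v$mnv_id)), 1L)
  expect_equal(nrow(d$origins), 1L)
  ## middle base unchanged is emitted nowhere: ACT>GCA -> A>G@50, T>A@52
  y <- mkVar(pos = 50L, ref = "ACT", alt = "GCA", callers = "lancet")
  dv <- recordTable(decomposeMnvs(y)$variants)
  expect_equal(dv$pos, c(50L, 52L))
  expect_equal(dv$ref, c("A", "T"))
  expect_equal(dv$alt, c("G", "A"))
  ## SNVs pass through untouched
  snv <- mkVar(pos = 5L, ref = "A", alt = "G", callers = "strelka2")
  d2 <- decomposeMnvs(snv)
  expect_equal(recordTable(d2$variants), recordTable(snv))
  expect_equal(nrow(d2$origins), 0L)
})

test_that("cross-caller merge unions support on the identity key", {
  a <- mkVar(pos = 100L, callers = "strelka2")
  b <- mkVar(pos = 100L, callers = "mutect2")
  c_ <- mkVar(pos = 900L, ref = "C", alt = "T", callers = "lancet")
  m <- mergeSmallCallsets(list(strelka2 = a, mutect2 = b, lancet = c_))
  expect_equal(nRecords(m), 2L)
  expect_equal(callerSupport(m)[[1]], c("strelka2", "mutect2"))
  expect_equal(callerSupport(m)[[2]], "lancet")
  ## empty input
  expect_equal(nRecords(mergeSmallCallsets(list())), 0L)
})

test_that("merge equals a brute-force key grouping on partial overlaps", {
  set.seed(42)
  for (rep in 1:5) {
    sets <- lapply(c(strelka2 = 1, mutect2 = 2, lancet = 3), function(s) {
      n <- sample(3:8, 1)
      pos <- sample(1:6, n, replace = TRUE) * 100L
      SmallVariants(chrom = "chr1", pos = pos, ref = "A", alt = "G",
                    callers = lapply(seq_len(n), function(i) character()))
    })
    m <- mergeSmallCallsets(sets)
    ## oracle: group the concatenated (caller, key) pairs by key
    pairs <- do.call(rbind, lapply(names(sets), function(cl) {
      v <- recordTable(sets[[cl]])
      if (!nrow(v)) return(NULL)
      data.frame(caller = cl, key = paste0("chr1:", v$pos, ":A:G"))
    }))
    oracle <- vapply(split(pairs$caller, pairs$key), function(x)
      paste(sort(unique(x)), collapse = ","), character(1))
    got <- setNames(vapply(callerSupport(m), function(cl)
      paste(sort(cl), collapse = ","), character(1)), recordKeys(m))
    expect_equal(got[order(names(got))],
                 oracle[order(names(oracle))])
  }
})

test_that("merge retains per-caller counts for later selection", {
  a <- mkVar(pos = 100L, callers = "strelka2", t_ref = 30, t_alt = 10,
             t_depth = 40, t_vaf = 0.25, t_source = "STRELKA2",
             n_ref = 20, n_alt = 0, n_depth = 20, n_vaf = 0,
             n_source = "STRELKA2")
  b <- mkVar(pos = 100L, callers = "mutect2", t_ref = 28, t_alt = 12,
             t_depth = 40, t_vaf = 0.3, t_source = "MUTECT2",
             n_ref = 22, n_alt = 0, n_depth = 22, n_vaf = 0,
             n_source = "MUTECT2")
  m <- mergeSmallCallsets(list(strelka2 = a, mutect2 = b))
  cc <- recordTable(m)$caller_counts[[1]]
  expect_setequal(cc$caller, c("strelka2", "mutect2"))
  expect_equal(cc$t_alt[cc$caller == "mutect2"], 12)
})

test_that("MNVs re-constitute only when constituent support is identical", {
  ## MuTect2 calls AC>GT; Strelka2 independently calls both SNVs
  mnv <- mkVar(pos = 100L, ref = "AC", alt = "GT", callers = "mutect2")
  d <- decomposeMnvs(mnv)
  s_snvs <- SmallVariants(chrom = "chr1", pos = c(100L, 101L),
                          ref = c("A", "C"), alt = c("G", "T"),
                          callers = "strelka2")
  m <- mergeSmallCallsets(list(mutect2 = d$variants, strelka2 = s_snvs))
  out <- reconstituteMnvs(m, d$origins)
  v <- recordTable(out)
  expect_equal(nrow(v), 1L)
  expect_equal(v$vtype, "MNV")
  expect_equal(v$ref, "AC")
  expect_equal(callerSupport(out)[[1]], c("strelka2", "mutect2"))
  ## unequal support -> two SNVs retained
  s_one <- mkVar(pos = 100L, ref = "A", alt = "G", callers = "strelka2")
  m2 <- mergeSmallCallsets(list(mutect2 = d$variants, strelka2 = s_one))
  out2 <- reconstituteMnvs(m2, d$origins)
  v2 <- recordTable(out2)
  expect_equal(nrow(v2), 2L)
  expect_true(all(v2$vtype == "SNV"))
  ## no origins -> identity
  expect_equal(recordTable(reconstituteMnvs(m2, NULL)), recordTable(m2))
})

test_that("decompose -> merge -> reconstitute is the identity for one caller", {
  set.seed(11)
  bases <- c("A", "C", "G", "T")
  for (rep in 1:10) {
    n <- sample(1:5, 1)
    len <- sample(2:4, n, replace = TRUE)
    pos <- cumsum(sample(10:100, n)) + 1L
    ref <- vapply(len, function(l)
      paste(sample(bases, l, TRUE), collapse = ""), character(1))
    alt <- vapply(strsplit(ref, ""), function(b)
      paste(vapply(b, function(x) sample(setdiff(bases, x), 1),
                   character(1)), collapse = ""), character(1))
    x <- SmallVariants(chrom = "chr1", pos = pos, ref = ref, alt = alt,
                       callers = "mutect2")
    d <- decomposeMnvs(x)
    m <- mergeSmallCallsets(list(mutect2 = d$variants))
    out <- reconstituteMnvs(m, d$origins)
    v <- recordTable(out)
    o <- recordTable(x)[order(pos), , drop = FALSE]
    expect_equal(v$pos, o$pos)
    expect_equal(v$ref, o$ref)
    expect_equal(v$alt, o$alt)
    expect_equal(v$callers, o$callers)
    ## altered-base count is conserved by decompose/reconstitute
    altered <- function(tab) sum(mapply(function(r, a)
      sum(strsplit(r, "")[[1]] != strsplit(a, "")[[1]]), tab$ref, tab$alt))
    expect_equal(altered(v), altered(recordTable(d$variants)))
  }
})

test_that("merge is idempotent and order-independent", {
  a <- randomSmallVariants(15, seed = 3)
  b <- randomSmallVariants(15, seed = 4)
  m1 <- mergeSmallCallsets(list(strelka2 = a, mutect2 = b))
  m2 <- mergeSmallCallsets(list(mutect2 = b, strelka2 = a))
  expect_equal(recordTable(m1)[, c("chrom", "pos", "ref", "alt")],
               recordTable(m2)[, c("chrom", "pos", "ref", "alt")])
  expect_equal(callerSupport(m1), callerSupport(m2))
  ## merging the merged set again adds nothing
  m3 <- mergeSmallCallsets(list(m1))
  expect_equal(recordKeys(m3), recordKeys(m1))
  expect_equal(callerSupport(m3), callerSupport(m1))
})
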