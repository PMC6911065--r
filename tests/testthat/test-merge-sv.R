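test_that("event span uses outer interval bounds; TRA/INS undefined", {
  del <- BreakendPairs("chr1", 999L, 1000L, "chr1", 4999L, 5000L,
                       svtype = "DEL")
  expect_equal(svSpan(del), 4001)
  tra <- mkSv(chrom2 = "chr5", svtype = "TRA", strand2 = "+")
  expect_true(is.na(svSpan(tra)))
  ins <- mkSv(s2 = 10001L, svtype = "INS")
  expect_true(is.na(svSpan(ins)))
  ## wide confidence intervals stretch the span
  inv <- BreakendPairs("chr1", 1000L, 1300L, "chr1", 9000L, 9300L,
                       strand1 = "+", strand2 = "+", svtype = "INV")
  expect_equal(svSpan(inv), 8300)
})

test_that("minimum-size filter removes spans strictly below the cutoff", {
  spans <- c(100L, 499L, 500L, 10000L)
  x <- BreakendPairs(chrom1 = rep("chr1", 4), start1 = 0L, end1 = 1L,
                     chrom2 = "chr1", start2 = spans - 1L, end2 = spans,
                     svtype = "DEL")
  kept <- filterMinSize(x)
  expect_equal(svSpan(kept), c(500, 10000))
  ## undefined spans are always retained
  tra <- mkSv(chrom2 = "chr2", svtype = "TRA")
  expect_equal(nRecords(filterMinSize(tra)), 1L)
  expect_equal(nRecords(filterMinSize(BreakendPairs())), 0L)
})

test_that("sv matching requires type, strands, slop overlap and reciprocal span", {
  a <- mkSv(s1 = 10000L, s2 = 20000L)
  expect_true(svMatch(a, a))                       # reflexive
  ## 10 kb DELs offset by 250 bp at both ends: slop 300 satisfied,
  ## reciprocal overlap 97.5%
  b <- mkSv(s1 = 10250L, s2 = 20250L)
  expect_true(svMatch(a, b))
  expect_true(svMatch(b, a))                       # symmetric
  ## strand mismatch at breakend 2
  c_ <- mkSv(s1 = 10000L, s2 = 20000L, strand2 = "+", svtype = "INV",
             strand1 = "+")
  expect_false(svMatch(a, c_))
  d <- mkSv(s1 = 10000L, s2 = 20000L, svtype = "DUP", strand1 = "-",
            strand2 = "+")
  expect_false(svMatch(a, d))                      # DUP never matches DEL
  ## slop satisfied but reciprocal violated: nested spans
  e <- mkSv(s1 = 10100L, s2 = 12000L)
  expect_false(svMatch(a, e))
  ## reciprocal waived for TRA
  t1 <- mkSv(chrom2 = "chr5", s2 = 500L, svtype = "TRA")
  t2 <- mkSv(chrom2 = "chr5", s1 = 10100L, s2 = 600L, svtype = "TRA")
  expect_true(svMatch(t1, t2))
})

test_that("merging collapses match-graph components with priority coordinates", {
  m <- mkSv(s1 = 10000L, s2 = 20000L, callers = "manta")
  l <- mkSv(s1 = 10120L, s2 = 20100L, callers = "lumpy")
  merged <- mergeSvCallsets(list(manta = m, lumpy = l))
  expect_equal(nRecords(merged), 1L)
  expect_equal(callerSupport(merged)[[1]], c("manta", "lumpy"))
  expect_equal(recordTable(merged)$start1, 10000L)  # manta's coordinates
  ## chain A~B, B~C with A not matching C still forms one component
  ## slop pads both events, so breakends up to 600 bp apart still overlap
  a <- mkSv(s1 = 10000L, s2 = 20000L, callers = "manta")
  b <- mkSv(s1 = 10590L, s2 = 20590L, callers = "lumpy")
  c_ <- mkSv(s1 = 11180L, s2 = 21180L, callers = "svaba")
  expect_true(svMatch(a, b) && svMatch(b, c_) && !svMatch(a, c_))
  chain <- mergeSvCallsets(list(manta = a, lumpy = b, svaba = c_))
  expect_equal(nRecords(chain), 1L)
  expect_equal(callerSupport(chain)[[1]], c("manta", "lumpy", "svaba"))
  ## disjoint events stay separate
  far <- mkSv(s1 = 500000L, s2 = 600000L, callers = "lumpy")
  two <- mergeSvCallsets(list(manta = a, lumpy = far))
  expect_equal(nRecords(two), 2L)
})

test_that("merge equals brute-force transitive closure on random sets", {
  for (seed in 1:4) {
    x <- randomBreakendPairs(60, seed = seed)
    p <- recordTable(x)
    per_caller <- lapply(c(manta = "manta", lumpy = "lumpy",
                           svaba = "svaba"), function(cl) {
      idx <- vapply(p$callers, function(s) cl %in% s, logical(1))
      new("BreakendPairSet", pairs = p[idx, , drop = FALSE])
    })
    merged <- mergeSvCallsets(per_caller)
    ## oracle: iterative label propagation over the svMatch relation
    n <- nrow(p)
    lab <- seq_len(n)
    repeat {
      changed <- FALSE
      for (i in seq_len(n - 1)) for (j in (i + 1):n) {
        if (svMatch(new("BreakendPairSet", pairs = p[i, , drop = FALSE]),
                    new("BreakendPairSet", pairs = p[j, , drop = FALSE]))) {
          m <- min(lab[i], lab[j])
          if (lab[i] != m || lab[j] != m) {
            lab[lab == lab[i] | lab == lab[j]] <- m
            changed <- TRUE
          }
        }
      }
      if (!changed) break
    }
    expect_equal(nRecords(merged), length(unique(lab)))
    ## support multisets agree
    oracle_support <- sort(vapply(split(seq_len(n), lab), function(idx)
      paste(sort(unique(unlist(p$callers[idx]))), collapse = ","),
      character(1)))
    got_support <- sort(vapply(callerSupport(merged), function(cl)
      paste(sort(cl), collapse = ","), character(1)))
    expect_equal(got_support, unname(oracle_support))
  }
})

test_that("merging the merged set again creates nothing new", {
  x <- randomBreakendPairs(40, seed = 9)
  m1 <- mergeSvCallsets(list(pool = x))
  m2 <- mergeSvCallsets(list(pool = m1))
  expect_equal(nRecords(m2), nRecords(m1))
  expect_equal(lapply(callerSupport(m2), sort),
               lapply(callerSupport(m1), sort))
})
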