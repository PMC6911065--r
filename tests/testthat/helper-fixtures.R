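## Shared fixture builders. Everything is generated in code; no binary
## fixtures.

## shorthand single-variant constructor
mkVar <- function(chrom = "chr1", pos = 100L, ref = "A", alt = "G", ...) {
  SmallVariants(chrom = chrom, pos = pos, ref = ref, alt = alt, ...)
}

## random small-variant set exercising every field, for round-trip tests
randomSmallVariants <- function(n, seed = 1) {
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), character(1))
  ## sprinkle in indels and MNVs
  idx <- sample(n, max(1, n %/% 4))
  for (i in idx) {
    if (runif(1) < 0.5) {
      ref[i] <- paste0(ref[i], paste(sample(bases, 3, TRUE), collapse = ""))
    } else {
      ref[i] <- paste(sample(bases, 2, TRUE), collapse = "")
      alt[i] <- paste(vapply(strsplit(ref[i], "")[[1]], function(b)
        sample(setdiff(bases, b), 1), character(1)), collapse = "")
    }
  }
  tr <- rpois(n, 30); ta <- rpois(n, 10)
  nr <- rpois(n, 30); na_ <- rep(0, n)
  SmallVariants(
    chrom = sample(c("chr1", "chr2"), n, TRUE),
    pos = sample.int(1e6, n), ref = ref, alt = alt,
    callers = lapply(seq_len(n), function(i)
      sort(sample(c("strelka2", "mutect2", "lancet"), sample(1:3, 1)))),
    filters = lapply(seq_len(n), function(i)
      if (runif(1) < 0.3) "PON" else character()),
    hc = runif(n) < 0.5,
    t_ref = tr, t_alt = ta, t_depth = tr + ta + rpois(n, 2),
    t_vaf = ta / (tr + ta), t_source = "PILEUP",
    n_ref = nr, n_alt = na_, n_depth = nr + rpois(n, 2),
    n_vaf = na_ / (nr + na_), n_source = "PILEUP",
    pop_af = lapply(seq_len(n), function(i)
      if (runif(1) < 0.4) c(gnomad = round(runif(1), 4)) else
        setNames(numeric(), character())))
}

## random breakend-pair set
randomBreakendPairs <- function(n, seed = 1, contig_len = 1e6,
                                span_range = c(600, 5e4)) {
  set.seed(seed)
  svtype <- sample(c("DEL", "DUP", "INV", "TRA"), n, TRUE,
                   prob = c(0.4, 0.25, 0.25, 0.1))
  chrom1 <- sample(c("chr1", "chr2"), n, TRUE)
  chrom2 <- ifelse(svtype == "TRA",
                   ifelse(chrom1 == "chr1", "chr2", "chr1"), chrom1)
  span <- round(runif(n, span_range[1], span_range[2]))
  s1 <- sample.int(contig_len - max(span) - 10L, n)
  s2 <- ifelse(svtype == "TRA", sample.int(contig_len, n), s1 + span)
  strands <- rbind(DEL = c("+", "-"), DUP = c("-", "+"),
                   INV = c("+", "+"), TRA = c("+", "-"))
  BreakendPairs(
    chrom1 = chrom1, start1 = s1, end1 = s1 + sample(1:50, n, TRUE),
    chrom2 = chrom2, start2 = s2, end2 = s2 + sample(1:50, n, TRUE),
    strand1 = strands[svtype, 1], strand2 = strands[svtype, 2],
    svtype = svtype, name = sprintf("rsv%03d", seq_len(n)),
    callers = lapply(seq_len(n), function(i)
      sample(c("manta", "lumpy", "svaba"), 1)),
    split_t = rpois(n, 4), split_n = 0)
}

## a single DEL breakend pair
mkSv <- function(chrom1 = "chr1", s1 = 10000L, chrom2 = chrom1,
                 s2 = 60000L, svtype = "DEL", strand1 = "+", strand2 = "-",
                 callers = "manta", width = 1L, ...) {
  BreakendPairs(chrom1 = chrom1, start1 = s1, end1 = s1 + width,
                chrom2 = chrom2, start2 = s2, end2 = s2 + width,
                strand1 = strand1, strand2 = strand2, svtype = svtype,
                callers = list(callers), ...)
}

## read evidence rows
mkEvidence <- function(n_alt, n_ref, n_other = 0, mq = 60, bq = 30,
                       dup = FALSE, prefix = "f") {
  n <- n_alt + n_ref + n_other
  data.frame(
    fragment_id = paste0(prefix, seq_len(n)),
    allele = c(rep("ALT", n_alt), rep("REF", n_ref), rep("OTHER", n_other)),
    mq = rep_len(mq, n), bq = rep_len(bq, n),
    is_duplicate = rep_len(dup, n), is_supplementary = FALSE,
    is_qcfail = FALSE, is_unmapped = FALSE, stringsAsFactors = FALSE)
}

## write a minimal two-sample VCF for reader tests
writeTestVcf <- function(path, body_lines,
                         samples = c("TUMOR", "NORMAL")) {
  hdr <- c("##fileformat=VCFv4.2",
           "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"depth\">",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"gt\">",
           "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"depths\">",
           "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"depth\">",
           paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
                  if (length(samples))
                    paste0("\tFORMAT\t", paste(samples, collapse = "\t"))
                  else ""))
  writeLines(c(hdr, body_lines), path)
  path
}

## decomposed truth keys (MNVs as constituent SNVs), for recall vs truth
truthKeys <- function(truth) {
  v <- truth@variants
  if (!nrow(v)) return(character())
  unlist(lapply(seq_len(nrow(v)), function(i) {
    if (v$vtype[i] == "MNV") {
      rb <- strsplit(v$ref[i], "")[[1]]
      ab <- strsplit(v$alt[i], "")[[1]]
      k <- which(rb != ab)
      paste(v$chrom[i], v$pos[i] + k - 1L, rb[k], ab[k], sep = ":")
    } else paste(v$chrom[i], v$pos[i], v$ref[i], v$alt[i], sep = ":")
  }))
}

## run simulator + pipeline once, return recalls vs truth
simulatedRun <- function(t_frac, seed, tumor_depth = 80, normal_depth = 40,
                         truth_params = list()) {
  tr <- simulateTruth(truth_params, seed = seed)
  ev <- simulateSampleCounts(tr, tumor_depth, normal_depth, t_frac = t_frac,
                             seed = seed + 1L)
  co <- simulateCallerOutputs(tr, ev, seed = seed + 2L)
  res <- runPipeline(small_callsets = co$small, sv_callsets = co$sv,
                     segments = tr@segments, tumor_evidence = ev$tumor,
                     normal_evidence = ev$normal, evidence = co$evidence)
  list(truth = tr, callers = co, result = res)
}
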