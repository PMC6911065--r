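## Synthetic-data generation: somatic truth sets, per-sample read evidence
## under tumor/normal mixing, mock caller outputs with tunable sensitivity
## and context bias, and error-profiled reads for the mismatch profiler.
## All generators are pure functions of (params, seed).

#' TruthSet: simulated somatic ground truth
#'
#' @slot variants data.frame of somatic small variants: chrom, pos, ref,
#'   alt, vtype, clone (clone fraction), c_alt (mutant copies), c_tot
#'   (total tumor copies at the locus), n_cn (normal copy number), m
#'   (effective mutant dosage clone * c_alt) and vaf (pure-tumor VAF m/c_tot)
#' @slot svs a [BreakendPairSet-class] of true SVs
#' @slot segments a [CNVSegmentSet-class] with integer tumor copy numbers,
#'   tiling each contig without overlap
#' @slot t_ploidy average tumor ploidy implied by the segments
#' @slot contigs named numeric of contig lengths
#' @export
setClass("TruthSet",
         representation(variants = "data.frame", svs = "BreakendPairSet",
                        segments = "CNVSegmentSet", t_ploidy = "numeric",
                        contigs = "numeric"))

setValidity("TruthSet", function(object) {
  v <- object@variants
  if (nrow(v) && (any(v$vaf <= 0) || any(v$vaf > 1)))
    return("truth VAFs must lie in (0,1]")
  s <- object@segments@segments
  if (nrow(s)) {
    if (any(s$t_cn < 0, na.rm = TRUE))
      return("segment copy numbers must be >= 0")
    for (ch in unique(s$chrom)) {
      d <- s[s$chrom == ch, , drop = FALSE]
      d <- d[order(d$start), , drop = FALSE]
      if (nrow(d) > 1L && any(d$start[-1L] < d$end[-nrow(d)]))
        return("segments must tile contigs without overlap")
    }
  }
  TRUE
})

#' Default simulation parameters
#'
#' The defaults emulate a compact tumor-normal pair of a heavily
#' copy-number-altered, near-tetraploid tumor: two 1-Mb contigs tiled by
#' segments with integer copy numbers centred on 4, a clonal mutation load
#' dominated by SNVs with a minority of MNVs and indels, and SVs above the
#' pipeline's minimum size. See the package vignette for the reasoning
#' behind each value.
#' @return named list of parameters accepted by [simulateTruth()]
#' @export
defaultTruthParams <- function() {
  list(
    contigs = c(chr1 = 1e6, chr2 = 1e6),
    n_snv = 100L, n_mnv = 6L, n_indel = 24L, n_sv = 10L,
    segments_per_contig = 5L,
    cn_states = c(0L, 1L, 2L, 3L, 4L, 6L),
    cn_weights = c(0.05, 0.1, 0.15, 0.2, 0.4, 0.1),
    clone_fractions = c(1, 0.4), clone_weights = c(0.8, 0.2),
    vaf_mean = NULL, vaf_conc = 10,
    indel_len_range = c(1L, 15L), mnv_len_range = c(2L, 3L),
    sv_span_range = c(1e3, 2e5))
}

.randSeq <- function(n, len) {
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = ""),
    character(1))
}

## alt allele differing from ref at every position
.mutate <- function(ref) {
  vapply(strsplit(ref, ""), function(b)
    paste(vapply(b, function(x)
      sample(setdiff(c("A", "C", "G", "T"), x), 1L), character(1)),
      collapse = ""), character(1))
}

#' Simulate a somatic truth set
#'
#' Generates CNV segments tiling each contig with integer tumor copy
#' numbers, then somatic SNVs/MNVs/indels whose pure-tumor VAFs reflect
#' clone fraction and local copy state (VAF = clone * c_alt / c_tot), and
#' SVs with spans above the pipeline minimum. When `vaf_mean` is set, VAFs
#' are instead drawn from a Beta distribution with that mean (concentration
#' `vaf_conc`). Reproducible for a fixed seed.
#'
#' @param params parameter list, see [defaultTruthParams()]; entries given
#'   override the defaults
#' @param seed RNG seed
#' @return a [TruthSet-class]
#' @export
simulateTruth <- function(params = list(), seed = 1) {
  p <- utils::modifyList(defaultTruthParams(), params)
  if (any(p$contigs <= 0)) stop("contig lengths must be positive")
  set.seed(seed)
  ## CNV segments tiling each contig
  seg_rows <- list()
  for (ch in names(p$contigs)) {
    len <- p$contigs[[ch]]
    k <- p$segments_per_contig
    cuts <- sort(sample.int(len - 1L, k - 1L))
    bounds <- c(0L, cuts, as.integer(len))
    cn <- sample(p$cn_states, k, replace = TRUE, prob = p$cn_weights)
    seg_rows[[ch]] <- data.frame(chrom = ch, start = bounds[-(k + 1L)],
                                 end = bounds[-1L], t_cn = cn,
                                 stringsAsFactors = FALSE)
  }
  segs <- do.call(rbind, seg_rows)
  t_ploidy <- sum((segs$end - segs$start) * segs$t_cn) / sum(p$contigs)
  purity1_log2 <- log2(pmax(segs$t_cn, 0.01) / t_ploidy)  # pure-tumor ratio
  segments <- CNVSegments(chrom = segs$chrom, start = segs$start,
                          end = segs$end, obs_log2 = purity1_log2,
                          t_cn = segs$t_cn)
  ## small variants
  n_small <- p$n_snv + p$n_mnv + p$n_indel
  variants <- NULL
  if (n_small > 0L) {
    vtype <- c(rep("SNV", p$n_snv), rep("MNV", p$n_mnv),
               rep("INDEL", p$n_indel))
    chrom <- sample(names(p$contigs), n_small, replace = TRUE)
    pos <- vapply(chrom, function(ch)
      sample.int(p$contigs[[ch]] - 50L, 1L), integer(1))
    ref <- character(n_small); alt <- character(n_small)
    is_snv <- vtype == "SNV"
    ref[is_snv] <- .randSeq(sum(is_snv), 1L)
    alt[is_snv] <- .mutate(ref[is_snv])
    is_mnv <- vtype == "MNV"
    if (any(is_mnv)) {
      mlen <- sample(seq(p$mnv_len_range[1], p$mnv_len_range[2]),
                     sum(is_mnv), replace = TRUE)
      ref[is_mnv] <- vapply(mlen, function(l) .randSeq(1L, l), character(1))
      alt[is_mnv] <- .mutate(ref[is_mnv])
    }
    is_ind <- vtype == "INDEL"
    if (any(is_ind)) {
      ilen <- sample(seq(p$indel_len_range[1], p$indel_len_range[2]),
                     sum(is_ind), replace = TRUE)
      ins <- runif(sum(is_ind)) < 0.5
      anchor <- .randSeq(sum(is_ind), 1L)
      extra <- vapply(ilen, function(l) .randSeq(1L, l), character(1))
      ref[is_ind] <- ifelse(ins, anchor, paste0(anchor, extra))
      alt[is_ind] <- ifelse(ins, paste0(anchor, extra), anchor)
    }
    ## copy state from the overlying segment
    seg_cn <- mapply(function(ch, x) {
      d <- segs[segs$chrom == ch, , drop = FALSE]
      d$t_cn[x > d$start & x <= d$end][1L]
    }, chrom, pos)
    c_tot <- pmax(as.integer(seg_cn), 1L)
    if (!is.null(p$vaf_mean)) {
      a <- p$vaf_mean * p$vaf_conc
      b <- (1 - p$vaf_mean) * p$vaf_conc
      vaf <- pmin(pmax(stats::rbeta(n_small, a, b), 1e-4), 1)
      clone <- rep(NA_real_, n_small)
      c_alt <- rep(NA_real_, n_small)
      m <- vaf * c_tot
    } else {
      clone <- sample(p$clone_fractions, n_small, replace = TRUE,
                      prob = p$clone_weights)
      c_alt <- vapply(c_tot, function(ct) sample.int(max(1L, ct %/% 2L +
                                                           (ct == 1L)), 1L),
                      integer(1))
      m <- clone * c_alt
      vaf <- m / c_tot
    }
    variants <- data.frame(chrom = chrom, pos = as.integer(pos), ref = ref,
                           alt = alt, vtype = vtype, clone = clone,
                           c_alt = c_alt, c_tot = c_tot, n_cn = 2,
                           m = m, vaf = vaf, stringsAsFactors = FALSE)
    variants <- variants[!duplicated(variantKey(
      variants$chrom, variants$pos, variants$ref, variants$alt)), ,
      drop = FALSE]
    rownames(variants) <- NULL
  } else {
    variants <- data.frame(chrom = character(), pos = integer(),
                           ref = character(), alt = character(),
                           vtype = character(), clone = numeric(),
                           c_alt = numeric(), c_tot = numeric(),
                           n_cn = numeric(), m = numeric(), vaf = numeric(),
                           stringsAsFactors = FALSE)
  }
  ## SVs: intrachromosomal DEL/DUP/INV plus occasional TRA
  svs <- BreakendPairs()
  if (p$n_sv > 0L) {
    svtype <- sample(c("DEL", "DUP", "INV", "TRA"), p$n_sv, replace = TRUE,
                     prob = c(0.4, 0.25, 0.25, 0.1))
    chrom1 <- sample(names(p$contigs), p$n_sv, replace = TRUE)
    span <- round(runif(p$n_sv, p$sv_span_range[1], p$sv_span_range[2]))
    s1 <- vapply(seq_len(p$n_sv), function(i)
      sample.int(max(1L, as.integer(p$contigs[[chrom1[i]]] - span[i] - 10L)),
                 1L), integer(1))
    chrom2 <- chrom1
    s2 <- s1 + span
    tra <- svtype == "TRA"
    if (any(tra)) {
      chrom2[tra] <- vapply(chrom1[tra], function(ch)
        sample(names(p$contigs), 1L), character(1))
      s2[tra] <- vapply(chrom2[tra], function(ch)
        sample.int(as.integer(p$contigs[[ch]] - 10L), 1L), integer(1))
    }
    strands <- list(DEL = c("+", "-"), DUP = c("-", "+"),
                    INV = c("+", "+"), TRA = c("+", "-"),
                    INS = c("+", "-"))
    svs <- BreakendPairs(
      chrom1 = chrom1, start1 = s1, end1 = s1 + 1L,
      chrom2 = chrom2, start2 = s2, end2 = s2 + 1L,
      strand1 = vapply(svtype, function(t) strands[[t]][1], character(1)),
      strand2 = vapply(svtype, function(t) strands[[t]][2], character(1)),
      svtype = svtype, name = sprintf("truth_sv%03d", seq_len(p$n_sv)))
  }
  new("TruthSet", variants = variants, svs = svs, segments = segments,
      t_ploidy = t_ploidy, contigs = p$contigs)
}

#' Mixture VAF of a somatic variant at a given tumor read fraction
#'
#' Copy-number-weighted allele dosage: with `m` mutant copies (clone
#' fraction times mutant copy number) out of `c_tot` tumor copies and
#' `n_cn` normal copies, a read fraction `t_frac` from the tumor library
#' gives expected VAF
#' \deqn{v_{mix} = \frac{T_{frac} m}{T_{frac} c_{tot} + (1-T_{frac}) N_{CN}}}
#' @param t_frac tumor read fraction
#' @param m effective mutant copies
#' @param c_tot total tumor copies at the locus
#' @param n_cn normal copy number (default 2)
#' @return expected mixture VAF
#' @export
mixtureVaf <- function(t_frac, m, c_tot, n_cn = 2) {
  t_frac * m / (t_frac * c_tot + (1 - t_frac) * n_cn)
}

#' Default read-evidence noise parameters
#' @return named list: probabilities of exclusion flags and low-quality
#'   reads, quality values, and the normal-sample background alt rate
#' @export
defaultEvidenceParams <- function() {
  list(p_dup = 0.02, p_lowmq = 0.03, p_lowbq = 0.03, p_other = 0.005,
       mq_hi = 60, mq_lo = 5, bq_hi = 30, bq_lo = 8,
       normal_alt_rate = 0.001)
}

.evidenceFor <- function(n_ref, n_alt, n_other, p, prefix) {
  n <- n_ref + n_alt + n_other
  if (n == 0L)
    return(data.frame(fragment_id = character(), allele = character(),
                      mq = numeric(), bq = numeric(),
                      is_duplicate = logical(), is_supplementary = logical(),
                      is_qcfail = logical(), is_unmapped = logical(),
                      stringsAsFactors = FALSE))
  allele <- c(rep("ALT", n_alt), rep("REF", n_ref), rep("OTHER", n_other))
  data.frame(
    fragment_id = paste0(prefix, seq_len(n)),
    allele = allele,
    mq = ifelse(runif(n) < p$p_lowmq, p$mq_lo, p$mq_hi),
    bq = ifelse(runif(n) < p$p_lowbq, p$bq_lo, p$bq_hi),
    is_duplicate = runif(n) < p$p_dup,
    is_supplementary = FALSE, is_qcfail = FALSE, is_unmapped = FALSE,
    stringsAsFactors = FALSE)
}

#' Simulate per-variant read evidence for a tumor/normal mixture
#'
#' For every truth variant, draws tumor-sample fragment counts
#' alt ~ Binomial(depth_draw, v_mix) with the copy-number-weighted mixture
#' VAF of [mixtureVaf()], and normal-sample counts under a germline-only
#' background model (somatic loci have only sequencing-error alt reads in
#' the normal). Fragment flags and qualities are drawn from the evidence
#' noise parameters. Mixing is simulated at the fragment-count level, which
#' preserves the statistical structure of read mixing at desk scale.
#'
#' @param truth a [TruthSet-class]
#' @param tumor_depth,normal_depth mean sequencing depths of the mixed
#'   "tumor" sample and of the normal sample
#' @param t_frac fraction of the mixed sample's reads drawn from the tumor
#'   library
#' @param seed RNG seed
#' @param noise evidence noise parameters ([defaultEvidenceParams()])
#' @return list with `tumor` and `normal`: named lists (variant key ->
#'   evidence data.frame)
#' @export
simulateSampleCounts <- function(truth, tumor_depth, normal_depth, t_frac,
                                 seed = 1, noise = list()) {
  stopifnot(is(truth, "TruthSet"), tumor_depth > 0, normal_depth > 0,
            t_frac >= 0, t_frac <= 1)
  p <- utils::modifyList(defaultEvidenceParams(), noise)
  set.seed(seed)
  v <- truth@variants
  tumor <- list(); normal <- list()
  if (!nrow(v)) return(list(tumor = tumor, normal = normal))
  keys <- variantKey(v$chrom, v$pos, v$ref, v$alt)
  vmix <- mixtureVaf(t_frac, v$m, v$c_tot, v$n_cn)
  for (i in seq_len(nrow(v))) {
    dt <- stats::rpois(1L, tumor_depth)
    at <- stats::rbinom(1L, dt, min(1, vmix[i]))
    ot <- stats::rbinom(1L, dt - at, p$p_other)
    tumor[[keys[i]]] <- .evidenceFor(dt - at - ot, at, ot, p,
                                     paste0("t", i, "_"))
    dn <- stats::rpois(1L, normal_depth)
    an <- stats::rbinom(1L, dn, p$normal_alt_rate)
    normal[[keys[i]]] <- .evidenceFor(dn - an, an, 0L, p,
                                      paste0("n", i, "_"))
  }
  list(tumor = tumor, normal = normal)
}

#' Default mock-caller profiles
#'
#' Four small-variant callers and three SV callers with distinct
#' sensitivity curves and false-positive rates; the context-bias knob
#' (for platform-specific artifact spectra) is left uniform by default.
#' @return named list of [CallerProfile-class] objects
#' @export
defaultCallerProfiles <- function() {
  list(
    strelka2 = CallerProfile("strelka2", p_max = 0.98, k = 3, h = 2,
                             fp_per_mb = 0.4),
    mutect2 = CallerProfile("mutect2", p_max = 0.99, k = 2.5, h = 2,
                            fp_per_mb = 1.2),
    lancet = CallerProfile("lancet", p_max = 0.95, k = 3.5, h = 2,
                           fp_per_mb = 0.3),
    svaba = CallerProfile("svaba", p_max = 0.85, k = 4, h = 2,
                          fp_per_mb = 0.6),
    manta = CallerProfile("manta", p_max = 0.95, k = 3, h = 2,
                          fp_per_mb = 0.2),
    lumpy = CallerProfile("lumpy", p_max = 0.9, k = 3.5, h = 2,
                          fp_per_mb = 0.3))
}

## passing alt/ref fragment counts from an evidence table (the quantity a
## caller "sees")
.passingCounts <- function(ev, mq_min = 10, bq_min = 10) {
  pc <- pileupCounts(ev, mq_min, bq_min)
  c(ref = pc$ref_count, alt = pc$alt_count, depth = pc$depth)
}

.noisyCount <- function(x, sd) {
  pmax(0, round(x + stats::rnorm(length(x), 0, sd)))
}

#' Simulate mock caller outputs from read evidence
#'
#' Each small-variant caller detects each truth variant independently with
#' probability given by its sensitivity curve evaluated at the tumor alt
#' fragment count; false positives are placed uniformly at the caller's
#' per-Mb rate with substitution types drawn from its context-bias weights;
#' reported counts are the evidence counts plus reporting noise. MuTect2
#' and Lancet report MNVs as MNVs, Strelka2 reports the constituent SNVs
#' (it does not phase), and SvABA calls indels only. SV callers detect
#' truth SVs with their sensitivity at the simulated split-read count and
#' jitter breakend coordinates. Orthogonal-evidence sets (targeted
#' validation calls, Manta-derived small calls, split-read support, CNV
#' changepoints) are fabricated alongside.
#'
#' @param truth a [TruthSet-class]
#' @param evidence output of [simulateSampleCounts()]
#' @param profiles named list of [CallerProfile-class]
#'   ([defaultCallerProfiles()])
#' @param seed RNG seed
#' @param sv_jitter_sd sd (bp) of breakend coordinate jitter across callers
#' @param validation_sens detection probability of the targeted validation
#'   re-run and of the Manta small-SV evidence
#' @return list: `small` (caller -> [SmallVariantSet-class]), `sv` (caller
#'   -> [BreakendPairSet-class]), `evidence` (a [supportEvidence()] bundle)
#' @export
simulateCallerOutputs <- function(truth, evidence,
                                  profiles = defaultCallerProfiles(),
                                  seed = 1, sv_jitter_sd = 20,
                                  validation_sens = 0.8) {
  stopifnot(is(truth, "TruthSet"))
  set.seed(seed)
  v <- truth@variants
  keys <- if (nrow(v)) variantKey(v$chrom, v$pos, v$ref, v$alt)
          else character()
  counts_t <- lapply(keys, function(k)
    .passingCounts(evidence$tumor[[k]]))
  counts_n <- lapply(keys, function(k)
    .passingCounts(evidence$normal[[k]]))
  genome_mb <- sum(truth@contigs) / 1e6
  small_callers <- intersect(names(profiles), SMALL_CALLERS)
  small <- list()
  for (cl in small_callers) {
    pr <- profiles[[cl]]
    rows <- list()
    for (i in seq_len(nrow(v))) {
      eligible <- switch(cl,
        svaba = v$vtype[i] == "INDEL",
        TRUE)
      if (!eligible) next
      alt <- counts_t[[i]][["alt"]]
      if (runif(1) >= profileSensitivity(pr, alt)) next
      tr <- .noisyCount(counts_t[[i]][["ref"]], pr@count_noise_sd)
      ta <- max(1, .noisyCount(alt, pr@count_noise_sd))
      nr <- .noisyCount(counts_n[[i]][["ref"]], pr@count_noise_sd)
      na_ <- .noisyCount(counts_n[[i]][["alt"]], pr@count_noise_sd)
      emit_snvs <- v$vtype[i] == "MNV" && cl == "strelka2"
      if (emit_snvs) {
        cons <- .mnvConstituents(v$chrom[i], v$pos[i], v$ref[i], v$alt[i])
        rows[[length(rows) + 1L]] <- data.frame(
          chrom = cons$chrom, pos = cons$pos, ref = cons$ref,
          alt = cons$alt, t_ref = tr, t_alt = ta, t_depth = tr + ta,
          n_ref = nr, n_alt = na_, n_depth = nr + na_,
          stringsAsFactors = FALSE)
      } else {
        rows[[length(rows) + 1L]] <- data.frame(
          chrom = v$chrom[i], pos = v$pos[i], ref = v$ref[i],
          alt = v$alt[i], t_ref = tr, t_alt = ta, t_depth = tr + ta,
          n_ref = nr, n_alt = na_, n_depth = nr + na_,
          stringsAsFactors = FALSE)
      }
    }
    ## false positives, uniform positions, type from context bias
    n_fp <- stats::rpois(1L, pr@fp_per_mb * genome_mb)
    if (n_fp > 0L) {
      chan <- sample(collapsedChannels(), n_fp, replace = TRUE,
                     prob = pr@context_bias)
      fp_ref <- substr(chan, 3, 3)
      fp_alt <- substr(chan, 5, 5)
      fp_chrom <- sample(names(truth@contigs), n_fp, replace = TRUE)
      fp_pos <- vapply(fp_chrom, function(ch)
        sample.int(as.integer(truth@contigs[[ch]]), 1L), integer(1))
      fp_alt_n <- 1L + stats::rpois(n_fp, 2)
      fp_ref_n <- stats::rpois(n_fp, 40)
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = fp_chrom, pos = fp_pos, ref = fp_ref, alt = fp_alt,
        t_ref = fp_ref_n, t_alt = fp_alt_n,
        t_depth = fp_ref_n + fp_alt_n,
        n_ref = stats::rpois(n_fp, 40), n_alt = 0L,
        n_depth = NA_real_, stringsAsFactors = FALSE)
    }
    if (!length(rows)) {
      small[[cl]] <- SmallVariants()
      next
    }
    d <- do.call(rbind, rows)
    d$n_depth <- ifelse(is.na(d$n_depth), d$n_ref + d$n_alt, d$n_depth)
    d <- d[!duplicated(variantKey(d$chrom, d$pos, d$ref, d$alt)), ,
           drop = FALSE]
    ## SvABA reports no reference allele count, so no VAF can be formed
    if (cl == "svaba") {
      d$t_ref <- NA_real_
      d$n_ref <- NA_real_
    }
    src <- if (toupper(cl) %in% COUNT_SOURCES) toupper(cl) else NA_character_
    small[[cl]] <- SmallVariants(
      chrom = d$chrom, pos = d$pos, ref = d$ref, alt = d$alt,
      callers = cl,
      t_ref = d$t_ref, t_alt = d$t_alt, t_depth = d$t_depth,
      t_vaf = vafFrom(d$t_ref, d$t_alt), t_source = src,
      n_ref = d$n_ref, n_alt = d$n_alt, n_depth = d$n_depth,
      n_vaf = vafFrom(d$n_ref, d$n_alt), n_source = src)
  }
  ## SV callers
  sv_callers <- intersect(names(profiles), SV_CALLERS)
  tsv <- truth@svs@pairs
  split_true <- if (nrow(tsv)) 3L + stats::rpois(nrow(tsv), 5) else integer()
  sv <- list()
  for (cl in sv_callers) {
    pr <- profiles[[cl]]
    detected <- if (nrow(tsv))
      runif(nrow(tsv)) < profileSensitivity(pr, split_true) else logical()
    d <- tsv[detected, , drop = FALSE]
    if (nrow(d)) {
      jit <- function(x) pmax(0L, as.integer(round(
        x + stats::rnorm(length(x), 0, sv_jitter_sd))))
      d$start1 <- jit(d$start1); d$end1 <- d$start1 + 1L
      d$start2 <- jit(d$start2); d$end2 <- d$start2 + 1L
      swap <- d$chrom1 == d$chrom2 & d$start1 > d$start2
      if (any(swap)) {
        tmp <- d[swap, c("start1", "end1")]
        d[swap, c("start1", "end1")] <- d[swap, c("start2", "end2")]
        d[swap, c("start2", "end2")] <- tmp
      }
      d$split_t <- split_true[detected]
      d$split_n <- 0
    }
    n_fp <- stats::rpois(1L, pr@fp_per_mb * genome_mb)
    if (n_fp > 0L) {
      fp_chrom <- sample(names(truth@contigs), n_fp, replace = TRUE)
      fp_s1 <- vapply(fp_chrom, function(ch)
        sample.int(as.integer(truth@contigs[[ch]] - 5e4), 1L), integer(1))
      fp_span <- round(runif(n_fp, 600, 4e4))
      fp <- BreakendPairs(
        chrom1 = fp_chrom, start1 = fp_s1, end1 = fp_s1 + 1L,
        chrom2 = fp_chrom, start2 = fp_s1 + fp_span,
        end2 = fp_s1 + fp_span + 1L,
        strand1 = "+", strand2 = "-", svtype = "DEL",
        split_t = stats::rpois(n_fp, 1), split_n = stats::rpois(n_fp, 1))
      d <- rbind(d, fp@pairs)
    }
    if (nrow(d)) {
      d$callers <- rep(list(cl), nrow(d))
      d$filters <- rep(list(character()), nrow(d))
      d$hc <- FALSE
      d$name <- sprintf("%s_sv%03d", cl, seq_len(nrow(d)))
    }
    sv[[cl]] <- new("BreakendPairSet", pairs = d)
  }
  ## orthogonal evidence: validation re-run and Manta-derived small calls
  val <- keys[runif(length(keys)) < validation_sens]
  manta_small <- if (nrow(v))
    keys[v$vtype == "INDEL" & runif(nrow(v)) < validation_sens]
  else character()
  segs <- truth@segments@segments
  cps <- lapply(split(segs, segs$chrom), function(d)
    sort(unique(c(d$start, d$end))))
  list(small = small, sv = sv,
       evidence = supportEvidence(lancet_validation = val,
                                  manta_small = manta_small,
                                  changepoints = cps))
}

#' The purity-ladder mixing grid
#'
#' Tumor downsampled to 10-70X mixed with the matched normal at 70-10X
#' (steps of 10), giving tumor read fractions 0.125 to 0.875.
#' @return data.frame(tumor_depth, normal_depth, t_frac)
#' @export
defaultPurityLadder <- function() {
  td <- seq(10, 70, 10)
  nd <- seq(70, 10, -10)
  data.frame(tumor_depth = td, normal_depth = nd, t_frac = td / (td + nd))
}

#' The coverage-ladder pairing grid
#'
#' Tumor depths 10, 20, 30, 40, 60, 80, 90X crossed with normal depths
#' 10, 20, 30, 40X.
#' @return data.frame(tumor_depth, normal_depth)
#' @export
defaultCoverageLadder <- function() {
  expand.grid(tumor_depth = c(10, 20, 30, 40, 60, 80, 90),
              normal_depth = c(10, 20, 30, 40))
}

#' Default sequencing-error profile for the read simulator
#' @param rate overall per-base mismatch rate on eligible bases
#' @param weights 192-channel weights (uniform by default), normalised to
#'   sum to 1
#' @param g_run_extend probability that a base following a G is flipped to
#'   G (2-colour-chemistry-style homopolymer inflation; 0 disables)
#' @return named list consumed by [simulateReads()]
#' @export
errorProfile <- function(rate = 0.002, weights = NULL, g_run_extend = 0) {
  w <- weights %||% stats::setNames(rep(1 / 192, 192L), mismatchChannels())
  if (is.null(names(w))) names(w) <- mismatchChannels()
  w <- w / sum(w)
  list(rate = rate, weights = w, g_run_extend = g_run_extend)
}

#' Simulate error-profiled aligned reads over a reference
#'
#' Reads of length `read_length` tile the reference at evenly spaced
#' starts to the requested depth. Per-base errors are drawn from the
#' 192-channel profile: a base with reference context (5', ref, 3') is
#' mis-read as alt with probability rate * 64 * w(5'[ref>alt]3'), so a
#' uniform profile yields the requested overall rate. The
#' `g_run_extend` knob then extends G runs (each base whose predecessor in
#' the read is G flips to G with that probability), emulating the
#' no-signal-G artifact of 2-colour chemistry. All reads are emitted
#' forward-strand, mapq 60, uniform base quality 30, alternating R1/R2.
#'
#' @param reference single contig as a named character vector (name =
#'   contig) or a length-1 [Biostrings::DNAStringSet-class]
#' @param depth target mean depth
#' @param error_profile an [errorProfile()] list
#' @param read_length read length in bp (default 150)
#' @param seed RNG seed
#' @return list: `reads` (aligned-read table) and `reference` (named
#'   character)
#' @export
simulateReads <- function(reference, depth, error_profile = errorProfile(),
                          read_length = 150, seed = 1) {
  if (is(reference, "DNAStringSet")) {
    nm <- names(reference)
    reference <- stats::setNames(as.character(reference), nm)
  }
  stopifnot(length(reference) == 1L, !is.null(names(reference)))
  rlen <- nchar(reference[[1]])
  if (rlen < read_length) stop("reference shorter than the read length")
  set.seed(seed)
  chrom <- names(reference)
  rc <- strsplit(reference[[1]], "")[[1]]
  ## per-position error probability and alt distribution
  bases <- c("A", "C", "G", "T")
  w <- error_profile$weights[mismatchChannels()]
  p_alt <- matrix(0, nrow = rlen, ncol = 3L)
  alt_of <- matrix(NA_character_, nrow = rlen, ncol = 3L)
  inner <- 2:(rlen - 1L)
  ctx_known <- inner[rc[inner] %in% bases & rc[inner - 1L] %in% bases &
                       rc[inner + 1L] %in% bases]
  for (j in ctx_known) {
    alts <- setdiff(bases, rc[j])
    chans <- paste0(rc[j - 1L], "[", rc[j], ">", alts, "]", rc[j + 1L])
    alt_of[j, ] <- alts
    p_alt[j, ] <- error_profile$rate * 64 * as.numeric(w[chans])
  }
  p_tot <- pmin(rowSums(p_alt), 0.75)
  n_reads <- ceiling(depth * rlen / read_length)
  starts <- as.integer(round(seq(1, rlen - read_length + 1,
                                 length.out = n_reads)))
  qual <- paste(rep(rawToChar(as.raw(30 + 33)), read_length), collapse = "")
  seqs <- character(n_reads)
  for (r in seq_len(n_reads)) {
    idx <- starts[r]:(starts[r] + read_length - 1L)
    b <- rc[idx]
    u <- runif(read_length)
    err <- which(u < p_tot[idx])
    for (e in err) {
      j <- idx[e]
      b[e] <- sample(alt_of[j, ], 1L, prob = p_alt[j, ] / sum(p_alt[j, ]))
    }
    if (error_profile$g_run_extend > 0) {
      flip <- runif(read_length) < error_profile$g_run_extend
      for (e in which(flip[-1L]) + 1L) if (b[e - 1L] == "G") b[e] <- "G"
    }
    seqs[r] <- paste(b, collapse = "")
  }
  reads <- data.frame(
    qname = sprintf("frag%06d", seq_len(n_reads)),
    read_index = ifelse(seq_len(n_reads) %% 2L == 1L, "R1", "R2"),
    chrom = chrom, pos = starts, seq = seqs, qual = qual,
    mapq = 60L, cigar = NA_character_,
    is_reverse = FALSE, is_duplicate = FALSE, is_supplementary = FALSE,
    is_qcfail = FALSE, is_unmapped = FALSE, stringsAsFactors = FALSE)
  list(reads = reads, reference = reference)
}

#' Identity keys of a truth set's small variants
#'
#' Keys in the `chrom:pos:ref:alt` form used throughout the evaluation
#' module; MNVs are decomposed to their constituent SNV keys by default,
#' matching how callsets are compared across runs.
#' @param truth a [TruthSet-class]
#' @param decompose_mnv decompose MNV keys to SNV keys (default TRUE)
#' @return character vector of variant keys
#' @export
truthVariantKeys <- function(truth, decompose_mnv = TRUE) {
  stopifnot(is(truth, "TruthSet"))
  v <- truth@variants
  if (!nrow(v)) return(character())
  unlist(lapply(seq_len(nrow(v)), function(i) {
    if (decompose_mnv && v$vtype[i] == "MNV") {
      cons <- .mnvConstituents(v$chrom[i], v$pos[i], v$ref[i], v$alt[i])
      variantKey(cons$chrom, cons$pos, cons$ref, cons$alt)
    } else variantKey(v$chrom[i], v$pos[i], v$ref[i], v$alt[i])
  }))
}
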