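#' @import methods
#' @importFrom stats rbinom rpois rnorm runif setNames
NULL

## ---------------------------------------------------------------------------
## SmallVariantSet
## ---------------------------------------------------------------------------

.SMALL_VARIANT_COLS <- c(
  "chrom", "pos", "ref", "alt", "vtype", "callers", "mnv_id", "filters",
  "hc", "t_ref", "t_alt", "t_depth", "t_vaf", "t_source",
  "n_ref", "n_alt", "n_depth", "n_vaf", "n_source",
  "pop_af", "caller_counts")

#' SmallVariantSet: a collection of somatic SNVs, MNVs and indels
#'
#' Stores one record per small variant with 1-based VCF-convention
#' coordinates, the set of supporting callers, filter tags (tag-based
#' filtering: an empty tag set means the record is a member of the
#' AllSomatic callset), the high-confidence flag, final tumor/normal allele
#' counts, per-caller reported counts, and population allele frequencies.
#'
#' @slot variants data.frame with one row per variant; list-columns hold the
#'   caller-support sets, filter tags, population AFs and per-caller counts.
#' @export
setClass("SmallVariantSet", representation(variants = "data.frame"))

setValidity("SmallVariantSet", function(object) {
  v <- object@variants
  missing_cols <- setdiff(.SMALL_VARIANT_COLS, names(v))
  if (length(missing_cols))
    return(paste("missing columns:", paste(missing_cols, collapse = ", ")))
  if (nrow(v) == 0L) return(TRUE)
  if (any(v$pos < 1L)) return("pos must be >= 1 (1-based)")
  if (any(v$ref == v$alt)) return("ref and alt must differ")
  expected <- inferVtype(v$ref, v$alt)
  if (any(v$vtype != expected))
    return("vtype inconsistent with allele lengths")
  if (!all(v$vtype %in% c("SNV", "MNV", "INDEL")))
    return("vtype must be SNV, MNV or INDEL")
  ok_src <- function(s) all(is.na(s) | s %in% COUNT_SOURCES)
  if (!ok_src(v$t_source) || !ok_src(v$n_source))
    return("unknown count source")
  ## vaf consistency where both counts and vaf are present
  chk <- function(rc, ac, vaf, src) {
    have <- !is.na(rc) & !is.na(ac) & !is.na(vaf) & !is.na(src) & src != "NONE"
    all(abs(vaf[have] - vafFrom(rc[have], ac[have])) < 1e-8, na.rm = TRUE)
  }
  if (!chk(v$t_ref, v$t_alt, v$t_vaf, v$t_source) ||
      !chk(v$n_ref, v$n_alt, v$n_vaf, v$n_source))
    return("vaf inconsistent with ref/alt counts")
  TRUE
})

#' Construct a SmallVariantSet
#'
#' Vectorised constructor; `vtype` is inferred from allele lengths. Counts
#' and VAFs default to missing; `callers` and `filters` accept a single
#' character vector (recycled) or a list of character vectors per record.
#'
#' @param chrom,pos,ref,alt variant identity (pos is 1-based)
#' @param callers caller support; character vector or list of such
#' @param filters filter tags; empty means PASS / AllSomatic member
#' @param mnv_id optional MNV origin identifier (see [decomposeMnvs()])
#' @param hc logical high-confidence flag
#' @param t_ref,t_alt,t_depth,t_vaf,t_source tumor-sample final counts
#' @param n_ref,n_alt,n_depth,n_vaf,n_source normal-sample final counts
#' @param pop_af list of named numeric vectors (database -> MAF)
#' @param caller_counts list of per-caller reported count tables
#' @return a [SmallVariantSet-class]
#' @examples
#' sv <- SmallVariants(chrom = "chr1", pos = 100L, ref = "A", alt = "G",
#'                     callers = "strelka2")
#' nRecords(sv)
#' @export
SmallVariants <- function(chrom = character(), pos = integer(),
                          ref = character(), alt = character(),
                          callers = list(), filters = list(),
                          mnv_id = NA_character_, hc = FALSE,
                          t_ref = NA_real_, t_alt = NA_real_,
                          t_depth = NA_real_, t_vaf = NA_real_,
                          t_source = NA_character_,
                          n_ref = NA_real_, n_alt = NA_real_,
                          n_depth = NA_real_, n_vaf = NA_real_,
                          n_source = NA_character_,
                          pop_af = list(), caller_counts = list()) {
  n <- length(chrom)
  as_listcol <- function(x, default) {
    if (is.null(x) || (is.list(x) && length(x) == 0L && n > 0L))
      return(rep(list(default), n))
    if (!is.list(x)) return(rep(list(x), n))
    if (length(x) == 1L && n > 1L) return(rep(x, n))
    x
  }
  v <- data.frame(chrom = as.character(chrom), pos = as.integer(pos),
                  ref = as.character(ref), alt = as.character(alt),
                  stringsAsFactors = FALSE)
  v$vtype <- if (n) inferVtype(v$ref, v$alt) else character()
  v$callers <- as_listcol(callers, character())
  v$mnv_id <- rep_len(as.character(mnv_id), n)
  v$filters <- as_listcol(filters, character())
  v$hc <- rep_len(as.logical(hc), n)
  for (col in c("t_ref", "t_alt", "t_depth", "t_vaf",
                "n_ref", "n_alt", "n_depth", "n_vaf")) {
    v[[col]] <- rep_len(as.numeric(get(col)), n)
  }
  v$t_source <- rep_len(as.character(t_source), n)
  v$n_source <- rep_len(as.character(n_source), n)
  v$pop_af <- as_listcol(pop_af, stats::setNames(numeric(), character()))
  v$caller_counts <- as_listcol(caller_counts, NULL)
  v <- v[, .SMALL_VARIANT_COLS]
  new("SmallVariantSet", variants = v)
}

## ---------------------------------------------------------------------------
## BreakendPairSet
## ---------------------------------------------------------------------------

.BREAKEND_COLS <- c("chrom1", "start1", "end1", "chrom2", "start2", "end2",
                    "strand1", "strand2", "svtype", "name", "callers",
                    "filters", "hc", "split_t", "split_n")

#' BreakendPairSet: structural variants as paired breakend intervals
#'
#' BEDPE-convention container: both breakend confidence intervals are
#' 0-based half-open. Intrachromosomal events are stored with breakend 1
#' upstream of breakend 2 (swapped at construction if needed, strands
#' following their breakends).
#'
#' @slot pairs data.frame, one row per SV event.
#' @export
setClass("BreakendPairSet", representation(pairs = "data.frame"))

setValidity("BreakendPairSet", function(object) {
  p <- object@pairs
  missing_cols <- setdiff(.BREAKEND_COLS, names(p))
  if (length(missing_cols))
    return(paste("missing columns:", paste(missing_cols, collapse = ", ")))
  if (nrow(p) == 0L) return(TRUE)
  if (any(p$start1 >= p$end1) || any(p$start2 >= p$end2))
    return("breakend intervals must satisfy start < end")
  if (any(p$start1 < 0L) || any(p$start2 < 0L))
    return("coordinates are 0-based and must be >= 0")
  if (!all(p$strand1 %in% c("+", "-")) || !all(p$strand2 %in% c("+", "-")))
    return("strands must be '+' or '-'")
  if (!all(p$svtype %in% SV_TYPES))
    return(paste("svtype must be one of", paste(SV_TYPES, collapse = "/")))
  intra <- p$chrom1 == p$chrom2
  if (any(intra & p$start1 > p$start2))
    return("intrachromosomal events must have breakend 1 <= breakend 2")
  bad_sr <- function(x) any(!is.na(x) & x < 0)
  if (bad_sr(p$split_t) || bad_sr(p$split_n))
    return("split-read counts must be >= 0")
  TRUE
})

#' Construct a BreakendPairSet
#'
#' Coordinates are 0-based half-open per breakend interval. Intrachromosomal
#' events with breakend 1 downstream of breakend 2 are swapped (with their
#' strands) to the canonical orientation.
#'
#' @param chrom1,start1,end1,chrom2,start2,end2 breakend intervals
#' @param strand1,strand2 breakend strands ("+"/"-")
#' @param svtype one of DEL, DUP, INV, INS, TRA
#' @param name event identifier (generated if missing)
#' @param callers,filters list-columns as in [SmallVariants()]
#' @param hc high-confidence flag
#' @param split_t,split_n tumor/normal split-read support (NA if unknown)
#' @return a [BreakendPairSet-class]
#' @export
BreakendPairs <- function(chrom1 = character(), start1 = integer(),
                          end1 = integer(), chrom2 = character(),
                          start2 = integer(), end2 = integer(),
                          strand1 = "+", strand2 = "-",
                          svtype = character(), name = NA_character_,
                          callers = list(), filters = list(), hc = FALSE,
                          split_t = NA_real_, split_n = NA_real_) {
  n <- length(chrom1)
  as_listcol <- function(x) {
    if (is.null(x) || (is.list(x) && length(x) == 0L && n > 0L))
      return(rep(list(character()), n))
    if (!is.list(x)) return(rep(list(x), n))
    if (length(x) == 1L && n > 1L) return(rep(x, n))
    x
  }
  p <- data.frame(chrom1 = as.character(chrom1), start1 = as.integer(start1),
                  end1 = as.integer(end1), chrom2 = as.character(chrom2),
                  start2 = as.integer(start2), end2 = as.integer(end2),
                  strand1 = rep_len(as.character(strand1), n),
                  strand2 = rep_len(as.character(strand2), n),
                  svtype = rep_len(as.character(svtype), n),
                  name = rep_len(as.character(name), n),
                  stringsAsFactors = FALSE)
  swap <- p$chrom1 == p$chrom2 & p$start1 > p$start2
  if (any(swap)) {
    tmp <- p[swap, c("chrom1", "start1", "end1", "strand1")]
    p[swap, c("chrom1", "start1", "end1", "strand1")] <-
      p[swap, c("chrom2", "start2", "end2", "strand2")]
    p[swap, c("chrom2", "start2", "end2", "strand2")] <- tmp
  }
  miss <- is.na(p$name)
  if (any(miss)) p$name[miss] <- sprintf("sv%04d", which(miss))
  p$callers <- as_listcol(callers)
  p$filters <- as_listcol(filters)
  p$hc <- rep_len(as.logical(hc), n)
  p$split_t <- rep_len(as.numeric(split_t), n)
  p$split_n <- rep_len(as.numeric(split_n), n)
  p <- p[, .BREAKEND_COLS]
  new("BreakendPairSet", pairs = p)
}

## ---------------------------------------------------------------------------
## CNVSegmentSet
## ---------------------------------------------------------------------------

.SEGMENT_COLS <- c("chrom", "start", "end", "obs_log2", "adj_log2",
                   "t_cn", "n_cn", "category", "neg_cn")

#' CNVSegmentSet: copy-number segments with observed and adjusted log2 ratios
#'
#' 0-based half-open genomic intervals with an observed log2 copy ratio,
#' an optional purity/ploidy-adjusted log2, the inferred absolute tumor copy
#' number, the assumed normal copy number (2 on autosomes by default), and
#' the AMP/DEL/NEUTRAL category derived from the active log2 value.
#'
#' @slot segments data.frame, one row per segment.
#' @export
setClass("CNVSegmentSet", representation(segments = "data.frame"))

setValidity("CNVSegmentSet", function(object) {
  s <- object@segments
  missing_cols <- setdiff(.SEGMENT_COLS, names(s))
  if (length(missing_cols))
    return(paste("missing columns:", paste(missing_cols, collapse = ", ")))
  if (nrow(s) == 0L) return(TRUE)
  if (any(s$end <= s$start)) return("segments must satisfy end > start")
  if (!all(s$category %in% CNV_CATEGORIES))
    return("unknown CNV category")
  TRUE
})

#' Construct a CNVSegmentSet
#'
#' @param chrom,start,end 0-based half-open segment interval
#' @param obs_log2 observed log2 copy ratio
#' @param adj_log2 purity/ploidy-adjusted log2 (NA until adjusted)
#' @param t_cn absolute tumor copy number (NA until inferred)
#' @param n_cn normal copy number for the segment (default 2)
#' @param category AMP/DEL/NEUTRAL/UNDEFINED; derived from `obs_log2` with
#'   the default thresholds when not supplied
#' @return a [CNVSegmentSet-class]
#' @export
CNVSegments <- function(chrom = character(), start = integer(),
                        end = integer(), obs_log2 = numeric(),
                        adj_log2 = NA_real_, t_cn = NA_real_, n_cn = 2,
                        category = NULL) {
  n <- length(chrom)
  s <- data.frame(chrom = as.character(chrom), start = as.integer(start),
                  end = as.integer(end), obs_log2 = as.numeric(obs_log2),
                  adj_log2 = rep_len(as.numeric(adj_log2), n),
                  t_cn = rep_len(as.numeric(t_cn), n),
                  n_cn = rep_len(as.numeric(n_cn), n),
                  stringsAsFactors = FALSE)
  s$category <- if (is.null(category)) {
    if (n) categorizeLog2(s$obs_log2) else character()
  } else rep_len(as.character(category), n)
  s$neg_cn <- rep_len(FALSE, n)
  s <- s[, .SEGMENT_COLS]
  new("CNVSegmentSet", segments = s)
}

## ---------------------------------------------------------------------------
## PurityMixture
## ---------------------------------------------------------------------------

#' PurityMixture: tumor/normal read-mixture specification
#'
#' Holds the mixing fraction and ploidies of an in-silico tumor-normal
#' mixture together with the derived true tumor purity:
#' \deqn{T_{purity} = \frac{T_{frac} N_{ploidy}}
#'   {(1-T_{frac}) T_{ploidy} + T_{frac} N_{ploidy}}}
#'
#' @slot t_frac fraction of reads drawn from the tumor library, in [0,1]
#' @slot t_ploidy average tumor ploidy (> 0)
#' @slot n_ploidy average normal ploidy (default 2)
#' @slot t_purity derived tumor purity
#' @export
setClass("PurityMixture",
         representation(t_frac = "numeric", t_ploidy = "numeric",
                        n_ploidy = "numeric", t_purity = "numeric"))

setValidity("PurityMixture", function(object) {
  if (object@t_frac < 0 || object@t_frac > 1)
    return("t_frac must lie in [0,1]")
  if (object@t_ploidy <= 0 || object@n_ploidy <= 0)
    return("ploidies must be positive")
  expect <- purityFromMixture(object@t_frac, object@t_ploidy, object@n_ploidy)
  if (abs(object@t_purity - expect) > 1e-10)
    return("t_purity inconsistent with the mixture purity equation")
  TRUE
})

#' Construct a PurityMixture
#' @param t_frac tumor read fraction in [0,1]
#' @param t_ploidy average tumor ploidy
#' @param n_ploidy average normal ploidy (default 2)
#' @return a [PurityMixture-class] with `t_purity` derived
#' @examples
#' PurityMixture(t_frac = 10 / (10 + 70), t_ploidy = 4)
#' @export
PurityMixture <- function(t_frac, t_ploidy, n_ploidy = 2) {
  new("PurityMixture", t_frac = t_frac, t_ploidy = t_ploidy,
      n_ploidy = n_ploidy,
      t_purity = purityFromMixture(t_frac, t_ploidy, n_ploidy))
}

## ---------------------------------------------------------------------------
## EvalCounts
## ---------------------------------------------------------------------------

#' EvalCounts: TP/FP/FN tallies with derived precision, recall and F1
#'
#' @slot tp,fp,fn,ignored non-negative tallies (variants, or bases for the
#'   CNV base-level comparison); `ignored` counts test calls present in the
#'   reference AllSomatic but not HighConfidence callset
#' @slot precision,recall,f1 derived scores; NA when the denominator is zero
#' @export
setClass("EvalCounts",
         representation(tp = "numeric", fp = "numeric", fn = "numeric",
                        ignored = "numeric", precision = "numeric",
                        recall = "numeric", f1 = "numeric"))

setValidity("EvalCounts", function(object) {
  if (any(c(object@tp, object@fp, object@fn, object@ignored) < 0))
    return("tallies must be non-negative")
  TRUE
})

#' Construct an EvalCounts
#'
#' Precision = TP/(TP+FP), Recall = TP/(TP+FN),
#' F1 = 2 * Precision * Recall / (Precision + Recall); each is NA when its
#' denominator is zero.
#' @param tp,fp,fn,ignored tallies
#' @return an [EvalCounts-class] with the scores filled in
#' @export
EvalCounts <- function(tp = 0, fp = 0, fn = 0, ignored = 0) {
  prec <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  rec  <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  f1   <- if (!is.na(prec) && !is.na(rec) && (prec + rec) > 0)
    2 * prec * rec / (prec + rec) else NA_real_
  new("EvalCounts", tp = as.numeric(tp), fp = as.numeric(fp),
      fn = as.numeric(fn), ignored = as.numeric(ignored),
      precision = prec, recall = rec, f1 = f1)
}

## ---------------------------------------------------------------------------
## Panels of normals
## ---------------------------------------------------------------------------

#' SmallPon: panel of normals for SNVs and indels
#'
#' Location-keyed (chrom, pos) site list with the number of distinct normal
#' individuals each site was observed in. Only sites seen in at least
#' `min_individuals` individuals are retained at build time.
#' @slot sites data.frame(chrom, pos, n_individuals)
#' @export
setClass("SmallPon", representation(sites = "data.frame"))

#' SvPon: panel of normals for structural variants
#'
#' Clustered normal-sample SV events (same type, same strands, breakends
#' within a maximum distance) with the distinct-individual count per cluster.
#' @slot events data.frame of BreakendPairSet columns plus `n_individuals`
#' @export
setClass("SvPon", representation(events = "data.frame"))

## ---------------------------------------------------------------------------
## MismatchCounts
## ---------------------------------------------------------------------------

#' MismatchCounts: 192-channel read-strand mismatch tallies
#'
#' Counts of single-nucleotide mismatches indexed by the 12 ref>read
#' substitution types crossed with the 16 flanking-base contexts
#' ("A[C>A]G" naming), plus the number of eligible (quality-passing,
#' context-complete) aligned bases.
#'
#' @slot counts named numeric of length 192
#' @slot eligible_bases denominator for the mismatch rate
#' @slot read_index "R1", "R2" or "combined"
#' @export
setClass("MismatchCounts",
         representation(counts = "numeric", eligible_bases = "numeric",
                        read_index = "character"))

setValidity("MismatchCounts", function(object) {
  if (length(object@counts) != 192L)
    return("counts must have 192 channels")
  if (any(object@counts < 0)) return("counts must be non-negative")
  if (sum(object@counts) > object@eligible_bases + 1e-9)
    return("channel sum exceeds eligible bases")
  TRUE
})

#' All 192 read-strand mismatch channel names
#'
#' Channels are named `5'[REF>READ]3'` over the 12 substitution types and 16
#' flanking contexts, in a fixed order shared by the profiler and simulator.
#' @return character vector of length 192
#' @export
mismatchChannels <- function() {
  bases <- c("A", "C", "G", "T")
  types <- unlist(lapply(bases, function(r)
    paste0(r, ">", setdiff(bases, r))))
  unlist(lapply(types, function(t)
    paste0(rep(bases, each = 4), "[", t, "]", rep(bases, 4))))
}

#' Construct a MismatchCounts
#' @param counts named numeric over the [mismatchChannels()] names (missing
#'   channels filled with 0) or NULL for all-zero
#' @param eligible_bases eligible-base denominator
#' @param read_index "R1", "R2" or "combined"
#' @return a [MismatchCounts-class]
#' @export
MismatchCounts <- function(counts = NULL, eligible_bases = 0,
                           read_index = "combined") {
  ch <- mismatchChannels()
  full <- stats::setNames(numeric(192L), ch)
  if (!is.null(counts)) {
    unknown <- setdiff(names(counts), ch)
    if (length(unknown))
      stop("unknown mismatch channel(s): ", paste(unknown, collapse = ", "))
    full[names(counts)] <- counts
  }
  new("MismatchCounts", counts = full,
      eligible_bases = as.numeric(eligible_bases),
      read_index = read_index)
}

## ---------------------------------------------------------------------------
## CallerProfile
## ---------------------------------------------------------------------------

#' CallerProfile: behavioural profile of a mock variant caller
#'
#' Sensitivity is a saturating Hill curve of the alt read count,
#' p(alt) = p_max * alt^h / (alt^h + k^h). False positives are placed at a
#' per-megabase rate and their substitution channels drawn from 96-channel
#' context-bias weights (e.g. elevated T>G in NTT contexts, as seen on
#' 2-colour-chemistry instruments). Reported counts get additive
#' Gaussian noise.
#'
#' @slot name caller name
#' @slot p_max,k,h sensitivity-curve parameters
#' @slot fp_per_mb false-positive rate per megabase
#' @slot context_bias numeric of length 96 (collapsed-channel weights),
#'   normalised to sum to 1
#' @slot count_noise_sd sd of the count-reporting noise (reads)
#' @export
setClass("CallerProfile",
         representation(name = "character", p_max = "numeric", k = "numeric",
                        h = "numeric", fp_per_mb = "numeric",
                        context_bias = "numeric", count_noise_sd = "numeric"))

setValidity("CallerProfile", function(object) {
  if (object@p_max < 0 || object@p_max > 1)
    return("p_max must lie in [0,1]")
  if (length(object@context_bias) != 96L)
    return("context_bias must have 96 channels")
  if (any(object@context_bias < 0))
    return("context_bias weights must be non-negative")
  TRUE
})

#' Construct a CallerProfile
#' @param name caller name
#' @param p_max asymptotic detection probability
#' @param k alt-read count at half-maximal detection
#' @param h Hill coefficient (steepness)
#' @param fp_per_mb false positives per megabase
#' @param context_bias optional 96-long weight vector (uniform by default)
#' @param count_noise_sd sd of reported-count noise
#' @return a [CallerProfile-class]
#' @export
CallerProfile <- function(name, p_max = 0.98, k = 3, h = 2,
                          fp_per_mb = 0.5, context_bias = NULL,
                          count_noise_sd = 0.5) {
  cb <- context_bias %||% rep(1 / 96, 96L)
  cb <- cb / sum(cb)
  new("CallerProfile", name = name, p_max = p_max, k = k, h = h,
      fp_per_mb = fp_per_mb, context_bias = cb,
      count_noise_sd = count_noise_sd)
}

## detection probability at a given alt read count
profileSensitivity <- function(profile, alt) {
  ifelse(alt <= 0, 0,
         profile@p_max * alt^profile@h / (alt^profile@h + profile@k^profile@h))
}
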