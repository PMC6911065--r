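## Final allele-count selection (pileup or caller priority) and the
## count-based AllSomatic filters.
##
## Read evidence is a data.frame with one row per read observation at a
## locus: fragment_id, allele (REF/ALT/OTHER), mq, bq, and the exclusion
## flags is_duplicate, is_supplementary, is_qcfail, is_unmapped.

#' Pileup allele counts at one locus
#'
#' Counts unique read-pairs supporting each allele: flagged reads
#' (duplicate, supplementary, QC-fail, unmapped) and reads below the
#' mapping/base quality thresholds are excluded; the surviving reads are
#' deduplicated by fragment so a pair counts once; fragments whose two
#' mates disagree on the allele are dropped. Depth is the number of
#' surviving fragments (REF + ALT + OTHER); VAF = alt/(ref+alt), missing
#' when that denominator is zero.
#'
#' @param evidence read-evidence data.frame for one locus and one sample
#' @param mq_min,bq_min minimum mapping and base quality (default 10 each)
#' @return list with ref_count, alt_count, depth, vaf, source = "PILEUP"
#' @export
pileupCounts <- function(evidence, mq_min = 10, bq_min = 10) {
  empty <- list(ref_count = 0, alt_count = 0, depth = 0, vaf = NA_real_,
                source = "PILEUP")
  if (is.null(evidence) || !nrow(evidence)) return(empty)
  needed <- c("fragment_id", "allele", "mq", "bq", "is_duplicate",
              "is_supplementary", "is_qcfail", "is_unmapped")
  missing_cols <- setdiff(needed, names(evidence))
  if (length(missing_cols))
    stop("evidence lacks columns: ", paste(missing_cols, collapse = ", "))
  keep <- !evidence$is_duplicate & !evidence$is_supplementary &
    !evidence$is_qcfail & !evidence$is_unmapped &
    evidence$mq >= mq_min & evidence$bq >= bq_min
  ev <- evidence[keep, , drop = FALSE]
  if (!nrow(ev)) return(empty)
  frag_allele <- tapply(ev$allele, ev$fragment_id, function(a) {
    u <- unique(a)
    if (length(u) == 1L) u else NA_character_  # mate disagreement -> drop
  })
  frag_allele <- frag_allele[!is.na(frag_allele)]
  ref_n <- sum(frag_allele == "REF")
  alt_n <- sum(frag_allele == "ALT")
  list(ref_count = ref_n, alt_count = alt_n, depth = length(frag_allele),
       vaf = if (ref_n + alt_n > 0) alt_n / (ref_n + alt_n) else NA_real_,
       source = "PILEUP")
}

## does the pileup path apply to this allele pair?
.usesPileup <- function(ref, alt, indel_maxlen = 10) {
  vt <- inferVtype(ref, alt)
  simple <- nchar(ref) == 1L | nchar(alt) == 1L
  vt != "INDEL" | (simple & indelLength(ref, alt) < indel_maxlen)
}

#' Select final allele counts for merged variants
#'
#' SNVs, MNVs and simple indels with net length change below `indel_maxlen`
#' (10 nt) take pileup counts; larger indels and complex events take the
#' counts reported by the first available caller among Strelka2, MuTect2,
#' Lancet (in that order). When only SvABA called a large indel no final
#' counts are reported (source NONE): SvABA does not report a reference
#' allele count, so no VAF can be formed.
#'
#' @param x a merged [SmallVariantSet-class]
#' @param tumor_pileup,normal_pileup named lists (variant key ->
#'   [pileupCounts()] result); keys as in [recordKeys()]. May be NULL when
#'   no pileup evidence exists.
#' @param indel_maxlen indel length at which counting switches to the
#'   caller-priority path (exclusive bound; default 10)
#' @return `x` with t_/n_ count columns and sources filled in
#' @export
selectFinalCounts <- function(x, tumor_pileup = NULL, normal_pileup = NULL,
                              indel_maxlen = 10) {
  stopifnot(is(x, "SmallVariantSet"))
  v <- x@variants
  if (!nrow(v)) return(x)
  keys <- variantKey(v$chrom, v$pos, v$ref, v$alt)
  priority <- c("strelka2", "mutect2", "lancet")
  for (i in seq_len(nrow(v))) {
    if (.usesPileup(v$ref[i], v$alt[i], indel_maxlen)) {
      tc <- tumor_pileup[[keys[i]]] %||%
        list(ref_count = NA_real_, alt_count = NA_real_, depth = NA_real_,
             vaf = NA_real_, source = "PILEUP")
      nc <- normal_pileup[[keys[i]]] %||%
        list(ref_count = NA_real_, alt_count = NA_real_, depth = NA_real_,
             vaf = NA_real_, source = "PILEUP")
      v$t_ref[i] <- tc$ref_count; v$t_alt[i] <- tc$alt_count
      v$t_depth[i] <- tc$depth; v$t_vaf[i] <- tc$vaf
      v$t_source[i] <- "PILEUP"
      v$n_ref[i] <- nc$ref_count; v$n_alt[i] <- nc$alt_count
      v$n_depth[i] <- nc$depth; v$n_vaf[i] <- nc$vaf
      v$n_source[i] <- "PILEUP"
      next
    }
    cc <- v$caller_counts[[i]]
    chosen <- NULL
    for (cl in priority) {
      if (!is.null(cc) && cl %in% cc$caller) {
        row <- cc[cc$caller == cl, , drop = FALSE][1L, ]
        if (!is.na(row$t_alt)) { chosen <- row; break }
      }
    }
    if (is.null(chosen)) {
      v[i, c("t_ref", "t_alt", "t_depth", "t_vaf")] <- NA_real_
      v[i, c("n_ref", "n_alt", "n_depth", "n_vaf")] <- NA_real_
      v$t_source[i] <- "NONE"
      v$n_source[i] <- "NONE"
    } else {
      v$t_ref[i] <- chosen$t_ref; v$t_alt[i] <- chosen$t_alt
      v$t_depth[i] <- chosen$t_depth
      v$t_vaf[i] <- vafFrom(chosen$t_ref, chosen$t_alt)
      v$n_ref[i] <- chosen$n_ref; v$n_alt[i] <- chosen$n_alt
      v$n_depth[i] <- chosen$n_depth
      v$n_vaf[i] <- vafFrom(chosen$n_ref, chosen$n_alt)
      v$t_source[i] <- toupper(chosen$caller)
      v$n_source[i] <- toupper(chosen$caller)
    }
  }
  new("SmallVariantSet", variants = v)
}

.COUNT_TAGS <- c("LOW_TUMOR_VAF", "HIGH_NORMAL_VAF", "LOW_DEPTH",
                 "NORMAL_GT_TUMOR", "NO_COUNTS")

#' Apply the count-based somatic filters
#'
#' Tags (never removes) variants failing the final-count criteria:
#' \itemize{
#'   \item LOW_TUMOR_VAF: tumor VAF < `tumor_vaf_min` (default 0.0001;
#'     exactly 0.0001 passes)
#'   \item HIGH_NORMAL_VAF: normal VAF > `normal_vaf_max` (default 0.2;
#'     exactly 0.2 passes)
#'   \item LOW_DEPTH: depth < `min_depth` (default 2) in either sample
#'   \item NORMAL_GT_TUMOR: normal VAF strictly greater than tumor VAF
#' }
#' Records without usable counts in either sample (source NONE) get the
#' informational NO_COUNTS tag but remain AllSomatic members — they cannot
#' be judged by these filters. Re-running is idempotent: the five tags are
#' recomputed from the stored counts each time.
#'
#' @param x a [SmallVariantSet-class] with final counts selected
#' @param tumor_vaf_min,normal_vaf_max,min_depth thresholds
#' @return `x` with count-filter tags set
#' @export
applySomaticFilters <- function(x, tumor_vaf_min = 0.0001,
                                normal_vaf_max = 0.2, min_depth = 2) {
  stopifnot(is(x, "SmallVariantSet"))
  v <- x@variants
  if (!nrow(v)) return(x)
  tags <- lapply(v$filters, function(tg) setdiff(tg, .COUNT_TAGS))
  no_counts <- (!is.na(v$t_source) & v$t_source == "NONE") |
    (!is.na(v$n_source) & v$n_source == "NONE") |
    (is.na(v$t_vaf) & is.na(v$t_depth)) |
    (is.na(v$n_vaf) & is.na(v$n_depth))
  low_t <- !no_counts & !is.na(v$t_vaf) & v$t_vaf < tumor_vaf_min
  high_n <- !no_counts & !is.na(v$n_vaf) & v$n_vaf > normal_vaf_max
  low_d <- !no_counts &
    ((!is.na(v$t_depth) & v$t_depth < min_depth) |
       (!is.na(v$n_depth) & v$n_depth < min_depth))
  n_gt_t <- !no_counts & !is.na(v$t_vaf) & !is.na(v$n_vaf) &
    v$n_vaf > v$t_vaf
  tags <- .addTag(tags, which(no_counts), "NO_COUNTS")
  tags <- .addTag(tags, which(low_t), "LOW_TUMOR_VAF")
  tags <- .addTag(tags, which(high_n), "HIGH_NORMAL_VAF")
  tags <- .addTag(tags, which(low_d), "LOW_DEPTH")
  tags <- .addTag(tags, which(n_gt_t), "NORMAL_GT_TUMOR")
  v$filters <- tags
  new("SmallVariantSet", variants = v)
}
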