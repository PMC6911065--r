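## End-to-end post-calling pipeline: merge -> PON -> germline -> counts ->
## somatic filters -> high confidence -> CNV adjustment -> reports.

#' Default pipeline configuration
#'
#' All thresholds of the post-calling stack with their default values:
#' CNV categorization (amp 0.2 / del -0.235), SV merging (min size 500 bp,
#' slop 300 bp, 50% reciprocal overlap), PON (2 individuals, 300 bp SV
#' cluster distance), germline MAF 1%, count filters (tumor VAF >= 0.0001,
#' normal VAF <= 0.2, depth >= 2), pileup thresholds (MQ/BQ 10, indel
#' length switch at 10 nt), high-confidence support (3 tumor-only split
#' reads, 1000 bp changepoint distance), targeted-validation padding
#' (250 nt) and the profiler downsampling depth (8X).
#' @return named list of defaults
#' @export
defaultConfig <- function() {
  list(amp_threshold = 0.2, del_threshold = -0.235,
       sv_min_size = 500, sv_slop = 300, sv_reciprocal = 0.5,
       pon_min_individuals = 2, pon_sv_max_distance = 300,
       germline_maf = 0.01,
       tumor_vaf_min = 0.0001, normal_vaf_max = 0.2, min_depth = 2,
       pileup_mq = 10, pileup_bq = 10, pileup_indel_maxlen = 10,
       hc_min_split_reads = 3, hc_changepoint_dist = 1000,
       lancet_pad = 250, mismatch_depth = 8)
}

#' Attach population allele frequencies to variants
#'
#' Annotation step standing in for the VEP-style database lookup: a map
#' from variant key to named numeric (database -> MAF) is merged into the
#' `pop_af` column.
#' @param x a [SmallVariantSet-class]
#' @param af_map named list (variant key -> named numeric)
#' @return annotated [SmallVariantSet-class]
#' @export
annotatePopulationAf <- function(x, af_map) {
  stopifnot(is(x, "SmallVariantSet"))
  v <- x@variants
  if (!nrow(v) || !length(af_map)) return(x)
  keys <- variantKey(v$chrom, v$pos, v$ref, v$alt)
  hit <- keys %in% names(af_map)
  v$pop_af[hit] <- lapply(keys[hit], function(k)
    .mergeAf(list(v$pop_af[[match(k, keys)]], af_map[[k]])))
  new("SmallVariantSet", variants = v)
}

#' Run the post-calling somatic pipeline
#'
#' Executes the stages in order: MNV decomposition and cross-caller merge;
#' SV size filter and merge; PON filtering (small and SV); common-germline
#' filtering; final allele-count selection from pileup evidence; somatic
#' count filters; high-confidence annotation; CNV categorization and
#' (when purity is supplied) purity/ploidy adjustment. Filters tag, never
#' delete: the returned callsets carry every merged record with
#' AllSomatic/HighConfidence membership derivable via [isAllSomatic()] and
#' [highConfidence()]. A per-stage record-count log is returned, and
#' outputs are written to `out_dir` when given.
#'
#' @param small_callsets named list (caller -> [SmallVariantSet-class])
#' @param sv_callsets named list (caller -> [BreakendPairSet-class])
#' @param segments optional [CNVSegmentSet-class] (observed log2 ratios)
#' @param tumor_evidence,normal_evidence named lists (variant key ->
#'   read-evidence data.frame) for the pileup counts
#' @param evidence a [supportEvidence()] bundle for high-confidence rules
#' @param small_pon,sv_pon optional panels of normals (skipped when NULL)
#' @param germline_sv_catalog optional germline SV catalog
#' @param pop_af optional population-AF map for [annotatePopulationAf()]
#' @param purity optional list(t_purity, t_ploidy, n_ploidy = 2) for CNV
#'   adjustment
#' @param config threshold overrides over [defaultConfig()]
#' @param out_dir optional output directory for the merged files
#' @return list: `small`, `svs`, `segments` (annotated containers),
#'   `log` (per-stage record counts), `paths` (written files, if any)
#' @export
runPipeline <- function(small_callsets = list(), sv_callsets = list(),
                        segments = NULL,
                        tumor_evidence = NULL, normal_evidence = NULL,
                        evidence = supportEvidence(),
                        small_pon = NULL, sv_pon = NULL,
                        germline_sv_catalog = NULL, pop_af = NULL,
                        purity = NULL, config = list(), out_dir = NULL) {
  cfg <- utils::modifyList(defaultConfig(), config)
  log <- list()
  ## --- small variants: decompose, merge, reconstitute ---
  origins <- list()
  decomposed <- lapply(small_callsets, function(cs) {
    d <- decomposeMnvs(cs)
    origins[[length(origins) + 1L]] <<- d$origins
    d$variants
  })
  merged <- mergeSmallCallsets(decomposed)
  merged <- reconstituteMnvs(merged, do.call(rbind, origins))
  log$merged_small <- nRecords(merged)
  ## --- SVs: size filter then merge ---
  svs <- mergeSvCallsets(lapply(sv_callsets, filterMinSize,
                                min_size = cfg$sv_min_size),
                         slop = cfg$sv_slop,
                         reciprocal = cfg$sv_reciprocal)
  log$merged_sv <- nRecords(svs)
  ## --- PON ---
  if (!is.null(small_pon)) {
    merged <- applySmallPon(merged, small_pon)
    log$pon_small_tagged <- sum(vapply(filterTags(merged), function(f)
      "PON" %in% f, logical(1)))
  } else log$pon_small_tagged <- NA_integer_
  if (!is.null(sv_pon)) {
    svs <- applySvPon(svs, sv_pon,
                      min_individuals = cfg$pon_min_individuals,
                      slop = cfg$sv_slop, reciprocal = cfg$sv_reciprocal)
    log$pon_sv_tagged <- sum(vapply(filterTags(svs), function(f)
      "PON" %in% f, logical(1)))
  } else log$pon_sv_tagged <- NA_integer_
  ## --- common germline ---
  if (!is.null(pop_af)) merged <- annotatePopulationAf(merged, pop_af)
  merged <- germlineAfFilter(merged, threshold = cfg$germline_maf)
  svs <- germlineAfFilter(svs, catalog = germline_sv_catalog,
                          slop = cfg$sv_slop,
                          reciprocal = cfg$sv_reciprocal)
  ## --- allele counts ---
  pu <- function(ev_list) {
    if (is.null(ev_list)) return(NULL)
    lapply(ev_list, pileupCounts, mq_min = cfg$pileup_mq,
           bq_min = cfg$pileup_bq)
  }
  merged <- selectFinalCounts(merged, pu(tumor_evidence),
                              pu(normal_evidence),
                              indel_maxlen = cfg$pileup_indel_maxlen)
  ## --- somatic count filters ---
  merged <- applySomaticFilters(merged,
                                tumor_vaf_min = cfg$tumor_vaf_min,
                                normal_vaf_max = cfg$normal_vaf_max,
                                min_depth = cfg$min_depth)
  log$allsomatic_small <- sum(isAllSomatic(merged))
  log$allsomatic_sv <- sum(isAllSomatic(svs))
  ## --- high confidence ---
  merged <- annotateHighConfidence(merged, evidence)
  svs <- annotateHighConfidence(svs, evidence,
                                max_cp_dist = cfg$hc_changepoint_dist,
                                min_split = cfg$hc_min_split_reads)
  log$hc_small <- sum(highConfidence(merged) & isAllSomatic(merged))
  log$hc_sv <- sum(highConfidence(svs) & isAllSomatic(svs))
  ## --- CNV ---
  if (is.null(segments)) segments <- CNVSegments()
  if (nRecords(segments)) {
    s <- segments@segments
    s$category <- categorizeLog2(s$obs_log2, cfg$amp_threshold,
                                 cfg$del_threshold)
    segments <- new("CNVSegmentSet", segments = s)
    if (!is.null(purity)) {
      segments <- adjustLog2(segments, t_purity = purity$t_purity,
                             t_ploidy = purity$t_ploidy,
                             n_ploidy = purity$n_ploidy %||% 2,
                             amp_threshold = cfg$amp_threshold,
                             del_threshold = cfg$del_threshold)
    }
  }
  log$segments <- nRecords(segments)
  paths <- NULL
  if (!is.null(out_dir))
    paths <- writeMergedOutputs(merged, svs, segments, out_dir)
  list(small = merged, svs = svs, segments = segments, log = log,
       paths = paths)
}

#' AllSomatic and HighConfidence key sets of a pipeline result
#'
#' Convenience extractor for evaluation: returns the small-variant keys in
#' the AllSomatic callset and in its high-confidence subset, with MNVs
#' optionally decomposed to SNV keys (the representation used for
#' cross-run comparisons).
#' @param small a [SmallVariantSet-class] from [runPipeline()]
#' @param decompose_mnv decompose MNV keys into SNV keys (default TRUE)
#' @return list(all = character, hc = character)
#' @export
callsetKeys <- function(small, decompose_mnv = TRUE) {
  stopifnot(is(small, "SmallVariantSet"))
  v <- small@variants
  expand <- function(idx) {
    if (!length(idx)) return(character())
    unlist(lapply(idx, function(i) {
      if (decompose_mnv && v$vtype[i] == "MNV") {
        cons <- .mnvConstituents(v$chrom[i], v$pos[i], v$ref[i], v$alt[i])
        variantKey(cons$chrom, cons$pos, cons$ref, cons$alt)
      } else variantKey(v$chrom[i], v$pos[i], v$ref[i], v$alt[i])
    }))
  }
  all_idx <- which(.allSomaticFromTags(v$filters))
  hc_idx <- which(.allSomaticFromTags(v$filters) & v$hc)
  list(all = expand(all_idx), hc = expand(hc_idx))
}
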