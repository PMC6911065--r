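## Generics and accessor methods for the core containers. Slot access from
## user code should go through these.

#' Number of records in a container
#' @param x a SmallVariantSet, BreakendPairSet or CNVSegmentSet
#' @return integer count of records
#' @export
setGeneric("nRecords", function(x) standardGeneric("nRecords"))

#' Record table of a container
#'
#' Returns the underlying per-record data.frame (a copy; mutating it does
#' not alter the object).
#' @param x a container object
#' @return data.frame
#' @export
setGeneric("recordTable", function(x) standardGeneric("recordTable"))

#' Identity keys of the records
#'
#' Small variants: `chrom:pos:ref:alt`; SVs: the event name; CNV segments:
#' `chrom:start-end`.
#' @param x a container object
#' @return character vector
#' @export
setGeneric("recordKeys", function(x) standardGeneric("recordKeys"))

#' Caller support sets
#' @param x a SmallVariantSet or BreakendPairSet
#' @return list of character vectors, one per record
#' @export
setGeneric("callerSupport", function(x) standardGeneric("callerSupport"))

#' Filter tags per record
#' @param x a SmallVariantSet or BreakendPairSet
#' @return list of character vectors (empty = PASS)
#' @export
setGeneric("filterTags", function(x) standardGeneric("filterTags"))

#' High-confidence flags
#' @param x a SmallVariantSet or BreakendPairSet
#' @return logical vector
#' @export
setGeneric("highConfidence", function(x) standardGeneric("highConfidence"))

#' AllSomatic membership
#'
#' A record belongs to the AllSomatic callset when it carries none of the
#' disqualifying tags (PON, COMMON_GERMLINE, or any of the four count-based
#' filters). The informational NO_COUNTS tag does not disqualify.
#' @param x a SmallVariantSet or BreakendPairSet
#' @return logical vector
#' @export
setGeneric("isAllSomatic", function(x) standardGeneric("isAllSomatic"))

#' @describeIn nRecords small variants
#' @export
setMethod("nRecords", "SmallVariantSet", function(x) nrow(x@variants))
#' @describeIn nRecords breakend pairs
#' @export
setMethod("nRecords", "BreakendPairSet", function(x) nrow(x@pairs))
#' @describeIn nRecords CNV segments
#' @export
setMethod("nRecords", "CNVSegmentSet", function(x) nrow(x@segments))

#' @describeIn recordTable small variants
#' @export
setMethod("recordTable", "SmallVariantSet", function(x) x@variants)
#' @describeIn recordTable breakend pairs
#' @export
setMethod("recordTable", "BreakendPairSet", function(x) x@pairs)
#' @describeIn recordTable CNV segments
#' @export
setMethod("recordTable", "CNVSegmentSet", function(x) x@segments)

#' @describeIn recordKeys small variants
#' @export
setMethod("recordKeys", "SmallVariantSet", function(x) {
  v <- x@variants
  variantKey(v$chrom, v$pos, v$ref, v$alt)
})
#' @describeIn recordKeys breakend pairs
#' @export
setMethod("recordKeys", "BreakendPairSet", function(x) x@pairs$name)
#' @describeIn recordKeys CNV segments
#' @export
setMethod("recordKeys", "CNVSegmentSet", function(x) {
  s <- x@segments
  paste0(s$chrom, ":", s$start, "-", s$end)
})

#' @describeIn callerSupport small variants
#' @export
setMethod("callerSupport", "SmallVariantSet", function(x) x@variants$callers)
#' @describeIn callerSupport breakend pairs
#' @export
setMethod("callerSupport", "BreakendPairSet", function(x) x@pairs$callers)

#' @describeIn filterTags small variants
#' @export
setMethod("filterTags", "SmallVariantSet", function(x) x@variants$filters)
#' @describeIn filterTags breakend pairs
#' @export
setMethod("filterTags", "BreakendPairSet", function(x) x@pairs$filters)

#' @describeIn highConfidence small variants
#' @export
setMethod("highConfidence", "SmallVariantSet", function(x) x@variants$hc)
#' @describeIn highConfidence breakend pairs
#' @export
setMethod("highConfidence", "BreakendPairSet", function(x) x@pairs$hc)

.allSomaticFromTags <- function(tags) {
  vapply(tags, function(tg) !any(tg %in% SOMATIC_FAIL_TAGS), logical(1))
}

#' @describeIn isAllSomatic small variants
#' @export
setMethod("isAllSomatic", "SmallVariantSet",
          function(x) .allSomaticFromTags(x@variants$filters))
#' @describeIn isAllSomatic breakend pairs
#' @export
setMethod("isAllSomatic", "BreakendPairSet",
          function(x) .allSomaticFromTags(x@pairs$filters))

## internal: add a tag to selected records of a list-column
.addTag <- function(tags, idx, tag) {
  tags[idx] <- lapply(tags[idx], function(tg) sort(unique(c(tg, tag))))
  tags
}

## internal: subset containers by row index
.subsetVariants <- function(x, i) new("SmallVariantSet",
                                      variants = x@variants[i, , drop = FALSE])
.subsetPairs <- function(x, i) new("BreakendPairSet",
                                   pairs = x@pairs[i, , drop = FALSE])

setMethod("show", "SmallVariantSet", function(object) {
  v <- object@variants
  cat("SmallVariantSet with", nrow(v), "records\n")
  if (nrow(v)) {
    cat("  types:", paste(names(table(v$vtype)), table(v$vtype),
                          sep = "=", collapse = " "), "\n")
    cat("  AllSomatic:", sum(.allSomaticFromTags(v$filters)),
        " HighConfidence:", sum(v$hc), "\n")
  }
})

setMethod("show", "BreakendPairSet", function(object) {
  p <- object@pairs
  cat("BreakendPairSet with", nrow(p), "events\n")
  if (nrow(p)) {
    cat("  types:", paste(names(table(p$svtype)), table(p$svtype),
                          sep = "=", collapse = " "), "\n")
    cat("  AllSomatic:", sum(.allSomaticFromTags(p$filters)),
        " HighConfidence:", sum(p$hc), "\n")
  }
})

setMethod("show", "CNVSegmentSet", function(object) {
  s <- object@segments
  cat("CNVSegmentSet with", nrow(s), "segments\n")
  if (nrow(s))
    cat("  categories:", paste(names(table(s$category)), table(s$category),
                               sep = "=", collapse = " "), "\n")
})

setMethod("show", "PurityMixture", function(object) {
  cat(sprintf(
    "PurityMixture: t_frac=%.4g t_ploidy=%.3g n_ploidy=%.3g -> t_purity=%.4g\n",
    object@t_frac, object@t_ploidy, object@n_ploidy, object@t_purity))
})

setMethod("show", "EvalCounts", function(object) {
  cat(sprintf(
    "EvalCounts: TP=%g FP=%g FN=%g ignored=%g | P=%.4g R=%.4g F1=%.4g\n",
    object@tp, object@fp, object@fn, object@ignored,
    object@precision, object@recall, object@f1))
})

setMethod("show", "MismatchCounts", function(object) {
  cat(sprintf("MismatchCounts (%s): %g mismatches / %g eligible bases\n",
              object@read_index, sum(object@counts), object@eligible_bases))
})

#' Extract slots of an EvalCounts as a named list
#' @param x an EvalCounts
#' @return named list with tp, fp, fn, ignored, precision, recall, f1
#' @export
evalMetrics <- function(x) {
  stopifnot(is(x, "EvalCounts"))
  list(tp = x@tp, fp = x@fp, fn = x@fn, ignored = x@ignored,
       precision = x@precision, recall = x@recall, f1 = x@f1)
}
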