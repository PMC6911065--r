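## Concordance, TP/FP/FN classification with the ignore rule, precision/
## recall/F1, VAF-binned recall, and base-level CNV comparison.

#' Concordance between two variant key sets
#'
#' 100 * |intersection| / |union|. Missing (NA) when both sets are empty.
#' @param a,b character vectors of variant keys
#' @return percentage in [0, 100], or NA
#' @examples
#' concordance(c("a", "b", "c"), c("b", "c", "d"))  # 50
#' @export
concordance <- function(a, b) {
  a <- unique(a); b <- unique(b)
  u <- length(union(a, b))
  if (u == 0L) return(NA_real_)
  100 * length(intersect(a, b)) / u
}

#' Classify a test callset against a reference run
#'
#' True positives are test calls present in the reference HighConfidence
#' callset; false positives are test calls absent from the reference
#' AllSomatic callset; false negatives are reference HighConfidence calls
#' absent from the test set. Test calls present in AllSomatic but not in
#' HighConfidence are ignored — they cannot be confidently assigned either
#' way. tp + fp + ignored = |test|.
#'
#' @param test character vector of test-callset keys
#' @param ref_all reference AllSomatic keys
#' @param ref_hc reference HighConfidence keys; must be a subset of
#'   `ref_all`
#' @return an [EvalCounts-class]
#' @export
classifyCalls <- function(test, ref_all, ref_hc) {
  test <- unique(test); ref_all <- unique(ref_all); ref_hc <- unique(ref_hc)
  if (length(setdiff(ref_hc, ref_all)))
    stop("ref_hc must be a subset of ref_all")
  tp <- length(intersect(test, ref_hc))
  fp <- length(setdiff(test, ref_all))
  fn <- length(setdiff(ref_hc, test))
  ignored <- length(intersect(test, setdiff(ref_all, ref_hc)))
  EvalCounts(tp = tp, fp = fp, fn = fn, ignored = ignored)
}

#' Complete precision, recall and F1 on an EvalCounts
#'
#' Recomputes the derived scores from the stored tallies (Precision =
#' TP/(TP+FP), Recall = TP/(TP+FN), F1 = 2PR/(P+R); NA on zero
#' denominators).
#' @param x an [EvalCounts-class]
#' @return the completed [EvalCounts-class]
#' @export
precisionRecallF1 <- function(x) {
  stopifnot(is(x, "EvalCounts"))
  EvalCounts(tp = x@tp, fp = x@fp, fn = x@fn, ignored = x@ignored)
}

## per-category IRanges list by chrom, with an overlap check
.segRanges <- function(seg, category) {
  s <- seg@segments
  s <- s[s$category == category, , drop = FALSE]
  by_chrom <- split(s, s$chrom)
  lapply(by_chrom, function(d) {
    ir <- IRanges::IRanges(start = d$start + 1L, end = d$end)
    if (length(ir) > 1L && any(IRanges::countOverlaps(ir, ir) > 1L))
      stop("overlapping segments within one sample")
    IRanges::reduce(ir)
  })
}

#' Base-level CNV comparison
#'
#' Compares categorized segments of a test sample against a reference
#' sample at the base level: TP bases carry the category in both samples,
#' FP bases in the test only, FN bases in the reference only. Computed per
#' category (AMP or DEL) with interval arithmetic. Segments within one
#' sample must not overlap.
#'
#' @param test,ref [CNVSegmentSet-class] objects
#' @param category "AMP" or "DEL"
#' @return an [EvalCounts-class] with tallies in bases
#' @export
cnvBaseCompare <- function(test, ref, category = c("AMP", "DEL")) {
  stopifnot(is(test, "CNVSegmentSet"), is(ref, "CNVSegmentSet"))
  category <- match.arg(category)
  t_r <- .segRanges(test, category)
  r_r <- .segRanges(ref, category)
  chroms <- union(names(t_r), names(r_r))
  tp <- fp <- fn <- 0
  for (ch in chroms) {
    a <- t_r[[ch]] %||% IRanges::IRanges()
    b <- r_r[[ch]] %||% IRanges::IRanges()
    tp <- tp + sum(IRanges::width(IRanges::intersect(a, b)))
    fp <- fp + sum(IRanges::width(IRanges::setdiff(a, b)))
    fn <- fn + sum(IRanges::width(IRanges::setdiff(b, a)))
  }
  EvalCounts(tp = tp, fp = fp, fn = fn)
}

#' Recall per reference-VAF bin
#'
#' Partitions the reference HighConfidence variants by their reference VAF
#' into left-closed bins `[e_i, e_{i+1})` (the last bin closed on both
#' sides) and computes recall of the test set within each bin.
#'
#' @param test character vector of test keys
#' @param ref_hc character vector of reference HighConfidence keys
#' @param ref_vaf numeric reference VAFs parallel to `ref_hc`, in [0,1]
#' @param bin_edges increasing numeric vector of bin boundaries
#' @return data.frame(bin, n_ref, tp, recall)
#' @export
recallByVafBin <- function(test, ref_hc, ref_vaf,
                           bin_edges = c(0, 0.1, 0.2, 0.3, 0.5, 1)) {
  stopifnot(length(ref_hc) == length(ref_vaf))
  if (any(ref_vaf < 0 | ref_vaf > 1, na.rm = TRUE))
    stop("reference VAFs must lie in [0,1]")
  bins <- cut(ref_vaf, breaks = bin_edges, right = FALSE,
              include.lowest = TRUE)
  ## cut(right = FALSE) makes bins left-closed; include.lowest closes the
  ## final bin at the top edge so VAF == max(bin_edges) is counted
  out <- lapply(levels(bins), function(b) {
    in_bin <- !is.na(bins) & bins == b
    n_ref <- sum(in_bin)
    tp <- sum(ref_hc[in_bin] %in% test)
    data.frame(bin = b, n_ref = n_ref, tp = tp,
               recall = if (n_ref > 0) tp / n_ref else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' SV membership in a reference set
#'
#' A test SV is "seen in" a reference set when it matches any reference
#' event under the [svMatch()] criteria — exact coordinates differ across
#' runs, so SV set operations use the merge criteria rather than exact
#' keys.
#' @param test,ref [BreakendPairSet-class] objects
#' @param slop,reciprocal matching parameters
#' @return logical vector over the test events
#' @export
svSeenIn <- function(test, ref, slop = 300, reciprocal = 0.5) {
  stopifnot(is(test, "BreakendPairSet"), is(ref, "BreakendPairSet"))
  p <- test@pairs
  q <- ref@pairs
  if (!nrow(p)) return(logical())
  if (!nrow(q)) return(rep(FALSE, nrow(p)))
  vapply(seq_len(nrow(p)), function(i)
    any(.svMatchVec(p[rep(i, nrow(q)), , drop = FALSE], q,
                    slop, reciprocal)), logical(1))
}

#' Classify a test SV callset against a reference run
#'
#' SV analogue of [classifyCalls()], with set membership decided by
#' [svMatch()] (see [svSeenIn()]).
#' @param test,ref_all,ref_hc [BreakendPairSet-class] objects; `ref_hc`
#'   should be the high-confidence subset of `ref_all`
#' @param slop,reciprocal matching parameters
#' @return an [EvalCounts-class]
#' @export
classifySvCalls <- function(test, ref_all, ref_hc, slop = 300,
                            reciprocal = 0.5) {
  in_hc <- svSeenIn(test, ref_hc, slop, reciprocal)
  in_all <- svSeenIn(test, ref_all, slop, reciprocal)
  tp <- sum(in_hc)
  fp <- sum(!in_all)
  ignored <- sum(in_all & !in_hc)
  found <- svSeenIn(ref_hc, test, slop, reciprocal)
  fn <- sum(!found)
  EvalCounts(tp = tp, fp = fp, fn = fn, ignored = ignored)
}
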