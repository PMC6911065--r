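## High-confidence annotation. Orthogonal support evidence is consumed as
## data (validation-call key sets, split-read counts, CNV changepoints);
## no external caller is executed.

#' Bundle orthogonal support evidence
#'
#' @param lancet_validation character vector of small-variant keys seen in
#'   targeted assembly re-runs around single-caller variants
#' @param manta_small character vector of small-variant keys derived from
#'   Manta's small SV calls
#' @param splazers data.frame(name, split_t, split_n): split-read support
#'   per SV event from an independent split-read mapper
#' @param changepoints named list (chrom -> numeric CNV boundary positions)
#' @return list of class-free evidence, as consumed by [hcSmall()]/[hcSv()]
#' @export
supportEvidence <- function(lancet_validation = character(),
                            manta_small = character(),
                            splazers = NULL, changepoints = list()) {
  if (is.null(splazers))
    splazers <- data.frame(name = character(), split_t = numeric(),
                           split_n = numeric(), stringsAsFactors = FALSE)
  stopifnot(all(splazers$split_t >= 0, na.rm = TRUE),
            all(splazers$split_n >= 0, na.rm = TRUE))
  list(lancet_validation = lancet_validation, manta_small = manta_small,
       splazers = splazers, changepoints = changepoints)
}

#' High-confidence rule for small variants
#'
#' A small variant is high confidence when it was called by two or more
#' callers, or by exactly one caller and also seen in the targeted
#' validation calls or in the Manta small-SV-derived calls.
#'
#' @param x a [SmallVariantSet-class]
#' @param evidence a [supportEvidence()] bundle
#' @return logical vector, one per record
#' @export
hcSmall <- function(x, evidence = supportEvidence()) {
  stopifnot(is(x, "SmallVariantSet"))
  v <- x@variants
  if (!nrow(v)) return(logical())
  keys <- variantKey(v$chrom, v$pos, v$ref, v$alt)
  n_callers <- vapply(v$callers, length, integer(1))
  orthogonal <- keys %in% c(evidence$lancet_validation, evidence$manta_small)
  n_callers >= 2L | (n_callers == 1L & orthogonal)
}

#' Distance from SV breakends to the nearest CNV changepoint
#'
#' Minimum over the two breakends of the distance to the nearest CNV
#' boundary on the same chromosome; breakend coordinate is the interval
#' start. Infinite when no boundary exists on either chromosome.
#'
#' @param x a [BreakendPairSet-class]
#' @param changepoints named list (chrom -> numeric boundary positions)
#' @return numeric vector of distances (Inf where none)
#' @export
changepointDistance <- function(x, changepoints = list()) {
  stopifnot(is(x, "BreakendPairSet"))
  p <- x@pairs
  if (!nrow(p)) return(numeric())
  one <- function(chrom, coord) {
    cps <- changepoints[[chrom]]
    if (is.null(cps) || !length(cps)) return(Inf)
    min(abs(cps - coord))
  }
  vapply(seq_len(nrow(p)), function(i)
    min(one(p$chrom1[i], p$start1[i]), one(p$chrom2[i], p$start2[i])),
    numeric(1))
}

#' High-confidence rule for structural variants
#'
#' An SV is high confidence when it was called by two or more callers; or
#' called by Manta or Lumpy alone with either a CNV changepoint within
#' `max_cp_dist` (1000 bp, inclusive) of a breakend, or split-read support
#' of at least `min_split` (3) reads in the tumor and none in the normal.
#' Split-read counts already stored on the records are used when the
#' evidence table has no entry for an event.
#'
#' @param x a [BreakendPairSet-class]
#' @param evidence a [supportEvidence()] bundle
#' @param max_cp_dist maximum changepoint distance in bp (default 1000)
#' @param min_split minimum tumor split reads (default 3)
#' @return logical vector, one per record
#' @export
hcSv <- function(x, evidence = supportEvidence(), max_cp_dist = 1000,
                 min_split = 3) {
  stopifnot(is(x, "BreakendPairSet"))
  p <- x@pairs
  if (!nrow(p)) return(logical())
  n_callers <- vapply(p$callers, length, integer(1))
  single_ml <- n_callers == 1L &
    vapply(p$callers, function(cl) all(cl %in% c("manta", "lumpy")),
           logical(1))
  cp_dist <- changepointDistance(x, evidence$changepoints)
  sp <- evidence$splazers
  idx <- match(p$name, sp$name)
  split_t <- ifelse(!is.na(idx), sp$split_t[idx], p$split_t)
  split_n <- ifelse(!is.na(idx), sp$split_n[idx], p$split_n)
  split_ok <- !is.na(split_t) & !is.na(split_n) &
    split_t >= min_split & split_n == 0
  n_callers >= 2L | (single_ml & (cp_dist <= max_cp_dist | split_ok))
}

#' Annotate high-confidence flags on merged callsets
#'
#' Sets the `hc` flag from [hcSmall()]/[hcSv()]. HighConfidence is reported
#' as the intersection with AllSomatic downstream, so the flag itself is a
#' pure function of caller support and orthogonal evidence.
#' @param x a [SmallVariantSet-class] or [BreakendPairSet-class]
#' @param evidence a [supportEvidence()] bundle
#' @param ... passed to [hcSv()] (thresholds)
#' @return `x` with `hc` set
#' @export
annotateHighConfidence <- function(x, evidence = supportEvidence(), ...) {
  if (is(x, "SmallVariantSet")) {
    x@variants$hc <- hcSmall(x, evidence)
    validObject(x)
    return(x)
  }
  if (is(x, "BreakendPairSet")) {
    x@pairs$hc <- hcSv(x, evidence, ...)
    validObject(x)
    return(x)
  }
  stop("annotateHighConfidence expects a SmallVariantSet or BreakendPairSet")
}
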