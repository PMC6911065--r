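## Panel-of-Normals construction and application, plus the common-germline
## population-AF filter. Filters annotate with tags; nothing is deleted.

#' Build a small-variant panel of normals
#'
#' Sites (keyed by chrom and pos only — location-based, not allele-based)
#' observed in at least `min_individuals` distinct normal individuals are
#' retained. An individual contributes a site at most once even if several
#' alleles were called there.
#'
#' @param per_individual named list (individual -> [SmallVariantSet-class])
#' @param min_individuals minimum distinct individuals per site (default 2)
#' @return a [SmallPon-class]
#' @export
buildSmallPon <- function(per_individual, min_individuals = 2) {
  stopifnot(is.list(per_individual))
  sites <- lapply(per_individual, function(cs) {
    stopifnot(is(cs, "SmallVariantSet"))
    v <- cs@variants
    unique(paste(v$chrom, v$pos, sep = "\r"))
  })
  tab <- table(unlist(sites))
  keep <- names(tab)[tab >= min_individuals]
  if (!length(keep))
    return(new("SmallPon", sites = data.frame(
      chrom = character(), pos = integer(), n_individuals = integer(),
      stringsAsFactors = FALSE)))
  parts <- strsplit(keep, "\r", fixed = TRUE)
  df <- data.frame(
    chrom = vapply(parts, `[`, character(1), 1L),
    pos = as.integer(vapply(parts, `[`, character(1), 2L)),
    n_individuals = as.integer(tab[keep]),
    stringsAsFactors = FALSE)
  df <- df[order(df$chrom, df$pos), , drop = FALSE]
  rownames(df) <- NULL
  new("SmallPon", sites = df)
}

#' Apply a small-variant panel of normals
#'
#' Adds the "PON" filter tag to every variant whose (chrom, pos) is in the
#' panel, regardless of allele. Tag-only and idempotent; no records are
#' removed.
#' @param x a [SmallVariantSet-class]
#' @param pon a [SmallPon-class]
#' @return `x` with PON tags added
#' @export
applySmallPon <- function(x, pon) {
  stopifnot(is(x, "SmallVariantSet"), is(pon, "SmallPon"))
  v <- x@variants
  if (!nrow(v) || !nrow(pon@sites)) return(x)
  hit <- paste(v$chrom, v$pos) %in% paste(pon@sites$chrom, pon@sites$pos)
  v$filters <- .addTag(v$filters, which(hit), "PON")
  new("SmallVariantSet", variants = v)
}

#' Build a structural-variant panel of normals
#'
#' SURVIVOR-style clustering of normal-sample SV calls: events are merged
#' (connected components) when they are of the same type, have the same
#' strand orientation, and both corresponding breakends lie within
#' `max_distance` of each other. No minimum size is applied. Each cluster
#' records the number of distinct contributing individuals.
#'
#' @param per_individual named list (individual -> [BreakendPairSet-class])
#' @param max_distance maximum breakend distance in bp (default 300)
#' @return an [SvPon-class]
#' @export
buildSvPon <- function(per_individual, max_distance = 300) {
  stopifnot(is.list(per_individual))
  rows <- list()
  for (ind in names(per_individual)) {
    cs <- per_individual[[ind]]
    stopifnot(is(cs, "BreakendPairSet"))
    p <- cs@pairs
    if (!nrow(p)) next
    p$individual <- ind
    rows[[length(rows) + 1L]] <- p
  }
  if (!length(rows))
    return(new("SvPon", events = cbind(BreakendPairs()@pairs,
                                       n_individuals = integer())))
  pooled <- do.call(rbind, rows)
  ## same type + same strands + breakend midpoint distance <= max_distance
  ## at both ends; encoded as a match with slop = max_distance on point
  ## breakends and no reciprocal requirement
  n <- nrow(pooled)
  edges <- integer()
  bdist <- function(a, b, end) {
    s <- paste0("start", end); e <- paste0("end", end)
    pmax(a[[s]], b[[s]]) - pmin(a[[e]], b[[e]])  # gap; <= 0 when overlapping
  }
  for (i in seq_len(max(0L, n - 1L))) {
    a <- pooled[rep(i, n - i), , drop = FALSE]
    b <- pooled[(i + 1L):n, , drop = FALSE]
    ok <- a$svtype == b$svtype & a$strand1 == b$strand1 &
      a$strand2 == b$strand2 & a$chrom1 == b$chrom1 & a$chrom2 == b$chrom2 &
      bdist(a, b, 1L) <= max_distance & bdist(a, b, 2L) <= max_distance
    hit <- which(ok)
    if (length(hit)) edges <- c(edges, rbind(i, i + hit))
  }
  comp <- igraph::components(
    igraph::make_graph(edges, n = n, directed = FALSE))$membership
  merged <- lapply(split(seq_len(n), comp), function(idx) {
    g <- pooled[idx, , drop = FALSE]
    out <- g[1L, , drop = FALSE]
    out$n_individuals <- length(unique(g$individual))
    out$individual <- NULL
    out
  })
  ev <- do.call(rbind, merged)
  ev <- ev[order(ev$chrom1, ev$start1), , drop = FALSE]
  ev$name <- sprintf("pon%04d", seq_len(nrow(ev)))
  rownames(ev) <- NULL
  new("SvPon", events = ev)
}

#' Apply a structural-variant panel of normals
#'
#' Tags with "PON" every SV that matches ([svMatch()] with the given slop
#' and reciprocal overlap) a panel event observed in at least
#' `min_individuals` individuals. Tag-only and idempotent.
#' @param x a [BreakendPairSet-class]
#' @param pon an [SvPon-class]
#' @param min_individuals minimum panel individual count (default 2)
#' @param slop,reciprocal matching parameters (defaults 300 bp, 0.5)
#' @return `x` with PON tags added
#' @export
applySvPon <- function(x, pon, min_individuals = 2, slop = 300,
                       reciprocal = 0.5) {
  stopifnot(is(x, "BreakendPairSet"), is(pon, "SvPon"))
  p <- x@pairs
  ev <- pon@events
  ev <- ev[ev$n_individuals >= min_individuals, , drop = FALSE]
  if (!nrow(p) || !nrow(ev)) return(x)
  hit <- vapply(seq_len(nrow(p)), function(i)
    any(.svMatchVec(p[rep(i, nrow(ev)), , drop = FALSE], ev,
                    slop, reciprocal)), logical(1))
  p$filters <- .addTag(p$filters, which(hit), "PON")
  new("BreakendPairSet", pairs = p)
}

#' Common-germline filtering by population allele frequency
#'
#' Small variants are tagged "COMMON_GERMLINE" when any annotated population
#' minor-allele frequency is at or above `threshold` (1% by default, in
#' either 1000 Genomes or gnomAD-style databases — any database present in
#' the `pop_af` annotation counts). SVs are tagged when they match an event
#' of a supplied germline SV catalog under the [svMatch()] criteria. CNV
#' segments are never filtered (annotation-only by design); pass them
#' through unchanged.
#'
#' @param x a [SmallVariantSet-class] or [BreakendPairSet-class]
#' @param threshold MAF threshold, inclusive (default 0.01)
#' @param catalog for SVs: a [BreakendPairSet-class] of known germline
#'   events
#' @param slop,reciprocal SV matching parameters
#' @return `x` with COMMON_GERMLINE tags added
#' @export
germlineAfFilter <- function(x, threshold = 0.01, catalog = NULL,
                             slop = 300, reciprocal = 0.5) {
  if (is(x, "SmallVariantSet")) {
    v <- x@variants
    if (!nrow(v)) return(x)
    hit <- vapply(v$pop_af, function(af)
      length(af) > 0 && any(af >= threshold), logical(1))
    v$filters <- .addTag(v$filters, which(hit), "COMMON_GERMLINE")
    return(new("SmallVariantSet", variants = v))
  }
  if (is(x, "BreakendPairSet")) {
    if (is.null(catalog) || nRecords(catalog) == 0L || nRecords(x) == 0L)
      return(x)
    stopifnot(is(catalog, "BreakendPairSet"))
    p <- x@pairs
    cat_p <- catalog@pairs
    hit <- vapply(seq_len(nrow(p)), function(i)
      any(.svMatchVec(p[rep(i, nrow(cat_p)), , drop = FALSE], cat_p,
                      slop, reciprocal)), logical(1))
    p$filters <- .addTag(p$filters, which(hit), "COMMON_GERMLINE")
    return(new("BreakendPairSet", pairs = p))
  }
  stop("germlineAfFilter expects a SmallVariantSet or BreakendPairSet")
}
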