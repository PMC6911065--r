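## SV size filtering and cross-caller BEDPE merging: pairtopair-style
## matching (slop, same strand orientation, reciprocal span overlap) and
## connected-component clustering of the pooled events.

#' Event span of a breakend pair
#'
#' Intrachromosomal events: `end2 - start1` using the outer bounds of the
#' two breakend confidence intervals. Undefined (NA) for translocations and
#' insertions, where a linear span has no meaning.
#' @param x a [BreakendPairSet-class]
#' @return numeric vector of spans (NA where undefined)
#' @export
svSpan <- function(x) {
  stopifnot(is(x, "BreakendPairSet"))
  p <- x@pairs
  span <- as.numeric(p$end2 - p$start1)
  span[p$chrom1 != p$chrom2 | p$svtype %in% c("TRA", "INS")] <- NA_real_
  span
}

#' Remove SVs below a minimum span
#'
#' Intrachromosomal events with span strictly below `min_size` are removed;
#' events with undefined span (translocations, insertions) are retained.
#' @param x a [BreakendPairSet-class]
#' @param min_size minimum span in bp (default 500)
#' @return filtered [BreakendPairSet-class]
#' @export
filterMinSize <- function(x, min_size = 500) {
  stopifnot(is(x, "BreakendPairSet"))
  span <- svSpan(x)
  .subsetPairs(x, which(is.na(span) | span >= min_size))
}

## vectorised match of one event (row a) against many (rows b)
.svMatchVec <- function(a, b, slop, reciprocal) {
  ok <- a$svtype == b$svtype &
    a$strand1 == b$strand1 & a$strand2 == b$strand2 &
    a$chrom1 == b$chrom1 & a$chrom2 == b$chrom2
  ## breakend intervals, each padded by slop, must overlap at both ends
  ov <- function(s1, e1, s2, e2)
    pmax(s1 - slop, s2 - slop) < pmin(e1 + slop, e2 + slop)
  ok <- ok & ov(a$start1, a$end1, b$start1, b$end1) &
    ov(a$start2, a$end2, b$start2, b$end2)
  ## reciprocal span overlap, waived when either span is undefined
  defined <- !(a$chrom1 != a$chrom2 | a$svtype %in% c("TRA", "INS")) &
    !(b$chrom1 != b$chrom2 | b$svtype %in% c("TRA", "INS"))
  spanA <- a$end2 - a$start1
  spanB <- b$end2 - b$start1
  inter <- pmin(a$end2, b$end2) - pmax(a$start1, b$start1)
  recip <- inter >= reciprocal * spanA & inter >= reciprocal * spanB
  ok & (!defined | recip)
}

#' Do two SV events match?
#'
#' True when the events (i) are of the same svtype, (ii) have matching
#' strand orientation at both breakends, (iii) have their breakend
#' confidence intervals, each padded by `slop`, overlapping at both ends on
#' the same chromosomes, and (iv) for events with defined spans, overlap by
#' at least the `reciprocal` fraction of both spans. The reciprocal
#' condition is waived when either span is undefined (TRA/INS). Symmetric
#' in its arguments.
#'
#' @param a,b single-event [BreakendPairSet-class] objects (or sets; `a` is
#'   compared pairwise against rows of `b`, recycling row 1 of `a`)
#' @param slop breakend padding in bp (default 300)
#' @param reciprocal reciprocal span-overlap fraction (default 0.5)
#' @return logical vector
#' @export
svMatch <- function(a, b, slop = 300, reciprocal = 0.5) {
  stopifnot(is(a, "BreakendPairSet"), is(b, "BreakendPairSet"))
  pa <- a@pairs
  pb <- b@pairs
  if (!nrow(pa) || !nrow(pb)) return(logical(0))
  if (nrow(pa) == 1L && nrow(pb) > 1L)
    pa <- pa[rep(1L, nrow(pb)), , drop = FALSE]
  .svMatchVec(pa, pb, slop, reciprocal)
}

## pairwise match graph -> component membership (integer labels)
.svComponents <- function(p, slop, reciprocal) {
  n <- nrow(p)
  if (n == 0L) return(integer())
  edges <- integer()
  for (i in seq_len(n - 1L)) {
    a <- p[rep(i, n - i), , drop = FALSE]
    b <- p[(i + 1L):n, , drop = FALSE]
    hit <- which(.svMatchVec(a, b, slop, reciprocal))
    if (length(hit)) edges <- c(edges, rbind(i, i + hit))
  }
  g <- igraph::make_graph(edges, n = n, directed = FALSE)
  igraph::components(g)$membership
}

#' Merge per-caller SV callsets
#'
#' Pools the (already size-filtered) callsets, links events that satisfy
#' [svMatch()], and collapses every connected component of the match graph
#' into one record. Caller support is the union over the component;
#' representative coordinates come from the highest-priority caller present
#' (manta > lumpy > svaba); split-read support is the per-sample maximum
#' over the component.
#'
#' @param callsets named list (caller -> [BreakendPairSet-class])
#' @param slop,reciprocal matching parameters passed to [svMatch()]
#' @return merged [BreakendPairSet-class]
#' @export
mergeSvCallsets <- function(callsets, slop = 300, reciprocal = 0.5) {
  stopifnot(is.list(callsets))
  rows <- list()
  nms <- names(callsets) %||% rep("", length(callsets))
  for (k in seq_along(callsets)) {
    cs <- callsets[[k]]
    stopifnot(is(cs, "BreakendPairSet"))
    p <- cs@pairs
    if (!nrow(p)) next
    empty <- !vapply(p$callers, length, integer(1))
    if (any(empty) && nzchar(nms[k])) p$callers[empty] <- list(nms[k])
    rows[[length(rows) + 1L]] <- p
  }
  if (!length(rows)) return(BreakendPairs())
  pooled <- do.call(rbind, rows)
  comp <- .svComponents(pooled, slop, reciprocal)
  merged <- lapply(split(seq_len(nrow(pooled)), comp), function(idx) {
    g <- pooled[idx, , drop = FALSE]
    support <- orderCallers(unique(unlist(g$callers)), "sv")
    ## representative record: first caller in priority order, then leftmost
    prio <- vapply(g$callers, function(cl)
      min(match(cl, SV_CALLERS)), numeric(1))
    rep_i <- order(prio, g$chrom1, g$start1)[1L]
    out <- g[rep_i, , drop = FALSE]
    out$callers[[1]] <- support
    out$filters[[1]] <- sort(unique(unlist(g$filters)))
    out$hc <- any(g$hc)
    mx <- function(x) if (all(is.na(x))) NA_real_ else max(x, na.rm = TRUE)
    out$split_t <- mx(g$split_t)
    out$split_n <- mx(g$split_n)
    out
  })
  res <- do.call(rbind, merged)
  res <- res[order(res$chrom1, res$start1, res$chrom2, res$start2), ,
             drop = FALSE]
  res$name <- sprintf("sv%04d", seq_len(nrow(res)))
  rownames(res) <- NULL
  new("BreakendPairSet", pairs = res)
}
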