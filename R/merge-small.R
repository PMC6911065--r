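## Cross-caller consensus for SNVs/MNVs/indels. MNVs are decomposed to SNVs
## before merging (some callers phase adjacent substitutions, others do not)
## and re-constituted afterwards when every constituent SNV ends up with the
## same caller support.

.mnvId <- function(chrom, pos, ref, alt) {
  paste0(chrom, ":", pos, ":", ref, ">", alt)
}

## constituent SNVs of an MNV: positions where ref and alt bases differ
.mnvConstituents <- function(chrom, pos, ref, alt) {
  rb <- strsplit(ref, "")[[1]]
  ab <- strsplit(alt, "")[[1]]
  i <- which(rb != ab)
  data.frame(chrom = chrom, pos = pos + i - 1L, ref = rb[i], alt = ab[i],
             stringsAsFactors = FALSE)
}

.emptyOrigins <- function() {
  data.frame(mnv_id = character(), caller = character(),
             chrom = character(), pos = integer(), ref = character(),
             alt = character(), t_ref = numeric(), t_alt = numeric(),
             t_depth = numeric(), n_ref = numeric(), n_alt = numeric(),
             n_depth = numeric(), stringsAsFactors = FALSE)
}

#' Decompose MNVs into their constituent SNVs
#'
#' Every MNV record is replaced by one SNV per position at which the ref and
#' alt bases differ (positions ascending; unchanged middle bases are emitted
#' nowhere). Each derived SNV carries an `mnv_id` linking it to its origin,
#' and an origin table records the original MNV alleles per caller so the
#' merge stage can later re-constitute them. Non-MNV records pass through
#' unchanged.
#'
#' @param x a [SmallVariantSet-class]
#' @return list with elements `variants` (SmallVariantSet, MNV-free) and
#'   `origins` (data.frame of original MNV calls)
#' @export
decomposeMnvs <- function(x) {
  stopifnot(is(x, "SmallVariantSet"))
  v <- x@variants
  is_mnv <- v$vtype == "MNV"
  if (!any(is_mnv))
    return(list(variants = x, origins = .emptyOrigins()))
  keep <- v[!is_mnv, , drop = FALSE]
  pieces <- list(keep)
  origins <- list(.emptyOrigins())
  for (i in which(is_mnv)) {
    row <- v[i, , drop = FALSE]
    cons <- .mnvConstituents(row$chrom, row$pos, row$ref, row$alt)
    id <- .mnvId(row$chrom, row$pos, row$ref, row$alt)
    snvs <- row[rep(1L, nrow(cons)), , drop = FALSE]
    snvs$pos <- cons$pos
    snvs$ref <- cons$ref
    snvs$alt <- cons$alt
    snvs$vtype <- "SNV"
    snvs$mnv_id <- id
    pieces[[length(pieces) + 1L]] <- snvs
    callers <- row$callers[[1]]
    if (!length(callers)) callers <- NA_character_
    origins[[length(origins) + 1L]] <- data.frame(
      mnv_id = id, caller = callers, chrom = row$chrom, pos = row$pos,
      ref = row$ref, alt = row$alt,
      t_ref = row$t_ref, t_alt = row$t_alt, t_depth = row$t_depth,
      n_ref = row$n_ref, n_alt = row$n_alt, n_depth = row$n_depth,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  list(variants = new("SmallVariantSet", variants = out),
       origins = do.call(rbind, origins))
}

## union of named numeric vectors (later entries do not override earlier)
.mergeAf <- function(afs) {
  out <- stats::setNames(numeric(), character())
  for (af in afs) {
    if (length(af)) out[setdiff(names(af), names(out))] <-
        af[setdiff(names(af), names(out))]
  }
  out
}

## per-caller reported counts of a single ingested record
.callerCountsRow <- function(row) {
  callers <- row$callers[[1]]
  existing <- row$caller_counts[[1]]
  if (!is.null(existing)) return(existing)
  if (!length(callers)) return(NULL)
  data.frame(caller = callers, t_ref = row$t_ref, t_alt = row$t_alt,
             t_depth = row$t_depth, n_ref = row$n_ref, n_alt = row$n_alt,
             n_depth = row$n_depth, stringsAsFactors = FALSE)
}

#' Merge per-caller small-variant callsets
#'
#' Pools the callsets and collapses records sharing the identity key
#' (chrom, pos, ref, alt) into a single record whose caller support is the
#' union of the inputs' support. The counts each caller reported are
#' retained per caller (in the `caller_counts` list-column) for the later
#' final-count selection. MNVs must already be decomposed; variants are
#' assumed normalized (see [normalizeAlleles()]). Output is coordinate
#' sorted. The operation is idempotent and independent of the order of the
#' caller map.
#'
#' @param callsets named list (caller -> [SmallVariantSet-class]); records
#'   with empty caller support inherit their list name
#' @return a merged [SmallVariantSet-class]
#' @export
mergeSmallCallsets <- function(callsets) {
  stopifnot(is.list(callsets))
  rows <- list()
  nms <- names(callsets) %||% rep("", length(callsets))
  for (k in seq_along(callsets)) {
    nm <- nms[k]
    cs <- callsets[[k]]
    stopifnot(is(cs, "SmallVariantSet"))
    v <- cs@variants
    if (!nrow(v)) next
    empty <- !vapply(v$callers, length, integer(1))
    if (any(empty) && nzchar(nm)) v$callers[empty] <- list(nm)
    rows[[length(rows) + 1L]] <- v
  }
  if (!length(rows)) return(SmallVariants())
  pooled <- do.call(rbind, rows)
  key <- variantKey(pooled$chrom, pooled$pos, pooled$ref, pooled$alt)
  groups <- split(seq_len(nrow(pooled)), key)
  merged <- lapply(groups, function(idx) {
    g <- pooled[idx, , drop = FALSE]
    out <- g[1L, , drop = FALSE]
    out$callers[[1]] <- orderCallers(unique(unlist(g$callers)), "small")
    ids <- g$mnv_id[!is.na(g$mnv_id)]
    out$mnv_id <- if (length(ids)) ids[[1]] else NA_character_
    out$filters[[1]] <- sort(unique(unlist(g$filters)))
    out$hc <- any(g$hc)
    cc <- do.call(rbind, Filter(Negate(is.null),
                                lapply(seq_len(nrow(g)), function(j)
                                  .callerCountsRow(g[j, , drop = FALSE]))))
    if (!is.null(cc)) cc <- cc[!duplicated(cc$caller), , drop = FALSE]
    out$caller_counts[[1]] <- cc
    out$pop_af[[1]] <- .mergeAf(g$pop_af)
    ## final counts are selected downstream; drop per-caller values here
    out[, c("t_ref", "t_alt", "t_depth", "t_vaf")] <- NA_real_
    out[, c("n_ref", "n_alt", "n_depth", "n_vaf")] <- NA_real_
    out$t_source <- NA_character_
    out$n_source <- NA_character_
    out
  })
  res <- do.call(rbind, merged)
  res <- res[order(res$chrom, res$pos, res$ref, res$alt), , drop = FALSE]
  rownames(res) <- NULL
  new("SmallVariantSet", variants = res)
}

#' Re-constitute MNVs from merged SNVs
#'
#' For each origin MNV (attempted longest first), if every constituent SNV
#' is present in the merged set, not yet consumed by another origin, and
#' all constituents share an identical caller-support set, the SNVs are
#' replaced by a single MNV record with that common support. Otherwise the
#' constituents remain individual SNVs. Each SNV is consumed at most once.
#'
#' @param merged output of [mergeSmallCallsets()]
#' @param origins origin table from [decomposeMnvs()] (tables from several
#'   callers may be rbind-ed)
#' @return a [SmallVariantSet-class]
#' @export
reconstituteMnvs <- function(merged, origins) {
  stopifnot(is(merged, "SmallVariantSet"))
  v <- merged@variants
  if (is.null(origins) || !nrow(origins) || !nrow(v)) return(merged)
  uniq <- origins[!duplicated(origins$mnv_id), , drop = FALSE]
  uniq <- uniq[order(-nchar(uniq$ref), uniq$chrom, uniq$pos), , drop = FALSE]
  keys <- variantKey(v$chrom, v$pos, v$ref, v$alt)
  consumed <- rep(FALSE, nrow(v))
  new_rows <- list()
  for (i in seq_len(nrow(uniq))) {
    o <- uniq[i, , drop = FALSE]
    cons <- .mnvConstituents(o$chrom, o$pos, o$ref, o$alt)
    ckeys <- variantKey(cons$chrom, cons$pos, cons$ref, cons$alt)
    idx <- match(ckeys, keys)
    if (anyNA(idx) || any(consumed[idx])) next
    supports <- v$callers[idx]
    first <- supports[[1]]
    same <- all(vapply(supports, function(s)
      length(s) == length(first) && all(s == first), logical(1)))
    if (!same) next
    consumed[idx] <- TRUE
    mnv <- v[idx[1L], , drop = FALSE]
    mnv$pos <- o$pos
    mnv$ref <- o$ref
    mnv$alt <- o$alt
    mnv$vtype <- "MNV"
    mnv$mnv_id <- o$mnv_id
    mnv$callers[[1]] <- first
    mnv$filters[[1]] <- sort(unique(unlist(v$filters[idx])))
    mnv$hc <- any(v$hc[idx])
    ## per-caller counts of the original MNV calls, where recorded
    orows <- origins[origins$mnv_id == o$mnv_id & !is.na(origins$caller), ,
                     drop = FALSE]
    mnv$caller_counts[[1]] <- if (nrow(orows)) {
      cc <- data.frame(caller = orows$caller, t_ref = orows$t_ref,
                       t_alt = orows$t_alt, t_depth = orows$t_depth,
                       n_ref = orows$n_ref, n_alt = orows$n_alt,
                       n_depth = orows$n_depth, stringsAsFactors = FALSE)
      cc[!duplicated(cc$caller), , drop = FALSE]
    } else NULL
    mnv$pop_af[[1]] <- .mergeAf(v$pop_af[idx])
    new_rows[[length(new_rows) + 1L]] <- mnv
  }
  keep <- v[!consumed, , drop = FALSE]
  ## SNVs that did not re-constitute drop their origin link
  keep$mnv_id[keep$vtype == "SNV"] <- NA_character_
  out <- rbind(keep, do.call(rbind, new_rows))
  out <- out[order(out$chrom, out$pos, out$ref, out$alt), , drop = FALSE]
  rownames(out) <- NULL
  new("SmallVariantSet", variants = out)
}
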