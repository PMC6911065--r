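## Readers and writers for the formats the pipeline touches. Small variants
## use VCF (1-based); SVs use BEDPE and CNV segments a TSV, both 0-based
## half-open. VCF parsing goes through vcfR; the package's own merged-VCF
## dialect carries CALLERS/HC/VT/MNVID/PAF INFO keys and ADR:ADA:DP:VF:CSRC
## per-sample fields so that a write -> read round trip preserves every
## typed field.

.fmtNum <- function(x) ifelse(is.na(x), ".", format(x, digits = 15,
                                                    scientific = FALSE,
                                                    trim = TRUE))
.parseNum <- function(x) suppressWarnings(
  ifelse(x %in% c(".", "", "NA"), NA_real_, as.numeric(x)))

#' Trim and left-align variant alleles
#'
#' Parsimony trimming removes the shared allele suffix, then the shared
#' prefix (advancing `pos`), so that identical variants written with
#' different anchors share one representation. When a reference is
#' supplied, simple indels are additionally left-aligned by shifting
#' through repeat sequence. Cross-caller merging relies on this
#' normalization: identical indels from different callers otherwise fail
#' to share a key.
#'
#' @param chrom,pos,ref,alt parallel vectors (pos 1-based)
#' @param reference optional named character / DNAStringSet of contig
#'   sequences for left alignment
#' @return data.frame(chrom, pos, ref, alt)
#' @export
normalizeAlleles <- function(chrom, pos, ref, alt, reference = NULL) {
  if (is(reference, "DNAStringSet")) {
    nm <- names(reference)
    reference <- stats::setNames(as.character(reference), nm)
  }
  pos <- as.integer(pos)
  n <- length(pos)
  for (i in seq_len(n)) {
    r <- ref[i]; a <- alt[i]; p <- pos[i]
    ## trim shared suffix
    while (nchar(r) > 1L && nchar(a) > 1L &&
           substr(r, nchar(r), nchar(r)) == substr(a, nchar(a), nchar(a))) {
      r <- substr(r, 1L, nchar(r) - 1L)
      a <- substr(a, 1L, nchar(a) - 1L)
    }
    ## trim shared prefix
    while (nchar(r) > 1L && nchar(a) > 1L &&
           substr(r, 1L, 1L) == substr(a, 1L, 1L)) {
      r <- substr(r, 2L, nchar(r))
      a <- substr(a, 2L, nchar(a))
      p <- p + 1L
    }
    ## left-align simple indels through repeats
    if (!is.null(reference) && xor(nchar(r) == 1L, nchar(a) == 1L) &&
        substr(r, 1L, 1L) == substr(a, 1L, 1L)) {
      rc <- reference[[chrom[i]]]
      ## vt-style left shift: while the alleles end in the same base,
      ## drop it; when one allele empties, pull in the reference base to
      ## the left and continue
      while (p > 1L) {
        lr <- substr(r, nchar(r), nchar(r))
        la <- substr(a, nchar(a), nchar(a))
        if (lr != la) break
        r <- substr(r, 1L, nchar(r) - 1L)
        a <- substr(a, 1L, nchar(a) - 1L)
        if (!nchar(r) || !nchar(a)) {
          prev <- substr(rc, p - 1L, p - 1L)
          r <- paste0(prev, r)
          a <- paste0(prev, a)
          p <- p - 1L
        }
      }
    }
    ref[i] <- r; alt[i] <- a; pos[i] <- p
  }
  data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
             stringsAsFactors = FALSE)
}

## pull one key out of a vector of VCF INFO strings
.infoField <- function(info, key) {
  m <- regmatches(info, regexpr(paste0("(?:^|;)", key, "=([^;]*)"), info))
  out <- rep(NA_character_, length(info))
  hit <- grepl(paste0("(?:^|;)", key, "="), info)
  out[hit] <- sub(paste0("^.*(?:^|;)", key, "=([^;]*).*$"), "\\1", info[hit])
  out
}

.gtField <- function(gt_col, format, key) {
  keys <- strsplit(format, ":")
  vals <- strsplit(gt_col, ":")
  vapply(seq_along(gt_col), function(i) {
    j <- match(key, keys[[i]])
    if (is.na(j) || j > length(vals[[i]])) NA_character_ else vals[[i]][j]
  }, character(1))
}

#' Read a per-caller small-variant VCF
#'
#' One [SmallVariantSet-class] record per (by default) PASS record and alt
#' allele; multi-allelic records are split, alleles are parsimony-trimmed
#' (and left-aligned when a reference is given), and caller support is set
#' to `caller`. Tumor/normal counts are taken from AD (ref,alt) and DP of
#' the TUMOR/NORMAL sample columns when present (first and second sample
#' columns otherwise).
#'
#' @param path VCF file (v4.x, plain or bgzipped)
#' @param caller one of strelka2, mutect2, lancet, svaba
#' @param pass_only keep only PASS/unfiltered records (default TRUE)
#' @param reference optional contig sequences for indel left alignment
#' @return a [SmallVariantSet-class]
#' @export
readCallerVcf <- function(path, caller, pass_only = TRUE,
                          reference = NULL) {
  orderCallers(caller, "small")  # validates the name
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(fix) || nrow(fix) == 0L) return(SmallVariants())
  fix <- as.data.frame(fix, stringsAsFactors = FALSE)
  gt <- vcf@gt
  if (pass_only) {
    keep <- fix$FILTER %in% c("PASS", ".", NA)
    fix <- fix[keep, , drop = FALSE]
    gt <- if (!is.null(gt) && nrow(gt)) gt[keep, , drop = FALSE] else gt
  }
  if (!nrow(fix)) return(SmallVariants())
  samples <- if (!is.null(gt) && ncol(gt) > 1L) colnames(gt)[-1L]
             else character()
  pick <- function(want, fallback) {
    j <- match(want, toupper(samples))
    if (!is.na(j)) j else fallback
  }
  t_j <- pick("TUMOR", 1L)
  n_j <- pick("NORMAL", 2L)
  rows <- list()
  for (i in seq_len(nrow(fix))) {
    alts <- strsplit(fix$ALT[i], ",", fixed = TRUE)[[1]]
    for (ai in seq_along(alts)) {
      cnt <- list(t_ref = NA_real_, t_alt = NA_real_, t_depth = NA_real_,
                  n_ref = NA_real_, n_alt = NA_real_, n_depth = NA_real_)
      if (length(samples) >= 2L) {
        fmt <- gt[i, 1L]
        getc <- function(j) {
          col <- gt[i, j + 1L]
          ad <- .gtField(col, fmt, "AD")
          dp <- .parseNum(.gtField(col, fmt, "DP"))
          if (!is.na(ad)) {
            parts <- .parseNum(strsplit(ad, ",")[[1]])
            list(ref = parts[1L],
                 alt = if (length(parts) > ai) parts[ai + 1L] else NA_real_,
                 dp = dp)
          } else list(ref = NA_real_, alt = NA_real_, dp = dp)
        }
        tc <- getc(t_j); nc <- getc(n_j)
        cnt <- list(t_ref = tc$ref, t_alt = tc$alt, t_depth = tc$dp,
                    n_ref = nc$ref, n_alt = nc$alt, n_depth = nc$dp)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = fix$CHROM[i], pos = as.integer(fix$POS[i]),
        ref = fix$REF[i], alt = alts[ai],
        t_ref = cnt$t_ref, t_alt = cnt$t_alt, t_depth = cnt$t_depth,
        n_ref = cnt$n_ref, n_alt = cnt$n_alt, n_depth = cnt$n_depth,
        stringsAsFactors = FALSE)
    }
  }
  d <- do.call(rbind, rows)
  norm <- normalizeAlleles(d$chrom, d$pos, d$ref, d$alt, reference)
  csrc <- if (toupper(caller) %in% COUNT_SOURCES) toupper(caller)
          else NA_character_
  SmallVariants(
    chrom = norm$chrom, pos = norm$pos, ref = norm$ref, alt = norm$alt,
    callers = caller,
    t_ref = d$t_ref, t_alt = d$t_alt, t_depth = d$t_depth,
    t_vaf = vafFrom(d$t_ref, d$t_alt),
    t_source = ifelse(is.na(d$t_alt), NA_character_, csrc),
    n_ref = d$n_ref, n_alt = d$n_alt, n_depth = d$n_depth,
    n_vaf = vafFrom(d$n_ref, d$n_alt),
    n_source = ifelse(is.na(d$n_alt), NA_character_, csrc))
}

## BND bracket orientation -> (strand1, strand2), per the VCF spec
.bndStrands <- function(alt) {
  if (grepl("^[ACGTN]+\\[", alt)) c("+", "-")
  else if (grepl("^[ACGTN]+\\]", alt)) c("+", "+")
  else if (grepl("^\\]", alt)) c("-", "+")
  else if (grepl("^\\[", alt)) c("-", "-")
  else stop("unrecognised BND ALT: ", alt)
}

.bndMate <- function(alt) {
  m <- regmatches(alt, regexpr("[\\[\\]]([^\\[\\]:]+):([0-9]+)[\\[\\]]",
                               alt, perl = TRUE))
  if (!length(m)) stop("unrecognised BND ALT: ", alt)
  core <- gsub("[][]", "", m)
  parts <- strsplit(core, ":")[[1]]
  list(chrom = parts[1L], pos = as.integer(parts[2L]))
}

#' Read a structural-variant VCF as breakend pairs
#'
#' Symbolic records (SVTYPE with END) become one event each; BND mate
#' records are paired by ID/MATEID and emitted once, with strands derived
#' from the bracket orientation and svtype TRA when the mates lie on
#' different chromosomes (DEL/DUP/INV by strand pattern otherwise).
#' Breakend confidence intervals come from CIPOS/CIEND when present, else
#' single-base intervals. Unpaired BND mates are dropped with a warning.
#'
#' @param path VCF file
#' @param caller one of manta, lumpy, svaba
#' @param pass_only keep only PASS/unfiltered records (default TRUE)
#' @return a [BreakendPairSet-class]
#' @export
readSvVcf <- function(path, caller, pass_only = TRUE) {
  orderCallers(caller, "sv")
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf, getINFO = TRUE)
  if (is.null(fix) || nrow(fix) == 0L) return(BreakendPairs())
  fix <- as.data.frame(fix, stringsAsFactors = FALSE)
  if (pass_only)
    fix <- fix[fix$FILTER %in% c("PASS", ".", NA), , drop = FALSE]
  if (!nrow(fix)) return(BreakendPairs())
  svtype <- .infoField(fix$INFO, "SVTYPE")
  ci <- function(which_, i) {
    raw <- .infoField(fix$INFO[i], which_)
    if (is.na(raw)) c(0L, 0L)
    else as.integer(strsplit(raw, ",")[[1L]])
  }
  out <- list()
  is_bnd <- !is.na(svtype) & svtype == "BND"
  ## symbolic (non-BND) records
  strands_of <- list(DEL = c("+", "-"), DUP = c("-", "+"),
                     INV = c("+", "+"), INS = c("+", "-"))
  for (i in which(!is_bnd)) {
    st <- svtype[i]
    if (is.na(st)) next
    pos <- as.integer(fix$POS[i])
    end <- as.integer(.infoField(fix$INFO[i], "END"))
    if (is.na(end)) end <- pos
    cp <- ci("CIPOS", i); ce <- ci("CIEND", i)
    strands <- strands_of[[st]] %||% c("+", "-")
    out[[length(out) + 1L]] <- data.frame(
      chrom1 = fix$CHROM[i], start1 = pos - 1L + cp[1L],
      end1 = pos + cp[2L],
      chrom2 = fix$CHROM[i], start2 = end - 1L + ce[1L],
      end2 = end + ce[2L],
      strand1 = strands[1L], strand2 = strands[2L], svtype = st,
      name = fix$ID[i], stringsAsFactors = FALSE)
  }
  ## BND mate pairing
  bnd <- fix[is_bnd, , drop = FALSE]
  if (nrow(bnd)) {
    mate_of <- .infoField(bnd$INFO, "MATEID")
    seen <- character()
    dropped <- 0L
    for (i in seq_len(nrow(bnd))) {
      id <- bnd$ID[i]
      if (id %in% seen) next
      j <- match(mate_of[i], bnd$ID)
      if (is.na(j)) {
        ## fall back: locate the mate record at the ALT's coordinates
        mt <- tryCatch(.bndMate(bnd$ALT[i]), error = function(e) NULL)
        if (!is.null(mt))
          j <- which(bnd$CHROM == mt$chrom &
                       as.integer(bnd$POS) == mt$pos & bnd$ID != id)[1L]
      }
      if (is.na(j)) { dropped <- dropped + 1L; next }
      seen <- c(seen, id, bnd$ID[j])
      s1 <- .bndStrands(bnd$ALT[i])
      pos1 <- as.integer(bnd$POS[i])
      pos2 <- as.integer(bnd$POS[j])
      ch1 <- bnd$CHROM[i]; ch2 <- bnd$CHROM[j]
      st <- if (ch1 != ch2) "TRA"
      else switch(paste0(s1[1L], s1[2L]),
                  "+-" = "DEL", "-+" = "DUP", "DEL")
      if (ch1 == ch2 && s1[1L] == s1[2L]) st <- "INV"
      cp <- ci("CIPOS", which(is_bnd)[i])
      out[[length(out) + 1L]] <- data.frame(
        chrom1 = ch1, start1 = pos1 - 1L + cp[1L], end1 = pos1 + cp[2L],
        chrom2 = ch2, start2 = pos2 - 1L, end2 = pos2,
        strand1 = s1[1L], strand2 = s1[2L], svtype = st,
        name = sub("_[12]$", "", id), stringsAsFactors = FALSE)
    }
    if (dropped > 0L)
      warning(dropped, " unpaired BND record(s) dropped")
  }
  if (!length(out)) return(BreakendPairs())
  d <- do.call(rbind, out)
  BreakendPairs(chrom1 = d$chrom1, start1 = d$start1, end1 = d$end1,
                chrom2 = d$chrom2, start2 = d$start2, end2 = d$end2,
                strand1 = d$strand1, strand2 = d$strand2,
                svtype = d$svtype, name = d$name, callers = caller)
}

## ---------------------------------------------------------------------------
## Merged-output writers/readers
## ---------------------------------------------------------------------------

.encodeAf <- function(af) {
  if (!length(af)) return(".")
  paste(paste0(names(af), ":", .fmtNum(af)), collapse = ",")
}
.decodeAf <- function(s) {
  if (is.na(s) || s == ".") return(stats::setNames(numeric(), character()))
  parts <- strsplit(strsplit(s, ",")[[1]], ":")
  stats::setNames(vapply(parts, function(x) as.numeric(x[2]), numeric(1)),
                  vapply(parts, `[`, character(1), 1))
}

#' Write a merged small-variant callset as VCF
#'
#' INFO carries CALLERS (comma list), HC (0/1), VT, MNVID and PAF
#' (db:af,...); FILTER carries the tags (PASS when none); TUMOR/NORMAL
#' sample columns carry ADR:ADA:DP:VF:CSRC. [readSomaticVcf()] inverts the
#' encoding field-for-field.
#' @param x a [SmallVariantSet-class]
#' @param path output file
#' @return `path`, invisibly
#' @export
writeSomaticVcf <- function(x, path) {
  stopifnot(is(x, "SmallVariantSet"))
  v <- x@variants
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=CALLERS,Number=.,Type=String,Description=\"Supporting callers\">",
    "##INFO=<ID=HC,Number=1,Type=Integer,Description=\"High confidence flag\">",
    "##INFO=<ID=VT,Number=1,Type=String,Description=\"Variant type\">",
    "##INFO=<ID=MNVID,Number=1,Type=String,Description=\"MNV origin id\">",
    "##INFO=<ID=PAF,Number=.,Type=String,Description=\"Population AFs db:af\">",
    "##FORMAT=<ID=ADR,Number=1,Type=Float,Description=\"Ref fragment count\">",
    "##FORMAT=<ID=ADA,Number=1,Type=Float,Description=\"Alt fragment count\">",
    "##FORMAT=<ID=DP,Number=1,Type=Float,Description=\"Fragment depth\">",
    "##FORMAT=<ID=VF,Number=1,Type=Float,Description=\"Variant allele frequency\">",
    "##FORMAT=<ID=CSRC,Number=1,Type=String,Description=\"Count source\">",
    paste0("#", paste(c("CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                        "FILTER", "INFO", "FORMAT", "TUMOR", "NORMAL"),
                      collapse = "\t")))
  body <- vapply(seq_len(nrow(v)), function(i) {
    filt <- v$filters[[i]]
    info <- paste0(
      "CALLERS=", if (length(v$callers[[i]]))
        paste(v$callers[[i]], collapse = ",") else ".",
      ";HC=", as.integer(v$hc[i]),
      ";VT=", v$vtype[i],
      ";MNVID=", ifelse(is.na(v$mnv_id[i]), ".", v$mnv_id[i]),
      ";PAF=", .encodeAf(v$pop_af[[i]]))
    samp <- function(pre) paste(
      .fmtNum(v[[paste0(pre, "_ref")]][i]),
      .fmtNum(v[[paste0(pre, "_alt")]][i]),
      .fmtNum(v[[paste0(pre, "_depth")]][i]),
      .fmtNum(v[[paste0(pre, "_vaf")]][i]),
      ifelse(is.na(v[[paste0(pre, "_source")]][i]), ".",
             v[[paste0(pre, "_source")]][i]), sep = ":")
    paste(v$chrom[i], v$pos[i], ".", v$ref[i], v$alt[i], ".",
          if (length(filt)) paste(filt, collapse = ";") else "PASS",
          info, "ADR:ADA:DP:VF:CSRC", samp("t"), samp("n"), sep = "\t")
  }, character(1))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a merged small-variant VCF written by [writeSomaticVcf()]
#' @param path VCF file
#' @return a [SmallVariantSet-class]
#' @export
readSomaticVcf <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf, getINFO = TRUE)
  if (is.null(fix) || nrow(fix) == 0L) return(SmallVariants())
  fix <- as.data.frame(fix, stringsAsFactors = FALSE)
  gt <- vcf@gt
  callers <- lapply(.infoField(fix$INFO, "CALLERS"), function(s)
    if (is.na(s) || s == ".") character()
    else strsplit(s, ",")[[1]])
  filters <- lapply(fix$FILTER, function(f)
    if (is.na(f) || f %in% c("PASS", ".")) character()
    else strsplit(f, ";")[[1]])
  pop_af <- lapply(.infoField(fix$INFO, "PAF"), .decodeAf)
  mnv_id <- .infoField(fix$INFO, "MNVID")
  mnv_id[mnv_id == "."] <- NA_character_
  sampcol <- function(j, key) {
    col <- gt[, j + 1L]
    vapply(seq_along(col), function(i)
      .gtField(col[i], gt[i, 1L], key), character(1))
  }
  src_fix <- function(x) ifelse(x == ".", NA_character_, x)
  SmallVariants(
    chrom = fix$CHROM, pos = as.integer(fix$POS), ref = fix$REF,
    alt = fix$ALT, callers = callers, filters = filters,
    mnv_id = mnv_id,
    hc = .infoField(fix$INFO, "HC") == "1",
    t_ref = .parseNum(sampcol(1L, "ADR")),
    t_alt = .parseNum(sampcol(1L, "ADA")),
    t_depth = .parseNum(sampcol(1L, "DP")),
    t_vaf = .parseNum(sampcol(1L, "VF")),
    t_source = src_fix(sampcol(1L, "CSRC")),
    n_ref = .parseNum(sampcol(2L, "ADR")),
    n_alt = .parseNum(sampcol(2L, "ADA")),
    n_depth = .parseNum(sampcol(2L, "DP")),
    n_vaf = .parseNum(sampcol(2L, "VF")),
    n_source = src_fix(sampcol(2L, "CSRC")),
    pop_af = pop_af)
}

.BEDPE_HEADER <- c("chrom1", "start1", "end1", "chrom2", "start2", "end2",
                   "name", "score", "strand1", "strand2", "svtype",
                   "callers", "filters", "hc", "splitreads_t",
                   "splitreads_n")

#' Write SVs as 16-column BEDPE
#'
#' Standard six BEDPE interval columns plus name/score/strands and svtype,
#' comma-joined callers (canonical order), semicolon-joined filter tags
#' ("PASS" when none), the high-confidence flag and split-read counts.
#' @param x a [BreakendPairSet-class]
#' @param path output file
#' @return `path`, invisibly
#' @export
writeBedpe <- function(x, path) {
  stopifnot(is(x, "BreakendPairSet"))
  p <- x@pairs
  d <- data.frame(
    chrom1 = p$chrom1, start1 = p$start1, end1 = p$end1,
    chrom2 = p$chrom2, start2 = p$start2, end2 = p$end2,
    name = p$name, score = ".", strand1 = p$strand1, strand2 = p$strand2,
    svtype = p$svtype,
    callers = vapply(p$callers, function(cl)
      if (length(cl)) paste(orderCallers(cl, "sv"), collapse = ",")
      else ".", character(1)),
    filters = vapply(p$filters, function(f)
      if (length(f)) paste(f, collapse = ";") else "PASS", character(1)),
    hc = as.integer(p$hc),
    splitreads_t = .fmtNum(p$split_t), splitreads_n = .fmtNum(p$split_n),
    stringsAsFactors = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#", paste(.BEDPE_HEADER, collapse = "\t")), con)
  if (nrow(d))
    utils::write.table(d, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BEDPE written by [writeBedpe()]
#' @param path BEDPE file
#' @return a [BreakendPairSet-class]
#' @export
readBedpe <- function(path) {
  d <- utils::read.table(path, sep = "\t", header = FALSE,
                         stringsAsFactors = FALSE, comment.char = "#",
                         col.names = .BEDPE_HEADER,
                         colClasses = c("character", "integer", "integer",
                                        "character", "integer", "integer",
                                        "character", "character",
                                        "character", "character",
                                        "character", "character",
                                        "character", "integer",
                                        "character", "character"))
  if (!nrow(d)) return(BreakendPairs())
  out <- BreakendPairs(
    chrom1 = d$chrom1, start1 = d$start1, end1 = d$end1,
    chrom2 = d$chrom2, start2 = d$start2, end2 = d$end2,
    strand1 = d$strand1, strand2 = d$strand2, svtype = d$svtype,
    name = d$name,
    callers = lapply(d$callers, function(s)
      if (s == ".") character() else strsplit(s, ",")[[1]]),
    filters = lapply(d$filters, function(s)
      if (s %in% c("PASS", ".")) character() else strsplit(s, ";")[[1]]),
    hc = d$hc == 1L,
    split_t = .parseNum(d$splitreads_t), split_n = .parseNum(d$splitreads_n))
  out
}

#' Write CNV segments as TSV
#' @param x a [CNVSegmentSet-class]
#' @param path output file
#' @return `path`, invisibly
#' @export
writeSegments <- function(x, path) {
  stopifnot(is(x, "CNVSegmentSet"))
  s <- x@segments
  d <- data.frame(chrom = s$chrom, start = s$start, end = s$end,
                  obs_log2 = .fmtNum(s$obs_log2),
                  adj_log2 = .fmtNum(s$adj_log2),
                  t_cn = .fmtNum(s$t_cn), n_cn = .fmtNum(s$n_cn),
                  category = s$category, neg_cn = as.integer(s$neg_cn),
                  stringsAsFactors = FALSE)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a CNV segment TSV written by [writeSegments()]
#' @param path TSV file
#' @return a [CNVSegmentSet-class]
#' @export
readSegments <- function(path) {
  d <- utils::read.table(path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE,
                         colClasses = "character")
  if (!nrow(d)) return(CNVSegments())
  out <- CNVSegments(chrom = d$chrom, start = as.integer(d$start),
                     end = as.integer(d$end),
                     obs_log2 = .parseNum(d$obs_log2),
                     adj_log2 = .parseNum(d$adj_log2),
                     t_cn = .parseNum(d$t_cn), n_cn = .parseNum(d$n_cn),
                     category = d$category)
  out@segments$neg_cn <- d$neg_cn == "1"
  out
}

#' Write all merged outputs of a pipeline run
#'
#' Small variants as VCF, SVs as BEDPE, and CNV segments as TSV under
#' `out_dir` (created if needed).
#' @param variants a [SmallVariantSet-class]
#' @param svs a [BreakendPairSet-class]
#' @param segments a [CNVSegmentSet-class]
#' @param out_dir output directory
#' @return named character vector of the written paths
#' @export
writeMergedOutputs <- function(variants, svs, segments, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    variants = writeSomaticVcf(variants,
                               file.path(out_dir, "somatic.vcf")),
    svs = writeBedpe(svs, file.path(out_dir, "somatic.sv.bedpe")),
    segments = writeSegments(segments,
                             file.path(out_dir, "somatic.cnv.tsv")))
  paths
}

#' Write/read a small-variant PON site list
#' @param pon a [SmallPon-class]
#' @param path TSV file (chrom, pos, n_individuals)
#' @return `path` / a [SmallPon-class]
#' @export
writeSmallPon <- function(pon, path) {
  stopifnot(is(pon, "SmallPon"))
  utils::write.table(pon@sites, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname writeSmallPon
#' @export
readSmallPon <- function(path) {
  d <- utils::read.table(path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE)
  new("SmallPon", sites = d)
}

#' Write/read read-evidence tables
#'
#' Fixture format for pileup evidence: one row per read observation with
#' columns chrom, pos, sample, fragment_id, allele, mq, bq, flags (comma
#' list over dup/supp/qcfail/unmapped, or "."). [readEvidenceTable()]
#' returns the named-list-of-data.frames layout consumed by
#' [selectFinalCounts()] via [pileupCounts()], split by sample.
#'
#' @param evidence named list (variant key -> evidence data.frame), as
#'   produced by [simulateSampleCounts()] for one sample
#' @param sample sample label ("TUMOR"/"NORMAL")
#' @param path TSV file (append when writing both samples to one file)
#' @param append append instead of overwrite (default FALSE)
#' @return `path` / named list of evidence tables per sample
#' @export
writeEvidenceTable <- function(evidence, sample, path, append = FALSE) {
  rows <- list()
  for (key in names(evidence)) {
    ev <- evidence[[key]]
    if (!nrow(ev)) next
    parts <- strsplit(key, ":", fixed = TRUE)[[1]]
    flags <- apply(cbind(dup = ev$is_duplicate, supp = ev$is_supplementary,
                         qcfail = ev$is_qcfail, unmapped = ev$is_unmapped),
                   1, function(f) {
                     on <- names(f)[as.logical(f)]
                     if (length(on)) paste(on, collapse = ",") else "."
                   })
    rows[[length(rows) + 1L]] <- data.frame(
      chrom = parts[1], pos = as.integer(parts[2]), key = key,
      sample = sample, fragment_id = ev$fragment_id, allele = ev$allele,
      mq = ev$mq, bq = ev$bq, flags = flags, stringsAsFactors = FALSE)
  }
  d <- if (length(rows)) do.call(rbind, rows) else
    data.frame(chrom = character(), pos = integer(), key = character(),
               sample = character(), fragment_id = character(),
               allele = character(), mq = numeric(), bq = numeric(),
               flags = character(), stringsAsFactors = FALSE)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = !append, append = append)
  invisible(path)
}

#' @rdname writeEvidenceTable
#' @export
readEvidenceTable <- function(path) {
  d <- utils::read.table(path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE)
  out <- list()
  for (smp in unique(d$sample)) {
    ds <- d[d$sample == smp, , drop = FALSE]
    out[[smp]] <- lapply(split(ds, ds$key), function(g) data.frame(
      fragment_id = g$fragment_id, allele = g$allele, mq = g$mq, bq = g$bq,
      is_duplicate = grepl("dup", g$flags),
      is_supplementary = grepl("supp", g$flags),
      is_qcfail = grepl("qcfail", g$flags),
      is_unmapped = grepl("unmapped", g$flags),
      stringsAsFactors = FALSE))
  }
  out
}
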