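## Read-level homopolymer and trinucleotide-context mismatch profiling.
##
## Reads are held in a data.frame ("aligned-read table") with columns:
## qname, read_index ("R1"/"R2"), chrom, pos (1-based leftmost), seq, qual
## (Phred+33 string), mapq, cigar (NA = all-matched), is_reverse,
## is_duplicate, is_supplementary, is_qcfail, is_unmapped. The simulator
## emits this format directly; SAM/BAM files are imported with
## readAlignments().

.COMP <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

#' Longest homopolymer run of each base
#'
#' For each sequence, the length of the longest consecutive run of each of
#' A, C, G and T. N is tolerated but breaks runs and is never counted; any
#' other symbol is an error.
#' @param seqs character vector of nucleotide strings
#' @return matrix (length(seqs) x 4) with columns A, C, G, T
#' @examples
#' longestRuns("AAAT")
#' @export
longestRuns <- function(seqs) {
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) stop("sequence contains non-ACGTN symbols")
  out <- matrix(0L, nrow = length(seqs), ncol = 4L,
                dimnames = list(NULL, c("A", "C", "G", "T")))
  for (i in seq_along(seqs)) {
    if (!nzchar(seqs[i])) next
    r <- rle(strsplit(seqs[i], "")[[1]])
    for (b in c("A", "C", "G", "T")) {
      len <- r$lengths[r$values == b]
      if (length(len)) out[i, b] <- max(len)
    }
  }
  out
}

#' Distribution of longest-run lengths by base and read index
#'
#' Empirical distribution, per base and read index, of the per-read longest
#' homopolymer run length (reads lacking a base contribute length 0).
#' Fractions sum to 1 within each (base, read_index).
#' @param reads aligned-read table (columns `seq` and `read_index`), or a
#'   character vector of sequences (treated as one combined read index)
#' @return data.frame(base, run_length, read_index, n, fraction)
#' @export
runLengthDistribution <- function(reads) {
  if (is.character(reads))
    reads <- data.frame(seq = reads, read_index = "combined",
                        stringsAsFactors = FALSE)
  out <- list()
  for (ri in unique(reads$read_index)) {
    runs <- longestRuns(reads$seq[reads$read_index == ri])
    for (b in colnames(runs)) {
      tab <- table(runs[, b])
      out[[length(out) + 1L]] <- data.frame(
        base = b, run_length = as.integer(names(tab)), read_index = ri,
        n = as.integer(tab), fraction = as.numeric(tab) / sum(tab),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

## aligned (read_pos, ref_pos) pairs from a CIGAR; NA cigar = full match
.alignedPairs <- function(cigar, slen, pos) {
  if (is.na(cigar) || cigar == "*")
    return(cbind(read = seq_len(slen), ref = pos + seq_len(slen) - 1L))
  ops <- regmatches(cigar, gregexpr("[0-9]+[MIDNSHP=X]", cigar))[[1]]
  n <- as.integer(sub("[A-Z=]$", "", ops))
  op <- sub("^[0-9]+", "", ops)
  read_i <- 1L
  ref_i <- pos
  pairs <- list()
  for (k in seq_along(op)) {
    if (op[k] %in% c("M", "=", "X")) {
      pairs[[length(pairs) + 1L]] <-
        cbind(read = read_i + seq_len(n[k]) - 1L,
              ref = ref_i + seq_len(n[k]) - 1L)
      read_i <- read_i + n[k]
      ref_i <- ref_i + n[k]
    } else if (op[k] %in% c("I", "S")) {
      read_i <- read_i + n[k]
    } else if (op[k] %in% c("D", "N")) {
      ref_i <- ref_i + n[k]
    }  # H, P consume nothing
  }
  do.call(rbind, pairs)
}

#' Profile single-nucleotide mismatches by trinucleotide context
#'
#' Tallies mismatches between aligned reads and the reference over the 192
#' channels (12 ref>read substitution types x 16 flanking contexts), in
#' read-strand orientation: for reverse-strand alignments the reference
#' base, read base and flanking context are all reverse-complemented.
#' Duplicate, unmapped, supplementary and QC-failed reads are skipped
#' entirely; reads below `mq_min` are skipped; aligned non-indel positions
#' with base quality >= `bq_min` are eligible provided both flanking
#' positions are part of the same gapless aligned block (read ends and
#' indel-adjacent bases are therefore ineligible) and neither base nor
#' context contains N.
#'
#' @param reads aligned-read table (see module header)
#' @param reference named character vector or
#'   [Biostrings::DNAStringSet-class] of contig sequences
#' @param mq_min,bq_min quality cut-offs (default 10 each)
#' @param read_index restrict to "R1"/"R2", or "combined" for all reads
#' @return a [MismatchCounts-class]
#' @export
profileMismatches <- function(reads, reference, mq_min = 10, bq_min = 10,
                              read_index = "combined") {
  if (is(reference, "DNAStringSet")) reference <- as.character(reference)
  stopifnot(!is.null(names(reference)))
  if (read_index != "combined")
    reads <- reads[reads$read_index == read_index, , drop = FALSE]
  ch <- mismatchChannels()
  counts <- stats::setNames(numeric(192L), ch)
  eligible <- 0
  ref_chars <- lapply(reference, function(s) strsplit(s, "")[[1]])
  for (i in seq_len(nrow(reads))) {
    rd <- reads[i, ]
    if (rd$is_duplicate || rd$is_supplementary || rd$is_qcfail ||
        rd$is_unmapped || rd$mapq < mq_min) next
    rc <- ref_chars[[rd$chrom]]
    if (is.null(rc)) stop("read aligned to unknown contig: ", rd$chrom)
    sq <- strsplit(rd$seq, "")[[1]]
    bq <- utf8ToInt(rd$qual) - 33L
    pairs <- .alignedPairs(rd$cigar, length(sq), rd$pos)
    if (max(pairs[, "ref"]) > length(rc))
      stop("alignment extends past the end of the reference")
    np <- nrow(pairs)
    if (np < 3L) next
    j <- 2:(np - 1L)
    gapless <- pairs[j - 1L, "read"] + 1L == pairs[j, "read"] &
      pairs[j, "read"] + 1L == pairs[j + 1L, "read"] &
      pairs[j - 1L, "ref"] + 1L == pairs[j, "ref"] &
      pairs[j, "ref"] + 1L == pairs[j + 1L, "ref"]
    j <- j[gapless]
    if (!length(j)) next
    read_pos <- pairs[j, "read"]
    ref_pos <- pairs[j, "ref"]
    ok_q <- bq[read_pos] >= bq_min
    read_b <- sq[read_pos]
    ref_b <- rc[ref_pos]
    up <- rc[ref_pos - 1L]
    dn <- rc[ref_pos + 1L]
    ok_n <- read_b != "N" & ref_b != "N" & up != "N" & dn != "N"
    use <- ok_q & ok_n
    eligible <- eligible + sum(use)
    mm <- use & read_b != ref_b
    if (!any(mm)) next
    if (rd$is_reverse) {
      chan <- paste0(.COMP[dn[mm]], "[", .COMP[ref_b[mm]], ">",
                     .COMP[read_b[mm]], "]", .COMP[up[mm]])
    } else {
      chan <- paste0(up[mm], "[", ref_b[mm], ">", read_b[mm], "]", dn[mm])
    }
    tab <- table(chan)
    counts[names(tab)] <- counts[names(tab)] + as.numeric(tab)
  }
  MismatchCounts(counts = counts, eligible_bases = eligible,
                 read_index = read_index)
}

#' The 96 collapsed mismatch channel names
#' @return character vector: 6 pyrimidine-reference types x 16 contexts
#' @export
collapsedChannels <- function() {
  bases <- c("A", "C", "G", "T")
  types <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
  unlist(lapply(types, function(t)
    paste0(rep(bases, each = 4), "[", t, "]", rep(bases, 4))))
}

#' Collapse 192 mismatch channels to the 6 x 16 representation
#'
#' Purine-reference channels are added into their reverse-complement
#' pyrimidine channels (alleles complemented, context reversed and
#' complemented); pyrimidine channels are unchanged. The total count is
#' conserved.
#' @param x a [MismatchCounts-class]
#' @return named numeric of length 96 over [collapsedChannels()]
#' @export
collapseToSix <- function(x) {
  stopifnot(is(x, "MismatchCounts"))
  out <- stats::setNames(numeric(96L), collapsedChannels())
  for (name in names(x@counts)) {
    cnt <- x@counts[[name]]
    if (cnt == 0) next
    up <- substr(name, 1, 1)
    ref <- substr(name, 3, 3)
    alt <- substr(name, 5, 5)
    dn <- substr(name, 7, 7)
    if (ref %in% c("A", "G")) {
      key <- paste0(.COMP[dn], "[", .COMP[ref], ">", .COMP[alt], "]",
                    .COMP[up])
    } else {
      key <- name
    }
    out[key] <- out[key] + cnt
  }
  out
}

#' Overall mismatch rate
#' @param x a [MismatchCounts-class]
#' @return total mismatches / eligible bases; NA when no eligible bases
#' @export
mismatchRate <- function(x) {
  stopifnot(is(x, "MismatchCounts"))
  if (x@eligible_bases <= 0) return(NA_real_)
  sum(x@counts) / x@eligible_bases
}

#' Downsample reads to a target depth
#'
#' Uniform random subsampling of whole fragments (reads sharing a qname are
#' kept or dropped together) with keep probability target/current depth.
#' Seed-reproducible.
#' @param reads aligned-read table
#' @param target_depth target mean depth (default 8)
#' @param genome_size total reference length in bp
#' @param seed RNG seed
#' @return subsetted aligned-read table
#' @export
downsampleReads <- function(reads, target_depth = 8, genome_size, seed = 1) {
  current <- sum(nchar(reads$seq)) / genome_size
  if (target_depth > current + 1e-9)
    stop("target depth ", target_depth, " exceeds current depth ",
         signif(current, 4))
  p_keep <- min(1, target_depth / current)
  frags <- unique(reads$qname)
  set.seed(seed)
  keep <- frags[runif(length(frags)) < p_keep]
  reads[reads$qname %in% keep, , drop = FALSE]
}

#' Import alignments from SAM or BAM into the aligned-read table
#'
#' BAM files are read through Rsamtools (if installed); SAM text files are
#' read from their mandatory 11 columns. Read index is derived from the
#' first/second-of-pair flag bits.
#' @param path SAM or BAM file
#' @return aligned-read table as consumed by [profileMismatches()]
#' @export
readAlignments <- function(path) {
  is_bam <- grepl("\\.bam$", path, ignore.case = TRUE)
  if (is_bam) {
    if (!requireNamespace("Rsamtools", quietly = TRUE))
      stop("reading BAM requires the Rsamtools package")
    b <- Rsamtools::scanBam(path)[[1]]
    flag <- b$flag
    df <- data.frame(qname = b$qname, chrom = as.character(b$rname),
                     pos = b$pos, mapq = b$mapq, cigar = b$cigar,
                     seq = as.character(b$seq), qual = as.character(b$qual),
                     stringsAsFactors = FALSE)
  } else {
    lines <- readLines(path)
    lines <- lines[!startsWith(lines, "@")]
    fields <- strsplit(lines, "\t")
    if (any(vapply(fields, length, integer(1)) < 11L))
      stop("malformed SAM record: fewer than 11 mandatory fields")
    gf <- function(k) vapply(fields, `[`, character(1), k)
    flag <- as.integer(gf(2))
    df <- data.frame(qname = gf(1), chrom = gf(3),
                     pos = as.integer(gf(4)), mapq = as.integer(gf(5)),
                     cigar = gf(6), seq = gf(10), qual = gf(11),
                     stringsAsFactors = FALSE)
  }
  df$cigar[df$cigar == "*"] <- NA_character_
  df$is_unmapped <- bitwAnd(flag, 4L) > 0L
  df$is_reverse <- bitwAnd(flag, 16L) > 0L
  df$is_duplicate <- bitwAnd(flag, 1024L) > 0L
  df$is_supplementary <- bitwAnd(flag, 2048L) > 0L
  df$is_qcfail <- bitwAnd(flag, 512L) > 0L
  df$read_index <- ifelse(bitwAnd(flag, 128L) > 0L, "R2", "R1")
  df
}
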