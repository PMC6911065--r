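## Shared internal helpers: caller orderings, variant keys, allele typing.

SMALL_CALLERS <- c("strelka2", "mutect2", "lancet", "svaba")
SV_CALLERS    <- c("manta", "lumpy", "svaba")
SV_TYPES      <- c("DEL", "DUP", "INV", "INS", "TRA")
CNV_CATEGORIES <- c("AMP", "DEL", "NEUTRAL", "UNDEFINED")
COUNT_SOURCES <- c("PILEUP", "STRELKA2", "MUTECT2", "LANCET", "NONE")

## Count-derived filter tags plus the merge-stage tags; AllSomatic membership
## is defined over these (NO_COUNTS deliberately not disqualifying).
SOMATIC_FAIL_TAGS <- c("LOW_TUMOR_VAF", "HIGH_NORMAL_VAF", "LOW_DEPTH",
                       "NORMAL_GT_TUMOR", "PON", "COMMON_GERMLINE")

#' Order caller names canonically
#'
#' Small-variant priority is strelka2 > mutect2 > lancet > svaba; SV priority
#' is manta > lumpy > svaba. Used for representative-record selection and for
#' deterministic output ordering.
#' @param callers character vector of caller names
#' @param type `"small"` or `"sv"`
#' @return `callers` sorted by priority
#' @keywords internal
orderCallers <- function(callers, type = c("small", "sv")) {
  type <- match.arg(type)
  ref <- if (type == "small") SMALL_CALLERS else SV_CALLERS
  unknown <- setdiff(callers, ref)
  if (length(unknown))
    stop("unknown caller name(s): ", paste(unknown, collapse = ", "))
  ref[ref %in% callers]
}

## (chrom, pos, ref, alt) identity used for all small-variant set operations
variantKey <- function(chrom, pos, ref, alt) {
  paste(chrom, pos, ref, alt, sep = ":")
}

## Classify alleles: SNV (1/1), MNV (equal length > 1), INDEL (unequal)
inferVtype <- function(ref, alt) {
  lr <- nchar(ref); la <- nchar(alt)
  ifelse(lr == la, ifelse(lr == 1L, "SNV", "MNV"), "INDEL")
}

## Net allele-length change; the "indel length" of the allele-count rules
indelLength <- function(ref, alt) {
  abs(nchar(ref) - nchar(alt))
}

checkDna <- function(x, what = "allele") {
  bad <- grepl("[^ACGT]", x)
  if (any(bad))
    stop(what, " contains non-ACGT characters: ",
         paste(utils::head(x[bad], 3), collapse = ", "))
  invisible(x)
}

revComp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

## vaf with missing-on-zero-denominator semantics
vafFrom <- function(ref_count, alt_count) {
  den <- ref_count + alt_count
  ifelse(!is.na(den) & den > 0, alt_count / den, NA_real_)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## Deterministic per-purpose seed derivation, kept inside 32-bit range
deriveSeed <- function(seed, offset) {
  (as.integer(seed) + as.integer(offset) * 10007L) %% 2147483647L
}
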