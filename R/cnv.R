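## CNV categorization, mixture-derived tumor purity, and purity/ploidy
## adjustment of log2 copy ratios.

#' Categorize log2 copy ratios
#'
#' Segments with log2 > 0.2 are amplifications and segments with
#' log2 < -0.235 are deletions (a single copy change at 30% purity in a
#' diploid genome); everything in between is neutral. Both inequalities are
#' strict, so the boundary values themselves are NEUTRAL. Non-finite values
#' get category UNDEFINED.
#'
#' @param log2_value numeric vector of log2 copy ratios
#' @param amp_threshold amplification threshold (default 0.2)
#' @param del_threshold deletion threshold (default -0.235)
#' @return character vector over AMP/DEL/NEUTRAL/UNDEFINED
#' @examples
#' categorizeLog2(c(0.25, -0.3, 0.2, -0.235))
#' @export
categorizeLog2 <- function(log2_value, amp_threshold = 0.2,
                           del_threshold = -0.235) {
  out <- rep("NEUTRAL", length(log2_value))
  out[!is.finite(log2_value)] <- "UNDEFINED"
  fin <- is.finite(log2_value)
  out[fin & log2_value > amp_threshold] <- "AMP"
  out[fin & log2_value < del_threshold] <- "DEL"
  out
}

#' True tumor purity of a tumor/normal read mixture
#'
#' For a mixture in which a fraction `t_frac` of reads comes from the tumor
#' library, the DNA-weighted tumor purity is
#' \deqn{T_{purity} = \frac{T_{frac} N_{ploidy}}
#'   {(1-T_{frac}) T_{ploidy} + T_{frac} N_{ploidy}}}
#' The ploidy weighting accounts for the fact that a tetraploid tumor
#' contributes twice the DNA per cell of a diploid normal, so equal read
#' fractions do not mean equal cell fractions.
#'
#' @param t_frac tumor read fraction in [0,1] (e.g. 10/(10+70) = 0.125 for a
#'   10X tumor + 70X normal mixture)
#' @param t_ploidy average tumor ploidy (> 0)
#' @param n_ploidy average normal ploidy (default 2)
#' @return tumor purity in [0,1]; equals `t_frac` when the ploidies are equal
#' @examples
#' purityFromMixture(0.125, t_ploidy = 4)   # tetraploid tumor
#' purityFromMixture(0.5, t_ploidy = 2)     # diploid: purity == t_frac
#' @export
purityFromMixture <- function(t_frac, t_ploidy, n_ploidy = 2) {
  if (any(t_frac < 0 | t_frac > 1)) stop("t_frac must lie in [0,1]")
  if (any(t_ploidy <= 0) || any(n_ploidy <= 0))
    stop("ploidies must be positive")
  (t_frac * n_ploidy) / ((1 - t_frac) * t_ploidy + t_frac * n_ploidy)
}

#' Absolute tumor copy number from an observed log2 ratio
#'
#' Inverts the read-depth mixture model for a segment:
#' \deqn{T_{CN} = \frac{T_{ploidy} N_{CN} (2^{Obs_{log2}} - (1-T_{purity}))}
#'   {N_{ploidy} T_{purity}}}
#' The result can be non-positive when \eqn{2^{Obs_{log2}} \le 1-T_{purity}}
#' (observed depth lower than the normal contamination alone allows); such
#' values are returned as-is so callers can flag them.
#'
#' @param obs_log2 observed log2 copy ratio
#' @param t_purity tumor purity in (0,1]
#' @param t_ploidy average tumor ploidy
#' @param n_ploidy average normal ploidy (default 2)
#' @param n_cn normal copy number of the segment (default 2)
#' @return absolute tumor copy number (real-valued)
#' @examples
#' tumorCopyNumber(log2(0.85), t_purity = 0.3, t_ploidy = 2)  # 1.0
#' @export
tumorCopyNumber <- function(obs_log2, t_purity, t_ploidy, n_ploidy = 2,
                            n_cn = 2) {
  if (any(t_purity <= 0) || any(t_purity > 1))
    stop("t_purity must lie in (0,1]")
  if (any(t_ploidy <= 0) || any(n_ploidy <= 0))
    stop("ploidies must be positive")
  t_ploidy * n_cn * (2^obs_log2 - (1 - t_purity)) / (n_ploidy * t_purity)
}

#' Adjust segment log2 ratios for tumor purity and ploidy
#'
#' Computes the absolute tumor copy number of every segment via
#' [tumorCopyNumber()] and the purity/ploidy-adjusted ratio
#' \deqn{Adj_{log2} = \log_2\left(\frac{T_{CN}}{T_{ploidy}}
#'   \frac{N_{ploidy}}{N_{CN}}\right)}
#' then re-derives the AMP/DEL/NEUTRAL category from the adjusted value.
#' At purity 1 the adjustment is the identity on `obs_log2`. Segments whose
#' inferred copy number is non-positive get a missing `adj_log2`, category
#' DEL, and the `neg_cn` flag set (flagged, not clamped, so downstream
#' evaluation can count them).
#'
#' @param segments a [CNVSegmentSet-class]
#' @param t_purity tumor purity in (0,1]
#' @param t_ploidy average tumor ploidy
#' @param n_ploidy average normal ploidy (default 2)
#' @param amp_threshold,del_threshold categorization thresholds
#' @return the CNVSegmentSet with `adj_log2`, `t_cn`, `category` and
#'   `neg_cn` filled in
#' @export
adjustLog2 <- function(segments, t_purity, t_ploidy, n_ploidy = 2,
                       amp_threshold = 0.2, del_threshold = -0.235) {
  stopifnot(is(segments, "CNVSegmentSet"))
  s <- segments@segments
  if (!nrow(s)) return(segments)
  t_cn <- tumorCopyNumber(s$obs_log2, t_purity, t_ploidy, n_ploidy, s$n_cn)
  neg <- t_cn <= 0
  adj <- rep(NA_real_, length(t_cn))
  adj[!neg] <- log2((t_cn[!neg] / t_ploidy) * (n_ploidy / s$n_cn[!neg]))
  s$t_cn <- t_cn
  s$adj_log2 <- adj
  s$neg_cn <- neg
  s$category <- categorizeLog2(adj, amp_threshold, del_threshold)
  s$category[neg] <- "DEL"
  new("CNVSegmentSet", segments = s)
}
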