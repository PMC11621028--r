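#' Somatic SNV filter cascade
#'
#' Filters a candidate-variant table down to confident somatic SNVs using
#' per-spot tumor proportions. A spot is normal when its tumor proportion is
#' below 0.5. A variant survives when it passes every rule:
#' \enumerate{
#'   \item not a known germline SNP (population-panel flag);
#'   \item genic (intergenic reads are likely sequencing/alignment errors);
#'   \item no germline evidence from normal spots: zero variant reads in all
#'     normal spots AND total normal read depth at least
#'     \code{normal_depth_min} (a shallow normal pile-up cannot rule
#'     germline out);
#'   \item pooled variant count over tumor spots >= \code{min_alt} and
#'     pooled tumor variant allele frequency > \code{min_vaf}.
#' }
#' Each rule is a pure predicate, so the surviving set is the intersection
#' of the individual rules and does not depend on their order.
#'
#' @param vt data.frame with one row per variant: \code{chrom}, \code{pos},
#'   \code{ref}, \code{alt}, logical \code{germline} and \code{genic} flags,
#'   plus matrices/columns \code{AD} (variant counts, variant x spot) and
#'   \code{DP} (total counts) supplied via the \code{AD}/\code{DP}
#'   arguments.
#' @param AD,DP variant x spot matrices of variant and total read counts.
#' @param theta per-spot tumor proportions (no NAs among used spots).
#' @param min_alt minimum pooled tumor variant count (default 5).
#' @param min_vaf minimum pooled tumor VAF, exclusive (default 0.3).
#' @param normal_depth_min minimum pooled normal depth to accept absence of
#'   germline evidence (default 15).
#' @return the surviving rows of \code{vt}, with pooled tumor counts and VAF
#'   appended, plus a per-variant \code{reason} attribute for removals.
#' @export
filter_somatic <- function(vt, AD, DP, theta, min_alt = 5, min_vaf = 0.3,
                           normal_depth_min = 15) {
  if (is.null(theta)) stop("tumor proportions are required")
  stopifnot(nrow(AD) == nrow(vt), identical(dim(AD), dim(DP)),
            ncol(AD) == length(theta))
  if (any((DP - AD) < 0)) stop("AD must be <= DP")
  normal <- !is.na(theta) & theta < 0.5
  tumor <- !is.na(theta) & theta >= 0.5
  alt_norm <- rowSums(AD[, normal, drop = FALSE])
  dep_norm <- rowSums(DP[, normal, drop = FALSE])
  alt_tum <- rowSums(AD[, tumor, drop = FALSE])
  dep_tum <- rowSums(DP[, tumor, drop = FALSE])
  vaf_tum <- ifelse(dep_tum > 0, alt_tum / dep_tum, 0)
  pass_panel <- !as.logical(vt$germline)
  pass_genic <- as.logical(vt$genic)
  pass_normal <- alt_norm == 0 & dep_norm >= normal_depth_min
  pass_tumor <- alt_tum >= min_alt & vaf_tum > min_vaf
  keep <- pass_panel & pass_genic & pass_normal & pass_tumor
  reason <- rep("somatic", nrow(vt))
  reason[!pass_tumor] <- "low_tumor_support"
  reason[!pass_normal] <- ifelse(alt_norm[!pass_normal] > 0,
                                 "germline_evidence", "shallow_normal")
  reason[!pass_genic] <- "intergenic"
  reason[!pass_panel] <- "known_germline"
  out <- vt[keep, , drop = FALSE]
  out$tumor_alt <- alt_tum[keep]
  out$tumor_depth <- dep_tum[keep]
  out$tumor_vaf <- vaf_tum[keep]
  attr(out, "reason") <- reason
  out
}
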