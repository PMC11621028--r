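# Conversion of latent per-state (RDR, BAF) values into allele-specific
# integer copy numbers per clone.

#' Allele-specific integer copy numbers from latent state parameters
#'
#' For each candidate ploidy scale gamma (copies per unit RDR), each
#' copy-number state (mu_k, p_k) is matched to the integer pair (a, b) with
#' 0 <= a, b <= \code{max_cn}, a + b >= 1, minimising
#' \code{((a+b)/gamma - mu_k)^2 + w_baf * (b/(a+b) - p_k)^2}; the scale with
#' the smallest total (state-occupancy-weighted) error wins. b counts copies
#' of the B haplotype (inferred haplotype 1).
#'
#' @param states state table (columns \code{mu}, \code{p}).
#' @param Z bin x clone state matrix.
#' @param max_cn maximum copies per haplotype (default 6; higher
#'   amplifications are not reliably identifiable from expression).
#' @param ploidy_candidates candidate gamma values.
#' @param w_baf weight of the BAF term (default 1).
#' @return object of class \code{integer_cn}: bin x clone matrices \code{A}
#'   and \code{B}, the per-state assignment table, and the selected
#'   \code{ploidy_scale}.
#' @export
assign_integer_cn <- function(states, Z, max_cn = 6,
                              ploidy_candidates = c(1.5, 2, 2.5, 3, 3.5, 4),
                              w_baf = 1) {
  stopifnot(max_cn >= 1, all(states$mu > 0), all(states$p > 0 & states$p < 1))
  K <- nrow(states)
  pairs <- expand.grid(a = 0:max_cn, b = 0:max_cn)
  pairs <- pairs[pairs$a + pairs$b >= 1, ]
  occupancy <- tabulate(as.vector(Z), nbins = K)
  if (all(occupancy == 0)) occupancy <- rep(1, K)
  # states covering under 1% of the genome carry no weight in the scale
  # choice: gamma and 2*gamma explain even-total profiles equally well, and
  # a single noisily decoded bin must not resolve that degeneracy
  wsel <- occupancy * (occupancy >= 0.01 * sum(occupancy))
  if (all(wsel == 0)) wsel <- occupancy
  best <- NULL
  # candidates closest to diploid first, so exact ties (e.g. a genome whose
  # occupied states fit both gamma = 2 and gamma = 4 perfectly) resolve to
  # the most parsimonious scale
  ploidy_candidates <- ploidy_candidates[order(abs(ploidy_candidates - 2))]
  for (g in ploidy_candidates) {
    per_state <- t(vapply(seq_len(K), function(k) {
      err <- ((pairs$a + pairs$b) / g - states$mu[k])^2 +
        w_baf * (pairs$b / (pairs$a + pairs$b) - states$p[k])^2
      i <- which.min(err)
      c(a = pairs$a[i], b = pairs$b[i], err = err[i])
    }, numeric(3)))
    # weak diploid-parsimony penalty: with RDR anchored to the modal
    # (balanced) state the scale is nearly unidentifiable -- every scale
    # explains even-total profiles equally -- so moving away from 2 copies
    # per unit RDR must be earned by a material fit improvement
    tot <- sum(wsel * per_state[, "err"]) +
      0.02 * sum(wsel) * (g / 2 - 1)^2
    if (is.null(best) || tot < best$tot * (1 - 1e-9) - 1e-12)
      best <- list(gamma = g, per_state = per_state, tot = tot)
  }
  if (length(unique(states$mu)) == 1 && length(unique(states$p)) == 1) {
    warning("all states identical; ploidy scale unidentifiable, using gamma = 2")
    best$gamma <- 2
  }
  A <- matrix(best$per_state[, "a"][as.vector(Z)], nrow(Z), ncol(Z))
  B <- matrix(best$per_state[, "b"][as.vector(Z)], nrow(Z), ncol(Z))
  structure(list(A = A, B = B, ploidy_scale = best$gamma,
                 state_cn = data.frame(state = seq_len(K),
                                       a = best$per_state[, "a"],
                                       b = best$per_state[, "b"])),
            class = "integer_cn")
}

#' @export
print.integer_cn <- function(x, ...) {
  cat(sprintf("integer_cn: %d bins x %d clones, ploidy scale %.1f\n",
              nrow(x$A), ncol(x$A), x$ploidy_scale))
  invisible(x)
}

# event label of one (a, b) pair against a diploid (1, 1) baseline
cn_event_label <- function(a, b) {
  tot <- a + b
  if (a == 1 && b == 1) return("neutral")
  if (min(a, b) == 0) return(if (tot == 2) "CNLOH" else "LOH")
  if (tot < 2) return("del")
  if (tot > 2) return("amp")
  "neutral"
}

#' Classify copy-number events per genomic segment
#'
#' Segments are maximal runs of bins (within a chromosome) over which every
#' clone's (a, b) pair is constant. Each segment x clone combination is
#' labelled neutral / del / amp / CNLOH / LOH against a diploid baseline,
#' and a segment is flagged mirrored when two clones carry allelic imbalance
#' in opposite orientations (one a > b, the other a < b).
#'
#' @param cn an \code{integer_cn}.
#' @param bins bin table (\code{chrom}, \code{start}, \code{end}); defaults
#'   to one segment row per bin index when omitted.
#' @return data.frame with one row per segment: chrom, bin range, per-clone
#'   labels (comma-joined), and \code{mirrored} flag.
#' @export
classify_events <- function(cn, bins = NULL) {
  Bn <- nrow(cn$A); M <- ncol(cn$A)
  chrom <- if (!is.null(bins)) bins$chrom else rep("chr1", Bn)
  key <- apply(cbind(chrom, cn$A, cn$B), 1L, paste, collapse = "|")
  newseg <- c(TRUE, key[-1] != key[-Bn])
  seg_id <- cumsum(newseg)
  out <- do.call(rbind, lapply(unique(seg_id), function(sid) {
    idx <- which(seg_id == sid)
    a <- cn$A[idx[1], ]; b <- cn$B[idx[1], ]
    labels <- vapply(seq_len(M), function(m) cn_event_label(a[m], b[m]),
                     character(1))
    unbal <- a != b
    mirrored <- any(outer(seq_len(M), seq_len(M), Vectorize(function(m1, m2)
      m1 < m2 && unbal[m1] && unbal[m2] &&
        sign(a[m1] - b[m1]) != sign(a[m2] - b[m2]))))
    data.frame(segment = sid, chrom = chrom[idx[1]],
               bin_start = idx[1], bin_end = idx[length(idx)],
               labels = paste(labels, collapse = ","),
               mirrored = mirrored)
  }))
  rownames(out) <- NULL
  out
}
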