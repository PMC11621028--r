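#' Identify normal (diploid) spots
#'
#' Clusters spots on their per-bin phased BAF profiles (k-means; bins without
#' coverage in a spot are imputed at the balanced value 0.5) and marks as
#' normal the cluster whose centre deviates least from BAF = 0.5.
#' Alternatively, when per-spot tumor proportions are supplied, spots with
#' \code{theta < 0.5} are marked normal directly.
#'
#' @param bg a \code{binned_genome}.
#' @param n_clusters number of BAF clusters (default 5).
#' @param theta optional per-spot tumor proportions; when given, clustering is
#'   skipped and the mask is \code{theta < 0.5}.
#' @param seed RNG seed for k-means initialisation.
#' @return logical per-spot normal mask.
#' @export
identify_normal_spots <- function(bg, n_clusters = 5, theta = NULL, seed = 0) {
  if (!is.null(theta)) {
    stopifnot(length(theta) == ncol(bg$Y))
    return(!is.na(theta) & theta < 0.5)
  }
  stopifnot(n_clusters >= 2)
  baf <- t(bg$Y / bg$D)              # spots x bins
  baf[!is.finite(baf)] <- 0.5
  uniq <- nrow(unique(round(baf, 10)))
  if (uniq == 1) return(rep(TRUE, nrow(baf)))
  set.seed(seed)
  km <- suppressWarnings(
    stats::kmeans(baf, centers = min(n_clusters, uniq), nstart = 5, iter.max = 50))
  # score each cluster by its pooled, depth-normalised BAF deviation:
  # mean over bins of d * (baf - 0.5)^2 has null expectation ~0.25
  # irrespective of cluster size, whereas raw centre deviations make small
  # clusters look aberrant and large ones balanced
  dev <- vapply(seq_len(max(km$cluster)), function(cl) {
    sp <- km$cluster == cl
    y <- rowSums(bg$Y[, sp, drop = FALSE])
    d <- rowSums(bg$D[, sp, drop = FALSE])
    nz <- d > 0
    if (!any(nz)) return(Inf)
    mean(d[nz] * (y[nz] / d[nz] - 0.5)^2)
  }, numeric(1))
  best <- which.min(dev)
  if (sum(km$cluster == best) <= 1)
    warning("normal cluster is a singleton; baseline may be unstable")
  km$cluster == best
}

#' Baseline expression profile from normal spots
#'
#' Pools transcript counts over normal spots and normalises to a per-bin
#' proportion vector lambda (summing to 1), the diploid expression baseline
#' against which copy-number-driven expression shifts are measured.
#'
#' @param bg a \code{binned_genome}.
#' @param normal_mask logical per-spot mask from [identify_normal_spots()].
#' @return numeric per-bin baseline proportions.
#' @export
compute_baseline <- function(bg, normal_mask) {
  stopifnot(any(normal_mask))
  tot <- rowSums(bg$X[, normal_mask, drop = FALSE])
  s <- sum(tot)
  if (s == 0) stop("normal spots have zero transcript counts")
  tot / s
}

#' Mask bins with CNA-irrelevant allele-specific expression
#'
#' Some bins show allelic imbalance even in normal tissue (imprinting,
#' expression QTLs). Pooled normal-spot allele counts per bin are tested
#' against BAF = 0.5 with a two-sided exact binomial test; bins rejected
#' after Benjamini-Hochberg correction at level \code{alpha} are masked out
#' of downstream CNA inference. Bins with no normal coverage are retained
#' (no evidence of imbalance).
#'
#' @param bg a \code{binned_genome}.
#' @param normal_mask logical per-spot mask.
#' @param alpha BH false-discovery level (default 0.05).
#' @return logical per-bin mask, TRUE = retained.
#' @export
filter_ase_bins <- function(bg, normal_mask, alpha = 0.05) {
  stopifnot(any(normal_mask))
  y <- rowSums(bg$Y[, normal_mask, drop = FALSE])
  d <- rowSums(bg$D[, normal_mask, drop = FALSE])
  pv <- rep(1, length(y))
  nz <- d > 0
  pv[nz] <- vapply(which(nz), function(j)
    stats::binom.test(round(y[j]), round(d[j]), p = 0.5)$p.value, numeric(1))
  padj <- stats::p.adjust(pv, method = "BH")
  padj >= alpha | !nz
}

#' Compute the full baseline profile
#'
#' @inheritParams identify_normal_spots
#' @inheritParams filter_ase_bins
#' @return list with \code{normal_mask}, \code{lambda} (renormalised over
#'   retained bins) and \code{ase_mask}.
#' @export
baseline_profile <- function(bg, n_clusters = 5, theta = NULL, alpha = 0.05,
                             seed = 0) {
  nm <- identify_normal_spots(bg, n_clusters = n_clusters, theta = theta,
                              seed = seed)
  if (!any(nm)) {
    warning("no normal spots identified; using all spots for the baseline")
    nm <- rep(TRUE, ncol(bg$X))
  }
  lam <- compute_baseline(bg, nm)
  am <- filter_ase_bins(bg, nm, alpha = alpha)
  lam <- lam * am
  if (sum(lam) == 0) stop("all bins masked; cannot form a baseline")
  list(normal_mask = nm, lambda = lam / sum(lam), ase_mask = am)
}
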