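# Tumor proportion from the B-allele frequency at LOH regions.
#
# A spot mixing a fraction theta of tumor cells carrying an LOH (one
# haplotype fully lost, RDR mu) with 1 - theta normal cells shows a pooled
# BAF of f = 0.5 (1 - theta) / (theta mu + (1 - theta)) at the lost
# haplotype; inverting gives theta = (0.5 - f) / (0.5 + mu f - f).

#' Forward BAF-mixture relation
#'
#' Expected phased BAF of the lost haplotype in a spot with tumor proportion
#' \code{theta} when the tumor's LOH state has relative depth \code{mu}.
#'
#' @param theta tumor proportion in [0, 1].
#' @param mu RDR of the LOH state (> 0).
#' @return expected BAF in [0, 0.5].
#' @export
loh_baf_forward <- function(theta, mu) {
  0.5 * (1 - theta) / (theta * mu + (1 - theta))
}

#' Invert the BAF-mixture relation
#'
#' @param f observed pooled BAF at LOH regions.
#' @param mu RDR of the LOH state.
#' @param clip clip the estimate to [0, 1] (sampling noise can push it out).
#' @return tumor proportion estimate.
#' @export
loh_theta_inverse <- function(f, mu, clip = TRUE) {
  th <- (0.5 - f) / (0.5 + mu * f - f)
  if (clip) th <- pmin(pmax(th, 0), 1)
  th
}

#' Detect LOH regions from a BAF-only single-clone run
#'
#' Runs the copy-number state HMM on the all-spot pseudobulk with allele
#' (BAF) emissions only and a single clone, then flags the states whose
#' estimated BAF deviates from the balanced value 0.5 by at least
#' \code{threshold} (default 0.2). Bins assigned to a flagged state form the
#' LOH region set; the lost haplotype per bin is the minority one (B when
#' the state BAF is below 0.5, A otherwise).
#'
#' @param bg a \code{binned_genome}.
#' @param threshold minimum |BAF - 0.5| of an LOH state (in (0, 0.5)).
#' @param K number of states for the BAF-only run.
#' @param mu optional per-bin RDR estimates for Eq.-(3)-style correction; by
#'   default the LOH state RDR is taken as 1 (the BAF-only run does not
#'   estimate depth).
#' @return list \code{loh_regions}: \code{bins} (indices), \code{lost}
#'   ("A"/"B" per bin), \code{baf} (state BAF per bin), \code{mu} (scalar
#'   support-weighted RDR used downstream), plus the fitted single-clone
#'   HMM.
#' @export
detect_loh <- function(bg, threshold = 0.2, K = 7, mu = NULL) {
  stopifnot(threshold > 0, threshold < 0.5)
  N <- ncol(bg$X)
  lambda <- rep(1 / nrow(bg$bins), nrow(bg$bins))
  hm <- hmm_update(bg, ell = rep(1L, N), lambda = lambda,
                   states = make_cn_states(K), use_rdr = FALSE, use_baf = TRUE)
  z <- hm$Z[, 1]
  st <- hm$states
  is_loh_state <- abs(st$p - 0.5) >= threshold
  bins <- which(is_loh_state[z])
  if (!length(bins)) {
    return(list(bins = integer(0), lost = character(0), baf = numeric(0),
                mu = 1, hmm = hm))
  }
  baf <- st$p[z[bins]]
  lost <- ifelse(baf < 0.5, "B", "A")
  mu_used <- if (is.null(mu)) 1 else {
    supp <- rowSums(bg$D)[bins]
    sum(mu[bins] * supp) / sum(supp)
  }
  list(bins = bins, lost = lost, baf = baf, mu = mu_used, hmm = hm)
}

#' Per-spot tumor proportion from LOH BAF
#'
#' Orients the phased counts in each LOH bin so the lost haplotype is the
#' numerator, pools counts over all LOH bins per spot, and inverts the
#' BAF-mixture relation. Spots with pooled LOH coverage below
#' \code{min_support} get no direct estimate; if a spatial graph is given
#' their proportion is imputed as the mean over graph neighbours with
#' estimates, otherwise it is NA.
#'
#' @param bg a \code{binned_genome}.
#' @param loh output of [detect_loh()] (must be nonempty).
#' @param mu RDR of the LOH state (default: the value carried in \code{loh}).
#' @param min_support minimum pooled LOH UMIs per spot (default 10).
#' @param graph optional spatial graph from [build_graph()] for imputation.
#' @return data.frame with per-spot \code{theta}, \code{f}, \code{support}
#'   and an \code{imputed} flag.
#' @export
estimate_theta <- function(bg, loh, mu = NULL, min_support = 10, graph = NULL) {
  if (!length(loh$bins)) stop("no LOH regions; cannot estimate tumor proportions")
  mu <- mu %||% loh$mu
  Y <- bg$Y[loh$bins, , drop = FALSE]
  D <- bg$D[loh$bins, , drop = FALSE]
  flip <- loh$lost == "A"
  Y[flip, ] <- D[flip, , drop = FALSE] - Y[flip, , drop = FALSE]
  num <- colSums(Y); den <- colSums(D)
  f <- ifelse(den > 0, num / den, NA_real_)
  theta <- ifelse(den >= min_support, loh_theta_inverse(f, mu), NA_real_)
  imputed <- rep(FALSE, length(theta))
  if (!is.null(graph)) {
    for (s in which(is.na(theta))) {
      nb <- graph$nbr[[s]]
      vals <- theta[nb]
      if (length(vals) && any(!is.na(vals))) {
        theta[s] <- mean(vals, na.rm = TRUE)
        imputed[s] <- TRUE
      }
    }
  }
  data.frame(theta = theta, f = f, support = den, imputed = imputed)
}
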