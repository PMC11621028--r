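#' Pool allele counts across spots
#'
#' Sums the per-spot allele counts into a pseudobulk sample: every cell in a
#' tissue shares the same maternal/paternal haplotypes, so pooling across
#' spots boosts the per-SNP allele signal used to correct phasing errors.
#'
#' @param bundle a [raw_bundle()].
#' @return list with vectors \code{y0} (haplotype-1 counts) and \code{d0}
#'   (total counts), one entry per retained SNP.
#' @export
pseudobulk <- function(bundle) {
  list(y0 = as.numeric(Matrix::rowSums(bundle$Y0)),
       d0 = as.numeric(Matrix::rowSums(bundle$D0)))
}

#' Phasing HMM emission log-likelihood
#'
#' Beta-binomial emission of the joint (phase, BAF-cluster) phasing HMM:
#' for haplotype 1 the shapes are (tau * p, tau * (1 - p)); for haplotype 2
#' they are swapped, so the two phases of a cluster are mirror images.
#'
#' @param y,d pseudobulk haplotype-1 and total counts at a SNP.
#' @param h phase, 1 or 2.
#' @param p cluster BAF in (0, 1).
#' @param tau beta-binomial concentration, > 0.
#' @return log emission probability.
#' @export
phasing_emission_loglik <- function(y, d, h, p, tau) {
  stopifnot(all(y >= 0), all(y <= d), all(p > 0), all(p < 1), all(tau > 0))
  pp <- ifelse(h == 1, p, 1 - p)
  dbetabinom(y, d, tau * pp, tau * (1 - pp))
}

# Build the joint transition matrix over (cluster z, phase h) states.
# State index s = (h - 1) * K + z. Transitions factorize:
# P(z'|z) = t if equal else (1-t)/(K-1); P(h'|h) = q if equal else 1-q.
phasing_transition <- function(K, t, q) {
  Tz <- matrix((1 - t) / max(K - 1, 1), K, K); diag(Tz) <- if (K > 1) t else 1
  Th <- matrix(1 - q, 2, 2); diag(Th) <- q
  kronecker(Th, Tz)
}

phasing_logE <- function(y0, d0, p, tau) {
  K <- length(p)
  E <- matrix(NA_real_, length(y0), 2L * K)
  for (i in seq_len(K)) {
    E[, i]     <- dbetabinom(y0, d0, tau * p[i], tau * (1 - p[i]))
    E[, K + i] <- dbetabinom(y0, d0, tau * (1 - p[i]), tau * p[i])
  }
  E
}

#' Fit the pseudobulk phasing HMM
#'
#' Corrects switch errors left by population-based phasing. Hidden states are
#' pairs (BAF cluster z, phase h); emissions are beta-binomial on the
#' pseudobulk haplotype-1 counts (see [phasing_emission_loglik()]); the
#' transition factorizes into a cluster self-transition probability \code{t}
#' and a phase self-transition probability \code{q}. Parameters are estimated
#' by Baum-Welch (EM) and the per-SNP phase/cluster labels are the joint
#' Viterbi (MAP) path. Chromosomes are treated as independent chains.
#'
#' @param pb pseudobulk counts from [pseudobulk()].
#' @param snp_index SNP table with a \code{chrom} column (genome order).
#' @param K_phase number of BAF clusters (default 5).
#' @param tau,t,q initial values of the concentration and self-transition
#'   probabilities.
#' @param max_iter,tol EM iteration cap and relative log-likelihood tolerance.
#' @return list with \code{model} (p, tau, t, q, loglik trace, converged flag)
#'   and \code{assignment} (h in {1,2}, z cluster labels, posterior
#'   probability of h = 1 per SNP).
#' @export
fit_phasing_hmm <- function(pb, snp_index, K_phase = 5,
                            tau = 30, t = 1 - 1e-4, q = 1 - 1e-3,
                            max_iter = 30, tol = 1e-5) {
  y0 <- pb$y0; d0 <- pb$d0
  G <- length(y0)
  stopifnot(nrow(snp_index) == G, K_phase >= 1)
  chain <- snp_index$chrom
  # initial cluster BAFs spread over (0.05, 0.5]
  p <- if (K_phase == 1) 0.5 else seq(0.05, 0.5, length.out = K_phase)
  S <- 2L * K_phase
  logpi <- rep(log(1 / S), S)
  trace <- numeric(0)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    logE <- phasing_logE(y0, d0, p, tau)
    logA <- log(phasing_transition(K_phase, t, q))
    fb <- hmm_forward_backward(logE, logA, logpi, chain)
    trace <- c(trace, fb$loglik)
    if (it > 1 && abs(trace[it] - trace[it - 1]) <=
        tol * (abs(trace[it - 1]) + 1e-8)) { converged <- TRUE }
    g <- fb$gamma
    xi <- fb$xi
    # cluster / phase self-transition estimates from marginalised xi
    zi <- rep(seq_len(K_phase), 2L)
    hi <- rep(1:2, each = K_phase)
    if (K_phase > 1) {
      same_z <- outer(zi, zi, `==`)
      t <- max(min(sum(xi[same_z]) / sum(xi), 1 - 1e-6), 1e-6)
    }
    same_h <- outer(hi, hi, `==`)
    q <- max(min(sum(xi[same_h]) / sum(xi), 1 - 1e-6), 1e-6)
    # per-cluster BAF by weighted beta-binomial maximisation (phase 2
    # contributes with y and d - y swapped)
    informative <- d0 > 0
    for (i in seq_len(K_phase)) {
      w1 <- g[, i]; w2 <- g[, K_phase + i]
      if (sum(w1) + sum(w2) < 1e-8) next
      obj <- function(pi_) -sum(w1[informative] *
              dbetabinom(y0[informative], d0[informative],
                         tau * pi_, tau * (1 - pi_))) -
             sum(w2[informative] *
              dbetabinom(d0[informative] - y0[informative], d0[informative],
                         tau * pi_, tau * (1 - pi_)))
      p[i] <- stats::optimize(obj, c(1e-3, 0.5))$minimum
    }
    ordp <- order(p)
    p <- p[ordp]
    # shared concentration tau by 1-D maximisation on the log scale
    gw <- g
    obj_tau <- function(lt) {
      tt <- exp(lt)
      -sum(gw[informative, ] * phasing_logE(y0[informative], d0[informative], p, tt))
    }
    tau <- exp(stats::optimize(obj_tau, c(log(1), log(5000)))$minimum)
    if (converged) break
  }
  if (!converged) warning("phasing HMM did not converge in ", max_iter, " iterations")
  logE <- phasing_logE(y0, d0, p, tau)
  logA <- log(phasing_transition(K_phase, t, q))
  fb <- hmm_forward_backward(logE, logA, logpi, chain)
  path <- hmm_viterbi(logE, logA, logpi, chain)
  z <- ifelse(path > K_phase, path - K_phase, path)
  h <- ifelse(path > K_phase, 2L, 1L)
  post_h1 <- rowSums(fb$gamma[, seq_len(K_phase), drop = FALSE])
  list(model = list(K_phase = K_phase, p = p, tau = tau, t = t, q = q,
                    loglik = fb$loglik, trace = trace, converged = converged),
       assignment = list(h = h, z = z, posterior_h1 = post_h1))
}

#' Variable-length genomic binning
#'
#' Greedy left-to-right accumulation of consecutive SNPs within each
#' chromosome: a bin is closed as soon as its summed pseudobulk total allele
#' count reaches \code{min_total}; the trailing remainder of each chromosome
#' forms a final bin that may fall short of the minimum.
#'
#' @param snp_index SNP table (chrom, pos) in genome order.
#' @param pb pseudobulk counts from [pseudobulk()].
#' @param min_total minimum summed total allele count per closed bin
#'   (default 300).
#' @return data.frame with one row per SNP: \code{bin} id (integer, genome
#'   ordered), plus a \code{bins} attribute table (bin, chrom, start, end,
#'   n_snps).
#' @export
make_bins <- function(snp_index, pb, min_total = 300) {
  stopifnot(min_total > 0)
  G <- nrow(snp_index)
  bin <- integer(G)
  b <- 0L
  for (ch in unique(snp_index$chrom)) {
    idx <- which(snp_index$chrom == ch)
    acc <- 0
    b <- b + 1L
    for (i in idx) {
      if (acc >= min_total) { b <- b + 1L; acc <- 0 }
      bin[i] <- b
      acc <- acc + pb$d0[i]
    }
  }
  tab <- data.frame(
    bin = sort(unique(bin)),
    chrom = tapply(as.character(snp_index$chrom), bin, `[`, 1L)[as.character(sort(unique(bin)))],
    start = as.numeric(tapply(snp_index$pos, bin, min)),
    end = as.numeric(tapply(snp_index$pos, bin, max)),
    n_snps = as.integer(table(bin)),
    row.names = NULL)
  structure(data.frame(bin = bin), bins = tab)
}

#' Aggregate haplotype-aware counts into bins
#'
#' Builds the binned matrices used by all downstream inference. Per bin j and
#' spot s the total allele count is \code{D[j,s] = sum_g D0[g,s]}, and the
#' phased B-allele count flips each SNP according to its inferred phase:
#' \code{Y[j,s] = sum_g 1[h_g = 1] Y0[g,s] + 1[h_g = 2] (D0[g,s] - Y0[g,s])}.
#' The inferred haplotype 1 is called the B haplotype. Transcript counts are
#' aggregated by assigning each gene to the bin whose genomic span (a
#' covering partition of the chromosome, with boundaries midway between
#' adjacent bins' SNPs) contains its transcription start.
#'
#' @param bundle a filtered [raw_bundle()].
#' @param h per-SNP phase labels (1 or 2) from [fit_phasing_hmm()].
#' @param bins output of [make_bins()].
#' @return a \code{binned_genome}: list with \code{bins} table (chrom, start,
#'   end, n_snps, n_genes), matrices \code{X}, \code{Y}, \code{D}
#'   (bin x spot), per-spot metadata carried over from the bundle, and the
#'   per-bin gene/SNP memberships.
#' @export
aggregate_counts <- function(bundle, h, bins) {
  G <- nrow(bundle$Y0)
  stopifnot(length(h) == G, nrow(bins) == G)
  bin <- bins$bin
  tab <- attr(bins, "bins")
  B <- nrow(tab)
  M1 <- Matrix::sparseMatrix(i = bin, j = seq_len(G), x = 1, dims = c(B, G))
  D <- as.matrix(M1 %*% bundle$D0)
  flip <- h == 2L
  Yterm <- bundle$Y0
  Yterm[flip, ] <- (bundle$D0 - bundle$Y0)[flip, ]
  Y <- as.matrix(M1 %*% Yterm)

  # gene -> bin by transcription start within a covering partition of each
  # chromosome built from the bins' SNP spans
  gi <- bundle$gene_index
  gene_bin <- rep(NA_integer_, nrow(gi))
  for (ch in unique(tab$chrom)) {
    tb <- tab[tab$chrom == ch, , drop = FALSE]
    tb <- tb[order(tb$start), , drop = FALSE]
    cuts <- if (nrow(tb) > 1)
      c(-Inf, (utils::head(tb$end, -1) + utils::tail(tb$start, -1)) / 2, Inf)
    else c(-Inf, Inf)
    gidx <- which(gi$chrom == ch)
    if (!length(gidx)) next
    slot <- findInterval(gi$start[gidx], cuts, rightmost.closed = TRUE)
    slot[slot < 1] <- 1L; slot[slot > nrow(tb)] <- nrow(tb)
    gene_bin[gidx] <- tb$bin[slot]
  }
  X <- matrix(0, B, ncol(bundle$X0))
  hasg <- which(!is.na(gene_bin))
  if (length(hasg)) {
    M2 <- Matrix::sparseMatrix(i = gene_bin[hasg], j = hasg, x = 1,
                               dims = c(B, nrow(gi)))
    X <- as.matrix(M2 %*% bundle$X0)
  }
  tab$n_genes <- as.integer(tabulate(gene_bin[hasg], nbins = B))
  dimnames(X) <- dimnames(Y) <- dimnames(D) <-
    list(NULL, colnames(bundle$X0))
  structure(list(bins = tab, X = X, Y = Y, D = D,
                 S = bundle$S, slice_id = bundle$slice_id,
                 snp_bin = bin, gene_bin = gene_bin,
                 h = h),
            class = "binned_genome")
}

#' @export
print.binned_genome <- function(x, ...) {
  cat(sprintf("binned_genome: %d bins x %d spots (%d chromosome(s))\n",
              nrow(x$bins), ncol(x$X), length(unique(x$bins$chrom))))
  invisible(x)
}

#' Run phasing and binning in one step
#'
#' @param bundle a filtered [raw_bundle()].
#' @param K_phase number of BAF clusters for the phasing HMM.
#' @param min_total per-bin minimum total allele count.
#' @param ... passed to [fit_phasing_hmm()].
#' @return list with \code{bg} (a \code{binned_genome}), \code{phasing}
#'   (model + assignment) and \code{bins}.
#' @export
phase_and_bin <- function(bundle, K_phase = 5, min_total = 300, ...) {
  pb <- pseudobulk(bundle)
  ph <- fit_phasing_hmm(pb, bundle$snp_index, K_phase = K_phase, ...)
  bins <- make_bins(bundle$snp_index, pb, min_total = min_total)
  bg <- aggregate_counts(bundle, ph$assignment$h, bins)
  list(bg = bg, phasing = ph, bins = bins)
}
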