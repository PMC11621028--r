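# Shared fixtures and small oracles, all built in code at test time.

# tiny raw bundle with explicit matrices (genes x spots, snps x spots)
toy_bundle <- function(X0, Y0, D0, S = NULL, slice_id = NULL,
                       snp_chrom = NULL, snp_pos = NULL,
                       gene_chrom = NULL, gene_start = NULL, gene_end = NULL,
                       ig = FALSE, hla = FALSE) {
  n <- ncol(X0)
  if (is.null(S)) S <- cbind(seq_len(n), 0)
  if (is.null(slice_id)) slice_id <- rep("s1", n)
  g <- nrow(X0); v <- nrow(Y0)
  if (is.null(snp_chrom)) snp_chrom <- rep("chr1", v)
  if (is.null(snp_pos)) snp_pos <- seq_len(v) * 100
  if (is.null(gene_chrom)) gene_chrom <- rep("chr1", g)
  if (is.null(gene_start)) gene_start <- seq_len(g) * 1000
  if (is.null(gene_end)) gene_end <- gene_start + 500
  raw_bundle(X0, Y0, D0, S, slice_id,
             data.frame(chrom = snp_chrom, pos = snp_pos, phase = 0L),
             data.frame(gene = paste0("g", seq_len(g)), chrom = gene_chrom,
                        start = gene_start, end = gene_end,
                        ig = rep_len(ig, g), hla = rep_len(hla, g)))
}

# minimal binned_genome built directly from matrices (bins x spots)
toy_bg <- function(X, Y, D, chrom = NULL, S = NULL, slice_id = NULL) {
  B <- nrow(Y); n <- ncol(Y)
  if (is.null(chrom)) chrom <- rep("chr1", B)
  if (is.null(S)) S <- cbind(seq_len(n), 0)
  if (is.null(slice_id)) slice_id <- rep("s1", n)
  if (is.null(X)) X <- matrix(0, B, n)
  structure(list(
    bins = data.frame(bin = seq_len(B), chrom = chrom, start = seq_len(B) * 1e3,
                      end = seq_len(B) * 1e3 + 500, n_snps = 1L, n_genes = 1L),
    X = X, Y = Y, D = D, S = S, slice_id = slice_id,
    snp_bin = seq_len(B), gene_bin = seq_len(B), h = rep(1L, B)),
    class = "binned_genome")
}

# adjusted Rand index (independent implementation for truth comparisons)
ari <- function(a, b) {
  t_ <- table(a, b)
  n <- sum(t_)
  si <- sum(choose(rowSums(t_), 2)); sj <- sum(choose(colSums(t_), 2))
  sij <- sum(choose(t_, 2))
  e <- si * sj / choose(n, 2)
  (sij - e) / ((si + sj) / 2 - e)
}

# beta-binomial pmf by numeric integration over a fine probability grid
# (independent oracle for the closed-form density)
bb_pmf_grid <- function(y, d, alpha, beta, ngrid = 20000) {
  p <- (seq_len(ngrid) - 0.5) / ngrid
  w <- stats::dbeta(p, alpha, beta) / ngrid
  sum(w * stats::dbinom(y, d, p))
}

# brute-force minimum star-homoplasy gains of one marker on a tree:
# smallest node set G such that leaves below G are exactly the carriers
brute_min_gains <- function(parent, nleaf, pres) {
  n <- length(parent)
  anc_or_self <- function(v) {
    out <- v
    while (parent[v] > 0) { v <- parent[v]; out <- c(out, v) }
    out
  }
  covers <- lapply(seq_len(nleaf), anc_or_self)
  best <- Inf
  for (mask in 0:(2^n - 1)) {
    G <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    if (length(G) >= best) next
    covered <- vapply(seq_len(nleaf), function(l) any(covers[[l]] %in% G),
                      logical(1))
    if (all(covered == (pres > 0))) best <- length(G)
  }
  best
}

# somatic-SNV cascade fixture: 6 candidate variants, 6 spots (3 normal,
# 3 tumor); each row exercises one rule; only variant 6 survives
snv_fixture <- function() {
  vt <- data.frame(
    chrom = "chr1", pos = 1:6 * 1000, ref = "A", alt = "T",
    germline = c(TRUE, FALSE, FALSE, FALSE, FALSE, FALSE),
    genic    = c(TRUE, FALSE, TRUE, TRUE, TRUE, TRUE))
  theta <- c(0.1, 0.2, 0.3, 0.9, 0.8, 0.7)
  normal <- 1:3; tumor <- 4:6
  AD <- matrix(0L, 6, 6); DP <- matrix(0L, 6, 6)
  DP[, normal] <- 10L                    # 30 normal reads each by default
  DP[, tumor] <- 10L
  AD[, tumor] <- 4L                      # tumor alt 12, VAF 0.4 by default
  AD[3, 1] <- 1L                         # v3: one alt read in a normal spot
  DP[4, normal] <- 4L                    # v4: normal depth 12 < 15
  AD[5, tumor] <- 1L                     # v5: tumor alt 3 < 5
  list(vt = vt, AD = AD, DP = DP, theta = theta)
}
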