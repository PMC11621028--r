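test_that("pseudobulk sums allele counts across spots", {
  b <- toy_bundle(matrix(1, 2, 2),
                  Y0 = rbind(c(1, 2), c(0, 3)),
                  D0 = rbind(c(2, 2), c(1, 4)))
  pb <- pseudobulk(b)
  expect_equal(pb$y0, c(3, 3))
  expect_equal(pb$d0, c(4, 5))
  one <- toy_bundle(matrix(1, 2, 1), Y0 = cbind(c(1, 0)), D0 = cbind(c(2, 1)))
  expect_equal(pseudobulk(one)$y0, c(1, 0))
})

test_that("phasing emissions are mirror-symmetric and match an integration oracle", {
  # p = 0.5: both phases identical
  expect_equal(phasing_emission_loglik(3, 10, 1, 0.5, 20),
               phasing_emission_loglik(3, 10, 2, 0.5, 20))
  # d = 0 carries no information
  expect_equal(phasing_emission_loglik(0, 0, 1, 0.2, 20), 0)
  # numeric-integration oracle for the beta-binomial pmf
  oracle <- log(bb_pmf_grid(2, 10, 20 * 0.1, 20 * 0.9))
  expect_equal(phasing_emission_loglik(2, 10, 1, 0.1, 20), oracle,
               tolerance = 1e-6)
  # haplotype 2 swaps the shape parameters
  expect_equal(phasing_emission_loglik(2, 10, 2, 0.1, 20),
               log(bb_pmf_grid(2, 10, 20 * 0.9, 20 * 0.1)), tolerance = 1e-6)
})

test_that("forward likelihood of the joint phasing HMM matches path enumeration", {
  set.seed(3)
  y <- c(1, 4, 0, 3, 2, 5); d <- c(5, 8, 3, 6, 4, 9)
  p <- c(0.2, 0.5); tau <- 15; t_ <- 0.9; q <- 0.95
  logE <- spacna:::phasing_logE(y, d, p, tau)
  logA <- log(spacna:::phasing_transition(2, t_, q))
  logpi <- rep(log(1 / 4), 4)
  chain <- rep(1, 6)
  fb <- spacna:::hmm_forward_backward(logE, logA, logpi, chain)
  enum <- spacna:::hmm_loglik_enumerate(logE, logA, logpi, chain)
  expect_equal(fb$loglik, enum, tolerance = 1e-10)
  # chain resets: two chromosomes of 3 SNPs factorise the likelihood
  chain2 <- rep(1:2, each = 3)
  fb2 <- spacna:::hmm_forward_backward(logE, logA, logpi, chain2)
  enum2 <- spacna:::hmm_loglik_enumerate(logE, logA, logpi, chain2)
  expect_equal(fb2$loglik, enum2, tolerance = 1e-10)
})

test_that("planted switch errors are corrected in imbalanced blocks", {
  set.seed(7)
  G <- 200
  # alternating imbalanced (BAF 0.2) and balanced blocks of 25 SNPs
  block <- rep(rep(c(TRUE, FALSE), each = 25), 4)
  p_true <- ifelse(block, 0.2, 0.5)
  d <- rpois(G, 40) + 10
  yB <- rbetabinom(G, d, 40 * p_true, 40 * (1 - p_true))
  # switch-error process: block flips
  flips <- runif(G) < 0.03
  e <- cumsum(flips) %% 2
  y <- ifelse(e == 0, yB, d - yB)
  snp_index <- data.frame(chrom = "chr1", pos = seq_len(G))
  fit <- fit_phasing_hmm(list(y0 = y, d0 = d), snp_index, K_phase = 3)
  h_true <- ifelse(e == 0, 1L, 2L)
  acc <- mean(fit$assignment$h[block] == h_true[block])
  expect_gte(max(acc, 1 - acc), 0.95)
  # EM monotonicity to numerical tolerance
  tr <- fit$model$trace
  expect_true(all(diff(tr) >= -1e-8 * (abs(tr[-length(tr)]) + 1)))
})

test_that("phase is unidentifiable on balanced data", {
  set.seed(1)
  d <- rep(40, 50)
  y <- rbinom(50, d, 0.5)
  fit <- fit_phasing_hmm(list(y0 = y, d0 = d),
                         data.frame(chrom = "chr1", pos = 1:50), K_phase = 1)
  expect_true(all(abs(fit$assignment$posterior_h1 - 0.5) < 0.35))
  expect_equal(mean(fit$assignment$posterior_h1), 0.5, tolerance = 0.05)
})

test_that("variable-length binning follows the greedy rule with end-of-chromosome exception", {
  si <- data.frame(chrom = rep("chr1", 4), pos = 1:4)
  b <- make_bins(si, list(y0 = rep(0, 4), d0 = c(5, 5, 5, 5)), min_total = 10)
  expect_equal(b$bin, c(1, 1, 2, 2))
  b2 <- make_bins(data.frame(chrom = rep("chr1", 3), pos = 1:3),
                  list(y0 = rep(0, 3), d0 = c(5, 5, 3)), min_total = 10)
  expect_equal(b2$bin, c(1, 1, 2))      # trailing deficient bin allowed
  b3 <- make_bins(si, list(y0 = rep(0, 4), d0 = rep(2, 4)), min_total = 1)
  expect_equal(b3$bin, 1:4)             # min 1: one bin per SNP
  # bins never span chromosomes
  si2 <- data.frame(chrom = rep(c("chr1", "chr2"), each = 2), pos = c(1, 2, 1, 2))
  b4 <- make_bins(si2, list(y0 = rep(0, 4), d0 = rep(100, 4)), min_total = 1000)
  expect_equal(b4$bin, c(1, 1, 2, 2))
})

test_that("aggregation applies the phase indicator formula and conserves totals", {
  Y0 <- rbind(c(3), c(1)); D0 <- rbind(c(5), c(4))
  b <- toy_bundle(matrix(0, 1, 1), Y0, D0, snp_pos = c(100, 200),
                  gene_start = 100, gene_end = 300)
  bins <- make_bins(b$snp_index, pseudobulk(b), min_total = 100)
  bg <- aggregate_counts(b, h = c(1L, 2L), bins)
  expect_equal(as.numeric(bg$Y), 3 + (4 - 1))
  expect_equal(as.numeric(bg$D), 9)
  # degenerate indicators
  bg1 <- aggregate_counts(b, h = c(1L, 1L), bins)
  expect_equal(as.numeric(bg1$Y), 4)
  bg2 <- aggregate_counts(b, h = c(2L, 2L), bins)
  expect_equal(as.numeric(bg2$Y), 9 - 4)
  # conservation of D per spot under any binning
  sim <- simulate_srt(sim_config(n_rows = 3, n_cols = 3, M = 1, n_chrom = 2,
                                 bins_per_chrom = 3, snps_per_bin = 4,
                                 genes_per_bin = 2, transcripts_per_spot = 200,
                                 allele_umis_per_spot = 100, n_loh = 1,
                                 mirrored = FALSE, seed = 5))
  pb <- pseudobulk(sim$bundle)
  bins2 <- make_bins(sim$bundle$snp_index, pb, min_total = 150)
  h <- sample(1:2, nrow(sim$bundle$Y0), replace = TRUE)
  bg3 <- aggregate_counts(sim$bundle, h, bins2)
  expect_equal(colSums(bg3$D), Matrix::colSums(sim$bundle$D0),
               ignore_attr = TRUE)
  # label-swap symmetry: flipping h and Y0 -> D0 - Y0 leaves |0.5 - BAF| as is
  b_sw <- sim$bundle
  b_sw$Y0 <- b_sw$D0 - b_sw$Y0
  bg_sw <- aggregate_counts(b_sw, 3L - h, bins2)
  baf <- bg3$Y / pmax(bg3$D, 1); baf_sw <- bg_sw$Y / pmax(bg_sw$D, 1)
  expect_equal(abs(0.5 - baf), abs(0.5 - baf_sw), tolerance = 1e-12)
})
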