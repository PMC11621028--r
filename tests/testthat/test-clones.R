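test_that("spatial graph has hexagonal neighbourhoods and alignment edges", {
  S <- spacna:::hex_lattice(10, 10)
  g <- build_graph(S, rep("s1", 100), k_spatial = 6)
  deg <- vapply(g$nbr, length, integer(1))
  # spots at least two rings from the boundary have exactly 6 neighbours
  # (boundary spots reach further for their k nearest, inflating first-ring
  # degrees under the symmetrised union)
  deep <- S[, 1] > min(S[, 1]) + 180 & S[, 1] < max(S[, 1]) - 180 &
          S[, 2] > min(S[, 2]) + 180 & S[, 2] < max(S[, 2]) - 180
  expect_gt(sum(deep), 0)
  expect_true(all(deg[deep] == 6))
  # two slices with identity-like alignment: one inter-slice edge per spot
  S2 <- rbind(S, S)
  sl <- rep(c("a", "b"), each = 100)
  W <- diag(100)
  g2 <- build_graph(S2, sl, W = W, k_spatial = 6)
  inter <- g2$edges[g2$edges$i <= 100 & g2$edges$j > 100, ]
  expect_equal(nrow(inter), 100)
  expect_equal(inter$j - inter$i, rep(100, 100))
  # expr_weight = 0 leaves the spatial graph unchanged
  g3 <- build_graph(S, rep("s1", 100), k_spatial = 6, expr_weight = 0)
  expect_equal(g3$edges, g$edges)
})

test_that("admixture mixing reduces to the documented limits", {
  st <- make_cn_states(7)
  # theta = 0: every state is pure normal
  expect_true(all(abs(spacna:::rdr_eff(st$mu, 0) - 1) < 1e-12))
  expect_true(all(abs(spacna:::baf_eff(st$p, st$mu, 0) - 0.5) < 1e-12))
  # theta = 1: parameters act unmixed
  expect_equal(spacna:::rdr_eff(st$mu, 1), st$mu)
  expect_equal(spacna:::baf_eff(st$p, st$mu, 1), st$p)
  # LOH state p = 0 at theta = 0.5, mu = 1 matches the purity forward formula
  expect_equal(spacna:::baf_eff(0, 1, 0.5), loh_baf_forward(0.5, 1))
  expect_equal(spacna:::baf_eff(0, 1, 0.5), 0.25)
})

test_that("emission likelihood is mirror-symmetric in haplotype orientation", {
  set.seed(1)
  B <- 8; N <- 5
  D <- matrix(rpois(B * N, 20), B); Y <- matrix(rbinom(B * N, D, 0.3), B)
  X <- matrix(rpois(B * N, 50), B)
  lam <- rep(1 / B, B); Ts <- colSums(X); th <- rep(1, N)
  ll1 <- emission_loglik(X, Y, D, lam, Ts, th, rep(1, N), mu = 1.2, p = 0.3,
                         phi = 0.1, tau_bb = 25)
  ll2 <- emission_loglik(X, D - Y, D, lam, Ts, th, rep(1, N), mu = 1.2, p = 0.7,
                         phi = 0.1, tau_bb = 25)
  expect_equal(ll1, ll2, tolerance = 1e-12)
})

test_that("clone-state HMM forward pass matches exhaustive enumeration", {
  set.seed(5)
  logE <- matrix(log(runif(6 * 2)), 6, 2)
  logA <- log(spacna:::cn_transition(2, 0.9))
  logpi <- rep(log(0.5), 2)
  fb <- spacna:::hmm_forward_backward(logE, logA, logpi, rep(1, 6))
  expect_equal(fb$loglik,
               spacna:::hmm_loglik_enumerate(logE, logA, logpi, rep(1, 6)),
               tolerance = 1e-10)
})

test_that("label update matches exhaustive maximisation on a path graph", {
  # constructed emissions: two spatially coherent halves with one noisy spot
  ll <- rbind(c(2, 0), c(1.2, 0.8), c(0, 2), c(0.5, 1.5))
  S <- cbind(1:4, 0)
  g <- build_graph(S, rep("s1", 4), k_spatial = 1)   # path 1-2-3-4
  beta <- 1.0
  obj <- function(ell) sum(ll[cbind(1:4, ell)]) +
    beta * spacna:::potts_energy(ell, g)
  labs <- as.matrix(expand.grid(rep(list(1:2), 4)))
  best <- labs[which.max(apply(labs, 1, obj)), ]
  got <- hmrf_update(ll, g, beta, ell = max.col(ll))
  expect_equal(obj(got), obj(best))
  expect_equal(got, c(1L, 1L, 2L, 2L))
  # beta = 0: per-spot maximum likelihood
  set.seed(9)
  llr <- matrix(rnorm(4 * 2), 4, 2)
  expect_equal(hmrf_update(llr, g, 0, rep(1L, 4)), max.col(llr))
  # large beta on a connected graph: one label everywhere
  expect_length(unique(hmrf_update(llr, g, 1e6, rep(1L, 4))), 1)
  # random instances: the result is always a local maximum (no single-spot
  # flip improves) and never decreases the objective of its initialisation
  for (rep_ in 1:10) {
    llr <- matrix(rnorm(4 * 3), 4, 3)
    init <- sample(1:3, 4, replace = TRUE)
    res <- hmrf_update(llr, g, 1.5, init)
    o <- function(ell) sum(llr[cbind(1:4, ell)]) +
      1.5 * spacna:::potts_energy(ell, g)
    expect_gte(o(res), o(init))
    for (s in 1:4) for (m in 1:3) {
      alt <- res; alt[s] <- m
      expect_lte(o(alt), o(res) + 1e-12)
    }
  }
})

test_that("state parameters are recovered on synthetic clone data", {
  sim <- simulate_srt(sim_config(n_rows = 10, n_cols = 10, M = 2, n_chrom = 4,
                                 bins_per_chrom = 12, snps_per_bin = 6,
                                 genes_per_bin = 3, transcripts_per_spot = 2500,
                                 allele_umis_per_spot = 300, n_loh = 3,
                                 mirrored = FALSE, seed = 21))
  flt <- apply_filters(sim$bundle)
  pb <- suppressWarnings(phase_and_bin(flt$bundle, min_total = 400))
  bg <- pb$bg
  hm <- suppressWarnings(
    hmm_update(bg, ell = sim$truth$ell, lambda = rep(1 / nrow(bg$bins), nrow(bg$bins))))
  # hard-EM objective is monotone
  expect_true(all(diff(hm$trace) >= -1e-6 * (abs(hm$trace[-length(hm$trace)]) + 1)))
  # planted CNLOH / deletion states: some state should sit near BAF 0 and
  # the occupied imbalanced states' RDR should be within 0.1 of truth
  occ <- sort(unique(as.vector(hm$Z)))
  st <- hm$states[occ, ]
  imb <- st[abs(st$p - 0.5) > 0.2, ]
  expect_gte(nrow(imb), 1)
  expect_true(any(pmin(imb$p, 1 - imb$p) < 0.1))
  # clones sharing a planted event agree on its state
  shared <- which(sim$truth$A[, 1] == sim$truth$A[, 2] &
                    sim$truth$B[, 1] == sim$truth$B[, 2] &
                    sim$truth$A[, 1] != sim$truth$B[, 1])
  if (length(shared) && ncol(hm$Z) == 2) {
    tb <- vapply(seq_len(nrow(bg$bins)), function(j) {
      sb <- sim$truth$snp_bin[bg$snp_bin == j]
      as.integer(names(sort(table(sb), decreasing = TRUE))[1])
    }, integer(1))
    on_shared <- which(tb %in% shared)
    expect_gte(mean(hm$Z[on_shared, 1] == hm$Z[on_shared, 2]), 0.9)
  }
})

test_that("joint fit recovers planted clones and merges redundant ones", {
  sim <- simulate_srt(sim_config(n_rows = 10, n_cols = 10, M = 2, n_chrom = 3,
                                 bins_per_chrom = 10, snps_per_bin = 8,
                                 genes_per_bin = 4, transcripts_per_spot = 2000,
                                 allele_umis_per_spot = 250, n_loh = 3,
                                 mirrored = FALSE, normal_region = FALSE,
                                 seed = 5))
  flt <- apply_filters(sim$bundle)
  pb <- suppressWarnings(phase_and_bin(flt$bundle, min_total = 400))
  bg <- pb$bg
  base <- baseline_profile(bg)
  graph <- build_graph(bg$S, bg$slice_id)
  model <- suppressWarnings(
    fit_clones(bg, base, graph, M_init = 4, K = 7, seed = 0, outer_max = 6))
  expect_gte(ari(model$ell, sim$truth$ell), 0.9)
  expect_equal(ncol(model$Z), 2)
  # joint objective non-decreasing across outer iterations
  expect_true(all(diff(model$objective) >=
                    -1e-6 * (abs(model$objective[-length(model$objective)]) + 1)))
})

test_that("a single planted clone collapses to one profile", {
  sim <- simulate_srt(sim_config(n_rows = 7, n_cols = 7, M = 1, n_chrom = 2,
                                 bins_per_chrom = 10, snps_per_bin = 6,
                                 genes_per_bin = 3, transcripts_per_spot = 1500,
                                 allele_umis_per_spot = 200, n_loh = 2,
                                 mirrored = FALSE, normal_region = FALSE,
                                 seed = 13))
  flt <- apply_filters(sim$bundle)
  pb <- suppressWarnings(phase_and_bin(flt$bundle, min_total = 400))
  base <- baseline_profile(pb$bg)
  graph <- build_graph(pb$bg$S, pb$bg$slice_id)
  model <- suppressWarnings(
    fit_clones(pb$bg, base, graph, M_init = 3, K = 5, seed = 1, outer_max = 5))
  expect_equal(ncol(model$Z), 1)
})

test_that("spot order only permutes labels", {
  set.seed(11)
  n <- 20
  S <- cbind(runif(n), runif(n))
  ll <- matrix(rnorm(n * 2, sd = 3), n, 2)
  g <- build_graph(S, rep("s1", n), k_spatial = 3)
  ell <- hmrf_update(ll, g, 0, rep(1L, n))   # beta 0: order-free by definition
  perm <- sample(n)
  gp <- build_graph(S[perm, ], rep("s1", n), k_spatial = 3)
  ellp <- hmrf_update(ll[perm, ], gp, 0, rep(1L, n))
  expect_equal(ellp, ell[perm])
})
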