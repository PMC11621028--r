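# Joint inference of copy-number states along the genome (HMM) and clone
# labels over space (hidden Markov random field), by block coordinate ascent.
#
# All three updates -- Viterbi re-estimation of the state paths Z, 1-D
# conditional maximisations of the state parameters, and iterated
# conditional modes on the clone labels -- ascend one shared objective,
#   F = sum_s sum_j log P(x_js, y_js | z_{j, l_s}; params)
#       + sum_m log P(Z_m)  +  beta * sum_edges w 1[l_i = l_j],
# so the trace reported by fit_clones() is non-decreasing by construction.

#' Default copy-number state space
#'
#' Paired-orientation state table: every allelically imbalanced state is
#' present in both haplotype orientations (BAF p and 1 - p), the two sharing
#' one RDR value, so mirrored events in different clones map to mirrored
#' states. State 1 is the balanced-diploid anchor (RDR fixed at 1, BAF fixed
#' at 0.5), which pins the otherwise scale-free RDR.
#'
#' @param K total number of states; must be odd (1 balanced + mirror pairs).
#' @return data.frame with columns \code{mu}, \code{p}, \code{pair}
#'   (mirror-pair id), \code{balanced}.
#' @export
make_cn_states <- function(K = 7) {
  stopifnot(K >= 1, K %% 2 == 1)
  npair <- (K - 1) / 2
  mu0 <- c(0.55, 1.0, 1.45, 0.75, 1.9, 1.2)[seq_len(npair)]
  p0 <- c(0.12, 0.22, 0.35, 0.30, 0.40, 0.45)[seq_len(npair)]
  df <- data.frame(mu = 1, p = 0.5, pair = 0L, balanced = TRUE)
  for (i in seq_len(npair)) {
    df <- rbind(df,
      data.frame(mu = mu0[i], p = p0[i],     pair = i, balanced = FALSE),
      data.frame(mu = mu0[i], p = 1 - p0[i], pair = i, balanced = FALSE))
  }
  rownames(df) <- NULL
  df
}

# normal-admixture mixing of state parameters with tumor proportion theta:
# a spot with proportion theta of tumor cells in state (mu, p) and 1 - theta
# normal cells has effective relative depth theta*mu + (1-theta) and
# effective BAF (theta*p*mu + 0.5*(1-theta)) / (theta*mu + (1-theta)).
rdr_eff <- function(mu, theta) theta * mu + (1 - theta)
baf_eff <- function(p, mu, theta) {
  (theta * p * mu + 0.5 * (1 - theta)) / rdr_eff(mu, theta)
}

#' Spatial neighbour graph over spots
#'
#' Union of per-slice k-nearest-neighbour graphs in spatial coordinates
#' (weight 1, symmetrised), optional inter-slice edges taken from a slice
#' alignment matrix (entries above \code{w_threshold}; weight = alignment
#' mass), and optional expression-space kNN edges scaled by
#' \code{expr_weight}.
#'
#' @param S spot x 2 coordinate matrix.
#' @param slice_id per-spot slice labels.
#' @param W alignment: a matrix for two slices, or a list of matrices for
#'   consecutive slice pairs (rows = spots of the earlier slice, columns =
#'   spots of the later one, in spot order within slice). NULL for none.
#' @param k_spatial intra-slice neighbourhood size (default 6, the hexagonal
#'   Visium lattice).
#' @param expr_weight weight of expression-similarity edges (default 0 = off).
#' @param expr_features spot x feature matrix for expression kNN.
#' @param w_threshold minimum alignment mass for an inter-slice edge.
#' @return list with \code{edges} (data.frame i, j, w with i < j) and
#'   per-spot adjacency lists \code{nbr}, \code{wts}.
#' @export
build_graph <- function(S, slice_id, W = NULL, k_spatial = 6,
                        expr_weight = 0, expr_features = NULL,
                        w_threshold = 0) {
  n <- nrow(S)
  stopifnot(length(slice_id) == n)
  slices <- unique(slice_id)
  ei <- integer(0); ej <- integer(0); ew <- numeric(0)
  for (sl in slices) {
    idx <- which(slice_id == sl)
    if (length(idx) < 2) next
    nn <- knn_indices(S[idx, , drop = FALSE], k_spatial)
    for (kk in seq_len(ncol(nn))) {
      ei <- c(ei, idx); ej <- c(ej, idx[nn[, kk]]); ew <- c(ew, rep(1, length(idx)))
    }
  }
  if (!is.null(W)) {
    if (is.matrix(W)) W <- list(W)
    if (length(W) != length(slices) - 1)
      stop("need one alignment matrix per consecutive slice pair")
    for (a in seq_along(W)) {
      ia <- which(slice_id == slices[a]); ib <- which(slice_id == slices[a + 1])
      if (!identical(dim(W[[a]]), c(length(ia), length(ib))))
        stop("alignment matrix dimensions do not match slice spot counts")
      hit <- which(W[[a]] > w_threshold, arr.ind = TRUE)
      if (nrow(hit)) {
        ei <- c(ei, ia[hit[, 1]]); ej <- c(ej, ib[hit[, 2]])
        ew <- c(ew, W[[a]][hit])
      }
    }
  }
  if (expr_weight > 0) {
    stopifnot(!is.null(expr_features), nrow(expr_features) == n)
    nn <- knn_indices(expr_features, k_spatial)
    for (kk in seq_len(ncol(nn))) {
      ei <- c(ei, seq_len(n)); ej <- c(ej, nn[, kk])
      ew <- c(ew, rep(expr_weight, n))
    }
  }
  # symmetrise: keep each undirected pair once with the maximum weight
  lo <- pmin(ei, ej); hi <- pmax(ei, ej)
  keep <- lo != hi
  key <- paste(lo[keep], hi[keep])
  agg <- tapply(ew[keep], key, max)
  parts <- do.call(rbind, strsplit(names(agg), " "))
  edges <- data.frame(i = as.integer(parts[, 1]), j = as.integer(parts[, 2]),
                      w = as.numeric(agg))
  edges <- edges[order(edges$i, edges$j), , drop = FALSE]
  rownames(edges) <- NULL
  nbr <- vector("list", n); wts <- vector("list", n)
  for (r in seq_len(nrow(edges))) {
    nbr[[edges$i[r]]] <- c(nbr[[edges$i[r]]], edges$j[r])
    nbr[[edges$j[r]]] <- c(nbr[[edges$j[r]]], edges$i[r])
    wts[[edges$i[r]]] <- c(wts[[edges$i[r]]], edges$w[r])
    wts[[edges$j[r]]] <- c(wts[[edges$j[r]]], edges$w[r])
  }
  list(edges = edges, nbr = nbr, wts = wts, n = n)
}

cn_transition <- function(K, t_cn) {
  A <- matrix((1 - t_cn) / max(K - 1, 1), K, K)
  diag(A) <- if (K > 1) t_cn else 1
  A
}

#' Per-spot per-bin emission log-likelihood for one state
#'
#' Transcript term: negative binomial with mean
#' \code{T_s * lambda_j * rdr_eff(mu, theta_s) / c_s}, where \code{c_s} is
#' the scale of the clone the spot is being evaluated under (a free
#' parameter absorbing the genome-wide expected depth of the clone's
#' profile). Allele term: beta-binomial with mean
#' \code{baf_eff(p, mu, theta_s)} and concentration \code{tau_bb}. With
#' theta = 0 every state reduces to the pure-normal (RDR 1, BAF 0.5)
#' emission; with theta = 1 the state parameters act unmixed.
#'
#' @param X,Y,D bin x spot count matrices (retained bins).
#' @param lam per-bin baseline proportions.
#' @param Ts per-spot transcript totals over retained bins.
#' @param theta per-spot tumor proportions.
#' @param c_s per-spot scale (clone scale of the profile being evaluated).
#' @param mu,p state RDR and BAF.
#' @param phi,tau_bb NB dispersion and BB concentration.
#' @param use_rdr,use_baf include transcript / allele term.
#' @return bin x spot matrix of log-likelihoods.
#' @export
emission_loglik <- function(X, Y, D, lam, Ts, theta, c_s, mu, p,
                            phi, tau_bb, use_rdr = TRUE, use_baf = TRUE) {
  B <- nrow(Y); N <- ncol(Y)
  ll <- matrix(0, B, N)
  if (use_rdr && !is.null(X)) {
    re <- rdr_eff(mu, theta)                       # length N
    mu_mat <- outer(lam, Ts * re / c_s)
    ll <- ll + stats::dnbinom(X, size = 1 / phi, mu = pmax(mu_mat, 1e-12),
                              log = TRUE)
  }
  if (use_baf) {
    be <- pmin(pmax(baf_eff(p, mu, theta), 1e-6), 1 - 1e-6)  # length N
    a_ <- matrix(tau_bb * be, B, N, byrow = TRUE)
    ll <- ll + dbetabinom(Y, D, a_, tau_bb - a_)
  }
  ll
}

#' Copy-number state HMM update (genome axis)
#'
#' Given fixed clone labels, runs hard (Viterbi) EM over the concatenated
#' per-clone chromosome chains: the per-clone emission of a bin/state is the
#' sum of the member spots' per-spot log-likelihoods ([emission_loglik()]),
#' the MAP state paths Z are re-decoded each iteration, and the state
#' parameters (shared RDR per mirror pair, mirrored BAF, per-clone scale,
#' NB dispersion, BB concentration, self-transition probability) are updated
#' by exact conditional maximisation given Z. Each sub-step ascends the same
#' joint objective, so the returned trace is non-decreasing. Mirror-paired
#' states share RDR and have BAF p and 1 - p; the balanced state is fixed at
#' (1, 0.5), anchoring the RDR scale. Tumor proportions, when supplied, mix
#' every state with the normal state per spot.
#'
#' @param bg a \code{binned_genome}.
#' @param ell per-spot clone labels in 1..M (0 = excluded).
#' @param lambda per-bin baseline proportions (0 for masked bins).
#' @param states state table from [make_cn_states()] (current values used as
#'   initialisation).
#' @param theta optional per-spot tumor proportions.
#' @param phi,tau_bb initial NB dispersion / BB concentration.
#' @param t_cn initial state self-transition probability.
#' @param c_scale optional per-clone scale initial values.
#' @param Z0 optional bin x clone initial state matrix (retained bins only
#'   are used).
#' @param use_rdr,use_baf include the transcript / allele emission terms.
#' @param max_iter,tol iteration control.
#' @return list with updated \code{states}, \code{Z} (bin x clone MAP states;
#'   masked bins get the balanced state), \code{c_scale}, \code{phi},
#'   \code{tau_bb}, \code{t_cn}, objective \code{trace}, \code{score}
#'   (emission + transition part of the joint objective), \code{retained}
#'   bin mask and the surviving clone ids \code{clones}.
#' @export
hmm_update <- function(bg, ell, lambda, states = make_cn_states(7),
                       theta = NULL, phi = 0.1, tau_bb = 30, t_cn = 1 - 5e-3,
                       c_scale = NULL, Z0 = NULL,
                       use_rdr = TRUE, use_baf = TRUE,
                       max_iter = 10, tol = 1e-6) {
  present <- sort(unique(ell[ell > 0]))
  if (!length(present)) stop("no spots assigned to any clone")
  if (length(present) < max(ell)) warning("empty clone(s) dropped from HMM update")
  retained <- lambda > 0 | !use_rdr
  Bn <- sum(retained)
  K <- nrow(states)
  N <- ncol(bg$X)
  if (is.null(theta)) theta <- rep(1, N)
  use <- ell > 0
  Xr <- bg$X[retained, use, drop = FALSE]
  Yr <- bg$Y[retained, use, drop = FALSE]
  Dr <- bg$D[retained, use, drop = FALSE]
  th <- theta[use]
  lu <- match(ell[use], present)
  Mp <- length(present)
  lam <- lambda[retained]; lam <- lam / sum(lam)
  Ts <- colSums(Xr)
  chrom <- bg$bins$chrom[retained]
  chain_of_clone <- function(m) paste0(m, "_", chrom)
  balanced <- which(states$balanced)[1]
  if (is.null(c_scale)) c_scale <- rep(1, Mp)
  c_scale <- rep_len(c_scale, Mp)
  Z <- if (!is.null(Z0)) matrix(Z0[retained, seq_len(Mp)], Bn, Mp)
       else matrix(balanced, Bn, Mp)
  ind <- Matrix::sparseMatrix(i = seq_along(lu), j = lu, x = 1,
                              dims = c(length(lu), Mp))
  logpi <- rep(log(1 / K), K)
  trace <- numeric(0)
  score <- -Inf
  for (it in seq_len(max_iter)) {
    # per-state per-spot log-likelihood, then pooled per clone
    LL <- array(NA_real_, c(Bn, length(lu), K))
    cs <- c_scale[lu]
    for (k in seq_len(K))
      LL[, , k] <- emission_loglik(Xr, Yr, Dr, lam, Ts, th, cs,
                                   states$mu[k], states$p[k], phi, tau_bb,
                                   use_rdr, use_baf)
    Em <- vapply(seq_len(K), function(k)
      as.matrix(LL[, , k] %*% ind), matrix(0, Bn, Mp))   # Bn x Mp x K
    logE <- do.call(rbind, lapply(seq_len(Mp), function(m) Em[, m, ]))
    chain <- unlist(lapply(seq_len(Mp), chain_of_clone))
    logA <- log(cn_transition(K, t_cn))
    path <- hmm_viterbi(logE, logA, logpi, chain)
    Z <- matrix(path, Bn, Mp)
    # objective: emissions at the decoded path + transition log-probs
    emis <- sum(logE[cbind(seq_along(path), path)])
    tr_pairs <- 0; tr_self <- 0
    for (m in seq_len(Mp)) for (ch in unique(chrom)) {
      z <- Z[chrom == ch, m]
      if (length(z) > 1) {
        tr_pairs <- tr_pairs + length(z) - 1
        tr_self <- tr_self + sum(z[-1] == z[-length(z)])
      }
    }
    trans_score <- tr_self * log(t_cn) +
      (tr_pairs - tr_self) * log((1 - t_cn) / max(K - 1, 1)) +
      Mp * length(unique(chrom)) * logpi[1]
    score <- emis + trans_score
    trace <- c(trace, score)
    if (it > 1 && trace[it] - trace[it - 1] <= tol * (abs(trace[it - 1]) + 1)) break
    # conditional maximisations given Z
    # clamp away from 1: hard EM on an all-balanced decode would otherwise
    # drive the self-transition to its ceiling, making any short event's two
    # chain crossings prohibitively expensive (a self-reinforcing attractor)
    if (K > 1 && tr_pairs > 0)
      t_cn <- min(max(tr_self / tr_pairs, 0.5), 0.995)
    zcols <- Z[, lu, drop = FALSE]                 # Bn x spots: state per entry
    for (pr in unique(states$pair[states$pair > 0])) {
      ks <- which(states$pair == pr)
      sel1 <- zcols == ks[1]; sel2 <- zcols == ks[2]
      if (!any(sel1) && !any(sel2)) next
      th_m <- matrix(th, Bn, length(lu), byrow = TRUE)
      cs_m <- matrix(cs, Bn, length(lu), byrow = TRUE)
      Tl_m <- outer(lam, Ts)
      pick <- function(M_, sel) M_[sel]
      if (use_rdr) {
        obj_mu <- function(lmu) {
          mu <- exp(lmu)
          v <- 0
          for (sel in list(sel1, sel2)) {
            if (!any(sel)) next
            mm <- pick(Tl_m, sel) * rdr_eff(mu, pick(th_m, sel)) / pick(cs_m, sel)
            v <- v + sum(stats::dnbinom(pick(Xr, sel), size = 1 / phi,
                                        mu = pmax(mm, 1e-12), log = TRUE))
          }
          -v
        }
        states$mu[ks] <- exp(stats::optimize(obj_mu, c(log(0.05), log(8)),
                                             tol = 1e-4)$minimum)
      }
      if (use_baf) {
        obj_p <- function(pp) {
          v <- 0
          mu <- states$mu[ks[1]]
          for (i in 1:2) {
            sel <- if (i == 1) sel1 else sel2
            if (!any(sel)) next
            p_i <- if (i == 1) pp else 1 - pp
            be <- pmin(pmax(baf_eff(p_i, mu, pick(th_m, sel)), 1e-6), 1 - 1e-6)
            v <- v + sum(dbetabinom(pick(Yr, sel), pick(Dr, sel),
                                    tau_bb * be, tau_bb * (1 - be)))
          }
          -v
        }
        states$p[ks[1]] <- stats::optimize(obj_p, c(1e-4, 0.5), tol = 1e-5)$minimum
        states$p[ks[2]] <- 1 - states$p[ks[1]]
      }
    }
    if (use_rdr) {
      # per-clone scale and shared dispersion
      mu_z <- matrix(states$mu[zcols], Bn, length(lu))
      re <- rdr_eff(mu_z, matrix(th, Bn, length(lu), byrow = TRUE))
      base_mean <- outer(lam, Ts) * re
      for (m in seq_len(Mp)) {
        cols <- which(lu == m)
        if (!length(cols)) next
        xm <- Xr[, cols, drop = FALSE]; bm <- base_mean[, cols, drop = FALSE]
        obj_c <- function(lc)
          -sum(stats::dnbinom(xm, size = 1 / phi,
                              mu = pmax(bm / exp(lc), 1e-12), log = TRUE))
        c_scale[m] <- exp(stats::optimize(obj_c, c(log(0.2), log(5)),
                                          tol = 1e-4)$minimum)
      }
      cs <- c_scale[lu]
      mean_all <- base_mean / matrix(cs, Bn, length(lu), byrow = TRUE)
      obj_phi <- function(lp)
        -sum(stats::dnbinom(Xr, size = exp(-lp), mu = pmax(mean_all, 1e-12),
                            log = TRUE))
      phi <- exp(stats::optimize(obj_phi, c(log(1e-4), log(2)), tol = 1e-3)$minimum)
    }
    if (use_baf) {
      p_z <- matrix(states$p[zcols], Bn, length(lu))
      mu_z <- matrix(states$mu[zcols], Bn, length(lu))
      be <- pmin(pmax(baf_eff(p_z, mu_z, matrix(th, Bn, length(lu), byrow = TRUE)),
                      1e-6), 1 - 1e-6)
      obj_tau <- function(lt)
        -sum(dbetabinom(Yr, Dr, exp(lt) * be, exp(lt) * (1 - be)))
      tau_bb <- exp(stats::optimize(obj_tau, c(log(2), log(5000)), tol = 1e-3)$minimum)
    }
  }
  Zfull <- matrix(balanced, nrow(bg$bins), Mp)
  Zfull[retained, ] <- Z
  list(states = states, Z = Zfull, c_scale = c_scale, phi = phi,
       tau_bb = tau_bb, t_cn = t_cn, score = score,
       trans_score = trans_score, trace = trace,
       retained = retained, clones = present, lambda_used = lam)
}

# Per-spot per-clone total emission log-likelihood under fitted states/Z.
# Column m evaluates every spot under clone m's state path and scale.
spot_clone_loglik <- function(bg, hm, theta = NULL,
                              use_rdr = TRUE, use_baf = TRUE) {
  N <- ncol(bg$X)
  if (is.null(theta)) theta <- rep(1, N)
  retained <- hm$retained
  lam <- hm$lambda_used
  st <- hm$states
  X <- bg$X[retained, , drop = FALSE]
  Y <- bg$Y[retained, , drop = FALSE]
  D <- bg$D[retained, , drop = FALSE]
  Ts <- colSums(X)
  Mp <- ncol(hm$Z)
  out <- matrix(0, N, Mp)
  for (m in seq_len(Mp)) {
    z <- hm$Z[retained, m]
    ll <- matrix(0, sum(retained), N)
    for (k in unique(z)) {
      rows <- z == k
      ll[rows, ] <- emission_loglik(
        X[rows, , drop = FALSE], Y[rows, , drop = FALSE],
        D[rows, , drop = FALSE], lam[rows], Ts, theta,
        rep(hm$c_scale[m], N), st$mu[k], st$p[k], hm$phi, hm$tau_bb,
        use_rdr, use_baf)
    }
    out[, m] <- colSums(ll)
  }
  out
}

#' Clone label update by iterated conditional modes (space axis)
#'
#' Maximises the Potts-form objective
#' \code{sum_s loglik(s, l_s) + beta * sum_edges w * 1[l_i = l_j]} by
#' coordinate-wise sweeps in spot order; ties go to the lowest clone index.
#' The objective is non-decreasing per move, so sweeps terminate.
#'
#' @param ll N x M per-spot per-clone log-likelihoods.
#' @param graph from [build_graph()].
#' @param beta spatial coherence weight per unit edge weight.
#' @param ell initial labels.
#' @param fixed optional logical mask of spots whose label may not change.
#' @param max_sweeps sweep cap.
#' @return integer label vector.
#' @export
hmrf_update <- function(ll, graph, beta, ell, fixed = NULL, max_sweeps = 50) {
  N <- nrow(ll); M <- ncol(ll)
  stopifnot(length(ell) == N)
  if (is.null(fixed)) fixed <- rep(FALSE, N)
  for (sw in seq_len(max_sweeps)) {
    changed <- FALSE
    for (s in seq_len(N)) {
      if (fixed[s]) next
      score <- ll[s, ]
      nb <- graph$nbr[[s]]
      if (length(nb)) {
        wv <- graph$wts[[s]]
        for (m in seq_len(M))
          score[m] <- score[m] + beta * sum(wv[ell[nb] == m])
      }
      best <- which.max(score)   # first maximiser = lowest index on ties
      if (best != ell[s]) { ell[s] <- best; changed <- TRUE }
    }
    if (!changed) break
  }
  ell
}

# Potts prior value of a labelling (for the joint objective trace)
potts_energy <- function(ell, graph) {
  e <- graph$edges
  sum(e$w[ell[e$i] == ell[e$j]])
}

# initial partition by k-means on per-spot phased-BAF profiles (uncovered
# bins imputed at the balanced value): starts the ascent near the allelic
# structure instead of at an arbitrary spatial split, which matters because
# ICM cannot cross the Potts energy barrier one spot at a time
init_labels_baf <- function(bg, M, seed = 0) {
  baf <- t(bg$Y / bg$D)
  baf[!is.finite(baf)] <- 0.5
  uniq <- nrow(unique(round(baf, 10)))
  if (uniq < M) return(NULL)
  set.seed(seed)
  km <- suppressWarnings(stats::kmeans(baf, centers = M, nstart = 5,
                                       iter.max = 50))
  km$cluster
}

# fallback: spatially contiguous partition, M seed spots chosen by seeded
# RNG, labels grown outward over the neighbour graph (BFS order)
init_labels_region_grow <- function(graph, M, seed = 0) {
  n <- graph$n
  set.seed(seed)
  seeds <- sample.int(n, M)
  ell <- integer(n)
  ell[seeds] <- seq_len(M)
  queue <- seeds
  while (length(queue)) {
    s <- queue[1]; queue <- queue[-1]
    for (nb in graph$nbr[[s]]) {
      if (ell[nb] == 0L) { ell[nb] <- ell[s]; queue <- c(queue, nb) }
    }
  }
  ell[ell == 0L] <- 1L
  ell
}

#' Joint clone and copy-number inference
#'
#' Block coordinate ascent for the joint model: alternates the genome-axis
#' state update ([hmm_update()], clone labels fixed) with the space-axis
#' label update ([hmrf_update()], states fixed) until the joint objective
#' (emission log-likelihood + state-transition term + Potts coherence term)
#' stops improving; the trace is non-decreasing by construction. Optionally
#' appends an always-balanced normal profile that spots may choose, pinning
#' spots with supplied tumor proportion below 0.5 to it.
#'
#' @param bg a \code{binned_genome}.
#' @param baseline output of [baseline_profile()].
#' @param graph spatial graph from [build_graph()].
#' @param M_init initial number of tumor clones.
#' @param K number of copy-number states (odd; see [make_cn_states()]).
#' @param theta optional per-spot tumor proportions.
#' @param beta spatial coherence weight (default 2).
#' @param normal_clone append an always-balanced normal profile.
#' @param pin_normal with \code{theta}: pin spots with theta < 0.5 to the
#'   normal profile.
#' @param seed seed for the initial spatially contiguous partition.
#' @param outer_max,tol outer-loop control.
#' @param merge merge near-identical clones afterwards ([merge_clones()]).
#' @param sim_threshold merge threshold (fraction of differing bins).
#' @param use_rdr,use_baf emission terms to include.
#' @return a \code{clone_model}: clone labels \code{ell} (0 = normal profile
#'   when enabled), state matrix \code{Z}, state table, dispersion
#'   parameters, per-clone scales, objective trace, and bookkeeping.
#' @export
fit_clones <- function(bg, baseline, graph, M_init = 5, K = 7, theta = NULL,
                       beta = 2.0, normal_clone = FALSE, pin_normal = !is.null(theta),
                       seed = 0, outer_max = 10, tol = 1e-4,
                       merge = TRUE, sim_threshold = 0.02,
                       use_rdr = TRUE, use_baf = TRUE) {
  stopifnot(M_init >= 1, K >= 1)
  N <- ncol(bg$X)
  lambda <- baseline$lambda
  ell <- init_labels_baf(bg, M_init, seed = seed)
  if (is.null(ell)) ell <- init_labels_region_grow(graph, M_init, seed = seed)
  fixed <- rep(FALSE, N)
  if (normal_clone && pin_normal && !is.null(theta))
    fixed <- !is.na(theta) & theta < 0.5
  obj_trace <- numeric(0)
  hm <- NULL
  for (it in seq_len(outer_max)) {
    hm <- hmm_update(bg, ell, lambda,
                     states = if (is.null(hm)) make_cn_states(K) else hm$states,
                     theta = theta, phi = hm$phi %||% 0.1,
                     tau_bb = hm$tau_bb %||% 30, t_cn = hm$t_cn %||% (1 - 5e-3),
                     c_scale = hm$c_scale, Z0 = hm$Z,
                     use_rdr = use_rdr, use_baf = use_baf)
    # relabel to the clones that survived the update (0 = normal stays 0)
    ell <- ifelse(ell == 0L, 0L, match(ell, hm$clones))
    ell[is.na(ell)] <- 1L
    ll <- spot_clone_loglik(bg, hm, theta = theta,
                            use_rdr = use_rdr, use_baf = use_baf)
    if (normal_clone) {
      hm0 <- hm
      bal <- which(hm$states$balanced)[1]
      hm0$Z <- matrix(bal, nrow(hm$Z), 1)
      hm0$c_scale <- 1
      ll0 <- spot_clone_loglik(bg, hm0, theta = theta,
                               use_rdr = use_rdr, use_baf = use_baf)
      ll <- cbind(ll, ll0)
      normal_idx <- ncol(ll)
      ell[ell == 0L] <- normal_idx
      if (any(fixed)) ell[fixed] <- normal_idx
    }
    # ICM is a local ascent, so run it from two starts -- the warm labels
    # and the per-spot ML labels (which let a coherent group such as the
    # normal region move together across the Potts barrier) -- and keep the
    # better labelling; including the warm start keeps the trace monotone
    icm_obj <- function(lab) sum(ll[cbind(seq_len(N), lab)]) +
      beta * potts_energy(lab, graph)
    ml <- max.col(ll)
    ml[fixed] <- ell[fixed]
    cands <- lapply(list(ell, ml), function(init)
      hmrf_update(ll, graph, beta, init, fixed = fixed))
    scores <- vapply(cands, icm_obj, numeric(1))
    ell_new <- cands[[which.max(scores)]]
    obj <- max(scores) + hm$trans_score
    obj_trace <- c(obj_trace, obj)
    done <- identical(ell_new, ell) ||
      (it > 1 && abs(obj_trace[it] - obj_trace[it - 1]) <=
         tol * (abs(obj_trace[it - 1]) + 1))
    if (normal_clone) {
      is_normal <- ell_new == ncol(ll)
      ell <- ifelse(is_normal, 0L, ell_new)
      if (all(is_normal)) ell[1] <- 1L
    } else ell <- ell_new
    if (done) break
  }
  model <- structure(list(
    ell = ell, Z = hm$Z, states = hm$states, phi = hm$phi, tau_bb = hm$tau_bb,
    t_cn = hm$t_cn, c_scale = hm$c_scale, beta = beta, theta = theta,
    retained = hm$retained, lambda = lambda, lambda_used = hm$lambda_used,
    clones = hm$clones, objective = obj_trace, hmm_trace = hm$trace,
    normal_clone = normal_clone, use_rdr = use_rdr, use_baf = use_baf,
    graph = graph), class = "clone_model")
  if (merge) model <- merge_clones(model, bg, sim_threshold = sim_threshold)
  if (normal_clone) model <- fold_balanced_clones(model, bg)
  model
}

# with the dedicated normal profile enabled, a fitted clone whose entire
# profile is balanced duplicates it: relabel its spots to the normal label 0
# and drop the column
fold_balanced_clones <- function(model, bg) {
  st <- model$states
  bal_clone <- vapply(seq_len(ncol(model$Z)), function(m) {
    z <- model$Z[model$retained, m]
    all(abs(st$mu[z] - 1) < 0.02 & abs(st$p[z] - 0.5) < 0.02)
  }, logical(1))
  if (!any(bal_clone) || all(bal_clone)) return(model)
  keep <- which(!bal_clone)
  relab <- rep(0L, ncol(model$Z))
  relab[keep] <- seq_along(keep)
  model$ell <- ifelse(model$ell == 0L, 0L, relab[model$ell])
  model$Z <- model$Z[, keep, drop = FALSE]
  model$c_scale <- model$c_scale[keep]
  model$clones <- seq_along(keep)
  model
}

#' @export
print.clone_model <- function(x, ...) {
  cat(sprintf("clone_model: %d clone(s)%s, %d states, %d spots\n",
              ncol(x$Z), if (x$normal_clone) " + normal profile" else "",
              nrow(x$states), length(x$ell)))
  invisible(x)
}

# fraction of retained bins on which two clones' states imply practically
# different (RDR, BAF) values; states closer than `tol` in both are treated
# as the same copy-number state, and isolated single-bin differences are
# ignored as Viterbi decoding flicker (a real event spans several bins --
# the phylogeny marker filter itself requires 3)
clone_profile_distance <- function(model, m1, m2, tol = 0.02) {
  z1 <- model$Z[model$retained, m1]; z2 <- model$Z[model$retained, m2]
  st <- model$states
  differ <- abs(st$mu[z1] - st$mu[z2]) > tol | abs(st$p[z1] - st$p[z2]) > tol
  if (!any(differ)) return(0)
  runs <- rle(differ)
  isolated <- runs$lengths == 1 & runs$values
  runs$values[isolated] <- FALSE
  mean(inverse.rle(runs))
}

#' Merge clones with near-identical copy-number profiles
#'
#' Repeatedly merges the pair of clones whose profiles (state-implied RDR
#' and BAF over retained bins) differ on the smallest fraction of bins,
#' while that fraction is below \code{sim_threshold}; spots are pooled and
#' the state HMM refit after every merge. This heuristically selects the
#' number of clones from a deliberately generous initial count.
#'
#' @param model a \code{clone_model}.
#' @param bg the \code{binned_genome} it was fitted on.
#' @param sim_threshold maximum differing-bin fraction for a merge.
#' @return the (possibly) reduced \code{clone_model}.
#' @export
merge_clones <- function(model, bg, sim_threshold = 0.02) {
  repeat {
    M <- ncol(model$Z)
    if (M <= 1) break
    dmat <- matrix(Inf, M, M)
    for (a in seq_len(M - 1)) for (b in (a + 1):M)
      dmat[a, b] <- clone_profile_distance(model, a, b)
    best <- which(dmat == min(dmat), arr.ind = TRUE)[1, ]
    if (dmat[best[1], best[2]] >= sim_threshold) break
    a <- best[1]; b <- best[2]
    ell <- model$ell
    ell[ell == b] <- a
    ell[ell > b] <- ell[ell > b] - 1L
    hm <- hmm_update(bg, ell, model$lambda, states = model$states,
                     theta = model$theta, phi = model$phi,
                     tau_bb = model$tau_bb, t_cn = model$t_cn,
                     use_rdr = model$use_rdr, use_baf = model$use_baf)
    model$ell <- ifelse(ell == 0L, 0L, match(ell, hm$clones))
    model$ell[is.na(model$ell)] <- 0L
    model$Z <- hm$Z; model$states <- hm$states
    model$phi <- hm$phi; model$tau_bb <- hm$tau_bb; model$t_cn <- hm$t_cn
    model$c_scale <- hm$c_scale
    model$clones <- hm$clones
    model$lambda_used <- hm$lambda_used; model$retained <- hm$retained
  }
  model
}
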