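# Generic discrete-state HMM machinery in log space, shared by the phasing
# HMM and the copy-number-state HMM. Observation sequences may be split into
# independent chains (chromosomes, or chromosome-by-clone concatenations);
# the chain restarts from the start distribution at each chain boundary.

# logE: T x S matrix of emission log-likelihoods
# logA: S x S transition log-probability matrix (rows sum to 1 on prob scale)
# logpi: length-S start log-distribution
# chain: integer/factor of length T marking contiguous independent chains
# Returns log-likelihood, posterior state probabilities gamma (T x S) and the
# expected transition count matrix xi (S x S) summed over transitions.
hmm_forward_backward <- function(logE, logA, logpi, chain) {
  T_ <- nrow(logE); S <- ncol(logE)
  chain <- as.integer(factor(chain, levels = unique(chain)))
  alpha <- matrix(NA_real_, T_, S)
  beta  <- matrix(0, T_, S)
  loglik <- 0
  gamma <- matrix(NA_real_, T_, S)
  xi <- matrix(0, S, S)
  for (ch in unique(chain)) {
    idx <- which(chain == ch)
    n <- length(idx)
    a <- matrix(NA_real_, n, S)
    a[1L, ] <- logpi + logE[idx[1L], ]
    if (n > 1L) for (t in 2:n) {
      # a[t, s'] = logsum_s (a[t-1, s] + logA[s, s']) + logE[t, s']
      prev <- a[t - 1L, ]
      a[t, ] <- apply(logA + prev, 2L, logsumexp) + logE[idx[t], ]
    }
    b <- matrix(0, n, S)
    if (n > 1L) for (t in (n - 1L):1L) {
      nxt <- b[t + 1L, ] + logE[idx[t + 1L], ]
      b[t, ] <- apply(t(logA) + nxt, 2L, logsumexp)
    }
    ll <- logsumexp(a[n, ])
    loglik <- loglik + ll
    g <- a + b - ll
    gamma[idx, ] <- exp(g)
    if (n > 1L) for (t in 1:(n - 1L)) {
      m <- outer(a[t, ], b[t + 1L, ] + logE[idx[t + 1L], ], `+`) + logA - ll
      xi <- xi + exp(m)
    }
    alpha[idx, ] <- a
    beta[idx, ] <- b
  }
  list(loglik = loglik, gamma = gamma, xi = xi)
}

# Viterbi decoding with the same chain-reset convention.
# Ties are broken toward the lower-indexed state.
hmm_viterbi <- function(logE, logA, logpi, chain) {
  T_ <- nrow(logE); S <- ncol(logE)
  chain <- as.integer(factor(chain, levels = unique(chain)))
  path <- integer(T_)
  for (ch in unique(chain)) {
    idx <- which(chain == ch)
    n <- length(idx)
    delta <- matrix(NA_real_, n, S)
    psi <- matrix(NA_integer_, n, S)
    delta[1L, ] <- logpi + logE[idx[1L], ]
    if (n > 1L) for (t in 2:n) {
      for (s in seq_len(S)) {
        cand <- delta[t - 1L, ] + logA[, s]
        j <- which.max(cand)   # which.max returns the first (lowest) maximiser
        psi[t, s] <- j
        delta[t, s] <- cand[j] + logE[idx[t], s]
      }
    }
    p <- integer(n)
    p[n] <- which.max(delta[n, ])
    if (n > 1L) for (t in (n - 1L):1L) p[t] <- psi[t + 1L, p[t + 1L]]
    path[idx] <- p
  }
  path
}

# Brute-force observed-data log-likelihood by summing over every state path.
# Exponential in chain length; used only as an independent oracle in tests.
hmm_loglik_enumerate <- function(logE, logA, logpi, chain) {
  chain <- as.integer(factor(chain, levels = unique(chain)))
  S <- ncol(logE)
  total <- 0
  for (ch in unique(chain)) {
    idx <- which(chain == ch)
    n <- length(idx)
    paths <- as.matrix(expand.grid(rep(list(seq_len(S)), n)))
    lp <- apply(paths, 1L, function(z) {
      v <- logpi[z[1L]] + logE[idx[1L], z[1L]]
      if (n > 1L) for (t in 2:n)
        v <- v + logA[z[t - 1L], z[t]] + logE[idx[t], z[t]]
      v
    })
    total <- total + logsumexp(lp)
  }
  total
}
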