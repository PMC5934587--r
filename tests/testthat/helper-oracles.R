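# Independent oracles, deliberately coded differently from the package:
# rate-matrix exponentials via eigendecomposition (not the closed form),
# quadratic dynamic-programming alignment, quadrature gamma rates.

NTS <- c("A", "C", "G", "T")

random_seq <- function(n, freqs = rep(0.25, 4))
  paste(sample(NTS, n, replace = TRUE, prob = freqs), collapse = "")

mutate_seq <- function(s, pos, mode = c("any", "transition", "transversion")) {
  mode <- match.arg(mode)
  v <- strsplit(s, "")[[1]]
  ts <- c(A = "G", C = "T", G = "A", T = "C")
  tv <- c(A = "C", C = "A", G = "T", T = "G")
  for (i in pos) {
    v[i] <- switch(mode,
                   transition = ts[[v[i]]],
                   transversion = tv[[v[i]]],
                   any = sample(setdiff(NTS, v[i]), 1))
  }
  paste(v, collapse = "")
}

# HKY rate matrix normalized to unit mean rate, exponentiated by
# eigendecomposition
oracle_P <- function(t, kappa, freqs) {
  Q <- matrix(0, 4, 4, dimnames = list(NTS, NTS))
  for (i in 1:4) for (j in 1:4) {
    if (i == j) next
    transition <- (NTS[i] %in% c("A", "G")) == (NTS[j] %in% c("A", "G"))
    Q[i, j] <- freqs[j] * if (transition) kappa else 1
  }
  diag(Q) <- -rowSums(Q)
  mu <- -sum(freqs * diag(Q))
  Q <- Q / mu
  e <- eigen(Q)
  Re(e$vectors %*% diag(exp(e$values * t)) %*% solve(e$vectors))
}

# quadrature-based equal-probability gamma category mean rates
oracle_gamma_rates <- function(alpha, ncat) {
  qs <- qgamma(seq(0, 1, length.out = ncat + 1), shape = alpha, rate = alpha)
  vapply(seq_len(ncat), function(i) {
    ncat * integrate(function(x) x * dgamma(x, shape = alpha, rate = alpha),
                     qs[i], qs[i + 1], rel.tol = 1e-10)$value
  }, numeric(1))
}

# site-by-site +I/+G mixture log-likelihood using oracle_P
oracle_pair_loglik <- function(s1, s2, t, kappa, freqs, alpha = NULL,
                               ncat = 1, p_inv = 0) {
  a <- strsplit(toupper(s1), "")[[1]]
  b <- strsplit(toupper(s2), "")[[1]]
  rates <- if (is.null(alpha)) 1 else oracle_gamma_rates(alpha, ncat)
  Ps <- lapply(rates, function(r) oracle_P(t * r, kappa, freqs))
  ll <- 0
  for (i in seq_along(a)) {
    x <- match(a[i], NTS); y <- match(b[i], NTS)
    if (is.na(x) || is.na(y)) next
    mix <- mean(vapply(Ps, function(P) P[x, y], numeric(1)))
    site <- unname(p_inv * freqs[x] * (x == y) + (1 - p_inv) * freqs[x] * mix)
    ll <- ll + log(max(site, 1e-300))  # eigen round-off can graze zero
  }
  ll
}

# grid-search ML distance over the oracle likelihood
oracle_grid_distance <- function(s1, s2, kappa, freqs, alpha = NULL,
                                 ncat = 1, p_inv = 0, t_max = 1,
                                 step = 1e-4) {
  ll <- function(t) oracle_pair_loglik(s1, s2, t, kappa, freqs, alpha,
                                       ncat, p_inv)
  # coarse pass, then the full-resolution grid around the coarse optimum
  coarse <- seq(0, t_max, by = 100 * step)
  t0 <- coarse[which.max(vapply(coarse, ll, numeric(1)))]
  fine <- seq(max(0, t0 - 200 * step), min(t_max, t0 + 200 * step), by = step)
  fine[which.max(vapply(fine, ll, numeric(1)))]
}

# plain quadratic Smith-Waterman with affine gaps (score only)
oracle_sw_score <- function(q, s, match = 2, mismatch = -3,
                            gap_open = 5, gap_extend = 2) {
  a <- strsplit(toupper(q), "")[[1]]
  b <- strsplit(toupper(s), "")[[1]]
  n <- length(a); m <- length(b)
  H <- matrix(0, n + 1, m + 1)   # best ending in a match/mismatch or fresh
  E <- matrix(-Inf, n + 1, m + 1) # gap in query (consume subject)
  F <- matrix(-Inf, n + 1, m + 1) # gap in subject (consume query)
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      E[i, j] <- max(H[i, j - 1] - gap_open - gap_extend,
                     E[i, j - 1] - gap_extend)
      F[i, j] <- max(H[i - 1, j] - gap_open - gap_extend,
                     F[i - 1, j] - gap_extend)
      sc <- if (a[i - 1] == b[j - 1]) match else mismatch
      H[i, j] <- max(0, H[i - 1, j - 1] + sc, E[i, j], F[i, j])
      if (H[i, j] > best) best <- H[i, j]
    }
  }
  best
}

printed_lset_model <- function()
  subst_model("HKY85", base_freqs = c(0.3624, 0.2434, 0.0914, 0.3028),
              tratio = 6.1561, gamma_shape = 0.8490, ncat = 4L,
              p_inv = 0.4860)

# small helper: simulate one pair of sequences at divergence t under a
# model, using the package simulator on a 2-tip tree
sim_pair_at <- function(t, model, n_sites, seed) {
  tr <- ape::read.tree(text = sprintf("(a:%f,b:%f);", t / 2, t / 2))
  db <- sim_alignment(tr, model, n_sites = n_sites, n_per_species = 1L,
                      intra_divergence = 0, seed = seed)
  setNames(db$records$aligned_seq, db$records$species)
}

# thin wrappers over package internals used to spawn query states in tests
evolve_from_states <- function(states, t, model, rates)
  coidentify:::evolve_states_coding(states, t, model, rates)
states_to_string_test <- function(states) coidentify:::states_to_string(states)
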