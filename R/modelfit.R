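## Composite-likelihood model fitting and AICc model selection.
##
## The full tree-based model search of dedicated model-selection software
## is replaced by a composite (pairwise) likelihood: the sum over all
## sequence pairs of the pairwise log-likelihood, with one divergence per
## pair and the substitution parameters shared. Candidate ranking uses
## AICc with k counting substitution parameters only (pairwise divergences
## are a nuisance common to every candidate, so ranking is unaffected).

n_subst_params <- function(family, gamma, invar) {
  k <- switch(family, JC69 = 0L, K80 = 1L, F81 = 3L, HKY85 = 4L,
              stop("unknown family ", family))
  k + as.integer(gamma) + as.integer(invar)
}

#' Corrected Akaike Information Criterion
#'
#' `AICc = -2 lnL + 2k + 2k(k+1)/(n - k - 1)`.
#'
#' @param loglik Maximized log-likelihood.
#' @param k Number of free parameters.
#' @param n Sample size (alignment columns).
#' @export
aicc <- function(loglik, k, n) {
  if (n <= k + 1) stop("AICc undefined: n_sites <= k + 1")
  -2 * loglik + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

empirical_base_freqs <- function(E) {
  cnt <- tabulate(E[!is.na(E)], nbins = 4L)
  if (any(cnt == 0)) cnt <- cnt + 0.5  # keep frequencies strictly positive
  p <- cnt / sum(cnt)
  names(p) <- NT_LEVELS
  p
}

## quick per-pair initial divergences (JC correction of the p-distance)
init_divergences <- function(counts_mat) {
  apply(counts_mat, 2L, function(ct) {
    n <- sum(ct)
    if (n == 0) return(NA_real_)
    p <- (n - sum(ct[c(1, 6, 11, 16)])) / n
    if (p >= 0.70) return(3)
    max(-0.75 * log(1 - 4 * p / 3), 0)
  })
}

#' Fit a substitution model to an alignment by composite likelihood
#'
#' Base frequencies are set to the empirical frequencies of unambiguous
#' characters (JC69/K80 use equal frequencies). Each remaining free
#' parameter (kappa, gamma shape, invariant proportion) is maximized on
#' its profile composite likelihood: for every candidate value the
#' per-pair divergences are re-optimized, which avoids the poor fixed
#' points that plain coordinate alternation hits when divergences and
#' rate-heterogeneity parameters are strongly coupled. Deterministic
#' given the data.
#'
#' For AICc the composite maximum is rescaled to a per-sequence scale
#' (`n_seqs / n_pairs`): every site enters `choose(n, 2)` pair terms
#' instead of roughly `n` independent ones, and without the rescaling
#' the pair-count inflation of likelihood differences would swamp the
#' parameter penalty for any alignment of more than a few sequences.
#'
#' @param x Alignment: a `reference_db` or named vector of equal-length
#'   aligned sequences (>= 3).
#' @param family Model family (`"JC69"`, `"K80"`, `"F81"`, `"HKY85"`).
#' @param gamma Add discrete-gamma rate heterogeneity (+G)?
#' @param invar Add an invariant-site proportion (+I)?
#' @param ncat Gamma categories when `gamma = TRUE`.
#' @param rounds Profile-optimization sweeps over the free parameters.
#' @param max_pairs Cap on the number of sequence pairs entering the
#'   composite likelihood (an evenly spaced deterministic subset is used
#'   above the cap; fitting cost grows with pairs, not sites).
#' @return An object of class `"model_fit"`: list with `model`
#'   ([subst_model()]), `loglik` (composite maximum over the pairs
#'   used), `n_params`, `aicc`, `n_sites`, and the fitted per-pair
#'   `divergences`.
#' @export
estimate_model_params <- function(x, family = "HKY85", gamma = FALSE,
                                  invar = FALSE, ncat = 4L, rounds = 2L,
                                  max_pairs = 90L) {
  seqs <- aligned_seq_set(x)
  if (length(seqs) < 3L) stop("need >= 3 sequences to fit a model")
  L <- nchar(seqs[[1L]])
  E <- vapply(seqs, encode_nt, integer(L))
  n <- ncol(E)
  pairs <- utils::combn(n, 2L)
  counts <- apply(pairs, 2L, function(ij) pair_pattern_counts(E[, ij[1L]], E[, ij[2L]]))
  counts <- counts[, colSums(counts) > 0, drop = FALSE]
  if (ncol(counts) > max_pairs) {
    pick <- unique(round(seq(1L, ncol(counts), length.out = max_pairs)))
    counts <- counts[, pick, drop = FALSE]
  }
  npairs <- ncol(counts)

  freqs <- if (family %in% c("JC69", "K80")) rep(0.25, 4) else empirical_base_freqs(E)
  kappa <- if (family %in% c("JC69", "F81")) 1 else 2
  alpha <- if (gamma) 1 else NULL
  pinv <- if (invar) 0.2 else 0

  build <- function(kappa, alpha, pinv)
    subst_model(family, base_freqs = freqs, kappa = kappa,
                gamma_shape = alpha, ncat = ncat, p_inv = pinv)
  ## profile composite log-likelihood: divergences re-optimized per call
  prof_ll <- function(model, tol = 1e-4) {
    eng <- ll_engine(model)
    s <- 0
    for (j in seq_len(npairs))
      s <- s + eng(counts[, j],
                   ml_dist_from_counts(counts[, j], model, tol = tol,
                                       engine = eng))
    s
  }

  for (r in seq_len(rounds)) {
    if (family %in% c("K80", "HKY85")) {
      kappa <- exp(stats::optimize(function(lk) prof_ll(build(exp(lk), alpha, pinv)),
                                   interval = log(c(0.1, 60)), maximum = TRUE,
                                   tol = 0.02)$maximum)
    }
    if (gamma) {
      alpha <- exp(stats::optimize(function(la) prof_ll(build(kappa, exp(la), pinv)),
                                   interval = log(c(0.02, 100)), maximum = TRUE,
                                   tol = 0.02)$maximum)
    }
    if (invar) {
      pinv <- stats::optimize(function(pi_) prof_ll(build(kappa, alpha, pi_)),
                              interval = c(0, 0.99), maximum = TRUE,
                              tol = 0.005)$maximum
    }
  }
  ## +G+I sits on a ridge (a low gamma shape mimics invariant sites), so
  ## sequential scalar profiles stall; refine (alpha, p_inv) jointly
  if (gamma && invar) {
    par0 <- c(log(alpha), stats::qlogis(min(max(pinv, 0.01), 0.97)))
    opt <- stats::optim(par0, function(par)
      -prof_ll(build(kappa, exp(par[1]), stats::plogis(par[2]))),
      method = "Nelder-Mead", control = list(maxit = 150, reltol = 1e-8))
    alpha <- exp(opt$par[1]); pinv <- stats::plogis(opt$par[2])
    if (family %in% c("K80", "HKY85")) {
      kappa <- exp(stats::optimize(function(lk) prof_ll(build(exp(lk), alpha, pinv)),
                                   interval = log(c(0.1, 60)), maximum = TRUE,
                                   tol = 0.02)$maximum)
    }
  }
  model <- build(kappa, alpha, pinv)
  eng <- ll_engine(model)
  tv <- vapply(seq_len(npairs), function(j)
    ml_dist_from_counts(counts[, j], model, tol = 1e-8, engine = eng),
    numeric(1))
  ll <- sum(vapply(seq_len(npairs), function(j) eng(counts[, j], tv[j]),
                   numeric(1)))
  k <- n_subst_params(family, gamma, invar)
  ## AICc on the pair-averaged composite likelihood: every pair re-explains
  ## the same shared evolutionary history, so raw composite differences
  ## grow with the pair count; averaging keeps likelihood differences on
  ## the scale of one pairwise observation of the alignment and makes the
  ## AICc penalty bite as intended
  ll_eff <- ll / npairs
  structure(list(model = model, loglik = ll, n_params = k,
                 aicc = aicc(ll_eff, k, L), n_sites = L,
                 divergences = tv),
            class = "model_fit")
}

#' @export
print.model_fit <- function(x, ...) {
  cat(sprintf("Composite-likelihood fit: lnL = %.3f, k = %d, AICc = %.3f (n_sites = %d)\n",
              x$loglik, x$n_params, x$aicc, x$n_sites))
  print(x$model)
  invisible(x)
}

#' Rank substitution models by AICc
#'
#' Fits every candidate in `families x {+/-G} x {+/-I}` via
#' [estimate_model_params()] and ranks by ascending AICc; among equal AICc
#' the candidate with fewer parameters ranks first. Candidates for which
#' AICc is undefined (`n_sites <= k+1`) are skipped with a warning.
#'
#' @inheritParams estimate_model_params
#' @param families Character vector of model families to consider.
#' @param with_G,with_I Include +G / +I variants alongside the plain models?
#' @return Class `"model_selection"`: list with a ranked `table`
#'   (data.frame: family, gamma, invar, k, loglik, aicc, delta_aicc), the
#'   ranked `fits` list, and `best` (the top fit).
#' @export
select_model_aicc <- function(x, families = c("JC69", "K80", "F81", "HKY85"),
                              with_G = TRUE, with_I = TRUE, ncat = 4L,
                              rounds = 3L) {
  if (!length(families)) stop("candidate set is empty")
  grid <- expand.grid(family = families,
                      gamma = if (with_G) c(FALSE, TRUE) else FALSE,
                      invar = if (with_I) c(FALSE, TRUE) else FALSE,
                      stringsAsFactors = FALSE)
  fits <- list(); rows <- list()
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    fit <- tryCatch(
      estimate_model_params(x, family = g$family, gamma = g$gamma,
                            invar = g$invar, ncat = ncat, rounds = rounds),
      error = function(e) {
        warning("candidate ", g$family, if (g$gamma) "+G", if (g$invar) "+I",
                " skipped: ", conditionMessage(e))
        NULL
      })
    if (is.null(fit)) next
    fits[[length(fits) + 1L]] <- fit
    rows[[length(rows) + 1L]] <- data.frame(
      family = g$family, gamma = g$gamma, invar = g$invar,
      k = fit$n_params, loglik = fit$loglik, aicc = fit$aicc)
  }
  if (!length(fits)) stop("no candidate model could be fitted")
  tab <- do.call(rbind, rows)
  ord <- order(tab$aicc, tab$k)
  tab <- tab[ord, , drop = FALSE]
  tab$delta_aicc <- tab$aicc - tab$aicc[1L]
  rownames(tab) <- NULL
  structure(list(table = tab, fits = fits[ord], best = fits[ord][[1L]]),
            class = "model_selection")
}

#' @export
print.model_selection <- function(x, ...) {
  cat("Model selection by AICc (composite pairwise likelihood)\n")
  print(x$table, digits = 6)
  invisible(x)
}
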