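## Pairwise maximum-likelihood distances under JC/K80/F81/HKY (+G, +I).
##
## All likelihood computations work on 4x4 site-pattern counts, so a
## likelihood evaluation is O(16 * ncat) regardless of sequence length.

NT_LEVELS <- c("A", "C", "G", "T")

#' Encode an aligned nucleotide sequence for likelihood computation
#'
#' Maps A/C/G/T (case-insensitive) to 1..4 and every other symbol
#' (ambiguity codes, gaps `-`, missing `?`) to `NA`. Sites that are `NA`
#' in either member of a pair are dropped (pairwise deletion).
#'
#' @param s A character string or character vector of single letters.
#' @return Integer vector with `NA` at non-ACGT positions.
#' @keywords internal
encode_nt <- function(s) {
  if (length(s) == 1L && nchar(s) > 1L) s <- strsplit(s, "", fixed = TRUE)[[1]]
  match(toupper(s), NT_LEVELS)
}

## 16-cell site-pattern counts for an encoded pair (cell = 4*(x-1)+y)
pair_pattern_counts <- function(a, b, weights = NULL) {
  ok <- !is.na(a) & !is.na(b)
  if (is.null(weights)) {
    idx <- (a[ok] - 1L) * 4L + b[ok]
    tabulate(idx, nbins = 16L)
  } else {
    idx <- (a[ok] - 1L) * 4L + b[ok]
    cnt <- numeric(16L)
    agg <- rowsum(weights[ok], idx)
    cnt[as.integer(rownames(agg))] <- agg[, 1L]
    cnt
  }
}

## Fast likelihood engine for the 16 ordered site patterns.
##
## The HKY transition probability is linear in e2 = exp(-beta*t*r) and the
## group decay e3, so the gamma-category mixture collapses to the same
## closed form evaluated at the category means of e2/e3 — one evaluation
## regardless of ncat. The engine precomputes the coefficient vectors
## (cell order 4*(x-1)+y) and returns ll(counts, t).
ll_engine <- function(model) {
  p <- model$base_freqs
  k <- model$kappa
  piR <- unname(p["A"] + p["G"]); piY <- unname(p["C"] + p["T"])
  beta <- 1 / (2 * k * (p["A"] * p["G"] + p["C"] * p["T"]) + 2 * piR * piY)
  beta <- unname(beta)
  PJ <- matrix(p, 4, 4, byrow = TRUE)
  PIg <- matrix(c(piR, piY, piR, piY), 4, 4, byrow = TRUE)
  sameg <- .HKY_SAME_GROUP; dg <- .HKY_DIAG
  A <- PJ; B <- -PJ
  C_R <- matrix(0, 4, 4); C_Y <- matrix(0, 4, 4)
  B[sameg] <- (PJ * (1 / PIg - 1))[sameg]
  Cmat <- matrix(0, 4, 4)
  Cmat[sameg] <- (-PJ / PIg)[sameg]
  Cmat[dg] <- ((PIg - PJ) / PIg)[dg]
  jR <- matrix(c(TRUE, FALSE, TRUE, FALSE), 4, 4, byrow = TRUE)
  C_R[jR] <- Cmat[jR]; C_Y[!jR] <- Cmat[!jR]
  PX <- matrix(p, 4, 4)                       # pi_x down rows
  w <- 1 - model$p_inv
  vA <- as.vector(t(w * PX * A))
  vB <- as.vector(t(w * PX * B))
  vR <- as.vector(t(w * PX * C_R))
  vY <- as.vector(t(w * PX * C_Y))
  inv <- matrix(0, 4, 4); diag(inv) <- model$p_inv * p
  vI <- as.vector(t(inv))
  rates <- model$rates
  aR <- 1 + piR * (k - 1); aY <- 1 + piY * (k - 1)
  function(counts, t) {
    d <- beta * t * rates
    m2 <- mean(exp(-d))
    mR <- mean(exp(-d * aR))
    mY <- mean(exp(-d * aY))
    ## cancellation at t -> 0 can leave a zero-probability cell a hair
    ## below zero; floor it so log() stays defined
    L <- pmax(vA + vB * m2 + vR * mR + vY * mY + vI, 1e-300)
    use <- counts > 0
    sum(counts[use] * log(L[use]))
  }
}

## site likelihoods for the 16 ordered patterns at branch length t:
## L_xy = p_inv*pi_x*[x==y] + (1-p_inv)/ncat * sum_c pi_x P_xy(t*r_c)
pattern_likelihoods <- function(model, t) {
  p <- model$base_freqs
  mix <- matrix(0, 4, 4)
  for (r in model$rates) mix <- mix + transition_matrix(model, t, r)
  mix <- mix / model$ncat
  L <- (1 - model$p_inv) * (p * mix)          # pi_x recycles down rows (x = row)
  if (model$p_inv > 0) diag(L) <- diag(L) + model$p_inv * p
  as.vector(t(L))                             # cell order 4*(x-1)+y
}

loglik_from_counts <- function(counts, t, model) {
  ll_engine(model)(counts, t)
}

#' Log-likelihood of an aligned sequence pair at a fixed divergence
#'
#' Sites where either sequence has a gap, ambiguity code or missing symbol
#' are excluded (pairwise deletion). The likelihood mixes the invariant-site
#' class with equal-probability discrete-gamma rate categories:
#' `L_site = p_inv*pi_x*1[x==y] + (1-p_inv)/ncat * sum_c pi_x P_xy(t*r_c)`.
#'
#' @param s1,s2 Aligned sequences (equal-length strings or letter vectors).
#' @param t Divergence in substitutions/site.
#' @param model A [subst_model()].
#' @return Scalar log-likelihood.
#' @export
pair_loglik <- function(s1, s2, t, model) {
  a <- encode_nt(s1); b <- encode_nt(s2)
  if (length(a) != length(b)) stop("aligned sequences must have equal length")
  counts <- pair_pattern_counts(a, b)
  if (sum(counts) == 0) stop("no shared unambiguous sites: likelihood undefined")
  loglik_from_counts(counts, t, model)
}

ml_dist_from_counts <- function(counts, model, t_max = 10, tol = 1e-8,
                                engine = NULL) {
  n <- sum(counts)
  if (n == 0) return(NA_real_)
  off <- sum(counts) - sum(counts[c(1, 6, 11, 16)])
  if (off == 0) return(0)
  if (is.null(engine)) engine <- ll_engine(model)
  opt <- stats::optimize(function(t) engine(counts, t),
                         interval = c(0, t_max), maximum = TRUE, tol = tol)
  ## optimize() never returns an exact endpoint; snap near-zero optima
  if (opt$maximum < tol && engine(counts, 0) >= opt$objective)
    return(0)
  opt$maximum
}

#' Maximum-likelihood pairwise distance
#'
#' Branch length maximizing [pair_loglik()] by Brent's bracketed scalar
#' optimization over `[0, t_max]` (tolerance `1e-8`). Identical retained
#' sites give exactly 0.
#'
#' @inheritParams pair_loglik
#' @param t_max Upper bracket for the divergence (substitutions/site).
#' @return ML distance in substitutions/site, or `NA` if the pair shares
#'   no unambiguous sites.
#' @export
ml_pair_distance <- function(s1, s2, model, t_max = 10) {
  a <- encode_nt(s1); b <- encode_nt(s2)
  if (length(a) != length(b)) stop("aligned sequences must have equal length")
  ml_dist_from_counts(pair_pattern_counts(a, b), model, t_max = t_max)
}

#' Pairwise ML distance matrix
#'
#' All pairwise [ml_pair_distance()] values under one shared substitution
#' model. Pairs with no shared unambiguous sites are `NA` (flagged with a
#' warning); downstream averaging skips them.
#'
#' @param x A `reference_db`, or a named character vector / list of
#'   equal-length aligned sequences.
#' @param model A [subst_model()].
#' @return Symmetric numeric matrix with zero diagonal and sequence labels
#'   as dimnames.
#' @export
distance_matrix <- function(x, model) {
  seqs <- aligned_seq_set(x)
  if (length(seqs) < 2L) stop("need at least 2 sequences")
  E <- vapply(seqs, encode_nt, integer(nchar(seqs[[1]])))
  n <- length(seqs)
  eng <- ll_engine(model)
  D <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    d <- ml_dist_from_counts(pair_pattern_counts(E[, i], E[, j]), model,
                             engine = eng)
    D[i, j] <- D[j, i] <- d
  }
  if (anyNA(D)) warning("some pairs share no unambiguous sites; entries set to NA")
  D
}

## normalize the various alignment containers to a named character vector
aligned_seq_set <- function(x) {
  if (inherits(x, "reference_db")) {
    seqs <- x$records$aligned_seq
    names(seqs) <- x$records$accession
  } else if (is.list(x)) {
    seqs <- unlist(x)
  } else seqs <- x
  if (is.null(names(seqs)) || anyDuplicated(names(seqs)))
    stop("sequences must carry unique names")
  if (length(unique(nchar(seqs))) != 1L)
    stop("aligned sequences must share one length")
  seqs
}

#' Mean distance from a query to each species' reference members
#'
#' For every species in `species_map`, the arithmetic mean of the query's
#' distance to that species' members, skipping missing (`NA`) entries.
#' Species whose entries are all missing are dropped with a warning.
#'
#' @param query_label Label of the query row in `dm`.
#' @param dm Distance matrix from [distance_matrix()].
#' @param species_map Named character vector mapping every non-query label
#'   to its species.
#' @return Named numeric vector (species -> mean distance), ascending.
#' @export
avg_species_distance <- function(query_label, dm, species_map) {
  if (!query_label %in% rownames(dm)) stop("query '", query_label, "' not in distance matrix")
  others <- setdiff(rownames(dm), query_label)
  unmapped <- setdiff(others, names(species_map))
  if (length(unmapped))
    stop("labels without a species mapping: ", paste(unmapped, collapse = ", "))
  d <- dm[query_label, others]
  sp <- species_map[others]
  means <- tapply(d, sp, function(v) mean(v, na.rm = TRUE))
  bad <- is.nan(means)
  if (any(bad)) {
    warning("species with all-missing distances excluded: ",
            paste(names(means)[bad], collapse = ", "))
    means <- means[!bad]
  }
  sort(c(means))
}

#' Write a distance matrix in square PHYLIP format
#'
#' @param dm Matrix from [distance_matrix()].
#' @param file Output path.
#' @param digits Decimal places (reports use 4, mirroring standard
#'   barcode-survey tables).
#' @export
write_phylip_dist <- function(dm, file, digits = 6) {
  con <- file(file, "w"); on.exit(close(con))
  writeLines(sprintf("%5d", nrow(dm)), con)
  for (i in seq_len(nrow(dm))) {
    writeLines(paste(formatC(rownames(dm)[i], width = -12),
                     paste(formatC(dm[i, ], format = "f", digits = digits),
                           collapse = " ")), con)
  }
  invisible(file)
}
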