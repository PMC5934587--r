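#' Substitution models for barcode distance estimation
#'
#' Constructs a nucleotide substitution model of the JC69/K80/F81/HKY85
#' family, optionally with discrete-gamma rate heterogeneity across sites
#' (`+G`) and a proportion of invariant sites (`+I`). HKY85 is the general
#' case; JC69, K80 and F81 are obtained by constraining base frequencies
#' and/or the transition/transversion ratio.
#'
#' The transition/transversion ratio can be supplied either as `tratio`
#' (the *expected* ratio of transition to transversion events, the PAUP*
#' `tratio` convention) or as `kappa` (the instantaneous rate ratio); the
#' other is derived through the base frequencies.
#'
#' @param family One of `"JC69"`, `"K80"`, `"F81"`, `"HKY85"`.
#' @param base_freqs Numeric length-4 vector of base frequencies in the
#'   order A, C, G, T. Must be strictly positive and sum to 1. Forced to
#'   `c(1,1,1,1)/4` for JC69 and K80.
#' @param tratio Expected transition/transversion ratio (ignored for
#'   JC69/F81, where it is fixed by `kappa = 1`).
#' @param kappa Instantaneous transition/transversion rate ratio;
#'   alternative to `tratio`.
#' @param gamma_shape Shape `alpha` of the discrete-gamma distribution of
#'   site rates, or `NULL` for rate homogeneity.
#' @param ncat Number of discrete gamma categories (forced to 1 when
#'   `gamma_shape` is `NULL`).
#' @param p_inv Proportion of invariant sites in `[0, 1)`.
#' @return An object of class `"subst_model"`: a list with elements
#'   `family`, `base_freqs`, `kappa`, `tratio`, `gamma_shape`, `ncat`,
#'   `p_inv` and the precomputed category `rates`.
#' @examples
#' # the HKY+G+I model used for shark-market barcodes, PAUP*-style input
#' m <- subst_model("HKY85", base_freqs = c(0.3624, 0.2434, 0.0914, 0.3028),
#'                  tratio = 6.1561, gamma_shape = 0.8490, ncat = 4,
#'                  p_inv = 0.4860)
#' m$kappa
#' @export
subst_model <- function(family = c("HKY85", "JC69", "K80", "F81"),
                        base_freqs = NULL, tratio = NULL, kappa = NULL,
                        gamma_shape = NULL, ncat = 4L, p_inv = 0) {
  family <- match.arg(family)
  if (family %in% c("JC69", "K80")) {
    if (!is.null(base_freqs) && any(abs(base_freqs - 0.25) > 1e-9))
      warning(family, " forces equal base frequencies; supplied values ignored")
    base_freqs <- rep(0.25, 4)
  }
  if (is.null(base_freqs))
    stop("base_freqs required for ", family)
  base_freqs <- as.numeric(base_freqs)
  if (length(base_freqs) != 4L || any(base_freqs <= 0))
    stop("base_freqs must be 4 strictly positive proportions (A, C, G, T)")
  if (abs(sum(base_freqs) - 1) > 1e-6)
    stop("base_freqs must sum to 1 (got ", format(sum(base_freqs)), ")")
  base_freqs <- base_freqs / sum(base_freqs)
  names(base_freqs) <- c("A", "C", "G", "T")

  if (family %in% c("JC69", "F81")) {
    kappa <- 1
    tratio <- kappa_to_tratio(1, base_freqs)
  } else {
    if (!is.null(kappa) && !is.null(tratio))
      stop("supply tratio or kappa, not both")
    if (is.null(kappa) && is.null(tratio))
      stop(family, " requires tratio or kappa")
    if (is.null(kappa)) kappa <- tratio_to_kappa(tratio, base_freqs)
    else tratio <- kappa_to_tratio(kappa, base_freqs)
  }

  if (is.null(gamma_shape)) {
    ncat <- 1L
  } else {
    if (!is.numeric(gamma_shape) || gamma_shape <= 0)
      stop("gamma_shape must be > 0")
    ncat <- as.integer(ncat)
    if (ncat < 1L) stop("ncat must be >= 1")
  }
  if (!is.numeric(p_inv) || p_inv < 0 || p_inv >= 1)
    stop("p_inv must lie in [0, 1)")

  structure(list(family = family, base_freqs = base_freqs,
                 kappa = kappa, tratio = tratio,
                 gamma_shape = gamma_shape, ncat = ncat, p_inv = p_inv,
                 rates = discrete_gamma_rates(gamma_shape, ncat)),
            class = "subst_model")
}

#' @export
print.subst_model <- function(x, ...) {
  tag <- x$family
  if (!is.null(x$gamma_shape)) tag <- paste0(tag, "+G")
  if (x$p_inv > 0) tag <- paste0(tag, "+I")
  cat("Substitution model:", tag, "\n")
  cat("  base freqs (ACGT):", paste(sprintf("%.4f", x$base_freqs), collapse = " "), "\n")
  cat(sprintf("  kappa = %.4f (tratio = %.4f)\n", x$kappa, x$tratio))
  if (!is.null(x$gamma_shape))
    cat(sprintf("  gamma shape = %.4f, %d categories\n", x$gamma_shape, x$ncat))
  cat(sprintf("  p_inv = %.4f\n", x$p_inv))
  invisible(x)
}

#' Convert between expected and instantaneous transition/transversion ratios
#'
#' Under HKY85 the expected ratio of transition to transversion events is
#' `R = kappa * (piA*piG + piC*piT) / (piR * piY)` with `piR = piA + piG`
#' and `piY = piC + piT`. `tratio_to_kappa()` inverts this relation.
#'
#' @param tratio,kappa The ratio to convert.
#' @param base_freqs Base frequencies (A, C, G, T).
#' @return The converted ratio (scalar).
#' @export
tratio_to_kappa <- function(tratio, base_freqs) {
  stopifnot(is.numeric(tratio), tratio > 0)
  p <- check_freqs(base_freqs)
  cross <- p["A"] * p["G"] + p["C"] * p["T"]
  if (cross <= 0) stop("degenerate base frequencies: piA*piG + piC*piT = 0")
  unname(tratio * (p["A"] + p["G"]) * (p["C"] + p["T"]) / cross)
}

#' @rdname tratio_to_kappa
#' @export
kappa_to_tratio <- function(kappa, base_freqs) {
  stopifnot(is.numeric(kappa), kappa > 0)
  p <- check_freqs(base_freqs)
  piR <- p["A"] + p["G"]; piY <- p["C"] + p["T"]
  if (piR <= 0 || piY <= 0) stop("degenerate base frequencies: a purine or pyrimidine pair sums to 0")
  unname(kappa * (p["A"] * p["G"] + p["C"] * p["T"]) / (piR * piY))
}

check_freqs <- function(p) {
  p <- as.numeric(p)
  if (length(p) != 4L || any(!is.finite(p)) || any(p < 0))
    stop("base frequencies must be 4 nonnegative numbers")
  if (abs(sum(p) - 1) > 1e-6) stop("base frequencies must sum to 1")
  names(p) <- c("A", "C", "G", "T")
  p
}

#' Discrete-gamma site-rate categories
#'
#' Equal-probability discretization of the mean-one gamma distribution of
#' relative site rates, with each category represented by its conditional
#' mean (the PAUP*/jModelTest convention, as opposed to category medians).
#'
#' @param alpha Gamma shape parameter (> 0), or `NULL` for a single
#'   unit-rate category.
#' @param ncat Number of categories.
#' @return Numeric vector of `ncat` rates with mean exactly 1.
#' @export
discrete_gamma_rates <- function(alpha, ncat = 4L) {
  ncat <- as.integer(ncat)
  if (ncat < 1L) stop("ncat must be >= 1")
  if (is.null(alpha) || ncat == 1L) return(rep(1, ncat))
  if (!is.numeric(alpha) || alpha <= 0) stop("alpha must be > 0")
  ## category mean of Gamma(alpha, rate = alpha) between consecutive
  ## equal-probability quantiles: ncat * [P(alpha+1, b_{i+1}) - P(alpha+1, b_i)]
  b <- stats::qgamma(seq(0, 1, length.out = ncat + 1), shape = alpha, rate = alpha)
  p <- stats::pgamma(b, shape = alpha + 1, rate = alpha)
  r <- ncat * diff(p)
  r / mean(r) * 1  # numerically exact mean 1
}

#' Transition probability matrix
#'
#' Closed-form HKY85 transition probabilities `P(t)` (JC69, K80 and F81
#' fall out as special cases). The generator is normalized to one expected
#' substitution per unit branch length at the model's base frequencies, so
#' `t` is measured in substitutions per site.
#'
#' @param model A [subst_model()].
#' @param t Branch length (>= 0), substitutions/site.
#' @param rate Site-rate multiplier (gamma category rate), >= 0.
#' @return A 4x4 row-stochastic matrix with rows/columns A, C, G, T.
#' @export
transition_matrix <- function(model, t, rate = 1) {
  if (!inherits(model, "subst_model")) stop("model must be a subst_model")
  if (!is.numeric(t) || length(t) != 1L || is.na(t) || t < 0)
    stop("branch length t must be a single number >= 0")
  if (rate < 0) stop("rate must be >= 0")
  p <- model$base_freqs
  k <- model$kappa
  piR <- p["A"] + p["G"]; piY <- p["C"] + p["T"]
  beta <- 1 / (2 * k * (p["A"] * p["G"] + p["C"] * p["T"]) + 2 * piR * piY)
  d <- beta * t * rate
  e2 <- exp(-d)
  eR <- exp(-d * (1 + piR * (k - 1)))
  eY <- exp(-d * (1 + piY * (k - 1)))
  ## vectorized closed form over the 4x4 cell grid; .HKY_* masks are
  ## package-level constants (same purine/pyrimidine group, diagonal)
  PJ <- matrix(p, 4, 4, byrow = TRUE)                      # pi_j by column
  PIg <- matrix(c(piR, piY, piR, piY), 4, 4, byrow = TRUE) # group freq of j
  E3 <- matrix(c(eR, eY, eR, eY), 4, 4, byrow = TRUE)      # group decay of j
  P <- PJ * (1 - e2)                                       # transversion cells
  s <- .HKY_SAME_GROUP
  P[s] <- (PJ + PJ * (1 / PIg - 1) * e2 - PJ / PIg * E3)[s]
  dg <- .HKY_DIAG
  P[dg] <- (PJ + PJ * (1 / PIg - 1) * e2 + (PIg - PJ) / PIg * E3)[dg]
  dimnames(P) <- list(names(p), names(p))
  P
}

.HKY_SAME_GROUP <- outer(c("R", "Y", "R", "Y"), c("R", "Y", "R", "Y"), "==")
.HKY_DIAG <- diag(4) == 1
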