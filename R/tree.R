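## Neighbor-joining trees on ML distances, nonparametric bootstrap over
## alignment columns, and the conspecific-cluster corroboration check.
##
## The tree's role in the identification workflow is corroborative: it
## confirms (or fails to confirm) that a query clusters with references
## of its candidate species. NJ over model-based distances preserves that
## decision surface at desk scale; the report labels the method honestly.

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei agglomeration (Studier-Keppler criterion, via
#' [ape::nj()]). Labels are put in lexicographic order before
#' agglomeration so the result is deterministic and invariant to input
#' order; negative estimated branch lengths are clamped to zero with the
#' deficit moved to the longest sibling branch (standard practice; this
#' affects printed lengths, never topology).
#'
#' @param dm Symmetric distance matrix with labeled rows/columns
#'   (>= 3 labels, no `NA`).
#' @return An unrooted `phylo` tree.
#' @export
nj_tree <- function(dm) {
  if (nrow(dm) < 3L) stop("neighbor-joining needs >= 3 labels")
  if (anyNA(dm)) stop("distance matrix contains missing entries")
  if (max(abs(dm - t(dm))) > 1e-12) stop("distance matrix must be symmetric")
  ord <- order(rownames(dm))
  tr <- ape::nj(dm[ord, ord])
  clamp_negative_branches(tr)
}

clamp_negative_branches <- function(tr) {
  for (pass in 1:5) {
    neg <- which(tr$edge.length < 0)
    if (!length(neg)) break
    for (i in neg) {
      if (tr$edge.length[i] >= 0) next
      d <- tr$edge.length[i]
      tr$edge.length[i] <- 0
      sib <- which(tr$edge[, 1L] == tr$edge[i, 1L])
      sib <- setdiff(sib, i)
      if (length(sib)) {
        j <- sib[which.max(tr$edge.length[sib])]
        tr$edge.length[j] <- tr$edge.length[j] + d
      }
    }
  }
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}

#' Bootstrap supports for the NJ tree of an alignment
#'
#' Resamples alignment columns with replacement, recomputes the ML
#' distance matrix and NJ tree for each replicate, and scores every
#' internal bipartition of the original tree by the percentage of
#' replicates in which it reappears. Replicates in which some pair
#' retains no unambiguous sites are dropped (reported via
#' `n_effective`).
#'
#' @param x Alignment (a `reference_db` or named equal-length sequences).
#' @param model A [subst_model()] shared by all replicates.
#' @param n_reps Number of bootstrap replicates (>= 1).
#' @param seed Integer seed; same seed, same supports.
#' @return The original-tree `phylo` object with `node.label` holding
#'   bipartition supports (percent, `NA` for the root node) and
#'   attribute `n_effective`.
#' @export
bootstrap_supports <- function(x, model, n_reps = 100L, seed = 1L) {
  if (n_reps < 1L) stop("n_reps must be >= 1")
  seqs <- aligned_seq_set(x)
  L <- nchar(seqs[[1L]])
  E <- vapply(seqs, encode_nt, integer(L))
  dm0 <- distance_matrix(seqs, model)
  tr <- nj_tree(dm0)
  n <- ncol(E)
  eng <- ll_engine(model)
  boot <- vector("list", n_reps)
  dropped <- 0L
  with_preserved_rng({
    set.seed(seed)
    for (r in seq_len(n_reps)) {
      cols <- sample.int(L, L, replace = TRUE)
      D <- matrix(0, n, n, dimnames = dimnames(dm0))
      ok <- TRUE
      for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
        ct <- pair_pattern_counts(E[cols, i], E[cols, j])
        if (sum(ct) == 0) { ok <- FALSE; break }
        D[i, j] <- D[j, i] <- ml_dist_from_counts(ct, model, tol = 1e-6,
                                                  engine = eng)
      }
      if (!ok) { dropped <- dropped + 1L; next }
      boot[[r]] <- nj_tree(D)
    }
  })
  boot <- boot[!vapply(boot, is.null, TRUE)]
  n_eff <- length(boot)
  if (!n_eff) stop("all bootstrap replicates dropped (no shared sites)")
  if (dropped) message(dropped, " bootstrap replicate(s) dropped")
  counts <- ape::prop.clades(tr, boot, rooted = FALSE)
  counts[is.na(counts)] <- 0L
  sup <- 100 * counts / n_eff
  sup[1L] <- NA_real_  # root of the unrooted representation: trivial split
  tr$node.label <- sup
  attr(tr, "n_effective") <- n_eff
  tr
}

#' Does the query cluster with references of one species, and how strongly?
#'
#' A query is "clustered" with a species when the tree contains a
#' bipartition whose smaller side consists of the query plus only
#' reference members of that species (at least one). The reported
#' support is the maximum bootstrap percentage over qualifying
#' bipartitions (`NA` when the tree carries no supports). For a species
#' with a single reference member the criterion reduces to the query and
#' that member being sisters.
#'
#' @param tree A `phylo` from [nj_tree()] or [bootstrap_supports()].
#' @param query_label Tip label of the query.
#' @param species Candidate species.
#' @param species_map Named character vector tip label -> species for
#'   all reference tips.
#' @return List with `clustered` (logical) and `support` (percent, 0 if
#'   not clustered, `NA` if clustered but unsupported tree).
#' @export
conspecific_cluster_support <- function(tree, query_label, species, species_map) {
  tips <- tree$tip.label
  if (!query_label %in% tips) stop("query '", query_label, "' not in tree")
  members <- names(species_map)[species_map == species]
  members <- intersect(members, tips)
  if (!length(members))
    stop("species '", species, "' has no members in the tree")
  parts <- ape::prop.part(tree)
  labs <- attr(parts, "labels")
  supports <- tree$node.label
  ntip <- length(tips)
  qsup <- numeric(0); clustered <- FALSE
  for (i in seq_along(parts)) {
    side1 <- labs[parts[[i]]]
    if (length(side1) == ntip) next  # root: trivial bipartition
    side2 <- setdiff(labs, side1)
    sides <- if (length(side1) < length(side2)) list(side1)
             else if (length(side2) < length(side1)) list(side2)
             else list(side1, side2)
    for (s in sides) {
      if (!query_label %in% s) next
      others <- setdiff(s, query_label)
      if (length(others) && all(others %in% members)) {
        clustered <- TRUE
        qsup <- c(qsup, if (is.null(supports)) NA_real_ else supports[i])
      }
    }
  }
  if (!clustered) return(list(clustered = FALSE, support = 0))
  list(clustered = TRUE,
       support = if (all(is.na(qsup))) NA_real_ else max(qsup, na.rm = TRUE))
}

#' Write a support-labeled tree in Newick format
#' @param tree `phylo` with optional `node.label` supports.
#' @param file Output path.
#' @export
write_support_newick <- function(tree, file) {
  if (!is.null(tree$node.label))
    tree$node.label <- ifelse(is.na(tree$node.label), "",
                              as.character(round(tree$node.label)))
  ape::write.tree(tree, file)
  invisible(file)
}
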