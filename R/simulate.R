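## Synthetic-data generators with known ground truth: species trees,
## reference databases evolved under the package's substitution models,
## Sanger-style read pairs, and full mislabeled-market scenarios.
##
## Every generator is a pure function of (config, seed): the caller's RNG
## stream is never disturbed, and the same seed regenerates byte-identical
## output.

#' Default barcode substitution model for simulations
#'
#' HKY+G+I with the parameter values estimated for a large elasmobranch
#' COI reference alignment (PAUP*-style input: base frequencies A, C, G
#' with T by normalization, expected transition/transversion ratio
#' 6.1561, gamma shape 0.8490 over 4 categories, invariant proportion
#' 0.4860). With these defaults, "data like a real shark-barcode survey"
#' is the standard fixture.
#'
#' @return A [subst_model()].
#' @export
default_barcode_model <- function()
  subst_model("HKY85", base_freqs = c(0.3624, 0.2434, 0.0914, 0.3028),
              tratio = 6.1561, gamma_shape = 0.8490, ncat = 4L,
              p_inv = 0.4860)

#' Simulate a pure-birth (Yule) species tree
#'
#' Starts from the root split (two lineages) and adds speciations with
#' exponential waiting times at total rate `k * birth_rate` for `k`
#' extant lineages; after the n-th species arises the tree is extended
#' by one further waiting time so pendant branches have positive length.
#' The expected root-to-tip depth is `(H_n - 1) / birth_rate` with `H_n`
#' the n-th harmonic number.
#'
#' @param n_species Number of tips (>= 2).
#' @param birth_rate Speciation rate (events per unit branch length).
#' @param seed Integer seed.
#' @param tip_depth Optional target root-to-tip depth
#'   (substitutions/site); the tree is rescaled to it. The default `NULL`
#'   keeps the simulated depth. Barcode-scale surveys typically use
#'   depths giving interspecific distances of 1-15%.
#' @return Ultrametric `phylo` with tips `sp1..spN`.
#' @export
sim_species_tree <- function(n_species, birth_rate = 1, seed = 1L,
                             tip_depth = NULL) {
  if (n_species < 2L) stop("n_species must be >= 2")
  with_preserved_rng({
    set.seed(seed)
    ## active lineages: parent node id + birth time of the pendant edge
    n_tip <- n_species
    root <- n_tip + 1L
    next_internal <- root + 1L
    active_parent <- c(root, root)
    active_birth <- c(0, 0)
    now <- 0
    edges <- NULL; elen <- NULL
    while (length(active_parent) < n_species) {
      k <- length(active_parent)
      now <- now + stats::rexp(1L, rate = k * birth_rate)
      i <- sample.int(k, 1L)
      v <- next_internal; next_internal <- next_internal + 1L
      edges <- rbind(edges, c(active_parent[i], v))
      elen <- c(elen, now - active_birth[i])
      active_parent <- c(active_parent[-i], v, v)
      active_birth <- c(active_birth[-i], now, now)
    }
    now <- now + stats::rexp(1L, rate = n_species * birth_rate)
    ord <- sample.int(n_species)  # random tip placement
    for (i in seq_along(active_parent)) {
      edges <- rbind(edges, c(active_parent[i], ord[i]))
      elen <- c(elen, now - active_birth[i])
    }
    tr <- list(edge = edges, edge.length = elen,
               tip.label = paste0("sp", seq_len(n_species)),
               Nnode = n_species - 1L)
    class(tr) <- "phylo"
    tr <- ape::reorder.phylo(tr, "cladewise")
    if (!is.null(tip_depth)) {
      h <- max(ape::node.depth.edgelength(tr))
      tr$edge.length <- tr$edge.length * tip_depth / h
    }
    tr
  })
}

## ---- sequence evolution ------------------------------------------------

MITO_STOPS <- c("TAA", "TAG", "AGA", "AGG")  # vertebrate mitochondrial code

## draw a stop-free coding root sequence from the model's base frequencies
draw_root_sequence <- function(n_sites, model) {
  n_codons <- ceiling(n_sites / 3)
  codons <- character(n_codons)
  for (i in seq_len(n_codons)) {
    repeat {
      cd <- paste(sample(NT_LEVELS, 3L, replace = TRUE,
                         prob = model$base_freqs), collapse = "")
      if (!cd %in% MITO_STOPS) break
    }
    codons[i] <- cd
  }
  encode_nt(substr(paste(codons, collapse = ""), 1L, n_sites))
}

## per-site rate multipliers: invariant sites get 0, others a gamma
## category rate (category and invariant flag fixed once, shared by the
## whole tree, as in the +G+I likelihood)
draw_site_rates <- function(n_sites, model) {
  r <- model$rates[sample.int(model$ncat, n_sites, replace = TRUE)]
  inv <- stats::runif(n_sites) < model$p_inv
  r[inv] <- 0
  r
}

## evolve integer-encoded states along one branch (vectorized by
## parent-state x distinct-rate blocks)
evolve_states <- function(states, t, model, site_rates, sites = NULL) {
  if (is.null(sites)) sites <- seq_along(states)
  out <- states
  if (t == 0) return(out)
  for (r in unique(site_rates[sites])) {
    if (r == 0) next
    P <- transition_matrix(model, t, r)
    idx <- sites[site_rates[sites] == r]
    for (x in 1:4) {
      ix <- idx[states[idx] == x]
      if (length(ix))
        out[ix] <- sample.int(4L, length(ix), replace = TRUE, prob = P[x, ])
    }
  }
  out
}

## indices of frame-0 codons (as site triples) containing a stop
stop_codon_sites <- function(states) {
  n3 <- length(states) %/% 3L
  if (!n3) return(integer(0))
  m <- matrix(states[seq_len(3L * n3)], nrow = 3L)
  cods <- paste0(NT_LEVELS[m[1L, ]], NT_LEVELS[m[2L, ]], NT_LEVELS[m[3L, ]])
  bad <- which(cods %in% MITO_STOPS)
  as.vector(vapply(bad, function(b) (b - 1L) * 3L + 1:3, integer(3)))
}

## evolve child from parent, re-drawing any codon that acquired an
## in-frame stop (the simulator emits coding sequences by construction)
evolve_states_coding <- function(parent, t, model, site_rates, max_iter = 200L) {
  child <- evolve_states(parent, t, model, site_rates)
  for (i in seq_len(max_iter)) {
    bad <- stop_codon_sites(child)
    if (!length(bad)) return(child)
    child[bad] <- evolve_states(parent, t, model, site_rates, sites = bad)[bad]
  }
  ## last resort: revert offending codons to the (stop-free) parent state
  bad <- stop_codon_sites(child)
  child[bad] <- parent[bad]
  child
}

states_to_string <- function(states) paste(NT_LEVELS[states], collapse = "")

#' Simulate a species-labeled reference alignment along a tree
#'
#' A stop-free coding root sequence is drawn from the model's base
#' frequencies, each site receives a gamma-category rate and an
#' invariant flag once (shared down the tree), and states evolve along
#' every branch by sampling from the model's transition matrices. Each
#' species then receives `n_per_species` conspecific reference sequences
#' on a star genealogy of depth `intra_divergence / 2`, so conspecific
#' pairs sit at roughly `intra_divergence`. Codons that acquire an
#' in-frame stop (vertebrate mitochondrial code) are re-drawn, so every
#' emitted sequence passes [numt_screen()].
#'
#' @param tree `phylo` with species names as tip labels; branch lengths
#'   in substitutions/site.
#' @param model A [subst_model()] (see [default_barcode_model()]).
#' @param n_sites Alignment columns (ungapped simulation).
#' @param n_per_species Length-2 range of conspecific references per
#'   species (default 2-8, as in curated congener sets).
#' @param intra_divergence Typical conspecific pairwise distance
#'   (substitutions/site; default 0.005, i.e. <1%).
#' @param seed Integer seed.
#' @param genus Optional character vector (or single grouping function)
#'   of genus keys per tip; default takes the first token of the label.
#' @param coding Keep every sequence free of in-frame stop codons
#'   (default). `FALSE` simulates unconstrained sequences exactly under
#'   the substitution model -- the right setting for estimator- and
#'   selection-consistency experiments, where the coding constraint
#'   would itself be a (real) deviation from the nominal model.
#' @return A [reference_db()]; attribute `species_states` holds the
#'   integer-encoded species-level barcode of every tip (used to spawn
#'   query individuals from the same ground truth).
#' @export
sim_alignment <- function(tree, model, n_sites = 650L,
                          n_per_species = c(2L, 8L),
                          intra_divergence = 0.005, seed = 1L,
                          genus = NULL, coding = TRUE) {
  if (n_sites < 1L) stop("n_sites must be >= 1")
  if (length(n_per_species) == 1L) n_per_species <- rep(n_per_species, 2L)
  with_preserved_rng({
    set.seed(seed)
    root_states <- if (coding) draw_root_sequence(n_sites, model)
                   else sample.int(4L, n_sites, replace = TRUE,
                                   prob = model$base_freqs)
    site_rates <- draw_site_rates(n_sites, model)
    evolver <- if (coding) evolve_states_coding else evolve_states
    tip_states <- evolve_tree_states(tree, root_states, model, site_rates,
                                     evolver)
    acc <- character(0); sp <- character(0); seqs <- character(0)
    species_states <- tip_states
    for (i in seq_along(tree$tip.label)) {
      lab <- tree$tip.label[i]
      n_i <- sample(seq(n_per_species[1L], n_per_species[2L]), 1L)
      for (j in seq_len(n_i)) {
        st <- evolver(tip_states[[i]], intra_divergence / 2,
                      model, site_rates)
        acc <- c(acc, sprintf("SIM%03d_%02d", i, j))
        sp <- c(sp, lab)
        seqs <- c(seqs, states_to_string(st))
      }
    }
    gen <- if (is.null(genus)) NULL else genus[match(sp, tree$tip.label)]
    db <- reference_db(acc, sp, genus = gen, aligned_seq = seqs)
    attr(db, "species_states") <- species_states
    attr(db, "site_rates") <- site_rates
    db
  })
}

## preorder evolution over a phylo tree; returns tip states (list, in
## tip.label order), keeping every node stop-free
evolve_tree_states <- function(tree, root_states, model, site_rates,
                               evolver = evolve_states_coding) {
  tr <- ape::reorder.phylo(tree, "cladewise")
  n_tip <- length(tr$tip.label)
  states <- vector("list", n_tip + tr$Nnode)
  states[[n_tip + 1L]] <- root_states
  for (e in seq_len(nrow(tr$edge))) {
    par <- tr$edge[e, 1L]; child <- tr$edge[e, 2L]
    states[[child]] <- evolver(states[[par]], tr$edge.length[e],
                               model, site_rates)
  }
  stats::setNames(states[seq_len(n_tip)], tr$tip.label)
}

#' Simulate a Sanger-style forward/reverse read pair from a template
#'
#' The forward read covers the 5' region and the reverse read (stored as
#' read, i.e. reverse-complemented) the 3' region, overlapping in the
#' middle. Per-base qualities start at `q_start` and decline by
#' `q_decay` per base; each base is miscalled with probability
#' `10^(-q/10)` (uniformly to one of the other three bases).
#'
#' @param template Ungapped template string (>= 100 bp).
#' @param read_frac Fraction of the template covered by each read
#'   (default 0.65, giving ~30% mutual overlap).
#' @param q_start Starting Phred score (use `Inf` for error-free reads;
#'   stored capped at 93).
#' @param q_decay Per-base quality decline.
#' @param seed Integer seed.
#' @param read_id Base identifier; reads are `<id>/1` and `<id>/2`.
#' @return List with `fwd` and `rev` [quality_read()] objects.
#' @export
sim_read_pair <- function(template, read_frac = 0.65, q_start = 40,
                          q_decay = 0.02, seed = 1L, read_id = "sim") {
  L <- nchar(template)
  if (L < 100L) stop("template must be >= 100 bp")
  rl <- min(L, ceiling(read_frac * L))
  with_preserved_rng({
    set.seed(seed)
    call_read <- function(seg) {
      n <- nchar(seg)
      q <- pmax(floor(pmin(q_start, 93) - q_decay * (seq_len(n) - 1L)), 2L)
      if (is.infinite(q_start)) q <- rep(93L, n)
      v <- strsplit(seg, "")[[1L]]
      perr <- if (is.infinite(q_start)) rep(0, n) else 10^(-q / 10)
      hit <- which(stats::runif(n) < perr)
      for (i in hit) v[i] <- sample(setdiff(c("A", "C", "G", "T"), v[i]), 1L)
      list(bases = paste(v, collapse = ""), quals = as.integer(q))
    }
    f <- call_read(substr(template, 1L, rl))
    r <- call_read(rc_string(substr(template, L - rl + 1L, L)))
    list(fwd = quality_read(paste0(read_id, "/1"), f$bases, f$quals, "forward"),
         rev = quality_read(paste0(read_id, "/2"), r$bases, r$quals, "reverse"))
  })
}

## ---- full market scenario ---------------------------------------------

#' Configuration for a simulated mislabeled-market survey
#'
#' @param n_species Total species across all genera.
#' @param n_genera Number of genera (species are spread as evenly as
#'   possible).
#' @param n_sites Barcode length in sites.
#' @param n_queries Number of market samples to simulate.
#' @param n_refs Range of reference sequences per species.
#' @param intra_divergence Conspecific pairwise distance scale (default
#'   0.5%).
#' @param min_interspecific Minimum congeneric interspecific distance
#'   (default 5%).
#' @param genus_depth Between-genus divergence (default 12%).
#' @param query_skew Geometric decay of per-species sampling weights
#'   (default 0.8: a few species dominate the market, as in real
#'   surveys).
#' @param frac_out_of_db Fraction of queries drawn from a species whose
#'   references are withheld from the database (a congener remains, so
#'   such queries get moderate-identity top hits).
#' @param mislabel_lineage If `TRUE`, one species receives a distinct
#'   intraspecific lineage whose reference entries are deliberately
#'   labeled as a congener (database-confusion construction); queries of
#'   that species are drawn from the mislabeled lineage.
#' @param lineage_split Divergence between the two intraspecific
#'   lineages of the mislabeled species (default 1.5%).
#' @param status_probs Named probabilities over conservation categories
#'   used to draw per-species statuses.
#' @param model A [subst_model()]; default [default_barcode_model()].
#' @return A config list (class `"market_config"`).
#' @export
market_config <- function(n_species = 15L, n_genera = 4L, n_sites = 650L,
                          n_queries = 63L, n_refs = c(2L, 8L),
                          intra_divergence = 0.005,
                          min_interspecific = 0.05, genus_depth = 0.12,
                          query_skew = 0.8, frac_out_of_db = 0,
                          mislabel_lineage = FALSE, lineage_split = 0.015,
                          status_probs = c(CR = 0.10, EN = 0.15, VU = 0.20,
                                           NT = 0.15, LC = 0.20, DD = 0.15,
                                           NE = 0.05),
                          model = default_barcode_model()) {
  stopifnot(n_species >= 2L, n_genera >= 1L, n_genera <= n_species)
  if (frac_out_of_db < 0 || frac_out_of_db > 1)
    stop("frac_out_of_db must lie in [0, 1]")
  if (abs(sum(status_probs) - 1) > 1e-6) stop("status_probs must sum to 1")
  structure(as.list(environment()), class = "market_config")
}

#' Simulate a complete market-survey scenario with known truth
#'
#' Builds a multi-genus species tree (pure-birth within genera, deep
#' star between genera), evolves a species-labeled reference database
#' and query individuals under the configured model, optionally withholds
#' species from the database and mislabels one intraspecific lineage as
#' a congener, assigns conservation statuses, and returns everything the
#' identification pipeline consumes plus the ground-truth table.
#'
#' @param config A [market_config()].
#' @param seed Integer seed; scenarios regenerate identically.
#' @return Object of class `"sim_scenario"`: list with `tree`, `model`,
#'   `refdb`, `queries` (list of [consensus_record()]), `truth`
#'   (data.frame: sample_id, true_species, in_db, mislabeled_lineage),
#'   `label_map` (all samples sold under one umbrella market label),
#'   `status_table`, `group_map`, `config`, `seed`.
#' @export
sim_market_scenario <- function(config = market_config(), seed = 1L) {
  stopifnot(inherits(config, "market_config"))
  cfg <- config
  with_preserved_rng({
    set.seed(seed)
    ## species-per-genus allocation, names
    base_n <- cfg$n_species %/% cfg$n_genera
    extra <- cfg$n_species %% cfg$n_genera
    k_g <- rep(base_n, cfg$n_genera) + c(rep(1L, extra), rep(0L, cfg$n_genera - extra))
    genus_names <- paste0("Simulogenus", LETTERS[seq_len(cfg$n_genera)])
    ## per-genus subtrees scaled so the closest congeners sit at
    ## min_interspecific, joined on a deep star
    sub_newicks <- character(cfg$n_genera)
    species <- character(0); genus_of <- character(0)
    for (g in seq_len(cfg$n_genera)) {
      sp_g <- paste0(genus_names[g], ".sp", seq_len(k_g[g]))
      if (k_g[g] == 1L) {
        sub_newicks[g] <- sprintf("%s:%.8f", sp_g, cfg$genus_depth / 2)
      } else {
        tr_g <- sim_species_tree(k_g[g], birth_rate = 1,
                                 seed = sample.int(1e6, 1L))
        coph <- stats::cophenetic(tr_g)
        scale <- cfg$min_interspecific / min(coph[coph > 0])
        tr_g$edge.length <- tr_g$edge.length * scale
        tr_g$tip.label <- sp_g[as.integer(sub("sp", "", tr_g$tip.label))]
        depth_g <- max(ape::node.depth.edgelength(tr_g))
        stem <- max(cfg$genus_depth / 2 - depth_g, cfg$min_interspecific)
        nwk <- sub(";$", "", ape::write.tree(tr_g))
        sub_newicks[g] <- sprintf("%s:%.8f", nwk, stem)
      }
      species <- c(species, sp_g)
      genus_of <- c(genus_of, rep(genus_names[g], k_g[g]))
    }
    tree <- ape::read.tree(text = paste0("(", paste(sub_newicks, collapse = ","), ");"))
    names(genus_of) <- species

    ## reference database + species-level true barcodes
    db <- sim_alignment(tree, cfg$model, n_sites = cfg$n_sites,
                        n_per_species = cfg$n_refs,
                        intra_divergence = cfg$intra_divergence,
                        seed = sample.int(1e6, 1L),
                        genus = genus_of[tree$tip.label])
    species_states <- attr(db, "species_states")
    site_rates <- attr(db, "site_rates")

    ## withheld (out-of-database) species: only from genera with >= 2
    ## species, so a congener stays behind
    eligible <- species[genus_of %in% names(which(table(genus_of) >= 2L))]
    n_out <- round(cfg$frac_out_of_db * cfg$n_species)
    out_species <- if (n_out > 0L) sample(eligible, min(n_out, length(eligible)))
                   else character(0)

    ## mislabeled lineage: species Y gets a second lineage whose refs are
    ## labeled as congener X; queries of Y come from that lineage
    mislabel_species <- NA_character_; mislabel_as <- NA_character_
    lineage_states <- NULL
    if (cfg$mislabel_lineage) {
      cand_y <- setdiff(eligible, out_species)
      if (!length(cand_y)) stop("mislabel_lineage needs a genus with >= 2 species kept in the db")
      mislabel_species <- sample(cand_y, 1L)
      g <- genus_of[mislabel_species]
      mislabel_as <- sample(setdiff(species[genus_of == g],
                                    c(mislabel_species, out_species)), 1L)
      lineage_states <- evolve_states_coding(species_states[[mislabel_species]],
                                             cfg$lineage_split, cfg$model,
                                             site_rates)
      ## a single confused entry: any candidate subsample of >= 2 records
      ## then still contains genuine members of the wrong label's species,
      ## keeping that species' mean distance high and the conflict certain
      extra_seq <- states_to_string(evolve_states_coding(lineage_states,
                                                         cfg$intra_divergence / 2,
                                                         cfg$model, site_rates))
      rec <- db$records
      rec <- rbind(rec[, c("accession", "species", "genus", "aligned_seq", "source_flags")],
                   data.frame(accession = "MISL01",
                              species = mislabel_as, genus = g,
                              aligned_seq = extra_seq,
                              source_flags = "suspected-mislabel",
                              stringsAsFactors = FALSE))
      db <- reference_db(rec$accession, rec$species, rec$genus,
                         rec$aligned_seq, rec$source_flags)
    }
    if (length(out_species))
      db <- subset_refdb(db, !db$records$species %in% out_species)

    ## market queries: skewed species abundances
    w <- cfg$query_skew ^ (seq_len(cfg$n_species) - 1L)
    qs <- sample(species, cfg$n_queries, replace = TRUE, prob = w / sum(w))
    ## the mislabeled-lineage construction only bites if such queries occur
    if (cfg$mislabel_lineage && !mislabel_species %in% qs)
      qs[sample.int(cfg$n_queries, 1L)] <- mislabel_species
    queries <- vector("list", cfg$n_queries)
    from_lineage <- logical(cfg$n_queries)
    for (i in seq_len(cfg$n_queries)) {
      src <- if (!is.na(mislabel_species) && qs[i] == mislabel_species) {
        from_lineage[i] <- TRUE
        lineage_states
      } else species_states[[qs[i]]]
      st <- evolve_states_coding(src, cfg$intra_divergence / 2, cfg$model,
                                 site_rates)
      queries[[i]] <- suppressWarnings(
        consensus_record(sprintf("MKT%03d", i), states_to_string(st)))
    }
    truth <- data.frame(sample_id = vapply(queries, `[[`, "", "sample_id"),
                        true_species = qs,
                        in_db = !qs %in% out_species,
                        mislabeled_lineage = from_lineage,
                        stringsAsFactors = FALSE)
    ## conservation statuses per species, one umbrella market label
    cats <- names(cfg$status_probs)
    draw_cat <- function(n) sample(cats, n, replace = TRUE, prob = cfg$status_probs)
    status_table <- data.frame(species = species,
                               common_name = paste("sim fish", seq_along(species)),
                               status_global = draw_cat(cfg$n_species),
                               status_national = draw_cat(cfg$n_species),
                               status_regional_1 = draw_cat(cfg$n_species),
                               status_regional_2 = draw_cat(cfg$n_species),
                               stringsAsFactors = FALSE)
    structure(list(tree = tree, model = cfg$model, refdb = db,
                   queries = queries, truth = truth,
                   label_map = stats::setNames(rep("cacao", cfg$n_queries),
                                               truth$sample_id),
                   status_table = status_table,
                   group_map = stats::setNames(rep("elasmobranch",
                                                   length(species)), species),
                   mislabel_species = mislabel_species,
                   mislabel_as = mislabel_as,
                   config = cfg, seed = seed),
              class = "sim_scenario")
  })
}

#' @export
print.sim_scenario <- function(x, ...) {
  cat(sprintf("<sim_scenario: %d species, %d refs, %d queries, seed %d>\n",
              x$config$n_species, nrow(x$refdb$records),
              length(x$queries), x$seed))
  invisible(x)
}

#' Write a simulated scenario to disk
#'
#' Writes the reference FASTA, query FASTA, ground-truth TSV and status
#' CSV of a scenario into a directory.
#'
#' @param scenario A [sim_market_scenario()] result.
#' @param dir Output directory (created if needed).
#' @export
write_scenario <- function(scenario, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_refdb_fasta(scenario$refdb, file.path(dir, "refdb.fasta"))
  write_consensus_fasta(scenario$queries, file.path(dir, "queries.fasta"))
  utils::write.table(scenario$truth, file.path(dir, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.csv(scenario$status_table, file.path(dir, "status.csv"),
                   row.names = FALSE)
  invisible(dir)
}
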