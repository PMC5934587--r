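# A hand-built congener database around one genus: three Squalus-like
# species at ~5% interspecific divergence with conspecific references at
# ~0.4%, plus a distant outgroup genus.
build_assign_db <- function(seed = 5, n_sites = 650) {
  tr <- ape::read.tree(text = paste0(
    "(((spA:0.025,spB:0.025):0.01,spC:0.035):0.08,",
    "(outX:0.02,outY:0.02):0.095);"))
  genus <- c(spA = "Squalodes", spB = "Squalodes", spC = "Squalodes",
             outX = "Raiopsis", outY = "Raiopsis")
  sim_alignment(tr, default_barcode_model(), n_sites = n_sites,
                n_per_species = 3L, intra_divergence = 0.004, seed = seed,
                genus = genus[tr$tip.label])
}

test_that("queries are assigned to the nearest species with full bookkeeping", {
  db <- build_assign_db()
  states <- attr(db, "species_states")
  rates <- attr(db, "site_rates")
  q <- suppressWarnings(consensus_record(
    "Q1", states_to_string_test(
      evolve_from_states(states[["spB"]], 0.002, default_barcode_model(), rates))))
  res <- assign_sample(q, db, default_barcode_model(),
                       assign_config(bootstrap_reps = 25, seed = 7))
  expect_s3_class(res, "assignment_result")
  expect_equal(res$candidate_species, "spB")
  expect_false(res$conflict)
  expect_lte(res$avg_distance, res$runner_up_distance)
  expect_equal(res$decision_basis, "distance+tree")
  expect_true(res$qc$pass)
  # candidate db was restricted to the top-hit genus
  expect_true(all(names(res$species_means) %in% c("spA", "spB", "spC")))
  # a query identical to a reference: zero distance, that species wins
  ref1 <- db$records[1, ]
  q0 <- suppressWarnings(consensus_record("Q0", ref1$ungapped_seq))
  res0 <- assign_sample(q0, db, default_barcode_model(),
                        assign_config(bootstrap_reps = 0, corroborate = FALSE))
  expect_equal(res0$candidate_species, ref1$species)
  expect_equal(res0$avg_distance,
               min(res0$species_means))
  expect_equal(unname(res0$species_means[ref1$species]) > 0, TRUE)
})

test_that("a single-species candidate genus gives a distance-only verdict", {
  db <- build_assign_db()
  keep <- db$records$species %in% c("outX") | db$records$genus == "Raiopsis"
  db1 <- subset_refdb(db, db$records$species == "outX")
  states <- attr(db, "species_states")
  rates <- attr(db, "site_rates")
  q <- suppressWarnings(consensus_record(
    "Q2", states_to_string_test(
      evolve_from_states(states[["outX"]], 0.002, default_barcode_model(), rates))))
  res <- assign_sample(q, db1, default_barcode_model(),
                       assign_config(bootstrap_reps = 0, corroborate = FALSE))
  expect_equal(res$candidate_species, "outX")
  expect_true(is.na(res$runner_up_species))
  expect_equal(res$decision_basis, "distance-only")
})

test_that("a mislabeled reference lineage raises the conflict flag", {
  # species Y keeps correctly labeled lineage-A references; its distinct
  # lineage B is present only under congener X's label. Queries from
  # lineage B: top hit X (identity ~100) but argmin mean distance Y.
  m <- default_barcode_model()
  db <- build_assign_db(seed = 11)
  states <- attr(db, "species_states")
  rates <- attr(db, "site_rates")
  lineageB <- evolve_from_states(states[["spB"]], 0.015, m, rates)
  mislabeled <- states_to_string_test(evolve_from_states(lineageB, 0.002, m, rates))
  rec <- db$records
  rec2 <- rbind(rec[, c("accession", "species", "genus", "aligned_seq", "source_flags")],
                data.frame(accession = "BAD1", species = "spA",
                           genus = "Squalodes", aligned_seq = mislabeled,
                           source_flags = "suspected-mislabel",
                           stringsAsFactors = FALSE))
  db2 <- reference_db(rec2$accession, rec2$species, rec2$genus,
                      rec2$aligned_seq, rec2$source_flags)
  for (i in 1:5) {
    q <- suppressWarnings(consensus_record(
      paste0("QB", i),
      states_to_string_test(evolve_from_states(lineageB, 0.002, m, rates))))
    res <- assign_sample(q, db2, m,
                         assign_config(bootstrap_reps = 0, corroborate = FALSE,
                                       seed = i))
    expect_equal(res$top_hit_species, "spA")   # hits a mislabeled entry
    expect_equal(res$candidate_species, "spB") # distance verdict is right
    expect_true(res$conflict)
  }
})

test_that("batches isolate failures, keep order, and rerun identically", {
  db <- build_assign_db()
  states <- attr(db, "species_states")
  rates <- attr(db, "site_rates")
  m <- default_barcode_model()
  mk <- function(id, sp) suppressWarnings(consensus_record(
    id, states_to_string_test(evolve_from_states(states[[sp]], 0.002, m, rates))))
  queries <- list(mk("S1", "spA"), mk("S2", "spC"),
                  suppressWarnings(consensus_record("S3", strrep("N", 200))),
                  mk("S4", "outY"))
  cfg <- assign_config(bootstrap_reps = 0, corroborate = FALSE, seed = 3)
  ba <- batch_assign(queries, db, m, cfg)
  expect_equal(ba$summary$sample_id, c("S1", "S2", "S3", "S4"))
  expect_equal(ba$summary$status, c("ok", "ok", "error", "ok"))
  expect_equal(ba$summary$candidate_species[c(1, 2, 4)],
               c("spA", "spC", "outY"))
  # deterministic rerun, byte-identical TSV
  f1 <- tempfile(); f2 <- tempfile()
  batch_assign(queries, db, m, cfg, file = f1)
  batch_assign(queries, db, m, cfg, file = f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_error(batch_assign(list(), db, m, cfg), "non-empty")
})

test_that("Numt-failing queries are rejected unless explicitly allowed", {
  db <- build_assign_db()
  states <- attr(db, "species_states")
  m <- default_barcode_model()
  # a genuine spA-like barcode with a planted segment carrying stop
  # codons in every reading frame (vertebrate mitochondrial code)
  good <- states_to_string_test(states[["spA"]])
  bad_seq <- paste0(substr(good, 1, 300), strrep("TAGA", 3),
                    substr(good, 313, nchar(good)))
  q <- suppressWarnings(consensus_record("QN", bad_seq))
  expect_error(assign_sample(q, db, m, assign_config()), "Numt")
  cfg <- assign_config(allow_numt_fail = TRUE, bootstrap_reps = 0,
                       corroborate = FALSE)
  expect_warning(res <- assign_sample(q, db, m, cfg), "Numt")
  expect_false(res$qc$pass)
  expect_equal(res$candidate_species, "spA")
})
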