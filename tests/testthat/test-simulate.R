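test_that("pure-birth species trees have the analytic expected depth", {
  tr2 <- sim_species_tree(2, seed = 1)
  expect_equal(ape::Ntip(tr2), 2)
  expect_equal(tr2$edge.length[1], tr2$edge.length[2])  # equal pendants
  # determinism
  expect_identical(ape::write.tree(sim_species_tree(7, seed = 42)),
                   ape::write.tree(sim_species_tree(7, seed = 42)))
  # expected root-to-tip depth of the generator: (H_n - 1) / birth_rate
  n <- 10; lambda <- 2; reps <- 400
  depths <- vapply(seq_len(reps), function(s)
    max(ape::node.depth.edgelength(sim_species_tree(n, lambda, seed = s))),
    numeric(1))
  expected <- (sum(1 / seq_len(n)) - 1) / lambda
  se <- sd(depths) / sqrt(reps)
  expect_lt(abs(mean(depths) - expected), max(0.1 * expected, 3 * se))
  # rescaling hits the requested depth exactly
  tr <- sim_species_tree(6, seed = 3, tip_depth = 0.04)
  expect_equal(max(ape::node.depth.edgelength(tr)), 0.04, tolerance = 1e-12)
  expect_error(sim_species_tree(1), ">= 2")
})

test_that("alignments evolve under the model: identity at zero branches, stationarity at long ones", {
  m <- default_barcode_model()
  tr0 <- ape::read.tree(text = "(a:0,b:0);")
  db0 <- suppressWarnings(sim_alignment(tr0, m, n_sites = 90,
                                        n_per_species = 2L,
                                        intra_divergence = 0, seed = 5))
  expect_equal(length(unique(db0$records$aligned_seq)), 1L)
  # long-branch tips approach the stationary composition
  trL <- ape::read.tree(text = "(a:5,b:5);")
  dbL <- sim_alignment(trL, m, n_sites = 10000, n_per_species = 1L,
                       intra_divergence = 0, seed = 6, coding = FALSE)
  comp <- table(factor(strsplit(dbL$records$aligned_seq[1], "")[[1]],
                       levels = c("A", "C", "G", "T"))) / 10000
  expect_lt(max(abs(as.numeric(comp) - m$base_freqs)), 0.01)
})

test_that("pairwise distance estimates recover the true simulated separation", {
  m <- default_barcode_model()
  ests <- vapply(1:30, function(s) {
    seqs <- sim_pair_at(0.10, m, 2000, seed = 900 + s)
    ml_pair_distance(seqs[[1]], seqs[[2]], m)
  }, numeric(1))
  expect_lt(abs(mean(ests) - 0.10) / 0.10, 0.10)
})

test_that("every simulated reference passes the Numt screen", {
  sc <- sim_market_scenario(market_config(n_species = 6, n_genera = 2,
                                          n_queries = 8), seed = 3)
  passes <- vapply(sc$refdb$records$ungapped_seq,
                   function(s) numt_screen(s)$pass, logical(1))
  expect_true(all(passes))
  qpass <- vapply(sc$queries, function(q) numt_screen(q$sequence)$pass,
                  logical(1))
  expect_true(all(qpass))
  # and a planted in-frame stop is caught
  s <- sc$refdb$records$ungapped_seq[1]
  broken <- paste0(substr(s, 1, 30), "AGA", substr(s, 34, nchar(s)))
  expect_false(numt_screen(broken)$pass)
})

test_that("simulated read pairs reassemble the template and match the error model", {
  set.seed(60)
  tpl <- random_seq(650)
  rp <- sim_read_pair(tpl, q_start = Inf, seed = 2)
  cr <- assemble_consensus(rp$fwd, rp$rev)
  expect_equal(cr$sequence, tpl)   # error-free round trip
  expect_equal(rp$fwd$orientation, "forward")
  expect_equal(rp$rev$orientation, "reverse")
  # a planted disagreement resolves to the higher-quality call
  rp2 <- sim_read_pair(tpl, q_start = Inf, seed = 3)
  v <- strsplit(rp2$fwd$bases, "")[[1]]
  pos <- 300
  v[pos] <- setdiff(c("A", "C", "G", "T"), v[pos])[1]
  fwd_low <- quality_read(rp2$fwd$read_id, paste(v, collapse = ""),
                          replace(rp2$fwd$quals, pos, 10L), "forward")
  cr2 <- assemble_consensus(fwd_low, rp2$rev)
  expect_equal(substr(cr2$sequence, pos, pos), substr(tpl, pos, pos))
  # Q20 miscall rate ~1% (binomial check over 10,000 bases)
  n_err <- 0; n_tot <- 0
  for (s in 1:16) {
    rp3 <- sim_read_pair(tpl, q_start = 20, q_decay = 0, seed = 100 + s)
    n_err <- n_err + sum(strsplit(rp3$fwd$bases, "")[[1]] !=
                           strsplit(substr(tpl, 1, nchar(rp3$fwd$bases)), "")[[1]])
    n_tot <- n_tot + nchar(rp3$fwd$bases)
  }
  p <- 0.01
  expect_lt(abs(n_err / n_tot - p), 3 * sqrt(p * (1 - p) / n_tot))
})

test_that("market scenarios regenerate identically and honor their truth table", {
  cfg <- market_config(n_species = 8, n_genera = 3, n_queries = 12,
                       frac_out_of_db = 0.15)
  s1 <- sim_market_scenario(cfg, seed = 11)
  s2 <- sim_market_scenario(cfg, seed = 11)
  expect_identical(s1$refdb$records, s2$refdb$records)
  expect_identical(vapply(s1$queries, `[[`, "", "sequence"),
                   vapply(s2$queries, `[[`, "", "sequence"))
  expect_identical(s1$truth, s2$truth)
  # withheld species have no reference records but appear in the truth
  out_sp <- unique(s1$truth$true_species[!s1$truth$in_db])
  expect_gte(length(out_sp), 1)
  expect_false(any(out_sp %in% s1$refdb$records$species))
  # per-species reference counts respect the configured range
  per <- table(s1$refdb$records$species)
  expect_true(all(per >= 2 & per <= 8))
  # true distances between congeners match the configured separation scale
  m <- cfg$model
  states <- s1$truth$true_species[1]
  expect_s3_class(s1$tree, "phylo")
  coph <- cophenetic(s1$tree)
  same_genus <- outer(sub("\\..*", "", rownames(coph)),
                      sub("\\..*", "", colnames(coph)), "==")
  congeneric <- coph[same_genus & coph > 0]
  expect_gte(min(congeneric), cfg$min_interspecific * 0.9)
  # bad config errors
  expect_error(market_config(frac_out_of_db = 1.5), "frac_out_of_db")
})

test_that("a mislabeled reference lineage is constructed as specified", {
  cfg <- market_config(n_species = 6, n_genera = 2, n_queries = 10,
                       mislabel_lineage = TRUE)
  sc <- sim_market_scenario(cfg, seed = 21)
  expect_false(is.na(sc$mislabel_species))
  expect_false(is.na(sc$mislabel_as))
  flagged <- sc$refdb$records[sc$refdb$records$source_flags == "suspected-mislabel", ]
  expect_equal(nrow(flagged), 1)
  expect_equal(unique(flagged$species), sc$mislabel_as)
  # queries of the mislabeled species exist and are marked
  expect_true(any(sc$truth$mislabeled_lineage))
  expect_true(all(sc$truth$true_species[sc$truth$mislabeled_lineage] ==
                    sc$mislabel_species))
})

test_that("scenario files round-trip through the writer", {
  sc <- sim_market_scenario(market_config(n_species = 4, n_genera = 2,
                                          n_queries = 5), seed = 2)
  dir <- tempfile("scen")
  write_scenario(sc, dir)
  db <- read_refdb_fasta(file.path(dir, "refdb.fasta"))
  expect_equal(db$records$accession, sc$refdb$records$accession)
  expect_equal(db$records$species, sc$refdb$records$species)
  truth <- read.delim(file.path(dir, "truth.tsv"))
  expect_equal(nrow(truth), 5)
  st <- read_status_table(file.path(dir, "status.csv"))
  expect_equal(nrow(st), 4)
})
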