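test_that("pair log-likelihood matches an independent site-by-site oracle", {
  m <- printed_lset_model()
  set.seed(3)
  s1 <- random_seq(20, m$base_freqs)
  s2 <- mutate_seq(s1, sample(20, 3))
  for (t in c(0.01, 0.05, 0.4)) {
    expect_equal(pair_loglik(s1, s2, t, m),
                 oracle_pair_loglik(s1, s2, t, m$kappa, m$base_freqs,
                                    alpha = 0.8490, ncat = 4, p_inv = 0.4860),
                 tolerance = 1e-8)
  }
  # reversibility
  expect_equal(pair_loglik(s1, s2, 0.07, m), pair_loglik(s2, s1, 0.07, m),
               tolerance = 1e-12)
  # identical pair at t = 0 collapses to the stationary log-probability
  expect_equal(pair_loglik(s1, s1, 0, m),
               sum(log(m$base_freqs[strsplit(s1, "")[[1]]])),
               tolerance = 1e-9)
  # pairwise deletion: gap/ambiguity sites are excluded
  s2g <- sub("^.", "-", s2)
  expect_equal(pair_loglik(s1, s2g, 0.05, m),
               pair_loglik(substring(s1, 2), substring(s2g, 2), 0.05, m))
  expect_error(pair_loglik("---", "AAA", 0.1, m), "no shared")
})

test_that("JC69 ML distance matches the analytic formula over many random pairs", {
  mj <- subst_model("JC69")
  set.seed(21)
  worst <- 0
  for (i in 1:1000) {
    n <- sample(80:300, 1)
    s1 <- random_seq(n)
    k <- sample(0:floor(0.6 * n), 1)
    s2 <- if (k) mutate_seq(s1, sample(n, k)) else s1
    p <- mean(strsplit(s1, "")[[1]] != strsplit(s2, "")[[1]])
    closed <- if (p == 0) 0 else -0.75 * log(1 - 4 * p / 3)
    worst <- max(worst, abs(ml_pair_distance(s1, s2, mj) - closed))
  }
  expect_lt(worst, 1e-6)
})

test_that("K80 at the joint ML solution matches its closed form", {
  # 20 transitions (P = 0.10) and 10 transversions (Q = 0.05) in 200 sites
  set.seed(5)
  s1 <- random_seq(200)
  s2 <- mutate_seq(s1, 1:20, mode = "transition")
  s2 <- mutate_seq(s2, 21:30, mode = "transversion")
  closed <- -0.5 * log(1 - 2 * 0.10 - 0.05) - 0.25 * log(1 - 2 * 0.05)
  expect_equal(closed, 0.17018, tolerance = 5e-5)
  # optimize (t, kappa) jointly on the package likelihood
  fit <- optim(c(log(0.1), log(2)), function(par) {
    -pair_loglik(s1, s2, exp(par[1]), subst_model("K80", kappa = exp(par[2])))
  }, method = "Nelder-Mead", control = list(reltol = 1e-12))
  expect_equal(exp(fit$par[1]), closed, tolerance = 1e-5)
})

test_that("HKY85 with equal base frequencies reproduces K80 distances", {
  set.seed(9)
  for (i in 1:20) {
    n <- 400
    s1 <- random_seq(n)
    s2 <- mutate_seq(s1, sample(n, sample(5:80, 1)))
    mh <- subst_model("HKY85", base_freqs = rep(0.25, 4), kappa = 4)
    mk <- subst_model("K80", kappa = 4)
    expect_equal(ml_pair_distance(s1, s2, mh), ml_pair_distance(s1, s2, mk),
                 tolerance = 1e-6)
  }
})

test_that("HKY+G+I distances match an independent grid-search oracle", {
  m <- printed_lset_model()
  set.seed(13)
  tr <- ape::read.tree(text = "((a:0.02,b:0.02):0.03,(c:0.02,d:0.02):0.03);")
  db <- suppressWarnings(sim_alignment(tr, m, n_sites = 60, n_per_species = 1L,
                                       intra_divergence = 0, seed = 77))
  seqs <- setNames(db$records$aligned_seq, db$records$species)
  for (i in 1:3) for (j in (i + 1):4) {
    got <- ml_pair_distance(seqs[[i]], seqs[[j]], m)
    want <- oracle_grid_distance(seqs[[i]], seqs[[j]], m$kappa, m$base_freqs,
                                 alpha = 0.8490, ncat = 4, p_inv = 0.4860)
    expect_lt(abs(got - want), 2e-4)
  }
})

test_that("ML distances are nonnegative, symmetric and zero iff identical", {
  m <- printed_lset_model()
  set.seed(31)
  for (i in 1:25) {
    n <- 150
    s1 <- random_seq(n, m$base_freqs)
    k <- sample(0:30, 1)
    s2 <- if (k) mutate_seq(s1, sample(n, k)) else s1
    d <- ml_pair_distance(s1, s2, m)
    expect_gte(d, 0)
    expect_equal(d, ml_pair_distance(s2, s1, m), tolerance = 1e-6)
    if (k == 0) expect_identical(d, 0) else expect_gt(d, 0)
  }
})

test_that("a larger invariant-site proportion inflates the fitted distance", {
  set.seed(41)
  s1 <- random_seq(500)
  s2 <- mutate_seq(s1, sample(500, 40))
  freqs <- rep(0.25, 4)
  d <- vapply(c(0, 0.3, 0.6), function(pi_)
    ml_pair_distance(s1, s2, subst_model("HKY85", base_freqs = freqs,
                                         kappa = 2, p_inv = pi_)),
    numeric(1))
  expect_true(all(diff(d) > 0))
})

test_that("distance matrices are symmetric with zero diagonal; equal inputs give equal rows", {
  m <- subst_model("JC69")
  set.seed(8)
  s1 <- random_seq(200)
  s2 <- mutate_seq(s1, 1:12)
  dm <- distance_matrix(c(a = s1, b = s2, c = s2), m)
  expect_equal(unname(diag(dm)), rep(0, 3))
  expect_equal(dm, t(dm))
  expect_equal(dm["a", "b"], dm["a", "c"])
  expect_equal(dm["b", "c"], 0)
  dm2 <- distance_matrix(c(x = s1, y = s1), m)
  expect_equal(unname(dm2), matrix(0, 2, 2))
})

test_that("per-species average distances follow the arithmetic-mean definition", {
  labs <- c("q", "m1", "m2")
  dm <- matrix(0, 3, 3, dimnames = list(labs, labs))
  dm["q", "m1"] <- dm["m1", "q"] <- 0.001
  dm["q", "m2"] <- dm["m2", "q"] <- 0.003
  dm["m1", "m2"] <- dm["m2", "m1"] <- 0.002
  out <- avg_species_distance("q", dm, c(m1 = "spA", m2 = "spA"))
  expect_equal(unname(out["spA"]), 0.002)
  out0 <- avg_species_distance("q", dm * 0, c(m1 = "spA", m2 = "spA"))
  expect_equal(unname(out0["spA"]), 0)
  expect_error(avg_species_distance("zz", dm, c(m1 = "spA", m2 = "spA")))
})

test_that("a curated spurdog-style distance fixture yields the expected species means", {
  # per-pair distances constructed so the species means reproduce a
  # published multi-congener comparison: the query is far closer to
  # Squalus mitsukurii (0.0009) than to any other candidate
  refs <- c(mit1 = 0.0008, mit2 = 0.0010,
            meg1 = 0.0026, meg2 = 0.0028,
            mon1 = 0.0043,
            chl1 = 0.0057, chl2 = 0.0059,
            cfm1 = 0.0088)
  sp <- c(mit1 = "Squalus mitsukurii", mit2 = "Squalus mitsukurii",
          meg1 = "Squalus cf. megalops", meg2 = "Squalus cf. megalops",
          mon1 = "Squalus montalbani",
          chl1 = "Squalus chloroculus", chl2 = "Squalus chloroculus",
          cfm1 = "Squalus cf. mitsukurii")
  labs <- c("MP16", names(refs))
  dm <- matrix(0, 9, 9, dimnames = list(labs, labs))
  dm["MP16", names(refs)] <- refs
  dm[names(refs), "MP16"] <- refs
  means <- avg_species_distance("MP16", dm, sp)
  expect_equal(unname(means["Squalus mitsukurii"]), 0.0009)
  expect_equal(unname(means["Squalus cf. megalops"]), 0.0027)
  expect_equal(unname(means["Squalus montalbani"]), 0.0043)
  expect_equal(unname(means["Squalus chloroculus"]), 0.0058)
  expect_equal(unname(means["Squalus cf. mitsukurii"]), 0.0088)
  expect_equal(names(means)[1], "Squalus mitsukurii")
})
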