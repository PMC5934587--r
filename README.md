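# coidentify

Species identification from COI DNA barcodes, built for seafood-forensics
surveys: filets sold under umbrella market labels ("cação" in Brazil covers
dozens of shark and ray species) carry no morphology, so the species — and
its conservation status — must be read off a ~650 bp fragment of the
mitochondrial cytochrome c oxidase I gene. `coidentify` implements the whole
desk workflow in R:

* consensus assembly of forward/reverse Sanger read pairs with quality
  trimming and quality-weighted conflict resolution (ambiguous columns get
  IUPAC codes);
* screening for nuclear mitochondrial pseudogenes (Numts) via internal stop
  codons in the vertebrate mitochondrial code and frame-breaking gaps;
* exact local-alignment search against a species-labeled reference database
  (score, %identity, %query-coverage; optional 8-mer prescreen for large
  batches);
* pairwise **maximum-likelihood genetic distances** under JC69 / K80 / F81 /
  HKY85 with discrete-gamma rate heterogeneity (+G) and invariant sites
  (+I): per site,
  `L = p_inv·π_x·1[x=y] + (1−p_inv)/C · Σ_c π_x P_xy(t·r_c)`,
  maximized over `t` by Brent search;
* substitution-model selection by AICc on a composite pairwise likelihood;
* neighbor-joining trees on the ML distances with nonparametric bootstrap,
  used to corroborate that a query clusters with its candidate species;
* the assignment rule itself: the candidate species is the one with the
  smallest mean distance to the query, with an explicit `conflict` flag
  whenever the database top hit disagrees (the signature of mislabeled
  reference entries);
* market-composition and conservation-threat reporting (threatened =
  CR ∪ EN ∪ VU per jurisdiction);
* a fully seeded synthetic-data module (`sim_market_scenario()`) that
  generates species trees, reference databases, read pairs, out-of-database
  species and mislabeled reference lineages with known ground truth.

## Worked example

Simulate a small market survey with known truth and identify every sample:

```r
library(coidentify)

cfg <- market_config(n_species = 8, n_genera = 3, n_sites = 650,
                     n_queries = 10)
sc <- sim_market_scenario(cfg, seed = 42)
ba <- batch_assign(sc$queries, sc$refdb, sc$model,
                   assign_config(bootstrap_reps = 50))
head(ba$summary[, c("sample_id", "candidate_species", "avg_distance",
                    "top_hit_identity", "conflict", "cluster_support")])
#>   sample_id candidate_species avg_distance top_hit_identity conflict cluster_support
#> 1    MKT001  SimulogenusC.sp1  0.000000000        100.00000    FALSE             100
#> 2    MKT002  SimulogenusC.sp1  0.000000000        100.00000    FALSE             100
#> 3    MKT003  SimulogenusA.sp2  0.006794933         99.84615    FALSE             100
#> 4    MKT004  SimulogenusB.sp3  0.002985735         99.84615    FALSE             100
#> 5    MKT005  SimulogenusB.sp1  0.010640418         99.53846    FALSE               0
#> 6    MKT006  SimulogenusA.sp3  0.009851139         99.69231    FALSE              98

mean(ba$summary$candidate_species == sc$truth$true_species)
#> [1] 1
```

Each row reads like a survey table: the candidate species, its mean ML
distance to the query (substitutions/site), the top search hit's identity,
whether hit and distance verdicts disagree, and the bootstrap support of the
conspecific cluster (sample `MKT005` was assigned by distance alone — its
cluster was unresolved, which the `decision_basis` column records).

The package also bundles a real 63-sample southern-Brazil market survey and
its conservation-status table:

```r
samples <- market_survey_samples()
cp <- composition(samples$species,
                  group_map = setNames(samples$group, samples$species))
cp
#> Market composition: 63 samples, 20 species
#>                  species count percent
#>          Prionace glauca    15    23.8
#>           Sphyrna lewini    14    22.2
#>          Xiphias gladius     6     9.5
#>  Rhizoprionodon lalandii     4     6.3
#>  ...

st <- market_survey_status()
threat_fractions(st$species, st, "global")         # -> 47  (8/17 threatened)
threat_fractions(st$species, st, "national")       # -> 53  (9/17 threatened)
threat_fractions(st$species, st, "national", "CR") # -> 47  (8/17 critically endangered)
```

The blue shark and the scalloped hammerhead dominate the market (23.8% and
22.2% of samples); 47% of the elasmobranch species found are globally
threatened and 53% nationally — the numbers a regulator actually needs from
such a survey.

Command-line wrappers over the same functions are installed under
`inst/scripts/` (`assign.R`, `simulate.R`).

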