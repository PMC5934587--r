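---
title: "Model-based species identification from COI barcodes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model-based species identification from COI barcodes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coidentify)
```

## The problem

Seafood sold as a filet carries no morphology. In Brazil the umbrella
label "cação" covers meat of dozens of shark and ray species (and the
occasional teleost), some of them red-listed, so neither the consumer
nor the regulator can tell what was actually caught. The standard
forensic instrument is the DNA barcode: ~650 bp of the mitochondrial
cytochrome c oxidase I (COI) gene, amplified from the tissue, sequenced
on both strands, and compared against a species-labeled reference
database. `coidentify` implements that workflow end to end at desk
scale — no external aligner, search engine, or phylogenetics binary —
together with a synthetic-data module that makes every stage testable
against known ground truth.

The pipeline mirrors how such surveys are actually analysed:

1. **Consensus assembly** of a forward/reverse Sanger read pair, with
   quality trimming and quality-weighted conflict resolution.
2. **Numt screening**: authentic COI translates without internal stop
   codons in the vertebrate mitochondrial code; nuclear copies (Numts)
   betray themselves by stops and frame-breaking gaps.
3. **Top-hit search** against the reference database by exact local
   alignment (a BLASTn analogue with score, %identity, %coverage).
4. **Candidate set**: all species of the top hit's genus, 2–8 reference
   sequences per species.
5. **Model-based distances**: pairwise maximum-likelihood distances
   under HKY85 (+G, +I), the model class typically selected for COI.
6. **Assignment** to the species with the smallest mean distance,
   corroborated by a neighbor-joining tree with bootstrap supports, and
   flagged whenever the top search hit disagrees.
7. **Reporting**: market composition and conservation-threat fractions.

## The substitution model and pairwise ML distances

The engine is the HKY85 family. With base frequencies
$\pi = (\pi_A, \pi_C, \pi_G, \pi_T)$ and transition/transversion rate
ratio $\kappa$, the instantaneous rate from base $i$ to $j \ne i$ is
$\kappa \pi_j$ for transitions and $\pi_j$ for transversions,
normalized to one expected substitution per unit branch length. JC69,
K80 and F81 are the constrained special cases. Transition probabilities
$P(t)$ use the standard closed form (checked in the tests against a
matrix-exponential oracle).

Practitioners often quote the *expected* transition/transversion ratio
$R$ (PAUP*'s `tratio`) instead of $\kappa$; the two are related by
$R = \kappa\,(\pi_A\pi_G + \pi_C\pi_T) / (\pi_R\,\pi_Y)$, and
`tratio_to_kappa()` / `kappa_to_tratio()` convert between them.

Rate heterogeneity uses the standard discrete-gamma approximation:
`ncat` equal-probability categories, each represented by its
conditional mean rate (the PAUP*/jModelTest convention), plus an
invariant-site proportion $p_\mathrm{inv}$. The likelihood of an
aligned pair at divergence $t$ is, per site,

$$\ell_{xy}(t) = p_\mathrm{inv}\,\pi_x\,\mathbf{1}[x{=}y] +
  (1-p_\mathrm{inv})\,\frac{1}{C}\sum_{c=1}^{C} \pi_x P_{xy}(t\,r_c),$$

with pairwise deletion of sites that are ambiguous, gapped or missing
in either sequence. `ml_pair_distance()` maximizes this by Brent
search on $[0, 10]$ at tolerance $10^{-8}$, returning exactly 0 for
identical retained sites. Because the likelihood depends on the data
only through the 16 site-pattern counts, a distance costs the same for
650 bp and 50 kb.

The default model (`default_barcode_model()`) is HKY+G+I with the
parameter values estimated for a large elasmobranch COI alignment:
frequencies A/C/G 0.3624/0.2434/0.0914 (T by normalization), tratio
6.1561, gamma shape 0.8490 with 4 categories, invariant proportion
0.4860. These are also the defaults of the simulator, so "data like a
real shark survey" is the package's standard fixture.

```{r}
m <- default_barcode_model()
m
```

## Model selection by AICc

`select_model_aicc()` ranks `{JC69, K80, F81, HKY85} x {±G} x {±I}`.
Full tree-based model selection is out of scope; the fit is a
*composite pairwise likelihood*: one divergence per sequence pair, the
substitution parameters shared across pairs. Three numerical choices
matter and are deliberate:

* **Profile optimization.** Each free parameter (κ, α,
  $p_\mathrm{inv}$) is optimized with the per-pair divergences
  re-optimized inside every candidate evaluation, plus a joint
  Nelder–Mead refinement of (α, $p_\mathrm{inv}$). Plain alternation
  between "optimize parameter" and "optimize divergences" stalls on
  the α/$p_\mathrm{inv}$ ridge (a low gamma shape mimics invariant
  sites) and can converge to grossly wrong shapes.
* **Pair-averaged AICc.** Every pair re-explains the same shared
  history — most visibly the realized root composition — so raw
  composite log-likelihood differences grow with the number of pairs
  and would swamp any fixed parameter penalty. AICc is therefore
  computed on the composite log-likelihood divided by the number of
  pairs, which restores likelihood differences to the scale of one
  pairwise observation of the alignment. Parameter counts follow the
  usual convention (JC69 = 0, K80 = 1, F81 = 3, HKY85 = 4, +1 each for
  G and I); the per-pair divergences are a nuisance common to every
  candidate and cancel from the ranking.
* **Consistency is asymptotic in sites.** In a pairwise likelihood the
  +I-versus-+G contrast is tiny per site, so at barcode length the
  decision between `HKY+G` and `HKY+G+I` sits inside AICc noise. The
  package's selection-consistency experiments therefore run at long
  simulated alignments (8 sequences × 50,000 sites, 20 seeded
  replicates), where both directions are decided correctly in 20/20
  replicates: HKY+G+I data ranks HKY+G+I first, and JC data ranks JC
  above HKY. These experiments also disable the simulator's coding
  constraint (`sim_alignment(coding = FALSE)`), because stop-codon
  avoidance is itself a real deviation from the nominal model that a
  richer model would (correctly) detect.

## Trees and corroboration

The tree's role here is corroborative, not inferential: it checks that
the query clusters with references of its candidate species.
`nj_tree()` runs Saitou–Nei neighbor joining (via `ape::nj`) on the ML
distance matrix, with labels sorted first so the result is
deterministic and order-invariant, and negative branch estimates
clamped to zero with the deficit moved to the longest sibling branch
(printed lengths only; topology is untouched). On any exactly additive
matrix NJ recovers the generating topology and path lengths — the
tests verify this on 50 random 6–10-taxon trees.

`bootstrap_supports()` resamples alignment columns, recomputes the
distance matrix and NJ tree per replicate, and scores each original
bipartition by its recurrence frequency.
`conspecific_cluster_support()` then asks whether some bipartition's
smaller side contains the query plus only members of the candidate
species; the default reporting threshold is 70 (supports below that
are conventionally not drawn), and the raw support is always recorded
so stricter conventions (e.g. 90) can be applied downstream.

One known limitation: with a degenerate, signal-free alignment
(identical sequences) every bootstrap replicate produces the same
arbitrary-but-deterministic topology, so supports are *not* a guard
against "no information" — they measure reproducibility under
resampling, and a deterministic tie-break is perfectly reproducible.

## The assignment rule

`assign_sample()` assigns the species with the smallest mean distance
between the query and that species' candidate references. The search
top hit does **not** decide: real surveys document cases where the
best database hit belongs to one species while the distance verdict
(and the tree) point to a close congener, typically because of a
mislabeled database entry. The disagreement is preserved as
`conflict = TRUE` for human review, and the tree corroboration is
advisory: a failed clustering downgrades `decision_basis`, never the
candidate. Exact ties in the species means are broken by the smaller
per-species minimum distance, then lexicographically, and always
flagged. No hard identity or distance cutoff is enforced — observed
conspecific means in practice stay below 3.5% — but all quantities are
reported so users can apply their own.

For large screens `search_top_hits()` can shortlist references by
shared 8-mers before exact Smith–Waterman alignment of the shortlist
(`strategy = "seed"`, chosen automatically above 30 records). This
mirrors the seeding idea of heuristic search tools; exact search over
every record remains available (`strategy = "exhaustive"`) and is the
default at desk scale. `batch_assign()` disables tree corroboration by
default only through its configuration — the acceptance experiments
run with `corroborate = FALSE` since they measure the distance
verdict.

## The synthetic-data module

`sim_market_scenario()` generates the whole study design with known
truth: a multi-genus species tree (pure-birth within genera, deep star
between them), a reference database evolved under the configured
model, skewed market sampling, conservation statuses, and optional
pathologies. Defaults encode the conditions of a realistic barcode
survey:

* barcode length 650 bp; conspecific divergence 0.5% (star
  genealogies, so truth stays analytic); congeneric species at least
  5% apart; genera ~12% apart;
* 2–8 references per species, matching curated congener sets;
* geometrically skewed market abundances (a few species dominate);
* optionally, a fraction of queries from species withheld from the
  database (their top hits have only moderate identity — the
  undescribed-species outcome), and one intraspecific lineage whose
  single reference entry is deliberately labeled as a congener. That
  last construction reproduces the classic database-confusion case:
  queries from the mislabeled lineage get the wrong label as top hit
  but the right species as distance argmin, so the conflict flag fires
  for every one of them. A single confused entry (rather than several)
  also guarantees that any candidate subsample of two or more records
  keeps genuine members of the wrong label's species, which is what
  keeps that species' mean distance high.

Simulated sequences are coding by construction: the root is drawn from
stop-free codons and any codon that acquires an in-frame stop
(vertebrate mitochondrial code) during evolution is re-drawn, so every
emitted sequence passes `numt_screen()`. Site-specific gamma-category
rates and invariant flags are drawn once and shared down the tree, as
the +G+I likelihood assumes. What the simulator does *not* model:
indels (reference alignments are generated gap-free), chromatogram
artifacts, heteroplasmy, codon-position rate structure beyond the
gamma mixture, and population-genetic geography. Passing the
end-to-end tests therefore demonstrates the pipeline's decision logic
under the model's own assumptions, not robustness to misalignment or
contamination.

`sim_read_pair()` emulates the two-strand Sanger design: forward and
reverse reads covering the 5' and 3' ends with configurable overlap,
per-base qualities declining linearly, and miscalls at the Phred rate
$10^{-q/10}$.

## Numerical choices and degenerate inputs

* Quality trimming: "high background noise" is operationalized as
  Phred < 20 (the conventional Sanger reliability floor) in runs of at
  least 5 bases; end runs are excised, interior runs are masked to `N`
  so codon coordinates survive for the Numt screen.
* "Similar quality" in consensus conflicts is a Phred difference below
  10 (a 10-fold error-odds ratio); such columns become IUPAC ambiguity
  codes and are counted in `ambiguity_count`.
* Overlap alignment for assembly: match +1, mismatch −1, gap −2, free
  end gaps, minimum overlap 50 — Sanger pairs of a 650 bp amplicon
  overlap almost fully.
* Local search scoring: +2/−3 with affine gaps 5/2 (BLASTN-like);
  compatible ambiguity codes score as matches, `N` never does.
  %identity counts identical columns over all alignment columns;
  %coverage is query cover.
* Distances: Brent bracket [0, 10], tolerance $10^{-8}$; pairs sharing
  no unambiguous sites are `NA` and are skipped by species averaging;
  reports print 4 decimals.
* Reading frame is inferred (the frame minimizing internal stops),
  never supplied; the vertebrate mitochondrial code is fixed.
* All intervals are 0-based half-open; reverse reads are
  reverse-complemented on input and all coordinates refer to the
  forward strand.

## Problem sizes used by the automated experiments

The packaged experiments are sized for a desk machine: the end-to-end
recovery scenario uses 15 species in 4 genera, 2,000-site barcodes and
500 queries (accuracy target ≥ 99%); the mislabeled-lineage scenario
uses 60 queries; model-selection consistency uses 8 sequences ×
50,000 sites × 20 replicates per direction; tree-engine checks use 50
random additive matrices and a 100-replicate bootstrap on a two-clade
alignment. The same quantities are recomputed from scratch by
`scripts/acceptance.R`.

## Worked example

```{r}
cfg <- market_config(n_species = 8, n_genera = 3, n_sites = 650,
                     n_queries = 10)
sc <- sim_market_scenario(cfg, seed = 42)
sc

ba <- batch_assign(sc$queries, sc$refdb, sc$model,
                   assign_config(bootstrap_reps = 50))
head(ba$summary[, c("sample_id", "candidate_species", "avg_distance",
                    "top_hit_identity", "conflict", "cluster_support")])
mean(ba$summary$candidate_species == sc$truth$true_species)
```

And the bundled southern-Brazil market survey:

```{r}
samples <- market_survey_samples()
cp <- composition(samples$species,
                  group_map = setNames(samples$group, samples$species))
cp
st <- market_survey_status()
threat_fractions(st$species, st, "global")    # threatened, IUCN global
threat_fractions(st$species, st, "national")  # threatened, national list
threat_fractions(st$species, st, "national", "CR")
```
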