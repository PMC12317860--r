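---
title: "Methods: clone detection, admixture and SNP fingerprinting in germplasm collections"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: clone detection, admixture and SNP fingerprinting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(germclone)
```

# Scope and data model

`germclone` characterises a clonally propagated germplasm collection from
biallelic diploid SNP genotypes. Everything downstream works on a single
substrate: an integer **dosage matrix** (samples × sites, values 0/1/2 =
count of alternate alleles, `NA` = missing), read from a VCF GT field
(`read_vcf()`), plus a sample table mapping sample ids to cultivar names,
with `UNKNOWN` for unnamed accessions and an optional `synonym_group`
column declaring name pairs known from prior literature to be synonymous.
Multi-allelic and non-SNP records are skipped (and counted), not split:
the analyses assume biallelic sites. Coordinates are 1-based as in VCF and
site ids follow the `chrom_pos` convention.

# Site filtering

Three filters are applied in a **fixed order** — missingness, then minor
allele frequency, then physical thinning (`apply_filters()`):

* **Missingness** (`max_missing`, default 10 in count mode): in count mode
  a site is kept iff *strictly fewer* than `max_missing` samples are
  missing; a fraction mode (`n_missing ≤ f·n`) is also provided, because
  collection-scale reports often quote percentage thresholds. Count mode
  is the default.
* **MAF** (`min_maf`, default 0.05): frequencies are computed on
  non-missing alleles and folded; a site exactly at the threshold is kept
  (only MAF *below* the threshold is excluded). Monomorphic sites are
  always removed, including at `min_maf = 0` — a monomorphic site carries
  no information for any stage here.
* **Thinning** (`thin_bp`, default 10000): a greedy left-to-right scan per
  chromosome keeps a site only if it lies at least `thin_bp` beyond the
  last kept site, the standard surrogate for removing physically linked
  SNPs when no LD estimates are available. No two kept sites on a
  chromosome are closer than `thin_bp`.

The order matters because the thinning outcome depends on which sites
survive the first two filters; fixing it makes the per-stage survivor
report (`$report`) reproducible and auditable.

# Distances and trees

The genetic distance is the **p-distance on dosages**: over sites where
both calls are present, the per-site distance is `|g_i − g_j|/2`
(identical 0, het vs hom 0.5, opposite homozygotes 1), and the pair's
distance is the mean. Missing data are handled by **pairwise-complete
deletion** — each pair uses its own site set — which is the tolerant
choice for filtered reduced-representation data; per-pair usable-site
counts are returned so degenerate pairs are visible. The implementation
uses indicator-matrix cross products and is exact (it is tested against a
direct per-pair loop). Triangle inequality is *not* guaranteed for
p-distances and is not asserted; symmetry, zero diagonal and the [0, 1]
range are.

Trees are built by neighbour joining (Saitou–Nei with the Studier–Keppler
criterion, via `ape::nj`), which is exact on additive distances — the test
suite checks recovery of random additive trees to 1e-9. Negative branch
lengths, which NJ can produce on non-additive input, are clamped to zero
with a message. Bootstrap support resamples sites with replacement
(`bootstrap_distance_matrices()`), rebuilds each replicate tree, and
annotates each internal edge of the main tree with the percentage of
replicates containing the same bipartition. Supports are mapped onto the
full-data tree rather than a majority-rule consensus: the full-data
topology is what the downstream seed-group search uses, so its edges are
the ones whose stability matters. Midpoint rooting is used purely as a
display/enumeration convention (`tight_clades()`); NJ trees are unrooted.

# Admixture by EM, and choosing K

The package fits the standard unlinked-SNP admixture model
(`g_il ~ Binomial(2, p_il)`, `p_il = Σ_k q_ik f_kl`) by **maximum
likelihood EM** rather than Bayesian MCMC. The EM route is deterministic
given a seed, runs a full multi-K scan in minutes on a desk machine, and
exposes per-run final log-likelihoods — exactly the ingredients the Evanno
ΔK statistic needs. The trade-offs are documented ones: no posterior
uncertainty on Q, and log-likelihood values are not numerically comparable
with MCMC estimates of the same model; only the *behaviour* of ΔK across K
(in particular its argmax) is comparable.

Numerical choices in `em_admixture()`:

* Q is initialised from a symmetric Dirichlet, F from observed allele
  frequencies with uniform jitter (±0.05), both seeded.
* F is clipped to `[1e-6, 1 − 1e-6]` every iteration, keeping the
  likelihood finite at monomorphic or near-fixed sites.
* The log-likelihood is verified non-decreasing at every iteration (a
  violated EM monotonicity aborts the run — it would indicate a bug, not
  data trouble); convergence is a relative change below `tol` (default
  1e-6, `max_iter` 500).
* Missing calls contribute nothing to either update or the likelihood.
* At K = 1 the EM fixed point is the closed form (Q ≡ 1, F = observed
  frequencies), verified to 1e-8 in tests.

`admixture_scan()` runs (default) 5 restarts per K over a contiguous K
range, keeps the best fit per K, and computes
`ΔK(K) = |L̄(K+1) − 2 L̄(K) + L̄(K−1)| / sd(L(K))` with the sample
standard deviation across restarts. A zero between-run sd leaves ΔK
*undefined and flagged* rather than infinite. Because EM labels are
arbitrary, multi-run collation uses greedy correlation matching of Q
columns (`match_cluster_labels()`); tests score recovery up to label
permutation.

Classification rules are strict inequalities: a sample belongs to a
cluster only if its ancestry *exceeds* 0.80 (a sample at exactly the
threshold is admixed), and with two pools a sample is F1-like if its
pool-1 ancestry is within ±0.02 of 0.5, BC1-like within ±0.02 of 0.25 or
0.75 (F1 has precedence; the classes cannot overlap for tolerance
≤ 0.125).

# The clone-distance cutoff and synonymy calls

The central procedure derives an objective "identical vs not" distance
cutoff from the data themselves:

1. **Sister pairs**: cherries in the NJ tree whose two tips share a
   cultivar name or a known-synonym group.
2. **Seed groups**: for every name with ≥ 2 samples, clades of the
   midpoint-rooted tree containing ≥ 2 matching tips and at most
   `max_extra` (default 2) non-matching tips. By default the *largest*
   qualifying clade per name is kept (`expand = "maximal"`), the
   expanded-cluster construction that reports whole near-identical groups
   with one or two interlopers; a `"minimal"` mode keeps the smallest
   clusters instead.
3. **Cutoff**: the maximum, over seed groups, of the maximum pairwise
   distance among the *same-named* members (`derive_cutoff()`).
4. **Clone groups**: single-linkage partition — connected components of
   the graph with an edge wherever `d ≤ cutoff` (`clone_groups()`).
5. **Nomenclature**: groups holding ≥ 2 distinct names are synonym sets; a
   name split across ≥ 2 groups/singletons is a homonym; an unknown sample
   grouped with exactly one name is suggested to be that cultivar (two or
   more names: ambiguous; alone: none).

Two design points deserve justification. First, the cutoff consumes
same-named distances only: interlopers inside a seed clade are precisely
the samples whose clone status the cutoff will later adjudicate, so
letting their distances enter the cutoff would be circular — and a lone
distant relative absorbed as an "extra" would inflate the cutoff
arbitrarily (in simulation this single change is the difference between
exact clone-partition recovery in 20/20 seeds and merging unrelated
founders). The all-member diameter is still reported per group
(`max_distance_all`). Second, single linkage operationalises "apply the
cutoff": observed clone groups chain through tree-adjacent members rather
than forming cliques, and single linkage is the unique partition rule
whose groups are exactly the ≤-cutoff connected components (tested against
a brute-force reachability closure). Raising the cutoff can only merge
groups, never split them.

# The fingerprinting panel

`greedy_min_panel()` builds a minimal discriminating SNP set by greedy set
cover over sample pairs: repeatedly select the site distinguishing the
most still-indistinguishable pairs, where a pair is distinguished at a
site only if *both* calls are present and the dosages differ — a panel
must never rely on missingness patterns, which are platform artefacts.
Ties break by genomic order for determinism. Pairs no single site can
separate are reported as `residual_pairs`, not raised as errors: genuinely
identical genotypes are a finding. `exhaustive_min_panel()` enumerates
subsets in increasing size for small instances (≤ 20 sites) and acts as
the optimality oracle in tests; greedy set cover cannot beat it, and on
100 random fixtures it is verified feasible and never smaller than the
optimum. Markers are reported with folded MAF and Botstein PIC
(`1 − p² − q² − 2p²q²` for biallelic markers, maximum 0.375 at MAF 0.5,
with equality iff MAF = 0.5).

# The synthetic cohort generator

`simulate_pools()` draws per-site ancestral frequencies uniform on
[0.05, 0.95] — bounded away from fixation so MAF filtering does not
degenerate — and pool frequencies from the Balding–Nichols beta
distribution at divergence `fst` (`fst = 0` collapses the pools to
identity). `simulate_cohort()` draws founder genotypes
`Binomial(2, Σ_k q_ik f_kl)` for pure-pool and hybrid ancestries, copies
clone-group founders exactly, and only then applies genotyping noise
(`corrupt_genotypes()`) in a fixed order: heterozygote→random-homozygote
miscalls, ±1 dosage errors (clipped), then missingness. The fixed order
makes per-site outcome probabilities enumerable, and the test suite checks
empirical within-clone distances against that enumeration. Noise defaults
(5% het miscall, 0.5% allele error, 5% missing) are the generator's own
calibration of "noticeable but not pathological" reduced-representation
noise — platform error rates are rarely published — and within-clone
p-distances they induce (~0.02 at these settings) sit an order of
magnitude below typical between-founder distances, which is the regime the
clone-calling procedure assumes.

What the generator deliberately does **not** emulate: linkage and
recombination (sites are exchangeable, so thinning is exercised only
mechanically), restriction-site dropout structure (missingness is
uniform), null alleles, and real cultivar-name sociology beyond two knobs
(`mislabel_fraction` renames clone copies to create homonyms;
`unknown_fraction` blanks names). Passing recovery tests therefore show
the procedures are sound in the regime they assume, not that any
particular real collection satisfies that regime.

# Test and simulation scale

The recovery simulations in the test suite use cohorts chosen to mirror a
realistic collection while keeping the full suite in a few minutes: the
clone-recovery chain runs 20 seeds of a 91-sample cohort (13 clone groups
of sizes 2–9 totalling 55 clonal samples, 23 singleton founders, 5 F1 and
8 BC1 hybrids, two pools at fst 0.3, 5000 sites, default noise) and
requires exact partition recovery in ≥ 90% of seeds with no cross-pool
merges; the admixture scan runs 5 seeds of a 60-sample, 2000-site, fst 0.4
cohort over K = 1..5 with 5 restarts and requires pure founders above 0.95
ancestry, F1 hybrids within ±0.05 of 0.5, and ΔK argmax at K = 2 in at
least 4 of 5 seeds. Oracle-based checks (NJ on additive trees, exhaustive
set cover, reachability closure, per-site corruption enumeration) run at
small n where the oracle is exact.

# Known limitations

* The cutoff procedure needs at least one same-named (or known-synonym)
  pair that is genuinely clonal; a collection with unique names throughout
  requires a manually supplied cutoff (`find_seed_groups()` says so
  explicitly).
* Somatic variants maintained clonally ("sports") are indistinguishable
  from genotyping noise at the distance level; the cutoff absorbs them by
  construction, which may be undesirable when sports are the object of
  study.
* EM finds local maxima; multi-start mitigates but does not guarantee the
  global optimum, and ΔK on EM log-likelihoods is a model-choice
  heuristic, not an inference.
* p-distances are uncorrected for multiple hits — appropriate within a
  species, not for divergent material.
* Homonym adjudication stops at detection: deciding which group is the
  "genuine" bearer of a name needs external evidence and is out of scope.
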