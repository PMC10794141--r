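---
title: "Methods: modelling and inferring a demic expansion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: modelling and inferring a demic expansion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the models, estimators and numerical choices in
`demic`, and states explicitly what the bundled synthetic-data
generators do and do not emulate. No empirical claim is made here beyond
what the package's tests and `scripts/acceptance.R` compute at run time.

## 1. The scientific setting

A demic expansion — population growth driving a spatial spread of
people, genes and languages together — leaves three coupled signatures:

1. **A serial-founder gradient.** Each newly colonized deme is founded
   by a small subset of an existing deme, so within-population diversity
   (haplotype richness, heterozygosity) declines with distance along the
   expansion path, and runs of homozygosity lengthen.
2. **Isolation by distance along routes, not as the crow flies.**
   Genetic differentiation (FST) between populations correlates with
   distance measured along the colonisation routes, which may detour
   around barriers.
3. **Gene–language congruence.** When languages spread with the people,
   linguistic distances correlate with genetic distances even after
   controlling for geography.

`demic` implements a forward-in-time lattice simulator of such an
expansion, estimators for each signature, an admixture-dating method for
later contact with resident populations, and route-tracing tools — plus
generators that produce self-contained synthetic datasets with known
truth for validating every estimator.

## 2. The expansion simulator

`simulate_expansion()` runs a discrete-generation Wright–Fisher model on
a rectangular lattice of demes (C++ core for speed; all randomness drawn
through R's RNG so `set.seed()` gives bitwise-reproducible output).

Per generation, in fixed order:

1. **Logistic growth.** A deme of census $N$ with capacity $K$ draws
   $N' \sim \mathrm{Binomial}\!\big(K,\ \min(1, (N + rN(1-N/K))/K)\big)$,
   floored at 1 so occupied demes never go extinct by drift in census.
2. **Reproduction.** $2N'$ offspring haplotypes are formed by sampling
   parent pairs with replacement and recombining: crossover counts per
   chromosome are Poisson in map length (Morgans), crossover positions
   uniform in genetic-map position.
3. **Migration.** For each 4-neighbour pair of occupied demes,
   $\mathrm{Binomial}(\min(2N_i, 2N_j), m)$ haplotypes are swapped
   symmetrically, leaving censuses unchanged.
4. **Colonisation.** A deme whose census exceeds
   `colonization_threshold` × $K$ sends `founder_size` haplotypes
   (an even count, i.e. whole diploids) into one uniformly chosen empty
   habitable neighbour. Demes are scanned in row-major order within a
   generation; a cell colonised this generation cannot itself bud until
   the next. This scan-order rule is our resolution of an otherwise
   under-determined event ordering; it makes the process exactly
   reproducible and introduces no directional bias beyond the lattice
   itself (verified by the mirror-symmetry test in
   `test-expansion.R`).

The founding event tree (which deme colonised which, and when) is
recorded and returned — it is the ground truth for route-tracing
validation.

### Route scenarios

`route_scenarios()` builds three habitability masks sharing one
geometry: a horizontal **barrier band** (uninhabitable rows) crossed by
a **southern corridor** (a column near the western edge), a **northern
corridor** (the eastern edge column), or **both**. `scenario_spec()`
validates parameters: growth rate $r > 0$, migration
$m \in [0, 0.25]$ (each deme exchanges with up to 4 neighbours, so
$4m \le 1$), even `founder_size` ≥ 2, threshold in $(0,1]$.

### Tunable parameters and defaults

| Parameter | Default | Rationale |
|---|---|---|
| `K` | 30 diploids | Small enough that 18-deme, 120-generation runs complete in seconds; large enough that drift does not destroy the gradient signal. |
| `r` | 0.6 | Mid-range logistic growth; demes refill within ~5 generations of founding. |
| `m` | 0.05 | Weak coupling: demes differentiate (pairwise FST ~0.02–0.6 in the bundled small world) but remain correlated with route distance. |
| `founder_size` | 8 haplotypes (4 diploids) | Strong founder effect without instant fixation. |
| `colonization_threshold` | 0.5 | A deme buds once half-full; expansion speed then reflects `r`. |
| chromosomes | 2 × 2000 SNPs, 100 cM each, 1 cM/Mb | Two independent linkage groups give within-run replication for LD/ROH statistics at desk scale. |
| `generations` | 120 | Leaves ≥ 60 generations of post-colonisation drift for the most distal demes. |

These problem sizes are the package's own desk-scale choices: large
enough that every estimator's sampling error is small relative to the
effect it measures, small enough that the full validation suite runs on
a laptop.

## 3. Synthetic-data generators

Each generator returns `panel` (a `genotype_panel`), `manifest` (sample
metadata with coordinates and linguistic group), and a `truth` object.

- **`generate_serial_founder_dataset()`** — the "small world": a 12 × 8
  lattice with a barrier band and southern corridor, origin in the
  north-west, 18 sampled demes chosen by arrival-time quantile so the
  sample spans the whole expansion, 10–30 diploids each (sample sizes
  are drawn within these bounds; downstream analyses can downsample to
  a common 30). Linguistic groups are assigned by arrival quartile.
- **`generate_stepping_stone_dataset()`** — the *negative control*:
  the same machinery with full initial occupancy and a burn-in of
  $20K$ generations, so isolation by distance exists but no
  origin-anchored diversity decline does.
- **`generate_admixed_dataset()`** — two source populations drifted
  apart for $0.3 \times 2N$ generations, then an admixed population
  founded with proportion `m_admix` of the minor source, mating
  randomly for `t_admix` generations with recombination while true
  ancestry tracts are tracked exactly. Defaults: $t = 30$, $m = 0.2$,
  200 diploids, 50 sampled.
- **`generate_island_dataset()`** — a finite island model simulated at
  the allele-frequency level; at $4Nm = 4$ theory predicts
  $F_{ST} \approx 1/(1+4Nm) = 0.2$, used to calibrate the FST
  estimator.
- **`generate_cognate_matrix()`** — vocabulary evolution on the
  founding tree by infinite-alleles replacement (each substitution
  creates a never-before-seen state), giving linguistic distances that
  grow with tree path length.

**What these emulate:** the *causal structure* of an expansion —
founder effects, route-constrained gene flow, tract-length decay,
gene–language co-descent — with known truth. **What they do not
emulate:** real ascertainment bias, genotyping error, uneven
recombination maps, background selection, continuous (non-lattice)
space, sex-biased processes, or realistic SNP densities. A passing
validation suite therefore shows the estimators are *correct under the
model*, not that the model captures any particular empirical dataset.

## 4. Estimators and numerical choices

**Hudson FST** (`hudson_fst_matrix()`): per-SNP numerator
$(p_1-p_2)^2 - \frac{p_1(1-p_1)}{n_1-1} - \frac{p_2(1-p_2)}{n_2-1}$,
denominator $p_1(1-p_2) + p_2(1-p_1)$, combined as a **ratio of
averages** across SNPs. We chose Hudson's estimator because it is
unbiased under unequal sample sizes and is the standard companion to
$f$-statistics; ratio-of-averages avoids the instability of averaging
per-SNP ratios.

**$f_3$ / $f_4$** (`f_statistic()`): $f_3(C; A, B) =
\overline{(c-a)(c-b)}$ with the sample-size correction
$c(1-c)/(n_C-1)$ subtracted per SNP (disable with
`corrected = FALSE`); $f_4(A,B;C,D) = \overline{(a-b)(c-d)}$.
Standard errors by delete-one **block jackknife** with blocks of
`block_snps = 50` consecutive SNPs, which exceeds the LD range at the
bundled SNP spacing.

**Haplotype richness** (`haplotype_richness()`): windows of
`window_snps = 20` SNPs; haplotypes with any missing call in a window
are dropped; richness is **rarefied to `g = 20` haplotypes** by
Monte-Carlo subsampling (`reps = 10`), then averaged over windows and
chromosomes. Rarefaction makes populations with different sample sizes
comparable; the test suite checks the Monte-Carlo mean against the
closed-form hypergeometric expectation. The 20-SNP window is wide
enough to be polymorphic at the bundled density and narrow enough that
recombination within a window is rare.

**Haplotype heterozygosity**: the unbiased estimator
$\frac{n}{n-1}\big(1-\sum_k p_k^2\big)$ over window-haplotype classes.

**LD decay** (`ld_decay()`): genotype-correlation $r^2$ for all SNP
pairs within `max_bp = 500000`, binned by physical distance; pairwise-
complete over missing data. 500 kb covers the full decay range at
1 cM/Mb.

**ROH** (`call_roh()`): per chromosome, a two-pointer scan for runs of
≥ `min_snps = 50` homozygous genotypes spanning ≥ `min_kb = 500` with
at most `het_allowance = 1` heterozygous call, trimmed so reported
segments start and end homozygous. Six length classes
(< 0.5, 0.5–1, 1–2, 2–4, 4–8, > 8 Mb) and a short/long split at
1.6 Mb separate background relatedness from recent parental
relatedness; $F_{ROH}$ is summed ROH length over the genotyped extent.

**Admixture dating** (`date_admixture_from_tracts()`): under a single
pulse $t$ generations ago with minor-ancestry fraction $m$, internal
tract lengths are exponential with mean $1/\big((1-m)\,t\big)$
Morgans. We estimate $\hat m$ from the genome fraction, exclude
**end-censored** tracts (those touching a chromosome end, whose length
is truncated), and invert:
$\hat t = 1/\big((1-\hat m)\,\bar L\big)$. Confidence intervals are
percentile bootstrap over haplotypes (`n_boot = 200`), respecting the
correlation of tracts within a haplotype. We date from tract lengths
directly (rather than ancestry-covariance decay curves) because the
package's tract calls are explicit inputs; the two approaches estimate
the same exponential scale.

**Ancestry masking** (`mask_by_ancestry()`): tracts are 0-based
half-open `[start_bp, end_bp)` intervals that must tile each haplotype
exactly (validated by `ancestry_tracts()`); alleles outside target-
ancestry tracts become `NA`. `prepare_masked_dataset()` then keeps
samples with ≥ 70 % target ancestry (cM-weighted), requires ≥ 10 per
population, and downsamples populations to ≤ 30 so no single
population dominates downstream statistics.

**Mantel and partial Mantel** (`mantel_test()`): Pearson correlation of
lower-triangle vectors; **two-sided** permutation p-value
$(1 + \#\{|r_{perm}| \ge |r_{obs}|\})/(1 + n_{perm})$ with
simultaneous row/column permutation (the exchangeable unit is the
population, not the pair). The partial version correlates residuals of
both matrices on the conditioning matrix. Two-sided because both
reinforcing and opposing structure are meaningful; the test suite
verifies null uniformity of p and agreement with `vegan::mantel`.

**PCA** (`genotype_pca()`): mean-imputed dosages scaled by
$\sqrt{p(1-p)}$; component signs fixed by making the largest-magnitude
loading positive, so results are reproducible across platforms.

**Procrustes** (`procrustes_fit()`): least-squares similarity transform
(rotation/reflection + scale + translation) of one configuration onto
another via SVD; similarity statistic
$t = \sum d_i / \sqrt{ss_a\, ss_b}$, significance by permutation.

**Linguistic distance** (`linguistic_distance_matrix()`): Hamming
proportion of differing cognate classes over mutually non-missing
slots — the natural distance for categorical cognate data and robust
to missing entries.

## 5. Route tracing and scenario inference

**`trace_routes()`** grows a minimum spanning tree over populations in
FST space outward from a declared origin (Prim's algorithm), breaking
exact weight ties first by smaller geographic distance, then by
lexicographic label, so output is deterministic. Leave-one-out
(`exclude =`) shows how routes re-wire when a hub population is
removed. The tests verify exact agreement with brute-force MST
enumeration over all spanning trees (Prüfer sequences) and topology
recovery against the simulator's founding tree.

**`gengrad_surface()`** interpolates an origin-FST profile onto a
hexagonal lattice by inverse-distance weighting (`idw_power = 2`
default; steeper powers track dense data more locally) and reports the
gradient magnitude $\left|\sum_i (v_i - v_0)\,\mathbf u_i/(3d)\right|$
over the six neighbours — exact for planar fields on the hex lattice.
Cells farther than `cutoff_deg` from every population are flagged
empty rather than extrapolated.

**Scenario inference** (`scenario_sweep()`, `scenario_support()`,
`rank_scenarios()`): an approximate-Bayesian-computation-style design.
The observable is the full pairwise FST vector; each of `n_sims = 200`
prior draws per scenario (uniform priors: $r \in [0.2, 1]$,
$m \in [0.01, 0.2]$, even founder size in $[2, 20]$, threshold in
$[0.25, 0.75]$) is scored by squared Pearson correlation with the
observed vector; a scenario's support is the best draw's $r^2$,
reported with the top-decile mean. We use correlation rather than
Euclidean distance so support is invariant to affine rescaling of FST
(drift-time calibration), which the priors do not attempt to match.
Draws under which a sampled deme is never colonised contribute no
support. `route_toy_design()` fixes a 9 × 6 geometry on which 200
draws per scenario discriminate the corridor scenarios reliably;
`scenario_recovery()` runs one full truth-generation → sweep → ranking
replicate.

## 6. Data interchange and QC

`read_panel()`/`write_panel()` support PLINK-style text PED/MAP
(alleles coded 1/2, missing 0, phase by allele order) and a phased TSV
(columns `<id>_A`, `<id>_B`, missing `.`). The manifest is CSV with
`;`-separated QC flags. `apply_qc_ledger()` removes flagged samples in
a fixed order — call-rate failures first, then kinship exclusions;
samples carrying both count against call rate — so reported removal
tallies are unambiguous.

## 7. Limitations

- The lattice simulator is demographically minimal: no selection, no
  long-range migration, no sex structure, no overlapping generations.
- Scenario support is a goodness-of-fit ranking over a fixed scenario
  set, not a posterior probability; it cannot flag "none of the above".
- Tract dating assumes a single pulse; continuous admixture biases
  $\hat t$ toward the midpoint of the contact period.
- IDW interpolation has no linear precision guarantee at sparse,
  irregular sampling; gradient estimates are reliable only where
  populations are dense relative to `hex_size`.
- Rarefaction to `g = 20` discards information when samples are much
  larger; raise `g` when all populations are well sampled.
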