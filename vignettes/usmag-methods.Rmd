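---
title: "Methods: abundance, transcription and co-occurrence of ultra-small prokaryote MAGs"
author: "usmag"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: abundance, transcription and co-occurrence of ultra-small prokaryote MAGs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(usmag)
```

`usmag` is built for a recurring analysis situation in groundwater
microbiology: a set of metagenome-assembled genomes (MAGs) dominated by
ultra-small prokaryotes — Patescibacteria (the Candidate Phyla Radiation),
Dependentiae, and DPANN archaea — observed across a modest number of
samples that differ in site, well, size fraction (planktonic groundwater
vs sediment-enriched water) and oxygen regime, with a companion
metatranscriptome and protein-alignment tables against reference genomes.
This vignette explains each model and procedure, the tunable parameters,
what the synthetic-data generator does and does not emulate, and the design
decisions that were genuinely open.

## Genome quality and size

Ultra-small lineages are systematically penalized by universal marker sets,
so completeness and contamination are computed from lineage-specific
single-copy gene (SCG) sets of fixed sizes: 51 bacterial markers
(Dependentiae), 43 (Patescibacteria), 38 archaeal markers (DPANN).

- completeness = fraction of the set observed at least once,
- contamination = fraction observed in two or more copies.

The duplication-based contamination parallels the CheckM convention; marker
*presence* alone carries no contamination signal, so duplication is the
natural single-table choice.

Estimated genome size removes the contaminated fraction and scales up by
completeness:
$$\hat{G} = \frac{B - B\,k}{c}$$
for bin size $B$, contamination $k$ and completeness $c$ (undefined at
$c = 0$). The estimator is linear in $B$, decreasing in $c$, and exact for
a complete, clean bin. On simulated bins built as
$B = G\,c\,(1+k)$ the relative error is $k^2 \le 0.25\%$, so the 5% median
recovery bound is limited by how well $c$ and $k$ themselves are known.

Quality tiers reproduce the reporting convention for these datasets
verbatim, including its asymmetry: completeness is a *strict* bound at the
50% and 70% tiers and *inclusive* at 80% and 90%; contamination is always
strict (`< 5%`). `qualityFilter()` infers the bound style from the
threshold (inclusive at ≥ 0.8) and lets callers override it.

Redox classes from dissolved oxygen use one fixed bound — oxic means
DO > 3 g/m³ — and configurable half-open intervals below it (defaults:
anoxic < 0.1, suboxic [0.1, 0.3), dysoxic [0.3, 3]). DO = 3 is therefore
dysoxic, not oxic.

## Abundance normalization and enrichment

Read counts are made comparable across samples by up-scaling every sample
column to the largest sample's total:
$x_{ij}' = x_{ij} \cdot \max_k T_k / T_j$ with $T_j$ the column total. This
equalizes depth while preserving within-sample proportions exactly
(`relativeAbundance(normalizeCounts(x)) == relativeAbundance(x)`); a
down-scaling alternative would discard no information either, but
up-scaling keeps integer-like magnitudes familiar from mapped-read tables.
All-zero samples are left untouched with a warning.

Enrichment between two sample groups is the ratio of mean relative
abundances (group A over group B). Classes:

- `exclusive-A` / `exclusive-B`: the other group's mean is exactly zero;
- `enriched-A` / `enriched-B`: the factor falls outside a multiplicative
  *neutral band* $[1/1.05,\ 1.05]$ (width configurable). A knife-edge rule
  at exactly 1 would classify ties unstably under floating-point noise,
  which is why the band exists; `neutralBand = 1` restores the strict rule.
- `absent`: zero everywhere.

Swapping the groups inverts the factor exactly for taxa present in both.

Presence means a strictly positive value by default (`floor = 0`,
configurable): with up-scaled counts there is no natural minimum-count
unit, and prevalence/Venn statistics should not depend on the scaling.

Diversity utilities delegate to standard ecology routines (Shannon via
`vegan::diversity`, Bray–Curtis via `vegan::vegdist`), with two defined
degenerate cases: a pair of all-zero samples has Bray–Curtis distance 0
(they are identical), and an all-zero vs non-zero pair has distance 1.
Rarefaction draws without replacement from the expanded read multiset with
an explicit seed; the hypergeometric closed form
$E[S_d] = \sum_i \left(1 - \binom{N-N_i}{d}/\binom{N}{d}\right)$
(`expectedRarefiedRichness()`) serves as its analytic check. Reported
rarefied richness is a single seeded draw, matching common practice.

## Modified-TPM transcription profiling

Transcript counts are normalized per gene and per library:
$$\text{modified-TPM} = n_\text{reads} \times \frac{1000}{L_\text{gene}} \times \frac{10^6}{\text{library size}}.$$
Unlike classical TPM there is no within-sample re-normalization by the sum
of rates, so values are comparable across genes *and* proportional to
mapped reads. "Library size" is taken as the total (quality-trimmed) reads
of the sample — the larger of the two defensible readings — and the column
totals of mapped counts are validated against it; a mapped-only mode is a
matter of passing those totals instead.

Per-MAG expression sums modified-TPM over the MAG's genes and can be
divided by the genome size in Mbp, so that large genomes do not dominate
purely by gene count; community share divides by the per-sample total.
Condition comparisons (fold changes, per-COG-category percentages) average
per sample first and then across samples within a condition — not pooled
counts — so unequal library sizes cannot tilt a condition. Category
percentages are complementary by construction
($p_A + p_B = 100$). Condition-exclusive features are those detected
(value > 0 by default) in at least one sample of one condition and none of
the other. The top-expressed listing flags cold-shock genes (cspA/B/C),
whose apparent expression is often an artifact of cold sample
preservation rather than in-situ activity.

## AAI and the family band

Average amino-acid identity between two genomes is the unweighted mean
percent identity over filtered, paired protein hits:

1. filter: identity ≥ 30% and alignment length ≥ 70% of the *shorter*
   protein (inclusive bounds). The printed filter wording ("over 70% of
   alignment length") is self-referential; the shorter-protein denominator
   is the common AAI convention and is the default, with a `literal` mode
   that applies only the identity filter.
2. pairing: reciprocal best hits by bitscore (ties broken by identity,
   then lexicographic subject id) — symmetric by construction; a one-way
   mode exists.
3. mean identity, unweighted (a length-weighted mean is a one-line change
   but is not what typical AAI tools report).

The family call classifies an AAI against the 45–65% band taken to delimit
a bacterial family: genomes whose best reference AAI falls below the band
are novel at family rank or higher. No genus/species calls are derived
from AAI — those require placement methods outside this package's scope.

## Correlation screens

`spearmanTest()` uses average ranks for ties and computes the two-sided
p-value by the t approximation with $n-2$ degrees of freedom; a seeded
Monte-Carlo permutation p is available and agrees with the approximation
to well under 0.01 at the sample sizes involved (n = 16). Pearson tests
delegate to `stats::cor.test`. The screen computes every
(feature, parameter) pair, handles missing chemistry pairwise-complete
with per-entry n, and flags raw p < α (default 0.05) — no multiplicity
correction by default, because the screens it mirrors report raw
thresholds; a Benjamini–Hochberg flag is provided. Type-I error of both
tests is calibrated within the binomial confidence band of α under
independent Gaussian nulls at n = 16 (verified in the acceptance tests).

## Co-occurrence network and cohorts

The network keeps an edge between two MAGs when Spearman ρ > 0.8 *and*
p < 0.001 *and* ρ > 0 — positive associations only. Isolated nodes are
retained (network membership is near-total in the data this mirrors);
constant-profile MAGs have no defined rank correlation and are excluded
but reported. Every edge's (ρ, p) is bit-identical to what
`spearmanTest()` returns for that pair.

Cohort detection operationalizes "hierarchical clustering confirmed by
rank correlation":

1. profiles are rank-transformed per MAG and z-scored, and clustered with
   Ward's minimum-variance linkage (`ward.D2`) on Euclidean distances.
   Euclidean distance between standardized rank vectors is a monotone
   function of Spearman ρ, so the tree's geometry agrees with the
   confirmation statistic; clustering raw z-scored magnitudes instead
   (available via `standardize = FALSE` plus a manual transform) lets
   magnitude outliers interleave foreign profiles into a cohort's subtree
   and fragment it.
2. the tree is cut by confirmation, walking from the root: a cluster is
   accepted when the **median pairwise ρ ≥ 0.8** *and* **every member's
   median ρ to the rest ≥ 0.8**; failing clusters are split at their top
   merge and re-examined. The per-member condition is essential: the
   cluster median alone is robust — a 15-member cohort can absorb a
   3-member foreign group while its median stays high — so median-only
   confirmation cannot bound cohort purity.
3. singletons and unconfirmed members are reported `unassigned`. Ties in
   merge order are resolved lexicographically by MAG id; the whole
   procedure is deterministic and invariant to row order.

Cohort preference consistency asks whether all members share one
enrichment class per grouping (fraction preference; DO preference), with
exclusives counted as enriched on their side and missing classes making a
cohort indeterminate rather than non-uniform.

## The synthetic-data generator

`simulateCommunity()` produces all pipeline inputs with the statistical
structure the analysis assumes, plus ground truth. The defaults encode the
study design this package targets: 4 sites × 2 wells × 2 fractions = 16
metagenome samples; 6 transcriptomes (2 oxic, 4 dysoxic); 200 ultra-small
MAGs (Patescibacteria-dominated, true sizes ~N(1, 0.4²) Mbp truncated at
0.4) plus 100 larger background MAGs; 20 cohorts of 2–20 members;
within-cohort noise CV 0.2; enrichment effect 4; site effect 10;
dissolved oxygen spanning 0.37–7.5 g/m³ with sites spread evenly across
the range (so both redox classes always exist), DOC 0–26 and nitrate-N
0.45–12.6 g/m³.

Structure of a cohort profile, per sample:

- a **well-level base** (log-normal), shared by the well's two fraction
  samples, so it cancels out of planktonic-vs-attached contrasts;
- log-bases are **centered within each site**, so which site dominates a
  cohort is decided by the site effect alone and can never be inverted by
  base-draw luck (an uncentered draw overwhelms a 10× site effect about
  once per hundred cohorts, which silently falsifies the planted truth);
- the remaining **within-site well contrast (sd 1.5)** and a **per-sample
  jitter (sdlog 0.4)** are shared by cohort members and independent
  between cohorts — they are the signal that separates cohorts with
  overlapping niches;
- a ×10 multiplier at the cohort's dominant site and a ×4 multiplier in
  its preferred condition (if any);
- member-level mean-one log-normal noise at the configured CV;
- multinomial read sampling per sample at depths drawn uniformly from a
  5× range (1–5 M reads), so column totals differ and normalization is
  non-trivial. Depths are deep enough that rank profiles stay informative;
  at shallow depth, shared blocks of zero counts tie ranks and inflate
  cross-cohort correlations.

Cohorts are planted in **distinct niches** — a niche being the pair
(preference label, dominant site), with oxygen labels restricted to sites
of matching redox class. Two cohorts sharing both coordinates are
rank-indistinguishable at 16 samples (they share every planted mask), so
niches are drawn without replacement and recycled only when more cohorts
are requested than niches exist (> 16 under the defaults). Unassigned
MAGs get private profiles with random niches. The background community
carries most of the read mass, keeping ultra-small taxa a minority of
each sample.

Transcript counts are negative binomial (dispersion 0.3) around means
composed of a per-gene baseline, a per-MAG oxic:dysoxic activity ratio
tied to the MAG's enrichment label (central fold 8, configurable), and a
per-COG-category ratio drawn log-uniformly from [1/4, 4] (configurable;
`c(1, 1)` plants no category effect). About 2% of genes are forced
exclusive to each condition. Because modified-TPM divides by library
size, it measures expression *relative to total community output*; the
ground-truth tables therefore store the effective, mass-weighted and
compositionally corrected ratios that an estimator can actually recover,
alongside the raw planted ones. Ultra-small genes are 84% unannotated
(matching the extreme unannotated expression share of these lineages),
background genes 25%.

What the generator does **not** emulate: real taxonomic composition or
phylogenetic signal, zero-inflation at realistic sequencing depth,
chimeric or cross-mapped bins, amplicon primer biases, or spatial
autocorrelation beyond the site/well hierarchy. Passing recovery tests on
it demonstrates that the computational chain is correct and calibrated —
not that any particular biological conclusion holds on real data.

## Numerical choices and degenerate inputs

- Half-open redox intervals; DO exactly 3 is dysoxic.
- Inclusive AAI filter bounds (identity 30.0 and coverage 0.70 are kept).
- Constant vectors: correlation undefined (`NA`, flagged), z-scores
  become zeros with a warning, min–max scaling maps to the lower bound
  with a warning.
- All-zero columns: left zero by normalization and relative abundance;
  Bray–Curtis defined as above.
- Ties: average ranks in correlations; lexicographic tie-breaks in
  best-hit selection, top-gene ranking and cohort merge order — every
  result is reproducible bit-for-bit under a fixed seed, and the same
  `SimulationConfig` yields byte-identical written files.
- Division-by-zero conventions: enrichment `Inf` = exclusive; fold change
  `Inf` when the denominator condition is silent; genome size undefined at
  completeness 0 (error).

## Problem sizes used by the tests

The unit suite runs on toy fixtures computed by hand or by independent
oracles (brute-force AAI enumeration, explicit rank-transform correlation,
hypergeometric rarefaction). The recovery tests use 60 ultra-small + 60
background MAGs with 8 planted cohorts for cohort recovery, the full
default design for enrichment accuracy (at CV 0.3) and expression-ratio
recovery, 200 hit pairs for AAI, 1,000 null rows for type-I calibration
and 500 for the network false-edge rate; the determinism test runs the
complete default pipeline twice. These sizes keep the whole suite under a
minute while leaving each statistical bound several standard errors of
headroom.

## Known limitations

- Cohorts whose niches overlap partially (e.g. sharing a dominant site
  with different preference labels) occasionally exceed the ρ = 0.8
  confirmation bound jointly and merge; in repeated simulations this
  affects roughly one run in thirty at the 8-cohort design. In such runs
  the merged groups are genuinely co-occurring by the method's own
  definition — the limitation is of identifiability at n = 16, not of the
  implementation.
- The t-approximation for Spearman p-values is adequate at n = 16 for the
  thresholds used here; for very small n or extreme ρ the permutation mode
  is the reference.
- The normalization rule ("scale to the deepest sample") is an
  interpretation of terse methods wording; the alternative reading
  (down-scale to the shallowest) differs only by a global constant and is
  available by rescaling.
- AAI novelty summarizes only the family band; finer ranks need
  phylogenetic placement, which is out of scope.
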