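---
title: "Classifying and characterizing benthic producer exometabolomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying and characterizing benthic producer exometabolomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reefexo)
```

## The problem

Benthic primary producers on coral reefs — corals, crustose coralline algae
(CCA), fleshy macroalgae, and turfing algae — release dissolved organic
matter (DOM) into the surrounding water. Untargeted LC-MS/MS of
solid-phase-extracted incubation water resolves thousands of MS1 features
(unique m/z x retention-time entities with XIC peak areas), only a fraction
of which are producer-derived. `reefexo` implements the downstream analysis
that turns an aligned feature-quantification table, sample metadata,
feature annotations and bulk water chemistry into (i) a defensible set of
producer exometabolite features, (ii) their energetic and elemental
characterization, and (iii) subnetwork-level structural summaries — and it
ships a synthetic-experiment generator with planted ground truth so every
stage is testable end to end without any external data.

The experimental design the package assumes: triplicate incubations of five
producers plus filtered-seawater Controls over an 8-h daytime and a
subsequent 8-h nighttime period, ambient reef water sampled before each
period, and daily process blanks (42 water samples + 8 blanks).

## The classification cascade

Features are classified by five sequential rules, each parameterized and
each defaulting to the conventional thresholds:

1. **Background**: mean peak area across non-blank samples below twice the
   maximum across blanks. Removed.
2. **Transient**: at or above the threshold peak area (`2e5`, twice the
   instrument noise threshold of `1e5`) in fewer than three samples.
   Removed.
3. **Ambient vs exudate**: a feature is an exudate if the log2 ratio of any
   endpoint-cell mean (Controls included) to the ambient-start mean exceeds
   1. Means are floored at the noise threshold before the ratio so that
   zero ambient means give finite, conservative fold changes; the floor
   preserves the "twofold" semantics at realistic intensities.
4. **Exometabolite**: among exudates, per diel period a one-way ANOVA
   across the six endpoint groups and one-sided Dunnett many-to-one
   comparisons of each producer against the Control, with
   Benjamini-Hochberg FDR across the pooled family of all features x five
   producers x two diel periods. A feature is an exometabolite if any
   adjusted p falls below 0.05; its significant (treatment, diel) cells
   define its treatment association.
5. **Subtypes** for the remaining exudates, with precedence artifact >
   benthic > planktonic: doubled over ambient in both Day and Night
   Controls (incubation artifact, excluded downstream), in one or more
   organismal treatments (benthic exudate), or in either Control
   (planktonic exudate).

Design choices where the convention was genuinely open:

* **Test scale.** The enrichment test runs on raw peak areas by default
  (`on = "raw"`), the same quantity whose fold changes define the classes.
  Testing per-sample relative abundances (`on = "relative"`) is available
  but couples features compositionally: a producer's own abundant exudates
  inflate its total peak area and dilute every other feature's share, which
  biases the one-sided test toward misses.
* **Direction.** Dunnett comparisons are one-sided (producer > Control)
  because the class is defined by enrichment; two-sided is available.
* **FDR family.** One pooled BH family across features, producers and diel
  periods — the most conservative defensible reading; a per-diel family is
  available.
* **Omnibus gating.** The ANOVA F-test is computed and reported but does
  not gate the Dunnett comparisons; gating is available by argument.
* **Subtype precedence.** The three subtype rules overlap; artifact wins
  (doubling in both Controls indicates an incubation effect whatever else
  happened), then benthic (producer origin), then planktonic.

## The Dunnett engine

Each comparison uses the pooled variance across all six groups. With
product-form correlation (shared control), conditioning on the control mean
and the pooled SD makes the comparisons independent, so the max-T tail is a
smooth two-dimensional integral. We evaluate it by Gauss–Legendre
quadrature (48 x 48 nodes), accumulating the inner product of normal CDFs
in log space so far-tail p-values (below `1e-6`) remain accurate. This is
fully deterministic — no Monte-Carlo seed — with quadrature error around
`1e-10`, and it is cross-checked in the test suite against `multcomp::glht`
and against a brute-force million-draw max-T simulation. When thousands of
t statistics share one design (the per-feature tests), the tail is computed
exactly on a dense 513-knot grid and interpolated monotonically on the log
scale, with interpolation error far below the quadrature error.

Degenerate inputs follow explicit conventions: zero total variance gives
p = 1 (flagged); zero within-group variance with unequal means gives p = 0.

## Energetics and stoichiometry

For formulas over C, H, N, O, P, S with net charge Z, the nominal oxidation
state of carbon is

NOSC = 4 − (−Z + 4C + H − 3N − 2O + 5P − 2S) / C,

anchored by glucose (0), CO2 (+4) and methane (−4). The standard Gibbs
energy of the carbon-oxidation half reaction is the affine map
ΔG°Cox = 60.3 − 28.5·NOSC kJ (mol C)⁻¹ at 298 K, from the published
regression of half-reaction energies on NOSC; the constants are exposed as
arguments so other calibrations can be substituted. More reduced carbon
yields more catabolic energy, so the map is strictly decreasing.

Only high-quality formula assignments enter these summaries: ZODIAC score
strictly above 0.98, non-chimeric, a fragmentation tree explaining more
than 4 fragments and more than 80% of spectral intensity.

Per producer endpoint sample, using that producer's significantly enriched
features:

* **Weighted NOSC** uses carbon-content weights (abundance x formula carbon
  count), making it scale-invariant in the abundances.
* **Elemental ratios** (N:C, P:C, H:C, O:C) are abundance-weighted means of
  per-molecule ratios ("per molecule"); the ratio-of-weighted-element-sums
  alternative is available via `mode = "element_sums"`.
* **Ternary stoichiometric classes** partition molecules by nutrient
  element presence — P-containing, N-containing without P, CHO(S)-only —
  with abundance-weighted shares summing to one. The three-class definition
  is our reading of the "three stoichiometric classes" convention; it is a
  function argument away from being replaced.
* **Feature-standardized weighting** is the ionization-bias robustness
  variant: each feature's areas are z-scored across samples and the weight
  of a feature in a sample is its z-score shifted non-negative (z minus the
  within-sample minimum plus one SD unit, so identical z-profiles reduce to
  the unweighted mean). Weighted means require non-negative weights; the
  shift convention is ours and is documented here because no standard
  exists.

## Ordination, subnetworks, congruency

Exometabolite relative abundances are angular transformed
(arcsine square root) and z-scored per feature; ordination is principal
coordinates on Euclidean distances of that matrix (equivalently PCA of the
transformed data — the metric is our choice, as only the transform and
"principal coordinates" are conventional), and PERMANOVA partitions the
same distances by treatment, diel and interaction with sequential sums of
squares (the `adonis2` default ordering) and free label permutation.
Pairwise treatment contrasts report raw and BH-adjusted permutation p.

Subnetworks (molecular families from spectral networking) are aggregated as
summed member relative abundances per sample, tested for producer
enrichment with the same Dunnett + pooled BH machinery on the summed
shares, and called enriched only when the adjusted p is below alpha *and*
the fold change over Control is at least twofold. Focus subnetworks for
presentation must be abundant (mean summed share above 0.05% of at least
one producer's daytime exometabolome), diverse (strictly more than five
exudate nodes) and enriched at FDR p < 0.01.

Congruency between treatment-association categories (source-producer set
plus day/night/both activity) and any label set (subnetwork id, structural
class, library match) is the likelihood-ratio uncertainty coefficient
U(category | labels) = G² / (2N·H(category)) — the "R-square (U)"
convention of common statistical software — with the χ² tail of G² as its
p-value and Cramér's V reported alongside. Note the coefficient's positive
small-sample bias when the label set has many levels relative to N.

## The synthetic-data generator

`generate_experiment()` emulates the study design with planted classes:

* **Noise model**: multiplicative mean-one lognormal noise (sdlog
  `sigma = 0.3`, a ~30% CV typical of triplicate incubation XIC areas —
  the within-treatment variance is a free parameter documented as such)
  plus additive detector-floor noise (SD `5e3`), truncated at zero.
* **Background** features appear in blanks at 60% of their sample mean;
  **ambient** features are flat everywhere; **transient** features occur in
  only 1–2 samples.
* **Exometabolite** features are enriched in their source producer cells by
  lognormal fold changes with geometric mean 40 and geometric SD factor 5,
  truncated below at 2 so every planted exometabolite is an exudate by
  construction. 86% of features have a single source producer; day-only
  activity dominates (60%), mirroring daytime-dominated exudation.
* **Benthic exudates** (exudates that are not statistically separable from
  Controls) are modeled as patchy release: one replicate per source cell
  carries a 6–12x spike, so the cell mean doubles over ambient while the
  within-cell variance stays structurally too large for significance. A
  homogeneous elevation cannot represent this class faithfully — it either
  doubles and tests significant or does neither.
* **Planktonic exudates** are elevated in a single Control cell;
  **incubation artifacts** are elevated in every incubated endpoint, both
  diels.
* **Formulas** come from five compound-class templates (lipid-like,
  sugar-like, peptide-like, P-rich, N-heterocycle) mixed per producer:
  corals phosphorus-rich (strongest in *Pocillopora*), the macroalga
  lipid-like (reduced, energy-rich), turf nitrogen heterocycles. Features
  in the top abundance quartile of a producer preferentially (85%) carry
  its signature template, reflecting the observation that a producer's
  hallmark compound families are its most abundant exudates; without this
  association, single dominant features make abundance-weighted ratios
  nearly irreproducible across simulated worlds.
* **Subnetworks** chunk each producer's exometabolites within template
  pools (sizes ~3–12), so subnetwork identity is more congruent with
  treatment association than the shared structural classes — the ordering
  the congruency analysis should recover.
* **Bulk chemistry**: DOC is a linear function of summed exudate peak area
  with residuals orthogonalized and scaled so the realized per-diel R²
  equals its target (0.84 day, 0.63 night); TDN/TDP derive from the planted
  per-sample exometabolite N:C and P:C; DO and pH carry the classic diel
  signature (daytime algal oxygenation, nighttime respiration).

What the generator does **not** emulate: retention-time drift, isotope
patterns, correlated ionization suppression, compositional closure of real
XIC areas, heteroscedastic blank contamination, or any microbial
transformation during incubations. Passing the planted-recovery tests
therefore demonstrates that the rules and statistics do what they claim on
data with the study's declared structure — not that the thresholds are
optimal for any particular real instrument.

## Problem sizes and numerical conventions

The default synthetic world has 870 features x 50 samples (a deliberate
~25x scale-down of the 20,742-feature batch, keeping the full design
structure); the test suite's calibration studies use 200 replicate worlds
of 1,000 null features, 100 random 50-feature fixtures for oracle
equivalence, and a 10⁶-draw Monte-Carlo oracle for the Dunnett tail.
PERMANOVA defaults to 999 permutations (499–199 in the heavier simulation
loops). All fold-change means are floored at `1e5`; relative-abundance
columns must sum to 1 within 1e−9; transformed features with zero variance
map to zero rows with a warning rather than NaN.

Known limitations: the cascade operates on whatever sample set it is given
(the original batch context of additional field samples is represented only
through the background-filter `universe` argument); gap-filled values below
the noise threshold are retained as exported; PERMANOVA uses free
permutation (no restriction to incubation blocks); and the uncertainty
coefficient is reported without small-sample bias correction.
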