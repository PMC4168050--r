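---
title: "Methods: entropy-based specificity mining of nodule expression compendia"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: entropy-based specificity mining of nodule expression compendia}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nodentropy)
```

## The analytical substrate

The package operates on a *compendium*: a gene × condition matrix of
linear-scale hybridization signals (RMA-style output, background
around 9, saturating in the tens of thousands) plus a condition
metadata table (organ, treatment, timepoint, sample class, replicate
group). Inputs are assumed normalized and complete — an empty or
negative cell is a hard error, never silently imputed — because the
compendia this package targets are distributed as finished matrices.
`NA` appears only in derived outputs (for example the entropy of a
gene with no signal anywhere) and serializes as `NA` in the TSV
writers, which print reals at 12 significant digits with a `.`
decimal separator.

## Tissue specificity by Shannon entropy

Conditions are first averaged into tissue classes. The default panel
(`default_tissue_map()`) uses untreated whole-organ samples of ten
tissues — leaf, petiole, stem, bud, flower, seed, pod, root, nodule,
mycorrhiza — with nodule represented by its 4/10/14/28 dpi stages,
seed by its developmental series, and root by its experiments
including the 0 dpi nodulation control. Averaging the root
experiments together (rather than keeping them as separate tissues)
is an assumption; a custom `tissue_map()` overrides it.

For gene $g$ with mean signal $W_{t/g}$ in tissue $t$ of $N$:

$$P_{t/g} = \frac{W_{t/g}}{\sum_{1 \le t \le N} W_{t/g}}, \qquad
  E_g = \sum_{1 \le t \le N} -P_{t/g}\,\log_2 P_{t/g}.$$

$E_g$ ranges from $0$ (one tissue only) to $\log_2 N$ (uniform);
with $N = 10$ the ceiling is $3.32$ bits. Numerical conventions:

* $0 \cdot \log_2 0 := 0$ (the standard entropy limit);
* genes with all-zero profiles are *excluded from ranking* rather
  than assigned maximal entropy — an unexpressed gene has no
  specificity to rank;
* no background subtraction is applied before normalization (a
  configurable floor could be added upstream, but entropy is computed
  on the values as given);
* entropy ties are broken lexicographically by gene id so ranks and
  the selected top-$k$ set are reproducible.

Because $P$ is scale-invariant, entropy is unaffected by per-gene
rescaling; it is also permutation-invariant over tissues. Both
properties, the $[0, \log_2 N]$ bounds, and agreement with a naive
term-by-term summation to $10^{-12}$ on 1,000 random profiles are
enforced by the test suite. Entropy measures *evenness*, not
*strength*: a gene uniformly expressed at background and one
uniformly expressed at saturation both score $\log_2 N$. That is why
the expression-strength statistics (below) complement it.

## Temporal waves and zone profiles

Over the nodule time course, replicate-averaged signals are expressed
per gene as ratios to the 14 dpi level (`temporal_ratios()`), the
stage by which the nodule-specific transcriptome is fully activated.
The wave rule (`assign_waves()`) declares a gene activated at the
first timepoint among 4, 6, 10, 14 dpi where its signal reaches both

* `activation_fraction` (default 0.5) of its own 14 dpi level, and
* `floor_factor` (default 5) × background (estimated as the 2nd
  percentile of all signals, which on these arrays sits at the
  hybridization floor; both configurable).

Activation at 4 dpi is wave 1, at 6 dpi wave 2, at 10 or 14 dpi
wave 3; never activated is `unassigned`. The relative threshold
ensures weakly-expressed genes are classified on their own scale; the
absolute floor keeps background flicker from "activating". Raising
`activation_fraction` can only push genes to later waves — a
monotonicity property under test. A gene is `declining` when its
latest-timepoint signal falls below `decline_fraction` (default 0.5)
of its temporal maximum. Fixing three waves by an activation-dpi rule
(rather than clustering) makes the classification testable and
directly expresses the observed staging: few genes fully on at 4 dpi,
most on but submaximal at 6 dpi, essentially all on by 10 dpi.

Zone profiles are $\log_2(\text{zone} / \text{mean of five zones})$
per gene over the hand-dissected samples I, II, II–III, III, IV
(apical → proximal). The back-transform invariant — the mean of
$2^{\text{profile}}$ over zones is exactly 1 for every defined gene —
is asserted in the tests.

The timepoint-correlation matrix (Pearson, over a gene subset's
replicate-averaged profiles) quantifies phase coherence: the
pre-activation timepoints (0, 3 dpi) and the fully activated ones
(10, 14 dpi) each correlate near 1, while cross-phase pairs do not.

## Clustering

Heat-map dendrograms use agglomerative average linkage (UPGMA) under
Euclidean or Pearson ($1 - r$, sign-sensitive by intent: co-activation
and anti-activation are different things) distance. Because the
clustering tools historically used for these figures leave
tie-breaking unspecified, leaf orders of published heat maps are not
reproducible in principle; this implementation therefore pins ties
down: among equal-distance merge candidates, the pair with the
lowest smallest original row index merges first, and the subtree with
the smaller minimum index goes left. Merge heights are validated to
$10^{-9}$ against an exhaustive recomputation of cluster-average
distances (no Lance–Williams shortcut) and against
`stats::hclust(method = "average")` on tie-free random matrices.
Rows with zero variance are rejected under Pearson distance with the
offending gene named.

## Screens and QC

All differential screens use Welch's unequal-variance $t$-test on
linear signals with raw (uncorrected) $p < \alpha$ (default 0.05),
replicating the original analytic choices; sidedness follows each
directional claim (one-sided where the question is "higher in X").
A Benjamini–Hochberg mode reports $q$-values because family-wide
screens at raw $\alpha$ are anticonservative; it is off by default to
keep the replication faithful. Fold changes are ratios of group means
(not means of per-replicate ratios). Degenerate inputs have defined
behaviour: both groups constant and equal gives $p = 1$; groups of
fewer than 2 replicates are errors.

The senescence screen reports per-gene treated/control ratios and
per-family fractions below/above 1 — the geometry of a scatter around
the unit line. Genes with zero control mean are excluded from the
fractions.

Expression strength takes each gene's *maximum* over all conditions
(the natural statistic for genes expressed in a single organ, whose
compendium-wide mean would be diluted by the silent conditions) and
summarizes a cohort by mean, median and the fractions exceeding
5,000 / 10,000 / 15,000 signal units.

Relaxed-specificity flagging marks a family gene expressed outside
the target organ: signal in ≥ 1 non-target condition above
$\max(\texttt{floor\_factor} \times \text{background},\;
\texttt{ratio\_cut} \times \text{own target maximum})$ with defaults
5 and 0.01 — the ratio cut captures exceptions expressed 10- to
100-fold lower outside nodules than inside. Background here is the
median non-target signal of non-family genes (robust, rather than
visual heat-map judgment). Conditions flagged by contamination QC are
excluded from the scan, since nodule signal leaking into a
contaminated sample is not relaxed specificity.

Contamination QC screens non-target conditions for marker signal that
should not be there (bacterial markers tracking rhizobial RNA outside
nodules), flagging conditions above median $+ z_{\text{cut}} \times
\text{MAD}$ (default $z_{\text{cut}} = 5$) of the non-target marker
means. The flag set shrinks monotonically in $z_{\text{cut}}$.

## The synthetic generator

`simulate_compendium()` draws compendia with planted, fully labelled
structure so that every stage above is tested by *recovery* rather
than by re-asserting its own output. Defaults emulate the atlas-scale
study conditions: 500 genes × 267 conditions across ten tissue
classes; a 0/3/4/6/10/14/28 dpi time course with 6 replicates per
timepoint (the source atlas holds 42 nodule samples); five zone and
five LCM cell-type sample groups at 3 replicates; senescence
control/nitrate/herbicide contrasts; 150 filler stress/hormone
conditions; a 60-gene nodule-specific family of which 5 are relaxed
and 2 uninfected-cell-biased (9.6× and 3.2× the infected-cell
level); 8 senescence markers; 10 bacterial markers; and one
mycorrhiza sample mixed 20 % with a 14 dpi nodule sample.

Model components, and why:

* **Noise** is multiplicative log-normal with unit mean (default cv
  0.2), the standard heteroscedastic microarray approximation; no
  noise model is given by the motivating study.
* **Probe-specific backgrounds.** Family genes sit at gene-specific
  backgrounds (log-normal around 9, capped at 10× background) shared
  across conditions — the probe-affinity effect that makes two
  pre-activation timepoints correlate near 1 on real arrays, which
  pure i.i.d. noise around a common background cannot produce.
* **Waves** are rescaled logistic activations in dpi (midpoints
  3.2 / 5.2 / 7.5, scales 0.5 / 0.6 / 0.5), pinned to exactly zero at
  ≤ 3 dpi: family expression requires infected cells, which do not
  exist before 4 dpi. The midpoints place wave 1 at ~72 % of its
  14 dpi level at 4 dpi, wave 2 at ~79 % at 6 dpi, and wave 3 at
  ~99 % at 10 dpi — few genes fully on at 4 dpi, most on but
  submaximal at 6, all on by 10.
* **Zone and cell-type weights** follow the wave → zone
  correspondence (wave 1 apical, wave 3 proximal; all waves lower in
  the senescent zone IV than in zone III; meristem essentially silent;
  uninfected cells at trace level except for the planted UC-biased
  genes).
* **Senescence** multiplies family genes by 0.2 and markers by 5 in
  treated samples — the rapid shutdown observed within hours of
  induction, against strongly activated markers.
* **Peaks** are log-uniform on 5,000–33,500, the signal ceiling of
  the platform; a hybridization floor clamps all expected signals at
  background from below.
* **Relaxed genes** carry a reproducible 600–3,000 signal in root and
  stem conditions — including ≤ 3 dpi nodule primordia, which are
  still mostly root tissue.
* **Ordinary genes** get per-organ baselines (log-normal level ×
  mild per-organ factors), with 6 % made organ-specific outside the
  nodule so that genuinely low-entropy non-family genes (seed-,
  flower-, root-specific clusters) compete in the specificity
  ranking.

What the generator does *not* emulate — and what passing recovery
tests therefore cannot show about real data: probe-level effects and
cross-hybridization between homologous family members,
amplification bias in LCM samples, correlated (batch) noise across
conditions, the long-tailed condition-specific responses of real
stress series, and any disagreement between platforms. Recovery rates
on synthetic data are upper bounds on real-data performance.

## Problem sizes and determinism

The test suite runs the default 500 × 267 compendium once (shared
across test files), 20 null compendia for the screen-calibration
check, 20 reduced compendia (150 genes) for the QC false-flag check,
1,000 random profiles for the entropy oracle, and 45 random 6 × 4
matrices for the clustering oracle — sizes chosen so the full suite
exercises every recovery property in well under a minute. The
generator is bit-reproducible given its config; the pipeline summary
is byte-identical across reruns with the same seed. For the
screen-calibration check, the expected flag rate is not nominal
$\alpha$ but the true null size of a 3-vs-3 one-sided Welch test
under log-normal noise (slightly conservative at this sample size),
which the test computes by direct simulation from the closed-form
statistic and compares under a binomial band.

## Known limitations

* The entropy ranking depends on the tissue panel: merging or
  splitting tissues changes $E_g$ and its ceiling ($\log_2 N$); the
  package reports $N$ alongside every table.
* Wave assignment presumes the reference timepoint (14 dpi)
  represents full activation; families with later maxima need a
  different reference.
* Screens on 2–3 replicates have limited power and approximate
  calibration; the BH mode mitigates multiplicity but not sample
  size.
* The CLI is a thin wrapper; programmatic use through `run_pipeline()`
  is the primary interface.
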