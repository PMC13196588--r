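---
title: "Quantifying phage resistance and its evolution with phageresist"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying phage resistance and its evolution with phageresist}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phageresist)
```

## The measurement problem

When a lytic phage is mixed with a susceptible bacterial culture, the culture
fails to grow; when the bacterium is resistant, growth is unaffected.
`phageresist` quantifies where each strain x phage interaction falls on that
continuum and follows the consequences: which resistances co-occur
(cross-resistance), what they cost the cell (growth rate, competitive
fitness), which mutations produce them, and in what order a population under
multi-phage pressure acquires them.

## The resistance statistic and its calibration

The core score is relative bacterial growth (RBG): the absorbance gain of a
phage-treated well divided by the gain of its no-phage control over the same
window (8 h by default, 16 h for slow growers),

$$\mathrm{RBG} = \frac{\Delta \mathrm{OD}_{600}^{\,\mathrm{phage}}}
                      {\Delta \mathrm{OD}_{600}^{\,\mathrm{control}}}.$$

RBG is 0 for complete sensitivity and 1 for complete resistance. Lysis below
the inoculum density yields a negative numerator; we clamp it to 0 (it is
"complete sensitivity", only more so) but keep a flag so the event is
auditable. Values above 1 — a strain that grows marginally better with phage
than without — are preserved as measured. A non-growing control makes the
score undefined and is an error, not a zero.

Across a panel of many strains and phages the mean RBG values are strongly
bimodal: one mode near 0 (sensitive interactions) and one near 1 (resistant).
`rbg_calibrate()` turns that empirical distribution into classification
thresholds:

1. a Gaussian kernel density with the Silverman-type `"nrd0"` rule-of-thumb
   bandwidth is evaluated on a 512-point grid spanning the observed range;
2. local maxima with prominence of at least 1% of the peak density are
   candidate modes; the two most prominent are the sensitive and resistant
   modes (fewer than two is an error — no thresholds are issued for a
   unimodal panel);
3. the grid argmin strictly between the modes is the valley — the natural
   class boundary; on a flat plateau the midpoint of the argmin set is taken;
4. the valley is bootstrapped (resample interactions with replacement, 1000
   times by default) and the percentile 95% interval, rounded *outward* to
   two decimals, gives the class bounds.

The rounding direction is deliberate: the interval between the bounds is an
"intermediate" buffer class, so widening it can only make the sensitive and
resistant calls more conservative. Classification is then

* sensitive: RBG $\le$ lower bound,
* resistant: RBG $\ge$ upper bound,
* intermediate otherwise.

```{r calibrate}
set.seed(1440)
panel <- c(rbeta(720, 2, 50), rbeta(720, 50, 2))  # a bimodal mean-RBG panel
cal <- rbg_calibrate(panel, n_boot = 300, seed = 1)
cal
```

The bandwidth, grid size, prominence threshold and bootstrap count are all
exposed as arguments; the defaults above are what we consider sensible for
panels of a few hundred to a few thousand interactions.

## Cross-resistance between receptor groups

Each strain in a panel is labelled by the phage that selected it, and each
phage by the receptor it targets (here: the LPS O-antigen, the LPS core
oligosaccharide, or the outer-membrane transporter BtuB).
`cross_resistance_summary()` asks, for every ordered pair of receptor groups:
of the strains selected by group A phages that are in fact resistant to their
own selecting phage, what fraction is also resistant to group B's phages?
Because the LPS core anchors the O-antigen, core-truncating mutations remove
both structures while O-antigen mutations leave the core intact — so the
matrix is expected to be asymmetric. Two counting rules are supported for
multi-phage target groups: `"all"` (default; resistant to every phage of the
group) and `"any"`. Intermediate calls never count as resistant. An empty
denominator is reported as undefined, not as 0%.

`cluster_rbg_matrix()` orders strains by profile similarity (Euclidean
distance, average linkage, ties broken by input order) and exports the tree
as Newick text.

## Growth kinetics and fitness costs

`summarize_kinetics()` reduces an OD600 time series to three numbers:

* **mu_max** — the maximum specific growth rate, estimated as the largest
  least-squares slope of log blank-corrected OD over sliding windows of 5
  consecutive readings (2 h at the standard 30-min sampling). Windows
  containing a reading below a detection floor (`min_od`, default 0.02 OD
  above blank) are excluded: below that floor the log-transform amplifies
  instrument noise so strongly that the max-over-windows statistic is
  dominated by noise rather than growth, and no plate-reader analyst would
  fit there. Blank-corrected ODs are floored at 1e-6 before the log.
* **auc** — the trapezoidal integral of blank-corrected OD on the raw
  sampling grid (no resampling; irregular grids are fine), with negative
  values clamped to 0 first.
* **endpoint_delta** — the raw OD change over the assay window (0-8 h by
  default, extensible to 16 h per sample).

We use the transparent window estimator rather than a parametric (logistic,
Baranyi, Gompertz) fit because it is assumption-light and trivially checkable
against a brute-force oracle that fits every admissible window with `lm()` —
the test suite does exactly that. By default no blank is subtracted
(`blank = 0`), since endpoint assays are typically already
background-corrected; pass the plate blank when it is not.

Fitness costs are expressed three ways:

* `relative_growth_rate()`: mutant mu_max over ancestral mu_max;
* `competition_fitness()`: from a 24-h head-to-head co-culture,
  $W = \ln[T_R(24)/T_R(0)] / \ln[T_S(24)/T_S(0)]$, with final densities
  split by the phenotypes of (by default) 20 sampled colonies. An all-or-none
  colony split gets a +0.5 continuity correction on both counts (on by
  default) rather than a log-of-zero failure; a wild type that failed to
  grow makes $W$ undefined and is flagged. Initial densities come from
  separate plating of each strain, not from an assumed 50:50 mix.
* `efficiency_of_plating()` and `adsorption_rate()`: titer ratios with a
  below-detection flag (EOP 0 with an upper bound from the detection limit)
  and clamping to [0, 1] respectively.

Group AUC comparisons (`compare_groups_auc()`) use two-sided Welch t-tests
on every ordered pair, reported raw with optional Benjamini-Hochberg
adjustment. More elaborate multiple-comparison procedures (Dunnett-type) are
out of scope.

## Mutation analysis

`read_variant_table()` consumes either breseq genome-diff files or a flat
TSV. The closed mutation vocabulary is {nonsense, missense, frameshift,
large_indel, synonymous, intergenic, other}; deletions/insertions of at
least 30 bp count as large indels (panels of resistant clones show 78, 824
and 2383 bp deletions clearly distinct from 1-2 bp frameshifts; "large" is
configurable because no standard boundary exists), shorter out-of-frame
coding indels are frameshifts, and mobile-element insertions in coding
sequence are treated as large indels.

`filter_lof_variants()` retains the four putatively function-destroying
classes — including missense, which is broader than a conventional
loss-of-function definition but matches how receptor-inactivating point
mutations behave in this assay system — at or above a 5% population
frequency floor (the usual polymorphism-calling threshold).
`subtract_background()` removes calls already present in the ancestor,
matched on (gene, nucleotide change) so that flat tables without genomic
coordinates still subtract correctly.

The built-in `default_gene_class_map()` assigns each receptor-pathway gene a
phenotype class and pathway group: the *rfb* cluster and *rfc* give
O-antigen-only resistance; core-truncating *rfa* genes (*rfaI*, *rfaJ*,
*rfaG*, *rfaF*, *rfaK*) and the regulator *rfaH* give resistance to both
LPS-targeting groups; *rfaP*, *pgm* and *galE* give core-only resistance.
Class is allele-dependent for *rfaJ*: its loss-of-function alleles truncate
the core (and with it the O-antigen), while the missense alleles
A198V/L229P/A275E/D216E alter the core without losing the O-antigen — an
allele-level override table captures this. *hldE*, occasionally seen early
in evolving populations, is mapped to sugar-precursor/core-only by pathway
analogy and flagged as inferred.

Population time courses are handled by `build_trajectories()` (frequencies
per replicate per timepoint, aggregated at gene, class or receptor-category
level). Distinct alleles of one gene are usually alternative sweeps of the
same target, so the default combine rule is `max`; `sum_capped` is available
when alleles are known to reside on distinct backgrounds — which of the two
a given experiment needs cannot be decided from the table alone, so both
are first-class. `detect_sequential_acquisition()` reports, per class, the
median (across replicates) first timepoint at which the frequency reaches a
dominance threshold of 0.5 — "more likely than not that a random cell
carries it" — and orders classes by it, flagging simultaneous crossings as
ties.

## Insertion-sequencing enrichment

`compute_enrichment()` is a deliberately transparent readout for
transposon-library phage-challenge screens: per-million normalization,
log2 fold change of mean normalized abundance (with a 1-per-million
pseudocount), a two-sided pooled proportion test per gene, and BH q-values.
It is designed for planted-signal recovery on synthetic tables and for
qualitative ordering of real screens (receptor-gene mutants enriched orders
of magnitude above everything else); it does not attempt to reproduce any
particular published pipeline's numeric fold changes, and site-level
modeling (TA bias, essentiality) is out of scope.

## The synthetic-data generator

Every analysis stage has a paired generator in `sim_config()` /
`gen_*()`, so the whole pipeline is testable with no external data. The
defaults encode the study designs the analyses assume:

* growth: logistic curves, r = 0.8 h^-1, K = 1.0, N0 = 0.01 OD, additive
  Gaussian noise sd 0.002 (typical plate-reader repeatability), 24 h at
  30-min sampling, triplicate wells; sensitive strains under phage stay at
  the inoculum (matching RBG = 0 semantics; an exponential-decline lysis
  mode is optional), resistant strains track their control;
* interaction panel: 180 strains (20 per selecting phage, 40 for the single
  O-antigen phage) x 8 phages x 3 replicates; RBG drawn from Beta
  distributions with modes 0.034 and 0.977 (concentration 52); resistance
  states drawn once per strain x receptor group — resistance is
  receptor-mediated, so all phages of a group share the state — with focal
  resistance probability 166/180 and cross-group probabilities 0.447
  (core to O-antigen), 0.216 (O-antigen to core) and 0.05 (LPS vs BtuB);
* sweeps: logistic allele-frequency trajectories
  $f(t) = f_0 e^{s(t-\mathrm{onset})}/(1 + f_0(e^{s(t-\mathrm{onset})}-1))$
  with s = 2.5 per day and f0 = 0.05, LPS onset day 0 and BtuB onset day 3,
  observed through binomial sampling at 100x depth at 12 h and days 1, 3,
  5, 7, in triplicate;
* competition: wild-type fold-growth lognormal around 10^4 (one 24-h cycle
  from a 10^5 inoculum), resistant fold-growth $G_S^W$ with true W = 0.93,
  20 colonies phenotyped binomially;
* insertion library: 500 genes with gamma-distributed base weights,
  multinomial libraries of 2x10^6 reads, 10 planted genes up-weighted
  2^12-fold in the infected condition, 3 replicates per condition.

Each generator is a pure function of its config: the same seed reproduces
the output bit for bit.

What the generator does *not* emulate: plate-edge and condensation
artifacts, lag-phase heterogeneity (lag can only be mimicked through N0),
phage-bacteria population dynamics (adsorption kinetics, burst sizes,
resurgent growth of resistant subpopulations during an assay), read-mapping
and variant-calling errors, and Tn-seq overdispersion beyond multinomial
sampling. Passing round-trip tests therefore demonstrates that the
estimators are correct and well-calibrated under the stated statistical
model, not that they are robust to every artifact of real instruments.

## Numerical choices and test scales

* The OD floor before the log (1e-6) and the detection floor (`min_od`,
  0.02) guard the window regression; both are arguments.
* The valley tie-break on density plateaus is the midpoint of the argmin
  set, making the calibration deterministic.
* The bootstrap is seeded explicitly; the workflow derives every stage's
  randomness from one top-level seed, so reruns of an unchanged config
  reproduce identical output digests.
* Rate-ratio recovery checks in the test suite average 24 simulated wells
  per strain, and competition-fitness recovery uses 500 simulated assays —
  Monte-Carlo scales chosen so the sampling error of the check itself is
  well inside the +/-0.02 tolerances being verified. Null-calibration and
  ordering checks sweep 20 seeds at reduced panel sizes (200-500 genes,
  depth 100-400).

## Known limitations

* The sliding-window rate estimator has a small upward relative bias when
  two strains with different rates are compared deep into the curved part
  of the curve (the faster strain saturates more within a fixed 2-h
  window); keeping `min_od` low and the inoculum small confines the fit to
  the near-exponential region where the bias is negligible.
* KDE mode detection near the domain edges can shift peak *locations*
  (boundary bias); the valley, which is what classification uses, is far
  from the edges and stable.
* The continuity correction makes extreme competition outcomes (0/20 or
  20/20 colonies) reportable but necessarily shrinks them toward the
  interior; with 20 colonies, W values implying final proportions beyond
  about 1/40 of either extreme are not resolvable.
* Workflow manifests record file digests and the config snapshot; they do
  not version external inputs.
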