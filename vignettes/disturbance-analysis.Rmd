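---
title: "Split-plot distance-based analysis of disturbance time series"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Split-plot distance-based analysis of disturbance time series}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(saltpulse)
```

## The design and why ordinary PERMANOVA is wrong for it

saltpulse analyses experiments in which whole plots, arranged in complete
blocks, receive a treatment once and are then sampled repeatedly through
time. The motivating layout is a salinity-pulse field experiment: 8 blocks,
each holding one plot per treatment — `control` (never disturbed), `novel`
(a single salt pulse), and `repeated` (two years of monthly pulses followed
by the same pulse) — sampled on 10 days over two months (days 0, 1, 3, 6, 8,
14, 20, 28, 42, 55). Community composition is summarised by Bray–Curtis
dissimilarities among samples,

$$d_{jk} = \frac{\sum_i |x_{ij} - x_{ik}|}{\sum_i (x_{ij} + x_{ik})},$$

and partitioned by distance-based ANOVA: the squared distances are
Gower-centred into $G = C(-\tfrac12 D \circ D)C$, whose trace is the total
sum of squares, and a term's sum of squares is the increment
$\mathrm{tr}(H_{\le t} G) - \mathrm{tr}(H_{< t} G)$ of cumulative hat
matrices, i.e. the sequential decomposition.

The repeated measurements make samples within a plot dependent, so two
standard shortcuts fail:

* **The residual error is the wrong denominator for Treatment.** Treatment
  is applied to plots, so its error stratum is the variation among plots
  within treatments (the *whole-plot error*), not the sample-level residual.
  The split-plot pseudo-F is
  $F = \frac{SS_T/\mathrm{df}_T}{SS_{P(T)}/\mathrm{df}_{P(T)}}$.
  In the sequential model this is obtained by fitting Treatment *before*
  Plot, so that the Plot row is exactly the plots-within-treatment stratum.
  (Fitting Plot first leaves Treatment with zero degrees of freedom, because
  plot identity determines treatment; `sequential_ss()` reports such terms
  as aliased rather than dropping them.)
* **Free sample permutation is the wrong null.** Exchangeability holds only
  within design strata. The package implements the four restricted schemes
  the design admits:
  `whole_plot` (plots exchange within blocks, a plot's series moving as a
  unit — tests Treatment and Day×Treatment), `within_plot` (days shuffle
  inside each plot — tests Day), `paired_within_plot` (for two-day
  contrasts, each plot swaps its pair or not, $2^m$ patterns), and
  `free_within_block` (single-day data, e.g. the day-0 baseline contrast).

Groups of at most 10,000 elements are enumerated exhaustively (p =
proportion of the group, identity included, with statistic at least the
observed); larger groups use seeded Monte Carlo draws with the add-one
convention $p = (1 + \#\{F^* \ge F\})/(1 + n_{perm})$, 999 draws by
default. Ties count as $\ge$ with tolerance `1e-12`. With 8 plots the
paired group has exactly 256 elements, so attainable p-values are multiples
of 1/256 and the second-smallest is 0.0078 to two significant figures — a
useful check that a reported p-grid is consistent with exhaustive paired
swaps.

Inside `permutation_test()` the whole-plot randomization is carried out as
plot-level treatment relabelling. On a complete design this induces the
same statistic distribution as moving each plot's sample set, but it stays
well defined when rarefaction attrition leaves plots with unequal day sets,
which a sample-index bijection cannot accommodate.

## Two preprocessing streams

Dissimilarity analyses run on counts rarefied without replacement
(multivariate hypergeometric, seed-controlled) to a common depth — default
5,500 reads — with singleton taxa then removed. Samples under the depth are
dropped, never padded, and the drop list is reported, because attrition
silently changes downstream degrees of freedom. Taxon-level summaries
(SIMPER, the heatmap matrix) instead use unrarefied relative abundance.
These are deliberately separate paths: subsampling noise is acceptable when
only the distance geometry matters, while relative abundance preserves all
reads for per-taxon interpretation.

## Resistance and resilience

Recovery is quantified against each treatment's *own* day-0 baseline (the
treatments already differed at day 0, so the control is not a valid
reference). For each later day, the treatment's day-0 and day-x samples are
compared by a one-factor PERMANOVA whose p comes from the exhaustive paired
swap group; a dispersion contrast is computed alongside. The pure rules on
the resulting p series are:

* `first_change_day()` — earliest day with $p < \alpha$ (resistance: later
  is more resistant; never significant means no detected change);
* `recovery_day()` — earliest day after the first change with
  $p \ge \alpha$ (resilience: sooner is more resilient). Later
  re-excursions are left to the full series.

$\alpha = 0.05$ throughout, with no correction across days; this mirrors
the convention of the analyses the package reproduces, and a Holm option is
exposed where contrasts are reported jointly. The degree of change is
tracked as each plot's Bray–Curtis distance from its own day-0 sample;
cross-treatment contrasts of those per-plot values use a block-restricted
label permutation with the absolute difference of treatment means as the
statistic. This replaces a REML mixed model with post-hoc contrasts by an
assumption-light permutation analogue of the same comparison — a deliberate
substitution, keeping every inference in the package permutation-based.

## Dispersion, SIMPER, and partial dbRDA

Beta-dispersion is the distance of each sample to its group centre in
principal-coordinate space. Bray–Curtis is semimetric, so the PCoA spectrum
has negative eigenvalues; these are kept, and squared distances computed on
the "imaginary" axes are subtracted: $z_j^2 = d^2_{\mathrm{real}} -
d^2_{\mathrm{imag}}$, clamped at zero with a counted warning (many clamps
signal strong non-Euclideanity). The default centre is the spatial median
(Weiszfeld iteration, tolerance 1e-9, max 1,000 iterations, per subspace),
matching common practice; centroids are available by flag. Group
differences in the $z$ values are tested by one-way ANOVA, with an optional
relabelling permutation p.

SIMPER decomposes each sample pair's Bray–Curtis exactly into per-taxon
contributions $c_i = |x_i - y_i| / \sum_k (x_k + y_k)$, averages them over
all between-group pairs, and attaches per-taxon permutation p-values by
relabelling group membership. The "top contributors" selection takes the k
(default 100) most significant taxa per comparison — ranked by ascending p,
ties broken by descending contribution, since significance alone is a
coarse key on a discrete p grid — and unions them across the three
treatment comparisons, deduplicated.

Partial dbRDA ordinates the positive-eigenvalue PCoA axes (discarded
negative inertia is reported), residualizes them on the conditioning
factors (typically block), regresses the residuals on the constraints, and
takes eigenvectors of the fitted cross-product. Eigenvalues are on the
sum-of-squares scale; with Euclidean input and no conditions they equal
classical RDA eigenvalues times $n-1$. Axis signs are fixed by making the
first nonzero loading positive. Constraints collinear with the conditions
yield zero constrained axes and a flag rather than an error.

## The synthetic-community generator

`simulate_study()` exists so every stage is testable without sequencing
data. It draws log-abundances per taxon and sample as

$$\eta = \text{baseline} + b_{\text{block}} + p_{\text{plot}} +
\varepsilon_{\text{sample}} + \text{press} + \text{pulse},$$

softmaxes to a composition, and draws counts Dirichlet-multinomially at a
negative-binomial depth. Fixed fractions of taxa are designated
salt-sensitive and salt-tolerant; the `repeated` treatment carries a
sustained press shift (tolerant up, sensitive down) and a shrunken plot
variance (its historically filtered, lower-dispersion community), and both
disturbed treatments receive a transient pulse
$\delta_0 e^{-(t - t_0)/\tau}$ from day 1 (day 0 is sampled
pre-disturbance), sensitive taxa down and tolerant up.

Defaults are the study layout (8 blocks × 3 treatments × 10 days) with
effect sizes chosen once for detectability at 8 plots per treatment, since
no field-data estimates exist to copy: 300 taxa, depth mean 20,000 (size
10), baseline sd 1, block/plot/sample sds 0.3/0.4/0.3, press shift 1,
dispersion shrink 0.6, pulse depths 2 (novel) and 0.5 (repeated), recovery
half-lives 6 and 2 days, 20% sensitive and 20% tolerant taxa, Dirichlet
concentration 300. `null_params()` zeroes every treatment term while
keeping the design variances, which is what the type-I calibration uses.

What the generator does *not* emulate: real ASV tables are far sparser and
longer-tailed, taxa covary through interactions rather than independent
log-normal noise, depth varies with extraction batch, and spatial
within-plot heterogeneity is absent. Passing tests therefore demonstrate
that the machinery is correct and calibrated under the stated model, not
that any field community behaves like the model.

## Numerical choices and edge cases

* Projectors come from pivoted QR (rank-revealing); aliased terms get df 0
  and a flag. Zero denominator sums of squares yield 0 (if the numerator is
  also zero) or a flagged `Inf`, never a crash.
* PCoA eigenvalues within `1e-9` of zero (relative) are treated as null
  axes. Sequential SS additivity holds to 1e-8 and is tested.
* Heatmap preparation uses $\log_{10}(x + 10^{-6})$; rows are centred and
  scaled, constant rows flagged and left unscaled; both the pseudocount and
  the base are arguments.
* All randomness (rarefaction, Monte-Carlo permutations, simulation) is
  seed-parameterised; `run_pipeline()` records every seed in its manifest.

## Problem sizes used by the test suite

The suite checks exactness against enumerable groups (36-element toy
designs), classical ANOVA on 1-D data, and vegan's `adonis2`,
`betadisper`, `simper` and `rda` as independent references. Calibration
properties use 600 null draws of the full 240-sample design with 99
Monte-Carlo permutations per test (the Monte-Carlo p is exactly sized at
the 0.05 grid for any permutation count), and the resistance-ordering
property uses 50 replicate studies at the default effect sizes. These sizes
give binomial standard errors comfortably inside the asserted bands while
keeping the suite routine to run.

## Known limitations

Only the four named permutation schemes are provided; arbitrary
exchangeability structures are out of scope. Marginal (Type III) sums of
squares, continuous covariates, and interactions beyond Day×Treatment are
not implemented. Significance of individual constrained ordination axes is
not tested (inference belongs to the PERMANOVA machinery). The whole-plot
scheme assumes plots are exchangeable within blocks under the null; designs
where blocks hold a single plot contribute only the identity and a warning.
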