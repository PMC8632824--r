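---
title: "Methods: drought time-course expression and cell-wall chemistry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: drought time-course expression and cell-wall chemistry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(droughtwall)
```

## The experimental design being modeled

droughtwall analyzes field drought trials on *Sorghum bicolor* of the
following shape: two cultivars with contrasting drought strategies (RTx430,
an early-senescing pre-flowering-drought-tolerant line, and BTx642, a
"stay-green" post-flowering-tolerant line) grown under three irrigation
regimes — a weekly-irrigated control, a pre-flowering drought in which water
is withheld during weeks 3–8 and re-watering follows (recovery), and a
post-flowering drought with water withheld from week 10 onward. Leaf and
root tissue is sampled weekly over 17 weeks from three replicate field
plots per genotype × condition, giving 2 × 3 × 17 × 3 = 306 samples per
tissue in the full factorial. Bulk RNA-seq count matrices and cell-wall
chemistry assays (monosaccharide composition, lignin, hydroxycinnamates,
saccharification) are collected on these samples.

## Time-course differential expression

### Model

Counts are filtered (default: mean count ≥ 1 across all samples) and
upper-quartile normalized: each sample is divided by the 75th percentile of
its nonzero counts, with factors rescaled to geometric mean one so values
stay on the counts scale. Modeling happens on `log2(normalized + 1)`.

For one genotype and one drought condition versus control, each gene is fit
by least squares with a smooth-in-time mean and a separate functional form
per condition:

$$y = \beta_0 + f(t) + \delta\,\mathbb{1}[\text{drought}] +
      g(t)\,\mathbb{1}[\text{drought}] + \varepsilon,$$

where $f$ and $g$ live in a natural cubic spline basis (default df = 4,
boundary knots at the first and last assayed week; df = 1 degenerates to a
centered linear term). The null model drops every condition term. The
per-week log2 fold-change trajectory is the difference of the two fitted
curves evaluated at each shared week,
$L_t = \delta + g(t)$, for $t = 1, \dots, T$.

The spline family and df are a design choice: the smooth-over-time model
with condition-specific forms needs a basis, and natural cubic splines with
modest df are the standard choice for ~17 time points — flexible enough for
a drought-onset bump plus recovery, stiff enough not to chase replicate
noise. Fitting least squares on the log scale (rather than a count GLM)
keeps the empirical-Bayes moderation below exact and matches the linear
modeling tradition this pipeline follows.

### Variance moderation and tests

Residual variances are moderated by empirical Bayes:
$\tilde s^2_g = (d_0 s_0^2 + d\, s_g^2)/(d_0 + d)$. The prior parameters
are estimated by moment matching on $\log s^2$: under the scaled-inverse-
chi-square prior, $\mathrm{var}(\log s^2) = \psi'(d/2) + \psi'(d_0/2)$, so
the observed excess over $\psi'(d/2)$ is inverted through the trigamma
function numerically; when there is no excess, $d_0$ is capped at $10^6$
and all variances shrink to $s_0^2$. The moderated statistic is
$F = ((\mathrm{RSS}_0 - \mathrm{RSS}_1)/q)/\tilde s^2$ on $(q, d_0 + d)$
degrees of freedom, with the $\chi^2_q/q$ limit at the cap; $q$ is the
number of condition-related parameters (1 + df). Parametric moderated-F
p-values are the default; the estimation scheme is implemented in the
package and cross-checked in the tests against an independent
empirical-Bayes implementation.

A genotype contrast (`fit_genotype_contrast`) reuses the same machinery
with genotype in place of condition within one irrigation regime; it is
exposed but sits outside the HVG path.

### Degenerate inputs

A design in which a condition is observed at a single week (or any
rank-deficient design) produces flagged NA fits rather than errors, and NA
p-values are counted and excluded downstream. Genes fit exactly by the null
model at rounding precision are reported as F = 0, p = 1 rather than a 0/0
artifact.

## Highly variable gene selection

Per gene, condition and tissue, the two genotype p-values are combined by
Fisher's method ($X^2 = -2\sum\ln p$ against $\chi^2_{2k}$), then adjusted
by Benjamini–Hochberg within each condition × tissue family. Genes with
adjusted p < 0.05 are eligible. Each eligible gene is ranked by its overall
log-fold change, and the top 5% and bottom 5% (ceiling rounding; ties by
smaller adjusted p, then gene id; the bottom tail truncates if the tails
would overlap) are labeled highly variable.

The overall log-fold change deserves a note. The formula as usually printed,
$\mathrm{sign}(\bar L) \times (\bar L)$, literally evaluates to
$|\bar L|$ — an absolute value cannot produce a "bottom 5%". The package
therefore ranks by the *signed* time-average $\bar L = (1/T)\sum_t L_t$ by
default, which supports both tails, and keeps the literal absolute-value
form available as `mode = "as_printed"` for comparison.

Eight lists are built per tissue: both genotypes × both drought conditions
on the full course, plus both genotypes × the pre-flowering drought-only
window (weeks 3–8) and recovery-only window (weeks 9–17), each with its own
DE run and eligibility. The merged set is their union, with every gene
tagged by its source lists. Eligibility uses the genotype-combined adjusted
p while ranking is genotype-specific; this reconciles "a unique p-value per
gene, condition and sample type" with genotype-labeled lists.

## Cell-wall annotation

Merged HVGs are restricted to cell-wall-related genes: a gene is kept when
it carries at least one of GO:0009832, GO:0071555, GO:0071554, GO:0042546,
or appears on a user-supplied curated list (curated genes are kept even
with no GO terms, tagged "curated"). Matching is by exact term id — the
filter is defined by four specific terms, not by a subtree — so no
ontology-graph propagation is applied. Retained genes are classified into
biosynthesis / modification / signaling through a family-to-category table
(`default_family_map()`: synthases and transferases → biosynthesis;
expansins, XTHs, peroxidases, pectin esterases/lyases, glycosyl hydrolases
→ modification; wall-associated and receptor-like kinases → signaling);
unmapped genes fall back to modification with a flag, modification being
the majority class in drought HVG sets. Summaries count cell-wall HVGs per
treatment × genotype × category, extract the week-7 and week-14 fold
changes (pre- and post-flowering focus points), and label each gene's main
trend from the mean trajectory over the treatment's active weeks, with a
"no change" band of |mean L| < 0.25 log2 units (the threshold is a
declared default; no principled value exists, and 0.25 is well under any
biologically notable fold change).

## Chemistry layer

Calibration curves are unweighted OLS lines through standards (≥ 3 distinct
levels; monosaccharides 2.5–200 µM, glucose 0–2 mg for the DNS assay), with
a warning under R² = 0.99. Quantification inverts the line, applies the
dilution factor, normalizes per mg biomass, flags values outside 0.5×–2× of
the calibration range as extrapolated, and clamps negative levels to zero
with a flag.

Acetyl-bromide soluble lignin uses Beer–Lambert directly:
$$\%\mathrm{ABSL} = 100 \cdot \frac{A_{280}}{\varepsilon \cdot \ell} \cdot
  \frac{V}{m},$$
with $\varepsilon = 18.19509\ \mathrm{g^{-1}\,L\,cm^{-1}}$ (the average of
known commelinid extinction coefficients) as the default; path length and
extract volume are required inputs since no universal values exist.

Saccharification series (DNS readings at 0/24/48/72 h) are converted to
glucose equivalents, the pre-incubation T0 value subtracted, and net
release per mg reported; negative net release is floored at zero with a
flag and missing timepoints yield NA.

Contrasts are pooled-variance Student t-tests of each droughted treatment
against its watered control within analyte × tissue × genotype × week
(Student rather than Welch: the design pools three plot replicates per arm
and the historical analyses of such assays use the classical test).
Percent change is $100\,(\bar x_T - \bar x_C)/\bar x_C$. BH adjustment is
applied within each tissue × genotype × week family across analytes (a
declared, configurable family: the natural reporting unit of one figure
panel), and a contrast is called significant when raw p < 0.05 *and* the
BH-adjusted p survives the configured FDR, default 0.25 — both thresholds
are reported side by side. An optional leave-one-out outlier rule removes
at most one replicate whose deviation from the others' mean exceeds
k = 4 of their SD, never below two survivors; every removal is logged. The
rule is declared policy: replicate removal is documented practice in these
assays, but no published criterion exists.

## The synthetic-data generator

The generator is first-class, tested code; it emulates the field design at
the count-matrix and assay-table level (no read-level simulation, no
alignment, no chromatogram traces).

Counts are negative binomial around genotype × condition × week means —
the standard bulk RNA-seq assumption — with gene-wise dispersion (default
0.1, a typical bulk value), per-gene baseline log2 means uniform on [2, 10]
(≈4–1000 counts, spanning quantification-limit to highly expressed), and
per-sample size factors log-uniform on [0.5, 2] so upper-quartile
normalization has real work to do. A fraction of genes (default 0.10) is
drought-responsive: each responsive gene gets, per drought condition, a
smooth half-sine bump (random width via a random sharpness exponent, random
sign) over the condition's active weeks — weeks 3–8 for pre-flowering
(with probability 0.5 an additional recovery-window bump of independent
sign), weeks 10–17 for post-flowering — rescaled so the peak absolute log2
fold change equals `effect_size_log2` (default 2). Each genotype ×
condition cell responds with probability 0.7 (at least one cell always
responds), making part of the response genotype-specific, as expected for
cultivars following different tolerance strategies. Responsive-gene counts
of zero trajectories and exact-peak normalization are invariants asserted
in the tests.

GO annotation simulation gives `round_half_up(frac × n)` genes (default
frac 0.10) one or two of the four cell-wall terms, with a configurable
share (default 0.5) drawn from the responsive set; a small disjoint curated
list and per-gene family labels (sampled modification-heavy from the
default family map) provide ground truth for the classification stage.
Chemistry simulation draws replicate triplets lognormally around
control-mean × (1 + planted percent effect) at CV 0.10; the default planted
effects are the reported leaf matrix-monosaccharide drought responses
(+62/33/62/37% for rhamnose/arabinose/glucose/galacturonic acid at week 7).

What the generator does *not* emulate: week-to-week autocorrelated field
noise, plot effects, library-size outliers beyond the log-uniform range,
count overdispersion heterogeneity across genes, GO-term correlation
structure, or assay limits of detection. Passing tests therefore
demonstrate that the pipeline's statistics are calibrated and its
selections exact *under its own model assumptions*; they do not certify
performance on real field data, where the DE model is misspecified to an
unknown degree.

## Numerical choices

* Upper-quartile factors use linear-interpolation percentiles on nonzero
  counts, rescaled to geometric mean one; log transform uses pseudocount 1.
* p-values of exactly 0 entering Fisher combination are clamped to the
  smallest positive double with a warning.
* NA/NaN p-values are excluded from the BH family size and propagated
  unchanged.
* Trigamma inversion is Newton iteration from $x_0 = 0.5 + 1/y$, tolerance
  $10^{-10}$ relative; the prior-df cap is $10^6$.
* Quantification extrapolation flags at 0.5×/2× of the calibration range
  are implementation policy.
* All simulation runs under an explicit seed with RNG state save/restore,
  so identical configuration + seed reproduce tables byte for byte.

## Problem sizes and calibration results computed by this package

The test suite and the acceptance script (`scripts/acceptance.R`) use
simulations of 2,000 genes × 306 samples for calibration and recovery
checks and 150–600 genes for structural and determinism checks; these sizes
give stable estimates (KS distances, rejection fractions) while keeping a
full run in seconds. The quantities themselves — null KS distance and
rejection fraction, chemistry null rejection rate, planted-effect power,
HVG recall, structural exactness indicators, quantification round-trip
errors — are computed fresh at run time and written as JSON; none are
stored constants.

## Known limitations

* The moderated-F p-values are parametric; a permutation mode is not
  implemented (the upstream analyses this mirrors may have used one).
* With top + bottom 5% per list, the eight merged lists can jointly cover
  at most ~80% of a shared eligible pool (8 × 10%, and only if the eight
  rankings were disjoint). Under realistic overlap between genotype
  rankings, the merged set recovers roughly a third to a half of planted
  responsive genes — high recall of *all* responders is not what a
  tail-selection statistic provides, by construction. The HVG set should be
  read as "most extreme responders", not "all responders".
* GO filtering is exact-term matching; descendant propagation from an OBO
  graph is not performed.
* No batch/surrogate-variable correction, no NB-GLM dispersion modeling,
  no mixed-effects plot modeling on the chemistry side.
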