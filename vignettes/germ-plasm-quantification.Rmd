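---
title: "Quantifying anterior germ-plasm enrichment: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying anterior germ-plasm enrichment: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(germquant)
```

## The measurement problem

When *oskar* mRNA is mistargeted to the anterior of the Drosophila oocyte
(via the *bicoid* 3'-UTR), the ectopic Oskar protein can recruit germ-plasm
components — Vasa protein, *nanos* and *pgc* mRNAs — and, in a fraction of
embryos, induce ectopic anterior pole cells. Comparing *oskar* variants
therefore requires putting numbers on two kinds of observation:

1. **How much of a component accumulates at the anterior** of a masked,
   anteroposterior (AP)-oriented confocal micrograph, in a way that is
   comparable across specimens that differ in size, shape, staining
   efficiency and illumination; and
2. **How often ectopic pole cells form** in scored embryo cohorts, and
   whether counts and penetrance differ between genotypes.

germquant implements both, plus the analytical size-exclusion
chromatography (SEC) arithmetic used to assign oligomeric states to
purified domains, and a synthetic-micrograph generator that provides
ground-truth inputs for validating every stage.

## Per-pixel standardization and the enrichment statistic

All image statistics operate on an `oriented_sample`: a 2-D multichannel
image (a sum-intensity projection of the confocal stack, `sum_project()`)
with a traced binary specimen mask, rotated so the AP axis is horizontal
with the anterior at the left (`orient_sample()`).

Each channel is standardized over the whole mask:

$$ z_i = \frac{I_i - \mu}{\sigma}, $$

with $\mu$ and $\sigma$ the mean and standard deviation of intensities
over all mask pixels. The **population** convention ($\div N$) is used
for $\sigma$; the z-scores then sum to exactly zero over the mask, which
gives the enrichment statistic a clean interpretation: the **anterior
integrated enrichment**

$$ E = \sum_{i \,\in\, \text{anterior 15\%}} z_i $$

is positive when the anterior holds more than its share of signal, and
the anterior statistic is exactly minus the statistic of the posterior
complement. (The sample convention, $\div (N-1)$, would rescale every
result by a constant factor close to 1 and change nothing qualitative;
one convention simply has to be fixed and asserted.) Standardization
also makes every downstream quantity invariant under positive affine
intensity maps $I \to aI + b$, so differences in detector gain or offset
between sessions cancel — this invariance is tested explicitly.

"The anterior-most 15%" admits two readings, and both are implemented in
`anterior_region()`:

* `mode = "pixels"` (default): the `round(0.15 * N)` mask pixels of
  smallest $x$, i.e. 15% of the specimen's *area*;
* `mode = "length"`: all mask pixels within the anterior 15% of the
  specimen's *AP extent*.

On a rectangular mask the two agree exactly; on an ellipse the length
mode selects fewer pixels (the anterior cap is thin). The pixel-count
reading is the default. Rounding is round-half-up, and ties at equal $x$
are broken by ascending $y$, so the selected set is deterministic.

## Standardized AP profiles

To compare the spatial distribution of signal across specimens of
different sizes, `ap_profile()` reduces the z-field to one value per
mask column (the mean z-score of that column's mask pixels), maps the
column positions linearly onto $[0, 1]$ (0 = anterior), and linearly
interpolates onto 300 equally spaced standard positions. Columns missing
from the interior of a mask are bridged linearly from their neighbours.
The per-column mean is the simplest reduction consistent with taking the
anterior and posterior boundaries from the mask; it weights every column
equally regardless of its pixel count, which suits profile *shape*
comparisons.

`aggregate_profiles()` averages profiles pointwise within a group and
draws a 95% confidence band as mean ± 1.96 standard errors of the mean
(sample SD, $n-1$); a single profile yields a zero-width band.

## HA-anchored colocalization

Colocalization asks whether, where the tagged Oskar variant (HA channel)
is concentrated, the candidate cargo is concentrated too. The procedure
(`colocalization()`):

1. select high-HA pixels *within the anterior region*, on the
   **unfiltered** HA channel;
2. Gaussian-filter both channels (σ = 1 px by default);
3. compute the Pearson correlation between the filtered channels on the
   selected pixels, provided at least 2 pixels were selected and neither
   channel is constant there — otherwise the result is flagged
   *undefined* and excluded from group summaries, never an error.

Two threshold modes are provided because the selection is described in
two ways in the source protocols: the default `mean_plus_2sd` keeps
pixels strictly above $\mu_{HA} + 2\sigma_{HA}$ (statistics over the
anterior region, population SD), while `top_fraction` keeps the
`round(0.175 * n)` brightest HA pixels. Both are exposed and the choice
is recorded in every result row. Which image was filtered — anchor,
target, or both — is equally ambiguous in the original description;
filtering **both** channels is the default here (the symmetric choice,
and the one under which $r = 1$ exactly when the channels are identical)
and σ is configurable, with σ = 0 disabling filtering entirely. The
filter itself is a separable Gaussian truncated at 4σ with a reflecting
boundary, so constant images and total intensity are preserved.

A numerical detail: $r$ is computed as
$\mathrm{cov}(x,y) / \sqrt{\mathrm{var}(x)\,\mathrm{var}(y)}$ and clamped
to $[-1, 1]$; with this form identical inputs give exactly 1.0 in IEEE
arithmetic, which the identity tests assert without tolerance.

## Pole-cell statistics

Score tables record, per embryo, a single phenotype category —
`negative`, `attempt` (pole-bud initiation without completed pole
cells), or `anterior_pole_cells` — and anterior/posterior pole-cell
counts. `summarize_scores()` computes per-genotype penetrance
(positives / embryos), the mean anterior count among positives, and the
mean posterior count over all embryos.

Two tests compare genotypes:

* **Pooled bootstrap for count differences**
  (`bootstrap_diff_means()`): the observed statistic is
  $\bar{x} - \bar{y}$; the null distribution is built by pooling both
  samples and drawing $|x|$ and $|y|$ values with replacement from the
  pool, 10,000 times by default. The p-value is the proportion of null
  statistics *equal to or more extreme* than the observed value
  (inclusive counting). "Resampling from the original dataset" does not
  by itself pin down the null construction; pooled resampling is the
  standard bootstrap null for a difference in means and is what is
  implemented, with the sidedness defaulting to two-sided on the
  absolute statistic (one-sided options exist). At finite $B$ the
  p-value can be exactly 0; a $(k+1)/(B+1)$ correction is available
  behind `plus_one = TRUE`, off by default to match the plain
  proportion formula. The test's calibration is verified two ways: a
  three-vs-three degenerate case whose pooled-resampling p-value
  ($2 \cdot (1/2)^3 (1/2)^3 = 0.03125$) can be enumerated exactly, and a
  500-replicate null simulation whose rejection rate at α = 0.05 must
  stay within [0.03, 0.07].
* **One-sided Fisher exact test for penetrance**
  (`compare_penetrance()`): the 2×2 table of embryos with/without the
  anterior-pole-cell phenotype per group, with the default direction
  asking whether the variant's penetrance is *lower* than the
  control's. The implementation delegates to `stats::fisher.test()`;
  the tests verify it against an independent exhaustive enumeration of
  all fixed-margin tables up to total 12. Significance is flagged at
  α = 0.05.

## SEC calibration and oligomer calls

For a gel-filtration column with void volume $V_0$ and total volume
$V_t$ (defaults: 0.86 mL and 2.4 mL, the constants of a Superose 6 PC
3.2/30 column), the partition coefficient of a species eluting at $V_e$
is

$$ K_{av} = \frac{V_e - V_0}{V_t - V_0}, $$

and $\log_{10}$ of molecular weight is linear in $K_{av}$ for standards
of similar surface chemistry and geometry. `fit_calibration()` fits that
line by ordinary least squares; `apparent_mw()` inverts it for samples.
$K_{av}$ outside $[0, 1]$ (anomalous elution) warns rather than errors.
Log base 10 is an arbitrary but fixed choice — any base gives identical
predictions.

`call_oligomer()` turns the apparent/monomer mass ratio into a state by
nearest integer multiple: ratio < 1.5 → monomer, 1.5–2.5 → dimer,
above → higher. The underlying published judgement is qualitative
("close to that of a dimer"); the cut-points make it reproducible and
are configurable. On the published masses the defaults reproduce the
published calls: 21.55 kDa against a 12.3 kDa monomer (ratio 1.75) is a
dimer; 10.03 kDa against 10.5 kDa (ratio 0.96) is a monomer.

## The synthetic-micrograph generator

No raw imaging data ships with the package; instead
`generate_sample_image()` produces micrographs with known ground truth:

* an axis-aligned elliptical specimen (default semi-axes 56 × 40 px in a
  96 × 128 frame, ~7,000 mask pixels) — the simplest shape that
  exercises mask logic and per-column aggregation;
* an anchor ("HA") channel
  $\text{baseline} + A e^{-\hat{x}/\lambda} + \mathcal{N}(0,
  \text{noise\_sd}^2)$, with $\hat{x}$ the normalized AP coordinate —
  an exponential decay from the anterior pole matching the qualitative
  anterior-peaked shape of real enrichment profiles (defaults $A = 1$,
  $\lambda = 0.2$, baseline 10, noise SD 0.5, i.e. an anterior signal
  twice the noise);
* a target channel $\text{baseline} + \alpha \cdot (\text{noise-free
  anchor signal}) + (1-\alpha) \cdot \text{independent noise}$, so the
  mixing coefficient $\alpha \in [0, 1]$ is the ground-truth dial for
  colocalization ($\alpha = 1$, zero noise ⇒ identical channels ⇒
  $r = 1$ exactly);
* additive Gaussian noise truncated at 0, zero outside the mask.

`generate_score_table()` draws per-embryo categories from a categorical
distribution and counts from Poissons, with anterior counts of positive
embryos zero-truncated so the category is self-consistent with a count
≥ 1. Its defaults are the wild-type study conditions: penetrance 0.151,
mean anterior count 20.5, mean posterior count 24.3, cohorts of 300.
The true count distribution of real embryos is not known to be Poisson;
it is a stand-in chosen for testability, not an inference about data.

What the generator deliberately does **not** emulate: 3-D stacks and
optics (no PSF), nuclei/actin channels, camera noise models, stage
variation, or irregular specimen outlines. Passing parameter-recovery
tests on this generator therefore demonstrates that the *estimators*
are correct and well-calibrated on signals of the assumed form — not
that the biological conclusions drawn from any particular real dataset
are right.

## Numerical conventions and degenerate inputs

* Coordinates are 1-based `(row y, column x)`, matching R's matrix
  indexing, anterior at the left.
* `orient_sample()` rotates counter-clockwise (image displayed with row
  1 on top), bilinear for intensities, nearest-neighbour for the mask so
  it stays binary; a rotation of 0° is an exact identity path. The
  rotation and interpolation conventions of the original acquisition
  scripts are not recoverable; these are recorded choices, not
  inferences.
* A constant channel (σ = 0) is a degenerate input and raises an
  explicit error in `zscore_field()`; an empty anterior selection and a
  single-column mask likewise error. By contrast an empty *high-HA*
  selection is a legitimate outcome and yields an undefined
  colocalization result.
* TIFF round trips store 32-bit float channels after division by one
  common positive factor per file (float TIFF is a `[0, 1]` format);
  since every statistic is scale-invariant this is lossless for
  analysis purposes.
* Profile interpolation is linear and never extrapolates (standard
  positions lie inside the observed column range by construction).

## Problem sizes used in the validation suite

The shipped tests run entirely on generated data, sized for quick
iteration while keeping Monte-Carlo margins honest: 100 random masks
for the z-score conservation law, 50 for oracle equivalence of the
enrichment sum, 20 replicates per amplitude level for parameter
recovery, 20 per mixing level for colocalization recovery, 500 null
replicates at $B = 1{,}000$ for bootstrap type-I calibration (the
$B = 10{,}000$ default is used for the enumerable three-vs-three case),
exhaustive Fisher enumeration up to table total 12, and a 20-sample
two-genotype cohort for the byte-identical end-to-end determinism
check.

## Known limitations

* The per-column mean is one of several defensible 2-D → 1-D profile
  reductions; area-weighted alternatives would weight wide columns more.
* The bootstrap null (pooled, two-sided) and the Gaussian filter σ are
  documented defaults for under-specified steps, not reconstructions of
  the original analysis scripts; conclusions sensitive to those choices
  should be checked under the alternatives exposed in the API.
* Headline quantities from the original study that depend on its raw
  micrographs and per-embryo tables (absolute enrichment box plots,
  specific p-values) are not recomputable here; the package validates
  the *machinery* on synthetic ground truth instead.
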