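---
title: "Detection p-values from non-specific background fluorescence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detection p-values from non-specific background fluorescence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methdetect)
```

## The problem

Infinium methylation microarrays (450K/EPIC) estimate the methylation level
of a CpG site from two fluorescence intensities: $U$ for the unmethylated
and $M$ for the methylated allele. Because essentially all of a locus's
signal lands on one of the two alleles, the total intensity $T = U + M$ is
roughly independent of the methylation level itself and indicates whether
the probe captured genuine signal at all. Probes whose target is absent
(deleted, mutated, lost in amplification — or a Y-chromosome probe in a
female sample) fluoresce at background level only; their $\beta$ values are
noise and should be masked before any downstream analysis.

The classical *detection p-value* formalizes this: fit a normal background
distribution $B$ to a set of probes believed to carry only noise, and test
each probe's observed $T$ against it with a one-sided z-test. Small $p$
means "unlikely to be background", i.e. *detected*.

Everything hinges on which probes estimate $B$.

## Two background estimates: NEG and NSP

**NEG** uses Illumina's negative-control probes, which are designed not to
match the human genome. They fluoresce at the very bottom of the intensity
scale — *below* genuine background — because a real probe facing an absent
target still picks up non-specific (off-target) binding. A background model
fit to negative controls is therefore too low, its p-values are too small,
and far too many background-level observations pass the filter.

**NSP** instead estimates $B$ from non-specific fluorescence measured where
it genuinely occurs: at the *silent allele* of CpG sites whose methylation
state is extreme. For a completely methylated site the $U$ bead faces no
complementary sequence, so its in-band intensity is pure non-specific
binding; mirror-wise for the $M$ bead of a completely unmethylated site.

Completely (un)methylated sites are identified from the $\beta$ value
distribution, which is strongly bimodal. Per color channel:

1. locate the two modes of a Gaussian-kernel density estimate of the
   channel's Type I $\beta$ values (`find_beta_peaks()`);
2. take the $k = 1000$ probes with $\beta$ *closest to each peak*
   (`select_background_probes()`). Probes at the extremes of the
   distribution are deliberately avoided: they exhibit atypically low
   background. Only Type I probes are eligible because they are read in a
   single color channel; Type II probes (and Type I out-of-band readings)
   suffer cross-talk — spectral leakage of the bright dye at the same bead
   into the other channel — which would inflate the background estimate.
   `crosstalk_ratio()` makes this leakage visible: out-of-band intensity at
   the loud bead of an extreme-methylation probe is a multiple of that at
   its silent bead;
3. pool, per channel, the $U$ intensities of the fully-methylated set and
   the $M$ intensities of the fully-unmethylated set, and take robust
   location and spread: the median and $1.4826 \cdot \mathrm{MAD}$
   (`estimate_background_nsp()`). Tukey biweight estimators are available
   via `estimator = "biweight"`.

The two subsets are pooled into a single per-channel $(\mu_c, \sigma_c)$
because the z-test needs one background law per channel; their sizes are
reported separately in the model object for diagnostics.

## The z-test and the variance bug

For a probe with total intensity $T$ the background law follows from its
design:

* Type II (M in green, U in red): $\mu = \mu_{Grn} + \mu_{Red}$,
  $\sigma^2 = \sigma_{Grn}^2 + \sigma_{Red}^2$;
* Type I Grn (both alleles in green): $\mu = 2\mu_{Grn}$,
  $\sigma^2 = 2\sigma_{Grn}^2$; Type I Red mirrored.

and $p = P\!\left(Z > (T - \mu)/\sigma\right)$, one-sided: detection asks
only whether $T$ *exceeds* background. A probe is detected when
$p < \alpha$ (strictly; the spec of "below the significance level" leaves
$p = \alpha$ undetected, an immaterial choice at continuous $p$). P-values
are intentionally not multiplicity-adjusted — cut-offs here are operating
points of a filter, swept and benchmarked, not hypothesis tests to report.

A historical implementation added the component *standard deviations*
instead of the variances ($\sigma = \sigma_{Grn} + \sigma_{Red}$, and
$2\sigma_c$ for Type I). Since
$\sigma_a + \sigma_b > \sqrt{\sigma_a^2 + \sigma_b^2}$ whenever both are
positive, the buggy spread is inflated and every above-background $T$
receives a larger p-value — which is how extreme cut-off recommendations
such as $10^{-16}$ arose. `detection_p(..., bug_mode = TRUE)` reproduces
this misspecification for comparison studies; the package's default is the
corrected variance addition.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `k` | 1000 | probes per peak and channel in the NSP selection; the published selection size |
| `cutoff` | 0.01 | detection significance level; the recommended operating point for NSP |
| `offset` | 100 | $\beta = M/(M+U+100)$; platform convention, stabilizes low-intensity ratios |
| `min_n` | 30 | smallest tolerated background pool per channel |
| peak bounds | 0.05, 0.95 | KDE mode search limits, guarding against edge artifacts |
| `outlier_threshold` | 0.20 | absolute replicate $\beta$ difference defining a large outlier (20 pp) |

Cut-off sweeps default to $1$ to $10^{-80}$ for NEG and $1$ to $10^{-3}$
for NSP (`default_cutoff_grid()`): NSP p-values are larger because the
estimated background is higher, so the informative range is short, whereas
NEG-based p-values need absurdly small cut-offs before they filter
comparably.

## Benchmarks

Because truth is unknown on real arrays, two indirect benchmarks judge a
filter:

* **Y-chromosome detection by sex** (`y_benchmark()`, `cutoff_sweep()`): Y
  probes should be detected in males and undetected in females. Per cut-off
  and sex the per-sample detected-Y count is summarized by median and
  2.5th/97.5th percentiles (linear-interpolation quantiles, stated because
  small-sample percentiles are convention-sensitive). Among females the
  per-probe *call rate* is computed; under a stringent filter the call-rate
  curve splits into a low plateau (well-behaved probes, call rate < 2%) and
  a high plateau (> 98%) of probes that are typically cross-reactive with
  autosomal loci and fluoresce regardless of a Y chromosome.
* **Technical replicates** (`replicate_concordance()`): paired
  measurements of the same DNA stratified into both-detected vs. the rest.
  Detected pairs should be concordant; pairs with an absolute $\beta$
  difference above 20 pp are *large outliers*, and the report counts how
  many of them the filter catches (undetected in at least one member — the
  literal reading of "either sample").

Sex labels are an input throughout; inferring sex from the array is a
quality-control concern outside this package's scope.

## The synthetic world

`sim_params()` / `simulate_manifest()` / `simulate_cohort()` state a small
generative world so that every claim above is testable without downloads:

* **Methylation** is drawn with genuine point masses: $P(m = 0) = 0.35$,
  $P(m = 1) = 0.45$, the remainder Beta(2, 2). The point masses make
  "completely (un)methylated" literal — the silent bead of such a site
  carries pure non-specific background, which is exactly the NSP premise.
  Observed $\beta$ peaks then *emerge* near 0.1/0.9 from the
  signal/background arithmetic rather than being painted on.
* **Backgrounds** are per-channel normal, with the non-specific floor
  strictly above the negative-control floor (Grn: N(450, 80²) vs
  N(300, 60²); Red: N(600, 100²) vs N(450, 75²)) — the ordering that makes
  NEG-based filters permissive. The gap is moderate on purpose: the NEG
  filter then *partially* over-detects background-level probes, mirroring
  the real-data regime where the conventional filter calls a large
  fraction (not all) of female Y probes detected.
* **Signal** is lognormal (meanlog $\log 5000$, sdlog 0.6): strictly
  positive and right-skewed like fluorescence data. The spread is
  deliberately large relative to the background spread. This matters for a
  subtle reason found during development: the $\beta$ value of a fully
  methylated site co-varies (weakly, negatively) with its silent-bead
  background, so if background variability contributed much of the $\beta$
  spread, selecting the $k$ sites *closest to the peak* would condition on
  the background and shrink its recovered spread. On real arrays signal
  variability dominates and $k = 1000$ is a tiny fraction of each
  channel's Type I probes, so the effect is negligible; the generator is
  sized to be in that same regime (a residual ≈ 3% shrink remains in the
  red channel and is covered by the 5% recovery tolerance).
* **Cross-talk** is linear leakage: out-of-band $= \lambda \times$ in-band
  at the same bead plus negative-control-level noise, $\lambda = 0.15$ —
  the minimal mechanism consistent with the loud-vs-silent bead asymmetry
  observed on real arrays.
* **Sex and dropouts**: every Y probe in a female is background-only;
  additionally 0.15% of probes drop to background in any sample, matching
  the order of data loss (~0.14% of observations) reported for the
  recommended filter on real cohorts.
* **Replicates** share the biological methylation state and signal level
  and redraw all measurement noise. Injected large outliers (rate 0.2%)
  come in two kinds: *intensity-driven* (30%; the probe collapses to
  background level in one member — catchable by a detection filter) and
  *intensity-independent* (the methylation state flips at full signal —
  invisible to any intensity filter). The second kind exists so that the
  simulated world reproduces the real finding that the majority of large
  outliers is not explained by low fluorescence, and no filter should ever
  mask everything.
* The default array (30 000 autosomal + 600 X + 416 Y probes, 600 negative
  controls, design mix I-Grn/I-Red/II = 0.10/0.18/0.72) is a scaled-down
  450K: the Y count and design shares match the real platform, and the
  smallest stratum (Type I Grn) is sized so the default $k = 1000$
  selection stays inside the pure point-mass pools.

What a green test on this world does **not** establish: the generator has
no batch or plate effects, no probe-sequence-level cross-reactivity (its
"cross-reactive" analogue is only the leakage mechanism), no dye-bias, and
normal backgrounds with exact independence between beads. Real-data
magnitudes (medians over 17 public datasets, the published 2.7×/3.8×
cross-talk ratios, the 6%/30% outlier-masking rates) therefore cannot be
reproduced at desk scale; the tests assert calibrations, recoveries and
directions, which is what the simulator can honestly support.

## Numerical and design choices

* "Robust estimators of location and spread" are realized as median and
  normal-consistent MAD; a Tukey biweight alternative is provided. The MAD
  keeps its known finite bias under heavy contamination — tests assert
  boundedness against exploding moments, not invariance.
* Peak finding uses Silverman's rule-of-thumb bandwidth on a 512-point
  grid over $[0,1]$, modes searched in $[0.05, 0.5)$ and $[0.5, 0.95]$. A
  mode on a search boundary raises an error (likely non-bimodal input), as
  does a constant $\beta$ vector.
* Peaks and probe sets are computed per channel and per sample, on the
  sample's own Type I $\beta$ values — the natural reading of a per-sample
  background; a reference-based variant would be a trivial extension.
* Ties in the $k$-closest selection break deterministically by (distance,
  probe id); a probe eligible for both peaks goes to the nearer one, exact
  mid-ties to the unmethylated side.
* Missing intensities (absent bead address) propagate as missing $\beta$
  and missing $p$ and count as undetected in all summaries — conservative,
  matching the filtering intent — while load-time messages preserve the
  distinction for logs.
* Type I totals assume independence of the two beads
  ($\sigma^2 = 2\sigma_c^2$); documented as an assumption rather than
  estimated, since per-bead covariance is not identifiable from a single
  array.
* Intensities are used raw for detection; dye-bias correction, performed
  before downstream regression in typical pipelines, is out of scope here
  and would cancel in neither the NSP pools nor the per-channel z-tests in
  an obvious way.

## Known limitations

* Ingestion is via plain TSV channel tables (and the bundled simulator);
  binary IDAT parsing requires an external parser not depended upon here.
  The table dialect is documented precisely so IDAT contents can be
  exported to it.
* The NSP procedure needs enough Type I probes per channel with extreme
  methylation; on unusual samples (e.g. globally hemi-methylated) the
  selection warns or errors rather than silently degrading.
* Detection p-values judge total intensity only; they cannot flag spurious
  values that fluoresce brightly, as the replicate benchmark's unmasked
  outliers demonstrate.
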