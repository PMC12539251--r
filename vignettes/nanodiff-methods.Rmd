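---
title: "Comparative current-signal detection of RNA modifications: models and choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparative current-signal detection of RNA modifications: models and choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nanodiff)
```

## The problem

Direct RNA sequencing reads native RNA molecules, so the chemical
modifications they carry are still present when the strand moves through
the pore, perturbing the ionic current at the modified base and its
neighbours. Modification-aware basecallers exist only for a few
modification types and, on bacterial RNA, produce many false positives.
The comparative strategy implemented here avoids any trained modification
model: an in vitro transcribed (IVT) copy of the same transcriptome is an
unmodified negative control, and any reproducible difference between the
native (WT) and IVT current distributions at a reference position is
evidence of a modification near that position — of whatever type. The
price is that the method is k-mer-level and type-agnostic: it localises a
modified neighbourhood but does not name the modification, and it does not
estimate per-read stoichiometry.

## Feature extraction

Raw current is pore- and read-specific, so each read's mapped samples are
standardised with robust location/scale before anything else:

$$\mathrm{norm} = \frac{\mathrm{raw} - \mathrm{median}}{\mathrm{MAD}},$$

where MAD is the *unscaled* median absolute deviation — no 1.4826
consistency factor. The choice is deliberate and consequential: the 0.18
mean-difference calling cutoff below is defined on this scale, so
re-scaling MAD would silently re-calibrate the caller. Normalized values
beyond ±5 (`clip`) are replaced by the bound; heavy-tailed excursions
(adapter stalls, blockages) would otherwise dominate per-site means. A
read whose MAD is zero carries no usable signal and is skipped with a
logged count.

Per read and reference base the package keeps four features: mean, median,
population standard deviation, and dwell (the number of raw samples, i.e.
residence time in samples; no conversion to seconds is attempted, and the
dwell-difference cutoff of 1 is in these units). Two corrections follow:

* **k-mer shift** (`kit_shift`, default 0): the pore reads a k-mer, so the
  event-aligned coordinate is systematically offset from the base that
  causes the signal. The offset is kit-specific and supplied by the user
  (published shift tables exist per chemistry); it is added on the plus
  strand and subtracted on the minus strand, and records shifted off the
  reference are dropped with a count. The default of 0 is a deliberate
  no-op: with a symmetric ±4-base matching window downstream, a small
  uncorrected shift moves calls within the window rather than losing them.
* **edge trimming** (`trim`, default 10): current is unstable while the
  read enters and leaves the pore, so the first and last 10 *aligned
  reference positions* of each read are discarded. Whether trimming should
  count aligned or basecalled positions is an open choice; aligned
  positions were chosen because the features are indexed by reference
  position throughout.

Feature tables are stored as plain TSV in aligned 100k-base windows
(`chunk_size`), purely to bound memory: the tests assert byte-level
round-trips and bit-identical comparison results for chunk sizes 10 and
100,000.

## Statistical comparison

At each position covered in both samples, WT and IVT per-read feature
vectors are compared. Three tests are offered:

* **MANOVA** (default): one-way, two-group, over all four features. The
  test statistic is Pillai's trace with its standard F approximation; with
  two groups this is exactly Hotelling's T², and the package computes the
  closed form
  $T^2 = \frac{n_1 n_2}{n}\, \mathbf{d}^\top S^{-1} \mathbf{d}$,
  $F = T^2\,\frac{n-p-1}{p\,(n-2)} \sim F_{p,\,n-p-1}$,
  where $\mathbf{d}$ is the vector of feature-mean differences and $S$ the
  pooled covariance. The closed form is orders of magnitude faster than a
  generic fitter over tens of thousands of sites and is verified against
  `stats::manova(..., test = "Pillai")` in the test suite. Features with
  zero pooled variance are dropped before inversion; if the pooled
  covariance is still singular a spectral pseudo-inverse is used, and if
  no feature carries variance the site is reported with p = 1 and a
  degenerate flag.
* **logistic regression** (mean only): likelihood-ratio test with one
  degree of freedom of `label ~ mean` against the intercept-only model.
  The LRT was preferred over the Wald test because near-separated sites
  (exactly the interesting ones) inflate Wald standard errors.
* **Kolmogorov–Smirnov** (mean only): two-sample, two-sided, asymptotic.

Unbalanced group sizes distort all three tests, so `balance = TRUE`
subsamples the larger group to the smaller group's size. The subsampling
RNG stream is derived from `(seed, contig, position, strand)`, making every
site's draw independent of processing order, chunk layout and worker
count — a requirement for the chunk-independence and determinism
invariants. Raw p-values are Benjamini–Hochberg adjusted across **all**
sites tested in the run (`stats::p.adjust`; the tests check it against an
independently coded step-up formula).

Effect sizes (`d_mean`, `d_median`, `d_std`, `d_dwell`) are the WT per-site
feature averages minus the IVT averages, computed on the full groups (not
the balanced subsample) and stored signed; the caller applies absolute
values. Swapping the samples therefore negates every delta and leaves
p-values unchanged, which is asserted as a property test.

## Calling and merging

A site is positive iff all four conditions hold: coverage
$\min(\mathrm{cov}_{WT}, \mathrm{cov}_{IVT}) \ge 50$,
$|\Delta\mathrm{mean}| \ge 0.18$, $|\Delta\mathrm{dwell}| \ge 1$, and
$-\log_{10} p_\mathrm{adj} \ge 3$. These are the cutoffs calibrated on the
36 well-characterised *E. coli* rRNA modification sites: below ~50×
coverage the null spread of $|\Delta\mathrm{mean}|$ between two negative
controls widens sharply (a property the simulator reproduces, see below),
and adjusted p ≤ 1e-3 is the recommended universal MANOVA cutoff across
coverage levels.

Because one modification perturbs several neighbouring positions, positive
sites are merged: sites at distance ≤ 4 (`merge_gap`) join one cluster and
each cluster is expanded by 4 bases (`expand`) on each side. Two readings
of "nearby" are defensible (within 4 vs strictly less than 4 bases); the
inclusive reading was implemented and `merge_gap` is configurable so the
strict one is one argument away. Expanded clusters that overlap or touch
are unioned — emitting overlapping BED regions would break most BED
consumers — and expansion clips at 0 and the contig end (transcript ends
are not consulted). Strands never merge. The merge is verified exactly
against a brute-force boolean-mask oracle on hundreds of random site sets.

## Evaluation

Predictions are matched to known sites with a ±`window` tolerance
(default 4; detection performance plateaus there). Precision is
prediction-centric (a prediction is correct if any truth is within the
window) and recall truth-centric (a truth is detected if any prediction is
within the window); a truth detected by several nearby predictions thus
produces no false positives, and 0/0 ratios are defined as 0. For ROC
analysis, the negative universe is the set of tested sites not within the
window of any truth, scores are the absolute per-feature differences, and
the AUC is the trapezoid under the threshold sweep — identical, ties
counted one half, to the pairwise-concordance statistic, which the tests
assert on random instances. Region-level agreement uses the conservative
min rule, `min(|A ∩ B|, |B ∩ A|)`, since overlap counts are asymmetric
between region sets.

Two single-formula utilities round this out: the Phred conversion
$-\log_{10}(1 - \mathrm{accuracy})$ (capped at 60 for perfect accuracy)
and counts-per-million $q_i / \sum_j q_j \times 10^6$.

## The bedMethyl differential filter

For modified basecalling output, the same comparative logic applies
downstream of `modkit pileup`: sites with valid coverage strictly above
20 in both samples are joined on (contig, position, strand, modification
code), the WT − IVT difference in "fraction modified" (percent) is
computed, and sites with a difference ≥ 35 (Ψ; 50 for the m⁵C and A-to-I
callers, where no single validated cutoff exists — the m⁶A threshold is
left to the user) are kept as high-confidence. Because bacterial
annotations lack UTRs, gene intervals are expanded ±100 bp before sites
are assigned; multi-gene overlaps keep every label with a primary one by
the precedence tRNA > rRNA > ncRNA > CDS.

## The simulator

`simulate_pair()` generates the paired feature tables directly — it
emulates the *feature-level* signal model, not raw pore kinetics. Per read
and position:

* mean ~ Normal(baseline + effect, `sigma`), with a per-position baseline
  drawn once per contig from N(0, 1) (normalized current levels are
  k-mer-dependent and roughly standard-normal after MAD scaling);
* dwell ~ 1 + Poisson(`dwell_base_mean` − 1 + dwell effect), guaranteeing
  dwell ≥ 1; `dwell_base_mean = 30` samples reflects ~130 bases/s
  translocation at ~4 kHz sampling;
* std is a population SD drawn from the scaled-χ distribution implied by a
  within-read sample SD of `sigma_within = 1` and the dwell;
* the median tracks the mean but receives only 80% of the modification
  effect plus sampling noise `0.75·sigma_within/√dwell` — a modification
  perturbs a subset of samples within the dwell window and the median is
  robust to them, which is also why the mean is the most discriminative
  feature.

Default `sigma = 0.3` (between-read SD of a per-site mean) makes the
default planted effect `delta_mean = 0.5` a clear but not degenerate
signal at 100× coverage. Each planted site perturbs positions within ±2
bases (`footprint`), so shift-window matching is genuinely exercised;
`stoichiometry` scales the fraction of WT reads carrying the
modifications, with 0 producing an exact null pair. Sites are planted one
per equal-width bin so their merged regions cannot collide. Everything is
drawn under one seed and the caller's RNG state is restored, so identical
configurations give byte-identical tables.

What the simulator does **not** model: k-mer-dependent effect directions
and magnitudes, alignment and basecalling errors, coverage decay along
transcripts, secondary-structure read ejection, correlated noise between
neighbouring positions. Passing tests therefore demonstrate the
statistical machinery is correct and calibrated under a clean signal
model — not that real-data performance figures are reproduced; headline
real-data numbers require the original multi-gigabyte raw dataset and are
out of scope here.

## Study sizes used by the tests and acceptance script

Calibration and recovery studies run on a 10-kb contig at 100× coverage
(10,000 tested sites per run): null calibration over 10 seeds and all
three tests, planted-site recovery (20 sites, `delta_mean` 0.5,
`delta_dwell` 3, stoichiometry 1) over 5 seeds, feature-AUC ordering with
`delta_mean = 0.08` and `delta_dwell = 0` — small enough that per-feature
AUCs sit near 0.8 rather than saturating at 1, so the mean > median > std
ordering is measurable — and the null-spread-vs-coverage study on a 2-kb
contig at {10, 50, 200, 1000}×, where the 99% interquantile range of
`d_mean` narrows monotonically with coverage, mirroring why the 50×
minimum-coverage cutoff exists.

```{r example, eval = FALSE}
sim <- simulate_pair(sim_config(seed = 1))
cmp <- compare_features(sim$wt, sim$ivt)
reg <- call_regions(cmp)
prf1(match_with_shift(attr(reg, "positive_sites"), sim$truth, window = 4))
```

## Known limitations

* Type-agnostic: regions say "modified near here", never which
  modification.
* No per-read calls or stoichiometry estimates; partial modification
  lowers the effective effect size roughly linearly.
* The MANOVA's F approximation assumes approximately multivariate-normal
  features within groups; dwell is discrete and right-skewed, which the
  null-calibration tests show is tolerable at the default coverages.
* Adjusted p-values lose discriminating power at very high coverage
  (everything becomes significant); the effect-size cutoffs then do the
  work, which is why they are part of the calling rule rather than a
  pre-filter.
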