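---
title: "Histology-directed MALDI-IMS profiling: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Histology-directed MALDI-IMS profiling: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(maldiprofiler)
```

## The problem

Low-grade phyllodes tumor (LGP) and fibroadenoma (FA) are biphasic
fibroepithelial breast lesions whose histologic overlap makes them hard to
tell apart, although the distinction drives very different surgical
management. Histology-directed MALDI imaging mass spectrometry acquires one
peptide profile per pathologist-annotated tissue spot (20 epithelial and 20
stromal 300 µm marks per case), giving a case/spot/compartment hierarchy of
spectra on which one can ask: do the two diagnoses differ in their
proteomic profiles at all?

`maldiprofiler` implements that analysis end to end — spectral
preprocessing, peak-matrix construction, linear-SVM classification with
case-level voting, differential-peak statistics, and the accompanying
clinical/IHC comparisons — together with a synthetic-cohort generator that
emulates the study's statistical structure, so every stage is tested
against planted ground truth without any instrument data.

## Preprocessing model

The chain runs in a fixed order, enforced by per-spectrum stage
bookkeeping: baseline → normalize → align. Running a stage out of order is
an error, not a warning.

**SNIP baseline.** Chemical noise is removed with statistics-sensitive
nonlinear iterative peak clipping: intensities are optionally compressed
with the LLS transform $v = \ln(\ln(\sqrt{y+1}+1)+1)$, then for window
half-widths $i$ decreasing from `snip_iterations` (default 20, the
standard setting for this workflow) to 1 every interior point is replaced
by $\min\{v_m, (v_{m-i}+v_{m+i})/2\}$, edges held fixed; the transform is
inverted and the baseline clipped into $[0, y]$. Vectors shorter than
$2\cdot\text{iterations}+1$ reduce the window with a warning. Note that on
pure noise SNIP tracks the *lower envelope*, so corrected spectra retain a
small positive pedestal; downstream SNR therefore measures height above
the median (below).

**TIC normalization.** Each spectrum is scaled so its total ion current
equals the dataset median TIC (keeping intensities on a physical scale; a
`unit` target is available). Zero-TIC spectra are excluded and reported.
The reference spectrum for alignment is the one whose TIC is closest to
the 50th quantile of the TIC distribution, ties to the lowest index.

**Mass-axis re-alignment.** Landmark peaks (SNR ≥ `landmark_snr`, default
5) detected in each spectrum are matched one-to-one to the reference
spectrum's landmarks within `align_tolerance_ppm` (default 2000), and a
global linear warp $m/z' = a \cdot m/z + b$ is fitted by least squares —
linear because TOF calibration drift is well captured by slope+intercept,
and a piecewise warp would be unidentifiable from ~10 landmarks. Fits need
`min_landmarks` (default 2) matches and a slope in (0.9, 1.1); otherwise
the spectrum keeps the identity warp and is flagged. Intensities are
linearly re-interpolated onto the original grid.

## Peak picking and the feature table

Peaks are picked once, on the overall mean spectrum of **all** spectra
(study and validation pooled), exactly as the profiling workflow
prescribes. This leaks the peak *panel* (not the class labels) into
validation; the package keeps the behavior for fidelity and exposes
`peaks_from = "study_only"` as the leak-free alternative. Because the
average of many zero-truncated noisy spectra re-acquires a pedestal, the
pipeline baseline-corrects the mean spectrum with one extra SNIP pass
before picking.

Noise is the Gaussian-scaled MAD, $1.4826 \cdot \mathrm{med}|y -
\mathrm{med}(y)|$. A peak is a local maximum strictly above its
neighbouring distinct values (plateaus count once, at their leftmost
index) whose robust z-score — height above the median divided by the MAD
noise — exceeds `snr_threshold` (default 3). The median centring matters:
with a bare height/noise ratio the SNIP pedestal pushes every floor ripple
over the threshold. Retained peaks are ≥ 2 grid steps apart (higher peak
wins) and centres are refined sub-grid by a three-point parabola, which is
what makes ±2 Da shift recovery to well under 0.1 Da possible on a 1 Da
grid.

The feature value of spectrum $i$ at peak $j$ is the maximum intensity
within ±`window_ppm` (default 2000, tied to the alignment tolerance) of
the centre — a windowed maximum is robust to residual misalignment; a
summed (`"sum"`) alternative is provided.

## Classification

Spots are classified with a linear-kernel SVM (`e1071`). Features are
standardized on the study set (parameters stored for prediction). The
soft-margin cost is tuned over {0.1, 0.5, 1, 5, 10} by stratified 5-fold
cross-validation **grouped by case** (`fold_unit = "case"`), so no case
contributes spots to both sides of a fold — the spot-level alternative is
retained for fidelity experiments, since the original description does not
say how folds were formed. Ties in pooled CV accuracy go to the smaller
cost (more regularization). Epithelial and stromal compartments are
modeled separately, mirroring the compartment-wise analysis.

Case calls are the modal spot call; `consistency` is the modal share; an
exact tie is `indeterminate` and scored incorrect (conservative).
Evaluation reports overall accuracy, per-class correct counts and the
number of fully consistent cases.

## Differential peaks

Per peak: AUROC via the rank-sum identity $\mathrm{AUROC} = U /(n_a n_b)$
with midranks; log2 ratio of class means (LGP/FA, means floored at machine
epsilon with a flag); Welch two-sided t (pooled-variance switch
available); Benjamini–Hochberg adjustment across peaks. Peaks with zero
variance in both classes get $t = 0, p = 1$, flagged.

The default analysis unit is the spot-level spectrum, as in the original
volcano plots. Spots within a case are correlated, so spot-level p-values
are pseudo-replicated: on a *null* synthetic cohort the study-scale run
finds ~55 of 75 peaks at raw p < 0.05 at spot level versus 2–3 of 75 at
the case-mean unit (`unit = "case"`). Calibration claims in the test suite
therefore use the case unit; the spot unit is kept for fidelity.

A related composition effect is worth knowing: TIC normalization
constrains every spectrum's total signal, so when a class gains real
signal mass (planted 4-fold peaks), all its other peaks are scaled down
and the measured fold change of the planted peaks shrinks (a planted
log2FC of 2 comes back ≈ 1.4 through the full chain at the test
conditions). Fold-change recovery is therefore asserted at the feature
table level, where the statistic's own accuracy is what is being tested.

## Clinical and IHC statistics

Wilcoxon–Mann–Whitney tests are two-sided with midranks, exact when
min(n) ≤ 8 without ties and normal-approximated with tie and continuity
correction otherwise; U is oriented as pairs with x > y. Fisher's exact
test uses the conditional "probability at most observed" two-sided rule
(the common software default; conventions differ, hence documented); the
reported odds ratio is the sample OR with +0.5 continuity on zero cells
applied to the OR only, never to p. Kaplan–Meier curves use the
product-limit estimator with events processed before tied censorings;
log-rank is the standard 1-df chi-square. Group summaries render uniformly
zero markers (stromal E-cadherin) with p = 1 rather than failing.

IHC tables carry two reader scores per case; the analysis value is their
average, as in the two-pathologist scoring protocol.

## The synthetic generator

A spot spectrum is
$$y(m) = g_c\Big[\textstyle\sum_k h_{ck}\, e^{-(m - \mu_k -
\delta_s)^2/2\sigma^2} + A e^{-d(m - m_{\min})}\Big] + \varepsilon,\qquad
\varepsilon \sim N(0, \tau^2),\ y \ge 0,$$
with per-case gain $g_c \sim \mathrm{LogNormal}(0, 0.4)$ (exercises TIC
normalization), per-case peak perturbation $h_{ck} = h_k \cdot
\mathrm{LogNormal}(0, 0.1)$ (tumor heterogeneity), per-spectrum mass shift
$\delta_s \sim U(-1, 1)$ Da (exercises alignment), Gaussian peaks of width
$\sigma = 2$ Da (symmetric TOF reflectron approximation) and an
exponential chemical-noise baseline. Defaults: 30 FA + 31 LGP cases, 20
spots per compartment, 800–3500 Da at 1 Da spacing (the tryptic-peptide
MALDI range; the acquisition range is a package convention, not a reported
fact), 60 peaks with log-normal heights, $\tau = 0.5$, $A = 20$,
$d = 0.002$. Discriminating peaks (default none — the null the study
observed) are multiplied by $2^{\text{effect\_log2fc}}$ in LGP spectra of
the configured compartments (default stromal, where the biology would
differ if anywhere). Identical config + seed reproduces the dataset bit
for bit.

Clinical tables draw ages, sizes and follow-up from normals clipped to the
printed group ranges with the printed means (e.g. LGP age mean 35.5 y,
range 14–63; clipping shifts the mean by ≈ 0.1 y, well inside sampling
error); recurrence is Bernoulli(2/31) for LGP and 0 for FA. IHC
positivity uses scaled Beta draws on the printed ranges with means matched
exactly to the printed group means, then symmetric two-reader scores.

**What the generator does not emulate.** No isotope envelopes, detector
physics, 2-D rasters, or m/z-dependent peak width; noise is truncated
Gaussian, not Poisson. Its spot-level variation is small relative to its
case effects, so synthetic case calls are nearly fully consistent across
spots — real cohorts show much lower within-case consistency. Passing
tests therefore demonstrate correctness of the algorithms and calibration
under this model, not performance on instrument data.

## Problem sizes and numerical choices

The replicate suites (null calibration, signal sanity) run 20 pipeline
replicates at 15 cases/class, 9 spots per compartment and 800–2000 Da —
sizes chosen so a replicate exercises every stage while the whole suite
stays interactive. Nine (odd) spots per compartment is deliberate: with an
even count, exact 50/50 spot ties are scored indeterminate-incorrect by
convention, which would bias null accuracy below 0.5 by construction.
Alignment fixtures place landmarks at 2400–3500 Da so the 2000 ppm
matching tolerance (≥ 4.8 Da there) accommodates the up-to-4 Da relative
shifts that ±2 Da planted shifts produce, and include a baseline floor so
zero-truncation does not distort the MAD.

Other conventions: reference-selection ties break to the lowest index;
tuned-cost ties to the smallest cost; warp slopes outside (0.9, 1.1) fall
back to identity; all-zero feature rows get the deterministic
intercept-sign class; a global seed is fanned out to per-stage streams by
a stable hash so stages can be rerun in isolation.

## Known limitations

Spot-level volcano p-values are anticonservative by design fidelity (see
above). mzML/imzML support is read-only and minimal (64/32-bit float,
zlib or no compression; continuous and processed imzML). The linear warp
cannot capture higher-order calibration error. The original study's
headline numbers (50% validation accuracy, tuned cost 0.5, 35% full
consistency) depend on raw spectra that are not distributed with this
package; the package reproduces the *negative result qualitatively* —
null cohorts classify at chance, signal cohorts do not — rather than
those exact values.
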