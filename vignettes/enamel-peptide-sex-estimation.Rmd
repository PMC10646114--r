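---
title: "Enamel peptide sex estimation: models, thresholds and design choices"
author: "ameloSex"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Enamel peptide sex estimation: models, thresholds and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ameloSex)
```

## The scientific problem

Commingled and scattered skeletal assemblages rarely preserve the pelvic
and cranial features classical osteology needs for sex estimation.
Amelogenin, an enamel matrix protein, is encoded on both sex chromosomes,
and the Y-isoform (AMELY, UniProt Q99218) yields tryptic-like peptides
that are absent in females. Detecting AMELY-specific peptides in an
enamel acid etch by LC-MS therefore gives a near-binary sex signal from a
single tooth, while AMELX peptides (Q99217) confirm that amelogenin
survived at all. `ameloSex` implements the full decision pipeline on
centroided MS1 data — theoretical marker m/z, extracted ion chromatograms
(XIC) at ppm tolerance, elution-peak detection, intensity-threshold sex
calls with extraction-blank QC — together with the osteological analyses
such a study pairs with it: odontometric sex classification and its
agreement with the peptide calls, wear-corrected age-of-onset estimation
for linear enamel hypoplasia (LEH), and cohort sex-ratio profiling.

## Marker panel and mass arithmetic

The default panel (`defaultPanel()`) holds six doubly protonated markers:
two AMELY-specific sex-diagnostic peptides (SM(ox)IRPPY at m/z 440.2233,
M(ox)IRPPY at 396.7073), the AMELX-specific SIRPPYPSY (540.2796), two
peptides shared by both isoforms used only as corroboration (SYEVLTPLK
525.2975, YEVLTPLKWY 656.3528), and one enamelin peptide (PYFGYFGYH
575.7533) used as a preservation/QC indicator. m/z is computed as
$(M + z\,m_p)/z$ from the monoisotopic mass
$M = \sum_i m_{\text{res},i} + m_{\mathrm{H_2O}} + \sum_j \Delta_j$,
with residue masses to five decimals, water 18.010565 Da, Met-oxidation
+15.994915 Da and the *proton* mass 1.007276 Da (not the hydrogen atom
mass) — required to match instrument inclusion-list values to four
decimals. Panel construction re-derives every m/z from sequence,
modification and charge and refuses reference values that disagree by
more than 0.0005, guarding the mass table against typos. The modification
vocabulary is deliberately restricted to Met-oxidation; unknown names are
rejected rather than ignored. The oxidised residue position is taken from
the parenthetical placement in the conventional labels.

## XIC extraction, noise and peak detection

`extractXIC()` sums, per scan, all centroids inside the symmetric window
$m/z \cdot (1 \pm \text{tol} \cdot 10^{-6})$; the default tolerance is
5 ppm. Only centroided MS1 data are accepted: profile spectra are
rejected on read because implicit centroiding would silently change the
intensities the calls depend on. Retention times are minutes everywhere
(mzML seconds are converted on read).

Noise is the median of the non-zero trace intensities (an all-zero trace
reports a configurable floor, default 1 count). The median was preferred
over MAD-based estimates for explainability: with a chemical baseline
populating most scans it estimates the baseline level directly.

`detectPeak()` locates the trace maximum in the retention-time window
(default: the whole run — published "expected" elution times are
gradient-specific and do not transfer) and then refines apex RT and
intensity by a log-quadratic fit through the three samples around the
maximum. A Gaussian elution profile is exactly log-quadratic, so this
recovers the true apex rather than the nearest grid sample; at a 3 s scan
cadence the raw grid maximum can under-read the apex by up to ~1.4%,
which matters when calls compare intensities against fixed thresholds.
Samples that do not form a positive concave triplet fall back to the raw
maximum. Detection requires both an absolute floor
(`min_abs_intensity`, default 1e4 counts) and a signal-to-noise gate
(`min_snr`, default 3). The peak area (trapezoid over the contiguous
above-noise region) is reported for completeness, but calling reasons on
apex intensity: published intensity bands for these markers are maximum
ion intensities, not areas. No multi-peak deconvolution is attempted —
each marker is expected to elute as a single peak.

## The sex-calling rule

With per-marker detections in hand (`evaluateMarkers()`), `callSex()`
applies:

* **male** — any AMELY-specific marker detected (one suffices; requiring
  both would ignore that the diagnostic signal is the *presence* of
  AMELY peptides);
* **female** — no AMELY and AMELX apex $\geq$ `female_min_amelx`
  (default 1e6 counts, within the 1e6–1e7 band reported for confident
  females);
* **probable female** — no AMELY and AMELX between `weak_floor`
  (default 1e4) and `female_min_amelx`: an attenuated AMELX signal
  (~1e5) can reflect taphonomic peptide loss in a female *or* an
  AMELY-deleted male, so the call stays cautious;
* **undetermined** — neither signal usable.

The shared and enamelin markers never influence the call; they only feed
a preservation count. The 1e6 boundary is an interpolation between the
published confident-female band and the single published ambiguous case;
it is surfaced in `callThresholds()` rather than hard-coded. The blank is
evaluated with the same detector (`qcBlank()`); any detected marker fails
QC, and `callBatch()` then flags — but does not discard — the batch.

## Odontometric analyses

Buccolingual diameters are measured in triplicate and only the median is
used. The reference classifier is a fixed cut-off (default 7.73 mm, from
a recent Portuguese reference population): strictly larger is male. The
tie rule (exactly at the cut-off classifies female) is not stated in the
reference sources; "greater than" was chosen, which also matches the
observed error direction when the study population is smaller-toothed
than the reference. Observer error uses the classical two-series
technical error of measurement,
$\mathrm{TEM} = \sqrt{\sum_i d_i^2 / 2n}$, with
$\%\mathrm{TEM} = 100\,\mathrm{TEM}/\bar{x}$ and reliability
$R = 1 - \mathrm{TEM}^2/s^2$ over all $2n$ values; three-or-more-way TEM
is out of scope. Agreement between peptide and odontometric calls is a
2x2 confusion matrix (probable females excluded, keeping the published
35-specimen denominators), overall and per-class accuracy, and Cohen's
kappa $\kappa = (p_o - p_e)/(1 - p_e)$. Because the reference analyses do
not state how their kappa p-value was obtained, the package computes it
by a seeded permutation test (default 10,000 label shuffles) rather than
an asymptotic formula. `sampleSpecificCutoffs()` reports the sex pooled
mean and the unweighted average of the two sex-specific means
("weighed sex pooled mean" is interpreted this way; the source does not
define it), with a warning below the recommended 40 specimens.

## LEH age of onset

Wear grades 0/1/2 map to 0%/5%/10% crown-height loss; higher grades make
a defect non-estimable and are excluded with an explicit reason. The
unworn crown height is reconstructed as $H_0 = H/(1-w)$ — wear removes
height from the cusp end only — and a defect at CEJ distance $d$ sits at
position fraction $f = (H_0 - d)/H_0$ from the cusp. The calibration
mapping $f$ to age is pluggable and monotone; the default interpolates
linearly between crown formation at the cusp (1.5 y) and completion at
the CEJ (6.5 y). Published regression calibrations live in cited
literature rather than in the source this package re-implements, so the
linear default keeps the pipeline self-contained while letting those
calibrations drop in (non-linear mappings are inverted numerically for
the generator's round trip). When an individual has several estimable
defects, its earliest onset represents it in the sex comparison
(configurable); overall LEH prevalence counts all individuals, while the
per-sex split uses confident sex calls only — mirroring the published
bookkeeping (24/36 overall, 15/23 and 9/12 by sex).

## Cohort statistics

Sex ratios are males per female over confident calls only; probable
females are a separate column, never a denominator. A cohort with no
females reports a distinct "undefined" state rather than infinity so that
banding stays total. Bands follow demographic convention: natural 0.95–
1.02, extreme at or below 0.90 and at or above 1.05, the gaps
intermediate. The chi-square helper is the uncorrected Pearson statistic
on 2x2 counts — on the published LEH-by-sex table the uncorrected
statistic reproduces the published p = 0.554, a continuity-corrected one
does not. The t helper is the unpaired equal-variance Student's t, with
zero-pooled-variance inputs answered by an explicit degenerate signal
instead of an error.

## What the synthetic generator emulates

`simulateRun()` produces centroided MS1 scans at a fixed cadence
(default 3 s over a 65-minute gradient, about 7+ points per peak FWHM).
Each emitted marker contributes one Gaussian elution peak (sigma
0.15 min) whose apex is drawn log-uniformly from its profile band:

| profile  | AMELY apex | AMELX apex | shared/ENAM |
|----------|------------|------------|-------------|
| male     | 1e5–1e6    | 1e6–1e7    | 3e5–3e6     |
| female   | none       | 1e6–1e7    | 3e5–3e6     |
| degraded | none       | 5e4–5e5    | 1e4–1e5     |
| blank    | none       | none       | none        |

Marker centroids carry Gaussian 1 ppm mass error; every scan additionally
receives 25 uniform noise centroids (m/z 300–1000, 50–500 counts) and,
for each marker, one faint in-window baseline centroid (50–200 counts,
1.5 ppm jitter) in *all* profiles including blanks — real chromatograms
carry chemical background at any mass, and this baseline is what makes
the median noise estimator meaningful. The degraded band sits between the
weak floor and the female threshold by construction, so a degraded run
yields exactly one probable-female call, mirroring the published
ambiguous sample whose AMELX signal was ~100-fold below the rest.

What the generator does **not** emulate: isotope envelopes, co-eluting
interferences, peak tailing (EMG shapes were rejected as unnecessary for
threshold-based calling on apex intensity), retention drift across runs,
deamidation or other PTMs, and intensity-dependent mass error. Passing
tests therefore demonstrate the decision logic and its thresholds, not
robustness to every pathology of real archaeological chromatograms.

`escouralFixture()` assembles the full validation cohort: 36 runs with
the published context structure (inside the cave 8 male / 21 female /
1 degraded; outside 4 male / 2 female), one blank, and matching
odontometric (sex means 7.95/7.30 mm, between-specimen sd 0.35, repeat
error 0.05 mm — plausible values around the published pooled means, set
once as configuration, not claims about the site) and LEH tables
(67% affected; onsets truncated-normal 3.6 plus or minus 0.5 y within
2.6–4.6 y; wear grades 0/1/2/3 at 30/25/20/25%). CEJ distances are
generated by inverting the calibration from the drawn onsets, so
re-estimation recovers them to numerical precision.

## Numerical choices and degenerate inputs

* All randomness flows through a single integer seed; cohort members get
  sub-seeds drawn deterministically from it, and the caller's RNG state
  is always restored.
* An empty run yields an empty trace, not an error; an rt window outside
  the run span yields a warning and a non-detection.
* Ratio of males to zero females: reported as undefined, never `Inf`.
* `t.test` refuses constant data; `studentsT()` instead reports t = 0,
  p = 1 for equal constant means and an exact-separation signal
  otherwise.
* Kappa permutation p uses the add-one estimator
  $(1 + \#\{\kappa^* \ge \kappa\})/(B + 1)$, so it is never exactly 0.
* mzML writing goes through the proteowizard bindings (`mzR`); the
  round trip preserves retention time, m/z and intensity to well below
  1e-6 relative.

## Problem sizes used in validation

The packaged tests run the complete cohort fixture at default scan
density over a 20-seed suite for the count-structure check, 50 seeded
replicates for apex recovery, 100 seeds for the observer-error bounds,
and 1000 replicates for the t-test's type-I error; the file-based
pipeline test uses a coarser 6 s cadence, which the apex refinement
renders equivalent for calling purposes. These sizes were chosen as the
smallest that make the stochastic assertions stable.

## Known limitations

Sex calling is categorical, not probabilistic: no posterior for AMELY
deletion or degradation is modelled. MS2 identity confirmation, isotope
pattern scoring and cross-run alignment are out of scope. The odontometric
cut-off is a single univariate rule; discriminant functions over multiple
dimensions are not provided. LEH onset estimation inherits the coarse
wear correction (5%/10%) and the calibration's assumptions; perikymata
counting is far more precise where preservation allows it.
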