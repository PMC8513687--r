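---
title: "Models and methods behind quadcell"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind quadcell}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(quadcell)
```

quadcell is a simulation and analysis toolkit for quad-modality cellular
interfacing array experiments: a 32 × 32 grid of multimodal pixels (58 µm
pitch, 1.85 mm field of view, four photodiode sites per pixel) that records
optical opacity, per-pixel light-intensity transients, extracellular
potentials and adjacent-electrode impedance while delivering biphasic
current stimulation. This vignette describes the models the package
implements, the tunable parameters that matter, and the choices made where
the design was genuinely open.

## Why synthetic data comes first

No public raw recordings exist for this class of experiment, so the package
treats the synthetic-data generator as a first-class module: it produces
multimodal recordings with *known ground truth* (fiducial times, capture
patterns, propagation slopes, adhesion kinetics), and every analysis stage
is validated by generator–extractor round trips. What passing tests show is
therefore that the *pipeline* is self-consistent and recovers known
structure at realistic signal scales — not that the generator reproduces
every feature of real recordings. Known simplifications: optical beats are
smooth two-segment transients (no motion artefacts or drift), noise is
white and Gaussian (real photodiode and amplifier noise has 1/f and
line-frequency components), the refractory rule is a hard threshold with no
relative-refractory latency shift beyond Gaussian jitter, and cell
morphology is radially symmetric.

## The optical beat model

A contraction transient is parameterized directly by its four reported
fiducials, all measured from the stimulus onset:

* `CT'_PKS` — contraction slope peak time (maximum of the first
  derivative during the rise),
* `CT_PKS` — contraction peak time (the intensity maximum),
* `RX'_PKS` — relaxation slope peak time (most negative derivative during
  the decay),
* `T_d` — optical cycle duration.

The waveform family is not prescribed by the measurements, only the
fiducials are; the generator therefore builds each beat from two
regularized-incomplete-beta segments,

$$y(t) = A\,I_{t/\mathrm{CT}}(a_1, b_1) \;\; (0 \le t \le \mathrm{CT}),
\qquad
y(t) = A\,I_{1-(t-\mathrm{CT})/D}(a_2, b_2) \;\;
(\mathrm{CT} < t \le \mathrm{CT}+D),$$

because this family joins the peak with zero slope from both sides (C1
continuity), starts and ends at baseline with zero slope, and exposes each
fiducial analytically: the rise derivative is a beta density whose mode is
pinned to `CT'_PKS` by choosing $a_1 = 1 + 4\,\mathrm{CT'}/\mathrm{CT}$
(with $a_1 + b_1 = 6$ fixed), and the decay's shape parameter and support
$D$ are solved numerically (`uniroot`, tolerance $10^{-10}$) so that the
steepest descent lands on `RX'_PKS` and the 10 %-of-peak crossing lands on
`T_d` — a verify-and-adjust construction. Realized fiducials agree with
requested ones within one sample at the 1 kHz default rate for all shipped
presets.

Two fiducials needed operational definitions that the measurements display
but never define:

* `T_d` is the time at which the signal first falls below 10 % of the peak
  above baseline (configurable via `decay_frac`);
* `FPD` (potential modality) is the interval from the evoked spike
  extremum to the T-wave apex.

## The extracellular potential model

Each captured pulse contributes a charge-balanced rectangular biphasic
artefact (~mV scale, dominating the recording), a sharp biphasic spike — a
dominant negative Gaussian lobe of width 1.2 ms at exactly
`t_ap_ms` after the onset, with a smaller delayed positive rebound,
rescaled so the sampled peak-to-peak amplitude equals `spike_amp_uv`
(~100 µV scale) — and a smooth unipolar Gaussian T-wave whose apex sits
exactly `fpd_ms` after the spike extremum. White noise is seeded and
reproducible.

## Feature extraction

Extraction never assumes the generator's waveform family. For optical
traces, beats are detected as prominent local maxima of the smoothed
signal, attributed to the most recent stimulation pulse (attribution
window = one period), and measured relative to that pulse. Thresholds are
robust-amplitude based: a peak is a beat when it exceeds 30 % of the median
detected peak height, with a noise floor at 6 MADs of the first-difference
scale; spikes in potential traces use 4 MADs of the artefact-blanked trace.
The stimulation artefact is blanked over two pulse phases plus a 5 ms guard
— a software analogue of the hardware practice of recording far from the
stimulation site. Edge beats truncated by the recording end (or by the next
pulse, at rates where the cycle does not finish) yield no feature row;
capture detection (`detect_captures`) counts attributed *peaks* instead, so
high-rate pacing is still scored correctly. If a derivative attains its
extremum at several samples, the earliest is taken.

Two smoothing modes are provided (`feature_config(smoother = ...)`):

* `"sgolay"` (default): cubic Savitzky–Golay over an 11 ms window with
  mirrored edges, then a central-difference derivative. On clean traces
  every fiducial is recovered to within 1–2 samples, which is what the
  deterministic recovery checks use.
* `"lowpass"`: zero-phase Butterworth filtering (5 Hz for the derivative,
  15 Hz for value features), quadratic-vertex refinement of extremum
  locations over ±120 ms windows, and an isotonic (monotone) fit of the
  decay for the `T_d` crossing. Under broadband noise of 5 % of the beat
  amplitude this keeps `CT'_PKS`, `CT_PKS` and `RX'_PKS` within ~5 ms of
  their noiseless values per single beat.

A known limitation, stated rather than hidden: the `T_d` crossing sits on a
decay whose local slope is only ~0.002 amplitude/ms, so at 5 % broadband
noise no single-trial estimator can localize it to a few milliseconds —
empirically the scatter is 10–15 ms whatever the smoothing. Beat averaging
is the appropriate remedy and is how such assays are actually run (19 beats
per dose in the baseline protocol); the 10-beat mean of `T_d` is stable to
within ~4 ms at the same noise level.

## Pacing, capture and the refractory period

The capture rule is deterministic and closed at the boundary: a pulse
captures iff the time since the last *captured* pulse is ≥ the absolute
refractory period (ARP), and the first pulse always captures. The closed
boundary is deliberate: with ARP 222 ms a 111 ms (9 Hz) train then yields
exactly 50 % capture, matching the experimental readout that anchors the
ARP estimate. The resulting pattern is periodic with one capture every
$m = \lceil \mathrm{ARP}/T \rceil$ pulses, so the model's asymptotic
capture fraction is $1/m$; `refractory_capture_model()` simulates the
pattern and reports that asymptotic fraction for trains of ≥ 20 pulses
(finite fractions for shorter trains). Two ARP estimators are provided:
frequency-doubling at the highest ~50 % capture frequency, and a 1 ms-grid
sweep inversion of the capture model that reports the smallest consistent
ARP together with the full consistent interval — e.g. observations
{4 Hz: 100 %, 5 Hz: 50 %} constrain the ARP to (200, 250] ms.

Relative-refractory behaviour (capture with altered latency near the
boundary) is represented only as Gaussian latency jitter; no second
threshold is modelled.

## Contraction-wave reconstruction

Real acquisitions scan the 1024 pixels sequentially under periodic pacing;
the movie is reconstructed by folding each pixel's trace to
stimulus-relative time (mean over its available cycles — the fold method is
a design choice; the number of averaged cycles per pixel is not dictated by
the source experiments) and referencing each folded trace at the stimulus
instant, so the frame at time zero is identically zero by construction.
Mechanical onsets are the first crossing of 20 % of the per-pixel peak
(configurable); the periphery-versus-centre index is the least-squares
slope of onset versus radial distance in ms/µm, negative when the rim moves
first (the mechanically coupled monolayer behaviour) and positive for
classical centre-outward electrical propagation (slope $1/v$). Radial
distances use pixel centres at the 58 µm pitch with the array centre at the
mean of the pixel centres.

The generator's mechanical onset model is linear in radius
(`intercept + slope · r` plus per-beat jitter); its defaults for full-array
scenarios (intercept 40 ms, slope −0.02 ms/µm, electrical conduction
200 µm/ms ≈ 20 cm/s, typical of neonatal rat ventricular myocyte
monolayers) are package design choices, as the source measurements report
the periphery-first observation qualitatively.

## Time-lapse imaging and adhesion

Opacity frames are sums of radial Gaussian blobs (amplitude decaying
exponentially as cells spread and become transparent, radius growing
linearly); impedance frames ramp from a cell-free baseline (0.3 MΩ design
default at the 100 kHz measurement point) toward a cell-type plateau —
1.15 MΩ for fibroblasts, 0.65 MΩ for cardiomyocyte spheroids, inside the
reported 1–1.2 and 0.5–0.8 MΩ ranges — under a logistic disc one pitch wide
at its edge, with a saturating (max, not sum) combination where aggregates
overlap. Enzymatic detachment multiplies the impedance excess by a
two-phase exponential: slow at room temperature until minute 11, faster at
37 °C, mirroring the reported assay timeline. `detachment_kinetics()` fits
the per-phase decay by log-linear least squares, which is exact for
single-exponential data and degrades gracefully (a warning, not an error)
on non-monotone series.

Pair-measurement images: each impedance measurement involves two adjacent
electrodes, and how pair values map to pixel images is not specified by the
source material; the package attributes each pair to both incident pixels
and averages (`assemble_impedance_frame`), which is linear and local. A
full scan of the 32 × 32 grid is 2 · 32 · 31 = 1984 pairs. Aggregate
centres for front-radius metrics are supplied by the caller or generator
metadata — segmentation is out of scope.

## Dose–response aggregation and the trend test

Per (dose, feature) the table reports the arithmetic mean, sample standard
deviation (n − 1) and count. The trend statistic is the least-squares slope
of per-beat values against the *dense rank* of dose — with three doses,
fitting log-concentration curves would be overreach, and the source
analysis reports only means and σ with no inferential statistics, so the
package's two-sided permutation test (dose labels shuffled across beats,
seeded, add-one correction; exhaustive enumeration available and exact for
small designs) is an addition, not a reproduction. Direction is reported
only when p < α (default 0.05). The 10 nM preset values are design
extrapolations (a further ~8 % proportional shortening of the 3 nM preset)
and are flagged non-authoritative in the presets file.

## Numerical and interface choices

* Default sampling rate 1 kHz: the reported intervals are printed at
  0.1 ms precision and all tolerances are ≥ 2 ms, so 1 kHz is ample; the
  generator accepts ≥ 200 Hz.
* One integer seed per generation call; every stochastic draw derives from
  it (`withr::with_seed`), so identical calls are bit-identical.
* Recordings and frame series live in HDF5 (schema attribute
  `quadcell-1`; readers refuse other majors), feature tables in CSV with a
  fixed column order, configs in YAML/JSON with unknown keys rejected.
* Problem sizes in the test suite: single-pixel or 8 × 8 recordings for
  round trips and properties, one full 32 × 32 / 4096-site pass for the
  reconstruction plumbing, 300 replicates × 199 permutations for the
  trend test's type-I check. These sizes were chosen to exercise every
  code path at full fidelity while keeping the suite quick to run.

## Worked example

```{r example, eval = FALSE}
p <- quadcell_preset("PACED_BEAT")
rec <- synth_paced_recording(p$monolayer, p$protocol)
feats <- extract_optical_features(get_trace(rec, rec$optical_pixels[1]),
                                  rec$train)
mean(feats$ct_pks_ms) # ~190 ms, sd ~13 ms across beats

detect_captures(get_trace(rec, rec$optical_pixels[1]), rec$train)
estimate_arp(tibble::tibble(frequency_hz = 9, capture_rate = 0.5))
```
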