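---
title: "Methods: simulating and analysing TMS-evoked EEG oscillations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and analysing TMS-evoked EEG oscillations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(teposc)
```

# The analysis problem

Single-pulse transcranial magnetic stimulation (TMS) delivered during EEG
evokes an oscillatory response whose strength and regional differentiation
carry information about cortical network function. The analysis implemented
here asks three questions about a two-group design (healthy controls, HC,
versus a clinical high-risk group, CHR-P; three stimulation sites — left
dorsolateral prefrontal cortex `lDLPFC`, left posterior parietal cortex
`lPPC`, dorsomedial prefrontal cortex `DMPFC`):

1. Does the theta-band (4–7.5 Hz) response over fronto-central electrodes
   differ between stimulation sites within a group?
2. Does that site differentiation differ between groups?
3. Is extracted band power associated with clinical symptom scores?

Because raw recordings of this kind are rarely shareable, the package pairs
the analysis chain with a synthetic cohort generator that reproduces the
statistical structure the chain assumes. Every stage is testable end to end
against generator ground truth.

# Time-frequency decomposition

Epochs (µV, `[epoch, channel, sample]`, time in ms relative to the pulse)
pass through a fixed chain, in this order:

1. **Pulse-window interpolation** (`interpolate_pulse_window()`): samples
   strictly inside (−1, 15) ms are replaced by the straight line through
   the enclosing boundary samples, per epoch and channel, removing residual
   pulse/decay artifacts.
2. **Zero-phase band-pass 3–100 Hz** (`bandpass()`): a real, Butterworth-
   magnitude gain (order 8 per edge) applied in the frequency domain. The
   normative contract is gain 1 ± 0.05 on [1.25·lo, 0.8·hi], ≥ 20 dB
   attenuation at 0.5·lo and 1.5·hi, and no measurable group delay; the
   filter family behind the contract is an implementation detail.
3. **Morlet decomposition** (`morlet_tfr()`): 30 frequencies and cycle
   counts in paired geometric progressions, `f_k = 3·(80/3)^((k−1)/29)` Hz
   and `c_k = 3·(10/3)^((k−1)/29)` cycles (`make_freq_grid()`). Wavelets
   are Gaussians in the frequency domain (spectral SD `f/c`), normalized so
   a unit sinusoid at the centre frequency has unit power. Single-epoch
   power is averaged across epochs — the *total* response, retaining
   non-phase-locked activity. `induced_tfr()` subtracts the across-epoch
   mean waveform (the ERP) from every epoch first, isolating induced from
   evoked power.
4. **dB baseline normalization** (`db_normalize()`): per frequency,
   channel and dataset, `10·log10(P / mean(P over −400..−200 ms))`.
5. **20-ms temporal binning** (`bin_time()`): non-overlapping means
   anchored at the epoch start; a trailing partial bin is dropped.

Normalization precedes binning; the two do not commute (Jensen), and a
regression test pins this order.

Averaging *power* rather than complex coefficients across trials is the
only reading consistent with the induced-activity control: subtracting the
ERP can only change the result if the total response contains
non-phase-locked power. The epoch extent defaults to [−1000, 1000] ms —
wide enough that the slowest wavelet (3 Hz, 3 cycles, ±3 SD ≈ ±477 ms)
leaves the baseline window and the 20–300 ms analysis windows free of edge
contamination (edge samples are flagged and the flags are carried through
binning).

# Regions of interest

`default_bands()` hard-codes the two response windows: theta 4–7.5 Hz /
60–300 ms and low gamma 30–45 Hz / 20–100 ms. Band membership is a closed
interval on grid frequencies and a half-open interval `[t_lo, t_hi)` on bin
centres — an explicit convention where several were possible. The theta
region of interest is the fixed fronto-central set FC1, FCz, FC2, C1, Cz,
C2 (`theta_electrodes()`); the spatially variable gamma response instead
uses, per stimulation site, the electrode with peak band power averaged
over 20–100 ms (`select_gamma_electrode()`, ties broken by montage order).
Both bands and electrodes are overridable through the pipeline
configuration.

# Cluster-based permutation statistics

For each subject the three site maps are mean-centred
(`center_by_subject()`): the across-site mean map is subtracted, so each
site's map becomes that subject's deviation from their average response.
Deviations sum to zero across sites by construction, and any subject-level
offset (including the phase-locked ERP, which is common to all sites)
cancels exactly.

**Within-group test** (`within_group_test()`): the null flips the sign of
each subject's whole deviation map independently per permutation (5000 by
default) and records the across-subject mean map. The z-map standardizes
the observed mean by the mean and SD (n−1 denominator) of the permuted
means. Cells with zero permutation spread get z = 0 with a warning.

**Cluster correction** (`cluster_correct()`): two-sided cluster-forming
threshold |z| ≥ 1.96 (α = 0.05); connected components by 8-connectivity in
the frequency × time plane (the common default for 2-D image labeling);
the cluster statistic is size in bins. Each permutation's own z-map is thresholded and labeled identically,
yielding a null distribution of maximum cluster sizes from the same single
pass of permutations; observed clusters whose size exceeds its 97.5th
percentile are significant. Positive and negative cells share one |z| mask
but clusters are reported with their signed peak (dB, Hz, ms, z, and a
two-sided normal p for the peak z).

**Between-group test** (`between_group_test()`): both groups are centred
per subject first; the observed statistic per site is the group difference
of mean deviation maps (A − B). The null reassigns subjects to groups at
random preserving group sizes; z-maps and cluster correction are as above.

Three conventions this family of analyses often leaves open are fixed here
and exposed as arguments: the cluster-forming threshold is two-sided (site
deviations of both signs are scientifically meaningful); positive and
negative clusters are pooled in the null max-size distribution; and peak
p-values use the two-sided normal mapping of the peak z rather than a
permutation rank.

The exhaustive-enumeration oracle in the test suite enumerates all 2^n
sign patterns (or all group splits) and standardizes by the *population*
SD of the complete permutation distribution — the estimand of the
Monte-Carlo sample SD. For n = 3 scalar deviations (1, 2, 3) this gives
z = 6/√14; Monte-Carlo z-maps converge to the enumeration values within
Monte-Carlo error, which the tests check at 3 standard errors.

# Band power, mixed models, associations

`extract_band_power()` reduces each subject × site dB map to the scalar
mean over band frequencies, window bins and ROI electrodes.
`fit_group_site_lmm()` fits

```
mean_power ~ group * site + age + antipsychotic + (1 | subject)
```

by REML with reference levels HC and lDLPFC, Satterthwaite denominator
degrees of freedom (via lmerTest), and conditional R² computed as
(fixed + random variance) / total. Singular random-effect fits are flagged
rather than fatal. `fit_comorbidity_lmm()` refits within CHR-P with
comorbid mood disorder replacing group.

`spearman_fdr()` computes Spearman rank correlations (average ranks on
ties) between band power per site and clinical items within CHR-P, with
pairwise deletion; pairs with fewer than 3 complete observations are
flagged undefined. Benjamini–Hochberg correction is applied within a
configurable family; the default family is all site × item tests of one
band (3 sites × 11 items = 33 tests per band). `"band_site"` and
`"global"` are available where a different multiplicity family is wanted.

# The synthetic cohort generator

`simulate_cohort()` draws, per subject × site, epochs of:

- **1/f background noise**: spectrally shaped Gaussian noise with log-log
  slope −1 over the analysis range (flattened below 2 Hz), broadband RMS
  10 µV.
- **A phase-locked ERP**: an N100/P200-like biphasic waveform (default
  5 µV), identical across trials, fronto-central topography.
- **A theta burst**: Gaussian-windowed sinusoid, 5.5 Hz carrier, centre
  180 ms, FWHM 240 ms, independent uniform phase per trial — so theta
  response is almost entirely *induced*, letting the induced-activity
  control be exercised.
- **A gamma burst**: 38 Hz, centre 60 ms, FWHM 80 ms, topography peaked at
  C1 (lateral sites) or Cz (DMPFC) so the peak-electrode selector has
  something to find.

Topographies fall off as the cosine of the great-circle scalp angle from
the peak electrode (floored at zero) on an approximate 64-channel 10-10
montage; no volume conduction is modelled.

**Amplitude calibration.** Burst amplitudes are specified in dB and
resolved operationally: the generator computes the expected wavelet noise
power per frequency analytically from the discrete noise spectrum (through
the band-pass and wavelet transfer functions) and the unit burst's binned
wavelet power by running the decomposition on the noiseless burst, then
solves for the scale factor making the expected ROI-mean dB equal the
requested value. This makes recovery tests well-posed: an injected
+3 dB cell is recovered by the full pipeline within ±0.5 dB at n = 20.

**Effect structure.** Group × site theta targets emulate the
differentiated-versus-flattened pattern this design probes: HC lDLPFC
2.88 dB with lPPC and DMPFC 0.92 and 1.03 dB lower (site effects of
roughly −1 dB, the magnitude typical of extracted theta responses); CHR-P
uniform at 2.7 dB — a flattened, uniformly elevated response; gamma 0.9 dB
everywhere with no group or site structure. Dispersion defaults are the
package's own: a subject-level amplitude offset (SD 1.2 dB, shared
across sites — it cancels exactly under mean-centering) and an independent
site-level jitter (SD 0.3 dB). The jitter is deliberately the smaller
component: it is the only noise source that survives mean-centering, and
it is set so that the site-differentiation pattern is reliably detectable
at the cohort sizes the package's simulation studies use (n ≈ 20/group),
while total between-subject SD (≈1.3 dB) stays within the 1.5–1.8 dB range
plausible for extracted band power in cohorts of this kind. Clinical items are drawn around
group-typical base rates with negative coupling to the subject's theta
amplitude on selected items (P1, N2, N4, N6), ordinal noise, clipping to
0–6, and realistic missingness (negative items unassessed in controls).

`simulate_null_cohort()` forces the amplitude maps to a single constant,
making the generative distribution exchangeable across sites and groups —
the basis of the family-wise-error calibration.

# Problem sizes used in the simulation studies

The generator's defaults are the study-scale protocol (100 pulses per
site, 2500 Hz, 64 channels). The package's own simulation studies
down-scale dimensions that do not affect the property under test:

- *Family-wise error calibration*: 200 null cohorts of 20 subjects,
  noise-only epochs (all amplitudes and amplitude SDs zero), 8 epochs per
  site, 200 Hz sampling, the 6 theta-ROI channels, a reduced 15-frequency
  grid (3–80 Hz), 500 permutations, tested on 20 bins over 0–400 ms. The
  fraction of (cohort, site) analyses reporting any significant cluster
  must stay at or below 5%.
- *Pattern recovery*: 25 replicate cohorts of 20 + 20 subjects at the full
  100 pulses per site, 150 Hz sampling, a 12-step 3–45 Hz grid (cycles
  3–8, matching the master grid's pairing at 45 Hz), band-pass 3–70 Hz.
  HC-like cohorts must show significant theta clusters at all three sites
  with the injected signs, flat CHR-P-like cohorts none, and the
  between-group test must flag lDLPFC — each in at least 80% of
  replicates.
- *Mixed-model recovery*: 300 band-power tables simulated directly from
  the LMM generative model (site effect −1.0 dB, interaction +0.8 dB,
  subject SD 0.5, residual SD 0.5, n = 50/group); site and interaction
  estimates must fall inside their 95% CIs in ≥ 90% of replicates
  (empirical coverage of both is ≈ 94–95%).

# What passing tests do and do not show

The generator emulates the *statistical* structure the analysis assumes:
stationary 1/f noise, a phase-locked ERP, induced band-limited bursts with
smooth topographies, subject-level amplitude heterogeneity, and
symptom–amplitude coupling. It does not emulate TMS decay or muscle
artifacts, auditory-evoked contamination, volume conduction, bad channels,
or non-stationary noise — the artifact-cleaning stages that handle those in
real data are upstream of this package's scope. Passing tests therefore
demonstrate correctness and calibration of the statistics under the stated
model, not robustness to real-world recording pathologies.

# Numerical choices and degenerate inputs

- FFT-based convolution pads to a fast composite length covering the
  longest wavelet; samples within 3 wavelet SDs of an epoch edge are
  flagged.
- Zero permutation spread yields z = 0 with a warning rather than NaN.
- Cluster significance is strict (`size > threshold`), with the threshold
  the type-7 quantile of the null maximum sizes.
- Amplitude targets that calibration cannot represent (≤ 0 dB after
  subject/site offsets) produce no burst; realized amplitudes are stored
  as ground truth.
- `epoch_set()` enforces uniform sampling, unique channel labels, and an
  epoch containing time zero; `cohort_spec()` rejects montages missing any
  theta-ROI electrode and epoch windows excluding the baseline or theta
  analysis window.
- All randomness flows from a single integer seed per cohort or test;
  identical configurations are bit-reproducible.

# Known limitations

- The approximate 10-10 montage geometry is adequate for smooth topography
  weights, not for source-space work.
- Spearman p-values use the asymptotic t approximation (ties permitted);
  exact permutation p-values are not implemented.
- The between-group statistic operates on mean-centred deviations, so a
  uniform (site-independent) group difference is invisible to it by
  design; the mixed model is the instrument for such effects.
- Serialization of epoch arrays and TF maps uses RDS alongside CSV/JSON
  tables.
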