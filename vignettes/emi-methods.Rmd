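---
title: "The extended modulation index: model, surrogates and origin labeling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The extended modulation index: model, surrogates and origin labeling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emipac)
```

## Phase-amplitude coupling and why naive estimators mislead

Phase-amplitude coupling (PAC) is the statistical dependence of a fast
oscillation's amplitude $A_{f_A}(t)$ on the phase $\Phi_{f_P}(t)$ of a slow
oscillation — theta-gamma coupling in hippocampus being the canonical
example. Two estimators are in wide use:

* the **direct PAC estimator** (dPAC), a normalised mean vector length
  $$\mathrm{dPAC} = \frac{1}{\sqrt{N}}\,
  \frac{\left|\sum_t A_{f_A}(t)\, e^{i\Phi_{f_P}(t)}\right|}
       {\sqrt{\sum_t A_{f_A}(t)^2}} \in [0, 1],$$
* the **modulation index** (MI), the Kullback–Leibler distance between the
  distribution $P(j)$ of mean amplitude over $J$ phase bins and the uniform
  distribution, normalised by $\log J$ so that $\mathrm{MI}\in[0,1]$.

Both report a number per frequency pair but say nothing about *why* the
number is large. Sharp, non-sinusoidal waveforms (epileptic spikes, mu
arches, semi-periodic transients) produce strong spurious PAC between the
repetition rate and the broad band of harmonics that build the sharp edge.
The **extended modulation index** (eMI) implemented here addresses this by
(1) analysing only phase frequencies that carry a genuine oscillation, (2)
measuring amplitude from a cycle-locked averaged wavelet energy map rather
than a band-pass filter, and (3) labeling every significant coupling region
**Reliable** or **Ambiguous** according to whether the comodulogram maximum
is congruent with an actual spectral peak.

## The eMI pipeline

1. **Screening.** The Welch spectrum of the signal is divided by its
   background — a piecewise-cubic (pchip) interpolation through the
   spectral minima, computed in $\log_{10}$ space so the interpolant stays
   positive. The same ratio is computed for 200 pink-noise realisations of
   equal length; a phase frequency is analysed only when its ratio exceeds
   the 95th percentile of the pink-noise ratios. Welch segments are
   $\max(2\,\mathrm{s},\,4/\min f_P)$ long with 50% overlap, Hann window
   and per-segment mean removal, so every segment holds at least four
   cycles of the slowest candidate.
2. **Phase identification.** The significant low-frequency oscillation is
   extracted with a zero-phase 4th-order Butterworth band-pass of width
   $\Delta f_P$. Local maxima with topographic prominence below 5% of the
   median prominence are discarded, as are maxima within $1.5/f_P$ of the
   signal ends. Non-overlapping sections are selected greedily from the
   first retained maximum: one-cycle windows (path A, used for the
   comodulogram) and three-cycle windows (path B, used for the auxiliary
   maps and spectra). Window lengths are rounded to an odd number of
   samples so each window centres exactly on its maximum. If fewer than 3
   path-A sections remain the frequency is abandoned ("insufficient
   cycles").
3. **Energy map.** The Morlet continuous wavelet transform with wavenumber
   $w$ gives the energy density $E(t, f)$; a margin of $w/\min(f_A)$
   seconds is cut from both ends, where the wavelet support at the lowest
   analysis frequency is distorted by the signal edges. FFT convolution
   uses zero padding; the trimmed margin strictly exceeds the retained
   wavelet half-support, so the boundary mode does not affect retained
   values.
4. **Averaging and MI.** Path-A sections of $E(t,f)$ are averaged into
   $M^A(t, f)$, and the averaged filtered cycle $SP^A(t)$ supplies the
   phase axis via its analytic signal. MI is evaluated with that phase
   against each frequency row of $M^A$.
5. **Surrogates.** Each surrogate repetition re-extracts the path-A
   sections after displacing every centre by $U(-\tfrac{1}{2f_P},
   +\tfrac{1}{2f_P})$ seconds and stretching or squeezing its window by an
   independent factor $U(0.9, 1.1)$ (a window of $\Delta t_A/\text{factor}$
   seconds is read and linearly resampled back to the path-A sample count;
   energy values are untouched). This destroys the phase-amplitude relation
   while preserving the time-frequency content, including the variability
   of the low-frequency period. Displaced windows that leave the trimmed
   map are redrawn up to 10 times, then skipped.
6. **Centering and significance.** Original and surrogate MI values are
   centred by the per-pair surrogate mean, making pairs comparable, and the
   family-wise threshold is the 95th percentile ($p_C$) of the
   per-surrogate comodulogram maxima. Centred values may be negative;
   negativity is preserved — only thresholding decides significance. Each
   pair additionally records its empirical percentile within the maxima
   distribution ($P_{vals}$), with p-values floored at $1/(N_s+1)$;
   percentiles use linear interpolation between order statistics
   throughout. Pairs whose phase-bin distribution $P(j)$ nowhere exceeds
   the per-pair $p_{PC}$ surrogate bin threshold are rejected — the
   augmentation is not localised in phase.
7. **Labeling.** Significant pairs are grouped into 8-connected regions.
   For each phase-frequency column of a region the comodulogram maximum
   $f_A^{max}$ is located; the wavelet's frequency resolution
   $\Delta f_A^{max} = 2\sqrt{2\ln 2}\, f_A^{max}/w$ defines the congruence
   interval. Of the two section spectra — the average of per-section
   Blackman–Harris periodograms ($AS$) and the periodogram of the averaged
   signal ($SA$) — the one with more power where it exceeds the other over
   the search set is searched for a proper peak (descending slopes on both
   sides). The column is Reliable when the peak falls inside the congruence
   interval; a region is Reliable when at least one column is. Harmonic
   chains (integer multiples of an Ambiguous base within $\Delta f_P$,
   strict inequality) are relabeled Ambiguous.

Synchronised bursts survive signal averaging, so genuine coupling shows a
peak in $SA$ congruent with the comodulogram; sharp transients instead
spread energy across frequencies, leave $AS$ flat and $SA$ harmonic, and
come out Ambiguous.

## Parameters

| parameter | default | meaning |
|---|---|---|
| `w` | 5 | Morlet wavenumber; larger = finer frequency, coarser time resolution. Choose so the wavelet time span at $f_A$ stays below one $f_P$ cycle. |
| `delta_f_P` | 1 Hz | low-frequency filter bandwidth; widen for variable rhythms (2 Hz for the in-vivo-like settings). |
| `J` | 18 | phase bins of the MI. |
| `n_surrogates` | 200 | surrogate repetitions; the p-value floor is $1/(N_s+1)$. |
| `p_C`, `p_PC` | 95 | percentiles for the comodulogram and phase-bin thresholds. |
| `n_pink` | 200 | pink-noise repetitions of the screening step. |

## The synthetic models

The validation suite generates every signal it tests:

* **Coupled oscillatory bursts** — a unit 6 Hz sine with Gabor bursts
  (carrier 77 Hz, Gaussian envelope $\sigma = 10$ ms, peak amplitude =
  `amplitudes_ratio`, default 0.1) centred on a fixed phase of each cycle
  (default: the peak, where the published example places them; the exact
  phase does not affect detection), plus white noise (SD = `noise_level`,
  default 0.1), at 512 Hz for 10 s. `filling` < 1 keeps a random subset of
  cycles.
* **Amplitude modulation** — $A_{f_A}(t) = \bar A_{f_A}\,[(1-\chi)\sin(2\pi
  f_P t) + 1 + \chi]/2$ riding on the slow sine plus noise; the depth of
  modulation is $1-\chi$.
* **Multimodal coupling** — the modulation envelope is a sum of $M$
  normalised Gaussian bumps of lagged sawtooth waves (default mode phases
  $4\pi/5$, $3\pi/2$, $\pi/10$). The sawtooth is taken on a phase scale
  ($[-\pi, \pi)$ rad), so the Gaussian's variance of 0.1 rad$^2$ gives
  bumps of $\approx 0.74$ rad FWHM: on the conventional $[-1,1]$ amplitude
  scale the same variance produces bumps so wide that the three default
  modes merge into a nearly flat envelope and the model loses the
  multimodal character it is meant to exhibit (distinct histogram modes;
  mean-vector cancellation that blinds dPAC).
* **No-coupling controls** — the same burst signal with uniformly random
  burst times, and a 6 Hz sine plus `[76, 78]` Hz band-passed noise
  rescaled to maximum 0.1.
* **Gaussian spike trains** — spikes of 15 ms FWHM and amplitude 2 or 5
  background SDs at jittered-periodic ($100 \pm 20$ ms, spectral peak at
  10 Hz) or uniformly random times, high-passed at 1 Hz and low-passed at
  250 Hz (zero-phase Butterworth, 2nd order), 10 s at 1000 Hz. The
  background is unit-SD synthetic pink noise (spectrally shaped white
  noise, PSD $\propto 1/f$) standing in for a PAC-free EEG recording — a
  deliberate substitution that removes any external-data dependency.

What the generators do *not* emulate: non-stationary rhythms, 1/f slopes
different from $-1$, multichannel structure, event-locked designs, or
phase-dependent amplitude *attenuation* (the pipeline targets
augmentations only). Passing tests therefore demonstrate correctness of
the machinery under idealised stationary conditions, not performance on
arbitrary recordings.

## Reference-method conventions

For MI and dPAC the signal is band-passed with linear-phase FIR filters of
order equal to the samples in three cycles of the band's low edge, applied
forward-backward (implemented in the frequency domain as $|B(f)|^2$ with
zero padding, which lets whole surrogate ensembles be filtered in one FFT
batch). The amplitude band is $f_A \pm \max(f_P)$; the phase band is $f_P
\pm \Delta f_P/2$. dPAC discards the first and last second after filtering;
MI does not. Surrogates replace the phase series by the phase of white
Gaussian noise run through the same low-frequency filters; thresholds are
extreme-value, exactly as for eMI. In Eq.-form dPAC the length $T$ is taken
as the number of samples so the constant-amplitude, constant-phase case is
exactly 1.

A consequence worth knowing: the family-wise threshold is set by the
noisiest rows of the comodulogram — the lowest phase frequencies, where 10
seconds contain few cycles and the surrogate nulls are heavy. On a grid
reaching down to 2 Hz this caps dPAC's sensitivity for weak coupling
(detection at `amplitudes_ratio` 0.1 is ~80%, not 100%), while MI and eMI
are unaffected. We keep the family-wise rule; per-pair thresholds would
trade this for uncontrolled multiplicity.

## Numerical choices and degenerate inputs

* Percentiles: `stats::quantile` type 7 everywhere (linear interpolation
  between order statistics).
* MI empty phase bins contribute mean amplitude 0 and their $0\log 0$ term
  is dropped; an all-zero amplitude series is an error for both estimators.
* Fewer than 2 interior spectral minima: the screening background falls
  back to the linear trend through the band endpoints.
* Spectral-peak ties break toward the lower frequency; spectrum-choice
  ties go to $AS$.
* A comodulogram maximum on the lower edge of the $f_A$ range cannot be
  distinguished from the tail of a peak below the range: the column is
  labeled Ambiguous with a warning.
* Abandoned phase frequencies propagate as `NA` columns; surrogate maxima
  are taken over the analysed columns only.
* Master seed → independent child streams (per pink-noise draw, per
  surrogate repetition, per phase frequency), so results are reproducible
  and insensitive to evaluation order.

## Problem sizes used in the shipped validation

In the sensitivity experiments, "detection" means a statistically
significant pair inside the simulated coupling's neighbourhood (phase
frequency within 1 Hz of 6 Hz, amplitude frequency within half the wavelet
FWHM of 77 Hz): a coupling is considered found when its region is flagged,
not only when the single nearest grid cell is. The false-positive studies
instead count any significant pair anywhere, as a false alarm has no
privileged location.

The packaged experiments run at desk scale: false-positive calibration
with 50 realisations and 50 surrogates per noise level on a 9 × 17 grid
(2–10 Hz step 1; 40–120 Hz step 5); sensitivity sweeps with 10 seeds per
parameter value and 100 surrogates; localization on the full grid (1–12 Hz
step 0.5; 20–200 Hz step 2) with the default 200 surrogates. Binomial
confidence intervals at these sizes are stated alongside each check in the
test suite.

## A worked example

```{r example, eval = FALSE}
x <- gen_coupled_bursts(burst_params(noise_level = 0.05), seed = 7)
r <- emi_pac(x, f_P = seq(2, 10, 1), f_A = seq(40, 120, 5),
             n_surrogates = 200, seed = 11)
print(r)
#> <emi_pac> grid 9 f_P x 17 f_A, w = 5, 200 surrogates
#>   analysed f_P: 6
#>   significant pairs: 14 in 1 region(s)
#>    region 1: f_P 6-6 Hz, f_A 50-115 Hz, Reliable
```

Only 6 Hz survives the screening; the coupling region sits on the 6 Hz
column, spans the wavelet's resolution around 77 Hz, and is labeled
Reliable because the averaged-signal spectrum shows a congruent peak.

## Known limitations

* Origin labeling is a heuristic and can err, particularly for non-periodic
  transients that happen to cluster; inspect the auxiliary maps and spectra
  (`per_fp`) before trusting a label.
* Amplitude attenuation coupling is out of scope by design.
* The per-column label aggregation (Reliable if any column is Reliable) and
  the integer-multiple harmonic detector are package choices where the
  procedure is otherwise underdetermined; both are recorded per column in
  each region's `audit` table.
* Single-signal analysis only: phase and amplitude are read from the same
  channel.
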