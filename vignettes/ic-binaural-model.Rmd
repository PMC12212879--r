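---
title: "A normative inferior-colliculus model of binaural sound separation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A normative inferior-colliculus model of binaural sound separation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(icbinaural)
```

## The model

An auditory scene is a superposition of sources. `icbinaural` considers one
signal $S(t)$ at a fixed interaural time difference (ITD) $\Delta t$ plus
independent left/right ear noises $N_{R/L}(t)$, with equal levels at both
ears (the low-frequency approximation):
$R(t) = S(t + \Delta t/2) + N_R(t)$, $L(t) = S(t - \Delta t/2) + N_L(t)$.
In the frequency domain this is a $2\times3$ linear mixture; the
minimum-mean-square estimate of $(S, N_R, N_L)$ from the two ear signals is
its Moore–Penrose pseudo-inverse, available in closed form
(`mixing_pseudoinverse()`). Its time-domain reading is a Jeffress
coincidence detector whose internal delay compensates the ITD
(`delay_line_estimate()`): the matched detector recovers $\tfrac23 S$, the
best any linear readout of two microphones can do. Delay lines, however,
are not found in the mammalian brainstem, so the package's core is an
alternative implementation using the actual anatomy.

The first binaural comparison happens in the superior olivary complex:
$\mathrm{MSO}(t) = R(t) + L(t - \Lambda_m)$ (bilateral excitation) and
$\mathrm{LSO}(t) = L(t) - R(t - \Lambda_l)$ (ipsilateral excitation,
contralateral inhibition). An IC neuron combines the ipsilateral MSO with
the contralateral LSO, delayed by the commissural latency $\Lambda_c$ and
weighted by a relative synaptic strength $a$:
$\mathrm{IC}(t) = [\mathrm{MSO}(t) + a\,\mathrm{LSO}(t - \Lambda_c)]/\sqrt{1+a^2}$.
Per frequency channel $\omega = 2\pi\,\mathrm{BF}$, latencies become phases
$\psi_x$ (stored in cycles throughout the package, because all canonical
values are quoted that way): `ic_transfer()` implements

$$\hat{IC}(\omega) = \big[\hat R\,(1 - a e^{-i(\psi_l+\psi_c)}) +
  \hat L\,(e^{-i\psi_m} + a e^{-i\psi_c})\big]/\sqrt{1+a^2},$$

and `ic_power_tuning()` the resulting pure-tone ITD tuning power
$|\hat{IC}|^2$. The afferent phases are fixed at their experimentally
reported values $\psi_m = 0.125$ cyc and $\psi_l = 0$; $\psi_c$ and $a$ are
free. Negative $a$ switches to the smaller ipsilateral inhibitory LSO
projection, whose transfer ($\gamma_R^{(i)} = 1 + a$) is independent of
$\psi_c$ and cancels all ITD sensitivity at $a = -1$.

A note on the printed tuning-power formula: its interference term is
stated as a cosine of $\arg(\gamma_R\bar\gamma_L)$ combined with
$\omega\Delta t$, which double-counts the stimulus phase if $\gamma_L$
already contains the factor $e^{-i\omega\Delta t}$ (as its definition
says). We therefore evaluate the power directly as
$|\gamma_R + \gamma_L|^2/(1+a^2)$, which is algebraically identical to the
squared magnitude of the pure-source transfer; the equivalence is asserted
on 1000 random parameter draws in the test suite.

## The two-step optimization

`optimize_circuit()` performs, independently per channel:

1. for every target ITD and candidate $\psi_c$, the weight
   $a(\mathrm{ITD}, \psi_c) = \arg\max_{a\in[-10,10]} |\hat{IC}|^2$ for a
   unit-power source at the target ITD (level-invariant, so the unit
   source is no restriction);
2. the commissural phase minimizing
   $\mathcal L(\psi_c) = \int_0^{\mathrm{ITD_{max}}}
   (|a| - \ln|a| + \lambda\,\mathrm{sign}(-a))\,d\mathrm{ITD}$ with
   $\lambda = 1$: small LSO weights are favored, the log barrier avoids
   the pure-MSO solution $a = 0$, and the sign term penalizes the
   anatomically minor inhibitory pathway.

Default grids — weight step 0.01 on $[-10, 10]$, $\psi_c$ step 0.01 cyc on
$[0, 1]$, 64 target ITDs, channels 200–1500 Hz in 25 Hz steps — resolve
the optimum well inside the ±0.05-cycle acceptance band at about 15 s per
ITD bound on one CPU. Ties in the argmax resolve to the smallest $|a|$
(positive before negative), matching the parsimony intent of the loss; a
grid-zero weight is clamped to the grid step inside the logarithm (the
barrier makes this unreachable in practice). Quadrature is trapezoidal on
the target-ITD grid.

For all three ITD bounds (0.7 ms ≈ human, 0.3 ms ≈ cat, 0.15 ms ≈ gerbil)
every channel selects $\psi_c \approx 0.31$ cycles, and the optimal weight
is a smooth function of the product IPD = ITD × BF alone, nonnegative
below IPD ≈ 0.25 cyc.

### Sign conventions

The ear equations define $\Delta t > 0$ as right-leading. The transfer
above is the right IC; the left IC is its mirror image (ears swapped).
The geometry of the optimization discriminates between the two possible
hemifield mappings: only when target ITDs label *contralateral*-leading
sources does the optimization produce the 0.3-cycle optimum with smooth
nonnegative weights and input-plane inclinations increasing with ITD
(`mso_lso_trajectory()`); the ipsilateral mapping yields a split
0.31/0.81 optimum carried by negative weights. The package therefore (a)
treats target-ITD labels as contralateral ITDs, and (b) lets the
experiment recipes model the **left** IC, so that sources lateralized with
positive `apply_itd()` ITDs (right-leading) are contralateral and align
sign-for-sign with the neuron labels. With this convention an $a = 0$
neuron peaks at +0.125 cycles IPD, the experimentally observed
contralateral bias.

## Signal path

Broadband stimuli (96 kHz throughout) are low-pass filtered per ear by a
first-order 500 Hz Butterworth filter — the phase-locking/synaptic-kinetics
limit — then analyzed in 4001-sample Blackman-windowed snippets offset by
2000 samples. Each snippet spectrum passes the IC transfer per bin (circuit
parameters looked up by nearest best frequency; bins outside the optimized
band inherit the nearest channel), and output waveforms are resynthesized
by windowed overlap-add with division by the accumulated squared-window
envelope, which restores identity transfer to better than $10^{-3}$
relative error away from the edges. Spectra are scaled to amplitude units
(a unit-amplitude sinusoid gives a unit-magnitude bin) so that pipeline
band powers are commensurate with the closed-form tuning powers; the
scaling is undone exactly on resynthesis. The first and last window are
excluded from all derived metrics. The signal path is linear by
construction — negative outputs are read as activity below the spontaneous
rate — and superposition is asserted in the tests.

Two nonlinearities sit outside the linear path:

* **Recurrent divisive inhibition** (`inhibitory_normalization()`):
  per channel and frame, rates are divided by
  $1 + (J/N)\sum_{\tau'} IC_{\tau'}$ with $J = 20$ by default. It enters
  firing-rate analyses only, never waveform correlations. Because the
  divisor is common to all neurons of a channel, tuning *shape* along the
  neuron axis is preserved exactly; sharpening is relative to the additive
  baseline, and detection contrasts change because the divisor differs
  between stimulus conditions.
* **SOC firing-rate adaptation** (`adapt_soc()`): attenuation variables
  with $d\alpha_X/dt = (1-\alpha_X)/\tau_a - \alpha_X c_X |X(t)|$,
  $\tau_a = 2$ s, $c_{\mathrm{MSO}} = 5/\tau_a$,
  $c_{\mathrm{LSO}} = 10/\tau_a$, applied to peak-normalized drives as
  $X(t)(b+\alpha_X)/(b+1)$ with $b = 0.1$ (the printed replacement rule is
  ambiguous between $b + \alpha_X$ and $b + \alpha_X X$; the stated
  baseline gain $b/(b+1)$ at full adaptation fixes the first reading).
  Forward Euler at the audio rate is used; the sample period is four
  orders of magnitude below $\tau_a$ and step-halving convergence is
  asserted to 0.1%.

## Stimuli and what the generators emulate

All stochastic generators are pure functions of their seed. Besides tones
and calibrated tone-in-noise mixtures (0 dB SNR = equal RMS of the tone
and the 300–500 Hz band-passed masker), the package synthesizes
phase-warp binaural stimuli — flat-magnitude spectra whose interaural
phase pattern shifts at a warp frequency, evoking acoustic motion or
flutter — over a single full-duration FFT with the warp frequency snapped
to the FFT grid. A `speech_surrogate()` stands in for recorded talkers: an
amplitude-modulated harmonic complex (F0 100–220 Hz, 1/h rolloff below
1.5 kHz, syllabic raised-cosine bursts with pauses). It reproduces the
features the experiments rely on — harmonic fine structure, strong
amplitude modulation, silent gaps — but not formant dynamics, consonant
noise or speaker identity, so speech-scene results with surrogates probe
separation of modulated harmonic sources, not intelligibility. Recorded
WAV files can be substituted everywhere a surrogate is used.

## Evaluation battery and chosen defaults

* `exp_bmld()`: tone-in-noise detection via the per-channel contrast
  `dmax()` (ratio of time-averaged powers, tone-present vs the identical
  noise realization alone, max over neurons, minus 1; the printed formula
  is corrupted and a magnitude-ratio variant is switchable), read out by
  the flanking-minima `peak_prominence()` rule with criterion 0.05 within
  ±50 Hz of the 400 Hz signal. SNRs are probed descending from 0 dB; the
  masker's sub-500 Hz component is presented at unit RMS, which places
  band powers in the partially saturated regime of the $J = 20$
  inhibition — presentation level is not stated in the source material,
  and deep saturation (much louder) or the linear regime (much softer)
  both flatten the inhibition's effect on detection.
* `exp_speech()`: talkers at distinct ITDs, broadband (no low-pass),
  scored by 20 ms windowed Pearson correlations (mean over neurons) and
  winner histograms of inhibited rates.
* `exp_phase_warp()`: vector strength (`vector_strength()`) of squared
  output waveforms at the warp frequency, over an integer number of warp
  periods.
* `exp_tuning()` / `population_best_ipd()`: the Fig-5-style single-cell
  statistic. Tuning curves are rectified at 0.67 × the channel's
  population mean and the best IPD extracted as the phase of the curve's
  Fourier mode at BF. The curve support is genuinely ambiguous in the
  source description; evaluating curves **over the physiological window**
  (±0.3 ms) reproduces the reported population mean of ≈ 0.125 cycles
  (we obtain 0.132), whereas a full-IPD-cycle support yields 0.214 —
  necessarily above 0.125, since every optimized weight shifts the peak
  contralaterally from the $a=0$ anchor. The windowed reading is the
  default; `window = "full_cycle"` selects the other. Under neither
  reading are the per-channel means strictly constant over BF (they ramp
  from ≈ 0.01 to ≈ 0.25 cycles in the windowed reading); the package
  asserts only that they stay within the contralateral hemifield band,
  and we flag the constancy claim as not reproduced by this
  implementation.
* `exp_adaptation()`: input-plane trajectories under adaptation; the
  principal-axis angle moves toward the 45° diagonal during sustained
  tones and recovers in pauses.

Experiment recipes default to 29 target-ITD neurons on [0, 0.7 ms]
(0 to the largest optimized bound); the test suite and examples use
smaller neuron counts, 1.5 s stimuli and a 50 Hz channel spacing, which
resolve the same orderings at desk scale. Problem sizes are parameters,
not model content.

## Known limitations

No cochlear nonlinearity (compression, half-wave rectification), no
spiking dynamics, no DNLL pathway, no envelope-ITD mechanism above the
phase-locking limit — the model is meant for the low-frequency fine-
structure pathway. Detection thresholds are relative orderings, not
psychophysical fits: the prominence rule is a plausible population
readout, not a decision model. Fractional delays are frequency-domain
phase ramps and therefore circular at signal edges; all analyses exclude
edge windows for this reason.
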