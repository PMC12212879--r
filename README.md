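# icbinaural

A simulator of how the mammalian inferior colliculus (IC) could read the
binaural code of the auditory brainstem to *separate* sound sources — not
just localize them — using interaural time differences (ITDs). It is aimed
at auditory computational neuroscientists and psychoacousticians who want a
circuit-level, testable account of low-frequency binaural phenomena: ITD
tuning in the IC, binaural masking level differences (BMLDs), tracking of
rapidly varying ITDs, and cocktail-party-style talker separation.

## The model in brief

A source $S(t)$ at ITD $\Delta t$ plus ear noises reaches the ears as
$R = S(t+\Delta t/2) + N_R$, $L = S(t-\Delta t/2) + N_L$. The
minimum-mean-square reconstruction of $(S, N_R, N_L)$ is the Moore–Penrose
pseudo-inverse of the mixing matrix — in the time domain, a Jeffress
delay-line coincidence detector recovering $\tfrac23 S$. Mammals lack
delay lines, so the package implements the same computation with the real
circuit: medial and lateral superior olive (MSO/LSO) activities are
combined per frequency channel as

$$\hat{IC}(\omega)=\frac{\hat R\,(1-a e^{-i(\psi_l+\psi_c)})+\hat L\,(e^{-i\psi_m}+a e^{-i\psi_c})}{\sqrt{1+a^2}},$$

with $\psi_m = 0.125$, $\psi_l = 0$ cycles fixed at their measured values,
a relative LSO weight $a$ and a commissural (LSO→IC) phase $\psi_c$. A
two-step normative optimization — maximize the firing rate for a source at
each target ITD over $a \in [-10, 10]$, then minimize a weight-parsimony
loss $\int(|a| - \ln|a| + \lambda\,\mathrm{sign}(-a))\,d\mathrm{ITD}$ over
$\psi_c$ — selects $\psi_c \approx 0.3$ cycles in every channel,
independent of the assumed head size. On top of the linear path the
package implements recurrent divisive inhibition across target-ITD neurons
($J = 20$) and first-order SOC firing-rate adaptation.

## Worked example

```r
library(icbinaural)

## optimize the circuit for the human ITD range (~15 s)
tab <- optimize_circuit(optimization_config(itd_max = 0.7e-3))
tab
#> Optimal IC parameter table: 53 channels (200-1500 Hz), 64 target ITDs (0-0.7 ms)
#>   psi_c_opt: mean 0.310 cyc, range [0.31, 0.31]
```

Every channel picks a commissural phase of 0.31 cycles — the model's
headline prediction for the stria of Held delay. With the optimized table,
run a classical binaural unmasking experiment (a 400 Hz tone in diotic
noise, tone either diotic, "S0N0", or sign-inverted at one ear, "SpiN0"):

```r
ptab <- optimize_circuit(optimization_config(
  itd_max = 0.7e-3, bf_channels = seq(100, 1500, 50),
  psi_c_grid = seq(0, 1, 0.02)))                     # pipeline-scale table
taus <- seq(0, 0.7e-3, length.out = 15)
snr <- seq(0, -30, by = -2)
s0  <- exp_bmld(ptab, "0",  snr_db = snr, target_itds = taus,
                duration = 1.5, seed = 7)
spi <- exp_bmld(ptab, "pi", snr_db = snr, target_itds = taus,
                duration = 1.5, seed = 7)
c(S0N0 = s0$threshold_db, SpiN0 = spi$threshold_db)
#>  S0N0 SpiN0
#>   -12   -24
```

The out-of-phase tone is detected 12 dB deeper in the noise — a binaural
masking level difference, which collapses to ~6 dB when the recurrent
inhibition is switched off (`j_inh = 0`). A two-talker scene at ITDs
0.2/0.4 ms (`exp_speech()`) yields winner histograms peaking at the true
source ITDs and windowed-correlation traces that track the optimal
delay-line reconstruction at r > 0.9.

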