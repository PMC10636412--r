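---
title: "Methods: infant frontal alpha asymmetry from interaction EEG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: infant frontal alpha asymmetry from interaction EEG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the model and the numerical decisions behind
`infasym`: what each stage computes, which parameters matter, what the
synthetic generator does and does not emulate, and where the design was
genuinely open and a choice had to be made.

## The measurement model

The paradigm presents four maternal actions of increasing sensory richness,
each 10 s long, separated by 15-s pauses, twice per run over two runs —
four iterations per action, 16 action epochs per infant. The quantity of
interest per action is the frontal asymmetry score

$$\mathrm{FAS} = \frac{F3 - F4}{F3 + F4},$$

where $F3$ and $F4$ are the mean alpha-band (6–9 Hz) Hilbert-envelope
amplitudes over seven-electrode clusters around the left and right frontal
sites, averaged across the aligned iterations of that action. FAS is
bounded in $[-1, 1]$, scale-invariant, antisymmetric, and zero when the
hemispheres carry equal alpha amplitude. Action 1, in which the mother is
present but not engaging, serves as a within-infant baseline and is
subtracted from actions 2–4. The package reports the sign exactly as
defined (positive = left-lateralized alpha envelope); the common
inverse-activity interpretation of alpha power is left to the reader and
never silently applied.

## Preprocessing chain and its parameters

The fixed order is: notch → band-pass → bad-channel detection →
interpolation → average reference → segmentation → amplitude-artifact
elimination. Defaults, all overridable via `default_config()`:

| parameter | default | role |
|---|---|---|
| `notch_hz`, `notch_width` | 60 Hz, 10 Hz | mains suppression (exact null at 60 Hz) |
| `bp_low`, `bp_high`, `bp_order` | 0.3–40 Hz, order 1 | broadband conditioning |
| `alpha_low`, `alpha_high`, `alpha_order` | 6–9 Hz, order 2 | infant alpha band |
| `amp_uv`, `amp_pad_ms`, `max_masked` | 120 μV, 100 ms, 0.5 | artifact sample masking |
| `max_bad` | 35 electrodes | session exclusion ceiling |
| `max_lag_ms` | 2000 ms | alignment search bound |
| `delay_ms`, `window_ms` | 2000 ms, 5000 ms | response window |

**Zero-phase filtering.** All filters are applied zero-phase. Rather than
discretising the Butterworth prototype and running it forward–backward, the
package multiplies the spectrum (after reflection padding) by the *squared
analytic magnitude response* — exactly the gain a forward–backward pass of
the stated filter would have, with no phase distortion and no transient
handling. The practical consequences: the effective roll-off is that of
twice the nominal order, and test oracles can use the closed-form response
$|H(f)|^2 = 1/(1 + (Q(f/f_0 - f_0/f))^{2n})$ directly. Phase linearity
matters here because the Hilbert envelope and the cross-correlation
alignment both assume the band-limited signal has not been phase-shifted.

**"Unusable" channels.** The exclusion rule (> 35 unusable electrodes)
presupposes a definition of unusable that the original description leaves
open. The package operationalises it as *flat* (SD < 0.1 μV) or *extreme*
(|amplitude| > 120 μV in more than 20% of samples), reusing the artifact
threshold as a channel-level screen. Usable-but-bad channels are repaired
by the unweighted mean of their montage neighbours (4-nearest-neighbour
adjacency from the shipped schematic layout); spherical-spline
interpolation would add realism for a true scalp geometry but is
unidentifiable on a schematic montage and is deliberately out of scope.

**Amplitude elimination.** "Eliminating amplitudes > 120 μV" is
implemented as sample masking on the cluster channels with a ±100 ms guard
band; epochs more than half masked become unusable. The scope of the rule
(cluster channels vs all channels) is configurable (`artifact_scope`)
because the original procedure does not state it; cluster scope is the
default since only cluster samples enter FAS.

## Alignment

Mothers vary in when they begin an action after the cue, so the four
iterations of an action are aligned before averaging. The alignment signal
is the alpha-band global field power (population SD across channels per
sample). The first usable iteration is the reference; every other
iteration's lag maximises the normalized cross-correlation with the
reference over integer lags within ±2 s, ties broken toward zero lag.
A positive lag means the iteration's response occurs *later* than the
reference's, and its extraction window is shifted later by the same
amount — the only sign convention under which the recovered lag and the
window shift compose correctly.

Two numerical choices required care:

* **Ripple removal.** The GFP of a narrow-band oscillation ripples at twice
  the alpha frequency. Cross-correlating raw GFP locks onto cycle
  alignment — lags quantised at half-periods (~67 ms) and occasionally off
  by several cycles. A one-alpha-period (133 ms) moving average removes the
  rectification ripple so the correlation tracks the response *profile*;
  in simulation this took jitter recovery from ~56% to >95% of lags within
  ±50 ms of truth. `smooth_ms = 0` restores the raw-GFP behaviour.
* **Masked samples.** Artifact-masked samples (dilated by 300 ms, because
  band-pass ringing and sub-threshold artifact tails extend beyond the
  100-ms guard) are excluded from both the correlation numerator and its
  normalization, rather than imputed. Imputation flattens part of the
  burst and biases the peak when an artifact lands on the response.
  The FFT engine evaluates the same masked statistic via three
  cross-spectra; candidate lags within float tolerance of the peak are
  re-evaluated with exact direct sums so the fast path selects *exactly*
  the lag the brute-force search would.

The window is the fixed [2000, 7000) ms response interval shifted by the
iteration lag, clamped to the epoch when the shift pushes it outside
(clamping is logged). Of the two plausible readings of the original
procedure — a peak-centred window vs a delay-anchored window — the
delay-anchored one is the default because it is the only reading consistent
with both the stated 2000-ms response delay and the no-overlap constraint
between consecutive actions; envelope edges (5% of epoch samples per side)
are trimmed from means to suppress Hilbert edge effects. Window means use
envelope *amplitude*; `fas_power = "squared"` switches to squared envelope
("alpha power" in the strict sense) since the source wording conflates the
two — the bounded ratio behaves almost identically under either.

## The synthetic world

`generate_session()` emulates what the pipeline needs from a real session,
not scalp biophysics:

* **Alpha bursts** are Hann-windowed sinusoids (default 5 s at 7.5 Hz)
  starting 2000 ms plus a jitter draw (SD 300 ms) after each action onset,
  coherent across the 14 cluster channels, with left amplitude
  $A(1 + a)$ and right $A(1 - a)$ for injected asymmetry $a$. The
  modulator is analytic, so envelope ground truth is exact.
* **Noise** is an equal-power white + 1/f mix, default 10 μV SD per channel
  at 1000 Hz.
* **Artifacts** are biphasic 200–400 ms pulses of 150–300 μV on the frontal
  channels (blink-like, guaranteed to engage the 120 μV rule) at 2/min.
* **Bad channels** alternate flat and railed, drawn outside the clusters so
  the injected asymmetry is untouched.
* **Behavioral codes** come from a latent-normal ordered-categorical model:
  latent mean `wecs_effect × (action − 1)` (flat for irritable infants),
  cut at ±0.75 into scores 1/2/3; drowsy iterations (probability 0.02)
  code sensitivity 0; irritable infants have inconsolable iterations and
  ≥ 2 consoling events, so the derived irritability classification is
  consistent by construction.
* **Defaults** state the world the analysis targets: 128 channels at
  1000 Hz; asymmetry progression (−0.15, −0.05, +0.15, +0.25) for
  non-irritable infants (negative-to-positive across actions) and flat
  −0.05 for irritable ones; action-1 asymmetry is a free parameter, not
  assumed zero, because the baseline action's neural state is not
  characterised a priori.

What the generator does *not* emulate — volume conduction, realistic scalp
topographies, non-stationary noise, mother EEG, coder disagreement — bounds
what a green test establishes: recovery results validate the *pipeline
algebra and estimation*, not claims about real infant EEG.

Two properties of the scaled-down test worlds deserve explicit note. First,
`noise_sd` is broadband, so tests at reduced sampling rates scale it to
preserve spectral density (10 μV @ 1000 Hz ≡ 4.47 μV @ 200 Hz); without
this the scaled world has several times the alpha-band noise power of the
stated one. Second, average referencing scales any signal confined to the
14 cluster channels by $(1 - 14/n_\mathrm{channels})$ — it attenuates
frontal artifacts below the 120 μV threshold at very low channel counts and
*amplifies* the FAS contrast by the reciprocal factor. Recovery tests
therefore run at ≥ 64 channels and assert sign and monotonicity of FAS
against ground truth, never magnitude equality.

## Statistics

Trends are pooled observation-level Pearson correlations between action
index and measure (equivalently the standardized slope of the simple
regression), because no repeated-measures structure is described for the
original analyses; the within-infant dependence this ignores is a known
caveat, stated rather than silently corrected. A measure constant across
actions reports $r = 0$, slope 0, with an undefined $p$. Interaction tests
are OLS `value ~ group * action`; the interaction effect size is reported
on an $r$ scale as $\mathrm{sign}(t)\sqrt{t^2/(t^2 + \mathrm{df})}$
(signed √partial R²), chosen to match the $r$-with-$p$ reporting convention
of the field; subgroup analyses are flagged as justified at $p \le 0.05$,
or "nearly significant" up to $p \le 0.10$. Grand-average WECS/FAS
correlations use the four action-level cohort means and are descriptive
($n = 4$); they are invariant under baseline subtraction of FAS because
subtracting a constant is an affine shift. All $p$ values are two-sided;
no multiplicity correction is applied by default (`adjust_bh()` exists for
those who want it). Simulation calibration (in the test suite) shows the
trend test holds its nominal 5% size under the null generator and exceeds
90% power at `wecs_effect = 0.4` with 25 infants; the group interaction is
detected in ≥ 80% of cohorts of 25 + 25.

## Known limitations

* Neighbour-mean interpolation and the schematic montage are adequate for
  the synthetic world but not a substitute for spline interpolation on
  measured electrode positions.
* The alignment reference is the first usable iteration, not an iterated
  template; with ≤ 4 iterations a template gains little, but the choice is
  a simplification.
* EDF output is 16-bit and quantizes to ~0.01 μV for typical scalp ranges;
  HDF5 output is lossless and preferred for round-tripping.
* The pooled trend statistics treat (infant, action) observations as
  exchangeable; a mixed-effects variant is out of scope by design.
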