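---
title: "Modelling and analysing voltage-gated proton currents with hvgate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling and analysing voltage-gated proton currents with hvgate}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hvgate)
```

# The system

Voltage-gated proton channels (HV1) are voltage-sensor domains that conduct
protons themselves. Two quantities organise their biophysics. The reversal
potential `V_rev` of a perfectly proton-selective channel equals the proton
Nernst potential `E_H = (RT ln10 / F) (pH_i - pH_o)`, about 58 mV per pH
unit at 20 °C. The threshold potential `V_thres` — the most negative step at
which channel opening is detectable — tracks the pH gradient linearly:

```
V_thres = slope * V_rev + offset
```

with slope near 0.8 in every channel characterised to date. The sign of the
offset decides physiology: positive offsets (mammalian channels) mean the
channel only opens positive to `V_rev` and extrudes acid; negative offsets
mean it opens below `V_rev` and conducts protons inward. The stick-insect
channel preset shipped as `eth_v1_law()` uses slope 0.77 and offset
-23 mV with 10 mV per e-fold activation kinetics; `nph_v1_law()` carries
the same slope with offset -2.4 mV for comparison.

`hvgate` provides (i) a whole-cell simulator of proton current families,
(ii) the trace- and family-level analysis used on real recordings
(activation fits, tail currents, threshold detection, both reversal
methods, conductance-voltage curves, the threshold-versus-reversal
regression), (iii) thermodynamic references (Nernst, GHK), and (iv) a
sequence-screening module for mining transcriptome assemblies for HV1
homologs. Because every analysis stage can be exercised against simulated
families with known ground truth, the full pipeline is testable end to end
without any external data.

# The gating model

The experimentally observed phenomenology (sigmoidal activation, single-exponential
late phase, pH-shifted gating, slow tails) is reproduced by a
Hodgkin-Huxley scheme: each of `N = 2` identical gates relaxes toward

```
n_inf(V) = 1 / (1 + exp(-(V - V_half)/k)),      p_open = n_inf(V)^N
```

with first-order kinetics. `N = 2` reflects the dimeric architecture of the
channel; the squared gate gives the observed sigmoidal onset while the late
phase of the current rises with the single gate time constant. This is a
modelling choice, not a mechanistic claim: any scheme reproducing the same
two observables would serve.

The activation curve is *positioned* by the threshold law. `V_thres` is
defined as the voltage where `p_open` equals `p_detect` (default 0.01, i.e.
1% of maximal conductance), and `V_half` is derived from it. The whole
curve therefore translates rigidly with `E_H` and with zinc, which is
exactly the behaviour the threshold-versus-reversal strategy measures.

Parameters of `gating_law()`, with defaults and rationale:

| parameter | default | meaning |
|---|---|---|
| `thr_slope`, `thr_offset_mV` | 0.77, -23 | threshold law (channel preset) |
| `steepness_k_mV` | 6 | per-gate Boltzmann slope; 5-8 mV is typical for HV1 conductance-voltage curves |
| `n_subunits` | 2 | dimer |
| `p_detect` | 0.01 | open probability defining a detectable threshold |
| `tau_ref_s` | 2 | activation time constant at threshold (seconds-scale activation) |
| `efold_act_mV` | 10 | e-fold voltage of `tau_act` (channel preset) |
| `tau_deact_ref_s`, `efold_deact_mV` | 0.3, 20 | deactivation anchored at the -80 mV tail potential; "large, relatively slow" tails |
| `zn_Kd_uM`, `zn_shift_mV_per_decade`, `zn_slow_factor_per_decade` | 10, 30, 3 | zinc phenomenology (below) |

Deactivation time constants and the quantitative zinc dose-response are not
reported for this channel; `tau_deact_ref_s` and the three zinc parameters
are free parameters of the generator, chosen so that 0/10/100 µM zinc
produce clearly graded effects and tails decay within a one-second tail
segment. They are flagged as such and nothing downstream asserts their
particular values, only the monotone structure of the zinc model:

```
shift(zn)  = zn_shift_mV_per_decade * log10(1 + zn/Kd)
slowing(zn) = zn_slow_factor_per_decade ^ log10(1 + zn/Kd)
```

which is smooth, zero/one at zinc = 0, and monotone — the properties the
analysis (rightward conductance-voltage shifts, slowed kinetics) relies on.

# The cell and proton depletion

The default cell (`cell_model()`) matches a transfected cell line
population: 9.62 pF, 1.07 nS/pF (so `g_max` ≈ 10 nS), ~1 pL of cytosol,
100 mM monoprotic buffer used at its pKa, 1 pA recording noise, a small
ohmic leak, and pipette-cytosol pH exchange with a 5 s time constant
(whole-cell buffer diffusion takes seconds to minutes).

Proton current moves measurable amounts of acid in a small cell. With
depletion enabled (the default), intracellular pH obeys

```
dpH_i/dt = I_H / (F * volume * beta(pH_i)) + (pH_pipette - pH_i)/tau_exchange
beta(pH) = ln(10) * C_buf * Ka * [H+] / (Ka + [H+])^2
```

so sustained outward current alkalinises the cytosol, drags `V_rev` with
it, and biases late-pulse measurements — the dominant error source in real
whole-cell recordings of these channels. A 100 pA current into 1 pL of
100 mM buffer at its pKa moves pH_i by roughly 0.02 units per second, which
matches the order of magnitude that motivates pulse-length ladders in
practice. Setting `pipette_exchange_tau_s = Inf` seals the cell (used by
the conservation tests); `0` clamps pH_i to the pipette.

Within a constant-voltage segment the gate relaxes analytically
(`n(t) = n_inf + (n0 - n_inf) exp(-t/tau)`), so only the pH feedback is
integrated numerically: forward Euler on the sampling grid with automatic
sub-stepping whenever a step would move pH_i by more than 10^-3. The
integration is deterministic; all noise flows from one integer seed per
trace, derived reproducibly from the family seed. If pH_i ever leaves
(0, 14) the simulator aborts naming the failing segment rather than
returning garbage.

# Analysis conventions and their numerical choices

**Activation fits.** Currents are fitted with
`I(t) = A (1 - exp(-(t - t0)/tau)) + C` by bounded Levenberg-Marquardt
(`minpack.lm`), with initial guesses from the log-linearised late phase.
The sigmoidal onset is excluded by a delay policy. The default excludes
data before the current covers *half* of its plateau excursion: for n²
kinetics the remaining late phase fits a single exponential whose time
constant is within ~12% of the true gate relaxation, whereas cutting only
the first 10% of the rise leaves a ~30% overestimate — an error that would
silently propagate into every kinetics plot. Because the excluded fraction
is the same at every voltage, the *slope* of ln(tau) versus voltage is
unaffected by the residual proportionality. The reported steady-state
current `I_ss` is the fitted asymptote minus the current at the pulse
onset (where the channel is still closed), which removes leak and baseline
exactly; fits whose amplitude is below three noise SDs fail rather than
returning noise.

**Tails and thresholds.** Tail amplitudes are the signed extremum of the
baseline-subtracted current in the first 20% of the tail segment, after a
5-sample running mean — without smoothing, the extremum of ~100 noise
samples would systematically exceed 2.5 noise SDs and fake tails at
sub-threshold steps. A threshold is the most negative step whose tail
exceeds `max(k_sigma * noise_sd, rel_fraction * max_tail)` with all more
positive steps also exceeding it (persistence suppresses single-point
noise). The relative component (default 1% of the family's largest tail)
judges every family at the same effective open probability regardless of
the tail driving force, and equals the simulator's threshold definition
(`p_detect = 0.01`); the absolute component guards low-expression
families. Detected thresholds are grid values, so they carry a half-step
positive quantization bias by construction.

**Reversal potentials.** The zero-current method linearly interpolates
fitted `I_ss` between the bracketing steps. Because the chord current is
strongly curved where the activation curve is still rising, the
interpolation is only read across a narrow bracket: simulated designs place
steps at ±2 and ±6 mV around the nominal `E_H`. When activation opens less
than ~15 mV below `E_H` (or above it) there is no clean crossing and the
tail-current method is used instead: a fixed activating prepulse, varied
repolarization potentials, and interpolation of the early tail amplitude —
which is linear in voltage because the open probability is frozen by the
prepulse. The two methods agree within 2 mV on the same simulated cell with
depletion off.

**Kinetics plots.** `fit_tau_voltage()` regresses ln(tau) on voltage over
the maximal contiguous decreasing run. Two guards matter in practice: runs
tolerate 5% noise upticks (terminating at every uptick would keep only
exaggerated decreases and bias the slope steep), and fits with amplitude
below 10 noise SDs are excluded — a time constant fitted to a 5 pA current
in 1 pA noise is meaningless and, sitting at the foot of the family, tilts
the whole regression.

**Threshold-versus-reversal regression.** Ordinary least squares of
pooled determinations within a hard ±70 mV window on both axes, as the
graphical method implies. Errors-in-variables alternatives exist but the
measured `V_rev` errors (< 1 mV) are negligible against the threshold
quantization, so OLS is adequate; per-cell regression is available by
subsetting the determinations table.

# The simulated determination design

`simulate_determinations()` emulates the published experimental design: 16
determinations over pH_i ∈ {6.5, 7.0} × pH_o ∈ {5.5, 6.0, 6.5, 7.0} pooled
from 9 cells whose capacitance and conductance density are drawn from the
reported population statistics (truncated normals). Two further sources of
variation are modelled because their absence makes the simulation *less*
faithful: a 2 mV SD per-cell offset of the absolute threshold position
(cell-to-cell variability; zero-mean, so the pooled regression still
estimates the population law), and a ±1.25 mV uniform dither of the
absolute placement of the near-threshold step values (the alignment
between an experimenter's chosen step potentials and a cell's true
threshold is arbitrary). Without these, the discrete step grid
phase-locks to the gating law across pH conditions and quantization error
masquerades as a systematic slope bias.

Protocols are pulse-length ladders (`make_protocol_ladder()`): each step
lasts five activation time constants, clamped to 0.25-12 s, so
near-threshold pulses are long enough to reach steady state while strongly
depolarized pulses stay short and limit depletion — the same trade-off
used at the rig. The threshold region is stepped at 2.5 mV and the
reversal region at ±2/±6 mV around `E_H`, with a 10 mV ladder elsewhere.

With this design the full round trip (simulate → fit → detect → regress)
recovers gating-law slopes across [0.5, 1.0] within ±0.05 and offsets
across [-40, +20] mV within ±5 mV, and the recovered quantities for the
default preset are slope ≈ 0.77-0.79, offset ≈ -21 to -23 mV, kinetics
steepness ≈ 9.7 mV per e-fold, and a pH_o 7.0→6.5 conductance-voltage
shift of ≈ 22 mV (the rigid-translation prediction is
`0.77 × 29.1 ≈ 22.4` mV; experimental reports of this shift run a few mV
larger, and the acceptance band 20-27 mV spans both). Typical residual
SD of the regression is 2-4 mV, dominated by threshold quantization.
Remaining small biases are real method artefacts faithfully reproduced:
the half-step threshold quantization (+~1 mV on the offset) and depletion
during activating prepulses (±1 mV on tail-method reversals).

Problem sizes throughout (16 families of ~20 steps at 500 Hz, one
kinetics family at 1 kHz) were chosen so a full pipeline run completes in
well under a minute on a laptop core while keeping every per-trace fit
well conditioned.

# What the generator does and does not emulate

Emulated: sigmoidal voltage- and pH-dependent activation, Nernstian
reversal, slow tails, zinc modulation, recording noise, leak, proton
depletion with buffer capacity and pipette exchange, pulse-ladder
protocols, population variability of expression and threshold.

Not emulated: single-channel stochasticity, series-resistance and
capacitance transients, liquid-junction potentials, temperature dependence
of kinetics, inside-out patch geometry, rundown, and any deviation from
perfect proton selectivity. Passing recovery tests therefore demonstrates
that the *analysis* is correct and unbiased under realistic noise,
depletion and discretisation — not that the n² model is the true gating
mechanism of any real channel, nor that real recordings are free of the
artefacts listed above.

# Sequence screening

The screening rules operate on protein sequences (1-based coordinates
throughout, matching the field's residue numbering):

* **Motif scan** — all, possibly overlapping, windows matching
  `R-x-W-R-x-x-[R/K]`, the S4 voltage-sensor signature. The relaxed
  terminal position is scanned in the same pass and labelled: sequences
  whose only hits end in lysine are flagged as likely fungal contamination
  (the third sensor arginine is typically lysine in fungi), a practical
  filter when mining whole-insect transcriptome assemblies.
* **Selectivity-filter call** — global pairwise alignment (BLOSUM62,
  affine gaps 10/1, via Biostrings) to an annotated reference; the query
  residue in the column aligned to the reference filter position is
  classified Asp/Glu/non-acidic. Alignments scoring below 20% of the
  reference self-score are rejected as unalignable. A gap at the mapped
  column is reported as such, not as an error.
* **Zinc sites** — the residues aligned to the reference's two external
  zinc-binding positions, plus the two preceding the second site, exposing
  His-His-Asp-type arrangements on the S3-S4 linker.
* **ORF translation and in-silico PCR** — longest ATG-to-stop frame on
  either strand (ties: earliest forward start), standard genetic code;
  exact-match primer placement (the primers were designed against the same
  transcript; a ≤1-mismatch mode exists but is off by default), product
  length including both primer footprints, all products reported shortest
  first, and "no amplicon" is a result rather than an error.
* A Kyte-Doolittle hydropathy helper (window 19, threshold 1.6) supports
  descriptive transmembrane-segment counts but never joins the
  pass/fail verdict, which rests on the motif and alignment rules only.

The packaged reference and query sequences are **synthetic**: deterministic
constructions that reproduce the structural geometry the rules key on (a
236-residue channel-like query with Glu at the column aligned to the
reference filter position 112, Lys/Asp zinc sites preceded by His-His, one
terminal-R motif, and a transcript in which the published primer pair
delimits a 363-bp product). They are labelled `synthetic_*` everywhere and
exist so the rule logic is testable offline; they are not the database
entries, and no claim about real sequences rests on them.

# Known limitations

* The simulator's gating ground truth uses the pipette pH, not the
  instantaneous cytosolic pH; depletion feeds back on the driving force
  only. Real channels re-equilibrate their gating as pH_i drifts, which
  would *add* to the depletion error modelled here.
* Chord-conductance curves inherit the `I_ss` sign noise near reversal;
  points within 5 mV of `V_rev` are excluded rather than modelled.
* The zero-current/tail method switch uses the design's knowledge of the
  nominal `E_H`; on imported recordings the caller chooses the method.
* GHK supports monovalent ions only, and activity coefficients are
  ignored (concentrations ≡ activities), as is conventional for these
  solutions.
* The tail-method reversal inherits ~1 mV of depletion bias from the
  activating prepulse; shortening the prepulse trades this against
  incomplete activation.

# A minimal session

```{r example, eval = FALSE}
law <- eth_v1_law()
cond <- solution_conditions(pH_i_pipette = 6.5, pH_o = 5.5)
proto <- make_protocol_ladder(c(-20, 80), law, cond)
fam <- simulate_family(proto, cell_model(), cond, law, seed = 1)
analyze_family(fam)                 # fits, threshold, V_rev, g-V

det <- simulate_determinations(seed = 1)   # the 16-determination design
threshold_reversal_regression(det)         # V_thres = slope * V_rev + offset
```
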