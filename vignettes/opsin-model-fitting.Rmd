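---
title: "Photocycle models and the staged fitting pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Photocycle models and the staged fitting pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(opsinkit)
```

## The models and their assumptions

`opsinkit` describes a light-gated ion channel population as a Markov
chain over photocycle states. Three schemes are provided, trading
biological detail against simplicity:

* **3-state** (`C`, `O`, `D`): one closed, one open, one desensitized
  state. Admits a closed-form solution (`analytic_three_state()`) but
  its off-phase decay is a single exponential.
* **4-state** (`C1`, `O1`, `O2`, `C2`): two coupled open states with
  conductance ratio $\gamma = g_{O2}/g_{O1}$, reproducing biexponential
  deactivation and the peak/plateau (inactivation) structure of ChR2
  photocurrents.
* **6-state**: adds intermediates `I1`, `I2` between the closed and
  open states, traversed at rates $G_{o1}$, $G_{o2}$. Their only
  observable consequence is a sub-millisecond-to-millisecond lag of the
  current peak behind the end of a short light pulse; for pulses of
  hundreds of milliseconds the 4- and 6-state responses are practically
  identical.

Light enters exclusively through saturating Hill-type transition rates,
e.g. $G_{a1}(\phi) = k_1 \phi^p/(\phi^p + \phi_m^p)$, with a shared
half-saturation flux $\phi_m$ and separate exponents $p$ (activation)
and $q$ (O1–O2 interconversion). The membrane voltage affects only the
instantaneous conductance, not the kinetics, through the empirical
inward-rectification factor

$$f_v(v) = \frac{v_1}{v - E}\Bigl(1 - e^{-(v-E)/v_0}\Bigr),$$

normalized to $f_v(-70\,\mathrm{mV}) = 1$ by tying
$v_1 = (70+E)/(e^{(70+E)/v_0} - 1)$. This constraint is active by
default everywhere; `opsin_params(..., constrain_v1 = FALSE)` releases
it. Large $v_0$ recovers the ohmic (non-rectifying) limit
$f_v \to v_1/v_0$. Temperature, pH and wavelength dependencies are out
of scope.

Units are fixed package-wide: ms and ms⁻¹, mV, pS, nA, photons
mm⁻² s⁻¹; the single pS·mV→nA factor $10^{-6}$ lives in the current
equation. State ordering (`C1 I1 O1 O2 I2 C2`, matching the model
definitions) is part of the public contract; exporters and CSV columns
rely on it.

## Parameters that matter

The reference 6-state ChR2 record (`chr2_params(6)`) and the rough
initial-guess record (`initial_params(6)`) used by the fitting examples:

| symbol | unit | reference | role |
|---|---|---|---|
| `g0` | pS | 2.76e4 | conductance scale at −70 mV |
| `gamma` | – | 8.33e-16 | open-state conductance ratio (0 allowed) |
| `phi_m` | ph mm⁻² s⁻¹ | 5.07e17 | half-saturation flux |
| `k1`, `k2` | ms⁻¹ | 18.5, 3.75 | maximal activation coefficients |
| `p`, `q` | – | 0.982, 1.45 | Hill exponents |
| `kf`, `kb`, `Gf0`, `Gb0` | ms⁻¹ | 0.121, 0.133, 0.0365, 0.0146 | O1↔O2 coupling (light/dark) |
| `Go1`, `Go2` | ms⁻¹ | 1.93, 2.65 | 6-state activation rates |
| `Gd1`, `Gd2` | ms⁻¹ | 0.108, 0.0111 | deactivation rates |
| `Gr0` | ms⁻¹ | 0.00033 | dark recovery (τ ≈ 3 s) |
| `E`, `v0`, `v1` | mV | 0, 43, 17.1 | rectification |

The 4-state companion record shares these values without `Go1`/`Go2`
(the 4-state scheme is their fast-activation limit); the 3-state record
is a self-generated approximation with a single open state and is
labelled as such in its documentation.

## Characterization protocols and the synthetic-data generator

`make_protocol()` ships the standard characterization set, each
overridable:

* **step** — 500 ms pulse to steady state, fluxes spanning orders of
  magnitude (defaults 0.1–100 mW mm⁻², converted to photon flux at
  470 nm via $E_{ph} = hc/\lambda$; the conversion wavelength is a
  documented, overridable choice because the literature quotes both
  unit systems).
* **rectifier** — one flux, clamp voltages {−100…80} mV in 30 mV steps.
* **recovery** — two 250 ms pulses separated by inter-pulse intervals
  {0.5, 1, 2.5, 5, 10} s at −70 mV.
* **shortPulse** — pulses of {0.5, 1, 2, 3, 5, 8, 10} ms at a
  *sub-saturating* flux (1.5e15 ph mm⁻² s⁻¹). The flux choice matters:
  the peak-lag analysis presumes the response is still rising when the
  light switches off. At saturating flux the transient peak moves
  inside the pulse for widths beyond a few milliseconds and the
  protocol no longer isolates the activation rates.
* **delta**, **ramp**, **sinusoid**, **chirp** — systems-analysis
  stimuli; the modulated waveforms use offset forms so the flux is
  non-negative everywhere, and their frequency defaults are arbitrary
  documented choices.

`generate_protocol_data()` runs the forward model through a protocol
and optionally adds i.i.d. Gaussian current noise (seed mandatory when
noise is on; noiseless output is bit-identical to `run_protocol()`).
`verification_dataset()` bundles the four characterization protocols
with the step fluxes log-spaced over 2.21e15–2.65e17 ph mm⁻² s⁻¹ — the
conditions of the parameter-recovery verification. The generator
emulates idealized voltage-clamp recordings: rectangular pulses, exact
annotations, no drift, capacitive transients, filtering or cell-to-cell
variability. Passing the recovery tests therefore demonstrates
correctness of the algorithms, not robustness to every artifact of real
recordings; the additive-noise path provides a first robustness probe
only.

## Numerical design

**Integration.** Within a constant-flux segment the state equations are
linear and time-invariant, so the engine propagates them by the exact
eigenmode solution of the rate matrix and restarts at every pulse edge
(discontinuities never sit inside a solver step). Time-varying segments
and the `method = "lsoda"` path use the adaptive stiff solver with
`rtol = 1e-8`, `atol = 1e-10`; the two routes agree to better than
1e-6 in every state, which is also how the closed-form 3-state solution
is validated. A defective eigenbasis (a measure-zero degeneracy)
triggers an automatic lsoda fallback.

**Removable singularity.** $f_v$ is evaluated by a second-order series
for $|v - E| < 10^{-3}|v_0|$ to avoid catastrophic cancellation near
the reversal potential; the two branches agree to 1e-9 at the switch.

**Plateau detection.** The steady-state current is the mean of the
final 10% of an on-phase, accepted only if a straight-line fit over
that window has |slope| below 1% of |mean| per 100 ms; shorter or
still-ramping on-phases are flagged `not at plateau`. Both constants
live in `plateau_config()`. Peak search uses |I| so the same code
serves depolarizing and hyperpolarizing opsins; no smoothing is applied
by default.

## The staged fitting pipeline

`fit_models()` proceeds through stages, skipping any whose protocol is
missing (the flux-dependence step set is the required minimum; with a
single flux the flux-dependence parameters $\phi_m$, $p$, $q$ are fixed
at their initial values):

1. **Rectifier:** the reversal potential is bracketed by the zero
   crossing of the steady-state I–V relation; linear interpolation
   seeds a least-squares fit of $I_{ss}(V) = c\,f_v(V)(V-E)$ with $v_1$
   tied to the normalization constraint and near-reversal voltages
   down-weighted. $E$ is released in this fit because pure linear
   interpolation between 30 mV-spaced samples of a curved I–V relation
   is biased by ~2 mV, while the joint fit recovers $E$ and $v_0$
   essentially exactly on clean data.
2. **Conductance:** $g_0 = I_p / (f_{open} f_v(v)(v-E)10^{-6})$ at the
   maximal flux. Before the kinetics are known, $f_{open}$ is the
   conservative constant 0.8 (typical maximal open-state occupancy of
   wild-type ChR2); after the on-curve stage it is recomputed from a
   forward simulation — the conductance correction.
3. **Recovery:** second-pulse peaks, aligned to the first pulse's
   offset, are fit with $I_{peak}(t) = I_{peak0} - a e^{-G_{r0} t}$
   (amplitude free; IPIs below 100 ms excluded since fast transitions
   distort the single-exponential form).
4. **Off-curves:** each off-phase is fit with a biexponential
   (variable-projection amplitudes, fixed log-spaced multi-start, ties
   broken by residual then by the faster rate). For the 3-state model
   the two rates collapse to one `Gd` by the amplitude-weighted mean
   across trials. For 4-/6-state models the fitted rates are the
   eigenvalues of the dark O1/O2 subsystem; with per-trial amplitudes
   free, the four dark rates are under-determined from eigenvalues
   alone, so `Gf0`/`Gb0` are held at their current estimates, `Gd1`/
   `Gd2` are solved from the trace/determinant relations, and the
   refinement stage finishes the job.
5. **Activation (6-state):** the observed mean peak lag of the ≤3 ms
   pulses is matched by 1-D root finding over $G_{o1}$ (with
   $G_{o2} = G_{o1}$ initially); peak times are refined by parabolic
   interpolation so the lag is not quantized to the sampling grid.
6. **On-curves:** all remaining light-dependence parameters (including
   $G_{o1,2}$ when short-pulse data exist) are optimized jointly over
   every on-phase with Powell's conjugate-direction method, each
   trial's residual normalized by its steady-state magnitude so
   high-flux trials do not dominate.
7. **Refinement (optional, default on):** a second joint optimization
   over the full traces (on- and off-phases of the step and short-pulse
   sets) with the dark and activation parameters bounded to 50–200% of
   their stage values. The result is a guarded descent: if the joint
   optimization ends worse than its start, the stage-1 values are kept.

Three optimization details deserve emphasis, as they decide whether the
pipeline converges:

* **Reference-rate coordinates.** At sub-saturating fluxes only the
  product $k \cdot \mathrm{Hill}(\phi)$ is observable, making each
  maximal coefficient $k$ nearly degenerate with $\phi_m$ — a long
  shallow valley in which direction-set and Levenberg–Marquardt
  optimizers alike stall with large correlated errors. The optimizer
  therefore works with the rate attained at the geometric-mean data
  flux instead of $k$ itself (exactly invertible afterwards), which
  aligns the sloppy direction with the $\phi_m$ coordinate.
* **Powell restarts.** Line searches use Brent's method on the
  box-feasible interval in log-scaled unit coordinates; whenever a
  Powell cycle converges, the direction set is re-seeded with the
  identity and the search continues until restarts stop paying.
* **Residual grid.** Long traces are thinned to a ~400-point backbone
  per trial (the global minimum of a noiseless exact-model fit does not
  depend on sampling density) but keep full resolution for 5 ms after
  every pulse edge: the fast transients there identify the activation
  kinetics, and a uniformly sparse grid admits spurious solutions that
  fit the samples yet miss the onset shape between them.

Everything in the pipeline is deterministic — optimizer, multi-starts
and tie-breaks are fixed — so identical data and configuration give
identical results; no seed is involved in fitting.

## Interpretation choices on under-specified points

* The fitting algorithm's symbol list for the on-curve stage includes a
  recovery coefficient never defined among the model equations; it is
  interpreted as the 3-state light-driven recovery coefficient `kr`
  (the Hill coefficient of $G_r(\phi)$).
* The off-curve-to-parameter mapping and the activation-rate iteration
  are documented package constructions (eigenvalue identification and
  lag matching, respectively); their acceptance surface is parameter
  recovery on synthetic data, not formula identity with any particular
  published appendix.
* $G_{o2}$ is structurally weakly constrained by single-pulse
  protocols: from the dark-adapted ground state the `C2`→`I2`→`O2` path
  carries almost no flux, so its traversal rate barely shapes the
  observable current. The verification run reports it with a
  correspondingly wide error, which is expected rather than a defect;
  all other kinetic parameters recover to well within a few percent.

## Problem sizes and runtime

The shipped configuration simulates the verification data set (6 step
fluxes, 7 rectifier voltages, 5 recovery IPIs, 7 short-pulse durations;
output steps 0.05–0.1 ms) in about a second and completes the full
staged fit in a few minutes on one core, with the Powell sweep budgets
of `fit_config()` (60 on-curve, 160 refinement sweeps). These budgets
are package defaults chosen to converge well past the verification
tolerances; raising them changes the runtime, not the result.

## Known limitations

* Single-wavelength, fixed-temperature, fixed-pH modelling only.
* `g0` estimation relies on the simulated maximal open-state occupancy;
  for opsins far from the ChR2 regime the 0.8 fallback used before the
  kinetic stages is crude (the post-fit correction supersedes it).
* The exporters emit structurally standard NMODL and equation text, but
  byte compatibility with any particular published mechanism file is
  not a goal; validation is structural.
* Real-recording artifacts (drift, capacitive transients, filtering,
  liquid-junction offsets) are neither emulated nor corrected for.
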