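---
title: "Methods: estimating isotopic contamination in paired labelling chambers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: estimating isotopic contamination in paired labelling chambers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isocontam)
```

## The model

A chamber operated as an open gas-exchange cuvette receives CO₂ at
concentration $C_\mathrm{in}$ and isotopic composition
$\delta^{13}C_\mathrm{in}$, and the stand inside draws it down to
$C_\mathrm{out}$. Photosynthetic discrimination $\Delta^{13}C$ enriches the
remaining chamber air in ¹³C. How strongly depends on
$\xi = C_\mathrm{in}/(C_\mathrm{in}-C_\mathrm{out})$, the ratio of CO₂
supply to net uptake: solving the Evans open-system relation for the outlet
gives the *uncontaminated* outlet composition

$$\delta^{13}C_\mathrm{outlet\,pure} =
  \frac{\Delta + \xi\,\delta_\mathrm{in}\,\Delta/1000 + \xi\,\delta_\mathrm{in}}
       {(\Delta/1000)(\xi-1) + \xi},$$

implemented in `delta_outlet_pure()`. A flux-weighted isotope mass balance
over the chamber then yields the composition of the carbon actually removed
by the stand, the contamination-free reference

$$\delta^{13}C_\mathrm{Ref} =
  \frac{\delta_\mathrm{in} F_\mathrm{in} - \delta_\mathrm{outlet\,pure} F_\mathrm{out}}
       {F_\mathrm{in} - F_\mathrm{out}},$$

(`delta_ref()`). With fluxes consistent with $\xi$ this is algebraically the
Farquhar relation applied to chamber air,
$(\delta_\mathrm{outlet\,pure} - \Delta)/(1 + \Delta/1000)$; the test suite
enforces the identity to below $10^{-9}$ ‰ over $\Delta \in [0, 40]$ ‰,
$\xi \in [2, 100]$, $\delta_\mathrm{in} \in [-50, 0]$ ‰.

Two chambers run in parallel, identical except for their CO₂ source
(defaults −5.6 ‰ and −43.5 ‰). The contamination fraction of sample kind $X$
is

$$f_\mathrm{contam} = 1 - \frac{d\delta^{13}C_X}{d\delta^{13}C_\mathrm{Ref}},$$

with $d$ denoting the enriched-minus-depleted difference
(`contamination_fraction()`). The statistic rests on three assumptions:

* **Shared contaminant.** The contaminating source has the same δ¹³C and
  contributes the same carbon fraction in both chambers (they are operated
  simultaneously, in the same room, with identical protocols). This is what
  makes the contaminant term cancel from the difference.
* **Steady state.** The reference chain uses steady-state light-phase
  records; transients after disturbances are removed by QC, not modelled.
* **Known discrimination.** $\Delta^{13}C$ must be assumed (default 21 ‰,
  typical of unstressed C₃ grass); `sensitivity_sweep()` quantifies the
  consequences of that assumption.

Two useful properties follow directly from the difference form, and are
tested: a calibration offset common to both chambers cancels exactly, and
the estimate is invariant to which chamber is labelled "enriched" (the
pairing layer orients chambers by their source δ¹³C, never by input order).

## Parameters that matter

| Parameter | Unit | Default | Why |
|---|---|---|---|
| `disc` (Δ¹³C assumption) | ‰ | 21 | unstressed C₃ grass canopy; the single largest systematic lever, see sensitivity below |
| `target_co2` | µmol mol⁻¹ | 400 (200/800 for treatments) | glacial / ambient / end-of-century levels |
| `drawdown_fraction` | — | 0.125 | facility operating point below its 14 % cap; gives ξ = 8 |
| `flow_slpm` | SLPM | 500 | mid-range of the 250–750 SLPM supply |
| `volume_l`, `ground_area_m2` | L, m² | 3000, 1.5 | chamber geometry; sets the washout constant τ = V/flow |
| `window_min`, `recovery_min` | min | 45 | exclusion windows after lights-on and door openings |
| `iqr_k` | — | 1.5 | outlier fence multiplier |
| `noise_delta_gas` | ‰ | 0.2 | long-term gas-measurement precision |
| `noise_delta_sample` | ‰ | 0.4 | whole-system per-sample SD (chamber operation + processing) |

SLPM is referenced to 0 °C / 101.325 kPa (molar volume 22.414 L mol⁻¹).
Vendors differ here; the molar volume is an argument throughout. The choice
cancels from $f_\mathrm{contam}$ (a ratio of δ-differences) but not from
absolute exchange rates.

## The sensitivity sweep

`sensitivity_sweep()` holds the measured $d\delta^{13}C_X$ fixed and
recomputes the whole reference chain over a grid of assumed $\Delta^{13}C$.
The curve decreases strictly with $\Delta$, and crosses zero where the
reference difference equals the measured one. In the small-drawdown limit
($\xi \to \infty$) it has the closed form
$f(\Delta) = 1 - d\delta^{13}C_X (1+\Delta/1000)/(\delta_E - \delta_D)$,
which the implementation matches to $10^{-9}$ at $\xi = 10^9$. Two numerical
notes: `chamber_reference()` evaluates the Farquhar-equivalent form rather
than the literal flux difference $\xi\delta_\mathrm{in} - (\xi-1)
\delta_\mathrm{outlet\,pure}$, because the latter cancels catastrophically
at large $\xi$ (rounding error grows as $\sim 10^{-16}\,\xi\,|\delta|$)
while the two are algebraically identical; and the finite-$\xi$ deviation
from the closed form scales as $(\Delta/1000)/\xi$, so "large ξ" means
$\gtrsim 10^8$ for nine-digit agreement.

## Error propagation

The difference of two independent measurements of equal SD $s$ has SD
$s\sqrt{2}$ (`whole_system_sd()`). A contamination $f$ produces a
δ-difference signal $f \cdot d\delta^{13}C_\mathrm{Ref}$
(`signal_for_fraction()`), so the CV of a single-pair estimate is
$100\,\sqrt{2}\,s / (f\,d\delta^{13}C_\mathrm{Ref})$. At $s = 0.4$ ‰ and
$f = 3\,\%$ this is ≈ 52 %. `contamination_cv()` accepts either the rounded
two-decimal inputs (0.57, 1.1) or full-precision values; both paths are
exercised in the tests. The acceptance suite validates the propagation by
Monte Carlo: across 200 simulated experiments with 0.4 ‰ sample noise, the
empirical SD of $\hat f$ matches $\sqrt{2}\cdot 0.4 /
d\delta^{13}C_\mathrm{Ref}$ within 15 %.

## QC conventions

Three rules, all configurable (`qc_flags()`):

* records in the half-open window [lights-on, lights-on + 45 min) — chamber
  air re-equilibrates after the dark–light transition;
* records within [door opening, opening + 45 min) per chamber, overlapping
  windows merged. The daytime recovery length is not independently
  specified anywhere, so 45 min is adopted by symmetry with the photoperiod
  rule; it also matches the washout arithmetic, since a pulse decays to
  $e^{-45/12} \approx 2.4\,\%$ of its initial size within 45 min even at the
  slowest flow (τ = 12 min);
* values strictly outside centre ± 1.5 × IQR, quartiles by linear
  interpolation (R type 7), computed per chamber × day × location series on
  records passing the first two rules. The rule is applied to both the CO₂
  and the δ¹³C series (either flag excludes the record), because both
  reported time series are screened this way.

The centre is the series **mean** by default, with a median-centred variant
available. The two differ in a degenerate case worth documenting: when the
IQR is exactly zero (a majority-constant series), the median equals the
majority value and deviations from it are genuine outliers, whereas the mean
is displaced by the outlier itself and the mean-centred rule would flag
every value. The implementation therefore flags nothing in the
zero-IQR case under the mean convention and flags values differing from the
median under the median convention. Whether the rule targets δ¹³C, CO₂ or a
derived series in any given pipeline is a configuration choice
(`iqr_on`), since `flag_iqr_outliers()` is a generic series filter.

The filter chain is idempotent and order-insensitive, and raising `iqr_k`
never flags more points — all property-tested.

## The virtual experiment

`run_virtual_experiment()` emulates the facility forward: steady-state
light-phase records (outlet = inlet × (1 − drawdown); outlet δ from the
Evans relation at the true Δ), dark-phase records where respiration of
substrate formed from chamber air adds CO₂ to the stream, discrete
door-opening bouts that instantaneously replace a fraction of chamber CO₂
with extraneous CO₂ followed by exponential washout (τ = V/flow), Gaussian
measurement noise, and a sample table whose δ¹³C is the
contamination-weighted mixture of source-derived and contaminant-derived
tissue. Both chambers receive identical contamination — the design's
defining assumption is built into the generator, so the estimator's exact
inverse relationship to it (noise-free recovery to < 10⁻⁹) validates the
algebra, not the assumption.

Defaults encode the facility's stated conditions: 16 h light / 8 h dark,
~30-min measurement cycles, drawdown ≤ 14 %, 0.2 ‰ gas noise, source δ¹³C
−5.6 / −43.5 ‰. Where no value is stated, realistic choices were fixed
once: two daytime access bouts (mid-light and end-of-light, three door
openings each — entering, sampling, leaving); 10 % of chamber CO₂ exchanged
per bout; stand respiration 4 µmol m⁻² s⁻¹; per-kind sample masses typical
of ryegrass stands. The extraneous CO₂ defaults to the fifty-fifty mixture
of the two sources plus the ~3 ‰ photosynthetic chamber enrichment,
0.5(−43.5) + 0.5(−5.6) + 3 = −21.55 ‰, evaluated from the formula (the
printed value accompanying that formula elsewhere, 27.6 ‰, does not follow
from it and is not used). Contamination enters samples as a per-kind
fraction directly rather than through pool-turnover kinetics, which the
underlying data cannot constrain.

What the simulator does **not** emulate: within-day photosynthetic dynamics
(light response, stomatal behaviour), plant growth over the labelling
period, spatial gradients inside the chamber (well-mixed assumption),
drifting source δ¹³C between gas cylinders, and contamination that differs
between the paired chambers. Passing end-to-end tests therefore demonstrate
that the estimator inverts the stated model exactly and degrades as error
propagation predicts — not that real facility data satisfy the model.

## Pipeline conventions

* ξ, the pure outlet δ and δ¹³C_Ref are computed **per paired measurement**
  and aggregated afterwards (per-chamber mean); period-level aggregation
  before the nonlinear steps would bias the reference slightly whenever ξ
  varies.
* Inlet and outlet rows are paired by nearest timestamp within 3 min,
  matching the facility's sampling alternation.
* The default reference mode is **global**: one
  $d\delta^{13}C_\mathrm{Ref}$ — the mean over CO₂-level-specific values —
  used for all kinds and treatments, mirroring the constant-Δ convention;
  `reference_mode = "per-treatment"` keeps each CO₂ level's own reference,
  which is what a Δ-corrected reanalysis needs.
* Respired δ¹³C is computed per dark-phase pair, averaged per night, and
  differenced across chambers night by night.
* The pooled WSC δ¹³C for the WSC-free biomass balance is the
  carbon-weighted mean of the component fractions
  (`pooled_wsc_delta()`); a measured bulk-extract δ¹³C can be supplied
  instead by passing it directly to `wsc_free_biomass_delta()`. Both routes
  exist because purified-fraction and bulk-extract workflows are both
  common.
* The WSC-free biomass balance is an extrapolation and may legitimately
  leave the range of its inputs; the tests assert this deliberately rather
  than "fixing" it.
* Isotope mixing is linear in δ throughout, as the mass-balance equations
  are written; an exact ratio-based mode (`mix_delta(..., method =
  "exact")`) exists and differs by < 0.01 ‰ at natural-abundance values
  (property-tested), so the approximation is immaterial here.

## Degenerate inputs and tolerances

δ ≤ −1000 ‰ is rejected everywhere (zero ¹³C); Δ outside 0–40 ‰ warns but
proceeds. $C_\mathrm{in} = C_\mathrm{out}$ and $F_\mathrm{in} =
F_\mathrm{out}$ are degenerate-exchange errors (ξ and the mass balances are
undefined); phase-inconsistent flux ordering warns. Dark-phase ξ is
returned negative rather than rejected — callers select phase from the
photoperiod schedule. Round-trip identities are tested at 10⁻¹⁰–10⁻¹² ‰;
the cross-module reference identity at 10⁻⁹ ‰.

## Problem sizes

The test suite simulates 1–5 day experiments (32 light + 16 dark records
per chamber-day), a 10⁴-point grid for the reference identity, 200-run
Monte Carlo for the error-propagation check, and 15 noise-free
level × fraction recovery combinations; the whole suite runs in well under
two minutes on one core.

## Known limitations

* The reference chain inherits any bias in the assumed Δ¹³C; the sweep
  quantifies but cannot remove it. Treatment-dependent discrimination
  (e.g. Δ rising with CO₂ level) needs `reference_mode = "per-treatment"`
  plus per-level `disc` values.
* Respiration estimates amplify gas-measurement noise by
  $F_\mathrm{out}/(R_n A)$ — over an order of magnitude at typical flows —
  and are accordingly the least precise kind.
* The statistic cannot attribute contamination to a source; it quantifies
  the total.
* Inference (ANOVA, mixed models) on the estimates is out of scope; the
  summaries are descriptive.
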