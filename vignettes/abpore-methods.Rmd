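---
title: "Models and methods behind abpore"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind abpore}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(abpore)
```

This vignette explains the models the package implements, the choices made
where the underlying methodology left room, and what the validation on
synthetic data does and does not demonstrate.

## 1. Pore-formation kinetics

### The two estimators

A Quin-2 vesicle assay reports Ca²⁺ influx as a fluorescence rise after
peptide addition at `t_add`, normalized so that the maximum induced by a
Ca²⁺ ionophore equals 1 (`normalize_trace()`; the pre-addition mean is
subtracted first so the relative plateau is well defined when the baseline
is not zero). Two models are fitted independently, and deliberately kept
independent:

1. **Single exponential**, `F(t) = F_eq (1 − e^{−k_exp (t − t_add)})`
   (`fit_single_exponential()`, Levenberg–Marquardt via minpack.lm).
   Yields `F_rel = F_eq` on the normalized scale and the observed rate
   `k_exp` (s⁻¹).
2. **Second-order association**: pore formation treated as a second-order
   process in the membrane-bound peptide, linearized as
   `y(t) = F_eq/([P_b](F_eq − F_t)) = 1/[P_b] + k_a t`
   (`linearize_second_order()` + `fit_ka()`). The slope is `k_a`
   (M⁻¹s⁻¹); the fitted intercept divided by `1/[P_b]`
   (`intercept_ratio`) and a quadratic curvature coefficient serve as
   model-consistency diagnostics — single-exponential data produce a
   convex plot (`y ∝ e^{k t}`), which is flagged rather than silently
   fitted.

`[P_b]`, the molar concentration of membrane-bound peptide particles, is a
required external input per condition (measured independently, e.g. by
microelectrophoresis); the package makes no attempt to re-derive binding
isotherms.

The affinity constant is the exact ratio `K_p = k_a/k_exp`
(`affinity_constant()`), and the mean oligomer count per pore follows from
an association model: the default is **isodesmic stepwise association**
(equal affinity at every step), whose mean aggregate size is
`n = (1 + √(1 + 4 K_p [P_b]))/2`. The true closed form used in the
original analysis is not available to us, so this default is an explicit,
replaceable assumption (`register_n_model()`); `n` values derived with it
should be compared across conditions, not taken as absolute.

### Numerical choices for the noisy linearization

The transform `1/(F_eq − F_t)` is singular at saturation. Two rules keep
it usable:

* a hard floor (default `floor_frac = 0.01`): points with
  `F_eq − F_t < 0.01·F_eq` are dropped and reported. If fewer than five
  usable points remain the call errors — that indicates a wrong `F_eq`,
  not a fittable trace.
* for noisy traces, dropping points by their *observed* distance from
  `F_eq` preferentially keeps points whose noise inflated that distance,
  which biases the slope low (we measured up to −95% at high saturation
  with plain OLS on σ = 0.01 traces). `fit_pore_kinetics()` therefore
  restricts the fit to the time window where the *modelled* signal stays
  below `sat_frac·F_eq` (default 0.9), determined self-consistently: a
  preliminary rate from the half-rise time fixes the window, the weighted
  fit updates the rate, and the loop runs a few iterations (default 4).
  Weights are the fourth power of the model-predicted distance from
  saturation — the inverse variance of the transformed ordinate under
  additive noise — evaluated from the current rate so they are independent
  of the noise realization. On the validation grid
  (`k_a ∈ {10⁴, 10⁵, 2.5×10⁵}` M⁻¹s⁻¹, `[P_b] ∈ {0.5, 2, 5}` µM,
  σ = 0.01, 200 seeds) this estimator is exact to machine precision on
  noise-free traces and biased by at most ~1.6%.

`fit_ka()` itself defaults to ordinary least squares (with optional
user-supplied weights), matching how the linear plots are conventionally
read.

`F_eq` deserves care: for second-order data the exponential model is
misspecified, so its fitted plateau is a biased estimate of the
equilibrium level on traces that have not plateaued. Recovery tests and
the acceptance grid therefore pass the known `f_eq` explicitly; on real
data the measured plateau should be preferred when available.

## 2. Polarized ATR-FTIR

### Band decomposition

`fit_bands()` fits a spectral region with pseudo-Voigt components
(Gaussian by default, mixing fraction configurable) by Levenberg–Marquardt
with box bounds. Centers and widths are **shared between the two
polarizations** while amplitudes are free — without shared shapes the
per-component dichroic ratio `R = a_∥/a_⊥` would be ill-defined. The
default amide I assignment windows are turns 1670–1700, α-helix
1654–1660, irregular 1642–1644, β-sheet 1628–1630 and side chains
1600–1620 cm⁻¹. A linear baseline anchored at the region endpoints is
subtracted by default (`baseline = "none"` disables it); fit the widest
region your data allow, since anchoring a baseline where band wings are
still appreciable biases areas by several percent. Amplitude starting
values come from a linear least-squares solve at the starting shapes
(amplitudes are conditionally linear), which in our testing is what makes
the five-component fit land in the right basin. Components whose width
hits a bound are flagged.

`structure_fractions()` divides conformational areas by their total,
excluding side-chain bands. For oriented films the polarizations weight
orientations differently, so a combination must be chosen: the default
`area_∥ + 2·area_⊥` is the pseudo-isotropic invariant for uniaxial
symmetry; pure-∥ and pure-⊥ modes are available since measured fractions
are sometimes reported from a single polarization.

### From dichroic ratios to order parameters

For a uniaxial distribution on a thick film, the dichroic ratio of a band
whose transition dipoles have order parameter `S_d` relative to the
membrane normal is

`R = [E_x²(1 − C)/2 + E_z² C] / [E_y²(1 − C)/2]`, `C = (2 S_d + 1)/3`,

with interface field amplitudes `E = (1.398, 1.516, 0.629)` by default —
the thick-film values for a germanium element at 45° incidence, fully
configurable. Inverting for `C` is exact, so
`order_parameter_from_r()` ∘ `r_from_order_parameter()` is an identity.
The molecular-axis order parameter is `S = S_d / S(α)` with
`S(x) = (3cos²x − 1)/2` and `α` the dipole-to-axis angle; `α` at the
magic angle (54.7°) is rejected, and `S` outside `[−0.5, 1]` is flagged
rather than clipped. Isotropy corresponds to `R = (E_x² + E_z²)/E_y²`
≈ 1.022 with the default fields.

`lipid_order()` applies this with `α = 90°` to the total CH₂ stretching
area (antisymmetric ≈ 2922, symmetric ≈ 2852 cm⁻¹) and also reports the
antisymmetric peak position, an independent fluidity marker.

### Strand tilt in a tilted barrel

For β-strands at angle `β` from the axis of a barrel itself tilted by `γ`
from the membrane normal, the package uses the nested uniaxial
factorization

`S_dipole = S(γ) · S(β) · S(θ_d)`,

with `θ_d = 90°` for the amide I dipole relative to the strand axis
(configurable). Given a measured `R_β`, `strand_tilt()` solves for `β` on
a grid of `γ` and flags tilts for which the required strand factor leaves
`[−0.5, 1]` (no real solution). This factorization is deliberately
isolated in one function: it is the package's stand-in for the full
barrel-orientation formalism, exact for azimuthally symmetric
distributions at each nesting level but blind to the correlated azimuths
of a real barrel wall.

**Known limitation.** With the default fields, `R_β = 0.89` gives
`β(γ=0) = 27.0°` — at the top of the experimentally reported 20–27°
band — but remains solvable up to `γ ≈ 27°`. The original analysis
reports that tilts above 10° are incompatible with `R_β = 0.89`; our
stand-in does not reproduce that cutoff, and the tests assert the
stand-in's own closed-form boundary instead. A stricter orientation model
(or the original's exact relation, if available) can be swapped in at this
single point.

## 3. CD difference spectra

With a bound fraction `f_bound`, a spectrum measured in the presence of
vesicles is a population mixture. `bound_difference_spectrum()` computes
`(measured − (1 − f_bound)·free) / f_bound`; the division restores the
per-residue scale so bound spectra are comparable across conditions — it
is on by default but switchable, since plain subtraction is also common.
Grids are intersected by linear interpolation; no extrapolation. The
module is unit-agnostic (mdeg vs mean-residue ellipticity) and records the
unit label. `find_minima()` smooths lightly (3 nm default) and reports
prominence-filtered local minima, deepest first — enough to locate the
diagnostic 208/216/222 nm features without committing to a basis-set
deconvolution.

## 4. Barrel geometry

All geometry is closed-form: `R = d/(2 sin(π/z) cos β)` (ideal cylinder
through the backbone; the strand tilt enters only through `1/cos β`),
`h_b = m·a·cos β`, `V = πR²h_b`, with `d = 4.72` Å and `a = 3.48` Å as
standard β-barrel lattice constants. Side chains alternate faces along a
strand, giving exactly two inward topologies for the 11-mer
(`assign_topology()`); packing feasibility compares the barrel volume with
`z` times the summed van der Waals volumes of the inward residues (Gly 48,
Ala 67, Ser 73, Asn 96, Ile/Leu/Met 124, Lys 135 ų). Leftover volume is
expressed as an equivalent coaxial channel radius `√(V_free/(π h_b))` — an
idealization, since free volume need not form a connected passage.

For the supramolecular pore, `ring_pore_radius()` places `n` barrels of
outer radius `R_out = R + lining` (default lining 2 Å for a side-chain
layer) tangent in a ring: centers at `ρ = R_out/sin(π/n)`, raw central
hole `ρ − R_out` (for a hexagon this equals `R_out` exactly). Because the
side chains facing the central cavity do not form a continuous 2 Å shell,
the effective pore radius subtracts a configurable central lining
defaulting to half the interbarrel value; with the 6-stranded barrel
(`R₆ = 5.09` Å) this yields 6.1 Å, inside the expected 6–7 Å band. Both
conventions are reported.

## 5. Synthetic data and what the tests show

The generators produce the study's data shapes with known ground truth:
traces with a flat baseline, addition at 248 s, 1 s sampling over 1500 s
and a saturating rise to `F_eq < 1` under either kinetic law
(`simulate_trace()`); amide I and CH₂ ∥/⊥ pairs built from pseudo-Voigt
components whose polarized areas satisfy `a_∥/a_⊥ = R` exactly before
noise, with the pseudo-isotropic total fixed by the component area
(`simulate_polarized_pair()`; the default amide scenario has a sheet
fraction of 0.40 and sheet `R = 0.89`, the experimental scale); and CD
mixtures `f_bound·B + (1 − f_bound)·F` (`simulate_cd_mixture()`). Noise
is additive i.i.d. Gaussian — σ = 0.01 on the normalized fluorescence
scale and 0.5% of peak absorbance are the levels used throughout testing —
and every generator is a deterministic function of its seed.

Validation problem sizes: 200 seeds per condition for the kinetics grid,
500 seeds for exponential-fit bias, 10–25 seeds for spectral round-trips.

Passing these tests demonstrates estimator correctness under the stated
noise model: unbiased recovery, exact identities, correct flagging. It
does **not** demonstrate robustness to what real spectra add — correlated
baselines, water-vapour lines, band-shape deviations from pseudo-Voigt,
heteroscedastic detector noise, vesicle light-scattering drifts — nor does
it validate the isodesmic `n` model or the strand-tilt stand-in against
independent structural measurements. Those are modelling assumptions,
documented above, with single points of replacement in the code.
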