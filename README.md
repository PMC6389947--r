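# abpore

Quantitative analysis of membrane pore formation by the amyloid-β(25–35)
peptide (GSNKGAIIGLM, residues 25–35 of Aβ). The 11-mer fragment
permeabilizes lipid vesicles to Ca²⁺; this package implements the full
analysis chain used to characterize those pores from three kinds of
measurements, plus the closed-form β-barrel geometry of the proposed pore
structure:

* **Dye-influx kinetics** — Quin-2 fluorescence traces from
  Ca²⁺-loaded vesicle assays are fitted two ways: a single exponential
  `F(t) = F_eq (1 − e^{−k_exp t})` gives the relative equilibrium
  fluorescence `F_rel = F_eq/F_max` and the observed rate `k_exp`, and the
  second-order association law

  `F_eq / ([P_b](F_eq − F_t)) = 1/[P_b] + k_a t`

  linearizes the trace so that the slope is the second-order
  pore-formation rate constant `k_a` (M⁻¹s⁻¹) and the intercept checks
  against `1/[P_b]`, the inverse membrane-bound peptide concentration.
  The ratio `K_p = k_a / k_exp` is the in-membrane peptide–peptide
  affinity constant, and an association model (isodesmic by default)
  converts `K_p[P_b]` into the mean number `n` of oligomer units per pore.

* **Polarized ATR-FTIR spectroscopy** — amide I spectra measured at ∥ and
  ⊥ polarization are decomposed into turn / α-helix / irregular / β-sheet /
  side-chain components (shared centers and widths, free amplitudes) to give
  secondary-structure fractions and per-band dichroic ratios
  `R = a_∥/a_⊥`. The thick-film internal-reflection relation converts `R`
  into uniaxial order parameters `S = (3⟨cos²θ⟩ − 1)/2 ∈ [−0.5, 1]`:
  acyl-chain order `S_L` from the CH₂ stretching bands (dipole ⊥ chain),
  and the β-strand tilt `β` from the sheet band through the nested
  factorization `S_dipole = S(γ)·S(β)·S(θ_d)` for a barrel tilted by `γ`
  from the membrane normal.

* **CD difference spectroscopy** — the spectrum of the membrane-bound
  peptide is isolated as `(measured − (1 − f_bound)·free)/f_bound` and
  its diagnostic minima located.

* **β-barrel geometry** — for a barrel of `z` strands tilted by `β`,
  `R = d/(2 sin(π/z) cos β)` with interstrand distance `d = 4.72` Å,
  height `h_b = m·a·cos β` (`a = 3.48` Å per residue), volume `V = πR²h_b`;
  the two alternating side-chain topologies of the 11-mer strand, their van
  der Waals volume requirements, packing feasibility, the equivalent
  free-volume channel radius `√(V_free/(π h_b))`, and the central pore of a
  tangent ring of barrels.

Every input has a seeded synthetic generator with embedded ground truth
(`simulate_trace()`, `simulate_polarized_pair()`, `simulate_cd_mixture()`),
so each estimator is validated by parameter recovery. The package is
tidyverse-styled: data frames in, tibbles out, `tidy()`/`glance()` on all
fitted objects, `autoplot()` everywhere.

## Worked example

Simulate a trace under the second-order model at a known rate constant and
recover the full kinetic characterization:

```r
library(abpore)

tr <- simulate_trace(model = "second_order", f_eq = 0.6,
                     k_a = 1e5, p_b = 2e-6, noise = 0.01, seed = 3)
res <- fit_pore_kinetics(tr, p_b = 2e-6, f_eq = 0.6)
glance(res)
#> # A tibble: 1 × 8
#>   f_rel  k_exp    k_a      k_p     n      p_b r.squared intercept_ratio
#>   <dbl>  <dbl>  <dbl>    <dbl> <dbl>    <dbl>     <dbl>           <dbl>
#> 1 0.591 0.0956 99288. 1038622.  2.03 0.000002     0.981            1.04
```

`k_a` is recovered within 1% of the generating 10⁵ M⁻¹s⁻¹ and the
intercept of the linearized plot sits within 4% of `1/[P_b]`
(`intercept_ratio`), confirming second-order behaviour; `k_p = k_a/k_exp`
and the isodesmic mean oligomer count `n` follow. On real data, `[P_b]`
comes from an independent binding measurement and `f_eq` from the fitted
or measured plateau.

The geometry side needs no data at all — the measured strand tilt
(β = 22°) fixes everything:

```r
pore_report(z = c(6, 8), beta = 22)$packing
#> # A tibble: 4 × 8
#>       z  beta topology   volume required feasible free_volume channel_radius
#>   <dbl> <dbl> <chr>       <dbl>    <dbl> <lgl>          <dbl>          <dbl>
#> 1     6    22 topology-1  2890.     3138 FALSE         -248.           NA
#> 2     8    22 topology-1  4933.     4184 TRUE           749.            2.59
#> 3     6    22 topology-2  2890.     2928 FALSE          -38.4          NA
#> 4     8    22 topology-2  4933.     3904 TRUE          1029.            3.04
```

A 6-stranded barrel at 22° cannot quite host either side-chain topology
(topology-2 misses by only 38 ų — it fits at β = 24°), while an
8-stranded barrel hosts either with 750–1030 ų to spare, an equivalent
channel of ~2.6–3.0 Å radius. The supramolecular pore — a ring of six
6-stranded barrels — follows from `ring_pore_radius(6, inner_r = 5.09)`.

Strand tilts from a measured sheet dichroic ratio:

```r
strand_tilt(0.89, gamma = c(0, 10, 20))
#> # A tibble: 3 × 5
#>   gamma s_dipole s_strand  beta solvable
#>   <dbl>    <dbl>    <dbl> <dbl> <lgl>
#> 1     0   -0.345    0.690  27.0 TRUE
#> 2    10   -0.345    0.723  25.4 TRUE
#> 3    20   -0.345    0.837  19.2 TRUE
```

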