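---
title: "Binding spectroscopy with specbind: models, estimators and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Binding spectroscopy with specbind}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(specbind)
```

specbind implements the classical in-vitro workflow for characterising a
small-molecule drug binding to a protein by titration spectroscopy. The
motivating system is a lysozyme-type protein (10 µM) titrated with a ligand
over 0–30 µM (UV–vis) and 0–60 µM (fluorescence), with synchronous and 3D
fluorescence reporting microenvironment changes and far-UV circular
dichroism reporting secondary structure. All estimators are the field's
standard linearised graphical methods, implemented as ordinary
least-squares fits on transformed variables — deliberately reproducing the
classical estimators rather than replacing them with nonlinear refits, so
that results are comparable with the literature that uses these plots.

## UV–vis binding model

The absorbance change at the aromatic band, `dA([S]) = A([S]) − A(0)` read
at 280 nm (configurable; linear interpolation if the wavelength falls
between grid points), follows the 1:1 isotherm
`dA = dA_inf [S] / (K_d + [S])`. Two linearisations are fitted:

* **Double-reciprocal plot**: `1/dA = (K_d/dA_inf)(1/[S]) + 1/dA_inf`.
  The OLS line gives `K_d = slope/intercept` and `dA_inf = 1/intercept`.
  Points with `dA ≤ 0` have no reciprocal and are excluded with a warning;
  fewer than three usable points is an error. A non-positive intercept, or
  a `K_d` at or below numerical resolution on the concentration scale
  (the saturated-titration limit, where the slope is zero up to rounding),
  raises a nonphysical-fit error rather than returning a misleading number.
* **Hill plot**: `log10(dA/(dA_inf − dA)) = h·log10[S] + log10 K_a`, using
  `dA_inf` from the double-reciprocal fit. The slope is the cooperativity
  `h` (1 for independent binding); `10^intercept` is an independent `K_a`
  estimate. Base-10 logarithms throughout, the convention of Hill-plot
  practice.

`K_a = 1/K_d` and the Hill-intercept `K_a` are reported side by side and
never reconciled: on real data the two disagree slightly because `K_d` is
estimated with finite precision, and hiding that disagreement would hide a
diagnostic. The free energy `ΔG⁰ = −RT ln K_a` uses `K_a = 1/K_d` and
`R = 1.987204 × 10⁻³ kcal mol⁻¹ K⁻¹`; output is kcal mol⁻¹.

```{r}
t <- simulate_uv_titration(sim_config(seed = 1, binding = list(sigma = 0)))
uv_binding_fit(t)
```

## Fluorescence quenching

The peak emission intensity (maximum over the scanned range, ties to the
lowest wavelength — a deterministic rule that matters only for degenerate
flat spectra) per quencher concentration feeds three estimators:

* **Stern–Volmer**: `F0/F = 1 + K_sv[Q]`. The regression fits an intercept
  instead of forcing the model value of 1; the fitted intercept is reported
  as a model-adequacy diagnostic (inner-filter effects and mixed quenching
  bend the plot and move the intercept). On ideal data the slope equals the
  forced-intercept estimator exactly. `F0/F < 1` points are retained but
  logged, so violations of monotone quenching stay visible.
* **Bimolecular rate**: `k_q = K_sv/τ₀` with `τ₀ = 5.78 × 10⁻⁹ s` by
  default (literature lifetime of the protein's intrinsic fluorescence;
  configurable, since it is protein-specific).
* **Mechanism call**: `k_q` far above the diffusion-limited collisional
  reference `2 × 10¹⁰ M⁻¹ s⁻¹` implies ground-state complex formation
  (static quenching); far below implies collisional (dynamic) quenching.
  Because the reference is an order-of-magnitude figure, a ±5% band around
  it returns `indeterminate` instead of a knife-edge call.
* **Double-log (modified Stern–Volmer)**:
  `log10((F0−F)/F) = log10 K_b + n·log10[Q]` yields the binding constant
  `K_b` and binding-site number `n`. On data that are exactly Stern–Volmer,
  `(F0−F)/F = K_sv[Q]` algebraically, so `n = 1` and `K_b = K_sv` — a
  property the test suite asserts.

```{r}
quench_fit(simulate_quenching(sim_config(seed = 1,
                                         quenching = list(sigma = 0))))
```

## Synchronous fluorescence and EEM peaks

A synchronous spectrum samples the excitation–emission matrix along
`λ_em = λ_ex + Δλ` (bilinear interpolation). `Δλ = 15 nm` reports the
tyrosine microenvironment, `Δλ = 60 nm` tryptophan. Across a titration,
the net movement of the synchronous maximum
(`λ_max(highest) − λ_max(0)`) is called `red` (> +1 nm, increased
polarity), `blue` (< −1 nm) or `negligible`; 1 nm is one grid step at
typical instrument resolution, below which a "shift" is indistinguishable
from sampling.

EEM peak detection reports strict local maxima of the intensity matrix
under 8-neighbour comparison (boundary points compare against existing
neighbours), keeps those at or above 5% of the global maximum, and
classifies each by geometry: Rayleigh scatter if `|λ_em − λ_ex| ≤ 10 nm`,
second-order scatter if `|λ_em − 2λ_ex| ≤ 30 nm` (real second-order ridges
sit noticeably below the ideal `2λ_ex` line, hence the wide band),
otherwise a genuine fluorophore. Two robustness choices deserve note:

* **Minimum peak separation (45 nm).** Instrument noise on the flat crest
  of a band or scatter ridge splits one physical feature into several
  strict maxima a grid step or two apart. Reported peaks closer than 45 nm
  (Euclidean, in the excitation–emission plane) to a stronger peak are
  suppressed, keeping the strongest representative — standard non-maximum
  suppression, as in image peak pickers. 45 nm sits below the 50 nm
  spacing of the two protein fluorophore bands (excitation 230 vs 280 nm),
  so distinct real bands are never merged. Every reported peak is still a
  strict local maximum of the raw matrix.
* **Sampling adequacy in the generator.** A ridge along `λ_em = 2λ_ex`
  advances two emission grid steps per excitation step, so on a 5 nm grid
  a ridge narrower than ~2 grid steps aliases into a chain of spurious
  strict maxima. The synthetic second-order ridge width (25 nm) and the
  25 nm Gaussian source-intensity envelope (which confines scatter crests
  above the detection floor to a few grid steps, matching how instruments
  report single scatter "peaks") are chosen to respect that sampling
  limit. The Rayleigh line is 4 nm wide — slit-limited — which also keeps
  its tail negligible at the Δλ = 15 nm synchronous offset.

```{r}
find_eem_peaks(simulate_eem(sim_config(seed = 1)))
```

## Circular dichroism

Observed ellipticity in millidegrees is converted pointwise to mean
residue ellipticity, `MRE(λ) = θ_obs(λ)/(C_p · n · l · 10)`, with `C_p`
the protein molar concentration (mol/L), `n` the residue count
(default 130, human lysozyme — a documented assumption that must be
overridden for other proteins) and `l` the path length in cm (default
0.1 cm, the conventional far-UV cell; also an assumption to override when
known). The helix fraction uses the empirical two-point formula at 208 nm,
`%α-helix = (−MRE₂₀₈ − 4000)/(33000 − 4000) × 100`, where 4000 and 33000
are the canonical 208 nm MRE magnitudes of random coil/β form and pure
helix. The formula is a two-point interpolation, not a physical law:
values outside 0–100% are reported with an `out_of_model` flag and never
clamped, so breakdown is visible. MRE at 208 nm is linearly interpolated
when 208 nm is off the grid; interpolation chords the curved band top, so
a 2 nm grid biases the estimate low by about 1% — measure on a grid
containing 208 nm when that matters. The unit contract (mdeg in, mol/L,
cm) is fixed and documented rather than guessed per dataset.

```{r}
cd_helix(simulate_cd(sim_config(seed = 1, cd = list(sigma = 0))))
```

## Synthetic data: what it emulates, and what it does not

Every generator is seeded (bit-reproducible, without disturbing the global
RNG stream) and attaches a ground-truth manifest (`sim_truth()`); recovery
tests read truth only from the manifest. Defaults are the study
conditions: `K_d = 5.18 µM`, `dA_inf = 0.30 AU`, `h = 1`, titration
0–30 µM in 2 µM steps; `F0 = 1000` counts, `K_sv = 3320 M⁻¹`, 341 nm
emission band, 0–60 µM in 5 µM steps; EEM on 200–400 / 200–550 nm grids
at 5 nm with fluorophore bands at (280, 340) and (230, 340) and
amplitudes mirroring the instrument counts of the reference system
(Rayleigh 2.45 × 10⁵, bands 9.7 × 10⁴ / 3.6 × 10⁴; the second-order ridge
uses 2 × 10⁴, about 8% of the Rayleigh peak, so that it clears the 5%
detection floor — weaker second-order scatter is handled by lowering
`min_prominence`); CD at 7 µM protein, 31.97% helix. Noise is additive
Gaussian per channel, defaulting to 1% of the saturation signal
(0.003 AU, 10 counts), 200 counts on the EEM and 0.05 mdeg on CD.

Deliberate non-realism, and hence what passing tests do **not** show about
real data: no Poisson/shot noise (the estimators read maxima or single
wavelengths, for which the Gaussian model suffices); Gaussian band shapes
(shape is irrelevant to every estimator); no inner-filter effect, drift,
or temperature dependence; band red shifts are modelled as translation of
the whole band along both axes, which makes the synchronous maximum shift
equal the configured value exactly — real shifts deform bands as well as
moving them. Recovery on this generator demonstrates estimator
correctness, not robustness to instrument systematics.

## Numerical choices

* All fits are unweighted OLS on the transformed variables via `lm()`;
  `r²` is computed directly from residuals (identical to `summary.lm`, but
  silent on degenerate perfect fits).
* Wavelength lookups interpolate linearly and refuse extrapolation with a
  range error.
* Ties in any `λ_max` resolve to the lowest wavelength, for determinism.
* Concentrations are mol/L internally; readers accept M, mM, µM, nM via a
  `units` header and convert on ingest. Wavelengths are nm throughout.
* Files are written with 17 significant digits, so write-then-read is the
  identity at full double precision (the test suite asserts bitwise
  equality for all four types in both CSV and JSON).
* Typed error conditions (`sb_validation_error`, `sb_format_error`,
  `sb_range_error`, `sb_domain_error`, `sb_insufficient_data_error`,
  `sb_nonphysical_fit_error`, `sb_shape_error`) make every documented
  failure mode programmatically catchable; readers never coerce silently.

## Test problem sizes

The suite runs titrations at their natural sizes (15–16 UV concentrations,
13 quenching concentrations), 200 seeded replicates for the noisy-recovery
medians, 5 nm EEM grids (41 × 71) with 1 nm grids (201 × 351) only in the
grid-refinement invariance check, and 25 seeds for the peak-taxonomy
stability property. These sizes were chosen to exercise the estimators at
realistic instrument resolution while keeping the default check fast.

## Limitations

Single-temperature analysis only (no van't Hoff thermodynamics); no FRET
distances or time-resolved lifetimes; no multi-wavelength global fitting
or absorbance inner-filter correction; CD is the 208 nm two-point helix
estimate, not a full secondary-structure deconvolution; EEM analysis stops
at peak taxonomy (no PARAFAC, no scatter excision for downstream
chemometrics). Docking and molecular-dynamics observables are outside the
package's scope entirely.
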