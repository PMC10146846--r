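# specbind

Analysis of drug–protein binding from titration spectroscopy, for
biophysics and drug-discovery labs that characterise small-molecule
binding to a protein (lysozyme, serum albumins, and similar model
carriers) with the standard battery of bench instruments: a UV–vis
spectrophotometer, a spectrofluorophotometer (steady-state, synchronous
and 3D/EEM modes), and a far-UV CD spectropolarimeter.

## What it computes

Given concentration-indexed spectra of a protein titrated with ligand,
specbind implements the field's classical graphical estimators:

* **UV–vis binding.** With ΔA = A([S]) − A₀ at the 280 nm aromatic band,
  the double-reciprocal line 1/ΔA = (K_d/ΔA_∞)(1/[S]) + 1/ΔA_∞ gives the
  dissociation constant K_d and saturation amplitude ΔA_∞; K_a = 1/K_d;
  the Hill plot log₁₀(ΔA/(ΔA_∞−ΔA)) = h·log₁₀[S] + log₁₀K_a gives the
  cooperativity h; ΔG⁰ = −RT ln K_a.
* **Fluorescence quenching.** Stern–Volmer F₀/F = 1 + K_sv[Q]; the
  bimolecular rate k_q = K_sv/τ₀ against the diffusion limit
  2 × 10¹⁰ M⁻¹ s⁻¹ classifies the mechanism (static vs dynamic); the
  double-log plot log₁₀((F₀−F)/F) = log₁₀K_b + n·log₁₀[Q] gives the
  binding constant K_b and site number n.
* **Synchronous fluorescence** at constant Δλ (15 nm tyrosine, 60 nm
  tryptophan) with red/blue/negligible calls on the emission-maximum
  shift across the titration.
* **EEM peak taxonomy**: strict local maxima classified as Rayleigh
  scatter (λem ≈ λex), second-order scatter (λem ≈ 2λex) or genuine
  fluorophore bands.
* **CD secondary structure**: mean residue ellipticity
  MRE = θ_obs/(C_p·n·l·10) and
  %α-helix = (−MRE₂₀₈ − 4000)/(33000 − 4000) × 100.

A seeded synthetic-data generator (`sim_config()`, `simulate_*()`,
`write_simulation()`) emulates all four instruments with ground-truth
manifests, so every estimator is testable by parameter recovery. CSV/JSON
readers and writers (`read_titration()`, `read_eem()`, `read_cd()`, and
`write_*` counterparts) round-trip at full double precision. A thin CLI
(`inst/cli/specbind`) exposes one verb per analysis stage.

## Worked example

Simulate a full instrument session and analyse the directory end to end:

```r
library(specbind)
cfg <- sim_config(seed = 7)        # K_d = 5.18 uM, K_sv = 3320 M^-1, ...
write_simulation(cfg, "demo")      # uv.csv, quench.csv, eem_*.csv, cd.csv
report <- run_all("demo")
print(report)
```

```
specbind report (specbind-report/1)

UV-vis binding (280 nm)
  T (K)  K_d (M)      K_a (M^-1)   h        dG0 (kcal/mol)
  298    5.4e-06      1.85e+05     0.973    -7.18

Quenching: K_sv = 3.23e+03 M^-1, k_q = 5.59e+11 M^-1 s^-1 (static), K_b = 1.03e+03 M^-1, n = 0.885

EEM peaks:
  eem_01.csv: 4 peak(s) [rayleigh, fluorophore, fluorophore, second_order]
  eem_02.csv: 4 peak(s) [rayleigh, fluorophore, fluorophore, second_order]
  eem_03.csv: 4 peak(s) [rayleigh, fluorophore, fluorophore, second_order]
Synchronous delta_lambda = 15 nm: net shift +0.00 nm (negligible)
Synchronous delta_lambda = 60 nm: net shift +0.00 nm (negligible)

CD: MRE208 = -13271.56 deg cm^2 dmol^-1, helix = 31.97 %
```

Reading the output: the titration was generated with K_d = 5.18 µM and 1%
channel noise, and the double-reciprocal fit recovers 5.4 µM with h close
to 1 (independent binding); K_sv ≈ 3.2 × 10³ M⁻¹ gives
k_q ≈ 5.6 × 10¹¹ M⁻¹ s⁻¹, far above the 2 × 10¹⁰ M⁻¹ s⁻¹ diffusion limit,
hence a static (complex-forming) quenching call; each EEM shows the two
protein fluorophore bands plus the two scatter features; the generator's
band positions were not shifted, so both synchronous calls are negligible;
the CD spectrum generated at 31.97% helix converts back to 31.97%.
`write_report(report, "report.json")` saves the same content as JSON.

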