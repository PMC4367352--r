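# phantomspec

Forward and inverse modelling of diffuse reflectance and fluorescence
spectroscopy in homogeneous turbid media, built around the liquid phantoms
used to validate miniaturized (few-spectral-band) optical screening of
gastrointestinal tissue.

Early gastrointestinal dysplasia changes two things an optical probe can
see: haemoglobin concentration rises (absorption, `mua`) and the epithelium
thickens over the collagen matrix (reduced scattering, `musp`), while the
fluorophores NADH and collagen shift the autofluorescence spectrum. A
chip-sized spectrometer cannot record full spectra — only a handful of
filtered bands — so the question the package addresses is: **can tissue
optical properties and intrinsic fluorescence still be extracted after
sparse-band sampling and spline reconstruction?** It answers this on
synthetic phantoms with known ground truth: a haemoglobin-like absorber,
1 µm polystyrene microspheres as the scatterer, and an NADH-like plus a
carbostyril-like (collagen surrogate) fluorophore.

The chain, each stage a composable function:

* **Mie theory** (`mie_efficiencies()`, `suspension_optics()`) — expected
  `mus`, `g`, `musp` of the bead suspension from the partial-wave series.
* **Monte Carlo transport** (`simulate_transport()`, compiled) — diffuse
  reflectance of a slab with implicit capture, Henyey–Greenstein
  scattering, Fresnel boundaries, Russian roulette, and the
  per-interaction-count escape histogram `N_reflect(j)`.
* **Albedo scaling** (`scaling_model()`, `scaled_reflectance()`) — one
  reference run predicts the reflectance at any albedo
  `c = musp/(musp + mua)` through
  `R(c) = sum_j N_reflect(j) (c/c_sim)^j`, exactly at `c = c_sim`.
* **Inverse model** (`slab_scaling_model()`, `invert_reflectance()`) —
  bounded least squares for `mua(lambda) = ln(10) eps(lambda) C` and a
  scattering law (power law, or a known spectral shape with free
  amplitude), using the sample-cell thickness to fix the absolute scale
  that a semi-infinite measurement cannot determine.
* **Sparse bands** (`sample_bands()`, `reconstruct_spectrum()`,
  `band_ratio()`) — 16-band reflectance and 10-band fluorescence sampling
  with cubic-spline reconstruction.
* **Intrinsic fluorescence** (`fluor_context()`, `extract_intrinsic()`,
  `apply_distortion()`, `decompose_fluorophores()`) — photon-migration
  correction of the bulk signal, exact round trip by construction, plus
  non-negative spectral unmixing.
* **Synthetic phantoms** (`validation_phantoms()`, `build_dataset()`,
  `run_full_chain()`) — the five crossed-ladder recipes with ground truth,
  and the end-to-end validation study.
* **Temperature statistics** (`partial_correlation()`,
  `synth_temperature_table()`) — the partial-correlation null analysis of
  temperature against signal intensity.

Everything is seed-reproducible; spectra are tibbles; fitted objects have
`tidy()`/`glance()` and `autoplot()` methods. The methods vignette
(`vignettes/phantomspec-methods.Rmd`) documents the models, defaults and
numerical decisions.

## Worked example

```r
library(phantomspec)

# one synthetic phantom: 1 mg/mL absorber, 0.15% beads, two fluorophores
recipe <- validation_phantoms()[3, ]
ds <- build_dataset(recipe, seed = 5)

# sparse-band reconstruction of its measured reflectance
rec <- reconstruct_spectrum(
  sample_bands(ds$observed$reflectance, reflectance_bands()),
  reflectance_grid(), kind = "reflectance")

# extract coefficients against the known bead scattering shape
slab  <- slab_scaling_model(mc_config(seed = 99, n_photons = 1e5))
lib   <- chromophore_library()
beads <- suspension_optics(bead_suspension(1, 1), reflectance_grid())
fit <- invert_reflectance(
  rec, slab, extinction = lib$extinction$hb,
  basis = "shape",
  scatter_shape = spectrum(reflectance_grid(), beads$musp, "coefficient"),
  l_cm = 0.2, fit_bands = reflectance_bands(), seed = 1)
print(fit)
#> <reflectance_fit> basis = shape, residual norm = 0.00759, converged
#>    C = 1.021, a = 5.55
glance(fit)[, c("C_mg_per_ml", "a_per_cm")]
#> # A tibble: 1 x 2
#>   C_mg_per_ml a_per_cm
#>         <dbl>    <dbl>
#> 1        1.02     5.55
```

The extracted absorber concentration `C` is in mg/mL (truth: 1.00) and `a`
is `musp` at 500 nm in cm⁻¹ (truth from Mie: 5.44) — both recovered within
about 2% here, from 16 reflectance values. The whole five-phantom study,
including the fluorescence leg, is one call:

```r
chain <- run_full_chain(seed = 1)
chain$metrics  # per-phantom median errors, band ratios, peak restoration
autoplot(chain)  # extracted vs expected coefficient scatter
```

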