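---
title: "Models and methods behind phantomspec"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind phantomspec}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

phantomspec models the optical characterization workflow used to validate
miniaturized spectroscopy for gastrointestinal tissue screening: liquid
phantoms containing a haemoglobin-like absorber, polystyrene microsphere
scatterers and two fluorophores are measured by diffuse reflectance
(350--750 nm) and fluorescence (380--600 nm, excitation 350 nm); a Monte
Carlo based inverse model extracts the absorption coefficient
$\mu_a(\lambda)$ and the reduced scattering coefficient $\mu_s'(\lambda)$
from the reflectance; a photon-migration model extracts intrinsic
fluorescence from the bulk signal; and both extractions must still work when
the spectra are reconstructed from a handful of spectral bands, as a
filter-on-photodiode microsystem would record them. The package provides
each stage as a composable function plus a synthetic phantom generator with
known ground truth, so that the whole chain can be validated end to end.

This vignette records the models, the parameter choices and the numerical
decisions. All quantitative statements about performance are computed by the
test suite and by `scripts/acceptance.R`; nothing here is asserted from
memory.

## Monte Carlo photon transport

`simulate_transport()` is a standard photon-packet random walk in a
homogeneous slab (MCML lineage): step lengths drawn from an exponential with
attenuation $\mu_t = \mu_a + \mu_s$, implicit capture (a fraction
$\mu_a/\mu_t$ of the packet weight deposited at each interaction),
Henyey--Greenstein scattering with anisotropy $g$, unpolarized Fresnel
reflection/refraction at the faces, and Russian roulette (threshold
$10^{-4}$, survival factor 10) for low-weight packets. Weight escaping
through the illuminated face accumulates into the diffuse reflectance
$R$ and is binned by the packet's interaction count $j$, giving the
histogram $N_\mathrm{reflect}(j)$ with $\sum_j N_\mathrm{reflect}(j) = R$
as an exact bookkeeping identity. The default geometry is a semi-infinite
aqueous medium ($n_\mathrm{in} = 1.33$, $n_\mathrm{out} = 1$) under a pencil
beam at normal incidence; matched boundaries and finite slabs are
configuration options. The engine is compiled (Rcpp) and draws from R's RNG,
so a seed makes runs bit-for-bit reproducible; the seed is a mandatory field
of `mc_config()` — there is no hidden global state.

Bookkeeping is closed exactly: specular + reflected + transmitted + absorbed
+ the net roulette weight transfer sums to 1 to machine precision, and the
closure without the roulette tally is unbiased (tested over seeds). Packets
in a *conservative* ($\mu_a = 0$) semi-infinite medium escape upward with
probability 1; the walk is closed analytically for the tiny fraction
(about $10^{-3}$ at the default cap of $10^6$ steps) whose first passage
exceeds the step cap, which is unbiased in exactly that case. The
interaction-count histogram is capped at $10^4$ bins with an overflow bin
whose mass must stay below $10^{-4}$ of the reflectance (checked in tests).

## Albedo scaling of diffuse reflectance

With implicit capture, the *geometry* of a packet's path in a semi-infinite
medium, measured in mean free paths, does not depend on the albedo
$c = \mu_s'/(\mu_s' + \mu_a)$ (reduced, similarity-transformed
representation with $g = 0$); only the escaping weight does, as $c^{\,j}$
after $j$ interactions. A single reference run at albedo $c_\mathrm{sim}$
therefore predicts the reflectance at any other albedo:

$$R(c) \;=\; \sum_j N_\mathrm{reflect}(j)\,
\left(\frac{c}{c_\mathrm{sim}}\right)^{\!j},$$

which is exact in expectation, reduces to the reference's total reflectance
at $c = c_\mathrm{sim}$ identically, and is evaluated in log space
(`scaled_r_values()`). Scaling is only stable *downward*: for
$c > c_\mathrm{sim}$ the factor $(c/c_\mathrm{sim})^j$ amplifies the
noisy, roulette-dominated histogram tail exponentially, so
`scaled_reflectance()` refuses it and the reference albedo must dominate
every target. The default $c_\mathrm{sim} = 0.9995$ was chosen because the
validation phantoms' albedo reaches $\approx 0.999$ at 700--750 nm, where
the haemoglobin-like absorber is nearly transparent; a more absorbing
reference (such as 0.99) would force upward scaling exactly where the
phantoms are brightest.

## Identifiability and the slab-aware model

The total diffuse reflectance of a semi-infinite medium is scale invariant:
it depends on $(\mu_a, \mu_s')$ only through their ratio. Any extraction of
*separate* coefficient spectra from a single semi-infinite reflectance
spectrum is therefore ill-posed — multiplying both coefficients by a common
factor changes nothing. The package exposes this honestly: with a
semi-infinite `scaling_model()`, `invert_reflectance(basis = "albedo")`
returns the pointwise albedo spectrum, the quantity the measurement
actually determines.

Separating the coefficients needs an absolute length scale, and a real
phantom has one: the sample cell. `slab_scaling_model()` runs the reference
simulation at a grid of optical thicknesses
$\tau = (\mu_a + \mu_s')\,\ell$ (22 log-spaced nodes over 0.3--60 by
default); at fixed $\tau$ the albedo-scaling identity is exact, and between
nodes the model blends the exact per-node sums with a $C^1$ Catmull--Rom
cubic in $\log\tau$ (a piecewise-linear table stalls derivative-based
optimizers on its kinks). Transmission loss through the back face makes the
reflectance scale-sensitive. The synthetic reflectance measurements use a
thin cell, `refl_path_cm = 0.2` by default: with a 1 cm path the denser
phantoms are optically semi-infinite and the scale direction degenerates
again, while a 2 mm cell keeps $\tau$ in the range 1--30 where the
conditioning analysis gives a few percent parameter uncertainty at the
default 1% measurement noise. The fluorescence cuvette remains 1 cm
(`thickness_cm` in the recipe); the two instruments use different cells.

## Coefficient extraction

`invert_reflectance()` minimizes the plain (unweighted) sum of squared
reflectance residuals with bounded Levenberg--Marquardt from 10 seeded
random starts. Three parameterizations:

* **physical** — $\mu_a = \ln 10 \cdot \varepsilon(\lambda)\, C$
  (Beer--Lambert against a known extinction spectrum, concentration free)
  and $\mu_s' = a\,(\lambda/500\,\mathrm{nm})^{-b}$, the standard scattering
  power law. Bounds $C \in [0,5]$ mg/mL, $a \in [0,100]$ cm$^{-1}$,
  $b \in [0,4]$ bracket tissue-like phantoms by a wide margin. For
  micron-sized spheres the Mie curve deviates from a power law by several
  percent, and because the coefficient scale is the weakly determined
  direction, that shape mismatch leaks into a substantial scale bias — this
  basis is the general-purpose (tissue) choice, not the most accurate one
  for bead phantoms.
* **shape** — $\mu_s' = a\,S(\lambda)$ with a known scattering shape
  (normalized to 1 at 500 nm, so $a = \mu_s'(500)$). This is the
  validation-phantom mode: the scatterer family of a designed phantom is
  known, only concentrations are unknown, and the basis mismatch is zero.
  `run_full_chain()` uses it with the Mie shape of the recipe's bead
  suspension.
* **albedo** — pointwise albedo by monotone root bracketing, as above.

$C$ and $a$ are optimized on the log scale: they are positive scale
parameters, and in linear space Levenberg--Marquardt can jump onto the
all-zero boundary corner, a saturated plateau (albedo and optical thickness
both clamped) where the Jacobian vanishes and the fit silently "converges".

When the measured spectrum is a sparse-band spline reconstruction, the fit
residuals are evaluated at the band centres (`fit_bands`): a spline is an
interpolant, so at the band centres it reproduces the measured values
exactly, whereas between bands it contributes correlated interpolation
error — around the steep Soret edges several times the measurement noise —
that a plain least-squares fit would otherwise chase. The spectral basis
supplies the between-band information instead, and the extracted coefficient
curves are always returned on the full 1 nm grid.

## Mie theory for the microsphere scatterer

`mie_efficiencies()` implements the Lorenz--Mie partial-wave series with the
Wiscombe truncation $n_\mathrm{max} = \lceil x + 4.05x^{1/3} + 2\rceil$,
downward recurrence for the logarithmic derivative (stable at large size
parameter) and upward recurrence for the Riccati--Bessel functions. For the
real refractive indices used here, $Q_\mathrm{ext} = Q_\mathrm{sca}$ to
numerical precision, and the Rayleigh closed form is reproduced within 1%
for $x < 0.01$ (both tested). The suite also compares three size parameters
against values frozen from an independent implementation built on spherical
Bessel functions rather than recurrences. `suspension_optics()` converts a
bead suspension to coefficients via the number density
$(\mathrm{mass\ fraction})/(\rho_\mathrm{bead} \cdot
\pi d^3/6)$ with $\rho_\mathrm{bead} = 1.05$ g/mL, the size parameter using
the wavelength in the medium, and $\mu_s = \rho_N Q_\mathrm{sca} \pi r^2$ —
independent scatterers, adequate at the $\le 0.5$ w/v% concentrations used.
Refractive indices are Cauchy dispersion fits (polystyrene $\approx 1.59$,
water $\approx 1.33$ at 589 nm); the exact dispersion a given bead lot
follows should be supplied by the user when known.

## Sparse spectral bands

`sample_bands()` reads a spectrum at band centres (ideal point samples by
default; a top-hat average of configurable width is available for filter
realism) and `reconstruct_spectrum()` interpolates the samples back onto the
dense grid with a cubic spline. The default end condition is `"fmm"`
(cubics fitted through the boundary points), which reproduces cubic
polynomials exactly — the natural end condition, also available, does not,
because it forces zero second derivatives at the ends. Negative
reconstructed values are clamped to zero with a counter.

The 10 fluorescence bands are fixed at 380, 400, 420, 450, 480, 510, 540,
560, 580 and 600 nm. The 16 reflectance band centres used for GI screening
are instrument-specific and not published as a list; the package ships a
stand-in — 13 evenly spread anchors over 350--750 nm plus 420, 540 and
577 nm for the haemoglobin Soret and Q features — and every function takes
an arbitrary `band_set()`, so a validated set can be dropped in.

## Intrinsic fluorescence

The photon-migration model relates bulk fluorescence $F$ (measured from the
turbid sample) to intrinsic fluorescence $f$ through a per-emission-
wavelength correction built from the diffuse reflectance at excitation and
emission ($R_x$, $R_m$), their zero-absorption counterparts ($R_{0,x}$,
$R_{0,m}$, obtained by Monte Carlo with $\mu_a := 0$), the scattering
coefficient at excitation, the anisotropy factors, the sample thickness
$\ell$ and a probe constant $S$. With
$\varepsilon_k = e^{S(1-g_k)} - 1$:

$$f = F \cdot \frac{\mu_{s,x}\,\ell\;\sqrt{R_{0,x} R_{0,m}\,
\varepsilon_x \varepsilon_m}}
{\dfrac{R_x}{R_{0,x}}\left(\dfrac{R_m}{R_{0}} + \varepsilon_m\right)},$$

where the emission normalization $R_0$ in the denominator is $R_{0,x}$ by
default with $R_{0,m}$ available via the `convention` flag — the two agree
whenever $R_{0,x} = R_{0,m}$, as in the semi-infinite geometry. The typeset
sources for this model family leave the grouping of the factors genuinely
ambiguous, so the package pins it down by behaviour instead: the factor
arrangement above is the one under which the forward map
(`apply_distortion()`, the exact algebraic inverse) makes the bulk signal
*fall* both when absorption rises (lower $R_m$, $R_x$ — the Soret valley
dims the 420 nm region) and when scattering rises (larger $\mu_{s,x}$),
which is how phantom fluorescence is observed to behave. The whole
arrangement lives in one pure function (`fluor_correction()`) whose contract
is the exact round-trip identity, so a revised grouping is a one-line
change. The probe constant defaults to $S = 1$ (order unity; at
$S \sim 0.1$ the $\varepsilon_m$ term is so small that the model leaves the
regime described above) and must be calibrated per instrument, as must the
assumed anisotropies ($g = 0.9$ defaults).

In the full chain the correction context is built from the *extracted*
scattering coefficient ($\mu_s = \mu_s'/(1-g)$ with the assumed $g$), not
ground truth. The 10 band samples of the bulk signal are corrected first
and the corrected values spline-reconstructed: the bulk spectrum carries the
sharp Soret distortion that 10 bands cannot resolve (reconstructing it first
shifts the recovered peak by several nm), while the intrinsic spectrum is
smooth and splines to about a nanometre. `decompose_fluorophores()`
unmixes the result into non-negative weights on unit-area emission
lineshapes by non-negative least squares.

## The synthetic phantom generator

`build_dataset()` composes Beer--Lambert absorption, Mie scattering, Monte
Carlo reflectance and the fluorescence distortion into a dataset with ground
truth and "observed" spectra, reproducible from (recipe, seed, noise level)
alone. The five shipped recipes (`validation_phantoms()`, also as JSON under
`inst/extdata/`) are crossed ladders of absorber (0.25--1 mg/mL), scatterer
(0.15--0.5 w/v%), and fluorophores (0.5--1.5 µg/mL) so that pairs share one
property: phantoms 3 and 5 share the absorber, 2 and 5 (and 1 and 4) the
scatterer, and the NADH-like concentration rises across phantoms 1 to 3.

Choices a user should know about:

* The haemoglobin-like extinction spectrum is *parametric* (Soret Gaussian
  at 415 nm, Q-band Gaussians at 542/577 nm, decaying baseline), a synthetic
  stand-in with the right features rather than a digitized literature
  spectrum; any tabulated spectrum can replace it. Its red-tail amplitude
  matters: it sets the 700--750 nm albedo that the reference albedo must
  dominate.
* Fluorophore emission lineshapes are unit-area log-normals (NADH-like:
  455 nm peak, 100 nm FWHM, quantum yield 0.02; carbostyril-like: 417 nm,
  60 nm, 0.97; an optional right shoulder mimics aggregation at high
  concentration). Intrinsic amplitude is concentration × excitation
  strength × quantum yield: brightness at the 350 nm excitation includes
  the fluorophore's absorption there, and the NADH-like species is assigned
  a 10× excitation strength (350 nm sits on the NADH absorption maximum but
  on the red edge of the carbostyril band). With yield-only weighting the
  NADH ladder would contribute ~1% of the signal and the strongly rising
  450/390 band ratio observed across the phantom series could not occur;
  with the 10× factor the phantom-3 intrinsic spectrum still keeps a single
  peak near 420 nm, as reported for such mixtures.
* Observation noise is multiplicative log-normal with CV 0.01: benchtop
  acquisition divides out lamp fluctuations, leaving small residual noise.
* The observed reflectance comes from direct per-wavelength Monte Carlo of
  the thin slab every 10 nm (spline-interpolated to 1 nm; the band centres
  used downstream are close to simulated wavelengths), in the reduced
  $g = 0$ representation; a fast semi-infinite scaling mode exists for
  trend checks. The fluorescence context uses the semi-infinite geometry,
  where the zero-absorption reflectance is exactly $1 - R_\mathrm{specular}$.

What the generator does *not* emulate: instrument response functions and
wavelength-dependent throughput, stray light, fluorophore photobleaching or
inner-filter effects beyond the photon-migration model, dependent
scattering at high bead loads, polydispersity, and any temperature
dependence of the optical properties (the temperature analysis below is a
null calibration, reflecting the finding that temperature effects are not
significant). Passing tests on synthetic phantoms therefore demonstrates
the *chain's* correctness and conditioning, not instrument-level accuracy on
real tissue.

## Temperature analysis

`partial_correlation()` implements the first-order partial correlation by
the residual construction (both variables regressed on the controls, Pearson
correlation of residuals, two-sided p from the $t$ transform with
$n - k - 2$ degrees of freedom). `synth_temperature_table()` generates the
record layout of a temperature study — intensity across wavelengths,
compositions and 22--42 °C — with intensity *linear* in the controls,
because the residual construction only has its nominal null distribution
when the control model is correctly specified. The null calibration (200
tables) checks a near-uniform p distribution and small mean $|r|$; an
injected temperature slope is detected as a positive control.

## Problem sizes and runtime

Default study sizes are chosen so the full validation runs on a laptop-class
single core: reference simulations use $2$--$3\times10^5$ packets
(per slab node for the 22-node slab model), direct per-wavelength
measurements $3$--$5\times10^4$ packets, and the five-phantom chain
completes in about a minute. Halving or doubling these changes Monte Carlo
noise as $1/\sqrt{n}$; all tolerances in the test suite were set with these
sizes in mind.

## Known limitations

* Semi-infinite total reflectance alone cannot separate $\mu_a$ from
  $\mu_s'$; the separation rests on the known sample-cell thickness, and its
  conditioning degrades as the cell becomes optically thick.
* The power-law basis is biased for narrowly dispersed microsphere
  scatterers (use the shape basis when the scatterer family is known).
* The photon-migration correction assumes the probe constant and anisotropy
  are known; in the chain they are assumed, not fitted, and a miscalibrated
  $S$ rescales but also mildly reshapes the recovered intrinsic spectrum.
* Albedo scaling is performed in the reduced ($g = 0$) representation;
  boundary-mismatch effects make similarity slightly approximate, which is
  why the scaled-versus-direct agreement is validated numerically rather
  than assumed.
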