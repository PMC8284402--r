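---
title: "Propagation-based phase retrieval with holopr: models, methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Propagation-based phase retrieval with holopr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(holopr)
```

## The imaging problem

In near-field propagation-based X-ray imaging, a coherent beam traverses a
weakly refracting object and the detector records, after free-space
propagation, the intensity of the Fresnel transform of the object's exit
wave. Writing the projected object as a phase shift
$\varphi(x) = -\tfrac{2\pi}{\lambda}\int \delta\, \mathrm{d}z \le 0$ and an
absorption exponent $B(x) = \tfrac{2\pi}{\lambda}\int \beta\, \mathrm{d}z
\ge 0$ (with refractive index $n = 1 - \delta + i\beta$), the exit wave is
$u = e^{-B + i\varphi}$ and the measurement at effective distance $D$ is
$I_D = |\mathcal{F}^{-1}[H_D\,\mathcal{F}u]|^2$ with the Fresnel transfer
function $H_D(f) = e^{-i\chi_D(f)}$, $\chi_D(f) = \pi\lambda D |f|^2$
(frequencies $f$ in cycles per metre throughout). Phase retrieval inverts
this map: recover $\varphi$ (and possibly $B$) from one or several $I_D$.

Which algorithm applies depends on the Fresnel number
$F = a^2/(\lambda L)$ of the finest feature $a$: $F \gtrsim 1$ is the
edge-enhancement regime where transport-of-intensity (TIE) linearizations
hold; $F \ll 1$ is the holographic regime, where contrast-transfer-function
(CTF) and iterative methods are needed.

## Cone-beam geometry and Fresnel scaling

Divergent-beam data taken with focus-to-sample distance $z_1$ and
focus-to-detector distance $z_D$ are equivalent to parallel-beam data at the
effective distance $D = z_1(z_D - z_1)/z_D$, sampled at the demagnified
pixel $p/M$, $M = z_D/z_1$ (Fresnel scaling theorem). `acquisition_geometry()`
derives all of these; the identity $D \cdot M = z_D - z_1$ and the bound
$D \le z_D/4$ are asserted in the tests. The wavelength conversion uses the
fixed constant $\lambda[\mathrm{m}] = 1.23984193\times 10^{-9}/E[\mathrm{keV}]$
for bit-reproducibility. The package computes the effective pixel rather
than calibrating it against a measured value.

## Forward models and conventions

`fresnel_propagate()` is the single-FFT transfer-function propagator. Sign
conventions are fixed once — $u = e^{-B+i\varphi}$, $H_D = e^{-i\chi_D}$ —
and every linearized formula below is the one consistent with them; the
full-Fresnel operator is the arbiter in the test suite, since sign
conventions differ between implementations in this field.

The weak-object (CTF) linearization of the intensity spectrum is
$$\tilde I_D(f) = \delta_{\mathrm{Dirac}}(f)
  + 2\sin\chi_D(f)\,\tilde\varphi(f) - 2\cos\chi_D(f)\,\tilde B(f),$$
and the short-distance (TIE) linearization is
$$I_D = I_0 - \frac{\lambda D}{2\pi}\,
  \nabla\!\cdot\!\left(I_0 \nabla\varphi\right), \qquad I_0 = e^{-2B},$$
with spectral derivatives (periodic boundaries). Both are verified against
the Fresnel operator in their validity limits (weak contrast, resp.
$F = 50$) at the tolerances the tests state.

**Padding.** The unpadded propagator is exactly unitary and composes
exactly (`propagate(D1)` then `propagate(D2)` equals `propagate(D1+D2)`);
those contracts hold only for the periodic operator, so `pad = FALSE` is
the default. For non-periodic real data, `pad = TRUE` reflect-pads to twice
the size and crops back, suppressing wrap-around at the cost of exact
unitarity — the tests demonstrate an order-of-magnitude artifact reduction
for a phase tilt. This inverts the usual default deliberately: simulated
phantoms here are vignetted on a unit background, where wrap-around is
negligible, and the exact operator algebra is what the iterative methods'
adjoint computations rely on.

## Direct (filter-based) methods

All direct methods work per Fourier coefficient on background-normalized
images (background $\approx 1$; `normalize_stack()` divides by the flat or
the mean). The mean phase is unobservable and set to zero. A floor
$\alpha_{\min} = 10^{-12}$ is always added to denominators to protect exact
chirp zeros; the user-facing `alpha` (default $10^{-8}$) is applied
uniformly over frequency. A two-band (low/high frequency) regularization
split exists in parts of the literature but is not specified precisely
enough to reproduce, so uniform $\alpha$ is a deliberate design choice.

- **WTIE** (weak-absorption TIE): single distance,
  $\tilde\varphi = \tilde I'_D / (2\pi\lambda D|f|^2 + \alpha)$.
- **TIE-HOM** (homogeneous/Paganin): single material with
  $\gamma = \delta/\beta$, filter $g_D = 1 + \pi\lambda D\gamma|f|^2$
  applied to $I_D$, then $B = -\ln A/2$, $\varphi = \gamma \ln A /2$,
  thickness $t = B\lambda/(2\pi\beta)$; several distances combine as a
  Tikhonov-regularized least squares over $g_D$.
- **CTF**: per-frequency $2\times 2$ normal equations of the weak-object
  model over all distances, recovering $\varphi$ and $B$ jointly.
- **CTFPurePhase**: the $B = 0$ reduction.
- **Mixed approach**: solves for $\psi = I_0\varphi$ from
  $\tilde\Delta_D = \tilde I_D - \cos\chi_D\,\tilde I_0$ given a measured
  contact image $I_0$, with a prior $\psi_{\mathrm{prior}}$ entering at
  weight $\alpha$: none, homogeneous
  ($\varphi_{\mathrm{prior}} = \tfrac{\gamma}{2}\ln I_0$), multi-material
  (per-pixel $\gamma$ by thresholding $\ln I_0$) or heterogeneous
  (caller-supplied map from the absorption proxy $-\ln I_0/2$ to $\gamma$).

Each method exactly inverts its own linearized forward model (the primary
oracle suite) and is additionally checked on full-Fresnel simulations:
CTF with three distances reaches NRMSE$(\varphi) \le 2\%$ on a weak
$256^2$ phantom, TIE-HOM recovers a homogeneous disc's thickness to
$\le 2\%$ at $F(\text{finest feature}) = 10$, and the mixed approach with
the true $\delta/\beta$ prior reaches $\le 3\%$. Multi-distance stacks must
be co-aligned and on a common pixel grid; `prepare_stack()` provides
phase-correlation alignment and Fourier pad/crop resampling to the smallest
pixel.

## Iterative refinement

The iterate is the full complex wave $u$, not the phase alone, so phase and
amplitude refine together; the displayed phase is $\arg u$. Both schemes
should be initialized from a direct method — from flat or random starts
they find poor local optima, except in simple supported cases.

**Gradient descent** minimizes
$C(u) = \sum_D \lVert\, |P_D u|^2 - I_D \rVert^2$ with the Wirtinger
gradient $\nabla C = \sum_D 4 P_{-D}[(|u_D|^2 - I_D)u_D]$, validated
against central finite differences to $10^{-5}$ relative before any
optimization test runs. Armijo backtracking (halving from
$\text{step}_0 = 1/(8\sum_D \max I_D)$) makes the cost history
non-increasing by construction.

**HIO/ER** alternate between the detector modulus constraint (replace
$|u_D|$ by $\sqrt{I_D}$, keep the phase) and object-domain constraints
(support, with background $1+0i$ outside; optionally $|u| \le 1$, i.e.
$B \ge 0$). Distances are visited cyclically within an iteration. ER resets
violating pixels to the constrained value; HIO applies the generalized
feedback $u - \beta_{\mathrm{fb}}\,(u' - P(u'))$ with $P$ the
object-constraint projection and $\beta_{\mathrm{fb}} = 0.9$ by default.
The textbook feedback $u - \beta_{\mathrm{fb}} u'$ assumes a zero
background; with the unit-transmission background used here it has no
fixed point at the true object, so the generalized form (which reduces to
the textbook one for zero background) is used instead. The ER residual is
non-increasing (alternating projections); the HIO residual is not required
to be and is reported as a history.

The published "average of five iterations of successively 45 HIO + 5 ER,
separately on each acquired image" recipe is ambiguous; `hio_er_per_distance()`
implements one documented reading — per cycle, run the schedule
independently on each single-distance sub-stack from the current estimate,
average the waves, and iterate the cycle five times.

## The simulator as a stated world

`simulate_stack()` emulates a cone-beam multi-distance acquisition of a
known phantom: the exit wave is formed once on the phantom's
effective-pixel grid and propagated over each Fresnel-scaled effective
distance; per-distance magnification changes are recorded in metadata but
the images are not re-magnified. This is the standard parallel-equivalent
model that multi-distance CTF retrieval assumes; real data additionally
need per-distance re-magnification and deformable registration, which are
out of scope (a Fourier resampler and rigid phase-correlation alignment
are provided instead and are stated limitations for strongly
magnification-mismatched data).

Noise is Poisson counting noise only — with $N_0$ incident photons per
pixel, each pixel becomes $\mathrm{Pois}(N_0 I)/N_0$ — plus an optional
smooth multiplicative flat (off by default) to exercise the flat/dark
correction path. No detector PSF, partial coherence or drift is simulated,
so a green recovery test establishes correctness of the inversion under
the stated forward model, not robustness to those effects. Seeds are
explicit; the caller's RNG stream is never consumed; the same seed gives
bit-identical datasets.

Default test conditions, chosen once as representative of
nano-holotomography practice and not revisited: $\lambda = 10^{-10}$ m
(12.4 keV), 1 µm effective pixel, weak phantoms with
$\lVert\varphi\rVert_\infty = 0.01$ and $\lVert B\rVert_\infty = 0.005$ and
4-pixel correlation length, homogeneous discs with $\delta/\beta = 100$
and $B_{\max} = 0.02$ ($\varphi_{\min} = -2$ rad, soft-tissue-like), disc
edges smoothed over $\sigma = 2$ px so the finest feature is $\approx 4$ px,
and the worked-example cone-beam geometry (13 keV, $z_D = 1.12$ m,
$z_1 = 10.1$ mm, 650 nm detector pixel; $M = 110.9$, 6 nm effective pixel).

## Numerical choices and degenerate inputs

- Frequencies in cycles/m; DFT via `stats::fft`; the DC phase coefficient
  is zeroed (unobservable mean).
- $A \le 0$ pixels in TIE-HOM's log, and $I_0 \le 0$ pixels in the mixed
  approach, are clipped at $10^{-8}$ with a warning and a count on the
  result; `correct_image()` clips negative corrected intensities at 0 and
  errors when $\mathrm{flat}-\mathrm{dark} \le 0$.
- `wtie()` rejects $D = 0$ (degenerate filter); `hologram_stack()` rejects
  duplicate distances and negative intensities.
- Fractional `apply_shift()` keeps the unpaired Nyquist bin's phase factor
  real so real images stay real; shifts of band-limited images invert to
  $10^{-10}$.
- Phase-correlation peaks are refined by a per-axis 3-point parabolic fit
  (half-pixel shifts recovered within 0.1 px).
- TIFF I/O is a minimal uncompressed 32-bit float baseline codec (no TIFF
  package is available in the target environment); datasets are
  directories of per-distance TIFFs with a JSON metadata file.

## Known limitations

No polychromaticity, partial coherence or source blur; no deformable
registration; no tomographic reconstruction; no automatic $\delta/\beta$
selection; angular-spectrum and multi-slice propagation are out of scope.
Conjugate-gradient, ADMM and Fréchet-derivative refinements are not
implemented.

## A worked example

```{r example, eval = FALSE}
geom <- acquisition_geometry(13, z1_m = 10.1e-3, zd_m = 1.12,
                             pixel_m = 650e-9)
ph <- make_disc_phantom(c(256, 256), c(128, 128), 50, t_max = 2e-6,
                        delta = 1e-6, beta = 1e-8,
                        pixel = 1e-6, edge_sigma = 2)
sim <- simulate_stack(ph, geom, z1_list = c(5e-3, 8e-3, 10.1e-3),
                      n0_photons = 1e4, seed = 1)
rec <- ctf_retrieve(normalize_stack(sim$stack), alpha = 1e-8)
nrmse(rec$phi, sim$truth$phi)
plot(rec)
```
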