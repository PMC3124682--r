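---
title: "Emission imaging from Compton-scattered radiation: models and numerics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Emission imaging from Compton-scattered radiation: models and numerics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The imaging principle

A gamma-emitting object (for example an organ carrying a Tc-99m tracer,
source line $E_0 = 140$ keV) sits inside a scattering medium. A photon
emitted at a source point $S$ may Compton-scatter once at a site $N$ and
then reach a detector pixel $D$. The scattering angle $\omega$ between the
two legs fixes the detected energy through the Compton relation

$$E(\omega) = \frac{E_0}{1 + \epsilon\,(1 - \cos\omega)}, \qquad
  \epsilon = E_0 / m_e c^2 ,$$

a strictly decreasing bijection from $[0, \pi]$ onto
$[E_0/(1+2\epsilon),\, E_0]$. A detector with fine energy resolution can
therefore sort its counts by scattering angle *without moving*: each energy
window is one angle, and the angle plays the role that camera rotation plays
in conventional SPECT. The probability of scattering by $\omega$ is the
Klein–Nishina angular weight $\mathcal{P}(\omega)$, multiplied by the
electron density $n_e$ of the medium; the package implements the reference
text's printed form of $\mathcal{P}$ verbatim and keeps the textbook recoil
term available as `variant = "textbook"`. The two differ in their last term:
only the textbook form reduces to the Thomson shape $1 + \cos^2\omega$ at
small $\epsilon$ (the printed form becomes isotropic there). Since the
factor multiplies whole projections and is divided out again during
inversion, reconstruction quality is insensitive to this choice; it matters
only for absolute count levels.

Fixing the detection direction (a collimated planar camera, normal $z$), the
locus of possible source points for one scattering site is a circular cone
of vertex $N$, axis $z$, half-angle $\omega$. Summing over all sites on the
axis through a pixel gives the **compounded conical Radon transform**
(CCRT): the data $\hat f(x_D, y_D, \omega)$ integrate the activity $f$ over
a one-parameter family of cones, with inverse-square photometric factors on
both legs and the kinematic factor $K(\omega) = \pi r_e^2 n_e
\mathcal{P}(\omega)$. In two dimensions the cone degenerates to a "V" of two
half-lines above a linear detector, with $1/r$ photometric factors: the
**compounded V-line Radon transform** (CVLRT). Removing the collimator lets
every vertex in the half-space contribute (**gCCRT**); the point response is
then supported on a torus of revolution around the source–pixel line, and
reconstruction proceeds algebraically.

## The 2D modality

With $\tau = \tan\omega$ and the vertex at height $\eta$ above the detector
point $\zeta$, the data are

$$\hat f(\zeta, \omega) = K^*(\omega) \int_0^\infty \frac{d\eta}{\eta}
  \int_0^\infty \frac{dr}{r}\,
  \big[ f(\zeta + r\sin\omega, \eta + r\cos\omega)
      + f(\zeta - r\sin\omega, \eta + r\cos\omega) \big].$$

Defining the photometric smear $h(x, y) = \int_0^\infty d\eta/\eta\,
f(x, \eta + y)$ turns this into a plain V-line transform of $h$, inverted in
two steps: a filtered cosine back-projection recovers $h$, and a
deconvolution of the $1/\eta$ smear recovers $f$.

**Back-projection.** In the detector frequency $u$ the inversion is
$\tilde h(u, y) = 2|u|\, y \int_0^\infty d\tau \cos(2\pi u y \tau)\,
\hat f(u, \tau)$; the $|u|$ filter is the spectral form of the
principal-value-filtered derivative, and the closure
$\int_0^\infty \cos(a\tau)\cos(b\tau)\, d\tau = \tfrac{\pi}{2}\delta(a - b)$
makes it exact. (The constant in front is fixed by this closure; the
reference text's printed prefactor is off by $-1/2\pi$.) Two numerical
points decide the quality of this step:

* *Filon quadrature.* The angular grid cannot resolve the oscillation of
  $\cos(2\pi u y \tau)$ at large $\tau$. Integrating the kernel exactly
  against a piecewise-linear interpolant of the data attenuates the
  unresolved region smoothly instead of aliasing it.
* *Nyquist cap.* On rows spaced $\Delta y$ the kernel outruns the grid
  beyond $\tau = 1/(2 u \Delta y)$. On the half-integer row grid a sharp cap
  exactly cancels the cross-talk between rows (the truncated closure kernel
  has zeros on the lattice), so the discrete inversion of discretely sampled
  data is essentially exact.

**Deconvolution.** The continuum $1/\eta$ smear is logarithmically divergent
at the vertex; its regularized Fourier symbol is
$-[\log 2\pi|k| + \gamma - i\tfrac{\pi}{2}\,\mathrm{sgn}\,k]$ with Euler's
constant $\gamma$ (the package verifies $\gamma$ numerically from the
one-sided integral, `euler_gamma_from_eta_integral()`). Any discretization
regularizes the divergence with a pitch-dependent constant, so dividing
gridded data by the scale-free symbol leaves a large systematic error. The
default `filter = "matched"` therefore inverts exactly the operator the
projectors apply: on the grid the midpoint-rule smear is an upper-triangular
Toeplitz correlation with unit diagonal, invertible by back-substitution.
Because its kernel averages adjacent rows it annihilates the grid-Nyquist
band, so a small second-difference Tikhonov term (`lambda`, default 0.05 in
pitch units) stabilizes the inverse; the bias this adds on smooth fields is
orders of magnitude below the percent level. The scale-free symbol remains
available as `filter = "analytic"`.

**Quadrature node placement.** Both singular measures avoid their endpoints:
$\eta$ nodes sit at $(j + \tfrac12)\Delta$, and the slant integral uses the
substitution $y = r\cos\omega$ (so $dr/r = dy/y$), which places the slant
nodes on the grid's own rows — midpoint nodes of step
$\Delta/\cos\omega$ — and never touches $r = 0$. This choice makes the
projector numerically identical to the transform the spectral inversion
inverts, which is why forward/inverse round trips converge cleanly as the
angular step shrinks.

**Lateral boundary.** Any FFT-based inversion assumes laterally periodic
sampling. `forward_cvlrt(periodic = TRUE)` matches that model exactly (V
arms leaving one edge re-enter at the other); it is the recommended mode for
studying the inversion itself. A finite truncated detector is the physical
acquisition: its missing far-field arms break the lowest few detector
frequencies (they would require arms at $\tau \approx \mathrm{aperture}/y$),
which the inversion repairs by re-fitting a low-order polynomial per row on
the region known to hold no activity — the compact-support assumption in
practice. The indeterminate zero frequency is repaired the same way in both
modes.

**Filtered back-projection.** `fbp_cvlrt()` ramp-filters each projection
(with a per-projection cutoff at the row-grid Nyquist, $|u| \le
1/(2\tau\Delta y)$), back-projects in real space along both half-lines with
angular substepping, and switches to the spectral Filon rule for the
strongly scattered tail ($\tau$ above `tau_split`, default 8) whose arm
motion per angular step exceeds the pixel scale. The two routes agree to a
fraction of a percent on smooth fields and are compared in the test suite.

## The collimated 3D modality

For the collimated camera the transform factorizes over transverse spatial
frequency $(u, v)$, $q = \sqrt{u^2 + v^2}$: each axial offset
$\sigma = |z_S - z_N|$ contributes a ring of radius $\sigma\,|\tan\omega|$,
whose transverse spectrum is the Bessel kernel
$J_0(2\pi q \sigma |\tan\omega|)$. Writing $t = \tan\omega$ and normalizing
the data by $K(\omega)\sin\omega/2$ gives, per frequency,

$$G(u, v, t) = \int_0^\infty \frac{d\sigma}{\sigma}\,
  J_0(2\pi q \sigma |t|)\; C_\pm(\sigma), \qquad
  C_\pm(\sigma) = \int \nu(z_N)\, \tilde f(u, v, z_N \pm \sigma)\, dz_N ,$$

with the two signs the two hemispheres $\omega \lessgtr \pi/2$ and
$\nu(d) = 1/d^2$ the photometric model. The Hankel-type identity

$$C(\sigma) = -2\pi q \sigma \int_0^\infty t\, J_1(2\pi q \sigma t)\,
  \partial_t G(u, v, t)\, dt$$

recovers the axial correlation profile per branch; the photometric smear
over vertex heights is then a small Toeplitz system in the $n_z$ plane
values, solved by least squares over both branches, and a 3D inverse Fourier
transform yields the map. This discrete, exact solve *is* the deconvolution
by the Fourier transform of $\nu$: it uses the actual $\nu$ samples over the
actual finite medium rather than the infinite-window idealization.

Numerical choices, in the order they matter:

* *Exponential $t$ sampling.* $|t|$ is sampled geometrically on each side of
  $90^\circ$ (`angle_grid_exp_t`), concentrating angles near the ends of the
  5–175 degree range where the weakly and strongly backscattered photons
  carry the high axial frequencies; a one-degree guard band around
  $90^\circ$ is excluded ($t$ diverges there). Uniform grids of equal size
  measure worse on the reference scene, and halving the angular step reduces
  the reconstruction error monotonically; both facts are test-covered.
* *Integration by parts.* Differentiating measured $G$ numerically
  (3-point Lagrange on the nonuniform grid, available as
  `deriv = "central"`) amplifies exactly the oscillatory content the grid
  barely resolves, and at the reference problem size it fails by an order of
  magnitude. The default route integrates by parts so the quadrature acts on
  $G$ itself, with $\int t J_0(bt)\,dt$ and $\int t^2 J_0(bt)\,dt$ evaluated
  in closed form against a piecewise-linear interpolant (the cumulative
  $\int J_0$ is tabulated once to $10^{-5}$).
* *Axial Nyquist cap and Gram correction.* As in 2D, the $t$ integral is
  capped at $1/(2 q \Delta z)$. Unlike the cosine case the Bessel closure is
  only asymptotically exact on the lattice, so the remaining cross-talk of
  the capped quadrature — its exact action on the $J_0$ basis, a computable
  $n_z \times n_z$ matrix per frequency — is folded into the axial
  least-squares solve. A second-difference penalty (`lambda`, default 0.02)
  settles the half-determined $\sigma$-Nyquist band.
* *Transverse zero frequency.* The identity degenerates at $q = 0$ (the
  plane means); they are restored per plane from the empty border frame of
  the reconstruction, again the compact-support assumption.
* *Two projector evaluations.* `method = "binned"` assigns voxel-level
  events to the angle bin of their exact scattering angle and is identical,
  term by term, to the brute-force event sum — the right model for wide
  energy windows, and the one the oracle-equality tests use. At dense
  angular grids the voxel lattice quantizes the scattering angle more
  coarsely than the bins, so `method = "spectral"` evaluates the ring
  spectra exactly ($J_0$, no angular binning); it is the transform the
  analytic inversion inverts and the one the experiment harness uses.

**Study design for the reference scene.** The cylinder-in-cube study
(16-voxel cube, cylinder height 6, angles 5–175 degrees, standoff 200 mm,
$n_e = 3.5\times10^{23}\,\mathrm{cm}^{-3}$, activity
$4.84\times10^{10}$ counts min$^{-1}$ cm$^{-3}$) leaves the cylinder radius
unstated; the package fixes it at 4 voxels and records it in the report. To
avoid the inverse crime of reconstructing data synthesized in the
reconstruction's own basis, the harness generates the projections with an
8-fold finer axial quadrature than the reconstruction model (4-fold,
sources staying piecewise constant per voxel). The reported error is then a
genuine convergence gap between two discretizations of the same continuum
transform — the same kind of discretization-limited figure a simulation
study reports. `scripts/acceptance.R` recomputes it from scratch (about
1.5 % relative L2 at these settings). The detector is modelled as a
laterally periodic 48-pixel grid: an oblique cone from a 16 mm object at
200 mm standoff lands far outside any camera of the object's own footprint,
and the periodic model is the exact counterpart of the Fourier inversion.

## The open (uncollimated) geometry

`forward_gccrt()` sums single-scatter events over every (source voxel,
vertex, pixel) triple, with the scattering angle measured between the legs
and the same weight convention as the collimated projector — so the
collimated event set is a subset with equal weights, and open-geometry data
dominate collimated data pixel-wise (test-covered as an exact inequality).
Vertices sit on the voxel grid of the medium (transversely at voxel centres,
axially at plane boundaries); directions are induced by the triples, so the
inscribed-angle condition $\angle SND = \pi - \omega$ holds exactly per
event and the vertex set for one (source, pixel) pair samples the stated
torus. The weight matrix collects each voxel's response at every angle; it
reproduces the projector to rounding, is entrywise nonnegative, and its
explicit storage makes the adjoint identity trivial to verify.

`cg_positive()` solves the normal equations by conjugate gradients with
Jacobi (unit column norm) preconditioning, projecting each iterate onto the
nonnegative orthant, restarting conjugacy whenever the projection clips, and
accepting a step only if the data misfit does not increase (backtracking
otherwise). The scheme is deterministic and parameter-free beyond the
iteration budget. On the reference 13x13x9 nested-cubes scene (30x30x15 cm
medium, 1 cm standoff, $E_0 = 140.1$ keV,
$n_e = 3.34\times10^{23}\,\mathrm{cm}^{-3}$) the harness reconstructs the
inner-cube mean to within a few percent; the detector is taken as 13x13
pixels aligned with the voxel columns (the reference reduces a 256-pixel
camera to 13x13 without stating the resulting pitch; aligning it with the
mesh keeps the collimated comparison exact).

## Phantoms and noise

The generators are deterministic given their arguments. The cylinder and
nested-cube scenes use the reference constants as defaults (1 mm pitch for
the 16-cube study; 23.1/16.7 mm anisotropic voxels for the open-geometry
scene). The thyroid image is a stylized stand-in built from ellipses — two
tilted lobes, an isthmus, and four nodules (two hot, two cold, contrast
0.8 of the lobe level) whose centres, radii and values are returned as
attributes so tests measure recovery against constructed truth rather than
against any particular figure. The Shepp-Logan phantom is the standard
10-ellipse table, clipped at zero. `add_poisson_noise()` draws seeded
Poisson counts per voxel at the configured dwell time (0.1 s per projection
in the reference settings) and rescales back to concentrations.

What passing tests show — and what they do not: the synthetic scenes are
noise-free or Poisson-perturbed voxel fields under exactly the single-scatter
model. Real acquisitions add multiple scatter, detector energy blur,
collimator response and septal penetration, none of which are modelled here;
a detector with $\Delta E$ energy windows sees the angle grid induced by
`angle_grid_from_energy()` (about half a keV per window is needed for the
axial resolution of the 3D study), and `energy_binning()` maps such windowed
counts onto angle bins conserving totals.

## Problem sizes

The shipped tests and the acceptance script run the studies at the sizes the
package adopts as its own: the 16-cube collimated study with 300 angles
(about a minute), the 13x13x9 open-geometry study with 24 angles and 400 CG
iterations (about two minutes), the 2D studies at 256 (thyroid) and 128
(Shepp-Logan) pixels with the reference angular step of 0.005 rad — exactly
314 projections over the quarter turn. The 512-pixel thyroid image of the
reference figures is available from the same generator
(`make_thyroid_2d(512)`) and runs through the same pipeline in a few
minutes.

## Known limitations

* Uniform attenuation is supported in every forward model but not undone by
  the analytic inversions (the algebraic route handles it through the weight
  matrix); non-uniform attenuation is out of scope.
* The electron density is constant by assumption; simultaneous recovery of
  activity and density from the same data is underdetermined and not
  attempted.
* Only first-order scattering is modelled.
* The analytic 2D inversion on a truncated (non-periodic) detector loses the
  aperture-limited lowest frequencies; the polynomial repair recovers smooth
  backgrounds but wide objects on narrow detectors remain aperture-limited.
  This is a physical limit of the acquisition, not of the algorithm.
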