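---
title: "Near-field holotomography of wood xylem: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Near-field holotomography of wood xylem: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(holoxylem)
```

# The imaging problem

Wood anatomy at the cell-wall level — pit chambers, pit membranes a few
hundred nanometres thick, slit-shaped pit canals — sits below the
resolution of laboratory micro-CT. Near-field holography (NFH) images such
weakly absorbing tissue by phase contrast: a nano-focused X-ray beam
diverges from a focal spot, the specimen sits a short defocus distance
`z1` behind the focus, and free-space propagation to a distant detector
turns phase shifts into measurable intensity fringes. Recording full
tomographic scans at several defocus distances and inverting the fringes
computationally yields a 3D map of the refractive-index decrement
$\delta$ at a ~26 nm voxel pitch.

`holoxylem` implements this chain end to end as testable code: synthetic
wood-anatomy phantoms, a wave-optical hologram simulator, flat-field
correction and geometry refinement, multi-distance phase retrieval with
support and range constraints, stripe removal, filtered backprojection,
and region-growing morphometry. Because no public NFH wood dataset
exists, the phantoms are first-class citizens: their construction
parameters are the reference dimensions that the pipeline must recover.

# Geometry and the Fresnel scaling theorem

The cone beam from a point focus is never simulated explicitly. A
hologram recorded with focus–sample distance $z_1$ and focus–detector
distance $z_\mathrm{det}$ equals a parallel-beam hologram at

$$M = \frac{z_\mathrm{det}}{z_1}, \qquad
  z_\mathrm{eff} = \frac{z_1 (z_\mathrm{det}-z_1)}{z_\mathrm{det}}, \qquad
  \Delta x_\mathrm{eff} = \frac{\Delta x_\mathrm{det}}{M}.$$

With the effective pixel as length unit the propagation regime is set by
a single dimensionless number, the Fresnel number per pixel

$$F = \frac{\Delta x^2}{\lambda\, z_\mathrm{eff}},$$

about $8.6\times10^{-5}$ for the reference geometry (11 keV, $z_1$ = 70
mm, detector at 16.269 m, 26 nm pixel) — order $10^{-4}$. Conventions for
$F$ differ between authors (feature size or field of view instead of the
pixel); this package always means the per-pixel definition above.
`geometry_config()` stores only the primitive scan parameters; every
derived quantity is recomputed on demand (`geometry_derived()`), never
cached, so it can not go stale.

# Phantoms

Two reference phantoms emulate the study specimens at desk scale, both
as labelled voxel grids (0 air, 1 cell wall, 2 pit membrane, 3 gallium)
at 26 nm pitch on a 256³ grid (a 6.7 µm cube):

* **Pit pair** (`build_pit_pair_phantom()`): two fused wall slabs
  perpendicular to the canal axis; a biconvex chamber formed by two
  half-ellipsoid caps whose flat bases (diameter 4,230 nm) face each
  other across a planar, unaspirated membrane (428 nm); slit-shaped
  canals (stadium cross-section, long axis 1,053 nm) connecting the
  chamber apices to the lumina. The caps are half-ellipsoids rather than
  spherical caps so that the maximal chamber diameter is realized
  immediately adjacent to the membrane: with spherical caps the lens
  narrows by almost two voxels within the first voxel beside a 428 nm
  membrane, and no measurement on the rasterized void could return the
  nominal diameter. The slit's minor width (312 nm) and the chamber
  depth (1,988 nm) are free parameters of the model; the reference only
  fixes the three printed dimensions.
* **Tracheid wall cross** (`build_tracheid_phantom()`): square lumina
  separated by fused double walls of total thickness 3,617 nm on a
  square lattice; at the default grid this gives one central wall cross
  and four lumina.

Both phantoms live inside a finite cylindrical pillar (radius 0.47 of
the in-plane extent, height 0.94 of the vertical extent), mirroring
FIB-milled specimen pillars. The pillar serves three numerical purposes:
projections are never truncated at any rotation angle, the exit wave
equals the vacuum value on the frame border (so padding the forward
model with vacuum is exact), and the projection footprint provides a
support constraint for retrieval.

Optical constants come from the classical electron-density relation
$\delta = r_e \lambda^2 n_e / 2\pi$ with $n_e = \rho N_A (Z/A)$:
cellulose-like wall material ($\rho$ = 1.5 g/cm³, $Z/A$ = 0.53,
$\delta \approx 2.7\times10^{-6}$ at 11 keV) and metallic gallium
($\rho$ = 5.91, $\delta \approx 9.0\times10^{-6}$). Absorption is set as
a fraction of $\delta$ (1% for the wall polymer, 5% for gallium) —
weakly absorbing, as appropriate for light matter at 11 keV; all values
are overridable.

**Gallium coating.** FIB preparation implants gallium on specimen
surfaces. `add_gallium_layer()` relabels a surface shell of wall voxels
of the requested thickness (the k-iteration morphological boundary
peel). The `faces` argument selects the exposure directions; the
pipeline profiles coat along the milling direction only (`"+x"`,
`"-x"`): implantation is directional and cannot reach surfaces shadowed
inside the pit chamber and canal, and an all-faces peel would wrap the
312 nm canal slit in an unphysical gallium tube. The coating thickness
(78 nm, 3 voxels) is a free parameter; the reference reports only that
contamination was present.

**Illumination.** `make_illumination()` builds mean-one flat fields with
a horizontal sinusoidal ripple plus a few sharp horizontal stripes,
emulating monochromator artifacts in the illumination. Horizontal means
constant along the transverse detector coordinate `u` and varying along
the vertical coordinate `v`.

# Forward model

The projection approximation gives the exit wave
$u = \exp(i\varphi - \mu)$ with
$\varphi = -(2\pi/\lambda)\sum_m \delta_m t_m$ and
$\mu = (2\pi/\lambda)\sum_m \beta_m t_m$, where $t_m$ are per-material
thickness maps from bilinear-interpolated line integrals
(`project_thickness()`). Propagation uses the Fourier transfer function

$$H(\nu) = \exp\!\left(-i \pi |\nu|^2 / F\right)$$

(sign convention: $e^{+ikz}$ carrier, nonpositive phases, positive first
CTF lobe — asserted by the weak-object closed-form test). The simulator
embeds the exit wave in a factor-2 zero-padded frame at the vacuum value
and propagates without windowing; because the pillar ends inside the
frame this padding is exact, not an approximation. The generic
`fresnel_propagate()` additionally offers raised-cosine edge apodization
for fields that do not decay to their background at the frame border.

Per angle and defocus distance the recorded frame is
$|u_z|^2 \cdot I_0$, optionally Poisson-sampled at a configurable
photons-per-pixel scale (default 5,000 in the pipeline; exposure is
printed in the reference but photon flux is not, so the noise scale is a
free parameter). All randomness is seeded.

# Phase retrieval

**Linear path.** For a weak phase object each flat-corrected hologram
obeys the contrast-transfer relation
$\widetilde{I-1}(\nu) = 2\sin(\pi|\nu|^2/F_d)\,\tilde\varphi(\nu)$.
`ctf_retrieve()` inverts this jointly over the distances by
Tikhonov-regularized least squares ($\alpha$ added to the summed squared
CTF; default $10^{-3}$). The mean phase is not encoded (the CTF vanishes
at $\nu = 0$); it is re-anchored on the frame-border median, where the
field is vacuum.

**Nonlinear path.** Projected phases of the reference phantoms reach
−3.15 rad — far outside the weak-object regime — so the pipeline refines
the CTF estimate by iterative projections (`iterative_retrieve()`)
between (a) the data sets (propagate, replace the modulus by $\sqrt I$
on the measured window, back-propagate, average over distances) and
(b) the object constraint set: phase clipped to `[phase_min, 0]`
(negativity), amplitude to `[amp_min, 1]`, vacuum outside the support
mask. All iterations run on the factor-2 padded grid and replace moduli
only on the measured window, which keeps forward and backward
propagation exact inverses of each other. Three update rules are
provided — averaged alternating projections (`"aap"`), the
Douglas–Rachford difference map (`"dm"`, the default: on the reference
phantom it reaches a given misfit in roughly a fifth of the AAP
iterations) and RAAR (`beta` = 0.75).

Two numerical details matter at strong phase:

* *Branch selection.* Phases slightly beyond $-\pi$ are wrapped by
  `Arg()` to $+\pi$, where a naive nonpositive clamp would destroy them.
  When `phase_min < -pi` the wrapped values are unambiguously mapped
  back below $-\pi$ (the constraint range is nonpositive, so no genuine
  positive phase can occur there).
* *Warm starts.* `retrieve_phases()` can chain angles (initialize each
  angle from its neighbour's solution) and sweep multiple passes. This
  reaches lower per-angle misfit at a third of the compute, but the
  residual errors become correlated across angles and backproject into
  ring artifacts centred on the rotation axis — precisely where the pit
  is measured. The pipeline therefore cold-starts every angle
  independently (14 iterations from the CTF estimate for the pit
  profile, 10 for the coarser wall profile); the warm-start path
  remains available for interactive use.

The pipeline derives the constraint box from its own study conditions:
the phase floor is the phantom's worst-case projected phase (sampled at
four angles, 10% headroom — a fixed floor clipped genuine gallium-sheet
columns in early designs), `amp_min = 0.8` (true amplitudes stay above
0.85), and the support is the projection footprint of the specimen
pillar plus a 2-pixel margin. In a real experiment the phase floor would
be estimated from a preliminary reconstruction. No single-material
(homogeneity) constraint is imposed: the specimen has two materials
with very different refractive indices, and the three defocus distances
are the compensating constraint. A consequence of the nearly equal
distances is a genuine very-low-frequency blind spot (scales beyond a
few hundred pixels): reconstructed plateau levels of large uniform
regions can sit below truth even when edges are sharp, which is why the
measurements below are designed to be local.

**Geometry refinement.** `refine_fresnel_number()` grid-searches F
around a starting value, scoring each candidate by the total variation
of the single-shot CTF inversion: residual defocus fringes raise the TV,
so the minimum marks the correct F (the criterion function is
pluggable). Magnification alignment across distances is analytic
(`M_ref/M_i`); `register_multidistance()` applies it and removes
residual shifts by cross-correlation with local-DFT subpixel refinement.
The simulator emits all distances on one common effective-pixel grid, so
the pipeline registers with `rescale = "none"` (and, being jitter-free
and co-registered by construction, skips registration by default).

# Destriping

Stripe artifacts from the illumination survive flat-field correction
imperfectly and imprint the retrieved phases. `destripe()` separates
them by a wavelet–Fourier decomposition: per level of a Haar pyramid,
the subband that is low-pass along the stripe axis and high-pass across
it is Fourier-transformed along the stripe axis and its stripe-aligned
(zero-frequency) coefficients are damped. The damping is
outlier-limited rather than a plain notch: a coefficient is only
reduced towards 1.25x the magnitude of its immediate nonzero-frequency
neighbours. Stripes are exactly coherent along their axis and tower
above the band's local spectrum there, while object structure of finite
extent continues smoothly across the zero frequency — a plain notch
(tested during development) removed up to 0.8 rad of genuine anatomy
from ground-truth projections, the outlier-limited version is
machine-precision-neutral on them. `damping_sigma > 1` adds a Gaussian
notch on the lowest nonzero frequencies for stripes that are not
perfectly uniform. Destriping operates on the retrieved phase
projections, after retrieval and before reconstruction.

# Reconstruction

`fbp_reconstruct()` is standard parallel-beam filtered backprojection
over the half turn: per-slice 1D ramp filtering and
linear-interpolation backprojection with the $\pi/n_\mathrm{angles}$
quadrature weight. The ramp is built from its band-limited spatial
impulse response ($h(0) = 1/4$, $h(\pm\,\mathrm{odd}) = -1/(\pi n)^2$)
rather than by sampling $|\nu|$, which would bias the DC level — the
analytic-disc oracle reconstructs to 0.1% with this filter. A Hann
window is applied by default (noise suppression); pure Ram-Lak is
available for oracle tests. Voxels outside the inscribed cylinder,
where a parallel-beam scan has only partial angular coverage, are
masked to zero. The rotation centre comes from correlating the first
projection with the mirrored last one (`find_rotation_center()`), with
the geometric centre as fallback; reprojection-based jitter alignment
(`align_projections()`) exists for jittered data and is off by default
for the jitter-free simulator. With `output = "delta"` the phase
sinogram is rescaled by $-\lambda/(2\pi\,\Delta x)$ so voxel values
estimate $\delta$ directly.

Note on display polarity: reconstructions here are $\delta$-proportional
(gallium > wall > air). Displays that render high $\delta$ dark — as in
the reference figures, where gallium appears dark — invert this; the
ordering on $\delta$ is the invariant.

# Morphometry

* `region_grow()` floods from a seed voxel, including 6-connected (or
  26-connected) neighbours within a grayscale tolerance of the seed
  value. 6-connectivity is the default: it is conservative against
  leakage through single-voxel diagonal gaps at the membrane. On
  noiseless single-level objects it provably equals global thresholding
  (tested voxel-for-voxel against that oracle).
* The pipeline Gaussian-denoises the tomogram (1 voxel) before growing
  — the symmetric kernel keeps 50% contours in place while restoring
  connectivity through noisy thin voids — and picks the chamber
  tolerance as half the contrast between the void level (a
  neighbourhood median at the seed) and the 80th percentile of the
  tomogram (a robust wall level), placing the mask boundary at the 50%
  contour. Each canal gets its own seed with a locally estimated
  contrast, mirroring ROI-based region-growing practice: the slit
  reconstructs at reduced contrast and a single global tolerance
  under-segments it.
* `wall_thickness()` measures, per probe line, the distance between the
  50%-contrast crossings of the two dominant edges. For symmetric
  (erf-like) edges the 50% crossing coincides with the gradient
  extremum, so the crossings are located as parabola-refined derivative
  peaks of the (lightly smoothed) profile — a purely local definition
  that is immune to the low-frequency plateau deficits described above.
  Probes whose profile shows more than two comparably strong edges
  (e.g. crossing two walls, or a gallium rim) are excluded and the mean
  is taken over the valid ones (default 4 arms × 5 probes via
  `wall_probes()`; the reference does not state its probe count).
* `pit_metrics()` measures on the void mask: membrane thickness as the
  gap between the two chamber voids along the canal axis (read as a
  3×3 majority vote of centre lines, robust to isolated noise voxels);
  maximal chamber diameter as the largest through-centre extent of the
  chamber void across membrane-parallel slices; canal width as the
  extent of the canal cross-section at the aperture (the last slice
  before the lumen, detected as the void filling the slice or the
  optional cylindrical ROI). Per-slice extents come from radial
  boundary casting — 72 rays from the canal axis, each direction's
  radius being the outermost mask voxel that ends a sustained void run
  and is followed by a sustained wall run — which tolerates both
  artifact holes inside the void and thin segmentation leaks through
  the wall, where connected-component Feret measurements proved
  brittle. A `direction_quantile` below 1 (the pipeline uses 0.7 for
  the round chamber; 1, the exact maximum, is the default and the
  clean-data contract) additionally ignores a few leak-contaminated
  directions. The pipeline reads the slit-canal width as the in-slice
  maximal extent, aggregated as the median across clean canal slices
  (the slit is prismatic along the canal, and "maximum width" in the
  reference denotes the slit's long axis within a slice). "Maximal
  chamber diameter" as a caliper extent on 2D slices is an
  interpretation of the reference's 2D-slice measurements and is
  documented as such. Extents count the unit width of the end voxels.
* `void_volume()` is voxel-count arithmetic: `count × pitch³`, the same
  definition as the reference's 1,220,270-voxel, 21.44 µm³ pit volume
  (21.447 µm³ exactly; the reference truncates).
* `exclude_gallium()` removes mask voxels above a $\delta$ threshold,
  reproducing the reference's observation that the contamination
  separates by thresholding.

# Scaled-down study conditions

The reference instrument records 900 projections of 2048² pixels at
three distances. The package's reference profiles run 180 angles at
256³/26 nm — the largest configuration that keeps a full
simulate–retrieve–reconstruct–measure cycle within minutes on one CPU —
and the methods are dimension-agnostic. Two consequences of the smaller
frame are worth knowing:

* At $F \approx 10^{-4}$ per pixel, holographic fringes of
  mid-frequency features spread across hundreds of pixels; a 256-pixel
  frame truncates more of them than a 2048-pixel frame. The weak-object
  CTF agreement test therefore runs at a geometry whose fringes fit its
  frame, and the reference-scale recovery tests go through the
  constrained iterative path, which tolerates the truncation.
* The three defocus distances differ by only ~1.4%, so their CTF zeros
  nearly coincide and the linear inversion leaves a genuine
  low-frequency hole; the negativity, amplitude-range and support
  constraints of the iterative path fill it.

What passing tests show: the implemented chain recovers the printed
wall, chamber and canal dimensions within ±2 voxels from its own
wave-optically simulated, noisy, artifact-laden data, and every stage
obeys its analytic oracle. The 428 nm membrane is the hardest quantity:
the retrieval residual leaves a shallow negative bowl around the
membrane disc that deepens the band-limit undershoot of the
reconstructed ridge, and its measured gap can read two to three voxels
narrow under photon noise (on noise-free data it reads within one
voxel). This is a genuine resolution limitation of the scaled-down
study conditions, not a segmentation artifact — every plateau-free
reading of the ridge agrees — and it is reported as measured. What they cannot show: performance on real detector
data (partial coherence, detector PSF, scintillator blur and flat-field
drift are out of the model), or membrane behaviour under moisture
change, which the phantom does not model.

# Reproducing the reference quantities

`scripts/acceptance.R` reruns both reference profiles from scratch at a
given seed and writes the four measured quantities (membrane thickness,
chamber diameter, canal width, double-wall thickness) as JSON; see the
README for the invocation.

# Known limitations

* The iterative retrieval operates per projection angle (the reference
  does not state whether retrieval was per-angle or joint); an
  angle-coupled scheme would regularize further but is future work, and
  naive warm-start coupling demonstrably produces ring artifacts.
* Ring-artifact correction in sinogram space and iterative (SART/CGLS)
  reconstruction are deliberately out of scope.
* The gridrec reconstruction of the reference is replaced by its
  mathematical equivalent (ramp-filtered backprojection); spectral
  equivalence on phantoms, not bit-level agreement, is the tested
  contract.
* The theoretical focus size quoted for the instrument (83 nm) does not
  follow from the Rayleigh criterion for the stated zone plate and is
  not reproduced here; the 26 nm effective pixel is taken as
  authoritative.
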