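---
title: "Models and methods behind spisort"
author: "spisort authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind spisort}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`spisort` sorts X-ray free-electron-laser single-particle diffraction
snapshots into single-hit and non-single-hit classes and evaluates the
3D models reconstructed from the selected patterns.  This vignette
documents the models, the numerical choices, and what the packaged
synthetic data can and cannot demonstrate.

## 1. The synthetic data generator

### Particle and intensities

The particle is a solid regular icosahedron (voxel inside iff
$\max_f \hat{n}_f \cdot \mathbf{v} \le r_\mathrm{in}$ over the 20 face
normals) with a denser interior core sphere mimicking packaged DNA,
optionally displaced toward a vertex.  Default geometry: a 32-voxel
grid, inradius 10 voxels, voxel size 2.8 nm, so the particle diameter
is ~70 nm — the scale of a tailless icosahedral coliphage.  Densities
are dimensionless contrasts (capsid 1, core 1.5); a Gaussian blur of
1 voxel softens the facet edges, as a map at this resolution would
have.  The 3D intensity is $I(\mathbf{q}) = |F(\mathbf{q})|^2$ with
$F$ the centred DFT of the density zero-padded to 4× per edge (linear
oversampling 4, comfortably above the Nyquist factor of 2 that phasing
requires).  Friedel symmetry $I(\mathbf{q}) = I(-\mathbf{q})$ is exact
because the density is real.

### Frames

Detector frames are central slices of the rotated intensity volume
(trilinear interpolation), a *flat-Ewald* approximation: at the
small-angle resolutions simulated here (detector edge
$q \approx 0.56$ nm$^{-1}$, i.e. ~11 nm), Ewald-sphere curvature
displaces the slice by well under a voxel, so it is neglected and
documented as an approximation.  The default detector is 64×64 pixels
with the beam centre at pixel (33, 33), one volume-voxel of $q$ per
pixel.

* **Single hits** scale the slice to an expected photon budget (default
  10 000 photons/frame — bright-hit territory for a ~70 nm virus at an
  AMO-class instrument; per-frame photon statistics vary widely between
  instruments and runs, and the default was chosen once as a value a
  classifier study would call realistic and separable) and draw
  per-pixel Poisson counts.
* **Multi hits** combine complex structure factors *before* squaring,
  $F_\mathrm{tot}(\mathbf{q}) = F(R_1\mathbf{q}) +
  e^{i\mathbf{q}\cdot\mathbf{d}} F(R_2\mathbf{q})$, producing the
  interference fringes that make these frames poison for merging.  The
  separation $|\mathbf{d}|$ is uniform in 26–60 voxels — from
  just-touching particles to a few diameters — giving fringe periods of
  ~2–5 detector pixels.
* **Non-hits** are uniform-sphere droplet profiles
  ($I(q)/I(0) = [3(\sin qR - qR\cos qR)/(qR)^3]^2$, radius 20–60 nm)
  plus flat Poisson background.

Counts become ADU via gain 28 ADU/photon with Gaussian read noise of
4 ADU — a fixed, arbitrary calibration that the preprocessing module
inverts exactly in tests.  About 1% of pixels are marked dead to
exercise the Friedel repair.  Class counts follow largest-remainder
apportionment so printed fractions map to deterministic integers, and
the labelled training subset defaults to 200 patterns at 79 single :
121 non-single.  Orientations are uniform on SO(3) via normalized
4-Gaussian quaternions; every draw is governed by one integer seed.

**What the generator does not emulate:** detector panel gaps and
tiling, beam-intensity jitter, hydration layers and solvent contrast,
conformational heterogeneity, and Ewald curvature.  Passing tests on
this generator therefore demonstrate algorithmic correctness and
operating-point behaviour, not performance on experimental data —
selections and resolutions obtained from beamline datasets depend on
data and manual labels this package deliberately does not ship.

## 2. Preprocessing

The chain is bin → Friedel repair → photon conversion, after which the
integer photon patterns branch off (for orientation work) and the
classifier inputs continue through $\log(1+k)$ scaling and mean
normalization.

* **Binning** sums $f\times f$ blocks (photon conservation; a mean
  would discard counts) and masks an output pixel only when every
  contributing pixel was masked.
* **Friedel repair** replaces a masked pixel by its point reflection
  through the (possibly fractional) beam centre, located by nearest
  pixel without interpolation; pixels whose mates are masked or
  off-detector stay masked at 0.  Unmasked pixels are never altered,
  so the operation is idempotent.
* **Photon conversion** computes `round(ADU/gain)` (round-half-even)
  and zeroes every pixel whose analogue signal is below one photon —
  the "< 1 photon" reading is taken literally, so a 0.6-photon signal
  is zeroed even though it would round to 1.
* **Log scaling** uses the natural logarithm; since the subsequent
  mean normalization absorbs any global scale, the base is immaterial.
  The target mean defaults to 1.

## 3. The graph-cut classifier

Patterns are vertices of a k-NN graph (k = 10, Euclidean distance on
the flattened feature images, edge set symmetrized by union) with
locally scaled weights
$w_{ij} = \exp(-d^2(x_i, x_j)/\sigma_i\sigma_j)$.

**The local scale.** $\sigma_i$ is the root-mean-square of the
distances from $x_i$ to its $k$ nearest neighbours — the standard
deviation of the neighbours *about the point itself*.  The centred
standard deviation of the neighbour distances is the other reading of
"standard deviation" here; it is one to two orders of magnitude smaller
than the distances in a 4096-dimensional feature space, which drives
every $d^2/\sigma_i\sigma_j$ to $10^3$–$10^5$ and all weights to exact
zero.  The RMS convention keeps the exponent of order one, which is
what local scaling is for, and is the choice under which the
classifier actually reaches its expected operating point (above 96%
accuracy on the packaged data); it is a documented design choice of
this implementation.

**Region force.** The class-1 prior of vertex $x$ is the
similarity-weighted vote of the labelled seeds,
$p_1(x) = \sum_{y \in S_1} w(x,y) / \sum_{y \in S} w(x,y)$, evaluated
directly against every seed with the same locally scaled kernel,
clipped to $[10^{-6}, 1-10^{-6}]$; seeds are pinned at $1-\epsilon$ for
their own class.  Unary costs are $C_1 = -\log p_1$,
$C_0 = -\log(1-p_1)$.  Other region-force constructions exist; this
similarity-weighted vote is the one this package defines and tests.

**The functional and solver.** The labelling field $u \in [0,1]^V$
minimizes
$$E(u) = \sum_x [C_1(x)u(x) + C_0(x)(1-u(x))]
        + \lambda \sum_{(i,j)} w_{ij} |u_i - u_j|,$$
the convex relaxation of the binary min-cut; its dual is a max-flow
problem, and the implementation is a Chambolle–Pock primal–dual scheme
whose dual variable is the edge flow.  Steps satisfy
$\tau\sigma L^2 \le 1$ with $L$ the operator norm of the incidence
matrix estimated by 30 power iterations; iteration stops at a relative
duality gap of $10^{-6}$ (cap 4000, best iterate returned with a
warning otherwise).  Classes are cut at $u > 0.5$, strict, so a score
exactly at the threshold is class 0.  By the co-area property the
threshold choice is immaterial on instances with a unique discrete
optimum, which the tests verify against exhaustive enumeration.

**$\lambda$.** The default is 0.1, chosen by a coarse grid
(0.1/0.3/1/3 giving 99.4/97.9/85.1/83.4% transductive accuracy on the
packaged 700-pattern dataset).  Larger $\lambda$ over-smooths: the TV
term begins to overrule confident unary evidence near the class
boundary.

## 4. The convolutional network

The default specification has exactly 316 trainable parameters on
64×64 inputs: three 3×3 convolutions without bias (channels 1→2→2→3,
weights 18+36+54), batch norm after each (scale+shift, 4+4+6), ReLU,
2×2 max-pooling (64→32→16→8) and dropout (rate 0.2) per stage; flatten
(192), one hidden dense unit with bias (193), and a bias-free sigmoid
output unit (1).  This is one consistent realization of the printed
parameter count, with hidden and output layers kept distinct.

The hidden dense unit uses **tanh**, not ReLU: its inputs (pooled ReLU
activations) are non-negative, so a single ReLU unit whose weights
initialize negative has an exactly zero gradient and can never
recover — an untrainable network, observed with the default
initialization.  tanh always propagates gradient; the conv stack keeps
ReLU.

Training: Adam (lr $10^{-3}$), batch 32, 200 epochs, binary
cross-entropy on logits, He initialization, batch-norm momentum 0.1
with running statistics frozen at inference, dropout active only in
training.  Forward and backward passes are written directly on R
arrays (im2col convolutions; the input gradient is computed as a
same-padded correlation with the flipped kernels), making training
bit-reproducible from one seed on one CPU — there is no deep-learning
framework underneath.  Gradients are verified against central
differences to $10^{-7}$ in the tests.

## 5. The diffusion map

Affinity $A_{ij} = \exp(-d^2/\epsilon)$ with $\epsilon$ = median
squared k-NN distance ("auto", making the embedding invariant to
global feature rescaling); row normalization $P = D^{-1}A$ computed
through the symmetric conjugate $D^{-1/2}AD^{-1/2}$ (same spectrum,
stable eigenproblem); plain row normalization (no density correction)
is used.  The trivial constant eigenvector is dropped; the next
$m = 5$ eigenvectors, scaled by $\lambda^t$ with diffusion time
$t = 1$, are the coordinates.  Labelling is nearest-centroid from the
seeds with score $d_0^2/(d_0^2+d_1^2)$ — a deliberately simple rule,
since clustering on diffusion coordinates is inherently
problem-specific.  Dense eigendecomposition is used below 2000
patterns.

## 6. Phase retrieval

One iteration works between two constraint sets: the **modulus** set
(Fourier amplitudes equal $\sqrt{I}$ on measured voxels; unmeasured
voxels float freely) and the **support** set, re-selected every
iteration as the `support_size` voxels with the largest positive
density, with negativity clipped to zero inside.

Selecting by *positive part* rather than by magnitude makes the
support step the exact Euclidean projection onto "at most $N$
non-negative non-zero voxels" — and exact projections are what make
the error-reduction error monotone.  Ranking by $|\rho|$ can admit a
large negative voxel that is then zeroed, which breaks the projection
property and, with it, the guaranteed monotonicity; the difference is
negligible on converged runs but the monotone variant is the one whose
error trace is provably non-increasing, and the tests assert exactly
that.  Ties are broken toward the smallest voxel index, so the
support is deterministic.  Positivity itself is a modelling choice —
electron density is non-negative — consistent with averaging real
maps.

* **Error reduction**: $\rho \leftarrow P_S P_M \rho$.
* **Difference map** ($\beta = 1$):
  $\rho \leftarrow \rho + P_S(2P_M\rho - \rho) - P_M\rho$, the common
  two-projection form to which Elser's general estimators collapse.
* **Schedule**: 100 ER, 200 DM, 200 ER; initial phases uniform in
  $[0, 2\pi)$ from the run seed.
* **Traces**: convergence $\|\rho_k - \rho_{k-1}\|_2 / \|\rho_k\|_2$
  and modulus error
  $\||F(\rho_k)| - \sqrt{I}\|_2 / \|\sqrt{I}\|_2$ over measured
  voxels.  Both are relative-$L_2$ normalizations, this package's
  stated convention; internally each iteration spends exactly one
  forward and one inverse FFT, the forward transform serving both the
  projection and the error trace.

Ensembles run 40 independent seeds.  Alignment tests integer circular
shifts and the inverted twin $\rho(-\mathbf{r})$ (the intrinsic twin
ambiguity) by FFT cross-correlation against the first run; rotational
alignment is unnecessary because all runs phase the same volume.  The
PRTF is $|\frac{1}{N}\sum_k e^{i\phi_k}|$ per voxel, shell-averaged,
with resolution read at the $1/e$ crossing.  For independent random
phases the PRTF concentrates near $N^{-1/2}$ ($\approx 0.16$ at
$N = 40$), the floor against which a real crossing is judged.

**Benchmark scale.** The packaged phasing benchmark is a 16-voxel
hard-edged particle at oversampling 2 (a 32³ volume) with the support
size set to the true particle voxel count; 40 runs of the full
schedule take a few minutes on one CPU and recover the ground truth
with correlation ≥ 0.95 in ≥ 35 runs, with ensemble PRTF ≥ 0.9 to the
edge shell.  The 2000-voxel default of `update_support` is the
support size appropriate to a production-scale experimental grid; the
benchmark instead uses the particle's own voxel count.

## 7. Metrics

* **Radial profiles** use $q = (4\pi/\lambda)\sin(\theta/2)$, reduced
  to $q \approx (\text{pixel step}) \times r$ in the small-angle
  regime; masked pixels are excluded and empty shells are NA, never
  zero.
* **R factors**:
  $R = \sum ||F_a| - |F_b|| / \sum(|F_a| + |F_b|)/2$ per shell and
  overall, with $|F| = \sqrt{I}$.  The symmetrized denominator is
  the package's stated convention, chosen to make $R$ symmetric in its
  arguments.
* **FSC**: $\mathrm{Re}\sum F_a F_b^* / \sqrt{\sum|F_a|^2\sum|F_b|^2}$
  per shell; resolution at the 0.5 crossing, reported as $1/q$ —
  with the $1/q$ (not $2\pi/q$) convention a crossing at
  $q \approx 0.1$ nm$^{-1}$ reads as a 10 nm resolution, the reading
  used consistently across the package's curves.
* **Orientation probabilities** (one EMC expectation step): Poisson
  log-likelihood $\sum_i [K_i\log W_{ij} - W_{ij}]$ of pattern $K$
  against slices $W$ rendered on an orientation grid (Fibonacci beam
  axes × in-plane angles), floored at $10^{-12}$, row-softmaxed under
  a uniform prior.  Note that with flat-Ewald slices, in-plane
  rotations $\psi$ and $\psi+\pi$ are Friedel-identical, so grids with
  an even in-plane count contain exact twins of every orientation;
  the uniform baseline $1/N_\mathrm{orient}$ and the $10^{-4}$
  low-confidence cutoff are the package's reporting conventions.
* **Eccentricity**: section planes from a Fibonacci lattice; each
  central section's boundary contour at half its maximum is traced
  sub-voxel along radial rays, and the *filled* region enclosed by the
  polar contour is fit by an ellipse through its exact area moments,
  $e = \sqrt{1 - \lambda_2/\lambda_1}$.  Second moments of the
  thresholded pixel set — the obvious alternative — carry 1–2%
  voxelization anisotropy, which $e$ (whose square is a *difference*
  of near-equal quantities) amplifies to $e \sim 0.1$ for a perfect
  digitized ball; the contour-integral estimator with a light Gaussian
  pre-filter (σ = 1.5 voxels) brings that artefact below 0.05 while
  remaining unbiased on a 2:1 ellipsoid (max section $e$ = 0.868 vs
  $\sqrt{3}/2 \approx 0.866$).

## 8. Reproducibility and problem sizes

Every stochastic step takes an explicit integer seed: dataset
generation, CNN initialization/shuffling/dropout, phasing starts.  The
packaged study sizes — 700 patterns (200 train / 500 held out) for
classification, a 32³ volume with 40 phasing runs, 40–120-orientation
grids for the E-step tests — were chosen once as the smallest sizes at
which the operating points of the methods are cleanly expressed, and
the test suite and acceptance script run them end to end.

## 9. Known limitations

* Transductive graph cut: no out-of-sample extension; classifying new
  patterns means rebuilding the graph.
* The CNN architecture is one consistent 316-parameter realization
  of the three-conv-plus-one-hidden-layer family; other layer layouts
  with the same count exist.
* The orientation E-step assumes a known intensity volume and a single
  fluence scale; no iterative merge, no per-pattern fluence fit.
* Flat-Ewald rendering bounds the validity of the generator to
  small-angle geometries (resolution coarse relative to the particle
  size).
* No shrinkwrap, HIO, or partial-coherence refinement in phasing.
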