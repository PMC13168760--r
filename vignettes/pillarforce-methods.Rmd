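---
title: "Methods: force, orientation and compaction quantification for two-pillar muscle microtissues"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: force, orientation and compaction quantification for two-pillar muscle microtissues}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pillarforce)
```

## The measurement problem

Engineered skeletal-muscle microtissues are commonly anchored between two
compliant vertical pillars. As the tissue matures it compacts, pulling the
pillars together (passive tension); under electrical stimulation it twitches
or tetanizes, deflecting the pillars further (active force). Because the
pillars are calibrated springs, every force of interest is read out from
microscope video as a pillar displacement. `pillarforce` implements that
readout chain end to end:

1. **beam mechanics** — pillar deflection to force via an elliptical-section
   cantilever model;
2. **orientation analysis** — myofiber alignment from fluorescence textures,
   summarised by a cosine-weighted orientation index;
3. **pillar tracking** — sub-pixel centroid tracking giving deflection and
   interpillar-distance (compaction) traces;
4. **contractility** — twitch, tetanus and force–frequency metrics under
   stimulation protocols, dose–response summaries and effect sizes;
5. **field model** — the stimulation-chamber electric field;
6. **synthetic data** — generators for every input, with exact ground
   truth, so the full pipeline is testable without raw microscopy.

## Beam model and its assumptions

A pillar is modeled as a clamped Euler–Bernoulli cantilever with elliptical
cross-section. For a lateral point load applied at height $h$ above the
base, the lateral stiffness is

$$k(h) = \frac{3EI}{h^3}, \qquad I = \frac{\pi a b^3}{4},$$

with $a$ the semi-major and $b$ the semi-minor axis, where $b$ is the
semi-axis **along the bending direction** (the pillars are elongated
orthogonally to the muscle axis precisely so that bending is biased along
the line of action). Force follows Hooke's law, $F = k\,\delta$, per
pillar; a two-pillar tissue exerting 76 µN in total loads each pillar with
38 µN.

Default parameters (all overridable in `pillar_geometry()`):

| parameter | default | meaning |
|---|---|---|
| `semi_major_a_um` | 300 µm | cross-section semi-major axis |
| `semi_minor_b_um` | 200 µm | semi-axis along bending |
| `height_h_mm` | 4 mm | load application height |
| `youngs_modulus_mpa` | 2.414 MPa | print-resin modulus (back-calculated from a force–displacement test) |
| `poisson_nu` | 0.49 | nearly incompressible elastomer |

These defaults give $k \approx 0.213$ µN/µm and a shear modulus
$\mu = E/(2(1+\nu)) \approx 0.81$ MPa. The package also accepts an
*empirically calibrated* spring constant wherever a stiffness is consumed
(the physical platform's mechanical calibration yields 0.249 µN/µm). The
two disagree by ~15%; the formula value assumes the load acts exactly at
the full pillar height, while the tissue in practice wraps the pillar head
somewhat lower and mechanical calibration absorbs print-geometry deviations.
We therefore treat the formula as the default and the calibration as an
explicit override — never a silent one: `resolve_stiffness()` errors when a
run configuration provides neither.

Assumptions and limits: linear elasticity and small deflections. The
linear model is exact for the algebra used here, and deflections beyond
10% of the pillar height are flagged (`pillarforce_large_deflection`
warning) rather than silently extrapolated. Geometric nonlinearity and 3D
solid effects are out of scope; an independent numerical oracle
(`cantilever_deflection_numeric()`, cumulative-trapezoid integration of
$w''(x) = M(x)/EI$) agrees with the closed form to $<0.1\%$ and guards
against algebra errors rather than model error.

`design_space_sweep()` reproduces the design logic for pillar dimensioning:
heights 3–5 mm in 0.5-mm steps and bending semi-axes 150–300 µm in 50-µm
steps at a fixed 1.5:1 aspect ratio, under a 38-µN reference load — taller,
thinner pillars deflect more and are therefore more sensitive force
transducers.

## Orientation index

Myofiber alignment is summarised from the binned angular distribution
$P(\theta_i)$ of fiber orientations on $[-90°, +90°]$ (36 bins of 5°,
centers $-87.5°,\dots,+87.5°$) as the cosine-weighted average

$$\mathrm{OI} = \sum_{i=1}^{K} P(\theta_i)\cos\theta_i .$$

Because $\cos\theta \ge 0$ on the range, $\mathrm{OI} \in [0,1]$: 1 for
fibers parallel to the interpillar axis ($\theta = 0$), 0 for perpendicular
fibers, and $2/\pi \approx 0.637$ for an isotropic texture. The discrete
uniform 36-bin distribution evaluates to 0.6368, i.e. 0.637 at three
decimals, converging to $2/\pi$ as the bins shrink. The constructor
refuses unnormalized weights rather than renormalizing, and the idealized
limits are representable exactly because `orientation_distribution()`
accepts arbitrary angle/weight pairs, not only binned histograms.

The histogram itself (`orientation_histogram()`) uses a tiled 2D Fourier
method: 64-px tiles with 50% overlap are Hann-windowed, the power spectrum
of each tile is accumulated into 5° angular sectors (spectral angle rotated
by 90° back to real-space fiber angle), and each sector is
density-corrected by its count of Cartesian frequency samples so an
isotropic texture maps to a flat histogram. Frequencies below $2/\text{tile}$
(DC leakage) and above 0.45 cycles/px (corner anisotropy) are excluded.
Angle convention throughout: 0° = horizontal interpillar axis,
counterclockwise positive with y up. Constant images yield a flagged
uniform histogram with a warning, not an error.

This is a spectral estimator, not a segmentation: it recovers the modal
angle of synthetic stripe textures within one bin down to SNR 5 and tracks
graded concentration monotonically, but its histogram is systematically
broader than the true angle distribution (finite tiles blur spectral
sectors). Tests therefore compare distributions with a bounded symmetric
chi-square distance rather than expecting bin-exact agreement.

## Pillar tracking

`detect_pillar_centroids()` is deliberately simple and deterministic:
global Otsu threshold, connected components, area filter, then an
intensity-weighted centroid over each surviving component. Requiring
*exactly* the expected number of components converts segmentation surprises
into hard errors naming the frame. Centroids are 0-based pixel centers;
on the synthetic fixtures localization error is below 0.05 px noiseless and
below 1 px at 10% Gaussian noise.

`track_sequence()` assigns identities by nearest neighbor between
consecutive frames and treats an assignment step larger than half the
current interpillar distance as a suspected identity swap (error, not
warning). Deflection is the signed displacement of each centroid along the
*frame-0* interpillar axis, with motion toward the opposite pillar
positive ("contraction positive"). Two conventions follow from this
choice:

* the first frame defines zero deflection, so pre-tension built up before
  recording is not recoverable from video — force estimates are relative to
  the recording start and underestimate absolute force when
  stimulation-evoked deflection is small next to pre-deflection;
* interpillar distance is measured centroid-to-centroid of the tracked
  pillar heads.

`compaction_metrics()` reports distance reductions over user windows
(positive = shortening), interpolating linearly between frames. A
fixed-length (spacer) culture regime appears as a zero-reduction trace.

## Contractility metrics

`force_trace()` applies $F = k\delta$ per pillar and also reports the
two-pillar sum. Metric extraction is deterministic and documented:

* **baseline** — median of the 2 s preceding the epoch (falling back to
  the epoch minimum when no pre-stimulus samples exist). Both this choice
  and the per-period maxima below make the metrics exactly invariant to a
  constant pre-tension offset.
* **twitch** (default 1 Hz epoch) — the epoch is sliced into stimulation
  periods; amplitude is the mean per-period maximum above baseline.
  Maxima must clear a noise floor of 3× the MAD-estimated trace noise;
  otherwise the amplitude is 0 with a warning.
* **tetanus** (default 90 Hz epoch) — mean of the last 50% of the epoch
  (the plateau, excluding the fusion transient) above baseline, plus the
  within-plateau ripple. Epochs shorter than twice the twitch relaxation
  time trigger an unreliable-plateau warning.
* **fusion ratio** — tetanic plateau over twitch amplitude; $>1$ indicates
  temporal summation.

`simulate_contraction()` provides the forward model used in testing: each
stimulus pulse contributes an alpha-like kernel
$g(t) \propto e^{-t/\tau_d} - e^{-t/\tau_r}$ (defaults
$\tau_r = 30$ ms, $\tau_d = 200$ ms, peak-normalized), kernels sum
linearly, and Gaussian noise is optional and seeded. This linear summation
is a deliberate simplification of excitation–contraction coupling: it
reproduces the qualitative physiology the metrics must resolve —
frequency-dependent fusion, a plateau exceeding the single twitch, a
non-decreasing force–frequency relation across 0.5–90 Hz — with a
closed-form steady-state mean ($A/\hat g \cdot (\tau_d - \tau_r) f$)
that the tests check against. It does not model fatigue, calcium dynamics
or length–tension effects.

`dose_response_summary()` gives per-dose means, SDs, vehicle-normalized
ratios and a monotonic-trend flag (sign of the Spearman correlation of dose
versus group mean). `effect_sizes()` reports pooled-SD Cohen's *d* and the
two-group $\eta^2$; inferential tests are intentionally left to the user's
statistical environment.

## Electric field model

`uniform_field_estimate()` is the parallel-plate estimate $E = V/d$
(40 V across 22 mm → 1.82 V/mm). `solve_field_fd()` solves the 2D Laplace
equation on a rectangular chamber cross-section with Dirichlet electrode
columns, zero-flux walls, and perfectly insulating inclusions handled by
dropping stencil links (zero normal flux), assembled sparsely and solved
directly; the residual is verified below $10^{-6}$ of the applied voltage.
The 2D section stands in for full 3D electrostatics on the grounds that
the stimulation well is shallow relative to its lateral extent; the demo
geometry is schematic because chamber dimensions beyond the electrode gap
are not part of the model. The solver reproduces the parallel-plate limit
to $<0.5\%$ and the classical perfect-insulator cylinder perturbation
(flank enhancement approaching $2E_0$), which is the behavior relevant to
parylene-coated pillars perturbing the field locally.

## Synthetic data: what it emulates, and what it does not

The generators define the study conditions under which the pipeline is
validated:

* **pillar sequences** — two soft-edged elliptical blobs (quartic radial
  falloff, so edges are smooth enough for sub-pixel centroiding) on a
  seeded textured background; 2.6-mm centroid spacing at 10 µm/px
  (260 px); compaction as a linear ramp split equally between pillars;
  contraction as an arbitrary per-frame waveform; Gaussian and Poisson
  noise options. Compaction cohorts default to 8 frames, emulating
  every-other-day imaging over 14 days.
* **fiber textures** — anti-aliased line segments with angles drawn from a
  wrapped normal around the modal angle (concentration $\kappa$, SD
  $1/\sqrt{\kappa}$ rad), uniform for "isotropic", rendered by bilinear
  splatting; SNR sets line contrast over Gaussian noise.
* **cohorts** — per-tissue artifacts with condition-dependent programmed
  effects: compaction means/SDs per condition (a spacer condition programs
  zero), or per-dose twitch-amplitude multipliers with 5% log-normal
  between-tissue variability for drug scenarios. Effect directions follow
  the studied compounds (glucocorticoid atrophy decreasing force,
  anabolic-androgen support increasing it); absolute effect magnitudes are
  free parameters, not encoded truth.

Everything is bitwise reproducible given (parameters, seed), and each
artifact carries its ground truth as an attribute. What the generators do
**not** emulate: optical blur and shading, debris and occlusion, tissue
deformation between the pillar heads, out-of-plane motion, photobleaching,
and non-stationary noise. Passing tests therefore demonstrate correctness
of the measurement chain under controlled imaging, not robustness to every
real-microscopy artifact; the hard-error contracts in detection and
tracking are the designed failure mode for inputs outside that envelope.

## Numerical choices and degenerate inputs

* Unit discipline: user-facing quantities are µm, mm, µN, MPa, Hz; SI
  conversions are centralized in one helper block (µN/µm is numerically
  N/m, which keeps the stiffness algebra free of factors).
* `cospi()` is used for the orientation index so the ±90° limit is exactly
  zero in floating point.
* Weights must sum to 1 within $10^{-9}$; histograms renormalize once
  after density correction to absorb rounding.
* Coincident centroids return distance 0 with a warning; constant frames
  and images are hard errors (detection) or flagged-uniform results
  (orientation), matching how each situation should propagate.
* Sweeps and grids are ordered deterministically by (height, section);
  per-tissue cohort seeds are derived affinely from the master seed, so
  cohorts are reproducible tissue-by-tissue.
* Problem sizes used in validation: 80×360-px frames (single sequences up
  to ~760 frames for stimulated videos), 256-px fiber textures, 5-point
  Laplace grids up to ~180×90 cells, cohorts of 10 tissues × 8 frames.

## Known limitations

* Absolute force accuracy inherits the stiffness calibration; the
  formula-vs-calibration gap (~15%) is irreducible from video alone.
* The orientation histogram is a blurred estimate of the angle
  distribution; OI values from strongly multimodal textures compress
  toward the middle of the scale.
* The tracker handles exactly the expected number of pillars; it is not a
  general multi-object tracker and makes no attempt at occlusion recovery.
* The field model is electrostatic and 2D; electrode polarization and
  medium conductivity are out of scope.
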