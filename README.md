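# pillarforce

Quantification pipeline for engineered skeletal-muscle microtissues
suspended between two compliant force-sensing pillars — the standard
readout geometry of muscle-on-chip contractility platforms. The package
turns microscope image sequences into calibrated contractile forces,
fiber-alignment indices, compaction metrics and dose–response summaries,
and ships a synthetic-data module that generates every input with exact
ground truth so the whole chain is testable without raw microscopy data.

It is written for tissue-engineering and microphysiological-systems labs
that record pillar-deflection videos and fluorescence fiber textures and
need a deterministic, scriptable alternative to interactive trackers and
image-analysis plugins.

## The models at the core

**Beam mechanics.** Each pillar is a clamped Euler–Bernoulli cantilever
with elliptical cross-section. For a lateral load at height *h*:

    k(h) = 3 E I / h³,   I = π a b³ / 4,   F = k δ

with *b* the semi-axis along the bending direction. Defaults (a = 300 µm,
b = 200 µm, h = 4 mm, E = 2.414 MPa, ν = 0.49) give k ≈ 0.213 µN/µm and a
shear modulus µ = E / (2(1+ν)) ≈ 0.81 MPa; an empirically calibrated
spring constant (e.g. 0.249 µN/µm from mechanical testing) can be supplied
anywhere a stiffness is consumed. A numerical beam oracle cross-checks the
closed form to < 0.1%.

**Orientation index.** Fiber alignment is summarised from the binned
angular distribution P(θ) on [−90°, +90°] (36 bins of 5°) as the
cosine-weighted average

    OI = Σᵢ P(θᵢ) cos θᵢ  ∈ [0, 1]

(1 = aligned with the interpillar axis, 0 = perpendicular, 2/π ≈ 0.637 =
isotropic), with the histogram estimated by a tiled, Hann-windowed 2D FFT
power spectrum binned by angular sector.

**Tracking and contractility.** Pillar centroids are detected per frame
(Otsu threshold → connected components → intensity-weighted sub-pixel
centroid), tracked with nearest-neighbor identity assignment, and
converted to deflection along the interpillar axis (contraction positive).
Twitch amplitude (per-period peaks above a pre-epoch baseline), tetanic
plateau (last half of the high-frequency epoch), fusion ratio,
dose–response tables with Spearman trend flags, and Cohen's d / η² effect
sizes follow. A finite-difference Laplace solver models the
stimulation-chamber field around insulating inclusions, next to the
parallel-plate estimate E = V/d.

## Worked example

Simulate a stimulated recording (1-Hz twitch epoch, then a 90-Hz tetanic
epoch), image it as a synthetic two-pillar video, and recover the force
metrics:

```r
library(pillarforce)

g <- pillar_geometry()
g
#> <pillar_geometry>
#>   cross-section: a = 300 um, b = 200 um (bending axis)
#>   height h = 4 mm, E = 2.414 MPa, nu = 0.49
#>   k(h) = 0.2133 uN/um

proto <- stimulus_protocol(1, epochs = tibble::tibble(
  t_start = c(2, 14), t_end = c(12, 18), frequency_hz = c(1, 90)))
sim <- simulate_contraction(proto, amplitude_un = 40, fs_hz = 40,
                            duration_s = 19)
video <- generate_pillar_sequence(n_frames = nrow(sim),
                                  contraction_um = sim$force_un,
                                  frame_rate_hz = 40, noise_sd = 0.1,
                                  seed = 1)
trace  <- track_sequence(video)
forces <- force_trace(trace, stiffness_un_per_um = 0.249)
glance(fusion_ratio(twitch_metrics(forces, proto),
                    tetanic_metrics(forces, proto)))
#> # A tibble: 1 × 4
#>   baseline_force_un twitch_amplitude_un tetanic_force_un fusion_ratio
#>               <dbl>               <dbl>            <dbl>        <dbl>
#> 1             0.275                10.0             250.         25.0
```

The programmed twitch deflection of 40 µm at k = 0.249 µN/µm corresponds
to 9.96 µN per pillar; the pipeline recovers 10.0 µN from the noisy video
(0.4% error), and the 90-Hz epoch fuses into a 250-µN plateau —
a fusion ratio of 25 with the default 200-ms twitch decay.

Orientation and field, in two lines each:

```r
img <- generate_fiber_image(modal_angle_deg = 0, concentration = 30, seed = 1)
oi_pipeline(img)
#> [1] 0.9650  # strongly aligned along the interpillar axis

uniform_field_estimate(40, 22)
#> [1] 1.818182  # V/mm, the parallel-plate estimate for the chamber
autoplot(solve_field_fd(chamber_spec()))
```

A thin command-line wrapper over the same functions ships at
`inst/cli/pillarforce` (subcommands `generate`, `track`, `oi`, `contract`,
`field`, `report`).

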