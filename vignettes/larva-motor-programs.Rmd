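---
title: "Models and methods: segment-resolved larval crawling analysis"
author: "larvagram"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: segment-resolved larval crawling analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(larvagram)
```

## The scientific problem

A crawling *Drosophila* larva navigates by alternating two motor programs:
peristalsis — waves of segmental contraction that travel from tail to head
and push the animal forward — and asymmetric contraction of a group of
anterior segments that swings the head sideways during reorientation
maneuvers. On a temperature stimulus the animal biases the frequency and
the size of these maneuvers (more and larger turns while cooling), which
is the behavioral basis of larval thermotaxis.

`larvagram` implements the full measurement chain for this behavior —
outline, head/tail and centerline extraction from fluorescence video of a
larva with labelled musculature, per-segment contraction and asymmetry
kymographs, peristalsis-wave and head-sweep event detection, and the
run-and-turn navigation statistics — together with a ground-truthed
synthetic video generator that emulates both motor programs. Every stage
of the analysis can therefore be validated by parameter recovery without
any external data.

## The body model and the two motor programs

The body is a chain of 11 segments (thoracic T1–T3, abdominal A1–A8)
along a planar spine. The *body coordinate* runs from 0 at the head tip
to 11 at the tail tip; segment $i$ occupies $[i-1, i]$. Default geometry:
2 mm body length, equal segment rest lengths, a width profile that is
widest (0.35 mm) over the mid-abdomen, tapers towards the anterior, and
ends in rounded tip caps (apex radii 20% and 30% of the body width) so
that both tips are well-resolved curvature maxima at the default pixel
scale of 0.01 mm/px. Dimensions are generator defaults, not biological
claims.

**Peristalsis.** A contraction pulse (raised cosine, half-width 1.5
segments) travels tail-to-head at constant speed; a segment under the
pulse peak shortens by the contraction amplitude (default 0.15). Pulses
take 2.0 s to traverse the body, so that at 8 Hz acquisition the
contraction peaks of adjacent segments are at least one frame apart —
the resolution limit of peak chaining. Forward translation is pulsed:
each wave advances the tail anchor by its per-wave displacement (drawn
around 0.13 body lengths, sd 0.013) through a smooth ramp placed midway
between the rearmost- and frontmost-segment contraction peaks. The wave
period (1/0.65 s) equals the peak-to-peak window of one wave, so the tail
displacement accrued between a detected wave's first and last peaks is
exactly one wave's displacement — the property the per-wave displacement
measurement relies on (verified numerically to machine precision and
robust to one-frame detection jitter).

**Head sweeps.** A sweep adds a signed curvature-density profile over the
pivot segments (T3–A3), an asymmetric raised cosine peaked at A1. The
amplitude rises smoothly (0.7 s), plateaus briefly, and is calibrated per
body so that the *operational bend angle* (below) attains the target
sweep size exactly. Because the offset boundaries follow the spine, the
left/right side-length asymmetry $a = \ln(L_\mathrm{right}/L_\mathrm{left})$
emerges from the geometry rather than being painted on: a leftward bend
shortens the left (inner) sides of the pivot segments, so $a > 0$.

**Straightening.** After the accepted sweep, peristalsis resumes — at the
tail for small sweeps (< 90°), or at the posterior edge of the bent
region for large sweeps (≥ 90°), mirroring the observed initiation-site
switch. Each straightening wave translates the curvature profile
tail-ward by `segmentsPerWaveAroundBend` (default 2) segments as the
pulse passes through it. Curvature mass carried past body coordinate
10.4 (the rigid tail cap) is absorbed into the base heading: the body
re-aligns with the head's new direction, and the operational bend angle
declines gradually, reaching the straightened criterion after about 3
waves for small and 3–4 waves for large sweeps. The heading bookkeeping
keeps the head direction fixed during straightening (the tail swings into
line), so a completed maneuver changes the run heading by exactly the
accepted sweep angle.

**Behavior program.** Reorientation onsets are an inhomogeneous Poisson
process with phase-specific rates (warming/cooling by the sign of the
smoothed temperature derivative, threshold 0.001 °C/s). Sweep sizes are
drawn from a normal truncated to [45°, 130°] whose location parameter is
solved so the *realized* (truncated) mean equals the configured Table
value — the printed field statistic is a mean over flagged (> 40°)
sweeps, so the configured value is interpreted the same way. Each
non-final sweep is rejected with a logistic probability in d$T$/d$t$
(baseline 0.3 at zero, raised by cooling), producing multi-sweep
maneuvers separated by single intervening waves. Onsets that arrive
during an ongoing maneuver are deferred, never dropped, so the realized
event rate matches the configured rate; maneuvers are kept short enough
(≈ 5–8 s) that this queueing rarely carries an event across a phase
boundary. A maneuver starts only after the last initiated wave has
completed, reproducing the observed motor-program sequencing.

## The measurement chain

Per frame: Otsu threshold (configurable), one erosion + dilation with a
2 px disk, boundary of the largest component, a half-pixel outward-normal
offset (boundary tracing follows the centers of edge pixels, which sit
about half a pixel inside the true boundary), and circular Gaussian
smoothing of the vertices with sd equal to 0.5% of the vertex count.
Signed curvature comes from the turning angle across a sliding window of
20% of the boundary length; the head and tail are the two highest
curvature maxima separated by at least a quarter of the perimeter,
disambiguated by proximity to the previous frame (ground truth or user
input seeds the first frame). A second, fine-scale pass (6% window,
±7% neighbourhood) re-localizes each tip: the broad window is robust for
candidate selection but its maximum drifts when a body bend sits next to
a tip. The centerline is the sequence of midpoints between the two side
arcs resampled to 51 equal-arc points.

The **operational bend angle** θ is the signed angle from the
tail-to-midpoint vector to the ¾-point-to-head vector, with fractional
positions measured *from the tail* (so the ¾-point is anterior, next to
the pivot); leftward is positive. Image coordinates are y-down, so all
vision geometry is computed in a flipped y-up frame to keep "leftward
positive" aligned with the animal's left. Head sweeps are flagged when
|θ| reaches 40° and released below 20° (hysteresis; the release value is
a design choice to prevent chatter) or on a sign flip; events shorter
than 3 frames are discarded as tracking glitches, and dropout gaps of up
to 2 frames are bridged. Because θ plateaus at the peak while the bent
region is already moving tail-ward, the reported peak frame is the
*first attainment* of the peak (within 2°), which is the frame at which
the unshifted pivot should be measured.

Segment metrics use the 20-point boundary annotation (from generator
ground truth, or a CSV for hand-clicked data) snapped to the nearest
outline vertices, with arc positions refined to sub-vertex accuracy by
projection. A segment's side length is the outline arc length between
its bounding points — the quantity that enters
$a = \ln(L_\mathrm{right}/L_\mathrm{left})$; the transverse-chord
reading would not support that asymmetry index. Quadrant intensities
split each segment by the chord between side-arc midpoints and the local
midline, insetting each polygon by 1 px to avoid edge-pixel mixing.
Fractional-change kymographs use a reference frame chosen in two passes:
a provisional first-frame reference supports an initial wave detection,
then the inter-wave frame with minimal total fractional length deviation
becomes the reference and the kymographs are rebuilt once.

Waves are detected by chaining per-segment contraction peaks (≥ 5%
fractional change) that progress head-ward with inter-segment lags of
1–16 frames (one skipped segment tolerated, minimum chain 4 segments).
Maneuvers merge consecutive sweeps unless |θ| stayed below 20° for at
least 1 s between them; the last sweep is the accepted one. Waves to
straighten are counted from the accepted sweep's *peak* until the
straightened criterion first holds — counting from the hysteresis
release would miss the waves that do the straightening, since release
(20°) coincides with the straightened threshold.

## Parameters that matter

| parameter | units | default | rationale |
|---|---|---|---|
| `frameRate` | Hz | 8 | acquisition rate of the imaging rig |
| `pixelScale` | mm/px | 0.01 | 2 mm body ≈ 200 px |
| `waveRate` | s⁻¹ | 0.65 | equals 1/(peak-to-peak window) so per-wave displacement is measurable |
| `waveTraversal` | s | 2.0 | keeps inter-segment peak lag ≥ 1 frame at 8 Hz |
| `displacementPerWave` | body lengths | 0.13 | published forward displacement per wave |
| `contractionAmplitude` | fraction | 0.15 | gives 10–20% fractional intensity peaks |
| `pivotAnterior/Center/Posterior` | labels | T3/A1/A3 | published pivot extent and peak |
| `segmentsPerWaveAroundBend` | segments | 2 | published bend progression per wave |
| `turnRateWarming/Cooling` | min⁻¹ | strain presets | published reorientation rates |
| `sweepMeanWarming/Cooling` | deg | strain presets | published first-sweep sizes |
| `sweepSd`, `sweepMin`, `sweepMax` | deg | 10, 45, 130 | spread and truncation of sweep sizes |
| `rejectionBaseline`, `rejectionScale` | –, °C/s | 0.3, 0.025 | logistic rejection model in d$T$/d$t$ |
| `noiseSd` | fraction | 0.02 | additive camera noise (of rest intensity) |
| `sweepThreshold` / `sweepRelease` | deg | 40 / 20 | flag onset / hysteresis release |
| `curvatureWindowFrac` | fraction | 0.20 | head/tail curvature window |
| `boundarySmoothFrac` | fraction | 0.005 | outline smoothing width |

Strain presets: `canton_s` (warming 3.2, cooling 3.8 min⁻¹; sweeps
53°/57°; thermotaxis drift 0.075 mm/s) and `mhc_gfp` (2.6/3.8; 53°/60°;
0.055 mm/s), following the published wild-type and transgenic values.

## What the generator does and does not emulate

It reproduces: conserved-fluorophore rendering (contraction concentrates
signal, so per-segment mean intensity × area is constant to machine
precision), per-frame recentering by the tracking stage with recorded
origins, phase-dependent Poisson reorientations, truncated sweep-size
distributions, rejection-driven multi-sweep maneuvers, tail- versus
within-bend wave initiation, and the two-segments-per-wave bend
progression.

It does not emulate muscle-fiber texture, three-dimensional rolling or
hunching, self-overlapping (curled) postures, illumination gradients, or
photobleaching. Passing recovery tests therefore validates the
measurement chain's geometry and statistics, not its robustness to every
artifact of real video. Two caveats carry over to real data: the side
lengths of the triangular tip segments (T1, A8) depend strongly on the
exact tip position — the recovery tests hold the interior segments to 2%
and the tip segments only to 10% — and head-sweep sizes of merged
same-direction sweeps are reported as a single event.

## Numerical choices

* Half-pixel outward offset of traced boundaries removes the systematic
  area (−4%) and tip-position (~1.5 px) bias of pixel-center tracing.
* Two-scale tip refinement keeps tail localization within 3 px even when
  a residual bend sits next to the tail late in straightening.
* The rigid tail cap (body coordinate > 10.4) prevents the bend profile
  from curling the tail tip, which would make the tip ambiguous for any
  curvature-based detector.
* Sweep amplitude is calibrated against the same operational-midline θ
  the pipeline measures, by inverting a 30-point monotone grid.
* Degenerate inputs raise classed conditions (`larvagram_no_larva`,
  `larvagram_too_small`, `larvagram_self_occlusion`,
  `larvagram_misregistration`, …) rather than propagating NAs silently;
  per-frame failures are recorded and skipped by the drivers.
* Ties in wave-peak chaining resolve to the latest compatible chain;
  chains shorter than 4 segments are discarded.

## Problem sizes

The test suite validates recovery on a 5-minute rendered run
(~195 waves), a two-maneuver rendered sweep video, 90 minutes of
event-level behavior for turn rates, 75 minutes for sweep sizes
(> 100 maneuvers per phase), 20-minute speed tracks, a 20-animal
drift population, and 10–11 rendered maneuvers for the straightening
statistics; these sizes give 3-standard-error recovery bands a few
percent wide while keeping the default suite in a few minutes on one
core. `scripts/acceptance.R` re-runs the same measurements from scratch.

## Known limitations

Tip-segment metrics are measurement-limited (above). The event-level
fast path (`geometry = "theta"`) skips rendering, so it validates the
kinematic and statistical stages but not the vision stage. At turn rates
well above ~4 min⁻¹ maneuver queueing would begin to blur phase
attribution of events near phase boundaries. The quarter-annulus
centerline approximation degrades for |θ| beyond ~140°, and such deeply
curled postures are rejected by the self-occlusion guard rather than
measured.
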