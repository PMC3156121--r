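# larvagram

Segment-resolved analysis of crawling *Drosophila* larvae for researchers
studying larval locomotion and thermotactic navigation. The package
implements the full measurement chain for fluorescence video of a larva
with labelled musculature — body outline, head/tail and centerline
extraction, the signed body-bend angle, per-segment contraction and
asymmetry kymographs, peristalsis-wave and head-sweep detection, and
run-and-turn navigation statistics — plus a ground-truthed synthetic
video generator that emulates the two larval motor programs, so every
stage can be validated by parameter recovery without external data.

## The model in brief

The larva's body is 11 segments (T1–T3, A1–A8) along a midline. Two
motor programs drive navigation:

* **Peristalsis**: contraction waves travel tail to head, each advancing
  the body by ~0.13 body lengths. Contraction is measured two ways — the
  fractional change in each segment's left/right boundary lengths
  relative to an inter-wave reference image, and the fractional change in
  mean fluorescence intensity (muscle contraction concentrates the
  fluorophore, so intensity rises as length falls).
* **Asymmetric anterior contraction**: head sweeps are actuated by the
  pivot segments T3–A3 (peak at A1). The asymmetry index per segment is
  *a* = ln(*L*<sub>right</sub>/*L*<sub>left</sub>), positive for leftward
  bends. The body-bend angle θ is the signed angle between the
  tail-to-midpoint and ¾-point-to-head centerline chords (leftward
  positive); |θ| ≥ 40° flags a head sweep, and > 90° marks it large.

Reorientation maneuvers assemble one or more sweeps (all but the last
"rejected") with the peristalsis waves that straighten the body, each
wave carrying ~2 segments around the bend; turn frequency, first-sweep
size, forward speed and population thermotaxis speed summarize
navigation per warming/cooling phase (classified by dT/dt against
0.001 °C/s).

## Worked example

Simulate 30 s of crawling with one reorientation, run the vision and
event pipeline, and measure the motor programs:

```r
library(larvagram)
cfg <- simulationConfig()
ds  <- simulateLarvaDataset(cfg, duration = 30, seed = 1)
ds
#> LarvaDataset: 240 frames, 226x228 px, 241 temperature samples

meas <- analyzeSynthetic(ds@truth, cfg, images = ds@images)
ev   <- analyzeEvents(meas, cfg)
ev$waves[1:3, c("wave_id", "onset_frame", "init_segment",
                "term_segment", "speed_seg_s")]
#>   wave_id onset_frame init_segment term_segment speed_seg_s
#> 1       1           5           A8           T1    6.666667
#> 2       2          17           A8           T1    6.666667
#> 3       3          30           A8           T1    7.272727

d <- waveDisplacements(meas, ev$waves, bodyLength(larvaBodyModel()))
round(c(mean = mean(d, na.rm = TRUE),
        se = sd(d, na.rm = TRUE) / sqrt(sum(is.finite(d)))), 4)
#>   mean     se
#> 0.1225 0.0027

ev$maneuvers[, c("accepted_peak_deg", "size_class", "init_segment",
                 "init_class", "region_peak", "waves_to_straighten")]
#>   accepted_peak_deg size_class init_segment init_class region_peak waves_to_straighten
#> 1          53.69244      small           A8       tail          A1                   3
#> 2          47.91158      small           A8       tail          A1                   2
```

Every wave is detected travelling A8 → T1; the mean per-wave
displacement (0.12 ± 0.003 body lengths over this short clip) matches
the configured 0.13; both head sweeps are small, centered on A1, resume
peristalsis at the tail, and straighten in 2–3 waves.
`plot(ev$kymoLength)` and `plot(ev$kymoAsym)` draw the kymographs. A
command-line front end (`inst/scripts/larvagram`) chains
simulate → track → kymo → events → stats over an artifact directory with
a reproducibility manifest; `runPipeline()` is the R-level equivalent.

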