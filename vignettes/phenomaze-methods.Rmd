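---
title: "Methods: trajectory metrics, strategy classification and morphometry in phenomaze"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: trajectory metrics, strategy classification and morphometry in phenomaze}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenomaze)
```

phenomaze quantifies behavioural phenotypes of inbred mouse strains — the
BTBR strain, a widely used autism model, against C57BL/6 (B6) controls —
from tracked trajectories in three apparatuses (Morris water task, open
field, balance beam) and from histological sections (volumetry, cortical
thickness, cell density). This vignette documents the models and
conventions the package commits to, the tunable parameters and their
defaults, what the synthetic-data generator does and does not emulate, and
the numerical choices that matter when reproducing results.

## Coordinate frame and arena geometry

All positions are centimetres in an arena-centred frame: origin at the
arena centre, the positive y axis pointing to the "North" release point,
angles counter-clockwise from East. Quadrants 1–4 are the four 90° sectors
counter-clockwise from East, half-open in angle (`[0°, 90°)` is quadrant
1), so every point — including boundary rays and the centre, which maps to
quadrant 1 — receives exactly one quadrant.

The pool and the open field are 154 cm across. The escape platform
(radius 12 cm) sits on its quadrant's bisector half-way between centre and
wall, i.e. at radial distance 38.5 cm. The open field's central zone is the
concentric 52-cm disk. The beam is 92 cm × 1 cm. Release points sit 2 cm
inside the wall at the four cardinal positions. Tracked points may stray up
to 1 cm beyond the wall (tracking jitter) before a trajectory is rejected.

## Per-trial swim measures

* **Path length / speed** — polyline length of the track; binned speed
  splits the session into exact bins (four 5-min bins for the 20-min
  open-field session) with positions interpolated at bin boundaries. A
  session that does not divide into whole bins is an error rather than a
  silently truncated bin.
* **Latency** — time to first platform contact (centre-to-centre distance
  ≤ 12 cm), with the crossing solved exactly inside the straddling segment
  (the squared distance along a linear segment is quadratic in time).
  Trials with no contact are censored at the 60-s cap and flagged.
* **Corridor percent path** (the swim error index) — the percentage of
  path length inside the 20-cm-wide straight band from the release point
  to the platform centre, capped at both ends. Segments are clipped
  analytically (Liang–Barsky against the corridor-frame rectangle), so
  in-corridor plus off-corridor is exactly 100%. The band is capped at the
  platform *centre*, the simpler and monotone of the two defensible
  conventions. The index is length-weighted by default; a time-weighted
  variant is exposed because both phrasings circulate in the literature.
* **Path efficiency ratio** — actual path length divided by the direct
  distance. Because every platform-terminated track ends at the platform
  *edge*, the direct distance is measured to the edge too (centre distance
  minus 12 cm): this is the shortest swim that achieves contact, it makes
  the ratio ≥ 1 with equality exactly for a straight approach, and it
  keeps the three noise-free identities (ratio 1, corridor 100%, latency =
  distance/speed) simultaneously true. Passing `platform_radius_cm = 0`
  restores the centre-to-centre convention.
* **Quadrant occupancy** (probe trials) — time-weighted shares with
  segments split exactly at the two quadrant axes; shares sum to 100.
* **Central-zone path and stops** (open field) — zone path length clips
  segments at the 26-cm circle analytically. A *stop* is a maximal
  interval of smoothed speed below 2 cm/s lasting at least 1 s, with a
  0.5-s moving-average smoother. The tracking literature rarely states its
  stop criterion; these three numbers are this package's definition and
  are configurable.
* **Strides** (beam) — stance phases are near-zero-velocity plateaus
  (default: smoothed speed < 5 cm/s for ≥ 0.12 s at 60 fps); stride k is
  the distance between consecutive stance positions. Fewer than two
  plateaus (a continuous slide) is an error, not a zero.

All zone and corridor computations are exact for the recorded polyline,
which is what makes the metrics robust to the tracker's sample rate: on
one continuous path resampled at 0.04–0.2 s the headline metrics agree
within 2% (tested).

## The eight-class search-strategy classifier

Published work on water-task search strategies typically relies on trained
raters. phenomaze replaces the raters with a deterministic first-match
cascade over quantitative path features, so labels are reproducible and
auditable. Features: efficiency ratio and corridor fraction (path-based);
time-weighted occupancy of the wall zone (within 8 cm of the wall), the
platform-orbit annulus (radial distance within 10 cm of 38.5 cm), the
inner disk (half the pool radius), 30-cm proximity disks around the
current and the previously learned platform; and a 10×10 grid coverage
diagnostic (computed, not used by the default rules).

The cascade, with default thresholds:

1. **DSw** (direct swim): efficiency ≤ 1.3 and corridor fraction ≥ 0.8
2. **DSe** (directed search): corridor fraction ≥ 0.7
3. **FS** (focal search): platform-proximity fraction ≥ 0.5
4. **P** (perseverance): previous-platform proximity fraction ≥ 0.5
5. **T** (thigmotaxis): wall fraction ≥ 0.65
6. **C** (chaining): annulus fraction ≥ 0.7
7. **S** (scanning): inner fraction ≥ 0.6
8. **RS** (random swim): otherwise

Spatial rules run first so that near-goal behaviour dominates ambiguous
paths, and perseverance runs before the non-spatial rules so focal search
at the old goal is not absorbed by scanning. DSe/FS/DSw/P are the spatial
category; T/RS/S/C non-spatial. `spatial_percent()` is the share of
spatial labels, and the improvement rate is the percentage-point change in
spatial use between the first and last training days (44% → 87% is a
43-point improvement). Thresholds are arguments, not constants; they were
fixed while designing the noise-free archetypes below and validated by
recovery (macro recall ≈ 0.96 at the generator's default noise; 1.0
noise-free), but they cannot be validated against human raters because
raters' numeric criteria are never published.

## What the synthetic-data generator emulates

Each strategy is a correlated-heading walk: per 0.1-s step the heading is
the strategy's steering direction perturbed by von Mises noise
(concentration `1/sd²`, default sd 0.3 rad), the animal advances at
constant speed, reflects off the wall, and the trial ends at the exact
platform-edge crossing or at 60 s. Steering archetypes: wall-following at
4 cm inside the wall (T); ballistic wandering (RS); a deterministic
rosette confined to the inner zone (S); orbiting the 38.5-cm annulus the
long way round to the platform (C); a sinusoidal weave inside the corridor
(amplitude 8 cm, wavelength 26 cm — chosen so the weave stays inside the
corridor while its arc length exceeds the direct-swim efficiency cutoff)
(DSe); direct approach then an 18-cm search orbit for 10–18 s before
homing (FS); a straight goal approach (DSw); and FS behaviour anchored at
the previously learned platform position (P).

Preset parameters are the published group conditions: swim speeds 0.217
(control-like) and 0.314 m/s (BTBR-like); group sizes 13 and 9; four
trials per day for five reversal-training days; day-1 → day-5
spatial-mixture anchors 44% → 87% and 31% → 36%, linearly interpolated,
back-derived from the published day-5 percentages and improvement rates
(43 and 5 points). Within-category label weights are design choices: the
BTBR-like preset puts more of its non-spatial mass on chaining and
scanning, mirroring the strains' described behaviour. Open-field presets
move at 0.12 and 0.23 m/s (derived from the published 20-min path lengths
of ≈144 m and ≈280 m) with an explicit Markov pause process (onset hazard
0.03 s⁻¹; dwell 2 s plus an exponential mean 1 s; 2-s refractory period so
consecutive pauses cannot fuse), whose emitted pause count is the stop
ground truth. Stride series place Gaussian strides (default 8 ± 0.5 cm)
as stationary plateaus linked by cosine-eased swings at 60 fps, never
exceeding the beam. Section images place dark disks (grey level 100–170,
inside the 90–180 detection band) on a 230-grey background, optionally as
touching pairs (centre distance = sum of radii − 2 px) to exercise
watershed splitting.

What the generator does **not** emulate: learning within a day, fatigue,
floating, variable swim speed, thigmotaxis-to-search transitions within a
trial, video artefacts (occlusion, identity swaps, lens distortion),
staining gradients, non-circular cell shapes, or anisotropic shrinkage.
Passing recovery tests on this generator therefore demonstrates that the
metrics and the cascade are internally consistent and robust to sampling
and noise as modelled — not that the classifier reproduces human labels
on real video, which would require annotated tracks.

## Morphometry

Sectional volume follows the standard serial-section estimator: summed
areas × 0.040 mm slice thickness × sampling interval 5 (8 sections for
cortex, 4 for dorsal hippocampus; other counts warn). Missing sections are
imputed as the flanking mean — only isolated interior gaps, at most two
per set, because a flanking mean is undefined for runs and edges; more
missing data rejects the set. Thickness tables (3 points × 2 hemispheres ×
7 slices, ≤ 6 measurements per section) aggregate to means overall, per
point, or per hemisphere, with missing cells excluded and counted.

Particle counting mirrors the ImageJ-style procedure: inclusive [90, 180]
band on the 8-bit grey scale (images in [0,1] are rescaled by 255; RGB is
converted by luminance weights), optional watershed on the distance map to
split merged particles, 8-connected components, then pixel-area and
circularity (4πA/P²) filters. Two numerical choices matter: the watershed
height tolerance defaults to 0.3, which in development separated touching
cell-sized disk pairs reliably (tolerance 1 left about a third unsplit)
without ever fragmenting single disks; and discrete perimeter estimates
can push circularity slightly above 1 for small round objects, so computed
circularity is capped at 1 — otherwise the conventional [0, 1] "keep
everything" filter would silently drop the roundest cells. Density is
count over ROI area (dorsal ≈ 0.352 mm², lateral ≈ 0.30 mm²).

## Statistics

Group comparisons are rank-based and two-tailed at α = 0.05: Mann–Whitney
U (reported as min(U₁, U₂) from midrank sums; exact p by enumeration when
the combined n ≤ 16 without ties, otherwise the tie-corrected normal
approximation), Kruskal–Wallis H (tie-corrected, χ² p), and Spearman's ρ
(exact for n ≤ 7 without ties, otherwise the t approximation). Bonferroni
adjustment is applied within declared families — in `run_report()`, each
across-day metric family — with the family size recorded, because the
original analyses do not enumerate their family structure. The test suite
checks every statistic against brute-force enumeration on small instances
and the U test's null rejection rate (5% ± 1% at n = 9 vs 13 over 10,000
simulations).

## Problem sizes and determinism

The bundled studies use the published group sizes (13 + 9 subjects, 5
days × 4 trials); recovery studies use 200 trials per class; particle
studies use 50–100 fixtures of 256² px; the calibration study 10,000
null draws. Every stochastic routine takes a `seed` and restores the RNG
state afterwards (`withr::with_seed`); identical configs and seeds yield
byte-identical trajectories, labels and report files, which the suite
verifies at the byte level.

## Known limitations

The classifier thresholds are not validated against human raters. The
corridor cap at the platform centre and the efficiency-ratio edge
convention are documented choices among defensible alternatives. Tissue
shrinkage is not corrected (areas are treated as post-shrinkage, as
measured). The particle counter assumes roughly convex, disk-like somata;
heavily overlapping or elongated cells would need a different splitting
strategy. The generator's archetypes are caricatures intended for
validation, not biomechanical models of swimming mice.
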