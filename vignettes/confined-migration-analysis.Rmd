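---
title: "Quantifying confined T-cell migration and morphology with migrochip"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying confined T-cell migration and morphology with migrochip}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(migrochip)
```

## The measurement problem

Regulatory T cells (Tregs) migrating through dense tissue move under strong
geometric confinement. Two microfabricated devices reduce this situation to
measurable assays: *microchannels* (4 µm wide, 5 µm high, ~900 µm long)
force one-dimensional migration, so a cell's behaviour collapses onto a
single axial coordinate; *micropillar forests* (10 µm pillars spaced 30 µm
on a square lattice, 5 µm chamber height) permit confined two-dimensional
migration. In both, DAPI-stained nuclei are imaged by time-lapse
epifluorescence (typically one frame every 3 min over 16 h) and the
centre-of-mass position of every cell is reconstituted into an x–y path.

This package implements the full analysis chain for such experiments —
detection, linking, and the per-cell migration statistics — together with
confocal z-stack morphometry and a qPCR methylation readout. Because raw
movies from such studies are rarely deposited, the package also ships
simulators that generate every input with known ground truth, so each
stage is testable end to end.

## Motion model of the simulator

The 2-D simulator is a heading-increment persistent random walk (PRW). At
each step of duration $\Delta t$ the heading receives Gaussian noise,

$$\theta_{k+1} = \theta_k + \eta_k,\qquad \eta_k \sim
\mathcal{N}(0, \sigma^2),$$

and the cell advances by $v_k\,\Delta t$ along $\theta_{k+1}$, with the
speed $v_k \sim \mathcal{N}(\mu_v, \sigma_v^2)$ truncated at zero and drawn
independently per step. For this model the expected cosine of the turning
angle is $\mathrm{E}[\cos\alpha] = e^{-\sigma^2/2}$, which the test suite
verifies by Monte-Carlo sampling. $\sigma = 0$ yields straight lines
(persistence 1); $\sigma = \infty$ is implemented as a fresh uniform
heading per step, making the turning angle uniform on $[0^\circ,
180^\circ]$. Published tracking studies use a range of motion models; the
heading-increment PRW is the simplest one with a single tunable
persistence parameter, which is all the downstream statistics require.

Collisions with pillar disks and arena walls are resolved by *specular
reflection* of the remaining displacement, and the post-bounce direction
becomes the new heading. Reflection (rather than redrawing the heading)
keeps the zero-noise limit deterministic. One consequence worth knowing:
the recorded per-frame positions are the endpoints of possibly-reflected
moves, so a bounce shortens the recorded step chord relative to
$v\,\Delta t$; path-length identities are exact only away from obstacles.

The 1-D channel simulator models entry as a Bernoulli trial per frame at
the entrance (entry must be a controllable ground truth, since "number of
cells entering" is a primary readout), then forward motion with per-step
truncated-Gaussian speed, optional direction reversal, and clamping to
$[-\text{entry margin}, \text{channel length}]$. An optional
`speed_profile` function of time lets a cohort start fast and slow down,
emulating time-resolved speed decay.

## From movies to tracks

`render_movie()` draws each nucleus as an isotropic Gaussian blob on a
constant background with additive Gaussian noise. Image arrays are indexed
`[x, y]` with 0-based pixel centres; a position in µm maps to pixel
coordinate `x_um / pixel_size`. The default pixel size, 0.65 µm/px, is a
typical CCD-behind-10× value and is explicitly a placeholder — calibrated
acquisitions must supply their own.

`detect_nuclei()` smooths each frame (Gaussian, default σ = 2 px),
thresholds (Otsu by default, fixed threshold available), labels connected
components, and returns the intensity-weighted centre of mass of each
component of at least `min_area` pixels, using the above-threshold part of
the raw signal as weights so centroids are sub-pixel. Touching nuclei are
*not* separated (no watershed): at realistic densities this costs a few
percent of positions when walkers cross, which is visible in the recovery
figures below.

`link_tracks()` performs greedy mutual-nearest-neighbour linking: between
an open track end and a new detection, candidate links are consumed in
order of increasing displacement (ties broken by smaller track id), links
longer than `max_disp` are forbidden, leftovers seed new tracks, and
tracks shorter than `min_track_length` are dropped. Gap closing is off by
default (`max_gap = 0`): at a 3-min cadence, detection gaps in channels
are rare, and gap closing is an opt-in. At the densities these devices
produce, the greedy solution coincides with exhaustive
minimum-total-displacement matching (the suite checks this against a
brute-force enumeration oracle on small cases); a full assignment solver
is deliberately out of scope.

The frame interval is always taken from data/metadata, never assumed:
published methods for these devices report both 2-min and 3-min cadences,
so hard-coding either would silently mis-scale every speed.

## Migration statistics

For channels, per-cell summaries use the *axial* coordinate (lateral
motion inside a 4 µm channel is sub-pixel):

* **entry**: the axial coordinate crosses the entrance from outside and
  subsequently penetrates at least 10 µm (about one cell length). The
  margin rejects entrance-grazing cells, whose apparent crossings are
  detection jitter.
* **speed fluctuation**: the sample standard deviation (n−1) of a track's
  instantaneous speeds, in µm/min. Reported cohort values in the
  literature for this statistic are printed without units and without a
  formal definition, so the package documents its choice prominently and
  offers the coefficient of variation behind `cv = TRUE`.
* **furthest distance** and its histogram (`density_profile()`), plus
  `fraction_within()` — the fraction of entered cells that never pass a
  cutoff (default 200 µm), the "accumulation near the entrance" readout.
* **time-resolved speed**: mean of instantaneous speeds binned by step
  midpoint into windows tiling the observation span.

For pillar chambers, the turning angle $\alpha$ at each interior point is
the angle between consecutive displacement vectors (law-of-cosines
checked; $0^\circ$ straight, $180^\circ$ reversal). Steps are *motile*
when their displacement exceeds `motile_min_disp` (default 0.65 µm, one
pixel at the default calibration — "motile time" is never formally defined
in this assay literature, so the threshold is a documented, configurable
choice). Motile steps with a defined angle are *persistent* when
$\alpha < 30^\circ$ and *confined* when $\alpha \ge 30^\circ$. The
boundary value $30^\circ$ is assigned to confined: the conventional
definition uses strict inequalities on both sides and leaves the boundary
unassigned, and assigning it toward confinement is the conservative choice
for a statistic meant to flag direction instability. Zero-displacement
steps are non-motile regardless of angle and break the angle triple (no
interpolation across missing detections). `percent_time_confined()` is
then 100 × confined / (motile interior steps), and `top_n_tracks()`
selects the n longest paths (total path length, not net displacement) for
trajectory overlays.

## Morphometry of confocal z-stacks

`segment_cells()` thresholds the phalloidin (F-actin) channel (global
Otsu by default), fills the membrane shell per z-slice, labels components
in 3-D, and flags border-touching cells. Measurements per cell:

* **projected inner surface**: the area of the z-axis maximum projection
  of the filled mask, in µm². Reported "inner-membrane surface" values of
  ~24–38 µm² for ~6–7 µm cells match an enclosed projected area, not a
  3-D membrane area, and the quantity is explicitly defined on a z-stack
  projection; the package therefore reports projected area, with the 3-D
  voxel-face area available separately as `mask_surface_area_3d()`.
* **spikes**: on the projected outline, the reference body is obtained by
  *morphological opening* with a disc of radius `smoothing_radius`
  (opening removes protrusions thinner than the disc — closing, which
  fills concavities, cannot isolate protrusions); connected residual
  components whose maximal distance beyond the reference reaches
  `min_spike_length` are counted, that distance being the spike length.
  Spike detection is 2-D by design, matching how projection figures are
  scored; 3-D spike detection is out of scope.
* **organelle volume**: organelle-channel voxels above threshold inside
  the cell mask; reported as µm³ and as percent of cell volume. The same
  operation serves any organelle marker (early endosomes, Golgi) — there
  is no marker-specific logic.

The `synth_cell_3d()` fixture generates an ellipsoidal membrane shell with
equatorial radial spikes and interior organelle blobs, storing analytic
ground truth ($\pi ab$ projected area, $\tfrac{4}{3}\pi abc$ volume, spike
count, realised organelle voxel fraction). The default radius 3.47 µm
makes the analytic projected area ≈ 37.8 µm², i.e. the fixture sits at the
scale of real Treg measurements.

## qPCR TSDR demethylation

The Foxp3 Treg-specific demethylated region (TSDR) demethylation
percentage is computed from methylation-specific and
demethylation-specific qPCR Ct values as

$$\%\,\text{demethylation} = \frac{100}{1 + 2^{\,Ct_\text{meth} -
Ct_\text{demeth}}}.$$

The formula is implemented exactly as conventionally printed
(`convention = "as_printed"`). Note the sign subtlety: a fully
demethylated sample amplifies earlier in the demethylation-specific
reaction, so $Ct_\text{meth} - Ct_\text{demeth}$ is large and *positive*
— under the printed sign this yields a value near 100 only if the
subtraction order is interpreted with $Ct_\text{meth}$ large. Because
assay write-ups are ambiguous about which Ct is subtracted from which,
`convention = "flipped"` implements the opposite order; the convention
used is recorded on the output rather than silently corrected. The
function is strictly decreasing in $\Delta Ct$, bounded in (0, 100), and
satisfies $f(\Delta) + f(-\Delta) = 100$ exactly. `synth_tsdr()` inverts
the formula ($\Delta Ct = \log_2(100/f - 1)$, undefined at f = 0 or 100,
which are rejected) and adds independent Gaussian Ct noise per reaction.

## Worked example

A small pillar-chamber study with two simulated genotypes differing only
in angular noise:

```{r example}
geo <- pillar_geometry(arena_size = c(300, 300))
wt <- simulate_prw_2d(simulation_config(mean_speed = 4, speed_sd = 1,
                                        angular_noise_sd = 0.4,
                                        duration = 300, n_cells = 40,
                                        seed = 1), geo)
ko <- simulate_prw_2d(simulation_config(mean_speed = 4, speed_sd = 1,
                                        angular_noise_sd = 0.8,
                                        duration = 300, n_cells = 40,
                                        seed = 2), geo)
conf <- function(tr)
  mean(percent_time_confined_by_track(
    classify_steps(step_metrics(tr)))$percent_confined, na.rm = TRUE)
c(wt = conf(wt), ko = conf(ko))
```

The noisier cohort spends a larger share of its motile time confined, the
same direction of effect that distinguishes motility-impaired cells in
the real assay.

```{r plot, fig.width = 5, fig.height = 5}
plot(top_n_tracks(ko, 16), recenter = TRUE,
     main = "Top 16 longest trajectories")
```

## Problem sizes, tolerances and degenerate inputs

The packaged checks run the pipeline at desk scale, chosen once as
realistic for these devices: tracking recovery uses 50 cells over 100
frames in a 600 × 600 µm arena at 0.65 µm/px with blob peak / noise SD
= 10; PRW limit laws use 500 tracks × 100 steps (uniform heading) and
5 noise levels × 200 tracks (monotonicity); morphometry fixtures use
0.2 µm voxels. At that density, blob merging during cell crossings —
not detector noise — is what bounds recovery (~96% of positions within
1 px); real movies with touching nuclei will do worse, and nothing in
the synthetic data emulates photobleaching, focus drift, cell division
or death, or nuclear-shape deformation, so passing tests bound
algorithmic error, not biological image complexity.

Numerical choices: turning angles clamp the cosine into [−1, 1] before
`acos` (guarding collinear round-off); angles at ~10⁴ µm coordinates are
exact only to ~10⁻⁴ degrees by floating-point cancellation; Otsu
thresholds are computed on min–max-normalised data and mapped back to raw
units; a flat frame yields zero detections rather than an error; tracks
shorter than 3 points have no defined turning angle, fewer than 3 speeds
give an NA speed fluctuation, and a cohort with no entered cells reports
NA for `fraction_within` rather than 0.

## Known limitations

Touching nuclei are merged (no watershed); linking is greedy, not a
global assignment; spike detection sees only equatorial/projected
protrusions; organelle thresholding assumes bimodal intensity within the
cell box; the TIFF writer stores physical metadata in a YAML sidecar
rather than embedded OME-XML. The statistics deliberately stop at
per-cell summaries — group comparison (t-tests etc.) is standard R and
out of scope.
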