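# migrochip

Quantification of confined T-cell migration in microfabricated devices,
confocal morphometry, and qPCR methylation readouts — with simulators
providing ground truth for every stage.

## The problem

Regulatory T cells (Tregs) navigating dense tissue migrate under strong
geometric confinement. Two microfabricated assays make this measurable:
**microchannels** (4 × 5 µm cross-section, ~900 µm long) reduce migration
to one dimension, and **micropillar forests** (10 µm pillars spaced 30 µm)
allow confined two-dimensional migration. DAPI-stained nuclei are imaged
by time-lapse microscopy and each cell's centre-of-mass path is
reconstituted in x–y coordinates. This package implements the analysis
chain for such experiments, for cell-migration labs that today rely on
ad-hoc Fiji macros:

- **Tracking**: blob detection (Gaussian smoothing, Otsu threshold,
  intensity-weighted sub-pixel centroids) and greedy mutual-nearest-
  neighbour linking.
- **Channel statistics**: entry counts (entrance crossing + 10 µm
  penetration), instantaneous axial speed, per-cell speed fluctuation
  (sample SD of speeds, µm/min), furthest-distance density profiles,
  fraction of cells accumulating before a cutoff, time-resolved speed.
- **Pillar statistics**: turning angle α between consecutive displacement
  vectors, step classification (*persistent* α < 30°, *confined*
  α ≥ 30°, non-motile below a displacement threshold), percent of motile
  time confined, path lengths, top-N trajectory selection.
- **Morphometry**: phalloidin-based 3-D segmentation, projected
  inner-membrane surface (µm²), membrane spike counting on the projected
  outline, organelle volume and percent of cell volume.
- **qPCR**: Foxp3 TSDR demethylation percent,
  `100 / (1 + 2^(Ct_meth − Ct_demeth))`, with the subtraction-order
  ambiguity surfaced as an explicit convention flag.
- **Simulators** for all of the above: persistent random walks with
  specular pillar reflection, Bernoulli channel entry, Gaussian-blob
  movie rendering, two-channel ellipsoid-with-spikes z-stacks, and Ct
  tables inverted from a known demethylation fraction — each with exact
  ground truth and bit-for-bit seed reproducibility.

At its core is the turning-angle confinement statistic: with displacement
vectors **d**ᵢ = **p**ᵢ − **p**ᵢ₋₁, the angle αᵢ = ∠(**d**ᵢ, **d**ᵢ₊₁) is
computed at every interior point of every track; among steps whose
displacement exceeds a motility threshold, the fraction with α ≥ 30° is
the *percent of motile time confined* — a readout of directional
instability that discriminates motility phenotypes even when total path
lengths are identical.

## Worked example

Two simulated cohorts in a pillar chamber, identical except for angular
noise (0.4 vs 0.8 rad/step):

```r
library(migrochip)
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
round(c(wt = conf(wt), ko = conf(ko)), 1)
#>   wt   ko
#> 36.8 58.5
round(c(wt = mean(track_lengths(wt)$length_um),
        ko = mean(track_lengths(ko)$length_um)), 1)
#>     wt     ko
#> 1123.4 1122.3
```

The noisier cohort spends 58.5% of its motile time confined versus 36.8%,
at indistinguishable path lengths — the same dissociation (similar
distance travelled, different directionality) that separates
motility-impaired cells in the real assay.

Channel assay with stochastic entry and occasional direction reversal:

```r
ch <- channel_geometry()   # 4 x 5 um, 900 um long
tr <- simulate_channel_1d(simulation_config(mean_speed = 2, speed_sd = 1,
                                            duration = 240, n_cells = 80,
                                            seed = 3),
                          ch, entry_prob = 0.15, reverse_prob = 0.1)
s <- channel_cell_summary(tr, ch)
sum(s$entered)
#> [1] 80
round(mean(s$speed_fluctuation, na.rm = TRUE), 2)   # um/min
#> [1] 1.13
fraction_within(s, 200)
#> [1] 0.8
```

80 of 80 cells entered; the mean per-cell speed fluctuation is
1.13 µm/min, and 80% of entered cells never progressed past 200 µm —
the "accumulation near the entrance" signature.

TSDR demethylation from Ct pairs:

```r
round(as.numeric(demethylation_percent(c(25, 15, 35), c(25, 25, 25))), 2)
#> [1] 50.00 99.90  0.10
```

See the vignette (`vignettes/confined-migration-analysis.Rmd`) for the
model details, parameter definitions and design choices, and
`inst/cli/migrochip.R` for the command-line front end.

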