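# paintkit

Simulation and analysis of transient-binding (PAINT-style) single-molecule
localization microscopy (SMLM) experiments in live cells.

In these experiments a fluorescent binder docks transiently onto binding
sites on a protein of interest; every binding event appears as a short-lived
diffraction-limited spot, is fitted to nanometer precision, and the
accumulated localizations reveal structure far below the diffraction limit —
nuclear histone nanodomains, motile mitochondrial tubes. `paintkit` covers
the complete computational chain for such data:

* **Simulation** (`make_clutch_scene`, `make_tube_scene`,
  `simulate_binding`, `events_to_localizations`, `render_stack`): clustered
  or tube-like ground-truth scenes, Poisson binding with exponential
  residence times (`Exp(tau)`), and either ground-truth localization tables
  or Poisson-noise camera frame stacks with pixel-integrated Gaussian PSFs.
* **Localization** (`detect_spots`, `fit_gaussian`, `estimate_precision`,
  `localize_stack`, `filter_precision`): difference-of-Gaussians detection,
  least-squares sub-pixel 2D Gaussian fits, and the Thompson-style precision
  `sigma_loc = sqrt((s^2 + a^2/12)/N + 8*pi*s^4*b^2/(a^2*N^2))` with a
  strict `< 30` nm filter by default.
* **Event linking** (`merge_localizations`, `residence_histogram`,
  `fit_residence`): greedy frame-ordered linking (20 nm radius, at most one
  dark frame) and censoring-aware exponential residence-time estimation.
* **Rendering** (`render_histogram`, `render_gaussian`, `max_projection`,
  `temporal_color_map`, `moving_window_stack`): count-conserving SR
  reconstructions, diffraction-limited projections, temporal color-coding
  and 25 s / 0.5 s moving-window stacks.
* **Resolution** (`frc_curve`, `frc_resolution`,
  `resolution_vs_integration`): Fourier ring correlation over random half
  splits with the fixed 1/7 threshold, and resolution versus integration
  time (n = 3 random frame subsets per time).
* **Cluster analysis** (`dbscan_cluster`, `cluster_metrics`, `nn_distances`,
  `local_density_map`, `highlight_threshold`): exact DBSCAN
  (eps 0.3 um, min 5 by default), convex-hull areas, axis-ratio
  eccentricity (minor/major), and nearest-neighbor local density with
  cluster-scaled radii.
* **I/O and pipeline** (`read_localization_csv`, `write_localization_csv`,
  `pipeline_config`, `run_pipeline`): ThunderSTORM-style CSV tables,
  multi-page TIFF stacks, and a seeded, manifest-writing end-to-end driver.
  A thin command-line wrapper lives at `inst/cli/paintkit-cli.R`.

## Worked example

Simulate a nuclear-like scene of 60 nanoclusters, image it for 50 s of
PAINT binding, and push the localizations through the full pipeline:

```r
library(paintkit)

scene <- make_clutch_scene(n_clusters = 60, sites_per_cluster = 30,
                           cluster_sigma = 50, fov = c(20000, 20000), seed = 1)
kin   <- kinetics_params(site_on_rate = 0.05, mean_residence = 0.1, duration = 50)
trace <- simulate_binding(scene, kin, seed = 1)
locs  <- events_to_localizations(scene, trace, kin, precision_model = 20, seed = 1)

cfg <- pipeline_config(frc_times = c(10, 25, 50), window = 25, step = 12.5, seed = 1)
res <- run_pipeline(locs, cfg, out_dir = "pk_out")
```

which logs, stage by stage:

```
[pipeline] filter: 8876 of 8876 records below 30 nm precision
[pipeline] merge: 7123 chains from 8876 localizations
[pipeline] render: 2000 x 2000 px at 10 nm/px, mass 8876
[pipeline] frc: resolution 105.3/77.8/70.3 nm at times 10/25/50 s
[pipeline] cluster: 57 clusters, 100.00% clustered
[pipeline] density: 8849 of 8876 members within 5x mean NN distance
[pipeline] dynamics: 3 windows of 25 s, step 12.5 s
```

Reading the numbers: all 8 876 simulated localizations survive the 30 nm
precision filter (the simulation used a constant 20 nm precision); linking
collapses them into 7 123 binding-event chains; the reconstruction's mass
equals the record count (count conservation); the FRC resolution improves
from 105 nm at 10 s of integration to 70 nm at 50 s as localizations
accumulate; DBSCAN at eps 0.3 um recovers 57 of the 60 simulated clusters
(nearby clusters can merge) with every localization clustered; and the
moving-window stack holds three 25 s reconstructions. `res$clusters` then
prints per-cluster morphology:

```
Cluster result: 57 clusters, 100.00% of 8876 points clustered
  mean area 0.04496, mean axis ratio 0.736, mean within-cluster NN 0.008488
```

(areas and distances in um^2 / um since the pipeline clusters in
micrometers). Note that residence-time estimation (`fit_residence`) wants
low positional noise: at 20 nm precision the frame-to-frame jitter of one
event exceeds the 20 nm link radius and chains fragment — simulate with
`precision_model = 5` or smaller when studying kinetics.

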