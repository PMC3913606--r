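# boldtrack

Personality, foraging strategy and fitness consequences in GPS-tracked
seabirds — a complete, tested analysis pipeline.

Seabird ecologists increasingly ask whether individuals differ
*consistently* — in how boldly they face a novel object at the nest, and in
how far, how long and in which direction they forage at sea — and whether
those differences matter for fitness. boldtrack implements that entire
analysis chain for colonial seabirds tracked with GPS loggers, scored with
novel-object assays, and followed in a long-term breeding programme:

1. **Trips** — segment 2-minute GPS fixes into foraging trips with a 2-km
   colony buffer; extract duration, foraging range and latitude extents.
2. **Area-restricted search (ARS)** — first-passage time (FPT): the time to
   cross a circle of radius *r* centred on each point of the 1-km
   interpolated track. The variance of log FPT across the track peaks at
   the spatial scale of intensive search; points with FPT above an Otsu
   threshold at that scale, merged under a 10-km rule, are foraging zones.
3. **Habitat** — classify each zone centre from bathymetry: shelf
   (< 200 m), shelf edge (200–2000 m), oceanic (> 2000 m); proportional-odds
   models (written in-package, with random bird/trip intercepts) relate
   habitat to boldness.
4. **Fisheries** — 19-km, +1-h discarding zones around longline haul-end
   points; fix-level overlap, trip/bird bookkeeping and binomial GLMMs.
5. **Personality scores** — PC1 of the correlation-matrix PCA of assay
   counts (boldness) and of trip metrics (foraging personality);
   per-individual mean-centred scores; repeatability
   r = σ²ᵢ/(σ²ᵢ+σ²ₑ) with parametric-bootstrap intervals and a
   ½χ²₀+½χ²₁ boundary test; Spearman correlation between the two scores.
6. **Fitness** — fledging success over 23 seasons modelled as
   logit P = β₀ + βₛs + βₘm + βₐa + interactions + u_bird + u_year,
   with s the centred score, m sex, a centred SSTa (September–November
   sea-surface temperature anomaly, a year-quality proxy); the
   score×sex×SSTa interaction is a 4-df ML likelihood-ratio test.

Field data of this kind are rarely deposited, so the package includes a
synthetic-data generator (`sim_config()`, `simulate_all()`) that emulates
the full study design — colony at 48.4° S 68.4° E, two-minute fixes,
planted 5-km prey patches, a radial shelf, shelf-edge longliners, latent
ICCs and fledging effect sizes — with every planted quantity recorded, so
each stage is validated by recovery tests.

## Worked example

The analysis is organised as numbered drivers under `analysis/`
(`01_simulate.R` … `06_fitness.R`), each a thin script over the package
functions, writing its tables under `results/`. Running them in order with
the default seed prints:

```
$ Rscript analysis/01_simulate.R
Simulated 77817 GPS fixes for 69 birds at 120 s sampling.
Novel-object tests: 170 on 154 birds ( 16 retested ).

$ Rscript analysis/02_trips.R
Segmented 207 trips from 77817 fixes.
12 trips excluded as late-incubation; 195 retained.
Median foraging range 180 km; median duration 11.5 h.

$ Rscript analysis/03_fpt_ars.R
FPT analysed 195 trips ( 0 skipped ); 196 ARS zones.
Median variance-peak scale 7 km (IQR 5-8 km).

$ Rscript analysis/04_habitat_fisheries.R
Habitat of ARS centres:      shelf shelf_edge    oceanic
                                54        130         12
Fisheries overlap: 46 of 195 trips (24%), 36 of 65 birds (55%).

$ Rscript analysis/05_personality.R
Boldness repeatability r = 0.43 +- 0.20 (CI 0.00-0.74; p = 0.177).
Foraging repeatability r = 0.68 +- 0.06 (CI 0.55-0.76; p = 7.44e-22).
Boldness vs foraging score: Spearman rho = -0.15 (p = 0.244, n = 65).

$ Rscript analysis/06_fitness.R
boldness x sex x SSTa: chi2(4) = 39.38, p = 5.823e-08 (n = 1357 bird-years).
```

Reading: trips carrying a planted 5-km prey patch peak in log-FPT variance
at ~7 km and yield one foraging zone each, mostly on the shelf edge where
the simulated longliners also operate (about a quarter of trips meet a
discarding zone). Trip metrics are strongly repeatable (bird identity
explains 68% of PC1 variance), the boldness assay moderately so but with a
wide interval at only 16 retests, and the planted sex-opposite
boldness-fitness effects are detected by the 4-df interaction test. The
same chain is available as a single call, `run_pipeline(sim_config())`,
which also writes a run manifest with per-stage exclusion bookkeeping.

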