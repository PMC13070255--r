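# efferoquant

Quantitative image analysis for receptor nanoscale organization and the
efferocytic synapse — the ordered contact zone a macrophage builds on an
apoptotic target. Efferocytic receptors such as MERTK are sparse on the
cell surface; they compensate by pre-clustering with integrin
co-receptors (β₁, β₂, αₓβ₂) into nanodomains, activating the integrins
inside-out, and assembling an integrin ring that drives engulfment.
Testing that model quantitatively requires five distinct measurements,
each implemented here as a tested, reusable module:

1. **smlm** — co-clustering statistics on two-species single-molecule
   localization data: the cross-species radial distribution
   `G(r) = ρ_target(r) / ρ̄_target` with Monte-Carlo randomization
   envelopes, OPTICS cluster segmentation, and
   colocalized / contacting / neither cluster-relation fractions.
2. **photobleach** — molecules per cluster from stepwise photobleaching:
   change-point staircase fitting, direct counting up to a reliability
   limit (default 28 steps), and regression extrapolation
   `N = I₀ / I_unit` for larger clusters, with `I_unit` from an OLS fit
   over the final plateaus.
3. **fret** — corrected sensitized-emission FRET for integrin
   conformation: bleed-through coefficients α, β, γ, δ from single-label
   controls, `F_c = Ida − β(Idd − α·Iaa) − γ·Iaa`, `E_A = F_c/Iaa`
   clamped to the FITC/ORB maximum 0.3136, Otsu-AND masking, ROI
   quantification. Activation of the integrin *decreases* E_A.
4. **spt** — single-particle trajectory analysis: 25 nm precision
   filter, MSD diffusion coefficients, moment-scaling-spectrum
   classification (slope ≈ 0.5 Brownian, < 0.5 confined, > 0.5
   directed), confinement-zone diameters.
5. **morphometry** — Feret's-diameter synapse expansion, Pearson
   colocalization, radial profiles, base-to-leading-edge cup profiles,
   and the phagocytic/efferocytic index (mean targets internalized per
   cell, with inside/outside discrimination by surface labelling).

Because the corresponding imaging study deposited no raw image data,
every module ships with a seeded synthetic-data generator
(`gen_point_pattern`, `gen_bleach_trace`, `gen_fret_stack`,
`gen_trajectories`, `gen_uptake_scene`) whose ground truth pins the
estimators end to end; the FRET generator is the exact algebraic inverse
of the FRET estimator.

## Worked example

```r
library(efferoquant)

# co-clustered two-species pattern: 15 nanoclusters, 50 + 50 molecules each
pat <- gen_point_pattern(pattern_spec(mode = "coclustered", field_size = 10000,
                                      n_clusters = 15, cluster_occupancy = c(50, 50),
                                      seed = 2))
A <- subset(pat$table, species == "A")
B <- subset(pat$table, species == "B")

gr <- radial_distribution(A, B, bins = seq(0, 500, 25), roi = pat$roi)
round(gr$g[1:6], 1)
#> [1] 440.3 331.8 204.7  99.2  24.9   1.5

rel <- classify_cluster_relations(extract_clusters(A, 5, 60),
                                  extract_clusters(B, 5, 60),
                                  roi = pat$roi, seed = 3)
rel
#> cluster relations (n=15 A clusters): colocalized 1.000, contacting 0.000, neither 0.000
#>   randomized baseline: colocalized 0.000, contacting 0.000
```

G(r) is hundreds-fold above 1 inside the ~120 nm clusters and decays to
the random level by ~150 nm; every B cluster is intermixed with an A
cluster, while randomizing positions over the same field abolishes the
association — the signature of genuine co-clustering rather than chance
proximity.

```r
# count molecules in a cluster from its photobleaching trace
g <- gen_bleach_trace(trace_spec(n_steps = 24, unit_intensity = 100,
                                 noise_sd = 20, seed = 9))
fit <- count_molecules(g$trace)
c(fit$molecule_count, fit$method, round(fit$unit_intensity, 1))
#> "24"  "direct_count"  "99.9"

# classify confined receptor diffusion and size the corral
tr <- gen_trajectories(motion_spec("confined", corral_diameter = 200,
                                   n_tracks = 50, track_length = 100, seed = 4))
summ <- fraction_confined(analyze_tracks(tr), seed = 1)
summ[, c("motion_class", "fraction", "mean_confinement_diameter")]
#>   motion_class fraction mean_confinement_diameter
#> 1         free        0                        NA
#> 2     confined        1                  208.1451
#> 3     directed        0                        NA
```

All 24 bleaching steps are recovered exactly, and the 200 nm corral is
sized within 5%.

Any stage can also be driven from a YAML config via `run_stage()` (or the
`inst/scripts/efferoquant.R` wrapper), which records parameters, seed and
input checksums for reproducibility.

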