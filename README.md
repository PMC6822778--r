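# rdcolony

Reaction-diffusion and positional-information analysis of micropatterned
stem-cell colonies.

When human pluripotent stem cells are confined to circular micropatterned
islands and treated with BMP4, phosphorylated SMAD1 (pSMAD1) organises into a
radial signalling gradient - peripheral-high, centre-low - and germ-layer- or
neurulation-associated fates pattern accordingly. Whether Nodal signalling is
active decides the outcome: with Nodal, the high-signalling rim acquires a
primitive-streak (BRA) fate; with Nodal blocked (SB431542), the rim becomes
non-neural ectoderm (GATA3) around a preneural SOX2 centre. `rdcolony`
implements the computational core of that biology as a tested pipeline:

* **Reaction-diffusion model** (`rd_params`, `build_domain`, `simulate_rd`,
  `linear_stability`): a BMP activator `b` and a pooled secreted-antagonist
  species `n` ("BMPi": Noggin plus the Nodal-driven antagonists CER1/GDF3/FST)
  on a colony disc embedded in a cell-free margin,

  ```
  db/dt = D_b lap(b) + m(x) rho_b b^2 / ((n0 + n)(1 + kappa b^2))
          - mu_b b - lambda_s S(r,t) b + k_ex (c_dose - b)
  dn/dt = D_n lap(n) + m(x) rho_n b^q - mu_n n
  ```

  with production masked to the colony (`m`), well-mixed bath exchange for
  the exogenous dose, and an optional Gaussian Nodal-inhibition ring
  `S(r, t)` (`nodal_ring`). The pSMAD1-like readout is
  `b / (1 + lambda_s S)`. Antagonist escape across the colony edge generates
  the peripheral readout peak; on large (3 mm) colonies at high dose the
  `"turing"` preset breaks into periodic foci whose spacing matches the
  fastest-growing wavelength from `linear_stability`.

* **Positional-information fate rule** (`exposure_map`, `assign_fates`):
  cumulative signalling exposure `E = integral of readout dt` thresholded
  into SOX2-like / GATA3-like (or BRA-like with Nodal) / unpatterned fates,
  reproducing the dose-by-time interchangeability of fate induction.

* **Single-cell colony quantification** (`assign_colonies`,
  `filter_colonies`, `radial_profile`, `hex_map`, `percent_positive`):
  DBSCAN colony assignment with noise rejection, annular radial profiles with
  SD and t-based 95% confidence intervals (colonies weighted equally),
  hexagonal-bin expression maps, and Otsu / Gaussian-mixture percent-positive
  statistics - the analysis applied to Cellomics-style per-cell exports.

* **Periodicity statistics** (`detect_foci`, `nn_distances`,
  `compare_distributions`, `mc_test`): marker-negative focus detection,
  nearest-neighbour distance histograms, Shannon entropy, Jensen-Shannon
  divergence, and Monte-Carlo significance against uniform-random or
  jittered-hexagonal reference patterns.

* **Expression analysis** (`ddct_log2fc`, `cluster_responders`):
  delta-delta-Ct log2 fold changes (GAPDH-referenced, day-0 baseline) and
  k-means clustering of cell lines into Strong / Intermediate / Weak
  responders per gene.

* **Synthetic data generators** (`generate_plate`, `generate_point_pattern`,
  `generate_qpcr`): seeded per-cell plate tables with ground-truth sidecars,
  reference point patterns, and qPCR Ct tables with planted cluster
  structure, so every stage is testable without external data.

## Worked example

```r
library(rdcolony)

# 500 um colony, 25 ng/ml BMP4 with Nodal blocked, 24 h
dom <- build_domain("radial-1D", R_colony = 250, R_domain = 500, h = 5)
sim <- simulate_rd(rd_params("SB"), dom, T = 24, save_every = 2)
sim
#> <rd_sim> preset 'SB', radial-1D colony R = 250 um, dose 25 a.u.
#>   13 saved fields over t = 0..24 h (dt = 0.05 h)
#>   final readout range: 5 .. 8.86 a.u.

round(readout_radial(sim, n_bins = 5)$mean, 2)
#> [1] 7.34 7.41 7.57 7.92 8.53
```

The readout rises monotonically from the colony centre (7.34 a.u.) to the
periphery (8.53 a.u.): the edge-high pSMAD1 gradient organised by antagonist
escape. Feeding the signalling history through the fate rule labels the
boundary annulus GATA3-like and the centre SOX2-like:

```r
fm <- assign_fates(exposure_map(sim), fate_thresholds())
fm
#> <fate_map> (Nodal off)
#>   SOX2       35 positions (70.0%)
#>   GATA3       7 positions (14.0%)
#>   BRA         0 positions (0.0%)
#>   none        8 positions (16.0%)

st <- linear_stability(rd_params("turing"))
st
#> <rd_dispersion> steady state b* = 11.7 , n* = 68.46
#>   Turing band present: max growth 0.852 1/h at wavelength 419 um
```

On a 3 mm colony at 200 ng/ml the same `"turing"` preset develops interior
signalling foci whose mean nearest-neighbour spacing (~350 um) sits within
25% of that 419 um wavelength; `mc_test` then rejects spatial randomness for
such patterns against a matched uniform null.

## Package layout

| Area | Functions |
| --- | --- |
| RD model | `rd_params`, `build_domain`, `nodal_ring`, `simulate_rd`, `readout_radial`, `linear_stability`, `field_maxima` |
| Fate rule | `exposure_map`, `fate_thresholds`, `assign_fates`, `fate_fractions` |
| Quantification | `assign_colonies`, `filter_colonies`, `radial_profile`, `hex_map`, `percent_positive`, `otsu_threshold` |
| Periodicity | `detect_foci`, `nn_distances`, `compare_distributions`, `mc_test` |
| Expression | `ddct_log2fc`, `log2fc_features`, `cluster_responders` |
| Synthetic data | `plate_spec`/`generate_plate`, `pattern_spec`/`generate_point_pattern`, `qpcr_spec`/`generate_qpcr`, `channel_spec` |
| Configuration | `read_run_config` (YAML run descriptions) |

The methods vignette (`vignettes/methods.Rmd`) documents the model, its
assumptions, the numerical scheme, all tunable parameters with units and
defaults, and what the synthetic-data generators do and do not emulate.
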