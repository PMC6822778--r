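---
title: "Models and methods behind rdcolony"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind rdcolony}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rdcolony)
```

`rdcolony` models and quantifies fate patterning in geometrically confined
human pluripotent stem-cell (hPSC) colonies treated with BMP4. This vignette
is the package's own account of the science: the model and its assumptions,
every tunable parameter with units and defaults, the numerical choices, the
design decisions that were genuinely open, and the limitations of the
synthetic data the test-suite runs on.

## 1. The reaction-diffusion model

### Species and equations

Two fields live on the simulation domain: the activator `b`, extracellular
BMP4 read out as pSMAD1 activity, and a single pooled inhibitor `n`
representing all secreted BMP antagonists - Noggin, which BMP4 itself
induces, together with the Nodal-pathway antagonists (CER1, GDF3,
Follistatin) when Nodal signalling is active. Pooling is a deliberate
simplification: the biology distinguishes these antagonists, but their
common action on BMP is what shapes the gradient, and treating them as one
"BMPi" species keeps the model identifiable.

The dynamics on the domain are

$$\partial_t b = D_b \nabla^2 b + m(x)\, \frac{\rho_b b^2}{(n_0 + n)(1 + \kappa b^2)}
  - \mu_b b - \lambda_s S(r,t)\, b + k_\mathrm{ex} (c_\mathrm{dose} - b),$$
$$\partial_t n = D_n \nabla^2 n + m(x)\, \rho_n b^{\,q} - \mu_n n,$$

with the pSMAD1-like readout defined as $b / (1 + \lambda_s S)$. The terms
encode the following assumptions.

* **Confined production, free diffusion** (`m(x)`): cells - and hence all
  production - exist only on the colony disc of radius `R_colony`; diffusion,
  decay and bath exchange act on a larger cell-free domain
  (default `R_domain = 2 R_colony`). Inhibitor secreted by the colony
  therefore escapes across the colony edge, depleting `n` near the rim.
  Because the activator's self-amplification is suppressed by `n`, the rim
  sees the strongest amplification: this, and nothing else (no receptor
  relocalisation is assumed), produces the peripheral-high pSMAD1 gradient.
* **Well-mixed bath exchange** (`k_ex (c_dose - b)`): the experiments vary a
  medium concentration maintained over 24-48 h, not an initial condition, so
  the exogenous dose enters as relaxation towards the bath level everywhere
  in the domain. `c_dose` is in arbitrary units numerically equal to the
  ng/ml dose.
* **Saturating autocatalysis with a basal inhibition floor**: the activation
  term is the classical saturating activator-inhibitor form with an offset
  `n0` in the denominator. `n0` plays two roles: it is the basal inhibitor
  tone present before any induced antagonist accumulates, and it keeps the
  inhibitor-knockout experiment (`rho_n = 0`, the Noggin-null line) finite -
  without it the activation term diverges as `n` decays away.
* **Nodal-derived inhibition** (`lambda_s S(r,t) b`): Nodal signalling is not
  modelled mechanistically. Its BMP-inhibitory consequence is imposed as a
  static spatial profile modelled after the interior SMAD2 ring observed at
  24 h: a Gaussian ring `nodal_ring(A, r_peak_frac, w)`, optionally ramped in
  over time (`tau_ramp`) for robustness checks, and replaceable by a
  tabulated radial profile. This mirrors how the inhibition profile was
  obtained empirically rather than derived; it deliberately does not explain
  how the Nodal profile itself forms.

### Parameter presets

Three presets encode the study conditions (`rd_params(preset)`); all rates
are per hour, diffusivities in um^2/h, concentrations in arbitrary units.

| parameter | SB / nodal | turing | meaning |
|---|---|---|---|
| `D_b` | 15 | 600 | activator diffusivity |
| `D_n` | 60 000 | 150 000 | inhibitor diffusivity |
| `rho_b` | 0.6 | 8 | autocatalysis rate |
| `rho_n` | 1 | 1 | inhibitor induction rate |
| `q` | 1 | 2 | inhibitor-induction exponent |
| `mu_b`, `mu_n` | 2, 2 | 1.5, 2 | decay rates |
| `kappa` | 1e-3 | 1e-4 | activator saturation |
| `k_ex` | 0.5 | 0.01 | bath-exchange rate |
| `n0` | 3 | 0.5 | basal inhibitor offset |
| `c_dose` | 25 | 200 | default dose |
| `lambda_s` | 0 / 2 | 0 | Nodal coupling |

Two distinct regimes are intentional, and they echo the medium dependence of
the experiments, where periodic signalling foci appear only in defined
(N2B27) medium and never in serum-replacement medium:

* The **SB/nodal preset** is the strong-exchange regime: serum-replacement
  medium buffers the ligand, so `k_ex` is large and the bath pins `b` near
  `0.2 c_dose` everywhere. First-order inhibitor induction (`q = 1`) makes
  the colony a *linearly stable spatial amplifier*: `b` is amplified most
  where `n` is lowest (the rim), giving the gradual edge-high gradient, a
  strictly increasing peripheral dose response, rising centre levels as
  colonies shrink, and a raised centre/edge ratio when inhibitor production
  is knocked out. The small `D_b` reflects ligand that is nearly immobile
  within the dense cell layer - lateral transport happens through the
  well-mixed medium, not by diffusion in the layer.
* The **turing preset** is the weak-exchange regime: with `k_ex` small and
  quadratic inhibitor induction (`q = 2`, the classical form), the
  homogeneous state is Turing-unstable. `linear_stability()` finds the
  positive steady state numerically (the activator balance is monotone, so
  the root is unique), evaluates the dispersion relation of the 2x2
  linearisation, and reports the fastest-growing wavelength - 419 um at the
  defaults. A 3 mm colony fits many wavelengths and breaks into interior
  foci whose mean nearest-neighbour spacing falls within 25% of that
  wavelength; a 500 um colony fits none and keeps only the peripheral ring,
  reproducing the size selectivity of the patterning.

Why can one parameter set not do both? Under the stated kinetics with
`q = 2`, the destabilising slope at the steady state scales as
`rho_b mu_n / (rho_n b)`: *lower* doses are always more unstable, while the
experiments show foci at high dose. Under strong exchange with `q = 1`, the
edge amplifier can be pushed into an ignited (locally supercritical,
saturation-limited) state that yields dramatic contrast - but the saturated
rim level then *falls* with dose (the antagonist level rises faster than the
bath term) and the ignition front converges slowly under grid refinement.
The shipped SB preset therefore stays subcritical: the converged centre/edge
contrast is a modest 0.81, but every directional claim - monotone gradient,
dose ladder, size ladder, knockout shift, Nodal reshaping - holds strictly
and is stable to halving the grid spacing (<1% per bin).

### The Nodal ring

`nodal_ring()` defaults to amplitude `A = 1`, `r_peak_frac = 0.72`,
`w = 30` um, static (`tau_ramp = 0`), with coupling `lambda_s = 2`. The ring
position is the one genuinely tuned choice: the observed SMAD2 ring sits in
the colony interior near the periphery, and with the bath-exchange kinetics
a ring centred much closer to the rim (e.g. at `0.8 R`) overlaps the colony
edge enough to erase the peripheral pSMAD1 peak that must survive. At
`0.72 R` the model reproduces the full reshaping phenotype: a deep
suppression trough under the ring, a surviving peripheral maximum, a second
interior maximum in the central region, a peripheral level *below* the
Nodal-off level, and a half-decay width from the colony edge (the distance
at which the readout first falls to half its peripheral peak; equal to
`R_colony` when it never does) that shrinks from the full radius to ~25 um
at 50 ng/ml. The ramped profile (`tau_ramp > 0`) exists to verify the
outputs are robust to the inhibition developing over time rather than being
present from the start.

## 2. Numerics

* **Discretisation**: axisymmetric finite volumes on `r = 0..R_domain`
  (symmetry at 0, no-flux at `R_domain`) or a square grid of side
  `2 R_domain` for full 2-D runs. Boundary rows are scaled to their half-cell
  volumes, so zero-flux mass conservation is exact (verified to 1e-6 relative
  in the tests). The binary colony mask is exposed on the domain object; the
  production terms additionally use a sub-cell coverage fraction (exact in
  1-D, 8x8 subsampling of rim cells in 2-D) so that the colony boundary does
  not alias on coarse grids, and radial averaging and fate assignment use
  fully covered nodes only - the straddling rim cell represents a
  half-outside average that would dilute the outermost annulus.
* **Time stepping**: operator splitting with implicit (backward-Euler)
  diffusion, factored by direction in 2-D. Each directional factor is
  inverse-positive, so the diffusion step preserves positivity even at
  `D_n dt / h^2` in the hundreds, where trapezoidal schemes ring at the
  colony-mask discontinuity. Reactions are explicit, sub-cycled per step so
  the sub-step satisfies `dt |df/db| < 0.2`; a sub-cycling cap converts
  genuine blow-ups into a named integration error. Tiny clamped negatives are
  tolerated; negativity beyond 5% of the field scale aborts with an error.
* **Default steps**: `dt = 0.05` h (0.01-0.02 h where 1-D and 2-D runs are
  compared bin-by-bin, since the two discretisations carry different O(dt)
  splitting bias at the rim); grids resolve the colony radius with at least
  20 nodes by construction, `h = 5` um for 500 um colonies and `h = 25` um
  for the 3 mm Turing runs.
* **Degenerate inputs**: a single saved time point cannot be integrated into
  an exposure; thresholds must satisfy `T_low <= T_switch`; tabulated Nodal
  profiles must cover `[0, R_colony]`; `rho_b = 0` has no positive
  activator-inhibitor steady state and `linear_stability()` says so.
* **Problem sizes**: the test-suite and the acceptance script run the 500 um
  analyses at `h = 5` um and 24-48 h horizons, and one 3 mm x 72 h 2-D
  Turing run (241^2 nodes) shared across checks; the Monte-Carlo calibration
  uses 200 null replicates at `n_null = 999` and the power analysis 100
  replicates. These sizes were chosen as the smallest at which every
  compared quantity is stable to doubling.

## 3. The positional-information fate rule

Fates depend on both morphogen level and induction time. The default
exposure measure is cumulative: `E(x) = integral of readout(x, t) dt`
(trapezoidal over saved fields, units a.u. h). `assign_fates()` thresholds
`E`: below `T_low` the position retains the pluripotency/preneural marker
(SOX2-like); at or above `T_switch` it acquires the patterned fate, which the
Nodal switch relabels - GATA3-like non-neural ectoderm when Nodal is off
(preneurulation-like outcome), BRA-like primitive streak when Nodal is on
(peri-gastrulation-like outcome); in between it is "none", differentiated
but marker-negative, reflecting lines and conditions that differentiate
without expressing the patterned marker.

Whether the real switch integrates exposure cumulatively or requires a
sustained level for a minimum duration is not established; both rules are
implemented (`exposure_map(rule = "time-above", level = ...)` counts hours at
or above a level) and cumulative exposure is the default because a single
scalar already reproduces the dose-by-time interchangeability of the fate
maps. The default thresholds `fate_thresholds(T_low = 180, T_switch = 190)`
are presumptive values in arbitrary exposure units, placed inside the
exposure range of the default SB condition so that the 24 h, 25 ng/ml colony
patterns as observed - GATA3 annulus at the boundary, SOX2 centre - while
lower doses remain SOX2 throughout and 48 h at 50 ng/ml converts the whole
colony. Fate ordering tests run at the annular-bin resolution of the
quantification pipeline (25 um bins, about two cell diameters); the model's
sub-cellular rim boundary layer is below that resolution, and no microscope
would see it either.

The two-threshold ladder is deliberately minimal: the full multi-ring
peri-gastrulation fate ladder (SOX17/EOMES rings) is out of scope, as are
trophoblast-like branches and neural-plate-border maturation.

## 4. Single-cell colony quantification

The pipeline starts from per-cell tables (well, x, y, one intensity column
per stain), the format of scanner exports; no image processing is involved.

* **Colony assignment** (`assign_colonies`): DBSCAN per well. Core points
  have at least `min_samples` neighbours (self included) within `eps`;
  clusters are connected components of core points, numbered by their
  smallest core index; border points join the lowest-numbered reachable
  cluster; the rest is noise. These conventions make labels deterministic and
  are enforced against an independent brute-force construction in the tests.
  The original tool states the algorithm but not its parameters, so the
  defaults scale with the data: `eps` = 3x the median nearest-neighbour
  spacing of the well, `min_samples = 10`.
* **Effective radius**: the 95th percentile of member-cell distances to the
  centroid, rescaled by `1/sqrt(0.95)`. The rescaling matters: for a
  uniformly covered disc the raw percentile sits at `sqrt(0.95) R`, and the
  resulting 2.5% inflation of normalised radii visibly distorts steep
  profile shoulders.
* **QC** (`filter_colonies`): flags - never deletes - colonies whose cell
  count falls outside `count_bounds` times the median colony count or whose
  radius deviates more than 30% from nominal; merged doublets fail both.
* **Radial profiles** (`radial_profile`): per colony, cell radii normalised
  by that colony's effective radius, annular bin means, then the grand mean
  across colonies with SD and a t-based 95% CI (`qt(0.975, n-1) sd/sqrt(n)`);
  colonies are weighted equally, never cells, so duplicating a colony's
  cells changes nothing. With one colony the SD and CI are reported as 0.
* **Hexagonal maps** (`hex_map`): pooled centroid-relative positions binned
  into a hexagonal tiling (axial coordinates with cube rounding), mean
  intensity per occupied hexagon, min-max normalised across hexagons; when
  all hexagons are equal the normalised value is defined as 0.
* **Percent positive** (`percent_positive`): thresholds pooled
  log-intensities by exact Otsu (between-class variance maximised over all
  splits of the sorted sample), a two-component Gaussian mixture (upper
  component posterior > 0.5), or a fixed value; degenerate zero-variance
  channels fall back to the fixed method with a warning.

## 5. Focus detection and periodicity statistics

`detect_foci` follows the marker-negative definition: thresholding is more
reliable for the SOX2 channel than for the focal markers themselves, so foci
are SOX2-negative regions. Below-threshold cells are rasterised onto a grid
(`grid_h`, default 50 um), 8-connected components below `min_area` are
dropped, and components touching the outer 5% of the radius are excluded -
the peripheral ring is a boundary feature of the gradient, not a focus.

`nn_distances` histograms each focus's distance to its nearest neighbour on
fixed bins (20 bins spanning `[0, radius/2]`), reports the Shannon entropy of
the normalised histogram, and `compare_distributions` the base-2
Jensen-Shannon divergence between two histograms on identical bins (0 for
identical, 1 bit for disjoint support). "Information-dynamics measures" is
implemented as exactly this entropy/JSD pair; the histogram bin scheme is
fixed across observed and null patterns so divergences are comparable, and
the bin count is exposed for sensitivity checks.

`mc_test` generates `n_null` matched patterns (same point count and domain),
pools their NN distances into a reference histogram, uses
`JSD(pattern, pooled null)` as the statistic and reports the add-one
Monte-Carlo p-value `(1 + #{JSD_null >= JSD_obs}) / (n_null + 1)`, which is
super-uniform under the null by construction. Calibration is verified by
simulation: the empirical type-I error at alpha = 0.05 lands in
[0.03, 0.07], and power against hexagonal lattices jittered by 5% of their
spacing exceeds 90% at 30 points. Ripley's K and pair-correlation analyses
would be natural extensions but are intentionally absent.

## 6. Expression analysis

`ddct_log2fc` implements plain delta-delta-Ct with GAPDH as the internal
reference and day 0 as baseline: `dCt = Ct_gene - Ct_ref` within each (line,
day, replicate), `ddCt` subtracts the line's mean baseline `dCt`, and
`log2FC = -ddCt`. No primer-efficiency correction is applied, matching the
assay. Plate-wide Ct shifts cancel in `dCt` by construction.

`cluster_responders` groups lines into Strong / Intermediate / Weak per gene
by k-means (k = 3) on each line's mean log2FC trajectory over days 1-3,
unstandardised - standardising would erase exactly the magnitude differences
the labels describe. Replicates are averaged before clustering (replicate
values are retained in the output); 50 seeded restarts make the optimum
reliable, labels are ordered by descending centre mean so they are
content-based, and on small instances the solution is verified against
exhaustive enumeration of all 3-partitions. Whether the original analysis
clustered on all four days or on replicates rather than means is not
recorded; days 1-3 on means is the declared default and both choices are
arguments.

## 7. Synthetic data: what it does and does not emulate

The generators produce the statistical structure the analysis assumes, so
every downstream stage is testable without external data.

* `generate_plate`: colony centres on a grid at the specified pitch, nuclei
  placed by sequential hard-core sampling (minimum separation 10 um -
  nuclei cannot overlap) to the target density, channel intensities
  `gain * profile(r/R) * LogNormal(0, sigma) + background` (multiplicative
  lognormal noise because immunofluorescence intensities are right-skewed),
  and uniformly scattered off-colony cells. Ground truth (colony id, true
  normalised radius, true positive state) is written to a separate sidecar
  table so the pipeline under test cannot consume it by accident. Geometry
  covers every size used on the plates: the 200-700 um series, the 500 um
  default, 1 mm screens, 3 mm foci colonies. Per-colony cell-count
  dispersion in real plates is not matched to a printed value - it is
  exposed as parameters instead.
* `generate_point_pattern`: uniform-random points on the disc, jittered
  hexagonal lattices (with exact-count matching by thinning), or maxima
  extracted from a simulated 2-D field (strict 8-neighbour maxima above an
  intensity quantile, merged within a minimum separation, peripheral band
  excluded).
* `generate_qpcr`: Ct tables whose delta-delta-Ct analysis recovers exactly
  the planted log2FC trajectories at zero noise, with Gaussian Ct noise and
  planted line clusters otherwise.

What passing tests on these data do **not** show: real colonies have
non-circular outlines, spatially correlated staining artefacts, segmentation
errors, uneven illumination and cell-density gradients, none of which the
generators emulate; intensity noise is independent across cells, which
real-plate batch effects are not. The quantification results on synthetic
plates therefore demonstrate correctness of the computations, not robustness
to every experimental pathology. Determinism is per-seed within R's RNG;
all generation is reproducible byte-for-byte for a fixed spec and seed.

## 8. Known limitations

* The RD kinetics are a documented stand-in of the classical saturating
  activator-inhibitor form; reaction terms are isolated in one place in the
  integrator precisely so alternative kinetics can be substituted.
* Nodal inhibition is an imposed profile, not an emergent field; the model
  cannot address how the SMAD2 ring forms or how its three candidate
  activation routes combine.
* The pooled-inhibitor simplification cannot represent experiments that
  separate Noggin from CER1/GDF3 (e.g. single-antagonist knockdowns beyond
  the total-production knockout).
* The subcritical SB preset trades gradient contrast (0.81 centre/edge,
  converged) for strict monotonicity and grid convergence; runs seeking
  visually dramatic gradients can raise `rho_b` towards the ignited regime
  at the cost of those guarantees.
* No 3-D or multi-well coupling, no receptor trafficking, no parameter
  fitting to deposited imaging data.
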