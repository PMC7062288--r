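---
title: "gliosim: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{gliosim: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gliosim)
```

# The model

`gliosim` simulates PDGF-driven glioblastoma as a hybrid discrete-continuum
system, modeled on the retrovirally induced rat tumor in which infected glial
progenitors overexpress platelet-derived growth factor (PDGF) and recruit
normal progenitors into the lesion. Three interacting representations share
one brain-tissue domain:

* **Cells** are off-lattice agents with continuous positions (micrometers,
  image convention: origin top-left, y downward). Each cell carries an
  inherited *potential* phenotype — an intermitotic time $\tau$ (h), i.e. a
  maximal proliferation rate $p_{pot} = 1/\tau$, and a maximal migration
  speed $m_{pot}$ (um/h) — plus cycle progress, a quiescence flag and a
  stop-and-go migration state.
* **Cell density** is tracked on a coarse 100 um square mesh used only for
  crowding: a node holds at most $\kappa$ cells in gray matter and
  $2\kappa/3$ in white matter. Cells above capacity become quiescent (the
  cycle freezes where it left off and resumes when room opens up).
* **PDGF** lives on a fine hexagonal lattice (pointy-top, 25 um center
  spacing, node radius equal to the 12.5 um cell radius) and undergoes
  secretion by infected cells, consumption by all active cells, first-order
  decay, and diffusion.

The *observed* phenotype is the potential scaled by the local PDGF response,

$$ (p, m) = \big(p_{pot}\,\gamma_p(C),\; m_{pot}\,\gamma_m(C)\big), $$

with a Hill response evaluated separately for proliferation and migration
(each with its own half-max $K$ and recruited sensitivity $\beta$):

$$ \gamma(C_{PP}) =
  \begin{cases}
  \dfrac{C_{PA} + C_{PP}}{C_{PA} + C_{PP} + K} & \text{infected cells} \\[2ex]
  \dfrac{C_{PP}}{C_{PP} + \beta K} & \text{recruited cells,}
  \end{cases} $$

where $C_{PP}$ is the paracrine concentration at the cell's hex node,
$C_{PA}$ (`p_a`) is a constant autocrine boost only infected cells receive,
and $\beta \in (0.1, 1]$ lowers the recruited cells' activation barrier while
keeping them inactive at $C_{PP} = 0$. An inactive *recruitable* progenitor
field (seeded as a Poisson field at `rho_R`% of local capacity) activates
permanently wherever local PDGF exceeds $5\times10^{-4}$ ng/mL (strict
inequality); the same threshold doubles as a per-step activity cutoff for
active cells in essentially PDGF-free tissue, where $\gamma \le 0.001$.

Division places a daughter one cell radius (12.5 um) away at a uniform
random angle (resampled up to 10 times if it lands outside tissue, else atop
the parent); the daughter copies the parental $(\tau, m_{pot})$ exactly —
inheritance has no mutation, so all heritable heterogeneity present at any
time descends from the initial draws. Phenotypes are drawn from truncated
normals ($\tau \ge 5$ h; $0 \le m_{pot} \le 100$ um/h); setting
$\sigma_\tau = \sigma_v = 0$ recovers the fully homogeneous model in which
all observed heterogeneity is environmental.

Migration is a stop-and-go persistent random walk. At each persistence
expiry the cell flips an unbiased coin between stopping and moving (the
asymmetry between observed stop and move durations comes from the
persistence means, 70.1 vs 42.6 min, not from the coin; the coin probability
is configurable), samples a new exponential persistence time, and turns:
uniformly in gray matter, or by a normal deviation with standard deviation
`sigma_theta` about its current heading in white matter, where moving runs
are also lengthened 1.5-fold. A cell may not enter non-tissue space — it
retries up to 10 random angles, escalating the step by one cell diameter per
round up to three diameters — and may enter a node at or above capacity only
if that node currently holds fewer cells than its own.

## One engine step

Each step of length `dt` executes: density rebuild; activation sweep (new
recruits draw their phenotype immediately but enter the loop next step); the
cell loop (quiescence, cycle advance, division, migration, then PDGF
secretion `r_s dt` and clipped consumption `r_c r_s dt` at post-move
positions); field decay then diffusion; and the anti-proliferative kill
sweep while treatment is active. Treatments: **AP** removes, every step,
each active non-quiescent cell with $\tau <$ 60 h (quiescent cells are
spared regardless of $\tau$, which is what makes recurrence from the dense
core possible); **AM** multiplies all effective speeds by 0.1 while on,
reversibly.

# Parameters

The sixteen searched parameters and their admissible ranges are returned by
`param_ranges()`; `parameter_set()` adds fixed constants. Points worth
noting:

* `kappa` (capacity per 100 um node) is a pure scale factor: every size
  metric thresholds density *relative* to capacity (10%, 50%, 1%), so
  results are invariant to it and it can be chosen for compute budget. The
  package default is 100 (a proxy for a 300-um-thick slice); the bundled
  calibration runs use 25.
* The PDGF decay rate is treated as a first-order rate in day^-1 (its
  printed unit elsewhere, ng/mL/day, is dimensionally inconsistent for a
  first-order process; the admissible range 0-0.5 is kept).
* All secreted PDGF enters the paracrine field; the autocrine pool is a
  constant `p_a`, not a tracked quantity.
* Consumption is parameterized as a fraction `r_c` of the secretion rate.
* Recruited and recruitable cells draw their phenotypes from the same
  distributions as infected cells; nothing in the biology fixes a separate
  distribution and the fit cannot identify one.
* Quiescent cells still migrate by default (quiescence models contact
  inhibition of proliferation, and migration is evaluated after the
  quiescence check); `quiescent_migrate = FALSE` switches this off.

# Numerical choices

* **Hex diffusion.** The Laplacian uses the standard second-order hexagonal
  stencil $\nabla^2 C_i \approx \tfrac{2}{3h^2}\sum_{j \in N(i)}(C_j - C_i)$
  with $h = 25$ um, explicit sub-steps bounded by
  $\Delta t \le 0.9\,(3h^2)/(12 D_p)$, and no-flux boundaries (missing
  neighbors exchange nothing). The update matrix has unit column sums, so
  mass is conserved to machine precision in closed tissue; a point release
  on uniform tissue reproduces the 2D Gaussian variance growth $4 D t$
  within 5% (tested).
* **Decay** is applied in exponential form $e^{-r_d dt}$ rather than forward
  Euler; the difference is $O(dt^2)$ and the form is step-size robust.
* **Cell loop vectorization.** The per-cell loop is executed as vectorized
  sweeps. The only order-dependent interaction — moves that cross density
  nodes near capacity — is resolved exactly: crossings whose admission
  cannot depend on ordering (worst-case density bounds) are committed in
  one pass, and the remaining contested crossings are processed
  sequentially in randomized order against live counters, so no
  fixed-iteration-order artifact can arise.
* **Nearest-node maps.** Ties (points equidistant between nodes) resolve to
  the lower node id; the hot path exploits that the nearest hex node always
  lies in one of the two bracketing rows.
* **Determinism.** One base-R RNG stream is seeded once per run (replicates
  and cohort members derive distinct seeds arithmetically); identical
  (parameters, schedule, seed) give bit-identical trajectories, which the
  suite asserts.
* **Time step.** `dt` defaults to 0.25 h; the bundled calibration uses
  0.5 h, and virtual tracking runs use 0.05 h so the frame cadence matches
  the 3-minute hand-tracking cadence of the experimental assay.

# The synthetic brain

`make_synthetic_brain()` emulates only the features of the atlas slice the
model actually consumes: a gray-matter field, one white-matter band (a
synthetic corpus callosum, optionally gently curved), optional ventricular
holes, and an optional elliptical outline. It writes and reads the same
8-bit raster encoding (0 empty / 128 gray / 255 white) as
`load_tissue_raster()`, so a real atlas-derived raster can be substituted
without code changes. It does **not** reproduce anatomical geometry — cortical
folding, multiple tracts, asymmetric ventricles — so passing tests
demonstrate correct mechanics and calibrated dynamics on a brain-like
domain, not anatomical transferability.

# Metrics

* **Tumor diameter** (the imaging proxy): nodes at $\ge$ 10% of capacity;
  about their mass centroid, the maximal suprathreshold radius is taken in
  each of 360 angular bins and the diameter is twice the bin mean. Each
  node fills the angular interval its 100 um square subtends, so sparse
  outer nodes do not leave bins empty; an equivalent-area-circle variant
  was considered and rejected because the angular form degrades more
  gracefully for non-circular tumors.
* **Core and rim**: core diameter $d_c$ at the 50% threshold, rim extent
  $d_r$ = (1%-threshold diameter) $-$ $d_c$, i.e. the difference of the two
  average diameters (not half of it).
* **Phenotype statistics**: measured $(p, m)$ at each cell's local PDGF,
  over non-quiescent cells; potential statistics over all active cells.
* **Ki-67 proxy**: a non-quiescent cell is positive when its remaining
  cycle time $(1 - \text{progress})\,\tau/\gamma_p$ is at most 20 h; the
  index is the positive percentage within the density node of highest
  positive count (the stained-region analogue; the window and region are
  configurable).
* **Outcome classes** from the end-of-treatment diameter: complete response
  (< 0.5 mm), small (0.5-2), medium (2-3), large (> 3).

# Track statistics

Virtual tracking samples cells from the tumor rim (node density between 1%
and 50% of capacity), records positions at the engine cadence, and follows
daughters after division (the mother's track ends; both post-division cells
start fresh tracks flagged `divided`). Per-cell speed is total distance over
time *moving* (frames below a 1 um resolution are stops). Segmentation
yields directional runs split at stops and at turns above a 15 degree
threshold. Because consecutive same-state persistence periods are
indistinguishable in a trajectory, observed block means overestimate the
underlying persistence means; under memoryless persistence the merge count
is geometric, so `population_stats()` also reports corrected estimates
(`persistence_stop_min = mean_stop * move_prob`, and runs corrected by the
probability of an undetected small turn, valid for uniform turning, i.e.
gray matter). The bulk proliferation rate is division events divided by
starting cell count and observation time (% per hour).

# Calibration

`ga_random_search()` implements the hybrid genetic-algorithm/random-sampling
search: per generation, the elite survives, a `ga_fraction` (default 0.7) of
the population is bred by tournament selection (k = 2), uniform crossover
(rate 0.9) and per-parameter Gaussian mutation (sd = 10% of range), and the
remainder are random immigrants drawn uniformly from the admissible box.
These internals are this package's own choices — acceptance is by objective
value, not by search trajectory — and all are exposed as arguments. The
objective is the weighted mean relative error against `reference_metrics()`:
in size-only mode the three tumor diameters (1.7, 2.4, 3.2 mm at days 5, 10,
17); in extended mode additionally the cell-scale metrics, with equal
weights by default. Simulation failures (population-cap aborts) score
`Inf` and are discarded. Replicates per evaluation default to 3 in the API;
the bundled search used 1 replicate per evaluation with a re-scored final
pick, trading evaluation noise for search breadth.

The bundled best-fit configuration (`inst/extdata/best_fit_config.yaml`) was
produced by this search on the synthetic brain at the desk scale stated
there (8 x 8 mm domain, `kappa` 25, `dt` 0.5 h); the identifiability caveat —
many distinct parameter sets fit the three sizes equally well — is itself a
property of the problem and is asserted as such in the tests. A small
archive of accepted fits ships as `inst/extdata/mini_cohort.csv` for cohort
treatment experiments; it is a miniature, synthetic-brain stand-in for the
full 300-member cohort, not a reproduction of it.

`go_or_grow_mode()` provides the constrained fitting variant that splits the
population into a non-migrating "grow" class and a slowly proliferating
($\tau = 200$ h) "go" class.

# Known limitations

* No angiogenesis, hypoxia, necrosis, or death outside AP treatment; no
  phenotypic drift in recruited cells. These are model scope decisions, not
  omissions of the implementation.
* Migration is not PDGF-gradient-directed (no chemotaxis); white-matter
  anisotropy enters only through turning and run persistence.
* The 2D domain stands in for a tissue slice; `kappa` absorbs the implied
  thickness.
* The persistence estimator corrections assume exponential persistence and
  uniform turning; they are biased in strongly persistent white matter.
* Desk-scale problem sizes (domain, `kappa`, `dt`, cohort sizes and budgets
  used in the tests) are deliberate choices documented above; conclusions at
  full scale follow the same mechanics but were not re-verified here.
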