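---
title: "Methods: simulating a self-organizing vascular cell factory"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating a self-organizing vascular cell factory}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(vascufab)
```

This vignette documents the model, every parameter with its units and
rationale, the calibration procedure that produced the frozen defaults, and
the numerical choices and limitations of the implementation. Internal units
are micrometres, seconds, picograms and pascals; concentrations are areal
(pg/µm²); diffusivities are supplied in SI (m²/s) and converted on load.

# The system being simulated

A rectangular culture domain holds three cell populations between two
*circulatory columns* — immobile cell files along the left (source) and right
(sink) walls that stand in for perfusable manifolds. Interior cells are a
mixture of *vascular* cells (motile, adhesive, chemotactic) and *producer*
cells (immobile, synthesize product). The simulation asks: can the vascular
cells self-organize into a network that connects the two columns, and how
much does that network raise the factory's product output?

Two reference geometries ship as profiles: `default_config("full")`
(516 × 1028 µm, 24 000 interior cells) and `scaled_config()` (258 × 258 µm,
3 000 interior cells, 390 circulatory cells), the desk-scale profile used by
the tests and bundled experiments.

# Phase I: vasculogenesis

## Chemoattractant fields

Vascular and circulatory cells secrete diffusible chemoattractant at the
Monod-limited rate `mu_c * N_c0 / (N_c0 + k) * biomass` (pg/s), deposited
over the pixels each cell covers. Two fields are maintained and summed for
the gradient response:

* a **short-range** field secreted by vascular cells, decay `beta_v = 1e-4`/s;
* a **long-range** field secreted by the circulatory columns, decay
  `beta_c = 2.5e-5`/s.

With diffusivity `D_c = 1e-13` m²/s (0.1 µm²/s, protein-scale in tissue) the
decay lengths are `sqrt(D_c/beta)` ≈ 32 µm and 63 µm. The separation matters:
the short-range field drives local cord formation between neighboring
vascular cells, while the long-range column field biases cords to grow toward
the manifolds. `biomass_circulatory = 0.5` pg (vs 10 pg for interior cells)
sets the column field's amplitude low enough that vascular cells condense
with each other instead of plating onto the columns.

Both fields are relaxed to quasi-steady state each mechanical step (warm
start, explicit stepping at 90% of the `h²/(4D)` stability bound, relative
tolerance `eps_field`), an operator-splitting scheme standard in
individual-based biofilm simulators: solute dynamics are much faster than
cell motion, so the fields are treated as instantaneously equilibrated.

## Chemotaxis

Each vascular cell, once per mechanical step, draws one uniformly random
direction, samples the summed field one radius ahead (`C+`) and behind
(`C−`), and computes the saturating response

```
F = lambda * ( C+/(1 + beta_sat*C+) − C−/(1 + beta_sat*C−) )
```

applied along the sampled direction only when `F > 0` (cells climb gradients
or hold still; they are never pushed downhill). `lambda = 0.1` sets the
displacement scale (with `mobility = 1` and `dt_mech = 1` s, forces are
displacements in µm, capped at half a radius per step); `beta_sat = 1e-3`
keeps the response unsaturated at typical field values near cords while
bounding it near the columns.

Two modifiers shape the motility:

* **Contact inhibition** (`contact_inhibition = 4`, `contact_range = 0.5`
  µm): the response is scaled by `max(0, 1 − contacts/4)`, counting vascular
  neighbors within surface gap 0.5 µm, and motion into an existing contact
  is suppressed. Without it, condensation proceeds to round blobs; with it,
  aggregates extend into cords — the classic cord-formation ingredient.
* **Velocity persistence** (`persistence`, default 0): the step displacement
  is `v ← persistence·v + mobility·F·dt`. The parameter is exposed because
  persistent motion is a documented alternative route to network formation,
  but calibration at this cell density showed no benefit (cells are captured
  by nearby aggregates long before ballistic motion matters), so the default
  is fully overdamped.

## Adhesion: persistent bonds

Adhesion acts through **persistent bonds**. When two adhesive cells (two
vascular cells, or a vascular and a circulatory cell) approach to a surface
gap below `bond_form = 8` µm, a bond forms; bonds pull with the constant
contraction force `adhesion_strength = 1` (ramped linearly to zero over the
final micron before contact) and, with `bond_break = Inf`, never release.
Bonded pairs are treated as immature vessel cords from then on (see
extraction below). Setting `bond_form: null` in a config falls back to a
memoryless pairwise adhesion law of range `adhesion_range`.

This mechanism was the decisive calibration outcome, and the alternatives
are worth recording because each failed for an instructive reason:

* *Memoryless short-range adhesion* (force only while within 2–6 µm):
  local condensation stretches inter-cluster links past the range and the
  network fragments into dozens of islands.
* *Breakable bonds* (`bond_break` = 12–16 µm): the bonds under the most
  tension are exactly the load-bearing bridges between clusters, so even one
  or two breaks per step preferentially destroys the spanning structure.
* *Linear-spring bonds*: the bonded web equilibrates with many bonds
  stretched to ~5 µm gaps; the cell disks then rasterize as a dashed, not
  connected, mask.

Permanent constant-force bonds fix all three, and drawing each bond as a
solid capsule at rasterization makes mask connectivity equal bond-graph
connectivity. The calibration can also be read as a percolation argument:
bonds form within center distance `2r + bond_form = 12` µm, so at vascular
fraction `f` the expected bond degree is ≈ 20.4·f on the scaled geometry;
the Gilbert-graph percolation threshold (mean degree ≈ 4.5) predicts a
connectivity transition near f ≈ 0.22, matching the measured behavior (no
connected runs at ≤ 15%, transition at 20–25%, reliable connection at
≥ 30%).

Vascular–circulatory bonds anchor cords to the columns; the final micron
ramp prevents jitter at contact.

## Mechanics and convergence

After forces are applied, an iterative shoving relaxation displaces
overlapping pairs apart (circulatory cells are immovable) until the largest
overlap is below 0.05 µm. The phase ends when the largest per-step
displacement stays below `eps_move = 0.05` µm and the relative field change
below `eps_field = 5e-3` for `patience = 10` consecutive steps, or at
`max_steps` (400 on the scaled profile — enough for the bond network to
stop rearranging at all fractions tested).

# Phase II: network extraction and flow

1. **Rasterize** vascular and circulatory cells as disks at `resolution = 1`
   µm/px, plus a one-radius-wide capsule along every bond (bonded pairs are
   cords, so the mask is connected exactly where the bond graph is).
2. **Width map**: twice the exact Euclidean distance transform to the
   background — the local-thickness approximation of vessel diameter.
3. **Skeletonize** by topology-preserving thinning ordered by the distance
   transform (simple, non-endpoint pixels removed medially), preserving
   component and hole counts exactly (property-tested on phantoms).
4. **Graph**: skeleton pixels with 3+ neighbors cluster into junction nodes;
   branches are traced into edges with length = summed pixel steps and
   radius = half the mean local width along the path.
5. **Terminals**: skeleton nodes within `terminal_band = 12` µm
   (= `bond_form` + one cell diameter: a vessel end within bonding reach of
   a column is plumbed into the manifold) of the left/right walls are wired
   to virtual SOURCE/SINK supernodes. This happens *before* spur pruning so
   that short fingers reaching the columns gain degree ≥ 2 and survive;
   pruning then removes interior spurs shorter than `min_spur_length`
   (2 cell radii) and degree-2 chains are merged.

Flow solves the Poiseuille/Kirchhoff system: each edge is a pipe of
conductance `pi r⁴ / (8 eta l)`; SOURCE nodes are pinned at
`delta_P = 1000` Pa, SINK nodes at 0; interior pressures solve the sparse
weighted-Laplacian node-law system (loops balance identically because flows
derive from a potential). Water viscosity `eta = 8.9e-4` Pa·s. Dead ends,
self-loops and components not bridging the terminals carry exactly zero
flow. The solver is cross-checked in the test suite against an independent
loop-formulation oracle on random networks, and against closed forms for
series/parallel pipes.

# Phase III: factory operation

Nutrient `N` and product `X` live on the pixel grid, both initially zero.
Per time step:

* every flowing vessel (the extracted edges plus the two columns, which
  always exchange as single pipes) delivers nutrient along its skeleton path
  at `rho_n · 2πr · |Q|/(k_out+|Q|) · k_l/(k_l+N_local)` per unit length —
  saturating in flow, throttled as local nutrient accumulates — and removes
  product at `rho_p · 2πr · |Q|/(k_in+|Q|) · X_local/(k_p+X_local)`,
  clipped so `X` stays non-negative ("local" = mean over a 1-pixel
  neighborhood of the path);
* every producer synthesizes product at
  `mu_p · N/(N+k_p) · k_i/(X+k_i) · M_p` (Michaelis–Menten in nutrient,
  inhibited by accumulated product) and consumes nutrient at the same form
  scaled by `mu_n`;
* both fields diffuse explicitly with `D_p` (zero-flux boundary).

Mass is conserved to numerical precision: the change in total field mass
equals delivered − consumed (for `N`) and produced − removed (for `X`)
exactly, which the test suite checks to 1e-6 relative (measured ~1e-14).

A producer is *active* when its local nutrient exceeds
`activation_threshold = k_p/10`. Throughput is the product-removal rate
(µg/h), monitored over `steady_window = 60` s blocks; the run is steady when
the block rate changes by less than `steady_tol = 2%` twice consecutively,
after which removal is integrated over `production_window` more seconds and
averaged. Because the steady state is stationary, the window length does not
affect the value (tested), only the averaging cost; the scaled profile uses
240 s.

## Kinetic calibration

The kinetic constants are not measurements; they were chosen once, by
calibration on the scaled profile, then frozen:

* `mu_n/mu_p = 5` and `rho_n = 0.25` set a nutrient boundary layer around
  the columns much thinner than the domain half-width, so an avascular
  factory starves its interior (center nutrient ≪ activation threshold —
  asserted in the tests) while near-vessel producers activate;
* `k_i = 1` makes product inhibition visible wherever removal is absent,
  so poorly vascularized regions are doubly penalized (starved and
  self-inhibited);
* `k_out = k_in = 1e4` µm³/s place typical single-vessel flows on the rising
  part of the flow-saturation curve, so wider/shorter vessels genuinely
  deliver more;
* `D_p = 5e-12` m²/s (5 µm²/s) keeps exchange local on the 258 µm domain.

No kinetic constant was adjusted after the evaluation quantities were first
computed with this set.

# Numerics and determinism

* Explicit diffusion steps run at 90% of the `h²/(4D)` stability bound;
  violating the bound is an error, not a warning.
* First-order decay uses the exact factor `exp(−beta·dt)`.
* All randomness flows from one integer seed: initial placement and the
  per-step sampling directions. Reruns are bit-identical (tested), and
  experiment harnesses derive per-run seeds as
  `(master mod 2^20) + 7919·i`, so every run of a study is reproducible in
  isolation.
* Phase III and the inner morphogenesis kernels are C++ (Rcpp); the
  factory's diffusion uses preallocated swap buffers, making a full scaled
  run a matter of seconds rather than minutes.

# Worked example

```{r example}
library(vascufab)
cfg <- load_config(system.file("extdata", "example_config.yaml",
                               package = "vascufab"))
res <- run_pipeline(cfg, seed = cfg$seed, verbose = TRUE)
res$connected
res$throughput                      # ug/h at steady state
res$factory$active_fraction
```

The bundled experiment harnesses reproduce the evaluation quantities:

```{r experiments}
sw <- sweep_vascular_fraction(scaled_config(),
                              fractions = c(0.30, 0.45, 0.60, 0.75),
                              reps = 3, master_seed = 1)
sw$summary

rb <- robustness_study(scaled_config(), n_seeds = 10, fraction = 0.30)
rb$cv

ws <- width_scaling_study(scaled_config(), widths = c(258, 516), reps = 3)
ws$max_relative_spread
```

# Limitations

* The model is two-dimensional; volumetric productivity uses a slab-depth
  convention of one cell diameter, so absolute µg/h values are
  convention-dependent and only relative quantities should be compared.
* Kinetics are calibrated, not measured; absolute throughputs have no
  physical meaning beyond internal consistency.
* Vessels are rigid pipes fixed after Phase I: no remodeling, pruning by
  shear stress, or growth during operation.
* Nutrient supply is chemostat-like (unlimited external reservoir); product
  is removed to an infinite sink with no downstream separation.
* The scaled profile's stochastic claims (connectivity threshold, optimum
  fraction) are grid-resolution statements over small seed panels, not
  continuum limits.
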