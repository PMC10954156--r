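---
title: "Model design choices in an on-lattice tumor ABM: methods and rationale"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model design choices in an on-lattice tumor ABM}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(latticetumor)
```

# What this package models

`latticetumor` simulates the growth of a cancer cell population on a regular
lattice and quantifies how *model design choices* — not biological
parameters — change the emergent behavior of the simulation. The design
choices form three factorial studies:

* **System representation**: rectangular vs. hexagonal lattice geometry,
  crossed with dimension (2D, 3D, and the center slice of 3D, "3DC").
* **Cell-to-cell variability**: initial cell volumes constant at
  $v^* = 2250\,\mu m^3$ or drawn from $N(2250, 200)\,\mu m^3$, crossed with
  initial ages zero or drawn from $U(0, 12\ \text{weeks})$.
* **Nutrient dynamics**: glucose source profile (constant, pulse, cyclic)
  crossed with level (low, basal, high).

Each run produces three emergent-behavior metrics — colony growth rate,
colony symmetry, and mean cell cycle length — and a two-way ANOVA decision
pipeline compares them across factor levels.

# Lattice geometries

Cell agents occupy grid locations: $(x, y, z)$ in rectangular mode and
axial hexagonal coordinates $(u, v, w, z)$ with $u + v + w = 0$ in
hexagonal mode. Internally only $(u, v)$ are stored and $w = -u-v$ is
derived, which makes the coordinate invariant impossible to violate. The
domain is each geometry's natural ball of radius $R$: the square
$|x|,|y| \le R$, or the hexagon $\max(|u|,|v|,|w|) \le R$.

In 2D a location has 4 (rectangular) or 6 (hexagonal) same-layer
neighbors. In 3D, layers are stacked with alternating offsets:
rectangular layers alternate offset/no-offset (class $z \bmod 2$), and
hexagonal layers cycle no-offset → offset a → offset b (class
$z \bmod 3$). Each location then gains 4 vertical neighbors above and 4
below: the directly stacked location plus a class-dependent triple. For the
hexagonal stack, two bracketed offset triples serve three layer classes; we
assign them cyclically (classes 0 and 2 share one triple) and derive the
below-triples as the negations of the above-triples of the layer
underneath. Any assignment drawn from the defining offset triples that satisfies
reciprocity is observationally equivalent for diffusion and migration;
the test suite verifies reciprocity exhaustively over a radius-4, 5-layer
domain in both modes.

Molecules live on a finer lattice: each rectangular location covers a
2 × 2 block of rectangular fine sites (sublocations indexed clockwise from
top left), and each hexagon covers six triangles (indexed clockwise from
the upward-pointing triangle at the top — the anchor we chose for the
"clockwise from upper center" convention; any consistent bijection yields
the same diffusion behavior). A triangle neighbors the two triangles
beside it in its hexagon and one triangle of the hexagon across its outer
edge.

# Nutrient environment

Glucose, oxygen, and a TGF$\alpha$ surrogate diffuse by
$\partial C/\partial t = D \nabla^2 C$, discretized on the fine lattice.
The explicit scheme uses in-plane coefficients $D\Delta t/\Delta s^2$
(rectangular, 4 neighbors) or $4D\Delta t/(3\Delta s^2)$ (triangular, 3
neighbors) and a vertical coefficient $2D\Delta t/\Delta z^2$ gated by
$\delta \in \{0, 1\}$ ($\delta = 0$ iff a single layer), with
$\Delta t = 1$ s, $\Delta s = 15\,\mu m$, $\Delta z = 8.7\,\mu m$. Von
Neumann stability requires
$\lambda = 4 D \Delta t (1/\Delta s^2 + \delta/\Delta z^2) < 1$; with
realistic small-molecule diffusivities at this resolution
($D = 500\,\mu m^2/s$ gives $\lambda \approx 8.9$) the scheme is unstable,
so the engine uses the pseudo-steady-state approximation: each site becomes
a weighted neighbor average (in-plane weight 1, vertical weights
$2\Delta s^2/\Delta z^2$ rectangular or $3\Delta s^2/(2\Delta z^2)$
triangular, normalized by the total weight of the neighbors present).
Solver selection is automatic per molecule from $\lambda$.

Sources: the lateral border ring of the domain acts as a Dirichlet bath
held at the source concentration, emulating an external supply feeding
inward; interior borders are zero-flux. Three temporal profiles modulate
the glucose bath:

* **constant** — fixed at the level's concentration;
* **pulse** — media-change dynamics: reset to $C_0$ whenever
  $t \bmod t^* = 0$ and deplete as $(N_{t-1} - n_t)/V$ between pulses,
  where $N$ tracks the media molecule total and $n$ the cells' consumption;
* **cyclic** — a smoothed sawtooth
  $C_0\left[\tanh((3t - \lfloor 3t\rfloor - 0.5)\sigma) / (2\tanh(0.5\sigma))
  + \lfloor 3t\rfloor + 1.5 - 3t\right]$ with $\sigma = 15$: period 1/3
  day, three peaks per day, daily mean $C_0$.

Defaults with no canonical literature value, chosen once at realistic
values and config-overridable: basal glucose source 0.005 fmol/$\mu m^3$
(5 mM) with low/basal/high as 0.5×/1×/2× multipliers; oxygen bath
0.005 fmol/$\mu m^3$; diffusivities 500 / 2000 / 100 $\mu m^2/s$ for
glucose / oxygen / TGF$\alpha$; pulse interval $t^* = 2$ days; media
volume $V$ equal to one domain fine-lattice volume.

**Clock nesting.** The agent tick is 60 min. The pseudo-steady relaxation
(default 50 Jacobi sweeps) runs once per agent tick rather than once per
one-minute generator tick: the pseudo-steady operator is memoryless — its
fixed point is independent of sweep cadence — so finer nesting changes
nothing but cost. Generator additions are accumulated over the tick.

# Cell agents

Cells are cancerous or healthy, with states quiescent, migratory,
proliferative, apoptotic, necrotic, senescent, and the transient
"undecided" in which each tick's rules are evaluated. Cancer cells modify
three baseline parameters exactly once at construction: crowding tolerance
+50%, metabolic preference +50%, migratory threshold −50%.

The metabolism and signaling behaviors of the original framework are
represented here by deliberately simple, fully documented rules:

1. **Uptake**: demand = 10 fmol/h at critical volume, scaling linearly
   with volume and the metabolic-preference multiplier; actual uptake is
   capped at 50% of the locally available amount (the cell's 4/6 fine
   sites), subtracted evenly from those sites.
2. **Growth**: $dV = 10\,\mu m^3$ per fmol taken up, capped at twice the
   cell's critical volume.
3. **State decision**: a cell whose local TGF$\alpha$ surrogate exceeds
   its migratory threshold (baseline $2\times10^{-4}$ fmol/$\mu m^3$)
   becomes migratory, otherwise proliferative. Cells secrete the surrogate
   at 0.1 fmol/h, so crowded interiors accumulate it and disperse while
   sparse rims proliferate.
4. **Migration**: move to the least-occupied admissible neighbor (total
   volume plus the mover within the crowding tolerance, and no more
   crowded than the current site), ties broken uniformly at random; if no
   neighbor is admissible the cell is quiescent this tick.
5. **Division**: at volume $\ge 2 v^*_{cell}$ a proliferative cell splits
   with fraction $f \sim N(0.5, 0.02)$ truncated to $[0.4, 0.6]$; the
   daughter receives $f V$ and the mother's age (age inheritance), volume
   is conserved exactly, and the division target follows the same
   least-occupied rule. With no admissible target the division is
   deferred and the cell marked quiescent.
6. **Starvation**: 36 h continuously below 10% of the basal glucose
   concentration turns a cell necrotic; necrotic cells keep occupying
   their site.
7. **Apoptosis**: the hazard rate rises linearly from 0 at half-lifespan
   to 0.25/day at the lifespan (converted per tick as $1 - e^{-r\Delta t}$),
   with certain death at the lifespan. The default lifespan is 14 weeks —
   just above the 12-week maximum of the initial age distribution — so the
   age distribution is preserved with a visible cutoff at the lifespan and
   the oldest initialized cells apoptose early in a two-week run, while
   colonies seeded by a single aged cell still establish before the seed
   dies. A literal per-tick death probability reaching 1 would extinguish
   any aged colony within hours and is therefore not used.
8. **Senescence**: optional division-count cap, off by default.

Initialization seeds cancer cells at the domain center (one per layer in
3D); the tissue context also fills every other location with a healthy
cell. In the variable-volume mode the initial draw doubles as the cell's
critical volume, so small-initialized cells divide sooner; daughters use
the population default $v^* = 2250\,\mu m^3$. Cells are stepped in a
seeded-shuffled order each tick to avoid positional bias, and every
stochastic draw comes from the run's seed, making runs bit-for-bit
reproducible.

# Emergent-behavior metrics

* **Growth rate**: colony diameter is the maximum per-axis occupied span
  ($\max(D_x, D_y)$ rectangular, $\max(D_u, D_v, D_w)$ hexagonal; maximum
  across z slices in 3D, z = 0 slice for 3DC). The growth rate is the
  least-squares slope of diameter against time from day 2 onward,
  requiring at least three points.
* **Symmetry**: $1 - \frac{1}{N}\sum_i n_i/\lambda_i$ over the $N$ unique
  occupied locations, where $n_i$ counts unoccupied symmetry partners and
  $\lambda_i$ is 5 (hexagonal) or 3 / 7 (rectangular generic / axis-or-
  diagonal). "Unique occupied locations" is read as the deduplicated
  occupancy set; the alternative orbit-representative reading is isolated
  behind one function. 3D symmetry averages per-slice values over
  non-empty slices. By definition, only $x = y$ (not $x = -y$) receives the
  seven-partner treatment, so the rectangular metric is invariant under
  the point reflection but not under quarter turns; we implement it as
  defined.
* **Cycle length**: per-cell durations from entering the proliferative
  state to a completed division, averaged first within cells then across
  cancer cells (healthy cells excluded); 3DC restricts to z = 0 cells. A
  cell that fails to find space keeps its entry timestamp while
  quiescent, so deferred divisions lengthen the measured cycle rather
  than resetting it.

# Statistical pipeline

For each metric, a two-way ANOVA with interaction at $\alpha = 0.05$. If
the interaction is significant: simple main effects (each factor within
each level of the other, Bonferroni divisor = number of conditioning
levels) and pairwise Tukey tests within conditioning levels at
$\alpha = 0.01$ for factors with more than two levels. If not: the ANOVA
is refit without the interaction and significant multi-level factors get
full-data Tukey tests. Balanced tables use classical sums of squares;
unbalanced tables (failed runs are kept as missing and dropped with a
warning) use Type-II. Degenerate tables with a constant response report
$F = 0$ for every term — zero between-level variation is evidence of no
effect, not a numerical accident.

# Numerical and scale choices

Desk-scale defaults keep full factorial studies tractable on one CPU:
domain radius $R = 20$ (about 1 260 hexagons), $H = 7$ layers in 3D, 14
simulated days, metrics recorded every 12 h, replicates $n = 10$ per
condition. The test suite uses radius 3–6 domains for exact checks,
radius 20 for emergent-structure checks, 200 random colonies per geometry
for metric-oracle agreement, and 2 000 Monte-Carlo tables for the ANOVA
null calibration. Jacobi relaxation with a Dirichlet border converges
geometrically (about 1 500 sweeps to $10^{-8}$ on a radius-4 hexagonal
domain); the engine's 50 sweeps per tick track the moving quasi-steady
profile rather than resolving it exactly each tick, which is the intended
regime of a pseudo-steady approximation.

# What the generator emulates — and what it does not

The simulator generates all of its own data; the synthetic conditions are
the study conditions. Passing tests demonstrate that the defining
formulas, conventions, and qualitative regimes (quiescent core with a
proliferative rim; growth monotone in glucose level; age variability
driving early apoptosis) are implemented faithfully at desk scale. They
do not calibrate the model to any real tumor: absolute growth rates and
cycle lengths depend on the documented package-chosen defaults (uptake rate,
growth yield, thresholds), real nutrient fields are shaped by vasculature
rather than a border bath, and the metabolism/signaling rules are
one-line surrogates for pathway models. Conclusions should be read as
statements about model design choices, not about tumor biology.

# Known limitations

* The graph-based vasculature representation and pattern capillary
  layouts are out of scope; only border sources are provided.
* Oxygen is transported and consumed but not coupled to any state rule.
* The rectangular symmetry metric's location classes follow their
  definition exactly, with the quarter-turn anisotropy noted above.
* 3DC is an analysis view of a 3D run; it is never simulated separately.

# A worked example

```{r example, eval = FALSE}
sim <- run_simulation(sim_config(geometry = "hexagonal", dimension = "2D",
                                 context = "colony", days = 14,
                                 radius = 20, seed = 1))
sim_metrics(sim, "2D")
autoplot(sim)

tab <- run_factorial(experiment_design("nutrient", replicates = 10,
                                       base_seed = 1))
res <- decision_pipeline(tab, growth_rate, profile, level)
glance(res)
autoplot(res)
```
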