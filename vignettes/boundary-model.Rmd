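---
title: "A coupled vertex-model / Hedgehog-signaling model of the wing-disc compartment boundary"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A coupled vertex-model / Hedgehog-signaling model of the wing-disc compartment boundary}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wingvertex)
```

## The problem

The developing *Drosophila* wing primordium is partitioned into an anterior
(A) and a posterior (P) compartment. Cells never cross the interface between
them, even though cell divisions constantly push cells around: the boundary
is kept straight by mechanics, not by a fence. Laser-ablation experiments
indicate that junctions along the boundary carry roughly 2–2.5-fold more
line tension than junctions in the bulk. The puzzle is how Hedgehog (Hh)
signaling — which P cells send and A cells receive over a stripe many cell
diameters wide — produces a mechanical effect confined to a single
cell-cell interface.

`wingvertex` implements a tissue-scale answer: a hypothetical transmembrane
Hh target gene (called TMx throughout) is expressed at a basal level
everywhere and induced in a graded anterior stripe. TMx engages
*homotypically* across junctions and redistributes a fixed per-cell budget
of cortical tension toward the junctions with the most engaged TMx. Because
the redistribution depends only on TMx *ratios* between neighbors, a smooth
12-fold expression step at the boundary turns into a sharp, local tension
difference — and nothing happens inside the smooth stripe.

## The mechanical model

The apical tissue surface is a planar polygonal cell complex (a vertex
model): vertices carry positions, cells are counterclockwise vertex cycles,
and straight edges are the cell-cell junctions. Stable configurations
minimize the dimensionless work function

$$\bar E \;=\; \sum_{\langle ij\rangle} \bar\Lambda\,\bar\lambda_{ij}\,
\bar\ell_{ij} \;+\; \sum_\alpha \tfrac12\,(\bar A_\alpha - a_\alpha)^2
\;+\; \sum_\alpha \tfrac{\bar\Gamma}{2}\,\bar L_\alpha^2,$$

with lengths in units of $\sqrt{A_0}$ and areas in units of the target area
$A_0$ (a regular hexagon of edge $\ell = \sqrt{2/(3\sqrt3)}$ has unit
area). The three terms are junctional line tension (scaled per edge by the
TMx-dependent factor $\bar\lambda_{ij}$, see below), cell area elasticity
around the current target-area multiplier $a_\alpha$, and perimeter
elasticity. Defaults $\bar\Lambda = 0.12$, $\bar\Gamma = 0.04$ are the
standard parameter point of the underlying vertex model, at which relaxed
disordered tissue shows hexagons as the modal polygon class and mean cell
area increasing with polygon number. Margin edges (the tissue has an
explicit open margin; no periodic boundary conditions) use their own
coefficient, equal to $\bar\Lambda$ by default.

Growth follows the standard protocol: one randomly chosen cell at a time
ramps its target area linearly to $2A_0$ over `growth_steps` increments
(default 4), each followed by a quasi-static relaxation, then divides
through its centroid at a uniformly random angle; both daughters restart at
target area $A_0$ and inherit compartment, genotype, clone id and
concentrations (conserving molecule amounts). T1 neighbor exchanges fire on
junctions shorter than $\ell_{T1} = 0.05$ between minimization rounds,
which is what lets cells rearrange and sort.

## The signaling model

Seven species per cell, all concentrations in arbitrary units, everything
initialized at zero:

* **Hh** — produced in P cells, diffuses from cell to cell, binds Ptc.
* **Ptc** — anterior-only receptor: basal production plus induction by
  active Smo (Ptc is itself a Hh target, producing the classic Ptc stripe).
* **HhPtc** — the bound complex; receptor-mediated degradation of Hh.
* **Smo** — produced everywhere; production is multiplied by the genotype
  factor (0 in *smo* mutants, 2 in twin spots).
* **Lx** — a hypothetical Smo ligand flowing in from a reservoir; free Ptc
  actively pumps it away from Smo.
* **LxSmo** — the active Smo complex: Hh titrates free Ptc, the pump stops,
  Lx accumulates and activates Smo.
* **TMx** — basal production everywhere plus anterior induction
  proportional to LxSmo.

All reactions are mass action. Hh diffusion is discretized by the finite
volume method with the cell polygons as control volumes: the flux between
neighbors $\alpha,\beta$ is $D\,(\ell_{\alpha\beta}/d_{\alpha\beta})
(\mathrm{Hh}_\beta - \mathrm{Hh}_\alpha)$ with $\ell$ the shared edge
length and $d$ the centroid distance; margin edges carry zero flux, so
total Hh amount is conserved exactly under pure diffusion.

### Parameter calibration

Absolute kinetic rates for this pathway are not experimentally available;
what is well constrained is the *shape* of the response: a sigmoid total-Ptc
stripe hugging the boundary, a graded anterior TMx stripe at least ten cell
rows wide, a basal TMx level of 0.2 a.u. everywhere, a first-anterior-row
(A1) TMx level near 2.4 a.u. — a twelve-fold step across the boundary —
and, mechanically, a roughly two-fold boundary tension excess. The shipped
defaults of `kinetic_params()` were chosen once to satisfy those shape
constraints. The decisive quantity is the contrast in active Smo between A1
and the far anterior; it is maximized by making the Lx pump dominate Lx
turnover (`k_pump` large relative to `k_f`, `delta_Lx`) and by a small
effective Hh–Ptc dissociation constant
$K = (k_\mathrm{off}+\delta_\mathrm{HhPtc})/k_\mathrm{on}$. Because TMx is
purely downstream (it feeds back on nothing), the induction coefficient
`k_TMx_Smo_A` that yields an exact twelve-fold A1/basal ratio follows in
closed form from one steady-state run; `calibrate_tmx()` implements that
solve, and its output is frozen as the package default.

```{r calibration, eval = FALSE}
p <- calibrate_tmx(kinetic_params(), target_ratio = 12)
attr(p, "achieved_ratio")  # 12.0000
```

## Tension coupling

`compute_factors()` converts per-cell TMx into per-edge scaling factors in
four steps: every cell assigns its own TMx value to each of its edges; each
internal edge adopts the larger of its two cells' values (homotypic
recruitment — TMx enriches where binding partners face it); each cell
normalizes its edge values to unit mean (the per-cell effector budget is
fixed; signaling only redistributes it); and each edge's effective factor
is the mean over its one or two incident cells. Two properties follow
exactly: uniform TMx gives factors of 1 everywhere, and the factors are
invariant under global rescaling of TMx. On a hexagonal P1 cell with one
junction facing a twelve-fold A1 neighbor, the construction gives
$\lambda = 72/17 \approx 4.24$ on the boundary junction and $6/17$ on the
others. With the calibrated graded profile and the two-boundary-edge
geometry of the hexagonal lattice, the mean effective boundary tension
comes out at about $1.8\times$ bulk — the model's counterpart of the
measured ablation ratio.

## Numerical choices

* **Minimizer.** The energy is minimized by limited-memory BFGS (history 8)
  with Armijo backtracking, to a tolerance of $10^{-6}$ on the largest
  gradient component for stand-alone relaxations and $10^{-4}$ inside
  growth runs. Nonlinear conjugate gradient was evaluated first and
  rejected: on ill-conditioned configurations (cells squeezed near the
  boundary) it stalls for thousands of iterations where L-BFGS converges in
  tens.
* **Stiff kinetics.** The Ptc-dependent Lx pump makes the per-cell ODEs
  stiff. The compiled core integrates them with an L-stable second-order
  SDIRK scheme (two Newton solves on the 7-species system per step),
  operator-split (Strang) around second-order finite-volume diffusion,
  with a macro step of 0.25 time units. The diffusion substep uses
  explicit Heun steps while the mesh permits them and falls back to an
  L-stable implicit TR-BDF2 solve (Jacobi-preconditioned conjugate
  gradient on the area-weighted Laplacian system) whenever transiently
  degenerate cells would crush the explicit stability bound — growing,
  rearranging meshes pass through such states routinely. At these
  settings the split steady state agrees with a monolithic fine-step
  integration to better than 1%. Centroid distances in the two-point flux
  are floored at 0.1 length units for the same reason. Quasi-steady state
  is declared when the largest relative concentration change per unit
  time drops below the tolerance (`2e-3` per cycle inside runs,
  `1e-4`–`1e-5` for profile work).
* **Local relaxation.** Mechanical perturbations from a single growth
  increment are screened over a few cell rows, so in-run relaxations move
  only the vertices within 4 rows of the growing cell and of any junction
  already below the T1 threshold; a full relaxation runs every 25
  divisions and at the end of every run.
* **Topological safeguards.** T1 exchanges are refused if a participating
  cell would drop below four edges, and divisions redraw their angle rather
  than create a triangular daughter; a collapsed junction that immediately
  re-collapses after its T1 is left as a stable fourfold vertex for the
  rest of that relaxation. Margin edges that collapse fuse into a single
  margin vertex. Finally, a cell crushed below 2% of the target area whose
  junctions can no longer rearrange is extruded from the sheet (its
  vertices fuse at its centroid). Extrusion is deliberately not part of the
  biological model — it is a rare numerical safeguard (typically a handful
  of events per ten thousand divisions, at the boundary), without which a
  crushed cell pins the minimizer at a non-smooth point of the energy.
* **Degenerate inputs.** Division lines through a vertex, or closer than 5%
  of an edge length to one, signal a retry condition and the driver redraws
  the angle (up to 25 times). The explicit diffusion step refuses time
  steps above the stability bound by name.

## What the simulations emulate — and what they do not

A run starts from 220 hexagonal cells in a fixed rectangular block (20
columns by 11 rows; the left half anterior, the right half posterior, so the
interface is vertical) and grows by randomly oriented divisions to a target
cell count, with signaling advanced to quasi-steady state and mechanics
re-relaxed after every growth increment — the three time scales (growth ≫
signaling ≫ mechanics) are kept strictly separated. Clone experiments
relabel 20 cells as *smo* mutants (zero Smo production), each paired with
an adjacent twin spot (doubled production), spread uniformly at the start.

The full protocol runs to 6000 cells (the approximate cell count of a
third-instar wing pouch) over 10 seeds and takes CPU hours per run. The package's test suite and worked examples use scaled-down
versions of the same protocol — clone runs of 220 → 800 cells (5 seeds)
plus 220 → 420 cells (5 more seeds), and paired coupled/uncoupled controls
of 220 → 350 cells — sized to keep a complete test session within tens of
minutes on one CPU. At these sizes the boundary phenotypes are robust:
coupled boundaries stay near the lattice-straightness floor while
uncoupled controls wander, first-posterior-row cells enlarge, and
boundary-straddling anterior clones sort into posterior territory (never
the reverse). The clone-*roundness* distance trend is a weaker readout:
clones of a few cells are nearly shape-neutral under the per-cell
normalization (a lone low-TMx cell takes its neighbors' bond values on
every edge and feels no asymmetry at all), so the rounding signal grows
with clone size and, in our hands, is not yet statistically resolvable at
these scaled sizes — the corresponding acceptance check documents this
rather than papering over it. The full-size protocol is available by
simply raising `n_stop`.

Biological simplifications inherited from the model: no regulation of
overall growth or final size (runs stop at a cell count), no apoptosis, no
Dpp or other pathways, no explicit Ci transcription factor, 2-D apical
geometry only, and straight junctions.

## Limitations

* The kinetic parameter set is a calibrated point, not a fit: many
  parameter combinations produce the same constrained shapes, and absolute
  concentrations/times are in arbitrary units.
* Whether the Lx pump senses free Ptc only (assumed here) or total Ptc is
  not resolvable from the available material; with receptor occupancy high
  near the boundary the two choices differ quantitatively but not
  qualitatively.
* The bound complex HhPtc decays at its own first-order rate; partner
  release on decay is not modeled.
* Boundary roughness is measured as interface length over the largest
  pairwise distance between interface vertices, which is robust to the
  branched interfaces of uncoupled controls but saturates at
  $2/\sqrt3 \approx 1.155$ (not exactly 1) on a hexagonal lattice, whose
  straightest interface is a zigzag of slant edges.
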