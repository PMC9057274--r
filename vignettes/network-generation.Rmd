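---
title: "Generating disordered 2D networks by degree-transferring bond switching"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Generating disordered 2D networks by degree-transferring bond switching}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netswitch)
```

## The model

Many two-dimensional biological networks — basement membranes assembled from
collagen IV or laminin, actin meshes, and their inorganic analogues — are
well described as planar tilings of polygons: nodes where strands meet,
edges between them, and rings (faces) bounded by the edges. `netswitch`
generates such networks with a *variable* node-coordination distribution by
an extension of the Wooten–Winer–Weaire (WWW) bond-switching idea. The
classic WWW switch preserves the coordination number $k$ of every node;
here a move instead *transfers one unit of coordination*:

1. pick an edge $(A, B)$ uniformly at random, with random orientation;
2. delete $A\!-\!B$ and add $A\!-\!C$, where $C$ is a neighbour of $B$
   that is not already bonded to $A$;
3. relax the geometry locally around the switching site and compute the
   energy change $\Delta E$;
4. accept with the Metropolis probability
   $p = \min[1, \exp(-\Delta E / k_B T)]$ (we set $k_B = 1$, temperatures
   in reduced units);
5. on rejection, restore the previous accepted state exactly.

Node $B$ loses a unit of degree and $C$ gains one, so individual $k$
fluctuate while the mean $\langle k \rangle$ is conserved exactly — on a
trivalent start it stays 3 forever, and with it the mean ring size
$\langle n \rangle = 2E/F = 6$ on a periodic cell, by Euler's
characteristic for the torus ($V - E + F = 0$).

The energy is a simplified Keating-type potential with harmonic bond and
angle terms,

$$E = \sum_{\text{bonds}} \tfrac{k_r}{2}\,(r - r_{\mathrm{eqm}})^2
 + \sum_{\text{nodes}} \sum_{\text{gaps}} \tfrac{K_\theta}{2}\,
   (\theta - \theta_{\mathrm{eqm}}(k))^2 ,$$

with $r_{\mathrm{eqm}} = 1$ and the coordination-dependent equilibrium
angle $\theta_{\mathrm{eqm}}(k) = 2\pi/k$, recomputed whenever a node's
coordination changes. The angle sum runs over the $k$ consecutive-neighbour
angular gaps around each node (they add up to $2\pi$, making $2\pi/k$ the
exact per-gap optimum); a 2-coordinate node therefore prefers a straight
angle, i.e. a long boundary between two large rings. A fixed-$\theta$ mode
(`fixed_theta = TRUE`) is available but off by default; freezing the
equilibrium angle is known to leave more artefacts. Both force constants
$k_r$ and $K_\theta$ are free parameters in reduced units; because they
only set the energy scale, multiplying both by a constant is equivalent to
rescaling temperature, a fact worth keeping in mind when reading sweep
results.

## Moves, screening and ring bookkeeping

Configurations are screened before the Metropolis step. A trial move is
rejected outright ("screening rejection") when

* $B$ would drop below `k_min` (default 2 — dangling ends fall outside the
  polygon formalism) or $C$ would exceed `k_max` (default 7, i.e. reject
  $k \ge 8$; `k_max` is the knob varied in coordination-capped sweeps);
* either ring created by the switch would have fewer than 3 or more than
  `n_max` sides (default 19, i.e. reject $n \ge 20$);
* $C$ does not lie on the ring formed by notionally deleting $A\!-\!B$
  (the planarity guard: without it the new edge must cross others), or the
  merged ring would not be a simple cycle.

$C$ is drawn uniformly from the candidates passing all checks. We also
tested drawing $C$ uniformly from all neighbours of $B$ and rejecting
invalid picks; it widens the melt degree distribution and was not adopted.

Rings are maintained *combinatorially*: the two rings bordering
$A\!-\!B$ are merged, then split along $A\!-\!C$, all other rings
untouched. This keeps $\sum_i n_i = 2E$ and the torus Euler relation exact
after every accepted move (the engine can verify both after each
acceptance). Geometric face traversal (`find_rings()`, leftmost-turn over
angularly sorted half-edges) is used to build rings for well-embedded
networks — the honeycomb start, extracted images — but strongly disordered
states can carry crossed edges for which traversal is unreliable; that is
why generated networks serialise their ring list in the JSON format rather
than relying on re-traversal.

## Local relaxation

After the topological switch, nodes within `radius` graph hops (default 2)
of $\{A, B, C\}$ are relaxed by Polak–Ribière conjugate gradient with an
Armijo backtracking line search, until the gradient norm over the mobile
nodes falls below `force_tol` ($10^{-6}$) or `max_iter` (200) iterations.
All other coordinates stay bit-identical, and $\Delta E$ is the exact
full-network energy difference against the last accepted state. The
analytic gradient is verified against central finite differences in the
test suite.

## Protocols

* **Thermalisation** (`thermalize()`): `therm_steps` attempted moves at
  $T_{\mathrm{start}} = 10^4$, which accepts essentially every screened
  move and melts the lattice completely.
* **Annealing** (`anneal()`): geometric cooling, `moves_per_T` attempts per
  rung, temperature multiplied by `factor` $= 10^{-0.2}$ per rung from
  $10^4$ down to and including the first rung at or below
  $T_{\min} = 10^{-2}$ — 31 rungs with the defaults. "Steps" and "moves"
  both count *attempted* switches, screening rejections included.
* **Fixed temperature** (`run_fixed_T()`): partial thermalisation at one
  temperature, used to map the defect-driven region of the landscape.

The starting lattice is a periodic honeycomb (`build_honeycomb()`), the
strain-free zero of the potential. Cell dimensions are fixed by the ring
counts: width $n_x\sqrt{3}$, height $1.5\,n_y$ (bond lengths of 1). A
honeycomb with an odd number of hexagon rows is not periodic under a plain
rectangular wrap (the zigzag parity flips per row); the cell therefore
carries a shear term — a vertical wrap offsets $x$ by $\sqrt{3}/2$ — so
odd sizes are strain-free too. The default system size of $10 \times 10$
rings (200 nodes) is a package choice, comparable to the polygon counts of
typical experimental micrographs, and keeps a full annealing run at
desk scale (seconds).

## Metrics

`network_report()` assembles the metric set used to compare networks:

* $\langle k \rangle$ and $\mu_2(k)$ — mean and **second central moment**
  (population variance) of node coordination. The central-moment convention
  makes $\mu_2(k) = 0$ for the hexagonal lattice.
* $\langle n \rangle$, $\mu_2(n)$, $N$ — polygon side-count statistics and
  ring count. For a *finite* trivalent network Euler's characteristic with
  the outer face excluded gives $N = E - V + 1$ and $V = 2E/3$, hence
  $E = 3(N-1)$ and, counting two polygon sides per edge,
  $\langle n \rangle = 2E/N = 6(N-1)/N$: at $N = 100$, exactly 5.94.
  `trivalent_patch(100)` builds an explicit cross-check — a 99-gonal prism
  with $V = 198$, $E = 297$, all nodes trivalent and 100 counted rings.
* $r$ — the assortativity of ring sizes over the ring-adjacency (dual)
  network, i.e. Newman's degree-correlation formula applied to the sizes of
  adjacent ring pairs, each shared primal edge contributing one dual edge
  and each dual edge counted in both orientations. $r < 0$ means polygons
  neighbour dissimilar polygons (the Aboav–Weaire tendency of defect-rich
  but ordered networks), $r > 0$ similar polygons (demixing), $r = 0$ no
  preference. When every ring has the same size the statistic is undefined
  and reported as `NA`, never as 0.

For finite, image-derived networks `boundary_prune()` applies the standard
frame convention: every edge terminated by the image boundary is removed,
reducing $k$ for edge nodes, and dangling chains (degree $\le 1$) are then
removed iteratively so the result stays inside the polygon formalism.

## The render/extract round trip

To emulate the micrograph-analysis half of a network study without any
external images, `render_network()` draws a network as a binary raster and
`extract_graph()` traces a graph back out: Zhang–Suen thinning to unit
width, pixel classification by Rutovitz crossing number, junction-cluster
merging within `junction_merge_radius`, branch tracing, spur pruning below
`min_branch_length`, and boundary flagging within `boundary_margin` of the
frame. Chains of degree-2 pixels between junctions are contracted to single
edges by default (their count is recorded — mirroring the real ambiguity of
whether a strand is one biomolecule or two); `mode = "keep"` retains them.
Junction-free closed curves are kept as rings by inserting three synthetic
degree-2 division points (the minimal simple cycle; the network invariants
forbid self-loops and parallel edges). `roundtrip_check()` compares the
extracted, boundary-pruned graph against the degree-2-contracted source —
the quotient both representations share — and on clean, well-resolved
renders recovers the interior ring-size multiset exactly. Over-thick
strokes that fuse adjacent edges are the designed failure mode: rings merge
or vanish and the report flags the mismatch. This tracer is a simplified
stand-in; it makes no claim of equivalence to ridge-detection tooling, and
metrics obtained from real micrographs carry interpretation uncertainty
that the round trip only partially emulates.

## The network landscape

`run_sweep()` maps generated ensembles into the $\{\mu_2(k), r\}$ plane.
With the default $5\times5$ log-spaced force-constant grid
($0.01$–$100$), annealed networks populate a band of $\mu_2(k)$ values
that falls as $k_r$ grows (bond stiffness is what orders the network —
with soft bonds, coordination defects are nearly free because angles can
stay at their optimum while bonds stretch) and of small $|r|$. Fixed-
temperature runs separate two regions: at low $T_{\mathrm{fixed}}$,
isolated Stone–Wales-like defect pairs in a near-pristine lattice give low
$\mu_2(k)$ and negative $r$ (defects surrounded by ordered hexagons are
disassortative); warmer runs drift up and to the right, through a mildly
assortative partial-demixing window, toward the entropy-dominated melt.

What passing the suite shows — and what it does not: the generator's tests
establish exact conservation laws, seeded reproducibility, balanced
dynamics (melt-down and pristine-up runs at the same temperature converge
to the same $\mu_2(k)$), and the qualitative landscape structure. They do
not certify agreement with any particular experimental imagery, and one
quantitative note is in order: under this Hamiltonian and move set the
equilibrium $\mu_2(k)$ at effective temperatures of order 1 is about
1.1–1.5, and annealed grids reach maxima near 2. Published envelopes for
comparable simulated ensembles top out nearer 1.2; since force constants
only rescale temperature, the softest corner of the grid cannot cool below
an effective temperature of order 1 under the default ladder, so this
difference is a property of the model variant (gap-based angle terms,
uniform-over-valid candidate selection), not a sampling artefact. The
acceptance machinery reports the measured values as they are.

## Numerical choices and degenerate inputs

* Angular ties in face traversal are broken by node id; traversal is
  deterministic and independent of node labelling.
* The outer face of a finite component is the face of largest absolute
  enclosed (shoelace) area, with the signed-area sign as cross-check;
  disconnected inputs are traversed per component with a warning.
* `k_min = k_max = 3` is the degenerate WWW-like limit: the move set is
  empty and every proposal is a screening rejection.
* Temperatures must be positive; the final annealing rung *includes* the
  first temperature at or below $T_{\min}$.
* All randomness flows through R's global RNG: `set.seed()` (or the
  `seed` fields of schedules and `generate_network()`) makes entire
  trajectories, sweeps and the acceptance script reproducible.
* Test and example problem sizes — $4\times4$ to $10\times10$ ring
  lattices, a few thousand attempted moves, two seeds per sweep point —
  are the package's desk-scale defaults; the full protocol (thermalise
  10000 steps, 1000 moves per rung) is the `anneal_schedule()` default for
  production use.

## Limitations

* Local relaxation does not untangle a fully melted embedding; strongly
  disordered states may carry crossed edges. Ring bookkeeping remains
  exact combinatorially, but geometric re-traversal of such states is
  refused rather than silently wrong.
* The potential has no excluded-volume term, and more detailed forms
  (e.g. exponential–quadratic bonds) are out of scope.
* Polygon-area laws (Lewis, Lemaître) and Aboav–Weaire $\alpha$ fits are
  not computed; the assortativity recast is the only neighbour-similarity
  statistic.
* The skeleton tracer assumes clean binary input; grayscale handling,
  denoising and sub-pixel ridge localisation are out of scope.
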