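---
title: "skeinpath: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{skeinpath: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(skeinpath)
```

## The model

A polygonal link is an ordered set of 3D points partitioned into
components, each an open or closed polygonal path. The link must be
*simple* (non-adjacent edges never meet in 3D) and all topology is read
from the standard projection onto the xy-plane, which must be
*regular*: finitely many transversal double points, none at a vertex,
no two coincident. `ensure_general_position()` enforces regularity by
seeded rigid rotations; every operation is a pure function of its
inputs and seed.

At a crossing, over/under comes from the z coordinates of the two
lifted points and the oriented sign from the right-hand rule: approach
along the underpass in the direction of its orientation; if the
overpass runs left to right the sign is +1.

The invariant computed is the HOMFLY polynomial in the convention

$$\ell\,P(L_+) + \ell^{-1}P(L_-) + m\,P(L_0) = 0,\qquad P(\mathrm{unknot}) = 1,$$

so the $k$-component unlink has $P = \delta^{k-1}$ with
$\delta = -(\ell+\ell^{-1})/m$. The Jones polynomial is the
substitution $\ell = i\,t^{-1}$, $m = i(t^{-1/2}-t^{1/2})$ and the
Alexander polynomial $\ell = i$, $m = i(t^{1/2}-t^{-1/2})$; both are
verified in the tests against the classical tables for $3_1$, $4_1$,
$5_1$, $5_2$ and $6_1$ (including determinants 3, 5, 5, 7, 9).
Handedness labels are anchored at one reproducible choice: the
$(2,3)$ torus-knot fixture with the shipped parametrization is
*defined* to be the right-handed trefoil, and every L/R label in the
embedded table follows from it by the mirror substitution
$\ell \leftrightarrow \ell^{-1}$.

## Minimal structure reduction (MSR)

A *generalized Reidemeister move* replaces a subpath $M$ (from vertex
$i_s$ to $i_f$, interior vertices removed) by the straight segment $s$
joining its endpoints. The move is admissible when, reading the signed
intersection matrix of the projection:

* **C1** — $M$ is ascending or descending: at every self-crossing of
  $M$ the strand met first passes consistently over or consistently
  under;
* **C2** — the over/under statuses of crossings between $M$ and the
  other components form a set of at most one element;
* **C3** — adding the statuses of $M$ against the remainder of its own
  component keeps that set at one element;
* additionally (a deliberate strengthening, see *Design choices*), the
  replacement segment $s$ itself shares that single status against
  everything it crosses, keeps the link simple in 3D, and leaves the
  projection regular.

Under these conditions the move is an explicit ambient isotopy: lift
$M$ vertically above (or below) everything it crosses — possible
because all its external crossings have one status and C1 makes the
lifted arc unknotted rel endpoints — translate it, and drop it onto
$s$, whose crossings have the same status. The move length is defined
as $i_f - i_s - 2$, so the classical one-vertex triangle move has
length 0; single moves may remove arbitrarily many vertices.

After an accepted move the intersection matrix is updated
*incrementally*: rows and columns of the removed edges are deleted and
one freshly computed row/column inserted for $s$. Equality with a
from-scratch recomputation is asserted on a 500-move randomized
battery in the acceptance suite.

`msr_reduce()` sweeps start indices in order, longest candidate first
per start, restarting at the same index after an acceptance, until a
full sweep accepts nothing. Closed components are then relabelled at a
shifted seam (a pure renumbering) and the sweep retried, so subpaths
spanning the stored seam are also considered; the reduction is a
fixpoint (`msr_reduce(msr_reduce(L)) = msr_reduce(L)`, tested).

## Geometric skein triples

To apply the skein relation on the 3D structure, both remaining
members of the Conway triple are built inside a *clean quadrilateral*:

1. One vertex per cut edge (the four half-edges meeting at the
   crossing), at parameter $t \in (0,1]$ from the crossing; all $t$
   start at 1 and, while any quadrilateral side still meets another
   edge of the projection (the Xclean status table, updated
   incrementally per touched vertex), the parameter of the longest
   dirty cut edge is halved.
2. The quadrilateral is rotated about the crossing point so that no
   side is parallel to either crossing edge; the angle starts at half
   the minimum of the angle between the two projected crossing-edge
   lines and the smallest angular gap between cut directions (so no
   vertex sweeps across another edge), and is halved until the rotated
   quadrilateral is clean again. Rotated vertices keep the z of their
   unrotated lifts.
3. **Switch** ($L_\mp$): the under strand is rerouted through the two
   rotated vertices on its cut edges and lifted through a perturbed
   copy of the point reflection $W$ of the underpass through the
   overpass: $P(\alpha) = V_{out} + \alpha\,(W - V_{out})$, with
   $\alpha$ starting at 0.9 and updated $\alpha \leftarrow
   (1+\alpha)/2$ until the projection is regular, exactly one crossing
   changed, and the new crossing an overpass. (The naive formula that
   perturbs $W$ toward the overpass point is degenerate — both project
   to the crossing point, so the new vertex would sit exactly on the
   double point at every $\alpha$; attracting toward the outgoing
   quadrilateral vertex preserves the stated contract, including the
   convergence-to-1 overpass guarantee.)
4. **Smoothing** ($L_0$): the four cut strands are reconnected through
   two opposite sides of the rotated quadrilateral — the oriented
   reconnection joins the incoming strand of each edge to the outgoing
   strand of the other. A self-crossing splits its component in two; a
   crossing between two components merges them, with separator indices
   renumbered.

Every construction is verified before being accepted: the outer
rerouted pieces must meet the same edges, in the same order, with the
same statuses as the original cut edges (the topological check, via
ordered path signatures); the reconnection chords must be
crossing-free; and a global diagram diff confirms that, apart from the
processed crossing, partners, statuses and signs of every crossing are
unchanged. On failure the rotation angle is halved and the
construction retried.

The skein tree roots at the MSR-reduced link; at each node the
candidate crossings are those first met as an underpass along the
traversal (switching these progresses towards a descending diagram,
which is an unlink — the leaf condition). The *greedy* strategy
switches the candidate whose reduced switch configuration has the
fewest points; *fixed* takes the first candidate in traversal order.
Both give identical polynomials (tested on the full battery); greedy
trees are never larger in the median and often much smaller (7 versus
37 nodes on the Stevedore knot). Weights propagate bottom-up:
leaves get $\delta^{k-1}$, and an inner node with skein sign
$\varepsilon$ combines its children as
$P = -\ell^{-2\varepsilon}P_{switch} - \ell^{-\varepsilon}m\,P_{0}$.

## The independent oracle

`homfly_from_diagram()` runs the same skein recursion on *signed Gauss
codes* — purely combinatorial diagrams with no geometry, no reduction,
no quadrilaterals. Switching flips a crossing's passages and sign;
smoothing splices the passage sequences. The only code shared with the
geometric pipeline is crossing extraction from a projection, so
agreement between the two routes (asserted over all mirror/reversal
flips of the full fixture battery) validates the geometric
constructions end to end.

## Protein pipeline

Chains are the C-alpha trace (first model, first altloc, HETATM
excluded); consecutive C-alpha distances above 4.5 Å split the chain
into *parts* (the virtual bond is ~3.8 Å; 4.5 tolerates distortion and
flags true gaps — bridging gaps with straight lines is a known source
of artificial entanglement, prevented here by construction). Parts
shorter than 4 residues are dropped.

Classification reduces the open part first, then closes it — `direct`
(straight segment between the reduced termini; reduction makes this
segment short relative to the structure) or `radial` (termini extended
from the centroid to a bounding sphere and joined outside it) — then
re-reduces and computes the polynomial. Deeply knotted fixtures
classify identically under both policies (tested). A part whose
reduction reaches 2 points is reported unknotted directly.

Knotted-core trimming scans the N-terminus first: `n_trim` is the
minimal number of removed N-residues that unknots the part. The
C-terminus is then scanned with the N side fixed at `n_trim - 1` (the
deepest still-knotted prefix trim), giving `c_trim`. This is the one
reading under which a deeply buried knot reports large trims on *both*
sides; fixing N at `n_trim` would trivially give `c_trim = 0`.
Slipknots are not searched for: only gap-delimited parts are analysed.

## Synthetic data

The fixture generator is first-class, tested code and the package's
whole test surface:

* parametric torus knots $((2+\cos qt)\cos pt, (2+\cos qt)\sin pt,
  -\sin qt)$ and the standard figure-eight curve, sampled with a 0.32
  sample-step phase offset (the unshifted uniform sample hits exact
  symmetric vertex coincidences, a measure-zero degeneracy of the
  idealized curve);
* twist knots as closed braids with one crossing per letter by
  construction ($5_2$: word $(1,1,1,2,-1,2)$; $6_1$:
  $(1,1,2,-1,-3,2,-3)$), identities pinned by their Alexander
  polynomials and determinants;
* minimal stick forms: the 6-stick trefoil (frozen from the MSR
  reduction of the torus fixture) and a 7-stick figure-eight (frozen
  from a seeded random search), both verified against the oracle;
* random protein-like chains: self-avoiding walks with exact 3.8 Å
  steps and a 3.0 Å excluded-volume floor, the `helix_mix` style
  interleaving α-helix-like bond/torsion geometry with coil. For the
  lengths used in tests (≤ 150 points) at least 95% of seeded chains
  are unknots, mirroring real short proteins.

What a green test does *not* establish: fixtures are smooth,
well-separated curves; real PDB entries bring missing atoms,
alternate conformations beyond A, distorted bonds, and the full
preprocessing controls of a production census (out of scope here, as
are whole-PDB counts and the statistical analyses built on them).

## Numerical choices

* Simplicity tolerance: non-adjacent edges must stay `1e-9` of the
  bounding-box diagonal apart in 3D.
* Regularity tolerance: crossings within `1e-7` of the diagonal from a
  vertex or from each other void the projection and trigger rotation
  (at most 50 seeded attempts).
* Quadrilateral/rotation loops: at most 60 halvings (an underflow
  guard at `2^-60`); rotation angle underflow below `1e-12` rad
  signals pathological geometry to the caller.
* Perturbation: $\alpha_0 = 0.9$, $\alpha \leftarrow (1+\alpha)/2$,
  failure declared within `1e-12` of 1.
* Skein recursion depth capped at 64 (non-termination guard; never
  reached on the battery).
* Coefficients are integers held in doubles; all polynomial equality
  is exact.

## Known limitations

* `homfly()` requires closed components (the oriented smoothing
  between open components is undefined); open chains are closed by
  `close_and_classify()` first.
* Knot identification is an exact polynomial lookup against the
  embedded table (unknot through $6_1$, Hopf links, small unlinks);
  anything else is reported as `unidentified` with the polynomial
  echoed — by design, not failure.
* MSR finds *a* minimal structure, not the global stick minimum: the
  figure-eight fixture reduces to 10 points, above its stick number 7;
  all invariants are nevertheless preserved exactly.
* Computation is exponential in the residual crossing number, as for
  any HOMFLY algorithm; MSR keeps the battery well inside budget but
  pathological dense links will be slow.
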