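---
title: "Orienting coarse-grained membrane proteins in implicit bilayers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Orienting coarse-grained membrane proteins in implicit bilayers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(memorient)
```

## The model

A membrane protein adopts its orientation because the time-averaged
interaction of its surface with lipids and solvent is much more favorable in
one placement than another. `memorient` treats a coarse-grained (CG,
Martini-style) protein as a rigid body and scores placements with a
mean-field potential instead of explicit lipids.

For two CG beads of types $T_A$ and $T_B$ the Lennard-Jones pair potential
$U_{\epsilon,\sigma}(r) = 4\epsilon\left((\sigma/r)^{12} - (\sigma/r)^6\right)$
has minimum $-\epsilon(T_A, T_B)$ at $r = 2^{1/6}\sigma$. Because lipid and
solvent beads are highly mobile on the orientation timescale, the
environment of a surface bead is well approximated by probe beads sitting at
that minimum distance. Each surface bead therefore carries a quasi-uniform
(Fibonacci) shell of $n$ probes at radius $d = 2^{1/6}\bar\sigma$, and each
probe contributes the mean-field value of the zone it falls in: solvent,
head-group, or hydrophobic core, with plateau values
$-\epsilon(T_A, T_\text{zone})$. Probes that fall inside the protein itself
are excluded. Zone transitions are smoothed with a sigmoid
$s(x) = 1/(1+e^{-x})$ of the signed boundary distance divided by a smoothing
width, which removes the zero-gradient plateaus a hard zone assignment would
create and makes the total score differentiable everywhere.

The total potential $P(z, \Theta)$ sums the bead scores after the rigid-body
placement: an insertion depth $z$ along the membrane normal plus a rotation
$\Theta$ encoded by a direction 3-vector $v$ and a spin 2-vector $w$. The
5-vector encoding avoids the coordinate singularities and artificial
minimization barriers of $(\theta, \phi)$ angles. Lateral position does not
enter: the field depends only on the signed distance from the membrane
midplane, so $P$ is invariant under in-plane translation and rotation about
the normal.

Charged beads add a Coulomb term computed against each leaflet's head-group
plane, approximated as a uniformly charged sheet and integrated numerically
over a disc of the cutoff radius below the bead. The default sheet charge is
zero — on average that orients best, because membrane charges are sparse and
mobile — but a slight negative density on the inner leaflet is switched on
during ranking to test the positive-inside rule: with a symmetric neutral
membrane, a placement and its mirror image through the midplane score
identically, and the small inner-leaflet charge breaks the tie toward the
side that puts positive residues inside.

## Minimization, clustering, ranking

$P$ has many local minima and the biologically relevant orientation need not
be the global one, so all well-supported minima are found and reported. The
pipeline:

1. **Grid.** Starting directions are taken from a Fibonacci spiral lattice
   over the upper hemisphere ($\theta \in [0, \pi/2]$); 36 starts by
   default, 72 for peripheral proteins. The initial depth for each direction
   places the hydrophobic band — beads whose smoothed
   water-interaction-weakness score exceeds an automatic cutoff — at the
   membrane center; proteins without a band (peripheral proteins) instead
   use a grid scan of $P$ over $z$.
2. **Minimization.** AdaDelta gradient descent runs from every start, 150
   iterations by default (300 for peripheral presets). The gradient is
   analytic in $(z, v, w)$: the C++ kernel accumulates the field gradient
   and the outer-product matrix $A = \sum_k \nabla M'(y_k)\, u_k^\top$, so
   the rotation components are inner products of $A$ with the (cheaply
   differenced) Jacobian of the $3\times3$ rotation map. Spacing and
   curvature derivatives are analytic through the field.
3. **Reflection test.** Each minimum is compared against its midplane mirror
   under the slight inner-leaflet charge; the rule-obeying side is kept.
4. **Clustering.** Minima are clustered by the iterative rule: a result
   joins the first cluster containing a member within tolerance
   ($\max(|\Delta z|/t_z,\ \Delta\alpha/t_\text{ang}) \le 1$, defaults
   $t_z = 0.3$ nm, $t_\text{ang} = 8^\circ$), else founds a new cluster.
   The angular component compares protein-frame membrane normals
   $R^\top \hat z$, because the potential is invariant under world rotation
   about the normal and a full-rotation metric would split each physical
   orientation into arbitrarily many spin variants.
5. **Ranking.** Representatives (mean depth; mean normal applied to the
   best member's rotation) are sorted by
   $R_i = P(L_i) + \lambda\,(-\log(|C_i|/|G|))$ with $\lambda = 2$ kJ/mol:
   the potential penalized for small basin occupancy, which stands in for
   basin depth. A much deeper minimum still outranks a popular shallow one
   once $\Delta P$ exceeds the penalty scale.

## Double membranes, curvature, the cell wall

For periplasm-spanning or gap-junction proteins the field gains a second
membrane at center-to-center spacing $D$ (midplanes at $\pm D/2$);
$P(z, \Theta, D)$ is minimized with $D$ seeded per start by a coarse grid
search. Global curvature is modeled as a sphere of radius $1/|c|$ tangent to
the planar midplane, with a formulation continuous at $c = 0$; $c$ can be
scanned for the leading orientations or minimized as a free coordinate.
Curved and double-membrane modes are mutually exclusive — curvature is
developed for single membranes. Curvature results should be read as
suggestions: an isolated protein cannot distinguish local deformation from
global curvature, and a planar-optimal protein should (and in tests does)
recover $|c| \le 0.01\ \text{nm}^{-1}$.

The peptidoglycan (PG) layer position along an oriented double-membrane
protein is scored by $P_\text{PG}(z) = C(z) + L(z)$: $L$ sums a
sigmoid-smoothed 2 nm slab field (built like the membrane field but from
the Martini-2-style PG table, representative bead type `Nda`, smoothing
0.1 nm — sharper than the membrane default because the wall is a dense
polymer, and sharp enough that the slab-center plateau is attained) and $C$
collects charged-sheet terms — PG charges are immobile, so unlike the
bilayer case electrostatics matter. The global minimum is the prediction,
but all local minima and the full curve are reported because external
anchors (e.g. Braun's lipoprotein) can select a different minimum; a
supplied position guess adds a strong quadratic bias
(50 kJ/mol/nm$^2$ by default). The convex hull of each 2 nm slab of the
protein gives the cross-sectional area profile — a hull, because the mesh
cannot fill concavities.

## Building the PG mesh

`generate_pg_mesh()` lays glycan strands (NAG–NAM units, 1 nm per unit,
2 nm strand spacing, one or more layers) across a periodic cell; a freshly
generated strand wraps the cell and is effectively infinite. Units colliding
with a protein are carved out. The strand-length distribution is then
matched to a user-defined Gaussian mixture by MCMC with break/join moves,
accepted with probability $\max(0,\ 1 - e^{(K - K_p)/K_t})$ where $K$ is
the Kullback–Leibler divergence of the proposed length histogram from the
target and $K_p$ the last accepted value ($K_t = 0.05$; histograms binned at
one unit with $10^{-6}$ additive smoothing). The formula accepts improving
moves with probability approaching one and rejects worsening ones; with the
target equal to the current distribution nothing is ever accepted. One
consequence required care: cutting a cyclic (infinite) strand once yields a
linear strand of identical histogram length, a zero-$\Delta K$ move the
acceptance rule can never take, so the break move severs a cyclic strand at
two bonds — it breaks it in two, exactly what the closing pass does to any
strand still spanning the cell. Break and join moves never create or
destroy units.

Cross-links form by visiting units in random order: each unit selects the
lattice-aligned unit on the adjacent strand in its randomly assigned
left/right direction (overridden with probability $P_l$ to the adjacent
layer), links with probability $P_\text{cl}$, and — successful or not — the
pair is flagged and never reselected. A third unit may extend an existing
dimer into an oligomer with probability $P_o$; pairs whose peptide stem tips
are farther apart than 2.2 nm are rejected as sterically invalid.

The built mesh is slightly stretched by construction, so a simplified
network (one node per unit; bonds along the backbone and across
cross-links; a straightening term on backbone triplets, since glycan
strands are stiff and without it sparse cross-links merely pull local
bulges instead of contracting the cell) is relaxed by damped spring
dynamics under periodic boundaries. At fixed intervals the net bond strain
along each in-plane axis rescales that cell length (positions rescaling
affinely); termination requires both the mean absolute strain and each
axis's net strain to fall below 0.2%. A mesh built at rest lengths is a
fixed point; a uniformly 10% pre-stretched, fully cross-linked mesh relaxes
to within 2% of the cell at which every bond sits at its rest length.
Units stay outside the protein clearance throughout. `write_pg_topology()`
exports GRO coordinates (four beads per unit: two sugars, two stem beads)
and a GROMACS `.itp` listing bonds, backbone angles, and for every peptide
cross-link the two interpeptide-link angle potentials with equilibrium
angles 114° and 95° and force constants 75 kJ/mol — bundled constants from
a CG-over-atomistic fit; the fitting itself is outside this package's
scope.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `core_half_width` | 1.4 nm | hydrophobic core half-thickness |
| `head_width` | 0.6 nm | head-group zone width |
| `smoothing_width` | 0.25 nm | sigmoid zone smoothing (membrane) |
| `n_probes` | 32 | probes per surface bead |
| `occupancy_radius` | 0.264 nm | interior-probe exclusion radius |
| `n_grid` / `n_iters` | 36 / 150 | starts and AdaDelta iterations (72 / 300 peripheral) |
| `t_z`, `t_ang` | 0.3 nm, 8° | clustering tolerances |
| `lambda` | 2 kJ/mol | rank occupancy penalty |
| `dielectric_scale` | 15 | relative-dielectric divisor for sheet Coulomb |
| `positive_inside_density` | −0.02 e/nm² | inner-leaflet test charge |
| `pg_sheet_density` | −0.3 e/nm² | PG sheet charge |
| `K_t` | 0.05 | MCMC acceptance temperature |
| `P_cl`, `P_l`, `P_o` | 0.5, 0, 0 | cross-link probabilities |

Numerical choices made where the design was genuinely open:

* **Probe shells are attached in the protein frame** and rotate rigidly
  with it. The interior-occupancy test then depends only on the protein's
  own geometry and is computed once, which is what makes
  grid × iterations × probes affordable; plateau values, reflection
  symmetry and lateral invariance are unaffected.
* **A single representative shell radius per bead** ($2^{1/6}$ times the
  mean $\sigma$ of the bead's pairs) rather than per-pair shells, which
  would multiply cost without resolving which pair a probe represents.
* **AdaDelta** uses $\rho = 0.95$, $\varepsilon = 10^{-4}$ and coordinate
  scales (depth 2, rotation 1, spacing 2, curvature 0.05). The larger
  regularizer is deliberate: with $\varepsilon = 10^{-6}$ the step-size
  warm-up is so slow that a 50° initial tilt error is still ~30° after 150
  iterations, while with $10^{-4}$ it converges below 1°. The minimizer
  tracks and returns the best placement seen, so the reported potential
  never exceeds the starting one.
* **Degenerate inputs**: a single-bead protein is its own surface; a
  direction antipodal to the pole uses an explicit 180° rotation; proteins
  without a hydrophobic band fall back to the depth scan with a warning;
  ties in the clustering order are resolved by grid order (first-founder).

## What the synthetic fixtures do and do not show

The fixture generator builds idealized CG bodies with known ground truth:
helical bundles and barrels with a hydrophobic belt at a known depth, rods
with two belts at a known spacing, a bundle with a charged ring, and a
dense cylinder for carving tests. Belt beads are LEU side-chain beads
(apolar), the rest SER backbone beads (polar), ring beads LYS side-chain
beads (+1 e); coordinates get a small seeded jitter. These fixtures emulate
the *geometry* of membrane proteins — a belt the core should capture, known
tilt and depth, two belts for double membranes — but not the chemical
heterogeneity, partial burial, conformational flexibility, or marginal
hydrophobicity of real proteins. Passing the recovery tests therefore
demonstrates that the potential, minimizer and postprocessing do what they
claim on well-posed inputs; it does not bound accuracy on real structures,
which depends on the force-field tables and on how rigid the true protein
is. The bundled interaction tables are themselves synthetic
reconstructions of a Martini-like interaction-level scheme over a reduced
13-type alphabet — adequate for the orientation physics (hydrophobic
ordering, charge classes), but not the published force field; users with
real Martini parameters can supply them as a CSV.

Problem sizes used throughout the tests — fixtures of 100–400 beads, grids
of 12–36 starts, a 40-strand toy wall cell, 20,000 MCMC steps — are the
package's chosen study conditions; they keep each property check
self-contained and fast while exercising every code path.

## Known limitations

* The protein is rigid; flexible linkers between domains straddling two
  membranes are not modeled.
* The membrane does not deform around the protein; only a single global
  curvature is available, and it is a suggestion, not a prediction.
* Electrostatics use charged sheets with a scalar dielectric; no screening
  by ionic strength.
* Atomistic structures must be coarse-grained before use; bead naming must
  be resolvable through the (editable) mapping file, and unknown names are
  an error by design — silently dropping beads would corrupt the potential.
* The PG builder's topology export covers bonds and angles (including the
  two interpeptide terms); dihedrals and full per-bead Martini PG topology
  are out of scope.
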