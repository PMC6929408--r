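---
title: "Long-range shape complementarity docking: model, numerics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Long-range shape complementarity docking: model, numerics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lscdock)
```

# The model

`lscdock` performs exhaustive rigid-body docking of two protein structures.
The receptor is held fixed; the ligand is rotated through a deterministic
orientation sample and, for each orientation, translated over every offset
of a shared cubic lattice. The pose score is a shape-complementarity
correlation between complex-valued grids, evaluated for all translations at
once by FFT. The output is one best-translation prediction per orientation,
ranked by score.

## Lattice discretization and the three layers

A lattice point is *inside* a molecule when its Euclidean distance to some
atom center is at most that atom's van der Waals radius (closed ball).
Inside points are partitioned by face (6-)connectivity:

* **surface**: an inside point with at least one outside face-neighbour;
* **near-surface**: a remaining inside point with a surface face-neighbour;
* **core**: every other inside point.

The surface layer is a one-point-thick spacer between interior and
exterior and is typically *not* atom-occupied in the packing sense; the
near-surface layer and the core are where atoms sit. Off-grid neighbours
count as outside, and the grid is sized so no molecule can reach the
boundary (below), which makes the boundary convention unobservable in
practice.

Face connectivity is a deliberate choice: with 26-connectivity every
inside point of a thin feature has a corner neighbour outside, so the whole
feature becomes "surface" and no near-surface layer survives anywhere thin.
6-connectivity reproduces the intended three-layer onion even for a single
atom (18 surface points around 1 near-surface point at 1.2 Å spacing and a
1.9 Å carbon radius).

## Grid values

With $J^2 = -1$ and $r$ the distance between index triples *in grid units*,

$$R(l,m,n) = \begin{cases}
-\sum_{i,j,k} \exp[-(r-1)^2] + J & \text{surface, } (i,j,k) \in \pm 3 \text{ box}\\
-1 + 2J \sum_{i,j,k} \exp(-r^2) & \text{near-surface, } (i,j,k) \in \pm 1 \text{ box}\\
-1 + 10J & \text{core}\\
0 & \text{outside}
\end{cases}$$

$$L(l,m,n) = \begin{cases}
1 - J & \text{surface}\\
1 - 2J \sum_{i,j,k} \exp(-r^2) & \text{near-surface}\\
1 - 10J & \text{core}\\
0 & \text{outside}
\end{cases}$$

where both sums run over points $(i,j,k)$ of the *same* molecule belonging
to the near-surface layer or the core. The $\pm 3$ box gives the surface
term reach — roughly 3.6 Å at the default spacing — which is what makes
this scoring function long-range compared to nearest-neighbour schemes;
the $\pm 1$ box makes the near-surface weight track local atom density.

Two details of these sums are not forced by their defining description and
are therefore explicit, switchable decisions:

* **Self-inclusion.** A near-surface point belongs to its own $\pm 1$ box
  and satisfies the only stated membership condition, so its $r = 0$ term
  (contributing $\exp(0) = 1$, hence an imaginary part of at least $2$) is
  *included* by default. `receptor_grid(..., include_self = FALSE)`
  switches it off for sensitivity analysis.
* **Box shape.** The $\pm 3$ neighbourhood is the full cubic box
  ($i \in [l-3, l+3]$, etc.), not a sphere of radius 3, matching the
  interval notation it is defined with.

$r$ is measured in index units, not Å: the boxes are defined in index
space and $\exp[-(r-1)^2]$ peaks exactly at the adjacent-point distance
$r = 1$ only in those units.

## The correlation score and its sign

The translational score is

$$E(o,p,q) = \mathrm{Re}\!\left[\sum_{l,m,n} R(l,m,n)\, L(l+o, m+p, n+q)\right]$$

with indices wrapped modulo $N$. Multiplying the layer values pairwise
shows what $E$ rewards *as printed*: every pairing of two nonzero imaginary
parts enters $\mathrm{Re}[RL] = \mathrm{Re}_R\mathrm{Re}_L -
\mathrm{Im}_R\mathrm{Im}_L$ with a positive sign (receptor imaginary parts
are positive, ligand ones negative), so an overlapping core–core pair
contributes $\mathrm{Re}[(-1+10J)(1-10J)] = +99$ — maximizing $E$ drives
the ligand *into* the receptor. The verbal description of the function is
the opposite: the near-surface sum is a *repulsion* weight and the surface
sum a *favourable* term. No single conjugation fixes every pairing;
negating only the ligand imaginary parts, for example, makes every overlap
pairing non-positive, so the global optimum is any non-touching pose and
no docking signal remains.

The convention that reproduces the described physics is to negate the
ligand grid as a whole — equivalently, to rank the printed correlation
*ascending*. Per overlapping pair (writing $s$ for a surface sum and $t$
for a near-surface sum) the effective score $-E$ is then:

| pairing (receptor × ligand) | contribution | reading |
|---|---|---|
| surface × surface | $s - 1$ | contact reward, scaled by protein mass behind the patch |
| surface × near-surface | $s - 2t$ | contact reward minus crowding |
| surface × core | $s - 10$ | reward only where the surface is well backed |
| near-surface × core | $1 - 20t$ | strong repulsion, scaled by the near-surface sum |
| near-surface × near-surface | $1 - 4t_R t_L$ | repulsion |
| core × core | $-101$ | deep clash |

The package ships both conventions (`sign_mode = "as_printed"` /
`"repulsive_core"`) and does not guess beyond an empirical arbiter:
`sanity_audit()` docks the deterministic knob/socket fixture and checks
the single best pose for (a) interface contact — at least one receptor
surface point overlapped by a ligand near-surface/core point — and (b) at
most 2% of ligand core points overlapping receptor core. In this build
`repulsive_core` passes and `as_printed` fails with near-total core
overlap, exactly as the table predicts; `sign_mode = "auto"` runs the
audit once per session, caches the verdict and logs the chosen mode.

## FFT realization

The cross-correlation is computed as
`Re(fft(P * fft(L), inverse = TRUE)) / N³` with
`P = Conj(fft(Conj(R)))` precomputed once per receptor. Because both grids
are complex, the familiar real-input identity
$\widehat{R}(-k) = \overline{\widehat{R}(k)}$ does not hold, and the
pairing above is *verified against the direct sum*, not assumed: the test
suite checks every shift of random complex grids at $N \in \{4, 6, 8\}$
against the $O(N^3)$-per-shift oracle `direct_score()` to a relative
$10^{-6}$ (observed agreement is at machine precision).

## Grid sizing, centering and pose realization

`choose_grid()` picks $N$ so that
$N \cdot a \ge \mathrm{ext}(R) + \mathrm{ext}(L) + 2(2 r_{max} + 2a)$,
with extents measured rotation-invariantly as twice the largest
centroid-to-atom distance, rounded up to an FFT-friendly size (factors 2,
3, 5; capped at 256 per axis). This guarantees that any receptor-plus-
ligand contact configuration fits without circular-wraparound aliasing, so
no wrap-ambiguous translation can ever score as a contact pose and no
post-hoc filtering is needed.

Both molecules are gridded with their centroid at the lattice center; the
ligand is re-rotated about its own centroid and re-gridded for every
orientation. A shift index $(o,p,q)$ of the correlation samples the ligand
displaced by $-(o,p,q)$ grid units, so predictions store the ligand
displacement $d = (-o) \bmod N$ and realize the physical translation as
$\mathrm{unwrap}(d)\cdot a$ with $\mathrm{unwrap}(s) = s$ for
$s \le N/2$, else $s - N$. A realized pose, re-gridded and re-scored,
reproduces its prediction score exactly when the translation is a lattice
vector — the test suite asserts this self-consistency, which pins down the
sign and unwrap conventions jointly.

Ties in the best translation (exact in constant regions, or within a
$10^{-9}$ relative band absorbing FFT round-off) resolve to the
lexicographically smallest shift triple; equal-scoring rotations keep
ascending rotation index. Together with the deterministic rotation sample
this makes whole runs byte-reproducible.

## Rotational sampling

Orientations are built as $K$ quasi-uniform directions × $M$ in-plane
spins, with $K = \mathrm{round}(4\pi/\Delta^2)$ ($\Delta$ in radians) and
$M = \mathrm{round}(360^\circ/\Delta)$. At $\Delta = 15^\circ$:
$K = 183$, $M = 24$, i.e. 4392 orientations; at $30^\circ$: $46 \times 12
= 552$. The $K$ formula is the unique parameter-free cap-counting rule
consistent with 4392 entries at 15°. Directions come from a Fibonacci
spiral pinned so its first point is exactly the $+z$ pole, making the
identity orientation entry 1 and the whole set seed-free and
deterministic. Any other quasi-uniform covering of the same size would be
an equally valid sample; individual poses are therefore not comparable
pose-by-pose across implementations, only statistically. The mean
nearest-neighbour angular separation of the directions stays within 35%
of the nominal interval (property-tested).

Euler triples use the right-handed active z-y-z convention,
$R = R_z(\alpha) R_y(\beta) R_z(\gamma)$, documented so poses are
reproducible from the TSV output alone.

# The synthetic test system

Real benchmark complexes require downloads and hours of compute, so the
package generates its own ground-truth cases. `make_knob_socket()` builds
a receptor as a jittered-lattice atom cloud (2.2 Å spacing, ±0.25 Å
jitter) filling a sphere, with a spherical pocket carved around a socket
point just outside the surface; the ligand fills the pocket ball
(its own lattice, spaced so the ball holds the requested atom count with
~30% slack). A ring of receptor atoms is then placed radially
1.0 × (sum of radii) = 3.8 Å outside the ligand's outermost shell atoms.
The ring makes the interface invariants hold *by construction* — no pair
closer than 0.8 × the radius sum, and at least 10 pairs within 1.2 × —
and every construction re-audits them before returning. Atoms are all
carbon (1.9 Å), grouped three per residue as CA, C, C on chains A/B so
backbone and Cα selectors work. Defaults (300 receptor atoms, 80 ligand
atoms, 6 Å knob, seed 1) give a ~20 Å receptor with a genuinely concave
socket on a 60³ grid.

What the fixture does *not* emulate: real packing density, chemistry,
secondary structure, unbound-state conformational change, or the size of
real proteins (a few hundred pseudo-atoms versus thousands). Passing the
redocking test shows the geometry pipeline and score optimum behave as
designed; it says nothing quantitative about benchmark success rates on
real complexes.

`perturb_pose()` supplies seeded rigid perturbations with exact metric
properties (a pure translation of $d$ Å has ligand-Cα RMSD exactly $d$),
and `mini_benchmark()` writes several cases of varied size with a case
list consumable by the evaluation front end, with category labels (EI,
AA, OT) attached purely as metadata.

# Evaluation conventions

Ligand RMSD superposes the receptors on paired backbone atoms
(least-squares Kabsch via SVD, with the determinant correction against
reflections), applies the transform to the predicted ligand, and takes the
RMSD over paired ligand Cα atoms. Atom pairing is by chain, residue
number and atom name, with repeated names within a residue paired by
occurrence order and unmatched atoms dropped — bound and unbound forms of
benchmark structures frequently disagree in coverage, and backbone-based
superposition keeps the measure defined when side chains differ. The hit
threshold is *strictly* less than 10 Å. Success rate and mean hits are
non-decreasing in the number of top predictions considered by
construction, and the suite property-tests both.

# Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| `spacing` | 1.2 | Å | the method's stated lattice resolution; halving it multiplies work by ~8 |
| `interval` | 15 | degrees | the stated rotational resolution (4392 orientations); coarser values are for tests and audits |
| `sign_mode` | `auto` | — | empirically audited sign convention, see above |
| `include_self` | `TRUE` | — | the $r=0$ term of near-surface sums |
| `grid_cap` | 256 | points/axis | refuses grids that will not fit in memory/time |
| hit threshold | 10 | Å | standard ligand-RMSD hit definition |
| radii table | C 1.9, N 1.7, O 1.6, S 2.0, H 1.2, P 2.1, default 1.8 | Å | documented stand-in set in the conventional docking range; user-substitutable via a two-column text file |

# Problem sizes used by the shipped checks

The test suite and examples run entirely on synthetic fixtures chosen to
exercise every code path at desk scale: oracle comparisons on $4^3$–$8^3$
grids, layer audits on $\sim 15^3$ grids, coarse-interval docking runs
(45°–90°) of 120–150-atom fixtures, and one full-resolution redocking of
the default fixture (15°, 4392 orientations, 60³ grid) which completes in
a few minutes on one CPU. These sizes are the package's chosen test
conditions; the engine itself is limited only by `grid_cap`.

# Known limitations

* Shape only: no electrostatics, desolvation or statistical potentials,
  no flexibility, no post-docking refinement or clustering — exactly one
  retained pose per orientation.
* The `as_printed` convention is kept for transparency but fails its own
  audit; results produced with it should be treated as diagnostic.
* The rotation generator reproduces the *size* and uniformity of the
  reference sample, not its individual members (the original generator is
  unpublished).
* PDB handling is deliberately minimal: first MODEL, highest-occupancy
  altLoc, HETATM opt-in, no structure repair, no mmCIF.
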