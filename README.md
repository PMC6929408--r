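# lscdock

Rigid-body protein–protein docking in R, built around a long-range pairwise
shape-complementarity (LSC) scoring function evaluated by FFT correlation.

## The problem and the method

Given a receptor and a ligand structure, rigid-body docking searches the six
degrees of freedom (three rotations, three translations) for poses whose
surfaces fit. `lscdock` does the classic grid-correlation search:

1. **Discretization.** Each protein is mapped onto a cubic lattice
   (spacing 1.2 Å by default). A point is *inside* the protein when it lies
   within the van der Waals radius of any atom. Inside points are split into
   three layers: the **surface** layer (an outside face-neighbour exists),
   the **near-surface** layer (a surface face-neighbour exists) and the
   **core** (everything else). The surface layer is the spacer between
   interior and exterior; the near-surface layer and core are atom-occupied.

2. **Complex-valued scoring grids.** Each lattice point gets a complex value
   (grid index distance r, J² = −1):

   | layer        | receptor R(l,m,n)                     | ligand L(l,m,n) |
   |--------------|----------------------------------------|-----------------|
   | surface      | −Σ exp[−(r−1)²] + J  (±3 index box)    | 1 − J           |
   | near-surface | −1 + 2J·Σ exp(−r²)   (±1 index box)    | 1 − 2J·Σ exp(−r²) |
   | core         | −1 + 10J                               | 1 − 10J         |
   | outside      | 0                                      | 0               |

   The exponential sums run over near-surface and core points, so the
   surface term grows with the amount of protein behind a surface patch
   (a long-range attraction) and the near-surface term with local atom
   density (a repulsion weight). The ±3 box is what makes the function
   *long-range* relative to nearest-neighbour shape scores.

3. **FFT translational search.** For a translation (o,p,q) the score is
   `E(o,p,q) = Re[Σ R(l,m,n)·L(l+o,m+p,n+q)]` with circular index
   wraparound; all N³ translations are evaluated at once with forward and
   inverse FFTs.

4. **Rotational sampling.** Ligand orientations come from a deterministic
   quasi-uniform Euler-angle sample: `K = round(4π/Δ²)` sphere directions ×
   `round(360°/Δ)` spins. At the default interval Δ = 15° that is
   183 × 24 = **4392 orientations**; the best translation is kept for each,
   giving 4392 ranked predictions per run.

5. **Evaluation.** Predictions are scored against a native complex by the
   ligand RMSD (Lrmsd): superpose the receptors on backbone atoms
   (Kabsch), then take the Cα RMSD of the ligand. A pose with
   Lrmsd < 10 Å is a *hit*; the success rate at K is the percentage of
   cases with ≥ 1 hit among the top K predictions.

Taken literally, the printed grid values reward deep interpenetration (a
core–core overlap scores Re[(−1+10J)(1−10J)] = +99). The package therefore
ships two sign conventions: `as_printed`, and `repulsive_core`, which
negates the ligand grid (equivalently ranks the same correlation ascending)
so that atom–atom overlap is penalized (core–core −101) and surface contact
backed by protein mass is rewarded. `sanity_audit()` docks a deterministic
knob/socket fixture and verifies which convention produces contacting,
clash-free top poses; `sign_mode = "auto"` uses the audited mode. See the
methods vignette (`vignettes/lsc-docking-methods.Rmd`) for the full
arithmetic.

## Worked example

Everything below is synthetic — no downloads. `make_knob_socket()` builds a
deterministic pseudo-protein complex with a known bound pose (a knob-shaped
ligand seated in a carved socket):

```r
library(lscdock)

toy <- make_knob_socket(seed = 1)        # 300 + 80 pseudo-atoms
fit <- lsc_dock(toy$receptor, toy$ligand,
                interval = 30, sign_mode = "repulsive_core")
summary(fit, top = 5)
```

```
Rigid-body docking run (long-range shape complementarity)
<lsc_dock> 552 predictions (interval 30 deg), grid 60^3 @ 1.2 A, mode repulsive_core
top score: 528.2712 (rotation 73, shift 6,0,0)

Top predictions:
 rank rotation_index   alpha    beta gamma  tx   ty   tz  score
    1             73 105.047  42.833     0 7.2  0.0  0.0 528.27
    2            362 165.233 109.471    30 7.2  0.0  0.0 524.34
    3            395  80.248 114.975   300 8.4 -1.2  1.2 516.48
    4            346 250.217 104.149   270 8.4  0.0 -1.2 515.76
    5            439 270.280 126.870   180 7.2  0.0  0.0 511.75
```

Each row is one ligand orientation (z-y-z Euler angles, degrees) with its
best translation (Å, receptor frame) and correlation score. Scoring the
run against the known bound pose:

```r
cr <- evaluate_predictions(fit, toy$receptor, toy$ligand)
round(cr$lrmsd_by_rank[1:5], 2)
#> [1] 6.82 8.15 6.86 7.38 7.74       # all five are hits (< 10 A)
summarize_benchmark(list(cr), k_values = c(1, 10, 100))
#>  category   k n_cases success_rate mean_hits
#>       all   1       1          100         1
#>       all  10       1          100        10
#>       all 100       1          100       100
```

`realize_pose(fit, 1)` (or `predict(fit, rank = 1)`) returns the posed
ligand as a structure you can `write_pdb()`.

A shell front end with `dock`, `eval`, `fixtures` and `audit` commands is
installed at `system.file("scripts", "lscdock", package = "lscdock")`.

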