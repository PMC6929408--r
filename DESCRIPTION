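Package: lscdock
Title: FFT-Based Rigid-Body Protein-Protein Docking with Long-Range
    Shape Complementarity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Rigid-body protein-protein docking by exhaustive
    fast-Fourier-transform translational search over a cubic lattice,
    scored with a long-range pairwise shape-complementarity (LSC)
    function. Proteins are discretized into surface, near-surface and
    core lattice layers; each grid point carries a complex value whose
    neighbour sums weight attraction at the molecular surface and
    repulsion at atom-occupied layers with an exponential distance
    decay. Ligand orientations are sampled on a deterministic
    quasi-uniform Euler-angle lattice (4392 orientations at the default
    15 degree interval) and the best translation per orientation is
    retained. Includes pose realization, ligand-RMSD evaluation against
    a native complex with hit and success-rate summaries, deterministic
    knob-and-socket synthetic complexes for end-to-end testing, and a
    command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    bio3d,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
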