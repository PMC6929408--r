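# in-code fixtures and naive reference implementations used across tests

atoms_structure <- function(xyz, r = 1.9, chain = "A", label = "test") {
  xyz <- matrix(xyz, ncol = 3)
  n <- nrow(xyz)
  resno <- (seq_len(n) - 1L) %/% 3L + 1L
  name <- rep(c("CA", "C", "C"), length.out = n)
  name[!duplicated(resno)] <- "CA"
  dock_structure(data.frame(
    atom_name = name, element = "C", residue_name = "ALA",
    residue_number = resno, chain_id = chain,
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    occupancy = 1, vdw_radius = r, stringsAsFactors = FALSE), label = label)
}

single_atom <- function(x = 0, y = 0, z = 0, r = 1.9) {
  atoms_structure(c(x, y, z), r = r)
}

random_cloud <- function(n, seed, extent = 8, r = 1.9) {
  set.seed(seed)
  atoms_structure(matrix(runif(3 * n, -extent / 2, extent / 2), ncol = 3),
                  r = r)
}

# naive O(atoms * N^3) layer classification: the reference for the kernels
naive_layers <- function(structure, spec) {
  n <- spec$n
  ax <- spec$origin[1] + (seq_len(n) - 1) * spec$spacing
  pos <- as.matrix(expand.grid(x = ax,
                               y = spec$origin[2] + (seq_len(n) - 1) * spec$spacing,
                               z = spec$origin[3] + (seq_len(n) - 1) * spec$spacing))
  xyz <- coords(structure)
  rad <- structure$atoms$vdw_radius
  inside_v <- rep(FALSE, nrow(pos))
  for (a in seq_len(nrow(xyz))) {
    inside_v <- inside_v |
      rowSums(sweep(pos, 2, xyz[a, ])^2) <= rad[a]^2
  }
  inside <- array(inside_v, dim = rep(n, 3))
  at <- function(arr, i, j, k, fill) {
    if (i < 1 || j < 1 || k < 1 || i > n || j > n || k > n) fill
    else arr[i, j, k]
  }
  nb <- function(i, j, k) list(c(i - 1, j, k), c(i + 1, j, k), c(i, j - 1, k),
                               c(i, j + 1, k), c(i, j, k - 1), c(i, j, k + 1))
  lab <- array(0L, dim = rep(n, 3))
  for (k in 1:n) for (j in 1:n) for (i in 1:n) {
    if (!inside[i, j, k]) next
    out_nb <- any(vapply(nb(i, j, k),
                         function(v) !at(inside, v[1], v[2], v[3], FALSE),
                         logical(1)))
    lab[i, j, k] <- if (out_nb) 1L else 3L
  }
  for (k in 1:n) for (j in 1:n) for (i in 1:n) {
    if (lab[i, j, k] != 3L) next
    surf_nb <- any(vapply(nb(i, j, k),
                          function(v) at(lab, v[1], v[2], v[3], 0L) == 1L,
                          logical(1)))
    if (surf_nb) lab[i, j, k] <- -2L
  }
  lab[lab == -2L] <- 2L
  lab
}

# naive exponential neighbour sum at points of target_label
naive_sums <- function(lab, target_label, box, shift, include_self = TRUE) {
  n <- dim(lab)[1]
  out <- array(0, dim = dim(lab))
  for (k in 1:n) for (j in 1:n) for (i in 1:n) {
    if (lab[i, j, k] != target_label) next
    s <- 0
    for (dk in -box:box) for (dj in -box:box) for (di in -box:box) {
      if (!include_self && di == 0 && dj == 0 && dk == 0) next
      ii <- i + di; jj <- j + dj; kk <- k + dk
      if (ii < 1 || jj < 1 || kk < 1 || ii > n || jj > n || kk > n) next
      if (lab[ii, jj, kk] %in% c(2L, 3L)) {
        r <- sqrt(di^2 + dj^2 + dk^2)
        s <- s + exp(-(r - shift)^2)
      }
    }
    out[i, j, k] <- s
  }
  out
}

random_complex_grid <- function(n, seed, side = "receptor") {
  set.seed(seed)
  v <- array(complex(real = rnorm(n^3), imaginary = rnorm(n^3)),
             dim = rep(n, 3))
  structure(list(spec = grid_spec(max(n, 4), 1.0), values = v, side = side),
            class = "complex_grid")
}

delta_grid <- function(n, at, value, side = "receptor") {
  v <- array(0 + 0i, dim = rep(n, 3))
  v[at[1], at[2], at[3]] <- value
  structure(list(spec = grid_spec(max(n, 4), 1.0), values = v, side = side),
            class = "complex_grid")
}

write_test_pdb <- function(lines, path = tempfile(fileext = ".pdb")) {
  writeLines(lines, path)
  path
}

pdb_atom_line <- function(serial, name, resname, chain, resno, x, y, z,
                          occ = 1, elem = "C", record = "ATOM  ",
                          altloc = " ") {
  name4 <- if (nchar(name) < 4L) sprintf(" %-3s", name) else
    sprintf("%-4s", name)
  sprintf("%s%5d %s%s%-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, serial, name4, altloc, resname, chain, resno,
          x, y, z, occ, 0, elem)
}
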