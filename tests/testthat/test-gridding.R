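test_that("grid size follows the margin rule and FFT-friendly rounding", {
  # extents 30 and 20 A, spacing 1.2, max radius 2.0:
  # need 30 + 20 + 2*(2*2.0 + 2*1.2) = 64.8 A -> n >= 54 = 2 * 27
  rec <- atoms_structure(rbind(c(-15, 0, 0), c(15, 0, 0)), r = 2.0)
  lig <- atoms_structure(rbind(c(-10, 0, 0), c(10, 0, 0)), r = 2.0)
  spec <- choose_grid(rec, lig, spacing = 1.2)
  expect_equal(spec$n, 54L)
  # two single atoms: tiny but never below the floor of 4
  tiny <- choose_grid(single_atom(r = 0.5), single_atom(r = 0.5),
                      spacing = 10)
  expect_gte(tiny$n, 4L)
  expect_error(choose_grid(rec, lig, spacing = 1.2, cap = 16L), "cap")
  expect_error(choose_grid(rec, atoms_structure(c(0, 0, 0), r = NA)),
               "radii")
})

test_that("an isolated on-node atom produces the 19-point onion", {
  # radius 1.9, spacing 1.2: inside offsets |o|^2 in {0,1,2} -> 1+6+12 = 19
  spec <- grid_spec(9, 1.2)
  s <- single_atom(x = spec$center[1], y = spec$center[2], z = spec$center[3])
  lay <- classify_layers(s, spec)
  counts <- table(factor(lay$labels, levels = 0:3))
  expect_equal(as.integer(counts[["1"]]), 18L)  # surface
  expect_equal(as.integer(counts[["2"]]), 1L)   # near-surface center
  expect_equal(as.integer(counts[["3"]]), 0L)   # no core
  c5 <- (spec$n + 1) / 2
  expect_equal(lay$labels[c5, c5, c5], 2L)

  rg <- receptor_grid(lay)
  lg <- ligand_grid(lay)
  # center: only itself qualifies in the +/-1 box -> T = exp(0) = 1
  expect_equal(rg$values[c5, c5, c5], -1 + 2i)
  expect_equal(lg$values[c5, c5, c5], 1 - 2i)
  # face surface point: single term at index distance r = 1
  expect_equal(rg$values[c5 + 1, c5, c5], -1 + 1i)
  expect_equal(lg$values[c5 + 1, c5, c5], 1 - 1i)
  # edge surface point at r = sqrt(2)
  expect_equal(rg$values[c5 + 1, c5 + 1, c5],
               complex(real = -exp(-(sqrt(2) - 1)^2), imaginary = 1))
  # disabling the self term drops the center sum to zero
  rg0 <- receptor_grid(lay, include_self = FALSE)
  expect_equal(rg0$values[c5, c5, c5], -1 + 0i)
})

test_that("a solid ball develops a core valued -1+10i / 1-10i exactly", {
  g <- expand.grid(x = seq(-6, 6, 2), y = seq(-6, 6, 2), z = seq(-6, 6, 2))
  ball <- as.matrix(g[rowSums(g^2) <= 36, ])
  s <- atoms_structure(ball)
  spec <- grid_spec(18, 1.2)
  lay <- classify_layers(center_structure(s, spec), spec)
  expect_gt(sum(lay$labels == 3L), 0L)
  rg <- receptor_grid(lay)
  lg <- ligand_grid(lay)
  expect_true(all(rg$values[lay$labels == 3L] == -1 + 10i))
  expect_true(all(lg$values[lay$labels == 3L] == 1 - 10i))
  # every core point's face neighbours are core or near-surface
  idx <- which(lay$labels == 3L, arr.ind = TRUE)
  for (r in seq_len(nrow(idx))) {
    i <- idx[r, ]
    for (d in list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                   c(0, 0, 1), c(0, 0, -1))) {
      expect_true(lay$labels[i[1] + d[1], i[2] + d[2], i[3] + d[3]] %in%
                    c(2L, 3L))
    }
  }
})

test_that("layer labels match the naive reference on random clouds", {
  for (seed in 1:3) {
    s <- random_cloud(12, seed, extent = 7)
    spec <- grid_spec(14, 1.2)
    s <- center_structure(s, spec)
    lay <- classify_layers(s, spec)
    expect_identical(lay$labels, naive_layers(s, spec))
  }
})

test_that("layer labels partition the grid and satisfy adjacency rules", {
  for (seed in 4:6) {
    s <- center_structure(random_cloud(15, seed, extent = 8), spec <- grid_spec(15, 1.2))
    lab <- classify_layers(s, spec)$labels
    n <- spec$n
    expect_true(all(lab %in% 0:3))
    at <- function(i, j, k) {
      if (i < 1 || j < 1 || k < 1 || i > n || j > n || k > n) 0L
      else lab[i, j, k]
    }
    nbs <- function(i, j, k) c(at(i - 1, j, k), at(i + 1, j, k),
                               at(i, j - 1, k), at(i, j + 1, k),
                               at(i, j, k - 1), at(i, j, k + 1))
    idx <- which(lab != 0L, arr.ind = TRUE)
    for (r in seq_len(nrow(idx))) {
      i <- idx[r, 1]; j <- idx[r, 2]; k <- idx[r, 3]
      nb <- nbs(i, j, k)
      if (lab[i, j, k] == 1L) {
        expect_true(any(nb == 0L))            # surface touches outside
      } else if (lab[i, j, k] == 2L) {
        expect_true(any(nb == 1L))            # near-surface touches surface
        expect_false(any(nb == 0L))           # but never outside
      } else {
        expect_false(any(nb %in% c(0L, 1L)))  # core is buried
      }
    }
  }
})

test_that("compiled neighbour sums equal the naive triple loop", {
  for (seed in 7:8) {
    s <- center_structure(random_cloud(20, seed, extent = 9),
                          spec <- grid_spec(16, 1.2))
    lay <- classify_layers(s, spec)
    lab <- lay$labels
    rg <- receptor_grid(lay)
    surf <- lab == 1L
    ns <- lab == 2L
    expect_equal(Re(rg$values)[surf], -naive_sums(lab, 1L, 3, 1)[surf],
                 tolerance = 1e-12)
    expect_equal(Im(rg$values)[ns], 2 * naive_sums(lab, 2L, 1, 0)[ns],
                 tolerance = 1e-12)
    rg0 <- receptor_grid(lay, include_self = FALSE)
    expect_equal(Im(rg0$values)[ns],
                 2 * naive_sums(lab, 2L, 1, 0, include_self = FALSE)[ns],
                 tolerance = 1e-12)
  }
})

test_that("grid value ranges and the outside-zero invariant hold", {
  s <- center_structure(random_cloud(25, 9, extent = 8),
                        spec <- grid_spec(16, 1.2))
  lay <- classify_layers(s, spec)
  lab <- lay$labels
  rg <- receptor_grid(lay)
  lg <- ligand_grid(lay)
  expect_true(all(rg$values[lab == 0L] == 0))
  expect_true(all(lg$values[lab == 0L] == 0))
  expect_true(all(Re(rg$values)[lab != 0L] <= 0))
  expect_true(all(Im(rg$values)[lab == 1L] == 1))
  expect_true(all(Im(rg$values)[lab == 2L] >= 2))     # self term counts 2
  expect_true(all(Re(lg$values) %in% c(0, 1)))
  im <- Im(lg$values)[lab != 0L]
  expect_true(all(im <= -1 & im >= -10))
})

test_that("adding an atom never turns inside points outside", {
  spec <- grid_spec(14, 1.2)
  s1 <- center_structure(random_cloud(10, 11, extent = 6), spec)
  lab1 <- classify_layers(s1, spec)$labels
  s2 <- s1
  s2$atoms <- rbind(s2$atoms, s2$atoms[1, ])
  s2$atoms$x[nrow(s2$atoms)] <- s2$atoms$x[1] + 2
  lab2 <- classify_layers(s2, spec)$labels
  expect_true(all(lab2[lab1 != 0L] != 0L))
})

test_that("atoms outside the lattice are reported by name", {
  spec <- grid_spec(6, 1.0)
  expect_error(classify_layers(single_atom(x = 99), spec), "outside the grid")
})
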