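#' @useDynLib lscdock, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

# integer label codes shared with src/kernels.cpp
LAYER_OUTSIDE <- 0L
LAYER_SURFACE <- 1L
LAYER_NEAR_SURFACE <- 2L
LAYER_CORE <- 3L

layer_codes <- c(outside = LAYER_OUTSIDE, surface = LAYER_SURFACE,
                 near_surface = LAYER_NEAR_SURFACE, core = LAYER_CORE)

#' Cubic lattice geometry
#'
#' Describes the shared N x N x N lattice both proteins are discretized on:
#' `spacing` in Angstrom, `n` points per axis, and the physical position
#' `origin` of index (1,1,1). The lattice `center`, where molecule centroids
#' are placed before gridding, is `origin + (n-1)/2 * spacing`.
#'
#' @param n points per axis (>= 4).
#' @param spacing lattice spacing in Angstrom (> 0; 1.2 is the method's
#'   default).
#' @param center physical position of the lattice center (default origin-less,
#'   c(0,0,0)).
#' @return An object of class `grid_spec`.
#' @export
grid_spec <- function(n, spacing = 1.2, center = c(0, 0, 0)) {
  stopifnot(spacing > 0, n >= 4, length(center) == 3)
  n <- as.integer(n)
  origin <- center - (n - 1) / 2 * spacing
  structure(list(n = n, spacing = spacing, origin = origin, center = center),
            class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %d^3 points, spacing %.3g A, extent %.1f A\n",
              x$n, x$spacing, (x$n - 1) * x$spacing))
  invisible(x)
}

# smallest integer >= n whose prime factors are all in {2, 3, 5}
next_fft_size <- function(n) {
  n <- as.integer(ceiling(n))
  if (n < 1L) return(1L)
  repeat {
    m <- n
    for (p in c(2L, 3L, 5L)) while (m %% p == 0L) m <- m %/% p
    if (m == 1L) return(n)
    n <- n + 1L
  }
}

# rotation-invariant extent: twice the largest centroid-to-atom distance
struct_extent <- function(structure) {
  xyz <- coords(structure)
  cen <- colMeans(xyz)
  2 * sqrt(max(rowSums(sweep(xyz, 2, cen)^2)))
}

#' Choose the docking lattice for a receptor/ligand pair
#'
#' The box must hold the receptor plus the ligand in any orientation at any
#' contact translation without circular-wraparound aliasing, so
#' `n * spacing >= extent(receptor) + extent(ligand) + 2 * margin` with
#' `margin = 2 * max(vdw radius) + 2 * spacing`. Extents are
#' rotation-invariant (twice the largest centroid-to-atom distance). `n` is
#' rounded up to an FFT-friendly size (products of 2, 3 and 5).
#'
#' @param receptor,ligand [dock_structure()]s with radii assigned.
#' @param spacing lattice spacing in Angstrom (default 1.2).
#' @param cap maximum permitted n (default 256); larger grids raise an error.
#' @return A [grid_spec()] centered at the origin.
#' @export
choose_grid <- function(receptor, ligand, spacing = 1.2, cap = 256L) {
  stopifnot(n_atoms(receptor) > 0L, n_atoms(ligand) > 0L)
  if (anyNA(receptor$atoms$vdw_radius) || anyNA(ligand$atoms$vdw_radius)) {
    stop("assign radii before gridding")
  }
  max_r <- max(receptor$atoms$vdw_radius, ligand$atoms$vdw_radius)
  margin <- 2 * max_r + 2 * spacing
  need <- struct_extent(receptor) + struct_extent(ligand) + 2 * margin
  n <- next_fft_size(max(4, ceiling(need / spacing)))
  if (n > cap) {
    stop(sprintf("required grid %d^3 exceeds the cap %d^3; increase spacing",
                 n, cap))
  }
  grid_spec(n, spacing)
}

#' Classify lattice points into outside/surface/near-surface/core
#'
#' A point is inside the protein when it lies within (closed ball) the van
#' der Waals radius of any atom. Inside points with an outside face-neighbour
#' form the surface layer; remaining inside points adjacent to the surface
#' layer form the near-surface layer; everything else inside is core.
#' Off-grid neighbours count as outside. Coordinates are used as-is: center
#' the structure on `spec$center` first (see [center_structure()]).
#'
#' @param structure a [dock_structure()] with radii assigned.
#' @param spec a [grid_spec()].
#' @return An object of class `layer_grid`: list(spec, labels) where labels
#'   is an integer n^3 array with codes 0=outside, 1=surface, 2=near-surface,
#'   3=core.
#' @export
classify_layers <- function(structure, spec) {
  if (anyNA(structure$atoms$vdw_radius)) stop("assign radii before gridding")
  xyz <- coords(structure)
  hi <- spec$origin + (spec$n - 1) * spec$spacing
  bad <- which(xyz[, 1] < spec$origin[1] | xyz[, 1] > hi[1] |
               xyz[, 2] < spec$origin[2] | xyz[, 2] > hi[2] |
               xyz[, 3] < spec$origin[3] | xyz[, 3] > hi[3])
  if (length(bad) > 0L) {
    stop(sprintf("atom %d (%s %s%d) lies outside the grid", bad[1],
                 structure$atoms$atom_name[bad[1]],
                 structure$atoms$chain_id[bad[1]],
                 structure$atoms$residue_number[bad[1]]))
  }
  inside <- cpp_mark_inside(xyz, structure$atoms$vdw_radius,
                            spec$origin, spec$spacing, spec$n)
  lab <- cpp_classify_layers(inside, spec$n)
  structure(list(spec = spec,
                 labels = array(lab, dim = rep(spec$n, 3))),
            class = "layer_grid")
}

#' @export
print.layer_grid <- function(x, ...) {
  tab <- table(factor(x$labels, levels = layer_codes, names(layer_codes)))
  cat("<layer_grid> ", x$spec$n, "^3: ",
      paste(names(tab), as.integer(tab), sep = "=", collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Translate a structure so its centroid sits at the grid center
#' @param structure a [dock_structure()].
#' @param spec a [grid_spec()].
#' @return The translated structure.
#' @export
center_structure <- function(structure, spec) {
  set_coords(structure, sweep(coords(structure), 2,
                              centroid(structure) - spec$center))
}

# neighbour-sum fields of the scoring function, in index units:
#   surface:      sum over near-surface/core in the +/-3 box of exp(-(r-1)^2)
#   near-surface: sum over near-surface/core in the +/-1 box of exp(-r^2),
#                 the point itself included by default (r = 0 term)
lsc_sums <- function(layers, include_self = TRUE) {
  lab <- as.integer(layers$labels)
  n <- layers$spec$n
  list(
    surface = array(cpp_layer_sums(lab, n, LAYER_SURFACE, 3L, 1.0, TRUE),
                    dim = rep(n, 3)),
    near    = array(cpp_layer_sums(lab, n, LAYER_NEAR_SURFACE, 1L, 0.0,
                                   include_self),
                    dim = rep(n, 3)))
}

#' Complex-valued receptor scoring grid
#'
#' Assigns every lattice point of the fixed (receptor) protein its complex
#' LSC value: surface points get `-S + 1i` where S is the exponential sum
#' `sum exp(-(r-1)^2)` over near-surface/core points within the +/-3 index
#' box; near-surface points get `-1 + 2i * T` with
#' `T = sum exp(-r^2)` over the +/-1 box (self term included by default);
#' core points get `-1 + 10i`; outside is 0.
#'
#' @param layers a `layer_grid` from [classify_layers()].
#' @param include_self include the r = 0 self term in the near-surface sum
#'   (default TRUE).
#' @return An object of class `complex_grid`: list(spec, values, side).
#' @export
receptor_grid <- function(layers, include_self = TRUE) {
  s <- lsc_sums(layers, include_self)
  lab <- layers$labels
  v <- array(0 + 0i, dim = dim(lab))
  v[lab == LAYER_SURFACE] <- complex(real = -s$surface[lab == LAYER_SURFACE],
                                     imaginary = 1)
  ns <- lab == LAYER_NEAR_SURFACE
  v[ns] <- complex(real = -1, imaginary = 2 * s$near[ns])
  v[lab == LAYER_CORE] <- -1 + 10i
  structure(list(spec = layers$spec, values = v, side = "receptor"),
            class = "complex_grid")
}

#' Complex-valued ligand scoring grid
#'
#' The moving (ligand) protein's counterpart of [receptor_grid()]: surface
#' points are `1 - 1i` (no neighbour sum), near-surface points
#' `1 - 2i * T` with the same +/-1 box sum, core points `1 - 10i`,
#' outside 0.
#'
#' @inheritParams receptor_grid
#' @return An object of class `complex_grid`.
#' @export
ligand_grid <- function(layers, include_self = TRUE) {
  s <- lsc_sums(layers, include_self)
  lab <- layers$labels
  v <- array(0 + 0i, dim = dim(lab))
  v[lab == LAYER_SURFACE] <- 1 - 1i
  ns <- lab == LAYER_NEAR_SURFACE
  v[ns] <- complex(real = 1, imaginary = -2 * s$near[ns])
  v[lab == LAYER_CORE] <- 1 - 10i
  structure(list(spec = layers$spec, values = v, side = "ligand"),
            class = "complex_grid")
}

#' @export
print.complex_grid <- function(x, ...) {
  cat(sprintf("<complex_grid> %s side, %d^3, %d nonzero points\n",
              x$side, x$spec$n, sum(x$values != 0)))
  invisible(x)
}

#' Dump a small grid as a text table
#'
#' Debug helper: one row per nonzero point with its index triple, layer label
#' (for a `layer_grid`) or real/imaginary value (for a `complex_grid`).
#'
#' @param grid a `layer_grid` or `complex_grid`.
#' @param path output TSV path.
#' @return Invisibly, `path`.
#' @export
dump_grid <- function(grid, path) {
  n <- grid$spec$n
  idx <- which(if (inherits(grid, "layer_grid")) grid$labels != 0
               else grid$values != 0, arr.ind = TRUE)
  df <- data.frame(i = idx[, 1], j = idx[, 2], k = idx[, 3])
  if (inherits(grid, "layer_grid")) {
    df$label <- names(layer_codes)[match(grid$labels[idx], layer_codes)]
  } else {
    df$real <- Re(grid$values[idx])
    df$imag <- Im(grid$values[idx])
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
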