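#' Deterministic quasi-uniform rotational sample
#'
#' Orientation space is covered by K quasi-uniform view directions combined
#' with M in-plane spin angles. K is set by the angular interval `delta` (in
#' degrees) as `K = round(4 * pi / delta_rad^2)` — the number of spherical
#' caps of angular radius ~delta tiling the sphere — and `M = round(360 /
#' delta)`. Directions come from a deterministic Fibonacci spiral whose
#' first point is the exact +z pole, so the identity orientation (first
#' direction, spin 0) is always entry 1. Each (direction, spin) pair is
#' expressed as a z-y-z Euler triple (alpha, beta, gamma) in degrees:
#' `alpha = atan2(dy, dx)`, `beta = acos(dz)`, `gamma = spin`. At the
#' method's default 15 degree interval this yields K = 183, M = 24, i.e.
#' 4392 orientations.
#'
#' @param interval angular interval in degrees, in (0, 90].
#' @return An object of class `rotation_set`: data frame with columns
#'   `alpha`, `beta`, `gamma` (degrees) plus attributes `interval`.
#' @export
generate_rotation_set <- function(interval = 15) {
  if (!is.numeric(interval) || length(interval) != 1 ||
      interval <= 0 || interval > 90) {
    stop("interval must be a single angle in (0, 90] degrees")
  }
  delta <- interval * pi / 180
  K <- round(4 * pi / delta^2)
  M <- round(360 / interval)
  dirs <- fibonacci_sphere(K)
  alpha <- (atan2(dirs[, 2], dirs[, 1]) * 180 / pi) %% 360
  beta <- acos(pmin(1, pmax(-1, dirs[, 3]))) * 180 / pi
  gamma <- (seq_len(M) - 1) * interval
  entries <- data.frame(
    alpha = rep(alpha, each = M),
    beta  = rep(beta, each = M),
    gamma = rep(gamma, times = K))
  structure(entries, interval = interval, K = K, M = M,
            class = c("rotation_set", "data.frame"))
}

# K deterministic quasi-uniform unit vectors: Fibonacci spiral including
# both poles (z linear from 1 to -1, golden-angle azimuth, first azimuth 0)
fibonacci_sphere <- function(K) {
  i <- seq_len(K) - 1
  z <- if (K == 1) 1 else 1 - 2 * i / (K - 1)
  golden <- pi * (3 - sqrt(5))
  phi <- i * golden
  s <- sqrt(pmax(0, 1 - z^2))
  cbind(cos(phi) * s, sin(phi) * s, z)
}

#' @export
print.rotation_set <- function(x, ...) {
  cat(sprintf(
    "<rotation_set> %d orientations (interval %g deg: %d directions x %d spins)\n",
    nrow(x), attr(x, "interval"), attr(x, "K"), attr(x, "M")))
  invisible(x)
}

#' Rotation matrix from z-y-z Euler angles
#'
#' Right-handed active rotation `Rz(alpha) %*% Ry(beta) %*% Rz(gamma)`.
#'
#' @param alpha,beta,gamma angles in degrees; alternatively `alpha` may be a
#'   length-3 vector (alpha, beta, gamma).
#' @return Orthonormal 3 x 3 matrix with determinant +1.
#' @export
rotation_matrix <- function(alpha, beta = NULL, gamma = NULL) {
  if (is.null(beta)) { beta <- alpha[2]; gamma <- alpha[3]; alpha <- alpha[1] }
  rz <- function(t) {
    t <- t * pi / 180
    matrix(c(cos(t), sin(t), 0, -sin(t), cos(t), 0, 0, 0, 1), 3, 3)
  }
  ry <- function(t) {
    t <- t * pi / 180
    matrix(c(cos(t), 0, -sin(t), 0, 1, 0, sin(t), 0, cos(t)), 3, 3)
  }
  rz(alpha) %*% ry(beta) %*% rz(gamma)
}

#' Rigidly rotate a structure about a pivot
#'
#' Every atom position p maps to `matrix %*% (p - pivot) + pivot`.
#'
#' @param structure a [dock_structure()].
#' @param matrix orthonormal 3 x 3 rotation matrix.
#' @param pivot rotation pivot (default: the structure centroid).
#' @return The rotated structure.
#' @export
apply_rotation <- function(structure, matrix, pivot = centroid(structure)) {
  if (max(abs(crossprod(matrix) - diag(3))) > 1e-8) {
    stop("rotation matrix is not orthonormal")
  }
  xyz <- coords(structure)
  set_coords(structure,
             sweep(sweep(xyz, 2, pivot) %*% t(matrix), 2, pivot, `+`))
}

#' Export a rotation set as TSV
#' @param rotations a `rotation_set`.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_rotation_set <- function(rotations, path) {
  df <- data.frame(index = seq_len(nrow(rotations)),
                   alpha = rotations$alpha, beta = rotations$beta,
                   gamma = rotations$gamma)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
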