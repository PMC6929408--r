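# run code under a seeded RNG without disturbing the caller's RNG state
#
# Fixture geometry notes: the receptor is a jittered-lattice ball with a
# spherical pocket carved around a socket point just outside its surface;
# the ligand fills the pocket ball. A ring of receptor atoms is then placed
# radially 1.0 x (sum of radii) outside the ligand's outermost shell atoms,
# which guarantees the bound-pose interface invariants (no pair closer than
# 0.8 x sum of radii, at least 10 pairs within 1.2 x) by construction
# rather than by lattice luck.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(code)
}

#' Deterministic knob-and-socket pseudo-protein complex
#'
#' Builds a synthetic rigid-body docking case with a known ground-truth
#' bound pose and a genuinely complementary interface: the receptor is a
#' jittered-lattice atom cloud filling a sphere with a spherical socket
#' carved out near one pole, the ligand a matching knob-shaped cloud sitting
#' in the socket. All pseudo-atoms are carbon with the shipped table radius;
#' atoms are grouped three per residue (names CA, C, C) on chain A
#' (receptor) and chain B (ligand) so backbone and C-alpha selectors work.
#' The construction is a pure function of its arguments: the same seed gives
#' byte-identical PDB output.
#'
#' The returned pair is *in the bound pose* (`true_pose` is the identity).
#' By construction every receptor-ligand atom pair is separated by at least
#' the carve clearance (no clash: minimum distance >= 0.8 x sum of radii)
#' and at least 10 pairs sit within 1.2 x the sum of radii (a real
#' interface); both properties are audited before returning.
#'
#' @param seed integer RNG seed.
#' @param n_receptor number of receptor atoms (>= 50).
#' @param n_ligand number of ligand atoms (>= 20).
#' @param knob_radius knob/socket radius in Angstrom.
#' @return An object of class `toy_complex`: list(receptor, ligand,
#'   true_pose, seed, socket_center).
#' @export
make_knob_socket <- function(seed = 1L, n_receptor = 300L, n_ligand = 80L,
                             knob_radius = 6) {
  if (n_receptor < 50L) stop("n_receptor must be at least 50")
  if (n_ligand < 20L) stop("n_ligand must be at least 20")
  if (knob_radius <= 0) stop("knob_radius must be positive")
  a <- 2.2              # pseudo-atom lattice spacing, Angstrom
  jitter <- 0.25
  clearance <- 3.1      # min receptor-ligand atom gap carved into the socket
  atom_r <- 1.9         # carbon radius of the shipped table
  contact_gap <- 3.8    # registered contact-pair distance (= sum of radii)
  shell_depth <- 0.7    # ligand outer shell feeding the contact ring

  with_seed(seed, {
    g <- seq(-16, 16, by = a)
    pts <- as.matrix(expand.grid(x = g, y = g, z = g))
    pts <- pts + matrix(stats::runif(length(pts), -jitter, jitter),
                        ncol = 3)

    # initial receptor radius from the target atom count, then grow until
    # the carved sphere still holds n_receptor points
    r_rec <- (3 * n_receptor * a^3 / (4 * pi))^(1 / 3)
    repeat {
      if (knob_radius >= 0.75 * r_rec) {
        stop("knob_radius too large for this receptor size")
      }
      socket <- c(r_rec + 0.2 * knob_radius, 0, 0)
      d_socket <- sqrt(rowSums(sweep(pts, 2, socket)^2))
      rec_keep <- sqrt(rowSums(pts^2)) <= r_rec & d_socket >= knob_radius +
        clearance
      if (sum(rec_keep) >= n_receptor) break
      r_rec <- r_rec + 0.3
      if (r_rec > 15.5) stop("cannot fit n_receptor atoms; reduce knob_radius")
    }
    # the ligand gets its own candidate lattice, spaced so the knob ball
    # comfortably holds n_ligand atoms (floored at 1.6 A: pseudo-atoms are
    # never packed tighter than a bond length)
    a_lig <- max(1.6, min(a, (4 / 3 * pi * knob_radius^3 /
                                (1.3 * n_ligand))^(1 / 3)))
    gl <- seq(-(knob_radius + 1), knob_radius + 1, by = a_lig)
    lpts <- as.matrix(expand.grid(x = gl, y = gl, z = gl))
    lpts <- sweep(lpts + matrix(stats::runif(length(lpts), -jitter, jitter),
                                ncol = 3), 2, socket, `+`)
    lig_d_all <- sqrt(rowSums(sweep(lpts, 2, socket)^2))
    lig_keep <- lig_d_all <= knob_radius
    if (sum(lig_keep) < n_ligand) {
      stop("knob_radius too small to hold n_ligand atoms")
    }
    lig_xyz <- lpts[lig_keep, , drop = FALSE]
    lig_d <- lig_d_all[lig_keep]
    sel <- order(lig_d)[seq_len(n_ligand)]
    lig_xyz <- lig_xyz[sel, , drop = FALSE]
    lig_d <- lig_d[sel]

    # contact ring: receptor atoms placed radially contact_gap outside the
    # outermost ligand atoms. Candidates closer than 0.8 x (sum of radii)
    # to any non-partner ligand atom are discarded, so the no-clash
    # invariant holds by construction.
    shell <- order(-lig_d)[seq_len(min(14L, n_ligand))]
    ring_xyz <- t(vapply(shell, function(i) {
      u <- (lig_xyz[i, ] - socket) / lig_d[i]
      socket + u * (lig_d[i] + contact_gap)
    }, numeric(3)))
    ring_min <- apply(ring_xyz, 1, function(p) {
      sqrt(min(rowSums(sweep(lig_xyz, 2, p)^2)))
    })
    ring_xyz <- ring_xyz[ring_min >= 0.8 * 2 * atom_r + 0.01, , drop = FALSE]
    if (nrow(ring_xyz) < 10L) {
      stop("knob_radius too small to form the contact interface")
    }

    n_fill <- n_receptor - nrow(ring_xyz)
    rec_cloud <- pts[rec_keep, , drop = FALSE]
    rec_cloud <- rec_cloud[order(d_socket[rec_keep])[seq_len(n_fill)], ,
                           drop = FALSE]
    rec_xyz <- rbind(ring_xyz, rec_cloud)

    receptor <- pseudo_structure(rec_xyz, chain = "A", atom_r,
                                 label = "knob_socket_receptor")
    ligand <- pseudo_structure(lig_xyz, chain = "B", atom_r,
                               label = "knob_socket_ligand")

    # construction audit of the bound-pose interface invariants
    dmin <- min_cross_dist(rec_xyz, lig_xyz)
    n_contact <- n_contact_pairs(rec_xyz, lig_xyz, 1.2 * 2 * atom_r)
    if (dmin < 0.8 * 2 * atom_r) {
      stop(sprintf("fixture audit failed: clash (min pair distance %.2f A)",
                   dmin))
    }
    if (n_contact < 10L) {
      stop(sprintf("fixture audit failed: only %d interface pairs", n_contact))
    }
    structure(list(receptor = receptor, ligand = ligand,
                   true_pose = list(rotation = diag(3),
                                    translation = c(0, 0, 0)),
                   seed = seed, socket_center = socket),
              class = "toy_complex")
  })
}

pseudo_structure <- function(xyz, chain, atom_r, label) {
  n <- nrow(xyz)
  resno <- (seq_len(n) - 1L) %/% 3L + 1L
  name <- rep(c("CA", "C", "C"), length.out = n)
  name[!duplicated(resno)] <- "CA"
  dock_structure(data.frame(
    atom_name = name, element = "C", residue_name = "ALA",
    residue_number = resno, chain_id = chain,
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    occupancy = 1, vdw_radius = atom_r,
    stringsAsFactors = FALSE), label = label)
}

min_cross_dist <- function(a, b) {
  sqrt(min(outer(rowSums(a^2), rowSums(b^2), `+`) - 2 * a %*% t(b)))
}

n_contact_pairs <- function(a, b, cutoff) {
  d2 <- outer(rowSums(a^2), rowSums(b^2), `+`) - 2 * a %*% t(b)
  sum(d2 <= cutoff^2)
}

#' @export
print.toy_complex <- function(x, ...) {
  cat(sprintf("<toy_complex> seed %d: receptor %d atoms, ligand %d atoms\n",
              x$seed, n_atoms(x$receptor), n_atoms(x$ligand)))
  invisible(x)
}

#' Randomly perturb the bound ligand pose
#'
#' Rotates the ligand about its centroid by a seeded random axis through the
#' given angle, then translates it along a seeded random direction by the
#' given displacement. With `angle = 0` the ligand C-alpha RMSD to the bound
#' pose is exactly `displacement`.
#'
#' @param complex a `toy_complex`.
#' @param angle rotation magnitude in degrees.
#' @param displacement translation magnitude in Angstrom.
#' @param seed integer RNG seed.
#' @return The perturbed ligand [dock_structure()].
#' @export
perturb_pose <- function(complex, angle = 0, displacement = 0, seed = 1L) {
  with_seed(seed, {
    axis <- random_unit()
    dir <- random_unit()
    lig <- complex$ligand
    if (angle != 0) {
      lig <- apply_rotation(lig, axis_angle_matrix(axis, angle))
    }
    set_coords(lig, sweep(coords(lig), 2, dir * displacement, `+`))
  })
}

random_unit <- function() {
  v <- stats::rnorm(3)
  v / sqrt(sum(v^2))
}

# Rodrigues rotation about a unit axis by an angle in degrees
axis_angle_matrix <- function(axis, angle) {
  t <- angle * pi / 180
  k <- matrix(c(0, axis[3], -axis[2], -axis[3], 0, axis[1],
                axis[2], -axis[1], 0), 3, 3)
  diag(3) + sin(t) * k + (1 - cos(t)) * (k %*% k)
}

#' Write a small synthetic benchmark of knob/socket cases
#'
#' Generates `n_cases` knob/socket complexes of varied sizes, writes each as
#' receptor/ligand/native PDB triples plus a case-list TSV (columns case_id,
#' category, receptor_pdb, ligand_pdb, native_pdb; paths relative to the
#' TSV) consumable by [cmd_eval()]. Categories cycle EI, AA, OT as labels
#' only. Fully deterministic per seed.
#'
#' @param n_cases number of cases (>= 1).
#' @param seed integer seed; case i uses `seed * 1000 + i`.
#' @param out_dir output directory (created if needed).
#' @return Invisibly, the case-list data frame; the TSV is at
#'   `file.path(out_dir, "cases.tsv")`.
#' @export
mini_benchmark <- function(n_cases, seed = 1L, out_dir) {
  if (n_cases < 1L) stop("n_cases must be at least 1")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("cannot create output directory ", out_dir)
  cats <- c("EI", "AA", "OT")
  rows <- lapply(seq_len(n_cases), function(i) {
    v <- (i - 1L) %% 3L
    toy <- make_knob_socket(seed = seed * 1000L + i,
                            n_receptor = 220L + 40L * v,
                            n_ligand = 45L + 12L * v,
                            knob_radius = 5.5 + 0.25 * v)
    id <- sprintf("case%02d", i)
    rec <- sprintf("%s_receptor.pdb", id)
    lig <- sprintf("%s_ligand.pdb", id)
    nat <- sprintf("%s_native.pdb", id)
    write_pdb(toy$receptor, file.path(out_dir, rec))
    write_pdb(toy$ligand, file.path(out_dir, lig))
    write_pdb(combine_structures(toy$receptor, toy$ligand),
              file.path(out_dir, nat))
    data.frame(case_id = id, category = cats[v + 1L], receptor_pdb = rec,
               ligand_pdb = lig, native_pdb = nat, stringsAsFactors = FALSE)
  })
  cases <- do.call(rbind, rows)
  utils::write.table(cases, file.path(out_dir, "cases.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(cases)
}

#' Concatenate two structures into one
#' @param a,b [dock_structure()]s.
#' @return A [dock_structure()] with the atoms of `a` then `b`.
#' @export
combine_structures <- function(a, b) {
  dock_structure(rbind(a$atoms, b$atoms), label = paste0(a$label, "+", b$label))
}
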