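#' Atomic structures for docking
#'
#' A `dock_structure` is an ordered table of atoms — the rigid body that the
#' docking engine discretizes onto a lattice. It is a thin S3 wrapper around a
#' data frame with one row per atom and columns `atom_name`, `element`,
#' `residue_name`, `residue_number`, `chain_id`, `x`, `y`, `z`, `occupancy`
#' and `vdw_radius` (NA until [assign_radii()] has run). Multiple chains in
#' one file are treated as a single rigid body.
#'
#' @param atoms data frame with the columns listed above (`occupancy` and
#'   `vdw_radius` optional).
#' @param label short text label carried through to output files.
#' @return An object of class `dock_structure`.
#' @seealso [read_pdb()], [assign_radii()], [select_atoms()]
#' @export
dock_structure <- function(atoms, label = "structure") {
  needed <- c("atom_name", "element", "residue_name", "residue_number",
              "chain_id", "x", "y", "z")
  missing_cols <- setdiff(needed, names(atoms))
  if (length(missing_cols) > 0L) {
    stop("atom table lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (is.null(atoms$occupancy)) atoms$occupancy <- 1
  if (is.null(atoms$vdw_radius)) atoms$vdw_radius <- NA_real_
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  rownames(atoms) <- NULL
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  if (nrow(atoms) > 0L && !all(is.finite(xyz))) {
    stop("non-finite atom coordinates")
  }
  structure(list(atoms = atoms, label = label), class = "dock_structure")
}

#' @export
print.dock_structure <- function(x, ...) {
  cat(sprintf("<dock_structure '%s'>: %d atoms, %d residues, chains: %s\n",
              x$label, n_atoms(x),
              length(unique(paste(x$atoms$chain_id, x$atoms$residue_number))),
              paste(unique(x$atoms$chain_id), collapse = ",")))
  invisible(x)
}

#' Number of atoms in a structure
#' @param structure a [dock_structure()].
#' @return Integer atom count.
#' @export
n_atoms <- function(structure) nrow(structure$atoms)

#' Atom coordinates as a matrix
#' @param structure a [dock_structure()].
#' @return Numeric n-by-3 matrix of coordinates in Angstrom.
#' @export
coords <- function(structure) {
  unname(as.matrix(structure$atoms[, c("x", "y", "z")]))
}

#' Replace atom coordinates
#' @param structure a [dock_structure()].
#' @param xyz numeric n-by-3 matrix.
#' @return The structure with new coordinates.
#' @export
set_coords <- function(structure, xyz) {
  stopifnot(nrow(xyz) == n_atoms(structure), ncol(xyz) == 3)
  structure$atoms$x <- xyz[, 1]
  structure$atoms$y <- xyz[, 2]
  structure$atoms$z <- xyz[, 3]
  structure
}

#' Centroid of a structure
#' @param structure a [dock_structure()].
#' @return Length-3 numeric vector, the unweighted mean atom position.
#' @export
centroid <- function(structure) colMeans(coords(structure))

backbone_names <- c("N", "CA", "C", "O")

#' Read a protein structure from a PDB file
#'
#' Parses ATOM records (bio3d does the format work). Only the first MODEL of
#' a multi-model file is kept. Alternate locations are resolved by highest
#' occupancy, ties broken in favour of altLoc 'A' (then alphabetically).
#' HETATM records (ligands, waters) are excluded unless `include_hetatm`.
#'
#' @param path path to a PDB file.
#' @param include_hetatm keep HETATM records as well (default FALSE).
#' @param label optional structure label; defaults to the file name.
#' @return A [dock_structure()].
#' @export
read_pdb <- function(path, include_hetatm = FALSE, label = NULL) {
  if (!file.exists(path)) stop("cannot read PDB file: ", path)
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE,
                                     verbose = FALSE)),
    error = function(e) stop("unreadable PDB file '", path, "': ",
                             conditionMessage(e)))
  at <- pdb$atom
  if (!include_hetatm) at <- at[at$type == "ATOM", , drop = FALSE]
  at <- resolve_altloc(at)
  if (nrow(at) == 0L) stop("no atoms left after filtering in ", path)
  elem <- at$elesy
  # fall back to the leading letter of the atom name when the element
  # column is blank (common in minimal files)
  blank <- is.na(elem) | elem == ""
  if (any(blank)) elem[blank] <- sub("^[0-9]*([A-Za-z]).*$", "\\1",
                                     trimws(at$elety[blank]))
  dock_structure(data.frame(
    atom_name      = trimws(at$elety),
    element        = toupper(trimws(elem)),
    residue_name   = trimws(at$resid),
    residue_number = as.integer(at$resno),
    chain_id       = ifelse(is.na(at$chain) | at$chain == "", "A", at$chain),
    x = at$x, y = at$y, z = at$z,
    occupancy = ifelse(is.na(at$o), 1, at$o),
    stringsAsFactors = FALSE
  ), label = if (is.null(label)) basename(path) else label)
}

# keep, per (chain, residue, atom name), the alternate location with the
# highest occupancy; ties prefer 'A' then alphabetical order
resolve_altloc <- function(at) {
  alt <- at$alt
  if (is.null(alt)) return(at)
  alt[is.na(alt)] <- ""
  if (all(alt == "")) return(at)
  key <- paste(at$chain, at$resno, trimws(at$elety), sep = "|")
  occ <- ifelse(is.na(at$o), 0, at$o)
  pref <- ifelse(alt == "" | alt == "A", 0L, 1L)
  ord <- order(key, -occ, pref, alt)
  keep_first <- !duplicated(key[ord])
  keep <- sort(ord[keep_first])
  at[keep, , drop = FALSE]
}

#' Write a structure as PDB ATOM records
#'
#' Coordinates are written with the standard fixed-width \%8.3f fields; values
#' that do not fit the field (|x| >= 10000) raise an error before anything is
#' written, so no truncated file is left behind.
#'
#' @param structure a non-empty [dock_structure()].
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
write_pdb <- function(structure, path) {
  if (n_atoms(structure) == 0L) stop("refusing to write an empty structure")
  xyz <- coords(structure)
  if (any(abs(xyz) >= 9999.9995)) {
    stop("coordinate exceeds the PDB fixed-width field; nothing written")
  }
  a <- structure$atoms
  name4 <- vapply(a$atom_name, function(nm) {
    # standard PDB alignment: 1-3 char names start in column 14
    if (nchar(nm) < 4L) sprintf(" %-3s", nm) else sprintf("%-4s", nm)
  }, character(1))
  lines <- sprintf(
    "ATOM  %5d %s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    seq_len(nrow(a)) %% 100000L, name4, a$residue_name,
    substr(a$chain_id, 1, 1), a$residue_number %% 10000L,
    a$x, a$y, a$z, a$occupancy, 0, a$element)
  con <- file(path, "wb")  # binary mode: one byte-stable newline convention
  on.exit(close(con))
  writeLines(c(lines, "END"), con, sep = "\n")
  invisible(path)
}

#' Select a subset of atoms
#'
#' @param structure a [dock_structure()].
#' @param selector `"backbone"` (N, CA, C, O), `"calpha"`, or `"chain"`.
#' @param chain chain identifier, required for `selector = "chain"`.
#' @return A [dock_structure()] with the subset in the original order. An
#'   empty selection is returned (not an error) with a warning so callers can
#'   decide severity.
#' @export
select_atoms <- function(structure, selector = c("backbone", "calpha", "chain"),
                         chain = NULL) {
  selector <- match.arg(selector)
  a <- structure$atoms
  keep <- switch(selector,
    backbone = a$atom_name %in% backbone_names,
    calpha   = a$atom_name == "CA",
    chain    = {
      if (is.null(chain)) stop("chain selector requires a chain id")
      a$chain_id == chain
    })
  if (!any(keep)) warning("empty selection (", selector, ")")
  out <- structure
  out$atoms <- a[keep, , drop = FALSE]
  rownames(out$atoms) <- NULL
  out
}

#' Read a van der Waals radii table
#'
#' Plain-text two-column format: element symbol and radius in Angstrom,
#' whitespace separated, `#` comments allowed. An entry for element
#' `DEFAULT` supplies the fallback radius for unknown elements. The table
#' shipped with the package (`system.file("extdata", "vdw_radii.txt",
#' package = "lscdock")`) is a documented stand-in set; substitute your own
#' file to change the discretization.
#'
#' @param path path to the table; default is the shipped table.
#' @return Named numeric vector of radii with a `"DEFAULT"` entry.
#' @export
read_radii_table <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "vdw_radii.txt", package = "lscdock")
  }
  tab <- utils::read.table(path, comment.char = "#",
                           col.names = c("element", "radius"),
                           stringsAsFactors = FALSE)
  r <- stats::setNames(tab$radius, toupper(tab$element))
  if (!"DEFAULT" %in% names(r)) r["DEFAULT"] <- 1.8
  if (any(r <= 0)) stop("radii must be positive")
  r
}

#' Assign van der Waals radii to every atom
#'
#' Total: every atom leaves with a positive radius. Unknown elements get the
#' table's default with one warning listing them. Re-assignment with another
#' table simply overwrites.
#'
#' @param structure a [dock_structure()].
#' @param table named radii vector from [read_radii_table()] (default: the
#'   shipped table).
#' @return The structure with `vdw_radius` filled in.
#' @export
assign_radii <- function(structure, table = read_radii_table()) {
  el <- toupper(structure$atoms$element)
  r <- unname(table[el])
  unknown <- is.na(r)
  if (any(unknown)) {
    warning("unknown element(s) ", paste(unique(el[unknown]), collapse = ", "),
            "; using default radius ", table[["DEFAULT"]])
    r[unknown] <- table[["DEFAULT"]]
  }
  structure$atoms$vdw_radius <- r
  structure
}
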