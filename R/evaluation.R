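#' Least-squares rigid superposition (Kabsch)
#'
#' Finds the proper rotation R and translation t minimizing the RMSD of
#' `R %*% p + t` over paired atoms (rows of `mobile` correspond to rows of
#' `reference`).
#'
#' @param mobile,reference [dock_structure()]s with equal atom counts in
#'   corresponding order, or n-by-3 coordinate matrices.
#' @return list(rotation = 3x3 proper rotation, translation = length-3,
#'   rmsd = residual RMSD in Angstrom), of class `superposition`.
#' @export
kabsch_superpose <- function(mobile, reference) {
  p <- if (inherits(mobile, "dock_structure")) coords(mobile) else mobile
  q <- if (inherits(reference, "dock_structure")) coords(reference) else
    reference
  if (nrow(p) != nrow(q)) stop("atom counts differ; cannot pair")
  if (nrow(p) < 3L) stop("need at least 3 atoms to superpose")
  cp <- colMeans(p); cq <- colMeans(q)
  pc <- sweep(p, 2, cp); qc <- sweep(q, 2, cq)
  if (any(svd(pc)$d[2:3] < 1e-9 * (1 + svd(pc)$d[1]))) {
    stop("degenerate (collinear) atom set")
  }
  s <- svd(crossprod(pc, qc))       # H = P^T Q = U D V^T
  d <- sign(det(s$v %*% t(s$u)))
  rot <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  trans <- cq - as.numeric(rot %*% cp)
  resid <- qc - pc %*% t(rot)
  structure(list(rotation = rot, translation = trans,
                 rmsd = sqrt(mean(rowSums(resid^2)))),
            class = "superposition")
}

#' @export
print.superposition <- function(x, ...) {
  cat(sprintf("<superposition> rmsd %.4f A\n", x$rmsd))
  invisible(x)
}

rmsd_xyz <- function(a, b) sqrt(mean(rowSums((a - b)^2)))

# match atoms of a onto b by (chain, residue number, atom name); repeated
# names within a residue pair by occurrence order; returns index pairs
# ordered by b; unmatched atoms are dropped with a count note
pair_atoms <- function(a, b, quiet = TRUE) {
  key <- function(s) {
    k <- paste(s$atoms$chain_id, s$atoms$residue_number,
               s$atoms$atom_name, sep = "|")
    paste(k, stats::ave(seq_along(k), k, FUN = seq_along), sep = "#")
  }
  ka <- key(a); kb <- key(b)
  common <- intersect(kb, ka)
  if (length(common) == 0L) stop("no common atoms to pair")
  ib <- which(kb %in% common)
  ia <- match(kb[ib], ka)
  dropped <- (length(ka) - length(common)) + (length(kb) - length(common))
  if (!quiet && dropped > 0L) {
    message(dropped, " unmatched atoms dropped from the pairing")
  }
  list(a = ia, b = ib)
}

#' Ligand RMSD of a predicted complex against the native complex
#'
#' The predicted receptor is superposed onto the native receptor on paired
#' backbone atoms (Kabsch least squares); the resulting rigid transform is
#' applied to the predicted ligand, and the RMSD over paired ligand C-alpha
#' atoms is returned. Pairing is by chain, residue number and atom name;
#' unmatched atoms are dropped.
#'
#' @param pred_receptor,pred_ligand the predicted complex.
#' @param native_receptor,native_ligand the native complex.
#' @return The ligand RMSD in Angstrom.
#' @export
ligand_rmsd <- function(pred_receptor, pred_ligand,
                        native_receptor, native_ligand) {
  prb <- select_atoms(pred_receptor, "backbone")
  nrb <- select_atoms(native_receptor, "backbone")
  pr <- pair_atoms(prb, nrb)
  sup <- kabsch_superpose(coords(prb)[pr$a, , drop = FALSE],
                          coords(nrb)[pr$b, , drop = FALSE])
  plc <- select_atoms(pred_ligand, "calpha")
  nlc <- select_atoms(native_ligand, "calpha")
  pl <- pair_atoms(plc, nlc)
  if (length(pl$b) == 0L) stop("no common ligand C-alpha atoms")
  moved <- sweep(coords(plc)[pl$a, , drop = FALSE] %*% t(sup$rotation), 2,
                 sup$translation, `+`)
  rmsd_xyz(moved, coords(nlc)[pl$b, , drop = FALSE])
}

#' Hit criterion
#'
#' A predicted pose is a hit when its ligand RMSD is strictly below the
#' threshold (default 10 Angstrom).
#'
#' @param lrmsd ligand RMSD value(s) in Angstrom.
#' @param threshold hit threshold in Angstrom (default 10).
#' @return Logical vector.
#' @export
is_hit <- function(lrmsd, threshold = 10) {
  stopifnot(all(lrmsd >= 0))
  lrmsd < threshold
}

#' Per-case evaluation result
#'
#' @param case_id case identifier.
#' @param lrmsd_by_rank numeric vector of ligand RMSDs in rank order.
#' @param category complex category label (`"EI"`, `"AA"`, `"OT"` or
#'   `"unlabeled"`); metadata only.
#' @return An object of class `case_result`.
#' @export
case_result <- function(case_id, lrmsd_by_rank, category = "unlabeled") {
  stopifnot(all(lrmsd_by_rank >= 0))
  structure(list(case_id = case_id, category = category,
                 lrmsd_by_rank = lrmsd_by_rank), class = "case_result")
}

#' Evaluate every prediction of a docking run against the native complex
#'
#' Computes the ligand RMSD of each ranked prediction. The receptor
#' superposition onto the native receptor is computed once and reused.
#'
#' @param fit an [lsc_dock()] object.
#' @param native_receptor,native_ligand the native complex.
#' @param case_id,category metadata for the result.
#' @return A [case_result()] with one ligand RMSD per rank.
#' @export
evaluate_predictions <- function(fit, native_receptor, native_ligand,
                                 case_id = "case", category = "unlabeled") {
  prb <- select_atoms(fit$receptor, "backbone")
  nrb <- select_atoms(native_receptor, "backbone")
  pr <- pair_atoms(prb, nrb)
  sup <- kabsch_superpose(coords(prb)[pr$a, , drop = FALSE],
                          coords(nrb)[pr$b, , drop = FALSE])
  plc <- select_atoms(fit$ligand, "calpha")
  nlc <- select_atoms(native_ligand, "calpha")
  pl <- pair_atoms(plc, nlc)
  nat_ca <- coords(nlc)[pl$b, , drop = FALSE]
  ca0 <- sweep(coords(plc)[pl$a, , drop = FALSE], 2, centroid(fit$ligand))
  cen_r <- centroid(fit$receptor)
  d <- fit$predictions
  lr <- vapply(seq_len(nrow(d)), function(i) {
    rm3 <- rotation_matrix(d$alpha[i], d$beta[i], d$gamma[i])
    ca <- sweep(ca0 %*% t(rm3), 2, cen_r + c(d$tx[i], d$ty[i], d$tz[i]), `+`)
    rmsd_xyz(sweep(ca %*% t(sup$rotation), 2, sup$translation, `+`), nat_ca)
  }, numeric(1))
  case_result(case_id, lr, category)
}

#' Success rate and mean hits over a set of cases
#'
#' For each requested K: the success rate is the percentage of cases with at
#' least one hit among their top K predictions; mean hits is the average
#' number of hits among the top K. A per-category breakdown is added when
#' categories are present.
#'
#' @param results list of [case_result()]s.
#' @param k_values integer vector of K values (each >= 1).
#' @param threshold hit threshold in Angstrom.
#' @return Data frame with columns category, k, n_cases, success_rate
#'   (percent), mean_hits.
#' @export
summarize_benchmark <- function(results, k_values = c(1, 10, 100, 1000),
                                threshold = 10) {
  if (length(results) == 0L) stop("no case results to summarize")
  if (any(k_values < 1)) stop("k values must be >= 1")
  cats <- vapply(results, function(r) r$category, character(1))
  groups <- c(list(all = results),
              if (length(unique(cats)) > 1L)
                split(results, cats))
  rows <- lapply(names(groups), function(g) {
    rs <- groups[[g]]
    do.call(rbind, lapply(sort(k_values), function(k) {
      hits_k <- vapply(rs, function(r) {
        sum(is_hit(utils::head(r$lrmsd_by_rank, k), threshold))
      }, numeric(1))
      data.frame(category = g, k = k, n_cases = length(rs),
                 success_rate = 100 * mean(hits_k >= 1),
                 mean_hits = mean(hits_k))
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
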