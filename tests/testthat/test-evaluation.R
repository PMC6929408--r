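test_that("Kabsch superposition recovers exact and noisy transforms", {
  s <- random_cloud(40, seed = 5)
  sup0 <- kabsch_superpose(s, s)
  expect_equal(sup0$rotation, diag(3), tolerance = 1e-9)
  expect_equal(sup0$rmsd, 0, tolerance = 1e-9)

  m <- rotation_matrix(25, 60, 110)
  shift <- c(3, -2, 7)
  moved <- set_coords(s, sweep(coords(s) %*% t(m), 2, shift, `+`))
  sup <- kabsch_superpose(moved, s)
  expect_equal(sup$rotation %*% m, diag(3), tolerance = 1e-6)
  expect_equal(sup$rmsd, 0, tolerance = 1e-6)

  set.seed(99)
  noisy <- set_coords(s, coords(s) + matrix(rnorm(120, sd = 0.1), ncol = 3))
  supn <- kabsch_superpose(noisy, s)
  expect_gt(supn$rmsd, 0.05)
  expect_lt(supn$rmsd, 0.2)
  # the optimal residual never exceeds the unsuperposed rmsd
  expect_lte(supn$rmsd, sqrt(mean(rowSums((coords(noisy) - coords(s))^2))))

  expect_error(kabsch_superpose(s, random_cloud(10, 1)), "counts differ")
  line <- atoms_structure(cbind(1:5, 0, 0))
  expect_error(kabsch_superpose(line, line), "degenerate")
})

test_that("Kabsch agrees with the bio3d reference fit", {
  s <- random_cloud(30, seed = 6)
  m <- rotation_matrix(40, 20, 310)
  moved <- set_coords(s, sweep(coords(s) %*% t(m), 2, c(1, 2, 3), `+`))
  sup <- kabsch_superpose(moved, s)
  ref <- bio3d::fit.xyz(fixed = as.numeric(t(coords(s))),
                        mobile = as.numeric(t(coords(moved))),
                        fixed.inds = 1:90, mobile.inds = 1:90)
  expect_equal(sup$rmsd,
               sqrt(mean(rowSums((matrix(ref, ncol = 3, byrow = TRUE) -
                                    coords(s))^2))),
               tolerance = 1e-6)
})

test_that("ligand RMSD identities: zero at native, norm for pure shifts", {
  toy <- make_knob_socket(seed = 11, n_receptor = 90L, n_ligand = 24L,
                          knob_radius = 4.5)
  rec <- toy$receptor; lig <- toy$ligand
  expect_equal(ligand_rmsd(rec, lig, rec, lig), 0, tolerance = 1e-9)
  shifted <- set_coords(lig, sweep(coords(lig), 2, c(6, 8, 0), `+`))
  expect_equal(ligand_rmsd(rec, shifted, rec, lig), 10, tolerance = 1e-9)
  # matches a from-scratch formula under a random rigid perturbation
  pert <- perturb_pose(toy, angle = 25, displacement = 4, seed = 2)
  got <- ligand_rmsd(rec, pert, rec, lig)
  pca <- coords(select_atoms(pert, "calpha"))
  nca <- coords(select_atoms(lig, "calpha"))
  expect_equal(got, sqrt(mean(rowSums((pca - nca)^2))), tolerance = 1e-9)
})

test_that("ligand RMSD is invariant under common rigid motion of the pose", {
  toy <- make_knob_socket(seed = 12, n_receptor = 90L, n_ligand = 24L,
                          knob_radius = 4.5)
  pert <- perturb_pose(toy, angle = 15, displacement = 5, seed = 3)
  base <- ligand_rmsd(toy$receptor, pert, toy$receptor, toy$ligand)
  m <- rotation_matrix(77, 31, 245)
  shift <- c(-4, 9, 2)
  move <- function(s) set_coords(s, sweep(coords(s) %*% t(m), 2, shift, `+`))
  expect_equal(ligand_rmsd(move(toy$receptor), move(pert),
                           toy$receptor, toy$ligand),
               base, tolerance = 1e-6)
})

test_that("the hit boundary is strict at the threshold", {
  expect_true(is_hit(9.999))
  expect_false(is_hit(10.0))
  expect_true(is_hit(0))
  expect_false(is_hit(10 + 1e-12))
  expect_true(is_hit(4.9, threshold = 5))
  expect_error(is_hit(-1))
})

test_that("success rate and mean hits count exactly and monotonically", {
  mk <- function(id, first_hits, len = 2000) {
    lr <- rep(50, len)
    lr[first_hits] <- 1
    case_result(id, lr)
  }
  results <- list(mk("a", 3), mk("b", 50), mk("c", integer(0)), mk("d", 1200))
  s10 <- summarize_benchmark(results, k_values = 10)
  expect_equal(s10$success_rate, 25)
  s2000 <- summarize_benchmark(results, k_values = 2000)
  expect_equal(s2000$success_rate, 75)
  one <- list(mk("e", c(1, 2, 5)))
  expect_equal(summarize_benchmark(one, k_values = 5)$mean_hits, 3)
  # monotone in K, saturating at the fraction of cases with any hit
  ks <- c(1, 5, 10, 100, 1200, 2000)
  s <- summarize_benchmark(results, k_values = ks)
  expect_true(all(diff(s$success_rate) >= 0))
  expect_true(all(diff(s$mean_hits) >= 0))
  expect_equal(s$success_rate[length(ks)], 75)
  expect_error(summarize_benchmark(results, k_values = 0), "k value")
  expect_error(summarize_benchmark(list()), "no case")
})

test_that("category labels split the summary into per-class rows", {
  mk <- function(id, cat, hit) {
    case_result(id, if (hit) c(1, rep(50, 9)) else rep(50, 10), category = cat)
  }
  results <- list(mk("a", "EI", TRUE), mk("b", "EI", TRUE),
                  mk("c", "AA", FALSE))
  s <- summarize_benchmark(results, k_values = 10)
  expect_setequal(s$category, c("all", "EI", "AA"))
  expect_equal(s$success_rate[s$category == "EI"], 100)
  expect_equal(s$success_rate[s$category == "AA"], 0)
  expect_equal(s$success_rate[s$category == "all"], 100 * 2 / 3)
})

test_that("evaluate_predictions scores every rank of a docking run", {
  toy <- make_knob_socket(seed = 13, n_receptor = 120L, n_ligand = 24L,
                          knob_radius = 4.5)
  fit <- lsc_dock(toy$receptor, toy$ligand, interval = 60,
                  sign_mode = "repulsive_core")
  cr <- evaluate_predictions(fit, toy$receptor, toy$ligand, case_id = "t")
  expect_equal(length(cr$lrmsd_by_rank), nrow(fit$predictions))
  expect_true(all(cr$lrmsd_by_rank >= 0))
  # spot-check rank 1 against the full-structure path
  expect_equal(cr$lrmsd_by_rank[1],
               ligand_rmsd(fit$receptor, realize_pose(fit, 1),
                           toy$receptor, toy$ligand),
               tolerance = 1e-9)
})
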