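test_that("superposition collapses rigidly shuffled copies of one structure", {
  topo <- make_topology(12)
  ens <- ensemble_subset(topo, members = rep(1, 5))
  ens <- rigid_shuffle(ens, seed = 20)
  sup <- superpose(ens)
  for (m in 2:5)
    expect_lt(sqrt(mean((member_coords(sup, m) - member_coords(sup, 1))^2)),
              1e-6)
})

test_that("two-member superposition matches the pairwise fit oracle", {
  spec <- generator_spec(n_residues = 10, n_members = 2, seed = 21)
  ens <- generate_ensemble(spec)
  sup <- superpose(ens, selection = "all")
  # brute-force two-structure fit: the pairwise fitted RMSD must equal the
  # RMSD between the two superposed members
  direct <- ensdyn:::rmsd_fit(member_coords(ens, 1), member_coords(ens, 2))
  after <- sqrt(mean(rowSums((member_coords(sup, 1) - member_coords(sup, 2))^2)))
  expect_equal(after, direct, tolerance = 1e-6)
})

test_that("superposition never reflects: mirror images keep RMSD > 0", {
  topo <- make_topology(12)
  mirror <- member_coords(topo, 1)
  mirror[, 1] <- -mirror[, 1]
  ens <- ens_from_coords(topo$atoms, list(member_coords(topo, 1), mirror))
  sup <- superpose(ens, selection = "all")
  expect_gt(sqrt(mean(rowSums((member_coords(sup, 1) -
                                member_coords(sup, 2))^2))), 0.5)
})

test_that("ensemble RMSD follows the sub-ensemble convention", {
  topo <- make_topology(10)
  base <- member_coords(topo, 1)
  shifted <- base
  sel <- atom_select(topo, "backbone")
  # move every backbone atom by the same amount along x after fitting has
  # no effect; use a structured distortion instead
  set.seed(22)
  shifted <- base + matrix(rnorm(length(base), sd = 0.5), ncol = 3)
  ens <- ens_from_coords(topo$atoms, list(base, shifted))
  r <- ensemble_rmsd(ens)
  expect_equal(unname(r["sd"]), 0)
  expect_equal(unname(r["mean"]),
               ensdyn:::rmsd_fit(base[sel, ], shifted[sel, ]),
               tolerance = 1e-10)
  # identical members give 0 +/- 0
  same <- ens_from_coords(topo$atoms, list(base, base))
  expect_equal(unname(ensemble_rmsd(same)), c(0, 0), tolerance = 1e-12)
  expect_error(ensemble_rmsd(ensemble_subset(ens, members = 1)), ">= 2")
  # replica structure: mean and sd across sub-ensembles
  four <- ens_from_coords(topo$atoms, list(base, shifted, base, base),
                          sub_ids = c("a", "a", "b", "b"))
  r4 <- ensemble_rmsd(four)
  expect_equal(unname(r4["mean"]), unname(r["mean"]) / 2, tolerance = 1e-10)
  expect_equal(unname(r4["sd"]), stats::sd(c(unname(r["mean"]), 0)),
               tolerance = 1e-10)
})

test_that("PCA recovers planted variance structure", {
  # single planted mode: first eigenvalue carries almost all variance
  spec1 <- generator_spec(n_residues = 15, n_members = 100,
                          mode_sds = c(2), noise_sd = 0.01, seed = 23)
  dec1 <- pca_modes(generate_ensemble(spec1))
  expect_gte(dec1$eigenvalues[1] / sum(dec1$eigenvalues), 0.99)
  # two planted modes, variance ratio 4:1 at n = 500
  spec2 <- generator_spec(n_members = 500, mode_sds = c(2, 1),
                          noise_sd = 0.1, seed = 24)
  dec2 <- pca_modes(generate_ensemble(spec2))
  expect_equal(dec2$eigenvalues[1] / dec2$eigenvalues[2], 4, tolerance = 0.1)
})

test_that("mode decompositions satisfy their algebraic identities", {
  spec <- generator_spec(n_residues = 12, n_members = 30, seed = 25)
  dec <- pca_modes(generate_ensemble(spec))
  k <- ncol(dec$modes)
  # orthonormality
  expect_lt(max(abs(crossprod(dec$modes) - diag(k))), 1e-8)
  # eigenvalues non-negative, non-increasing, summing to total variance
  expect_true(all(diff(dec$eigenvalues) <= 1e-10))
  expect_true(all(dec$eigenvalues >= -1e-10))
  X <- dec$ensemble$xyz
  total_var <- sum(apply(X, 2, stats::var))
  expect_equal(sum(dec$eigenvalues), total_var, tolerance = 1e-6 * total_var)
  # projections: zero mean, variance = eigenvalue
  expect_lt(max(abs(colMeans(dec$projections))), 1e-8)
  pv <- apply(dec$projections, 2, stats::var)
  expect_equal(pv[1:2], dec$eigenvalues[1:2],
               tolerance = 1e-6 * dec$eigenvalues[1])
  # reconstruction from all modes reproduces superposed coordinates
  mu <- colMeans(X)
  rec <- sweep(dec$projections %*% t(dec$modes), 2, mu, `+`)
  expect_lt(max(abs(rec - X)), 1e-6)
})

test_that("two displaced clusters separate along PC1 with bimodal projections", {
  spec <- generator_spec(n_members = 150, mode_sds = c(0.5, 1),
                         state_displacement = 6, seed = 26)
  st <- generate_state_ensembles(spec)
  dec <- pca_modes(st$apo, st$holo)
  lab <- dec$member_labels
  p1 <- dec$projections[, 1]
  # planted displacement recovered within 5%
  gap <- abs(mean(p1[lab == "holo"]) - mean(p1[lab == "apo"]))
  # displacement in projection units: offset difference times mode norm
  modes <- attr(st$apo, "mode_vectors")
  planted_gap <- 6 * ensdyn:::vec_norm(modes[, 1])
  expect_equal(gap, planted_gap, tolerance = 0.05 * planted_gap)
  # linear separability: no misassignment at the midpoint threshold
  thr <- (mean(p1[lab == "holo"]) + mean(p1[lab == "apo"])) / 2
  side <- sign(mean(p1[lab == "holo"]) - thr)
  expect_true(all(side * (p1[lab == "holo"] - thr) > 0))
  expect_true(all(side * (p1[lab == "apo"] - thr) < 0))
})

test_that("square fluctuations decompose the eigenvalue over residues", {
  spec <- generator_spec(n_residues = 12, n_members = 40, seed = 27)
  dec <- pca_modes(generate_ensemble(spec))
  sf <- square_fluctuations(dec, 1)
  expect_equal(sum(sf), dec$eigenvalues[1], tolerance = 1e-9)
  expect_error(square_fluctuations(dec, 10000), "mode_index")
  # a mode localized on one residue puts all fluctuation there
  dec2 <- dec
  v <- rep(0, nrow(dec$modes))
  v[1:3] <- c(1, 0, 0)
  dec2$modes[, 1] <- v
  sf2 <- square_fluctuations(dec2, 1)
  expect_equal(unname(sf2[as.character(dec$atoms$resno[1])]),
               dec2$eigenvalues[1])
  expect_equal(sum(sf2[-1]), 0)
})

test_that("distance-mode correlations flag planted reporter pairs", {
  spec <- generator_spec(n_members = 500, mode_sds = c(2, 1),
                         noise_sd = 0.1, seed = 24)
  ens <- generate_ensemble(spec)
  dec <- pca_modes(ens)
  topo <- attr(ens, "topology")
  modes <- attr(ens, "mode_vectors")
  rp <- planted_reporter_pair(topo, modes, 1)
  M1 <- distance_mode_correlation(dec, 1)
  M2 <- distance_mode_correlation(dec, 2)
  i <- as.character(rp[1]); j <- as.character(rp[2])
  expect_gte(abs(M1[i, j]), 0.9)
  expect_lte(abs(M2[i, j]), 0.3)
  # symmetry and undefined diagonal
  expect_equal(M1[i, j], M1[j, i])
  expect_true(all(is.na(diag(M1))))
})

test_that("a pair moving affinely with the projection correlates at +1", {
  # two atoms whose distance is an affine function of a planted coordinate
  n <- 20
  atoms <- data.frame(resno = 1:3, resid = "ALA", elety = "CA", chain = "A")
  set.seed(28)
  a <- rnorm(n, sd = 2)
  coords <- lapply(a, function(ai)
    rbind(c(-5 - ai / 2, 0, 0), c(5 + ai / 2, 0, 0), c(0, 7, 0)))
  ens <- ens_from_coords(atoms, coords)
  dec <- pca_modes(ens)
  M <- distance_mode_correlation(dec, 1)
  expect_equal(abs(M["1", "2"]), 1, tolerance = 1e-6)
})

test_that("distance-mode correlation is invariant to rigid-body motions", {
  spec <- generator_spec(n_residues = 12, n_members = 40, seed = 29)
  ens <- generate_ensemble(spec)
  M <- distance_mode_correlation(pca_modes(ens), 1)
  M_shuffled <- distance_mode_correlation(pca_modes(rigid_shuffle(ens, 30)), 1)
  # modes may flip sign between runs; compare absolute correlations
  expect_equal(abs(M_shuffled), abs(M), tolerance = 1e-4)
})

test_that("top pairs rank by |correlation| with deterministic tie-breaks", {
  M <- matrix(NA_real_, 3, 3, dimnames = list(1:3, 1:3))
  M[1, 2] <- M[2, 1] <- -0.9
  M[1, 3] <- M[3, 1] <- 0.9
  M[2, 3] <- M[3, 2] <- 0.5
  class(M) <- "distance_mode_correlation"
  top <- top_correlated_pairs(M, 2)
  # tie at |0.9|: lower first index wins
  expect_equal(top$res_i, c(1, 1))
  expect_equal(top$res_j, c(2, 3))
  expect_equal(nrow(top_correlated_pairs(M, 0)), 0L)
  expect_equal(top_correlated_pairs(M, 1, sign = "positive")$correlation, 0.9)
  expect_equal(top_correlated_pairs(M, 1, sign = "negative")$correlation, -0.9)
  expect_warning(top_correlated_pairs(M, 10), "truncating")
})

test_that("mode decompositions persist to NMD, PDB and CSV", {
  spec <- generator_spec(n_residues = 10, n_members = 10, seed = 31)
  dec <- pca_modes(generate_ensemble(spec))
  prefix <- file.path(tempdir(), "dectest")
  paths <- write_mode_decomposition(dec, prefix)
  expect_true(all(file.exists(paths)))
  nmd <- readLines(paste0(prefix, ".nmd"))
  expect_true(any(grepl("^coordinates ", nmd)))
  expect_equal(sum(grepl("^mode ", nmd)), 2L)
  proj <- read.csv(paste0(prefix, "_projections.csv"))
  expect_equal(nrow(proj), 10L)
})
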