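test_that("min-max normalization maps to [0, 1] and flags constants", {
  expect_equal(as.numeric(minmax_normalize(c(2, 4, 6))), c(0, 0.5, 1))
  z <- minmax_normalize(c(3, 3, 3))
  expect_equal(as.numeric(z), c(0, 0, 0))
  expect_true(attr(z, "degenerate"))
  # positive affine transforms change nothing
  x <- c(1.2, 5.5, 2.2, 9.1)
  expect_equal(as.numeric(minmax_normalize(3.7 * x + 11)),
               as.numeric(minmax_normalize(x)), tolerance = 1e-12)
  expect_error(minmax_normalize(1), "2 entries")
})

test_that("predicted deltas aggregate reference differences correctly", {
  spec <- generator_spec(n_residues = 10, n_members = 3, seed = 50)
  ref <- generate_ensemble(spec)
  pred <- shift_predictor_surrogate()
  # a pool conformer identical to a single reference gives an all-zero profile
  one_ref <- ensemble_subset(ref, members = 1)
  d0 <- predicted_delta(one_ref, one_ref, pred)
  expect_equal(max(abs(d0)), 0)
  # two references: plain mean of the per-reference |differences|
  two_ref <- ensemble_subset(ref, members = 1:2)
  pool <- ensemble_subset(ref, members = 3)
  d_mean <- predicted_delta(pool, two_ref, pred)
  p <- function(ens, m) {
    t <- pred(ens, m)
    setNames(t$shift[t$nucleus == "N"], t$resno[t$nucleus == "N"])
  }
  manual <- (abs(p(pool, 1) - p(two_ref, 1)) +
             abs(p(pool, 1) - p(two_ref, 2))) / 2
  expect_equal(d_mean[1, names(manual)], manual, tolerance = 1e-12)
  # median and best aggregations are monotone alternatives
  d_best <- predicted_delta(pool, two_ref, pred, aggregate = "best")
  expect_true(all(d_best <= d_mean + 1e-12))
})

test_that("predicted deltas match the explicit double-loop oracle", {
  spec <- generator_spec(n_residues = 8, n_members = 4, seed = 51)
  ref <- generate_ensemble(spec)
  pool <- generate_ensemble(spec, seed_offset = 5L, label = "pool")
  pred <- shift_predictor_surrogate()
  fast <- predicted_delta(pool, ref, pred)
  slow <- bf_predicted_delta(pool, ref, pred)
  expect_equal(fast, slow[, colnames(fast)], tolerance = 1e-10)
})

test_that("candidate scoring is exact on proportional and anti-ordered data", {
  # profile proportional to |delta omega| at every temperature
  profile <- matrix(c(0.1, 0.4, 0.2, 0.9, 0.55), nrow = 1,
                    dimnames = list(NULL, 1:5))
  dw <- delta_omega_set(rep(1:5, 3), rep(c(283, 287, 291), each = 5),
                        rep(3.2 * profile[1, ], 3))
  sc <- score_candidates(profile, dw)
  expect_equal(sc$mean_correlation, 1, tolerance = 1e-12)
  expect_equal(sc$mean_rmsd, 0, tolerance = 1e-12)
  # reversed ranking over 3 residues: correlation -1
  prof2 <- matrix(c(1, 2, 3), nrow = 1, dimnames = list(NULL, 1:3))
  dw2 <- delta_omega_set(1:3, rep(283, 3), c(3, 2, 1))
  sc2 <- score_candidates(prof2, dw2)
  expect_equal(sc2$mean_correlation, -1, tolerance = 1e-12)
  # scores are invariant to positive affine rescaling of either side
  sc3 <- score_candidates(prof2 * 100 + 3, dw2)
  expect_equal(sc3$mean_correlation, sc2$mean_correlation, tolerance = 1e-12)
  expect_equal(sc3$mean_rmsd, sc2$mean_rmsd, tolerance = 1e-12)
})

test_that("per-temperature sets are honored and removal recomputes the mean", {
  profile <- matrix(c(0.1, 0.4, 0.2, 0.9), nrow = 1,
                    dimnames = list(NULL, 1:4))
  # different residue coverage per temperature
  dw <- delta_omega_set(c(1:4, 1:3, 2:4),
                        c(rep(283, 4), rep(287, 3), rep(291, 3)),
                        c(0.1, 0.4, 0.2, 0.9, 0.3, 0.1, 0.6, 0.5, 0.1, 0.7))
  sc_all <- score_candidates(profile, dw)
  per_t <- attr(sc_all, "per_temperature")
  # oracle: the mean score is the plain mean of the per-temperature scores
  expect_equal(sc_all$mean_correlation, mean(per_t$correlation),
               tolerance = 1e-12)
  # dropping one temperature equals recomputing the mean over the rest
  dw2 <- dw[dw$temperature != 287, ]
  class(dw2) <- class(dw)
  sc2 <- score_candidates(profile, dw2)
  expect_equal(sc2$mean_correlation,
               mean(per_t$correlation[per_t$temperature != 287]),
               tolerance = 1e-12)
})

test_that("selection thresholds split candidates independently", {
  sc <- data.frame(conformer = 1:4,
                   mean_correlation = c(0.9, 0.2, 0.5, NA),
                   mean_rmsd = c(0.002, 0.001, 0.9, 0.001))
  class(sc) <- c("candidate_scores", "data.frame")
  sel <- select_candidates(sc)
  expect_setequal(sel$selected_by_correlation, c(1L, 3L))
  expect_setequal(sel$selected_by_rmsd, c(1L, 2L, 4L))
  # conformer 3 passes only the correlation criterion
  expect_true(3L %in% sel$selected_by_correlation)
  expect_false(3L %in% sel$selected_by_rmsd)
  # all below both criteria -> empty selections
  low <- data.frame(conformer = 1:2, mean_correlation = c(0, 0.1),
                    mean_rmsd = c(0.5, 0.9))
  class(low) <- c("candidate_scores", "data.frame")
  sel2 <- select_candidates(low)
  expect_length(sel2$selected_by_correlation, 0)
  expect_length(sel2$selected_by_rmsd, 0)
  # default thresholds
  expect_equal(unname(sel$thresholds["correlation"]), 0.35)
  expect_equal(unname(sel$thresholds["rmsd"]), 0.00603)
})

test_that("the planted conformer outscores its decoys", {
  spec <- generator_spec(n_members = 10, seed = 52, n_decoys = 50)
  apo <- generate_ensemble(spec, label = "apo")
  hs <- plant_hidden_state(apo, spec)
  deltas <- predicted_delta(hs$pool, apo, shift_predictor_surrogate())
  sc <- score_candidates(deltas, hs$delta_omega)
  expect_equal(which.max(sc$mean_correlation), hs$planted_id)
  expect_equal(which.min(sc$mean_rmsd), hs$planted_id)
})
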