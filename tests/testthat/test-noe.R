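test_that("destereo expands stereo partners against the topology", {
  tf <- tempfile(fileext = ".pdb")
  write_tiny_pdb(tf)
  ens <- read_pdb_ensemble(tf)
  r <- single_restraint(23L, "HD11", 25L, "HA")
  r$resid_a <- "LEU"
  r$resid_b <- "ALA"
  out <- destereo(r, ens)
  # one Leu HD methyl proton becomes all six HD protons
  expect_setequal(out$group_a[[1]],
                  c("HD11", "HD12", "HD13", "HD21", "HD22", "HD23"))
  # Ala HA has no stereo partner
  expect_equal(out$group_b[[1]], "HA")
  # Gly HA2 -> HA2/HA3
  r2 <- single_restraint(24L, "HA2", 25L, "HA")
  r2$resid_a <- "GLY"
  r2$resid_b <- "ALA"
  expect_setequal(destereo(r2, ens)$group_a[[1]], c("HA2", "HA3"))
  # wildcard groups expand but gain nothing extra
  r3 <- single_restraint(23L, "HD#", 25L, "HA")
  r3$resid_a <- "LEU"
  r3$resid_b <- "ALA"
  expect_setequal(destereo(r3, ens)$group_a[[1]], out$group_a[[1]])
  # unknown atom errors
  r4 <- single_restraint(23L, "HZ9", 25L, "HA")
  r4$resid_a <- "LEU"
  expect_error(destereo(r4, ens), "not found")
})

test_that("upper bounds bin by ceiling, clamped to the 4-10 A range", {
  expect_equal(bin_upper_bound(4.3), 5)
  expect_equal(bin_upper_bound(3.2), 4)
  expect_equal(bin_upper_bound(9.0), 9)
  expect_equal(bin_upper_bound(c(4.01, 10)), c(5, 10))
  expect_error(bin_upper_bound(10.2), "outside")
  expect_error(bin_upper_bound(0), "positive")
})

test_that("effective distance matches closed-form and brute-force values", {
  # identity: one member, one pair
  expect_equal(effective_distance(pair_ensemble(3), single_restraint()), 3)
  # two members at 3 and 5 A: ((3^-6 + 5^-6)/2)^(-1/6)
  expect_equal(effective_distance(pair_ensemble(c(3, 5)), single_restraint()),
               ((3^-6 + 5^-6) / 2)^(-1 / 6), tolerance = 1e-12)
  # two pairs both at 3 A: (2 * 3^-6)^(-1/6)
  atoms <- data.frame(resno = c(1L, 2L, 2L), resid = "ALA",
                      elety = c("H", "HA", "HB1"), chain = "A")
  ens <- ens_from_coords(atoms, list(rbind(c(0, 0, 0), c(3, 0, 0), c(0, 3, 0))))
  r <- single_restraint(1L, "H", 2L, c("HA", "HB1"))
  expect_equal(effective_distance(ens, r), (2 * 3^-6)^(-1 / 6),
               tolerance = 1e-12)
  # mean-combination flag divides by the pair count
  expect_equal(effective_distance(ens, r, combine = "mean"), 3,
               tolerance = 1e-12)
})

test_that("effective distance obeys ensemble-averaging bounds", {
  ens <- pair_ensemble(c(2.5, 3.7, 5.1))
  r <- single_restraint()
  eff <- effective_distance(ens, r)
  per_member <- vapply(1:3, function(m)
    effective_distance(ensemble_subset(ens, members = m), r), numeric(1))
  expect_gte(eff, min(per_member))
  expect_lte(eff, max(per_member))
  # multi-pair group: effective distance below the closest single pair
  atoms <- data.frame(resno = c(1L, 2L, 2L), resid = "ALA",
                      elety = c("H", "HA", "HB1"), chain = "A")
  ens2 <- ens_from_coords(atoms, list(rbind(c(0, 0, 0), c(3, 0, 0), c(0, 4, 0))))
  expect_lt(effective_distance(ens2, single_restraint(1L, "H", 2L, c("HA", "HB1"))),
            3)
  # duplicating every conformer leaves effective distances unchanged
  dup <- ensemble_subset(ens, members = c(1, 2, 3, 1, 2, 3))
  expect_equal(effective_distance(dup, r), eff, tolerance = 1e-12)
})

test_that("effective distance equals the explicit brute-force loop", {
  spec <- generator_spec(n_residues = 8, n_members = 5, seed = 4)
  ens <- generate_ensemble(spec)
  obs <- synth_observables(ens, spec)
  r <- obs$restraints[1:10, ]
  eff <- effective_distance(ens, r)
  idx <- ensdyn:::resolve_indices(r, ens)
  for (i in seq_len(nrow(r))) {
    expect_equal(eff[i], bf_effective_distance(ens, idx$a[[i]], idx$b[[i]]),
                 tolerance = 1e-10)
  }
})

test_that("violation reports count strict exceedances of bin + tolerance", {
  ens <- pair_ensemble(4.49)
  r <- bin_restraints(single_restraint(upper = 4))
  expect_equal(violation_report(ens, r)$percent_violated, 0)
  # exactly at the limit is not a violation; just above is
  expect_equal(violation_report(pair_ensemble(4.5), r)$percent_violated, 0)
  expect_equal(violation_report(pair_ensemble(4.5001), r)$percent_violated, 100)
  # percentage arithmetic and monotonicity in tolerance
  many <- do.call(rbind, rep(list(single_restraint(upper = 4)), 8))
  many$id <- 1:8
  class(many) <- c("noe_restraints", "data.frame")
  many <- bin_restraints(many)
  ens2 <- pair_ensemble(4.8)
  v_tight <- violation_report(ens2, many, tolerance = 0.5)
  v_loose <- violation_report(ens2, many, tolerance = 1.0)
  expect_equal(v_tight$percent_violated, 100)
  expect_equal(v_loose$percent_violated, 0)
  expect_error(violation_report(ens, many[0, ]), "empty")
  expect_error(violation_report(ens, single_restraint(upper = 4)), "binned")
})

test_that("filter_unviolated leaves a self-consistent restraint set", {
  spec <- generator_spec(n_residues = 10, n_members = 5, seed = 6)
  ens <- generate_ensemble(spec)
  obs <- synth_observables(ens, spec)
  r <- obs$restraints
  # tighten bounds artificially so some restraints violate
  r$bin <- pmax(r$bin - 2, 4)
  kept <- filter_unviolated(r, ens)
  expect_lte(nrow(kept), nrow(r))
  if (nrow(kept) > 0) {
    expect_equal(violation_report(ens, kept)$percent_violated, 0)
    # order preserved
    expect_true(!is.unsorted(match(kept$id, r$id)))
  }
  # empty input passes through
  expect_equal(nrow(filter_unviolated(r[0, ], ens)), 0L)
})
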