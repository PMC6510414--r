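# A hand-built donor/acceptor geometry: N-H pointing at a carbonyl O at
# configurable distance and angle.
hb_probe <- function(h_a_dist = 2.0, angle = 180) {
  # donor N at origin, H along +x; acceptor O placed so that the
  # D-H...A angle and H...A distance are as requested
  theta <- (180 - angle) * pi / 180
  O <- c(1.01 + h_a_dist * cos(theta), h_a_dist * sin(theta), 0)
  atoms <- data.frame(resno = c(1L, 1L, 5L, 5L),
                      resid = "ALA",
                      elety = c("N", "H", "C", "O"),
                      chain = "A")
  coords <- list(rbind(c(0, 0, 0), c(1.01, 0, 0), O + c(1.23, 0, 0), O))
  ens_from_coords(atoms, coords)
}

test_that("hydrogen bonds require all three geometric criteria", {
  # linear N-H...O at 2.0 A -> detected
  hb <- detect_hbonds(hb_probe(2.0, 180))
  expect_equal(nrow(hb), 1L)
  expect_equal(hb$donor_resno, 1L)
  expect_equal(hb$acceptor_atom, "O")
  # angle 90 degrees -> rejected
  expect_equal(nrow(detect_hbonds(hb_probe(2.0, 90))), 0L)
  # H...A 2.6 A -> rejected by the distance threshold
  expect_equal(nrow(detect_hbonds(hb_probe(2.6, 180))), 0L)
  # custom criteria re-admit it
  loose <- hbond_criteria(h_acceptor_max = 3.0, donor_acceptor_max = 4.5)
  expect_equal(nrow(detect_hbonds(hb_probe(2.6, 180), criteria = loose)), 1L)
  # missing hydrogens is an explicit error
  topo <- make_topology(8)
  heavy <- ensemble_subset(topo, atoms = "heavy")
  expect_error(detect_hbonds(heavy), "hydrogen")
})

test_that("hydrogen bond detection is invariant to rigid motion", {
  topo <- make_topology(20)
  hb0 <- detect_hbonds(topo)
  moved <- rigid_shuffle(topo, seed = 33)
  hb1 <- detect_hbonds(moved)
  key <- function(h) sort(paste(h$donor_resno, h$donor_atom,
                                h$acceptor_resno, h$acceptor_atom))
  expect_equal(key(hb1), key(hb0))
})

test_that("occupancies equal the brute-force member count", {
  spec <- generator_spec(n_residues = 12, n_members = 5, seed = 34)
  ens <- generate_ensemble(spec)
  occ <- hbond_occupancy(ens)
  expect_s3_class(occ, "occupancy_table")
  expect_true(all(occ$occupancy > 0 & occ$occupancy <= 1))
  for (i in seq_len(min(nrow(occ), 8))) {
    expect_equal(occ$occupancy[i],
                 bf_occupancy(ens, occ$donor_resno[i], occ$donor_atom[i],
                              occ$acceptor_resno[i], occ$acceptor_atom[i]),
                 tolerance = 1e-12)
  }
  # sparsity: never-formed bonds are absent rather than zero
  far_pairs <- nrow(unique(ens$atoms[, c("resno", "elety")]))^2
  expect_lt(nrow(occ), far_pairs)
  # duplicating members leaves occupancies unchanged
  dup <- ensemble_subset(ens, members = rep(seq_len(n_members(ens)), 2))
  occ2 <- hbond_occupancy(dup)
  expect_equal(occ2$occupancy, occ$occupancy)
})

test_that("state differencing labels and sorts changing bonds", {
  mk_occ <- function(dn, da, an, aa, occ, n = 10L) {
    d <- data.frame(donor_resno = dn, donor_atom = da, acceptor_resno = an,
                    acceptor_atom = aa, occupancy = occ,
                    stringsAsFactors = FALSE)
    attr(d, "n_members") <- n
    class(d) <- c("occupancy_table", "data.frame")
    d
  }
  apo <- mk_occ(c(73L, 64L, 90L), c("OG1", "N", "N"), c(72L, 69L, 101L),
                c("O", "OG", "O"), c(0.9, 0.95, 0.6))
  holo <- mk_occ(c(73L, 64L, 90L), c("N", "N", "N"), c(73L, 69L, 101L),
                 c("OG1", "OG", "O"), c(0.85, 0.1, 0.05))
  d <- state_difference(apo, holo)
  # sorted by donor residue number
  expect_equal(d$donor_resno, sort(d$donor_resno))
  # a bond present only in apo at 0.9 vs 0 is a plain apo bond
  row_apo <- d[d$donor_atom == "OG1", ]
  expect_equal(row_apo$state, "apo")
  expect_equal(row_apo$delta, -0.9)
  # present only in holo at 0.85 -> plain holo
  row_holo <- d[d$acceptor_atom == "OG1", ]
  expect_equal(row_holo$state, "holo")
  # 0.95 -> 0.1 is |delta| 0.85 -> apo; 0.6 -> 0.05 is 0.55 -> mostly apo
  expect_equal(d$state[d$donor_resno == 64], "apo")
  expect_equal(d$state[d$donor_resno == 90], "mostly apo")
  # equal occupancies are not listed
  same <- state_difference(apo, apo)
  expect_equal(nrow(same), 0L)
  # antisymmetry under swapping the states
  rev <- state_difference(holo, apo)
  expect_equal(sort(rev$delta), sort(-d$delta))
  swap <- c(apo = "holo", holo = "apo", `mostly apo` = "mostly holo",
            `mostly holo` = "mostly apo")
  key <- function(x) paste(x$donor_resno, x$donor_atom, x$acceptor_resno,
                           x$acceptor_atom)
  expect_equal(unname(swap[d$state]), rev$state[match(key(d), key(rev))])
})

test_that("planted hydrogen-bond switches surface in the state difference", {
  st <- generate_state_ensembles(generator_spec(n_members = 25, seed = 35))
  expect_gte(nrow(st$switches), 1L)
  occ_a <- hbond_occupancy(st$apo)
  occ_h <- hbond_occupancy(st$holo)
  diffs <- state_difference(occ_a, occ_h)
  for (i in seq_len(nrow(st$switches))) {
    hit <- diffs[diffs$donor_resno == st$switches$donor_resno[i] &
                 diffs$acceptor_resno == st$switches$acceptor_resno[i] &
                 diffs$donor_atom == "N" & diffs$acceptor_atom == "O", ]
    expect_equal(nrow(hit), 1L)
    expect_match(hit$state, st$switches$state[i])
  }
})

test_that("occupancy tables serialize with the documented key convention", {
  spec <- generator_spec(n_residues = 10, n_members = 3, seed = 36)
  occ <- hbond_occupancy(generate_ensemble(spec))
  tf <- tempfile(fileext = ".csv")
  write_occupancy_csv(occ, tf)
  d <- read.csv(tf)
  expect_true(all(grepl("^a_\\d+_[A-Z0-9]+_a_\\d+_[A-Z0-9]+$", d$bond)))
  expect_equal(d$occupancy, occ$occupancy)
})
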