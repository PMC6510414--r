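# Synthetic conformer ensembles with planted ground truth: an idealized
# sheet+helix topology, two orthogonal collective modes, observables
# (S2, NOE restraints, shifts) and a planted excited-state conformer.

# --- internal chain building (NeRF) ----------------------------------------

# Place atom d given positions a, b, c with |cd| = bond,
# angle(b, c, d) = ang (deg) and torsion(a, b, c, d) = tor (deg).
nerf_place <- function(a, b, c, bond, ang, tor) {
  ang <- ang * pi / 180
  tor <- tor * pi / 180
  bc <- unit(c - b)
  n <- unit(cross3(b - a, bc))
  m <- cross3(n, bc)
  d2 <- bond * c(-cos(ang), sin(ang) * cos(tor), sin(ang) * sin(tor))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

# canonical backbone geometry (Angstrom, degrees)
.bb <- list(n_ca = 1.458, ca_c = 1.525, c_n = 1.329, c_o = 1.231, n_h = 1.010,
            ang_n_ca_c = 111.2, ang_ca_c_n = 116.2, ang_c_n_ca = 121.7,
            ang_ca_c_o = 120.8, omega = 180)

#' Build an idealized backbone topology
#'
#' Constructs a single-chain conformer with N, H, CA, C, O atoms per
#' residue at canonical bond lengths and angles, arranged as an
#' antiparallel beta-hairpin (two strands closed by a tight turn) followed
#' by a short linker and one alpha-helix, so that both helix and strand
#' hydrogen-bond patterns are present. All residues are alanine-like
#' (backbone only); torsions: strands (-139, 135), turn (45, 49)/(131, -47)
#' (tuned once so the two strands hydrogen-bond as an antiparallel
#' ladder), helix (-57, -47).
#'
#' @param n_residues number of residues (>= 5).
#' @return a single-member [conf_ensemble()].
#' @export
make_topology <- function(n_residues) {
  if (n_residues < 5L) stop("need at least 5 residues")
  n <- n_residues
  if (n >= 16L) {
    # segment plan: strand, turn (2), strand, linker (2), helix
    helix_len <- max(6L, floor(0.4 * n))
    rest <- n - helix_len - 4L
    s1 <- max(2L, floor(rest / 2))
    s2 <- max(2L, rest - s1)
    helix_len <- n - s1 - s2 - 4L
    phi <- c(rep(-139, s1), 45, 131, rep(-139, s2), -70, -70, rep(-57, helix_len))
    psi <- c(rep(135, s1), 49, -47, rep(135, s2), 140, 140, rep(-47, helix_len))
  } else {
    # too short for a separate helix: hairpin only
    s1 <- max(1L, floor((n - 2L) / 2))
    s2 <- n - 2L - s1
    phi <- c(rep(-139, s1), 45, 131, rep(-139, s2))
    psi <- c(rep(135, s1), 49, -47, rep(135, s2))
  }
  stopifnot(length(phi) == n)

  pos <- vector("list", n)
  # seed first three atoms
  N1 <- c(0, 0, 0)
  CA1 <- c(.bb$n_ca, 0, 0)
  C1 <- nerf_place(c(0, 1, 0), N1, CA1, .bb$ca_c, .bb$ang_n_ca_c, psi[1] - 120)
  pos[[1]] <- list(N = N1, CA = CA1, C = C1)
  for (i in 2:n) {
    p <- pos[[i - 1]]
    Ni <- nerf_place(p$N, p$CA, p$C, .bb$c_n, .bb$ang_ca_c_n, psi[i - 1])
    CAi <- nerf_place(p$CA, p$C, Ni, .bb$n_ca, .bb$ang_c_n_ca, .bb$omega)
    Ci <- nerf_place(p$C, Ni, CAi, .bb$ca_c, .bb$ang_n_ca_c, phi[i])
    pos[[i]] <- list(N = Ni, CA = CAi, C = Ci)
  }
  # amide H: bisector of CA and previous C, in plane; carbonyl O:
  # bisector of CA and next N
  rows <- list()
  for (i in 1:n) {
    p <- pos[[i]]
    if (i > 1) {
      H <- p$N + .bb$n_h * unit(unit(p$N - p$CA) + unit(p$N - pos[[i - 1]]$C))
    } else {
      H <- p$N + .bb$n_h * unit(unit(p$N - p$CA) + c(0, 0, 1) * 0.5)
    }
    if (i < n) {
      O <- p$C + .bb$c_o * unit(unit(p$C - p$CA) + unit(p$C - pos[[i + 1]]$N))
    } else {
      O <- p$C + .bb$c_o * unit(unit(p$C - p$CA))
    }
    rows[[i]] <- rbind(N = p$N, H = H, CA = p$CA, C = p$C, O = O)
  }
  atoms <- data.frame(
    resno = rep(seq_len(n), each = 5L),
    resid = "ALA",
    elety = rep(c("N", "H", "CA", "C", "O"), n),
    chain = "A",
    stringsAsFactors = FALSE
  )
  xyz <- mat_to_xyz(do.call(rbind, rows))
  conf_ensemble(atoms, matrix(xyz, nrow = 1), label = "topology")
}

# --- generator specification -----------------------------------------------

#' Specification for the synthetic ensemble generator
#'
#' Defines the statistical structure of the generated data: an idealized
#' topology whose conformational variance is dominated by a small number
#' of orthogonal collective modes (smooth sinusoidal displacement fields
#' along the chain, purged of rigid-body components) plus isotropic
#' per-coordinate noise, with planted observables.
#'
#' @param n_residues chain length.
#' @param n_members ensemble size (default 168, a typical restrained-MD
#'   ensemble pooled from replicas).
#' @param n_replicas replica tags distributed over the members (sub-
#'   ensemble structure used by [ensemble_rmsd()]).
#' @param mode_sds standard deviations (Angstrom) of the Gaussian
#'   coefficients of the collective modes; their length sets the number of
#'   modes.
#' @param noise_sd isotropic per-coordinate noise sd in Angstrom.
#' @param seed integer seed; fixed seed gives bit-identical output.
#' @param s2_noise_sd additive observation noise on the planted S2 values.
#' @param state_displacement separation (Angstrom, along mode 1) between
#'   the apo and holo ensemble means in [generate_state_ensembles()].
#' @param planted_hbond_switches optional data.frame with columns
#'   \code{donor_resno}, \code{acceptor_resno}, \code{state} ("apo" or
#'   "holo"): hydrogen bonds present only in that state; \code{NULL}
#'   auto-selects inter-strand bonds of the topology.
#' @param hidden_mode mode along which the hidden conformer is displaced;
#'   defaults to mode 2 (or mode 1 when only one mode is planted).
#' @param hidden_displacement displacement (Angstrom) of the planted
#'   hidden conformer along \code{hidden_mode}.
#' @param n_decoys decoy pool size for [plant_hidden_state()].
#' @param dw_noise multiplicative noise level on the emitted |delta omega|
#'   values.
#' @param dw_temperatures temperatures (K) at which |delta omega| profiles
#'   are emitted.
#' @param dw_residue_fraction fraction of residues retained (independently
#'   per temperature) in the |delta omega| tables, emulating the partial
#'   residue coverage of relaxation-dispersion data.
#' @return a \code{generator_spec} list.
#' @export
generator_spec <- function(n_residues = 40L, n_members = 168L,
                           n_replicas = 8L, mode_sds = c(2, 1),
                           noise_sd = 0.1, seed = 1L,
                           s2_noise_sd = 0.02, state_displacement = 6,
                           planted_hbond_switches = NULL,
                           hidden_mode = NULL, hidden_displacement = 6,
                           n_decoys = 200L, dw_noise = 0.1,
                           dw_temperatures = c(283, 287, 291),
                           dw_residue_fraction = 0.8) {
  if (is.null(hidden_mode)) hidden_mode <- min(2L, length(mode_sds))
  stopifnot(n_residues >= 5L, n_members >= 1L, all(mode_sds >= 0),
            noise_sd >= 0, hidden_displacement >= 0,
            hidden_mode >= 1L, hidden_mode <= length(mode_sds),
            dw_residue_fraction > 0, dw_residue_fraction <= 1)
  spec <- list(n_residues = as.integer(n_residues),
               n_members = as.integer(n_members),
               n_replicas = as.integer(n_replicas),
               mode_sds = mode_sds, noise_sd = noise_sd,
               seed = as.integer(seed), s2_noise_sd = s2_noise_sd,
               state_displacement = state_displacement,
               planted_hbond_switches = planted_hbond_switches,
               hidden_mode = as.integer(hidden_mode),
               hidden_displacement = hidden_displacement,
               n_decoys = as.integer(n_decoys), dw_noise = dw_noise,
               dw_temperatures = dw_temperatures,
               dw_residue_fraction = dw_residue_fraction)
  class(spec) <- "generator_spec"
  spec
}

#' Planted collective mode vectors for a topology
#'
#' Builds one displacement field per requested mode: a smooth sinusoidal
#' per-residue envelope (frequency increasing with mode number) applied
#' along a fixed Cartesian axis, then orthogonalized against the six
#' rigid-body motions of the topology and against earlier modes, and
#' scaled to a common 3N norm such that the largest per-atom displacement
#' of mode 1 is 1 Angstrom per unit coefficient. The smooth envelopes
#' localize each mode on part of the chain, so specific residue pairs act
#' as distance reporters of each mode.
#'
#' @param topology a single-member [conf_ensemble()] from
#'   [make_topology()].
#' @param n_modes number of modes.
#' @return 3N x n_modes matrix of mutually orthogonal mode vectors.
#' @export
make_mode_vectors <- function(topology, n_modes = 2L) {
  atoms <- topology$atoms
  coords <- member_coords(topology, 1L)
  na <- nrow(coords)
  t_res <- (atoms$resno - 1) / max(atoms$resno - 1)
  axes <- list(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  raw <- sapply(seq_len(n_modes), function(k) {
    env <- sin((k + 1) * pi * t_res)
    as.numeric(t(outer(env, axes[[(k - 1L) %% 3L + 1L]])))
  })
  # rigid-body basis: 3 translations + 3 rotations about the centroid
  cen <- sweep(coords, 2, colMeans(coords))
  rigid <- cbind(
    rep(c(1, 0, 0), na), rep(c(0, 1, 0), na), rep(c(0, 0, 1), na),
    as.numeric(t(cbind(0, -cen[, 3], cen[, 2]))),
    as.numeric(t(cbind(cen[, 3], 0, -cen[, 1]))),
    as.numeric(t(cbind(-cen[, 2], cen[, 1], 0)))
  )
  basis <- qr.Q(qr(rigid))
  modes <- matrix(0, 3 * na, n_modes)
  for (k in seq_len(n_modes)) {
    v <- raw[, k]
    v <- v - basis %*% crossprod(basis, v)
    if (k > 1)
      for (j in seq_len(k - 1))
        v <- v - modes[, j] %*% crossprod(modes[, j], v) /
          sum(modes[, j]^2)
    modes[, k] <- v
  }
  # common norm; unit coefficient = 1 A peak atom displacement of mode 1
  peak <- max(sqrt(rowSums(xyz_to_mat(modes[, 1])^2)))
  target <- vec_norm(modes[, 1]) / peak
  for (k in seq_len(n_modes)) modes[, k] <- modes[, k] / vec_norm(modes[, k]) * target
  modes
}

#' Generate a synthetic conformer ensemble
#'
#' Member m is \code{topology + sum_k a_mk mode_k + eps} with
#' \code{a_mk ~ N(offset_k, mode_sd_k^2)} and isotropic per-coordinate
#' noise \code{eps ~ N(0, noise_sd^2)}. One global random stream is seeded
#' from \code{spec$seed + seed_offset} and consumed in a fixed order (mode
#' coefficients, then noise), so output is bit-identical under a fixed
#' seed; coordinates are rounded to 0.001 Angstrom, the precision of the
#' interchange format.
#'
#' @param spec a [generator_spec()].
#' @param mode_offsets mean coefficient per mode (Angstrom), recycled.
#' @param label ensemble label.
#' @param seed_offset added to \code{spec$seed} so that related ensembles
#'   (apo/holo, decoy pools) use distinct, documented streams.
#' @return a [conf_ensemble()] with attributes \code{"topology"} and
#'   \code{"mode_vectors"} (the planted ground truth).
#' @export
generate_ensemble <- function(spec, mode_offsets = 0, label = "synthetic",
                              seed_offset = 0L) {
  topo <- make_topology(spec$n_residues)
  modes <- make_mode_vectors(topo, length(spec$mode_sds))
  set.seed(spec$seed + seed_offset)
  nm <- spec$n_members
  k <- length(spec$mode_sds)
  offs <- rep_len(mode_offsets, k)
  coef <- matrix(stats::rnorm(nm * k), nm, k)
  coef <- sweep(coef, 2, spec$mode_sds, `*`)
  coef <- sweep(coef, 2, offs, `+`)
  noise <- matrix(stats::rnorm(nm * ncol(topo$xyz), sd = spec$noise_sd),
                  nm, ncol(topo$xyz))
  xyz <- matrix(rep(topo$xyz[1, ], each = nm), nm) + coef %*% t(modes) + noise
  xyz <- round(xyz, 3)
  sub <- rep_len(paste0("rep", seq_len(spec$n_replicas)), nm)
  ens <- conf_ensemble(topo$atoms, xyz, label = label,
                       sub_ids = sort(sub))
  attr(ens, "topology") <- topo
  attr(ens, "mode_vectors") <- modes
  attr(ens, "mode_coefficients") <- coef
  ens
}

#' Residue pair most sensitive to a planted mode
#'
#' The Calpha pair whose inter-residue distance changes fastest per unit
#' coefficient of the given mode (largest |directional derivative| at the
#' topology), i.e. the natural distance reporter of that mode.
#'
#' @param topology single-member [conf_ensemble()].
#' @param modes mode matrix from [make_mode_vectors()].
#' @param mode_index mode number.
#' @return integer vector \code{c(res_i, res_j)}.
#' @export
planted_reporter_pair <- function(topology, modes, mode_index = 1L) {
  atoms <- topology$atoms
  coords <- member_coords(topology, 1L)
  v <- xyz_to_mat(modes[, mode_index])
  res <- sort(unique(atoms$resno))
  ca <- vapply(res, function(r) find_atom(atoms, r, "CA"), integer(1))
  best <- c(NA_integer_, NA_integer_)
  best_val <- -1
  for (i in seq_along(res)[-length(res)]) {
    for (j in (i + 1):length(res)) {
      dp <- coords[ca[i], ] - coords[ca[j], ]
      dv <- v[ca[i], ] - v[ca[j], ]
      sens <- abs(sum(dp * dv)) / vec_norm(dp)
      if (sens > best_val) {
        best_val <- sens
        best <- c(res[i], res[j])
      }
    }
  }
  best
}

#' Synthetic observables consistent with a generated ensemble
#'
#' Emits (i) a planted S2 set: the back-calculated ensemble order
#' parameters plus additive Gaussian observation noise, truncated to
#' [0, 1]; (ii) an NOE restraint list: all inter-residue H-H pairs whose
#' ensemble-mean distance is below 5 Angstrom, with the binned mean
#' distance as upper bound (already binned); (iii) chemical shifts: the
#' surrogate predictor applied to the ensemble mean structure. Draws come
#' from a stream seeded with \code{spec$seed + 1}.
#'
#' @param ensemble a [conf_ensemble()] from [generate_ensemble()].
#' @param spec the [generator_spec()] used to create it.
#' @return list with \code{s2} ([order_params()]), \code{restraints}
#'   (binned \code{noe_restraints}) and \code{shifts} ([shift_table()]).
#' @export
synth_observables <- function(ensemble, spec) {
  set.seed(spec$seed + 1L)
  s2_true <- backcalc_s2(ensemble)
  s2_obs <- s2_true$s2 + stats::rnorm(nrow(s2_true), sd = spec$s2_noise_sd)
  s2_obs <- pmin(pmax(s2_obs, 0), 1)
  s2 <- order_params(s2_true$resno, s2_obs)

  atoms <- ensemble$atoms
  h_idx <- which(is_hydrogen_name(atoms$elety))
  nm <- n_members(ensemble)
  # ensemble-mean H-H distances
  pairs <- utils::combn(h_idx, 2)
  same_res <- atoms$resno[pairs[1, ]] == atoms$resno[pairs[2, ]]
  pairs <- pairs[, !same_res, drop = FALSE]
  dmean <- rep(0, ncol(pairs))
  for (m in seq_len(nm)) {
    cm <- member_coords(ensemble, m)
    dmean <- dmean + sqrt(rowSums((cm[pairs[1, ], ] - cm[pairs[2, ], ])^2))
  }
  dmean <- dmean / nm
  keep <- which(dmean < 5)
  restraints <- if (length(keep) > 0L) {
    d <- data.frame(
      resno_a = atoms$resno[pairs[1, keep]],
      resid_a = atoms$resid[pairs[1, keep]],
      group_a = I(as.list(atoms$elety[pairs[1, keep]])),
      resno_b = atoms$resno[pairs[2, keep]],
      resid_b = atoms$resid[pairs[2, keep]],
      group_b = I(as.list(atoms$elety[pairs[2, keep]])),
      upper = dmean[keep], bin = NA_real_, stringsAsFactors = FALSE)
    d$id <- seq_len(nrow(d))
    class(d) <- c("noe_restraints", "data.frame")
    bin_restraints(d)
  } else empty_restraints()

  mean_ens <- conf_ensemble(atoms, matrix(colMeans(ensemble$xyz), nrow = 1),
                            label = "mean")
  shifts <- shift_predictor_surrogate()(mean_ens, 1L)
  list(s2 = s2, restraints = restraints, shifts = shifts)
}

#' Generate displaced apo/holo state ensembles
#'
#' Two ensembles from the same generative model whose means are separated
#' by \code{spec$state_displacement} along planted mode 1 (half each way),
#' emulating the ligation-dependent barrel opening. Planted hydrogen-bond
#' switches are applied afterwards: a bond tagged \code{"holo"} is broken
#' in every apo member by swinging the donor amide hydrogen away from the
#' acceptor (and vice versa), so the two states differ in occupancy at
#' those bonds. When \code{spec$planted_hbond_switches} is \code{NULL},
#' the two strongest inter-strand backbone bonds of the topology are
#' switched (first to apo, second to holo).
#'
#' @param spec a [generator_spec()].
#' @return list with \code{apo} and \code{holo} ensembles and the
#'   \code{switches} data.frame applied.
#' @export
generate_state_ensembles <- function(spec) {
  half <- spec$state_displacement / 2
  apo <- generate_ensemble(spec, mode_offsets = c(-half, rep(0, length(spec$mode_sds) - 1)),
                           label = "apo", seed_offset = 0L)
  holo <- generate_ensemble(spec, mode_offsets = c(half, rep(0, length(spec$mode_sds) - 1)),
                            label = "holo", seed_offset = 10L)
  switches <- spec$planted_hbond_switches
  if (is.null(switches)) {
    # pick backbone donor/acceptor pairs whose N...O distance stays within
    # bonding range in >= 70% of the members of BOTH states, so the
    # planted switch (not the mode displacement) drives the contrast
    cand <- candidate_switch_pairs(apo, holo, min_frac = 0.7)
    # one switch per donor amide: a single N-H cannot be pointed at two
    # acceptors at once
    cand <- cand[!duplicated(cand$donor_resno), , drop = FALSE]
    n_sw <- min(2L, nrow(cand))
    switches <- if (n_sw > 0L)
      data.frame(donor_resno = cand$donor_resno[seq_len(n_sw)],
                 acceptor_resno = cand$acceptor_resno[seq_len(n_sw)],
                 state = rep_len(c("apo", "holo"), n_sw),
                 stringsAsFactors = FALSE)
    else
      data.frame(donor_resno = integer(), acceptor_resno = integer(),
                 state = character(), stringsAsFactors = FALSE)
  }
  for (i in seq_len(nrow(switches))) {
    dn <- switches$donor_resno[i]
    an <- switches$acceptor_resno[i]
    if (switches$state[i] == "holo") {
      apo <- switch_hbond(apo, dn, an, on = FALSE)
      holo <- switch_hbond(holo, dn, an, on = TRUE)
    } else {
      apo <- switch_hbond(apo, dn, an, on = TRUE)
      holo <- switch_hbond(holo, dn, an, on = FALSE)
    }
  }
  list(apo = apo, holo = holo, switches = switches)
}

# Backbone N(i)...O(j) pairs (|i-j| >= 3) whose distance stays in the
# bondable window [2.5, 3.4] A in at least min_frac of the members of
# both ensembles, best first.
candidate_switch_pairs <- function(apo, holo, min_frac = 0.7) {
  atoms <- apo$atoms
  res <- sort(unique(atoms$resno))
  iN <- vapply(res, function(r) find_atom(atoms, r, "N"), integer(1))
  iO <- vapply(res, function(r) find_atom(atoms, r, "O"), integer(1))
  frac_close <- function(ens, i, j) {
    d <- sqrt(rowSums((ens$xyz[, xyz_cols(iN[i]), drop = FALSE] -
                         ens$xyz[, xyz_cols(iO[j]), drop = FALSE])^2))
    mean(d >= 2.5 & d <= 3.4)
  }
  rows <- list()
  for (i in seq_along(res)) {
    for (j in seq_along(res)) {
      if (abs(i - j) < 3L || is.na(iN[i]) || is.na(iO[j])) next
      fa <- frac_close(apo, i, j)
      if (fa < min_frac) next
      fh <- frac_close(holo, i, j)
      if (fh < min_frac) next
      rows[[length(rows) + 1L]] <- data.frame(
        donor_resno = res[i], acceptor_resno = res[j], min_frac = min(fa, fh))
    }
  }
  if (length(rows) == 0L)
    return(data.frame(donor_resno = integer(), acceptor_resno = integer(),
                      min_frac = numeric()))
  out <- do.call(rbind, rows)
  out[order(-out$min_frac, out$donor_resno), ]
}

# Plant or break the amide H-bond donor_resno N-H -> acceptor_resno O in
# every member. on = TRUE points the hydrogen straight at the acceptor
# whenever the N...O distance permits a bond (2.2-3.5 A); on = FALSE (and
# out-of-range members) swings it to point away. The hydrogen stays
# covalently bonded to its nitrogen.
switch_hbond <- function(ensemble, donor_resno, acceptor_resno, on) {
  iH <- find_atom(ensemble$atoms, donor_resno, "H")
  iN <- find_atom(ensemble$atoms, donor_resno, "N")
  iO <- find_atom(ensemble$atoms, acceptor_resno, "O")
  if (anyNA(c(iH, iN, iO)))
    stop("hydrogen-bond switch references atoms absent from the topology")
  hc <- xyz_cols(iH); ncl <- xyz_cols(iN); oc <- xyz_cols(iO)
  for (m in seq_len(n_members(ensemble))) {
    N <- ensemble$xyz[m, ncl]
    O <- ensemble$xyz[m, oc]
    d <- vec_norm(O - N)
    dir <- if (on && d >= 2.2 && d <= 3.5) unit(O - N) else unit(N - O)
    ensemble$xyz[m, hc] <- N + 1.01 * dir
  }
  ensemble
}

#' Plant a hidden excited-state conformer in a decoy pool
#'
#' Builds a conformer pool of \code{spec$n_decoys} independent draws from
#' the generative model plus one planted conformer displaced by
#' \code{spec$hidden_displacement} along mode \code{spec$hidden_mode}
#' (appended last), and emits the matching experimental observable: the
#' planted conformer's predicted |15N shift difference| profile relative
#' to the apo reference ensemble, replicated over the configured
#' temperatures with independent multiplicative noise
#' \code{(1 + N(0, dw_noise^2))} and truncated at zero, with an
#' independent random residue subset retained per temperature
#' (\code{dw_residue_fraction}). Draws come from a stream seeded with
#' \code{spec$seed + 2}.
#'
#' @param apo_ensemble the apo reference [conf_ensemble()].
#' @param spec a [generator_spec()].
#' @param predictor shift predictor used both to build the emitted
#'   profile and (by the analyst) to score candidates.
#' @return list with \code{pool} (a [conf_ensemble()]),
#'   \code{delta_omega} (a [delta_omega_set()]) and \code{planted_id}
#'   (index of the planted conformer in the pool).
#' @export
plant_hidden_state <- function(apo_ensemble, spec,
                               predictor = shift_predictor_surrogate()) {
  topo <- make_topology(spec$n_residues)
  modes <- make_mode_vectors(topo, length(spec$mode_sds))
  decoy_spec <- spec
  decoy_spec$n_members <- spec$n_decoys
  decoys <- generate_ensemble(decoy_spec, label = "pool", seed_offset = 20L)
  set.seed(spec$seed + 2L)
  planted_xyz <- topo$xyz[1, ] +
    spec$hidden_displacement * modes[, spec$hidden_mode] +
    stats::rnorm(ncol(topo$xyz), sd = spec$noise_sd)
  pool <- conf_ensemble(topo$atoms,
                        rbind(decoys$xyz, round(planted_xyz, 3)),
                        label = "pool")
  planted_id <- n_members(pool)

  planted_only <- ensemble_subset(pool, members = planted_id)
  profile <- predicted_delta(planted_only, apo_ensemble, predictor)[1, ]
  resnos <- as.integer(names(profile))
  keep_n <- max(3L, round(spec$dw_residue_fraction * length(resnos)))
  rows <- lapply(spec$dw_temperatures, function(tt) {
    keep <- sort(sample(seq_along(resnos), keep_n))
    vals <- profile[keep] * (1 + stats::rnorm(keep_n, sd = spec$dw_noise))
    data.frame(resno = resnos[keep], temperature = tt,
               delta_omega = pmax(vals, 0))
  })
  dw <- do.call(rbind, rows)
  list(pool = pool,
       delta_omega = delta_omega_set(dw$resno, dw$temperature, dw$delta_omega),
       planted_id = planted_id)
}
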