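# Fixture builders and independent brute-force oracles.

# Minimal ensemble from a named coordinate list: atoms is a data.frame
# (resno, resid, elety), coords a list of n_atoms x 3 matrices.
ens_from_coords <- function(atoms, coords, ...) {
  xyz <- do.call(rbind, lapply(coords, ensdyn:::mat_to_xyz))
  conf_ensemble(atoms, xyz, ...)
}

# Two-atom ensemble: one inter-residue H-H pair at the given distances
# (one member per distance).
pair_ensemble <- function(distances) {
  atoms <- data.frame(resno = c(1L, 2L), resid = "ALA", elety = c("H", "H"),
                      chain = "A")
  coords <- lapply(distances, function(d) rbind(c(0, 0, 0), c(d, 0, 0)))
  ens_from_coords(atoms, coords)
}

single_restraint <- function(resno_a = 1L, atoms_a = "H", resno_b = 2L,
                             atoms_b = "H", upper = 5, bin = NA_real_) {
  d <- data.frame(resno_a = resno_a, resid_a = "ALA",
                  group_a = I(list(atoms_a)),
                  resno_b = resno_b, resid_b = "ALA",
                  group_b = I(list(atoms_b)),
                  upper = upper, bin = bin, id = 1L,
                  stringsAsFactors = FALSE)
  class(d) <- c("noe_restraints", "data.frame")
  d
}

# Apply an independent random rigid-body motion to every member.
rigid_shuffle <- function(ens, seed = 1) {
  set.seed(seed)
  for (m in seq_len(n_members(ens))) {
    R <- ensdyn:::random_rotation()
    t <- rnorm(3, sd = 10)
    cm <- member_coords(ens, m)
    ens$xyz[m, ] <- ensdyn:::mat_to_xyz(sweep(cm %*% R, 2, t, `+`))
  }
  ens
}

# --- brute-force oracles ---------------------------------------------------

# r^-6 effective distance by explicit loops over members and cross pairs.
bf_effective_distance <- function(ens, idx_a, idx_b) {
  s_members <- numeric(0)
  for (m in seq_len(n_members(ens))) {
    cm <- member_coords(ens, m)
    s <- 0
    for (i in idx_a) for (j in idx_b) {
      r <- sqrt(sum((cm[i, ] - cm[j, ])^2))
      s <- s + r^-6
    }
    s_members <- c(s_members, s)
  }
  mean(s_members)^(-1 / 6)
}

# Hydrogen-bond occupancy of one donor/acceptor pair by explicit loops,
# re-deriving the geometry from scratch.
bf_occupancy <- function(ens, donor_resno, donor_atom, acceptor_resno,
                         acceptor_atom, crit = hbond_criteria()) {
  atoms <- ens$atoms
  hits <- 0
  for (m in seq_len(n_members(ens))) {
    cm <- member_coords(ens, m)
    id <- which(atoms$resno == donor_resno & atoms$elety == donor_atom)
    ia <- which(atoms$resno == acceptor_resno & atoms$elety == acceptor_atom)
    found <- FALSE
    for (ih in which(grepl("^[0-9]?H", atoms$elety))) {
      # hydrogen must belong to this donor: nearest N/O and covalent
      d_don <- sqrt(sum((cm[ih, ] - cm[id, ])^2))
      if (d_don > crit$covalent_max) next
      elem <- substr(sub("^[0-9]", "", atoms$elety), 1, 1)
      others <- which(elem %in% c("N", "O"))
      dmin <- min(sqrt(rowSums(sweep(cm[others, , drop = FALSE], 2, cm[ih, ])^2)))
      if (d_don > dmin + 1e-12) next
      dha <- sqrt(sum((cm[ih, ] - cm[ia, ])^2))
      daa <- sqrt(sum((cm[id, ] - cm[ia, ])^2))
      v1 <- cm[id, ] - cm[ih, ]
      v2 <- cm[ia, ] - cm[ih, ]
      ang <- acos(sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))) * 180 / pi
      if (dha <= crit$h_acceptor_max && daa <= crit$donor_acceptor_max &&
          ang >= crit$angle_min) {
        found <- TRUE
        break
      }
    }
    if (found) hits <- hits + 1
  }
  hits / n_members(ens)
}

# Mean-over-references |shift difference| profile by explicit double loop.
bf_predicted_delta <- function(pool, reference, predictor, nucleus = "N") {
  n_pool <- n_members(pool)
  n_ref <- n_members(reference)
  prof <- function(ens, m) {
    t <- predictor(ens, m)
    t <- t[t$nucleus == nucleus, ]
    setNames(t$shift, t$resno)
  }
  p1 <- prof(pool, 1)
  out <- matrix(0, n_pool, length(p1), dimnames = list(NULL, names(p1)))
  for (m in seq_len(n_pool)) {
    pm <- prof(pool, m)
    for (res in names(p1)) {
      acc <- 0
      for (r in seq_len(n_ref)) {
        pr <- prof(reference, r)
        acc <- acc + abs(pm[[res]] - pr[[res]])
      }
      out[m, res] <- acc / n_ref
    }
  }
  out
}

# A small two-model PDB file with a leucine (stereo methyls), a glycine
# and an alanine, written from code.
write_tiny_pdb <- function(path, n_models = 2L, jitter = 0) {
  atom_line <- function(serial, name, resid, resno, x, y, z) {
    nm <- if (nchar(name) < 4) sprintf(" %-3s", name) else name
    sprintf("ATOM  %5d %4s %3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00",
            serial, nm, resid, resno, x, y, z)
  }
  base <- list(
    list("N", "LEU", 23L), list("H", "LEU", 23L), list("CA", "LEU", 23L),
    list("C", "LEU", 23L), list("O", "LEU", 23L), list("CB", "LEU", 23L),
    list("HB2", "LEU", 23L), list("HB3", "LEU", 23L), list("CG", "LEU", 23L),
    list("HD11", "LEU", 23L), list("HD12", "LEU", 23L), list("HD13", "LEU", 23L),
    list("HD21", "LEU", 23L), list("HD22", "LEU", 23L), list("HD23", "LEU", 23L),
    list("N", "GLY", 24L), list("H", "GLY", 24L), list("CA", "GLY", 24L),
    list("HA2", "GLY", 24L), list("HA3", "GLY", 24L), list("C", "GLY", 24L),
    list("O", "GLY", 24L),
    list("N", "ALA", 25L), list("H", "ALA", 25L), list("CA", "ALA", 25L),
    list("HA", "ALA", 25L), list("C", "ALA", 25L), list("O", "ALA", 25L)
  )
  set.seed(99)
  coords <- matrix(rnorm(3 * length(base), sd = 3), ncol = 3)
  lines <- character(0)
  for (mdl in seq_len(n_models)) {
    lines <- c(lines, sprintf("MODEL     %4d", mdl))
    off <- (mdl - 1) * jitter
    for (i in seq_along(base)) {
      b <- base[[i]]
      lines <- c(lines, atom_line(i, b[[1]], b[[2]], b[[3]],
                                  coords[i, 1] + off, coords[i, 2],
                                  coords[i, 3]))
    }
    lines <- c(lines, "ENDMDL")
  }
  writeLines(c(lines, "END"), path)
  path
}
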