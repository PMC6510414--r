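# Simplified three-state secondary structure assignment from backbone
# hydrogen bonding, for per-conformer ensemble maps.

#' Electrostatic backbone hydrogen-bond energy
#'
#' The classic point-charge model of the backbone C=O...H-N interaction:
#' \deqn{E = 0.084 \cdot 332 \cdot (1/r_{ON} + 1/r_{CH} - 1/r_{OH} - 1/r_{CN})}
#' with distances in Angstrom and E in kcal/mol. A pair is considered
#' hydrogen bonded when \eqn{E < -0.5} kcal/mol.
#'
#' @param r_on,r_ch,r_oh,r_cn distances O...N, C...H, O...H, C...N between
#'   the acceptor carbonyl (C, O) and donor amide (N, H) atoms, Angstrom.
#' @return energy in kcal/mol.
#' @export
backbone_hbond_energy <- function(r_on, r_ch, r_oh, r_cn) {
  0.084 * 332 * (1 / r_on + 1 / r_ch - 1 / r_oh - 1 / r_cn)
}

# Residue-by-residue backbone H-bond matrix for one member:
# bonded[i, j] is TRUE when the carbonyl of residue i accepts a hydrogen
# bond from the amide N-H of residue j (E < cutoff). Sequence neighbors
# are excluded.
bb_hbond_matrix <- function(ensemble, member, cutoff = -0.5) {
  atoms <- ensemble$atoms
  cm <- member_coords(ensemble, member)
  res <- sort(unique(atoms$resno))
  nr <- length(res)
  get <- function(r, name) {
    i <- find_atom(atoms, r, name)
    if (is.na(i)) NULL else cm[i, ]
  }
  Cp <- lapply(res, get, name = "C")
  O <- lapply(res, get, name = "O")
  N <- lapply(res, get, name = "N")
  H <- lapply(res, get, name = "H")
  bonded <- matrix(FALSE, nr, nr)
  for (i in seq_len(nr)) {
    if (is.null(Cp[[i]]) || is.null(O[[i]])) next
    for (j in seq_len(nr)) {
      if (abs(i - j) <= 1L) next
      if (is.null(N[[j]]) || is.null(H[[j]])) next
      r_on <- vec_norm(O[[i]] - N[[j]])
      if (r_on > 5.2) next  # beyond plausible H-bond range; E ~ 0
      e <- backbone_hbond_energy(r_on,
                                 vec_norm(Cp[[i]] - H[[j]]),
                                 vec_norm(O[[i]] - H[[j]]),
                                 vec_norm(Cp[[i]] - N[[j]]))
      bonded[i, j] <- e < cutoff
    }
  }
  dimnames(bonded) <- list(res, res)
  bonded
}

#' Assign helix/strand/coil secondary structure to one conformer
#'
#' A simplified discrete assignment built on the backbone hydrogen-bond
#' pattern: residues covered by repeating i -> i+4 hydrogen bonds (two
#' consecutive helical turns, hence segments of at least 4 residues)
#' become \code{H}; residues participating in inter-strand hydrogen-bond
#' bridges (parallel or antiparallel ladders) over at least 2 consecutive
#' positions become \code{E}; everything else is \code{C}. 3-10 and pi
#' helices are folded into \code{H}; isolated bridges into \code{C}.
#' Chains are split at breaks (consecutive Calpha atoms more than 4.5
#' Angstrom apart) and patterns never span a break.
#'
#' @param ensemble a [conf_ensemble()] with full backbone (N, H, CA, C, O).
#' @param member member index.
#' @return named character vector (residue number -> \code{"H"},
#'   \code{"E"} or \code{"C"}).
#' @export
assign_ss <- function(ensemble, member = 1L) {
  atoms <- ensemble$atoms
  res <- sort(unique(atoms$resno))
  nr <- length(res)
  ss <- rep("C", nr)
  if (nr >= 3L) {
    cm <- member_coords(ensemble, member)
    ca <- vapply(res, function(r) find_atom(atoms, r, "CA"), integer(1))
    # chain segments split at CA-CA breaks
    seg <- cumsum(c(1L, vapply(seq_len(nr - 1L), function(i) {
      if (is.na(ca[i]) || is.na(ca[i + 1])) return(1L)
      as.integer(vec_norm(cm[ca[i], ] - cm[ca[i + 1], ]) > 4.5)
    }, integer(1))))
    bonded <- bb_hbond_matrix(ensemble, member)

    # helices: turn(i) = CO(i) accepts from NH(i+4); two consecutive
    # turns mark residues i..i+3 helical
    turn <- rep(FALSE, nr)
    for (i in seq_len(nr)) {
      if (i + 4L <= nr && seg[i] == seg[i + 4L] && bonded[i, i + 4L])
        turn[i] <- TRUE
    }
    helix <- rep(FALSE, nr)
    for (i in 2:nr) {
      if (turn[i - 1L] && turn[i] && i + 3L <= nr)
        helix[i:(i + 3L)] <- TRUE
    }

    # strands: DSSP-style bridges between non-near residues
    bridge <- rep(FALSE, nr)
    for (i in seq_len(nr)) {
      for (j in seq_len(nr)) {
        if (abs(i - j) < 3L) next
        anti <- (bonded[i, j] && bonded[j, i]) ||
          (i > 1L && j < nr && i + 1L <= nr && j - 1L >= 1L &&
             bonded[i - 1L, j + 1L] && bonded[j - 1L, i + 1L])
        par <- (i > 1L && i + 1L <= nr && bonded[i - 1L, j] && bonded[j, i + 1L]) ||
          (j > 1L && j + 1L <= nr && bonded[j - 1L, i] && bonded[i, j + 1L])
        if (anti || par) {
          bridge[i] <- TRUE
          bridge[j] <- TRUE
        }
      }
    }
    # ladders: keep only runs of >= 2 consecutive bridged residues within
    # one segment, and do not override helix
    strand <- rep(FALSE, nr)
    i <- 1L
    while (i <= nr) {
      if (bridge[i]) {
        j <- i
        while (j < nr && bridge[j + 1L] && seg[j + 1L] == seg[j]) j <- j + 1L
        if (j - i + 1L >= 2L) strand[i:j] <- TRUE
        i <- j + 1L
      } else i <- i + 1L
    }
    ss[helix] <- "H"
    ss[strand & !helix] <- "E"
  }
  stats::setNames(ss, res)
}

#' Secondary structure map of a whole ensemble
#'
#' @param ensemble a [conf_ensemble()].
#' @return object of class \code{ss_map}: character matrix, one row per
#'   member (in ensemble order), one column per residue, entries
#'   \code{"H"}, \code{"E"} or \code{"C"}.
#' @export
ensemble_ss_map <- function(ensemble) {
  nm <- n_members(ensemble)
  if (nm < 1L) stop("empty ensemble")
  rows <- lapply(seq_len(nm), function(m) assign_ss(ensemble, m))
  M <- do.call(rbind, rows)
  rownames(M) <- ensemble$model_ids
  class(M) <- c("ss_map", class(M))
  M
}

#' @export
print.ss_map <- function(x, ...) {
  cat("ss_map:", nrow(x), "members x", ncol(x), "residues\n")
  for (i in seq_len(min(nrow(x), 20L)))
    cat(paste(x[i, ], collapse = ""), "\n")
  if (nrow(x) > 20L) cat("...\n")
  invisible(x)
}

#' Per-member secondary structure content
#'
#' @param map an \code{ss_map}.
#' @return data.frame with per-member fractions of helix, strand and coil
#'   (each row sums to 1).
#' @export
ss_content <- function(map) {
  data.frame(member = rownames(map),
             helix = rowMeans(unclass(map) == "H"),
             strand = rowMeans(unclass(map) == "E"),
             coil = rowMeans(unclass(map) == "C"))
}

#' Write a secondary structure map
#'
#' Plain-text form: one row per member, one character per residue;
#' optionally also a long-format CSV.
#'
#' @param map an \code{ss_map}.
#' @param path output text file.
#' @param csv_path optional CSV output (member, resno, ss).
#' @return \code{path}, invisibly.
#' @export
write_ss_map <- function(map, path, csv_path = NULL) {
  writeLines(apply(unclass(map), 1, paste, collapse = ""), path)
  if (!is.null(csv_path)) {
    d <- expand.grid(member = rownames(map), resno = colnames(map),
                     stringsAsFactors = FALSE)
    d$ss <- as.vector(unclass(map))
    utils::write.csv(d, csv_path, row.names = FALSE)
  }
  invisible(path)
}
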