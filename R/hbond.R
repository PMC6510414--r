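# Distance-angle hydrogen bond detection, per-ensemble occupancies and
# apo/holo occupancy differencing.

#' Hydrogen bond detection criteria
#'
#' @param h_acceptor_max maximum H...acceptor distance in Angstrom.
#' @param angle_min minimum donor-H...acceptor angle in degrees.
#' @param donor_acceptor_max maximum donor...acceptor heavy-atom distance
#'   in Angstrom.
#' @param covalent_max maximum donor-H covalent distance in Angstrom used
#'   to attach hydrogens to their donor heavy atom.
#' @return list of criteria for [detect_hbonds()].
#' @export
hbond_criteria <- function(h_acceptor_max = 2.5, angle_min = 120,
                           donor_acceptor_max = 3.5, covalent_max = 1.2) {
  list(h_acceptor_max = h_acceptor_max, angle_min = angle_min,
       donor_acceptor_max = donor_acceptor_max, covalent_max = covalent_max)
}

#' Detect hydrogen bonds in one conformer
#'
#' Donors are N or O heavy atoms with a covalently attached hydrogen
#' (within \code{covalent_max}); acceptors are any other N or O atom. A
#' donor-H-acceptor triple is a hydrogen bond when all criteria hold:
#' H...A <= \code{h_acceptor_max}, D-H...A angle >= \code{angle_min} and
#' D...A <= \code{donor_acceptor_max}.
#'
#' @param ensemble a [conf_ensemble()] with explicit hydrogens.
#' @param member member index.
#' @param criteria a [hbond_criteria()] list.
#' @return data.frame with one row per bond: donor, hydrogen and acceptor
#'   residue numbers and atom names, plus the geometric measures.
#' @export
detect_hbonds <- function(ensemble, member = 1L, criteria = hbond_criteria()) {
  require_hydrogens(ensemble, "detect_hbonds")
  atoms <- ensemble$atoms
  cm <- member_coords(ensemble, member)
  elem <- substr(sub("^[0-9]", "", atoms$elety), 1, 1)
  heavyNO <- which(elem %in% c("N", "O"))
  hyd <- which(is_hydrogen_name(atoms$elety))
  if (length(heavyNO) == 0L || length(hyd) == 0L)
    return(empty_hbond_table())
  # attach each hydrogen to its nearest N/O within covalent range
  d_h_heavy <- outer(seq_along(hyd), seq_along(heavyNO), function(i, j)
    sqrt(rowSums((cm[hyd[i], , drop = FALSE] - cm[heavyNO[j], , drop = FALSE])^2)))
  nearest <- apply(d_h_heavy, 1, which.min)
  cov_ok <- d_h_heavy[cbind(seq_along(hyd), nearest)] <= criteria$covalent_max
  hyd <- hyd[cov_ok]
  donors <- heavyNO[nearest[cov_ok]]
  if (length(hyd) == 0L) return(empty_hbond_table())
  rows <- list()
  for (k in seq_along(hyd)) {
    ih <- hyd[k]; id <- donors[k]
    acc <- heavyNO[heavyNO != id]
    dv <- cm[acc, , drop = FALSE]
    dha <- sqrt(rowSums(sweep(dv, 2, cm[ih, ])^2))
    daa <- sqrt(rowSums(sweep(dv, 2, cm[id, ])^2))
    cand <- which(dha <= criteria$h_acceptor_max &
                  daa <= criteria$donor_acceptor_max)
    for (a in cand) {
      ia <- acc[a]
      ang <- angle_deg(cm[id, ], cm[ih, ], cm[ia, ])
      if (ang >= criteria$angle_min) {
        rows[[length(rows) + 1L]] <- data.frame(
          donor_resno = atoms$resno[id], donor_atom = atoms$elety[id],
          hydrogen = atoms$elety[ih],
          acceptor_resno = atoms$resno[ia], acceptor_atom = atoms$elety[ia],
          h_a_dist = dha[a], d_a_dist = daa[a], angle = ang,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0L) return(empty_hbond_table())
  do.call(rbind, rows)
}

empty_hbond_table <- function() {
  data.frame(donor_resno = integer(), donor_atom = character(),
             hydrogen = character(), acceptor_resno = integer(),
             acceptor_atom = character(), h_a_dist = numeric(),
             d_a_dist = numeric(), angle = numeric(),
             stringsAsFactors = FALSE)
}

#' Hydrogen-bond occupancies over an ensemble
#'
#' For each donor-heavy-atom/acceptor pair, the fraction of members in
#' which any hydrogen of that donor satisfies the criteria. Pairs never
#' observed are absent from the table (sparse contract), not listed with
#' zero occupancy.
#'
#' @inheritParams detect_hbonds
#' @return object of class \code{occupancy_table}: data.frame with
#'   \code{donor_resno}, \code{donor_atom}, \code{acceptor_resno},
#'   \code{acceptor_atom}, \code{occupancy}; attribute \code{n_members}.
#' @export
hbond_occupancy <- function(ensemble, criteria = hbond_criteria()) {
  nm <- n_members(ensemble)
  keys <- character(0)
  counts <- integer(0)
  store <- new.env(parent = emptyenv())
  for (m in seq_len(nm)) {
    hb <- detect_hbonds(ensemble, m, criteria)
    if (nrow(hb) == 0L) next
    k <- unique(paste(hb$donor_resno, hb$donor_atom, hb$acceptor_resno,
                      hb$acceptor_atom, sep = "|"))
    for (kk in k) {
      store[[kk]] <- (store[[kk]] %||% 0L) + 1L
    }
  }
  keys <- ls(store)
  if (length(keys) == 0L) {
    out <- data.frame(donor_resno = integer(), donor_atom = character(),
                      acceptor_resno = integer(), acceptor_atom = character(),
                      occupancy = numeric(), stringsAsFactors = FALSE)
  } else {
    parts <- do.call(rbind, strsplit(keys, "|", fixed = TRUE))
    out <- data.frame(donor_resno = as.integer(parts[, 1]),
                      donor_atom = parts[, 2],
                      acceptor_resno = as.integer(parts[, 3]),
                      acceptor_atom = parts[, 4],
                      occupancy = vapply(keys, function(k) store[[k]],
                                         integer(1)) / nm,
                      stringsAsFactors = FALSE)
    out <- out[order(out$donor_resno, out$donor_atom, out$acceptor_resno,
                     out$acceptor_atom), ]
    rownames(out) <- NULL
  }
  attr(out, "n_members") <- nm
  class(out) <- c("occupancy_table", "data.frame")
  out
}

#' Hydrogen bonds changing most between two states
#'
#' Differences two occupancy tables (apo and holo) and lists bonds whose
#' occupancy changes by at least \code{min_delta}. Bonds are labeled
#' \code{"apo"} or \code{"holo"} when the occupancy difference reaches
#' \code{mostly_cutoff}, and \code{"mostly apo"} / \code{"mostly holo"}
#' for intermediate margins. Output is sorted by donor residue number.
#'
#' @param occ_apo,occ_holo \code{occupancy_table} objects from comparable
#'   topologies.
#' @param min_delta minimum |occupancy difference| to report.
#' @param mostly_cutoff margin separating the plain state labels from the
#'   "mostly" labels.
#' @return data.frame with the bond key columns, \code{occ_apo},
#'   \code{occ_holo}, \code{delta} (holo - apo) and \code{state}.
#' @export
state_difference <- function(occ_apo, occ_holo, min_delta = 0.5,
                             mostly_cutoff = 0.75) {
  key <- function(d) paste(d$donor_resno, d$donor_atom, d$acceptor_resno,
                           d$acceptor_atom, sep = "|")
  all_keys <- union(key(occ_apo), key(occ_holo))
  oa <- unname(stats::setNames(occ_apo$occupancy, key(occ_apo))[all_keys])
  oh <- unname(stats::setNames(occ_holo$occupancy, key(occ_holo))[all_keys])
  oa[is.na(oa)] <- 0
  oh[is.na(oh)] <- 0
  delta <- oh - oa
  keep <- abs(delta) >= min_delta
  if (!any(keep))
    return(data.frame(donor_resno = integer(), donor_atom = character(),
                      acceptor_resno = integer(), acceptor_atom = character(),
                      occ_apo = numeric(), occ_holo = numeric(),
                      delta = numeric(), state = character(),
                      stringsAsFactors = FALSE))
  parts <- do.call(rbind, strsplit(all_keys[keep], "|", fixed = TRUE))
  state <- ifelse(delta[keep] > 0,
                  ifelse(abs(delta[keep]) >= mostly_cutoff, "holo", "mostly holo"),
                  ifelse(abs(delta[keep]) >= mostly_cutoff, "apo", "mostly apo"))
  out <- data.frame(donor_resno = as.integer(parts[, 1]),
                    donor_atom = parts[, 2],
                    acceptor_resno = as.integer(parts[, 3]),
                    acceptor_atom = parts[, 4],
                    occ_apo = as.numeric(oa[keep]),
                    occ_holo = as.numeric(oh[keep]),
                    delta = as.numeric(delta[keep]),
                    state = state, stringsAsFactors = FALSE)
  out <- out[order(out$donor_resno, out$donor_atom, out$acceptor_resno), ]
  rownames(out) <- NULL
  out
}

#' Write an occupancy table as CSV
#'
#' Bond keys follow the convention
#' \code{a_<donorRes>_<donorAtom>_a_<acceptorRes>_<acceptorAtom>}.
#'
#' @param x an \code{occupancy_table}.
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_occupancy_csv <- function(x, path) {
  d <- data.frame(
    bond = sprintf("a_%d_%s_a_%d_%s", x$donor_resno, x$donor_atom,
                   x$acceptor_resno, x$acceptor_atom),
    occupancy = x$occupancy,
    n_members = attr(x, "n_members"))
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}
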