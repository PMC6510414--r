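# Ensemble-averaged chemical shift evaluation with a pluggable
# structure -> shift predictor.

#' Backbone phi/psi torsions of one conformer
#'
#' @param ensemble a [conf_ensemble()] with N, CA, C backbone atoms.
#' @param member member index.
#' @return data.frame with \code{resno}, \code{phi}, \code{psi} in degrees
#'   (\code{NA} at chain termini).
#' @export
backbone_torsions <- function(ensemble, member = 1L) {
  atoms <- ensemble$atoms
  cm <- member_coords(ensemble, member)
  resnos <- sort(unique(atoms$resno))
  at <- function(r, name) {
    i <- find_atom(atoms, r, name)
    if (is.na(i)) NULL else cm[i, ]
  }
  phi <- psi <- rep(NA_real_, length(resnos))
  for (k in seq_along(resnos)) {
    r <- resnos[k]
    N <- at(r, "N"); CA <- at(r, "CA"); C <- at(r, "C")
    if (is.null(N) || is.null(CA) || is.null(C)) next
    Cprev <- if (k > 1) at(resnos[k - 1], "C") else NULL
    Nnext <- if (k < length(resnos)) at(resnos[k + 1], "N") else NULL
    if (!is.null(Cprev)) phi[k] <- dihedral(Cprev, N, CA, C)
    if (!is.null(Nnext)) psi[k] <- dihedral(N, CA, C, Nnext)
  }
  data.frame(resno = resnos, phi = phi, psi = psi)
}

#' Deterministic surrogate chemical shift predictor
#'
#' Returns a predictor closure mapping one conformer to a [shift_table()]
#' for amide \code{N} and \code{H}. The surrogate is a fixed linear map
#' from local backbone geometry -- the phi/psi dihedrals and Calpha
#' neighbor distances d(CA(i-1), CA(i+1)) and d(CA(i), CA(i+2)) -- to
#' shifts, with frozen coefficients chosen to span realistic amide shift
#' ranges (~105-130 ppm for 15N, ~7-9.5 ppm for 1H). It is deterministic
#' and bit-reproducible: the same conformer always yields the same shifts.
#' It is a structural sensitivity probe for pipeline testing, not an
#' empirical predictor; swap in the output of a real predictor via
#' [read_shiftx_table()] for production use.
#'
#' @return a function \code{(ensemble, member)} returning a
#'   [shift_table()].
#' @export
shift_predictor_surrogate <- function() {
  function(ensemble, member = 1L) {
    tor <- backbone_torsions(ensemble, member)
    atoms <- ensemble$atoms
    cm <- member_coords(ensemble, member)
    resnos <- tor$resno
    ca <- vapply(resnos, function(r) find_atom(atoms, r, "CA"), integer(1))
    d_flank <- rep(0, length(resnos))   # d(CA(i-1), CA(i+1)) - 5.4
    d_next2 <- rep(0, length(resnos))   # d(CA(i), CA(i+2)) - 6.0
    for (k in seq_along(resnos)) {
      if (k > 1 && k < length(resnos) && !is.na(ca[k - 1]) && !is.na(ca[k + 1]))
        d_flank[k] <- vec_norm(cm[ca[k - 1], ] - cm[ca[k + 1], ]) - 5.4
      if (k <= length(resnos) - 2 && !is.na(ca[k]) && !is.na(ca[k + 2]))
        d_next2[k] <- vec_norm(cm[ca[k], ] - cm[ca[k + 2], ]) - 6.0
    }
    rad <- pi / 180
    phi <- ifelse(is.na(tor$phi), -120, tor$phi) * rad
    psi <- ifelse(is.na(tor$psi), 130, tor$psi) * rad
    n_shift <- 118.0 + 4.0 * sin(phi) + 3.0 * cos(psi) + 0.8 * d_flank
    h_shift <- 8.30 + 0.60 * cos(phi) + 0.40 * sin(psi) + 0.15 * d_next2
    shift_table(rep(resnos, 2), rep(c("N", "H"), each = length(resnos)),
                c(n_shift, h_shift))
  }
}

#' Ensemble-averaged predicted chemical shifts
#'
#' Applies the predictor to every member and averages arithmetically per
#' (residue, nucleus).
#'
#' @param ensemble a [conf_ensemble()].
#' @param predictor a function \code{(ensemble, member)} returning a
#'   [shift_table()], e.g. [shift_predictor_surrogate()].
#' @return a [shift_table()] of mean shifts.
#' @export
ensemble_average_shifts <- function(ensemble, predictor) {
  tabs <- lapply(seq_len(n_members(ensemble)), function(m) {
    t <- tryCatch(predictor(ensemble, m), error = function(e)
      stop("predictor failed on member ", m, ": ", conditionMessage(e)))
    t
  })
  all <- do.call(rbind, tabs)
  agg <- stats::aggregate(shift ~ resno + nucleus, data = all, FUN = mean)
  shift_table(agg$resno, agg$nucleus, agg$shift)
}

#' Pearson correlation between two shift tables for one nucleus
#'
#' Entries are matched by residue number; residues missing from either
#' table are dropped pairwise, never imputed.
#'
#' @param experimental,calculated [shift_table()] objects.
#' @param nucleus nucleus label, e.g. \code{"N"} or \code{"H"}.
#' @return Pearson correlation over the shared entries.
#' @export
shift_correlation <- function(experimental, calculated, nucleus = "N") {
  e <- experimental[experimental$nucleus == nucleus, ]
  c2 <- calculated[calculated$nucleus == nucleus, ]
  shared <- intersect(e$resno, c2$resno)
  if (length(shared) < 3L)
    stop("need at least 3 shared (residue, nucleus) entries, got ",
         length(shared))
  stats::cor(e$shift[match(shared, e$resno)], c2$shift[match(shared, c2$resno)])
}

#' Ensemble shift correlation against experiment
#'
#' Convenience wrapper comparing experimental shifts with predictions over
#' an ensemble. \code{method = "ensemble_mean"} correlates the experimental
#' table with the ensemble-averaged predicted shifts (the default
#' convention); \code{method = "per_model_mean"} instead averages the
#' per-model correlations.
#'
#' @inheritParams ensemble_average_shifts
#' @param experimental a [shift_table()].
#' @param nucleus nucleus label.
#' @param method correlation convention, see Details.
#' @return a correlation coefficient.
#' @export
ensemble_shift_correlation <- function(ensemble, predictor, experimental,
                                       nucleus = "N",
                                       method = c("ensemble_mean", "per_model_mean")) {
  method <- match.arg(method)
  if (method == "ensemble_mean") {
    calc <- ensemble_average_shifts(ensemble, predictor)
    shift_correlation(experimental, calc, nucleus)
  } else {
    mean(vapply(seq_len(n_members(ensemble)), function(m)
      shift_correlation(experimental, predictor(ensemble, m), nucleus),
      numeric(1)))
  }
}

#' Read the tabular output of the SHIFTX family of shift predictors
#'
#' Adapter for the CSV output format (columns \code{NUM}, \code{RES},
#' \code{ATOMNAME}, \code{SHIFT}) written by structure-based shift
#' predictors; rows with nuclei outside the package vocabulary are
#' dropped. The predictor binary is never invoked from the library; run it
#' externally and read its output here.
#'
#' @param path CSV file path.
#' @return a [shift_table()].
#' @export
read_shiftx_table <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  names(d) <- toupper(names(d))
  need <- c("NUM", "ATOMNAME", "SHIFT")
  if (!all(need %in% names(d)))
    stop("predictor table must have columns NUM, ATOMNAME, SHIFT")
  keep <- d$ATOMNAME %in% c("N", "H", "HN", "CA", "CB", "C", "HA")
  d <- d[keep, ]
  nuc <- ifelse(d$ATOMNAME == "HN", "H", d$ATOMNAME)
  shift_table(d$NUM, nuc, d$SHIFT)
}
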