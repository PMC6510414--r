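#' Conformer ensembles
#'
#' A \code{conf_ensemble} is an ordered set of conformers (models) sharing a
#' single topology. Coordinates are stored bio3d-style as an
#' \code{n_members x 3 n_atoms} matrix whose columns are grouped
#' \code{(x, y, z)} per atom, alongside an atom table identifying each column
#' triplet by author residue number, residue name and PDB atom name.
#'
#' @param atoms data.frame with columns \code{resno} (integer, author
#'   numbering), \code{resid} (3-letter residue code), \code{elety} (PDB atom
#'   name) and optionally \code{chain}.
#' @param xyz numeric matrix, one row per conformer, \code{3 * nrow(atoms)}
#'   columns; all coordinates finite, in Angstrom.
#' @param model_ids integer vector of model identifiers (defaults to
#'   \code{1:n}).
#' @param label free-text ensemble label.
#' @param temperature temperature in Kelvin, or \code{NA}.
#' @param sub_ids optional per-member sub-ensemble (replica) tags used by
#'   [ensemble_rmsd()].
#' @return An object of class \code{conf_ensemble}.
#' @export
conf_ensemble <- function(atoms, xyz, model_ids = NULL, label = "",
                          temperature = NA_real_, sub_ids = NULL) {
  stopifnot(is.data.frame(atoms), all(c("resno", "resid", "elety") %in% names(atoms)))
  if (!is.matrix(xyz)) xyz <- matrix(xyz, nrow = 1)
  if (ncol(xyz) != 3L * nrow(atoms))
    stop("xyz must have 3 columns per atom (got ", ncol(xyz), " for ",
         nrow(atoms), " atoms)")
  if (nrow(xyz) < 1L) stop("ensemble must contain at least one conformer")
  if (!all(is.finite(xyz))) stop("all coordinates must be finite")
  if (any(atoms$resno < 1L)) stop("residue numbers must be >= 1")
  if (!"chain" %in% names(atoms)) atoms$chain <- "A"
  key <- atom_key(atoms)
  if (anyDuplicated(key)) stop("duplicate atoms in topology: ",
                               paste(key[duplicated(key)][1], collapse = ", "))
  if (is.null(model_ids)) model_ids <- seq_len(nrow(xyz))
  if (!is.null(sub_ids) && length(sub_ids) != nrow(xyz))
    stop("sub_ids must have one entry per member")
  structure(list(atoms = atoms, xyz = unname(xyz), model_ids = as.integer(model_ids),
                 label = label, temperature = temperature, sub_ids = sub_ids),
            class = "conf_ensemble")
}

atom_key <- function(atoms) paste(atoms$chain, atoms$resno, atoms$elety, sep = "|")

#' @export
print.conf_ensemble <- function(x, ...) {
  cat("conf_ensemble:", n_members(x), "members,", n_atoms(x), "atoms,",
      length(unique(x$atoms$resno)), "residues")
  if (nzchar(x$label)) cat(" [", x$label, "]", sep = "")
  if (!is.na(x$temperature)) cat(" @", x$temperature, "K")
  cat("\n")
  invisible(x)
}

#' @rdname conf_ensemble
#' @param x a \code{conf_ensemble}.
#' @export
n_members <- function(x) nrow(x$xyz)

#' @rdname conf_ensemble
#' @export
n_atoms <- function(x) nrow(x$atoms)

#' Coordinates of one member as an n_atoms x 3 matrix
#'
#' @param x a \code{conf_ensemble}.
#' @param i member index (1-based, in ensemble order).
#' @return numeric matrix with one row per atom.
#' @export
member_coords <- function(x, i) {
  stopifnot(i >= 1, i <= n_members(x))
  xyz_to_mat(x$xyz[i, ])
}

#' Select atoms of an ensemble
#'
#' @param x a \code{conf_ensemble}.
#' @param selection either a character keyword (\code{"all"},
#'   \code{"calpha"}, \code{"backbone"} for N/CA/C, \code{"backbone_full"}
#'   for N/H/CA/C/O, \code{"heavy"}, \code{"hydrogen"}) or an integer vector
#'   of atom indices.
#' @return integer atom indices into \code{x$atoms}.
#' @export
atom_select <- function(x, selection = "all") {
  if (is.numeric(selection)) return(as.integer(selection))
  el <- x$atoms$elety
  idx <- switch(selection,
    all = seq_len(n_atoms(x)),
    calpha = which(el == "CA"),
    backbone = which(el %in% c("N", "CA", "C")),
    backbone_full = which(el %in% c("N", "H", "CA", "C", "O")),
    heavy = which(!is_hydrogen_name(el)),
    hydrogen = which(is_hydrogen_name(el)),
    stop("unknown selection keyword: ", selection)
  )
  if (length(idx) == 0L) stop("selection '", selection, "' matched no atoms")
  idx
}

is_hydrogen_name <- function(elety) {
  # PDB v3 hydrogen names start with H or a digit followed by H (e.g. 1HB)
  grepl("^[0-9]?H", elety)
}

# Columns of the xyz matrix covering the given atom indices.
xyz_cols <- function(atom_idx) {
  as.integer(t(outer(3L * (atom_idx - 1L), 1:3, `+`)))
}

#' Restrict an ensemble to a subset of atoms or members
#'
#' @param x a \code{conf_ensemble}.
#' @param atoms integer atom indices or a selection keyword for
#'   [atom_select()]; \code{NULL} keeps all atoms.
#' @param members integer member indices; \code{NULL} keeps all members.
#' @return a new \code{conf_ensemble}.
#' @export
ensemble_subset <- function(x, atoms = NULL, members = NULL) {
  ai <- if (is.null(atoms)) seq_len(n_atoms(x)) else atom_select(x, atoms)
  mi <- if (is.null(members)) seq_len(n_members(x)) else as.integer(members)
  conf_ensemble(x$atoms[ai, , drop = FALSE],
                x$xyz[mi, xyz_cols(ai), drop = FALSE],
                model_ids = x$model_ids[mi], label = x$label,
                temperature = x$temperature,
                sub_ids = if (!is.null(x$sub_ids)) x$sub_ids[mi])
}

#' Concatenate ensembles sharing one topology into a pooled ensemble
#'
#' Used to pool apo, holo and exploratory conformers ahead of a joint
#' principal component analysis. Members keep their original order;
#' \code{sub_ids} records the ensemble of origin.
#'
#' @param ... \code{conf_ensemble} objects with identical atom tables.
#' @param label label for the pooled ensemble.
#' @return a \code{conf_ensemble} whose \code{sub_ids} tags each member with
#'   the label (or position) of its source ensemble.
#' @export
pool_ensembles <- function(..., label = "pool") {
  xs <- list(...)
  stopifnot(length(xs) >= 1)
  ref <- atom_key(xs[[1]]$atoms)
  for (x in xs[-1]) {
    if (!identical(atom_key(x$atoms), ref))
      stop("ensembles must share an identical atom set to be pooled")
  }
  tags <- vapply(seq_along(xs), function(i) {
    if (nzchar(xs[[i]]$label)) xs[[i]]$label else paste0("set", i)
  }, character(1))
  conf_ensemble(xs[[1]]$atoms,
                do.call(rbind, lapply(xs, `[[`, "xyz")),
                model_ids = seq_len(sum(vapply(xs, n_members, 1L))),
                label = label,
                sub_ids = rep(tags, vapply(xs, n_members, 1L)))
}

# Indices of atoms of one residue, by atom name, NA when absent.
find_atom <- function(atoms, resno, elety) {
  i <- which(atoms$resno == resno & atoms$elety == elety)
  if (length(i) == 0L) NA_integer_ else i[1]
}
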