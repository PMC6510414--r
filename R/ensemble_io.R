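#' Read a multi-model PDB file into a conformer ensemble
#'
#' Each \code{MODEL}/\code{ENDMDL} block becomes one conformer, in file
#' order; a file without \code{MODEL} records is read as a single-member
#' ensemble. Author residue numbering is kept verbatim. Alternate locations
#' other than blank or \code{'A'} are discarded. When models do not share an
#' identical atom set, the atom tables are equalized by intersection across
#' models, with a warning.
#'
#' @param path path to a PDB file.
#' @param selection optional atom selection applied after reading (keyword
#'   understood by [atom_select()]), e.g. \code{"backbone"}.
#' @param label,temperature metadata stored on the ensemble.
#' @return a [conf_ensemble()].
#' @export
read_pdb_ensemble <- function(path, selection = NULL, label = basename(path),
                              temperature = NA_real_) {
  if (!file.exists(path)) stop("cannot read PDB file: ", path)
  lines <- readLines(path, warn = FALSE)
  starts <- grep("^MODEL", lines)
  ends <- grep("^ENDMDL", lines)
  if (length(starts) == 0L) {
    blocks <- list(lines)
    model_ids <- 1L
  } else {
    if (length(starts) != length(ends))
      stop("malformed PDB: ", length(starts), " MODEL but ", length(ends),
           " ENDMDL records")
    blocks <- Map(function(s, e) lines[(s + 1L):(e - 1L)], starts, ends)
    model_ids <- vapply(lines[starts], function(l) {
      id <- suppressWarnings(as.integer(substr(l, 7, 80)))
      if (is.na(id)) NA_integer_ else id
    }, integer(1), USE.NAMES = FALSE)
    if (anyNA(model_ids)) model_ids <- seq_along(blocks)
  }
  models <- lapply(blocks, parse_pdb_block)
  models <- Filter(function(m) nrow(m) > 0L, models)
  if (length(models) == 0L) stop("no atoms found in ", path)

  keys <- lapply(models, function(m) atom_key(m))
  common <- Reduce(intersect, keys)
  if (length(common) == 0L)
    stop("models share no common atoms; cannot build an ensemble")
  if (any(vapply(keys, length, 1L) != length(common)))
    warning("models differ in atom content; restricted to the ",
            length(common), "-atom intersection")
  # order atoms as they appear in the first model
  ord <- keys[[1]][keys[[1]] %in% common]
  atoms <- models[[1]][match(ord, keys[[1]]), c("resno", "resid", "elety", "chain")]
  rownames(atoms) <- NULL
  xyz <- do.call(rbind, lapply(seq_along(models), function(i) {
    m <- models[[i]][match(ord, keys[[i]]), ]
    mat_to_xyz(as.matrix(m[, c("x", "y", "z")]))
  }))
  ens <- conf_ensemble(atoms, xyz, model_ids = model_ids[seq_len(nrow(xyz))],
                       label = label, temperature = temperature)
  if (!is.null(selection)) ens <- ensemble_subset(ens, atoms = selection)
  ens
}

# Parse ATOM/HETATM records of one model; keep altloc blank or 'A'.
parse_pdb_block <- function(lines) {
  rec <- lines[substr(lines, 1, 6) %in% c("ATOM  ", "HETATM")]
  if (length(rec) == 0L)
    return(data.frame(resno = integer(), resid = character(),
                      elety = character(), chain = character(),
                      x = numeric(), y = numeric(), z = numeric()))
  alt <- substr(rec, 17, 17)
  rec <- rec[alt %in% c(" ", "A")]
  d <- data.frame(
    resno = as.integer(substr(rec, 23, 26)),
    resid = trimws(substr(rec, 18, 20)),
    elety = trimws(substr(rec, 13, 16)),
    chain = trimws(substr(rec, 22, 22)),
    x = as.numeric(substr(rec, 31, 38)),
    y = as.numeric(substr(rec, 39, 46)),
    z = as.numeric(substr(rec, 47, 54)),
    stringsAsFactors = FALSE
  )
  d$chain[d$chain == ""] <- "A"
  if (anyNA(d$x) || anyNA(d$y) || anyNA(d$z) || anyNA(d$resno))
    stop("unparseable ATOM record in PDB input")
  d
}

#' Write a conformer ensemble as a multi-model PDB file
#'
#' Coordinates are written at the standard PDB precision (0.001 Angstrom),
#' so a write-then-read round trip reproduces them to that precision.
#'
#' @param x a [conf_ensemble()].
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_pdb_ensemble <- function(x, path) {
  bio3d::write.pdb(file = path, xyz = x$xyz, resno = x$atoms$resno,
                   resid = x$atoms$resid, elety = x$atoms$elety,
                   chain = x$atoms$chain)
  invisible(path)
}

# ---------------------------------------------------------------------------
# NOE restraint lists

#' Read an NOE distance restraint list
#'
#' Two dialects are supported and yield identical restraint tables on
#' equivalent content:
#' \describe{
#'   \item{\code{tsv}}{three pipe-separated fields:
#'     \code{resno resname atom | resno resname atom | upper_bound},
#'     with \code{'#'} as a trailing wildcard for pseudo-atom groups
#'     (e.g. \code{HB#}). Lines starting with \code{!} are comments.}
#'   \item{\code{upl}}{CYANA-style whitespace columns
#'     \code{resno resname atom resno resname atom upper_bound}; CYANA
#'     pseudo-atom names (\code{QB}, \code{QD1}, \code{QQD}, ...) are
#'     normalized to the wildcard form (\code{HB#}, \code{HD1#},
#'     \code{HD#}).}
#' }
#' Atom groups are stored verbatim (wildcards unexpanded); use [destereo()]
#' and the evaluation functions, which resolve them against a topology.
#'
#' @param path path to the restraint file.
#' @param dialect \code{"auto"} (by extension), \code{"tsv"} or \code{"upl"}.
#' @return a \code{noe_restraints} data.frame with columns \code{resno_a},
#'   \code{resid_a}, \code{group_a} (list of atom-name patterns),
#'   \code{resno_b}, \code{resid_b}, \code{group_b}, \code{upper},
#'   \code{bin} (\code{NA} until [bin_upper_bound()] is applied).
#' @export
read_restraints <- function(path, dialect = c("auto", "tsv", "upl")) {
  dialect <- match.arg(dialect)
  if (dialect == "auto")
    dialect <- if (grepl("\\.upl$", path, ignore.case = TRUE)) "upl" else "tsv"
  lines <- readLines(path, warn = FALSE)
  keep <- which(nzchar(trimws(lines)) & !grepl("^\\s*!", lines))
  if (length(keep) == 0L) return(empty_restraints())
  rows <- lapply(keep, function(i) {
    ln <- trimws(lines[i])
    if (dialect == "tsv") {
      parts <- trimws(strsplit(ln, "|", fixed = TRUE)[[1]])
      if (length(parts) != 3L)
        stop("malformed restraint at line ", i, ": expected 3 pipe-separated fields")
      ga <- strsplit(parts[1], "\\s+")[[1]]
      gb <- strsplit(parts[2], "\\s+")[[1]]
      ub <- suppressWarnings(as.numeric(parts[3]))
    } else {
      f <- strsplit(ln, "\\s+")[[1]]
      if (length(f) < 7L)
        stop("malformed restraint at line ", i, ": expected 7 whitespace fields")
      ga <- f[1:3]
      gb <- f[4:6]
      ub <- suppressWarnings(as.numeric(f[7]))
      ga[3] <- cyana_to_wildcard(ga[3])
      gb[3] <- cyana_to_wildcard(gb[3])
    }
    if (length(ga) != 3L || length(gb) != 3L)
      stop("malformed restraint at line ", i, ": each group needs resno, resname, atom")
    if (is.na(ub) || ub <= 0)
      stop("non-positive or unreadable upper bound at line ", i)
    data.frame(resno_a = as.integer(ga[1]), resid_a = ga[2],
               group_a = I(list(ga[3])),
               resno_b = as.integer(gb[1]), resid_b = gb[2],
               group_b = I(list(gb[3])),
               upper = ub, bin = NA_real_, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$id <- seq_len(nrow(out))
  class(out) <- c("noe_restraints", "data.frame")
  out
}

empty_restraints <- function() {
  out <- data.frame(resno_a = integer(), resid_a = character(),
                    group_a = I(list()), resno_b = integer(),
                    resid_b = character(), group_b = I(list()),
                    upper = numeric(), bin = numeric(), id = integer(),
                    stringsAsFactors = FALSE)
  class(out) <- c("noe_restraints", "data.frame")
  out
}

#' Write an NOE restraint list in the pipe-separated dialect
#'
#' Inverse of [read_restraints()] for the \code{tsv} dialect. Only
#' single-pattern groups (as produced by parsing or by the synthetic
#' generator) can be serialized; destereo-expanded multi-atom groups have
#' no file representation and are rejected.
#'
#' @param restraints a \code{noe_restraints} table.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_restraints <- function(restraints, path) {
  multi <- vapply(restraints$group_a, length, 1L) > 1L |
    vapply(restraints$group_b, length, 1L) > 1L
  if (any(multi))
    stop("cannot serialize multi-atom groups; write before destereo()")
  lines <- sprintf("%d %s %s | %d %s %s | %g",
                   restraints$resno_a, restraints$resid_a,
                   unlist(restraints$group_a),
                   restraints$resno_b, restraints$resid_b,
                   unlist(restraints$group_b), restraints$upper)
  writeLines(lines, path)
  invisible(path)
}

# CYANA pseudo-atom name -> wildcard pattern; plain names pass through.
cyana_to_wildcard <- function(a) {
  if (grepl("^QQ", a)) return(paste0("H", substring(a, 3), "#"))
  if (grepl("^Q", a)) return(paste0("H", substring(a, 2), "#"))
  a
}

# ---------------------------------------------------------------------------
# Delimited NMR observable tables

#' Read a typed NMR observable table
#'
#' Tables are tab-separated text with a header line. Expected columns:
#' \describe{
#'   \item{\code{shifts}}{\code{resno}, \code{nucleus} (one of N, H, CA, CB,
#'     C, HA), \code{shift} (ppm).}
#'   \item{\code{s2}}{\code{resno}, \code{s2}; the temperature comes from
#'     the \code{temperature} argument or a \code{temperature} column.}
#'   \item{\code{delta_omega}}{\code{resno}, \code{temperature} (K),
#'     \code{delta_omega} (ppm, |15N shift difference|, non-negative).}
#' }
#'
#' @param path file path.
#' @param kind one of \code{"shifts"}, \code{"s2"}, \code{"delta_omega"}.
#' @param temperature temperature in K attached to an S2 table when the file
#'   has no \code{temperature} column.
#' @return a data.frame of class \code{shift_table}, \code{order_params} or
#'   \code{delta_omega}; \code{order_params} carries a \code{temperature}
#'   attribute.
#' @export
read_nmr_table <- function(path, kind = c("shifts", "s2", "delta_omega"),
                           temperature = NA_real_) {
  kind <- match.arg(kind)
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  switch(kind,
    shifts = shift_table(d$resno, d$nucleus, d$shift),
    s2 = {
      if ("temperature" %in% names(d)) {
        tt <- unique(d$temperature)
        if (length(tt) > 1L) stop("an S2 table holds a single temperature")
        temperature <- tt
      }
      order_params(d$resno, d$s2, temperature = temperature)
    },
    delta_omega = delta_omega_set(d$resno, d$temperature, d$delta_omega)
  )
}

#' Construct a chemical shift table
#'
#' @param resno integer residue numbers.
#' @param nucleus nucleus labels from \code{N, H, CA, CB, C, HA}.
#' @param shift shifts in ppm.
#' @return data.frame of class \code{shift_table}.
#' @export
shift_table <- function(resno, nucleus, shift) {
  vocab <- c("N", "H", "CA", "CB", "C", "HA")
  if (!all(nucleus %in% vocab))
    stop("unknown nucleus label(s): ",
         paste(setdiff(unique(nucleus), vocab), collapse = ", "))
  if (!all(is.finite(shift))) stop("shifts must be finite")
  d <- data.frame(resno = as.integer(resno), nucleus = as.character(nucleus),
                  shift = as.numeric(shift), stringsAsFactors = FALSE)
  dup <- duplicated(d[, c("resno", "nucleus")])
  if (any(dup))
    stop("duplicate (residue, nucleus) entries at row(s) ",
         paste(which(dup), collapse = ", "))
  class(d) <- c("shift_table", "data.frame")
  d
}

#' Construct a per-residue S2 order parameter set
#'
#' @param resno integer residue numbers.
#' @param s2 order parameters, each in [0, 1].
#' @param temperature temperature in Kelvin (may be \code{NA}).
#' @return data.frame of class \code{order_params} with a
#'   \code{temperature} attribute.
#' @export
order_params <- function(resno, s2, temperature = NA_real_) {
  bad <- which(!is.finite(s2) | s2 < 0 | s2 > 1)
  if (length(bad) > 0L)
    stop("S2 outside [0, 1] at row(s) ", paste(bad, collapse = ", "))
  dup <- duplicated(resno)
  if (any(dup))
    stop("duplicate residue number(s) at row(s) ",
         paste(which(dup), collapse = ", "))
  d <- data.frame(resno = as.integer(resno), s2 = as.numeric(s2))
  attr(d, "temperature") <- temperature
  class(d) <- c("order_params", "data.frame")
  d
}

#' Construct a |delta omega|(15N) magnitude set
#'
#' @param resno integer residue numbers.
#' @param temperature temperature in Kelvin per entry.
#' @param delta_omega non-negative |delta omega| magnitudes in ppm.
#' @return data.frame of class \code{delta_omega}.
#' @export
delta_omega_set <- function(resno, temperature, delta_omega) {
  if (any(!is.finite(delta_omega) | delta_omega < 0))
    stop("|delta omega| values must be finite and non-negative")
  d <- data.frame(resno = as.integer(resno),
                  temperature = as.numeric(temperature),
                  delta_omega = as.numeric(delta_omega))
  dup <- duplicated(d[, c("resno", "temperature")])
  if (any(dup))
    stop("duplicate (residue, temperature) entries at row(s) ",
         paste(which(dup), collapse = ", "))
  class(d) <- c("delta_omega", "data.frame")
  d
}

#' Write a typed NMR observable table
#'
#' Inverse of [read_nmr_table()]; tab-separated with a header.
#'
#' @param x a \code{shift_table}, \code{order_params} or \code{delta_omega}
#'   object.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_nmr_table <- function(x, path) {
  d <- as.data.frame(x)
  if (inherits(x, "order_params") && !is.na(attr(x, "temperature")))
    d$temperature <- attr(x, "temperature")
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Fail loudly when an operation needs hydrogens the structure lacks.
require_hydrogens <- function(x, op) {
  if (!any(is_hydrogen_name(x$atoms$elety)))
    stop(op, " requires hydrogen atoms, but the ensemble contains none; ",
         "supply a structure with explicit hydrogens")
  invisible(TRUE)
}
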