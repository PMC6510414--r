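# NOE restraint preprocessing and per-ensemble violation statistics.

# Stereo-equivalent proton sets per residue type. Removal of
# stereospecificity replaces any member of a set by the whole set:
# methylene HB2/HB3 pairs, isopropyl methyls of Val/Leu (all six protons),
# freely rotating methyls and amine groups, and symmetric aromatic ring
# positions (slow ring flips make HD1/HD2 etc. NMR-equivalent).
.stereo_sets <- local({
  hb <- c("HB2", "HB3")
  list(
    GLY = list(c("HA2", "HA3")),
    ALA = list(c("HB1", "HB2", "HB3")),
    VAL = list(c("HG11", "HG12", "HG13", "HG21", "HG22", "HG23")),
    LEU = list(hb, c("HD11", "HD12", "HD13", "HD21", "HD22", "HD23")),
    ILE = list(c("HG12", "HG13"), c("HG21", "HG22", "HG23"),
               c("HD11", "HD12", "HD13")),
    PRO = list(hb, c("HG2", "HG3"), c("HD2", "HD3")),
    MET = list(hb, c("HG2", "HG3"), c("HE1", "HE2", "HE3")),
    PHE = list(hb, c("HD1", "HD2"), c("HE1", "HE2")),
    TYR = list(hb, c("HD1", "HD2"), c("HE1", "HE2")),
    TRP = list(hb),
    SER = list(hb),
    THR = list(c("HG21", "HG22", "HG23")),
    CYS = list(hb),
    ASN = list(hb, c("HD21", "HD22")),
    GLN = list(hb, c("HG2", "HG3"), c("HE21", "HE22")),
    ASP = list(hb),
    GLU = list(hb, c("HG2", "HG3")),
    LYS = list(hb, c("HG2", "HG3"), c("HD2", "HD3"), c("HE2", "HE3"),
               c("HZ1", "HZ2", "HZ3")),
    ARG = list(hb, c("HG2", "HG3"), c("HD2", "HD3"),
               c("HH11", "HH12", "HH21", "HH22")),
    HIS = list(hb)
  )
})

# Expand one atom-name pattern (trailing '#' wildcard) against the atom
# names of one residue. Returns matching names; errors when none match.
expand_pattern <- function(pattern, res_atoms, resno) {
  if (grepl("#$", pattern)) {
    stem <- sub("#$", "", pattern)
    hits <- res_atoms[startsWith(res_atoms, stem) & is_hydrogen_name(res_atoms)]
  } else {
    hits <- res_atoms[res_atoms == pattern]
  }
  if (length(hits) == 0L)
    stop("atom '", pattern, "' of residue ", resno, " not found in topology")
  hits
}

stereo_equivalents <- function(resid, atom_name) {
  sets <- .stereo_sets[[resid]]
  if (!is.null(sets)) {
    for (s in sets) if (atom_name %in% s) return(s)
  }
  atom_name
}

#' Remove stereospecificity from NOE restraints
#'
#' Every stereospecific atom name in a restraint group is replaced by the
#' full set of its stereo-equivalent atoms present in the topology
#' (e.g. \code{HB2} by \code{\{HB2, HB3\}}, any Leu \code{HD} methyl proton
#' by all six \code{HD} protons). Trailing-\code{'#'} wildcard patterns are
#' expanded against the topology first; groups that are already ambiguous
#' are left as their expanded atom set.
#'
#' @param restraints a \code{noe_restraints} table from [read_restraints()].
#' @param ensemble a [conf_ensemble()] providing the topology (atom names
#'   per residue).
#' @return the restraint table with \code{group_a}/\code{group_b} holding
#'   concrete atom-name sets.
#' @export
destereo <- function(restraints, ensemble) {
  atoms <- ensemble$atoms
  expand_side <- function(resno, resid, patterns) {
    res_atoms <- atoms$elety[atoms$resno == resno]
    if (length(res_atoms) == 0L)
      stop("residue ", resno, " not present in topology")
    hits <- unlist(lapply(patterns, expand_pattern, res_atoms = res_atoms,
                          resno = resno))
    out <- unique(unlist(lapply(hits, function(a) {
      eq <- stereo_equivalents(resid, a)
      intersect(eq, res_atoms)
    })))
    sort(out)
  }
  restraints$group_a <- I(Map(expand_side, restraints$resno_a,
                              restraints$resid_a, restraints$group_a))
  restraints$group_b <- I(Map(expand_side, restraints$resno_b,
                              restraints$resid_b, restraints$group_b))
  restraints
}

#' Bin an NOE upper bound to the next integer Angstrom
#'
#' Restrained distances are rounded up to the next integer Angstrom,
#' creating 1-Angstrom-wide bins from 4 to 10 Angstrom. Integer bounds are
#' their own bin; bounds below 4 clamp up to the smallest (4 Angstrom) bin;
#' bounds above 10 are outside the declared bin range and rejected.
#'
#' @param d positive upper bound(s) in Angstrom.
#' @return integer bin(s) in 4..10.
#' @export
bin_upper_bound <- function(d) {
  if (any(d <= 0)) stop("upper bounds must be positive")
  if (any(d > 10)) stop("upper bound above 10 Angstrom is outside the 4-10 bin range")
  pmax(ceiling(d), 4)
}

#' @rdname bin_upper_bound
#' @param restraints a \code{noe_restraints} table; its \code{upper} column
#'   is binned into the \code{bin} column.
#' @export
bin_restraints <- function(restraints) {
  restraints$bin <- bin_upper_bound(restraints$upper)
  restraints
}

# Resolve restraint groups to atom indices; destereo() or wildcard
# expansion must already have produced concrete names, otherwise patterns
# are expanded here without stereo expansion.
resolve_indices <- function(restraints, ensemble) {
  atoms <- ensemble$atoms
  side <- function(resno, patterns) {
    res_idx <- which(atoms$resno == resno)
    if (length(res_idx) == 0L)
      stop("residue ", resno, " not present in topology")
    hits <- unlist(lapply(patterns, expand_pattern,
                          res_atoms = atoms$elety[res_idx], resno = resno))
    res_idx[match(unique(hits), atoms$elety[res_idx])]
  }
  list(a = Map(side, restraints$resno_a, restraints$group_a),
       b = Map(side, restraints$resno_b, restraints$group_b))
}

#' Ensemble r^-6 effective distance of NOE restraints
#'
#' For each member \eqn{m} the inverse sixth powers of all cross-pair
#' distances between the two atom groups are combined (summed by default,
#' the standard pseudo-atom convention) into \eqn{s_m}; the effective
#' distance is \eqn{(\mathrm{mean}_m\, s_m)^{-1/6}}, i.e. r^-6 averaging
#' both over the intramolecular ambiguity and over the members of the
#' ensemble with uniform weights.
#'
#' @param ensemble a [conf_ensemble()] containing every restraint atom in
#'   every member.
#' @param restraints a \code{noe_restraints} table (see [read_restraints()],
#'   [destereo()]).
#' @param combine how the intramolecular ambiguity is combined: \code{"sum"}
#'   of r^-6 over cross pairs (default) or their \code{"mean"}.
#' @return numeric vector of effective distances in Angstrom, one per
#'   restraint.
#' @export
effective_distance <- function(ensemble, restraints, combine = c("sum", "mean")) {
  combine <- match.arg(combine)
  require_hydrogens(ensemble, "effective_distance")
  if (nrow(restraints) == 0L) return(numeric(0))
  idx <- resolve_indices(restraints, ensemble)
  nm <- n_members(ensemble)
  coords <- lapply(seq_len(nm), function(m) member_coords(ensemble, m))
  vapply(seq_len(nrow(restraints)), function(r) {
    ia <- idx$a[[r]]
    ib <- idx$b[[r]]
    s <- vapply(coords, function(cm) {
      d2 <- outer(seq_along(ia), seq_along(ib), function(i, j) {
        rowSums((cm[ia[i], , drop = FALSE] - cm[ib[j], , drop = FALSE])^2)
      })
      if (any(d2 == 0)) stop("zero distance between restraint atoms")
      v <- sum(d2^-3)
      if (combine == "mean") v <- v / length(d2)
      v
    }, numeric(1))
    mean(s)^(-1 / 6)
  }, numeric(1))
}

#' Per-ensemble NOE violation report
#'
#' A binned restraint is violated when its ensemble effective distance
#' exceeds \code{bin + tolerance} (strict inequality).
#'
#' @inheritParams effective_distance
#' @param tolerance violation tolerance in Angstrom (default 0.5).
#' @return object of class \code{violation_report}: a list with the
#'   per-restraint \code{table} (effective distance and violation flag),
#'   \code{n}, \code{n_violated}, \code{percent_violated} and
#'   \code{tolerance}.
#' @export
violation_report <- function(ensemble, restraints, tolerance = 0.5,
                             combine = c("sum", "mean")) {
  if (nrow(restraints) == 0L) stop("empty restraint list")
  if (anyNA(restraints$bin))
    stop("restraints must be binned first; see bin_restraints()")
  eff <- effective_distance(ensemble, restraints, combine = combine)
  violated <- eff > restraints$bin + tolerance
  tab <- data.frame(
    id = restraints$id,
    group_a = vapply(seq_len(nrow(restraints)), function(i)
      paste0(restraints$resno_a[i], " ", restraints$resid_a[i], " ",
             paste(restraints$group_a[[i]], collapse = "/")), character(1)),
    group_b = vapply(seq_len(nrow(restraints)), function(i)
      paste0(restraints$resno_b[i], " ", restraints$resid_b[i], " ",
             paste(restraints$group_b[[i]], collapse = "/")), character(1)),
    bin = restraints$bin,
    effective_distance = eff,
    violated = violated,
    stringsAsFactors = FALSE
  )
  structure(list(table = tab, n = nrow(tab), n_violated = sum(violated),
                 percent_violated = 100 * mean(violated),
                 tolerance = tolerance),
            class = "violation_report")
}

#' @export
print.violation_report <- function(x, ...) {
  cat(sprintf("NOE violation report: %d restraints, %d violated (%.2f%%), tolerance %.2f A\n",
              x$n, x$n_violated, x$percent_violated, x$tolerance))
  invisible(x)
}

#' Write a violation report as CSV plus a JSON summary
#'
#' @param x a \code{violation_report}.
#' @param csv_path per-restraint CSV output path.
#' @param json_path JSON summary output path (\code{n}, \code{n_violated},
#'   \code{percent}, \code{tolerance}); omitted when \code{NULL}.
#' @return \code{csv_path}, invisibly.
#' @export
write_violation_report <- function(x, csv_path, json_path = NULL) {
  utils::write.csv(x$table, csv_path, row.names = FALSE)
  if (!is.null(json_path))
    jsonlite::write_json(list(n = x$n, n_violated = x$n_violated,
                              percent = x$percent_violated,
                              tolerance = x$tolerance),
                         json_path, auto_unbox = TRUE, digits = NA)
  invisible(csv_path)
}

#' Keep restraints unviolated in a reference ensemble
#'
#' Used to transfer a restraint list between ligation states: only
#' restraints whose effective distance in the reference ensemble is within
#' \code{bin + tolerance} are retained, in their original order. Re-running
#' [violation_report()] on the result against the same reference gives
#' 0.00\% by construction.
#'
#' @inheritParams violation_report
#' @param reference_ensemble the [conf_ensemble()] the restraints are
#'   checked against.
#' @return the unviolated subset of \code{restraints}.
#' @export
filter_unviolated <- function(restraints, reference_ensemble, tolerance = 0.5,
                              combine = c("sum", "mean")) {
  if (nrow(restraints) == 0L) return(restraints)
  if (anyNA(restraints$bin))
    stop("restraints must be binned first; see bin_restraints()")
  eff <- effective_distance(reference_ensemble, restraints, combine = combine)
  restraints[eff <= restraints$bin + tolerance, , drop = FALSE]
}
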