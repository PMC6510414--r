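# Backbone amide S2 order parameters: back-calculation from an ensemble
# and correspondence statistics against experiment.

#' Back-calculate backbone N-H S2 order parameters from an ensemble
#'
#' For each residue with amide N and H atoms, the unit bond vectors
#' \eqn{\mu_m} over the members enter the symmetric second-moment form
#' \deqn{S^2 = \frac{3\left(\langle x^2\rangle^2 + \langle y^2\rangle^2 +
#'   \langle z^2\rangle^2 + 2\langle xy\rangle^2 + 2\langle xz\rangle^2 +
#'   2\langle yz\rangle^2\right) - 1}{2}}
#' with uniform member weights. The result is clipped to [0, 1] within a
#' 1e-9 numerical tolerance. Prolines and residues lacking an amide
#' hydrogen are skipped with a warning, matching NMR observability.
#'
#' @param ensemble a [conf_ensemble()]; at least 2 members give a
#'   non-trivial result.
#' @param h_names atom names accepted for the amide proton.
#' @return an [order_params()] object (one S2 per evaluable residue),
#'   tagged with the ensemble temperature.
#' @export
backcalc_s2 <- function(ensemble, h_names = c("H", "HN")) {
  atoms <- ensemble$atoms
  resnos <- unique(atoms$resno)
  skipped <- integer(0)
  out_res <- integer(0)
  out_s2 <- numeric(0)
  nm <- n_members(ensemble)
  for (r in resnos) {
    resid <- atoms$resid[atoms$resno == r][1]
    iN <- find_atom(atoms, r, "N")
    iH <- NA_integer_
    for (h in h_names) {
      iH <- find_atom(atoms, r, h)
      if (!is.na(iH)) break
    }
    if (identical(resid, "PRO") || is.na(iN) || is.na(iH)) {
      skipped <- c(skipped, r)
      next
    }
    ncols <- xyz_cols(iN)
    hcols <- xyz_cols(iH)
    v <- ensemble$xyz[, hcols, drop = FALSE] - ensemble$xyz[, ncols, drop = FALSE]
    lens <- sqrt(rowSums(v^2))
    if (any(lens == 0)) stop("zero-length N-H bond vector at residue ", r)
    u <- v / lens
    s2 <- s2_from_unit_vectors(u)
    out_res <- c(out_res, r)
    out_s2 <- c(out_s2, s2)
  }
  if (length(skipped) > 0L)
    warning("skipped ", length(skipped),
            " residue(s) without observable amide N-H: ",
            paste(utils::head(skipped, 10), collapse = ", "),
            if (length(skipped) > 10) ", ...")
  if (length(out_res) == 0L) stop("no residue with amide N and H atoms found")
  order_params(out_res, out_s2, temperature = ensemble$temperature)
}

# S2 from an n x 3 matrix of unit vectors, uniform weights.
s2_from_unit_vectors <- function(u) {
  xx <- mean(u[, 1]^2); yy <- mean(u[, 2]^2); zz <- mean(u[, 3]^2)
  xy <- mean(u[, 1] * u[, 2]); xz <- mean(u[, 1] * u[, 3]); yz <- mean(u[, 2] * u[, 3])
  s2 <- (3 * (xx^2 + yy^2 + zz^2 + 2 * xy^2 + 2 * xz^2 + 2 * yz^2) - 1) / 2
  if (s2 < -1e-9 || s2 > 1 + 1e-9)
    stop("back-calculated S2 out of range beyond numerical tolerance: ", s2)
  min(max(s2, 0), 1)
}

#' Compare experimental and back-calculated S2 values
#'
#' Computes the Pearson correlation over shared residues, and a corrected
#' correlation excluding residues whose absolute experimental-minus-
#' calculated difference exceeds \code{cutoff} (default 0.2). With
#' \code{cutoff = Inf} the corrected value equals the plain correlation.
#'
#' @param experimental an [order_params()] object.
#' @param calculated an [order_params()] object or a named numeric vector
#'   (names = residue numbers), e.g. from [backcalc_s2()].
#' @param cutoff exclusion cutoff on |difference| (dimensionless).
#' @return object of class \code{s2_comparison}: list with
#'   \code{per_residue} (resno, experimental, calculated, abs_difference),
#'   \code{correlation}, \code{corrected_correlation} (\code{NA} and
#'   flagged \code{degenerate} when fewer than 3 residues survive the
#'   exclusion), \code{excluded} (residue numbers) and \code{cutoff}.
#' @export
s2_compare <- function(experimental, calculated, cutoff = 0.2) {
  if (inherits(calculated, "order_params")) {
    calc <- stats::setNames(calculated$s2, calculated$resno)
  } else {
    calc <- calculated
    if (is.null(names(calc))) stop("calculated must be named by residue number")
  }
  shared <- intersect(experimental$resno, as.integer(names(calc)))
  if (length(shared) < 3L)
    stop("need at least 3 shared residues, got ", length(shared))
  e <- experimental$s2[match(shared, experimental$resno)]
  c2 <- as.numeric(calc[as.character(shared)])
  diffs <- abs(e - c2)
  excluded <- shared[diffs > cutoff]
  keep <- diffs <= cutoff
  corrected <- NA_real_
  degenerate <- FALSE
  if (sum(keep) >= 3L) {
    corrected <- stats::cor(e[keep], c2[keep])
  } else {
    degenerate <- TRUE
  }
  structure(list(
    per_residue = data.frame(resno = shared, experimental = e,
                             calculated = c2, abs_difference = diffs),
    correlation = stats::cor(e, c2),
    corrected_correlation = corrected,
    excluded = excluded,
    cutoff = cutoff,
    degenerate = degenerate
  ), class = "s2_comparison")
}

#' @export
print.s2_comparison <- function(x, ...) {
  cat(sprintf("S2 comparison over %d residues: r = %.3f, corrected r = %s (%d excluded at |diff| > %g)\n",
              nrow(x$per_residue), x$correlation,
              if (is.na(x$corrected_correlation)) "NA" else
                sprintf("%.3f", x$corrected_correlation),
              length(x$excluded), x$cutoff))
  invisible(x)
}

#' Plot experimental vs back-calculated S2 profiles
#'
#' Per-residue profile plot of the experimental and calculated values, with
#' excluded residues marked.
#'
#' @param x an \code{s2_comparison}.
#' @param ... passed to [graphics::plot()].
#' @export
plot.s2_comparison <- function(x, ...) {
  d <- x$per_residue
  graphics::plot(d$resno, d$experimental, type = "b", pch = 16,
                 ylim = c(0, 1), xlab = "residue", ylab = expression(S^2), ...)
  graphics::lines(d$resno, d$calculated, type = "b", pch = 1, col = "red3")
  if (length(x$excluded) > 0L)
    graphics::points(x$excluded,
                     d$experimental[match(x$excluded, d$resno)],
                     pch = 4, cex = 1.6, col = "blue")
  graphics::legend("bottomleft", legend = c("experimental", "calculated",
                                            "excluded"),
                   pch = c(16, 1, 4), col = c("black", "red3", "blue"),
                   bty = "n")
  invisible(x)
}

#' Write an S2 comparison as CSV plus a JSON summary
#'
#' @param x an \code{s2_comparison}.
#' @param csv_path per-residue CSV output path.
#' @param json_path JSON summary output path; omitted when \code{NULL}.
#' @return \code{csv_path}, invisibly.
#' @export
write_s2_comparison <- function(x, csv_path, json_path = NULL) {
  utils::write.csv(x$per_residue, csv_path, row.names = FALSE)
  if (!is.null(json_path))
    jsonlite::write_json(list(correlation = x$correlation,
                              corrected_correlation = x$corrected_correlation,
                              n_excluded = length(x$excluded),
                              excluded = x$excluded, cutoff = x$cutoff),
                         json_path, auto_unbox = TRUE, digits = NA)
  invisible(csv_path)
}
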