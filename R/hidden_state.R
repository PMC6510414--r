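# Selection of "invisible state" candidate conformers by matching
# predicted 15N chemical-shift differences against CPMG-derived
# |delta omega| profiles.

#' Predicted |15N shift difference| profiles of pool conformers
#'
#' For each pool conformer, the predictor's 15N shift is compared with the
#' prediction for each reference (unliganded ground state) conformer; the
#' per-residue absolute differences are aggregated over the references by
#' the chosen statistic (arithmetic mean by default; \code{"median"} and
#' the per-reference minimum \code{"best"} are alternatives).
#'
#' @param pool a [conf_ensemble()] of candidate conformers.
#' @param reference a [conf_ensemble()] of ground-state (apo) conformers.
#' @param predictor a shift predictor, e.g. [shift_predictor_surrogate()].
#' @param nucleus nucleus used for the profile (default \code{"N"}).
#' @param aggregate aggregation over reference conformers.
#' @return numeric matrix, pool members x shared residues, of
#'   |delta delta| values in ppm; residue numbers as column names.
#' @export
predicted_delta <- function(pool, reference, predictor, nucleus = "N",
                            aggregate = c("mean", "median", "best")) {
  aggregate <- match.arg(aggregate)
  if (n_members(reference) < 1L) stop("empty reference ensemble")
  get_profile <- function(ens, m) {
    t <- predictor(ens, m)
    t <- t[t$nucleus == nucleus, ]
    stats::setNames(t$shift, t$resno)
  }
  ref_profiles <- lapply(seq_len(n_members(reference)), function(m)
    get_profile(reference, m))
  pool_profiles <- lapply(seq_len(n_members(pool)), function(m)
    get_profile(pool, m))
  shared <- Reduce(intersect, c(lapply(ref_profiles, names),
                                lapply(pool_profiles, names)))
  if (length(shared) == 0L) stop("no residues shared between pool and reference")
  if (length(shared) < length(names(pool_profiles[[1]])))
    warning("residue coverage mismatch; restricted to ", length(shared),
            " shared residues")
  R <- do.call(rbind, lapply(ref_profiles, `[`, shared))
  out <- t(vapply(pool_profiles, function(p) {
    D <- abs(sweep(R, 2, p[shared], function(r, x) r - x))
    switch(aggregate,
           mean = colMeans(D),
           median = apply(D, 2, stats::median),
           best = apply(D, 2, min))
  }, numeric(length(shared))))
  colnames(out) <- shared
  out
}

#' Min-max normalization to the 0-1 range
#'
#' \code{(x - min) / (max - min)}. A constant vector cannot be normalized:
#' all entries map to 0 and the result carries attribute
#' \code{degenerate = TRUE}.
#'
#' @param x numeric vector with at least 2 entries.
#' @return the normalized vector; attribute \code{"degenerate"} flags a
#'   constant input.
#' @export
minmax_normalize <- function(x) {
  if (length(x) < 2L) stop("need at least 2 entries to normalize")
  rng <- range(x)
  if (rng[1] == rng[2]) {
    out <- rep(0, length(x))
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  out <- (x - rng[1]) / (rng[2] - rng[1])
  attr(out, "degenerate") <- FALSE
  out
}

#' Score pool conformers against experimental |delta omega| profiles
#'
#' Per temperature, the predicted |delta delta| profile and the
#' experimental |delta omega| values are restricted to their shared
#' residue set, both min-max normalized to the 0-1 range, and compared by
#' Pearson correlation and the root-mean-square difference of the
#' normalized vectors. The per-temperature values are averaged (plain
#' mean) into one score per conformer. Temperatures whose normalization
#' degenerates on either side are skipped and recorded.
#'
#' @param deltas matrix from [predicted_delta()] (pool members x residues).
#' @param delta_omega a [delta_omega_set()] with per-temperature entries.
#' @return object of class \code{candidate_scores}: data.frame with
#'   \code{conformer}, \code{mean_correlation}, \code{mean_rmsd}; the
#'   per-temperature values in attribute \code{"per_temperature"}, skipped
#'   temperatures in attribute \code{"skipped"}.
#' @export
score_candidates <- function(deltas, delta_omega) {
  temps <- sort(unique(delta_omega$temperature))
  nm <- nrow(deltas)
  res_avail <- as.integer(colnames(deltas))
  per_t <- list()
  skipped <- numeric(0)
  for (tt in temps) {
    dw <- delta_omega[delta_omega$temperature == tt, ]
    shared <- intersect(res_avail, dw$resno)
    if (length(shared) < 3L)
      stop("need at least 3 residues shared with the ", tt, " K |delta omega| set")
    y <- minmax_normalize(dw$delta_omega[match(shared, dw$resno)])
    if (isTRUE(attr(y, "degenerate"))) {
      skipped <- c(skipped, tt)
      next
    }
    corr <- rmsd <- rep(NA_real_, nm)
    for (m in seq_len(nm)) {
      x <- minmax_normalize(deltas[m, as.character(shared)])
      if (isTRUE(attr(x, "degenerate"))) next
      corr[m] <- stats::cor(x, y)
      rmsd[m] <- sqrt(mean((x - y)^2))
    }
    per_t[[as.character(tt)]] <- data.frame(conformer = seq_len(nm),
                                            temperature = tt,
                                            correlation = corr, rmsd = rmsd)
  }
  if (length(per_t) == 0L) stop("all temperatures degenerate; nothing to score")
  allt <- do.call(rbind, per_t)
  mc <- tapply(allt$correlation, allt$conformer, mean)
  mr <- tapply(allt$rmsd, allt$conformer, mean)
  out <- data.frame(conformer = as.integer(names(mc)),
                    mean_correlation = as.numeric(mc),
                    mean_rmsd = as.numeric(mr))
  out <- out[order(out$conformer), ]
  rownames(out) <- NULL
  attr(out, "per_temperature") <- allt
  attr(out, "skipped") <- skipped
  class(out) <- c("candidate_scores", "data.frame")
  out
}

#' Select invisible-state candidates by score thresholds
#'
#' Two independent selections, mirroring the two criteria used to pick
#' excited-state candidates: conformers with mean correlation above
#' \code{corr_threshold} and conformers with mean normalized RMSD below
#' \code{rmsd_threshold}. The RMSD threshold lives on the min-max
#' normalized 0-1 scale, not in ppm.
#'
#' @param scores a \code{candidate_scores} object.
#' @param corr_threshold mean-correlation selection threshold.
#' @param rmsd_threshold mean normalized-RMSD selection threshold.
#' @return list with \code{selected_by_correlation},
#'   \code{selected_by_rmsd} (conformer ids) and \code{thresholds}.
#' @export
select_candidates <- function(scores, corr_threshold = 0.35,
                              rmsd_threshold = 0.00603) {
  if (nrow(scores) == 0L) stop("empty score table")
  list(
    selected_by_correlation =
      scores$conformer[!is.na(scores$mean_correlation) &
                       scores$mean_correlation > corr_threshold],
    selected_by_rmsd =
      scores$conformer[!is.na(scores$mean_rmsd) &
                       scores$mean_rmsd < rmsd_threshold],
    thresholds = c(correlation = corr_threshold, rmsd = rmsd_threshold,
                   rmsd_scale = NA)
  )
}

#' Scatter candidate scores over the PCA plane
#'
#' Plots pool conformers at their PC1/PC2 projections, highlighting the
#' selected candidates, in the style of an excited-state selection map.
#'
#' @param decomposition a \code{mode_decomposition} whose pooled members
#'   include (in order) the scored pool conformers.
#' @param scores a \code{candidate_scores} object.
#' @param selection result of [select_candidates()]; its correlation-based
#'   selection is highlighted.
#' @param pool_members indices of the scored pool conformers within the
#'   decomposition's pooled members (default: all members).
#' @param ... passed to [graphics::plot()].
#' @export
plot_candidate_map <- function(decomposition, scores, selection,
                               pool_members = seq_len(nrow(decomposition$projections)),
                               ...) {
  pr <- decomposition$projections
  graphics::plot(pr[, 1], pr[, 2], col = "grey70", pch = 1,
                 xlab = "PC1 (A)", ylab = "PC2 (A)", ...)
  hit <- pool_members[selection$selected_by_correlation]
  if (length(hit) > 0L)
    graphics::points(pr[hit, 1], pr[hit, 2], pch = 16, col = "black")
  invisible(NULL)
}

#' Write candidate scores and selections
#'
#' @param scores a \code{candidate_scores} object.
#' @param selection result of [select_candidates()].
#' @param csv_path per-conformer CSV output.
#' @param json_path JSON output of the selections; omitted when
#'   \code{NULL}.
#' @return \code{csv_path}, invisibly.
#' @export
write_candidate_scores <- function(scores, selection, csv_path,
                                   json_path = NULL) {
  utils::write.csv(as.data.frame(scores), csv_path, row.names = FALSE)
  if (!is.null(json_path))
    jsonlite::write_json(
      list(selected_by_correlation = selection$selected_by_correlation,
           selected_by_rmsd = selection$selected_by_rmsd,
           corr_threshold = unname(selection$thresholds["correlation"]),
           rmsd_threshold = unname(selection$thresholds["rmsd"])),
      json_path, auto_unbox = TRUE, digits = NA)
  invisible(csv_path)
}
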