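# Collective motions: superposition, pooled PCA, square fluctuations,
# ensemble RMSD and distance-versus-mode correlation maps.

#' Iteratively superpose an ensemble onto its mean structure
#'
#' Each member is least-squares fitted (optimal rotation and translation,
#' determinant +1, i.e. no reflection) onto the mean structure of a
#' selection; the mean is recomputed and the fit repeated until it moves by
#' less than \code{tol} (RMS, Angstrom) or \code{max_iter} rounds. The fit
#' is computed on the selection and applied to all atoms.
#'
#' @param ensemble a [conf_ensemble()].
#' @param selection fit selection, default \code{"calpha"}; needs >= 3
#'   atoms.
#' @param max_iter,tol iteration controls.
#' @return the superposed ensemble, with the converged mean coordinates of
#'   the selection in attribute \code{"mean_selection"}.
#' @export
superpose <- function(ensemble, selection = "calpha", max_iter = 50L,
                      tol = 1e-6) {
  sel <- atom_select(ensemble, selection)
  if (length(sel) < 3L) stop("superposition needs at least 3 selection atoms")
  nm <- n_members(ensemble)
  xyz <- ensemble$xyz
  sel_cols <- xyz_cols(sel)
  ref <- xyz_to_mat(xyz[1, sel_cols])
  for (iter in seq_len(max_iter)) {
    for (m in seq_len(nm)) {
      ft <- kabsch(ref, xyz_to_mat(xyz[m, sel_cols]))
      xyz[m, ] <- mat_to_xyz(apply_fit(xyz_to_mat(xyz[m, ]), ft))
    }
    new_ref <- xyz_to_mat(colMeans(xyz[, sel_cols, drop = FALSE]))
    shift <- sqrt(mean(rowSums((new_ref - ref)^2)))
    ref <- new_ref
    if (shift < tol) break
  }
  out <- ensemble
  out$xyz <- xyz
  attr(out, "mean_selection") <- ref
  out
}

#' Mean and spread of pairwise backbone RMSD within an ensemble
#'
#' All member pairs within each sub-ensemble are individually least-squares
#' fitted on the selection and their RMSD computed; the within-sub-ensemble
#' means are then summarized as mean +/- sd across sub-ensembles. An
#' ensemble without \code{sub_ids} (e.g. a deposited PDB ensemble) forms a
#' single sub-ensemble, so its sd is 0 by construction.
#'
#' @param ensemble a [conf_ensemble()] with >= 2 members.
#' @param selection RMSD atom selection; default \code{"backbone"}
#'   (N, CA, C).
#' @return named numeric vector \code{c(mean = , sd = )} in Angstrom.
#' @export
ensemble_rmsd <- function(ensemble, selection = "backbone") {
  if (n_members(ensemble) < 2L) stop("pairwise RMSD needs >= 2 members")
  sel <- atom_select(ensemble, selection)
  sel_cols <- xyz_cols(sel)
  groups <- ensemble$sub_ids %||% rep("all", n_members(ensemble))
  per_sub <- vapply(unique(groups), function(g) {
    idx <- which(groups == g)
    if (length(idx) < 2L) return(NA_real_)
    pr <- utils::combn(idx, 2)
    mean(vapply(seq_len(ncol(pr)), function(k) {
      rmsd_fit(xyz_to_mat(ensemble$xyz[pr[1, k], sel_cols]),
               xyz_to_mat(ensemble$xyz[pr[2, k], sel_cols]))
    }, numeric(1)))
  }, numeric(1))
  per_sub <- per_sub[!is.na(per_sub)]
  if (length(per_sub) == 0L) stop("no sub-ensemble with >= 2 members")
  c(mean = mean(per_sub),
    sd = if (length(per_sub) > 1L) stats::sd(per_sub) else 0)
}

#' Principal component analysis of pooled conformers
#'
#' Superposes the pooled conformers (all ensembles jointly, so apo and
#' holo members share one PC plane), then eigen-decomposes the 3n x 3n
#' covariance matrix of the selected coordinates about the pooled mean.
#' Modes are orthonormal columns; each mode's sign is fixed so that its
#' largest-magnitude component is positive. Projections are the centered
#' coordinates dotted with the modes.
#'
#' @param ... one or more [conf_ensemble()] objects sharing a topology
#'   (pooled), or a single ensemble.
#' @param selection PCA atom selection, default \code{"calpha"}.
#' @return object of class \code{mode_decomposition}: list with
#'   \code{mean} (n x 3 mean coordinates), \code{modes} (3n x k),
#'   \code{eigenvalues} (Angstrom^2, non-increasing), \code{projections}
#'   (members x k, Angstrom), \code{atoms} (selection atom table),
#'   \code{member_labels} (source ensemble of each pooled member) and the
#'   superposed pooled \code{ensemble}.
#' @export
pca_modes <- function(..., selection = "calpha") {
  pooled <- if (...length() == 1L) ..1 else pool_ensembles(...)
  if (n_members(pooled) < 3L) stop("PCA needs at least 3 pooled members")
  sub <- ensemble_subset(pooled, atoms = selection)
  sub <- superpose(sub, selection = "all")
  X <- sub$xyz
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  if (max(abs(Xc)) < 1e-12) stop("degenerate pool: zero coordinate variance")
  cv <- crossprod(Xc) / (nrow(Xc) - 1L)
  eig <- eigen(cv, symmetric = TRUE)
  vals <- pmax(eig$values, 0)
  vecs <- eig$vectors
  # deterministic sign: largest-|component| positive
  for (k in seq_len(ncol(vecs))) {
    i <- which.max(abs(vecs[, k]))
    if (vecs[i, k] < 0) vecs[, k] <- -vecs[, k]
  }
  proj <- Xc %*% vecs
  structure(list(mean = xyz_to_mat(mu), modes = vecs, eigenvalues = vals,
                 projections = proj, atoms = sub$atoms,
                 member_labels = pooled$sub_ids %||%
                   rep(pooled$label, n_members(pooled)),
                 ensemble = sub),
            class = "mode_decomposition")
}

#' @export
print.mode_decomposition <- function(x, ...) {
  tot <- sum(x$eigenvalues)
  cat(sprintf("mode_decomposition: %d members, %d atoms; PC1 %.1f%%, PC2 %.1f%% of variance\n",
              nrow(x$projections), nrow(x$atoms),
              100 * x$eigenvalues[1] / tot, 100 * x$eigenvalues[2] / tot))
  invisible(x)
}

#' Per-residue square fluctuations of one PCA mode
#'
#' The contribution of a mode to the coordinate variance of each residue:
#' eigenvalue times the summed squared x, y, z components of the residue
#' in the unit mode vector. Summed over residues this equals the
#' eigenvalue.
#'
#' @param decomposition a \code{mode_decomposition}.
#' @param mode_index mode number (1 = largest eigenvalue).
#' @return named numeric vector (residue number -> Angstrom^2).
#' @export
square_fluctuations <- function(decomposition, mode_index = 1L) {
  k <- ncol(decomposition$modes)
  if (mode_index < 1L || mode_index > k)
    stop("mode_index must be in 1..", k)
  v <- decomposition$modes[, mode_index]
  lam <- decomposition$eigenvalues[mode_index]
  per_atom <- rowSums(xyz_to_mat(v)^2)
  res <- decomposition$atoms$resno
  out <- tapply(lam * per_atom, res, sum)
  stats::setNames(as.numeric(out), names(out))
}

#' Correlation of Calpha-Calpha distances with a mode's projections
#'
#' For every residue pair, the Pearson correlation between the member-wise
#' Calpha-Calpha distance and the member-wise projection on the chosen
#' mode. Pairs whose distance has zero variance across members are flagged
#' \code{NA}, not 0.
#'
#' @param decomposition a \code{mode_decomposition} (its superposed pooled
#'   ensemble and projections are used).
#' @param mode_index mode number.
#' @return object of class \code{distance_mode_correlation}: a symmetric
#'   residue-by-residue matrix of correlations with \code{NA} diagonal,
#'   with the mode index in attribute \code{"mode_index"}.
#' @export
distance_mode_correlation <- function(decomposition, mode_index = 1L) {
  ens <- decomposition$ensemble
  proj <- decomposition$projections[, mode_index]
  res <- sort(unique(ens$atoms$resno))
  ca <- vapply(res, function(r) find_atom(ens$atoms, r, "CA"), integer(1))
  if (anyNA(ca)) {
    res <- res[!is.na(ca)]
    ca <- ca[!is.na(ca)]
  }
  nr <- length(res)
  nm <- n_members(ens)
  # member x atom coordinate slabs
  cx <- ens$xyz[, 3 * (ca - 1) + 1, drop = FALSE]
  cy <- ens$xyz[, 3 * (ca - 1) + 2, drop = FALSE]
  cz <- ens$xyz[, 3 * (ca - 1) + 3, drop = FALSE]
  M <- matrix(NA_real_, nr, nr, dimnames = list(res, res))
  pv <- proj - mean(proj)
  pss <- sqrt(sum(pv^2))
  for (i in seq_len(nr - 1)) {
    di <- sqrt((cx[, (i + 1):nr, drop = FALSE] - cx[, i])^2 +
               (cy[, (i + 1):nr, drop = FALSE] - cy[, i])^2 +
               (cz[, (i + 1):nr, drop = FALSE] - cz[, i])^2)
    dc <- sweep(di, 2, colMeans(di))
    dss <- sqrt(colSums(dc^2))
    r <- as.numeric(crossprod(dc, pv)) / (dss * pss)
    r[dss == 0] <- NA_real_
    M[i, (i + 1):nr] <- r
    M[(i + 1):nr, i] <- r
  }
  structure(M, mode_index = mode_index, class = "distance_mode_correlation")
}

#' Most strongly mode-correlated residue pairs
#'
#' @param matrix a \code{distance_mode_correlation}.
#' @param k number of pairs to return; truncated with a warning when fewer
#'   are available.
#' @param sign \code{"both"} ranks by |correlation|; \code{"positive"} or
#'   \code{"negative"} restrict to that sign first.
#' @return data.frame with \code{res_i}, \code{res_j} (res_i < res_j) and
#'   \code{correlation}, ordered by decreasing |correlation|; ties broken
#'   by (lower first residue, then second).
#' @export
top_correlated_pairs <- function(matrix, k, sign = c("both", "positive", "negative")) {
  sign <- match.arg(sign)
  res <- as.integer(rownames(matrix))
  ut <- which(upper.tri(matrix), arr.ind = TRUE)
  vals <- matrix[ut]
  keep <- !is.na(vals)
  if (sign == "positive") keep <- keep & vals > 0
  if (sign == "negative") keep <- keep & vals < 0
  ut <- ut[keep, , drop = FALSE]
  vals <- vals[keep]
  if (k > length(vals)) {
    warning("only ", length(vals), " pairs available; truncating k")
    k <- length(vals)
  }
  if (k == 0L)
    return(data.frame(res_i = integer(), res_j = integer(),
                      correlation = numeric()))
  ord <- order(-abs(vals), res[ut[, 1]], res[ut[, 2]])[seq_len(k)]
  data.frame(res_i = res[ut[ord, 1]], res_j = res[ut[ord, 2]],
             correlation = vals[ord])
}

#' Persist a mode decomposition
#'
#' Writes the mean structure (PDB), the modes and eigenvalues in NMD
#' format (readable by common normal-mode viewers), and the projections as
#' CSV.
#'
#' @param decomposition a \code{mode_decomposition}.
#' @param prefix output path prefix; files \code{<prefix>_mean.pdb},
#'   \code{<prefix>.nmd} and \code{<prefix>_projections.csv} are written.
#' @param n_modes number of modes to write to the NMD file.
#' @return invisibly, the paths written.
#' @export
write_mode_decomposition <- function(decomposition, prefix, n_modes = 2L) {
  d <- decomposition
  mean_path <- paste0(prefix, "_mean.pdb")
  bio3d::write.pdb(file = mean_path, xyz = mat_to_xyz(d$mean),
                   resno = d$atoms$resno, resid = d$atoms$resid,
                   elety = d$atoms$elety, chain = d$atoms$chain)
  nmd_path <- paste0(prefix, ".nmd")
  con <- file(nmd_path, "w")
  on.exit(close(con))
  writeLines(c(
    paste("title", basename(prefix)),
    paste("names", paste(d$atoms$elety, collapse = " ")),
    paste("resnames", paste(d$atoms$resid, collapse = " ")),
    paste("resids", paste(d$atoms$resno, collapse = " ")),
    paste("coordinates", paste(sprintf("%.3f", mat_to_xyz(d$mean)), collapse = " "))
  ), con)
  for (k in seq_len(min(n_modes, ncol(d$modes)))) {
    writeLines(paste("mode", k, sprintf("%.6f", sqrt(d$eigenvalues[k])),
                     paste(sprintf("%.6f", d$modes[, k]), collapse = " ")), con)
  }
  proj_path <- paste0(prefix, "_projections.csv")
  pr <- as.data.frame(d$projections[, seq_len(min(n_modes, ncol(d$projections))),
                                    drop = FALSE])
  names(pr) <- paste0("PC", seq_along(pr))
  pr <- cbind(member = seq_len(nrow(pr)), source = d$member_labels, pr)
  utils::write.csv(pr, proj_path, row.names = FALSE)
  invisible(c(mean_path, nmd_path, proj_path))
}
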