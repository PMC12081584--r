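#' Kabsch superposition of one coordinate set onto another
#'
#' Least-squares rigid-body superposition (proper rotation only, det = +1)
#' of `mobile` onto `ref`, fitted on `selection` and applied to all atoms.
#'
#' @param mobile,ref n x 3 coordinate matrices (angstrom).
#' @param selection optional row indices used for the fit (default: all).
#' @return A list with `rmsd` (angstrom, over the fitted selection) and
#'   `coords` (the transformed mobile coordinates, all rows).
#' @export
kabsch_superpose <- function(mobile, ref, selection = NULL) {
  mobile <- as.matrix(mobile); ref <- as.matrix(ref)
  if (is.null(selection)) {
    if (nrow(mobile) != nrow(ref)) stop("selected atom counts differ")
    selection <- seq_len(nrow(mobile))
  }
  ms <- mobile[selection, , drop = FALSE]
  rs <- ref[selection, , drop = FALSE]
  if (nrow(ms) != nrow(rs)) stop("selected atom counts differ")
  if (nrow(ms) < 3L) stop("need at least 3 atoms to superpose")
  cm <- colMeans(ms); cr <- colMeans(rs)
  A <- sweep(ms, 2, cm); B <- sweep(rs, 2, cr)
  s <- svd(crossprod(A, B))          # H = A^T B
  d <- sign(det(s$v %*% t(s$u)))
  if (d == 0) stop("degenerate (collinear) coordinates")
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  fitted <- sweep(sweep(mobile, 2, cm) %*% t(R), 2, cr, "+")
  rmsd <- sqrt(mean(rowSums((fitted[selection, , drop = FALSE] - rs)^2)))
  list(rmsd = rmsd, coords = fitted)
}

#' Superposition-minimised RMSD of every frame against a fixed reference
#'
#' @param traj a [trajectory_ensemble()].
#' @param ref_structure reference [structure_model()] (or n x 3 matrix) with
#'   the same atom roster.
#' @param selection atom selection (names, indices or logical on the roster)
#'   used both for fitting and for the RMSD.
#' @return Data frame with `time` (ns) and `rmsd` (angstrom).
#' @export
rmsd_series <- function(traj, ref_structure, selection = NULL) {
  idx <- resolve_selection(traj$roster, selection)
  ref <- if (inherits(ref_structure, "structure_model")) coords(ref_structure)
         else as.matrix(ref_structure)
  r <- vapply(traj$frames,
              function(f) kabsch_superpose(f[idx, , drop = FALSE],
                                           ref[idx, , drop = FALSE])$rmsd,
              numeric(1))
  data.frame(time = traj$times, rmsd = r)
}

pairwise_rmsd_matrix <- function(traj, idx) {
  nf <- length(traj$frames)
  sel <- lapply(traj$frames, function(f) f[idx, , drop = FALSE])
  M <- matrix(0, nf, nf)
  for (i in seq_len(nf - 1)) for (j in (i + 1):nf) {
    M[i, j] <- M[j, i] <- kabsch_superpose(sel[[i]], sel[[j]])$rmsd
  }
  M
}

#' GROMOS-style conformational clustering of trajectory frames
#'
#' Computes the pairwise superposition-RMSD matrix on the selection, then
#' repeatedly takes the frame with the most neighbours within `cutoff` as a
#' cluster centre (ties broken by lowest frame index), assigns it and its
#' neighbours to a cluster, removes them and repeats. Clusters are ordered by
#' decreasing population.
#'
#' @param traj a [trajectory_ensemble()].
#' @param selection atom selection on the roster (default all atoms).
#' @param cutoff RMSD neighbour cutoff in angstrom (default 2.0, i.e. 0.2 nm).
#' @return A list of class `cluster_assignment` with `labels` (per-frame
#'   cluster index, 1 = most populated), `centers` (per-cluster representative
#'   frame index), `populations` and `cutoff`.
#' @export
cluster_gromos <- function(traj, selection = NULL, cutoff = 2.0) {
  if (cutoff <= 0) stop("cutoff must be > 0")
  nf <- length(traj$frames)
  if (nf == 0L) stop("empty trajectory")
  idx <- resolve_selection(traj$roster, selection)
  M <- pairwise_rmsd_matrix(traj, idx)
  remaining <- rep(TRUE, nf)
  labels <- integer(nf)
  centers <- integer(0)
  populations <- integer(0)
  k <- 0L
  while (any(remaining)) {
    k <- k + 1L
    counts <- vapply(seq_len(nf), function(i) {
      if (!remaining[i]) return(-1L)
      sum(M[i, remaining] <= cutoff)   # includes self
    }, integer(1))
    center <- which.max(counts)        # lowest index wins ties
    members <- which(remaining & M[center, ] <= cutoff)
    labels[members] <- k
    centers[k] <- center
    populations[k] <- length(members)
    remaining[members] <- FALSE
  }
  ord <- order(-populations, centers)
  relabel <- integer(k); relabel[ord] <- seq_len(k)
  structure(list(labels = relabel[labels], centers = centers[ord],
                 populations = populations[ord], cutoff = cutoff),
            class = "cluster_assignment")
}

#' Per-residue root-mean-square fluctuation about a reference frame
#'
#' Each frame is superposed onto the reference frame on the selection; the
#' per-atom RMS deviation from the reference positions is then averaged
#' within residues. When `reference_frame_index` is `NULL` the centre of the
#' most populated GROMOS cluster is used, mirroring the practice of taking
#' the representative structure of the dominant conformational state.
#'
#' @param traj a [trajectory_ensemble()].
#' @param reference_frame_index frame index of the reference, or `NULL`.
#' @param selection atom selection on the roster (default all atoms).
#' @param cluster_cutoff cutoff passed to [cluster_gromos()] when the
#'   reference is derived from clustering.
#' @return Data frame with `chain_id`, `residue_id` and `rmsf` (angstrom).
#' @export
rmsf <- function(traj, reference_frame_index = NULL, selection = NULL,
                 cluster_cutoff = 2.0) {
  nf <- length(traj$frames)
  if (nf == 0L) stop("empty trajectory window")
  if (is.null(reference_frame_index)) {
    cl <- cluster_gromos(traj, selection, cluster_cutoff)
    reference_frame_index <- cl$centers[1]
  }
  if (reference_frame_index < 1 || reference_frame_index > nf)
    stop("reference frame index out of range")
  idx <- resolve_selection(traj$roster, selection)
  ref <- traj$frames[[reference_frame_index]]
  sq <- matrix(0, nrow = length(idx), ncol = nf)
  for (i in seq_len(nf)) {
    fit <- kabsch_superpose(traj$frames[[i]], ref, selection = idx)$coords
    sq[, i] <- rowSums((fit[idx, , drop = FALSE] - ref[idx, , drop = FALSE])^2)
  }
  atom_rmsf <- sqrt(rowMeans(sq))
  key <- paste(traj$roster$chain_id[idx], traj$roster$residue_id[idx])
  agg <- tapply(atom_rmsf, key, mean)
  parts <- do.call(rbind, strsplit(names(agg), " "))
  out <- data.frame(chain_id = parts[, 1], residue_id = as.integer(parts[, 2]),
                    rmsf = as.numeric(agg), stringsAsFactors = FALSE)
  out[order(out$chain_id, out$residue_id), , drop = FALSE]
}

#' Gate-perimeter time series of a tetrameric channel
#'
#' Locates the single matching atom per chain (exactly four chains), fixes
#' their cyclic order by azimuth about the pore axis in the first frame, and
#' reports per frame the four adjacent-pair distances and their sum.
#'
#' @param traj a [trajectory_ensemble()].
#' @param gate_residue_id residue number of the gate residue (e.g. 173).
#' @param atom_name atom name to monitor (default `"CA"`).
#' @return A list of class `aperture_series` with `times` (ns),
#'   `perimeter` (angstrom) and `pair_distances` (n x 4 matrix, angstrom).
#' @export
gate_perimeter <- function(traj, gate_residue_id, atom_name = "CA") {
  roster <- traj$roster
  idx <- which(roster$residue_id == gate_residue_id & roster$name == atom_name)
  if (length(idx) != 4L || length(unique(roster$chain_id[idx])) != 4L)
    stop(sprintf("expected exactly 4 gate atoms (one per chain), found %d",
                 length(idx)))
  g0 <- traj$frames[[1]][idx, , drop = FALSE]
  ctr <- colMeans(g0)
  cg <- sweep(g0, 2, ctr)
  ev <- eigen(crossprod(cg), symmetric = TRUE)
  axis <- ev$vectors[, 3]                       # pore axis ~ plane normal
  e1 <- ev$vectors[, 1]; e2 <- ev$vectors[, 2]
  az <- atan2(cg %*% e2, cg %*% e1)
  ord <- idx[order(az)]
  nf <- length(traj$frames)
  pd <- matrix(NA_real_, nf, 4,
               dimnames = list(NULL, paste0("d", 1:4)))
  for (i in seq_len(nf)) {
    g <- traj$frames[[i]][ord, , drop = FALSE]
    nxt <- c(2:4, 1)
    pd[i, ] <- sqrt(rowSums((g - g[nxt, , drop = FALSE])^2))
  }
  structure(list(times = traj$times, perimeter = rowSums(pd),
                 pair_distances = pd, axis = axis),
            class = "aperture_series")
}

#' Summary statistics of a time series over a time window
#'
#' @param series an `aperture_series`, or a list/data frame with `times` and a
#'   numeric value vector (`perimeter` or `value`).
#' @param t_start,t_end window bounds in ns; frames with
#'   `t_start <= t <= t_end` are used (set `right_closed = FALSE` for a
#'   half-open window, as used for trailing analysis windows).
#' @param right_closed include the right endpoint (default `TRUE`).
#' @return A list with `median`, `mean`, `sd` (n-1), `iqr` and `n`.
#' @export
window_summary <- function(series, t_start, t_end, right_closed = TRUE) {
  v <- if (!is.null(series$perimeter)) series$perimeter else series$value
  t <- series$times
  keep <- t >= t_start & (if (right_closed) t <= t_end else t < t_end)
  if (!any(keep)) stop("window contains no frames")
  x <- v[keep]
  list(median = stats::median(x), mean = mean(x),
       sd = if (length(x) > 1) stats::sd(x) else 0,
       iqr = stats::IQR(x), n = length(x))
}

#' Summary over the trailing window of a series
#'
#' Convenience wrapper for "last w ns" analysis windows: the half-open window
#' `[t_max - w, t_max]` (right endpoint included so the final frame counts).
#'
#' @param series as in [window_summary()].
#' @param w window length in ns.
#' @return See [window_summary()].
#' @export
last_window_summary <- function(series, w) {
  tmax <- max(series$times)
  window_summary(series, tmax - w, tmax, right_closed = TRUE)
}
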