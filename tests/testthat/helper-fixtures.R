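# Shared fixtures and independent oracles used across the test files.

std_tetramer <- function(seed = 1, side = 15.51) {
  gen_toy_tetramer(tetramer_spec(residues_per_chain = 12, gate_residue_index = 6,
                                 gate_side_length = side, seed = seed))
}

# Brute-force minimum RMSD over rigid motions: coarse Euler-angle grid then
# Nelder-Mead refinement. Independent of the SVD route under test.
bruteforce_rmsd <- function(mobile, ref) {
  rotmat <- function(a, b, g) {
    Rz1 <- matrix(c(cos(a), -sin(a), 0, sin(a), cos(a), 0, 0, 0, 1), 3, byrow = TRUE)
    Ry <- matrix(c(cos(b), 0, sin(b), 0, 1, 0, -sin(b), 0, cos(b)), 3, byrow = TRUE)
    Rz2 <- matrix(c(cos(g), -sin(g), 0, sin(g), cos(g), 0, 0, 0, 1), 3, byrow = TRUE)
    Rz1 %*% Ry %*% Rz2
  }
  A <- sweep(mobile, 2, colMeans(mobile))
  B <- sweep(ref, 2, colMeans(ref))
  obj <- function(ang) {
    R <- rotmat(ang[1], ang[2], ang[3])
    sqrt(mean(rowSums((A %*% t(R) - B)^2)))
  }
  grid <- expand.grid(a = seq(0, 2 * pi, length.out = 13)[-13],
                      b = seq(0, pi, length.out = 7),
                      g = seq(0, 2 * pi, length.out = 13)[-13])
  vals <- apply(grid, 1, obj)
  best <- as.numeric(grid[which.min(vals), ])
  stats::optim(best, obj, method = "Nelder-Mead",
               control = list(reltol = 1e-14, maxit = 5000))$value
}

# Independent GROMOS-style greedy clustering on a distance matrix computed
# with bio3d's fitted RMSD (different superposition code path).
oracle_gromos <- function(traj, cutoff) {
  nf <- length(traj$frames)
  xyz <- do.call(rbind, lapply(traj$frames, function(f) as.vector(t(f))))
  M <- matrix(0, nf, nf)
  for (i in seq_len(nf - 1)) for (j in (i + 1):nf) {
    M[i, j] <- M[j, i] <- bio3d::rmsd(xyz[i, ], xyz[j, ], fit = TRUE)
  }
  remaining <- rep(TRUE, nf)
  labels <- integer(nf); centers <- integer(0); pops <- integer(0)
  k <- 0L
  while (any(remaining)) {
    k <- k + 1L
    counts <- sapply(seq_len(nf), function(i)
      if (remaining[i]) sum(M[i, remaining] <= cutoff) else -1L)
    ctr <- which.max(counts)
    mem <- which(remaining & M[ctr, ] <= cutoff)
    labels[mem] <- k; centers[k] <- ctr; pops[k] <- length(mem)
    remaining[mem] <- FALSE
  }
  ord <- order(-pops, centers)
  relab <- integer(k); relab[ord] <- seq_len(k)
  list(labels = relab[labels], centers = centers[ord], populations = pops[ord])
}

random_rotation <- function(angle = NULL) {
  ax <- stats::rnorm(3); ax <- ax / sqrt(sum(ax^2))
  th <- if (is.null(angle)) stats::runif(1, 0, 2 * pi) else angle
  K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0), 3, byrow = TRUE)
  diag(3) + sin(th) * K + (1 - cos(th)) * K %*% K
}
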