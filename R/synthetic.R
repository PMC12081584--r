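#' Specification of a four-fold-symmetric toy tetramer
#'
#' Desk-scale stand-in for a tetrameric inward-rectifier channel: four chains
#' related by 90 degree rotations about the z axis, one alpha-carbon analogue
#' per residue, and a tagged gate residue per chain whose four atoms form a
#' square of side `gate_side_length`.
#'
#' @param residues_per_chain residues per chain (>= `gate_residue_index`).
#' @param gate_residue_index 1-based index of the gate residue within a chain.
#' @param gate_side_length distance between adjacent gate atoms, angstrom.
#' @param seed integer RNG seed; generation is a pure function of the specification object.
#' @return A list of class `tetramer_spec`.
#' @export
tetramer_spec <- function(residues_per_chain = 20L, gate_residue_index = 10L,
                          gate_side_length = 15.51, seed = 1L) {
  if (gate_side_length <= 0) stop("gate_side_length must be > 0")
  if (gate_residue_index < 1L || residues_per_chain < gate_residue_index)
    stop("need residues_per_chain >= gate_residue_index >= 1")
  structure(list(chains = 4L,
                 residues_per_chain = as.integer(residues_per_chain),
                 gate_residue_index = as.integer(gate_residue_index),
                 gate_side_length = gate_side_length,
                 seed = as.integer(seed)),
            class = "tetramer_spec")
}

#' Generate a four-fold-symmetric toy tetramer structure
#'
#' Chain A is laid out on a loose helix around the z axis with seeded
#' positional variation; chains B, C and D are exact 90/180/270 degree
#' rotations of chain A, so the four gate alpha-carbon analogues form a
#' perfect square of side `gate_side_length` (perimeter 4 x side).
#'
#' @param spec a [tetramer_spec()].
#' @return A [structure_model()] with one `CA` atom per residue, carbon
#'   radii (1.9 angstrom) and zero charges.
#' @export
gen_toy_tetramer <- function(spec) {
  if (!inherits(spec, "tetramer_spec")) spec <- do.call(tetramer_spec, spec)
  m <- spec$residues_per_chain
  gate_r <- spec$gate_side_length / sqrt(2)   # circumradius of the gate square
  chainA <- with_seed(spec$seed, {
    # helical walk within the first quadrant's azimuthal sector
    phi <- pi / 4 + stats::runif(m, -0.55, 0.55)
    rad <- gate_r + stats::runif(m, -2.5, 2.5)
    z <- seq(0, by = 1.5, length.out = m) + stats::runif(m, -0.3, 0.3)
    g <- spec$gate_residue_index
    phi[g] <- pi / 4
    rad[g] <- gate_r
    z[g] <- (g - 1) * 1.5
    cbind(rad * cos(phi), rad * sin(phi), z)
  })
  rot90 <- function(xyz, k) {
    a <- k * pi / 2
    R <- matrix(c(cos(a), -sin(a), 0, sin(a), cos(a), 0, 0, 0, 1), 3, 3, byrow = TRUE)
    xyz %*% t(R)
  }
  xyz <- do.call(rbind, lapply(0:3, function(k) rot90(chainA, k)))
  n <- 4L * m
  structure_model(
    atom_id = seq_len(n), name = "CA",
    residue_name = ifelse(rep(seq_len(m), 4L) == spec$gate_residue_index, "GLN", "ALA"),
    residue_id = rep(seq_len(m), 4L),
    chain_id = rep(c("A", "B", "C", "D"), each = m),
    xyz = xyz, radius = 1.9, charge = 0
  )
}

#' Specification of stochastic gate-aperture drift
#'
#' The gate perimeter follows an Ornstein-Uhlenbeck (OU) path
#' `dP = reversion_rate (mean_perimeter - P) dt + volatility dW`; all atoms
#' additionally receive independent Gaussian jitter each frame.
#'
#' @param mean_perimeter long-run mean gate perimeter, angstrom.
#' @param reversion_rate OU mean-reversion rate, 1/ns (>= 0).
#' @param volatility OU volatility, angstrom/sqrt(ns) (>= 0).
#' @param frame_dt frame spacing, ns.
#' @param n_frames number of frames (>= 2).
#' @param jitter_sd per-atom, per-coordinate Gaussian jitter sd, angstrom.
#' @param seed integer RNG seed.
#' @return A list of class `aperture_drift_spec`.
#' @export
aperture_drift_spec <- function(mean_perimeter = 60, reversion_rate = 2,
                                volatility = 1, frame_dt = 0.01,
                                n_frames = 1000L, jitter_sd = 0.05, seed = 1L) {
  if (reversion_rate < 0 || volatility < 0) stop("rate and volatility must be >= 0")
  if (n_frames < 2L) stop("n_frames must be >= 2")
  structure(list(mean_perimeter = mean_perimeter, reversion_rate = reversion_rate,
                 volatility = volatility, frame_dt = frame_dt,
                 n_frames = as.integer(n_frames), jitter_sd = jitter_sd,
                 seed = as.integer(seed)),
            class = "aperture_drift_spec")
}

#' Generate a synthetic trajectory with OU gate-aperture drift
#'
#' The perimeter path uses the exact OU transition density (initialised at the
#' mean), realised by radially rescaling the four gate atoms each frame;
#' independent Gaussian jitter is then added to every atom. Deterministic
#' under the specification seed.
#'
#' @param structure a tetramer [structure_model()] from [gen_toy_tetramer()]
#'   (one tagged gate residue per chain, residue name `GLN`).
#' @param drift an [aperture_drift_spec()].
#' @return A [trajectory_ensemble()].
#' @export
gen_trajectory <- function(structure, drift) {
  if (!inherits(drift, "aperture_drift_spec")) drift <- do.call(aperture_drift_spec, drift)
  gate_idx <- which(structure$residue_name == "GLN")
  if (length(gate_idx) != 4L || length(unique(structure$chain_id[gate_idx])) != 4L)
    stop("structure must carry exactly one tagged gate residue per chain")
  base <- coords(structure)
  # current gate square side from adjacent distances in frame geometry
  g <- base[gate_idx, , drop = FALSE]
  r0 <- sqrt(rowSums(sweep(g[, 1:2], 2, colMeans(g[, 1:2]))^2))
  P0 <- 4 * mean(r0) * sqrt(2)
  th <- drift$reversion_rate; sg <- drift$volatility; dt <- drift$frame_dt
  nf <- drift$n_frames
  with_seed(drift$seed, {
    P <- numeric(nf)
    P[1] <- drift$mean_perimeter
    if (nf > 1) {
      if (th > 0) {
        decay <- exp(-th * dt)
        sdq <- sg * sqrt((1 - exp(-2 * th * dt)) / (2 * th))
      } else {
        decay <- 1
        sdq <- sg * sqrt(dt)
      }
      eps <- stats::rnorm(nf - 1)
      for (k in 2:nf)
        P[k] <- drift$mean_perimeter + (P[k - 1] - drift$mean_perimeter) * decay +
          sdq * eps[k - 1]
    }
    frames <- vector("list", nf)
    for (k in seq_len(nf)) {
      f <- base
      scale <- P[k] / P0
      f[gate_idx, 1:2] <- f[gate_idx, 1:2] * scale
      if (drift$jitter_sd > 0)
        f <- f + matrix(stats::rnorm(length(f), sd = drift$jitter_sd), nrow = nrow(f))
      frames[[k]] <- f
    }
    trajectory_ensemble(frames, times = (seq_len(nf) - 1) * dt, roster = structure)
  })
}

#' Generate a receptor/ligand charge system with known ground truth
#'
#' Three geometries: `two_point_charges` (one +1e and one -1e atom at a fixed
#' separation, with the analytic Coulomb energy attached), `separated_clusters`
#' (two random blobs too far apart for any surface burial) and
#' `contact_complex` (two touching blobs).
#'
#' @param n_receptor_atoms,n_ligand_atoms atom counts (ignored for
#'   `two_point_charges`, which is always 1 + 1).
#' @param geometry one of `"two_point_charges"`, `"separated_clusters"`,
#'   `"contact_complex"`.
#' @param seed integer RNG seed.
#' @param separation centre separation in angstrom (default 10 for point
#'   charges, 100 for separated clusters, 6 for contact complexes).
#' @return A list with `receptor` and `ligand` [structure_model()]s; for
#'   `two_point_charges` also `analytic`, a function of the dielectric
#'   returning the exact Coulomb energy in kJ/mol.
#' @export
gen_charge_system <- function(n_receptor_atoms = 5L, n_ligand_atoms = 5L,
                              geometry = c("two_point_charges",
                                           "separated_clusters",
                                           "contact_complex"),
                              seed = 1L, separation = NULL) {
  geometry <- match.arg(geometry)
  blob <- function(n, centre, id0, chain) {
    xyz <- sweep(matrix(stats::rnorm(n * 3, sd = 1.5), ncol = 3), 2, centre, "+")
    structure_model(atom_id = id0 + seq_len(n), name = "C",
                    residue_name = "LIG", residue_id = 1L, chain_id = chain,
                    xyz = xyz, radius = stats::runif(n, 1.2, 2.0),
                    charge = stats::runif(n, -0.5, 0.5))
  }
  with_seed(seed, switch(geometry,
    two_point_charges = {
      d <- if (is.null(separation)) 10 else separation
      rec <- structure_model(1L, "Q1", "ION", 1L, "R", matrix(c(0, 0, 0), 1),
                             radius = 1.5, charge = 1)
      lig <- structure_model(2L, "Q2", "ION", 1L, "L", matrix(c(d, 0, 0), 1),
                             radius = 1.5, charge = -1)
      list(receptor = rec, ligand = lig,
           analytic = function(dielectric = 1)
             coulomb_k() * 1 * (-1) / (dielectric * d))
    },
    separated_clusters = {
      d <- if (is.null(separation)) 100 else separation
      list(receptor = blob(n_receptor_atoms, c(0, 0, 0), 0L, "R"),
           ligand = blob(n_ligand_atoms, c(d, 0, 0), n_receptor_atoms, "L"))
    },
    contact_complex = {
      d <- if (is.null(separation)) 6 else separation
      list(receptor = blob(n_receptor_atoms, c(0, 0, 0), 0L, "R"),
           ligand = blob(n_ligand_atoms, c(d, 0, 0), n_receptor_atoms, "L"))
    }))
}

#' Published per-cluster binding-energy components (kJ/mol)
#'
#' The nine cluster rows of the reference decomposition of ATP-Kir6.2 binding
#' at 0, 25 and 50 percent membrane cholesterol: solvation, Coulomb and
#' nonpolar components plus their sum. The 0\%/Cluster1 Coulomb entry is
#' stored as -73 kJ/mol: only the negative sign is consistent with both that
#' row's printed sum (231 - 73 - 52 = 106) and the printed column mean (-141).
#'
#' @return An `energy_table` data frame with 9 rows.
#' @export
table1_components <- function() {
  df <- data.frame(
    condition = rep(c("0%", "25%", "50%"), each = 3),
    cluster = rep(paste0("Cluster", 1:3), 3),
    dG_solv   = c(231, 251, 264,  299, 326, 239,  243, 240, 271),
    dG_coul   = c(-73, -112, -238, -171, -54, -115, -162, -54, -122),
    dG_nonelec = c(-52, -58, -55,  -60, -56, -60,  -56, -59, -59),
    stringsAsFactors = FALSE
  )
  df$dG_b <- df$dG_solv + df$dG_coul + df$dG_nonelec
  class(df) <- c("energy_table", "data.frame")
  df
}

#' Generate (and optionally write) an energy-component fixture table
#'
#' Always contains the nine packaged reference cluster rows
#' ([table1_components()]); any extra condition labels get three synthetic
#' cluster rows whose `dG_b` equals the component sum by construction.
#'
#' @param condition_labels extra synthetic condition labels (may be empty).
#' @param seed integer RNG seed for the synthetic rows.
#' @param path optional path; when given the table is also written as CSV.
#' @return The `energy_table` data frame.
#' @export
gen_energy_fixture <- function(condition_labels = character(), seed = 1L,
                               path = NULL) {
  df <- table1_components()
  if (length(condition_labels)) {
    extra <- with_seed(seed, do.call(rbind, lapply(condition_labels, function(lab) {
      solv <- round(stats::rnorm(3, 260, 30))
      coul <- round(stats::rnorm(3, -120, 50))
      nonp <- round(stats::rnorm(3, -57, 2))
      data.frame(condition = lab, cluster = paste0("Cluster", 1:3),
                 dG_solv = solv, dG_coul = coul, dG_nonelec = nonp,
                 dG_b = solv + coul + nonp, stringsAsFactors = FALSE)
    })))
    df <- rbind(as.data.frame(df), extra)
    class(df) <- c("energy_table", "data.frame")
  }
  if (!is.null(path)) write_results_table(df, path)
  df
}
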