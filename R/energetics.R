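# Coulomb constant in kJ * angstrom / (mol * e^2): 1/(4 pi eps0) in these units.
coulomb_k <- function() 1389.35

fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Shrake-Rupley solvent-accessible surface area
#'
#' Quasi-uniform points (Fibonacci lattice) are placed on each atom's sphere
#' inflated by the probe radius; the accessible fraction is the share of
#' points not inside any other atom's inflated sphere, scaled by
#' `4 pi (r_i + probe)^2`.
#'
#' @param structure a [structure_model()] with radii on every atom.
#' @param probe_radius solvent probe radius, angstrom (default 1.4).
#' @param n_points sphere points per atom (>= 100; default 960).
#' @return A list of class `sasa_result` with `total` and `per_atom`
#'   (angstrom^2), `probe_radius` and `n_sphere_points`.
#' @export
sasa_shrake_rupley <- function(structure, probe_radius = 1.4, n_points = 960L) {
  if (n_points < 100L) stop("n_points must be >= 100")
  r <- structure$radius
  if (any(is.na(r))) stop("every atom needs a radius for SASA")
  xyz <- coords(structure)
  n <- nrow(xyz)
  pts <- fibonacci_sphere(n_points)
  inflated <- r + probe_radius
  per_atom <- numeric(n)
  d2 <- as.matrix(stats::dist(xyz))^2
  for (i in seq_len(n)) {
    nb <- which(d2[i, ] < (inflated[i] + inflated)^2 & seq_len(n) != i)
    p <- sweep(pts * inflated[i], 2, xyz[i, ], "+")
    acc <- rep(TRUE, n_points)
    for (j in nb) {
      if (!any(acc)) break
      dj <- (p[, 1] - xyz[j, 1])^2 + (p[, 2] - xyz[j, 2])^2 + (p[, 3] - xyz[j, 3])^2
      acc <- acc & dj >= inflated[j]^2
    }
    per_atom[i] <- mean(acc) * 4 * pi * inflated[i]^2
  }
  structure(list(total = sum(per_atom), per_atom = per_atom,
                 probe_radius = probe_radius, n_sphere_points = as.integer(n_points)),
            class = "sasa_result")
}

#' Change in solvent-accessible surface area upon complex formation
#'
#' `ASA(complex) - ASA(receptor) - ASA(ligand)`; non-positive for any contact
#' complex (zero when the partners do not occlude each other).
#'
#' @param complex a [structure_model()] whose atoms are the receptor atoms
#'   followed by the ligand atoms (same names/residues, complex coordinates).
#' @param receptor,ligand the isolated partners.
#' @param probe_radius,n_points see [sasa_shrake_rupley()].
#' @return Delta-ASA in angstrom^2.
#' @export
delta_asa <- function(complex, receptor, ligand, probe_radius = 1.4,
                      n_points = 960L) {
  key <- function(m) paste(m$name, m$residue_name, m$residue_id, m$chain_id)
  if (!identical(key(complex), c(key(receptor), key(ligand))))
    stop("complex roster must be the receptor atoms followed by the ligand atoms")
  sasa_shrake_rupley(complex, probe_radius, n_points)$total -
    sasa_shrake_rupley(receptor, probe_radius, n_points)$total -
    sasa_shrake_rupley(ligand, probe_radius, n_points)$total
}

#' Nonpolar (surface-tension) contribution to the binding energy
#'
#' `gamma * delta_asa`, with the interfacial-tension coefficient
#' gamma = 0.021 kJ/(mol angstrom^2) by default.
#'
#' @param delta_asa change in accessible surface area, angstrom^2.
#' @param gamma interfacial tension, kJ/(mol angstrom^2) (> 0).
#' @return Energy in kJ/mol.
#' @export
nonpolar_energy <- function(delta_asa, gamma = 0.021) {
  if (gamma <= 0) stop("gamma must be > 0")
  gamma * delta_asa
}

#' Uniform-dielectric Coulomb interaction energy between binding partners
#'
#' Sum over receptor-ligand atom pairs of `k q_i q_j / (dielectric r_ij)`,
#' `k = 1389.35 kJ angstrom / (mol e^2)`; intramolecular pairs are excluded.
#' This is the in-package analogue of the Coulombic component of an
#' implicit-solvent electrostatics calculation.
#'
#' @param receptor,ligand [structure_model()]s with charges populated.
#' @param dielectric relative dielectric constant (> 0), e.g. 4 for the
#'   protein interior.
#' @return Energy in kJ/mol.
#' @export
coulomb_energy <- function(receptor, ligand, dielectric = 4) {
  if (dielectric <= 0) stop("dielectric must be > 0")
  qr <- receptor$charge; ql <- ligand$charge
  if (any(is.na(qr)) || any(is.na(ql))) stop("charges must be populated")
  xr <- coords(receptor); xl <- coords(ligand)
  d2 <- outer(rowSums(xr^2), rowSums(xl^2), "+") - 2 * xr %*% t(xl)
  d <- sqrt(pmax(d2, 0))
  if (any(d < 1e-6)) stop("overlapping atoms between partners (r < 1e-6 angstrom)")
  coulomb_k() / dielectric * sum(outer(qr, ql) / d)
}

#' Assemble binding energies from their components
#'
#' `dG_b = dG_solv + dG_coul + dG_nonelec` (exact sum), the implicit-solvent
#' decomposition of the binding free energy. Vectorised over clusters.
#'
#' @param dG_solv,dG_coul,dG_nonelec component energies, kJ/mol.
#' @param condition,cluster optional labels.
#' @return An `energy_table` data frame with a `dG_b` column.
#' @export
assemble_binding_energy <- function(dG_solv, dG_coul, dG_nonelec,
                                    condition = NA_character_,
                                    cluster = NA_character_) {
  if (anyNA(dG_solv) || anyNA(dG_coul) || anyNA(dG_nonelec) ||
      !all(is.finite(c(dG_solv, dG_coul, dG_nonelec))))
    stop("all components must be finite")
  df <- data.frame(condition = condition, cluster = cluster,
                   dG_solv = dG_solv, dG_coul = dG_coul,
                   dG_nonelec = dG_nonelec,
                   dG_b = dG_solv + dG_coul + dG_nonelec,
                   stringsAsFactors = FALSE)
  class(df) <- c("energy_table", "data.frame")
  df
}

#' Per-condition means and sample standard deviations of energy components
#'
#' Arithmetic mean and n-1 standard deviation of each component and of
#' `dG_b`, per condition label (at least two rows per condition).
#'
#' @param rows an `energy_table` (e.g. from [read_energy_table()] or
#'   [assemble_binding_energy()]); a missing `dG_b` column is assembled.
#' @return Data frame with one row per condition: `mean_*` and `sd_*` for
#'   `dG_solv`, `dG_coul`, `dG_nonelec`, `dG_b`, plus `n`.
#' @export
aggregate_condition <- function(rows) {
  if (is.null(rows$dG_b))
    rows$dG_b <- rows$dG_solv + rows$dG_coul + rows$dG_nonelec
  counts <- table(rows$condition)
  if (any(counts < 2))
    stop("need >= 2 rows per condition (violated for: ",
         paste(names(counts)[counts < 2], collapse = ", "), ")")
  comps <- c("dG_solv", "dG_coul", "dG_nonelec", "dG_b")
  out <- do.call(rbind, lapply(unique(rows$condition), function(cond) {
    sub <- rows[rows$condition == cond, ]
    stats <- unlist(lapply(comps, function(cc)
      c(mean(sub[[cc]]), stats::sd(sub[[cc]]))))
    names(stats) <- as.vector(rbind(paste0("mean_", comps), paste0("sd_", comps)))
    data.frame(condition = cond, t(stats), n = nrow(sub),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Generalised-Born-style polarisation energy of a charge set
#'
#' Still-style pairwise estimate with effective Born radii taken as the
#' intrinsic atomic radii:
#' `G = -(k/2) (1/eps_in - 1/eps_out) sum_ij q_i q_j / f_GB(r_ij)`,
#' `f_GB = sqrt(r^2 + R_i R_j exp(-r^2 / (4 R_i R_j)))`. For a single ion
#' this reduces to the Born formula. Approximate by construction; it is not
#' a Poisson-Boltzmann solution.
#'
#' @param model a [structure_model()] with charges and radii.
#' @param eps_solute,eps_solvent interior and solvent dielectric constants.
#' @return Polarisation energy in kJ/mol.
#' @export
gb_polarization_energy <- function(model, eps_solute = 4, eps_solvent = 78) {
  q <- model$charge; r <- model$radius
  if (any(is.na(q)) || any(is.na(r))) stop("charges and radii must be populated")
  xyz <- coords(model)
  n <- nrow(xyz)
  d2 <- as.matrix(stats::dist(xyz))^2
  RR <- outer(r, r)
  fgb <- sqrt(d2 + RR * exp(-d2 / (4 * RR)))
  -(coulomb_k() / 2) * (1 / eps_solute - 1 / eps_solvent) *
    sum(outer(q, q) / fgb)
}

#' Generalised-Born stand-in for the solvation component of binding
#'
#' `G_pol(complex) - G_pol(receptor) - G_pol(ligand)` from
#' [gb_polarization_energy()]. A fast pairwise approximation used to run the
#' pipeline end to end on synthetic systems; documented as approximate and
#' not equivalent to a finite-difference Poisson-Boltzmann calculation.
#'
#' @param receptor,ligand the isolated partners (charges and radii populated).
#' @param complex optional complex model; defaults to the concatenation of
#'   receptor and ligand at their given coordinates.
#' @param eps_solute,eps_solvent dielectric constants (defaults 4 and 78).
#' @return Solvation contribution to binding, kJ/mol.
#' @export
born_solvation_standin <- function(receptor, ligand, complex = NULL,
                                   eps_solute = 4, eps_solvent = 78) {
  if (is.null(complex)) {
    complex <- rbind(as.data.frame(receptor), as.data.frame(ligand))
    complex$atom_id <- seq_len(nrow(complex))
    class(complex) <- c("structure_model", "data.frame")
  }
  gb_polarization_energy(complex, eps_solute, eps_solvent) -
    gb_polarization_energy(receptor, eps_solute, eps_solvent) -
    gb_polarization_energy(ligand, eps_solute, eps_solvent)
}
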