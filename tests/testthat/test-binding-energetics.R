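one_atom <- function(q = 0, r = 1.9, at = c(0, 0, 0), id = 1L, chain = "R") {
  structure_model(id, "C", "LIG", 1L, chain, matrix(at, 1), radius = r, charge = q)
}

two_sphere_complex <- function(d, r = 1.9) {
  rec <- one_atom(r = r)
  lig <- one_atom(r = r, at = c(d, 0, 0), id = 2L, chain = "L")
  cx <- rbind(as.data.frame(rec), as.data.frame(lig))
  cx$atom_id <- 1:2
  class(cx) <- c("structure_model", "data.frame")
  list(complex = cx, receptor = rec, ligand = lig)
}

test_that("Shrake-Rupley SASA matches analytic sphere areas", {
  m <- one_atom(r = 1.9)
  s <- sasa_shrake_rupley(m, probe_radius = 1.4, n_points = 960)
  expect_equal(s$total, 4 * pi * 3.3^2, tolerance = 0.005)
  expect_equal(s$total, 136.85, tolerance = 0.005 * 136.85)

  # far-separated atoms: no occlusion, areas add
  far <- two_sphere_complex(d = 50)
  st <- sasa_shrake_rupley(far$complex)
  expect_equal(st$total, 2 * 4 * pi * 3.3^2, tolerance = 1e-6)
  expect_equal(sum(st$per_atom), st$total)

  # small atom fully buried inside a large sphere
  host <- structure_model(1:2, c("S", "C"), "LIG", 1L, "R",
                          rbind(c(0, 0, 0), c(0.5, 0, 0)),
                          radius = c(6, 1), charge = 0)
  sb <- sasa_shrake_rupley(host)
  expect_equal(sb$per_atom[2], 0)
  expect_error(sasa_shrake_rupley(m, n_points = 50), "n_points")
  m2 <- m; m2$radius <- NA_real_
  expect_error(sasa_shrake_rupley(m2), "radius")
})

test_that("SASA is non-increasing as two atoms approach", {
  prev <- Inf
  for (d in c(10, 8, 6.6, 6, 5, 4, 3, 2)) {
    tot <- sasa_shrake_rupley(two_sphere_complex(d)$complex)$total
    expect_lte(tot, prev + 0.5)
    prev <- tot
  }
})

test_that("delta-ASA matches the two-sphere cap formula and sign contract", {
  # touching equal spheres: each loses a cap of area 2 pi R h, h = R - d/2
  R <- 1.9 + 1.4
  d <- 4
  sys <- two_sphere_complex(d)
  da <- delta_asa(sys$complex, sys$receptor, sys$ligand)
  expect_equal(da, -2 * 2 * pi * R * (R - d / 2), tolerance = 0.01 * abs(da))
  expect_lt(da, 0)

  far <- two_sphere_complex(50)
  expect_equal(delta_asa(far$complex, far$receptor, far$ligand), 0)
  expect_error(delta_asa(far$complex, far$ligand, far$receptor), "roster")
})

test_that("nonpolar term is gamma times delta-ASA", {
  expect_equal(nonpolar_energy(0), 0)
  expect_equal(nonpolar_energy(-2761.9), -58.0, tolerance = 1e-3)
  expect_equal(nonpolar_energy(-2619.0), -55.0, tolerance = 1e-3)
  # the delta-ASA implied by a -58 kJ/mol nonpolar term at the default gamma
  expect_equal(-58 / 0.021, -2761.9, tolerance = 1e-4)
  expect_error(nonpolar_energy(-100, gamma = 0), "gamma")
})

test_that("Coulomb energy matches the closed form and its scaling laws", {
  rec <- one_atom(q = 1)
  lig <- one_atom(q = -1, at = c(10, 0, 0), id = 2L, chain = "L")
  e <- coulomb_energy(rec, lig, dielectric = 4)
  expect_equal(e, 1389.35 * (-1) / 40, tolerance = 1e-6 * abs(e))
  expect_equal(e, -34.73, tolerance = 1e-2)
  expect_equal(coulomb_energy(rec, lig, dielectric = 8), e / 2)

  sys <- gen_charge_system(6, 5, geometry = "contact_complex", seed = 12)
  lig0 <- sys$ligand; lig0$charge <- 0
  expect_equal(coulomb_energy(sys$receptor, lig0), 0)

  # invariance under rigid motion of the whole complex
  e1 <- coulomb_energy(sys$receptor, sys$ligand)
  R <- random_rotation(1.1)
  mv <- function(m) {
    xyz <- sweep(coords(m) %*% t(R), 2, c(5, 6, -2), "+")
    m$x <- xyz[, 1]; m$y <- xyz[, 2]; m$z <- xyz[, 3]
    m
  }
  expect_equal(coulomb_energy(mv(sys$receptor), mv(sys$ligand)), e1,
               tolerance = 1e-9)

  overlap <- one_atom(q = -1, at = c(0, 0, 0), id = 2L, chain = "L")
  expect_error(coulomb_energy(rec, overlap), "overlap")
})

test_that("binding energies assemble as exact component sums", {
  e <- assemble_binding_energy(251, -112, -58)
  expect_equal(e$dG_b, 81)
  e2 <- assemble_binding_energy(264, -238, -55)
  expect_equal(e2$dG_b, -29)
  expect_equal(assemble_binding_energy(0, 0, 0)$dG_b, 0)
  expect_error(assemble_binding_energy(NaN, 1, 1), "finite")
})

test_that("condition aggregation uses arithmetic mean and n-1 sd", {
  t1 <- table1_components()
  agg <- aggregate_condition(t1)
  z <- agg[agg$condition == "0%", ]
  expect_equal(z$mean_dG_b, mean(c(106, 81, -29)))
  expect_equal(z$sd_dG_b, stats::sd(c(106, 81, -29)))
  expect_equal(round(z$mean_dG_b), 53)
  expect_equal(round(z$sd_dG_b), 72)
  expect_equal(round(agg$mean_dG_b[agg$condition == "25%"]), 116)

  same <- assemble_binding_energy(c(10, 10), c(-5, -5), c(-1, -1),
                                  condition = "x", cluster = c("a", "b"))
  expect_equal(aggregate_condition(same)$sd_dG_b, 0)
  expect_error(aggregate_condition(t1[1, ]), ">= 2 rows")
})

test_that("generalised-Born stand-in reduces to the Born formula", {
  k <- 1389.35
  ion <- one_atom(q = 1, r = 2)
  born <- -(k / 2) * (1 / 4 - 1 / 78) * 1 / 2
  expect_equal(gb_polarization_energy(ion, 4, 78), born, tolerance = 1e-6)

  sys <- gen_charge_system(4, 4, geometry = "contact_complex", seed = 9)
  lig0 <- sys$ligand; lig0$charge <- 0
  rec0 <- sys$receptor; rec0$charge <- 0
  expect_equal(born_solvation_standin(rec0, lig0), 0)

  # additivity limit: far-separated partners contribute nothing
  farlig <- sys$ligand
  farlig$x <- farlig$x + 1e5
  expect_lt(abs(born_solvation_standin(sys$receptor, farlig)), 0.01)
  expect_error(gb_polarization_energy(one_atom(q = NA_real_)), "populated")
})
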