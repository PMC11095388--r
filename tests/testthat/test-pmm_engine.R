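bohr_A <- 1 / 1.8897259886  # Angstrom per bohr

test_that("potential and field follow Coulomb's law and superposition", {
  qc <- toy_qc()
  # empty environment
  fr <- toy_frame(list(qc))
  pf <- compute_potential_and_field(fr, qc)
  expect_equal(pf$potential, 0)
  expect_equal(pf$field, c(0, 0, 0))

  # +1 charge 10 bohr along +x
  fr <- toy_frame(list(qc), env_coords = matrix(c(10 * bohr_A, 0, 0), 1),
                  env_charges = 1)
  pf <- compute_potential_and_field(fr, qc)
  expect_equal(pf$potential, 0.1, tolerance = 1e-12)
  expect_equal(pf$field, c(-0.01, 0, 0), tolerance = 1e-12)

  # +1 at (+1 bohr, 0, 0), -1 at (-1 bohr, 0, 0)
  fr <- toy_frame(list(qc),
                  env_coords = rbind(c(bohr_A, 0, 0), c(-bohr_A, 0, 0)),
                  env_charges = c(1, -1))
  pf <- compute_potential_and_field(fr, qc, min_distance = 0.2)
  expect_equal(pf$potential, 0, tolerance = 1e-14)
  expect_equal(pf$field, c(-2, 0, 0), tolerance = 1e-12)
})

test_that("close contacts trip the numerical-safety guard", {
  qc <- toy_qc()
  fr <- toy_frame(list(qc), env_coords = matrix(c(0.3, 0, 0), 1),
                  env_charges = 0.5)
  expect_error(compute_potential_and_field(fr, qc), "0.300 Angstrom")
  # and the guard is configurable
  pf <- compute_potential_and_field(fr, qc, min_distance = 0.1)
  expect_true(is.finite(pf$potential))
})

test_that("perturbed Hamiltonian assembles by direct substitution", {
  el <- toy_electronic(gap = 0.07, mu01 = c(1, 0, 0))
  zero <- perturbation_field(0, c(0, 0, 0), c(0, 0, 0))
  expect_equal(build_perturbed_hamiltonian(el, 0, zero), diag(c(0, 0.07)))

  # neutral QC: potential term vanishes
  v5 <- perturbation_field(5, c(0, 0, 0), c(0, 0, 0))
  expect_equal(build_perturbed_hamiltonian(el, 0, v5), diag(c(0, 0.07)))

  ex <- perturbation_field(0, c(0.001, 0, 0), c(0, 0, 0))
  expect_equal(build_perturbed_hamiltonian(el, 0, ex),
               matrix(c(0, -0.001, -0.001, 0.07), 2))
})

test_that("charged QC picks up q_T * V on the diagonal only", {
  el <- toy_electronic()
  for (v in c(-2, 0.3, 5)) {
    pf <- perturbation_field(v, c(0, 0, 0), c(0, 0, 0))
    h <- build_perturbed_hamiltonian(el, 1L, pf)
    st <- diagonalize_perturbed(h)
    expect_equal(st$energies, c(0, 0.07) + v, tolerance = 1e-12)
    expect_equal(diff(st$energies), 0.07, tolerance = 1e-12)  # gap unchanged
  }
})

test_that("a field orthogonal to every dipole element leaves H diagonal", {
  el <- toy_electronic(mu01 = c(1, 0, 0), p0 = c(0.5, 0, 0),
                       p1 = c(-0.2, 0, 0))
  pf <- perturbation_field(0, c(0, 0.02, 0.03), c(0, 0, 0))
  h <- build_perturbed_hamiltonian(el, 0, pf)
  expect_equal(h, diag(diag(h)))
})

test_that("diagonalization matches the 2x2 closed form", {
  h <- matrix(c(0, -0.001, -0.001, 0.07), 2)
  st <- diagonalize_perturbed(h)
  expect_equal(st$energies,
               0.035 + c(-1, 1) * sqrt(0.035^2 + 1e-6), tolerance = 1e-12)
  expect_equal(diff(st$energies), sqrt(0.07^2 + 4e-6), tolerance = 1e-14)
  expect_equal(site_energy(st), 27.2114 * 0.0700286, tolerance = 1e-4)

  expect_error(diagonalize_perturbed(matrix(c(0, 1, 0, 1), 2)),
               "not symmetric")
})

test_that("eigensolver agrees with the brute-force Jacobi oracle", {
  set.seed(42)
  for (n in c(3, 5, 8)) {
    for (rep in 1:5) {
      h <- random_symmetric(n, scale = 0.1)
      st <- diagonalize_perturbed(h)
      ref <- jacobi_eigen(h)
      expect_equal(st$energies, ref$values, tolerance = 1e-8)
      # orthonormality and reconstruction
      expect_equal(crossprod(st$eigenvectors), diag(n), tolerance = 1e-10)
      expect_equal(st$eigenvectors %*% diag(st$energies) %*%
                     t(st$eigenvectors), h, tolerance = 1e-10)
    }
  }
})

test_that("site_energy converts the unperturbed gap and flags degeneracy", {
  st <- diagonalize_perturbed(diag(c(0, 0.07)))
  expect_equal(site_energy(st), 1.9048, tolerance = 1e-4)
  st0 <- diagonalize_perturbed(diag(c(0.1, 0.1)))
  expect_warning(e <- site_energy(st0), "degenerate")
  expect_equal(e, 0)
})

test_that("perturbed transition dipole reduces correctly in known limits", {
  el <- toy_electronic(mu01 = c(0.3, -1.2, 0.5))
  st <- diagonalize_perturbed(diag(c(0, 0.07)))
  expect_equal(perturbed_transition_dipole(el, st), c(0.3, -1.2, 0.5))

  # sign flip of one eigenvector flips mu', magnitude unchanged
  st2 <- st
  st2$eigenvectors[, 2] <- -st2$eigenvectors[, 2]
  mu2 <- perturbed_transition_dipole(el, st2)
  expect_equal(mu2, -c(0.3, -1.2, 0.5))

  # 2-state mixing angle with zero permanent dipoles: |mu'| = |mu||cos 2theta|
  for (theta in c(0.1, 0.4, pi / 4, 1.2)) {
    vecs <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2)
    st3 <- structure(list(energies = c(0, 1), eigenvectors = vecs,
                          hamiltonian = diag(2)), class = "perturbed_state")
    mu <- perturbed_transition_dipole(el, st3)
    # independent brute-force sandwich
    direct <- vapply(1:3, function(k) {
      as.numeric(t(vecs[, 1]) %*% el$dipoles[, , k] %*% vecs[, 2])
    }, 0)
    expect_equal(mu, direct, tolerance = 1e-14)
    expect_equal(sqrt(sum(mu^2)),
                 sqrt(sum(c(0.3, -1.2, 0.5)^2)) * abs(cos(2 * theta)),
                 tolerance = 1e-12)
  }
})

test_that("oscillator strength follows the length-gauge formula", {
  gap_eV <- convert_energy(0.07, "hartree", "eV")
  expect_equal(oscillator_strength(gap_eV, sqrt(c(1, 1, 1))), 0.14,
               tolerance = 1e-12)
  expect_equal(oscillator_strength(1.9, c(0, 0, 0)), 0)
  # inverse relation: f = 0.19 at 1.846 eV implies |mu| ~ 2.05 a.u.
  mu_mag <- sqrt(0.19 / ((2 / 3) * convert_energy(1.846, "eV", "hartree")))
  expect_equal(mu_mag, 2.05, tolerance = 0.005)
  expect_equal(oscillator_strength(1.846, c(mu_mag, 0, 0)), 0.19,
               tolerance = 1e-12)
})

test_that("trace identity holds frame by frame", {
  set.seed(8)
  el <- toy_electronic(gap = 0.07, mu01 = c(1, 0.2, -0.3),
                       p0 = c(0.5, 0, 0.1), p1 = c(-0.2, 0.4, 0))
  for (rep in 1:10) {
    pf <- perturbation_field(rnorm(1), rnorm(3, sd = 0.01), c(0, 0, 0))
    for (qT in c(0L, 1L, -2L)) {
      h <- build_perturbed_hamiltonian(el, qT, pf)
      mu_diag <- el$dipoles[1, 1, ] + el$dipoles[2, 2, ]
      expect_equal(sum(diag(h)),
                   sum(el$energies) + 2 * qT * pf$potential -
                     sum(pf$field * mu_diag),
                   tolerance = 1e-14)
    }
  }
})

test_that("zero-charge environment reproduces unperturbed values exactly", {
  qc <- toy_qc(gap = 0.07)
  frames <- lapply(1:10, function(i) {
    toy_frame(list(qc), env_coords = matrix(rnorm(9, sd = 8), 3),
              env_charges = rep(0, 3), frame_index = i)
  })
  traces <- run_site_energy_stage(frames, list(qc))
  tr <- traces[["A"]]
  expect_equal(nrow(tr), 10)
  expect_equal(tr$site_energy_eV,
               rep(convert_energy(0.07, "hartree", "eV"), 10))
  expect_equal(unique(tr$mu_x), 1)
  expect_equal(tr$e_ground_Ha, rep(0, 10))
})

test_that("each QC's own atoms are excluded, other QCs' atoms included", {
  a <- toy_qc("A", origin = c(0, 0, 0))
  b <- toy_qc("B", origin = c(10, 0, 0))
  # QC atoms themselves carry charge in this frame
  fr <- toy_frame(list(a, b), qc_charges = c(0.5, -0.5))
  pf_a <- compute_potential_and_field(fr, a)
  pf_b <- compute_potential_and_field(fr, b)
  r <- 10 * 1.8897259886
  expect_equal(pf_a$potential, -0.5 / r, tolerance = 1e-12)  # only B's atom
  expect_equal(pf_b$potential, 0.5 / r, tolerance = 1e-12)   # only A's atom
})

test_that("bad frames abort with context, or are skipped when allowed", {
  qc <- toy_qc()
  good <- toy_frame(list(qc), matrix(c(5, 0, 0), 1), 0.2, frame_index = 1L)
  bad <- toy_frame(list(qc), matrix(c(0.2, 0, 0), 1), 0.2, frame_index = 2L)
  expect_error(run_site_energy_stage(list(good, bad), list(qc)),
               "frame 2")
  expect_warning(
    traces <- run_site_energy_stage(list(good, bad), list(qc),
                                    skip_bad_frames = TRUE),
    "skipping")
  expect_equal(traces[["A"]]$frame_index, 1L)
})
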