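test_that("site-energy statistics recover constructed moments", {
  tr <- data.frame(frame_index = 1:5, site_energy_eV = rep(1.90, 5))
  st <- site_energy_statistics(list(A = tr))
  expect_equal(st$mean_eV, 1.90)
  expect_equal(st$sd_eV, 0)
  expect_equal(st$skewness, 0)

  set.seed(3)
  x <- rnorm(4000, 1.873, 0.005)
  st2 <- site_energy_statistics(list(
    A = data.frame(frame_index = seq_along(x), site_energy_eV = x),
    B = data.frame(frame_index = 1:10, site_energy_eV = rep(2, 10))))
  expect_equal(st2$mean_eV[1], 1.873, tolerance = 3 * 0.005 / sqrt(4000) / 1.873)
  expect_equal(st2$sd_eV[1], 0.005, tolerance = 0.1)
  expect_equal(st2$mean_eV[2], 2)  # per-QC independence
  expect_s3_class(st2$histogram[[1]], "histogram")
})

test_that("electrochromic shifts reproduce the printed table columns", {
  st <- read_site_table(fixture_path("cp43_site_energies.csv"))
  sh <- electrochromic_shift(st)
  expect_equal(sh$shift_monomer[sh$site == "C1"], -22L)
  expect_equal(sh$shift_monomer[sh$site == "C6"], 75L)
  # whole columns agree with the table's own printed shifts
  expect_equal(sh$shift_isolated, as.integer(st$shift_isolated))
  expect_equal(sh$shift_monomer, as.integer(st$shift_monomer))

  same <- st
  same$E_monomer <- same$E_gas
  expect_equal(electrochromic_shift(same)$shift_monomer, rep(0L, 13))
  expect_error(electrochromic_shift(st, gas_col = "E_nope"), "E_nope")
})

test_that("range summaries locate the printed extremes with labels", {
  st <- read_site_table(fixture_path("cp43_site_energies.csv"))
  r <- range_summary(st$E_monomer, st$site)
  expect_equal(r$min, list(label = "C1", value = 1.846))
  expect_equal(r$max, list(label = "C11", value = 1.983))
  g <- range_summary(st$E_gas, st$site)
  expect_equal(g$min$value, 1.868)
  expect_equal(g$max$value, 1.966)
  one <- range_summary(c(X = 2.0))
  expect_equal(one$min, one$max)
  # ties broken by order
  tie <- range_summary(c(5, 5), c("a", "b"))
  expect_equal(tie$max$label, "a")
})

test_that("first-exciton distribution handles constant and mixed input", {
  mk <- function(e, fi) {
    diagonalize_exciton(matrix(e, 1, 1), basis_ids = "A", frame_index = fi,
                        unit = "eV")
  }
  sols <- lapply(1:5, function(i) mk(1.9, i))
  fd <- first_exciton_distribution(sols)
  expect_equal(length(fd$histogram$counts), 1)
  expect_equal(sum(fd$histogram$counts), 5)
  expect_equal(rowSums(fd$contributions), rep(1, 5), ignore_attr = TRUE)
  expect_null(fd$mixture)
})

test_that("the mixture fit separates constructed subpopulations", {
  set.seed(5)
  mk <- function(e, fi) {
    diagonalize_exciton(matrix(e, 1, 1), basis_ids = "A", frame_index = fi,
                        unit = "eV")
  }
  e <- c(rnorm(300, 1.852, 0.004), rnorm(300, 1.872, 0.004))
  sols <- lapply(seq_along(e), function(i) mk(e[i], i))
  fd <- first_exciton_distribution(sols)
  expect_false(is.null(fd$mixture))
  expect_equal(fd$mixture$means, c(1.852, 1.872), tolerance = 1e-3)
})

test_that("statistics are invariant to frame ordering", {
  set.seed(19)
  spec <- synthetic_spec(n_qcs = 2, n_frames = 12, n_env_atoms = 20, seed = 6)
  ds <- generate_dataset(spec, NULL)
  traces <- run_site_energy_stage(ds$ensemble, ds$qcs)
  sols <- run_exciton_stage(traces, ds$ensemble, ds$qcs)
  perm <- sample(length(sols))
  fd1 <- first_exciton_distribution(sols, fit_mixture = FALSE)
  fd2 <- first_exciton_distribution(sols[perm], fit_mixture = FALSE)
  expect_equal(mean(fd1$energies), mean(fd2$energies))
  expect_equal(sd(fd1$energies), sd(fd2$energies))
  cs1 <- coupling_statistics(sols)
  cs2 <- coupling_statistics(sols[perm])
  expect_equal(cs1$mean, cs2$mean)
  expect_equal(cs1$sd, cs2$sd)
})

test_that("group contributions track the perturbative detuning limit", {
  sol1 <- diagonalize_exciton(matrix(1.9, 1, 1), basis_ids = "A",
                              unit = "eV")
  cb <- contribution_by_energy(list(sol1), c(A = "g1"))
  expect_equal(cb$g1, 1.0)

  v <- 0.01
  sol2 <- diagonalize_exciton(matrix(c(1.9, v, v, 1.9), 2),
                              basis_ids = c("A", "B"), unit = "eV")
  cb2 <- contribution_by_energy(list(sol2), c(A = "gA", B = "gB"))
  expect_equal(cb2$gA, 0.5, tolerance = 1e-10)
  expect_equal(cb2$gB, 0.5, tolerance = 1e-10)

  # |Delta| >> |V|: low-site weight -> 1 - (V/Delta)^2
  delta <- 0.2
  v <- 0.01
  sol3 <- diagonalize_exciton(matrix(c(1.8, v, v, 1.8 + delta), 2),
                              basis_ids = c("lo", "hi"), unit = "eV")
  cb3 <- contribution_by_energy(list(sol3), c(lo = "low", hi = "high"))
  expect_equal(cb3$low, 1 - (v / delta)^2, tolerance = 1e-4)

  expect_error(contribution_by_energy(list(sol3), c(lo = "low")), "hi")
})

test_that("line shape places, weighs and measures peaks correctly", {
  sol <- diagonalize_exciton(matrix(1.85, 1, 1), basis_ids = "A",
                             unit = "eV",
                             transition_dipoles = matrix(c(2, 0, 0), 1))
  sp <- absorption_lineshape(list(sol), width = 0.5)
  expect_equal(sp$peak_nm, 1239.841984 / 1.85, tolerance = 1e-3)
  area <- sum((sp$intensity[-1] + sp$intensity[-length(sp$intensity)]) / 2 *
                diff(sp$wavelength_nm))
  expect_equal(area, 1, tolerance = 1e-6)
  expect_equal(sp$total_weight, 4)  # |mu|^2 before normalization

  # two equal sticks at 670 and 682 nm with 2 nm kernels: splitting 12 nm
  e670 <- 1239.841984 / 670
  e682 <- 1239.841984 / 682
  s1 <- diagonalize_exciton(matrix(e670, 1, 1), unit = "eV")
  s2 <- diagonalize_exciton(matrix(e682, 1, 1), unit = "eV")
  sp2 <- absorption_lineshape(list(s1, s2), width = 2)
  expect_equal(sp2$splitting_nm, 12, tolerance = 0.1)

  # FWHM grows monotonically with the kernel width
  w1 <- absorption_lineshape(list(s1), width = 2)$bandwidth_nm
  w2 <- absorption_lineshape(list(s1), width = 4)$bandwidth_nm
  expect_gt(w2, w1)
  expect_equal(w1, 2 * sqrt(2 * log(2)) * 2, tolerance = 0.05)

  expect_error(absorption_lineshape(list(s1), width = 2, grid = numeric(0)),
               "grid")
})

test_that("a weak secondary population appears as a shoulder splitting", {
  e670 <- 1239.841984 / 670
  e682 <- 1239.841984 / 682
  s_main <- diagonalize_exciton(matrix(e670, 1, 1), unit = "eV",
                                transition_dipoles = matrix(c(2, 0, 0), 1))
  s_weak <- diagonalize_exciton(matrix(e682, 1, 1), unit = "eV",
                                transition_dipoles = matrix(c(1, 0, 0), 1))
  # broad kernels merge the weak band into a shoulder, not a maximum
  sp <- absorption_lineshape(c(rep(list(s_main), 4), list(s_weak)),
                             width = 4)
  n_maxima <- with(list(dy = diff(sp$intensity)),
                   sum(dy[-length(dy)] > 0 & dy[-1] <= 0))
  expect_identical(n_maxima, 1L)
  expect_false(is.na(sp$splitting_nm))
  expect_equal(sp$splitting_nm, 12, tolerance = 4)
})
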