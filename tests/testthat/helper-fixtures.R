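# Small in-code builders shared across the suite.

fixture_path <- function(name) {
  system.file("extdata", name, package = "excitonpmm", mustWork = TRUE)
}

# Two-state electronic data: gap in Hartree, transition dipole mu01 (a.u.),
# optional permanent dipoles on the diagonal.
toy_electronic <- function(gap = 0.07, mu01 = c(1, 0, 0),
                           p0 = c(0, 0, 0), p1 = c(0, 0, 0)) {
  dip <- array(0, c(2, 2, 3))
  dip[1, 1, ] <- p0
  dip[2, 2, ] <- p1
  dip[1, 2, ] <- dip[2, 1, ] <- mu01
  electronic_data(c(0, gap), dip)
}

toy_qc <- function(id = "A", gap = 0.07, mu01 = c(1, 0, 0),
                   p0 = c(0, 0, 0), p1 = c(0, 0, 0), charge = 0L,
                   origin = c(0, 0, 0)) {
  atoms <- data.frame(element = "C",
                      x = origin[1], y = origin[2], z = origin[3])
  quantum_center(id, atoms, charge, toy_electronic(gap, mu01, p0, p1))
}

# A frame holding the given QCs (single-atom each) plus environment charges.
toy_frame <- function(qcs, env_coords = NULL, env_charges = NULL,
                      frame_index = 1L, qc_charges = NULL) {
  qc_xyz <- t(vapply(qcs, function(q) {
    as.numeric(q$atoms[1, c("x", "y", "z")])
  }, numeric(3)))
  nq <- nrow(qc_xyz)
  if (is.null(qc_charges)) qc_charges <- rep(0, nq)
  coords <- qc_xyz
  charges <- qc_charges
  if (!is.null(env_coords)) {
    coords <- rbind(coords, env_coords)
    charges <- c(charges, env_charges)
  }
  qmap <- as.list(seq_len(nq))
  names(qmap) <- vapply(qcs, `[[`, character(1), "id")
  environment_frame(frame_index, coords, charges, qmap)
}

# Random symmetric matrix for eigensolver cross-checks.
random_symmetric <- function(n, scale = 1) {
  a <- matrix(stats::rnorm(n * n, sd = scale), n, n)
  (a + t(a)) / 2
}
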