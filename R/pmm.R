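#' Electrostatic potential and field at a quantum center
#'
#' Sums the Coulomb potential and field of every environment point charge at
#' the QC's instantaneous center of mass, in atomic units. Atoms belonging to
#' the QC itself (per the frame's `qc_atom_map`) are excluded; atoms of other
#' QCs are included with their fixed charges.
#'
#' @param frame an [environment_frame].
#' @param qc a [quantum_center] whose id appears in the frame's `qc_atom_map`.
#' @param min_distance numerical-safety guard (Angstrom): an environment atom
#'   closer than this to the evaluation point raises an error. Default 0.5.
#' @return a [perturbation_field]: `potential` (a.u.), `field` (a.u. 3-vector),
#'   `evaluation_point` (Angstrom).
#' @export
compute_potential_and_field <- function(frame, qc, min_distance = 0.5) {
  stopifnot(inherits(frame, "environment_frame"),
            inherits(qc, "quantum_center"))
  own <- frame$qc_atom_map[[qc$id]]
  if (is.null(own)) {
    stop("QC '", qc$id, "' is not resolved in frame ", frame$frame_index,
         " (missing from qc_atom_map)", call. = FALSE)
  }
  if (length(own) != nrow(qc$atoms)) {
    stop("QC '", qc$id, "': qc_atom_map has ", length(own),
         " atoms but the property file declares ", nrow(qc$atoms),
         call. = FALSE)
  }
  r0 <- center_of_mass(qc$atoms, coords = frame$coords[own, , drop = FALSE])
  env_idx <- setdiff(seq_len(nrow(frame$coords)), own)
  .potential_field_at(r0, frame$coords[env_idx, , drop = FALSE],
                      frame$charges[env_idx], min_distance,
                      frame$frame_index)
}

# r0 and coords in Angstrom; returns a.u. quantities.
.potential_field_at <- function(r0, coords, charges, min_distance,
                                frame_index = NA_integer_) {
  if (length(charges) == 0L) {
    return(perturbation_field(0, c(0, 0, 0), r0))
  }
  d <- sweep(coords, 2, r0)            # r_j - r0, Angstrom
  r_ang <- sqrt(rowSums(d * d))
  if (any(r_ang < min_distance)) {
    j <- which.min(r_ang)
    stop(sprintf(
      "environment atom %d at %.3f Angstrom from the evaluation point (< %.3f) in frame %s",
      j, r_ang[j], min_distance, frame_index), call. = FALSE)
  }
  r <- r_ang * BOHR_PER_ANGSTROM       # bohr
  v <- sum(charges / r)
  # E = sum q_j (r0 - r_j) / |r0 - r_j|^3, with displacement in bohr
  disp_bohr <- -d * BOHR_PER_ANGSTROM
  e <- colSums(disp_bohr * (charges / r^3))
  perturbation_field(v, e, r0)
}

#' Build the perturbed electronic Hamiltonian
#'
#' Adds the multipolar perturbation, truncated at the dipole term, to the
#' unperturbed Hamiltonian expressed in its own eigenbasis:
#' `H_ij = E_i^0 delta_ij + q_T V delta_ij - E . mu_ij`. The result is
#' symmetric by construction (the dipole matrix is symmetric).
#'
#' @param electronic an [electronic_data] object.
#' @param q_T total QC charge (e).
#' @param pf a [perturbation_field].
#' @return n x n symmetric matrix in Hartree.
#' @export
build_perturbed_hamiltonian <- function(electronic, q_T, pf) {
  stopifnot(inherits(electronic, "electronic_data"),
            inherits(pf, "perturbation_field"))
  n <- electronic$n_states
  e <- pf$field
  h <- -(electronic$dipoles[, , 1] * e[1] +
         electronic$dipoles[, , 2] * e[2] +
         electronic$dipoles[, , 3] * e[3])
  diag(h) <- diag(h) + electronic$energies + q_T * pf$potential
  h
}

#' Diagonalize a perturbed Hamiltonian
#'
#' Returns ascending eigenvalues and phase-fixed eigenvectors: in each
#' eigenvector the component of largest magnitude is made positive, so
#' perturbed transition-dipole signs are reproducible.
#'
#' @param h symmetric matrix (Hartree).
#' @return object of class `perturbed_state` with `hamiltonian`, `energies`
#'   (ascending, Hartree) and `eigenvectors` (columns).
#' @export
diagonalize_perturbed <- function(h) {
  h <- as.matrix(h)
  if (max(abs(h - t(h))) > 1e-10) {
    stop("Hamiltonian is not symmetric (contract violation)", call. = FALSE)
  }
  es <- eigen((h + t(h)) / 2, symmetric = TRUE)
  ord <- order(es$values)              # eigen() returns descending
  vals <- es$values[ord]
  vecs <- es$vectors[, ord, drop = FALSE]
  vecs <- .fix_phase(vecs)
  structure(list(hamiltonian = h, energies = vals, eigenvectors = vecs),
            class = "perturbed_state")
}

.fix_phase <- function(vecs) {
  for (k in seq_len(ncol(vecs))) {
    j <- which.max(abs(vecs[, k]))
    if (vecs[j, k] < 0) vecs[, k] <- -vecs[, k]
  }
  vecs
}

#' Site energy of a perturbed state
#'
#' The difference between the perturbed first-excited and ground-state
#' energies, converted to eV. A degenerate pair (gap 0) is allowed but
#' flagged with a warning.
#'
#' @param state a `perturbed_state`.
#' @return site energy in eV.
#' @export
site_energy <- function(state) {
  stopifnot(inherits(state, "perturbed_state"),
            length(state$energies) >= 2)
  gap <- state$energies[2] - state$energies[1]
  if (gap == 0) warning("degenerate ground/first-excited pair: site energy 0")
  convert_energy(gap, "hartree", "eV")
}

#' Perturbed ground-to-first-excited transition dipole
#'
#' Sandwiches each Cartesian slice of the dipole matrix between the perturbed
#' ground- and first-excited-state eigenvectors: `mu'_01 = c0^T M c1`.
#'
#' @param electronic an [electronic_data] object.
#' @param state a `perturbed_state` from the same QC.
#' @return length-3 numeric vector (a.u.).
#' @export
perturbed_transition_dipole <- function(electronic, state) {
  c0 <- state$eigenvectors[, 1]
  c1 <- state$eigenvectors[, 2]
  vapply(1:3, function(k) {
    as.numeric(c0 %*% electronic$dipoles[, , k] %*% c1)
  }, numeric(1))
}

#' Oscillator strength (length gauge)
#'
#' `f = (2/3) * dE * |mu|^2` with the gap in Hartree and the transition
#' dipole in a.u.
#'
#' @param gap_eV transition energy in eV (non-negative).
#' @param mu_au transition dipole 3-vector (a.u.), or its squared norm if a
#'   scalar is given.
#' @return dimensionless oscillator strength.
#' @export
oscillator_strength <- function(gap_eV, mu_au) {
  stopifnot(all(gap_eV >= 0))
  mu2 <- if (length(mu_au) == 3) sum(mu_au^2) else as.numeric(mu_au)
  (2 / 3) * convert_energy(gap_eV, "eV", "hartree") * mu2
}

#' Run the per-frame site-energy stage
#'
#' For every quantum center and every frame: compute the environment's
#' potential and field at the QC's instantaneous center of mass, build and
#' diagonalize the perturbed Hamiltonian, and record the site energy,
#' perturbed transition dipole and oscillator strength. The QC's electronic
#' data stay fixed at their reference (QM/MM-optimized) values; only its
#' center of mass follows the trajectory.
#'
#' @param ensemble list of [environment_frame] objects.
#' @param qcs list of [quantum_center] objects.
#' @param min_distance close-contact guard in Angstrom (default 0.5).
#' @param skip_bad_frames if `TRUE`, frames failing the numerical-safety
#'   check are dropped (with a warning naming them) instead of aborting.
#' @return named list (by QC id) of `site_energy_trace` data.frames with
#'   columns `frame_index`, `site_energy_eV`, `e_ground_Ha`, `e_excited_Ha`,
#'   `mu_x`, `mu_y`, `mu_z`, `f_osc`.
#' @export
run_site_energy_stage <- function(ensemble, qcs, min_distance = 0.5,
                                  skip_bad_frames = FALSE) {
  stopifnot(length(ensemble) >= 1, length(qcs) >= 1)
  if (inherits(qcs, "quantum_center")) qcs <- list(qcs)
  ids <- vapply(qcs, `[[`, character(1), "id")
  out <- lapply(qcs, function(qc) {
    rows <- lapply(ensemble, function(frame) {
      rec <- tryCatch({
        pf <- compute_potential_and_field(frame, qc, min_distance)
        h <- build_perturbed_hamiltonian(qc$electronic, qc$total_charge, pf)
        st <- diagonalize_perturbed(h)
        es <- site_energy(st)
        mu <- perturbed_transition_dipole(qc$electronic, st)
        data.frame(frame_index = frame$frame_index, site_energy_eV = es,
                   e_ground_Ha = st$energies[1], e_excited_Ha = st$energies[2],
                   mu_x = mu[1], mu_y = mu[2], mu_z = mu[3],
                   f_osc = oscillator_strength(es, mu))
      }, error = function(e) {
        if (!skip_bad_frames) {
          stop("QC '", qc$id, "', frame ", frame$frame_index, ": ",
               conditionMessage(e), call. = FALSE)
        }
        warning("skipping QC '", qc$id, "' frame ", frame$frame_index, ": ",
                conditionMessage(e), call. = FALSE)
        NULL
      })
      rec
    })
    tr <- do.call(rbind, rows)
    class(tr) <- c("site_energy_trace", class(tr))
    attr(tr, "qc_id") <- qc$id
    tr
  })
  names(out) <- ids
  out
}
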