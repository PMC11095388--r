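#' Point-dipole excitonic coupling
#'
#' Dipole-dipole interaction of two point transition dipoles placed at the
#' chromophore centers of mass:
#' `V = [mu_k . mu_k' - 3 (mu_k . n)(mu_k' . n)] / R^3` in atomic units,
#' with `n` the unit separation vector and `R` in bohr. This is the neutral-QC
#' form of the interaction operator; monopole terms vanish for neutral
#' chromophores and are not implemented.
#'
#' @param mu_k,mu_kp transition dipole 3-vectors (a.u.).
#' @param r_k,r_kp chromophore centers of mass (Angstrom).
#' @param screening scalar multiplying the vacuum coupling (default 1:
#'   no dielectric screening).
#' @return coupling in Hartree.
#' @export
pda_coupling <- function(mu_k, mu_kp, r_k, r_kp, screening = 1.0) {
  stopifnot(length(mu_k) == 3, length(mu_kp) == 3,
            length(r_k) == 3, length(r_kp) == 3)
  dr <- (r_k - r_kp) * BOHR_PER_ANGSTROM
  r <- sqrt(sum(dr * dr))
  if (r == 0) stop("coincident chromophore centers", call. = FALSE)
  n <- dr / r
  screening * (sum(mu_k * mu_kp) - 3 * sum(mu_k * n) * sum(mu_kp * n)) / r^3
}

#' Assemble the Frenkel excitation matrix
#'
#' Diagonal: perturbed site energies; off-diagonal: excitonic couplings.
#' Inputs and output share one unit (the pipeline uses Hartree internally).
#'
#' @param site_energies numeric vector.
#' @param couplings symmetric matrix with zero diagonal, same unit.
#' @return symmetric excitation matrix.
#' @export
build_excitation_matrix <- function(site_energies, couplings) {
  n <- length(site_energies)
  couplings <- as.matrix(couplings)
  if (!all(dim(couplings) == c(n, n))) {
    stop("coupling matrix dimensions do not match the number of sites",
         call. = FALSE)
  }
  if (max(abs(couplings - t(couplings))) > 1e-10) {
    stop("coupling matrix is not symmetric (contract violation)",
         call. = FALSE)
  }
  h <- couplings
  diag(h) <- site_energies
  h
}

#' Diagonalize the excitation matrix
#'
#' @param dH symmetric excitation matrix in Hartree (or eV if
#'   `unit = "eV"`).
#' @param basis_ids character labels of the site basis (QC ids).
#' @param frame_index optional frame label.
#' @param unit unit of `dH`, `"hartree"` (default) or `"eV"`.
#' @param transition_dipoles optional n x 3 matrix of the sites' perturbed
#'   transition dipoles (a.u.), carried along for spectra.
#' @param com optional n x 3 matrix of site centers of mass (Angstrom).
#' @return object of class `exciton_solution`: `exciton_energies` (ascending,
#'   eV), `site_energies` (eV), `coupling_matrix` (cm^-1), `eigenvectors`
#'   (phase-fixed columns), `contributions` (squared coefficients; column a is
#'   exciton a, rows sum to the site's total weight, each column sums to 1).
#' @export
diagonalize_exciton <- function(dH, basis_ids = NULL, frame_index = NA_integer_,
                                unit = c("hartree", "eV"),
                                transition_dipoles = NULL, com = NULL) {
  unit <- match.arg(unit)
  dH <- as.matrix(dH)
  if (max(abs(dH - t(dH))) > 1e-10) {
    stop("excitation matrix is not symmetric", call. = FALSE)
  }
  if (is.null(basis_ids)) basis_ids <- paste0("S", seq_len(nrow(dH)))
  dH_ha <- if (unit == "eV") convert_energy(dH, "eV", "hartree") else dH
  st <- diagonalize_perturbed(dH_ha)
  contrib <- st$eigenvectors^2
  dimnames(contrib) <- list(site = basis_ids, exciton = NULL)
  site_eV <- convert_energy(diag(dH_ha), "hartree", "eV")
  coup <- dH_ha
  diag(coup) <- 0
  structure(list(
    frame_index = as.integer(frame_index),
    basis_ids = basis_ids,
    site_energies = site_eV,
    coupling_matrix = convert_energy(coup, "hartree", "cm-1"),
    exciton_energies = convert_energy(st$energies, "hartree", "eV"),
    eigenvectors = st$eigenvectors,
    contributions = contrib,
    transition_dipoles = transition_dipoles,
    com = com
  ), class = "exciton_solution")
}

#' @export
print.exciton_solution <- function(x, ...) {
  cat(sprintf("<exciton_solution frame %s: %d sites, first exciton %.4f eV>\n",
              x$frame_index, length(x$basis_ids), x$exciton_energies[1]))
  invisible(x)
}

#' Run the per-frame exciton stage
#'
#' For every frame, builds the excitation matrix over the chosen QC basis —
#' diagonal from the site-energy traces, off-diagonal point-dipole couplings
#' from the frame's perturbed transition dipoles and instantaneous centers of
#' mass — and diagonalizes it. One excitation (the lowest, Qy-like transition)
#' enters per QC.
#'
#' @param traces named list of site-energy traces from
#'   [run_site_energy_stage()], one entry per basis QC.
#' @param ensemble list of [environment_frame] objects (source of per-frame
#'   centers of mass).
#' @param qcs list of [quantum_center] objects forming the exciton basis.
#' @param screening optional scalar screening factor for the couplings.
#' @return list of `exciton_solution`, one per frame.
#' @export
run_exciton_stage <- function(traces, ensemble, qcs, screening = 1.0) {
  if (inherits(qcs, "quantum_center")) qcs <- list(qcs)
  ids <- vapply(qcs, `[[`, character(1), "id")
  qt <- vapply(qcs, `[[`, integer(1), "total_charge")
  if (any(qt != 0L)) {
    stop("charged QC(s) in the exciton basis (", paste(ids[qt != 0L],
         collapse = ", "), "): monopole coupling terms are not implemented",
         call. = FALSE)
  }
  missing <- setdiff(ids, names(traces))
  if (length(missing)) {
    stop("no site-energy trace for basis QC(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  n <- length(qcs)
  lapply(ensemble, function(frame) {
    fi <- frame$frame_index
    e_site <- numeric(n)
    mus <- matrix(0, n, 3)
    coms <- matrix(0, n, 3)
    for (i in seq_len(n)) {
      tr <- traces[[ids[i]]]
      row <- tr[tr$frame_index == fi, , drop = FALSE]
      if (nrow(row) != 1L) {
        stop("QC '", ids[i], "' has no trace record for frame ", fi,
             call. = FALSE)
      }
      e_site[i] <- row$site_energy_eV
      mus[i, ] <- c(row$mu_x, row$mu_y, row$mu_z)
      own <- frame$qc_atom_map[[ids[i]]]
      coms[i, ] <- center_of_mass(qcs[[i]]$atoms,
                                  coords = frame$coords[own, , drop = FALSE])
    }
    coup <- matrix(0, n, n)
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        coup[i, j] <- coup[j, i] <-
          pda_coupling(mus[i, ], mus[j, ], coms[i, ], coms[j, ],
                       screening = screening)
      }
    }
    dH <- build_excitation_matrix(convert_energy(e_site, "eV", "hartree"),
                                  coup)
    diagonalize_exciton(dH, basis_ids = ids, frame_index = fi,
                        transition_dipoles = mus, com = coms)
  })
}

#' Ensemble statistics of the coupling matrix
#'
#' Element-wise mean and sample standard deviation (n - 1) of the per-frame
#' coupling matrices, in cm^-1.
#'
#' @param solutions list of `exciton_solution`.
#' @return list with symmetric matrices `mean` and `sd` (cm^-1), labelled by
#'   basis id.
#' @export
coupling_statistics <- function(solutions) {
  stopifnot(length(solutions) >= 2)
  ids <- solutions[[1]]$basis_ids
  mats <- vapply(solutions, function(s) s$coupling_matrix,
                 matrix(0, length(ids), length(ids)))
  m <- apply(mats, c(1, 2), mean)
  s <- apply(mats, c(1, 2), stats::sd)
  dimnames(m) <- dimnames(s) <- list(ids, ids)
  list(mean = m, sd = s)
}
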