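# Independent brute-force reference implementation.
#
# Everything here is deliberately written as plain element-wise loops, with
# its own cyclic-Jacobi eigensolver, and calls none of the pipeline's
# functions (only shared physical constants and the atomic-mass table). It
# serves as the oracle the pipeline is checked against, frame by frame.

#' Jacobi eigensolver (reference implementation)
#'
#' Cyclic Jacobi rotations for a real symmetric matrix; ascending
#' eigenvalues, eigenvector columns with their largest-magnitude component
#' made positive. Deliberately independent of LAPACK: this is the oracle the
#' pipeline's eigensolver is cross-checked against.
#'
#' @param a real symmetric matrix.
#' @param tol off-diagonal convergence threshold (relative).
#' @param max_sweeps maximum number of full sweeps.
#' @return list with `values` (ascending) and `vectors` (columns).
#' @export
jacobi_eigen <- function(a, tol = 1e-14, max_sweeps = 100) {
  a <- as.matrix(a)
  n <- nrow(a)
  v <- diag(n)
  for (sweep in seq_len(max_sweeps)) {
    off <- 0
    for (p in seq_len(n - 1)) for (q in (p + 1):n) off <- off + a[p, q]^2
    if (sqrt(2 * off) < tol * max(1, max(abs(diag(a))))) break
    for (p in seq_len(n - 1)) {
      for (q in (p + 1):n) {
        if (abs(a[p, q]) < 1e-300) next
        theta <- (a[q, q] - a[p, p]) / (2 * a[p, q])
        t_ <- sign(theta) / (abs(theta) + sqrt(theta^2 + 1))
        if (theta == 0) t_ <- 1
        c_ <- 1 / sqrt(t_^2 + 1)
        s_ <- t_ * c_
        rot <- diag(n)
        rot[p, p] <- c_; rot[q, q] <- c_
        rot[p, q] <- s_; rot[q, p] <- -s_
        a <- t(rot) %*% a %*% rot
        v <- v %*% rot
      }
    }
  }
  vals <- diag(a)
  ord <- order(vals)
  vals <- vals[ord]
  vecs <- v[, ord, drop = FALSE]
  for (k in seq_len(n)) {
    j <- which.max(abs(vecs[, k]))
    if (vecs[j, k] < 0) vecs[, k] <- -vecs[, k]
  }
  list(values = vals, vectors = vecs)
}

#' Brute-force evaluation of one frame (reference implementation)
#'
#' Site energies, perturbed transition dipoles, pairwise point-dipole
#' couplings and exciton energies for the given QCs, all via naive
#' element-wise loops and [jacobi_eigen()]; shares nothing with the
#' pipeline's code path beyond physical constants.
#'
#' @param qcs list of [quantum_center] objects.
#' @param frame an [environment_frame].
#' @param min_distance close-contact guard (Angstrom).
#' @param screening scalar coupling screening factor.
#' @return list with `ids`, `site_energies_eV`, `transition_dipoles`, `com`,
#'   `couplings_Ha`, `exciton_energies_eV`, `contributions`.
#' @export
oracle_frame <- function(qcs, frame, min_distance = 0.5, screening = 1.0) {
  if (inherits(qcs, "quantum_center")) qcs <- list(qcs)
  nq <- length(qcs)
  site_eV <- numeric(nq)
  mus <- matrix(0, nq, 3)
  coms <- matrix(0, nq, 3)
  ids <- character(nq)
  for (qi in seq_len(nq)) {
    qc <- qcs[[qi]]
    ids[qi] <- qc$id
    own <- frame$qc_atom_map[[qc$id]]
    # mass-weighted mean, loop form
    msum <- 0
    com <- c(0, 0, 0)
    for (k in seq_along(own)) {
      m <- ATOMIC_MASSES[[qc$atoms$element[k]]]
      msum <- msum + m
      com <- com + m * frame$coords[own[k], ]
    }
    com <- com / msum
    coms[qi, ] <- com
    # Coulomb sums over every non-own atom
    v <- 0
    e <- c(0, 0, 0)
    for (j in seq_len(nrow(frame$coords))) {
      if (j %in% own) next
      d_ang <- frame$coords[j, ] - com
      r_ang <- sqrt(sum(d_ang^2))
      if (r_ang < min_distance) {
        stop("oracle: atom ", j, " within ", min_distance,
             " Angstrom of QC '", qc$id, "' in frame ", frame$frame_index,
             call. = FALSE)
      }
      r <- r_ang * BOHR_PER_ANGSTROM
      q <- frame$charges[j]
      v <- v + q / r
      e <- e + q * (-d_ang * BOHR_PER_ANGSTROM) / r^3
    }
    n <- qc$electronic$n_states
    h <- matrix(0, n, n)
    for (a in 1:n) {
      for (b in 1:n) {
        h[a, b] <- -(e[1] * qc$electronic$dipoles[a, b, 1] +
                     e[2] * qc$electronic$dipoles[a, b, 2] +
                     e[3] * qc$electronic$dipoles[a, b, 3])
        if (a == b) {
          h[a, b] <- h[a, b] + qc$electronic$energies[a] +
            qc$total_charge * v
        }
      }
    }
    es <- jacobi_eigen(h)
    site_eV[qi] <- (es$values[2] - es$values[1]) * HARTREE_EV
    for (k in 1:3) {
      acc <- 0
      for (a in 1:n) for (b in 1:n) {
        acc <- acc + es$vectors[a, 1] * qc$electronic$dipoles[a, b, k] *
          es$vectors[b, 2]
      }
      mus[qi, k] <- acc
    }
  }
  coup <- matrix(0, nq, nq)
  if (nq >= 2) {
    for (i in 1:(nq - 1)) {
      for (j in (i + 1):nq) {
        dr <- (coms[i, ] - coms[j, ]) * BOHR_PER_ANGSTROM
        r <- sqrt(sum(dr^2))
        nhat <- dr / r
        vij <- (sum(mus[i, ] * mus[j, ]) -
                3 * sum(mus[i, ] * nhat) * sum(mus[j, ] * nhat)) / r^3
        coup[i, j] <- coup[j, i] <- screening * vij
      }
    }
  }
  dh <- coup
  for (i in seq_len(nq)) dh[i, i] <- site_eV[i] / HARTREE_EV
  exc <- jacobi_eigen(dh)
  list(ids = ids, site_energies_eV = site_eV, transition_dipoles = mus,
       com = coms, couplings_Ha = coup,
       exciton_energies_eV = exc$values * HARTREE_EV,
       contributions = exc$vectors^2)
}

#' Check pipeline output against the brute-force reference
#'
#' Re-evaluates every frame of a synthetic dataset with an independently
#' coded brute-force implementation (plain Coulomb/Hamiltonian loops and a
#' Jacobi eigensolver) and reports the maximum absolute deviation of the
#' pipeline's site energies, couplings and exciton energies from it.
#'
#' @param qcs list of [quantum_center] objects used by the pipeline run.
#' @param ensemble the same list of [environment_frame] objects.
#' @param traces output of [run_site_energy_stage()].
#' @param solutions output of [run_exciton_stage()] (optional).
#' @param tol flag threshold in Hartree (default 1e-10).
#' @return list with per-quantity maximum absolute deviations (Hartree) and
#'   a logical `ok`.
#' @export
ground_truth_check <- function(qcs, ensemble, traces, solutions = NULL,
                               tol = 1e-10) {
  if (inherits(qcs, "quantum_center")) qcs <- list(qcs)
  ids <- vapply(qcs, `[[`, character(1), "id")
  dev_site <- 0
  dev_coup <- 0
  dev_exc <- 0
  for (fi in seq_along(ensemble)) {
    frame <- ensemble[[fi]]
    ref <- oracle_frame(qcs, frame)
    for (qi in seq_along(ids)) {
      tr <- traces[[ids[qi]]]
      row <- tr[tr$frame_index == frame$frame_index, ]
      dev_site <- max(dev_site,
        abs(row$site_energy_eV - ref$site_energies_eV[qi]) / HARTREE_EV)
    }
    if (!is.null(solutions)) {
      s <- solutions[[fi]]
      dev_coup <- max(dev_coup,
        max(abs(s$coupling_matrix / EV_CM1 / HARTREE_EV - ref$couplings_Ha)))
      dev_exc <- max(dev_exc,
        max(abs(s$exciton_energies - ref$exciton_energies_eV)) / HARTREE_EV)
    }
  }
  out <- list(max_dev_site_Ha = dev_site, max_dev_coupling_Ha = dev_coup,
              max_dev_exciton_Ha = dev_exc,
              ok = max(dev_site, dev_coup, dev_exc) <= tol)
  out
}
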