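# Standard atomic weights (IUPAC 2021, conventional values), isotope-averaged.
# Hydrogens count toward the center of mass; every atom listed in a property
# file contributes (truncation atoms included).
ATOMIC_MASSES <- c(
  H = 1.008, He = 4.0026, Li = 6.94, Be = 9.0122, B = 10.81, C = 12.011,
  N = 14.007, O = 15.999, F = 18.998, Ne = 20.180, Na = 22.990, Mg = 24.305,
  Al = 26.982, Si = 28.085, P = 30.974, S = 32.06, Cl = 35.45, Ar = 39.95,
  K = 39.098, Ca = 40.078, Mn = 54.938, Fe = 55.845, Co = 58.933, Ni = 58.693,
  Cu = 63.546, Zn = 65.38, Br = 79.904, I = 126.90
)

atomic_mass <- function(element) {
  m <- ATOMIC_MASSES[element]
  if (anyNA(m)) {
    bad <- unique(element[is.na(m)])
    stop("unknown element symbol(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  unname(m)
}

#' Mass-weighted center of mass
#'
#' @param atoms data.frame with columns `element`, `x`, `y`, `z` (Angstrom),
#'   or a [quantum_center].
#' @param coords optional n x 3 matrix overriding the reference coordinates
#'   (e.g. the atoms' instantaneous positions in a trajectory frame).
#' @return length-3 numeric vector (Angstrom).
#' @export
center_of_mass <- function(atoms, coords = NULL) {
  if (inherits(atoms, "quantum_center")) atoms <- atoms$atoms
  stopifnot(is.data.frame(atoms), nrow(atoms) > 0)
  m <- atomic_mass(atoms$element)
  if (is.null(coords)) {
    coords <- cbind(atoms$x, atoms$y, atoms$z)
  } else {
    coords <- as.matrix(coords)
    stopifnot(nrow(coords) == nrow(atoms), ncol(coords) == 3)
  }
  as.numeric(colSums(coords * m) / sum(m))
}

#' Unperturbed electronic data of a quantum center
#'
#' Holds the gas-phase electronic structure a perturbed-matrix calculation
#' starts from: the eigenvalues of the unperturbed Hamiltonian and the full
#' dipole matrix (diagonal entries are permanent dipoles, off-diagonal entries
#' transition dipoles), everything in atomic units.
#'
#' @param energies numeric vector of state energies in Hartree, ascending.
#' @param dipoles numeric array of dimension `c(n, n, 3)`: the (i, j) dipole
#'   3-vector in a.u. Must be symmetric in its first two indices.
#' @return an object of class `electronic_data`.
#' @export
electronic_data <- function(energies, dipoles) {
  n <- length(energies)
  if (n < 2) stop("at least 2 electronic states are required", call. = FALSE)
  if (is.unsorted(energies)) {
    stop("state energies must be ascending", call. = FALSE)
  }
  dipoles <- .as_dipole_array(dipoles, n)
  for (k in 1:3) {
    s <- dipoles[, , k]
    if (max(abs(s - t(s))) > 1e-10) {
      stop("dipole matrix must be symmetric (mu_ij = mu_ji)", call. = FALSE)
    }
  }
  structure(list(n_states = n, energies = as.numeric(energies),
                 dipoles = dipoles),
            class = "electronic_data")
}

.as_dipole_array <- function(dipoles, n) {
  dipoles <- unname(dipoles)
  if (!is.array(dipoles) || length(dim(dipoles)) != 3 ||
      !all(dim(dipoles) == c(n, n, 3))) {
    stop("dipoles must be an n x n x 3 array matching length(energies)",
         call. = FALSE)
  }
  storage.mode(dipoles) <- "double"
  dipoles
}

#' A quantum center: pigment treated quantum mechanically
#'
#' A quantum center (QC) is the fragment of the system treated at the quantum
#' level — here a chlorophyll-like chromophore (or an explicitly computed
#' dimer) with its atoms, total charge and unperturbed electronic data. All
#' other atoms form the perturbing environment.
#'
#' @param id short label, e.g. `"C1"` or `"C7-C9"`.
#' @param atoms data.frame with columns `element`, `x`, `y`, `z` (reference
#'   geometry, Angstrom).
#' @param total_charge integer total charge q_T in electron units.
#' @param electronic an [electronic_data] object.
#' @param kind `"monomer"` or `"dimer"`.
#' @return object of class `quantum_center`.
#' @export
quantum_center <- function(id, atoms, total_charge, electronic,
                           kind = c("monomer", "dimer")) {
  kind <- match.arg(kind)
  stopifnot(is.character(id), length(id) == 1, nzchar(id))
  stopifnot(is.data.frame(atoms), nrow(atoms) > 0,
            all(c("element", "x", "y", "z") %in% names(atoms)))
  if (abs(total_charge - round(total_charge)) > 1e-9) {
    stop("total_charge must be an integer number of electron charges",
         call. = FALSE)
  }
  atomic_mass(atoms$element)  # validates symbols early
  stopifnot(inherits(electronic, "electronic_data"))
  structure(list(id = id, atoms = atoms[c("element", "x", "y", "z")],
                 total_charge = as.integer(round(total_charge)),
                 electronic = electronic, kind = kind),
            class = "quantum_center")
}

#' @export
print.quantum_center <- function(x, ...) {
  cat(sprintf("<quantum_center %s (%s): %d atoms, q_T = %+d, %d states>\n",
              x$id, x$kind, nrow(x$atoms), x$total_charge,
              x$electronic$n_states))
  invisible(x)
}

#' One configuration of the perturbing environment
#'
#' @param frame_index integer frame label.
#' @param coords n x 3 matrix of all-atom coordinates (Angstrom).
#' @param charges length-n numeric vector of fixed partial charges (e).
#' @param qc_atom_map named list: for each QC id, the integer indices of that
#'   QC's own atoms within `coords` (disjoint across QCs).
#' @return object of class `environment_frame`.
#' @export
environment_frame <- function(frame_index, coords, charges, qc_atom_map) {
  coords <- as.matrix(coords)
  if (ncol(coords) != 3) stop("coords must be n x 3", call. = FALSE)
  if (nrow(coords) != length(charges)) {
    stop(sprintf("frame %d: %d coordinates but %d charges",
                 frame_index, nrow(coords), length(charges)), call. = FALSE)
  }
  idx <- unlist(qc_atom_map, use.names = FALSE)
  if (anyDuplicated(idx)) {
    stop("qc_atom_map index sets overlap between QCs", call. = FALSE)
  }
  if (length(idx) && (min(idx) < 1 || max(idx) > nrow(coords))) {
    stop("qc_atom_map indices outside the frame's atom range", call. = FALSE)
  }
  structure(list(frame_index = as.integer(frame_index), coords = coords,
                 charges = as.numeric(charges), qc_atom_map = qc_atom_map),
            class = "environment_frame")
}

#' Electrostatic perturbation at a quantum center
#'
#' @param potential scalar potential V in a.u.
#' @param field length-3 electric field in a.u.
#' @param evaluation_point length-3 evaluation point (QC center of mass, Angstrom).
#' @return object of class `perturbation_field`.
#' @export
perturbation_field <- function(potential, field, evaluation_point) {
  stopifnot(length(potential) == 1, length(field) == 3,
            length(evaluation_point) == 3)
  if (!all(is.finite(c(potential, field)))) {
    stop("non-finite perturbation (charge too close to evaluation point?)",
         call. = FALSE)
  }
  structure(list(potential = as.numeric(potential),
                 field = as.numeric(field),
                 evaluation_point = as.numeric(evaluation_point)),
            class = "perturbation_field")
}
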