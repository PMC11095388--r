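# Synthetic-data generator: emulates the statistical structure of the real
# inputs (an MD trajectory of a pigment-protein complex plus excited-state
# calculations per pigment) with a fully known ground truth, so every
# pipeline stage is testable without external data. Pseudo-atoms are plain
# mass carriers; the electronic data are prescribed, not computed.

#' Specification for a synthetic dataset
#'
#' Defaults state a chlorophyll-like world: first excitation gaps spread over
#' 1.87-1.97 eV, second excitations ~0.4 eV above, transition dipoles of
#' ~2 a.u. (oscillator strength ~0.2 at 1.9 eV), mean-zero fixed partial
#' charges whose per-frame positional jitter produces roughly Gaussian
#' site-energy distributions with meV-scale standard deviations, frames
#' spaced 10 ps apart. The optional two-basin switch relocates a charged
#' group between two sites in alternating blocks, producing bimodal
#' first-exciton energies.
#'
#' @param n_qcs number of quantum centers.
#' @param gaps_eV per-QC unperturbed first-excitation gaps (eV); default
#'   evenly spaced over 1.87-1.97.
#' @param gap2_offset_eV second excitation sits this far above the first.
#' @param dipole_magnitude_au transition-dipole magnitude (a.u.).
#' @param n_env_atoms number of environment point charges.
#' @param charge_sd_e standard deviation of the fixed charges (e).
#' @param jitter_sigma_A per-frame isotropic positional jitter of environment
#'   atoms (Angstrom).
#' @param qc_jitter_sigma_A per-frame rigid-body translation jitter of each
#'   QC (Angstrom).
#' @param n_frames number of frames.
#' @param frame_spacing_ps time between frames (ps).
#' @param seed mandatory RNG seed (R's default Mersenne-Twister).
#' @param qc_spacing_A spacing of QC centers along x (Angstrom).
#' @param min_env_distance_A minimum distance of environment charges from
#'   every QC center of mass.
#' @param two_basin `NULL`, or a list with `block_length` (frames per basin
#'   block), `displacement_A` (how far the switch group moves), `group_size`
#'   and `group_charge_e`.
#' @return object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_qcs = 3,
                           gaps_eV = NULL,
                           gap2_offset_eV = 0.4,
                           dipole_magnitude_au = 2.0,
                           n_env_atoms = 150,
                           charge_sd_e = 0.15,
                           jitter_sigma_A = 0.3,
                           qc_jitter_sigma_A = 0.05,
                           n_frames = 100,
                           frame_spacing_ps = 10,
                           seed,
                           qc_spacing_A = 15,
                           min_env_distance_A = 6,
                           two_basin = NULL) {
  if (missing(seed) || is.null(seed)) {
    stop("a seed is mandatory for reproducibility", call. = FALSE)
  }
  if (is.null(gaps_eV)) {
    gaps_eV <- if (n_qcs == 1) 1.90 else seq(1.87, 1.97, length.out = n_qcs)
  }
  stopifnot(length(gaps_eV) == n_qcs, n_qcs >= 1, n_env_atoms >= 1,
            n_frames >= 1, frame_spacing_ps > 0, jitter_sigma_A >= 0,
            qc_jitter_sigma_A >= 0, dipole_magnitude_au > 0)
  if (!is.null(two_basin)) {
    defaults <- list(block_length = max(1L, n_frames %/% 10L),
                     displacement_A = 4, group_size = 6L,
                     group_charge_e = 0.35)
    two_basin <- utils::modifyList(defaults, two_basin)
    two_basin$block_length <- as.integer(two_basin$block_length)
    two_basin$group_size <- as.integer(two_basin$group_size)
  }
  structure(list(n_qcs = n_qcs, gaps_eV = gaps_eV,
                 gap2_offset_eV = gap2_offset_eV,
                 dipole_magnitude_au = dipole_magnitude_au,
                 n_env_atoms = n_env_atoms, charge_sd_e = charge_sd_e,
                 jitter_sigma_A = jitter_sigma_A,
                 qc_jitter_sigma_A = qc_jitter_sigma_A,
                 n_frames = n_frames, frame_spacing_ps = frame_spacing_ps,
                 seed = as.integer(seed), qc_spacing_A = qc_spacing_A,
                 min_env_distance_A = min_env_distance_A,
                 two_basin = two_basin),
            class = "synthetic_spec")
}

.random_unit_vector <- function() {
  v <- stats::rnorm(3)
  v / sqrt(sum(v^2))
}

# Five carbon pseudo-atoms in a fixed cross; enough to define a center of
# mass and give the QC spatial extent.
.qc_template_atoms <- function() {
  data.frame(element = rep("C", 5),
             x = c(0, 1.5, -1.5, 0, 0),
             y = c(0, 0, 0, 1.5, -1.5),
             z = rep(0, 5))
}

#' Generate the quantum-center set
#'
#' Creates `n_qcs` three-state quantum centers: first gap exactly the
#' requested target (pre-perturbation), second gap `gap2_offset_eV` above,
#' randomly oriented transition dipoles of the requested magnitude, small
#' random permanent-dipole differences (the lever arm the fluctuating field
#' acts on). QCs are laid out along x at `qc_spacing_A`.
#'
#' @param spec a [synthetic_spec].
#' @param out_dir optional directory; when given, one JSON property file per
#'   QC is written.
#' @return list with `qcs` (list of [quantum_center]) and `files`.
#' @export
generate_qc_set <- function(spec, out_dir = NULL) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  qcs <- vector("list", spec$n_qcs)
  files <- character(0)
  for (qi in seq_len(spec$n_qcs)) {
    gap1 <- convert_energy(spec$gaps_eV[qi], "eV", "hartree")
    gap2 <- convert_energy(spec$gaps_eV[qi] + spec$gap2_offset_eV,
                           "eV", "hartree")
    energies <- c(0, gap1, gap2)
    dip <- array(0, c(3, 3, 3))
    mu01 <- spec$dipole_magnitude_au * .random_unit_vector()
    mu02 <- 0.5 * .random_unit_vector()
    mu12 <- 0.3 * .random_unit_vector()
    # permanent dipoles: ground small, excited differ by ~1.5 a.u.
    p0 <- 0.3 * .random_unit_vector()
    p1 <- p0 + 1.5 * .random_unit_vector()
    p2 <- p0 + 1.0 * .random_unit_vector()
    dip[1, 1, ] <- p0; dip[2, 2, ] <- p1; dip[3, 3, ] <- p2
    dip[1, 2, ] <- dip[2, 1, ] <- mu01
    dip[1, 3, ] <- dip[3, 1, ] <- mu02
    dip[2, 3, ] <- dip[3, 2, ] <- mu12
    atoms <- .qc_template_atoms()
    atoms$x <- atoms$x + (qi - 1) * spec$qc_spacing_A
    qc <- quantum_center(sprintf("Q%02d", qi), atoms, 0L,
                         electronic_data(energies, dip), kind = "monomer")
    qcs[[qi]] <- qc
    if (!is.null(out_dir)) {
      dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
      f <- file.path(out_dir, sprintf("qc_%02d.json", qi))
      write_qc_properties(qc, f)
      files <- c(files, f)
    }
  }
  list(qcs = qcs, files = files)
}

#' Generate the environment ensemble
#'
#' Places `n_env_atoms` fixed point charges uniformly in a box around the
#' QCs, at least `min_env_distance_A` from every QC center of mass (bounded
#' retries), then jitters every atom per frame by an isotropic Gaussian. QCs
#' undergo small rigid-body translations so their centers of mass move. In
#' two-basin mode an extra charged group alternates between two sites in
#' blocks of `block_length` frames, producing two distinct mean
#' perturbations.
#'
#' @param spec a [synthetic_spec].
#' @param qcs QC list from [generate_qc_set()].
#' @param out_dir optional directory; when given, `ensemble.xyz`,
#'   `charges.dat` and `manifest.json` are written.
#' @return list with `ensemble` (list of [environment_frame]), `manifest`
#'   and `files`.
#' @export
generate_environment_ensemble <- function(spec, qcs, out_dir = NULL) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed + 1L)
  qc_coms <- t(vapply(qcs, function(q) center_of_mass(q$atoms), numeric(3)))
  lo <- apply(qc_coms, 2, min) - 12
  hi <- apply(qc_coms, 2, max) + 12
  n_env <- spec$n_env_atoms
  env_pos <- matrix(0, n_env, 3)
  placed <- 0L
  tries <- 0L
  max_tries <- 200L * n_env
  while (placed < n_env) {
    tries <- tries + 1L
    if (tries > max_tries) {
      stop("could not place environment charges after ", max_tries,
           " attempts (box too crowded?)", call. = FALSE)
    }
    p <- stats::runif(3, lo, hi)
    d <- sqrt(rowSums(sweep(qc_coms, 2, p)^2))
    if (min(d) < spec$min_env_distance_A) next
    placed <- placed + 1L
    env_pos[placed, ] <- p
  }
  env_charges <- stats::rnorm(n_env, 0, spec$charge_sd_e)

  tb <- spec$two_basin
  switch_pos_A <- switch_pos_B <- NULL
  switch_charges <- numeric(0)
  if (!is.null(tb)) {
    g <- tb$group_size
    base <- qc_coms[1, ] + c(0, 7, 0)
    switch_pos_A <- matrix(rep(base, each = g), g, 3) +
      matrix(stats::rnorm(3 * g, 0, 1), g, 3)
    switch_pos_B <- sweep(switch_pos_A, 2, c(0, tb$displacement_A, 0), `+`)
    switch_charges <- rep(tb$group_charge_e, g)
  }

  qc_atoms_list <- lapply(qcs, function(q) as.matrix(q$atoms[, c("x", "y", "z")]))
  qc_elems <- lapply(qcs, function(q) q$atoms$element)
  n_qc_atoms <- vapply(qc_atoms_list, nrow, integer(1))
  offsets <- cumsum(c(0, n_qc_atoms[-length(n_qc_atoms)]))
  qc_atom_map <- lapply(seq_along(qcs), function(i) {
    offsets[i] + seq_len(n_qc_atoms[i])
  })
  names(qc_atom_map) <- vapply(qcs, `[[`, character(1), "id")
  n_qc_total <- sum(n_qc_atoms)

  charges <- c(rep(0, n_qc_total), env_charges, switch_charges)
  elements <- c(unlist(qc_elems), rep("He", n_env),
                rep("Na", length(switch_charges)))

  basin_of_frame <- function(fi) {
    if (is.null(tb)) return(NA_integer_)
    1L + (((fi - 1L) %/% tb$block_length) %% 2L)
  }

  ensemble <- vector("list", spec$n_frames)
  for (fi in seq_len(spec$n_frames)) {
    coords <- matrix(0, length(charges), 3)
    for (i in seq_along(qcs)) {
      shift <- stats::rnorm(3, 0, spec$qc_jitter_sigma_A)
      coords[qc_atom_map[[i]], ] <- sweep(qc_atoms_list[[i]], 2, shift, `+`)
    }
    env_jit <- env_pos + matrix(stats::rnorm(3 * n_env, 0,
                                             spec$jitter_sigma_A), n_env, 3)
    coords[n_qc_total + seq_len(n_env), ] <- env_jit
    if (!is.null(tb)) {
      sp <- if (basin_of_frame(fi) == 1L) switch_pos_A else switch_pos_B
      g <- nrow(sp)
      coords[n_qc_total + n_env + seq_len(g), ] <-
        sp + matrix(stats::rnorm(3 * g, 0, spec$jitter_sigma_A), g, 3)
    }
    ef <- environment_frame(fi, coords, charges, qc_atom_map)
    ef$elements <- elements
    ensemble[[fi]] <- ef
  }

  manifest <- list(
    generator = "excitonpmm synthetic_data",
    seed = spec$seed,
    n_qcs = spec$n_qcs,
    gaps_eV = spec$gaps_eV,
    dipole_magnitude_au = spec$dipole_magnitude_au,
    n_env_atoms = n_env,
    charge_sd_e = spec$charge_sd_e,
    jitter_sigma_A = spec$jitter_sigma_A,
    qc_jitter_sigma_A = spec$qc_jitter_sigma_A,
    n_frames = spec$n_frames,
    frame_spacing_ps = spec$frame_spacing_ps,
    span_ps = spec$n_frames * spec$frame_spacing_ps,
    qc_atom_map = qc_atom_map,
    two_basin = if (is.null(tb)) NULL else c(tb, list(
      basin_of_frame = vapply(seq_len(spec$n_frames), basin_of_frame,
                              integer(1))))
  )

  files <- character(0)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    fx <- file.path(out_dir, "ensemble.xyz")
    write_xyz(ensemble, fx)
    fq <- file.path(out_dir, "charges.dat")
    writeLines(sprintf("%d %.10f", seq_along(charges), charges), fq)
    fm <- file.path(out_dir, "manifest.json")
    manifest$coordinates <- "ensemble.xyz"
    manifest$charge_table <- "charges.dat"
    manifest$qc_property_files <- sprintf("qc_%02d.json", seq_len(spec$n_qcs))
    jsonlite::write_json(manifest, fm, auto_unbox = TRUE, digits = NA)
    files <- c(fx, fq, fm)
  }
  list(ensemble = ensemble, manifest = manifest, files = files)
}

#' Generate a complete synthetic dataset on disk
#'
#' Convenience wrapper: [generate_qc_set()] then
#' [generate_environment_ensemble()], all files under `out_dir`.
#'
#' @param spec a [synthetic_spec].
#' @param out_dir output directory.
#' @return list with `qcs`, `ensemble`, `manifest`, `files`.
#' @export
generate_dataset <- function(spec, out_dir) {
  qs <- generate_qc_set(spec, out_dir)
  env <- generate_environment_ensemble(spec, qs$qcs, out_dir)
  list(qcs = qs$qcs, ensemble = env$ensemble, manifest = env$manifest,
       files = c(qs$files, env$files))
}

#' Reference (unjittered) site energies of a synthetic dataset
#'
#' Evaluates the brute-force oracle on the reference configuration — every
#' atom at its mean position, the switch group (if any) at the requested
#' basin — giving the ground-truth baseline the jittered ensemble fluctuates
#' around.
#'
#' @param spec a [synthetic_spec].
#' @param qcs,ensemble from [generate_dataset()] (the first frame's layout is
#'   reused; only positions are replaced by their means).
#' @param basin 1 or 2 (ignored without two-basin mode).
#' @return list as from `oracle_frame`.
#' @export
reference_frame_quantities <- function(spec, qcs, ensemble, basin = 1L) {
  # Mean positions: QC atoms at template positions, environment at its base
  # placement. Regenerate deterministically from the seed.
  env <- .regenerate_base_positions(spec, qcs)
  coords <- env$coords
  if (!is.null(spec$two_basin) && basin == 2L) {
    g <- spec$two_basin$group_size
    n <- nrow(coords)
    idx <- (n - g + 1L):n
    coords[idx, ] <- sweep(coords[idx, ], 2,
                           c(0, spec$two_basin$displacement_A, 0), `+`)
  }
  frame <- environment_frame(0L, coords, env$charges, env$qc_atom_map)
  oracle_frame(qcs, frame)
}

# Re-draws the base placement with the same RNG stream the generator used
# (same seed offset and draw order, before any per-frame jitter).
.regenerate_base_positions <- function(spec, qcs) {
  set.seed(spec$seed + 1L)
  qc_coms <- t(vapply(qcs, function(q) center_of_mass(q$atoms), numeric(3)))
  lo <- apply(qc_coms, 2, min) - 12
  hi <- apply(qc_coms, 2, max) + 12
  n_env <- spec$n_env_atoms
  env_pos <- matrix(0, n_env, 3)
  placed <- 0L
  while (placed < n_env) {
    p <- stats::runif(3, lo, hi)
    d <- sqrt(rowSums(sweep(qc_coms, 2, p)^2))
    if (min(d) < spec$min_env_distance_A) next
    placed <- placed + 1L
    env_pos[placed, ] <- p
  }
  env_charges <- stats::rnorm(n_env, 0, spec$charge_sd_e)
  tb <- spec$two_basin
  switch_pos <- NULL
  switch_charges <- numeric(0)
  if (!is.null(tb)) {
    g <- tb$group_size
    base <- qc_coms[1, ] + c(0, 7, 0)
    switch_pos <- matrix(rep(base, each = g), g, 3) +
      matrix(stats::rnorm(3 * g, 0, 1), g, 3)
    switch_charges <- rep(tb$group_charge_e, g)
  }
  qc_atoms <- lapply(qcs, function(q) as.matrix(q$atoms[, c("x", "y", "z")]))
  n_qc_atoms <- vapply(qc_atoms, nrow, integer(1))
  offsets <- cumsum(c(0, n_qc_atoms[-length(n_qc_atoms)]))
  qc_atom_map <- lapply(seq_along(qcs), function(i) {
    offsets[i] + seq_len(n_qc_atoms[i])
  })
  names(qc_atom_map) <- vapply(qcs, `[[`, character(1), "id")
  coords <- do.call(rbind, c(qc_atoms, list(env_pos),
                             if (is.null(switch_pos)) NULL else list(switch_pos)))
  charges <- c(rep(0, sum(n_qc_atoms)), env_charges, switch_charges)
  list(coords = coords, charges = charges, qc_atom_map = qc_atom_map)
}
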