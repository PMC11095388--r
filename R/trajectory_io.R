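# Readers and writers. Coordinates arrive as multi-frame XYZ or multi-MODEL
# PDB in Angstrom; charges come from a separate plain-text table (explicit and
# format-stable, not PDB B-factors). No PBC handling: inputs are assumed
# pre-imaged.

.read_xyz_frames <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) | seq_along(lines) %in% integer(0)]
  frames <- list()
  i <- 1L
  k <- 0L
  while (i <= length(lines)) {
    nat <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(nat) || nat <= 0) {
      stop("XYZ parse error at line ", i, ": expected an atom count",
           call. = FALSE)
    }
    if (i + 1L + nat > length(lines)) {
      stop("XYZ truncated: frame starting at line ", i, " declares ", nat,
           " atoms", call. = FALSE)
    }
    block <- lines[(i + 2L):(i + 1L + nat)]
    parts <- strsplit(trimws(block), "[[:space:]]+")
    elem <- vapply(parts, `[[`, character(1), 1L)
    xyz <- t(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3)))
    if (anyNA(xyz)) {
      stop("XYZ parse error in frame ", k + 1L, ": non-numeric coordinate",
           call. = FALSE)
    }
    k <- k + 1L
    frames[[k]] <- list(elements = elem, coords = xyz)
    i <- i + 2L + nat
  }
  frames
}

.read_pdb_frames <- function(path) {
  lines <- readLines(path)
  atom <- grepl("^(ATOM  |HETATM)", lines)
  model_starts <- which(grepl("^MODEL", lines))
  parse_block <- function(ls) {
    ls <- ls[grepl("^(ATOM  |HETATM)", ls)]
    elem <- trimws(substr(ls, 77, 78))
    fallback <- trimws(substr(ls, 13, 14))
    elem[!nzchar(elem)] <- gsub("[0-9]", "", fallback[!nzchar(elem)])
    xyz <- cbind(as.numeric(substr(ls, 31, 38)),
                 as.numeric(substr(ls, 39, 46)),
                 as.numeric(substr(ls, 47, 54)))
    if (anyNA(xyz)) stop("PDB parse error: bad coordinate field", call. = FALSE)
    list(elements = elem, coords = xyz)
  }
  if (length(model_starts) == 0L) {
    return(list(parse_block(lines[atom])))
  }
  ends <- c(model_starts[-1] - 1L, length(lines))
  lapply(seq_along(model_starts), function(k) {
    parse_block(lines[model_starts[k]:ends[k]])
  })
}

.read_charge_table <- function(path) {
  dt <- data.table::fread(path, header = FALSE)
  if (ncol(dt) == 1L) {
    q <- dt[[1]]
  } else {
    q <- dt[[2]][order(dt[[1]])]
  }
  if (!is.numeric(q) || anyNA(q)) {
    stop("charge table '", path, "' contains non-numeric charges",
         call. = FALSE)
  }
  as.numeric(q)
}

#' Read an environment ensemble
#'
#' Reads a multi-frame XYZ (or multi-MODEL PDB) coordinate file plus a
#' per-atom fixed-charge table, and resolves the atom-index sets of each
#' quantum center. Every frame must carry the same atom count, equal to the
#' charge-table length; mismatches are rejected, never truncated.
#'
#' @param coordinates_path multi-frame `.xyz` or multi-MODEL `.pdb` file.
#' @param charge_table_path text file with one charge per atom (either a
#'   single column, or `index charge` pairs).
#' @param qc_definitions named list mapping QC id to the integer atom indices
#'   of that QC within each frame (disjoint sets).
#' @return list of [environment_frame] objects.
#' @export
read_environment_ensemble <- function(coordinates_path, charge_table_path,
                                      qc_definitions = list()) {
  raw <- if (grepl("\\.pdb$", coordinates_path, ignore.case = TRUE)) {
    .read_pdb_frames(coordinates_path)
  } else {
    .read_xyz_frames(coordinates_path)
  }
  charges <- .read_charge_table(charge_table_path)
  lapply(seq_along(raw), function(k) {
    fr <- raw[[k]]
    if (nrow(fr$coords) != length(charges)) {
      stop(sprintf(
        "frame %d has %d atoms but the charge table lists %d charges",
        k, nrow(fr$coords), length(charges)), call. = FALSE)
    }
    ef <- environment_frame(k, fr$coords, charges, qc_definitions)
    ef$elements <- fr$elements
    ef
  })
}

#' Subsample frames on a time window
#'
#' Selects frames at times `start_time + k * stride`, `k >= 1`, up to and
#' including `end_time` (half-open at the start), given a declared frame
#' spacing. A 30 ns window at 10 ps stride thus yields exactly 3000 frames.
#' Frame `i` is taken to sit at time `(i - 1) * frame_spacing`.
#'
#' @param frames list of [environment_frame] objects.
#' @param start_time,end_time window bounds (ps).
#' @param stride sampling interval (ps), > 0.
#' @param frame_spacing time between stored frames (ps), > 0.
#' @return the selected sub-list of frames (possibly empty, with a warning).
#' @export
subsample_frames <- function(frames, start_time, end_time, stride,
                             frame_spacing = stride) {
  if (stride <= 0) stop("stride must be > 0", call. = FALSE)
  if (frame_spacing <= 0) stop("frame_spacing must be > 0", call. = FALSE)
  times <- seq(start_time + stride, end_time, by = stride)
  idx <- round(times / frame_spacing) + 1L
  idx <- idx[idx >= 1L & idx <= length(frames)]
  if (length(idx) == 0L) {
    warning("subsample_frames: empty selection")
    return(list())
  }
  frames[idx]
}

#' Read a quantum-center property file
#'
#' Loads one QC from a structured-text (JSON) property file holding the
#' gas-phase electronic data an external excited-state calculation produced:
#' state energies (Hartree) and the dipole matrix entries `(i, j, dx, dy, dz)`
#' in a.u. with 0-based state indices. Upper-triangle entries suffice; the
#' matrix is symmetrized on load. Every pair `i <= j` must appear exactly
#' once and energies must be ascending.
#'
#' @param path JSON file conforming to the property-file schema.
#' @return a [quantum_center].
#' @export
read_qc_properties <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  req <- c("id", "kind", "total_charge", "atoms", "n_states", "energies",
           "dipoles")
  miss <- setdiff(req, names(doc))
  if (length(miss)) {
    stop("property file '", path, "' missing key(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  n <- as.integer(doc$n_states)
  if (length(doc$energies) != n) {
    stop("property file '", path, "': energies length != n_states",
         call. = FALSE)
  }
  if (is.unsorted(doc$energies)) {
    stop("property file '", path, "': energies not ascending", call. = FALSE)
  }
  dip <- as.data.frame(doc$dipoles)
  need <- c("i", "j", "dx", "dy", "dz")
  if (!all(need %in% names(dip))) {
    stop("property file '", path, "': dipole entries need columns i, j, dx, dy, dz",
         call. = FALSE)
  }
  # normalize to upper triangle (0-based indices in the file)
  ii <- pmin(dip$i, dip$j)
  jj <- pmax(dip$i, dip$j)
  key <- paste(ii, jj)
  if (anyDuplicated(key)) {
    stop("property file '", path, "': duplicate dipole entry (",
         key[duplicated(key)][1], ")", call. = FALSE)
  }
  expect <- outer(0:(n - 1), 0:(n - 1), function(a, b) paste(a, b))
  expect <- expect[upper.tri(expect, diag = TRUE)]
  miss <- setdiff(expect, key)
  if (length(miss)) {
    stop("property file '", path, "': missing dipole pair(s): ",
         paste(paste0("(", gsub(" ", ",", miss), ")"), collapse = " "),
         call. = FALSE)
  }
  arr <- array(0, c(n, n, 3))
  for (r in seq_len(nrow(dip))) {
    a <- ii[r] + 1L
    b <- jj[r] + 1L
    v <- c(dip$dx[r], dip$dy[r], dip$dz[r])
    arr[a, b, ] <- v
    arr[b, a, ] <- v
  }
  atoms <- as.data.frame(doc$atoms)
  quantum_center(doc$id, atoms, doc$total_charge,
                 electronic_data(as.numeric(doc$energies), arr),
                 kind = doc$kind)
}

#' Write a quantum-center property file
#'
#' Inverse of [read_qc_properties()]; upper-triangle dipole entries only.
#'
#' @param qc a [quantum_center].
#' @param path output JSON path.
#' @export
write_qc_properties <- function(qc, path) {
  n <- qc$electronic$n_states
  entries <- list()
  for (a in 1:n) for (b in a:n) {
    entries[[length(entries) + 1L]] <- list(
      i = a - 1L, j = b - 1L,
      dx = qc$electronic$dipoles[a, b, 1],
      dy = qc$electronic$dipoles[a, b, 2],
      dz = qc$electronic$dipoles[a, b, 3])
  }
  doc <- list(id = qc$id, kind = qc$kind, total_charge = qc$total_charge,
              atoms = qc$atoms, n_states = n,
              energies = qc$electronic$energies,
              dipoles = data.table::rbindlist(entries))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}

# Paper tables use the Unicode minus; normalize on ingest.
.ascii_minus <- function(x) gsub("−", "-", x)

#' Read a tabulated site-energy table
#'
#' CSV keyed by pigment label with named numeric columns (gas-phase energy
#' and oscillator strength; embedded energies, oscillator strengths and
#' shifts; ensemble mean and standard deviation). Unicode minus signs are
#' normalized to ASCII on ingest.
#'
#' @param csv_path CSV file with a header row and a `site` column.
#' @return data.frame of class `site_table`, one row per pigment.
#' @export
read_site_table <- function(csv_path) {
  df <- as.data.frame(data.table::fread(csv_path, header = TRUE))
  if (!"site" %in% names(df)) {
    stop("site table '", csv_path, "' needs a 'site' column", call. = FALSE)
  }
  for (cn in setdiff(names(df), "site")) {
    v <- df[[cn]]
    if (is.character(v)) v <- suppressWarnings(as.numeric(.ascii_minus(v)))
    if (anyNA(v)) {
      stop("non-numeric cell in site table column '", cn, "', row '",
           df$site[which(is.na(v))[1]], "'", call. = FALSE)
    }
    df[[cn]] <- v
  }
  class(df) <- c("site_table", "data.frame")
  df
}

#' Read a tabulated coupling matrix
#'
#' CSV with pigment labels on both axes, upper-triangular or full; the result
#' is symmetrized with a zero diagonal, in cm^-1.
#'
#' @param csv_path CSV file; first column holds the row labels.
#' @return symmetric labelled matrix (cm^-1).
#' @export
read_coupling_table <- function(csv_path) {
  df <- as.data.frame(data.table::fread(csv_path, header = TRUE,
                                        colClasses = "character"))
  row_labels <- as.character(df[[1]])
  col_labels <- names(df)[-1]
  labels <- unique(c(row_labels, col_labels))
  m <- matrix(0, length(labels), length(labels),
              dimnames = list(labels, labels))
  for (r in seq_along(row_labels)) {
    for (cn in col_labels) {
      raw <- df[r, cn]
      if (is.na(raw) || !nzchar(trimws(raw))) next  # empty: other triangle
      v <- suppressWarnings(as.numeric(.ascii_minus(raw)))
      if (is.na(v)) {
        stop("non-numeric cell in coupling table at (", row_labels[r], ", ",
             cn, "): '", raw, "'", call. = FALSE)
      }
      m[row_labels[r], cn] <- v
      m[cn, row_labels[r]] <- v
    }
  }
  diag(m) <- 0
  m
}

#' Write pipeline results
#'
#' Writes per-frame site energies, a mean/std summary, the mean coupling
#' matrix and JSON exciton summaries under `out_dir`. Full per-frame
#' eigenvector matrices are optionally dumped as one long-format CSV.
#'
#' @param traces named list of site-energy traces (may be `NULL`).
#' @param solutions list of `exciton_solution` (may be `NULL`).
#' @param out_dir output directory (created if absent).
#' @param eigenvectors if `TRUE`, also dump per-frame exciton eigenvectors.
#' @return invisible character vector of the files written.
#' @export
write_results <- function(traces, solutions, out_dir, eigenvectors = FALSE) {
  if ((is.null(traces) || length(traces) == 0) &&
      (is.null(solutions) || length(solutions) == 0)) {
    stop("nothing to write: both traces and solutions are empty",
         call. = FALSE)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  if (!is.null(traces) && length(traces)) {
    per <- data.table::rbindlist(lapply(names(traces), function(id) {
      cbind(qc = id, traces[[id]])
    }))
    f <- file.path(out_dir, "site_energies.csv")
    data.table::fwrite(per, f)
    written <- c(written, f)
    summ <- data.table::rbindlist(lapply(names(traces), function(id) {
      tr <- traces[[id]]
      data.table::data.table(qc = id, n_frames = nrow(tr),
                             mean_eV = mean(tr$site_energy_eV),
                             sd_eV = stats::sd(tr$site_energy_eV),
                             mean_f_osc = mean(tr$f_osc))
    }))
    f <- file.path(out_dir, "site_summary.csv")
    data.table::fwrite(summ, f)
    written <- c(written, f)
  }
  if (!is.null(solutions) && length(solutions)) {
    if (length(solutions) >= 2) {
      cs <- coupling_statistics(solutions)
      f <- file.path(out_dir, "coupling_mean_cm1.csv")
      data.table::fwrite(data.table::as.data.table(cs$mean, keep.rownames = "site"), f)
      written <- c(written, f)
      f <- file.path(out_dir, "coupling_sd_cm1.csv")
      data.table::fwrite(data.table::as.data.table(cs$sd, keep.rownames = "site"), f)
      written <- c(written, f)
    }
    ids <- solutions[[1]]$basis_ids
    summary <- list(
      basis = ids,
      n_frames = length(solutions),
      first_exciton_mean_eV = mean(vapply(solutions, function(s)
        s$exciton_energies[1], numeric(1))),
      first_exciton_sd_eV = stats::sd(vapply(solutions, function(s)
        s$exciton_energies[1], numeric(1))),
      mean_contributions_first_exciton = stats::setNames(as.list(
        rowMeans(vapply(solutions, function(s) s$contributions[, 1],
                        numeric(length(ids))))), ids)
    )
    f <- file.path(out_dir, "excitons.json")
    jsonlite::write_json(summary, f, auto_unbox = TRUE, digits = NA)
    written <- c(written, f)
    per <- data.table::rbindlist(lapply(solutions, function(s) {
      data.table::data.table(
        frame_index = s$frame_index,
        exciton = seq_along(s$exciton_energies),
        energy_eV = s$exciton_energies,
        top_contributor = s$basis_ids[apply(s$contributions, 2, which.max)],
        weight = apply(s$contributions, 2, max))
    }))
    f <- file.path(out_dir, "excitons_per_frame.csv")
    data.table::fwrite(per, f)
    written <- c(written, f)
    if (eigenvectors) {
      ev <- data.table::rbindlist(lapply(solutions, function(s) {
        data.table::data.table(
          frame_index = s$frame_index,
          site = rep(s$basis_ids, times = length(ids)),
          exciton = rep(seq_along(ids), each = length(ids)),
          coefficient = as.vector(s$eigenvectors))
      }))
      f <- file.path(out_dir, "eigenvectors.csv")
      data.table::fwrite(ev, f)
      written <- c(written, f)
    }
  }
  invisible(written)
}

#' Write a multi-frame XYZ file
#'
#' @param frames list of [environment_frame] objects carrying `elements`.
#' @param path output path.
#' @param digits coordinate precision (default 6 decimals).
#' @export
write_xyz <- function(frames, path, digits = 6) {
  con <- file(path, "w")
  on.exit(close(con))
  for (fr in frames) {
    elem <- fr$elements
    if (is.null(elem)) elem <- rep("X", nrow(fr$coords))
    writeLines(as.character(nrow(fr$coords)), con)
    writeLines(sprintf("frame %d", fr$frame_index), con)
    writeLines(sprintf(paste0("%s %.", digits, "f %.", digits, "f %.",
                              digits, "f"),
                       elem, fr$coords[, 1], fr$coords[, 2], fr$coords[, 3]),
               con)
  }
  invisible(path)
}
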