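#' Per-QC site-energy statistics
#'
#' Sample mean, standard deviation (n - 1), skewness, and a histogram
#' (Freedman-Diaconis binning by default, or a fixed bin width in meV).
#'
#' @param traces named list of site-energy traces.
#' @param bin_width_meV optional fixed histogram bin width in meV; default
#'   `NULL` uses Freedman-Diaconis.
#' @return data.frame (one row per QC) with a `histogram` list-column.
#' @export
site_energy_statistics <- function(traces, bin_width_meV = NULL) {
  stopifnot(length(traces) >= 1)
  rows <- lapply(names(traces), function(id) {
    x <- traces[[id]]$site_energy_eV
    if (length(x) < 2) stop("QC '", id, "': need >= 2 frames", call. = FALSE)
    breaks <- if (is.null(bin_width_meV)) "FD" else {
      w <- bin_width_meV / 1000
      seq(floor(min(x) / w) * w, max(x) + w, by = w)
    }
    h <- graphics::hist(x, breaks = breaks, plot = FALSE)
    d <- data.frame(qc = id, n = length(x), mean_eV = mean(x),
                    sd_eV = stats::sd(x), skewness = .skewness(x))
    d$histogram <- list(h)
    d
  })
  do.call(rbind, rows)
}

.skewness <- function(x) {
  m <- mean(x)
  s2 <- mean((x - m)^2)
  if (s2 == 0) return(0)
  mean((x - m)^3) / s2^1.5
}

#' Electrochromic shifts from a site table
#'
#' Shift of each pigment's excitation energy caused by the environment's
#' electrostatics: `(embedded - gas_phase) * 1000`, rounded to integer meV
#' (matching the tables' presentation).
#'
#' @param site_table a `site_table` from [read_site_table()].
#' @param gas_col name of the gas-phase energy column (default `"E_gas"`).
#' @param embedded_cols names of the embedded-energy columns; default every
#'   column starting with `"E_"` except the gas-phase and ensemble-mean ones.
#' @return data.frame: `site` plus one `shift_*` column (meV) per embedded
#'   column.
#' @export
electrochromic_shift <- function(site_table, gas_col = "E_gas",
                                 embedded_cols = NULL) {
  stopifnot(inherits(site_table, "site_table") || is.data.frame(site_table))
  if (!gas_col %in% names(site_table)) {
    stop("gas-phase column '", gas_col, "' not present", call. = FALSE)
  }
  if (is.null(embedded_cols)) {
    embedded_cols <- setdiff(grep("^E_", names(site_table), value = TRUE),
                             c(gas_col, "E_pmm_mean"))
  }
  miss <- setdiff(embedded_cols, names(site_table))
  if (length(miss)) {
    stop("embedded column(s) not present: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  out <- data.frame(site = site_table$site)
  for (cn in embedded_cols) {
    out[[sub("^E_", "shift_", cn)]] <-
      as.integer(round((site_table[[cn]] - site_table[[gas_col]]) * 1000))
  }
  out
}

#' Labelled min/max summary
#'
#' @param values numeric vector.
#' @param labels labels of the values (default names of `values`).
#' @return list with `min`/`max`, each `(label, value)`; ties broken by
#'   label order.
#' @export
range_summary <- function(values, labels = names(values)) {
  stopifnot(length(values) >= 1)
  if (is.null(labels)) labels <- as.character(seq_along(values))
  i_min <- which(values == min(values))[1]
  i_max <- which(values == max(values))[1]
  list(min = list(label = labels[i_min], value = values[[i_min]]),
       max = list(label = labels[i_max], value = values[[i_max]]))
}

# Deterministic 1-D two-component Gaussian-mixture EM, quantile-initialised.
.fit_gaussian_mixture2 <- function(x, max_iter = 500, tol = 1e-10) {
  n <- length(x)
  mu <- stats::quantile(x, c(0.25, 0.75), names = FALSE)
  sd0 <- stats::sd(x)
  if (sd0 == 0 || diff(mu) == 0) return(NULL)
  s <- c(sd0, sd0) / 2
  w <- c(0.5, 0.5)
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    d1 <- w[1] * stats::dnorm(x, mu[1], s[1])
    d2 <- w[2] * stats::dnorm(x, mu[2], s[2])
    tot <- d1 + d2
    if (any(tot == 0) || anyNA(tot)) return(NULL)
    g <- d1 / tot
    w <- c(mean(g), 1 - mean(g))
    if (min(w) < 1e-6) return(NULL)
    mu <- c(sum(g * x) / sum(g), sum((1 - g) * x) / sum(1 - g))
    s <- sqrt(c(sum(g * (x - mu[1])^2) / sum(g),
                sum((1 - g) * (x - mu[2])^2) / sum(1 - g)))
    if (any(s < 1e-12)) return(NULL)
    ll <- sum(log(tot))
    if (abs(ll - ll_old) < tol) break
    ll_old <- ll
  }
  ord <- order(mu)
  list(means = mu[ord], sds = s[ord], weights = w[ord], loglik = ll)
}

#' Distribution of the first exciton energy
#'
#' Histogram of per-frame first-exciton energies plus the paired per-frame
#' contribution vectors, and an optional two-component Gaussian-mixture
#' summary operationalizing a two-subpopulation (two conformational basin)
#' structure. If the mixture fit degenerates, a unimodal summary is returned
#' with a warning.
#'
#' @param solutions list of `exciton_solution`.
#' @param fit_mixture attempt the two-component fit (default `TRUE`).
#' @param bin_width_meV optional fixed histogram bin width (meV).
#' @return list with `energies`, `contributions` (frames x sites),
#'   `histogram`, and `mixture` (`NULL` if unimodal/failed).
#' @export
first_exciton_distribution <- function(solutions, fit_mixture = TRUE,
                                       bin_width_meV = NULL) {
  stopifnot(length(solutions) >= 1)
  e <- vapply(solutions, function(s) s$exciton_energies[1], numeric(1))
  contrib <- do.call(rbind, lapply(solutions, function(s) s$contributions[, 1]))
  colnames(contrib) <- solutions[[1]]$basis_ids
  breaks <- if (is.null(bin_width_meV)) {
    if (length(unique(e)) == 1) 1 else "FD"
  } else {
    w <- bin_width_meV / 1000
    seq(floor(min(e) / w) * w, max(e) + w, by = w)
  }
  h <- graphics::hist(e, breaks = breaks, plot = FALSE)
  mix <- NULL
  if (fit_mixture && length(e) >= 10 && stats::sd(e) > 0) {
    mix <- .fit_gaussian_mixture2(e)
    if (is.null(mix)) {
      warning("two-component mixture fit failed; unimodal summary only")
    }
  }
  list(energies = e, contributions = contrib, histogram = h, mixture = mix)
}

#' Group contributions versus first-exciton energy
#'
#' For every frame, sums the squared first-exciton coefficients within named
#' pigment groups and pairs them with that frame's first-exciton energy (the
#' scatter underlying contribution-versus-energy plots).
#'
#' @param solutions list of `exciton_solution`.
#' @param group_map named character vector or list mapping every basis id to
#'   a group name.
#' @return data.frame: `frame_index`, `energy_eV`, one column per group.
#' @export
contribution_by_energy <- function(solutions, group_map) {
  stopifnot(length(solutions) >= 1)
  group_map <- unlist(group_map)
  ids <- solutions[[1]]$basis_ids
  unmapped <- setdiff(ids, names(group_map))
  if (length(unmapped)) {
    stop("basis id(s) not in group_map: ", paste(unmapped, collapse = ", "),
         call. = FALSE)
  }
  groups <- unique(unname(group_map[ids]))
  rows <- lapply(solutions, function(s) {
    w <- s$contributions[, 1]
    sums <- vapply(groups, function(g) {
      sum(w[ids %in% names(group_map)[group_map == g]])
    }, numeric(1))
    c(frame_index = s$frame_index, energy_eV = s$exciton_energies[1], sums)
  })
  out <- as.data.frame(do.call(rbind, rows))
  names(out) <- c("frame_index", "energy_eV", groups)
  out
}

#' Ensemble absorption line shape
#'
#' Inhomogeneously broadened spectrum on a wavelength axis: each exciton of
#' each frame contributes a Gaussian kernel centered at its transition
#' wavelength, weighted by its dipole strength `|mu_exc|^2` (exciton
#' transition dipole = coefficient-weighted sum of the sites' perturbed
#' transition dipoles). The spectrum is normalized to unit area. Reported
#' metrics: peak splitting (distance between the global peak and the most
#' prominent secondary peak or shoulder, found by second-derivative sign
#' change) and FWHM bandwidth.
#'
#' @param solutions list of `exciton_solution` carrying `transition_dipoles`.
#' @param width Gaussian kernel standard deviation in nm (> 0).
#' @param grid wavelength grid (nm); default 600-750 nm at 0.05 nm.
#' @return list of class `absorption_spectrum`: `wavelength_nm`, `intensity`,
#'   `splitting_nm`, `bandwidth_nm`, `peak_nm`, `total_weight`.
#' @export
absorption_lineshape <- function(solutions, width,
                                 grid = seq(600, 750, by = 0.05)) {
  stopifnot(length(solutions) >= 1, width > 0)
  if (length(grid) < 3) stop("empty or degenerate wavelength grid",
                             call. = FALSE)
  centers <- numeric(0)
  weights <- numeric(0)
  for (s in solutions) {
    e <- s$exciton_energies
    if (is.null(s$transition_dipoles)) {
      w <- rep(1, length(e))
    } else {
      mu_exc <- t(s$eigenvectors) %*% s$transition_dipoles  # n_exc x 3
      w <- rowSums(mu_exc^2)
    }
    centers <- c(centers, convert_energy(e, "eV", "nm"))
    weights <- c(weights, w)
  }
  intensity <- numeric(length(grid))
  for (k in seq_along(centers)) {
    intensity <- intensity +
      weights[k] * stats::dnorm(grid, centers[k], width)
  }
  total_weight <- sum(weights)
  dl <- diff(grid)
  area <- sum((intensity[-1] + intensity[-length(grid)]) / 2 * dl)
  if (area > 0) intensity <- intensity / area
  peaks <- .find_peaks(grid, intensity)
  peak_nm <- grid[which.max(intensity)]
  splitting <- NA_real_
  if (nrow(peaks) >= 2) {
    others <- peaks[peaks$wavelength != peak_nm, , drop = FALSE]
    second <- others$wavelength[which.max(others$prominence)]
    splitting <- abs(peak_nm - second)
  }
  structure(list(wavelength_nm = grid, intensity = intensity,
                 peak_nm = peak_nm, splitting_nm = splitting,
                 bandwidth_nm = .fwhm(grid, intensity),
                 total_weight = total_weight),
            class = "absorption_spectrum")
}

# Local maxima of the curve, plus shoulders. A single smooth peak has exactly
# two extrema of dy/dx (its inflection points); a shoulder that never becomes
# a maximum adds an extra pair (second-derivative sign changes), whose
# location marks the shoulder.
.find_peaks <- function(x, y) {
  dy <- diff(y)
  n <- length(dy)
  up <- which(dy[-n] > 0 & dy[-1] <= 0) + 1L  # true local maxima of y
  res <- data.frame(wavelength = x[up], height = y[up], prominence = y[up])
  ext <- which((dy[-c(n - 1, n)] < dy[-c(1, n)] & dy[-c(1, 2)] < dy[-c(1, n)]) |
               (dy[-c(n - 1, n)] > dy[-c(1, n)] & dy[-c(1, 2)] > dy[-c(1, n)])) + 1L
  if (length(ext) > 2) {
    # drop the two canonical inflections of the dominant peak
    canon <- c(ext[which.max(dy[ext])], ext[which.min(dy[ext])])
    cand <- setdiff(ext, canon)
    cand <- cand[!cand %in% unlist(lapply(up, function(i) (i - 3L):(i + 3L)))]
    if (length(cand)) {
      sh <- data.frame(wavelength = x[cand], height = y[cand],
                       prominence = y[cand] * 0.5)
      res <- rbind(res, sh)
    }
  }
  res[order(-res$prominence), , drop = FALSE]
}

.fwhm <- function(x, y) {
  half <- max(y) / 2
  above <- which(y >= half)
  if (length(above) < 2) return(0)
  # linear interpolation at the outermost crossings
  lo <- above[1]
  hi <- above[length(above)]
  x_lo <- if (lo == 1) x[1] else {
    stats::approx(y[(lo - 1):lo], x[(lo - 1):lo], xout = half)$y
  }
  x_hi <- if (hi == length(x)) x[length(x)] else {
    stats::approx(y[hi:(hi + 1)], x[hi:(hi + 1)], xout = half)$y
  }
  x_hi - x_lo
}
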