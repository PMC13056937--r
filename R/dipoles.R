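#' Per-mode dipole variation (mass-weighted effective charge)
#'
#' For each mode l, the dipole-variation vector is the charge-weighted
#' sum of the mode's Cartesian eigenvector components,
#' d_l = sum_{i in subset} q_i e_{l,i}, and its magnitude rho_l = ||d_l||
#' is the mass-weighted effective charge (dipole derivative) that couples
#' the mode to an electric field. Component restriction applies to the
#' charge sum only: the eigenvectors are always those of the whole
#' system, so component vectors are exactly additive over a partition of
#' the atoms.
#'
#' @param modeset a `mode_set`.
#' @param subset component selector: `"whole"` (default), `"protein"`,
#'   `"water"`, `"ligand"`, `"protein+ligand"`, or an integer vector of
#'   atom indices.
#' @return object of class `dipole_table`: `component` (label),
#'   `vectors` (3 x M matrix, C kg^(-1/2)), `magnitudes` (rho_l per
#'   mode), `frequencies` (Hz, copied from the mode set).
#' @export
#' @examples
#' sys <- build_harmonic_system("ring", 3, seed = 1)
#' ms <- select_vibrational_modes(solve_modes(sys))
#' mode_dipole(ms)$magnitudes
mode_dipole <- function(modeset, subset = "whole") {
  stopifnot(inherits(modeset, "mode_set"))
  idx <- resolve_subset(modeset$atoms, subset)
  q <- numeric(modeset$atoms$n_atoms)
  q[idx] <- modeset$atoms$charges[idx]
  qrow <- rep(q, each = 3L)                       # per-DOF charge mask
  ev <- modeset$eigenvectors * qrow
  n <- modeset$atoms$n_atoms
  vx <- colSums(ev[seq(1, 3 * n, by = 3), , drop = FALSE])
  vy <- colSums(ev[seq(2, 3 * n, by = 3), , drop = FALSE])
  vz <- colSums(ev[seq(3, 3 * n, by = 3), , drop = FALSE])
  vec <- rbind(vx, vy, vz)
  rownames(vec) <- c("x", "y", "z")
  structure(list(
    component = if (is.numeric(subset)) "custom" else subset,
    vectors = vec,
    magnitudes = sqrt(colSums(vec^2)),
    frequencies = modeset$frequencies
  ), class = "dipole_table")
}

#' @export
print.dipole_table <- function(x, ...) {
  cat("<dipole_table> component '", x$component, "', ",
      length(x$magnitudes), " modes, max rho = ",
      format(max(x$magnitudes), digits = 4), " C kg^-1/2\n", sep = "")
  invisible(x)
}

#' Angle between two components' dipole-variation vectors, per mode
#'
#' theta_l = arccos(a_l . b_l / (||a_l|| ||b_l||)) in degrees, with the
#' cosine clamped to [-1, 1] against round-off. Modes where either vector
#' has zero magnitude have an undefined angle: they are returned as NA
#' and excluded from any averaging downstream.
#'
#' @param dipoles_a,dipoles_b `dipole_table`s with identical mode count
#'   (from the same mode set, different subsets).
#' @return object of class `angle_table`: `angles_deg` per mode (NA
#'   where undefined), `n_undefined`, `frequencies`.
#' @export
component_angles <- function(dipoles_a, dipoles_b) {
  stopifnot(inherits(dipoles_a, "dipole_table"),
            inherits(dipoles_b, "dipole_table"))
  if (length(dipoles_a$magnitudes) != length(dipoles_b$magnitudes))
    stop("mode-count mismatch between dipole tables")
  dot <- colSums(dipoles_a$vectors * dipoles_b$vectors)
  denom <- dipoles_a$magnitudes * dipoles_b$magnitudes
  ang <- rep(NA_real_, length(dot))
  ok <- denom > 0
  ang[ok] <- acos(pmin(1, pmax(-1, dot[ok] / denom[ok]))) * 180 / pi
  structure(list(angles_deg = ang,
                 n_undefined = sum(!ok),
                 frequencies = dipoles_a$frequencies),
            class = "angle_table")
}

#' @export
print.angle_table <- function(x, ...) {
  cat("<angle_table> ", length(x$angles_deg), " modes",
      if (!is.null(x$mean_deg)) " (ensemble profile)", ", ",
      x$n_undefined, " undefined\n", sep = "")
  invisible(x)
}

#' Ensemble mean and sd of inter-component dipole angles, by mode rank
#'
#' Computes the angle between two components' dipole vectors for every
#' replica, matches modes across replicas by ascending-frequency rank,
#' and returns per-rank arithmetic mean and standard deviation. Undefined
#' angles (zero-magnitude component vectors) are excluded from the
#' statistics and counted.
#'
#' @param ensemble a `mode_ensemble` whose replicas share topology.
#' @param subset_a,subset_b component selectors (see [mode_dipole()]).
#' @param n_modes number of leading mode ranks to report.
#' @return `angle_table` with `mean_deg`, `sd_deg`, `n_defined` per
#'   rank, plus per-replica `angles_deg` matrix (rank x replica).
#' @export
ensemble_angle_profile <- function(ensemble, subset_a = "protein",
                                   subset_b = "water", n_modes = NULL) {
  stopifnot(inherits(ensemble, "mode_ensemble"))
  avail <- ensemble$n_modes
  if (is.null(n_modes)) n_modes <- avail
  if (n_modes > avail)
    stop("n_modes (", n_modes, ") exceeds available modes (", avail, ")")
  per <- vapply(ensemble$replicas, function(ms) {
    a <- mode_dipole(ms, subset_a)
    b <- mode_dipole(ms, subset_b)
    component_angles(a, b)$angles_deg[seq_len(n_modes)]
  }, numeric(n_modes))
  per <- matrix(per, nrow = n_modes)
  n_def <- rowSums(!is.na(per))
  mean_deg <- rowMeans(per, na.rm = TRUE)
  mean_deg[n_def == 0] <- NA_real_
  sd_deg <- apply(per, 1, function(v) {
    v <- v[!is.na(v)]
    if (length(v) < 2L) 0 else stats::sd(v)
  })
  structure(list(angles_deg = per,
                 mean_deg = mean_deg, sd_deg = sd_deg,
                 n_defined = n_def,
                 n_undefined = sum(is.na(per)),
                 mode_rank = seq_len(n_modes)),
            class = "angle_table")
}

#' Per-residue RMS displacement profile of one eigenvector
#'
#' For a chosen mode, returns for each residue the root mean square over
#' its atoms of the Cartesian eigenvector norm ||e_{l,i}|| (kg^(-1/2)).
#' Localized modes show support on few residues; delocalized modes are
#' flat.
#'
#' @param modeset a `mode_set` with populated residue indices.
#' @param mode_index mode number (1-based, in the mode set's ordering).
#' @return named numeric vector, one RMS value per residue index.
#' @export
residue_displacement_profile <- function(modeset, mode_index) {
  stopifnot(inherits(modeset, "mode_set"))
  if (mode_index < 1L || mode_index > modeset$n_modes)
    stop("mode_index out of range (1..", modeset$n_modes, ")")
  ev <- matrix(modeset$eigenvectors[, mode_index], nrow = 3L)
  norm2 <- colSums(ev^2)                       # ||e_{l,i}||^2 per atom
  res <- modeset$atoms$residue_index
  ms <- tapply(norm2, res, mean)
  out <- as.numeric(sqrt(ms))
  names(out) <- names(ms)
  out
}
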