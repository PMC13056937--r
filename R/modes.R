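#' Convert vibrational wavenumbers to linear frequency
#'
#' Multiplies by the speed of light in cm/s, 2.99792458e10, so 1 cm^-1
#' maps to 29.9792458 GHz.
#'
#' @param wavenumber_cm1 numeric, wavenumbers in cm^-1; must be >= 0.
#' @return frequencies in Hz.
#' @export
#' @examples
#' wavenumber_to_frequency(1)       # 2.99792458e10
#' wavenumber_to_frequency(33.3564) # ~1e12
wavenumber_to_frequency <- function(wavenumber_cm1) {
  if (any(!is.finite(wavenumber_cm1)) || any(wavenumber_cm1 < 0))
    stop("wavenumbers must be finite and non-negative")
  .const$cm1_to_hz * wavenumber_cm1
}

#' Normal-mode set for one replica
#'
#' Binds mode frequencies and Cartesian mass-weighted eigenvectors to the
#' atom metadata they refer to. Eigenvectors are stored as a 3N x M matrix
#' (columns are modes; rows are x,y,z of atom 1, then atom 2, ...), in
#' kg^(-1/2) as output by mass-weighted Hessian diagonalization: if u is
#' orthonormal in mass-weighted coordinates, the Cartesian eigenvector is
#' e_i = u_i / sqrt(m_i) and satisfies sum_i m_i e_{l,i} . e_{l',i} =
#' delta_{ll'}.
#'
#' Frequencies may be negative on input: a negative value is the
#' conventional marker for an imaginary frequency (negative Hessian
#' eigenvalue, i.e. an incompletely minimized structure). They are kept
#' as-is here and policed by [select_vibrational_modes()].
#'
#' @param atoms an `atom_set`.
#' @param frequencies_hz numeric, one linear frequency per mode, sorted
#'   ascending.
#' @param eigenvectors 3N x M numeric matrix in kg^(-1/2).
#' @param check logical; verify mass-weighted orthonormality (tolerance
#'   1e-8) and dimensions. Disable only for trusted internal callers.
#' @return object of class `mode_set` with fields `atoms`,
#'   `frequencies` (Hz), `eigenvectors`, `n_modes`,
#'   `degrees_of_freedom` (3N - 6).
#' @export
mode_set <- function(atoms, frequencies_hz, eigenvectors, check = TRUE) {
  stopifnot(inherits(atoms, "atom_set"))
  eigenvectors <- as.matrix(eigenvectors)
  m <- length(frequencies_hz)
  if (ncol(eigenvectors) != m)
    stop("eigenvector matrix must have one column per mode")
  if (nrow(eigenvectors) != 3L * atoms$n_atoms)
    stop("eigenvector rows (", nrow(eigenvectors), ") != 3 * n_atoms (",
         3L * atoms$n_atoms, ")")
  if (is.unsorted(frequencies_hz))
    stop("mode frequencies must be sorted ascending")
  if (check) check_orthonormality(atoms, eigenvectors)
  structure(list(
    atoms = atoms,
    frequencies = as.numeric(frequencies_hz),
    eigenvectors = eigenvectors,
    n_modes = m,
    degrees_of_freedom = 3L * atoms$n_atoms - 6L
  ), class = "mode_set")
}

# Mass-weighted orthonormality E' diag(m) E = I within tol; errors with the
# worst offending mode pair.
check_orthonormality <- function(atoms, eigenvectors, tol = 1e-8) {
  w <- rep(atoms$masses, each = 3L)
  g <- crossprod(eigenvectors * sqrt(w))
  dev <- abs(g - diag(nrow(g)))
  if (max(dev) > tol) {
    ij <- arrayInd(which.max(dev), dim(dev))
    stop(sprintf(
      "eigenvectors not mass-weighted orthonormal: modes (%d, %d) deviate by %.3g (tol %.1g)",
      ij[1], ij[2], max(dev), tol))
  }
  invisible(TRUE)
}

#' @export
print.mode_set <- function(x, ...) {
  cat("<mode_set> ", x$n_modes, " modes over ", x$atoms$n_atoms,
      " atoms; frequencies ",
      format(min(x$frequencies) / 1e9, digits = 4), " to ",
      format(max(x$frequencies) / 1e9, digits = 4), " GHz\n", sep = "")
  invisible(x)
}

#' Ensemble of mode sets (replicas)
#'
#' @param replicas list of `mode_set` objects sharing atom topology
#'   (same atom and mode counts).
#' @return object of class `mode_ensemble`.
#' @export
mode_ensemble <- function(replicas) {
  if (!length(replicas)) stop("empty replica list")
  if (!all(vapply(replicas, inherits, logical(1), "mode_set")))
    stop("all replicas must be mode_set objects")
  na <- vapply(replicas, function(r) r$atoms$n_atoms, integer(1))
  nm <- vapply(replicas, function(r) r$n_modes, integer(1))
  if (length(unique(na)) != 1L || length(unique(nm)) != 1L)
    stop("replicas differ in atom or mode count")
  structure(list(replicas = replicas,
                 n_replicas = length(replicas),
                 n_atoms = na[1], n_modes = nm[1],
                 shared_topology = TRUE),
            class = "mode_ensemble")
}

#' @export
print.mode_ensemble <- function(x, ...) {
  cat("<mode_ensemble> ", x$n_replicas, " replicas x ", x$n_modes,
      " modes, ", x$n_atoms, " atoms\n", sep = "")
  invisible(x)
}

#' Drop rigid-body modes and truncate to the leading vibrational modes
#'
#' Removes the six rigid-body modes of a nonlinear 3-D system -- the six
#' smallest-|frequency| modes, which must lie below `zero_tolerance_hz` --
#' then truncates to at most `max_modes` vibrational modes, still sorted
#' ascending. Any mode flagged imaginary (negative frequency) with
#' magnitude above the tolerance signals an incompletely minimized
#' structure and raises an error.
#'
#' @param modeset a `mode_set`.
#' @param max_modes maximum vibrational modes to keep (default all).
#' @param zero_tolerance_hz frequencies with |nu| below this are treated
#'   as rigid-body; default 1 GHz.
#' @return a `mode_set` containing only vibrational modes.
#' @export
select_vibrational_modes <- function(modeset, max_modes = Inf,
                                     zero_tolerance_hz = 1e9) {
  stopifnot(inherits(modeset, "mode_set"))
  f <- modeset$frequencies
  if (any(f < -zero_tolerance_hz))
    stop("imaginary frequency beyond tolerance (",
         format(min(f)), " Hz): structure not at a minimum")
  near_zero <- which(abs(f) < zero_tolerance_hz)
  if (length(near_zero) < 6L)
    warning("only ", length(near_zero),
            " modes below zero tolerance; expected 6 rigid-body modes ",
            "for a nonlinear 3-D system")
  # drop the smallest-|nu| modes, but never a genuine vibration above
  # tolerance (linear molecules have only 5 rigid modes)
  drop <- order(abs(f))[seq_len(min(6L, length(near_zero)))]
  keep <- setdiff(seq_len(modeset$n_modes), drop)
  keep <- keep[order(f[keep])]
  if (is.finite(max_modes)) keep <- keep[seq_len(min(max_modes, length(keep)))]
  out <- modeset
  out$frequencies <- f[keep]
  out$eigenvectors <- modeset$eigenvectors[, keep, drop = FALSE]
  out$n_modes <- length(keep)
  out
}

#' Vibrational density of states histogram
#'
#' Bins mode frequencies into half-open intervals [edge, edge + width) of
#' fixed width covering [min nu, max nu], so no mode is double-counted and
#' counts conserve mode number. Also attaches the per-degree-of-freedom
#' normalization g_n(nu_j) = n_j / (N_f * width), which collapses systems
#' of different size onto a common curve in the low-frequency regime where
#' the raw density scales like N_f * nu.
#'
#' @param modeset a `mode_set` (typically after
#'   [select_vibrational_modes()]).
#' @param bin_width_hz bin width in Hz, > 0. The customary bin size for
#'   sub-THz work is 10 GHz.
#' @return object of class `vdos_histogram` with `bin_edges` (length
#'   nbins+1, Hz), `counts`, `bin_width`, `normalized` (g_n, 1/Hz per
#'   DOF), `degrees_of_freedom`.
#' @export
mode_density <- function(modeset, bin_width_hz = 1e10) {
  stopifnot(inherits(modeset, "mode_set"))
  if (!is.numeric(bin_width_hz) || bin_width_hz <= 0)
    stop("bin_width_hz must be > 0")
  f <- modeset$frequencies
  if (!length(f)) stop("empty mode set")
  lo <- min(f)
  nbins <- max(1L, ceiling((max(f) - lo) / bin_width_hz + 1e-12))
  edges <- lo + bin_width_hz * (0:nbins)
  idx <- pmin(floor((f - lo) / bin_width_hz) + 1L, nbins)
  counts <- tabulate(idx, nbins)
  structure(list(
    bin_edges = edges,
    counts = counts,
    bin_width = bin_width_hz,
    normalized = counts / (modeset$degrees_of_freedom * bin_width_hz),
    degrees_of_freedom = modeset$degrees_of_freedom
  ), class = "vdos_histogram")
}

#' @export
print.vdos_histogram <- function(x, ...) {
  cat("<vdos_histogram> ", length(x$counts), " bins of ",
      format(x$bin_width / 1e9), " GHz, ", sum(x$counts), " modes\n", sep = "")
  invisible(x)
}
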