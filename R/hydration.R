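#' Assign waters to distance-band shells around a protein
#'
#' A water's shell is the band containing its minimum distance to any
#' protein atom. Distances beyond the outermost edge map to -1
#' (outside all shells). Coordinates are in nm; shell boundaries follow
#' the hydration-analysis convention of Angstrom.
#'
#' @param protein_coords_nm n_protein x 3 matrix, nm.
#' @param water_coords_nm n_water x 3 matrix of water reference points
#'   (conventionally the oxygen atom), nm.
#' @param boundaries_angstrom strictly increasing band edges starting at
#'   0; default c(0, 3, 5, 7, 9) defines four shells 0..3.
#' @return integer vector, shell index per water: 0-based band index or
#'   -1.
#' @export
#' @examples
#' p <- matrix(0, 1, 3)
#' w <- matrix(c(0.2, 0, 0, 1.2, 0, 0), 2, 3, byrow = TRUE)
#' assign_shells(p, w)  # 0 (2 A) and -1 (12 A)
assign_shells <- function(protein_coords_nm, water_coords_nm,
                          boundaries_angstrom = c(0, 3, 5, 7, 9)) {
  protein_coords_nm <- as.matrix(protein_coords_nm)
  water_coords_nm <- as.matrix(water_coords_nm)
  if (!nrow(protein_coords_nm)) stop("empty protein coordinate set")
  if (!nrow(water_coords_nm)) stop("empty water coordinate set")
  if (is.unsorted(boundaries_angstrom, strictly = TRUE) ||
      boundaries_angstrom[1] != 0)
    stop("boundaries must be strictly increasing and start at 0")
  dmin_a <- apply(water_coords_nm, 1, function(w) {
    sqrt(min(colSums((t(protein_coords_nm) - w)^2))) * 10  # nm -> Angstrom
  })
  # half-open bands [lo, hi); beyond last edge -> -1
  idx <- findInterval(dmin_a, boundaries_angstrom,
                      left.open = FALSE, rightmost.closed = FALSE)
  out <- idx - 1L
  out[idx >= length(boundaries_angstrom)] <- -1L
  as.integer(out)
}

#' Shell persistence fraction per frame
#'
#' A water in shell s at frame f is persistent if it remains in s over
#' all frames spanning at least `threshold_ps` starting at f: with
#' ceiling(threshold / Delta-t) = 1 this reduces to shell(f) ==
#' shell(f+1). For each shell and each frame f in 0..(n_frames - 2) the
#' result is 100 * persistent / occupants; frames where a shell is empty
#' give NA for that shell.
#'
#' @param traj a `shell_trajectory`.
#' @param threshold_ps persistence time threshold, ps; must be >= the
#'   trajectory frame spacing. Default 20.
#' @return object of class `persistence_result`: `per_frame_percent`
#'   is an (n_frames - n_steps) x n_shells matrix (rows are start
#'   frames), plus `threshold_ps`, `boundaries`, `shell_mean_percent`.
#'   The outside state (-1) is not a shell and is not reported.
#' @export
persistence_fraction <- function(traj, threshold_ps = 20) {
  stopifnot(inherits(traj, "shell_trajectory"))
  if (threshold_ps < traj$frame_spacing)
    stop("threshold (", threshold_ps, " ps) below frame spacing (",
         traj$frame_spacing, " ps): persistence unresolvable")
  n_steps <- ceiling(threshold_ps / traj$frame_spacing - 1e-9)
  if (traj$n_frames <= n_steps)
    stop("trajectory too short for the requested threshold")
  n_shells <- length(traj$boundaries) - 1L
  sh <- traj$shell_index
  n_start <- traj$n_frames - n_steps
  # stays[f, w]: water w keeps its frame-f shell for the next n_steps frames
  stays <- matrix(TRUE, n_start, traj$n_waters)
  for (k in seq_len(n_steps)) {
    stays <- stays & (sh[seq_len(n_start) + k, , drop = FALSE] ==
                      sh[seq_len(n_start), , drop = FALSE])
  }
  pct <- matrix(NA_real_, n_start, n_shells)
  for (s in seq_len(n_shells) - 1L) {
    inshell <- sh[seq_len(n_start), , drop = FALSE] == s
    occ <- rowSums(inshell)
    per <- rowSums(inshell & stays)
    pct[, s + 1L] <- ifelse(occ > 0, 100 * per / occ, NA_real_)
  }
  colnames(pct) <- sprintf("shell_%d", seq_len(n_shells) - 1L)
  structure(list(per_frame_percent = pct,
                 threshold_ps = threshold_ps,
                 boundaries = traj$boundaries,
                 shell_mean_percent = colMeans(pct, na.rm = TRUE)),
            class = "persistence_result")
}

#' @export
print.persistence_result <- function(x, ...) {
  cat("<persistence_result> threshold ", x$threshold_ps, " ps; mean % by shell: ",
      paste(format(x$shell_mean_percent, digits = 3), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Count bound waters within a cutoff of the protein
#'
#' Number of waters whose reference point lies within `cutoff_angstrom`
#' of any protein atom. With the conventional 3 Angstrom cutoff this is
#' the bound-water count n_b per protein used by the dilute-mixing
#' correction.
#'
#' @param atoms an `atom_set` with coordinates, containing protein and
#'   water atoms (the water reference points are its water-labelled
#'   atoms, conventionally one oxygen entry per molecule).
#' @param cutoff_angstrom distance cutoff, Angstrom (> 0); default 3.
#' @param heavy_only if TRUE, measure distances to protein atoms with
#'   mass > 2 amu only (exclude hydrogens).
#' @return integer count of bound waters.
#' @export
count_bound_waters <- function(atoms, cutoff_angstrom = 3,
                               heavy_only = FALSE) {
  stopifnot(inherits(atoms, "atom_set"))
  if (cutoff_angstrom <= 0) stop("cutoff must be > 0")
  if (is.null(atoms$coordinates)) stop("atom set has no coordinates")
  prot <- atoms$component == "protein"
  if (heavy_only) prot <- prot & (atoms$masses > 2 * .const$amu)
  if (!any(prot)) stop("no protein atoms")
  wat <- which(atoms$component == "water")
  if (!length(wat)) return(0L)
  sh <- assign_shells(atoms$coordinates[prot, , drop = FALSE],
                      atoms$coordinates[wat, , drop = FALSE],
                      boundaries_angstrom = c(0, cutoff_angstrom))
  sum(sh == 0L)
}
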