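#' Atom metadata container
#'
#' Bundles the per-atom quantities every downstream computation needs:
#' masses, partial charges, a component label (protein / water / ligand),
#' a residue index, and optionally Cartesian coordinates. Inputs follow
#' force-field conventions (masses in amu, charges in elementary-charge
#' units); everything is converted to SI on construction and stored that
#' way.
#'
#' @param masses_amu numeric, atomic masses in amu; all strictly positive.
#' @param charges_e numeric, partial charges in units of the elementary
#'   charge; must be finite.
#' @param component character or factor, one of `"protein"`, `"water"`,
#'   `"ligand"` per atom. Recycled if length 1.
#' @param residue_index integer residue index per atom. Recycled if
#'   length 1; defaults to one residue per atom.
#' @param coordinates_nm optional n x 3 matrix of coordinates in nm. Only
#'   required by hydration / bound-water operations.
#' @return An object of class `atom_set` with fields `n_atoms`,
#'   `masses` (kg), `charges` (C), `component` (factor),
#'   `residue_index`, `coordinates` (nm, or NULL).
#' @export
#' @examples
#' a <- atom_set(masses_amu = c(12, 16), charges_e = c(0.4, -0.4),
#'               component = "protein")
#' a$masses  # kg
atom_set <- function(masses_amu, charges_e,
                     component = "protein",
                     residue_index = NULL,
                     coordinates_nm = NULL) {
  n <- length(masses_amu)
  if (n < 1L) stop("atom_set needs at least one atom")
  if (length(charges_e) == 1L) charges_e <- rep_len(charges_e, n)
  if (length(charges_e) != n) stop("charges_e must match masses_amu length")
  if (any(!is.finite(masses_amu)) || any(masses_amu <= 0))
    stop("masses must be strictly positive and finite")
  if (any(!is.finite(charges_e))) stop("charges must be finite")
  component <- rep_len(as.character(component), n)
  bad <- setdiff(unique(component), c("protein", "water", "ligand"))
  if (length(bad))
    stop("unknown component label(s): ", paste(bad, collapse = ", "))
  if (is.null(residue_index)) residue_index <- seq_len(n)
  residue_index <- rep_len(as.integer(residue_index), n)
  if (!is.null(coordinates_nm)) {
    coordinates_nm <- as.matrix(coordinates_nm)
    if (nrow(coordinates_nm) != n || ncol(coordinates_nm) != 3L)
      stop("coordinates_nm must be an n x 3 matrix")
    storage.mode(coordinates_nm) <- "double"
  }
  structure(list(
    n_atoms = n,
    masses = masses_amu * .const$amu,
    charges = charges_e * .const$e_charge,
    component = factor(component, levels = c("protein", "water", "ligand")),
    residue_index = residue_index,
    coordinates = coordinates_nm
  ), class = "atom_set")
}

#' @export
print.atom_set <- function(x, ...) {
  cat("<atom_set> ", x$n_atoms, " atoms (",
      paste(sprintf("%s: %d", levels(x$component), tabulate(x$component, 3L)),
            collapse = ", "),
      "); coordinates ", if (is.null(x$coordinates)) "absent" else "present",
      "\n", sep = "")
  invisible(x)
}

#' Resolve a component selector to atom indices
#'
#' Accepts `"whole"`, a component label (`"protein"`, `"water"`,
#' `"ligand"`), the combination `"protein+ligand"`, or an integer index
#' vector.
#'
#' @param atoms an `atom_set`.
#' @param subset selector as above.
#' @return integer vector of atom indices (1-based).
#' @keywords internal
resolve_subset <- function(atoms, subset) {
  if (is.numeric(subset)) {
    idx <- as.integer(subset)
    if (length(idx) == 0L) stop("empty atom subset")
    if (any(idx < 1L | idx > atoms$n_atoms))
      stop("subset indices outside atom set (1..", atoms$n_atoms, ")")
    return(idx)
  }
  subset <- match.arg(subset,
                      c("whole", "protein", "water", "ligand", "protein+ligand"))
  idx <- switch(subset,
    whole = seq_len(atoms$n_atoms),
    "protein+ligand" = which(atoms$component %in% c("protein", "ligand")),
    which(atoms$component == subset))
  if (length(idx) == 0L) stop("subset '", subset, "' selects no atoms")
  idx
}
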