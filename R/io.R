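#' Read a frequency file (XVG dialect)
#'
#' Lines starting with `#` or `@` are comments/metadata; data lines are
#' "index value" pairs. Values are wavenumbers in cm^-1 by default (the
#' GROMACS nmeig convention) and converted to Hz; pass `unit = "hz"` if
#' the file already holds Hz.
#'
#' @param path file path.
#' @param unit `"cm-1"` (default) or `"hz"`.
#' @return numeric vector of frequencies in Hz, in file order.
#' @export
read_frequency_xvg <- function(path, unit = c("cm-1", "hz")) {
  unit <- match.arg(unit)
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*[#@]", lines) & nzchar(trimws(lines))]
  if (!length(lines)) stop("no data lines in ", path)
  vals <- vapply(strsplit(trimws(lines), "\\s+"), function(tok) {
    if (length(tok) < 2L) stop("malformed frequency line: expected 'index value'")
    as.numeric(tok[2])
  }, numeric(1))
  if (any(!is.finite(vals))) stop("non-numeric frequency value in ", path)
  if (unit == "cm-1") {
    # negative wavenumbers mark imaginary frequencies; keep the sign
    sign(vals) * wavenumber_to_frequency(abs(vals))
  } else vals
}

#' Write a frequency XVG file
#'
#' @param frequencies_hz frequencies in Hz.
#' @param path output path.
#' @param unit write as `"cm-1"` (default) or `"hz"`.
#' @export
write_frequency_xvg <- function(frequencies_hz, path, unit = c("cm-1", "hz")) {
  unit <- match.arg(unit)
  vals <- if (unit == "cm-1") frequencies_hz / .const$cm1_to_hz else frequencies_hz
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# mode frequencies",
               sprintf("@ yaxis label \"frequency (%s)\"", unit)), con)
  writeLines(sprintf("%d %.12g", seq_along(vals), vals), con)
  invisible(path)
}

#' Read an eigenvector table
#'
#' Tab-separated, one row per (mode, atom): columns mode_index,
#' atom_index, ex, ey, ez in kg^(-1/2). A header line is expected.
#'
#' @param path file path.
#' @param n_atoms expected atom count (validated).
#' @return 3N x M matrix (columns = modes).
#' @export
read_eigenvectors_tsv <- function(path, n_atoms) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t")
  need <- c("mode_index", "atom_index", "ex", "ey", "ez")
  if (!all(need %in% names(tab)))
    stop("eigenvector table must have columns: ", paste(need, collapse = ", "))
  modes <- sort(unique(tab$mode_index))
  if (nrow(tab) != length(modes) * n_atoms)
    stop("eigenvector table has ", nrow(tab), " rows; expected ",
         length(modes), " modes x ", n_atoms, " atoms")
  ev <- matrix(NA_real_, 3L * n_atoms, length(modes))
  for (k in seq_along(modes)) {
    sub <- tab[tab$mode_index == modes[k], ]
    if (nrow(sub) != n_atoms || !setequal(sub$atom_index, seq_len(n_atoms)))
      stop("mode ", modes[k], ": atom indices do not cover 1..", n_atoms)
    sub <- sub[order(sub$atom_index), ]
    ev[, k] <- as.numeric(t(as.matrix(sub[, c("ex", "ey", "ez")])))
  }
  if (any(!is.finite(ev))) stop("non-finite eigenvector entries in ", path)
  ev
}

#' Write an eigenvector table
#'
#' @param eigenvectors 3N x M matrix.
#' @param path output path.
#' @export
write_eigenvectors_tsv <- function(eigenvectors, path) {
  n_atoms <- nrow(eigenvectors) / 3L
  m <- ncol(eigenvectors)
  df <- data.frame(
    mode_index = rep(seq_len(m), each = n_atoms),
    atom_index = rep(seq_len(n_atoms), times = m),
    ex = as.numeric(eigenvectors[seq(1, 3 * n_atoms, 3), ]),
    ey = as.numeric(eigenvectors[seq(2, 3 * n_atoms, 3), ]),
    ez = as.numeric(eigenvectors[seq(3, 3 * n_atoms, 3), ]))
  utils::write.table(format(df, digits = 17, scientific = TRUE, trim = TRUE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read atom metadata (companion TSV, optionally with coordinates)
#'
#' The metadata TSV has columns atom_index, mass_amu, charge_e,
#' component, residue_index. Coordinates, if needed, come from a GRO or
#' PDB file with matching atom count and order.
#'
#' @param metadata_path TSV path.
#' @param coordinates_path optional GRO (.gro) or PDB (.pdb) path.
#' @return an `atom_set`.
#' @export
read_atom_metadata <- function(metadata_path, coordinates_path = NULL) {
  tab <- utils::read.table(metadata_path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  need <- c("atom_index", "mass_amu", "charge_e", "component", "residue_index")
  if (!all(need %in% names(tab)))
    stop("atom metadata must have columns: ", paste(need, collapse = ", "))
  tab <- tab[order(tab$atom_index), ]
  coords <- NULL
  if (!is.null(coordinates_path)) {
    coords <- read_coordinates(coordinates_path)
    if (nrow(coords) != nrow(tab))
      stop("coordinate file has ", nrow(coords), " atoms; metadata has ",
           nrow(tab))
  }
  atom_set(tab$mass_amu, tab$charge_e, component = tab$component,
           residue_index = tab$residue_index, coordinates_nm = coords)
}

#' Write atom metadata TSV (and optionally a GRO coordinate file)
#'
#' @param atoms an `atom_set`.
#' @param metadata_path TSV output path.
#' @param coordinates_path optional `.gro` output path for coordinates.
#' @export
write_atom_metadata <- function(atoms, metadata_path,
                                coordinates_path = NULL) {
  df <- data.frame(atom_index = seq_len(atoms$n_atoms),
                   mass_amu = atoms$masses / .const$amu,
                   charge_e = atoms$charges / .const$e_charge,
                   component = as.character(atoms$component),
                   residue_index = atoms$residue_index)
  utils::write.table(format(df, digits = 17, trim = TRUE), metadata_path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(coordinates_path)) {
    if (is.null(atoms$coordinates)) stop("atom set has no coordinates")
    write_gro(atoms, coordinates_path)
  }
  invisible(metadata_path)
}

# Minimal fixed-width GRO reader: title, count, atom lines (coords in nm
# at columns 21-44), box line.
read_gro <- function(path) {
  lines <- readLines(path)
  n <- as.integer(trimws(lines[2]))
  at <- lines[3:(2 + n)]
  x <- as.numeric(substr(at, 21, 28))
  y <- as.numeric(substr(at, 29, 36))
  z <- as.numeric(substr(at, 37, 44))
  cbind(x, y, z)
}

write_gro <- function(atoms, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("synthetic system", sprintf("%5d", atoms$n_atoms)), con)
  comp <- substr(toupper(as.character(atoms$component)), 1, 3)
  writeLines(sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                     atoms$residue_index, comp, "BD",
                     seq_len(atoms$n_atoms) %% 100000,
                     atoms$coordinates[, 1], atoms$coordinates[, 2],
                     atoms$coordinates[, 3]), con)
  writeLines("   10.00000   10.00000   10.00000", con)
  invisible(path)
}

# Minimal PDB ATOM/HETATM reader; coordinates Angstrom -> nm.
read_pdb <- function(path) {
  lines <- readLines(path)
  at <- lines[grepl("^(ATOM  |HETATM)", lines)]
  if (!length(at)) stop("no ATOM/HETATM records in ", path)
  x <- as.numeric(substr(at, 31, 38))
  y <- as.numeric(substr(at, 39, 46))
  z <- as.numeric(substr(at, 47, 54))
  cbind(x, y, z) / 10
}

read_coordinates <- function(path) {
  if (grepl("\\.gro$", path, ignore.case = TRUE)) read_gro(path)
  else if (grepl("\\.pdb$", path, ignore.case = TRUE)) read_pdb(path)
  else stop("unrecognized coordinate format (expect .gro or .pdb): ", path)
}

#' Read a mode ensemble from frequency + eigenvector + metadata files
#'
#' One frequency file and one eigenvector file per replica, sharing one
#' atom-metadata file. Invariants (atom counts, mass-weighted
#' orthonormality) are validated on read.
#'
#' @param frequency_files character vector of XVG paths, one per
#'   replica.
#' @param eigenvector_files character vector of TSV paths, same length.
#' @param atom_metadata path to the metadata TSV.
#' @param coordinates_path optional GRO/PDB coordinates.
#' @param frequency_unit `"cm-1"` (default) or `"hz"`.
#' @return a `mode_ensemble`.
#' @export
read_mode_ensemble <- function(frequency_files, eigenvector_files,
                               atom_metadata, coordinates_path = NULL,
                               frequency_unit = "cm-1") {
  if (length(frequency_files) != length(eigenvector_files))
    stop("need one eigenvector file per frequency file")
  atoms <- read_atom_metadata(atom_metadata, coordinates_path)
  reps <- lapply(seq_along(frequency_files), function(r) {
    f <- read_frequency_xvg(frequency_files[r], unit = frequency_unit)
    ev <- read_eigenvectors_tsv(eigenvector_files[r], atoms$n_atoms)
    if (ncol(ev) != length(f))
      stop("replica ", r, ": ", length(f), " frequencies but ",
           ncol(ev), " eigenvector modes")
    ord <- order(f)
    mode_set(atoms, f[ord], ev[, ord, drop = FALSE], check = TRUE)
  })
  mode_ensemble(reps)
}

#' Write a mode ensemble as the files [read_mode_ensemble()] reads
#'
#' @param ensemble a `mode_ensemble`.
#' @param dir output directory (created if absent).
#' @param basename file-name stem; replica r gets
#'   `<stem>_freq_r.xvg` and `<stem>_evec_r.tsv`, plus
#'   `<stem>_atoms.tsv` (and `<stem>_coords.gro` when coordinates are
#'   present).
#' @return named list of the written paths.
#' @export
write_mode_ensemble <- function(ensemble, dir, basename = "modes") {
  stopifnot(inherits(ensemble, "mode_ensemble"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  atoms <- ensemble$replicas[[1]]$atoms
  meta <- file.path(dir, paste0(basename, "_atoms.tsv"))
  coords <- if (!is.null(atoms$coordinates))
    file.path(dir, paste0(basename, "_coords.gro"))
  write_atom_metadata(atoms, meta, coords)
  ff <- ee <- character(ensemble$n_replicas)
  for (r in seq_len(ensemble$n_replicas)) {
    ff[r] <- file.path(dir, sprintf("%s_freq_%d.xvg", basename, r))
    ee[r] <- file.path(dir, sprintf("%s_evec_%d.tsv", basename, r))
    write_frequency_xvg(ensemble$replicas[[r]]$frequencies, ff[r])
    write_eigenvectors_tsv(ensemble$replicas[[r]]$eigenvectors, ee[r])
  }
  list(frequency_files = ff, eigenvector_files = ee,
       atom_metadata = meta, coordinates = coords)
}

#' Write a spectrum table (TSV with units in the header)
#'
#' Columns: nu_Hz, chi_re, chi_im, eps_re, eps_im, k, alpha_per_m.
#'
#' @param spectrum a `dielectric_spectrum`.
#' @param path output path.
#' @export
write_spectrum_tsv <- function(spectrum, path) {
  utils::write.table(format(as.data.frame(spectrum), digits = 12,
                            scientific = TRUE, trim = TRUE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
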