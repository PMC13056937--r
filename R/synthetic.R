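#' Build a toy harmonic system with an analytic Hessian
#'
#' Generates a small bead-spring system at mechanical equilibrium: every
#' spring's rest length equals the equilibrium inter-bead distance, so the
#' net force is exactly zero and the analytic Hessian is exact (no
#' minimizer needed). Springs are central forces, so the Hessian block for
#' a spring between i and j is k * (n n') with n the unit bond vector;
#' perpendicular curvature vanishes at equilibrium.
#'
#' Topologies:
#' \describe{
#'   \item{chain}{beads on a line, nearest-neighbour springs. Floppy for
#'     n > 2 (bending mechanisms); used for closed-form oracles.}
#'   \item{ring}{beads on a circle, nearest-neighbour springs. The n = 3
#'     triangle is the smallest rigid nonlinear system.}
#'   \item{random}{beads at random positions in a box; springs sampled
#'     until the network is rigid, i.e. its mass-weighted Hessian has
#'     exactly 6 near-zero eigenvalues. Errors if rigidity is not reached
#'     (short of the complete graph).}
#' }
#'
#' @param topology `"chain"`, `"ring"` or `"random"`.
#' @param n_atoms number of beads (>= 2; ring needs >= 3).
#' @param masses_amu per-bead masses in amu (recycled); default 12.
#' @param charges_e per-bead partial charges in e (recycled); default
#'   alternating +0.4 / -0.4, the magnitude of typical backbone partial
#'   charges.
#' @param spring_constant spring stiffness in N/m (scalar). The default
#'   0.02 N/m puts carbon-mass bead frequencies in the 100 GHz range, the
#'   sub-THz window of interest.
#' @param component per-bead component label (recycled), default
#'   `"protein"`.
#' @param residue_index per-bead residue index (recycled over beads);
#'   default one residue per bead.
#' @param spacing_nm equilibrium bond length, nm.
#' @param seed integer seed controlling the random topology/geometry;
#'   systems are deterministic given the seed.
#' @return object of class `harmonic_system`: fields `atoms`
#'   (`atom_set` with coordinates), `springs` (data.frame i, j,
#'   k_spring, rest_length), `hessian` (3N x 3N, N/m).
#' @export
#' @examples
#' sys <- build_harmonic_system("ring", n_atoms = 3, seed = 1)
#' solve_modes(sys)
build_harmonic_system <- function(topology = c("chain", "ring", "random"),
                                  n_atoms,
                                  masses_amu = 12,
                                  charges_e = NULL,
                                  spring_constant = 0.02,
                                  component = "protein",
                                  residue_index = NULL,
                                  spacing_nm = 0.3,
                                  seed = 1L) {
  topology <- match.arg(topology)
  if (n_atoms < 2L) stop("need at least 2 atoms")
  if (spring_constant <= 0) stop("spring constant must be > 0")
  if (is.null(charges_e))
    charges_e <- rep_len(c(0.4, -0.4), n_atoms)
  masses_amu <- rep_len(masses_amu, n_atoms)
  charges_e <- rep_len(charges_e, n_atoms)

  rng <- local_rng(seed)
  if (topology == "chain") {
    coords <- cbind(spacing_nm * (seq_len(n_atoms) - 1), 0, 0)
    springs <- cbind(seq_len(n_atoms - 1L), seq_len(n_atoms - 1L) + 1L)
  } else if (topology == "ring") {
    if (n_atoms < 3L) stop("ring needs at least 3 atoms")
    r <- spacing_nm / (2 * sin(pi / n_atoms))
    th <- 2 * pi * (seq_len(n_atoms) - 1) / n_atoms
    coords <- cbind(r * cos(th), r * sin(th), 0)
    springs <- cbind(seq_len(n_atoms), c(seq_len(n_atoms)[-1], 1L))
  } else {
    got <- random_rigid_network(n_atoms, spacing_nm, rng)
    coords <- got$coords
    springs <- got$springs
  }

  atoms <- atom_set(masses_amu, charges_e, component = component,
                    residue_index = residue_index, coordinates_nm = coords)
  spr <- data.frame(i = springs[, 1], j = springs[, 2],
                    k_spring = spring_constant,
                    rest_length = sqrt(rowSums(
                      (coords[springs[, 1], , drop = FALSE] -
                       coords[springs[, 2], , drop = FALSE])^2)))
  structure(list(atoms = atoms, springs = spr,
                 hessian = spring_hessian(coords, spr)),
            class = "harmonic_system")
}

# Seed the RNG for a generator call. Seeds are explicit arguments
# everywhere; NULL leaves the current RNG stream untouched.
local_rng <- function(seed) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  invisible(NULL)
}

# Random geometry + springs, densified until the central-force network is
# rigid (exactly 6 zero modes). Starts from a distance-cutoff graph and
# adds random extra edges; falls back to the complete graph.
random_rigid_network <- function(n_atoms, spacing_nm, rng) {
  coords <- matrix(stats::runif(3 * n_atoms, 0, spacing_nm * n_atoms^(1 / 3)),
                   ncol = 3)
  all_pairs <- t(utils::combn(n_atoms, 2L))
  d <- sqrt(rowSums((coords[all_pairs[, 1], , drop = FALSE] -
                     coords[all_pairs[, 2], , drop = FALSE])^2))
  ord <- order(d)
  # take the shortest edges first; grow until rigid
  need <- 3L * n_atoms - 6L
  for (m in seq(from = min(need, nrow(all_pairs)), to = nrow(all_pairs))) {
    springs <- all_pairs[ord[seq_len(m)], , drop = FALSE]
    spr <- data.frame(i = springs[, 1], j = springs[, 2],
                      k_spring = 1, rest_length = d[ord[seq_len(m)]])
    h <- spring_hessian(coords, spr)
    ev <- eigen(h, symmetric = TRUE, only.values = TRUE)$values
    nzero <- sum(abs(ev) < 1e-9 * max(abs(ev)))
    if (nzero == 6L) return(list(coords = coords, springs = springs))
  }
  stop("could not generate a rigid random network (degenerate geometry); try another seed")
}

# Analytic Hessian of central-force springs at equilibrium (rest length =
# current length): per-spring block k * outer(n, n). Units N/m.
spring_hessian <- function(coords_nm, springs) {
  n <- nrow(coords_nm)
  h <- matrix(0, 3 * n, 3 * n)
  for (s in seq_len(nrow(springs))) {
    i <- springs$i[s]; j <- springs$j[s]
    if (i == j) stop("spring endpoints must be distinct")
    v <- coords_nm[j, ] - coords_nm[i, ]
    nv <- v / sqrt(sum(v^2))
    blk <- springs$k_spring[s] * tcrossprod(nv)
    ii <- (3 * i - 2):(3 * i); jj <- (3 * j - 2):(3 * j)
    h[ii, ii] <- h[ii, ii] + blk
    h[jj, jj] <- h[jj, jj] + blk
    h[ii, jj] <- h[ii, jj] - blk
    h[jj, ii] <- h[jj, ii] - blk
  }
  h
}

#' @export
print.harmonic_system <- function(x, ...) {
  cat("<harmonic_system> ", x$atoms$n_atoms, " atoms, ",
      nrow(x$springs), " springs\n", sep = "")
  invisible(x)
}

#' Diagonalize a harmonic system into a mode set
#'
#' Forms the mass-weighted Hessian D = M^(-1/2) H M^(-1/2), diagonalizes
#' it, and returns Cartesian eigenvectors e = u / sqrt(m) in kg^(-1/2)
#' with frequencies nu_l = sqrt(lambda_l) / (2 pi). Eigenvalues are sorted
#' ascending; negative eigenvalues beyond tolerance (a saddle, not a
#' minimum) raise an error, and small negative round-off is clamped to
#' zero.
#'
#' @param system a `harmonic_system`.
#' @param neg_tol relative tolerance on negative eigenvalues, as a
#'   fraction of the largest eigenvalue.
#' @return a `mode_set` containing all 3N modes (rigid-body included;
#'   use [select_vibrational_modes()] before spectra).
#' @export
solve_modes <- function(system, neg_tol = 1e-9) {
  stopifnot(inherits(system, "harmonic_system"))
  m_atom <- system$atoms$masses
  w <- rep(m_atom, each = 3L)                 # kg, per Cartesian DOF
  d <- system$hessian / sqrt(outer(w, w))     # 1/s^2 scale after /kg... (N/m/kg = 1/s^2)
  d <- (d + t(d)) / 2
  es <- eigen(d, symmetric = TRUE)
  lam <- rev(es$values)
  u <- es$vectors[, rev(seq_along(lam)), drop = FALSE]
  if (min(lam) < -neg_tol * max(abs(lam)))
    stop("negative Hessian eigenvalue (", format(min(lam)),
         "): system is not at a potential-energy minimum")
  lam <- pmax(lam, 0)
  freq <- sqrt(lam) / (2 * pi)
  evec <- u / sqrt(w)                          # Cartesian, kg^(-1/2)
  mode_set(system$atoms, freq, evec, check = TRUE)
}

#' Attach a hydration shell of tethered particles to a core system
#'
#' Emulates a hydration layer: `n_shell_particles` water-labelled beads
#' are placed just outside randomly chosen core atoms and tethered by
#' central-force springs to their three nearest core atoms (three
#' non-collinear anchors keep the augmented network rigid). Stiff
#' tethering makes the composite effectively stiffer than the bare core,
#' reproducing the hydration blue-shift of the lowest vibrational band.
#'
#' @param core a `harmonic_system`.
#' @param n_shell_particles number of shell beads (>= 1).
#' @param attach_stiffness tether spring constant, N/m (> 0). "Stiff"
#'   means large relative to the core spring constant.
#' @param n_anchors core atoms each shell bead is tethered to (its
#'   nearest ones), default 5. With only 3 tethers the bead's 3 degrees
#'   of freedom absorb all 3 constraints and the stiff limit adds pure
#'   mass (a red-shift); every tether beyond the third bridges core
#'   atoms and stiffens the composite, mirroring a water molecule
#'   hydrogen-bonding to several surface atoms at once.
#' @param shell_mass_amu shell bead mass, default 18 (water).
#' @param shell_charge_e shell bead charge, default -0.8 (water-oxygen
#'   scale).
#' @param offset_nm radial distance of shell beads from their host core
#'   atom.
#' @param seed integer seed.
#' @return a `harmonic_system` whose atoms are core atoms followed by
#'   shell particles labelled `component = "water"`.
#' @export
synth_hydrated_variant <- function(core, n_shell_particles,
                                   attach_stiffness,
                                   n_anchors = 5L,
                                   shell_mass_amu = 18,
                                   shell_charge_e = -0.8,
                                   offset_nm = 0.25,
                                   seed = 1L) {
  stopifnot(inherits(core, "harmonic_system"))
  if (attach_stiffness <= 0) stop("attach_stiffness must be > 0")
  if (n_shell_particles < 1L) stop("need at least one shell particle")
  cc <- core$atoms$coordinates
  if (is.null(cc)) stop("core system has no coordinates")
  nc <- nrow(cc)
  rng <- local_rng(seed)
  centroid <- colMeans(cc)
  hosts <- sample.int(nc, n_shell_particles, replace = TRUE)
  shell <- t(vapply(seq_len(n_shell_particles), function(s) {
    dir <- cc[hosts[s], ] - centroid + stats::rnorm(3, sd = 0.05)
    nrm <- sqrt(sum(dir^2))
    if (nrm < 1e-12) dir <- c(1, 0, 0) else dir <- dir / nrm
    cc[hosts[s], ] + offset_nm * dir
  }, numeric(3)))
  coords <- rbind(cc, shell)

  # tether each shell bead to its n_anchors nearest core atoms
  if (n_anchors < 3L) stop("n_anchors must be >= 3 for a rigid attachment")
  extra <- do.call(rbind, lapply(seq_len(n_shell_particles), function(s) {
    d2 <- rowSums((cc - matrix(shell[s, ], nc, 3, byrow = TRUE))^2)
    anchors <- order(d2)[seq_len(min(n_anchors, nc))]
    cbind(anchors, nc + s)
  }))
  springs <- rbind(as.matrix(core$springs[, c("i", "j")]), extra)
  ks <- c(core$springs$k_spring, rep(attach_stiffness, nrow(extra)))

  atoms <- atom_set(
    masses_amu = c(core$atoms$masses / .const$amu, rep(shell_mass_amu, n_shell_particles)),
    charges_e = c(core$atoms$charges / .const$e_charge,
                  rep_len(shell_charge_e, n_shell_particles)),
    component = c(as.character(core$atoms$component),
                  rep("water", n_shell_particles)),
    residue_index = c(core$atoms$residue_index,
                      max(core$atoms$residue_index) + seq_len(n_shell_particles)),
    coordinates_nm = coords)
  spr <- data.frame(i = springs[, 1], j = springs[, 2], k_spring = ks,
                    rest_length = sqrt(rowSums(
                      (coords[springs[, 1], , drop = FALSE] -
                       coords[springs[, 2], , drop = FALSE])^2)))
  structure(list(atoms = atoms, springs = spr,
                 hessian = spring_hessian(coords, spr)),
            class = "harmonic_system")
}

#' Markov-chain water-shell trajectory
#'
#' Generates a per-frame shell assignment for each water as a first-order
#' Markov chain: a water stays in its current shell with probability
#' `stay_probability`, otherwise jumps uniformly to one of the other
#' shells (including the "outside all shells" state, coded -1). This is
#' the synthetic stand-in for shell assignments extracted from an MD
#' trajectory and has a known stay probability against which persistence
#' estimators can be checked.
#'
#' @param n_waters number of waters.
#' @param stay_probability probability in [0, 1] of remaining in the
#'   current state between consecutive frames.
#' @param n_frames number of frames (>= 2).
#' @param boundaries_angstrom ordered shell edges in Angstrom; default
#'   c(0, 3, 5, 7, 9) defines four bands.
#' @param frame_spacing_ps frame spacing Delta-t in ps, default 20.
#' @param include_outside logical; include the outside (-1) state in the
#'   chain's state space (default TRUE).
#' @param seed integer seed.
#' @return object of class `shell_trajectory`: `shell_index` is an
#'   n_frames x n_waters integer matrix with values in 0..(n_shells-1) or
#'   -1; plus `n_frames`, `frame_spacing`, `boundaries`.
#' @export
synth_shell_trajectory <- function(n_waters, stay_probability, n_frames,
                                   boundaries_angstrom = c(0, 3, 5, 7, 9),
                                   frame_spacing_ps = 20,
                                   include_outside = TRUE,
                                   seed = 1L) {
  if (stay_probability < 0 || stay_probability > 1)
    stop("stay_probability must be in [0, 1]")
  if (n_frames < 2L) stop("need at least 2 frames (persistence undefined)")
  if (is.unsorted(boundaries_angstrom, strictly = TRUE))
    stop("boundaries must be strictly increasing")
  n_shells <- length(boundaries_angstrom) - 1L
  states <- c(seq_len(n_shells) - 1L, if (include_outside) -1L)
  ns <- length(states)
  if (ns < 2L && stay_probability < 1)
    stop("need at least two states to jump between")
  rng <- local_rng(seed)
  sh <- matrix(0L, n_frames, n_waters)
  sh[1L, ] <- sample(states, n_waters, replace = TRUE)
  for (f in 2L:n_frames) {
    stay <- stats::runif(n_waters) < stay_probability
    prev <- sh[f - 1L, ]
    nxt <- prev
    mv <- which(!stay)
    if (length(mv)) {
      # uniform among the ns-1 other states: shift a 1..(ns-1) draw past self
      cur_pos <- match(prev[mv], states)
      off <- sample.int(ns - 1L, length(mv), replace = TRUE)
      nxt[mv] <- states[1L + (cur_pos - 1L + off) %% ns]
    }
    sh[f, ] <- nxt
  }
  shell_trajectory(sh, boundaries_angstrom, frame_spacing_ps)
}

#' Construct a shell trajectory from a shell-index matrix
#'
#' @param shell_index n_frames x n_waters integer matrix, entries in
#'   0..(n_shells - 1) or -1 for outside.
#' @param boundaries_angstrom strictly increasing shell edges, Angstrom.
#' @param frame_spacing_ps frame spacing, ps.
#' @return object of class `shell_trajectory`.
#' @export
shell_trajectory <- function(shell_index, boundaries_angstrom,
                             frame_spacing_ps = 20) {
  shell_index <- as.matrix(shell_index)
  storage.mode(shell_index) <- "integer"
  if (is.unsorted(boundaries_angstrom, strictly = TRUE))
    stop("boundaries must be strictly increasing")
  n_shells <- length(boundaries_angstrom) - 1L
  if (any(shell_index < -1L | shell_index >= n_shells))
    stop("shell_index values out of range")
  if (frame_spacing_ps <= 0) stop("frame_spacing_ps must be > 0")
  structure(list(shell_index = shell_index,
                 n_frames = nrow(shell_index),
                 n_waters = ncol(shell_index),
                 frame_spacing = frame_spacing_ps,
                 boundaries = as.numeric(boundaries_angstrom)),
            class = "shell_trajectory")
}

#' @export
print.shell_trajectory <- function(x, ...) {
  cat("<shell_trajectory> ", x$n_waters, " waters x ", x$n_frames,
      " frames, dt = ", x$frame_spacing, " ps, shells (",
      paste(x$boundaries, collapse = ", "), ") A\n", sep = "")
  invisible(x)
}
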