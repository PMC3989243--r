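# Synthetic U-bend cross-beta oligomer builder and trajectory generator.
#
# The generator lays backbone atoms (N, H, CA, C, O) plus one pseudo-
# sidechain atom (CB) per non-Gly residue on an idealized parallel
# in-register lattice: residues advance along x at `rise_per_residue`,
# chains stack along the fibril axis y at `interchain_spacing`, and the two
# strands of the U-bend fold occupy parallel sheets separated along z,
# joined by a semicircular turn. Amide N-H groups of strand residues point
# along +y with the acceptor carbonyl O of the next chain placed on the
# same axis, so every inter-chain backbone H-bond geometry (N...O = 2.9 A,
# D-H-A = 180 deg) is satisfied by construction. This is an H-bond-lattice
# scaffold, not stereochemistry.

.HIAPP_SEQ <- c("LYS", "CYS", "ASN", "THR", "ALA", "THR", "CYS", "ALA",
                "THR", "GLN", "ARG", "LEU", "ALA", "ASN", "PHE", "LEU",
                "VAL", "HIS", "SER", "SER", "ASN", "ASN", "PHE", "GLY",
                "ALA", "ILE", "LEU", "SER", "SER", "THR", "ASN", "VAL",
                "GLY", "SER", "ASN", "THR", "TYR")

# CHARMM-flavoured backbone nonbonded parameters (charge e, eps kcal/mol,
# rmin/2 A) so the synthetic system is usable by interaction_energy().
.BB_PARAMS <- list(
  N  = c(-0.47, 0.20, 1.85),
  H  = c( 0.31, 0.046, 0.2245),
  CA = c( 0.07, 0.07, 2.275),
  C  = c( 0.51, 0.11, 2.00),
  O  = c(-0.51, 0.12, 1.70),
  CB = c( 0.09, 0.08, 2.06))

#' Specify an idealized U-bend beta-sheet oligomer
#'
#' Defaults emulate a single-layer parallel in-register amyloid oligomer of
#' 37-residue chains folded as beta-strand (1-17) - turn (18-27) -
#' beta-strand (28-37), with standard cross-beta lattice constants
#' (4.8 A stacking, 3.4 A rise per strand residue).
#'
#' @param n_chains number of peptide chains (>= 2).
#' @param n_residues residues per chain.
#' @param strand1,turn,strand2 integer ranges partitioning `1:n_residues`.
#' @param interchain_spacing chain stacking distance along the fibril axis, A.
#' @param rise_per_residue along-strand residue spacing, A.
#' @param sheet_separation distance between the two strand sheets, A.
#' @return an `oligomer_spec` list.
#' @export
oligomer_spec <- function(n_chains = 5, n_residues = 37,
                          strand1 = 1:17, turn = 18:27, strand2 = 28:37,
                          interchain_spacing = 4.8, rise_per_residue = 3.4,
                          sheet_separation = 12) {
  if (n_chains < 2) stop("an oligomer requires n_chains >= 2")
  if (!identical(sort(c(strand1, turn, strand2)), 1:n_residues))
    stop("strand1, turn, strand2 must partition 1:n_residues")
  if (interchain_spacing <= 0 || rise_per_residue <= 0)
    stop("spacings must be positive")
  structure(list(n_chains = n_chains, n_residues = n_residues,
                 strand1 = strand1, turn = turn, strand2 = strand2,
                 interchain_spacing = interchain_spacing,
                 rise_per_residue = rise_per_residue,
                 sheet_separation = sheet_separation),
            class = "oligomer_spec")
}

#' Specify per-frame disorder for the trajectory generator
#'
#' @param orientation_sigma sd (degrees) of the random rigid rotation
#'   applied independently to each chain about its centroid, per frame.
#' @param fray_terminal number of C-terminal residues of each edge chain
#'   displaced per frame (terminal fraying).
#' @param ladder_break_fraction fraction of constructed inter-chain
#'   backbone H-bond geometries broken per frame (the donor amide H is
#'   rotated out of alignment, leaving everything else intact).
#' @param seed RNG seed; identical specs and seeds give bit-identical
#'   trajectories.
#' @export
disorder_spec <- function(orientation_sigma = 0, fray_terminal = 0,
                          ladder_break_fraction = 0, seed = 1) {
  if (ladder_break_fraction < 0 || ladder_break_fraction > 1)
    stop("ladder_break_fraction must be in [0, 1]")
  if (orientation_sigma < 0 || fray_terminal < 0)
    stop("disorder magnitudes must be non-negative")
  structure(list(orientation_sigma = orientation_sigma,
                 fray_terminal = as.integer(fray_terminal),
                 ladder_break_fraction = ladder_break_fraction,
                 seed = as.integer(seed)),
            class = "disorder_spec")
}

#' Build the ordered oligomer template
#'
#' @param spec an [oligomer_spec()].
#' @return list with elements `topology` (an `oligo_topology`), `coords`
#'   (atoms x 3 matrix), and `ladder_bonds` (data.frame of the constructed
#'   inter-chain H-bond geometries: donor chain index, residue, and the
#'   donor H / N atom rows — the generator's ground truth).
#' @export
build_ordered_oligomer <- function(spec) {
  if (!inherits(spec, "oligomer_spec")) spec <- do.call(oligomer_spec, spec)
  nc <- spec$n_chains; nr <- spec$n_residues
  rise <- spec$rise_per_residue; dy <- spec$interchain_spacing
  zsep <- spec$sheet_separation
  x17 <- rise * (length(spec$strand1) - 1)
  r_turn <- zsep / 2
  nt <- length(spec$turn)
  o_drop <- dy - 2.9  # puts acceptor O 2.9 A from the next chain's donor N

  seq3 <- if (nr == 37) .HIAPP_SEQ else rep("ALA", nr)

  rows <- list(); coords <- list(); serial <- 0L
  add_atom <- function(name, element, chain, resno, resname, xyz) {
    serial <<- serial + 1L
    p <- .BB_PARAMS[[name]]
    if (is.null(p)) p <- c(0, 0.05, 1.5)
    rows[[serial]] <<- data.frame(
      serial = serial, name = name, element = element, chain_id = chain,
      residue_index = resno, residue_name = resname, is_ligand = FALSE,
      molecule_id = 0L, mass = unname(.ELEMENT_MASS[element]),
      charge = p[1], lj_epsilon = p[2], lj_rmin_half = p[3],
      stringsAsFactors = FALSE)
    coords[[serial]] <<- xyz
  }
  ladder <- list()

  for (c_i in seq_len(nc)) {
    y <- (c_i - 1) * dy
    chain <- LETTERS[c_i]
    for (r in seq_len(nr)) {
      resname <- seq3[r]
      in_s1 <- r %in% spec$strand1
      in_s2 <- r %in% spec$strand2
      if (in_s1 || in_s2) {
        if (in_s1) {
          x <- rise * (r - 1); z <- 0; dir <- 1
        } else {
          x <- x17 - rise * (r - spec$strand2[1] + 1); z <- zsep; dir <- -1
        }
        n_xyz <- c(x - 1.2 * dir, y, z)
        h_xyz <- n_xyz + c(0, 1, 0)
        ca_xyz <- c(x, y, z)
        c_xyz <- c(x + 1.2 * dir, y, z)
        o_xyz <- c(x - 1.2 * dir, y - o_drop, z)
        cb_dir <- if (r %% 2 == 0) 1 else -1
        cb_xyz <- ca_xyz + c(0, 0, cb_dir * (if (z == 0) 1.5 else 1.5))
        if (c_i < nc)
          ladder[[length(ladder) + 1L]] <- data.frame(
            donor_chain = c_i, residue = r,
            h_serial = serial + 2L, n_serial = serial + 1L)
      } else {
        k <- match(r, spec$turn)
        phi <- -pi / 2 + pi * k / (nt + 1)
        radial <- c(cos(phi), 0, sin(phi))
        tangent <- c(-sin(phi), 0, cos(phi))
        ca_xyz <- c(x17, y, r_turn) + r_turn * radial
        n_xyz <- ca_xyz - 1.2 * tangent
        h_xyz <- n_xyz + radial        # points in xz-plane: no ladder bond
        c_xyz <- ca_xyz + 1.2 * tangent
        o_xyz <- c_xyz + 1.23 * radial
        cb_xyz <- ca_xyz + 1.5 * radial + c(0, 0.8, 0)
      }
      add_atom("N", "N", chain, r, resname, n_xyz)
      add_atom("H", "H", chain, r, resname, h_xyz)
      add_atom("CA", "C", chain, r, resname, ca_xyz)
      add_atom("C", "C", chain, r, resname, c_xyz)
      add_atom("O", "O", chain, r, resname, o_xyz)
      if (resname != "GLY") add_atom("CB", "C", chain, r, resname, cb_xyz)
    }
  }
  atoms <- do.call(rbind, rows)
  xyz <- do.call(rbind, coords)
  h_parent <- infer_h_parents(atoms)
  top <- topology(atoms, h_parent, residues_per_chain = nr)
  ladder_bonds <- if (length(ladder)) do.call(rbind, ladder) else
    data.frame(donor_chain = integer(), residue = integer(),
               h_serial = integer(), n_serial = integer())
  list(topology = top, coords = xyz, ladder_bonds = ladder_bonds,
       spec = spec)
}

# Random rotation matrix: angle about a uniformly random axis.
.rot_matrix <- function(axis, angle) {
  a <- axis / sqrt(sum(axis^2))
  c_ <- cos(angle); s_ <- sin(angle)
  K <- matrix(c(0, -a[3], a[2], a[3], 0, -a[1], -a[2], a[1], 0), 3, 3,
              byrow = TRUE)
  diag(3) * c_ + s_ * K + (1 - c_) * (a %o% a)
}

#' Generate a trajectory with controlled disorder
#'
#' Each frame applies independent perturbations to the ordered template:
#' ladder breaks first (the donor amide H of a sampled fraction of the
#' constructed inter-chain H-bond geometries is rotated to point along the
#' strand, failing the angle criterion), then a random rigid rotation per
#' chain, then terminal fraying (random rigid displacement of the last
#' `fray_terminal` residues of the two edge chains). With an all-zero
#' disorder spec every frame equals the template.
#'
#' @param base result of [build_ordered_oligomer()].
#' @param disorder a [disorder_spec()].
#' @param n_frames number of frames (>= 1).
#' @param timestep ps between frames.
#' @return an `oligo_trajectory` with attribute `ground_truth`: the
#'   disorder spec plus per-frame broken-bond counts and the template
#'   ladder-bond table.
#' @export
generate_trajectory <- function(base, disorder = disorder_spec(),
                                n_frames = 1, timestep = 1) {
  if (n_frames < 1) stop("n_frames must be >= 1")
  top <- base$topology
  at <- top$atoms
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(disorder$seed)
  nb <- nrow(base$ladder_bonds)
  chains <- top$chains
  chain_rows <- lapply(chains, function(ch)
    which(at$chain_id == ch & !at$is_ligand))
  nr <- top$residues_per_chain
  fray_res <- if (disorder$fray_terminal > 0)
    (nr - disorder$fray_terminal + 1):nr else integer()
  edge_chains <- c(chains[1], chains[length(chains)])

  broken_per_frame <- integer(n_frames)
  coords <- vector("list", n_frames)
  for (f in seq_len(n_frames)) {
    xyz <- base$coords
    if (disorder$ladder_break_fraction > 0 && nb > 0) {
      brk <- which(stats::runif(nb) < disorder$ladder_break_fraction)
      broken_per_frame[f] <- length(brk)
      for (b in brk) {
        hs <- base$ladder_bonds$h_serial[b]
        ns <- base$ladder_bonds$n_serial[b]
        xyz[hs, ] <- xyz[ns, ] + c(1, 0, 0)  # H now perpendicular to N...O
      }
    }
    if (disorder$orientation_sigma > 0) {
      for (rows in chain_rows) {
        ang <- stats::rnorm(1, 0, disorder$orientation_sigma) * pi / 180
        axis <- stats::rnorm(3)
        ctr <- colMeans(xyz[rows, , drop = FALSE])
        R <- .rot_matrix(axis, ang)
        xyz[rows, ] <- sweep(sweep(xyz[rows, , drop = FALSE], 2, ctr) %*%
                               t(R), 2, ctr, "+")
      }
    }
    if (length(fray_res)) {
      for (ch in edge_chains) {
        for (r in fray_res) {
          rows <- which(at$chain_id == ch & at$residue_index == r &
                          !at$is_ligand)
          shift <- stats::rnorm(3, 0, 2.5)
          xyz[rows, ] <- sweep(xyz[rows, , drop = FALSE], 2, shift, "+")
        }
      }
    }
    coords[[f]] <- xyz
  }
  traj <- trajectory(top, coords, times = (seq_len(n_frames) - 1) * timestep)
  attr(traj, "ground_truth") <- list(
    disorder = disorder, ladder_bonds = base$ladder_bonds,
    n_ladder_bonds = nb, broken_per_frame = broken_per_frame)
  traj
}
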