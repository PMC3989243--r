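# Fixtures built in code: toy topologies, an ideal helix scaffold, and
# independent brute-force oracles.

# Minimal topology from flat vectors; one atom per row.
toy_topology <- function(name, element, chain, residue, xyz,
                         is_ligand = rep(FALSE, length(name)),
                         molecule_id = rep(0L, length(name)),
                         charge = rep(NA_real_, length(name)),
                         resname = rep("ALA", length(name)),
                         h_parent = rep(NA_integer_, length(name)),
                         residues_per_chain = NULL) {
  atoms <- data.frame(serial = seq_along(name), name = name,
                      element = element, chain_id = chain,
                      residue_index = residue, residue_name = resname,
                      is_ligand = is_ligand, molecule_id = molecule_id,
                      mass = ifelse(element == "H", 1.008, 14),
                      charge = charge, stringsAsFactors = FALSE)
  topology(atoms, h_parent, residues_per_chain = residues_per_chain)
}

# Topology of n_chains chains whose end-to-end C-alpha vectors are given:
# chain i runs from origin_i to origin_i + vectors[i, ].
chains_with_vectors <- function(vectors, origins = NULL) {
  nc <- nrow(vectors)
  if (is.null(origins)) origins <- cbind(seq_len(nc) * 50, 0, 0)
  name <- rep("CA", 2 * nc)
  chain <- rep(as.character(seq_len(nc)), each = 2)
  residue <- rep(c(1L, 2L), nc)
  xyz <- matrix(0, 2 * nc, 3)
  for (i in seq_len(nc)) {
    xyz[2 * i - 1, ] <- origins[i, ]
    xyz[2 * i, ] <- origins[i, ] + vectors[i, ]
  }
  list(top = toy_topology(name, rep("C", 2 * nc), chain, residue, xyz,
                          residues_per_chain = 2),
       coords = xyz)
}

# Ideal alpha-helix backbone scaffold: C-alphas on a 2.3 A helix with
# 1.5 A rise and 100 deg twist; carbonyl O of residue i placed 2.9 A from
# N(i+4) on the line toward C(i), and the amide H of residue i aligned
# from N(i) toward O(i-4), so every i -> i+4 hydrogen bond holds by
# construction.
build_ideal_helix <- function(n = 12) {
  r <- 2.3; rise <- 1.5; twist <- 100 * pi / 180
  ca <- t(vapply(seq_len(n), function(i)
    c(r * cos(i * twist), r * sin(i * twist), rise * i), numeric(3)))
  outward <- ca; outward[, 3] <- 0
  outward <- outward / sqrt(rowSums(outward^2))
  n_at <- sweep(ca - 0.6 * outward, 2, c(0, 0, -0.8), "+")
  c_at <- sweep(ca - 0.6 * outward, 2, c(0, 0, 0.8), "+")
  o_at <- matrix(0, n, 3); h_at <- matrix(0, n, 3)
  for (i in seq_len(n)) {
    if (i + 4 <= n) {
      v <- c_at[i, ] - n_at[i + 4, ]
      o_at[i, ] <- n_at[i + 4, ] + 2.9 * v / sqrt(sum(v^2))
    } else {
      o_at[i, ] <- c_at[i, ] + 1.23 * outward[i, ]
    }
  }
  for (i in seq_len(n)) {
    if (i >= 5) {
      v <- o_at[i - 4, ] - n_at[i, ]
      h_at[i, ] <- n_at[i, ] + v / sqrt(sum(v^2))
    } else {
      h_at[i, ] <- n_at[i, ] + outward[i, ]
    }
  }
  name <- rep(c("N", "H", "CA", "C", "O"), n)
  residue <- rep(seq_len(n), each = 5)
  element <- rep(c("N", "H", "C", "C", "O"), n)
  xyz <- matrix(0, 5 * n, 3)
  for (i in seq_len(n)) {
    xyz[5 * i - 4, ] <- n_at[i, ]; xyz[5 * i - 3, ] <- h_at[i, ]
    xyz[5 * i - 2, ] <- ca[i, ]; xyz[5 * i - 1, ] <- c_at[i, ]
    xyz[5 * i, ] <- o_at[i, ]
  }
  h_parent <- rep(NA_integer_, 5 * n)
  h_parent[seq(2, 5 * n, by = 5)] <- seq(1, 5 * n, by = 5)
  top <- toy_topology(name, element, rep("A", 5 * n), residue, xyz,
                      h_parent = h_parent, residues_per_chain = n)
  list(top = top, coords = xyz)
}

# Exhaustive H-bond oracle: explicit loop over every donor hydrogen against
# every N/O acceptor; strict < 3.5 A on D...A and strict > 150 deg on D-H-A.
brute_force_hbonds <- function(coords, top) {
  at <- top$atoms
  hp <- top$h_parent
  out <- list()
  for (h in which(at$element == "H" & !is.na(hp))) {
    d <- hp[h]
    if (!at$element[d] %in% c("N", "O")) next
    for (a in which(at$element %in% c("N", "O"))) {
      if (a == d) next
      if (at$chain_id[a] == at$chain_id[d] &&
          at$residue_index[a] == at$residue_index[d] &&
          at$is_ligand[a] == at$is_ligand[d] &&
          at$molecule_id[a] == at$molecule_id[d]) next
      dist_da <- sqrt(sum((coords[d, ] - coords[a, ])^2))
      if (dist_da >= 3.5) next
      v1 <- coords[d, ] - coords[h, ]
      v2 <- coords[a, ] - coords[h, ]
      ang <- acos(min(1, max(-1, sum(v1 * v2) /
                               sqrt(sum(v1^2) * sum(v2^2))))) * 180 / pi
      if (ang > 150)
        out[[length(out) + 1L]] <- c(donor = d, hydrogen = h, acceptor = a)
    }
  }
  if (!length(out)) return(matrix(integer(), 0, 3))
  m <- do.call(rbind, out)
  m[order(m[, 1], m[, 2], m[, 3]), , drop = FALSE]
}

# Random dense frame of donor/acceptor groups for detector cross-checks:
# n_res "residues" of (N, H, O) scattered in a box.
random_hbond_system <- function(n_res, box = 18, seed = 1) {
  set.seed(seed)
  name <- rep(c("N", "H", "O"), n_res)
  element <- rep(c("N", "H", "O"), n_res)
  chain <- rep(rep(c("A", "B"), length.out = n_res), each = 3)
  residue <- rep(seq_len(n_res), each = 3)
  base <- matrix(runif(3 * n_res, 0, box), n_res, 3)
  xyz <- matrix(0, 3 * n_res, 3)
  for (i in seq_len(n_res)) {
    xyz[3 * i - 2, ] <- base[i, ]
    u <- rnorm(3); u <- u / sqrt(sum(u^2))
    xyz[3 * i - 1, ] <- base[i, ] + u          # H, 1 A from its N
    xyz[3 * i, ] <- base[i, ] + runif(3, -2, 2)
  }
  h_parent <- rep(NA_integer_, 3 * n_res)
  h_parent[seq(2, 3 * n_res, by = 3)] <- seq(1, 3 * n_res, by = 3)
  top <- toy_topology(name, element, chain, residue, xyz,
                      h_parent = h_parent)
  list(top = top, coords = xyz)
}

# Standard ordered 5-mer fixture shared across tests.
ordered_pentamer <- function() build_ordered_oligomer(oligomer_spec())

# Two-state trajectory: frames drawn from two rigid conformers (the second
# has chain A translated away), with tiny seeded jitter so frames are
# distinct; returns trajectory plus true state labels.
two_state_trajectory <- function(n1 = 60, n2 = 40, jitter = 0.05,
                                 seed = 7) {
  base <- ordered_pentamer()
  at <- base$topology$atoms
  conf2 <- base$coords
  rows <- which(at$chain_id == "A")
  conf2[rows, ] <- sweep(conf2[rows, , drop = FALSE], 2, c(0, 0, 25), "+")
  set.seed(seed)
  states <- c(rep(1, n1), rep(2, n2))
  coords <- lapply(states, function(s) {
    xyz <- if (s == 1) base$coords else conf2
    xyz + matrix(rnorm(length(xyz), 0, jitter), nrow(xyz), 3)
  })
  list(traj = trajectory(base$topology, coords), states = states)
}

# ZYZ Euler rotation used by the superposition grid oracle.
.grid_rot <- function(a, b, c_) {
  Rz <- matrix(c(cos(a), -sin(a), 0, sin(a), cos(a), 0, 0, 0, 1), 3, 3,
               byrow = TRUE)
  Ry <- matrix(c(cos(b), 0, sin(b), 0, 1, 0, -sin(b), 0, cos(b)), 3, 3,
               byrow = TRUE)
  Rz2 <- matrix(c(cos(c_), -sin(c_), 0, sin(c_), cos(c_), 0, 0, 0, 1), 3, 3,
                byrow = TRUE)
  Rz %*% Ry %*% Rz2
}

# Compact single-ring ligand template (small footprint): used to build two
# copies whose consensus contact sets coincide on one pocket residue.
mini_ligand_template <- function() {
  ang <- seq(0, by = pi / 3, length.out = 6)
  ring <- cbind(1.4 * cos(ang), 1.4 * sin(ang), 0)
  o <- ring[1, ] * (1.4 + 1.36) / 1.4
  h_at <- ring[1, ] * (1.4 + 2.33) / 1.4
  coords <- rbind(ring, o, h_at)
  atoms <- data.frame(name = c(paste0("C", 1:6), "O1", "HO1"),
                      element = c(rep("C", 6), "O", "H"),
                      charge = 0,
                      lj_epsilon = c(rep(0.12, 6), 0.12, 0.046),
                      lj_rmin_half = c(rep(1.1, 6), 1.0, 0.2245),
                      stringsAsFactors = FALSE)
  structure(list(atoms = atoms, coords = coords,
                 h_parent = c(rep(NA_integer_, 7), 7L), resname = "MNL",
                 rings = list(A = paste0("C", 1:6))),
            class = "ligand_template")
}
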