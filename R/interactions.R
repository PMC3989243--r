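# Geometric hydrogen-bond detection, residue-pair H-bond maps, ligand
# contacts, pi-stacking classification, and switched nonbonded
# interaction-energy traces.

.HB_DIST <- 3.5    # D...A distance cutoff, strict "<"
.HB_ANGLE <- 150   # D-H-A angle cutoff at H, strict ">"
.CONTACT_DIST <- 3.5
COULOMB_CONST <- 332.0636  # kcal A mol^-1 e^-2

#' Detect hydrogen bonds in one frame
#'
#' A bond is recorded for a donor-H-acceptor triple when the donor-acceptor
#' distance is strictly less than 3.5 A and the D-H-A angle (at the
#' hydrogen) is strictly greater than 150 degrees. Donors are N/O heavy
#' atoms with at least one parented hydrogen; acceptors are N/O atoms.
#' Intra-residue pairs are excluded. Triples are directional, so no
#' symmetric double counting can occur.
#'
#' @param coords atoms x 3 coordinate matrix.
#' @param top the topology; hydrogens must be parented (structures without
#'   hydrogens are refused rather than reconstructed).
#' @param scope `"backbone"` restricts donors to backbone amide hydrogens
#'   and acceptors to backbone carbonyl O of protein chains; `"all"` uses
#'   every N/O (protein and ligand).
#' @return data.frame(donor, hydrogen, acceptor, distance, angle) of atom
#'   row indices plus geometry; attribute `scope`.
#' @export
detect_hbonds <- function(coords, top, scope = c("backbone", "all")) {
  scope <- match.arg(scope)
  at <- top$atoms
  hp <- top$h_parent
  h_idx <- which(at$element == "H" & !is.na(hp))
  if (!length(h_idx))
    stop("topology has no parented hydrogens; H-bond analysis requires ",
         "explicit hydrogens (reconstruction is not performed)")
  d_idx <- hp[h_idx]
  keep <- at$element[d_idx] %in% c("N", "O")
  h_idx <- h_idx[keep]; d_idx <- d_idx[keep]
  if (scope == "backbone") {
    bb <- backbone_mask(top)
    keep <- bb[d_idx] & at$name[d_idx] == "N" & !at$is_ligand[d_idx]
    h_idx <- h_idx[keep]; d_idx <- d_idx[keep]
    a_idx <- which(bb & at$name == "O" & !at$is_ligand)
  } else {
    a_idx <- which(at$element %in% c("N", "O"))
  }
  if (!length(h_idx) || !length(a_idx))
    return(structure(data.frame(donor = integer(), hydrogen = integer(),
                                acceptor = integer(), distance = numeric(),
                                angle = numeric()), scope = scope))
  D <- coords[d_idx, , drop = FALSE]
  A <- coords[a_idx, , drop = FALSE]
  d2 <- outer(rowSums(D^2), rowSums(A^2), "+") - 2 * D %*% t(A)
  d2[d2 < 0] <- 0
  cand <- which(d2 < .HB_DIST^2, arr.ind = TRUE)
  if (nrow(cand)) {
    di <- d_idx[cand[, 1]]; hi <- h_idx[cand[, 1]]; ai <- a_idx[cand[, 2]]
    same_res <- at$chain_id[di] == at$chain_id[ai] &
      at$residue_index[di] == at$residue_index[ai] &
      at$is_ligand[di] == at$is_ligand[ai] &
      at$molecule_id[di] == at$molecule_id[ai]
    self <- di == ai
    keep <- !same_res & !self
    di <- di[keep]; hi <- hi[keep]; ai <- ai[keep]
    cand <- cand[keep, , drop = FALSE]
    if (length(di)) {
      v1 <- coords[di, , drop = FALSE] - coords[hi, , drop = FALSE]
      v2 <- coords[ai, , drop = FALSE] - coords[hi, , drop = FALSE]
      cosang <- rowSums(v1 * v2) /
        (sqrt(rowSums(v1^2)) * sqrt(rowSums(v2^2)))
      cosang <- pmin(1, pmax(-1, cosang))
      ang <- acos(cosang) * 180 / pi
      dist <- sqrt(d2[cand])
      keep <- ang > .HB_ANGLE
      return(structure(data.frame(donor = di[keep], hydrogen = hi[keep],
                                  acceptor = ai[keep],
                                  distance = dist[keep],
                                  angle = ang[keep]), scope = scope))
    }
  }
  structure(data.frame(donor = integer(), hydrogen = integer(),
                       acceptor = integer(), distance = numeric(),
                       angle = numeric()), scope = scope)
}

#' Per-frame count of inter-peptide backbone hydrogen bonds
#'
#' Counts backbone-backbone triples whose donor and acceptor lie on
#' different protein chains (the fibril-integrity monitor).
#'
#' @param traj an `oligo_trajectory`.
#' @return data.frame(time, hbonds).
#' @export
backbone_hbond_count_series <- function(traj) {
  at <- traj$topology$atoms
  counts <- vapply(traj$coords, function(xyz) {
    hb <- detect_hbonds(xyz, traj$topology, scope = "backbone")
    sum(at$chain_id[hb$donor] != at$chain_id[hb$acceptor])
  }, numeric(1))
  data.frame(time = traj$times, hbonds = counts)
}

#' Residue-pair backbone H-bond map for one chain pair
#'
#' Accumulates backbone H-bond counts between residues of chains X and Y
#' (either donor direction) over the frame window, then normalizes so the
#' largest cell equals 1. An all-zero map is returned unnormalized with
#' attribute `normalized = FALSE`.
#'
#' @param traj an `oligo_trajectory`.
#' @param chain_pair character vector of two distinct chain ids, e.g.
#'   `c("A", "B")`.
#' @param frame_window integer frame indices (default all frames).
#' @return residues x residues matrix (rows: chain X, cols: chain Y) with
#'   attributes `chain_pair` and `normalized`; class `hbond_map`.
#' @export
hbond_map <- function(traj, chain_pair, frame_window = NULL) {
  if (length(chain_pair) != 2 || chain_pair[1] == chain_pair[2])
    stop("chain_pair must name two distinct chains (inter-chain maps only)")
  if (is.null(frame_window)) frame_window <- seq_len(n_frames(traj))
  top <- traj$topology
  at <- top$atoms
  nr <- top$residues_per_chain
  M <- matrix(0, nr, nr,
              dimnames = list(paste0(chain_pair[1], seq_len(nr)),
                              paste0(chain_pair[2], seq_len(nr))))
  for (f in frame_window) {
    hb <- detect_hbonds(traj$coords[[f]], top, scope = "backbone")
    if (!nrow(hb)) next
    dc <- at$chain_id[hb$donor]; ac <- at$chain_id[hb$acceptor]
    dr <- at$residue_index[hb$donor]; ar <- at$residue_index[hb$acceptor]
    fwd <- dc == chain_pair[1] & ac == chain_pair[2]
    rev_ <- dc == chain_pair[2] & ac == chain_pair[1]
    for (k in which(fwd)) M[dr[k], ar[k]] <- M[dr[k], ar[k]] + 1
    for (k in which(rev_)) M[ar[k], dr[k]] <- M[ar[k], dr[k]] + 1
  }
  mx <- max(M)
  normalized <- mx > 0
  if (normalized) M <- M / mx
  structure(M, chain_pair = chain_pair, normalized = normalized,
            class = c("hbond_map", "matrix"))
}

#' Occupancy of one specific hydrogen bond
#'
#' Fraction of window frames in which the given donor/acceptor atom pairing
#' is hydrogen-bonded (through any of the donor's hydrogens). Distinct
#' donor-acceptor atom pairs between the same residues are independent keys.
#'
#' @param traj an `oligo_trajectory`.
#' @param donor,acceptor each a `list(chain=, residue=, name=)` atom key;
#'   for ligand atoms use `list(molecule=, name=)`.
#' @param frame_window integer frame indices (default all).
#' @param scope passed to [detect_hbonds()].
#' @return fraction in [0, 1].
#' @export
hbond_occupancy <- function(traj, donor, acceptor, frame_window = NULL,
                            scope = "all") {
  if (is.null(frame_window)) frame_window <- seq_len(n_frames(traj))
  top <- traj$topology
  d <- .resolve_atom(top, donor)
  a <- .resolve_atom(top, acceptor)
  hits <- vapply(frame_window, function(f) {
    hb <- detect_hbonds(traj$coords[[f]], top, scope = scope)
    any(hb$donor == d & hb$acceptor == a)
  }, logical(1))
  mean(hits)
}

.resolve_atom <- function(top, key) {
  at <- top$atoms
  if (!is.null(key$molecule)) {
    idx <- which(at$is_ligand & at$molecule_id == key$molecule &
                   at$name == key$name)
  } else {
    idx <- which(!at$is_ligand & at$chain_id == key$chain &
                   at$residue_index == key$residue & at$name == key$name)
  }
  if (length(idx) != 1)
    stop("atom key does not resolve to exactly one atom: ",
         paste(unlist(key), collapse = ":"))
  idx
}

# ---- ligand contacts -------------------------------------------------------

#' Residues contacting a ligand molecule in one frame
#'
#' A residue is backbone-contacted if any of its backbone atoms lies
#' strictly within 3.5 A of any atom of the ligand molecule; sidechain
#' likewise. Protein heavy atoms only by default (`include_protein_h`
#' flips this); all ligand atoms always count.
#'
#' @param coords atoms x 3 coordinate matrix.
#' @param top topology.
#' @param molecule_id ligand molecule id.
#' @param include_protein_h include protein hydrogens in the distance test.
#' @return data.frame(chain, residue, backbone, sidechain, n_backbone,
#'   n_sidechain): contact flags plus atom-pair contact counts.
#' @export
ligand_contacts <- function(coords, top, molecule_id,
                            include_protein_h = FALSE) {
  at <- top$atoms
  lig <- which(at$is_ligand & at$molecule_id == molecule_id)
  if (!length(lig)) stop("no ligand with molecule_id ", molecule_id)
  prot <- which(!at$is_ligand)
  if (!include_protein_h) prot <- prot[at$element[prot] != "H"]
  P <- coords[prot, , drop = FALSE]
  L <- coords[lig, , drop = FALSE]
  d2 <- outer(rowSums(P^2), rowSums(L^2), "+") - 2 * P %*% t(L)
  n_contact <- rowSums(d2 < .CONTACT_DIST^2)
  bb <- backbone_mask(top)[prot]
  key <- paste(at$chain_id[prot], at$residue_index[prot])
  ukey <- unique(key)
  n_bb <- tapply(n_contact * bb, key, sum)[ukey]
  n_sc <- tapply(n_contact * !bb, key, sum)[ukey]
  parts <- do.call(rbind, strsplit(ukey, " "))
  data.frame(chain = parts[, 1], residue = as.integer(parts[, 2]),
             backbone = as.numeric(n_bb) > 0,
             sidechain = as.numeric(n_sc) > 0,
             n_backbone = as.numeric(n_bb), n_sidechain = as.numeric(n_sc),
             stringsAsFactors = FALSE)
}

#' Per-residue ligand contact probabilities and mean contact numbers
#'
#' Probability = fraction of window frames with at least one contact;
#' mean contact number = mean count of atom pairs within the cutoff,
#' reported separately for backbone and sidechain atoms. Residues whose
#' probability exceeds `probability_threshold` are flagged "important".
#'
#' @param traj an `oligo_trajectory`.
#' @param molecule_ids ligand molecule ids pooled into the profile.
#' @param frame_window integer frame indices (default all).
#' @param probability_threshold importance cutoff (default 0.1).
#' @param include_protein_h passed to [ligand_contacts()].
#' @return a `contact_profile`: data.frame(chain, residue, p_backbone,
#'   p_sidechain, n_backbone, n_sidechain, important_backbone,
#'   important_sidechain).
#' @export
contact_profile <- function(traj, molecule_ids, frame_window = NULL,
                            probability_threshold = 0.1,
                            include_protein_h = FALSE) {
  if (is.null(frame_window)) frame_window <- seq_len(n_frames(traj))
  if (!length(frame_window)) stop("empty frame window")
  acc <- NULL
  for (f in frame_window) {
    per_mol <- lapply(molecule_ids, function(m)
      ligand_contacts(traj$coords[[f]], traj$topology, m, include_protein_h))
    fr <- per_mol[[1]][, c("chain", "residue")]
    fr$bb <- Reduce(`|`, lapply(per_mol, `[[`, "backbone"))
    fr$sc <- Reduce(`|`, lapply(per_mol, `[[`, "sidechain"))
    fr$nbb <- Reduce(`+`, lapply(per_mol, `[[`, "n_backbone"))
    fr$nsc <- Reduce(`+`, lapply(per_mol, `[[`, "n_sidechain"))
    if (is.null(acc)) {
      acc <- fr
      acc$bb <- as.numeric(acc$bb); acc$sc <- as.numeric(acc$sc)
    } else {
      acc$bb <- acc$bb + fr$bb; acc$sc <- acc$sc + fr$sc
      acc$nbb <- acc$nbb + fr$nbb; acc$nsc <- acc$nsc + fr$nsc
    }
  }
  nf <- length(frame_window)
  out <- data.frame(chain = acc$chain, residue = acc$residue,
                    p_backbone = acc$bb / nf, p_sidechain = acc$sc / nf,
                    n_backbone = acc$nbb / nf, n_sidechain = acc$nsc / nf,
                    stringsAsFactors = FALSE)
  out$important_backbone <- out$p_backbone > probability_threshold
  out$important_sidechain <- out$p_sidechain > probability_threshold
  structure(out, threshold = probability_threshold,
            class = c("contact_profile", "data.frame"))
}

# ---- pi stacking -----------------------------------------------------------

#' Classify aromatic ring-ring stacking geometries
#'
#' For every pair (ring in `rings_a`, ring in `rings_b`) whose centroid
#' distance is at most 5.5 A, reports the interplanar angle (between
#' best-fit ring normals, folded to [0, 90] deg) and a geometry class:
#' parallel (< 30 deg), perpendicular (> 60 deg), else tilted.
#'
#' @param coords atoms x 3 coordinate matrix.
#' @param rings_a,rings_b named lists of integer atom-index vectors
#'   (>= 3 atoms each).
#' @param max_centroid_dist centroid distance cutoff in A.
#' @return data.frame(ring_a, ring_b, distance, angle, class).
#' @export
pi_stacking <- function(coords, rings_a, rings_b, max_centroid_dist = 5.5) {
  ring_geom <- function(idx) {
    if (length(idx) < 3) stop("a ring needs >= 3 atoms")
    x <- coords[idx, , drop = FALSE]
    ctr <- colMeans(x)
    n <- svd(sweep(x, 2, ctr))$v[, 3]
    list(ctr = ctr, normal = n)
  }
  ga <- lapply(rings_a, ring_geom)
  gb <- lapply(rings_b, ring_geom)
  out <- list()
  for (i in seq_along(ga)) for (j in seq_along(gb)) {
    d <- sqrt(sum((ga[[i]]$ctr - gb[[j]]$ctr)^2))
    if (d > max_centroid_dist) next
    cosang <- abs(sum(ga[[i]]$normal * gb[[j]]$normal))
    ang <- acos(pmin(1, cosang)) * 180 / pi
    cls <- if (ang < 30) "parallel" else if (ang > 60) "perpendicular" else
      "tilted"
    out[[length(out) + 1L]] <- data.frame(
      ring_a = names(ga)[i] %||% i, ring_b = names(gb)[j] %||% j,
      distance = d, angle = ang, class = cls, stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(ring_a = character(), ring_b = character(),
                      distance = numeric(), angle = numeric(),
                      class = character(), stringsAsFactors = FALSE))
  do.call(rbind, out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- interaction energy ----------------------------------------------------

#' CHARMM-style switching function
#'
#' S(r) = 1 for r <= r_on, 0 for r >= r_off, and the cubic switch
#' (r_off^2 - r^2)^2 (r_off^2 + 2 r^2 - 3 r_on^2) / (r_off^2 - r_on^2)^3
#' in between; S and dS/dr are continuous at both boundaries.
#'
#' @param r distances (A), vectorized.
#' @param r_on,r_off switching interval bounds (default 10 and 12 A).
#' @return switching factors in [0, 1].
#' @export
switching_function <- function(r, r_on = 10, r_off = 12) {
  s <- ifelse(r <= r_on, 1,
              ifelse(r >= r_off, 0,
                     (r_off^2 - r^2)^2 * (r_off^2 + 2 * r^2 - 3 * r_on^2) /
                       (r_off^2 - r_on^2)^3))
  s
}

#' Group-group nonbonded interaction-energy trace
#'
#' Pairwise Coulomb (332.0636 q_i q_j / r) plus 12-6 Lennard-Jones with
#' Lorentz-Berthelot combining (eps_ij = sqrt(eps_i eps_j),
#' rmin_ij = rmin_half_i + rmin_half_j), both multiplied by the
#' [switching_function()] so pairs beyond `r_off` contribute exactly zero.
#' No periodicity and no solvation term: a plugin-style group-group
#' vacuum energy.
#'
#' @param traj an `oligo_trajectory` whose topology carries `charge`,
#'   `lj_epsilon`, `lj_rmin_half` for every atom in both groups (or supply
#'   `params`, a data.frame(residue_name, name, charge, lj_epsilon,
#'   lj_rmin_half) overriding by residue+atom name).
#' @param group_a,group_b integer atom-index vectors.
#' @param frame_window integer frame indices (default all).
#' @param r_on,r_off switching interval (A).
#' @param params optional flat parameter table.
#' @return an `energy_trace` data.frame(frame, time, vdw, elec, total) with
#'   attributes `mean_total` and `sd_total` over the window.
#' @export
interaction_energy <- function(traj, group_a, group_b, frame_window = NULL,
                               r_on = 10, r_off = 12, params = NULL) {
  if (is.null(frame_window)) frame_window <- seq_len(n_frames(traj))
  at <- traj$topology$atoms
  q <- at$charge; eps <- at$lj_epsilon; rmh <- at$lj_rmin_half
  if (!is.null(params)) {
    key_top <- paste(at$residue_name, at$name)
    key_par <- paste(params$residue_name, params$name)
    hit <- match(key_top, key_par)
    q[!is.na(hit)] <- params$charge[hit[!is.na(hit)]]
    eps[!is.na(hit)] <- params$lj_epsilon[hit[!is.na(hit)]]
    rmh[!is.na(hit)] <- params$lj_rmin_half[hit[!is.na(hit)]]
  }
  both <- c(group_a, group_b)
  bad <- both[is.na(q[both]) | is.na(eps[both]) | is.na(rmh[both])]
  if (length(bad))
    stop("missing nonbonded parameters for atoms: ",
         paste(utils::head(paste0(at$chain_id[bad], ":",
                                  at$residue_index[bad], ":", at$name[bad]),
                           10), collapse = ", "))
  if (!length(group_a) || !length(group_b)) {
    tr <- data.frame(frame = frame_window,
                     time = traj$times[frame_window], vdw = 0, elec = 0,
                     total = 0)
    return(structure(tr, mean_total = 0, sd_total = 0,
                     class = c("energy_trace", "data.frame")))
  }
  qa <- q[group_a]; qb <- q[group_b]
  eij <- sqrt(eps[group_a] %o% eps[group_b])
  rmin <- outer(rmh[group_a], rmh[group_b], "+")
  qq <- qa %o% qb
  rows <- lapply(frame_window, function(f) {
    xyz <- traj$coords[[f]]
    A <- xyz[group_a, , drop = FALSE]; B <- xyz[group_b, , drop = FALSE]
    d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
    r <- sqrt(pmax(d2, 1e-12))
    s <- switching_function(r, r_on, r_off)
    elec <- sum(COULOMB_CONST * qq / r * s)
    sr6 <- (rmin / r)^6
    vdw <- sum(eij * (sr6^2 - 2 * sr6) * s)
    c(vdw = vdw, elec = elec)
  })
  m <- do.call(rbind, rows)
  tr <- data.frame(frame = frame_window, time = traj$times[frame_window],
                   vdw = m[, "vdw"], elec = m[, "elec"],
                   total = m[, "vdw"] + m[, "elec"])
  structure(tr, mean_total = mean(tr$total), sd_total = stats::sd(tr$total),
            class = c("energy_trace", "data.frame"))
}
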