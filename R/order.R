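# Global order and fluctuation metrics: nematic order parameter P2 over
# chain end-to-end vectors, Kabsch superposition and RMSD, chain-averaged
# per-residue RMSF, and radius of gyration.

#' Nematic order parameter P2 of one frame
#'
#' Each protein chain contributes a unit vector u_i linking the C-alpha of
#' its first residue to the C-alpha of its last residue. The ordering
#' tensor Q = (1/N) sum_i (3/2 u_i u_i' - 1/2 I) is diagonalized; the
#' director is the eigenvector with the largest eigenvalue and
#' P2 = (1/N) sum_i (3/2 (u_i . d)^2 - 1/2) equals that eigenvalue.
#' With the eigen-director, P2 lies in [0, 1]: 1 for perfect alignment,
#' small for isotropic orientations.
#'
#' @param coords atoms x 3 coordinate matrix of one frame.
#' @param top the `oligo_topology`.
#' @return a `director_result`: list(p2, director, chain_vectors, n_chains).
#' @export
nematic_p2 <- function(coords, top) {
  at <- top$atoms
  nr <- top$residues_per_chain
  u <- t(vapply(top$chains, function(ch) {
    first <- which(at$chain_id == ch & at$residue_index == 1 &
                     at$name == "CA" & !at$is_ligand)
    last <- which(at$chain_id == ch & at$residue_index == nr &
                    at$name == "CA" & !at$is_ligand)
    if (length(first) != 1 || length(last) != 1)
      stop("chain ", ch, ": missing terminal C-alpha atom(s)")
    v <- coords[last, ] - coords[first, ]
    v / sqrt(sum(v^2))
  }, numeric(3)))
  N <- nrow(u)
  Q <- matrix(0, 3, 3)
  for (i in seq_len(N)) Q <- Q + 1.5 * (u[i, ] %o% u[i, ]) - 0.5 * diag(3)
  Q <- Q / N
  e <- eigen(Q, symmetric = TRUE)
  k <- which.max(e$values)
  d <- e$vectors[, k]
  structure(list(p2 = e$values[k], director = d / sqrt(sum(d^2)),
                 chain_vectors = u, n_chains = N),
            class = "director_result")
}

#' @export
print.director_result <- function(x, ...) {
  cat(sprintf("P2 = %.4f over %d chains; director = (%.3f, %.3f, %.3f)\n",
              x$p2, x$n_chains, x$director[1], x$director[2], x$director[3]))
  invisible(x)
}

#' P2 series for every frame of a trajectory
#'
#' @param traj an `oligo_trajectory`.
#' @return data.frame(time, p2).
#' @export
p2_series <- function(traj) {
  data.frame(time = traj$times,
             p2 = vapply(traj$coords, function(xyz)
               nematic_p2(xyz, traj$topology)$p2, numeric(1)))
}

#' Classify a P2 series as ordered or disordered
#'
#' The system is called "ordered" iff the mean P2 strictly exceeds 0.5
#' (the conventional nematic cutoff for fibril-like peptide assemblies);
#' a mean of exactly 0.5 is "disordered".
#'
#' @param p2_series numeric vector of per-frame P2 values.
#' @return list(label, mean, sd).
#' @export
classify_order <- function(p2_series) {
  if (!length(p2_series)) stop("empty P2 series")
  m <- mean(p2_series)
  list(label = if (m > 0.5) "ordered" else "disordered",
       mean = m, sd = stats::sd(p2_series))
}

#' Optimal rigid-body superposition (Kabsch)
#'
#' Least-squares fits `mobile` onto `reference` over the given atom
#' selection (rotation + translation, reflections excluded) and returns the
#' transformed coordinates with the minimized RMSD over the selection.
#'
#' @param mobile,reference atoms x 3 coordinate matrices.
#' @param selection integer atom indices used for the fit (>= 3).
#' @return list(coords, rmsd, rotation, translation).
#' @export
superpose <- function(mobile, reference, selection) {
  if (length(selection) < 3)
    stop("superposition needs >= 3 atoms in the selection")
  A <- mobile[selection, , drop = FALSE]
  B <- reference[selection, , drop = FALSE]
  ca <- colMeans(A); cb <- colMeans(B)
  H <- t(sweep(A, 2, ca)) %*% sweep(B, 2, cb)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  out <- sweep(sweep(mobile, 2, ca) %*% t(R), 2, cb, "+")
  rmsd <- sqrt(mean(rowSums((out[selection, , drop = FALSE] - B)^2)))
  list(coords = out, rmsd = rmsd, rotation = R,
       translation = cb - as.vector(R %*% ca))
}

#' Superpose every frame of a trajectory onto a reference frame
#'
#' @param traj an `oligo_trajectory`.
#' @param selection atom indices for the fit; default all protein C-alpha.
#' @param ref_frame reference frame index (default 1).
#' @return the trajectory with fitted coordinates and `superposed = TRUE`.
#' @export
superpose_trajectory <- function(traj, selection = NULL, ref_frame = 1) {
  if (is.null(selection)) selection <- select_atoms(traj$topology, "calpha")
  ref <- traj$coords[[ref_frame]]
  traj$coords <- lapply(traj$coords, function(xyz)
    superpose(xyz, ref, selection)$coords)
  traj$superposed <- TRUE
  traj
}

#' Per-frame RMSD to a reference frame after superposition
#'
#' @param traj an `oligo_trajectory`.
#' @param selection atom indices (default all protein C-alpha).
#' @param ref_frame reference frame index.
#' @return data.frame(time, rmsd) in Angstrom.
#' @export
rmsd_series <- function(traj, selection = NULL, ref_frame = 1) {
  if (is.null(selection)) selection <- select_atoms(traj$topology, "calpha")
  ref <- traj$coords[[ref_frame]]
  data.frame(time = traj$times,
             rmsd = vapply(traj$coords, function(xyz)
               superpose(xyz, ref, selection)$rmsd, numeric(1)))
}

#' Chain-averaged per-residue C-alpha RMSF
#'
#' Per-atom root-mean-square fluctuation about the time-mean position,
#' averaged across chains at equal residue index. The trajectory must have
#' been superposed first ([superpose_trajectory()]); fluctuations without
#' removal of rigid-body motion are meaningless and are refused.
#'
#' @param traj a superposed `oligo_trajectory` with >= 2 frames.
#' @param from_frame first frame of the analysis window (equilibrated part).
#' @return data.frame(residue, rmsf) of length `residues_per_chain`, in A.
#' @export
rmsf_per_residue <- function(traj, from_frame = 1) {
  if (!isTRUE(traj$superposed))
    stop("trajectory is not superposed; call superpose_trajectory() first")
  frames <- from_frame:n_frames(traj)
  if (length(frames) < 2) stop("RMSF needs >= 2 frames in the window")
  top <- traj$topology
  ca <- select_atoms(top, "calpha")
  X <- simplify2array(lapply(traj$coords[frames],
                             function(xyz) xyz[ca, , drop = FALSE]))
  mean_pos <- apply(X, c(1, 2), mean)
  dev2 <- apply(sweep(X, c(1, 2), mean_pos)^2, c(1, 3), sum)
  rmsf_atom <- sqrt(rowMeans(dev2))
  res <- top$atoms$residue_index[ca]
  agg <- tapply(rmsf_atom, res, mean)
  data.frame(residue = as.integer(names(agg)), rmsf = as.numeric(agg))
}

#' Radius of gyration
#'
#' sqrt(sum(w_i |r_i - rbar|^2) / sum(w_i)); weights are atomic masses if
#' `mass_weighted`, else 1.
#'
#' @param coords atoms x 3 coordinate matrix.
#' @param top the topology.
#' @param selection atom indices (default all protein atoms).
#' @param mass_weighted logical.
#' @return Rg in Angstrom.
#' @export
radius_of_gyration <- function(coords, top, selection = NULL,
                               mass_weighted = FALSE) {
  if (is.null(selection)) selection <- select_atoms(top, "protein")
  if (!length(selection)) stop("empty selection")
  x <- coords[selection, , drop = FALSE]
  w <- if (mass_weighted) top$atoms$mass[selection] else
    rep(1, length(selection))
  ctr <- colSums(x * w) / sum(w)
  sqrt(sum(w * rowSums(sweep(x, 2, ctr)^2)) / sum(w))
}

#' Rg series over a trajectory
#'
#' @inheritParams radius_of_gyration
#' @param traj an `oligo_trajectory`.
#' @return data.frame(time, rg) in Angstrom.
#' @export
rg_series <- function(traj, selection = NULL, mass_weighted = FALSE) {
  data.frame(time = traj$times,
             rg = vapply(traj$coords, function(xyz)
               radius_of_gyration(xyz, traj$topology, selection,
                                  mass_weighted), numeric(1)))
}
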