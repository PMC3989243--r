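# Rigid ligand template and surface placement.
#
# The default template is a three-ring polyphenol caricature (two
# hydroxylated six-membered rings plus an ester-linked third ring), flat in
# its local xy-plane, with hydroxyl donors and carbonyl/ester acceptors.
# It is NOT a parameterized real molecule; real ligand coordinates and
# charges can be supplied as a custom template.

.hexagon <- function(center, r = 1.4, phase = 0) {
  ang <- phase + seq(0, by = pi / 3, length.out = 6)
  cbind(center[1] + r * cos(ang), center[2] + r * sin(ang), 0)
}

#' Default rigid polyphenol-like ligand template
#'
#' @param resname 3-letter residue name used for the ligand atoms.
#' @param rings number of six-membered rings (1, 2 or 3). The full 3-ring
#'   caricature is the default; smaller variants give molecules of smaller
#'   surface footprint (useful for constructing binding sites of known
#'   decreasing contact density).
#' @return a `ligand_template`: list with `atoms` (name, element, charge,
#'   lj_epsilon, lj_rmin_half), `coords`, `h_parent` (within-template row
#'   indices) and `rings` (named list of ring atom-name sets, usable with
#'   [pi_stacking()]).
#' @export
default_ligand_template <- function(resname = "EGC", rings = 3) {
  stopifnot(rings %in% 1:3)
  nm <- character(); el <- character(); q <- numeric()
  eps <- numeric(); rmh <- numeric(); xyz <- NULL; hp <- integer()
  add <- function(name, element, charge, e, r, coord, parent = NA_integer_) {
    nm <<- c(nm, name); el <<- c(el, element); q <<- c(q, charge)
    eps <<- c(eps, e); rmh <<- c(rmh, r)
    xyz <<- rbind(xyz, coord); hp <<- c(hp, parent)
    length(nm)
  }
  add_ring <- function(center, tag, phase = 0) {
    h <- .hexagon(center, phase = phase)
    vapply(1:6, function(i)
      add(paste0("C", tag, i), "C", 0, 0.12, 1.10, h[i, ]), integer(1))
  }
  add_oh <- function(ring_idx, otag, center) {
    cpos <- xyz[ring_idx, ]
    dir_ <- cpos - c(center, 0)          # radially outward from ring center
    dir_ <- dir_ / sqrt(sum(dir_^2))
    o <- add(paste0("O", otag), "O", 0, 0.12, 1.00, cpos + 1.36 * dir_)
        add(paste0("HO", otag), "H", 0, 0.046, 0.2245,
        xyz[o, ] + 0.97 * dir_, parent = o)
  }
  ctrA <- c(0, 0); ctrB <- c(3.6, 0); ctrG <- c(1.8, 3.8)
  ring_names <- list(A = paste0("CA", 1:6))
  rA <- add_ring(ctrA, "A")                      # trihydroxyphenyl-like
  add_oh(rA[1], "1", ctrA); add_oh(rA[3], "2", ctrA); add_oh(rA[5], "3", ctrA)
  if (rings >= 2) {
    rB <- add_ring(ctrB, "B", phase = pi / 6)    # chromane-like ring
    add_oh(rB[2], "4", ctrB)
    ring_names$B <- paste0("CB", 1:6)
  }
  if (rings >= 3) {
    rG <- add_ring(ctrG, "G", phase = pi / 6)    # gallate-like ring
    add_oh(rG[3], "5", ctrG); add_oh(rG[5], "6", ctrG)
    # ester link: carbonyl O (acceptor, no H) + bridging O
    cB <- xyz[rG[1], ]
    add("OE1", "O", 0, 0.12, 1.00, cB + c(0.0, -1.3, 0.4))
    add("OE2", "O", 0, 0.12, 1.00, cB + c(1.0, -1.0, -0.4))
    ring_names$G <- paste0("CG", 1:6)
  }
  atoms <- data.frame(name = nm, element = el, charge = q,
                      lj_epsilon = eps, lj_rmin_half = rmh,
                      stringsAsFactors = FALSE)
  structure(list(atoms = atoms, coords = xyz, h_parent = hp,
                 resname = resname,
                 rings = ring_names),
            class = "ligand_template")
}

#' Describe where and how to place rigid ligand copies
#'
#' @param template a `ligand_template`.
#' @param site list of anchor residues, each `list(chain=, residue=)`, or
#'   `NULL` for free-floating (diffusing) copies re-positioned randomly
#'   around the protein every frame.
#' @param offset target distance (A) of the ligand centroid from the anchor
#'   atom centroid, along the outward normal from the protein centroid.
#' @param n_copies number of rigid copies to insert.
#' @param tilt docking tilt in degrees between the ligand ring-plane normal
#'   and the outward surface normal, or `NULL` (default) for a random
#'   orientation. `tilt = 0` lays the rings flat against the surface
#'   (maximal contact density), `tilt = 90` docks them edge-on (minimal);
#'   this is the generator's lever for building sites of known decreasing
#'   contact density.
#' @export
ligand_placement <- function(template = default_ligand_template(),
                             site = NULL, offset = 4.5, n_copies = 1,
                             tilt = NULL) {
  at <- template$atoms
  has_donor <- any(at$element == "H" & !is.na(template$h_parent))
  has_acceptor <- any(at$element %in% c("N", "O"))
  if (!has_donor || !has_acceptor)
    stop("ligand template needs >= 1 donor-capable and >= 1 acceptor atom")
  if (!is.null(tilt) && (tilt < 0 || tilt > 90))
    stop("tilt must be in [0, 90] degrees")
  structure(list(template = template, site = site, offset = offset,
                 n_copies = as.integer(n_copies), tilt = tilt),
            class = "ligand_placement")
}

.append_ligand_topology <- function(top, template, n_copies, resname) {
  at <- top$atoms
  next_serial <- max(at$serial)
  next_mol <- if (any(at$is_ligand)) max(at$molecule_id) else 0L
  next_res <- if (any(at$is_ligand))
    max(at$residue_index[at$is_ligand]) else 0L
  nt <- nrow(template$atoms)
  new_rows <- do.call(rbind, lapply(seq_len(n_copies), function(k) {
    data.frame(serial = next_serial + (k - 1) * nt + seq_len(nt),
               name = template$atoms$name,
               element = template$atoms$element,
               chain_id = "X", residue_index = next_res + k,
               residue_name = resname, is_ligand = TRUE,
               molecule_id = next_mol + k,
               mass = unname(.ELEMENT_MASS[template$atoms$element]),
               charge = template$atoms$charge,
               lj_epsilon = template$atoms$lj_epsilon,
               lj_rmin_half = template$atoms$lj_rmin_half,
               stringsAsFactors = FALSE)
  }))
  new_hp <- unlist(lapply(seq_len(n_copies), function(k)
    ifelse(is.na(template$h_parent), NA_integer_,
           nrow(at) + (k - 1) * nt + template$h_parent)))
  topology(rbind(at, new_rows), c(top$h_parent, new_hp),
           residues_per_chain = top$residues_per_chain)
}

#' Insert rigid ligand copies into every frame of a trajectory
#'
#' Anchored copies are docked once, in the first frame, against a heavy
#' atom of the anchor residues along the local outward surface normal,
#' with a random rigid orientation, subject to: minimum 2.5 A from any
#' protein atom, within 3.5 A of at least one anchor-residue atom, and no
#' two copies closer than 2.5 A. In later frames the pose rides along with
#' the anchor chain's rigid motion (Kabsch transform of that chain from
#' frame 1), sliding outward if the perturbed protein clashes; if the
#' carried pose breaks the constraints it is re-docked for that frame.
#' Docking is retried with fresh orientations up to `max_tries` times;
#' infeasible placement is an error naming the site. Free-floating copies
#' (`site = NULL`) are scattered on a distant shell independently every
#' frame (diffusing, never in persistent contact).
#'
#' @param traj an `oligo_trajectory` (protein only or with prior ligands).
#' @param placement a [ligand_placement()].
#' @param seed RNG seed for orientations and placement jitter.
#' @param max_tries placement attempts per copy per frame.
#' @return a new `oligo_trajectory` including the ligand atoms.
#' @export
place_ligands <- function(traj, placement, seed = 1, max_tries = 400) {
  if (placement$n_copies == 0) return(traj)
  top <- traj$topology
  at <- top$atoms
  prot <- which(!at$is_ligand)
  tmpl <- placement$template
  tmpl_xyz <- sweep(tmpl$coords, 2, colMeans(tmpl$coords))
  anchor_rows <- NULL
  if (!is.null(placement$site)) {
    anchor_rows <- unlist(lapply(placement$site, function(s) {
      rows <- which(at$chain_id == s$chain & at$residue_index == s$residue &
                      !at$is_ligand)
      if (!length(rows))
        stop("anchor residue ", s$chain, ":", s$residue,
             " does not exist in the topology")
      rows
    }))
  }
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)

  new_top <- .append_ligand_topology(top, tmpl, placement$n_copies,
                                     tmpl$resname)
  nt <- nrow(tmpl$atoms)
  site_label <- if (is.null(placement$site)) "free" else
    paste(vapply(placement$site, function(s)
      paste0(s$chain, ":", s$residue), character(1)), collapse = ",")

  # outward surface normal at the anchors: smallest principal component of
  # the local protein patch, signed toward the emptier side
  local_normal <- function(prot_xyz, anc_ctr) {
    near <- which(sqrt(rowSums(sweep(prot_xyz, 2, anc_ctr)^2)) < 8)
    patch <- prot_xyz[near, , drop = FALSE]
    out_dir <- svd(sweep(patch, 2, colMeans(patch)))$v[, 3]
    crowd <- function(dir_) {
      rel <- sweep(prot_xyz, 2, anc_ctr)
      proj <- as.vector(rel %*% dir_)
      sum(proj > 1 & proj <= 12 & rowSums(rel^2) - proj^2 < 36)
    }
    if (crowd(-out_dir) < crowd(out_dir)) -out_dir else out_dir
  }
  anchor_heavy <- anchor_rows[at$element[anchor_rows] != "H"]
  constraints_ok <- function(lig, prot_xyz, anchors_xyz, placed,
                             existing_lig) {
    if (.min_cross_dist(lig, prot_xyz) < 2.5) return(FALSE)
    if (!is.null(anchors_xyz) &&
        .min_cross_dist(lig, anchors_xyz) > 3.45) return(FALSE)
    for (p in placed) if (.min_cross_dist(lig, p) < 2.5) return(FALSE)
    if (!is.null(existing_lig) &&
        .min_cross_dist(lig, existing_lig) < 2.5) return(FALSE)
    TRUE
  }
  # dock with a fresh random orientation: inward-most ligand atom placed
  # 2.8 A out from a random heavy anchor atom, then slid clear of clashes
  dock_once <- function(xyz, prot_xyz, placed, existing_lig) {
    out_dir <- local_normal(prot_xyz,
                            colMeans(xyz[anchor_rows, , drop = FALSE]))
    for (try_i in seq_len(max_tries)) {
      if (is.null(placement$tilt)) {
        R <- .rot_matrix(stats::rnorm(3), stats::runif(1, 0, 2 * pi))
      } else {
        # random spin about the ring normal, then set the normal at the
        # requested tilt from the outward surface normal
        spin <- .rot_matrix(c(0, 0, 1), stats::runif(1, 0, 2 * pi))
        perp <- stats::rnorm(3)
        perp <- perp - sum(perp * out_dir) * out_dir
        if (sqrt(sum(perp^2)) < 1e-6) perp <- c(0, 1, 0) -
            sum(c(0, 1, 0) * out_dir) * out_dir
        perp <- perp / sqrt(sum(perp^2))
        target_n <- cos(placement$tilt * pi / 180) * out_dir +
          sin(placement$tilt * pi / 180) * perp
        axis <- .cross3(c(0, 0, 1), target_n)
        ang <- acos(max(-1, min(1, target_n[3])))
        R <- if (sqrt(sum(axis^2)) < 1e-9) diag(3) else
          .rot_matrix(axis, ang)
        R <- R %*% spin
      }
      lig <- tmpl_xyz %*% t(R)
      li <- which.min(lig %*% out_dir)  # inward-most atom leads the dock
      ai <- anchor_heavy[sample.int(length(anchor_heavy), 1)]
      lig <- sweep(lig, 2, xyz[ai, ] + 2.8 * out_dir - lig[li, ], "+")
      for (push in 1:10) {
        dmin <- .min_cross_dist(lig, prot_xyz)
        if (dmin >= 2.5) break
        lig <- sweep(lig, 2, (2.55 - dmin) * out_dir, "+")
      }
      if (constraints_ok(lig, prot_xyz, xyz[anchor_heavy, , drop = FALSE],
                         placed, existing_lig))
        return(list(lig = lig, out_dir = out_dir))
    }
    stop("ligand placement infeasible at site [", site_label,
         "] after ", max_tries, " tries")
  }
  place_free <- function(prot_xyz, placed, existing_lig) {
    prot_ctr <- colMeans(prot_xyz)
    shell <- max(sqrt(rowSums(sweep(prot_xyz, 2, prot_ctr)^2)))
    for (try_i in seq_len(max_tries)) {
      R <- .rot_matrix(stats::rnorm(3), stats::runif(1, 0, 2 * pi))
      u <- stats::rnorm(3); u <- u / sqrt(sum(u^2))
      lig <- sweep(tmpl_xyz %*% t(R), 2,
                   prot_ctr + (shell + stats::runif(1, 8, 25)) * u, "+")
      if (constraints_ok(lig, prot_xyz, NULL, placed, existing_lig))
        return(lig)
    }
    stop("ligand placement infeasible at site [free] after ", max_tries,
         " tries")
  }

  anchor_chain_rows <- if (!is.null(placement$site))
    which(at$chain_id == at$chain_id[anchor_rows[1]] & !at$is_ligand)
  ref_xyz <- traj$coords[[1]]
  poses <- vector("list", placement$n_copies)  # frame-1 poses (anchored)

  new_coords <- vector("list", length(traj$coords))
  for (f in seq_along(traj$coords)) {
    xyz <- traj$coords[[f]]
    prot_xyz <- xyz[prot, , drop = FALSE]
    existing_lig <- if (nrow(xyz) > length(prot))
      xyz[-prot, , drop = FALSE] else NULL
    placed <- list()
    for (k in seq_len(placement$n_copies)) {
      if (is.null(placement$site)) {
        lig <- place_free(prot_xyz, placed, existing_lig)
      } else if (f == 1) {
        dock <- dock_once(xyz, prot_xyz, placed, existing_lig)
        poses[[k]] <- dock
        lig <- dock$lig
      } else {
        # carry the frame-1 pose along with the anchor chain's rigid motion
        fit <- superpose(ref_xyz, xyz, anchor_chain_rows)
        lig <- sweep(poses[[k]]$lig %*% t(fit$rotation), 2,
                     fit$translation, "+")
        out_dir <- as.vector(fit$rotation %*% poses[[k]]$out_dir)
        for (push in 1:10) {
          dmin <- .min_cross_dist(lig, prot_xyz)
          if (dmin >= 2.5) break
          lig <- sweep(lig, 2, (2.55 - dmin) * out_dir, "+")
        }
        if (!constraints_ok(lig, prot_xyz,
                            xyz[anchor_heavy, , drop = FALSE], placed,
                            existing_lig))
          lig <- dock_once(xyz, prot_xyz, placed, existing_lig)$lig
      }
      placed[[k]] <- lig
    }
    new_coords[[f]] <- rbind(xyz, do.call(rbind, placed))
  }
  out <- trajectory(new_top, new_coords, times = traj$times)
  attr(out, "ground_truth") <- attr(traj, "ground_truth")
  out
}

# minimum distance between two coordinate sets
.min_cross_dist <- function(a, b) {
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * a %*% t(b)
  sqrt(max(0, min(d2)))
}

.cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}
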