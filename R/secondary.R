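# Hydrogen-bond-ladder secondary-structure assignment ("STRIDE-like": same
# six-letter alphabet, but topology rules over a geometric H-bond criterion
# rather than STRIDE's unpublished dihedral propensity energies) and
# beta-content accounting.

.SS_ALPHABET <- c("H", "G", "E", "B", "T", "C")

#' Assign per-residue secondary structure for one frame
#'
#' Rules, applied with priority H > G > E > B > T > C:
#' \itemize{
#'   \item H: part of >= 2 consecutive i -> i+4 backbone H-bonds
#'     (O(i) accepting from N(i+4), same chain).
#'   \item G: analogous with i -> i+3.
#'   \item E: participates in an inter-strand backbone H-bond bridge that is
#'     part of a ladder (two consecutive bridge residues with partners on
#'     the same chain one apart). Bridges are H-bonds between residues of
#'     different chains, or of the same chain at sequence separation >= 5.
#'   \item B: an isolated single bridge.
#'   \item T: within the span of a single i -> i+3 / i -> i+4 H-bond turn,
#'     or backbone reversal (C-alpha(i) to C-alpha(i+3) < 7 A, either
#'     direction), without a helix/strand label.
#'   \item C: otherwise. Residues missing backbone atoms are labeled C with
#'     a warning.
#' }
#'
#' @param coords atoms x 3 coordinate matrix.
#' @param top topology.
#' @param hbonds backbone H-bond table from
#'   [detect_hbonds()]`(coords, top, scope = "backbone")`; detected
#'   on the fly when `NULL`.
#' @return character matrix chains x residues of labels.
#' @export
assign_secondary_structure <- function(coords, top, hbonds = NULL) {
  if (is.null(hbonds)) hbonds <- detect_hbonds(coords, top, "backbone")
  at <- top$atoms
  chains <- top$chains
  nr <- top$residues_per_chain
  nc <- length(chains)
  lab <- matrix("C", nc, nr, dimnames = list(chains, NULL))

  # warn-and-coil for residues missing backbone atoms
  prot <- !at$is_ligand & at$name %in% c("N", "CA", "C", "O")
  bb_count <- table(factor(at$chain_id[prot], levels = chains),
                    factor(at$residue_index[prot], levels = seq_len(nr)))
  if (any(bb_count < 4)) {
    bad <- which(bb_count < 4, arr.ind = TRUE)
    warning(nrow(bad), " residue(s) missing backbone atoms; labeled C ",
            "(first: chain ", chains[bad[1, 1]], " residue ", bad[1, 2], ")")
  }

  dch <- match(at$chain_id[hbonds$donor], chains)
  ach <- match(at$chain_id[hbonds$acceptor], chains)
  dres <- at$residue_index[hbonds$donor]
  ares <- at$residue_index[hbonds$acceptor]

  # --- helices: O(i) <- N(i+4) (alpha) and O(i) <- N(i+3) (3-10)
  nturn_of <- function(sep) {
    nt <- matrix(FALSE, nc, nr)  # nt[c, i]: O(i) accepts from N(i+sep)
    sel <- which(dch == ach & dres == ares + sep)
    for (k in sel) nt[ach[k], ares[k]] <- TRUE
    nt
  }
  turn4 <- nturn_of(4)
  turn3 <- nturn_of(3)
  for (hx in list(list(nt = turn4, sep = 4, letter = "H"),
                  list(nt = turn3, sep = 3, letter = "G"))) {
    for (ci in seq_len(nc)) {
      for (i in seq_len(max(0, nr - hx$sep - 1))) {
        if (hx$nt[ci, i] && hx$nt[ci, i + 1]) {
          span <- (i + 1):(i + hx$sep)
          lab[ci, span][lab[ci, span] == "C"] <- hx$letter
        }
      }
    }
  }

  # --- bridges and ladders
  is_bridge <- dch != ach | abs(dres - ares) >= 5
  br <- unique(data.frame(c1 = pmin(dch, ach),
                          r1 = ifelse(dch <= ach, dres, ares),
                          c2 = pmax(dch, ach),
                          r2 = ifelse(dch <= ach, ares, dres))[is_bridge, ])
  if (nrow(br)) {
    br_key <- paste(br$c1, br$r1, br$c2, br$r2)
    in_ladder <- rep(FALSE, nrow(br))
    for (k in seq_len(nrow(br))) {
      for (s1 in c(-1, 1)) for (s2 in c(-1, 1)) {
        nb <- paste(br$c1[k], br$r1[k] + s1, br$c2[k], br$r2[k] + s2)
        if (nb %in% br_key) in_ladder[k] <- TRUE
      }
    }
    for (k in seq_len(nrow(br))) {
      letter <- if (in_ladder[k]) "E" else "B"
      for (side in list(c(br$c1[k], br$r1[k]), c(br$c2[k], br$r2[k]))) {
        cur <- lab[side[1], side[2]]
        if (cur %in% c("C", "T") ||
            (letter == "E" && cur == "B"))
          lab[side[1], side[2]] <- letter
      }
    }
  }

  # --- turns: single H-bond turn spans and backbone reversal
  ca_rows <- which(at$name == "CA" & !at$is_ligand)
  ca_idx <- matrix(NA_integer_, nc, nr)
  ca_idx[cbind(match(at$chain_id[ca_rows], chains),
               at$residue_index[ca_rows])] <- ca_rows
  for (ci in seq_len(nc)) {
    turn_flag <- rep(FALSE, nr)
    for (i in seq_len(nr)) {
      if (i + 4 <= nr && turn4[ci, i]) turn_flag[i:(i + 4)] <- TRUE
      if (i + 3 <= nr && turn3[ci, i]) turn_flag[i:(i + 3)] <- TRUE
    }
    # backbone reversal: C-alpha(j) to C-alpha(j+3) < 7 A marks j..j+3
    if (nr >= 4) {
      a <- ca_idx[ci, 1:(nr - 3)]; b <- ca_idx[ci, 4:nr]
      okpair <- !is.na(a) & !is.na(b)
      d3 <- rep(Inf, nr - 3)
      d3[okpair] <- sqrt(rowSums((coords[a[okpair], , drop = FALSE] -
                                    coords[b[okpair], , drop = FALSE])^2))
      for (j in which(d3 < 7)) turn_flag[j:(j + 3)] <- TRUE
    }
    lab[ci, turn_flag & lab[ci, ] == "C"] <- "T"
  }
  lab
}

#' Secondary-structure assignment over a trajectory
#'
#' @param traj an `oligo_trajectory`.
#' @param frame_window integer frame indices (default all).
#' @return an `ss_assignment`: list of per-frame chains x residues label
#'   matrices, plus `times`.
#' @export
assign_ss_trajectory <- function(traj, frame_window = NULL) {
  if (is.null(frame_window)) frame_window <- seq_len(n_frames(traj))
  labels <- lapply(frame_window, function(f)
    assign_secondary_structure(traj$coords[[f]], traj$topology))
  structure(list(labels = labels, times = traj$times[frame_window],
                 frames = frame_window),
            class = "ss_assignment")
}

#' Beta-sheet content per frame
#'
#' Per-frame fraction of residues in beta structure: (#E + #B) divided by
#' the total residue count (chains x residues per chain). Set
#' `include_bridges = FALSE` to count extended (E) residues only.
#'
#' @param assignment an `ss_assignment` from [assign_ss_trajectory()].
#' @param include_bridges count isolated bridges (B) as beta.
#' @return list(series = data.frame(time, beta), mean, sd).
#' @export
beta_content <- function(assignment, include_bridges = TRUE) {
  beta_set <- if (include_bridges) c("E", "B") else "E"
  frac <- vapply(assignment$labels, function(m)
    sum(m %in% beta_set) / length(m), numeric(1))
  list(series = data.frame(time = assignment$times, beta = frac),
       mean = mean(frac), sd = stats::sd(frac))
}

#' Secondary-structure content fractions
#'
#' Time-averaged fractions of coil (C), turn (T), beta (E + B) and helix
#' (H + G); the four classes partition all residues, so they sum to 1.
#'
#' @param assignment an `ss_assignment`.
#' @return list(coil, turn, beta, helix, per_frame) with means, sds and the
#'   per-frame series.
#' @export
ss_content <- function(assignment) {
  classes <- list(coil = "C", turn = "T", beta = c("E", "B"),
                  helix = c("H", "G"))
  per <- lapply(classes, function(set)
    vapply(assignment$labels, function(m) sum(m %in% set) / length(m),
           numeric(1)))
  out <- lapply(per, function(x) c(mean = mean(x), sd = stats::sd(x)))
  out$per_frame <- data.frame(time = assignment$times,
                              coil = per$coil, turn = per$turn,
                              beta = per$beta, helix = per$helix)
  out
}

#' Long-format per-residue secondary-structure timeline
#'
#' One row per (frame, chain, residue), suitable for raster plotting of the
#' label evolution.
#'
#' @param assignment an `ss_assignment`.
#' @return data.frame(time, chain, residue, label).
#' @export
ss_timeline <- function(assignment) {
  do.call(rbind, lapply(seq_along(assignment$labels), function(k) {
    m <- assignment$labels[[k]]
    data.frame(time = assignment$times[k],
               chain = rep(rownames(m), ncol(m)),
               residue = rep(seq_len(ncol(m)), each = nrow(m)),
               label = as.vector(m), stringsAsFactors = FALSE)
  }))
}
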