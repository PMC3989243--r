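# Study orchestration: run configuration, binding-site discovery from
# contact persistence, and the full report bundle.

#' Configuration for a full analysis run
#'
#' @param traj input `oligo_trajectory`, or a multi-model PDB path.
#' @param ligand_resnames ligand residue names (used when `traj` is a path).
#' @param equilibrated_from start of the analysis window as a fraction of
#'   the trajectory (0.5 = last half, the convention for converged MD) or
#'   an integer frame index.
#' @param temperature Kelvin for the FEL.
#' @param bins FEL bin counts (nx, ny).
#' @param cluster_k cluster count for the conformational clustering.
#' @param seed top-level seed; stage seeds are split from it
#'   deterministically (seed + fixed offsets).
#' @param p2_cutoff ordered/disordered boundary on mean P2.
#' @param contact_importance contact-probability threshold for "important"
#'   residues.
#' @param persistence_fraction site-forming persistence threshold.
#' @param out_dir output directory for the report bundle.
#' @return a validated `run_config`.
#' @export
run_config <- function(traj, ligand_resnames = character(),
                       equilibrated_from = 0.5, temperature = 310,
                       bins = c(40, 40), cluster_k = 3, seed = 1,
                       p2_cutoff = 0.5, contact_importance = 0.1,
                       persistence_fraction = 0.5,
                       out_dir = tempfile("oligotraj_run")) {
  if (is.character(traj)) traj <- read_multimodel_pdb(traj, ligand_resnames)
  nf <- n_frames(traj)
  if (equilibrated_from >= 1) {
    from <- as.integer(equilibrated_from)
    if (from > nf)
      stop("equilibrated window starts at frame ", from,
           " but the trajectory has only ", nf, " frames")
  } else {
    from <- max(1L, as.integer(floor(nf * equilibrated_from)) + 1L)
  }
  stopifnot(temperature > 0, all(bins >= 1), cluster_k >= 1,
            p2_cutoff > 0, contact_importance > 0,
            persistence_fraction > 0, persistence_fraction <= 1)
  structure(list(traj = traj, from_frame = from, temperature = temperature,
                 bins = bins, cluster_k = cluster_k, seed = as.integer(seed),
                 p2_cutoff = p2_cutoff,
                 contact_importance = contact_importance,
                 persistence_fraction = persistence_fraction,
                 out_dir = out_dir),
            class = "run_config")
}

.jaccard <- function(a, b) {
  u <- length(union(a, b))
  if (u == 0) return(0)
  length(intersect(a, b)) / u
}

#' Discover persistent ligand binding sites
#'
#' A ligand is site-forming when, in at least `persistence_fraction` of the
#' window frames, its contacted-residue set has Jaccard overlap >= 0.5 with
#' its consensus set (the residues it contacts in at least half of the
#' window frames). Site-forming ligands whose consensus sets overlap with
#' Jaccard >= 0.5 are merged into one site. Sites are ranked by mean
#' ligand-protein interaction energy, most negative first (contact-count
#' ranking is used if nonbonded parameters are absent).
#'
#' @param traj an `oligo_trajectory` with ligands.
#' @param molecule_ids ligand ids to consider (default all).
#' @param frame_window integer frame indices (default all).
#' @param persistence_fraction persistence threshold (default 0.5).
#' @param contact_importance probability threshold for a site's anchor
#'   residues.
#' @return list of `site_group`s: list(site, ligands, anchor_residues,
#'   mean_energy, sd_energy, mean_contacts), ranked; empty list when no
#'   ligand persists.
#' @export
discover_sites <- function(traj, molecule_ids = NULL, frame_window = NULL,
                           persistence_fraction = 0.5,
                           contact_importance = 0.1) {
  at <- traj$topology$atoms
  if (is.null(molecule_ids)) {
    molecule_ids <- sort(unique(at$molecule_id[at$is_ligand]))
    if (!length(molecule_ids)) return(list())
  }
  if (is.null(frame_window)) frame_window <- seq_len(n_frames(traj))
  nf <- length(frame_window)

  per_lig <- lapply(molecule_ids, function(m) {
    sets <- lapply(frame_window, function(f) {
      cc <- ligand_contacts(traj$coords[[f]], traj$topology, m)
      hit <- which(cc$backbone | cc$sidechain)
      if (!length(hit)) character(0) else
        paste0(cc$chain[hit], ":", cc$residue[hit])
    })
    tab <- table(unlist(sets))
    consensus <- names(tab)[tab >= nf / 2]
    persist <- mean(vapply(sets, function(s)
      .jaccard(s, consensus) >= 0.5, logical(1)))
    mean_contacts <- mean(vapply(sets, length, numeric(1)))
    list(mol = m, consensus = consensus, persistence = persist,
         mean_contacts = mean_contacts)
  })
  forming <- Filter(function(l)
    l$persistence >= persistence_fraction && length(l$consensus) > 0,
    per_lig)
  if (!length(forming)) return(list())

  # merge ligands with overlapping consensus sets
  groups <- list()
  for (l in forming) {
    placed <- FALSE
    for (gi in seq_along(groups)) {
      if (any(vapply(groups[[gi]], function(g)
        .jaccard(g$consensus, l$consensus) >= 0.5, logical(1)))) {
        groups[[gi]] <- c(groups[[gi]], list(l))
        placed <- TRUE
        break
      }
    }
    if (!placed) groups[[length(groups) + 1L]] <- list(l)
  }

  prot <- which(!at$is_ligand)
  has_params <- !anyNA(at$charge[prot]) && !anyNA(at$lj_epsilon[prot]) &&
    !anyNA(at$lj_rmin_half[prot])
  sites <- lapply(groups, function(g) {
    mols <- vapply(g, `[[`, numeric(1), "mol")
    lig_atoms <- which(at$is_ligand & at$molecule_id %in% mols)
    me <- NA_real_; se <- NA_real_
    if (has_params && !anyNA(at$charge[lig_atoms])) {
      tr <- interaction_energy(traj, lig_atoms, prot,
                               frame_window = frame_window)
      me <- attr(tr, "mean_total"); se <- attr(tr, "sd_total")
    }
    prof <- contact_profile(traj, mols, frame_window,
                            probability_threshold = contact_importance)
    anchors <- prof[prof$important_backbone | prof$important_sidechain,
                    c("chain", "residue")]
    list(ligands = mols,
         anchor_residues = if (!nrow(anchors)) character(0) else
           paste0(anchors$chain, ":", anchors$residue),
         mean_energy = me, sd_energy = se,
         mean_contacts = sum(vapply(g, `[[`, numeric(1), "mean_contacts")))
  })
  rank_key <- vapply(sites, function(s)
    if (is.na(s$mean_energy)) -s$mean_contacts else s$mean_energy,
    numeric(1))
  sites <- sites[order(rank_key)]
  for (i in seq_along(sites)) sites[[i]]$site <- paste0("S", i)
  sites
}

#' Run the full study and write a report bundle
#'
#' Executes, on one trajectory: the convergence panel (C-alpha RMSD,
#' beta-content and inter-peptide backbone H-bond series), the order panel
#' (P2 series with ordered/disordered classification, chain-averaged
#' RMSF), the (beta-content, Rg) free-energy landscape with basins,
#' backbone H-bond maps for all adjacent chain pairs, conformational
#' clustering, and — when ligands are present — binding-site discovery.
#' Writes fixed-name CSV/JSON files plus a run log of every setting;
#' reruns with the same config and seed are byte-identical. Any stage
#' failure aborts with the stage name and removes partial outputs.
#'
#' @param config a [run_config()].
#' @return the report as a list, invisibly; files under `config$out_dir`.
#' @export
run_full_report <- function(config) {
  stopifnot(inherits(config, "run_config"))
  traj <- config$traj
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character()
  stage <- "setup"
  on_fail <- function(e) {
    unlink(written)
    stop("stage '", stage, "' failed: ", conditionMessage(e), call. = FALSE)
  }
  emit_csv <- function(df, name) {
    p <- file.path(config$out_dir, name)
    utils::write.csv(df, p, row.names = FALSE)
    written <<- c(written, p)
  }
  emit_json <- function(x, name) {
    p <- file.path(config$out_dir, name)
    jsonlite::write_json(x, p, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    written <<- c(written, p)
  }
  report <- tryCatch({
    win <- config$from_frame:n_frames(traj)

    stage <- "convergence"
    rmsd <- rmsd_series(traj)
    ss <- assign_ss_trajectory(traj)
    beta <- beta_content(ss)
    hbs <- backbone_hbond_count_series(traj)
    conv <- data.frame(time = traj$times, rmsd = rmsd$rmsd,
                       beta = beta$series$beta, hbonds = hbs$hbonds)
    emit_csv(conv, "convergence.csv")

    stage <- "order"
    p2 <- p2_series(traj)
    ord <- classify_order(p2$p2[win])
    emit_csv(p2, "p2.csv")
    sup <- superpose_trajectory(traj)
    rmsf <- rmsf_per_residue(sup, from_frame = config$from_frame)
    emit_csv(rmsf, "rmsf.csv")

    stage <- "secondary_structure"
    emit_csv(ss_timeline(ss), "ss_timeline.csv")
    cont <- ss_content(ss)
    ss_sum <- lapply(cont[c("coil", "turn", "beta", "helix")],
                     function(x) list(mean = unname(x["mean"]),
                                      sd = unname(x["sd"])))

    stage <- "fel"
    rg <- rg_series(traj)
    fel <- build_fel(beta$series$beta[win], rg$rg[win] / 10,
                     bins = config$bins, temperature = config$temperature)
    fel <- find_basins(fel)
    emit_csv(fel_table(fel), "fel.csv")

    stage <- "hbond_maps"
    chains <- traj$topology$chains
    maps <- list()
    if (length(chains) >= 2) {
      for (i in seq_len(length(chains) - 1)) {
        pair <- c(chains[i], chains[i + 1])
        m <- hbond_map(traj, pair, frame_window = win)
        nm <- paste0("hbond_map_", pair[1], pair[2], ".csv")
        emit_csv(as.data.frame(unclass(m)), nm)
        maps[[paste(pair, collapse = "-")]] <- attr(m, "normalized")
      }
    }

    stage <- "clustering"
    cl <- cluster_frames(traj, k = config$cluster_k,
                         seed = config$seed + 101L, stride = 1)

    stage <- "sites"
    lig_ids <- sort(unique(
      traj$topology$atoms$molecule_id[traj$topology$atoms$is_ligand]))
    sites <- if (length(lig_ids))
      discover_sites(traj, lig_ids, frame_window = win,
                     persistence_fraction = config$persistence_fraction,
                     contact_importance = config$contact_importance)
    else list()

    stage <- "summary"
    summary <- list(
      n_frames = n_frames(traj),
      analysis_window = c(config$from_frame, n_frames(traj)),
      order = list(label = ord$label, p2_mean = ord$mean, p2_sd = ord$sd,
                   cutoff = config$p2_cutoff),
      beta_content = list(mean = mean(beta$series$beta[win]),
                          sd = stats::sd(beta$series$beta[win])),
      ss_content = ss_sum,
      fel = list(kT = fel$kT, n_basins = nrow(fel$basins),
                 basins = fel$basins[, c("x", "y", "depth")]),
      clusters = list(k = cl$k, occupancies = cl$occupancies,
                      representatives = cl$representatives),
      n_sites = length(sites),
      sites = lapply(sites, function(s)
        s[c("site", "ligands", "anchor_residues", "mean_energy",
            "mean_contacts")]),
      settings = config[setdiff(names(config), "traj")])
    emit_json(summary, "summary.json")
    summary
  }, error = on_fail)
  invisible(report)
}
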