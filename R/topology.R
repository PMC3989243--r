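# Core containers: topology, frames, trajectories, atom selection, and
# multi-model PDB / CSV I/O. Coordinates are in Angstrom throughout.

.ELEMENT_MASS <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999,
                   S = 32.06, P = 30.974)

.element_from_name <- function(name) {
  # First alphabetic character of the atom-name token; good enough for
  # standard protein/ligand naming when the PDB element column is absent.
  el <- toupper(sub("^[0-9]*([A-Za-z]).*$", "\\1", name))
  el[!el %in% names(.ELEMENT_MASS)] <- "C"
  el
}

#' Construct a topology
#'
#' A topology holds the atom table shared by every frame of a trajectory:
#' one row per atom with chain, residue and naming metadata, ligand flags,
#' and optional nonbonded parameters (partial charge, Lennard-Jones
#' epsilon and rmin/2) used by [interaction_energy()].
#'
#' @param atoms data.frame with columns `serial`, `name`, `element`,
#'   `chain_id`, `residue_index`, `residue_name`, `is_ligand`,
#'   `molecule_id`, `mass` and optionally `charge`, `lj_epsilon`,
#'   `lj_rmin_half`.
#' @param h_parent integer vector, one entry per atom: row index of the
#'   heavy atom each hydrogen is bonded to (`NA` for heavy atoms and for
#'   hydrogens whose parent could not be inferred).
#' @param residues_per_chain number of residues per protein chain
#'   (all protein chains are assumed to share one layout).
#' @return an object of class `oligo_topology`.
#' @export
topology <- function(atoms, h_parent = rep(NA_integer_, nrow(atoms)),
                     residues_per_chain = NULL) {
  need <- c("serial", "name", "element", "chain_id", "residue_index",
            "residue_name", "is_ligand", "molecule_id", "mass")
  miss <- setdiff(need, names(atoms))
  if (length(miss))
    stop("atom table is missing columns: ", paste(miss, collapse = ", "))
  for (col in c("charge", "lj_epsilon", "lj_rmin_half"))
    if (is.null(atoms[[col]])) atoms[[col]] <- NA_real_
  if (length(h_parent) != nrow(atoms))
    stop("h_parent must have one entry per atom")
  key <- paste(atoms$chain_id, atoms$residue_index, atoms$name,
               atoms$is_ligand, atoms$molecule_id)
  if (anyDuplicated(key))
    stop("duplicate (chain_id, residue_index, name) atom keys in topology")
  if (any(atoms$is_ligand & atoms$molecule_id < 1))
    stop("ligand atoms must carry molecule_id >= 1")
  if (any(!atoms$is_ligand & atoms$molecule_id != 0))
    stop("protein atoms must carry molecule_id = 0")
  chains <- unique(atoms$chain_id[!atoms$is_ligand])
  if (is.null(residues_per_chain) && length(chains))
    residues_per_chain <- max(atoms$residue_index[!atoms$is_ligand])
  rownames(atoms) <- NULL
  structure(list(atoms = atoms, chains = chains,
                 residues_per_chain = residues_per_chain,
                 h_parent = as.integer(h_parent)),
            class = "oligo_topology")
}

#' @export
print.oligo_topology <- function(x, ...) {
  cat("Topology:", nrow(x$atoms), "atoms,",
      length(x$chains), "protein chain(s)",
      if (any(x$atoms$is_ligand))
        sprintf("+ %d ligand molecule(s)", max(x$atoms$molecule_id)) else "",
      "\n")
  invisible(x)
}

n_atoms <- function(top) nrow(top$atoms)

#' Construct a trajectory
#'
#' @param top an `oligo_topology`.
#' @param coords list of numeric `n_atoms x 3` coordinate matrices
#'   (Angstrom), one per frame.
#' @param times frame times in ps; must be strictly increasing.
#' @return an object of class `oligo_trajectory`. The `superposed`
#'   attribute records whether frames have been least-squares fitted onto
#'   a reference (required by [rmsf_per_residue()]).
#' @export
trajectory <- function(top, coords, times = seq_along(coords) - 1) {
  if (!inherits(top, "oligo_topology")) stop("top must be an oligo_topology")
  if (!length(coords)) stop("trajectory must contain at least one frame")
  for (i in seq_along(coords)) {
    xyz <- coords[[i]]
    if (!is.matrix(xyz) || ncol(xyz) != 3 || nrow(xyz) != n_atoms(top))
      stop("frame ", i, ": coordinates must be a ", n_atoms(top),
           " x 3 matrix")
    if (!all(is.finite(xyz)))
      stop("frame ", i, ": non-finite coordinates")
  }
  if (length(times) != length(coords) ||
      (length(times) > 1 && any(diff(times) <= 0)))
    stop("times must be strictly increasing, one per frame")
  structure(list(topology = top, coords = coords, times = as.numeric(times),
                 superposed = FALSE),
            class = "oligo_trajectory")
}

#' @export
print.oligo_trajectory <- function(x, ...) {
  cat("Trajectory:", length(x$coords), "frame(s) x", n_atoms(x$topology),
      "atoms", if (isTRUE(x$superposed)) "(superposed)" else "", "\n")
  invisible(x)
}

n_frames <- function(traj) length(traj$coords)

# ---- hydrogen parentage ----------------------------------------------------

# Infer the bonded heavy atom of each hydrogen from standard PDB naming:
# "H"/"HN"/"HT*" -> N; exact match H<heavy> (e.g. "HO1" -> "O1"); otherwise
# match the remainder stem against heavy-atom name stems within the residue
# ("HA" -> "CA", "HB2" -> "CB", "HG11" -> "CG1"). CONECT-derived bonds, when
# available, override name-based inference.
infer_h_parents <- function(atoms, conect = NULL) {
  n <- nrow(atoms)
  parent <- rep(NA_integer_, n)
  is_h <- atoms$element == "H"
  if (!any(is_h)) return(parent)
  res_key <- paste(atoms$chain_id, atoms$residue_index, atoms$is_ligand,
                   atoms$molecule_id)
  split_idx <- split(seq_len(n), res_key)
  for (idx in split_idx) {
    heavy <- idx[!is_h[idx]]
    if (!length(heavy)) next
    hn <- atoms$name[heavy]
    heavy_stem <- sub("[0-9]+$", "", substring(hn, 2))
    for (i in idx[is_h[idx]]) {
      nm <- atoms$name[i]
      if (nm %in% c("H", "HN") || grepl("^HT[0-9]*$", nm)) {
        hit <- heavy[hn == "N"]
      } else if (substring(nm, 2) %in% hn) {
        hit <- heavy[hn == substring(nm, 2)]
      } else {
        rem <- sub("[0-9]+$", "", sub("^H", "", nm))
        hit <- heavy[nzchar(rem) & heavy_stem == rem]
      }
      if (length(hit) == 1) parent[i] <- hit
    }
  }
  if (!is.null(conect) && nrow(conect)) {
    serial_to_idx <- match(conect$serial, atoms$serial)
    bonded_to_idx <- match(conect$bonded, atoms$serial)
    ok <- !is.na(serial_to_idx) & !is.na(bonded_to_idx)
    for (k in which(ok)) {
      a <- serial_to_idx[k]; b <- bonded_to_idx[k]
      if (is_h[a] && !is_h[b]) parent[a] <- b
      if (is_h[b] && !is_h[a]) parent[b] <- a
    }
  }
  unparented <- which(is_h & is.na(parent))
  if (length(unparented))
    warning(length(unparented), " hydrogen(s) with unrecognized naming left ",
            "unparented (excluded from H-bond donor search): ",
            paste(utils::head(atoms$name[unparented], 5), collapse = ", "))
  parent
}

# ---- multi-model PDB I/O ---------------------------------------------------

#' Read a multi-model PDB file as a trajectory
#'
#' Each MODEL block becomes one frame; a file without MODEL records yields a
#' single-frame trajectory. Atoms whose residue name is listed in
#' `ligand_resnames` are flagged as ligand atoms, with molecule ids assigned
#' per contiguous ligand residue in file order. Hydrogen parentage is
#' inferred from standard naming plus any CONECT records; unrecognized
#' hydrogens are left unparented with a warning.
#'
#' @param path PDB file path.
#' @param ligand_resnames character vector of 3-letter ligand residue names.
#' @param timestep time between saved frames in ps (PDB stores no time).
#' @return an `oligo_trajectory`.
#' @export
read_multimodel_pdb <- function(path, ligand_resnames = character(),
                                timestep = 1) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  # Contract pre-scan: per-MODEL atom counts must agree.
  rec <- substr(lines, 1, 6)
  is_atom <- rec == "ATOM  " | rec == "HETATM"
  model_starts <- which(startsWith(lines, "MODEL"))
  if (length(model_starts) > 1) {
    bounds <- c(model_starts, length(lines) + 1L)
    counts <- vapply(seq_along(model_starts), function(m) {
      sum(is_atom[bounds[m]:(bounds[m + 1] - 1L)])
    }, integer(1))
    if (length(unique(counts)) > 1) {
      bad <- which(counts != counts[1])[1]
      stop("atom count mismatch across MODELs: model ", bad, " has ",
           counts[bad], " atoms, expected ", counts[1])
    }
  }
  if (!any(is_atom)) stop("no ATOM/HETATM records in ", path)
  conect_lines <- lines[rec == "CONECT"]
  conect <- NULL
  if (length(conect_lines)) {
    pairs <- do.call(rbind, lapply(conect_lines, function(l) {
      flds <- suppressWarnings(as.integer(strsplit(trimws(substring(l, 7)),
                                                   "\\s+")[[1]]))
      flds <- flds[!is.na(flds)]
      if (length(flds) < 2) return(NULL)
      cbind(serial = flds[1], bonded = flds[-1])
    }))
    if (!is.null(pairs)) conect <- as.data.frame(pairs)
  }
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  at <- pdb$atom
  if (all(is.na(at$chain)) || any(!nzchar(at$chain) | is.na(at$chain)))
    stop("PDB file lacks chain identifiers")
  element <- at$elesy
  bad_el <- is.na(element) | !nzchar(trimws(element))
  element[bad_el] <- .element_from_name(at$elety[bad_el])
  element <- trimws(element)
  is_lig <- at$resid %in% ligand_resnames
  mol_id <- integer(nrow(at))
  if (any(is_lig)) {
    res_tag <- paste(at$chain, at$resno, at$resid)
    lig_tags <- unique(res_tag[is_lig])
    mol_id[is_lig] <- match(res_tag[is_lig], lig_tags)
  }
  atoms <- data.frame(serial = at$eleno, name = at$elety, element = element,
                      chain_id = at$chain, residue_index = at$resno,
                      residue_name = at$resid, is_ligand = is_lig,
                      molecule_id = mol_id,
                      mass = unname(.ELEMENT_MASS[element]),
                      stringsAsFactors = FALSE)
  atoms$mass[is.na(atoms$mass)] <- 12.011
  h_parent <- infer_h_parents(atoms, conect)
  top <- topology(atoms, h_parent)
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  coords <- lapply(seq_len(nrow(xyz)), function(i) {
    matrix(xyz[i, ], ncol = 3, byrow = TRUE)
  })
  trajectory(top, coords, times = (seq_along(coords) - 1) * timestep)
}

#' Write a trajectory as a multi-model PDB file
#'
#' @param traj an `oligo_trajectory`.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_multimodel_pdb <- function(traj, path) {
  at <- traj$topology$atoms
  xyz <- do.call(rbind, lapply(traj$coords, function(m) as.vector(t(m))))
  bio3d::write.pdb(file = path, xyz = xyz,
                   type = ifelse(at$is_ligand, "HETATM", "ATOM"),
                   eleno = at$serial, elety = at$name,
                   resid = at$residue_name, chain = at$chain_id,
                   resno = at$residue_index, elesy = at$element)
  invisible(path)
}

#' Write keyed records as a CSV table
#'
#' All rows must share an identical key set; writes a header plus one line
#' per record, round-trippable with any CSV reader.
#'
#' @param rows list of named lists/vectors sharing one key set, or a
#'   data.frame.
#' @param path output file path.
#' @export
write_series_table <- function(rows, path) {
  if (is.data.frame(rows)) {
    utils::write.csv(rows, path, row.names = FALSE)
    return(invisible(path))
  }
  if (!length(rows)) stop("cannot infer header from an empty row list; ",
                          "pass a (possibly 0-row) data.frame instead")
  keys <- names(rows[[1]])
  for (i in seq_along(rows)) {
    if (!identical(sort(names(rows[[i]])), sort(keys)))
      stop("row ", i, " has keys {", paste(names(rows[[i]]), collapse = ","),
           "}, expected {", paste(keys, collapse = ","), "}")
  }
  df <- do.call(rbind, lapply(rows, function(r)
    as.data.frame(as.list(r[keys]), stringsAsFactors = FALSE)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

# ---- atom selection --------------------------------------------------------

.BACKBONE_NAMES <- c("N", "CA", "C", "O", "OXT")

backbone_mask <- function(top) {
  at <- top$atoms
  bb <- !at$is_ligand & at$name %in% .BACKBONE_NAMES
  # backbone hydrogens: parented to a backbone heavy atom
  is_h <- at$element == "H" & !at$is_ligand
  hp <- top$h_parent
  bb_h <- is_h & !is.na(hp) & bb[pmax(hp, 1)]
  bb_h[is.na(bb_h)] <- FALSE
  bb | bb_h
}

#' Select atoms with a small query language
#'
#' Queries are conjunctions of clauses joined by `and`:
#' \itemize{
#'   \item `chain <id>` — single-letter chain label
#'   \item `residue <i>` or `residue <i>-<j>` — residue index (range)
#'   \item `name <atom-name>` — exact atom-name token
#'   \item `backbone` — N, CA, C, O (+ OXT) and hydrogens bonded to them
#'   \item `sidechain` — protein atoms that are not backbone
#'   \item `calpha` — protein CA atoms
#'   \item `ligand` / `protein` — ligand vs protein atoms
#' }
#' e.g. `"chain A and calpha"`, `"backbone and residue 26"`.
#'
#' @param top an `oligo_topology`.
#' @param query selection expression.
#' @return topology-ordered integer atom indices (possibly empty).
#' @export
select_atoms <- function(top, query) {
  at <- top$atoms
  m <- gregexpr("\\S+", query)[[1]]
  toks <- regmatches(query, gregexpr("\\S+", query))[[1]]
  pos <- as.integer(m)
  if (!length(toks)) stop("malformed selection at position 1: empty query")
  bad <- function(i) stop("malformed selection at position ",
                          if (i <= length(pos)) pos[i] else nchar(query) + 1,
                          ": '", if (i <= length(toks)) toks[i] else "<end>",
                          "'", call. = FALSE)
  mask <- rep(TRUE, nrow(at))
  i <- 1
  expect_clause <- TRUE
  while (i <= length(toks)) {
    tok <- tolower(toks[i])
    if (!expect_clause) {
      if (tok != "and") bad(i)
      i <- i + 1
      expect_clause <- TRUE
      next
    }
    clause <- switch(tok,
      backbone  = backbone_mask(top),
      sidechain = !at$is_ligand & !backbone_mask(top),
      calpha    = !at$is_ligand & at$name == "CA",
      ligand    = at$is_ligand,
      protein   = !at$is_ligand,
      chain = {
        if (i + 1 > length(toks)) bad(i + 1)
        i <- i + 1
        at$chain_id == toks[i]
      },
      residue = {
        if (i + 1 > length(toks)) bad(i + 1)
        i <- i + 1
        spec <- toks[i]
        if (grepl("^[0-9]+$", spec)) {
          at$residue_index == as.integer(spec)
        } else if (grepl("^[0-9]+[-:][0-9]+$", spec)) {
          rng <- as.integer(strsplit(spec, "[-:]")[[1]])
          at$residue_index >= rng[1] & at$residue_index <= rng[2]
        } else bad(i)
      },
      name = {
        if (i + 1 > length(toks)) bad(i + 1)
        i <- i + 1
        at$name == toks[i]
      },
      bad(i))
    mask <- mask & clause
    i <- i + 1
    expect_clause <- FALSE
  }
  if (expect_clause) bad(length(toks) + 1)
  which(mask)
}
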