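# Two-dimensional free-energy landscapes over (beta-content, Rg) and
# RMSD-based k-medoids conformational clustering.

KB_KCAL <- 0.0019872  # kcal mol^-1 K^-1

#' Build a 2D free-energy landscape from two reaction-coordinate series
#'
#' Histograms the per-frame (x, y) pairs on a regular grid padded 2% beyond
#' the data range, then converts counts to free energies
#' dG = -kT ln(P / Pmax), so the most populated bin sits at exactly 0 and
#' empty bins are +Inf. The conventional axes are beta-sheet content
#' (fraction) and radius of gyration (nm at this boundary; use `rg_A / 10`).
#'
#' @param x_series,y_series equal-length numeric vectors, one value per
#'   frame.
#' @param bins integer length-2: number of bins (nx, ny); default 40 x 40.
#' @param temperature Kelvin (kT = 0.0019872 T kcal/mol); default 310.
#' @return a `fel_grid`: list(x_edges, y_edges, counts, delta_g, kT,
#'   basins = NULL).
#' @export
build_fel <- function(x_series, y_series, bins = c(40, 40),
                      temperature = 310) {
  if (length(x_series) != length(y_series) || !length(x_series))
    stop("x and y series must be equal-length and non-empty")
  kT <- KB_KCAL * temperature
  pad_edges <- function(v, nb) {
    rng <- range(v)
    if (rng[1] == rng[2]) return(c(rng[1] - 0.5, rng[1] + 0.5))
    pad <- diff(rng) * 0.02
    seq(rng[1] - pad, rng[2] + pad, length.out = nb + 1)
  }
  zero_x <- length(unique(x_series)) == 1
  zero_y <- length(unique(y_series)) == 1
  if (zero_x && zero_y)
    warning("both reaction coordinates are constant; single-bin grid")
  x_edges <- pad_edges(x_series, if (zero_x) 1 else bins[1])
  y_edges <- pad_edges(y_series, if (zero_y) 1 else bins[2])
  xi <- findInterval(x_series, x_edges, rightmost.closed = TRUE,
                     all.inside = TRUE)
  yi <- findInterval(y_series, y_edges, rightmost.closed = TRUE,
                     all.inside = TRUE)
  counts <- matrix(0, length(x_edges) - 1, length(y_edges) - 1)
  for (k in seq_along(xi)) counts[xi[k], yi[k]] <- counts[xi[k], yi[k]] + 1
  delta_g <- matrix(Inf, nrow(counts), ncol(counts))
  nz <- counts > 0
  delta_g[nz] <- -kT * log(counts[nz] / max(counts)) + 0  # +0 drops IEEE -0
  structure(list(x_edges = x_edges, y_edges = y_edges, counts = counts,
                 delta_g = delta_g, kT = kT, temperature = temperature,
                 basins = NULL),
            class = "fel_grid")
}

#' @export
print.fel_grid <- function(x, ...) {
  cat(sprintf("FEL grid %d x %d, kT = %.4f kcal/mol, %d frames\n",
              nrow(x$counts), ncol(x$counts), x$kT, sum(x$counts)))
  if (!is.null(x$basins) && nrow(x$basins))
    cat(nrow(x$basins), "basin(s); global minimum at (",
        sprintf("%.3f, %.3f", x$basins$x[1], x$basins$y[1]), ")\n")
  invisible(x)
}

#' Detect basins on a free-energy grid
#'
#' Local minima of dG over the 8-neighborhood (empty bins count as +Inf),
#' kept if dG <= `max_depth`, sorted deepest first (ties broken by lower x
#' center, then lower y center) and greedily filtered so retained basins
#' are pairwise separated by at least `min_separation_bins` (Chebyshev bin
#' distance). The global minimum is always first.
#'
#' @param grid a `fel_grid`.
#' @param min_separation_bins minimum bin separation between basins.
#' @param max_depth report only basins with dG at most this (kcal/mol).
#' @return the grid with `basins`: data.frame(x, y, depth, i, j).
#' @export
find_basins <- function(grid, min_separation_bins = 3, max_depth = Inf) {
  dg <- grid$delta_g
  nx <- nrow(dg); ny <- ncol(dg)
  xc <- (grid$x_edges[-1] + grid$x_edges[-length(grid$x_edges)]) / 2
  yc <- (grid$y_edges[-1] + grid$y_edges[-length(grid$y_edges)]) / 2
  cand <- list()
  for (i in seq_len(nx)) for (j in seq_len(ny)) {
    v <- dg[i, j]
    if (!is.finite(v) || v > max_depth) next
    nb <- dg[max(1, i - 1):min(nx, i + 1), max(1, j - 1):min(ny, j + 1)]
    if (v <= min(nb))
      cand[[length(cand) + 1L]] <- data.frame(x = xc[i], y = yc[j],
                                              depth = v, i = i, j = j)
  }
  basins <- if (length(cand)) do.call(rbind, cand) else
    data.frame(x = numeric(), y = numeric(), depth = numeric(),
               i = integer(), j = integer())
  if (nrow(basins)) {
    basins <- basins[order(basins$depth, basins$x, basins$y), , drop = FALSE]
    keep <- integer()
    for (k in seq_len(nrow(basins))) {
      ok <- TRUE
      for (m in keep) {
        if (max(abs(basins$i[k] - basins$i[m]),
                abs(basins$j[k] - basins$j[m])) < min_separation_bins)
          ok <- FALSE
      }
      if (ok) keep <- c(keep, k)
    }
    basins <- basins[keep, , drop = FALSE]
    rownames(basins) <- NULL
  }
  grid$basins <- basins
  grid
}

#' Export a FEL grid as a long-format table
#'
#' @param grid a `fel_grid`.
#' @return data.frame(x, y, count, delta_g); empty bins carry `Inf`.
#' @export
fel_table <- function(grid) {
  xc <- (grid$x_edges[-1] + grid$x_edges[-length(grid$x_edges)]) / 2
  yc <- (grid$y_edges[-1] + grid$y_edges[-length(grid$y_edges)]) / 2
  data.frame(x = rep(xc, times = length(yc)),
             y = rep(yc, each = length(xc)),
             count = as.vector(grid$counts),
             delta_g = as.vector(grid$delta_g))
}

# ---- clustering ------------------------------------------------------------

# Pairwise C-alpha RMSD matrix of frames already fitted to a common
# reference (no per-pair refit, matching superpose-then-cluster protocols).
pairwise_rmsd_matrix <- function(coord_list) {
  n <- length(coord_list)
  D <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    xi <- coord_list[[i]]
    for (j in (i + 1):n) {
      d <- sqrt(mean(rowSums((xi - coord_list[[j]])^2)))
      D[i, j] <- D[j, i] <- d
    }
  }
  D
}

# Seeded alternating k-medoids on a distance matrix. Assignment ties go to
# the lowest cluster index; the medoid update picks the member minimizing
# the summed within-cluster distance (lowest frame index on ties).
.kmedoids <- function(D, k, seed) {
  n <- nrow(D)
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  medoids <- sort(sample.int(n, k))
  for (iter in 1:100) {
    labels <- apply(D[, medoids, drop = FALSE], 1, which.min)
    new_medoids <- vapply(seq_len(k), function(c_) {
      members <- which(labels == c_)
      if (!length(members)) return(medoids[c_])
      members[which.min(colSums(D[members, members, drop = FALSE]))]
    }, integer(1))
    if (identical(new_medoids, medoids)) break
    medoids <- new_medoids
  }
  labels <- apply(D[, medoids, drop = FALSE], 1, which.min)
  list(labels = labels, medoids = medoids)
}

#' RMSD-based k-medoids conformational clustering
#'
#' Frames (optionally strided) are superposed onto the first selected frame
#' over the atom selection, the pairwise RMSD matrix is formed, and seeded
#' k-medoids partitions it. Deterministic for a fixed seed. If duplicate
#' medoids arise (e.g. identical frames), clusters are merged with a
#' warning and reported empty.
#'
#' @param traj an `oligo_trajectory`.
#' @param k number of clusters (1 <= k <= number of used frames).
#' @param seed RNG seed for medoid initialization.
#' @param selection atom indices (default all protein C-alpha).
#' @param stride keep every `stride`-th frame (default 1).
#' @return a `cluster_result`: list(labels, occupancies, representatives,
#'   k, frames, rmsd_matrix).
#' @export
cluster_frames <- function(traj, k, seed = 1, selection = NULL, stride = 1) {
  if (is.null(selection)) selection <- select_atoms(traj$topology, "calpha")
  frames <- seq(1, n_frames(traj), by = stride)
  if (k < 1) stop("k must be >= 1")
  if (k > length(frames))
    stop("k = ", k, " exceeds the ", length(frames), " frames available")
  ref <- traj$coords[[frames[1]]]
  fitted <- lapply(frames, function(f)
    superpose(traj$coords[[f]], ref, selection)$coords[selection, ,
                                                       drop = FALSE])
  D <- pairwise_rmsd_matrix(fitted)
  km <- .kmedoids(D, k, seed)
  # degenerate duplicate medoids: merge into the lowest cluster id
  if (anyDuplicated(km$medoids) ||
      any(D[km$medoids, km$medoids][upper.tri(diag(k))] == 0 & k > 1)) {
    med_d <- D[km$medoids, km$medoids, drop = FALSE]
    for (c2 in seq_len(k)) {
      c1 <- which(med_d[, c2] == 0)[1]
      if (c1 < c2) km$labels[km$labels == c2] <- c1
    }
    if (length(unique(km$labels)) < k)
      warning("degenerate clustering: duplicate frames leave ",
              k - length(unique(km$labels)), " empty cluster(s)")
  }
  occ <- vapply(seq_len(k), function(c_) mean(km$labels == c_), numeric(1))
  structure(list(labels = km$labels, occupancies = occ,
                 representatives = frames[km$medoids], k = k,
                 frames = frames, rmsd_matrix = D),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat("k =", x$k, "clusters over", length(x$frames), "frames\n")
  cat("occupancies:", paste(sprintf("%.1f%%", 100 * x$occupancies),
                            collapse = ", "), "\n")
  cat("representative frames:", paste(x$representatives, collapse = ", "),
      "\n")
  invisible(x)
}

#' Cluster-occupancy stability across several k
#'
#' Runs [cluster_frames()] for each k and reports occupancies sorted
#' descending plus the cumulative occupancy of the top two clusters — the
#' consistency check used to argue that a conformational ensemble is
#' dominated by few states regardless of the chosen cluster count.
#'
#' @param traj an `oligo_trajectory`.
#' @param k_list integer vector of cluster counts, e.g. `3:5`.
#' @param seed RNG seed.
#' @param selection,stride passed to [cluster_frames()].
#' @return list(per_k = named list of sorted occupancy vectors,
#'   top2 = data.frame(k, top2_cumulative)).
#' @export
stability_over_k <- function(traj, k_list, seed = 1, selection = NULL,
                             stride = 1) {
  per_k <- lapply(k_list, function(k) {
    sort(cluster_frames(traj, k, seed = seed, selection = selection,
                        stride = stride)$occupancies, decreasing = TRUE)
  })
  names(per_k) <- paste0("k", k_list)
  top2 <- vapply(per_k, function(o) sum(utils::head(o, 2)), numeric(1))
  list(per_k = per_k, top2 = data.frame(k = k_list,
                                        top2_cumulative = unname(top2)))
}
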