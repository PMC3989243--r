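# Nematic order parameter, superposition/RMSD, RMSF, radius of gyration.

test_that("P2 analytic values: aligned chains and perpendicular pair", {
  aligned <- chains_with_vectors(matrix(rep(c(1, 0, 0), 5), 5, 3,
                                        byrow = TRUE))
  r <- nematic_p2(aligned$coords, aligned$top)
  expect_equal(r$p2, 1, tolerance = 1e-12)
  expect_equal(abs(r$director), c(1, 0, 0), tolerance = 1e-9)
  expect_equal(r$n_chains, 5)

  # hand eigendecomposition: Q = diag(1/4, 1/4, -1/2) -> max eigenvalue 1/4
  perp <- chains_with_vectors(rbind(c(1, 0, 0), c(0, 1, 0)))
  expect_equal(nematic_p2(perp$coords, perp$top)$p2, 0.25,
               tolerance = 1e-12)
})

test_that("P2 is invariant to global rotation and chain-vector flips", {
  set.seed(3)
  vecs <- matrix(rnorm(15), 5, 3)
  vecs <- vecs / sqrt(rowSums(vecs^2))
  sys <- chains_with_vectors(vecs)
  p0 <- nematic_p2(sys$coords, sys$top)$p2
  R <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  if (det(R) < 0) R[, 1] <- -R[, 1]
  rot <- chains_with_vectors(vecs %*% t(R))
  expect_equal(nematic_p2(rot$coords, rot$top)$p2, p0, tolerance = 1e-9)
  flipped <- vecs; flipped[2, ] <- -flipped[2, ]
  fl <- chains_with_vectors(flipped)
  expect_equal(nematic_p2(fl$coords, fl$top)$p2, p0, tolerance = 1e-9)
})

test_that("eigen-director maximizes P2 over random directors", {
  set.seed(4)
  for (rep_i in 1:5) {
    vecs <- matrix(rnorm(12), 4, 3)
    vecs <- vecs / sqrt(rowSums(vecs^2))
    sys <- chains_with_vectors(vecs)
    r <- nematic_p2(sys$coords, sys$top)
    p2_for <- function(d) mean(1.5 * (vecs %*% d)^2 - 0.5)
    for (k in 1:200) {
      d <- rnorm(3); d <- d / sqrt(sum(d^2))
      expect_lte(p2_for(d), r$p2 + 1e-9)
    }
  }
})

test_that("missing terminal C-alpha is an error naming the chain", {
  sys <- chains_with_vectors(rbind(c(1, 0, 0), c(0, 1, 0)))
  at <- sys$top$atoms
  at <- at[-4, ]  # drop last CA of second chain
  top <- topology(at, rep(NA_integer_, nrow(at)), residues_per_chain = 2)
  expect_error(nematic_p2(sys$coords[-4, ], top), "chain 2")
})

test_that("classify_order uses a strict 0.5 boundary", {
  r <- classify_order(rep(0.62, 4))
  expect_equal(r$label, "ordered")
  expect_equal(r$mean, 0.62)
  expect_equal(r$sd, 0)
  expect_equal(classify_order(rep(0.5, 3))$label, "disordered")
  r2 <- classify_order(c(0.4, 0.8))
  expect_equal(r2$label, "ordered")
  expect_equal(r2$mean, 0.6)
  expect_error(classify_order(numeric()), "empty")
})

test_that("superposition removes rigid motion and matches a brute-force fit", {
  base <- build_ordered_oligomer(oligomer_spec(n_chains = 2))
  sel <- select_atoms(base$topology, "calpha")
  shifted <- sweep(base$coords, 2, c(5, 0, 0), "+")
  fit <- superpose(shifted, base$coords, sel)
  expect_lt(fit$rmsd, 1e-9)
  expect_lt(max(abs(fit$coords - base$coords)), 1e-6)
  fit_id <- superpose(base$coords, base$coords, sel)
  expect_lt(fit_id$rmsd, 1e-9)
  expect_equal(fit_id$rotation, diag(3), tolerance = 1e-9)

  # toy instance: optimal rmsd cross-checked by a rotation-grid search
  set.seed(9)
  ref <- matrix(rnorm(12, sd = 3), 4, 3)
  mob <- ref
  mob[2, ] <- mob[2, ] + c(0.7, -0.4, 0.2)
  mob <- sweep(mob %*% t(.grid_rot(0.3, 0.8, 1.2)), 2, c(1, 2, 3), "+")
  fit2 <- superpose(mob, ref, 1:4)
  rmsd_at <- function(euler) {
    m <- mob %*% t(.grid_rot(euler[1], euler[2], euler[3]))
    m <- sweep(m, 2, colMeans(ref) - colMeans(m), "+")
    sqrt(mean(rowSums((m - ref)^2)))
  }
  grid_min <- Inf; grid_arg <- c(0, 0, 0)
  angs <- seq(0, 2 * pi, length.out = 19)[-19]
  half <- seq(0, pi, length.out = 10)
  for (a in angs) for (b in half) for (c_ in angs) {
    v <- rmsd_at(c(a, b, c_))
    if (v < grid_min) { grid_min <- v; grid_arg <- c(a, b, c_) }
  }
  # refine the best grid point with a generic optimizer (independent of
  # the closed-form Kabsch solution)
  refined <- stats::optim(grid_arg, rmsd_at)$value
  expect_lte(fit2$rmsd, refined + 1e-9)
  expect_equal(fit2$rmsd, refined, tolerance = 1e-4)
  # symmetry of the minimized RMSD
  expect_equal(superpose(ref, mob, 1:4)$rmsd, fit2$rmsd, tolerance = 1e-9)
  expect_error(superpose(mob, ref, 1:2), ">= 3 atoms")
})

test_that("superpose agrees with bio3d::fit.xyz on a random pair", {
  set.seed(21)
  ref <- matrix(rnorm(30, sd = 4), 10, 3)
  mob <- ref + matrix(rnorm(30, sd = 0.5), 10, 3)
  ours <- superpose(mob, ref, 1:10)
  b3d <- bio3d::fit.xyz(as.vector(t(ref)), as.vector(t(mob)),
                        fixed.inds = 1:30, mobile.inds = 1:30)
  rmsd_b3d <- sqrt(mean(rowSums((matrix(b3d, ncol = 3, byrow = TRUE) -
                                   ref)^2)))
  expect_equal(ours$rmsd, rmsd_b3d, tolerance = 1e-6)
})

test_that("RMSF: static zero, two-state closed form, chain averaging", {
  # 5 chains x 2 residues of CAs; residue 2 of chain 1 oscillates +-1 in x
  nc <- 5
  name <- rep("CA", 2 * nc)
  chain <- rep(as.character(1:nc), each = 2)
  residue <- rep(c(1L, 2L), nc)
  xyz <- cbind(seq_len(2 * nc) * 10, 0, 0)
  top <- toy_topology(name, rep("C", 2 * nc), chain, residue, xyz,
                      residues_per_chain = 2)
  static <- trajectory(top, replicate(6, xyz, simplify = FALSE))
  static$superposed <- TRUE
  expect_true(all(rmsf_per_residue(static)$rmsf == 0))

  coords <- lapply(1:6, function(f) {
    x <- xyz
    x[2, 1] <- x[2, 1] + ifelse(f %% 2 == 0, 1, -1)
    x
  })
  tr <- trajectory(top, coords)
  expect_error(rmsf_per_residue(tr), "not superposed")
  tr$superposed <- TRUE
  r <- rmsf_per_residue(tr)
  expect_equal(r$rmsf[r$residue == 1], 0, tolerance = 1e-12)
  expect_equal(r$rmsf[r$residue == 2], 1 / nc, tolerance = 1e-12)
})

test_that("radius of gyration closed forms and invariances", {
  top2 <- toy_topology(c("A1", "A2"), c("C", "C"), c("A", "A"), c(1L, 2L),
                       rbind(c(0, 0, 0), c(2, 0, 0)))
  expect_equal(radius_of_gyration(rbind(c(0, 0, 0), c(2, 0, 0)), top2, 1:2),
               1)
  expect_equal(radius_of_gyration(rbind(c(0, 0, 0), c(2, 0, 0)), top2, 1),
               0)
  cube <- as.matrix(expand.grid(c(-1, 1), c(-1, 1), c(-1, 1)))
  top8 <- toy_topology(paste0("C", 1:8), rep("C", 8), rep("A", 8), 1:8,
                       cube)
  expect_equal(radius_of_gyration(cube, top8, 1:8), sqrt(3),
               tolerance = 1e-12)
  # translation invariance and linear scaling
  expect_equal(radius_of_gyration(sweep(cube, 2, c(3, -2, 7), "+"), top8,
                                  1:8), sqrt(3), tolerance = 1e-12)
  expect_equal(radius_of_gyration(2.5 * cube, top8, 1:8), 2.5 * sqrt(3),
               tolerance = 1e-12)
})
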