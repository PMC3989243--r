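# Geometric H-bond detection, count series, maps, and occupancies.

# three-atom donor/acceptor system with controllable geometry: donor N at
# origin, H along +x, acceptor O at distance d and D-H-A angle ang (deg)
hb_probe <- function(d, ang) {
  # place A so that |D-A| = d and the angle at H between D and A is ang
  h <- c(1, 0, 0)
  # solve for A = h + t*u with angle(D-H, A-H) = ang; use planar geometry
  theta <- ang * pi / 180
  dir_a <- c(cos(pi - theta), sin(pi - theta), 0)  # from H, angle to H->D
  # find t so |A - D| = d
  f <- function(t) sqrt(sum((h + t * dir_a)^2)) - d
  t <- stats::uniroot(f, c(0.01, 10))$root
  a <- h + t * dir_a
  xyz <- rbind(c(0, 0, 0), h, a)
  top <- toy_topology(c("N", "H", "O"), c("N", "H", "O"),
                      c("A", "A", "B"), c(1L, 1L, 1L), xyz,
                      h_parent = c(NA, 1L, NA))
  list(top = top, coords = xyz)
}

test_that("detection thresholds are strict on both criteria", {
  ok <- hb_probe(2.9, 165)
  hb <- detect_hbonds(ok$coords, ok$top, scope = "all")
  expect_equal(nrow(hb), 1)
  expect_equal(hb$distance, 2.9, tolerance = 1e-6)
  expect_equal(hb$angle, 165, tolerance = 1e-6)

  expect_equal(nrow(detect_hbonds(hb_probe(3.6, 179)$coords,
                                  hb_probe(3.6, 179)$top, "all")), 0)
  boundary <- hb_probe(3.0, 149.999)
  expect_equal(nrow(detect_hbonds(boundary$coords, boundary$top, "all")), 0)
  just_over <- hb_probe(3.0, 150.5)
  expect_equal(nrow(detect_hbonds(just_over$coords, just_over$top, "all")), 1)
  at_dist <- hb_probe(3.5001, 170)
  expect_equal(nrow(detect_hbonds(at_dist$coords, at_dist$top, "all")), 0)
})

test_that("structures without hydrogens are refused", {
  top <- toy_topology(c("N", "O"), c("N", "O"), c("A", "B"), c(1L, 1L),
                      matrix(0, 2, 3))
  expect_error(detect_hbonds(matrix(0, 2, 3), top, "all"),
               "no parented hydrogens")
})

test_that("detector matches the exhaustive brute-force oracle", {
  for (seed in 1:6) {
    sys <- random_hbond_system(40, box = 12, seed = seed)
    got <- detect_hbonds(sys$coords, sys$top, scope = "all")
    got_m <- as.matrix(got[, c("donor", "hydrogen", "acceptor")])
    got_m <- got_m[order(got_m[, 1], got_m[, 2], got_m[, 3]), ,
                   drop = FALSE]
    storage.mode(got_m) <- "integer"
    oracle <- brute_force_hbonds(sys$coords, sys$top)
    storage.mode(oracle) <- "integer"
    expect_gt(nrow(oracle), 0)
    expect_equal(unname(got_m), unname(oracle),
                 label = paste("seed", seed))
  }
})

test_that("inter-peptide backbone count series matches the construction", {
  base <- ordered_pentamer()
  tr <- generate_trajectory(base, disorder_spec(), n_frames = 2)
  s <- backbone_hbond_count_series(tr)
  expect_equal(s$hbonds, rep(nrow(base$ladder_bonds), 2))
  # full breakage removes essentially all inter-chain bonds
  tr1 <- generate_trajectory(base,
                             disorder_spec(ladder_break_fraction = 1),
                             n_frames = 3)
  expect_true(all(backbone_hbond_count_series(tr1)$hbonds == 0))
})

test_that("H-bond maps: in-register band, normalization, zero map flag", {
  base <- ordered_pentamer()
  tr <- generate_trajectory(base, disorder_spec(), n_frames = 2)
  m <- hbond_map(tr, c("A", "B"))
  expect_equal(max(m), 1)
  expect_true(all(m >= 0 & m <= 1))
  # parallel in-register ladder: all mass on the diagonal
  diag_mass <- sum(diag(unclass(m)))
  expect_equal(diag_mass, sum(m))
  expect_true(attr(m, "normalized"))
  expect_error(hbond_map(tr, c("A", "A")), "distinct")

  # C-terminal-only breakage reduces C-terminal cells, not N-terminal
  gt <- attr(tr, "ground_truth")
  base2 <- base
  cterm <- base2$ladder_bonds$residue >= 28
  tr2 <- tr
  for (f in 1:2) {
    xyz <- tr2$coords[[f]]
    hs <- base2$ladder_bonds$h_serial[cterm]
    ns <- base2$ladder_bonds$n_serial[cterm]
    xyz[hs, ] <- xyz[ns, ] + matrix(rep(c(1, 0, 0), length(hs)),
                                    ncol = 3, byrow = TRUE)
    tr2$coords[[f]] <- xyz
  }
  m2 <- hbond_map(tr2, c("A", "B"))
  expect_equal(sum(m2[28:37, 28:37]), 0)
  expect_gt(sum(m2[1:17, 1:17]), 0)

  far <- generate_trajectory(base,
                             disorder_spec(ladder_break_fraction = 1),
                             n_frames = 1)
  m0 <- hbond_map(far, c("A", "B"))
  expect_false(attr(m0, "normalized"))
  expect_true(all(m0 == 0))
})

test_that("H-bond occupancy counts the exact donor/acceptor atom pair", {
  base <- ordered_pentamer()
  tr <- generate_trajectory(base,
                            disorder_spec(ladder_break_fraction = 0.5,
                                          seed = 5), n_frames = 20)
  # the A10 -> B10 ladder bond: donor N of A:10, acceptor O of B:10
  occ <- hbond_occupancy(tr, donor = list(chain = "A", residue = 10,
                                          name = "N"),
                         acceptor = list(chain = "B", residue = 10,
                                         name = "O"), scope = "backbone")
  gt <- attr(tr, "ground_truth")
  lb <- gt$ladder_bonds
  bond_id <- which(lb$donor_chain == 1 & lb$residue == 10)
  # reconstruct per-frame survival of that bond from the seeded generator
  present <- vapply(seq_len(20), function(f) {
    hb <- detect_hbonds(tr$coords[[f]], tr$topology, "backbone")
    at <- tr$topology$atoms
    any(at$chain_id[hb$donor] == "A" & at$residue_index[hb$donor] == 10 &
          at$chain_id[hb$acceptor] == "B" &
          at$residue_index[hb$acceptor] == 10)
  }, logical(1))
  expect_equal(occ, mean(present))
  expect_gte(occ, 0.2); expect_lte(occ, 0.8)

  # always-present bond in the unperturbed template
  tr0 <- generate_trajectory(base, disorder_spec(), n_frames = 5)
  expect_equal(hbond_occupancy(tr0, list(chain = "A", residue = 10,
                                         name = "N"),
                               list(chain = "B", residue = 10, name = "O"),
                               scope = "backbone"), 1)
})
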