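# H-bond-ladder secondary-structure assignment and beta-content accounting.

test_that("ordered sheet: strand residues E, turn residues T", {
  base <- ordered_pentamer()
  lab <- assign_secondary_structure(base$coords, base$topology)
  spec <- oligomer_spec()
  for (ch in rownames(lab)) {
    expect_true(all(lab[ch, c(spec$strand1, spec$strand2)] == "E"),
                label = paste("chain", ch, "strands all E"))
    expect_true(all(lab[ch, spec$turn] %in% c("T", "C")))
  }
  expect_true(any(lab[, spec$turn] == "T"))
})

test_that("an isolated extended chain gets no E labels", {
  # single chain: no inter-strand partners, hence no bridges
  n <- 10
  name <- rep(c("N", "H", "CA", "C", "O"), n)
  xyz <- matrix(0, 5 * n, 3)
  for (i in seq_len(n)) {
    x <- 3.4 * i
    xyz[5 * i - 4, ] <- c(x - 1.2, 0, 0); xyz[5 * i - 3, ] <- c(x - 1.2, 1, 0)
    xyz[5 * i - 2, ] <- c(x, 0, 0); xyz[5 * i - 1, ] <- c(x + 1.2, 0, 0)
    xyz[5 * i, ] <- c(x + 1.2, -1, 0)
  }
  hp <- rep(NA_integer_, 5 * n)
  hp[seq(2, 5 * n, by = 5)] <- seq(1, 5 * n, by = 5)
  top <- toy_topology(name, rep(c("N", "H", "C", "C", "O"), n),
                      rep("A", 5 * n), rep(1:n, each = 5), xyz,
                      h_parent = hp, residues_per_chain = n)
  lab <- assign_secondary_structure(xyz, top)
  expect_false(any(lab %in% c("E", "B")))
})

test_that("ideal helix interior is labeled H", {
  hx <- build_ideal_helix(12)
  hb <- detect_hbonds(hx$coords, hx$top, scope = "backbone")
  # the scaffold satisfies the i -> i+4 ladder by construction
  at <- hx$top$atoms
  expect_gte(sum(at$residue_index[hb$donor] ==
                   at$residue_index[hb$acceptor] + 4), 6)
  lab <- assign_secondary_structure(hx$coords, hx$top, hb)
  expect_true(all(lab[1, 4:8] == "H"))
  expect_false(any(lab == "E"))
})

test_that("beta content arithmetic and timeline aggregation agree", {
  base <- ordered_pentamer()
  tr <- generate_trajectory(base, disorder_spec(), n_frames = 3)
  ss <- assign_ss_trajectory(tr)
  b <- beta_content(ss)
  expect_equal(b$series$beta, rep(27 / 37, 3), tolerance = 1e-12)
  expect_equal(b$sd, 0)

  tl <- ss_timeline(ss)
  expect_equal(nrow(tl), 3 * 5 * 37)
  agg <- mean(tl$label %in% c("E", "B"))
  expect_equal(agg, b$mean, tolerance = 1e-12)
  cont <- ss_content(ss)
  expect_equal(cont$beta[["mean"]] + cont$turn[["mean"]] +
                 cont$coil[["mean"]] + cont$helix[["mean"]], 1,
               tolerance = 1e-12)
  expect_equal(cont$beta[["mean"]], b$mean, tolerance = 1e-12)
})

test_that("timeline export shape and constancy for a static assignment", {
  base <- build_ordered_oligomer(oligomer_spec(n_chains = 2))
  tr <- generate_trajectory(base, disorder_spec(), n_frames = 2)
  tl <- ss_timeline(assign_ss_trajectory(tr))
  expect_equal(nrow(tl), 2 * 2 * 37)
  lab1 <- tl$label[tl$time == tl$time[1]]
  lab2 <- tl$label[tl$time != tl$time[1]]
  expect_identical(lab1, lab2)
})

test_that("assignment is invariant under global rotation and translation", {
  base <- build_ordered_oligomer(oligomer_spec(n_chains = 3))
  lab0 <- assign_secondary_structure(base$coords, base$topology)
  R <- .grid_rot(0.4, 1.1, 2.0)
  moved <- sweep(base$coords %*% t(R), 2, c(10, -4, 2), "+")
  expect_identical(assign_secondary_structure(moved, base$topology), lab0)
})

test_that("C-terminal fraying flips C-terminal strand labels, not N-terminal", {
  base <- ordered_pentamer()
  tr <- generate_trajectory(base, disorder_spec(fray_terminal = 5, seed = 3),
                            n_frames = 10)
  ss <- assign_ss_trajectory(tr)
  tl <- ss_timeline(ss)
  edge <- tl$chain %in% c("A", "E")
  cterm <- edge & tl$residue >= 33
  nterm <- edge & tl$residue <= 17
  expect_lt(mean(tl$label[cterm] == "E"), 0.6)
  expect_equal(mean(tl$label[nterm] == "E"), 1)
})

test_that("beta content is monotone in ladder breakage (mean over seeds)", {
  base <- ordered_pentamer()
  mean_beta <- function(frac) {
    mean(vapply(1:3, function(s) {
      tr <- generate_trajectory(base,
                                disorder_spec(ladder_break_fraction = frac,
                                              seed = s), n_frames = 10)
      beta_content(assign_ss_trajectory(tr))$mean
    }, numeric(1)))
  }
  b0 <- mean_beta(0); b5 <- mean_beta(0.5); b9 <- mean_beta(0.9)
  expect_gt(b0, b5)
  expect_gt(b5, b9)
  expect_gte(b0, 0.7)  # ideal sheet
})

test_that("residues missing backbone atoms are labeled C with a warning", {
  base <- build_ordered_oligomer(oligomer_spec(n_chains = 2))
  at <- base$topology$atoms
  drop <- which(at$chain_id == "A" & at$residue_index == 5 &
                  at$name == "O")
  # h_parent indices shift after dropping a row; re-infer from names
  top2 <- topology(at[-drop, ], oligotraj:::infer_h_parents(at[-drop, ]),
                   residues_per_chain = 37)
  expect_warning(assign_secondary_structure(base$coords[-drop, ], top2),
                 "missing backbone")
})
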