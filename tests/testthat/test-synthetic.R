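# Synthetic U-bend oligomer generator: construction guarantees,
# determinism, and monotone degradation under disorder.

test_that("spec validation rejects degenerate oligomers", {
  expect_error(oligomer_spec(n_chains = 1), "n_chains >= 2")
  expect_error(oligomer_spec(strand1 = 1:16), "partition")
  expect_error(disorder_spec(ladder_break_fraction = 1.2), "\\[0, 1\\]")
})

test_that("ordered template is highly aligned and fully H-bond laddered", {
  base <- ordered_pentamer()
  expect_gte(nematic_p2(base$coords, base$topology)$p2, 0.9)

  # 2-chain template: every strand residue of chain A donates or accepts
  # an inter-chain backbone H-bond under the 3.5 A / 150 deg rule
  b2 <- build_ordered_oligomer(oligomer_spec(n_chains = 2))
  hb <- detect_hbonds(b2$coords, b2$topology, scope = "backbone")
  at <- b2$topology$atoms
  inter <- at$chain_id[hb$donor] != at$chain_id[hb$acceptor]
  touched <- unique(c(
    paste(at$chain_id[hb$donor[inter]], at$residue_index[hb$donor[inter]]),
    paste(at$chain_id[hb$acceptor[inter]],
          at$residue_index[hb$acceptor[inter]])))
  spec <- oligomer_spec()
  for (r in c(spec$strand1, spec$strand2))
    expect_true(paste("A", r) %in% touched, label = paste("A", r, "bonded"))
})

test_that("trajectories are deterministic and identity at zero disorder", {
  base <- build_ordered_oligomer(oligomer_spec(n_chains = 3))
  t1 <- generate_trajectory(base, disorder_spec(10, 2, 0.3, seed = 42),
                            n_frames = 5)
  t2 <- generate_trajectory(base, disorder_spec(10, 2, 0.3, seed = 42),
                            n_frames = 5)
  expect_identical(t1$coords, t2$coords)
  t3 <- generate_trajectory(base, disorder_spec(10, 2, 0.3, seed = 43),
                            n_frames = 5)
  expect_false(identical(t1$coords, t3$coords))

  t0 <- generate_trajectory(base, disorder_spec(), n_frames = 10)
  for (f in 1:10) expect_identical(t0$coords[[f]], base$coords)
  ca <- select_atoms(base$topology, "calpha")
  expect_true(all(rmsd_series(t0, ca)$rmsd < 1e-9))
})

test_that("orientational disorder degrades P2 monotonically (mean over seeds)", {
  base <- ordered_pentamer()
  means <- vapply(c(5, 60), function(sig) {
    mean(vapply(1:5, function(s) {
      tr <- generate_trajectory(base, disorder_spec(orientation_sigma = sig,
                                                    seed = s), n_frames = 20)
      mean(p2_series(tr)$p2)
    }, numeric(1)))
  }, numeric(1))
  expect_gt(means[1], means[2])
})

test_that("ladder breakage halves the inter-chain H-bond count at 0.5", {
  base <- ordered_pentamer()
  full <- backbone_hbond_count_series(
    generate_trajectory(base, disorder_spec(), n_frames = 1))$hbonds
  tr <- generate_trajectory(base,
                            disorder_spec(ladder_break_fraction = 0.5,
                                          seed = 11), n_frames = 30)
  counts <- backbone_hbond_count_series(tr)$hbonds
  gt <- attr(tr, "ground_truth")
  # exact per-frame recovery of the constructed count
  expect_equal(counts, full - gt$broken_per_frame)
  # and within 20% of the nominal half
  expect_lt(abs(mean(counts) - 0.5 * full) / (0.5 * full), 0.2)
})

test_that("anchored ligands are placed in persistent surface contact", {
  base <- ordered_pentamer()
  tr <- generate_trajectory(base, disorder_spec(orientation_sigma = 5,
                                                seed = 2), n_frames = 15)
  pl <- ligand_placement(site = list(list(chain = "B", residue = 26)))
  tr2 <- place_ligands(tr, pl, seed = 3)
  at <- tr2$topology$atoms
  prot <- which(!at$is_ligand)
  lig <- which(at$is_ligand)
  for (f in seq_len(15)) {
    d <- tr2$coords[[f]]
    dmin <- min(as.matrix(dist(rbind(d[lig, ], d[prot, ])))[
      seq_along(lig), length(lig) + seq_along(prot)])
    expect_gte(dmin, 2.5)
  }
  prof <- contact_profile(tr2, 1)
  hit <- prof[prof$chain == "B" & prof$residue == 26, ]
  expect_gte(max(hit$p_backbone, hit$p_sidechain), 0.95)
})

test_that("ligand placement contract cases", {
  base <- build_ordered_oligomer(oligomer_spec(n_chains = 3))
  tr <- generate_trajectory(base, disorder_spec(), n_frames = 2)
  expect_identical(place_ligands(tr, ligand_placement(n_copies = 0)), tr)
  expect_error(place_ligands(tr, ligand_placement(
    site = list(list(chain = "Z", residue = 5)))), "Z:5")
})

test_that("default ligand template has donors, acceptors and flat rings", {
  tmpl <- default_ligand_template()
  expect_true(any(tmpl$atoms$element == "H" & !is.na(tmpl$h_parent)))
  expect_true(any(tmpl$atoms$element == "O"))
  for (ring in tmpl$rings) {
    idx <- match(ring, tmpl$atoms$name)
    expect_false(anyNA(idx))
    expect_lt(max(abs(tmpl$coords[idx, 3])), 1e-9)  # planar template
  }
})
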