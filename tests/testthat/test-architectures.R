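test_that("linear chains have the right bonds, angles and bond lengths", {
  set.seed(1)
  fl <- build_linear_chain(1600)
  expect_identical(fl$topology$n_beads, 1600L)
  expect_identical(nrow(fl$topology$bonds), 1599L)
  expect_null(fl$topology$angles)
  sf <- build_linear_chain(400, semiflexible = TRUE)
  expect_identical(nrow(sf$topology$bonds), 399L)
  expect_identical(nrow(sf$topology$angles), 398L)
  expect_identical(nrow(build_linear_chain(2)$topology$bonds), 1L)
  # initial coordinates: bonds at ~0.96, no hard overlaps
  p <- sf$frame$positions
  bl <- sqrt(rowSums((p[-1, ] - p[-400, ])^2))
  expect_equal(max(abs(bl - 0.96)), 0, tolerance = 1e-9)
  expect_gt(min(stats::dist(p)), 0.8)
})

test_that("star builder counts beads and bonds correctly", {
  set.seed(2)
  s3 <- build_star(3, 800)
  expect_identical(s3$topology$n_beads, 2401L)
  expect_identical(nrow(s3$topology$bonds), 2400L)
  expect_identical(build_star(12, 800)$topology$n_beads, 9601L)
  # degenerate one-arm star is a chain
  s1 <- build_star(1, 5)
  expect_identical(s1$topology$n_beads, 6L)
  expect_identical(nrow(s1$topology$bonds), 5L)
  # center bead (index 1) appears in n_arms bonds
  expect_identical(sum(s3$topology$bonds == 1L), 3L)
})

test_that("diamond microgel is a loop-free 4-coordinated network after carving", {
  dm <- build_diamond_microgel(32, 10)
  top <- dm$topology
  expect_identical(top$architecture, "diamond_microgel")
  expect_gt(dm$n_nodes, 10)
  # interior nodes are 4-coordinated; all others less
  deg <- tabulate(c(top$bonds), top$n_beads)
  expect_lte(max(deg[dm$node_beads]), 4L)
  expect_true(any(deg[dm$node_beads] == 4L))
  # strand beads always 2-coordinated or chain ends
  expect_true(all(deg >= 1L & deg <= 4L))
  # tree-likeness of the carved network: a diamond lattice has cycles,
  # but no cross-links join reactive groups of one chain (no loop records)
  expect_identical(nrow(top$crosslinks), 0L)
  # one connected component
  comp <- polycollapse:::graph_components(top$n_beads, top$bonds)
  expect_identical(max(comp), 1L)
  # bonds at the unstrained rest length
  p <- dm$frame$positions
  bl <- sqrt(rowSums((p[top$bonds[, 1], ] - p[top$bonds[, 2], ])^2))
  expect_equal(mean(bl), 0.96, tolerance = 1e-6)
  expect_error(build_diamond_microgel(1, 5))
})

test_that("mass matching: beads, nodes and strands satisfy the network identity", {
  for (cfg in list(c(16L, 6L), c(32L, 10L))) {
    dm <- build_diamond_microgel(cfg[1], cfg[2])
    n_strands <- (dm$topology$n_beads - dm$n_nodes) / cfg[2]
    expect_equal(n_strands, round(n_strands))   # complete strands only
    expect_identical(nrow(dm$topology$bonds),
                     as.integer(n_strands * (cfg[2] + 1L)))
    # interior-dominated networks approach 2 strands per node (4-coord)
    expect_gt(n_strands / dm$n_nodes, 1)
    expect_lte(n_strands / dm$n_nodes, 2)
  }
})

test_that("in-cavity synthesis reaches full conversion with valid cross-links", {
  sp <- synthesis_params(n_chains = 2, beads_per_chain = 30,
                         reactive_per_chain = 2, cavity_radius = 8,
                         seed = 12)
  out <- synthesize_disordered_microgel(sp, equil_steps = 4000L,
                                        max_sweeps = 30000L,
                                        reequil_steps = 1000L)
  rep <- out$report
  expect_equal(rep$conversion, 1)
  expect_identical(rep$n_crosslinks, 2L)   # Ncha*Nr/2
  expect_equal(rep$f, 2 / 30)
  cl <- out$topology$crosslinks
  # each reactive group cross-linked exactly once
  expect_false(any(duplicated(c(cl$i, cl$j))))
  # no duplicated bonds anywhere
  b <- out$topology$bonds
  key <- paste(pmin(b[, 1], b[, 2]), pmax(b[, 1], b[, 2]))
  expect_false(any(duplicated(key)))
  # loop flag consistent with the chain map
  ch <- out$topology$chain_of_bead
  expect_identical(cl$intra, ch[cl$i] == ch[cl$j])
})

test_that("synthesis parameters validate and report density and f", {
  expect_error(synthesis_params(n_chains = 3, reactive_per_chain = 3))
  sp <- synthesis_params()
  dens <- 3 * sp$n_chains * sp$beads_per_chain / (4 * pi * sp$cavity_radius^3)
  expect_equal(dens, 0.03, tolerance = 0.05)
  expect_equal(sp$reactive_per_chain / sp$beads_per_chain, 0.02)
})
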