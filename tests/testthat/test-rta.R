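test_that("transmission equals planted values; severed and redundant variants", {
  for (t in 0:3) {
    toy <- gen_allosteric_toy(t, pathway_length = 2, seed = 10 + t)
    tr <- rta_transmission(toy$network, toy$siteA, toy$siteB)
    expect_equal(tr$transmitted, t)
    expect_equal(tr$dof_B_before, t)
    expect_gte(tr$transmitted, 0)
    # different components -> 0
    expect_equal(rta_transmission(toy$severed, toy$siteA, toy$siteB)$transmitted, 0)
    # redundant bridge bar leaves transmission unchanged
    expect_equal(rta_transmission(toy$redundant, toy$siteA, toy$siteB)$transmitted, t)
  }
  toy <- gen_allosteric_toy(2)
  expect_error(rta_transmission(toy$network, toy$siteA, toy$siteA), "overlap")
})

test_that("transmission is 0 when the target already sits in the LRC", {
  toy <- gen_allosteric_toy(0)
  dec <- rigid_clusters(toy$network)
  b_bodies <- rigidnet:::site_bodies(toy$siteB, toy$network)
  expect_length(unique(dec$cluster_id[b_bodies]), 1)  # B inside one cluster
  expect_equal(rta_transmission(toy$network, toy$siteA, toy$siteB)$transmitted, 0)
})

test_that("exhaustive bar-insertion oracle: independent flexible linkers", {
  # A and B hang off independent flexible linkers from a common hub:
  # rigidifying A cannot remove DOF at B
  e <- function(i, j, b) data.frame(i = i, j = j, bars = as.integer(b),
                                    kind = "covalent_rotatable",
                                    energy = NA_real_)
  edges <- rbind(e(1, 2, 5),            # site A pair (1 hinge)
                 e(2, 3, 5), e(3, 4, 5),  # flexible linker to hub 4
                 e(4, 5, 5), e(5, 6, 5),  # flexible linker to B
                 e(6, 7, 5))              # site B pair (1 hinge)
  atoms <- data.frame(id = 1:7, key = residue_key("A", 1:7), name = "X",
                      element = "C", is_hetero = FALSE)
  net <- new_constraint_network(7, edges, atoms = atoms)
  A <- site_definition("A", residues = residue_key("A", 1:2))
  B <- site_definition("B", residues = residue_key("A", 6:7))
  tr <- rta_transmission(net, A, B)
  # oracle: brute-force DOF at B via the rank oracle, before and after
  # adding 6 bars inside A
  before <- rank_oracle_dof(net, seed = 1)
  rigidified <- net
  rigidified$edges <- rbind(edges, e(1, 2, 6))
  after <- rank_oracle_dof(rigidified, seed = 1)
  expect_equal(before - after, 1)  # global DOF drop = A's hinge only
  expect_equal(tr$transmitted, 0)  # none of it reaches B
})

test_that("windowed scan: indexing, planted pathway, cutoff invariance", {
  toy <- gen_allosteric_toy(2, pathway_length = 4)
  # bodies: a1=1, m=2, a2=3; a1-arm linkers 4:7, b1=8; a2-arm 9:12, b2=13
  prof <- rta_scan_profile(toy$network, toy$siteB)
  n_res <- toy$network$n_bodies
  expect_equal(nrow(prof), n_res)
  # target residues are excluded from windows (NA intensity)
  b_res <- toy$siteB$residues
  expect_true(all(is.na(prof$intensity[prof$residue %in% b_res])))
  # nonzero intensity only where windows cover the planted site-A path
  nz <- prof$residue[!is.na(prof$intensity) & prof$intensity > 0]
  expect_true(all(nz %in% residue_key("A", 1:5)))
  expect_true(residue_key("A", 2) %in% nz)
  # rigid-linker residues away from the site-A path transmit nothing
  expect_equal(prof$intensity[prof$residue == residue_key("A", 6)], 0)
  # no-hbond network: profile identical across any cutoff grid
  prof2 <- rta_scan_profile(toy$network, toy$siteB,
                            cutoffs = seq(0, -2, by = -0.5))
  expect_equal(prof2$intensity, prof$intensity)
})

test_that("window averaging follows the three-windows-per-residue rule", {
  # 5 scannable residues -> 3 windows; residue 3 averages windows {1,2,3}
  e <- function(i, j, b) data.frame(i = i, j = j, bars = as.integer(b),
                                    kind = "covalent_rotatable",
                                    energy = NA_real_)
  # chain of hinges; target = residues 6:7 appended rigidly
  edges <- rbind(e(1, 2, 5), e(2, 3, 5), e(3, 4, 5), e(4, 5, 5),
                 e(5, 6, 6), e(6, 7, 6))
  atoms <- data.frame(id = 1:7, key = residue_key("A", 1:7), name = "X",
                      element = "C", is_hetero = FALSE)
  net <- new_constraint_network(7, edges, atoms = atoms)
  B <- site_definition("B", residues = residue_key("A", 6:7))
  prof <- rta_scan_profile(net, B)
  scannable <- prof[!prof$residue %in% B$residues, ]
  expect_equal(nrow(scannable), 5)
  # recompute residue 3's intensity from the three window transmissions
  win_tr <- vapply(1:3, function(w) {
    A <- site_definition("w", residues = residue_key("A", w:(w + 2)))
    rta_transmission(net, A, B)$transmitted
  }, numeric(1))
  expect_equal(prof$intensity[prof$residue == residue_key("A", 3)],
               mean(win_tr))
  # terminal residue 1 is covered by window 1 only
  expect_equal(prof$intensity[prof$residue == residue_key("A", 1)],
               win_tr[1])
})

test_that("AUC: printed two-term formula, oracle agreement, additivity", {
  x <- seq(0, 1, length.out = 11)
  expect_equal(allosteric_auc(x, rep(3, 11))$value, 3)
  expect_equal(allosteric_auc(x, x)$value, 0.5)
  expect_equal(allosteric_auc(seq(0, 1, length.out = 57),
                              seq(0, 1, length.out = 57))$value, 0.5)
  set.seed(4)
  for (k in 1:5) {
    x <- sort(runif(40)); x <- x[!duplicated(x)]
    y <- rnorm(length(x))
    expect_equal(allosteric_auc(x, y)$value, trapezoid_oracle(x, y),
                 tolerance = 1e-12)
    # additive over contiguous sub-intervals
    m <- 17
    expect_equal(allosteric_auc(x[1:m], y[1:m])$value +
                   allosteric_auc(x[m:length(x)], y[m:length(x)])$value,
                 allosteric_auc(x, y)$value, tolerance = 1e-12)
  }
  expect_error(allosteric_auc(c(1, 0.5, 2), 1:3), "ascending")
  expect_error(allosteric_auc(1, 1), "length")
})

test_that("hotspot calling: flat profiles yield nothing, peaks are exact", {
  flat <- structure(data.frame(residue = residue_key("A", 1:20),
                               intensity = rep(2, 20), persistence = 1),
                    class = c("RTAProfile", "data.frame"))
  expect_length(call_hotspots(flat), 0)
  peak <- flat
  peak$intensity <- c(rep(0.5, 9), 6, 6, rep(0.5, 9))
  expect_equal(sort(call_hotspots(peak)),
               sort(residue_key("A", 10:11)))
  # antenna-style mask removes the peak
  expect_length(call_hotspots(peak, exclude = residue_key("A", 10:11)), 0)
  zero <- flat
  zero$intensity <- 0
  expect_warning(hs <- call_hotspots(zero), "all-zero")
  expect_length(hs, 0)
})

test_that("removing the regulatory-ligand bodies never increases transmission", {
  # positive-modulator analogue: the toy's bridge runs through 'ligand'
  # bodies; deleting them disconnects A from B, so transmission can only drop
  toy <- gen_allosteric_toy(2, pathway_length = 2)
  base <- rta_transmission(toy$network, toy$siteA, toy$siteB)$transmitted
  stripped <- toy$network
  drop_bodies <- toy$pathway_bodies[1]
  keep_edges <- !(stripped$edges$i %in% drop_bodies |
                    stripped$edges$j %in% drop_bodies)
  stripped$edges <- stripped$edges[keep_edges, , drop = FALSE]
  after <- rta_transmission(stripped, toy$siteA, toy$siteB)$transmitted
  expect_lte(after, base)
})
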