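test_that("superpose recovers constructed transforms and never reflects", {
  m <- backbone_chain(8)
  expect_equal(superpose(m, m)$rmsd, 0, tolerance = 1e-10)
  expect_equal(superpose(m, m)$rotation, diag(3), tolerance = 1e-10)

  rot <- transform_model(m, axis = c(1, 2, 0.5), angle = 25,
                         shift = c(4, -3, 7))
  fit <- superpose(m, rot)
  expect_equal(rigidnet:::rotation_angle_of(fit$rotation), 25,
               tolerance = 1e-6)
  expect_equal(fit$rmsd, 0, tolerance = 1e-8)
  # rmsd invariant to any rigid pre-transform of mobile
  rot2 <- transform_model(rot, axis = c(0, 1, 0), angle = 111,
                          shift = c(-2, 2, 9))
  expect_equal(superpose(m, rot2)$rmsd, fit$rmsd, tolerance = 1e-8)

  # reflected coordinates: returned rotation still proper, rmsd > 0
  df <- as.data.frame(m)
  df$z <- -df$z
  refl <- rigidnet:::new_structure_model(df)
  fitr <- superpose(m, refl)
  expect_equal(det(fitr$rotation), 1, tolerance = 1e-9)
  expect_gt(fitr$rmsd, 0.1)
  # SVD oracle with determinant correction gives the same rmsd
  A <- rigidnet:::model_xyz(refl)[refl$name == "CA", ]
  B <- rigidnet:::model_xyz(m)[m$name == "CA", ]
  A0 <- scale(A, scale = FALSE); B0 <- scale(B, scale = FALSE)
  sv <- svd(t(A0) %*% B0)
  R <- sv$v %*% diag(c(1, 1, sign(det(sv$v %*% t(sv$u))))) %*% t(sv$u)
  expect_equal(fitr$rmsd, sqrt(mean(rowSums((A0 %*% t(R) - B0)^2))),
               tolerance = 1e-9)

  expect_error(superpose(m, m, residues = residue_key("A", 1)), "at least 3")
})

test_that("per-residue CA rmsd isolates a displaced residue", {
  m <- backbone_chain(10)
  fit0 <- superpose(m, m)
  expect_true(all(per_residue_ca_rmsd(m, m, fit0)$deviation < 1e-10))

  df <- as.data.frame(m)
  i <- which(df$res_seq == 7 & df$name == "CA")
  df$x[i] <- df$x[i] + 2
  moved <- rigidnet:::new_structure_model(df)
  core <- residue_key("A", c(1:6, 8:10))
  fit <- superpose(m, moved, residues = core)
  prof <- per_residue_ca_rmsd(m, moved, fit)
  expect_equal(prof$deviation[prof$residue == residue_key("A", 7)], 2,
               tolerance = 1e-8)
  expect_true(all(prof$deviation[prof$residue != residue_key("A", 7)] < 1e-8))

  # permutation-invariance to atom file order
  shuf <- rigidnet:::new_structure_model(df[sample(nrow(df)), ])
  prof2 <- per_residue_ca_rmsd(m, shuf, superpose(m, shuf, residues = core))
  expect_equal(prof2$deviation[match(prof$residue, prof2$residue)],
               prof$deviation, tolerance = 1e-8)
})

test_that("residue pair distances: 3-4-5 triangle and brute force", {
  m <- toy_model(list(
    list("CA", "C", "GLY", "A", 1, c(0, 0, 0)),
    list("CA", "C", "GLY", "A", 2, c(3, 4, 0))))
  tab <- residue_pair_distances(list(one = m),
                                list(c(residue_key("A", 1), residue_key("A", 2))))
  expect_equal(tab$one, 5)

  set.seed(7)
  atoms <- unlist(lapply(1:12, function(r)
    lapply(1:4, function(k) list(paste0("C", k), "C", "ALA", "A", r,
                                 runif(3, 0, 15)))), recursive = FALSE)
  big <- toy_model(atoms)
  keys <- unique(rigidnet:::atom_residue_keys(big))
  pairs <- list(c(keys[1], keys[5]), c(keys[2], keys[9]), c(keys[3], keys[12]))
  tab <- residue_pair_distances(list(m = big), pairs)
  xyz <- rigidnet:::model_xyz(big)
  ak <- rigidnet:::atom_residue_keys(big)
  for (r in seq_along(pairs)) {
    ia <- which(ak == pairs[[r]][1]); ib <- which(ak == pairs[[r]][2])
    brute <- min(apply(expand.grid(ia, ib), 1, function(ij)
      rigidnet:::vnorm(xyz[ij[1], ] - xyz[ij[2], ])))
    expect_equal(tab$m[r], brute, tolerance = 1e-12)
  }
  expect_error(residue_pair_distances(list(m = big),
                                      list(c(keys[1], "Z:99:"))), "Z:99")
})

test_that("backbone dihedrals: trans peptide, nulls, mirror parity", {
  m <- backbone_chain(6, phi = -57, psi = -47)
  d <- backbone_dihedrals(m, residue_key("A", 3))
  expect_lt(angdiff(d[["omega"]], 180), 1e-6)
  expect_equal(d[["phi"]], -57, tolerance = 1e-6)
  expect_equal(d[["psi"]], -47, tolerance = 1e-6)
  # chain ends: phi undefined at N-terminus, psi/omega at C-terminus
  expect_true(is.na(backbone_dihedrals(m, residue_key("A", 1))[["phi"]]))
  expect_true(is.na(backbone_dihedrals(m, residue_key("A", 6))[["psi"]]))
  # mirror image negates the dihedrals
  df <- as.data.frame(m)
  df$x <- -df$x
  mm <- rigidnet:::new_structure_model(df)
  dm <- backbone_dihedrals(mm, residue_key("A", 3))
  expect_equal(dm[["phi"]], -d[["phi"]], tolerance = 1e-6)
  expect_equal(dm[["psi"]], -d[["psi"]], tolerance = 1e-6)
})

test_that("helix rotation angle recovers planted rotations", {
  hx0 <- gen_ideal_helix(20, rotation = 0)
  r0 <- helix_rotation_angle(hx0$reference, hx0$transformed,
                             hx0$helix_residues, hx0$core_residues)
  expect_lt(r0$angle, 1e-6)
  hx <- gen_ideal_helix(20, rotation = 15)
  r <- helix_rotation_angle(hx$reference, hx$transformed,
                            hx$helix_residues, hx$core_residues)
  expect_equal(r$angle, 15, tolerance = 0.5)
  expect_error(helix_rotation_angle(hx$reference, hx$transformed,
                                    hx$helix_residues[1:3],
                                    hx$core_residues), "too short")
})

test_that("buried interface area: zero when distant, spherical-cap law", {
  far <- toy_model(list(
    list("C1", "C", "LIG", "B", 1, c(60, 0, 0), het = TRUE),
    list("CA", "C", "ALA", "A", 1, c(0, 0, 0)),
    list("CB", "C", "ALA", "A", 1, c(1.5, 0, 0))))
  expect_equal(buried_interface_area(far, residue_key("B", 1))$bsa, 0)

  # two identical carbon spheres: BSA = 2 * 2 pi R (R - d/2), R = r + probe
  two <- toy_model(list(
    list("C1", "C", "LIG", "B", 1, c(0, 0, 0), het = TRUE),
    list("CA", "C", "ALA", "A", 1, c(2.5, 0, 0))))
  res <- buried_interface_area(two, residue_key("B", 1), n_points = 4000)
  R <- 1.7 + 1.4
  analytic <- 2 * 2 * pi * R * (R - 2.5 / 2)
  expect_equal(res$bsa, analytic, tolerance = 0.02 * analytic)
  expect_equal(res$half_bsa, res$bsa / 2)
})

test_that("interaction network finds hbond and pipi edges; diff(A,A) empty", {
  # lone donor-acceptor pair at near-ideal geometry -> exactly one hbond
  m <- toy_model(list(
    list("N", "N", "GLY", "A", 1, c(0, 0, 0)),
    list("CA", "C", "GLY", "A", 1, c(0.4, 0, -1.4)),
    list("H", "H", "GLY", "A", 1, c(0, 0, 1.01)),
    list("O", "O", "GLY", "A", 5, c(0, 0, 2.9)),
    list("C", "C", "GLY", "A", 5, c(1.0, 0, 3.6))))
  rin <- interaction_network(m)
  expect_equal(sum(rin$kind == "hbond"), 1)
  expect_lt(rin$energy[rin$kind == "hbond"], -1)
  expect_equal(nrow(interaction_diff(rin, rin)$added), 0)
  expect_equal(nrow(interaction_diff(rin, rin)$lost), 0)

  # two parallel six-rings, centroids 4.0 apart -> one pipi edge
  ring <- function(z, res) lapply(1:6, function(k) {
    th <- 2 * pi * k / 6
    list(c("CG", "CD1", "CE1", "CZ", "CE2", "CD2")[k], "C", "PHE", "A", res,
         c(1.4 * cos(th), 1.4 * sin(th), z))
  })
  rm <- toy_model(c(ring(0, 1), ring(4, 6)))
  rin2 <- interaction_network(rm)
  expect_equal(sum(rin2$kind == "pipi"), 1)
  # diff picks up the lost pipi edge when rings separate
  rm2 <- toy_model(c(ring(0, 1), ring(9, 6)))
  d <- interaction_diff(rin2, interaction_network(rm2))
  expect_true("pipi" %in% d$lost$kind)
})
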