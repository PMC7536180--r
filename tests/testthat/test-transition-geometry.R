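test_that("peptide geometry measures constructed internal coordinates", {
  gen <- gen_dihedral_ensemble(3, matrix(c(-60, 30, 100), 7, 3, byrow = TRUE),
                               psi = -45)
  rec <- peptide_geometry(gen$ensemble)
  # planted phi recovered to 1e-6 degrees
  m <- merge(rec, gen$truth, by = c("residue", "frame"))
  expect_lt(max(abs(m$phi.x - m$phi.y)), 1e-6)
  # default construction uses the 121.7-degree reference angle exactly
  expect_lt(max(abs(rec$angle_C1_N_CA - 121.7)), 1e-6)
  # first and last two residues of the chain are absent
  expect_setequal(unique(rec$residue), residue_key("A", 3:5))
  # ideal trans peptide: d(O-1...C) matches direct coordinate arithmetic
  f1 <- gen$ensemble$frames[[1]]
  keys <- rigidnet:::atom_residue_keys(f1)
  xyz <- rigidnet:::model_xyz(f1)
  o2 <- xyz[which(keys == residue_key("A", 2) & f1$name == "O"), ]
  c3 <- xyz[which(keys == residue_key("A", 3) & f1$name == "C"), ]
  expect_equal(rec$d_O1_C[rec$residue == residue_key("A", 3) & rec$frame == 1],
               rigidnet:::vnorm(c3 - o2), tolerance = 1e-12)
})

test_that("planted geometry (angle and distance models) is realized exactly", {
  phis <- matrix(seq(-110, 110, length.out = 20), 8, 20, byrow = TRUE)
  gen <- gen_dihedral_ensemble(20, phis, cosine_amplitude = 6,
                               quadratic_coefs = c(5e-5, 1e-4, 3.0397),
                               noise_sd = 0, seed = 5)
  rec <- peptide_geometry(gen$ensemble)
  m <- merge(rec, gen$truth, by = c("residue", "frame"))
  expect_lt(max(abs(m$angle_C1_N_CA.x - m$angle_C1_N_CA.y)), 1e-9)
  expect_lt(max(abs(m$d_O1_C - m$target_d)), 1e-9)
})

test_that("rigid-motion invariance of all internal coordinates", {
  gen <- gen_dihedral_ensemble(2, matrix(c(-70, 40), 6, 2, byrow = TRUE))
  rec <- peptide_geometry(gen$ensemble)
  moved <- new_ensemble(lapply(gen$ensemble$frames, transform_model,
                               axis = c(1, 1, 0), angle = 77,
                               shift = c(5, -9, 3)))
  rec2 <- peptide_geometry(moved)
  for (col in c("phi", "psi", "angle_C1_N_CA", "angle_O1_C1_N",
                "angle_CA1_C1_N", "d_O1_C"))
    expect_equal(rec2[[col]], rec[[col]], tolerance = 1e-9)
})

test_that("transition zone scan counts the open interval, planted occupancy", {
  rec <- data.frame(residue = c("A:1:", "A:1:", "A:1:", "A:2:"),
                    frame = c(1, 2, 3, 1),
                    phi = c(0, -36, 35 - 1e-9, -35))
  z <- transition_zone_scan(rec)
  # phi = 0 counted; -36 outside; boundary -35 excluded (open interval)
  expect_equal(z$count[z$residue == "A:1:"], 2L)
  expect_equal(z$count[z$residue == "A:2:"], 0L)

  # planted occupancies reproduced exactly, invariant to frame order
  n_frames <- 20
  phi <- matrix(80, 9, n_frames)
  phi[5, 1:12] <- 0       # residue 5: 12 frames in zone
  phi[7, 1:3] <- -20      # residue 7: 3 frames in zone
  gen <- gen_dihedral_ensemble(n_frames, phi)
  rec2 <- peptide_geometry(gen$ensemble)
  z2 <- transition_zone_scan(rec2)
  expect_equal(z2$count[z2$residue == residue_key("A", 5)], 12L)
  expect_equal(z2$count[z2$residue == residue_key("A", 7)], 3L)
  expect_equal(z2$residue[1], residue_key("A", 5))  # ranked descending
  shuffled <- rec2[sample(nrow(rec2)), ]
  expect_equal(transition_zone_scan(shuffled), z2)
})

test_that("distortion fits: noiseless recovery, Monte-Carlo, degenerate input", {
  # noiseless quadratic recovery to 1e-10, R^2 = 1
  phi <- runif(200, -150, 150)
  rec <- data.frame(residue = "A:5:", frame = seq_along(phi), phi = phi,
                    d_O1_C = 5e-5 * phi^2 + 1e-4 * phi + 3.04)
  fit <- fit_distortion_models(rec, "d_O1_C", "quadratic_in_phi")
  expect_equal(unname(fit$coefficients), c(5e-5, 1e-4, 3.04),
               tolerance = 1e-10)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  # normal equations: residuals orthogonal to the design columns
  resid <- rec$d_O1_C - (fit$coefficients["a"] * phi^2 +
                           fit$coefficients["b"] * phi +
                           fit$coefficients["c"])
  expect_lt(abs(sum(resid * phi)), 1e-8)
  expect_lt(abs(sum(resid * phi^2)), 1e-8)

  # cosine amplitude recovery within 3 s.e. at n = 500, fixed seed
  set.seed(31)
  phi2 <- runif(500, -120, 120)
  y <- 6 * cos(phi2 * pi / 120) + rnorm(500, 0, 0.5)
  rec2 <- data.frame(residue = "A:5:", frame = seq_along(phi2), phi = phi2,
                     distortion = y)
  fit2 <- fit_distortion_models(rec2, "distortion", "cosine_in_phi")
  expect_lt(abs(fit2$coefficients[["I"]] - 6), 3 * fit2$se[["I"]])

  # constant response: a, b ~ 0 and R^2 ~ 0
  rec3 <- data.frame(residue = "A:5:", frame = 1:50,
                     phi = runif(50, -150, 150), d_O1_C = 3.1)
  fit3 <- fit_distortion_models(rec3, "d_O1_C", "quadratic_in_phi")
  expect_lt(abs(fit3$coefficients[["a"]]), 1e-12)
  expect_lt(abs(fit3$coefficients[["b"]]), 1e-12)
  expect_lt(fit3$r_squared, 1e-6)

  expect_error(fit_distortion_models(rec3[1:3, ], "d_O1_C"), "at least 5")
})

test_that("end-to-end: generator + geometry + fit recover planted models", {
  set.seed(77)
  n_frames <- 120
  phi <- matrix(runif(9 * n_frames, -120, 120), 9, n_frames)
  gen <- gen_dihedral_ensemble(n_frames, phi, cosine_amplitude = 6,
                               quadratic_coefs = c(5e-5, 1e-4, 3.0397),
                               noise_sd = 0.01, seed = 13)
  rec <- peptide_geometry(gen$ensemble)
  fq <- fit_distortion_models(rec, "d_O1_C", "quadratic_in_phi")
  expect_lt(abs(fq$coefficients[["a"]] - 5e-5), 3 * fq$se[["a"]])
  expect_lt(abs(fq$coefficients[["b"]] - 1e-4), 3 * fq$se[["b"]])
  expect_lt(abs(fq$coefficients[["c"]] - 3.0397), 3 * fq$se[["c"]])
  fc <- fit_distortion_models(rec, "angle_C1_N_CA", "cosine_in_phi")
  expect_lt(abs(fc$coefficients[["I"]] - 6), 3 * fc$se[["I"]])
  expect_gt(fc$r_squared, 0.99)
})

test_that("ramachandran density: single bin, periodic wrap, uniform limit", {
  one <- data.frame(residue = "A:3:", frame = 1, phi = 12, psi = -40)
  h <- ramachandran_density(one, bins = 36)
  expect_equal(sum(h$density), 1)
  expect_equal(sum(h$density > 0), 1)
  # phi = 180 and phi = -180 land in the same bin
  two <- data.frame(residue = "A:3:", frame = 1:2, phi = c(180, -180),
                    psi = c(0, 0))
  h2 <- ramachandran_density(two, bins = 36)
  expect_equal(sum(h2$density > 0), 1)
  # uniform angles: occupancy flattens as n grows (chi-square sanity)
  set.seed(101)
  n <- 1e5; bins <- 6
  u <- data.frame(residue = "A:3:", frame = 1:n,
                  phi = runif(n, -180, 180), psi = runif(n, -180, 180))
  h3 <- ramachandran_density(u, bins = bins)
  counts <- h3$density * n
  chi2 <- sum((counts - n / bins^2)^2 / (n / bins^2))
  expect_lt(chi2, qchisq(0.999, bins^2 - 1))
  expect_gt(min(h3$density) / max(h3$density), 0.8)
})
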