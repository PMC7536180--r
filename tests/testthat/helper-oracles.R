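# Independent oracles and fixture builders used across the suite.

# Brute-force body-bar rigidity-matrix oracle: internal DOF of a network
# at a random generic placement, 6n - 6c - rank.
rank_oracle_dof <- function(net, seed = 1) {
  set.seed(seed)
  n <- net$n_bodies
  ctr <- matrix(stats::runif(3 * n, 0, 50), n, 3)
  cr <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                         a[3] * b[1] - a[1] * b[3],
                         a[1] * b[2] - a[2] * b[1])
  rows <- list()
  for (r in seq_len(nrow(net$edges))) {
    i <- net$edges$i[r]; j <- net$edges$j[r]
    for (b in seq_len(net$edges$bars[r])) {
      ai <- ctr[i, ] + stats::runif(3, -2, 2)
      aj <- ctr[j, ] + stats::runif(3, -2, 2)
      u <- aj - ai
      row <- numeric(6 * n)
      row[(6 * i - 5):(6 * i)] <- c(u, cr(ai, u))
      row[(6 * j - 5):(6 * j)] <- -c(u, cr(aj, u))
      rows[[length(rows) + 1]] <- row
    }
  }
  rk <- if (length(rows)) qr(do.call(rbind, rows), tol = 1e-7)$rank else 0L
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (r in seq_len(nrow(net$edges))) {
      i <- net$edges$i[r]; j <- net$edges$j[r]
      if (comp[i] != comp[j]) {
        cm <- min(comp[i], comp[j])
        comp[comp == comp[i] | comp == comp[j]] <- cm
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  6 * n - 6 * length(unique(comp)) - rk
}

# A random small framework (possibly multi-edge) for property tests.
random_framework <- function(seed, max_bodies = 8) {
  set.seed(seed)
  n <- sample(3:max_bodies, 1)
  ne <- sample(2:10, 1)
  ed <- data.frame(i = sample(n, ne, TRUE), j = sample(n, ne, TRUE),
                   bars = sample(c(2L, 5L, 6L), ne, TRUE))
  ed <- ed[ed$i != ed$j, , drop = FALSE]
  if (!nrow(ed)) ed <- data.frame(i = 1L, j = 2L, bars = 5L)
  new_constraint_network(
    n, data.frame(i = pmin(ed$i, ed$j), j = pmax(ed$i, ed$j),
                  bars = ed$bars, kind = "covalent_locked",
                  energy = NA_real_, stringsAsFactors = FALSE))
}

# Independently coded trapezoid rule (the oracle for allosteric_auc).
trapezoid_oracle <- function(x, y) {
  s <- 0
  for (i in 2:length(x)) s <- s + (x[i] - x[i - 1]) * (y[i] + y[i - 1]) / 2
  s
}

# Minimal StructureModel from an atom table specified as a list of
# list(name, element, res_name, chain, res_seq, xyz, het).
toy_model <- function(atoms) {
  rows <- lapply(seq_along(atoms), function(k) {
    a <- atoms[[k]]
    data.frame(serial = k, name = a[[1]], altloc = "", res_name = a[[3]],
               chain = a[[4]], res_seq = a[[5]], icode = "",
               x = a[[6]][1], y = a[[6]][2], z = a[[6]][3],
               occupancy = 1, b_factor = 0, element = a[[2]],
               is_hetero = isTRUE(a$het), stringsAsFactors = FALSE)
  })
  rigidnet:::new_structure_model(do.call(rbind, rows))
}

# Poly-alanine backbone helper built from planted dihedrals.
backbone_chain <- function(n_res, phi = -57, psi = -47) {
  gen_dihedral_ensemble(1, matrix(phi, n_res, 1), psi = psi)$ensemble$frames[[1]]
}

# Apply a rigid transform (rotation about `axis` by `angle` plus shift)
# to every atom of a model.
transform_model <- function(model, axis = c(0, 0, 1), angle = 0,
                            shift = c(0, 0, 0)) {
  R <- rigidnet:::rotation_about_axis(axis, angle)
  xyz <- rigidnet:::model_xyz(model) %*% t(R)
  xyz <- sweep(xyz, 2, shift, `+`)
  df <- as.data.frame(model)
  df$x <- xyz[, 1]; df$y <- xyz[, 2]; df$z <- xyz[, 3]
  rigidnet:::new_structure_model(df)
}

tempfile_with <- function(lines) {
  tf <- tempfile(fileext = ".pdb")
  writeLines(lines, tf)
  tf
}

angdiff <- function(a, b) {
  d <- (a - b) %% 360
  pmin(d, 360 - d)
}
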