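# Synthetic-structure generators with known ground truth: body-bar
# frameworks, ideal helices with applied rotations, two-site allosteric
# toys with planted DOF transmission, and backbone ensembles with planted
# phi trajectories and peptide-geometry distortions.

# Run fn with a locally seeded RNG, restoring the caller's RNG state.
.with_seed <- function(seed, fn) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  fn()
}

# Generic random coordinates in a box with a minimum pairwise distance,
# so pebble-game counts are compared against truly generic placements.
.generic_coords <- function(n, box = 10 * n^(1 / 3) + 10, min_dist = 1.5) {
  xyz <- matrix(NA_real_, n, 3)
  for (i in seq_len(n)) {
    repeat {
      p <- stats::runif(3, 0, box)
      if (i == 1) break
      d2 <- (xyz[1:(i - 1), 1] - p[1])^2 + (xyz[1:(i - 1), 2] - p[2])^2 +
        (xyz[1:(i - 1), 3] - p[3])^2
      if (min(d2) >= min_dist^2) break
    }
    xyz[i, ] <- p
  }
  xyz
}

#' Generate a body-bar framework with known degree-of-freedom count
#'
#' Topologies: "chain" (path), "ring" (cycle), "tree" (random tree), or
#' "custom" (explicit edge list). Generic coordinates are attached as
#' `$xyz` for rank-oracle comparisons. The analytic ground truth uses the
#' generic body-bar count: independent bars = min(6n - 6, sum of per-pair
#' bars capped at 6), internal DOF = 6n - 6 - independent, redundant =
#' total - independent (valid for these path/cycle/tree graphs and extra
#' chords across existing pairs).
#'
#' @param topology "chain", "ring", "tree" or "custom"
#' @param n_bodies number of bodies
#' @param bars bars per edge (2, 5 or 6; default 5)
#' @param edges for "custom": data.frame with i, j, bars
#' @param extra_edges optional additional data.frame(i, j, bars) chords
#' @param seed RNG seed (default 1)
#' @return list with `network` (`ConstraintNetwork`, coordinates in
#'   `$xyz`), `expected_internal_dof`, `expected_redundant`
#' @export
gen_body_bar_framework <- function(topology = c("chain", "ring", "tree", "custom"),
                                   n_bodies, bars = 5L, edges = NULL,
                                   extra_edges = NULL, seed = 1) {
  topology <- match.arg(topology)
  stopifnot(n_bodies >= 2)
  .with_seed(seed, function() {
    base <- switch(topology,
      chain = data.frame(i = 1:(n_bodies - 1), j = 2:n_bodies, bars = bars),
      ring = data.frame(i = 1:n_bodies,
                        j = c(2:n_bodies, 1L), bars = bars),
      tree = {
        parent <- c(NA, vapply(2:n_bodies, function(i)
          if (i == 2) 1L else sample.int(i - 1, 1), integer(1)))
        data.frame(i = parent[-1], j = 2:n_bodies, bars = bars)
      },
      custom = {
        if (is.null(edges)) stop("custom topology needs an edge list")
        edges
      })
    if (!is.null(extra_edges)) base <- rbind(base, extra_edges)
    base$bars <- as.integer(base$bars)
    if (!all(base$bars %in% c(2L, 5L, 6L)))
      stop("invalid framework spec: bars must be 2, 5 or 6")
    if (any(base$i == base$j)) stop("invalid framework spec: self-edge")
    pair <- paste(pmin(base$i, base$j), pmax(base$i, base$j))
    per_pair <- tapply(base$bars, pair, sum)
    independent <- min(6 * n_bodies - 6, sum(pmin(per_pair, 6)))
    total <- sum(base$bars)
    kinds <- c("2" = "hydrophobic", "5" = "covalent_rotatable",
               "6" = "covalent_locked")
    net <- new_constraint_network(
      n_bodies,
      data.frame(i = pmin(base$i, base$j), j = pmax(base$i, base$j),
                 bars = base$bars, kind = kinds[as.character(base$bars)],
                 energy = NA_real_, stringsAsFactors = FALSE),
      source_label = paste0("synthetic_", topology))
    net$xyz <- .generic_coords(n_bodies)
    list(network = net,
         expected_internal_dof = 6L * n_bodies - 6L - independent,
         expected_redundant = total - independent)
  })
}

#' Generate an ideal helix pair with a planted axis rotation
#'
#' Builds two parallel poly-alanine-like backbones (N, CA, C, O on an
#' ideal helical lattice): a static core helix (chain C) and a mobile
#' helix (chain H) 12 Angstrom away. The transformed copy has chain H
#' rotated by `rotation` about its own helix axis while the
#' core is untouched, mirroring a core-superposed helix-rotation
#' measurement.
#'
#' @param n_res residues per helix (>= 6)
#' @param rise rise per residue, Angstrom (default 1.5)
#' @param twist twist per residue, degrees (default 100)
#' @param rotation planted rotation about the mobile helix axis, degrees (default 0)
#' @return list with `reference`, `transformed` (`StructureModel`s),
#'   `axis` (unit vector), `core_residues`, `helix_residues`
#' @export
gen_ideal_helix <- function(n_res, rise = 1.5, twist = 100,
                            rotation = 0) {
  stopifnot(n_res >= 6)
  one_helix <- function(chain, x0) {
    rows <- list()
    for (k in seq_len(n_res)) {
      th <- rad(twist) * (k - 1)
      z <- rise * (k - 1)
      ca <- c(x0 + 2.3 * cos(th), 2.3 * sin(th), z)
      nn <- c(x0 + 1.6 * cos(th - rad(26)), 1.6 * sin(th - rad(26)), z - 0.9)
      cc <- c(x0 + 1.7 * cos(th + rad(26)), 1.7 * sin(th + rad(26)), z + 0.9)
      oo <- cc + c(0.4 * cos(th + rad(80)), 0.4 * sin(th + rad(80)), 1.1)
      for (at in list(list("N", "N", nn), list("CA", "C", ca),
                      list("C", "C", cc), list("O", "O", oo)))
        rows[[length(rows) + 1]] <- data.frame(
          serial = length(rows) + 1L, name = at[[1]], altloc = "",
          res_name = "ALA", chain = chain, res_seq = k, icode = "",
          x = at[[3]][1], y = at[[3]][2], z = at[[3]][3],
          occupancy = 1, b_factor = 0, element = at[[2]],
          is_hetero = FALSE, stringsAsFactors = FALSE)
    }
    do.call(rbind, rows)
  }
  core <- one_helix("C", 0)
  mobile <- one_helix("H", 12)
  reference <- new_structure_model(rbind(core, mobile))
  moved <- mobile
  if (rotation != 0) {
    ctr <- c(12, 0, 0)
    R <- rotation_about_axis(c(0, 0, 1), rotation)
    xyz <- sweep(as.matrix(mobile[, c("x", "y", "z")]), 2, ctr)
    xyz <- sweep(xyz %*% t(R), 2, ctr, `+`)
    moved$x <- xyz[, 1]; moved$y <- xyz[, 2]; moved$z <- xyz[, 3]
  }
  transformed <- new_structure_model(rbind(core, moved))
  list(reference = reference, transformed = transformed,
       axis = c(0, 0, 1),
       core_residues = residue_key("C", seq_len(n_res)),
       helix_residues = residue_key("H", seq_len(n_res)))
}

#' Generate a two-site network with planted rigidity transmission
#'
#' Site A is a path a1 - m1 - ... - mt - a2 of `transmission_dof` 5-bar
#' hinge edges (each hinge one internal torsion); site B is a body pair
#' {b1, b2} with b1 rigidly linked (6-bar chains of `pathway_length`
#' bodies) to a1 and b2 to a2. The DOF available at B equals the planted
#' value, and rigidifying A removes exactly all of it. A severed variant
#' (one linker edge removed, so B's component is disconnected from part
#' of A) and a redundant variant (an extra 6-bar chord across a rigid
#' linker pair) are also returned.
#'
#' @param transmission_dof planted transmitted DOF (>= 0)
#' @param pathway_length bodies per rigid linker arm (default 2)
#' @param seed RNG seed for the generic coordinates (default 1)
#' @return list with `network`, `severed`, `redundant`, `siteA`, `siteB`,
#'   `transmission`
#' @export
gen_allosteric_toy <- function(transmission_dof = 2, pathway_length = 2,
                               seed = 1) {
  t <- as.integer(transmission_dof)
  stopifnot(t >= 0, pathway_length >= 1)
  # bodies: a1, hinge intermediates (t-1 of them when t >= 2), a2,
  # linker1 (pathway_length), b1, linker2 (pathway_length), b2
  n_mid <- max(0L, t - 1L)
  a1 <- 1L
  mids <- if (n_mid) a1 + seq_len(n_mid) else integer()
  a2 <- a1 + n_mid + 1L
  link1 <- a2 + seq_len(pathway_length)
  b1 <- max(link1) + 1L
  link2 <- b1 + seq_len(pathway_length)
  b2 <- max(link2) + 1L
  n <- b2
  e <- function(i, j, bars) data.frame(i = i, j = j, bars = as.integer(bars))
  a_path <- c(a1, mids, a2)
  edges <- list()
  if (t == 0) {
    edges[[1]] <- e(a1, a2, 6L)
  } else {
    for (k in seq_len(length(a_path) - 1))
      edges[[length(edges) + 1]] <- e(a_path[k], a_path[k + 1], 5L)
  }
  arm1 <- c(a1, link1, b1)
  arm2 <- c(a2, link2, b2)
  for (arm in list(arm1, arm2))
    for (k in seq_len(length(arm) - 1))
      edges[[length(edges) + 1]] <- e(arm[k], arm[k + 1], 6L)
  edges <- do.call(rbind, edges)
  kinds <- c("5" = "covalent_rotatable", "6" = "covalent_locked")
  mk_net <- function(ed, label) {
    # residue back-map: one residue per body, chain A, in body order
    atoms <- data.frame(id = seq_len(n), key = residue_key("A", seq_len(n)),
                        name = "X", element = "C", is_hetero = FALSE,
                        stringsAsFactors = FALSE)
    net <- new_constraint_network(
      n, data.frame(i = pmin(ed$i, ed$j), j = pmax(ed$i, ed$j),
                    bars = ed$bars, kind = kinds[as.character(ed$bars)],
                    energy = NA_real_, stringsAsFactors = FALSE),
      atoms = atoms, source_label = label)
    net$xyz <- .with_seed(seed, function() .generic_coords(n))
    net
  }
  network <- mk_net(edges, "allosteric_toy")
  severed <- mk_net(edges[-(nrow(edges)), , drop = FALSE], "allosteric_toy_severed")
  redundant <- mk_net(rbind(edges, e(arm1[1], arm1[2], 6L)),
                      "allosteric_toy_redundant")
  siteA <- site_definition("siteA", residues = residue_key("A", a_path))
  siteB <- site_definition("siteB", residues = residue_key("A", c(b1, b2)))
  list(network = network, severed = severed, redundant = redundant,
       siteA = siteA, siteB = siteB, transmission = t,
       pathway_bodies = sort(c(link1, link2)))
}

# ---- backbone ensembles with planted dihedrals ---------------------------

# Build one backbone frame (N, CA, C, O per residue) realizing the given
# phi/psi exactly (omega fixed trans), with optional per-residue override
# of the C(-1)-N-CA angle and of the O(-1)...C distance.
.build_backbone_frame <- function(phi, psi, angle_C1_N_CA = NULL,
                                  target_d = NULL) {
  n <- length(phi)
  stopifnot(length(psi) == n)
  if (is.null(angle_C1_N_CA)) angle_C1_N_CA <- rep(121.7, n)
  N <- CA <- C <- O <- matrix(NA_real_, n, 3)
  N[1, ] <- c(0, 0, 0)
  CA[1, ] <- c(1.458, 0, 0)
  C[1, ] <- CA[1, ] + 1.525 * c(cos(rad(180 - 111.2)), sin(rad(180 - 111.2)), 0)
  for (i in 2:n) {
    N[i, ] <- place_atom(N[i - 1, ], CA[i - 1, ], C[i - 1, ], 1.329, 116.2,
                         psi[i - 1])
    CA[i, ] <- place_atom(CA[i - 1, ], C[i - 1, ], N[i, ], 1.458,
                          angle_C1_N_CA[i], 180)
    C[i, ] <- place_atom(C[i - 1, ], N[i, ], CA[i, ], 1.525, 111.2, phi[i])
    O[i - 1, ] <- place_atom(N[i - 1, ], CA[i - 1, ], C[i - 1, ], 1.231,
                             120.8, psi[i - 1] + 180)
  }
  O[n, ] <- place_atom(N[n, ], CA[n, ], C[n, ], 1.231, 120.8, psi[n] + 180)
  # realize planted O(-1)...C distances: keep the C(-1)=O bond length and
  # move O(i-1) on its bond sphere to the point with the requested
  # distance to C(i) nearest the ideal placement (distances outside the
  # sphere-intersection range are clamped to the nearest endpoint)
  if (!is.null(target_d)) {
    r_co <- 1.231
    for (i in seq_len(n)) {
      if (!is.finite(target_d[i]) || i < 2) next
      cc <- C[i - 1, ]
      D <- vnorm(C[i, ] - cc)
      tgt <- min(max(target_d[i], D - r_co + 1e-6), D + r_co - 1e-6)
      u <- unit(C[i, ] - cc)
      ca <- (D^2 + r_co^2 - tgt^2) / (2 * D * r_co)
      v <- O[i - 1, ] - cc
      w_raw <- v - sum(v * u) * u
      w <- if (vnorm(w_raw) > 1e-9) unit(w_raw) else {
        ref <- CA[i - 1, ] - cc
        unit(ref - sum(ref * u) * u)
      }
      O[i - 1, ] <- cc + r_co * (ca * u + sqrt(max(0, 1 - ca^2)) * w)
    }
  }
  rows <- list()
  for (i in seq_len(n)) {
    for (at in list(list("N", "N", N[i, ]), list("CA", "C", CA[i, ]),
                    list("C", "C", C[i, ]), list("O", "O", O[i, ])))
      rows[[length(rows) + 1]] <- data.frame(
        serial = length(rows) + 1L, name = at[[1]], altloc = "",
        res_name = "ALA", chain = "A", res_seq = i, icode = "",
        x = at[[3]][1], y = at[[3]][2], z = at[[3]][3],
        occupancy = 1, b_factor = 0, element = at[[2]],
        is_hetero = FALSE, stringsAsFactors = FALSE)
  }
  new_structure_model(do.call(rbind, rows))
}

#' Generate a backbone ensemble with planted dihedrals and distortions
#'
#' Builds `n_frames` backbone conformers realizing a planted phi
#' trajectory exactly (NeRF internal-coordinate construction, trans
#' peptide). Optionally plants a cosine distortion of the C(-1)-N-CA bond
#' angle, angle = 121.7 + I cos(phi pi / 120) + N(0, noise_sd), and/or a
#' quadratic O(-1)...C distance, d = a phi^2 + b phi + c + N(0, noise_sd)
#' (realized by rotating the preceding carbonyl oxygen about its CA-C
#' axis).
#'
#' @param n_frames number of frames
#' @param phi_trajectory n_res x n_frames matrix of planted phi (degrees)
#' @param psi fixed psi value or n_res vector (default -45)
#' @param cosine_amplitude amplitude I of the planted angle distortion
#'   (NULL = none)
#' @param quadratic_coefs c(a, b, c) of the planted distance model
#'   (NULL = none)
#' @param noise_sd Gaussian noise sd applied to the planted responses
#'   (default 0)
#' @param seed RNG seed
#' @return list with `ensemble` and `truth` (data.frame: residue, frame,
#'   phi, angle_C1_N_CA, target_d)
#' @export
gen_dihedral_ensemble <- function(n_frames, phi_trajectory, psi = -45,
                                  cosine_amplitude = NULL,
                                  quadratic_coefs = NULL,
                                  noise_sd = 0, seed = 1) {
  phi_trajectory <- as.matrix(phi_trajectory)
  n_res <- nrow(phi_trajectory)
  stopifnot(ncol(phi_trajectory) == n_frames, n_res >= 2)
  psi <- rep(psi, length.out = n_res)
  .with_seed(seed, function() {
    frames <- vector("list", n_frames)
    truth <- list()
    for (f in seq_len(n_frames)) {
      phi <- phi_trajectory[, f]
      ang <- rep(121.7, n_res)
      if (!is.null(cosine_amplitude))
        ang <- 121.7 + cosine_amplitude * cos(phi * pi / 120) +
          stats::rnorm(n_res, 0, noise_sd)
      td <- rep(NA_real_, n_res)
      if (!is.null(quadratic_coefs))
        td <- quadratic_coefs[1] * phi^2 + quadratic_coefs[2] * phi +
          quadratic_coefs[3] + stats::rnorm(n_res, 0, noise_sd)
      frames[[f]] <- .build_backbone_frame(phi, psi, ang, td)
      truth[[f]] <- data.frame(residue = residue_key("A", seq_len(n_res)),
                               frame = f, phi = phi, angle_C1_N_CA = ang,
                               target_d = td, stringsAsFactors = FALSE)
    }
    list(ensemble = new_ensemble(frames, frame_times = 10 * seq_len(n_frames)),
         truth = do.call(rbind, truth))
  })
}
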