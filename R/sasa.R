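# Solvent-accessible surface area (Shrake-Rupley) and ligand buried
# interface area.

# Near-uniform unit sphere points (golden-spiral / Fibonacci lattice).
sphere_points <- function(n = 960) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(cos(theta) * sin(phi), sin(theta) * sin(phi), cos(phi))
}

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' Computed on expanded spheres of radius vdW + probe (Bondi radii);
#' reported per atom as 4 pi (r + probe)^2 times the accessible fraction.
#'
#' @param xyz n x 3 coordinate matrix
#' @param elements element symbols (length n)
#' @param probe probe radius, Angstrom (default 1.4)
#' @param n_points sphere test points per atom (default 960)
#' @return numeric vector of per-atom SASA (Angstrom^2)
#' @export
shrake_rupley_sasa <- function(xyz, elements, probe = 1.4, n_points = 960) {
  n <- nrow(xyz)
  R <- vdw_radius(elements) + probe
  pts <- sphere_points(n_points)
  out <- numeric(n)
  maxR <- max(R)
  for (i in seq_len(n)) {
    d2 <- rowSums(sweep(xyz, 2, xyz[i, ])^2)
    nb <- which(d2 < (R[i] + maxR)^2 & seq_len(n) != i)
    nb <- nb[d2[nb] < (R[i] + R[nb])^2]
    p <- sweep(pts * R[i], 2, xyz[i, ], `+`)
    acc <- rep(TRUE, n_points)
    for (j in nb) {
      dd <- (p[, 1] - xyz[j, 1])^2 + (p[, 2] - xyz[j, 2])^2 +
        (p[, 3] - xyz[j, 3])^2
      acc <- acc & dd > R[j]^2
      if (!any(acc)) break
    }
    out[i] <- 4 * pi * R[i]^2 * sum(acc) / n_points
  }
  out
}

#' Buried interface area between a ligand and the protein
#'
#' BSA = SASA(protein alone) + SASA(ligand alone) - SASA(complex), using
#' Shrake-Rupley with Bondi radii. The full buried area is the headline
#' value; the per-side convention (half of it) is reported alongside.
#'
#' @param model a `StructureModel` containing the ligand
#' @param ligand residue key of the ligand
#' @param probe probe radius (default 1.4 Angstrom)
#' @param n_points sphere points (default 960)
#' @return list with `bsa` (Angstrom^2), `half_bsa`, and the three SASA
#'   totals
#' @export
buried_interface_area <- function(model, ligand, probe = 1.4, n_points = 960) {
  lig_idx <- residue_atom_idx(model, ligand)
  pro_idx <- setdiff(seq_len(nrow(model)), lig_idx)
  xyz <- model_xyz(model)
  s_complex <- sum(shrake_rupley_sasa(xyz, model$element, probe, n_points))
  s_pro <- sum(shrake_rupley_sasa(xyz[pro_idx, , drop = FALSE],
                                  model$element[pro_idx], probe, n_points))
  s_lig <- sum(shrake_rupley_sasa(xyz[lig_idx, , drop = FALSE],
                                  model$element[lig_idx], probe, n_points))
  bsa <- s_pro + s_lig - s_complex
  list(bsa = bsa, half_bsa = bsa / 2, sasa_protein = s_pro,
       sasa_ligand = s_lig, sasa_complex = s_complex)
}
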