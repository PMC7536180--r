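# Conformer comparison: Kabsch superposition, per-residue RMSD, residue
# pair distances, backbone dihedrals, and helix rotation angles.

# Matched coordinate pairs for a selection (residue keys + atom-name filter).
.paired_coords <- function(ref, mobile, residues = NULL, atom_names = "CA") {
  kr <- atom_residue_keys(ref); km <- atom_residue_keys(mobile)
  sel_r <- if (is.null(atom_names)) rep(TRUE, nrow(ref)) else ref$name %in% atom_names
  sel_m <- if (is.null(atom_names)) rep(TRUE, nrow(mobile)) else mobile$name %in% atom_names
  if (!is.null(residues)) {
    sel_r <- sel_r & kr %in% residues
    sel_m <- sel_m & km %in% residues
  }
  idr <- paste(kr, ref$name)[sel_r]
  idm <- paste(km, mobile$name)[sel_m]
  common <- intersect(idr, idm)
  ir <- which(sel_r)[match(common, idr)]
  im <- which(sel_m)[match(common, idm)]
  list(ref = model_xyz(ref)[ir, , drop = FALSE],
       mobile = model_xyz(mobile)[im, , drop = FALSE], ids = common)
}

#' Optimal rigid superposition (Kabsch)
#'
#' Least-squares proper rotation + translation mapping `mobile` onto `ref`
#' over a paired atom selection. A reflection is never returned: the SVD
#' determinant correction guarantees det(rotation) = +1.
#'
#' @param ref,mobile `StructureModel`s sharing residue numbering
#' @param residues optional residue-key subset
#' @param atom_names atom-name filter (default "CA"); NULL for all atoms
#' @return object of class `SuperpositionResult`: list with `rotation`
#'   (3x3), `translation` (length 3), `rmsd` (Angstrom), `selection_size`
#' @export
superpose <- function(ref, mobile, residues = NULL, atom_names = "CA") {
  pc <- .paired_coords(ref, mobile, residues, atom_names)
  kabsch_fit(pc$mobile, pc$ref)
}

# Matrix-level Kabsch: optimal proper rotation R and translation t with
# sweep(A %*% t(R), 2, t, "+") approximating B.
kabsch_fit <- function(A, B) {
  n <- nrow(A)
  if (n < 3) stop("superposition needs at least 3 paired atoms, got ", n)
  ca <- colMeans(A); cb <- colMeans(B)
  A0 <- sweep(A, 2, ca); B0 <- sweep(B, 2, cb)
  sv <- svd(crossprod(A0, B0))
  if (sv$d[2] < 1e-9 * max(sv$d[1], 1))
    stop("degenerate (collinear) selection: superposition undefined")
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  t_vec <- cb - as.vector(R %*% ca)
  moved <- sweep(A %*% t(R), 2, t_vec, `+`)
  rmsd <- sqrt(mean(rowSums((moved - B)^2)))
  structure(list(rotation = R, translation = t_vec, rmsd = rmsd,
                 selection_size = n),
            class = "SuperpositionResult")
}

#' @export
print.SuperpositionResult <- function(x, ...) {
  cat(sprintf("SuperpositionResult: %d atoms, rmsd %.3f A, rotation %.2f deg\n",
              x$selection_size, x$rmsd, rotation_angle_of(x$rotation)))
  invisible(x)
}

#' Apply a superposition transform to a model
#' @param model a `StructureModel`
#' @param fit a `SuperpositionResult`
#' @return the transformed model
#' @export
apply_superposition <- function(model, fit) {
  xyz <- model_xyz(model) %*% t(fit$rotation)
  model_xyz(model) <- sweep(xyz, 2, fit$translation, `+`)
  model
}

#' Per-residue C-alpha deviation after superposition
#'
#' @param ref,mobile `StructureModel`s
#' @param fit `SuperpositionResult` computed on a core selection
#' @return `RMSDProfile`: data.frame with residue key and deviation
#'   (Angstrom) over residues common to both models; residues lacking a
#'   CA are omitted with a warning
#' @export
per_residue_ca_rmsd <- function(ref, mobile, fit) {
  mobile <- apply_superposition(mobile, fit)
  pc <- .paired_coords(ref, mobile, NULL, "CA")
  keys_all <- union(model_residues(ref, protein_only = TRUE),
                    model_residues(mobile, protein_only = TRUE))
  keys <- sub(" CA$", "", pc$ids)
  miss <- setdiff(keys_all, keys)
  if (length(miss))
    warning(length(miss), " residue(s) lacking a paired CA omitted")
  dev <- sqrt(rowSums((pc$ref - pc$mobile)^2))
  structure(data.frame(residue = keys, deviation = dev,
                       stringsAsFactors = FALSE),
            class = c("RMSDProfile", "data.frame"))
}

#' Residue-residue distances across labeled conformers
#'
#' One row per residue pair with per-state distance and, when states named
#' "open" and "closed" are both present, the open/closed ratio.
#'
#' @param models named list of `StructureModel`s (names are state labels)
#' @param pairs list of length-2 character vectors of residue keys
#' @param metric "min_heavy" (default: minimum heavy-atom distance) or "ca"
#' @return `DistanceTable` data.frame
#' @export
residue_pair_distances <- function(models, pairs, metric = c("min_heavy", "ca")) {
  metric <- match.arg(metric)
  one <- function(model, a, b) {
    ia <- residue_atom_idx(model, a); ib <- residue_atom_idx(model, b)
    if (metric == "ca") {
      ia <- ia[model$name[ia] == "CA"]; ib <- ib[model$name[ib] == "CA"]
    } else {
      ia <- ia[model$element[ia] != "H"]; ib <- ib[model$element[ib] != "H"]
    }
    if (!length(ia) || !length(ib))
      stop("no atoms for metric '", metric, "' in pair ", a, " - ", b)
    xa <- model_xyz(model)[ia, , drop = FALSE]
    xb <- model_xyz(model)[ib, , drop = FALSE]
    sqrt(min(outer(rowSums(xa^2), rowSums(xb^2), `+`) - 2 * xa %*% t(xb)))
  }
  rows <- lapply(pairs, function(p) {
    d <- vapply(models, one, numeric(1), a = p[1], b = p[2])
    r <- data.frame(res_a = p[1], res_b = p[2], metric = metric,
                    stringsAsFactors = FALSE)
    for (nm in names(models)) r[[nm]] <- d[[nm]]
    if (all(c("open", "closed") %in% names(models)))
      r$ratio_open_closed <- d[["open"]] / d[["closed"]]
    r
  })
  structure(do.call(rbind, rows), class = c("DistanceTable", "data.frame"))
}

#' Backbone dihedrals of one residue
#'
#' IUPAC sign convention, range (-180, 180]. Angles whose flanking-residue
#' atoms are absent are returned as NA.
#'
#' @param model a `StructureModel`
#' @param residue residue key
#' @return named numeric vector c(phi, psi, omega) in degrees
#' @export
backbone_dihedrals <- function(model, residue) {
  keys <- model_residues(model)
  ri <- match(residue, keys)
  if (is.na(ri)) stop("residue key not found: ", residue)
  rk <- parse_residue_key(keys)
  prev <- if (ri > 1 && rk$chain[ri - 1] == rk$chain[ri]) keys[ri - 1] else NA
  nxt <- if (ri < length(keys) && rk$chain[ri + 1] == rk$chain[ri]) keys[ri + 1] else NA
  g <- function(key, nm) {
    if (is.na(key)) return(NULL)
    i <- named_atom_idx(model, key, nm)
    if (is.na(i)) NULL else model_xyz(model)[i, ]
  }
  N <- g(residue, "N"); CA <- g(residue, "CA"); C <- g(residue, "C")
  Cp <- g(prev, "C"); Nn <- g(nxt, "N"); CAn <- g(nxt, "CA")
  dih <- function(a, b, c, d)
    if (is.null(a) || is.null(b) || is.null(c) || is.null(d)) NA_real_
    else dihedral_angle(a, b, c, d)
  c(phi = dih(Cp, N, CA, C), psi = dih(N, CA, C, Nn),
    omega = dih(CA, C, Nn, CAn))
}

#' Helix rotation angle between two conformers
#'
#' After superposing `other` onto `apo` over a core selection, fits the
#' helix axis through the apo helix C-alphas (curvature-based
#' construction, exact for ideal helices; see `helix_axis`),
#' computes the optimal rigid transform taking the apo helix onto the
#' superposed other-helix, and reports the twist component of that rotation
#' about the apo axis. Sense is judged viewing down the axis from the
#' N-terminal end: positive right-handed twist about the N-to-C axis
#' appears clockwise from that vantage point.
#'
#' @param apo,other `StructureModel`s
#' @param helix residue keys of the helix (>= 6 residues with CA)
#' @param core residue keys of the superposition core
#' @return `HelixRotation` list: `angle` (degrees, 0..180), `sense`
#'   ("clockwise"/"anticlockwise"), `axis`, `fit`
#' @export
helix_rotation_angle <- function(apo, other, helix, core) {
  fit <- superpose(apo, other, residues = core, atom_names = "CA")
  other_s <- apply_superposition(other, fit)
  pc <- .paired_coords(apo, other_s, residues = helix, atom_names = "CA")
  if (nrow(pc$ref) < 6) stop("helix too short: ", nrow(pc$ref), " paired CA")
  ax <- helix_axis(pc$ref)
  hel_fit <- kabsch_fit(pc$ref, pc$mobile)
  tw <- twist_about_axis(hel_fit$rotation, ax$axis)
  structure(list(angle = abs(tw),
                 sense = if (tw >= 0) "clockwise" else "anticlockwise",
                 axis = ax$axis, fit = hel_fit),
            class = "HelixRotation")
}

#' @export
print.HelixRotation <- function(x, ...) {
  cat(sprintf("HelixRotation: %.2f deg (%s)\n", x$angle, x$sense))
  invisible(x)
}
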