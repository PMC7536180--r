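# Elastic network models: Gaussian (GNM) and anisotropic (ANM), with mode
# statistics (frequency dispersion, collectivity), sign-based domain
# splitting with hinge prediction, and mode-overlap analysis.

.ca_nodes <- function(model) {
  idx <- which(model$name == "CA" & !model$is_hetero)
  if (!length(idx)) stop("model has no C-alpha atoms")
  list(idx = idx, xyz = model_xyz(model)[idx, , drop = FALSE],
       keys = atom_residue_keys(model)[idx])
}

new_mode_set <- function(values, vectors, n_zero, kind, cutoff, keys, xyz) {
  structure(list(eigenvalues = values, eigenvectors = vectors,
                 n_zero_modes = n_zero, model_kind = kind, cutoff = cutoff,
                 nodes = keys, node_xyz = xyz),
            class = "ModeSet")
}

#' @export
print.ModeSet <- function(x, ...) {
  cat(sprintf("ModeSet (%s, cutoff %.1f A): %d nodes, %d zero modes\n",
              x$model_kind, x$cutoff, length(x$nodes), x$n_zero_modes))
  invisible(x)
}

.zero_mode_count <- function(values, tol = 1e-8) {
  sum(values < tol * max(abs(values), 1))
}

#' Gaussian network model modes
#'
#' Unit-spring Kirchhoff matrix over C-alpha nodes within `cutoff`;
#' eigenvalues ascending. Zero modes (one per connected component) are
#' excluded from global-mode numbering.
#'
#' @param model a `StructureModel` with >= 2 C-alpha atoms
#' @param cutoff contact cutoff in Angstrom (default 7.3)
#' @return a `ModeSet`
#' @export
gnm_modes <- function(model, cutoff = 7.3) {
  nd <- .ca_nodes(model)
  n <- nrow(nd$xyz)
  if (n < 2) stop("GNM needs at least 2 C-alpha nodes")
  D2 <- as.matrix(stats::dist(nd$xyz))^2
  K <- -(D2 <= cutoff^2) * 1
  diag(K) <- 0
  diag(K) <- -rowSums(K)
  e <- eigen(K, symmetric = TRUE)
  values <- rev(e$values); vectors <- e$vectors[, n:1, drop = FALSE]
  values[values < 0 & values > -1e-10] <- 0
  new_mode_set(values, vectors, .zero_mode_count(values), "GNM", cutoff,
               nd$keys, nd$xyz)
}

#' Anisotropic network model modes
#'
#' Standard 3N ANM Hessian with unit force constant; a connected,
#' non-degenerate structure has exactly 6 zero modes.
#'
#' @param model a `StructureModel` with >= 3 non-collinear C-alpha atoms
#' @param cutoff contact cutoff in Angstrom (default 15)
#' @return a `ModeSet` (eigenvectors are 3N x 3N, node-major x,y,z)
#' @export
anm_modes <- function(model, cutoff = 15) {
  nd <- .ca_nodes(model)
  n <- nrow(nd$xyz)
  if (n < 3) stop("ANM needs at least 3 C-alpha nodes")
  H <- matrix(0, 3 * n, 3 * n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    d <- nd$xyz[j, ] - nd$xyz[i, ]
    r2 <- sum(d * d)
    if (r2 > cutoff^2) next
    blk <- -outer(d, d) / r2
    ri <- (3 * i - 2):(3 * i); rj <- (3 * j - 2):(3 * j)
    H[ri, rj] <- blk; H[rj, ri] <- blk
    H[ri, ri] <- H[ri, ri] - blk; H[rj, rj] <- H[rj, rj] - blk
  }
  e <- eigen(H, symmetric = TRUE)
  values <- rev(e$values); vectors <- e$vectors[, (3 * n):1, drop = FALSE]
  values[values < 0 & values > -1e-9] <- 0
  nz <- .zero_mode_count(values)
  if (nz > 6) warning("degenerate geometry: ", nz, " near-zero ANM modes")
  new_mode_set(values, vectors, nz, "ANM", cutoff, nd$keys, nd$xyz)
}

# Index into the eigen arrays of the k-th global (nontrivial) mode.
.global_mode_col <- function(modes, mode_index) {
  stopifnot(mode_index >= 1)
  col <- modes$n_zero_modes + mode_index
  if (col > length(modes$eigenvalues))
    stop("mode index ", mode_index, " out of range")
  col
}

#' Displace a structure along an ANM mode to a target amplitude
#'
#' @param model the input `StructureModel`
#' @param modes an ANM `ModeSet` of the model
#' @param mode_index global mode number (1 = first nontrivial)
#' @param amplitude target C-alpha RMSD of the displaced conformer from
#'   the input, Angstrom
#' @return displaced `StructureModel` (C-alpha coordinates shifted)
#' @export
anm_displace <- function(model, modes, mode_index = 2, amplitude = 4) {
  stopifnot(modes$model_kind == "ANM")
  col <- .global_mode_col(modes, mode_index)
  u <- modes$eigenvectors[, col]
  u <- u / sqrt(sum(u^2))
  n <- length(modes$nodes)
  disp <- matrix(u, ncol = 3, byrow = TRUE) * amplitude * sqrt(n)
  idx <- which(model$name == "CA" & !model$is_hetero)
  xyz <- model_xyz(model)
  xyz[idx, ] <- xyz[idx, ] + disp
  model_xyz(model) <- xyz
  model
}

#' Frequency dispersion and collectivity of a mode
#'
#' Dispersion is the reciprocal eigenvalue. Collectivity is the
#' exponential-entropy measure kappa = (1/N) exp(-sum a_i log a_i) over
#' normalized per-residue squared amplitudes a_i (3 Cartesian components
#' summed per node for ANM); kappa = 1 for a uniform mode, 1/N for a
#' single-node mode.
#'
#' @param modes a `ModeSet`
#' @param mode_index global mode number (default 2, the "second global
#'   mode")
#' @return `ModeStats`: list with `mode_index`, `eigenvalue`,
#'   `frequency_dispersion`, `collectivity`
#' @export
mode_stats <- function(modes, mode_index = 2) {
  col <- .global_mode_col(modes, mode_index)
  lambda <- modes$eigenvalues[col]
  if (lambda <= 0) stop("mode ", mode_index, " is a zero mode")
  u <- modes$eigenvectors[, col]
  a <- if (modes$model_kind == "ANM") rowSums(matrix(u^2, ncol = 3, byrow = TRUE))
       else u^2
  a <- a / sum(a)
  nz <- a[a > 0]
  kappa <- exp(-sum(nz * log(nz))) / length(a)
  structure(list(mode_index = mode_index, eigenvalue = lambda,
                 frequency_dispersion = 1 / lambda, collectivity = kappa),
            class = "ModeStats")
}

#' @export
print.ModeStats <- function(x, ...) {
  cat(sprintf("ModeStats: global mode %d, dispersion %.4g, collectivity %.4g\n",
              x$mode_index, x$frequency_dispersion, x$collectivity))
  invisible(x)
}

#' Sign-based domain split and hinge prediction (GNM)
#'
#' Nodes are split into contiguous domains by the sign of the chosen GNM
#' mode eigenvector; residues flanking each sign change are hinges, and
#' nodes with |component| below `band` are reported as the hinge band.
#'
#' @param modes a GNM `ModeSet`
#' @param mode_index global mode number (default 2)
#' @param band near-zero amplitude threshold (default 1e-3)
#' @return `DomainSplit`: list with `sign` (per node), `domains`
#'   (data.frame of contiguous runs), `hinges` (residue keys flanking
#'   sign changes), `hinge_band`
#' @export
domain_split_hinges <- function(modes, mode_index = 2, band = 1e-3) {
  stopifnot(modes$model_kind == "GNM")
  col <- .global_mode_col(modes, mode_index)
  u <- modes$eigenvectors[, col]
  sgn <- ifelse(u >= 0, "+", "-")
  flips <- which(sgn[-1] != sgn[-length(sgn)])
  runs <- rle(sgn)
  ends <- cumsum(runs$lengths)
  starts <- c(1, utils::head(ends, -1) + 1)
  domains <- data.frame(sign = runs$values,
                        from = modes$nodes[starts], to = modes$nodes[ends],
                        n_nodes = runs$lengths, stringsAsFactors = FALSE)
  hinges <- unique(modes$nodes[sort(c(flips, flips + 1))])
  structure(list(sign = sgn, domains = domains, hinges = hinges,
                 hinge_band = modes$nodes[abs(u) < band],
                 n_sign_changes = length(flips)),
            class = "DomainSplit")
}

#' Overlap of modes with an observed displacement
#'
#' overlap_k = |u_k . dr| / (||u_k|| ||dr||); the cumulative overlap is
#' the square root of the running sum of squares (reaches 1 when dr lies
#' in the span of the supplied modes).
#'
#' @param modes a `ModeSet`
#' @param displacement numeric displacement vector (3N for ANM, N for
#'   GNM), from superposed conformers
#' @return data.frame with mode (global numbering), overlap, cumulative
#' @export
mode_overlap <- function(modes, displacement) {
  nr <- sqrt(sum(displacement^2))
  if (nr < 1e-12) stop("zero displacement: overlap undefined")
  cols <- (modes$n_zero_modes + 1):length(modes$eigenvalues)
  ov <- vapply(cols, function(cl) {
    u <- modes$eigenvectors[, cl]
    abs(sum(u * displacement)) / (sqrt(sum(u^2)) * nr)
  }, numeric(1))
  data.frame(mode = seq_along(cols), overlap = ov,
             cumulative = sqrt(cumsum(ov^2)))
}

#' GNM mean-square fluctuations (pseudo-inverse diagonal)
#' @param modes a GNM `ModeSet`
#' @return numeric vector of per-node MSFs (arbitrary units)
#' @export
gnm_msf <- function(modes) {
  stopifnot(modes$model_kind == "GNM")
  cols <- (modes$n_zero_modes + 1):length(modes$eigenvalues)
  v <- modes$eigenvectors[, cols, drop = FALSE]
  rowSums(sweep(v^2, 2, modes$eigenvalues[cols], `/`))
}

#' Export modes in NMD text format
#' @param modes a `ModeSet`
#' @param path output path
#' @param n_modes number of nontrivial modes to write (default 5)
#' @return `path` invisibly
#' @export
write_nmd <- function(modes, path, n_modes = 5) {
  cols <- modes$n_zero_modes + seq_len(
    min(n_modes, length(modes$eigenvalues) - modes$n_zero_modes))
  lines <- c(
    paste("names", paste(modes$nodes, collapse = " ")),
    paste("coordinates", paste(format(t(modes$node_xyz), trim = TRUE),
                               collapse = " ")))
  for (k in seq_along(cols)) {
    u <- modes$eigenvectors[, cols[k]]
    if (modes$model_kind == "GNM") u <- as.vector(rbind(u, u, u))
    lines <- c(lines, paste("mode", k, paste(format(u, trim = TRUE),
                                             collapse = " ")))
  }
  writeLines(lines, path)
  invisible(path)
}
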