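# Rigidity-transmission allostery (RTA): perturb the rigidity of one site
# and measure the resulting loss of conformational degrees of freedom at a
# distant site.

#' Define a site by residues and/or explicit bodies
#'
#' @param label site label
#' @param residues residue keys (resolved against a network's atom table)
#' @param bodies explicit body ids (optional; used directly if given)
#' @return `SiteDefinition`
#' @export
site_definition <- function(label, residues = NULL, bodies = NULL) {
  if (is.null(residues) && is.null(bodies))
    stop("site '", label, "' is empty: give residues or bodies")
  structure(list(label = label, residues = residues, bodies = bodies),
            class = "SiteDefinition")
}

site_bodies <- function(site, network) {
  b <- site$bodies
  if (is.null(b)) {
    b <- network$atoms$id[network$atoms$key %in% site$residues]
  }
  b <- sort(unique(as.integer(b)))
  if (!length(b))
    stop("site '", site$label, "' resolves to no bodies in this network")
  b
}

# Rigidify a body set in-place: pin every body to the first with up to 6
# bars each (redundant bars are skipped by the game itself).
pg_rigidify_set <- function(st, bodies) {
  if (length(bodies) < 2) return(invisible(st))
  a0 <- bodies[1]
  for (ai in bodies[-1]) {
    for (b in 1:6) pg_insert_bar(st, a0, ai)
  }
  invisible(st)
}

#' Degree-of-freedom transmission between two sites
#'
#' Counts the conformational DOF available at site B (free pebbles
#' gatherable onto B beyond the 6 trivial ones), rigidifies site A by
#' inserting independent bars until A is internally rigid, and reports the
#' drop in B's available DOF.
#'
#' @param network a `ConstraintNetwork`
#' @param siteA,siteB disjoint `SiteDefinition`s
#' @return `TransmissionResult`: list with `dof_B_before`, `dof_B_after`,
#'   `transmitted`, `cutoff`
#' @export
rta_transmission <- function(network, siteA, siteB) {
  A <- site_bodies(siteA, network)
  B <- site_bodies(siteB, network)
  if (length(intersect(A, B)))
    stop("sites '", siteA$label, "' and '", siteB$label, "' overlap")
  pg <- pebble_game_dof(network)
  before <- pg_free_dof_set(pg$state, B)
  st2 <- pg_clone(pg$state)
  pg_rigidify_set(st2, A)
  after <- pg_free_dof_set(st2, B)
  structure(list(dof_B_before = before, dof_B_after = after,
                 transmitted = before - after,
                 cutoff = network$hbond_cutoff),
            class = "TransmissionResult")
}

#' @export
print.TransmissionResult <- function(x, ...) {
  cat(sprintf("TransmissionResult: DOF at B %d -> %d, transmitted %d\n",
              x$dof_B_before, x$dof_B_after, x$transmitted))
  invisible(x)
}

#' Windowed RTA transmission scan
#'
#' Slides a window of `window` consecutive residues from the N-terminus,
#' rigidifies each window, and records the DOF transmitted to `target`,
#' repeating over a descending H-bond cutoff grid (for networks built from
#' structures; synthetic networks without H-bond candidates are evaluated
#' once). The per-residue intensity is the mean transmitted DOF over the
#' (up to `window`) windows containing the residue, averaged over the
#' grid; persistence is the fraction of the grid with nonzero
#' transmission, averaged the same way.
#'
#' @param network a `ConstraintNetwork`
#' @param target `SiteDefinition` of the site whose DOF are monitored
#' @param window window length in residues (default 3)
#' @param cutoffs descending H-bond cutoff grid (default 0 to -2 by 0.01);
#'   collapsed to a single evaluation when the network has no H-bond
#'   candidate table
#' @param exclude residue keys never included in windows (e.g. the target
#'   site itself is always excluded)
#' @return `RTAProfile` data.frame: residue, intensity, persistence
#' @export
rta_scan_profile <- function(network, target, window = 3,
                             cutoffs = seq(0, -2, by = -0.01),
                             exclude = NULL) {
  tgt_bodies <- site_bodies(target, network)
  tgt_res <- unique(network$atoms$key[network$atoms$id %in% tgt_bodies])
  prot <- network$atoms[!network$atoms$is_hetero, , drop = FALSE]
  residues <- unique(prot$key)
  if (length(residues) < window)
    stop("chain has fewer residues (", length(residues),
         ") than the window (", window, ")")
  if (is.null(network$hbond_candidates) ||
      !nrow(network$hbond_candidates)) cutoffs <- cutoffs[1]
  skip <- union(exclude, tgt_res)
  n_win <- length(residues) - window + 1
  trans <- matrix(0, n_win, length(cutoffs))
  for (ci in seq_along(cutoffs)) {
    net <- if (length(cutoffs) > 1 || !is.null(network$hbond_candidates))
      network_at_cutoff(network, cutoffs[ci]) else network
    pg <- pebble_game_dof(net)
    before <- pg_free_dof_set(pg$state, tgt_bodies)
    for (w in seq_len(n_win)) {
      win_res <- residues[w:(w + window - 1)]
      if (any(win_res %in% skip)) { trans[w, ci] <- NA; next }
      bodies <- network$atoms$id[network$atoms$key %in% win_res]
      st2 <- pg_clone(pg$state)
      pg_rigidify_set(st2, bodies)
      trans[w, ci] <- before - pg_free_dof_set(st2, tgt_bodies)
    }
  }
  win_mean <- rowMeans(trans)
  win_persist <- rowMeans(trans > 0)
  rows <- lapply(seq_along(residues), function(ri) {
    ws <- intersect(seq_len(n_win), (ri - window + 1):ri)
    ws <- ws[!is.na(win_mean[ws])]
    data.frame(residue = residues[ri],
               intensity = if (length(ws)) mean(win_mean[ws]) else NA_real_,
               persistence = if (length(ws)) mean(win_persist[ws]) else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  structure(out, class = c("RTAProfile", "data.frame"),
            target = target$label, window = window, cutoffs = cutoffs)
}

#' Area under a curve (rectangle-plus-triangle rule)
#'
#' AUC = sum over i of (x_i - x_{i-1}) * y_{i-1}
#'       + (1/2) (x_i - x_{i-1}) (y_i - y_{i-1}),
#' which for each panel is a rectangle plus a triangle (algebraically the
#' trapezoid rule, implemented exactly in this two-term form).
#'
#' @param x strictly ascending grid
#' @param y curve values, same length as x
#' @return `AUCResult`: list with `value`, `x_range`, `n`
#' @export
allosteric_auc <- function(x, y) {
  if (length(x) != length(y) || length(x) < 2)
    stop("x and y must have equal length >= 2")
  if (any(diff(x) <= 0)) stop("x must be strictly ascending")
  dx <- diff(x)
  value <- sum(dx * y[-length(y)] + 0.5 * dx * diff(y))
  structure(list(value = value, x_range = range(x), n = length(x)),
            class = "AUCResult")
}

#' @export
print.AUCResult <- function(x, ...) {
  cat(sprintf("AUC = %.6g over [%g, %g] (%d points)\n",
              x$value, x$x_range[1], x$x_range[2], x$n))
  invisible(x)
}

#' Call allosteric hotspots from an RTA profile
#'
#' Default rule: residues whose intensity reaches the 90th percentile of
#' the nonzero intensities and strictly exceeds the smallest nonzero
#' intensity (so a flat profile yields no calls). Regions such as the
#' antenna can be masked out.
#'
#' @param profile an `RTAProfile`
#' @param quantile percentile threshold on nonzero intensities (default 0.9)
#' @param exclude residue keys excluded before thresholding
#' @return character vector of hotspot residue keys (possibly empty, with
#'   a warning when the profile is all zero)
#' @export
call_hotspots <- function(profile, quantile = 0.9, exclude = NULL) {
  p <- profile[!is.na(profile$intensity), , drop = FALSE]
  if (!is.null(exclude)) p <- p[!(p$residue %in% exclude), , drop = FALSE]
  nz <- p$intensity[p$intensity > 0]
  if (!length(nz)) {
    warning("all-zero RTA profile: no hotspots")
    return(character())
  }
  thr <- stats::quantile(nz, quantile, names = FALSE)
  p$residue[p$intensity >= thr & p$intensity > min(nz)]
}
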