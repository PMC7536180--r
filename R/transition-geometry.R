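# Ensemble analysis of backbone dihedrals and peptide-bond geometry:
# transition-zone occupancy, distortion fits, Ramachandran densities.

# Engh-Huber-style reference values for backbone angle distortions.
.ANGLE_REFERENCES <- c(angle_C1_N_CA = 121.7, angle_O1_C1_N = 123.0,
                       angle_CA1_C1_N = 116.2, angle_N_CA_C = 111.2,
                       angle_CA_C_O = 120.8, angle_CA_C_N1 = 116.2)

#' Per-residue, per-frame peptide geometry of an ensemble
#'
#' For every frame and every residue with at least two residues on each
#' side in its chain, records phi/psi, the bond angles around the peptide
#' unit (C(-1)-N-CA, O(-1)-C(-1)-N, CA(-1)-C(-1)-N, N-CA-C, CA-C-O,
#' CA-C-N(+1)) and the O(-1)...C distance. Records with missing backbone
#' atoms are omitted.
#'
#' @param ensemble an `Ensemble` (or a single `StructureModel`)
#' @param residues optional residue-key filter
#' @return `PeptideGeometryRecord` data.frame, one row per (residue, frame)
#' @export
peptide_geometry <- function(ensemble, residues = NULL) {
  frames <- if (inherits(ensemble, "Ensemble")) ensemble$frames else list(ensemble)
  m0 <- frames[[1]]
  keys <- model_residues(m0, protein_only = TRUE)
  rk <- parse_residue_key(keys)
  eligible <- vapply(seq_along(keys), function(i) {
    lo <- i - 2; hi <- i + 2
    lo >= 1 && hi <= length(keys) &&
      all(rk$chain[lo:hi] == rk$chain[i])
  }, logical(1))
  keep <- keys[eligible]
  if (!is.null(residues)) keep <- intersect(keep, residues)
  rows <- list()
  for (f in seq_along(frames)) {
    m <- frames[[f]]
    mkeys <- atom_residue_keys(m)
    xyz <- model_xyz(m)
    at <- function(key, nm) {
      i <- which(mkeys == key & m$name == nm)
      if (length(i)) xyz[i[1], ] else NULL
    }
    for (key in keep) {
      i <- match(key, keys)
      prev <- keys[i - 1]; nxt <- keys[i + 1]
      N <- at(key, "N"); CA <- at(key, "CA"); C <- at(key, "C")
      C0 <- at(prev, "C"); O0 <- at(prev, "O"); CA0 <- at(prev, "CA")
      O <- at(key, "O"); N1 <- at(nxt, "N")
      if (is.null(N) || is.null(CA) || is.null(C) || is.null(C0) ||
          is.null(O0) || is.null(CA0) || is.null(O) || is.null(N1)) next
      rows[[length(rows) + 1]] <- data.frame(
        residue = key, frame = f,
        phi = dihedral_angle(C0, N, CA, C),
        psi = dihedral_angle(N, CA, C, N1),
        angle_C1_N_CA = vec_angle(C0, N, CA),
        angle_O1_C1_N = vec_angle(O0, C0, N),
        angle_CA1_C1_N = vec_angle(CA0, C0, N),
        angle_N_CA_C = vec_angle(N, CA, C),
        angle_CA_C_O = vec_angle(CA, C, O),
        angle_CA_C_N1 = vec_angle(CA, C, N1),
        d_O1_C = vnorm(C - O0),
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(residue = character(), frame = integer(), phi = numeric(),
               psi = numeric())
  structure(out, class = c("PeptideGeometryRecord", "data.frame"))
}

#' Transition-zone occupancy scan
#'
#' Counts, per residue, the frames whose phi lies strictly inside the
#' high-energy transition zone (default the open interval (-35, +35)
#' degrees), ranked descending.
#'
#' @param records output of [peptide_geometry()]
#' @param zone length-2 numeric interval in degrees (open; default
#'   c(-35, 35))
#' @return `TransitionZoneReport` data.frame: residue, count, n_frames
#' @export
transition_zone_scan <- function(records, zone = c(-35, 35)) {
  if (!nrow(records)) stop("no records")
  inzone <- records$phi > zone[1] & records$phi < zone[2]
  counts <- tapply(inzone, records$residue, sum)
  nfr <- tapply(records$frame, records$residue, function(x) length(unique(x)))
  out <- data.frame(residue = names(counts),
                    count = as.integer(counts),
                    n_frames = as.integer(nfr[names(counts)]),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$count, out$residue), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("TransitionZoneReport", "data.frame"), zone = zone)
}

#' Fit peptide-geometry distortion models
#'
#' Quadratic model y = a phi^2 + b phi + c (for the O(-1)...C distance) or
#' single-amplitude cosine model y = I cos(phi pi / 120) (period fixed at
#' 240 degrees, for bond-angle distortions measured relative to the
#' Engh-Huber reference value). Ordinary least squares; returns R^2.
#'
#' @param records output of [peptide_geometry()] (or any data.frame with
#'   a `phi` column)
#' @param response column name, e.g. "d_O1_C" or "angle_C1_N_CA"
#' @param model "quadratic_in_phi" or "cosine_in_phi"
#' @return `FitResult`: list with `model`, `coefficients`, `r_squared`,
#'   `se` (standard errors), `n`
#' @export
fit_distortion_models <- function(records,
                                  response = "d_O1_C",
                                  model = c("quadratic_in_phi", "cosine_in_phi")) {
  model <- match.arg(model)
  y <- records[[response]]
  phi <- records$phi
  ok <- is.finite(y) & is.finite(phi)
  y <- y[ok]; phi <- phi[ok]
  if (length(y) < 5) stop("need at least 5 records to fit, got ", length(y))
  if (model == "quadratic_in_phi") {
    fit <- stats::lm(y ~ phi + I(phi^2))
    cf <- stats::coef(fit)
    sm <- suppressWarnings(summary(fit))  # exact fits are expected here
    if (any(!is.finite(cf))) stop("rank-deficient design for quadratic fit")
    coefficients <- c(a = unname(cf["I(phi^2)"]), b = unname(cf["phi"]),
                      c = unname(cf["(Intercept)"]))
    se <- c(a = sm$coefficients["I(phi^2)", 2], b = sm$coefficients["phi", 2],
            c = sm$coefficients["(Intercept)", 2])
    # a response with (numerically) no variance explains nothing
    r2 <- if (stats::var(y) < 1e-20) 0 else sm$r.squared
  } else {
    if (response %in% names(.ANGLE_REFERENCES))
      y <- y - .ANGLE_REFERENCES[[response]]
    cs <- cos(phi * pi / 120)
    if (sum(cs^2) < 1e-12) stop("rank-deficient design for cosine fit")
    fit <- stats::lm(y ~ 0 + cs)
    sm <- suppressWarnings(summary(fit))
    coefficients <- c(I = unname(stats::coef(fit)["cs"]))
    se <- c(I = sm$coefficients["cs", 2])
    ss_res <- sum(stats::residuals(fit)^2)
    ss_tot <- sum((y - mean(y))^2)
    r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else 0
  }
  structure(list(model = model, coefficients = coefficients, se = se,
                 r_squared = r2, n = length(y)),
            class = "FitResult")
}

#' @export
print.FitResult <- function(x, ...) {
  cat(sprintf("FitResult (%s): %s; R^2 = %.4f, n = %d\n", x$model,
              paste(sprintf("%s = %.4g", names(x$coefficients),
                            x$coefficients), collapse = ", "),
              x$r_squared, x$n))
  invisible(x)
}

#' Two-dimensional phi/psi density (Ramachandran histogram)
#'
#' Periodic binning on (-180, 180] (both -180 and 180 map to the same
#' bin); returns the normalized density per bin and its negative log.
#'
#' @param records output of [peptide_geometry()]
#' @param bins number of bins per axis (default 36, i.e. 10-degree bins)
#' @return list with `phi_breaks`, `psi_breaks`, `density` (bins x bins,
#'   sums to 1), `neg_log_density`
#' @export
ramachandran_density <- function(records, bins = 36) {
  if (!nrow(records)) stop("no records")
  wrap <- function(a) {
    a <- (a + 180) %% 360 - 180
    a[a == -180] <- 180
    a
  }
  brk <- seq(-180, 180, length.out = bins + 1)
  bin_of <- function(a) pmin(pmax(ceiling((wrap(a) + 180) / (360 / bins)), 1), bins)
  h <- matrix(0, bins, bins)
  bi <- bin_of(records$phi); bj <- bin_of(records$psi)
  for (k in seq_along(bi)) h[bi[k], bj[k]] <- h[bi[k], bj[k]] + 1
  dens <- h / sum(h)
  list(phi_breaks = brk, psi_breaks = brk, density = dens,
       neg_log_density = -log(dens))
}
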