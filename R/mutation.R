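# In silico point mutations: side chains rebuilt with ideal internal
# coordinates from a coarse built-in rotamer set, choosing the rotamer
# with the fewest heavy-atom clashes; plus wild-type vs mutant rigidity
# difference reports.
#
# Template rows: atom name; three reference atoms a, b, c (the new atom
# bonds to c; angle is b-c-new, torsion a-b-c-new); bond length; angle;
# torsion = numeric offset added to the chi it belongs to, or a fixed
# value when chi = 0.

.sc_row <- function(name, a, b, c, len, ang, chi, off) {
  data.frame(name = name, a = a, b = b, c = c, len = len, ang = ang,
             chi = chi, off = off, stringsAsFactors = FALSE)
}

.CB <- .sc_row("CB", "N", "C", "CA", 1.53, 110.6, 0, 122.7)

.SIDECHAIN_TEMPLATES <- list(
  GLY = NULL,
  ALA = .CB,
  SER = rbind(.CB, .sc_row("OG", "N", "CA", "CB", 1.42, 110.5, 1, 0)),
  CYS = rbind(.CB, .sc_row("SG", "N", "CA", "CB", 1.81, 114.4, 1, 0)),
  THR = rbind(.CB, .sc_row("OG1", "N", "CA", "CB", 1.43, 109.6, 1, 0),
              .sc_row("CG2", "N", "CA", "CB", 1.52, 110.5, 1, -120)),
  VAL = rbind(.CB, .sc_row("CG1", "N", "CA", "CB", 1.52, 110.5, 1, 0),
              .sc_row("CG2", "N", "CA", "CB", 1.52, 110.5, 1, 120)),
  LEU = rbind(.CB, .sc_row("CG", "N", "CA", "CB", 1.53, 116.3, 1, 0),
              .sc_row("CD1", "CA", "CB", "CG", 1.52, 110.7, 2, 0),
              .sc_row("CD2", "CA", "CB", "CG", 1.52, 110.7, 2, 120)),
  ILE = rbind(.CB, .sc_row("CG1", "N", "CA", "CB", 1.53, 110.4, 1, 0),
              .sc_row("CG2", "N", "CA", "CB", 1.52, 110.5, 1, -120),
              .sc_row("CD1", "CA", "CB", "CG1", 1.52, 113.8, 2, 0)),
  MET = rbind(.CB, .sc_row("CG", "N", "CA", "CB", 1.52, 114.1, 1, 0),
              .sc_row("SD", "CA", "CB", "CG", 1.81, 112.7, 2, 0),
              .sc_row("CE", "CB", "CG", "SD", 1.79, 100.9, 3, 0)),
  ASP = rbind(.CB, .sc_row("CG", "N", "CA", "CB", 1.52, 112.6, 1, 0),
              .sc_row("OD1", "CA", "CB", "CG", 1.25, 118.4, 2, 0),
              .sc_row("OD2", "CA", "CB", "CG", 1.25, 118.4, 2, 180)),
  ASN = rbind(.CB, .sc_row("CG", "N", "CA", "CB", 1.52, 112.6, 1, 0),
              .sc_row("OD1", "CA", "CB", "CG", 1.23, 120.8, 2, 0),
              .sc_row("ND2", "CA", "CB", "CG", 1.33, 116.4, 2, 180)),
  GLU = rbind(.CB, .sc_row("CG", "N", "CA", "CB", 1.52, 114.1, 1, 0),
              .sc_row("CD", "CA", "CB", "CG", 1.52, 112.6, 2, 0),
              .sc_row("OE1", "CB", "CG", "CD", 1.25, 118.4, 3, 0),
              .sc_row("OE2", "CB", "CG", "CD", 1.25, 118.4, 3, 180)),
  GLN = rbind(.CB, .sc_row("CG", "N", "CA", "CB", 1.52, 114.1, 1, 0),
              .sc_row("CD", "CA", "CB", "CG", 1.52, 112.6, 2, 0),
              .sc_row("OE1", "CB", "CG", "CD", 1.23, 120.8, 3, 0),
              .sc_row("NE2", "CB", "CG", "CD", 1.33, 116.4, 3, 180)),
  LYS = rbind(.CB, .sc_row("CG", "N", "CA", "CB", 1.52, 114.1, 1, 0),
              .sc_row("CD", "CA", "CB", "CG", 1.52, 111.3, 2, 0),
              .sc_row("CE", "CB", "CG", "CD", 1.52, 111.3, 3, 0),
              .sc_row("NZ", "CG", "CD", "CE", 1.49, 111.9, 4, 0)),
  ARG = rbind(.CB, .sc_row("CG", "N", "CA", "CB", 1.52, 114.1, 1, 0),
              .sc_row("CD", "CA", "CB", "CG", 1.52, 111.3, 2, 0),
              .sc_row("NE", "CB", "CG", "CD", 1.46, 112.0, 3, 0),
              .sc_row("CZ", "CG", "CD", "NE", 1.33, 124.2, 4, 0),
              .sc_row("NH1", "CD", "NE", "CZ", 1.33, 120.0, 0, 0),
              .sc_row("NH2", "CD", "NE", "CZ", 1.33, 120.0, 0, 180)),
  PHE = rbind(.CB, .sc_row("CG", "N", "CA", "CB", 1.50, 113.8, 1, 0),
              .sc_row("CD1", "CA", "CB", "CG", 1.39, 120.8, 2, 0),
              .sc_row("CD2", "CA", "CB", "CG", 1.39, 120.8, 2, 180),
              .sc_row("CE1", "CB", "CG", "CD1", 1.39, 120.8, 0, 180),
              .sc_row("CE2", "CB", "CG", "CD2", 1.39, 120.8, 0, 180),
              .sc_row("CZ", "CG", "CD1", "CE1", 1.39, 120.0, 0, 0)),
  TYR = rbind(.CB, .sc_row("CG", "N", "CA", "CB", 1.50, 113.8, 1, 0),
              .sc_row("CD1", "CA", "CB", "CG", 1.39, 120.8, 2, 0),
              .sc_row("CD2", "CA", "CB", "CG", 1.39, 120.8, 2, 180),
              .sc_row("CE1", "CB", "CG", "CD1", 1.39, 120.8, 0, 180),
              .sc_row("CE2", "CB", "CG", "CD2", 1.39, 120.8, 0, 180),
              .sc_row("CZ", "CG", "CD1", "CE1", 1.39, 120.0, 0, 0),
              .sc_row("OH", "CD1", "CE1", "CZ", 1.38, 119.9, 0, 180)),
  TRP = rbind(.CB, .sc_row("CG", "N", "CA", "CB", 1.50, 113.8, 1, 0),
              .sc_row("CD1", "CA", "CB", "CG", 1.37, 126.9, 2, 0),
              .sc_row("CD2", "CA", "CB", "CG", 1.43, 126.7, 2, 180),
              .sc_row("NE1", "CB", "CG", "CD1", 1.38, 110.2, 0, 180),
              .sc_row("CE2", "CB", "CG", "CD2", 1.41, 107.2, 0, 180),
              .sc_row("CE3", "CB", "CG", "CD2", 1.40, 133.9, 0, 0),
              .sc_row("CZ2", "CG", "CD2", "CE2", 1.40, 122.4, 0, 180),
              .sc_row("CZ3", "CG", "CD2", "CE3", 1.39, 118.6, 0, 180),
              .sc_row("CH2", "CD2", "CE2", "CZ2", 1.37, 117.5, 0, 0)),
  HIS = rbind(.CB, .sc_row("CG", "N", "CA", "CB", 1.49, 113.8, 1, 0),
              .sc_row("ND1", "CA", "CB", "CG", 1.38, 122.7, 2, 0),
              .sc_row("CD2", "CA", "CB", "CG", 1.36, 131.0, 2, 180),
              .sc_row("CE1", "CB", "CG", "ND1", 1.32, 109.2, 0, 180),
              .sc_row("NE2", "CB", "CG", "CD2", 1.37, 107.2, 0, 180))
)

# Coarse rotamer chi sets (<= 9 per residue type), deterministic order.
.ROTAMER_SETS <- list(
  GLY = list(numeric()), ALA = list(numeric()),
  SER = list(-60, 180, 60), CYS = list(-60, 180, 60),
  THR = list(-60, 180, 60), VAL = list(180, -60, 60),
  LEU = list(c(-60, 175), c(180, 65), c(180, 175), c(65, 175)),
  ILE = list(c(-60, 170), c(180, 170), c(-60, -60), c(60, 170)),
  MET = list(c(-60, 180, 180), c(180, 180, 180), c(-60, -60, 180),
             c(60, 180, 180)),
  ASP = list(c(-70, 0), c(180, 0), c(60, 0), c(-70, 90), c(180, 90),
             c(60, 90)),
  ASN = list(c(-70, 0), c(180, 0), c(60, 0), c(-70, 90), c(180, 90),
             c(60, 90)),
  GLU = list(c(-60, 180, 0), c(180, 180, 0), c(60, 180, 0),
             c(-60, -60, 0)),
  GLN = list(c(-60, 180, 0), c(180, 180, 0), c(60, 180, 0),
             c(-60, -60, 0)),
  LYS = list(c(-60, 180, 180, 180), c(180, 180, 180, 180),
             c(60, 180, 180, 180), c(-60, -60, 180, 180)),
  ARG = list(c(-60, 180, 180, 180), c(180, 180, 180, 180),
             c(60, 180, 180, 180), c(-60, -60, 180, 180)),
  PHE = list(c(-60, 90), c(180, 90), c(60, 90), c(-60, -90), c(180, -90),
             c(60, -90)),
  TYR = list(c(-60, 90), c(180, 90), c(60, 90), c(-60, -90), c(180, -90),
             c(60, -90)),
  TRP = list(c(-60, 90), c(180, 90), c(60, 90), c(-60, -90), c(180, -90),
             c(60, -90)),
  HIS = list(c(-60, 90), c(180, 90), c(60, 90), c(-60, -90), c(180, -90),
             c(60, -90))
)

#' Describe a point mutation
#' @param site residue key of the mutated residue
#' @param from_aa,to_aa 3-letter residue codes
#' @return `MutationSpec`
#' @export
mutation_spec <- function(site, from_aa, to_aa) {
  from_aa <- toupper(from_aa); to_aa <- toupper(to_aa)
  if (!to_aa %in% names(.SIDECHAIN_TEMPLATES))
    stop("no side-chain template for residue type ", to_aa)
  structure(list(site = site, from_aa = from_aa, to_aa = to_aa),
            class = "MutationSpec")
}

# Build side-chain coordinates for a rotamer; returns a named list of
# 3-vectors (template order).
.build_sidechain <- function(backbone, template, chis) {
  pos <- backbone  # named list with N, CA, C
  out <- list()
  for (r in seq_len(nrow(template))) {
    tt <- template[r, ]
    tor <- if (tt$chi > 0) chis[[tt$chi]] + tt$off else tt$off
    p <- place_atom(pos[[tt$a]], pos[[tt$b]], pos[[tt$c]],
                    tt$len, tt$ang, tor)
    pos[[tt$name]] <- p
    out[[tt$name]] <- p
  }
  out
}

#' Apply an in silico point mutation
#'
#' Backbone atoms (and the backbone amide H) are untouched; the side
#' chain is rebuilt with ideal bond lengths and angles, choosing from a
#' coarse built-in rotamer set the rotamer with the fewest heavy-atom
#' clashes (non-bonded contacts < `clash_cutoff` Angstrom to atoms
#' outside the mutated residue). Ties keep the first rotamer in list
#' order; if no rotamer is clash-free the least-clashing one is used with
#' a warning. Side-chain hydrogens of the old residue are removed; rerun
#' [add_polar_hydrogens()] afterwards if polar hydrogens are needed.
#'
#' @param model a `StructureModel`
#' @param spec a `MutationSpec` (see [mutation_spec()])
#' @param clash_cutoff heavy-atom clash distance (default 2.5 Angstrom)
#' @return the mutated `StructureModel`
#' @export
apply_point_mutation <- function(model, spec, clash_cutoff = 2.5) {
  idx <- residue_atom_idx(model, spec$site)
  observed <- toupper(model$res_name[idx[1]])
  if (observed != spec$from_aa)
    stop("site ", spec$site, " is ", observed, ", not ", spec$from_aa)
  backbone_names <- c("N", "CA", "C", "O", "OXT", "H")
  keep <- idx[model$name[idx] %in% backbone_names]
  bb <- list()
  for (nm in c("N", "CA", "C")) {
    i <- keep[match(nm, model$name[keep])]
    if (is.na(i)) stop("site ", spec$site, " lacks backbone atom ", nm)
    bb[[nm]] <- model_xyz(model)[i, ]
  }
  template <- .SIDECHAIN_TEMPLATES[[spec$to_aa]]
  rotamers <- .ROTAMER_SETS[[spec$to_aa]]
  other <- setdiff(seq_len(nrow(model)), idx)
  other <- other[model$element[other] != "H"]
  oxyz <- model_xyz(model)[other, , drop = FALSE]
  clash_count <- function(side) {
    if (!length(side) || !nrow(oxyz)) return(0L)
    s <- do.call(rbind, side)
    sum(vapply(seq_len(nrow(s)), function(k) {
      d2 <- (oxyz[, 1] - s[k, 1])^2 + (oxyz[, 2] - s[k, 2])^2 +
        (oxyz[, 3] - s[k, 3])^2
      sum(d2 < clash_cutoff^2)
    }, numeric(1)))
  }
  sides <- lapply(rotamers, function(ch)
    if (is.null(template)) list() else .build_sidechain(bb, template, ch))
  clashes <- vapply(sides, clash_count, numeric(1))
  best <- which.min(clashes)  # ties keep list order
  if (clashes[best] > 0)
    warning("no clash-free rotamer for ", spec$site, " -> ", spec$to_aa,
            "; using least-clash rotamer (", clashes[best], " contacts)")
  side <- sides[[best]]
  rows <- model[keep, , drop = FALSE]
  rows$res_name <- spec$to_aa
  if (length(side)) {
    add <- do.call(rbind, lapply(names(side), function(nm) {
      a <- model[keep[1], , drop = FALSE]
      a$name <- nm
      a$element <- substr(sub("^[0-9]*", "", nm), 1, 1)
      a$res_name <- spec$to_aa
      a$x <- side[[nm]][1]; a$y <- side[[nm]][2]; a$z <- side[[nm]][3]
      a$occupancy <- 1; a$b_factor <- 0
      a
    }))
    rows <- rbind(rows, add)
  }
  rest <- setdiff(seq_len(nrow(model)), idx)
  out <- rbind(as.data.frame(model)[rest, , drop = FALSE], rows)
  out$serial <- seq_len(nrow(out))
  new_structure_model(out, attr(model, "model_id"))
}

# Retained H-bond identity strings (donor/acceptor residue:atom) of a
# structure-derived network at its cutoff.
.hbond_ids <- function(network) {
  hb <- network$hbond_candidates
  if (is.null(hb) || !nrow(hb)) return(character())
  hb <- hb[hb$energy <= network$hbond_cutoff, , drop = FALSE]
  a <- network$atoms
  paste0(a$key[hb$donor], ".", a$name[hb$donor], "-",
         a$key[hb$acceptor], ".", a$name[hb$acceptor])
}

#' Rigidity difference report between wild type and mutant
#'
#' Builds the constraint network of both structures at the given H-bond
#' cutoff, runs the rigid-cluster decomposition, and reports the change
#' in largest-rigid-cluster size, wild-type clusters split into multiple
#' mutant clusters, hydrogen bonds lost and gained, and (optionally) the
#' per-residue RTA intensity difference toward a target site. Structures
#' lacking hydrogens are protonated with [add_polar_hydrogens()] first.
#'
#' @param wild,mutant `StructureModel`s agreeing in numbering everywhere
#'   except (at most) one mutated residue
#' @param cutoff H-bond energy cutoff, kcal/mol (default -1.0)
#' @param target_site optional `SiteDefinition` for the transmission diff
#' @return `RigidityDiff`: list with `delta_lrc_size`, `split_clusters`,
#'   `lost_hbonds`, `gained_hbonds`, `delta_transmission`, `site`
#' @export
rigidity_diff <- function(wild, mutant, cutoff = -1.0, target_site = NULL) {
  kw <- model_residues(wild); km <- model_residues(mutant)
  if (length(kw) != length(km) || any(kw != km))
    stop("alignment error: wild and mutant residue sets differ")
  rw <- vapply(kw, function(k) wild$res_name[residue_atom_idx(wild, k)[1]], "")
  rm_ <- vapply(km, function(k) mutant$res_name[residue_atom_idx(mutant, k)[1]], "")
  changed <- kw[rw != rm_]
  if (length(changed) > 1)
    stop("alignment error: more than one residue differs (",
         paste(changed, collapse = ", "), ")")
  if (!any(wild$element == "H")) wild <- add_polar_hydrogens(wild)
  if (!any(mutant$element == "H")) mutant <- add_polar_hydrogens(mutant)
  nw <- build_constraint_network(wild, hbond_cutoff = cutoff)
  nm <- build_constraint_network(mutant, hbond_cutoff = cutoff)
  dw <- rigid_clusters(nw)
  dm <- rigid_clusters(nm)
  # map wild bodies onto mutant bodies by residue:atom identity
  idw <- paste0(nw$atoms$key, ".", nw$atoms$name)
  idm <- paste0(nm$atoms$key, ".", nm$atoms$name)
  common <- intersect(idw, idm)
  iw <- match(common, idw); im <- match(common, idm)
  split_clusters <- list()
  for (cl in as.integer(names(dw$sizes))) {
    members <- which(dw$cluster_id == cl)
    mm <- im[match(members, iw)]
    mm <- mm[!is.na(mm)]
    if (length(mm) < 2) next
    frag <- unique(dm$cluster_id[mm])
    if (length(frag) > 1) {
      split_clusters[[length(split_clusters) + 1]] <- list(
        wild_cluster = cl,
        residues = sort(unique(nw$atoms$key[members])),
        mutant_fragments = length(frag))
    }
  }
  hw <- .hbond_ids(nw); hm <- .hbond_ids(nm)
  delta_tr <- NULL
  if (!is.null(target_site)) {
    pw <- rta_scan_profile(nw, target_site, cutoffs = cutoff)
    pm <- rta_scan_profile(nm, target_site, cutoffs = cutoff)
    delta_tr <- data.frame(residue = pw$residue,
                           delta = pm$intensity[match(pw$residue, pm$residue)] -
                             pw$intensity, stringsAsFactors = FALSE)
  }
  structure(list(delta_lrc_size = dm$lrc_size - dw$lrc_size,
                 split_clusters = split_clusters,
                 lost_hbonds = setdiff(hw, hm),
                 gained_hbonds = setdiff(hm, hw),
                 delta_transmission = delta_tr,
                 site = if (length(changed)) changed else NA_character_,
                 wild_decomposition = dw, mutant_decomposition = dm),
            class = "RigidityDiff")
}

#' @export
print.RigidityDiff <- function(x, ...) {
  cat(sprintf(
    "RigidityDiff at %s: delta LRC %+d bodies, %d split cluster(s), %d H-bond(s) lost, %d gained\n",
    x$site, x$delta_lrc_size, length(x$split_clusters),
    length(x$lost_hbonds), length(x$gained_hbonds)))
  invisible(x)
}
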