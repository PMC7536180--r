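# Molecular constraint network: covalent bonds (5 or 6 bars), Mayo-energy
# hydrogen bonds (5 bars), and hydrophobic tethers (2 bars), plus the
# hydrogen-bond dilution series.

#' Mayo hydrogen-bond energy
#'
#' E = V0 * (5 (d0/d)^12 - 6 (d0/d)^10) * F(theta, phi, gamma) with
#' V0 = 8 kcal/mol, d0 = 2.8 Angstrom and d the donor-acceptor distance.
#' The angular factor F follows the Dahiyat-Gordon-Mayo hybridization
#' cases (theta = D-H...A angle, phi = H...A-base angle, gamma = out-of-
#' plane angle for the sp2-sp2 case; when no gamma is supplied the sp2-sp2
#' case reduces to phi). Geometric gates: donor-acceptor distance <= 3.6
#' Angstrom and theta strictly greater than 90 degrees; outside the gates
#' the function returns 0 (no bond).
#'
#' @param donor,hydrogen,acceptor,acceptor_base numeric 3-vectors
#' @param donor_hyb,acceptor_hyb "sp2" or "sp3"
#' @param gamma optional sp2-plane angle (degrees) for the sp2-sp2 case
#' @param V0,d0 potential well depth (kcal/mol) and equilibrium distance
#' @return energy in kcal/mol (<= 0 for an accepted bond; 0 means no bond)
#' @export
mayo_hbond_energy <- function(donor, hydrogen, acceptor, acceptor_base,
                              donor_hyb = "sp3", acceptor_hyb = "sp3",
                              gamma = NULL, V0 = 8, d0 = 2.8) {
  d <- vnorm(acceptor - donor)
  if (d > 3.6) return(0)
  theta <- vec_angle(donor, hydrogen, acceptor)
  if (theta <= 90) return(0)
  phi <- vec_angle(hydrogen, acceptor, acceptor_base)
  cs <- function(ang) cos(rad(ang))^2
  F <- if (donor_hyb == "sp3" && acceptor_hyb == "sp3") {
    cs(theta) * cs(phi - 109.5)
  } else if (donor_hyb == "sp3" && acceptor_hyb == "sp2") {
    cs(theta) * cs(phi)
  } else if (donor_hyb == "sp2" && acceptor_hyb == "sp3") {
    cs(theta)^2
  } else {
    g <- if (is.null(gamma)) phi else max(phi, gamma)
    cs(theta) * cs(g)
  }
  r <- d0 / d
  V0 * (5 * r^12 - 6 * r^10) * F
}

# ---- covalent bonds ------------------------------------------------------

#' Detect covalent bonds of a model
#'
#' Standard amino acids are bonded from residue templates; peptide bonds
#' link consecutive residues (C-N < 1.8 Angstrom); disulfides link SG
#' pairs <= 2.3 Angstrom; hydrogens attach to their nearest heavy atom
#' within 1.25 Angstrom. Residues without a template (ligands such as GTP
#' or NADH) fall back to distance-based detection
#' (d <= r_cov(i) + r_cov(j) + 0.4 Angstrom) with a warning. Peptide
#' bonds, double/partial-double bonds and bonds to single-neighbor atoms
#' are locked (6 bars); all other covalent bonds are rotatable (5 bars).
#'
#' @param model a `StructureModel`
#' @return data.frame with columns i, j (atom row indices, i < j), kind
#'   ("covalent_locked"/"covalent_rotatable"), bars
#' @export
detect_covalent_bonds <- function(model) {
  n <- nrow(model)
  xyz <- model_xyz(model)
  keys <- atom_residue_keys(model)
  res_keys <- unique(keys)
  ii <- integer(); jj <- integer(); locked_pair <- logical()
  add_bond <- function(a, b, locked = FALSE) {
    ii[[length(ii) + 1]] <<- min(a, b)
    jj[[length(jj) + 1]] <<- max(a, b)
    locked_pair[[length(locked_pair) + 1]] <<- locked
  }
  dist_ij <- function(a, b) sqrt(sum((xyz[a, ] - xyz[b, ])^2))
  no_template <- character()
  for (key in res_keys) {
    idx <- which(keys == key)
    rn <- toupper(model$res_name[idx[1]])
    if (is_standard_aa(rn) && !model$is_hetero[idx[1]]) {
      tmpl <- rbind(cbind("N", "CA"), cbind("CA", "C"), cbind("C", "O"),
                    cbind("C", "OXT"), .SIDECHAIN_BONDS[[rn]])
      lockt <- rbind(cbind("C", "O"), cbind("C", "OXT"),
                     .LOCKED_SIDECHAIN_BONDS[[rn]])
      lock_id <- paste(lockt[, 1], lockt[, 2])
      for (r in seq_len(nrow(tmpl))) {
        a <- idx[match(tmpl[r, 1], model$name[idx])]
        b <- idx[match(tmpl[r, 2], model$name[idx])]
        if (!is.na(a) && !is.na(b))
          add_bond(a, b, paste(tmpl[r, 1], tmpl[r, 2]) %in% lock_id)
      }
    } else {
      no_template <- c(no_template, rn)
      # distance fallback within the residue (heavy atoms)
      hv <- idx[model$element[idx] != "H"]
      if (length(hv) > 1) {
        for (ai in seq_along(hv)[-length(hv)]) for (bi in (ai + 1):length(hv)) {
          a <- hv[ai]; b <- hv[bi]
          if (dist_ij(a, b) <= cov_radius(model$element[a]) +
              cov_radius(model$element[b]) + 0.4)
            add_bond(a, b, FALSE)
        }
      }
    }
  }
  if (length(no_template))
    warning("no bond template for residue(s): ",
            paste(unique(no_template), collapse = ", "),
            "; distance-based fallback used")
  # peptide bonds between consecutive residues of a chain
  rk <- parse_residue_key(res_keys)
  for (r in seq_along(res_keys)[-1]) {
    if (rk$chain[r] != rk$chain[r - 1]) next
    a <- named_atom_idx(model, res_keys[r - 1], "C")
    b <- named_atom_idx(model, res_keys[r], "N")
    if (!is.na(a) && !is.na(b) && dist_ij(a, b) < 1.8)
      add_bond(a, b, TRUE)
  }
  # disulfides
  sg <- which(model$name == "SG" & toupper(model$res_name) == "CYS")
  if (length(sg) > 1) {
    for (ai in seq_along(sg)[-length(sg)]) for (bi in (ai + 1):length(sg)) {
      if (dist_ij(sg[ai], sg[bi]) <= 2.3) add_bond(sg[ai], sg[bi], FALSE)
    }
  }
  # hydrogens to their nearest heavy atom
  hs <- which(model$element == "H")
  heavy <- which(model$element != "H")
  for (h in hs) {
    d2 <- (xyz[heavy, 1] - xyz[h, 1])^2 + (xyz[heavy, 2] - xyz[h, 2])^2 +
      (xyz[heavy, 3] - xyz[h, 3])^2
    k <- which.min(d2)
    if (d2[k] < 1.25^2) add_bond(heavy[k], h, TRUE)
  }
  if (!length(ii))
    return(data.frame(i = integer(), j = integer(), kind = character(),
                      bars = integer(), stringsAsFactors = FALSE))
  bonds <- data.frame(i = ii, j = jj, locked = locked_pair)
  bonds <- bonds[!duplicated(bonds[, c("i", "j")]), , drop = FALSE]
  # terminal bonds (an endpoint with a single neighbor) are locked too
  degree <- tabulate(c(bonds$i, bonds$j), nbins = n)
  bonds$locked <- bonds$locked | degree[bonds$i] == 1 | degree[bonds$j] == 1
  data.frame(i = bonds$i, j = bonds$j,
             kind = ifelse(bonds$locked, "covalent_locked", "covalent_rotatable"),
             bars = ifelse(bonds$locked, 6L, 5L), stringsAsFactors = FALSE)
}

# ---- hydrogen bonds ------------------------------------------------------

# All donor-H...acceptor candidates with Mayo energies (no cutoff applied).
# Salt bridges get the fixed salt_bridge_energy. Pairs within covalent graph
# distance <= 2 of the donor are excluded.
find_hbond_candidates <- function(model, covalent = detect_covalent_bonds(model),
                                  salt_bridge_energy = -10) {
  xyz <- model_xyz(model)
  keys <- atom_residue_keys(model)
  n <- nrow(model)
  adj <- vector("list", n)
  for (r in seq_len(nrow(covalent))) {
    a <- covalent$i[r]; b <- covalent$j[r]
    adj[[a]] <- c(adj[[a]], b); adj[[b]] <- c(adj[[b]], a)
  }
  near_cov <- function(a) unique(c(a, unlist(adj[c(a, adj[[a]])])))
  # donors: heavy atoms with an attached H
  donors <- list()
  for (h in which(model$element == "H")) {
    d <- adj[[h]]
    if (!length(d)) next
    d <- d[1]
    if (!(model$element[d] %in% c("N", "O", "S"))) next
    rn <- toupper(model$res_name[d])
    hyb <- if (model$is_hetero[d]) "sp3" else atom_hybridization(rn, model$name[d])
    donors[[length(donors) + 1]] <- list(d = d, h = h, hyb = hyb)
  }
  # acceptors
  acc_idx <- integer(); acc_hyb <- character()
  for (a in which(model$element %in% c("N", "O", "S"))) {
    rn <- toupper(model$res_name[a]); nm <- model$name[a]
    ok <- if (model$is_hetero[a]) {
      model$element[a] %in% c("O", "N")
    } else if (nm %in% c("O", "OXT")) TRUE
    else {
      acc <- .SIDECHAIN_ACCEPTORS[[rn]]
      !is.null(acc) && nm %in% names(acc)
    }
    if (ok) {
      acc_idx <- c(acc_idx, a)
      acc_hyb <- c(acc_hyb, if (model$is_hetero[a]) "sp3"
                   else atom_hybridization(rn, nm))
    }
  }
  is_salt_d <- function(d) {
    rn <- toupper(model$res_name[d])
    !is.null(.SALT_DONOR_ATOMS[[rn]]) && model$name[d] %in% .SALT_DONOR_ATOMS[[rn]]
  }
  is_salt_a <- function(a) {
    rn <- toupper(model$res_name[a])
    !is.null(.SALT_ACCEPTOR_ATOMS[[rn]]) && model$name[a] %in% .SALT_ACCEPTOR_ATOMS[[rn]]
  }
  rows <- list()
  for (don in donors) {
    excl <- near_cov(don$d)
    for (k in seq_along(acc_idx)) {
      a <- acc_idx[k]
      if (a %in% excl || keys[a] == keys[don$d]) next
      dda <- sqrt(sum((xyz[a, ] - xyz[don$d, ])^2))
      if (dda > 3.6) next
      base <- adj[[a]]
      base <- base[model$element[base] != "H"]
      if (!length(base)) next
      e <- if (is_salt_d(don$d) && is_salt_a(a)) {
        salt_bridge_energy
      } else {
        mayo_hbond_energy(xyz[don$d, ], xyz[don$h, ], xyz[a, ],
                          xyz[base[1], ], don$hyb, acc_hyb[k])
      }
      if (e < 0)
        rows[[length(rows) + 1]] <- data.frame(
          donor = don$d, hydrogen = don$h, acceptor = a, energy = e,
          salt_bridge = is_salt_d(don$d) && is_salt_a(a))
    }
  }
  if (!length(rows))
    return(data.frame(donor = integer(), hydrogen = integer(),
                      acceptor = integer(), energy = numeric(),
                      salt_bridge = logical()))
  hb <- do.call(rbind, rows)
  # one bond per donor-H: keep the strongest acceptor
  hb <- hb[order(hb$hydrogen, hb$energy), , drop = FALSE]
  hb <- hb[!duplicated(hb$hydrogen), , drop = FALSE]
  rownames(hb) <- NULL
  hb
}

# ---- network assembly ----------------------------------------------------

new_constraint_network <- function(n_bodies, edges, atoms = NULL,
                                   hbond_cutoff = NA_real_,
                                   source_label = "network",
                                   hbond_candidates = NULL) {
  edges$i <- as.integer(edges$i)
  edges$j <- as.integer(edges$j)
  edges$bars <- as.integer(edges$bars)
  stopifnot(all(edges$bars %in% c(2L, 5L, 6L)), all(edges$i != edges$j))
  if (is.null(atoms))
    atoms <- data.frame(id = seq_len(n_bodies),
                        key = residue_key("A", seq_len(n_bodies)),
                        name = "X", element = "C", is_hetero = FALSE,
                        stringsAsFactors = FALSE)
  structure(list(n_bodies = as.integer(n_bodies), edges = edges,
                 atoms = atoms, hbond_cutoff = hbond_cutoff,
                 source_label = source_label,
                 hbond_candidates = hbond_candidates),
            class = "ConstraintNetwork")
}

#' @export
print.ConstraintNetwork <- function(x, ...) {
  cat(sprintf("ConstraintNetwork '%s': %d bodies, %d edges (%s)\n",
              x$source_label, x$n_bodies, nrow(x$edges),
              paste(sprintf("%s: %d", names(table(x$edges$kind)),
                            as.integer(table(x$edges$kind))), collapse = ", ")))
  invisible(x)
}

#' Build the molecular constraint network of a structure
#'
#' Bodies are all atoms (ligands included). Edges: covalent bonds (5 bars
#' rotatable / 6 bars locked), hydrogen bonds with Mayo energy E <= cutoff
#' (5 bars; salt bridges fixed at `salt_bridge_energy`), and hydrophobic
#' tethers (2 bars) between apolar C/S atoms of different residues with
#' vdW surface separation <= 0.25 Angstrom.
#'
#' @param model a `StructureModel` (run [add_polar_hydrogens()] first so
#'   hydrogen bonds can be typed)
#' @param hbond_cutoff retain H-bonds with energy <= cutoff (kcal/mol;
#'   default -0.5, weaker bonds are ignored)
#' @param hydrophobic include hydrophobic tethers (default TRUE)
#' @param salt_bridge_energy fixed energy assigned to salt bridges
#'   (default -10, i.e. always retained)
#' @return a `ConstraintNetwork`
#' @export
build_constraint_network <- function(model, hbond_cutoff = -0.5,
                                     hydrophobic = TRUE,
                                     salt_bridge_energy = -10) {
  if (!nrow(model))
    return(new_constraint_network(0L, data.frame(
      i = integer(), j = integer(), bars = integer(), kind = character(),
      energy = numeric())))
  cov <- detect_covalent_bonds(model)
  hb <- find_hbond_candidates(model, cov, salt_bridge_energy)
  if (!any(model$element == "H"))
    warning("model has no hydrogens: no hydrogen bonds can be detected")
  hb_keep <- hb[hb$energy <= hbond_cutoff, , drop = FALSE]
  edges <- data.frame(i = cov$i, j = cov$j, bars = cov$bars, kind = cov$kind,
                      energy = NA_real_, stringsAsFactors = FALSE)
  if (nrow(hb_keep)) {
    e_h <- data.frame(i = pmin(hb_keep$hydrogen, hb_keep$acceptor),
                      j = pmax(hb_keep$hydrogen, hb_keep$acceptor),
                      bars = 5L, kind = "hbond", energy = hb_keep$energy,
                      stringsAsFactors = FALSE)
    edges <- rbind(edges, e_h)
  }
  if (hydrophobic) {
    th <- .hydrophobic_tethers(model, cov)
    if (nrow(th)) edges <- rbind(edges, th)
  }
  edges <- edges[!duplicated(edges[, c("i", "j", "kind")]), , drop = FALSE]
  rownames(edges) <- NULL
  keys <- atom_residue_keys(model)
  atoms <- data.frame(id = seq_len(nrow(model)), key = keys,
                      name = model$name, element = model$element,
                      is_hetero = model$is_hetero, stringsAsFactors = FALSE)
  new_constraint_network(nrow(model), edges, atoms, hbond_cutoff,
                         source_label = "structure", hbond_candidates = hb)
}

# Hydrophobic tethers: apolar carbons (no bonded N/O) and sulfurs, from
# different residues, surface distance <= 0.25 A, not covalently bonded.
.hydrophobic_tethers <- function(model, cov) {
  n <- nrow(model)
  adj <- vector("list", n)
  for (r in seq_len(nrow(cov))) {
    adj[[cov$i[r]]] <- c(adj[[cov$i[r]]], cov$j[r])
    adj[[cov$j[r]]] <- c(adj[[cov$j[r]]], cov$i[r])
  }
  apolar <- vapply(seq_len(n), function(i) {
    el <- model$element[i]
    if (el == "S") return(TRUE)
    if (el != "C") return(FALSE)
    !any(model$element[adj[[i]]] %in% c("N", "O"))
  }, logical(1))
  idx <- which(apolar)
  keys <- atom_residue_keys(model)
  xyz <- model_xyz(model)
  rows <- list()
  cov_id <- paste(cov$i, cov$j)
  if (length(idx) > 1) {
    for (ai in seq_along(idx)[-length(idx)]) for (bi in (ai + 1):length(idx)) {
      a <- idx[ai]; b <- idx[bi]
      if (keys[a] == keys[b]) next
      lim <- vdw_radius(model$element[a]) + vdw_radius(model$element[b]) + 0.25
      if (sum((xyz[a, ] - xyz[b, ])^2) > lim^2) next
      if (paste(a, b) %in% cov_id) next
      rows[[length(rows) + 1]] <- data.frame(
        i = a, j = b, bars = 2L, kind = "hydrophobic", energy = NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(i = integer(), j = integer(), bars = integer(),
                      kind = character(), energy = numeric(),
                      stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

# Re-filter a structure-derived network at a new H-bond cutoff without
# redetecting anything.
network_at_cutoff <- function(network, cutoff) {
  stopifnot(inherits(network, "ConstraintNetwork"))
  base <- network$edges[network$edges$kind != "hbond", , drop = FALSE]
  hb <- network$hbond_candidates
  if (!is.null(hb) && nrow(hb)) {
    keep <- hb[hb$energy <= cutoff, , drop = FALSE]
    if (nrow(keep))
      base <- rbind(base, data.frame(
        i = pmin(keep$hydrogen, keep$acceptor),
        j = pmax(keep$hydrogen, keep$acceptor),
        bars = 5L, kind = "hbond", energy = keep$energy,
        stringsAsFactors = FALSE))
  }
  rownames(base) <- NULL
  out <- network
  out$edges <- base
  out$hbond_cutoff <- cutoff
  out
}

#' Hydrogen-bond dilution series
#'
#' Rebuilds the retained hydrogen-bond set over a descending energy-cutoff
#' grid and records, per cutoff, the retained H-bond count, the largest
#' rigid cluster size and the cluster count.
#'
#' @param model a `StructureModel` (with polar hydrogens), or a
#'   `ConstraintNetwork` whose `hbond_candidates` were kept
#' @param start,stop,step cutoff grid (kcal/mol, default 0 to -2 by 0.01)
#' @return `DilutionSeries` data.frame: cutoff, n_hbonds, lrc_size,
#'   n_clusters, internal_dof
#' @export
dilution_series <- function(model, start = 0, stop = -2, step = 0.01) {
  stopifnot(step > 0, start >= stop)
  network <- if (inherits(model, "ConstraintNetwork")) model
    else build_constraint_network(model, hbond_cutoff = start)
  cutoffs <- seq(start, stop, by = -step)
  rows <- lapply(cutoffs, function(ct) {
    net <- network_at_cutoff(network, ct)
    dec <- rigid_clusters(net)
    data.frame(cutoff = ct, n_hbonds = sum(net$edges$kind == "hbond"),
               lrc_size = dec$lrc_size, n_clusters = dec$n_clusters,
               internal_dof = dec$internal_dof)
  })
  structure(do.call(rbind, rows), class = c("DilutionSeries", "data.frame"))
}

# ---- edge-list serialization (also the pebble-game fixture format) ------

#' Write a ConstraintNetwork as a TSV edge list
#' @param network a `ConstraintNetwork`
#' @param path output path
#' @return `path` invisibly
#' @export
write_network_tsv <- function(network, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# n_bodies=%d hbond_cutoff=%s source=%s",
                     network$n_bodies, format(network$hbond_cutoff),
                     network$source_label), con)
  utils::write.table(
    network$edges[, c("i", "j", "kind", "bars", "energy")], con, sep = "\t",
    quote = FALSE, row.names = FALSE,
    col.names = c("body_i", "body_j", "kind", "bars", "energy"))
  invisible(path)
}

#' Read a ConstraintNetwork from a TSV edge list
#' @param path file written by [write_network_tsv()]
#' @return a `ConstraintNetwork` (atom back-map not restored)
#' @export
read_network_tsv <- function(path) {
  first <- readLines(path, n = 1)
  n_bodies <- as.integer(sub(".*n_bodies=([0-9]+).*", "\\1", first))
  cutoff <- suppressWarnings(as.numeric(
    sub(".*hbond_cutoff=([^ ]+).*", "\\1", first)))
  df <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                          stringsAsFactors = FALSE)
  new_constraint_network(
    n_bodies,
    data.frame(i = df$body_i, j = df$body_j, bars = as.integer(df$bars),
               kind = df$kind, energy = df$energy, stringsAsFactors = FALSE),
    hbond_cutoff = cutoff, source_label = "tsv")
}
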