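# Structure containers and PDB/mmCIF I/O.
#
# A StructureModel is a data.frame of atom records (one row per atom) with
# class c("StructureModel", "data.frame") and attributes `model_id` and
# `ligands` (character vector of residue keys of hetero groups). Columns:
# serial, name, altloc, res_name, chain, res_seq, icode, x, y, z,
# occupancy, b_factor, element, is_hetero.
#
# Residue keys are strings "chain:res_seq:icode" (icode blank -> empty
# trailing field), orderable via the residue ordering of the model.

#' Build a residue key
#'
#' @param chain chain identifier
#' @param res_seq residue sequence number
#' @param icode insertion code ("" if none)
#' @return character key "chain:res_seq:icode"
#' @export
residue_key <- function(chain, res_seq, icode = "") {
  icode[is.na(icode)] <- ""
  paste(chain, as.integer(res_seq), trimws(icode), sep = ":")
}

#' Split residue keys back into components
#' @param key character vector of keys from [residue_key()]
#' @return data.frame with chain, res_seq, icode
#' @export
parse_residue_key <- function(key) {
  parts <- strsplit(key, ":", fixed = TRUE)
  data.frame(chain = vapply(parts, `[`, "", 1),
             res_seq = as.integer(vapply(parts, `[`, "", 2)),
             icode = vapply(parts, function(p) if (length(p) >= 3) p[3] else "", ""),
             stringsAsFactors = FALSE)
}

atom_residue_keys <- function(model) {
  residue_key(model$chain, model$res_seq, model$icode)
}

new_structure_model <- function(atoms, model_id = 1L) {
  ord <- order(atoms$chain, atoms$res_seq, atoms$icode, seq_len(nrow(atoms)))
  atoms <- atoms[ord, , drop = FALSE]
  rownames(atoms) <- NULL
  keys <- residue_key(atoms$chain, atoms$res_seq, atoms$icode)
  ligands <- unique(keys[atoms$is_hetero & !(atoms$res_name %in% c("HOH", "WAT", "DOD"))])
  structure(atoms, class = c("StructureModel", "data.frame"),
            model_id = as.integer(model_id), ligands = ligands)
}

#' @export
print.StructureModel <- function(x, ...) {
  keys <- atom_residue_keys(x)
  cat(sprintf("StructureModel: %d atoms, %d residues, %d chain(s), model %d\n",
              nrow(x), length(unique(keys)), length(unique(x$chain)),
              attr(x, "model_id")))
  if (length(attr(x, "ligands")))
    cat("  ligands:", paste(attr(x, "ligands"), collapse = ", "), "\n")
  invisible(x)
}

#' Hetero-group (ligand) residue keys of a model
#' @param model a StructureModel
#' @return character vector of residue keys
#' @export
ligand_keys <- function(model) attr(model, "ligands")

model_xyz <- function(model) cbind(model$x, model$y, model$z)

`model_xyz<-` <- function(model, value) {
  model$x <- value[, 1]; model$y <- value[, 2]; model$z <- value[, 3]
  model
}

# Row indices of a residue's atoms; error if the key is unknown.
residue_atom_idx <- function(model, key, required = TRUE) {
  idx <- which(atom_residue_keys(model) == key)
  if (required && !length(idx))
    stop("residue key not found in model: ", key)
  idx
}

# Index of a named atom in a residue, or NA.
named_atom_idx <- function(model, key, atom_name) {
  idx <- residue_atom_idx(model, key, required = FALSE)
  idx[match(atom_name, model$name[idx])]
}

# Unique residue keys in model (chain/res_seq/icode) order.
model_residues <- function(model, protein_only = FALSE) {
  keys <- atom_residue_keys(model)
  if (protein_only) keys <- keys[!model$is_hetero]
  unique(keys)
}

.parse_pdb_atom_lines <- function(lines, line_no) {
  f <- function(start, stop) trimws(substr(lines, start, stop))
  num <- function(start, stop, what) {
    v <- suppressWarnings(as.numeric(f(start, stop)))
    bad <- which(!is.finite(v))
    if (length(bad))
      stop(sprintf("PDB format error at line %d: unreadable %s field '%s'",
                   line_no[bad[1]], what, f(start, stop)[bad[1]]))
    v
  }
  element <- f(77, 78)
  name <- f(13, 16)
  # element fallback from the atom-name column
  guess <- sub("^[0-9']*", "", name)
  guess <- ifelse(substr(guess, 1, 1) %in% c("H", "D") & nchar(guess) > 0, "H",
                  substr(guess, 1, 1))
  element <- ifelse(nchar(element) > 0, element, guess)
  occ <- suppressWarnings(as.numeric(f(55, 60)))
  occ[!is.finite(occ)] <- 1
  bfac <- suppressWarnings(as.numeric(f(61, 66)))
  bfac[!is.finite(bfac)] <- 0
  data.frame(
    serial = suppressWarnings(as.integer(f(7, 11))),
    name = name,
    altloc = f(17, 17),
    res_name = f(18, 20),
    chain = f(22, 22),
    res_seq = as.integer(num(23, 26, "resSeq")),
    icode = f(27, 27),
    x = num(31, 38, "x"), y = num(39, 46, "y"), z = num(47, 54, "z"),
    occupancy = occ, b_factor = bfac,
    element = toupper(element),
    is_hetero = startsWith(lines, "HETATM"),
    stringsAsFactors = FALSE)
}

# Keep the highest-occupancy altloc per (chain,res,icode,name); ties keep 'A'
# (or the alphabetically first present altloc).
.resolve_altloc <- function(atoms) {
  id <- paste(atoms$chain, atoms$res_seq, atoms$icode, atoms$name, sep = "\r")
  if (!anyDuplicated(id)) return(atoms)
  keep <- unlist(lapply(split(seq_len(nrow(atoms)), id), function(ix) {
    if (length(ix) == 1) return(ix)
    occ <- atoms$occupancy[ix]
    best <- ix[occ == max(occ)]
    best[order(atoms$altloc[best])][1]
  }), use.names = FALSE)
  atoms[sort(keep), , drop = FALSE]
}

.split_pdb_models <- function(lines) {
  model_starts <- grep("^MODEL ", lines)
  if (!length(model_starts)) {
    atom_mask <- grepl("^(ATOM  |HETATM)", lines)
    if (!any(atom_mask)) stop("PDB format error: no ATOM/HETATM records found")
    return(list(list(lines = lines[atom_mask], line_no = which(atom_mask))))
  }
  model_ends <- grep("^ENDMDL", lines)
  lapply(seq_along(model_starts), function(k) {
    lo <- model_starts[k]
    hi <- c(model_ends[model_ends > lo], length(lines))[1]
    blk <- lines[lo:hi]
    mask <- grepl("^(ATOM  |HETATM)", blk)
    list(lines = blk[mask], line_no = (lo:hi)[mask])
  })
}

.read_mmcif_atoms <- function(lines) {
  tag_idx <- grep("^_atom_site\\.", lines)
  if (!length(tag_idx)) stop("mmCIF format error: no _atom_site loop found")
  tags <- sub("^_atom_site\\.", "", trimws(lines[tag_idx]))
  body_start <- max(tag_idx) + 1
  body <- character()
  for (i in body_start:length(lines)) {
    ln <- trimws(lines[i])
    if (ln == "" || startsWith(ln, "#") || startsWith(ln, "_") ||
        startsWith(ln, "loop_")) break
    body <- c(body, ln)
  }
  if (!length(body)) stop("mmCIF format error: empty _atom_site loop")
  fields <- lapply(body, function(ln) scan(text = ln, what = "", quiet = TRUE))
  nf <- lengths(fields)
  if (any(nf != length(tags)))
    stop("mmCIF format error: atom_site row with ", nf[nf != length(tags)][1],
         " fields, expected ", length(tags))
  m <- do.call(rbind, fields)
  colnames(m) <- tags
  col <- function(nm, alt = NULL) {
    if (nm %in% tags) return(m[, nm])
    if (!is.null(alt) && alt %in% tags) return(m[, alt])
    rep(NA_character_, nrow(m))
  }
  qm <- function(v) ifelse(v %in% c("?", "."), "", v)
  data.frame(
    serial = as.integer(col("id")),
    name = qm(col("auth_atom_id", "label_atom_id")),
    altloc = qm(col("label_alt_id")),
    res_name = qm(col("auth_comp_id", "label_comp_id")),
    chain = qm(col("auth_asym_id", "label_asym_id")),
    res_seq = as.integer(qm(col("auth_seq_id", "label_seq_id"))),
    icode = qm(col("pdbx_PDB_ins_code")),
    x = as.numeric(col("Cartn_x")), y = as.numeric(col("Cartn_y")),
    z = as.numeric(col("Cartn_z")),
    occupancy = {o <- suppressWarnings(as.numeric(qm(col("occupancy"))))
                 o[!is.finite(o)] <- 1; o},
    b_factor = {b <- suppressWarnings(as.numeric(qm(col("B_iso_or_equiv"))))
                b[!is.finite(b)] <- 0; b},
    element = toupper(qm(col("type_symbol"))),
    is_hetero = col("group_PDB") == "HETATM",
    model_num = {mn <- suppressWarnings(as.integer(qm(col("pdbx_PDB_model_num"))))
                 mn[is.na(mn)] <- 1L; mn},
    stringsAsFactors = FALSE)
}

#' Read one model from a PDB or mmCIF file
#'
#' Parses ATOM/HETATM records (fixed-width PDB columns or the mmCIF
#' `_atom_site` loop), resolves alternate locations by keeping the
#' highest-occupancy copy (ties keep altloc 'A'), and flags hetero groups
#' as ligands (waters excluded).
#'
#' @param path file path; format detected from extension (.cif/.mmcif) or
#'   content
#' @param model_index which MODEL to return (1-based; default 1)
#' @return a `StructureModel`
#' @export
read_structure <- function(path, model_index = 1L) {
  lines <- readLines(path, warn = FALSE)
  is_cif <- grepl("\\.(cif|mmcif)$", path, ignore.case = TRUE) ||
    any(grepl("^_atom_site\\.", utils::head(lines, 400)))
  if (is_cif) {
    atoms <- .read_mmcif_atoms(lines)
    models <- sort(unique(atoms$model_num))
    if (model_index > length(models))
      stop("model index ", model_index, " out of range: file has ",
           length(models), " model(s)")
    atoms <- atoms[atoms$model_num == models[model_index], , drop = FALSE]
    atoms$model_num <- NULL
  } else {
    blocks <- .split_pdb_models(lines)
    if (model_index > length(blocks))
      stop("model index ", model_index, " out of range: file has ",
           length(blocks), " model(s)")
    blk <- blocks[[model_index]]
    atoms <- .parse_pdb_atom_lines(blk$lines, blk$line_no)
  }
  new_structure_model(.resolve_altloc(atoms), model_id = model_index)
}

#' Read a multi-model PDB file as an Ensemble
#'
#' All frames must share the same atom topology: identical atom count and
#' identical (chain, res_seq, name) ordering after per-model sorting.
#'
#' @param path multi-model PDB file
#' @return an `Ensemble`: list with `frames` (list of StructureModel) and
#'   `frame_times` (NULL unless set by a generator)
#' @export
read_ensemble <- function(path) {
  lines <- readLines(path, warn = FALSE)
  blocks <- .split_pdb_models(lines)
  frames <- lapply(seq_along(blocks), function(k)
    new_structure_model(.resolve_altloc(
      .parse_pdb_atom_lines(blocks[[k]]$lines, blocks[[k]]$line_no)), k))
  sig <- function(m) paste(m$chain, m$res_seq, m$name, sep = "|")
  ref <- sig(frames[[1]])
  for (k in seq_along(frames)[-1]) {
    s <- sig(frames[[k]])
    if (length(s) != length(ref) || any(s != ref)) {
      bad <- if (length(s) != length(ref)) {
        sprintf("frame %d has %d atoms, frame 1 has %d", k, length(s), length(ref))
      } else sprintf("frame %d first mismatch at atom %d: '%s' vs '%s'",
                     k, which(s != ref)[1], s[which(s != ref)[1]],
                     ref[which(s != ref)[1]])
      stop("ensemble topology error: ", bad)
    }
  }
  new_ensemble(frames)
}

new_ensemble <- function(frames, frame_times = NULL) {
  structure(list(frames = frames, frame_times = frame_times),
            class = "Ensemble")
}

#' @export
print.Ensemble <- function(x, ...) {
  cat(sprintf("Ensemble: %d frame(s), %d atoms/frame\n",
              length(x$frames), nrow(x$frames[[1]])))
  invisible(x)
}

#' @export
length.Ensemble <- function(x) length(x$frames)

.pdb_atom_line <- function(a) {
  rec <- ifelse(a$is_hetero, "HETATM", "ATOM  ")
  nm <- a$name
  nm <- ifelse(nchar(nm) < 4 & nchar(a$element) == 1,
               paste0(" ", nm), nm)
  sprintf("%s%5d %-4s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          rec, a$serial %% 100000L, substr(nm, 1, 4), substr(a$altloc, 1, 1),
          a$res_name, substr(a$chain, 1, 1), a$res_seq,
          substr(paste0(a$icode, " "), 1, 1),
          a$x, a$y, a$z, a$occupancy, a$b_factor, substr(a$element, 1, 2))
}

#' Write a StructureModel or Ensemble to a PDB file
#'
#' @param x a `StructureModel` or `Ensemble`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_pdb <- function(x, path) {
  if (inherits(x, "Ensemble")) {
    out <- character()
    for (k in seq_along(x$frames)) {
      m <- x$frames[[k]]
      m$serial <- seq_len(nrow(m))
      out <- c(out, sprintf("MODEL     %4d", k), .pdb_atom_line(m), "ENDMDL")
    }
    writeLines(c(out, "END"), path)
  } else {
    m <- x
    m$serial <- seq_len(nrow(m))
    writeLines(c(.pdb_atom_line(m), "END"), path)
  }
  invisible(path)
}

# ---- polar hydrogen placement -------------------------------------------

.has_attached_h <- function(model, idx, xyz = model_xyz(model)) {
  h <- which(model$element == "H")
  if (!length(h)) return(rep(FALSE, length(idx)))
  vapply(idx, function(i) {
    d2 <- (xyz[h, 1] - xyz[i, 1])^2 + (xyz[h, 2] - xyz[i, 2])^2 +
      (xyz[h, 3] - xyz[i, 3])^2
    any(d2 < 1.25^2)
  }, logical(1))
}

.h_row <- function(model, donor_idx, name, xyz) {
  a <- model[donor_idx, , drop = FALSE]
  a$serial <- NA_integer_
  a$name <- name
  a$element <- "H"
  a$x <- xyz[1]; a$y <- xyz[2]; a$z <- xyz[3]
  a$occupancy <- 1; a$b_factor <- 0
  a
}

#' Add polar hydrogens with ideal geometry
#'
#' Places a backbone amide H (1.01 Angstrom, in the C(-1)-N-CA plane,
#' bisecting the external angle) on every non-proline, non-N-terminal
#' residue, and ideal-geometry hydrogens on side-chain donors
#' (Ser/Thr/Tyr/Cys hydroxyl-thiol, Lys NZ, Arg NE/NH1/NH2, His ND1/NE2,
#' Trp NE1, Asn/Gln amide). Existing hydrogens are preserved; a donor that
#' already carries an H, or whose supporting heavy atoms are missing, is
#' skipped (with a warning in the latter case). Idempotent.
#'
#' @param model a `StructureModel` with heavy atoms present
#' @return a new `StructureModel` with hydrogens appended
#' @export
add_polar_hydrogens <- function(model) {
  xyz <- model_xyz(model)
  keys <- atom_residue_keys(model)
  res_keys <- unique(keys)
  new_rows <- list()
  skipped <- character()
  at <- function(key, nm) {
    i <- which(keys == key & model$name == nm)
    if (length(i)) i[1] else NA_integer_
  }
  pos <- function(i) xyz[i, ]
  add <- function(i, nm, p) {
    new_rows[[length(new_rows) + 1]] <<- .h_row(model, i, nm, p)
  }
  has_h <- function(i, n_expected = 1L) {
    h <- which(model$element == "H" & keys == keys[i])
    if (!length(h)) return(FALSE)
    d2 <- (xyz[h, 1] - xyz[i, 1])^2 + (xyz[h, 2] - xyz[i, 2])^2 +
      (xyz[h, 3] - xyz[i, 3])^2
    sum(d2 < 1.25^2) >= n_expected
  }
  # map chain -> ordered residue keys for N-terminus / previous-residue logic
  rk <- parse_residue_key(res_keys)
  for (ci in unique(rk$chain)) {
    chain_keys <- res_keys[rk$chain == ci]
    for (ri in seq_along(chain_keys)) {
      key <- chain_keys[ri]
      res_name <- model$res_name[which(keys == key)[1]]
      if (model$is_hetero[which(keys == key)[1]]) next
      # backbone amide H
      if (ri > 1 && !(res_name %in% "PRO")) {
        iN <- at(key, "N"); iCA <- at(key, "CA")
        iC0 <- at(chain_keys[ri - 1], "C")
        if (!is.na(iN) && !has_h(iN)) {
          if (is.na(iCA) || is.na(iC0)) {
            skipped <- c(skipped, paste0(key, ":N"))
          } else if (vnorm(pos(iC0) - pos(iN)) < 2.0) {  # bonded previous C
            u <- unit(unit(pos(iC0) - pos(iN)) + unit(pos(iCA) - pos(iN)))
            add(iN, "H", pos(iN) - 1.01 * u)
          }
        }
      }
      # side-chain donors
      don <- .SIDECHAIN_DONORS[[toupper(res_name)]]
      if (is.null(don)) next
      for (dn in names(don)) {
        i <- at(key, dn)
        if (is.na(i)) { skipped <- c(skipped, paste0(key, ":", dn)); next }
        placed <- switch(paste(toupper(res_name), dn),
          "SER OG" = ,
          "THR OG1" = ,
          "TYR OH" = ,
          "CYS SG" = {
            # one H anti to the preceding bond; length 0.96 (O-H) / 1.34 (S-H)
            b <- if (dn == "SG") at(key, "CB") else
              at(key, c(OG = "CB", OG1 = "CB", OH = "CZ")[dn])
            g <- if (dn == "OH") at(key, "CE1") else at(key, "CA")
            if (is.na(b) || is.na(g)) NULL else {
              len <- if (dn == "SG") 1.34 else 0.96
              ang <- if (dn == "SG") 96 else 109.5
              hn <- c(OG = "HG", OG1 = "HG1", OH = "HH", SG = "HG")[dn]
              list(list(hn, place_atom(pos(g), pos(b), pos(i), len, ang, 180)))
            }
          },
          "LYS NZ" = {
            b <- at(key, "CE"); g <- at(key, "CD")
            if (is.na(b) || is.na(g)) NULL else
              lapply(1:3, function(k) list(paste0("HZ", k),
                place_atom(pos(g), pos(b), pos(i), 1.01, 109.5, 60 + 120 * (k - 1))))
          },
          "ARG NE" = {
            b <- at(key, "CD"); z <- at(key, "CZ")
            if (is.na(b) || is.na(z)) NULL else {
              u <- -unit(unit(pos(b) - pos(i)) + unit(pos(z) - pos(i)))
              list(list("HE", pos(i) + 1.01 * u))
            }
          },
          "ARG NH1" = ,
          "ARG NH2" = {
            z <- at(key, "CZ"); e <- at(key, "NE")
            if (is.na(z) || is.na(e)) NULL else
              lapply(1:2, function(k) list(paste0("H", substr(dn, 3, 3), k),
                place_atom(pos(e), pos(z), pos(i), 1.01, 120, c(0, 180)[k])))
          },
          "HIS ND1" = ,
          "HIS NE2" = ,
          "TRP NE1" = {
            nb <- which(keys == key & model$element != "H" &
                          sqrt((xyz[, 1] - xyz[i, 1])^2 + (xyz[, 2] - xyz[i, 2])^2 +
                                 (xyz[, 3] - xyz[i, 3])^2) < 1.8 &
                          seq_len(nrow(model)) != i)
            if (length(nb) < 2) NULL else {
              u <- -unit(unit(pos(nb[1]) - pos(i)) + unit(pos(nb[2]) - pos(i)))
              list(list(paste0("H", substr(dn, 2, 10)), pos(i) + 1.01 * u))
            }
          },
          "ASN ND2" = ,
          "GLN NE2" = {
            cc <- at(key, if (dn == "ND2") "CG" else "CD")
            oo <- at(key, if (dn == "ND2") "OD1" else "OE1")
            if (is.na(cc) || is.na(oo)) NULL else
              lapply(1:2, function(k) list(paste0("H", substr(dn, 2, 10), k),
                place_atom(pos(oo), pos(cc), pos(i), 1.01, 120, c(0, 180)[k])))
          },
          NULL)
        if (is.null(placed)) {
          skipped <- c(skipped, paste0(key, ":", dn))
        } else if (!has_h(i, length(placed))) {
          for (p in placed) add(i, p[[1]], p[[2]])
        }
      }
    }
  }
  if (length(skipped))
    warning("donors skipped (missing supporting heavy atoms): ",
            paste(utils::head(skipped, 10), collapse = ", "),
            if (length(skipped) > 10) " ..." else "")
  if (!length(new_rows)) return(model)
  out <- rbind(as.data.frame(model), do.call(rbind, new_rows))
  out$serial <- seq_len(nrow(out))
  new_structure_model(out, attr(model, "model_id"))
}

#' Select the protein neighborhood of a ligand
#'
#' Returns every non-ligand atom within `radius` (closed interval) of any
#' ligand atom, with the contributing residues.
#'
#' @param model a `StructureModel`
#' @param ligand residue key of the ligand (see [residue_key()])
#' @param radius neighborhood radius in Angstrom (default 3.0)
#' @return list with `atoms` (row indices), `residues` (residue keys)
#' @export
select_neighborhood <- function(model, ligand, radius = 3.0) {
  stopifnot(radius >= 0)
  lig_idx <- residue_atom_idx(model, ligand)
  xyz <- model_xyz(model)
  other <- setdiff(seq_len(nrow(model)), lig_idx)
  if (!length(other))
    return(list(atoms = integer(), residues = character()))
  lx <- xyz[lig_idx, , drop = FALSE]
  sel <- other[vapply(other, function(i) {
    d2 <- (lx[, 1] - xyz[i, 1])^2 + (lx[, 2] - xyz[i, 2])^2 +
      (lx[, 3] - xyz[i, 3])^2
    any(d2 <= radius^2)
  }, logical(1))]
  list(atoms = sel, residues = unique(atom_residue_keys(model)[sel]))
}
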