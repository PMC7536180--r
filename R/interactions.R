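# Residue interaction networks: hydrogen-bond, van der Waals and pi-pi
# edges, with diffs between conformers.

#' Residue interaction network of a structure
#'
#' Edge types: `hbond` (Mayo-potential acceptance, energy attached;
#' requires polar hydrogens), `vdw` (heavy-atom distance <= sum of Bondi
#' radii + 0.5 Angstrom, between residues not already covalently bonded
#' or hydrogen bonded at that atom pair), and `pipi` (aromatic ring
#' centroids <= 5.5 Angstrom with interplanar angle <= 30 degrees
#' (stacked) or >= 60 degrees (T-shaped)). Edges are between distinct
#' residues.
#'
#' @param model a `StructureModel` (run [add_polar_hydrogens()] first)
#' @param selection optional residue-key filter (edge kept if either
#'   endpoint is in the selection)
#' @return `InteractionNetwork` data.frame: kind, res_a, res_b, atom_a,
#'   atom_b, distance, energy
#' @export
interaction_network <- function(model, selection = NULL) {
  keys <- atom_residue_keys(model)
  xyz <- model_xyz(model)
  cov <- detect_covalent_bonds(model)
  rows <- list()
  push <- function(kind, ia, ib, distance, energy = NA_real_) {
    a <- keys[ia]; b <- keys[ib]
    if (a == b) return()
    if (a > b) { tmp <- ia; ia <- ib; ib <- tmp; tmp <- a; a <- b; b <- tmp }
    rows[[length(rows) + 1]] <<- data.frame(
      kind = kind, res_a = a, res_b = b,
      atom_a = model$name[ia], atom_b = model$name[ib],
      distance = distance, energy = energy, stringsAsFactors = FALSE)
  }
  # hydrogen bonds (donor heavy atom to acceptor)
  hb <- find_hbond_candidates(model, cov)
  for (r in seq_len(nrow(hb)))
    push("hbond", hb$donor[r], hb$acceptor[r],
         vnorm(xyz[hb$acceptor[r], ] - xyz[hb$donor[r], ]), hb$energy[r])
  hb_pair <- if (nrow(hb)) paste(pmin(hb$donor, hb$acceptor),
                                 pmax(hb$donor, hb$acceptor)) else character()
  cov_pair <- paste(cov$i, cov$j)
  # van der Waals contacts between heavy atoms of different residues
  heavy <- which(model$element != "H")
  if (length(heavy) > 1) {
    rv <- vdw_radius(model$element)
    for (ai in seq_along(heavy)[-length(heavy)]) {
      i <- heavy[ai]
      js <- heavy[(ai + 1):length(heavy)]
      js <- js[keys[js] != keys[i]]
      if (!length(js)) next
      d <- sqrt((xyz[js, 1] - xyz[i, 1])^2 + (xyz[js, 2] - xyz[i, 2])^2 +
                  (xyz[js, 3] - xyz[i, 3])^2)
      hit <- js[d <= rv[i] + rv[js] + 0.5]
      for (j in hit) {
        pr <- paste(min(i, j), max(i, j))
        if (pr %in% cov_pair || pr %in% hb_pair) next
        push("vdw", i, j, sqrt(sum((xyz[j, ] - xyz[i, ])^2)))
      }
    }
  }
  # pi-pi between aromatic rings
  rings <- list()
  for (key in unique(keys)) {
    rdef <- .AROMATIC_RINGS[[toupper(model$res_name[which(keys == key)[1]])]]
    if (is.null(rdef)) next
    for (ring in rdef) {
      idx <- vapply(ring, function(nm) {
        i <- which(keys == key & model$name == nm)
        if (length(i)) i[1] else NA_integer_
      }, integer(1))
      if (anyNA(idx)) next
      pts <- xyz[idx, , drop = FALSE]
      ctr <- colMeans(pts)
      sv <- svd(sweep(pts, 2, ctr))
      rings[[length(rings) + 1]] <- list(key = key, idx = idx[1], ctr = ctr,
                                         normal = sv$v[, 3])
    }
  }
  if (length(rings) > 1) {
    for (ai in seq_along(rings)[-length(rings)]) for (bi in (ai + 1):length(rings)) {
      ra <- rings[[ai]]; rb <- rings[[bi]]
      if (ra$key == rb$key) next
      d <- vnorm(ra$ctr - rb$ctr)
      if (d > 5.5) next
      ang <- deg(acos(min(1, abs(sum(ra$normal * rb$normal)))))
      if (ang <= 30 || ang >= 60) push("pipi", ra$idx, rb$idx, d)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(kind = character(), res_a = character(), res_b = character(),
               atom_a = character(), atom_b = character(),
               distance = numeric(), energy = numeric(),
               stringsAsFactors = FALSE)
  if (!is.null(selection))
    out <- out[out$res_a %in% selection | out$res_b %in% selection, ,
               drop = FALSE]
  out <- out[!duplicated(out[, c("kind", "res_a", "res_b", "atom_a", "atom_b")]), ,
             drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("InteractionNetwork", "data.frame"))
}

#' Diff two interaction networks
#'
#' Edges are keyed by (kind, residue pair); returns edges present only in
#' the second network (`added`) and only in the first (`lost`).
#'
#' @param a,b `InteractionNetwork`s (e.g. open and closed conformers)
#' @return list with `added` and `lost` data.frames
#' @export
interaction_diff <- function(a, b) {
  key <- function(x) paste(x$kind, x$res_a, x$res_b)
  ka <- unique(key(a)); kb <- unique(key(b))
  list(added = b[key(b) %in% setdiff(kb, ka) & !duplicated(key(b)), ,
                 drop = FALSE],
       lost = a[key(a) %in% setdiff(ka, kb) & !duplicated(key(a)), ,
                drop = FALSE])
}
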