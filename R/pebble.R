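# The (6,6) body-bar pebble game.
#
# Each body starts with 6 pebbles (its 6 rigid-body degrees of freedom).
# A bar between u and v is independent (accepted) iff 7 pebbles can be
# gathered on {u, v}; accepting consumes one pebble and orients a directed
# edge away from the paying endpoint. Pebble searches are depth-first with
# deterministic ascending-id tie-breaking, so the final free-pebble count
# and the rigid-cluster partition are independent of edge insertion order
# (a matroid property of the game).
#
# State is an environment: n, peb (free pebbles per body), out (n x n
# integer matrix of directed bar multiplicities), comp (union-find parent).

pg_new <- function(n) {
  st <- new.env(parent = emptyenv())
  st$n <- as.integer(n)
  st$peb <- rep(6L, n)
  st$out <- matrix(0L, n, n)
  st$comp <- seq_len(n)
  st
}

pg_clone <- function(st) {
  st2 <- new.env(parent = emptyenv())
  st2$n <- st$n; st2$peb <- st$peb; st2$out <- st$out; st2$comp <- st$comp
  st2
}

pg_find_root <- function(st, v) {
  while (st$comp[v] != v) {
    st$comp[v] <- st$comp[st$comp[v]]
    v <- st$comp[v]
  }
  v
}

pg_union <- function(st, u, v) {
  ru <- pg_find_root(st, u); rv <- pg_find_root(st, v)
  if (ru != rv) st$comp[max(ru, rv)] <- min(ru, rv)
}

# Depth-first search from `target` along directed edges for a free pebble
# at any vertex not in `forbidden`; on success the path is reversed and
# one pebble moves to `target`. Returns TRUE/FALSE.
pg_find_pebble <- function(st, target, forbidden = integer()) {
  n <- st$n
  visited <- logical(n)
  visited[target] <- TRUE
  parent <- integer(n)
  stack <- c(target)
  found <- 0L
  forbid <- logical(n)
  forbid[forbidden] <- TRUE
  while (length(stack)) {
    v <- stack[[length(stack)]]
    stack <- stack[-length(stack)]
    nbrs <- which(st$out[v, ] > 0L & !visited)
    for (w in nbrs) {
      visited[w] <- TRUE
      parent[w] <- v
      if (!forbid[w] && st$peb[w] > 0L) { found <- w; break }
      stack <- c(stack, w)
    }
    if (found) break
  }
  if (!found) return(FALSE)
  # reverse the path found -> target, moving the pebble
  st$peb[found] <- st$peb[found] - 1L
  st$peb[target] <- st$peb[target] + 1L
  w <- found
  while (w != target) {
    v <- parent[w]
    st$out[v, w] <- st$out[v, w] - 1L
    st$out[w, v] <- st$out[w, v] + 1L
    w <- v
  }
  TRUE
}

# Try to insert one bar between u and v. Returns TRUE if independent
# (accepted), FALSE if redundant.
pg_insert_bar <- function(st, u, v) {
  stopifnot(u != v)
  while (st$peb[u] < 6L && pg_find_pebble(st, u, forbidden = v)) {}
  while (st$peb[u] + st$peb[v] < 7L && pg_find_pebble(st, v, forbidden = u)) {}
  pg_union(st, u, v)
  if (st$peb[u] + st$peb[v] < 7L) return(FALSE)
  if (st$peb[u] > 0L) {
    st$peb[u] <- st$peb[u] - 1L
    st$out[u, v] <- st$out[u, v] + 1L
  } else {
    st$peb[v] <- st$peb[v] - 1L
    st$out[v, u] <- st$out[v, u] + 1L
  }
  TRUE
}

# TRUE iff u and v are mutually rigid (a probe bar would be redundant).
# Only relocates pebbles; never consumes them.
pg_mutually_rigid <- function(st, u, v) {
  while (st$peb[u] < 6L && pg_find_pebble(st, u, forbidden = v)) {}
  while (st$peb[u] + st$peb[v] < 7L && pg_find_pebble(st, v, forbidden = u)) {}
  st$peb[u] + st$peb[v] < 7L
}

# Maximum number of pebbles collectable on a body set (pure relocation).
pg_gather_set <- function(st, bodies) {
  repeat {
    moved <- FALSE
    for (s in bodies) {
      while (st$peb[s] < 6L && pg_find_pebble(st, s, forbidden = bodies)) {
        moved <- TRUE
      }
    }
    if (!moved) break
  }
  sum(st$peb[bodies])
}

# Free DOF available at a body set beyond the 6 trivial rigid-body ones.
pg_free_dof_set <- function(st, bodies) {
  max(0L, pg_gather_set(st, bodies) - 6L)
}

.pg_run <- function(network) {
  edges <- network$edges
  stopifnot(inherits(network, "ConstraintNetwork"))
  if (!all(edges$bars %in% c(2L, 5L, 6L)))
    stop("invalid bar count: bars must be 2, 5 or 6")
  st <- pg_new(network$n_bodies)
  redundant <- 0L
  if (nrow(edges)) {
    ord <- order(edges$i, edges$j)
    for (r in ord) {
      u <- as.integer(edges$i[r]); v <- as.integer(edges$j[r])
      for (b in seq_len(edges$bars[r])) {
        if (!pg_insert_bar(st, u, v)) redundant <- redundant + 1L
      }
    }
  }
  list(state = st, redundant = redundant)
}

#' Run the (6,6) body-bar pebble game
#'
#' Counts the internal (conformational) degrees of freedom of a constraint
#' network: total free pebbles minus 6 per connected component. Bars that
#' cannot gather 7 pebbles are redundant.
#'
#' @param network a `ConstraintNetwork`
#' @return list with `internal_dof`, `redundant_bars`, `free_pebbles`,
#'   `n_components`, and the final pebble `state`
#' @export
pebble_game_dof <- function(network) {
  run <- .pg_run(network)
  st <- run$state
  roots <- vapply(seq_len(st$n), function(v) pg_find_root(st, v), integer(1))
  ncomp <- length(unique(roots))
  free <- sum(st$peb)
  list(internal_dof = free - 6L * ncomp, redundant_bars = run$redundant,
       free_pebbles = free, n_components = ncomp, state = st,
       components = roots)
}

#' Rigid-cluster decomposition
#'
#' Partitions the bodies into maximal rigid clusters: two bodies share a
#' cluster iff they are mutually rigid (a probe bar between them would be
#' redundant). Cluster labels are the smallest member body id; clusters
#' are reported sorted by size (descending, ties by label).
#'
#' @param network a `ConstraintNetwork`
#' @return `RigidClusterDecomposition`: list with `cluster_id` (per body),
#'   `sizes` (named, sorted), `lrc_id`, `lrc_size`, `n_clusters`,
#'   `internal_dof`, `redundant_bars`, and the network's `atoms` table
#' @export
rigid_clusters <- function(network) {
  pg <- pebble_game_dof(network)
  st <- pg$state
  n <- st$n
  cluster <- integer(n)
  for (s in seq_len(n)) {
    if (cluster[s] != 0L) next
    cluster[s] <- s
    cand <- which(cluster == 0L & pg$components == pg$components[s])
    cand <- cand[cand > s]
    for (v in cand) {
      if (pg_mutually_rigid(st, s, v)) cluster[v] <- s
    }
  }
  sizes <- table(cluster)
  sizes <- sizes[order(-as.integer(sizes), as.integer(names(sizes)))]
  lrc_id <- as.integer(names(sizes)[1])
  structure(list(cluster_id = cluster, sizes = sizes, lrc_id = lrc_id,
                 lrc_size = as.integer(sizes[1]),
                 n_clusters = length(sizes),
                 internal_dof = pg$internal_dof,
                 redundant_bars = pg$redundant_bars,
                 atoms = network$atoms),
            class = "RigidClusterDecomposition")
}

#' @export
print.RigidClusterDecomposition <- function(x, ...) {
  cat(sprintf(
    "RigidClusterDecomposition: %d clusters, LRC %d bodies (id %d), %d internal DOF, %d redundant bars\n",
    x$n_clusters, x$lrc_size, x$lrc_id, x$internal_dof, x$redundant_bars))
  invisible(x)
}

#' Fraction of a residue range inside the largest rigid cluster
#'
#' @param decomp a `RigidClusterDecomposition` from a structure-derived
#'   network (its `atoms` table carries the residue back-map)
#' @param residues character vector of residue keys
#' @return atom-weighted fraction in [0, 1]
#' @export
cluster_membership_stats <- function(decomp, residues) {
  if (!length(residues)) stop("empty residue range")
  idx <- which(decomp$atoms$key %in% residues)
  if (!length(idx)) stop("no atoms found for the given residues")
  mean(decomp$cluster_id[idx] == decomp$lrc_id)
}

#' Export a decomposition as a per-atom cluster table
#' @param decomp a `RigidClusterDecomposition`
#' @param path output TSV path
#' @return `path` invisibly
#' @export
write_cluster_tsv <- function(decomp, path) {
  df <- data.frame(body = seq_along(decomp$cluster_id),
                   residue = decomp$atoms$key,
                   atom = decomp$atoms$name,
                   cluster = decomp$cluster_id,
                   in_lrc = decomp$cluster_id == decomp$lrc_id)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
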