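# Max-tree merge analysis of the sequence-count landscape.
#
# Sweeping a threshold down from the landscape maximum, connected components
# (toroidal 8-neighborhood) appear at regional maxima (the reliable
# pathways) and join as the threshold falls.  Each join of two components
# that already existed above the current level is a "merge": the cells that
# enter at the merge level and lie close to both parents are the
# semi-transmissive bridge between two reliable pathways.

# toroidal 8-neighbors of cell ids (1-based, x varies fastest)
torus_neighbors8 <- function(ids, nrows) {
  x <- (ids - 1L) %% nrows
  y <- (ids - 1L) %/% nrows
  out <- integer(0)
  for (dx in -1:1) for (dy in -1:1) {
    if (dx == 0L && dy == 0L) next
    out <- c(out, ((y + dy) %% nrows) * nrows + ((x + dx) %% nrows) + 1L)
  }
  matrix(out, nrow = length(ids))  # one row per id, 8 columns
}

#' Build the merge tree of a landscape
#'
#' Descending integer-threshold sweep over the landscape with toroidal
#' 8-neighborhood connectivity.  A merge is recorded at the highest threshold
#' at which two components, each born strictly above that threshold (i.e.
#' each containing a regional maximum above it), become connected.  When a
#' level joins more than two such components, `m` components yield `m - 1`
#' merges at that level.
#'
#' @param landscape a [sequence_landscape()] object, or an integer vector of
#'   length `nrows^2`.
#' @param geometry matching [build_grid()] object.
#' @return `stas_mergetree`: list with `merges` (list of records: `threshold`,
#'   `comp_a`, `comp_b` cell-id sets, `entering` cells at the merge level),
#'   `n_merges`, `end_nodes`, `nrows`.
#' @export
build_max_tree <- function(landscape, geometry) {
  count <- if (inherits(landscape, "stas_landscape")) landscape$count else landscape
  nrows <- geometry$nrows
  n <- nrows * nrows
  if (length(count) != n) stop("landscape length must equal nrows^2")
  if (any(count < 0)) stop("landscape must be nonnegative")

  if (max(count) == 0)
    return(structure(list(merges = list(), n_merges = 0L, end_nodes = 0L,
                          nrows = nrows),
                     class = "stas_mergetree"))

  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  added <- logical(n)
  nbrs <- torus_neighbors8(seq_len(n), nrows)
  merges <- list()

  for (L in sort(unique(count), decreasing = TRUE)) {
    newcells <- which(count == L)
    # snapshot of the components existing strictly above this level
    prev_root <- rep(NA_integer_, n)
    prev_cells <- which(added)
    if (length(prev_cells))
      prev_root[prev_cells] <- vapply(prev_cells, find, integer(1))

    for (cell in newcells) {
      added[cell] <- TRUE
      for (nb in nbrs[cell, ]) {
        if (added[nb]) {
          a <- find(cell); b <- find(nb)
          if (a != b) parent[b] <- a
        }
      }
    }

    if (!length(prev_cells)) next
    # group pre-existing components by their root after this level's unions
    prev_roots_unique <- unique(prev_root[prev_cells])
    now_root_of_prev <- vapply(prev_roots_unique, find, integer(1))
    for (g in unique(now_root_of_prev)) {
      comps <- prev_roots_unique[now_root_of_prev == g]
      if (length(comps) < 2L) next
      sets <- lapply(comps, function(r) prev_cells[prev_root[prev_cells] == r])
      sets <- sets[order(-vapply(sets, length, integer(1)))]
      entering <- newcells[vapply(newcells, find, integer(1)) == g]
      acc <- sets[[1]]
      for (k in 2:length(sets)) {
        merges[[length(merges) + 1L]] <- list(
          threshold = L, comp_a = acc, comp_b = sets[[k]], entering = entering)
        acc <- c(acc, sets[[k]])
      }
    }
  }

  structure(list(merges = merges, n_merges = length(merges),
                 end_nodes = length(merges) + 1L, nrows = nrows),
            class = "stas_mergetree")
}

#' @method print stas_mergetree
#' @export
print.stas_mergetree <- function(x, ...) {
  cat("stas_mergetree: ", x$n_merges, " merges, ", x$end_nodes,
      " end nodes (", x$nrows, "x", x$nrows, " landscape)\n", sep = "")
  invisible(x)
}

# min toroidal distance from each of `ids` to the cell set `set`
dist_to_set <- function(ids, set, nrows) {
  px <- (ids - 1L) %% nrows;  py <- (ids - 1L) %/% nrows
  sx <- (set - 1L) %% nrows;  sy <- (set - 1L) %/% nrows
  vapply(seq_along(ids), function(i) {
    dx <- abs(px[i] - sx); dx <- pmin(dx, nrows - dx)
    dy <- abs(py[i] - sy); dy <- pmin(dy, nrows - dy)
    sqrt(min(dx * dx + dy * dy))
  }, numeric(1))
}

#' Extract semi-transmissive bridge neurons
#'
#' For each merge of the tree, the bridge is formed by the cells that enter
#' the joined component at the merge threshold and lie within `d_max` of both
#' parent components; it is augmented by the 8-neighbors of those cells that
#' are within `neighbor_radius` of both components.  The `d_max` filter
#' removes artifact cells of the merge level that are far from one of the
#' pathways.
#'
#' @param tree a [build_max_tree()] object.
#' @param landscape the landscape the tree was built from (unused; kept for
#'   interface completeness).
#' @param geometry matching [build_grid()] object.
#' @param d_max maximum distance to both parent components (default 4).
#' @param neighbor_radius inclusion radius for neighbors of bridge cells
#'   (default 10).
#' @return list of `stas_bridge`: `neurons` (cell ids), `merge_ref` (index
#'   into `tree$merges`), `threshold`, `d_max`, `neighbor_radius`.
#' @export
extract_bridges <- function(tree, landscape = NULL, geometry,
                            d_max = 4, neighbor_radius = 10) {
  nrows <- geometry$nrows
  lapply(seq_along(tree$merges), function(mi) {
    m <- tree$merges[[mi]]
    cand <- m$entering
    if (length(cand)) {
      da <- dist_to_set(cand, m$comp_a, nrows)
      db <- dist_to_set(cand, m$comp_b, nrows)
      core <- cand[da <= d_max & db <= d_max]
    } else core <- integer(0)
    neurons <- core
    if (length(core)) {
      nb <- unique(as.vector(torus_neighbors8(core, nrows)))
      nb <- setdiff(nb, core)
      if (length(nb)) {
        da <- dist_to_set(nb, m$comp_a, nrows)
        db <- dist_to_set(nb, m$comp_b, nrows)
        neurons <- sort(c(core, nb[da <= neighbor_radius & db <= neighbor_radius]))
      }
    }
    structure(list(neurons = neurons, merge_ref = mi,
                   threshold = m$threshold, d_max = d_max,
                   neighbor_radius = neighbor_radius),
              class = "stas_bridge")
  })
}

#' Merge-count statistics across networks
#'
#' @param trees list of [build_max_tree()] objects.
#' @return list with `mean_merges` and `histogram` (table of merge counts).
#' @export
merge_statistics <- function(trees) {
  if (!length(trees)) stop("need at least one tree")
  counts <- vapply(trees, function(t) as.numeric(t$n_merges), numeric(1))
  list(mean_merges = mean(counts), histogram = table(counts))
}

#' Export a merge report as delimited text
#'
#' One row per merge: threshold, parent component sizes, bridge-neuron count.
#'
#' @param tree a [build_max_tree()] object.
#' @param bridges matching [extract_bridges()] list.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
export_merge_report <- function(tree, bridges, path) {
  df <- do.call(rbind, lapply(seq_along(tree$merges), function(i) {
    m <- tree$merges[[i]]
    data.frame(merge = i, threshold = m$threshold,
               size_a = length(m$comp_a), size_b = length(m$comp_b),
               n_bridge = length(bridges[[i]]$neurons))
  }))
  if (is.null(df))
    df <- data.frame(merge = integer(), threshold = numeric(),
                     size_a = integer(), size_b = integer(),
                     n_bridge = integer())
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
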