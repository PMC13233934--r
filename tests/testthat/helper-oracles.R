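# Brute-force reference implementations (oracles), kept independent of the
# package's optimized code paths.

# minimal-image distance as the minimum over the 9 shifted images
oracle_toroidal_distance <- function(a, b, nrows) {
  best <- Inf
  for (dx in c(-nrows, 0, nrows)) for (dy in c(-nrows, 0, nrows)) {
    d <- sqrt((a[1] - b[1] + dx)^2 + (a[2] - b[2] + dy)^2)
    best <- min(best, d)
  }
  best
}

# O(n^2) density clustering with the full toroidal metric on (x, y, t*ts):
# core points have >= min_samples neighbors (self included) within eps;
# clusters are connected components of core points; border points attach to
# any core neighbor.  Returns integer labels, 0 = noise.
oracle_toroidal_dbscan <- function(cloud, eps, min_samples, nrows,
                                   time_scale = 1) {
  n <- nrow(cloud)
  if (!n) return(integer(0))
  dx <- abs(outer(cloud$x, cloud$x, "-")); dx <- pmin(dx, nrows - dx)
  dy <- abs(outer(cloud$y, cloud$y, "-")); dy <- pmin(dy, nrows - dy)
  dt <- outer(cloud$t, cloud$t, "-") * time_scale
  adj <- dx^2 + dy^2 + dt^2 <= eps^2
  core <- rowSums(adj) >= min_samples
  labels <- integer(n)
  cl <- 0L
  for (i in which(core)) {
    if (labels[i] > 0) next
    cl <- cl + 1L
    queue <- i
    labels[i] <- cl
    while (length(queue)) {
      j <- queue[1]; queue <- queue[-1]
      nb <- which(adj[j, ])
      for (k in nb) {
        if (labels[k] == 0) {
          labels[k] <- cl
          if (core[k]) queue <- c(queue, k)
        }
      }
    }
  }
  labels
}

# partitions equal up to label permutation on the points both labelings
# assign to clusters; the noise sets may differ by at most `noise_tol`
same_partition_core <- function(a, b, noise_tol = 0.05) {
  if (length(a) != length(b)) return(FALSE)
  if (mean((a == 0) != (b == 0)) > noise_tol) return(FALSE)
  keep <- a != 0 & b != 0
  if (!any(keep)) return(TRUE)
  tab <- table(a[keep], b[keep])
  all(rowSums(tab > 0) == 1) && all(colSums(tab > 0) == 1)
}

# partitions equal up to label permutation (noise must match exactly)
same_partition <- function(a, b) {
  if (length(a) != length(b)) return(FALSE)
  if (!all((a == 0) == (b == 0))) return(FALSE)
  keep <- a != 0
  if (!any(keep)) return(TRUE)
  tab <- table(a[keep], b[keep])
  all(rowSums(tab > 0) == 1) && all(colSums(tab > 0) == 1)
}

# naive max-tree merge count: independent flood-fill labeling per threshold
# level; merges at level L = pre-existing components (from the level above)
# that become connected, counted pairwise
oracle_merge_sweep <- function(count, nrows) {
  n <- nrows * nrows
  neighbors <- function(id) {
    x <- (id - 1) %% nrows; y <- (id - 1) %/% nrows
    out <- integer(0)
    for (dx in -1:1) for (dy in -1:1) {
      if (dx == 0 && dy == 0) next
      out <- c(out, ((y + dy) %% nrows) * nrows + ((x + dx) %% nrows) + 1)
    }
    out
  }
  components <- function(cells) {
    lab <- integer(n); cl <- 0
    inset <- logical(n); inset[cells] <- TRUE
    for (c0 in cells) {
      if (lab[c0] > 0) next
      cl <- cl + 1
      queue <- c0; lab[c0] <- cl
      while (length(queue)) {
        j <- queue[1]; queue <- queue[-1]
        for (k in neighbors(j)) if (inset[k] && lab[k] == 0) {
          lab[k] <- cl; queue <- c(queue, k)
        }
      }
    }
    lab
  }
  if (max(count) == 0) return(list(n_merges = 0L, thresholds = integer(0)))
  levels <- sort(unique(count), decreasing = TRUE)
  merges <- integer(0)
  prev_lab <- NULL
  for (L in levels) {
    cells <- which(count >= L)
    lab <- components(cells)
    if (!is.null(prev_lab)) {
      prev_ids <- unique(prev_lab[prev_lab > 0])
      for (g in unique(lab[lab > 0])) {
        prev_in_g <- unique(prev_lab[lab == g & prev_lab > 0])
        if (length(prev_in_g) >= 2)
          merges <- c(merges, rep(L, length(prev_in_g) - 1))
      }
    }
    prev_lab <- lab
  }
  list(n_merges = length(merges), thresholds = sort(merges, decreasing = TRUE))
}

# O(u^2) max pairwise toroidal distance
oracle_extent <- function(xy, nrows) {
  best <- 0
  if (nrow(xy) < 2) return(0)
  for (i in 1:(nrow(xy) - 1)) for (j in (i + 1):nrow(xy)) {
    best <- max(best, oracle_toroidal_distance(xy[i, ], xy[j, ], nrows))
  }
  best
}

# enumeration oracle for transmission tallies on a crossing table
oracle_transmission <- function(crossings, pre, post) {
  ids <- unique(crossings$seq_id)
  n_pre <- n_post <- n_both <- n_ord <- 0
  for (id in ids) {
    a <- crossings[crossings$seq_id == id & crossings$spot == pre, ]
    b <- crossings[crossings$seq_id == id & crossings$spot == post, ]
    ca <- nrow(a) && a$crossed; cb <- nrow(b) && b$crossed
    if (ca) n_pre <- n_pre + 1
    if (cb) n_post <- n_post + 1
    if (ca && cb) {
      n_both <- n_both + 1
      if (a$t_first <= b$t_first) n_ord <- n_ord + 1
    }
  }
  list(n_pre = n_pre, n_post = n_post, n_both = n_both, n_ordered = n_ord)
}

# fake rate trace for detection tests: rates is neurons x steps
fake_trace <- function(rates, nrows, dt = 1) {
  structure(list(rates = rates, time = seq_len(ncol(rates)) * dt,
                 record = "exc",
                 config = sim_config(t_sim = ncol(rates) * dt,
                                     t_warmup = 0, dt = dt),
                 noise = NULL, connectome_seed = NA, nrows = nrows),
            class = "stas_trace")
}

# synthetic sequence with a straight event trail (for spot/motif tests)
fake_sequence <- function(id, path_xy, t0, nrows, step_ms = 1) {
  ev <- data.frame(x = path_xy[, 1], y = path_xy[, 2],
                   t = t0 + (seq_len(nrow(path_xy)) - 1) * step_ms,
                   neuron = as.integer(path_xy[, 2] * nrows + path_xy[, 1] + 1))
  structure(list(id = id, events = ev, neurons = sort(unique(ev$neuron)),
                 t_start = min(ev$t), t_end = max(ev$t),
                 duration = max(ev$t) - min(ev$t),
                 extent = oracle_extent(as.matrix(ev[, c("x", "y")]), nrows)),
            class = "stas_sequence")
}
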