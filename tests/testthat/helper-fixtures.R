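# shared fixtures and independent oracles, all built in code

# digital cylinder along z: radius in voxels, value fg_hu inside
make_cylinder_volume <- function(r_vox, length_vox = 40, pad = 4,
                                 fg_hu = 3000, bg_hu = 0, spacing = 1) {
  side <- 2 * ceiling(r_vox) + 2 * pad + 1
  ctr <- (side + 1) / 2
  arr <- array(bg_hu, c(side, side, length_vox))
  for (i in seq_len(side)) for (j in seq_len(side))
    if ((i - ctr)^2 + (j - ctr)^2 <= r_vox^2) arr[i, j, ] <- fg_hu
  voxel_volume(arr, spacing = spacing)
}

# digital sphere of radius r_vox
make_sphere_mask <- function(r_vox, pad = 3) {
  side <- 2 * ceiling(r_vox) + 2 * pad + 1
  ctr <- (side + 1) / 2
  arr <- array(FALSE, c(side, side, side))
  for (i in seq_len(side)) for (j in seq_len(side)) for (k in seq_len(side))
    if ((i - ctr)^2 + (j - ctr)^2 + (k - ctr)^2 <= r_vox^2) arr[i, j, k] <- TRUE
  threshold_volume(voxel_volume(arr + 0, spacing = 1), 0.5, 1.5)
}

# brute-force average distance to the k-th nearest neighbour
knn_avg_oracle <- function(pts, ks) {
  dm <- as.matrix(stats::dist(pts))
  diag(dm) <- Inf
  vapply(ks, function(k) {
    mean(apply(dm, 1, function(row) sort(row)[k]))
  }, numeric(1))
}

# literal O(n^2) replay of the three linking rules; returns a canonical
# edge matrix (two columns, from < to) for comparison with the package
naive_reconstruct_edges <- function(pts, scales) {
  n <- nrow(pts)
  dm <- as.matrix(stats::dist(pts))
  diag(dm) <- Inf
  adj <- lapply(seq_len(n), function(i) integer(0))
  deg <- integer(n)
  edges <- matrix(integer(0), ncol = 2)
  add_edge <- function(i, j) {
    adj[[i]] <<- c(adj[[i]], j); adj[[j]] <<- c(adj[[j]], i)
    deg[i] <<- deg[i] + 1L; deg[j] <<- deg[j] + 1L
    edges <<- rbind(edges, c(min(i, j), max(i, j)))
  }
  reachable <- function(a, b) {
    seen <- logical(n); queue <- a; seen[a] <- TRUE
    while (length(queue) > 0) {
      v <- queue[1]; queue <- queue[-1]
      for (w in adj[[v]]) if (!seen[w]) {
        if (w == b) return(TRUE)
        seen[w] <- TRUE; queue <- c(queue, w)
      }
    }
    FALSE
  }
  # stage 1: nearest suitable (unconnected, degree < 2) neighbour,
  # ties to lower id
  for (i in seq_len(n)) {
    ord <- order(dm[i, ], seq_len(n))
    for (j in ord) {
      if (dm[i, j] >= scales$nn2) break
      if (deg[j] < 2L && !reachable(i, j)) { add_edge(i, j); break }
    }
  }
  # stage 2: endpoints to their nearest not-yet-reachable node within nn5
  for (u in seq_len(n)) {
    if (deg[u] > 1L) next
    ord <- order(dm[u, ], seq_len(n))
    for (j in ord) {
      if (dm[u, j] >= scales$nn5) break
      if (reachable(u, j)) next
      add_edge(u, j)
      break
    }
  }
  # stage 3: degree-1 nodes to the nearest node of another component
  comp_of <- function() {
    comp <- integer(n); c0 <- 0L
    for (s in seq_len(n)) {
      if (comp[s] != 0L) next
      c0 <- c0 + 1L; queue <- s; comp[s] <- c0
      while (length(queue) > 0) {
        v <- queue[1]; queue <- queue[-1]
        for (w in adj[[v]]) if (comp[w] == 0L) { comp[w] <- c0; queue <- c(queue, w) }
      }
    }
    comp
  }
  for (u in seq_len(n)) {
    if (deg[u] != 1L) next
    comp <- comp_of()
    other <- which(comp != comp[u])
    if (length(other) == 0) break
    j <- other[which.min(dm[u, other])]
    if (dm[u, j] >= scales$nn10) next
    add_edge(u, j)
  }
  edges[order(edges[, 1], edges[, 2]), , drop = FALSE]
}

canonical_edges <- function(g) {
  e <- cbind(pmin(g$edges$from, g$edges$to), pmax(g$edges$from, g$edges$to))
  e[order(e[, 1], e[, 2]), , drop = FALSE]
}

# random spatial point set mixing a jittered polyline and a sparse cloud,
# exercising chains, endpoints and disconnected fragments
random_centerline_points <- function(n, seed) {
  set.seed(seed)
  n_line <- ceiling(n * 0.7)
  t <- sort(runif(n_line, 0, 100))
  line <- cbind(t, 10 * sin(t / 12), 6 * cos(t / 19)) +
    matrix(rnorm(3 * n_line, 0, 0.4), ncol = 3)
  cloud <- cbind(runif(n - n_line, 0, 100), runif(n - n_line, -20, 20),
                 runif(n - n_line, -15, 15))
  pts <- rbind(line, cloud)
  pts[!duplicated(round(pts, 9)), , drop = FALSE]
}

# random segment-level tree (for Strahler oracle tests): returns a list with
# a segments tibble, a minimal vascular_graph, and the root node id
random_segment_tree <- function(n_segments, seed) {
  set.seed(seed)
  # node 1 is the root; each new segment attaches to a uniformly chosen
  # existing attachment node
  from <- integer(0); to <- integer(0)
  attach_nodes <- 1L
  next_node <- 2L
  for (s in seq_len(n_segments)) {
    a <- sample(attach_nodes, 1)
    from <- c(from, a); to <- c(to, next_node)
    attach_nodes <- c(attach_nodes, next_node)
    next_node <- next_node + 1L
  }
  n <- next_node - 1L
  nodes <- tibble::tibble(id = seq_len(n), x = runif(n), y = runif(n),
                          z = runif(n), d = runif(n, 10, 100))
  g <- vasctree:::new_vascular_graph(
    nodes, tibble::tibble(from = from, to = to,
                          length = runif(length(from), 1, 10)))
  segments <- tibble::tibble(
    segment = seq_along(from), from = from, to = to,
    length = g$edges$length, diameter = runif(length(from), 10, 100),
    n_nodes = 2L, path = lapply(seq_along(from), function(k) c(from[k], to[k])))
  list(segments = segments, graph = g, root = 1L)
}

# independent recursive-definition Strahler oracle on a segment tree
strahler_oracle <- function(segments, root) {
  # child segments of a segment share its far endpoint; root segment is the
  # one incident to the root node
  n <- nrow(segments)
  # orient: BFS over segments from the root node
  incident <- function(node) which(segments$from == node | segments$to == node)
  parent_end <- integer(n); child_end <- integer(n)
  seen <- logical(n)
  queue <- root
  node_seen <- root
  while (length(queue) > 0) {
    v <- queue[1]; queue <- queue[-1]
    for (k in incident(v)) {
      if (seen[k]) next
      seen[k] <- TRUE
      parent_end[k] <- v
      child_end[k] <- if (segments$from[k] == v) segments$to[k] else segments$from[k]
      queue <- c(queue, child_end[k])
    }
  }
  so <- rep(NA_integer_, n)
  calc <- function(k) {
    if (!is.na(so[k])) return(so[k])
    kids <- which(parent_end == child_end[k])
    if (length(kids) == 0) { so[k] <<- 0L; return(0L) }
    d <- vapply(kids, calc, integer(1))
    m <- max(d)
    so[k] <<- if (sum(d == m) >= 2L) m + 1L else m
    so[k]
  }
  for (k in seq_len(n)) calc(k)
  so
}

# level-`level` Menger sponge cell centres in the unit cube
menger_points <- function(level) {
  keep <- function(i, j, k) !((i == 1) + (j == 1) + (k == 1) >= 2)
  cells <- cbind(0, 0, 0)
  size <- 1
  for (l in seq_len(level)) {
    size <- size / 3
    off <- expand.grid(i = 0:2, j = 0:2, k = 0:2)
    off <- off[keep(off$i, off$j, off$k), ]
    cells <- do.call(rbind, lapply(seq_len(nrow(off)), function(r)
      sweep(cells, 2, c(off$i[r], off$j[r], off$k[r]) * size, `+`)))
  }
  tibble::tibble(x = cells[, 1] + size / 2, y = cells[, 2] + size / 2,
                 z = cells[, 3] + size / 2)
}
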