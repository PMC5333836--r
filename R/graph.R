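new_vascular_graph <- function(nodes, edges, root = NULL, directed = FALSE,
                               log = list()) {
  structure(list(nodes = nodes, edges = edges, root = root,
                 directed = directed, log = log),
            class = "vascular_graph")
}

#' @export
print.vascular_graph <- function(x, ...) {
  deg <- node_degrees(x)
  cat("<vascular_graph> ", nrow(x$nodes), " nodes, ", nrow(x$edges),
      " edges\n", sep = "")
  cat("  degree census:", paste(sprintf("%d:%d", as.integer(names(table(deg))),
                                        as.integer(table(deg))), collapse = " "), "\n")
  if (!is.null(x$root)) cat("  root node:", x$root, "\n")
  invisible(x)
}

# adjacency as a list of integer vectors over node row indices (not ids)
vg_index <- function(g) {
  n <- nrow(g$nodes)
  adj <- vector("list", n)
  if (nrow(g$edges) > 0) {
    fi <- match(g$edges$from, g$nodes$id)
    ti <- match(g$edges$to, g$nodes$id)
    for (e in seq_along(fi)) {
      adj[[fi[e]]] <- c(adj[[fi[e]]], ti[e])
      adj[[ti[e]]] <- c(adj[[ti[e]]], fi[e])
    }
  }
  adj
}

node_degrees <- function(g) lengths(vg_index(g))

#' Convert a vascular graph to an igraph object
#'
#' @param g A `vascular_graph`.
#' @return An [igraph::graph] with node attributes `x`, `y`, `z`, `d` and
#'   edge attribute `length`.
#' @export
as_igraph <- function(g) {
  stopifnot(inherits(g, "vascular_graph"))
  igraph::graph_from_data_frame(
    d = data.frame(from = as.character(g$edges$from),
                   to = as.character(g$edges$to),
                   length = g$edges$length),
    directed = FALSE,
    vertices = data.frame(name = as.character(g$nodes$id),
                          x = g$nodes$x, y = g$nodes$y, z = g$nodes$z,
                          d = g$nodes$d)
  )
}

#' Average distances to the 2nd, 5th and 10th nearest neighbours
#'
#' These three scales calibrate the staged linking protocol to the local
#' point density of the exported skeleton: stage 1 links within the mean
#' 2nd-neighbour distance, stage 2 within the 5th, stage 3 within the 10th.
#'
#' @param cs A [centerline()] tibble (or any data frame with `x`, `y`, `z`),
#'   with at least 11 points.
#' @return A one-row tibble with columns `nn2`, `nn5`, `nn10`.
#' @export
compute_neighbor_scales <- function(cs) {
  if (nrow(cs) < 11)
    stop("need at least 11 points to compute neighbour scales; ",
         "supply nn2/nn5/nn10 manually for smaller sets", call. = FALSE)
  pts <- as.matrix(cs[, c("x", "y", "z")])
  avg <- cpp_knn_avg(pts, c(2L, 5L, 10L))
  out <- tibble::tibble(nn2 = avg[1], nn5 = avg[2], nn10 = avg[3])
  stopifnot(out$nn2 > 0, out$nn2 <= out$nn5, out$nn5 <= out$nn10)
  out
}

# union-find helpers -----------------------------------------------------
uf_new <- function(n) seq_len(n)
uf_find <- function(p, i) {
  while (p[i] != i) i <- p[i]
  i
}
uf_union <- function(p, a, b) {
  ra <- uf_find(p, a); rb <- uf_find(p, b)
  if (ra != rb) p[ra] <- rb
  p
}

#' Linking stage 1: greedy chain formation
#'
#' Visits nodes in ascending id order. From node `i`, an edge is created to
#' its nearest suitable neighbour `j`: `j` must have fewer than 2 existing
#' connections, must not already be connected to `i` (no path between the
#' two, so the stage can never close a loop), and must lie closer than the
#' average second-nearest-neighbour distance `nn2`. Distance ties are broken
#' by the lower node id. The result is a chain-dominated forest.
#'
#' @param cs A [centerline()] tibble; node ids are the row numbers.
#' @param scales Output of [compute_neighbor_scales()] (or a one-row data
#'   frame with manual `nn2`, `nn5`, `nn10`).
#' @return A `vascular_graph`.
#' @export
link_stage1 <- function(cs, scales) {
  pts <- as.matrix(cs[, c("x", "y", "z")])
  n <- nrow(pts)
  nodes <- tibble::tibble(id = seq_len(n), x = cs$x, y = cs$y, z = cs$z, d = cs$d)
  nbrs <- cpp_range_neighbors(pts, scales$nn2)
  adj <- vector("list", n)
  deg <- integer(n)
  p <- uf_new(n)
  from <- integer(0); to <- integer(0); len <- numeric(0)
  for (i in seq_len(n)) {
    cand <- nbrs[[i]]
    ok <- cand$dist < scales$nn2
    idxs <- cand$idx[ok]; dsts <- cand$dist[ok]
    for (t in seq_along(idxs)) {
      j <- idxs[t]
      if (deg[j] < 2L && uf_find(p, i) != uf_find(p, j)) {
        adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
        deg[i] <- deg[i] + 1L; deg[j] <- deg[j] + 1L
        p <- uf_union(p, i, j)
        from <- c(from, i); to <- c(to, j); len <- c(len, dsts[t])
        break
      }
    }
  }
  new_vascular_graph(nodes,
                     tibble::tibble(from = from, to = to, length = len),
                     log = list(stage1_edges = length(from)))
}

#' Linking stage 2: endpoint completion
#'
#' Every node with degree 0 or 1 (visited in ascending id order, degrees
#' re-evaluated after each accepted edge) is connected to its nearest node
#' among those it has no existing path to, provided that node is closer than
#' the average fifth-neighbour distance `nn5`. The no-path requirement means
#' the stage can never close a loop within a component.
#'
#' @param g A `vascular_graph` from [link_stage1()].
#' @param scales Neighbour scales (see [compute_neighbor_scales()]).
#' @return A `vascular_graph`.
#' @export
link_stage2 <- function(g, scales) {
  pts <- as.matrix(g$nodes[, c("x", "y", "z")])
  n <- nrow(pts)
  nbrs <- cpp_range_neighbors(pts, scales$nn5)
  adj <- vg_index(g)
  deg <- lengths(adj)
  p <- uf_new(n)
  fi <- match(g$edges$from, g$nodes$id); ti <- match(g$edges$to, g$nodes$id)
  for (e in seq_along(fi)) p <- uf_union(p, fi[e], ti[e])
  from <- integer(0); to <- integer(0); len <- numeric(0)
  for (u in seq_len(n)) {
    if (deg[u] > 1L) next
    cand <- nbrs[[u]]
    for (t in seq_along(cand$idx)) {
      j <- cand$idx[t]; d <- cand$dist[t]
      if (d >= scales$nn5) break
      if (uf_find(p, u) == uf_find(p, j)) next  # path exists: would loop
      adj[[u]] <- c(adj[[u]], j); adj[[j]] <- c(adj[[j]], u)
      deg[u] <- deg[u] + 1L; deg[j] <- deg[j] + 1L
      p <- uf_union(p, u, j)
      from <- c(from, u); to <- c(to, j); len <- c(len, d)
      break
    }
  }
  g$edges <- dplyr::bind_rows(
    g$edges,
    tibble::tibble(from = g$nodes$id[from], to = g$nodes$id[to], length = len))
  g$log$stage2_edges <- length(from)
  g
}

#' Linking stage 3: bridging sub-networks
#'
#' Nodes of degree 1 (ascending id order) are bridged to the nearest node in
#' a *different* connected sub-network when that node is closer than the
#' average tenth-neighbour distance `nn10`; sub-network labels are updated
#' after every accepted bridge.
#'
#' @inheritParams link_stage2
#' @return A `vascular_graph` with a `subnet` column added to its nodes.
#' @export
link_stage3 <- function(g, scales) {
  pts <- as.matrix(g$nodes[, c("x", "y", "z")])
  n <- nrow(pts)
  adj <- vg_index(g)
  deg <- lengths(adj)
  p <- uf_new(n)
  fi <- match(g$edges$from, g$nodes$id); ti <- match(g$edges$to, g$nodes$id)
  for (e in seq_along(fi)) p <- uf_union(p, fi[e], ti[e])
  from <- integer(0); to <- integer(0); len <- numeric(0)
  for (u in seq_len(n)) {
    if (deg[u] != 1L) next
    ru <- uf_find(p, u)
    roots <- vapply(seq_len(n), function(v) uf_find(p, v), integer(1))
    other <- which(roots != ru)
    if (length(other) == 0) break
    dd <- sqrt(colSums((t(pts[other, , drop = FALSE]) - pts[u, ])^2))
    best <- which.min(dd)
    if (dd[best] >= scales$nn10) next
    j <- other[best]
    adj[[u]] <- c(adj[[u]], j); adj[[j]] <- c(adj[[j]], u)
    deg[u] <- deg[u] + 1L; deg[j] <- deg[j] + 1L
    p <- uf_union(p, u, j)
    from <- c(from, u); to <- c(to, j); len <- c(len, dd[best])
  }
  g$edges <- dplyr::bind_rows(
    g$edges,
    tibble::tibble(from = g$nodes$id[from], to = g$nodes$id[to], length = len))
  g$log$stage3_edges <- length(from)
  roots <- vapply(seq_len(n), function(v) uf_find(p, v), integer(1))
  g$nodes$subnet <- match(roots, unique(roots))
  g
}

#' Prune reconstruction artifacts
#'
#' Removes, in a single pass over the post-linking degrees: (a) all isolated
#' (degree-0) nodes; (b) every short spur -- a degree-1 node, together with
#' at most one intermediate degree-2 node, hanging off a bifurcation
#' (degree >= 3) node; and (c) every connected component other than the
#' largest. Degrees are recomputed once afterwards, not iterated to a
#' fixpoint.
#'
#' @param g A `vascular_graph` after the three linking stages.
#' @return A `vascular_graph`.
#' @export
prune_artifacts <- function(g) {
  adj <- vg_index(g)
  deg <- lengths(adj)
  n <- nrow(g$nodes)
  drop <- deg == 0L
  n_spur <- 0L
  for (u in which(deg == 1L)) {
    path <- u
    prev <- 0L; cur <- u
    repeat {
      nxt <- setdiff(adj[[cur]], prev)
      if (length(nxt) == 0) break            # dead end (tiny chain)
      nxt <- nxt[1]
      if (deg[nxt] >= 3L) {                  # reached a bifurcation
        if (length(path) - 1L <= 1L) {       # <= 1 intermediate node
          drop[path] <- TRUE
          n_spur <- n_spur + 1L
        }
        break
      }
      if (deg[nxt] != 2L || length(path) > 2L) break
      path <- c(path, nxt)
      prev <- cur; cur <- nxt
    }
  }
  keep <- which(!drop)
  if (length(keep) == 0) stop("graph is empty after pruning", call. = FALSE)
  keep_ids <- g$nodes$id[keep]
  edges <- g$edges[g$edges$from %in% keep_ids & g$edges$to %in% keep_ids, ]
  g2 <- new_vascular_graph(g$nodes[keep, ], edges, log = g$log)
  # keep only the largest remaining component
  adj2 <- vg_index(g2)
  p <- uf_new(nrow(g2$nodes))
  fi <- match(g2$edges$from, g2$nodes$id); ti <- match(g2$edges$to, g2$nodes$id)
  for (e in seq_along(fi)) p <- uf_union(p, fi[e], ti[e])
  roots <- vapply(seq_len(nrow(g2$nodes)), function(v) uf_find(p, v), integer(1))
  comp <- match(roots, unique(roots))
  main <- which.max(tabulate(comp))
  sel <- comp == main
  keep_ids2 <- g2$nodes$id[sel]
  edges2 <- g2$edges[g2$edges$from %in% keep_ids2 & g2$edges$to %in% keep_ids2, ]
  out <- new_vascular_graph(g2$nodes[sel, ], edges2, log = g$log)
  out$log$pruned_isolated <- sum(deg == 0L)
  out$log$pruned_spurs <- n_spur
  out$log$pruned_minor_components <- n - sum(deg == 0L) - sum(drop & deg != 0L) - sum(sel)
  out$nodes$subnet <- NULL
  if (nrow(out$edges) == 0 && nrow(out$nodes) > 1)
    stop("graph is empty after pruning", call. = FALSE)
  out
}

#' Reconstruct a vascular graph from a centerline set
#'
#' Runs the three nearest-neighbour linking stages followed by artifact
#' pruning.
#'
#' @param cs A [centerline()] tibble.
#' @param scales Optional manual neighbour scales; computed from `cs` when
#'   `NULL`.
#' @return A pruned, connected `vascular_graph`.
#' @export
reconstruct_graph <- function(cs, scales = NULL) {
  scales <- scales %||% compute_neighbor_scales(cs)
  g <- link_stage1(cs, scales)
  g <- link_stage2(g, scales)
  g <- link_stage3(g, scales)
  prune_artifacts(g)
}

#' Select the root (injection inlet) node
#'
#' By default the degree-1 node carrying the largest local diameter; ties go
#' to the lower node id.
#'
#' @param g A pruned `vascular_graph`.
#' @param root Optional explicit node id, overriding the default choice.
#' @return A node id.
#' @export
choose_root <- function(g, root = NULL) {
  if (!is.null(root)) {
    if (!root %in% g$nodes$id) stop("root node ", root, " not in graph", call. = FALSE)
    return(root)
  }
  deg <- node_degrees(g)
  tips <- which(deg == 1L)
  if (length(tips) == 0) stop("graph has no degree-1 node to use as root", call. = FALSE)
  tips <- tips[order(-g$nodes$d[tips], g$nodes$id[tips])]
  g$nodes$id[tips[1]]
}

#' Extract vessel segments from a pruned graph
#'
#' Partitions the edges into maximal paths whose interior nodes have degree
#' 2 and whose endpoints are either bifurcations (degree >= 3) or terminals
#' (degree 1). Each segment carries its length `l_k` (sum of Euclidean
#' inter-node distances) and average diameter `D_k` (mean of the embedded
#' node diameters).
#'
#' @param g A pruned `vascular_graph`.
#' @return A tibble with one row per segment: `segment`, `from`, `to`
#'   (endpoint node ids), `length` and `diameter` (micrometres), `n_nodes`,
#'   and a `path` list-column of node ids.
#' @export
extract_segments <- function(g) {
  n <- nrow(g$nodes)
  fi <- match(g$edges$from, g$nodes$id); ti <- match(g$edges$to, g$nodes$id)
  adj <- vector("list", n)     # entries are (neighbour index, edge index)
  for (e in seq_along(fi)) {
    adj[[fi[e]]] <- rbind(adj[[fi[e]]], c(ti[e], e))
    adj[[ti[e]]] <- rbind(adj[[ti[e]]], c(fi[e], e))
  }
  deg <- vapply(adj, function(a) if (is.null(a)) 0L else nrow(a), integer(1))
  used <- logical(nrow(g$edges))
  pts <- as.matrix(g$nodes[, c("x", "y", "z")])
  segs <- list()
  junctions <- which(deg != 2L)
  if (length(junctions) == 0 && nrow(g$edges) > 0) {
    warning("graph contains only degree-2 nodes (a closed loop); ",
            "no segments extracted", call. = FALSE)
    junctions <- integer(0)
  }
  for (j in junctions) {
    a <- adj[[j]]
    if (is.null(a)) next
    for (r in seq_len(nrow(a))) {
      if (used[a[r, 2]]) next
      path <- j
      cur <- a[r, 1]; used[a[r, 2]] <- TRUE
      path <- c(path, cur)
      while (deg[cur] == 2L) {
        nxt <- adj[[cur]][!used[adj[[cur]][, 2]], , drop = FALSE]
        if (nrow(nxt) == 0) break
        used[nxt[1, 2]] <- TRUE
        cur <- nxt[1, 1]
        path <- c(path, cur)
      }
      steps <- sqrt(rowSums((pts[path[-1], , drop = FALSE] -
                             pts[path[-length(path)], , drop = FALSE])^2))
      segs[[length(segs) + 1]] <- tibble::tibble(
        from = g$nodes$id[path[1]],
        to = g$nodes$id[path[length(path)]],
        length = sum(steps),
        diameter = mean(g$nodes$d[path]),
        n_nodes = length(path),
        path = list(g$nodes$id[path])
      )
    }
  }
  out <- dplyr::bind_rows(segs)
  if (nrow(out) == 0)
    return(tibble::tibble(segment = integer(), from = integer(), to = integer(),
                          length = numeric(), diameter = numeric(),
                          n_nodes = integer(), path = list()))
  dplyr::bind_cols(tibble::tibble(segment = seq_len(nrow(out))), out)
}

#' Export a vascular graph and its segments
#'
#' Writes an edge-list CSV (node ids, coordinates, diameters), a GraphML
#' file, and a segments CSV.
#'
#' @param g A `vascular_graph`.
#' @param segments Optional segment tibble from [extract_segments()] (or the
#'   ordered version); the `path` list-column is dropped in the CSV.
#' @param dir Output directory, created if missing.
#' @return The directory, invisibly.
#' @export
write_graph_exports <- function(g, segments = NULL, dir = ".") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  nd <- g$nodes
  ed <- dplyr::left_join(g$edges, nd, by = c(from = "id")) |>
    dplyr::rename(x_from = "x", y_from = "y", z_from = "z", d_from = "d") |>
    dplyr::left_join(nd, by = c(to = "id")) |>
    dplyr::rename(x_to = "x", y_to = "y", z_to = "z", d_to = "d")
  utils::write.csv(nd, file.path(dir, "nodes.csv"), row.names = FALSE)
  utils::write.csv(ed, file.path(dir, "edges.csv"), row.names = FALSE)
  igraph::write_graph(as_igraph(g), file.path(dir, "graph.graphml"),
                      format = "graphml")
  if (!is.null(segments)) {
    seg <- segments[!vapply(segments, is.list, logical(1))]
    utils::write.csv(seg, file.path(dir, "segments.csv"), row.names = FALSE)
  }
  invisible(dir)
}
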