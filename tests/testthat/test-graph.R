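test_that("neighbour scales match a brute-force oracle", {
  set.seed(21)
  pts <- matrix(runif(3 * 200, 0, 50), ncol = 3)
  cs <- centerline(tibble::tibble(x = pts[, 1], y = pts[, 2], z = pts[, 3],
                                  d = 10))
  sc <- compute_neighbor_scales(cs)
  oracle <- knn_avg_oracle(pts, c(2, 5, 10))
  expect_equal(c(sc$nn2, sc$nn5, sc$nn10), oracle, tolerance = 1e-12)
  expect_true(sc$nn2 <= sc$nn5 && sc$nn5 <= sc$nn10)

  # 1D lattice of step h: nn2 equals the boundary-corrected brute force
  lat <- centerline(tibble::tibble(x = seq(0, 95, by = 5), y = 0, z = 0, d = 1))
  sc1 <- compute_neighbor_scales(lat)
  expect_equal(sc1$nn2, knn_avg_oracle(as.matrix(lat[, 1:3]), 2), tolerance = 1e-12)

  expect_error(compute_neighbor_scales(lat[1:10, ]), "at least 11")
})

test_that("stage 1 builds chains under the greedy cap", {
  sc <- tibble::tibble(nn2 = 2, nn5 = 5, nn10 = 10)
  three <- centerline(tibble::tibble(x = c(0, 1, 2), y = 0, z = 0, d = 1))
  g <- link_stage1(three, sc)
  expect_identical(nrow(g$edges), 2L)
  expect_identical(sort(vasctree:::node_degrees(g)), c(1L, 1L, 2L))

  two_far <- centerline(tibble::tibble(x = c(0, 5), y = 0, z = 0, d = 1))
  expect_identical(nrow(link_stage1(two_far, sc)$edges), 0L)

  # dense jittered line: most nodes reach degree 2
  set.seed(5)
  line <- centerline(tibble::tibble(x = seq(0, 100, length.out = 200),
                                    y = rnorm(200, 0, 0.02),
                                    z = rnorm(200, 0, 0.02), d = 1))
  scl <- compute_neighbor_scales(line)
  g2 <- link_stage1(line, scl)
  expect_gte(mean(vasctree:::node_degrees(g2) == 2), 0.9)
})

test_that("stage 2 joins fragments but never closes a loop", {
  sc <- tibble::tibble(nn2 = 1.5, nn5 = 4, nn10 = 10)
  # two chain fragments with an end gap < nn5
  pts <- centerline(tibble::tibble(
    x = c(0, 1, 2, 5, 6, 7), y = 0, z = 0, d = 1))
  g <- link_stage1(pts, sc)
  expect_identical(nrow(g$edges), 4L)
  g <- link_stage2(g, sc)
  expect_identical(nrow(g$edges), 5L)   # single chain now
  ig <- as_igraph(g)
  expect_equal(igraph::count_components(ig), 1)
  expect_equal(igraph::ecount(ig), igraph::vcount(ig) - 1)  # no cycle

  # folded chain: the two ends of the same chain are close but stay unjoined
  theta <- seq(0, 1.9 * pi, length.out = 24)
  fold <- centerline(tibble::tibble(x = cos(theta), y = sin(theta), z = 0, d = 1))
  scf <- tibble::tibble(nn2 = 0.3, nn5 = 2, nn10 = 4)
  gf <- link_stage2(link_stage1(fold, scf), scf)
  igf <- as_igraph(gf)
  expect_identical(igraph::ecount(igf), igraph::vcount(igf) - 1)

  # isolated node near a chain gets attached
  iso <- centerline(tibble::tibble(x = c(0, 1, 2, 3.2), y = 0, z = 0, d = 1))
  gi <- link_stage2(link_stage1(iso, sc), sc)
  expect_identical(min(vasctree:::node_degrees(gi)), 1L)
})

test_that("stage 2 never creates cycles across random fragment sets", {
  for (seed in 1:100) {
    pts <- random_centerline_points(60, seed)
    cs <- centerline(tibble::tibble(x = pts[, 1], y = pts[, 2], z = pts[, 3], d = 1))
    sc <- compute_neighbor_scales(cs)
    g <- link_stage2(link_stage1(cs, sc), sc)
    ig <- as_igraph(g)
    expect_identical(igraph::ecount(ig) + igraph::count_components(ig),
                     igraph::vcount(ig))
  }
})

test_that("stage 3 bridges sub-networks within nn10 only", {
  sc <- tibble::tibble(nn2 = 1.5, nn5 = 2, nn10 = 8)
  # two chains 4 apart (= 0.5 * nn10): bridged
  pts <- centerline(tibble::tibble(x = c(0, 1, 2, 6, 7, 8), y = 0, z = 0, d = 1))
  g <- link_stage3(link_stage2(link_stage1(pts, sc), sc), sc)
  expect_identical(max(g$nodes$subnet), 1L)

  # two chains 2*nn10 apart: separate
  far <- centerline(tibble::tibble(x = c(0, 1, 2, 18, 19, 20), y = 0, z = 0, d = 1))
  gf <- link_stage3(link_stage2(link_stage1(far, sc), sc), sc)
  expect_identical(max(gf$nodes$subnet), 2L)

  # three fragments chained within nn10: one component, exactly 2 bridges
  tri <- centerline(tibble::tibble(x = c(0, 1, 2, 6, 7, 8, 12, 13, 14),
                                   y = 0, z = 0, d = 1))
  g1 <- link_stage2(link_stage1(tri, sc), sc)
  g3 <- link_stage3(g1, sc)
  expect_identical(max(g3$nodes$subnet), 1L)
  expect_identical(nrow(g3$edges) - nrow(g1$edges), 2L)
})

test_that("pruning removes spurs, isolated nodes and minor components", {
  # Y-tree with three long arms, a 2-node spur off the junction and a
  # disconnected 2-node fragment
  nodes <- tibble::tibble(
    id = 1:17,
    x = c(0, 1, 2, 3, 4,            # arm A: 1..5, junction at 5
          6, 7, 8, 9,               # arm B: 6..9
          rep(5, 4),                # arm C: 10..13
          5.5, 6.5,                 # spur: 14 (intermediate), 15 (tip)
          30, 31),                  # fragment: 16-17
    y = c(rep(0, 5), 1:4, -(1:4), 1.2, 2.2, 0, 0),
    z = 0,
    d = c(rep(40, 5), rep(20, 8), 5, 5, 9, 9))
  edges <- tibble::tibble(
    from = c(1, 2, 3, 4, 5, 6, 7, 8, 5, 10, 11, 12, 5, 14, 16),
    to   = c(2, 3, 4, 5, 6, 7, 8, 9, 10, 11, 12, 13, 14, 15, 17))
  edges$length <- sqrt((nodes$x[edges$from] - nodes$x[edges$to])^2 +
                       (nodes$y[edges$from] - nodes$y[edges$to])^2)
  g <- vasctree:::new_vascular_graph(nodes, edges)
  pruned <- prune_artifacts(g)
  expect_false(any(c(14, 15) %in% pruned$nodes$id))  # spur (tip + 1) gone
  expect_false(any(c(16, 17) %in% pruned$nodes$id))  # minor component gone
  expect_setequal(pruned$nodes$id, 1:13)             # long arms untouched

  # long-armed Y stays unchanged
  set.seed(2)
  arm <- function(x0, y0, dx, dy, n) tibble::tibble(
    x = x0 + dx * seq_len(n), y = y0 + dy * seq_len(n), z = 0, d = 10)
  cs <- centerline(dplyr::bind_rows(
    tibble::tibble(x = 0, y = 0, z = 0, d = 10),
    arm(0, 0, 1, 0, 10), arm(10, 0, 0.7, 0.7, 10), arm(10, 0, 0.7, -0.7, 10)))
  sc <- compute_neighbor_scales(cs)
  g2 <- link_stage3(link_stage2(link_stage1(cs, sc), sc), sc)
  p2 <- prune_artifacts(g2)
  expect_identical(nrow(p2$nodes), nrow(cs))
})

test_that("segments partition the graph and conserve edge length", {
  # Y-tree: one degree-3 node, three tips -> 3 segments
  cs <- centerline(tibble::tibble(
    x = c(0, 1, 2, 3, 3, 4, 4), y = c(0, 0, 0, 1, -1, 2, -2), z = 0, d = 10))
  sc <- tibble::tibble(nn2 = 1.6, nn5 = 2, nn10 = 4)
  g <- link_stage3(link_stage2(link_stage1(cs, sc), sc), sc)
  seg <- extract_segments(g)
  expect_identical(nrow(seg), 3L)

  # straight 5-node chain with unit steps: one segment of length 4
  chain <- centerline(tibble::tibble(x = 0:4, y = 0, z = 0, d = 10))
  gc <- link_stage2(link_stage1(chain, sc), sc)
  sc2 <- extract_segments(gc)
  expect_identical(nrow(sc2), 1L)
  expect_equal(sc2$length, 4)

  # conservation: segment lengths sum exactly to edge lengths
  tr <- generate_tree(tree_spec(depth = 3, seed = 4))
  cst <- tree_to_centerline(tr, step = 20)
  gt <- reconstruct_graph(cst)
  st <- extract_segments(gt)
  expect_equal(sum(st$length), sum(gt$edges$length), tolerance = 1e-12)
})

test_that("three-stage linking matches the literal rule-replay oracle", {
  for (seed in c(1, 7, 23, 40)) {
    n <- sample(c(80, 150, 250), 1)
    pts <- random_centerline_points(n, seed)
    cs <- centerline(tibble::tibble(x = pts[, 1], y = pts[, 2], z = pts[, 3], d = 1))
    sc <- compute_neighbor_scales(cs)
    g <- link_stage3(link_stage2(link_stage1(cs, sc), sc), sc)
    expect_identical(canonical_edges(g), naive_reconstruct_edges(pts, sc),
                     info = paste("seed", seed))
  }
})

test_that("reconstruction of a jittered generator centerline is an exact tree", {
  tr <- generate_tree(tree_spec(jitter_sd = 4, seed = 9))  # 0.25 * spacing
  cs <- tree_to_centerline(tr, step = 16)
  g <- reconstruct_graph(cs)
  expect_identical(nrow(g$edges), nrow(g$nodes) - 1L)
  seg <- extract_segments(g)
  expect_identical(nrow(seg), tr$ground_truth$n_segments)
})

test_that("reconstruction is deterministic for a fixed input order", {
  pts <- random_centerline_points(120, 3)
  cs <- centerline(tibble::tibble(x = pts[, 1], y = pts[, 2], z = pts[, 3], d = 1))
  sc <- compute_neighbor_scales(cs)
  e1 <- canonical_edges(link_stage3(link_stage2(link_stage1(cs, sc), sc), sc))
  e2 <- canonical_edges(link_stage3(link_stage2(link_stage1(cs, sc), sc), sc))
  expect_identical(e1, e2)
})

test_that("root selection prefers the widest terminal", {
  cs <- centerline(tibble::tibble(x = 0:5, y = 0, z = 0,
                                  d = c(50, 40, 30, 20, 10, 5)))
  sc <- tibble::tibble(nn2 = 1.5, nn5 = 2, nn10 = 4)
  g <- link_stage2(link_stage1(cs, sc), sc)
  expect_identical(choose_root(g), 1L)
  expect_identical(choose_root(g, root = 6), 6)
  expect_error(choose_root(g, root = 99), "not in graph")
})
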