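test_that("box-counting recovers analytic dimensions", {
  set.seed(31)
  # line segment: D_f = 1
  line <- tibble::tibble(x = runif(10000, 0, 1000), y = 0, z = 0)
  fl <- fractal_dimension(line, box_sizes = 1000 / 2^(2:7))
  expect_equal(fl$d_f, 1, tolerance = 0.05)

  # solid cube lattice: D_f = 3
  gcoord <- seq(0, 115, by = 5)
  cube <- expand.grid(x = gcoord, y = gcoord, z = gcoord)
  fc <- fractal_dimension(cube, box_sizes = c(5, 10, 20, 40))
  expect_equal(fc$d_f, 3, tolerance = 0.1)

  # level-4 Menger sponge: D_f = log 20 / log 3
  mg <- menger_points(4)
  fm <- fractal_dimension(mg, box_sizes = 3^-(1:4))
  expect_equal(fm$d_f, log(20) / log(3), tolerance = 0.1)
  expect_gt(fm$r_squared, 0.999)

  expect_error(fractal_dimension(tibble::tibble(x = c(1, 1), y = 1, z = 1),
                                 box_sizes = c(1, 2, 4, 8)), "distinct")
})

test_that("box counts are monotone non-increasing in box size", {
  set.seed(32)
  for (rep in 1:5) {
    pts <- tibble::tibble(x = rnorm(400, 0, 30), y = rnorm(400, 0, 30),
                          z = rnorm(400, 0, 30))
    f <- fractal_dimension(pts, box_sizes = 2^(0:6))
    expect_true(all(diff(f$counts) <= 0))
  }
})

test_that("totals follow the cylinder-sum formulas and are additive", {
  expect_identical(total_length(tibble::tibble(length = numeric())), 0)
  expect_equal(total_length(tibble::tibble(length = c(3, 4))), 7)
  one <- tibble::tibble(length = 1, diameter = 2)
  expect_equal(total_volume(one), pi)
  expect_equal(total_volume(dplyr::bind_rows(one, one)), 2 * pi)

  # concatenating two trees adds lengths and volumes exactly
  a <- generate_tree(tree_spec(depth = 2, seed = 1))$ground_truth
  b <- generate_tree(tree_spec(depth = 3, seed = 2))$ground_truth
  seg_a <- tibble::tibble(length = a$segment_table$length,
                          diameter = a$segment_table$diameter)
  seg_b <- tibble::tibble(length = b$segment_table$length,
                          diameter = b$segment_table$diameter)
  both <- dplyr::bind_rows(seg_a, seg_b)
  expect_equal(total_length(both), total_length(seg_a) + total_length(seg_b))
  expect_equal(total_volume(both), total_volume(seg_a) + total_volume(seg_b))

  # generator tree: reconstructed totals match the analytic ground truth
  tr <- generate_tree(tree_spec())
  cs <- tree_to_centerline(tr, step = 16)
  g <- reconstruct_graph(cs)
  seg <- extract_segments(g)
  expect_lt(abs(total_length(seg) - tr$ground_truth$l_total) /
              tr$ground_truth$l_total, 0.05)
})

test_that("histograms use half-open bins and weigh samples equally", {
  seg <- tibble::tibble(diameter = c(10, 19, 20), length = c(1, 2, 3))
  d <- segment_distributions(seg, dD = 10, dl = 50)
  dd <- d[d$metric == "diameter", ]
  expect_equal(dd$bin_low, c(10, 20))
  expect_equal(dd$n_mean, c(2, 1))
  # one sample: P sums to 1
  expect_equal(sum(dd$p_mean), 1)

  # two samples, 10 and 30 segments: P weighs samples equally, not segments
  s1 <- tibble::tibble(diameter = rep(5, 10), length = 1, sample = "a")
  s2 <- tibble::tibble(diameter = rep(15, 30), length = 1, sample = "b")
  d2 <- segment_distributions(dplyr::bind_rows(s1, s2), dD = 10, dl = 50)
  d2d <- d2[d2$metric == "diameter", ]
  # each sample concentrates in one bin with P = 1 -> group average 0.5 each
  expect_equal(d2d$p_mean, c(0.5, 0.5))
  expect_equal(d2d$n_mean, c(5, 15))
})

test_that("per-order resistance follows the fourth-power law", {
  st <- tibble::tibble(order = 0L, n_count = 1L, diameter_mean = 1,
                       diameter_sd = 0, length_mean = 1)
  expect_equal(resistance_per_order(st)$resistance, 1)
  st2 <- dplyr::mutate(st, diameter_mean = 2)
  expect_equal(resistance_per_order(st2)$resistance, 1 / 16)
  expect_error(resistance_per_order(dplyr::mutate(st, diameter_mean = 0)),
               "positive")

  # Murray-tapered generator: counts double, diameters shrink by 2^(1/3)
  tr <- generate_tree(tree_spec())
  gt <- tr$ground_truth$segment_table
  st3 <- tibble::tibble(
    order = sort(unique(gt$so_true)),
    n_count = as.integer(table(gt$so_true)),
    diameter_mean = as.numeric(tapply(gt$diameter, gt$so_true, mean)),
    diameter_sd = 0,
    length_mean = as.numeric(tapply(gt$length, gt$so_true, mean)))
  got <- resistance_per_order(st3)$resistance
  hand <- vapply(st3$order, function(o) {
    rows <- gt[gt$so_true == o, ]
    mean(rows$length) / (nrow(rows) * mean(rows$diameter)^4)
  }, numeric(1))
  expect_equal(got, unname(hand), tolerance = 1e-12)
})

test_that("bifurcation angles are exact on constructed geometries", {
  # daughters along +x and +y from a junction at the origin
  nodes <- tibble::tibble(id = 1:4,
                          x = c(0, 0, 3, 0), y = c(-3, 0, 0, 3), z = 0,
                          d = c(30, 30, 10, 10))
  edges <- tibble::tibble(from = c(1, 2, 2), to = c(2, 3, 4), length = 3)
  g <- vasctree:::new_vascular_graph(nodes, edges)
  seg <- extract_segments(g)
  so <- assign_strahler(seg, g, root = 1L)
  a <- bifurcation_angles(so, g)
  expect_equal(a$angle_deg, 90)

  # antiparallel daughters
  nodes2 <- dplyr::mutate(nodes, x = c(0, 0, 3, -3), y = c(-3, 0, 0, 0))
  g2 <- vasctree:::new_vascular_graph(nodes2, edges)
  so2 <- assign_strahler(extract_segments(g2), g2, root = 1L)
  expect_equal(bifurcation_angles(so2, g2)$angle_deg, 180)

  # generator tree with jitter: mean angle near the constructed 90 degrees
  tr <- generate_tree(tree_spec(jitter_sd = 2, seed = 6))
  cs <- tree_to_centerline(tr, step = 16)
  g3 <- reconstruct_graph(cs)
  so3 <- assign_strahler(extract_segments(g3), g3, choose_root(g3))
  a3 <- bifurcation_angles(so3, g3, lookahead = "endpoint")
  expect_equal(mean(a3$angle_deg), 90, tolerance = 2)
})

test_that("all metrics are invariant under rigid motion", {
  tr <- generate_tree(tree_spec(depth = 3, seed = 14))
  cs <- tree_to_centerline(tr, step = 20)
  run <- function(cs) {
    g <- reconstruct_graph(cs)
    seg <- assign_strahler(extract_segments(g), g, choose_root(g))
    dd <- assign_ddso(seg)
    ang <- bifurcation_angles(dd, g, lookahead = "endpoint")
    dmin <- terminal_distances(g)
    list(l = total_length(dd), v = total_volume(dd),
         ang = sort(ang$angle_deg), dmin = sort(dmin$d_min))
  }
  base <- run(cs)
  # a random rotation + translation
  set.seed(15)
  th <- runif(3, 0, 2 * pi)
  Rx <- rbind(c(1, 0, 0), c(0, cos(th[1]), -sin(th[1])), c(0, sin(th[1]), cos(th[1])))
  Rz <- rbind(c(cos(th[2]), -sin(th[2]), 0), c(sin(th[2]), cos(th[2]), 0), c(0, 0, 1))
  R <- Rz %*% Rx
  xyz <- as.matrix(cs[, c("x", "y", "z")]) %*% t(R)
  cs2 <- centerline(tibble::tibble(x = xyz[, 1] + 100, y = xyz[, 2] - 50,
                                   z = xyz[, 3] + 7, d = cs$d))
  rot <- run(cs2)
  expect_equal(rot$l, base$l, tolerance = 1e-9)
  expect_equal(rot$v, base$v, tolerance = 1e-9)
  expect_equal(rot$ang, base$ang, tolerance = 1e-6)
  expect_equal(rot$dmin, base$dmin, tolerance = 1e-9)
})

test_that("terminal distances report density and homogeneity", {
  # two terminals 100 um apart hanging off one root
  nodes <- tibble::tibble(id = 1:3, x = c(50, 0, 100), y = c(80, 0, 0), z = 0,
                          d = c(30, 10, 10))
  edges <- tibble::tibble(from = c(1, 1), to = c(2, 3), length = 1)
  g <- vasctree:::new_vascular_graph(nodes, edges)
  td <- terminal_distances(g, root = 1L)
  expect_identical(nrow(td), 2L)
  expect_equal(attr(td, "mean"), 100)
  # fewer than 2 terminals errors
  g1 <- vasctree:::new_vascular_graph(nodes[1:2, ], edges[1, ])
  expect_error(terminal_distances(g1, root = 1L), "at least 2 terminals")

  # terminals on a regular grid of pitch p: all d_min equal p
  p <- 40
  grid <- expand.grid(x = p * (0:3), y = p * (0:3))
  n <- nrow(grid)
  nodes2 <- tibble::tibble(id = seq_len(n + 1),
                           x = c(grid$x, 60), y = c(grid$y, 60),
                           z = c(rep(0, n), 500), d = c(rep(10, n), 80))
  edges2 <- tibble::tibble(from = rep(n + 1, n), to = seq_len(n), length = 1)
  g2 <- vasctree:::new_vascular_graph(nodes2, edges2)
  td2 <- terminal_distances(g2, root = n + 1L)
  expect_true(all(abs(td2$d_min - p) < 1e-9))
  expect_equal(attr(td2, "mean"), p)

  # clustered tips have larger d_min variance than uniform tips
  uni <- td2
  clust <- tibble::tibble(id = 1:9,
                          x = c(0, 1, 2, 100, 101, 102, 200, 201, 300) * 1.0,
                          y = 0, z = 0, d = 10)
  nodes3 <- dplyr::bind_rows(clust, tibble::tibble(id = 10L, x = 150, y = 200,
                                                   z = 0, d = 50))
  edges3 <- tibble::tibble(from = rep(10L, 9), to = 1:9, length = 1)
  g3 <- vasctree:::new_vascular_graph(nodes3, edges3)
  td3 <- terminal_distances(g3, root = 10L)
  expect_gt(attr(td3, "variance"), attr(uni, "variance"))
})

test_that("vascular_metrics bundles a full coherent report", {
  tr <- generate_tree(tree_spec(depth = 3, seed = 10))
  cs <- tree_to_centerline(tr, step = 16)
  g <- reconstruct_graph(cs)
  dd <- assign_ddso(assign_strahler(extract_segments(g), g, choose_root(g)))
  m <- vascular_metrics(cs, g, dd)
  expect_s3_class(glance(m), "tbl_df")
  expect_identical(glance(m)$n_segments, nrow(dd))
  expect_identical(tidy(m), m$per_order)
  expect_true(all(c("resistance", "diameter_mean") %in% names(m$per_order)))
  expect_gte(min(m$angles$angle_deg), 0)
  expect_lte(max(m$angles$angle_deg), 180)
  expect_gt(m$global$l_total, 0)
})
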