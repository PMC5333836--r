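#' Box-counting fractal dimension of a point cloud
#'
#' Covers the points with cubic boxes of edge `x` anchored at the bounding
#' box minimum and counts the occupied boxes `N(x)`. Under the scaling law
#' `N(x) ~ x^-Df`, the fractal dimension is the negative slope of the least
#' squares line through `(ln x, ln N(x))`.
#'
#' @param points A data frame with columns `x`, `y`, `z` (a [centerline()]
#'   works directly); at least 2 distinct points.
#' @param box_sizes Ladder of box edges (same units as the points). Default:
#'   geometric sequence of factor 2 from `2 * spacing` up to one quarter of
#'   the largest bounding-box edge.
#' @param spacing Point spacing used to anchor the default ladder; taken
#'   from the `centerline` attribute when present.
#' @param fit_range Indices of the ladder used in the fit (default: all).
#' @return An object of class `fractal_fit` with elements `box_sizes`,
#'   `counts`, `d_f`, `r_squared`, `fit_range` and the underlying `lm` fit.
#' @export
fractal_dimension <- function(points, box_sizes = NULL, spacing = NULL,
                              fit_range = NULL) {
  pts <- as.matrix(points[, c("x", "y", "z")])
  if (nrow(unique(pts)) < 2)
    stop("need at least 2 distinct points", call. = FALSE)
  mins <- apply(pts, 2, min)
  ext <- max(apply(pts, 2, max) - mins)
  if (is.null(box_sizes)) {
    spacing <- spacing %||% attr(points, "spacing") %||% stop(
      "supply `box_sizes` or `spacing` to build the default ladder", call. = FALSE)
    lo <- 2 * max(spacing)
    if (lo >= ext / 4) stop("bounding box too small for the default ladder; ",
                            "supply `box_sizes`", call. = FALSE)
    box_sizes <- lo * 2^(0:floor(log2((ext / 4) / lo)))
  }
  box_sizes <- sort(unique(as.numeric(box_sizes)))
  if (length(box_sizes) < 4) stop("need a ladder of at least 4 box sizes", call. = FALSE)
  counts <- vapply(box_sizes, function(x) {
    key <- floor(sweep(pts, 2, mins, `-`) / x + 1e-12)
    nrow(unique(key))
  }, numeric(1))
  fit_range <- fit_range %||% seq_along(box_sizes)
  fit <- stats::lm(log(counts[fit_range]) ~ log(box_sizes[fit_range]))
  d_f <- -unname(coef(fit)[2])
  y <- log(counts[fit_range])
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot > 0) 1 - sum(stats::residuals(fit)^2) / ss_tot else 1
  structure(list(box_sizes = box_sizes, counts = counts, d_f = d_f,
                 r_squared = r2, fit_range = fit_range, fit = fit),
            class = "fractal_fit")
}

#' @export
print.fractal_fit <- function(x, ...) {
  cat("<fractal_fit> D_f =", signif(x$d_f, 4),
      " (r^2 =", signif(x$r_squared, 4), ",",
      length(x$fit_range), "of", length(x$box_sizes), "ladder points)\n")
  invisible(x)
}

#' @export
tidy.fractal_fit <- function(x, ...) {
  tibble::tibble(box_size = x$box_sizes, count = x$counts,
                 in_fit = seq_along(x$box_sizes) %in% x$fit_range)
}

#' @export
glance.fractal_fit <- function(x, ...) {
  tibble::tibble(d_f = x$d_f, r_squared = x$r_squared,
                 n_sizes = length(x$box_sizes))
}

#' Total vessel length
#'
#' Sum of the segment lengths `l_k` over all segments.
#'
#' @param segments Segment tibble (needs a `length` column).
#' @return Total length in micrometres.
#' @export
total_length <- function(segments) sum(segments$length)

#' Total vessel volume
#'
#' Cylinder-sum approximation `V = sum_k pi * l_k * (D_k / 2)^2` over all
#' segments.
#'
#' @param segments Segment tibble (needs `length` and `diameter`).
#' @return Total volume in cubic micrometres.
#' @export
total_volume <- function(segments) {
  sum(pi * segments$length * (segments$diameter / 2)^2)
}

#' Absolute and relative distributions of segment diameters and lengths
#'
#' Histograms on half-open bins `[v, v + bin)`. The absolute histogram
#' `N(.)` counts segments; the relative histogram `P(.)` is each sample's
#' `N(.)` divided by its own segment count, so that samples weigh equally
#' when averaged within a phenotype group.
#'
#' @param segments Segment tibble; optional `sample` and `group` columns
#'   identify samples and phenotype groups (a single unnamed sample/group is
#'   assumed otherwise).
#' @param dD Diameter bin width in micrometres (default 10).
#' @param dl Length bin width in micrometres (default 50).
#' @return A tibble with columns `group`, `metric` (`"diameter"` or
#'   `"length"`), `bin_low`, `bin_high`, `n_mean` (group-averaged absolute
#'   count), `p_mean` (group-averaged relative frequency), `n_samples`.
#' @export
segment_distributions <- function(segments, dD = 10, dl = 50) {
  if (dD <= 0 || dl <= 0) stop("bin widths must be > 0", call. = FALSE)
  seg <- tibble::as_tibble(segments)
  if (!"sample" %in% names(seg)) seg$sample <- "sample1"
  if (!"group" %in% names(seg)) seg$group <- "all"
  one_metric <- function(values, bin) floor(values / bin) * bin
  long <- dplyr::bind_rows(
    dplyr::mutate(seg, metric = "diameter", bin_low = one_metric(.data$diameter, dD),
                  bin_width = dD),
    dplyr::mutate(seg, metric = "length", bin_low = one_metric(.data$length, dl),
                  bin_width = dl)
  )
  per_sample <- long |>
    dplyr::group_by(.data$group, .data$sample, .data$metric) |>
    dplyr::mutate(n_seg = dplyr::n()) |>
    dplyr::group_by(.data$group, .data$sample, .data$metric, .data$bin_low,
                    .data$bin_width, .data$n_seg) |>
    dplyr::summarise(n = dplyr::n(), .groups = "drop") |>
    dplyr::mutate(p = .data$n / .data$n_seg)
  # union of bins within a group; a sample missing a bin contributes 0
  per_sample |>
    dplyr::group_by(.data$group, .data$metric, .data$bin_low, .data$bin_width) |>
    dplyr::summarise(n_present = dplyr::n(), n_sum = sum(.data$n),
                     p_sum = sum(.data$p), .groups = "drop") |>
    dplyr::left_join(
      per_sample |> dplyr::distinct(.data$group, .data$metric, .data$sample) |>
        dplyr::count(.data$group, .data$metric, name = "n_samples"),
      by = c("group", "metric")) |>
    dplyr::transmute(.data$group, .data$metric, .data$bin_low,
                     bin_high = .data$bin_low + .data$bin_width,
                     n_mean = .data$n_sum / .data$n_samples,
                     p_mean = .data$p_sum / .data$n_samples,
                     .data$n_samples) |>
    dplyr::arrange(.data$group, .data$metric, .data$bin_low)
}

#' Hagen-Poiseuille-type resistance per order
#'
#' `R = <l> / (n * <D>^4)` per diameter-defined order, in arbitrary units:
#' laminar-flow resistance of one segment scales as length over the fourth
#' power of diameter, and the `n` parallel segments of an order divide it.
#' The blood-viscosity and `128/pi` constants are deliberately dropped; the
#' estimate is proportional, not absolute.
#'
#' @param stats Per-order statistics from [order_statistics()].
#' @return The statistics tibble with a `resistance` column appended.
#' @export
resistance_per_order <- function(stats) {
  if (any(stats$diameter_mean <= 0))
    stop("mean diameter must be positive in every order", call. = FALSE)
  dplyr::mutate(stats,
                resistance = .data$length_mean /
                  (.data$n_count * .data$diameter_mean^4))
}

#' Bifurcation angles at branch nodes
#'
#' At every branch node, for each pair of daughter segments, the angle
#' between the two daughter direction vectors is
#' `theta = acos(r_i . r_j / (|r_i| |r_j|))`. Each direction vector points
#' from the branch node toward the `lookahead`-th node along the daughter's
#' path (default 1, the immediate neighbour); `lookahead = "endpoint"` uses
#' the daughter's far endpoint. By construction the angles are invariant to
#' global translation and rotation.
#'
#' @param ordered_segments Output of [assign_strahler()] or [assign_ddso()]
#'   (daughter relations and path orientation are required).
#' @param g The `vascular_graph` the segments came from.
#' @param lookahead Positive integer number of path nodes to look ahead, or
#'   `"endpoint"`.
#' @return A tibble with one row per daughter pair: `node` (branch node id),
#'   `segment_i`, `segment_j`, `angle_deg`, and the parent segment's `ddso`
#'   (or `so`) as `order`.
#' @export
bifurcation_angles <- function(ordered_segments, g, lookahead = 1) {
  seg <- ordered_segments
  if (!"daughters" %in% names(seg))
    stop("segments carry no daughter relations; run assign_strahler() first",
         call. = FALSE)
  coords <- as.matrix(g$nodes[, c("x", "y", "z")])
  rownames(coords) <- as.character(g$nodes$id)
  dir_vec <- function(k) {
    p <- seg$path[[k]]  # oriented parent_node -> child_node
    tgt <- if (identical(lookahead, "endpoint")) p[length(p)]
           else p[min(1 + lookahead, length(p))]
    coords[as.character(tgt), ] - coords[as.character(p[1]), ]
  }
  rows <- list()
  ord_col <- seg[["ddso"]] %||% seg[["so"]]
  for (k in seq_len(nrow(seg))) {
    d <- seg$daughters[[k]]
    if (length(d) < 2) next
    prs <- utils::combn(d, 2)
    for (c_i in seq_len(ncol(prs))) {
      i <- prs[1, c_i]; j <- prs[2, c_i]
      vi <- dir_vec(i); vj <- dir_vec(j)
      ni <- sqrt(sum(vi^2)); nj <- sqrt(sum(vj^2))
      if (ni == 0 || nj == 0) {
        message("zero-length direction vector at node ", seg$child_node[k],
                "; pair skipped")
        next
      }
      ang <- acos(pmin(pmax(sum(vi * vj) / (ni * nj), -1), 1)) * 180 / pi
      rows[[length(rows) + 1]] <- tibble::tibble(
        node = seg$child_node[k], segment_i = seg$segment[i],
        segment_j = seg$segment[j], angle_deg = ang,
        order = ord_col[k])
    }
  }
  if (length(rows) == 0)
    return(tibble::tibble(node = integer(), segment_i = integer(),
                          segment_j = integer(), angle_deg = numeric(),
                          order = integer()))
  dplyr::bind_rows(rows)
}

#' Shortest distances between terminal points
#'
#' For every terminal (degree-1 node, root excluded), the Euclidean distance
#' to its nearest other terminal. The mean gauges the density of the
#' pre-capillary arterioles; the variance gauges the homogeneity of their
#' spatial distribution.
#'
#' @param g A pruned `vascular_graph`.
#' @param root Root node id, excluded from the terminals.
#' @return A tibble with columns `node` and `d_min` (micrometres);
#'   attributes `mean`, `sd`, `variance`.
#' @export
terminal_distances <- function(g, root = choose_root(g)) {
  deg <- node_degrees(g)
  term <- g$nodes$id[deg == 1L]
  term <- setdiff(term, root)
  if (length(term) < 2)
    stop("need at least 2 terminals (root excluded)", call. = FALSE)
  idx <- match(term, g$nodes$id)
  pts <- as.matrix(g$nodes[idx, c("x", "y", "z")])
  dm <- as.matrix(stats::dist(pts))
  diag(dm) <- Inf
  d_min <- apply(dm, 1, min)
  out <- tibble::tibble(node = term, d_min = unname(d_min))
  attr(out, "mean") <- mean(out$d_min)
  attr(out, "sd") <- stats::sd(out$d_min)
  attr(out, "variance") <- stats::var(out$d_min)
  out
}

#' Assemble the full metrics report
#'
#' Bundles the global, per-order and morphofunctional quantities of one
#' sample into a `vascular_metrics` object.
#'
#' @param cs The sample's [centerline()] tibble.
#' @param g The pruned `vascular_graph`.
#' @param ordered_segments Output of [assign_ddso()].
#' @param root Root node id.
#' @param lookahead Angle lookahead (see [bifurcation_angles()]).
#' @param dD,dl Histogram bin widths (micrometres).
#' @param box_sizes Optional explicit box ladder for [fractal_dimension()].
#' @param sd_type SD convention for per-order statistics.
#' @return An object of class `vascular_metrics`.
#' @export
vascular_metrics <- function(cs, g, ordered_segments, root = choose_root(g),
                             lookahead = 1, dD = 10, dl = 50,
                             box_sizes = NULL, sd_type = "sample") {
  seg <- ordered_segments
  frac <- fractal_dimension(cs, box_sizes = box_sizes)
  stats <- order_statistics(seg, sd_type = sd_type)
  stats <- resistance_per_order(stats)
  ang <- bifurcation_angles(seg, g, lookahead = lookahead)
  dmin <- terminal_distances(g, root = root)
  structure(list(
    global = tibble::tibble(
      n_segments = nrow(seg),
      l_total = total_length(seg),
      v_total = total_volume(seg),
      d_f = frac$d_f,
      d_f_r_squared = frac$r_squared,
      max_ddso = max(seg$ddso),
      n_ddso = length(unique(seg$ddso)),
      angle_mean = if (nrow(ang)) mean(ang$angle_deg) else NA_real_,
      angle_sd = if (nrow(ang) > 1) stats::sd(ang$angle_deg) else NA_real_,
      d_min_mean = attr(dmin, "mean"),
      d_min_sd = attr(dmin, "sd"),
      d_min_variance = attr(dmin, "variance")),
    per_order = stats,
    distributions = segment_distributions(seg, dD = dD, dl = dl),
    angles = ang,
    terminals = dmin,
    fractal = frac),
    class = "vascular_metrics")
}

#' @export
print.vascular_metrics <- function(x, ...) {
  g <- x$global
  cat("<vascular_metrics>\n")
  cat(sprintf("  %d segments | l = %.4g um | V = %.4g um^3 | D_f = %.3f\n",
              g$n_segments, g$l_total, g$v_total, g$d_f))
  cat(sprintf("  DDSO levels: %d (max order %d)\n", g$n_ddso, g$max_ddso))
  cat(sprintf("  bifurcation angle: %.1f +/- %.1f deg | d_min: %.1f +/- %.1f um\n",
              g$angle_mean, g$angle_sd, g$d_min_mean, g$d_min_sd))
  invisible(x)
}

#' @export
tidy.vascular_metrics <- function(x, ...) x$per_order

#' @export
glance.vascular_metrics <- function(x, ...) x$global

#' Broom-style tidiers
#'
#' `tidy()` returns per-component tables (ladder points of a fractal fit,
#' per-order statistics of a metrics report); `glance()` returns one-row
#' summaries.
#'
#' @param x A `fractal_fit` or `vascular_metrics` object.
#' @param ... Unused.
#' @return A tibble.
#' @name tidiers
#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' @rdname tidiers
#' @export
glance <- function(x, ...) UseMethod("glance")

#' Serialize a metrics report to JSON and CSV
#'
#' @param metrics A `vascular_metrics` object.
#' @param dir Output directory.
#' @return The directory, invisibly.
#' @export
write_metrics_report <- function(metrics, dir = ".") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(
    list(global = as.list(metrics$global),
         per_order = metrics$per_order,
         fractal = list(box_sizes = metrics$fractal$box_sizes,
                        counts = metrics$fractal$counts)),
    file.path(dir, "metrics.json"), auto_unbox = TRUE, digits = NA)
  utils::write.csv(metrics$per_order, file.path(dir, "per_order.csv"),
                   row.names = FALSE)
  utils::write.csv(metrics$distributions, file.path(dir, "distributions.csv"),
                   row.names = FALSE)
  utils::write.csv(metrics$angles, file.path(dir, "angles.csv"), row.names = FALSE)
  utils::write.csv(metrics$terminals, file.path(dir, "terminal_distances.csv"),
                   row.names = FALSE)
  invisible(dir)
}
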