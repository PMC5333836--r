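# run code under a fixed RNG seed without disturbing the caller's RNG state
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Specification of a synthetic vascular tree
#'
#' Defaults describe a strictly bifurcating arterial tree with five
#' diameter-defined order levels: four branching generations, 90 degree
#' bifurcations, Murray-law tapering (parent cubed diameter equals the sum
#' of the daughters' cubed diameters), a 160 um root artery and terminal
#' arterioles of about 64 um.
#'
#' @param depth Number of branching generations (>= 1).
#' @param branching_angle Angle in degrees between the two daughters at each
#'   bifurcation (default 90).
#' @param length_ratio Daughter/parent length factor in (0, 1] (default 0.8).
#' @param taper_exponent Murray-type taper exponent `m`: each daughter
#'   diameter is `parent * 2^(-1/m)` (default 3, Murray's law for a
#'   symmetric bifurcation).
#' @param root_diameter,root_length Root segment diameter and length (um).
#' @param jitter_sd SD of Gaussian positional noise applied by
#'   [tree_to_centerline()] (um, default 0).
#' @param dropout_fraction Fraction of centerline points randomly dropped by
#'   [tree_to_centerline()] (default 0).
#' @param cavity_rate Interior voxels flipped to background per 1000
#'   foreground voxels in [voxelize_tree()] (default 0.5), emulating
#'   inhomogeneous contrast filling.
#' @param seed RNG seed fixing all randomness (default 1).
#' @return A list of class `tree_spec`.
#' @export
tree_spec <- function(depth = 4, branching_angle = 90, length_ratio = 0.8,
                      taper_exponent = 3, root_diameter = 160,
                      root_length = 800, jitter_sd = 0,
                      dropout_fraction = 0, cavity_rate = 0.5, seed = 1) {
  stopifnot(depth >= 1, branching_angle > 0, branching_angle < 180,
            length_ratio > 0, length_ratio <= 1, taper_exponent > 0,
            root_diameter > 0, root_length > 0, jitter_sd >= 0,
            dropout_fraction >= 0, dropout_fraction < 1, cavity_rate >= 0)
  structure(list(depth = depth, branching_angle = branching_angle,
                 length_ratio = length_ratio, taper_exponent = taper_exponent,
                 root_diameter = root_diameter, root_length = root_length,
                 jitter_sd = jitter_sd, dropout_fraction = dropout_fraction,
                 cavity_rate = cavity_rate, seed = as.integer(seed)),
            class = "tree_spec")
}

unit_perp <- function(u, phi) {
  # unit vector perpendicular to u, at azimuth phi around u
  ref <- if (abs(u[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  e1 <- ref - sum(ref * u) * u
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(u[2] * e1[3] - u[3] * e1[2],
          u[3] * e1[1] - u[1] * e1[3],
          u[1] * e1[2] - u[2] * e1[1])
  cos(phi) * e1 + sin(phi) * e2
}

#' Generate a synthetic vascular tree with exact ground truth
#'
#' Builds a strictly bifurcating 3D tree: every segment of generation `g`
#' has length `root_length * length_ratio^g` and diameter
#' `root_diameter * 2^(-g/m)`, and daughters leave each bifurcation at
#' `branching_angle` to each other, symmetric about the parent direction,
#' with a seeded random azimuth of the branching plane.
#'
#' @param spec A [tree_spec()].
#' @return A list of class `synthetic_tree` with elements `segments` (tibble
#'   with geometry: `segment`, `parent`, `generation`, start/end coordinates,
#'   `length`, `diameter`, `so_true`) and `ground_truth` (list with
#'   `segment_table`, `l_total`, `v_total`, `tip_positions`, `branch_angle`,
#'   `max_so`).
#' @export
generate_tree <- function(spec) {
  stopifnot(inherits(spec, "tree_spec"))
  alpha <- spec$branching_angle / 2 * pi / 180
  rows <- list()
  with_seed(spec$seed, {
    queue <- list(list(start = c(0, 0, 0), dir = c(0, 0, 1), gen = 0L, parent = 0L))
    while (length(queue) > 0) {
      cur <- queue[[1]]; queue <- queue[-1]
      g <- cur$gen
      len <- spec$root_length * spec$length_ratio^g
      dia <- spec$root_diameter * 2^(-g / spec$taper_exponent)
      if (dia <= 0) stop("taper produced a non-positive diameter; adjust the spec",
                         call. = FALSE)
      end <- cur$start + len * cur$dir
      id <- length(rows) + 1L
      rows[[id]] <- tibble::tibble(
        segment = id, parent = cur$parent, generation = g,
        x0 = cur$start[1], y0 = cur$start[2], z0 = cur$start[3],
        x1 = end[1], y1 = end[2], z1 = end[3],
        length = len, diameter = dia)
      if (g < spec$depth) {
        phi <- stats::runif(1, 0, 2 * pi)
        w <- unit_perp(cur$dir, phi)
        for (s in c(1, -1)) {
          ddir <- cos(alpha) * cur$dir + s * sin(alpha) * w
          ddir <- ddir / sqrt(sum(ddir^2))
          queue <- c(queue, list(list(start = end, dir = ddir,
                                      gen = g + 1L, parent = id)))
        }
      }
    }
  })
  seg <- dplyr::bind_rows(rows)
  # classic Strahler ground truth from the known topology
  so <- rep(NA_integer_, nrow(seg))
  children <- split(seg$segment, seg$parent)
  calc_so <- function(k) {
    kids <- children[[as.character(k)]]
    if (is.null(kids)) return(0L)
    d <- vapply(kids, calc_so, integer(1))
    m <- max(d)
    if (sum(d == m) >= 2L) m + 1L else m
  }
  for (k in seg$segment) so[k] <- calc_so(k)
  seg$so_true <- so
  leaves <- seg$generation == spec$depth
  gt <- list(
    segment_table = seg[, c("segment", "parent", "generation", "length",
                            "diameter", "so_true")],
    l_total = sum(seg$length),
    v_total = sum(pi * seg$length * (seg$diameter / 2)^2),
    tip_positions = as.matrix(seg[leaves, c("x1", "y1", "z1")]),
    branch_angle = spec$branching_angle,
    max_so = max(so),
    n_segments = nrow(seg))
  structure(list(segments = seg, ground_truth = gt, spec = spec),
            class = "synthetic_tree")
}

#' @export
print.synthetic_tree <- function(x, ...) {
  cat("<synthetic_tree> depth", x$spec$depth, "->", nrow(x$segments),
      "segments, total length", signif(x$ground_truth$l_total, 5), "um\n")
  invisible(x)
}

#' Sample a synthetic tree into a centerline set
#'
#' Points are placed along every segment at the given arc-length step (the
#' shared junction point belongs to the parent segment, so coordinates are
#' unique), optionally perturbed with isotropic Gaussian jitter and randomly
#' dropped. Diameters are the true local segment diameters.
#'
#' @param tree A `synthetic_tree`.
#' @param step Sampling step along each segment (um, default 16).
#' @param jitter_sd,dropout_fraction,seed Override the values in the tree's
#'   spec.
#' @return A [centerline()] tibble.
#' @export
tree_to_centerline <- function(tree, step = 16,
                               jitter_sd = tree$spec$jitter_sd,
                               dropout_fraction = tree$spec$dropout_fraction,
                               seed = tree$spec$seed) {
  stopifnot(inherits(tree, "synthetic_tree"), step > 0)
  seg <- tree$segments
  pts <- purrr::map(seq_len(nrow(seg)), function(k) {
    len <- seg$length[k]
    s <- unique(c(seq(0, len, by = step), len))
    # drop samples separated by floating-point dust (len ~ multiple of step)
    s <- s[c(TRUE, diff(s) > 1e-6 * step)]
    if (seg$parent[k] != 0L) s <- s[s > 0]   # junction point owned by parent
    a <- c(seg$x0[k], seg$y0[k], seg$z0[k])
    u <- (c(seg$x1[k], seg$y1[k], seg$z1[k]) - a) / len
    tibble::tibble(x = a[1] + s * u[1], y = a[2] + s * u[2],
                   z = a[3] + s * u[3], d = seg$diameter[k])
  })
  out <- dplyr::bind_rows(pts)
  with_seed(seed + 1L, {
    if (jitter_sd > 0) {
      out$x <- out$x + stats::rnorm(nrow(out), 0, jitter_sd)
      out$y <- out$y + stats::rnorm(nrow(out), 0, jitter_sd)
      out$z <- out$z + stats::rnorm(nrow(out), 0, jitter_sd)
    }
    if (dropout_fraction > 0) {
      keep <- stats::runif(nrow(out)) >= dropout_fraction
      out <- out[keep, ]
    }
  })
  out <- out[!duplicated(out[c("x", "y", "z")]), ]
  centerline(out, spacing = step)
}

#' Voxelize a synthetic tree into an attenuation volume
#'
#' Rasterizes the tree as a union of capsules (cylinders with hemispherical
#' caps) on an isotropic grid, adds Gaussian attenuation noise, and flips
#' interior foreground voxels to background at `cavity_rate` per 1000
#' foreground voxels to emulate inhomogeneous contrast-agent filling.
#'
#' @param tree A `synthetic_tree`.
#' @param spacing Voxel edge (um, default 16).
#' @param foreground_hu,background_hu Attenuation of vessel / background
#'   voxels (defaults 3000 / 0).
#' @param noise_sd SD of additive Gaussian attenuation noise (default 100).
#' @param cavity_rate Interior cavities per 1000 foreground voxels; default
#'   taken from the tree's spec.
#' @param seed RNG seed; default from the tree's spec.
#' @param max_voxels Guard against accidentally huge volumes (default 3e7).
#' @return A [voxel_volume()] whose `origin` places the voxel grid in the
#'   tree's physical coordinate frame.
#' @export
voxelize_tree <- function(tree, spacing = 16, foreground_hu = 3000,
                          background_hu = 0, noise_sd = 100,
                          cavity_rate = tree$spec$cavity_rate,
                          seed = tree$spec$seed, max_voxels = 3e7) {
  stopifnot(inherits(tree, "synthetic_tree"), spacing > 0)
  seg <- tree$segments
  if (any(seg$diameter < spacing))
    stop("tree contains sub-voxel diameters (min ",
         signif(min(seg$diameter), 4), " um at spacing ", spacing,
         " um); increase root_diameter or reduce depth/spacing", call. = FALSE)
  r <- seg$diameter / 2
  lo <- c(min(pmin(seg$x0, seg$x1) - r), min(pmin(seg$y0, seg$y1) - r),
          min(pmin(seg$z0, seg$z1) - r)) - 2 * spacing
  hi <- c(max(pmax(seg$x0, seg$x1) + r), max(pmax(seg$y0, seg$y1) + r),
          max(pmax(seg$z0, seg$z1) + r)) + 2 * spacing
  dims <- as.integer(ceiling((hi - lo) / spacing)) + 1L
  if (prod(dims) > max_voxels)
    stop("volume would have ", prod(dims), " voxels (> max_voxels)", call. = FALSE)
  fg <- array(FALSE, dims)
  ax <- lo[1] + (seq_len(dims[1]) - 1) * spacing
  ay <- lo[2] + (seq_len(dims[2]) - 1) * spacing
  az <- lo[3] + (seq_len(dims[3]) - 1) * spacing
  for (k in seq_len(nrow(seg))) {
    a <- c(seg$x0[k], seg$y0[k], seg$z0[k])
    b <- c(seg$x1[k], seg$y1[k], seg$z1[k])
    rk <- r[k]
    ix <- which(ax >= min(a[1], b[1]) - rk - spacing & ax <= max(a[1], b[1]) + rk + spacing)
    iy <- which(ay >= min(a[2], b[2]) - rk - spacing & ay <= max(a[2], b[2]) + rk + spacing)
    iz <- which(az >= min(a[3], b[3]) - rk - spacing & az <= max(a[3], b[3]) + rk + spacing)
    if (!length(ix) || !length(iy) || !length(iz)) next
    u <- b - a
    L2 <- sum(u^2)
    gx <- ax[ix]; gy <- ay[iy]; gz <- az[iz]
    px <- rep(gx, times = length(iy) * length(iz))
    py <- rep(rep(gy, each = length(ix)), times = length(iz))
    pz <- rep(gz, each = length(ix) * length(iy))
    t <- pmin(pmax(((px - a[1]) * u[1] + (py - a[2]) * u[2] + (pz - a[3]) * u[3]) / L2, 0), 1)
    d2 <- (px - (a[1] + t * u[1]))^2 + (py - (a[2] + t * u[2]))^2 +
      (pz - (a[3] + t * u[3]))^2
    inside <- d2 <= rk^2
    if (any(inside)) {
      sub <- array(FALSE, c(length(ix), length(iy), length(iz)))
      sub[inside] <- TRUE
      fg[ix, iy, iz] <- fg[ix, iy, iz] | sub
    }
  }
  hu <- array(background_hu, dims)
  hu[fg] <- foreground_hu
  with_seed(seed + 2L, {
    if (cavity_rate > 0 && any(fg)) {
      surf <- array(cpp_surface_voxels(as.logical(fg), dims), dims)
      interior <- which(fg & !surf)
      n_cav <- round(cavity_rate * sum(fg) / 1000)
      if (n_cav > 0 && length(interior) > 0) {
        cav <- sample(interior, min(n_cav, length(interior)))
        hu[cav] <- background_hu
      }
    }
    if (noise_sd > 0)
      hu <- hu + array(stats::rnorm(length(hu), 0, noise_sd), dims)
  })
  voxel_volume(hu, spacing = spacing, origin = lo)
}
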