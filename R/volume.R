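#' Construct a voxel volume
#'
#' A `voxel_volume` is a 3D numeric array of attenuation values (Hounsfield
#' units or HU-like), together with the physical voxel spacing and the
#' physical coordinate of the centre of voxel (0, 0, 0).
#'
#' @param data 3D numeric array of attenuation values.
#' @param spacing Physical voxel edge length per axis in micrometres; a
#'   single number is recycled to all three axes. Default 16, the isotropic
#'   resolution typical of whole-kidney microCT.
#' @param origin Physical coordinate (micrometres) of the centre of the first
#'   voxel. Default `c(0, 0, 0)`.
#' @return An object of class `voxel_volume`.
#' @export
voxel_volume <- function(data, spacing = 16, origin = c(0, 0, 0)) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array", call. = FALSE)
  if (any(dim(data) < 2L))
    stop("`data` must have at least 2 voxels along every axis", call. = FALSE)
  spacing <- rep_len(as.numeric(spacing), 3L)
  if (any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be positive on all axes", call. = FALSE)
  structure(
    list(data = data, spacing = spacing, origin = rep_len(as.numeric(origin), 3L)),
    class = "voxel_volume"
  )
}

#' @export
print.voxel_volume <- function(x, ...) {
  cat("<voxel_volume> ", paste(dim(x$data), collapse = " x "),
      " voxels, spacing ", paste(signif(x$spacing, 4), collapse = " x "),
      " um\n", sep = "")
  cat("  attenuation range: [", signif(min(x$data), 5), ", ",
      signif(max(x$data), 5), "]\n", sep = "")
  invisible(x)
}

new_binary_mask <- function(data, spacing, origin) {
  structure(list(data = data, spacing = spacing, origin = origin),
            class = "binary_mask")
}

#' @export
print.binary_mask <- function(x, ...) {
  cat("<binary_mask> ", paste(dim(x$data), collapse = " x "),
      " voxels, ", sum(x$data), " foreground\n", sep = "")
  invisible(x)
}

#' Read a voxel volume from disk
#'
#' Supports multi-page TIFF stacks (via the tiff package), NIfTI files (via
#' RNifti), and raw binary volumes accompanied by a JSON metadata file
#' holding `shape`, `dtype` (`"uint8"`, `"int16"`, `"float32"`, `"float64"`),
#' and `spacing`.
#'
#' @param path File path (`.tif`/`.tiff`, `.nii`/`.nii.gz`, or `.raw` with a
#'   sibling `.json`).
#' @param spacing Voxel spacing in micrometres, overriding any file metadata.
#' @return A [voxel_volume()].
#' @export
read_volume <- function(path, spacing = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  ext <- tolower(sub(".*\\.", "", sub("\\.gz$", "", path)))
  if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE))
      stop("reading TIFF requires the 'tiff' package", call. = FALSE)
    pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    arr <- array(0, dim = c(nrow(pages[[1]]), ncol(pages[[1]]), length(pages)))
    for (k in seq_along(pages)) arr[, , k] <- pages[[k]]
    vol <- voxel_volume(arr, spacing %||% 16)
  } else if (ext %in% c("nii", "hdr", "img")) {
    if (!requireNamespace("RNifti", quietly = TRUE))
      stop("reading NIfTI requires the 'RNifti' package", call. = FALSE)
    img <- RNifti::readNifti(path)
    sp <- spacing %||% (RNifti::pixdim(img) * 1000)  # NIfTI mm -> um
    vol <- voxel_volume(array(as.numeric(img), dim = dim(img)), sp)
  } else if (ext == "raw") {
    meta_path <- sub("\\.raw$", ".json", path)
    if (!file.exists(meta_path))
      stop("raw volume needs a sibling JSON metadata file: ", meta_path, call. = FALSE)
    meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
    dtype <- match.arg(meta$dtype, c("uint8", "int16", "int32", "float32", "float64"))
    size <- c(uint8 = 1L, int16 = 2L, int32 = 4L, float32 = 4L, float64 = 8L)[[dtype]]
    what <- if (dtype %in% c("float32", "float64")) "numeric" else "integer"
    n <- prod(meta$shape)
    con <- file(path, "rb")
    on.exit(close(con))
    raw_vals <- readBin(con, what = what, n = n, size = size,
                        signed = dtype != "uint8")
    vol <- voxel_volume(array(as.numeric(raw_vals), dim = meta$shape),
                        spacing %||% meta$spacing %||% 16)
  } else {
    stop("unsupported volume format: .", ext, call. = FALSE)
  }
  vol
}

#' Write a voxel volume
#'
#' @param vol A [voxel_volume()] or binary mask.
#' @param path Output path; `.tif` writes a multi-page TIFF stack (values
#'   rescaled to `[0, 1]`), `.nii` a NIfTI file, `.raw` a float64 raw volume
#'   with sibling JSON metadata.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  arr <- if (inherits(vol, "binary_mask")) vol$data + 0 else vol$data
  ext <- tolower(sub(".*\\.", "", path))
  if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE))
      stop("writing TIFF requires the 'tiff' package", call. = FALSE)
    rng <- range(arr)
    scl <- if (diff(rng) > 0) (arr - rng[1]) / diff(rng) else arr * 0
    tiff::writeTIFF(lapply(seq_len(dim(arr)[3]), function(k) scl[, , k]), path)
  } else if (ext == "nii") {
    if (!requireNamespace("RNifti", quietly = TRUE))
      stop("writing NIfTI requires the 'RNifti' package", call. = FALSE)
    img <- RNifti::asNifti(arr)
    RNifti::pixdim(img) <- vol$spacing / 1000
    RNifti::writeNifti(img, path)
  } else if (ext == "raw") {
    con <- file(path, "wb")
    writeBin(as.numeric(arr), con, size = 8)
    close(con)
    jsonlite::write_json(
      list(shape = dim(arr), dtype = "float64", spacing = vol$spacing),
      sub("\\.raw$", ".json", path), auto_unbox = FALSE, digits = NA)
  } else stop("unsupported volume format: .", ext, call. = FALSE)
  invisible(path)
}

#' Threshold a voxel volume into a binary vessel mask
#'
#' Voxels whose attenuation lies inside the closed window
#' `[hu_low, hu_high]` become foreground. The window has no default: in
#' contrast-perfused microCT it is chosen per study to compensate for
#' perfusion differences; [suggest_hu_window()] proposes one.
#'
#' @param vol A [voxel_volume()].
#' @param hu_low,hu_high Lower/upper attenuation thresholds (HU).
#' @return A `binary_mask`.
#' @export
threshold_volume <- function(vol, hu_low, hu_high) {
  stopifnot(inherits(vol, "voxel_volume"))
  if (!is.finite(hu_low) || !is.finite(hu_high) || hu_low >= hu_high)
    stop("need hu_low < hu_high", call. = FALSE)
  m <- vol$data >= hu_low & vol$data <= hu_high
  if (!any(m))
    warning("thresholding produced an empty foreground", call. = FALSE)
  new_binary_mask(m, vol$spacing, vol$origin)
}

#' Suggest an attenuation window by Otsu's method
#'
#' Computes Otsu's threshold on the volume histogram and proposes
#' `[otsu, max]` as the window. The suggestion is only reported, never
#' applied silently.
#'
#' @param vol A [voxel_volume()].
#' @param n_bins Histogram bins used for the Otsu search.
#' @return Named numeric vector `c(hu_low = ..., hu_high = ...)`.
#' @export
suggest_hu_window <- function(vol, n_bins = 256) {
  stopifnot(inherits(vol, "voxel_volume"))
  v <- as.numeric(vol$data)
  rng <- range(v)
  if (diff(rng) == 0) stop("volume is constant; no window to suggest", call. = FALSE)
  br <- seq(rng[1], rng[2], length.out = n_bins + 1)
  h <- tabulate(findInterval(v, br, rightmost.closed = TRUE), nbins = n_bins)
  mids <- (br[-1] + br[-length(br)]) / 2
  w <- cumsum(h); total <- w[n_bins]
  mu <- cumsum(h * mids); mu_t <- mu[n_bins]
  between <- (mu_t * w - mu * total)^2 / (w * (total - w) * total^2)
  between[!is.finite(between)] <- -Inf
  thr <- mids[which.max(between)]
  out <- c(hu_low = thr, hu_high = rng[2])
  message("suggested attenuation window: [", signif(thr, 6), ", ",
          signif(rng[2], 6), "] (Otsu)")
  out
}

# pad a logical array with `r` background voxels on every side
pad_mask <- function(m, r) {
  d <- dim(m)
  out <- array(FALSE, d + 2L * r)
  out[r + seq_len(d[1]), r + seq_len(d[2]), r + seq_len(d[3])] <- m
  out
}

unpad_mask <- function(m, r, d) {
  m[r + seq_len(d[1]), r + seq_len(d[2]), r + seq_len(d[3])]
}

#' Morphological closing of a binary mask
#'
#' Dilation followed by erosion with a Euclidean ball structuring element.
#' Fills interior cavities left by inhomogeneous contrast-agent filling while
#' preserving the overall vessel shape. The volume is padded before the
#' operation so the closing is extensive (never removes original foreground).
#'
#' @param mask A `binary_mask`.
#' @param closing_radius Ball radius in voxels (default 1); 0 is the identity.
#' @return A `binary_mask`.
#' @export
close_mask <- function(mask, closing_radius = 1) {
  stopifnot(inherits(mask, "binary_mask"))
  if (closing_radius < 0) stop("closing_radius must be >= 0", call. = FALSE)
  if (closing_radius == 0) return(mask)
  d <- dim(mask$data)
  r <- as.integer(ceiling(closing_radius))
  padded <- pad_mask(mask$data, r)
  dil <- cpp_ball_dilate(as.logical(padded), dim(padded), closing_radius)
  ero <- cpp_ball_erode(dil, dim(padded), closing_radius)
  out <- unpad_mask(array(ero, dim(padded)), r, d)
  new_binary_mask(out, mask$spacing, mask$origin)
}

#' Remove small connected components from a binary mask
#'
#' Deletes every 26-connected foreground component with fewer than
#' `min_component_voxels` voxels; these are typically contrast-agent specks
#' that are not part of the vessel structure.
#'
#' @param mask A `binary_mask`.
#' @param min_component_voxels Components below this size are removed
#'   (default 50); 0 is the identity.
#' @return A `binary_mask`.
#' @export
remove_small_components <- function(mask, min_component_voxels = 50) {
  stopifnot(inherits(mask, "binary_mask"))
  if (min_component_voxels < 0) stop("min_component_voxels must be >= 0", call. = FALSE)
  if (min_component_voxels == 0 || !any(mask$data)) return(mask)
  lab <- cpp_label_components(as.logical(mask$data), dim(mask$data), 26L)
  sizes <- tabulate(lab)
  keep <- which(sizes >= min_component_voxels)
  out <- array(lab %in% keep, dim(mask$data))
  if (!any(out))
    warning("all components were below the size cutoff; mask is empty", call. = FALSE)
  new_binary_mask(out, mask$spacing, mask$origin)
}

#' Skeletonize a binary vessel mask
#'
#' Topology-preserving sequential 3D thinning: voxels that are simple in the
#' (26, 6) sense are peeled from six directions in turn until no further
#' deletion is possible; curve endpoints are preserved so branch tips
#' survive. The result is a thin, 26-connected curve skeleton with the same
#' number of connected components as the input.
#'
#' @param mask A `binary_mask`.
#' @return A `binary_mask` holding the skeleton voxels.
#' @export
skeletonize_mask <- function(mask) {
  stopifnot(inherits(mask, "binary_mask"))
  if (!any(mask$data)) return(mask)
  skel <- cpp_skeletonize(as.logical(mask$data), dim(mask$data))
  new_binary_mask(array(skel, dim(mask$data)), mask$spacing, mask$origin)
}

# number of 26-connected foreground components
count_components <- function(mask) {
  if (!any(mask$data)) return(0L)
  max(cpp_label_components(as.logical(mask$data), dim(mask$data), 26L))
}

# 0-based voxel coordinates (n x 3 matrix) of the foreground voxels
mask_positions <- function(mask) {
  w <- which(mask$data)
  d <- dim(mask$data)
  k <- (w - 1L) %/% (d[1] * d[2])
  rem <- (w - 1L) %% (d[1] * d[2])
  cbind(rem %% d[1], rem %/% d[1], k)
}

voxel_to_physical <- function(pos, mask) {
  sweep(sweep(pos, 2, mask$spacing, `*`), 2, mask$origin, `+`)
}

#' Estimate the local vessel radius at every skeleton voxel
#'
#' For each skeleton voxel, `s_min` is the distance to the nearest surface
#' voxel (a foreground voxel with a background 6-neighbour). Because vessel
#' cross-sections are not perfect circles after discretisation, `s_min` alone
#' underestimates the radius; instead all surface voxels within
#' `radius_factor * s_min` of the skeleton voxel are collected and their own
#' nearest distances to the skeleton are averaged. Because surface voxel
#' centres lie about half a voxel inside the continuous vessel surface, half
#' a voxel edge is added to the averaged distance. All distances are
#' Euclidean in physical units.
#'
#' @param skeleton A `binary_mask` holding the skeleton (from
#'   [skeletonize_mask()]).
#' @param mask The `binary_mask` the skeleton was derived from.
#' @param radius_factor Neighbourhood multiplier (default 1.5; must be >= 1).
#' @return A tibble with one row per skeleton voxel: physical coordinates
#'   `x`, `y`, `z` (micrometres), `s_min`, `radius` and `diameter`
#'   (micrometres), and `fallback` (TRUE where no surface voxel fell inside
#'   the neighbourhood and `s_min` was used).
#' @export
estimate_radius <- function(skeleton, mask, radius_factor = 1.5) {
  stopifnot(inherits(skeleton, "binary_mask"), inherits(mask, "binary_mask"))
  if (radius_factor < 1) stop("radius_factor must be >= 1", call. = FALSE)
  if (!any(skeleton$data)) stop("skeleton is empty", call. = FALSE)
  if (!all(mask$data[skeleton$data]))
    stop("skeleton voxels must lie on the mask foreground", call. = FALSE)
  surf <- cpp_surface_voxels(as.logical(mask$data), dim(mask$data))
  surf_mask <- new_binary_mask(array(surf, dim(mask$data)), mask$spacing, mask$origin)
  if (!any(surf_mask$data)) stop("mask has no surface voxels", call. = FALSE)
  skel_phys <- voxel_to_physical(mask_positions(skeleton), skeleton)
  surf_phys <- voxel_to_physical(mask_positions(surf_mask), mask)
  est <- cpp_estimate_radius(skel_phys, surf_phys, radius_factor)
  if (any(est$fallback))
    message(sum(est$fallback), " skeleton voxel(s) had an empty surface ",
            "neighbourhood; s_min used as radius there")
  # surface voxel centres sit about half a voxel inside the continuous
  # vessel surface, so the averaged centre-to-centre distance systematically
  # underestimates the radius; add the half-voxel offset back
  radius <- est$radius + min(mask$spacing) / 2
  tibble::tibble(
    x = skel_phys[, 1], y = skel_phys[, 2], z = skel_phys[, 3],
    s_min = est$s_min, radius = radius, diameter = 2 * radius,
    fallback = est$fallback
  )
}

#' Full image-segmentation stage: volume to centerline set
#'
#' Thresholds, closes, cleans, skeletonizes and estimates radii in one call.
#'
#' @inheritParams threshold_volume
#' @inheritParams close_mask
#' @inheritParams remove_small_components
#' @inheritParams estimate_radius
#' @return A centerline tibble (see [centerline()]).
#' @export
segment_volume <- function(vol, hu_low, hu_high, closing_radius = 1,
                           min_component_voxels = 50, radius_factor = 1.5) {
  mask <- threshold_volume(vol, hu_low, hu_high)
  mask <- close_mask(mask, closing_radius)
  mask <- remove_small_components(mask, min_component_voxels)
  if (!any(mask$data)) {
    warning("empty vessel mask; returning an empty centerline set", call. = FALSE)
    return(centerline(tibble::tibble(x = numeric(), y = numeric(),
                                     z = numeric(), d = numeric()),
                      spacing = mask$spacing))
  }
  skel <- skeletonize_mask(mask)
  est <- estimate_radius(skel, mask, radius_factor)
  centerline(
    tibble::tibble(x = est$x, y = est$y, z = est$z, d = est$diameter),
    spacing = mask$spacing
  )
}
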