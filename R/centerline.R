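`%||%` <- function(a, b) if (is.null(a)) b else a

#' Construct a centerline set
#'
#' The pipeline's interchange format: one row per skeleton point, with
#' physical coordinates `x`, `y`, `z` and the local average vessel diameter
#' `d`, all in micrometres.
#'
#' @param points A data frame with columns `x`, `y`, `z`, `d`.
#' @param spacing Voxel spacing (micrometres) of the source volume, kept as
#'   metadata; default 16.
#' @param sample_id Optional sample label kept as metadata.
#' @return A tibble of class `centerline`.
#' @export
centerline <- function(points, spacing = 16, sample_id = NULL) {
  points <- tibble::as_tibble(points)
  need <- c("x", "y", "z", "d")
  if (!all(need %in% names(points)))
    stop("centerline points need columns x, y, z, d", call. = FALSE)
  points <- points[need]
  if (nrow(points) > 0) {
    if (any(!is.finite(as.matrix(points))))
      stop("centerline points must be finite", call. = FALSE)
    if (any(points$d <= 0))
      stop("all centerline diameters must be > 0", call. = FALSE)
    if (anyDuplicated(points[c("x", "y", "z")]))
      stop("centerline points must have distinct coordinates", call. = FALSE)
  }
  structure(points,
            spacing = rep_len(as.numeric(spacing), 3L),
            sample_id = sample_id,
            class = c("centerline", class(tibble::tibble())))
}

#' Write a centerline set to the ASCII interchange format
#'
#' One whitespace-separated record `x y z D` per line (micrometres), the
#' format used for deposited vascular-skeleton data. Comment lines starting
#' with `#` carry metadata and are skipped on read.
#'
#' @param cs A [centerline()] tibble.
#' @param path Output path; a `.gz` suffix writes gzip-compressed text.
#' @return `path`, invisibly.
#' @export
write_centerline <- function(cs, path) {
  stopifnot(inherits(cs, "centerline"))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "# vascular centerline: x y z D (micrometres)",
    sprintf("# spacing: %s", paste(attr(cs, "spacing"), collapse = " ")),
    if (!is.null(attr(cs, "sample_id")))
      sprintf("# sample: %s", attr(cs, "sample_id"))
  ), con)
  writeLines(sprintf("%.10g %.10g %.10g %.10g", cs$x, cs$y, cs$z, cs$d), con)
  invisible(path)
}

#' Read a centerline set from the ASCII interchange format
#'
#' @param path Input path (optionally gzip-compressed).
#' @param spacing Voxel spacing metadata; if `NULL`, taken from a
#'   `# spacing:` comment when present, else 16.
#' @return A [centerline()] tibble.
#' @export
read_centerline <- function(path, spacing = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(if (grepl("\\.gz$", path)) gzfile(path) else path)
  is_comment <- grepl("^\\s*#", lines)
  is_blank <- grepl("^\\s*$", lines)
  if (is.null(spacing)) {
    sp_line <- grep("^\\s*#\\s*spacing:", lines, value = TRUE)
    if (length(sp_line) > 0)
      spacing <- as.numeric(strsplit(trimws(sub(".*spacing:", "", sp_line[1])),
                                     "\\s+")[[1]])
  }
  data_idx <- which(!is_comment & !is_blank)
  fields <- strsplit(trimws(lines[data_idx]), "\\s+")
  nf <- lengths(fields)
  if (any(nf != 4)) {
    bad <- data_idx[which(nf != 4)[1]]
    stop("malformed centerline record at line ", bad,
         ": expected 4 fields 'x y z D', got ", nf[which(nf != 4)[1]],
         call. = FALSE)
  }
  vals <- suppressWarnings(matrix(as.numeric(unlist(fields)), ncol = 4, byrow = TRUE))
  if (anyNA(vals)) {
    bad <- data_idx[which(rowSums(is.na(vals)) > 0)[1]]
    stop("non-numeric centerline record at line ", bad, call. = FALSE)
  }
  if (any(vals[, 4] <= 0)) {
    bad <- data_idx[which(vals[, 4] <= 0)[1]]
    stop("non-positive diameter at line ", bad, call. = FALSE)
  }
  centerline(tibble::tibble(x = vals[, 1], y = vals[, 2], z = vals[, 3],
                            d = vals[, 4]),
             spacing = spacing %||% 16)
}
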