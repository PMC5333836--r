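#' Pipeline configuration
#'
#' A validated, serializable bundle of all stage parameters for one sample.
#' Unknown fields are rejected, so a config file round trips exactly.
#'
#' @param input Path to the input file (or `""` for in-memory runs).
#' @param kind `"centerline"` (ASCII x y z D) or `"volume"` (TIFF/NIfTI/raw).
#' @param hu_low,hu_high Attenuation window; required for `kind = "volume"`.
#' @param closing_radius,min_component_voxels,radius_factor Segmentation
#'   parameters (see [close_mask()], [remove_small_components()],
#'   [estimate_radius()]).
#' @param nn2,nn5,nn10 Optional manual neighbour scales overriding
#'   [compute_neighbor_scales()].
#' @param convention Strahler parent rule, `"classic"` or `"literal"`.
#' @param root Optional root node id.
#' @param lookahead Bifurcation-angle lookahead in path nodes (or
#'   `"endpoint"`). Default 1 for centerline inputs; [run_sample()] uses
#'   `"endpoint"` for volume inputs, where the immediate-neighbour direction
#'   is quantised to the 26 voxel-lattice directions.
#' @param dD,dl Histogram bin widths (um).
#' @param sd_type Per-order SD convention.
#' @param output_dir Where [run_sample()] writes artifacts.
#' @param seed RNG seed (reserved for stochastic inputs; the pipeline itself
#'   is deterministic).
#' @param sample_id,group Labels used by [run_group()].
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(input = "", kind = c("centerline", "volume"),
                            hu_low = NULL, hu_high = NULL, closing_radius = 1,
                            min_component_voxels = 50, radius_factor = 1.5,
                            nn2 = NULL, nn5 = NULL, nn10 = NULL,
                            convention = "classic", root = NULL,
                            lookahead = NULL, dD = 10, dl = 50,
                            sd_type = "sample", output_dir = NULL,
                            seed = 1, sample_id = NULL, group = NULL) {
  kind <- match.arg(kind)
  if (kind == "volume" && (is.null(hu_low) || is.null(hu_high)))
    stop("volume inputs need an explicit hu_low/hu_high window ",
         "(see suggest_hu_window())", call. = FALSE)
  cfg <- list(input = input, kind = kind, hu_low = hu_low, hu_high = hu_high,
              closing_radius = closing_radius,
              min_component_voxels = min_component_voxels,
              radius_factor = radius_factor, nn2 = nn2, nn5 = nn5, nn10 = nn10,
              convention = convention, root = root, lookahead = lookahead,
              dD = dD, dl = dl, sd_type = sd_type, output_dir = output_dir,
              seed = seed, sample_id = sample_id, group = group)
  structure(cfg, class = "pipeline_config")
}

#' Read / write a pipeline configuration
#'
#' YAML round trip; unknown keys in the file are rejected.
#'
#' @param path YAML file path.
#' @return [read_config()] returns a `pipeline_config`.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0)
    stop("unknown config keys: ", paste(unknown, collapse = ", "), call. = FALSE)
  do.call(pipeline_config, raw)
}

#' @param cfg A `pipeline_config`.
#' @rdname read_config
#' @export
write_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "pipeline_config"))
  yaml::write_yaml(cfg[!vapply(cfg, is.null, logical(1))], path)
  invisible(path)
}

stage_msg <- function(stage, ...) message("[", stage, "] ", ...)

#' Run the full pipeline on one sample
#'
#' Volume inputs go through thresholding, closing, component cleanup,
#' skeletonization and radius estimation; centerline inputs skip straight to
#' reconstruction. Both then run the staged linking, pruning, segment
#' extraction, Strahler + DDSO ordering, and the full metrics suite. Every
#' stage logs its counts; artifacts (centerline, graph exports, ordered
#' segment table, metrics JSON/CSV) are written when `output_dir` is set.
#'
#' @param config A [pipeline_config()].
#' @param input Optional in-memory input overriding `config$input`: a
#'   [voxel_volume()] or a [centerline()] tibble.
#' @return A `vascular_metrics` report (invisibly carries the graph and
#'   ordered segments as attributes `graph` and `segments`).
#' @export
run_sample <- function(config, input = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.null(input)) {
    if (!nzchar(config$input) || !file.exists(config$input))
      stop("read stage: input file not found: ", config$input, call. = FALSE)
    input <- if (config$kind == "volume") read_volume(config$input)
             else read_centerline(config$input)
  }
  if (config$kind == "volume") {
    stopifnot(inherits(input, "voxel_volume"))
    stage_msg("segment", "thresholding in [", config$hu_low, ", ",
              config$hu_high, "]")
    cs <- segment_volume(input, config$hu_low, config$hu_high,
                         config$closing_radius, config$min_component_voxels,
                         config$radius_factor)
    if (nrow(cs) == 0) stop("segment stage: no vessel voxels survived", call. = FALSE)
    stage_msg("segment", nrow(cs), " centerline points")
    lookahead <- config$lookahead %||% "endpoint"
  } else {
    cs <- if (inherits(input, "centerline")) input else centerline(input)
    if (nrow(cs) == 0) stop("read stage: empty centerline set", call. = FALSE)
    lookahead <- config$lookahead %||% 1
  }
  scales <- if (!is.null(config$nn2))
    tibble::tibble(nn2 = config$nn2, nn5 = config$nn5, nn10 = config$nn10)
  else compute_neighbor_scales(cs)
  stage_msg("reconstruct", sprintf("scales nn2=%.3g nn5=%.3g nn10=%.3g",
                                   scales$nn2, scales$nn5, scales$nn10))
  g <- link_stage1(cs, scales)
  stage_msg("reconstruct", "stage 1 added ", g$log$stage1_edges, " edges")
  g <- link_stage2(g, scales)
  stage_msg("reconstruct", "stage 2 added ", g$log$stage2_edges, " edges")
  g <- link_stage3(g, scales)
  stage_msg("reconstruct", "stage 3 added ", g$log$stage3_edges, " edges")
  g <- prune_artifacts(g)
  stage_msg("reconstruct", "pruned to ", nrow(g$nodes), " nodes / ",
            nrow(g$edges), " edges (", g$log$pruned_spurs, " spurs removed)")
  segments <- extract_segments(g)
  stage_msg("segments", nrow(segments), " vessel segments")
  root <- choose_root(g, config$root)
  seg_o <- assign_strahler(segments, g, root, convention = config$convention)
  seg_o <- assign_ddso(seg_o, sd_type = config$sd_type)
  stage_msg("order", "max SO ", max(seg_o$so), ", ",
            length(unique(seg_o$ddso)), " DDSO levels (converged: ",
            attr(seg_o, "converged"), ")")
  metrics <- vascular_metrics(cs, g, seg_o, root = root,
                              lookahead = lookahead, dD = config$dD,
                              dl = config$dl, sd_type = config$sd_type)
  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
    write_centerline(cs, file.path(config$output_dir, "centerline.txt"))
    write_graph_exports(g, seg_o, config$output_dir)
    write_segment_table(seg_o, file.path(config$output_dir, "segments_ordered.csv"))
    write_metrics_report(metrics, config$output_dir)
    stage_msg("report", "artifacts written to ", config$output_dir)
  }
  attr(metrics, "graph") <- g
  attr(metrics, "segments") <- seg_o
  attr(metrics, "sample_id") <- config$sample_id
  attr(metrics, "group") <- config$group
  attr(metrics, "spacing") <- attr(cs, "spacing")
  metrics
}

#' Aggregate metrics reports by phenotype group
#'
#' Averages the relative and absolute distributions across the samples of
#' each group (samples weigh equally, regardless of their segment counts)
#' and summarises every global scalar as mean and SD.
#'
#' @param reports A list of `vascular_metrics` objects (from [run_sample()]).
#' @param labels Character vector of group labels, one per report; defaults
#'   to each report's `group` attribute.
#' @return A list of class `vascular_group` with elements `scalars` (tibble:
#'   group, metric, mean, sd, n) and `distributions` (group-averaged
#'   histograms).
#' @export
run_group <- function(reports, labels = NULL) {
  stopifnot(length(reports) >= 1)
  labels <- labels %||% vapply(reports, function(r) attr(r, "group") %||% "all",
                               character(1))
  stopifnot(length(labels) == length(reports))
  spacings <- unique(vapply(reports, function(r)
    paste(attr(r, "spacing") %||% NA, collapse = "x"), character(1)))
  if (length(spacings) > 1)
    warning("samples have mixed voxel spacing (", paste(spacings, collapse = "; "),
            "); group histograms mix resolutions", call. = FALSE)
  glob <- dplyr::bind_rows(lapply(seq_along(reports), function(i)
    dplyr::mutate(reports[[i]]$global, group = labels[i],
                  sample = attr(reports[[i]], "sample_id") %||% paste0("s", i))))
  scalars <- glob |>
    tidyr::pivot_longer(-c("group", "sample"), names_to = "metric") |>
    dplyr::group_by(.data$group, .data$metric) |>
    dplyr::summarise(mean = mean(.data$value),
                     sd = if (dplyr::n() > 1) stats::sd(.data$value) else 0,
                     n = dplyr::n(), .groups = "drop")
  seg_all <- dplyr::bind_rows(lapply(seq_along(reports), function(i) {
    s <- attr(reports[[i]], "segments")
    tibble::tibble(length = s$length, diameter = s$diameter,
                   sample = attr(reports[[i]], "sample_id") %||% paste0("s", i),
                   group = labels[i])
  }))
  dists <- segment_distributions(seg_all)
  structure(list(scalars = scalars, distributions = dists,
                 n_samples = table(labels)),
            class = "vascular_group")
}

#' @export
print.vascular_group <- function(x, ...) {
  cat("<vascular_group> ", length(x$n_samples), " group(s): ",
      paste(sprintf("%s (n=%d)", names(x$n_samples), as.integer(x$n_samples)),
            collapse = ", "), "\n", sep = "")
  key <- x$scalars[x$scalars$metric %in% c("l_total", "v_total", "d_f"), ]
  print(key)
  invisible(x)
}
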