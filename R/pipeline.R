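#' Write crown polygons as GeoJSON
#'
#' @param segments Segment tibble with `boundary` list-column (or any tibble
#'   with a polygon list-column named by `geom_col`).
#' @param path Output `.geojson` path.
#' @param geom_col Name of the polygon list-column.
#' @param props Character vector of property columns to carry.
#' @return `path`, invisibly.
#' @export
write_crowns_geojson <- function(segments, path, geom_col = "boundary",
                                 props = c("tree_id", "area")) {
  feats <- purrr::map(seq_len(nrow(segments)), function(i) {
    poly <- segments[[geom_col]][[i]]
    if (is.null(poly)) return(NULL)
    ring <- cbind(poly[, 1], poly[, 2])
    if (!all(ring[1, ] == ring[nrow(ring), ])) ring <- rbind(ring, ring[1, ])
    list(
      type = "Feature",
      properties = as.list(segments[i, intersect(props, names(segments))]),
      geometry = list(
        type = "Polygon",
        coordinates = list(lapply(seq_len(nrow(ring)),
                                  function(k) unname(ring[k, ])))
      )
    )
  })
  feats <- feats[!vapply(feats, is.null, logical(1))]
  jsonlite::write_json(
    list(type = "FeatureCollection", features = feats),
    path, auto_unbox = TRUE, digits = 8, pretty = FALSE
  )
  invisible(path)
}

read_stems_csv <- function(path) {
  df <- utils::read.csv(path)
  need <- c("tree_id", "stem_x", "stem_y", "total_height")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("stem table is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  tibble::as_tibble(df)
}

#' Run the end-to-end pipeline from a declarative config
#'
#' The config (a YAML file or an equivalent named list) names either a
#' synthetic scene (`scene:` block with [scene_config()] fields) or real
#' inputs (`inputs:` block with `cloud`, `ortho`, optionally `stems`), an
#' `output_dir`, a `seed`, and analysis `params:` overrides (see
#' [analyze_plot()]). All stages run in order — preprocessing, canopy height
#' model, segmentation, classification, scorch assessment, evaluation — and
#' every table, raster, polygon set and a JSON summary are written to the
#' output directory together with a run log recording the parameters and
#' seed.
#'
#' @param config Path to a YAML config or a named list.
#' @return The output directory, invisibly; the summary list as attribute
#'   `"summary"`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config$output_dir)) stop("config is missing `output_dir`", call. = FALSE)
  out_dir <- config$output_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  params <- if (is.null(config$params)) list() else config$params
  log_path <- file.path(out_dir, "run_log.txt")
  logf <- function(...) cat(sprintf(...), "\n", sep = "", file = log_path,
                            append = TRUE)
  cat("", file = log_path)
  logf("crownscorch pipeline run")
  logf("seed: %d", seed)
  logf("params: %s", jsonlite::toJSON(params, auto_unbox = TRUE))

  truth <- NULL
  if (!is.null(config$scene)) {
    sc_args <- config$scene
    sc_args$seed <- seed
    cfg <- do.call(scene_config, sc_args)
    full_sf <- if (is.null(config$full_scorch_fraction)) 0.2 else
      config$full_scorch_fraction
    truths <- simulate_truths(cfg, full_scorch_fraction = full_sf)
    scene <- generate_scene(truths, cfg)
    cloud <- scene$cloud
    truth <- scene$truth
    ortho <- render_orthomosaic(cloud, cell = cfg$ortho_cell,
                                ground_color = cfg$ground_color)
    utils::write.csv(
      dplyr::select(truth, "tree_id", "stem_x", "stem_y", "total_height",
                    "crown_base_height", "scorch_height", "cvs_true"),
      file.path(out_dir, "truth.csv"), row.names = FALSE)
    write_point_cloud(cloud, file.path(out_dir, "cloud.las"))
    logf("scene: %d trees, %d points", nrow(truth), nrow(cloud))
  } else if (!is.null(config$inputs)) {
    inp <- config$inputs
    if (is.null(inp$cloud)) stop("config inputs are missing `cloud`", call. = FALSE)
    if (is.null(inp$ortho)) stop("config inputs are missing `ortho`", call. = FALSE)
    cloud <- read_point_cloud(inp$cloud)
    ortho <- read_raster(inp$ortho)
    if (!is.null(inp$stems)) truth <- read_stems_csv(inp$stems)
    logf("inputs: cloud %s (%d points), ortho %s", inp$cloud, nrow(cloud),
         inp$ortho)
  } else {
    stop("config must contain a `scene` or an `inputs` block", call. = FALSE)
  }

  res <- analyze_plot(cloud, ortho = ortho, truth = truth, params = params)
  write_raster(ortho, file.path(out_dir, "ortho.tif"))
  if (!is.null(res$chm)) write_raster(res$chm, file.path(out_dir, "chm.tif"))
  summary <- list(seed = seed)
  if (is.null(res$segments) || nrow(res$segments) == 0) {
    logf("no crowns detected")
    summary$n_segments <- 0L
  } else {
    segs <- res$segments
    write_crowns_geojson(segs, file.path(out_dir, "crowns.geojson"))
    calls_out <- dplyr::select(res$calls, "tree_id", "positive_gli_fraction",
                               "label", "n_pixels")
    utils::write.csv(calls_out, file.path(out_dir, "burn_calls.csv"),
                     row.names = FALSE)
    assess_out <- dplyr::select(
      res$assessments, "tree_id", "label", "positive_gli_fraction",
      scorch_height_m = "scorch_height", cbh_m = "crown_base_height",
      cl_m = "cl", cls_m = "cls", cvs_pct = "cvs", "flags")
    utils::write.csv(assess_out, file.path(out_dir, "assessments.csv"),
                     row.names = FALSE)
    write_profile_dumps(segs, res$calls, cloud, params, out_dir)
    summary$n_segments <- nrow(segs)
    summary$n_burned_calls <- sum(res$calls$label == "burned", na.rm = TRUE)
    summary$n_unburned_calls <- sum(res$calls$label == "unburned", na.rm = TRUE)
    if (!is.null(res$match)) {
      mr <- res$match
      jsonlite::write_json(
        list(tp = mr$tp, fn = mr$fn, fp = mr$fp,
             recall = signif(mr$recall, 6), precision = signif(mr$precision, 6)),
        file.path(out_dir, "match_report.json"), auto_unbox = TRUE, digits = NA)
      if (!is.null(mr$pairs)) {
        utils::write.csv(mr$pairs, file.path(out_dir, "match_pairs.csv"),
                         row.names = FALSE)
      }
      summary$match <- list(tp = mr$tp, fn = mr$fn, fp = mr$fp,
                            recall = signif(mr$recall, 6),
                            precision = signif(mr$precision, 6))
    }
    if (!is.null(res$per_tree) && "label_true" %in% names(res$per_tree)) {
      pt <- res$per_tree
      cs <- summarize_classification(
        dplyr::select(pt, tree_id = "segment_id", "label"),
        dplyr::select(pt, tree_id = "segment_id", label = "label_true"))
      summary$classification <- list(
        n = cs$n,
        unburned_accuracy = signif(cs$unburned_accuracy, 6),
        burned_accuracy = signif(cs$burned_accuracy, 6),
        overall_accuracy = signif(cs$overall_accuracy, 6))
      bc <- pt[!is.na(pt$label) & pt$label == "burned" &
                 pt$label_true == "burned", ]
      if (nrow(bc) >= 3 && stats::var(bc$scorch_height) > 0) {
        reg <- scorch_height_regression(bc$scorch_height, bc$scorch_height_truth)
        summary$scorch_regression <- list(
          n = reg$n, slope = signif(reg$slope, 6),
          r_squared = signif(reg$r_squared, 6), rmse = signif(reg$rmse, 6))
        agr <- cvs_agreement(bc$cvs, bc$cvs_true)
        summary$cvs_agreement <- list(
          n = agr$n, within_10 = signif(agr$within_10, 6),
          within_30 = signif(agr$within_30, 6))
      }
    }
  }
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  logf("done")
  invisible(structure(out_dir, summary = summary))
}

write_profile_dumps <- function(segments, calls, cloud, params, out_dir) {
  p <- utils::modifyList(list(slice = 0.10, smoothing = 0.65,
                              min_height = 2.0), params)
  pc <- suppressWarnings(preprocess(cloud, min_height = p$min_height))
  rows <- purrr::map_dfr(seq_len(nrow(segments)), function(i) {
    id <- segments$tree_id[i]
    lab <- calls$label[calls$tree_id == id]
    if (!length(lab) || is.na(lab[1]) || lab[1] != "burned") return(NULL)
    pts <- pc[segments$point_idx[[i]], ]
    if (nrow(pts) == 0) return(NULL)
    prof <- vertical_gli_profile(pts, slice = p$slice)
    sp <- suppressWarnings(fit_profile_spline(prof, smoothing = p$smoothing))
    tibble::tibble(tree_id = id, height = prof$height,
                   median_gli = prof$stat, n = prof$n,
                   spline = sp$predict(prof$height))
  })
  if (nrow(rows)) {
    utils::write.csv(rows, file.path(out_dir, "profiles.csv"), row.names = FALSE)
  }
}
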