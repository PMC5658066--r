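# End-to-end orchestration: segmentation in -> interfaces -> features ->
# directed scores -> synapse table -> connectome, with every artifact
# written to the output directory and stamped with the config hash and
# seed.

#' Pipeline configuration
#'
#' @param raw_path,seg_path TIFF volume paths ([write_volume()] format).
#'   Leave `NULL` to pass volumes in memory to [run_pipeline()].
#' @param out_dir Output directory (created if missing).
#' @param model_path Optional stump-ensemble JSON; if `NULL` and
#'   annotations are supplied, a model is trained in-run.
#' @param theta Score threshold for detection.
#' @param min_border_voxels Interface size filter.
#' @param distances_nm Subvolume shell distances.
#' @param cluster_cutoff_nm Single-linkage cutoff for synapse clustering.
#' @param gamma_nn Binarization threshold.
#' @param n_learners,learning_rate,cost_synaptic Training parameters used
#'   when a model is trained in-run.
#' @param seed Seed recorded with the artifacts.
#' @return A `pipeline_config` list that round-trips through JSON.
#' @export
pipeline_config <- function(raw_path = NULL, seg_path = NULL,
                            out_dir = tempfile("emsynapse_run_"),
                            model_path = NULL,
                            theta = 0,
                            min_border_voxels = 151L,
                            distances_nm = c(40, 80, 160),
                            cluster_cutoff_nm = 1500,
                            gamma_nn = 1L,
                            n_learners = 1500L,
                            learning_rate = 0.1,
                            cost_synaptic = 100,
                            seed = 0L) {
  structure(as.list(environment()), class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param path JSON file path.
#' @export
write_pipeline_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_pipeline_config <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- do.call(pipeline_config, obj[setdiff(names(obj), character(0))])
  cfg
}

config_hash <- function(config) {
  # order-stable structural hash; no external digest dependency needed
  s <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA,
                        null = "null")
  sum(utf8ToInt(s) * (seq_along(utf8ToInt(s)) %% 97 + 1)) %% 1e9
}

#' Run the full detection pipeline
#'
#' Stages: interface extraction, filter bank, directed feature vectors,
#' scoring (training a model first when annotations are given and no model
#' file is configured), interface classification at `theta`, synapse
#' clustering, weighted/binary connectome, and a PR report when ground
#' truth is available. Each stage failure aborts with a stage-named error.
#'
#' @param config A [pipeline_config()].
#' @param raw,seg In-memory volumes (used when the config has no paths).
#' @param annotations Optional interface annotations for in-run training.
#' @param ground_truth Optional ground truth (as from [generate_scene()])
#'   for a PR report.
#' @param model Optional in-memory `stump_ensemble` (overrides
#'   `model_path`).
#' @return Invisible list of the main artifacts (also written to
#'   `config$out_dir`).
#' @export
run_pipeline <- function(config, raw = NULL, seg = NULL,
                         annotations = NULL, ground_truth = NULL,
                         model = NULL) {
  stage <- function(name, expr) {
    tryCatch(force(expr),
             error = function(e) stop("pipeline stage [", name, "] failed: ",
                                      conditionMessage(e), call. = FALSE))
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  stamp <- list(config_hash = config_hash(config), seed = config$seed)

  raw <- stage("read_raw", raw %||% read_volume(config$raw_path))
  seg <- stage("read_seg", seg %||% read_volume(config$seg_path))

  interfaces <- stage("extract", extract_interfaces(seg, config$min_border_voxels))
  write_table_csv(interface_table(interfaces),
                  file.path(config$out_dir, "interfaces.csv"))

  maps <- stage("filter_bank",
                compute_filter_bank(raw, filter_bank_config(voxel_size(raw))))
  feats <- stage("features",
                 interface_features(maps, seg, interfaces, config$distances_nm))

  model <- stage("model", {
    if (!is.null(model)) model
    else if (!is.null(config$model_path)) read_model(config$model_path)
    else if (!is.null(annotations)) {
      lv <- build_label_variant(annotations, "directed")
      key <- paste(feats$info$interface_id, feats$info$direction)
      y <- lv$synaptic[match(key, paste(lv$interface_id, lv$direction))]
      m <- train_stump_ensemble(feats$X, y, config$n_learners,
                                config$learning_rate, config$cost_synaptic,
                                seed = config$seed,
                                label_variant = "directed")
      write_model(m, file.path(config$out_dir, "model.json"))
      m
    } else stop("no model, model_path or annotations supplied")
  })

  scores <- stage("score", {
    s <- predict(model, feats$X)
    fwd <- s[feats$info$direction == "fwd"]
    rev <- s[feats$info$direction == "rev"]
    dplyr::bind_cols(
      tibble::tibble(interface_id = interfaces$id,
                     score_fwd = fwd, score_rev = rev),
      classify_interface(fwd, rev, config$theta))
  })
  write_table_csv(scores, file.path(config$out_dir, "scores.csv"))

  areas <- stage("areas", purrr::pmap_dbl(
    list(interfaces$border, interfaces$id1, interfaces$id2),
    function(b, i1, i2) interface_area_um2(seg, b, i1, i2)))

  detections <- stage("synapses", {
    det <- scores[scores$detected, ]
    idx <- match(det$interface_id, interfaces$id)
    tibble::tibble(
      interface_id = det$interface_id,
      pre_id = ifelse(det$direction == "fwd", interfaces$id1[idx],
                      interfaces$id2[idx]),
      post_id = ifelse(det$direction == "fwd", interfaces$id2[idx],
                       interfaces$id1[idx]),
      x_nm = interfaces$centroid_x_nm[idx],
      y_nm = interfaces$centroid_y_nm[idx],
      z_nm = interfaces$centroid_z_nm[idx],
      area_um2 = areas[idx])
  })
  synapses <- stage("cluster", cluster_synapses(detections, config$cluster_cutoff_nm))
  write_table_csv(dplyr::select(synapses, -"interface_ids"),
                  file.path(config$out_dir, "synapses.csv"))

  cw <- stage("connectome", weighted_connectome(synapses))
  cb <- binarize_connectome(cw, config$gamma_nn)
  write_table_csv(cw, file.path(config$out_dir, "connectome_weighted.csv"))
  write_table_csv(cb, file.path(config$out_dir, "connectome_binary.csv"))

  pr <- NULL
  if (!is.null(ground_truth) && nrow(ground_truth) > 0) {
    pr <- stage("evaluate", {
      gt_ifaces <- purrr::map(ground_truth$border, function(b)
        interfaces$id[purrr::map_lgl(interfaces$border, ~ any(.x %in% b))])
      gt <- tibble::tibble(synapse_id = ground_truth$synapse_id,
                           interface_ids = gt_ifaces)
      pr_curve(tibble::tibble(interface_id = scores$interface_id,
                              score = scores$score), gt)
    })
    write_table_csv(pr, file.path(config$out_dir, "pr_curve.csv"))
  }

  jsonlite::write_json(stamp, file.path(config$out_dir, "run_stamp.json"),
                       auto_unbox = TRUE)
  invisible(list(interfaces = interfaces, scores = scores,
                 synapses = synapses, weighted = cw, binary = cb,
                 pr = pr, model = model, stamp = stamp))
}
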