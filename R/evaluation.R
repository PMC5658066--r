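# Synapse-level evaluation: a ground-truth synapse is detected if at least
# one of the interfaces overlapping it is detected; a detected interface
# overlapping no synapse is one false positive.

#' Match detected interfaces against ground-truth synapses
#'
#' @param detections Integer vector of detected interface ids.
#' @param gt Tibble of ground-truth synapses with columns `synapse_id` and
#'   list-column `interface_ids` (non-empty integer vectors).
#' @return Tibble with `tp`, `fn`, `fp` counts.
#' @export
match_detections <- function(detections, gt) {
  hit <- purrr::map_lgl(gt$interface_ids, ~ any(.x %in% detections))
  synaptic_ifaces <- unique(unlist(gt$interface_ids))
  tibble::tibble(tp = sum(hit),
                 fn = sum(!hit),
                 fp = sum(!(detections %in% synaptic_ifaces)))
}

#' Precision-recall curve over score thresholds
#'
#' Thresholds the per-interface max-direction score, matches detections to
#' ground truth at every threshold and reports synapse-level precision and
#' recall. With no detections at a threshold, precision is reported as 1
#' and flagged. Optionally restricts ground truth to one synapse class
#' (e.g. spine-only evaluation).
#'
#' @param scored Tibble with `interface_id` and `score` (max over the two
#'   directions).
#' @param gt Ground-truth tibble as in [match_detections()]; an optional
#'   `class` column supports `class_filter`.
#' @param thresholds Numeric vector of score thresholds; defaults to the
#'   sorted unique scores.
#' @param class_filter Optional ground-truth class to keep.
#' @return A `pr_curve` tibble with `threshold`, `tp`, `fp`, `fn`,
#'   `precision`, `recall`, `no_detections`.
#' @export
pr_curve <- function(scored, gt, thresholds = NULL, class_filter = NULL) {
  if (!is.null(class_filter)) gt <- gt[gt$class %in% class_filter, ]
  if (is.null(thresholds))
    thresholds <- sort(unique(c(-Inf, scored$score)))
  rows <- purrr::map(thresholds, function(th) {
    det <- scored$interface_id[scored$score > th]
    cbind(tibble::tibble(threshold = th), match_detections(det, gt),
          tibble::tibble(no_detections = length(det) == 0))
  })
  out <- dplyr::bind_rows(rows)
  out$precision <- ifelse(out$no_detections, 1, out$tp / (out$tp + out$fp))
  out$recall <- ifelse(out$tp + out$fn == 0, 1, out$tp / (out$tp + out$fn))
  out <- tibble::as_tibble(out)
  class(out) <- c("pr_curve", class(out))
  out
}

#' Exclude interfaces near the volume boundary
#'
#' Drops interfaces whose centroid is closer than `margin_nm` to any face of
#' the volume, so that every evaluated interface has complete subvolumes.
#'
#' @param interfaces Tibble from [extract_interfaces()] (attributes carry
#'   volume shape and voxel size).
#' @param margin_nm Exclusion margin (default 160 nm, the largest shell).
#' @return Filtered interface tibble.
#' @export
exclude_margin <- function(interfaces, margin_nm = 160) {
  dims <- attr(interfaces, "volume_shape")
  vs <- attr(interfaces, "voxel_size_nm")
  hi <- dims * vs
  keep <- interfaces$centroid_x_nm >= margin_nm &
    interfaces$centroid_x_nm <= hi[1] - margin_nm &
    interfaces$centroid_y_nm >= margin_nm &
    interfaces$centroid_y_nm <= hi[2] - margin_nm &
    interfaces$centroid_z_nm >= margin_nm &
    interfaces$centroid_z_nm <= hi[3] - margin_nm
  out <- interfaces[keep, ]
  attr(out, "volume_shape") <- dims
  attr(out, "voxel_size_nm") <- vs
  out
}

#' @export
autoplot.pr_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$recall, y = .data$precision)) +
    ggplot2::geom_path() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "Synapse recall", y = "Synapse precision") +
    ggplot2::theme_minimal()
}

#' Direction accuracy of confident detections
#'
#' Among detected interfaces that are truly synaptic, the fraction whose
#' resolved presynaptic direction matches the annotated one.
#'
#' @param detections Tibble with `interface_id` and `direction` (as from
#'   [classify_interface()], detected rows only).
#' @param annotations Interface annotations with `interface_id`,
#'   `synaptic`, `direction`.
#' @return Tibble with `n_confident`, `n_correct`, `accuracy` (`NaN` with
#'   no confident detections).
#' @export
direction_accuracy <- function(detections, annotations) {
  ann <- annotations[match(detections$interface_id, annotations$interface_id), ]
  keep <- !is.na(ann$synaptic) & ann$synaptic
  n <- sum(keep)
  ok <- sum(detections$direction[keep] == ann$direction[keep])
  tibble::tibble(n_confident = n, n_correct = ok, accuracy = ok / n)
}

#' Best F1 operating point of a PR curve
#'
#' @param curve A `pr_curve`.
#' @return One-row tibble at the threshold maximizing the synapse-level F1.
#' @export
best_f1 <- function(curve) {
  f1 <- 2 * curve$precision * curve$recall /
    pmax(curve$precision + curve$recall, .Machine$double.eps)
  out <- curve[which.max(f1), ]
  out$f1 <- max(f1)
  out
}
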