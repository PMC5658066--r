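# From detected interfaces to connectomes: single-linkage clustering of
# interface centroids into synapses per neurite pair, contact-area and
# synapse-count matrices, and the analytic neuron-to-neuron precision /
# recall model that propagates single-synapse error rates.

#' Cluster detected interfaces into synapses
#'
#' Within each (presynaptic, postsynaptic) process pair, interface centroids
#' are clustered by single-linkage hierarchical clustering cut at
#' `cutoff_nm`; each cluster is one synapse. The default 1500 nm cutoff is
#' used for connectome construction (concatenating multi-active-zone or
#' split-segment synapses); 320.12 nm is the calibrated cutoff for
#' volume-wide synapse counting.
#'
#' @param detections Tibble with columns `interface_id`, `pre_id`,
#'   `post_id`, centroid `x_nm`, `y_nm`, `z_nm`, and optionally `area_um2`.
#' @param cutoff_nm Single-linkage distance cutoff (default 1500).
#' @return Synapse tibble: `synapse_id`, `pre_id`, `post_id`,
#'   `n_interfaces`, list-column `interface_ids`, centroid columns (mean of
#'   members) and `area_um2` (sum of member areas, `NA` without areas).
#' @export
cluster_synapses <- function(detections, cutoff_nm = 1500) {
  if (nrow(detections) == 0) {
    return(tibble::tibble(synapse_id = integer(), pre_id = integer(),
                          post_id = integer(), n_interfaces = integer(),
                          interface_ids = list(), x_nm = double(),
                          y_nm = double(), z_nm = double(),
                          area_um2 = double()))
  }
  has_area <- "area_um2" %in% names(detections)
  groups <- dplyr::group_split(dplyr::group_by(detections, .data$pre_id,
                                               .data$post_id))
  res <- purrr::map(groups, function(g) {
    cl <- if (nrow(g) == 1) 1L else {
      d <- dist(cbind(g$x_nm, g$y_nm, g$z_nm))
      cutree(hclust(d, method = "single"), h = cutoff_nm)
    }
    dplyr::summarise(
      dplyr::group_by(tibble::tibble(g, cl = cl), .data$cl),
      pre_id = .data$pre_id[1], post_id = .data$post_id[1],
      n_interfaces = dplyr::n(),
      interface_ids = list(.data$interface_id),
      x_nm = mean(.data$x_nm), y_nm = mean(.data$y_nm),
      z_nm = mean(.data$z_nm),
      area_um2 = if (has_area) sum(.data$area_um2) else NA_real_,
      .groups = "drop")
  })
  out <- dplyr::select(dplyr::bind_rows(res), -"cl")
  out$synapse_id <- seq_len(nrow(out))
  dplyr::relocate(out, "synapse_id")
}

#' Axon-spine interface area of a synapse
#'
#' Sum of the areas of all member interfaces of a detected synapse.
#'
#' @param areas_um2 Numeric vector of member interface areas.
#' @return Total area in square micrometers.
#' @export
asi_area <- function(areas_um2) sum(areas_um2)

#' Weighted connectome from a synapse table
#'
#' @param synapses Output of [cluster_synapses()].
#' @return Tibble `pre_id`, `post_id`, `n_synapses`.
#' @export
weighted_connectome <- function(synapses) {
  dplyr::count(synapses, .data$pre_id, .data$post_id, name = "n_synapses")
}

#' Binarize a weighted connectome
#'
#' A pair is connected when its synapse count reaches `gamma_nn`. A
#' per-presynaptic-type threshold (1 for excitatory, 2 for inhibitory) is
#' supported by passing `pre_types` and a named `gamma_nn`.
#'
#' @param cw Tibble `pre_id`, `post_id`, `n_synapses`.
#' @param gamma_nn Integer threshold (scalar, or named vector by type).
#' @param pre_types Optional tibble `pre_id`, `type` used to look up the
#'   per-type `gamma_nn`.
#' @return `cw` with an added logical column `connected`.
#' @export
binarize_connectome <- function(cw, gamma_nn = 1L, pre_types = NULL) {
  if (any(gamma_nn < 1)) stop("gamma_nn must be >= 1", call. = FALSE)
  gam <- if (!is.null(pre_types)) {
    type <- pre_types$type[match(cw$pre_id, pre_types$pre_id)]
    unname(gamma_nn[type])
  } else gamma_nn
  dplyr::mutate(cw, connected = .data$n_synapses >= gam)
}

#' Contactome: total contact area per process pair
#'
#' Sums interface areas over all contacts (synaptic or not) between mapped
#' pre- and postsynaptic processes. Interfaces whose segments map to no
#' (pre, post) process pair are skipped and counted in the
#' `n_skipped` attribute.
#'
#' @param interfaces Tibble with `id1`, `id2` and `area_um2` per interface.
#' @param pre_map,post_map Tibbles `segment_id`, `process_id` mapping
#'   segments to presynaptic/postsynaptic processes.
#' @return Tibble `pre_id`, `post_id`, `total_area_um2`.
#' @export
contactome <- function(interfaces, pre_map, post_map) {
  pre1 <- pre_map$process_id[match(interfaces$id1, pre_map$segment_id)]
  pre2 <- pre_map$process_id[match(interfaces$id2, pre_map$segment_id)]
  post1 <- post_map$process_id[match(interfaces$id1, post_map$segment_id)]
  post2 <- post_map$process_id[match(interfaces$id2, post_map$segment_id)]
  # orient each interface as (pre, post) if exactly one consistent mapping
  pre <- ifelse(!is.na(pre1) & !is.na(post2), pre1,
                ifelse(!is.na(pre2) & !is.na(post1), pre2, NA))
  post <- ifelse(!is.na(pre1) & !is.na(post2), post2,
                 ifelse(!is.na(pre2) & !is.na(post1), post1, NA))
  ok <- !is.na(pre) & !is.na(post)
  out <- dplyr::summarise(
    dplyr::group_by(tibble::tibble(pre_id = pre[ok], post_id = post[ok],
                                   area = interfaces$area_um2[ok]),
                    .data$pre_id, .data$post_id),
    total_area_um2 = sum(.data$area), .groups = "drop")
  attr(out, "n_skipped") <- sum(!ok)
  out
}

check_pn <- function(p_n) {
  if (is.null(names(p_n)) || abs(sum(p_n) - 1) > 1e-8 || any(p_n < 0))
    stop("p_n must be a named non-negative vector summing to 1 (names = synapse counts)",
         call. = FALSE)
  invisible(p_n)
}

#' Point-mass synapse-count distribution
#'
#' @param n Number of synapses per connected pair (6 for the inhibitory
#'   model).
#' @return Named probability vector usable as `p_n`.
#' @export
delta_pn <- function(n) setNames(1, as.character(n))

#' Neuron-to-neuron connection recall
#'
#' Exact binomial propagation of single-synapse recall: a connected pair
#' with n synapses is recovered when at least `gamma_nn` of its synapses
#' are detected independently with probability `r_s`, so
#' `R_nn = sum_n P(Bin(n, r_s) >= gamma_nn) p(n)`.
#'
#' @param r_s Single-synapse recall in `[0, 1]`.
#' @param p_n Named probability vector over synapse counts per connected
#'   pair (names are the counts); see [delta_pn()].
#' @param gamma_nn Binarization threshold (>= 1).
#' @return `R_nn` in `[0, 1]`.
#' @export
nn_recall <- function(r_s, p_n, gamma_nn = 1L) {
  stopifnot(r_s >= 0, r_s <= 1, gamma_nn >= 1)
  check_pn(p_n)
  n <- as.numeric(names(p_n))
  sum(pbinom(gamma_nn - 1, n, r_s, lower.tail = FALSE) * p_n)
}

#' Neuron-to-neuron connection precision
#'
#' False-positive synapse detections are assumed to scatter uniformly over
#' the connectome; the per-pair false count is Poisson with rate
#' `lambda = (1 - p_s)/p_s * r_s * c_r * mean_n_syn`, and a previously
#' empty pair becomes a false connection when at least `gamma_nn` land on
#' it. `P_nn = c_r R_nn / (c_r R_nn + (1 - c_r) P(Poi(lambda) >= gamma_nn))`
#' is exact and independent of the connectome size N (N cancels).
#'
#' @param p_s Single-synapse precision in `(0, 1]`.
#' @param r_s Single-synapse recall.
#' @param r_nn Neuron-to-neuron recall from [nn_recall()].
#' @param c_r Pairwise connectivity rate (0.2 excitatory, 0.6 inhibitory).
#' @param mean_n_syn Mean synapses per connected pair (4.3 excitatory, 6
#'   inhibitory).
#' @param gamma_nn Binarization threshold.
#' @return `P_nn` in `[0, 1]`.
#' @export
nn_precision <- function(p_s, r_s, r_nn, c_r, mean_n_syn, gamma_nn = 1L) {
  if (p_s <= 0) stop("p_s must be positive", call. = FALSE)
  stopifnot(c_r > 0, c_r < 1, gamma_nn >= 1)
  lambda <- (1 - p_s) / p_s * r_s * c_r * mean_n_syn
  fp_tail <- ppois(gamma_nn - 1, lambda, lower.tail = FALSE)
  c_r * r_nn / (c_r * r_nn + (1 - c_r) * fp_tail)
}

#' Pairwise connectivity model
#'
#' Bundles the synapse-count distribution, connectivity rate and
#' binarization thresholds of one presynaptic type, and evaluates the
#' neuron-to-neuron performance implied by a single-synapse operating
#' point. `inhibitory_model()` is the fixed-count (n = 6, c_r = 0.6)
#' inhibitory variant; the excitatory variant takes an empirical `p_n`
#' (mean 4.3) supplied by the user.
#'
#' @param p_n Named probability vector of synapses per connected pair.
#' @param c_r Pairwise connectivity rate.
#' @param mean_n_syn Mean synapses per connection; default from `p_n`.
#' @param gamma_nn Integer vector of binarization thresholds to evaluate.
#' @return A `connectivity_model` object.
#' @export
connectivity_model <- function(p_n, c_r, mean_n_syn = NULL,
                               gamma_nn = c(1L, 2L)) {
  check_pn(p_n)
  mean_n_syn <- mean_n_syn %||% sum(as.numeric(names(p_n)) * p_n)
  structure(list(p_n = p_n, c_r = c_r, mean_n_syn = mean_n_syn,
                 gamma_nn = as.integer(gamma_nn)),
            class = "connectivity_model")
}

#' @rdname connectivity_model
#' @export
inhibitory_model <- function(gamma_nn = c(1L, 2L)) {
  connectivity_model(delta_pn(6), c_r = 0.6, mean_n_syn = 6,
                     gamma_nn = gamma_nn)
}

#' Neuron-to-neuron performance at an operating point
#'
#' @param model A [connectivity_model()].
#' @param p_s,r_s Single-synapse precision and recall.
#' @return Tibble `gamma_nn`, `r_nn`, `p_nn`.
#' @export
nn_performance <- function(model, p_s, r_s) {
  purrr::map_dfr(model$gamma_nn, function(g) {
    r_nn <- nn_recall(r_s, model$p_n, g)
    tibble::tibble(gamma_nn = g, r_nn = r_nn,
                   p_nn = nn_precision(p_s, r_s, r_nn, model$c_r,
                                       model$mean_n_syn, g))
  })
}

#' @export
print.connectivity_model <- function(x, ...) {
  cat(sprintf("<connectivity_model> c_r = %g, <n_syn> = %g, gamma_nn = %s\n",
              x$c_r, x$mean_n_syn, paste(x$gamma_nn, collapse = ", ")))
  invisible(x)
}

#' @export
tidy.connectivity_model <- function(x, ...) {
  tibble::tibble(n_syn = as.numeric(names(x$p_n)), p = unname(x$p_n))
}

#' @export
glance.connectivity_model <- function(x, ...) {
  tibble::tibble(c_r = x$c_r, mean_n_syn = x$mean_n_syn,
                 n_support = length(x$p_n))
}

#' @export
autoplot.connectivity_model <- function(object, p_s = 0.9, ...) {
  r_s <- seq(0.01, 1, by = 0.01)
  df <- purrr::map_dfr(r_s, function(r) {
    perf <- nn_performance(object, p_s, r)
    perf$r_s <- r
    perf
  })
  df <- tidyr::pivot_longer(df, c("r_nn", "p_nn"), names_to = "measure")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$r_s, y = .data$value,
                                   color = factor(.data$gamma_nn),
                                   linetype = .data$measure)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Single-synapse recall", y = "Neuron-to-neuron rate",
                  color = "gamma_nn", linetype = NULL) +
    ggplot2::theme_minimal()
}

#' Round a rate to the reported percent format
#'
#' Half-away-from-zero rounding to one decimal in percent, the format used
#' in the reported threshold tables.
#'
#' @param x Rate in `[0, 1]`.
#' @return Percent value with one decimal.
#' @export
percent1 <- function(x) {
  sign(x) * floor(abs(x) * 1000 + 0.5) / 10
}
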