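# Cost-weighted boosted decision stumps on directed feature vectors.
# LogitBoost (Newton-step regression stumps on working responses, with the
# usual response/probability clamping) is the default; AdaBoost.M1 is
# retained as the historic alternative. The synaptic-class misclassification
# cost enters as a multiplicative observation weight.

#' Build a label set variant from raw interface annotations
#'
#' Raw annotations carry, per interface, whether it is synaptic and (for
#' synapses) the true direction (`"fwd"` = segment id1 presynaptic).
#' Variants: `undirected` keeps one entry per interface ignoring direction;
#' `augmented` emits both directed copies, both labeled synaptic for a
#' synapse; `directed` emits both copies but labels only the true direction
#' synaptic.
#'
#' @param annotations Tibble with columns `interface_id`,
#'   `synaptic` (logical), `direction` (`"fwd"`/`"rev"`; may be `NA` for
#'   non-synaptic rows).
#' @param variant One of `"undirected"`, `"augmented"`, `"directed"`.
#' @return Tibble with `interface_id`, `direction` (`NA` for undirected),
#'   `synaptic`.
#' @export
build_label_variant <- function(annotations,
                                variant = c("directed", "augmented",
                                            "undirected")) {
  variant <- match.arg(variant)
  if (variant == "undirected") {
    return(tibble::tibble(interface_id = annotations$interface_id,
                          direction = NA_character_,
                          synaptic = annotations$synaptic))
  }
  if (variant == "directed" &&
      any(annotations$synaptic & is.na(annotations$direction)))
    stop("directed label set requires a direction for every synaptic annotation",
         call. = FALSE)
  both <- tidyr::expand_grid(
    annotations[c("interface_id", "synaptic", "direction")],
    dir = c("fwd", "rev"))
  lab <- if (variant == "augmented") both$synaptic
         else both$synaptic & both$dir == both$direction
  tibble::tibble(interface_id = both$interface_id,
                 direction = both$dir,
                 synaptic = lab)
}

#' Train a boosted decision-stump ensemble
#'
#' Fits an additive model of depth-1 stumps by LogitBoost (default) or
#' AdaBoost.M1. The score of an example is
#' `sum(learning_rate * branch response)` over the stumps; higher scores are
#' more synaptic. Synaptic observations receive `cost_synaptic` times the
#' weight of non-synaptic ones. Training is deterministic for fixed inputs.
#'
#' @param X Numeric feature matrix, one row per (interface, direction).
#' @param y Logical or 0/1 vector of synaptic labels, one per row of `X`.
#' @param n_learners Number of stumps (default 1500).
#' @param learning_rate Shrinkage (default 0.1).
#' @param cost_synaptic Misclassification cost of the synaptic class,
#'   applied as observation weighting (default 100).
#' @param algorithm `"logitboost"` or `"adaboostm1"`.
#' @param seed Recorded in the model metadata (the core fit is
#'   deterministic; the seed covers optional subsampling extensions).
#' @param label_variant Free-text tag recorded in the metadata.
#' @return A `stump_ensemble` object.
#' @export
train_stump_ensemble <- function(X, y, n_learners = 1500L,
                                 learning_rate = 0.1, cost_synaptic = 100,
                                 algorithm = c("logitboost", "adaboostm1"),
                                 seed = 0L, label_variant = NA_character_) {
  algorithm <- match.arg(algorithm)
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  y <- as.integer(as.logical(y))
  if (length(y) != nrow(X)) stop("length(y) must match nrow(X)", call. = FALSE)
  if (length(unique(y)) < 2)
    stop("training requires both classes", call. = FALSE)
  if (!all(is.finite(X))) stop("non-finite feature values", call. = FALSE)
  w0 <- ifelse(y == 1L, cost_synaptic, 1)
  w0 <- w0 / sum(w0) * length(y)
  st <- if (algorithm == "logitboost") {
    .logitboost_train_cpp(X, y, w0, as.integer(n_learners), learning_rate,
                          4, 1e-10)
  } else {
    .adaboostm1_train_cpp(X, y, w0, as.integer(n_learners), learning_rate)
  }
  stumps <- tibble::tibble(
    feature = as.integer(st[, 1]),
    threshold = st[, 2],
    left = st[, 3],
    right = st[, 4],
    gain = st[, 5])
  structure(list(stumps = stumps,
                 learning_rate = learning_rate,
                 n_learners = as.integer(n_learners),
                 cost_synaptic = cost_synaptic,
                 algorithm = algorithm,
                 n_features = ncol(X),
                 seed = as.integer(seed),
                 label_variant = label_variant),
            class = "stump_ensemble")
}

#' @export
print.stump_ensemble <- function(x, ...) {
  cat(sprintf("<stump_ensemble> %s, %d stumps, learning rate %g, cost %g, %d features\n",
              x$algorithm, nrow(x$stumps), x$learning_rate, x$cost_synaptic,
              x$n_features))
  invisible(x)
}

#' Score feature vectors with a stump ensemble
#'
#' @param object A `stump_ensemble`.
#' @param newdata Numeric matrix (rows are examples) or a single vector of
#'   length `n_features`.
#' @param ... Unused.
#' @return Numeric score per row; higher is more synaptic.
#' @export
predict.stump_ensemble <- function(object, newdata, ...) {
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1)
  if (ncol(newdata) != object$n_features)
    stop("feature vector length ", ncol(newdata), " does not match model (",
         object$n_features, ")", call. = FALSE)
  s <- numeric(nrow(newdata))
  st <- object$stumps
  for (m in seq_len(nrow(st))) {
    if (st$feature[m] == 0L) {
      s <- s + object$learning_rate * st$left[m]
    } else {
      left <- newdata[, st$feature[m]] <= st$threshold[m]
      s <- s + object$learning_rate * ifelse(left, st$left[m], st$right[m])
    }
  }
  s
}

#' @export
tidy.stump_ensemble <- function(x, ...) x$stumps

#' @export
glance.stump_ensemble <- function(x, ...) {
  tibble::tibble(algorithm = x$algorithm,
                 n_learners = x$n_learners,
                 learning_rate = x$learning_rate,
                 cost_synaptic = x$cost_synaptic,
                 n_features = x$n_features,
                 n_features_used = length(unique(x$stumps$feature[x$stumps$feature > 0])),
                 label_variant = x$label_variant)
}

#' Resolve interface direction from the two directed scores
#'
#' An interface is detected as synaptic when the larger of its two directed
#' scores exceeds `theta`; the argmax direction is reported (ties go to
#' forward).
#'
#' @param score_fwd,score_rev Numeric vectors of directed scores.
#' @param theta Score threshold.
#' @return Tibble with `score` (the max), `detected` (logical) and
#'   `direction` (`"fwd"`/`"rev"`; `NA` when not detected).
#' @export
classify_interface <- function(score_fwd, score_rev, theta) {
  m <- pmax(score_fwd, score_rev)
  det <- m > theta
  dir <- ifelse(score_fwd >= score_rev, "fwd", "rev")
  tibble::tibble(score = m, detected = det,
                 direction = ifelse(det, dir, NA_character_))
}

#' Feature importance of a stump ensemble
#'
#' Split-gain accumulation: each feature's importance is the sum of the
#' split gains of the stumps that use it; unused features have importance
#' zero.
#'
#' @param model A `stump_ensemble`.
#' @return Tibble (`feature`, `importance`, `rank`) sorted by decreasing
#'   importance, covering all model features.
#' @export
feature_importance <- function(model) {
  st <- dplyr::filter(model$stumps, .data$feature > 0L)
  acc <- dplyr::summarise(dplyr::group_by(st, .data$feature),
                          importance = sum(.data$gain), .groups = "drop")
  out <- tibble::tibble(feature = seq_len(model$n_features)) |>
    dplyr::left_join(acc, by = "feature") |>
    dplyr::mutate(importance = dplyr::coalesce(.data$importance, 0)) |>
    dplyr::arrange(dplyr::desc(.data$importance), .data$feature)
  out$rank <- seq_len(nrow(out))
  out
}

#' Undirected validation of a directed classifier
#'
#' Combines the thresholded predictions of the two directions by logical OR
#' and reports precision and recall of the synaptic class against
#' undirected labels. With no detections, precision is reported as 1 and
#' flagged.
#'
#' @param score_fwd,score_rev Directed scores, one per interface.
#' @param synaptic Logical undirected labels, one per interface.
#' @param theta Score threshold.
#' @return Tibble with `precision`, `recall`, `tp`, `fp`, `fn`,
#'   `no_detections` flag.
#' @export
validate_undirected <- function(score_fwd, score_rev, synaptic, theta) {
  detected <- score_fwd > theta | score_rev > theta
  tp <- sum(detected & synaptic)
  fp <- sum(detected & !synaptic)
  fn <- sum(!detected & synaptic)
  none <- !any(detected)
  tibble::tibble(
    precision = if (none) 1 else tp / (tp + fp),
    recall = if (tp + fn == 0) 1 else tp / (tp + fn),
    tp = tp, fp = fp, fn = fn,
    no_detections = none)
}

#' Serialize / restore a stump ensemble as JSON
#'
#' Full-precision, bit-stable serialization of the stump table and the
#' training metadata.
#'
#' @param model A `stump_ensemble`.
#' @param path JSON file path.
#' @return `write_model` returns `path` invisibly; `read_model` the model.
#' @export
write_model <- function(model, path) {
  obj <- list(
    type = "stump_ensemble",
    algorithm = model$algorithm,
    learning_rate = model$learning_rate,
    n_learners = model$n_learners,
    cost_synaptic = model$cost_synaptic,
    n_features = model$n_features,
    seed = model$seed,
    label_variant = model$label_variant,
    stumps = as.list(model$stumps))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  if (!file.exists(path)) stop("model_file_missing: ", path, call. = FALSE)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(stumps = tibble::as_tibble(obj$stumps),
                 learning_rate = obj$learning_rate,
                 n_learners = as.integer(obj$n_learners),
                 cost_synaptic = obj$cost_synaptic,
                 algorithm = obj$algorithm,
                 n_features = as.integer(obj$n_features),
                 seed = as.integer(obj$seed),
                 label_variant = obj$label_variant),
            class = "stump_ensemble")
}

#' Reference score thresholds and operating points
#'
#' The shipped operating points for the two threshold profiles (optimized
#' for single-synapse vs. neuron-to-neuron performance) of excitatory and
#' inhibitory presynaptic types, with the associated single-synapse
#' precision and recall measured on their respective test sets.
#'
#' @return Tibble with `type`, `profile`, `theta`, `p_s`, `r_s`.
#' @export
reference_operating_points <- function() {
  tibble::tribble(
    ~type, ~profile, ~theta, ~p_s, ~r_s,
    "exc", "synapse",    -1.67, 0.885, 0.881,
    "exc", "connectome", -0.08, 0.994, 0.651,
    "inh", "synapse",    -2.06, 0.821, 0.749,
    "inh", "connectome", -1.58, 0.886, 0.678)
}
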