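# Feature aggregation: each of the 51 texture maps is pooled over the 7
# subvolumes with 9 summary statistics (3213 values), then 11 shape values
# are appended, giving the 3224-entry vector. Each interface yields two
# directed vectors related by a fixed index permutation that swaps the
# pre/post roles of the two segments.

SUMMARY_STAT_NAMES <- c("q25", "median", "q75", "min", "max",
                        "mean", "var", "skewness", "kurtosis")

SUBVOLUME_NAMES <- c("border", "s1_40", "s2_40", "s1_80", "s2_80",
                     "s1_160", "s2_160")

SHAPE_FEATURE_NAMES <- c("n_border", "n_s1_160", "n_s2_160", "diameter",
                         "pax1", "pax2", "pax3", "pax_product",
                         "hull_border", "hull_s1_160", "hull_s2_160")

#' Nine pooled summary statistics
#'
#' Quantiles 0.25/0.5/0.75, min, max, mean, unbiased variance, and the
#' biased standardized third and fourth moments (kurtosis is non-excess, 3
#' for a Gaussian). Quantiles use linear interpolation between order
#' statistics (type 7). Conventions for degenerate inputs: an empty sample
#' yields all zeros; a constant (or single) sample yields zero variance,
#' skewness and kurtosis.
#'
#' @param x Numeric vector of samples (possibly empty).
#' @return Named numeric vector of length 9 in the order
#'   `r paste(SUMMARY_STAT_NAMES, collapse = ", ")`.
#' @export
summary_statistics <- function(x) {
  if (length(x) == 0) return(setNames(numeric(9), SUMMARY_STAT_NAMES))
  n <- length(x)
  q <- quantile(x, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  mu <- mean(x)
  m2 <- sum((x - mu)^2) / n
  if (m2 > 0) {
    skew <- (sum((x - mu)^3) / n) / m2^1.5
    kurt <- (sum((x - mu)^4) / n) / m2^2
  } else {
    skew <- 0
    kurt <- 0
  }
  setNames(c(q[1], q[2], q[3], min(x), max(x), mu,
             if (n > 1) var(x) else 0, skew, kurt),
           SUMMARY_STAT_NAMES)
}

#' Texture features of one interface
#'
#' Pools every texture map over the seven subvolumes with the nine summary
#' statistics, in canonical order: maps outermost, then subvolumes (border,
#' S1/S2 at 40, 80, 160 nm), then statistics. Empty subvolumes contribute
#' zeros for all nine statistics.
#'
#' @param maps A `texture_maps` object from [compute_filter_bank()].
#' @param subvols A `subvolume_set` from [compute_subvolumes()].
#' @return Numeric vector of length `51 * 7 * 9 = 3213`.
#' @export
texture_features <- function(maps, subvols) {
  vals <- lapply(subvols, function(idx) lapply(maps, function(m) m[idx]))
  out <- numeric(length(maps) * length(subvols) * 9L)
  pos <- 0L
  for (m in seq_along(maps)) {
    for (sv in seq_along(subvols)) {
      out[pos + 1:9] <- summary_statistics(vals[[sv]][[m]])
      pos <- pos + 9L
    }
  }
  out
}

first_principal_component <- function(co) {
  if (nrow(co) < 2) return(NULL)
  cv <- cov(co)
  if (!all(is.finite(cv)) || sum(diag(cv)) <= 0) return(NULL)
  eigen(cv, symmetric = TRUE)$vectors[, 1]
}

#' Shape features of one interface
#'
#' Eleven scalars: voxel counts of the border and the two 160 nm
#' subvolumes; voxel-based diameter of the border (diameter of a sphere
#' whose volume equals the border voxel count); the three principal-axis
#' lengths (covariance eigenvalues, descending) of the border voxel cloud;
#' the absolute scalar product of the first principal components of the two
#' 160 nm voxel clouds; and convex-hull voxel counts (lattice points inside
#' the hull) of the border and the two 160 nm subvolumes. Voxel coordinates
#' are used as-is (no physical rescaling). Degenerate clouds give zero
#' principal axes / axis product, and hulls of affine rank < 3 count only
#' their own voxels.
#'
#' @param subvols A `subvolume_set` from [compute_subvolumes()].
#' @return Named numeric vector of length 11 in the order
#'   `r paste(SHAPE_FEATURE_NAMES, collapse = ", ")`.
#' @export
shape_features <- function(subvols) {
  dims <- attr(subvols, "volume_shape")
  co <- lapply(subvols[c("border", "s1_160", "s2_160")],
               function(idx) coords_from_index(idx, dims))
  n <- vapply(co, nrow, integer(1))
  diameter <- 2 * (3 * n[["border"]] / (4 * pi))^(1 / 3)
  pax <- c(0, 0, 0)
  if (n[["border"]] >= 2) {
    ev <- eigen(cov(co[["border"]]), symmetric = TRUE, only.values = TRUE)$values
    pax <- sort(pmax(ev, 0), decreasing = TRUE)
  }
  p1 <- first_principal_component(co[["s1_160"]])
  p2 <- first_principal_component(co[["s2_160"]])
  pax_prod <- if (is.null(p1) || is.null(p2)) 0 else abs(sum(p1 * p2))
  hulls <- vapply(co, function(m) hull_voxel_count(m), numeric(1))
  setNames(c(n[["border"]], n[["s1_160"]], n[["s2_160"]], diameter,
             pax[1], pax[2], pax[3], pax_prod,
             hulls[["border"]], hulls[["s1_160"]], hulls[["s2_160"]]),
           SHAPE_FEATURE_NAMES)
}

#' Layout of the directed feature vector
#'
#' One row per entry of the 3224-vector, mapping index to texture map,
#' subvolume and statistic (or shape feature name).
#'
#' @param manifest Texture manifest, e.g. `filter_bank_config()$manifest`.
#' @return Tibble with columns `index`, `block`, `map_index`, `subvolume`,
#'   `statistic`.
#' @export
feature_layout <- function(manifest = filter_bank_config()$manifest) {
  tex <- tidyr::expand_grid(map_index = manifest$index,
                            subvolume = SUBVOLUME_NAMES,
                            statistic = SUMMARY_STAT_NAMES)
  tex$block <- "texture"
  shp <- tibble::tibble(map_index = NA_integer_,
                        subvolume = NA_character_,
                        statistic = SHAPE_FEATURE_NAMES,
                        block = "shape")
  out <- dplyr::bind_rows(tex, shp)
  out$index <- seq_len(nrow(out))
  dplyr::relocate(out, "index", "block")
}

#' Direction-swap permutation of the feature vector
#'
#' The fixed permutation of indices 1..3224 that exchanges the roles of the
#' two segments: per texture map, the S1/S2 subvolume blocks at each
#' distance swap; among the shape entries, the voxel counts and hull counts
#' of the two 160 nm subvolumes swap. Direction-symmetric entries (border
#' blocks, diameter, border principal axes, axis product) map to
#' themselves. The permutation is an involution.
#'
#' @param n_maps Number of texture maps (default 51).
#' @return Integer vector `p` such that `v_reversed = v[p]`.
#' @export
swap_direction <- function(n_maps = 51L) {
  sv_swap <- c(1L, 3L, 2L, 5L, 4L, 7L, 6L)  # border, then S1<->S2 per distance
  tex <- integer(n_maps * 7L * 9L)
  for (m in seq_len(n_maps)) {
    for (sv in 1:7) {
      src <- ((m - 1L) * 7L + (sv_swap[sv] - 1L)) * 9L + 1:9
      dst <- ((m - 1L) * 7L + (sv - 1L)) * 9L + 1:9
      tex[dst] <- src
    }
  }
  base <- n_maps * 63L
  shape <- base + c(1L, 3L, 2L, 4L, 5L, 6L, 7L, 8L, 9L, 11L, 10L)
  c(tex, shape)
}

#' Assemble the two directed feature vectors of an interface
#'
#' The forward vector treats segment S1 (the smaller id of the canonical
#' pair) as the presynaptic candidate; the reverse vector is the same
#' scalars under the [swap_direction()] permutation.
#'
#' @param texture Length-3213 texture feature vector.
#' @param shape Length-11 shape feature vector.
#' @return List with `forward` and `reverse` numeric vectors (length 3224).
#' @export
assemble_directed_vectors <- function(texture, shape) {
  fwd <- c(unname(texture), unname(shape))
  list(forward = fwd, reverse = fwd[swap_direction(length(texture) / 63L)])
}

#' Directed feature matrix for a set of interfaces
#'
#' Runs subvolume construction, texture pooling and shape features for each
#' interface and stacks both directed vectors.
#'
#' @param maps A `texture_maps` object.
#' @param seg The [seg_volume()] the interfaces came from.
#' @param interfaces Tibble from [extract_interfaces()].
#' @param distances_nm Shell distances (default `c(40, 80, 160)`).
#' @return List with `X` (matrix, `2 * nrow(interfaces)` rows by 3224
#'   columns) and `info` (tibble with `row`, `interface_id`, `direction`;
#'   direction `"fwd"` means segment `id1` is the presynaptic candidate).
#' @export
interface_features <- function(maps, seg, interfaces,
                               distances_nm = c(40, 80, 160)) {
  n <- nrow(interfaces)
  X <- matrix(0, nrow = 2L * n, ncol = length(maps) * 63L + 11L)
  info <- tibble::tibble(
    row = seq_len(2L * n),
    interface_id = rep(interfaces$id, each = 2L),
    direction = rep(c("fwd", "rev"), n))
  for (i in seq_len(n)) {
    sv <- compute_subvolumes(seg, interfaces$border[[i]],
                             interfaces$id1[i], interfaces$id2[i],
                             distances_nm)
    dv <- assemble_directed_vectors(texture_features(maps, sv),
                                    shape_features(sv))
    X[2L * i - 1L, ] <- dv$forward
    X[2L * i, ] <- dv$reverse
  }
  list(X = X, info = info)
}

#' Lattice points inside the convex hull of a voxel cloud
#'
#' Counts integer lattice points inside or on the convex hull of the given
#' voxel center coordinates. Clouds of affine rank below 3 fall back to
#' their own distinct voxel count.
#'
#' @param coords Numeric matrix (n x 3) of voxel coordinates.
#' @return Lattice point count.
#' @export
hull_voxel_count <- function(coords) {
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  .hull_lattice_count_cpp(coords)
}
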