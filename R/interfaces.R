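# Interface extraction: collect boundary voxels (label 0) whose
# 26-neighborhood contains a given pair of segment ids, split each pair's
# voxel set into 26-connected components, and discard small components.

coords_from_index <- function(idx, dims) {
  idx0 <- idx - 1L
  x <- idx0 %% dims[1]
  y <- (idx0 %/% dims[1]) %% dims[2]
  z <- idx0 %/% (dims[1] * dims[2])
  cbind(x + 1L, y + 1L, z + 1L)
}

index_from_coords <- function(xyz, dims) {
  (xyz[, 1] - 1L) + dims[1] * ((xyz[, 2] - 1L) + dims[2] * (xyz[, 3] - 1L)) + 1L
}

offsets26 <- function() {
  o <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  o[rowSums(abs(o)) > 0, , drop = FALSE]
}

#' Extract neurite-neurite interfaces from a segmentation
#'
#' Boundary voxels (label 0) are assigned to every unordered pair of segment
#' ids present in their 26-neighborhood. Each pair's voxel set is split into
#' 26-connected components; every component is a candidate interface.
#' Components of `min_border_voxels - 1` voxels or fewer are discarded
#' (reference processing discarded components of 150 voxels or less).
#'
#' @param seg A [seg_volume()].
#' @param min_border_voxels Minimum component size kept (default 151).
#' @return Tibble with one interface per row: `id`, canonical segment pair
#'   `id1 < id2`, `n_border`, centroid in nm, and a list-column `border` of
#'   linear voxel indices into `seg`. Volume shape and voxel size are kept
#'   as attributes.
#' @export
extract_interfaces <- function(seg, min_border_voxels = 151L) {
  dims <- dim(seg)
  lab <- as.integer(seg)
  if (any(lab < 0)) stop("negative segment labels", call. = FALSE)
  vs <- voxel_size(seg)
  bidx <- which(lab == 0L)
  empty <- tibble::tibble(
    id = integer(), id1 = integer(), id2 = integer(), n_border = integer(),
    centroid_x_nm = double(), centroid_y_nm = double(), centroid_z_nm = double(),
    border = list())
  attr(empty, "volume_shape") <- dims
  attr(empty, "voxel_size_nm") <- vs
  if (length(bidx) == 0) {
    warning("segmentation has no boundary (0) voxels; no interfaces")
    return(empty)
  }
  bco <- coords_from_index(bidx, dims)
  offs <- offsets26()
  # long table of (boundary voxel, neighboring segment label)
  vox <- integer(0); nb <- integer(0)
  for (k in seq_len(nrow(offs))) {
    nx <- bco[, 1] + offs[k, 1]; ny <- bco[, 2] + offs[k, 2]; nz <- bco[, 3] + offs[k, 3]
    ok <- nx >= 1 & nx <= dims[1] & ny >= 1 & ny <= dims[2] & nz >= 1 & nz <= dims[3]
    if (!any(ok)) next
    nlab <- lab[index_from_coords(cbind(nx[ok], ny[ok], nz[ok]), dims)]
    pos <- nlab > 0L
    vox <- c(vox, bidx[ok][pos])
    nb <- c(nb, nlab[pos])
  }
  if (length(vox) == 0) return(empty)
  long <- dplyr::distinct(tibble::tibble(vox = vox, lab = nb))
  pairs <- dplyr::inner_join(long, long, by = "vox",
                             relationship = "many-to-many")
  pairs <- dplyr::filter(pairs, .data$lab.x < .data$lab.y)
  if (nrow(pairs) == 0) return(empty)
  pair_groups <- dplyr::group_by(pairs, .data$lab.x, .data$lab.y)
  keys <- dplyr::group_keys(pair_groups)
  vox_sets <- dplyr::group_split(pair_groups)
  out <- vector("list", length(vox_sets))
  for (g in seq_along(vox_sets)) {
    vset <- sort(vox_sets[[g]]$vox)
    comp <- connected_components_26(vset, dims)
    sizes <- tabulate(comp)
    keep <- which(sizes >= min_border_voxels)
    if (length(keep) == 0) next
    out[[g]] <- lapply(keep, function(cc) {
      bv <- vset[comp == cc]
      co <- coords_from_index(bv, dims)
      list(id1 = keys$lab.x[g], id2 = keys$lab.y[g], border = bv,
           centroid = colMeans((co - 0.5) * rep(vs, each = nrow(co))))
    })
  }
  recs <- purrr::flatten(purrr::compact(out))
  if (length(recs) == 0) return(empty)
  res <- tibble::tibble(
    id = seq_along(recs),
    id1 = purrr::map_int(recs, ~ as.integer(.x$id1)),
    id2 = purrr::map_int(recs, ~ as.integer(.x$id2)),
    n_border = purrr::map_int(recs, ~ length(.x$border)),
    centroid_x_nm = purrr::map_dbl(recs, ~ .x$centroid[1]),
    centroid_y_nm = purrr::map_dbl(recs, ~ .x$centroid[2]),
    centroid_z_nm = purrr::map_dbl(recs, ~ .x$centroid[3]),
    border = purrr::map(recs, "border"))
  attr(res, "volume_shape") <- dims
  attr(res, "voxel_size_nm") <- vs
  res
}

# 26-connected components of a sorted set of linear voxel indices.
connected_components_26 <- function(vset, dims) {
  n <- length(vset)
  if (n == 1) return(1L)
  co <- coords_from_index(vset, dims)
  offs <- offsets26()
  offs <- offs[seq_len(13), , drop = FALSE]  # half the neighborhood suffices
  from <- integer(0); to <- integer(0)
  for (k in seq_len(nrow(offs))) {
    nx <- co[, 1] + offs[k, 1]; ny <- co[, 2] + offs[k, 2]; nz <- co[, 3] + offs[k, 3]
    ok <- nx >= 1 & nx <= dims[1] & ny >= 1 & ny <= dims[2] & nz >= 1 & nz <= dims[3]
    nidx <- index_from_coords(cbind(nx[ok], ny[ok], nz[ok]), dims)
    hit <- match(nidx, vset)
    fnd <- !is.na(hit)
    from <- c(from, which(ok)[fnd])
    to <- c(to, hit[fnd])
  }
  g <- igraph::graph_from_edgelist(cbind(from, to), directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, n - igraph::vcount(g)))
  igraph::components(g)$membership[seq_len(n)]
}

#' Perisynaptic subvolumes of an interface
#'
#' The seven aggregation regions of an interface: the border itself plus,
#' for each adjacent segment, the voxels of that segment within 40, 80 and
#' 160 nm (anisotropic Euclidean distance between voxel centers) of any
#' border voxel.
#'
#' @param seg A [seg_volume()].
#' @param border Integer vector of linear voxel indices of the interface
#'   border (as in the `border` column of [extract_interfaces()]).
#' @param id1,id2 The canonical segment pair of the interface.
#' @param distances_nm Strictly increasing shell distances (default
#'   `c(40, 80, 160)`).
#' @return A `subvolume_set`: named list of linear-index vectors `border`,
#'   `s1_40`, `s2_40`, `s1_80`, `s2_80`, `s1_160`, `s2_160` (for the default
#'   distances), ordered border first, then distances inner to outer with S1
#'   before S2 at each distance.
#' @export
compute_subvolumes <- function(seg, border, id1, id2,
                               distances_nm = c(40, 80, 160)) {
  if (is.unsorted(distances_nm, strictly = TRUE) || any(distances_nm <= 0))
    stop("distances must be strictly increasing and positive", call. = FALSE)
  dims <- dim(seg)
  vs <- voxel_size(seg)
  seeds <- coords_from_index(as.integer(border), dims)
  dres <- .seed_distance_cpp(seeds, as.integer(dims), as.numeric(vs),
                             max(distances_nm))
  darr <- dres$dist
  lo <- dres$lo
  bd <- dim(darr)
  box_idx <- which(is.finite(darr))
  bco <- coords_from_index(box_idx, bd)
  gco <- cbind(bco[, 1] + lo[1] - 1L, bco[, 2] + lo[2] - 1L, bco[, 3] + lo[3] - 1L)
  gidx <- index_from_coords(gco, dims)
  glab <- as.integer(seg)[gidx]
  dval <- darr[box_idx]
  out <- list(border = sort(as.integer(border)))
  for (d in distances_nm) {
    for (s in c(1, 2)) {
      sid <- if (s == 1) id1 else id2
      out[[sprintf("s%d_%g", s, d)]] <- sort(gidx[glab == sid & dval <= d])
    }
  }
  # reorder: border, then per-distance S1/S2
  nm <- c("border", as.vector(t(outer(distances_nm, 1:2,
                                      function(d, s) sprintf("s%d_%g", s, d)))))
  out <- out[nm]
  structure(out, segments = c(id1, id2), distances_nm = distances_nm,
            volume_shape = dims, class = "subvolume_set")
}

#' Physical contact area of an interface
#'
#' Area from exposed voxel faces: every face between a border voxel and a
#' voxel of either adjacent segment (6-connectivity) contributes its
#' physical face area; the two per-segment totals are averaged. For a flat
#' axis-aligned interface this equals face area times face count.
#'
#' @inheritParams compute_subvolumes
#' @return Area in square micrometers.
#' @export
interface_area_um2 <- function(seg, border, id1, id2) {
  dims <- dim(seg)
  vs <- voxel_size(seg)
  face_area <- c(vs[2] * vs[3], vs[1] * vs[3], vs[1] * vs[2]) / 1e6  # um^2
  co <- coords_from_index(as.integer(border), dims)
  lab <- as.integer(seg)
  a <- c(0, 0)
  for (ax in 1:3) {
    for (sgn in c(-1L, 1L)) {
      nco <- co
      nco[, ax] <- nco[, ax] + sgn
      ok <- nco[, ax] >= 1 & nco[, ax] <= dims[ax]
      nlab <- lab[index_from_coords(nco[ok, , drop = FALSE], dims)]
      a[1] <- a[1] + sum(nlab == id1) * face_area[ax]
      a[2] <- a[2] + sum(nlab == id2) * face_area[ax]
    }
  }
  mean(a)
}

#' Interface table without voxel data
#'
#' Drops the `border` list-column so the table can be written as CSV.
#' @param interfaces Output of [extract_interfaces()].
#' @return Tibble of per-interface scalars.
#' @export
interface_table <- function(interfaces) {
  dplyr::select(interfaces, -dplyr::any_of("border"))
}
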