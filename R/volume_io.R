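# Volumes are plain 3D arrays indexed [x, y, z] (1-based, inclusive ranges
# everywhere) carrying the physical voxel size as an attribute. TIFF stacks
# store one z-slice per page; the voxel size travels in a JSON sidecar.

DEFAULT_VOXEL_SIZE_NM <- c(11.24, 11.24, 28)

#' Construct a raw intensity volume
#'
#' An 8-bit grayscale electron-microscopy volume with anisotropic physical
#' voxel size. Data are stored as a 3D array indexed `[x, y, z]`.
#'
#' @param data 3D numeric array with values in `[0, 255]`.
#' @param voxel_size_nm Length-3 positive numeric, voxel extent in nm along
#'   x, y, z. The reference acquisition is `c(11.24, 11.24, 28)`.
#' @param origin Length-3 integer, global voxel offset of the first voxel
#'   (1-based), used when the volume is a cutout of a larger dataset.
#' @return A `vox_volume` object.
#' @export
vox_volume <- function(data, voxel_size_nm = DEFAULT_VOXEL_SIZE_NM,
                       origin = c(1L, 1L, 1L)) {
  data <- as.array(data)
  if (length(dim(data)) != 3) stop("`data` must be a 3D array", call. = FALSE)
  rng <- range(data)
  if (rng[1] < 0 || rng[2] > 255)
    stop("intensities must lie in [0, 255]", call. = FALSE)
  if (length(voxel_size_nm) != 3 || any(voxel_size_nm <= 0))
    stop("`voxel_size_nm` must be 3 positive values", call. = FALSE)
  structure(data,
            voxel_size_nm = as.numeric(voxel_size_nm),
            origin = as.integer(origin),
            class = c("vox_volume", "array"))
}

#' Construct a segmentation volume
#'
#' Integer label volume co-registered with a raw volume. Label 0 marks the
#' one-voxel boundary/extracellular space between segments; labels > 0 are
#' segment ids.
#'
#' @param labels 3D array of non-negative integers.
#' @inheritParams vox_volume
#' @return A `seg_volume` object.
#' @export
seg_volume <- function(labels, voxel_size_nm = DEFAULT_VOXEL_SIZE_NM,
                       origin = c(1L, 1L, 1L)) {
  labels <- as.array(labels)
  if (length(dim(labels)) != 3) stop("`labels` must be a 3D array", call. = FALSE)
  if (any(labels < 0)) stop("segment labels must be >= 0", call. = FALSE)
  if (any(labels != round(labels))) stop("segment labels must be integers", call. = FALSE)
  storage.mode(labels) <- "integer"
  structure(labels,
            voxel_size_nm = as.numeric(voxel_size_nm),
            origin = as.integer(origin),
            class = c("seg_volume", "array"))
}

#' @export
print.vox_volume <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<vox_volume> %d x %d x %d voxels, voxel size %s nm\n",
              d[1], d[2], d[3],
              paste(signif(voxel_size(x), 4), collapse = " x ")))
  invisible(x)
}

#' @export
print.seg_volume <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<seg_volume> %d x %d x %d voxels, %d segments\n",
              d[1], d[2], d[3], length(setdiff(unique(as.vector(x)), 0L))))
  invisible(x)
}

#' Physical voxel size of a volume
#' @param x A `vox_volume` or `seg_volume`.
#' @return Length-3 numeric, nm per voxel along x, y, z.
#' @export
voxel_size <- function(x) {
  vs <- attr(x, "voxel_size_nm")
  if (is.null(vs)) DEFAULT_VOXEL_SIZE_NM else vs
}

sidecar_path <- function(path) paste0(path, ".json")

#' Write a volume as a multi-page TIFF stack
#'
#' One page per z-slice; raw volumes are written as 8-bit, segmentations as
#' 32-bit float pages (rounded back to integers on read). Voxel size and
#' origin go into a JSON sidecar next to the TIFF.
#'
#' @param vol A `vox_volume` or `seg_volume`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  d <- dim(vol)
  is_seg <- inherits(vol, "seg_volume")
  pages <- lapply(seq_len(d[3]), function(z) {
    # TIFF pages are row = y, col = x
    if (is_seg) t(vol[, , z]) / (2^32 - 1) else t(vol[, , z]) / 255
  })
  tiff::writeTIFF(pages, path, bits.per.sample = if (is_seg) 32L else 8L)
  jsonlite::write_json(
    list(voxel_size_nm = voxel_size(vol),
         origin = attr(vol, "origin") %||% c(1L, 1L, 1L),
         kind = if (is_seg) "segmentation" else "raw"),
    sidecar_path(path), auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' Read a volume from a multi-page TIFF stack
#'
#' @param path TIFF file written by [write_volume()] (or any grayscale
#'   multi-page TIFF; without a sidecar the reference voxel size is assumed,
#'   with a warning).
#' @param bounding_box Optional 2x3 integer matrix `rbind(lo, hi)` of
#'   1-based inclusive voxel ranges to cut out.
#' @return A `vox_volume` or `seg_volume` depending on the sidecar `kind`.
#' @export
read_volume <- function(path, bounding_box = NULL) {
  if (!file.exists(path))
    stop("volume_file_missing: ", path, call. = FALSE)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  d <- c(ncol(pages[[1]]), nrow(pages[[1]]), length(pages))
  meta <- if (file.exists(sidecar_path(path))) {
    jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  } else {
    warning("no voxel-size sidecar for ", path,
            "; assuming ", paste(DEFAULT_VOXEL_SIZE_NM, collapse = " x "), " nm")
    list(voxel_size_nm = DEFAULT_VOXEL_SIZE_NM, origin = c(1L, 1L, 1L),
         kind = "raw")
  }
  is_seg <- identical(meta$kind, "segmentation")
  arr <- array(0, dim = d)
  for (z in seq_len(d[3])) {
    arr[, , z] <- t(pages[[z]]) * if (is_seg) (2^32 - 1) else 255
  }
  arr <- round(arr)
  if (!is.null(bounding_box)) {
    bb <- rbind(as.integer(bounding_box[1, ]), as.integer(bounding_box[2, ]))
    if (any(bb[1, ] < 1) || any(bb[2, ] > d) || any(bb[1, ] > bb[2, ]))
      stop("bounding_box_out_of_range: box [",
           paste(bb[1, ], collapse = ","), "]-[",
           paste(bb[2, ], collapse = ","), "] vs extent ",
           paste(d, collapse = "x"), call. = FALSE)
    arr <- arr[bb[1, 1]:bb[2, 1], bb[1, 2]:bb[2, 2], bb[1, 3]:bb[2, 3],
               drop = FALSE]
  }
  if (is_seg) {
    seg_volume(arr, voxel_size_nm = meta$voxel_size_nm,
               origin = as.integer(meta$origin))
  } else {
    vox_volume(arr, voxel_size_nm = meta$voxel_size_nm,
               origin = as.integer(meta$origin))
  }
}

#' Tile a volume into overlapping cuboids
#'
#' Core regions partition the volume; each padded region is its core dilated
#' by `overlap` and clipped to the volume, so any filter whose reach does
#' not exceed the overlap can be computed per padded tile and stitched back
#' from the cores without border effects. The reference processing used
#' cuboids of 548 x 548 x 268 voxels overlapping by 72, 72 and 24 voxels.
#'
#' @param volume_shape Length-3 integer volume extent in voxels.
#' @param tile_shape Length-3 integer core tile extent.
#' @param overlap Length-3 integer padding per side, component-wise smaller
#'   than `tile_shape`.
#' @return A `tile_grid` tibble with one row per tile and list-columns
#'   `core_lo`, `core_hi`, `pad_lo`, `pad_hi` (1-based inclusive).
#' @export
make_tiles <- function(volume_shape, tile_shape,
                       overlap = c(0L, 0L, 0L)) {
  volume_shape <- as.integer(volume_shape)
  tile_shape <- as.integer(tile_shape)
  overlap <- as.integer(overlap)
  if (any(tile_shape < 1)) stop("tile shape must be positive", call. = FALSE)
  if (any(overlap < 0)) stop("overlap must be non-negative", call. = FALSE)
  if (any(overlap >= tile_shape))
    stop("overlap must be smaller than the tile shape", call. = FALSE)
  starts <- lapply(1:3, function(d) seq(1L, volume_shape[d], by = tile_shape[d]))
  grid <- expand.grid(x = starts[[1]], y = starts[[2]], z = starts[[3]],
                      KEEP.OUT.ATTRS = FALSE)
  tiles <- purrr::pmap(grid, function(x, y, z) {
    lo <- c(x, y, z)
    hi <- pmin(lo + tile_shape - 1L, volume_shape)
    list(core_lo = lo, core_hi = hi,
         pad_lo = pmax(lo - overlap, 1L),
         pad_hi = pmin(hi + overlap, volume_shape))
  })
  out <- tibble::tibble(
    tile = seq_along(tiles),
    core_lo = purrr::map(tiles, "core_lo"),
    core_hi = purrr::map(tiles, "core_hi"),
    pad_lo = purrr::map(tiles, "pad_lo"),
    pad_hi = purrr::map(tiles, "pad_hi"))
  class(out) <- c("tile_grid", class(out))
  attr(out, "volume_shape") <- volume_shape
  attr(out, "overlap") <- overlap
  out
}

crop3 <- function(arr, lo, hi) arr[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]

#' Apply a volume filter tile-by-tile and stitch the cores
#'
#' Runs `fun` on every padded tile and reassembles the outputs from the core
#' regions. For any translation-invariant filter whose reach is at most the
#' tile overlap, the result equals running `fun` on the whole volume.
#'
#' @param vol 3D array (or `vox_volume`).
#' @param tiles A `tile_grid` from [make_tiles()].
#' @param fun Function taking and returning a 3D array of identical shape.
#' @return 3D array with the stitched output.
#' @export
apply_tiled <- function(vol, tiles, fun) {
  out <- array(NA_real_, dim = dim(vol))
  for (i in seq_len(nrow(tiles))) {
    plo <- tiles$pad_lo[[i]]; phi <- tiles$pad_hi[[i]]
    clo <- tiles$core_lo[[i]]; chi <- tiles$core_hi[[i]]
    res <- fun(crop3(unclass(vol), plo, phi))
    out[clo[1]:chi[1], clo[2]:chi[2], clo[3]:chi[3]] <-
      res[(clo[1] - plo[1] + 1):(chi[1] - plo[1] + 1),
          (clo[2] - plo[2] + 1):(chi[2] - plo[2] + 1),
          (clo[3] - plo[3] + 1):(chi[3] - plo[3] + 1)]
  }
  out
}

#' Read or write interface/label/score tables as CSV
#'
#' Thin readr wrappers fixing the column contract used across the package.
#' @param x Tibble to write.
#' @param path File path.
#' @return `read_table_csv` returns a tibble; `write_table_csv` returns
#'   `path` invisibly.
#' @export
write_table_csv <- function(x, path) {
  readr::write_csv(x, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_table_csv
#' @export
read_table_csv <- function(path) {
  if (!file.exists(path)) stop("table_file_missing: ", path, call. = FALSE)
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
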