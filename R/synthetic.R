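# Seeded synthetic neuropil: a Voronoi partition of cell processes with
# one-voxel dark membranes, and planted synapses expressing the three image
# cues the classifier exploits -- a dark postsynaptic-density band at the
# contact, a high-variance vesicle speckle in the presynaptic 160 nm shell,
# and a smooth bright spine-like lumen postsynaptically. Deliberately
# minimal texture (bands + speckle + noise), not photorealism.

#' Synthetic scene configuration
#'
#' @param volume_shape Voxel extent (default 96 x 96 x 48, about 1.6 um^3
#'   at the reference voxel size -- large enough for a handful of processes
#'   and one or two synapses per scene at cortical density).
#' @param voxel_size_nm Physical voxel size (default reference 11.24 x
#'   11.24 x 28 nm).
#' @param n_processes Number of cell processes (Voronoi seeds).
#' @param synapse_density Planted synapses per cubic micrometer (default 1,
#'   the cortical neuropil value).
#' @param vesicle_speckle `c(amplitude, grain)`: darkening amplitude (gray
#'   levels) and dot radius (voxels, in-plane) of the presynaptic vesicle
#'   texture.
#' @param psd_contrast Extra darkening of the synaptic border band below
#'   the plain membrane level.
#' @param spine_lumen_level Bright uniform postsynaptic fill (gray level).
#' @param membrane_dark_level Gray level of plain membranes.
#' @param cytoplasm_level Gray level of unremarkable cytoplasm.
#' @param noise_sd Gaussian pixel noise standard deviation.
#' @param min_border_voxels Interface size filter used when picking
#'   candidate contacts (matches the extraction default).
#' @param placement_margin_nm Minimum centroid distance of planted contacts
#'   from the volume faces (default 160 nm, the largest shell), keeping
#'   planted subvolumes complete.
#' @param seed RNG seed; every random choice in the scene derives from it.
#' @return A `scene_config` list.
#' @export
scene_config <- function(volume_shape = c(96L, 96L, 48L),
                         voxel_size_nm = DEFAULT_VOXEL_SIZE_NM,
                         n_processes = 9L,
                         synapse_density = 1.0,
                         vesicle_speckle = c(amplitude = 90, grain = 2),
                         psd_contrast = 60,
                         spine_lumen_level = 190,
                         membrane_dark_level = 70,
                         cytoplasm_level = 150,
                         noise_sd = 6,
                         min_border_voxels = 151L,
                         placement_margin_nm = 160,
                         seed = 0L) {
  stopifnot(synapse_density >= 0, n_processes >= 2,
            all(c(spine_lumen_level, membrane_dark_level,
                  cytoplasm_level) >= 0),
            all(c(spine_lumen_level, membrane_dark_level,
                  cytoplasm_level) <= 255))
  structure(as.list(environment()), class = "scene_config")
}

ball_offsets <- function(r) {
  g <- as.matrix(expand.grid(dx = -r:r, dy = -r:r,
                             dz = -ceiling(r / 2):ceiling(r / 2)))
  g[g[, 1]^2 + g[, 2]^2 + (2 * g[, 3])^2 <= r^2, , drop = FALSE]
}

#' Generate a synthetic neuropil scene
#'
#' Space is partitioned into `n_processes` convex-ish processes by nearest
#' anisotropic distance to seeded points, with a one-voxel 0-label boundary
#' wherever the forward (+x/+y/+z) neighbor belongs to a different process.
#' The planted synapse count is Poisson with mean
#' `synapse_density * volume`; synapses are placed on distinct interfaces
#' away from the volume margin, with a random presynaptic side. Output is
#' fully reproducible from `config$seed`.
#'
#' @param config A [scene_config()].
#' @return List with `raw` ([vox_volume()]), `seg` ([seg_volume()]),
#'   `ground_truth` (tibble: `synapse_id`, `pre_id`, `post_id`,
#'   `direction` relative to the canonical pair, list-column `border`), and
#'   `interfaces` (the extraction the placement used).
#' @export
generate_scene <- function(config = scene_config()) {
  withr::with_seed(config$seed, generate_scene_impl(config))
}

generate_scene_impl <- function(config) {
  dims <- as.integer(config$volume_shape)
  vs <- config$voxel_size_nm
  n <- prod(dims)

  # Voronoi partition in physical coordinates
  pts <- cbind(runif(config$n_processes, 1, dims[1]) * vs[1],
               runif(config$n_processes, 1, dims[2]) * vs[2],
               runif(config$n_processes, 1, dims[3]) * vs[3])
  cx <- (seq_len(dims[1]) - 0.5) * vs[1]
  cy <- (seq_len(dims[2]) - 0.5) * vs[2]
  cz <- (seq_len(dims[3]) - 0.5) * vs[3]
  best <- rep(Inf, n); lab <- integer(n)
  gx <- rep(cx, times = dims[2] * dims[3])
  gy <- rep(rep(cy, each = dims[1]), times = dims[3])
  gz <- rep(cz, each = dims[1] * dims[2])
  for (p in seq_len(config$n_processes)) {
    d2 <- (gx - pts[p, 1])^2 + (gy - pts[p, 2])^2 + (gz - pts[p, 3])^2
    upd <- d2 < best
    best[upd] <- d2[upd]
    lab[upd] <- p
  }
  lab <- array(lab, dim = dims)

  # one-voxel boundary where a forward neighbor differs
  boundary <- array(FALSE, dim = dims)
  boundary[-dims[1], , ] <- boundary[-dims[1], , ] | (lab[-dims[1], , ] != lab[-1, , ])
  boundary[, -dims[2], ] <- boundary[, -dims[2], ] | (lab[, -dims[2], ] != lab[, -1, ])
  boundary[, , -dims[3]] <- boundary[, , -dims[3]] | (lab[, , -dims[3]] != lab[, , -1])
  seg_arr <- lab
  seg_arr[boundary] <- 0L
  seg <- seg_volume(seg_arr, voxel_size_nm = vs)

  interfaces <- extract_interfaces(seg, config$min_border_voxels)

  # candidate contacts: fully inside the 160 nm evaluation margin
  eligible <- exclude_margin(interfaces, config$placement_margin_nm)
  vol_um3 <- prod(dims * vs) / 1e9
  n_syn <- rpois(1, config$synapse_density * vol_um3)
  if (n_syn > nrow(eligible)) {
    warning("synapse density asks for ", n_syn, " contacts but only ",
            nrow(eligible), " candidates exist; placing ", nrow(eligible))
    n_syn <- nrow(eligible)
  }
  chosen <- if (n_syn > 0) sort(sample(nrow(eligible), n_syn)) else integer(0)

  # ground-truth voxel sets exclude junction voxels shared between
  # interfaces of different segment pairs, as a human cleft annotation
  # would; the any-overlap labeling rule then marks exactly the planted
  # interface as synaptic
  all_border <- unlist(interfaces$border)
  shared <- unique(all_border[duplicated(all_border)])

  # paint raw intensities
  raw <- array(config$cytoplasm_level, dim = dims)
  raw[seg_arr == 0L] <- config$membrane_dark_level
  amp <- config$vesicle_speckle[[1]]
  grain <- max(1L, as.integer(config$vesicle_speckle[[2]]))
  dots <- ball_offsets(grain)
  gt_rows <- vector("list", n_syn)
  for (k in seq_along(chosen)) {
    iface <- eligible[chosen[k], ]
    sv <- compute_subvolumes(seg, iface$border[[1]], iface$id1, iface$id2)
    fwd <- runif(1) < 0.5
    pre_sv <- if (fwd) sv$s1_160 else sv$s2_160
    post_sv <- if (fwd) sv$s2_160 else sv$s1_160
    post_near <- if (fwd) sv$s2_40 else sv$s1_40
    # bright smooth postsynaptic lumen
    raw[post_sv] <- config$spine_lumen_level
    # presynaptic vesicle speckle: dark dots covering ~25% of the shell
    n_dots <- ceiling(0.25 * length(pre_sv) / nrow(dots))
    if (n_dots > 0 && length(pre_sv) > 0) {
      centers <- coords_from_index(sample(pre_sv, n_dots, replace = TRUE), dims)
      for (d in seq_len(nrow(dots))) {
        pos <- cbind(centers[, 1] + dots[d, 1], centers[, 2] + dots[d, 2],
                     centers[, 3] + dots[d, 3])
        ok <- pos[, 1] >= 1 & pos[, 1] <= dims[1] &
          pos[, 2] >= 1 & pos[, 2] <= dims[2] &
          pos[, 3] >= 1 & pos[, 3] <= dims[3]
        idx <- index_from_coords(pos[ok, , drop = FALSE], dims)
        idx <- idx[seg_arr[idx] == (if (fwd) iface$id1 else iface$id2)]
        raw[idx] <- config$cytoplasm_level - amp
      }
    }
    # dark PSD band: the border plus the postsynaptic 40 nm shell
    raw[iface$border[[1]]] <- max(0, config$membrane_dark_level - config$psd_contrast)
    raw[post_near] <- max(0, config$membrane_dark_level - config$psd_contrast)
    gt_border <- setdiff(iface$border[[1]], shared)
    if (length(gt_border) == 0) gt_border <- iface$border[[1]]
    gt_rows[[k]] <- tibble::tibble(
      synapse_id = k,
      pre_id = if (fwd) iface$id1 else iface$id2,
      post_id = if (fwd) iface$id2 else iface$id1,
      direction = if (fwd) "fwd" else "rev",
      border = list(gt_border))
  }
  raw <- raw + rnorm(n, 0, config$noise_sd)
  raw <- round(pmin(pmax(raw, 0), 255))

  gt <- if (n_syn > 0) dplyr::bind_rows(gt_rows) else
    tibble::tibble(synapse_id = integer(), pre_id = integer(),
                   post_id = integer(), direction = character(),
                   border = list())
  list(raw = vox_volume(raw, voxel_size_nm = vs),
       seg = seg,
       ground_truth = gt,
       interfaces = interfaces)
}

#' Interface annotations from planted ground truth
#'
#' Marks an interface synaptic (with its true direction) when its border
#' voxels overlap a planted synapse's voxel set. A planted synapse matching
#' no interface indicates a generation bug and fails loudly.
#'
#' @param gt Ground-truth tibble from [generate_scene()].
#' @param interfaces Tibble from [extract_interfaces()] on the same scene.
#' @return Annotation tibble (`interface_id`, `synaptic`, `direction`)
#'   suitable for [build_label_variant()].
#' @export
label_table <- function(gt, interfaces) {
  ann <- tibble::tibble(interface_id = interfaces$id,
                        synaptic = FALSE,
                        direction = NA_character_)
  matched <- logical(nrow(gt))
  for (k in seq_len(nrow(gt))) {
    hit <- which(purrr::map_lgl(interfaces$border,
                                ~ any(.x %in% gt$border[[k]])))
    if (length(hit) == 0)
      stop("planted synapse ", gt$synapse_id[k],
           " overlaps no extracted interface (generation bug)", call. = FALSE)
    matched[k] <- TRUE
    for (h in hit) {
      ann$synaptic[h] <- TRUE
      ann$direction[h] <-
        if (gt$pre_id[k] == interfaces$id1[h]) "fwd" else "rev"
    }
  }
  ann
}
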