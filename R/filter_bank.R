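# Anisotropy-aware 3D texture filter bank. All Gaussian scales are given in
# voxels as multiples of the base scale s = base_nm / voxel_size_nm, so that
# one multiple of s corresponds to the same physical scale (default 12 nm)
# along every axis. Kernels are evaluated on the integer grid
# [-f, f]^3 with per-axis half-size f = round(sigma/s * ceil(2*s)) and the
# plain Gaussian is normalized by its sum; derivative kernels are the
# normalized Gaussian times the analytic polynomial factors and are not
# re-normalized.

#' Base Gaussian scale in voxels
#'
#' @param voxel_size_nm Physical voxel size (nm).
#' @param base_nm Physical base scale; 12 nm reproduces the reference setup
#'   (s = 12/11.24 in x,y and 12/28 in z).
#' @return Length-3 numeric scale `s` in voxels.
#' @export
base_scale <- function(voxel_size_nm = DEFAULT_VOXEL_SIZE_NM, base_nm = 12) {
  base_nm / voxel_size_nm
}

round_half_up <- function(x) floor(x + 0.5)

# per-axis kernel half-size for a scale multiplier m (sigma = m * s)
half_size_mult <- function(m, s) as.integer(round_half_up(m * ceiling(2 * s)))

gauss1d <- function(sigma, f, order = 0L) {
  x <- seq(-f, f)
  g <- exp(-x^2 / (2 * sigma^2))
  g <- g / sum(g)  # per-axis normalization; the 3D product is sum-normalized
  switch(order + 1L,
         g,
         g * (-x / sigma^2),
         g * (x^2 / sigma^4 - 1 / sigma^2))
}

#' Sum-normalized 3D Gaussian kernel
#'
#' The unnormalized Gaussian density evaluated at integer offsets
#' `[-f, f]^3` and divided by its sum, optionally multiplied by the analytic
#' derivative factors for partial derivatives up to total order 2.
#'
#' @param sigma Length-3 standard deviation in voxels.
#' @param filter_size Length-3 integer half-size `f`.
#' @param orders Length-3 non-negative integer derivative multi-index with
#'   sum at most 2 (e.g. `c(1, 0, 0)` for d/dx).
#' @return 3D array of size `2 * filter_size + 1`.
#' @export
gaussian_kernel <- function(sigma, filter_size, orders = c(0L, 0L, 0L)) {
  if (any(sigma <= 0)) stop("sigma must be positive", call. = FALSE)
  if (any(filter_size < 0)) stop("filter size must be >= 0", call. = FALSE)
  if (any(orders < 0) || sum(orders) > 2)
    stop("unsupported derivative order", call. = FALSE)
  ks <- lapply(1:3, function(d) gauss1d(sigma[d], filter_size[d], orders[d]))
  k <- outer(outer(ks[[1]], ks[[2]]), ks[[3]])
  array(k, dim = 2 * filter_size + 1)
}

conv_sep <- function(vol, kx, ky, kz) {
  v <- as.double(vol)
  dim(v) <- dim(vol)
  v <- .conv_axis_cpp(v, kx, 0L)
  v <- .conv_axis_cpp(v, ky, 1L)
  .conv_axis_cpp(v, kz, 2L)
}

#' Gaussian smoothing, derivatives, and derived filters
#'
#' `gaussian_smooth` convolves with the sum-normalized Gaussian;
#' `gaussian_derivative` with the analytic Gaussian-derivative kernel of the
#' given multi-index (total order at most 2). Boundary handling is
#' replicate-padding throughout.
#'
#' @param vol 3D array (or `vox_volume`).
#' @param sigma Length-3 standard deviation in voxels.
#' @param filter_size Length-3 half-size; when `NULL`, derived from `sigma`
#'   and the base scale `s` via the size rule `round(sigma/s * ceil(2*s))`.
#' @param s Base scale in voxels (used only to derive `filter_size`).
#' @param orders Derivative multi-index, see [gaussian_kernel()].
#' @return 3D array of filter responses.
#' @export
gaussian_smooth <- function(vol, sigma, filter_size = NULL,
                            s = base_scale()) {
  f <- filter_size %||% half_size_mult(max(sigma / s), s)
  conv_sep(vol, gauss1d(sigma[1], f[1]), gauss1d(sigma[2], f[2]),
           gauss1d(sigma[3], f[3]))
}

#' @rdname gaussian_smooth
#' @export
gaussian_derivative <- function(vol, sigma, orders, filter_size = NULL,
                                s = base_scale()) {
  if (any(orders < 0) || sum(orders) > 2)
    stop("unsupported derivative order", call. = FALSE)
  f <- filter_size %||% half_size_mult(max(sigma / s), s)
  conv_sep(vol,
           gauss1d(sigma[1], f[1], orders[1]),
           gauss1d(sigma[2], f[2], orders[2]),
           gauss1d(sigma[3], f[3], orders[3]))
}

#' @rdname gaussian_smooth
#' @param k Scale factor of the second (subtracted) Gaussian.
#' @export
difference_of_gaussians <- function(vol, sigma, k, s = base_scale()) {
  if (k <= 0) stop("k must be positive", call. = FALSE)
  gaussian_smooth(vol, sigma, s = s) -
    gaussian_smooth(vol, k * sigma, s = s)
}

#' @rdname gaussian_smooth
#' @export
gradient_magnitude <- function(vol, sigma, s = base_scale()) {
  gx <- gaussian_derivative(vol, sigma, c(1, 0, 0), s = s)
  gy <- gaussian_derivative(vol, sigma, c(0, 1, 0), s = s)
  gz <- gaussian_derivative(vol, sigma, c(0, 0, 1), s = s)
  sqrt(gx^2 + gy^2 + gz^2)
}

#' @rdname gaussian_smooth
#' @export
laplacian_of_gaussian <- function(vol, sigma, s = base_scale()) {
  gaussian_derivative(vol, sigma, c(2, 0, 0), s = s) +
    gaussian_derivative(vol, sigma, c(0, 2, 0), s = s) +
    gaussian_derivative(vol, sigma, c(0, 0, 2), s = s)
}

sorted_tensor_eigs <- function(xx, xy, xz, yy, yz, zz) {
  .tensor_eigenvalues_cpp(xx, xy, xz, yy, yz, zz)
}

#' Structure tensor and Hessian eigenvalue maps
#'
#' The structure tensor is the outer product of first-order Gaussian
#' derivatives (scale `sigma_d`) smoothed component-wise by a Gaussian
#' window (scale `sigma_w`); the Hessian is the matrix of second-order
#' Gaussian derivatives at scale `sigma`. Per-voxel eigenvalues are
#' returned sorted by increasing absolute value (ties by signed value).
#'
#' @inheritParams gaussian_smooth
#' @param sigma_d,sigma_w Derivative and window scales in voxels.
#' @return List of three 3D arrays (eigenvalue maps).
#' @export
structure_tensor_eigenvalues <- function(vol, sigma_d, sigma_w,
                                         s = base_scale()) {
  gx <- gaussian_derivative(vol, sigma_d, c(1, 0, 0), s = s)
  gy <- gaussian_derivative(vol, sigma_d, c(0, 1, 0), s = s)
  gz <- gaussian_derivative(vol, sigma_d, c(0, 0, 1), s = s)
  sm <- function(a) gaussian_smooth(a, sigma_w, s = s)
  sorted_tensor_eigs(sm(gx * gx), sm(gx * gy), sm(gx * gz),
                     sm(gy * gy), sm(gy * gz), sm(gz * gz))
}

#' @rdname structure_tensor_eigenvalues
#' @export
hessian_eigenvalues <- function(vol, sigma, s = base_scale()) {
  d2 <- function(ox, oy, oz) gaussian_derivative(vol, sigma, c(ox, oy, oz), s = s)
  sorted_tensor_eigs(d2(2, 0, 0), d2(1, 1, 0), d2(1, 0, 1),
                     d2(0, 2, 0), d2(0, 1, 1), d2(0, 0, 2))
}

box_sum <- function(vol, side) {
  ones <- rep(1, side)
  v <- as.double(vol); dim(v) <- dim(vol)
  v <- .conv_axis_cpp(v, ones, 0L)
  v <- .conv_axis_cpp(v, ones, 1L)
  .conv_axis_cpp(v, ones, 2L)
}

#' Local intensity statistics filters
#'
#' `local_stddev` is the unbiased sample standard deviation over a cubic
#' neighborhood; `intensity_variance` is the unnormalized contrast statistic
#' `sum(I^2) - (sum(I))^2` over the neighborhood, kept exactly in this form
#' (it is not divided by the neighborhood size); `local_entropy` is the
#' Shannon entropy (bits) of the 8-bit intensity histogram in the
#' neighborhood; `sphere_average` is the mean intensity over an anisotropy
#' corrected spherical neighborhood `x^2 + y^2 + (2z)^2 <= r^2`.
#'
#' @param vol 3D array; `local_entropy` requires integer values in 0..255.
#' @param side Cubic neighborhood edge length in voxels (odd; default 5).
#' @param r Sphere radius in voxels.
#' @return 3D array of filter responses.
#' @export
local_stddev <- function(vol, side = 5L) {
  n <- side^3
  s1 <- box_sum(vol, side)
  s2 <- box_sum(unclass(vol)^2, side)
  v <- (s2 - s1^2 / n) / (n - 1)
  sqrt(pmax(v, 0))
}

#' @rdname local_stddev
#' @export
intensity_variance <- function(vol, side = 3L) {
  s1 <- box_sum(vol, side)
  s2 <- box_sum(unclass(vol)^2, side)
  s2 - s1^2
}

#' @rdname local_stddev
#' @export
local_entropy <- function(vol, side = 5L) {
  v <- unclass(vol)
  if (any(v != round(v)) || any(v < 0) || any(v > 255))
    stop("local_entropy requires integer intensities in 0..255", call. = FALSE)
  iv <- as.integer(v)
  dim(iv) <- dim(vol)
  .local_entropy_cpp(iv, as.integer((side - 1) / 2))
}

sphere_offsets <- function(r) {
  g <- as.matrix(expand.grid(dx = -r:r, dy = -r:r, dz = -r:r))
  g[g[, 1]^2 + g[, 2]^2 + (2 * g[, 3])^2 <= r^2, , drop = FALSE]
}

#' @rdname local_stddev
#' @export
sphere_average <- function(vol, r) {
  v <- as.double(vol); dim(v) <- dim(vol)
  .offset_mean_cpp(v, sphere_offsets(r))
}

#' Filter bank configuration
#'
#' Families and parameter instances of the 51-map texture bank (raw data is
#' instance 1): structure-tensor eigenvalues at five (window, derivative)
#' scale pairs, Hessian eigenvalues at four scales, Gaussian smoothing at
#' three, difference of Gaussians at five (scale, k) pairs, Laplacian of
#' Gaussian at four scales, gradient magnitude at five, local standard
#' deviation (5^3), intensity/variance (3^3 and 5^3), local entropy (5^3)
#' and sphere averages at radii 3 and 6 voxels.
#'
#' @inheritParams base_scale
#' @return A `filter_bank_config` list with the base scale `s`, per-family
#'   parameter lists, and the canonical 51-row manifest.
#' @export
filter_bank_config <- function(voxel_size_nm = DEFAULT_VOXEL_SIZE_NM,
                               base_nm = 12) {
  s <- base_scale(voxel_size_nm, base_nm)
  cfg <- list(
    s = s,
    voxel_size_nm = voxel_size_nm,
    st_pairs = list(c(w = 1, d = 1), c(w = 1, d = 2), c(w = 2, d = 1),
                    c(w = 2, d = 2), c(w = 3, d = 3)),
    hessian_mult = 1:4,
    smooth_mult = 1:3,
    dog_pairs = list(c(m = 1, k = 1.5), c(m = 1, k = 2), c(m = 2, k = 1.5),
                     c(m = 2, k = 2), c(m = 3, k = 1.5)),
    log_mult = 1:4,
    grad_mult = 1:5,
    std_side = 5L,
    intvar_sides = c(3L, 5L),
    entropy_side = 5L,
    sphere_radii = c(3L, 6L))
  cfg$manifest <- filter_bank_manifest(cfg)
  class(cfg) <- "filter_bank_config"
  cfg
}

filter_bank_manifest <- function(cfg) {
  rows <- list(tibble::tibble(family = "raw", params = "", eig_rank = NA_integer_))
  for (p in cfg$st_pairs)
    rows <- c(rows, list(tibble::tibble(
      family = "structure_tensor",
      params = sprintf("sw=%gs,sd=%gs", p["w"], p["d"]),
      eig_rank = 1:3)))
  for (m in cfg$hessian_mult)
    rows <- c(rows, list(tibble::tibble(
      family = "hessian", params = sprintf("s=%gs", m), eig_rank = 1:3)))
  rows <- c(rows, list(
    tibble::tibble(family = "smoothing",
                   params = sprintf("s=%gs", cfg$smooth_mult),
                   eig_rank = NA_integer_),
    tibble::tibble(family = "dog",
                   params = purrr::map_chr(cfg$dog_pairs,
                                           ~ sprintf("s=%gs,k=%g", .x["m"], .x["k"])),
                   eig_rank = NA_integer_),
    tibble::tibble(family = "log", params = sprintf("s=%gs", cfg$log_mult),
                   eig_rank = NA_integer_),
    tibble::tibble(family = "gradient", params = sprintf("s=%gs", cfg$grad_mult),
                   eig_rank = NA_integer_),
    tibble::tibble(family = "local_std", params = sprintf("U=%d", cfg$std_side),
                   eig_rank = NA_integer_),
    tibble::tibble(family = "intvar", params = sprintf("U=%d", cfg$intvar_sides),
                   eig_rank = NA_integer_),
    tibble::tibble(family = "entropy", params = sprintf("U=%d", cfg$entropy_side),
                   eig_rank = NA_integer_),
    tibble::tibble(family = "sphere", params = sprintf("r=%d", cfg$sphere_radii),
                   eig_rank = NA_integer_)))
  out <- dplyr::bind_rows(rows)
  out$index <- seq_len(nrow(out))
  dplyr::relocate(out, "index")
}

#' Maximal filter reach of a configuration
#'
#' Per-axis half-size of the widest effective kernel in the bank (the
#' structure tensor reaches derivative plus window half-sizes). Tiles padded
#' by at least this much produce border-free core outputs.
#'
#' @param cfg A [filter_bank_config()].
#' @return Length-3 integer voxel reach.
#' @export
filter_reach <- function(cfg) {
  s <- cfg$s
  h <- function(m) half_size_mult(m, s)
  reach <- h(max(cfg$smooth_mult))
  for (p in cfg$st_pairs) reach <- pmax(reach, h(p[["d"]]) + h(p[["w"]]))
  reach <- pmax(reach, h(max(cfg$hessian_mult)), h(max(cfg$log_mult)),
                h(max(cfg$grad_mult)))
  for (p in cfg$dog_pairs) reach <- pmax(reach, h(p[["m"]] * p[["k"]]))
  reach <- pmax(reach, (max(cfg$std_side, cfg$intvar_sides, cfg$entropy_side) - 1) / 2)
  reach <- pmax(reach, c(max(cfg$sphere_radii), max(cfg$sphere_radii),
                         ceiling(max(cfg$sphere_radii) / 2)))
  as.integer(reach)
}

#' Compute the full texture filter bank
#'
#' Produces the 51 feature maps in canonical order (see
#' [filter_bank_config()]'s manifest): raw data, structure-tensor
#' eigenvalues, Hessian eigenvalues, smoothing, difference of Gaussians,
#' Laplacian of Gaussian, gradient magnitude, local standard deviation,
#' intensity/variance, local entropy, sphere averages.
#'
#' @param vol A [vox_volume()] (8-bit intensities).
#' @param cfg A [filter_bank_config()]; defaults to the volume's voxel size.
#' @return A `texture_maps` object: list of 51 aligned 3D arrays with the
#'   manifest tibble as attribute.
#' @export
compute_filter_bank <- function(vol, cfg = filter_bank_config(voxel_size(vol))) {
  s <- cfg$s
  v <- as.double(vol); dim(v) <- dim(vol)
  maps <- vector("list", nrow(cfg$manifest))
  i <- 0L
  add <- function(m) { i <<- i + 1L; maps[[i]] <<- m }

  add(v)  # raw

  # first derivatives, cached per scale multiplier
  deriv_mult <- sort(unique(c(purrr::map_dbl(cfg$st_pairs, "d"), cfg$grad_mult)))
  d1 <- lapply(setNames(deriv_mult, deriv_mult), function(m) {
    list(x = gaussian_derivative(v, m * s, c(1, 0, 0), s = s),
         y = gaussian_derivative(v, m * s, c(0, 1, 0), s = s),
         z = gaussian_derivative(v, m * s, c(0, 0, 1), s = s))
  })

  for (p in cfg$st_pairs) {
    g <- d1[[as.character(p[["d"]])]]
    sw <- p[["w"]] * s
    sm <- function(a) gaussian_smooth(a, sw, s = s)
    ev <- sorted_tensor_eigs(sm(g$x * g$x), sm(g$x * g$y), sm(g$x * g$z),
                             sm(g$y * g$y), sm(g$y * g$z), sm(g$z * g$z))
    for (e in ev) add(e)
  }

  log_cache <- list()
  for (m in cfg$hessian_mult) {
    d2 <- function(ox, oy, oz) gaussian_derivative(v, m * s, c(ox, oy, oz), s = s)
    xx <- d2(2, 0, 0); yy <- d2(0, 2, 0); zz <- d2(0, 0, 2)
    ev <- sorted_tensor_eigs(xx, d2(1, 1, 0), d2(1, 0, 1), yy, d2(0, 1, 1), zz)
    for (e in ev) add(e)
    log_cache[[as.character(m)]] <- xx + yy + zz
  }

  for (m in cfg$smooth_mult) add(gaussian_smooth(v, m * s, s = s))
  for (p in cfg$dog_pairs)
    add(difference_of_gaussians(v, p[["m"]] * s, p[["k"]], s = s))
  for (m in cfg$log_mult) {
    cached <- log_cache[[as.character(m)]]
    add(cached %||% laplacian_of_gaussian(v, m * s, s = s))
  }
  for (m in cfg$grad_mult) {
    g <- d1[[as.character(m)]]
    add(sqrt(g$x^2 + g$y^2 + g$z^2))
  }
  add(local_stddev(v, cfg$std_side))
  for (u in cfg$intvar_sides) add(intensity_variance(v, u))
  add(local_entropy(round(v), cfg$entropy_side))
  for (r in cfg$sphere_radii) add(sphere_average(v, r))

  stopifnot(i == nrow(cfg$manifest))
  structure(maps, manifest = cfg$manifest, class = "texture_maps")
}

#' @export
print.texture_maps <- function(x, ...) {
  cat(sprintf("<texture_maps> %d maps of %s voxels\n", length(x),
              paste(dim(x[[1]]), collapse = " x ")))
  invisible(x)
}
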