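test_that("gaussian kernels are normalized, symmetric and DC-preserving", {
  k <- gaussian_kernel(c(1, 1, 1), c(2, 2, 2))
  expect_equal(sum(k), 1, tolerance = 1e-12)
  expect_equal(k, k[5:1, 5:1, 5:1])                     # central symmetry
  expect_equal(which.max(k), (length(k) + 1) %/% 2)     # maximum at origin
  expect_error(gaussian_kernel(c(0, 1, 1), c(2, 2, 2)), "positive")

  v <- array(100, c(10, 10, 10))
  sm <- gaussian_smooth(v, c(1, 1, 0.5), filter_size = c(3, 3, 2))
  expect_equal(as.vector(sm), rep(100, 1000), tolerance = 1e-12)
})

test_that("derivative kernels kill constants and see ramps", {
  dims <- c(12, 12, 10)
  cst <- array(7, dims)
  dx <- gaussian_derivative(cst, c(1, 1, 0.5), c(1, 0, 0), filter_size = c(3, 3, 2))
  expect_lt(max(abs(interior(dx, c(3, 3, 2)))), 1e-12)

  ramp <- array(rep(seq_len(dims[1]), times = prod(dims[2:3])), dims)
  gx <- interior(gaussian_derivative(ramp, c(1, 1, 0.5), c(1, 0, 0),
                                     filter_size = c(3, 3, 2)), c(3, 3, 2))
  gy <- interior(gaussian_derivative(ramp, c(1, 1, 0.5), c(0, 1, 0),
                                     filter_size = c(3, 3, 2)), c(3, 3, 2))
  expect_lt(max(gx) - min(gx), 1e-9)  # constant response on a ramp
  expect_gt(min(gx), 0.9)             # positive, close to unit slope
  expect_lt(max(abs(gy)), 1e-12)

  # odd symmetry of the first-derivative kernel
  k <- gaussian_kernel(c(1, 1, 1), c(2, 2, 2), orders = c(1, 0, 0))
  expect_equal(k, -k[5:1, , ])
  expect_error(gaussian_kernel(c(1, 1, 1), c(2, 2, 2), orders = c(2, 1, 0)),
               "order")
})

test_that("linear filters match dense direct convolution", {
  v <- unclass(random_vox(c(14, 13, 12), seed = 31))
  cases <- list(list(sig = c(1.2, 1.2, 0.6), f = c(3, 3, 2), ord = c(0, 0, 0)),
                list(sig = c(1.0, 1.4, 0.5), f = c(3, 3, 1), ord = c(1, 0, 0)),
                list(sig = c(1.2, 1.2, 0.6), f = c(3, 3, 2), ord = c(0, 1, 1)),
                list(sig = c(1.2, 1.2, 0.6), f = c(2, 3, 2), ord = c(0, 0, 2)))
  for (cs in cases) {
    k <- gaussian_kernel(cs$sig, cs$f, cs$ord)
    want <- interior(oracle_conv(v, k), cs$f)
    got <- interior(gaussian_derivative(v, cs$sig, cs$ord, filter_size = cs$f),
                    cs$f)
    expect_equal(got, want, tolerance = 1e-9)
  }
})

test_that("DoG, gradient magnitude and LoG behave analytically", {
  dims <- c(12, 12, 10)
  cst <- array(42, dims)
  s <- base_scale()
  expect_lt(max(abs(difference_of_gaussians(cst, 1 * s, 1.5))), 1e-10)
  expect_lt(max(abs(difference_of_gaussians(cst, 2 * s, 2))), 1e-10)
  expect_error(difference_of_gaussians(cst, s, -1), "positive")

  v <- unclass(random_vox(dims, seed = 32))
  expect_equal(difference_of_gaussians(v, 1 * s, 1), array(0, dims))

  # single bright voxel: center value is g_sigma(0) - g_{k sigma}(0)
  imp <- array(0, c(15, 15, 15)); imp[8, 8, 8] <- 1
  f1 <- half_size_mult_for_test(1); f2 <- half_size_mult_for_test(1.5)
  d <- difference_of_gaussians(imp, 1 * s, 1.5)
  k1 <- gaussian_kernel(1 * s, f1); k2 <- gaussian_kernel(1.5 * s, f2)
  expect_equal(d[8, 8, 8], k1[f1[1] + 1, f1[2] + 1, f1[3] + 1] -
                 k2[f2[1] + 1, f2[2] + 1, f2[3] + 1], tolerance = 1e-12)

  # gradient magnitude of a ramp is direction-independent in voxel units
  rampx <- array(rep(seq_len(dims[1]), times = prod(dims[2:3])), dims)
  rampy <- aperm(array(rep(seq_len(dims[2]), times = prod(dims[c(1, 3)])),
                       dims[c(2, 1, 3)]), c(2, 1, 3))
  gmx <- interior(gradient_magnitude(rampx, c(1, 1, 1), s = c(1, 1, 1)), c(3, 3, 3))
  gmy <- interior(gradient_magnitude(rampy, c(1, 1, 1), s = c(1, 1, 1)), c(3, 3, 3))
  expect_equal(gmx, gmy, tolerance = 1e-9)
  expect_lt(max(abs(gradient_magnitude(cst, s))), 1e-10)

  # gradient magnitude equals the composition of derivative maps
  gx <- gaussian_derivative(v, s, c(1, 0, 0))
  gy <- gaussian_derivative(v, s, c(0, 1, 0))
  gz <- gaussian_derivative(v, s, c(0, 0, 1))
  expect_equal(gradient_magnitude(v, s), sqrt(gx^2 + gy^2 + gz^2),
               tolerance = 1e-9)
})

test_that("structure tensor and Hessian eigenvalues match per-voxel eigen()", {
  v <- unclass(random_vox(c(12, 12, 10), seed = 33))
  s <- base_scale()
  st <- structure_tensor_eigenvalues(v, 1 * s, 1 * s)
  he <- hessian_eigenvalues(v, 2 * s)

  # oracle: rebuild the tensors from the same linear maps, then eigen()
  gx <- gaussian_derivative(v, s, c(1, 0, 0))
  gy <- gaussian_derivative(v, s, c(0, 1, 0))
  gz <- gaussian_derivative(v, s, c(0, 0, 1))
  sm <- function(a) gaussian_smooth(a, s)
  comp <- list(xx = sm(gx * gx), xy = sm(gx * gy), xz = sm(gx * gz),
               yy = sm(gy * gy), yz = sm(gy * gz), zz = sm(gz * gz))
  idx <- sample(length(v), 200)
  for (i in idx) {
    m <- matrix(c(comp$xx[i], comp$xy[i], comp$xz[i],
                  comp$xy[i], comp$yy[i], comp$yz[i],
                  comp$xz[i], comp$yz[i], comp$zz[i]), 3, 3)
    ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
    ev <- ev[order(abs(ev), ev)]
    got <- c(st[[1]][i], st[[2]][i], st[[3]][i])
    expect_equal(got, ev, tolerance = 1e-6)
    expect_true(all(got >= -1e-8 * max(abs(ev), 1)))  # PSD tensor
  }

  d2 <- function(o1, o2, o3) gaussian_derivative(v, 2 * s, c(o1, o2, o3))
  hx <- list(xx = d2(2, 0, 0), xy = d2(1, 1, 0), xz = d2(1, 0, 1),
             yy = d2(0, 2, 0), yz = d2(0, 1, 1), zz = d2(0, 0, 2))
  for (i in idx[1:100]) {
    m <- matrix(c(hx$xx[i], hx$xy[i], hx$xz[i],
                  hx$xy[i], hx$yy[i], hx$yz[i],
                  hx$xz[i], hx$yz[i], hx$zz[i]), 3, 3)
    ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
    ev <- ev[order(abs(ev), ev)]
    expect_equal(c(he[[1]][i], he[[2]][i], he[[3]][i]), ev, tolerance = 1e-6)
  }

  # trace identity: sum of Hessian eigenvalues equals the LoG map
  lg <- laplacian_of_gaussian(v, 2 * s)
  expect_equal(he[[1]] + he[[2]] + he[[3]], lg, tolerance = 1e-8)

  # constant input: all eigenvalue maps vanish
  cst <- array(9, c(10, 10, 8))
  stc <- structure_tensor_eigenvalues(cst, s, s)
  expect_lt(max(abs(interior(stc[[3]], c(4, 4, 2)))), 1e-10)
})

test_that("local entropy matches the histogram definition", {
  # constant patch: zero entropy
  cst <- array(7, c(8, 8, 8))
  expect_equal(local_entropy(cst), array(0, c(8, 8, 8)))

  # 125 distinct equiprobable values in the window: log2(125)
  v <- array(0L, c(5, 5, 5))
  v[] <- 0:124
  e <- local_entropy(v)
  expect_equal(e[3, 3, 3], log2(125), tolerance = 1e-12)

  # random volume vs. brute-force histogram at interior voxels
  rv <- unclass(random_vox(c(9, 9, 9), seed = 40))
  e <- local_entropy(rv)
  for (co in list(c(3, 3, 3), c(5, 4, 6), c(7, 7, 5))) {
    w <- rv[(co[1] - 2):(co[1] + 2), (co[2] - 2):(co[2] + 2),
            (co[3] - 2):(co[3] + 2)]
    p <- table(w) / 125
    expect_equal(e[co[1], co[2], co[3]], -sum(p * log2(p)), tolerance = 1e-12)
  }
  expect_error(local_entropy(array(0.5, c(3, 3, 3))), "integer")
})

test_that("local standard deviation and intensity/variance filters", {
  cst <- array(5, c(8, 8, 8))
  expect_lt(max(abs(local_stddev(cst))), 1e-9)

  # checkerboard of 0/2 against brute-force unbiased sd
  dims <- c(9, 9, 9)
  co <- as.matrix(expand.grid(x = 1:9, y = 1:9, z = 1:9))
  cb <- array(2 * ((co[, 1] + co[, 2] + co[, 3]) %% 2), dims)
  sdm <- local_stddev(cb)
  for (pt in list(c(4, 4, 4), c(5, 6, 4))) {
    w <- cb[(pt[1] - 2):(pt[1] + 2), (pt[2] - 2):(pt[2] + 2),
            (pt[3] - 2):(pt[3] + 2)]
    expect_equal(sdm[pt[1], pt[2], pt[3]], stats::sd(as.vector(w)),
                 tolerance = 1e-10)
  }
  # homogeneity: scaling input scales output
  rv <- unclass(random_vox(c(8, 8, 8), seed = 41))
  expect_equal(local_stddev(rv * 3), 3 * local_stddev(rv), tolerance = 1e-9)

  # int/var implements sum(I^2) - (sum I)^2 verbatim
  expect_equal(intensity_variance(array(0, dims)), array(0, dims))
  c7 <- array(7, c(9, 9, 9))
  iv <- intensity_variance(c7, side = 3L)
  expect_equal(iv[5, 5, 5], 27 * 49 * (1 - 27), tolerance = 1e-9)
  # single bright voxel against direct summation
  imp <- array(0, c(7, 7, 7)); imp[4, 4, 4] <- 9
  ivi <- intensity_variance(imp, side = 3L)
  for (pt in list(c(4, 4, 4), c(3, 4, 4), c(2, 4, 4))) {
    w <- imp[max(1, pt[1] - 1):min(7, pt[1] + 1),
             max(1, pt[2] - 1):min(7, pt[2] + 1),
             max(1, pt[3] - 1):min(7, pt[3] + 1)]
    expect_equal(ivi[pt[1], pt[2], pt[3]], sum(w^2) - sum(w)^2,
                 tolerance = 1e-9)
  }
})

test_that("sphere average uses the anisotropy-corrected lattice ball", {
  cst <- array(3, c(10, 10, 10))
  expect_equal(sphere_average(cst, 3), array(3, c(10, 10, 10)))

  # lattice count by brute force
  g <- expand.grid(x = -3:3, y = -3:3, z = -3:3)
  n3 <- sum(g$x^2 + g$y^2 + 4 * g$z^2 <= 9)
  imp <- array(0, c(11, 11, 11)); imp[6, 6, 6] <- 1
  sa <- sphere_average(imp, 3)
  expect_equal(sa[6, 6, 6], 1 / n3, tolerance = 1e-12)

  # symmetry under (x, y) swap of a symmetric input
  v <- unclass(random_vox(c(9, 9, 9), seed = 42))
  vsym <- (v + aperm(v, c(2, 1, 3))) / 2
  sa <- sphere_average(vsym, 3)
  expect_equal(sa, aperm(sa, c(2, 1, 3)), tolerance = 1e-12)
})

test_that("the full bank yields 51 deterministic maps with correct constants", {
  cfg <- filter_bank_config()
  expect_equal(nrow(cfg$manifest), 51L)
  counts <- table(cfg$manifest$family)
  expect_equal(as.integer(counts[c("raw", "structure_tensor", "hessian",
                                   "smoothing", "dog", "log", "gradient",
                                   "local_std", "intvar", "entropy", "sphere")]),
               c(1L, 15L, 12L, 3L, 5L, 4L, 5L, 1L, 2L, 1L, 2L))

  v <- random_vox(c(12, 12, 10), seed = 50)
  b1 <- compute_filter_bank(v)
  b2 <- compute_filter_bank(v)
  expect_identical(b1[], b2[])  # bit-identical reruns
  expect_length(b1, 51L)

  cst <- vox_volume(array(99, c(12, 12, 10)))
  bc <- compute_filter_bank(cst)
  man <- attr(bc, "manifest")
  # first-derivative-based maps, DoG, std and entropy vanish exactly
  zero_fams <- c("structure_tensor", "dog", "gradient", "local_std", "entropy")
  for (i in man$index[man$family %in% zero_fams])
    expect_lt(max(abs(bc[[i]])), 1e-7)
  # the truncated second-derivative kernels keep a small DC response
  # (largest along z where the kernel is 3 taps wide), so Hessian and LoG
  # maps are constant but not zero on constant input
  for (i in man$index[man$family %in% c("hessian", "log")])
    expect_lt(max(bc[[i]]) - min(bc[[i]]), 1e-7)
  for (i in man$index[man$family %in% c("raw", "smoothing", "sphere")])
    expect_equal(as.vector(bc[[i]]), rep(99, 12 * 12 * 10), tolerance = 1e-9)
})

test_that("base scale equalizes the physical sigma across axes", {
  s <- base_scale()
  expect_equal(s * c(11.24, 11.24, 28), rep(12, 3))
})
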