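# Shared fixtures built in code.

# 5 x 3 x 3 volume: segment 1 at x in 1:2, boundary plane at x = 3,
# segment 2 at x in 4:5; the classic planar interface with 9 border voxels.
planar_seg <- function() {
  lab <- array(0L, c(5, 3, 3))
  lab[1:2, , ] <- 1L
  lab[4:5, , ] <- 2L
  seg_volume(lab)
}

# mirror-symmetric segmentation for direction-symmetry tests: segments of
# equal extent either side of a central boundary plane
mirror_seg <- function(n = 9L) {
  half <- (n - 1L) %/% 2L
  lab <- array(0L, c(n, 5, 5))
  lab[1:half, , ] <- 1L
  lab[(half + 2L):n, , ] <- 2L
  seg_volume(lab)
}

# mirror-symmetric raw volume matching mirror_seg
mirror_raw <- function(n = 9L, value = 120) {
  vox_volume(array(value, c(n, 5, 5)))
}

config_hash_for_test <- function(cfg) emsynapse:::config_hash(cfg)

# filter half-size rule (mirrors the package's size rule for oracle use)
half_size_mult_for_test <- function(m) {
  as.integer(floor(m * ceiling(2 * base_scale()) + 0.5))
}

# small random intensity volume
random_vox <- function(dims, seed) {
  withr::with_seed(seed,
    vox_volume(array(sample(0:255, prod(dims), TRUE), dims)))
}
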