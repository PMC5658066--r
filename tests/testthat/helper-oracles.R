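# Independent brute-force oracles. These deliberately avoid the package's
# implementation paths: extraction scans full 26-neighborhoods per voxel
# and flood-fills naively; convolution is evaluated by direct summation;
# moments from their definitions; clustering as connected components of the
# within-cutoff graph; the connectivity model by Monte-Carlo simulation.

# --- random label volumes -------------------------------------------------

# Voronoi-style label volume with one-voxel 0 boundaries, independent of
# the package generator (different boundary rule is irrelevant: oracles and
# implementation see the same volume).
random_label_volume <- function(dims, n_segments, seed) {
  withr::with_seed(seed, {
    pts <- cbind(runif(n_segments, 1, dims[1]),
                 runif(n_segments, 1, dims[2]),
                 runif(n_segments, 1, dims[3]))
    co <- as.matrix(expand.grid(x = seq_len(dims[1]), y = seq_len(dims[2]),
                                z = seq_len(dims[3])))
    best <- rep(Inf, nrow(co)); lab <- integer(nrow(co))
    for (p in seq_len(n_segments)) {
      d2 <- (co[, 1] - pts[p, 1])^2 + (co[, 2] - pts[p, 2])^2 +
        (co[, 3] - pts[p, 3])^2
      upd <- d2 < best; best[upd] <- d2[upd]; lab[upd] <- p
    }
    lab <- array(lab, dim = dims)
    bnd <- array(FALSE, dims)
    bnd[-dims[1], , ] <- bnd[-dims[1], , ] | (lab[-dims[1], , ] != lab[-1, , ])
    bnd[, -dims[2], ] <- bnd[, -dims[2], ] | (lab[, -dims[2], ] != lab[, -1, ])
    bnd[, , -dims[3]] <- bnd[, , -dims[3]] | (lab[, , -dims[3]] != lab[, , -1])
    lab[bnd] <- 0L
    lab
  })
}

oracle_coords <- function(idx, dims) {
  idx0 <- idx - 1L
  cbind(idx0 %% dims[1] + 1L,
        (idx0 %/% dims[1]) %% dims[2] + 1L,
        idx0 %/% (dims[1] * dims[2]) + 1L)
}

# --- interface extraction oracle ------------------------------------------

# Every 0-voxel's full 26-neighborhood is scanned for segment pairs; per
# pair the voxel set is split by naive BFS flood fill under 26-adjacency;
# components of < min_border voxels are dropped.
oracle_extract <- function(lab, min_border = 1L) {
  dims <- dim(lab)
  zer <- which(lab == 0L)
  pair_vox <- list()
  for (v in zer) {
    co <- oracle_coords(v, dims)
    labs <- integer(0)
    for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
      if (dx == 0 && dy == 0 && dz == 0) next
      x <- co[1] + dx; y <- co[2] + dy; z <- co[3] + dz
      if (x < 1 || x > dims[1] || y < 1 || y > dims[2] || z < 1 || z > dims[3]) next
      l <- lab[x, y, z]
      if (l > 0) labs <- c(labs, l)
    }
    labs <- sort(unique(labs))
    if (length(labs) >= 2) {
      for (a in seq_len(length(labs) - 1)) for (b in (a + 1):length(labs)) {
        key <- paste(labs[a], labs[b])
        pair_vox[[key]] <- c(pair_vox[[key]], v)
      }
    }
  }
  out <- list()
  for (key in names(pair_vox)) {
    ids <- as.integer(strsplit(key, " ")[[1]])
    vset <- sort(pair_vox[[key]])
    seen <- rep(FALSE, length(vset))
    co <- oracle_coords(vset, dims)
    while (any(!seen)) {
      start <- which(!seen)[1]
      comp <- start; frontier <- start; seen[start] <- TRUE
      while (length(frontier) > 0) {
        nxt <- integer(0)
        for (f in frontier) {
          adj <- which(!seen &
                         abs(co[, 1] - co[f, 1]) <= 1 &
                         abs(co[, 2] - co[f, 2]) <= 1 &
                         abs(co[, 3] - co[f, 3]) <= 1)
          seen[adj] <- TRUE
          nxt <- c(nxt, adj)
        }
        comp <- c(comp, nxt)
        frontier <- nxt
      }
      if (length(comp) >= min_border)
        out[[length(out) + 1]] <- list(id1 = ids[1], id2 = ids[2],
                                       border = sort(vset[comp]))
    }
  }
  out
}

# canonical string form of an interface set for comparison
iface_key <- function(id1, id2, border) {
  paste(id1, id2, paste(border, collapse = ","))
}

# --- exhaustive shell distance oracle -------------------------------------

# min over border voxels of the anisotropic center-to-center distance.
# Candidates are restricted to the border bounding box padded by the voxel
# reach of max(ds) (a voxel further than that along any axis cannot be
# within reach), which keeps the pairwise computation exhaustive but
# bounded. Returns one sorted index vector per requested distance.
oracle_shell_multi <- function(lab, border, sid, ds, vs) {
  dims <- dim(lab)
  bco <- oracle_coords(border, dims)
  m <- ceiling(max(ds) / vs)
  lo <- pmax(apply(bco, 2, min) - m, 1)
  hi <- pmin(apply(bco, 2, max) + m, dims)
  cand <- as.matrix(expand.grid(x = lo[1]:hi[1], y = lo[2]:hi[2],
                                z = lo[3]:hi[3]))
  cidx <- (cand[, 1] - 1L) + dims[1] * ((cand[, 2] - 1L) +
                                          dims[2] * (cand[, 3] - 1L)) + 1L
  keep <- lab[cidx] == sid
  cand <- cand[keep, , drop = FALSE]
  cidx <- cidx[keep]
  if (length(cidx) == 0) return(lapply(ds, function(d) integer(0)))
  dmin <- rep(Inf, length(cidx))
  for (b in seq_len(nrow(bco))) {
    d2 <- ((cand[, 1] - bco[b, 1]) * vs[1])^2 +
      ((cand[, 2] - bco[b, 2]) * vs[2])^2 +
      ((cand[, 3] - bco[b, 3]) * vs[3])^2
    dmin <- pmin(dmin, d2)
  }
  setNames(lapply(ds, function(d) sort(cidx[sqrt(dmin) <= d])),
           as.character(ds))
}

# single-distance convenience; exhaustive over the whole segment
oracle_shell <- function(lab, border, sid, d_nm, vs) {
  oracle_shell_multi(lab, border, sid, d_nm, vs)[[1]]
}

# --- dense convolution oracle ---------------------------------------------

# direct triple-sum convolution with replicate padding
oracle_conv <- function(vol, kernel) {
  dims <- dim(vol); kd <- dim(kernel); f <- (kd - 1) / 2
  out <- array(0, dims)
  cl <- function(i, n) pmin(pmax(i, 1), n)
  for (x in seq_len(dims[1])) for (y in seq_len(dims[2])) for (z in seq_len(dims[3])) {
    acc <- 0
    for (tx in -f[1]:f[1]) for (ty in -f[2]:f[2]) for (tz in -f[3]:f[3]) {
      acc <- acc + kernel[tx + f[1] + 1, ty + f[2] + 1, tz + f[3] + 1] *
        vol[cl(x - tx, dims[1]), cl(y - ty, dims[2]), cl(z - tz, dims[3])]
    }
    out[x, y, z] <- acc
  }
  out
}

interior <- function(arr, margin) {
  d <- dim(arr)
  arr[(margin[1] + 1):(d[1] - margin[1]),
      (margin[2] + 1):(d[2] - margin[2]),
      (margin[3] + 1):(d[3] - margin[3])]
}

# --- moment oracle --------------------------------------------------------

oracle_stats <- function(x) {
  n <- length(x)
  mu <- sum(x) / n
  m2 <- sum((x - mu)^2) / n
  m3 <- sum((x - mu)^3) / n
  m4 <- sum((x - mu)^4) / n
  c(q25 = unname(quantile(x, 0.25, type = 7)),
    median = unname(quantile(x, 0.5, type = 7)),
    q75 = unname(quantile(x, 0.75, type = 7)),
    min = min(x), max = max(x), mean = mu,
    var = if (n > 1) sum((x - mu)^2) / (n - 1) else 0,
    skewness = if (m2 > 0) m3 / m2^1.5 else 0,
    kurtosis = if (m2 > 0) m4 / m2^2 else 0)
}

# --- clustering oracle ----------------------------------------------------

# single linkage at a cutoff == connected components of the graph joining
# points at distance <= cutoff
oracle_cluster <- function(xyz, cutoff) {
  n <- nrow(xyz)
  if (n == 1) return(1L)
  d <- as.matrix(dist(xyz))
  adj <- d <= cutoff
  comp <- integer(n); cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] > 0) next
    cur <- cur + 1L
    frontier <- s; comp[s] <- cur
    while (length(frontier) > 0) {
      nxt <- unique(unlist(lapply(frontier, function(f) which(adj[f, ] & comp == 0L))))
      comp[nxt] <- cur
      frontier <- nxt
    }
  }
  comp
}

# --- Monte-Carlo connectome oracle ----------------------------------------

# samples the generative assumptions of the analytic model: pairs connect
# at rate c_r, connected pairs draw a synapse count from p_n, each true
# synapse is detected independently with probability r_s, and false
# detections land per pair as Poisson with the rate implied by p_s.
mc_connectome <- function(n_pairs, c_r, p_n, r_s, p_s, mean_n_syn, gamma,
                          reps, seed) {
  withr::with_seed(seed, {
    lambda <- (1 - p_s) / p_s * r_s * c_r * mean_n_syn
    counts <- as.numeric(names(p_n))
    tp <- fp <- con <- numeric(reps)
    for (r in seq_len(reps)) {
      connected <- runif(n_pairs) < c_r
      n_syn <- counts[sample.int(length(counts), n_pairs, replace = TRUE,
                                 prob = p_n)]
      det_tp <- rbinom(n_pairs, n_syn, r_s) * connected
      fp_syn <- rpois(n_pairs, lambda)
      tp[r] <- sum(connected & det_tp >= gamma)
      fp[r] <- sum(!connected & fp_syn >= gamma)
      con[r] <- sum(connected)
    }
    # pooled ratio estimates (bias O(1/(n_pairs * reps))) with jackknife SE
    jack <- function(num, den) {
      est <- sum(num) / sum(den)
      loo <- (sum(num) - num) / (sum(den) - den)
      se <- sqrt((reps - 1) / reps * sum((loo - mean(loo))^2))
      list(est = est, se = se)
    }
    r <- jack(tp, con)
    p <- jack(tp, tp + fp)
    list(r_nn = r$est, r_se = r$se, p_nn = p$est, p_se = p$se)
  })
}
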