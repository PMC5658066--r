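test_that("single-linkage clustering chains within the cutoff", {
  det <- tibble::tibble(interface_id = 1:2, pre_id = 1L, post_id = 2L,
                        x_nm = c(0, 1000), y_nm = 0, z_nm = 0)
  expect_equal(nrow(cluster_synapses(det, 1500)), 1L)

  chain <- tibble::tibble(interface_id = 1:3, pre_id = 1L, post_id = 2L,
                          x_nm = c(0, 1400, 2800), y_nm = 0, z_nm = 0)
  expect_equal(nrow(cluster_synapses(chain, 1500)), 1L)  # chaining property
  expect_equal(nrow(cluster_synapses(chain, 1300)), 3L)

  # clustering never merges across neurite pairs
  two <- tibble::tibble(interface_id = 1:2, pre_id = c(1L, 1L),
                        post_id = c(2L, 3L), x_nm = 0, y_nm = 0, z_nm = 0)
  expect_equal(nrow(cluster_synapses(two, 1500)), 2L)
})

test_that("clustering equals connected components of the cutoff graph", {
  for (seed in 1:8) {
    withr::with_seed(seed, {
      n <- 25
      xyz <- cbind(runif(n, 0, 6000), runif(n, 0, 6000), runif(n, 0, 3000))
    })
    det <- tibble::tibble(interface_id = seq_len(n), pre_id = 1L, post_id = 2L,
                          x_nm = xyz[, 1], y_nm = xyz[, 2], z_nm = xyz[, 3])
    for (cutoff in c(320.12, 800, 1500)) {
      got <- cluster_synapses(det, cutoff)
      want <- oracle_cluster(xyz, cutoff)
      # same partition: compare membership up to relabeling
      got_member <- integer(n)
      for (i in seq_len(nrow(got)))
        got_member[match(got$interface_ids[[i]], det$interface_id)] <- i
      expect_equal(length(unique(want)), nrow(got))
      tab <- table(got_member, want)
      expect_true(all(rowSums(tab > 0) == 1) && all(colSums(tab > 0) == 1))
    }
    # synapse count is monotone non-increasing in the cutoff
    counts <- vapply(c(100, 320.12, 800, 1500, 4000),
                     function(cc) nrow(cluster_synapses(det, cc)), numeric(1))
    expect_true(all(diff(counts) <= 0))
  }
})

test_that("synapse areas sum over member interfaces", {
  expect_equal(asi_area(0.1), 0.1)
  expect_equal(asi_area(c(0.1, 0.2)), 0.3)
  det <- tibble::tibble(interface_id = 1:3, pre_id = 1L, post_id = 2L,
                        x_nm = c(0, 100, 5000), y_nm = 0, z_nm = 0,
                        area_um2 = c(0.1, 0.2, 0.4))
  syn <- cluster_synapses(det, 1500)
  expect_equal(sort(syn$area_um2), c(0.3, 0.4))
})

test_that("binarization thresholds synapse counts, per type if asked", {
  cw <- tibble::tibble(pre_id = c(1L, 1L, 2L, 2L),
                       post_id = c(1L, 2L, 1L, 2L),
                       n_synapses = c(0L, 1L, 2L, 3L))
  expect_equal(binarize_connectome(cw, 1L)$connected, c(FALSE, TRUE, TRUE, TRUE))
  expect_equal(binarize_connectome(cw, 2L)$connected, c(FALSE, FALSE, TRUE, TRUE))
  expect_equal(binarize_connectome(cw, 9L)$connected, rep(FALSE, 4))
  expect_error(binarize_connectome(cw, 0L), "gamma")

  types <- tibble::tibble(pre_id = c(1L, 2L), type = c("exc", "inh"))
  b <- binarize_connectome(cw, c(exc = 1L, inh = 2L), types)
  expect_equal(b$connected, c(FALSE, TRUE, TRUE, TRUE))
})

test_that("contactome sums areas per mapped process pair", {
  ifs <- tibble::tibble(id1 = c(1L, 1L, 2L, 5L), id2 = c(3L, 3L, 4L, 6L),
                        area_um2 = c(0.1, 0.2, 0.3, 0.9))
  pre <- tibble::tibble(segment_id = c(1L, 2L), process_id = c(10L, 20L))
  post <- tibble::tibble(segment_id = c(3L, 4L), process_id = c(30L, 40L))
  ct <- contactome(ifs, pre, post)
  expect_equal(ct$total_area_um2[ct$pre_id == 10 & ct$post_id == 30], 0.3)
  expect_equal(ct$total_area_um2[ct$pre_id == 20 & ct$post_id == 40], 0.3)
  expect_equal(attr(ct, "n_skipped"), 1L)

  none <- contactome(ifs[0, ], pre, post)
  expect_equal(nrow(none), 0L)

  # permutation equivariance of process ids
  pre2 <- tibble::tibble(segment_id = c(1L, 2L), process_id = c(20L, 10L))
  ct2 <- contactome(ifs, pre2, post)
  expect_equal(ct2$total_area_um2[ct2$pre_id == 20 & ct2$post_id == 30], 0.3)
})

test_that("nn_recall evaluates the exact binomial tail mixture", {
  # closed forms
  expect_equal(nn_recall(1, delta_pn(4), 1), 1)
  expect_equal(nn_recall(1, delta_pn(4), 4), 1)
  expect_equal(nn_recall(0.5, delta_pn(2), 1), 0.75)
  # inhibitory operating point: R_s = 0.678, n = 6, gamma = 2
  expect_equal(round(nn_recall(0.678, delta_pn(6), 2), 3), 0.985)
  # mixtures
  pn <- c("1" = 0.5, "3" = 0.5)
  expect_equal(nn_recall(0.5, pn, 1), 0.5 * 0.5 + 0.5 * (1 - 0.125))
  expect_error(nn_recall(0.5, c("1" = 0.7, "2" = 0.7), 1), "summing to 1")
})

test_that("nn_precision matches closed forms and the printed operating point", {
  # perfect precision: no false positives at all
  expect_equal(nn_precision(1, 0.9, 0.99, 0.2, 4.3, 1), 1)
  # inhibitory theta_s point at gamma = 2
  r_nn <- nn_recall(0.749, delta_pn(6), 2)
  expect_equal(round(nn_precision(0.821, 0.749, r_nn, 0.6, 6, 2), 3), 0.927)
  # hand-computable case: P_s = 0.5, R_s = 1, c_r = 0.5, <n> = 1, gamma = 1
  lam <- 1 * 0.5 * 1  # (1-Ps)/Ps * Rs * cr * n = 0.5
  want <- 0.5 * 1 / (0.5 * 1 + 0.5 * (1 - exp(-lam)))
  expect_equal(nn_precision(0.5, 1, 1, 0.5, 1, 1), want)
  expect_error(nn_precision(0, 0.5, 0.5, 0.5, 1, 1), "positive")
})

test_that("the analytic model agrees with Monte-Carlo simulation", {
  model <- inhibitory_model()
  for (case in list(c(r_s = 0.7, p_s = 0.8, gamma = 1),
                    c(r_s = 0.9, p_s = 0.95, gamma = 2))) {
    mc <- mc_connectome(n_pairs = 4000, c_r = 0.6, p_n = delta_pn(6),
                        r_s = case["r_s"], p_s = case["p_s"],
                        mean_n_syn = 6, gamma = case["gamma"],
                        reps = 20, seed = 100 + case["gamma"])
    r_nn <- nn_recall(case[["r_s"]], delta_pn(6), case[["gamma"]])
    p_nn <- nn_precision(case[["p_s"]], case[["r_s"]], r_nn, 0.6, 6,
                         case[["gamma"]])
    expect_lt(abs(r_nn - mc$r_nn), 3 * mc$r_se + 1e-9)
    expect_lt(abs(p_nn - mc$p_nn), 3 * mc$p_se + 1e-9)
  }
})

test_that("P_nn is independent of the connectome size by construction", {
  # N never enters nn_precision; verify the cancellation argument by
  # recomputing the N-dependent form at several N
  p_s <- 0.821; r_s <- 0.749; c_r <- 0.6; n_syn <- 6; gamma <- 2
  r_nn <- nn_recall(r_s, delta_pn(6), gamma)
  vals <- vapply(c(100, 1000, 10000), function(N) {
    n_total <- N^2 * c_r * n_syn
    fp_s <- (1 - p_s) / p_s * r_s * n_total
    fp_nn <- N^2 * (1 - c_r) * ppois(gamma - 1, fp_s / N^2, lower.tail = FALSE)
    tp_nn <- N^2 * c_r * r_nn
    tp_nn / (tp_nn + fp_nn)
  }, numeric(1))
  expect_lt(max(abs(vals - vals[1])) / vals[1], 1e-12)
  expect_equal(vals[1], nn_precision(p_s, r_s, r_nn, c_r, n_syn, gamma),
               tolerance = 1e-12)
})

test_that("connectivity model objects expose tidy summaries", {
  m <- inhibitory_model()
  expect_equal(glance(m)$c_r, 0.6)
  expect_equal(tidy(m)$n_syn, 6)
  perf <- nn_performance(m, p_s = 0.821, r_s = 0.749)
  expect_equal(perf$gamma_nn, 1:2)
  expect_true(all(perf$r_nn >= 0 & perf$r_nn <= 1))
  expect_s3_class(autoplot(m), "ggplot")
})

test_that("percent rounding is half away from zero to one decimal", {
  expect_equal(percent1(0.99975), 100)
  expect_equal(percent1(0.92665), 92.7)
  expect_equal(percent1(0.12345), 12.3)
  expect_equal(percent1(0.015), 1.5)
})
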