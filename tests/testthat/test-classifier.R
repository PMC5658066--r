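toy_separable <- function(n = 20, seed = 70) {
  withr::with_seed(seed, {
    y <- rep(c(TRUE, FALSE), each = n / 2)
    x1 <- ifelse(y, rnorm(n, 3), rnorm(n, -3))
    x2 <- rnorm(n)
    list(X = cbind(x1, x2), y = y)
  })
}

test_that("label set variants count entries as specified", {
  ann <- tibble::tibble(interface_id = 1:3,
                        synaptic = c(TRUE, FALSE, FALSE),
                        direction = c("fwd", NA, NA))
  d <- build_label_variant(ann, "directed")
  expect_equal(nrow(d), 6L)
  expect_equal(sum(d$synaptic), 1L)
  a <- build_label_variant(ann, "augmented")
  expect_equal(nrow(a), 6L)
  expect_equal(sum(a$synaptic), 2L)
  u <- build_label_variant(ann, "undirected")
  expect_equal(nrow(u), 3L)
  expect_equal(sum(u$synaptic), 1L)

  bad <- tibble::tibble(interface_id = 1L, synaptic = TRUE,
                        direction = NA_character_)
  expect_error(build_label_variant(bad, "directed"), "direction")
  expect_equal(sum(build_label_variant(bad, "augmented")$synaptic), 2L)
})

test_that("training separates a separable toy set and flips with labels", {
  toy <- toy_separable()
  m <- train_stump_ensemble(toy$X, toy$y, n_learners = 50)
  s <- predict(m, toy$X)
  expect_true(all(s[toy$y] > 0) && all(s[!toy$y] < 0))  # zero training error

  # label inversion negates the decision
  m2 <- train_stump_ensemble(toy$X, !toy$y, n_learners = 50)
  s2 <- predict(m2, toy$X)
  expect_true(all(sign(s2) == -sign(s)))

  expect_error(train_stump_ensemble(toy$X, rep(TRUE, 20)), "both classes")
  expect_error(train_stump_ensemble(cbind(c(1, NA), c(0, 1)), c(TRUE, FALSE)),
               "finite")
})

test_that("training is deterministic including serialization", {
  toy <- toy_separable(seed = 71)
  dir <- withr::local_tempdir()
  m1 <- train_stump_ensemble(toy$X, toy$y, n_learners = 30)
  m2 <- train_stump_ensemble(toy$X, toy$y, n_learners = 30)
  p1 <- file.path(dir, "m1.json"); p2 <- file.path(dir, "m2.json")
  write_model(m1, p1); write_model(m2, p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("scores follow the additive stump definition", {
  empty <- structure(list(
    stumps = tibble::tibble(feature = integer(), threshold = double(),
                            left = double(), right = double(), gain = double()),
    learning_rate = 0.1, n_learners = 0L, cost_synaptic = 100,
    algorithm = "logitboost", n_features = 3L, seed = 0L,
    label_variant = NA_character_), class = "stump_ensemble")
  expect_equal(predict(empty, c(1, 2, 3)), 0)

  one <- empty
  one$stumps <- tibble::tibble(feature = 2L, threshold = 0.5, left = 2,
                               right = -4, gain = 1)
  expect_equal(predict(one, c(9, 0.2, 0)), 0.1 * 2)
  expect_equal(predict(one, c(9, 0.8, 0)), 0.1 * -4)
  expect_error(predict(one, c(1, 2)), "length")

  # batch scoring equals per-example scoring
  toy <- toy_separable(seed = 72)
  m <- train_stump_ensemble(toy$X, toy$y, n_learners = 40)
  batch <- predict(m, toy$X)
  single <- vapply(seq_len(nrow(toy$X)), function(i) predict(m, toy$X[i, ]),
                   numeric(1))
  expect_equal(batch, single, tolerance = 1e-12)
})

test_that("interface classification picks the argmax direction", {
  r <- classify_interface(-0.5, -3, theta = -1)
  expect_true(r$detected)
  expect_equal(r$direction, "fwd")
  r2 <- classify_interface(-2, -2, theta = -1)
  expect_false(r2$detected)
  expect_true(is.na(r2$direction))

  # raising theta never converts a non-detection into a detection
  withr::with_seed(80, {
    fwd <- rnorm(200); rev <- rnorm(200)
    thetas <- sort(rnorm(15))
    prev <- rep(TRUE, 200)
    for (th in thetas) {
      det <- classify_interface(fwd, rev, th)$detected
      expect_true(all(det <= prev))
      prev <- det
    }
  })
})

test_that("feature importance ranks informative features first", {
  one <- structure(list(
    stumps = tibble::tibble(feature = 3L, threshold = 0, left = 1,
                            right = -1, gain = 2.5),
    learning_rate = 0.1, n_learners = 1L, cost_synaptic = 100,
    algorithm = "logitboost", n_features = 4L, seed = 0L,
    label_variant = NA_character_), class = "stump_ensemble")
  fi <- feature_importance(one)
  expect_equal(fi$feature[1], 3L)
  expect_equal(fi$importance[1], 2.5)
  expect_equal(sum(fi$importance), 2.5)  # conservation of accumulated gain

  toy <- toy_separable(seed = 73)
  m <- train_stump_ensemble(toy$X, toy$y, n_learners = 60)
  fi <- feature_importance(m)
  expect_equal(fi$feature[1], 1L)  # only feature 1 is informative
  expect_equal(sum(fi$importance), sum(m$stumps$gain[m$stumps$feature > 0]))
})

test_that("undirected OR-validation matches a hand-computed confusion matrix", {
  # 10 interfaces; 4 synaptic
  synaptic <- c(TRUE, TRUE, TRUE, TRUE, rep(FALSE, 6))
  fwd <- c(2, -3, 0.5, -2, -5, 1.5, -4, -4, -4, -4)
  rev <- c(-1, 1.2, -2, -3, -4, -6, 2.2, -4, -4, -4)
  # theta = 0: detected = {1, 2, 3} via OR, {6, 7} false
  r <- validate_undirected(fwd, rev, synaptic, theta = 0)
  expect_equal(r$tp, 3); expect_equal(r$fp, 2); expect_equal(r$fn, 1)
  expect_equal(r$precision, 3 / 5)
  expect_equal(r$recall, 3 / 4)

  perfect <- validate_undirected(c(1, 1, -1), c(1, -1, -1),
                                 c(TRUE, TRUE, FALSE), 0)
  expect_equal(perfect$precision, 1)
  expect_equal(perfect$recall, 1)

  none <- validate_undirected(c(-1, -1), c(-1, -1), c(TRUE, FALSE), 0)
  expect_equal(none$precision, 1)
  expect_true(none$no_detections)
  expect_equal(none$recall, 0)
})

test_that("raising the synaptic cost never lowers training recall", {
  withr::with_seed(81, {
    n <- 60
    y <- rep(c(TRUE, FALSE), c(15, 45))
    X <- cbind(ifelse(y, rnorm(n, 1.0), rnorm(n, -1.0)), rnorm(n))
  })
  recalls <- vapply(c(1, 10, 100), function(cost) {
    m <- train_stump_ensemble(X, y, n_learners = 25, cost_synaptic = cost)
    s <- predict(m, X)
    sum(s > 0 & y) / sum(y)
  }, numeric(1))
  expect_true(all(diff(recalls) >= 0))
})

test_that("adaboostm1 remains available as the historic configuration", {
  toy <- toy_separable(seed = 74)
  m <- train_stump_ensemble(toy$X, toy$y, n_learners = 40,
                            algorithm = "adaboostm1")
  s <- predict(m, toy$X)
  expect_true(all(s[toy$y] > 0) && all(s[!toy$y] < 0))
  expect_equal(glance(m)$algorithm, "adaboostm1")
})
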