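test_that("cell labeling follows the case:control ratio rule", {
  d <- data.frame(status_case = rep(c(1, 0), c(40, 40)),
                  f = c(rep(1, 30), rep(0, 10), rep(1, 10), rep(0, 30)))
  m <- mdr_label_cells(d, "f")
  expect_equal(unname(m$cell_labels[c("1", "0")]), c("high", "low"))
  expect_equal(m$threshold, 1)
  # exact threshold ratio is labeled high (ties go high)
  tie <- data.frame(status_case = rep(c(1, 0), c(20, 20)),
                    f = c(rep(1, 10), rep(0, 10), rep(1, 10), rep(0, 10)))
  expect_equal(unname(mdr_label_cells(tie, "f")$cell_labels), c("high", "high"))
  expect_error(mdr_label_cells(d[d$status_case == 1, ], "f"), "both cases")
})

test_that("cell labels equal brute-force per-cell enumeration", {
  set.seed(13)
  d <- data.frame(status_case = rbinom(200, 1, 0.5),
                  a = sample(0:1, 200, TRUE),
                  b = sample(c("x", "y", "z"), 200, TRUE))
  m <- mdr_label_cells(d, c("a", "b"))
  thr <- sum(d$status_case) / sum(1 - d$status_case)
  for (av in 0:1)
    for (bv in c("x", "y", "z")) {
      cell <- d$a == av & d$b == bv
      ca <- sum(d$status_case[cell]); co <- sum(1 - d$status_case[cell])
      want <- if (ca + co == 0) "low"
              else if (co == 0) "high"
              else if (ca / co >= thr) "high" else "low"
      expect_equal(unname(m$cell_labels[paste(av, bv, sep = ".")]), want)
    }
})

test_that("balanced accuracy matches a hand confusion matrix", {
  train <- data.frame(status_case = c(1, 1, 1, 0, 0, 0),
                      f = c(1, 1, 0, 0, 0, 1))
  model <- mdr_label_cells(train, "f")  # cell 1: 2/1 high; cell 0: 1/2 low
  test <- data.frame(status_case = c(1, 1, 0, 0, 1, 0, 0, 1),
                     f = c(1, 0, 1, 0, 1, 0, 0, 1))
  # predictions: f=1 -> case. cases have f = 1,0,1,1 -> 3/4 correct;
  # controls have f = 1,0,0,0 -> predicted control for 3/4
  r <- mdr_balanced_accuracy(model, test)
  expect_equal(r$sensitivity, 3 / 4)
  expect_equal(r$specificity, 3 / 4)
  expect_equal(r$balanced_accuracy, 3 / 4)
  # perfectly separating factor scores 1
  perf <- data.frame(status_case = rep(c(1, 0), each = 10),
                     f = rep(c(1, 0), each = 10))
  expect_equal(
    mdr_balanced_accuracy(mdr_label_cells(perf, "f"), perf)$balanced_accuracy,
    1)
  expect_error(mdr_balanced_accuracy(model, test[test$status_case == 1, ]),
               "both cases")
})

test_that("combinations unseen in training predict the low-risk default", {
  train <- data.frame(status_case = rep(c(1, 0), each = 6),
                      f = factor(rep(c("a", "b"), 6), levels = c("a", "b", "c")))
  model <- mdr_label_cells(train, "f")
  expect_equal(unname(model$cell_labels["c"]), "low")
})

test_that("cross-validation scores a perfect predictor at 1 and noise at 0.5", {
  d <- perfect_predictor_data(25)
  cv <- mdr_cross_validate(d, "signal", folds = 5, repeats = 2, seed = 8)
  expect_equal(cv$accuracies, rep(1, 10))
  # held-out accuracy of a noise factor sits at (or slightly below) chance:
  # cell labels overfit the training folds, never exceeding chance on test
  noise <- mdr_cross_validate(d, "noise1", folds = 5, repeats = 10, seed = 8)
  expect_lt(noise$mean_accuracy, 0.56)
  expect_gt(noise$mean_accuracy, 0.38)
})

test_that("search enumerates all combinations and finds embedded signal", {
  d <- perfect_predictor_data(25)
  res <- mdr_search(d, c("signal", "noise1", "noise2"), folds = 5,
                    repeats = 2, seed = 4)
  expect_equal(length(res$combinations), 7)  # C(3,1)+C(3,2)+C(3,3)
  expect_equal(res$best_per_size$factors[1], "signal")
  expect_equal(res$best_per_size$cvc[1], 10)
  expect_equal(res$overall_best, "signal")
  expect_equal(res$overall_accuracy, 1)
})

test_that("search equals brute-force re-evaluation on a tiny dataset", {
  set.seed(21)
  d <- data.frame(status_case = rep(c(1, 0), each = 60),
                  a = sample(0:1, 120, TRUE), b = sample(0:1, 120, TRUE),
                  c = sample(0:1, 120, TRUE))
  folds <- 3; repeats <- 2; seed <- 99
  res <- mdr_search(d, c("a", "b", "c"), max_size = 2, folds = folds,
                    repeats = repeats, seed = seed)
  # oracle: rebuild the same stratified folds with the same seeded stream,
  # then evaluate every combination by direct table arithmetic
  y <- d$status_case
  combos <- list("a", "b", "c", c("a", "b"), c("a", "c"), c("b", "c"))
  acc <- matrix(NA_real_, length(combos), folds * repeats)
  set.seed(seed)
  assignments <- lapply(seq_len(repeats), function(r) {
    fold <- integer(length(y))
    for (cls in unique(y)) {
      idx <- which(y == cls)
      fold[idx] <- sample(rep(seq_len(folds), length.out = length(idx)))
    }
    fold
  })
  e <- 0
  for (fold in assignments)
    for (f in seq_len(folds)) {
      e <- e + 1
      tr <- d[fold != f, ]; te <- d[fold == f, ]
      thr <- sum(tr$status_case) / sum(1 - tr$status_case)
      for (ci in seq_along(combos)) {
        key_tr <- do.call(paste, tr[combos[[ci]]])
        key_te <- do.call(paste, te[combos[[ci]]])
        high <- names(Filter(isTRUE, tapply(tr$status_case, key_tr,
          function(v) if (sum(v == 0) == 0) sum(v) > 0
                      else sum(v) / sum(v == 0) >= thr)))
        pred <- as.integer(key_te %in% high)
        sens <- sum(pred == 1 & te$status_case == 1) / sum(te$status_case)
        spec <- sum(pred == 0 & te$status_case == 0) /
          sum(1 - te$status_case)
        acc[ci, e] <- (sens + spec) / 2
      }
    }
  expect_equal(res$mean_accuracy, rowMeans(acc), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("search recovers an embedded two-factor interaction", {
  cfg <- cohort_config(n_cases = 1000, n_controls = 1000, seed = 314,
                       genotype_or = 1.0,
                       interaction_ors = c(t2dm = 2.0))
  d <- simulate_cohort(cfg)
  res <- mdr_search(d, c("g_dominant", "t2dm", "smoking", "drinking"),
                    max_size = 2, folds = 5, repeats = 2, seed = 11)
  two <- res$best_per_size[res$best_per_size$size == 2, ]
  expect_equal(two$factors, "g_dominant, t2dm")
})

test_that("accuracy on permuted outcomes is at chance and p is calibrated", {
  set.seed(55)
  d <- data.frame(status_case = rep(c(1, 0), each = 100),
                  a = sample(0:1, 200, TRUE), b = sample(0:1, 200, TRUE))
  d_perm <- d
  d_perm$status_case <- sample(d$status_case)
  cv <- mdr_cross_validate(d_perm, c("a", "b"), folds = 5, repeats = 4,
                           seed = 2)
  expect_equal(cv$mean_accuracy, 0.5, tolerance = 0.07)
  pt <- mdr_permutation_test(d, c("a", "b"), n_perm = 60, folds = 4,
                             repeats = 1, seed = 31)
  expect_gt(pt$p, 0.05)
  expect_gte(pt$p, 1 / 61)
})

test_that("permutation significance detects a strong embedded signal", {
  d <- perfect_predictor_data(25)
  pt <- mdr_permutation_test(d, c("signal", "noise1"), n_perm = 100,
                             folds = 5, repeats = 1, seed = 7)
  expect_lte(pt$p, 0.01)
})

test_that("MDR runs are deterministic under a fixed seed", {
  d <- small_cohort(150, seed = 77)
  a <- mdr_search(d, c("g_dominant", "t2dm"), folds = 4, repeats = 2,
                  seed = 5)
  b <- mdr_search(d, c("g_dominant", "t2dm"), folds = 4, repeats = 2,
                  seed = 5)
  expect_identical(a$cvc, b$cvc)
  expect_identical(a$mean_accuracy, b$mean_accuracy)
})

test_that("entropy graph satisfies the XOR and redundancy identities", {
  # XOR: no univariate signal, pairwise synergy = 100% of H(Y)
  grid <- expand.grid(a = 0:1, b = 0:1)
  d <- grid[rep(1:4, each = 25), ]
  d$status_case <- as.integer(xor(d$a, d$b))
  eg <- entropy_graph(d, c("a", "b"))
  expect_equal(unname(eg$univariate), c(0, 0), tolerance = 1e-10)
  expect_equal(eg$pairwise$percent, 100, tolerance = 1e-10)
  expect_equal(eg$pairwise$strength, "strong")
  # duplicated factor: interaction information is pure redundancy -I(A;Y)
  set.seed(3)
  d2 <- data.frame(a = sample(0:1, 300, TRUE))
  d2$b <- d2$a
  d2$status_case <- rbinom(300, 1, ifelse(d2$a == 1, 0.7, 0.3))
  eg2 <- entropy_graph(d2, c("a", "b"))
  expect_equal(eg2$pairwise$percent, -unname(eg2$univariate["a"]),
               tolerance = 1e-10)
  # symmetry and order invariance
  eg3 <- entropy_graph(d2, c("b", "a"))
  expect_equal(unname(eg3$univariate["a"]), unname(eg2$univariate["a"]))
  expect_equal(eg3$pairwise$percent, eg2$pairwise$percent)
  # independent factor explains ~0% of outcome entropy
  d2$c <- sample(0:1, 300, TRUE)
  eg4 <- entropy_graph(d2, "c")
  expect_lt(unname(eg4$univariate["c"]), 1)
  expect_error(entropy_graph(transform(d2, status_case = 1), "a"),
               "constant")
})
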