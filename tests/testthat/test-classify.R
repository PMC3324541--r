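test_that("feature encoding lays out one-hot LME blocks then gene bits", {
  panel <- toy_panel4()
  d <- tibble::tibble(neuron_id = "n1", layer = "L2/3", morphology = "LBC",
                      etype = "cAD", A = 1L, B = 1L, C = 0L, D = 0L)
  X <- encode_features(d, panel)
  expect_equal(dim(X), c(1, 12))
  expect_equal(sum(X), 3)
  X2 <- encode_features(d, panel, c("A", "B"))
  expect_equal(dim(X2), c(1, 14))
  expect_equal(sum(X2), 5)
  # permutation equivariance over records
  dd <- planted_and_data(seed = 3)
  perm <- withr::with_seed(1, sample(nrow(dd)))
  expect_equal(encode_features(dd, panel)[perm, ],
               encode_features(dd[perm, ], panel))
  expect_error(encode_features(d, panel, "Z"), "unknown gene")
})

test_that("hyper grid spans powers of two with the documented shape", {
  g <- make_hyper_grid()
  expect_equal(nrow(g), 961)
  expect_equal(length(unique(g$C)), 31)
  expect_equal(min(g$C), 2^-15)
  expect_equal(max(g$gamma), 2^15)
  expect_equal(min(g$C), 3.0517578125e-05)
  g2 <- make_hyper_grid(-1, 1, 2)
  expect_equal(nrow(g2), 4)
  expect_setequal(unique(g2$C), c(0.5, 2))
  expect_error(make_hyper_grid(3, -3), "lo_exp < hi_exp")
})

test_that("cross-validation is deterministic and handles degenerate targets", {
  panel <- toy_panel4()
  d <- planted_and_data(seed = 2)
  d$D <- 0L # constant target
  ev <- cv_accuracy(d, "D", panel, params = hyper_params(1, 0.5), k = 5,
                    seed = 3)
  expect_equal(ev$cv_accuracy, 1)
  expect_true(is.na(ev$auc))

  ev1 <- cv_accuracy(d, "A", panel, c("B", "C"),
                     params = hyper_params(1, 0.5), k = 5, seed = 7)
  ev2 <- cv_accuracy(d, "A", panel, c("B", "C"),
                     params = hyper_params(1, 0.5), k = 5, seed = 7)
  expect_identical(ev1$fold_accuracies, ev2$fold_accuracies)
  expect_identical(ev1$predictions, ev2$predictions)
  expect_equal(ev1$cv_accuracy, mean(ev1$fold_accuracies))
  expect_error(cv_accuracy(d, "A", panel, k = 1000, seed = 1), "exceed")
  expect_error(cv_accuracy(d, "A", panel, input_genes = "A"), "own inputs")
})

test_that("a separable planted relation reaches perfect accuracy", {
  panel <- toy_panel4()
  # target equals one input gene exactly
  d <- planted_and_data(seed = 4)
  d$A <- d$B
  ev <- cv_accuracy(d, "A", panel, "B", params = hyper_params(10, kernel = "linear"),
                    k = 5, seed = 1)
  expect_equal(ev$cv_accuracy, 1)
})

test_that("majority-class CV accuracy equals the majority fraction", {
  panel <- toy_panel4()
  d <- planted_and_data(seed = 6)
  # gene D has a clear majority class, so the training majority is stable
  maj <- max(mean(d$D), 1 - mean(d$D))
  X <- encode_features(d, panel)
  y <- as.integer(d$D)
  folds <- ionrules:::make_folds(nrow(d), 5, seed = 2)
  lme <- lme_key(d$layer, d$morphology, d$etype)
  ev <- ionrules:::cv_engine(X, y, lme, folds, function(Xtr, ytr, Xte) {
    m <- as.integer(mean(ytr) >= 0.5)
    list(pred = rep(m, nrow(Xte)), score = rep(m, nrow(Xte)))
  })
  expect_equal(ev$cv_accuracy, maj, tolerance = 1 / nrow(d) + 1e-9)
})

test_that("grid search obeys the tie-break contract and evaluation count", {
  panel <- toy_panel4()
  d <- planted_and_data(seed = 2)
  d$D <- 0L
  g <- make_hyper_grid(-1, 1, 2)
  gs <- grid_search(d, "D", panel, grid = g, k = 5, seed = 1)
  # all settings tie at accuracy 1; smallest C, then smallest gamma, rbf
  expect_equal(gs$best$C, 0.5)
  expect_equal(gs$best$gamma, 0.5)
  expect_equal(gs$best$kernel, "rbf")
  expect_equal(nrow(gs$trace), 4 + 2) # 4 rbf pairs + 2 linear C values

  # invariant to grid-row order
  gs2 <- grid_search(d, "A", panel, c("B", "C"), grid = small_grid(),
                     k = 5, seed = 5)
  gs3 <- grid_search(d, "A", panel, c("B", "C"),
                     grid = small_grid()[withr::with_seed(2, sample(nrow(small_grid()))), ],
                     k = 5, seed = 5)
  expect_equal(gs2$best, gs3$best)
  expect_equal(gs2$result$cv_accuracy, gs3$result$cv_accuracy)
})

test_that("logistic baseline uses the frequency cutoff and flags fallbacks", {
  panel <- toy_panel4()
  d <- planted_and_data(seed = 8)
  d$D <- 0L
  ev <- lr_baseline(d, "D", panel, k = 5, seed = 1)
  expect_equal(ev$cv_accuracy, 1)
  expect_true(all(ev$predictions$pred == 0))

  # lowering the cutoff never decreases the number of predicted 1s
  n_pos <- vapply(c(0.9, 0.5, 0.1), function(ct) {
    sum(lr_baseline(d, "A", panel, c("B", "C"), cutoff = ct, k = 5,
                    seed = 4)$predictions$pred)
  }, numeric(1))
  expect_true(all(diff(n_pos) >= 0))
  expect_error(lr_baseline(d, "A", panel, cutoff = 1.5), "between 0 and 1")
})

test_that("rank AUC matches the pairwise oracle and its known anchors", {
  expect_equal(roc_auc(c(1, 1, 1, 1), c(0, 1, 0, 1)), 0.5)
  expect_equal(roc_auc(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1)), 1)
  expect_true(is.na(roc_auc(1:4, c(1, 1, 1, 1))))
  withr::with_seed(11, {
    for (i in 1:20) {
      n <- sample(5:30, 1)
      scores <- round(stats::rnorm(n), 1) # rounding forces ties
      labels <- stats::rbinom(n, 1, 0.4)
      if (length(unique(labels)) < 2) next
      expect_equal(roc_auc(scores, labels), auc_pairwise(scores, labels))
      # invariance under strictly monotone transform
      expect_equal(roc_auc(exp(scores), labels), roc_auc(scores, labels))
    }
  })
})
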