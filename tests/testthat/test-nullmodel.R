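test_that("Bernoulli resampling respects marginals and preserves labels", {
  panel <- toy_panel4()
  d <- planted_and_data(seed = 41)
  rs <- bernoulli_resample(d, panel, c(A = 0, B = 1, C = 0.5, D = 0.5),
                           seed = 1)
  expect_true(all(rs$A == 0))
  expect_true(all(rs$B == 1))
  expect_equal(rs[, c("neuron_id", "layer", "morphology", "etype")],
               d[, c("neuron_id", "layer", "morphology", "etype")])

  # binomial concentration at n = 1000
  big <- d[rep(seq_len(nrow(d)), length.out = 1000), ]
  big$neuron_id <- sprintf("n%04d", 1:1000)
  rs2 <- bernoulli_resample(big, panel, c(A = 0.5, B = 0.5, C = 0.5, D = 0.5),
                            seed = 2)
  se <- sqrt(0.25 / 1000)
  expect_lt(abs(mean(rs2$C) - 0.5), 3 * se)

  expect_error(bernoulli_resample(d, panel, c(A = 1.5, B = 0, C = 0, D = 0)),
               "\\[0, 1\\]")
  # default frequencies come from the data itself
  rs3 <- bernoulli_resample(d, panel, seed = 3)
  expect_equal(dim(rs3), dim(d))
})

test_that("random-input models score degenerate targets perfectly", {
  panel <- toy_panel4()
  d <- planted_and_data(seed = 42)
  d$A <- 0L
  acc <- riisvm_run(d, "A", panel, n_inputs = 0, seed = 1,
                    grid = small_grid(), k = 5)
  expect_equal(acc, 1)
  expect_error(riisvm_run(d, "A", panel, n_inputs = 4), "panel size")
})

test_that("random-input accuracies vary across seeds on real structure", {
  panel <- toy_panel4()
  d <- planted_and_data(seed = 43, n_per = 25)
  accs <- vapply(1:15, function(s) {
    riisvm_run(d, "A", panel, n_inputs = 2, seed = s, grid = small_grid(),
               k = 5)
  }, numeric(1))
  expect_gt(stats::var(accs), 0)
  # on planted data the tuned greedy model beats random inputs on average
  m <- incremental_select(d, "A", panel, k = 5, seed = 1,
                          grid = small_grid())
  expect_gt(m$accuracy, mean(accs))
})

test_that("distribution comparison matches closed-form ANOVA", {
  a <- c(1, 2, 3)
  b <- c(2, 3, 4)
  c3 <- c(5, 6, 10)
  got <- compare_accuracy_distributions(a, b, c3)
  want <- anova_closed_form(list(a, b, c3))
  expect_equal(got$anova_F, want$F)
  expect_equal(got$anova_p, want$p)
  expect_equal(nrow(got$pairwise), 3)

  # identical samples: no between-group variance
  same <- compare_accuracy_distributions(a, a, a)
  expect_equal(same$anova_F, 0)
  expect_equal(same$anova_p, 1)
  expect_false(same$degenerate)

  # zero variance everywhere is flagged, not crashed
  deg <- compare_accuracy_distributions(c(1, 1), c(1, 1), c(1, 1))
  expect_true(deg$degenerate)
  expect_true(is.na(deg$anova_F))

  # power sanity: two groups five SDs apart
  withr::with_seed(5, {
    x <- stats::rnorm(50)
    y <- stats::rnorm(50) + 5
  })
  sep <- compare_accuracy_distributions(x, y, x)
  expect_lt(sep$pairwise$p[[1]], 1e-6)
  expect_error(compare_accuracy_distributions(1, c(1, 2), c(1, 2)),
               "at least 2")
})

test_that("the null experiment is reproducible and ordered as expected", {
  panel <- toy_panel4()
  d <- planted_and_data(seed = 44, n_per = 25)
  run1 <- null_experiment(d, panel, n_iter = 2, seed = 3, k = 5,
                          grid = small_grid(), retune = "once",
                          targets = c("A", "B"))
  run2 <- null_experiment(d, panel, n_iter = 2, seed = 3, k = 5,
                          grid = small_grid(), retune = "once",
                          targets = c("A", "B"))
  expect_equal(tibble::as_tibble(run1), tibble::as_tibble(run2))
  expect_equal(sort(unique(run1$kind)), c("isvm", "rdisvm", "riisvm"))
  expect_equal(sum(run1$kind == "isvm"), 2 * 2)

  s <- null_summary(run1)
  expect_equal(nrow(s$means), 3)
  # planted structure: the fitted models outscore the data-destroying null
  m <- s$means
  expect_gte(m$mean_accuracy[m$kind == "isvm"],
             m$mean_accuracy[m$kind == "rdisvm"] - 0.05)
})

test_that("resampled-data accuracy approaches the majority-class ceiling", {
  panel <- toy_panel4()
  # pure Bernoulli data with known p: the best achievable accuracy for
  # independent targets is max(p, 1-p) per gene
  p <- c(A = 0.15, B = 0.3, C = 0.2, D = 0.25)
  d <- generate_synthetic(synth_config(
    panel = panel, group_counts = two_type_counts(30),
    frequencies = p, mode = "bernoulli", seed = 45
  ))
  run <- null_experiment(d, panel, n_iter = 2, seed = 6, k = 5,
                         grid = small_grid(), retune = "once")
  rd <- run[run$kind == "rdisvm", ]
  expected <- mean(pmax(p, 1 - p))
  expect_lt(abs(mean(rd$accuracy) - expected), 0.1)
})
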