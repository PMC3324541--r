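test_that("selection recovers a planted two-gene rule with perfect accuracy", {
  panel <- toy_panel4()
  d <- planted_and_data(seed = 21, n_per = 25)
  m <- incremental_select(d, "A", panel, k = 5, seed = 1,
                          grid = small_grid())
  expect_setequal(m$selected, c("B", "C"))
  expect_equal(m$accuracy, 1)
  expect_gt(m$accuracy, m$base_accuracy)
})

test_that("a never-expressed target selects nothing and predicts zero", {
  panel <- toy_panel4()
  d <- planted_and_data(seed = 22)
  d$A <- 0L
  m <- incremental_select(d, "A", panel, k = 5, seed = 1,
                          grid = small_grid())
  expect_length(m$selected, 0)
  expect_equal(m$accuracy, 1)
  expect_true(all(m$base_result$predictions$pred == 0))
})

test_that("trace obeys its invariants and max_inputs caps selection", {
  panel <- toy_panel4()
  d <- planted_and_data(seed = 23, n_per = 25)
  m <- incremental_select(d, "A", panel, k = 5, seed = 2,
                          grid = small_grid())
  expect_equal(nrow(m$trace), length(m$selected))
  if (nrow(m$trace) > 1) {
    expect_true(all(diff(m$trace$accuracy) > 0))
  }
  expect_true(all(m$trace$accuracy > m$base_accuracy))
  expect_false(m$target %in% m$selected)
  expect_false(any(duplicated(m$selected)))

  m0 <- incremental_select(d, "A", panel, k = 5, seed = 2,
                           grid = small_grid(), max_inputs = 0)
  expect_length(m0$selected, 0)
  expect_equal(m0$accuracy, m0$base_accuracy)

  m1 <- incremental_select(d, "A", panel, k = 5, seed = 2,
                           grid = small_grid(), max_inputs = 1)
  expect_lte(length(m1$selected), 1)
})

test_that("greedy selection never ends below the base accuracy", {
  panel <- toy_panel4()
  for (s in 1:5) {
    d <- generate_synthetic(synth_config(
      panel = panel, group_counts = two_type_counts(15),
      mode = "bernoulli", seed = 30 + s
    ))
    m <- incremental_select(d, "B", panel, k = 5, seed = s,
                            grid = small_grid(), retune = "once")
    expect_gte(m$accuracy, m$base_accuracy)
  }
})

test_that("selection is deterministic given the seed", {
  panel <- toy_panel4()
  d <- planted_and_data(seed = 24, n_per = 25)
  m1 <- incremental_select(d, "A", panel, k = 5, seed = 9,
                           grid = small_grid())
  m2 <- incremental_select(d, "A", panel, k = 5, seed = 9,
                           grid = small_grid())
  expect_identical(m1$selected, m2$selected)
  expect_identical(m1$accuracy, m2$accuracy)
  expect_identical(m1$trace, m2$trace)
})

test_that("fitting all targets returns one model per gene with summaries", {
  panel <- toy_panel4()
  d <- planted_and_data(seed = 25, n_per = 25)
  fit <- fit_all_targets(d, panel, k = 5, seed = 1, grid = small_grid())
  expect_length(fit, 4)
  expect_named(fit, panel$alias)
  s <- tidy(fit)
  expect_equal(nrow(s), 4)
  # the planted target improves over base; its inputs are B and C
  expect_gt(s$accuracy[s$target == "A"], s$base_accuracy[s$target == "A"])
  g <- glance(fit)
  expect_equal(g$n_targets, 4)
  path <- withr::local_tempfile(fileext = ".json")
  write_isvm_json(fit, path)
  dump <- jsonlite::read_json(path)
  expect_length(dump, 4)
  expect_equal(unlist(dump$A$selected), fit$A$selected_genes)
})

test_that("accuracy table covers the three classifiers per target", {
  panel <- toy_panel4()
  d <- planted_and_data(seed = 26, n_per = 20)
  fit <- fit_all_targets(d, panel, k = 5, seed = 1, grid = small_grid(),
                         retune = "once", targets = c("A", "B"))
  tab <- model_accuracy_table(d, fit, panel)
  expect_equal(names(tab), c("target", "lr", "svm_base", "isvm"))
  expect_equal(nrow(tab), 2)
  expect_true(all(tab$isvm >= tab$svm_base))
})

test_that("generalization predictions apply fitted models to new neurons", {
  panel <- toy_panel4()
  d <- planted_and_data(seed = 27, n_per = 25)
  gen <- generate_synthetic(synth_config(
    panel = panel,
    group_counts = tibble::tibble(layer = "L2/3", morphology = "PC",
                                  etype = "cFS", n = 10),
    frequencies = c(A = 0.3, B = 0.7, C = 0.7, D = 0.4),
    planted_rules = list(list(target = "A", formula = "B AND C")),
    mode = "planted", seed = 28
  ))
  m <- incremental_select(d, "A", panel, k = 5, seed = 1,
                          grid = small_grid())
  ga <- generalization_accuracy(structure(list(A = m), class = "isvm_fit"),
                                d, gen, panel)
  # the planted relation transfers to the unseen LME combination
  expect_gt(ga$overall, 0.8)
  expect_equal(ga$per_type$n, 10)
})
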