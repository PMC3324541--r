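test_that("the printed single-input pattern yields its known truth table", {
  panel <- hcn3_panel()
  d <- hcn3_kv14_pattern()
  tab <- truth_table(d, "Kv1.4", "HCN3", panel)
  expect_equal(nrow(tab), 2)
  expect_equal(tab$n1[tab$pattern == 1], 3)
  expect_equal(tab$n0[tab$pattern == 1], 0)
  expect_equal(tab$n1[tab$pattern == 0], 1)
  expect_equal(tab$n0[tab$pattern == 0], 5)
  expect_equal(sum(tab$n1) + sum(tab$n0), nrow(d))
})

test_that("minimizing the printed pattern returns the identity rule at 8/9", {
  panel <- hcn3_panel()
  d <- hcn3_kv14_pattern()
  tab <- truth_table(d, "Kv1.4", "HCN3", panel)
  f <- minimize_boolean(tab)
  expect_equal(deparse_formula(f), "HCN3")
  occ <- rule_occurrence(f, d, "Kv1.4", panel)
  expect_equal(occ$n_match, 8)
  expect_equal(occ$n_total, 9)
})

test_that("degenerate truth tables are handled", {
  panel <- toy_panel4()
  d <- planted_and_data(seed = 31)[1:10, ]
  d$A <- 1L
  tab <- truth_table(d, "A", "B", panel)
  expect_equal(deparse_formula(minimize_boolean(tab)), "TRUE")
  # constant-TRUE rule on an all-1 target matches every neuron
  occ <- rule_occurrence(parse_formula("TRUE"), d, "A", panel)
  expect_equal(occ$n_match, occ$n_total)

  # all observed rows tied -> no rule
  d2 <- d[1:4, ]
  d2$B <- c(1L, 1L, 0L, 0L)
  d2$A <- c(1L, 0L, 1L, 0L)
  expect_null(minimize_boolean(truth_table(d2, "A", "B", panel)))

  # all neurons identical -> single-row table
  d3 <- d[rep(1, 5), ]
  expect_equal(nrow(truth_table(d3, "A", c("B", "C"), panel)), 1)
})

test_that("rule occurrence equals per-neuron brute-force evaluation", {
  panel <- toy_panel4()
  withr::with_seed(7, {
    for (rep in 1:10) {
      d <- planted_and_data(seed = 100 + rep)[sample(40, 15), ]
      f <- parse_formula(sample(c("B", "NOT B", "B AND C", "B OR NOT C"), 1))
      occ <- rule_occurrence(f, d, "A", panel)
      manual <- sum(vapply(seq_len(nrow(d)), function(i) {
        as.integer(eval_formula(f, d[i, ], panel = panel)) == d$A[[i]]
      }, logical(1)))
      expect_equal(occ$n_match, manual)
      expect_equal(occ$n_total, 15)
    }
  })
})

test_that("candidate types are those with strict per-type improvement", {
  base_pt <- tibble::tibble(lme = c("t1", "t2"), n = c(5, 5),
                            accuracy = c(0.6, 0.9))
  model <- list(
    base_result = list(per_type_accuracy = base_pt),
    final_result = list(per_type_accuracy = base_pt)
  )
  expect_length(candidate_types(model), 0)
  model$final_result$per_type_accuracy$accuracy <- c(0.8, 0.9)
  expect_equal(candidate_types(model), "t1")
})

test_that("planted rules are extracted in the types where they hold", {
  panel <- toy_panel4()
  d <- planted_and_data(seed = 33, n_per = 25)
  fit <- fit_all_targets(d, panel, k = 5, seed = 1, grid = small_grid(),
                         targets = "A")
  rules <- extract_rules(d, fit, panel)
  expect_gt(nrow(rules), 0)
  hit <- rules[rules$target == "A" & rules$retained, ]
  expect_gt(nrow(hit), 0)
  planted <- parse_formula("B AND C")
  expect_true(any(vapply(seq_len(nrow(hit)), function(i) {
    formula_equivalent(parse_formula(hit$formula[[i]]), planted,
                       panel$alias)
  }, logical(1))))
})

test_that("raising the occurrence threshold only shrinks the retained set", {
  panel <- toy_panel4()
  d <- planted_and_data(seed = 34, n_per = 25, fn_rate = 0.1)
  fit <- fit_all_targets(d, panel, k = 5, seed = 1, grid = small_grid(),
                         targets = "A")
  r80 <- extract_rules(d, fit, panel, min_occurrence = 0.8)
  r100 <- extract_rules(d, fit, panel, min_occurrence = 1.0)
  expect_lte(sum(r100$retained), sum(r80$retained))
  # same rules, different retention flags
  expect_equal(r80$formula, r100$formula)
})

test_that("consistency groups merge equivalent formulas and flag conflicts", {
  rules <- tibble::tibble(
    target = c("HCN2", "HCN2", "Kv1.2", "Kv1.2", "Kv1.2"),
    lme = c("L2/3 LBC-cAD", "L5 MC-cAD", "t1", "t2", "t3"),
    formula = c("Kv3.1 AND Kv2.2 AND NOT Kv4.3",
                "NOT Kv3.1 AND NOT Kv2.2 AND NOT Kv4.3",
                "Kv3.1 AND Kv3.2", "Kv3.1 AND Kv3.2", "Kv3.1 AND Kv3.2"),
    n_match = 4L, n_total = 5L, occurrence = 0.8, retained = TRUE,
    dropped_context = "", constant = FALSE
  )
  class(rules) <- c("rule_set", class(rules))
  g <- cross_type_consistency(rules)
  # contradictory formulas for one target stay distinct and are flagged
  hcn2 <- g[g$target == "HCN2", ]
  expect_equal(nrow(hcn2), 2)
  expect_true(all(!hcn2$consistent))
  expect_true(all(!hcn2$target_consistent))
  kv12 <- g[g$target == "Kv1.2", ]
  expect_equal(kv12$n_types, 3L)
  expect_true(kv12$consistent)
  expect_true(kv12$target_consistent)

  # syntactically different but equivalent formulas group together after
  # canonicalization
  panel_order <- c("Kv2.2", "Kv3.1", "Kv3.2", "Kv4.3", "HCN2", "Kv1.2")
  raw <- c("Kv3.1 AND Kv3.2", "NOT (NOT Kv3.1 OR NOT Kv3.2)")
  canon <- vapply(raw, function(t) {
    deparse_formula(canonicalize_formula(parse_formula(t), panel_order))
  }, character(1))
  expect_equal(canon[[1]], canon[[2]])
})

test_that("rules round-trip through TSV and JSON writers", {
  panel <- toy_panel4()
  d <- planted_and_data(seed = 35, n_per = 25)
  fit <- fit_all_targets(d, panel, k = 5, seed = 1, grid = small_grid(),
                         targets = "A")
  rules <- extract_rules(d, fit, panel)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_rules(rules, tsv)
  back <- readr::read_tsv(tsv, show_col_types = FALSE)
  expect_equal(back$formula, rules$formula)
  js <- withr::local_tempfile(fileext = ".json")
  write_rules_json(rules, js)
  jback <- jsonlite::read_json(js)
  expect_length(jback, nrow(rules))
  # formula text round-trips through the grammar
  for (txt in rules$formula) {
    expect_true(formula_equivalent(parse_formula(txt),
                                   parse_formula(deparse_formula(
                                     parse_formula(txt)))))
  }
})
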