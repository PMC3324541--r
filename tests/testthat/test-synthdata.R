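test_that("generation is deterministic and honours degenerate frequencies", {
  panel <- toy_panel4()
  cfg <- synth_config(panel = panel, group_counts = two_type_counts(10),
                      frequencies = c(A = 0, B = 0, C = 0, D = 0),
                      mode = "bernoulli", seed = 1)
  d <- generate_synthetic(cfg)
  expect_true(all(d[, panel$alias] == 0))
  expect_identical(generate_synthetic(cfg), d)

  cfg1 <- synth_config(panel = panel, group_counts = two_type_counts(10),
                       frequencies = c(A = 1, B = 1, C = 1, D = 1),
                       mode = "bernoulli", seed = 1)
  expect_true(all(generate_synthetic(cfg1)[, panel$alias] == 1))
})

test_that("empirical frequencies concentrate around the configured values", {
  panel <- toy_panel4()
  cfg <- synth_config(
    panel = panel,
    group_counts = tibble::tibble(layer = "L4", morphology = "PC",
                                  etype = "cAD", n = 2000),
    frequencies = c(A = 0.1, B = 0.23, C = 0.4, D = 0.5),
    mode = "bernoulli", seed = 2
  )
  d <- generate_synthetic(cfg)
  for (g in panel$alias) {
    p <- attr(d, "frequencies")[[g]]
    se <- sqrt(p * (1 - p) / 2000)
    expect_lt(abs(mean(d[[g]]) - p), 3 * se)
  }
})

test_that("noise-free planted rules hold exactly in their types", {
  panel <- toy_panel4()
  d <- planted_and_data(seed = 3, fn_rate = 0)
  expect_true(all(d$A == (d$B & d$C)))

  # restricted to one type: elsewhere the target is plain Bernoulli
  cfg <- synth_config(
    panel = panel, group_counts = two_type_counts(50),
    frequencies = c(A = 0.3, B = 0.7, C = 0.7, D = 0.4),
    planted_rules = list(list(target = "A", formula = "B AND C",
                              types = "L2/3 MC-cAD")),
    mode = "planted", seed = 4
  )
  d2 <- generate_synthetic(cfg)
  d2 <- add_lme_key(d2)
  inside <- d2[d2$lme == "L2/3 MC-cAD", ]
  outside <- d2[d2$lme != "L2/3 MC-cAD", ]
  expect_true(all(inside$A == (inside$B & inside$C)))
  expect_false(all(outside$A == (outside$B & outside$C)))
})

test_that("false-negative noise only ever clears expressed bits", {
  panel <- toy_panel4()
  base <- synth_config(panel = panel, group_counts = two_type_counts(40),
                       frequencies = c(A = 0.5, B = 0.5, C = 0.5, D = 0.5),
                       mode = "bernoulli", seed = 5)
  clean <- generate_synthetic(base)
  noisy <- generate_synthetic(synth_config(
    panel = panel, group_counts = two_type_counts(40),
    frequencies = c(A = 0.5, B = 0.5, C = 0.5, D = 0.5),
    mode = "bernoulli", seed = 5, fn_rate = 0.3
  ))
  for (g in panel$alias) {
    expect_true(all(noisy[[g]] <= clean[[g]]))
  }
})

test_that("rule occurrence decays weakly with the false-negative rate", {
  panel <- toy_panel4()
  occ_at <- function(fn) {
    occs <- vapply(1:8, function(s) {
      d <- planted_and_data(seed = 200 + s, n_per = 40, fn_rate = fn)
      occ <- rule_occurrence(parse_formula("B AND C"), d, "A", panel)
      occ$n_match / occ$n_total
    }, numeric(1))
    mean(occs)
  }
  o <- vapply(c(0, 0.2, 0.5), occ_at, numeric(1))
  expect_equal(o[[1]], 1)
  expect_true(all(diff(o) < 0))
})

test_that("misconfigured generators fail loudly", {
  panel <- toy_panel4()
  expect_error(synth_config(panel = panel,
                            planted_rules = list(list(target = "A",
                                                      formula = "A AND B"))),
               "target as an input")
  expect_error(synth_config(panel = panel,
                            planted_rules = list(list(target = "A",
                                                      formula = "Z"))),
               "unknown gene")
  expect_error(synth_config(panel = panel, fn_rate = 2), "fn_rate")
  expect_error(synth_config(panel = panel,
                            frequencies = c(A = 2, B = 0, C = 0, D = 0)),
               "\\[0, 1\\]")
})
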