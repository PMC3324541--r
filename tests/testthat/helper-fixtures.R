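# Shared fixtures: tiny panels, planted-rule datasets and a small
# hyper-parameter grid that keeps SVM fits fast in tests.

toy_panel4 <- function() gene_panel(c("A", "B", "C", "D"))
toy_panel5 <- function() gene_panel(c("A", "B", "C", "D", "E"))

small_grid <- function() make_hyper_grid(-3, 3, 3)

two_type_counts <- function(n_per = 20) {
  tibble::tibble(layer = c("L2/3", "L4"), morphology = c("MC", "PC"),
                 etype = c("cAD", "cFS"), n = c(n_per, n_per))
}

# Dataset where target A is exactly B AND C (no noise), input frequencies
# high enough that A is roughly balanced.
planted_and_data <- function(seed = 1, n_per = 20, fn_rate = 0) {
  generate_synthetic(synth_config(
    panel = toy_panel4(),
    group_counts = two_type_counts(n_per),
    frequencies = c(A = 0.3, B = 0.7, C = 0.7, D = 0.4),
    planted_rules = list(list(target = "A", formula = "B AND C")),
    mode = "planted", fn_rate = fn_rate, seed = seed
  ))
}

# Three neurons with one incomplete label, for filtering tests.
tiny_labelled_data <- function() {
  tibble::tibble(
    neuron_id = c("n1", "n2", "n3"),
    layer = c("L2/3", "L4", "L5"),
    morphology = c("MC", "PC", "LBC"),
    etype = c("cAD", NA, "cFS"),
    A = c(1L, 0L, 1L), B = c(0L, 1L, 1L),
    C = c(0L, 0L, 0L), D = c(1L, 1L, 0L)
  )
}

# The printed single-input pattern: 9 neurons of one type; the target is
# expressed in the 3 neurons where the input is expressed, absent in 5 of
# the 6 where it is not, and expressed once discordantly.
hcn3_kv14_pattern <- function() {
  tibble::tibble(
    neuron_id = sprintf("n%d", 1:9),
    layer = "L5", morphology = "MC", etype = "cAD",
    HCN3 = c(1L, 1L, 1L, 0L, 0L, 0L, 0L, 0L, 0L),
    Kv1.4 = c(1L, 1L, 1L, 0L, 0L, 0L, 0L, 0L, 1L)
  )
}

hcn3_panel <- function() gene_panel(c("HCN3", "Kv1.4"))
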