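# Independent oracles used to check the implementation by a second route.

# O(n^2) pairwise AUC: P(score_pos > score_neg) + 0.5 P(tie).
auc_pairwise <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  if (length(pos) == 0 || length(neg) == 0) return(NA_real_)
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + (p > q) + 0.5 * (p == q)
  }
  total / (length(pos) * length(neg))
}

# Brute-force count of non-empty subsets of an n-set.
subset_count_bruteforce <- function(n) {
  count <- 0L
  for (mask in 1:(2^n - 1)) count <- count + 1L
  count
}

# Re-implementation of the model/generalization partition predicate,
# straight from its definition, on a group-count tibble.
split_predicate_bruteforce <- function(groups, min_count) {
  assign <- character(nrow(groups))
  model <- groups$n >= min_count
  assign[model] <- "model"
  for (i in which(!model)) {
    ok <- any(model & groups$layer == groups$layer[i]) &&
      any(model & groups$morphology == groups$morphology[i]) &&
      any(model & groups$etype == groups$etype[i])
    assign[i] <- if (ok) "generalization" else "discarded"
  }
  assign
}

# Closed-form one-way ANOVA on a list of numeric groups.
anova_closed_form <- function(groups) {
  k <- length(groups)
  n <- sum(lengths(groups))
  grand <- mean(unlist(groups))
  ssb <- sum(vapply(groups, function(g) length(g) * (mean(g) - grand)^2,
                    numeric(1)))
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  f <- (ssb / (k - 1)) / (ssw / (n - k))
  p <- stats::pf(f, k - 1, n - k, lower.tail = FALSE)
  list(F = f, p = p)
}

# Exhaustive subset-search counterpart of the greedy selection: the best
# cross-validated accuracy achievable over every subset of candidate input
# genes, using the same folds and grid protocol as incremental_select.
exhaustive_best_accuracy <- function(data, target, panel, k, seed, grid,
                                     kernels = c("rbf", "linear")) {
  target_alias <- ionrules:::resolve_genes(target, panel)
  folds <- ionrules:::make_folds(nrow(data), k, seed)
  candidates <- setdiff(panel$alias, target_alias)
  best <- -Inf
  for (mask in 0:(2^length(candidates) - 1)) {
    inputs <- candidates[bitwAnd(mask, 2^(seq_along(candidates) - 1)) != 0]
    gs <- grid_search(data, target_alias, panel, inputs, grid = grid,
                      kernels = kernels, folds = folds)
    best <- max(best, gs$result$cv_accuracy)
  }
  best
}

# Truth-table equality of two formulas over an explicit variable set.
formulas_agree_bruteforce <- function(f, g, vars) {
  n <- length(vars)
  for (mask in 0:(2^n - 1)) {
    bits <- as.integer(bitwAnd(mask, 2^(seq_len(n) - 1)) != 0)
    row <- stats::setNames(as.list(bits), vars)
    row <- lapply(row, function(b) b)
    if (!identical(eval_formula(f, row), eval_formula(g, row))) return(FALSE)
  }
  TRUE
}
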