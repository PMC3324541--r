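#' Truth table of a target gene over its input genes within one type
#'
#' Counts, for each observed combination of the input-gene bits, how many
#' neurons of the type express the target and how many do not. Unobserved
#' combinations are absent (they become don't-cares during minimization).
#'
#' @param data Expression tibble restricted to one neuronal type.
#' @param target Target gene (display name or alias).
#' @param inputs Ordered character vector of input genes (non-empty). The
#'   first input maps to the least-significant bit of `pattern`.
#' @param panel A [gene_panel()].
#' @return Tibble with one row per observed input pattern: one 0/1 column
#'   per input (aliases), `pattern` (integer encoding), `n1` and `n0`
#'   (target expressed / not expressed counts).
#' @export
truth_table <- function(data, target, inputs, panel) {
  if (length(inputs) == 0) stop("inputs must be non-empty", call. = FALSE)
  if (nrow(data) == 0) stop("no neurons in this type", call. = FALSE)
  target <- resolve_genes(target, panel)
  inputs <- resolve_genes(inputs, panel)
  bits <- as.matrix(data[, inputs, drop = FALSE])
  pattern <- as.integer(bits %*% 2^(seq_along(inputs) - 1))
  y <- as.integer(data[[target]])
  tab <- tibble::tibble(pattern = pattern, y = y)
  out <- dplyr::summarise(dplyr::group_by(tab, .data$pattern),
                          n1 = sum(.data$y == 1L), n0 = sum(.data$y == 0L),
                          .groups = "drop")
  for (i in seq_along(inputs)) {
    out[[inputs[[i]]]] <- as.integer(bitwAnd(out$pattern,
                                             bitwShiftL(1L, i - 1L)) != 0L)
  }
  out <- out[, c(inputs, "pattern", "n1", "n0")]
  attr(out, "inputs") <- inputs
  attr(out, "target") <- target
  out
}

#' Minimize a truth table into a Boolean expression rule
#'
#' The majority target label of each observed input pattern defines the
#' on/off-set; patterns with tied counts and unobserved patterns are
#' don't-cares. The result is the exact minimal DNF (Quine-McCluskey),
#' with ties between equal-size covers broken by fewer literals and then
#' lexicographic order, so minimization is deterministic.
#'
#' @param table A truth table from [truth_table()].
#' @return A `bool_formula` (possibly constant `TRUE`/`FALSE`), or `NULL`
#'   when every observed pattern is tied so no rule is supported.
#' @export
minimize_boolean <- function(table) {
  inputs <- attr(table, "inputs")
  if (is.null(inputs)) {
    inputs <- setdiff(names(table), c("pattern", "n1", "n0"))
  }
  on <- table$pattern[table$n1 > table$n0]
  off <- table$pattern[table$n1 < table$n0]
  if (length(on) == 0 && length(off) == 0) return(NULL)
  n_pat <- bitwShiftL(1L, length(inputs))
  dc <- setdiff(0:(n_pat - 1L), c(on, off))
  qm_minimize(on, dc, inputs)
}

#' Neuronal types where the full model outperforms the base model
#'
#' Rules are only extracted in types where adding the selected input genes
#' actually improved held-out prediction, i.e. where the iSVM per-type CV
#' accuracy strictly exceeds the base (LME-only) per-type accuracy.
#'
#' @param model An `isvm_model` (carries both per-type accuracy tables).
#' @return Character vector of LME keys.
#' @export
candidate_types <- function(model) {
  base <- model$base_result$per_type_accuracy
  full <- model$final_result$per_type_accuracy
  j <- dplyr::inner_join(base, full, by = "lme", suffix = c("_base", "_isvm"))
  j$lme[j$accuracy_isvm > j$accuracy_base]
}

#' Occurrence of a rule in a set of neurons
#'
#' A neuron matches the rule when the formula, evaluated on its input-gene
#' bits, equals its observed target bit. Occurrence is reported as
#' `n_match` out of `n_total`.
#'
#' @param formula A `bool_formula`.
#' @param data Expression tibble (typically one neuronal type).
#' @param target Target gene (display name or alias).
#' @param panel A [gene_panel()].
#' @return Named list `n_match`, `n_total`.
#' @export
rule_occurrence <- function(formula, data, target, panel) {
  target <- resolve_genes(target, panel)
  pred <- eval_formula(formula, data, panel = panel)
  list(n_match = sum(as.integer(pred) == as.integer(data[[target]])),
       n_total = nrow(data))
}

#' Extract combinatorial expression rules from fitted models
#'
#' For every fitted target model with at least one selected input gene, and
#' every neuronal type where the model outperformed the LME-only base
#' ([candidate_types()]): input genes constant within the type are dropped
#' (recorded as context), the within-type truth table is built and
#' minimized ([minimize_boolean()]), and the rule's occurrence is counted.
#' Rules at or above `min_occurrence` are marked retained; sub-threshold
#' rules are kept in the output with `retained = FALSE` so exceptions
#' remain visible.
#'
#' @param data Expression tibble (the model dataset).
#' @param fit An `isvm_fit` (or a named list of `isvm_model`s).
#' @param panel A [gene_panel()].
#' @param min_occurrence Minimum occurrence fraction to retain a rule
#'   (default 0.8).
#' @return A tibble of class `rule_set`: `target`, `lme`, `formula`
#'   (canonical text), `n_match`, `n_total`, `occurrence`, `retained`,
#'   `dropped_context` (within-type-constant inputs as `gene=bit`,
#'   comma-separated), `constant` (logical: formula is constant
#'   TRUE/FALSE). The parsed formulas are in `attr(x, "formulas")`.
#' @export
extract_rules <- function(data, fit, panel, min_occurrence = 0.8) {
  data <- add_lme_key(data)
  rows <- list()
  formulas <- list()
  for (model in unclass(fit)) {
    if (length(model$selected) == 0) next
    for (type in candidate_types(model)) {
      sub <- data[data$lme == type, , drop = FALSE]
      if (nrow(sub) == 0) next
      const <- vapply(model$selected,
                      function(g) length(unique(sub[[g]])) == 1, logical(1))
      context <- if (any(const)) {
        paste(sprintf("%s=%d", model$selected[const],
                      vapply(model$selected[const],
                             function(g) sub[[g]][[1]], integer(1))),
              collapse = ",")
      } else ""
      inputs <- model$selected[!const]
      if (length(inputs) == 0) next
      tab <- truth_table(sub, model$target, inputs, panel)
      f <- minimize_boolean(tab)
      if (is.null(f)) next
      f <- canonicalize_formula(f, var_order = panel$alias)
      occ <- rule_occurrence(f, sub, model$target, panel)
      rows[[length(rows) + 1]] <- tibble::tibble(
        target = model$target_gene,
        lme = type,
        formula = deparse_formula(f),
        n_match = occ$n_match,
        n_total = occ$n_total,
        occurrence = occ$n_match / occ$n_total,
        retained = occ$n_match / occ$n_total >= min_occurrence,
        dropped_context = context,
        constant = f$ast$op == "const"
      )
      formulas[[length(formulas) + 1]] <- f
    }
  }
  out <- if (length(rows)) dplyr::bind_rows(rows) else tibble::tibble(
    target = character(), lme = character(), formula = character(),
    n_match = integer(), n_total = integer(), occurrence = numeric(),
    retained = logical(), dropped_context = character(), constant = logical()
  )
  attr(out, "formulas") <- formulas
  attr(out, "min_occurrence") <- min_occurrence
  class(out) <- c("rule_set", class(out))
  out
}

#' Group rules that are consistent across neuronal types
#'
#' Partitions extracted rules by target and canonical formula. A group
#' found in two or more types is flagged consistent; a target whose types
#' disagree on the formula appears in multiple groups and is flagged
#' inconsistent.
#'
#' @param rules A `rule_set` (canonical formulas, as produced by
#'   [extract_rules()]).
#' @return Tibble: `target`, `formula`, `types` (comma-separated LME keys),
#'   `n_types`, `consistent` (>= 2 types with this formula),
#'   `target_consistent` (all of the target's types share one formula).
#' @export
cross_type_consistency <- function(rules) {
  if (nrow(rules) == 0) {
    return(tibble::tibble(target = character(), formula = character(),
                          types = character(), n_types = integer(),
                          consistent = logical(),
                          target_consistent = logical()))
  }
  g <- dplyr::summarise(
    dplyr::group_by(tibble::as_tibble(rules), .data$target, .data$formula),
    types = paste(sort(.data$lme), collapse = ", "),
    n_types = dplyr::n(), .groups = "drop_last"
  )
  g <- dplyr::mutate(g,
                     consistent = .data$n_types >= 2L,
                     target_consistent = dplyr::n() == 1L)
  dplyr::ungroup(g)
}

#' Write extracted rules
#'
#' `write_rules()` emits a TSV (target, type, formula text, occurrence);
#' `write_rules_json()` additionally serializes the parsed formula ASTs.
#'
#' @param rules A `rule_set`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_rules <- function(rules, path) {
  readr::write_tsv(tibble::as_tibble(rules), path)
  invisible(path)
}

#' @rdname write_rules
#' @export
write_rules_json <- function(rules, path) {
  items <- lapply(seq_len(nrow(rules)), function(i) {
    list(
      target = rules$target[[i]],
      lme = rules$lme[[i]],
      formula = rules$formula[[i]],
      ast = attr(rules, "formulas")[[i]]$ast,
      n_match = rules$n_match[[i]],
      n_total = rules$n_total[[i]],
      retained = rules$retained[[i]]
    )
  })
  jsonlite::write_json(items, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
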