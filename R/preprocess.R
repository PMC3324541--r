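#' Filter neurons with complete LME labels
#'
#' Neurons are excluded from modelling when any of the three defining
#' characteristics (layer, morphology, electrical type) is unknown. Row
#' order is preserved in both partitions.
#'
#' @param data Expression tibble.
#' @return A list with tibbles `kept` (complete labels) and `dropped`.
#' @export
filter_complete <- function(data) {
  ok <- !is.na(data$layer) & !is.na(data$morphology) & !is.na(data$etype)
  list(kept = data[ok, , drop = FALSE], dropped = data[!ok, , drop = FALSE])
}

#' Split neurons into model and generalization datasets
#'
#' Groups complete-labelled neurons by their LME triple and partitions the
#' groups: groups with at least `min_count` neurons form the model dataset;
#' smaller groups whose layer, morphology and electrical type each occur
#' somewhere in the model dataset (but whose triple does not) form the
#' generalization dataset; the remaining groups are discarded (their L, M or
#' E value is unrepresented in the model data, so predictions for them would
#' extrapolate over an unseen categorical level).
#'
#' @param data Expression tibble with complete LME labels (see
#'   [filter_complete()]).
#' @param min_count Minimum group size for the model dataset (default 4).
#' @return An object of class `lme_split`: a list with tibbles `model`,
#'   `generalization`, `discarded` (each with an `lme` column) and a group
#'   summary tibble `groups` (`lme`, `layer`, `morphology`, `etype`, `n`,
#'   `assignment`). [tidy()] returns `groups`; [glance()] a one-row summary.
#' @export
split_model_generalization <- function(data, min_count = 4) {
  if (!is.numeric(min_count) || length(min_count) != 1 || min_count < 1) {
    stop("min_count must be a positive integer", call. = FALSE)
  }
  if (anyNA(data$layer) || anyNA(data$morphology) || anyNA(data$etype)) {
    stop("data contains neurons with incomplete LME labels; ",
         "run filter_complete() first", call. = FALSE)
  }
  data <- add_lme_key(data)
  groups <- dplyr::count(data, .data$layer, .data$morphology, .data$etype,
                         .data$lme, name = "n")

  is_model <- groups$n >= min_count
  mod <- groups[is_model, , drop = FALSE]
  rest <- groups[!is_model, , drop = FALSE]
  is_gen <- rest$layer %in% mod$layer &
    rest$morphology %in% mod$morphology &
    rest$etype %in% mod$etype
  groups$assignment <- NA_character_
  groups$assignment[is_model] <- "model"
  groups$assignment[!is_model] <- ifelse(is_gen, "generalization", "discarded")
  groups <- dplyr::arrange(groups, dplyr::desc(.data$assignment == "model"),
                           .data$lme)
  groups <- groups[, c("lme", "layer", "morphology", "etype", "n",
                       "assignment")]

  pick <- function(a) {
    data[data$lme %in% groups$lme[groups$assignment == a], , drop = FALSE]
  }
  out <- list(
    model = pick("model"),
    generalization = pick("generalization"),
    discarded = pick("discarded"),
    groups = groups,
    min_count = min_count
  )
  class(out) <- "lme_split"
  out
}

#' @export
print.lme_split <- function(x, ...) {
  g <- x$groups
  n_of <- function(a) sum(g$n[g$assignment == a])
  k_of <- function(a) sum(g$assignment == a)
  cat("<lme_split> min_count = ", x$min_count, "\n",
      "  model:          ", n_of("model"), " neurons in ",
      k_of("model"), " LME groups\n",
      "  generalization: ", n_of("generalization"), " neurons in ",
      k_of("generalization"), " LME groups\n",
      "  discarded:      ", n_of("discarded"), " neurons in ",
      k_of("discarded"), " LME groups\n", sep = "")
  invisible(x)
}

#' @rdname split_model_generalization
#' @param x An `lme_split`.
#' @param ... Unused.
#' @method tidy lme_split
#' @export
tidy.lme_split <- function(x, ...) x$groups

#' @rdname split_model_generalization
#' @method glance lme_split
#' @export
glance.lme_split <- function(x, ...) {
  g <- x$groups
  tibble::tibble(
    n_model = sum(g$n[g$assignment == "model"]),
    n_model_groups = sum(g$assignment == "model"),
    n_generalization = sum(g$n[g$assignment == "generalization"]),
    n_generalization_groups = sum(g$assignment == "generalization"),
    n_discarded = sum(g$n[g$assignment == "discarded"]),
    n_discarded_groups = sum(g$assignment == "discarded"),
    min_count = x$min_count
  )
}

#' Write a split report
#'
#' One TSV row per LME group: key, neuron count and assignment.
#'
#' @param split An `lme_split`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_split_report <- function(split, path) {
  readr::write_tsv(split$groups, path)
  invisible(path)
}
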