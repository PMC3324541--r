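#' Incremental forward selection of input genes (iSVM)
#'
#' Greedy wrapper feature selection for one target gene. The base model
#' predicts the target's binary expression from the LME labels alone; at
#' each iteration every not-yet-selected candidate gene is appended to the
#' current inputs and evaluated by cross-validated accuracy (with its own
#' hyper-parameter grid search when `retune = "always"`). The best candidate
#' is retained only if it strictly improves on the current accuracy; the
#' loop stops when no candidate improves or `max_inputs` is reached.
#'
#' One fold assignment (derived from `seed`) is shared by the base model and
#' every candidate evaluation of this target, so all comparisons are paired
#' and the stopping rule reacts to the candidate, not to fold resampling.
#' Candidates constant across the dataset are skipped (they cannot inform
#' and would create spurious ties).
#'
#' @inheritParams grid_search
#' @param max_inputs Maximum number of input genes to select (default
#'   unlimited; selection normally stops on its own).
#' @param retune `"always"` re-tunes C/gamma by full grid search at every
#'   candidate evaluation (default); `"once"` tunes the base model only and
#'   reuses its parameters, which is much cheaper for large panels.
#' @return An object of class `isvm_model`: list with `target`,
#'   `selected` (ordered aliases), `params`, `base_accuracy`, `accuracy`,
#'   `base_result` / `final_result` (`ion_eval`s) and a per-iteration
#'   `trace` tibble.
#' @export
incremental_select <- function(data, target, panel, k = 10, seed = 1,
                               max_inputs = Inf,
                               grid = make_hyper_grid(),
                               kernels = c("rbf", "linear"),
                               retune = c("always", "once"),
                               use_lme = TRUE) {
  retune <- match.arg(retune)
  target <- resolve_genes(target, panel)
  folds <- make_folds(nrow(data), k, seed)

  base <- grid_search(data, target, panel, character(), grid = grid,
                      kernels = kernels, use_lme = use_lme, folds = folds)
  params <- base$best
  best_result <- base$result
  best_acc <- best_result$cv_accuracy

  selected <- character()
  trace <- list()
  constant <- panel$alias[vapply(panel$alias,
                                 function(g) length(unique(data[[g]])) == 1,
                                 logical(1))]
  iter <- 0L
  while (length(selected) < max_inputs) {
    iter <- iter + 1L
    candidates <- setdiff(panel$alias, c(target, selected, constant))
    if (length(candidates) == 0) break
    cand_acc <- numeric(length(candidates))
    cand_fit <- vector("list", length(candidates))
    for (i in seq_along(candidates)) {
      inputs <- c(selected, candidates[[i]])
      if (retune == "always") {
        gs <- grid_search(data, target, panel, inputs, grid = grid,
                          kernels = kernels, use_lme = use_lme, folds = folds)
        cand_acc[[i]] <- gs$result$cv_accuracy
        cand_fit[[i]] <- gs
      } else {
        ev <- cv_accuracy(data, target, panel, inputs, params = params,
                          use_lme = use_lme, folds = folds)
        cand_acc[[i]] <- ev$cv_accuracy
        cand_fit[[i]] <- list(best = params, result = ev)
      }
    }
    best_i <- which(cand_acc >= max(cand_acc) - 1e-12)[[1]] # lowest panel index
    if (!(cand_acc[[best_i]] > best_acc + 1e-12)) break
    selected <- c(selected, candidates[[best_i]])
    params <- cand_fit[[best_i]]$best
    best_result <- cand_fit[[best_i]]$result
    best_acc <- cand_acc[[best_i]]
    trace[[length(trace) + 1]] <- tibble::tibble(
      iteration = length(selected),
      n_candidates = length(candidates),
      gene = panel$gene[match(candidates[[best_i]], panel$alias)],
      accuracy = best_acc,
      C = params$C, gamma = params$gamma, kernel = params$kernel
    )
  }
  trace <- if (length(trace)) dplyr::bind_rows(trace) else tibble::tibble(
    iteration = integer(), n_candidates = integer(), gene = character(),
    accuracy = numeric(), C = numeric(), gamma = numeric(),
    kernel = character()
  )
  structure(list(
    target = target,
    target_gene = panel$gene[match(target, panel$alias)],
    selected = selected,
    selected_genes = panel$gene[match(selected, panel$alias)],
    params = params,
    base_params = base$best,
    base_accuracy = base$result$cv_accuracy,
    accuracy = best_acc,
    base_result = base$result,
    final_result = best_result,
    trace = trace,
    k = k, seed = seed, retune = retune
  ), class = "isvm_model")
}

#' @export
print.isvm_model <- function(x, ...) {
  cat("<isvm_model> target ", x$target_gene, "\n",
      "  base accuracy ", sprintf("%.3f", x$base_accuracy),
      " -> iSVM accuracy ", sprintf("%.3f", x$accuracy), "\n",
      "  inputs: ", if (length(x$selected)) {
        paste(x$selected_genes, collapse = ", ")
      } else "(none)", "\n", sep = "")
  invisible(x)
}

#' @rdname incremental_select
#' @param x An `isvm_model`.
#' @param ... Unused.
#' @method tidy isvm_model
#' @export
tidy.isvm_model <- function(x, ...) x$trace

#' @rdname incremental_select
#' @method glance isvm_model
#' @export
glance.isvm_model <- function(x, ...) {
  tibble::tibble(
    target = x$target_gene,
    n_selected = length(x$selected),
    base_accuracy = x$base_accuracy,
    accuracy = x$accuracy,
    auc = x$final_result$auc,
    C = x$params$C,
    gamma = x$params$gamma,
    kernel = x$params$kernel
  )
}

#' Fit an iSVM model for every panel gene
#'
#' Runs [incremental_select()] independently per target, each with its own
#' fold seed derived from `seed`.
#'
#' @inheritParams incremental_select
#' @param targets Optional subset of genes to fit (default the whole panel).
#' @param progress Print one line per fitted target (default `FALSE`).
#' @return A named list of `isvm_model`s of class `isvm_fit`; [tidy()]
#'   returns one summary row per target.
#' @export
fit_all_targets <- function(data, panel, k = 10, seed = 1,
                            grid = make_hyper_grid(),
                            kernels = c("rbf", "linear"),
                            retune = c("always", "once"),
                            max_inputs = Inf, targets = NULL,
                            progress = FALSE) {
  retune <- match.arg(retune)
  targets <- if (is.null(targets)) panel$alias else resolve_genes(targets, panel)
  models <- vector("list", length(targets))
  names(models) <- targets
  for (i in seq_along(targets)) {
    models[[i]] <- incremental_select(
      data, targets[[i]], panel, k = k,
      seed = seed + 7919L * match(targets[[i]], panel$alias),
      max_inputs = max_inputs, grid = grid, kernels = kernels, retune = retune
    )
    if (progress) {
      m <- models[[i]]
      message(sprintf("%-8s base %.3f -> %.3f (%d inputs)", m$target_gene,
                      m$base_accuracy, m$accuracy, length(m$selected)))
    }
  }
  structure(models, class = "isvm_fit", panel = panel, seed = seed)
}

#' @export
print.isvm_fit <- function(x, ...) {
  cat("<isvm_fit> ", length(x), " target models\n", sep = "")
  print(tidy(x))
  invisible(x)
}

#' @rdname fit_all_targets
#' @param x An `isvm_fit`.
#' @param ... Unused.
#' @method tidy isvm_fit
#' @export
tidy.isvm_fit <- function(x, ...) {
  dplyr::bind_rows(lapply(unclass(x), glance))
}

#' @rdname fit_all_targets
#' @method glance isvm_fit
#' @export
glance.isvm_fit <- function(x, ...) {
  s <- tidy(x)
  tibble::tibble(
    n_targets = nrow(s),
    mean_base_accuracy = mean(s$base_accuracy),
    mean_accuracy = mean(s$accuracy),
    mean_auc = mean(s$auc, na.rm = TRUE),
    max_selected = max(c(0L, s$n_selected))
  )
}

#' Accuracy table across classifiers
#'
#' Cross-validated accuracy per target gene for the logistic-regression
#' baseline, the LME-only base model and the full iSVM model.
#'
#' @param data Expression tibble the models were fitted on.
#' @param fit An `isvm_fit`.
#' @param panel A [gene_panel()].
#' @param cutoff LR probability cutoff (default: panel mean frequency).
#' @return Tibble with columns `target`, `lr`, `svm_base`, `isvm`.
#' @export
model_accuracy_table <- function(data, fit, panel, cutoff = NULL) {
  rows <- lapply(unclass(fit), function(m) {
    lr <- lr_baseline(data, m$target, panel, cutoff = cutoff,
                      k = m$k, seed = m$seed)
    tibble::tibble(target = m$target_gene, lr = lr$cv_accuracy,
                   svm_base = m$base_accuracy, isvm = m$accuracy)
  })
  dplyr::bind_rows(rows)
}

#' Predict expression of new neurons with a fitted iSVM model
#'
#' Refits the final model (selected inputs + tuned parameters) on the full
#' training data and predicts the target gene for new neurons, e.g. the
#' generalization dataset of held-out LME combinations.
#'
#' @param object An `isvm_model`.
#' @param newdata Expression tibble of new neurons (complete LME labels).
#' @param data Training expression tibble.
#' @param panel A [gene_panel()].
#' @param ... Unused.
#' @return Integer vector of 0/1 predictions for `newdata`.
#' @export
predict.isvm_model <- function(object, newdata, data, panel, ...) {
  Xtr <- encode_features(data, panel, object$selected, use_lme = TRUE)
  Xte <- encode_features(newdata, panel, object$selected, use_lme = TRUE)
  y <- as.integer(data[[object$target]])
  svm_fit_predict(Xtr, y, Xte, object$params)$pred
}

#' Generalization accuracy on held-out LME combinations
#'
#' Mean prediction accuracy of the fitted models on neurons whose LME triple
#' was not part of the training data, overall and per LME type.
#'
#' @param fit An `isvm_fit` trained on `data`.
#' @param data Training expression tibble.
#' @param newdata Generalization expression tibble.
#' @param panel A [gene_panel()].
#' @return List with `overall` (fraction) and `per_type` tibble
#'   (`lme`, `n`, `accuracy`).
#' @export
generalization_accuracy <- function(fit, data, newdata, panel) {
  per_gene <- lapply(unclass(fit), function(m) {
    pred <- predict(m, newdata, data, panel)
    tibble::tibble(
      lme = lme_key(newdata$layer, newdata$morphology, newdata$etype),
      correct = pred == as.integer(newdata[[m$target]])
    )
  })
  long <- dplyr::bind_rows(per_gene)
  per_type <- dplyr::summarise(dplyr::group_by(long, .data$lme),
                               n = dplyr::n(), accuracy = mean(.data$correct),
                               .groups = "drop")
  list(overall = mean(long$correct), per_type = per_type)
}

#' Write fitted models as JSON
#'
#' One object per target: selection order, tuned parameters and the
#' per-iteration accuracy trace.
#'
#' @param fit An `isvm_fit`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_isvm_json <- function(fit, path) {
  dump <- lapply(unclass(fit), function(m) {
    list(
      target = m$target_gene,
      selected = m$selected_genes,
      params = list(C = m$params$C, gamma = m$params$gamma,
                    kernel = m$params$kernel),
      base_accuracy = m$base_accuracy,
      accuracy = m$accuracy,
      trace = m$trace
    )
  })
  jsonlite::write_json(dump, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Plot per-target accuracies of the fitted models
#'
#' Dot-and-line comparison of base and iSVM cross-validated accuracy per
#' target gene.
#'
#' @param object An `isvm_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot isvm_fit
#' @export
autoplot.isvm_fit <- function(object, ...) {
  s <- tidy(object)
  long <- tidyr::pivot_longer(
    s[, c("target", "base_accuracy", "accuracy")],
    cols = c("base_accuracy", "accuracy"),
    names_to = "model", values_to = "cv_accuracy"
  )
  long$model <- ifelse(long$model == "accuracy", "iSVM", "base SVM")
  long$target <- factor(long$target, levels = s$target)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$target, y = .data$cv_accuracy,
                                     colour = .data$model,
                                     group = .data$model)) +
    ggplot2::geom_point() +
    ggplot2::geom_line() +
    ggplot2::labs(x = NULL, y = "10-fold CV accuracy", colour = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}
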