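#' Resample a dataset gene-wise from Bernoulli marginals
#'
#' Builds the random-data null: the neurons, their LME labels and group
#' counts are kept exactly, but every expression bit is redrawn
#' independently from a Bernoulli distribution at the gene's observed
#' marginal expression frequency, destroying any between-gene structure.
#'
#' @param data Expression tibble.
#' @param frequencies A `freq_profile` (see [expression_frequencies()]) or
#'   named numeric vector of per-gene probabilities; default: frequencies
#'   observed in `data`.
#' @param panel A [gene_panel()].
#' @param seed Integer seed.
#' @return An expression tibble of the same shape as `data`.
#' @export
bernoulli_resample <- function(data, panel, frequencies = NULL, seed = 1) {
  if (is.null(frequencies)) frequencies <- expression_frequencies(data, panel)
  if (inherits(frequencies, "freq_profile")) {
    p <- stats::setNames(frequencies$frequency, frequencies$alias)
  } else {
    p <- frequencies
    names(p) <- resolve_genes(names(p), panel)
  }
  p <- p[panel$alias]
  if (anyNA(p)) stop("frequencies must cover the panel", call. = FALSE)
  if (any(p < 0 | p > 1)) {
    stop("frequencies must lie in [0, 1]", call. = FALSE)
  }
  withr::with_seed(seed, {
    for (g in panel$alias) {
      data[[g]] <- stats::rbinom(nrow(data), 1, p[[g]])
    }
  })
  data
}

#' Accuracy of a random-input model (riiSVM)
#'
#' Draws `n_inputs` input genes uniformly without replacement (excluding
#' the target) and a random (C, gamma) grid point, then returns the
#' cross-validated accuracy of that arbitrary model. Across many draws this
#' yields the accuracy distribution expected when the input genes and
#' hyper-parameters carry no information about the target.
#'
#' @inheritParams cv_accuracy
#' @param n_inputs Number of random input genes (0 to panel size - 1).
#' @param grid Hyper-parameter grid to draw from.
#' @return CV accuracy (fraction).
#' @export
riisvm_run <- function(data, target, panel, n_inputs, seed = 1,
                       grid = make_hyper_grid(), k = 10) {
  target <- resolve_genes(target, panel)
  if (n_inputs > nrow(panel) - 1) {
    stop("n_inputs must be at most panel size - 1", call. = FALSE)
  }
  draw <- withr::with_seed(seed, {
    list(
      inputs = sample(setdiff(panel$alias, target), n_inputs),
      row = sample.int(nrow(grid), 1)
    )
  })
  params <- hyper_params(grid$C[[draw$row]], grid$gamma[[draw$row]], "rbf")
  ev <- cv_accuracy(data, target, panel, draw$inputs, params = params,
                    k = k, seed = seed + 1L)
  ev$cv_accuracy
}

#' Compare accuracy distributions of the three model kinds
#'
#' One-way ANOVA across the three accuracy samples plus pairwise two-sample
#' Student's t-tests (equal variances).
#'
#' @param a,b,c Numeric accuracy samples (length >= 2 each), conventionally
#'   iSVM, riiSVM and rdiSVM.
#' @param labels Group labels (default `c("isvm", "riisvm", "rdisvm")`).
#' @return List with `anova_F`, `anova_p`, `pairwise` (tibble: `pair`,
#'   `t`, `p`) and `degenerate` (`TRUE` when every group has zero
#'   within-group variance, leaving the F statistic undefined).
#' @export
compare_accuracy_distributions <- function(a, b, c,
                                           labels = c("isvm", "riisvm",
                                                      "rdisvm")) {
  groups <- list(a, b, c)
  if (any(vapply(groups, length, integer(1)) < 2)) {
    stop("each sample needs at least 2 values", call. = FALSE)
  }
  x <- unlist(groups)
  g <- factor(rep(labels, vapply(groups, length, integer(1))),
              levels = labels)
  degenerate <- all(vapply(groups, stats::var, numeric(1)) == 0)
  if (degenerate) {
    anova_F <- NA_real_
    anova_p <- NA_real_
  } else {
    fit <- stats::aov(x ~ g)
    s <- summary(fit)[[1]]
    anova_F <- s[["F value"]][[1]]
    anova_p <- s[["Pr(>F)"]][[1]]
  }
  pairs <- utils::combn(3, 2, simplify = FALSE)
  pairwise <- dplyr::bind_rows(lapply(pairs, function(ij) {
    gi <- groups[[ij[[1]]]]
    gj <- groups[[ij[[2]]]]
    if (stats::var(gi) == 0 && stats::var(gj) == 0) {
      tt <- list(statistic = NA_real_, p.value = NA_real_)
    } else {
      tt <- stats::t.test(gi, gj, var.equal = TRUE)
    }
    tibble::tibble(pair = paste(labels[ij], collapse = " vs "),
                   t = unname(tt$statistic), p = tt$p.value)
  }))
  list(anova_F = anova_F, anova_p = anova_p, pairwise = pairwise,
       degenerate = degenerate)
}

#' Run the null-model experiment
#'
#' Per iteration, three accuracy streams are produced for every target:
#' the fitted iSVM models re-evaluated under freshly randomized CV folds
#' (the models are deterministic given the data, so fold noise is their
#' only stochastic source); riiSVM models with random inputs and
#' hyper-parameters drawn jointly; and rdiSVM models fitted from scratch by
#' [incremental_select()] on a freshly Bernoulli-resampled dataset. All
#' streams are independently seeded and reproducible.
#'
#' @inheritParams fit_all_targets
#' @param n_iter Number of iterations (the study used 1000; scale down for
#'   exploratory runs — rdiSVM refits every target per iteration).
#' @param fit Optional pre-fitted `isvm_fit`; fitted here when `NULL`.
#' @param n_inputs_max riiSVM draws its input count uniformly from
#'   1..`n_inputs_max` (default 5, the largest selection observed in
#'   practice).
#' @return A tibble of class `null_experiment` with columns `kind`
#'   (`isvm`/`riisvm`/`rdisvm`), `iteration`, `target`, `accuracy` and, for
#'   rdiSVM rows, `n_selected`.
#' @export
null_experiment <- function(data, panel, n_iter = 1000, seed = 1,
                            fit = NULL, k = 10, grid = make_hyper_grid(),
                            kernels = c("rbf", "linear"),
                            retune = c("always", "once"),
                            n_inputs_max = 5, targets = NULL) {
  retune <- match.arg(retune)
  if (n_iter < 1) stop("n_iter must be >= 1", call. = FALSE)
  n_inputs_max <- min(n_inputs_max, nrow(panel) - 1L)
  targets <- if (is.null(targets)) panel$alias else resolve_genes(targets, panel)
  if (is.null(fit)) {
    fit <- fit_all_targets(data, panel, k = k, seed = seed, grid = grid,
                           kernels = kernels, retune = retune,
                           targets = targets)
  }
  freqs <- expression_frequencies(data, panel)
  rows <- list()
  for (it in seq_len(n_iter)) {
    it_seed <- seed + 104729L * it
    # iSVM: fixed models, re-randomized folds
    for (m in unclass(fit)) {
      ev <- cv_accuracy(data, m$target, panel, m$selected,
                        params = m$params, k = k, seed = it_seed)
      rows[[length(rows) + 1]] <- tibble::tibble(
        kind = "isvm", iteration = it, target = m$target_gene,
        accuracy = ev$cv_accuracy, n_selected = NA_integer_
      )
    }
    # riiSVM: random inputs and hyper-parameters, jointly redrawn
    for (j in seq_along(targets)) {
      tg <- targets[[j]]
      rs <- it_seed + 31L * j
      n_in <- withr::with_seed(rs, sample.int(n_inputs_max, 1))
      acc <- riisvm_run(data, tg, panel, n_in, seed = rs + 1L,
                        grid = grid, k = k)
      rows[[length(rows) + 1]] <- tibble::tibble(
        kind = "riisvm", iteration = it,
        target = panel$gene[match(tg, panel$alias)],
        accuracy = acc, n_selected = n_in
      )
    }
    # rdiSVM: full refit on resampled data
    rd <- bernoulli_resample(data, panel, freqs, seed = it_seed + 7L)
    for (j in seq_along(targets)) {
      m <- incremental_select(rd, targets[[j]], panel, k = k,
                              seed = it_seed + 13L * j, grid = grid,
                              kernels = kernels, retune = retune)
      rows[[length(rows) + 1]] <- tibble::tibble(
        kind = "rdisvm", iteration = it, target = m$target_gene,
        accuracy = m$accuracy, n_selected = length(m$selected)
      )
    }
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("null_experiment", class(out))
  out
}

#' Summarize a null experiment
#'
#' Per-iteration mean accuracies per kind, compared by
#' [compare_accuracy_distributions()]. With a single iteration only the
#' per-kind means are returned.
#'
#' @param x A `null_experiment`.
#' @return List with `means` (tibble: kind, mean_accuracy) and, when
#'   `n_iter >= 2`, `tests` (see [compare_accuracy_distributions()]).
#' @export
null_summary <- function(x) {
  per_iter <- dplyr::summarise(
    dplyr::group_by(tibble::as_tibble(x), .data$kind, .data$iteration),
    accuracy = mean(.data$accuracy), .groups = "drop"
  )
  means <- dplyr::summarise(dplyr::group_by(per_iter, .data$kind),
                            mean_accuracy = mean(.data$accuracy),
                            .groups = "drop")
  out <- list(means = means)
  if (all(table(per_iter$kind) >= 2)) {
    get <- function(kk) per_iter$accuracy[per_iter$kind == kk]
    out$tests <- compare_accuracy_distributions(get("isvm"), get("riisvm"),
                                                get("rdisvm"))
  }
  out
}

#' Boxplots of the three accuracy distributions
#'
#' @param object A `null_experiment`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot null_experiment
#' @export
autoplot.null_experiment <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$kind <- factor(df$kind, levels = c("isvm", "riisvm", "rdisvm"),
                    labels = c("iSVM", "riiSVM", "rdiSVM"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$kind, y = .data$accuracy,
                                   fill = .data$kind)) +
    ggplot2::geom_boxplot(show.legend = FALSE) +
    ggplot2::scale_fill_manual(values = c("red", "blue", "green")) +
    ggplot2::labs(x = NULL, y = "10-fold CV accuracy") +
    ggplot2::theme_minimal()
}
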