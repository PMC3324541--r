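#' Configure a full pipeline run
#'
#' Collects every setting of the end-to-end analysis: input data (a
#' delimited expression table or a synthetic-data config), gene panel, CV
#' and grid-search settings, split threshold, rule threshold and
#' null-experiment size.
#'
#' @param input Path to a CSV/TSV expression table, or `NULL` to simulate.
#' @param synth A [synth_config()] used when `input` is `NULL`.
#' @param panel A [gene_panel()]; defaults to the synth config's panel or,
#'   for file input, the default panel.
#' @param seed Integer base seed for every stochastic step.
#' @param k CV folds (default 10).
#' @param grid_lo,grid_hi,grid_n Hyper-parameter grid: exponent range and
#'   points per axis (defaults -15, 15, 31; see [make_hyper_grid()]).
#' @param kernels Kernels for the grid search.
#' @param retune Hyper-parameter handling during incremental selection
#'   (see [incremental_select()]).
#' @param max_inputs Cap on selected input genes per target.
#' @param min_count Model/generalization split threshold (default 4).
#' @param min_occurrence Rule retention threshold (default 0.8).
#' @param n_iter Null-experiment iterations (0 skips the null stage).
#' @param targets Optional subset of target genes.
#' @return A list of class `run_config`.
#' @export
run_config <- function(input = NULL, synth = NULL, panel = NULL, seed = 1,
                       k = 10, grid_lo = -15, grid_hi = 15, grid_n = 31,
                       kernels = c("rbf", "linear"),
                       retune = c("always", "once"), max_inputs = Inf,
                       min_count = 4, min_occurrence = 0.8, n_iter = 0,
                       targets = NULL) {
  retune <- match.arg(retune)
  if (is.null(input) && is.null(synth)) {
    synth <- synth_config(seed = seed)
  }
  if (is.null(panel)) {
    panel <- if (!is.null(synth)) synth$panel else default_panel()
  }
  structure(list(input = input, synth = synth, panel = panel, seed = seed,
                 k = k, grid_lo = grid_lo, grid_hi = grid_hi,
                 grid_n = grid_n, kernels = kernels, retune = retune,
                 max_inputs = max_inputs, min_count = min_count,
                 min_occurrence = min_occurrence, n_iter = n_iter,
                 targets = targets),
            class = "run_config")
}

#' Run the full analysis pipeline
#'
#' Sequences the stages: load or simulate the expression table; filter and
#' split into model/generalization datasets; fit per-target incremental
#' models on the model data; optionally run the null experiment; extract
#' and group Boolean rules; build and export the predictivity network. All
#' artifacts plus a manifest of every setting are written to `out_dir`;
#' re-running with the same config reproduces them bit-for-bit. A failure
#' in any stage removes the partial artifacts and aborts with a
#' stage-named error.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (created if needed).
#' @param stages Character subset of
#'   `c("simulate", "split", "fit", "null", "rules", "network")` or
#'   `"all"`. Later stages pull in the stages they need.
#' @param quiet Suppress progress messages (default `TRUE`).
#' @return Invisibly, a list with the in-memory results (`data`, `split`,
#'   `fit`, `rules`, `network`, ...).
#' @export
run_pipeline <- function(config, out_dir, stages = "all", quiet = TRUE) {
  stopifnot(inherits(config, "run_config"))
  all_stages <- c("simulate", "split", "fit", "null", "rules", "network")
  if (identical(stages, "all")) stages <- all_stages
  stages <- match.arg(stages, all_stages, several.ok = TRUE)
  # dependency closure
  if (any(c("null", "rules", "network") %in% stages)) stages <- c(stages, "fit")
  if ("fit" %in% stages) stages <- c(stages, "split")
  stages <- intersect(all_stages, unique(stages))

  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  written <- character()
  emit <- function(fun, file) {
    path <- file.path(out_dir, file)
    fun(path)
    written <<- c(written, path)
    path
  }
  say <- function(...) if (!quiet) message(...)
  res <- list(config = config)

  run_stage <- function(name, body) {
    tryCatch(body(), error = function(e) {
      unlink(written)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  panel <- config$panel
  grid <- make_hyper_grid(config$grid_lo, config$grid_hi, config$grid_n)

  run_stage("load", function() {
    if (!is.null(config$input)) {
      res$data <<- read_expression_table(config$input, panel)
    } else {
      res$data <<- generate_synthetic(config$synth)
      if ("simulate" %in% stages) {
        emit(function(p) write_expression_table(res$data, p, panel),
             "simulated_expression.tsv")
      }
    }
    say("loaded ", nrow(res$data), " neurons")
  })

  if ("split" %in% stages) {
    run_stage("split", function() {
      fc <- filter_complete(res$data)
      res$split <<- split_model_generalization(fc$kept, config$min_count)
      res$dropped <<- fc$dropped
      emit(function(p) write_split_report(res$split, p), "split_report.tsv")
      res$frequencies <<- expression_frequencies(res$split$model, panel)
      emit(function(p) readr::write_tsv(tibble::as_tibble(res$frequencies), p),
           "frequencies.tsv")
      say("split: ", nrow(res$split$model), " model / ",
          nrow(res$split$generalization), " generalization neurons")
    })
  }

  if ("fit" %in% stages) {
    run_stage("fit", function() {
      res$fit <<- fit_all_targets(
        res$split$model, panel, k = config$k, seed = config$seed,
        grid = grid, kernels = config$kernels, retune = config$retune,
        max_inputs = config$max_inputs, targets = config$targets,
        progress = !quiet
      )
      emit(function(p) write_isvm_json(res$fit, p), "isvm_models.json")
      acc <- model_accuracy_table(res$split$model, res$fit, panel)
      res$accuracy_table <<- acc
      emit(function(p) readr::write_tsv(acc, p), "accuracy_table.tsv")
      if (nrow(res$split$generalization) > 0) {
        gen <- generalization_accuracy(res$fit, res$split$model,
                                       res$split$generalization, panel)
        res$generalization <<- gen
        emit(function(p) {
          jsonlite::write_json(list(overall = gen$overall,
                                    per_type = gen$per_type),
                               p, auto_unbox = TRUE, digits = NA)
        }, "generalization.json")
      }
    })
  }

  if ("null" %in% stages && config$n_iter > 0) {
    run_stage("null", function() {
      res$null <<- null_experiment(
        res$split$model, panel, n_iter = config$n_iter, seed = config$seed,
        fit = res$fit, k = config$k, grid = grid, kernels = config$kernels,
        retune = config$retune, targets = config$targets
      )
      emit(function(p) readr::write_tsv(tibble::as_tibble(res$null), p),
           "null_long.tsv")
      s <- null_summary(res$null)
      emit(function(p) {
        jsonlite::write_json(
          list(means = s$means,
               anova_F = s$tests$anova_F %||% NA,
               anova_p = s$tests$anova_p %||% NA,
               pairwise = s$tests$pairwise %||% NULL),
          p, auto_unbox = TRUE, digits = NA)
      }, "null_summary.json")
    })
  }

  if ("rules" %in% stages) {
    run_stage("rules", function() {
      res$rules <<- extract_rules(res$split$model, res$fit, panel,
                                  config$min_occurrence)
      emit(function(p) write_rules(res$rules, p), "rules.tsv")
      emit(function(p) write_rules_json(res$rules, p), "rules.json")
      emit(function(p) readr::write_tsv(cross_type_consistency(res$rules), p),
           "rule_consistency.tsv")
      say(sum(res$rules$retained), " rule(s) at or above the occurrence ",
          "threshold")
    })
  }

  if ("network" %in% stages) {
    run_stage("network", function() {
      res$network <<- build_network(res$fit, panel)
      emit(function(p) export_network(res$network, p, "sif"), "network.sif")
      emit(function(p) export_network(res$network, p, "graphml"),
           "network.graphml")
      emit(function(p) export_network(res$network, p, "dot"), "network.dot")
      emit(function(p) readr::write_tsv(degree_table(res$network), p),
           "degree_table.tsv")
    })
  }

  run_stage("manifest", function() {
    manifest <- list(
      package = "ionrules",
      version = as.character(utils::packageVersion("ionrules")),
      stages = stages,
      settings = {
        s <- unclass(config)[setdiff(names(config),
                                     c("panel", "synth", "targets"))]
        if (is.infinite(s$max_inputs)) s$max_inputs <- "unlimited"
        s
      },
      panel = panel$gene,
      synth = if (!is.null(config$synth)) {
        s <- config$synth
        list(mode = s$mode, seed = s$seed, fn_rate = s$fn_rate,
             n_groups = nrow(s$group_counts), n_neurons = sum(s$group_counts$n),
             n_rules = length(s$planted_rules))
      }
    )
    emit(function(p) {
      jsonlite::write_json(manifest, p, auto_unbox = TRUE, digits = NA,
                           pretty = TRUE, null = "null")
    }, "manifest.json")
  })

  invisible(res)
}
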