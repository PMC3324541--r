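#' Per-gene expression frequencies
#'
#' The fraction of neurons expressing each gene, plus the panel-wide mean.
#' In the study data the panel mean is low (about 23%), no gene exceeding
#' 50%; the per-gene frequencies are also the Bernoulli probabilities used
#' by the resampling null model ([bernoulli_resample()]).
#'
#' @param data Expression tibble.
#' @param panel A [gene_panel()].
#' @return A tibble of class `freq_profile` with columns `gene`, `alias`,
#'   `frequency`; the panel-wide mean is available via [glance()] or
#'   `attr(x, "overall_mean")`.
#' @export
expression_frequencies <- function(data, panel) {
  assert_expression_data(data, panel)
  if (nrow(data) == 0) {
    stop("need at least one neuron to compute frequencies", call. = FALSE)
  }
  freq <- vapply(panel$alias, function(g) mean(data[[g]]), numeric(1))
  out <- tibble::tibble(gene = panel$gene, alias = panel$alias,
                        frequency = unname(freq))
  attr(out, "overall_mean") <- mean(out$frequency)
  attr(out, "n_neurons") <- nrow(data)
  class(out) <- c("freq_profile", class(out))
  out
}

#' @rdname expression_frequencies
#' @param x A `freq_profile`.
#' @param ... Unused.
#' @method glance freq_profile
#' @export
glance.freq_profile <- function(x, ...) {
  tibble::tibble(
    n_neurons = attr(x, "n_neurons"),
    n_genes = nrow(x),
    overall_mean = attr(x, "overall_mean")
  )
}

#' @export
print.freq_profile <- function(x, ...) {
  cat("<freq_profile> ", nrow(x), " genes, ", attr(x, "n_neurons"),
      " neurons, overall mean ",
      sprintf("%.2f%%", 100 * attr(x, "overall_mean")), "\n", sep = "")
  NextMethod()
}

#' Plot expression frequencies
#'
#' Bar chart of per-gene expression frequency with the panel mean as a
#' dashed line.
#'
#' @param object A `freq_profile`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot freq_profile
#' @export
autoplot.freq_profile <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$gene <- factor(df$gene, levels = df$gene)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$gene, y = .data$frequency)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(yintercept = attr(object, "overall_mean"),
                        linetype = "dashed") +
    ggplot2::scale_y_continuous(labels = function(v) sprintf("%.0f%%", 100 * v)) +
    ggplot2::labs(x = NULL, y = "expression frequency") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}
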