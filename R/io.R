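#' Read a binary expression table
#'
#' Reads a delimited text file of neurons by (labels + genes) into a tidy
#' expression tibble: one row per neuron with columns `neuron_id`, `layer`,
#' `morphology`, `etype` (character; `NA` when the label is missing) followed
#' by one 0/1 integer column per panel gene, named by the gene's ASCII alias.
#'
#' The header must name an id column (`neuron_id` or `id`), `Layer`,
#' `Morphology`, `EType` (case-insensitive) and every panel gene (display
#' symbol or alias). Blank label cells become `NA`; expression cells are
#' parsed strictly as 0/1.
#'
#' @param path Path to a CSV or TSV file.
#' @param panel A [gene_panel()].
#' @param delim Field delimiter; `NULL` (default) sniffs tab vs comma from
#'   the header line.
#' @return A tibble of neurons (see Details).
#' @export
read_expression_table <- function(path, panel, delim = NULL) {
  if (is.null(delim)) {
    header <- readLines(path, n = 1L, encoding = "UTF-8")
    delim <- if (grepl("\t", header)) "\t" else ","
  }
  raw <- readr::read_delim(path, delim = delim, col_types = readr::cols(
    .default = readr::col_character()
  ), na = character(), show_col_types = FALSE, progress = FALSE)
  names(raw) <- trimws(names(raw))

  find_col <- function(cands) {
    hit <- match(tolower(cands), tolower(names(raw)))
    hit <- hit[!is.na(hit)]
    if (length(hit) == 0) {
      stop("missing required column: ", cands[[1]], call. = FALSE)
    }
    names(raw)[hit[[1]]]
  }
  id_col <- find_col(c("neuron_id", "id"))
  lay_col <- find_col("Layer")
  mor_col <- find_col("Morphology")
  ety_col <- find_col("EType")

  gene_cols <- character(nrow(panel))
  for (i in seq_len(nrow(panel))) {
    hit <- match(c(panel$alias[i], panel$gene[i]), names(raw))
    hit <- hit[!is.na(hit)]
    if (length(hit) == 0) {
      stop("missing required column: ", panel$gene[i], call. = FALSE)
    }
    gene_cols[i] <- names(raw)[hit[[1]]]
  }

  parse_label <- function(x, levels, what) {
    x <- trimws(x)
    x[!nzchar(x) | is.na(x)] <- NA_character_
    bad <- !is.na(x) & !(x %in% levels)
    if (any(bad)) {
      stop("invalid ", what, " value(s): ",
           paste(unique(x[bad]), collapse = ", "), call. = FALSE)
    }
    x
  }

  out <- tibble::tibble(
    neuron_id = as.character(raw[[id_col]]),
    layer = parse_label(raw[[lay_col]], ionrules_layers(), "Layer"),
    morphology = parse_label(raw[[mor_col]], ionrules_morphologies(),
                             "Morphology"),
    etype = parse_label(raw[[ety_col]], ionrules_etypes(), "EType")
  )
  for (i in seq_len(nrow(panel))) {
    v <- trimws(raw[[gene_cols[i]]])
    bad <- !(v %in% c("0", "1"))
    if (any(bad)) {
      stop("non-binary expression value for gene ", panel$gene[i],
           " at row ", which(bad)[[1]], call. = FALSE)
    }
    out[[panel$alias[i]]] <- as.integer(v)
  }
  out
}

#' Write a binary expression table
#'
#' Inverse of [read_expression_table()]: gene columns are written under their
#' ASCII aliases and missing labels as empty cells, so a write/read
#' round-trip is bit-identical.
#'
#' @param data Expression tibble (as returned by [read_expression_table()]
#'   or [generate_synthetic()]).
#' @param path Output path.
#' @param panel A [gene_panel()].
#' @param delim Field delimiter (default tab).
#' @return `path`, invisibly.
#' @export
write_expression_table <- function(data, path, panel, delim = "\t") {
  assert_expression_data(data, panel)
  out <- data[, c("neuron_id", "layer", "morphology", "etype", panel$alias)]
  names(out)[2:4] <- c("Layer", "Morphology", "EType")
  readr::write_delim(out, path, delim = delim, na = "")
  invisible(path)
}

# Validate the tidy expression-table contract used across the package.
assert_expression_data <- function(data, panel) {
  need <- c("neuron_id", "layer", "morphology", "etype", panel$alias)
  miss <- setdiff(need, names(data))
  if (length(miss) > 0) {
    stop("expression data lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  for (g in panel$alias) {
    v <- data[[g]]
    if (anyNA(v) || !all(v %in% c(0L, 1L))) {
      stop("gene column ", g, " must be binary 0/1", call. = FALSE)
    }
  }
  invisible(data)
}

#' Compose and split LME type keys
#'
#' The LME key is the triple (cortical Layer, Morphological type, Electrical
#' type) written as e.g. `"L2/3 MC-cAD"`.
#'
#' @param layer,morphology,etype Character vectors.
#' @return Character vector of keys (`NA` where any component is missing).
#' @export
lme_key <- function(layer, morphology, etype) {
  ifelse(is.na(layer) | is.na(morphology) | is.na(etype),
         NA_character_,
         paste0(layer, " ", morphology, "-", etype))
}

#' Add an `lme` key column to an expression tibble
#'
#' @param data Expression tibble.
#' @return `data` with an `lme` column (after `etype`).
#' @export
add_lme_key <- function(data) {
  data$lme <- lme_key(data$layer, data$morphology, data$etype)
  dplyr::relocate(data, "lme", .after = "etype")
}
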