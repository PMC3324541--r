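#' Gene panels
#'
#' A gene panel is an ordered set of gene symbols with ASCII aliases. Symbols
#' may contain Greek letters (e.g. \eqn{Kv\beta1}); aliases transliterate
#' \eqn{\alpha} to "a" and \eqn{\beta} to "b" so that file headers and R
#' column names stay portable. Both forms are accepted on input; the alias is
#' used for in-memory column names, the display symbol for reporting.
#'
#' @param genes Character vector of gene symbols (display form). Must be
#'   unique, non-empty, and of length >= 2.
#' @param aliases Optional character vector of ASCII aliases, same length as
#'   `genes`. Defaults to an automatic transliteration of `genes`.
#' @return A tibble of class `gene_panel` with columns `gene` and `alias`.
#' @examples
#' gene_panel(c("HCN1", "Kv\u03b21"))
#' @export
gene_panel <- function(genes, aliases = NULL) {
  genes <- as.character(genes)
  if (length(genes) < 2) {
    stop("a gene panel needs at least 2 genes", call. = FALSE)
  }
  if (anyNA(genes) || any(!nzchar(genes))) {
    stop("gene symbols must be non-empty", call. = FALSE)
  }
  if (anyDuplicated(genes)) {
    stop("gene symbols must be unique", call. = FALSE)
  }
  if (is.null(aliases)) aliases <- ascii_alias(genes)
  aliases <- as.character(aliases)
  if (length(aliases) != length(genes) || anyDuplicated(aliases)) {
    stop("aliases must be unique and match the panel length", call. = FALSE)
  }
  out <- tibble::tibble(gene = genes, alias = aliases)
  class(out) <- c("gene_panel", class(out))
  out
}

#' Transliterate gene symbols to ASCII aliases
#'
#' Maps Greek alpha/beta to "a"/"b"; all other characters pass through.
#'
#' @param x Character vector of gene symbols.
#' @return Character vector of ASCII aliases.
#' @export
ascii_alias <- function(x) {
  x <- gsub("\u03b1", "a", x)
  gsub("\u03b2", "b", x)
}

#' Default ion-channel gene panel
#'
#' The 24 voltage-gated potassium, HCN, SK and calcium channel subunit genes
#' of the multiplex single-cell RT-PCR panel. The assay profiled 26 genes;
#' two panel members are not identifiable from the available description, so
#' `n_placeholders` can append clearly-labelled synthetic stand-ins
#' (`ICG25`, `ICG26`, ...) when a full-width panel is needed (e.g. for
#' synthetic data at study scale). Supply your own panel file via
#' [read_panel()] for full fidelity.
#'
#' @param n_placeholders Number of synthetic placeholder genes to append
#'   (default 0).
#' @return A [gene_panel()].
#' @export
default_panel <- function(n_placeholders = 0) {
  b <- "\u03b2"; a <- "\u03b1"
  genes <- c(
    "Kv1.1", "Kv1.2", "Kv1.4", "Kv1.6",
    paste0("Kv", b, "1"), paste0("Kv", b, "2"),
    "Kv2.1", "Kv2.2", "Kv3.1", "Kv3.2", "Kv3.3", "Kv4.3",
    "HCN1", "HCN2", "HCN3", "HCN4", "SK2",
    paste0("Ca", a, "1A"), paste0("Ca", a, "1B"),
    paste0("Ca", a, "1G"), paste0("Ca", a, "1I"),
    paste0("Ca", b, "1"), paste0("Ca", b, "3"), paste0("Ca", b, "4")
  )
  if (n_placeholders > 0) {
    genes <- c(genes, paste0("ICG", length(genes) + seq_len(n_placeholders)))
  }
  gene_panel(genes)
}

#' Read a gene panel from a file
#'
#' Plain-text panels list one symbol per line (lines starting with `#` are
#' skipped). JSON panels (detected by a `.json` extension) are either an
#' array of symbols or an object `{"genes": [...], "aliases": [...]}`.
#'
#' @param path Path to the panel file.
#' @return A [gene_panel()].
#' @export
read_panel <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    x <- jsonlite::read_json(path, simplifyVector = TRUE)
    if (is.character(x)) return(gene_panel(x))
    return(gene_panel(x$genes, aliases = x$aliases))
  }
  lines <- readLines(path, encoding = "UTF-8")
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  gene_panel(lines)
}

#' Count the theoretically possible gene combinations
#'
#' The number of distinct non-empty subsets of a panel, \eqn{2^n - 1}. For
#' the 26-gene panel this exceeds 67 million, which is why exhaustive
#' combinatorial screening is infeasible and a greedy wrapper is used
#' instead.
#'
#' @param panel_size Number of genes in the panel (positive integer; exact up
#'   to 53, the double-precision integer limit).
#' @return The exact count as a double.
#' @examples
#' panel_combination_count(26) # 67,108,863
#' @export
panel_combination_count <- function(panel_size) {
  if (!is.numeric(panel_size) || length(panel_size) != 1 ||
      panel_size < 1 || panel_size != floor(panel_size)) {
    stop("panel_size must be a positive integer", call. = FALSE)
  }
  if (panel_size > 53) {
    stop("exact integer arithmetic limited to panel_size <= 53", call. = FALSE)
  }
  2^panel_size - 1
}

# Label enumerations for cortical layer, morphological and electrical type.
ionrules_layers <- function() c("L2/3", "L4", "L5", "L6")
ionrules_morphologies <- function() c("LBC", "MC", "NBC", "PC")
ionrules_etypes <- function() c("cAD", "cFS", "dFS", "cST")

# Resolve a vector of gene names (display or alias, mixed) to panel aliases.
# Errors on unknown names.
resolve_genes <- function(x, panel) {
  hit <- match(x, panel$alias)
  miss <- is.na(hit)
  hit[miss] <- match(x[miss], panel$gene)
  if (anyNA(hit)) {
    stop("unknown gene(s): ", paste(x[is.na(hit)], collapse = ", "),
         call. = FALSE)
  }
  panel$alias[hit]
}

#' @export
print.gene_panel <- function(x, ...) {
  cat("<gene_panel> ", nrow(x), " genes\n", sep = "")
  NextMethod()
}
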