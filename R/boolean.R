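# Boolean formulas over gene literals.
#
# A formula is stored as a small AST of nested lists:
#   list(op = "var", name = <gene>)
#   list(op = "not", arg = <node>)
#   list(op = "and"|"or", args = list(<node>, ...))
#   list(op = "const", value = TRUE|FALSE)
# The user-facing text syntax is `A AND NOT B OR C` with optional
# parentheses; AND binds tighter than OR. Canonical form is the exact
# Quine-McCluskey-minimal DNF with deterministic tie-breaks, so logically
# equivalent formulas deparse identically.

new_bool_formula <- function(ast) {
  structure(list(ast = ast), class = "bool_formula")
}

bf_var <- function(name) list(op = "var", name = name)
bf_not <- function(arg) list(op = "not", arg = arg)
bf_and <- function(args) if (length(args) == 1) args[[1]] else list(op = "and", args = args)
bf_or <- function(args) if (length(args) == 1) args[[1]] else list(op = "or", args = args)
bf_const <- function(value) list(op = "const", value = value)

#' Parse a Boolean expression-rule formula
#'
#' Accepts the rule grammar `A AND NOT B OR C` with parentheses; `AND` binds
#' tighter than `OR`, `NOT` applies to the following atom. Gene names are
#' any tokens that are not the (case-insensitive) keywords.
#'
#' @param text Formula text.
#' @return A `bool_formula`.
#' @examples
#' parse_formula("Kv3.1 AND NOT HCN2 OR Kv3.2")
#' @export
parse_formula <- function(text) {
  toks <- regmatches(text, gregexpr("\\(|\\)|[^()[:space:]]+", text))[[1]]
  pos <- 1L
  peek <- function() if (pos <= length(toks)) toks[[pos]] else NA_character_
  take <- function() {
    t <- peek()
    pos <<- pos + 1L
    t
  }
  kw <- function(t, w) !is.na(t) && toupper(t) == w

  parse_expr <- function() {
    terms <- list(parse_term())
    while (kw(peek(), "OR")) {
      take()
      terms[[length(terms) + 1]] <- parse_term()
    }
    bf_or(terms)
  }
  parse_term <- function() {
    factors <- list(parse_factor())
    while (kw(peek(), "AND")) {
      take()
      factors[[length(factors) + 1]] <- parse_factor()
    }
    bf_and(factors)
  }
  parse_factor <- function() {
    t <- peek()
    if (is.na(t)) stop("unexpected end of formula", call. = FALSE)
    if (kw(t, "NOT")) {
      take()
      return(bf_not(parse_factor()))
    }
    if (t == "(") {
      take()
      e <- parse_expr()
      if (!identical(take(), ")")) {
        stop("unbalanced parenthesis in formula", call. = FALSE)
      }
      return(e)
    }
    if (t == ")") stop("unexpected ')' in formula", call. = FALSE)
    take()
    if (toupper(t) == "TRUE") return(bf_const(TRUE))
    if (toupper(t) == "FALSE") return(bf_const(FALSE))
    bf_var(t)
  }

  ast <- parse_expr()
  if (pos <= length(toks)) {
    stop("trailing tokens in formula: ",
         paste(toks[pos:length(toks)], collapse = " "), call. = FALSE)
  }
  new_bool_formula(ast)
}

#' Deparse a Boolean formula to rule text
#'
#' Produces the `A AND NOT B OR C` syntax; parentheses are inserted only
#' where precedence requires them, so canonical DNF deparse is
#' parenthesis-free.
#'
#' @param f A `bool_formula`.
#' @return A character string; `parse_formula(deparse_formula(f))` is
#'   logically identical to `f`.
#' @export
deparse_formula <- function(f) {
  wrap_child <- function(child, parent) {
    s <- dep(child)
    need <- (parent == "and" && child$op == "or") ||
      (parent == "not" && child$op %in% c("and", "or"))
    if (need) paste0("(", s, ")") else s
  }
  dep <- function(node) {
    switch(node$op,
      const = if (node$value) "TRUE" else "FALSE",
      var = node$name,
      not = paste0("NOT ", wrap_child(node$arg, "not")),
      and = paste(vapply(node$args, wrap_child, character(1),
                         parent = "and"), collapse = " AND "),
      or = paste(vapply(node$args, wrap_child, character(1),
                        parent = "or"), collapse = " OR ")
    )
  }
  dep(f$ast)
}

#' @export
print.bool_formula <- function(x, ...) {
  cat("<bool_formula> ", deparse_formula(x), "\n", sep = "")
  invisible(x)
}

#' @export
format.bool_formula <- function(x, ...) deparse_formula(x)

#' Variables appearing in a formula
#'
#' @param f A `bool_formula`.
#' @return Character vector of distinct gene names, in order of first
#'   appearance.
#' @export
formula_vars <- function(f) {
  vars <- character()
  walk <- function(node) {
    switch(node$op,
      var = vars[[length(vars) + 1]] <<- node$name,
      not = walk(node$arg),
      and = ,
      or = for (a in node$args) walk(a),
      const = invisible(NULL)
    )
  }
  walk(f$ast)
  unique(vars)
}

#' Evaluate a formula on binary expression data
#'
#' @param f A `bool_formula`.
#' @param data A data frame / tibble with one 0-1 (or logical) column per
#'   formula variable, or a named list of equal-length vectors.
#' @param panel Optional [gene_panel()] used to translate display gene
#'   names in the formula to column aliases.
#' @return Logical vector, one value per row of `data`.
#' @export
eval_formula <- function(f, data, panel = NULL) {
  lookup <- function(name) {
    if (!is.null(panel)) name <- resolve_genes(name, panel)
    if (is.null(data[[name]])) {
      stop("formula variable not found in data: ", name, call. = FALSE)
    }
    as.logical(data[[name]])
  }
  n <- if (is.data.frame(data)) nrow(data) else length(data[[1]])
  ev <- function(node) {
    switch(node$op,
      const = rep(node$value, n),
      var = lookup(node$name),
      not = !ev(node$arg),
      and = Reduce(`&`, lapply(node$args, ev)),
      or = Reduce(`|`, lapply(node$args, ev))
    )
  }
  ev(f$ast)
}

# ---- Quine-McCluskey ----

# Prime implicants of union(minterms, dontcares) over n_vars variables.
# Implicants are (value, mask) pairs; mask bits set = fixed positions; a
# pattern m is covered iff bitwAnd(m, mask) == value. Variable i (1-based)
# maps to bit 2^(i-1), i.e. the first variable is the least significant bit.
qm_primes <- function(terms, n_vars) {
  full_mask <- bitwShiftL(1L, n_vars) - 1L
  cur <- unique(data.frame(value = as.integer(terms), mask = full_mask))
  primes <- list()
  while (nrow(cur) > 0) {
    combined <- rep(FALSE, nrow(cur))
    nxt <- list()
    for (i in seq_len(nrow(cur))) {
      for (j in seq_len(nrow(cur))) {
        if (i == j || cur$mask[i] != cur$mask[j]) next
        d <- bitwXor(cur$value[i], cur$value[j])
        if (bitwAnd(d, d - 1L) == 0L && d != 0L) { # single-bit difference
          combined[i] <- TRUE
          nxt[[length(nxt) + 1]] <- c(value = bitwAnd(cur$value[i],
                                                      bitwNot(d)),
                                      mask = bitwAnd(cur$mask[i], bitwNot(d)))
        }
      }
    }
    for (i in which(!combined)) {
      primes[[length(primes) + 1]] <- c(value = cur$value[i],
                                        mask = cur$mask[i])
    }
    if (length(nxt) == 0) break
    nxt <- unique(do.call(rbind, nxt))
    cur <- data.frame(value = nxt[, "value"], mask = nxt[, "mask"])
  }
  unique(do.call(rbind, primes))
}

# Bit population count for small non-negative integers.
popcount <- function(x) {
  n <- 0L
  while (any(x > 0)) {
    n <- n + bitwAnd(x, 1L)
    x <- bitwShiftR(x, 1L)
  }
  n
}

# Implicant -> clause (named 0/1 vector over var_names; 1 = positive literal).
implicant_clause <- function(value, mask, var_names) {
  idx <- which(bitwAnd(mask, bitwShiftL(1L, seq_along(var_names) - 1L)) != 0L)
  bits <- as.integer(bitwAnd(value, bitwShiftL(1L, idx - 1L)) != 0L)
  stats::setNames(bits, var_names[idx])
}

clause_text <- function(clause) {
  if (length(clause) == 0) return("TRUE")
  paste(ifelse(clause == 1, names(clause), paste0("NOT ", names(clause))),
        collapse = " AND ")
}

# Minimal DNF cover of `minterms` using primes of minterms+dontcares.
# Preference: fewest clauses, then fewest total literals, then
# lexicographically smallest canonical text. Returns a bool_formula.
qm_minimize <- function(minterms, dontcares, var_names) {
  n_vars <- length(var_names)
  n_pat <- bitwShiftL(1L, n_vars)
  minterms <- as.integer(minterms)
  dontcares <- setdiff(as.integer(dontcares), minterms)
  if (length(minterms) == 0) return(new_bool_formula(bf_const(FALSE)))
  if (length(minterms) + length(dontcares) == n_pat) {
    return(new_bool_formula(bf_const(TRUE)))
  }
  primes <- qm_primes(c(minterms, dontcares), n_vars)
  covers <- function(i, m) {
    bitwAnd(m, primes[i, "mask"]) == primes[i, "value"]
  }
  cover_mat <- outer(seq_len(nrow(primes)), minterms, Vectorize(covers))
  cover_mat <- matrix(cover_mat, nrow = nrow(primes))

  lits <- vapply(seq_len(nrow(primes)),
                 function(i) popcount(primes[i, "mask"]), integer(1))
  best <- NULL
  for (size in seq_len(nrow(primes))) {
    subsets <- utils::combn(nrow(primes), size, simplify = FALSE)
    ok <- Filter(function(s) {
      all(colSums(cover_mat[s, , drop = FALSE]) > 0)
    }, subsets)
    if (length(ok) > 0) {
      key <- function(s) {
        cl <- lapply(s, function(i) {
          implicant_clause(primes[i, "value"], primes[i, "mask"], var_names)
        })
        txt <- sort(vapply(cl, clause_text, character(1)))
        list(nlit = sum(lits[s]), txt = paste(txt, collapse = " | "))
      }
      keys <- lapply(ok, key)
      nlit <- vapply(keys, function(k) k$nlit, numeric(1))
      txts <- vapply(keys, function(k) k$txt, character(1))
      best <- ok[[order(nlit, txts)[[1]]]]
      break
    }
  }
  clauses <- lapply(best, function(i) {
    implicant_clause(primes[i, "value"], primes[i, "mask"], var_names)
  })
  # canonical order: fewest literals first, then text
  ord <- order(vapply(clauses, length, integer(1)),
               vapply(clauses, clause_text, character(1)))
  clauses <- clauses[ord]
  ast <- bf_or(lapply(clauses, function(cl) {
    bf_and(lapply(seq_along(cl), function(i) {
      if (cl[[i]] == 1) bf_var(names(cl)[[i]]) else bf_not(bf_var(names(cl)[[i]]))
    }))
  }))
  new_bool_formula(ast)
}

#' Canonicalize a Boolean formula
#'
#' Rewrites a formula as its exact minimal disjunctive normal form
#' (Quine-McCluskey over the formula's full truth table), with literals
#' ordered by `var_order` and deterministic tie-breaks (fewest clauses,
#' then fewest literals, then lexicographic). Logically equivalent formulas
#' canonicalize to the identical form, and canonicalization is idempotent.
#'
#' @param f A `bool_formula`.
#' @param var_order Character vector fixing variable precedence (e.g. the
#'   panel's aliases); variables absent from it are appended alphabetically.
#' @return A canonical `bool_formula`.
#' @export
canonicalize_formula <- function(f, var_order = NULL) {
  vars <- formula_vars(f)
  vars <- c(intersect(var_order, vars), sort(setdiff(vars, var_order)))
  if (length(vars) == 0) {
    val <- eval_formula(f, stats::setNames(list(logical(1)), "..dummy.."))
    return(new_bool_formula(bf_const(val[[1]])))
  }
  if (length(vars) > 12) {
    stop("canonicalization supports at most 12 variables", call. = FALSE)
  }
  n_pat <- bitwShiftL(1L, length(vars))
  pats <- 0:(n_pat - 1L)
  cols <- lapply(seq_along(vars), function(i) {
    bitwAnd(pats, bitwShiftL(1L, i - 1L)) != 0L
  })
  names(cols) <- vars
  truth <- eval_formula(f, cols)
  qm_minimize(pats[truth], integer(0), vars)
}

#' Test two formulas for logical equivalence
#'
#' @param f,g `bool_formula`s.
#' @param var_order Optional variable ordering passed to
#'   [canonicalize_formula()].
#' @return `TRUE` if the formulas have identical truth tables over the
#'   union of their variables.
#' @export
formula_equivalent <- function(f, g, var_order = NULL) {
  vars <- union(formula_vars(f), formula_vars(g))
  vars <- c(intersect(var_order, vars), sort(setdiff(vars, var_order)))
  if (length(vars) == 0) {
    d <- stats::setNames(list(logical(1)), "..dummy..")
    return(identical(eval_formula(f, d), eval_formula(g, d)))
  }
  n_pat <- bitwShiftL(1L, length(vars))
  pats <- 0:(n_pat - 1L)
  cols <- lapply(seq_along(vars), function(i) {
    bitwAnd(pats, bitwShiftL(1L, i - 1L)) != 0L
  })
  names(cols) <- vars
  identical(eval_formula(f, cols), eval_formula(g, cols))
}
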