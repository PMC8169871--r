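#' Parse a gene-protein-reaction (GPR) rule
#'
#' Parses an infix boolean rule linking genes to the reaction they enable.
#' `or` joins isoenzymes (any one gene suffices), `and` joins members of an
#' enzyme complex (all genes required). `and` binds tighter than `or`;
#' parentheses override precedence. Operators are case-insensitive; gene
#' tokens may contain letters, digits, underscores, dots and dashes.
#'
#' @param text Rule string, e.g. `"g1 and (g2 or g3)"`. Empty or
#'   whitespace-only text yields `NULL` (no gene association).
#' @return A GPR tree: either `NULL`, a leaf (`list(type = "gene",
#'   gene = <id>)`), or a node (`list(type = "and"|"or", args = <list>)`).
#'   Nested nodes of the same operator are flattened so the tree is
#'   canonical up to argument order.
#' @examples
#' parse_gpr("HMGCR")
#' parse_gpr("ACAT1 or ACAT2")
#' parse_gpr("SC4MOL and SC5D")
#' @export
parse_gpr <- function(text) {
  if (is.null(text) || length(text) == 0L) return(NULL)
  stopifnot(is.character(text), length(text) == 1L)
  if (!nzchar(trimws(text))) return(NULL)

  tokens <- gpr_tokenize(text)
  state <- new.env(parent = emptyenv())
  state$tokens <- tokens
  state$pos <- 1L
  tree <- gpr_parse_or(state, text)
  if (state$pos <= length(state$tokens)) {
    tk <- state$tokens[[state$pos]]
    stop(sprintf("GPR parse error at position %d: unexpected '%s' in \"%s\"",
                 tk$at, tk$value, text), call. = FALSE)
  }
  tree
}

# Lexer: returns list of list(type = "gene"|"and"|"or"|"("|")", value, at)
gpr_tokenize <- function(text) {
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  n <- length(chars)
  tokens <- list()
  i <- 1L
  is_word <- function(ch) grepl("^[A-Za-z0-9_.-]$", ch)
  while (i <= n) {
    ch <- chars[i]
    if (ch %in% c(" ", "\t", "\n")) {
      i <- i + 1L
    } else if (ch == "(") {
      tokens[[length(tokens) + 1L]] <- list(type = "(", value = "(", at = i)
      i <- i + 1L
    } else if (ch == ")") {
      tokens[[length(tokens) + 1L]] <- list(type = ")", value = ")", at = i)
      i <- i + 1L
    } else if (is_word(ch)) {
      j <- i
      while (j <= n && is_word(chars[j])) j <- j + 1L
      word <- paste(chars[i:(j - 1L)], collapse = "")
      type <- switch(tolower(word), "and" = "and", "or" = "or", "gene")
      tokens[[length(tokens) + 1L]] <- list(type = type, value = word, at = i)
      i <- j
    } else {
      stop(sprintf("GPR parse error at position %d: illegal character '%s'",
                   i, ch), call. = FALSE)
    }
  }
  tokens
}

gpr_peek <- function(state) {
  if (state$pos > length(state$tokens)) NULL else state$tokens[[state$pos]]
}

gpr_parse_or <- function(state, text) {
  args <- list(gpr_parse_and(state, text))
  while (!is.null(tk <- gpr_peek(state)) && tk$type == "or") {
    state$pos <- state$pos + 1L
    args[[length(args) + 1L]] <- gpr_parse_and(state, text)
  }
  gpr_node("or", args)
}

gpr_parse_and <- function(state, text) {
  args <- list(gpr_parse_atom(state, text))
  while (!is.null(tk <- gpr_peek(state)) && tk$type == "and") {
    state$pos <- state$pos + 1L
    args[[length(args) + 1L]] <- gpr_parse_atom(state, text)
  }
  gpr_node("and", args)
}

gpr_parse_atom <- function(state, text) {
  tk <- gpr_peek(state)
  if (is.null(tk)) {
    stop(sprintf("GPR parse error at position %d: dangling operator in \"%s\"",
                 nchar(text) + 1L, text), call. = FALSE)
  }
  if (tk$type == "gene") {
    state$pos <- state$pos + 1L
    return(list(type = "gene", gene = tk$value))
  }
  if (tk$type == "(") {
    open_at <- tk$at
    state$pos <- state$pos + 1L
    inner <- gpr_parse_or(state, text)
    tk2 <- gpr_peek(state)
    if (is.null(tk2) || tk2$type != ")") {
      stop(sprintf("GPR parse error at position %d: unbalanced '(' in \"%s\"",
                   open_at, text), call. = FALSE)
    }
    state$pos <- state$pos + 1L
    return(inner)
  }
  stop(sprintf("GPR parse error at position %d: unexpected '%s' in \"%s\"",
               tk$at, tk$value, text), call. = FALSE)
}

# n-ary node with same-operator flattening; a single argument collapses to it
gpr_node <- function(op, args) {
  if (length(args) == 1L) return(args[[1L]])
  flat <- list()
  for (a in args) {
    if (is.list(a) && identical(a$type, op)) {
      flat <- c(flat, a$args)
    } else {
      flat <- c(flat, list(a))
    }
  }
  list(type = op, args = flat)
}

#' Genes referenced by a GPR tree
#'
#' @param gpr A GPR tree as returned by [parse_gpr()], or `NULL`.
#' @return Character vector of unique gene identifiers (empty for `NULL`).
#' @export
gpr_genes <- function(gpr) {
  if (is.null(gpr)) return(character(0))
  if (identical(gpr$type, "gene")) return(gpr$gene)
  unique(unlist(lapply(gpr$args, gpr_genes)))
}

#' Evaluate a GPR tree against per-gene expression values
#'
#' Maps gene expression onto a reaction: isoenzymes (`or`) take the maximum
#' of their children, enzyme complexes (`and`) the minimum.
#'
#' @param gpr GPR tree or `NULL`.
#' @param values Named numeric vector of per-gene expression values.
#' @return The mapped reaction value, or `NA_real_` when `gpr` is `NULL` or
#'   any referenced gene is absent from `values`.
#' @export
gpr_value <- function(gpr, values) {
  if (is.null(gpr)) return(NA_real_)
  if (identical(gpr$type, "gene")) {
    if (!gpr$gene %in% names(values)) return(NA_real_)
    return(unname(values[[gpr$gene]]))
  }
  child <- vapply(gpr$args, gpr_value, numeric(1), values = values)
  if (anyNA(child)) return(NA_real_)
  if (identical(gpr$type, "or")) max(child) else min(child)
}

#' Render a GPR tree back to rule text
#'
#' @param gpr GPR tree or `NULL`.
#' @return A rule string (`""` for `NULL`). Parentheses are emitted only
#'   where needed, so `deparse_gpr(parse_gpr(x))` is a fixed point.
#' @export
deparse_gpr <- function(gpr) {
  if (is.null(gpr)) return("")
  if (identical(gpr$type, "gene")) return(gpr$gene)
  parts <- vapply(gpr$args, function(a) {
    s <- deparse_gpr(a)
    # an OR child under AND needs parentheses to survive re-parsing
    if (identical(gpr$type, "and") && is.list(a) && identical(a$type, "or")) {
      s <- paste0("(", s, ")")
    }
    s
  }, character(1))
  paste(parts, collapse = paste0(" ", gpr$type, " "))
}
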