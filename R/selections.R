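#' Atom selection expressions
#'
#' A minimal selection grammar used throughout the pipeline to name atoms,
#' e.g. the guanidinium carbon of R320 as `"resid 320 and name CZ"`.
#' Supported keywords: `resid` (residue numbers, single values or
#' hyphenated ranges like `266-277`), `resname`, `name`, `chain`.
#' A keyword may be followed by several values, which are OR-ed
#' (`"name N CA C O"`). Terms combine with `and` / `or` (`and` binds
#' tighter) and parentheses.
#'
#' @param expression character(1) selection expression.
#' @return An object of class `atom_selection`.
#' @examples
#' sel <- atom_selection("resid 320 and name CZ")
#' @export
atom_selection <- function(expression) {
  stopifnot(is.character(expression), length(expression) == 1L, nzchar(expression))
  ast <- parse_selection(expression)
  structure(list(expression = expression, ast = ast), class = "atom_selection")
}

#' @export
print.atom_selection <- function(x, ...) {
  cat("<atom_selection> ", x$expression, "\n", sep = "")
  invisible(x)
}

as_selection <- function(x) {
  if (inherits(x, "atom_selection")) x else atom_selection(x)
}

# --- recursive-descent parser ------------------------------------------------
# grammar: expr := term ('or' term)* ; term := factor ('and' factor)* ;
#          factor := '(' expr ')' | keyword value+

sel_tokenize <- function(expression) {
  expr <- gsub("([()])", " \\1 ", expression)
  toks <- strsplit(trimws(expr), "\\s+")[[1]]
  toks[nzchar(toks)]
}

parse_selection <- function(expression) {
  toks <- sel_tokenize(expression)
  if (length(toks) == 0L) stop("empty selection expression", call. = FALSE)
  pos <- 1L
  peek <- function() if (pos <= length(toks)) toks[pos] else NA_character_
  advance <- function() {
    t <- peek()
    pos <<- pos + 1L
    t
  }
  keywords <- c("resid", "resname", "name", "chain")
  stoppers <- c("and", "or", "(", ")")

  parse_expr <- function() {
    node <- parse_term()
    while (!is.na(peek()) && tolower(peek()) == "or") {
      advance()
      node <- list(op = "or", lhs = node, rhs = parse_term())
    }
    node
  }
  parse_term <- function() {
    node <- parse_factor()
    while (!is.na(peek()) && tolower(peek()) == "and") {
      advance()
      node <- list(op = "and", lhs = node, rhs = parse_factor())
    }
    node
  }
  parse_factor <- function() {
    t <- peek()
    if (is.na(t)) {
      stop(sprintf("selection '%s': unexpected end of expression at token %d",
                   expression, pos), call. = FALSE)
    }
    if (t == "(") {
      advance()
      node <- parse_expr()
      if (is.na(peek()) || peek() != ")") {
        stop(sprintf("selection '%s': missing ')' at token %d", expression, pos),
             call. = FALSE)
      }
      advance()
      return(node)
    }
    kw <- tolower(advance())
    if (!kw %in% keywords) {
      stop(sprintf("selection '%s': unknown keyword '%s' at token %d",
                   expression, kw, pos - 1L), call. = FALSE)
    }
    vals <- character(0)
    while (!is.na(peek()) && !tolower(peek()) %in% stoppers) vals <- c(vals, advance())
    if (length(vals) == 0L) {
      stop(sprintf("selection '%s': keyword '%s' needs at least one value (token %d)",
                   expression, kw, pos), call. = FALSE)
    }
    list(op = kw, values = vals)
  }

  node <- parse_expr()
  if (!is.na(peek())) {
    stop(sprintf("selection '%s': unexpected token '%s' at position %d",
                 expression, peek(), pos), call. = FALSE)
  }
  node
}

sel_expand_resid <- function(values) {
  out <- integer(0)
  for (v in values) {
    if (grepl("^-?[0-9]+--?[0-9]+$", v) && grepl("^[0-9]", v)) {
      parts <- as.integer(strsplit(v, "-")[[1]][1:2])
      out <- c(out, seq.int(parts[1], parts[2]))
    } else if (grepl("^-?[0-9]+$", v)) {
      out <- c(out, as.integer(v))
    } else {
      stop(sprintf("invalid residue number '%s' in selection", v), call. = FALSE)
    }
  }
  out
}

sel_eval <- function(node, atoms) {
  if (!is.null(node$op) && node$op %in% c("and", "or")) {
    l <- sel_eval(node$lhs, atoms)
    r <- sel_eval(node$rhs, atoms)
    return(if (node$op == "and") l & r else l | r)
  }
  switch(node$op,
    resid   = atoms$residue_number %in% sel_expand_resid(node$values),
    resname = atoms$residue_name %in% toupper(node$values),
    name    = atoms$atom_name %in% toupper(node$values),
    chain   = atoms$chain_id %in% node$values,
    stop("unknown selection node op: ", node$op, call. = FALSE)
  )
}

#' Resolve an atom selection against a topology
#'
#' Resolution is a pure function of its inputs: the same selection on the
#' same topology always yields the same ordered set. An empty match is a
#' valid result, not an error.
#'
#' @param sel an `atom_selection` or a character expression.
#' @param top a [topology] object.
#' @return Integer vector of 0-based `atom_index` values, in topology order.
#' @examples
#' top <- build_toy_topology(synthetic_spec(seed = 1))$topology
#' resolve_selection("resid 320 and name CZ", top)
#' @export
resolve_selection <- function(sel, top) {
  sel <- as_selection(sel)
  stopifnot(inherits(top, "topology"))
  hit <- sel_eval(sel$ast, top$atoms)
  top$atoms$atom_index[hit]
}
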