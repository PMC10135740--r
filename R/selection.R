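# A minimal, documented atom-selection grammar:
#
#   expr    := andexpr ( "or" andexpr )*
#   andexpr := notexpr ( "and" notexpr )*
#   notexpr := "not" notexpr | "(" expr ")" | primary
#   primary := "all"
#            | keyword value+            keyword in {element, name, resname, chainid}
#            | "resid" ( int | int "to" int )+
#
# Keywords and operators are case-insensitive; values match topology entries
# case-insensitively (atom and residue names are conventionally upper case).

tokenize_selection <- function(expr) {
  expr <- gsub("([()])", " \\1 ", expr)
  toks <- strsplit(trimws(expr), "\\s+")[[1]]
  if (!length(toks) || !nzchar(toks[1]))
    selection_error("empty selection expression")
  toks
}

sel_keywords <- c("element", "name", "resname", "resid", "chainid")
sel_reserved <- c(sel_keywords, "and", "or", "not", "to", "all", "(", ")")

parse_selection <- function(tokens) {
  pos <- 1L
  peek <- function() if (pos <= length(tokens)) tolower(tokens[pos]) else NA
  advance <- function() { t <- tokens[pos]; pos <<- pos + 1L; t }
  expect <- function(tok) {
    if (is.na(peek()) || peek() != tok)
      selection_error(sprintf("expected '%s' near position %d", tok, pos))
    advance()
  }

  parse_expr <- function() {
    node <- parse_and()
    while (!is.na(peek()) && peek() == "or") {
      advance()
      node <- list(op = "or", lhs = node, rhs = parse_and())
    }
    node
  }
  parse_and <- function() {
    node <- parse_not()
    while (!is.na(peek()) && peek() == "and") {
      advance()
      node <- list(op = "and", lhs = node, rhs = parse_not())
    }
    node
  }
  parse_not <- function() {
    if (!is.na(peek()) && peek() == "not") {
      advance()
      return(list(op = "not", arg = parse_not()))
    }
    if (!is.na(peek()) && peek() == "(") {
      advance()
      node <- parse_expr()
      expect(")")
      return(node)
    }
    parse_primary()
  }
  parse_primary <- function() {
    kw <- peek()
    if (is.na(kw)) selection_error("unexpected end of selection expression")
    if (kw == "all") { advance(); return(list(op = "all")) }
    if (!kw %in% sel_keywords)
      selection_error(sprintf("unexpected token '%s'", tokens[pos]))
    advance()
    if (kw == "resid") {
      ranges <- list()
      repeat {
        v <- peek()
        if (is.na(v) || is.na(suppressWarnings(as.integer(v)))) break
        lo <- as.integer(advance())
        hi <- lo
        if (!is.na(peek()) && peek() == "to") {
          advance()
          hi <- suppressWarnings(as.integer(advance()))
          if (is.na(hi)) selection_error("'to' must be followed by an integer")
        }
        ranges[[length(ranges) + 1L]] <- c(lo, hi)
      }
      if (!length(ranges)) selection_error("'resid' needs at least one integer")
      return(list(op = "resid", ranges = ranges))
    }
    vals <- character(0)
    while (!is.na(peek()) && !peek() %in% sel_reserved) vals <- c(vals, advance())
    if (!length(vals))
      selection_error(sprintf("'%s' needs at least one value", kw))
    list(op = kw, values = vals)
  }

  node <- parse_expr()
  if (!is.na(peek()))
    selection_error(sprintf("trailing tokens starting at '%s'", tokens[pos]))
  node
}

eval_selection <- function(node, topology) {
  n <- nrow(topology)
  switch(node$op,
    all = rep(TRUE, n),
    or  = eval_selection(node$lhs, topology) | eval_selection(node$rhs, topology),
    and = eval_selection(node$lhs, topology) & eval_selection(node$rhs, topology),
    not = !eval_selection(node$arg, topology),
    resid = {
      hit <- rep(FALSE, n)
      for (rg in node$ranges)
        hit <- hit | (topology$resid >= rg[1] & topology$resid <= rg[2])
      hit
    },
    element = toupper(topology$element) %in% toupper(node$values),
    name    = toupper(topology$name) %in% toupper(node$values),
    resname = toupper(topology$resname) %in% toupper(node$values),
    chainid = toupper(topology$chain) %in% toupper(node$values),
    selection_error(paste0("unknown selection node: ", node$op))
  )
}

#' Resolve an atom selection against a trajectory's topology
#'
#' @param traj a [trajectory] (or anything with a `$topology` data.frame).
#' @param expression either a selection string in the package's minimal
#'   grammar (see Details) or an integer vector of 1-based atom indices.
#' @return sorted unique integer vector of 1-based atom indices; an explicit
#'   selection error if nothing matches.
#' @details Supported constructs: `element`, `name`, `resname`, `chainid`
#'   keywords followed by one or more values; `resid` with integers and
#'   `a to b` ranges; `all`; boolean `and`/`or`/`not` and parentheses.
#' @export
resolve_selection <- function(traj, expression) {
  topology <- if (is.data.frame(traj)) traj else traj$topology
  if (is.numeric(expression)) {
    idx <- as.integer(expression)
    if (any(is.na(idx)) || any(idx < 1L) || any(idx > nrow(topology)))
      selection_error("atom index out of range for the topology")
    return(sort(unique(idx)))
  }
  node <- parse_selection(tokenize_selection(expression))
  hit <- which(eval_selection(node, topology))
  if (!length(hit))
    selection_error(paste0("selection matched no atoms: ", expression))
  hit
}

#' Named reference and target particle groups
#'
#' Resolves selections into the named index groups over which the RDF engines
#' iterate: every reference group is paired with every target group.
#'
#' @param traj a [trajectory].
#' @param ref named list (or single string/vector) of reference selections.
#' @param target named list (or single string/vector) of target selections.
#' @return object of class `particle_groups`: lists `ref` and `target` of
#'   1-based atom index vectors.
#' @export
particle_groups <- function(traj, ref, target) {
  as_group_list <- function(x, label) {
    if (!is.list(x)) x <- list(x)
    if (is.null(names(x)) || any(!nzchar(names(x))))
      names(x) <- vapply(seq_along(x), function(i) {
        nm <- names(x)[i]
        if (!is.null(nm) && nzchar(nm)) nm
        else if (is.character(x[[i]])) x[[i]] else paste0(label, i)
      }, character(1))
    lapply(x, function(e) resolve_selection(traj, e))
  }
  structure(list(ref = as_group_list(ref, "ref"),
                 target = as_group_list(target, "target")),
            class = "particle_groups")
}

#' @export
print.particle_groups <- function(x, ...) {
  cat("<particle_groups>\n  reference:\n")
  for (nm in names(x$ref)) cat(sprintf("    %s: %d atoms\n", nm, length(x$ref[[nm]])))
  cat("  target:\n")
  for (nm in names(x$target)) cat(sprintf("    %s: %d atoms\n", nm, length(x$target[[nm]])))
  invisible(x)
}
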