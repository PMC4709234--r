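# Port selector grammar (EBNF; whitespace between tokens is ignored):
#
#   selector := [ term { "," term } ]
#   term     := factor { ("+" | ".+") factor }
#   factor   := path | "(" selector ")"
#   path     := segment { segment }
#   segment  := "/" ( name | integer | "*" ) | bracket
#   bracket  := "[" item { "," item } "]"
#   item     := name | integer | range
#   range    := integer ":" integer          (half-open: i inclusive, j exclusive)
#   name     := (letter | "_") { letter | digit | "_" }
#   integer  := digit { digit }
#
# "," at the top level is union of complete selectors; "+" concatenates every
# left identifier with every right identifier (left-major product); ".+"
# concatenates elementwise and requires equal cardinality. "*" may appear
# only as the final level of a path and only be resolved against a universe.
# A level consisting solely of digits is an integer index; "/med/L1/0" and
# "/med/L1[0]" are the same identifier.

.selCondition <- function(msg, class, pos = NULL) {
  if (!is.null(pos)) msg <- sprintf("%s (at position %d)", msg, pos)
  errorCondition(msg, class = c(class, "lpuSimError"), call = sys.call(-1))
}

.selStop <- function(msg, class, pos = NULL) stop(.selCondition(msg, class, pos))

# --- character-level cursor -------------------------------------------------

.newCursor <- function(text) {
  e <- new.env(parent = emptyenv())
  e$ch <- strsplit(text, "", fixed = TRUE)[[1]]
  e$n <- length(e$ch)
  e$i <- 1L
  e
}

.peek <- function(cur) if (cur$i > cur$n) "" else cur$ch[cur$i]

.advance <- function(cur) cur$i <- cur$i + 1L

.skipWs <- function(cur) {
  while (cur$i <= cur$n && cur$ch[cur$i] %in% c(" ", "\t")) .advance(cur)
}

.isNameStart <- function(c) grepl("^[A-Za-z_]$", c)
.isNameChar  <- function(c) grepl("^[A-Za-z0-9_]$", c)
.isDigit     <- function(c) grepl("^[0-9]$", c)

.scanName <- function(cur) {
  start <- cur$i
  while (cur$i <= cur$n && .isNameChar(cur$ch[cur$i])) .advance(cur)
  paste(cur$ch[start:(cur$i - 1L)], collapse = "")
}

.scanInt <- function(cur) {
  start <- cur$i
  while (cur$i <= cur$n && .isDigit(cur$ch[cur$i])) .advance(cur)
  paste(cur$ch[start:(cur$i - 1L)], collapse = "")
}

# --- recursive descent ------------------------------------------------------

.parseSelectorExpr <- function(cur) {
  args <- list()
  repeat {
    .skipWs(cur)
    if (.peek(cur) == "" || .peek(cur) == ")") break
    args[[length(args) + 1L]] <- .parseTerm(cur)
    .skipWs(cur)
    if (.peek(cur) == ",") .advance(cur) else break
  }
  if (length(args) == 1L) args[[1L]] else list(kind = "union", args = args)
}

.parseTerm <- function(cur) {
  left <- .parseFactor(cur)
  repeat {
    .skipWs(cur)
    p <- .peek(cur)
    if (p == "+") {
      .advance(cur)
      right <- .parseFactor(cur)
      left <- .mkConcat(left, right)
    } else if (p == ".") {
      .advance(cur)
      if (.peek(cur) != "+")
        .selStop("expected '+' after '.'", "selectorSyntaxError", cur$i)
      .advance(cur)
      right <- .parseFactor(cur)
      left <- .mkZip(left, right)
    } else break
  }
  left
}

.parseFactor <- function(cur) {
  .skipWs(cur)
  if (.peek(cur) == "(") {
    .advance(cur)
    s <- .parseSelectorExpr(cur)
    .skipWs(cur)
    if (.peek(cur) != ")")
      .selStop("unbalanced parenthesis", "selectorSyntaxError", cur$i)
    .advance(cur)
    s
  } else {
    .parsePath(cur)
  }
}

.parsePath <- function(cur) {
  levels <- list()
  repeat {
    p <- .peek(cur)
    if (p == "/") {
      .advance(cur)
      q <- .peek(cur)
      if (q == "[") {
        levels[[length(levels) + 1L]] <-
          list(type = "set", tokens = .parseBracket(cur))
      } else if (q == "*") {
        .advance(cur)
        levels[[length(levels) + 1L]] <- list(type = "wild")
      } else if (.isNameStart(q)) {
        levels[[length(levels) + 1L]] <-
          list(type = "set", tokens = .scanName(cur))
      } else if (.isDigit(q)) {
        levels[[length(levels) + 1L]] <-
          list(type = "set", tokens = .scanInt(cur))
      } else {
        .selStop("expected level name, index, or '*' after '/'",
                 "selectorSyntaxError", cur$i)
      }
    } else if (p == "[") {
      levels[[length(levels) + 1L]] <-
        list(type = "set", tokens = .parseBracket(cur))
    } else {
      break
    }
  }
  if (length(levels) == 0L)
    .selStop("expected a port path", "selectorSyntaxError", cur$i)
  wild <- vapply(levels, function(l) identical(l$type, "wild"), logical(1))
  if (any(wild[-length(wild)]))
    .selStop("wildcard '*' may appear only as the final level",
             "wildcardError", cur$i)
  list(kind = "path", levels = levels)
}

.parseBracket <- function(cur) {
  open <- cur$i
  .advance(cur)  # past '['
  items <- character(0)
  repeat {
    .skipWs(cur)
    p <- .peek(cur)
    if (p == "") .selStop("unterminated bracket", "selectorSyntaxError", open)
    if (p == "-")
      .selStop("negative indices are not allowed", "selectorSyntaxError", cur$i)
    if (.isNameStart(p)) {
      items <- c(items, .scanName(cur))
    } else if (.isDigit(p)) {
      lo <- .scanInt(cur)
      .skipWs(cur)
      if (.peek(cur) == ":") {
        .advance(cur)
        .skipWs(cur)
        if (.peek(cur) == "-")
          .selStop("negative range bound", "selectorSyntaxError", cur$i)
        if (!.isDigit(.peek(cur)))
          .selStop("expected integer upper range bound",
                   "selectorSyntaxError", cur$i)
        hi <- .scanInt(cur)
        lo <- as.numeric(lo); hi <- as.numeric(hi)
        if (hi > lo)  # half-open [lo, hi)
          items <- c(items, format(seq.int(lo, hi - 1), scientific = FALSE,
                                   trim = TRUE))
      } else {
        items <- c(items, lo)
      }
    } else {
      .selStop(sprintf("unexpected character '%s' in bracket", p),
               "selectorSyntaxError", cur$i)
    }
    .skipWs(cur)
    p <- .peek(cur)
    if (p == ",") { .advance(cur); next }
    if (p == "]") { .advance(cur); break }
    if (p == "") .selStop("unterminated bracket", "selectorSyntaxError", open)
    .selStop(sprintf("unexpected character '%s' in bracket", p),
             "selectorSyntaxError", cur$i)
  }
  items
}

.astHasWild <- function(node) {
  switch(node$kind,
    path = any(vapply(node$levels,
                      function(l) identical(l$type, "wild"), logical(1))),
    any(vapply(node$args, .astHasWild, logical(1))))
}

.mkConcat <- function(a, b) {
  if (.astHasWild(a) || .astHasWild(b))
    .selStop("wildcard '*' may appear only as the final level of a selector",
             "wildcardError")
  list(kind = "concat", args = list(a, b))
}

.mkZip <- function(a, b) {
  if (.astHasWild(a) || .astHasWild(b))
    .selStop("wildcard '*' may appear only as the final level of a selector",
             "wildcardError")
  list(kind = "zip", args = list(a, b))
}

# --- expansion --------------------------------------------------------------

.formatTokens <- function(toks) {
  isInt <- grepl("^[0-9]+$", toks)
  paste0(ifelse(isInt, paste0("[", toks, "]"), paste0("/", toks)),
         collapse = "")
}

# expand an AST into a list of token vectors; errors on wildcard
.expandAst <- function(node) {
  switch(node$kind,
    path = {
      seqs <- list(character(0))
      for (lev in node$levels) {
        if (identical(lev$type, "wild"))
          .selStop(paste("selector contains a wildcard and cannot be expanded",
                         "standalone; resolve it against a universe with",
                         "expandAgainst()"), "wildcardError")
        toks <- lev$tokens
        seqs <- unlist(lapply(seqs, function(s)
          lapply(toks, function(tk) c(s, tk))), recursive = FALSE)
      }
      seqs
    },
    union = unlist(lapply(node$args, .expandAst), recursive = FALSE),
    concat = {
      a <- .expandAst(node$args[[1L]])
      b <- .expandAst(node$args[[2L]])
      unlist(lapply(a, function(x) lapply(b, function(y) c(x, y))),
             recursive = FALSE)
    },
    zip = {
      a <- .expandAst(node$args[[1L]])
      b <- .expandAst(node$args[[2L]])
      if (length(a) != length(b))
        .selStop(sprintf(
          "elementwise join requires equal cardinality (%d vs %d)",
          length(a), length(b)), "cardinalityError")
      Map(c, a, b)
    },
    stop("internal: unknown AST node kind ", node$kind))
}

.newSelector <- function(ast, source) {
  new("PortSelector", ast = ast, source = source,
      cache = new.env(parent = emptyenv()))
}

#' Parse a port selector string
#'
#' Parses a path-like selector expression into a [PortSelector]. See the
#' grammar in the package vignette; examples: `"/med/L1[0]"` (one port),
#' `"/med/L1[0:10]"` (ten ports, half-open range), `"/med/[L1,L2][0]"` (two
#' ports), `"/med/L1/*"` (wildcard: all ports under the prefix),
#' `"/a,/b"` (union), `"/med+/L1[0]"` (concatenation/product),
#' `"/med/[L1,L2].+[0:2]"` (elementwise join).
#'
#' @param text selector string.
#' @return a [PortSelector].
#' @examples
#' expandSelector(parseSelector("/med/[L1,L2][0]"))
#' countPorts(parseSelector("/med/L1[0:10]"))
#' @export
parseSelector <- function(text) {
  stopifnot(is.character(text), length(text) == 1L, !is.na(text))
  cur <- .newCursor(text)
  ast <- .parseSelectorExpr(cur)
  .skipWs(cur)
  if (.peek(cur) != "")
    .selStop(sprintf("unexpected character '%s'", .peek(cur)),
             "selectorSyntaxError", cur$i)
  .newSelector(ast, text)
}

#' Coerce to a PortSelector
#'
#' Accepts a [PortSelector] (returned unchanged), a single selector string,
#' or a character vector of identifier/selector strings (joined as a union).
#'
#' @param x object to coerce.
#' @return a [PortSelector].
#' @export
portSelector <- function(x) {
  if (is(x, "PortSelector")) return(x)
  if (is.character(x)) {
    if (length(x) == 0L) return(parseSelector(""))
    return(parseSelector(paste(x, collapse = ",")))
  }
  stop("cannot coerce object of class ", class(x)[1L], " to PortSelector")
}

# Fast identifier resolution: canonical-form character vectors pass through
# untouched (keeping first occurrence of duplicates); anything else goes
# through the parser.
.canonicalIdRegex <- "^(/[A-Za-z_][A-Za-z0-9_]*|\\[[0-9]+\\])+$"

.ids <- function(x) {
  if (is.character(x) && all(grepl(.canonicalIdRegex, x)))
    return(unique(x))
  expandSelector(portSelector(x))
}

#' Expand a selector into its ordered identifier set
#'
#' Returns the canonical identifier strings denoted by a wildcard-free
#' selector, duplicate-free, in documented expansion order: lists and ranges
#' in source order, products left-major, duplicates removed keeping the first
#' occurrence.
#'
#' @param x a [PortSelector], selector string, or identifier vector.
#' @param ... unused.
#' @return character vector of canonical identifiers.
#' @examples
#' expandSelector("/med/L1[0:3]")
#' @export
#' @rdname expandSelector
setMethod("expandSelector", "PortSelector", function(x, ...) {
  if (!is.null(x@cache$ids)) return(x@cache$ids)
  seqs <- .expandAst(x@ast)
  ids <- unique(vapply(seqs, .formatTokens, character(1)))
  x@cache$ids <- ids
  ids
})

#' @export
#' @rdname expandSelector
setMethod("expandSelector", "character",
          function(x, ...) expandSelector(portSelector(x)))

#' Count the ports denoted by a selector
#'
#' @inheritParams expandSelector
#' @return integer count, equal to `length(expandSelector(x))`.
#' @examples
#' countPorts("/a/in/gpot[0:2]")  # 2
#' @export
#' @rdname countPorts
setMethod("countPorts", "PortSelector",
          function(x, ...) length(expandSelector(x)))

#' @export
#' @rdname countPorts
setMethod("countPorts", "character",
          function(x, ...) countPorts(portSelector(x)))

#' Resolve a selector against a universe of ports
#'
#' Returns the members of `universe` matched by the selector, in universe
#' order. A trailing wildcard level matches any identifier extending the
#' prefix by at least one level. Wildcard-free selectors reduce to set
#' membership. An empty result is valid.
#'
#' @param x a [PortSelector] or selector string (wildcards allowed).
#' @param universe character vector of identifiers, or a wildcard-free
#'   selector.
#' @param ... unused.
#' @return character vector, an ordered subset of `universe`.
#' @examples
#' expandAgainst("/med/L1/*", c("/med/L1[0]", "/med/L1[1]", "/med/L2[0]"))
#' @export
#' @rdname expandAgainst
setMethod("expandAgainst", "PortSelector", function(x, universe, ...) {
  u <- .ids(universe)
  branches <- if (identical(x@ast$kind, "union")) x@ast$args else list(x@ast)
  keep <- logical(length(u))
  for (br in branches) {
    if (.astHasWild(br)) {
      # the parser guarantees a wild branch is a path ending in the wildcard
      prefixAst <- list(kind = "path",
                        levels = br$levels[-length(br$levels)])
      prefixes <- vapply(.expandAst(prefixAst), .formatTokens, character(1))
      for (p in prefixes) {
        ext <- startsWith(u, p) & nchar(u) > nchar(p) &
          substr(u, nchar(p) + 1L, nchar(p) + 1L) %in% c("/", "[")
        keep <- keep | ext
      }
    } else {
      ids <- vapply(.expandAst(br), .formatTokens, character(1))
      keep <- keep | (u %in% ids)
    }
  }
  u[keep]
})

#' @export
#' @rdname expandAgainst
setMethod("expandAgainst", "character",
          function(x, universe, ...) expandAgainst(portSelector(x), universe))

#' Combine two selectors
#'
#' * `"union"`: ordered concatenation of the two identifier sets, duplicates
#'   removed keeping the first occurrence.
#' * `"product"`: every left identifier concatenated with every right
#'   identifier, left-major order (the string-level `+` operator).
#' * `"elementwise"`: i-th left identifier concatenated with i-th right
#'   identifier; both sides must have equal cardinality (the `.+` operator).
#'
#' @param a,b selectors (any form accepted by [portSelector()]).
#' @param operator one of `"union"`, `"product"`, `"elementwise"`.
#' @return a [PortSelector].
#' @examples
#' expandSelector(combineSelectors("/med", "/L1[0]", "product"))
#' @export
combineSelectors <- function(a, b,
                             operator = c("union", "product", "elementwise")) {
  operator <- match.arg(operator)
  a <- portSelector(a); b <- portSelector(b)
  ast <- switch(operator,
    union = list(kind = "union", args = list(a@ast, b@ast)),
    product = .mkConcat(a@ast, b@ast),
    elementwise = .mkZip(a@ast, b@ast))
  sel <- .newSelector(ast, switch(operator,
    union = paste0(a@source, ",", b@source),
    product = paste0("(", a@source, ")+(", b@source, ")"),
    elementwise = paste0("(", a@source, ").+(", b@source, ")")))
  if (operator == "elementwise")
    expandSelector(sel)  # validate cardinality eagerly
  sel
}

#' @param e1,e2 [PortSelector] objects.
#' @describeIn combineSelectors `+` on two selectors is set union, matching
#'   the convention of combining disjoint interface subsets into one
#'   interface selector.
#' @export
setMethod("+", signature("PortSelector", "PortSelector"),
          function(e1, e2) combineSelectors(e1, e2, "union"))

#' Render a selector in canonical form
#'
#' Emits a canonical string: wildcard-free branches as a comma-joined list of
#' bracketed identifiers, wildcard branches as `prefix/*`. `parseSelector()`
#' of the result denotes the same set (rendering is idempotent under
#' parse-render round trips).
#'
#' @inheritParams expandSelector
#' @return canonical selector string.
#' @export
#' @rdname renderSelector
setMethod("renderSelector", "PortSelector", function(x, ...) {
  branches <- if (identical(x@ast$kind, "union")) x@ast$args else list(x@ast)
  parts <- character(0)
  for (br in branches) {
    if (.astHasWild(br)) {
      prefixAst <- list(kind = "path", levels = br$levels[-length(br$levels)])
      prefixes <- vapply(.expandAst(prefixAst), .formatTokens, character(1))
      parts <- c(parts, paste0(prefixes, "/*"))
    } else {
      parts <- c(parts, vapply(.expandAst(br), .formatTokens, character(1)))
    }
  }
  paste(unique(parts), collapse = ",")
})

#' @export
#' @rdname renderSelector
setMethod("renderSelector", "character",
          function(x, ...) renderSelector(portSelector(x)))

#' @export
setMethod("show", "PortSelector", function(object) {
  hasWild <- .astHasWild(object@ast)
  cat("PortSelector: ", object@source, "\n", sep = "")
  if (hasWild) {
    cat("  (wildcard selector; resolve with expandAgainst())\n")
  } else {
    ids <- expandSelector(object)
    cat("  ", length(ids), " port(s)", sep = "")
    if (length(ids) > 0)
      cat(": ", paste(utils::head(ids, 6), collapse = ", "),
          if (length(ids) > 6) ", ..." else "", sep = "")
    cat("\n")
  }
  invisible(object)
})

#' @export
setMethod("length", "PortSelector", function(x) countPorts(x))
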