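#' Boolean expression trees
#'
#' Update functions of a Boolean network are stored as small expression
#' trees with node types `const`, `var`, `not`, `and`, `or`.  Constructors
#' are exported so compiled networks can be assembled programmatically;
#' most users will obtain expressions from [parse_bool_expr()] or from the
#' pathway compiler.
#'
#' @param value 0 or 1.
#' @param name variable (node) name.
#' @param x,... child expressions.
#' @return An object of class `bn_expr`.
#' @seealso [parse_bool_expr()], [eval_bool_expr()]
#' @examples
#' e <- bx_and(bx_var("Nrf2"), bx_not(bx_var("ARE")))
#' format(e)
#' eval_bool_expr(e, c(Nrf2 = 1, ARE = 0))
#' @name bn_expr
NULL

new_bn_expr <- function(type, ...) {
  structure(list(type = type, ...), class = "bn_expr")
}

#' @rdname bn_expr
#' @export
bx_const <- function(value) {
  value <- as.integer(value)
  stopifnot(length(value) == 1L, value %in% c(0L, 1L))
  new_bn_expr("const", value = value)
}

#' @rdname bn_expr
#' @export
bx_var <- function(name) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  new_bn_expr("var", name = name)
}

#' @rdname bn_expr
#' @export
bx_not <- function(x) {
  stopifnot(inherits(x, "bn_expr"))
  new_bn_expr("not", child = x)
}

#' @rdname bn_expr
#' @export
bx_and <- function(...) {
  kids <- list(...)
  if (length(kids) == 1L && is.list(kids[[1L]]) && !inherits(kids[[1L]], "bn_expr"))
    kids <- kids[[1L]]
  stopifnot(length(kids) >= 2L, all(vapply(kids, inherits, TRUE, "bn_expr")))
  new_bn_expr("and", children = kids)
}

#' @rdname bn_expr
#' @export
bx_or <- function(...) {
  kids <- list(...)
  if (length(kids) == 1L && is.list(kids[[1L]]) && !inherits(kids[[1L]], "bn_expr"))
    kids <- kids[[1L]]
  stopifnot(length(kids) >= 2L, all(vapply(kids, inherits, TRUE, "bn_expr")))
  new_bn_expr("or", children = kids)
}

#' Evaluate a Boolean expression
#'
#' Evaluation is total and deterministic given a complete assignment.  The
#' assignment values may be vectors (all of one common length), in which
#' case the expression is evaluated elementwise; this is how the state
#' transition graph is built in one vectorized pass.
#'
#' @param expr a `bn_expr`.
#' @param env named numeric/integer vector or list of 0/1 vectors, one
#'   entry per variable the expression may reference.
#' @return Integer vector of 0/1 values.
#' @export
eval_bool_expr <- function(expr, env) {
  stopifnot(inherits(expr, "bn_expr"))
  if (!is.list(env)) env <- as.list(env)
  ev <- function(e) {
    switch(e$type,
      const = e$value,
      var = {
        v <- env[[e$name]]
        if (is.null(v)) stop("undefined variable in expression: '", e$name, "'",
                             call. = FALSE)
        v
      },
      not = 1L - ev(e$child),
      and = {
        out <- ev(e$children[[1L]])
        for (k in e$children[-1L]) out <- out * ev(k)
        out
      },
      or = {
        out <- ev(e$children[[1L]])
        for (k in e$children[-1L]) { v <- ev(k); out <- out + v - out * v }
        out
      },
      stop("corrupt bn_expr node type: ", e$type, call. = FALSE)
    )
  }
  out <- ev(expr)
  storage.mode(out) <- "integer"
  out
}

#' Variables referenced by an expression
#' @param expr a `bn_expr`.
#' @return Character vector of distinct variable names, in first-use order.
#' @export
expr_vars <- function(expr) {
  stopifnot(inherits(expr, "bn_expr"))
  acc <- character(0)
  walk <- function(e) {
    switch(e$type,
      var = acc[[length(acc) + 1L]] <<- e$name,
      not = walk(e$child),
      and = ,
      or = for (k in e$children) walk(k),
      const = invisible(NULL)
    )
  }
  walk(expr)
  unique(acc)
}

#' @export
format.bn_expr <- function(x, ...) {
  # precedence: ! > & > |
  fmt <- function(e, parent) {
    switch(e$type,
      const = as.character(e$value),
      var = e$name,
      not = {
        inner <- fmt(e$child, "not")
        if (e$child$type %in% c("and", "or")) paste0("!(", inner, ")")
        else paste0("!", inner)
      },
      and = {
        s <- vapply(e$children, fmt, "", parent = "and")
        paste(s, collapse = " & ")
      },
      or = {
        s <- vapply(e$children, fmt, "", parent = "or")
        out <- paste(s, collapse = " | ")
        if (parent %in% c("and", "not")) paste0("(", out, ")") else out
      }
    )
  }
  fmt(x, "top")
}

#' @export
print.bn_expr <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' Parse a Boolean expression
#'
#' Grammar: identifiers, literals `0`/`1`, `!` (NOT), `&` (AND), `|` (OR)
#' and parentheses; `!` binds tightest, then `&`, then `|`.
#'
#' @param text a single string.
#' @return A `bn_expr`.
#' @examples
#' parse_bool_expr("Nrf2 & (!ARE | !Bach1)")
#' @export
parse_bool_expr <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  toks <- tokenize_expr(text)
  pos <- 1L
  peek <- function() if (pos <= length(toks)) toks[[pos]] else NULL
  take <- function() { t <- peek(); pos <<- pos + 1L; t }
  expect <- function(val) {
    t <- take()
    if (is.null(t) || t != val)
      stop("expected '", val, "' in expression: ", text, call. = FALSE)
  }
  p_or <- function() {
    kids <- list(p_and())
    while (identical(peek(), "|")) { take(); kids[[length(kids) + 1L]] <- p_and() }
    if (length(kids) == 1L) kids[[1L]] else bx_or(kids)
  }
  p_and <- function() {
    kids <- list(p_unary())
    while (identical(peek(), "&")) { take(); kids[[length(kids) + 1L]] <- p_unary() }
    if (length(kids) == 1L) kids[[1L]] else bx_and(kids)
  }
  p_unary <- function() {
    if (identical(peek(), "!")) { take(); return(bx_not(p_unary())) }
    p_atom()
  }
  p_atom <- function() {
    t <- take()
    if (is.null(t)) stop("unexpected end of expression: ", text, call. = FALSE)
    if (t == "(") { e <- p_or(); expect(")"); return(e) }
    if (t == "0") return(bx_const(0L))
    if (t == "1") return(bx_const(1L))
    if (grepl("^[A-Za-z_][A-Za-z0-9_.]*$", t)) return(bx_var(t))
    stop("unexpected token '", t, "' in expression: ", text, call. = FALSE)
  }
  out <- p_or()
  if (pos <= length(toks))
    stop("trailing input after expression: '", toks[[pos]], "' in: ", text,
         call. = FALSE)
  out
}

tokenize_expr <- function(text) {
  s <- text
  toks <- character(0)
  repeat {
    s <- sub("^[[:space:]]+", "", s)
    if (!nzchar(s)) break
    m <- regmatches(s, regexpr("^([A-Za-z_][A-Za-z0-9_.]*|[01()!&|])", s))
    if (length(m) == 0L || !nzchar(m))
      stop("invalid character in expression near: '", substr(s, 1, 12), "'",
           call. = FALSE)
    toks[[length(toks) + 1L]] <- m
    s <- substr(s, nchar(m) + 1L, nchar(s))
  }
  toks
}
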