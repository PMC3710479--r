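#' Boolean expression trees
#'
#' Update rules are stored as small expression trees over variable atoms,
#' with n-ary conjunction/disjunction, negation and the two constants.
#' Constructors simplify eagerly (constant folding, single-child collapse,
#' same-operator flattening) so that the generated rules match the compact
#' form in which update equations are conventionally written: an empty
#' disjunction is `FALSE`, an empty conjunction `TRUE`, and `OR(x)` is `x`.
#'
#' @param var variable identifier (single string).
#' @param x,... child expressions (`bool_expr` objects); `b_and()`/`b_or()`
#'   also accept a single list of children.
#' @return a `bool_expr` object.
#' @examples
#' e <- b_or(b_atom("Sln1_AP_Sln1"),
#'           b_and(b_atom("Sln1-{P}"), b_not(b_atom("Sln1_PT_Ypd1"))))
#' format(e)
#' @name bool_expr
NULL

new_bexpr <- function(kind, ...) {
  structure(list(kind = kind, ...), class = "bool_expr")
}

#' @rdname bool_expr
#' @export
b_true <- function() new_bexpr("const", value = TRUE)

#' @rdname bool_expr
#' @export
b_false <- function() new_bexpr("const", value = FALSE)

#' @rdname bool_expr
#' @export
b_atom <- function(var) {
  stopifnot(is.character(var), length(var) == 1L, nzchar(var))
  new_bexpr("atom", var = unname(var))
}

#' @rdname bool_expr
#' @export
b_not <- function(x) {
  stopifnot(inherits(x, "bool_expr"))
  if (x$kind == "const") return(if (x$value) b_false() else b_true())
  if (x$kind == "not") return(x$child)
  new_bexpr("not", child = x)
}

collect_children <- function(dots) {
  if (length(dots) == 1L && is.list(dots[[1]]) && !inherits(dots[[1]], "bool_expr")) {
    dots <- dots[[1]]
  }
  stopifnot(all(vapply(dots, inherits, logical(1), "bool_expr")))
  dots
}

nary <- function(op, children) {
  absorb <- op == "and"          # constant that annihilates: FALSE for and
  kids <- list()
  for (k in children) {
    if (k$kind == "const") {
      if (k$value == absorb) next        # identity element, drop
      return(if (absorb) b_false() else b_true())
    }
    if (k$kind == op) kids <- c(kids, k$children) else kids <- c(kids, list(k))
  }
  if (length(kids) == 0L) return(if (absorb) b_true() else b_false())
  if (length(kids) == 1L) return(kids[[1]])
  new_bexpr(op, children = kids)
}

#' @rdname bool_expr
#' @export
b_and <- function(...) nary("and", collect_children(list(...)))

#' @rdname bool_expr
#' @export
b_or <- function(...) nary("or", collect_children(list(...)))

#' Evaluate a Boolean expression under a truth assignment
#'
#' @param e a `bool_expr`.
#' @param assignment named logical vector, total over the atoms of `e`.
#' @return logical scalar.
#' @export
eval_expr <- function(e, assignment) {
  switch(e$kind,
    const = e$value,
    atom  = {
      v <- assignment[[e$var]]
      if (is.null(v) || is.na(v)) stop("unbound variable: ", e$var)
      v
    },
    not   = !eval_expr(e$child, assignment),
    and   = all(vapply(e$children, eval_expr, logical(1), assignment)),
    or    = any(vapply(e$children, eval_expr, logical(1), assignment))
  )
}

#' Variables appearing in an expression
#' @param e a `bool_expr`.
#' @return character vector of atom ids, in first-appearance order.
#' @export
expr_vars <- function(e) {
  switch(e$kind,
    const = character(),
    atom  = e$var,
    not   = expr_vars(e$child),
    unique(unlist(lapply(e$children, expr_vars)))
  )
}

#' Structural equality of expressions
#'
#' Equality is structural (same tree after eager simplification), not
#' semantic: child order matters, as it does when comparing against a
#' printed equation.
#' @param a,b `bool_expr` objects.
#' @export
expr_equal <- function(a, b) identical(unclass2(a), unclass2(b))

unclass2 <- function(e) {
  e <- unclass(e)
  if (!is.null(e$child)) e$child <- unclass2(e$child)
  if (!is.null(e$children)) e$children <- lapply(e$children, unclass2)
  e
}

prec <- c(or = 1L, and = 2L, not = 3L, atom = 4L, const = 4L)

#' @export
format.bool_expr <- function(x, ...) render_expr(x, 0L)

render_expr <- function(e, parent_prec) {
  p <- prec[[e$kind]]
  s <- switch(e$kind,
    const = if (e$value) "TRUE" else "FALSE",
    atom  = e$var,
    not   = paste0("! ", render_expr(e$child, p)),
    and   = paste(vapply(e$children, render_expr, character(1), p), collapse = " & "),
    or    = paste(vapply(e$children, render_expr, character(1), p), collapse = " | ")
  )
  if (p < parent_prec) paste0("(", s, ")") else s
}

#' @export
print.bool_expr <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

# Compile to an R language object over a positional logical vector `s`,
# for fast repeated evaluation inside the simulators.
expr_to_lang <- function(e, index) {
  switch(e$kind,
    const = e$value,
    atom  = {
      i <- index[[e$var]]
      if (is.null(i) || is.na(i)) stop("atom not a declared variable: ", e$var)
      call("[[", as.name("s"), i)
    },
    not   = call("!", expr_to_lang(e$child, index)),
    and   = Reduce(function(a, b) call("&", a, b),
                   lapply(e$children, expr_to_lang, index)),
    or    = Reduce(function(a, b) call("|", a, b),
                   lapply(e$children, expr_to_lang, index))
  )
}
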