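# Pattern language: the OPPL 2 subset used for template population.
#
# A script is a comma-separated variable section followed by a BEGIN..END
# action block:
#
#   ?cell:CLASS,
#   ?anatomyPart:CLASS,
#   ?partOfRestriction:CLASS = cell and ro:part_of some ?anatomyPart,
#   ?anatomyIntersection:CLASS = createIntersection(?partOfRestriction.VALUES)
#   BEGIN
#   ADD ?cell equivalentTo ?anatomyIntersection
#   END;
#
# Supported: CLASS variables, defined variables (class-expression templates
# or the createIntersection macro over a variable's .VALUES), existential
# (some) restrictions, intersections, ADD actions with SubClassOf /
# EquivalentTo. Other OPPL constructs (REMOVE, SELECT, constraints) are
# rejected with an explicit unsupported-construct error.

UNSUPPORTED_OPPL <- c("remove", "select", "where", "match", "fail")

# ---- AST constructors -----------------------------------------------------

op_named <- function(name) structure(list(name = name), class = c("op_named", "op_expr"))
op_var   <- function(name) structure(list(name = name), class = c("op_var", "op_expr"))
op_some  <- function(prop, filler)
  structure(list(prop = prop, filler = filler), class = c("op_some", "op_expr"))
op_and   <- function(children)
  structure(list(children = children), class = c("op_and", "op_expr"))
op_term  <- function(term) structure(list(term = term), class = c("op_term", "op_expr"))
op_macro <- function(macro, var)
  structure(list(macro = macro, var = var), class = "op_macro")

node_kind <- function(node) class(node)[1]

# canonical string key; used for syntactic dedup and set comparisons
node_key <- function(node) {
  switch(node_kind(node),
    op_named = paste0("N(", node$name, ")"),
    op_var   = paste0("V(", node$name, ")"),
    op_term  = paste0("T(", node$term$iri, ")"),
    op_some  = paste0("S(", node_key(node$prop), ",", node_key(node$filler), ")"),
    op_and   = paste0("A(", paste(vapply(node$children, node_key, ""),
                                  collapse = ","), ")"),
    stop("node_key: unknown node"))
}

# ---- tokenizer ------------------------------------------------------------

oppl_tokens <- function(text) {
  toks <- list()
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  if (length(lines) == 0L) lines <- ""
  for (ln in seq_along(lines)) {
    s <- lines[[ln]]
    i <- 1L; n <- nchar(s)
    while (i <= n) {
      ch <- substr(s, i, i)
      if (ch %in% c(" ", "\t", "\r")) { i <- i + 1L; next }
      if (ch == "/" && substr(s, i + 1L, i + 1L) == "/") break  # line comment
      if (ch %in% c(",", "(", ")", "=", ";", ":", ".")) {
        toks[[length(toks) + 1L]] <- list(tok = ch, type = "punct", line = ln, col = i)
        i <- i + 1L; next
      }
      if (ch == "?") {
        m <- regexpr("^\\?[A-Za-z_][A-Za-z0-9_]*", substr(s, i, n))
        if (m < 0L) stop(sprintf("pattern: bad variable at line %d col %d", ln, i),
                         call. = FALSE)
        tok <- regmatches(substr(s, i, n), m)
        toks[[length(toks) + 1L]] <- list(tok = tok, type = "var", line = ln, col = i)
        i <- i + nchar(tok); next
      }
      m <- regexpr("^[A-Za-z_][A-Za-z0-9_]*(:[A-Za-z0-9_]+)?", substr(s, i, n))
      if (m < 0L)
        stop(sprintf("pattern: unexpected character '%s' at line %d col %d",
                     ch, ln, i), call. = FALSE)
      tok <- regmatches(substr(s, i, n), m)
      # don't swallow the ':' of '?x:CLASS' style when nothing follows it
      if (endsWith(tok, ":")) tok <- substr(tok, 1L, nchar(tok) - 1L)
      toks[[length(toks) + 1L]] <- list(tok = tok, type = "name", line = ln, col = i)
      i <- i + nchar(tok)
    }
  }
  toks
}

#' Parse a pattern script
#'
#' @param text pattern script text, or a path to a file holding one.
#' @param id identifier recorded in provenance tags (defaults to the file
#'   name, or `"pattern"` for inline text).
#' @return an object of class `pattern_script` with fields `declarations`
#'   (variable names in declaration order), `definitions` (named list of
#'   body ASTs, in order), and `actions`.
#' @examples
#' s <- parse_pattern("?cell:CLASS, ?nucleation:CLASS
#'   BEGIN ADD ?cell SubClassOf hasNucleation some ?nucleation END;")
#' input_variables(s)
#' @export
parse_pattern <- function(text, id = NULL) {
  if (length(text) == 1L && !grepl("\n", text) && file.exists(text)) {
    if (is.null(id)) id <- basename(text)
    text <- paste(readLines(text, warn = FALSE), collapse = "\n")
  }
  if (is.null(id)) id <- "pattern"
  text <- paste(text, collapse = "\n")
  toks <- oppl_tokens(text)
  pos <- 1L
  npos <- length(toks)

  peek <- function(k = 0L) if (pos + k <= npos) toks[[pos + k]] else NULL
  fail <- function(msg, at = peek()) {
    loc <- if (is.null(at)) "end of input" else
      sprintf("line %d col %d", at$line, at$col)
    stop(sprintf("pattern: %s at %s", msg, loc), call. = FALSE)
  }
  advance <- function() { t <- toks[[pos]]; pos <<- pos + 1L; t }
  is_kw <- function(t, kw) !is.null(t) && t$type == "name" && tolower(t$tok) == kw
  expect_punct <- function(p) {
    t <- peek()
    if (is.null(t) || t$type != "punct" || t$tok != p)
      fail(paste0("expected '", p, "'"))
    advance()
  }
  check_supported <- function(t) {
    if (!is.null(t) && t$type == "name" && tolower(t$tok) %in% UNSUPPORTED_OPPL)
      fail(paste0("unsupported OPPL construct '", t$tok, "'"), t)
  }

  parse_atom <- function() {
    t <- peek()
    if (is.null(t)) fail("expected a class expression")
    if (t$type == "punct" && t$tok == "(") {
      advance()
      e <- parse_expr()
      expect_punct(")")
      return(e)
    }
    if (t$type == "var") { advance(); return(op_var(t$tok)) }
    if (t$type == "name") {
      check_supported(t)
      if (tolower(t$tok) %in% c("and", "some", "begin", "end", "add",
                                "subclassof", "equivalentto"))
        fail(paste0("unexpected keyword '", t$tok, "'"), t)
      advance()
      return(op_named(t$tok))
    }
    fail(paste0("unexpected token '", t$tok, "'"), t)
  }

  parse_conjunct <- function() {
    a <- parse_atom()
    if (is_kw(peek(), "some")) {
      advance()
      filler <- parse_atom()
      if (!node_kind(a) %in% c("op_named", "op_var"))
        fail("restriction property must be a name or variable")
      return(op_some(a, filler))
    }
    a
  }

  parse_expr <- function() {
    parts <- list(parse_conjunct())
    while (is_kw(peek(), "and")) {
      advance()
      parts[[length(parts) + 1L]] <- parse_conjunct()
    }
    if (length(parts) == 1L) parts[[1]] else op_and(parts)
  }

  # variable section
  declarations <- character()
  definitions <- list()
  repeat {
    t <- peek()
    if (is.null(t)) fail("expected BEGIN")
    if (is_kw(t, "begin")) break
    check_supported(t)
    if (t$type != "var") fail("expected a variable declaration")
    vname <- advance()$tok
    if (vname %in% c(declarations, names(definitions)))
      fail(paste0("duplicate variable '", vname, "'"))
    expect_punct(":")
    ct <- peek()
    if (!is_kw(ct, "class"))
      fail(paste0("only CLASS variables are supported, got '",
                  if (is.null(ct)) "" else ct$tok, "'"), ct)
    advance()
    t <- peek()
    if (!is.null(t) && t$type == "punct" && t$tok == "=") {
      advance()
      mt <- peek()
      if (is_kw(mt, "createintersection")) {
        advance()
        expect_punct("(")
        vt <- peek()
        if (is.null(vt) || vt$type != "var") fail("createIntersection expects a variable")
        mvar <- advance()$tok
        expect_punct(".")
        valt <- peek()
        if (!is_kw(valt, "values")) fail("expected .VALUES")
        advance()
        expect_punct(")")
        if (!mvar %in% c(declarations, names(definitions)))
          fail(paste0("createIntersection over undeclared variable '", mvar, "'"))
        definitions[[vname]] <- op_macro("createIntersection", mvar)
      } else {
        body <- parse_expr()
        for (ref in expr_vars(body))
          if (!ref %in% c(declarations, names(definitions)))
            fail(paste0("definition of '", vname,
                        "' references undeclared variable '", ref, "'"))
        definitions[[vname]] <- body
      }
    }
    declarations <- c(declarations, vname)
    t <- peek()
    if (!is.null(t) && t$type == "punct" && t$tok == ",") { advance(); next }
    if (is_kw(t, "begin")) break
    fail("expected ',' or BEGIN")
  }
  advance()  # BEGIN

  # actions
  actions <- list()
  repeat {
    t <- peek()
    if (is.null(t)) fail("expected END")
    if (is_kw(t, "end")) break
    check_supported(t)
    if (!is_kw(t, "add")) fail("expected ADD")
    advance()
    st <- peek()
    if (is.null(st) || st$type != "var") fail("ADD expects a subject variable")
    subject <- advance()$tok
    kt <- peek()
    kind <- if (is_kw(kt, "subclassof")) "SubClassOf"
            else if (is_kw(kt, "equivalentto")) "EquivalentTo"
            else fail("expected SubClassOf or equivalentTo", kt)
    advance()
    object <- parse_expr()
    actions[[length(actions) + 1L]] <- list(kind = kind, subject = subject,
                                            object = object)
  }
  advance()  # END
  t <- peek()
  if (!is.null(t) && t$type == "punct" && t$tok == ";") advance()
  if (!is.null(peek())) fail("trailing content after END")

  if (length(actions) == 0L) stop("pattern: no actions between BEGIN and END",
                                  call. = FALSE)
  # every variable used in actions must be declared or defined
  known <- c(declarations, names(definitions))
  for (a in actions) {
    used <- c(a$subject, expr_vars(a$object))
    miss <- setdiff(used, known)
    if (length(miss))
      stop("pattern: action uses undeclared variable '", miss[1], "'",
           call. = FALSE)
  }
  structure(list(declarations = declarations, definitions = definitions,
                 actions = actions, id = id),
            class = "pattern_script")
}

expr_vars <- function(node) {
  switch(node_kind(node),
    op_var = node$name,
    op_some = c(expr_vars(node$prop), expr_vars(node$filler)),
    op_and = unique(unlist(lapply(node$children, expr_vars))),
    character(0))
}

#' @export
print.pattern_script <- function(x, ...) {
  cat("<pattern_script> '", x$id, "': ",
      length(x$declarations) - length(x$definitions), " input variables, ",
      length(x$definitions), " defined, ", length(x$actions), " actions\n",
      sep = "")
  invisible(x)
}

#' Input variables of a pattern
#'
#' The declared variables that carry no definition, in declaration order;
#' exactly these require a column binding.
#'
#' @param script a `pattern_script`.
#' @return character vector of `?`-prefixed names.
#' @export
input_variables <- function(script) {
  stopifnot(inherits(script, "pattern_script"))
  setdiff(script$declarations, names(script$definitions))
}

# ---- pretty printer -------------------------------------------------------

render_expr <- function(node, parens_restriction = FALSE) {
  switch(node_kind(node),
    op_named = node$name,
    op_var = node$name,
    op_term = node$term$curie,
    op_some = {
      s <- paste0(render_expr(node$prop), " some ", render_expr(node$filler))
      if (parens_restriction) paste0("(", s, ")") else s
    },
    op_and = paste(vapply(node$children, function(ch) {
      if (node_kind(ch) %in% c("op_some", "op_and"))
        paste0("(", render_expr(ch), ")")
      else render_expr(ch)
    }, ""), collapse = " and "),
    stop("render_expr: unknown node"))
}

#' Render a pattern script back to text
#'
#' Produces canonical script text; `parse_pattern(render_pattern(s))` is
#' structurally equal to `s`.
#'
#' @param script a `pattern_script`.
#' @return single string.
#' @export
render_pattern <- function(script) {
  decls <- vapply(script$declarations, function(v) {
    if (v %in% names(script$definitions)) {
      body <- script$definitions[[v]]
      rhs <- if (inherits(body, "op_macro"))
        paste0("createIntersection(", body$var, ".VALUES)")
      else render_expr(body)
      paste0(v, ":CLASS = ", rhs)
    } else paste0(v, ":CLASS")
  }, "")
  acts <- vapply(script$actions, function(a)
    paste0("ADD ", a$subject, " ",
           if (a$kind == "EquivalentTo") "equivalentTo" else a$kind, " ",
           render_expr(a$object)), "")
  paste0(paste(decls, collapse = ",\n"), "\nBEGIN\n",
         paste(acts, collapse = "\n"), "\nEND;")
}

# ---- expansion ------------------------------------------------------------

flatten_and <- function(nodes) {
  out <- list()
  for (n in nodes) {
    if (node_kind(n) == "op_and") out <- c(out, flatten_and(n$children))
    else out <- c(out, list(n))
  }
  out
}

dedup_nodes <- function(nodes) {
  keys <- vapply(nodes, node_key, "")
  nodes[!duplicated(keys)]
}

make_intersection <- function(conjuncts) {
  conjuncts <- dedup_nodes(flatten_and(conjuncts))
  if (length(conjuncts) == 0L) return(NULL)
  if (length(conjuncts) == 1L) return(conjuncts[[1]])
  op_and(conjuncts)
}

# instantiate a template expression: substitute variables from `env`
# (a named list of single ground nodes) and resolve bare/CURIE names
instantiate_expr <- function(node, env, resolve) {
  switch(node_kind(node),
    op_var = {
      v <- env[[node$name]]
      if (is.null(v)) stop("expand: unbound variable '", node$name, "'",
                           call. = FALSE)
      v
    },
    op_named = {
      t <- if (is.null(resolve)) NULL else resolve(node$name)
      if (is.null(t)) node else op_term(t)
    },
    op_term = node,
    op_some = op_some(instantiate_expr(node$prop, env, resolve),
                      instantiate_expr(node$filler, env, resolve)),
    op_and = op_and(lapply(node$children, instantiate_expr,
                           env = env, resolve = resolve)),
    stop("instantiate_expr: unknown node"))
}

# all instantiations of a template over the bound values of its variables;
# a single referenced variable (the common case) yields one instance per
# value in order; several referenced variables yield their cartesian
# product, first variable slowest
instantiations <- function(body, values, resolve) {
  refs <- expr_vars(body)
  refs <- refs[refs %in% names(values)]
  if (length(refs) == 0L)
    return(list(instantiate_expr(body, list(), resolve)))
  lens <- vapply(values[refs], length, 0L)
  if (any(lens == 0L)) return(list())
  idx <- expand.grid(rev(lapply(lens, seq_len)), KEEP.OUT.ATTRS = FALSE)
  idx <- idx[, rev(seq_along(refs)), drop = FALSE]
  names(idx) <- refs
  lapply(seq_len(nrow(idx)), function(i) {
    env <- stats::setNames(lapply(refs, function(r) values[[r]][[idx[i, r]]]), refs)
    instantiate_expr(body, env, resolve)
  })
}

new_axiom <- function(kind, subject, object = NULL, annotation = NULL) {
  structure(list(kind = kind, subject = subject, object = object,
                 annotation = annotation),
            class = "ground_axiom")
}

#' @export
print.ground_axiom <- function(x, ...) {
  obj <- if (!is.null(x$object)) render_expr(x$object) else
    if (!is.null(x$annotation)) paste0("\"", x$annotation$value, "\"") else ""
  cat("<ground_axiom> ", x$kind, "(", x$subject$curie, ", ", obj, ")\n", sep = "")
  invisible(x)
}

#' Expand a bound pattern into ground axioms
#'
#' For every defined variable, the definition is instantiated once per bound
#' value of each input variable it references (`.VALUES` semantics);
#' `createIntersection` conjoins those instances, flattening nested
#' intersections and removing syntactically duplicate conjuncts (a single
#' instance stays unwrapped). Each action then emits one axiom per subject
#' value. A `SubClassOf` action whose object is an intersection is split
#' into one axiom per conjunct; `EquivalentTo` objects are kept whole. An
#' action referencing a variable with zero bound values emits nothing.
#'
#' @param script a `pattern_script`.
#' @param binding named list mapping each input variable to a (possibly
#'   empty) list of [term_ref].
#' @param resolve optional function mapping a bare/CURIE name in the script
#'   (e.g. `"cell"`, `"ro:part_of"`) to a [term_ref]; unresolved names stay
#'   symbolic.
#' @return list of `ground_axiom`.
#' @export
expand <- function(script, binding = list(), resolve = NULL) {
  stopifnot(inherits(script, "pattern_script"))
  ivars <- input_variables(script)
  miss <- setdiff(ivars, names(binding))
  # missing entries are only an error if an action actually needs them
  values <- list()
  for (v in ivars) {
    vals <- if (v %in% names(binding)) binding[[v]] else NULL
    values[[v]] <- lapply(vals, function(t) {
      stopifnot(inherits(t, "term_ref"))
      op_term(t)
    })
  }
  for (v in names(script$definitions)) {
    body <- script$definitions[[v]]
    if (inherits(body, "op_macro")) {
      src <- values[[body$var]]
      if (is.null(src)) stop("expand: macro over unbound variable '",
                             body$var, "'", call. = FALSE)
      node <- make_intersection(src)
      values[[v]] <- if (is.null(node)) list() else list(node)
    } else {
      values[[v]] <- instantiations(body, values, resolve)
    }
  }

  axioms <- list()
  for (a in script$actions) {
    for (used in c(a$subject, intersect(expr_vars(a$object), ivars)))
      if (used %in% miss)
        stop("expand: input variable '", used,
             "' referenced by an action has no binding", call. = FALSE)
    subjects <- values[[a$subject]]
    if (is.null(subjects)) subjects <- list()
    objects <- if (node_kind(a$object) == "op_var") {
      ov <- values[[a$object$name]]
      if (is.null(ov)) list() else ov
    } else {
      instantiations(a$object, values, resolve)
    }
    for (s in subjects) {
      if (node_kind(s) != "op_term")
        stop("expand: action subject must be bound to terms", call. = FALSE)
      for (o in objects) {
        if (a$kind == "SubClassOf" && node_kind(o) == "op_and") {
          for (cj in o$children)
            axioms[[length(axioms) + 1L]] <- new_axiom("SubClassOf", s$term, cj)
        } else {
          axioms[[length(axioms) + 1L]] <- new_axiom(a$kind, s$term, o)
        }
      }
    }
  }
  axioms
}
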