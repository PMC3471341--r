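# Triple-level RDF support.
#
# Both RDF dialects are reduced to a common triple table
# (s, p, o, o_literal) with blank nodes as "_:name"; the snapshot builder
# and the axiom reader work over that table, so each dialect needs only a
# syntax layer. Only the constructs the package emits or the miniature
# vocabularies use are supported: prefix declarations, prefixed names and
# IRIs, blank nodes ([] and _:label), collections, plain/lang-tagged string
# literals, and predicate/object lists.

RDF  <- "http://www.w3.org/1999/02/22-rdf-syntax-ns#"
RDFS <- "http://www.w3.org/2000/01/rdf-schema#"
OWL  <- "http://www.w3.org/2002/07/owl#"

triple_df <- function(s = character(), p = character(), o = character(),
                      o_literal = logical()) {
  data.frame(s = s, p = p, o = o, o_literal = o_literal,
             stringsAsFactors = FALSE)
}

# ---- Turtle reading -------------------------------------------------------

turtle_tokens <- function(text) {
  # strip comments outside literals, then scan
  toks <- list(); types <- character(); lines <- integer()
  n <- nchar(text); i <- 1L; line <- 1L
  push <- function(tok, type, ln) {
    toks[[length(toks) + 1L]] <<- tok
    types[length(types) + 1L] <<- type
    lines[length(lines) + 1L] <<- ln
  }
  while (i <= n) {
    ch <- substr(text, i, i)
    if (ch == "\n") { line <- line + 1L; i <- i + 1L; next }
    if (ch %in% c(" ", "\t", "\r")) { i <- i + 1L; next }
    if (ch == "#") { while (i <= n && substr(text, i, i) != "\n") i <- i + 1L; next }
    if (ch %in% c(".", ";", ",", "[", "]", "(", ")")) {
      push(ch, "punct", line); i <- i + 1L; next
    }
    if (ch == "<") {
      j <- regexpr(">", substr(text, i, n), fixed = TRUE)
      if (j < 0L) stop(sprintf("turtle: unterminated IRI at line %d", line), call. = FALSE)
      push(substr(text, i + 1L, i + j - 2L), "iri", line); i <- i + j; next
    }
    if (ch == "\"") {
      j <- i + 1L; buf <- character()
      while (j <= n) {
        cj <- substr(text, j, j)
        if (cj == "\\") { buf <- c(buf, substr(text, j + 1L, j + 1L)); j <- j + 2L; next }
        if (cj == "\"") break
        if (cj == "\n") line <- line + 1L
        buf <- c(buf, cj); j <- j + 1L
      }
      if (j > n) stop(sprintf("turtle: unterminated literal at line %d", line), call. = FALSE)
      i <- j + 1L
      # optional @lang or ^^datatype, recorded but not kept
      rest <- substr(text, i, n)
      m <- regexpr("^(@[A-Za-z-]+|\\^\\^[^\\s;,.)\\]]+)", rest)
      if (m > 0L) i <- i + attr(m, "match.length")
      push(paste0(buf, collapse = ""), "literal", line); next
    }
    # pname, blank node label, or @keyword
    m <- regexpr("^[^\\s;,\\[\\]()\"]+", substr(text, i, n), perl = TRUE)
    tok <- regmatches(substr(text, i, n), m)
    if (length(tok) == 0L)
      stop(sprintf("turtle: unexpected character '%s' at line %d", ch, line),
           call. = FALSE)
    # a trailing '.' ends the statement unless part of a pname local with more after
    while (endsWith(tok, ".")) tok <- substr(tok, 1L, nchar(tok) - 1L)
    if (!nzchar(tok)) stop(sprintf("turtle: stray '.' at line %d", line), call. = FALSE)
    type <- if (startsWith(tok, "@")) "keyword"
            else if (startsWith(tok, "_:")) "blank"
            else "pname"
    push(tok, type, line)
    i <- i + nchar(tok)
  }
  list(tok = toks, type = types, line = lines)
}

parse_turtle <- function(text) {
  tk <- turtle_tokens(text)
  prefixes <- character()
  rows <- list()
  bcount <- 0L
  pos <- 1L
  npos <- length(tk$tok)

  peek <- function() if (pos <= npos) tk$tok[[pos]] else NULL
  ptype <- function() if (pos <= npos) tk$type[[pos]] else "eof"
  advance <- function() { t <- tk$tok[[pos]]; pos <<- pos + 1L; t }
  fail <- function(msg) {
    ln <- if (pos <= npos) tk$line[[pos]] else tk$line[[npos]]
    stop(sprintf("turtle: %s at line %d", msg, ln), call. = FALSE)
  }
  expect <- function(tok) if (!identical(peek(), tok)) fail(paste0("expected '", tok, "'")) else advance()
  emit <- function(s, p, o, lit = FALSE) rows[[length(rows) + 1L]] <<- list(s = s, p = p, o = o, lit = lit)
  fresh_blank <- function() { bcount <<- bcount + 1L; paste0("_:tb", bcount) }

  resolve <- function(tok, type) {
    if (type == "iri") return(tok)
    if (type == "blank") return(tok)
    if (type == "pname") {
      if (tok == "a") return(paste0(RDF, "type"))
      colon <- regexpr(":", tok, fixed = TRUE)
      if (colon < 0L) fail(paste0("bare name '", tok, "'"))
      pfx <- substr(tok, 1L, colon - 1L)
      if (!pfx %in% names(prefixes)) fail(paste0("undeclared prefix '", pfx, ":'"))
      return(paste0(prefixes[[pfx]], substr(tok, colon + 1L, nchar(tok))))
    }
    fail(paste0("unexpected token '", tok, "'"))
  }

  parse_node <- function() {
    # returns list(id, lit)
    t <- peek(); ty <- ptype()
    if (ty == "literal") { advance(); return(list(id = t, lit = TRUE)) }
    if (identical(t, "[")) {
      advance()
      b <- fresh_blank()
      if (!identical(peek(), "]")) parse_polist(b)
      expect("]")
      return(list(id = b, lit = FALSE))
    }
    if (identical(t, "(")) {
      advance()
      items <- list()
      while (!identical(peek(), ")")) items[[length(items) + 1L]] <- parse_node()
      advance()
      if (length(items) == 0L) return(list(id = paste0(RDF, "nil"), lit = FALSE))
      ids <- vapply(seq_along(items), function(i) fresh_blank(), character(1))
      for (i in seq_along(items)) {
        emit(ids[i], paste0(RDF, "first"), items[[i]]$id, items[[i]]$lit)
        emit(ids[i], paste0(RDF, "rest"),
             if (i < length(items)) ids[i + 1L] else paste0(RDF, "nil"))
      }
      return(list(id = ids[1L], lit = FALSE))
    }
    advance()
    list(id = resolve(t, ty), lit = FALSE)
  }

  parse_polist <- function(subj) {
    repeat {
      ptok <- advance_checked()
      p <- resolve(ptok, last_type)
      repeat {
        o <- parse_node()
        emit(subj, p, o$id, o$lit)
        if (identical(peek(), ",")) { advance(); next }
        break
      }
      if (identical(peek(), ";")) {
        advance()
        # allow trailing ';' before ']' or '.'
        if (identical(peek(), "]") || identical(peek(), ".")) break
        next
      }
      break
    }
  }
  last_type <- NULL
  advance_checked <- function() {
    if (pos > npos) fail("unexpected end of input")
    last_type <<- ptype()
    advance()
  }

  while (pos <= npos) {
    t <- peek()
    if (ptype() == "keyword") {
      kw <- tolower(advance())
      if (kw == "@prefix") {
        label <- advance()  # "p:" form
        label <- sub(":$", "", label)
        if (ptype() != "iri") fail("@prefix expects an IRI")
        ns <- advance()
        expect(".")
        prefixes[label] <- ns
        next
      }
      if (kw == "@base") { advance(); expect("."); next }
      fail(paste0("unsupported directive '", kw, "'"))
    }
    subj <- parse_node()
    if (subj$lit) fail("literal cannot be a subject")
    if (!identical(peek(), ".")) parse_polist(subj$id)
    expect(".")
  }

  tri <- if (length(rows)) {
    triple_df(vapply(rows, `[[`, "", "s"), vapply(rows, `[[`, "", "p"),
              vapply(rows, `[[`, "", "o"), vapply(rows, function(r) r$lit, TRUE))
  } else triple_df()
  attr(tri, "prefixes") <- prefixes
  tri
}

# ---- RDF/XML reading ------------------------------------------------------

parse_rdfxml <- function(text) {
  doc <- tryCatch(xml2::read_xml(text),
                  error = function(e) stop("rdfxml: ", conditionMessage(e), call. = FALSE))
  rows <- list()
  bcount <- 0L
  emit <- function(s, p, o, lit = FALSE) rows[[length(rows) + 1L]] <<- list(s = s, p = p, o = o, lit = lit)
  fresh_blank <- function() { bcount <<- bcount + 1L; paste0("_:xb", bcount) }

  full_name <- function(node) {
    # namespace-resolved element name
    ns <- xml2::xml_ns(doc)
    nm <- xml2::xml_name(node, ns = ns)
    colon <- regexpr(":", nm, fixed = TRUE)
    if (colon < 0L) return(nm)
    pfx <- substr(nm, 1L, colon - 1L)
    paste0(ns[[pfx]], substr(nm, colon + 1L, nchar(nm)))
  }
  rattr <- function(node, what) {
    v <- xml2::xml_attr(node, what, ns = xml2::xml_ns(doc))
    if (is.na(v)) NULL else v
  }

  node_id <- function(node) {
    ab <- rattr(node, "rdf:about")
    if (!is.null(ab)) return(ab)
    nid <- rattr(node, "rdf:nodeID")
    if (!is.null(nid)) return(paste0("_:", nid))
    fresh_blank()
  }

  walk_node <- function(node) {
    # a node element: typed or rdf:Description; returns its id
    id <- node_id(node)
    fn <- full_name(node)
    if (fn != paste0(RDF, "RDF") && fn != paste0(RDF, "Description"))
      emit(id, paste0(RDF, "type"), fn)
    for (prop in xml2::xml_children(node)) {
      pn <- full_name(prop)
      res <- rattr(prop, "rdf:resource")
      if (!is.null(res)) { emit(id, pn, res); next }
      nid <- rattr(prop, "rdf:nodeID")
      if (!is.null(nid)) { emit(id, pn, paste0("_:", nid)); next }
      kids <- xml2::xml_children(prop)
      if (length(kids) == 0L) {
        emit(id, pn, xml2::xml_text(prop), lit = TRUE)
      } else {
        cid <- walk_node(kids[[1L]])
        emit(id, pn, cid)
      }
    }
    id
  }

  root <- xml2::xml_root(doc)
  if (full_name(root) == paste0(RDF, "RDF")) {
    for (child in xml2::xml_children(root)) walk_node(child)
  } else {
    walk_node(root)
  }

  if (length(rows)) {
    triple_df(vapply(rows, `[[`, "", "s"), vapply(rows, `[[`, "", "p"),
              vapply(rows, `[[`, "", "o"), vapply(rows, function(r) r$lit, TRUE))
  } else triple_df()
}

# ---- writing helpers ------------------------------------------------------

turtle_escape <- function(x) {
  x <- gsub("\\", "\\\\", x, fixed = TRUE)
  gsub("\"", "\\\"", x, fixed = TRUE)
}

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}
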