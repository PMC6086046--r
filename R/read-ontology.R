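#' Read an ontology file into a raw triple set
#'
#' Parses an OWL/OBO ontology into a flat table of RDF-style triples, the
#' common denominator the rest of the pipeline works from. Three dialects are
#' supported: OWL RDF/XML (via xml2), OWL Turtle (a restricted parser
#' covering `@prefix` directives, prefixed names, IRIs, literals with
#' `^^`/`@lang` suffixes, and `;`/`,` continuation), and OBO 1.4 flat files
#' (`[Term]`/`[Typedef]` stanzas mapped onto the equivalent OWL vocabulary).
#'
#' @param path Path to the ontology file.
#' @param dialect One of `"auto"`, `"rdf-xml"`, `"turtle"`, `"obo"`. With
#'   `"auto"` the dialect is chosen from the file extension
#'   (`.owl`/`.rdf`/`.xml`, `.ttl`, `.obo`).
#' @return An object of class `ontropy_raw`: a list with `source_path`,
#'   `dialect`, and `triples`, a tibble with columns `subject`, `predicate`,
#'   `object` and `object_type` (one of `"iri"`, `"literal"`, `"blank"`).
#'   Annotation literals are preserved verbatim.
#' @export
#' @examples
#' ttl <- tempfile(fileext = ".ttl")
#' writeLines(c(
#'   "@prefix owl: <http://www.w3.org/2002/07/owl#> .",
#'   "@prefix rdfs: <http://www.w3.org/2000/01/rdf-schema#> .",
#'   "@prefix : <http://example.org/onto#> .",
#'   ":A a owl:Class ; rdfs:label \"alpha\" .",
#'   ":B a owl:Class ; rdfs:subClassOf :A ."
#' ), ttl)
#' raw <- read_ontology(ttl)
#' raw$triples
read_ontology <- function(path, dialect = c("auto", "rdf-xml", "turtle", "obo")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) {
    abort(paste0("ontology file not found: ", path), class = "ontropy_io_error")
  }
  if (dialect == "auto") {
    ext <- tolower(tools::file_ext(path))
    dialect <- switch(ext,
      owl = , rdf = , xml = "rdf-xml",
      ttl = "turtle",
      obo = "obo",
      abort(
        paste0("cannot infer ontology dialect from extension '.", ext,
               "'; pass dialect explicitly"),
        class = "ontropy_config_error"
      )
    )
  }
  triples <- switch(dialect,
    "rdf-xml" = parse_rdf_xml(path),
    "turtle"  = parse_turtle(path),
    "obo"     = parse_obo(path)
  )
  structure(
    list(source_path = path, dialect = dialect, triples = triples),
    class = "ontropy_raw"
  )
}

#' @export
print.ontropy_raw <- function(x, ...) {
  cat("<ontropy_raw> ", basename(x$source_path), " [", x$dialect, "]: ",
      nrow(x$triples), " triples\n", sep = "")
  invisible(x)
}

new_triples <- function(subject = character(), predicate = character(),
                        object = character(), object_type = character()) {
  tibble(subject = subject, predicate = predicate,
         object = object, object_type = object_type)
}

## ---- RDF/XML -------------------------------------------------------------

# Striped-syntax RDF/XML: node elements alternate with property elements.
# Covers the serialization styles Protege and OBO releases emit; rdf:parseType
# and reification are out of scope and raise a dialect error.
parse_rdf_xml <- function(path) {
  doc <- tryCatch(
    xml2::read_xml(path),
    error = function(e) abort(
      paste0("RDF/XML parse failure in ", path, ": ", conditionMessage(e)),
      class = "ontropy_dialect_error"
    )
  )
  nsmap <- xml2::xml_ns(doc)
  state <- new.env(parent = emptyenv())
  state$rows <- vector("list", 0L)
  state$blank <- 0L

  expand_name <- function(node) {
    qn <- xml2::xml_name(node, nsmap)
    parts <- strsplit(qn, ":", fixed = TRUE)[[1]]
    if (length(parts) == 2L && parts[1] %in% names(nsmap)) {
      paste0(nsmap[[parts[1]]], parts[2])
    } else {
      qn
    }
  }
  attr_local <- function(node, local) {
    at <- xml2::xml_attrs(node)
    hit <- grepl(paste0("(^|:)", local, "$"), names(at))
    if (any(hit)) at[[which(hit)[1]]] else NA_character_
  }
  emit <- function(s, p, o, type) {
    state$rows[[length(state$rows) + 1L]] <-
      list(subject = s, predicate = p, object = o, object_type = type)
  }

  parse_node <- function(node) {
    subj <- attr_local(node, "about")
    if (is.na(subj)) {
      id <- attr_local(node, "ID")
      if (!is.na(id)) subj <- paste0("#", id)
    }
    subj_type <- "iri"
    if (is.na(subj)) {
      state$blank <- state$blank + 1L
      subj <- paste0("_:b", state$blank)
      subj_type <- "blank"
    }
    ename <- expand_name(node)
    if (ename != paste0("http://www.w3.org/1999/02/22-rdf-syntax-ns#", "Description")) {
      emit(subj, IRI$type, ename, "iri")
    }
    for (prop in xml2::xml_children(node)) {
      pred <- expand_name(prop)
      res <- attr_local(prop, "resource")
      kids <- xml2::xml_children(prop)
      if (!is.na(res)) {
        emit(subj, pred, res, "iri")
      } else if (length(kids) > 0L) {
        for (k in kids) {
          nested <- parse_node(k)
          emit(subj, pred, nested$subject, nested$type)
        }
      } else {
        emit(subj, pred, xml2::xml_text(prop), "literal")
      }
    }
    list(subject = subj, type = subj_type)
  }

  root_name <- xml2::xml_name(xml2::read_xml(path))
  top <- xml2::xml_children(doc)
  if (identical(root_name, "RDF")) {
    for (n in top) parse_node(n)
  } else {
    parse_node(xml2::xml_root(doc))
  }
  rows_to_triples(state$rows)
}

rows_to_triples <- function(rows) {
  if (length(rows) == 0L) return(new_triples())
  new_triples(
    subject = vapply(rows, `[[`, character(1), "subject"),
    predicate = vapply(rows, `[[`, character(1), "predicate"),
    object = vapply(rows, `[[`, character(1), "object"),
    object_type = vapply(rows, `[[`, character(1), "object_type")
  )
}

## ---- Turtle --------------------------------------------------------------

# Restricted Turtle: @prefix, IRIs, prefixed names, the `a` keyword, plain and
# typed/lang-tagged double-quoted literals, `;` and `,` continuation.
# Blank-node syntax and collections are rejected with a dialect error.
parse_turtle <- function(path) {
  text <- readLines(path, warn = FALSE, encoding = "UTF-8")
  toks <- turtle_tokenize(text, path)
  i <- 1L
  n <- length(toks$value)
  pfx_names <- character(0)
  pfx_iris <- character(0)
  rows <- list()

  stop_at <- function(msg, pos) {
    line <- if (pos <= n) toks$line[pos] else toks$line[n]
    abort(paste0("Turtle parse failure in ", path, " at line ", line, ": ", msg),
          class = "ontropy_dialect_error")
  }
  peek_kind <- function() if (i <= n) toks$kind[i] else "eof"
  take <- function() {
    if (i > n) stop_at("unexpected end of input", n)
    v <- list(kind = toks$kind[i], value = toks$value[i], line = toks$line[i])
    i <<- i + 1L
    v
  }
  expect_punct <- function(ch) {
    t <- take()
    if (t$kind != "punct" || t$value != ch) {
      stop_at(paste0("expected '", ch, "', got '", t$value, "'"), i - 1L)
    }
  }
  resolve_term <- function(t) {
    switch(t$kind,
      iri = list(value = t$value, type = "iri"),
      pname = {
        parts <- strsplit(t$value, ":", fixed = TRUE)[[1]]
        pfx <- if (length(parts) >= 1L) parts[1] else ""
        local <- if (length(parts) == 2L) parts[2] else ""
        if (t$value == "a") {
          list(value = IRI$type, type = "iri")
        } else {
          pos <- match(pfx, pfx_names)
          if (is.na(pos)) {
            stop_at(paste0("undeclared prefix '", pfx, ":'"), i - 1L)
          }
          list(value = paste0(pfx_iris[pos], local), type = "iri")
        }
      },
      literal = list(value = t$value, type = "literal"),
      stop_at(paste0("unexpected token '", t$value, "'"), i - 1L)
    )
  }

  while (i <= n) {
    t <- take()
    if (t$kind == "pname" && t$value %in% c("@prefix", "@base")) {
      if (t$value == "@base") stop_at("@base is not supported", i - 1L)
      pt <- take()
      if (pt$kind != "pname" || !grepl(":$", pt$value)) {
        stop_at("expected prefix name after @prefix", i - 1L)
      }
      iri_t <- take()
      if (iri_t$kind != "iri") stop_at("expected IRI in @prefix", i - 1L)
      expect_punct(".")
      pfx_names <- c(pfx_names, sub(":$", "", pt$value))
      pfx_iris <- c(pfx_iris, iri_t$value)
      next
    }
    subj <- resolve_term(t)
    if (subj$type != "iri") stop_at("subject must be an IRI", i - 1L)
    repeat {
      verb <- resolve_term(take())
      if (verb$type != "iri") stop_at("predicate must be an IRI", i - 1L)
      repeat {
        obj <- resolve_term(take())
        rows[[length(rows) + 1L]] <- list(
          subject = subj$value, predicate = verb$value,
          object = obj$value, object_type = obj$type
        )
        if (peek_kind() == "punct" && toks$value[i] == ",") { take(); next }
        break
      }
      if (peek_kind() == "punct" && toks$value[i] == ";") {
        take()
        # tolerate trailing ';' before '.'
        if (peek_kind() == "punct" && toks$value[i] == ".") break
        next
      }
      break
    }
    expect_punct(".")
  }
  rows_to_triples(rows)
}

turtle_tokenize <- function(lines, path) {
  kinds <- character(0); values <- character(0); linenos <- integer(0)
  push <- function(kind, value, line) {
    kinds <<- c(kinds, kind); values <<- c(values, value); linenos <<- c(linenos, line)
  }
  for (ln in seq_along(lines)) {
    s <- lines[[ln]]
    j <- 1L; len <- nchar(s)
    while (j <= len) {
      ch <- substr(s, j, j)
      if (grepl("^\\s$", ch)) { j <- j + 1L; next }
      if (ch == "#") break
      if (ch == "<") {
        close <- regexpr(">", substr(s, j + 1L, len), fixed = TRUE)
        if (close == -1L) {
          abort(paste0("Turtle parse failure in ", path, " at line ", ln,
                       ": unterminated IRI"), class = "ontropy_dialect_error")
        }
        push("iri", substr(s, j + 1L, j + close - 1L), ln)
        j <- j + close + 1L
        next
      }
      if (ch == "\"") {
        k <- j + 1L; buf <- character(0); closed <- FALSE
        while (k <= len) {
          c2 <- substr(s, k, k)
          if (c2 == "\\") {
            esc <- substr(s, k + 1L, k + 1L)
            buf <- c(buf, switch(esc, n = "\n", t = "\t", r = "\r",
                                 "\"" = "\"", "\\" = "\\", esc))
            k <- k + 2L
          } else if (c2 == "\"") { closed <- TRUE; k <- k + 1L; break
          } else { buf <- c(buf, c2); k <- k + 1L }
        }
        if (!closed) {
          abort(paste0("Turtle parse failure in ", path, " at line ", ln,
                       ": unterminated string literal"),
                class = "ontropy_dialect_error")
        }
        # consume optional datatype / language tag, keep the lexical form
        rest <- substr(s, k, len)
        sfx <- regmatches(rest, regexpr("^(\\^\\^\\S+|@[A-Za-z-]+)", rest))
        if (length(sfx) == 1L) {
          if (startsWith(sfx, "^^<")) {
            close <- regexpr(">", rest, fixed = TRUE)
            sfx <- substr(rest, 1L, close)
          }
          k <- k + nchar(sfx)
        }
        push("literal", paste(buf, collapse = ""), ln)
        j <- k
        next
      }
      if (ch %in% c(".", ";", ",")) { push("punct", ch, ln); j <- j + 1L; next }
      if (ch %in% c("[", "]", "(", ")")) {
        abort(paste0("Turtle parse failure in ", path, " at line ", ln,
                     ": blank-node/collection syntax is not supported"),
              class = "ontropy_dialect_error")
      }
      m <- regexpr("^[^\\s;,.\"<>\\[\\]()#]+\\.?", substr(s, j, len), perl = TRUE)
      word <- regmatches(substr(s, j, len), m)
      # a trailing '.' after a pname ends the statement
      if (grepl("\\.$", word) && word != "@prefix") {
        word2 <- sub("\\.$", "", word)
        push("pname", word2, ln)
        push("punct", ".", ln)
      } else {
        push("pname", word, ln)
      }
      j <- j + nchar(word)
    }
  }
  list(kind = kinds, value = values, line = linenos)
}

## ---- OBO 1.4 -------------------------------------------------------------

# [Term] and [Typedef] stanzas mapped to the OWL vocabulary: is_a becomes
# rdfs:subClassOf, name rdfs:label, def the IAO textual-definition
# annotation, relationship a plain object-property assertion.
parse_obo <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  rows <- list()
  emit <- function(s, p, o, type) {
    rows[[length(rows) + 1L]] <<- list(subject = s, predicate = p,
                                       object = o, object_type = type)
  }
  stanza <- NULL
  id <- NA_character_
  pending <- list()
  flush <- function() {
    if (is.null(stanza) || is.na(id)) return()
    cls <- if (stanza == "Term") IRI$class else IRI$objprop
    emit(id, IRI$type, cls, "iri")
    for (p in pending) emit(id, p$pred, p$obj, p$type)
  }
  for (raw_line in lines) {
    line <- sub("(?<!\\\\)!.*$", "", raw_line, perl = TRUE)
    line <- trimws(line)
    if (!nzchar(line)) next
    if (grepl("^\\[.*\\]$", line)) {
      flush()
      stanza <- sub("^\\[(.*)\\]$", "\\1", line)
      id <- NA_character_
      pending <- list()
      next
    }
    if (is.null(stanza)) next  # header lines
    m <- regmatches(line, regexec("^([A-Za-z_]+):\\s*(.*)$", line))[[1]]
    if (length(m) != 3L) next
    key <- m[2]; val <- trimws(m[3])
    if (key == "id") { id <- val; next }
    pend <- switch(key,
      name = list(pred = IRI$label, obj = val, type = "literal"),
      def = {
        q <- regmatches(val, regexec("^\"(.*)\"", val))[[1]]
        if (length(q) == 2L) list(pred = IRI$definition, obj = q[2], type = "literal") else NULL
      },
      is_a = list(pred = IRI$subclassof, obj = val, type = "iri"),
      equivalent_to = list(pred = IRI$equivalent, obj = val, type = "iri"),
      disjoint_from = list(pred = IRI$disjoint, obj = val, type = "iri"),
      relationship = {
        parts <- strsplit(val, "\\s+")[[1]]
        if (length(parts) >= 2L) list(pred = parts[1], obj = parts[2], type = "iri") else NULL
      },
      NULL
    )
    if (!is.null(pend)) pending[[length(pending) + 1L]] <- pend
  }
  flush()
  rows_to_triples(rows)
}
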