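#' @title RDF serialization and dereferencing
#' @description
#' Turtle for human-facing output, N-Triples for line-oriented bulk dumps.
#' Both round-trip losslessly: literals containing double quotes, newlines
#' and non-ASCII text survive serialize-then-parse (escaping is handled
#' here once, not ad hoc at the print site, which historically was a
#' failure mode of string-built exporters).
#' @name rdf-io
NULL

.escape_literal <- function(x) {
  x <- gsub("\\", "\\\\", x, fixed = TRUE)
  x <- gsub("\"", "\\\"", x, fixed = TRUE)
  x <- gsub("\n", "\\n", x, fixed = TRUE)
  x <- gsub("\r", "\\r", x, fixed = TRUE)
  gsub("\t", "\\t", x, fixed = TRUE)
}

.unescape_literal <- function(x) {
  vapply(x, function(s) {
    if (!grepl("\\", s, fixed = TRUE)) return(s)
    chars <- strsplit(s, "", fixed = TRUE)[[1]]
    out <- character(0)
    i <- 1L
    n <- length(chars)
    while (i <= n) {
      if (chars[i] == "\\" && i < n) {
        nxt <- chars[i + 1L]
        if (nxt == "u" && i + 5L <= n) {
          code <- strtoi(paste(chars[(i + 2L):(i + 5L)], collapse = ""), 16L)
          out <- c(out, intToUtf8(code))
          i <- i + 6L
        } else if (nxt == "U" && i + 9L <= n) {
          code <- strtoi(paste(chars[(i + 2L):(i + 9L)], collapse = ""), 16L)
          out <- c(out, intToUtf8(code))
          i <- i + 10L
        } else {
          out <- c(out, switch(nxt, n = "\n", r = "\r", t = "\t",
                               "\\" = "\\", "\"" = "\"", "'" = "'", nxt))
          i <- i + 2L
        }
      } else {
        out <- c(out, chars[i])
        i <- i + 1L
      }
    }
    paste(out, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

.term_nt <- function(object, object_type, datatype, lang) {
  ifelse(object_type == "blank", object,
  ifelse(object_type == "iri", paste0("<", object, ">"),
         paste0("\"", .escape_literal(object), "\"",
                ifelse(!is.na(lang), paste0("@", lang),
                       ifelse(!is.na(datatype),
                              paste0("^^<", datatype, ">"), "")))))
}

#' Serialize a graph to N-Triples
#'
#' Line-oriented and diff-friendly; rows are emitted in a deterministic
#' (sorted) order.
#'
#' @param graph An `rdf_graph`.
#' @return A single character scalar (the document).
#' @export
serialize_ntriples <- function(graph) {
  t <- tibble::as_tibble(graph)
  if (nrow(t) == 0) return("")
  subj <- ifelse(startsWith(t$subject, "_:"), t$subject,
                 paste0("<", t$subject, ">"))
  lines <- paste0(subj, " <", t$predicate, "> ",
                  .term_nt(t$object, t$object_type, t$datatype, t$lang), " .")
  paste0(paste(sort(lines), collapse = "\n"), "\n")
}

# shorten an IRI to a prefixed name when a bound namespace matches and the
# local part is safe; otherwise keep <iri>
.shorten <- function(iri, ns) {
  bases <- unname(ns)
  prefixes <- names(ns)
  ord <- order(nchar(bases), decreasing = TRUE)
  out <- paste0("<", iri, ">")
  out[is.na(iri)] <- NA_character_
  done <- rep(FALSE, length(iri)) | is.na(iri)
  for (i in ord) {
    hit <- !done & startsWith(iri, bases[i])
    hit[is.na(hit)] <- FALSE
    if (!any(hit)) next
    local <- substring(iri[hit], nchar(bases[i]) + 1L)
    safe <- grepl("^[A-Za-z_][A-Za-z0-9_-]*$", local)
    idx <- which(hit)[safe]
    out[idx] <- paste0(prefixes[i], ":",
                       substring(iri[which(hit)][safe],
                                 nchar(bases[i]) + 1L))
    done[idx] <- TRUE
  }
  out
}

#' Serialize a graph to Turtle
#'
#' Prefix declarations from the graph's namespace bindings, triples grouped
#' by subject with `;`/`,` continuation, `a` for `rdf:type`.  Deterministic
#' output for a given graph.
#'
#' @param graph An `rdf_graph`.
#' @return A single character scalar (the document).
#' @export
serialize_turtle <- function(graph) {
  t <- tibble::as_tibble(graph)
  ns <- attr(graph, "namespaces") %||% default_namespaces()
  header <- paste0("@prefix ", names(ns), ": <", unname(ns), "> .")
  if (nrow(t) == 0) return(paste0(paste(header, collapse = "\n"), "\n"))

  rdf_type <- paste0(ns[["rdf"]] %||%
                       "http://www.w3.org/1999/02/22-rdf-syntax-ns#", "type")
  subj_tok <- ifelse(startsWith(t$subject, "_:"), t$subject,
                     .shorten(t$subject, ns))
  pred_tok <- ifelse(t$predicate == rdf_type, "a", .shorten(t$predicate, ns))
  obj_tok <- ifelse(
    t$object_type == "blank", t$object,
    ifelse(t$object_type == "iri", .shorten(t$object, ns),
           paste0("\"", .escape_literal(t$object), "\"",
                  ifelse(!is.na(t$lang), paste0("@", t$lang),
                         ifelse(!is.na(t$datatype),
                                paste0("^^", .shorten(t$datatype, ns)), "")))))
  d <- tibble::tibble(s = subj_tok, p = pred_tok, o = obj_tok) |>
    dplyr::arrange(.data$s, .data$p != "a", .data$p, .data$o)
  blocks <- d |>
    dplyr::group_by(.data$s, .data$p) |>
    dplyr::summarise(po = paste(.data$o, collapse = " , "),
                     .groups = "drop_last") |>
    dplyr::summarise(
      block = paste0(.data$s[1], " ",
                     paste(paste(.data$p, .data$po), collapse = " ;\n    "),
                     " ."),
      .groups = "drop")
  paste0(paste(header, collapse = "\n"), "\n\n",
         paste(blocks$block, collapse = "\n"), "\n")
}

#' Serialize a graph
#'
#' @param graph An `rdf_graph`.
#' @param format `"turtle"` or `"ntriples"`.
#' @return Character scalar.
#' @export
serialize_rdf <- function(graph, format = c("turtle", "ntriples")) {
  switch(match.arg(format),
         turtle = serialize_turtle(graph),
         ntriples = serialize_ntriples(graph))
}

# ---- N-Triples parser -------------------------------------------------------

.parse_nt_object <- function(tok, lineno) {
  if (startsWith(tok, "<")) {
    if (!grepl("^<[^>]*>$", tok)) {
      stop("line ", lineno, ": malformed IRI object", call. = FALSE)
    }
    return(list(o = substr(tok, 2, nchar(tok) - 1), type = "iri",
                dt = NA_character_, lang = NA_character_))
  }
  if (startsWith(tok, "_:")) {
    return(list(o = tok, type = "blank", dt = NA_character_,
                lang = NA_character_))
  }
  m <- regmatches(tok, regexec(
    '^"((?:[^"\\\\]|\\\\.)*)"(?:@([A-Za-z]+(?:-[A-Za-z0-9]+)*)|\\^\\^<([^>]*)>)?$',
    tok))[[1]]
  if (length(m) == 0) {
    stop("line ", lineno, ": malformed object term: ", tok, call. = FALSE)
  }
  list(o = .unescape_literal(m[2]), type = "literal",
       dt = if (nzchar(m[4])) m[4] else NA_character_,
       lang = if (nzchar(m[3])) m[3] else NA_character_)
}

#' Parse an N-Triples document
#'
#' @param text Document text (character scalar or lines).
#' @param namespaces Namespace bindings to attach to the result.
#' @return An `rdf_graph` (set semantics: duplicate statements collapse).
#' @export
parse_ntriples <- function(text, namespaces = default_namespaces()) {
  lines <- unlist(strsplit(paste(text, collapse = "\n"), "\n", fixed = TRUE))
  keep <- which(nzchar(trimws(lines)) & !grepl("^\\s*#", lines))
  rows <- lapply(keep, function(i) {
    ln <- trimws(lines[i])
    m <- regmatches(ln, regexec(
      "^(<[^>]*>|_:\\S+)\\s+<([^>]*)>\\s+(.*?)\\s*\\.$", ln))[[1]]
    if (length(m) == 0) {
      stop("N-Triples syntax error at line ", i, ": ", ln, call. = FALSE)
    }
    s <- if (startsWith(m[2], "<")) substr(m[2], 2, nchar(m[2]) - 1) else m[2]
    obj <- .parse_nt_object(m[4], i)
    tibble::tibble(subject = s, predicate = m[3], object = obj$o,
                   object_type = obj$type, datatype = obj$dt,
                   lang = obj$lang)
  })
  rdf_graph(dplyr::bind_rows(rows), namespaces = namespaces)
}

# ---- Turtle parser ----------------------------------------------------------

# one-pass tokenizer: a single alternation regex finds every token, then
# gaps between consecutive tokens are checked to be pure whitespace
.turtle_token_re <- paste0(
  "(?:",
  '"""(?:[^\\\\]|\\\\.)*?"""',                        # long string
  '|"(?:[^"\\\\\n]|\\\\.)*"',                          # string
  "|@(?:prefix|base)\\b",                             # directive
  "|<[^<>\"{}|^`\\\\\\s]*>",                          # IRIREF
  "|_:[A-Za-z0-9][A-Za-z0-9_.-]*",                    # blank node
  "|\\^\\^",                                          # datatype sep
  "|@[A-Za-z]+(?:-[A-Za-z0-9]+)*",                    # language tag
  "|[A-Za-z_][A-Za-z0-9_.-]*:[A-Za-z0-9_][A-Za-z0-9_.-]*", # pname
  "|[A-Za-z_][A-Za-z0-9_.-]*:",                       # pname, empty local
  "|:[A-Za-z0-9_][A-Za-z0-9_.-]*",                    # pname, empty prefix
  "|[+-]?[0-9]+(?:\\.[0-9]+)?(?:[eE][+-]?[0-9]+)?",   # number
  "|\\b(?:a|true|false)\\b",                          # keywords
  "|[.;,]",                                           # punctuation
  "|#[^\n]*",                                         # comment
  ")"
)

.tokenize_turtle <- function(text) {
  src <- paste(text, collapse = "\n")
  if (!nzchar(trimws(src))) return(list())
  mlist <- gregexpr(.turtle_token_re, src, perl = TRUE)
  m <- mlist[[1]]
  starts <- as.integer(m)
  lens <- attr(m, "match.length")
  if (starts[1] == -1) {
    stop("Turtle syntax error at line 1 near: ", substr(src, 1, 30),
         call. = FALSE)
  }
  # any non-whitespace between tokens is a syntax error
  nl_pos <- c(0L, gregexpr("\n", src, fixed = TRUE)[[1]])
  line_of <- function(pos) findInterval(pos - 1L, nl_pos)
  gap_start <- c(1L, starts + lens)
  gap_end <- c(starts - 1L, nchar(src))
  for (i in seq_along(gap_start)) {
    if (gap_start[i] <= gap_end[i]) {
      gap <- substr(src, gap_start[i], gap_end[i])
      if (grepl("[^[:space:]]", gap)) {
        stop("Turtle syntax error at line ", line_of(gap_start[i]),
             " near: ", substr(trimws(gap), 1, 30), call. = FALSE)
      }
    }
  }
  vals <- regmatches(src, mlist)[[1]]
  lines <- line_of(starts)
  keep <- !startsWith(vals, "#")
  vals <- vals[keep]
  lines <- lines[keep]
  type <- character(length(vals))
  first <- substr(vals, 1, 1)
  type[first == "<"] <- "IRIREF"
  type[vals %in% c("@prefix", "@base")] <- "DIRECTIVE"
  is_str <- first == "\"" & type == ""
  type[is_str] <- "STRING"
  type[startsWith(vals, "_:")] <- "BLANK"
  type[vals == "^^"] <- "DTSEP"
  type[first == "@" & type == ""] <- "LANG"
  type[vals == "a"] <- "A"
  type[vals %in% c("true", "false")] <- "BOOL"
  type[vals %in% c(".", ";", ",")] <- "PUNCT"
  type[type == "" & grepl("^[+-]?[0-9]", vals)] <- "NUMBER"
  type[type == "" & grepl(":", vals, fixed = TRUE)] <- "PNAME"
  if (any(type == "")) {
    bad <- which(type == "")[1]
    stop("Turtle syntax error at line ", lines[bad], " near: ", vals[bad],
         call. = FALSE)
  }
  vals[type == "IRIREF"] <- substr(vals[type == "IRIREF"], 2,
                                   nchar(vals[type == "IRIREF"]) - 1L)
  long <- is_str & startsWith(vals, '"""')
  vals[long] <- substr(vals[long], 4, nchar(vals[long]) - 3L)
  short <- is_str & !long
  vals[short] <- substr(vals[short], 2, nchar(vals[short]) - 1L)
  type[type == "LANG"] <- "LANG"
  vals[type == "LANG"] <- substring(vals[type == "LANG"], 2)
  purrr::pmap(list(type, vals, lines),
              function(ty, v, ln) list(type = ty, value = v, line = ln))
}

#' Parse a Turtle document
#'
#' Supports the Turtle subset the serializer emits, plus numeric/boolean
#' shorthand literals, long strings, and comments: prefix directives,
#' prefixed names, IRIs, labelled blank nodes, typed and language-tagged
#' literals, and `;`/`,` continuation.  Syntax errors are fatal and report
#' the line number.
#'
#' @param text Document text.
#' @param namespaces Extra namespace bindings (the document's own
#'   `@prefix` directives take precedence).
#' @return An `rdf_graph`.
#' @export
parse_turtle <- function(text, namespaces = default_namespaces()) {
  toks <- .tokenize_turtle(text)
  ns <- namespaces
  xsd <- function(l) paste0("http://www.w3.org/2001/XMLSchema#", l)
  i <- 1L
  nt <- length(toks)
  rows <- list()
  peek <- function() if (i <= nt) toks[[i]] else list(type = "EOF", line = NA)
  take <- function() {
    t <- peek()
    i <<- i + 1L
    t
  }
  expect <- function(type, what) {
    t <- take()
    if (!identical(t$type, type) ||
        (type == "PUNCT" && !identical(t$value, what))) {
      stop("Turtle syntax error at line ", t$line, ": expected ",
           what %||% type, call. = FALSE)
    }
    t
  }
  expand_pname <- function(tok) {
    parts <- strsplit(tok$value, ":", fixed = TRUE)[[1]]
    prefix <- if (length(parts) >= 1) parts[1] else ""
    local <- if (length(parts) >= 2) paste(parts[-1], collapse = ":") else ""
    base <- ns[[prefix]]
    if (is.null(base)) {
      stop("Turtle error at line ", tok$line, ": unknown prefix '", prefix,
           "'", call. = FALSE)
    }
    paste0(base, local)
  }
  term <- function(role) {
    t <- take()
    if (t$type == "IRIREF") {
      return(list(v = t$value, type = "iri", dt = NA_character_,
                  lang = NA_character_))
    }
    if (t$type == "PNAME") {
      return(list(v = expand_pname(t), type = "iri", dt = NA_character_,
                  lang = NA_character_))
    }
    if (t$type == "BLANK" && role != "predicate") {
      return(list(v = t$value, type = "blank", dt = NA_character_,
                  lang = NA_character_))
    }
    if (role == "object") {
      if (t$type == "STRING") {
        dt <- NA_character_
        lang <- NA_character_
        nxt <- peek()
        if (nxt$type == "LANG") {
          lang <- take()$value
        } else if (nxt$type == "DTSEP") {
          take()
          dtok <- take()
          dt <- if (dtok$type == "IRIREF") dtok$value
                else if (dtok$type == "PNAME") expand_pname(dtok)
                else stop("Turtle error at line ", dtok$line,
                          ": expected datatype IRI", call. = FALSE)
        }
        return(list(v = .unescape_literal(t$value), type = "literal",
                    dt = dt, lang = lang))
      }
      if (t$type == "NUMBER") {
        dt <- if (grepl("[.eE]", t$value)) xsd("double") else xsd("integer")
        return(list(v = t$value, type = "literal", dt = dt,
                    lang = NA_character_))
      }
      if (t$type == "BOOL") {
        return(list(v = t$value, type = "literal", dt = xsd("boolean"),
                    lang = NA_character_))
      }
    }
    stop("Turtle syntax error at line ", t$line, ": unexpected ", t$type,
         " as ", role, call. = FALSE)
  }
  while (i <= nt) {
    t <- peek()
    if (t$type == "DIRECTIVE") {
      take()
      if (t$value == "@base") {
        expect("IRIREF", "base IRI")
      } else {
        p <- expect("PNAME", "prefix declaration")
        prefix <- sub(":.*$", "", p$value)
        iri <- expect("IRIREF", "namespace IRI")
        ns[[prefix]] <- iri$value
      }
      expect("PUNCT", ".")
      next
    }
    subj <- term("subject")
    repeat {
      ptok <- peek()
      pred <- if (ptok$type == "A") {
        take()
        "http://www.w3.org/1999/02/22-rdf-syntax-ns#type"
      } else {
        term("predicate")$v
      }
      repeat {
        obj <- term("object")
        rows[[length(rows) + 1L]] <- tibble::tibble(
          subject = subj$v, predicate = pred, object = obj$v,
          object_type = obj$type, datatype = obj$dt, lang = obj$lang)
        nxt <- peek()
        if (nxt$type == "PUNCT" && nxt$value == ",") take() else break
      }
      nxt <- peek()
      if (nxt$type == "PUNCT" && nxt$value == ";") {
        take()
        # tolerate trailing ';' before '.'
        if (peek()$type == "PUNCT" && peek()$value == ".") break
      } else {
        break
      }
    }
    expect("PUNCT", ".")
  }
  ns_chr <- unlist(ns)
  rdf_graph(dplyr::bind_rows(rows), namespaces = ns_chr)
}

#' Parse RDF text
#'
#' @param text Document text.
#' @param format `"turtle"` or `"ntriples"`.
#' @param namespaces Namespace bindings.
#' @return An `rdf_graph`.
#' @export
parse_rdf <- function(text, format = c("turtle", "ntriples"),
                      namespaces = default_namespaces()) {
  switch(match.arg(format),
         turtle = parse_turtle(text, namespaces),
         ntriples = parse_ntriples(text, namespaces))
}

.format_from_path <- function(path) {
  switch(tolower(tools::file_ext(path)),
         ttl = "turtle", turtle = "turtle",
         nt = "ntriples", ntriples = "ntriples",
         stop("cannot infer RDF format from extension of ", path,
              " (use .ttl or .nt)", call. = FALSE))
}

#' Write a graph to a file
#'
#' Format inferred from the extension (`.ttl` Turtle, `.nt` N-Triples)
#' unless given.
#'
#' @param graph An `rdf_graph`.
#' @param path Output path.
#' @param format Optional explicit format.
#' @return `path`, invisibly.
#' @export
write_rdf <- function(graph, path, format = NULL) {
  format <- format %||% .format_from_path(path)
  writeLines(serialize_rdf(graph, format), path, useBytes = TRUE)
  invisible(path)
}

#' Read a graph from a file
#'
#' @param path Input path (`.ttl` or `.nt`).
#' @param format Optional explicit format.
#' @return An `rdf_graph`.
#' @export
read_rdf <- function(path, format = NULL) {
  format <- format %||% .format_from_path(path)
  parse_rdf(readLines(path, warn = FALSE, encoding = "UTF-8"), format)
}

# ---- dereferencing ----------------------------------------------------------

#' Bounded description of a resource
#'
#' All triples with the IRI as subject, expanded transitively through
#' blank-node objects, so attached structures (target-confidence
#' constructs, descriptor nodes, role restrictions) are included whole.
#' Unknown IRIs yield an empty graph.
#'
#' @param graph An `rdf_graph`.
#' @param uri Resource IRI.
#' @return An `rdf_graph`.
#' @export
describe_resource <- function(graph, uri) {
  t <- tibble::as_tibble(graph)
  frontier <- uri
  seen <- character(0)
  out <- t[0, ]
  while (length(frontier) > 0) {
    seen <- c(seen, frontier)
    sel <- t[t$subject %in% frontier, ]
    out <- dplyr::bind_rows(out, sel)
    frontier <- setdiff(unique(sel$object[sel$object_type == "blank"]), seen)
  }
  rdf_graph(out, namespaces = attr(graph, "namespaces"))
}

#' Pick a response format from an Accept header
#'
#' RDF media types select an RDF serialization; anything else -- including
#' an absent header or unknown types -- falls back to an HTML rendering.
#'
#' @param accept_header Accept header string (or `NULL`).
#' @return `"turtle"`, `"ntriples"` or `"html"`.
#' @export
negotiate <- function(accept_header = NULL) {
  if (is.null(accept_header) || !nzchar(accept_header %||% "")) return("html")
  types <- vapply(strsplit(accept_header, ",", fixed = TRUE)[[1]],
                  function(x) trimws(sub(";.*$", "", x)), character(1),
                  USE.NAMES = FALSE)
  for (ty in types) {
    if (ty %in% c("text/turtle", "application/x-turtle",
                  "application/turtle")) {
      return("turtle")
    }
    if (ty %in% c("application/n-triples", "text/ntriples")) {
      return("ntriples")
    }
    if (ty == "text/html") return("html")
  }
  "html"
}

.html_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

#' Render a description as a plain HTML triple table
#'
#' @param graph An `rdf_graph` (typically a bounded description).
#' @param uri The described resource, shown as the page heading.
#' @return Character scalar of HTML.
#' @export
render_html_description <- function(graph, uri) {
  t <- tibble::as_tibble(graph)
  rows <- paste0(
    "<tr><td>", .html_escape(t$subject), "</td><td>",
    .html_escape(t$predicate), "</td><td>", .html_escape(t$object),
    "</td></tr>", collapse = "\n")
  paste0("<!DOCTYPE html>\n<html><head><title>", .html_escape(uri),
         "</title></head>\n<body><h1>", .html_escape(uri),
         "</h1>\n<table border=\"1\">\n",
         "<tr><th>subject</th><th>predicate</th><th>object</th></tr>\n",
         rows, "\n</table></body></html>\n")
}

#' Handle a dereferencing request
#'
#' Pure request handler behind the linked-data endpoint: looks up the
#' bounded description and serializes it in the negotiated format.
#' Unknown resources get a 404.
#'
#' @param graph An `rdf_graph`.
#' @param uri Requested resource IRI.
#' @param accept Accept header (or `NULL`).
#' @return List with `status`, `content_type` and `body`.
#' @export
handle_request <- function(graph, uri, accept = NULL) {
  desc <- describe_resource(graph, uri)
  if (nrow(desc) == 0) {
    return(list(status = 404L, content_type = "text/plain",
                body = paste0("unknown resource: ", uri, "\n")))
  }
  fmt <- negotiate(accept)
  switch(fmt,
    turtle = list(status = 200L, content_type = "text/turtle",
                  body = serialize_turtle(desc)),
    ntriples = list(status = 200L, content_type = "application/n-triples",
                    body = serialize_ntriples(desc)),
    html = list(status = 200L, content_type = "text/html",
                body = render_html_description(desc, uri))
  )
}

#' Serve a graph as dereferencable linked data
#'
#' Minimal HTTP layer over [handle_request()]: request paths are
#' translated back to canonical IRIs with [translate_for_proxy()] and the
#' bounded description is returned with content negotiation.  Blocks until
#' interrupted.
#'
#' @param graph An `rdf_graph`.
#' @param port TCP port.
#' @param host Bind address.
#' @param policy A [uri_policy()] for URL translation.
#' @return Never returns normally.
#' @export
serve_graph <- function(graph, port = 8080L, host = "127.0.0.1",
                        policy = uri_policy()) {
  if (!requireNamespace("httpuv", quietly = TRUE)) {
    stop("serve_graph requires the httpuv package", call. = FALSE)
  }
  local_base <- sprintf("http://%s:%d/chembl/", host, port)
  app <- list(call = function(req) {
    uri <- tryCatch(
      translate_for_proxy(paste0(local_base,
                                 sub("^/chembl/", "", req$PATH_INFO)),
                          local_base, "backward", policy),
      error = function(e) NULL)
    if (is.null(uri)) {
      return(list(status = 404L,
                  headers = list("Content-Type" = "text/plain"),
                  body = "unknown path\n"))
    }
    res <- handle_request(graph, uri, req$HTTP_ACCEPT)
    list(status = res$status,
         headers = list("Content-Type" = res$content_type),
         body = res$body)
  })
  message("serving on ", local_base)
  httpuv::runServer(host, port, app)
}
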