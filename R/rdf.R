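#' Minimal RDF input/output
#'
#' The annotation documents handled here are small RDF/XML or Turtle files
#' describing model entities. Parsing yields a plain triple table:
#' `data.frame(subject, predicate, object, object_type)` with `object_type`
#' in `{"iri", "blank", "literal"}`; blank nodes are keyed `_:b<N>`.
#'
#' The RDF/XML reader covers the striped syntax used by repository
#' annotations: `rdf:Description` and typed node elements, `rdf:about`,
#' `rdf:ID`, `rdf:resource`, `rdf:nodeID`, `rdf:parseType="Resource"`,
#' nested node elements and plain literals. The Turtle reader covers
#' `@prefix`/`@base` directives, IRIs, prefixed names, `a`, literal objects
#' (language tags and datatypes are dropped), `;`/`,` lists and anonymous
#' `[...]` blank nodes. Both are deliberately small: they parse the
#' annotation subset this package emits and the equivalent output of
#' standard RDF serializers for such documents.
#'
#' @name rdf-io
NULL

.rdf_ns <- "http://www.w3.org/1999/02/22-rdf-syntax-ns#"

.expand_name <- function(qname, ns) {
  parts <- strsplit(qname, ":", fixed = TRUE)[[1]]
  if (length(parts) == 2L && parts[1] %in% names(ns)) {
    paste0(ns[[parts[1]]], parts[2])
  } else {
    qname
  }
}

.resolve_iri <- function(iri, base) {
  if (is.null(base) || !nzchar(base)) return(iri)
  if (grepl("^[A-Za-z][A-Za-z0-9+.-]*:", iri)) return(iri)  # absolute
  if (startsWith(iri, "#")) return(paste0(base, iri))
  if (!nzchar(iri)) return(base)
  paste0(base, "/", iri)
}

#' Parse an RDF/XML document into a triple table
#'
#' @param x A file path or a character scalar of XML text.
#' @return A triple `data.frame`; see [rdf-io].
#' @export
read_rdf_xml <- function(x) {
  doc <- tryCatch(
    xml2::read_xml(x),
    error = function(e) stop("malformed RDF/XML", if (file.exists(x[1])) paste0(" in ", x), ": ",
                             conditionMessage(e), call. = FALSE)
  )
  ns <- xml2::xml_ns(doc)
  root <- xml2::xml_root(doc)
  base <- xml2::xml_attr(root, "base")
  if (is.na(base)) base <- NULL
  state <- new.env(parent = emptyenv())
  state$triples <- list()
  state$blank_n <- 0L
  state$node_ids <- new.env(parent = emptyenv())

  fresh_blank <- function() {
    state$blank_n <- state$blank_n + 1L
    paste0("_:b", state$blank_n)
  }
  named_blank <- function(id) {
    key <- paste0("id:", id)
    if (!exists(key, envir = state$node_ids, inherits = FALSE)) {
      assign(key, fresh_blank(), envir = state$node_ids)
    }
    get(key, envir = state$node_ids, inherits = FALSE)
  }
  emit <- function(s, p, o, type) {
    state$triples[[length(state$triples) + 1L]] <-
      data.frame(subject = s, predicate = p, object = o, object_type = type,
                 stringsAsFactors = FALSE)
  }
  rdf_attr <- function(el, local) {
    attrs <- xml2::xml_attrs(el, ns = ns)
    nm <- names(attrs)
    full <- vapply(nm, .expand_name, character(1), ns = ns)
    hit <- which(full == paste0(.rdf_ns, local))
    if (length(hit)) unname(attrs[hit[1]]) else NA_character_
  }

  parse_node <- function(el) {
    about <- rdf_attr(el, "about")
    idattr <- rdf_attr(el, "ID")
    nodeid <- rdf_attr(el, "nodeID")
    subject <- if (!is.na(about)) {
      .resolve_iri(about, base)
    } else if (!is.na(idattr)) {
      .resolve_iri(paste0("#", idattr), base)
    } else if (!is.na(nodeid)) {
      named_blank(nodeid)
    } else {
      fresh_blank()
    }
    subj_type <- if (startsWith(subject, "_:")) "blank" else "iri"
    el_name <- .expand_name(xml2::xml_name(el, ns), ns)
    if (el_name != paste0(.rdf_ns, "Description")) {
      emit(subject, paste0(.rdf_ns, "type"), el_name, "iri")
    }
    for (prop in xml2::xml_children(el)) {
      parse_property(subject, prop)
    }
    list(id = subject, type = subj_type)
  }

  parse_property <- function(subject, prop) {
    pred <- .expand_name(xml2::xml_name(prop, ns), ns)
    res <- rdf_attr(prop, "resource")
    nodeid <- rdf_attr(prop, "nodeID")
    ptype <- rdf_attr(prop, "parseType")
    kids <- xml2::xml_children(prop)
    if (!is.na(res)) {
      emit(subject, pred, .resolve_iri(res, base), "iri")
    } else if (!is.na(nodeid)) {
      emit(subject, pred, named_blank(nodeid), "blank")
    } else if (!is.na(ptype) && ptype == "Resource") {
      b <- fresh_blank()
      emit(subject, pred, b, "blank")
      for (inner in kids) parse_property(b, inner)
    } else if (length(kids)) {
      for (kid in kids) {
        obj <- parse_node(kid)
        emit(subject, pred, obj$id, obj$type)
      }
    } else {
      emit(subject, pred, xml2::xml_text(prop), "literal")
    }
  }

  for (child in xml2::xml_children(root)) parse_node(child)
  if (!length(state$triples)) {
    return(data.frame(subject = character(0), predicate = character(0),
                      object = character(0), object_type = character(0),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, state$triples)
  rownames(out) <- NULL
  out
}

# ---- Turtle subset ---------------------------------------------------------

.ttl_tokenize <- function(text) {
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  n <- length(chars)
  tokens <- character(0)
  i <- 1L
  push <- function(tok) tokens[[length(tokens) + 1L]] <<- tok
  while (i <= n) {
    ch <- chars[i]
    if (ch %in% c(" ", "\t", "\r", "\n")) { i <- i + 1L; next }
    if (ch == "#") {  # comment to end of line
      while (i <= n && chars[i] != "\n") i <- i + 1L
      next
    }
    if (ch == "<") {
      j <- i + 1L
      while (j <= n && chars[j] != ">") j <- j + 1L
      if (j > n) stop("unterminated IRI in Turtle input", call. = FALSE)
      push(paste0(chars[i:j], collapse = ""))
      i <- j + 1L
      next
    }
    if (ch == "\"") {
      j <- i + 1L
      buf <- "\""
      while (j <= n) {
        if (chars[j] == "\\" && j < n) {
          buf <- paste0(buf, chars[j], chars[j + 1L]); j <- j + 2L
        } else if (chars[j] == "\"") {
          buf <- paste0(buf, "\""); j <- j + 1L; break
        } else {
          buf <- paste0(buf, chars[j]); j <- j + 1L
        }
      }
      # swallow datatype/lang suffix
      if (j <= n - 1L && chars[j] == "^" && chars[j + 1L] == "^") {
        j <- j + 2L
        if (j <= n && chars[j] == "<") { while (j <= n && chars[j] != ">") j <- j + 1L; j <- j + 1L }
        else while (j <= n && !(chars[j] %in% c(" ", "\t", "\r", "\n", ".", ";", ","))) j <- j + 1L
      } else if (j <= n && chars[j] == "@") {
        while (j <= n && !(chars[j] %in% c(" ", "\t", "\r", "\n", ".", ";", ","))) j <- j + 1L
      }
      push(buf)
      i <- j
      next
    }
    if (ch %in% c(".", ";", ",", "[", "]")) {
      # '.' inside a prefixed name is handled below; here '.' is punctuation
      push(ch); i <- i + 1L; next
    }
    j <- i
    buf <- character(0)
    while (j <= n && !(chars[j] %in% c(" ", "\t", "\r", "\n", ";", ",", "[", "]", "<", "\"")) &&
           !(chars[j] == "." && (j == n || chars[j + 1L] %in% c(" ", "\t", "\r", "\n") || j == n))) {
      buf <- c(buf, chars[j]); j <- j + 1L
    }
    push(paste0(buf, collapse = ""))
    i <- j
  }
  tokens
}

#' Parse a Turtle document into a triple table
#'
#' @param x A file path or a character scalar of Turtle text.
#' @return A triple `data.frame`; see [rdf-io].
#' @export
read_turtle <- function(x) {
  text <- if (length(x) == 1L && !grepl("\n", x) && file.exists(x)) {
    paste(readLines(x, encoding = "UTF-8", warn = FALSE), collapse = "\n")
  } else {
    paste(x, collapse = "\n")
  }
  tokens <- .ttl_tokenize(text)
  prefixes <- character(0)
  base <- NULL
  triples <- list()
  blank_n <- 0L
  pos <- 1L
  peek <- function() if (pos <= length(tokens)) tokens[[pos]] else NA_character_
  advance <- function() { tok <- peek(); pos <<- pos + 1L; tok }
  emit <- function(s, p, o, type) {
    triples[[length(triples) + 1L]] <<-
      data.frame(subject = s, predicate = p, object = o, object_type = type,
                 stringsAsFactors = FALSE)
  }
  resolve_term <- function(tok) {
    if (startsWith(tok, "<")) {
      iri <- substr(tok, 2L, nchar(tok) - 1L)
      return(list(value = .resolve_iri(iri, base), type = "iri"))
    }
    if (startsWith(tok, "\"")) {
      lit <- substr(tok, 2L, nchar(tok) - 1L)
      lit <- gsub("\\\\\"", "\"", lit)
      lit <- gsub("\\\\n", "\n", lit)
      lit <- gsub("\\\\\\\\", "\\\\", lit)
      return(list(value = lit, type = "literal"))
    }
    if (tok == "a") {
      return(list(value = paste0(.rdf_ns, "type"), type = "iri"))
    }
    if (startsWith(tok, "_:")) {
      return(list(value = tok, type = "blank"))
    }
    parts <- strsplit(tok, ":", fixed = TRUE)[[1]]
    if (length(parts) >= 1L) {
      pfx <- if (length(parts) == 1L) "" else parts[1]
      local <- if (length(parts) == 1L) parts[1] else paste(parts[-1], collapse = ":")
      if (pfx %in% names(prefixes)) {
        return(list(value = paste0(prefixes[[pfx]], local), type = "iri"))
      }
    }
    stop("cannot resolve Turtle term: ", tok, call. = FALSE)
  }
  parse_object <- function() {
    tok <- peek()
    if (identical(tok, "[")) {
      advance()
      blank_n <<- blank_n + 1L
      b <- paste0("_:t", blank_n)
      if (!identical(peek(), "]")) parse_predicate_object_list(b)
      if (!identical(advance(), "]")) stop("expected ']' in Turtle input", call. = FALSE)
      return(list(value = b, type = "blank"))
    }
    resolve_term(advance())
  }
  parse_predicate_object_list <- function(subject) {
    repeat {
      pred <- resolve_term(advance())
      repeat {
        obj <- parse_object()
        emit(subject, pred$value, obj$value, obj$type)
        if (identical(peek(), ",")) { advance(); next }
        break
      }
      if (identical(peek(), ";")) {
        advance()
        if (identical(peek(), ".") || identical(peek(), "]")) break
        next
      }
      break
    }
  }
  while (!is.na(peek())) {
    tok <- peek()
    if (tok %in% c("@prefix", "PREFIX")) {
      advance()
      pfx <- advance()
      pfx <- sub(":$", "", pfx)
      iri_tok <- advance()
      prefixes[[pfx]] <- substr(iri_tok, 2L, nchar(iri_tok) - 1L)
      if (identical(peek(), ".")) advance()
      next
    }
    if (tok %in% c("@base", "BASE")) {
      advance()
      iri_tok <- advance()
      base <- substr(iri_tok, 2L, nchar(iri_tok) - 1L)
      if (identical(peek(), ".")) advance()
      next
    }
    subj <- parse_object()
    parse_predicate_object_list(subj$value)
    if (!identical(advance(), ".")) stop("expected '.' in Turtle input", call. = FALSE)
  }
  if (!length(triples)) {
    return(data.frame(subject = character(0), predicate = character(0),
                      object = character(0), object_type = character(0),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, triples)
  rownames(out) <- NULL
  out
}

# split an IRI into (namespace, local-name) at the last '#' or '/'
.split_iri <- function(iri) {
  m <- regexpr("[#/][^#/]*$", iri)
  if (m < 0) return(c(iri, ""))
  c(substr(iri, 1L, m), substr(iri, m + 1L, nchar(iri)))
}

.xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  gsub("\"", "&quot;", x, fixed = TRUE)
}

#' Serialize a triple table to RDF/XML
#'
#' Deterministic flat serialization: one `rdf:Description` per subject (in
#' sorted order), blank nodes via `rdf:nodeID`, namespace prefixes assigned
#' in order of first appearance. The output re-parses to the same triple set.
#'
#' @param triples A triple `data.frame`; see [rdf-io].
#' @param path Optional output file; when `NULL`, the XML text is returned.
#' @return The XML text (invisibly when `path` is given).
#' @export
write_rdf_xml <- function(triples, path = NULL) {
  ns_map <- c(rdf = .rdf_ns)
  prefix_for <- function(ns_iri) {
    hit <- which(ns_map == ns_iri)
    if (length(hit)) return(names(ns_map)[hit[1]])
    pfx <- paste0("ns", length(ns_map))
    ns_map[pfx] <<- ns_iri
    pfx
  }
  pred_qnames <- vapply(triples$predicate, function(p) {
    parts <- .split_iri(p)
    if (!nzchar(parts[2])) stop("predicate IRI has no local name: ", p, call. = FALSE)
    paste0(prefix_for(parts[1]), ":", parts[2])
  }, character(1))
  lines <- character(0)
  subjects <- sort(unique(triples$subject))
  # emit IRI subjects before blank nodes for readability
  subjects <- c(subjects[!startsWith(subjects, "_:")], subjects[startsWith(subjects, "_:")])
  body <- character(0)
  for (s in subjects) {
    rows <- which(triples$subject == s)
    rows <- rows[order(pred_qnames[rows], triples$object[rows])]
    opening <- if (startsWith(s, "_:")) {
      sprintf("  <rdf:Description rdf:nodeID=\"%s\">", .xml_escape(sub("^_:", "", s)))
    } else {
      sprintf("  <rdf:Description rdf:about=\"%s\">", .xml_escape(s))
    }
    body <- c(body, opening)
    for (r in rows) {
      q <- pred_qnames[r]
      o <- triples$object[r]
      line <- switch(triples$object_type[r],
        iri = sprintf("    <%s rdf:resource=\"%s\"/>", q, .xml_escape(o)),
        blank = sprintf("    <%s rdf:nodeID=\"%s\"/>", q, .xml_escape(sub("^_:", "", o))),
        literal = sprintf("    <%s>%s</%s>", q, .xml_escape(o), q)
      )
      body <- c(body, line)
    }
    body <- c(body, "  </rdf:Description>")
  }
  decls <- paste(sprintf("xmlns:%s=\"%s\"", names(ns_map), unname(ns_map)),
                 collapse = "\n         ")
  xml <- paste(c(
    "<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
    sprintf("<rdf:RDF %s>", decls),
    body,
    "</rdf:RDF>", ""
  ), collapse = "\n")
  if (!is.null(path)) {
    writeLines(xml, path, sep = "", useBytes = TRUE)
    return(invisible(xml))
  }
  xml
}

#' Read an RDF document, detecting its format
#'
#' @param x File path or document text.
#' @param format `"auto"`, `"rdfxml"` or `"turtle"`. Auto-detection uses the
#'   file extension (`.ttl` means Turtle) or, for text, whether the content
#'   starts with an XML declaration/element.
#' @return A triple `data.frame`; see [rdf-io].
#' @export
read_rdf <- function(x, format = c("auto", "rdfxml", "turtle")) {
  format <- match.arg(format)
  if (format == "auto") {
    is_file <- length(x) == 1L && !grepl("\n", x) && file.exists(x)
    format <- if (is_file) {
      if (grepl("\\.ttl$", x, ignore.case = TRUE)) "turtle" else "rdfxml"
    } else {
      if (grepl("^\\s*<", paste(x, collapse = "\n"))) "rdfxml" else "turtle"
    }
  }
  if (format == "rdfxml") read_rdf_xml(x) else read_turtle(x)
}
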