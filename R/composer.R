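#' Enumerate class combinations across the final phrases
#'
#' Each final phrase may be associated with several ontology classes; a
#' combination picks exactly one class per phrase. The full Cartesian
#' product is enumerated, ordered by decreasing total association score; a
#' configurable cap prunes the lowest-scoring combinations first when the
#' fan-out is pathological.
#'
#' @param annotation An [annotate()] result (or a named list phrase_id ->
#'   data.frame with `class` and `score`).
#' @param max_combinations Cap on the number of returned combinations.
#' @return A list of `class_combination` objects; each is a data.frame with
#'   one row per phrase: `phrase_id`, `class`, `score`.
#' @export
enumerate_combinations <- function(annotation,
                                   max_combinations = if (inherits(annotation, "nlq_annotation")) annotation$config$max_combinations else 64L) {
  per_phrase <- if (inherits(annotation, "nlq_annotation")) {
    ids <- annotation$final_phrases
    stats::setNames(lapply(ids, function(id) {
      df <- annotation$final[annotation$final$phrase_id == id, c("class", "score")]
      df[order(-df$score, df$class), , drop = FALSE]
    }), ids)
  } else {
    annotation
  }
  if (!length(per_phrase)) stop("no final phrases to combine", call. = FALSE)
  idx <- do.call(expand.grid, c(lapply(per_phrase, function(df) seq_len(nrow(df))),
                                KEEP.OUT.ATTRS = FALSE))
  combos <- lapply(seq_len(nrow(idx)), function(i) {
    rows <- Map(function(df, k) df[k, , drop = FALSE], per_phrase, as.integer(idx[i, ]))
    out <- do.call(rbind, rows)
    out <- cbind(phrase_id = names(per_phrase), out, stringsAsFactors = FALSE)
    rownames(out) <- NULL
    class(out) <- c("class_combination", "data.frame")
    out
  })
  totals <- vapply(combos, function(cb) sum(cb$score), numeric(1))
  keys <- vapply(combos, function(cb) paste(cb$class, collapse = " "), character(1))
  combos <- combos[order(-totals, keys)]
  if (length(combos) > max_combinations) combos <- combos[seq_len(max_combinations)]
  combos
}

#' Keep combinations with at least one matching annotation pattern
#'
#' A combination is viable when some entity root is annotated with all its
#' classes, i.e. the intersection of the per-class root sets in the RGI is
#' non-empty. Non-viable combinations have no matching results in the
#' repository and are discarded.
#'
#' @param combinations A list from [enumerate_combinations()].
#' @param rgi A [build_rgi()] index.
#' @return The viable sublist, in input order.
#' @export
viable_combinations <- function(combinations, rgi) {
  Filter(function(cb) length(roots_for(rgi, unique(cb$class))) > 0L, combinations)
}

#' Annotation patterns realizing a combination
#'
#' For each root shared by all of a combination's classes, every choice of
#' one predicate path per class is an annotation pattern. Patterns are
#' deduplicated across roots: each distinct per-class path choice yields one
#' pattern carrying the set of roots that realize it.
#'
#' @param combination A `class_combination`.
#' @param rgi A [build_rgi()] index.
#' @return A list of `annotation_pattern` objects: `combination`, `paths`
#'   (named list class -> predicate IRI vector) and `roots`. Empty for a
#'   non-viable combination.
#' @export
patterns_for <- function(combination, rgi) {
  classes <- unique(combination$class)
  roots <- roots_for(rgi, classes)
  if (!length(roots)) return(list())
  acc <- new.env(parent = emptyenv())
  order_keys <- character(0)
  for (root in roots) {
    per_class <- lapply(classes, function(cl) paths_for(rgi, cl, root))
    if (any(!lengths(per_class))) next
    idx <- do.call(expand.grid, c(lapply(per_class, seq_along), KEEP.OUT.ATTRS = FALSE))
    for (i in seq_len(nrow(idx))) {
      paths <- stats::setNames(
        Map(function(plist, k) plist[[k]], per_class, as.integer(idx[i, ])),
        classes
      )
      key <- paste(vapply(paths, paste, character(1), collapse = " "), collapse = "\x1f")
      if (!exists(key, envir = acc, inherits = FALSE)) {
        assign(key, list(combination = combination, paths = paths,
                         roots = character(0)), envir = acc)
        order_keys <- c(order_keys, key)
      }
      entry <- get(key, envir = acc, inherits = FALSE)
      entry$roots <- sort(unique(c(entry$roots, root)))
      assign(key, entry, envir = acc)
    }
  }
  lapply(sort(order_keys), function(key) {
    structure(get(key, envir = acc, inherits = FALSE), class = "annotation_pattern")
  })
}

#' Compile an annotation pattern into a SPARQL query
#'
#' Emits a SPARQL 1.1 `SELECT DISTINCT` over the entity root variable with
#' one basic graph pattern chain per class path: `?entity` connects through
#' fresh intermediate variables (`?v0`, `?v1`, ... in path-major order) to
#' the class IRI bound exactly. Output is byte-stable for a fixed pattern.
#'
#' @param pattern An [patterns_for()] annotation pattern.
#' @return An object of class `composed_query`: `sparql` (text), `score`
#'   (sum of the combination's association scores) and `pattern`.
#' @export
compose_sparql <- function(pattern) {
  if (is.null(pattern$paths) || !length(pattern$paths)) {
    stop("empty annotation pattern", call. = FALSE)
  }
  lines <- character(0)
  v <- 0L
  for (cl in names(pattern$paths)) {
    path <- pattern$paths[[cl]]
    subject <- "?entity"
    if (length(path) > 1L) {
      for (p in path[-length(path)]) {
        obj <- sprintf("?v%d", v)
        v <- v + 1L
        lines <- c(lines, sprintf("  %s <%s> %s .", subject, p, obj))
        subject <- obj
      }
    }
    lines <- c(lines, sprintf("  %s <%s> <%s> .", subject, path[length(path)], cl))
  }
  sparql <- paste(c("SELECT DISTINCT ?entity", "WHERE {", lines, "}"),
                  collapse = "\n")
  structure(
    list(sparql = sparql, score = sum(pattern$combination$score),
         pattern = pattern),
    class = "composed_query"
  )
}

#' @export
print.composed_query <- function(x, ...) {
  cat(sprintf("# score: %.4f\n%s\n", x$score, x$sparql))
  invisible(x)
}

#' Rank composed queries
#'
#' Queries are ordered by decreasing score. When predicate associations are
#' available (xner mode), a query whose pattern uses a matched predicate
#' receives that predicate's association score as a bonus, once per distinct
#' matched predicate. Ties are broken by lexicographic order of the SPARQL
#' text, so ranking is stable across runs.
#'
#' @param queries A list of [compose_sparql()] results.
#' @param predicate_associations Optional data.frame with `predicate` and
#'   `score` columns (see [annotate()]).
#' @return The re-ordered list; each query's `score` includes its bonus.
#' @export
rank_queries <- function(queries, predicate_associations = NULL) {
  if (!length(queries)) return(queries)
  if (!is.null(predicate_associations) && nrow(predicate_associations)) {
    pa <- predicate_associations
    best <- tapply(pa$score, pa$predicate, max)
    queries <- lapply(queries, function(q) {
      used <- unique(unlist(q$pattern$paths, use.names = FALSE))
      matched <- intersect(used, names(best))
      q$score <- q$score + sum(best[matched])
      q
    })
  }
  scores <- vapply(queries, `[[`, numeric(1), "score")
  texts <- vapply(queries, `[[`, character(1), "sparql")
  queries[order(-scores, texts)]
}

#' Retrieve entities directly from the index
#'
#' SPARQL-free retrieval: the entity roots annotated with all of the
#' combination's classes, straight from the RGI. Exactly the union of the
#' result sets of the combination's composed queries over the indexed
#' repository — but it cannot see RDF documents added after the index was
#' built, unlike running the SPARQL against a live endpoint.
#'
#' @param combination A `class_combination` (or a character vector of class
#'   IRIs).
#' @param rgi A [build_rgi()] index.
#' @return Sorted character vector of entity roots.
#' @export
retrieve_entities <- function(combination, rgi) {
  classes <- if (is.data.frame(combination)) unique(combination$class) else combination
  roots_for(rgi, classes)
}

#' Execute a composed SPARQL query over a triple table
#'
#' A small basic-graph-pattern matcher for the dialect this package emits
#' (triple patterns with `?variables`, exact IRIs in angle brackets, no
#' OPTIONAL/FILTER). Used to verify composed queries against fixture graphs
#' without an external SPARQL engine.
#'
#' Bindings for the root variable that are blank nodes are dropped: a chain
#' pattern can match with its head anchored at an interior blank node, but
#' model entities are addressable IRIs.
#'
#' @param sparql SPARQL text from [compose_sparql()].
#' @param triples A triple `data.frame` (see [rdf-io]).
#' @return Sorted character vector of IRI bindings for `?entity`.
#' @export
execute_sparql <- function(sparql, triples) {
  lines <- strsplit(sparql, "\n", fixed = TRUE)[[1]]
  pat_lines <- grep("^\\s*(\\?|<)", lines, value = TRUE)
  pat_lines <- sub("\\s*\\.\\s*$", "", pat_lines)
  parse_term <- function(tok) {
    if (startsWith(tok, "?")) {
      list(kind = "var", value = substring(tok, 2L))
    } else if (startsWith(tok, "<")) {
      list(kind = "iri", value = substr(tok, 2L, nchar(tok) - 1L))
    } else {
      stop("unsupported SPARQL term: ", tok, call. = FALSE)
    }
  }
  patterns <- lapply(pat_lines, function(line) {
    toks <- strsplit(trimws(line), "\\s+")[[1]]
    stopifnot(length(toks) == 3L)
    lapply(toks, parse_term)
  })
  # iterative join over bindings
  bindings <- list(stats::setNames(list(), character(0)))
  for (tp in patterns) {
    new_bindings <- list()
    for (b in bindings) {
      term_val <- function(t) {
        if (t$kind == "iri") t$value
        else if (t$value %in% names(b)) b[[t$value]]
        else NA_character_
      }
      s <- term_val(tp[[1]]); p <- term_val(tp[[2]]); o <- term_val(tp[[3]])
      rows <- seq_len(nrow(triples))
      if (!is.na(s)) rows <- rows[triples$subject[rows] == s]
      if (!is.na(p)) rows <- rows[triples$predicate[rows] == p]
      if (!is.na(o)) rows <- rows[triples$object[rows] == o]
      for (r in rows) {
        nb <- b
        if (tp[[1]]$kind == "var" && is.na(s)) nb[[tp[[1]]$value]] <- triples$subject[r]
        if (tp[[2]]$kind == "var" && is.na(p)) nb[[tp[[2]]$value]] <- triples$predicate[r]
        if (tp[[3]]$kind == "var" && is.na(o)) nb[[tp[[3]]$value]] <- triples$object[r]
        new_bindings[[length(new_bindings) + 1L]] <- nb
      }
    }
    bindings <- new_bindings
    if (!length(bindings)) break
  }
  out <- unique(vapply(bindings, function(b) b[["entity"]], character(1)))
  sort(out[!startsWith(out, "_:")])
}

#' Translate an annotated query into ranked SPARQL
#'
#' The full composer stage: enumerate class combinations from the final
#' phrases, keep those realized by at least one annotation pattern in the
#' RGI, compile every pattern into SPARQL and rank the results.
#'
#' @param annotation An [annotate()] result.
#' @param rgi A [build_rgi()] index.
#' @param max_combinations Cap on enumerated combinations.
#' @return A list of ranked `composed_query` objects (possibly empty).
#' @export
compose_queries <- function(annotation, rgi,
                            max_combinations = annotation$config$max_combinations) {
  if (!length(annotation$final_phrases)) return(list())
  combos <- enumerate_combinations(annotation, max_combinations)
  viable <- viable_combinations(combos, rgi)
  queries <- list()
  for (cb in viable) {
    for (pattern in patterns_for(cb, rgi)) {
      queries[[length(queries) + 1L]] <- compose_sparql(pattern)
    }
  }
  rank_queries(queries, annotation$predicate_associations)
}

#' End-to-end translation of a natural-language query
#'
#' Convenience wrapper: [annotate()] then [compose_queries()].
#'
#' @param query Query text.
#' @param tfi A [build_tfi()] index.
#' @param rgi A [build_rgi()] index.
#' @param config An [annotator_config()].
#' @return A list with `annotation`, `queries` (ranked `composed_query`s)
#'   and `entities` (SPARQL-free retrieval for the top-ranked viable
#'   combination union, sorted).
#' @export
nlq_to_sparql <- function(query, tfi, rgi, config = annotator_config()) {
  annotation <- annotate(query, tfi, rgi, config)
  queries <- compose_queries(annotation, rgi)
  entities <- sort(unique(unlist(lapply(queries, function(q) q$pattern$roots))))
  list(annotation = annotation, queries = queries,
       entities = if (is.null(entities)) character(0) else entities)
}
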