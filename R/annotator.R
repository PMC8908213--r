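#' Candidate phrases
#'
#' A candidate phrase is a span of the query (0-based half-open token
#' offsets) with its own normalized terms and per-term dependency levels.
#' `source` records how it arose: `"parse"` (chunker), `"ner"` (entity
#' recognizer) or `"ner_context"` (an NER span's enclosing phrase with the
#' span text replaced by its entity-type label). Context phrases keep the
#' enclosing span for overlap bookkeeping while carrying substituted terms.
#'
#' @param start,end Token offsets into the query (0-based half-open).
#' @param terms Normalized phrase terms.
#' @param dl Per-term dependency levels (all `>= 1`).
#' @param source One of `"parse"`, `"ner"`, `"ner_context"`.
#' @param entity_type NER label or `NA`.
#' @return An object of class `candidate_phrase`.
#' @export
candidate_phrase <- function(start, end, terms, dl, source = "parse",
                             entity_type = NA_character_) {
  stopifnot(end > start, length(terms) > 0L, length(dl) == length(terms), all(dl >= 1L))
  id <- paste0(start, "-", end,
               if (source == "ner_context") paste0(":", paste(terms, collapse = "_")))
  structure(
    list(id = id, start = as.integer(start), end = as.integer(end),
         terms = terms, dl = as.integer(dl), source = source,
         entity_type = entity_type),
    class = "candidate_phrase"
  )
}

#' @export
print.candidate_phrase <- function(x, ...) {
  cat(sprintf("[%d,%d) \"%s\" (%s%s) dl=%s\n", x$start, x$end,
              paste(x$terms, collapse = " "), x$source,
              if (is.na(x$entity_type)) "" else paste0("/", x$entity_type),
              paste(x$dl, collapse = ",")))
  invisible(x)
}

#' Dependency levels of a phrase
#'
#' Levels are node depth in the phrase's dependency tree plus one, so the
#' head term has level 1 and exactly one term per tree is a head.
#'
#' @param terms Normalized phrase terms (non-empty).
#' @param adapter A parser adapter; defaults to the built-in heuristic.
#' @return Integer vector of levels, parallel to `terms`.
#' @export
dependency_levels <- function(terms, adapter = builtin_parser()) {
  stopifnot(length(terms) > 0L)
  dl <- as.integer(adapter$deps(terms))
  stopifnot(length(dl) == length(terms), all(dl >= 1L))
  dl
}

#' Chunk a query into candidate phrases
#'
#' `chunk_parse` runs the adapter's constituency-style chunker and returns
#' the full query, every noun phrase and every noun head as candidates
#' (duplicates merged). `chunk_ner` runs the adapter's entity recognizer and
#' additionally forms, for each entity span, a context phrase: the span's
#' smallest enclosing chunk with the span text replaced by the entity-type
#' label.
#'
#' @param query Query text or an already-normalized term vector.
#' @param adapter A parser adapter.
#' @return A list of [candidate_phrase()] objects.
#' @export
chunk_parse <- function(query, adapter = builtin_parser()) {
  terms <- if (is.character(query) && length(query) == 1L) {
    normalize_terms(query)
  } else {
    query
  }
  if (!length(terms)) stop("empty query", call. = FALSE)
  spans <- tryCatch(
    adapter$chunk(terms),
    error = function(e) stop("parser adapter '", adapter$name, "' failed: ",
                             conditionMessage(e), call. = FALSE)
  )
  out <- list()
  seen <- character(0)
  for (i in seq_len(nrow(spans))) {
    s <- spans$start[i]; e <- spans$end[i]
    key <- paste0(s, "-", e)
    if (key %in% seen) next
    seen <- c(seen, key)
    p_terms <- terms[(s + 1L):e]
    out[[length(out) + 1L]] <- candidate_phrase(
      s, e, p_terms, dependency_levels(p_terms, adapter), source = "parse"
    )
  }
  out
}

#' @rdname chunk_parse
#' @param context Also build `ner_context` phrases (the xStanza-style
#'   extension).
#' @export
chunk_ner <- function(query, adapter = builtin_parser(), context = TRUE) {
  terms <- if (is.character(query) && length(query) == 1L) {
    normalize_terms(query)
  } else {
    query
  }
  if (!length(terms)) stop("empty query", call. = FALSE)
  if (is.null(adapter$ner)) return(list())
  spans <- adapter$ner(terms)
  if (!nrow(spans)) return(list())
  out <- list()
  chunks <- if (context) adapter$chunk(terms)
  for (i in seq_len(nrow(spans))) {
    s <- spans$start[i]; e <- spans$end[i]; type <- spans$type[i]
    p_terms <- terms[(s + 1L):e]
    out[[length(out) + 1L]] <- candidate_phrase(
      s, e, p_terms, dependency_levels(p_terms, adapter),
      source = "ner", entity_type = type
    )
    if (!context) next
    # smallest chunk strictly containing the span
    enclosing <- chunks[chunks$start <= s & chunks$end >= e &
                          (chunks$end - chunks$start) > (e - s), , drop = FALSE]
    if (!nrow(enclosing)) next
    j <- which.min(enclosing$end - enclosing$start)
    es <- enclosing$start[j]; ee <- enclosing$end[j]
    type_terms <- normalize_terms(gsub("_", " ", tolower(type)))
    ctx_terms <- c(
      if (s > es) terms[(es + 1L):s],
      type_terms,
      if (e < ee) terms[(e + 1L):ee]
    )
    out[[length(out) + 1L]] <- candidate_phrase(
      es, ee, ctx_terms, dependency_levels(ctx_terms, adapter),
      source = "ner_context", entity_type = type
    )
  }
  out
}

#' Degree of association between a phrase and an ontology class
#'
#' The weighted sum over the class's features: `alpha` x preferred label +
#' `beta` x synonym + `gamma` x definition + `delta` x parent label +
#' `theta` x description. Synonym and parent contributions take the maximum
#' over the class's records of that kind. With `dep = TRUE` the
#' dependency-level similarity is used for dictionary features, otherwise
#' the length-normalized overlap.
#'
#' @param terms Phrase terms.
#' @param dl Phrase dependency levels (parallel to `terms`).
#' @param iri Class IRI (must be present in the index).
#' @param tfi A [build_tfi()] index.
#' @param config An [annotator_config()].
#' @return A one-row data.frame: `class`, `score` and the per-feature
#'   contributions `pl`, `syn`, `def`, `par`, `desc`.
#' @export
degree_of_association <- function(terms, dl, iri, tfi,
                                  config = annotator_config()) {
  if (!exists(iri, envir = tfi$classes, inherits = FALSE)) {
    stop("class not indexed: ", iri, call. = FALSE)
  }
  cl <- get(iri, envir = tfi$classes, inherits = FALSE)
  fsim <- function(rec) {
    if (is.null(rec)) return(0)
    if (config$dep) {
      sim_dependency(terms, rec$terms, dl, rec$dl, config$k1, config$k2)
    } else {
      sim_length_norm(terms, rec$terms)
    }
  }
  max_sim <- function(records) {
    if (!length(records)) return(0)
    max(vapply(records, fsim, numeric(1)))
  }
  stats <- description_stats(tfi, iri)
  pl <- fsim(cl$preferred_label)
  syn <- max_sim(cl$synonyms)
  def <- fsim(cl$definition)
  par <- max_sim(cl$parent_labels)
  desc <- sim_description(terms, stats$terms, stats$te_a, stats$te_o,
                          config$desc_teo_denominator)
  score <- config$alpha * pl + config$beta * syn + config$gamma * def +
    config$delta * par + config$theta * desc
  data.frame(class = iri, score = score, pl = pl, syn = syn, def = def,
             par = par, desc = desc, stringsAsFactors = FALSE)
}

.score_phrase <- function(phrase, tfi, config) {
  if (length(config$stopwords)) {
    keep <- !(phrase$terms %in% config$stopwords)
    terms <- phrase$terms[keep]
    dl <- phrase$dl[keep]
  } else {
    terms <- phrase$terms
    dl <- phrase$dl
  }
  if (!length(terms)) return(NULL)
  cands <- candidate_classes(tfi, terms)
  if (!length(cands)) return(NULL)
  rows <- lapply(cands, function(iri) {
    degree_of_association(terms, dl, iri, tfi, config)
  })
  out <- do.call(rbind, rows)
  out <- cbind(phrase_id = phrase$id, out, stringsAsFactors = FALSE)
  out[order(-out$score, out$class), , drop = FALSE]
}

# best association score of a phrase against every predicate in the RGI
.predicate_associations <- function(phrase, rgi) {
  if (is.null(rgi)) {
    return(data.frame(phrase_id = character(0), predicate = character(0),
                      score = numeric(0), stringsAsFactors = FALSE))
  }
  preds <- ls(rgi$predicate_labels)
  if (!length(preds)) {
    return(data.frame(phrase_id = character(0), predicate = character(0),
                      score = numeric(0), stringsAsFactors = FALSE))
  }
  scores <- vapply(preds, function(p) {
    label <- get(p, envir = rgi$predicate_labels, inherits = FALSE)
    if (!length(label)) return(0)
    sim_length_norm(phrase$terms, label)
  }, numeric(1))
  keep <- scores > 0
  data.frame(phrase_id = rep(phrase$id, sum(keep)), predicate = preds[keep],
             score = unname(scores[keep]), stringsAsFactors = FALSE)
}

#' Select the final non-overlapping phrase set
#'
#' Among candidate phrases that retained at least one association, selection
#' maximizes the summed best association score, then the number of query
#' tokens covered, then prefers fewer phrases; remaining ties are broken by
#' earliest span start. Solved by dynamic programming over token positions
#' (equivalent to exhaustive search over non-overlapping subsets).
#'
#' @param phrases A data.frame with columns `phrase_id`, `start`, `end`,
#'   `score` (the phrase's best association score).
#' @return The selected subset of `phrases`, ordered by span start.
#' @export
select_final_phrases <- function(phrases) {
  if (!nrow(phrases)) return(phrases)
  n <- max(phrases$end)
  better <- function(a, b) {
    # lexicographic: score, coverage, fewer phrases
    if (abs(a[1] - b[1]) > 1e-12) return(a[1] > b[1])
    if (a[2] != b[2]) return(a[2] > b[2])
    a[3] > b[3]
  }
  # value[i+1]: best (score, coverage, -count) using tokens i..n-1
  value <- vector("list", n + 2L)
  choice <- integer(n + 1L)  # 0 = skip this token
  value[[n + 1L]] <- c(0, 0, 0)
  ord <- order(phrases$start, -phrases$score, phrases$end, phrases$phrase_id)
  ph <- phrases[ord, , drop = FALSE]
  for (i in seq(n - 1L, 0L)) {
    best <- value[[i + 2L]]  # skip token i
    pick <- 0L
    starting <- which(ph$start == i)
    for (k in starting) {
      cand <- c(ph$score[k], ph$end[k] - ph$start[k], -1) + value[[ph$end[k] + 1L]]
      if (better(cand, best)) {
        best <- cand
        pick <- k
      }
    }
    value[[i + 1L]] <- best
    choice[i + 1L] <- pick
  }
  selected <- integer(0)
  i <- 0L
  while (i < n) {
    pick <- choice[i + 1L]
    if (pick == 0L) {
      i <- i + 1L
    } else {
      selected <- c(selected, pick)
      i <- ph$end[pick]
    }
  }
  out <- ph[selected, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Annotate a natural-language query against the indexes
#'
#' Runs the full phrase-annotation stage: chunk the query into candidate
#' phrases (via the configured parser adapter), shortlist candidate classes
#' through the Text Feature Index, score each phrase-class pair
#' ([degree_of_association()]), drop associations below the threshold `tau`,
#' and select the final non-overlapping phrase set. In NER mode
#' (`parser = "builtin-ner"` / `"builtin-xner"` or a registered NER-capable
#' adapter), candidates come from entity spans; the xner variant adds
#' context phrases, each kept as an extra class-bearing phrase when its best
#' class association beats its best predicate association and otherwise
#' contributing predicate associations for SPARQL ranking.
#'
#' @param query Query text (non-empty).
#' @param tfi A [build_tfi()] index.
#' @param rgi Optionally, a [build_rgi()] index (needed for predicate
#'   associations in xner mode).
#' @param config An [annotator_config()].
#' @return An object of class `nlq_annotation` with elements `query`,
#'   `terms`, `phrases` (all candidates), `associations` (threshold-filtered
#'   data.frame), `final_phrases` (selected phrase ids), `final` (their
#'   associations) and `predicate_associations`.
#' @export
annotate <- function(query, tfi, rgi = NULL, config = annotator_config()) {
  terms <- normalize_terms(query)
  if (!length(terms)) stop("empty query", call. = FALSE)
  adapter <- get_parser_adapter(config$parser)
  ner_mode <- grepl("(^|-)n?x?ner$", config$parser)
  xner <- grepl("xner$", config$parser)
  phrases <- if (ner_mode) {
    chunk_ner(terms, adapter, context = xner)
  } else {
    chunk_parse(terms, adapter)
  }
  names(phrases) <- vapply(phrases, `[[`, character(1), "id")

  assoc <- list()
  pred_assoc <- list()
  keep_phrases <- list()
  for (phrase in phrases) {
    scored <- .score_phrase(phrase, tfi, config)
    scored <- if (is.null(scored)) NULL else scored[scored$score >= config$tau, , drop = FALSE]
    has_class <- !is.null(scored) && nrow(scored) > 0L
    if (phrase$source == "ner_context") {
      # context phrase: class-like or predicate-like?
      pa <- .predicate_associations(phrase, rgi)
      best_class <- if (has_class) max(scored$score) else -Inf
      best_pred <- if (nrow(pa)) max(pa$score) else -Inf
      if (has_class && best_class >= best_pred) {
        assoc[[length(assoc) + 1L]] <- scored
        keep_phrases[[phrase$id]] <- phrase
      } else if (nrow(pa)) {
        pred_assoc[[length(pred_assoc) + 1L]] <- pa
      }
    } else if (has_class) {
      assoc[[length(assoc) + 1L]] <- scored
      keep_phrases[[phrase$id]] <- phrase
    }
  }
  associations <- if (length(assoc)) {
    do.call(rbind, assoc)
  } else {
    data.frame(phrase_id = character(0), class = character(0),
               score = numeric(0), pl = numeric(0), syn = numeric(0),
               def = numeric(0), par = numeric(0), desc = numeric(0),
               stringsAsFactors = FALSE)
  }
  rownames(associations) <- NULL
  predicate_associations <- if (length(pred_assoc)) {
    do.call(rbind, pred_assoc)
  } else {
    data.frame(phrase_id = character(0), predicate = character(0),
               score = numeric(0), stringsAsFactors = FALSE)
  }
  rownames(predicate_associations) <- NULL

  # class-like context phrases are additional phrases: they carry extra
  # ontology classes but do not compete in the overlap selection
  spanning <- Filter(function(p) p$source != "ner_context", keep_phrases)
  eligible <- if (length(spanning)) {
    data.frame(
      phrase_id = vapply(spanning, `[[`, character(1), "id"),
      start = vapply(spanning, `[[`, integer(1), "start"),
      end = vapply(spanning, `[[`, integer(1), "end"),
      score = vapply(spanning, function(p) {
        max(associations$score[associations$phrase_id == p$id])
      }, numeric(1)),
      stringsAsFactors = FALSE
    )
  } else {
    data.frame(phrase_id = character(0), start = integer(0), end = integer(0),
               score = numeric(0), stringsAsFactors = FALSE)
  }
  rownames(eligible) <- NULL
  final <- select_final_phrases(eligible)
  ctx_ids <- vapply(Filter(function(p) p$source == "ner_context", keep_phrases),
                    `[[`, character(1), "id", USE.NAMES = FALSE)
  final_ids <- c(final$phrase_id, ctx_ids)
  structure(
    list(
      query = if (is.character(query) && length(query) == 1L) query else paste(terms, collapse = " "),
      terms = terms,
      phrases = phrases,
      associations = associations,
      final_phrases = final_ids,
      final = associations[associations$phrase_id %in% final_ids, , drop = FALSE],
      predicate_associations = predicate_associations,
      config = config
    ),
    class = "nlq_annotation"
  )
}

#' @export
print.nlq_annotation <- function(x, ...) {
  cat(sprintf("Query: \"%s\"\n", x$query))
  cat(sprintf("%d candidate phrase(s), %d association(s) >= tau=%g\n",
              length(x$phrases), nrow(x$associations), x$config$tau))
  cat("Final phrases:\n")
  for (id in x$final_phrases) {
    p <- x$phrases[[id]]
    sub <- x$associations[x$associations$phrase_id == id, , drop = FALSE]
    top <- sub[which.max(sub$score), , drop = FALSE]
    cat(sprintf("  \"%s\" -> %s (S=%.3f)\n", paste(p$terms, collapse = " "),
                top$class, top$score))
  }
  invisible(x)
}
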