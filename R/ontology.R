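#' Ontology classes and their textual features
#'
#' An ontology class is represented by its IRI, the identifier of the source
#' ontology, and a set of textual feature records: the preferred label
#' (always present), zero or more synonyms, an optional definition and zero
#' or more parent labels. Each feature record stores the normalized terms,
#' their dependency levels (`dl_tf`, computed with the same dependency
#' provider used for queries) and the feature length `|F|`.
#'
#' @param kind One of `"preferred_label"`, `"synonym"`, `"definition"`,
#'   `"parent_label"`, `"description"`.
#' @param text Raw feature text (normalized internally) — or, via `terms`,
#'   an already-normalized sequence.
#' @param terms Optional pre-normalized terms (overrides `text`).
#' @param adapter Parser adapter supplying the dependency provider.
#' @return `feature_record` returns a list with fields `kind`, `terms`,
#'   `dl`, `length`.
#' @export
feature_record <- function(kind, text = NULL, terms = NULL,
                           adapter = builtin_parser()) {
  kind <- match.arg(kind, c("preferred_label", "synonym", "definition",
                            "parent_label", "description"))
  if (is.null(terms)) terms <- normalize_terms(text)
  dl <- adapter$deps(terms)
  structure(
    list(kind = kind, terms = terms, dl = dl, length = length(terms)),
    class = "feature_record"
  )
}

#' Construct an ontology class record
#'
#' @param iri Class IRI (unique within an index).
#' @param ontology_id Label of the source ontology (e.g. `"FMA"`, `"CHEBI"`).
#' @param preferred_label The primary label text; required and non-empty.
#' @param synonyms Character vector of synonym texts (each indexed as its own
#'   feature record).
#' @param definition Definition text or `NULL`/`""` when absent.
#' @param parent_labels Character vector of parent preferred labels.
#' @param adapter Parser adapter used to assign feature dependency levels.
#' @return An object of class `ontology_class`.
#' @export
ontology_class <- function(iri, ontology_id, preferred_label,
                           synonyms = character(0), definition = NULL,
                           parent_labels = character(0),
                           adapter = builtin_parser()) {
  pl <- feature_record("preferred_label", preferred_label, adapter = adapter)
  if (pl$length == 0L) {
    stop("ontology class ", iri, " has an empty preferred label", call. = FALSE)
  }
  synonyms <- synonyms[nzchar(synonyms)]
  parent_labels <- parent_labels[nzchar(parent_labels)]
  def <- if (!is.null(definition) && nzchar(definition)) {
    feature_record("definition", definition, adapter = adapter)
  }
  structure(
    list(
      iri = iri,
      ontology_id = ontology_id,
      preferred_label = pl,
      synonyms = lapply(synonyms, function(s) {
        feature_record("synonym", s, adapter = adapter)
      }),
      definition = def,
      parent_labels = lapply(parent_labels, function(s) {
        feature_record("parent_label", s, adapter = adapter)
      })
    ),
    class = "ontology_class"
  )
}

#' @export
print.ontology_class <- function(x, ...) {
  cat(sprintf("<%s> [%s] pl=\"%s\" (%d synonym(s), %d parent(s)%s)\n",
              x$iri, x$ontology_id, paste(x$preferred_label$terms, collapse = " "),
              length(x$synonyms), length(x$parent_labels),
              if (is.null(x$definition)) "" else ", definition"))
  invisible(x)
}

#' Read and write the ontology dictionary format
#'
#' One record per line, UTF-8, six tab-separated fields: IRI, ontology id,
#' preferred label, `|`-joined synonyms, definition, `|`-joined parent
#' labels. Empty fields denote absent features.
#'
#' @param path File path.
#' @param adapter Parser adapter for feature dependency levels.
#' @return `read_ontology_dictionary` returns a list of [ontology_class()]
#'   objects; `write_ontology_dictionary` returns `path` invisibly.
#' @export
read_ontology_dictionary <- function(path, adapter = builtin_parser()) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  lapply(lines, function(line) {
    f <- strsplit(line, "\t", fixed = TRUE)[[1]]
    length(f) <- 6L
    f[is.na(f)] <- ""
    split_multi <- function(s) {
      if (!nzchar(s)) character(0) else strsplit(s, "|", fixed = TRUE)[[1]]
    }
    ontology_class(
      iri = f[1], ontology_id = f[2], preferred_label = f[3],
      synonyms = split_multi(f[4]), definition = f[5],
      parent_labels = split_multi(f[6]), adapter = adapter
    )
  })
}

#' @rdname read_ontology_dictionary
#' @param classes A list of `ontology_class` objects. Feature texts are
#'   written back as space-joined terms.
#' @export
write_ontology_dictionary <- function(classes, path) {
  join <- function(records) {
    paste(vapply(records, function(r) paste(r$terms, collapse = " "),
                 character(1)), collapse = "|")
  }
  lines <- vapply(classes, function(cl) {
    paste(
      cl$iri, cl$ontology_id,
      paste(cl$preferred_label$terms, collapse = " "),
      join(cl$synonyms),
      if (is.null(cl$definition)) "" else paste(cl$definition$terms, collapse = " "),
      join(cl$parent_labels),
      sep = "\t"
    )
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Distribute the preferred label into the other features (WPL)
#'
#' Empty features lower the degree of association for classes that lack
#' synonyms, definitions or parent labels. WPL mitigates this: every
#' non-preferred feature becomes the concatenation of the preferred-label
#' terms and its original terms (with length and dependency levels
#' recomputed), and absent features become a copy of the preferred label.
#' Applied exactly once, at index build time.
#'
#' @param class An [ontology_class()].
#' @param adapter Parser adapter used to recompute dependency levels.
#' @param enabled If `FALSE`, the class is returned unchanged.
#' @return The modified `ontology_class`.
#' @export
apply_wpl <- function(class, adapter = builtin_parser(), enabled = TRUE) {
  if (!enabled) return(class)
  pl <- class$preferred_label
  extend <- function(record, kind) {
    feature_record(kind, terms = c(pl$terms, record$terms), adapter = adapter)
  }
  copy_pl <- function(kind) feature_record(kind, terms = pl$terms, adapter = adapter)
  class$synonyms <- if (length(class$synonyms)) {
    lapply(class$synonyms, extend, kind = "synonym")
  } else {
    list(copy_pl("synonym"))
  }
  class$definition <- if (!is.null(class$definition)) {
    extend(class$definition, "definition")
  } else {
    copy_pl("definition")
  }
  class$parent_labels <- if (length(class$parent_labels)) {
    lapply(class$parent_labels, extend, kind = "parent_label")
  } else {
    list(copy_pl("parent_label"))
  }
  class
}

.class_features <- function(class) {
  c(list(class$preferred_label), class$synonyms,
    if (!is.null(class$definition)) list(class$definition),
    class$parent_labels)
}

#' Build the Text Feature Index (TFI)
#'
#' The TFI is an inverted index from terms to `(class, feature kind, dl_tf,
#' |F|)` postings, used to shortlist the ontology classes worth scoring
#' against a phrase. Entity descriptions are aggregated per class into
#' description statistics: the pooled term multiset, the total description
#' term count `te_a`, and the number of annotated entities `te_o`.
#'
#' @param classes List of [ontology_class()] objects (unique IRIs).
#' @param entity_annotations Named list: entity id -> character vector of
#'   class IRIs annotating that entity.
#' @param entity_descriptions Named list or character vector: entity id ->
#'   description text.
#' @param config An [annotator_config()]; controls WPL and stop words.
#' @param adapter Parser adapter for recomputed dependency levels under WPL.
#' @return An object of class `tfi`.
#' @export
build_tfi <- function(classes, entity_annotations = list(),
                      entity_descriptions = list(),
                      config = annotator_config(),
                      adapter = get_parser_adapter(config$parser)) {
  iris <- vapply(classes, `[[`, character(1), "iri")
  dup <- iris[duplicated(iris)]
  if (length(dup)) {
    stop("duplicate class IRI in dictionary: ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  class_store <- new.env(parent = emptyenv())
  for (cl in classes) {
    if (config$wpl) cl <- apply_wpl(cl, adapter = adapter)
    assign(cl$iri, cl, envir = class_store)
  }
  # description stats, aggregated per class over the entities it annotates
  desc_store <- new.env(parent = emptyenv())
  for (entity in names(entity_annotations)) {
    terms <- normalize_terms(.entity_text(entity_descriptions, entity))
    terms <- setdiff2_keep(terms, config$stopwords)
    for (iri in entity_annotations[[entity]]) {
      if (!exists(iri, envir = class_store, inherits = FALSE)) next
      cur <- if (exists(iri, envir = desc_store, inherits = FALSE)) {
        get(iri, envir = desc_store, inherits = FALSE)
      } else {
        list(terms = character(0), te_a = 0L, te_o = 0L)
      }
      cur$terms <- c(cur$terms, terms)
      cur$te_a <- cur$te_a + length(terms)
      cur$te_o <- cur$te_o + 1L
      assign(iri, cur, envir = desc_store)
    }
  }
  postings <- .rebuild_postings(class_store, desc_store, config)
  structure(
    list(postings = postings, classes = class_store, desc = desc_store,
         config = config),
    class = "tfi"
  )
}

.entity_text <- function(descriptions, entity) {
  if (is.null(descriptions)) return("")
  val <- if (is.list(descriptions)) descriptions[[entity]] else descriptions[entity]
  if (is.null(val) || is.na(val)) "" else as.character(val)
}

# multiset-aware difference: drop all occurrences of `drop` terms
setdiff2_keep <- function(terms, drop) {
  if (!length(drop)) terms else terms[!(terms %in% drop)]
}

#' @export
print.tfi <- function(x, ...) {
  cat(sprintf("Text Feature Index: %d classes, %d indexed terms, %d classes with descriptions\n",
              length(ls(x$classes)), length(ls(x$postings)), length(ls(x$desc))))
  invisible(x)
}

#' Shortlist candidate ontology classes for a phrase
#'
#' Returns exactly the classes having at least one indexed feature (including
#' the description feature) that shares at least one term with the phrase.
#'
#' @param tfi A [build_tfi()] index.
#' @param terms Non-empty normalized phrase terms.
#' @return A sorted character vector of class IRIs (possibly empty).
#' @export
candidate_classes <- function(tfi, terms) {
  stopifnot(length(terms) > 0L)
  hits <- unlist(lapply(unique(terms), function(t) {
    if (exists(t, envir = tfi$postings, inherits = FALSE)) {
      get(t, envir = tfi$postings, inherits = FALSE)$class
    }
  }), use.names = FALSE)
  sort(unique(as.character(hits)))
}

#' Description statistics for a class
#'
#' @param tfi A [build_tfi()] index.
#' @param iri Class IRI.
#' @return A list with `terms` (pooled multiset), `te_a`, `te_o`; zeros and
#'   an empty multiset when the class annotates no described entity.
#' @export
description_stats <- function(tfi, iri) {
  if (exists(iri, envir = tfi$desc, inherits = FALSE)) {
    get(iri, envir = tfi$desc, inherits = FALSE)
  } else {
    list(terms = character(0), te_a = 0L, te_o = 0L)
  }
}
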