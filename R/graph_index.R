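#' Recognizing ontology-class leaves
#'
#' An IRI leaf is treated as an ontology class when it matches one of these
#' namespace patterns (OBO PURLs, identifiers.org, MIRIAM URNs by default).
#' Unmatched IRI leaves are kept as literal-kind leaves so their text can
#' still contribute to entity descriptions.
#'
#' @return A character vector of regular expressions.
#' @export
default_ontology_namespaces <- function() {
  c(
    "^https?://purl\\.obolibrary\\.org/obo/",
    "^https?://identifiers\\.org/",
    "^urn:miriam:",
    "^https?://purl\\.org/obo/owl/"
  )
}

.is_ontology_iri <- function(iri, patterns) {
  any(vapply(patterns, function(p) grepl(p, iri), logical(1)))
}

# compact leaf id for an ontology IRI (local name), used in reporting
.iri_local <- function(iri) .split_iri(iri)[2]

#' Parse RDF annotation documents into per-entity trees
#'
#' Each detected root (a subject that never occurs as an object, unless an
#' explicit root list is given) yields one annotation tree whose leaves are
#' either ontology-class IRIs (per the namespace map) or text literals
#' (captured as entity descriptions).
#'
#' @param documents Character vector of file paths and/or document texts
#'   (RDF/XML or Turtle, auto-detected).
#' @param ontology_namespaces Regex patterns identifying ontology-class IRIs.
#' @param roots Optional explicit root IRIs overriding root detection.
#' @return A list of `annotation_tree` objects: each has `root`, `edges`
#'   (data.frame `parent`, `predicate`, `child`, `child_type`) and `leaves`
#'   (data.frame `node`, `kind`, `value` with `kind` in
#'   `{"ontology_class", "literal"}`).
#' @export
parse_annotations <- function(documents,
                              ontology_namespaces = default_ontology_namespaces(),
                              roots = NULL) {
  trees <- list()
  for (doc in documents) {
    triples <- read_rdf(doc)
    if (!nrow(triples)) next
    doc_roots <- if (is.null(roots)) {
      objs <- triples$object[triples$object_type %in% c("iri", "blank")]
      setdiff(unique(triples$subject), objs)
    } else {
      intersect(roots, unique(triples$subject))
    }
    for (r in sort(doc_roots)) {
      trees[[length(trees) + 1L]] <-
        .build_tree(r, triples, ontology_namespaces, doc)
    }
  }
  trees
}

.build_tree <- function(root, triples, patterns, doc_name) {
  edges <- list()
  leaves <- list()
  visit <- function(node, on_path) {
    if (node %in% on_path) {
      stop("cyclic annotation at node ", node, " (document ",
           substr(doc_name, 1L, 60L), ")", call. = FALSE)
    }
    rows <- which(triples$subject == node)
    if (!length(rows)) {
      # IRI with no outgoing edges: a leaf
      kind <- if (.is_ontology_iri(node, patterns)) "ontology_class" else "literal"
      leaves[[length(leaves) + 1L]] <<-
        data.frame(node = node, kind = kind, value = node, stringsAsFactors = FALSE)
      return(invisible(NULL))
    }
    for (r in rows) {
      obj <- triples$object[r]
      otype <- triples$object_type[r]
      edges[[length(edges) + 1L]] <<- data.frame(
        parent = node, predicate = triples$predicate[r],
        child = obj, child_type = otype, stringsAsFactors = FALSE
      )
      if (otype == "literal") {
        leaves[[length(leaves) + 1L]] <<-
          data.frame(node = obj, kind = "literal", value = obj,
                     stringsAsFactors = FALSE)
      } else {
        visit(obj, c(on_path, node))
      }
    }
  }
  visit(root, character(0))
  structure(
    list(
      root = root,
      edges = if (length(edges)) {
        e <- do.call(rbind, edges); rownames(e) <- NULL; e
      } else {
        data.frame(parent = character(0), predicate = character(0),
                   child = character(0), child_type = character(0))
      },
      leaves = if (length(leaves)) {
        l <- unique(do.call(rbind, leaves)); rownames(l) <- NULL; l
      } else {
        data.frame(node = character(0), kind = character(0), value = character(0))
      }
    ),
    class = "annotation_tree"
  )
}

#' @export
print.annotation_tree <- function(x, ...) {
  n_ont <- sum(x$leaves$kind == "ontology_class")
  cat(sprintf("Annotation tree rooted at %s: %d edge(s), %d ontology leaf(s), %d literal leaf(s)\n",
              x$root, nrow(x$edges), n_ont, nrow(x$leaves) - n_ont))
  invisible(x)
}

# enumerate all root-to-leaf predicate paths of a tree
.tree_paths <- function(tree) {
  out <- list()
  walk <- function(node, path) {
    rows <- which(tree$edges$parent == node)
    if (!length(rows)) {
      leaf <- tree$leaves[tree$leaves$node == node, , drop = FALSE]
      if (nrow(leaf)) {
        out[[length(out) + 1L]] <<-
          list(path = path, leaf = leaf$value[1], kind = leaf$kind[1])
      }
      return(invisible(NULL))
    }
    for (r in rows) {
      child <- tree$edges$child[r]
      pred <- tree$edges$predicate[r]
      if (tree$edges$child_type[r] == "literal") {
        out[[length(out) + 1L]] <<-
          list(path = c(path, pred), leaf = child, kind = "literal")
      } else {
        walk(child, c(path, pred))
      }
    }
  }
  walk(tree$root, character(0))
  out
}

.pred_label_terms <- function(predicate) {
  local <- .iri_local(predicate)
  if (!nzchar(local)) local <- predicate
  local <- gsub("([a-z0-9])([A-Z])", "\\1 \\2", local)
  normalize_terms(local)
}

.rgi_key <- function(class, root) paste(class, root, sep = "\x1f")

#' Build the RDF Graph Index (RGI)
#'
#' The RGI records every semantic annotation pattern present in a set of
#' annotation trees: which entity roots each ontology class annotates
#' (`class -> roots`), by which predicate paths (`(class, root) -> paths`),
#' the tokenized local names of all predicates (used for predicate
#' association scoring), and the literal description text attached to each
#' root.
#'
#' @param trees A list of [parse_annotations()] trees.
#' @return An object of class `rgi`.
#' @export
build_rgi <- function(trees) {
  class_to_roots <- new.env(parent = emptyenv())
  class_root_paths <- new.env(parent = emptyenv())
  predicate_labels <- new.env(parent = emptyenv())
  root_descriptions <- new.env(parent = emptyenv())
  n_paths <- 0L
  leaf_values <- character(0)
  ont_leaves <- character(0)
  roots <- character(0)
  for (tree in trees) {
    roots <- c(roots, tree$root)
    desc_parts <- character(0)
    for (entry in .tree_paths(tree)) {
      n_paths <- n_paths + 1L
      leaf_values <- c(leaf_values, entry$leaf)
      for (p in entry$path) {
        if (!exists(p, envir = predicate_labels, inherits = FALSE)) {
          assign(p, .pred_label_terms(p), envir = predicate_labels)
        }
      }
      if (entry$kind == "ontology_class") {
        ont_leaves <- c(ont_leaves, entry$leaf)
        cur <- if (exists(entry$leaf, envir = class_to_roots, inherits = FALSE)) {
          get(entry$leaf, envir = class_to_roots, inherits = FALSE)
        } else {
          character(0)
        }
        assign(entry$leaf, unique(c(cur, tree$root)), envir = class_to_roots)
        key <- .rgi_key(entry$leaf, tree$root)
        cur_p <- if (exists(key, envir = class_root_paths, inherits = FALSE)) {
          get(key, envir = class_root_paths, inherits = FALSE)
        } else {
          list()
        }
        sig <- paste(entry$path, collapse = " ")
        if (!sig %in% vapply(cur_p, paste, character(1), collapse = " ")) {
          cur_p[[length(cur_p) + 1L]] <- entry$path
        }
        assign(key, cur_p, envir = class_root_paths)
      } else {
        desc_parts <- c(desc_parts, entry$leaf)
      }
    }
    if (length(desc_parts)) {
      assign(tree$root, paste(desc_parts, collapse = " "),
             envir = root_descriptions)
    }
  }
  # order-stable path lists
  for (key in ls(class_root_paths)) {
    paths <- get(key, envir = class_root_paths, inherits = FALSE)
    sig <- vapply(paths, paste, character(1), collapse = " ")
    assign(key, paths[order(sig)], envir = class_root_paths)
  }
  structure(
    list(
      class_to_roots = class_to_roots,
      class_root_paths = class_root_paths,
      predicate_labels = predicate_labels,
      root_descriptions = root_descriptions,
      roots = sort(unique(roots)),
      stats = c(
        entities = length(trees),
        distinct_leaves = length(unique(leaf_values)),
        paths = n_paths,
        distinct_ontology_leaves = length(unique(ont_leaves))
      )
    ),
    class = "rgi"
  )
}

#' @export
print.rgi <- function(x, ...) {
  s <- x$stats
  cat(sprintf("RDF Graph Index: %d entities, %d distinct leaves, %d root-to-leaf paths, %d distinct ontology leaves\n",
              s[["entities"]], s[["distinct_leaves"]], s[["paths"]],
              s[["distinct_ontology_leaves"]]))
  invisible(x)
}

#' Entity roots annotated with all of the given classes
#'
#' @param rgi A [build_rgi()] index.
#' @param classes Non-empty character vector of class IRIs.
#' @return Sorted character vector of roots (possibly empty). Adding a class
#'   to `classes` can only shrink the result.
#' @export
roots_for <- function(rgi, classes) {
  stopifnot(length(classes) > 0L)
  sets <- lapply(classes, function(cl) {
    if (exists(cl, envir = rgi$class_to_roots, inherits = FALSE)) {
      get(cl, envir = rgi$class_to_roots, inherits = FALSE)
    } else {
      character(0)
    }
  })
  sort(Reduce(intersect, sets))
}

#' Predicate paths linking a class to a root
#'
#' @param rgi A [build_rgi()] index.
#' @param class Class IRI.
#' @param root Entity root IRI.
#' @return A list of character vectors (predicate IRIs from root to leaf),
#'   order-stable; empty when the pair is not indexed.
#' @export
paths_for <- function(rgi, class, root) {
  key <- .rgi_key(class, root)
  if (exists(key, envir = rgi$class_root_paths, inherits = FALSE)) {
    get(key, envir = rgi$class_root_paths, inherits = FALSE)
  } else {
    list()
  }
}

#' Corpus statistics of an RDF Graph Index
#'
#' @param rgi A [build_rgi()] index.
#' @return Named numeric vector: `entities`, `distinct_leaves`, `paths`
#'   (root-to-leaf path count) and `distinct_ontology_leaves`.
#' @export
corpus_stats <- function(rgi) {
  rgi$stats
}

# ---- persistence -----------------------------------------------------------

.env_to_list <- function(env) {
  keys <- ls(env)
  stats::setNames(lapply(keys, get, envir = env, inherits = FALSE), keys)
}

.list_to_env <- function(lst) {
  env <- new.env(parent = emptyenv())
  for (k in names(lst)) assign(k, lst[[k]], envir = env)
  env
}

#' Save and load the RDF Graph Index
#'
#' The index is written as JSON into a content-addressed file
#' `rgi-<md5>.json` inside `dir`, so rebuilds from updated repositories can
#' coexist and the loader can verify integrity. `load_rgi` accepts either
#' the file path or the directory (in which case the newest index is used).
#'
#' @param rgi A [build_rgi()] index.
#' @param dir Output directory (created if needed).
#' @param path Saved index file or directory.
#' @return `save_rgi` returns the file path; `load_rgi` the restored `rgi`.
#' @export
save_rgi <- function(rgi, dir) {
  payload <- list(
    format = "rgi/1",
    class_to_roots = .env_to_list(rgi$class_to_roots),
    class_root_paths = .env_to_list(rgi$class_root_paths),
    predicate_labels = .env_to_list(rgi$predicate_labels),
    root_descriptions = .env_to_list(rgi$root_descriptions),
    roots = rgi$roots,
    stats = as.list(rgi$stats)
  )
  .save_content_addressed(payload, dir, "rgi")
}

#' @rdname save_rgi
#' @export
load_rgi <- function(path) {
  payload <- .load_content_addressed(path, "rgi")
  structure(
    list(
      class_to_roots = .list_to_env(lapply(payload$class_to_roots, unlist)),
      class_root_paths = .list_to_env(
        lapply(payload$class_root_paths, function(paths) lapply(paths, unlist))
      ),
      predicate_labels = .list_to_env(
        lapply(payload$predicate_labels, function(x) as.character(unlist(x)))
      ),
      root_descriptions = .list_to_env(lapply(payload$root_descriptions, unlist)),
      roots = as.character(unlist(payload$roots)),
      stats = unlist(payload$stats)
    ),
    class = "rgi"
  )
}

.save_content_addressed <- function(payload, dir, stem) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tmp <- tempfile(fileext = ".json")
  jsonlite::write_json(payload, tmp, auto_unbox = TRUE, digits = NA, null = "null")
  hash <- unname(tools::md5sum(tmp))
  dest <- file.path(dir, sprintf("%s-%s.json", stem, hash))
  file.copy(tmp, dest, overwrite = TRUE)
  unlink(tmp)
  dest
}

.load_content_addressed <- function(path, stem) {
  if (dir.exists(path)) {
    candidates <- list.files(path, pattern = sprintf("^%s-[0-9a-f]{32}\\.json$", stem),
                             full.names = TRUE)
    if (!length(candidates)) {
      stop("no saved ", stem, " index found in ", path, call. = FALSE)
    }
    path <- candidates[which.max(file.mtime(candidates))]
  }
  if (!file.exists(path)) stop("index file not found: ", path, call. = FALSE)
  expected <- sub(sprintf("^%s-([0-9a-f]{32})\\.json$", stem), "\\1", basename(path))
  if (grepl("^[0-9a-f]{32}$", expected)) {
    actual <- unname(tools::md5sum(path))
    if (!identical(actual, expected)) {
      stop("index file ", basename(path), " failed its integrity check", call. = FALSE)
    }
  }
  payload <- jsonlite::read_json(path)
  if (!identical(payload$format, paste0(stem, "/1"))) {
    stop("unsupported index format in ", basename(path), call. = FALSE)
  }
  payload
}

#' Derive entity annotations and descriptions from an RGI
#'
#' Convenience extraction of the two inputs [build_tfi()] needs from an
#' already-built graph index: which classes annotate each entity and each
#' entity's literal description.
#'
#' @param rgi A [build_rgi()] index.
#' @return A list with `annotations` (entity -> class IRIs) and
#'   `descriptions` (entity -> text).
#' @export
entity_inputs_from_rgi <- function(rgi) {
  annotations <- list()
  for (cl in ls(rgi$class_to_roots)) {
    for (root in get(cl, envir = rgi$class_to_roots, inherits = FALSE)) {
      annotations[[root]] <- c(annotations[[root]], cl)
    }
  }
  annotations <- lapply(annotations, sort)
  descriptions <- .env_to_list(rgi$root_descriptions)
  list(annotations = annotations, descriptions = descriptions)
}
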