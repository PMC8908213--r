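# Independent brute-force oracles and shared fixture builders.
# These deliberately avoid the package's index structures: candidates are
# found by rescanning every feature, roots and paths by walking raw trees,
# and phrase selection by exhaustive subset enumeration.

# exhaustive feature scan: classes sharing >= 1 term with the phrase
brute_candidate_classes <- function(tfi, terms) {
  hits <- character(0)
  for (iri in ls(tfi$classes)) {
    cl <- get(iri, envir = tfi$classes)
    feats <- c(list(cl$preferred_label), cl$synonyms,
               if (!is.null(cl$definition)) list(cl$definition),
               cl$parent_labels)
    feat_terms <- unlist(lapply(feats, `[[`, "terms"))
    stats <- description_stats(tfi, iri)
    if (length(intersect(terms, c(feat_terms, stats$terms)))) {
      hits <- c(hits, iri)
    }
  }
  sort(hits)
}

# walk a tree's edges, returning every root-to-leaf (path, leaf, kind)
walk_tree_paths <- function(tree) {
  out <- list()
  recurse <- function(node, path) {
    rows <- which(tree$edges$parent == node)
    if (!length(rows)) {
      leaf <- tree$leaves[tree$leaves$node == node, , drop = FALSE]
      if (nrow(leaf)) {
        out[[length(out) + 1L]] <<- list(path = path, leaf = leaf$value[1],
                                         kind = leaf$kind[1])
      }
      return(invisible(NULL))
    }
    for (r in rows) {
      child <- tree$edges$child[r]
      if (tree$edges$child_type[r] == "literal") {
        out[[length(out) + 1L]] <<- list(path = c(path, tree$edges$predicate[r]),
                                         leaf = child, kind = "literal")
      } else {
        recurse(child, c(path, tree$edges$predicate[r]))
      }
    }
  }
  recurse(tree$root, character(0))
  out
}

# roots annotated with every class in `classes`, by scanning all trees
brute_roots_for <- function(trees, classes) {
  hits <- character(0)
  for (tree in trees) {
    leaves <- tree$leaves$value[tree$leaves$kind == "ontology_class"]
    if (all(classes %in% leaves)) hits <- c(hits, tree$root)
  }
  sort(hits)
}

# predicate paths between one class and one root, by scanning all trees
brute_paths_for <- function(trees, class, root) {
  out <- list()
  for (tree in trees) {
    if (tree$root != root) next
    for (entry in walk_tree_paths(tree)) {
      if (entry$kind == "ontology_class" && entry$leaf == class) {
        out[[length(out) + 1L]] <- entry$path
      }
    }
  }
  sigs <- vapply(out, paste, character(1), collapse = " ")
  unique(out[order(sigs)])
}

# exhaustive search over non-overlapping phrase subsets, maximizing
# (summed score, tokens covered, fewer phrases), tie-break earliest start
brute_select <- function(phrases) {
  n <- nrow(phrases)
  stopifnot(n <= 12)
  best <- NULL
  best_val <- c(-Inf, -Inf, -Inf, Inf)
  for (mask in 0:(2^n - 1)) {
    rows <- which(bitwAnd(mask, 2^(seq_len(n) - 1L)) > 0)
    if (length(rows) > 1L) {
      spans <- phrases[rows, , drop = FALSE]
      spans <- spans[order(spans$start), , drop = FALSE]
      if (any(spans$end[-nrow(spans)] > spans$start[-1])) next
    }
    val <- c(sum(phrases$score[rows]),
             sum(phrases$end[rows] - phrases$start[rows]),
             -length(rows),
             if (length(rows)) min(phrases$start[rows]) else Inf)
    better <- FALSE
    for (i in 1:3) {
      d <- val[i] - best_val[i]
      if (abs(d) > 1e-12) { better <- d > 0; break }
    }
    if (!better && all(abs(val[1:3] - best_val[1:3]) <= 1e-12) &&
        val[4] < best_val[4]) {
      better <- TRUE
    }
    if (better) { best <- rows; best_val <- val }
  }
  sort(phrases$phrase_id[best])
}

# worked-example pipeline pieces, built once per test run
worked_example_index <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      wx <- worked_example_fixture()
      trees <- parse_annotations(wx$document)
      rgi <- build_rgi(trees)
      inputs <- entity_inputs_from_rgi(rgi)
      tfi <- build_tfi(wx$classes, inputs$annotations, inputs$descriptions)
      cache <<- list(wx = wx, trees = trees, rgi = rgi, tfi = tfi)
    }
    cache
  }
})

# a small random corpus (ontology + repository + indexes) for a seed
random_corpus <- function(seed, n_classes = 20L, n_entities = 10L) {
  spec <- fixture_spec(seed = seed, n_classes = n_classes, n_entities = n_entities)
  ontology <- gen_ontology(spec)
  repo <- gen_repository(spec, ontology)
  trees <- parse_annotations(repo$document)
  rgi <- build_rgi(trees)
  inputs <- entity_inputs_from_rgi(rgi)
  tfi <- build_tfi(ontology, inputs$annotations, inputs$descriptions)
  list(spec = spec, ontology = ontology, repo = repo, trees = trees,
       rgi = rgi, tfi = tfi)
}

# top-scoring class per final phrase of an annotation
predicted_classes <- function(ann) {
  vapply(ann$final_phrases, function(id) {
    sub <- ann$associations[ann$associations$phrase_id == id, , drop = FALSE]
    sub$class[which.max(sub$score)]
  }, character(1), USE.NAMES = FALSE)
}
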