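#' Synthetic fixtures
#'
#' Deterministic generators for ontology dictionaries, RDF-annotated model
#' repositories and ground-truth queries, so every pipeline stage is
#' testable without network access. The vocabulary is synthetic but
#' biology-flavored (anatomy, chemical and physics term pools), which lets
#' the built-in mock NER operate on generated text. Entities carry one to
#' three ontology-class leaves — composite annotations rarely use more — and
#' a literal description.
#'
#' @name fixtures
NULL

# run code under a seed without disturbing the caller's RNG state
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

.vocab_pools <- function() {
  list(
    anatomy = c("extracellular", "intracellular", "space", "membrane", "cytosol",
                "nucleus", "mitochondrion", "apical", "basolateral", "plasma",
                "epithelial", "cell", "lumen", "tissue", "cardiac", "myocyte",
                "vesicle", "matrix", "capillary", "interstitium"),
    chemical = c("potassium", "sodium", "calcium", "chloride", "glucose",
                 "bicarbonate", "proton", "atp", "lactate", "urea", "oxygen",
                 "insulin", "albumin", "creatinine", "phosphate", "magnesium",
                 "ammonia", "citrate", "pyruvate", "glycogen"),
    physics = c("concentration", "flux", "pressure", "volume", "amount",
                "density", "current", "voltage", "resistance", "permeability",
                "rate", "flow", "tension", "charge", "capacitance",
                "diffusivity", "osmolarity", "stiffness", "temperature",
                "energy"),
    filler = c("model", "variable", "component", "simulation", "dynamics",
               "transport", "regulation", "kinetics", "exchange", "balance")
  )
}

.fixture_predicates <- function() {
  bq <- "http://biomodels.net/biology-qualifiers/"
  ss <- "http://bime.uw.edu/semsim/"
  c(paste0(bq, c("is", "isVersionOf", "isPropertyOf", "occursIn", "isPartOf", "hasPart")),
    paste0(ss, c("hasPhysicalDefinition", "physicalPropertyOf")))
}

.desc_predicate <- "http://purl.org/dc/terms/description"

#' Describe a synthetic corpus
#'
#' @param seed Integer seed; the same seed yields byte-identical fixtures.
#' @param n_classes Number of ontology classes (`>= 1`).
#' @param n_entities Number of annotated model entities.
#' @param classes_per_entity Probability weights for an entity carrying 1, 2
#'   or 3 ontology-class leaves.
#' @param depth_probs Probability weights for a class leaf sitting 1, 2 or 3
#'   predicates below the root.
#' @param absent_feature_fraction Probability that a class lacks a synonym /
#'   definition / parent label (exercising the WPL empty-feature path).
#' @param description_terms Range (min, max) of filler terms added to each
#'   entity's description literal.
#' @return An object of class `fixture_spec`.
#' @export
fixture_spec <- function(seed = 1L, n_classes = 50L, n_entities = 20L,
                         classes_per_entity = c(0.3, 0.5, 0.2),
                         depth_probs = c(0.4, 0.4, 0.2),
                         absent_feature_fraction = 0.3,
                         description_terms = c(2L, 6L)) {
  if (n_classes < 1L) stop("n_classes must be >= 1", call. = FALSE)
  stopifnot(n_entities >= 0L, length(classes_per_entity) == 3L,
            length(depth_probs) == 3L,
            absent_feature_fraction >= 0, absent_feature_fraction <= 1)
  structure(
    list(seed = as.integer(seed), n_classes = as.integer(n_classes),
         n_entities = as.integer(n_entities),
         classes_per_entity = classes_per_entity, depth_probs = depth_probs,
         absent_feature_fraction = absent_feature_fraction,
         description_terms = as.integer(description_terms)),
    class = "fixture_spec"
  )
}

#' Generate a synthetic ontology dictionary
#'
#' Classes draw unique preferred labels from the controlled vocabulary; a
#' configurable fraction lack synonyms, definitions or parent labels.
#'
#' @param spec A [fixture_spec()].
#' @param adapter Parser adapter for feature dependency levels.
#' @return A list of [ontology_class()] objects.
#' @export
gen_ontology <- function(spec, adapter = builtin_parser()) {
  pools <- .vocab_pools()
  content <- c(pools$anatomy, pools$chemical, pools$physics)
  with_seed(spec$seed, {
    label_sets <- list()
    classes <- vector("list", spec$n_classes)
    onts <- c("OPB", "FMA", "CHEBI", "GO")
    for (i in seq_len(spec$n_classes)) {
      repeat {
        n_terms <- sample(1:3, 1L, prob = c(0.35, 0.45, 0.2))
        label_terms <- sample(content, n_terms)
        # preferred labels form an antichain under term-set inclusion:
        # a label nested inside another scores identically on its shared
        # terms, so a planted class would not be uniquely recoverable
        nested <- any(vapply(label_sets, function(s) {
          all(s %in% label_terms) || all(label_terms %in% s)
        }, logical(1)))
        if (!nested) break
      }
      label <- paste(label_terms, collapse = " ")
      label_sets[[length(label_sets) + 1L]] <- label_terms
      present <- stats::runif(3) >= spec$absent_feature_fraction
      synonyms <- if (present[1]) {
        paste(sample(content, max(1L, n_terms)), collapse = " ")
      } else {
        character(0)
      }
      definition <- if (present[2]) {
        paste(c(strsplit(label, " ")[[1]],
                sample(c(content, pools$filler), 4L)), collapse = " ")
      } else {
        NULL
      }
      parents <- if (present[3]) {
        paste(sample(content, sample(1:2, 1L)), collapse = " ")
      } else {
        character(0)
      }
      classes[[i]] <- ontology_class(
        iri = sprintf("http://purl.obolibrary.org/obo/SYN_%07d", i),
        ontology_id = onts[(i - 1L) %% length(onts) + 1L],
        preferred_label = label, synonyms = synonyms,
        definition = definition, parent_labels = parents,
        adapter = adapter
      )
    }
    classes
  })
}

#' Generate a synthetic RDF-annotated repository
#'
#' Each entity becomes a root with 1-3 ontology-class leaves reached through
#' predicate chains of depth 1-3 (interior nodes are blanks) and a literal
#' description built from its classes' labels plus filler terms. The ground
#' truth records every generated fact for oracle tests.
#'
#' @param spec A [fixture_spec()].
#' @param ontology A [gen_ontology()] dictionary.
#' @return A list with `document` (RDF/XML text), `triples`, `ground_truth`
#'   (per entity: classes, paths, description) and `stats` (the corpus
#'   statistics the generator knows to be true).
#' @export
gen_repository <- function(spec, ontology) {
  preds <- .fixture_predicates()
  with_seed(spec$seed + 1L, {
    triples <- list()
    blank_n <- 0L
    gt <- list()
    n_paths <- 0L
    leaf_values <- character(0)
    ont_leaves <- character(0)
    emit <- function(s, p, o, type) {
      triples[[length(triples) + 1L]] <<-
        data.frame(subject = s, predicate = p, object = o, object_type = type,
                   stringsAsFactors = FALSE)
    }
    for (e in seq_len(spec$n_entities)) {
      root <- sprintf("http://models.example.org/synthetic#entity_%03d", e)
      k <- sample(1:3, 1L, prob = spec$classes_per_entity)
      picked <- sample(ontology, k)
      paths <- list()
      for (cl in picked) {
        depth <- sample(1:3, 1L, prob = spec$depth_probs)
        chain <- sample(preds, depth, replace = TRUE)
        subject <- root
        if (depth > 1L) {
          for (p in chain[-depth]) {
            blank_n <- blank_n + 1L
            b <- sprintf("_:b%d", blank_n)
            emit(subject, p, b, "blank")
            subject <- b
          }
        }
        emit(subject, chain[depth], cl$iri, "iri")
        paths[[cl$iri]] <- chain
        n_paths <- n_paths + 1L
        leaf_values <- c(leaf_values, cl$iri)
        ont_leaves <- c(ont_leaves, cl$iri)
      }
      label_terms <- unlist(lapply(picked, function(cl) cl$preferred_label$terms))
      extra <- sample(.vocab_pools()$filler,
                      sample(spec$description_terms[1]:spec$description_terms[2], 1L),
                      replace = TRUE)
      description <- paste(c(label_terms, extra), collapse = " ")
      emit(root, .desc_predicate, description, "literal")
      n_paths <- n_paths + 1L
      leaf_values <- c(leaf_values, description)
      gt[[root]] <- list(
        classes = sort(vapply(picked, `[[`, character(1), "iri")),
        paths = paths, description = description
      )
    }
    triple_df <- if (length(triples)) do.call(rbind, triples) else
      data.frame(subject = character(0), predicate = character(0),
                 object = character(0), object_type = character(0))
    rownames(triple_df) <- NULL
    list(
      document = write_rdf_xml(triple_df),
      triples = triple_df,
      ground_truth = gt,
      stats = c(
        entities = spec$n_entities,
        distinct_leaves = length(unique(leaf_values)),
        paths = n_paths,
        distinct_ontology_leaves = length(unique(ont_leaves))
      )
    )
  })
}

#' Generate ground-truth queries from a repository
#'
#' Each query is planted from one entity: the preferred labels of (a subset
#' of) its classes joined with connective words. At noise 0 the query quotes
#' the labels verbatim; with noise, a phrase is replaced by the class's
#' synonym (when one exists) with the given probability.
#'
#' @param repository A [gen_repository()] result.
#' @param ontology The dictionary the repository was generated from.
#' @param n_queries Number of queries.
#' @param noise Per-phrase probability of synonym substitution, in `[0, 1]`.
#' @param seed Integer seed.
#' @return A data.frame-less list of queries; each has `text`, `phrases`
#'   (planted label texts), `classes` (planted IRIs) and `entity` (the
#'   source root).
#' @export
gen_queries <- function(repository, ontology, n_queries = 10L, noise = 0,
                        seed = 1L) {
  iris <- vapply(ontology, `[[`, character(1), "iri")
  connectives <- c("of", "in")
  with_seed(seed + 2L, {
    roots <- names(repository$ground_truth)
    lapply(seq_len(n_queries), function(i) {
      root <- sample(roots, 1L)
      classes <- repository$ground_truth[[root]]$classes
      phrases <- character(0)
      used <- character(0)
      for (iri in classes) {
        cl <- ontology[[which(iris == iri)]]
        text <- paste(cl$preferred_label$terms, collapse = " ")
        if (noise > 0 && length(cl$synonyms) && stats::runif(1) < noise) {
          text <- paste(cl$synonyms[[1]]$terms, collapse = " ")
        }
        phrases <- c(phrases, text)
        used <- c(used, iri)
      }
      joiners <- sample(connectives, max(0L, length(phrases) - 1L), replace = TRUE)
      parts <- phrases[1]
      if (length(phrases) > 1L) {
        for (j in seq_along(joiners)) {
          parts <- c(parts, joiners[j], phrases[j + 1L])
        }
      }
      list(text = paste(parts, collapse = " "), phrases = phrases,
           classes = used, entity = root)
    })
  })
}

#' The worked-example fixture
#'
#' A small, fully synthetic transcription of the running example: the query
#' "concentration of potassium in extracellular space", a dictionary of the
#' six candidate classes involved (OPB_00340 "concentration of chemical",
#' OPB_00592, CHEBI_29103 "potassium", CHEBI_26216, FMA_70022 "extracellular
#' space" with synonym "intercellular space" and parent "interstitial
#' space", FMA_17555), and one RDF/XML document describing the entity
#' `#K_e`, annotated with OPB_00340, FMA_70022 and CHEBI_29103 through
#' BioModels-qualifier-style predicate chains, plus a literal description.
#' Labels not fixed by the example are synthetic stand-ins; predicate IRIs
#' are representative placeholders (paths are opaque index keys).
#'
#' @param adapter Parser adapter for feature dependency levels.
#' @return A list: `classes` (dictionary), `document` (RDF/XML text),
#'   `query`, and `expected` (`phrases`, `classes`, `root`).
#' @export
worked_example_fixture <- function(adapter = builtin_parser()) {
  obo <- function(x) paste0("http://purl.obolibrary.org/obo/", x)
  classes <- list(
    ontology_class(obo("OPB_00340"), "OPB", "concentration of chemical",
                   adapter = adapter),
    ontology_class(obo("OPB_00592"), "OPB", "concentration of particles",
                   adapter = adapter),
    ontology_class(obo("CHEBI_29103"), "CHEBI", "potassium",
                   synonyms = "k+", adapter = adapter),
    ontology_class(obo("CHEBI_26216"), "CHEBI", "potassium molecular entity",
                   adapter = adapter),
    ontology_class(obo("FMA_70022"), "FMA", "extracellular space",
                   synonyms = "intercellular space",
                   parent_labels = "interstitial space", adapter = adapter),
    ontology_class(obo("FMA_17555"), "FMA", "extracellular matrix",
                   adapter = adapter)
  )
  bq <- "http://biomodels.net/biology-qualifiers/"
  base <- "http://models.example.org/potassium_model"
  root <- paste0(base, "#K_e")
  triples <- data.frame(
    subject = c(root, root, "_:b1", "_:b1", root),
    predicate = c(paste0(bq, "isVersionOf"), paste0(bq, "isPropertyOf"),
                  paste0(bq, "is"), paste0(bq, "occursIn"), .desc_predicate),
    object = c(obo("OPB_00340"), "_:b1", obo("CHEBI_29103"), obo("FMA_70022"),
               "Concentration of potassium in the extracellular space"),
    object_type = c("iri", "blank", "iri", "iri", "literal"),
    stringsAsFactors = FALSE
  )
  list(
    classes = classes,
    document = write_rdf_xml(triples),
    triples = triples,
    query = "concentration of potassium in extracellular space",
    expected = list(
      phrases = c("concentration", "potassium", "extracellular space"),
      classes = c(obo("OPB_00340"), obo("CHEBI_29103"), obo("FMA_70022")),
      root = root
    )
  )
}

#' Materialize fixtures to a directory
#'
#' Writes the dictionary (TSV dialect), the repository RDF/XML and a
#' queries TSV so the command-line interface can operate on files.
#'
#' @param dir Output directory.
#' @param spec A [fixture_spec()].
#' @param n_queries Number of ground-truth queries to write.
#' @return `dir`, invisibly.
#' @export
materialize_fixtures <- function(dir, spec = fixture_spec(), n_queries = 10L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ontology <- gen_ontology(spec)
  repo <- gen_repository(spec, ontology)
  queries <- gen_queries(repo, ontology, n_queries = n_queries, seed = spec$seed)
  write_ontology_dictionary(ontology, file.path(dir, "ontology.tsv"))
  writeLines(repo$document, file.path(dir, "repository.rdf"), sep = "",
             useBytes = TRUE)
  lines <- vapply(queries, function(q) {
    paste(q$text, paste(q$classes, collapse = "|"), q$entity, sep = "\t")
  }, character(1))
  writeLines(c("query\tclasses\tentity", lines), file.path(dir, "queries.tsv"),
             useBytes = TRUE)
  invisible(dir)
}
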