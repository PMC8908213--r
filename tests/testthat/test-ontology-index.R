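test_that("WPL fills absent features with the preferred label and prefixes present ones", {
  cl <- ontology_class("urn:x", "FMA", "extracellular space",
                       parent_labels = "interstitial space")
  wpl <- apply_wpl(cl)
  # absent synonym becomes a copy of the preferred label
  expect_length(wpl$synonyms, 1)
  expect_equal(wpl$synonyms[[1]]$terms, c("extracellular", "space"))
  # present parent is prefixed by the preferred label, |F| recomputed
  expect_equal(wpl$parent_labels[[1]]$terms,
               c("extracellular", "space", "interstitial", "space"))
  expect_equal(wpl$parent_labels[[1]]$length, 4L)
  expect_length(wpl$parent_labels[[1]]$dl, 4L)
  # preferred label itself unchanged
  expect_equal(wpl$preferred_label$terms, cl$preferred_label$terms)
  # disabled -> identity
  expect_identical(apply_wpl(cl, enabled = FALSE), cl)
})

test_that("a minimal dictionary indexes its preferred label", {
  cl <- ontology_class("urn:k", "CHEBI", "potassium")
  tfi <- build_tfi(list(cl), config = annotator_config(wpl = FALSE))
  post <- get("potassium", envir = tfi$postings)
  expect_equal(post$class, "urn:k")
  expect_equal(post$kind, "preferred_label")
  expect_equal(post$dl, 1L)
  expect_equal(post$flen, 1L)
})

test_that("duplicate class IRIs are rejected with identification", {
  cls <- list(ontology_class("urn:a", "GO", "one"),
              ontology_class("urn:a", "GO", "two"))
  expect_error(build_tfi(cls), "urn:a")
})

test_that("description statistics aggregate per class over annotated entities", {
  cl <- ontology_class("urn:c", "GO", "channel")
  tfi <- build_tfi(
    list(cl),
    entity_annotations = list(e1 = "urn:c"),
    entity_descriptions = list(e1 = "potassium channel model")
  )
  stats <- description_stats(tfi, "urn:c")
  expect_equal(stats$te_a, 3L)
  expect_equal(stats$te_o, 1L)
  expect_setequal(stats$terms, c("potassium", "channel", "model"))
  # unindexed class has zero stats
  empty <- description_stats(tfi, "urn:none")
  expect_equal(empty$te_a, 0L)
  expect_equal(empty$te_o, 0L)
})

test_that("candidate lookup equals a brute-force feature scan on random corpora", {
  for (seed in 1:20) {
    corpus <- random_corpus(seed, n_classes = 15L, n_entities = 6L)
    tfi <- corpus$tfi
    set.seed(seed)
    pools <- c("extracellular", "space", "potassium", "flux", "membrane",
               "concentration", "sodium", "pressure", "ribosome", "qqq")
    for (j in 1:4) {
      phrase <- sample(pools, sample(1:3, 1))
      expect_identical(candidate_classes(tfi, phrase),
                       brute_candidate_classes(tfi, phrase))
    }
  }
})

test_that("candidate lookup hits and misses behave on the worked example", {
  ix <- worked_example_index()
  hit <- candidate_classes(ix$tfi, c("extracellular", "space"))
  expect_true("http://purl.obolibrary.org/obo/FMA_70022" %in% hit)
  expect_identical(candidate_classes(ix$tfi, "ribosome"), character(0))
  expect_error(candidate_classes(ix$tfi, character(0)))
})

test_that("index construction is deterministic", {
  spec <- fixture_spec(seed = 5, n_classes = 12, n_entities = 5)
  ont <- gen_ontology(spec)
  repo <- gen_repository(spec, ont)
  trees <- parse_annotations(repo$document)
  inputs <- entity_inputs_from_rgi(build_rgi(trees))
  t1 <- build_tfi(ont, inputs$annotations, inputs$descriptions)
  t2 <- build_tfi(ont, inputs$annotations, inputs$descriptions)
  for (term in ls(t1$postings)) {
    expect_identical(get(term, envir = t1$postings), get(term, envir = t2$postings))
  }
  expect_identical(sort(ls(t1$postings)), sort(ls(t2$postings)))
})

test_that("WPL never loses preferred-label-driven candidates", {
  for (seed in 1:5) {
    spec <- fixture_spec(seed = seed, n_classes = 15, n_entities = 0)
    ont <- gen_ontology(spec)
    with_wpl <- build_tfi(ont, config = annotator_config(wpl = TRUE))
    without <- build_tfi(ont, config = annotator_config(wpl = FALSE))
    for (cl in ont[1:5]) {
      phrase <- cl$preferred_label$terms
      expect_true(all(candidate_classes(without, phrase) %in%
                      candidate_classes(with_wpl, phrase)))
    }
  }
})

test_that("the dictionary dialect round-trips", {
  spec <- fixture_spec(seed = 3, n_classes = 10)
  ont <- gen_ontology(spec)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_ontology_dictionary(ont, path)
  back <- read_ontology_dictionary(path)
  expect_length(back, length(ont))
  for (i in seq_along(ont)) {
    expect_equal(back[[i]]$iri, ont[[i]]$iri)
    expect_equal(back[[i]]$preferred_label$terms, ont[[i]]$preferred_label$terms)
    expect_equal(lapply(back[[i]]$synonyms, `[[`, "terms"),
                 lapply(ont[[i]]$synonyms, `[[`, "terms"))
    expect_equal(lapply(back[[i]]$parent_labels, `[[`, "terms"),
                 lapply(ont[[i]]$parent_labels, `[[`, "terms"))
  }
})
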