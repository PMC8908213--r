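test_that("chunking the running example yields the six candidate phrases", {
  phrases <- chunk_parse("concentration of potassium in extracellular space")
  texts <- vapply(phrases, function(p) paste(p$terms, collapse = " "), character(1))
  expect_setequal(texts, c(
    "concentration of potassium in extracellular space",
    "concentration of potassium", "concentration", "potassium",
    "extracellular space", "space"
  ))
  expect_length(chunk_parse("potassium"), 1)
  expect_error(chunk_parse(""), "empty query")
})

test_that("NER chunking attaches entity types and builds context phrases", {
  phrases <- chunk_ner("concentration of potassium in extracellular space")
  by_source <- split(phrases, vapply(phrases, `[[`, character(1), "source"))
  ner_texts <- vapply(by_source$ner, function(p) paste(p$terms, collapse = " "),
                      character(1))
  expect_setequal(ner_texts, c("potassium", "extracellular space"))
  ctx_texts <- vapply(by_source$ner_context,
                      function(p) paste(p$terms, collapse = " "), character(1))
  expect_true("concentration of simple chemical" %in% ctx_texts)
  # no recognized span -> no candidates
  expect_length(chunk_ner("unknown words only"), 0)
})

test_that("context phrases get dependency levels over the substituted text", {
  phrases <- chunk_ner("concentration of potassium in extracellular space")
  ctx <- Filter(function(p) p$source == "ner_context" &&
                  identical(p$terms, c("concentration", "of", "simple", "chemical")),
                phrases)
  expect_length(ctx, 1)
  expect_equal(ctx[[1]]$dl, c(1L, 3L, 3L, 2L))
})

test_that("annotation filters by threshold and keeps only associated phrases", {
  ix <- worked_example_index()
  ann <- annotate(ix$wx$query, ix$tfi, ix$rgi)
  expect_true(all(ann$associations$score >= ann$config$tau))
  expect_true(all(ann$final_phrases %in% ann$associations$phrase_id))
  # raising tau above the maximum empties the result
  top <- max(ann$associations$score)
  ann2 <- annotate(ix$wx$query, ix$tfi, ix$rgi,
                   annotator_config(tau = top + 1))
  expect_equal(nrow(ann2$associations), 0L)
  expect_length(ann2$final_phrases, 0L)
  expect_error(annotate("", ix$tfi, ix$rgi), "empty query")
})

test_that("raising the threshold never adds associations", {
  ix <- worked_example_index()
  taus <- c(0, 1, 2, 4, 7)
  sizes <- vapply(taus, function(tau) {
    nrow(annotate(ix$wx$query, ix$tfi, ix$rgi,
                  annotator_config(tau = tau))$associations)
  }, numeric(1))
  expect_true(all(diff(sizes) <= 0))
  # and every lower-threshold set contains the higher-threshold set
  a_lo <- annotate(ix$wx$query, ix$tfi, ix$rgi, annotator_config(tau = 1))
  a_hi <- annotate(ix$wx$query, ix$tfi, ix$rgi, annotator_config(tau = 3))
  key <- function(a) paste(a$associations$phrase_id, a$associations$class)
  expect_true(all(key(a_hi) %in% key(a_lo)))
})

test_that("the worked example selects the three content phrases", {
  ix <- worked_example_index()
  ann <- annotate(ix$wx$query, ix$tfi, ix$rgi)
  texts <- vapply(ann$final_phrases, function(id) {
    paste(ann$phrases[[id]]$terms, collapse = " ")
  }, character(1), USE.NAMES = FALSE)
  expect_setequal(texts, c("concentration", "potassium", "extracellular space"))
  expect_setequal(predicted_classes(ann), ix$wx$expected$classes)
})

test_that("phrase selection equals exhaustive subset search", {
  set.seed(31)
  for (rep in 1:20) {
    n_tokens <- sample(4:8, 1)
    n_phrases <- sample(2:9, 1)
    starts <- sample(0:(n_tokens - 1), n_phrases, replace = TRUE)
    lens <- sample(1:3, n_phrases, replace = TRUE)
    phrases <- data.frame(
      phrase_id = sprintf("p%02d", seq_len(n_phrases)),
      start = starts,
      end = pmin(starts + lens, n_tokens),
      score = round(stats::runif(n_phrases, 0.1, 5), 3),
      stringsAsFactors = FALSE
    )
    phrases <- phrases[!duplicated(phrases[, c("start", "end")]), ]
    got <- select_final_phrases(phrases)
    expect_identical(sort(got$phrase_id), brute_select(phrases))
    # selected spans never overlap
    if (nrow(got) > 1) {
      expect_true(all(got$end[-nrow(got)] <= got$start[-1]))
    }
  }
})

test_that("noiseless planted queries are recovered with perfect precision and recall", {
  for (seed in c(3, 17, 29)) {
    corpus <- random_corpus(seed, n_classes = 20L, n_entities = 10L)
    queries <- gen_queries(corpus$repo, corpus$ontology, n_queries = 5,
                           noise = 0, seed = seed)
    for (q in queries) {
      ann <- annotate(q$text, corpus$tfi, corpus$rgi)
      prf <- precision_recall_f(predicted_classes(ann), q$classes)
      expect_equal(unname(prf[["precision"]]), 1.0)
      expect_equal(unname(prf[["recall"]]), 1.0)
    }
  }
})

test_that("a verbatim preferred label ranks its class first", {
  corpus <- random_corpus(8)
  for (cl in corpus$ontology[1:5]) {
    ann <- annotate(paste(cl$preferred_label$terms, collapse = " "),
                    corpus$tfi, corpus$rgi)
    top <- ann$associations[which.max(ann$associations$score), ]
    expect_equal(top$class, cl$iri)
  }
})
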