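obo <- function(x) paste0("http://purl.obolibrary.org/obo/", x)
k_e <- "http://models.example.org/potassium_model#K_e"

# a hand-built annotation-like structure: phrase -> candidate classes
assoc_table <- function(...) {
  lst <- list(...)
  lapply(lst, function(classes) {
    data.frame(class = classes, score = seq(length(classes), 1),
               stringsAsFactors = FALSE)
  })
}

test_that("combination enumeration is the Cartesian product across phrases", {
  expect_length(enumerate_combinations(assoc_table(
    p1 = c("a", "b"), p2 = c("c", "d"), p3 = c("e", "f")
  )), 8)
  expect_length(enumerate_combinations(assoc_table(p1 = "a")), 1)
  expect_length(enumerate_combinations(assoc_table(
    p1 = c("a", "b", "c"), p2 = "d", p3 = c("e", "f")
  )), 6)
  expect_error(enumerate_combinations(list()), "no final phrases")
})

test_that("the combination cap prunes lowest-scoring combinations first", {
  combos <- enumerate_combinations(assoc_table(
    p1 = c("a", "b"), p2 = c("c", "d"), p3 = c("e", "f")
  ), max_combinations = 3)
  expect_length(combos, 3)
  # the best combination (all top-scored classes) survives
  expect_equal(combos[[1]]$class, c("a", "c", "e"))
  totals <- vapply(combos, function(cb) sum(cb$score), numeric(1))
  expect_true(all(diff(totals) <= 0))
})

test_that("viability against the worked-example repository follows the RGI", {
  ix <- worked_example_index()
  combos <- enumerate_combinations(assoc_table(
    p1 = c(obo("OPB_00340"), obo("OPB_00592")),
    p2 = c(obo("CHEBI_29103"), obo("CHEBI_26216")),
    p3 = c(obo("FMA_70022"), obo("FMA_17555"))
  ))
  expect_length(combos, 8)
  viable <- viable_combinations(combos, ix$rgi)
  expect_length(viable, 1)
  expect_setequal(viable[[1]]$class,
                  c(obo("OPB_00340"), obo("CHEBI_29103"), obo("FMA_70022")))
  # a viable combination has exactly one pattern here (one path per class)
  patterns <- patterns_for(viable[[1]], ix$rgi)
  expect_length(patterns, 1)
  expect_equal(patterns[[1]]$roots, k_e)
  # non-viable combination -> no patterns
  bad <- combos[[which(vapply(combos, function(cb) obo("OPB_00592") %in% cb$class,
                              logical(1)))[1]]]
  expect_length(patterns_for(bad, ix$rgi), 0)
})

test_that("viability equals a brute-force scan over all trees", {
  for (seed in 1:10) {
    corpus <- random_corpus(seed, n_classes = 12L, n_entities = 8L)
    classes <- ls(corpus$rgi$class_to_roots)
    set.seed(seed + 50)
    for (j in 1:4) {
      pick <- sample(classes, min(length(classes), sample(1:3, 1)))
      combo <- data.frame(phrase_id = paste0("p", seq_along(pick)), class = pick,
                          score = 1, stringsAsFactors = FALSE)
      viable <- length(viable_combinations(list(combo), corpus$rgi)) == 1
      expect_equal(viable, length(brute_roots_for(corpus$trees, pick)) > 0)
    }
  }
})

test_that("pattern multiplicity equals the product of per-class path choices", {
  # one entity, one class reachable via two distinct paths
  ttl <- paste(
    "@prefix bq: <http://biomodels.net/biology-qualifiers/> .",
    "@prefix obo: <http://purl.obolibrary.org/obo/> .",
    "<http://m.example.org/x#e> bq:is obo:CHEBI_29103 .",
    "<http://m.example.org/x#e> bq:isPropertyOf [ bq:is obo:CHEBI_29103 ] .",
    "<http://m.example.org/x#e> bq:occursIn obo:FMA_70022 .",
    sep = "\n"
  )
  rgi <- build_rgi(parse_annotations(ttl))
  combo <- data.frame(phrase_id = c("p1", "p2"),
                      class = c(obo("CHEBI_29103"), obo("FMA_70022")),
                      score = c(2, 1), stringsAsFactors = FALSE)
  patterns <- patterns_for(combo, rgi)
  expect_length(patterns, 2)  # 2 paths x 1 path
  # and compilation of distinct patterns gives distinct, deterministic SPARQL
  q <- lapply(patterns, compose_sparql)
  expect_false(identical(q[[1]]$sparql, q[[2]]$sparql))
  expect_identical(compose_sparql(patterns[[1]])$sparql,
                   compose_sparql(patterns[[1]])$sparql)
})

test_that("composed SPARQL executes to the worked example's entity", {
  ix <- worked_example_index()
  res <- nlq_to_sparql(ix$wx$query, ix$tfi, ix$rgi)
  expect_gte(length(res$queries), 1)
  expect_equal(res$entities, k_e)
  for (q in res$queries) {
    expect_equal(execute_sparql(q$sparql, ix$wx$triples), k_e)
  }
})

test_that("an external SPARQL engine agrees on the worked example", {
  ix <- worked_example_index()
  res <- nlq_to_sparql(ix$wx$query, ix$tfi, ix$rgi)
  rdf_file <- withr::local_tempfile(fileext = ".rdf")
  writeLines(ix$wx$document, rdf_file, sep = "")
  q_file <- withr::local_tempfile(fileext = ".rq")
  writeLines(res$queries[[1]]$sparql, q_file)
  script <- paste(
    "import sys, rdflib",
    "g = rdflib.Graph(); g.parse(sys.argv[1])",
    "rows = g.query(open(sys.argv[2]).read())",
    "print('\\n'.join(sorted(str(r[0]) for r in rows)))",
    sep = "; "
  )
  out <- suppressWarnings(
    system2("python", c("-c", shQuote(script), rdf_file, q_file),
            stdout = TRUE, stderr = FALSE)
  )
  expect_equal(out[nzchar(out)], k_e)
})

test_that("SPARQL execution agrees with index retrieval on random corpora", {
  for (seed in 1:20) {
    corpus <- random_corpus(seed, n_classes = 12L, n_entities = 8L)
    triples <- read_rdf(corpus$repo$document)
    classes <- ls(corpus$rgi$class_to_roots)
    set.seed(seed + 200)
    for (j in 1:3) {
      pick <- sample(classes, min(length(classes), sample(1:2, 1)))
      combo <- data.frame(phrase_id = paste0("p", seq_along(pick)), class = pick,
                          score = 1, stringsAsFactors = FALSE)
      direct <- retrieve_entities(combo, corpus$rgi)
      patterns <- patterns_for(combo, corpus$rgi)
      via_sparql <- sort(unique(unlist(lapply(patterns, function(pat) {
        execute_sparql(compose_sparql(pat)$sparql, triples)
      }))))
      if (is.null(via_sparql)) via_sparql <- character(0)
      expect_identical(via_sparql, direct)
    }
  }
})

test_that("ranking is by score with lexicographic tie-break and predicate bonus", {
  mk <- function(sparql, score, paths = list()) {
    structure(list(sparql = sparql, score = score,
                   pattern = list(paths = paths)),
              class = "composed_query")
  }
  ranked <- rank_queries(list(mk("b", 2.0), mk("a", 3.1)))
  expect_equal(vapply(ranked, `[[`, numeric(1), "score"), c(3.1, 2.0))
  tied <- rank_queries(list(mk("zzz", 1), mk("aaa", 1)))
  expect_equal(vapply(tied, `[[`, character(1), "sparql"), c("aaa", "zzz"))
  # a matching predicate association can only improve a query's rank
  pa <- data.frame(phrase_id = "p", predicate = "urn:p1", score = 0.5,
                   stringsAsFactors = FALSE)
  with_pred <- mk("with", 1.0, paths = list(cls = c("urn:p1", "urn:p2")))
  without <- mk("without", 1.0)
  ranked2 <- rank_queries(list(without, with_pred), pa)
  expect_equal(ranked2[[1]]$sparql, "with")
  expect_equal(ranked2[[1]]$score, 1.5)
  expect_equal(ranked2[[2]]$score, 1.0)
})

test_that("retrieval without SPARQL matches the expected roots", {
  ix <- worked_example_index()
  combo <- data.frame(
    phrase_id = c("p1", "p2", "p3"),
    class = c(obo("OPB_00340"), obo("CHEBI_29103"), obo("FMA_70022")),
    score = c(1, 1, 1), stringsAsFactors = FALSE
  )
  expect_equal(retrieve_entities(combo, ix$rgi), k_e)
  bad <- data.frame(phrase_id = "p1", class = obo("OPB_00592"), score = 1,
                    stringsAsFactors = FALSE)
  expect_identical(retrieve_entities(bad, ix$rgi), character(0))
})
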