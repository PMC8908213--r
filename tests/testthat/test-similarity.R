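# Hand-derived expected values are frozen from closed-form evaluation of the
# similarity definitions; tolerance 1e-9 throughout.

test_that("coverage similarity is overlap over feature length", {
  expect_equal(sim_coverage(c("extracellular", "space"), c("extracellular", "space")), 1.0)
  expect_equal(sim_coverage("ribosome", c("extracellular", "space")), 0.0)
  # a long phrase fully covering a short feature ties with the exact phrase
  p_long <- normalize_terms("concentration of potassium in extracellular space")
  f <- c("extracellular", "space")
  expect_equal(sim_coverage(p_long, f), sim_coverage(f, f))
  expect_error(sim_coverage("x", character(0)), "\\|F\\| == 0")
})

test_that("length-normalized similarity reduces to coverage for short phrases", {
  for (np in 1:4) {
    p <- paste0("t", 1:np)
    f <- c(paste0("t", 1:2), "f3", "f4")  # |F| = 4 >= |P|
    expect_equal(sim_length_norm(p, f), sim_coverage(p, f), tolerance = 1e-9)
  }
})

test_that("length-normalized similarity matches hand evaluation and damps long phrases", {
  # |P| = 6, |F| = 2, overlap 2 -> 2 / (2 + ln 4)
  p <- c("a", "b", "c", "d", "extracellular", "space")
  f <- c("extracellular", "space")
  expect_equal(sim_length_norm(p, f), 2 / (2 + log(4)), tolerance = 1e-9)
  expect_equal(sim_length_norm(p, f), 0.5907, tolerance = 5e-4)
  # strictly decreasing in |P| once |P| > |F| + 1
  prev <- sim_length_norm(f, f)
  for (extra in 1:5) {
    cur <- sim_length_norm(c(f, paste0("x", seq_len(extra + 1))), f)
    expect_lt(cur, prev + 1e-12)
    if (extra > 1) expect_lt(cur, prev)
    prev <- cur
  }
})

test_that("dependency similarity matches closed-form hand evaluations", {
  # |P| = |F| = 1, overlap 1, dl 1: ln2 / ln2 = 1
  expect_equal(sim_dependency("a", "a", 1L, 1L, 2L, 1L), 1.0, tolerance = 1e-9)
  # |P| = |F| = 2, overlap 1: max dl 1 -> ln3/ln6; max dl 2 -> ln2/ln6
  expect_equal(sim_dependency(c("a", "x"), c("a", "y"), c(1L, 2L), c(1L, 2L)),
               log(3) / log(6), tolerance = 1e-9)
  expect_equal(sim_dependency(c("x", "a"), c("a", "y"), c(1L, 2L), c(2L, 1L)),
               log(2) / log(6), tolerance = 1e-9)
  expect_equal(sim_dependency(c("a", "b"), c("c", "d"), c(1L, 2L), c(1L, 2L)), 0.0)
})

test_that("an exact match with chain dependencies scores exactly 1", {
  for (n in 1:5) {
    f <- paste0("t", seq_len(n))
    dl <- seq_len(n)
    expect_equal(sim_dependency(f, f, dl, dl), 1.0, tolerance = 1e-9)
  }
})

test_that("dependency similarity is non-increasing in the dependency level", {
  f <- c("a", "b", "c")
  dl_f <- c(1L, 2L, 3L)
  scores <- vapply(1:6, function(dl) {
    sim_dependency(c("a", "x", "y"), f, c(dl, 1L, 1L), dl_f)
  }, numeric(1))
  expect_true(all(diff(scores) <= 1e-12))
  # collapses to a dl-independent value once |F| + k1 - max(dl) <= k1
  expect_equal(scores[4], scores[6], tolerance = 1e-9)
})

test_that("description similarity matches hand evaluation and rewards reuse", {
  expect_equal(sim_description(c("a", "b"), c("x", "y"), 2, 1), 0.0)
  # overlap 1, |P| = 2, te_a = 5, te_o = 1
  expect_equal(sim_description(c("a", "b"), c("a", "z"), 5, 1),
               (1 + log(2)) / ((1 + log(2)) * (1 + log(6))), tolerance = 1e-9)
  expect_equal(sim_description(c("a", "b"), c("a", "z"), 5, 1), 0.358, tolerance = 1e-3)
  # doubling te_o strictly increases the score
  lo <- sim_description(c("a", "b"), c("a", "z"), 5, 2)
  hi <- sim_description(c("a", "b"), c("a", "z"), 5, 4)
  expect_gt(hi, lo)
  # the alternative reading divides by the reuse factor instead
  alt <- sim_description(c("a", "b"), c("a", "z"), 5, 1, teo_in_denominator = TRUE)
  expect_equal(alt, 1 / ((1 + log(2)) * (1 + log(6)) * (1 + log(2))), tolerance = 1e-9)
})

test_that("all similarities are non-negative and finite on random inputs", {
  set.seed(11)
  vocab <- paste0("w", 1:12)
  for (i in 1:40) {
    p <- sample(vocab, sample(1:6, 1))
    f <- sample(vocab, sample(1:6, 1))
    dp <- sample(1:4, length(p), replace = TRUE)
    df <- sample(1:4, length(f), replace = TRUE)
    vals <- c(sim_coverage(p, f), sim_length_norm(p, f),
              sim_dependency(p, f, dp, df),
              sim_description(p, f, sample(0:20, 1), sample(0:10, 1)))
    expect_true(all(is.finite(vals)))
    expect_true(all(vals >= 0))
  }
})

test_that("degree of association equals an independently computed weighted sum", {
  ix <- worked_example_index()
  cfg <- annotator_config()  # alpha = beta = 3, gamma = delta = 0, theta = 0.38
  terms <- c("extracellular", "space")
  dl <- dependency_levels(terms)
  iri <- "http://purl.obolibrary.org/obo/FMA_70022"
  got <- degree_of_association(terms, dl, iri, ix$tfi, cfg)
  cl <- get(iri, envir = ix$tfi$classes)
  by_hand <- function(rec) sim_dependency(terms, rec$terms, dl, rec$dl, cfg$k1, cfg$k2)
  stats <- description_stats(ix$tfi, iri)
  expected <- cfg$alpha * by_hand(cl$preferred_label) +
    cfg$beta * max(vapply(cl$synonyms, by_hand, numeric(1))) +
    cfg$gamma * by_hand(cl$definition) +
    cfg$delta * max(vapply(cl$parent_labels, by_hand, numeric(1))) +
    cfg$theta * sim_description(terms, stats$terms, stats$te_a, stats$te_o)
  expect_equal(got$score, expected, tolerance = 1e-9)
})

test_that("degenerate multiplier configurations reduce as expected", {
  ix <- worked_example_index()
  terms <- "potassium"
  dl <- 1L
  iri <- "http://purl.obolibrary.org/obo/CHEBI_29103"
  zero <- annotator_config(alpha = 0, beta = 0, gamma = 0, delta = 0, theta = 0, tau = 0)
  expect_equal(degree_of_association(terms, dl, iri, ix$tfi, zero)$score, 0.0)
  only_pl <- annotator_config(alpha = 1, beta = 0, gamma = 0, delta = 0, theta = 0, tau = 0)
  got <- degree_of_association(terms, dl, iri, ix$tfi, only_pl)
  cl <- get(iri, envir = ix$tfi$classes)
  expect_equal(got$score,
               sim_dependency(terms, cl$preferred_label$terms, dl,
                              cl$preferred_label$dl),
               tolerance = 1e-9)
})
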