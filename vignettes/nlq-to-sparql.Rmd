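---
title: "From natural-language queries to ranked SPARQL over composite model annotations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From natural-language queries to ranked SPARQL over composite model annotations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nlqsparql)
```

## The problem

Biosimulation model repositories (the Physiome Model Repository, BioModels)
annotate model entities — variables, components, species — with *composite*
RDF annotations: the entity is the root of a small tree whose leaves are
ontology-class IRIs (OPB, FMA, ChEBI, GO, ...) and literal descriptions,
connected through chains of predicates. A query such as *"concentration of
potassium in extracellular space"* corresponds to an entity annotated with a
physics property (a concentration), a chemical (potassium) and an anatomical
location (the extracellular space) — three leaves reached by different
predicate paths. Writing the SPARQL for that by hand requires knowing both
the class IRIs and the tree shape. This package automates the translation:
it grounds query phrases to ontology classes, checks which class
combinations actually occur as annotation patterns in the indexed
repository, compiles each pattern into SPARQL and ranks the results.

## The association model

Candidate phrases are compared with five textual features of each ontology
class: the preferred label (`pl`), synonyms (`syn`), the definition (`def`),
parent labels (`par`) and the pooled description text of the entities the
class annotates (`desc`). For a phrase $P$ and a dictionary feature $F$
(both multisets of normalized terms), the similarity ladder is:

1. **Coverage**: $S(P,F) = |P \cap F| / |F|$.
2. **Length-normalized**: $S(P,F) = \sum_{t \in P \cap F}
   1 / (|F| + \ln\max(1, |P| - |F|))$. The log damps long phrases that
   trivially cover a short feature, and the measure reduces exactly to
   coverage whenever $|P| \le |F|$ — so "extracellular space" and the whole
   six-term query no longer tie against the two-term label
   "extracellular space".
3. **Dependency-weighted** (the default): each shared term is weighted by
   how central it is in the phrase's and the feature's dependency trees.
   With the *dependency level* $dl$ defined as node depth plus one (the head
   has level 1),
   $$S(P,F) = \sum_{t \in P\cap F}
   \frac{\ln\max(k_1,\ |F| + k_1 - \max(dl_{tp}, dl_{tf}))}
        {\left(1 + \frac{\ln\max(1,|P|-|F|)}{|F|}\right)\,\ln((|F|+k_2)!)}$$
   with $k_1 = 2$, $k_2 = 1$. Heads contribute more than modifiers; terms
   deeper than $|F| + k_1 - k_1$ still contribute a floor amount. The
   normalizer is calibrated so that an exact match whose dependency levels
   form a chain $1, 2, \dots, |F|$ scores exactly 1 — a property the test
   suite asserts.

The description feature uses its own smoothing because descriptions are much
longer than labels. With $te_a$ the total number of description terms
appearing with the class and $te_o$ the number of entities it annotates,
$$S_{desc}(P) = \sum_{t \in P \cap desc}
\frac{1 + \ln(1 + te_o)}{(1 + \ln|P|)(1 + \ln(1 + te_a))}.$$
The reuse factor $(1+\ln(1+te_o))$ *multiplies*: classes used to annotate
many entities are more important. The typeset form of this measure is also
readable with the reuse factor dividing; that alternative is available via
`annotator_config(desc_teo_denominator = TRUE)` but is not the default,
because a reuse *penalty* contradicts the measure's stated motivation.

The degree of association is the weighted sum
$$S = \alpha S(P,pl) + \beta S(P,syn) + \gamma S(P,def) + \delta S(P,par) + \theta S_{desc},$$
with defaults $\alpha = 3.0$, $\beta = 3.0$, $\gamma = 0$, $\delta = 0$,
$\theta = 0.38$ — the configuration reported to perform best at repository
scale. When a class has several synonyms or parents, each record is scored
separately and the maximum per feature kind is taken: summing would reward
synonym *count* rather than match quality.

**WPL.** Many classes lack synonyms, definitions or parents, which
systematically lowers their scores. With `wpl = TRUE` (default) every
non-preferred feature is prefixed with the preferred-label terms at index
build time, and absent features become copies of the preferred label.

**Threshold.** Associations below `tau` are dropped. Since every
per-feature similarity equals 1 for an exact match, the theoretical
per-feature maximum contribution is the largest multiplier; the default
`tau = 0.5 * max(alpha, beta, gamma, delta, theta)` (1.5 under the default
multipliers) is half of that. It is deliberately permissive: the final
phrase selection, not the threshold, does most of the discrimination.

## Chunking, dependency levels and the parser abstraction

Production deployments of this kind of system lean on external NLP stacks
(constituency parsers, biomedical NER models). Those are abstracted behind
a `parser_adapter` — three deterministic callbacks (`chunk`, `deps`, `ner`)
— so any backend can be registered with `register_parser_adapter()`. The
built-in adapter is dependency-free and deterministic:

* **Chunker**: candidate phrases are the full query, each prefix ending
  before a function word, each contiguous content-term group, and each group
  head. On "concentration of potassium in extracellular space" this yields
  the six candidates from the full query down to the bare head "space".
* **Dependency heuristic**: content terms are grouped at function words;
  the first group's head is the root (level 1), later group heads attach to
  it (level 2), modifiers chain onto their group head, and function words
  attach below the head of the following group. This reproduces the levels
  a universal-dependencies parse assigns to prepositional noun phrases,
  e.g. `[1, 3, 2]` for "concentration of potassium".
* **Mock NER**: a fixed gazetteer over the synthetic vocabulary, so the
  NER-driven code paths (entity-typed candidates, context phrases,
  predicate associations) are exercised in tests without model downloads.

In NER mode, each entity span additionally produces a *context phrase*: its
smallest enclosing chunk with the span text replaced by the entity-type
label ("concentration of simple chemical"). A context phrase whose best
class association beats its best predicate association joins the phrase set
as an additional class-bearing phrase; otherwise its predicate associations
feed the SPARQL ranking. Context phrases do not compete in the overlap
selection — they add classes, they never displace the span they came from.

## Final phrase selection

Among candidate phrases that kept at least one association, the final set
must be non-overlapping. Selection maximizes, lexicographically: the summed
best association score, then the number of query tokens covered, then fewer
phrases, with remaining ties broken by earliest span start. Score comes
first deliberately. A coverage-first objective always prefers the full
query (or any long prefix) as soon as it clears the threshold, because a
longer span covers more tokens — yet a long phrase matching a short label is
exactly the dilution the similarity ladder exists to penalize. Under the
score-first objective the running example resolves to "concentration" +
"potassium" + "extracellular space" with no threshold tuning. The selection
is solved by dynamic programming over token positions; the test suite
verifies it against exhaustive subset enumeration.

## Composition and ranking

Every choice of one class per final phrase is a candidate combination (full
Cartesian product, capped at `max_combinations = 64`, pruning lowest total
score first). A combination is *viable* when the RDF Graph Index knows at
least one root annotated with all its classes. Each viable combination
expands into annotation patterns — one per distinct choice of predicate path
per class realized by at least one root — and each pattern compiles into one
SPARQL `SELECT DISTINCT ?entity` query with a basic graph pattern chain per
class (`?v0, ?v1, ...` in deterministic order, class IRIs bound exactly).
Queries are ranked by the sum of their combination's association scores,
plus, in NER mode, the association score of each distinct predicate matched
by a predicate association; ties break lexicographically on the query text
so output is byte-stable. `retrieve_entities()` answers the same question
straight from the index without SPARQL — identical results over the indexed
corpus, but blind to documents added after the index was built.

## Numerical and degenerate-input choices

* All term comparisons use set semantics; a term occurring twice in a
  feature contributes through its most central (minimum-level) occurrence.
* `sim_*` functions reject `|F| = 0`; absent features contribute 0 through
  the max-over-records rule instead.
* An empty query is an error; a query with no association above `tau`
  yields an empty (but valid) result everywhere downstream.
* The SPARQL executor drops bindings that are blank nodes: a chain pattern
  can anchor its head at an interior blank, but model entities are
  addressable IRIs.
* Index persistence is content-addressed JSON (`tfi-<md5>.json`,
  `rgi-<md5>.json`); loading verifies the hash, so a rebuilt index never
  silently shadows a stale one.

## What the synthetic fixtures emulate — and what they do not

The generators reproduce the *shape* of repository corpora: entities carry
1–3 ontology-class leaves (composite annotations rarely use more), class
leaves sit 1–3 predicates below the root with blank interior nodes, every
entity has a literal description, and a configurable fraction of classes
lack synonyms/definitions/parents (exercising the WPL path). Two modelling
choices matter:

* **Labels contain no function words.** Planted phrases are joined with
  connectives ("of", "in"), and the chunker segments at function words; a
  label containing a preposition could not be planted cleanly.
* **Labels form an antichain under term-set inclusion.** If one label nests
  inside another ("volume" inside "volume oxygen"), the dependency-weighted
  similarity scores both classes identically on the shared term — the
  equations are calibrated so single-term features are insensitive to
  dependency level — and no implementation faithful to them could recover
  the planted class with certainty. The perfect-recovery property is only
  well-posed on an antichain, so the generator enforces one. Real
  dictionaries *do* contain nested labels; on them, ranking among the tied
  classes falls to synonyms and description statistics, and perfect
  precision is not expected.

Fixtures say nothing about real BioPortal dictionaries (four orders of
magnitude larger), real parsers, or real query logs; passing tests
demonstrate correctness of the machinery, not retrieval quality on
repository-scale data. Reproducing the published repository-scale
benchmarks would additionally require the external dictionary exports, a
repository snapshot and external parser models, all network-dependent and
out of scope here.

## Problem sizes

The test suite uses corpora of 12–20 classes and 6–12 entities across 20
seeds per oracle suite; the acceptance script uses 40 classes, 20 entities
and 20 planted queries with a 13-point threshold sweep. These sizes keep
every oracle comparison exhaustive (brute-force feature scans, tree
traversals, subset enumeration) while exercising all code paths.

## A worked run

```{r}
wx <- worked_example_fixture()
trees <- parse_annotations(wx$document)
rgi <- build_rgi(trees)
inputs <- entity_inputs_from_rgi(rgi)
tfi <- build_tfi(wx$classes, inputs$annotations, inputs$descriptions)
res <- nlq_to_sparql(wx$query, tfi, rgi)
res$annotation
cat(res$queries[[1]]$sparql)
res$entities
```

## Known limitations

* The built-in chunker and dependency heuristic target prepositional noun
  phrases; clause-level queries ("give me models containing ...") need an
  external parser adapter, or stop-word configuration to suppress the
  non-biological phrases.
* No lexical semantics: "K+" and "potassium" only meet if a dictionary
  synonym links them.
* Ranking is per query, not per returned entity; all entities retrieved by
  one SPARQL query share its rank.
* The Turtle reader covers the subset this package and standard serializers
  emit for such annotation documents, not the full grammar.
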