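# nlqsparql

Natural-language search over the RDF composite annotations of biosimulation
model repositories.

Model entities in repositories like the Physiome Model Repository and
BioModels are annotated as small RDF trees: the entity is the root, the
leaves are ontology-class IRIs (OPB, FMA, ChEBI, GO, ...) and literal
descriptions, and chains of predicates connect them. Finding "the
concentration of potassium in the extracellular space" therefore means
knowing three class IRIs *and* the tree shape — which is exactly what makes
hand-written SPARQL impractical for most users. `nlqsparql` translates the
free-text query into ranked SPARQL instead. It is aimed at maintainers of
model repositories and tool builders who want a search box over
RDF-annotated models, and at anyone studying ontology grounding of short
noun-phrase queries.

## The method in brief

Two indexes are built offline:

- **TFI (Text Feature Index)** — an inverted index from terms to
  `(class, feature, dependency level, |F|)` postings over the dictionary
  features of each ontology class: preferred label, synonyms, definition,
  parent labels, plus the pooled description text of the entities a class
  annotates.
- **RGI (RDF Graph Index)** — `class → entity roots` and
  `(class, root) → predicate paths`, i.e. every annotation pattern present
  in the indexed repository.

At query time the text is chunked into candidate phrases; each phrase *P*
is scored against each shortlisted class by a weighted sum over features

    S = α·S(P,pl) + β·S(P,syn) + γ·S(P,def) + δ·S(P,par) + θ·S_desc(P)

where the per-feature similarity weights each shared term by its dependency
level (head terms count more than modifiers) and penalizes phrases much
longer than the feature; defaults are α = β = 3.0, γ = δ = 0, θ = 0.38.
Associations below a threshold τ are dropped, a non-overlapping final
phrase set is selected, and every choice of one class per phrase that
matches a real annotation pattern in the RGI is compiled into a SPARQL
`SELECT DISTINCT ?entity` query and ranked by its summed association score.
The same answer is also available straight from the index without SPARQL
(`retrieve_entities()`).

## Worked example

```r
library(nlqsparql)

wx <- worked_example_fixture()          # 6-class dictionary + one annotated entity
trees <- parse_annotations(wx$document) # RDF/XML -> annotation trees
rgi <- build_rgi(trees)
inputs <- entity_inputs_from_rgi(rgi)
tfi <- build_tfi(wx$classes, inputs$annotations, inputs$descriptions)

res <- nlq_to_sparql(wx$query, tfi, rgi)
res$annotation
```

```
Query: "concentration of potassium in extracellular space"
6 candidate phrase(s), 13 association(s) >= tau=1.5
Final phrases:
  "concentration" -> http://purl.obolibrary.org/obo/OPB_00340 (S=2.826)
  "potassium" -> http://purl.obolibrary.org/obo/CHEBI_29103 (S=4.369)
  "extracellular space" -> http://purl.obolibrary.org/obo/FMA_70022 (S=4.690)
```

The query was chunked into six candidates; the selection kept the three
non-overlapping phrases with the highest summed association scores and
grounded them to a physics property (concentration), a chemical (potassium)
and an anatomical location (extracellular space). Their combination matches
one annotation pattern in the repository, which compiles to:

```r
cat(res$queries[[1]]$sparql)
```

```
SELECT DISTINCT ?entity
WHERE {
  ?entity <http://biomodels.net/biology-qualifiers/isVersionOf> <http://purl.obolibrary.org/obo/OPB_00340> .
  ?entity <http://biomodels.net/biology-qualifiers/isPropertyOf> ?v0 .
  ?v0 <http://biomodels.net/biology-qualifiers/is> <http://purl.obolibrary.org/obo/CHEBI_29103> .
  ?entity <http://biomodels.net/biology-qualifiers/isPropertyOf> ?v1 .
  ?v1 <http://biomodels.net/biology-qualifiers/occursIn> <http://purl.obolibrary.org/obo/FMA_70022> .
}
```

```r
res$entities
#> [1] "http://models.example.org/potassium_model#K_e"
```

Executing the query (with `execute_sparql()` or any SPARQL engine) returns
the same single entity the index retrieval reports: the potassium
concentration variable `#K_e`.

## Command line

```sh
inst/cli/nlq2sparql fixtures --out demo --seed 1
inst/cli/nlq2sparql index build --ontology demo/ontology.tsv --rdf demo/repository.rdf --out demo/index
inst/cli/nlq2sparql query "lactate in creatinine" --index demo/index --format sparql
```

(`demo/queries.tsv` lists the generated ground-truth queries;
"lactate in creatinine" is the first one for seed 1.)

`--config <yaml>` accepts the annotator parameters
(`alpha beta gamma delta theta k1 k2 tau wpl dep parser ...`).

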