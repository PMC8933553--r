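# trialgraph

Build a heterogeneous knowledge graph from the relational tables of a
clinical-trial registry, and use translational embeddings of that graph for
similarity retrieval and drug-repurposing candidate ranking.

Registries such as ClinicalTrials.gov (distributed relationally through the
AACT database) describe each trial across dozens of tables: interventions,
conditions, reported adverse events, participant groups, withdrawal records,
outcome measures, outcome analyses. That layout is made for lookup, not for
inference. `trialgraph` turns a registry export into a typed knowledge graph
with **18 node types and 21 relation types** — studies, conditions, drug
terms, event/baseline/drop/outcome groups, adverse events and their organ
systems, statistical methods, outcome measurements and analyses, standard
outcome measures, and outcome-title clusters — so that relations across
trials ("which drugs were studied for which conditions, with which adverse
events") become first-class, computable objects.

The scientific core is a set of deterministic normalizers that collapse the
registry's many surface forms of one medical entity into one node:

- **Study filter** — keep studies with drug interventions, conditions and
  outcome analyses, excluding in three fixed stages with per-stage counts.
- **Adverse-event cascade** — a term is looked up in a leveled dictionary
  (a stand-in for a MedDRA-style terminology) directly, then after stripping
  parentheticals, removing auxiliary/time-frame phrases ("left", "Baseline
  Phase", "for 12 hours"), stop-word removal + lemmatization, and finally an
  edit-distance rescue (Levenshtein ≤ 3) that fixes misspellings such as
  *Cholecyctitis* → *Cholecystitis*; matched level-1 terms roll up to their
  level-2 parent (*Eye itching*, *Ocular itching* → *itchy eyes*).
- **Drug-mention normalization** — dictionary tagging of intervention names
  and group titles/descriptions (longest match, word boundaries), tree-code
  class filtering (`D…` codes minus non-specific classes), and
  canonicalization brand → generic → vocabulary term (*cozaar* →
  *losartan*), with investigational identifiers kept as their own terms.
  Per study, drugs tied to an arm become `StudiedDrug` edges; drugs
  mentioned only in free text (e.g. as-needed pain reducers) become
  `UsedDrug` edges.
- **Method canonicalization** — statistical-method names are squashed to
  lowercase alphanumerics, merged by single-linkage components under edit
  distance ≤ 3 (*paired t test* / *paired t-tests* / *paited t-test*), then
  merged across word orderings (*pairedttest* = *ttestpaired*), keeping the
  highest-frequency raw name as canonical.
- **Outcome extraction and clustering** — Schwartz–Hearst abbreviation
  mining pairs parenthesized short forms with their definitions
  (*Bleeding Index (BI)*); definitions containing one of eleven keywords
  (scale, index, score, …) become standard-outcome nodes linked to every
  outcome whose text contains them; all outcome titles are TF-IDF embedded
  and partitioned by repeated-bisection spherical clustering, each cluster
  summarized by 5 descriptive and 5 discriminating words with contribution
  percentages.
- **TransE embeddings** — each node and relation gets a vector with
  `v_head + v_relation ≈ v_tail` for observed triples, trained by margin
  ranking loss against type-respecting uniform corruptions. Cosine
  similarities over the embeddings drive retrieval; condition–drug pairs
  that are similar but never co-studied are repurposing candidates.

A seeded synthetic-fixture generator emulates all inputs (tables,
dictionary, lexicon) with known ground truth, so the whole pipeline is
testable offline.

## Worked example

```r
library(trialgraph)

fx <- generate_fixture(fixture_config(n_studies = 12, seed = 42))
fo <- filter_studies(fx$tables)
fo
#> <filter_outcome> 12 studies in; excluded 4 (no drug intervention),
#>   2 (no outcome analysis), 1 (no condition); kept 5

kg <- assemble(fx$tables, fx$dict, fx$lexicon,
               assemble_config(clusters = 3, seed = 42))
kg
#> <trial_kg> 217 nodes (18 types), 361 edges (21 relations)
validate_graph(kg)
#> Empty data.table (0 rows and 4 cols): rule,where,id,message

normalize_ae("Throat tightness - Baseline Phase", fx$dict)[
  c("normalized_term", "matched", "stage")]
#> $normalized_term: "throat tightness"   $matched: TRUE   $stage: 2
```

The filter report shows the three-stage exclusion accounting (kept +
excluded sums to the input); the empty validation table means every schema
invariant (referential integrity, one-study-per-group cardinality, one
organ per adverse event, …) holds; the cascade result says the term matched
the dictionary at stage 2, after auxiliary-phrase removal.

Embedding analysis on the same graph:

```r
emb <- train_transe(kg, train_config(dim = 16, epochs = 40, seed = 42))
res <- topk_similar(emb, kg, "Condition", "DrugTerm", k = 3)
res$pairs
#>                    id_a                id_b    cosine
#> 1: condition:dermatitis drugterm:vinostatin 0.5362234
#> 2:    condition:obesity    drugterm:makimab 0.5181362
#> 3:  condition:psoriasis drugterm:vinostatin 0.3713403
res$mean_similarity
#> -0.020

repurposing_candidates(emb, kg, k = 3)
#>              condition                drug    cosine
#> 1: condition:psoriasis drugterm:vinostatin 0.3713403
#> 2:   condition:obesity  drugterm:nepamicin 0.3662541
#> 3:  condition:migraine  drugterm:raveazole 0.1767204
```

The top similarity pairs sit far above the mean condition–drug similarity
(−0.020); the repurposing ranking drops the (dermatitis, vinostatin) and
(obesity, makimab) pairs because those condition/drug pairs already share a
study, and promotes similar-but-never-co-studied pairs instead.

A thin command-line front end at `inst/cli/trialgraph` chains the stages
(`synth`, `build`, `validate`, `stats`, `embed`, `retrieve`, `repurpose`,
`normalize-ae`, `normalize-methods`, `cluster-outcomes`).

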