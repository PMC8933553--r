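---
title: "Building and embedding clinical-trial knowledge graphs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building and embedding clinical-trial knowledge graphs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trialgraph)
```

`trialgraph` converts AACT-style relational exports of a clinical-trial
registry into a typed knowledge graph and trains translational embeddings on
it. This vignette documents the model, the normalization procedures, the
parameters that matter, the numerical choices, and what the synthetic
fixtures do and do not demonstrate.

## The graph model

The schema declares 18 node types and 21 relation types. Studies are the
hubs: they link to shared `Condition` nodes, to `DrugTerm` nodes via
`StudiedDrug`/`UsedDrug`, to study-local `Outcome` nodes, and to four kinds
of group nodes (event, baseline, drop, outcome), each representing the same
participant arm under a different reporting lens — registries cannot merge
them into one group object, and neither do we. Chains hang off the groups:
event groups to adverse events to organ systems, drop groups to periods to
withdrawal records, outcome groups to measurements and analyses, analyses to
canonicalized statistical methods; outcomes additionally link to
standard-outcome measures and to one title cluster.

Each relation endpoint carries a cardinality class (`one`, `at_most_one`,
`many`) derived from the published per-relation unique-node counts: where
the edge count equals the node count of an endpoint type the relation is
`one` (every event group belongs to exactly one study); where fewer nodes
participate than exist, it is `at_most_one` (an outcome analysis names at
most one method, an outcome joins at most one cluster). Treating the
"fewer participants than nodes" relations as optional rather than mandatory
is a deliberate reading — the source statistics imply it but do not state
it. `validate_graph()` enforces referential integrity, endpoint types,
owning-study attributes on study-specific types, and these cardinality
classes; violations are reported as data, never raised, so a partially
broken graph can be inspected.

Node ids are prefixed with their type (`study:NCT…`, `drugterm:losartan`)
because registry identifiers are only unique within tables. All attribute
values are stored as text: registry exports mix numeric, categorical and
free text in the same columns, and a text store with typed interpretation
left to consumers round-trips losslessly. Export uses one TSV per node type
and per relation type, in the dialect (doubled quotes) that survives
embedded delimiters, quotes and newlines; empty strings are normalized to
missing on insertion so the round trip is exact.

## The study filter

Studies are kept only if they have a drug intervention, at least one
outcome-analysis row, and at least one condition, excluded in that fixed
order with per-stage counts. The order matters for the counts (a study
missing everything is counted at the first stage it fails) and is part of
the contract; the kept set itself is order-invariant. "Has outcome
analyses" is read strictly as analysis rows, not outcome rows — the stricter
of the two readings, matching the stage's name.

## Adverse-event normalization

A term is matched against a leveled term hierarchy (term, level 1–5,
parent), case-insensitively, through a five-stage cascade that stops at the
first hit: direct lookup; after removing balanced parenthesized spans; after
removing auxiliary words/phrases and time frames; after stop-word removal
and lemmatization; and finally by mapping to the nearest dictionary term at
Levenshtein distance ≤ 3 ("less than 4" read literally), ties broken by
distance then lexicographic order. Stages are cumulative — each operates on
the previous stage's output.

Decisions worth recording:

- *Nesting*: parenthesis stripping removes outermost balanced spans
  (nested content goes with its enclosing span); unbalanced parentheses are
  left untouched. The source procedure does not address nesting; this is
  the reading under which stripping is idempotent.
- *Stage 3 comparison*: after lemmatization the term is compared both
  directly against the dictionary and against a pre-computed simplified
  index of the dictionary (`simplify(term) == simplify(entry)`). A
  dictionary stores surface forms, so a literal "is the lemmatized string a
  dictionary term" test would almost never fire; the simplified index makes
  stage 3 meaningful while still returning a genuine dictionary term.
- *Stage 4 search* is exhaustive over the dictionary with a
  length-difference prefilter (a pair differing by more than 3 characters
  in length cannot be within distance 3).
- *Auxiliary phrases* are a packaged, extensible resource seeded with
  laterality/phase markers and wildcard time-frame patterns
  (`for <number> <time-unit>`); the stop-word list and lemma table are
  likewise pinned plain-text resources, because determinism matters more
  here than linguistic coverage. The lemmatizer is a lookup table plus a
  conservative plural rule (never touching words ending in
  -ss/-us/-is) — no statistical NLP.

Matched level-1 terms are rolled up to their level-2 parent so that one
adverse event maps to one node. When one term is reported under different
organ systems, the node keeps the majority organ (ties lexicographic): the
schema demands exactly one organ per event and the sources are silent on
conflicts. Unmatched terms become nodes under their fully processed surface
form, with the matched flag and stage recorded as node attributes — an open
stand-in dictionary has no licensing reason to hide them.

## Drug mentions

Tagging is deterministic dictionary matching: case-insensitive, word
boundaries at any non-alphanumeric character (so "tramadol/diclofenac"
yields both drugs), longest match first, left to right, non-overlapping.
This replaces an external entity-tagging service; a curation-override file
(surface → canonical) plays the role of the manual pass such services
require anyway. Canonicalization resolves abbreviation → full name →
lexicon canonical → generic name → the surface itself, the last rule
keeping investigational identifiers as their own terms. Tree-code filtering
accepts codes whose first segment starts with "D" and rejects the
non-specific classes (pharmaceutical preparations, drug combinations,
dosage forms, biomarkers) by dotted-prefix descent.

The studied/used split is an explicit rule: a drug tied to an arm — via an
intervention record or a group *title* — is studied; a drug appearing for
the study only in group *descriptions* is merely used. The two edge sets
are disjoint per study and studied wins, the natural reading of "studied in
at least one study group" when a drug appears in both roles.

## Statistical-method names

Names are squashed (lowercase, punctuation and whitespace removed), then
merged by **single-linkage connected components** under edit distance ≤ 3.
Single linkage is the minimal closure of the stated pairwise rule; it means
a chain a–b–c merges even when a and c are distance 6 apart, which is the
flagged interpretation here. The canonical of a component is its
highest-total-count raw member (ties lexicographic). A final step merges
components whose canonical names contain the same words in any order
(token multisets over the raw names — squashed forms have no word
boundaries left). The curation-override hook applies last. The mapping is
total, input-order invariant, and stable (canonicals map to themselves).

## Outcome measures

Abbreviation mining follows the Schwartz–Hearst candidate rules: a
parenthesized short form of at most 2 words and 10 characters, containing a
letter and starting alphanumerically, is matched right-to-left against at
most `min(|A| + 5, 2|A|)` preceding words so that every short-form character
occurs in order and the first character starts a word. Definitions
containing one of the eleven marker keywords (scale, index, score, test,
questionnaire, value, count, inventory, assessment, level, rate) become
standard-outcome candidates; keyword matching is whole-word with any
non-alphanumeric boundary, so "level-dependent" contains "level" — the
hyphenation question is resolved in favour of matching. Variants fold
through an override map, manual additions join the set, and outcomes link
to every standard whose text they contain (case-insensitive substring).

Outcome titles are clustered from unit-norm TF-IDF vectors (smoothed IDF
`log((1+N)/(1+df)) + 1`; lowercase, punctuation-split tokens minus stop
words) by repeated bisection: the largest cluster is split by spherical
2-means (5 seeded restarts, 25 iterations, cosine assignment), keeping the
bisection that maximizes the criterion `sum over clusters of
||composite vector||` — the documented default criterion of the classic
clustering toolkit this replaces, which is closed-source. Per cluster, the
descriptive percentage of a word is its share of the squared centroid
(`100 · c_w² / Σc²`) and the discriminating percentage its share of the
squared centroid difference against the complement
(`100 · (c_w − o_w)² / Σ(c − o)²`); the toolkit defers these formulas to
its manual, so they are defined here explicitly. Degenerate bisections
(all-identical vectors) peel off a single element so the requested cluster
count is always reached; `k` defaults to min(200, number of titles) — 200
matching the released graph, the cap because synthetic corpora are smaller.

## Embeddings

TransE: each node and relation receives a `dim`-vector; the score of a
triple is `−‖v_h + v_r − v_t‖` (L1 or L2). Training minimizes the margin
ranking loss over observed triples against corruptions by mini-batch SGD,
with entity vectors renormalized to unit norm after each epoch. Negative
sampling corrupts head or tail with equal probability **uniformly over
nodes of the type the schema permits in that slot** — stricter than vanilla
TransE's all-entity corruption, and the right choice on a strongly typed
graph where cross-type corruptions are trivially implausible. Defaults
(dim 200, margin 1, L2, learning rate 0.01, 200 epochs, one negative per
positive) are standard desk-scale library defaults; the sources state none.
All sampling is driven by one seed, making training bit-reproducible.

Retrieval is exact top-k cosine between two node types, reported together
with the mean pairwise similarity between the types — the baseline against
which "high" similarity is judged. Repurposing candidates are
condition/drug pairs ranked by cosine after excluding any pair connected
through a shared study (condition and drug both linked to the same study
node). The exclusion is deliberately study-mediated rather than
direct-edge-based: the graph has no direct condition–drug relation, and
"not studied together in any study" is the property that makes a pair a
candidate.

## The synthetic fixtures

`generate_fixture()` emulates the registry inputs end to end: studies with
planted stage-wise incompleteness driving the filter counts; adverse-event
terms wrapped as parentheticals, auxiliary phrases, stop-word/inflection
variants, or misspellings within edit distance 3 (each verified at
generation time to resolve uniquely back to its planted term, with
unmatchable gibberish planted at a configurable rate); drug mentions as
brand, generic or abbreviated surfaces; method-name variants with the base
spelling dominant so frequency-based canonical selection is well defined;
outcome titles drawn from disjoint topic vocabularies with embedded
"(ABBR)" definitions; and a planted similarity motif — two conditions
studied together in six studies with a shared drug pair, plus a third drug
studied only with the second condition, giving a held-out repurposing pair
that is never co-studied with the first condition.

What the fixtures do **not** emulate: the skewed term-frequency and
vocabulary-size distributions of real registry text, partial or inconsistent
reporting, cross-table noise, or any statistical structure of trial results.
Passing tests therefore demonstrate correctness of the procedures under
their stated assumptions (variants within the cascade's reach, separable
topics, clean referential structure), not performance on real registry
data, where dictionary coverage and free-text noise dominate.

Problem sizes used by the test and acceptance runs are the package's own
choices for a desk-scale demonstration: 500-variant recovery fixtures,
1,000 generated titles for the abbreviation invariant, a ~30-study /
~200-node graph with 16-dimensional embeddings trained for 40 epochs for
the ranking and structure-recovery checks, and exhaustive-plus-sampled
string pairs (all pairs to length 3, seeded samples to length 6) for the
edit-distance oracle comparison.

## Known limitations

- The cascade's stage-4 rescue can mis-map a term that is a genuine new
  concept within distance 3 of a dictionary term; on real vocabularies the
  curation-override file is the guard.
- Single-linkage method merging can chain distinct tests with very short
  squashed names; the override hook exists for exactly the documented
  manual-check reason.
- A drug mentioned in an intervention and as an auxiliary in the same study
  is classified studied (disjointness by precedence); the sources do not
  address the conflict.
- Embedding quality metrics (hits@k, similarity margins) on synthetic
  graphs say nothing quantitative about the released full-scale graph;
  similarity values depend on graph size, hyperparameters and
  initialization.
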