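---
title: "Ranking rule-based concept definitions against text: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ranking rule-based concept definitions against text: models, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ontorank)
```

## The problem

A curated knowledge base of rule-based concept definitions — phenotype
criteria encoded as SWRL-style rules over an OWL-style class hierarchy
being the motivating case — has to be kept in step with the literature.
Given a passage of text ("snippet") that defines one or more concepts,
the curator needs the encoded rules ranked by how likely the snippet is
to be talking about them. Three situations arise: the definition is
already encoded (the top-ranked rule should be it); the snippet gives an
alternative criterion for an encoded concept (the concept's other rules
should rank top); or the concept is absent altogether (a structurally
similar rule should rank top, to serve as an authoring template).
`ontorank` implements the ranking machinery, the template signatures,
and an evaluation harness for all three situations. Rules are data
here: nothing is ever executed or reasoned over.

## Models

**Snippets.** A snippet is tokenized (lowercasing; splits at every
non-alphanumeric character and at camel-case boundaries; a pinned,
overridable English stopword list; numeric tokens kept, because
cut-offs such as "24" are the informative content of threshold
definitions) and represented by tf-idf weights
`w[i,d] = tf[i,d] * log10(n / df[i])`. The base-10 logarithm is forced
by the method's own worked arithmetic (a term with tf 2 and df 5 in a
10-snippet corpus weighs 2·log10(2) ≈ 0.6); a term occurring in every
snippet is pruned. Term counts are taken after stopword filtering; the
worked example is insensitive to that choice.

**Rules, term-based.** The baseline vector of a rule holds the raw
occurrence counts of the defined concept's label terms
(`term_source = "head_label"`, the default): *Delayed Words* becomes
`{delayed: 1, words: 1}`. A literal reading — every class and property
predicate of the rule contributing its label terms — is available as
`term_source = "all_labels"`; the default reproduces the canonical
example, which ignores body predicates. Builtin predicates and
constants never contribute terms: they are syntax, not vocabulary.

**Rules, semantic.** The semantic vector additionally folds in the
labels of hierarchy neighbours, weighted by
`Sim(C1, C2) = 2^(-d(C1, C2))` where `d` is the shortest path in the
subclass graph. Contributions landing on the same term are summed —
forced by the worked example in which "words" weighs 1 + 0.5 = 1.5 for
*Delayed Words* under *Status of Age of Words*. Choices the formula
leaves open, and how this package resolves them:

* *Edge orientation.* Subclass links are traversed as undirected edges,
  so ancestors, descendants and collaterals are all "indirectly related
  concepts". The printed example only exercises the parent direction;
  undirected traversal is the reading that makes siblings reachable.
* *Multiple parents.* Hierarchies are DAGs; the distance is the minimum
  over all paths.
* *Hop cut-off.* `max_distance` defaults to 2: under halving, a
  distance-3 concept contributes at most 0.125 per term, which is noise
  against the weight-1 own label. Note that on a full hierarchy
  fragment with siblings whose labels share a term with the target (as
  *Words Not Delayed* and *No Words* share "words"), a cut-off of 2
  lifts that term above the textbook 1.5; the 1.5 value is exact at
  `max_distance = 1`, or at any cut-off when only the parent carries
  the shared term. The package treats the cut-off as an explicit
  parameter rather than hard-coding either reading.
* *Disconnected concepts* get similarity 0, not an error: sparse
  ontologies must still be rankable.
* *Property hierarchy.* Represented, but off by default
  (`include_property_hierarchy`): the only worked example uses the
  class hierarchy, and the original system's treatment of property
  neighbours is not documented. When enabled (with `all_labels`), the
  rule's property predicates are expanded through the property
  hierarchy with the same hop-halving weights.

**Scoring.** Cosine similarity over the union vocabulary. All weights
are nonnegative, so scores live in [0, 1]; empty vectors score 0 by
contract rather than dividing by zero. The denominator is computed as a
single square root of the product of squared norms, which keeps
identical vectors at exactly 1 in floating point. Ranked lists sort by
descending score with ties broken by ascending rule id in the C locale:
reproducible average ranks require a total order. Snippet vectors are
never semantically enriched — hierarchy expansion applies to the
concept side only.

**Signatures.** A rule's syntactic signature pools body and head atoms,
groups them by subject (the first argument; a class atom's sole
argument is its subject), maps each atom to a type code (C class, O
object property, D data property, B builtin), sorts codes within a
group, sorts groups, and parenthesizes: a rule that classifies a
subject and assigns it one data value is `(CD)`. The signature is
invariant under variable renaming and atom reordering; constants and
variables are not distinguished, because templates abstract over
cut-off values. This scheme is a deliberate simplification: the full
signature formalism it abbreviates distinguishes more of the SWRL
surface syntax, but the type-code-with-subject-grouping core is what
the template-matching scenario needs, and a `split_head_body` flag is
available for two-part `body->head` signatures.

## Evaluation protocol

Both methods are always evaluated on the identical key set (paired
design), and the paired ranks are compared with a Wilcoxon signed-rank
test: zero differences dropped, mid-ranks for ties, and — for up to 25
retained pairs — the exact null distribution of the statistic computed
by a generating-function convolution over doubled mid-ranks, which
stays exact in the presence of ties; larger samples use the normal
approximation with tie and continuity corrections. The test is authored
here rather than delegated because the reference implementation
abandons exactness as soon as ties appear, and rank data is almost all
ties. Reports carry both the signed and the absolute mean paired
difference, since "average pairwise difference" is ambiguous between
the two.

* **Scenario 1 (existing).** For each gold (snippet, concept) pair,
  rank all rules and record the best position among the concept's gold
  rules — any encoded alternative counts as correct.
* **Scenario 2 (alternative).** For each gold concept holding at least
  two rules, remove each rule in turn and record where the surviving
  alternatives rank. Removing a rule leaves every other rule's vector
  unchanged (the hierarchy is untouched), so the implementation
  subsets the precomputed vectors; a test verifies equality against a
  naive rebuild per removal.
* **Scenario 3 (template).** For each gold pair, delete the concept
  and all its rules (children keep their other parents; no re-wiring),
  re-vectorize — here the hierarchy *did* change — and record the
  position of the first surviving rule bearing the deleted rules'
  signature. Items whose signature survives nowhere are excluded and
  counted rather than scored at an arbitrary penalty rank, which would
  distort averages.

## The synthetic benchmark

The knowledge base and corpus this method was designed around are not
distributable, so the package generates structurally analogous data.
The generator's default parameters are the package's fixed study
conditions; they encode, at desk scale, the corpus statistics the
method targets: snippets of ~98 ± 42 raw terms (truncated normal,
floor 10), each verbalizing several definitions (1–6, capped by the
drawn length at roughly 18 terms per definition), 1–3 alternative
threshold rules per defined concept, at most five distinct rule
shapes, and a 0.2 probability per definition of name-dropping an
undefined sibling (distractor). A depth-3 hierarchy of 85 concepts is
generated with the label structure of real phenotype ontologies:

* internal category nodes carry fresh two-term labels, but leaf-parent
  categories end in a *measure* word drawn from a small shared
  vocabulary — distinct branches collide on label terms, the way "Age
  of First Words" and "Status of Age of Words" both lean on "age" and
  "words";
* leaf phenotypes are a *modifier* (from a five-word vocabulary reused
  across branches, as "delayed"/"no"/"not delayed" are) plus a term
  shared with the immediate parent (`label_share_prob`, default 1);
* measurement property names echo the branch term, as instrument item
  names do;
* roughly a third of leaves (`defined_fraction = 0.35`) carry rules,
  clustered by sibling group, since curators encode whole categories at
  a time and real rule bases cover a minority of ontology classes;
* each category group is encoded with one of five rule shapes
  (threshold and interval criteria, with or without a minted finding
  individual), so sibling rules share a template.

Snippets mix two definitional styles observed in real articles: a
*grouped* style (one category header, then each defined sibling with
its criterion) and a *scattered* style (a single definition phrased
through its category, restating the surrounding construct). Text is
templated English over pseudo-words, padded with filler vocabulary —
sufficient to exercise the vector models, and stated openly as not
imitating scientific prose.

What passing on this benchmark shows — and does not. The colliding
measure vocabulary makes the term-based baseline genuinely ambiguous
across branches, and the ancestor vocabulary present in definitional
context is exactly what the semantic vectors can exploit; under the
default seed the semantic method's average rank is better in all three
scenarios, mirroring the directional finding the method was built on.
It does not show performance on natural language: there is no
synonymy, no syntax, no negation, and gold annotations are perfect by
construction. The template scenario's margin is the smallest and the
noisiest of the three at this scale, because with five shapes over a
few dozen rules the first bearer of a signature often sits near the
top of either method's list.

All generation is integer-driven under a single seed;
knowledge bases, corpora and reports are byte-identical across runs
and platforms, and the corpus stream is offset from the knowledge-base
stream so the two stages draw independently.

## Numerical and interface choices

* Scores are reported to 6 decimals in artifacts; full precision is
  kept internally.
* Vectors store term weights unnormalized (cosine is scale-invariant,
  so ranking is unaffected); names are sorted so equal vectors are
  byte-identical.
* Degenerate inputs: empty corpora and empty rule bases load without
  error but refuse to rank; unresolved rule references are collected
  and reported at load time, never silently dropped; a cyclic
  hierarchy fails validation with one cycle listed.
* Namespace prefixes (`swrlb:`, `adi-r2003:`) are preserved in stored
  ids but are not a term source — labels are.
* The stemming configuration key is accepted for interface
  completeness but only `FALSE` is implemented; the default pipeline
  is deliberately unstemmed, since the worked examples imply exact
  term matching.
* Turtle import supports a documented subset (prefix declarations,
  `rdfs:subClassOf` and `rdfs:label` triples with `;` lists) — enough
  to seed a hierarchy from common ontology exports; rules always enter
  through the JSON dialect.

## Problem sizes

The shipped tests and the benchmark run at deliberate desk scale: an
85-concept hierarchy with ~50 rules, 18 snippets, ~50 gold items, and
oracle comparisons on instances of up to 30 nodes, 20 rules, or
2^10 sign assignments. These sizes are where the exhaustive oracles
(breadth-first search, brute-force score sorting, full sign-flip
enumeration) remain exact and fast; the algorithms themselves have no
scale-specific shortcuts.

## Known limitations

* Tokenization is whitespace/character-class based; no sentence
  structure, no named-entity recognition, no synonym resolution beyond
  the hierarchy expansion.
* The signature scheme abstracts less than a full SWRL syntactic
  analysis would; structurally distinct rules can share a signature.
* Scenario 2 treats every rule of a multi-rule concept as removable;
  if alternatives were encoded with distinct vocabularies
  (`all_labels` mode), leave-one-out ranks depend on which alternative
  was removed, and the report keys expose that.
* Average ranks depend on rule-base size; they are comparable between
  methods within a run, not across knowledge bases.
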