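# ontorank

Biomedical knowledge bases often define concepts — phenotypes in
particular — as rules: Horn-like statements that turn measurement
cut-offs on standardized instruments into class assertions (for example,
*a child who acquired first words after 24 months on the ADI-R has
Delayed Words*). Curators who maintain such rule bases read papers and
must decide, for each passage of text, whether the definition it
contains is already encoded, is an alternative to an encoded rule, or is
new and should be authored from a structural template. `ontorank` is an
R toolkit for that task: given an ontology class hierarchy, a rule base,
and a snippet of text, it ranks every rule by how likely the snippet is
to define it.

## The method

Snippets are modelled in a standard vector space. The weight of term
*i* in snippet *d* is

    w[i,d] = tf[i,d] * log10(n / df[i])

with `tf` the term count in the snippet, `n` the number of snippets and
`df[i]` the number of snippets containing the term.

Each rule is modelled two ways:

* **term-based** (baseline) — the raw occurrence counts of the defined
  concept's label terms, so the *Delayed Words* rule becomes
  `{delayed: 1, words: 1}`;
* **semantic** — the label terms of every hierarchy neighbour within a
  hop cut-off are folded in, each weighted by the semantic similarity

      Sim(C1, C2) = 2^(-ShortestPath(C1, C2))

  over undirected subclass links, contributions to the same term being
  summed. With *Status of Age of Words* as immediate parent, "words"
  carries weight 1 + 0.5 = 1.5 in the semantic vector of *Delayed
  Words*.

Rules are scored against a snippet by cosine similarity and returned as
a deterministically ordered list. Canonical syntactic signatures —
atom-type codes grouped by shared subject, e.g. `(CD)` for a rule that
classifies a subject and assigns it one data value — support the
new-concept case: structurally identical rules share a signature, and
the first ranked rule bearing the missing concept's signature is the
template offered to the curator.

An evaluation module reruns the three curation scenarios (existing
rule, alternative rule, new concept) on any annotated corpus, reporting
the average rank of the correct answer per method and a paired Wilcoxon
signed-rank test (exact null distribution up to n = 25, ties handled by
mid-ranks). A seeded synthetic generator emulates the statistical
structure of a curated phenotype corpus — multi-definition snippets of
~98 ± 42 terms, 1–3 alternative rules per concept, at most five rule
shapes, sibling distractor mentions — so the whole pipeline is testable
without any external data.

## Worked example

```r
library(ontorank)

kb     <- load_kb(system.file("extdata", "language_kb.json", package = "ontorank"))
corpus <- read_snippets(system.file("extdata", "language_snippets.jsonl",
                                    package = "ontorank"))

semantic_vector("delayed_words", kb, vectorizer_config("semantic", max_distance = 1))
#> <term_vector> 4 terms
#>     age delayed  status   words
#>     0.5     1.0     0.5     1.5

vecs <- vectorize_rulebase(kb, vectorizer_config("semantic"))
rank_rules("snippet2", corpus, vecs, "semantic")
#> <ranked_result> method: semantic — 2 rules
#>  rank              rule_id    score
#>     1 delayed_phrases_rule 0.475812
#>     2   delayed_words_rule 0.475812
```

The semantic vector of *Delayed Words* assigns "words" 1.5 (1 from its
own label, 0.5 from its parent *Status of Age of Words*). The second
packaged snippet defines the words-delay and phrases-delay groups with
perfectly parallel phrasing, so both rules match it with the same
positive score and the tie is broken by rule id; the packaged
background snippets, which define neither concept, score 0 against both
rules.

On the packaged synthetic benchmark (default parameters, seed 42):

```r
b <- generate_benchmark(synth_params())
evaluate_scenario1(b$kb, b$corpus, b$gold)
#> <evaluation_report> scenario: existing — 54 items
#>   average rank   semantic: 4.981   term-based: 5.963
#>   mean paired difference (term - semantic): 0.981  |.|: 0.981
#>   Wilcoxon V = 231  p = 9.537e-07 (exact)
```

Lower is better: the semantic method places the correct rule about one
position higher on average, and the paired test shows the difference is
systematic rather than noise.

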