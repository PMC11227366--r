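# sigcr — signature-based dictionary concept recognition for ontologies

`sigcr` annotates free text with ontology concepts. The motivating use case
is phenotype profiling with the Human Phenotype Ontology (HPO): finding
every span of a clinical note or publication abstract that expresses an HPO
term and linking it to the concept ID, fast enough that a whole corpus can
be re-annotated every time the ontology is updated. It is a dictionary
method — no training, no models — aimed at users who need concept
recognition that can be refreshed against a new ontology release in
minutes: registry curators, variant-prioritization pipelines, literature
annotation services.

## The method

Dictionary approaches founder on lexical variability: *short phalanx of the
thumb*, *shorter phalanges of the thumbs* and *shortening of the phalanx of
the thumb* all denote one concept, and lemmatization does not unify them
(the lemma of *shorter* is *short* but the lemma of *shortening* is
*shorten*). `sigcr` addresses this with three components:

1. **Cluster vocabulary.** A partition of a token vocabulary into clusters
   of morphologically equivalent forms, e.g. `{short, shorter, shorten,
   shortening}`, each with an opaque ID `C<k>`. Clusters may be loaded from
   a plain-text file (one cluster per line) or built deterministically:
   spelling normalization (`ae→e`, `oe→e`, so *haemorrhage* ≡
   *hemorrhage*), grouping by 4-letter prefix, then stem equivalence within
   the group under a pinned, pluggable stemmer.

2. **Signature index.** Every label and synonym of every non-obsolete
   concept is tokenized, stripped of stop words / auxiliary verbs /
   conjunctions, and its tokens replaced by cluster IDs. The surface is
   stored under its *signature*: the de-duplicated cluster IDs sorted
   lexicographically and joined with `-`, paired with the filtered token
   count ℓ. *Increased size of cranium* → `[increased, size, of, cranium]`
   → `[increased, size, cranium]` → `[C2, C26, C35]` → key `C2-C26-C35`,
   ℓ = 3. The token map closes over entire clusters, so a variant never
   seen in any term still resolves.

3. **Linear-time recognizer.** Text tokens are labeled with cluster IDs in
   one pass (one hash lookup per token, O(n) in the token count n). Tokens
   absent from the index leave gaps; the maximal runs between gaps are the
   only candidates considered, so boundary detection collapses into the
   lookup. Each candidate of k tokens is decomposed into all k(k+1)/2
   contiguous windows (covering nested concepts), and each window is
   resolved with a single signature lookup — O(n) in the number of
   candidates. Because signatures are order-free sets, *phalanx shortening*
   retrieves a concept indexed from *short phalanx*.

Evaluation utilities compute precision, recall and F1 = 2PR/(P+R) at
document level (per-document concept-ID sets, boundaries ignored) and
mention level (positioned mentions, exact or overlap span agreement), and
realign gold corpora annotated against older ontology releases by resolving
retired concept IDs through `alt_id`/`replaced_by`.

A synthetic fixture generator ships with the package, so every component is
testable end-to-end with no downloads: it emits a mini-ontology (OBO), a
cluster file, documents with planted mentions (morphological variants,
interleaved stop words, distractor tokens) and the gold annotations.

## Worked example

```r
library(sigcr)

clusters <- tempfile(fileext = ".txt")
writeLines(c("short shorter shorten shortening",
             "phalanx phalanges",
             "increased increase increasing",
             "size sizes sized",
             "cranium craniums"), clusters)
vocab <- load_clusters(clusters)

onto <- tempfile(fileext = ".obo")
writeLines(c("format-version: 1.4", "data-version: demo/2026-01", "",
             "[Term]", "id: HP:0000256", "name: Macrocephaly",
             'synonym: "Increased size of cranium" EXACT []', "",
             "[Term]", "id: HP:0009778", "name: Short phalanx"), onto)
index <- build_index(parse_ontology(onto), vocab)
index
#> <concept_index> 2 signatures, 14 tokens in map (ontology: demo/2026-01, clusterer: file:...)
#>   surfaces indexed: 2, skipped: 1

m <- annotate("Report notes an increased size of the cranium and phalanx shortening.",
              index)
m[, c("start", "end", "surface", "concept_id", "matched_term")]
#>   start end                       surface concept_id              matched_term
#> 1    16  45 increased size of the cranium HP:0000256 Increased size of cranium
#> 2    50  68            phalanx shortening HP:0009778             Short phalanx
```

Two things are worth reading off the output. The first mention matches the
indexed synonym even though the text inserts *the* (stop words are
transparent inside candidates) — the span runs from *increased* to
*cranium* and `surface` is the exact document slice (offsets are 0-based,
end-exclusive). The second matches *Short phalanx* from the reordered,
re-inflected *phalanx shortening*, via the cluster vocabulary and the
order-free signature. The skipped surface is the label *Macrocephaly*,
whose token is not covered by this toy cluster file; `index$skipped`
reports it.

A command-line wrapper with `build-clusters`, `index`, `annotate`,
`evaluate` and `fixtures` subcommands is installed at
`system.file("cli", "sigcr", package = "sigcr")`.

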