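---
title: "Signature-based concept recognition: method, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Signature-based concept recognition: method, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sigcr)
```

# The problem and the model

Concept recognition (CR) against an ontology such as the Human Phenotype
Ontology has two parts: boundary detection (which spans of text are
candidate entities) and entity linking (which concept each span denotes).
Machine-learned taggers solve both jointly but must be retrained whenever
the ontology changes — and phenotype ontologies change monthly, with terms
added, subsumed, and retired. `sigcr` implements the opposite trade-off: a
dictionary method whose entire knowledge of the ontology lives in an index
that can be rebuilt in seconds, so refreshing the concept inventory or
re-annotating an archive is cheap.

The method rests on one modeling assumption: that the lexical variability
of phenotype language is almost entirely *morphological* — inflection,
derivation, word order, and localized spelling — and can therefore be
pre-computed once as a partition of the vocabulary into clusters of
equivalent forms. Under that assumption, a term surface reduces to the
*set* of clusters its informative tokens belong to, plus its filtered
length, and recognition reduces to hash lookups:

* **Indexing.** Each label/synonym is tokenized (split on any
  non-alphanumeric character, lowercased), stop words / auxiliary verbs /
  conjunctions are removed, each remaining token is replaced by its cluster
  ID, and the surface is stored under its signature: the unique cluster IDs
  in lexicographic order joined by `-`, plus the filtered token count. The
  count distinguishes the rare surface in which one cluster occurs twice
  from its de-duplicated look-alike.
* **Recognition.** Every text token is looked up once. Tokens in no indexed
  cluster leave gaps; maximal runs between gaps are the candidates; each
  candidate's contiguous windows are looked up by signature, one hash probe
  per window. Lookup counts are therefore linear in tokens and in windows —
  the package asserts both as counter identities in its tests, not as
  wall-clock claims.

What the signature discards — token order and stop words — is exactly what
the method is robust to; what it keeps — cluster identity and filtered
length — is what separates concepts.

# Tunable parameters

| Parameter | Where | Default | Why |
|---|---|---|---|
| blacklist | `build_index`, index file | shipped `blacklist.txt` (~130 entries: stop words, auxiliary/copular verbs, conjunctions) | The blacklist must be a pinned artifact, or indexes are not reproducible; it is overridable per build. |
| stemmer | `build_clusters` | `suffix_stem`, pinned | See "Design choices". Any `function(character) -> character` may be plugged in; the identity is recorded in vocabulary and index metadata. |
| spelling table | `normalize_spelling` | `ae→e`, `oe→e`, applied to a fixed point | The digraphs medical English actually varies on; the fixed point makes the operation idempotent. |
| `exact_synonyms_only` | `build_index` | `FALSE` | All synonym scopes are indexed by default (broad/related synonyms trade precision for recall); the flag restricts to EXACT. |
| `window_cap` | `annotate` | 10 known tokens | Bounds the quadratic window count on pathological runs. Filtered ontology surfaces are far shorter (HPO labels average ~3 informative tokens), so the cap is never binding on real vocabulary; it only prunes windows that could not match anyway. |
| `policy` | `annotate` | `"all"` | `"all"` returns every matched window, nested matches included — the behaviour observed when scoring against corpora that do not mark nested entities. `"longest"` greedily keeps the longest non-overlapping mentions (ties to the leftmost) for precision-oriented use. |
| `span_policy` | `mention_level` | `"exact"` | Published mention-level scores rarely state their span criterion; both exact and overlap matching are provided, and exact true positives are provably a subset of overlap ones. |
| averaging | `doc_level` | micro | Counts are summed over documents before computing P/R/F1, the convention for document-level CR benchmarks; macro is available behind a flag. |

# Design choices where the design was open

**Stemmer.** The clustering stage needs whole derivational families that
share a 4-letter prefix to collapse: `short / shorter / shorten /
shortening` must form one cluster. Conservative algorithmic stemmers do not
do this (Porter leaves `shorter` unstemmed, and stems `shortening` only to
`shorten`), so the package ships its own deterministic iterative
suffix-stripper: an ordered rule table applied repeatedly, never shrinking
a stem below four characters. Within a prefix group, aggressive stripping
is safe — the 4-letter prefix has already confined the candidates — and it
is exactly as reproducible as a published table. The stemmer is a strategy
argument, so an external clustering (or any other stemmer) can be swapped
in; cluster files built elsewhere are loadable as-is.

**Cluster IDs.** IDs carry no meaning, but they must be *stable*:
`build_clusters` orders clusters lexicographically by smallest member and
numbers them `C1, C2, …`, so identical inputs give identical IDs regardless
of input order; `load_clusters` numbers by line. Signature keys sort with
byte (radix) order, never locale collation, for the same reason.

**Strict partition.** Whether token clusters may overlap is undefined in
principle; the recognizer's single-pass labeling requires a unique cluster
per token, so the partition is enforced — duplicate members across clusters
(also duplicates arising after spelling normalization, since lookup is by
canonical form) are an error, not a warning.

**Blacklist transparency.** Indexed signatures exclude stop words, so text
matching must neither break on them nor count them: inside a candidate,
blacklisted tokens are transparent (*increased size **of the** cranium*
matches a surface indexed without them), but they can never start or end a
mention's token set, and the reported span still covers them when they are
interior. This is the only transparency rule consistent with signatures
computed after filtering.

**Punctuation.** Every non-alphanumeric, non-whitespace run breaks
continuity, hyphens included — the conservative reading of "punctuation
breaks continuity". A compound like *short-stature* therefore yields two
single-token candidates; an ontology whose surfaces rely on hyphenated
compounds would need a custom tokenizer, which the module boundary allows.

**Ambiguity and duplicates.** Two concepts may share a signature (same
cluster set, same length); the index keeps both and the recognizer emits
one mention per concept, flagged `ambiguous`, resolving nothing silently.
The same concept matched at the same span through several windows (e.g. a
window widened only by transparent stop words) is reported once; the same
concept at different spans is distinct mentions.

**Obsolete concepts and alignment.** Obsolete terms are never indexed, but
their identity is not discarded: `align_corpus` resolves a gold annotation
whose ID is some concept's `alt_id`, or an obsolete term's `replaced_by`
target, to the current ID — deterministically, with an error if two
concepts claim one `alt_id`. Orphans (IDs resolvable nowhere) are excluded
from scoring but always reported, so the "no orphan annotations" property
can be *demonstrated* on any corpus rather than assumed. Mention matching
in evaluation is one-to-one greedy in document order, so one prediction
cannot satisfy duplicated gold.

**Metadata.** The index records the ontology version string and the
clusterer identity. It records a build timestamp only when the caller
supplies one: by default rebuilding from identical inputs produces a
byte-identical file, which makes index provenance checkable by hash.

# The synthetic data generator

`generate_fixtures()` emulates the *structure* the method's assumptions
rest on: multi-token terms whose synonyms permute the label's tokens,
morphological variants drawn from a cluster file, stop words interleaved
inside mentions, punctuation and never-indexed distractor tokens between
mentions, and obsolete concepts that donate their ID as an `alt_id` of a
current concept. Concepts draw tokens from disjoint cluster sets and all
surfaces of a concept share one token multiset, so — by construction — no
nested or ambiguous matches exist and the planted ledger is an exact
oracle: precision and recall against it must be 1.0, and the test suite
asserts precisely that, alongside a brute-force window-enumeration oracle
that re-derives every mention independently of the candidate/decomposition
machinery.

What the generator deliberately does **not** emulate: realistic clinical
prose, negation, coordination (*short and broad toes*), non-contiguous
mentions (*dysplastic left kidney*), abbreviation, typos, or
context-dependent senses. Passing the recovery and oracle suites therefore
shows the machinery is exact under the method's assumptions; it says
nothing about recall on real text where those assumptions fail — that is
what the external benchmark corpora measure, and the evaluation module is
the machinery for scoring them once a user supplies corpus, gold file and
cluster vocabulary.

Default generator conditions: 6 concepts of 2–3 tokens, 1–2 permuted
synonyms each, 2–3 morphological variants per token, 4 documents with 2–4
mentions, stop words interleaved at rate 0.25, distractors at rate 0.3,
obsolete fraction 0.2. The property suites run 200 randomized bundles
(≤ 50 surfaces, ≤ 200 tokens per document) against the brute-force oracle
and 100-document corpora for the counter identities — sizes chosen so the
whole suite exercises every code path in well under a minute per property.

# Numerical and degenerate-input choices

* Precision is defined as 0 when nothing is predicted, recall as 0 when
  there is no gold, F1 as 0 when P + R = 0 — reports never contain NaN.
* Empty documents, documents with no candidates, empty cluster queries and
  an empty concept list all produce empty-but-well-formed results; an
  ontology whose every surface is skipped produces a warning, not an error.
* Surfaces that are empty after filtering, or contain tokens with no
  cluster, are skipped and itemized in `index$skipped` — an index build
  never fails on an incomplete vocabulary, it reports its coverage.
* Mention ordering is deterministic: `(start, −length)`; longest-only
  selection breaks ties leftmost; all sorting is radix.

# Known limitations

Bound to the ontology's explicit labels/synonyms and the supplied cluster
vocabulary: unseen synonyms and out-of-vocabulary tokens cannot match
(they become candidate-breaking gaps). No coordination splitting, no
non-contiguous mentions, no negation or context disambiguation — these are
post-processing concerns outside the recognizer's contract. Tokenization
is ASCII-alphanumeric-oriented; ontologies with heavy Unicode or
hyphen-dependent surfaces need a custom tokenizer behind the same module
surface.
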