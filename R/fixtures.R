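#' Specification for a synthetic fixture bundle
#'
#' Describes a self-contained miniature of the data the recognizer consumes:
#' a mini-ontology with multi-token labels and synonyms, a cluster file of
#' morphological variants, documents with planted concept mentions (variant
#' substitution, optional interleaved stop words, distractor tokens,
#' punctuation between mentions), and the gold annotations recording exactly
#' what was planted.
#'
#' @param n_concepts Number of current (non-obsolete) concepts.
#' @param synonyms_per_concept Length-2 integer range of synonyms per
#'   concept (synonyms permute the label's tokens, mirroring order-free
#'   phrasings like `short phalanx` / `phalanx shortening`).
#' @param tokens_per_surface Length-2 integer range of tokens per label.
#' @param morph_variants_per_token Length-2 integer range of morphological
#'   forms per token cluster (the base form included).
#' @param n_docs Number of documents.
#' @param mentions_per_doc Length-2 integer range of planted mentions per
#'   document.
#' @param distractor_token_rate Probability in `[0, 1]` of inserting a
#'   distractor (never-indexed) token at each slot between mentions.
#' @param stopword_rate Probability in `[0, 1]` of interleaving a
#'   blacklisted stop word between two tokens of a planted mention.
#' @param obsolete_fraction Fraction in `[0, 1]` of additional obsolete
#'   concepts (each references a current replacement and donates its ID as
#'   that concept's `alt_id`).
#' @param seed Integer seed; generation is fully deterministic given the
#'   spec.
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(n_concepts = 6L,
                         synonyms_per_concept = c(1L, 2L),
                         tokens_per_surface = c(2L, 3L),
                         morph_variants_per_token = c(2L, 3L),
                         n_docs = 4L,
                         mentions_per_doc = c(2L, 4L),
                         distractor_token_rate = 0.3,
                         stopword_rate = 0.25,
                         obsolete_fraction = 0.2,
                         seed = 42L) {
  rng <- function(x) {
    stopifnot(length(x) %in% c(1L, 2L))
    if (length(x) == 1L) x <- c(x, x)
    stopifnot(x[[1L]] <= x[[2L]], x[[1L]] >= 0L)
    as.integer(x)
  }
  stopifnot(n_concepts >= 1L, n_docs >= 0L,
            distractor_token_rate >= 0, distractor_token_rate <= 1,
            stopword_rate >= 0, stopword_rate <= 1,
            obsolete_fraction >= 0, obsolete_fraction <= 1)
  spec <- list(
    n_concepts = as.integer(n_concepts),
    synonyms_per_concept = rng(synonyms_per_concept),
    tokens_per_surface = rng(tokens_per_surface),
    morph_variants_per_token = rng(morph_variants_per_token),
    n_docs = as.integer(n_docs),
    mentions_per_doc = rng(mentions_per_doc),
    distractor_token_rate = distractor_token_rate,
    stopword_rate = stopword_rate,
    obsolete_fraction = obsolete_fraction,
    seed = as.integer(seed)
  )
  if (spec$tokens_per_surface[[1L]] < 1L) stop_usage("tokens_per_surface must be >= 1")
  if (spec$morph_variants_per_token[[1L]] < 1L) {
    stop_usage("morph_variants_per_token must be >= 1")
  }
  if (spec$n_docs > 0L && spec$mentions_per_doc[[2L]] > 0L && spec$n_concepts == 0L) {
    stop_usage("cannot plant mentions with zero concepts")
  }
  class(spec) <- "fixture_spec"
  spec
}

rint <- function(range) if (range[[1L]] == range[[2L]]) range[[1L]] else
  sample(range[[1L]]:range[[2L]], 1L)

# Pronounceable unique base tokens over a restricted alphabet; "x"/"q" are
# reserved for distractors so the two vocabularies can never collide.
make_base_tokens <- function(n) {
  consonants <- c("b", "d", "f", "g", "k", "l", "m", "n", "p", "r", "t", "v")
  vowels <- c("a", "e", "i", "o", "u")
  out <- character(0)
  while (length(out) < n) {
    w <- paste0(
      paste0(sample(consonants, 3L, replace = TRUE),
             sample(vowels, 3L, replace = TRUE), collapse = ""),
      sample(consonants, 1L)
    )
    if (!(w %in% out)) out <- c(out, w)
  }
  out
}

make_distractor <- function() {
  paste0("xq", paste0(sample(letters[1:20], 5L, replace = TRUE), collapse = ""))
}

.fixture_suffixes <- c("", "er", "ing", "ed", "s", "en")

#' Generate a synthetic fixture bundle
#'
#' Deterministic given `spec$seed` (the caller's RNG state is left
#' untouched). Every planted mention uses a randomly chosen morphological
#' variant of each term token (so matching exercises the cluster closure),
#' optionally interleaved with stop words; consecutive mentions are always
#' separated by punctuation and optionally by distractor tokens that belong
#' to no cluster. Concepts draw their tokens from disjoint cluster sets and
#' all surfaces of a concept are token-permutations of its label, so no
#' nested or ambiguous matches can arise by construction and the planted
#' ledger is an exact oracle: annotating the bundle's documents with the
#' bundle's index must recover the gold annotations precisely.
#'
#' @param spec A [fixture_spec()].
#' @param dir Optional output directory; when given, writes `ontology.obo`,
#'   `clusters.txt`, `documents.jsonl` and `gold.tsv` there.
#' @return A `fixture_bundle` list: `concepts` (`ontology_concepts`),
#'   `vocab` (`cluster_vocabulary`), `docs` (data frame `id`/`text`),
#'   `gold` (data frame), `ledger` (identical to `gold`; the planted
#'   truth), `spec`, and `paths` when `dir` was given.
#' @export
generate_fixtures <- function(spec, dir = NULL) {
  stopifnot(inherits(spec, "fixture_spec"))
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old_seed, envir = globalenv())
    }
  })
  set.seed(spec$seed)

  blacklist <- default_blacklist()
  stop_fillers <- c("of", "the", "and", "with", "in")

  # --- clusters -------------------------------------------------------------
  sizes <- vapply(seq_len(spec$n_concepts), function(i) {
    rint(spec$tokens_per_surface)
  }, integer(1))
  n_base <- sum(sizes)
  base <- make_base_tokens(n_base)
  stopifnot(!any(base %in% blacklist))
  clusters <- lapply(base, function(b) {
    nv <- min(rint(spec$morph_variants_per_token), length(.fixture_suffixes))
    suf <- c("", sample(setdiff(.fixture_suffixes, ""), nv - 1L))
    paste0(b, suf)
  })
  names(clusters) <- base

  # --- concepts -------------------------------------------------------------
  offsets <- c(0L, cumsum(sizes))
  concept_ids <- sprintf("FX:%07d", seq_len(spec$n_concepts))
  concepts <- vector("list", spec$n_concepts)
  concept_tokens <- vector("list", spec$n_concepts)
  for (i in seq_len(spec$n_concepts)) {
    toks <- base[(offsets[[i]] + 1L):offsets[[i + 1L]]]
    concept_tokens[[i]] <- toks
    n_syn <- rint(spec$synonyms_per_concept)
    synonyms <- character(0)
    if (n_syn > 0L && length(toks) > 0L) {
      synonyms <- unique(vapply(seq_len(n_syn), function(k) {
        paste(sample(toks, length(toks)), collapse = " ")
      }, character(1)))
      synonyms <- setdiff(synonyms, paste(toks, collapse = " "))
    }
    concepts[[i]] <- list(
      id = concept_ids[[i]],
      label = paste(toks, collapse = " "),
      synonyms = synonyms,
      synonym_scopes = rep("EXACT", length(synonyms)),
      alt_ids = character(0),
      obsolete = FALSE,
      replaced_by = NA_character_
    )
  }

  n_obsolete <- as.integer(round(spec$obsolete_fraction * spec$n_concepts))
  if (n_obsolete > 0L) {
    targets <- sample(seq_len(spec$n_concepts), n_obsolete, replace = TRUE)
    for (k in seq_len(n_obsolete)) {
      old_id <- sprintf("FX:%07d", 9000000L + k)
      tgt <- targets[[k]]
      concepts[[spec$n_concepts + k]] <- list(
        id = old_id, label = sprintf("obsolete concept %d", k),
        synonyms = character(0), synonym_scopes = character(0),
        alt_ids = character(0), obsolete = TRUE,
        replaced_by = concept_ids[[tgt]]
      )
      concepts[[tgt]]$alt_ids <- c(concepts[[tgt]]$alt_ids, old_id)
    }
  }
  concepts <- structure(concepts, class = "ontology_concepts",
                        version = sprintf("fixture/%d", spec$seed))

  vocab <- new_cluster_vocabulary(
    stats::setNames(clusters, paste0("C", seq_along(clusters))),
    clusterer = sprintf("fixture-seed-%d", spec$seed)
  )
  variant_of <- function(tok) sample(clusters[[tok]], 1L)

  # --- documents with planted mentions --------------------------------------
  docs <- list()
  gold_rows <- list()
  for (d in seq_len(spec$n_docs)) {
    doc_id <- sprintf("doc%03d", d)
    n_mentions <- rint(spec$mentions_per_doc)
    text <- ""
    for (m in seq_len(n_mentions)) {
      ci <- sample(spec$n_concepts, 1L)
      toks <- sample(concept_tokens[[ci]], length(concept_tokens[[ci]]))
      pieces <- character(0)
      for (t in seq_along(toks)) {
        pieces <- c(pieces, variant_of(toks[[t]]))
        if (t < length(toks) && stats::runif(1L) < spec$stopword_rate) {
          pieces <- c(pieces, sample(stop_fillers, 1L))
        }
      }
      surface <- paste(pieces, collapse = " ")
      # lead-in: punctuation separates mentions; distractors pad the gap
      lead <- if (m == 1L) "" else ". "
      while (stats::runif(1L) < spec$distractor_token_rate) {
        lead <- paste0(lead, make_distractor(), " ")
      }
      start <- nchar(text) + nchar(lead)
      text <- paste0(text, lead, surface)
      gold_rows[[length(gold_rows) + 1L]] <- list(
        doc_id = doc_id, start = start, end = start + nchar(surface),
        surface = surface, concept_id = concept_ids[[ci]]
      )
    }
    text <- paste0(text, ".")
    docs[[d]] <- list(id = doc_id, text = text)
  }

  docs_df <- if (length(docs) == 0L) {
    data.frame(id = character(0), text = character(0), stringsAsFactors = FALSE)
  } else {
    data.frame(id = vapply(docs, `[[`, character(1), "id"),
               text = vapply(docs, `[[`, character(1), "text"),
               stringsAsFactors = FALSE)
  }
  gold <- if (length(gold_rows) == 0L) {
    data.frame(doc_id = character(0), start = integer(0), end = integer(0),
               surface = character(0), concept_id = character(0),
               stringsAsFactors = FALSE)
  } else {
    data.frame(
      doc_id = vapply(gold_rows, `[[`, character(1), "doc_id"),
      start = vapply(gold_rows, function(r) as.integer(r$start), integer(1)),
      end = vapply(gold_rows, function(r) as.integer(r$end), integer(1)),
      surface = vapply(gold_rows, `[[`, character(1), "surface"),
      concept_id = vapply(gold_rows, `[[`, character(1), "concept_id"),
      stringsAsFactors = FALSE
    )
  }

  bundle <- list(concepts = concepts, vocab = vocab, docs = docs_df,
                 gold = gold, ledger = gold, spec = spec)
  class(bundle) <- "fixture_bundle"

  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    paths <- list(
      ontology = file.path(dir, "ontology.obo"),
      clusters = file.path(dir, "clusters.txt"),
      documents = file.path(dir, "documents.jsonl"),
      gold = file.path(dir, "gold.tsv")
    )
    write_fixture_obo(concepts, paths$ontology)
    save_clusters(vocab, paths$clusters)
    con <- file(paths$documents, open = "w", encoding = "UTF-8")
    for (k in seq_len(nrow(docs_df))) {
      writeLines(jsonlite::toJSON(list(id = docs_df$id[[k]],
                                       text = docs_df$text[[k]]),
                                  auto_unbox = TRUE), con)
    }
    close(con)
    write_mentions_tsv(gold, paths$gold)
    bundle$paths <- paths
  }
  bundle
}

write_fixture_obo <- function(concepts, path) {
  lines <- c("format-version: 1.4",
             sprintf("data-version: %s", attr(concepts, "version")), "")
  for (c in concepts) {
    lines <- c(lines, "[Term]", sprintf("id: %s", c$id),
               sprintf("name: %s", c$label))
    for (k in seq_along(c$synonyms)) {
      scope <- if (length(c$synonym_scopes) >= k && nzchar(c$synonym_scopes[[k]])) {
        c$synonym_scopes[[k]]
      } else "EXACT"
      lines <- c(lines, sprintf('synonym: "%s" %s []', c$synonyms[[k]], scope))
    }
    for (a in c$alt_ids) lines <- c(lines, sprintf("alt_id: %s", a))
    if (isTRUE(c$obsolete)) {
      lines <- c(lines, "is_obsolete: true")
      if (!is.na(c$replaced_by)) {
        lines <- c(lines, sprintf("replaced_by: %s", c$replaced_by))
      }
    }
    lines <- c(lines, "")
  }
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' @export
print.fixture_bundle <- function(x, ...) {
  cat(sprintf(
    "<fixture_bundle> %d concepts, %d clusters, %d docs, %d planted mentions (seed %d)\n",
    sum(!vapply(x$concepts, `[[`, logical(1), "obsolete")),
    length(x$vocab$clusters), nrow(x$docs), nrow(x$gold), x$spec$seed
  ))
  invisible(x)
}
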