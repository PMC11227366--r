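# In-code builders for tiny ontologies and vocabularies, plus the
# brute-force window-enumeration oracle the recognizer is checked against.

make_concept <- function(id, label, synonyms = character(0),
                         scopes = rep("EXACT", length(synonyms)),
                         alt_ids = character(0), obsolete = FALSE,
                         replaced_by = NA_character_) {
  list(id = id, label = label, synonyms = synonyms, synonym_scopes = scopes,
       alt_ids = alt_ids, obsolete = obsolete, replaced_by = replaced_by)
}

make_concepts <- function(..., version = "test/1") {
  structure(list(...), class = "ontology_concepts", version = version)
}

# A macrocephaly-style mini ontology used across tests.
mini_concepts <- function() {
  make_concepts(
    make_concept("HP:0000256", "Macrocephaly",
                 synonyms = "Increased size of cranium"),
    make_concept("HP:0009778", "Short phalanx"),
    make_concept("HP:0100790", "Hernia"),
    make_concept("HP:0001537", "Umbilical hernia")
  )
}

mini_vocab <- function() {
  build_clusters(c(
    "macrocephaly", "increased", "increase", "increasing", "size", "sizes",
    "cranium", "cranial", "short", "shorter", "shorten", "shortening",
    "phalanx", "phalanges", "hernia", "hernias", "umbilical"
  ))
}

mini_index <- function() build_index(mini_concepts(), mini_vocab())

# Cluster file whose line numbers reproduce the worked indexing example:
# increased -> C2, size -> C26, cranium -> C35.
write_worked_example_clusters <- function(path) {
  lines <- paste0("filler", rep(letters[1:7], each = 5), letters[1:5])[1:35]
  lines[2] <- "increased increase increasing"
  lines[26] <- "size sizes sized"
  lines[35] <- "cranium craniums"
  writeLines(lines, path)
  path
}

# Brute-force oracle: enumerate EVERY contiguous token window that contains
# no break and no unknown token, drop blacklisted tokens, and compare the
# window's cluster-ID set plus its filtered length against every indexed
# surface. Spans are trimmed to the first/last non-blacklisted token.
# Independent of form_candidates/decompose/match_signature.
oracle_annotate <- function(text, index) {
  toks <- tokenize_text(text)
  black <- index$blacklist
  tm <- index$token_map
  found <- list()
  n <- nrow(toks)
  for (i in seq_len(n)) {
    for (j in i:n) {
      if (j > n) break
      w <- toks[i:j, , drop = FALSE]
      if (any(w$kind == "break")) next
      lw <- tolower(w$text)
      keep <- !(lw %in% black)
      if (!any(keep)) next
      keys <- ifelse(grepl("[0-9]", lw), lw, normalize_spelling(lw))
      cl <- unname(tm[keys[keep]])
      if (anyNA(cl)) next
      s <- w$start[which(keep)[1L]]
      e <- w$end[which(keep)[sum(keep)]]
      cl_set <- unique(cl)
      for (sig in index$signatures) {
        if (sig$length != length(cl)) next
        sig_set <- strsplit(sig$key, "-", fixed = TRUE)[[1L]]
        if (length(sig_set) == length(cl_set) && setequal(sig_set, cl_set)) {
          for (m in sig$matches) {
            found[[length(found) + 1L]] <-
              list(concept_id = m$id, start = s, end = e)
          }
        }
      }
    }
  }
  if (length(found) == 0L) {
    return(data.frame(concept_id = character(0), start = integer(0),
                      end = integer(0), stringsAsFactors = FALSE))
  }
  df <- data.frame(
    concept_id = vapply(found, `[[`, character(1), "concept_id"),
    start = vapply(found, `[[`, integer(1), "start"),
    end = vapply(found, `[[`, integer(1), "end"),
    stringsAsFactors = FALSE
  )
  df <- unique(df)
  df[order(df$start, df$end, df$concept_id, method = "radix"), , drop = FALSE]
}

mention_key_frame <- function(mentions) {
  df <- unique(mentions[, c("concept_id", "start", "end")])
  df <- df[order(df$start, df$end, df$concept_id, method = "radix"), , drop = FALSE]
  rownames(df) <- NULL
  df
}

expect_same_mention_set <- function(mentions, oracle) {
  got <- mention_key_frame(mentions)
  want <- oracle
  rownames(want) <- NULL
  expect_equal(got, want[, c("concept_id", "start", "end")])
}
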