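INDEX_SCHEMA_VERSION <- "1"

#' Default surface blacklist
#'
#' Standard English stop words, auxiliary/copular verbs and conjunctions,
#' shipped with the package as a pinned plain-text artifact
#' (`inst/extdata/blacklist.txt`). These tokens are removed from term
#' surfaces when the index is built and are transparent inside text
#' candidates when annotating.
#'
#' @return Character vector of blacklisted tokens.
#' @export
default_blacklist <- function() {
  path <- system.file("extdata", "blacklist.txt", package = "sigcr",
                      mustWork = TRUE)
  lines <- trimws(readLines(path, warn = FALSE, encoding = "UTF-8"))
  lines[nzchar(lines) & !startsWith(lines, "#")]
}

#' Tokenize a term surface
#'
#' Lowercases and splits on any run of non-alphanumeric characters, dropping
#' empty pieces and preserving order: `"Increased size of cranium"` becomes
#' `increased, size, of, cranium`; `"cleft lip/palate"` becomes
#' `cleft, lip, palate`.
#'
#' @param text A single string (a label or synonym).
#' @return Character vector of lowercase tokens.
#' @export
tokenize_surface <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  if (is.na(text) || !nzchar(text)) return(character(0))
  toks <- strsplit(tolower(text), "[^a-z0-9]+")[[1L]]
  toks[nzchar(toks)]
}

#' Remove blacklisted tokens
#'
#' Order-preserving removal; the count of surviving tokens is the signature
#' length recorded in the index.
#'
#' @param tokens Character vector of lowercase tokens.
#' @param blacklist Character vector of blacklisted tokens.
#' @return Filtered character vector.
#' @export
filter_blacklist <- function(tokens, blacklist = default_blacklist()) {
  tokens[!(tokens %in% blacklist)]
}

#' Replace surface tokens by cluster IDs
#'
#' Each letters-only token is looked up in the cluster vocabulary (after
#' spelling normalization); tokens containing digits are given an implicit
#' singleton cluster keyed by their own text (so `"type 1"` stays indexable
#' even though the cluster vocabulary covers proper words only). A surface
#' with any uncovered token is not an error but a miss-report: the offending
#' tokens are listed so the caller can log and skip it.
#'
#' @param tokens Character vector of blacklist-filtered lowercase tokens.
#' @param vocab A `cluster_vocabulary`.
#' @return List with `cluster_ids` (character, in token order) and `missing`
#'   (character vector of tokens that have no cluster; empty when fully
#'   consolidated).
#' @export
consolidate <- function(tokens, vocab) {
  if (length(tokens) == 0L) {
    return(list(cluster_ids = character(0), missing = character(0)))
  }
  has_digit <- grepl("[0-9]", tokens)
  ids <- character(length(tokens))
  ids[has_digit] <- tokens[has_digit]
  if (any(!has_digit)) {
    ids[!has_digit] <- cluster_of(vocab, tokens[!has_digit])
  }
  list(cluster_ids = ids, missing = unique(tokens[is.na(ids)]))
}

#' Build the order-free signature of a cluster-ID sequence
#'
#' The signature is the de-duplicated, lexicographically sorted (plain byte
#' order) cluster IDs joined with `"-"`, paired with the token count of the
#' sequence including duplicates. Sorting makes matching order-free
#' (`short phalanx` and `phalanx shortening` share a signature); the
#' retained length separates the rare surfaces in which one cluster occurs
#' twice from their de-duplicated look-alikes.
#'
#' @param cluster_ids Non-empty character vector of cluster IDs in token
#'   order.
#' @return A list of class `signature` with fields `key` and `length`.
#' @examples
#' make_signature(c("C3425", "C112", "C59"))  # key "C112-C3425-C59"
#' @export
make_signature <- function(cluster_ids) {
  if (length(cluster_ids) == 0L || any(is.na(cluster_ids))) {
    stop_data("empty surface after filtering")
  }
  structure(
    list(
      key = paste(sort(unique(cluster_ids), method = "radix"), collapse = "-"),
      length = length(cluster_ids)
    ),
    class = "signature"
  )
}

sig_slot <- function(key, length) paste0(key, "|", length)

#' Build a concept index from ontology concepts and a cluster vocabulary
#'
#' Every surface (label plus synonyms) of every non-obsolete concept is
#' tokenized, blacklist-filtered, consolidated to cluster IDs and stored
#' under its signature. The token map receives the *entire* membership of
#' every cluster that contributes to at least one indexed surface (variant
#' closure: this is how unseen morphological variants in text still match),
#' and nothing else — the index associates concepts with cluster-ID sets
#' only. Surfaces that are empty after filtering, or contain tokens with no
#' cluster, are skipped and reported.
#'
#' @param concepts An `ontology_concepts` list (see [parse_ontology()]).
#' @param vocab A `cluster_vocabulary`.
#' @param blacklist Character vector; defaults to [default_blacklist()].
#' @param exact_synonyms_only If `TRUE`, only synonyms whose scope is
#'   `EXACT` (or unscoped) are indexed; default indexes all synonym types.
#' @param created Optional build-time string stored in metadata; left unset
#'   by default so that rebuilding from identical inputs yields a
#'   byte-identical serialized index.
#' @return An object of class `concept_index` with fields `schema_version`,
#'   `metadata`, `blacklist`, `token_map` (named character: canonical token
#'   -> cluster ID), `signatures` (list of `key` / `length` / `matches`),
#'   and `skipped` (data frame of unindexable surfaces).
#' @export
build_index <- function(concepts, vocab, blacklist = default_blacklist(),
                        exact_synonyms_only = FALSE, created = NULL) {
  stopifnot(inherits(vocab, "cluster_vocabulary"))
  sig_entries <- new.env(parent = emptyenv(), hash = TRUE)
  used_clusters <- new.env(parent = emptyenv(), hash = TRUE)
  implicit <- new.env(parent = emptyenv(), hash = TRUE)
  skipped <- list()
  n_indexed <- 0L

  for (concept in concepts) {
    if (isTRUE(concept$obsolete)) next
    surfaces <- character(0); is_label <- logical(0)
    if (!is.na(concept$label) && nzchar(concept$label)) {
      surfaces <- concept$label; is_label <- TRUE
    }
    syn <- concept$synonyms
    if (exact_synonyms_only && length(syn) > 0L) {
      keep <- concept$synonym_scopes %in% c("EXACT", "")
      syn <- syn[keep]
    }
    surfaces <- c(surfaces, syn)
    is_label <- c(is_label, rep(FALSE, length(syn)))

    for (k in seq_along(surfaces)) {
      toks <- filter_blacklist(tokenize_surface(surfaces[[k]]), blacklist)
      if (length(toks) == 0L) {
        skipped[[length(skipped) + 1L]] <-
          list(concept_id = concept$id, surface = surfaces[[k]],
               reason = "empty after filtering")
        next
      }
      cons <- consolidate(toks, vocab)
      if (length(cons$missing) > 0L) {
        skipped[[length(skipped) + 1L]] <-
          list(concept_id = concept$id, surface = surfaces[[k]],
               reason = paste0("no cluster for: ",
                               paste(cons$missing, collapse = ", ")))
        next
      }
      sig <- make_signature(cons$cluster_ids)
      slot <- sig_slot(sig$key, sig$length)
      entry <- list(id = concept$id, surface = surfaces[[k]],
                    is_label = is_label[[k]])
      cur <- get0(slot, envir = sig_entries, ifnotfound = list())
      dupe <- any(vapply(cur, function(e) {
        e$id == entry$id && e$surface == entry$surface
      }, logical(1)))
      if (!dupe) assign(slot, c(cur, list(entry)), envir = sig_entries)
      tok_has_digit <- grepl("[0-9]", toks)
      for (cid in unique(cons$cluster_ids[!tok_has_digit])) {
        assign(cid, TRUE, envir = used_clusters)
      }
      for (tok in unique(toks[tok_has_digit])) {
        assign(tok, TRUE, envir = implicit)
      }
      n_indexed <- n_indexed + 1L
    }
  }

  if (n_indexed == 0L && length(concepts) > 0L) {
    warning("no surface could be indexed: empty concept index")
  }

  # variant closure: all members (canonical forms) of every used cluster
  token_map <- character(0)
  for (cid in ls(used_clusters)) {
    canon <- unique(normalize_spelling(vocab$clusters[[cid]]))
    m <- rep(cid, length(canon))
    names(m) <- canon
    token_map <- c(token_map, m)
  }
  for (tok in ls(implicit)) {
    m <- tok; names(m) <- tok
    token_map <- c(token_map, m)
  }
  if (length(token_map) > 0L) {
    token_map <- token_map[order(names(token_map), method = "radix")]
  }

  slots <- ls(sig_entries)
  signatures <- lapply(slots, function(slot) {
    parts <- strsplit(slot, "|", fixed = TRUE)[[1L]]
    matches <- get(slot, envir = sig_entries)
    ord <- order(vapply(matches, `[[`, character(1), "id"),
                 vapply(matches, `[[`, character(1), "surface"),
                 method = "radix")
    list(key = parts[[1L]], length = as.integer(parts[[2L]]),
         matches = matches[ord])
  })
  keys <- vapply(signatures, `[[`, character(1), "key")
  lens <- vapply(signatures, `[[`, integer(1), "length")
  signatures <- signatures[order(keys, lens, method = "radix")]

  skipped_df <- if (length(skipped) == 0L) {
    data.frame(concept_id = character(0), surface = character(0),
               reason = character(0), stringsAsFactors = FALSE)
  } else {
    data.frame(
      concept_id = vapply(skipped, `[[`, character(1), "concept_id"),
      surface = vapply(skipped, `[[`, character(1), "surface"),
      reason = vapply(skipped, `[[`, character(1), "reason"),
      stringsAsFactors = FALSE
    )
  }

  version <- attr(concepts, "version")
  new_concept_index(list(
    schema_version = INDEX_SCHEMA_VERSION,
    metadata = list(
      ontology_version = if (is.null(version) || is.na(version)) "unknown" else version,
      clusterer = vocab$clusterer,
      created = created,
      n_indexed_surfaces = n_indexed,
      n_skipped_surfaces = nrow(skipped_df)
    ),
    blacklist = sort(unique(blacklist), method = "radix"),
    token_map = token_map,
    signatures = signatures,
    skipped = skipped_df
  ))
}

# Attach lookup environments (token map, blacklist, signature slots) to a
# plain index list; these are runtime caches, never serialized.
new_concept_index <- function(x) {
  token_env <- new.env(parent = emptyenv(), hash = TRUE)
  tm <- x$token_map
  for (i in seq_along(tm)) assign(names(tm)[i], tm[[i]], envir = token_env)
  black_env <- new.env(parent = emptyenv(), hash = TRUE)
  for (b in x$blacklist) assign(b, TRUE, envir = black_env)
  sig_env <- new.env(parent = emptyenv(), hash = TRUE)
  for (s in x$signatures) {
    assign(sig_slot(s$key, s$length), s$matches, envir = sig_env)
  }
  structure(x, class = "concept_index", token_env = token_env,
            black_env = black_env, sig_env = sig_env)
}

#' Serialize / deserialize a concept index
#'
#' The index is written as a versioned JSON document
#' (`schema_version`, `metadata`, `blacklist`, `token_map`, `signatures`).
#' All maps are emitted in sorted key order, so identical inputs produce
#' byte-identical files, and `load_index(save_index(x))` reproduces `x`
#' field-for-field. Loading a document with a different schema version is an
#' explicit error.
#'
#' @param index A `concept_index`.
#' @param path Output (or input) path.
#' @return `save_index`: `path`, invisibly. `load_index`: a `concept_index`.
#' @export
save_index <- function(index, path) {
  stopifnot(inherits(index, "concept_index"))
  doc <- list(
    schema_version = index$schema_version,
    metadata = index$metadata,
    blacklist = index$blacklist,
    token_map = as.list(index$token_map),
    signatures = lapply(index$signatures, function(s) {
      list(key = s$key, length = s$length,
           matches = lapply(s$matches, function(m) {
             list(id = m$id, surface = m$surface, is_label = m$is_label)
           }))
    })
  )
  json <- jsonlite::toJSON(doc, auto_unbox = TRUE, null = "null", digits = NA,
                           pretty = FALSE)
  writeLines(json, path, useBytes = TRUE)
  invisible(path)
}

#' @rdname save_index
#' @export
load_index <- function(path) {
  if (!file.exists(path)) stop_usage(sprintf("index file not found: %s", path))
  doc <- tryCatch(
    jsonlite::fromJSON(path, simplifyVector = FALSE),
    error = function(e) stop_data(sprintf("cannot parse index %s: %s",
                                          path, conditionMessage(e)))
  )
  if (is.null(doc$schema_version) ||
      !identical(as.character(doc$schema_version), INDEX_SCHEMA_VERSION)) {
    stop_data(sprintf(
      "index schema version mismatch: file has %s, this build reads %s",
      if (is.null(doc$schema_version)) "<none>" else doc$schema_version,
      INDEX_SCHEMA_VERSION
    ))
  }
  token_map <- vapply(doc$token_map, function(v) as.character(v), character(1))
  signatures <- lapply(doc$signatures, function(s) {
    list(key = s$key, length = as.integer(s$length),
         matches = lapply(s$matches, function(m) {
           list(id = m$id, surface = m$surface, is_label = isTRUE(m$is_label))
         }))
  })
  meta <- doc$metadata
  meta$n_indexed_surfaces <- as.integer(meta$n_indexed_surfaces)
  meta$n_skipped_surfaces <- as.integer(meta$n_skipped_surfaces)
  new_concept_index(list(
    schema_version = as.character(doc$schema_version),
    metadata = meta,
    blacklist = vapply(doc$blacklist, as.character, character(1)),
    token_map = token_map,
    signatures = signatures,
    skipped = NULL
  ))
}

#' @export
print.concept_index <- function(x, ...) {
  cat(sprintf(
    "<concept_index> %d signatures, %d tokens in map (ontology: %s, clusterer: %s)\n",
    length(x$signatures), length(x$token_map),
    x$metadata$ontology_version, x$metadata$clusterer
  ))
  cat(sprintf("  surfaces indexed: %d, skipped: %d\n",
              x$metadata$n_indexed_surfaces, x$metadata$n_skipped_surfaces))
  invisible(x)
}
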