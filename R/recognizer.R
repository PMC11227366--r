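#' Tokenize a document, keeping offsets and punctuation breaks
#'
#' Splits a document with the same rule as [tokenize_surface()] (runs of
#' alphanumeric characters are words) but keeps 0-based, end-exclusive
#' character offsets into the original text, and emits an explicit break
#' marker for every run of punctuation between words. Whitespace alone does
#' not break continuity; any other character does (so `"short-stature"` is
#' `short | BREAK | stature`). Breaks are what later confine candidate
#' mentions to contiguous spans.
#'
#' @param text A single document string.
#' @return A data frame of class `doc_tokens` with columns `text`, `start`,
#'   `end` (0-based, end-exclusive) and `kind` (`"word"` or `"break"`).
#' @export
tokenize_text <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  empty <- data.frame(text = character(0), start = integer(0),
                      end = integer(0), kind = character(0),
                      stringsAsFactors = FALSE)
  class(empty) <- c("doc_tokens", "data.frame")
  if (is.na(text) || !nzchar(text)) return(empty)
  m <- gregexpr("[A-Za-z0-9]+|[^A-Za-z0-9[:space:]]+", text)[[1L]]
  if (m[[1L]] == -1L) return(empty)
  starts <- as.integer(m)
  lens <- attr(m, "match.length")
  pieces <- substring(text, starts, starts + lens - 1L)
  out <- data.frame(
    text = pieces,
    start = starts - 1L,
    end = starts + lens - 1L,
    kind = ifelse(grepl("^[A-Za-z0-9]", pieces), "word", "break"),
    stringsAsFactors = FALSE
  )
  class(out) <- c("doc_tokens", "data.frame")
  out
}

#' Label document tokens against a concept index
#'
#' Single pass, one lookup per word token: a token found in the index's
#' blacklist is `blacklisted`; otherwise it is looked up in the token map
#' (letters-only tokens after spelling normalization) and is `known` with
#' its cluster ID when present, else `unknown`. Break markers keep status
#' `break`.
#'
#' @param tokens A `doc_tokens` data frame from [tokenize_text()].
#' @param index A `concept_index`.
#' @return The same data frame with columns `status` and `cluster_id`
#'   added, plus attribute `n_lookups` (number of word tokens processed).
#' @export
label_tokens <- function(tokens, index) {
  stopifnot(inherits(index, "concept_index"))
  token_env <- attr(index, "token_env")
  black_env <- attr(index, "black_env")
  n <- nrow(tokens)
  status <- character(n)
  cluster_id <- rep(NA_character_, n)
  n_lookups <- 0L
  for (i in seq_len(n)) {
    if (tokens$kind[[i]] == "break") {
      status[[i]] <- "break"
      next
    }
    n_lookups <- n_lookups + 1L
    low <- tolower(tokens$text[[i]])
    if (!is.null(get0(low, envir = black_env, ifnotfound = NULL))) {
      status[[i]] <- "blacklisted"
      next
    }
    key <- if (grepl("[0-9]", low)) low else normalize_spelling(low)
    hit <- get0(key, envir = token_env, ifnotfound = NULL)
    if (is.null(hit)) {
      status[[i]] <- "unknown"
    } else {
      status[[i]] <- "known"
      cluster_id[[i]] <- hit
    }
  }
  tokens$status <- status
  tokens$cluster_id <- cluster_id
  attr(tokens, "n_lookups") <- n_lookups
  tokens
}

#' Form candidate runs from labeled tokens
#'
#' A candidate is a maximal run of `known` tokens in which interior
#' `blacklisted` tokens are transparent (skipped without breaking the run)
#' and `unknown` tokens or punctuation breaks terminate the run. Leading or
#' trailing blacklisted tokens belong to no candidate. These gaps are what
#' turn boundary detection into a by-product of the index content.
#'
#' @param tokens A labeled `doc_tokens` data frame (see [label_tokens()]).
#' @return List of candidates, each a list with `cluster_seq` (cluster IDs
#'   in text order), `token_indices` (row indices of the contributing known
#'   tokens), `start`, `end` (span over the first to last known token).
#' @export
form_candidates <- function(tokens) {
  candidates <- list()
  run <- integer(0)
  close_run <- function() {
    if (length(run) > 0L) {
      candidates[[length(candidates) + 1L]] <<- list(
        cluster_seq = tokens$cluster_id[run],
        token_indices = run,
        start = tokens$start[[run[[1L]]]],
        end = tokens$end[[run[[length(run)]]]]
      )
    }
    run <<- integer(0)
  }
  for (i in seq_len(nrow(tokens))) {
    s <- tokens$status[[i]]
    if (s == "known") {
      run <- c(run, i)
    } else if (s == "blacklisted") {
      # transparent: neither joins nor breaks the run
    } else {
      close_run()
    }
  }
  close_run()
  candidates
}

#' Enumerate contiguous sub-candidates of a candidate
#'
#' Decomposes a candidate into every contiguous window `(i, j)` — the
#' candidate itself plus all strictly shorter contiguous subsequences, left
#' to right — so nested concepts are covered; non-contiguous subsets are
#' never formed. A window cap bounds the quadratic window count on
#' pathological runs; filtered ontology surfaces are far shorter than the
#' default cap.
#'
#' @param cluster_seq Non-empty character vector of cluster IDs.
#' @param window_cap Maximum window length to enumerate (default 10).
#' @return List of windows, each a list with `ids` (the cluster-ID
#'   subsequence), `i`, `j` (1-based positions within the candidate).
#' @examples
#' length(decompose(c("C6894", "C6075", "C12497")))  # 6 windows
#' @export
decompose <- function(cluster_seq, window_cap = 10L) {
  k <- length(cluster_seq)
  stopifnot(k > 0L)
  out <- vector("list", 0L)
  for (len in seq_len(min(k, window_cap))) {
    for (i in seq_len(k - len + 1L)) {
      j <- i + len - 1L
      out[[length(out) + 1L]] <- list(ids = cluster_seq[i:j], i = i, j = j)
    }
  }
  out
}

#' Look up one sub-candidate in the index
#'
#' Builds the order-free signature of the window (sorted unique cluster IDs
#' plus window length counting duplicates) and returns every concept entry
#' stored under it — a single hash lookup. Word order in text is thereby
#' irrelevant: `phalanx shortening` retrieves a concept indexed from
#' `short phalanx`.
#'
#' @param cluster_ids Character vector of the window's cluster IDs.
#' @param index A `concept_index`.
#' @return List of match payloads (`id`, `surface`, `is_label`); empty when
#'   the signature is absent.
#' @export
match_signature <- function(cluster_ids, index) {
  stopifnot(inherits(index, "concept_index"))
  sig <- make_signature(cluster_ids)
  get0(sig_slot(sig$key, sig$length), envir = attr(index, "sig_env"),
       ifnotfound = list())
}

empty_mentions <- function() {
  data.frame(
    doc_id = character(0), start = integer(0), end = integer(0),
    surface = character(0), concept_id = character(0),
    matched_term = character(0), is_label = logical(0),
    ambiguous = logical(0), stringsAsFactors = FALSE
  )
}

#' Annotate a document with ontology concepts
#'
#' The full recognition pipeline: tokenize with offsets, label each token
#' against the index (one lookup per token), form gap-delimited candidates,
#' decompose each candidate into contiguous windows, and look each window up
#' by signature. A matched window becomes a mention spanning its first to
#' last contributing known token (interior blacklisted tokens included in
#' the span). Under `policy = "all"` every matched window is returned
#' (nested matches included); `policy = "longest"` greedily keeps the
#' longest non-overlapping mentions, ties going to the leftmost. Identical
#' (concept, span) duplicates are collapsed; when one signature maps to
#' several concepts, one mention per concept is emitted and flagged
#' `ambiguous`.
#'
#' @param text A single document string.
#' @param index A `concept_index`.
#' @param policy `"all"` (default) or `"longest"`.
#' @param doc_id Document identifier stamped on the mentions.
#' @param window_cap Maximum lookup window length (see [decompose()]).
#' @return A data frame of mentions (`doc_id`, `start`, `end`, `surface`,
#'   `concept_id`, `matched_term`, `is_label`, `ambiguous`), sorted by
#'   `(start, -length)`, with 0-based end-exclusive offsets; attribute
#'   `"counters"` holds `n_tokens`, `n_token_lookups`, `n_candidates`,
#'   `n_sig_lookups` and `candidate_lengths`.
#' @export
annotate <- function(text, index, policy = c("all", "longest"),
                     doc_id = "doc", window_cap = 10L) {
  policy <- match.arg(policy)
  tokens <- label_tokens(tokenize_text(text), index)
  candidates <- form_candidates(tokens)
  n_sig_lookups <- 0L
  rows <- list()
  for (cand in candidates) {
    for (win in decompose(cand$cluster_seq, window_cap)) {
      n_sig_lookups <- n_sig_lookups + 1L
      hits <- match_signature(win$ids, index)
      if (length(hits) == 0L) next
      first <- cand$token_indices[[win$i]]
      last <- cand$token_indices[[win$j]]
      start <- tokens$start[[first]]
      end <- tokens$end[[last]]
      amb <- length(unique(vapply(hits, `[[`, character(1), "id"))) > 1L
      for (h in hits) {
        rows[[length(rows) + 1L]] <- list(
          doc_id = doc_id, start = start, end = end,
          surface = substr(text, start + 1L, end),
          concept_id = h$id, matched_term = h$surface,
          is_label = h$is_label, ambiguous = amb
        )
      }
    }
  }
  mentions <- if (length(rows) == 0L) empty_mentions() else data.frame(
    doc_id = vapply(rows, `[[`, character(1), "doc_id"),
    start = vapply(rows, `[[`, integer(1), "start"),
    end = vapply(rows, `[[`, integer(1), "end"),
    surface = vapply(rows, `[[`, character(1), "surface"),
    concept_id = vapply(rows, `[[`, character(1), "concept_id"),
    matched_term = vapply(rows, `[[`, character(1), "matched_term"),
    is_label = vapply(rows, `[[`, logical(1), "is_label"),
    ambiguous = vapply(rows, `[[`, logical(1), "ambiguous"),
    stringsAsFactors = FALSE
  )
  if (nrow(mentions) > 0L) {
    # collapse duplicate (concept, span); prefer the label entry as the
    # reported matched term
    mentions <- mentions[order(mentions$start, -(mentions$end - mentions$start),
                               mentions$concept_id, !mentions$is_label,
                               method = "radix"), , drop = FALSE]
    dup <- duplicated(mentions[, c("doc_id", "start", "end", "concept_id")])
    mentions <- mentions[!dup, , drop = FALSE]
  }
  if (policy == "longest" && nrow(mentions) > 0L) {
    ord <- order(-(mentions$end - mentions$start), mentions$start,
                 method = "radix")
    keep <- logical(nrow(mentions))
    taken_start <- integer(0); taken_end <- integer(0)
    for (i in ord) {
      s <- mentions$start[[i]]; e <- mentions$end[[i]]
      if (!any(s < taken_end & e > taken_start)) {
        keep[[i]] <- TRUE
        taken_start <- c(taken_start, s)
        taken_end <- c(taken_end, e)
      }
    }
    mentions <- mentions[keep, , drop = FALSE]
    mentions <- mentions[order(mentions$start, method = "radix"), , drop = FALSE]
  }
  rownames(mentions) <- NULL
  attr(mentions, "counters") <- list(
    n_tokens = sum(tokens$kind == "word"),
    n_token_lookups = attr(tokens, "n_lookups"),
    n_candidates = length(candidates),
    n_sig_lookups = n_sig_lookups,
    candidate_lengths = vapply(candidates, function(c) length(c$cluster_seq),
                               integer(1))
  )
  mentions
}

#' Annotate a corpus of documents
#'
#' Applies [annotate()] document by document (constant memory in corpus
#' size) and aggregates the complexity counters, which downstream tests use
#' to assert the method's linear-time contract.
#'
#' @param docs A data frame with columns `id` and `text`, or a named list /
#'   named character vector of document texts.
#' @param index A `concept_index`.
#' @param policy,window_cap Passed to [annotate()].
#' @return A list with `mentions` (row-bound mention data frame) and
#'   `counters` (totals plus a `per_doc` data frame of `n_tokens`,
#'   `n_candidates`, `n_sig_lookups`, `n_mentions`).
#' @export
annotate_corpus <- function(docs, index, policy = c("all", "longest"),
                            window_cap = 10L) {
  policy <- match.arg(policy)
  if (is.data.frame(docs)) {
    stopifnot(all(c("id", "text") %in% names(docs)))
    ids <- as.character(docs$id); texts <- as.character(docs$text)
  } else {
    ids <- names(docs)
    if (is.null(ids)) stop_usage("docs must be a data frame or a named list")
    texts <- vapply(docs, function(t) as.character(t)[[1L]], character(1))
  }
  all_mentions <- vector("list", length(ids))
  per_doc <- vector("list", length(ids))
  for (k in seq_along(ids)) {
    m <- annotate(texts[[k]], index, policy = policy, doc_id = ids[[k]],
                  window_cap = window_cap)
    cnt <- attr(m, "counters")
    all_mentions[[k]] <- m
    per_doc[[k]] <- data.frame(
      doc_id = ids[[k]], n_tokens = cnt$n_tokens,
      n_candidates = cnt$n_candidates, n_sig_lookups = cnt$n_sig_lookups,
      n_mentions = nrow(m), stringsAsFactors = FALSE
    )
  }
  mentions <- do.call(rbind, c(list(empty_mentions()), all_mentions))
  rownames(mentions) <- NULL
  per_doc <- do.call(rbind, per_doc)
  list(
    mentions = mentions,
    counters = list(
      n_docs = length(ids),
      n_tokens = sum(per_doc$n_tokens %||% 0L),
      n_candidates = sum(per_doc$n_candidates %||% 0L),
      n_sig_lookups = sum(per_doc$n_sig_lookups %||% 0L),
      n_mentions = nrow(mentions),
      per_doc = per_doc
    )
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
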