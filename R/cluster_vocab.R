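#' @title Cluster vocabularies of morphologically equivalent tokens
#' @description
#' The recognizer rests on a partition of a token vocabulary into clusters of
#' morphologically equivalent forms (e.g. `short / shorter / shorten /
#' shortening`), so that any inflected or derived variant of a term token, or
#' a localized spelling of it, maps to the same opaque cluster ID. A
#' `cluster_vocabulary` object holds the clusters plus a canonical-form
#' lookup map, and is either built deterministically from a raw token set
#' ([build_clusters()]) or loaded from a plain-text cluster file
#' ([load_clusters()]), one cluster per line.
#' @name cluster_vocabulary
NULL

new_cluster_vocabulary <- function(clusters, clusterer) {
  # clusters: named list cluster_id -> character vector of members
  map <- character(0)
  for (id in names(clusters)) {
    canon <- unique(normalize_spelling(clusters[[id]]))
    m <- rep(id, length(canon))
    names(m) <- canon
    map <- c(map, m)
  }
  dup <- names(map)[duplicated(names(map))]
  if (length(dup) > 0L) {
    stop_data(sprintf("partition violation: %s", dup[[1L]]))
  }
  ord <- order(names(map), method = "radix")
  env <- new.env(parent = emptyenv(), hash = TRUE)
  for (i in seq_along(map)) assign(names(map)[i], map[[i]], envir = env)
  structure(
    list(
      clusters = clusters,
      token_to_cluster = map[ord],
      clusterer = clusterer
    ),
    class = "cluster_vocabulary",
    map_env = env
  )
}

check_vocab_tokens <- function(tokens, where) {
  norm <- normalize_token(tokens)
  bad <- tokens[is.na(norm)]
  if (length(bad) > 0L) {
    stop_data(sprintf("%s: not a letters-only token: '%s'", where, bad[[1L]]))
  }
  norm
}

#' Build a cluster vocabulary from a raw token set
#'
#' Tokens are spelling-normalized, then grouped by their 4-letter prefix, and
#' within a prefix group two tokens share a cluster iff they have the same
#' canonical stem. Tokens shorter than four letters form singleton groups
#' keyed by their full text. Cluster IDs `"C1", "C2", ...` are assigned in
#' lexicographic order of each cluster's smallest member, so the result is
#' identical for any input ordering.
#'
#' @param vocab Character vector (treated as a set) of lowercase letters-only
#'   tokens.
#' @param stemmer A `function(character) -> character` giving the canonical
#'   stem; defaults to [suffix_stem()]. The stemmer identity is recorded in
#'   the vocabulary so downstream indexes can be reproduced.
#' @param stemmer_id Short string identifying the stemmer in metadata.
#' @return A `cluster_vocabulary` object.
#' @examples
#' v <- build_clusters(c("short", "shorter", "shorten", "shortening", "shore"))
#' v$clusters
#' @export
build_clusters <- function(vocab, stemmer = suffix_stem,
                           stemmer_id = "suffix_stem") {
  if (length(vocab) == 0L) stop_data("empty vocabulary")
  vocab <- unique(vocab)
  norm <- check_vocab_tokens(vocab, "build_clusters")
  canon <- normalize_spelling(norm)
  key <- ifelse(
    nchar(canon) < 4L,
    paste0("short-token:", canon),
    paste0(substr(canon, 1L, 4L), ":", stemmer(canon))
  )
  groups <- split(norm, key)
  groups <- lapply(groups, function(m) sort(unique(m), method = "radix"))
  smallest <- vapply(groups, `[[`, character(1), 1L)
  groups <- groups[order(smallest, method = "radix")]
  names(groups) <- paste0("C", seq_along(groups))
  new_cluster_vocabulary(groups, clusterer = stemmer_id)
}

#' Load a cluster vocabulary from a cluster file
#'
#' The cluster file is UTF-8 plain text with one cluster per line, members
#' separated by whitespace; `#`-prefixed comment lines and blank lines are
#' ignored. IDs are assigned as `"C"` + the 1-based position of the line
#' among the retained cluster lines. A token occurring in two clusters (also
#' after spelling normalization, since lookup is by canonical form) is a
#' partition violation and raises an error.
#'
#' @param path Path to the cluster file.
#' @return A `cluster_vocabulary` object.
#' @export
load_clusters <- function(path) {
  if (!file.exists(path)) stop_usage(sprintf("cluster file not found: %s", path))
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) stop_data(sprintf("empty cluster file: %s", path))
  members <- lapply(strsplit(lines, "[[:space:]]+"), function(toks) {
    toks <- toks[nzchar(toks)]
    unique(check_vocab_tokens(tolower(toks), "load_clusters"))
  })
  all_raw <- unlist(members, use.names = FALSE)
  dup <- all_raw[duplicated(all_raw)]
  if (length(dup) > 0L) {
    stop_data(sprintf("partition violation: %s", dup[[1L]]))
  }
  names(members) <- paste0("C", seq_along(members))
  new_cluster_vocabulary(members, clusterer = paste0("file:", basename(path)))
}

#' Write a cluster vocabulary to a cluster file
#'
#' Inverse of [load_clusters()]: one cluster per line in cluster-ID order,
#' members space-separated. Reloading reproduces the induced partition
#' exactly (IDs may be renumbered if the vocabulary was built rather than
#' loaded in ID order).
#'
#' @param vocab A `cluster_vocabulary`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_clusters <- function(vocab, path) {
  stopifnot(inherits(vocab, "cluster_vocabulary"))
  ids <- names(vocab$clusters)
  ids <- ids[order(as.integer(sub("^C", "", ids)))]
  lines <- vapply(ids, function(id) paste(vocab$clusters[[id]], collapse = " "),
                  character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Look up the cluster of a token
#'
#' The query is normalized (case folding, letters-only check, spelling
#' normalization) before lookup, so `"hypocalcaemia"` and `"Hypocalcemia"`
#' resolve to the same cluster. Unknown tokens give `NA` (a miss, not an
#' error).
#'
#' @param vocab A `cluster_vocabulary`.
#' @param token Character vector of query tokens.
#' @return Character vector of cluster IDs, `NA` where absent.
#' @export
cluster_of <- function(vocab, token) {
  stopifnot(inherits(vocab, "cluster_vocabulary"))
  env <- attr(vocab, "map_env")
  canon <- normalize_spelling(normalize_token(token))
  vapply(canon, function(t) {
    if (is.na(t)) return(NA_character_)
    get0(t, envir = env, ifnotfound = NA_character_)
  }, character(1), USE.NAMES = FALSE)
}

#' @export
print.cluster_vocabulary <- function(x, ...) {
  sizes <- lengths(x$clusters)
  cat(sprintf(
    "<cluster_vocabulary> %d clusters, %d tokens (clusterer: %s)\n",
    length(x$clusters), length(x$token_to_cluster), x$clusterer
  ))
  cat(sprintf("  cluster sizes: min %d / median %s / max %d\n",
              min(sizes), format(stats::median(sizes)), max(sizes)))
  invisible(x)
}
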