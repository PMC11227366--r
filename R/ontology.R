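#' Parse an ontology's concepts from OBO or obographs JSON
#'
#' Reads the lexical layer of an ontology — concept IDs, labels, synonyms
#' (with their scope), `alt_id`s, obsolescence flags and `replaced_by`
#' pointers — which is all the recognizer uses; no axioms or hierarchy are
#' read. Both the OBO 1.4 flat format and the obographs JSON serialization
#' are supported and yield identical concept lists for the same ontology.
#'
#' @param path Path to the ontology file.
#' @param format `"auto"` (by extension: `.json` means obographs, anything
#'   else OBO), `"obo"`, or `"obographs-json"`.
#' @return An object of class `ontology_concepts`: a list of concepts, each a
#'   list with fields `id`, `label`, `synonyms` (character), `synonym_scopes`
#'   (character, parallel to `synonyms`; `"EXACT"`, `"BROAD"`, ... or `""`
#'   when the format carries none), `alt_ids` (character), `obsolete`
#'   (logical) and `replaced_by` (`NA` or a concept ID). The ontology version
#'   string, when present, is attached as attribute `"version"`.
#' @export
parse_ontology <- function(path, format = c("auto", "obo", "obographs-json")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop_usage(sprintf("ontology file not found: %s", path))
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "obographs-json" else "obo"
  }
  concepts <- switch(format,
    "obo" = parse_obo(path),
    "obographs-json" = parse_obographs(path)
  )
  ids <- vapply(concepts, `[[`, character(1), "id")
  if (anyDuplicated(ids)) {
    stop_data(sprintf("duplicate concept id in ontology: %s",
                      ids[duplicated(ids)][[1L]]))
  }
  obsolete <- vapply(concepts, `[[`, logical(1), "obsolete")
  alt <- unlist(lapply(concepts, `[[`, "alt_ids"), use.names = FALSE)
  clash <- intersect(alt, ids[!obsolete])
  if (length(clash) > 0L) {
    stop_data(sprintf("alt_id collides with a current concept id: %s", clash[[1L]]))
  }
  concepts
}

obo_unquote <- function(line) {
  # first double-quoted string on the line, with \" escapes
  m <- regmatches(line, regexpr('"(\\\\.|[^"\\\\])*"', line))
  if (length(m) == 0L) return(NA_character_)
  inner <- substr(m, 2L, nchar(m) - 1L)
  gsub('\\\\(.)', "\\1", inner)
}

parse_obo <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  version <- NA_character_
  concepts <- list()
  cur <- NULL
  in_term <- FALSE
  flush <- function() {
    if (!is.null(cur) && !is.null(cur$id)) concepts[[length(concepts) + 1L]] <<- cur
    cur <<- NULL
  }
  for (lineno in seq_along(lines)) {
    line <- lines[[lineno]]
    # strip OBO trailing comments (unescaped '!'), then whitespace
    line <- sub("[[:space:]]*(^|[^\\\\])!.*$", "\\1", line)
    line <- trimws(line)
    if (!nzchar(line)) next
    if (startsWith(line, "[")) {
      flush()
      in_term <- identical(line, "[Term]")
      if (in_term) {
        cur <- list(id = NULL, label = NA_character_, synonyms = character(0),
                    synonym_scopes = character(0), alt_ids = character(0),
                    obsolete = FALSE, replaced_by = NA_character_)
      }
      next
    }
    colon <- regexpr(":", line, fixed = TRUE)
    if (colon < 0L) {
      stop_data(sprintf("%s:%d: malformed OBO line: %s", path, lineno, line))
    }
    key <- substr(line, 1L, colon - 1L)
    val <- trimws(substr(line, colon + 1L, nchar(line)))
    if (!in_term) {
      if (key == "data-version") version <- val
      next
    }
    switch(key,
      "id" = { cur$id <- val },
      "name" = { cur$label <- val },
      "synonym" = {
        text <- obo_unquote(val)
        if (is.na(text)) {
          stop_data(sprintf("%s:%d: malformed synonym line", path, lineno))
        }
        rest <- sub('^"(\\\\.|[^"\\\\])*"[[:space:]]*', "", val)
        scope <- regmatches(rest, regexpr("^[A-Z]+", rest))
        cur$synonyms <- c(cur$synonyms, text)
        cur$synonym_scopes <- c(cur$synonym_scopes,
                                if (length(scope)) scope else "")
      },
      "alt_id" = { cur$alt_ids <- c(cur$alt_ids, val) },
      "is_obsolete" = { cur$obsolete <- identical(tolower(val), "true") },
      "replaced_by" = { cur$replaced_by <- val },
      NULL
    )
  }
  flush()
  structure(concepts, class = "ontology_concepts", version = version)
}

iri_to_curie <- function(x) {
  tail <- sub("^.*[/#]", "", x)
  ifelse(grepl("^[A-Za-z0-9]+_[A-Za-z0-9]+$", tail), sub("_", ":", tail), x)
}

parse_obographs <- function(path) {
  doc <- tryCatch(
    jsonlite::fromJSON(path, simplifyVector = FALSE),
    error = function(e) stop_data(sprintf("cannot parse obographs JSON %s: %s",
                                          path, conditionMessage(e)))
  )
  if (is.null(doc$graphs) || length(doc$graphs) == 0L) {
    stop_data(sprintf("%s: no 'graphs' element", path))
  }
  graph <- doc$graphs[[1L]]
  version <- NA_character_
  if (!is.null(graph$meta$version)) version <- graph$meta$version
  concepts <- lapply(graph$nodes, function(node) {
    if (!is.null(node$type) && !identical(node$type, "CLASS")) return(NULL)
    id <- iri_to_curie(node$id)
    syn <- character(0); scope <- character(0)
    alt <- character(0); obsolete <- FALSE; repl <- NA_character_
    meta <- node$meta
    if (!is.null(meta)) {
      for (s in meta$synonyms) {
        syn <- c(syn, s$val)
        pred <- if (is.null(s$pred)) "" else s$pred
        scope <- c(scope, switch(pred,
          hasExactSynonym = "EXACT", hasBroadSynonym = "BROAD",
          hasNarrowSynonym = "NARROW", hasRelatedSynonym = "RELATED", ""))
      }
      for (bpv in meta$basicPropertyValues) {
        p <- bpv$pred
        if (grepl("hasAlternativeId$", p)) alt <- c(alt, bpv$val)
        if (grepl("IAO_0100001$", p)) repl <- iri_to_curie(bpv$val)
      }
      if (isTRUE(meta$deprecated)) obsolete <- TRUE
    }
    list(id = id,
         label = if (is.null(node$lbl)) NA_character_ else node$lbl,
         synonyms = syn, synonym_scopes = scope, alt_ids = alt,
         obsolete = obsolete, replaced_by = repl)
  })
  concepts <- concepts[!vapply(concepts, is.null, logical(1))]
  structure(concepts, class = "ontology_concepts", version = version)
}

#' @export
print.ontology_concepts <- function(x, ...) {
  obs <- sum(vapply(x, `[[`, logical(1), "obsolete"))
  cat(sprintf("<ontology_concepts> %d concepts (%d obsolete), version: %s\n",
              length(x), obs, attr(x, "version")))
  invisible(x)
}
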