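#' Read / write annotation TSV files
#'
#' The interchange format for gold standards and recognizer output: a
#' tab-separated file with header
#' `doc_id  start  end  surface  concept_id` (recognizer output adds
#' `matched_term` and `is_label`). Offsets are 0-based and end-exclusive;
#' `-` marks absent offsets/surfaces (document-level gold).
#'
#' @param path File path.
#' @return `read_gold_tsv`: a data frame with columns `doc_id`, `start`,
#'   `end` (integer, `NA` when absent), `surface`, `concept_id`.
#' @export
read_gold_tsv <- function(path) {
  if (!file.exists(path)) stop_usage(sprintf("gold file not found: %s", path))
  df <- tryCatch(
    utils::read.delim(path, colClasses = "character", quote = "",
                      comment.char = "#", stringsAsFactors = FALSE),
    error = function(e) stop_data(sprintf("cannot parse gold TSV %s: %s",
                                          path, conditionMessage(e)))
  )
  need <- c("doc_id", "start", "end", "surface", "concept_id")
  if (!all(need %in% names(df))) {
    stop_data(sprintf("gold TSV %s lacks columns: %s", path,
                      paste(setdiff(need, names(df)), collapse = ", ")))
  }
  df$start <- suppressWarnings(as.integer(ifelse(df$start == "-", NA, df$start)))
  df$end <- suppressWarnings(as.integer(ifelse(df$end == "-", NA, df$end)))
  df$surface <- ifelse(df$surface == "-", NA_character_, df$surface)
  bad <- !is.na(df$start) & !is.na(df$end) & !(df$start >= 0L & df$start < df$end)
  if (any(bad)) {
    stop_data(sprintf("gold TSV %s: invalid offsets at row %d", path,
                      which(bad)[[1L]]))
  }
  df[, need]
}

#' @rdname read_gold_tsv
#' @param annotations A data frame of mentions or gold annotations.
#' @export
write_mentions_tsv <- function(annotations, path) {
  df <- annotations
  for (col in c("start", "end", "surface")) {
    if (col %in% names(df)) {
      df[[col]] <- ifelse(is.na(df[[col]]), "-", as.character(df[[col]]))
    }
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "-")
  invisible(path)
}

#' Align a gold corpus to an ontology version via alt_id
#'
#' Ontology releases retire concepts, leaving the retired ID behind as an
#' `alt_id` of the subsuming concept (or as an obsolete term with a
#' `replaced_by` pointer). Corpora annotated against an older release must
#' be realigned before scoring, else they point at virtually non-existing
#' concepts. Each gold ID is classified: already a current concept ID
#' (unchanged); found among a current concept's `alt_id`s, or resolvable
#' through an obsolete term's `replaced_by` (replaced); otherwise orphan —
#' reported, and dropped from the aligned set. An `alt_id` claimed by two
#' concepts is an error.
#'
#' @param gold Data frame of gold annotations (see [read_gold_tsv()]).
#' @param concepts An `ontology_concepts` list.
#' @return List with `aligned` (gold rows with updated `concept_id`, orphans
#'   removed) and `report` (list: `replaced` data frame of `old_id`/`new_id`
#'   pairs, `orphans` character vector of unresolvable IDs, `unchanged`
#'   count).
#' @export
align_corpus <- function(gold, concepts) {
  obsolete <- vapply(concepts, `[[`, logical(1), "obsolete")
  ids <- vapply(concepts, `[[`, character(1), "id")
  current <- ids[!obsolete]

  alt_map <- character(0)
  for (c in concepts[!obsolete]) {
    for (a in c$alt_ids) {
      if (!is.null(alt_map[a]) && !is.na(alt_map[a]) && alt_map[[a]] != c$id) {
        stop_data(sprintf("ambiguous alt_id %s claimed by %s and %s",
                          a, alt_map[[a]], c$id))
      }
      alt_map[[a]] <- c$id
    }
  }
  repl_map <- character(0)
  for (c in concepts[obsolete]) {
    if (!is.na(c$replaced_by)) repl_map[[c$id]] <- c$replaced_by
  }

  resolve <- function(id) {
    if (id %in% current) return(c("unchanged", id))
    if (!is.na(alt_map[id])) return(c("replaced", alt_map[[id]]))
    if (!is.na(repl_map[id])) {
      target <- repl_map[[id]]
      if (target %in% current) return(c("replaced", target))
      if (!is.na(alt_map[target])) return(c("replaced", alt_map[[target]]))
    }
    c("orphan", NA_character_)
  }

  status <- character(nrow(gold))
  new_id <- character(nrow(gold))
  for (i in seq_len(nrow(gold))) {
    r <- resolve(gold$concept_id[[i]])
    status[[i]] <- r[[1L]]
    new_id[[i]] <- r[[2L]]
  }
  replaced_rows <- which(status == "replaced")
  report <- list(
    replaced = data.frame(
      old_id = gold$concept_id[replaced_rows],
      new_id = new_id[replaced_rows],
      stringsAsFactors = FALSE
    ),
    orphans = unique(gold$concept_id[status == "orphan"]),
    unchanged = sum(status == "unchanged")
  )
  aligned <- gold[status != "orphan", , drop = FALSE]
  aligned$concept_id <- new_id[status != "orphan"]
  rownames(aligned) <- NULL
  list(aligned = aligned, report = report)
}

new_eval_report <- function(level, tp, fp, fn, extra = list()) {
  precision <- if (tp + fp > 0L) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0L) tp / (tp + fn) else 0
  f1 <- if (precision + recall > 0) 2 * precision * recall / (precision + recall) else 0
  structure(
    c(list(level = level, tp = tp, fp = fp, fn = fn,
           precision = precision, recall = recall, f1 = f1), extra),
    class = "eval_report"
  )
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> %s-level  tp=%d fp=%d fn=%d\n",
              x$level, x$tp, x$fp, x$fn))
  cat(sprintf("  P=%.4f  R=%.4f  F1=%.4f\n", x$precision, x$recall, x$f1))
  invisible(x)
}

doc_sets <- function(df) {
  ids <- unique(df$doc_id)
  stats::setNames(lapply(ids, function(d) {
    unique(df$concept_id[df$doc_id == d])
  }), ids)
}

#' Document-level evaluation
#'
#' Scores presence/absence of concept IDs per document, disregarding
#' boundary detection: per document, gold and predicted annotations are
#' reduced to concept-ID sets and true/false positives and false negatives
#' counted. Counts are micro-averaged by default (summed over documents
#' before computing P/R/F1); macro averaging (mean of per-document scores)
#' is available.
#'
#' @param gold,predicted Data frames with at least `doc_id` and
#'   `concept_id`.
#' @param average `"micro"` (default) or `"macro"`.
#' @return An `eval_report` with a `per_doc` data frame attached.
#' @export
doc_level <- function(gold, predicted, average = c("micro", "macro")) {
  average <- match.arg(average)
  g <- doc_sets(gold)
  p <- doc_sets(predicted)
  docs <- union(names(g), names(p))
  per_doc <- do.call(rbind, lapply(docs, function(d) {
    gs <- g[[d]] %||% character(0)
    ps <- p[[d]] %||% character(0)
    tp <- length(intersect(gs, ps))
    data.frame(doc_id = d, tp = tp, fp = length(ps) - tp,
               fn = length(gs) - tp, stringsAsFactors = FALSE)
  }))
  if (is.null(per_doc)) {
    per_doc <- data.frame(doc_id = character(0), tp = integer(0),
                          fp = integer(0), fn = integer(0))
  }
  report <- new_eval_report("document", sum(per_doc$tp), sum(per_doc$fp),
                            sum(per_doc$fn), extra = list(per_doc = per_doc))
  if (average == "macro" && nrow(per_doc) > 0L) {
    pr <- ifelse(per_doc$tp + per_doc$fp > 0, per_doc$tp / (per_doc$tp + per_doc$fp), 0)
    rc <- ifelse(per_doc$tp + per_doc$fn > 0, per_doc$tp / (per_doc$tp + per_doc$fn), 0)
    f1 <- ifelse(pr + rc > 0, 2 * pr * rc / (pr + rc), 0)
    report$precision <- mean(pr); report$recall <- mean(rc); report$f1 <- mean(f1)
    report$average <- "macro"
  }
  report
}

#' Mention-level evaluation
#'
#' Scores each positioned mention, taking boundary detection into account.
#' Matching is one-to-one and greedy in document order: a predicted mention
#' is a true positive iff some not-yet-consumed gold mention in the same
#' document has the same concept ID and an agreeing span — identical
#' offsets under `span_policy = "exact"`, at least one shared character
#' under `"overlap"`. Unmatched predictions are false positives, unconsumed
#' gold mentions false negatives.
#'
#' @param gold Data frame with `doc_id`, `start`, `end`, `concept_id`;
#'   offsets must be present.
#' @param predicted Data frame of mentions (same columns).
#' @param span_policy `"exact"` (default) or `"overlap"`.
#' @return An `eval_report`.
#' @export
mention_level <- function(gold, predicted, span_policy = c("exact", "overlap")) {
  span_policy <- match.arg(span_policy)
  if (nrow(gold) > 0L && (anyNA(gold$start) || anyNA(gold$end))) {
    stop_data("gold annotations lack offsets; use doc_level() instead")
  }
  tp <- 0L
  docs <- union(unique(gold$doc_id), unique(predicted$doc_id))
  for (d in docs) {
    gd <- gold[gold$doc_id == d, , drop = FALSE]
    gd <- gd[order(gd$start, gd$end, method = "radix"), , drop = FALSE]
    pd <- predicted[predicted$doc_id == d, , drop = FALSE]
    pd <- pd[order(pd$start, pd$end, method = "radix"), , drop = FALSE]
    used <- logical(nrow(gd))
    for (i in seq_len(nrow(pd))) {
      for (j in seq_len(nrow(gd))) {
        if (used[[j]]) next
        if (gd$concept_id[[j]] != pd$concept_id[[i]]) next
        hit <- if (span_policy == "exact") {
          gd$start[[j]] == pd$start[[i]] && gd$end[[j]] == pd$end[[i]]
        } else {
          gd$start[[j]] < pd$end[[i]] && pd$start[[i]] < gd$end[[j]]
        }
        if (hit) {
          used[[j]] <- TRUE
          tp <- tp + 1L
          break
        }
      }
    }
  }
  new_eval_report("mention", tp, nrow(predicted) - tp, nrow(gold) - tp,
                  extra = list(span_policy = span_policy))
}

#' Annotate a corpus and score it against a gold standard
#'
#' End-to-end evaluation protocol: read the corpus, annotate every document
#' with the index, then score against the gold annotations at the requested
#' level. Gold document IDs absent from the corpus are reported with a
#' warning and excluded; corpus documents without gold rows are scored
#' against an empty gold set.
#'
#' @param index A `concept_index`.
#' @param corpus A documents data frame (`id`, `text`), a directory of
#'   `.txt` files, or a JSONL file (see [read_documents()]).
#' @param gold A gold data frame or the path to a gold TSV.
#' @param level `"document"` or `"mention"`.
#' @param span_policy Passed to [mention_level()].
#' @param policy,window_cap Passed to [annotate_corpus()].
#' @return An `eval_report` with `per_doc` breakdown (document level) plus
#'   attributes `mentions` (the predictions) and `counters`.
#' @export
evaluate_run <- function(index, corpus, gold, level = c("document", "mention"),
                         span_policy = c("exact", "overlap"),
                         policy = c("all", "longest"), window_cap = 10L) {
  level <- match.arg(level)
  if (is.character(corpus)) corpus <- read_documents(corpus)
  if (is.character(gold)) gold <- read_gold_tsv(gold)
  missing_docs <- setdiff(unique(gold$doc_id), corpus$id)
  if (length(missing_docs) > 0L) {
    warning(sprintf("gold references %d document(s) absent from the corpus (excluded): %s",
                    length(missing_docs), paste(missing_docs, collapse = ", ")))
    gold <- gold[!(gold$doc_id %in% missing_docs), , drop = FALSE]
  }
  run <- annotate_corpus(corpus, index, policy = policy, window_cap = window_cap)
  report <- if (level == "document") {
    doc_level(gold, run$mentions)
  } else {
    mention_level(gold, run$mentions, span_policy = span_policy)
  }
  attr(report, "mentions") <- run$mentions
  attr(report, "counters") <- run$counters
  report
}

#' Read a corpus of documents
#'
#' Accepts either a directory of plain-text files (one document per file,
#' the file name minus extension is the document ID) or a JSONL file with
#' one `{"id": ..., "text": ...}` object per line. Unreadable entries are
#' skipped with a warning.
#'
#' @param path Directory or JSONL file path.
#' @return Data frame with columns `id` and `text`.
#' @export
read_documents <- function(path) {
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.txt$", full.names = TRUE))
    if (length(files) == 0L) stop_data(sprintf("no .txt documents in %s", path))
    texts <- character(0); ids <- character(0)
    for (f in files) {
      txt <- tryCatch(paste(readLines(f, warn = FALSE, encoding = "UTF-8"),
                            collapse = "\n"),
                      error = function(e) NULL)
      if (is.null(txt)) {
        warning(sprintf("skipping unreadable document: %s", f))
        next
      }
      ids <- c(ids, sub("\\.txt$", "", basename(f)))
      texts <- c(texts, txt)
    }
    return(data.frame(id = ids, text = texts, stringsAsFactors = FALSE))
  }
  if (!file.exists(path)) stop_usage(sprintf("corpus not found: %s", path))
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop_data(sprintf("empty corpus file: %s", path))
  ids <- character(0); texts <- character(0)
  for (k in seq_along(lines)) {
    obj <- tryCatch(jsonlite::fromJSON(lines[[k]], simplifyVector = TRUE),
                    error = function(e) NULL)
    if (is.null(obj) || is.null(obj$id) || is.null(obj$text)) {
      warning(sprintf("%s:%d: skipping malformed JSONL entry", path, k))
      next
    }
    ids <- c(ids, as.character(obj$id))
    texts <- c(texts, as.character(obj$text))
  }
  if (length(ids) == 0L) stop_data(sprintf("no readable documents in %s", path))
  data.frame(id = ids, text = texts, stringsAsFactors = FALSE)
}
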