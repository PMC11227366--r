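#' Normalize a raw token to a letters-only lowercase form
#'
#' The cluster vocabulary is defined over "proper words": tokens formed of
#' letters only. `normalize_token()` lowercases its input and returns `NA`
#' (a miss, not an error) for anything that still contains a non-letter
#' character, or is empty, after case folding. The operation is idempotent.
#'
#' @param raw Character vector of raw tokens.
#' @return Character vector of the same length; lowercase letters-only tokens,
#'   with `NA_character_` where the input is not a proper word.
#' @examples
#' normalize_token(c("Short", "C3-positive", "Haemorrhage"))
#' @export
normalize_token <- function(raw) {
  stopifnot(is.character(raw))
  low <- tolower(raw)
  ok <- grepl("^[a-z]+$", low)
  low[!ok] <- NA_character_
  low
}

# Ordered British -> American substitution table. Kept deliberately small and
# pinned: the medical digraphs are what phenotype vocabulary actually varies
# on (anaemia/anemia, oedema/edema, haemorrhage/hemorrhage, ...).
.spelling_table <- c(ae = "e", oe = "e")

#' Collapse localized (British/American) spelling variants
#'
#' Applies a fixed, ordered substitution table (`ae -> e`, `oe -> e`) to a
#' fixed point, so that e.g. `"hypocalcaemia"` and `"hypocalcemia"`, or
#' `"haemorrhage"` and `"hemorrhage"`, map to one canonical form. Running the
#' table to a fixed point makes the operation idempotent even on stacked
#' digraphs.
#'
#' @param token Character vector of normalized (lowercase, letters-only)
#'   tokens. `NA`s pass through.
#' @return Character vector of canonical spellings.
#' @examples
#' normalize_spelling(c("hypocalcaemia", "haemorrhage", "hemorrhage"))
#' @export
normalize_spelling <- function(token) {
  stopifnot(is.character(token))
  out <- token
  repeat {
    prev <- out
    for (i in seq_along(.spelling_table)) {
      out <- gsub(names(.spelling_table)[i], .spelling_table[[i]], out,
                  fixed = TRUE)
    }
    if (identical(out, prev)) break
  }
  out
}
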