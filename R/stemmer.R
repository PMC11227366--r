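# Suffix rules tried in order; a rule fires only if the replacement leaves a
# stem of >= 4 characters (the prefix-group width), then the scan restarts.
# "y" -> "i" is terminal (no rule matches a trailing "i"), so the loop halts.
.suffix_rules <- c(
  ization = "",  isation = "",  ations = "",  ation = "",
  ities   = "",  ity     = "",  iness = "",   ness  = "",
  ments   = "",  ment    = "",  ingly = "",   ing   = "",
  ies     = "i", ied     = "i", edly  = "",   ed    = "",
  est     = "",  ers     = "",  er    = "",   en    = "",
  ely     = "",  ly      = "",  ous   = "",   ive   = "",
  ful     = "",  ic      = "",  al    = "",   um    = "",
  es      = "",  s       = "",  e     = "",   y     = "i"
)

#' Deterministic iterative suffix stemmer
#'
#' The default stemming strategy behind [build_clusters()]. It repeatedly
#' strips (or rewrites) a fixed, ordered table of English inflectional and
#' derivational suffixes, refusing any step that would leave fewer than four
#' characters, until no rule applies. The table is tuned so that whole
#' derivational families sharing a 4-letter prefix collapse to one stem:
#' `short`, `shorter`, `shorten` and `shortening` all stem to `"short"`,
#' while `shore` stems to `"shor"` and stays separate. Classic algorithmic
#' stemmers are more conservative than that (they leave `shorter` intact),
#' which is why this aggressive-within-a-prefix-group variant is the pinned
#' default; any `function(character) -> character` can be supplied instead.
#'
#' A bare trailing `"s"` is never stripped off a double-s ending
#' (`shortness` loses `ness`, not `s`).
#'
#' @param token Character vector of lowercase letters-only tokens; `NA`s pass
#'   through.
#' @return Character vector of stems.
#' @examples
#' suffix_stem(c("short", "shorter", "shorten", "shortening", "shore"))
#' @export
suffix_stem <- function(token) {
  stopifnot(is.character(token))
  vapply(token, function(t) {
    if (is.na(t)) return(NA_character_)
    repeat {
      fired <- FALSE
      for (i in seq_along(.suffix_rules)) {
        suf <- names(.suffix_rules)[i]
        rep <- .suffix_rules[[i]]
        ns <- nchar(suf)
        nt <- nchar(t)
        if (nt > ns && substr(t, nt - ns + 1L, nt) == suf) {
          if (suf == "s" && substr(t, nt - 1L, nt - 1L) == "s") next
          cand <- paste0(substr(t, 1L, nt - ns), rep)
          if (nchar(cand) >= 4L) {
            t <- cand
            fired <- TRUE
            break
          }
        }
      }
      if (!fired) break
    }
    t
  }, character(1), USE.NAMES = FALSE)
}
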