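#' Parse a taxon query string
#'
#' Queries are either one word (a genus or higher rank, e.g. `"Lecudina"`)
#' or two words (a species binomial, e.g. `"Lecudina longissima"`).
#' Comparison is case-insensitive: the tokens are lowercased, so
#' `"X y"` and `"x Y"` parse to equal queries.
#'
#' @param raw Query string as typed by the user.
#' @return An object of class `taxon_query` with fields `raw` (the input),
#'   `tokens` (1 or 2 lowercase tokens) and `rank_hint` (`"monomial"` or
#'   `"binomial"`).
#' @examples
#' parse_taxon_query("Lecudina")
#' parse_taxon_query("Lecudina longissima")
#' @export
parse_taxon_query <- function(raw) {
  if (!is.character(raw) || length(raw) != 1L || is.na(raw)) {
    stop("empty query: the taxon must be a single character string",
         call. = FALSE)
  }
  trimmed <- trimws(raw)
  if (!nzchar(trimmed)) {
    stop("empty query", call. = FALSE)
  }
  tokens <- tolower(strsplit(trimmed, "\\s+")[[1L]])
  if (length(tokens) > 2L) {
    stop("unsupported query arity: expected 1 or 2 words, got ",
         length(tokens), call. = FALSE)
  }
  structure(
    list(
      raw = raw,
      tokens = tokens,
      rank_hint = if (length(tokens) == 2L) "binomial" else "monomial"
    ),
    class = "taxon_query"
  )
}

#' @export
print.taxon_query <- function(x, ...) {
  cat("<taxon_query> ", paste(x$tokens, collapse = " "),
      " (", x$rank_hint, ")\n", sep = "")
  invisible(x)
}

# two-word comparison form for binomials, single token for monomials
query_comparison_form <- function(query) {
  paste(query$tokens, collapse = " ")
}
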