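#' Tokenize post text
#'
#' Splits text into word tokens after Unicode NFC normalization and case
#' folding. A `#` immediately followed by word characters forms a single
#' hashtag token; all other punctuation and whitespace is a boundary. Token
#' order follows text order.
#'
#' @param text Character vector.
#' @return A list of character vectors, one per input string (a bare
#'   character vector when `text` has length one).
#' @export
#' @examples
#' tokenize_text("Vaccines CAUSE Harm")      # "vaccines" "cause" "harm"
#' tokenize_text("#VaxInjury is real")       # "#vaxinjury" "is" "real"
tokenize_text <- function(text) {
  text <- stringi::stri_trans_nfc(text)
  text <- stringi::stri_trans_tolower(text)
  toks <- stringi::stri_extract_all_regex(
    text, "#[\\p{L}\\p{N}_]+|[\\p{L}\\p{N}_]+",
    omit_no_match = TRUE
  )
  if (length(toks) == 1) toks[[1]] else toks
}

normalize_terms <- function(terms) {
  if (is.null(terms) || length(terms) == 0) return(character())
  terms <- stringi::stri_trans_tolower(stringi::stri_trans_nfc(terms))
  terms <- stringi::stri_trim_both(terms)
  terms <- unique(terms[nzchar(terms)])
  sort(terms)
}

#' Define a boolean keyword query
#'
#' The collection dialect has three term roles. A *standalone* term collects
#' a post on any mention. *Concurrent* terms are a pair rule: a post is
#' collected when any anchor term (abbreviated vaccine term) co-occurs with
#' any context term (health condition or vaccine-discourse term). *Exclusion*
#' terms veto collection globally, whatever positive rule fired. With
#' `auto_hashtag_variants`, every single-word term also matches its
#' `#`-prefixed hashtag form.
#'
#' Term presence means the term's token sequence occurs contiguously in the
#' tokenized text (word-level semantics, not substring: `"vax"` does not
#' match `"vaxxers"`).
#'
#' @param standalone Character vector of standalone terms (may be multi-word).
#' @param concurrent_anchor,concurrent_context Character vectors for the
#'   concurrent pair rule. Context terms without any anchor term is a
#'   configuration error (detected at compile time).
#' @param exclusion Character vector of veto terms.
#' @param auto_hashtag_variants Also match `#term` for single-word terms?
#'   Default `TRUE`.
#' @return An object of class `vx_query_spec`.
#' @export
#' @examples
#' query_spec(standalone = "measles", exclusion = "rabies")
query_spec <- function(standalone = character(),
                       concurrent_anchor = character(),
                       concurrent_context = character(),
                       exclusion = character(),
                       auto_hashtag_variants = TRUE) {
  spec <- structure(
    list(
      standalone = normalize_terms(standalone),
      concurrent_anchor = normalize_terms(concurrent_anchor),
      concurrent_context = normalize_terms(concurrent_context),
      exclusion = normalize_terms(exclusion),
      auto_hashtag_variants = isTRUE(auto_hashtag_variants)
    ),
    class = "vx_query_spec"
  )
  positive <- c(spec$standalone, spec$concurrent_anchor, spec$concurrent_context)
  clash <- intersect(positive, spec$exclusion)
  if (length(clash) > 0) {
    stop("term(s) listed both as positive and exclusion: ",
         paste(clash, collapse = ", "), call. = FALSE)
  }
  spec
}

#' @export
print.vx_query_spec <- function(x, ...) {
  cat(sprintf(
    "<vx_query_spec> %d standalone, %d anchor, %d context, %d exclusion terms (hashtag variants %s)\n",
    length(x$standalone), length(x$concurrent_anchor),
    length(x$concurrent_context), length(x$exclusion),
    if (x$auto_hashtag_variants) "on" else "off"
  ))
  invisible(x)
}

# Expand hashtag variants and tokenize each term into its token sequence.
# Matching is implemented on a sentinel-joined token string: the post's
# tokens are joined with "\x1f" and padded, and a term is present iff its
# own sentinel-joined sequence occurs as a substring. This is exactly
# contiguous-token-sequence matching.
compile_role <- function(terms, hashtags) {
  if (hashtags) {
    single <- terms[!stringi::stri_detect_fixed(terms, " ") &
                      !stringi::stri_startswith_fixed(terms, "#")]
    terms <- unique(c(terms, paste0("#", single)))
  }
  seqs <- lapply(terms, function(tm) tokenize_text(tm))
  seqs <- seqs[vapply(seqs, length, 1L) > 0]
  needles <- vapply(seqs, function(s) {
    paste0("\x1f", paste(s, collapse = "\x1f"), "\x1f")
  }, character(1))
  unique(needles)
}

#' Compile a keyword query
#'
#' Normalizes, deduplicates, and expands hashtag variants, producing a
#' matcher usable with [match_query()] and [collect_posts()]. Compilation is
#' deterministic: compiling the same spec twice yields identical matchers.
#'
#' @param spec A [query_spec()].
#' @return An object of class `vx_compiled_query`.
#' @export
compile_query <- function(spec) {
  stopifnot(inherits(spec, "vx_query_spec"))
  if (length(spec$concurrent_context) > 0 && length(spec$concurrent_anchor) == 0) {
    stop("concurrent context terms present but anchor set is empty", call. = FALSE)
  }
  if (length(spec$concurrent_anchor) > 0 && length(spec$concurrent_context) == 0) {
    stop("concurrent anchor terms present but context set is empty", call. = FALSE)
  }
  hv <- spec$auto_hashtag_variants
  structure(
    list(
      standalone = compile_role(spec$standalone, hv),
      concurrent_anchor = compile_role(spec$concurrent_anchor, hv),
      concurrent_context = compile_role(spec$concurrent_context, hv),
      exclusion = compile_role(spec$exclusion, hv),
      spec = spec
    ),
    class = "vx_compiled_query"
  )
}

# sentinel-joined token string for each text
token_haystack <- function(text) {
  toks <- stringi::stri_extract_all_regex(
    stringi::stri_trans_tolower(stringi::stri_trans_nfc(text)),
    "#[\\p{L}\\p{N}_]+|[\\p{L}\\p{N}_]+",
    omit_no_match = TRUE
  )
  vapply(toks, function(t) paste0("\x1f", paste(t, collapse = "\x1f"), "\x1f"),
         character(1))
}

any_term_present <- function(haystacks, needles) {
  if (length(needles) == 0) return(rep(FALSE, length(haystacks)))
  out <- rep(FALSE, length(haystacks))
  for (nd in needles) {
    rest <- !out
    if (!any(rest)) break
    out[rest] <- stringi::stri_detect_fixed(haystacks[rest], nd)
  }
  out
}

#' Match posts against a compiled query
#'
#' A text matches iff (any standalone term is present, or an anchor term and
#' a context term are both present) and no exclusion term is present.
#'
#' @param text Character vector of post texts.
#' @param query A [compile_query()] result.
#' @return Logical vector, one element per text.
#' @export
match_query <- function(text, query) {
  stopifnot(inherits(query, "vx_compiled_query"))
  hay <- token_haystack(text)
  pos <- any_term_present(hay, query$standalone)
  if (length(query$concurrent_anchor) > 0) {
    conc <- any_term_present(hay, query$concurrent_anchor) &
      any_term_present(hay, query$concurrent_context)
    pos <- pos | conc
  }
  pos & !any_term_present(hay, query$exclusion)
}

#' Collect the sub-corpus matching a query
#'
#' @param x A `vx_corpus`.
#' @param query A `vx_compiled_query` (a `vx_query_spec` is compiled on the
#'   fly).
#' @return A `vx_corpus` restricted to matching posts, order preserved.
#' @export
collect_posts <- function(x, query) {
  stopifnot(inherits(x, "vx_corpus"))
  if (inherits(query, "vx_query_spec")) query <- compile_query(query)
  keep <- match_query(x$posts$text, query)
  out <- x
  out$posts <- x$posts[keep, ]
  out
}

#' Expanded term inventory of a compiled query
#'
#' Lists every matcher pattern after normalization, deduplication and
#' hashtag-variant expansion, by role — the `compile-check` view of a query.
#'
#' @param query A `vx_compiled_query`.
#' @return A tibble with columns `role` and `term`.
#' @export
query_inventory <- function(query) {
  stopifnot(inherits(query, "vx_compiled_query"))
  role_terms <- function(role) {
    gsub("\x1f", " ", gsub("^\x1f|\x1f$", "", query[[role]]))
  }
  roles <- c("standalone", "concurrent_anchor", "concurrent_context", "exclusion")
  dplyr::bind_rows(lapply(roles, function(r) {
    tibble::tibble(role = r, term = role_terms(r))
  }))
}

#' Read or write a query rulebook (YAML)
#'
#' A rulebook file holds the opposition [query_spec()] plus the theme and
#' misinformation rule sets in a single YAML document with top-level keys
#' `opposition`, `themes` and `misinfo`.
#'
#' @param path YAML file.
#' @return For `read_rulebook`, a list with elements `opposition`
#'   (`vx_query_spec`), `themes` (list of [theme_rule()]), `misinfo` (list of
#'   [misinfo_rule()]).
#' @export
read_rulebook <- function(path) {
  doc <- yaml::read_yaml(path)
  spec_from <- function(q) {
    query_spec(
      standalone = unlist(q$standalone),
      concurrent_anchor = unlist(q$concurrent_anchor),
      concurrent_context = unlist(q$concurrent_context),
      exclusion = unlist(q$exclusion),
      auto_hashtag_variants = !isFALSE(q$auto_hashtag_variants)
    )
  }
  list(
    opposition = spec_from(doc$opposition),
    themes = lapply(doc$themes, function(t) {
      theme_rule(t$theme, spec_from(t$query))
    }),
    misinfo = lapply(doc$misinfo, function(m) {
      misinfo_rule(m$category, m$parent_theme, spec_from(m$query))
    })
  )
}

#' @rdname read_rulebook
#' @param rulebook A list as returned by [read_rulebook()] or
#'   [emit_rulebook()].
#' @export
write_rulebook <- function(rulebook, path) {
  spec_to <- function(s) {
    list(
      standalone = as.list(s$standalone),
      concurrent_anchor = as.list(s$concurrent_anchor),
      concurrent_context = as.list(s$concurrent_context),
      exclusion = as.list(s$exclusion),
      auto_hashtag_variants = s$auto_hashtag_variants
    )
  }
  doc <- list(
    opposition = spec_to(rulebook$opposition),
    themes = lapply(rulebook$themes, function(t) {
      list(theme = t$theme, query = spec_to(t$query))
    }),
    misinfo = lapply(rulebook$misinfo, function(m) {
      list(category = m$category, parent_theme = m$parent_theme,
           query = spec_to(m$query))
    })
  )
  yaml::write_yaml(doc, path)
  invisible(path)
}
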