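#' Theme and misinformation rules
#'
#' A theme rule names one conversation theme (e.g. negative health effects,
#' pharmaceutical industry, vaccine ingredients) and carries the keyword
#' query whose match assigns that theme. A misinformation rule names a
#' misinformation category nested under a parent theme; a post receives the
#' category only if it carries the parent theme *and* matches the category
#' query (parent gating).
#'
#' @param theme,category Rule name (unique within its rule set).
#' @param parent_theme Theme under which a misinformation category nests.
#' @param query A [query_spec()].
#' @return A `vx_theme_rule` / `vx_misinfo_rule`.
#' @export
theme_rule <- function(theme, query) {
  stopifnot(is.character(theme), length(theme) == 1, nzchar(theme),
            inherits(query, "vx_query_spec"))
  structure(list(theme = theme, query = query), class = "vx_theme_rule")
}

#' @rdname theme_rule
#' @export
misinfo_rule <- function(category, parent_theme, query) {
  stopifnot(is.character(category), length(category) == 1, nzchar(category),
            is.character(parent_theme), length(parent_theme) == 1,
            inherits(query, "vx_query_spec"))
  structure(list(category = category, parent_theme = parent_theme, query = query),
            class = "vx_misinfo_rule")
}

check_theme_rules <- function(rules) {
  stopifnot(length(rules) > 0,
            all(vapply(rules, inherits, TRUE, "vx_theme_rule")))
  nm <- vapply(rules, `[[`, "", "theme")
  if (anyDuplicated(nm)) {
    stop("duplicate theme name(s): ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "), call. = FALSE)
  }
  nm
}

#' Isolate the vaccine-opposition sub-corpus
#'
#' Applies the opposition keyword query to a collected corpus. Every
#' downstream analysis (theme tagging, top-author ranking, group comparison)
#' operates on this sub-corpus only.
#'
#' @param x A `vx_corpus` (typically the output of [collect_posts()] under
#'   the master vaccine-conversation query).
#' @param opposition_query A `vx_query_spec` or `vx_compiled_query`.
#' @return A `vx_corpus` of opposition posts, order preserved.
#' @export
filter_opposition <- function(x, opposition_query) {
  collect_posts(x, opposition_query)
}

#' Tag posts with conversation themes (multi-label)
#'
#' Each post receives every theme whose query matches its text; a post may
#' carry several themes or none. Retweets are tagged from their own text.
#'
#' @param x A `vx_corpus` of opposition posts.
#' @param rules List of [theme_rule()]s with unique names.
#' @return A tibble (class `vx_tagged`): the post columns plus `opposition`
#'   (logical, all `TRUE` here), `themes` (list column of character vectors)
#'   and `misinfo` (list column of `"theme/category"` strings, empty until
#'   [tag_misinformation()]).
#' @export
tag_themes <- function(x, rules) {
  stopifnot(inherits(x, "vx_corpus"))
  theme_names <- check_theme_rules(rules)
  p <- x$posts
  hits <- matrix(FALSE, nrow = nrow(p), ncol = length(rules),
                 dimnames = list(NULL, theme_names))
  for (j in seq_along(rules)) {
    cq <- compile_query(rules[[j]]$query)
    hits[, j] <- match_query(p$text, cq)
  }
  p$opposition <- rep(TRUE, nrow(p))
  p$themes <- lapply(seq_len(nrow(p)), function(i) theme_names[hits[i, ]])
  p$misinfo <- rep(list(character()), nrow(p))
  class(p) <- c("vx_tagged", class(p))
  p
}

#' Tag misinformation categories within themes
#'
#' A category is assigned only to posts that carry its parent theme and
#' match its query. Tags are recorded as `"parent_theme/category"` strings in
#' the `misinfo` list column.
#'
#' @param tagged A `vx_tagged` tibble from [tag_themes()].
#' @param rules List of [misinfo_rule()]s; every `parent_theme` must exist
#'   among the themes used for tagging (checked against the tags present
#'   plus `known_themes`).
#' @param known_themes Character vector of valid theme names (defaults to
#'   the union of themes present in `tagged`).
#' @return `tagged` with the `misinfo` column filled in.
#' @export
tag_misinformation <- function(tagged, rules,
                               known_themes = unique(unlist(tagged$themes))) {
  stopifnot(inherits(tagged, "vx_tagged"))
  if (length(rules) == 0) return(tagged)
  stopifnot(all(vapply(rules, inherits, TRUE, "vx_misinfo_rule")))
  parents <- vapply(rules, `[[`, "", "parent_theme")
  unknown <- setdiff(parents, known_themes)
  if (length(unknown) > 0) {
    stop("misinfo rule(s) reference unknown parent theme(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  mi <- tagged$misinfo
  for (r in rules) {
    cq <- compile_query(r$query)
    has_parent <- vapply(tagged$themes, function(th) r$parent_theme %in% th, TRUE)
    idx <- which(has_parent)
    if (length(idx) == 0) next
    hit <- idx[match_query(tagged$text[idx], cq)]
    tag <- paste0(r$parent_theme, "/", r$category)
    for (i in hit) mi[[i]] <- c(mi[[i]], tag)
  }
  tagged$misinfo <- lapply(mi, function(v) sort(unique(v)))
  tagged
}

#' Per-theme post counts
#'
#' @param tagged A `vx_tagged` tibble.
#' @param themes Theme inventory (defaults to themes present).
#' @return Named integer vector of post counts per theme.
#' @export
theme_counts <- function(tagged, themes = sort(unique(unlist(tagged$themes)))) {
  all_tags <- unlist(tagged$themes)
  vapply(themes, function(t) sum(all_tags == t), integer(1))
}

#' Theme saturation check
#'
#' During iterative theme creation, a newly created theme covering less than
#' 1% of the opposition conversation signals saturation: stop creating new
#' themes. The threshold is strict (`count/total < threshold`): a theme at
#' exactly 1% is not saturated.
#'
#' @param counts Named numeric vector of per-theme post counts.
#' @param total_opposition Total opposition posts (denominator, > 0).
#' @param threshold Saturation fraction, default `0.01`.
#' @return Named logical vector: `TRUE` where the theme is saturated.
#' @export
#' @examples
#' saturation_check(c(a = 9, b = 10), total_opposition = 1000)
saturation_check <- function(counts, total_opposition, threshold = 0.01) {
  if (!is.numeric(total_opposition) || total_opposition <= 0) {
    stop("total_opposition must be a positive count", call. = FALSE)
  }
  stats::setNames(counts / total_opposition < threshold, names(counts))
}

#' Theme coverage of the opposition conversation
#'
#' Fraction of opposition posts carrying at least one theme.
#'
#' @param tagged A nonempty `vx_tagged` tibble.
#' @return A fraction in `[0, 1]`.
#' @export
theme_coverage <- function(tagged) {
  if (nrow(tagged) == 0) {
    stop("coverage is undefined on an empty tagged set", call. = FALSE)
  }
  mean(vapply(tagged$themes, length, 1L) > 0)
}

#' Export tagged posts
#'
#' `write_tagged_jsonl()` writes one object per post with the post fields
#' plus `opposition`, `themes` and `misinfo` arrays. `tagged_long()` returns
#' the long-format (post_id, theme) table, suitable for CSV export.
#'
#' @param tagged A `vx_tagged` tibble.
#' @param path Output file.
#' @return The path (writer) or a tibble (`tagged_long`).
#' @export
write_tagged_jsonl <- function(tagged, path) {
  lines <- vapply(seq_len(nrow(tagged)), function(i) {
    rec <- as.list(tagged[i, setdiff(names(tagged), c("themes", "misinfo"))])
    rec$timestamp <- format_iso8601(rec$timestamp)
    if (is.na(rec$retweet_of)) rec$retweet_of <- NULL
    rec$themes <- tagged$themes[[i]]
    rec$misinfo <- tagged$misinfo[[i]]
    jsonlite::toJSON(rec, auto_unbox = TRUE, null = "null")
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_tagged_jsonl
#' @export
tagged_long <- function(tagged) {
  n_each <- vapply(tagged$themes, length, 1L)
  tibble::tibble(
    post_id = rep(tagged$post_id, n_each),
    theme = unlist(tagged$themes)
  )
}
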