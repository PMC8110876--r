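#' Draw a random validation sample for manual coding
#'
#' Uniform sampling without replacement, seeded for reproducibility
#' (Mersenne-Twister; the algorithm identifier is recorded in the result).
#' Retweets can be excluded from the eligible pool: manual coders skip them
#' because their text typically duplicates the original.
#'
#' @param x A `vx_corpus`.
#' @param n Sample size (at most the eligible pool size).
#' @param seed Integer RNG seed.
#' @param exclude_retweets Drop retweets before sampling? Default `TRUE`.
#' @return A `vx_validation_sample`: list with `sample` (tibble of sampled
#'   posts), `seed`, `exclude_retweets`, `rng`.
#' @export
draw_sample <- function(x, n, seed, exclude_retweets = TRUE) {
  stopifnot(inherits(x, "vx_corpus"))
  pool <- x$posts
  if (exclude_retweets) pool <- pool[!pool$is_retweet, ]
  if (n > nrow(pool)) {
    stop("requested sample of ", n, " exceeds eligible pool of ", nrow(pool),
         call. = FALSE)
  }
  idx <- withr::with_seed(seed, sample.int(nrow(pool), n),
                          .rng_kind = "Mersenne-Twister")
  structure(
    list(sample = pool[idx, ], seed = as.integer(seed),
         exclude_retweets = exclude_retweets, rng = "Mersenne-Twister"),
    class = "vx_validation_sample"
  )
}

#' @export
print.vx_validation_sample <- function(x, ...) {
  cat(sprintf("<vx_validation_sample> n=%d, seed=%d, retweets %s (%s)\n",
              nrow(x$sample), x$seed,
              if (x$exclude_retweets) "excluded" else "included", x$rng))
  invisible(x)
}

#' Export / re-ingest a manual-coding sheet
#'
#' The sample is written as a two-column CSV (`post_id`, `text`) plus an
#' empty `label` column for the coder; completed sheets are read back as a
#' named label vector.
#'
#' @param sample A `vx_validation_sample`.
#' @param path CSV file.
#' @return `read_manual_labels()` returns a character vector of labels named
#'   by `post_id`.
#' @export
write_coding_sheet <- function(sample, path) {
  readr::write_csv(
    tibble::tibble(post_id = sample$sample$post_id,
                   text = sample$sample$text,
                   label = ""),
    path, progress = FALSE
  )
  invisible(path)
}

#' @rdname write_coding_sheet
#' @export
read_manual_labels <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                        progress = FALSE)
  stats::setNames(df$label, df$post_id)
}

# Canonical form of a label set: multi-labels may arrive as "a;b" strings or
# list elements; compare as sorted sets.
normalize_label <- function(x) {
  if (is.list(x)) {
    vapply(x, function(v) paste(sort(unique(as.character(v))), collapse = ";"),
           character(1))
  } else {
    vapply(strsplit(as.character(x), ";", fixed = TRUE),
           function(v) paste(sort(unique(trimws(v))), collapse = ";"),
           character(1))
  }
}

#' Precision gate for an automated keyword query
#'
#' Compares automated labels with manual labels on the audited posts. The
#' query is approved when the fraction coded correctly reaches `threshold`
#' (default 0.90, inclusive: 90 correct of 100 passes).
#'
#' @param auto_labels,manual_labels Labels named by `post_id`; character
#'   vectors or lists of label sets. Manual keys must be a subset of auto
#'   keys and nonempty.
#' @param threshold Approval threshold, default `0.90`.
#' @param strict Require precision strictly above the threshold? Default
#'   `FALSE` (gate passes at exactly the threshold).
#' @return A `vx_precision_report`: list with `n_checked`, `n_correct`,
#'   `precision`, `threshold`, `passed`.
#' @export
#' @examples
#' a <- stats::setNames(rep("opposition", 10), paste0("p", 1:10))
#' m <- a; m[1] <- "other"
#' precision_gate(a, m)
precision_gate <- function(auto_labels, manual_labels, threshold = 0.90,
                           strict = FALSE) {
  ids <- names(manual_labels)
  if (length(ids) == 0) {
    stop("precision is undefined without manually checked posts", call. = FALSE)
  }
  missing_ids <- setdiff(ids, names(auto_labels))
  if (length(missing_ids) > 0) {
    stop("manual label(s) without automated counterpart: ",
         paste(utils::head(missing_ids, 5), collapse = ", "), call. = FALSE)
  }
  auto <- normalize_label(auto_labels[ids])
  manual <- normalize_label(manual_labels)
  n_correct <- sum(auto == manual)
  precision <- n_correct / length(ids)
  structure(
    list(
      n_checked = length(ids), n_correct = n_correct, precision = precision,
      threshold = threshold,
      passed = if (strict) precision > threshold else precision >= threshold
    ),
    class = "vx_precision_report"
  )
}

#' @export
print.vx_precision_report <- function(x, ...) {
  cat(sprintf("<vx_precision_report> %d/%d correct (%.1f%%), threshold %.0f%%: %s\n",
              x$n_correct, x$n_checked, 100 * x$precision, 100 * x$threshold,
              if (x$passed) "PASSED" else "FAILED"))
  invisible(x)
}

#' Write a precision report as JSON
#' @param report A `vx_precision_report`.
#' @param path Output file.
#' @export
write_precision_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Intercoder agreement
#'
#' Proportion of cross-coded posts on which two coders assigned identical
#' label sets (exact set equality; no partial credit). Symmetric in its
#' arguments. Coding is conventionally accepted when agreement exceeds 0.90.
#'
#' @param labels_a,labels_b Labels named by `post_id`; the key sets must
#'   coincide and be nonempty.
#' @return Fraction in `[0, 1]`.
#' @export
intercoder_agreement <- function(labels_a, labels_b) {
  ka <- names(labels_a); kb <- names(labels_b)
  if (length(ka) == 0 || length(kb) == 0) {
    stop("agreement is undefined on empty label maps", call. = FALSE)
  }
  if (!setequal(ka, kb) || length(ka) != length(kb)) {
    stop("coders labeled different post sets; keys must align", call. = FALSE)
  }
  a <- normalize_label(labels_a[ka])
  b <- normalize_label(labels_b[ka])
  mean(a == b)
}

#' Top-engagement posts within a theme
#'
#' The `n` posts of a theme with the highest interaction count (likes +
#' comments + shares), in descending order; ties broken by ascending
#' `post_id`. Used to select the high-visibility review set when defining
#' misinformation categories.
#'
#' @param tagged A `vx_tagged` tibble.
#' @param theme Theme name (must occur in the tag inventory supplied via
#'   `known_themes`).
#' @param n Number of posts to return (fewer if the theme is smaller).
#' @param known_themes Valid theme names, defaulting to those present.
#' @return A tibble of posts, ordered.
#' @export
top_engaged <- function(tagged, theme, n = 200,
                        known_themes = unique(unlist(tagged$themes))) {
  if (!theme %in% known_themes) {
    stop("unknown theme: ", theme, call. = FALSE)
  }
  has <- vapply(tagged$themes, function(th) theme %in% th, TRUE)
  sub <- tagged[has, ]
  sub$.interactions <- interaction_count(sub)
  ord <- order(-sub$.interactions, sub$post_id)
  sub <- sub[utils::head(ord, n), ]
  sub$.interactions <- NULL
  sub
}
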