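#' Post record columns
#'
#' Column order and types of the canonical post table used throughout the
#' package. Every reader, writer and pipeline stage preserves this schema.
#'
#' @format A character vector of column names.
#' @keywords internal
POST_COLUMNS <- c(
  "post_id", "author_id", "text", "timestamp", "is_retweet", "retweet_of",
  "likes", "comments", "shares", "author_followers"
)

#' Construct a post corpus
#'
#' A corpus bundles a table of post records with the half-open collection
#' window `[window_start, window_end)`. Posts are tweets or retweets with
#' engagement metadata (likes, comments, shares) and the author's follower
#' count at collection time.
#'
#' @param posts A data frame with columns `post_id`, `author_id`, `text`,
#'   `timestamp` (POSIXct, UTC), `is_retweet`, `retweet_of` (NA for original
#'   posts), `likes`, `comments`, `shares`, `author_followers`.
#' @param window_start,window_end UTC datetimes delimiting the collection
#'   window as a half-open interval. Defaults to the 2019 surveillance window
#'   (2019-06-01 to 2019-12-01, six calendar months).
#' @param validate Check invariants (unique ids, retweet linkage consistency,
#'   nonnegative counts)? Default `TRUE`.
#'
#' @return An object of class `vx_corpus`: a list with elements `posts`
#'   (tibble), `window_start`, `window_end`.
#' @export
#' @examples
#' corpus(tibble::tibble(
#'   post_id = "t1", author_id = "a1", text = "hello",
#'   timestamp = as.POSIXct("2019-07-04 12:00:00", tz = "UTC"),
#'   is_retweet = FALSE, retweet_of = NA_character_,
#'   likes = 1L, comments = 0L, shares = 2L, author_followers = 10L
#' ))
corpus <- function(posts,
                   window_start = as.POSIXct("2019-06-01 00:00:00", tz = "UTC"),
                   window_end = as.POSIXct("2019-12-01 00:00:00", tz = "UTC"),
                   validate = TRUE) {
  posts <- tibble::as_tibble(posts)
  missing_cols <- setdiff(POST_COLUMNS, names(posts))
  if (length(missing_cols) > 0) {
    stop("posts is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  posts <- posts[POST_COLUMNS]
  posts$post_id <- as.character(posts$post_id)
  posts$author_id <- as.character(posts$author_id)
  posts$text <- as.character(posts$text)
  posts$retweet_of <- as.character(posts$retweet_of)
  posts$is_retweet <- as.logical(posts$is_retweet)
  for (col in c("likes", "comments", "shares", "author_followers")) {
    posts[[col]] <- as.integer(posts[[col]])
  }
  attr(posts$timestamp, "tzone") <- "UTC"
  obj <- structure(
    list(posts = posts, window_start = window_start, window_end = window_end),
    class = "vx_corpus"
  )
  if (validate) validate_corpus(obj)
  obj
}

#' Validate corpus invariants
#'
#' Checks that post ids are unique, retweet flags agree with retweet linkage
#' (`is_retweet` true iff `retweet_of` set, never self-referential), every
#' resolvable `retweet_of` points at an original (non-retweet) post, and all
#' counts are nonnegative. Retweets whose original falls outside the corpus
#' are legitimate (vendor feeds capture retweets independently) and are only
#' reported via the returned summary.
#'
#' @param x A `vx_corpus`.
#' @return Invisibly, a list with `n_posts` and `n_unresolved_retweets`.
#' @export
validate_corpus <- function(x) {
  stopifnot(inherits(x, "vx_corpus"))
  p <- x$posts
  if (anyDuplicated(p$post_id)) {
    dup <- unique(p$post_id[duplicated(p$post_id)])
    stop("duplicate post_id: ", paste(utils::head(dup, 5), collapse = ", "),
         call. = FALSE)
  }
  if (any(p$is_retweet != !is.na(p$retweet_of))) {
    stop("is_retweet must be TRUE exactly when retweet_of is set", call. = FALSE)
  }
  if (any(!is.na(p$retweet_of) & p$retweet_of == p$post_id)) {
    stop("retweet_of must not equal post_id", call. = FALSE)
  }
  counts <- as.matrix(p[c("likes", "comments", "shares", "author_followers")])
  if (anyNA(counts) || any(counts < 0)) {
    stop("likes/comments/shares/author_followers must be nonnegative integers",
         call. = FALSE)
  }
  resolvable <- !is.na(p$retweet_of) & p$retweet_of %in% p$post_id
  if (any(resolvable)) {
    target_is_rt <- p$is_retweet[match(p$retweet_of[resolvable], p$post_id)]
    if (any(target_is_rt)) {
      stop("retweet_of must point at an original (non-retweet) post",
           call. = FALSE)
    }
  }
  invisible(list(
    n_posts = nrow(p),
    n_unresolved_retweets = sum(!is.na(p$retweet_of)) - sum(resolvable)
  ))
}

#' @export
print.vx_corpus <- function(x, ...) {
  cat(sprintf(
    "<vx_corpus> %d posts (%d retweets), window [%s, %s)\n",
    nrow(x$posts), sum(x$posts$is_retweet),
    format(x$window_start, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
    format(x$window_end, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  ))
  invisible(x)
}

#' Number of posts in a corpus
#' @param x A `vx_corpus`.
#' @return Integer post count.
#' @export
n_posts <- function(x) nrow(x$posts)

# Parse ISO-8601 timestamps; accepts trailing 'Z' or numeric offsets
# (+hh:mm / +hhmm), converting everything to UTC.
parse_iso8601 <- function(x) {
  x0 <- x
  x <- stringi::stri_replace_last_regex(x, "Z$", "+0000")
  x <- stringi::stri_replace_last_regex(x, "([+-]\\d{2}):(\\d{2})$", "$1$2")
  # bare timestamps (no offset) are taken as UTC
  bare <- !stringi::stri_detect_regex(x, "[+-]\\d{4}$")
  x[bare] <- paste0(x[bare], "+0000")
  out <- as.POSIXct(strptime(x, "%Y-%m-%dT%H:%M:%S%z", tz = "UTC"))
  if (anyNA(out) & !all(is.na(x0))) {
    bad <- which(is.na(out) & !is.na(x0))
    stop("unparseable timestamp at record(s) ",
         paste(utils::head(bad, 5), collapse = ", "),
         ": ", x0[bad[1]], call. = FALSE)
  }
  attr(out, "tzone") <- "UTC"
  out
}

format_iso8601 <- function(x) format(x, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")

#' Read a post corpus from JSON Lines or CSV
#'
#' JSONL carries one post object per line; CSV is RFC-4180 with a header row.
#' Timestamps must be ISO-8601; offsets are converted to UTC. Records missing
#' a required field or with duplicate `post_id` abort ingestion with the
#' offending line numbers.
#'
#' @param path File to read.
#' @param format `"jsonl"` or `"csv"`; default guessed from the extension.
#' @param window_start,window_end Optional collection window passed to
#'   [corpus()]. When `filter_window = TRUE`, posts outside
#'   `[window_start, window_end)` are dropped.
#' @param filter_window Drop posts outside the window? Default `FALSE`.
#' @return A `vx_corpus`, in file order.
#' @export
read_posts <- function(path, format = c("guess", "jsonl", "csv"),
                       window_start = as.POSIXct("2019-06-01 00:00:00", tz = "UTC"),
                       window_end = as.POSIXct("2019-12-01 00:00:00", tz = "UTC"),
                       filter_window = FALSE) {
  format <- match.arg(format)
  if (format == "guess") {
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "jsonl"
  }
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "jsonl") {
    lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
    lines <- lines[nzchar(lines)]
    if (length(lines) == 0) {
      df <- empty_posts()
    } else {
      recs <- lapply(seq_along(lines), function(i) {
        rec <- tryCatch(jsonlite::fromJSON(lines[[i]]),
                        error = function(e) NULL)
        if (is.null(rec)) stop("malformed JSON at line ", i, call. = FALSE)
        need <- setdiff(POST_COLUMNS, c(names(rec), "retweet_of"))
        if (length(need) > 0) {
          stop("line ", i, ": missing required field(s): ",
               paste(need, collapse = ", "), call. = FALSE)
        }
        tibble::tibble(
          post_id = as.character(rec$post_id),
          author_id = as.character(rec$author_id),
          text = as.character(rec$text),
          timestamp_raw = as.character(rec$timestamp),
          is_retweet = as.logical(rec$is_retweet),
          retweet_of = if (is.null(rec$retweet_of)) NA_character_ else as.character(rec$retweet_of),
          likes = as.integer(rec$likes),
          comments = as.integer(rec$comments),
          shares = as.integer(rec$shares),
          author_followers = as.integer(rec$author_followers)
        )
      })
      df <- dplyr::bind_rows(recs)
    }
  } else {
    df <- readr::read_csv(
      path,
      col_types = readr::cols(
        post_id = readr::col_character(),
        author_id = readr::col_character(),
        text = readr::col_character(),
        timestamp = readr::col_character(),
        is_retweet = readr::col_logical(),
        retweet_of = readr::col_character(),
        likes = readr::col_integer(),
        comments = readr::col_integer(),
        shares = readr::col_integer(),
        author_followers = readr::col_integer()
      ),
      na = "",
      trim_ws = FALSE,
      progress = FALSE
    )
    need <- setdiff(POST_COLUMNS, names(df))
    if (length(need) > 0) {
      stop("CSV is missing required column(s): ", paste(need, collapse = ", "),
           call. = FALSE)
    }
    df$text[is.na(df$text)] <- ""
    names(df)[names(df) == "timestamp"] <- "timestamp_raw"
  }
  if (nrow(df) > 0) {
    df$timestamp <- parse_iso8601(df$timestamp_raw)
    df$timestamp_raw <- NULL
  } else {
    df <- empty_posts()
  }
  out <- corpus(df, window_start = window_start, window_end = window_end)
  if (filter_window && nrow(out$posts) > 0) {
    keep <- out$posts$timestamp >= window_start & out$posts$timestamp < window_end
    out$posts <- out$posts[keep, ]
  }
  out
}

empty_posts <- function() {
  tibble::tibble(
    post_id = character(), author_id = character(), text = character(),
    timestamp = as.POSIXct(character(), tz = "UTC"),
    is_retweet = logical(), retweet_of = character(),
    likes = integer(), comments = integer(), shares = integer(),
    author_followers = integer()
  )
}

#' Write a post corpus to JSON Lines or CSV
#'
#' Inverse of [read_posts()]: `read_posts(write_posts(c))` reproduces the
#' corpus field-for-field. Timestamps are serialized as ISO-8601 UTC with a
#' trailing `Z`; `retweet_of` is `null`/empty for original posts.
#'
#' @param x A `vx_corpus`.
#' @param path Output file.
#' @param format `"jsonl"` or `"csv"`; default guessed from the extension.
#' @return `path`, invisibly.
#' @export
write_posts <- function(x, path, format = c("guess", "jsonl", "csv")) {
  stopifnot(inherits(x, "vx_corpus"))
  format <- match.arg(format)
  if (format == "guess") {
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "jsonl"
  }
  p <- x$posts
  p$timestamp <- format_iso8601(p$timestamp)
  if (format == "jsonl") {
    if (nrow(p) == 0) {
      writeLines(character(), path, useBytes = TRUE)
    } else {
      lines <- vapply(seq_len(nrow(p)), function(i) {
        rec <- as.list(p[i, ])
        if (is.na(rec$retweet_of)) rec$retweet_of <- NULL
        jsonlite::toJSON(rec, auto_unbox = TRUE, null = "null")
      }, character(1))
      writeLines(lines, path, useBytes = TRUE)
    }
  } else {
    readr::write_csv(p, path, na = "", progress = FALSE)
  }
  invisible(path)
}
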