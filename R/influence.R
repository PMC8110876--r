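#' Interaction count of a post
#'
#' An interaction is a like, a comment, or a share; a post's interaction
#' count is their sum.
#'
#' @param x A post table (any data frame with `likes`, `comments`, `shares`)
#'   or a `vx_corpus`.
#' @return Integer vector of per-post interaction counts.
#' @export
#' @examples
#' interaction_count(tibble::tibble(likes = 3L, comments = 2L, shares = 5L))
interaction_count <- function(x) {
  if (inherits(x, "vx_corpus")) x <- x$posts
  as.integer(x$likes + x$comments + x$shares)
}

utc_month <- function(timestamp) format(timestamp, "%Y-%m", tz = "UTC")

#' Monthly top-author registry
#'
#' For each calendar month (UTC) of the corpus, authors are ranked by total
#' interactions received on their opposition posts that month, descending;
#' ties are broken by post count (descending) then `author_id` (ascending).
#' The top `k` authors per month are ranked 1..k. The registry aggregates
#' the union of all monthly top authors and each member's persistence
#' (months ranked).
#'
#' Interactions on a retweet accrue to the retweet's own author; share
#' events on the original already live in the original's `shares` count.
#'
#' @param x A `vx_corpus` of opposition posts.
#' @param k Ranking depth per month, default 50.
#' @param deny_list Author ids to exclude before ranking (manual screening
#'   of mockery/news accounts).
#' @return A `vx_registry`: list with `by_month` (tibble: month, rank,
#'   author_id, interactions, n_posts), `union` (character), `months_as_top`
#'   (named integer), `k`.
#' @export
monthly_top_authors <- function(x, k = 50, deny_list = NULL) {
  stopifnot(inherits(x, "vx_corpus"))
  p <- x$posts
  if (!is.null(deny_list)) p <- p[!p$author_id %in% deny_list, ]
  stats <- tibble::tibble(
    month = utc_month(p$timestamp),
    author_id = p$author_id,
    interactions = interaction_count(p)
  )
  stats <- dplyr::summarise(
    dplyr::group_by(stats, .data$month, .data$author_id),
    interactions = sum(.data$interactions),
    n_posts = dplyr::n(),
    .groups = "drop"
  )
  stats <- dplyr::arrange(
    stats, .data$month, dplyr::desc(.data$interactions),
    dplyr::desc(.data$n_posts), .data$author_id
  )
  stats <- dplyr::mutate(dplyr::group_by(stats, .data$month),
                         rank = dplyr::row_number())
  by_month <- dplyr::ungroup(dplyr::filter(stats, .data$rank <= k))
  by_month <- by_month[c("month", "rank", "author_id", "interactions", "n_posts")]
  months_as_top <- table(by_month$author_id)
  structure(
    list(
      by_month = by_month,
      union = sort(unique(by_month$author_id)),
      months_as_top = stats::setNames(as.integer(months_as_top),
                                      names(months_as_top)),
      k = k
    ),
    class = "vx_registry"
  )
}

#' @export
print.vx_registry <- function(x, ...) {
  cat(sprintf("<vx_registry> top-%d by month: %d months, %d distinct top authors\n",
              x$k, length(unique(x$by_month$month)), length(x$union)))
  invisible(x)
}

#' Write a top-author registry
#'
#' CSV columns: month, rank, author_id, interactions, n_posts. The JSON form
#' additionally carries the union and persistence map.
#'
#' @param registry A `vx_registry`.
#' @param path Output file (`.csv` or `.json`).
#' @export
write_registry <- function(registry, path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(
      list(k = registry$k, by_month = registry$by_month,
           union = registry$union,
           months_as_top = as.list(registry$months_as_top)),
      path, auto_unbox = TRUE, digits = NA
    )
  } else {
    readr::write_csv(registry$by_month, path, progress = FALSE)
  }
  invisible(path)
}

#' Potential impressions of an original post
#'
#' Followers of the post's author plus the followers of every account that
#' shared (retweeted) it.
#'
#' @param post A one-row post table (the original).
#' @param sharers Post table of retweets of `post` (may be empty). Every
#'   `retweet_of` must equal `post$post_id`.
#' @return Integer impression count.
#' @export
#' @examples
#' orig <- tibble::tibble(post_id = "p", author_followers = 100L)
#' rts <- tibble::tibble(post_id = c("r1", "r2"), retweet_of = "p",
#'                       author_followers = c(10L, 5L))
#' potential_impressions(orig, rts)  # 115
potential_impressions <- function(post, sharers = NULL) {
  stopifnot(nrow(post) == 1)
  total <- as.numeric(post$author_followers)
  if (!is.null(sharers) && nrow(sharers) > 0) {
    if (any(is.na(sharers$retweet_of) | sharers$retweet_of != post$post_id)) {
      stop("sharer(s) are not retweets of post ", post$post_id, call. = FALSE)
    }
    total <- total + sum(as.numeric(sharers$author_followers))
  }
  total
}

#' Total potential impressions attributable to a set of authors
#'
#' Sums [potential_impressions()] over every original post by the given
#' authors, resolving sharers within the corpus.
#'
#' @param x A `vx_corpus`.
#' @param authors Author ids (e.g. `registry$union`).
#' @return Numeric total.
#' @export
total_impressions <- function(x, authors) {
  p <- x$posts
  originals <- p[!p$is_retweet & p$author_id %in% authors, ]
  if (nrow(originals) == 0) return(0)
  rts <- p[p$is_retweet & !is.na(p$retweet_of), ]
  shared <- tapply(as.numeric(rts$author_followers), rts$retweet_of, sum)
  extra <- shared[originals$post_id]
  extra[is.na(extra)] <- 0
  sum(as.numeric(originals$author_followers)) + sum(extra)
}

#' Partition tagged posts into top-author and general-opposition groups
#'
#' @param tagged A `vx_tagged` tibble (or any post table with `author_id`).
#' @param registry A `vx_registry` from [monthly_top_authors()].
#' @return List with `top` and `other`, a two-set partition of the input.
#' @export
partition_by_top_authors <- function(tagged, registry) {
  stopifnot(inherits(registry, "vx_registry"))
  is_top <- tagged$author_id %in% registry$union
  list(top = tagged[is_top, ], other = tagged[!is_top, ])
}
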