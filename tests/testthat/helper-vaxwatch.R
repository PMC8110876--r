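# Shared fixtures and independent oracles. Everything is built in code; no
# stored binary fixtures.

utc <- function(x) as.POSIXct(x, tz = "UTC")

utc_month_test <- function(ts) format(ts, "%Y-%m", tz = "UTC")

make_posts <- function(n = 3, text = paste("post number", seq_len(n)),
                       author = rep("a1", n),
                       timestamp = utc("2019-07-01 12:00:00") + seq_len(n) * 3600,
                       is_retweet = rep(FALSE, n),
                       retweet_of = rep(NA_character_, n),
                       likes = seq_len(n), comments = rep(0L, n),
                       shares = rep(0L, n), followers = rep(10L, n)) {
  tibble::tibble(
    post_id = sprintf("p%03d", seq_len(n)), author_id = author, text = text,
    timestamp = timestamp, is_retweet = is_retweet, retweet_of = retweet_of,
    likes = as.integer(likes), comments = as.integer(comments),
    shares = as.integer(shares), author_followers = as.integer(followers)
  )
}

make_corpus <- function(...) corpus(make_posts(...))

# --- naive query oracle -----------------------------------------------------
# Term presence by explicit position-by-position token scanning, with its own
# hashtag expansion; shares only tokenize_text() with the implementation.

oracle_term_present <- function(tokens, term) {
  term_toks <- tokenize_text(term)
  if (is.list(term_toks)) term_toks <- term_toks[[1]]
  k <- length(term_toks)
  if (k == 0 || length(tokens) < k) return(FALSE)
  for (s in seq_len(length(tokens) - k + 1)) {
    if (all(tokens[s:(s + k - 1)] == term_toks)) return(TRUE)
  }
  FALSE
}

oracle_expand <- function(terms) {
  single <- terms[!grepl(" ", terms) & !startsWith(terms, "#")]
  unique(c(terms, paste0("#", single)))
}

oracle_match <- function(text, spec) {
  tokens <- tokenize_text(text)
  if (is.list(tokens)) tokens <- tokens[[1]]
  pres <- function(terms) {
    if (length(terms) == 0) return(FALSE)
    if (spec$auto_hashtag_variants) terms <- oracle_expand(terms)
    any(vapply(terms, function(t) oracle_term_present(tokens, t), TRUE))
  }
  pos <- pres(spec$standalone) ||
    (pres(spec$concurrent_anchor) && pres(spec$concurrent_context))
  pos && !pres(spec$exclusion)
}

oracle_collect_ids <- function(corp, spec) {
  hit <- vapply(corp$posts$text, function(tx) oracle_match(tx, spec), TRUE,
                USE.NAMES = FALSE)
  corp$posts$post_id[hit]
}

# --- random instances for property tests ------------------------------------

random_words <- function(n, rng_words = c(
    "alpha", "bravo", "charlie", "delta", "echo", "foxtrot", "golf", "hotel",
    "india", "juliet", "kilo", "lima", "mike", "november", "oscar", "papa",
    "quebec", "romeo", "sierra", "tango")) {
  sample(rng_words, n, replace = TRUE)
}

random_query_spec <- function(vocab_size = 12) {
  vocab <- unique(random_words(vocab_size))
  roles <- split(vocab, sample(1:4, length(vocab), replace = TRUE,
                               prob = c(0.4, 0.2, 0.2, 0.2)))
  mk <- function(x) if (is.null(x)) character() else x
  standalone <- mk(roles[["1"]])
  anchor <- mk(roles[["2"]])
  context <- mk(roles[["3"]])
  exclusion <- setdiff(mk(roles[["4"]]),
                       c(standalone, anchor, context))
  if (length(context) > 0 && length(anchor) == 0) context <- character()
  if (length(anchor) > 0 && length(context) == 0) anchor <- character()
  query_spec(standalone = standalone, concurrent_anchor = anchor,
             concurrent_context = context, exclusion = exclusion,
             auto_hashtag_variants = sample(c(TRUE, FALSE), 1))
}

random_text <- function(n_tokens = 8) {
  words <- random_words(n_tokens)
  hash <- runif(n_tokens) < 0.15
  words[hash] <- paste0("#", words[hash])
  up <- runif(n_tokens) < 0.2
  words[up] <- toupper(words[up])
  paste(words, collapse = " ")
}

random_corpus <- function(n = 40) {
  corpus(make_posts(n, text = vapply(seq_len(n), function(i) random_text(), "")))
}

# --- small tagged fixture ----------------------------------------------------

tiny_rulebook <- function() {
  list(
    opposition = query_spec(standalone = c("badvax", "harm claim"),
                            exclusion = "petcare"),
    themes = list(
      theme_rule("death", query_spec(standalone = "deadly")),
      theme_rule("autism", query_spec(standalone = "autism"))
    ),
    misinfo = list(
      misinfo_rule("deaths", "death", query_spec(standalone = "body count"))
    )
  )
}
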