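month_corpus <- function() {
  # three authors over two months; b dominates interactions in both
  p <- make_posts(
    6,
    author = c("a", "b", "c", "a", "b", "b"),
    timestamp = utc(c("2019-06-05 10:00:00", "2019-06-10 10:00:00",
                      "2019-06-20 10:00:00", "2019-07-05 10:00:00",
                      "2019-07-06 10:00:00", "2019-07-07 10:00:00")),
    likes = c(1, 50, 3, 2, 40, 10), comments = c(0, 5, 0, 0, 2, 1),
    shares = c(0, 5, 1, 0, 3, 0))
  corpus(p)
}

test_that("interaction count is likes + comments + shares", {
  expect_equal(interaction_count(tibble::tibble(likes = 0L, comments = 0L,
                                                shares = 0L)), 0L)
  expect_equal(interaction_count(tibble::tibble(likes = 3L, comments = 2L,
                                                shares = 5L)), 10L)
  corp <- month_corpus()
  expect_equal(sum(interaction_count(corp)),
               sum(corp$posts$likes) + sum(corp$posts$comments) +
                 sum(corp$posts$shares))
})

test_that("monthly ranking orders by interactions, breaks ties deterministically", {
  reg <- monthly_top_authors(month_corpus(), k = 50)
  jun <- reg$by_month[reg$by_month$month == "2019-06", ]
  expect_equal(jun$author_id, c("b", "c", "a"))
  expect_equal(jun$rank, 1:3)
  expect_equal(jun$interactions[1], 60)
  jul <- reg$by_month[reg$by_month$month == "2019-07", ]
  expect_equal(jul$author_id[1], "b")
  expect_equal(jul$n_posts[1], 2)
  expect_setequal(reg$union, c("a", "b", "c"))
  expect_equal(reg$months_as_top[["b"]], 2)
  # ties: equal interactions and posts resolve by author_id ascending
  p <- make_posts(2, author = c("zed", "ann"), likes = c(5, 5))
  r2 <- monthly_top_authors(corpus(p), k = 1)
  expect_equal(r2$by_month$author_id, "ann")
})

test_that("k truncates rankings and the union is monotone in k", {
  corp <- month_corpus()
  r1 <- monthly_top_authors(corp, k = 1)
  r2 <- monthly_top_authors(corp, k = 2)
  r3 <- monthly_top_authors(corp, k = 50)
  expect_true(all(r1$union %in% r2$union))
  expect_true(all(r2$union %in% r3$union))
  expect_true(all(r1$by_month$rank <= 1))
  # no author appears twice within one month
  by_m <- split(r3$by_month$author_id, r3$by_month$month)
  expect_true(all(vapply(by_m, function(x) !anyDuplicated(x), TRUE)))
})

test_that("ranking is invariant to input order and honors the deny list", {
  corp <- month_corpus()
  perm <- corpus(corp$posts[c(4, 1, 6, 3, 2, 5), ])
  expect_equal(monthly_top_authors(perm, k = 2)$by_month,
               monthly_top_authors(corp, k = 2)$by_month)
  denied <- monthly_top_authors(corp, k = 50, deny_list = "b")
  expect_false("b" %in% denied$union)
})

test_that("a dominant planted author is top in all its months", {
  cfg <- sim_config(n_posts = 3000, n_influencers = 1, n_authors = 100,
                    influencer_share = 0.3, retweet_prob = 0)
  sim <- simulate_corpus(cfg, seed = 5)
  rb <- emit_rulebook(cfg)
  opp <- filter_opposition(sim$corpus, rb$opposition)
  reg <- monthly_top_authors(opp, k = 50)
  months_active <- unique(utc_month_test(opp$posts$timestamp[
    opp$posts$author_id == "inf0001"]))
  tops <- reg$by_month[reg$by_month$rank == 1, ]
  expect_true(all(tops$author_id[tops$month %in% months_active] == "inf0001"))
})

test_that("monthly rankings agree with a full-sort oracle on synthetic data", {
  cfg <- sim_config(n_posts = 4000)
  sim <- simulate_corpus(cfg, seed = 6)
  rb <- emit_rulebook(cfg)
  opp <- filter_opposition(sim$corpus, rb$opposition)
  k <- 20
  reg <- monthly_top_authors(opp, k = k)
  p <- opp$posts
  p$month <- utc_month_test(p$timestamp)
  p$inter <- p$likes + p$comments + p$shares
  for (m in unique(p$month)) {
    sub <- p[p$month == m, ]
    agg <- stats::aggregate(cbind(inter = sub$inter,
                                  npost = rep(1, nrow(sub))),
                            by = list(author_id = sub$author_id), FUN = sum)
    agg <- agg[order(-agg$inter, -agg$npost, agg$author_id), ]
    expect_equal(reg$by_month$author_id[reg$by_month$month == m],
                 utils::head(agg$author_id, k))
  }
})

test_that("potential impressions add sharer followers to the author's", {
  orig <- tibble::tibble(post_id = "p", author_followers = 100L)
  expect_equal(potential_impressions(orig), 100)
  rts <- tibble::tibble(post_id = c("r1", "r2"), retweet_of = "p",
                        author_followers = c(10L, 5L))
  expect_equal(potential_impressions(orig, rts), 115)
  bad <- tibble::tibble(post_id = "r3", retweet_of = "q", author_followers = 1L)
  expect_error(potential_impressions(orig, bad), "not retweets")
})

test_that("registry-level impressions match a brute-force sum", {
  cfg <- sim_config(n_posts = 2000)
  sim <- simulate_corpus(cfg, seed = 9)
  authors <- attr(sim, "influencers")[1:10]
  p <- sim$corpus$posts
  brute <- 0
  for (i in which(!p$is_retweet & p$author_id %in% authors)) {
    sharers <- p[!is.na(p$retweet_of) & p$retweet_of == p$post_id[i], ]
    brute <- brute + potential_impressions(p[i, ], sharers)
  }
  expect_equal(total_impressions(sim$corpus, authors), brute)
})

test_that("partition by top authors is a two-set partition of the input", {
  corp <- month_corpus()
  tg <- tag_themes(corp, list(theme_rule("any", query_spec(standalone = "post"))))
  reg <- monthly_top_authors(corp, k = 1)
  parts <- partition_by_top_authors(tg, reg)
  expect_equal(nrow(parts$top) + nrow(parts$other), nrow(tg))
  expect_length(intersect(parts$top$post_id, parts$other$post_id), 0)
  expect_true(all(parts$top$author_id %in% reg$union))
  empty_reg <- reg
  empty_reg$union <- character(0)
  parts0 <- partition_by_top_authors(tg, empty_reg)
  expect_equal(nrow(parts0$top), 0)
  expect_equal(nrow(parts0$other), nrow(tg))
})

test_that("registry exports to CSV and JSON", {
  reg <- monthly_top_authors(month_corpus(), k = 2)
  pc <- withr::local_tempfile(fileext = ".csv")
  pj <- withr::local_tempfile(fileext = ".json")
  write_registry(reg, pc)
  write_registry(reg, pj)
  back <- readr::read_csv(pc, col_types = "cicii", progress = FALSE)
  expect_equal(nrow(back), nrow(reg$by_month))
  j <- jsonlite::fromJSON(pj)
  expect_equal(j$k, 2)
  expect_setequal(j$union, reg$union)
})
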