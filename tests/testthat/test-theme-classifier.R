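opposition_fixture <- function() {
  corpus(make_posts(6, text = c(
    "badvax stories and the deadly stuff plus autism talk",   # both themes
    "badvax again, purely deadly material",                   # death only
    "harm claim with autism mentioned",                       # autism only
    "plain badvax message with nothing else",                 # no theme
    "deadly body count badvax post",                          # death + misinfo
    "body count but badvax only otherwise"                    # misinfo kw, no theme
  )))
}

test_that("opposition filtering is a subset, idempotent, and excludes vetoed posts", {
  rb <- tiny_rulebook()
  corp <- corpus(make_posts(4, text = c(
    "badvax rant", "harm claim here", "badvax petcare advice", "nothing at all")))
  opp <- filter_opposition(corp, rb$opposition)
  expect_equal(opp$posts$post_id, c("p001", "p002"))
  expect_true(all(opp$posts$post_id %in% corp$posts$post_id))
  expect_equal(filter_opposition(opp, rb$opposition)$posts, opp$posts)
})

test_that("theme tagging is multi-label and per-theme counts equal collect counts", {
  rb <- tiny_rulebook()
  opp <- opposition_fixture()
  tg <- tag_themes(opp, rb$themes)
  expect_setequal(tg$themes[[1]], c("death", "autism"))
  expect_equal(tg$themes[[2]], "death")
  expect_equal(tg$themes[[4]], character(0))
  counts <- theme_counts(tg, c("death", "autism"))
  for (rule in rb$themes) {
    expect_equal(unname(counts[rule$theme]),
                 n_posts(collect_posts(opp, rule$query)))
  }
  # multi-label percentages may sum past 100 of the themed-post denominator
  n_themed <- sum(vapply(tg$themes, length, 1L) > 0)
  expect_gt(sum(theme_proportions(tg, c("death", "autism"),
                                  denominator = n_themed)$percent), 100)
})

test_that("theme tagging equals per-rule collect on a random corpus (oracle)", {
  set.seed(33)
  rules <- list(theme_rule("t_alpha", query_spec(standalone = "alpha")),
                theme_rule("t_brav", query_spec(standalone = c("bravo", "echo"))))
  corp <- random_corpus(300)
  tg <- tag_themes(corp, rules)
  for (rule in rules) {
    with_theme <- tg$post_id[vapply(tg$themes, function(x) rule$theme %in% x, TRUE)]
    expect_equal(with_theme, collect_posts(corp, rule$query)$posts$post_id)
  }
})

test_that("duplicate theme names are a configuration error", {
  expect_error(
    tag_themes(opposition_fixture(),
               list(theme_rule("x", query_spec(standalone = "a")),
                    theme_rule("x", query_spec(standalone = "b")))),
    "duplicate theme")
})

test_that("misinformation tags are gated on the parent theme", {
  rb <- tiny_rulebook()
  tg <- tag_misinformation(tag_themes(opposition_fixture(), rb$themes),
                           rb$misinfo)
  expect_equal(tg$misinfo[[5]], "death/deaths")     # parent present + match
  expect_equal(tg$misinfo[[6]], character(0))       # match but no parent theme
  expect_equal(tg$misinfo[[1]], character(0))       # parent but no match
  # misinfo tags always sit under a theme the post carries
  for (i in seq_len(nrow(tg))) {
    parents <- sub("/.*$", "", tg$misinfo[[i]])
    expect_true(all(parents %in% tg$themes[[i]]))
  }
})

test_that("a misinfo rule with an unknown parent theme is rejected", {
  rb <- tiny_rulebook()
  tg <- tag_themes(opposition_fixture(), rb$themes)
  bad <- list(misinfo_rule("c", "no-such-theme", query_spec(standalone = "x")))
  expect_error(tag_misinformation(tg, bad, known_themes = c("death", "autism")),
               "unknown parent")
})

test_that("tagging is deterministic and order-independent", {
  rb <- tiny_rulebook()
  opp <- opposition_fixture()
  perm <- c(4, 2, 6, 1, 5, 3)
  shuffled <- opp
  shuffled$posts <- opp$posts[perm, ]
  tg <- tag_misinformation(tag_themes(opp, rb$themes), rb$misinfo)
  tg_perm <- tag_misinformation(tag_themes(shuffled, rb$themes), rb$misinfo)
  expect_equal(tg_perm$post_id, tg$post_id[perm])
  expect_equal(tg_perm$themes, tg$themes[perm])
  expect_equal(tg_perm$misinfo, tg$misinfo[perm])
})

test_that("saturation uses a strict 1% threshold", {
  out <- saturation_check(c(low = 9, edge = 10, high = 11), 1000)
  expect_equal(out, c(low = TRUE, edge = FALSE, high = FALSE))
  expect_error(saturation_check(c(a = 1), 0), "positive")
  # no published theme sits under the threshold of the whole conversation
  ref <- published_reference()
  sat <- saturation_check(
    stats::setNames(ref$counts$count_top + ref$counts$count_other,
                    ref$counts$theme),
    ref$denominator_top + ref$denominator_other)
  expect_false(any(sat))
})

test_that("coverage is the fraction of posts with at least one theme", {
  rb <- tiny_rulebook()
  tg <- tag_themes(opposition_fixture(), rb$themes)
  expect_equal(theme_coverage(tg), 4 / 6)
  all_themed <- tg[vapply(tg$themes, length, 1L) > 0, ]
  expect_equal(theme_coverage(all_themed), 1.0)
  expect_error(theme_coverage(tg[0, ]), "empty")
})

test_that("coverage recovers a planted single-theme rate of 75% at n = 5000", {
  vocab <- default_vocabulary()
  cfg <- sim_config(
    n_posts = 5000, opposition_rate = 1, retweet_prob = 0,
    theme_mix_top = c(health_effects = 0.75),
    theme_mix_other = c(health_effects = 0.75),
    misinfo_mix = list(), vocabulary = vocab)
  sim <- simulate_corpus(cfg, seed = 11)
  rb <- emit_rulebook(cfg)
  tg <- tag_themes(filter_opposition(sim$corpus, rb$opposition), rb$themes)
  expect_equal(theme_coverage(tg), 0.75, tolerance = 0.02 / 0.75)
})

test_that("planted opposition fraction is recovered within 3 points at n = 5000", {
  cfg <- sim_config(n_posts = 5000)
  sim <- simulate_corpus(cfg, seed = 12)
  rb <- emit_rulebook(cfg)
  opp <- filter_opposition(sim$corpus, rb$opposition)
  expect_lt(abs(n_posts(opp) / n_posts(sim$corpus) - 0.4), 0.03)
})

test_that("misinfo category proportions within a theme recover planted rates", {
  cfg <- sim_config(n_posts = 5000)
  sim <- simulate_corpus(cfg, seed = 13)
  rb <- emit_rulebook(cfg)
  opp <- filter_opposition(sim$corpus, rb$opposition)
  tg <- tag_misinformation(tag_themes(opp, rb$themes), rb$misinfo,
                           known_themes = names(cfg$theme_mix_top))
  has_theme <- vapply(tg$themes, function(x) "health_effects" %in% x, TRUE)
  frac <- mean(vapply(tg$misinfo[has_theme],
                      function(m) "health_effects/deaths" %in% m, TRUE))
  planted <- 0.595 * 0.665 + 0.405 * 0.145       # pooled over author groups
  expect_lt(abs(frac - planted), 0.03)
})

test_that("tagged exports carry themes in JSONL and long CSV form", {
  rb <- tiny_rulebook()
  tg <- tag_misinformation(tag_themes(opposition_fixture(), rb$themes),
                           rb$misinfo)
  pj <- withr::local_tempfile(fileext = ".jsonl")
  write_tagged_jsonl(tg, pj)
  rec <- jsonlite::fromJSON(readLines(pj)[1])
  expect_setequal(rec$themes, c("death", "autism"))
  expect_true(rec$opposition)
  long <- tagged_long(tg)
  expect_equal(nrow(long), sum(vapply(tg$themes, length, 1L)))
  expect_equal(sort(unique(long$theme)), c("autism", "death"))
})
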