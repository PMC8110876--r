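# closed-form Pearson chi-square on a 2x2 table, as an independent oracle
chi2_closed_form <- function(x1, n1, x2, n2) {
  a <- as.numeric(x1); b <- as.numeric(n1 - x1)
  c <- as.numeric(x2); d <- as.numeric(n2 - x2)
  n <- a + b + c + d
  stat <- n * (a * d - b * c)^2 / ((a + b) * (c + d) * (a + c) * (b + d))
  list(statistic = stat, p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE))
}

test_that("percent cells use half-up rounding", {
  expect_equal(round_half_up(0.25, 1), 0.3)
  expect_equal(round_half_up(-0.25, 1), -0.3)
  expect_equal(round_half_up(55.4321, 1), 55.4)
  expect_equal(round_half_up(c(1.05, 1.04), 1), c(1.1, 1.0))
})

test_that("theme proportions divide counts by the supplied group denominator", {
  rb <- tiny_rulebook()
  tg <- tag_themes(corpus(make_posts(4, text = c(
    "deadly one", "deadly two", "autism note", "nothing"))), rb$themes)
  props <- theme_proportions(tg, c("death", "autism", "empty_theme"),
                             denominator = 4)
  expect_equal(props$count, c(2L, 1L, 0L))
  expect_equal(props$percent, c(50.0, 25.0, 0.0))
  expect_error(theme_proportions(tg, denominator = 0), "positive")
})

test_that("published percent cells are reproduced from counts and denominators", {
  ref <- published_reference()
  expect_equal(round_half_up(100 * ref$counts$count_top / ref$denominator_top),
               ref$counts$pct_top_printed)
  expect_equal(round_half_up(100 * ref$counts$count_other / ref$denominator_other),
               ref$counts$pct_other_printed)
})

test_that("chi-square test matches the closed form and handles the null identity", {
  null_case <- chi2_two_proportion(10, 100, 20, 200)
  expect_equal(null_case$statistic, 0)
  expect_equal(null_case$p_value, 1)
  set.seed(77)
  for (rep in 1:25) {
    n1 <- sample(50:5000, 1); n2 <- sample(50:5000, 1)
    x1 <- sample.int(n1 - 1, 1); x2 <- sample.int(n2 - 1, 1)
    got <- chi2_two_proportion(x1, n1, x2, n2)
    want <- chi2_closed_form(x1, n1, x2, n2)
    expect_equal(got$statistic, want$statistic)
    expect_equal(got$p_value, want$p_value)
  }
  expect_error(chi2_two_proportion(0, 10, 0, 20), "margin")
})

test_that("chi-square is invariant to group order and to success/failure swap", {
  g1 <- chi2_two_proportion(117530, 212018, 71167, 144576)
  g2 <- chi2_two_proportion(71167, 144576, 117530, 212018)
  g3 <- chi2_two_proportion(212018 - 117530, 212018, 144576 - 71167, 144576)
  expect_equal(g1$p_value, g2$p_value)
  expect_equal(g1$p_value, g3$p_value)
})

test_that("the chi-square statistic scales linearly with sample size", {
  base <- chi2_two_proportion(150, 1000, 120, 800)
  doubled <- chi2_two_proportion(300, 2000, 240, 1600)
  expect_equal(doubled$statistic, 2 * base$statistic)
})

test_that("comparison tables sort by top percent and reject overlapping groups", {
  rb <- tiny_rulebook()
  top <- tag_themes(corpus(make_posts(4, text = c(
    "deadly a", "deadly b", "autism c", "plain"))), rb$themes)
  other_posts <- make_posts(5, text = c(
    "deadly x", "autism y", "autism z", "plain", "plain"))
  other_posts$post_id <- sprintf("q%03d", 1:5)
  other <- tag_themes(corpus(other_posts), rb$themes)
  tab <- build_comparison_table(top, other, themes = c("death", "autism"))
  expect_equal(tab$theme, c("death", "autism"))   # 50% > 25%
  expect_equal(tab$count_top, c(2L, 1L))
  expect_equal(tab$count_other, c(1L, 2L))
  expect_equal(tab$pct_top, c(50.0, 25.0))
  expect_equal(tab$pct_other, c(20.0, 40.0))
  expect_error(build_comparison_table(top, top), "overlap")
  # swapping the groups flips columns but keeps each p-value
  swapped <- build_comparison_table(other, top, themes = c("death", "autism"))
  swapped <- swapped[match(tab$theme, swapped$theme), ]
  expect_equal(swapped$p_value, tab$p_value)
  expect_equal(swapped$count_top, tab$count_other)
})

test_that("a synthetic comparison table matches row-by-row recomputation", {
  cfg <- sim_config(n_posts = 5000)
  sim <- simulate_corpus(cfg, seed = 21)
  rb <- emit_rulebook(cfg)
  res <- run_pipeline(sim$corpus, rb)
  tab <- res$comparison
  nt <- nrow(res$partition$top); no <- nrow(res$partition$other)
  for (i in seq_len(nrow(tab))) {
    ct <- sum(vapply(res$partition$top$themes,
                     function(x) tab$theme[i] %in% x, TRUE))
    co <- sum(vapply(res$partition$other$themes,
                     function(x) tab$theme[i] %in% x, TRUE))
    expect_equal(tab$count_top[i], ct)
    expect_equal(tab$count_other[i], co)
    expect_equal(tab$pct_top[i], round_half_up(100 * ct / nt))
    want <- chi2_closed_form(ct, nt, co, no)
    expect_equal(tab$p_value[i], want$p_value)
  }
})

test_that("bonferroni column is off by default and monotone when requested", {
  ref <- published_reference()
  plain <- comparison_from_counts(ref$counts$theme, ref$counts$count_top,
                                  ref$counts$count_other,
                                  ref$denominator_top, ref$denominator_other)
  expect_false("p_bonferroni" %in% names(plain))
  adj <- comparison_from_counts(ref$counts$theme, ref$counts$count_top,
                                ref$counts$count_other,
                                ref$denominator_top, ref$denominator_other,
                                bonferroni = TRUE)
  expect_true(all(adj$p_bonferroni >= adj$p_value))
})

test_that("markdown and CSV renderings carry the table contents", {
  ref <- published_reference()
  tab <- comparison_from_counts(ref$counts$theme, ref$counts$count_top,
                                ref$counts$count_other,
                                ref$denominator_top, ref$denominator_other)
  md <- comparison_markdown(tab)
  expect_match(md, "55.4 \\(117530\\)")
  expect_match(md, "<0.001")
  expect_match(md, "\\| 0.68 \\|")
  path <- withr::local_tempfile(fileext = ".csv")
  write_comparison(tab, path)
  back <- readr::read_csv(path, show_col_types = FALSE)
  expect_equal(back$count_top, tab$count_top)
})
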