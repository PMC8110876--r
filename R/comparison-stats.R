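#' Round half away from zero
#'
#' Published surveillance tables round percentages half-up (5 rounds away
#' from zero), unlike R's default round-half-even. Used for all percent
#' cells in comparison tables.
#'
#' @param x Numeric vector.
#' @param digits Decimal places, default 1.
#' @return Rounded numeric vector.
#' @export
#' @examples
#' round_half_up(0.25, 1)  # 0.3, where round(0.25, 1) gives 0.2
round_half_up <- function(x, digits = 1) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Per-theme counts and percentages for one author group
#'
#' Multi-label posts count once toward every theme they carry, so the
#' percent column may sum past 100. The denominator is the group's message
#' total, supplied explicitly.
#'
#' @param tagged A `vx_tagged` tibble for the group.
#' @param themes Theme inventory (rows of the result, in this order).
#' @param denominator Group message total (> 0); defaults to `nrow(tagged)`.
#' @return A tibble with `theme`, `count`, `percent` (half-up, one decimal).
#' @export
theme_proportions <- function(tagged, themes = sort(unique(unlist(tagged$themes))),
                              denominator = nrow(tagged)) {
  if (!is.numeric(denominator) || denominator <= 0) {
    stop("denominator must be a positive count", call. = FALSE)
  }
  counts <- unname(theme_counts(tagged, themes))
  tibble::tibble(
    theme = themes,
    count = as.integer(counts),
    percent = round_half_up(100 * counts / denominator, 1)
  )
}

#' Two-proportion Pearson chi-squared test
#'
#' Pearson's chi-squared on the 2x2 table `[[x1, n1-x1], [x2, n2-x2]]`
#' without continuity correction, 1 degree of freedom, two-sided p-value.
#' Delegates to [stats::chisq.test()].
#'
#' @param x1,n1 Successes and total in group 1.
#' @param x2,n2 Successes and total in group 2.
#' @return List with `statistic` and `p_value`.
#' @export
#' @examples
#' chi2_two_proportion(15508, 212018, 10628, 144576)  # p ~ 0.68
chi2_two_proportion <- function(x1, n1, x2, n2) {
  stopifnot(n1 > 0, n2 > 0, x1 >= 0, x2 >= 0, x1 <= n1, x2 <= n2)
  tab <- matrix(c(x1, n1 - x1, x2, n2 - x2), nrow = 2, byrow = TRUE)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("chi-squared test undefined: a table margin is zero", call. = FALSE)
  }
  ht <- stats::chisq.test(tab, correct = FALSE)
  list(statistic = unname(ht$statistic), p_value = unname(ht$p.value))
}

#' Build a theme comparison table (top vs general opposition)
#'
#' One row per theme: count and percent in each group, plus the
#' two-proportion chi-squared p-value on the group denominators. Rows are
#' sorted by the top-group percentage, descending. No multiple-testing
#' adjustment is applied by default (set `bonferroni = TRUE` for an
#' adjusted-p column).
#'
#' @param top,other `vx_tagged` tibbles for the two disjoint author groups.
#' @param themes Theme inventory.
#' @param denominator_top,denominator_other Group message totals; default to
#'   the group sizes.
#' @param bonferroni Add a Bonferroni-adjusted p column? Default `FALSE`.
#' @return A `vx_comparison` tibble with columns `theme`, `count_top`,
#'   `pct_top`, `count_other`, `pct_other`, `chi2_stat`, `p_value` (and
#'   `p_bonferroni` when requested); attributes `denominator_top`,
#'   `denominator_other`.
#' @export
build_comparison_table <- function(top, other,
                                   themes = sort(unique(c(unlist(top$themes),
                                                          unlist(other$themes)))),
                                   denominator_top = nrow(top),
                                   denominator_other = nrow(other),
                                   bonferroni = FALSE) {
  overlap <- intersect(top$post_id, other$post_id)
  if (length(overlap) > 0) {
    stop("groups overlap on ", length(overlap), " post(s); expected a partition",
         call. = FALSE)
  }
  comparison_from_counts(
    themes = themes,
    count_top = theme_counts(top, themes),
    count_other = theme_counts(other, themes),
    denominator_top = denominator_top,
    denominator_other = denominator_other,
    bonferroni = bonferroni
  )
}

#' Comparison table from published or precomputed counts
#'
#' Rebuilds the full comparison table (percent cells and chi-squared
#' p-values) from per-theme counts and group denominators — e.g. the counts
#' printed in a published surveillance table.
#'
#' @param themes Character vector of theme names.
#' @param count_top,count_other Per-theme message counts in each group.
#' @param denominator_top,denominator_other Group message totals.
#' @param bonferroni Add a Bonferroni-adjusted p column? Default `FALSE`.
#' @return A `vx_comparison` tibble (see [build_comparison_table()]).
#' @export
comparison_from_counts <- function(themes, count_top, count_other,
                                   denominator_top, denominator_other,
                                   bonferroni = FALSE) {
  count_top <- unname(count_top)
  count_other <- unname(count_other)
  stopifnot(length(count_top) == length(themes),
            length(count_other) == length(themes),
            denominator_top > 0, denominator_other > 0,
            all(count_top <= denominator_top),
            all(count_other <= denominator_other))
  # a theme absent from (or saturating) both groups has a degenerate 2x2
  # table; its test is undefined and reported as NA. The asymptotic
  # approximation caveat for sparse cells is muted here: surveillance tables
  # carry many rows and sparse ones are identifiable from their counts.
  tests <- lapply(seq_along(themes), function(i) {
    tryCatch(
      suppressWarnings(
        chi2_two_proportion(count_top[i], denominator_top,
                            count_other[i], denominator_other)),
      error = function(e) list(statistic = NA_real_, p_value = NA_real_)
    )
  })
  out <- tibble::tibble(
    theme = as.character(themes),
    count_top = as.integer(count_top),
    pct_top = round_half_up(100 * count_top / denominator_top, 1),
    count_other = as.integer(count_other),
    pct_other = round_half_up(100 * count_other / denominator_other, 1),
    chi2_stat = vapply(tests, `[[`, 0, "statistic"),
    p_value = vapply(tests, `[[`, 0, "p_value")
  )
  if (bonferroni) {
    out$p_bonferroni <- stats::p.adjust(out$p_value, method = "bonferroni")
  }
  out <- out[order(-out$pct_top, out$theme), ]
  attr(out, "denominator_top") <- denominator_top
  attr(out, "denominator_other") <- denominator_other
  class(out) <- c("vx_comparison", class(out))
  out
}

#' Format a comparison table
#'
#' `comparison_markdown()` renders the table as GitHub-flavoured Markdown
#' with `(%, n)` cells and `<0.001` for tiny p-values; `write_comparison()`
#' writes the raw table as CSV.
#'
#' @param x A `vx_comparison`.
#' @param path Output file.
#' @return A character scalar (markdown) or the path, invisibly.
#' @export
comparison_markdown <- function(x) {
  fmt_p <- function(p) ifelse(p < 0.001, "<0.001", sprintf("%.2f", p))
  lines <- c(
    "| Theme | Top authors (%, n) | Other authors (%, n) | P value |",
    "|---|---|---|---|",
    sprintf("| %s | %.1f (%d) | %.1f (%d) | %s |",
            x$theme, x$pct_top, x$count_top, x$pct_other, x$count_other,
            fmt_p(x$p_value))
  )
  paste(lines, collapse = "\n")
}

#' @rdname comparison_markdown
#' @export
write_comparison <- function(x, path) {
  readr::write_csv(as.data.frame(x), path, progress = FALSE)
  invisible(path)
}
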