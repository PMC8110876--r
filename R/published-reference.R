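#' Published 2019 vaccine-opposition surveillance summary
#'
#' Reference numbers from a published six-month (2019-06-01 to 2019-12-01)
#' Twitter surveillance study of vaccine opposition: the per-theme message
#' counts for the top-author and general-opposition groups (ten themes), the
#' group denominators, and the headline volume figures. These are the inputs
#' for reproducing the published comparison table with
#' [comparison_from_counts()].
#'
#' The source reports the top-author interaction total inconsistently as
#' both 212 018 and 212 019; both constants are preserved verbatim:
#' `denominator_top` (212 018) is the top-author message denominator, while
#' `interactions_total_alt` (212 019) is the denominator printed for the
#' 58.6% persistent-author interaction share.
#'
#' @return A list with elements:
#'   \describe{
#'     \item{counts}{tibble: `theme`, `count_top`, `count_other`,
#'       `pct_top_printed`, `pct_other_printed`, `p_printed`.}
#'     \item{denominator_top, denominator_other}{group message denominators
#'       (212 018 / 144 576).}
#'     \item{total_messages}{all opposition messages collected (356 594).}
#'     \item{n_top_accounts}{distinct monthly top-50 accounts (129).}
#'     \item{interactions_total_alt}{212 019.}
#'     \item{persistent_interactions}{interactions by accounts ranked in at
#'       least five months (124 243, from 15 accounts).}
#'     \item{coverage_printed}{fraction of opposition posts coded into at
#'       least one theme (0.748).}
#'     \item{impressions_printed}{potential impressions, millions (772.9).}
#'   }
#' @export
published_reference <- function() {
  path <- system.file("extdata", "published_theme_counts.csv",
                      package = "vaxwatch", mustWork = TRUE)
  counts <- readr::read_csv(
    path,
    col_types = readr::cols(
      theme = readr::col_character(),
      count_top = readr::col_integer(),
      count_other = readr::col_integer(),
      pct_top_printed = readr::col_double(),
      pct_other_printed = readr::col_double(),
      p_printed = readr::col_character()
    ),
    progress = FALSE
  )
  list(
    counts = counts,
    denominator_top = 212018L,
    denominator_other = 144576L,
    total_messages = 356594L,
    n_top_accounts = 129L,
    interactions_total_alt = 212019L,
    persistent_interactions = 124243L,
    n_persistent_accounts = 15L,
    coverage_printed = 0.748,
    impressions_printed = 772.9
  )
}
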