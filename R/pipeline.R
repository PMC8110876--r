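#' Run the full surveillance pipeline
#'
#' Wires the stages end to end: collect the vaccine conversation, isolate
#' the opposition sub-corpus, tag themes and misinformation categories,
#' rank monthly top authors by interactions, partition posts into
#' top-author vs general-opposition groups, and build the theme comparison
#' table with per-theme chi-squared tests. Artifacts (tagged posts, registry,
#' comparison table) and a run manifest are written when `output_dir` is
#' given.
#'
#' @param x A `vx_corpus` (the collected conversation, e.g. from
#'   [read_posts()] or [simulate_corpus()]).
#' @param rulebook A rulebook list (`opposition`, `themes`, `misinfo`), e.g.
#'   from [read_rulebook()] or [emit_rulebook()].
#' @param master_query Optional [query_spec()] applied first (keyword
#'   collection stage); `NULL` if `x` is already the collected conversation.
#' @param k Monthly ranking depth, default 50.
#' @param deny_list Author ids excluded from ranking (manual screening).
#' @param output_dir Directory for artifacts and `manifest.json`; `NULL`
#'   (default) writes nothing.
#' @return A list: `opposition` (corpus), `tagged` (tibble), `registry`,
#'   `partition` (list of `top`/`other` tagged tibbles), `comparison`
#'   (`vx_comparison`), `manifest` (stage record counts and timings).
#' @export
run_pipeline <- function(x, rulebook, master_query = NULL, k = 50,
                         deny_list = NULL, output_dir = NULL) {
  stopifnot(inherits(x, "vx_corpus"))
  manifest <- list(started = format_iso8601(Sys.time()), stages = list())
  t0 <- Sys.time()
  stage <- function(name, n_in, n_out) {
    manifest$stages[[name]] <<- list(
      n_in = n_in, n_out = n_out,
      elapsed_s = round(as.numeric(difftime(Sys.time(), t0, units = "secs")), 3)
    )
    t0 <<- Sys.time()
  }

  collected <- if (is.null(master_query)) x else collect_posts(x, master_query)
  stage("collect", n_posts(x), n_posts(collected))
  if (n_posts(collected) == 0) {
    stop("pipeline stage 'collect': no posts to analyze", call. = FALSE)
  }

  opposition <- filter_opposition(collected, rulebook$opposition)
  stage("filter_opposition", n_posts(collected), n_posts(opposition))
  if (n_posts(opposition) == 0) {
    stop("pipeline stage 'filter_opposition': no opposition posts matched",
         call. = FALSE)
  }

  tagged <- tag_themes(opposition, rulebook$themes)
  stage("tag_themes", n_posts(opposition), nrow(tagged))
  theme_names <- vapply(rulebook$themes, `[[`, "", "theme")
  tagged <- tag_misinformation(tagged, rulebook$misinfo,
                               known_themes = theme_names)
  stage("tag_misinformation", nrow(tagged), nrow(tagged))

  registry <- monthly_top_authors(opposition, k = k, deny_list = deny_list)
  stage("monthly_top_authors", n_posts(opposition), nrow(registry$by_month))

  parts <- partition_by_top_authors(tagged, registry)
  stage("partition", nrow(tagged), nrow(parts$top) + nrow(parts$other))

  comparison <- build_comparison_table(parts$top, parts$other,
                                       themes = theme_names)
  stage("comparison", length(theme_names), nrow(comparison))

  manifest$finished <- format_iso8601(Sys.time())
  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    write_tagged_jsonl(tagged, file.path(output_dir, "tagged_posts.jsonl"))
    readr::write_csv(tagged_long(tagged),
                     file.path(output_dir, "post_themes.csv"), progress = FALSE)
    write_registry(registry, file.path(output_dir, "top_authors.csv"))
    write_registry(registry, file.path(output_dir, "top_authors.json"))
    write_comparison(comparison, file.path(output_dir, "comparison.csv"))
    writeLines(comparison_markdown(comparison),
               file.path(output_dir, "comparison.md"))
    jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }

  list(opposition = opposition, tagged = tagged, registry = registry,
       partition = parts, comparison = comparison, manifest = manifest)
}
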