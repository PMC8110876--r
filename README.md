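# vaxwatch

Rule-based infodemiological surveillance of vaccine-opposition discourse
on microblogging platforms.

Public-health teams that monitor vaccine conversations need to know three
things: how much opposition content is circulating, what it talks about,
and who drives it. vaxwatch implements that workflow as a tested R
pipeline:

* a **boolean keyword query dialect** — *standalone* terms (any mention
  collects the post), *concurrent* anchor/context term pairs (an
  abbreviated vaccine word such as "vax" must co-occur with a condition
  or discourse word), and global *exclusion* terms (veterinary and
  medication-instruction vetoes), with automatic `#hashtag` variants and
  word-level (not substring) semantics;
* **multi-label theme tagging** and **misinformation-category tagging**
  nested under themes, with the human-audit machinery used to validate
  such rules: seeded random samples, a ≥90% precision gate, intercoder
  agreement, and top-engagement review sets;
* **top-author analysis** — authors ranked each calendar month by the
  interactions (likes + comments + shares) their opposition posts
  received, the monthly top 50 forming an influencer registry with
  persistence tracking and potential-impression accounting;
* a **Table-style group comparison** — per-theme counts and percentages
  for top authors versus the general opposition, each contrast tested
  with a two-proportion Pearson χ² (2×2 table `[[x₁, n₁−x₁], [x₂,
  n₂−x₂]]`, no continuity correction, 1 df);
* a **synthetic corpus generator** with full ground truth (heavy-tailed
  engagement and follower counts, retweet cascades, planted influencer
  share and theme mixes, exclusion-term confounders), so that every
  pipeline stage is validated end to end by parameter recovery.

## Worked example

Reproduce a published comparison table from its printed counts (the
package ships the per-theme counts and the group denominators 212 018 /
144 576):

```r
library(vaxwatch)
ref <- published_reference()
comparison_from_counts(ref$counts$theme,
                       ref$counts$count_top, ref$counts$count_other,
                       ref$denominator_top, ref$denominator_other)
#> # A tibble: 10 x 7
#>    theme             count_top pct_top count_other pct_other chi2_stat   p_value
#>  1 health_effects       117530    55.4       71167      49.2  1330.    3.05e-291
#>  2 pharma                35821    16.9       27346      18.9   240.    3.09e- 54
#>  3 research              32819    15.5        8097       5.6  8259.    0
#>  4 policy                31723    15         25621      17.7   485.    1.84e-107
#>  5 ingredients           29281    13.8       24858      17.2   764.    3.59e-168
#>  6 family                15508     7.3       10628       7.4     0.170 6.80e-  1
#>  7 disease_prevalen~     10885     5.1        4579       3.2   802.    2.50e-176
#>  8 school                 7733     3.6        3997       2.8   211.    1.05e- 47
#>  9 religion               6884     3.2        3343       2.3   270.    1.43e- 60
#> 10 natural_alternat~      1953     0.9        2287       1.6   319.    1.96e- 71
```

Every percent cell matches the published value at one decimal (half-up
rounding), the family theme is the single non-significant contrast
(p = 0.68), and all other themes differ at p < 0.001. Percentages may sum
past 100 because a post can carry several themes.

Run the full pipeline on a simulated six-month corpus:

```r
cfg <- sim_config(n_posts = 20000)        # 129 influencers, planted share 59.5%
sim <- simulate_corpus(cfg, seed = 1)
rb  <- emit_rulebook(cfg)                 # keyword rules matching the planted vocabulary
res <- run_pipeline(sim$corpus, rb)

res$registry
#> <vx_registry> top-50 by month: 6 months, 143 distinct top authors
nrow(res$partition$top) / nrow(res$tagged)
#> [1] 0.6008  — recovered top-author message share (planted 0.595)
```

`res$comparison` is the same ten-row table computed from the simulated
groups, and `res$manifest` records per-stage record counts. A thin CLI
(`inst/scripts/vaxwatch.R`) wraps the same functions as `simulate`,
`run`, `chisq` and `compile-check` subcommands.

## Package layout

| Area | Functions |
|---|---|
| Corpus I/O | `corpus()`, `read_posts()`, `write_posts()`, `validate_corpus()` |
| Query engine | `query_spec()`, `compile_query()`, `match_query()`, `collect_posts()`, `tokenize_text()`, `query_inventory()` |
| Classification | `filter_opposition()`, `tag_themes()`, `tag_misinformation()`, `saturation_check()`, `theme_coverage()` |
| Validation | `draw_sample()`, `precision_gate()`, `intercoder_agreement()`, `top_engaged()` |
| Influence | `interaction_count()`, `monthly_top_authors()`, `potential_impressions()`, `partition_by_top_authors()` |
| Comparison | `theme_proportions()`, `chi2_two_proportion()`, `build_comparison_table()`, `comparison_from_counts()` |
| Simulation | `sim_config()`, `simulate_corpus()`, `emit_rulebook()`, `default_vocabulary()` |
| Pipeline | `run_pipeline()`, `read_rulebook()`, `write_rulebook()`, `published_reference()` |

See `vignettes/vaccine-opposition-surveillance.Rmd` for the methods
account: the query dialect's semantics, the statistical conventions, what
the generator does and does not emulate, and the design decisions behind
the defaults.
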