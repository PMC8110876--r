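---
title: "Surveillance of vaccine-opposition discourse: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Surveillance of vaccine-opposition discourse: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vaxwatch)
```

## The surveillance problem

Vaccine opposition on social platforms is a public-health surveillance
target: a small set of influential accounts can drive the bulk of the
conversation, and the misinformation they promote is specific and
repetitive enough to be tracked with keyword rules. vaxwatch implements a
complete rule-based surveillance pipeline for this setting:

1. **Collection** — a boolean keyword query pulls the vaccine conversation
   from a post stream.
2. **Opposition isolation** — a second keyword query isolates the
   opposition sub-corpus; every downstream statistic is computed on it.
3. **Theme tagging** — named keyword rules assign conversation themes
   (multi-label: one post may carry several themes, so theme percentages
   can sum past 100%).
4. **Misinformation tagging** — category rules nested under themes; a
   category is assigned only when its parent theme is present.
5. **Influence accounting** — authors are ranked each calendar month by
   the interactions (likes + comments + shares) their opposition posts
   received; the monthly top *k* (default 50) form the top-author
   registry.
6. **Comparison** — theme proportions in the top-author group versus the
   remaining opposition, with a two-proportion Pearson chi-squared test per
   theme.

The human-in-the-loop quality gates of content-analysis practice are
modeled explicitly: seeded random samples for manual coding
(`draw_sample()`), a precision gate that approves an automated query only
when at least 90% of an audited sample is coded correctly
(`precision_gate()`), intercoder agreement on cross-coded posts
(`intercoder_agreement()`), and top-engagement review sets
(`top_engaged()`).

## The query dialect

A query has three term roles. *Standalone* terms collect a post on any
mention. *Concurrent* terms are a pair rule: an anchor term (an
abbreviated vaccine word such as "vax") must co-occur with a context term
(a vaccine-preventable condition or discourse word). *Exclusion* terms
veto collection globally — they remove veterinary and
medication-instruction content that shares vocabulary with the human
vaccine conversation.

Term presence is defined at the word level: the term's token sequence
must appear contiguously in the tokenized text. Tokenization applies
Unicode NFC normalization and case folding, splits on non-word
characters, and keeps `#hashtag` as a single token. Single-word terms
automatically match their hashtag variants. We deliberately do not use
substring matching: "vax" must not match "vaxxers", otherwise exclusion
terms would be unsafe. Variant expansion is applied uniformly to all
roles, including exclusions. No stemming or fuzzy matching is attempted;
the methodology relies on auditing keyword lists against samples, not on
linguistic generalization.

## Statistical comparison

The comparison table reports, per theme, the message count and percentage
in each author group, and the p-value of Pearson's chi-squared test on
the 2×2 table `[[x1, n1−x1], [x2, n2−x2]]` **without continuity
correction** and without multiple-testing adjustment (a Bonferroni column
is available but off by default). The no-correction choice is what
reproduces published tables of this kind from their printed counts; with
large group denominators the correction is immaterial, but we fix the
convention for exactness. Percentages are rounded half-up to one decimal
(`round_half_up()`), matching the rounding used in print; R's default
round-half-even would disagree on boundary cells. Group denominators are
always supplied explicitly (they are message totals per group), never
inferred from theme counts, because multi-label tagging breaks the
count-sum identity. Degenerate rows (a theme absent from both groups)
report `NA` rather than a test value.

`published_reference()` ships the printed per-theme counts and
denominators of a published six-month 2019 surveillance study (212 018
top-author and 144 576 general-opposition messages out of 356 594); the
package reproduces all twenty percent cells and the per-theme p-values
from those counts, which is exercised in the test suite and by
`scripts/acceptance.R`.

## The synthetic corpus generator

No public corpus of this kind can be redistributed, so the package treats
corpus simulation as a first-class, tested module. `sim_config()`
defaults encode the study conditions of the 2019 window, and every
planted parameter is recoverable by the corresponding pipeline stage:

* **Window and volume** — six calendar months (2019-06-01 to 2019-12-01,
  half-open), 20 000 posts by default with uniform-by-month timestamps.
  20 000 is the default problem size for end-to-end validation: binomial
  noise on recovered proportions is then a fraction of a point, well
  inside the ±2/±3-point recovery tolerances we test.
* **Opposition rate** — 0.4 of the collected conversation; opposition
  posts carry a planted marker (a standalone opposition keyword, or an
  anchor+context pair for a quarter of them, 15% of single-word keywords
  as hashtags).
* **Influencers** — 129 accounts, matching the published count of
  distinct monthly top-50 authors. Each influencer is active in one to
  six months, with tenure weights `(.45, .22, .12, .07, .04, .10)` chosen
  so that (a) the expected number active in any one month is close to the
  ranking depth k = 50, and (b) roughly 12–14% are active five or more
  months, mirroring the published persistent core of 15 accounts. Tenure
  is assigned in descending order of posting weight (Zipf, exponent 0.8),
  so persistent accounts are also high-volume ones. An opposition post is
  influencer-authored with probability 0.595 — the planted top-author
  message share.
* **Engagement and reach** — likes, comments and shares are negative
  binomial (size 0.25: heavy-tailed), with a 20× mean multiplier for
  influencer accounts and a 0.25× damp for retweets; follower counts are
  lognormal (median 500, sdlog 1.6) with a 50× influencer multiplier.
  These families are conventional choices for social-media count data and
  are configurable; no specific family is claimed for the real platform.
* **Retweets** — with probability 0.3 a post is a retweet of an earlier
  original (uniformly chosen), inheriting its text and therefore its
  tags. Retweet inheritance preserves the pooled theme marginals exactly
  but blends the two groups' mixes slightly (a retweet's author group
  need not match the original's); recovery checks therefore target the
  pooled planted expectation.
* **Confounders and near misses** — 5% of non-opposition posts carry an
  opposition keyword together with an exclusion term (the veterinary
  confounder the exclusion role exists for), and 10% carry
  near-miss vocabulary ("vaxxers", "provax") that substring matching
  would wrongly collect.
* **Theme and misinformation mixes** — per-group inclusion probabilities
  default to the published Table proportions (e.g. negative health
  effects 0.554 top / 0.492 other) and the published within-theme
  misinformation rates (e.g. deaths 0.665/0.145). Theme coverage is
  emergent from the mixes (≈0.80 under defaults), not a dial.

`emit_rulebook()` returns keyword rules that exactly match the planted
vocabulary, so on a clean corpus the classifier's output *equals* ground
truth by construction — the end-to-end tests then verify calibration of
the generator and the glue between stages, not a tautology about any one
matcher (a dedicated test asserts the filler phrase banks can never
complete a keyword sequence, including across phrase boundaries). In
noise mode the rulebook gains one ambiguous decoy term and the generator
plants that term in non-opposition posts at rate
`q = r(1−π) / (π(1−r)(1−c))` (r = opposition rate, c = confounder rate),
which makes the opposition query's precision equal the target π. The
default noise target 0.85 sits below the 0.90 gate, giving a
known-failing case for the validation machinery at audit sample size
1000.

What the generator does **not** emulate: natural language (texts are
keyword phrases embedded in a fixed neutral phrase bank), follower-graph
structure beyond retweet links, temporal bursts and seasonality, and
adversarial drift of opposition vocabulary. Passing recovery tests shows
the pipeline is correct and well-calibrated under the planted generative
structure; it does not certify recall on real discourse, where keyword
lists must be re-audited with the precision gate.

## Numerical and design choices

* **Timestamps** are serialized ISO-8601 UTC with `Z`; offset-bearing
  stamps convert to UTC on ingest. The collection window is half-open
  `[start, end)` so that a June-1-to-December-1 window is exactly six
  calendar months, as monthly ranking requires.
* **Tie-breaks** are total orders: author ranking by (interactions desc,
  post count desc, author id asc); top-engagement review sets by
  (interactions desc, post id asc). Rankings are therefore permutation-
  invariant to input order.
* **Saturation** of theme creation is strict: a theme covering less than
  1% of the opposition conversation (`count/total < 0.01`) signals
  stopping; exactly 1% does not.
* **Gates**: the precision gate passes at ≥ threshold (90 of 100 passes);
  intercoder agreement is conventionally required to be strictly above
  0.90 — both readings are configurable (`strict =`). Labels compare as
  exact sets; no partial credit for overlapping multi-label sets.
* **Sampling** uses R's Mersenne-Twister with an explicit seed; the
  algorithm identifier is recorded in the sample object for provenance.
* **Retweets** are tagged from their own text (which embeds the
  original's), not by copying the original's record; interactions on a
  retweet accrue to the retweeting account, while share events on the
  original are already part of the original's share count. Retweets
  whose original lies outside the corpus are retained and counted as
  unresolved, since vendor feeds deliver retweets independently.
* **Degenerate inputs** fail loudly: empty denominators, empty label
  maps, samples larger than the eligible pool, chi-squared tables with a
  zero margin, and misinformation rules referencing unknown themes are
  all errors with named context.

## Known limitations

Keyword rules cannot detect sarcasm or stance; the precision gate is the
designed mitigation, not a solution. Potential impressions sum follower
counts without deduplicating audiences and so overstate unique reach.
The message-share and interaction-share bases differ in published
tables of this kind; the package always takes denominators explicitly
rather than guessing the base. The per-group theme mixes in the
generator blend slightly under retweet inheritance, so per-group (as
opposed to pooled) recovery tolerances would need either group-matched
retweet sources or wider bands.
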