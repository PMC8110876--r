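#' Default keyword vocabulary for the synthetic corpus
#'
#' The planted vocabulary mirrors the structure of the real surveillance
#' dialect: opposition standalone terms, the three abbreviated-vaccine
#' anchor terms with health-condition context terms (concurrent rule),
#' veterinary/medication exclusion terms, ten theme keyword lists
#' reconstructed from the published results narrative (aluminum, mercury,
#' Merck, Gardasil, autism analogues), and misinformation categories nested
#' under three themes. `filler` and `pro` are neutral phrase banks whose
#' tokens never complete a keyword sequence; `near_miss` holds
#' confusable-but-non-matching vocabulary ("vaxxers" does not match "vax"
#' under word-level semantics); `ambiguous` is the noise-mode decoy term.
#'
#' @return A nested list (`opposition`, `themes`, `misinfo`, `filler`,
#'   `pro`, `near_miss`, `ambiguous`).
#' @export
default_vocabulary <- function() {
  list(
    opposition = list(
      standalone = c("antivax", "vaccines harm", "vaccine free",
                     "forced vaccination", "no jabs"),
      anchor = c("vax", "vaxx", "jab"),
      context = c("measles", "autism", "mmr", "flu shot", "whooping cough"),
      exclusion = c("rabies", "veterinary", "kennel cough", "pet meds",
                    "dosage chart")
    ),
    themes = list(
      health_effects = c("vaccine injury", "adverse reaction", "vaccine damaged"),
      pharma = c("big pharma", "pharma profits", "vaccine industry"),
      research = c("retracted study", "pseudoscience", "junk science"),
      policy = c("sb 276", "vaccine mandate", "injury act"),
      ingredients = c("vaccine ingredients", "heavy metals", "package insert"),
      family = c("my child", "as a parent"),
      disease_prevalence = c("measles outbreak", "vaccine derived polio"),
      school = c("no shots no school", "school mandate"),
      religion = c("religious exemption", "religious beliefs"),
      natural_alternatives = c("natural immunity", "homeopathic", "vaccine detox")
    ),
    misinfo = list(
      health_effects = list(
        deaths = c("vaccine deaths", "died after vaccination"),
        autism_claim = c("vaccines cause autism"),
        paralysis = c("vaccine paralysis"),
        seizures = c("vaccine seizures")
      ),
      ingredients = list(
        aluminum = c("aluminum"),
        mercury = c("mercury", "thimerosal"),
        fetal_tissue = c("aborted fetal")
      ),
      pharma = list(
        merck = c("merck", "gardasil")
      )
    ),
    filler = c(
      "the weather this weekend was lovely",
      "coffee tastes better in the morning",
      "watched the game with friends last night",
      "traffic on the bridge was terrible today",
      "trying a new recipe for dinner tonight",
      "the garden is finally blooming",
      "long week but the hiking trip made up for it",
      "reading a great mystery novel lately",
      "the concert downtown sold out quickly",
      "thinking about repainting the living room"
    ),
    pro = c(
      "got my flu shot today and it was quick",
      "grateful for modern medicine and immunization",
      "clinic visit went smoothly this morning",
      "public health workers deserve more credit",
      "booster appointment booked for next week"
    ),
    near_miss = c(
      "the vaxxers thread went on forever",
      "jabberwocky is still my favorite poem",
      "provax and skeptical voices both showed up"
    ),
    ambiguous = "shedding"
  )
}

#' Simulation configuration
#'
#' Defines the statistical structure of a generated corpus. Defaults encode
#' the study conditions of the 2019 surveillance window: a six-month
#' collection window, 129 influencer accounts ranked top-50 by month, an
#' influencer share of 59.5% of opposition messages, theme inclusion
#' probabilities equal to the published per-group theme proportions, and
#' misinformation category prevalences from the published within-theme
#' narrative. Engagement counts are negative binomial (heavy-tailed);
#' follower counts are lognormal.
#'
#' @param n_posts Number of posts, default 20000.
#' @param n_authors Total distinct authors, default 2000.
#' @param n_influencers Planted influencer accounts, default 129.
#' @param influencer_share Probability an opposition post is authored by an
#'   influencer, default 0.595.
#' @param opposition_rate Fraction of the collected conversation that is
#'   opposition content, default 0.4.
#' @param theme_mix_top,theme_mix_other Named per-theme multi-label
#'   inclusion probabilities for influencer-/non-influencer-authored
#'   opposition posts (need not sum to 1).
#' @param misinfo_mix Nested list `theme -> category -> c(top=, other=)` of
#'   conditional category probabilities given the parent theme.
#' @param retweet_prob Probability a post is a retweet of an earlier post,
#'   default 0.3.
#' @param engagement_mean Mean likes per ordinary original post, default 8
#'   (comments and shares scale at 1/4 and 1/2 of likes; retweets at 1/4
#'   overall).
#' @param engagement_dispersion Negative binomial size parameter; smaller is
#'   heavier-tailed. Default 0.25.
#' @param influencer_engagement_boost Multiplier on engagement means for
#'   influencer-authored posts, default 20.
#' @param follower_scale Median follower count (lognormal), default 500.
#' @param follower_sdlog Lognormal sd on the log scale, default 1.6.
#' @param influencer_follower_boost Multiplier on influencer follower
#'   counts, default 50.
#' @param confounder_rate Fraction of non-opposition posts that carry an
#'   opposition keyword together with an exclusion term (veterinary
#'   confounders), default 0.05.
#' @param concurrent_fraction Fraction of opposition posts marked by an
#'   anchor+context pair rather than a standalone term, default 0.25.
#' @param hashtag_fraction Probability a planted single-word keyword appears
#'   in its `#`-prefixed form, default 0.15.
#' @param noise_precision Target precision of the opposition query in noise
#'   mode (e.g. 0.85), or `NULL` for clean mode (precision 1 by
#'   construction).
#' @param window_start,window_end Collection window (half-open, UTC).
#' @param seed Integer RNG seed, default 20190601.
#' @param vocabulary Keyword vocabulary, default [default_vocabulary()].
#' @return A `vx_sim_config` list.
#' @export
sim_config <- function(n_posts = 20000,
                       n_authors = 2000,
                       n_influencers = 129,
                       influencer_share = 0.595,
                       opposition_rate = 0.4,
                       theme_mix_top = c(
                         health_effects = 0.554, pharma = 0.169,
                         research = 0.155, policy = 0.150,
                         ingredients = 0.138, family = 0.073,
                         disease_prevalence = 0.051, school = 0.036,
                         religion = 0.032, natural_alternatives = 0.009),
                       theme_mix_other = c(
                         health_effects = 0.492, pharma = 0.189,
                         research = 0.056, policy = 0.177,
                         ingredients = 0.172, family = 0.074,
                         disease_prevalence = 0.032, school = 0.028,
                         religion = 0.023, natural_alternatives = 0.016),
                       misinfo_mix = list(
                         health_effects = list(
                           deaths = c(top = 0.665, other = 0.145),
                           autism_claim = c(top = 0.438, other = 0.263),
                           paralysis = c(top = 0.059, other = 0.005),
                           seizures = c(top = 0.057, other = 0.008)),
                         ingredients = list(
                           aluminum = c(top = 0.445, other = 0.064),
                           mercury = c(top = 0.341, other = 0.069),
                           fetal_tissue = c(top = 0.093, other = 0.026)),
                         pharma = list(
                           merck = c(top = 0.581, other = 0.387))),
                       retweet_prob = 0.3,
                       engagement_mean = 8,
                       engagement_dispersion = 0.25,
                       influencer_engagement_boost = 20,
                       follower_scale = 500,
                       follower_sdlog = 1.6,
                       influencer_follower_boost = 50,
                       confounder_rate = 0.05,
                       concurrent_fraction = 0.25,
                       hashtag_fraction = 0.15,
                       noise_precision = NULL,
                       window_start = as.POSIXct("2019-06-01 00:00:00", tz = "UTC"),
                       window_end = as.POSIXct("2019-12-01 00:00:00", tz = "UTC"),
                       seed = 20190601,
                       vocabulary = default_vocabulary()) {
  cfg <- structure(as.list(environment()), class = "vx_sim_config")
  fracs <- c(influencer_share, opposition_rate, retweet_prob, confounder_rate,
             concurrent_fraction, hashtag_fraction,
             theme_mix_top, theme_mix_other)
  if (any(fracs < 0 | fracs > 1)) {
    stop("all fractions and inclusion probabilities must lie in [0, 1]",
         call. = FALSE)
  }
  if (n_influencers > n_authors) {
    stop("n_influencers must not exceed n_authors", call. = FALSE)
  }
  if (influencer_share > 0 && n_influencers == 0) {
    stop("influencer_share > 0 requires n_influencers > 0", call. = FALSE)
  }
  if (!setequal(names(theme_mix_top), names(theme_mix_other))) {
    stop("theme_mix_top and theme_mix_other must name the same themes",
         call. = FALSE)
  }
  if (!is.null(noise_precision) &&
      (noise_precision <= 0 || noise_precision > 1)) {
    stop("noise_precision must lie in (0, 1]", call. = FALSE)
  }
  cfg
}

#' @export
print.vx_sim_config <- function(x, ...) {
  cat(sprintf(
    "<vx_sim_config> %d posts, %d authors (%d influencers, share %.3f), opposition %.2f, %s mode\n",
    x$n_posts, x$n_authors, x$n_influencers, x$influencer_share,
    x$opposition_rate,
    if (is.null(x$noise_precision)) "clean" else sprintf("noise (precision %.2f)", x$noise_precision)
  ))
  invisible(x)
}

# Influencer activity model: each influencer is active in 1..n_months
# calendar months. The month-count distribution is weighted toward short
# tenures with a ~14% persistent (5-6 month) tail, and counts are assigned
# in descending order of posting weight, so high-volume accounts are also
# the persistent ones. With 129 accounts this puts the expected number of
# influencers active in any one month near the ranking depth k = 50.
influencer_activity <- function(n_influencers, n_months) {
  tenure_probs <- c(0.45, 0.22, 0.12, 0.07, 0.04, 0.10)
  if (n_months != 6) {
    tenure_probs <- rep(1 / n_months, n_months)
  }
  tenure <- sort(sample(n_months, n_influencers, replace = TRUE,
                        prob = tenure_probs), decreasing = TRUE)
  active <- matrix(FALSE, n_influencers, n_months)
  for (i in seq_len(n_influencers)) {
    active[i, sample.int(n_months, tenure[i])] <- TRUE
  }
  active
}

# one planted keyword, maybe hashtagged (single-word only), maybe upcased
decorate_keyword <- function(kw, hashtag_fraction) {
  single <- !grepl(" ", kw, fixed = TRUE)
  tag <- single & stats::runif(length(kw)) < hashtag_fraction
  kw[tag] <- paste0("#", kw[tag])
  up <- stats::runif(length(kw)) < 0.15
  kw[up] <- toupper(kw[up])
  kw
}

#' Generate a synthetic post corpus with ground truth
#'
#' Draws a corpus with the structure the pipeline assumes: uniform-by-month
#' timestamps over the window; opposition posts carrying planted opposition
#' markers (standalone keyword or anchor+context pair, optionally as
#' hashtags) plus theme and misinformation keyword phrases sampled from the
#' group-appropriate mixes; veterinary confounders bearing an opposition
#' keyword vetoed by an exclusion term; heavy-tailed engagement and
#' follower counts with boosted influencer engagement; and retweet cascades
#' pointing at earlier posts with inherited text. In noise mode
#' (`noise_precision < 1`) an ambiguous decoy term is planted in
#' non-opposition posts at the rate that makes the noise-mode opposition
#' query's precision equal the target.
#'
#' @param config A [sim_config()].
#' @param seed RNG seed; defaults to `config$seed`.
#' @return A list with `corpus` (a `vx_corpus`) and `truth` (tibble:
#'   `post_id`, `author_id`, `is_influencer`, `opposition`, `themes` (list),
#'   `misinfo` (list), `is_confounder`, `is_decoy`), plus attribute-level
#'   `influencers` (character vector of planted influencer ids).
#' @export
simulate_corpus <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "vx_sim_config"))
  withr::with_seed(as.integer(seed), simulate_corpus_impl(config),
                   .rng_kind = "Mersenne-Twister")
}

simulate_corpus_impl <- function(cfg) {
  voc <- cfg$vocabulary
  n <- cfg$n_posts
  boundaries <- seq(cfg$window_start, cfg$window_end, by = "1 month")
  n_months <- length(boundaries) - 1

  # authors
  influencers <- sprintf("inf%04d", seq_len(cfg$n_influencers))
  regulars <- sprintf("usr%05d", seq_len(cfg$n_authors - cfg$n_influencers))
  inf_weight <- seq_len(max(cfg$n_influencers, 1))^-0.8
  active <- if (cfg$n_influencers > 0) {
    influencer_activity(cfg$n_influencers, n_months)
  } else {
    matrix(FALSE, 0, n_months)
  }

  # timestamps: month uniform, then uniform within the month; sort so that
  # retweets can only point backwards in time
  mi <- sample.int(n_months, n, replace = TRUE)
  lo <- as.numeric(boundaries[mi])
  hi <- as.numeric(boundaries[mi + 1])
  ts <- sort(floor(lo + stats::runif(n) * (hi - lo)))
  ts <- as.POSIXct(ts, origin = "1970-01-01", tz = "UTC")
  month_of <- match(utc_month(ts), utc_month(boundaries[-length(boundaries)]))

  # retweet structure
  is_rt <- stats::runif(n) < cfg$retweet_prob
  is_rt[1] <- FALSE
  orig_before <- cumsum(!is_rt)
  orig_pos <- which(!is_rt)
  target <- rep(NA_integer_, n)
  rt_idx <- which(is_rt)
  target[rt_idx] <- orig_pos[ceiling(stats::runif(length(rt_idx)) *
                                       orig_before[rt_idx])]

  # opposition flags (originals), inherited by retweets below
  opposition <- !is_rt & stats::runif(n) < cfg$opposition_rate
  opposition[rt_idx] <- opposition[target[rt_idx]]

  # authorship: opposition posts come from an influencer with probability
  # influencer_share, the influencer drawn by posting weight among those
  # active in the post's month; everything else is drawn uniformly
  author <- character(n)
  is_inf_author <- logical(n)
  opp_all <- which(opposition)
  take_inf <- opp_all[stats::runif(length(opp_all)) < cfg$influencer_share &
                        rep(cfg$n_influencers > 0, length(opp_all))]
  is_inf_author[take_inf] <- TRUE
  for (m in seq_len(n_months)) {
    idx <- take_inf[month_of[take_inf] == m]
    if (length(idx) == 0) next
    w <- inf_weight * active[, m]
    if (sum(w) == 0) w <- inf_weight
    picks <- sample.int(cfg$n_influencers, length(idx), replace = TRUE, prob = w)
    author[idx] <- influencers[picks]
  }
  # all remaining posts go to regular accounts, so the influencer-authored
  # fraction of opposition posts is exactly the configured Bernoulli rate
  rest <- which(!is_inf_author)
  author[rest] <- sample(regulars, length(rest), replace = TRUE)

  # theme / misinfo planting for opposition originals
  themes_all <- names(cfg$theme_mix_top)
  theme_sets <- rep(list(character()), n)
  misinfo_sets <- rep(list(character()), n)
  opp_orig <- which(opposition & !is_rt)
  grp_top <- is_inf_author[opp_orig]
  text_body <- character(n)

  if (length(opp_orig) > 0) {
    # opposition marker: standalone keyword or anchor+context pair
    conc <- stats::runif(length(opp_orig)) < cfg$concurrent_fraction
    marker <- character(length(opp_orig))
    n_st <- sum(!conc)
    if (n_st > 0) {
      marker[!conc] <- decorate_keyword(
        sample(voc$opposition$standalone, n_st, replace = TRUE),
        cfg$hashtag_fraction)
    }
    n_cc <- sum(conc)
    if (n_cc > 0) {
      marker[conc] <- paste(
        decorate_keyword(sample(voc$opposition$anchor, n_cc, replace = TRUE),
                         cfg$hashtag_fraction),
        "debate over",
        sample(voc$opposition$context, n_cc, replace = TRUE))
    }
    body <- marker
    planted <- matrix(FALSE, length(opp_orig), length(themes_all),
                      dimnames = list(NULL, themes_all))
    for (th in themes_all) {
      p <- ifelse(grp_top, cfg$theme_mix_top[[th]], cfg$theme_mix_other[[th]])
      hit <- stats::runif(length(opp_orig)) < p
      planted[, th] <- hit
      if (any(hit)) {
        kw <- decorate_keyword(sample(voc$themes[[th]], sum(hit), replace = TRUE),
                               cfg$hashtag_fraction)
        body[hit] <- paste(body[hit], "and", kw)
      }
      cats <- cfg$misinfo_mix[[th]]
      for (cat in names(cats)) {
        pc <- ifelse(grp_top, cats[[cat]][["top"]], cats[[cat]][["other"]])
        chit <- hit & stats::runif(length(opp_orig)) < pc
        if (any(chit)) {
          ckw <- decorate_keyword(
            sample(voc$misinfo[[th]][[cat]], sum(chit), replace = TRUE),
            cfg$hashtag_fraction)
          body[chit] <- paste(body[chit], "and", ckw)
          tag <- paste0(th, "/", cat)
          for (i in which(chit)) {
            misinfo_sets[[opp_orig[i]]] <- c(misinfo_sets[[opp_orig[i]]], tag)
          }
        }
      }
    }
    for (i in seq_along(opp_orig)) {
      theme_sets[[opp_orig[i]]] <- themes_all[planted[i, ]]
    }
    text_body[opp_orig] <- paste(
      sample(voc$filler, length(opp_orig), replace = TRUE), body)
  }

  # non-opposition originals: neutral/pro content, veterinary confounders,
  # and (noise mode) ambiguous decoys at the precision-matched rate
  non_orig <- which(!opposition & !is_rt)
  if (length(non_orig) > 0) {
    base <- paste(sample(voc$filler, length(non_orig), replace = TRUE),
                  sample(voc$pro, length(non_orig), replace = TRUE))
    nm <- stats::runif(length(non_orig)) < 0.1
    base[nm] <- paste(base[nm],
                      sample(voc$near_miss, sum(nm), replace = TRUE))
    conf <- stats::runif(length(non_orig)) < cfg$confounder_rate
    if (any(conf)) {
      base[conf] <- paste(
        sample(voc$filler, sum(conf), replace = TRUE),
        sample(voc$opposition$standalone, sum(conf), replace = TRUE),
        "for the",
        sample(voc$opposition$exclusion, sum(conf), replace = TRUE))
    }
    decoy <- rep(FALSE, length(non_orig))
    if (!is.null(cfg$noise_precision) && cfg$noise_precision < 1) {
      pi_t <- cfg$noise_precision
      q <- cfg$opposition_rate * (1 - pi_t) /
        (pi_t * (1 - cfg$opposition_rate) * (1 - cfg$confounder_rate))
      decoy <- !conf & stats::runif(length(non_orig)) < q
      base[decoy] <- paste(base[decoy], "talk about", voc$ambiguous, "again")
    }
    text_body[non_orig] <- base
    conf_flag <- logical(n); conf_flag[non_orig[conf]] <- TRUE
    decoy_flag <- logical(n); decoy_flag[non_orig[decoy]] <- TRUE
  } else {
    conf_flag <- logical(n)
    decoy_flag <- logical(n)
  }

  # retweets inherit text (and hence tags) from their original
  post_id <- sprintf("t%07d", seq_len(n))
  if (length(rt_idx) > 0) {
    text_body[rt_idx] <- paste0("rt @", author[target[rt_idx]], ": ",
                                text_body[target[rt_idx]])
    theme_sets[rt_idx] <- theme_sets[target[rt_idx]]
    misinfo_sets[rt_idx] <- misinfo_sets[target[rt_idx]]
    conf_flag[rt_idx] <- conf_flag[target[rt_idx]]
    decoy_flag[rt_idx] <- decoy_flag[target[rt_idx]]
  }

  # engagement: negative binomial, boosted for influencer accounts,
  # damped for retweets
  boost <- ifelse(author %in% influencers, cfg$influencer_engagement_boost, 1)
  damp <- ifelse(is_rt, 0.25, 1)
  nb <- function(mu) {
    as.integer(stats::rnbinom(n, size = cfg$engagement_dispersion,
                              mu = mu * boost * damp))
  }
  likes <- nb(cfg$engagement_mean)
  comments <- nb(cfg$engagement_mean / 4)
  shares <- nb(cfg$engagement_mean / 2)

  # followers: lognormal per author, influencers boosted
  all_authors <- c(influencers, regulars)
  fol <- stats::rlnorm(length(all_authors), meanlog = log(cfg$follower_scale),
                       sdlog = cfg$follower_sdlog)
  fol[seq_len(cfg$n_influencers)] <- fol[seq_len(cfg$n_influencers)] *
    cfg$influencer_follower_boost
  fol <- stats::setNames(as.integer(pmin(ceiling(fol), 2^31 - 2)), all_authors)

  posts <- tibble::tibble(
    post_id = post_id,
    author_id = author,
    text = text_body,
    timestamp = ts,
    is_retweet = is_rt,
    retweet_of = ifelse(is.na(target), NA_character_, post_id[target]),
    likes = likes,
    comments = comments,
    shares = shares,
    author_followers = as.integer(fol[author])
  )
  truth <- tibble::tibble(
    post_id = post_id,
    author_id = author,
    is_influencer = author %in% influencers,
    opposition = opposition,
    themes = theme_sets,
    misinfo = lapply(misinfo_sets, function(v) sort(unique(v))),
    is_confounder = conf_flag,
    is_decoy = decoy_flag
  )
  out <- list(
    corpus = corpus(posts, window_start = cfg$window_start,
                    window_end = cfg$window_end),
    truth = truth
  )
  attr(out, "influencers") <- influencers
  out
}

#' Emit the rulebook matching a simulation's planted vocabulary
#'
#' The clean-mode rulebook matches the planted vocabulary exactly, so on a
#' clean corpus the classifier's decisions coincide with ground truth by
#' construction. In noise mode the opposition query additionally includes
#' the ambiguous decoy term, giving a known precision below 1 for
#' exercising the validation gate.
#'
#' @param config A [sim_config()].
#' @param noise Include the ambiguous decoy term in the opposition query?
#'   Defaults to `TRUE` when `config$noise_precision` is set.
#' @return A rulebook list (`opposition` [query_spec()], `themes`
#'   (list of [theme_rule()]), `misinfo` (list of [misinfo_rule()])),
#'   compatible with [write_rulebook()].
#' @export
emit_rulebook <- function(config,
                          noise = !is.null(config$noise_precision) &&
                            config$noise_precision < 1) {
  stopifnot(inherits(config, "vx_sim_config"))
  voc <- config$vocabulary
  standalone <- voc$opposition$standalone
  if (noise) standalone <- c(standalone, voc$ambiguous)
  themes <- names(config$theme_mix_top)
  list(
    opposition = query_spec(
      standalone = standalone,
      concurrent_anchor = voc$opposition$anchor,
      concurrent_context = voc$opposition$context,
      exclusion = voc$opposition$exclusion
    ),
    themes = lapply(themes, function(th) {
      theme_rule(th, query_spec(standalone = voc$themes[[th]]))
    }),
    misinfo = unlist(lapply(names(config$misinfo_mix), function(th) {
      lapply(names(config$misinfo_mix[[th]]), function(cat) {
        misinfo_rule(cat, th, query_spec(standalone = voc$misinfo[[th]][[cat]]))
      })
    }), recursive = FALSE)
  )
}
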