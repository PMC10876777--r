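# ---- truncated-normal machinery ----------------------------------------

# Mean of a normal(mu, sd) truncated to [lower, upper].
truncnorm_mean <- function(mu, sd, lower, upper) {
  a <- (lower - mu) / sd
  b <- (upper - mu) / sd
  da <- if (is.finite(a)) dnorm(a) else 0
  db <- if (is.finite(b)) dnorm(b) else 0
  z <- pnorm(b) - pnorm(a)
  mu + sd * (da - db) / z
}

# Location parameter such that the truncated distribution's MEAN equals
# `target`. Plain truncation would shift the mean (severely so for a latency
# profile like 0.38 +/- 0.54 truncated at 0), so the generator solves for the
# underlying location instead; the SD of the truncated draw remains
# approximate. See the methods vignette.
calibrate_truncnorm_mu <- function(target, sd, lower, upper) {
  if (sd == 0) return(target)
  if (target <= lower || target >= upper) {
    stop("target mean ", target, " outside the truncation interval [",
         lower, ", ", upper, "]", call. = FALSE)
  }
  if (!is.finite(lower) && !is.finite(upper)) return(target)
  f <- function(mu) truncnorm_mean(mu, sd, lower, upper) - target
  width <- 2 * sd
  repeat {
    lo <- target - width
    hi <- target + width
    if (f(lo) < 0 && f(hi) > 0) break
    width <- width * 2
    if (width > 100 * sd) {
      stop("could not bracket truncated-normal calibration for mean ",
           target, call. = FALSE)
    }
  }
  uniroot(f, c(lo, hi), tol = 1e-10)$root
}

# Draws whose truncated distribution has mean exactly `mean` (inverse-CDF
# sampling; sd of the draws is <= `sd` when truncation bites).
rtruncnorm_calibrated <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  if (sd == 0) return(rep(mean, n))
  mu <- calibrate_truncnorm_mu(mean, sd, lower, upper)
  u <- runif(n, pnorm(lower, mu, sd), pnorm(upper, mu, sd))
  qnorm(u, mu, sd)
}

# ---- cohort configuration ----------------------------------------------

#' Group profile for the synthetic-cohort generator
#'
#' The per-group distribution parameters the generator reproduces: mean and
#' sample SD of content-word log frequency (natural-log scale), mean
#' utterance latency (seconds, truncated at 0), spatial relational ratio
#' (proportion, truncated to `[0, 1]`), total content units (truncated to
#' `[0, n_units]` and integer-rounded), articulation rate (syllables/second),
#' and Bernoulli probabilities of mentioning the theme unit and the focus
#' unit.
#'
#' @param freq_mean,freq_sd Log-frequency mean and SD.
#' @param latency_mean,latency_sd Utterance latency mean and SD (s).
#' @param relational_mean,relational_sd Relational-ratio mean and SD.
#' @param cu_total_mean,cu_total_sd Content-unit total mean and SD.
#' @param theme_p,focus_p Mention probabilities of the theme and focus units.
#' @param articulation_mean,articulation_sd Articulation rate mean and SD.
#' @return An object of class `group_profile`.
#' @export
group_profile <- function(freq_mean, freq_sd, latency_mean, latency_sd,
                          relational_mean, relational_sd,
                          cu_total_mean, cu_total_sd, theme_p, focus_p,
                          articulation_mean, articulation_sd) {
  stopifnot(theme_p >= 0, theme_p <= 1, focus_p >= 0, focus_p <= 1,
            freq_sd >= 0, latency_sd >= 0, relational_sd >= 0,
            cu_total_sd >= 0, articulation_sd >= 0)
  structure(as.list(environment()), class = "group_profile")
}

#' Cohort configuration for the synthetic generators
#'
#' @param n_per_group Named integer vector `c(PCA = ..., CN = ...)`.
#' @param profiles Named list of [group_profile()]s, one per group.
#' @param seed Integer seed; mandatory — all randomness flows from it via
#'   per-participant substreams.
#' @param n_units Number of content units in the stimulus dictionary
#'   (default 32).
#' @param focus_unit Unit id of the focus unit (default `"fisherman"`).
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_per_group, profiles, seed, n_units = 32L,
                          focus_unit = "fisherman") {
  stopifnot(length(n_per_group) == 2L, all(n_per_group >= 2L),
            !is.null(names(n_per_group)),
            setequal(names(n_per_group), names(profiles)),
            is.numeric(seed), length(seed) == 1L, !is.na(seed))
  structure(
    list(n_per_group = n_per_group, profiles = profiles,
         seed = as.integer(seed), n_units = as.integer(n_units),
         focus_unit = focus_unit),
    class = "cohort_config"
  )
}

#' Default reference cohort configuration
#'
#' The study conditions the generator emulates: the published group profiles
#' of a PCA vs control picture-description cohort — log frequency 6.50 +/-
#' 0.53 (PCA) vs 5.85 +/- 0.40 (CN), latency 0.38 +/- 0.54 vs 0.03 +/- 0.05 s,
#' relational ratio 0.08 +/- 0.03 vs 0.09 +/- 0.02, content-unit totals 7.20
#' +/- 5.63 vs 16.28 +/- 4.41 of 32 units, theme ("picnic") mention
#' probability 0.16 vs 0.90, focus ("fisherman") mention probability 0.08 vs
#' 0.93, articulation rate 2.92 +/- 0.60 vs 3.14 +/- 0.35 syl/s — at the
#' study's group sizes n = 25 (PCA) and 29 (CN).
#'
#' @param seed Integer seed (default 1).
#' @return A [cohort_config()].
#' @export
default_reference_config <- function(seed = 1L) {
  cohort_config(
    n_per_group = c(PCA = 25L, CN = 29L),
    profiles = list(
      PCA = group_profile(
        freq_mean = 6.50, freq_sd = 0.53,
        latency_mean = 0.38, latency_sd = 0.54,
        relational_mean = 0.08, relational_sd = 0.03,
        cu_total_mean = 7.20, cu_total_sd = 5.63,
        theme_p = 0.16, focus_p = 0.08,
        articulation_mean = 2.92, articulation_sd = 0.60
      ),
      CN = group_profile(
        freq_mean = 5.85, freq_sd = 0.40,
        latency_mean = 0.03, latency_sd = 0.05,
        relational_mean = 0.09, relational_sd = 0.02,
        cu_total_mean = 16.28, cu_total_sd = 4.41,
        theme_p = 0.90, focus_p = 0.93,
        articulation_mean = 3.14, articulation_sd = 0.35
      )
    ),
    seed = seed
  )
}

# Per-participant substream seeds derived from the config seed, so each
# participant's draws are independent of cohort size and order.
participant_seeds <- function(seed, n) {
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

# ---- feature-level generation ------------------------------------------

#' Generate a feature-level synthetic cohort
#'
#' Draws per-participant feature vectors directly from the group profiles:
#' mean-calibrated truncated normals for the continuous features (latency
#' truncated at 0, relational ratio to `[0, 1]`, articulation rate positive),
#' an integer-rounded truncated normal on `[0, n_units]` for the content-unit
#' total, and Bernoulli draws for the theme and focus mentions. Features are
#' drawn independently (no published covariance to emulate); fully
#' reproducible from the config seed.
#'
#' @param config A [cohort_config()].
#' @return A tibble with `participant_id`, `group` and the feature columns.
#' @export
generate_feature_cohort <- function(config) {
  groups <- names(config$n_per_group)
  # group blocks drawn under a single seeded stream, patient group first
  set.seed(config$seed)
  out <- lapply(groups, function(g) {
    n <- config$n_per_group[[g]]
    p <- config$profiles[[g]]
    tibble::tibble(
      participant_id = sprintf("%s_%03d", g, seq_len(n)),
      group = g,
      mean_log_frequency = rtruncnorm_calibrated(n, p$freq_mean, p$freq_sd),
      mean_utterance_latency =
        rtruncnorm_calibrated(n, p$latency_mean, p$latency_sd, lower = 0),
      articulation_rate =
        rtruncnorm_calibrated(n, p$articulation_mean, p$articulation_sd,
                              lower = 0.1),
      relational_ratio =
        rtruncnorm_calibrated(n, p$relational_mean, p$relational_sd,
                              lower = 0, upper = 1),
      total_content_units =
        round(rtruncnorm_calibrated(n, p$cu_total_mean, p$cu_total_sd,
                                    lower = 0, upper = config$n_units)),
      theme_mentioned = rbinom(n, 1L, p$theme_p),
      focus_mentioned = rbinom(n, 1L, p$focus_p)
    )
  })
  do.call(rbind, out)
}

# ---- content-unit dictionary and lexicon fixtures ----------------------

#' Synthetic content-unit dictionary for a picnic scene
#'
#' A 32-unit dictionary for a lakeside picnic picture-description task. Five
#' units carry the distinctive roles discussed throughout the package — the
#' theme unit `picnic`, the small central `fisherman` focus unit, `clouds`,
#' `basket`, and `girl` (with the morphological-variant grouping girl /
#' daughter) — and the remaining 27 are ordinary scene elements. The
#' inventory is a synthetic configuration artifact for testing and
#' simulation, not a claim about any published stimulus inventory; users
#' reproducing a specific study must supply their own dictionary via
#' [read_cu_dictionary()].
#'
#' @return A [cu_dictionary()] with 32 units, theme `"picnic"`.
#' @export
picnic_cu_dictionary <- function() {
  units <- list(
    picnic = c("picnic"),
    fisherman = c("fisherman", "angler"),
    clouds = c("cloud"),
    basket = c("basket", "hamper"),
    girl = c("girl", "daughter"),
    boy = c("boy", "son"),
    man = c("man", "father", "dad"),
    woman = c("woman", "mother", "mom"),
    dog = c("dog", "puppy"),
    kite = c("kite"),
    flag = c("flag"),
    sailboat = c("sailboat", "boat"),
    lake = c("lake", "pond"),
    tree = c("tree"),
    house = c("house", "cottage"),
    blanket = c("blanket"),
    radio = c("radio"),
    book = c("book"),
    shoe = c("shoe", "sneaker"),
    pier = c("pier", "dock"),
    pole = c("pole", "fishing pole", "rod"),
    water = c("water"),
    sand = c("sand", "beach"),
    shore = c("shore", "shoreline"),
    car = c("car", "automobile"),
    bird = c("bird"),
    ball = c("ball"),
    cup = c("cup", "mug"),
    plate = c("plate"),
    sandwich = c("sandwich"),
    hat = c("hat", "cap"),
    grass = c("grass", "lawn")
  )
  cu_dictionary(units, theme_unit = "picnic")
}

#' Synthetic spoken-corpus frequency lexicon
#'
#' Builds a frequency lexicon shaped like spoken-corpus word counts: a dense
#' grid of content words (`w0001`, `w0002`, ...) whose natural-log counts
#' span `ln_range`, every single-word variant form of `cu_dict` at a fixed
#' mid-frequency count, and common function words at high counts. The grid
#' gives the transcript generator fine control over a sample's mean log
#' frequency. The corpus total defaults to the size of the Switchboard
#' telephone-speech corpus conventionally used for spoken-frequency norms.
#'
#' @param cu_dict A [cu_dictionary()] whose variant forms must be in
#'   vocabulary (default [picnic_cu_dictionary()]).
#' @param n_words Number of grid words (default 2000).
#' @param ln_range Range of natural-log counts spanned by the grid.
#' @param unit_count Raw count assigned to unit variant words (default 403,
#'   i.e. ln ~ 6.0).
#' @param corpus_total Reference corpus size (default 2,345,269).
#' @return A [frequency_lexicon()].
#' @export
make_synthetic_lexicon <- function(cu_dict = picnic_cu_dictionary(),
                                   n_words = 2000L, ln_range = c(2, 11),
                                   unit_count = 403L,
                                   corpus_total = 2345269) {
  grid <- pmax(1, round(exp(seq(ln_range[1L], ln_range[2L],
                                length.out = n_words))))
  names(grid) <- sprintf("w%04d", seq_len(n_words))
  unit_words <- unique(unlist(strsplit(unlist(cu_dict$units), " ",
                                       fixed = TRUE)))
  units <- rep(unit_count, length(unit_words))
  names(units) <- unit_words
  fn_words <- c("the", "a", "an", "is", "are", "there", "and", "on", "in",
                "under", "near", "by", "over", "behind", "beside", "it",
                "he", "she", "they")
  fn <- rep(50000, length(fn_words))
  names(fn) <- fn_words
  frequency_lexicon(c(grid, units, fn), corpus_total)
}

# ---- mention-set generation --------------------------------------------

# Draw per-participant mention sets for one group: theme and focus mentions
# are Bernoulli at the profile's probabilities; the participant's total is an
# integer-rounded mean-calibrated truncated normal; the remaining units are
# filled uniformly at random from the other n_units - 2 units.
draw_mention_sets <- function(n, profile, unit_ids, theme_unit, focus_unit) {
  others <- setdiff(unit_ids, c(theme_unit, focus_unit))
  lapply(seq_len(n), function(i) {
    forced <- c(if (runif(1) < profile$theme_p) theme_unit,
                if (runif(1) < profile$focus_p) focus_unit)
    total <- round(rtruncnorm_calibrated(1L, profile$cu_total_mean,
                                         profile$cu_total_sd,
                                         lower = 0, upper = length(unit_ids)))
    extra <- max(0L, min(length(others), total - length(forced)))
    c(forced, if (extra > 0L) sample(others, extra))
  })
}

#' Generate a synthetic mention matrix
#'
#' Draws a binary participant x unit mention matrix directly from the group
#' profiles (without synthesizing transcripts): the theme and focus units are
#' mentioned with their profile probabilities, each participant's total unit
#' count follows the profile's truncated-normal total, and the remaining
#' mentions are spread uniformly over the other units so expected totals
#' match the profile means.
#'
#' @param config A [cohort_config()].
#' @param dict A [cu_dictionary()] with at least `config$n_units` units.
#' @return A [mention_matrix()].
#' @export
generate_mention_matrix <- function(config, dict = picnic_cu_dictionary()) {
  unit_ids <- generator_unit_ids(config, dict)
  set.seed(config$seed)
  groups <- names(config$n_per_group)
  rows <- list(); grp <- character(); ids <- character()
  for (g in groups) {
    n <- config$n_per_group[[g]]
    sets <- draw_mention_sets(n, config$profiles[[g]], unit_ids,
                              dict$theme_unit, config$focus_unit)
    rows <- c(rows, sets)
    grp <- c(grp, rep(g, n))
    ids <- c(ids, sprintf("%s_%03d", g, seq_len(n)))
  }
  m <- matrix(0L, nrow = length(rows), ncol = length(unit_ids),
              dimnames = list(ids, unit_ids))
  for (i in seq_along(rows)) m[i, rows[[i]]] <- 1L
  structure(list(mentions = m, group = grp), class = "mention_matrix")
}

generator_unit_ids <- function(config, dict) {
  if (length(dict$units) < config$n_units) {
    stop("dictionary has ", length(dict$units), " units but the config asks",
         " for ", config$n_units, call. = FALSE)
  }
  unit_ids <- names(dict$units)[seq_len(config$n_units)]
  if (!dict$theme_unit %in% unit_ids) {
    stop("theme unit '", dict$theme_unit,
         "' not among the first n_units units", call. = FALSE)
  }
  if (!config$focus_unit %in% unit_ids) {
    stop("focus unit '", config$focus_unit, "' not in the dictionary",
         call. = FALSE)
  }
  unit_ids
}

# ---- transcript-level generation ---------------------------------------

#' Generate a transcript-level synthetic cohort
#'
#' Synthesizes word-timestamped transcripts whose extracted features follow
#' the group profiles, closing the loop between the generator and the
#' extraction pipeline. Per participant: a mention set is drawn as in
#' [generate_mention_matrix()] and each mentioned unit's first variant form
#' is named in a template clause with function-word filler; adposition
#' tokens (dependency relation `"case"`) are inserted to hit the drawn
#' relational ratio; content filler words are picked from the lexicon's
#' frequency grid so the sample's mean log frequency hits the drawn target;
#' word durations are set from syllable counts so the articulation rate
#' equals the drawn rate; and inter-word gaps are scaled exponential draws
#' whose mean equals the drawn latency. Gold annotation (lemma, universal
#' POS, dependency relation) is embedded so the cohort is tagger-independent.
#' Templates exercise the extraction contracts; they are not natural prose.
#'
#' All randomness derives from `config$seed` through per-participant
#' substreams.
#'
#' @param config A [cohort_config()].
#' @param cu_dict A [cu_dictionary()]; every unit's first variant must be a
#'   single word present in `lexicon`.
#' @param lexicon A [frequency_lexicon()] containing a `w####` frequency grid
#'   (see [make_synthetic_lexicon()]).
#' @return A list of annotated [transcript_sample()] objects (patient group
#'   first).
#' @export
generate_transcript_cohort <- function(config,
                                       cu_dict = picnic_cu_dictionary(),
                                       lexicon = make_synthetic_lexicon(cu_dict)) {
  unit_ids <- generator_unit_ids(config, cu_dict)
  first_forms <- vapply(cu_dict$units[unit_ids], `[[`, character(1L), 1L)
  if (any(grepl(" ", first_forms))) {
    stop("transcript generation requires single-word first variant forms; ",
         "offending unit(s): ",
         paste(unit_ids[grepl(" ", first_forms)], collapse = ", "),
         call. = FALSE)
  }
  if (anyNA(lexicon_count(lexicon, first_forms))) {
    stop("unit variant form(s) missing from the lexicon: ",
         paste(first_forms[is.na(lexicon_count(lexicon, first_forms))],
               collapse = ", "), call. = FALSE)
  }
  grid_words <- grep("^w[0-9]+$", names(lexicon$counts), value = TRUE)
  if (length(grid_words) < 10L) {
    stop("lexicon has no usable frequency grid; see make_synthetic_lexicon()",
         call. = FALSE)
  }
  grid_ln <- log(lexicon$counts[grid_words])
  ord <- order(grid_ln)
  grid_words <- grid_words[ord]
  grid_ln <- grid_ln[ord]

  groups <- names(config$n_per_group)
  n_total <- sum(config$n_per_group)
  seeds <- participant_seeds(config$seed, n_total)
  samples <- vector("list", n_total)
  idx <- 0L
  for (g in groups) {
    prof <- config$profiles[[g]]
    for (i in seq_len(config$n_per_group[[g]])) {
      idx <- idx + 1L
      set.seed(seeds[idx])
      mention <- draw_mention_sets(1L, prof, unit_ids, cu_dict$theme_unit,
                                   config$focus_unit)[[1L]]
      targets <- list(
        freq = rnorm(1L, prof$freq_mean, prof$freq_sd),
        latency = rtruncnorm_calibrated(1L, prof$latency_mean,
                                        prof$latency_sd, lower = 0),
        relational = rtruncnorm_calibrated(1L, prof$relational_mean,
                                           prof$relational_sd,
                                           lower = 0, upper = 1),
        rate = rtruncnorm_calibrated(1L, prof$articulation_mean,
                                     prof$articulation_sd, lower = 0.5)
      )
      samples[[idx]] <- synthesize_transcript(
        participant_id = sprintf("%s_%03d", g, i), group = g,
        mention_forms = first_forms[mention], targets = targets,
        lexicon = lexicon, grid_words = grid_words, grid_ln = grid_ln
      )
    }
  }
  samples
}

# Build one synthetic transcript hitting the drawn per-sample targets.
synthesize_transcript <- function(participant_id, group, mention_forms,
                                  targets, lexicon, grid_words, grid_ln) {
  k <- length(mention_forms)
  f <- k + 8L
  m_u <- if (k > 0L) mean(log(lexicon_count(lexicon, mention_forms))) else 0
  v <- ((k + f) * targets$freq - k * m_u) / f
  v <- min(max(v, grid_ln[1L]), grid_ln[length(grid_ln)])
  filler <- grid_words[which.min(abs(grid_ln - v))]

  nouns <- c(mention_forms, rep(filler, f))
  base_text <- c("there", "be", rbind(rep("the", length(nouns)), nouns))
  base_lemma <- base_text
  base_upos <- c("PRON", "AUX", rbind(rep("DET", length(nouns)),
                                      rep("NOUN", length(nouns))))
  base_deprel <- c("expl", "root", rbind(rep("det", length(nouns)),
                                         rep("obj", length(nouns))))

  n0 <- length(base_text)
  r <- targets$relational
  n_case <- round(r / (1 - r) * n0)
  if (n_case > 0L) {
    adp <- rep_len(c("on", "in", "under", "near", "by", "over", "behind",
                     "beside"), n_case)
    pos <- seq(2.5, n0 - 0.5, length.out = n_case)  # interleave evenly
    o <- order(c(seq_len(n0), pos))
    text <- c(base_text, adp)[o]
    lemma <- c(base_lemma, adp)[o]
    upos <- c(base_upos, rep("ADP", n_case))[o]
    deprel <- c(base_deprel, rep("case", n_case))[o]
  } else {
    text <- base_text; lemma <- base_lemma
    upos <- base_upos; deprel <- base_deprel
  }

  n <- length(text)
  syl <- count_syllables(text)
  dur <- syl / targets$rate
  gaps <- if (n > 1L) {
    if (targets$latency <= 0) rep(0, n - 1L) else {
      e <- rexp(n - 1L)
      targets$latency * e / mean(e)
    }
  } else numeric()
  start <- cumsum(c(0, dur[-n] + gaps))
  transcript_sample(
    participant_id = participant_id, group = group, task = "picture",
    tokens = tibble::tibble(text = text, start = start, end = start + dur,
                            lemma = lemma, upos = upos, deprel = deprel,
                            syllables = syl)
  )
}
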