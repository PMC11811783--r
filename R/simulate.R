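# Synthetic cohort generator.
#
# Emulates the statistical structure the imputer assumes: subjects fall into
# behaviour classes (abstainer, quitter, reducer, persistent), drinking is
# weekend-heavy and right-skewed, many women stop or reduce on pregnancy
# recognition, and the instrument's visit-driven 30-day reporting windows
# induce informative missingness — the more recently a subject drank before a
# visit, the more of her earlier timeline is never covered. Both the complete
# and the observed timeline are returned so truth is known.

#' Generator configuration
#'
#' Defaults are chosen to resemble a prenatal-alcohol cohort: roughly 60\% of
#' subjects drink at some point, most of those quit or cut down after
#' recognising the pregnancy (uniformly between days 30 and 90), amounts per
#' drinking day are lognormal (right-skewed), and drinking-day probability is
#' weekend-heavy. Two site profiles differ in enrollment timing and drinking
#' prevalence: `"SA"` enrolls late (more early-pregnancy missingness, heavier
#' drinking), `"NP"` enrolls early with more abstainers.
#'
#' @param n_subjects Cohort size.
#' @param site_profile `"SA"` (late enrollment) or `"NP"` (early enrollment);
#'   sets profile defaults for any argument left `NULL`.
#' @param class_probs Named probabilities over
#'   `c("abstainer", "quitter", "reducer", "persistent")`; must sum to 1.
#' @param drink_prob Named per-class baseline probability that a given day is
#'   a drinking day (before the weekday multiplier).
#' @param base_rate Named per-class mean standard drinks on a drinking day.
#' @param weekday_multipliers Seven nonnegative multipliers (Monday..Sunday)
#'   applied to `drink_prob`; strongly weekend-heavy by default, reflecting
#'   episodic weekend drinking.
#' @param recognition_range Inclusive day range pregnancy recognition is
#'   drawn from uniformly (default 30..90).
#' @param reducer_factor Multiplier applied to a reducer's drinking
#'   probability and amount after recognition (default 0.35).
#' @param amount_sdlog Within-subject lognormal sdlog of the per-drinking-day
#'   amount (default 0.4: a given drinker's occasions are fairly similar;
#'   the heavy right tail across the cohort comes from `level_sdlog`).
#' @param level_sdlog Lognormal sdlog of a per-subject multiplier on the mean
#'   amount per drinking day (default 0.5): drinkers differ widely in how
#'   heavy they are, which is what the imputer's scaling adjustment targets.
#' @param freq_sdlog Lognormal sdlog of a per-subject multiplier on the
#'   drinking-day probability (default 0.3).
#' @param habit_sdlog Lognormal sdlog of per-subject jitter on the weekday
#'   profile (default 0.8). Each drinker's weekday propensities are the
#'   cohort multipliers times subject-specific lognormal noise, renormalised
#'   to preserve her overall drinking-day rate: she concentrates drinking on
#'   her own habitual days of the week, the subject-specific pattern
#'   structure the imputer's weekday-aligned matching assumes. Set 0 for a
#'   shared weekday profile.
#' @param enrollment_range Inclusive day range of the first visit; profile
#'   default SA 60..140, NP 15..70.
#' @param visit_interval_range Inclusive range the gap between successive
#'   antenatal visits is drawn from, per subject and visit (profile default
#'   SA 40..110, NP 25..75); a delivery visit at day 310 always closes the
#'   series. Variable spacing means some continuing drinkers get dense
#'   coverage while others accumulate long unreported stretches.
#' @param visit_days Optional fixed visit-day vector applied to every
#'   subject, overriding enrollment/interval.
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(n_subjects = 500L,
                             site_profile = c("SA", "NP"),
                             class_probs = NULL,
                             drink_prob = NULL,
                             base_rate = NULL,
                             weekday_multipliers = c(0.4, 0.4, 0.5, 0.7,
                                                     1.6, 2.4, 1.0),
                             recognition_range = c(30L, 90L),
                             reducer_factor = 0.35,
                             amount_sdlog = 0.4,
                             level_sdlog = 0.5,
                             freq_sdlog = 0.3,
                             habit_sdlog = 0.8,
                             enrollment_range = NULL,
                             visit_interval_range = NULL,
                             visit_days = NULL) {
  site_profile <- match.arg(site_profile)
  prof <- if (site_profile == "SA") {
    list(class_probs = c(abstainer = 0.30, quitter = 0.28,
                         reducer = 0.22, persistent = 0.20),
         drink_prob = c(abstainer = 0, quitter = 0.28,
                        reducer = 0.25, persistent = 0.32),
         base_rate = c(abstainer = 0, quitter = 4.0,
                       reducer = 3.5, persistent = 4.5),
         enrollment_range = c(60L, 140L), visit_interval_range = c(40L, 110L))
  } else {
    list(class_probs = c(abstainer = 0.50, quitter = 0.22,
                         reducer = 0.16, persistent = 0.12),
         drink_prob = c(abstainer = 0, quitter = 0.20,
                        reducer = 0.18, persistent = 0.24),
         base_rate = c(abstainer = 0, quitter = 2.8,
                       reducer = 2.5, persistent = 3.2),
         enrollment_range = c(15L, 70L), visit_interval_range = c(25L, 75L))
  }
  cfg <- list(n_subjects = as.integer(n_subjects),
              site_profile = site_profile,
              class_probs = if (is.null(class_probs)) prof$class_probs else class_probs,
              drink_prob = if (is.null(drink_prob)) prof$drink_prob else drink_prob,
              base_rate = if (is.null(base_rate)) prof$base_rate else base_rate,
              weekday_multipliers = as.numeric(weekday_multipliers),
              recognition_range = as.integer(recognition_range),
              reducer_factor = as.numeric(reducer_factor),
              amount_sdlog = as.numeric(amount_sdlog),
              level_sdlog = as.numeric(level_sdlog),
              freq_sdlog = as.numeric(freq_sdlog),
              habit_sdlog = as.numeric(habit_sdlog),
              enrollment_range = if (is.null(enrollment_range)) prof$enrollment_range
                                 else as.integer(enrollment_range),
              visit_interval_range = if (is.null(visit_interval_range))
                                       prof$visit_interval_range
                                     else as.integer(visit_interval_range),
              visit_days = if (is.null(visit_days)) NULL else as.integer(visit_days))
  stopifnot(cfg$n_subjects >= 1L,
            abs(sum(cfg$class_probs) - 1) < 1e-8,
            all(cfg$weekday_multipliers >= 0),
            length(cfg$weekday_multipliers) == 7L)
  structure(cfg, class = "generator_config")
}

#' Simulate a cohort of complete and observed timelines
#'
#' Uses R's current RNG stream; call `set.seed()` first for reproducibility.
#'
#' The observation mechanism mirrors the instrument: the enrollment interview
#' covers days -15..15 around LMP; at each visit the subject reports her last
#' drinking day and the 30 days before it, so the days from 29 days before
#' the last drink through the visit day are covered. A subject with no
#' drinking before a visit has her whole timeline up to that visit covered.
#' Hence recent drinkers accumulate unobserved stretches before each
#' reporting window, while abstainers and early quitters end up complete.
#'
#' @param config A [generator_config()].
#' @return List with `complete` and `observed`: parallel lists of
#'   `subject_timeline` objects (subject ids `"<profile>_0001"`, ...), plus
#'   `classes` (character vector) and `recognition_day` (integer vector).
#' @export
simulate_cohort <- function(config = generator_config()) {
  n <- config$n_subjects
  classes <- sample(names(config$class_probs), n, replace = TRUE,
                    prob = config$class_probs)
  recog <- sample(config$recognition_range[1]:config$recognition_range[2],
                  n, replace = TRUE)
  days <- gestational_days()
  complete <- observed <- vector("list", n)
  for (i in seq_len(n)) {
    id <- sprintf("%s_%04d", config$site_profile, i)
    swd <- sample(0:6, 1L)
    cls <- classes[i]
    wd <- weekday_of_day(swd, days)
    level <- stats::rlnorm(1L, -config$level_sdlog^2 / 2, config$level_sdlog)
    freq <- stats::rlnorm(1L, -config$freq_sdlog^2 / 2, config$freq_sdlog)
    habit <- config$weekday_multipliers *
      stats::rlnorm(7L, 0, config$habit_sdlog)
    habit <- 7 * habit / sum(habit)         # preserve the overall daily rate
    p <- pmin(config$drink_prob[[cls]] * freq * habit[wd + 1L], 0.95)
    amount_mean <- rep(config$base_rate[[cls]] * level, N_DAYS)
    post <- days > recog[i]
    if (cls == "quitter") p[post] <- 0
    if (cls == "reducer") {
      p[post] <- p[post] * config$reducer_factor
      amount_mean[post] <- amount_mean[post] * config$reducer_factor
    }
    p <- pmin(p, 1)
    drinking <- stats::runif(N_DAYS) < p
    drinks <- numeric(N_DAYS)
    if (any(drinking)) {
      mu <- amount_mean[drinking]
      drinks[drinking] <- stats::rlnorm(sum(drinking),
                                        meanlog = log(pmax(mu, 1e-6)) -
                                          config$amount_sdlog^2 / 2,
                                        sdlog = config$amount_sdlog)
    }
    complete[[i]] <- subject_timeline(id, config$site_profile, swd, drinks)

    visits <- if (!is.null(config$visit_days)) config$visit_days
              else {
                v <- sample(config$enrollment_range[1]:config$enrollment_range[2], 1L)
                vs <- v
                while (v < DAY_MAX) {
                  v <- v + sample(config$visit_interval_range[1]:
                                    config$visit_interval_range[2], 1L)
                  vs <- c(vs, min(v, DAY_MAX))
                }
                unique(c(vs, DAY_MAX))
              }
    mask <- rep(FALSE, N_DAYS)
    mask[day_to_pos(DAY_MIN:min(15L, DAY_MAX))] <- TRUE   # LMP interview window
    drink_days <- days[drinks > 0]
    for (v in sort(visits)) {
      prior <- drink_days[drink_days <= v]
      from <- if (!length(prior)) DAY_MIN
              else max(DAY_MIN, prior[length(prior)] - 29L)
      mask[day_to_pos(from:v)] <- TRUE
    }
    obs <- drinks
    obs[!mask] <- NA_real_
    observed[[i]] <- subject_timeline(id, config$site_profile, swd, obs)
  }
  names(complete) <- names(observed) <- vapply(complete, `[[`, "", "subject_id")
  list(complete = complete, observed = observed,
       classes = classes, recognition_day = recog)
}

#' Missingness summary of a cohort
#'
#' @param timelines List of `subject_timeline` objects (typically the
#'   observed arm of [simulate_cohort()]).
#' @return Named list: `pct_person_days_missing`, `pct_subjects_complete`,
#'   `pct_drinkers` (subjects whose defined days total at least 1 standard
#'   drink), `n_subjects`, `n_person_days`.
#' @export
missingness_summary <- function(timelines) {
  stopifnot(length(timelines) > 0L)
  n_missing <- vapply(timelines, function(tl) sum(is.na(tl$drinks)), 0L)
  totals <- vapply(timelines, function(tl) sum(tl$drinks, na.rm = TRUE), 0)
  list(pct_person_days_missing = 100 * sum(n_missing) /
         (length(timelines) * N_DAYS),
       pct_subjects_complete = 100 * mean(n_missing == 0L),
       pct_drinkers = 100 * mean(totals >= 1),
       n_subjects = length(timelines),
       n_person_days = length(timelines) * N_DAYS)
}
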