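test_that("generator config applies site profiles and validates inputs", {
  sa <- generator_config(10, "SA")
  np <- generator_config(10, "NP")
  expect_equal(sum(sa$class_probs), 1)
  expect_equal(sum(np$class_probs), 1)
  expect_gt(np$class_probs[["abstainer"]], sa$class_probs[["abstainer"]])
  expect_gt(sa$enrollment_range[1], np$enrollment_range[2] - 60)  # SA enrolls later
  expect_equal(sa$drink_prob[["abstainer"]], 0)
  expect_error(generator_config(10, "SA",
                                class_probs = c(abstainer = 0.5, quitter = 0.4,
                                                reducer = 0.2, persistent = 0.2)))
})

test_that("simulation is deterministic under a seed and well-formed", {
  cfg <- generator_config(15, "NP")
  set.seed(61); a <- simulate_cohort(cfg)
  set.seed(61); b <- simulate_cohort(cfg)
  expect_equal(a, b)
  expect_length(a$complete, 15)
  expect_length(a$observed, 15)
  expect_equal(names(a$complete)[1], "NP_0001")
  for (i in seq_along(a$complete)) {
    expect_true(all(!is.na(a$complete[[i]]$drinks)))
    expect_true(all(a$complete[[i]]$drinks >= 0))
    expect_equal(a$complete[[i]]$subject_id, a$observed[[i]]$subject_id)
    expect_equal(a$complete[[i]]$start_weekday, a$observed[[i]]$start_weekday)
  }
})

test_that("observed timelines are exact restrictions of the complete ones", {
  set.seed(62)
  sim <- simulate_cohort(generator_config(25, "SA"))
  for (i in seq_along(sim$complete)) {
    obs <- sim$observed[[i]]$drinks
    com <- sim$complete[[i]]$drinks
    def <- !is.na(obs)
    expect_equal(obs[def], com[def])
    # the enrollment interview always covers days -15..15
    expect_true(all(def[day_to_pos(-15:15)]))
    # the delivery visit covers the last day
    expect_true(def[day_to_pos(310)])
  }
})

test_that("abstainers never drink and are observed completely", {
  set.seed(63)
  sim <- simulate_cohort(generator_config(
    30, "NP", class_probs = c(abstainer = 1, quitter = 0,
                              reducer = 0, persistent = 0)))
  expect_true(all(sim$classes == "abstainer"))
  for (tl in sim$complete) expect_true(all(tl$drinks == 0))
  # nothing to report means every visit covers the whole span up to it
  for (tl in sim$observed) expect_true(all(!is.na(tl$drinks)))
})

test_that("quitters stop after recognition; reducers damp but continue", {
  set.seed(64)
  sim <- simulate_cohort(generator_config(
    60, "SA", class_probs = c(abstainer = 0, quitter = 0.5,
                              reducer = 0.5, persistent = 0)))
  days <- gestational_days()
  for (i in seq_along(sim$complete)) {
    post <- days > sim$recognition_day[i]
    d <- sim$complete[[i]]$drinks
    if (sim$classes[i] == "quitter") expect_true(all(d[post] == 0))
  }
  red <- which(sim$classes == "reducer")
  pre_mean <- mean(unlist(lapply(red, function(i)
    sim$complete[[i]]$drinks[!(days > sim$recognition_day[i])])))
  post_mean <- mean(unlist(lapply(red, function(i)
    sim$complete[[i]]$drinks[days > sim$recognition_day[i]])))
  expect_lt(post_mean, pre_mean / 2)       # 0.35 on both rate and amount
})

test_that("missingness is informative: recent drinking leaves unreported gaps", {
  set.seed(65)
  sim <- simulate_cohort(generator_config(120, "SA"))
  n_missing <- vapply(sim$observed, function(tl) sum(is.na(tl$drinks)), 0L)
  drinker <- vapply(sim$complete, function(tl) sum(tl$drinks) >= 1, TRUE)
  expect_gt(mean(n_missing[drinker]), mean(n_missing[!drinker]))
  expect_equal(mean(n_missing[!drinker]), 0)  # nondrinkers fully covered
})

test_that("late SA enrollment loses more of the first trimester than NP", {
  set.seed(66)
  sa <- simulate_cohort(generator_config(120, "SA"))$observed
  np <- simulate_cohort(generator_config(120, "NP"))$observed
  t1_pos <- day_to_pos(1):day_to_pos(93)
  miss_t1 <- function(cohort) mean(vapply(cohort, function(tl)
    sum(is.na(tl$drinks[t1_pos])), 0L))
  expect_gt(miss_t1(sa), miss_t1(np))
})

test_that("weekday habit jitter concentrates a drinker's days idiosyncratically", {
  set.seed(67)
  sim <- simulate_cohort(generator_config(
    80, "SA", class_probs = c(abstainer = 0, quitter = 0,
                              reducer = 0, persistent = 1)))
  days <- gestational_days()
  # per-subject modal drinking weekday varies across subjects
  modal <- vapply(sim$complete, function(tl) {
    wd <- weekday_of_day(tl$start_weekday, days)
    tab <- tapply(tl$drinks > 0, wd, mean)
    as.integer(names(which.max(tab)))
  }, 0L)
  expect_gte(length(unique(modal)), 3)
  # but the cohort aggregate stays weekend-heavy (Fri/Sat above Mon/Tue)
  agg <- numeric(7)
  for (tl in sim$complete) {
    wd <- weekday_of_day(tl$start_weekday, days)
    agg <- agg + tapply(tl$drinks > 0, factor(wd, 0:6), sum)
  }
  expect_gt(agg[6] + agg[5], 2 * (agg[1] + agg[2]))
})

test_that("missingness summary arithmetic is exact on a tiny cohort", {
  a <- make_tl("a", -15:310, rep(0, 326))              # complete nondrinker
  b <- make_tl("b", 1:163, rep(1, 163))                # half missing, drinker
  s <- missingness_summary(list(a, b))
  expect_equal(s$n_subjects, 2)
  expect_equal(s$n_person_days, 652)
  expect_equal(s$pct_person_days_missing, 100 * 163 / 652)
  expect_equal(s$pct_subjects_complete, 50)
  expect_equal(s$pct_drinkers, 50)
})
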