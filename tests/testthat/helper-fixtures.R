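# Fixture builders: everything is generated in code at test time.

# A 326-day drinks vector with values at the given gestational days, NA
# elsewhere (or `fill` elsewhere when given).
drinks_at <- function(days, values, fill = NA_real_) {
  d <- rep(fill, 326)
  d[day_to_pos(days)] <- values
  d
}

make_tl <- function(id, days, values, site = "other", start_weekday = 0,
                    fill = NA_real_) {
  subject_timeline(id, site, start_weekday, drinks_at(days, values, fill))
}

# Fully observed weekly-periodic drinker: `pattern` is the 7 drink values for
# the subject's weekdays 0..6 (Monday..Sunday), repeated across the timeline.
periodic_tl <- function(id, pattern, site = "other", start_weekday = 0) {
  wd <- weekday_of_day(start_weekday, gestational_days())
  subject_timeline(id, site, start_weekday, pattern[wd + 1])
}

# Small random cohort with holes, for round-trip and pool tests.
random_cohort <- function(n, p_obs = 0.7, lambda = 0.8, sites = "other") {
  lapply(seq_len(n), function(i) {
    obs <- runif(326) < p_obs
    d <- ifelse(obs, round(rexp(326, 1 / lambda), 2), NA_real_)
    subject_timeline(sprintf("r%03d", i), sample(sites, 1), sample(0:6, 1), d)
  })
}
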