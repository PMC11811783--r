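# Preprocessing: weekday anchoring and alignment, Winsorization, cohort
# exclusion filters.
#
# Drinking behaviour varies strongly by day of the week, so neighbour
# candidates are matched on the weekday grid: before comparing two subjects,
# one timeline is shifted by 0..6 days so that aligned positions fall on the
# same weekday. The weekday of a subject's day -15 is derived from the
# distance between its calendar date and a fixed anchor, Saturday 1 January
# 2000.

#' Weekday of a gestational day
#'
#' @param start_weekday Integer 0..6: weekday of day -15 (0 = Monday).
#' @param day Gestational day in `[-15, 310]`.
#' @return Integer 0..6: the weekday of `day`, i.e.
#'   `(start_weekday + (day + 15)) mod 7`.
#' @examples
#' weekday_of_day(2, -15)  # a Wednesday start is a Wednesday on day -15
#' weekday_of_day(0, -13)  # a Monday start puts day -13 on a Wednesday
#' @export
weekday_of_day <- function(start_weekday, day) {
  stopifnot(all(start_weekday >= 0L & start_weekday <= 6L),
            all(day >= DAY_MIN & day <= DAY_MAX))
  (as.integer(start_weekday) + (as.integer(day) - DAY_MIN)) %% 7L
}

#' Weekday index of a calendar date
#'
#' Computes the 0 = Monday .. 6 = Sunday weekday index of a calendar date from
#' its distance to the anchor Saturday, 1 January 2000. Use on the calendar
#' date of gestational day -15 to obtain a timeline's `start_weekday`.
#'
#' @param date A `Date` (or string coercible to one).
#' @return Integer 0..6.
#' @export
start_weekday_from_date <- function(date) {
  delta <- as.integer(as.Date(date) - as.Date("2000-01-01"))
  (((delta %% 7L) + 7L) %% 7L + 5L) %% 7L  # 2000-01-01 is a Saturday (= 5)
}

#' Align two timelines on the weekday grid
#'
#' Finds the shift `delta` in 0..6 such that shifting `q` forward by `delta`
#' days puts it on the same weekday grid as `p`: position i of `p` pairs with
#' position i + delta of `q`. The first `delta` days of `q` and the last
#' `delta` days of `p` drop out of the pairing.
#'
#' @param p,q `subject_timeline` objects (only their `start_weekday` is used).
#' @return An object of class `alignment_map`: a list with `shift` (integer
#'   0..6), `p_days` and `q_days` (equal-length integer vectors of paired
#'   gestational days), `dropped_head_q` and `dropped_tail_p`.
#' @examples
#' p <- subject_timeline("p", "SA", 2, rep(0, 326))  # day -15 is a Wednesday
#' q <- subject_timeline("q", "SA", 0, rep(0, 326))  # day -15 is a Monday
#' a <- align(p, q)
#' a$shift        # 2
#' a$q_days[1]    # -13: q's Wednesday paired with p's day -15
#' @export
align <- function(p, q) {
  stopifnot(inherits(p, "subject_timeline"), inherits(q, "subject_timeline"))
  delta <- (p$start_weekday - q$start_weekday) %% 7L
  p_days <- DAY_MIN:(DAY_MAX - delta)
  q_days <- (DAY_MIN + delta):DAY_MAX
  structure(list(shift = delta,
                 p_days = p_days,
                 q_days = q_days,
                 dropped_head_q = if (delta > 0L) DAY_MIN:(DAY_MIN + delta - 1L) else integer(0),
                 dropped_tail_p = if (delta > 0L) (DAY_MAX - delta + 1L):DAY_MAX else integer(0)),
            class = "alignment_map")
}

#' @export
print.alignment_map <- function(x, ...) {
  cat(sprintf("<alignment_map> shift = %d day(s); %d aligned pairs\n",
              x$shift, length(x$p_days)))
  cat(sprintf("  p day %d <-> q day %d ... p day %d <-> q day %d\n",
              x$p_days[1], x$q_days[1],
              x$p_days[length(x$p_days)], x$q_days[length(x$q_days)]))
  invisible(x)
}

#' Resolve per-site Winsorization caps
#'
#' An explicit numeric cap is used as-is. `"auto"` computes, per site,
#' mean + 3 SD of the drink values on observed drinking days (values > 0)
#' pooled across the site's subjects; outlier caps are only meaningful on the
#' drinking-day distribution since most person-days are zero.
#'
#' @param timelines List of `subject_timeline` objects.
#' @param caps Named vector, one entry per site, each a positive number or
#'   `"auto"`. Sites absent from `caps` are left uncapped (`Inf`).
#' @return Named numeric vector of caps per site.
#' @export
resolve_caps <- function(timelines, caps = c(SA = 21, NP = 28)) {
  sites <- unique(vapply(timelines, `[[`, "", "site"))
  out <- rep(Inf, length(sites))
  names(out) <- sites
  for (s in sites) {
    if (!s %in% names(caps)) next
    cap <- caps[[s]]
    if (identical(cap, "auto")) {
      vals <- unlist(lapply(timelines, function(tl)
        if (tl$site == s) tl$drinks[!is.na(tl$drinks) & tl$drinks > 0]
        else numeric(0)))
      if (length(vals) == 0L)
        stop(sprintf("cannot compute 'auto' cap for site '%s': no drinking days", s))
      out[s] <- mean(vals) + 3 * stats::sd(vals)
      if (is.na(out[s])) out[s] <- Inf  # single drinking day: sd undefined
    } else {
      cap <- as.numeric(cap)
      if (is.na(cap) || cap <= 0) stop("explicit cap must be > 0")
      out[s] <- cap
    }
  }
  out
}

#' Winsorize drink values at a site cap
#'
#' Caps observed drink values at the site's Winsorization threshold; the
#' observation mask is untouched and values at or below the cap are unchanged.
#' Idempotent.
#'
#' @param x A `subject_timeline`, or a list of them.
#' @param caps For a single timeline, a positive number; for a list, a named
#'   per-site vector as accepted by [resolve_caps()] (default: 21 for SA,
#'   28 for NP).
#' @return Object of the same shape with capped values.
#' @export
winsorize <- function(x, caps = c(SA = 21, NP = 28)) {
  if (inherits(x, "subject_timeline")) {
    cap <- as.numeric(caps)
    stopifnot(length(cap) == 1L, cap > 0)
    x$drinks <- pmin(x$drinks, cap)
    return(x)
  }
  stopifnot(is.list(x))
  capv <- resolve_caps(x, caps)
  lapply(x, function(tl) winsorize(tl, capv[[tl$site]]))
}

#' Trimester boundaries
#'
#' Gestational-day ranges used throughout: periconceptional -15..0, then three
#' 13-week trimesters from LMP (1..93, 94..186, 187..310; the third runs to
#' the maximum pregnancy length).
#'
#' @return Named list of `c(first_day, last_day)` pairs.
#' @export
trimester_boundaries <- function() {
  list(periconceptional = c(-15L, 0L),
       t1 = c(1L, 93L),
       t2 = c(94L, 186L),
       t3 = c(187L, 310L))
}

#' Apply cohort exclusion filters
#'
#' Drops subjects whose drinking pattern cannot be established: those with no
#' observed day in the first trimester, and those missing more than
#' `max_missing` days overall.
#'
#' @param timelines List of `subject_timeline` objects.
#' @param max_missing Maximum tolerated number of unobserved days (default 200).
#' @param t1 First-trimester day range, default from [trimester_boundaries()].
#' @return List with `kept` (timelines passing both filters) and `dropped`
#'   (data.frame `subject_id`, `reason`; the first triggered rule is reported).
#' @export
apply_exclusions <- function(timelines, max_missing = 200L,
                             t1 = trimester_boundaries()$t1) {
  t1_pos <- day_to_pos(t1[1]):day_to_pos(t1[2])
  reasons <- vapply(timelines, function(tl) {
    if (!any(!is.na(tl$drinks[t1_pos]))) return("no_trimester1_data")
    if (sum(is.na(tl$drinks)) > max_missing) return("too_many_missing_days")
    NA_character_
  }, "")
  keep <- is.na(reasons)
  dropped <- data.frame(
    subject_id = vapply(timelines[!keep], `[[`, "", "subject_id"),
    reason = reasons[!keep], row.names = NULL)
  list(kept = timelines[keep], dropped = dropped)
}
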