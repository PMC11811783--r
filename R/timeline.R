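# Core domain object: one subject's day-indexed drinking timeline.
#
# A pregnancy timeline covers gestational days -15..310 relative to the last
# menstrual period (LMP, day 0): two weeks before LMP through the maximum
# pregnancy length. The vector therefore always has 326 positions; days the
# instrument did not cover are NA.

DAY_MIN <- -15L
DAY_MAX <- 310L
N_DAYS <- 326L

#' Gestational day index
#'
#' The fixed day range every timeline is indexed by: gestational day -15 (two
#' weeks before the last menstrual period) through day 310 (maximum pregnancy
#' length), 326 positions in total.
#'
#' @return Integer vector `-15:310`.
#' @export
gestational_days <- function() DAY_MIN:DAY_MAX

#' Convert between gestational day index and vector position
#'
#' @param day Integer gestational day in `[-15, 310]`.
#' @param pos Integer position in `[1, 326]`.
#' @return `day_to_pos()` gives the 1-based position of a gestational day in a
#'   timeline vector; `pos_to_day()` is its inverse.
#' @export
day_to_pos <- function(day) as.integer(day) - DAY_MIN + 1L

#' @rdname day_to_pos
#' @export
pos_to_day <- function(pos) as.integer(pos) + DAY_MIN - 1L

#' Construct a subject timeline
#'
#' @param subject_id Character scalar identifying the subject.
#' @param site Site label; conventionally `"SA"` (South Africa-like),
#'   `"NP"` (Northern Plains-like) or `"other"`.
#' @param start_weekday Integer 0..6: weekday of gestational day -15, with the
#'   convention 0 = Monday .. 6 = Sunday. See [start_weekday_from_date()] to
#'   derive it from a calendar date.
#' @param drinks Numeric vector of length 326 (days -15..310): standard drinks
#'   per day, `NA` where the day is unobserved. All defined values must be
#'   nonnegative.
#' @param provenance Optional character vector of length 326 recording, for
#'   each defined position, whether it is `"observed"`, `"imputed"` or
#'   `"imputed_chained"`; `NA` at undefined positions. Defaults to
#'   `"observed"` wherever `drinks` is defined.
#' @return An object of class `subject_timeline`.
#' @examples
#' d <- rep(NA_real_, 326)
#' d[day_to_pos(1:10)] <- c(2, 0, 0, 3, 0, 0, 0, 4, 1, 0)
#' tl <- subject_timeline("s1", "SA", start_weekday = 2, drinks = d)
#' tl
#' @export
subject_timeline <- function(subject_id, site = "other", start_weekday,
                             drinks, provenance = NULL) {
  subject_id <- as.character(subject_id)
  stopifnot(length(subject_id) == 1L, nchar(subject_id) > 0L)
  start_weekday <- as.integer(start_weekday)
  if (length(start_weekday) != 1L || is.na(start_weekday) ||
      start_weekday < 0L || start_weekday > 6L)
    stop("'start_weekday' must be a single integer in 0..6 (0 = Monday)")
  drinks <- as.numeric(drinks)
  if (length(drinks) != N_DAYS)
    stop(sprintf("'drinks' must have length %d (days %d..%d); got %d",
                 N_DAYS, DAY_MIN, DAY_MAX, length(drinks)))
  if (any(drinks < 0, na.rm = TRUE))
    stop(sprintf("negative drink values for subject '%s'", subject_id))
  defined <- !is.na(drinks)
  if (is.null(provenance)) {
    provenance <- ifelse(defined, "observed", NA_character_)
  } else {
    provenance <- as.character(provenance)
    if (length(provenance) != N_DAYS)
      stop("'provenance' must have length 326")
    if (any(defined != !is.na(provenance)))
      stop("'provenance' must be defined exactly where 'drinks' is defined")
  }
  structure(list(subject_id = subject_id,
                 site = as.character(site),
                 start_weekday = start_weekday,
                 drinks = drinks,
                 provenance = provenance),
            class = "subject_timeline")
}

#' Observation mask of a timeline
#'
#' @param x A `subject_timeline`.
#' @return Logical vector of length 326: `TRUE` where the day has a defined
#'   value (observed or imputed).
#' @export
observed_mask <- function(x) {
  stopifnot(inherits(x, "subject_timeline"))
  !is.na(x$drinks)
}

#' @export
print.subject_timeline <- function(x, ...) {
  n_def <- sum(!is.na(x$drinks))
  n_imp <- sum(x$provenance %in% c("imputed", "imputed_chained"))
  cat(sprintf("<subject_timeline> %s  site=%s  start_weekday=%d\n",
              x$subject_id, x$site, x$start_weekday))
  cat(sprintf("  days %d..%d: %d defined (%d imputed), %d missing\n",
              DAY_MIN, DAY_MAX, n_def, n_imp, N_DAYS - n_def))
  invisible(x)
}

# Maximal runs of missing days, as a data.frame (start_day, end_day, length).
missing_runs <- function(x) {
  r <- rle(is.na(x$drinks))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(start_day = pos_to_day(starts[keep]),
             end_day = pos_to_day(ends[keep]),
             length = r$lengths[keep])
}
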