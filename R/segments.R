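# Reference-segment pool: every gap-free L-day slice of every subject's
# timeline is a neighbour candidate. Pooling segments from ALL subjects —
# including those with missing data elsewhere — matters because subjects with
# complete timelines tend to be nondrinkers or light drinkers, and using only
# them as neighbours would bias imputed values downward.

#' Extract all gap-free segments of length L
#'
#' @param timelines List of `subject_timeline` objects (Winsorize first if
#'   caps apply; segment values are copied as-is).
#' @param L Segment length in days.
#' @param stride Spacing between candidate start positions (1 = maximally
#'   overlapping windows, `L` = disjoint).
#' @return An object of class `segment_pool`: list with `values` (matrix,
#'   one row per segment, `L` columns), `subject_id`, `site`, `start_day`,
#'   `start_weekday` (parallel vectors) and `L`. The pool may be empty.
#' @export
extract_segments <- function(timelines, L, stride = 1L) {
  L <- as.integer(L); stride <- as.integer(stride)
  stopifnot(L >= 1L, L <= N_DAYS, stride >= 1L)
  per <- lapply(timelines, function(tl) {
    obs <- !is.na(tl$drinks)
    cs <- c(0L, cumsum(obs))
    starts <- seq.int(1L, N_DAYS - L + 1L, by = stride)
    starts <- starts[cs[starts + L] - cs[starts] == L]
    if (!length(starts)) return(NULL)
    vals <- matrix(tl$drinks[outer(starts, 0:(L - 1L), `+`)],
                   nrow = length(starts), ncol = L)
    list(values = vals,
         subject_id = rep(tl$subject_id, length(starts)),
         site = rep(tl$site, length(starts)),
         start_day = pos_to_day(starts),
         start_weekday = weekday_of_day(tl$start_weekday, pos_to_day(starts)))
  })
  per <- per[!vapply(per, is.null, TRUE)]
  if (!length(per)) {
    return(structure(list(values = matrix(numeric(0), 0L, L),
                          subject_id = character(0), site = character(0),
                          start_day = integer(0), start_weekday = integer(0),
                          L = L),
                     class = "segment_pool"))
  }
  structure(list(values = do.call(rbind, lapply(per, `[[`, "values")),
                 subject_id = unlist(lapply(per, `[[`, "subject_id"), use.names = FALSE),
                 site = unlist(lapply(per, `[[`, "site"), use.names = FALSE),
                 start_day = unlist(lapply(per, `[[`, "start_day"), use.names = FALSE),
                 start_weekday = unlist(lapply(per, `[[`, "start_weekday"), use.names = FALSE),
                 L = L),
            class = "segment_pool")
}

#' Number of segments in a pool
#' @param pool A `segment_pool`.
#' @return Integer count.
#' @export
n_segments <- function(pool) nrow(pool$values)

#' @export
print.segment_pool <- function(x, ...) {
  cat(sprintf("<segment_pool> %d segment(s) of length %d from %d subject(s)\n",
              n_segments(x), x$L, length(unique(x$subject_id))))
  invisible(x)
}

# Complete-window count for one observation mask without materialising values.
count_complete_windows <- function(obs, L) {
  r <- rle(obs)
  sum(pmax(0L, r$lengths[r$values] - L + 1L))
}

#' Segment-count versus segment-length trade-off curve
#'
#' For each candidate length, the mean number of gap-free windows (stride 1)
#' per subject. Shorter segments yield more reference material but
#' characterise drinking patterns less specifically; the curve supports
#' choosing the default length of 55 days (about two months).
#'
#' @param timelines List of `subject_timeline` objects.
#' @param lengths Integer vector of candidate segment lengths.
#' @return data.frame with columns `length` and `mean_segments`
#'   (nonincreasing in `length`).
#' @export
segments_curve <- function(timelines, lengths = c(7, 14, 28, 55, 83, 111,
                                                  166, 222, 326)) {
  stopifnot(length(timelines) > 0L)
  lengths <- sort(unique(as.integer(lengths)))
  masks <- lapply(timelines, function(tl) !is.na(tl$drinks))
  mean_seg <- vapply(lengths, function(L)
    mean(vapply(masks, count_complete_windows, 0L, L = L)), 0)
  data.frame(length = lengths, mean_segments = mean_seg)
}
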