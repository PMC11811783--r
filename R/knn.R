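# The k-NN imputation core.
#
# A missing gap is filled from the k reference segments whose drinking
# pattern, compared over the query window's observed days on a weekday-aligned
# grid, is most similar in the cosine sense. Cosine similarity is
# magnitude-blind — it captures the *pattern* (e.g. "three times more on day 1
# than day 2") regardless of level — so each neighbour's contribution is
# rescaled by the ratio of Euclidean norms over the shared observed days to
# restore the query subject's own consumption level. Imputed values are the
# similarity-weighted average of the rescaled neighbour values.

#' Imputation configuration
#'
#' @param k Number of neighbours (default 5).
#' @param L Reference-segment / query-window length in days (default 55).
#' @param min_overlap Minimum number of observed query days a candidate must
#'   share with the window to be comparable (default 7, one week).
#' @param position_tolerance Maximum allowed difference in days between a
#'   candidate segment's start and the query window's start (default 28);
#'   `"unbounded"` disables the constraint. Drinking has a strong gestational
#'   trend, so by default candidates must come from a similar pregnancy
#'   period.
#' @param include_self_segments Whether a subject's own gap-free segments may
#'   serve as neighbours for their other gaps (default `TRUE`). Self-segments
#'   overlapping the gap being imputed are always excluded.
#' @param classify_threshold Total drinks at or above which an (imputed)
#'   segment is classified as drinking (default 0.5).
#' @param stride Segment-extraction stride used when a pool is built
#'   implicitly (default 1).
#' @return An object of class `imputation_config`.
#' @export
imputation_config <- function(k = 5L, L = 55L, min_overlap = 7L,
                              position_tolerance = 28L,
                              include_self_segments = TRUE,
                              classify_threshold = 0.5, stride = 1L) {
  if (identical(position_tolerance, "unbounded")) position_tolerance <- Inf
  position_tolerance <- as.numeric(position_tolerance)
  k <- as.integer(k); L <- as.integer(L); min_overlap <- as.integer(min_overlap)
  stopifnot(k >= 1L, L >= 1L, min_overlap >= 1L, min_overlap <= L,
            position_tolerance >= 0, stride >= 1L)
  structure(list(k = k, L = L, min_overlap = min_overlap,
                 position_tolerance = position_tolerance,
                 include_self_segments = isTRUE(include_self_segments),
                 classify_threshold = as.numeric(classify_threshold),
                 stride = as.integer(stride)),
            class = "imputation_config")
}

#' @export
print.imputation_config <- function(x, ...) {
  cat(sprintf(paste0("<imputation_config> k=%d L=%d min_overlap=%d ",
                     "position_tolerance=%s self_segments=%s tau=%g\n"),
              x$k, x$L, x$min_overlap,
              if (is.infinite(x$position_tolerance)) "unbounded"
              else format(x$position_tolerance),
              x$include_self_segments, x$classify_threshold))
  invisible(x)
}

#' Masked cosine similarity
#'
#' Cosine of the angle between two nonnegative vectors restricted to the
#' masked positions. Conventions for degenerate sub-vectors: both zero gives
#' similarity 1 (two abstinent stretches have identical pattern), exactly one
#' zero gives 0. Cosine distance is `1 - similarity`.
#'
#' @param x,y Numeric vectors of equal length, nonnegative on masked
#'   positions.
#' @param mask Logical vector selecting the positions to compare; `NULL`
#'   compares all positions. Must select at least one position.
#' @return Similarity in `[0, 1]`.
#' @examples
#' cosine_similarity(c(3, 1), c(6, 2))  # same 3:1 pattern -> 1
#' cosine_similarity(c(1, 0), c(0, 1))  # orthogonal -> 0
#' @export
cosine_similarity <- function(x, y, mask = NULL) {
  stopifnot(length(x) == length(y))
  if (is.null(mask)) mask <- rep(TRUE, length(x))
  stopifnot(length(mask) == length(x))
  xs <- x[mask]; ys <- y[mask]
  if (length(xs) == 0L) stop("empty mask: no positions to compare")
  nx <- sqrt(sum(xs^2)); ny <- sqrt(sum(ys^2))
  if (nx == 0 && ny == 0) return(1)
  if (nx == 0 || ny == 0) return(0)
  min(max(sum(xs * ys) / (nx * ny), 0), 1)
}

#' Consumption-level scale factor
#'
#' Ratio of Euclidean norms, query over segment, computed on the masked
#' (observed-overlap) positions. Multiplying a neighbour's values by this
#' factor restores the query subject's consumption magnitude, which cosine
#' matching deliberately ignores.
#'
#' @param query_values,segment_values Numeric vectors of equal length.
#' @param mask Logical vector of the positions entering the ratio (`NULL` =
#'   all).
#' @return Nonnegative scale; 1 when the segment's overlap norm is 0, 0 when
#'   only the query's is.
#' @examples
#' scale_factor(c(3, 1), c(6, 2))  # 0.5: same pattern at half the level
#' @export
scale_factor <- function(query_values, segment_values, mask = NULL) {
  stopifnot(length(query_values) == length(segment_values))
  if (is.null(mask)) mask <- rep(TRUE, length(query_values))
  qn <- sqrt(sum(query_values[mask]^2))
  sn <- sqrt(sum(segment_values[mask]^2))
  if (sn == 0) return(1)
  qn / sn
}

#' Build a query window around a gap
#'
#' Positions an L-day window to centre the gap, shifting as needed to stay
#' within the gestational day range. The window records the working values
#' (observed, or previously imputed during chained imputation) and which
#' positions count as context.
#'
#' @param timeline A `subject_timeline` (its current defined values are the
#'   context).
#' @param gap_start,gap_end Gestational days of the contiguous target run to
#'   fill (inclusive; at most `L` days).
#' @param config An [imputation_config()].
#' @return An object of class `query_window`: list with `subject_id`, `site`,
#'   `window_start` (day), `values` (length L, `NA` outside the context),
#'   `observed_mask`, `gap_days`, `start_weekday` (weekday of the window's
#'   first day).
#' @export
query_window <- function(timeline, gap_start, gap_end, config = imputation_config()) {
  stopifnot(inherits(timeline, "subject_timeline"),
            gap_start >= DAY_MIN, gap_end <= DAY_MAX, gap_start <= gap_end)
  L <- config$L
  g_len <- gap_end - gap_start + 1L
  if (g_len > L) stop("gap longer than the window; chunk it first")
  centre <- (gap_start + gap_end) %/% 2L
  ws <- centre - (L - 1L) %/% 2L
  ws <- max(DAY_MIN, min(ws, DAY_MAX - L + 1L))
  ws <- min(ws, gap_start)              # keep the whole gap inside the window
  ws <- max(ws, gap_end - L + 1L)
  # among all placements containing the gap, shift to maximise defined
  # context days; ties go to the placement nearest the centred one
  lo <- max(DAY_MIN, gap_end - L + 1L)
  hi <- min(DAY_MAX - L + 1L, gap_start)
  cand <- lo:hi
  cum <- c(0L, cumsum(!is.na(timeline$drinks)))
  ctx <- cum[day_to_pos(cand) + L] - cum[day_to_pos(cand)]
  best <- cand[ctx == max(ctx)]
  ws <- best[which.min(abs(best - ws))]
  pos <- day_to_pos(ws):day_to_pos(ws + L - 1L)
  vals <- timeline$drinks[pos]
  mask <- !is.na(vals)
  gap_rel <- (gap_start:gap_end) - ws + 1L
  mask[gap_rel] <- FALSE                # never use target positions as context
  vals[!mask] <- NA_real_
  structure(list(subject_id = timeline$subject_id, site = timeline$site,
                 window_start = ws, values = vals, observed_mask = mask,
                 gap_days = gap_start:gap_end,
                 start_weekday = weekday_of_day(timeline$start_weekday, ws)),
            class = "query_window")
}

#' Find the k nearest reference segments for a query window
#'
#' Candidates are filtered to those (a) starting on the same weekday as the
#' query window (weekday alignment), (b) within `position_tolerance` days of
#' the window start, (c) covering every gap day, (d) sharing at least
#' `min_overlap` observed query days, and (e) not being a self-segment that
#' overlaps the gap (nor any self-segment when `include_self_segments` is
#' `FALSE`). The top k by masked cosine similarity are returned; ties are
#' broken by proximity of segment start to window start, then subject id,
#' then start day. Weights are similarities normalised to sum to 1 (uniform
#' when all are 0).
#'
#' @param query A [query_window()].
#' @param pool A `segment_pool` with the same `L`.
#' @param config An [imputation_config()].
#' @return An object of class `neighbor_matches`: data.frame with columns
#'   `pool_index`, `subject_id`, `site`, `start_day`, `offset`, `similarity`,
#'   `weight`, `scale`. Zero rows when no candidate is eligible (the gap is
#'   un-imputable).
#' @export
find_neighbors <- function(query, pool, config = imputation_config()) {
  stopifnot(inherits(query, "query_window"), inherits(pool, "segment_pool"),
            pool$L == config$L)
  L <- config$L
  ws <- query$window_start
  gap_lo <- query$gap_days[1]
  gap_hi <- query$gap_days[length(query$gap_days)]
  cand <- which(pool$start_weekday == query$start_weekday &
                  abs(pool$start_day - ws) <= config$position_tolerance &
                  pool$start_day <= gap_lo &
                  pool$start_day + L - 1L >= gap_hi)
  if (length(cand)) {
    own <- pool$subject_id[cand] == query$subject_id
    if (!config$include_self_segments) {
      cand <- cand[!own]
    } else if (any(own)) {
      overlaps_gap <- pool$start_day[cand] <= gap_hi &
        pool$start_day[cand] + L - 1L >= gap_lo
      cand <- cand[!(own & overlaps_gap)]
    }
  }
  empty <- data.frame(pool_index = integer(0), subject_id = character(0),
                      site = character(0), start_day = integer(0),
                      offset = integer(0), similarity = numeric(0),
                      weight = numeric(0), scale = numeric(0))
  class(empty) <- c("neighbor_matches", "data.frame")
  if (!length(cand)) return(empty)

  obs_pos <- which(query$observed_mask)
  qv <- query$values
  delta <- pool$start_day[cand] - ws
  sims <- rep(NA_real_, length(cand))
  scales <- rep(NA_real_, length(cand))
  for (d in unique(delta)) {
    idx <- which(delta == d)
    lo <- max(1L, 1L + d); hi <- min(L, L + d)   # window positions the segment covers
    op <- obs_pos[obs_pos >= lo & obs_pos <= hi]
    if (length(op) < config$min_overlap) next
    qs <- qv[op]
    M <- pool$values[cand[idx], op - d, drop = FALSE]
    qn <- sqrt(sum(qs^2))
    sn <- sqrt(rowSums(M^2))
    dots <- as.numeric(M %*% qs)
    s <- if (qn == 0) ifelse(sn == 0, 1, 0)
         else ifelse(sn == 0, 0, pmin(pmax(dots / (qn * sn), 0), 1))
    sims[idx] <- s
    scales[idx] <- ifelse(sn == 0, 1, qn / sn)
  }
  ok <- !is.na(sims)
  if (!any(ok)) return(empty)
  cand <- cand[ok]; delta <- delta[ok]; sims <- sims[ok]; scales <- scales[ok]
  ord <- order(-sims, abs(delta), pool$subject_id[cand], pool$start_day[cand])
  top <- ord[seq_len(min(config$k, length(ord)))]
  sim_top <- sims[top]
  w <- if (sum(sim_top) > 0) sim_top / sum(sim_top)
       else rep(1 / length(top), length(top))
  out <- data.frame(pool_index = cand[top],
                    subject_id = pool$subject_id[cand[top]],
                    site = pool$site[cand[top]],
                    start_day = pool$start_day[cand[top]],
                    offset = delta[top],
                    similarity = sim_top,
                    weight = w,
                    scale = scales[top])
  class(out) <- c("neighbor_matches", "data.frame")
  out
}

#' Impute the gap of a query window from matched neighbours
#'
#' For each gap day d, the estimate is the weight- and scale-adjusted average
#' `sum_j w_j * s_j * segment_j[d]`, clipped to `[0, cap]`.
#'
#' @param query A [query_window()].
#' @param matches A `neighbor_matches` table from [find_neighbors()] (at
#'   least one row).
#' @param pool The `segment_pool` the matches index into.
#' @param cap Upper clip (the site's Winsorization cap); default `Inf`.
#' @return Numeric vector of imputed values, one per gap day.
#' @export
impute_gap <- function(query, matches, pool, cap = Inf) {
  stopifnot(inherits(query, "query_window"), nrow(matches) >= 1L)
  ws <- matches$start_day
  vapply(query$gap_days, function(d) {
    cols <- d - ws + 1L
    vals <- pool$values[cbind(matches$pool_index, cols)]
    min(max(sum(matches$weight * matches$scale * vals), 0), cap)
  }, 0)
}

#' Impute every missing gap in a cohort
#'
#' Processes each subject's maximal missing runs left to right. Runs that fit
#' one query window are imputed directly; longer runs are partitioned into
#' chunks of at most `L - min_overlap` days, imputed in order so that earlier
#' chunks provide (flagged) context for later ones. Observed values are never
#' modified. Gaps with no eligible neighbour are left `NA` and reported.
#'
#' @param timelines Preprocessed (Winsorized, exclusion-filtered) list of
#'   `subject_timeline` objects.
#' @param config An [imputation_config()].
#' @param pool Optional pre-built `segment_pool`; by default segments are
#'   extracted from `timelines` with the config's `L` and `stride`.
#' @param caps Named per-site cap vector used to clip imputed values
#'   (default: 21 for SA, 28 for NP; sites without a cap are unclipped).
#' @return List with `timelines` (imputed; provenance flags `"imputed"` /
#'   `"imputed_chained"`) and `gaps`, a data.frame describing every processed
#'   run (`subject_id`, `start_day`, `end_day`, `length`, `status`,
#'   `n_chunks`).
#' @export
impute_all <- function(timelines, config = imputation_config(), pool = NULL,
                       caps = c(SA = 21, NP = 28)) {
  if (is.null(pool))
    pool <- extract_segments(timelines, config$L, config$stride)
  capv <- resolve_caps(timelines, caps)
  max_chunk <- max(1L, config$L - config$min_overlap)
  gap_log <- list()
  out <- lapply(timelines, function(tl) {
    runs <- missing_runs(tl)
    if (!nrow(runs)) return(tl)
    cap <- capv[[tl$site]]
    for (r in seq_len(nrow(runs))) {
      g0 <- runs$start_day[r]; g1 <- runs$end_day[r]
      chunk_starts <- seq.int(g0, g1, by = max_chunk)
      chained <- length(chunk_starts) > 1L
      status <- "imputed"
      for (cs in chunk_starts) {
        ce <- min(cs + max_chunk - 1L, g1)
        qw <- query_window(tl, cs, ce, config)
        nb <- find_neighbors(qw, pool, config)
        if (!nrow(nb)) { status <- "unimputable"; next }
        vals <- impute_gap(qw, nb, pool, cap)
        pos <- day_to_pos(cs:ce)
        tl$drinks[pos] <- vals
        tl$provenance[pos] <- if (chained) "imputed_chained" else "imputed"
      }
      gap_log[[length(gap_log) + 1L]] <<- data.frame(
        subject_id = tl$subject_id, start_day = g0, end_day = g1,
        length = g1 - g0 + 1L, status = status,
        n_chunks = length(chunk_starts))
    }
    tl
  })
  gaps <- if (length(gap_log)) do.call(rbind, gap_log)
          else data.frame(subject_id = character(0), start_day = integer(0),
                          end_day = integer(0), length = integer(0),
                          status = character(0), n_chunks = integer(0))
  list(timelines = out, gaps = gaps)
}
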