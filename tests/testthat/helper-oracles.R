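# Independent brute-force oracles, deliberately written as plain loops over
# the published contracts rather than reusing the package's vectorised paths.

# Calendar oracle for weekday alignment: realise day -15 as an actual date
# with the requested weekday and let Date arithmetic do the rest.
# 2000-01-03 is a Monday (weekday index 0).
oracle_weekday <- function(start_weekday, day) {
  date0 <- as.Date("2000-01-03") + start_weekday
  as.integer(format(date0 + (day + 15), "%u")) - 1L
}

oracle_align_shift <- function(wd_p, wd_q) {
  for (delta in 0:6) {
    if (oracle_weekday(wd_q, -15 + delta) == oracle_weekday(wd_p, -15)) return(delta)
  }
  stop("no shift found")
}

# All complete L-windows of a timeline by scanning every start position.
oracle_segment_starts <- function(tl, L, stride = 1) {
  starts <- integer(0)
  for (p in seq(1, 326 - L + 1, by = stride)) {
    if (all(!is.na(tl$drinks[p:(p + L - 1)]))) starts <- c(starts, p)
  }
  pos_to_day(starts)
}

# Exhaustive neighbour ranking over every pool segment, applying the
# documented filters and tie-breaks one candidate at a time.
oracle_neighbors <- function(query, pool, config) {
  L <- config$L
  ws <- query$window_start
  gap_lo <- query$gap_days[1]
  gap_hi <- query$gap_days[length(query$gap_days)]
  obs <- which(query$observed_mask)
  rows <- list()
  for (j in seq_len(n_segments(pool))) {
    if (pool$start_weekday[j] != query$start_weekday) next
    if (abs(pool$start_day[j] - ws) > config$position_tolerance) next
    if (!(pool$start_day[j] <= gap_lo && pool$start_day[j] + L - 1 >= gap_hi)) next
    if (pool$subject_id[j] == query$subject_id) {
      overlaps_gap <- pool$start_day[j] <= gap_hi && pool$start_day[j] + L - 1 >= gap_lo
      if (!config$include_self_segments || overlaps_gap) next
    }
    d <- pool$start_day[j] - ws
    covered <- obs[obs >= max(1, 1 + d) & obs <= min(L, L + d)]
    if (length(covered) < config$min_overlap) next
    qs <- query$values[covered]
    ss <- pool$values[j, covered - d]
    sim <- cosine_similarity(qs, ss)
    sc <- if (sqrt(sum(ss^2)) == 0) 1 else sqrt(sum(qs^2)) / sqrt(sum(ss^2))
    rows[[length(rows) + 1]] <- data.frame(
      pool_index = j, subject_id = pool$subject_id[j],
      start_day = pool$start_day[j], offset = d, similarity = sim, scale = sc)
  }
  if (!length(rows)) return(NULL)
  tab <- do.call(rbind, rows)
  tab <- tab[order(-tab$similarity, abs(tab$offset), tab$subject_id,
                   tab$start_day), ]
  tab[seq_len(min(config$k, nrow(tab))), ]
}
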