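# Long-format I/O. The canonical on-disk form is a long CSV with one row per
# defined (subject, day) pair: subject_id, site, start_weekday, day, drinks
# [, provenance]. Sparse observation makes the long form natural; the wide
# 326-column form lives only in memory.

#' Read timelines from long-format records
#'
#' Converts long-format rows (one row per defined subject-day) into a list of
#' [subject_timeline] objects. Days absent from the input become unobserved
#' positions.
#'
#' @param records A data.frame with columns `subject_id`, `site`,
#'   `start_weekday`, `day`, `drinks` and optionally `provenance`, or the path
#'   of a CSV file with those columns.
#' @return Named list of `subject_timeline` objects (names = subject ids, in
#'   first-appearance order).
#' @details Hard errors are raised for duplicate (subject, day) pairs, days
#'   outside `[-15, 310]`, negative drink values, and subjects whose rows
#'   disagree on `site` or `start_weekday`.
#' @seealso [write_long()] for the inverse.
#' @export
read_long <- function(records) {
  if (is.character(records) && length(records) == 1L) {
    if (!file.exists(records)) stop("input file not found: ", records)
    records <- utils::read.csv(records, stringsAsFactors = FALSE)
  }
  records <- as.data.frame(records)
  need <- c("subject_id", "site", "start_weekday", "day", "drinks")
  miss <- setdiff(need, names(records))
  if (length(miss))
    stop("missing required columns: ", paste(miss, collapse = ", "))
  day <- as.integer(records$day)
  bad <- which(day < DAY_MIN | day > DAY_MAX)
  if (length(bad))
    stop(sprintf("day out of range [-15, 310]: subject '%s', day %d",
                 records$subject_id[bad[1]], day[bad[1]]))
  drinks <- as.numeric(records$drinks)
  bad <- which(drinks < 0)
  if (length(bad))
    stop(sprintf("negative drinks: subject '%s', day %d",
                 records$subject_id[bad[1]], day[bad[1]]))
  key <- paste(records$subject_id, day, sep = "\r")
  dup <- which(duplicated(key))
  if (length(dup))
    stop(sprintf("duplicate (subject, day) pair: subject '%s', day %d",
                 records$subject_id[dup[1]], day[dup[1]]))
  has_prov <- "provenance" %in% names(records)
  ids <- unique(as.character(records$subject_id))
  out <- lapply(ids, function(id) {
    rows <- records$subject_id == id
    site <- unique(as.character(records$site[rows]))
    swd <- unique(as.integer(records$start_weekday[rows]))
    if (length(site) != 1L || length(swd) != 1L)
      stop(sprintf("subject '%s' has inconsistent site or start_weekday", id))
    d <- rep(NA_real_, N_DAYS)
    d[day_to_pos(day[rows])] <- drinks[rows]
    prov <- NULL
    if (has_prov) {
      prov <- rep(NA_character_, N_DAYS)
      prov[day_to_pos(day[rows])] <- as.character(records$provenance[rows])
    }
    subject_timeline(id, site, swd, d, prov)
  })
  names(out) <- ids
  out
}

#' Write timelines as long-format records
#'
#' One row per defined (subject, day) pair; unobserved days are simply absent,
#' so `read_long(write_long(x))` reproduces `x` exactly.
#'
#' @param timelines List of `subject_timeline` objects.
#' @param file Optional path; when given, the table is also written as CSV
#'   (UTF-8, `"."` decimal).
#' @param include_provenance If `TRUE` (default), each row carries an
#'   observed/imputed provenance flag.
#' @return The long-format data.frame, invisibly when `file` is given.
#' @export
write_long <- function(timelines, file = NULL, include_provenance = TRUE) {
  stopifnot(length(timelines) > 0L)
  tabs <- lapply(timelines, function(tl) {
    stopifnot(inherits(tl, "subject_timeline"))
    pos <- which(!is.na(tl$drinks))
    tab <- data.frame(subject_id = rep(tl$subject_id, length(pos)),
                      site = rep(tl$site, length(pos)),
                      start_weekday = rep(tl$start_weekday, length(pos)),
                      day = pos_to_day(pos),
                      drinks = tl$drinks[pos])
    if (include_provenance) tab$provenance <- tl$provenance[pos]
    tab
  })
  out <- do.call(rbind, c(tabs, list(make.row.names = FALSE)))
  if (!is.null(file)) {
    utils::write.csv(out, file, row.names = FALSE, quote = FALSE)
    return(invisible(out))
  }
  out
}
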