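# Deletion-based validation harness.
#
# Performance is assessed by deleting a random run of 5-15 consecutive days
# from the first trimester of a subject who is fully observed there, imputing
# the run back, and comparing prediction with truth: RMSE per deleted
# segment, drinker/nondrinker classification (confusion matrix), and the
# distribution of prediction-truth differences. The first trimester is used
# because both the proportion of women drinking and the magnitude of drinking
# peak there.

#' Root mean squared error
#'
#' `sqrt(mean((prediction - truth)^2))` over a deleted segment of length n.
#'
#' @param truth,prediction Numeric vectors of equal length `n >= 1`.
#' @return Nonnegative scalar; 0 iff the prediction is exact.
#' @export
rmse <- function(truth, prediction) {
  if (length(truth) != length(prediction))
    stop("length mismatch: truth has ", length(truth),
         ", prediction has ", length(prediction))
  stopifnot(length(truth) >= 1L)
  sqrt(mean((prediction - truth)^2))
}

#' Classify a segment as drinking or nondrinking
#'
#' A segment counts as drinking when its total drinks reach the threshold.
#' For ground-truth segments use `tau = 0` semantics via `any_positive =
#' TRUE`: any strictly positive day makes the truth a drinking segment.
#'
#' @param values Numeric vector of daily drinks.
#' @param tau Total-drinks threshold (default 0.5), used when
#'   `any_positive = FALSE`.
#' @param any_positive If `TRUE`, classify as drinking iff any value is > 0.
#' @return `"drinking"` or `"nondrinking"`.
#' @export
classify_segment <- function(values, tau = 0.5, any_positive = FALSE) {
  drinking <- if (any_positive) any(values > 0) else sum(values) >= tau
  if (drinking) "drinking" else "nondrinking"
}

#' Delete a random first-trimester run from a fully observed subject
#'
#' Draws a run length uniformly from `len_range` and a start uniformly among
#' the first-trimester starts that keep the whole run inside the trimester,
#' then marks those days unobserved. Uses R's current RNG stream; seed with
#' `set.seed()` for reproducibility.
#'
#' @param timeline A `subject_timeline` fully observed on first-trimester
#'   days.
#' @param len_range Inclusive run-length range, default `c(5, 15)`.
#' @param t1 First-trimester day range, default from [trimester_boundaries()].
#' @return An object of class `deletion_trial`: list with `timeline` (the
#'   modified copy), `subject_id`, `start_day`, `end_day`, `length`, `truth`.
#' @export
delete_random_segment <- function(timeline, len_range = c(5L, 15L),
                                  t1 = trimester_boundaries()$t1) {
  stopifnot(inherits(timeline, "subject_timeline"))
  t1_pos <- day_to_pos(t1[1]):day_to_pos(t1[2])
  if (any(is.na(timeline$drinks[t1_pos])))
    stop(sprintf("subject '%s' has missing first-trimester data",
                 timeline$subject_id))
  len <- sample(len_range[1]:len_range[2], 1L)
  start <- sample(t1[1]:(t1[2] - len + 1L), 1L)
  end <- start + len - 1L
  pos <- day_to_pos(start):day_to_pos(end)
  truth <- timeline$drinks[pos]
  timeline$drinks[pos] <- NA_real_
  timeline$provenance[pos] <- NA_character_
  structure(list(timeline = timeline, subject_id = timeline$subject_id,
                 start_day = start, end_day = end, length = len,
                 truth = truth),
            class = "deletion_trial")
}

#' Run the deletion-validation experiment
#'
#' Per iteration: sample (with replacement) a subject fully observed in the
#' first trimester, delete a random 5-15-day run, and impute it with every k
#' in `k_list` against the reference pool built from the un-deleted cohort
#' (self-segments overlapping the deleted run are excluded automatically).
#' The same deletion is reused across k, so k-comparisons are paired. A
#' per-day column-mean baseline prediction is recorded alongside.
#'
#' @param timelines Preprocessed cohort (list of `subject_timeline`).
#' @param config An [imputation_config()]; its `k` is overridden by `k_list`.
#' @param k_list Integer vector of neighbour counts to sweep (default 1:10).
#' @param iterations Number of deletion trials (default 500).
#' @param len_range Deleted-run length range, default `c(5, 15)`.
#' @return An object of class `validation_report`; see
#'   [summary.validation_report()]. Its `trials` component holds one row per
#'   (iteration, k) with `rmse`, `total_diff` (sum prediction - sum truth),
#'   `mean_abs_diff` (per-day), truth and predicted classes, plus
#'   `baseline_rmse` rows with `k = NA`.
#' @export
run_validation <- function(timelines, config = imputation_config(),
                           k_list = 1:10, iterations = 500L,
                           len_range = c(5L, 15L)) {
  stopifnot(length(timelines) > 0L, iterations >= 1L)
  t1 <- trimester_boundaries()$t1
  t1_pos <- day_to_pos(t1[1]):day_to_pos(t1[2])
  eligible <- which(vapply(timelines, function(tl)
    !any(is.na(tl$drinks[t1_pos])), TRUE))
  if (!length(eligible))
    stop("no subject is fully observed in the first trimester")
  pool <- extract_segments(timelines, config$L, config$stride)
  day_means <- rowMeans(vapply(timelines, `[[`, numeric(N_DAYS), "drinks"),
                        na.rm = TRUE)
  day_means[is.nan(day_means)] <- 0
  kmax <- max(k_list)
  cfg_kmax <- config; cfg_kmax$k <- as.integer(kmax)

  rows <- vector("list", iterations)
  for (it in seq_len(iterations)) {
    tl <- timelines[[sample(eligible, 1L)]]
    trial <- delete_random_segment(tl, len_range, t1)
    truth <- trial$truth
    truth_class <- classify_segment(truth, any_positive = TRUE)
    qw <- query_window(trial$timeline, trial$start_day, trial$end_day, config)
    nb_all <- find_neighbors(qw, pool, cfg_kmax)
    per_k <- lapply(k_list, function(k) {
      if (!nrow(nb_all))
        return(data.frame(iter = it, subject_id = trial$subject_id,
                          start_day = trial$start_day, length = trial$length,
                          k = k, method = "knn", truth_class = truth_class,
                          pred_class = NA_character_, rmse = NA_real_,
                          total_diff = NA_real_, mean_abs_diff = NA_real_))
      nb <- nb_all[seq_len(min(k, nrow(nb_all))), , drop = FALSE]
      w <- if (sum(nb$similarity) > 0) nb$similarity / sum(nb$similarity)
           else rep(1 / nrow(nb), nrow(nb))
      nb$weight <- w
      pred <- impute_gap(qw, nb, pool)
      data.frame(iter = it, subject_id = trial$subject_id,
                 start_day = trial$start_day, length = trial$length,
                 k = k, method = "knn", truth_class = truth_class,
                 pred_class = classify_segment(pred, config$classify_threshold),
                 rmse = rmse(truth, pred),
                 total_diff = sum(pred) - sum(truth),
                 mean_abs_diff = mean(abs(pred - truth)))
    })
    base_pred <- day_means[day_to_pos(trial$start_day:trial$end_day)]
    base <- data.frame(iter = it, subject_id = trial$subject_id,
                       start_day = trial$start_day, length = trial$length,
                       k = NA_integer_, method = "column_mean",
                       truth_class = truth_class,
                       pred_class = classify_segment(base_pred,
                                                     config$classify_threshold),
                       rmse = rmse(truth, base_pred),
                       total_diff = sum(base_pred) - sum(truth),
                       mean_abs_diff = mean(abs(base_pred - truth)))
    rows[[it]] <- rbind(do.call(rbind, per_k), base)
  }
  trials <- do.call(rbind, rows)
  structure(list(trials = trials, k_list = k_list, iterations = iterations,
                 config = config, n_eligible = length(eligible)),
            class = "validation_report")
}

#' Summarise a validation report
#'
#' @param object A `validation_report`.
#' @param probs Quantile probabilities for the percentile confidence interval
#'   of the per-segment total difference (default 2.5\% / 97.5\%).
#' @param exact_tol Absolute per-segment total difference below which a
#'   prediction counts as exact (default 0.5 drinks).
#' @param within Per-day mean absolute difference at or below which a
#'   prediction counts as within +/- 1 drink/day (default 1).
#' @param ... Unused.
#' @return List with `rmse_by_k` (mean/sd RMSE per k and truth class),
#'   `confusion` (per k, row-normalised 2x2 actual x predicted proportions),
#'   `diff_by_class` (mean total difference with percentile CI, and the
#'   exact / within +/- 1 proportions, per truth class at the configured k),
#'   and `baseline` (column-mean RMSE by truth class).
#' @export
summary.validation_report <- function(object, probs = c(0.025, 0.975),
                                      exact_tol = 0.5, within = 1, ...) {
  tr <- object$trials
  knn <- tr[tr$method == "knn" & !is.na(tr$rmse), ]
  rmse_by_k <- do.call(rbind, lapply(split(knn, list(knn$k, knn$truth_class),
                                           drop = TRUE), function(d)
    data.frame(k = d$k[1], truth_class = d$truth_class[1], n = nrow(d),
               mean_rmse = mean(d$rmse), sd_rmse = stats::sd(d$rmse))))
  rmse_by_k <- rmse_by_k[order(rmse_by_k$truth_class, rmse_by_k$k), ]
  rownames(rmse_by_k) <- NULL

  confusion <- lapply(split(knn, knn$k), function(d) {
    tab <- table(factor(d$truth_class, c("drinking", "nondrinking")),
                 factor(d$pred_class, c("drinking", "nondrinking")))
    prop.table(tab, margin = 1)
  })

  k0 <- object$config$k
  at_k <- knn[knn$k == (if (k0 %in% object$k_list) k0 else object$k_list[1]), ]
  diff_by_class <- do.call(rbind, lapply(split(at_k, at_k$truth_class),
                                         function(d) {
    ci <- stats::quantile(d$total_diff, probs, names = FALSE)
    data.frame(truth_class = d$truth_class[1], n = nrow(d),
               mean_total_diff = mean(d$total_diff),
               ci_lo = ci[1], ci_hi = ci[2],
               prop_exact = mean(abs(d$total_diff) < exact_tol),
               prop_within_1_per_day = mean(d$mean_abs_diff <= within))
  }))
  rownames(diff_by_class) <- NULL

  base <- tr[tr$method == "column_mean", ]
  baseline <- do.call(rbind, lapply(split(base, base$truth_class), function(d)
    data.frame(truth_class = d$truth_class[1], n = nrow(d),
               mean_rmse = mean(d$rmse))))
  rownames(baseline) <- NULL

  list(rmse_by_k = rmse_by_k, confusion = confusion,
       diff_by_class = diff_by_class, baseline = baseline,
       iterations = object$iterations)
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("<validation_report> %d iteration(s), k in {%s}, %d eligible subject(s)\n",
              x$iterations, paste(x$k_list, collapse = ","), x$n_eligible))
  s <- summary(x)
  cat("RMSE by k and truth class:\n")
  print(s$rmse_by_k, digits = 3)
  invisible(x)
}

#' Mean drinks per person by site and trimester, before and after imputation
#'
#' Per-person total drinks per trimester (unobserved days count 0 in the
#' "before" cohort), averaged within site. The delta column quantifies how
#' much imputation raises apparent consumption, which is largest where early
#' pregnancy — the heaviest drinking period — is least observed.
#'
#' @param before,after Matching cohorts (same subjects, same order): observed
#'   and imputed timelines.
#' @param boundaries Trimester day ranges, default [trimester_boundaries()].
#' @return data.frame with columns `site`, `trimester`, `mean_before`,
#'   `mean_after`, `delta`.
#' @export
trimester_means <- function(before, after, boundaries = trimester_boundaries()) {
  stopifnot(length(before) == length(after))
  ids_b <- vapply(before, `[[`, "", "subject_id")
  ids_a <- vapply(after, `[[`, "", "subject_id")
  if (!identical(ids_b, ids_a)) stop("cohorts do not match subject-for-subject")
  sites <- vapply(before, `[[`, "", "site")
  rows <- list()
  for (s in unique(sites)) {
    sel <- which(sites == s)
    for (tn in names(boundaries)) {
      rng <- boundaries[[tn]]
      pos <- day_to_pos(rng[1]):day_to_pos(rng[2])
      tot_b <- vapply(before[sel], function(tl)
        sum(tl$drinks[pos], na.rm = TRUE), 0)
      tot_a <- vapply(after[sel], function(tl)
        sum(tl$drinks[pos], na.rm = TRUE), 0)
      rows[[length(rows) + 1L]] <- data.frame(
        site = s, trimester = tn,
        mean_before = mean(tot_b), mean_after = mean(tot_a),
        delta = mean(tot_a) - mean(tot_b))
    }
  }
  do.call(rbind, rows)
}
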