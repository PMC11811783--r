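# Hand-crafted three-day scenarios: every subject starts on the same weekday
# and donors are observed only on days 1..3, so each donor contributes exactly
# one candidate segment whose context/gap values are chosen by hand.
cfg3 <- imputation_config(k = 2, L = 3, min_overlap = 2)

donor3 <- function(id, v) make_tl(id, 1:3, v)

query3 <- function(ctx) {
  tl <- make_tl("qq", c(1, 3), ctx)
  query_window(tl, 2, 2, cfg3)
}

test_that("cosine similarity matches hand values and the zero conventions", {
  expect_equal(cosine_similarity(c(3, 1), c(6, 2)), 1)       # same 3:1 pattern
  expect_equal(cosine_similarity(c(1, 0), c(0, 1)), 0)       # orthogonal
  expect_equal(cosine_similarity(c(0, 0), c(0, 0)), 1)       # both abstinent
  expect_equal(cosine_similarity(c(0, 0), c(1, 2)), 0)       # exactly one zero
  expect_equal(cosine_similarity(1:8, c(2, 9, 1, 0, 5, 5, 5, 5),
                                 mask = c(TRUE, FALSE, TRUE, FALSE,
                                          TRUE, TRUE, TRUE, TRUE)),
               cosine_similarity(c(1, 3, 5, 6, 7, 8), c(2, 1, 5, 5, 5, 5)))
  expect_error(cosine_similarity(1, 1, mask = FALSE), "empty mask")
})

test_that("cosine similarity is scale-invariant, symmetric and in [0, 1]", {
  set.seed(41)
  for (i in 1:50) {
    n <- sample(2:30, 1)
    x <- round(rexp(n), 3) * rbinom(n, 1, 0.6)
    y <- round(rexp(n), 3) * rbinom(n, 1, 0.6)
    cc <- runif(1, 0.01, 50)
    expect_equal(cosine_similarity(x, cc * y), cosine_similarity(x, y))
    expect_equal(cosine_similarity(x, y), cosine_similarity(y, x))
    s <- cosine_similarity(x, y)
    expect_gte(s, 0); expect_lte(s, 1)
  }
})

test_that("scale factor is the overlap norm ratio with its degenerate cases", {
  expect_equal(scale_factor(c(3, 1), c(6, 2)), 0.5)
  expect_equal(scale_factor(c(2, 7), c(2, 7)), 1)
  expect_equal(scale_factor(c(0, 0), c(1, 2)), 0)     # zero query overlap
  expect_equal(scale_factor(c(1, 2), c(0, 0)), 1)     # zero segment overlap
})

test_that("query windows centre the gap and stay inside the day range", {
  tl <- periodic_tl("q", c(1, 0, 2, 0, 0, 3, 0))
  cfg <- imputation_config()
  tl$drinks[day_to_pos(100:109)] <- NA
  qw <- query_window(tl, 100, 109, cfg)
  expect_equal(qw$window_start, 104 - 27)             # centred on the gap
  expect_length(qw$values, 55)
  expect_false(any(qw$observed_mask[(100:109) - qw$window_start + 1]))
  expect_true(all(is.na(qw$values[!qw$observed_mask])))
  # clamped at the head of the range
  tl2 <- periodic_tl("q2", c(1, 0, 2, 0, 0, 3, 0))
  tl2$drinks[day_to_pos(-15:-10)] <- NA
  qw2 <- query_window(tl2, -15, -10, cfg)
  expect_equal(qw2$window_start, -15)
  # and at the tail
  tl2$drinks[day_to_pos(300:310)] <- NA
  qw3 <- query_window(tl2, 300, 310, cfg)
  expect_equal(qw3$window_start, 310 - 54)
})

test_that("a single perfectly matching neighbour imputes the scaled gap value", {
  # query context (3, ., 1); donor (6, 4, 2): same pattern at double level
  qw <- query3(c(3, 1))
  pool <- extract_segments(list(donor3("d1", c(6, 4, 2))), 3)
  nb <- find_neighbors(qw, pool, cfg3)
  expect_equal(nrow(nb), 1)
  expect_equal(nb$similarity, 1)
  expect_equal(nb$scale, 0.5)
  expect_equal(impute_gap(qw, nb, pool), 2)           # 0.5 * 4
})

test_that("weights are normalised similarities and combine scaled neighbours", {
  # context (1, ., 0); donor A context (2, 0): sim 1, scale 0.5, gap 4
  #                    donor B context (1, sqrt(3)): sim 0.5, scale 0.5, gap 2
  qw <- query3(c(1, 0))
  pool <- extract_segments(list(donor3("dA", c(2, 4, 0)),
                                donor3("dB", c(1, 2, sqrt(3)))), 3)
  nb <- find_neighbors(qw, pool, cfg3)
  expect_equal(nb$subject_id, c("dA", "dB"))
  expect_equal(nb$similarity, c(1, 0.5))
  expect_equal(nb$weight, c(2 / 3, 1 / 3))
  expect_equal(impute_gap(qw, nb, pool), 5 / 3)       # 2/3*.5*4 + 1/3*.5*2
})

test_that("all-zero similarities fall back to uniform weights", {
  qw <- query3(c(1, 0))
  pool <- extract_segments(list(donor3("dC", c(0, 5, 1)),
                                donor3("dD", c(0, 3, 2))), 3)
  nb <- find_neighbors(qw, pool, cfg3)
  expect_equal(nb$similarity, c(0, 0))
  expect_equal(nb$weight, c(0.5, 0.5))
})

test_that("an exact duplicate of the query ranks first with similarity 1", {
  set.seed(42)
  qw <- query3(c(3, 1))
  donors <- c(list(donor3("twin", c(3, 9, 1))),
              lapply(1:10, function(i) donor3(sprintf("r%02d", i), runif(3, 0, 5))))
  pool <- extract_segments(donors, 3)
  nb <- find_neighbors(qw, pool, imputation_config(k = 3, L = 3, min_overlap = 2))
  expect_equal(nb$subject_id[1], "twin")
  expect_equal(nb$similarity[1], 1)
})

test_that("self-segments overlapping the gap are excluded from the pool", {
  full <- periodic_tl("me", c(1, 0, 2, 0, 0, 3, 0))
  other <- periodic_tl("you", c(1, 0, 2, 0, 0, 3, 0))
  pool <- extract_segments(list(full, other), 3)      # built before deletion
  gap_tl <- full
  gap_tl$drinks[day_to_pos(2)] <- NA
  cfg <- imputation_config(k = 50, L = 3, min_overlap = 1)
  qw <- query_window(gap_tl, 2, 2, cfg)
  nb <- find_neighbors(qw, pool, cfg)
  own <- nb[nb$subject_id == "me", ]
  expect_true(all(own$start_day > 2 | own$start_day + 2 < 2))
  cfg_noself <- cfg; cfg_noself$include_self_segments <- FALSE
  nb2 <- find_neighbors(qw, pool, cfg_noself)
  expect_false(any(nb2$subject_id == "me"))
})

test_that("neighbour search equals exhaustive brute-force ranking", {
  set.seed(43)
  cohort <- random_cohort(8, p_obs = 0.9)
  cfg <- imputation_config(k = 5, L = 10, min_overlap = 3)
  pool <- extract_segments(cohort, 10)
  for (i in 1:20) {
    tl <- cohort[[sample(length(cohort), 1)]]
    start <- sample(0:280, 1)
    tl$drinks[day_to_pos(start:(start + 4))] <- NA
    qw <- query_window(tl, start, start + 4, cfg)
    if (sum(qw$observed_mask) < cfg$min_overlap) next
    nb <- find_neighbors(qw, pool, cfg)
    want <- oracle_neighbors(qw, pool, cfg)
    if (is.null(want)) {
      expect_equal(nrow(nb), 0)
    } else {
      expect_equal(nb$pool_index, want$pool_index)
      expect_equal(nb$similarity, want$similarity)
      expect_equal(nb$scale, want$scale)
    }
  }
})

test_that("a planted scaled twin recovers deleted values exactly", {
  set.seed(44)
  truth <- round(runif(326, 0, 4) * rbinom(326, 1, 0.5), 2)
  truth[day_to_pos(30)] <- 2.5                        # nonzero context guaranteed
  me <- subject_timeline("me", "other", 3, truth)
  gap_tl <- me
  gap_tl$drinks[day_to_pos(50:59)] <- NA
  twin <- subject_timeline("twin", "other", 3, 2 * truth)  # c = 2
  pool <- extract_segments(list(gap_tl, twin), 55)
  cfg <- imputation_config(k = 1)
  res <- impute_all(list(gap_tl), cfg, pool = pool, caps = NULL)
  got <- res$timelines[[1]]$drinks[day_to_pos(50:59)]
  expect_lt(max(abs(got - truth[day_to_pos(50:59)])), 1e-9)
})

test_that("imputing a complete cohort is a no-op", {
  cohort <- list(periodic_tl("a", c(1, 0, 2, 0, 0, 3, 0)),
                 periodic_tl("b", c(0, 0, 1, 0, 0, 2, 2)))
  res <- impute_all(cohort, imputation_config())
  expect_equal(res$timelines, cohort)
  expect_equal(nrow(res$gaps), 0)
})

test_that("long gaps are chunked, flagged as chained, and leave context intact", {
  set.seed(45)
  donors <- lapply(1:6, function(i)
    periodic_tl(sprintf("d%d", i), c(1, 0, 2, 0, 0, 3, 0) * runif(1, 0.5, 2)))
  me <- periodic_tl("me", c(1, 0, 2, 0, 0, 3, 0))
  gap_days <- 100:249                                 # 150 missing days
  me$drinks[day_to_pos(gap_days)] <- NA
  cfg <- imputation_config()
  res <- impute_all(c(list(me), donors), cfg)
  expect_equal(res$gaps$n_chunks[res$gaps$subject_id == "me"],
               ceiling(150 / (55 - 7)))               # 4 chunks
  out <- res$timelines[[1]]
  expect_true(all(out$provenance[day_to_pos(gap_days)] == "imputed_chained"))
  expect_true(all(!is.na(out$drinks)))
  expect_true(all(out$drinks >= 0))
  keep <- setdiff(-15:310, gap_days)
  expect_equal(out$drinks[day_to_pos(keep)], me$drinks[day_to_pos(keep)])
  expect_true(all(out$provenance[day_to_pos(keep)] == "observed"))
})
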