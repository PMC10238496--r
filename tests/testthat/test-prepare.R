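test_that("streams are bucketed into half-open clock hours", {
  set.seed(1)
  t0 <- ts_utc("2022-03-05 10:00:00")
  co <- as_cohort(list(T01 = make_patient(t0, 2 * 3600)))
  h <- segment_hours(co)
  expect_equal(nrow(h), 2)
  expect_equal(h$n_points, c(3600, 3600))

  ## a sample at exactly hh:00:00 belongs to hour hh
  co2 <- as_cohort(list(T01 = make_patient(ts_utc("2022-03-05 10:30:00"),
                                           2 * 3600)))
  h2 <- segment_hours(co2)
  expect_equal(h2$hour_start,
               ts_utc(c("2022-03-05 10:00:00", "2022-03-05 11:00:00",
                        "2022-03-05 12:00:00")))
  expect_equal(h2$n_points, c(1800, 3600, 1800))

  ## a fully gapped hour is reported with zero points
  p <- make_patient(t0, 3 * 3600)
  gap <- p$time >= t0 + 3600 & p$time < t0 + 2 * 3600
  p$time <- p$time[!gap]; p$values <- p$values[!gap, ]; p$quality <- p$quality[!gap, ]
  h3 <- segment_hours(as_cohort(list(T01 = p)))
  expect_equal(h3$n_points, c(3600, 0, 3600))

  ## unordered timestamps are a validation error
  p$time[2] <- p$time[1]
  expect_error(segment_hours(as_cohort(list(T01 = p))),
               "strictly increasing")
})

test_that("the 3000-point inclusion rule is a sharp threshold", {
  h <- data.frame(patient_id = "a", hour_start = 3600 * (1:10),
                  n_points = c(2999, 3000, 3600, 0, 1000, 2999, 3500,
                               3600, 2000, 3100),
                  i0 = 1, i1 = 1)
  kept <- filter_hours(h)
  expect_equal(nrow(kept), 5)
  expect_true(all(kept$n_points >= 3000))
  expect_false(2999 %in% kept$n_points)
  expect_equal(attr(kept, "retention"), 0.5)
})

test_that("cropping picks the earliest densest 3000-s window", {
  set.seed(2)
  t0 <- ts_utc("2022-03-07 08:00:00")
  ## gap-free hour: earliest window wins the tie
  co <- as_cohort(list(T01 = make_patient(t0, 3600)))
  cr <- crop_hours(co, filter_hours(segment_hours(co)))
  expect_equal(cr$crop_start, t0)
  expect_equal(cr$n_observed, 3000)

  ## random gap patterns match an exhaustive scan over all 601 offsets
  for (rep in 1:10) {
    drop <- sample(3600, sample(100:500, 1))
    p <- make_patient(t0, 3600, drop = drop)
    co2 <- as_cohort(list(T01 = p))
    h <- segment_hours(co2)
    cr2 <- crop_hours(co2, h, min_observed = 0)
    pres <- logical(3600); pres[p$time - t0 + 1] <- TRUE
    counts <- vapply(0:600, function(o) sum(pres[(o + 1):(o + 3000)]), 0L)
    expect_equal(cr2$n_observed, max(counts))
    expect_equal(cr2$crop_start - t0, which.max(counts) - 1)
  }

  ## an hour whose best window is too sparse is dropped with a reason
  p3 <- make_patient(t0, 3600)
  keep <- sort(sample(3600, 3100))
  p3$time <- p3$time[keep]; p3$values <- p3$values[keep, ]
  p3$quality <- p3$quality[keep, ]
  co3 <- as_cohort(list(T01 = p3))
  cr3 <- crop_hours(co3, segment_hours(co3), min_observed = 3000)
  expect_equal(nrow(cr3), 0)
  expect_equal(nrow(attr(cr3, "dropped")), 1)
})

## brute-force calendar oracle for the annotation rule
annotate_oracle <- function(hour_start, events, pre = 48, post = 24) {
  any(vapply(seq_len(nrow(events)), function(e) {
    d0 <- (events$onset_ts[e] %/% 86400) * 86400
    in_day <- hour_start >= d0 & hour_start < d0 + 86400
    in_pre <- hour_start >= d0 - pre * 3600 & hour_start < d0
    in_span <- hour_start >= (events$onset_ts[e] %/% 3600) * 3600 &
      hour_start < events$recovery_ts[e]
    in_post <- hour_start >= events$recovery_ts[e] &
      hour_start < events$recovery_ts[e] + post * 3600
    in_day || in_pre || in_span || in_post
  }, NA))
}

test_that("buffered non-regular windows match the calendar oracle", {
  hours <- data.frame(
    patient_id = "P1",
    hour_start = seq(ts_utc("2020-01-06 00:00:00"),
                     ts_utc("2020-01-14 23:00:00"), by = 3600),
    n_points = 3600)
  ev <- data.frame(patient_id = "P1", infectious = 1L,
                   onset_ts = ts_utc("2020-01-10 14:00:00"),
                   recovery_ts = ts_utc("2020-01-11 10:00:00"))
  ann <- annotate_hours(hours, ev)
  nr <- ann$hour_start[ann$label == "non_regular"]
  ## non-regular from 2020-01-08 00:00 through 2020-01-12 10:00
  ## (inclusive start, exclusive end)
  expect_equal(min(nr), ts_utc("2020-01-08 00:00:00"))
  expect_equal(max(nr), ts_utc("2020-01-12 09:00:00"))
  expect_true(all(diff(sort(nr)) == 3600))
  expect_true(all(ann$infectious_window[ann$label == "non_regular"]))

  ## randomized event tables agree with the brute-force oracle
  set.seed(33)
  for (rep in 1:15) {
    n_ev <- sample(1:3, 1)
    ev2 <- data.frame(
      patient_id = "P1", infectious = rbinom(n_ev, 1, 0.5),
      onset_ts = ts_utc("2020-01-08 00:00:00") +
        sample(0:(5 * 86400), n_ev) )
    ev2$recovery_ts <- ev2$onset_ts + sample(3600 * (1:48), n_ev)
    ann2 <- annotate_hours(hours, ev2)
    oracle <- vapply(hours$hour_start, annotate_oracle, NA, events = ev2)
    expect_identical(ann2$label == "non_regular", oracle)
  }
})

test_that("two overlapping events give the union of their windows", {
  hours <- data.frame(
    patient_id = "P1",
    hour_start = seq(ts_utc("2020-01-01 00:00:00"),
                     ts_utc("2020-01-20 23:00:00"), by = 3600),
    n_points = 3600)
  e1 <- data.frame(patient_id = "P1", infectious = 1L,
                   onset_ts = ts_utc("2020-01-08 06:00:00"),
                   recovery_ts = ts_utc("2020-01-09 06:00:00"))
  e2 <- data.frame(patient_id = "P1", infectious = 0L,
                   onset_ts = ts_utc("2020-01-09 20:00:00"),
                   recovery_ts = ts_utc("2020-01-10 02:00:00"))
  both <- annotate_hours(hours, rbind(e1, e2))
  u <- annotate_hours(hours, e1)$label == "non_regular" |
    annotate_hours(hours, e2)$label == "non_regular"
  expect_identical(both$label == "non_regular", u)

  ## enlarging buffers never shrinks the non-regular set
  small <- annotate_hours(hours, rbind(e1, e2), pre_buffer_h = 24,
                          post_buffer_h = 12)
  expect_true(all(which(small$label == "non_regular") %in%
                    which(both$label == "non_regular")))

  ## events for unknown patients are rejected
  e3 <- data.frame(patient_id = "ghost", infectious = 0L,
                   onset_ts = e1$onset_ts, recovery_ts = e1$recovery_ts)
  expect_error(annotate_hours(hours, e3), "unknown patient")
})

test_that("per-patient 90/10 splits are clean partitions", {
  n_reg <- c(a = 10L, b = 37L, c = 2L, d = 1L)
  manifest <- do.call(rbind, lapply(names(n_reg), function(p)
    data.frame(patient_id = p,
               hour_start = 3600 * seq_len(n_reg[[p]] + 5),
               label = c(rep("regular", n_reg[[p]]),
                         rep("non_regular", 5)))))
  folds <- make_splits(manifest, n_folds = 4, seed = 42)
  for (f in folds) {
    expect_equal(length(intersect(f$train, f$test)), 0)
    ## training contains regular hours only
    expect_true(all(manifest$label[f$train] == "regular"))
    ## all non-regular hours are tested
    expect_true(all(which(manifest$label == "non_regular") %in% f$test))
    ## per patient: a 10-hour patient gives 9 train / 1 test, and the
    ## train fraction is within one hour of 90%
    for (p in names(n_reg)) {
      reg_p <- which(manifest$patient_id == p & manifest$label == "regular")
      tr <- intersect(f$train, reg_p); te <- intersect(f$test, reg_p)
      expect_setequal(c(tr, te), reg_p)
      if (n_reg[[p]] >= 2) expect_gte(length(te), 1)
      expect_lte(abs(length(tr) - 0.9 * n_reg[[p]]), 1)
      if (n_reg[[p]] == 10) expect_equal(length(tr), 9)
    }
  }
  expect_identical(lapply(make_splits(manifest, n_folds = 4, seed = 42),
                          `[[`, "train"),
                   lapply(folds, `[[`, "train"))
  expect_error(make_splits(manifest, train_frac = 1.2), "train_frac")
})

test_that("patients without regular hours are excluded entirely", {
  manifest <- data.frame(
    patient_id = c(rep("a", 6), rep("b", 4)),
    hour_start = 3600 * 1:10,
    label = c(rep("regular", 3), rep("non_regular", 7)))
  folds <- make_splits(manifest, n_folds = 2, seed = 1)
  expect_equal(attr(folds, "excluded_patients"), "b")
  for (f in folds)
    expect_false(any(manifest$patient_id[c(f$train, f$test)] == "b"))
})

test_that("hour_matrix materializes the crop window with missing flags", {
  set.seed(4)
  t0 <- ts_utc("2022-03-08 00:00:00")
  p <- make_patient(t0, 3600, drop = 101:200)
  co <- as_cohort(list(T01 = p))
  hm <- hour_matrix(co, "T01", t0)
  expect_equal(dim(hm$values), c(3000, 12))
  expect_equal(sum(hm$mask), 2900)
  expect_true(all(is.na(hm$values[101:200, 1])))
  expect_equal(hm$values[1, ], p$values[1, ])
  expect_error(hour_matrix(co, "nope", t0), "unknown patient")
})
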