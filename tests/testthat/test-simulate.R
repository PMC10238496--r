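test_that("configuration invariants are enforced with named fields", {
  expect_error(sim_config(hours_per_patient = 12), "hours_per_patient")
  expect_error(sim_config(dropout_rate = 1.5), "dropout_rate")
  expect_error(sim_config(signals = default_signals()[1:11, ]), "signals")
  sg <- default_signals(); sg$has_quality[1] <- FALSE
  expect_error(sim_config(signals = sg), "quality")
  expect_error(
    sim_config(hours_per_patient = 30,
               event_specs = list(event_spec("x", TRUE, "ramp", 20, 20,
                                             c(heart_rate = 1), 1))),
    "recording span")
  expect_error(event_spec("x", TRUE, "step", 1, -2, c(heart_rate = 1), 1),
               "duration_h")
  expect_error(event_spec("x", TRUE, "step", 1, 2, c(heart_rate = Inf), 1),
               "effect_sizes")
})

test_that("a no-event cohort is all-regular and gap-free settings give full hours", {
  cfg <- sim_config(n_patients_ic = 1, n_patients_oc = 0,
                    hours_per_patient = 26, charging_gap_minutes = 0,
                    dropout_rate = 0, interruption_rate_per_day = 0,
                    event_specs = list(), seed = 3)
  co <- generate_cohort(cfg)
  expect_equal(nrow(co$events), 0)
  h <- segment_hours(co)
  ## full interior hours hold exactly 3600 one-second samples
  full <- h$n_points[h$hour_start > co$patients[[1]]$t0 &
                     h$hour_start + 3600 <= co$patients[[1]]$t0 + 26 * 3600]
  expect_true(all(full == 3600))
  ann <- annotate_hours(h, co$events)
  expect_true(all(ann$label == "regular"))
})

test_that("identical seeds reproduce the cohort exactly", {
  cfg <- sim_config(n_patients_ic = 1, n_patients_oc = 1,
                    hours_per_patient = 24, seed = 11,
                    event_specs = list())
  expect_identical(generate_cohort(cfg), generate_cohort(cfg))
})

test_that("daily charging gap removes exactly 90 minutes per complete day", {
  cfg <- sim_config(n_patients_ic = 1, n_patients_oc = 0,
                    hours_per_patient = 72, dropout_rate = 0,
                    interruption_rate_per_day = 0, event_specs = list(),
                    seed = 5)
  co <- generate_cohort(cfg)
  p <- co$patients[[1]]
  ## count missing seconds per complete calendar day inside the span
  d0 <- (p$t0 %/% 86400 + 1) * 86400
  while (d0 + 86400 <= p$t0 + p$n_seconds) {
    present <- sum(p$time >= d0 & p$time < d0 + 86400)
    expect_equal(86400 - present, 90 * 60)
    d0 <- d0 + 86400
  }
})

test_that("event injection adds the configured deviation and nothing else", {
  co <- generate_cohort(sim_config(n_patients_ic = 1, n_patients_oc = 0,
                                   hours_per_patient = 48,
                                   event_specs = list(), seed = 9))
  p <- co$patients[[1]]
  ## null effect leaves the stream untouched
  e0 <- event_spec("x", FALSE, "step", 10, 5, c(heart_rate = 0), 1)
  expect_identical(inject_event(p, e0)$values, p$values)

  ## a +3 SD step shifts exactly the window, by exactly 3 SD
  e1 <- event_spec("x", FALSE, "step", 10, 5, c(heart_rate = 3), 1)
  p1 <- inject_event(p, e1)
  onset <- p$t0 + 10 * 3600; recov <- onset + 5 * 3600
  inside <- p$time >= onset & p$time < recov
  sd_hr <- p$signal_params$baseline_sd[p$signal_params$name == "heart_rate"]
  expect_equal(p1$values[inside, "heart_rate"],
               p$values[inside, "heart_rate"] + 3 * sd_hr)
  expect_identical(p1$values[!inside, ], p$values[!inside, ])
  ## windowed mean is ~3 SD above the pre-window mean
  pre <- p$time < onset & p$time >= onset - 5 * 3600
  shift <- mean(p1$values[inside, "heart_rate"]) -
    mean(p1$values[pre, "heart_rate"])
  expect_lt(abs(shift / sd_hr - 3), 1)

  ## overlapping events add their deviations
  e2 <- event_spec("y", FALSE, "step", 12, 6, c(heart_rate = 2), 1)
  both <- inject_event(inject_event(p, e1), e2)
  d1 <- inject_event(p, e1)$values - p$values
  d2 <- inject_event(p, e2)$values - p$values
  expect_equal(both$values, p$values + d1 + d2)

  ## window outside the span is a range error
  e3 <- event_spec("z", FALSE, "step", 47, 2, c(heart_rate = 1), 1)
  expect_error(inject_event(p, e3), "outside recording span")
})

test_that("ramp deviation rises before onset and decays after recovery", {
  co <- generate_cohort(sim_config(n_patients_ic = 1, n_patients_oc = 0,
                                   hours_per_patient = 120,
                                   event_specs = list(), seed = 13))
  p <- co$patients[[1]]
  e <- event_spec("inf", TRUE, "ramp", 60, 24, c(heart_rate = 3), 1)
  d <- inject_event(p, e)$values[, "heart_rate"] - p$values[, "heart_rate"]
  onset <- p$t0 + 60 * 3600; recov <- onset + 24 * 3600
  t <- p$time
  expect_true(all(d[t < onset - 48 * 3600] == 0))
  expect_gt(d[which(t >= onset - 3600)[1]], d[which(t >= onset - 24 * 3600)[1]])
  expect_true(all(d[t >= recov + 20 * 3600] == 0))
})

test_that("cohort files round-trip losslessly and reject corrupt input", {
  cfg <- sim_config(n_patients_ic = 1, n_patients_oc = 1,
                    hours_per_patient = 24, seed = 21,
                    event_specs = list(event_spec(
                      "Hypertension", FALSE, "transient", 10, 2,
                      c(heart_rate = 4), 2)))
  co <- generate_cohort(cfg)
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  co2 <- read_cohort(dir)
  for (id in names(co$patients)) {
    expect_identical(co2$patients[[id]]$time, co$patients[[id]]$time)
    expect_equal(co2$patients[[id]]$values, co$patients[[id]]$values)
    expect_identical(unname(co2$patients[[id]]$quality[, 1]),
                     unname(co$patients[[id]]$quality[, 1]))
  }
  expect_equal(co2$events$onset_ts, co$events$onset_ts)

  ## non-monotone timestamps are rejected with context
  bad <- co
  bad$patients[[1]]$time[2] <- bad$patients[[1]]$time[1]
  dir2 <- withr::local_tempdir()
  write_cohort(bad, dir2)
  expect_error(read_cohort(dir2), "non-monotone timestamp")

  ## an empty cohort still writes valid files
  dir3 <- withr::local_tempdir()
  write_cohort(as_cohort(list()), dir3)
  expect_equal(length(read_cohort(dir3)$patients), 0)
})

test_that("injected 3 SD anomalies are separable by a mean-shift detector", {
  ## sanity floor: a trivial per-hour mean detector reaches AUROC > 0.9
  cfg <- sim_config(n_patients_ic = 2, n_patients_oc = 0,
                    hours_per_patient = 72,
                    event_specs = list(event_spec(
                      "inf", TRUE, "step", 30, 20,
                      c(heart_rate = 3, core_temperature = 3), 1)),
                    seed = 31)
  co <- generate_cohort(cfg)
  m <- prepare_hours(co)
  mu <- vapply(seq_len(nrow(m)), function(r) {
    p <- co$patients[[m$patient_id[r]]]
    w <- p$time >= m$hour_start[r] & p$time < m$hour_start[r] + 3600
    mean(p$values[w, "heart_rate"])
  }, 0)
  ## ground truth = hours inside the injected deviation window
  inside <- m$patient_id == "P001" &
    m$hour_start >= co$events$onset_ts[1] &
    m$hour_start < co$events$recovery_ts[1]
  expect_gt(auroc(mu, inside), 0.9)
})
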