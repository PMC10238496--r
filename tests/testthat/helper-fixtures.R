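## shared fixtures: a tiny cohort and a lazily trained toy encoder, cached
## for the whole test session

.fixture_cache <- new.env(parent = emptyenv())

## small cohort: 4 patients x 48 h with one infectious ramp; the ramp
## patient ends up with no regular hours, exercising the exclusion path
toy_cohort <- function() {
  if (is.null(.fixture_cache$cohort)) {
    cfg <- sim_config(
      n_patients_ic = 2, n_patients_oc = 2, hours_per_patient = 48,
      dropout_rate = 0.01, interruption_rate_per_day = 0,
      event_specs = list(event_spec(
        "Lung infection", infectious = TRUE, shape = "ramp",
        onset_offset_h = 24, duration_h = 8,
        effect_sizes = c(heart_rate = 3, core_temperature = 3,
                         respiration_rate = 2.5),
        patient = 1)),
      seed = 421L)
    .fixture_cache$cohort <- generate_cohort(cfg)
  }
  .fixture_cache$cohort
}

toy_manifest <- function() {
  if (is.null(.fixture_cache$manifest))
    .fixture_cache$manifest <- prepare_hours(toy_cohort())
  .fixture_cache$manifest
}

toy_split <- function() {
  if (is.null(.fixture_cache$split))
    .fixture_cache$split <- make_splits(toy_manifest(), n_folds = 1,
                                        seed = 7)[[1]]
  .fixture_cache$split
}

## small encoder configuration used by the toy model
toy_encoder_config <- function(epochs = 10L, seed = 99L) {
  encoder_config("test", n_blocks = 2L, width = 4L, kernel = 8L,
                 double_every = 2L, batch_size = 16L, epochs = epochs,
                 seed = seed)
}

toy_model <- function() {
  if (is.null(.fixture_cache$model)) {
    .fixture_cache$model <- train_encoder(
      toy_cohort(), toy_manifest(), toy_split()$train,
      toy_encoder_config())
  }
  .fixture_cache$model
}

## hand-built patient stream (gap-free unless seconds dropped) for
## segmentation tests; t0 in epoch seconds
make_patient <- function(t0, n_seconds, drop = integer(0),
                         patient_id = "T01") {
  tt <- t0 + 0:(n_seconds - 1)
  if (length(drop)) tt <- tt[-drop]
  n <- length(tt)
  vals <- matrix(rnorm(n * 12), n, 12,
                 dimnames = list(NULL, default_signals()$name))
  qual <- matrix(90L, n, 5,
                 dimnames = list(NULL, default_signals()$name[1:5]))
  list(patient_id = patient_id, cohort = "IC", t0 = tt[1],
       n_seconds = n_seconds, time = tt, values = vals, quality = qual,
       signal_params = data.frame(name = colnames(vals),
                                  baseline_mean = 0, baseline_sd = 1,
                                  has_quality = c(rep(TRUE, 5),
                                                  rep(FALSE, 7))))
}

as_cohort <- function(patients, events = NULL) {
  if (is.null(events))
    events <- data.frame(patient_id = character(), event_type = character(),
                         infectious = integer(), ctcae_grade = numeric(),
                         onset_ts = numeric(), recovery_ts = numeric())
  structure(list(patients = patients, events = events,
                 signals = default_signals(), config = NULL),
            class = "scc_cohort")
}

ts_utc <- function(s) as.double(as.POSIXct(s, tz = "UTC"))
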