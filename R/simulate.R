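## ---- synthetic wearable cohort generator -----------------------------------
##
## Emulates 1 Hz multichannel wearable recordings (12 signals, 5 of which
## carry a 0-100 quality index) for an inpatient (IC) and an outpatient (OC)
## cohort, with a daily charging gap, random dropouts and interruptions, and
## injected serious-clinical-complication (SCC) events with known ground
## truth.  Infectious events are slow ramps developing over one to two days;
## cardiac/hypertensive events are abrupt transients.

#' Describe one wearable signal
#'
#' @param name signal name.
#' @param baseline_mean population baseline mean, native units.
#' @param baseline_sd marginal standard deviation of the fast noise
#'   component, native units.  Event effect sizes are expressed in
#'   multiples of this value.
#' @param diurnal_amplitude amplitude of the sinusoidal circadian
#'   component, native units.
#' @param has_quality does the wearable report a 0-100 quality index for
#'   this signal?
#' @return a one-row `data.frame`.
#' @export
signal_spec <- function(name, baseline_mean, baseline_sd,
                        diurnal_amplitude = 0, has_quality = FALSE) {
  if (baseline_sd < 0) stop_cfg("baseline_sd", "must be >= 0")
  data.frame(name = name, baseline_mean = baseline_mean,
             baseline_sd = baseline_sd,
             diurnal_amplitude = diurnal_amplitude,
             has_quality = has_quality, stringsAsFactors = FALSE)
}

#' Default 12-signal wearable channel set
#'
#' Five channels (heart rate, heart-rate variability, SpO2, respiration
#' rate, blood pulse wave) carry a quality index, mirroring the layout of
#' a chest/arm-worn medical wearable; the remaining seven are raw values.
#' Units and magnitudes are plausible resting values for adults under
#' treatment.
#'
#' @return a 12-row `data.frame` of [signal_spec()] rows, quality-bearing
#'   channels first.
#' @export
default_signals <- function() {
  rbind(
    signal_spec("heart_rate",        72,   7,    5,    TRUE),
    signal_spec("hrv",               45,  12,    8,    TRUE),
    signal_spec("spo2",              97,   0.8,  0.3,  TRUE),
    signal_spec("respiration_rate",  16,   2,    1.2,  TRUE),
    signal_spec("blood_pulse_wave",   1.0, 0.25, 0.10, TRUE),
    signal_spec("core_temperature",  36.9, 0.25, 0.25, FALSE),
    signal_spec("skin_temperature",  33.5, 0.7,  0.5,  FALSE),
    signal_spec("activity",          12,   8,    8,    FALSE),
    signal_spec("step_count",         4,   4,    4,    FALSE),
    signal_spec("energy_expenditure", 1.3, 0.5,  0.5,  FALSE),
    signal_spec("gsr",                2.0, 0.8,  0.5,  FALSE),
    signal_spec("perfusion_index",    3.0, 1.0,  0.5,  FALSE)
  )
}

#' Describe one complication event to inject
#'
#' @param event_type CTCAE-style label.
#' @param infectious logical; infectious events use slow multi-hour ramps,
#'   non-infectious ones abrupt signatures.
#' @param shape one of `"ramp"`, `"step"`, `"transient"`.  A ramp rises
#'   linearly over the 48 h before onset, plateaus until recovery and
#'   decays over the 20 h after recovery (prodromal physiology precedes
#'   the documented diagnosis).  A step is constant on
#'   `[onset, recovery)`.  A transient follows a half-sine envelope on
#'   `[onset, recovery)`.
#' @param onset_offset_h onset time, hours after the patient's recording
#'   start.
#' @param duration_h onset-to-recovery duration in hours; must be > 0.
#' @param effect_sizes named numeric vector of per-signal shifts in units
#'   of that signal's `baseline_sd`.
#' @param patient index of the patient receiving the event (IC patients
#'   first, then OC).
#' @param ctcae_grade documented CTCAE grade (>= 3 for an SCC).
#' @return an object of class `scc_event_spec`.
#' @export
event_spec <- function(event_type, infectious, shape, onset_offset_h,
                       duration_h, effect_sizes, patient, ctcae_grade = 3) {
  shape <- match.arg(shape, c("ramp", "step", "transient"))
  if (!is.numeric(duration_h) || duration_h <= 0)
    stop_cfg("duration_h", "must be > 0")
  if (!all(is.finite(effect_sizes)))
    stop_cfg("effect_sizes", "must be finite")
  structure(list(event_type = event_type, infectious = isTRUE(infectious),
                 shape = shape, onset_offset_h = onset_offset_h,
                 duration_h = duration_h, effect_sizes = effect_sizes,
                 patient = as.integer(patient),
                 ctcae_grade = ctcae_grade),
            class = "scc_event_spec")
}

## vital-sign signatures used by the default event mix
.ramp_effects <- c(heart_rate = 2.5, respiration_rate = 2.5,
                   core_temperature = 3, hrv = -2, activity = -1.5)
.transient_effects <- c(heart_rate = 4, blood_pulse_wave = 3, hrv = -3)

#' Default event mix for a simulated cohort
#'
#' Deterministic assignment over patient indices `1..n`: two of every
#' four patients get an infectious ramp (lung infection or unspecified
#' infection), one gets a short cardiac transient, one stays event-free,
#' roughly matching the observed predominance of infectious complications
#' and the presence of patients without any complication.  Onsets are
#' staggered around 45% of the recording span so that the annotation
#' buffers fit inside it.
#'
#' @param n_patients total number of patients.
#' @param hours_per_patient recording span per patient, hours.
#' @param mix `"heterogeneous"` (infectious ramps plus cardiac
#'   transients, the package default) or `"ramp_only"` (every eventful
#'   patient gets an infectious ramp; the condition used by the
#'   end-to-end validation runs).
#' @return list of [event_spec()] objects.
#' @export
default_event_specs <- function(n_patients, hours_per_patient,
                                mix = c("heterogeneous", "ramp_only")) {
  mix <- match.arg(mix)
  specs <- list()
  ramp_dur <- min(48, floor(0.2 * hours_per_patient))
  trans_dur <- min(4, ramp_dur)
  for (i in seq_len(n_patients)) {
    r <- i %% 4L
    onset <- min(0.45 * hours_per_patient + (i %% 5L) * 6,
                 hours_per_patient - ramp_dur)
    if (r %in% c(1L, 2L) || (r == 3L && mix == "ramp_only")) {
      specs[[length(specs) + 1L]] <- event_spec(
        if (r == 1L) "Infections and infestations - other" else "Lung infection",
        infectious = TRUE, shape = "ramp",
        onset_offset_h = onset, duration_h = ramp_dur,
        effect_sizes = .ramp_effects, patient = i)
    } else if (r == 3L) {
      specs[[length(specs) + 1L]] <- event_spec(
        if (i %% 8L == 3L) "Paroxysmal atrial tachycardia" else "Hypertension",
        infectious = FALSE, shape = "transient",
        onset_offset_h = onset, duration_h = trans_dur,
        effect_sizes = .transient_effects, patient = i)
    }
  }
  specs
}

#' Simulation configuration
#'
#' @param n_patients_ic,n_patients_oc cohort sizes (inpatient, outpatient).
#' @param hours_per_patient recording span per patient in hours (>= 24).
#' @param signals 12-row signal table, see [default_signals()]; exactly 5
#'   rows must have `has_quality = TRUE`.
#' @param charging_gap_minutes daily battery-charging gap (default 90).
#' @param dropout_rate per-second probability of an isolated missing
#'   sample.
#' @param event_specs list of [event_spec()]s; `NULL` for the default
#'   mix generated by [default_event_specs()].
#' @param event_mix passed to [default_event_specs()] when `event_specs`
#'   is `NULL`: `"heterogeneous"` or `"ramp_only"`.
#' @param seed integer seed; the whole cohort is reproducible from it.
#' @param ar_phi lag-1 autocorrelation of the fast noise component.
#' @param slow_tau_h correlation time (hours) of the slow physiological
#'   state component shared by nearby intervals.
#' @param slow_sd amplitude of the slow component, in units of each
#'   signal's `baseline_sd`.
#' @param patient_sd between-patient baseline spread, in units of each
#'   signal's `baseline_sd`.
#' @param interruption_rate_per_day expected number of recording
#'   interruptions per day.
#' @param interruption_mean_min mean interruption length, minutes.
#' @param oc_activity_factor multiplier on activity-type baselines in the
#'   outpatient cohort (outpatients move more).
#' @return an object of class `scc_sim_config`.
#' @export
sim_config <- function(n_patients_ic = 8, n_patients_oc = 4,
                       hours_per_patient = 216,
                       signals = default_signals(),
                       charging_gap_minutes = 90,
                       dropout_rate = 0.02,
                       event_specs = NULL,
                       event_mix = c("heterogeneous", "ramp_only"),
                       seed = 1L,
                       ar_phi = 0.99,
                       slow_tau_h = 3,
                       slow_sd = 0.8,
                       patient_sd = 0.8,
                       interruption_rate_per_day = 0.3,
                       interruption_mean_min = 45,
                       oc_activity_factor = 2) {
  if (n_patients_ic < 0 || n_patients_oc < 0 || n_patients_ic + n_patients_oc < 1)
    stop_cfg("n_patients_ic/n_patients_oc", "must give at least one patient")
  if (hours_per_patient < 24) stop_cfg("hours_per_patient", "must be >= 24")
  if (nrow(signals) != N_SIGNALS)
    stop_cfg("signals", sprintf("must have exactly %d entries", N_SIGNALS))
  if (sum(signals$has_quality) != N_QUALITY)
    stop_cfg("signals", sprintf("exactly %d signals must have a quality index",
                                N_QUALITY))
  if (any(signals$baseline_sd < 0)) stop_cfg("signals", "baseline_sd must be >= 0")
  if (dropout_rate < 0 || dropout_rate > 1)
    stop_cfg("dropout_rate", "must be in [0, 1]")
  if (charging_gap_minutes < 0 || charging_gap_minutes > 24 * 60)
    stop_cfg("charging_gap_minutes", "must be in [0, 1440]")
  n <- n_patients_ic + n_patients_oc
  if (is.null(event_specs))
    event_specs <- default_event_specs(n, hours_per_patient,
                                       mix = match.arg(event_mix))
  for (ev in event_specs) {
    if (!inherits(ev, "scc_event_spec"))
      stop_cfg("event_specs", "entries must be created by event_spec()")
    if (ev$patient < 1 || ev$patient > n)
      stop_cfg("event_specs", sprintf("patient index %d out of range", ev$patient))
    if (ev$onset_offset_h + ev$duration_h > hours_per_patient ||
        ev$onset_offset_h < 0)
      stop_cfg("event_specs", "event window outside the recording span")
  }
  ## quality-bearing signals must come first: the encoder input layout
  ## depends on this ordering
  ord <- order(!signals$has_quality)
  signals <- signals[ord, , drop = FALSE]
  rownames(signals) <- NULL
  structure(list(
    n_patients_ic = as.integer(n_patients_ic),
    n_patients_oc = as.integer(n_patients_oc),
    hours_per_patient = hours_per_patient, signals = signals,
    charging_gap_minutes = charging_gap_minutes, dropout_rate = dropout_rate,
    event_specs = event_specs, seed = as.integer(seed),
    ar_phi = ar_phi, slow_tau_h = slow_tau_h, slow_sd = slow_sd,
    patient_sd = patient_sd,
    interruption_rate_per_day = interruption_rate_per_day,
    interruption_mean_min = interruption_mean_min,
    oc_activity_factor = oc_activity_factor), class = "scc_sim_config")
}

#' @exportS3Method base::print scc_sim_config
print.scc_sim_config <- function(x, ...) {
  cat("Wearable cohort simulation config\n")
  cat(sprintf("  patients: %d IC + %d OC, %g h each at 1 Hz\n",
              x$n_patients_ic, x$n_patients_oc, x$hours_per_patient))
  cat(sprintf("  signals: %d (%d with quality index)\n",
              nrow(x$signals), sum(x$signals$has_quality)))
  cat(sprintf("  gaps: %g min charging/day, dropout %g/s\n",
              x$charging_gap_minutes, x$dropout_rate))
  cat(sprintf("  events: %d injected\n", length(x$event_specs)))
  invisible(x)
}

## recording start of the simulated study period
.base_epoch <- as.double(as.POSIXct("2022-03-01 00:00:00", tz = "UTC"))

## event deviation profile on a grid of absolute times (seconds)
event_profile <- function(tt, spec, onset, recovery) {
  dev <- numeric(length(tt))
  if (spec$shape == "step") {
    w <- tt >= onset & tt < recovery
    dev[w] <- 1
  } else if (spec$shape == "transient") {
    w <- tt >= onset & tt < recovery
    dev[w] <- sin(pi * (tt[w] - onset) / (recovery - onset))
  } else { # ramp
    lead <- 48 * 3600
    tail_s <- 20 * 3600
    w <- tt >= (onset - lead) & tt < onset
    dev[w] <- (tt[w] - (onset - lead)) / lead
    w <- tt >= onset & tt < recovery
    dev[w] <- 1
    w <- tt >= recovery & tt < recovery + tail_s
    dev[w] <- 1 - (tt[w] - recovery) / tail_s
  }
  dev
}

#' Inject a complication signature into one patient stream
#'
#' Adds the event's per-signal shifts (in `baseline_sd` units of that
#' patient's effective signal parameters) to the recorded values inside
#' the event profile window; samples outside the window are untouched.
#' Overlapping events add.
#'
#' @param patient one element of `cohort$patients`.
#' @param spec an [event_spec()]; its `[onset, recovery]` window must lie
#'   within the patient's recording span.
#' @return the patient record with shifted values.
#' @export
inject_event <- function(patient, spec) {
  t0 <- patient$t0
  onset <- t0 + spec$onset_offset_h * 3600
  recovery <- onset + spec$duration_h * 3600
  t_end <- t0 + patient$n_seconds
  if (onset < t0 || recovery > t_end)
    stop("event window [", fmt_ts(onset), ", ", fmt_ts(recovery),
         ") outside recording span of patient ", patient$patient_id,
         call. = FALSE)
  dev <- event_profile(patient$time, spec, onset, recovery)
  w <- which(dev != 0)
  if (length(w)) {
    sg <- patient$signal_params
    for (nm in names(spec$effect_sizes)) {
      j <- match(nm, sg$name)
      if (is.na(j)) stop_cfg("effect_sizes", sprintf("unknown signal '%s'", nm))
      patient$values[w, j] <- patient$values[w, j] +
        spec$effect_sizes[[nm]] * sg$baseline_sd[j] * dev[w]
    }
  }
  patient
}

## simulate one patient's full-grid stream (before masking)
simulate_patient <- function(config, idx, cohort_name, patient_id) {
  sg <- config$signals
  hours <- config$hours_per_patient
  n <- as.integer(hours * 3600)
  ## random start hour-of-day so charging gaps and hour buckets are not
  ## aligned across patients
  t0 <- .base_epoch + sample(0:23, 1) * 3600 + sample(0:59, 1) * 60
  tt <- t0 + 0:(n - 1)

  eff_mean <- sg$baseline_mean +
    config$patient_sd * sg$baseline_sd * rnorm(nrow(sg))
  eff_sd <- sg$baseline_sd
  if (cohort_name == "OC") {
    act <- sg$name %in% c("activity", "step_count", "energy_expenditure")
    eff_mean[act] <- eff_mean[act] * config$oc_activity_factor
    eff_sd[act] <- eff_sd[act] * 1.5
  }

  phi_f <- config$ar_phi
  phi_s <- exp(-1 / (config$slow_tau_h * 3600))
  tod <- (tt %% 86400) / 86400
  phase <- seq(0, 2 * pi, length.out = nrow(sg) + 1)[seq_len(nrow(sg))]

  vals <- matrix(0, n, nrow(sg))
  colnames(vals) <- sg$name
  for (j in seq_len(nrow(sg))) {
    fast <- as.numeric(stats::filter(
      rnorm(n, sd = eff_sd[j] * sqrt(1 - phi_f^2)), phi_f,
      method = "recursive", init = rnorm(1, sd = eff_sd[j])))
    slow <- as.numeric(stats::filter(
      rnorm(n, sd = config$slow_sd * eff_sd[j] * sqrt(1 - phi_s^2)), phi_s,
      method = "recursive",
      init = rnorm(1, sd = config$slow_sd * eff_sd[j])))
    vals[, j] <- eff_mean[j] +
      sg$diurnal_amplitude[j] * sin(2 * pi * tod + phase[j]) + fast + slow
  }

  ## quality indices: concentrated near 100, dipping with high activity
  qsig <- which(sg$has_quality)
  act_j <- match("activity", sg$name)
  act_excess <- pmax(vals[, act_j] - (eff_mean[act_j] + eff_sd[act_j]), 0)
  qual <- matrix(0L, n, length(qsig))
  colnames(qual) <- sg$name[qsig]
  for (k in seq_along(qsig)) {
    q <- 100L - rbinom(n, 8L, 0.25) - as.integer(round(0.4 * act_excess))
    qual[, k] <- pmax(0L, pmin(100L, q))
  }

  list(patient_id = patient_id, cohort = cohort_name, t0 = t0,
       n_seconds = n, time = tt, values = vals, quality = qual,
       signal_params = data.frame(name = sg$name, baseline_mean = eff_mean,
                                  baseline_sd = eff_sd,
                                  has_quality = sg$has_quality,
                                  stringsAsFactors = FALSE))
}

## missing-data mask for one patient: daily charging gap, Poisson
## interruptions, iid dropouts.  TRUE = sample kept.
keep_mask <- function(config, patient) {
  n <- patient$n_seconds
  keep <- rep(TRUE, n)
  gap_s <- round(config$charging_gap_minutes * 60)
  if (gap_s > 0) {
    g0 <- sample(0:86399, 1)   # patient-specific charging time of day
    sec_of_day <- (patient$time - day_floor(patient$t0)) %% 86400
    off <- (sec_of_day - g0) %% 86400
    keep[off < gap_s] <- FALSE
  }
  n_days <- n / 86400
  n_int <- rpois(1, config$interruption_rate_per_day * n_days)
  if (n_int > 0) {
    starts <- sample.int(n, n_int, replace = TRUE)
    durs <- pmax(60, round(rexp(n_int, 1 / (config$interruption_mean_min * 60))))
    for (i in seq_len(n_int))
      keep[starts[i]:min(n, starts[i] + durs[i] - 1)] <- FALSE
  }
  if (config$dropout_rate > 0)
    keep[runif(n) < config$dropout_rate] <- FALSE
  keep
}

#' Generate a synthetic wearable cohort
#'
#' Simulates every patient's 1 Hz stream (baseline + circadian sinusoid +
#' slow physiological state + fast AR(1) noise), injects the configured
#' complication events, then applies the daily charging gap, random
#' interruptions and dropouts.  Fully reproducible from `config$seed`.
#'
#' @param config an [sim_config()] object.
#' @return an object of class `scc_cohort`: a list with `patients` (named
#'   list of per-patient streams), `events` (data.frame with columns
#'   `patient_id`, `event_type`, `infectious`, `ctcae_grade`, `onset_ts`,
#'   `recovery_ts`, timestamps in epoch seconds), `signals`, and `config`.
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "scc_sim_config"))
    stop_cfg("config", "must be created by sim_config()")
  n_ic <- config$n_patients_ic; n_oc <- config$n_patients_oc
  n <- n_ic + n_oc
  ids <- sprintf("P%03d", seq_len(n))
  cohorts <- rep(c("IC", "OC"), c(n_ic, n_oc))
  with_seed(config$seed, {
    patients <- vector("list", n)
    names(patients) <- ids
    ev_rows <- list()
    for (i in seq_len(n)) {
      p <- simulate_patient(config, i, cohorts[i], ids[i])
      for (ev in config$event_specs) {
        if (ev$patient != i) next
        p <- inject_event(p, ev)
        onset <- p$t0 + ev$onset_offset_h * 3600
        ev_rows[[length(ev_rows) + 1L]] <- data.frame(
          patient_id = ids[i], event_type = ev$event_type,
          infectious = as.integer(ev$infectious),
          ctcae_grade = ev$ctcae_grade,
          onset_ts = onset, recovery_ts = onset + ev$duration_h * 3600,
          stringsAsFactors = FALSE)
      }
      keep <- keep_mask(config, p)
      p$time <- p$time[keep]
      p$values <- p$values[keep, , drop = FALSE]
      p$quality <- p$quality[keep, , drop = FALSE]
      patients[[i]] <- p
    }
    events <- if (length(ev_rows)) do.call(rbind, ev_rows) else
      data.frame(patient_id = character(), event_type = character(),
                 infectious = integer(), ctcae_grade = numeric(),
                 onset_ts = numeric(), recovery_ts = numeric(),
                 stringsAsFactors = FALSE)
    structure(list(patients = patients, events = events,
                   signals = config$signals, config = config),
              class = "scc_cohort")
  })
}

#' @exportS3Method base::print scc_cohort
print.scc_cohort <- function(x, ...) {
  n_h <- sum(vapply(x$patients, function(p) length(p$time), 0)) / 3600
  cat(sprintf("Synthetic wearable cohort: %d patients (%d IC, %d OC)\n",
              length(x$patients),
              sum(vapply(x$patients, function(p) p$cohort == "IC", NA)),
              sum(vapply(x$patients, function(p) p$cohort == "OC", NA))))
  cat(sprintf("  %.0f recorded hours of 1 Hz data, %d signals\n",
              n_h, ncol(x$patients[[1]]$values)))
  cat(sprintf("  %d documented SCC events (%d infectious)\n",
              nrow(x$events), sum(x$events$infectious)))
  invisible(x)
}

#' @exportS3Method base::summary scc_cohort
summary.scc_cohort <- function(object, ...) {
  p <- object$patients
  d <- data.frame(
    patient_id = names(p),
    cohort = vapply(p, function(x) x$cohort, ""),
    recorded_h = vapply(p, function(x) length(x$time) / 3600, 0),
    span_h = vapply(p, function(x) x$n_seconds / 3600, 0),
    n_events = vapply(names(p), function(id)
      sum(object$events$patient_id == id), 0L),
    row.names = NULL)
  d
}

## ---- cohort file round trip ------------------------------------------------

#' Write / read a cohort as plain-text tables
#'
#' `write_cohort()` writes `signals.csv` (long format: `patient_id`,
#' `timestamp` ISO-8601, `signal`, `value`, `quality`; quality empty for
#' channels without an index), `events.csv` and `patients.csv` under
#' `path`.  `read_cohort()` reconstructs the in-memory cohort; the round
#' trip is lossless for timestamps, values and quality indices.  Intended
#' for small cohorts and interchange, not for bulk storage.
#'
#' @param cohort an `scc_cohort`.
#' @param path directory to create/read.
#' @return `read_cohort()` returns an `scc_cohort` (without simulation
#'   config).
#' @export
write_cohort <- function(cohort, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  sg <- cohort$signals
  qnames <- sg$name[sg$has_quality]
  rows <- lapply(cohort$patients, function(p) {
    n <- length(p$time)
    if (n == 0) return(NULL)
    ns <- ncol(p$values)
    data.table::data.table(
      patient_id = rep(p$patient_id, n * ns),
      timestamp = rep(fmt_ts(p$time), ns),
      signal = rep(colnames(p$values), each = n),
      value = sprintf("%.17g", as.vector(p$values)),
      quality = {
        q <- rep(NA_integer_, n * ns)
        for (k in seq_along(qnames)) {
          j <- match(qnames[k], colnames(p$values))
          q[((j - 1) * n + 1):(j * n)] <- p$quality[, k]
        }
        q
      })
  })
  long <- data.table::rbindlist(rows)
  if (nrow(long) == 0)
    long <- data.table::data.table(patient_id = character(),
                                   timestamp = character(),
                                   signal = character(),
                                   value = character(),
                                   quality = integer())
  data.table::fwrite(long, file.path(path, "signals.csv"))
  ev <- cohort$events
  ev$onset_ts <- fmt_ts(ev$onset_ts)
  ev$recovery_ts <- fmt_ts(ev$recovery_ts)
  data.table::fwrite(ev, file.path(path, "events.csv"))
  pat <- data.frame(
    patient_id = names(cohort$patients),
    cohort = vapply(cohort$patients, function(p) p$cohort, ""),
    t0 = fmt_ts(vapply(cohort$patients, function(p) p$t0, 0)),
    n_seconds = vapply(cohort$patients, function(p) p$n_seconds, 0))
  data.table::fwrite(pat, file.path(path, "patients.csv"))
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  f <- file.path(path, "signals.csv")
  if (!file.exists(f)) stop("parse error: missing ", f, call. = FALSE)
  long <- data.table::fread(f, colClasses = list(
    character = c("patient_id", "timestamp", "signal", "value")))
  pat <- data.table::fread(file.path(path, "patients.csv"))
  ev <- data.table::fread(file.path(path, "events.csv"))
  ev <- as.data.frame(ev)
  if (nrow(ev)) {
    ev$onset_ts <- parse_ts(ev$onset_ts)
    ev$recovery_ts <- parse_ts(ev$recovery_ts)
  }
  patients <- list()
  for (i in seq_len(nrow(pat))) {
    id <- pat$patient_id[i]
    sub <- long[long$patient_id == id]
    if (nrow(sub) == 0) {
      patients[[id]] <- list(patient_id = id, cohort = pat$cohort[i],
                             t0 = parse_ts(pat$t0[i]),
                             n_seconds = pat$n_seconds[i],
                             time = numeric(0),
                             values = matrix(0, 0, 0),
                             quality = matrix(0L, 0, 0))
      next
    }
    signames <- unique(sub$signal)
    tt <- parse_ts(sub$timestamp[sub$signal == signames[1]])
    if (any(diff(tt) <= 0))
      stop(sprintf(
        "parse error in %s: non-monotone timestamp for patient %s near record %d",
        f, id, which(diff(tt) <= 0)[1] + 1L), call. = FALSE)
    n <- length(tt)
    vals <- matrix(0, n, length(signames), dimnames = list(NULL, signames))
    qual_cols <- list()
    for (s in signames) {
      block <- sub[sub$signal == s]
      if (nrow(block) != n)
        stop(sprintf("parse error in %s: signal '%s' of patient %s has %d records, expected %d",
                     f, s, id, nrow(block), n), call. = FALSE)
      vals[, s] <- as.numeric(block$value)
      if (!all(is.na(block$quality))) qual_cols[[s]] <- as.integer(block$quality)
    }
    qual <- if (length(qual_cols))
      do.call(cbind, qual_cols) else matrix(0L, n, 0)
    patients[[id]] <- list(patient_id = id, cohort = pat$cohort[i],
                           t0 = parse_ts(pat$t0[i]),
                           n_seconds = pat$n_seconds[i],
                           time = tt, values = vals, quality = qual)
  }
  structure(list(patients = patients, events = ev, signals = NULL,
                 config = NULL), class = "scc_cohort")
}
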