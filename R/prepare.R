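## ---- hour segmentation, filtering, cropping, annotation, splits ------------
##
## Recordings are bucketed into half-open clock hours [hh:00:00, hh+1:00:00).
## Hours with >= 3000 of 3600 possible samples are retained, and within each
## retained hour a contiguous window of T = 3000 s is selected for the model.
## Hours are annotated regular / non-regular from the event table using the
## buffered-window rule, and regular hours are split 90/10 per patient for
## cross-validated training.

#' Segment patient streams into clock hours
#'
#' Buckets every sample of every patient into half-open clock-hour
#' intervals.  Hours inside the recording span with no samples (fully
#' gapped) are reported with `n_points = 0`.
#'
#' @param cohort an `scc_cohort`.
#' @return data.frame with one row per patient-hour: `patient_id`,
#'   `hour_start` (epoch seconds), `n_points`, and the row range
#'   `i0`/`i1` into the patient's stream (0 width when empty).
#' @export
segment_hours <- function(cohort) {
  out <- lapply(cohort$patients, function(p) {
    tt <- p$time
    if (length(tt) && any(diff(tt) <= 0))
      stop("timestamps not strictly increasing for patient ", p$patient_id,
           call. = FALSE)
    h0 <- hour_floor(p$t0)
    h1 <- hour_floor(p$t0 + p$n_seconds - 1)
    hours <- seq(h0, h1, by = 3600)
    idx <- if (length(tt)) (tt - h0) %/% 3600 + 1 else integer(0)
    counts <- tabulate(idx, nbins = length(hours))
    ends <- cumsum(counts)
    starts <- c(1L, head(ends, -1L) + 1L)
    data.frame(patient_id = p$patient_id, hour_start = hours,
               n_points = counts, i0 = starts, i1 = ends,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Drop hours with insufficient data
#'
#' @param hours data.frame from [segment_hours()].
#' @param min_points minimum samples per hour (default 3000).
#' @return the retained rows; the retention fraction is attached as
#'   attribute `"retention"`.
#' @export
filter_hours <- function(hours, min_points = 3000) {
  keep <- hours$n_points >= min_points
  out <- hours[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "retention") <- if (nrow(hours)) mean(keep) else NA_real_
  out
}

## presence mask (length 3600) of one hour
hour_presence <- function(patient, hour_start, i0, i1) {
  pres <- logical(3600)
  if (i1 >= i0)
    pres[patient$time[i0:i1] - hour_start + 1] <- TRUE
  pres
}

#' Select the T-second crop window of each retained hour
#'
#' Within each hour the contiguous window of `T` seconds containing the
#' most observed samples is selected (ties broken by earliest start).
#' Hours whose best window holds fewer than `min_observed` samples are
#' dropped, with the reason recorded in attribute `"dropped"`.
#'
#' @param cohort the source `scc_cohort`.
#' @param hours retained hours from [filter_hours()].
#' @param T window length in seconds (default 3000).
#' @param min_observed minimum observed samples inside the chosen window
#'   (default 2500).
#' @return `hours` with added columns `crop_start` (epoch seconds) and
#'   `n_observed`.
#' @export
crop_hours <- function(cohort, hours, T = 3000, min_observed = 2500) {
  n <- nrow(hours)
  crop_off <- integer(n)
  n_obs <- integer(n)
  for (r in seq_len(n)) {
    p <- cohort$patients[[hours$patient_id[r]]]
    pres <- hour_presence(p, hours$hour_start[r], hours$i0[r], hours$i1[r])
    cs <- c(0L, cumsum(pres))
    offs <- 0:(3600 - T)
    counts <- cs[offs + T + 1L] - cs[offs + 1L]
    best <- which.max(counts)   # earliest maximizer
    crop_off[r] <- offs[best]
    n_obs[r] <- counts[best]
  }
  hours$crop_start <- hours$hour_start + crop_off
  hours$n_observed <- n_obs
  keep <- n_obs >= min_observed
  dropped <- hours[!keep, c("patient_id", "hour_start", "n_observed")]
  out <- hours[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "dropped") <- dropped
  out
}

#' Annotate hours as regular / non-regular
#'
#' An hour is non-regular when its start lies in any event's buffered
#' window: every hour of each calendar day containing an onset, the
#' `pre_buffer_h` hours before that day's midnight, the event span from
#' onset through recovery, and the `post_buffer_h` hours after recovery.
#' Everything else is regular.  `infectious_window` is `TRUE` when at
#' least one covering event is infectious.
#'
#' @param hours data.frame of retained hours (with `patient_id`,
#'   `hour_start`).
#' @param events event table (`patient_id`, `infectious`, `onset_ts`,
#'   `recovery_ts`; epoch seconds).
#' @param pre_buffer_h buffer before the onset day's midnight (default 48).
#' @param post_buffer_h buffer after recovery (default 24).
#' @return `hours` with added columns `label` (`"regular"` /
#'   `"non_regular"`), `infectious_window`, and `day` (patient-local
#'   calendar day index).
#' @export
annotate_hours <- function(hours, events, pre_buffer_h = 48,
                           post_buffer_h = 24) {
  if (pre_buffer_h < 0 || post_buffer_h < 0)
    stop_cfg("pre_buffer_h/post_buffer_h", "must be >= 0")
  lab <- rep("regular", nrow(hours))
  inf <- rep(FALSE, nrow(hours))
  if (nrow(events)) {
    unknown <- setdiff(events$patient_id, hours$patient_id)
    if (length(unknown))
      stop("events reference unknown patient(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
    for (e in seq_len(nrow(events))) {
      pid <- events$patient_id[e]
      d0 <- day_floor(events$onset_ts[e])
      lo1 <- d0 - pre_buffer_h * 3600; hi1 <- d0 + 86400
      lo2 <- hour_floor(events$onset_ts[e])
      hi2 <- events$recovery_ts[e] + post_buffer_h * 3600
      hs <- hours$hour_start
      hit <- hours$patient_id == pid &
        ((hs >= lo1 & hs < hi1) | (hs >= lo2 & hs < hi2))
      lab[hit] <- "non_regular"
      if (events$infectious[e]) inf[hit] <- TRUE
    }
  }
  hours$label <- lab
  hours$infectious_window <- inf
  hours$day <- hours$hour_start %/% 86400
  hours
}

#' Build everything from a cohort in one call
#'
#' Convenience wrapper: [segment_hours()] then [filter_hours()],
#' [crop_hours()] and [annotate_hours()] with the cohort's own event
#' table.
#'
#' @inheritParams crop_hours
#' @inheritParams annotate_hours
#' @param min_points minimum samples per hour.
#' @return the annotated hours manifest.
#' @export
prepare_hours <- function(cohort, min_points = 3000, T = 3000,
                          min_observed = 2500, pre_buffer_h = 48,
                          post_buffer_h = 24) {
  h <- segment_hours(cohort)
  h <- filter_hours(h, min_points = min_points)
  h <- crop_hours(cohort, h, T = T, min_observed = min_observed)
  annotate_hours(h, cohort$events, pre_buffer_h = pre_buffer_h,
                 post_buffer_h = post_buffer_h)
}

#' Per-patient cross-validation splits of regular hours
#'
#' For each fold and each patient, the patient's regular hours are
#' partitioned at random into ~90% training and ~10% test (round half
#' down, but at least one test hour whenever the patient has two or more
#' regular hours).  Non-regular hours go to the test set of every fold.
#' Patients without any regular hour are excluded entirely (attribute
#' `"excluded_patients"`).
#'
#' @param manifest annotated hours manifest.
#' @param train_frac training fraction in (0, 1), default 0.9.
#' @param n_folds number of folds, default 10.
#' @param seed integer seed.
#' @return list of folds; each fold is a list with integer row indices
#'   `train` and `test` into `manifest`.
#' @export
make_splits <- function(manifest, train_frac = 0.9, n_folds = 10, seed = 1L) {
  if (train_frac <= 0 || train_frac >= 1)
    stop_cfg("train_frac", "must be in (0, 1)")
  reg_by_pat <- split(which(manifest$label == "regular"),
                      manifest$patient_id[manifest$label == "regular"])
  all_pat <- unique(manifest$patient_id)
  excluded <- setdiff(all_pat, names(reg_by_pat))
  ok <- !(manifest$patient_id %in% excluded)
  nonreg <- which(manifest$label == "non_regular" & ok)
  folds <- with_seed(seed, lapply(seq_len(n_folds), function(k) {
    train <- integer(0); test_reg <- integer(0)
    for (idx in reg_by_pat) {
      n <- length(idx)
      n_test <- if (n >= 2)
        max(1L, round_half_down(n * (1 - train_frac))) else 0L
      te <- if (n_test > 0) sample(idx, n_test) else integer(0)
      test_reg <- c(test_reg, te)
      train <- c(train, setdiff(idx, te))
    }
    list(train = sort(train), test = sort(c(test_reg, nonreg)))
  }))
  attr(folds, "excluded_patients") <- excluded
  folds
}

#' Materialize one cropped hour
#'
#' Returns the `T`-second window of a retained hour as dense matrices.
#' Missing seconds have `NA` values/quality and `mask = FALSE`; the
#' encoder turns them into all-zero input columns.
#'
#' @param cohort the `scc_cohort`.
#' @param patient_id patient identifier.
#' @param crop_start window start (epoch seconds), from the manifest.
#' @param T window length, seconds.
#' @return list with `values` (`T x 12`), `quality` (`T x 5` integer) and
#'   `mask` (length-`T` logical, `TRUE` = observed).
#' @export
hour_matrix <- function(cohort, patient_id, crop_start, T = 3000) {
  p <- cohort$patients[[patient_id]]
  if (is.null(p)) stop("unknown patient ", patient_id, call. = FALSE)
  j <- findInterval(c(crop_start - 0.5, crop_start + T - 0.5), p$time)
  rows <- if (j[2] >= j[1] + 1) (j[1] + 1L):j[2] else integer(0)
  sec <- p$time[rows] - crop_start + 1
  vals <- matrix(NA_real_, T, ncol(p$values),
                 dimnames = list(NULL, colnames(p$values)))
  qual <- matrix(NA_integer_, T, ncol(p$quality),
                 dimnames = list(NULL, colnames(p$quality)))
  mask <- logical(T)
  if (length(rows)) {
    vals[sec, ] <- p$values[rows, , drop = FALSE]
    qual[sec, ] <- p$quality[rows, , drop = FALSE]
    mask[sec] <- TRUE
  }
  list(values = vals, quality = qual, mask = mask)
}
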