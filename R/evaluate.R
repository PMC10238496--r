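## ---- evaluation battery ----------------------------------------------------
##
## AUROC via the Mann-Whitney statistic (ties get half credit), bootstrap
## and cross-validation errors, Youden cut-points, specificity at ~95%
## sensitivity, Welch t-tests with Bonferroni correction, z-score
## trajectories per event type, and event-anchored score curves.

as_binary_labels <- function(labels) {
  if (is.character(labels) || is.factor(labels))
    labels <- as.character(labels) == "non_regular"
  pos <- as.logical(labels)
  if (!any(pos) || all(pos))
    stop("both classes must be present", call. = FALSE)
  pos
}

#' Area under the ROC curve
#'
#' Computed as the normalized Mann-Whitney U statistic over midranks, so
#' tied scores contribute half credit.
#'
#' @param scores numeric scores (higher = more likely positive).
#' @param labels positives: logical/0-1, or `"non_regular"` labels.
#' @return AUROC in `[0, 1]`.
#' @export
auroc <- function(scores, labels) {
  pos <- as_binary_labels(labels)
  r <- rank(scores)
  n1 <- sum(pos); n0 <- sum(!pos)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Bootstrap standard deviation of the AUROC
#'
#' @inheritParams auroc
#' @param n_boot bootstrap resamples of the test set (default 1000).
#' @param seed integer seed.
#' @return list with `auroc`, `sd`, and the bootstrap draws.
#' @export
auroc_boot <- function(scores, labels, n_boot = 1000L, seed = 1L) {
  pos <- as_binary_labels(labels)
  n <- length(scores)
  draws <- with_seed(seed, vapply(seq_len(n_boot), function(b) {
    idx <- sample.int(n, n, replace = TRUE)
    if (all(pos[idx]) || !any(pos[idx])) return(NA_real_)
    auroc(scores[idx], pos[idx])
  }, 0))
  list(auroc = auroc(scores, pos), sd = sd(draws, na.rm = TRUE),
       draws = draws)
}

#' Youden-optimal operating point
#'
#' Scans all score thresholds (positive when `score > t`) and returns
#' the one maximizing sensitivity + specificity - 1, ties broken toward
#' the lower threshold.
#'
#' @inheritParams auroc
#' @return list with `threshold`, `sensitivity`, `specificity`, `J`.
#' @export
youden_cutpoint <- function(scores, labels) {
  pos <- as_binary_labels(labels)
  cand <- sort(unique(c(-Inf, scores)))
  n1 <- sum(pos); n0 <- sum(!pos)
  sens <- vapply(cand, function(t) sum(scores[pos] > t) / n1, 0)
  spec <- vapply(cand, function(t) sum(scores[!pos] <= t) / n0, 0)
  J <- sens + spec - 1
  best <- which.max(J)            # first (= lowest threshold) maximum
  list(threshold = cand[best], sensitivity = sens[best],
       specificity = spec[best], J = J[best])
}

#' Specificity at a sensitivity target
#'
#' Chooses the threshold whose sensitivity is the smallest achievable
#' value at or above `target` and reports both coordinates.  If the
#' target is unattainable the operating point at sensitivity 100% is
#' returned with `note = "target unattainable"`.
#'
#' @inheritParams auroc
#' @param target required sensitivity (default 0.95).
#' @return list with `threshold`, `sensitivity`, `specificity`, `note`.
#' @export
spec_at_sensitivity <- function(scores, labels, target = 0.95) {
  pos <- as_binary_labels(labels)
  cand <- sort(unique(c(-Inf, scores)))
  n1 <- sum(pos); n0 <- sum(!pos)
  sens <- vapply(cand, function(t) sum(scores[pos] > t) / n1, 0)
  spec <- vapply(cand, function(t) sum(scores[!pos] <= t) / n0, 0)
  ok <- sens >= target
  note <- ""
  if (!any(ok)) { ok <- sens >= max(sens); note <- "target unattainable" }
  sel <- which(ok)
  ## smallest achievable sensitivity >= target; among ties the highest
  ## specificity (= highest threshold)
  sel <- sel[sens[sel] == min(sens[sel])]
  best <- sel[which.max(spec[sel])]
  list(threshold = cand[best], sensitivity = sens[best],
       specificity = spec[best], note = note)
}

#' Two-sided group comparison with Bonferroni-adjusted level
#'
#' Welch two-sided t-test of regular vs non-regular scores; the
#' family-wise 0.05 level is divided by `n_comparisons` (12 comparisons
#' give 0.0042).
#'
#' @param regular_scores,nonregular_scores numeric score groups (n >= 2
#'   each).
#' @param n_comparisons number of comparisons in the family.
#' @return list with group means/SDs, `t`, `p`, `adjusted_alpha`,
#'   `significant`.
#' @export
group_ttest <- function(regular_scores, nonregular_scores,
                        n_comparisons = 12L) {
  if (length(regular_scores) < 2 || length(nonregular_scores) < 2)
    stop("each group needs at least 2 observations", call. = FALSE)
  tt <- t.test(nonregular_scores, regular_scores, var.equal = FALSE)
  adj <- 0.05 / n_comparisons
  list(mean_regular = mean(regular_scores), sd_regular = sd(regular_scores),
       mean_nonregular = mean(nonregular_scores),
       sd_nonregular = sd(nonregular_scores),
       t = unname(tt$statistic), p = tt$p.value, adjusted_alpha = adj,
       significant = tt$p.value < adj)
}

#' Average z-score trajectories per event type
#'
#' Within each fold, per-day scores of regular days define the baseline
#' mean and SD; each complication day is standardized against it, days
#' are averaged within each event, events within folds, and the fold
#' averages per event type are reported.
#'
#' @param day_table per-day score table (see [per_day_scores()]) with
#'   columns `fold`, `patient_id`, `day`, `label`, `per_day_score`.
#' @param events event table with `patient_id`, `event_type`,
#'   `onset_ts`, `recovery_ts`.
#' @return data.frame with `event_type`, `n` (events), `z`.
#' @export
zscore_trajectories <- function(day_table, events) {
  folds <- unique(day_table$fold)
  ev_z <- matrix(NA_real_, nrow(events), length(folds))
  for (fi in seq_along(folds)) {
    sub <- day_table[day_table$fold == folds[fi], ]
    reg <- sub$per_day_score[sub$label == "regular"]
    m <- mean(reg); s <- sd(reg)
    if (!is.finite(s) || s == 0)
      stop("regular per-day scores have zero variance", call. = FALSE)
    for (e in seq_len(nrow(events))) {
      d0 <- events$onset_ts[e] %/% 86400
      d1 <- events$recovery_ts[e] %/% 86400
      rows <- sub$patient_id == events$patient_id[e] &
        sub$day >= d0 & sub$day <= d1
      if (!any(rows)) next
      ev_z[e, fi] <- mean((sub$per_day_score[rows] - m) / s)
    }
  }
  z_ev <- rowMeans(ev_z, na.rm = TRUE)
  agg <- stats::aggregate(list(z = z_ev),
                          by = list(event_type = events$event_type),
                          FUN = mean, na.rm = TRUE)
  cnt <- stats::aggregate(list(n = z_ev),
                          by = list(event_type = events$event_type),
                          FUN = function(x) sum(is.finite(x)))
  out <- merge(agg, cnt, by = "event_type")
  out[order(-out$n), c("event_type", "n", "z")]
}

#' Event-anchored score curves
#'
#' Sets each infectious event's diagnosis time to t = 0 h and
#' aggregates hourly scores at offsets within `window_h` hours: mean and
#' SD across events per offset, plus the AUROC of offset-t hours against
#' all regular test hours.
#'
#' @param score_table hourly score table with `patient_id`, `hour_start`,
#'   `label`, `score`.
#' @param events event table; only rows with `infectious == 1` are used
#'   unless `infectious_only = FALSE`.
#' @param window_h half-width of the offset window in hours (default
#'   120).
#' @param infectious_only restrict to infectious events.
#' @return data.frame of class `scc_trajectory` with `offset_h`, `n`,
#'   `mean_score`, `sd_score`, `auroc`.
#' @export
event_anchored_curves <- function(score_table, events, window_h = 120L,
                                  infectious_only = TRUE) {
  if (infectious_only) events <- events[events$infectious == 1, , drop = FALSE]
  reg_scores <- score_table$score[score_table$label == "regular"]
  rows <- list()
  for (e in seq_len(nrow(events))) {
    sub <- score_table[score_table$patient_id == events$patient_id[e], ]
    off <- (sub$hour_start - hour_floor(events$onset_ts[e])) / 3600
    keep <- abs(off) <= window_h
    if (!any(keep)) next
    rows[[length(rows) + 1L]] <- data.frame(event = e,
                                            offset_h = off[keep],
                                            score = sub$score[keep])
  }
  if (!length(rows))
    return(structure(data.frame(offset_h = numeric(0), n = integer(0),
                                mean_score = numeric(0),
                                sd_score = numeric(0), auroc = numeric(0)),
                     class = c("scc_trajectory", "data.frame")))
  d <- do.call(rbind, rows)
  offs <- sort(unique(d$offset_h))
  out <- data.frame(offset_h = offs)
  out$n <- vapply(offs, function(o) sum(d$offset_h == o), 0L)
  out$mean_score <- vapply(offs, function(o) mean(d$score[d$offset_h == o]), 0)
  out$sd_score <- vapply(offs, function(o) {
    x <- d$score[d$offset_h == o]
    if (length(x) > 1) sd(x) else NA_real_
  }, 0)
  out$auroc <- vapply(offs, function(o) {
    x <- d$score[d$offset_h == o]
    auroc(c(reg_scores, x), c(rep(FALSE, length(reg_scores)),
                              rep(TRUE, length(x))))
  }, 0)
  structure(out, class = c("scc_trajectory", "data.frame"))
}

#' @exportS3Method graphics::plot scc_trajectory
plot.scc_trajectory <- function(x, ...) {
  plot(x$offset_h, x$mean_score, type = "l",
       xlab = "hours relative to diagnosis", ylab = "mean SCC-Score",
       main = "Event-anchored SCC-Score", ...)
  graphics::abline(v = 0, lty = 2)
  invisible(x)
}

#' AUROC as a function of patient-specific reference share
#'
#' For each fraction `f` the test patient's reference hours are all
#' kept while only a random `(1 - f)` share of the other patients'
#' reference vectors is retained, moving continuously from the
#' cohort-wide (`f = 0`) to the fully patient-specific (`f = 1`)
#' reference.
#'
#' @param fit an `scc_fit` (fitted pipeline; uses its stored test
#'   features).
#' @param fractions numeric vector in `[0, 1]`.
#' @param seed integer seed for subsampling.
#' @return data.frame with `fraction` and `auroc`.
#' @export
reference_fraction_sweep <- function(fit, fractions = seq(0, 1, 0.25),
                                     seed = 1L) {
  res <- with_seed(seed, vapply(fractions, function(f) {
    scores <- numeric(0); labs <- character(0)
    for (fd in fit$fold_data) {
      ref <- fd$reference
      pid_test <- fd$test_patient
      sc <- rep(NA_real_, length(pid_test))
      for (pid in unique(pid_test)) {
        own <- ref$patient_id == pid
        other <- which(!own)
        keep_other <- if (f >= 1) integer(0) else
          sample(other, round((1 - f) * length(other)))
        cols <- sort(c(which(own), keep_other))
        sel <- pid_test == pid
        kcols <- rep(sel, each = fd$K)
        sc[sel] <- score_features(
          fd$test_features[, kcols, drop = FALSE],
          ref$features[, cols, drop = FALSE], fd$K)
      }
      scores <- c(scores, sc)
      labs <- c(labs, fd$test_label)
    }
    auroc(scores, labs)
  }, 0))
  data.frame(fraction = fractions, auroc = res)
}
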