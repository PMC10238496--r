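## ---- end-to-end pipeline ---------------------------------------------------
##
## scc_fit() is the package's main entry point: starting from a cohort it
## prepares and annotates hours, builds per-patient cross-validation
## splits, trains one contrastive encoder per fold, scores all test hours
## against the cohort-wide and patient-specific reference sets, forms
## per-day scores and null distributions, and collects the evaluation
## battery.

#' Fit the SCC detection pipeline to a cohort
#'
#' @param cohort an `scc_cohort` (see [generate_cohort()] /
#'   [read_cohort()]).
#' @param encoder an [encoder_config()].
#' @param n_folds cross-validation folds (each retrains the encoder).
#' @param train_frac per-patient share of regular hours used for
#'   training (default 0.9).
#' @param K intervals per hour for reference building and scoring.
#' @param alpha significance level of the null-distribution detection
#'   test.
#' @param seed integer master seed (splits, training, interval draws).
#' @param verbose print progress.
#' @return an object of class `scc_fit` with components `manifest`,
#'   `splits`, `models`, `scores` (hourly score table), `day_scores`,
#'   `thresholds`, `fold_data` (per-fold features for sweeps) and
#'   `config`.
#' @export
scc_fit <- function(cohort, encoder = encoder_config(), n_folds = 2L,
                    train_frac = 0.9, K = 6L, alpha = 0.05, seed = 1L,
                    verbose = FALSE) {
  manifest <- prepare_hours(cohort, T = encoder$T)
  splits <- make_splits(manifest, train_frac = train_frac,
                        n_folds = n_folds, seed = child_seed(seed, 1L))
  pat_cohort <- vapply(cohort$patients, function(p) p$cohort, "")
  score_rows <- list()
  models <- list()
  fold_data <- list()
  for (k in seq_len(n_folds)) {
    if (verbose) message(sprintf("fold %d/%d: training encoder on %d hours",
                                 k, n_folds, length(splits[[k]]$train)))
    cfg <- encoder
    cfg$seed <- child_seed(seed, 10L + k)
    model <- train_encoder(cohort, manifest, splits[[k]]$train, cfg,
                           verbose = verbose)
    models[[k]] <- model
    ref <- build_reference(model, cohort, manifest, splits[[k]]$train,
                           K = K, seed = child_seed(seed, 20L + k))
    test_rows <- splits[[k]]$test
    hf <- hour_features(model, cohort, manifest, test_rows, K = K,
                        seed = child_seed(seed, 30L + k))
    pid_test <- manifest$patient_id[test_rows]
    sc_ns <- score_features(hf$features, ref$features, K)
    sc_sp <- rep(NA_real_, length(test_rows))
    for (pid in unique(pid_test)) {
      keep <- ref$patient_id == pid
      sel <- pid_test == pid
      cols <- rep(sel, each = K)
      sc_sp[sel] <- score_features(hf$features[, cols, drop = FALSE],
                                   ref$features[, keep, drop = FALSE], K)
    }
    base <- manifest[test_rows, c("patient_id", "hour_start", "label",
                                  "infectious_window", "day")]
    base$cohort <- pat_cohort[base$patient_id]
    base$fold <- k
    score_rows[[2 * k - 1]] <- cbind(base, approach = "non_specific",
                                     score = sc_ns)
    score_rows[[2 * k]] <- cbind(base, approach = "specific",
                                 score = sc_sp)
    fold_data[[k]] <- list(reference = ref, test_features = hf$features,
                           test_patient = pid_test,
                           test_label = manifest$label[test_rows],
                           K = K)
  }
  scores <- do.call(rbind, score_rows)
  rownames(scores) <- NULL
  day_scores <- per_day_scores(scores)
  ## per fold/approach null distributions and detection thresholds from
  ## the regular test hours
  thr <- do.call(rbind, lapply(seq_len(n_folds), function(k) {
    do.call(rbind, lapply(c("non_specific", "specific"), function(ap) {
      s <- scores$score[scores$fold == k & scores$approach == ap &
                          scores$label == "regular"]
      data.frame(fold = k, approach = ap,
                 threshold = detection_threshold(null_distribution(s),
                                                 alpha))
    }))
  }))
  structure(list(manifest = manifest, splits = splits, models = models,
                 scores = scores, day_scores = day_scores,
                 thresholds = thr, fold_data = fold_data,
                 events = cohort$events,
                 config = list(n_folds = n_folds, train_frac = train_frac,
                               K = K, alpha = alpha, seed = seed,
                               encoder = encoder)),
            class = "scc_fit")
}

#' @exportS3Method base::print scc_fit
print.scc_fit <- function(x, ...) {
  cat("SCC detection pipeline fit\n")
  cat(sprintf("  %d hours retained (%d regular, %d non-regular), %d folds\n",
              nrow(x$manifest), sum(x$manifest$label == "regular"),
              sum(x$manifest$label == "non_regular"), x$config$n_folds))
  for (ap in c("non_specific", "specific")) {
    sub <- x$scores[x$scores$approach == ap, ]
    a <- tryCatch(auroc(sub$score, sub$label), error = function(e) NA_real_)
    cat(sprintf("  hourly AUROC (%s): %s\n", ap,
                if (is.na(a)) "n/a (one class tested)" else sprintf("%.3f", a)))
  }
  invisible(x)
}

#' Evaluation summary of a fitted pipeline
#'
#' Builds the performance table: per approach, score granularity (hour /
#' day) and subset (all SCC / infectious), the group means, Welch t-test
#' with Bonferroni-adjusted level, Youden operating point, specificity
#' at ~95% sensitivity, and AUROC with cross-validation + bootstrap SD.
#'
#' @param object an `scc_fit`.
#' @param n_comparisons Bonferroni family size (default 12).
#' @param n_boot bootstrap resamples per fold.
#' @param ... unused.
#' @return data.frame of class `scc_eval`.
#' @exportS3Method base::summary scc_fit
summary.scc_fit <- function(object, n_comparisons = 12L, n_boot = 200L,
                            ...) {
  rows <- list()
  grids <- expand.grid(approach = c("non_specific", "specific"),
                       granularity = c("hour", "day"),
                       subset = c("all", "infectious"),
                       stringsAsFactors = FALSE)
  for (i in seq_len(nrow(grids))) {
    g <- grids[i, ]
    tab <- if (g$granularity == "hour") object$scores else object$day_scores
    tab <- tab[tab$approach == g$approach, ]
    sc <- if (g$granularity == "hour") tab$score else tab$per_day_score
    pos <- tab$label == "non_regular"
    if (g$subset == "infectious") {
      keep <- !pos | tab$infectious_window
      tab <- tab[keep, ]; sc <- sc[keep]; pos <- pos[keep]
    }
    if (!any(pos) || all(pos)) next
    ## AUROC and SD: bootstrap within folds, pooled
    folds <- unique(tab$fold)
    draws <- unlist(lapply(folds, function(k) {
      idx <- tab$fold == k
      auroc_boot(sc[idx], pos[idx], n_boot = n_boot,
                 seed = child_seed(object$config$seed, 40L + k))$draws
    }))
    tt <- group_ttest(sc[!pos], sc[pos], n_comparisons)
    yj <- youden_cutpoint(sc, pos)
    s95 <- spec_at_sensitivity(sc, pos, 0.95)
    rows[[i]] <- data.frame(
      approach = g$approach, granularity = g$granularity,
      subset = g$subset, n_regular = sum(!pos), n_nonregular = sum(pos),
      mean_regular = tt$mean_regular, sd_regular = tt$sd_regular,
      mean_nonregular = tt$mean_nonregular,
      sd_nonregular = tt$sd_nonregular, t = tt$t, p = tt$p,
      adjusted_alpha = tt$adjusted_alpha,
      sensitivity = 100 * yj$sensitivity,
      specificity = 100 * yj$specificity,
      sens95_sensitivity = 100 * s95$sensitivity,
      sens95_specificity = 100 * s95$specificity,
      auroc = auroc(sc, pos), auroc_sd = sd(draws, na.rm = TRUE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("scc_eval", "data.frame"))
}

#' @exportS3Method base::print scc_eval
print.scc_eval <- function(x, digits = 3, ...) {
  cat("SCC-Score performance\n")
  d <- as.data.frame(x)
  d$p <- format.pval(d$p, digits = 2)
  print(d[, c("approach", "granularity", "subset", "n_regular",
              "n_nonregular", "sensitivity", "specificity", "auroc",
              "auroc_sd", "p")],
        digits = digits, row.names = FALSE)
  invisible(x)
}

#' Detection outcomes of a fitted pipeline
#'
#' Applies the per-fold null-distribution test to all test-hour scores.
#'
#' @param fit an `scc_fit`.
#' @param approach `"specific"` or `"non_specific"`.
#' @param alpha significance level (default: the fit's).
#' @return the fit's hourly score table with a `detected` column.
#' @export
scc_detections <- function(fit, approach = "specific", alpha = NULL) {
  alpha <- alpha %||% fit$config$alpha
  tab <- fit$scores[fit$scores$approach == approach, ]
  out <- lapply(unique(tab$fold), function(k) {
    sub <- tab[tab$fold == k, ]
    null <- null_distribution(sub$score[sub$label == "regular"])
    sub$detected <- detect_scc(sub$score, null, alpha)
    sub
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' @exportS3Method graphics::plot scc_fit
plot.scc_fit <- function(x, type = c("loss", "scores", "anchored"),
                         approach = "specific", ...) {
  type <- match.arg(type)
  if (type == "loss") {
    for (k in seq_along(x$models)) {
      if (k == 1)
        plot(x$models[[k]]$log$epoch, x$models[[k]]$log$loss, type = "l",
             xlab = "epoch", ylab = "NT-Xent loss",
             main = "Training loss by fold", ...)
      else graphics::lines(x$models[[k]]$log$epoch, x$models[[k]]$log$loss,
                           lty = k)
    }
  } else if (type == "scores") {
    sub <- x$scores[x$scores$approach == approach, ]
    cols <- ifelse(sub$label == "non_regular", "red", "grey40")
    plot(as.POSIXct(sub$hour_start, origin = "1970-01-01", tz = "UTC"),
         sub$score, col = cols, pch = 16, cex = 0.4, xlab = "time",
         ylab = "hourly SCC-Score", main = paste("SCC-Scores,", approach),
         ...)
  } else {
    sub <- x$scores[x$scores$approach == approach, ]
    tr <- event_anchored_curves(sub, x$events, 120L)
    plot(tr, ...)
  }
  invisible(x)
}
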