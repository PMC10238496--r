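## ---- SCC-Score: nearest-neighbour cosine dissimilarity ---------------------
##
## The reference set holds K interval features per training regular hour.
## A test hour's SCC-Score is the mean, over K random intervals of that
## hour, of one minus the maximum cosine similarity to any reference
## vector.  Restricting the reference to the test patient's own regular
## hours gives the patient-specific score.  Detection compares scores to
## the empirical null distribution of regular test hours.

#' Cosine similarity between feature vectors
#'
#' @param a,b numeric vectors.
#' @return their cosine similarity in `[-1, 1]`.
#' @export
cosine_similarity <- function(a, b) {
  na <- sqrt(sum(a * a)); nb <- sqrt(sum(b * b))
  if (na == 0 || nb == 0) stop("zero vector has no direction", call. = FALSE)
  sum(a * b) / (na * nb)
}

#' Build a reference set of regular-hour features
#'
#' Extracts `K` interval features per reference hour with the trained
#' encoder; interval offsets are drawn uniformly over the cropped span.
#'
#' @param model an `scc_encoder`.
#' @param cohort the `scc_cohort`.
#' @param manifest prepared hours manifest.
#' @param rows manifest rows of the reference (training regular) hours.
#' @param K intervals per hour (default 6).
#' @param seed seed for interval placement.
#' @return object of class `scc_reference`: `features`
#'   (`feature_dim x K*N`), `patient_id`, `hour_start`, `K`.
#' @export
build_reference <- function(model, cohort, manifest, rows, K = 6L,
                            seed = 1L) {
  if (length(rows) == 0) stop("empty reference set", call. = FALSE)
  hf <- hour_features(model, cohort, manifest, rows, K = K, seed = seed)
  structure(list(features = hf$features,
                 patient_id = manifest$patient_id[hf$index$row],
                 hour_start = manifest$hour_start[hf$index$row],
                 K = as.integer(K)),
            class = "scc_reference")
}

#' Restrict a reference set to one patient
#'
#' @param ref an `scc_reference`.
#' @param patient_id patient to keep.
#' @return the restricted `scc_reference`.
#' @export
restrict_reference <- function(ref, patient_id) {
  keep <- ref$patient_id == patient_id
  if (!any(keep))
    stop("no patient baseline: patient ", patient_id,
         " has no hours in the reference set", call. = FALSE)
  structure(list(features = ref$features[, keep, drop = FALSE],
                 patient_id = ref$patient_id[keep],
                 hour_start = ref$hour_start[keep], K = ref$K),
            class = "scc_reference")
}

#' @exportS3Method base::print scc_reference
print.scc_reference <- function(x, ...) {
  cat(sprintf("SCC reference set: %d vectors (K = %d per hour, %d patients)\n",
              ncol(x$features), x$K, length(unique(x$patient_id))))
  invisible(x)
}

## score interval-feature columns against a reference feature matrix:
## per test hour (group of K columns) the mean of 1 - max similarity
score_features <- function(test_features, ref_features, K) {
  sims <- crossprod(test_features, ref_features)  # (K*n) x M
  j <- max.col(sims, ties.method = "first")
  per_int <- 1 - sims[cbind(seq_len(nrow(sims)), j)]
  n <- length(per_int) / K
  colMeans(matrix(per_int, nrow = K, ncol = n))
}

#' Hourly SCC-Score of one test hour
#'
#' Draws `K` random intervals from the test hour, extracts their
#' features, and averages `1 - max` cosine similarity to the reference
#' set.  Scores lie in `[0, 2]`; higher means more anomalous.
#'
#' @param model an `scc_encoder`.
#' @param cohort the `scc_cohort`.
#' @param manifest prepared hours manifest.
#' @param row manifest row of the test hour.
#' @param ref an `scc_reference` (must not contain the test hour).
#' @param K intervals from the test hour (default 6).
#' @param seed seed for interval placement.
#' @return the hourly SCC-Score.
#' @export
scc_score <- function(model, cohort, manifest, row, ref, K = 6L,
                      seed = 1L) {
  if (!inherits(ref, "scc_reference") || ncol(ref$features) == 0)
    stop("empty reference", call. = FALSE)
  hf <- hour_features(model, cohort, manifest, row, K = K, seed = seed)
  score_features(hf$features, ref$features, K)
}

## batch scorer used by the pipeline: one feature extraction pass for all
## test hours, then both reference restrictions
score_hours <- function(model, cohort, manifest, test_rows, ref,
                        K = 6L, seed = 1L,
                        approaches = c("non_specific", "specific")) {
  hf <- hour_features(model, cohort, manifest, test_rows, K = K,
                      seed = seed)
  out <- list()
  pid_test <- manifest$patient_id[test_rows]
  if ("non_specific" %in% approaches)
    out$non_specific <- score_features(hf$features, ref$features, K)
  if ("specific" %in% approaches) {
    sp <- rep(NA_real_, length(test_rows))
    for (pid in unique(pid_test)) {
      keep <- ref$patient_id == pid
      if (!any(keep))
        stop("no patient baseline: patient ", pid,
             " has no hours in the reference set", call. = FALSE)
      sel <- pid_test == pid
      cols <- rep(sel, each = K)
      sp[sel] <- score_features(hf$features[, cols, drop = FALSE],
                                ref$features[, keep, drop = FALSE], K)
    }
    out$specific <- sp
  }
  out
}

#' Per-day SCC-Scores
#'
#' Averages hourly scores over each patient's calendar days, using the
#' hours actually recorded on that day.  A day is labelled regular only
#' if all contributing hours are regular; it is in an infectious window
#' if any contributing hour is.
#'
#' @param score_table data.frame with columns `patient_id`, `day`,
#'   `label`, `infectious_window`, `score` and any grouping columns in
#'   `by` (e.g. `fold`, `approach`).
#' @param by extra grouping column names.
#' @return data.frame with one row per group-patient-day: `per_day_score`,
#'   `n_hours`, `label`, `infectious_window`.
#' @export
per_day_scores <- function(score_table, by = intersect(c("fold", "approach"),
                                                       names(score_table))) {
  dt <- data.table::as.data.table(score_table)
  keys <- c(by, "patient_id", "day")
  out <- dt[, list(per_day_score = mean(score), n_hours = .N,
                   label = if (all(label == "regular")) "regular" else "non_regular",
                   infectious_window = any(infectious_window)),
            by = keys]
  as.data.frame(out)
}

#' Empirical null distribution of regular-hour scores
#'
#' @param scores SCC-Scores of regular test hours (or days).
#' @param scope `"cohort"` or `"patient"`; recorded as an attribute.
#' @return sorted numeric vector of class `scc_null`.
#' @export
null_distribution <- function(scores, scope = c("cohort", "patient")) {
  scope <- match.arg(scope)
  scores <- scores[is.finite(scores)]
  if (!length(scores)) stop("empty null distribution", call. = FALSE)
  structure(sort(scores), scope = scope, class = "scc_null")
}

#' Null-distribution detection test
#'
#' Flags a score as SCC when it exceeds the empirical `(1 - alpha)`
#' threshold of the null: the order statistic of rank
#' `min(n, floor((1 - alpha) n) + 1)`, so that the fraction of null
#' scores strictly above the threshold is at most `alpha`.  Ties with
#' the threshold resolve to regular (strict `>`).
#'
#' @param score numeric vector of scores to test.
#' @param null an [null_distribution()] object (or numeric vector).
#' @param alpha significance level in (0, 1).
#' @return character vector, `"SCC"` or `"regular"`.
#' @export
detect_scc <- function(score, null, alpha = 0.05) {
  if (alpha <= 0 || alpha >= 1) stop_cfg("alpha", "must be in (0, 1)")
  if (!length(null)) stop("empty null distribution", call. = FALSE)
  thr <- detection_threshold(null, alpha)
  ifelse(score > thr, "SCC", "regular")
}

#' @rdname detect_scc
#' @export
detection_threshold <- function(null, alpha = 0.05) {
  x <- sort(as.numeric(null))
  n <- length(x)
  x[min(n, floor((1 - alpha) * n) + 1L)]
}
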