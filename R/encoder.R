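## ---- contrastive feature encoder -------------------------------------------
##
## Each second of wearable data becomes a 512-dimensional column: the five
## quality-bearing signals are positionally encoded (the signal value is
## written at the slot given by its integer 0-100 quality index inside a
## 101-long block) and the seven remaining signals are appended as raw
## scalars (5*101 + 7 = 512).  1000-second intervals are mapped to l2-
## normalized 128-dimensional features by a 1-D residual network trained
## with the temperature-scaled contrastive (NT-Xent) objective: two
## intervals from the same hour separated by at least 500 s form a positive
## pair, intervals from other hours in the minibatch act as negatives.

#' Encoder training configuration
#'
#' @param preset `"test"` (small widths and few epochs, suitable for a
#'   single CPU; the default) or `"full"` (24 residual blocks, width 32
#'   doubling after 12 blocks, batch 128, 500 epochs).
#' @param n_blocks number of residual blocks.
#' @param width channel count of the first blocks; doubled every
#'   `double_every` blocks.
#' @param kernel temporal kernel size of the block convolutions.
#' @param double_every blocks between channel doublings.
#' @param feature_dim output feature dimension (128).
#' @param temperature NT-Xent temperature, default 0.07.
#' @param batch_size hours per minibatch (n in the loss), default preset
#'   dependent.
#' @param epochs training epochs.
#' @param lr,beta1,beta2,weight_decay Adam hyperparameters; `lr` is the
#'   initial learning rate (preset default: 1e-3 for `"full"`, 3e-2 for
#'   `"test"`), betas (0.9, 0.98), weight decay 1e-3.
#' @param lr_schedule `"cosine"` (decay to zero over the run; both
#'   presets' default) or `"constant"`.
#' @param interval_length positive-pair interval length, seconds (1000).
#' @param min_separation minimum separation between the two intervals of
#'   a pair, seconds (500).
#' @param T cropped hour length, seconds (3000).
#' @param normalize_inputs z-scale each signal with training-set
#'   statistics before encoding: `"patient"` (each patient standardized
#'   by their own training regular hours; the default), `"cohort"`
#'   (pooled statistics; `TRUE` is accepted as an alias), or `FALSE`
#'   for raw values.
#' @param hours_per_patient_batch when > 0, assemble each minibatch from
#'   `batch_size / hours_per_patient_batch` randomly chosen patients
#'   with this many of their hours each, instead of sampling hours
#'   uniformly.  Same-patient negatives force the embedding to resolve
#'   within-patient physiological state, not just patient identity.
#' @param seed integer seed for weight init, pair sampling and batch
#'   order.
#' @return list of class `scc_encoder_config`.
#' @export
encoder_config <- function(preset = c("test", "full"),
                           n_blocks = NULL, width = NULL, kernel = 16L,
                           double_every = NULL, feature_dim = 128L,
                           temperature = 0.07, batch_size = NULL,
                           epochs = NULL, lr = NULL,
                           lr_schedule = NULL,
                           beta1 = 0.9,
                           beta2 = 0.98, weight_decay = 1e-3,
                           interval_length = 1000L, min_separation = 500L,
                           T = 3000L, normalize_inputs = "patient",
                           hours_per_patient_batch = 0L, seed = 1L) {
  preset <- match.arg(preset)
  def <- if (preset == "full")
    list(n_blocks = 24L, width = 32L, double_every = 12L,
         batch_size = 128L, epochs = 500L, lr = 1e-3,
         lr_schedule = "cosine")
  else
    ## desk-scale profile: shallow and wide trains best in few epochs on
    ## one CPU (deep stacks warp the embedding before they converge),
    ## with an aggressive decayed learning rate for the short run
    list(n_blocks = 2L, width = 16L, double_every = 2L,
         batch_size = 32L, epochs = 10L, lr = 3e-2,
         lr_schedule = "cosine")
  cfg <- list(preset = preset,
              n_blocks = as.integer(n_blocks %||% def$n_blocks),
              width = as.integer(width %||% def$width),
              kernel = as.integer(kernel),
              double_every = as.integer(double_every %||% def$double_every),
              feature_dim = as.integer(feature_dim),
              temperature = temperature,
              batch_size = as.integer(batch_size %||% def$batch_size),
              epochs = as.integer(epochs %||% def$epochs),
              lr = lr %||% def$lr,
              lr_schedule = match.arg(lr_schedule %||% def$lr_schedule,
                                      c("cosine", "constant")),
              beta1 = beta1, beta2 = beta2,
              weight_decay = weight_decay,
              interval_length = as.integer(interval_length),
              min_separation = as.integer(min_separation),
              T = as.integer(T),
              normalize_inputs = if (isTRUE(normalize_inputs)) "cohort"
                else normalize_inputs,
              hours_per_patient_batch = as.integer(hours_per_patient_batch),
              seed = as.integer(seed))
  if (cfg$temperature <= 0) stop_cfg("temperature", "must be > 0")
  if (2L * cfg$interval_length + cfg$min_separation > cfg$T)
    stop_cfg("min_separation",
             "infeasible: 2*interval_length + min_separation exceeds T")
  if (cfg$n_blocks < 1) stop_cfg("n_blocks", "must be >= 1")
  structure(cfg, class = "scc_encoder_config")
}

#' Encode wearable seconds as 512-dimensional input columns
#'
#' @param values `L x 12` matrix of signal values (quality-bearing
#'   signals in the first five columns); `NA` marks a missing second.
#' @param quality `L x 5` integer matrix of 0-100 quality indices.
#' @param stats optional list with `mean` and `sd` (length 12) used to
#'   z-scale values before placement.
#' @return dense `512 x L` matrix: per second, five 101-long blocks with
#'   the (scaled) signal value at the position given by its quality
#'   index, then the seven remaining (scaled) values; all-zero columns
#'   for missing seconds.
#' @export
encode_input <- function(values, quality, stats = NULL) {
  L <- nrow(values)
  if (ncol(values) != N_SIGNALS)
    stop("values must have ", N_SIGNALS, " columns", call. = FALSE)
  if (ncol(quality) != N_QUALITY || nrow(quality) != L)
    stop("quality must be ", L, " x ", N_QUALITY, call. = FALSE)
  pres <- !is.na(values[, 1])
  q <- quality[pres, , drop = FALSE]
  if (any(!is.na(q) & (q < 0 | q > 100 | q != floor(q))))
    stop("quality index outside [0, 100]", call. = FALSE)
  sp <- encode_sparse(list(list(values = values, quality = quality)), stats)
  as.matrix(sp)
}

## build the sparse 512 x (L*B) input for a list of interval items,
## each a list(values = L x 12, quality = L x 5)
encode_sparse <- function(items, stats = NULL) {
  L <- nrow(items[[1]]$values)
  B <- length(items)
  ii <- vector("list", B); jj <- vector("list", B); xx <- vector("list", B)
  for (b in seq_len(B)) {
    V <- items[[b]]$values
    Q <- items[[b]]$quality
    pres <- which(!is.na(V[, 1]))
    if (!length(pres)) next
    V <- V[pres, , drop = FALSE]
    Q <- Q[pres, , drop = FALSE]
    st <- items[[b]]$stats %||% stats
    if (!is.null(st))
      V <- (V - rep(st$mean, each = nrow(V))) /
        rep(st$sd, each = nrow(V))
    np <- length(pres)
    ## time-major batch layout: column (sec-1)*B + b
    cols <- (pres - 1L) * B + b
    i_q <- rep((0:(N_QUALITY - 1L)) * QBLOCK, each = np) + as.vector(Q) + 1L
    i_r <- rep(N_QUALITY * QBLOCK + seq_len(N_SIGNALS - N_QUALITY),
               each = np)
    ii[[b]] <- c(i_q, i_r)
    jj[[b]] <- c(rep(cols, N_QUALITY), rep(cols, N_SIGNALS - N_QUALITY))
    xx[[b]] <- c(as.vector(V[, seq_len(N_QUALITY)]),
                 as.vector(V[, (N_QUALITY + 1L):N_SIGNALS]))
  }
  Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                       dims = c(ENC_INPUT_DIM, L * B))
}

#' Sample a positive pair of interval offsets within a cropped hour
#'
#' Draws `(o1, o2)` uniformly over all offset pairs with both intervals
#' inside `[0, T - interval_length]` and `o2 >= o1 + interval_length +
#' min_separation`.
#'
#' @param T cropped hour length, seconds.
#' @param interval_length interval length, seconds.
#' @param min_separation minimum gap between the intervals, seconds.
#' @return integer vector `c(o1, o2)` of window start offsets.
#' @export
sample_positive_pair <- function(T = 3000L, interval_length = 1000L,
                                 min_separation = 500L) {
  m <- T - interval_length
  gap <- interval_length + min_separation
  if (m - gap < 0)
    stop_cfg("min_separation", "infeasible pair geometry for this T")
  o1_max <- m - gap
  w <- (m - gap) - (0:o1_max) + 1L     # choices of o2 for each o1
  o1 <- sample.int(o1_max + 1L, 1L, prob = w) - 1L
  o2 <- o1 + gap + sample.int(m - gap - o1 + 1L, 1L) - 1L
  c(o1, o2)
}

#' Temperature-scaled contrastive (NT-Xent) loss
#'
#' For `n` positive pairs with unit-norm features, the per-pair loss is
#' `-log( exp(sim(h_i, h_i')/tau) / (exp(sim(h_i, h_i')/tau) +
#' sum_{k != i} [exp(sim(h_i, h_k')/tau) + exp(sim(h_i', h_k)/tau)]) )`,
#' averaged over pairs.
#'
#' @param features `d x 2n` matrix of unit-norm feature columns: columns
#'   `1..n` are the first views, `n+i` is the partner of column `i`.
#' @param tau temperature (> 0).
#' @param grad also return the gradient with respect to `features`.
#' @return the scalar loss, or (with `grad = TRUE`) a list with `loss`
#'   and `grad`.
#' @export
nt_xent_loss <- function(features, tau = 0.07, grad = FALSE) {
  B <- ncol(features)
  if (B %% 2L != 0L) stop("features must hold 2n paired columns",
                          call. = FALSE)
  n <- B %/% 2L
  if (n < 2) stop("need at least 2 pairs (no negatives otherwise)",
                  call. = FALSE)
  S <- crossprod(features)
  E12 <- exp(S[seq_len(n), n + seq_len(n), drop = FALSE] / tau)
  E21 <- exp(S[n + seq_len(n), seq_len(n), drop = FALSE] / tau)
  pos <- diag(E12)
  D <- rowSums(E12) + rowSums(E21) - pos
  loss <- mean(log(D) - log(pos))
  if (!grad) return(loss)
  G <- matrix(0, B, B)
  G12 <- E12 / (tau * D)              # rows scaled by 1/D_i
  diag(G12) <- diag(G12) - 1 / tau
  G21 <- E21 / (tau * D)
  diag(G21) <- 0
  G[seq_len(n), n + seq_len(n)] <- G12
  G[n + seq_len(n), seq_len(n)] <- G21
  G <- G / n
  list(loss = loss, grad = features %*% (G + t(G)))
}

## ---- interval extraction ----------------------------------------------------

## materialize an interval of `len` seconds starting `offset` seconds into
## the cropped window of one manifest row
interval_item <- function(cohort, manifest, row, offset, len) {
  p <- cohort$patients[[manifest$patient_id[row]]]
  start <- manifest$crop_start[row] + offset
  ## the crop window lies inside the hour's row range; search only there
  i0 <- manifest$i0[row]; i1 <- manifest$i1[row]
  if (!is.null(i0) && !is.na(i0) && i1 >= i0) {
    tt <- p$time[i0:i1]
    j <- findInterval(c(start - 0.5, start + len - 0.5), tt) + (i0 - 1L)
  } else {
    j <- findInterval(c(start - 0.5, start + len - 0.5), p$time)
  }
  rows <- if (j[2] >= j[1] + 1L) (j[1] + 1L):j[2] else integer(0)
  vals <- matrix(NA_real_, len, N_SIGNALS)
  qual <- matrix(NA_integer_, len, N_QUALITY)
  if (length(rows)) {
    sec <- p$time[rows] - start + 1
    vals[sec, ] <- p$values[rows, , drop = FALSE]
    qual[sec, ] <- p$quality[rows, , drop = FALSE]
  }
  list(values = vals, quality = qual)
}

## draw one minibatch of hour rows: uniform, or stratified with `hpp`
## hours from each of batch/hpp sampled patients
sample_batch_hours <- function(train_rows, pid_train, batch, hpp) {
  if (hpp <= 0L) return(sample(train_rows, batch))
  pats <- unique(pid_train)
  n_pat <- max(1L, batch %/% hpp)
  out <- integer(0)
  take <- sample(pats, min(n_pat, length(pats)))
  for (p in take) {
    rows_p <- train_rows[pid_train == p]
    out <- c(out, sample(rows_p, min(hpp, length(rows_p))))
  }
  ## pad uniformly if stratification fell short of the batch size
  if (length(out) < batch) {
    pool <- setdiff(train_rows, out)
    out <- c(out, sample(pool, min(batch - length(out), length(pool))))
  }
  out
}

## per-signal z-scale statistics from a sample of training hours;
## scope "cohort" pools everything, scope "patient" adds per-patient
## means/SDs (with the cohort statistics as fallback)
input_stats <- function(cohort, manifest, rows, scope = "cohort",
                        max_hours = 60L) {
  moments <- function(use) {
    acc_n <- 0; acc_s <- numeric(N_SIGNALS); acc_q <- numeric(N_SIGNALS)
    for (r in use) {
      it <- interval_item(cohort, manifest, r, 0L, len = 3000L)
      v <- it$values[!is.na(it$values[, 1]), , drop = FALSE]
      acc_n <- acc_n + nrow(v)
      acc_s <- acc_s + colSums(v)
      acc_q <- acc_q + colSums(v * v)
    }
    mu <- acc_s / acc_n
    list(mean = mu, sd = sqrt(pmax(acc_q / acc_n - mu^2, 1e-12)))
  }
  thin <- function(x, k) if (length(x) > k)
    x[round(seq(1, length(x), length.out = k))] else x
  out <- moments(thin(rows, max_hours))
  out$scope <- scope
  if (scope == "patient") {
    by_pat <- split(rows, manifest$patient_id[rows])
    out$per_patient <- lapply(by_pat, function(rr)
      moments(thin(rr, max(8L, max_hours %/% length(by_pat)))))
  }
  out
}

## resolve the statistics to apply for one patient's intervals
stats_for <- function(stats, patient_id) {
  if (is.null(stats)) return(NULL)
  if (identical(stats$scope, "patient") &&
      patient_id %in% names(stats$per_patient))
    return(stats$per_patient[[patient_id]])
  stats
}

## ---- training ---------------------------------------------------------------

#' Train the contrastive encoder
#'
#' Runs minibatch NT-Xent training over the given (regular, training)
#' hours: each step samples `batch_size` distinct hours uniformly, draws
#' a fresh positive pair of 1000-s intervals per hour, and updates all
#' network weights with Adam.  Pairs are resampled every epoch.
#'
#' @param cohort the `scc_cohort`.
#' @param manifest annotated hours manifest (see [prepare_hours()]).
#' @param train_rows integer row indices of `manifest` to train on
#'   (regular hours of the training split).
#' @param config an [encoder_config()].
#' @param verbose print per-epoch loss.
#' @return an object of class `scc_encoder`: network parameters, batch-
#'   norm running statistics, architecture, input statistics and a
#'   per-epoch training log.
#' @export
train_encoder <- function(cohort, manifest, train_rows,
                          config = encoder_config(), verbose = FALSE) {
  if (length(train_rows) == 0) stop("empty training set", call. = FALSE)
  n_train <- length(train_rows)
  batch <- config$batch_size
  if (n_train < batch) {
    warning(sprintf("only %d training hours; shrinking batch from %d",
                    n_train, batch))
    batch <- max(2L, n_train)
  }
  if (batch < 2L) stop("need at least 2 training hours", call. = FALSE)
  with_seed(config$seed, {
    pid_train <- manifest$patient_id[train_rows]
    norm <- config$normalize_inputs
    if (isTRUE(norm)) norm <- "cohort"
    stats <- if (identical(norm, FALSE) || identical(norm, "none")) NULL
      else input_stats(cohort, manifest, train_rows, scope = norm)
    arch <- build_arch(config)
    prm <- init_params(config, arch)
    bn_env <- new.env(parent = emptyenv())
    st <- adam_init(prm)
    steps <- max(1L, ceiling(n_train / batch))
    total_steps <- steps * config$epochs
    log <- data.frame(epoch = seq_len(config$epochs),
                      loss = rep(NA_real_, config$epochs))
    t_global <- 0L
    for (ep in seq_len(config$epochs)) {
      ep_loss <- numeric(steps)
      for (s in seq_len(steps)) {
        hrs <- sample_batch_hours(train_rows, pid_train, batch,
                                  config$hours_per_patient_batch)
        offs <- vapply(seq_len(batch), function(i)
          sample_positive_pair(config$T, config$interval_length,
                               config$min_separation), integer(2))
        one_view <- function(v) lapply(seq_len(batch), function(i) {
          it <- interval_item(cohort, manifest, hrs[i], offs[v, i],
                              config$interval_length)
          it$stats <- stats_for(stats, manifest$patient_id[hrs[i]])
          it
        })
        items <- c(one_view(1L), one_view(2L))
        X <- encode_sparse(items, NULL)
        fw <- nn_forward(prm, arch, bn_env, X, 2L * batch, training = TRUE)
        ls <- nt_xent_loss(fw$H, config$temperature, grad = TRUE)
        ep_loss[s] <- ls$loss
        grads <- nn_backward(prm, arch, fw$caches, ls$grad, 2L * batch)
        t_global <- t_global + 1L
        lr_t <- if (identical(config$lr_schedule, "cosine"))
          config$lr * 0.5 * (1 + cos(pi * (t_global - 1) / total_steps))
        else config$lr
        up <- adam_step(prm, grads, st, lr_t, config$beta1,
                        config$beta2, config$weight_decay, t_global)
        prm <- up$params; st <- up$state
      }
      log$loss[ep] <- mean(ep_loss)
      if (verbose)
        message(sprintf("epoch %d/%d  loss %.4f", ep, config$epochs,
                        log$loss[ep]))
    }
    structure(list(params = prm, bn = bn_env, arch = arch,
                   config = config, stats = stats, log = log),
              class = "scc_encoder")
  })
}

#' Extract unit-norm features for intervals
#'
#' Runs the trained network in inference mode (batch-norm running
#' statistics); deterministic for fixed weights.
#'
#' @param model an `scc_encoder`.
#' @param items list of interval items (`values`, `quality`), or a
#'   prebuilt sparse input matrix.
#' @param B number of intervals when `items` is a matrix.
#' @return `feature_dim x B` matrix with unit-norm columns.
#' @export
extract_features <- function(model, items, B = NULL) {
  X <- if (is.list(items)) encode_sparse(items, model$stats) else items
  if (is.null(B)) B <- length(items)
  L <- model$config$interval_length
  if (ncol(X) != L * B)
    stop("input shape mismatch: expected ", L * B, " columns, got ",
         ncol(X), call. = FALSE)
  nn_forward(model$params, model$arch, model$bn, X, B, training = FALSE)$H
}

## features for K random intervals of each listed manifest row; returns
## feature matrix (feature_dim x K*n) plus the row/interval bookkeeping
hour_features <- function(model, cohort, manifest, rows, K = 6L,
                          seed = NULL, chunk = 64L) {
  cfg <- model$config
  max_off <- cfg$T - cfg$interval_length
  ## the interval draw of an hour depends only on (seed, manifest row),
  ## not on which other hours are featurized alongside it, so the same
  ## hour always yields the same intervals under the same seed
  offs <- lapply(seq_along(rows), function(i)
    with_seed(child_seed(seed, rows[i]),
              sample.int(max_off + 1L, K, replace = max_off + 1L < K) - 1L))
  idx <- data.frame(row = rep(rows, each = K),
                    k = rep(seq_len(K), length(rows)),
                    offset = unlist(offs))
  n <- nrow(idx)
  H <- matrix(0, cfg$feature_dim, n)
  for (start in seq(1L, n, by = chunk)) {
    end <- min(start + chunk - 1L, n)
    items <- lapply(start:end, function(i) {
      it <- interval_item(cohort, manifest, idx$row[i], idx$offset[i],
                          cfg$interval_length)
      it$stats <- stats_for(model$stats, manifest$patient_id[idx$row[i]])
      it
    })
    H[, start:end] <- extract_features(model, items)
  }
  list(features = H, index = idx)
}

#' @exportS3Method base::print scc_encoder
print.scc_encoder <- function(x, ...) {
  a <- x$arch
  cat(sprintf(
    "Contrastive wearable encoder (%s preset)\n", x$config$preset))
  cat(sprintf(
    "  %d residual blocks, width %d-%d, kernel %d -> %d-dim features\n",
    length(a$blocks), a$blocks[[1]]$cout, a$c_last, x$config$kernel,
    x$config$feature_dim))
  cat(sprintf("  trained %d epochs, final NT-Xent loss %.4f (tau = %g)\n",
              nrow(x$log), tail(x$log$loss, 1), x$config$temperature))
  invisible(x)
}

#' Features for new data from a trained encoder
#'
#' @param object an `scc_encoder`.
#' @param cohort an `scc_cohort`.
#' @param manifest prepared hours manifest for `cohort`.
#' @param rows manifest rows to featurize (default all).
#' @param K intervals per hour.
#' @param seed seed for interval placement.
#' @param ... unused.
#' @return list with `features` (`128 x K*length(rows)`) and `index`.
#' @exportS3Method stats::predict scc_encoder
predict.scc_encoder <- function(object, cohort, manifest,
                                rows = seq_len(nrow(manifest)), K = 6L,
                                seed = 1L, ...) {
  hour_features(object, cohort, manifest, rows, K = K, seed = seed)
}

#' @exportS3Method graphics::plot scc_encoder
plot.scc_encoder <- function(x, ...) {
  plot(x$log$epoch, x$log$loss, type = "b", xlab = "epoch",
       ylab = "NT-Xent loss", main = "Contrastive training loss", ...)
  invisible(x)
}
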