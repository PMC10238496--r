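test_that("each second is encoded into 5x101+7 = 512 dimensions", {
  set.seed(1)
  L <- 7L
  vals <- matrix(rnorm(L * 12), L, 12)
  qual <- matrix(sample(0:100, L * 5, TRUE), L, 5)
  x <- encode_input(vals, qual)
  expect_equal(dim(x), c(512L, L))
  ## every second holds exactly one entry per quality block plus 7 raws
  expect_true(all(colSums(x != 0) <= 12))
  for (s in 1:5) {
    block <- x[((s - 1) * 101 + 1):(s * 101), , drop = FALSE]
    expect_true(all(colSums(block != 0) <= 1))
    hit <- vapply(seq_len(L), function(t) block[qual[t, s] + 1, t], 0)
    expect_equal(hit, vals[, s])
  }
  expect_equal(x[506:512, 1], vals[1, 6:12])
})

test_that("quality boundaries, missing seconds and bad indices behave", {
  vals <- matrix(1, 2, 12); qual <- matrix(0L, 2, 5)
  x <- encode_input(vals, qual)
  ## quality 0 puts the value at block position 1, rest of block zero
  expect_equal(x[1, 1], 1); expect_true(all(x[2:101, 1] == 0))
  qual[] <- 100L
  x2 <- encode_input(vals, qual)
  expect_equal(x2[101, 1], 1)
  ## an all-missing second becomes an all-zero column
  vals[2, ] <- NA; qual[2, ] <- NA
  x3 <- encode_input(vals, qual)
  expect_true(all(x3[, 2] == 0))
  ## out-of-range quality is a validation error
  qual[1, 1] <- 101L
  expect_error(encode_input(vals, qual), "quality index")
  ## z-scaling statistics are applied before placement
  vals <- matrix(2, 1, 12); qual <- matrix(50L, 1, 5)
  st <- list(mean = rep(1, 12), sd = rep(2, 12))
  x4 <- encode_input(vals, qual, stats = st)
  expect_equal(x4[51, 1], 0.5)
  expect_equal(x4[506, 1], 0.5)
})

test_that("sparse batch encoding matches the dense single encoder", {
  set.seed(2)
  items <- lapply(1:3, function(i) {
    v <- matrix(rnorm(60), 5, 12); q <- matrix(sample(0:100, 25, TRUE), 5, 5)
    v[2, ] <- NA; q[2, ] <- NA
    list(values = v, quality = q)
  })
  sp <- as.matrix(sccscore:::encode_sparse(items, NULL))
  B <- 3
  for (b in seq_len(B)) {
    dense <- encode_input(items[[b]]$values, items[[b]]$quality)
    ## time-major layout: column (t-1)*B + b
    expect_equal(sp[, (seq_len(5) - 1) * B + b], dense)
  }
})

test_that("positive pairs are sampled inside the feasible region", {
  set.seed(3)
  draws <- t(replicate(500, sample_positive_pair(3000, 1000, 500)))
  expect_true(all(draws[, 1] >= 0 & draws[, 1] <= 500))
  expect_true(all(draws[, 2] >= draws[, 1] + 1500))
  expect_true(all(draws[, 2] <= 2000))
  ## both boundaries are reachable
  expect_lt(min(draws[, 1]), 50)
  expect_gt(max(draws[, 2]), 1950)
  ## infeasible geometry errors out
  expect_error(sample_positive_pair(3000, 1000, 3000), "infeasible")
  expect_error(encoder_config(min_separation = 3000), "min_separation")
  ## reproducible under a fixed seed
  set.seed(11); a <- sample_positive_pair()
  set.seed(11); b <- sample_positive_pair()
  expect_identical(a, b)
})

test_that("the contrastive loss matches closed forms and a naive oracle", {
  tau <- 0.07
  ## n = 2, identical positives, orthogonal across pairs:
  ## L = -log(exp(1/tau) / (exp(1/tau) + 2))
  H <- cbind(c(1, 0, 0, 0), c(0, 1, 0, 0), c(1, 0, 0, 0), c(0, 1, 0, 0))
  expected <- -log(exp(1 / tau) / (exp(1 / tau) + 2))
  expect_equal(nt_xent_loss(H, tau), expected, tolerance = 1e-6)
  ## first-order form log(1 + 2 e^{-1/tau}) ~ 2 e^{-1/tau}
  expect_equal(expected, 2 * exp(-1 / tau), tolerance = 1e-5)

  ## all four vectors identical: L = log 3
  H2 <- matrix(rep(c(1, 0, 0, 0), 4), 4)
  expect_equal(nt_xent_loss(H2, tau), log(3), tolerance = 1e-9)

  ## naive double-loop oracle on random unit vectors, n <= 8
  naive <- function(H, tau) {
    n <- ncol(H) / 2
    sim <- function(a, b) sum(H[, a] * H[, b])
    mean(vapply(seq_len(n), function(i) {
      pos <- exp(sim(i, n + i) / tau)
      den <- pos
      for (k in seq_len(n)) if (k != i)
        den <- den + exp(sim(i, n + k) / tau) + exp(sim(n + i, k) / tau)
      -log(pos / den)
    }, 0))
  }
  set.seed(4)
  for (n in c(2, 5, 8)) {
    H3 <- matrix(rnorm(16 * 2 * n), 16)
    H3 <- sweep(H3, 2, sqrt(colSums(H3^2)), "/")
    expect_equal(nt_xent_loss(H3, tau), naive(H3, tau), tolerance = 1e-6)
    ## invariance under permutation of the pairs
    pi <- sample(n)
    expect_equal(nt_xent_loss(H3[, c(pi, n + pi)], tau),
                 nt_xent_loss(H3, tau), tolerance = 1e-12)
  }
  ## a single pair has no negatives
  expect_error(nt_xent_loss(H[, c(1, 3)], tau), "at least 2")
})

test_that("the loss gradient matches finite differences", {
  set.seed(5)
  H <- matrix(rnorm(8 * 6), 8)
  H <- sweep(H, 2, sqrt(colSums(H^2)), "/")
  g <- nt_xent_loss(H, 0.07, grad = TRUE)$grad
  eps <- 1e-6
  for (i in sample(length(H), 8)) {
    Hp <- H; Hp[i] <- Hp[i] + eps
    Hm <- H; Hm[i] <- Hm[i] - eps
    ## gradient of the loss in the ambient (un-normalized) coordinates:
    ## compare against the raw matrix perturbation
    fd <- (nt_xent_loss(Hp, 0.07) - nt_xent_loss(Hm, 0.07)) / (2 * eps)
    expect_lt(abs(fd - g[i]) / max(1e-6, abs(fd) + abs(g[i])), 1e-4)
  }
})

test_that("features are unit-norm and deterministic at inference", {
  mod <- toy_model()
  m <- toy_manifest()
  co <- toy_cohort()
  hf1 <- predict(mod, co, m, rows = toy_split()$test[1:5], K = 3, seed = 1)
  hf2 <- predict(mod, co, m, rows = toy_split()$test[1:5], K = 3, seed = 1)
  expect_identical(hf1$features, hf2$features)
  expect_equal(colSums(hf1$features^2), rep(1, ncol(hf1$features)),
               tolerance = 1e-5)
})

test_that("training reduces the contrastive loss over random pairs", {
  co <- toy_cohort(); m <- toy_manifest(); tr <- toy_split()$train
  init <- train_encoder(co, m, tr, toy_encoder_config(epochs = 0L))
  trained <- toy_model()
  ## fresh positive pairs from training hours, common to both models
  set.seed(17)
  hrs <- sample(tr, 16)
  offs <- vapply(hrs, function(h) sample_positive_pair(), integer(2))
  items <- c(lapply(seq_along(hrs), function(i)
    sccscore:::interval_item(co, m, hrs[i], offs[1, i], 1000L)),
    lapply(seq_along(hrs), function(i)
      sccscore:::interval_item(co, m, hrs[i], offs[2, i], 1000L)))
  l0 <- nt_xent_loss(extract_features(init, items), 0.07)
  l1 <- nt_xent_loss(extract_features(trained, items), 0.07)
  expect_lt(l1, l0)
})

test_that("within-hour features align more than cross-hour features", {
  mod <- toy_model(); co <- toy_cohort(); m <- toy_manifest()
  rows <- toy_split()$test
  hf <- predict(mod, co, m, rows = rows, K = 2, seed = 23)
  H <- hf$features
  n <- length(rows)
  within <- vapply(seq_len(n), function(i) sum(H[, 2 * i - 1] * H[, 2 * i]), 0)
  set.seed(29)
  cross <- replicate(300, {
    ij <- sample(n, 2)
    sum(H[, 2 * ij[1] - 1] * H[, 2 * ij[2]])
  })
  expect_gt(mean(within), mean(cross))
})

test_that("training is seeded and degenerate inputs error", {
  co <- toy_cohort(); m <- toy_manifest()
  expect_error(train_encoder(co, m, integer(0), toy_encoder_config()),
               "empty training set")
  expect_warning(
    train_encoder(co, m, toy_split()$train[1:4],
                  toy_encoder_config(epochs = 1L)),
    "shrinking batch")
})
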