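test_that("entropy matches hand-computed values", {
  expect_equal(entropy_bits(c(5, 5)), 1.0)
  expect_equal(entropy_bits(c(10, 0)), 0.0)
  expect_equal(entropy_bits(c(3, 1)), -(0.75 * log2(0.75) + 0.25 * log2(0.25)))
  expect_equal(entropy_bits(c(3, 1)), 0.8113, tolerance = 1e-4)
  expect_error(entropy_bits(c(0, 0)), "all-zero")
  expect_error(entropy_bits(c(-1, 2)), "negative")
})

test_that("information gain matches its definition on known cases", {
  labels <- c(1, 1, 0, 0, 1, 0)
  expect_equal(information_gain(labels, labels), entropy_bits(table(labels)))
  expect_equal(information_gain(rep(0, 6), labels), 0)
  expect_equal(information_gain(c(1, 1, 0, 0), c(1, 0, 1, 0)), 0)
  expect_error(information_gain(c(1, 0), c(1, 0, 1)), "length")
})

test_that("information gain equals the contingency-table oracle", {
  set.seed(41)
  for (i in 1:150) {
    n <- sample(4:40, 1)
    feature <- rbinom(n, 1, runif(1, 0.2, 0.8))
    labels <- c(0, 1, rbinom(n - 2, 1, runif(1, 0.2, 0.8)))
    expect_equal(information_gain(feature, labels),
                 oracle_ig(feature, labels), tolerance = 1e-12)
  }
})

test_that("information gain is bounded by min(H(C), H(F))", {
  set.seed(43)
  for (i in 1:100) {
    n <- sample(4:30, 1)
    feature <- rbinom(n, 1, 0.5)
    labels <- c(0, 1, rbinom(n - 2, 1, 0.5))
    ig <- information_gain(feature, labels)
    expect_gte(ig, -1e-12)
    expect_lte(ig, entropy_bits(table(labels)) + 1e-12)
    expect_lte(ig, entropy_bits(table(feature)) + 1e-12)
  }
})

test_that("activation binarization maximizes training IG over midpoints", {
  bin <- binarize_activation(c(0, 0, 5, 5), c(0, 0, 1, 1))
  expect_gt(bin$threshold, 0)
  expect_lt(bin$threshold, 5)
  expect_equal(information_gain(bin$feature, c(0, 0, 1, 1)), 1.0)
  const <- binarize_activation(rep(2, 4), c(0, 1, 0, 1))
  expect_equal(const$feature, rep(0L, 4))
  set.seed(47)
  for (i in 1:40) {
    n <- sample(6:30, 1)
    pooled <- round(runif(n), 1)
    labels <- c(0, 1, rbinom(n - 2, 1, 0.5))
    if (length(unique(pooled)) < 2) next
    bin <- binarize_activation(pooled, labels)
    u <- sort(unique(pooled))
    cand <- (u[-1] + u[-length(u)]) / 2
    best <- max(vapply(cand, function(th) {
      information_gain(as.integer(pooled > th), labels)
    }, numeric(1)))
    expect_equal(information_gain(bin$feature, labels), best,
                 tolerance = 1e-12)
  }
})

test_that("the IG-ratio summary is a capped geometric mean", {
  expect_equal(ig_ratio_summary(c(1, 1, 1)), 1.0)
  expect_equal(ig_ratio_summary(c(0.25, 1)), 0.5)
  expect_equal(ig_ratio_summary(c(4, 0.25)), 0.5)  # ratios capped at 1
  prof <- data.frame(ig_train = c(0.5, 1e-9, 0.2),
                     ig_test = c(0.25, 0.5, 0.4))
  # second filter ineligible; third capped: sqrt(0.5 * 1)
  expect_equal(ig_ratio_summary(prof), sqrt(0.5))
  empty <- data.frame(ig_train = 1e-9, ig_test = 0.5)
  expect_warning(r <- ig_ratio_summary(empty), "undefined")
  expect_true(is.na(r))
})

test_that("the permutation noise floor separates signal from noise filters", {
  set.seed(55)
  n <- 300
  y <- rbinom(n, 1, 0.4)
  pooled <- cbind(y + rnorm(n, 0, 0.05),          # near-perfect filter
                  matrix(runif(n * 6), n, 6))      # label-independent noise
  floor_ig <- ig_noise_floor(pooled, y, rng_seed = 3)
  expect_gt(floor_ig, 0)
  ig_of <- function(j) {
    bin <- binarize_activation(pooled[, j], y)
    information_gain(bin$feature, y)
  }
  expect_gt(ig_of(1), floor_ig)
  # most noise filters fall at or below the chance level
  noise_igs <- vapply(2:7, ig_of, numeric(1))
  expect_gte(sum(noise_igs <= floor_ig), 4)
})

test_that("a filter aligned with a word's embedding ranks that word first", {
  tab <- toy_embedding()
  lp <- toy_planted(6, 6, len = 7, seed = 12)
  p <- init_cnn_params(channel_spec(1, 1), d = 4, rng_seed = 1)
  p$W[[1]][] <- tab$vectors["sig", ]
  p$b[[1]][] <- 0
  fit <- structure(list(params = p, channels = p$channels, d = 4),
                   class = "note_cnn")
  ng <- top_filter_ngrams(fit, 1, 1, lp$tokens, tab, k = 5)
  expect_equal(ng$ngram[1], "sig")
  expect_gt(ng$n_argmax[1], 0)
})

test_that("a zero filter yields an empty ranking", {
  tab <- toy_embedding()
  lp <- toy_planted(3, 3, seed = 2)
  p <- init_cnn_params(channel_spec(1, 1), d = 4, rng_seed = 1)
  p$W[[1]][] <- 0; p$b[[1]][] <- 0
  fit <- structure(list(params = p, channels = p$channels, d = 4),
                   class = "note_cnn")
  ng <- top_filter_ngrams(fit, 1, 1, lp$tokens, tab, k = 5)
  expect_equal(nrow(ng), 0)
})

test_that("n-gram ranking matches an exhaustive window scan", {
  set.seed(19)
  tab <- toy_embedding()
  lp <- toy_planted(8, 8, len = 9, seed = 19)
  p <- init_cnn_params(channel_spec(2, 1), d = 4, rng_seed = 19)
  p$W[[1]][] <- rnorm(8)
  p$b[[1]][] <- 0.1
  fit <- structure(list(params = p, channels = p$channels, d = 4),
                   class = "note_cnn")
  ng <- top_filter_ngrams(fit, 1, 1, lp$tokens, tab, k = 100)
  # brute force: activation of every distinct 2-gram window
  acts <- list()
  for (tk in lp$tokens) {
    tk <- tk[tk %in% rownames(tab$vectors)]
    if (length(tk) < 2) next
    for (t in seq_len(length(tk) - 1)) {
      g <- paste(tk[t], tk[t + 1])
      a <- max(sum(c(tab$vectors[tk[t], ], tab$vectors[tk[t + 1], ]) *
                     p$W[[1]][1, ]) + 0.1, 0)
      acts[[g]] <- max(acts[[g]] %||% -Inf, a)
    }
  }
  acts <- unlist(acts)
  acts <- sort(acts[acts > 0], decreasing = TRUE)
  expect_equal(ng$ngram[1], names(acts)[1])
  expect_equal(ng$activation, unname(acts[ng$ngram]), tolerance = 1e-12)
})

test_that("filter profiles carry per-filter IG and capped ratios", {
  lp <- toy_planted(10, 10, len = 8, seed = 33)
  cfg <- training_config(batch_size = 20, max_iterations = 80,
                         early_stop_window = 40, dropout_rate = 0.2,
                         rng_seed = 5)
  fit <- note_cnn(lp$enc, lp$y, channels = channel_spec(1:2, c(3, 2)),
                  config = cfg)
  prof <- filter_profiles(fit, lp$enc, lp$y, lp$enc, lp$y)
  expect_equal(nrow(prof), 5L)
  expect_true(all(prof$ig_train >= 0))
  hc <- entropy_bits(table(lp$y))
  expect_true(all(prof$ig_train <= hc + 1e-12))
  ok <- !is.na(prof$ig_ratio)
  expect_true(all(prof$ig_ratio[ok] <= 1))
  # identical train/test data: every eligible ratio is exactly 1
  expect_true(all(abs(prof$ig_ratio[ok] - 1) < 1e-12))
})
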