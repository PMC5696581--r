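test_that("default channel geometry pools 100 features", {
  p <- init_cnn_params(channel_spec(), d = 50, rng_seed = 1)
  expect_equal(n_pooled_features(p), 100L)
  expect_equal(dim(p$W[[1]]), c(40L, 50L))
  expect_equal(dim(p$W[[5]]), c(5L, 250L))
  p1 <- init_cnn_params(channel_spec(1, 1), d = 2, rng_seed = 1)
  expect_equal(dim(p1$W[[1]]), c(1L, 2L))
  # deterministic given the seed
  pa <- init_cnn_params(channel_spec(), 10, rng_seed = 42)
  pb <- init_cnn_params(channel_spec(), 10, rng_seed = 42)
  expect_identical(pa, pb)
  expect_true(all(abs(unlist(pa$W)) <= 0.05))
  expect_true(all(unlist(pa$b) == 0))
})

test_that("forward pass matches hand-computed single-filter cases", {
  p <- init_cnn_params(channel_spec(1, 1), d = 2, rng_seed = 1)
  p$W[[1]][] <- c(1, 0); p$b[[1]][] <- 0; p$w_out <- 1; p$b_out <- 0
  M <- matrix(c(1, 0, 0, 1, 2, 0), 3, 2, byrow = TRUE)
  fw <- cnn_forward(M, p)
  expect_equal(as.numeric(fw$pooled), 2)
  expect_equal(fw$prob, 1 / (1 + exp(-2)), tolerance = 1e-12)
  expect_equal(fw$prob, 0.8808, tolerance = 1e-4)

  p2 <- init_cnn_params(channel_spec(2, 1), d = 2, rng_seed = 1)
  p2$W[[1]][] <- c(1, 1, 1, 1); p2$b[[1]][] <- -1; p2$w_out <- 1; p2$b_out <- 0
  expect_equal(as.numeric(cnn_forward(M, p2)$pooled), 2)

  pz <- init_cnn_params(channel_spec(), d = 4, rng_seed = 1)
  for (c in seq_along(pz$W)) pz$W[[c]][] <- 0
  pz$w_out[] <- 0; pz$b_out <- 0
  Mz <- matrix(rnorm(20), 5, 4)
  expect_equal(cnn_forward(Mz, pz)$prob, 0.5)
})

test_that("forward pass agrees with the nested-loop oracle", {
  for (seed in 1:25) {
    inst <- random_cnn_instance(seed)
    fw <- cnn_forward(inst$M, inst$params)
    oc <- oracle_forward(inst$M, inst$params)
    expect_equal(as.numeric(fw$pooled), oc$pooled, tolerance = 1e-12)
    expect_equal(fw$prob, oc$prob, tolerance = 1e-12)
  }
})

test_that("a note shorter than the tallest filter is a contract violation", {
  p <- init_cnn_params(channel_spec(3, 1), d = 2, rng_seed = 1)
  expect_error(cnn_forward(matrix(0, 2, 2), p), "fewer rows")
})

test_that("cross-entropy loss matches its closed form plus L2 penalty", {
  expect_equal(cnn_loss(0.5, 1), log(2), tolerance = 1e-12)
  expect_equal(cnn_loss(1 - 1e-12, 1), 0, tolerance = 1e-9)
  expect_equal(cnn_loss(1e-20, 1), -log(1e-12), tolerance = 1e-6)
  set.seed(8)
  p <- init_cnn_params(channel_spec(c(1, 2), c(3, 2)), d = 3, rng_seed = 8)
  l2 <- 0.01
  expected_pen <- 0.5 * l2 * (sum(unlist(p$W)^2) + sum(p$w_out^2))
  expect_equal(cnn_loss(0.5, 1, p, l2), log(2) + expected_pen,
               tolerance = 1e-12)
})

test_that("analytic gradients match central differences", {
  for (seed in c(2, 5, 9)) {
    set.seed(seed)
    notes <- lapply(1:3, function(i) matrix(rnorm(6 * 3), 6, 3))
    p <- init_cnn_params(channel_spec(c(1, 2), c(2, 2)), d = 3,
                         rng_seed = seed)
    y <- c(1, 0, 1)
    l2 <- 0.001
    g <- icdcnn:::cpp_cnn_grad(notes, p$W, p$b, p$channels$h, p$w_out,
                               p$b_out, y, NULL, l2)
    ana <- c(unlist(g$gW), unlist(g$gb), g$g_wout, g$g_bout)
    pack <- function(par) {
      q <- p
      i <- 0
      for (c in seq_along(q$W)) {
        k <- length(q$W[[c]]); q$W[[c]][] <- par[i + seq_len(k)]; i <- i + k
      }
      for (c in seq_along(q$b)) {
        k <- length(q$b[[c]]); q$b[[c]][] <- par[i + seq_len(k)]; i <- i + k
      }
      k <- length(q$w_out); q$w_out <- par[i + seq_len(k)]; i <- i + k
      q$b_out <- par[i + 1]
      q
    }
    par0 <- c(unlist(p$W), unlist(p$b), p$w_out, p$b_out)
    lossfun <- function(par) {
      q <- pack(par)
      cnn_loss(cnn_forward(notes, q)$prob, y, q, l2)
    }
    num <- vapply(seq_along(par0), function(j) {
      h <- 1e-6
      up <- par0; up[j] <- up[j] + h
      dn <- par0; dn[j] <- dn[j] - h
      (lossfun(up) - lossfun(dn)) / (2 * h)
    }, numeric(1))
    expect_lt(max(abs(num - ana) / pmax(abs(num), 1e-8)), 1e-4)
    expect_equal(g$loss, lossfun(par0), tolerance = 1e-12)
  }
})

test_that("training reduces the loss on a separable planted-keyword set", {
  lp <- toy_planted(5, 5, seed = 4)
  cfg <- training_config(batch_size = 10, max_iterations = 150,
                         early_stop_window = 50, dropout_rate = 0.2,
                         validation_fraction = 0, rng_seed = 2)
  fit <- note_cnn(lp$enc, lp$y, channels = channel_spec(1:2, c(4, 2)),
                  config = cfg)
  traj <- fit$history$monitored_loss
  expect_lt(traj[length(traj)], traj[1])
  pr <- predict(fit, lp$enc)
  expect_true(all(pr > 0 & pr < 1))
  expect_gt(mean(pr[lp$y == 1]), mean(pr[lp$y == 0]))
  expect_identical(pr, predict(fit, lp$enc))
})

test_that("constant monitored loss stops after exactly one window", {
  lp <- toy_planted(5, 5, seed = 6)
  cfg <- training_config(batch_size = 10, learning_rate = 1e-30,
                         max_iterations = 500, early_stop_window = 100,
                         dropout_rate = 0, rng_seed = 1)
  fit <- note_cnn(lp$enc, lp$y, channels = channel_spec(1, 2), config = cfg)
  expect_equal(fit$iterations, 100L)
  expect_true(fit$converged)
})

test_that("a single-class corpus is refused", {
  lp <- toy_planted(5, 5, seed = 6)
  expect_error(note_cnn(lp$enc, rep(1, 10)), "single class")
})

test_that("forward is invariant to extra pad rows when biases are <= 0", {
  inst <- random_cnn_instance(13)
  p <- inst$params
  for (c in seq_along(p$b)) p$b[[c]][] <- -abs(p$b[[c]])
  M <- inst$M
  M_pad <- rbind(M, matrix(0, 4, ncol(M)))
  expect_equal(cnn_forward(M, p)$prob, cnn_forward(M_pad, p)$prob,
               tolerance = 1e-12)
})

test_that("strong L2 shrinks weights and pushes probabilities toward 1/2", {
  lp <- toy_planted(5, 5, seed = 3)
  base <- training_config(batch_size = 10, max_iterations = 100,
                          early_stop_window = 100, dropout_rate = 0,
                          validation_fraction = 0, rng_seed = 7)
  weak <- base; weak$l2 <- 1e-5
  strong <- base; strong$l2 <- 10
  ch <- channel_spec(1, 3)
  f_weak <- note_cnn(lp$enc, lp$y, channels = ch, config = weak)
  f_strong <- note_cnn(lp$enc, lp$y, channels = ch, config = strong)
  norm_of <- function(f) sqrt(sum(unlist(f$params$W)^2) + sum(f$params$w_out^2))
  expect_lt(norm_of(f_strong), norm_of(f_weak))
  expect_lt(max(abs(predict(f_strong, lp$enc) - 0.5)),
            max(abs(predict(f_weak, lp$enc) - 0.5)) + 1e-9)
  expect_lt(max(abs(predict(f_strong, lp$enc) - 0.5)), 0.05)
})

test_that("checkpoints round-trip through JSON", {
  lp <- toy_planted(4, 4, seed = 5)
  cfg <- training_config(batch_size = 8, max_iterations = 40,
                         early_stop_window = 20, rng_seed = 3)
  fit <- note_cnn(lp$enc, lp$y, channels = channel_spec(1:2, c(3, 2)),
                  config = cfg)
  path <- withr::local_tempfile(fileext = ".json")
  write_cnn(fit, path)
  back <- read_cnn(path)
  expect_equal(back$params$W, fit$params$W, tolerance = 1e-12)
  expect_equal(back$params$w_out, fit$params$w_out, tolerance = 1e-12)
  expect_equal(predict(back, lp$enc), predict(fit, lp$enc), tolerance = 1e-12)
  expect_error(read_cnn(withr::local_tempfile(fileext = ".json")))
})
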