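# Independent oracles used to validate the fast implementations.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Nested-loop CNN forward pass: convolution, ReLU, max pool, logistic.
oracle_forward <- function(M, params) {
  pooled <- numeric(0)
  for (c in seq_len(nrow(params$channels))) {
    h <- params$channels$h[c]
    W <- params$W[[c]]; b <- params$b[[c]]
    d <- ncol(M)
    nw <- nrow(M) - h + 1
    for (f in seq_len(nrow(W))) {
      acts <- numeric(nw)
      for (t in seq_len(nw)) {
        s <- 0
        for (o in 0:(h - 1)) {
          for (j in seq_len(d)) s <- s + M[t + o, j] * W[f, o * d + j]
        }
        acts[t] <- max(s + b[f], 0)
      }
      pooled <- c(pooled, max(acts))
    }
  }
  logit <- sum(pooled * params$w_out) + params$b_out
  list(prob = 1 / (1 + exp(-logit)), pooled = pooled)
}

# Brute-force Mann-Whitney AUC over all positive-negative pairs.
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg) tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# Information gain from the contingency table of (feature, label).
oracle_ig <- function(feature, labels) {
  tab <- table(feature, labels)
  n <- sum(tab)
  ent <- function(counts) {
    p <- counts[counts > 0] / sum(counts)
    -sum(p * log2(p))
  }
  h_c <- ent(colSums(tab))
  h_cond <- sum(vapply(seq_len(nrow(tab)), function(r) {
    sum(tab[r, ]) / n * ent(tab[r, ])
  }, numeric(1)))
  h_c - h_cond
}

# A tiny embedding table with a planted "signal" direction.
toy_embedding <- function(d = 4) {
  vecs <- rbind(
    sig = c(1, rep(0, d - 1)),
    foo = c(0, 1, rep(0, d - 2)),
    bar = c(0, 0, 1, rep(0, d - 3)),
    baz = rep(1 / sqrt(d), d))
  structure(list(d = d, vectors = vecs), class = "embedding_table")
}

# Planted-keyword toy corpus: positives contain "sig", negatives do not.
toy_planted <- function(n_pos = 5, n_neg = 5, len = 6, seed = 1) {
  set.seed(seed)
  tab <- toy_embedding()
  vocab_neg <- c("foo", "bar", "baz")
  tokens <- c(
    lapply(seq_len(n_pos), function(i) {
      sample(c("sig", sample(vocab_neg, len - 1, replace = TRUE)))
    }),
    lapply(seq_len(n_neg), function(i) {
      sample(vocab_neg, len, replace = TRUE)
    }))
  y <- c(rep(1, n_pos), rep(0, n_neg))
  list(tokens = tokens, y = y, table = tab,
       enc = encode_corpus(tokens, tab))
}

# Small random parameter set + random note matrices for oracle sweeps.
random_cnn_instance <- function(seed, d = 3, n_max = 8) {
  set.seed(seed)
  channels <- channel_spec(heights = c(1, 2, 3), filters = c(2, 2, 1))
  p <- init_cnn_params(channels, d, rng_seed = seed)
  for (c in seq_along(p$W)) {
    p$W[[c]][] <- rnorm(length(p$W[[c]]))
    p$b[[c]][] <- rnorm(length(p$b[[c]]), 0, 0.3)
  }
  p$w_out <- rnorm(length(p$w_out))
  p$b_out <- rnorm(1)
  M <- matrix(rnorm(sample(3:n_max, 1) * d), ncol = d)
  list(params = p, M = M)
}

micro_spec <- function(seed = 1, ...) {
  args <- list(n_notes = 150L, n_labels = 2L, prevalences = c(0.4, 0.3),
               signal_words_per_label = 4L, p_signal = 0.6,
               background_vocab = 60L, note_length = c(8L, 16L),
               d = 8L, sigma = 0.1, rng_seed = seed)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(corpus_spec, args)
}
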