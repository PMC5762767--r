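# Independent oracles and fixture builders shared across the suite.

# --- naive O(N^2) metric implementations (pair enumeration) ---------------

naive_rank <- function(s, l) {
  1L + sum(s > s[l]) + sum(s == s[l] & seq_along(s) < l)
}

naive_coverage <- function(S, labels) {
  mean(vapply(seq_len(nrow(S)), function(i) {
    max(vapply(labels[[i]], function(l) naive_rank(S[i, ], l), integer(1)))
  }, integer(1))) - 1
}

naive_ranking_loss <- function(S, labels) {
  n <- ncol(S)
  mean(vapply(seq_len(nrow(S)), function(i) {
    y <- labels[[i]]; yb <- setdiff(seq_len(n), y)
    bad <- 0L
    for (a in y) for (b in yb) if (S[i, a] <= S[i, b]) bad <- bad + 1L
    bad / (length(y) * length(yb))
  }, numeric(1)))
}

naive_average_precision <- function(S, labels) {
  mean(vapply(seq_len(nrow(S)), function(i) {
    y <- labels[[i]]
    mean(vapply(y, function(l) {
      r <- naive_rank(S[i, ], l)
      sum(vapply(y, function(l2) naive_rank(S[i, ], l2) <= r,
                 logical(1))) / r
    }, numeric(1)))
  }, numeric(1)))
}

# random (scores, labels) draw with proper non-empty label sets
random_scored_dataset <- function(m, n) {
  S <- matrix(runif(m * n), m, n)
  # sprinkle ties so the tie-break path is exercised
  if (m > 1 && runif(1) < 0.3) S[1, ] <- round(S[1, ] * 4) / 4
  labels <- lapply(seq_len(m), function(i) {
    sort(sample.int(n, sample(seq_len(n - 1L), 1L)))
  })
  list(scores = S, labels = labels)
}

# --- finite-difference gradient oracles -----------------------------------

fd_gradient <- function(f, x, h = 1e-6) {
  vapply(seq_along(x), function(j) {
    xp <- x; xm <- x
    xp[j] <- xp[j] + h
    xm[j] <- xm[j] - h
    (f(xp) - f(xm)) / (2 * h)
  }, numeric(1))
}

rel_err <- function(a, b) {
  max(abs(a - b)) / max(1e-8, max(abs(a)), max(abs(b)))
}

# --- small dataset builders -----------------------------------------------

tiny_dataset <- function(m = 12, n = 3, d = 10, seed = 42) {
  generate_dataset(synthetic_spec(
    n_instances = m, n_labels = n, n_terms = d,
    signature_terms_per_label = max(1L, d %/% (2L * n)),
    labels_per_instance = seq_len(min(2, n - 1)),
    signal_strength = 4, background_rate = 0.2, seed = seed))
}

# --- R reference training loops (mirror the compiled path exactly) --------

ref_train_dae <- function(X, d_prime, epochs, lr, loss, v, seed) {
  m <- nrow(X); d <- ncol(X)
  p <- withr::with_seed(sdamll::stream_seed(seed, "init"),
                        dae_params(d, d_prime))
  orders <- withr::with_seed(sdamll::stream_seed(seed, "shuffle"),
                             sdamll:::shuffle_orders(m, epochs))
  masks <- withr::with_seed(sdamll::stream_seed(seed, "corrupt"),
                            sdamll:::corruption_masks(d, v, m, epochs))
  trace <- numeric(epochs)
  for (e in seq_len(epochs)) {
    for (t in seq_len(m)) {
      i <- orders[t, e]
      x <- X[i, ]
      xt <- x
      if (nrow(masks)) xt[masks[, (e - 1L) * m + t]] <- 0
      g <- sdamll:::dae_gradients(p, x, xt, loss)
      p$W <- p$W - lr * g$W
      p$b <- p$b - lr * g$b
      p$b_prime <- p$b_prime - lr * g$b_prime
    }
    Z <- decode_dae(p, encode_dae(p, X))
    trace[e] <- mean(vapply(seq_len(m), function(i) {
      reconstruction_loss(X[i, ], Z[i, ], loss)
    }, numeric(1)))
  }
  list(params = p, trace = trace)
}

ref_train_bpmll <- function(X, labels, n_labels, M, alpha, epochs, seed) {
  net <- withr::with_seed(sdamll::stream_seed(seed, "init"),
                          bpmll_network(ncol(X), M, n_labels))
  orders <- withr::with_seed(sdamll::stream_seed(seed, "shuffle"),
                             sdamll:::shuffle_orders(nrow(X), epochs))
  for (e in seq_len(epochs)) {
    for (t in seq_len(nrow(X))) {
      i <- orders[t, e]
      up <- bpmll_gradients(net, X[i, ], labels[[i]], alpha)
      net$V <- net$V + up$V
      net$W <- net$W + up$W
      net$gamma <- net$gamma + up$gamma
      net$theta <- net$theta + up$theta
    }
  }
  net
}
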