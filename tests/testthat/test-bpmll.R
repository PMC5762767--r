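zero_net <- function(d, M, n) {
  net <- withr::with_seed(1, bpmll_network(d, M, n))
  net$V[] <- 0; net$W[] <- 0
  net
}

test_that("forward pass matches direct sigmoid evaluation", {
  net <- zero_net(3, 2, 2)
  fw <- bpmll_forward(net, c(0.4, 0.2, 0.9))
  expect_equal(fw$hidden, c(0.5, 0.5))
  expect_equal(fw$output, c(0.5, 0.5))

  chain <- zero_net(1, 1, 2)
  chain$V[] <- 1; chain$W[, 1] <- 1
  fw <- bpmll_forward(chain, 1)
  expect_equal(fw$hidden, 0.7310586, tolerance = 1e-7)
  expect_equal(fw$output[1], plogis(plogis(1)), tolerance = 1e-12)
  expect_equal(fw$output[1], 0.6750375, tolerance = 1e-7)

  rnd <- withr::with_seed(3, bpmll_network(4, 3, 5))
  out <- bpmll_forward(rnd, runif(4))$output
  expect_true(all(out > 0 & out < 1))
  expect_error(bpmll_forward(rnd, runif(5)), "length 4")
})

test_that("instance error matches hand-computed pair sums", {
  expect_equal(bpmll_instance_error(c(0.8, 0.3), 1), exp(-0.5),
               tolerance = 1e-12)
  expect_equal(bpmll_instance_error(c(0.8, 0.3), 1), 0.6065307,
               tolerance = 1e-7)
  expect_equal(bpmll_instance_error(c(0.9, 0.7, 0.1), c(1, 2)),
               (exp(-0.8) + exp(-0.6)) / 2, tolerance = 1e-12)
  expect_equal(bpmll_instance_error(c(0.9, 0.7, 0.1), c(1, 2)),
               0.4990703, tolerance = 1e-7)
  # all outputs equal: every pair contributes exp(0) = 1
  expect_equal(bpmll_instance_error(rep(0.37, 5), c(2, 4)), 1)
})

test_that("degenerate label sets are rejected with explicit messages", {
  expect_error(bpmll_instance_error(c(0.5, 0.5), integer(0)), "empty Y")
  expect_error(bpmll_instance_error(c(0.5, 0.5), c(1, 2)),
               "full label universe")
  net <- withr::with_seed(2, bpmll_network(3, 2, 3))
  expect_error(bpmll_gradients(net, runif(3), integer(0)), "degenerate")
  expect_error(bpmll_gradients(net, runif(3), 1:3), "degenerate")
})

test_that("global error is additive and matches pair enumeration", {
  net <- withr::with_seed(4, bpmll_network(5, 3, 4))
  withr::with_seed(5, {
    X <- matrix(runif(30), 6, 5)
    labels <- lapply(1:6, function(i) sort(sample.int(4, sample(1:3, 1))))
  })
  E1 <- bpmll_global_error(net, X[1, , drop = FALSE], labels[1])
  expect_equal(as.numeric(E1),
               bpmll_instance_error(bpmll_forward(net, X[1, ])$output,
                                    labels[[1]]))
  Edup <- bpmll_global_error(net, X[c(1, 1), ], labels[c(1, 1)])
  expect_equal(as.numeric(Edup), 2 * as.numeric(E1), tolerance = 1e-12)

  # brute-force pair re-summation over all instances
  E <- as.numeric(bpmll_global_error(net, X, labels))
  brute <- 0
  for (i in 1:6) {
    cvec <- bpmll_forward(net, X[i, ])$output
    y <- labels[[i]]; yb <- setdiff(1:4, y)
    for (k in y) for (l in yb) {
      brute <- brute + exp(-(cvec[k] - cvec[l])) / (length(y) * length(yb))
    }
  }
  expect_equal(E, brute, tolerance = 1e-12)

  # full-label-set instances are skipped and counted
  labels[[2]] <- 1:4
  expect_message(E2 <- bpmll_global_error(net, X, labels), "skipping 1")
  expect_identical(attr(E2, "skipped"), 1L)
})

test_that("gradient updates match finite differences of the error", {
  withr::with_seed(6, {
    for (rep in 1:5) {
      d <- sample(2:5, 1); M <- sample(2:4, 1); n <- sample(3:6, 1)
      net <- bpmll_network(d, M, n)
      net$gamma <- rnorm(M, sd = 0.2); net$theta <- rnorm(n, sd = 0.2)
      x <- runif(d)
      Y <- sort(sample.int(n, sample(seq_len(n - 1), 1)))
      up <- bpmll_gradients(net, x, Y, alpha = 1)
      err_at <- function(vec) {
        q <- net
        q$V <- matrix(vec[seq_len(d * M)], d, M)
        q$W <- matrix(vec[d * M + seq_len(M * n)], M, n)
        q$gamma <- vec[d * M + M * n + seq_len(M)]
        q$theta <- vec[d * M + M * n + M + seq_len(n)]
        bpmll_instance_error(bpmll_forward(q, x)$output, Y)
      }
      theta0 <- c(as.vector(net$V), as.vector(net$W), net$gamma, net$theta)
      fd <- fd_gradient(err_at, theta0)
      # updates are alpha * (negative gradient)
      an <- -c(as.vector(up$V), as.vector(up$W), up$gamma, up$theta)
      expect_lt(rel_err(an, fd), 1e-5)
    }
  })
})

test_that("updates push relevant outputs up, irrelevant down, linearly in alpha", {
  net <- zero_net(2, 2, 2)            # symmetric: c_1 = c_2 = 0.5
  x <- c(0.3, 0.7)
  up <- bpmll_gradients(net, x, 1, alpha = 0.1)
  expect_gt(up$theta[1], 0)           # d_1 > 0
  expect_lt(up$theta[2], 0)           # d_2 < 0
  up2 <- bpmll_gradients(net, x, 1, alpha = 0.2)
  expect_equal(up2$theta, 2 * up$theta, tolerance = 1e-14)
  expect_equal(up2$V, 2 * up$V, tolerance = 1e-14)
  expect_equal(up2$W, 2 * up$W, tolerance = 1e-14)
})

test_that("raising a relevant output strictly decreases the instance error", {
  withr::with_seed(7, {
    cvec <- runif(5)
    Y <- c(2, 4)
    for (k in Y) {
      c2 <- cvec
      c2[k] <- c2[k] + 0.05
      expect_lt(bpmll_instance_error(c2, Y), bpmll_instance_error(cvec, Y))
    }
  })
})

test_that("error is invariant under joint relabeling", {
  net <- withr::with_seed(8, bpmll_network(4, 3, 5))
  withr::with_seed(9, {
    X <- matrix(runif(20), 5, 4)
    labels <- lapply(1:5, function(i) sort(sample.int(5, 2)))
    perm <- sample.int(5)
  })
  net2 <- net
  net2$W <- net$W[, perm]
  net2$theta <- net$theta[perm]
  labels2 <- lapply(labels, function(y) sort(match(y, perm)))
  expect_equal(as.numeric(bpmll_global_error(net, X, labels)),
               as.numeric(bpmll_global_error(net2, X, labels2)),
               tolerance = 1e-12)
})

test_that("training descends, is deterministic, and matches the R loop", {
  ds <- tiny_dataset(m = 40, n = 2, d = 8, seed = 13)
  fit <- train_bpmll(ds$features, ds$labels, n_labels = 2, M = 8,
                     alpha = 0.1, max_epochs = 15, patience = 15, seed = 3)
  expect_lt(fit$trace[length(fit$trace)], fit$trace[1])
  fit2 <- train_bpmll(ds$features, ds$labels, n_labels = 2, M = 8,
                      alpha = 0.1, max_epochs = 15, patience = 15, seed = 3)
  expect_identical(fit$trace, fit2$trace)
  expect_identical(fit$network$V, fit2$network$V)

  # compiled loop == R reference loop run for the same 2 epochs
  small <- tiny_dataset(m = 10, n = 3, d = 6, seed = 14)
  fitc <- train_bpmll(small$features, small$labels, n_labels = 3, M = 4,
                      alpha = 0.2, max_epochs = 2, patience = 99, seed = 5)
  ref <- ref_train_bpmll(small$features, small$labels, n_labels = 3, M = 4,
                         alpha = 0.2, epochs = 2, seed = 5)
  expect_equal(fitc$network$V, ref$V, tolerance = 1e-12)
  expect_equal(fitc$network$W, ref$W, tolerance = 1e-12)
  expect_equal(fitc$network$theta, ref$theta, tolerance = 1e-12)
})

test_that("stopping rule fires once E stops decreasing", {
  ds <- tiny_dataset(m = 15, n = 3, d = 6, seed = 15)
  # alpha = 0: E constant, so the first non-decrease (epoch 2) stops it
  fit <- train_bpmll(ds$features, ds$labels, n_labels = 3, M = 4,
                     alpha = 0, max_epochs = 50, patience = 1, seed = 1)
  expect_identical(fit$epochs_run, 2L)
  expect_equal(fit$trace[1], fit$trace[2], tolerance = 1e-14)
  expect_error(train_bpmll(ds$features, ds$labels, 3, alpha = 1),
               "alpha")
})

test_that("training is covariant under feature permutation", {
  ds <- tiny_dataset(m = 20, n = 3, d = 8, seed = 16)
  perm <- withr::with_seed(2, sample.int(8))
  fit1 <- train_bpmll(ds$features, ds$labels, 3, M = 4, alpha = 0.1,
                      max_epochs = 5, patience = 99, seed = 7)
  fit2 <- train_bpmll(ds$features[, perm], ds$labels, 3, M = 4, alpha = 0.1,
                      max_epochs = 5, patience = 99, seed = 7)
  # init is drawn feature-by-feature, so permuting columns permutes V rows
  # only if the init is also permuted; compare traces via a net transplant
  net1p <- fit1$network
  net1p$V <- net1p$V[perm, ]
  X <- ds$features[, perm]
  expect_equal(sdamll:::bpmll_scores(net1p, X),
               sdamll:::bpmll_scores(fit1$network, ds$features),
               tolerance = 1e-12)
  expect_length(fit2$trace, length(fit1$trace))
})

test_that("predict_scores and predict_labels honour their contracts", {
  net <- zero_net(3, 2, 4)
  rp <- predict_scores(net, matrix(runif(6), 2, 3))
  expect_true(all(rp$scores == 0.5))
  expect_identical(label_ranks(rp$scores[1, ]), 1:4)   # tie-break order

  rnd <- withr::with_seed(11, bpmll_network(3, 2, 4))
  X <- matrix(runif(9), 3, 3)
  s0 <- predict_scores(rnd, X)$scores
  expect_true(all(s0 > 0 & s0 < 1))
  rnd2 <- rnd
  rnd2$theta[2] <- rnd2$theta[2] + 0.5
  s1 <- predict_scores(rnd2, X)$scores
  expect_true(all(s1[, 2] > s0[, 2]))
  expect_equal(s1[, -2], s0[, -2], tolerance = 1e-14)

  rp2 <- ranked_prediction(rbind(c(0.9, 0.1), c(0.2, 0.3)))
  expect_identical(predict_labels(rp2)[[1]], 1L)
  expect_message(pl <- predict_labels(rp2), "empty label set")
  expect_length(pl[[2]], 0)
  rp3 <- ranked_prediction(matrix(c(0.3, 0.2, 0.1), 1))
  expect_identical(predict_labels(rp3, rule = "topk", t = 2)[[1]],
                   c(1L, 2L))
})
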