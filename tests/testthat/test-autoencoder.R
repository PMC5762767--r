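test_that("corrupt zeroes exactly floor(v*d) positions, others untouched", {
  withr::with_seed(1, {
    x <- c(0.2, 0.5, 0.9, 0.1)
    expect_identical(corrupt(x, 0), x)
    expect_identical(corrupt(x, 1), rep(0, 4))
    for (rep in 1:20) {
      out <- corrupt(x, 0.5)
      expect_identical(sum(out == 0), 2L)
      keep <- out != 0
      expect_identical(out[keep], x[keep])
    }
    expect_error(corrupt(x, 1.2), "\\[0, 1\\]")
  })
})

test_that("encode/decode match direct sigmoid evaluation", {
  p0 <- dae_params(3, 2, W = matrix(0, 2, 3))
  expect_equal(encode_dae(p0, c(0.1, 0.9, 0.4)), c(0.5, 0.5))
  expect_equal(decode_dae(p0, c(0.3, 0.8)), rep(0.5, 3))

  p1 <- dae_params(1, 1, W = matrix(1, 1, 1))
  expect_equal(encode_dae(p1, 1), 0.7310586, tolerance = 1e-7)
  pm <- dae_params(1, 1, W = matrix(-1, 1, 1))
  expect_equal(encode_dae(pm, 1), 0.2689414, tolerance = 1e-7)
  expect_equal(encode_dae(p1, 1) + encode_dae(pm, 1), 1)   # s(t)+s(-t)=1

  p2 <- dae_params(1, 1, W = matrix(2, 1, 1))
  expect_equal(decode_dae(p2, 0.5), 0.7310586, tolerance = 1e-7)

  p35 <- withr::with_seed(2, dae_params(5, 3))
  z <- decode_dae(p35, runif(3))
  expect_length(z, 5)
  expect_true(all(z > 0 & z < 1))
  expect_error(encode_dae(p35, runif(4)), "length 5")
})

test_that("reconstruction losses match closed forms", {
  x <- c(0.2, 0.8, 0.5)
  expect_equal(reconstruction_loss(x, x, "squared_error"), 0)
  expect_equal(reconstruction_loss(1, 0.5, "cross_entropy"),
               0.6931472, tolerance = 1e-7)
  expect_equal(reconstruction_loss(c(0, 1), c(0.5, 0.5), "cross_entropy"),
               1.3862944, tolerance = 1e-7)
  expect_message(reconstruction_loss(c(0, 1), c(0, 1), "cross_entropy"),
                 "clamping")
})

test_that("DAE gradients match central finite differences (both losses)", {
  withr::with_seed(5, {
    for (kind in c("cross_entropy", "squared_error")) {
      for (rep in 1:5) {
        d <- sample(3:6, 1); dp <- sample(2:4, 1)
        p <- dae_params(d, dp)
        p$b <- rnorm(dp, sd = 0.3); p$b_prime <- rnorm(d, sd = 0.3)
        x <- runif(d)
        xt <- x; xt[sample(d, 1)] <- 0
        g <- sdamll:::dae_gradients(p, x, xt, kind)
        loss_at <- function(vec) {
          q <- p
          q$W <- matrix(vec[seq_len(dp * d)], dp, d)
          q$b <- vec[dp * d + seq_len(dp)]
          q$b_prime <- vec[dp * d + dp + seq_len(d)]
          reconstruction_loss(x, decode_dae(q, encode_dae(q, xt)), kind)
        }
        theta <- c(as.vector(p$W), p$b, p$b_prime)
        fd <- fd_gradient(loss_at, theta)
        an <- c(as.vector(g$W), g$b, g$b_prime)
        expect_lt(rel_err(an, fd), 1e-5)
      }
    }
  })
})

test_that("train_dae descends on a fixed target and is deterministic", {
  X <- matrix(rep(c(0.9, 0.1, 0.8, 0.2, 0.7), 50), nrow = 50, byrow = TRUE)
  fit <- train_dae(X, d_prime = 3, epochs = 30, learning_rate = 0.3,
                   v = 0, seed = 4)
  expect_lt(fit$trace[30], fit$trace[1])

  fit2 <- train_dae(X, d_prime = 3, epochs = 30, learning_rate = 0.3,
                    v = 0, seed = 4)
  expect_identical(fit$params$W, fit2$params$W)
  expect_identical(fit$trace, fit2$trace)
})

test_that("compiled DAE training reproduces the R reference loop exactly", {
  withr::with_seed(8, {
    X <- matrix(runif(15 * 6), 15, 6)
  })
  for (kind in c("cross_entropy", "squared_error")) {
    fit <- train_dae(X, d_prime = 4, epochs = 3, learning_rate = 0.2,
                     loss = kind, v = 0.5, seed = 9)
    ref <- ref_train_dae(X, d_prime = 4, epochs = 3, lr = 0.2,
                         loss = kind, v = 0.5, seed = 9)
    expect_equal(fit$params$W, ref$params$W, tolerance = 1e-12)
    expect_equal(fit$params$b_prime, ref$params$b_prime, tolerance = 1e-12)
    expect_equal(fit$trace, ref$trace, tolerance = 1e-12)
  }
})

test_that("pretrain_stack is greedy, shape-correct, identity when empty", {
  withr::with_seed(3, {
    X <- matrix(runif(40), 8, 5)
  })
  empty <- pretrain_stack(X, layer_sizes = 5, seed = 1)
  expect_length(empty$layers, 0)
  expect_identical(sda_transform(empty, X), X)

  withr::with_seed(6, {
    B <- matrix(runif(40), 20, 2)
    X2 <- plogis(B %*% matrix(rnorm(2 * 20), 2, 20))    # rank-2 structure
  })
  st <- pretrain_stack(X2, layer_sizes = c(20, 10, 5), epochs = 3,
                       seed = 2)
  expect_length(st$traces, 2)
  expect_length(st$traces[[1]], 3)       # layer-1 trace complete
  expect_identical(dim(sda_transform(st, X2)), c(20L, 5L))
  expect_error(sda_transform(st, X2[, 1:7]), "expected 20")
})

test_that("transforming through two stacks equals the concatenated stack", {
  withr::with_seed(10, {
    X <- matrix(runif(60), 10, 6)
    s1 <- pretrain_stack(X, c(6, 4), epochs = 2, seed = 3)
    H <- sda_transform(s1, X)
    s2 <- pretrain_stack(H, c(4, 2), epochs = 2, seed = 4)
    concat <- structure(list(layers = c(s1$layers, s2$layers),
                             layer_sizes = c(6L, 4L, 2L)),
                        class = "stacked_encoder")
    expect_equal(sda_transform(s2, sda_transform(s1, X)),
                 sda_transform(concat, X), tolerance = 1e-14)
  })
})

test_that("denoising training beats the untrained net on corrupted input", {
  # data with redundant correlated columns: reconstruction from a corrupted
  # copy is learnable
  withr::with_seed(12, {
    base <- matrix(runif(60 * 3), 60, 3)
    X <- cbind(base, base, base) + matrix(runif(60 * 9, 0, 0.02), 60, 9)
    X[X > 1] <- 1
    p0 <- withr::with_seed(stream_seed(21, "init"), dae_params(9, 4))
    fit <- train_dae(X, d_prime = 4, epochs = 40, learning_rate = 0.3,
                     v = 1 / 3, seed = 21)
    loss_on_corrupted <- function(p) {
      mean(vapply(seq_len(nrow(X)), function(i) {
        xt <- corrupt(X[i, ], 1 / 3)
        reconstruction_loss(X[i, ], decode_dae(p, encode_dae(p, xt)))
      }, numeric(1)))
    }
    withr::with_seed(99, l_trained <- loss_on_corrupted(fit$params))
    withr::with_seed(99, l_init <- loss_on_corrupted(p0))
    expect_lt(l_trained, l_init)
  })
})

test_that("non-finite loss aborts with the learning rate named", {
  X <- matrix(runif(100), 10, 10)
  expect_error(train_dae(X, 4, epochs = 30, learning_rate = 1e308, v = 0,
                         seed = 1),
               "learning_rate")
})
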