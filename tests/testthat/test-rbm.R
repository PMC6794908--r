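test_that("energy matches hand arithmetic and a loop-based oracle", {
  zero <- rbm_model(2, 1, weight = matrix(0, 2, 1),
                    visible_bias = c(0, 0), hidden_bias = 0)
  expect_equal(rbm_energy(zero, c(1, 1), 1), 0)
  expect_equal(rbm_energy(zero, c(0, 1), 0), 0)

  m <- rbm_model(2, 1, weight = matrix(c(2, 0), 2, 1),
                 visible_bias = c(1, 0), hidden_bias = 0)
  expect_equal(rbm_energy(m, c(1, 1), 1), -3)

  tiny <- tiny_rbm(4, 3, seed = 21)
  set.seed(1)
  for (rep in 1:5) {
    v <- rbinom(4, 1, 0.5); h <- rbinom(3, 1, 0.5)
    e <- -sum(tiny$visible_bias * v) - sum(tiny$hidden_bias * h)
    for (i in 1:4) for (j in 1:3) e <- e - tiny$weight[i, j] * v[i] * h[j]
    expect_equal(rbm_energy(tiny, v, h), e)
  }
  expect_error(rbm_energy(tiny, c(1, 0), c(1, 0, 1)), "dimension")
})

test_that("exact partition matches closed forms and full enumeration", {
  zero <- rbm_model(2, 1, weight = matrix(0, 2, 1),
                    visible_bias = c(0, 0), hidden_bias = 0)
  expect_equal(exact_partition(zero), 8)

  beta <- 0.7
  one <- rbm_model(1, 0, weight = matrix(0, 1, 0),
                   visible_bias = beta, hidden_bias = numeric(0))
  expect_equal(exact_partition(one), 1 + exp(beta))

  tiny <- tiny_rbm(4, 3, seed = 5)
  z_loop <- 0
  for (vi in 0:15) for (hi in 0:7) {
    v <- as.integer(intToBits(vi))[1:4]
    h <- as.integer(intToBits(hi))[1:3]
    z_loop <- z_loop + exp(-rbm_energy(tiny, v, h))
  }
  expect_equal(exact_partition(tiny), z_loop, tolerance = 1e-12)

  expect_error(exact_partition(rbm_model(30, 10, seed = 1)), "refused")
})

test_that("normalization: exp(-E)/z sums to one on enumerable machines", {
  tiny <- tiny_rbm(5, 3, seed = 17)
  z <- exact_partition(tiny)
  total <- 0
  V <- expand.grid(rep(list(0:1), 5)); H <- expand.grid(rep(list(0:1), 3))
  for (a in seq_len(nrow(V))) for (b in seq_len(nrow(H))) {
    total <- total + exp(-rbm_energy(tiny, as.numeric(V[a, ]),
                                     as.numeric(H[b, ]))) / z
  }
  expect_equal(total, 1, tolerance = 1e-12)
})

test_that("logistic conditionals equal enumerated conditionals", {
  zero <- rbm_model(3, 2, weight = matrix(0, 3, 2),
                    visible_bias = rep(0, 3), hidden_bias = rep(0, 2))
  expect_equal(conditional_hidden(zero, c(1, 0, 1)), c(0.5, 0.5))
  expect_equal(conditional_visible(zero, c(1, 1)), rep(0.5, 3))

  sat <- rbm_model(2, 1, weight = matrix(0, 2, 1),
                   visible_bias = c(0, 0), hidden_bias = 30)
  expect_gt(conditional_hidden(sat, c(0, 0)), 1 - 1e-12)

  # Bayes-ratio oracle: P(h_j = 1 | v) from joint enumeration
  tiny <- tiny_rbm(4, 2, seed = 33)
  H <- as.matrix(expand.grid(rep(list(0:1), 2)))
  V <- as.matrix(expand.grid(rep(list(0:1), 4)))
  for (a in seq_len(nrow(V))) {
    v <- as.numeric(V[a, ])
    joint <- apply(H, 1, function(h) exp(-rbm_energy(tiny, v, as.numeric(h))))
    for (j in 1:2) {
      expect_equal(conditional_hidden(tiny, v)[j],
                   sum(joint[H[, j] == 1]) / sum(joint), tolerance = 1e-10)
    }
  }
})

test_that("negative log-likelihood matches direct enumeration", {
  zero <- rbm_model(6, 2, weight = matrix(0, 6, 2),
                    visible_bias = rep(0, 6), hidden_bias = rep(0, 2))
  v <- c(1, 0, 1, 1, 0, 0)
  expect_equal(negative_log_likelihood(zero, v), 6 * log(2))

  tiny <- tiny_rbm(4, 3, seed = 2)
  data <- random_binary_matrix(5, 4, seed = 6)
  z <- exact_partition(tiny)
  H <- as.matrix(expand.grid(rep(list(0:1), 3)))
  pv <- apply(data, 1, function(v) {
    sum(apply(H, 1, function(h) exp(-rbm_energy(tiny, v, as.numeric(h))))) / z
  })
  expect_equal(negative_log_likelihood(tiny, data), -mean(log(pv)),
               tolerance = 1e-10)
  expect_error(negative_log_likelihood(tiny, data[0, , drop = FALSE]),
               "no samples")
})

test_that("contrastive divergence learns and is deterministic", {
  target <- c(1, 0, 1, 1, 0, 0)
  data <- matrix(rep(target, 20), 20, 6, byrow = TRUE)
  init <- rbm_model(6, 2, seed = 4)
  fit <- train_rbm(data, n_hidden = 2, learning_rate = 0.1, epochs = 400,
                   seed = 4)
  expect_lt(negative_log_likelihood(fit, data),
            negative_log_likelihood(init, data))

  fit2 <- train_rbm(data, n_hidden = 2, learning_rate = 0.1, epochs = 400,
                    seed = 4)
  expect_identical(fit$weight, fit2$weight)
  expect_identical(fit$visible_bias, fit2$visible_bias)

  expect_error(train_rbm(matrix(numeric(0), 0, 5)), "no training data")
  expect_error(train_rbm(matrix(c(0, 2, 1), 1)), "invalid")
})

test_that("exact-gradient descent decreases the loss", {
  tiny <- tiny_rbm(5, 2, seed = 10, w_sd = 0.5)
  data <- random_binary_matrix(6, 5, seed = 3)
  nll0 <- negative_log_likelihood(tiny, data)
  g <- exact_gradient(tiny, data)
  lr <- 0.05
  tiny$weight <- tiny$weight + lr * g$dW
  tiny$visible_bias <- tiny$visible_bias + lr * g$db
  tiny$hidden_bias <- tiny$hidden_bias + lr * g$dc
  expect_lt(negative_log_likelihood(tiny, data), nll0)
})

test_that("Gibbs sampling is uniform for the zero machine and deterministic", {
  zero <- rbm_model(6, 2, weight = matrix(0, 6, 2),
                    visible_bias = rep(0, 6), hidden_bias = rep(0, 2))
  s <- gibbs_sample(zero, n_total = 4000, n_keep = 2000, seed = 12)
  means <- colMeans(s$samples)
  sigma <- sqrt(0.25 / 2000)
  expect_true(all(abs(means - 0.5) < 3 * sigma))

  s2 <- gibbs_sample(zero, n_total = 4000, n_keep = 2000, seed = 12)
  expect_identical(s$samples, s2$samples)
  expect_error(gibbs_sample(zero, 100, 200), "n_keep")
  expect_error(gibbs_sample(zero, 100, 50, init = c(1, 0)), "dimension")
})

test_that("the Gibbs chain leaves the exact visible distribution stationary", {
  tiny <- tiny_rbm(4, 2, seed = 14, w_sd = 0.6)
  dist <- exact_visible_distribution(tiny)
  V <- dist$states
  H <- as.matrix(expand.grid(rep(list(0:1), 2)))
  # transition kernel P(v' | v) = sum_h P(h | v) P(v' | h)
  K <- matrix(0, nrow(V), nrow(V))
  for (a in seq_len(nrow(V))) {
    ph <- conditional_hidden(tiny, as.numeric(V[a, ]))
    for (hb in seq_len(nrow(H))) {
      h <- as.numeric(H[hb, ])
      p_h <- prod(ifelse(h == 1, ph, 1 - ph))
      pv <- conditional_visible(tiny, h)
      for (b in seq_len(nrow(V))) {
        vb <- as.numeric(V[b, ])
        K[a, b] <- K[a, b] + p_h * prod(ifelse(vb == 1, pv, 1 - pv))
      }
    }
  }
  expect_equal(as.numeric(dist$prob %*% K), dist$prob, tolerance = 1e-10)
})

test_that("contact_weight averages samples into a symmetric template", {
  v <- flatten_map(random_symmetric_map(5, seed = 2, p = 0.4))
  fixed <- matrix(rep(v, 4), 4, length(v), byrow = TRUE)
  w <- contact_weight(fixed, template_size = 5)
  expect_equal(unclass(w)[, ], unclass(unflatten_map(v, 5))[, ],
               ignore_attr = TRUE)

  two <- fixed[1:2, ]
  flip <- which(two[1, ] == 0)[1]
  two[2, flip] <- 1
  w2 <- contact_weight(two, template_size = 5)
  expect_equal(max(abs(w2 - t(w2))), 0)
  expect_equal(unname(diag(w2)), rep(0, 5))
  # exactly the flipped bit (mirrored) moves to 0.5; everything else is shared
  diffs <- which(w2 != unclass(unflatten_map(v, 5)))
  expect_length(diffs, 2L)
  expect_equal(unique(w2[diffs]), 0.5)
  expect_error(contact_weight(fixed[0, , drop = FALSE]), "no samples")
})
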