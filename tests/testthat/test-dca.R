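toy_msa <- function(rows) new_msa_for_test(rows)

new_msa_for_test <- function(rows) {
  read_msa(paste0(">s", seq_along(rows), "\n", rows, collapse = "\n"))
}

test_that("gap filtering removes rows with more than 50% gaps", {
  aln <- toy_msa(c("ACGU", "A---", "AC--", "----"))
  kept <- preprocess_msa(aln)
  expect_equal(kept$rows, c("ACGU", "AC--"))   # 75% and 100% dropped, 50% kept
  expect_error(preprocess_msa(toy_msa(c("A---", "----"))), "empty after filtering")

  set.seed(20)
  rows <- replicate(30, paste(sample(c("A", "C", "G", "U", "-"), 10,
                                     replace = TRUE, prob = c(1, 1, 1, 1, 3)),
                              collapse = ""))
  aln <- toy_msa(rows)
  gapfrac <- vapply(strsplit(rows, ""), function(x) mean(x == "-"), numeric(1))
  if (any(gapfrac <= 0.5)) {
    expect_equal(preprocess_msa(aln)$rows, rows[gapfrac <= 0.5])
  }
})

test_that("sequence weights equal brute-force neighbour counting", {
  same <- toy_msa(rep("ACGUA", 4))
  w <- sequence_weights(same)
  expect_equal(as.numeric(w), rep(0.25, 4))
  expect_equal(attr(w, "n_effective"), 1)

  distinct <- toy_msa(c("AAAA", "CCCC", "GGGG", "UUUU"))
  expect_equal(as.numeric(sequence_weights(distinct)), rep(1, 4))

  set.seed(31)
  rows <- replicate(20, paste(sample(c("A", "C"), 8, replace = TRUE),
                              collapse = ""))
  aln <- toy_msa(rows)
  w <- sequence_weights(aln, identity_threshold = 0.75)
  chars <- do.call(rbind, strsplit(rows, ""))
  for (s in 1:20) {
    nb <- sum(vapply(1:20, function(t)
      mean(chars[s, ] == chars[t, ]) >= 0.75, logical(1)))
    expect_equal(as.numeric(w[s]), 1 / nb)
  }
})

test_that("frequencies interpolate between empirical and uniform", {
  single <- toy_msa("AAAA")
  fm0 <- msa_frequencies(single, pseudocount_weight = 0)
  expect_equal(fm0$f_single[, 1], rep(1, 4))

  fm1 <- msa_frequencies(single, pseudocount_weight = 0.999)
  expect_true(all(abs(fm1$f_single - 0.2) < 1e-3))
  expect_error(msa_frequencies(single, pseudocount_weight = 1.2),
               "invalid pseudocount")
})

test_that("weighted frequencies match the direct summation oracle", {
  set.seed(12)
  rows <- replicate(15, paste(sample(c("A", "C", "G", "U", "-"), 6,
                                     replace = TRUE), collapse = ""))
  aln <- toy_msa(rows)
  w <- runif(15, 0.2, 1)
  lam <- 0.5
  fm <- msa_frequencies(aln, weights = w, pseudocount_weight = lam)
  chars <- do.call(rbind, strsplit(rows, ""))
  alph <- c("A", "C", "G", "U", "-")
  neff <- sum(w)
  for (i in c(1, 4, 6)) {
    for (a in 1:5) {
      emp <- sum(w * (chars[, i] == alph[a])) / neff
      expect_equal(fm$f_single[i, a], (1 - lam) * emp + lam / 5,
                   tolerance = 1e-12)
    }
  }
  for (pair in list(c(1, 2), c(3, 6))) {
    i <- pair[1]; j <- pair[2]
    for (a in 1:5) for (b in 1:5) {
      emp <- sum(w * (chars[, i] == alph[a] & chars[, j] == alph[b])) / neff
      expect_equal(fm$f_pair[i, j, a, b], (1 - lam) * emp + lam / 25,
                   tolerance = 1e-12)
    }
  }
})

test_that("pair marginals reproduce single frequencies exactly", {
  set.seed(13)
  rows <- replicate(12, paste(sample(c("A", "C", "G", "U", "-"), 5,
                                     replace = TRUE), collapse = ""))
  fm <- msa_frequencies(toy_msa(rows), pseudocount_weight = 0.3)
  L <- 5
  for (i in 1:L) for (j in 1:L) {
    expect_equal(rowSums(fm$f_pair[i, j, , ]), fm$f_single[i, ],
                 tolerance = 1e-12)
    expect_equal(colSums(fm$f_pair[i, j, , ]), fm$f_single[j, ],
                 tolerance = 1e-12)
  }
})

# analytically independent columns: f_ij = f_i f_j exactly
independent_freq_model <- function(f_list) {
  L <- length(f_list); q <- 5
  f_single <- do.call(rbind, f_list)
  f_pair <- array(0, dim = c(L, L, q, q))
  for (i in 1:L) for (j in 1:L) {
    f_pair[i, j, , ] <- if (i == j) diag(f_list[[i]], q, q)
    else outer(f_list[[i]], f_list[[j]])
  }
  structure(list(f_single = f_single, f_pair = f_pair,
                 sequence_weights = rep(1, 10), n_effective = 10,
                 pseudocount_weight = 0),
            class = "freq_model")
}

test_that("independent columns give zero couplings and zero DI", {
  set.seed(40)
  f_list <- lapply(1:4, function(i) {
    p <- runif(5, 0.5, 1.5); p / sum(p)
  })
  fm <- independent_freq_model(f_list)
  cm <- mean_field_couplings(fm)
  for (i in 1:3) for (j in (i + 1):4) {
    expect_lt(max(abs(cm$e[i, j, , ])), 1e-8)
  }
  di <- direct_information(fm, cm, tol = 1e-10)
  expect_lt(max(abs(di)), 1e-9)
})

test_that("two-column couplings match direct block inversion", {
  set.seed(41)
  # a correlated 2-column joint with full support
  J <- matrix(runif(25, 0.5, 2), 5, 5)
  J <- J / sum(J)
  fi <- rowSums(J); fj <- colSums(J)
  fm <- structure(list(
    f_single = rbind(fi, fj),
    f_pair = {
      fp <- array(0, dim = c(2, 2, 5, 5))
      fp[1, 1, , ] <- diag(fi, 5, 5); fp[2, 2, , ] <- diag(fj, 5, 5)
      fp[1, 2, , ] <- J; fp[2, 1, , ] <- t(J)
      fp
    },
    sequence_weights = rep(1, 10), n_effective = 10, pseudocount_weight = 0),
    class = "freq_model")
  cm <- mean_field_couplings(fm)
  # independent assembly of the 8x8 correlation matrix and its inverse
  C11 <- diag(fi[1:4], 4, 4) - outer(fi[1:4], fi[1:4])
  C22 <- diag(fj[1:4], 4, 4) - outer(fj[1:4], fj[1:4])
  C12 <- J[1:4, 1:4] - outer(fi[1:4], fj[1:4])
  Cfull <- rbind(cbind(C11, C12), cbind(t(C12), C22))
  inv <- solve(Cfull)
  expect_equal(cm$e[1, 2, 1:4, 1:4], -inv[1:4, 5:8], tolerance = 1e-8)
})

test_that("two-site fit satisfies its defining constraints", {
  set.seed(42)
  fi <- runif(5, 0.5, 1.5); fi <- fi / sum(fi)
  fj <- runif(5, 0.5, 1.5); fj <- fj / sum(fj)

  # zero couplings: joint is exactly the product of marginals
  fit0 <- rnadirect:::two_site_fit(matrix(1, 5, 5), fi, fj, tol = 1e-12)
  expect_equal(fit0$P, outer(fi, fj), tolerance = 1e-9)

  for (rep in 1:5) {
    e <- matrix(rnorm(25, sd = 0.8), 5, 5)
    e[5, ] <- 0; e[, 5] <- 0
    fit <- rnadirect:::two_site_fit(exp(e), fi, fj, tol = 1e-10)
    expect_lt(max(abs(rowSums(fit$P) - fi)), 1e-9)
    expect_lt(max(abs(colSums(fit$P) - fj)), 1e-9)
    # P must have the Boltzmann form exp(e + h_i + h_j) / Z: the ratio
    # P / exp(e) is a rank-one outer product
    R <- fit$P / exp(e)
    expect_lt(max(abs(R - outer(R[, 1], R[1, ] / R[1, 1]))), 1e-6)
  }
})

test_that("direct information recovers closed forms and the summation oracle", {
  # perfectly correlated uniform two-state pair
  P <- matrix(0, 5, 5); P[1, 1] <- P[2, 2] <- 0.5
  fi <- c(0.5, 0.5, 0, 0, 0)
  expect_equal(di_pair(P, fi, fi), log(2))

  set.seed(43)
  for (rep in 1:10) {
    fi <- runif(5, 0.5, 1.5); fi <- fi / sum(fi)
    fj <- runif(5, 0.5, 1.5); fj <- fj / sum(fj)
    e <- matrix(rnorm(25, sd = 0.6), 5, 5); e[5, ] <- 0; e[, 5] <- 0
    fit <- rnadirect:::two_site_fit(exp(e), fi, fj, tol = 1e-10)
    brute <- 0
    for (a in 1:5) for (b in 1:5) {
      brute <- brute + fit$P[a, b] * log(fit$P[a, b] / (fi[a] * fj[b]))
    }
    expect_equal(di_pair(fit$P, fi, fj), brute, tolerance = 1e-12)
    expect_gte(di_pair(fit$P, fi, fj), -1e-12)
  }
})

test_that("DI is non-negative, symmetric and deterministic on real input", {
  aln <- synth_msa(NULL, rbind(c(2, 9), c(4, 12)), n_sequences = 120,
                   coupling_strength = 2, gap_rate = 0.05, seed = 3,
                   length = 14)
  r1 <- dca(aln)
  r2 <- dca(aln)
  expect_identical(unclass(r1$di)[, ], unclass(r2$di)[, ])
  expect_equal(unclass(r1$di), t(unclass(r1$di)), tolerance = 1e-12)
  expect_true(all(r1$di > -1e-12))
})

test_that("independent alignments give vanishing DI; planted pairs stand out", {
  aln_ind <- synth_msa(NULL, matrix(integer(0), 0, 2), n_sequences = 2000,
                       coupling_strength = 0, gap_rate = 0, seed = 8,
                       length = 12)
  di_ind <- dca(aln_ind)$di
  expect_lt(max(di_ind), 0.05)

  pairs <- rbind(c(1, 8), c(2, 10), c(3, 12))
  aln_pl <- synth_msa(NULL, pairs, n_sequences = 400, coupling_strength = 3,
                      gap_rate = 0.05, seed = 9, length = 14)
  di_pl <- unclass(dca(aln_pl)$di)
  planted_mean <- mean(di_pl[pairs])
  mask <- upper.tri(di_pl)
  mask[pairs] <- FALSE
  expect_gt(planted_mean, mean(di_pl[mask]))
})
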