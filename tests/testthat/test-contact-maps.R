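test_that("distance_matrix takes the minimum over heavy-atom pairs", {
  ch <- point_chain(rbind(c(0, 0, 0), c(3, 4, 0)))
  expect_equal(distance_matrix(ch)[1, 2], 5)

  # residue i has two atoms at distances 9 and 7 from residue j's atom
  resi <- list(number = 1, insert = "", name = "A",
               atoms = rbind(P = c(9, 0, 0), `C4'` = c(7, 0, 0)))
  resj <- list(number = 2, insert = "", name = "U",
               atoms = rbind(P = c(0, 0, 0)))
  ch2 <- structure(list(chain_id = "A", residues = list(resi, resj)),
                   class = "structure_chain")
  expect_equal(distance_matrix(ch2)[1, 2], 7)
})

test_that("distance_matrix equals the brute-force double loop", {
  ch <- synth_structure(6, seed = 8)
  d <- distance_matrix(ch)
  for (i in 1:6) for (j in 1:6) {
    best <- Inf
    for (a in seq_len(nrow(ch$residues[[i]]$atoms))) {
      for (b in seq_len(nrow(ch$residues[[j]]$atoms))) {
        best <- min(best, sqrt(sum((ch$residues[[i]]$atoms[a, ] -
                                      ch$residues[[j]]$atoms[b, ])^2)))
      }
    }
    if (i == j) expect_equal(d[i, j], 0) else expect_equal(d[i, j], best)
  }
})

test_that("contact_map applies strict cutoff and separation rules", {
  d <- matrix(20, 10, 10); diag(d) <- 0
  d[1, 6] <- d[6, 1] <- 7.99   # sep 5
  d[2, 7] <- d[7, 2] <- 8.0    # boundary: not a contact
  d[3, 7] <- d[7, 3] <- 2.0    # sep 4: excluded
  m <- contact_map(d, cutoff = 8, min_separation = 4)
  expect_equal(m[1, 6], 1L)
  expect_equal(m[2, 7], 0L)
  expect_equal(m[3, 7], 0L)
  expect_error(contact_map(d, cutoff = -1), "invalid cutoff")

  # brute-force elementwise oracle, min_separation = 0
  set.seed(11)
  dr <- matrix(runif(100, 0, 16), 10, 10); dr <- (dr + t(dr)) / 2; diag(dr) <- 0
  m0 <- contact_map(dr, cutoff = 8, min_separation = 0)
  for (i in 1:10) for (j in 1:10) {
    expect_equal(m0[i, j], as.integer(i != j && dr[i, j] < 8))
  }
})

test_that("raising the cutoff never removes a contact", {
  set.seed(4)
  d <- matrix(runif(400, 0, 20), 20, 20); d <- (d + t(d)) / 2; diag(d) <- 0
  lo <- contact_map(d, cutoff = 6)
  hi <- contact_map(d, cutoff = 12)
  expect_true(all(hi[lo == 1L] == 1L))
})

test_that("resize is identity at equal size and preserves constants", {
  set.seed(2)
  d <- matrix(runif(36), 6, 6); d <- (d + t(d)) / 2
  expect_equal(resize_distance_matrix(d, 6), unname(d))
  cst <- matrix(3.3, 8, 8)
  expect_true(all(abs(resize_distance_matrix(cst, 20) - 3.3) < 1e-12))
})

test_that("resize doubles feature coordinates when upscaling 50 to 100", {
  d <- matrix(25, 50, 50); diag(d) <- 0
  block <- expand.grid(i = 20:22, j = 4:6)
  d[cbind(block$i, block$j)] <- 4
  d[cbind(block$j, block$i)] <- 4
  r <- resize_distance_matrix(d, 100)
  # separation filter removes the near-diagonal band where interpolation
  # mixes in the zero diagonal
  m <- contact_map(r, cutoff = 8, min_separation = 4)
  hits <- which(unclass(m) == 1L & row(m) > col(m), arr.ind = TRUE)
  expect_gt(nrow(hits), 0)
  # all thresholded contacts sit near the doubled source coordinates
  expect_true(all(hits[, 1] >= 2 * 20 - 3 & hits[, 1] <= 2 * 22 + 3))
  expect_true(all(hits[, 2] >= 2 * 4 - 3 & hits[, 2] <= 2 * 6 + 3))
})

test_that("resize commutes with transpose", {
  set.seed(9)
  d <- matrix(runif(64), 8, 8)   # deliberately non-symmetric input
  expect_equal(resize_distance_matrix(t(d), 13),
               t(resize_distance_matrix(d, 13)), tolerance = 1e-12)
})

test_that("flatten/unflatten round-trips with the documented length", {
  expect_length(flatten_map(matrix(0L, 100, 100)), 4950L)
  expect_true(all(flatten_map(matrix(0L, 10, 10)) == 0L))
  for (s in 1:20) {
    m <- random_symmetric_map(12, seed = s)
    v <- flatten_map(m)
    expect_equal(unclass(unflatten_map(v, 12))[, ], m[, ],
                 ignore_attr = TRUE)
    expect_equal(sum(v), sum(m[lower.tri(m)]))
  }
  expect_error(unflatten_map(rep(0, 10), 100), "size mismatch")
})

test_that("range classes follow the nt-separation bins and partition pairs", {
  expect_equal(classify_range(1, 5), "excluded")
  expect_equal(classify_range(1, 6), "short")
  expect_equal(classify_range(1, 13), "short")     # |i-j| = 12
  expect_equal(classify_range(1, 14), "medium")    # 13
  expect_equal(classify_range(1, 25), "medium")    # 24
  expect_equal(classify_range(1, 26), "long")      # 25
  expect_error(classify_range(3, 3), "self pair")
  pairs <- expand.grid(i = 1:30, j = 1:30)
  pairs <- pairs[pairs$i < pairs$j, ]
  cls <- classify_range(pairs$i, pairs$j)
  expect_true(all(cls %in% c("excluded", "short", "medium", "long")))
})

test_that("category classification matches hand-checked pairs and partitions", {
  ss <- read_dotbracket("((..))((..))")
  expect_equal(classify_category(1, 6, ss), "base_pair")
  expect_equal(classify_category(2, 5, ss), "base_pair")
  expect_equal(classify_category(3, 4, ss), "loop_loop")
  expect_equal(classify_category(3, 10, ss), "loop_loop")
  expect_equal(classify_category(3, 7, ss), "stem_loop")
  expect_equal(classify_category(1, 2, ss), "intra_stem_stem")
  expect_equal(classify_category(2, 8, ss), "inter_stem_stem")
  expect_error(classify_category(1, 13, ss), "index out of range")

  pairs <- expand.grid(i = 1:12, j = 1:12)
  pairs <- pairs[pairs$i < pairs$j, ]
  cls <- classify_category(pairs$i, pairs$j, ss)
  expect_true(all(cls %in% c("base_pair", "stem_loop", "loop_loop",
                             "intra_stem_stem", "inter_stem_stem")))
  expect_equal(sum(cls == "base_pair"), 4L)
})
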