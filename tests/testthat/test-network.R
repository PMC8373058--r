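test_that("network initialization is reproducible and seeds differ", {
  n1 <- initNetwork(10, 500, 20, seed = 0)
  n2 <- initNetwork(10, 500, 20, seed = 0)
  expect_identical(n1@W1, n2@W1)
  expect_identical(n1@W2, n2@W2)
  n3 <- initNetwork(10, 500, 20, seed = 1)
  expect_false(all(n1@W1 == n3@W1))
  expect_true(all(is.finite(embedCells(n1, matrix(0, 1, 10)))))
})

test_that("embedding is row-independent, shape-correct and deterministic", {
  net <- initNetwork(30, 500, 20, seed = 2)
  set.seed(9)
  x <- matrix(rnorm(100 * 30), 100, 30)
  e <- embedCells(net, x)
  expect_equal(dim(e), c(100L, 20L))
  e1 <- embedCells(net, x[5, , drop = FALSE])
  expect_equal(as.numeric(e1), as.numeric(e[5, ]), tolerance = 1e-6)
  x[7, ] <- x[3, ]
  e2 <- embedCells(net, x)
  expect_equal(e2[7, ], e2[3, ])
  expect_error(embedCells(net, matrix(0, 2, 31)), "features")
})

test_that("N-pair batches draw one anchor/positive pair per type, without replacement", {
  b <- simulateBatches(smallSimCfg(seed = 4))[[1]]
  b <- logNormalize(b)
  set.seed(11)
  nb <- sampleNPairBatch(b)
  expect_s4_class(nb, "NPairBatch")
  expect_equal(nb@cellTypes, c("A", "B", "C"))
  expect_equal(nrow(nb@anchors), 3L)
  expect_false(any(nb@anchorIds == nb@positiveIds))
  expect_length(unique(c(nb@anchorIds, nb@positiveIds)), 6)
  set.seed(11)
  nb2 <- sampleNPairBatch(b)
  expect_identical(nb@anchorIds, nb2@anchorIds)     # same seed, same batch

  one <- b[, cellTypes(b) == "A"]
  expect_error(sampleNPairBatch(one), ">= 2 cell types")
  tiny <- b[, c(which(cellTypes(b) == "A")[1], which(cellTypes(b) == "B"))]
  expect_error(sampleNPairBatch(tiny), "< 2 cells")
})

test_that("N-pair loss reproduces analytic values", {
  # identical embeddings: every difference is 0, inner sum = N - 1 -> log(N)
  for (N in c(2, 3, 5)) {
    f <- matrix(1, N, 4)
    expect_equal(npairLoss(f, f), log(N), tolerance = 1e-12)
  }
  # orthonormal pairs, N = 2: loss = log(1 + e^-1)
  f <- diag(2)
  expect_equal(npairLoss(f, f), log(1 + exp(-1)), tolerance = 1e-12)
  # well-separated pairs drive the loss to zero without overflow
  for (s in c(10, 30, 100)) {
    fs <- s * diag(3)
    expect_lt(npairLoss(fs, fs), 1e-6)
    expect_true(is.finite(npairLoss(fs, fs)))
  }
})

test_that("vectorized loss agrees with the brute-force double loop on random instances", {
  set.seed(101)
  for (k in 1:100) {
    N <- sample(2:6, 1)
    d <- sample(2:20, 1)
    F <- matrix(rnorm(N * d, sd = 2), N, d)
    Fp <- matrix(rnorm(N * d, sd = 2), N, d)
    expect_equal(npairLoss(F, Fp), bruteNpairLoss(F, Fp), tolerance = 1e-6)
  }
})

test_that("loss is permutation-invariant and monotone in the positive similarity", {
  set.seed(7)
  F <- matrix(rnorm(5 * 8), 5, 8)
  Fp <- matrix(rnorm(5 * 8), 5, 8)
  base <- npairLoss(F, Fp)
  for (k in 1:10) {
    p <- sample(5)
    expect_equal(npairLoss(F[p, ], Fp[p, ]), base, tolerance = 1e-12)
  }
  # raise f_2 . f_2+ while leaving every other inner product unchanged:
  # perturb Fp[2, ] inside the orthogonal complement of the other anchors
  Q <- qr.Q(qr(t(F[-2, , drop = FALSE])))
  delta <- F[2, ] - as.numeric(Q %*% crossprod(Q, F[2, ]))
  expect_gt(sum(F[2, ] * delta), 0)
  Fp2 <- Fp
  Fp2[2, ] <- Fp[2, ] + delta
  expect_lt(npairLoss(F, Fp2), base)
})

test_that("network loss path matches the embeddings path and the C++ core", {
  net <- initNetwork(12, 16, 6, seed = 3)
  b <- simulateBatches(smallSimCfg(nGenes = 12, nMitoGenes = 2,
                                   markerGenesPerType = 2, seed = 8))[[1]]
  b <- logNormalize(b)
  set.seed(1)
  nb <- sampleNPairBatch(b)
  lossNet <- npairLoss(net, nb)
  manual <- npairLoss(embedCells(net, nb@anchors),
                      embedCells(net, nb@positives))
  expect_equal(lossNet, manual, tolerance = 1e-12)
  g <- scMultiRef:::.npairGrad(net, nb@anchors, nb@positives)
  expect_equal(g$loss, manual, tolerance = 1e-10)
})
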