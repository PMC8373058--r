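test_that("per-iteration total loss over two byte-identical tasks is twice the single-task loss", {
  # each type holds two identical cells, so the sampled N-pair batch is the
  # same whatever the draw; with a zero learning rate the parameters stay
  # put and the summed loss is exactly additive across tasks
  set.seed(2)
  proto <- matrix(rexp(2 * 10), 2, 10)
  X <- rbind(proto[1, ], proto[1, ], proto[2, ], proto[2, ])
  task <- list(x = X, types = list(0:1, 2:3))
  net <- initNetwork(10, 8, 4, seed = 5)
  run <- function(tasks) {
    set.seed(99)
    scMultiRef:::cpp_train(tasks, net@W1, net@b1, net@W2, net@b2,
                           epochs = 1, batches_per_epoch = 1,
                           lr = 0, l2_rate = 0)$loss_history[1]
  }
  single <- run(list(task))
  both <- run(list(task, task))
  expect_equal(both, 2 * single, tolerance = 1e-12)
  expect_gt(single, 0)
})

test_that("analytic gradients match finite differences on a tiny two-task network", {
  set.seed(42)
  net <- initNetwork(5, 4, 3, seed = 42)
  A1 <- matrix(rnorm(3 * 5), 3, 5); P1 <- matrix(rnorm(3 * 5), 3, 5)
  A2 <- matrix(rnorm(2 * 5), 2, 5); P2 <- matrix(rnorm(2 * 5), 2, 5)

  lossAt <- function(net) {
    npairLoss(embedCells(net, A1), embedCells(net, P1)) +
      npairLoss(embedCells(net, A2), embedCells(net, P2))
  }
  g1 <- scMultiRef:::.npairGrad(net, A1, P1)
  g2 <- scMultiRef:::.npairGrad(net, A2, P2)
  analytic <- c(g1$dW1 + g2$dW1, g1$db1 + g2$db1,
                g1$dW2 + g2$dW2, g1$db2 + g2$db2)

  h <- 1e-5
  numeric <- numeric(0)
  for (slot in c("W1", "b1", "W2", "b2")) {
    th <- slot(net, slot)
    for (k in seq_along(th)) {
      np <- net; nm <- net
      thp <- th; thp[k] <- thp[k] + h; slot(np, slot) <- thp
      thm <- th; thm[k] <- thm[k] - h; slot(nm, slot) <- thm
      numeric <- c(numeric, (lossAt(np) - lossAt(nm)) / (2 * h))
    }
  }
  relErr <- max(abs(analytic - numeric)) / max(1e-8, max(abs(numeric)))
  expect_lt(relErr, 1e-4)
})

test_that("training is deterministic, reduces the loss, and m = 1 degenerates to plain DML", {
  batches <- simulateBatches(smallSimCfg(seed = 6))
  prep <- preprocessReferences(batches[-1], qc = FALSE)
  p <- tinyTrainParams(epochs = 8, seed = 3)
  m1 <- trainModel(prep$refs, p)
  m2 <- trainModel(prep$refs, p)
  expect_identical(m1@lossHistory, m2@lossHistory)
  expect_identical(m1@network@W1, m2@network@W1)
  expect_length(m1@lossHistory, 8)
  expect_lt(m1@lossHistory[8], m1@lossHistory[1])

  single <- trainModel(prep$refs[[1]], p)
  expect_length(single@references, 1)
  expect_s4_class(single, "MultiRefModel")

  # untrainable task: a reference with a single cell type
  oneType <- prep$refs[[1]][, cellTypes(prep$refs[[1]]) == "A"]
  expect_error(trainModel(list(oneType), p), "untrainable")
})

test_that("model save/load round-trips weights, centroids and assignments", {
  batches <- simulateBatches(smallSimCfg(seed = 10))
  prep <- preprocessReferences(batches[-3], qc = FALSE)
  model <- trainModel(prep$refs, tinyTrainParams(epochs = 5))
  path <- withr::local_tempfile(fileext = ".rds")
  saveModel(model, path)
  back <- loadModel(path)
  expect_identical(back@geneUnion, model@geneUnion)
  expect_identical(back@network@W1, model@network@W1)
  expect_identical(back@references[[1]]@centroids,
                   model@references[[1]]@centroids)
  expect_identical(back@config, model@config)

  q <- batches[[3]]
  expect_equal(assignCells(back, q), assignCells(model, q))

  expect_error(loadModel(file.path(tempdir(), "absent.rds")), "not found")
  # truncation is detected, not silently accepted
  raw <- readBin(path, "raw", file.info(path)$size)
  trunc <- withr::local_tempfile(fileext = ".rds")
  writeBin(raw[1:floor(length(raw) / 2)], trunc)
  expect_error(loadModel(trunc), "cannot load")
  notModel <- withr::local_tempfile(fileext = ".rds")
  saveRDS(list(a = 1), notModel)
  expect_error(loadModel(notModel), "archive")
})
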