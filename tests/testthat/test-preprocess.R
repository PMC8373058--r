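test_that("qcFilter applies the three strict default criteria exactly", {
  toy <- qcPlumbingToy()
  kept <- qcFilter(toy)
  expect_setequal(colnames(kept),
                  c(sprintf("X%02d", 1:9), sprintf("Y%02d", 1:10)))
  # each engineered failure is removed for its specific reason
  expect_false("fail_genes" %in% colnames(kept))    # 400 detected <= 500
  expect_false("fail_umi" %in% colnames(kept))      # total exactly 1500
  expect_false("fail_mito_eq" %in% colnames(kept))  # mito exactly 10%
  expect_false("fail_mito_hi" %in% colnames(kept))
  expect_false("fail_all" %in% colnames(kept))
  # idempotent
  expect_equal(colnames(qcFilter(kept)), colnames(kept))
})

test_that("boundary cells pass when strictly inside all thresholds", {
  # 600 detected genes, 2000 total, 5% mito: retained
  m <- matrix(0L, 700, 2, dimnames = list(
    c(paste0("MT-", 1:5), sprintf("G%03d", 1:695)), c("ok", "low")))
  m[6:605, "ok"] <- 3L          # 1800 non-mito over 600 genes
  m[1:5, "ok"] <- 20L           # 100 mito -> 100/1900 = 5.3%... adjust
  m[6:605, "ok"] <- 3L; m[1:5, "ok"] <- 20L
  # detected 605 > 500; total 1900 > 1500; mito 100/1900 = 5.26% < 10%
  m[6:406, "low"] <- 4L         # 401 detected -> fails detected-genes
  ds <- ScBatch(m, name = "b")
  kept <- qcFilter(ds)
  expect_equal(colnames(kept), "ok")
})

test_that("qcFilter honours custom thresholds and the mito prefix case-insensitively", {
  m <- matrix(c(5L, 5L, 0L,
                1L, 9L, 0L), nrow = 3, byrow = FALSE,
              dimnames = list(c("mt-1", "gA", "gB"), c("c1", "c2")))
  ds <- ScBatch(m, name = "b")
  thr <- qcThresholds(minGenesDetected = 1, minUMI = 5, maxMitoFraction = 0.4)
  kept <- qcFilter(ds, thr)
  # c1: mito 5/10 = 50% -> out; c2: mito 1/15 -> in
  expect_equal(colnames(kept), "c2")
  expect_error(qcFilter(kept, qcThresholds(minUMI = 10^6)), "every cell")
})

test_that("filterRareTypes drops types below the cutoff and keeps the boundary", {
  types <- c(rep("A", 12), rep("B", 9), rep("C", 30), rep("D", 10))
  m <- matrix(1L, 5, length(types))
  ds <- makeBatch(m, types = types, name = "b",
                  cells = sprintf("c%03d", seq_along(types)))
  out <- filterRareTypes(ds)
  expect_setequal(unique(cellTypes(out)), c("A", "C", "D"))  # 9-cell B dropped
  expect_equal(sum(cellTypes(out) == "D"), 10L)              # boundary kept
  expect_equal(ncol(out), 52L)
  expect_equal(colnames(filterRareTypes(out)), colnames(out))  # idempotent
  expect_error(filterRareTypes(ds, minCells = 100), "no cell type")
  expect_error(filterRareTypes(makeBatch(m[, 1:3], name = "q")), "labels")
})

test_that("logNormalize matches hand-computed values and conserves the scale budget", {
  m <- matrix(c(5L, 15L, 0L, 30L), 4, 1,
              dimnames = list(paste0("g", 1:4), "c1"))
  ds <- ScBatch(m, name = "b")
  norm <- logNormalize(ds)
  v <- as.numeric(exprMatrix(norm)[, 1])
  expect_equal(v, c(log(1001), log(3001), 0, log(6001)), tolerance = 1e-12)
  expect_true(isNormalized(norm))

  # one-gene budget and symmetry
  one <- logNormalize(ScBatch(matrix(7L, 1, 1,
    dimnames = list("g1", "c1")), name = "s"))
  expect_equal(as.numeric(exprMatrix(one)), log(10001))
  eq <- logNormalize(ScBatch(matrix(2L, 8, 1,
    dimnames = list(paste0("g", 1:8), "c1")), name = "e"))
  expect_equal(as.numeric(exprMatrix(eq)), rep(log(10000 / 8 + 1), 8))

  # per-cell sum of expm1 equals the scale for every cell of a random batch
  b <- simulateBatches(smallSimCfg(seed = 5))[[2]]
  nb <- logNormalize(b)
  budgets <- Matrix::colSums(expm1(exprMatrix(nb)))
  expect_equal(as.numeric(budgets), rep(10000, ncol(nb)), tolerance = 1e-6)

  expect_error(logNormalize(nb), "already normalized")
  zero <- ScBatch(matrix(c(1L, 0L), 1, 2,
    dimnames = list("g1", c("c1", "c2"))), name = "z")
  expect_error(logNormalize(zero), "zero total")
})

test_that("gene union is the sorted union and alignment projects exactly", {
  b1 <- makeBatch(matrix(1L, 2, 3), genes = c("g1", "g2"), name = "r1")
  b2 <- makeBatch(matrix(1L, 2, 3), genes = c("g3", "g2"), name = "r2")
  expect_equal(buildGeneUnion(list(b1, b2)), c("g1", "g2", "g3"))
  expect_equal(buildGeneUnion(list(b2)), c("g2", "g3"))
  d1 <- makeBatch(matrix(1L, 3, 2), genes = paste0("a", 1:3), name = "x")
  d2 <- makeBatch(matrix(1L, 4, 2), genes = paste0("b", 1:4), name = "y")
  expect_length(buildGeneUnion(list(d1, d2)), 7)

  ds <- makeBatch(matrix(c(1L, 2L, 3L, 4L, 5L, 6L), 2, 3),
                  genes = c("g2", "g1"), name = "q")
  ds <- logNormalize(ds)
  al <- alignToUnion(ds, c("g1", "g2", "g3"))
  expect_equal(rownames(al), c("g1", "g2", "g3"))
  expect_equal(as.numeric(exprMatrix(al)["g1", ]),
               as.numeric(exprMatrix(ds)["g1", ]))      # values preserved
  expect_equal(as.numeric(exprMatrix(al)["g3", ]), c(0, 0, 0))  # zero-filled
  expect_equal(as.matrix(exprMatrix(alignToUnion(al, c("g1", "g2", "g3")))),
               as.matrix(exprMatrix(al)))               # idempotent

  # genes outside the union are dropped, remaining values unchanged
  ds9 <- logNormalize(makeBatch(matrix(c(1L, 2L, 4L, 8L), 2, 2),
                                genes = c("g1", "g9"), name = "q9"))
  al9 <- alignToUnion(ds9, c("g1", "g2"))
  expect_equal(rownames(al9), c("g1", "g2"))
  expect_equal(as.numeric(exprMatrix(al9)["g1", ]),
               as.numeric(exprMatrix(ds9)["g1", ]))
  # identity when already in union order
  expect_identical(alignToUnion(al9, c("g1", "g2")), al9)
})

test_that("the full preprocessing pipeline leaves exactly the expected cells, types and columns", {
  toy <- qcPlumbingToy()
  other <- makeBatch(matrix(3L, 3, 24), genes = c("G001", "G990", "ZZZ"),
                     types = rep(c("Y", "Z"), each = 12), name = "other",
                     cells = sprintf("o%02d", 1:24))
  prep <- preprocessReferences(list(toy, other), qc = FALSE)
  expect_equal(prep$geneUnion,
               .lexSortForTest(unique(c(rownames(toy), "ZZZ"))))
  prep2 <- preprocessReferences(list(toy), qc = TRUE)
  ref <- prep2$refs[[1]]
  expect_equal(colnames(ref), sprintf("Y%02d", 1:10))   # X rare after QC
  expect_equal(unique(cellTypes(ref)), "Y")
  expect_equal(rownames(ref), sort(rownames(toy), method = "radix"))
  expect_true(isNormalized(ref))
})
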