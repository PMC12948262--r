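test_that("token attention is symmetric when projections coincide", {
  # drug and protein projected to identical tokens -> every head splits
  # its attention (0.5, 0.5)
  fp <- initFusionParams(drugDim = 4L, protDim = 4L, dModel = 8L,
                         nHeads = 2L, fclDims = c(6L, 3L), seed = 1L)
  fp$theta$Pp <- fp$theta$Pd
  x <- matrix(rnorm(8L), 2L, 4L)
  res <- multiHeadFuse(x, x, fp, returnAttention = TRUE)
  for (head in res$attention) {
    expect_equal(head$drugToken, matrix(0.5, 2L, 2L), tolerance = 1e-12)
    expect_equal(head$protToken, matrix(0.5, 2L, 2L), tolerance = 1e-12)
  }
})

test_that("fused width is 3072 with 8 heads at the reference configuration", {
  fp <- initFusionParams(seed = 1L)      # 512 + 2560, dModel 384, 8 heads
  f <- multiHeadFuse(rnorm(512L), rnorm(2560L), fp, returnAttention = TRUE)
  expect_equal(ncol(f$fused), 3072L)
  expect_length(f$attention, 8L)
  m <- assembleModel("wo_MG_PG", seed = 1L)   # reference dims, no encoders
  dims <- modelDimensions(m)
  expect_equal(dims$fusedDim, 3072L)
  expect_equal(dims$fclDims, c(1280L, 320L, 1L))
})

test_that("uniform-attention fusion matches the scalar oracle", {
  # 1 head, Q = K = 0, V = identity, WO = identity: attention is uniform and
  # each token's attention output is the mean of the two value vectors
  d <- 3L
  fp <- initFusionParams(drugDim = d, protDim = d, dModel = d, nHeads = 1L,
                         fclDims = c(4L, 2L), seed = 2L)
  fp$theta$WQ1 <- matrix(0, d, d)
  fp$theta$WK1 <- matrix(0, d, d)
  fp$theta$WV1 <- diag(d)
  fp$theta$WO <- diag(d)
  dv <- matrix(c(1, 2, 3), 1L)
  pv <- matrix(c(-1, 0, 5), 1L)
  res <- multiHeadFuse(dv, pv, fp, returnAttention = TRUE)
  expect_equal(res$attention[[1L]]$drugToken, matrix(0.5, 1L, 2L))
  Td <- dv %*% fp$theta$Pd
  Tp <- pv %*% fp$theta$Pp
  meanVal <- (Td + Tp) / 2
  wantD <- (Td + meanVal) %*% fp$theta$Ud   # residual + attention output
  wantP <- (Tp + meanVal) %*% fp$theta$Up
  expect_equal(res$fused, cbind(wantD, wantP), tolerance = 1e-10)
})

test_that("bypassing attention reduces fusion to plain concatenation", {
  fp <- initFusionParams(drugDim = 3L, protDim = 4L, dModel = 4L,
                         nHeads = 2L, fclDims = c(5L, 3L),
                         bypassAttention = TRUE, seed = 1L)
  d <- matrix(rnorm(6L), 2L); p <- matrix(rnorm(8L), 2L)
  expect_equal(multiHeadFuse(d, p, fp), cbind(d, p), ignore_attr = TRUE)
})

test_that("fusion is not symmetric under swapping the modalities", {
  fp <- initFusionParams(drugDim = 5L, protDim = 5L, dModel = 8L,
                         nHeads = 2L, fclDims = c(6L, 3L), seed = 3L)
  a <- matrix(rnorm(5L), 1L); b <- matrix(rnorm(5L), 1L)
  expect_false(isTRUE(all.equal(multiHeadFuse(a, b, fp),
                                multiHeadFuse(b, a, fp))))
})

test_that("batch normalization follows the explicit formula", {
  set.seed(1)
  x <- matrix(rnorm(2000L), 200L, 10L)
  out <- batchNorm(x)
  expect_equal(unname(colMeans(out)), rep(0, 10L), tolerance = 1e-6)
  expect_equal(unname(apply(out, 2L, stats::sd)), rep(1, 10L),
               tolerance = 1e-2)
  # constant batch: zero variance, epsilon regularizes, output = beta
  const <- matrix(5, 8L, 3L)
  expect_equal(batchNorm(const, gamma = c(1, 2, 3), beta = c(-1, 0, 1)),
               matrix(c(-1, 0, 1), 8L, 3L, byrow = TRUE),
               ignore_attr = TRUE)
  # integer fixture, hand-evaluated elementwise
  xf <- matrix(c(1, 2, 3, 4, 10, 20, 30, 40), 4L, 2L)
  got <- batchNorm(xf, gamma = c(2, 2), beta = c(1, 1), eps = 1e-5)
  mu <- colMeans(xf)
  v <- colMeans(sweep(xf, 2L, mu)^2)
  want <- sweep(sweep(sweep(sweep(xf, 2L, mu), 2L, sqrt(v + 1e-5), "/"),
                      2L, c(2, 2), "*"), 2L, c(1, 1), "+")
  expect_equal(got, want, tolerance = 1e-12)
  expect_equal(got[1L, 1L], (1 - 2.5) / sqrt(1.25 + 1e-5) * 2 + 1,
               tolerance = 1e-12)
  expect_error(batchNorm(matrix(1, 1L, 2L)), "at least 2")
  # inference mode uses the supplied running statistics
  got2 <- batchNorm(xf, training = FALSE, runningMean = c(0, 0),
                    runningVar = c(1, 1), eps = 0)
  expect_equal(got2, xf, ignore_attr = TRUE)
})

test_that("prediction stack has the contracted shapes and oracle values", {
  fp <- initFusionParams(drugDim = 4L, protDim = 6L, dModel = 4L,
                         nHeads = 2L, fclDims = c(8L, 5L), seed = 4L)
  # zero network outputs 0 (regression) / 0.5 (classification)
  z <- fp
  for (nm in c("W1", "b1", "be1", "W2", "b2", "be2", "W3", "b3"))
    z$theta[[nm]] <- z$theta[[nm]] * 0
  x <- matrix(rnorm(20L), 2L, 10L)
  expect_equal(predictFromFused(x, z), c(0, 0))
  zc <- z; zc$meta$headMode <- "classification"
  expect_equal(predictFromFused(x, zc), c(0.5, 0.5))
  # dense forward oracle in inference mode (running stats mean 0 var 1)
  th <- fp$theta
  bn <- function(m, g, b, eps) sweep(sweep(m, 2L, sqrt(1 + eps), "/"),
                                     2L, as.numeric(g), "*") +
    matrix(as.numeric(b), nrow(m), length(b), byrow = TRUE)
  z1 <- x %*% th$W1 + matrix(th$b1, 2L, 8L, byrow = TRUE)
  z1 <- pmax(bn(z1, th$g1, th$be1, fp$meta$eps), 0)
  z2 <- z1 %*% th$W2 + matrix(th$b2, 2L, 5L, byrow = TRUE)
  z2 <- pmax(bn(z2, th$g2, th$be2, fp$meta$eps), 0)
  want <- as.numeric(z2 %*% th$W3 + as.numeric(th$b3))
  expect_equal(predictFromFused(x, fp), want, tolerance = 1e-8)
  expect_error(predictFromFused(x * NA, fp), "finite")
})

test_that("classification probabilities stay inside (0, 1)", {
  fp <- initFusionParams(drugDim = 3L, protDim = 5L, dModel = 4L,
                         nHeads = 2L, fclDims = c(6L, 4L),
                         headMode = "classification", seed = 5L)
  set.seed(6)
  p <- predictFromFused(matrix(rnorm(8000L, sd = 3), 1000L, 8L), fp)
  expect_true(all(p > 0 & p < 1))
})

test_that("frozen running statistics make eval outputs batch-independent", {
  ft <- tinyFeatures()
  ma <- reducedModelArgs()
  m <- assembleModel("full", drugDim = ft$drugDim, protDim = ft$protDim,
                     heads = ma$heads, dModel = ma$dModel,
                     nFusionHeads = ma$nFusionHeads, fclDims = ma$fclDims,
                     seed = 2L)
  m <- trainModel(m, ft, trainConfig(epochs = 3L, seed = 2L))
  pAll <- predictAffinity(m, ft)
  pOne <- vapply(seq_len(nrow(ft$records)),
                 function(i) predictAffinity(m, ft, i), 0)
  expect_equal(pOne, pAll, tolerance = 1e-10)
  expect_identical(predictAffinity(m, ft), pAll)  # deterministic
})
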