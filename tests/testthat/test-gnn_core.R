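# Attention layers. The hand oracle below recomputes scores edge by edge
# with scalar arithmetic, independently of the tape implementation.

handAlpha <- function(h, src, dst, ef, p, mode, variant, leak = 0.2) {
  m <- length(src)
  score <- numeric(m)
  for (e in seq_len(m)) {
    cat_ <- c(h[dst[e], ], h[src[e], ], ef[e, ])
    z <- as.numeric(cat_ %*% p$W1) + as.numeric(p$b1)
    score[e] <- if (mode == "as_printed_linear") z / p$dk
    else if (variant == "gat") {
      t0 <- sum(z * p$a)
      (if (t0 > 0) t0 else leak * t0) / sqrt(p$dk)
    } else sum(ifelse(z > 0, z, leak * z) * p$a) / sqrt(p$dk)
  }
  alpha <- numeric(m)
  for (i in unique(dst)) {
    sel <- dst == i
    e <- exp(score[sel] - max(score[sel]))
    alpha[sel] <- e / sum(e)
  }
  alpha
}

test_that("attention coefficients normalize and match the scalar oracle", {
  h <- matrix(c(1, 0, 0, 1, 1, 1), 3L, 2L)   # 3-node path
  ei <- cbind(src = c(1L, 2L, 2L, 3L), dst = c(2L, 1L, 3L, 2L))
  ef <- matrix(c(0.5, 0.5, 0.25, 0.25), ncol = 1L)
  for (variant in c("gatv2", "gat")) for (mode in c("gatv2_canonical",
                                                    "as_printed_linear")) {
    cfg <- graphEncoderConfig(2L, edgeDim = 1L, variant = variant,
                              nLayers = 1L, hiddenDims = 2L, heads = 1L,
                              scoreMode = mode)
    enc <- initGraphEncoder(cfg, seed = 3L)
    # small integer-ish parameters for the oracle
    p <- enc$layers[[1L]]$heads[[1L]]
    p$W1 <- matrix(seq_len(length(p$W1)) %% 3 - 1, nrow(p$W1), ncol(p$W1))
    p$b1 <- p$b1 + 0.5
    if (mode != "as_printed_linear") p$a <- matrix(c(1, -1)[seq_len(nrow(p$a)) %% 2 + 1])
    enc$layers[[1L]]$heads[[1L]] <- p
    al <- attentionCoefficients(enc, h, ei, ef)
    agg <- as.numeric(tapply(al$alpha, al$dst, sum))
    expect_equal(agg, rep(1, 3L), tolerance = 1e-12)
    sl <- dualDTA:::.withSelfLoops(ei, ef, 3L, 1L)
    want <- handAlpha(h, sl$src, sl$dst, sl$ef, p, mode, variant)
    expect_equal(al$alpha, want, tolerance = 1e-12)
  }
})

test_that("degenerate neighbourhoods give the trivial softmax answers", {
  cfg <- graphEncoderConfig(2L, edgeDim = 0L, nLayers = 1L, hiddenDims = 2L,
                            heads = 1L, addSelfLoops = FALSE)
  enc <- initGraphEncoder(cfg, seed = 1L)
  # single in-neighbour, no self-loop: alpha = 1
  h <- matrix(rnorm(4L), 2L)
  al <- attentionCoefficients(enc, h, cbind(src = 1L, dst = 2L))
  expect_equal(al$alpha, 1)
  # two neighbours with identical features and edge features: 0.5 each
  h3 <- rbind(h[1L, ], h[1L, ], rnorm(2L))
  al2 <- attentionCoefficients(enc, h3,
                               cbind(src = c(1L, 2L), dst = c(3L, 3L)))
  expect_equal(al2$alpha, c(0.5, 0.5), tolerance = 1e-12)
})

test_that("attention sums to one on random graphs in both score modes", {
  set.seed(10)
  for (mode in c("gatv2_canonical", "as_printed_linear")) {
    for (rep in 1:50) {
      n <- sample(2:30, 1L)
      g <- randomTestGraph(n, de = 2L)
      cfg <- graphEncoderConfig(5L, edgeDim = 2L, nLayers = 1L,
                                hiddenDims = 4L, heads = 1L, scoreMode = mode)
      enc <- initGraphEncoder(cfg, seed = rep)
      al <- attentionCoefficients(enc, g$h, g$edgeIndex, g$edgeFeats)
      sums <- tapply(al$alpha, al$dst, sum)
      expect_true(all(abs(sums - 1) < 1e-6))
      expect_true(all(al$alpha > 0))
    }
  }
})

test_that("message passing reduces to gathering under identity weights", {
  cfg <- graphEncoderConfig(3L, edgeDim = 0L, nLayers = 1L, hiddenDims = 3L,
                            heads = 1L, activation = "identity",
                            addSelfLoops = FALSE)
  enc <- initGraphEncoder(cfg, seed = 1L)
  enc$layers[[1L]]$heads[[1L]]$W2 <- diag(3L)
  h <- matrix(rnorm(9L), 3L)
  # self-loop only: fixed point
  selfAl <- data.frame(src = 1:3, dst = 1:3, alpha = 1)
  expect_equal(messagePassingUpdate(enc, h, selfAl), h, tolerance = 1e-12)
  # single neighbour: h'_i = h_j
  al <- data.frame(src = c(2L, 1L, 2L), dst = c(1L, 2L, 3L), alpha = 1)
  out <- messagePassingUpdate(enc, h, al)
  expect_equal(out[1L, ], h[2L, ], tolerance = 1e-12)
  expect_equal(out[3L, ], h[2L, ], tolerance = 1e-12)
  # fixed alpha and W2: explicit weighted-sum oracle
  enc$layers[[1L]]$heads[[1L]]$W2 <- matrix(c(1, 2, 0, 0, 1, 1, 1, 0, 2), 3L)
  al3 <- data.frame(src = c(1L, 2L, 3L), dst = c(3L, 3L, 1L),
                    alpha = c(0.25, 0.75, 1))
  out3 <- messagePassingUpdate(enc, h, al3)
  W2 <- enc$layers[[1L]]$heads[[1L]]$W2
  expect_equal(out3[3L, ],
               as.numeric(0.25 * h[1L, ] %*% W2 + 0.75 * h[2L, ] %*% W2),
               tolerance = 1e-10)
  expect_equal(out3[1L, ], as.numeric(h[3L, ] %*% W2), tolerance = 1e-10)
  expect_equal(out3[2L, ], rep(0, 3L))   # no incoming messages
})

test_that("GCN update matches the dense normalized-adjacency oracle", {
  cfg <- graphEncoderConfig(3L, variant = "gcn", nLayers = 1L,
                            hiddenDims = 3L, activation = "identity")
  enc <- initGraphEncoder(cfg, seed = 2L)
  # isolated node with identity weights: unchanged
  encI <- enc
  encI$layers[[1L]]$W <- diag(3L)
  h1 <- matrix(rnorm(3L), 1L)
  expect_equal(gcnUpdate(encI, h1, cbind(src = integer(0), dst = integer(0))),
               h1, tolerance = 1e-12)
  # two connected nodes with equal features: equal outputs
  h2 <- rbind(c(1, 2, 3), c(1, 2, 3))
  ei2 <- cbind(src = c(1L, 2L), dst = c(2L, 1L))
  out2 <- gcnUpdate(enc, h2, ei2)
  expect_equal(out2[1L, ], out2[2L, ], tolerance = 1e-12)
  # 4-node fixture vs dense oracle A_hat H W
  set.seed(3)
  h4 <- matrix(rnorm(12L), 4L)
  ei4 <- cbind(src = c(1L, 2L, 2L, 3L, 3L, 4L), dst = c(2L, 1L, 3L, 2L, 4L, 3L))
  out4 <- gcnUpdate(enc, h4, ei4)
  A <- matrix(0, 4L, 4L)
  A[ei4] <- 1
  A <- A + diag(4L)
  Dm <- diag(1 / sqrt(colSums(A)))
  oracle <- Dm %*% A %*% Dm %*% h4 %*% enc$layers[[1L]]$W
  oracle <- sweep(oracle, 2L, as.numeric(enc$layers[[1L]]$b), "+")
  expect_equal(out4, oracle, ignore_attr = TRUE, tolerance = 1e-10)
})

test_that("graph encoding is permutation invariant and isomorphism safe", {
  p <- mockAtomProvider(dim = 8L, seed = 3L)
  cfg <- graphEncoderConfig(8L, edgeDim = 6L, nLayers = 3L, heads = 2L)
  enc <- initGraphEncoder(cfg, seed = 5L)
  g <- buildMolecularGraph("CC(=O)Oc1ccccc1", p)
  v1 <- encodeGraph(g, enc)
  # permute nodes and edges consistently
  set.seed(8)
  perm <- sample(numNodes(g))
  inv <- order(perm)
  g2 <- methods::new("MolecularGraph", smiles = g@smiles,
                     nodeFeatures = nodeFeatures(g)[inv, ],
                     edgeIndex = matrix(perm[edgeIndex(g)], ncol = 2L,
                                        dimnames = list(NULL, c("src", "dst"))),
                     edgeFeatures = edgeFeatures(g))
  expect_equal(encodeGraph(g2, enc), v1, tolerance = 1e-5)
  # the same molecule written with a different atom order
  va <- encodeGraph(buildMolecularGraph("CCO", p), enc)
  vb <- encodeGraph(buildMolecularGraph("OCC", p), enc)
  expect_equal(va, vb, tolerance = 1e-5)
  expect_error(encodeGraph(methods::new("MolecularGraph", smiles = "",
                                        nodeFeatures = matrix(0, 0, 8),
                                        edgeIndex = matrix(integer(0), 0, 2),
                                        edgeFeatures = matrix(0, 0, 6)), enc),
               "empty")
})

test_that("a single-node identity-configured stack is the identity", {
  cfg <- graphEncoderConfig(4L, edgeDim = 0L, nLayers = 2L, hiddenDims = c(4L, 4L),
                            heads = 1L, activation = "identity")
  enc <- initGraphEncoder(cfg, seed = 1L)
  for (l in 1:2) {
    enc$layers[[l]]$heads[[1L]]$W2 <- diag(4L)
  }
  h <- matrix(rnorm(4L), 1L)
  tp <- dualDTA:::tapeNew()
  out <- dualDTA:::.encoderForwardTape(tp, enc, dualDTA:::tpInput(tp, h),
                                       matrix(integer(0), 0L, 2L),
                                       matrix(0, 0L, 0L), 1L, 1L)
  expect_equal(as.numeric(dualDTA:::tpVal(tp, out)), as.numeric(h),
               tolerance = 1e-12)
})

test_that("GCN equals GATv2 with forced-uniform attention on a regular graph", {
  # ring of identical nodes: symmetry forces uniform attention, and the
  # symmetric normalization of GCN also reduces to 1/(deg+1)
  n <- 6L
  h <- matrix(rep(c(0.3, -0.2, 0.5), each = n), n)
  ei <- cbind(src = c(1:n, c(2:n, 1L)), dst = c(c(2:n, 1L), 1:n))
  W <- matrix(rnorm(9L), 3L)
  cfgA <- graphEncoderConfig(3L, edgeDim = 0L, variant = "gatv2",
                             nLayers = 1L, hiddenDims = 3L, heads = 1L,
                             activation = "identity")
  encA <- initGraphEncoder(cfgA, seed = 1L)
  encA$layers[[1L]]$heads[[1L]]$W2 <- W
  cfgC <- graphEncoderConfig(3L, edgeDim = 0L, variant = "gcn", nLayers = 1L,
                             hiddenDims = 3L, activation = "identity")
  encC <- initGraphEncoder(cfgC, seed = 1L)
  encC$layers[[1L]]$W <- W
  encC$layers[[1L]]$b <- matrix(0, 1L, 3L)
  al <- attentionCoefficients(encA, h, ei)
  outA <- messagePassingUpdate(encA, h, al)
  outC <- gcnUpdate(encC, h, ei)
  expect_equal(outA, outC, tolerance = 1e-6)
})
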