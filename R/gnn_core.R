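# Graph encoders: three-layer GATv2 (reference), GAT (static attention) and
# GCN (no attention) with mean-pool readout. A single tape-based forward
# serves both the exported inspection API (values only) and training
# (gradients), so the two paths cannot drift apart.

#' Configure a graph encoder
#'
#' The attention score in `"gatv2_canonical"` mode is
#' `a' LeakyReLU(W1 [h_i || h_j || e_ij] + b1) / sqrt(d_k)` (dynamic
#' attention); `"as_printed_linear"` keeps the bare linear form
#' `(w1 [h_i || h_j || e_ij] + b1) / d_k` with a scalar score and no
#' nonlinearity. `d_k` is the dimension of the concatenated vector. Edge
#' features enter the score by concatenation: the 6-D bond vector for
#' molecular graphs, the 1-D inverse-distance weight for protein graphs
#' (self-loops carry zero edge features). Variants: `"gatv2"`, `"gat"`
#' (LeakyReLU applied after the attention vector, i.e. static ranking) and
#' `"gcn"` (symmetric-normalized equal-weight aggregation, no attention).
#'
#' @param inputDim node feature dimensionality entering layer 1.
#' @param edgeDim edge feature dimensionality (0, 1 or 6 here).
#' @param variant `"gatv2"`, `"gat"` or `"gcn"`.
#' @param nLayers number of layers (default 3).
#' @param hiddenDims per-layer output dims per head; defaults to
#'   `inputDim` everywhere so the graph-level output keeps the embedding
#'   width.
#' @param heads attention heads per layer (recycled; heads are concatenated
#'   on all but the last layer, averaged on the last).
#' @param leak LeakyReLU negative slope for attention scores.
#' @param scoreMode `"gatv2_canonical"` or `"as_printed_linear"`.
#' @param activation `"elu"`, `"relu"` or `"identity"` for message updates.
#' @param addSelfLoops add a self-loop to every node before scoring.
#' @return a config list consumed by [initGraphEncoder()].
#' @export
graphEncoderConfig <- function(inputDim, edgeDim = 0L, variant = c("gatv2", "gat", "gcn"),
                               nLayers = 3L, hiddenDims = NULL, heads = 4L,
                               leak = 0.2,
                               scoreMode = c("gatv2_canonical", "as_printed_linear"),
                               activation = c("elu", "relu", "identity"),
                               addSelfLoops = TRUE) {
  variant <- match.arg(variant)
  scoreMode <- match.arg(scoreMode)
  activation <- match.arg(activation)
  if (is.null(hiddenDims)) hiddenDims <- rep(as.integer(inputDim), nLayers)
  stopifnot(length(hiddenDims) == nLayers, all(hiddenDims > 0), nLayers >= 1)
  heads <- rep_len(as.integer(heads), nLayers)
  if (variant == "gcn") heads <- rep(1L, nLayers)
  list(inputDim = as.integer(inputDim), edgeDim = as.integer(edgeDim),
       variant = variant, nLayers = as.integer(nLayers),
       hiddenDims = as.integer(hiddenDims), heads = heads, leak = leak,
       scoreMode = scoreMode, activation = activation,
       addSelfLoops = addSelfLoops)
}

.glorot <- function(fin, fout) {
  lim <- sqrt(6 / (fin + fout))
  matrix(stats::runif(fin * fout, -lim, lim), fin, fout)
}

# per-layer input dims given head concatenation
.layerInputDims <- function(config) {
  dims <- integer(config$nLayers)
  dims[1L] <- config$inputDim
  if (config$nLayers > 1L)
    for (l in 2:config$nLayers)
      dims[l] <- config$hiddenDims[l - 1L] *
        (if (l - 1L < config$nLayers) config$heads[l - 1L] else 1L)
  dims
}

#' Initialize encoder parameters
#'
#' Glorot-uniform weights for every layer/head of the configured variant.
#' Parameters are plain nested lists (`encoder$layers[[l]]$heads[[h]]` with
#' `W1`, `b1`, `a`, `W2` for attention variants; `encoder$layers[[l]]$W`
#' for GCN) so tests can substitute hand-chosen matrices.
#'
#' @param config from [graphEncoderConfig()].
#' @param seed integer seed.
#' @return list with elements `config` and `layers`.
#' @export
initGraphEncoder <- function(config, seed = 1L) {
  ins <- .layerInputDims(config)
  layers <- withRNG(seed, lapply(seq_len(config$nLayers), function(l) {
    din <- ins[l]; dh <- config$hiddenDims[l]
    if (config$variant == "gcn")
      return(list(W = .glorot(din, dh), b = matrix(0, 1L, dh)))
    dcat <- 2L * din + config$edgeDim
    hs <- lapply(seq_len(config$heads[l]), function(h) {
      if (config$scoreMode == "as_printed_linear")
        list(W1 = .glorot(dcat, 1L), b1 = matrix(0, 1L, 1L),
             a = matrix(1, 1L, 1L), W2 = .glorot(din, dh), dk = dcat)
      else
        list(W1 = .glorot(dcat, dh), b1 = matrix(0, 1L, dh),
             a = .glorot(dh, 1L), W2 = .glorot(din, dh), dk = dcat)
    })
    list(heads = hs)
  }))
  list(config = config, layers = layers)
}

# augment an edge list with self-loops carrying zero edge features
.withSelfLoops <- function(edgeIndex, edgeFeats, n, edgeDim) {
  src <- c(edgeIndex[, 1L], seq_len(n))
  dst <- c(edgeIndex[, 2L], seq_len(n))
  ef <- if (edgeDim > 0L)
    rbind(if (nrow(edgeIndex)) edgeFeats else matrix(0, 0L, edgeDim),
          matrix(0, n, edgeDim))
  else matrix(0, length(src), 0L)
  list(src = src, dst = dst, ef = ef)
}

# tape forward of one attention head; returns list(alpha, out) node ids
.headForwardTape <- function(tp, H, src, dst, efConst, p, config, n) {
  Hs <- tpGather(tp, H, src)
  Hd <- tpGather(tp, H, dst)
  C <- if (ncol(efConst) > 0L) tpCbind(tp, c(Hd, Hs, tpInput(tp, efConst)))
       else tpCbind(tp, c(Hd, Hs))
  S <- tpAddRowvec(tp, tpMatmul(tp, C, tpVal2(tp, p, "W1")),
                   tpVal2(tp, p, "b1"))
  sc <- if (config$scoreMode == "as_printed_linear") {
    tpScale(tp, S, 1 / p$dk)
  } else if (config$variant == "gat") {
    tpScale(tp, tpLeakyRelu(tp, tpMatmul(tp, S, tpVal2(tp, p, "a")),
                            config$leak), 1 / sqrt(p$dk))
  } else {
    tpScale(tp, tpMatmul(tp, tpLeakyRelu(tp, S, config$leak),
                         tpVal2(tp, p, "a")), 1 / sqrt(p$dk))
  }
  alpha <- tpSegmentSoftmax(tp, sc, dst, n)
  msg <- tpMulColvec(tp, tpMatmul(tp, Hs, tpVal2(tp, p, "W2")), alpha)
  list(alpha = alpha, out = tpSegmentSum(tp, msg, dst, n))
}

# merged multi-head attention layer: all heads share the gathered inputs and
# are evaluated through block-concatenated weight matrices, so the per-layer
# cost is a fixed number of dense operations regardless of head count.
# Numerically identical to composing .headForwardTape per head.
.attnLayerForwardTape <- function(tp, H, sl, lp, config, n, average) {
  heads <- lp$heads
  nH <- length(heads)
  dh <- if (is.matrix(heads[[1L]]$W2)) ncol(heads[[1L]]$W2)
        else ncol(tpVal(tp, heads[[1L]]$W2))
  dk <- heads[[1L]]$dk
  Hs <- tpGather(tp, H, sl$src)
  Hd <- tpGather(tp, H, sl$dst)
  C <- if (ncol(sl$ef) > 0L) tpCbind(tp, c(Hd, Hs, tpInput(tp, sl$ef)))
       else tpCbind(tp, c(Hd, Hs))
  W1c <- tpCbind(tp, vapply(heads, function(p) tpVal2(tp, p, "W1"), 0L))
  b1c <- tpCbind(tp, vapply(heads, function(p) tpVal2(tp, p, "b1"), 0L))
  S <- tpAddRowvec(tp, tpMatmul(tp, C, W1c), b1c)
  scores <- if (config$scoreMode == "as_printed_linear") {
    tpScale(tp, S, 1 / dk)       # W1 blocks are (dcat x 1): S is m x H
  } else {
    aRow <- tpCbind(tp, vapply(heads, function(p)
      tpTranspose(tp, tpVal2(tp, p, "a")), 0L))
    blockSum <- matrix(0, nH * nrow(if (is.matrix(heads[[1L]]$a)) heads[[1L]]$a
                                    else tpVal(tp, heads[[1L]]$a)), nH)
    dhs <- nrow(blockSum) / nH
    blockSum[cbind(seq_len(nrow(blockSum)), rep(seq_len(nH), each = dhs))] <- 1
    if (config$variant == "gat") {
      Sa <- tpMatmul(tp, tpMulRowvec(tp, S, aRow), tpInput(tp, blockSum))
      tpScale(tp, tpLeakyRelu(tp, Sa, config$leak), 1 / sqrt(dk))
    } else {
      Z <- tpLeakyRelu(tp, S, config$leak)
      tpScale(tp, tpMatmul(tp, tpMulRowvec(tp, Z, aRow), tpInput(tp, blockSum)),
              1 / sqrt(dk))
    }
  }
  alpha <- tpSegmentSoftmax(tp, scores, sl$dst, n)   # m x H, per-column
  W2c <- tpCbind(tp, vapply(heads, function(p) tpVal2(tp, p, "W2"), 0L))
  M <- tpMulColBlocks(tp, tpMatmul(tp, Hs, W2c), alpha, dh)
  agg <- tpSegmentSum(tp, M, sl$dst, n)              # n x H*dh
  if (average && nH > 1L) {
    avg <- matrix(0, nH * dh, dh)
    for (h in seq_len(nH))
      avg[((h - 1L) * dh + 1L):(h * dh), ] <- diag(dh) / nH
    agg <- tpMatmul(tp, agg, tpInput(tp, avg))
  }
  .activate(tp, agg, config$activation)
}

# parameters may arrive as plain matrices (inference) or pre-registered tape
# node ids (training); tpVal2 normalizes both cases to a node id
tpVal2 <- function(tp, p, field) {
  v <- p[[field]]
  if (is.matrix(v)) tpInput(tp, v) else v
}

.activate <- function(tp, id, activation) {
  switch(activation,
         elu = tpElu(tp, id),
         relu = tpRelu(tp, id),
         identity = id)
}

# full encoder forward on a (possibly batched) node matrix
# edges: raw directed edge index (no self-loops); graphId: node -> graph
.encoderForwardTape <- function(tp, encoder, X, edgeIndex, edgeFeats, graphId,
                                nGraphs, params = NULL) {
  config <- encoder$config
  n <- nrow(tpVal(tp, X))
  sl <- if (config$addSelfLoops)
    .withSelfLoops(edgeIndex, edgeFeats, n, config$edgeDim)
  else list(src = edgeIndex[, 1L], dst = edgeIndex[, 2L],
            ef = if (config$edgeDim > 0L) edgeFeats
                 else matrix(0, nrow(edgeIndex), 0L))
  layers <- if (is.null(params)) encoder$layers else params
  H <- X
  for (l in seq_len(config$nLayers)) {
    lp <- layers[[l]]
    if (config$variant == "gcn") {
      deg <- tabulate(sl$dst, nbins = n)
      norm <- 1 / sqrt(deg[sl$src] * deg[sl$dst])
      Hs <- tpGather(tp, H, sl$src)
      agg <- tpSegmentSum(tp, tpScaleRows(tp, Hs, norm), sl$dst, n)
      H <- .activate(tp, tpAddRowvec(tp, tpMatmul(tp, agg, tpVal2(tp, lp, "W")),
                                     tpVal2(tp, lp, "b")), config$activation)
    } else {
      H <- .attnLayerForwardTape(tp, H, sl, lp, config, n,
                                 average = (l == config$nLayers))
    }
  }
  # mean-pool readout per graph
  pooled <- tpSegmentSum(tp, H, graphId, nGraphs)
  sizes <- tabulate(graphId, nbins = nGraphs)
  tpScaleRows(tp, pooled, 1 / sizes)
}

#' Attention coefficients of one encoder layer
#'
#' Computes the per-edge attention `alpha_ij` (node `i = dst` attending over
#' its in-neighbours `j = src`, plus a self-loop when configured) for one
#' head of one layer. For every node the returned coefficients sum to 1.
#'
#' @param encoder from [initGraphEncoder()] (or hand-built params of the
#'   same shape).
#' @param h node feature matrix for this layer's input.
#' @param edgeIndex integer matrix (edges x 2, `src`/`dst`), no self-loops.
#' @param edgeFeats edge feature matrix (or NULL when `edgeDim = 0`).
#' @param layer,head which layer/head to evaluate.
#' @return data.frame with columns `src`, `dst`, `alpha` (self-loops
#'   included when configured).
#' @export
attentionCoefficients <- function(encoder, h, edgeIndex, edgeFeats = NULL,
                                  layer = 1L, head = 1L) {
  config <- encoder$config
  if (config$variant == "gcn") stop("GCN layers have no attention coefficients")
  n <- nrow(h)
  if (is.null(edgeFeats)) edgeFeats <- matrix(0, nrow(edgeIndex), config$edgeDim)
  if (ncol(edgeFeats) != config$edgeDim) stop("edge feature dimension mismatch")
  sl <- if (config$addSelfLoops)
    .withSelfLoops(edgeIndex, edgeFeats, n, config$edgeDim)
  else list(src = edgeIndex[, 1L], dst = edgeIndex[, 2L], ef = edgeFeats)
  tp <- tapeNew()
  H <- tpInput(tp, h)
  p <- encoder$layers[[layer]]$heads[[head]]
  res <- .headForwardTape(tp, H, sl$src, sl$dst, sl$ef, p, config, n)
  data.frame(src = sl$src, dst = sl$dst, alpha = as.numeric(tpVal(tp, res$alpha)))
}

#' Attention-weighted message passing update
#'
#' `h'_i = sigma(sum_j alpha_ij W2 h_j)` over the same neighbourhood the
#' coefficients were computed on.
#'
#' @inheritParams attentionCoefficients
#' @param alpha data.frame from [attentionCoefficients()] (its `src`, `dst`,
#'   `alpha` columns), rows aligned to the scored edge list.
#' @return updated node feature matrix.
#' @export
messagePassingUpdate <- function(encoder, h, alpha, layer = 1L, head = 1L) {
  config <- encoder$config
  p <- encoder$layers[[layer]]$heads[[head]]
  tp <- tapeNew()
  H <- tpInput(tp, h)
  Hs <- tpGather(tp, H, alpha$src)
  msg <- tpMulColvec(tp, tpMatmul(tp, Hs, tpVal2(tp, p, "W2")),
                     tpInput(tp, matrix(alpha$alpha, ncol = 1L)))
  out <- .activate(tp, tpSegmentSum(tp, msg, alpha$dst, nrow(h)),
                   config$activation)
  tpVal(tp, out)
}

#' GCN update (symmetric-normalized, equal-weight aggregation)
#'
#' `H' = sigma(D^{-1/2} (A + I) D^{-1/2} H W + b)` -- the attention-free
#' ablation layer.
#'
#' @inheritParams attentionCoefficients
#' @param layer which layer's weights to use.
#' @return updated node feature matrix.
#' @export
gcnUpdate <- function(encoder, h, edgeIndex, layer = 1L) {
  config <- encoder$config
  stopifnot(config$variant == "gcn")
  tp <- tapeNew()
  X <- tpInput(tp, h)
  sl <- .withSelfLoops(edgeIndex, matrix(0, nrow(edgeIndex), 0L), nrow(h), 0L)
  deg <- tabulate(sl$dst, nbins = nrow(h))
  norm <- 1 / sqrt(deg[sl$src] * deg[sl$dst])
  Hs <- tpGather(tp, X, sl$src)
  agg <- tpSegmentSum(tp, tpScaleRows(tp, Hs, norm), sl$dst, nrow(h))
  lp <- encoder$layers[[layer]]
  H <- .activate(tp, tpAddRowvec(tp, tpMatmul(tp, agg, tpVal2(tp, lp, "W")),
                                 tpVal2(tp, lp, "b")), config$activation)
  tpVal(tp, H)
}

#' Encode a graph into a graph-level vector
#'
#' Applies the configured layer stack and mean-pools the node states. The
#' result is invariant to consistent node reorderings.
#'
#' @param graph a [MolecularGraph-class] or [ProteinGraph-class].
#' @param encoder from [initGraphEncoder()].
#' @return numeric vector of length `hiddenDims[nLayers]`.
#' @export
encodeGraph <- function(graph, encoder) {
  X <- nodeFeatures(graph)
  if (nrow(X) == 0L) stop("cannot encode an empty graph")
  ef <- if (methods::is(graph, "ProteinGraph"))
    matrix(edgeWeights(graph), ncol = 1L)
  else edgeFeatures(graph)
  if (encoder$config$edgeDim != ncol(ef))
    stop("encoder edgeDim does not match the graph's edge features")
  tp <- tapeNew()
  out <- .encoderForwardTape(tp, encoder, tpInput(tp, X), edgeIndex(graph),
                             ef, rep(1L, nrow(X)), 1L)
  as.numeric(tpVal(tp, out))
}
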