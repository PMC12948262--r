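# Multimodal fusion: drug and protein graph-level vectors are projected to a
# shared model width, treated as a 2-token sequence under 8-head
# self-attention (with residual), re-expanded per modality and concatenated
# back to the fused width (3072-D at the reference configuration). The
# prediction stack is FCL 3072 -> 1280 -> 320 -> 1 with batch normalization
# before each ReLU; the final activation is linear (regression) or sigmoid
# (classification).

#' Initialize fusion and prediction-head parameters
#'
#' @param drugDim,protDim graph-level vector widths (512/2560 at reference;
#'   fused width is their sum).
#' @param dModel shared token width for self-attention (must be divisible
#'   by `nHeads`).
#' @param nHeads attention heads (8 at reference).
#' @param fclDims widths of the two hidden fully-connected layers
#'   (`c(1280, 320)` at reference).
#' @param headMode `"regression"` (linear output) or `"classification"`
#'   (sigmoid output).
#' @param eps batch-normalization epsilon.
#' @param momentum running-statistics momentum.
#' @param bypassAttention skip self-attention and fuse by plain
#'   concatenation (the degenerate literal reading; useful as a control).
#' @param seed integer seed.
#' @return a fusion parameter list with elements `meta`, `theta` (trainable
#'   matrices) and `running` (batch-norm running statistics).
#' @export
initFusionParams <- function(drugDim = 512L, protDim = 2560L, dModel = 384L,
                             nHeads = 8L, fclDims = c(1280L, 320L),
                             headMode = c("regression", "classification"),
                             eps = 1e-5, momentum = 0.1,
                             bypassAttention = FALSE, seed = 1L) {
  headMode <- match.arg(headMode)
  stopifnot(dModel %% nHeads == 0L, eps > 0, length(fclDims) == 2L)
  fused <- drugDim + protDim
  dh <- dModel %/% nHeads
  theta <- withRNG(seed, {
    th <- list(Pd = .glorot(drugDim, dModel), Pp = .glorot(protDim, dModel),
               WO = .glorot(dModel, dModel),
               Ud = .glorot(dModel, drugDim), Up = .glorot(dModel, protDim),
               W1 = .glorot(fused, fclDims[1L]), b1 = matrix(0, 1L, fclDims[1L]),
               g1 = matrix(1, 1L, fclDims[1L]), be1 = matrix(0, 1L, fclDims[1L]),
               W2 = .glorot(fclDims[1L], fclDims[2L]), b2 = matrix(0, 1L, fclDims[2L]),
               g2 = matrix(1, 1L, fclDims[2L]), be2 = matrix(0, 1L, fclDims[2L]),
               W3 = .glorot(fclDims[2L], 1L), b3 = matrix(0, 1L, 1L))
    for (i in seq_len(nHeads)) {
      th[[paste0("WQ", i)]] <- .glorot(dModel, dh)
      th[[paste0("WK", i)]] <- .glorot(dModel, dh)
      th[[paste0("WV", i)]] <- .glorot(dModel, dh)
    }
    th
  })
  list(meta = list(drugDim = as.integer(drugDim), protDim = as.integer(protDim),
                   dModel = as.integer(dModel), nHeads = as.integer(nHeads),
                   fclDims = as.integer(fclDims), headMode = headMode,
                   eps = eps, momentum = momentum,
                   bypassAttention = bypassAttention),
       theta = theta,
       running = list(m1 = rep(0, fclDims[1L]), v1 = rep(1, fclDims[1L]),
                      m2 = rep(0, fclDims[2L]), v2 = rep(1, fclDims[2L])))
}

#' Batch normalization (explicit form)
#'
#' `x_hat = (x - mu_B) / sqrt(sigma_B^2 + eps) * gamma + beta` per feature,
#' with biased batch statistics in training mode and supplied running
#' statistics in inference mode. Training requires a batch of at least two
#' rows (batch variance is undefined otherwise).
#'
#' @param x numeric B x D matrix.
#' @param gamma,beta scale and shift vectors of length D.
#' @param eps variance floor constant.
#' @param training use batch statistics (TRUE) or running statistics.
#' @param runningMean,runningVar statistics used when `training = FALSE`.
#' @return B x D matrix.
#' @export
batchNorm <- function(x, gamma = rep(1, ncol(x)), beta = rep(0, ncol(x)),
                      eps = 1e-5, training = TRUE,
                      runningMean = NULL, runningVar = NULL) {
  x <- as.matrix(x)
  if (training) {
    if (nrow(x) < 2L) stop("training-mode batch norm needs at least 2 rows")
    mu <- colMeans(x)
    v <- colMeans(sweep(x, 2L, mu)^2)
  } else {
    if (is.null(runningMean) || is.null(runningVar))
      stop("inference-mode batch norm needs running statistics")
    mu <- runningMean; v <- runningVar
  }
  xn <- sweep(sweep(x, 2L, mu), 2L, sqrt(v + eps), "/")
  sweep(sweep(xn, 2L, gamma, "*"), 2L, beta, "+")
}

# tape batch norm; training mode optionally updates running stats in `runEnv`
.bnTape <- function(tp, X, gamma, beta, eps, training, rmean, rvar,
                    runEnv = NULL, slot = NULL, momentum = 0.1) {
  if (training) {
    mu <- tpColMeans(tp, X)
    Xc <- tpAddRowvec(tp, X, tpScale(tp, mu, -1))
    v <- tpColMeans(tp, tpMul(tp, Xc, Xc))
    inv <- tpRsqrt(tp, v, eps)
    if (!is.null(runEnv)) {
      m <- momentum
      runEnv$running[[paste0("m", slot)]] <-
        (1 - m) * runEnv$running[[paste0("m", slot)]] + m * as.numeric(tpVal(tp, mu))
      runEnv$running[[paste0("v", slot)]] <-
        (1 - m) * runEnv$running[[paste0("v", slot)]] + m * as.numeric(tpVal(tp, v))
    }
    Xn <- tpMulRowvec(tp, Xc, inv)
  } else {
    Xc <- tpAddRowvec(tp, X, tpInput(tp, matrix(-rmean, 1L)))
    Xn <- tpMulRowvec(tp, Xc, tpInput(tp, matrix(1 / sqrt(rvar + eps), 1L)))
  }
  tpAddRowvec(tp, tpMulRowvec(tp, Xn, gamma), beta)
}

# stable two-way softmax of two n x 1 score nodes -> list(w1, w2)
.softmax2Tape <- function(tp, s1, s2) {
  shift <- pmax(as.numeric(tpVal(tp, s1)), as.numeric(tpVal(tp, s2)))
  sh <- tpInput(tp, matrix(shift, ncol = 1L))
  e1 <- tpExp(tp, tpSub(tp, s1, sh))
  e2 <- tpExp(tp, tpSub(tp, s2, sh))
  tot <- tpRecip(tp, tpAdd(tp, e1, e2))
  list(tpMul(tp, e1, tot), tpMul(tp, e2, tot))
}

# fusion forward; Dv, Pv: n x drugDim / n x protDim nodes; th: list of node
# ids or matrices (resolved by tpVal2). Returns list(F, attn).
.fusionForwardTape <- function(tp, Dv, Pv, fp, th = NULL) {
  meta <- fp$meta
  if (is.null(th)) th <- fp$theta
  g <- function(nm) tpVal2(tp, th, nm)
  if (meta$bypassAttention)
    return(list(F = tpCbind(tp, c(Dv, Pv)), attn = NULL))
  Td <- tpMatmul(tp, Dv, g("Pd"))
  Tp <- tpMatmul(tp, Pv, g("Pp"))
  dh <- meta$dModel %/% meta$nHeads
  outD <- vector("list", meta$nHeads)
  outP <- vector("list", meta$nHeads)
  attn <- vector("list", meta$nHeads)
  for (i in seq_len(meta$nHeads)) {
    qd <- tpMatmul(tp, Td, g(paste0("WQ", i)))
    kd <- tpMatmul(tp, Td, g(paste0("WK", i)))
    vd <- tpMatmul(tp, Td, g(paste0("WV", i)))
    qp <- tpMatmul(tp, Tp, g(paste0("WQ", i)))
    kp <- tpMatmul(tp, Tp, g(paste0("WK", i)))
    vp <- tpMatmul(tp, Tp, g(paste0("WV", i)))
    sc <- 1 / sqrt(dh)
    sdd <- tpScale(tp, tpRowSums(tp, tpMul(tp, qd, kd)), sc)
    sdp <- tpScale(tp, tpRowSums(tp, tpMul(tp, qd, kp)), sc)
    spd <- tpScale(tp, tpRowSums(tp, tpMul(tp, qp, kd)), sc)
    spp <- tpScale(tp, tpRowSums(tp, tpMul(tp, qp, kp)), sc)
    wD <- .softmax2Tape(tp, sdd, sdp)   # drug token over (drug, prot)
    wP <- .softmax2Tape(tp, spd, spp)   # prot token over (drug, prot)
    outD[[i]] <- tpAdd(tp, tpMulColvec(tp, vd, wD[[1L]]),
                       tpMulColvec(tp, vp, wD[[2L]]))
    outP[[i]] <- tpAdd(tp, tpMulColvec(tp, vd, wP[[1L]]),
                       tpMulColvec(tp, vp, wP[[2L]]))
    attn[[i]] <- list(drugToken = cbind(as.numeric(tpVal(tp, wD[[1L]])),
                                        as.numeric(tpVal(tp, wD[[2L]]))),
                      protToken = cbind(as.numeric(tpVal(tp, wP[[1L]])),
                                        as.numeric(tpVal(tp, wP[[2L]]))))
  }
  AD <- tpAdd(tp, Td, tpMatmul(tp, tpCbind(tp, unlist(outD)), g("WO")))
  AP <- tpAdd(tp, Tp, tpMatmul(tp, tpCbind(tp, unlist(outP)), g("WO")))
  Fd <- tpMatmul(tp, AD, g("Ud"))
  Fp <- tpMatmul(tp, AP, g("Up"))
  list(F = tpCbind(tp, c(Fd, Fp)), attn = attn)
}

# prediction stack forward; X: fused node; returns output node (n x 1)
.predictHeadTape <- function(tp, X, fp, th = NULL, training = FALSE,
                             runEnv = NULL) {
  meta <- fp$meta
  if (is.null(th)) th <- fp$theta
  g <- function(nm) tpVal2(tp, th, nm)
  r <- fp$running
  Z1 <- tpAddRowvec(tp, tpMatmul(tp, X, g("W1")), g("b1"))
  Z1 <- .bnTape(tp, Z1, g("g1"), g("be1"), meta$eps, training, r$m1, r$v1,
                runEnv, 1L, meta$momentum)
  Z1 <- tpRelu(tp, Z1)
  Z2 <- tpAddRowvec(tp, tpMatmul(tp, Z1, g("W2")), g("b2"))
  Z2 <- .bnTape(tp, Z2, g("g2"), g("be2"), meta$eps, training, r$m2, r$v2,
                runEnv, 2L, meta$momentum)
  Z2 <- tpRelu(tp, Z2)
  Z3 <- tpAddRowvec(tp, tpMatmul(tp, Z2, g("W3")), g("b3"))
  if (meta$headMode == "classification") tpSigmoid(tp, Z3) else Z3
}

#' Fuse drug and protein vectors by multi-head self-attention
#'
#' Projects the two modality vectors to the shared token width, applies
#' multi-head self-attention over the 2-token sequence (Q, K, V per head
#' with scaled dot-product scores, outputs concatenated and mixed by `WO`,
#' residual connection), re-expands each token to its modality width and
#' concatenates: `drugDim + protDim` output features (3072 at reference).
#'
#' @param drugVec,protVec numeric vectors, or matrices with one row per
#'   example.
#' @param fp fusion parameters from [initFusionParams()].
#' @param returnAttention also return the per-head token attention weights.
#' @return fused matrix (n x fused width); with `returnAttention = TRUE`, a
#'   list `(fused, attention)` where each head reports the 2-way attention
#'   of the drug and protein tokens.
#' @export
multiHeadFuse <- function(drugVec, protVec, fp, returnAttention = FALSE) {
  D <- if (is.matrix(drugVec)) drugVec else matrix(drugVec, nrow = 1L)
  P <- if (is.matrix(protVec)) protVec else matrix(protVec, nrow = 1L)
  if (ncol(D) != fp$meta$drugDim || ncol(P) != fp$meta$protDim)
    stop("input widths do not match the fusion configuration")
  tp <- tapeNew()
  res <- .fusionForwardTape(tp, tpInput(tp, D), tpInput(tp, P), fp)
  fused <- tpVal(tp, res$F)
  if (returnAttention) list(fused = fused, attention = res$attn) else fused
}

#' Run the prediction stack on fused features
#'
#' FCL `fused -> fclDims[1] -> fclDims[2] -> 1` with batch normalization and
#' ReLU after each hidden projection; linear output in regression mode,
#' sigmoid in classification mode. Inference mode (the default) uses the
#' stored running statistics, so single examples are valid.
#'
#' @param fused numeric vector or n x fused matrix from [multiHeadFuse()].
#' @param fp fusion parameters from [initFusionParams()].
#' @param training use batch statistics (requires >= 2 rows).
#' @return numeric vector of predictions.
#' @export
predictFromFused <- function(fused, fp, training = FALSE) {
  X <- if (is.matrix(fused)) fused else matrix(fused, nrow = 1L)
  if (any(!is.finite(X))) stop("fused features must be finite")
  tp <- tapeNew()
  out <- .predictHeadTape(tp, tpInput(tp, X), fp, training = training)
  as.numeric(tpVal(tp, out))
}
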