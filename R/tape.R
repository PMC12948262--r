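# Minimal reverse-mode automatic differentiation on dense matrices.
#
# A tape is an environment holding node values, parent ids and backward
# closures in creation order; backward() walks the tape in reverse and
# accumulates gradients. All values are base-R numeric matrices. Node handles
# are plain integer ids, so composing ops costs one list append each.
#
# Internal: not exported. Gradients are verified against central finite
# differences in the test suite.

tapeNew <- function() {
  tp <- new.env(parent = emptyenv())
  tp$n <- 0L
  tp$vals <- vector("list", 256L)
  tp$parents <- vector("list", 256L)
  tp$backfns <- vector("list", 256L)
  tp
}

.tpPush <- function(tp, value, parents = integer(0), backfn = NULL) {
  n <- tp$n + 1L
  if (n > length(tp$vals)) {  # grow geometrically
    length(tp$vals) <- 2L * n
    length(tp$parents) <- 2L * n
    length(tp$backfns) <- 2L * n
  }
  tp$n <- n
  tp$vals[[n]] <- value
  tp$parents[[n]] <- parents
  if (!is.null(backfn)) tp$backfns[[n]] <- backfn
  n
}

tpVal <- function(tp, id) { force(id); tp$vals[[id]] }

# leaf (constant or parameter)
tpInput <- function(tp, x) {
  if (!is.matrix(x)) x <- matrix(x, ncol = 1L)
  .tpPush(tp, x)
}

tpMatmul <- function(tp, a, b) {
  force(a); force(b)
  A <- tp$vals[[a]]; B <- tp$vals[[b]]
  .tpPush(tp, A %*% B, c(a, b), function(g) list(g %*% t(B), crossprod(A, g)))
}

tpAdd <- function(tp, a, b) {
  force(a); force(b)
  .tpPush(tp, tp$vals[[a]] + tp$vals[[b]], c(a, b), function(g) list(g, g))
}

tpSub <- function(tp, a, b) {
  force(a); force(b)
  .tpPush(tp, tp$vals[[a]] - tp$vals[[b]], c(a, b), function(g) list(g, -g))
}

tpMul <- function(tp, a, b) {
  force(a); force(b)
  A <- tp$vals[[a]]; B <- tp$vals[[b]]
  .tpPush(tp, A * B, c(a, b), function(g) list(g * B, g * A))
}

# add a plain scalar constant
tpAddConst <- function(tp, a, s) {
  force(a)
  .tpPush(tp, tp$vals[[a]] + s, a, function(g) list(g))
}

# multiply by a plain scalar constant
tpScale <- function(tp, a, s) {
  force(a)
  .tpPush(tp, tp$vals[[a]] * s, a, function(g) list(g * s))
}

# add a 1 x D row-vector node to every row of an n x D node
tpAddRowvec <- function(tp, a, v) {
  force(a); force(v)
  A <- tp$vals[[a]]; V <- as.numeric(tp$vals[[v]])
  .tpPush(tp, A + rep(V, each = nrow(A)), c(a, v),
          function(g) list(g, matrix(colSums(g), 1L)))
}

# multiply each row of an n x D node by a 1 x D row-vector node
tpMulRowvec <- function(tp, a, v) {
  force(a); force(v)
  A <- tp$vals[[a]]; V <- as.numeric(tp$vals[[v]])
  Vr <- rep(V, each = nrow(A))
  .tpPush(tp, A * Vr, c(a, v),
          function(g) list(g * Vr, matrix(colSums(g * A), 1L)))
}

# multiply each row of an n x D node by the matching entry of an n x 1 node
tpMulColvec <- function(tp, a, v) {
  force(a); force(v)
  A <- tp$vals[[a]]; V <- as.numeric(tp$vals[[v]])
  .tpPush(tp, A * V, c(a, v),
          function(g) list(g * V, matrix(rowSums(g * A), ncol = 1L)))
}

# row-wise scaling by a constant numeric vector (no gradient for the weights)
tpScaleRows <- function(tp, a, w) {
  force(a)
  .tpPush(tp, tp$vals[[a]] * w, a, function(g) list(g * w))
}

tpGather <- function(tp, a, idx) {
  force(a)
  A <- tp$vals[[a]]
  nr <- nrow(A)
  .tpPush(tp, A[idx, , drop = FALSE], a, function(g) {
    rs <- rowsum(g, group = idx)
    if (nrow(rs) == nr) return(list(unname(rs)))   # every row hit
    out <- matrix(0, nr, ncol(g))
    out[as.integer(rownames(rs)), ] <- rs
    list(out)
  })
}

# sum rows of an m x D node into nseg segments (seg in 1..nseg)
tpSegmentSum <- function(tp, a, seg, nseg) {
  force(a)
  A <- tp$vals[[a]]
  rs <- rowsum(A, group = seg)
  out <- if (nrow(rs) == nseg) unname(rs) else {
    o <- matrix(0, nseg, ncol(A))
    o[as.integer(rownames(rs)), ] <- rs
    o
  }
  .tpPush(tp, out, a, function(g) list(g[seg, , drop = FALSE]))
}

tpCbind <- function(tp, ids) {
  force(ids)
  vals <- lapply(ids, function(i) tp$vals[[i]])
  widths <- vapply(vals, ncol, 0L)
  ends <- cumsum(widths)
  starts <- c(1L, head(ends, -1L) + 1L)
  .tpPush(tp, do.call(cbind, vals), ids, function(g) {
    lapply(seq_along(widths),
           function(k) g[, starts[k]:ends[k], drop = FALSE])
  })
}

tpLeakyRelu <- function(tp, a, slope = 0.2) {
  force(a)
  A <- tp$vals[[a]]
  pos <- A > 0
  .tpPush(tp, pmax(A, 0) + slope * pmin(A, 0), a,
          function(g) list(g * (slope + (1 - slope) * pos)))
}

tpRelu <- function(tp, a) {
  force(a)
  A <- tp$vals[[a]]
  .tpPush(tp, pmax(A, 0), a, function(g) list(g * (A > 0)))
}

tpElu <- function(tp, a) {
  force(a)
  A <- tp$vals[[a]]
  neg <- expm1(pmin(A, 0))       # 0 where A >= 0
  V <- pmax(A, 0) + neg
  .tpPush(tp, V, a, function(g) list(g * ((A > 0) + (A <= 0) * (neg + 1))))
}

tpSigmoid <- function(tp, a) {
  force(a)
  V <- 1 / (1 + exp(-tp$vals[[a]]))
  .tpPush(tp, V, a, function(g) list(g * V * (1 - V)))
}

# log(1 + exp(x)), overflow-safe
tpSoftplus <- function(tp, a) {
  force(a)
  A <- tp$vals[[a]]
  V <- pmax(A, 0) + log1p(exp(-abs(A)))
  .tpPush(tp, V, a, function(g) list(g / (1 + exp(-A))))
}

tpExp <- function(tp, a) {
  force(a)
  V <- exp(tp$vals[[a]])
  .tpPush(tp, V, a, function(g) list(g * V))
}

tpLog <- function(tp, a) {
  force(a)
  A <- tp$vals[[a]]
  .tpPush(tp, log(A), a, function(g) list(g / A))
}

tpRecip <- function(tp, a) {
  force(a)
  A <- tp$vals[[a]]
  .tpPush(tp, 1 / A, a, function(g) list(-g / (A * A)))
}

# 1/sqrt(x + eps), used by batch normalization
tpRsqrt <- function(tp, a, eps = 0) {
  force(a)
  A <- tp$vals[[a]] + eps
  V <- 1 / sqrt(A)
  .tpPush(tp, V, a, function(g) list(-0.5 * g * V / A))
}

tpColMeans <- function(tp, a) {
  force(a)
  A <- tp$vals[[a]]
  n <- nrow(A)
  .tpPush(tp, matrix(colMeans(A), 1L), a,
          function(g) list(matrix(rep(as.numeric(g) / n, each = n), n)))
}

tpRowSums <- function(tp, a) {
  force(a)
  A <- tp$vals[[a]]
  .tpPush(tp, matrix(rowSums(A), ncol = 1L), a,
          function(g) list(matrix(as.numeric(g), nrow(A), ncol(A))))
}

tpMean <- function(tp, a) {
  force(a)
  A <- tp$vals[[a]]
  .tpPush(tp, matrix(mean(A)), a,
          function(g) list(matrix(as.numeric(g) / length(A), nrow(A), ncol(A))))
}

# softmax of a m x 1 score node within segments (numerically shifted by the
# global max, treated as a constant -- softmax is shift invariant so the
# gradient is unaffected)
tpSegmentSoftmax <- function(tp, score, seg, nseg) {
  force(score)
  shift <- max(tp$vals[[score]])
  e <- tpExp(tp, tpAddConst(tp, score, -shift))
  tot <- tpSegmentSum(tp, e, seg, nseg)
  tpMul(tp, e, tpRecip(tp, tpGather(tp, tot, seg)))
}

tpTranspose <- function(tp, a) {
  force(a)
  .tpPush(tp, t(tp$vals[[a]]), a, function(g) list(t(g)))
}

# multiply the h-th block of dh columns of `a` (m x H*dh) by column h of
# `alpha` (m x H); used to scale per-head messages by attention in one op
tpMulColBlocks <- function(tp, a, alpha, dh) {
  force(a); force(alpha)
  A <- tp$vals[[a]]; AL <- tp$vals[[alpha]]
  H <- ncol(AL)
  expIdx <- rep(seq_len(H), each = dh)
  ALx <- AL[, expIdx, drop = FALSE]
  fold <- matrix(0, H * dh, H)
  fold[cbind(seq_len(H * dh), expIdx)] <- 1
  .tpPush(tp, A * ALx, c(a, alpha),
          function(g) list(g * ALx, (g * A) %*% fold))
}

# reverse sweep; returns gradients for the requested leaf ids
tpBackward <- function(tp, loss, wrt) {
  grads <- vector("list", tp$n)
  g0 <- tp$vals[[loss]]
  grads[[loss]] <- matrix(1, nrow(g0), ncol(g0))
  for (id in tp$n:1L) {
    g <- grads[[id]]
    if (is.null(g)) next
    bf <- tp$backfns[[id]]
    if (is.null(bf)) next
    pg <- bf(g)
    ps <- tp$parents[[id]]
    for (k in seq_along(ps)) {
      p <- ps[k]
      grads[[p]] <- if (is.null(grads[[p]])) pg[[k]] else grads[[p]] + pg[[k]]
    }
    grads[id] <- list(NULL)  # free as we go
  }
  lapply(wrt, function(i) {
    g <- grads[[i]]
    if (is.null(g)) matrix(0, nrow(tp$vals[[i]]), ncol(tp$vals[[i]])) else g
  })
}
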