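# Model assembly, dataset featurization and the training loop (full-batch
# Adam on the autodiff tape). Graph encodings are computed once per step for
# the unique drugs/proteins and gathered per record, which keeps a full
# forward/backward pass to a handful of dense matrix operations.

#' Featurize an affinity dataset
#'
#' Builds one [MolecularGraph-class] per unique drug and one
#' [ProteinGraph-class] per unique protein, and indexes every record against
#' them. Protein coordinates are taken from `coords` (a named list keyed by
#' protein id, or a function `(sequence, proteinId) -> M x 3` acting as a
#' structure provider); synthetic datasets carry their coordinates in
#' `@metadata$coords`.
#'
#' @param dataset an [AffinityDataset-class].
#' @param atomProvider,residueProvider embedding providers.
#' @param coords per-protein C-alpha coordinates (see above); defaults to
#'   the dataset metadata.
#' @param cutoff contact cutoff in Angstrom.
#' @return a `DTAFeatures` list: `records` (with `drugIdx`, `protIdx`),
#'   `drugGraphs`, `protGraphs`, `drugDim`, `protDim`.
#' @export
featurizeDataset <- function(dataset, atomProvider, residueProvider,
                             coords = NULL, cutoff = 8.0) {
  rec <- records(dataset)
  if (is.null(coords)) coords <- dataset@metadata$coords
  if (is.null(coords)) stop("no coordinates: pass `coords` or use a dataset carrying them")
  drugs <- rec[!duplicated(rec$drugId), c("drugId", "drugSmiles")]
  prots <- rec[!duplicated(rec$proteinId), c("proteinId", "proteinSequence")]
  drugGraphs <- lapply(seq_len(nrow(drugs)), function(i)
    buildMolecularGraph(drugs$drugSmiles[i], atomProvider))
  names(drugGraphs) <- drugs$drugId
  protGraphs <- lapply(seq_len(nrow(prots)), function(i) {
    id <- prots$proteinId[i]; sq <- prots$proteinSequence[i]
    cc <- if (is.function(coords)) coords(sq, id) else coords[[id]]
    if (is.null(cc)) stop("no coordinates for protein ", id)
    buildProteinGraph(sq, cc, residueProvider, cutoff = cutoff)
  })
  names(protGraphs) <- prots$proteinId
  rec$drugIdx <- match(rec$drugId, drugs$drugId)
  rec$protIdx <- match(rec$proteinId, prots$proteinId)
  structure(list(records = rec, drugGraphs = drugGraphs,
                 protGraphs = protGraphs,
                 drugDim = atomProvider@dim, protDim = residueProvider@dim),
            class = "DTAFeatures")
}

# concatenate graphs into one batched block: node matrix, global edge list,
# edge features, node -> graph segment ids, raw per-graph feature means
.batchGraphs <- function(graphs, type = c("drug", "protein")) {
  type <- match.arg(type)
  ns <- vapply(graphs, numNodes, 0L)
  offs <- cumsum(c(0L, ns[-length(ns)]))
  X <- do.call(rbind, lapply(graphs, nodeFeatures))
  eis <- lapply(seq_along(graphs), function(i) edgeIndex(graphs[[i]]) + offs[i])
  ei <- do.call(rbind, eis)
  ef <- if (type == "drug") do.call(rbind, lapply(graphs, edgeFeatures))
  else matrix(unlist(lapply(graphs, edgeWeights)), ncol = 1L)
  gid <- rep(seq_along(graphs), ns)
  means <- t(vapply(graphs, function(g) colMeans(nodeFeatures(g)),
                    numeric(ncol(X))))
  list(X = X, edgeIndex = ei, edgeFeats = ef, graphId = gid,
       nGraphs = length(graphs), means = means)
}

#' Assemble a dual-graph affinity model
#'
#' Maps an ablation variant to a concrete architecture: `"full"` uses the
#' configured encoder (GATv2 by default) on both graphs; `"wo_MG"`/
#' `"wo_PG"` bypass the corresponding encoder and feed the column mean of
#' the raw provider node features; `"wo_MG_PG"` bypasses both (no graph
#' layers at all); `"wo_AM"` swaps the encoders for GCN; `"wo_DAM"` swaps
#' them for static-attention GAT.
#'
#' @param variant one of `full`, `wo_MG`, `wo_PG`, `wo_MG_PG`, `wo_AM`,
#'   `wo_DAM`.
#' @param drugDim,protDim node embedding widths (512/2560 at reference).
#' @param nLayers encoder depth (3 at reference).
#' @param heads encoder attention heads per layer.
#' @param dModel,nFusionHeads,fclDims fusion configuration (384/8/
#'   `c(1280, 320)` at reference).
#' @param headMode `"regression"` or `"classification"`.
#' @param scoreMode encoder score mode (see [graphEncoderConfig()]).
#' @param seed integer seed for parameter initialization.
#' @param ... further arguments to [graphEncoderConfig()].
#' @return an untrained [DTAModel-class].
#' @examples
#' m <- assembleModel("full", drugDim = 8, protDim = 12, heads = 2,
#'                    dModel = 8, fclDims = c(16, 8))
#' m
#' @export
assembleModel <- function(variant = c("full", "wo_MG", "wo_PG", "wo_MG_PG",
                                      "wo_AM", "wo_DAM"),
                          drugDim = 512L, protDim = 2560L, nLayers = 3L,
                          heads = 4L, dModel = 384L, nFusionHeads = 8L,
                          fclDims = c(1280L, 320L),
                          headMode = "regression",
                          scoreMode = "gatv2_canonical", seed = 1L, ...) {
  variant <- match.arg(variant)
  encVariant <- switch(variant, wo_AM = "gcn", wo_DAM = "gat", "gatv2")
  needDrug <- !variant %in% c("wo_MG", "wo_MG_PG")
  needProt <- !variant %in% c("wo_PG", "wo_MG_PG")
  # per-head hidden width dim/heads on concatenating layers keeps every
  # layer at the embedding width, and the final (averaged) layer restores
  # it, so graph-level vectors concatenate to drugDim + protDim
  encHidden <- function(dim) {
    if (encVariant == "gcn") return(rep(as.integer(dim), nLayers))
    c(rep(max(1L, dim %/% heads), max(0L, nLayers - 1L)), as.integer(dim))
  }
  drugEnc <- if (needDrug)
    initGraphEncoder(graphEncoderConfig(drugDim, edgeDim = 6L,
                                        variant = encVariant,
                                        nLayers = nLayers, heads = heads,
                                        hiddenDims = encHidden(drugDim),
                                        scoreMode = scoreMode, ...),
                     seed = seed)
  else list()
  protEnc <- if (needProt)
    initGraphEncoder(graphEncoderConfig(protDim, edgeDim = 1L,
                                        variant = encVariant,
                                        nLayers = nLayers, heads = heads,
                                        hiddenDims = encHidden(protDim),
                                        scoreMode = scoreMode, ...),
                     seed = seed + 1L)
  else list()
  fusion <- initFusionParams(drugDim, protDim, dModel = dModel,
                             nHeads = nFusionHeads, fclDims = fclDims,
                             headMode = headMode, seed = seed + 2L)
  methods::new("DTAModel", variant = variant, drugEncoder = drugEnc,
               protEncoder = protEnc, fusion = fusion,
               config = list(drugDim = as.integer(drugDim),
                             protDim = as.integer(protDim),
                             encoderVariant = encVariant,
                             nLayers = as.integer(nLayers),
                             headMode = headMode, seed = as.integer(seed)))
}

#' Widths of the fused vector and prediction stack
#'
#' @param model a [DTAModel-class].
#' @return list with `fusedDim` and `fclDims` (hidden widths then 1).
#' @export
modelDimensions <- function(model) {
  th <- model@fusion$theta
  list(fusedDim = nrow(th$W1),
       fclDims = c(ncol(th$W1), ncol(th$W2), ncol(th$W3)))
}

# ---- parameter flattening for the optimizer -------------------------------

# collect matrix leaves of a nested list, depth-first, with their paths
.paramLeaves <- function(x, path = integer(0)) {
  if (is.matrix(x)) return(list(list(path = path, value = x)))
  if (is.list(x)) {
    nms <- names(x)
    out <- list()
    for (k in seq_along(x)) {
      nm <- if (!is.null(nms)) nms[k] else ""
      if (nm %in% c("config", "meta", "running", "dk")) next
      out <- c(out, .paramLeaves(x[[k]], c(path, k)))
    }
    return(out)
  }
  list()
}

.setPath <- function(x, path, value) {
  if (length(path) == 1L) { x[[path]] <- value; return(x) }
  x[[path[1L]]] <- .setPath(x[[path[1L]]], path[-1L], value)
  x
}

# register every matrix leaf on the tape; returns the same structure with
# leaves replaced by node ids, plus the id vector in leaf order
.tapeParams <- function(tp, struct) {
  leaves <- .paramLeaves(struct)
  ids <- integer(length(leaves))
  for (k in seq_along(leaves)) {
    ids[k] <- tpInput(tp, leaves[[k]]$value)
    struct <- .setPath(struct, leaves[[k]]$path, ids[k])
  }
  list(struct = struct, ids = ids, leaves = leaves)
}

# ---- forward pass over a record batch -------------------------------------

# forward for record indices `idx`; returns list(pred node id, tape)
.modelForwardTape <- function(tp, model, bd, bp, recIdx, features, params,
                              training, runEnv = NULL) {
  rec <- features$records
  di <- rec$drugIdx[recIdx]
  pi_ <- rec$protIdx[recIdx]
  Dv <- if (length(model@drugEncoder)) {
    enc <- .encoderForwardTape(tp, model@drugEncoder, tpInput(tp, bd$X),
                               bd$edgeIndex, bd$edgeFeats, bd$graphId,
                               bd$nGraphs, params = params$drugLayers)
    tpGather(tp, enc, di)
  } else tpGather(tp, tpInput(tp, bd$means), di)
  Pv <- if (length(model@protEncoder)) {
    enc <- .encoderForwardTape(tp, model@protEncoder, tpInput(tp, bp$X),
                               bp$edgeIndex, bp$edgeFeats, bp$graphId,
                               bp$nGraphs, params = params$protLayers)
    tpGather(tp, enc, pi_)
  } else tpGather(tp, tpInput(tp, bp$means), pi_)
  fus <- .fusionForwardTape(tp, Dv, Pv, model@fusion, th = params$fusionTheta)
  .predictHeadTape(tp, fus$F, model@fusion, th = params$fusionTheta,
                   training = training, runEnv = runEnv)
}

#' Training configuration
#'
#' @param epochs maximum training epochs (full-batch steps by default).
#' @param batchSize records per step; `Inf` trains full-batch.
#' @param learningRate Adam step size.
#' @param optimizer only `"adam"`.
#' @param seed seed fixing initialization, the train/validation split and
#'   shuffling.
#' @param loss `"mse"` (regression) or `"bce"` (classification, on logits).
#' @param earlyStopPatience epochs without validation improvement before
#'   stopping; the best-validation parameters are restored.
#' @param valFraction fraction of the training records held out for
#'   validation-based early stopping; 0 disables the hold-out and tracks
#'   the training loss instead.
#' @param warmupEpochs linear learning-rate warmup over the first epochs.
#' @param restarts independent re-initializations; the run with the best
#'   validation loss is kept (guards against unlucky initializations).
#' @param weightDecay decoupled L2 weight decay applied at each step.
#' @param clipNorm global gradient-norm clipping threshold.
#' @param verbose print per-epoch losses.
#' @return a config list for [trainModel()].
#' @export
trainConfig <- function(epochs = 150L, batchSize = Inf, learningRate = 5e-3,
                        optimizer = "adam", seed = 1L,
                        loss = c("mse", "bce"), earlyStopPatience = 25L,
                        valFraction = 0.1, weightDecay = 1e-4, clipNorm = 5,
                        warmupEpochs = 0L, restarts = 1L, verbose = FALSE) {
  loss <- match.arg(loss)
  stopifnot(epochs >= 1, learningRate > 0, optimizer == "adam", clipNorm > 0,
            weightDecay >= 0)
  list(epochs = as.integer(epochs), batchSize = batchSize,
       learningRate = learningRate, optimizer = optimizer,
       seed = as.integer(seed), loss = loss,
       earlyStopPatience = as.integer(earlyStopPatience),
       valFraction = valFraction, weightDecay = weightDecay,
       clipNorm = clipNorm, warmupEpochs = as.integer(warmupEpochs),
       restarts = as.integer(restarts), verbose = isTRUE(verbose))
}

#' Train a dual-graph affinity model
#'
#' Full-batch (or mini-batch) Adam with validation-based early stopping;
#' the returned model carries the best-validation parameters and the
#' per-epoch loss history. Deterministic for a fixed `config$seed`.
#'
#' @param model an untrained [DTAModel-class] from [assembleModel()] (or a
#'   trained one to continue from).
#' @param features a `DTAFeatures` object from [featurizeDataset()].
#' @param config from [trainConfig()].
#' @param trainIdx record indices to train on (default: all records).
#' @return the trained [DTAModel-class].
#' @export
trainModel <- function(model, features, config = trainConfig(),
                       trainIdx = seq_len(nrow(features$records))) {
  labels <- features$records$labelValue
  if (config$loss == "mse") {
    # standardize the regression target on the training records; predictions
    # are mapped back by predictAffinity()
    ctr <- mean(labels[trainIdx])
    scl <- stats::sd(labels[trainIdx])
    if (!is.finite(scl) || scl == 0) scl <- 1
    model@config$labelCenter <- ctr
    model@config$labelScale <- scl
    labels <- (labels - ctr) / scl
  }
  bd <- .batchGraphs(features$drugGraphs, "drug")
  bp <- .batchGraphs(features$protGraphs, "protein")
  if (length(trainIdx) < 4L) stop("need at least 4 training records")

  best <- NULL
  for (r in seq_len(config$restarts)) {
    mr <- if (r == 1L) model else .reinitModel(model, config$seed + 101L * r)
    res <- .trainLoop(mr, features, config, trainIdx, labels, bd, bp,
                      runSeed = config$seed + 101L * (r - 1L))
    if (is.null(best) || res$bestLoss < best$bestLoss) best <- res
  }
  out <- .modelWithParams(best$model, best$struct, best$running)
  out@config <- model@config
  out@history <- best$history
  out@trained <- TRUE
  out
}

# fresh parameter draw with the architecture of an existing model
.reinitModel <- function(model, seed) {
  if (length(model@drugEncoder))
    model@drugEncoder <- initGraphEncoder(model@drugEncoder$config, seed = seed)
  if (length(model@protEncoder))
    model@protEncoder <- initGraphEncoder(model@protEncoder$config,
                                          seed = seed + 1L)
  meta <- model@fusion$meta
  model@fusion <- initFusionParams(meta$drugDim, meta$protDim,
                                   dModel = meta$dModel, nHeads = meta$nHeads,
                                   fclDims = meta$fclDims,
                                   headMode = meta$headMode, eps = meta$eps,
                                   momentum = meta$momentum,
                                   bypassAttention = meta$bypassAttention,
                                   seed = seed + 2L)
  model
}

# one optimization run; returns the best-validation state and its loss
.trainLoop <- function(model, features, config, trainIdx, labels, bd, bp,
                       runSeed) {
  nTrain <- length(trainIdx)
  struct <- list(drugLayers = if (length(model@drugEncoder)) model@drugEncoder$layers,
                 protLayers = if (length(model@protEncoder)) model@protEncoder$layers,
                 fusionTheta = model@fusion$theta)
  leaves0 <- .paramLeaves(struct)
  values <- lapply(leaves0, `[[`, "value")
  mAdam <- lapply(values, function(v) v * 0)
  vAdam <- lapply(values, function(v) v * 0)
  b1 <- 0.9; b2 <- 0.999; epsA <- 1e-8

  runEnv <- new.env(parent = emptyenv())
  runEnv$running <- model@fusion$running

  history <- data.frame()
  best <- list(loss = Inf, values = values, running = runEnv$running)
  wait <- 0L

  withRNG(runSeed, {
    if (config$valFraction > 0) {
      nVal <- max(2L, round(config$valFraction * nTrain))
      vsel <- sample(nTrain, nVal)
      valIdx <- trainIdx[vsel]
      fitIdx <- trainIdx[-vsel]
    } else {
      # no hold-out: early stopping tracks the training records instead
      valIdx <- trainIdx
      fitIdx <- trainIdx
    }
    yVal <- labels[valIdx]
    bs <- if (!is.finite(config$batchSize)) length(fitIdx)
          else min(config$batchSize, length(fitIdx))
    step <- 0L

    for (epoch in seq_len(config$epochs)) {
      lr <- config$learningRate *
        (if (config$warmupEpochs > 0L)
           min(1, epoch / config$warmupEpochs) else 1)
      ord <- if (bs < length(fitIdx)) sample(length(fitIdx)) else seq_along(fitIdx)
      epochLoss <- 0; nb <- 0L
      for (start in seq(1L, length(fitIdx), by = bs)) {
        sel <- ord[start:min(start + bs - 1L, length(fitIdx))]
        if (length(sel) < 2L) next  # batch norm needs >= 2 rows
        idx <- fitIdx[sel]
        tp <- tapeNew()
        reg <- .tapeParams(tp, struct)
        # refresh leaf values on the tape with current optimizer state
        for (k in seq_along(reg$ids)) tp$vals[[reg$ids[k]]] <- values[[k]]
        pred <- .modelForwardTape(tp, model, bd, bp, idx, features,
                                  reg$struct, training = TRUE,
                                  runEnv = runEnv)
        yNode <- tpInput(tp, matrix(labels[idx], ncol = 1L))
        loss <- if (config$loss == "mse") {
          d <- tpSub(tp, pred, yNode)
          tpMean(tp, tpMul(tp, d, d))
        } else {
          # bce on logits: mean(softplus(z) - y * z)
          tpMean(tp, tpSub(tp, tpSoftplus(tp, pred), tpMul(tp, yNode, pred)))
        }
        lv <- as.numeric(tpVal(tp, loss))
        if (!is.finite(lv)) stop("non-finite training loss at epoch ", epoch,
                                 " (diverged; lower the learning rate)")
        grads <- tpBackward(tp, loss, reg$ids)
        # global-norm gradient clipping stabilizes occasional bad seeds
        gnorm <- sqrt(sum(vapply(grads, function(g) sum(g * g), 0)))
        clip <- if (gnorm > config$clipNorm) config$clipNorm / gnorm else 1
        step <- step + 1L
        for (k in seq_along(values)) {
          gk <- grads[[k]] * clip
          mAdam[[k]] <- b1 * mAdam[[k]] + (1 - b1) * gk
          vAdam[[k]] <- b2 * vAdam[[k]] + (1 - b2) * gk * gk
          mh <- mAdam[[k]] / (1 - b1^step)
          vh <- vAdam[[k]] / (1 - b2^step)
          values[[k]] <- values[[k]] * (1 - lr * config$weightDecay) -
            lr * mh / (sqrt(vh) + epsA)
        }
        epochLoss <- epochLoss + lv; nb <- nb + 1L
      }
      # validation in eval mode with current running stats
      for (k in seq_along(values))
        struct <- .setPath(struct, leaves0[[k]]$path, values[[k]])
      modelNow <- .modelWithParams(model, struct, runEnv$running)
      pv <- .predictRecords(modelNow, features, bd, bp, valIdx)
      valLoss <- if (config$loss == "mse") mean((pv - yVal)^2)
      else mean(ifelse(pv > 30, pv, log1p(exp(pmin(pv, 30)))) - yVal * pv)
      if (!is.finite(valLoss))
        stop("non-finite validation loss at epoch ", epoch,
             " (diverged; lower the learning rate)")
      history <- rbind(history, data.frame(epoch = epoch,
                                           trainLoss = epochLoss / max(nb, 1L),
                                           valLoss = valLoss))
      if (config$verbose)
        message(sprintf("epoch %3d  train %.5f  val %.5f", epoch,
                        epochLoss / max(nb, 1L), valLoss))
      if (valLoss < best$loss - 1e-9) {
        best <- list(loss = valLoss, values = values, running = runEnv$running)
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= config$earlyStopPatience) break
      }
    }
  })
  for (k in seq_along(best$values))
    struct <- .setPath(struct, leaves0[[k]]$path, best$values[[k]])
  list(model = model, struct = struct, running = best$running,
       history = history, bestLoss = best$loss)
}

# write a parameter structure back into a model object
.modelWithParams <- function(model, struct, running) {
  if (length(model@drugEncoder)) model@drugEncoder$layers <- struct$drugLayers
  if (length(model@protEncoder)) model@protEncoder$layers <- struct$protLayers
  model@fusion$theta <- struct$fusionTheta
  model@fusion$running <- running
  model
}

# eval-mode predictions for record indices (values only, standardized scale)
.predictRecords <- function(model, features, bd, bp, idx) {
  params <- list(drugLayers = if (length(model@drugEncoder)) model@drugEncoder$layers,
                 protLayers = if (length(model@protEncoder)) model@protEncoder$layers,
                 fusionTheta = model@fusion$theta)
  tp <- tapeNew()
  out <- .modelForwardTape(tp, model, bd, bp, idx, features, params,
                           training = FALSE)
  as.numeric(tpVal(tp, out))
}

#' Predict affinities for records of a featurized dataset
#'
#' Runs the model in inference mode (batch-norm running statistics), so any
#' number of records -- including a single one -- is valid. Classification
#' models return probabilities in `(0, 1)`.
#'
#' @param model a trained [DTAModel-class].
#' @param features a `DTAFeatures` object.
#' @param idx record indices (default: all).
#' @return numeric vector of predictions.
#' @export
predictAffinity <- function(model, features, idx = seq_len(nrow(features$records))) {
  bd <- .batchGraphs(features$drugGraphs, "drug")
  bp <- .batchGraphs(features$protGraphs, "protein")
  p <- .predictRecords(model, features, bd, bp, idx)
  if (!is.null(model@config$labelCenter))
    p <- p * model@config$labelScale + model@config$labelCenter
  p
}
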