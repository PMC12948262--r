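#' @import methods
NULL

#' Molecular graph of a small molecule
#'
#' Atoms are nodes carrying provider-supplied embeddings (512-D for the
#' reference provider); every covalent bond contributes two directed edges
#' with identical 6-D one-hot features encoding bond type (single, double,
#' triple, aromatic), conjugation and a pi-capable hybridization flag.
#' Hydrogens are implicit: only heavy atoms appear.
#'
#' @slot smiles SMILES string the graph was built from.
#' @slot nodeFeatures numeric matrix, one row per heavy atom, in the parsed
#'   atom order shared with the embedding provider.
#' @slot edgeIndex integer matrix with columns `src`, `dst` (1-based).
#' @slot edgeFeatures numeric matrix (edges x 6) of 0/1 bond features.
#'
#' @seealso [buildMolecularGraph()], [encodeBondFeatures()]
#' @export
setClass("MolecularGraph",
  representation(smiles = "character", nodeFeatures = "matrix",
                 edgeIndex = "matrix", edgeFeatures = "matrix"))

setValidity("MolecularGraph", function(object) {
  n <- nrow(object@nodeFeatures)
  ei <- object@edgeIndex
  ef <- object@edgeFeatures
  msgs <- character(0)
  if (ncol(ei) != 2L && nrow(ei) > 0L)
    msgs <- c(msgs, "edgeIndex must have two columns (src, dst)")
  if (nrow(ei) != nrow(ef))
    msgs <- c(msgs, "edgeIndex and edgeFeatures disagree on edge count")
  if (nrow(ei) > 0L) {
    if (any(ei < 1L) || any(ei > n))
      msgs <- c(msgs, "edge endpoints out of node range")
    if (any(ei[, 1L] == ei[, 2L]))
      msgs <- c(msgs, "self-edges are not allowed at construction time")
    if (ncol(ef) != 6L)
      msgs <- c(msgs, "edgeFeatures must have 6 columns")
    else {
      if (!all(ef %in% c(0, 1)))
        msgs <- c(msgs, "edgeFeatures must be 0/1")
      if (any(rowSums(ef[, 1:4, drop = FALSE]) != 1))
        msgs <- c(msgs, "bond-type bits (first four) must be one-hot")
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' Residue-level protein contact graph
#'
#' Residues are nodes carrying provider-supplied embeddings (2560-D for the
#' reference provider). A directed edge `(i, j)` exists iff `i != j` and the
#' C-alpha Euclidean distance `d(i, j)` is at most `cutoff` (8 Angstrom by
#' default, inclusive); its weight is `1/d(i, j)` in 1/Angstrom. The edge set
#' is symmetric with equal weights in both directions.
#'
#' @slot sequence single-letter amino-acid string.
#' @slot coords numeric matrix (residues x 3) of C-alpha coordinates in
#'   Angstrom.
#' @slot nodeFeatures numeric matrix, one row per residue.
#' @slot edgeIndex integer matrix with columns `src`, `dst`.
#' @slot edgeWeights numeric vector of inverse distances (1/Angstrom).
#' @slot cutoff contact cutoff in Angstrom.
#'
#' @seealso [buildProteinGraph()]
#' @export
setClass("ProteinGraph",
  representation(sequence = "character", coords = "matrix",
                 nodeFeatures = "matrix", edgeIndex = "matrix",
                 edgeWeights = "numeric", cutoff = "numeric"))

setValidity("ProteinGraph", function(object) {
  m <- nrow(object@coords)
  msgs <- character(0)
  if (nchar(object@sequence) != m)
    msgs <- c(msgs, "sequence length must equal coordinate row count")
  if (nrow(object@nodeFeatures) != m)
    msgs <- c(msgs, "nodeFeatures row count must equal residue count")
  if (nrow(object@edgeIndex) != length(object@edgeWeights))
    msgs <- c(msgs, "edgeIndex and edgeWeights disagree on edge count")
  if (length(object@edgeWeights) &&
      any(object@edgeWeights < 1 / object@cutoff - 1e-9))
    msgs <- c(msgs, "edge weights must be >= 1/cutoff")
  if (length(msgs)) msgs else TRUE
})

#' A table of drug-protein affinity records
#'
#' One row per measured pair: drug identifier and SMILES, protein identifier
#' and sequence, a numeric label and its kind (`pKd`, `KIBA`, `pIC50` or
#' `binary`). Built by [readAffinityTable()] or
#' [generateSyntheticDataset()].
#'
#' @slot records data.frame with columns `drugId`, `drugSmiles`, `proteinId`,
#'   `proteinSequence`, `labelValue`, `labelKind`.
#' @slot metadata list of optional extras (e.g. per-protein C-alpha
#'   coordinates for synthetic datasets, rejection log from file loading).
#' @export
setClass("AffinityDataset",
  representation(records = "data.frame", metadata = "list"),
  prototype(metadata = list()))

setValidity("AffinityDataset", function(object) {
  need <- c("drugId", "drugSmiles", "proteinId", "proteinSequence",
            "labelValue", "labelKind")
  miss <- setdiff(need, names(object@records))
  if (length(miss))
    return(paste("records is missing columns:", paste(miss, collapse = ", ")))
  kinds <- unique(object@records$labelKind)
  bad <- setdiff(kinds, c("pKd", "KIBA", "pIC50", "binary"))
  if (length(bad)) return(paste("unknown labelKind:", paste(bad, collapse = ", ")))
  binv <- object@records$labelValue[object@records$labelKind == "binary"]
  if (length(binv) && !all(binv %in% c(0, 1)))
    return("binary labels must be 0 or 1")
  if (any(!is.finite(object@records$labelValue)))
    return("labelValue must be finite")
  TRUE
})

#' Cross-validation fold assignment
#'
#' Deterministic record-level partition into `k` folds whose sizes differ by
#' at most one; regenerating with the same record count, `k` and `seed`
#' reproduces the identical assignment.
#'
#' @slot foldOf integer vector mapping record index to fold id in `0..k-1`.
#' @slot k number of folds.
#' @slot seed integer seed the assignment was drawn with.
#' @seealso [makeCvFolds()]
#' @export
setClass("DatasetSplit",
  representation(foldOf = "integer", k = "integer", seed = "integer"))

setValidity("DatasetSplit", function(object) {
  sizes <- tabulate(object@foldOf + 1L, nbins = object@k)
  if (any(object@foldOf < 0L) || any(object@foldOf >= object@k))
    return("fold ids must lie in 0..k-1")
  if (length(object@foldOf) >= object@k && diff(range(sizes)) > 1L)
    return("fold sizes must differ by at most one")
  TRUE
})

#' Fold-wise evaluation metrics
#'
#' Regression reports carry per-fold MSE, MAE, Pearson r, concordance index
#' and rm-squared; classification reports carry ACC, AUC, balanced accuracy,
#' MCC and F1. `summary()` adds mean and standard deviation per metric.
#'
#' @slot perFold data.frame, one row per fold/run.
#' @slot task `"regression"` or `"classification"`.
#' @export
setClass("MetricsReport",
  representation(perFold = "data.frame", task = "character"))

#' Embedding and structure providers
#'
#' Providers decouple featurization from any particular pretrained model:
#' the reference configuration expects 512-D atom embeddings and 2560-D
#' residue embeddings, but any deterministic source of row-aligned matrices
#' satisfies the contract. `MockAtomProvider` and `MockResidueProvider` hash
#' local chemical identity into fixed pseudo-random vectors so the pipeline
#' runs without downloads; `PrecomputedProvider` serves matrices precomputed
#' elsewhere (e.g. real pretrained embedders) keyed by input string.
#'
#' @slot name provider label recorded in run manifests.
#' @slot dim embedding dimensionality.
#' @aliases MockAtomProvider-class MockResidueProvider-class
#'   PrecomputedProvider-class
#' @export
setClass("EmbeddingProvider",
  representation("VIRTUAL", name = "character", dim = "integer"))

#' @rdname EmbeddingProvider-class
#' @slot seed integer seed mixed into the identity hash.
#' @export
setClass("MockAtomProvider", contains = "EmbeddingProvider",
  representation(seed = "integer"))

#' @rdname EmbeddingProvider-class
#' @export
setClass("MockResidueProvider", contains = "EmbeddingProvider",
  representation(seed = "integer"))

#' @rdname EmbeddingProvider-class
#' @slot matrices named list of embedding matrices keyed by SMILES/sequence.
#' @export
setClass("PrecomputedProvider", contains = "EmbeddingProvider",
  representation(matrices = "list"))

#' Assembled dual-graph affinity model
#'
#' Holds the encoder and fusion parameters of one model variant, together
#' with the configuration it was assembled from and its training history.
#' Variants: `"full"` (GATv2 on both graphs), `"wo_MG"`/`"wo_PG"` (replace
#' one graph encoder by the mean of raw provider features), `"wo_MG_PG"`
#' (both), `"wo_AM"` (GCN layers), `"wo_DAM"` (static-attention GAT layers).
#'
#' @slot variant one of the six assembly recipes.
#' @slot drugEncoder,protEncoder encoder parameter lists (empty when that
#'   side is ablated).
#' @slot fusion fusion/prediction-head parameter list.
#' @slot config assembly configuration (dimensions, heads, score mode, ...).
#' @slot history data.frame of per-epoch training/validation loss.
#' @slot trained logical.
#' @export
setClass("DTAModel",
  representation(variant = "character", drugEncoder = "list",
                 protEncoder = "list", fusion = "list", config = "list",
                 history = "data.frame", trained = "logical"),
  prototype(history = data.frame(), trained = FALSE))
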