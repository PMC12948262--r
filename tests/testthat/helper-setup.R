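# Shared fixtures. Everything is generated in code at test time; expensive
# objects are built once per session and memoized here.

.fixtures <- new.env(parent = emptyenv())

# reduced-width model/training configuration used by all learning tests:
# 8-D atom and 12-D residue mock embeddings, 2 encoder heads, 8-D fusion
# tokens, 24/12 prediction stack
reducedModelArgs <- function() {
  list(heads = 2L, dModel = 8L, nFusionHeads = 2L, fclDims = c(24L, 12L))
}

reducedProviders <- function() {
  list(atom = mockAtomProvider(dim = 8L, seed = 3L),
       residue = mockResidueProvider(dim = 12L, seed = 4L))
}

# the planted-signal study dataset: 500 pairs over 150 drugs x 30 proteins
plantedFeatures <- function() {
  if (!is.null(.fixtures$planted)) return(.fixtures$planted)
  ds <- suppressWarnings(generateSyntheticDataset(seed = 11L))
  pv <- reducedProviders()
  ft <- suppressWarnings(featurizeDataset(ds, pv$atom, pv$residue))
  .fixtures$planted <- ft
  ft
}

# a small dataset for fast pipeline tests
tinyFeatures <- function() {
  if (!is.null(.fixtures$tiny)) return(.fixtures$tiny)
  ds <- suppressWarnings(
    generateSyntheticDataset(nPairs = 24L, nDrugs = 8L, nProteins = 4L,
                             proteinLengthRange = c(12L, 20L), seed = 5L))
  pv <- reducedProviders()
  .fixtures$tiny <- suppressWarnings(featurizeDataset(ds, pv$atom, pv$residue))
  .fixtures$tiny
}

# a random small graph on n nodes for attention property tests
randomTestGraph <- function(n, de, pEdge = 0.3) {
  adj <- which(upper.tri(matrix(TRUE, n, n)) &
                 matrix(stats::runif(n * n) < pEdge, n, n), arr.ind = TRUE)
  if (nrow(adj) == 0L) adj <- cbind(1L, 2L)
  ei <- cbind(src = c(adj[, 1L], adj[, 2L]), dst = c(adj[, 2L], adj[, 1L]))
  list(h = matrix(stats::rnorm(n * 5L), n),
       edgeIndex = ei,
       edgeFeats = matrix(stats::runif(nrow(ei) * de), nrow(ei)))
}
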