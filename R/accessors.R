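#' @rdname MolecularGraph-class
#' @export
setMethod("numNodes", "MolecularGraph", function(x) nrow(x@nodeFeatures))

#' @rdname ProteinGraph-class
#' @export
setMethod("numNodes", "ProteinGraph", function(x) nrow(x@coords))

#' @rdname MolecularGraph-class
#' @export
setMethod("nodeFeatures", "MolecularGraph", function(x) x@nodeFeatures)

#' @rdname ProteinGraph-class
#' @export
setMethod("nodeFeatures", "ProteinGraph", function(x) x@nodeFeatures)

#' @rdname MolecularGraph-class
#' @export
setMethod("edgeIndex", "MolecularGraph", function(x) x@edgeIndex)

#' @rdname ProteinGraph-class
#' @export
setMethod("edgeIndex", "ProteinGraph", function(x) x@edgeIndex)

#' @rdname MolecularGraph-class
#' @export
setMethod("edgeFeatures", "MolecularGraph", function(x) x@edgeFeatures)

#' @rdname ProteinGraph-class
#' @export
setMethod("edgeWeights", "ProteinGraph", function(x) x@edgeWeights)

#' @rdname AffinityDataset-class
#' @export
setMethod("records", "AffinityDataset", function(x) x@records)

#' @rdname AffinityDataset-class
#' @param object object to display
#' @export
setMethod("length", "AffinityDataset", function(x) nrow(x@records))

#' @rdname DatasetSplit-class
#' @export
setMethod("foldOf", "DatasetSplit", function(x) x@foldOf)

#' @rdname MetricsReport-class
#' @export
setMethod("perFold", "MetricsReport", function(x) x@perFold)

#' @describeIn MetricsReport-class mean and standard deviation per metric
#' @param object a `MetricsReport`
#' @param ... ignored
#' @export
setMethod("summary", "MetricsReport", function(object, ...) {
  pf <- object@perFold
  num <- pf[vapply(pf, is.numeric, TRUE)]
  data.frame(metric = names(num),
             mean = vapply(num, mean, 0),
             sd = vapply(num, stats::sd, 0),
             row.names = NULL)
})

setMethod("show", "MolecularGraph", function(object) {
  cat(sprintf("MolecularGraph: %s\n  %d heavy atoms, %d directed edges, %d-D node features\n",
              object@smiles, numNodes(object), nrow(object@edgeIndex),
              ncol(object@nodeFeatures)))
})

setMethod("show", "ProteinGraph", function(object) {
  cat(sprintf("ProteinGraph: %d residues, %d directed edges (cutoff %.1f A), %d-D node features\n",
              numNodes(object), nrow(object@edgeIndex), object@cutoff,
              ncol(object@nodeFeatures)))
})

setMethod("show", "AffinityDataset", function(object) {
  r <- object@records
  cat(sprintf("AffinityDataset: %d records, %d drugs, %d proteins; label kinds: %s\n",
              nrow(r), length(unique(r$drugId)), length(unique(r$proteinId)),
              paste(unique(r$labelKind), collapse = ", ")))
})

setMethod("show", "DatasetSplit", function(object) {
  cat(sprintf("DatasetSplit: %d records in %d folds (seed %d); sizes: %s\n",
              length(object@foldOf), object@k, object@seed,
              paste(tabulate(object@foldOf + 1L, object@k), collapse = "/")))
})

setMethod("show", "MetricsReport", function(object) {
  cat(sprintf("MetricsReport (%s), %d folds\n", object@task, nrow(object@perFold)))
  s <- summary(object)
  for (i in seq_len(nrow(s)))
    cat(sprintf("  %-9s %8.4f +- %.4f\n", s$metric[i], s$mean[i], s$sd[i]))
})

setMethod("show", "DTAModel", function(object) {
  cat(sprintf("DTAModel variant '%s'%s\n", object@variant,
              if (object@trained) " (trained)" else " (untrained)"))
  cfg <- object@config
  cat(sprintf("  drug dim %d, protein dim %d, fused dim %d; encoder: %s, %d layer(s)\n",
              cfg$drugDim, cfg$protDim, cfg$drugDim + cfg$protDim,
              cfg$encoderVariant, cfg$nLayers))
})

setMethod("show", "MockAtomProvider", function(object)
  cat(sprintf("MockAtomProvider '%s': %d-D, seed %d\n", object@name, object@dim, object@seed)))
setMethod("show", "MockResidueProvider", function(object)
  cat(sprintf("MockResidueProvider '%s': %d-D, seed %d\n", object@name, object@dim, object@seed)))
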