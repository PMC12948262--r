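#' @rdname MolecularGraph-class
#' @param x a graph object
#' @export
setGeneric("numNodes", function(x) standardGeneric("numNodes"))

#' @rdname MolecularGraph-class
#' @export
setGeneric("nodeFeatures", function(x) standardGeneric("nodeFeatures"))

#' @rdname MolecularGraph-class
#' @export
setGeneric("edgeIndex", function(x) standardGeneric("edgeIndex"))

#' @rdname MolecularGraph-class
#' @export
setGeneric("edgeFeatures", function(x) standardGeneric("edgeFeatures"))

#' @rdname ProteinGraph-class
#' @param x a `ProteinGraph`
#' @export
setGeneric("edgeWeights", function(x) standardGeneric("edgeWeights"))

#' Embed the heavy atoms of a molecule
#'
#' Returns one embedding row per heavy atom of the parsed molecule, in the
#' same atom order as [buildMolecularGraph()] uses. Deterministic: the same
#' SMILES always yields the identical matrix.
#'
#' @param provider an atom-level [EmbeddingProvider-class]
#' @param smiles a SMILES string
#' @return numeric matrix (atoms x dim)
#' @export
setGeneric("embedAtoms", function(provider, smiles) standardGeneric("embedAtoms"))

#' Embed the residues of a protein sequence
#'
#' Returns one embedding row per residue. Deterministic per sequence.
#'
#' @param provider a residue-level [EmbeddingProvider-class]
#' @param sequence single-letter amino-acid string
#' @return numeric matrix (residues x dim)
#' @export
setGeneric("embedResidues", function(provider, sequence) standardGeneric("embedResidues"))

#' @rdname AffinityDataset-class
#' @param x an `AffinityDataset`
#' @export
setGeneric("records", function(x) standardGeneric("records"))

#' @rdname DatasetSplit-class
#' @param x a `DatasetSplit`
#' @export
setGeneric("foldOf", function(x) standardGeneric("foldOf"))

#' @rdname MetricsReport-class
#' @param x a `MetricsReport`
#' @export
setGeneric("perFold", function(x) standardGeneric("perFold"))
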