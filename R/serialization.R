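# Portable JSON bundles for graphs and model checkpoints, so featurized
# graphs can be cached and trained parameters exchanged without binary
# formats. Numbers are written at full precision.

.mat2list <- function(m) list(dim = dim(m), data = as.numeric(m))
.list2mat <- function(l) matrix(l$data, l$dim[1L], l$dim[2L])

#' Serialize a graph to a JSON bundle
#'
#' Writes all slots of a [MolecularGraph-class] or [ProteinGraph-class]
#' (node features, edge index, edge features/weights, identifiers) to a
#' single JSON file; [readGraphBundle()] restores the identical object.
#'
#' @param graph the graph to serialize.
#' @param path output JSON file.
#' @return `path`, invisibly.
#' @export
writeGraphBundle <- function(graph, path) {
  b <- if (methods::is(graph, "MolecularGraph"))
    list(type = "MolecularGraph", smiles = graph@smiles,
         nodeFeatures = .mat2list(graph@nodeFeatures),
         edgeIndex = .mat2list(graph@edgeIndex),
         edgeFeatures = .mat2list(graph@edgeFeatures))
  else
    list(type = "ProteinGraph", sequence = graph@sequence,
         coords = .mat2list(graph@coords),
         nodeFeatures = .mat2list(graph@nodeFeatures),
         edgeIndex = .mat2list(graph@edgeIndex),
         edgeWeights = graph@edgeWeights, cutoff = graph@cutoff)
  jsonlite::write_json(b, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeGraphBundle
#' @export
readGraphBundle <- function(path) {
  b <- jsonlite::read_json(path, simplifyVector = TRUE)
  ei <- .list2mat(b$edgeIndex)
  storage.mode(ei) <- "integer"
  colnames(ei) <- c("src", "dst")
  if (b$type == "MolecularGraph")
    methods::new("MolecularGraph", smiles = b$smiles,
                 nodeFeatures = .list2mat(b$nodeFeatures), edgeIndex = ei,
                 edgeFeatures = .list2mat(b$edgeFeatures))
  else
    methods::new("ProteinGraph", sequence = b$sequence,
                 coords = .list2mat(b$coords),
                 nodeFeatures = .list2mat(b$nodeFeatures), edgeIndex = ei,
                 edgeWeights = as.numeric(b$edgeWeights), cutoff = b$cutoff)
}

# flatten/restore nested parameter lists (matrices at the leaves)
.paramsToJson <- function(x) {
  if (is.matrix(x)) return(list(.mat = .mat2list(x)))
  if (is.list(x)) return(lapply(x, .paramsToJson))
  x
}
.paramsFromJson <- function(x) {
  if (is.list(x) && !is.null(x$.mat)) return(.list2mat(x$.mat))
  if (is.list(x)) return(lapply(x, .paramsFromJson))
  x
}

#' Save / restore a model checkpoint as JSON
#'
#' The whole [DTAModel-class] -- variant, configuration, encoder and fusion
#' parameters, batch-norm running statistics and training history -- in one
#' portable JSON file. Restored models reproduce predictions to full double
#' precision.
#'
#' @param model a [DTAModel-class].
#' @param path JSON file path.
#' @return `writeModelCheckpoint`: `path` invisibly;
#'   `readModelCheckpoint`: the restored [DTAModel-class].
#' @export
writeModelCheckpoint <- function(model, path) {
  b <- list(variant = model@variant, config = model@config,
            trained = model@trained,
            drugEncoder = .paramsToJson(model@drugEncoder),
            protEncoder = .paramsToJson(model@protEncoder),
            fusion = .paramsToJson(model@fusion),
            history = model@history)
  jsonlite::write_json(b, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeModelCheckpoint
#' @export
readModelCheckpoint <- function(path) {
  b <- jsonlite::read_json(path, simplifyVector = FALSE)
  unbox <- function(x) {
    if (is.list(x) && length(x) && all(vapply(x, function(e)
      is.atomic(e) && length(e) == 1L, TRUE)) && is.null(names(x)))
      return(unlist(x))
    x
  }
  restore <- function(x) {
    if (is.list(x) && !is.null(x$.mat))
      return(.list2mat(list(dim = unlist(x$.mat$dim),
                            data = unlist(x$.mat$data))))
    if (is.list(x)) return(lapply(x, restore))
    x
  }
  simple <- function(x) {  # scalars arrive as length-1 lists
    if (is.list(x)) {
      out <- lapply(x, simple)
      if (all(vapply(out, function(e) is.atomic(e) && length(e) == 1L, TRUE)) &&
          is.null(names(out)))
        return(unlist(out))
      return(out)
    }
    x
  }
  fusion <- restore(b$fusion)
  fusion$meta <- simple(fusion$meta)
  fusion$meta$fclDims <- as.integer(fusion$meta$fclDims)
  fusion$running <- lapply(fusion$running, function(v) unlist(v))
  drugEnc <- restore(b$drugEncoder)
  if (length(drugEnc)) drugEnc$config <- simple(drugEnc$config)
  protEnc <- restore(b$protEncoder)
  if (length(protEnc)) protEnc$config <- simple(protEnc$config)
  hist <- do.call(rbind, lapply(b$history, function(r)
    data.frame(epoch = r$epoch, trainLoss = r$trainLoss, valLoss = r$valLoss)))
  methods::new("DTAModel", variant = b$variant[[1L]],
               drugEncoder = drugEnc,
               protEncoder = protEnc,
               fusion = fusion,
               config = simple(b$config),
               history = if (is.null(hist)) data.frame() else hist,
               trained = isTRUE(b$trained[[1L]]))
}
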