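# Residue contact graphs from C-alpha coordinates.

#' Pairwise C-alpha distance matrix
#'
#' Euclidean distances between all residue pairs: symmetric, zero diagonal.
#'
#' @param coords numeric matrix (residues x 3), Angstrom.
#' @return numeric matrix (residues x residues), Angstrom.
#' @export
computeDistanceMatrix <- function(coords) {
  coords <- as.matrix(coords)
  if (!is.numeric(coords) || ncol(coords) != 3L)
    stop("coords must be an M x 3 numeric matrix")
  if (any(!is.finite(coords))) stop("coords must be finite")
  as.matrix(stats::dist(coords))
}

#' Build a residue contact graph
#'
#' Connects residue pairs whose C-alpha distance is at most `cutoff`
#' (inclusive; 8 Angstrom by default) with weight `1/distance`. Sequence
#' neighbours receive no special treatment beyond their geometric proximity,
#' and isolated residues (degree 0) are permitted. Node features come from
#' the residue embedding provider, row-aligned to the sequence. Sequences
#' longer than `maxLength` are centre-truncated with a warning (coordinates
#' and features together), mirroring the input limits of common structure
#' predictors.
#'
#' @param sequence single-letter amino-acid string of length M.
#' @param coords M x 3 C-alpha coordinate matrix (Angstrom).
#' @param provider a residue [EmbeddingProvider-class].
#' @param cutoff contact cutoff in Angstrom (default 8, inclusive).
#' @param maxLength maximum sequence length before centre truncation.
#' @return a [ProteinGraph-class].
#' @examples
#' coords <- cbind(3.8 * (0:4), 0, 0)  # ideal straight chain
#' g <- buildProteinGraph("MKVLA", coords, mockResidueProvider(dim = 16))
#' range(edgeWeights(g))  # 1/7.6 .. 1/3.8
#' @export
buildProteinGraph <- function(sequence, coords, provider, cutoff = 8.0,
                              maxLength = 1022L) {
  coords <- as.matrix(coords)
  m <- nchar(sequence)
  if (nrow(coords) != m)
    stop("sequence length (", m, ") and coordinate rows (", nrow(coords),
         ") disagree")
  if (m > maxLength) {
    warning("sequence of length ", m, " centre-truncated to ", maxLength)
    start <- (m - maxLength) %/% 2L + 1L
    keep <- start:(start + maxLength - 1L)
    sequence <- paste0(strsplit(sequence, "")[[1L]][keep], collapse = "")
    coords <- coords[keep, , drop = FALSE]
    m <- maxLength
  }
  D <- unname(computeDistanceMatrix(coords))
  adj <- which(D <= cutoff & upper.tri(D), arr.ind = TRUE)
  if (nrow(adj)) {
    w <- unname(1 / D[adj])
    ei <- cbind(src = as.integer(c(adj[, 1L], adj[, 2L])),
                dst = as.integer(c(adj[, 2L], adj[, 1L])))
    ew <- c(w, w)
  } else {
    ei <- matrix(integer(0), 0L, 2L, dimnames = list(NULL, c("src", "dst")))
    ew <- numeric(0)
  }
  X <- embedResidues(provider, sequence)
  if (nrow(X) != m)
    stop("provider returned ", nrow(X), " rows for ", m, " residues")
  methods::new("ProteinGraph", sequence = sequence, coords = coords,
               nodeFeatures = X, edgeIndex = ei, edgeWeights = ew,
               cutoff = cutoff)
}
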