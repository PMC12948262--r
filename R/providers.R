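# Embedding providers. Mock providers hash local chemical identity into
# deterministic pseudo-random unit-variance vectors, so identical chemistry
# always maps to identical features and the planted-signal learning task is
# well-posed without any pretrained model.

# 31-ary rolling string hash mod (2^31 - 1), exact in doubles
.strHash <- function(key, seed = 0L) {
  m <- 2147483647
  h <- (as.numeric(seed) %% m)
  for (c in utf8ToInt(key)) h <- (h * 31 + c) %% m
  as.integer(h)
}

# deterministic unit-variance embedding for one identity key
.hashVector <- function(key, dim, seed) {
  withRNG(.strHash(key, seed), stats::rnorm(dim))
}

#' Mock embedding providers
#'
#' `mockAtomProvider()` embeds each heavy atom from a hash of its local
#' identity `(element, degree, aromatic flag, formal charge)`;
#' `mockResidueProvider()` embeds each residue from its identity plus the
#' identities of its sequence neighbours at offsets -1/+1. Both expand the
#' hash into a deterministic standard-normal (unit-variance) vector, so
#' chemically distinct identities receive distinct, near-orthogonal
#' embeddings. Reference dimensionalities are 512 (atoms) and 2560
#' (residues); any `dim >= 8` is accepted for reduced configurations.
#'
#' @param dim embedding dimensionality.
#' @param seed integer seed mixed into every hash.
#' @return a provider object answering [embedAtoms()] / [embedResidues()].
#' @examples
#' p <- mockAtomProvider(dim = 16)
#' dim(embedAtoms(p, "CCO"))  # 3 x 16
#' @export
mockAtomProvider <- function(dim = 512L, seed = 1L) {
  stopifnot(dim >= 8L)
  methods::new("MockAtomProvider", name = "mock-atom", dim = as.integer(dim),
               seed = as.integer(seed))
}

#' @rdname mockAtomProvider
#' @export
mockResidueProvider <- function(dim = 2560L, seed = 1L) {
  stopifnot(dim >= 8L)
  methods::new("MockResidueProvider", name = "mock-residue",
               dim = as.integer(dim), seed = as.integer(seed))
}

#' Provider serving precomputed embedding matrices
#'
#' Wraps matrices computed by an external embedder (for example a
#' pretrained molecular or protein language model), keyed by the exact
#' SMILES/sequence string. Matrices must be row-aligned to the parsed atom
#' order / residue order.
#'
#' @param matrices named list of numeric matrices.
#' @param dim embedding dimensionality (defaults to the first matrix).
#' @param name provider label.
#' @return a [PrecomputedProvider-class].
#' @export
precomputedProvider <- function(matrices, dim = ncol(matrices[[1L]]),
                                name = "precomputed") {
  methods::new("PrecomputedProvider", name = name, dim = as.integer(dim),
               matrices = matrices)
}

#' @rdname embedAtoms
#' @export
setMethod("embedAtoms", "MockAtomProvider", function(provider, smiles) {
  atoms <- .parseSmiles(smiles)$atoms
  keys <- paste("atom", atoms$element, atoms$degree,
                as.integer(atoms$aromatic), atoms$charge, sep = "|")
  t(vapply(keys, .hashVector, numeric(provider@dim),
           dim = provider@dim, seed = provider@seed, USE.NAMES = FALSE))
})

#' @rdname embedResidues
#' @export
setMethod("embedResidues", "MockResidueProvider", function(provider, sequence) {
  aa <- strsplit(sequence, "")[[1L]]
  m <- length(aa)
  prev <- c("^", aa[-m])
  nxt <- c(aa[-1L], "$")
  keys <- paste("res", prev, aa, nxt, sep = "|")
  t(vapply(keys, .hashVector, numeric(provider@dim),
           dim = provider@dim, seed = provider@seed, USE.NAMES = FALSE))
})

#' @rdname embedAtoms
#' @export
setMethod("embedAtoms", "PrecomputedProvider", function(provider, smiles) {
  m <- provider@matrices[[smiles]]
  if (is.null(m)) stop("no precomputed embedding for: ", smiles)
  m
})

#' @rdname embedResidues
#' @export
setMethod("embedResidues", "PrecomputedProvider", function(provider, sequence) {
  m <- provider@matrices[[sequence]]
  if (is.null(m)) stop("no precomputed embedding for sequence")
  m
})
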