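# Molecular graphs: SMILES -> atoms/bonds via ChemmineR/OpenBabel, 6-D
# one-hot bond features, provider-supplied node embeddings, ECFP4 Tanimoto.

.smilesCache <- new.env(parent = emptyenv())

# Parse a SMILES into atom and bond tables with perceived aromaticity.
# Returns list(atoms = data.frame(element, aromatic, charge, degree),
#              bonds = data.frame(a1, a2, order, aromatic)).
.parseSmiles <- function(smiles) {
  hit <- get0(smiles, envir = .smilesCache)
  if (!is.null(hit)) return(hit)
  sdf <- tryCatch(suppressWarnings(ChemmineR::smiles2sdf(smiles)[[1]]),
                  error = function(e) stop("invalid SMILES: ", smiles))
  ab <- ChemmineR::atomblock(sdf)
  if (is.null(ab) || nrow(ab) == 0L) stop("invalid SMILES: ", smiles)
  element <- sub("_.*$", "", rownames(ab))
  n <- nrow(ab)
  bb <- ChemmineR::bondblock(sdf)
  if (!is.null(bb) && is.null(dim(bb))) bb <- matrix(bb, nrow = 1L)
  # atom-only molecules come back with a placeholder 2-column block
  bonds <- if (is.null(bb) || nrow(bb) == 0L || ncol(bb) < 3L)
    data.frame(a1 = integer(0), a2 = integer(0), order = integer(0))
  else data.frame(a1 = as.integer(bb[, 1L]), a2 = as.integer(bb[, 2L]),
                  order = as.integer(bb[, 3L]))
  bonds <- bonds[bonds$a1 >= 1L & bonds$a2 >= 1L, , drop = FALSE]

  aromAtom <- rep(FALSE, n)
  aromBond <- rep(FALSE, nrow(bonds))
  if (nrow(bonds)) {
    rng <- tryCatch(ChemmineR::rings(sdf, type = "all", arom = TRUE),
                    error = function(e) list(RINGS = list(), AROMATIC = logical(0)))
    aromRings <- if (is.null(rng$AROMATIC)) list()
                 else rng$RINGS[which(as.logical(rng$AROMATIC))]
    bondKey <- paste(pmin(bonds$a1, bonds$a2), pmax(bonds$a1, bonds$a2))
    for (ring in aromRings) {
      idx <- as.integer(sub("^.*_", "", ring))
      aromAtom[idx] <- TRUE
      pairs <- cbind(idx, c(idx[-1L], idx[1L]))
      aromBond[bondKey %in% paste(pmin(pairs[, 1], pairs[, 2]),
                                  pmax(pairs[, 1], pairs[, 2]))] <- TRUE
    }
  }

  charge <- rep(0L, n)
  chg <- tryCatch(grep("^M  CHG", ChemmineR::sdf2str(sdf), value = TRUE),
                  error = function(e) character(0))
  for (line in chg) {
    f <- as.integer(strsplit(trimws(sub("^M  CHG\\s+\\d+", "", line)), "\\s+")[[1]])
    if (length(f) >= 2L) charge[f[seq(1, length(f), 2)]] <- f[seq(2, length(f), 2)]
  }

  degree <- tabulate(c(bonds$a1, bonds$a2), nbins = n)
  # pi-capable: aromatic, in a multiple bond, or a heteroatom whose neighbor
  # carries a multiple/aromatic bond (lone-pair conjugation)
  multi <- rep(FALSE, n)
  if (nrow(bonds)) {
    hasMulti <- bonds$order >= 2L | aromBond
    multi[unique(c(bonds$a1[hasMulti], bonds$a2[hasMulti]))] <- TRUE
  }
  sp2sp <- aromAtom | multi
  lonePair <- element %in% c("N", "O", "S", "P") & !sp2sp
  if (any(lonePair) && nrow(bonds)) {
    nbMulti <- rep(FALSE, n)
    nbMulti[bonds$a1[sp2sp[bonds$a2]]] <- TRUE
    nbMulti[bonds$a2[sp2sp[bonds$a1]]] <- TRUE
    piCap <- sp2sp | (lonePair & nbMulti)
  } else piCap <- sp2sp

  conj <- aromBond
  if (nrow(bonds)) {
    conj <- conj | (bonds$order == 1L & piCap[bonds$a1] & piCap[bonds$a2])
    # a multiple bond adjacent to a conjugated bond joins the system
    conjAtom <- rep(FALSE, n)
    conjAtom[unique(c(bonds$a1[conj], bonds$a2[conj]))] <- TRUE
    conj <- conj | (bonds$order >= 2L & (conjAtom[bonds$a1] | conjAtom[bonds$a2]))
  }

  out <- list(
    atoms = data.frame(element = element, aromatic = aromAtom,
                       charge = charge, degree = degree,
                       stringsAsFactors = FALSE),
    bonds = cbind(bonds, data.frame(aromatic = aromBond, conjugated = conj,
                                    sp2ends = if (nrow(bonds))
                                      sp2sp[bonds$a1] & sp2sp[bonds$a2]
                                    else logical(0))))
  assign(smiles, out, envir = .smilesCache)
  out
}

#' Atom and bond perception for a molecule
#'
#' Parses a SMILES string (OpenBabel backend) and reports the heavy-atom and
#' bond tables used for graph construction, including perceived aromaticity,
#' conjugation and the pi-capable (sp/sp2) flag of each bond's endpoints.
#'
#' @param smiles a SMILES string.
#' @return list with data.frames `atoms` (element, aromatic, charge, degree)
#'   and `bonds` (a1, a2, order, aromatic, conjugated, sp2ends).
#' @examples
#' moleculeTopology("C=CC=C")$bonds
#' @export
moleculeTopology <- function(smiles) .parseSmiles(smiles)

#' Encode a bond as a 6-D one-hot feature vector
#'
#' Layout: `[single, double, triple, aromatic, conjugated, hybridization]`.
#' Exactly one of the first four type bits is set. The hybridization bit is
#' 1 when both endpoint atoms are sp- or sp2-hybridized (a pi-capable bond
#' environment); conjugation follows the usual alternating-system
#' perception. Exotic bond orders are mapped to the nearest of the four
#' types with a warning.
#'
#' @param bond a one-row data.frame or list with fields `order`, `aromatic`,
#'   `conjugated`, `sp2ends` (as produced by [moleculeTopology()]).
#' @return numeric 0/1 vector of length 6.
#' @examples
#' top <- moleculeTopology("c1ccccc1")
#' encodeBondFeatures(top$bonds[1, ])
#' @export
encodeBondFeatures <- function(bond) {
  v <- numeric(6L)
  if (isTRUE(as.logical(bond$aromatic))) {
    v[4L] <- 1
  } else {
    ord <- as.integer(bond$order)
    if (!ord %in% 1:3) {
      warning("exotic bond order ", ord, " mapped to nearest standard type")
      ord <- max(1L, min(3L, ord))
    }
    v[ord] <- 1
  }
  v[5L] <- as.numeric(isTRUE(as.logical(bond$conjugated)))
  v[6L] <- as.numeric(isTRUE(as.logical(bond$sp2ends)))
  v
}

#' Build a molecular graph from a SMILES string
#'
#' Heavy atoms become nodes with embeddings from `provider` (row-aligned to
#' the parsed atom order); each bond becomes two directed edges sharing one
#' 6-D feature vector from [encodeBondFeatures()]. Self-loops are not stored
#' in the graph; the attention layers add them internally.
#'
#' @param smiles a SMILES string.
#' @param provider an atom [EmbeddingProvider-class] (see
#'   [mockAtomProvider()]).
#' @return a [MolecularGraph-class].
#' @examples
#' g <- buildMolecularGraph("CCO", mockAtomProvider(dim = 16))
#' numNodes(g)          # 3 heavy atoms
#' nrow(edgeIndex(g))   # 4 directed edges
#' @export
buildMolecularGraph <- function(smiles, provider) {
  top <- .parseSmiles(smiles)
  X <- embedAtoms(provider, smiles)
  if (nrow(X) != nrow(top$atoms))
    stop("provider returned ", nrow(X), " rows for ", nrow(top$atoms), " atoms")
  nb <- nrow(top$bonds)
  if (nb) {
    feats <- t(vapply(seq_len(nb),
                      function(i) encodeBondFeatures(top$bonds[i, ]),
                      numeric(6L)))
    ei <- cbind(src = c(top$bonds$a1, top$bonds$a2),
                dst = c(top$bonds$a2, top$bonds$a1))
    ef <- rbind(feats, feats)
  } else {
    ei <- matrix(integer(0), 0L, 2L, dimnames = list(NULL, c("src", "dst")))
    ef <- matrix(numeric(0), 0L, 6L)
  }
  methods::new("MolecularGraph", smiles = smiles, nodeFeatures = X,
               edgeIndex = ei, edgeFeatures = ef)
}

#' ECFP4 fingerprint of a molecule
#'
#' Radius-2 circular (ECFP4) fingerprint folded to `nbits` bits (default
#' 2048, the standard folding).
#'
#' @param smiles a SMILES string.
#' @param nbits folded fingerprint length.
#' @return integer 0/1 vector of length `nbits`.
#' @export
ecfp4Fingerprint <- function(smiles, nbits = 2048L) {
  ref <- tryCatch(ChemmineOB::forEachMol("SMILES", smiles, identity),
                  error = function(e) stop("invalid SMILES: ", smiles))
  raw <- ChemmineOB::fingerprint_OB(ref, "ECFP4")
  raw <- as.numeric(raw)
  if (length(raw) %% nbits != 0L)
    stop("cannot fold ", length(raw), " bits to ", nbits)
  folded <- rowSums(matrix(raw, nrow = nbits)) > 0
  as.integer(folded)
}

#' ECFP4 Tanimoto similarity between two molecules
#'
#' `|A intersect B| / |A union B|` over folded ECFP4 fingerprints; 1 for
#' identical structures, low values indicate scaffold novelty. Symmetric in
#' its arguments. Two molecules with no shared substructure bits score 0 by
#' convention (also when both fingerprints are empty).
#'
#' @param smilesA,smilesB SMILES strings.
#' @param nbits folded fingerprint length (default 2048).
#' @return similarity in `[0, 1]`.
#' @examples
#' tanimotoEcfp4("c1ccccc1", "c1ccccc1C")
#' @export
tanimotoEcfp4 <- function(smilesA, smilesB, nbits = 2048L) {
  a <- ecfp4Fingerprint(smilesA, nbits)
  b <- ecfp4Fingerprint(smilesB, nbits)
  u <- sum(a | b)
  if (u == 0L) return(0)
  sum(a & b) / u
}
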