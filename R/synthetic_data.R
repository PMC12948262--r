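# Deterministic synthetic fixtures: valid molecules from a joinable fragment
# vocabulary, protein sequences with chain-like 3-D geometry, and affinity
# labels carrying a planted drug x protein signal. Everything is seeded and
# runs offline; no fixture is read from disk.

.defaultVocabulary <- function() {
  list(aromatic = c("c1ccccc1", "c1ccncc1", "c1ccoc1", "c1ccsc1"),
       aliphatic = c("C", "CC", "CO", "N", "C(C)C", "C=C", "CS", "CN", "CCC"))
}

#' Hydrophobic residues used by the planted affinity signal
#' @export
HYDROPHOBIC_AA <- c("A", "V", "L", "I", "M", "F", "W")

#' Aromatic-atom fraction of a molecule
#' @param smiles a SMILES string.
#' @return fraction of heavy atoms perceived as aromatic, in `[0, 1]`.
#' @export
aromaticFraction <- function(smiles) {
  atoms <- .parseSmiles(smiles)$atoms
  mean(atoms$aromatic)
}

#' Hydrophobic-residue fraction of a protein sequence
#' @param sequence single-letter amino-acid string.
#' @return fraction of residues in `{A, V, L, I, M, F, W}`.
#' @export
hydrophobicFraction <- function(sequence) {
  aa <- strsplit(sequence, "")[[1L]]
  mean(aa %in% HYDROPHOBIC_AA)
}

#' Generate valid small molecules from a fragment vocabulary
#'
#' Builds each molecule by concatenating joinable SMILES fragments; every
#' fragment pair in the default vocabulary concatenates to a valid SMILES,
#' so validity holds by construction. Each molecule draws a target aromatic
#' fraction uniformly in `[0, 1]` and fragments are chosen greedily to
#' steer the running aromatic-atom fraction toward it, so the realized
#' fractions cover the whole unit interval across a batch.
#'
#' @param n number of molecules.
#' @param vocabulary list with character vectors `aromatic` and `aliphatic`.
#' @param seed integer seed; the same seed reproduces the same list.
#' @return character vector of `n` SMILES strings.
#' @export
generateMolecules <- function(n, vocabulary = .defaultVocabulary(), seed = 1L) {
  heavy <- function(s) nrow(.parseSmiles(s)$atoms)
  nArom <- vapply(vocabulary$aromatic, heavy, 0L)
  nAli <- vapply(vocabulary$aliphatic, heavy, 0L)
  withRNG(seed, {
    vapply(seq_len(n), function(i) {
      p <- stats::runif(1)                    # target aromatic fraction
      budget <- sample(6:40, 1L)
      units <- character(0)
      atoms <- 0L; arom <- 0L
      while (atoms < budget) {
        ja <- sample(length(vocabulary$aromatic), 1L)
        jb <- sample(length(vocabulary$aliphatic), 1L)
        # take whichever candidate lands the running fraction closer to p
        fracA <- (arom + nArom[ja]) / (atoms + nArom[ja])
        fracB <- arom / (atoms + nAli[jb])
        if (abs(fracA - p) < abs(fracB - p)) {
          units <- c(units, vocabulary$aromatic[ja])
          arom <- arom + nArom[ja]; atoms <- atoms + nArom[ja]
        } else {
          units <- c(units, vocabulary$aliphatic[jb])
          atoms <- atoms + nAli[jb]
        }
      }
      paste0(units, collapse = "")
    }, "")
  })
}

#' Generate protein sequences with controlled hydrophobicity
#'
#' Each sequence draws a target hydrophobic fraction uniformly in
#' `[0.1, 0.9]` and samples residues accordingly, so the planted
#' hydrophobicity signal varies across proteins.
#'
#' @param n number of sequences.
#' @param lengthRange integer range of sequence lengths.
#' @param seed integer seed.
#' @return character vector of sequences.
#' @export
generateProteinSequences <- function(n, lengthRange = c(40L, 80L), seed = 1L) {
  other <- setdiff(c("A","R","N","D","C","Q","E","G","H","I","K","L","M",
                     "F","P","S","T","W","Y","V"), HYDROPHOBIC_AA)
  withRNG(seed, {
    vapply(seq_len(n), function(i) {
      m <- sample(lengthRange[1L]:lengthRange[2L], 1L)
      q <- stats::runif(1, 0.1, 0.9)
      aa <- ifelse(stats::runif(m) < q,
                   sample(HYDROPHOBIC_AA, m, replace = TRUE),
                   sample(other, m, replace = TRUE))
      paste0(aa, collapse = "")
    }, "")
  })
}

#' Generate chain-like C-alpha coordinates
#'
#' All modes place consecutive residues exactly 3.8 Angstrom apart (the
#' C-alpha virtual bond length). `ideal_chain` is collinear; `helix` uses
#' ideal alpha-helix parameters (rise 1.5 Angstrom, 100 degrees per residue,
#' radius solved from those two so the virtual bond is exactly 3.8, i.e.
#' 2.2788 Angstrom); `random_walk` is a fixed-step self-avoiding walk with
#' minimum pairwise distance 3.0 Angstrom.
#'
#' @param M number of residues (>= 2).
#' @param mode `"ideal_chain"`, `"helix"` or `"random_walk"`.
#' @param seed integer seed (used by `random_walk` only).
#' @param maxRestarts restarts allowed when the walk traps itself.
#' @return numeric M x 3 matrix (Angstrom).
#' @examples
#' d <- dist(generateChainCoords(5, "ideal_chain"))
#' @export
generateChainCoords <- function(M, mode = c("random_walk", "ideal_chain", "helix"),
                                seed = 1L, maxRestarts = 20L) {
  mode <- match.arg(mode)
  M <- as.integer(M)
  if (M < 2L) stop("M must be at least 2")
  step <- 3.8
  if (mode == "ideal_chain")
    return(cbind(x = step * (seq_len(M) - 1L), y = 0, z = 0))
  if (mode == "helix") {
    rise <- 1.5
    twist <- 100 * pi / 180
    radius <- sqrt(step^2 - rise^2) / (2 * sin(twist / 2))
    th <- twist * (seq_len(M) - 1L)
    return(cbind(x = radius * cos(th), y = radius * sin(th),
                 z = rise * (seq_len(M) - 1L)))
  }
  withRNG(seed, {
    for (attempt in seq_len(maxRestarts)) {
      pts <- matrix(NA_real_, M, 3L)
      pts[1L, ] <- c(0, 0, 0)
      dir <- c(1, 0, 0)
      ok <- TRUE
      for (i in 2L:M) {
        placed <- FALSE
        for (try in 1:200) {
          # propose a direction correlated with the previous one (chain-like)
          prop <- dir + stats::rnorm(3L, sd = 0.8)
          prop <- prop / sqrt(sum(prop^2))
          cand <- pts[i - 1L, ] + step * prop
          if (i > 2L) {
            dmin <- min(sqrt(rowSums(sweep(pts[1:(i - 2L), , drop = FALSE],
                                           2L, cand)^2)))
            if (dmin < 3.0) next
          }
          pts[i, ] <- cand
          dir <- prop
          placed <- TRUE
          break
        }
        if (!placed) { ok <- FALSE; break }
      }
      if (ok) return(unname(pts))
    }
    stop("self-avoiding walk failed after ", maxRestarts,
         " restarts; try another seed")
  })
}

#' Planted affinity label
#'
#' `y = w_arom * AromFrac(mol) + w_hyd * HydFrac(seq) +
#'  w_inter * AromFrac * HydFrac + Normal(0, noiseSd^2)`,
#' where `AromFrac` is the aromatic-atom fraction of the molecule and
#' `HydFrac` the hydrophobic-residue fraction of the sequence. The
#' interaction term makes the label depend jointly on both modalities.
#'
#' @param smiles a SMILES string.
#' @param sequence amino-acid string.
#' @param weights numeric `(w_arom, w_hyd, w_inter)`.
#' @param noiseSd Gaussian noise standard deviation (0 for none).
#' @param seed integer seed for the noise draw.
#' @return numeric label.
#' @export
plantAffinity <- function(smiles, sequence, weights = c(2, 2, 2),
                          noiseSd = 0.3, seed = 1L) {
  af <- aromaticFraction(smiles)
  hf <- hydrophobicFraction(sequence)
  y <- weights[1L] * af + weights[2L] * hf + weights[3L] * af * hf
  if (noiseSd > 0) y <- y + withRNG(seed, stats::rnorm(1L, sd = noiseSd))
  y
}

#' Write a minimal C-alpha-only PDB fixture
#'
#' Emits fixed-column ATOM records (one CA per residue) readable by
#' [extractCaCoordinates()]; coordinates round-trip within the 1e-3
#' Angstrom PDB column precision.
#'
#' @param coords M x 3 coordinate matrix.
#' @param sequence amino-acid string of length M.
#' @param path output file.
#' @param chain chain identifier.
#' @return `path`, invisibly.
#' @export
writeFixturePdb <- function(coords, sequence, path, chain = "A") {
  aa3 <- c(A="ALA",R="ARG",N="ASN",D="ASP",C="CYS",Q="GLN",E="GLU",G="GLY",
           H="HIS",I="ILE",K="LYS",L="LEU",M="MET",F="PHE",P="PRO",S="SER",
           T="THR",W="TRP",Y="TYR",V="VAL",X="UNK")
  aa <- strsplit(sequence, "")[[1L]]
  stopifnot(length(aa) == nrow(coords))
  lines <- vapply(seq_along(aa), function(i)
    sprintf("ATOM  %5d  CA  %3s %s%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
            i, aa3[[aa[i]]], chain, i, coords[i, 1L], coords[i, 2L],
            coords[i, 3L]), "")
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Generate a complete synthetic affinity dataset
#'
#' Draws `nDrugs` molecules and `nProteins` sequences (with per-protein
#' C-alpha geometry), samples `nPairs` distinct drug-protein pairs, and
#' labels each with [plantAffinity()] shifted by `+4` so labels land on a
#' pKd-like scale (roughly 4-10 at the default weights). Fully reproducible
#' from the seed.
#'
#' @param nPairs number of affinity records.
#' @param nDrugs,nProteins entity counts to sample pairs from.
#' @param proteinLengthRange sequence length range.
#' @param vocabulary fragment vocabulary for [generateMolecules()].
#' @param plantedWeights `(w_arom, w_hyd, w_inter)` signal weights.
#' @param noiseSd label noise standard deviation.
#' @param geometryMode chain mode for [generateChainCoords()].
#' @param seed integer master seed.
#' @return an [AffinityDataset-class] with per-protein coordinates and the
#'   generating configuration in `@metadata`.
#' @examples
#' ds <- generateSyntheticDataset(nPairs = 20, nDrugs = 6, nProteins = 4,
#'                                seed = 7)
#' ds
#' @export
generateSyntheticDataset <- function(nPairs = 500L, nDrugs = 150L,
                                     nProteins = 30L,
                                     proteinLengthRange = c(40L, 80L),
                                     vocabulary = .defaultVocabulary(),
                                     plantedWeights = c(2, 2, 2),
                                     noiseSd = 0.3,
                                     geometryMode = "random_walk",
                                     seed = 1L) {
  if (nPairs > nDrugs * nProteins)
    stop("nPairs exceeds the number of distinct drug-protein pairs")
  smiles <- generateMolecules(nDrugs, vocabulary, seed = seed)
  seqs <- generateProteinSequences(nProteins, proteinLengthRange,
                                   seed = seed + 1L)
  drugIds <- sprintf("D%03d", seq_len(nDrugs))
  protIds <- sprintf("P%03d", seq_len(nProteins))
  coords <- lapply(seq_len(nProteins), function(i)
    generateChainCoords(nchar(seqs[i]), geometryMode, seed = seed + 100L + i))
  names(coords) <- protIds

  pairIdx <- withRNG(seed + 2L,
                     sample(nDrugs * nProteins, nPairs))
  di <- (pairIdx - 1L) %% nDrugs + 1L
  pi_ <- (pairIdx - 1L) %/% nDrugs + 1L
  labels <- vapply(seq_len(nPairs), function(r)
    4 + plantAffinity(smiles[di[r]], seqs[pi_[r]], plantedWeights, noiseSd,
                      seed = seed + 1000L + r), 0)
  rec <- data.frame(drugId = drugIds[di], drugSmiles = smiles[di],
                    proteinId = protIds[pi_], proteinSequence = seqs[pi_],
                    labelValue = labels, labelKind = "pKd",
                    stringsAsFactors = FALSE)
  methods::new("AffinityDataset", records = rec,
               metadata = list(coords = coords,
                               config = list(nPairs = nPairs, nDrugs = nDrugs,
                                             nProteins = nProteins,
                                             proteinLengthRange = proteinLengthRange,
                                             plantedWeights = plantedWeights,
                                             noiseSd = noiseSd,
                                             geometryMode = geometryMode,
                                             seed = seed)))
}
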