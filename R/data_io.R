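#' Read a drug-target affinity table
#'
#' Reads a CSV/TSV file with one measured drug-protein pair per row. The
#' header must name columns for the drug SMILES, the protein sequence and
#' the label; rows whose SMILES does not parse, whose sequence contains
#' characters outside the 20-letter alphabet (plus `X`), or whose label is
#' not finite are rejected with a logged reason rather than aborting the
#' load. Protein sequences may alternatively be resolved from a FASTA file
#' keyed by protein id.
#'
#' @param path file path.
#' @param dialect `"csv"` or `"tsv"`.
#' @param columns named character vector mapping the roles `drugId`,
#'   `drugSmiles`, `proteinId`, `proteinSequence`, `labelValue` to header
#'   names; roles absent from the table fall back to generated ids.
#' @param labelKind one of `"pKd"`, `"KIBA"`, `"pIC50"`, `"binary"`.
#' @param fasta optional FASTA file; sequences are matched to `proteinId`.
#' @param verbose print the rejection count.
#' @return an [AffinityDataset-class]; rejected rows are recorded in
#'   `metadata(x)$rejections`.
#' @examples
#' tab <- data.frame(smiles = c("CCO", "c1ccccc1"), sequence = "MKV",
#'                   label = c(7.2, 5.0))
#' f <- tempfile(fileext = ".csv"); write.csv(tab, f, row.names = FALSE)
#' readAffinityTable(f, columns = c(drugSmiles = "smiles",
#'   proteinSequence = "sequence", labelValue = "label"))
#' @export
readAffinityTable <- function(path, dialect = c("csv", "tsv"),
                              columns = c(drugSmiles = "drugSmiles",
                                          proteinSequence = "proteinSequence",
                                          labelValue = "labelValue"),
                              labelKind = "pKd", fasta = NULL,
                              verbose = FALSE) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- if (dialect == "csv") "," else "\t"
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           quote = "\"", comment.char = "")
  for (role in c("drugSmiles", "labelValue"))
    if (!columns[[role]] %in% names(tab))
      stop("required column '", columns[[role]], "' (", role, ") missing")

  smiles <- as.character(tab[[columns[["drugSmiles"]]]])
  label <- suppressWarnings(as.numeric(tab[[columns[["labelValue"]]]]))
  drugId <- if (!is.na(columns["drugId"]) && columns[["drugId"]] %in% names(tab))
    as.character(tab[[columns[["drugId"]]]]) else paste0("D", seq_along(smiles))
  protId <- if (!is.na(columns["proteinId"]) && columns[["proteinId"]] %in% names(tab))
    as.character(tab[[columns[["proteinId"]]]]) else NULL

  seqcol <- columns["proteinSequence"]
  if (!is.na(seqcol) && seqcol %in% names(tab)) {
    seqs <- toupper(as.character(tab[[seqcol]]))
  } else if (!is.null(fasta)) {
    if (is.null(protId)) stop("proteinId column required to resolve sequences from FASTA")
    fa <- .readFasta(fasta)
    seqs <- unname(fa[protId])
  } else stop("required column '", seqcol, "' (proteinSequence) missing")
  if (is.null(protId)) protId <- paste0("P", as.integer(factor(seqs)))

  ok <- rep(TRUE, length(smiles))
  reason <- character(length(smiles))
  aaOk <- grepl("^[ACDEFGHIKLMNPQRSTVWYX]+$", seqs) & !is.na(seqs)
  reason[!aaOk] <- "invalid or missing protein sequence"
  ok <- ok & aaOk
  finiteOk <- is.finite(label)
  if (labelKind == "binary") finiteOk <- finiteOk & label %in% c(0, 1)
  reason[ok & !finiteOk] <- "invalid label"
  ok <- ok & finiteOk
  heavy <- rep(NA_integer_, length(smiles))
  heavy[ok] <- vapply(smiles[ok], function(s) {
    m <- tryCatch(.parseSmiles(s), error = function(e) NULL)
    if (is.null(m)) 0L else nrow(m$atoms)
  }, 0L)
  smiOk <- !ok | (heavy >= 1L & !is.na(heavy))
  reason[ok & !smiOk] <- "unparseable SMILES"
  ok <- ok & smiOk

  rej <- data.frame(row = which(!ok), reason = reason[!ok])
  if (verbose && nrow(rej))
    message(nrow(rej), " row(s) rejected: ",
            paste(unique(rej$reason), collapse = "; "))
  rec <- data.frame(drugId = drugId[ok], drugSmiles = smiles[ok],
                    proteinId = protId[ok], proteinSequence = seqs[ok],
                    labelValue = label[ok], labelKind = labelKind,
                    stringsAsFactors = FALSE)
  methods::new("AffinityDataset", records = rec,
               metadata = list(rejections = rej, source = path))
}

#' Write an affinity table
#'
#' Inverse of [readAffinityTable()]: serializes the record table to CSV/TSV.
#'
#' @param x an [AffinityDataset-class].
#' @param path output file.
#' @param dialect `"csv"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
writeAffinityTable <- function(x, path, dialect = c("csv", "tsv")) {
  dialect <- match.arg(dialect)
  utils::write.table(records(x), path, sep = if (dialect == "csv") "," else "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

.readFasta <- function(path) {
  lines <- readLines(path)
  idx <- grep("^>", lines)
  ids <- sub("^>\\s*(\\S+).*$", "\\1", lines[idx])
  ends <- c(idx[-1L] - 1L, length(lines))
  seqs <- vapply(seq_along(idx), function(i)
    toupper(paste0(lines[(idx[i] + 1L):ends[i]], collapse = "")), "")
  stats::setNames(seqs, ids)
}

#' Transform a dissociation constant to pKd
#'
#' `pKd = -log10(Kd * 1e-9)` with Kd in nanomolar, the convention used by
#' the standard Davis-benchmark preprocessing: 1 nM maps to 9, and the
#' 10,000 nM placeholder used for non-binding kinase pairs maps to 5.
#'
#' @param kd_nM dissociation constant(s) in nM; must be positive.
#' @return pKd value(s); strictly decreasing in `kd_nM`.
#' @examples
#' pkdTransform(c(1, 30, 10000))
#' @export
pkdTransform <- function(kd_nM) {
  if (any(!is.finite(kd_nM)) || any(kd_nM <= 0))
    stop("kd_nM must be positive and finite")
  -log10(kd_nM * 1e-9)
}

#' Invert [pkdTransform()]
#' @param pkd pKd value(s).
#' @return Kd in nM.
#' @export
kdFromPkd <- function(pkd) 10^(9 - pkd)

#' Filter sparsely measured targets (KIBA-style)
#'
#' Retains exactly the records whose protein has at least `minPerTarget`
#' measurements in the table (the KIBA benchmark uses 10), preserving the
#' original record order. Optionally applies the symmetric rule per drug as
#' well; when both are enabled the two filters are iterated to a joint fixed
#' point, since dropping a target can push a drug below threshold.
#'
#' @param x an [AffinityDataset-class].
#' @param minPerTarget minimum measurements per protein.
#' @param perDrug also require `minPerTarget` measurements per drug.
#' @return the filtered [AffinityDataset-class]. Idempotent.
#' @export
filterKiba <- function(x, minPerTarget = 10L, perDrug = FALSE) {
  rec <- records(x)
  repeat {
    n0 <- nrow(rec)
    keep <- table(rec$proteinId)[rec$proteinId] >= minPerTarget
    rec <- rec[as.logical(keep), , drop = FALSE]
    if (perDrug && nrow(rec)) {
      keep <- table(rec$drugId)[rec$drugId] >= minPerTarget
      rec <- rec[as.logical(keep), , drop = FALSE]
    }
    if (!perDrug || nrow(rec) == n0) break
  }
  rownames(rec) <- NULL
  methods::initialize(x, records = rec)
}

#' Assign records to cross-validation folds
#'
#' Record-level random partition into `k` folds of near-equal size (the
#' benchmark protocol for affinity prediction; drugs and proteins may appear
#' in several folds). Deterministic for a fixed seed and independent of the
#' caller's RNG state.
#'
#' @param n number of records, or an [AffinityDataset-class].
#' @param k number of folds (default 5).
#' @param seed integer seed.
#' @return a [DatasetSplit-class].
#' @export
makeCvFolds <- function(n, k = 5L, seed = 1L) {
  if (methods::is(n, "AffinityDataset")) n <- nrow(records(n))
  n <- as.integer(n); k <- as.integer(k)
  if (n < k) stop("need at least k records (", n, " < ", k, ")")
  fold <- withRNG(seed, {
    sample(rep_len(seq_len(k) - 1L, n))
  })
  methods::new("DatasetSplit", foldOf = as.integer(fold), k = k,
               seed = as.integer(seed))
}

#' Serialize / restore a fold assignment as JSON
#' @param split a [DatasetSplit-class].
#' @param path JSON file path.
#' @return `writeDatasetSplit`: `path` invisibly; `readDatasetSplit`: the
#'   restored [DatasetSplit-class].
#' @export
writeDatasetSplit <- function(split, path) {
  jsonlite::write_json(list(foldOf = split@foldOf, k = split@k,
                            seed = split@seed),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeDatasetSplit
#' @export
readDatasetSplit <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  methods::new("DatasetSplit", foldOf = as.integer(x$foldOf),
               k = as.integer(x$k), seed = as.integer(x$seed))
}

#' Extract C-alpha coordinates from a PDB file
#'
#' Returns one coordinate per residue in sequence order, from the first
#' model only. Alternate locations are resolved to the highest-occupancy
#' altloc (ties broken alphabetically, i.e. in favour of 'A'); residues
#' lacking a C-alpha atom are skipped with a warning. Insertion-coded
#' residues are kept in file order.
#'
#' @param pdb path to a PDB file with fixed-column ATOM records.
#' @param chain optional chain identifier; default takes the first chain.
#' @return data.frame with columns `residueIndex` (1-based), `resid`
#'   (3-letter name), `x`, `y`, `z` (Angstrom).
#' @export
extractCaCoordinates <- function(pdb, chain = NULL) {
  p <- suppressWarnings(bio3d::read.pdb(pdb, multi = FALSE, rm.alt = FALSE,
                                        verbose = FALSE))
  at <- p$atom
  at <- at[at$type == "ATOM", , drop = FALSE]
  if (is.null(chain)) chain <- at$chain[1L]
  at <- at[at$chain %in% chain, , drop = FALSE]
  # residue key in file order (resno + insertion code)
  ins <- if ("insert" %in% names(at)) ifelse(is.na(at$insert), "", at$insert) else ""
  key <- paste(at$resno, ins, sep = "_")
  resKeys <- unique(key)
  ca <- at[at$elety == "CA", , drop = FALSE]
  if (nrow(ca) == 0L) stop("no C-alpha atoms found in ", pdb)
  caKey <- paste(ca$resno, if ("insert" %in% names(ca))
    ifelse(is.na(ca$insert), "", ca$insert) else "", sep = "_")
  rows <- lapply(resKeys, function(k) {
    sub <- ca[caKey == k, , drop = FALSE]
    if (nrow(sub) == 0L) return(NULL)
    if (nrow(sub) > 1L) {  # altloc: highest occupancy, ties -> 'A'
      occ <- ifelse(is.na(sub$o), 1, sub$o)
      alt <- ifelse(is.na(sub$alt), "A", sub$alt)
      sub <- sub[order(-occ, alt), , drop = FALSE][1L, , drop = FALSE]
    }
    sub
  })
  missing <- resKeys[vapply(rows, is.null, TRUE)]
  if (length(missing))
    warning(length(missing), " residue(s) lack a C-alpha atom and were skipped")
  rows <- do.call(rbind, rows)
  data.frame(residueIndex = seq_len(nrow(rows)), resid = rows$resid,
             x = rows$x, y = rows$y, z = rows$z)
}

# evaluate expr under a private RNG stream, restoring the caller's state
withRNG <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}
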