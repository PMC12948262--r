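writeTable <- function(df, dialect = "csv") {
  f <- tempfile(fileext = paste0(".", dialect))
  utils::write.table(df, f, sep = if (dialect == "csv") "," else "\t",
                     row.names = FALSE, quote = FALSE)
  f
}

cols <- c(drugSmiles = "smiles", proteinSequence = "sequence",
          labelValue = "label")

test_that("affinity tables load, reject bad rows, and round-trip", {
  tab <- data.frame(smiles = c("CCO", "c1ccccc1", "CCN"),
                    sequence = c("MKVL", "AAAA", "MKWX"),
                    label = c(7.1, 5.0, 6.2))
  ds <- readAffinityTable(writeTable(tab), columns = cols)
  expect_s4_class(ds, "AffinityDataset")
  expect_equal(nrow(records(ds)), 3L)

  bad <- tab
  bad$smiles[2L] <- "not_a_smiles(("
  ds2 <- readAffinityTable(writeTable(bad), columns = cols)
  expect_equal(nrow(records(ds2)), 2L)
  expect_equal(ds2@metadata$rejections$reason, "unparseable SMILES")

  seqBad <- tab; seqBad$sequence[1L] <- "MK1L"
  ds3 <- readAffinityTable(writeTable(seqBad), columns = cols)
  expect_equal(nrow(records(ds3)), 2L)

  expect_error(readAffinityTable(writeTable(tab[, -1L]), columns = cols),
               "missing")

  # write-then-read round trip over both dialects
  for (dialect in c("csv", "tsv")) {
    f <- tempfile()
    writeAffinityTable(ds, f, dialect)
    back <- readAffinityTable(f, dialect,
                              columns = c(drugId = "drugId",
                                          drugSmiles = "drugSmiles",
                                          proteinId = "proteinId",
                                          proteinSequence = "proteinSequence",
                                          labelValue = "labelValue"))
    expect_equal(records(back)[names(records(ds))], records(ds))
  }
})

test_that("sequences resolve from FASTA via protein id", {
  fa <- tempfile(fileext = ".fasta")
  writeLines(c(">P1 some description", "MKV", "LAA", ">P2", "WWWW"), fa)
  tab <- data.frame(smiles = c("CCO", "CC"), pid = c("P1", "P2"),
                    label = c(1, 2))
  ds <- readAffinityTable(writeTable(tab),
                          columns = c(drugSmiles = "smiles",
                                      proteinId = "pid",
                                      proteinSequence = "zzz",
                                      labelValue = "label"),
                          fasta = fa)
  expect_equal(records(ds)$proteinSequence, c("MKVLAA", "WWWW"))
})

test_that("pKd transform follows the nanomolar convention", {
  expect_equal(pkdTransform(1), 9)
  expect_equal(pkdTransform(10000), 5)      # Davis non-binder placeholder
  expect_equal(pkdTransform(30), 7.5229, tolerance = 1e-4)
  expect_error(pkdTransform(0), "positive")
  expect_error(pkdTransform(-3), "positive")
  # strictly decreasing and inverse-consistent across the realistic range
  kd <- 10^stats::runif(50, -3, 7)
  expect_true(all(diff(pkdTransform(sort(kd))) < 0))
  expect_equal(kdFromPkd(pkdTransform(kd)), kd, tolerance = 1e-9)
})

test_that("KIBA-style target filter keeps well-measured targets only", {
  rec <- data.frame(
    drugId = paste0("D", 1:26), drugSmiles = "CCO",
    proteinId = rep(c("A", "B", "C"), c(12L, 10L, 4L)),
    proteinSequence = "MKVL", labelValue = 1, labelKind = "KIBA")
  ds <- methods::new("AffinityDataset", records = rec)
  kept <- filterKiba(ds, 10L)
  expect_equal(nrow(records(kept)), 22L)
  expect_setequal(unique(records(kept)$proteinId), c("A", "B"))
  # order preserved, idempotent, identity when all pass
  expect_equal(records(kept)$drugId, rec$drugId[rec$proteinId != "C"])
  expect_equal(records(filterKiba(kept, 10L)), records(kept))
  expect_equal(records(filterKiba(ds, 4L)), records(ds))
  empty <- methods::new("AffinityDataset", records = rec[0L, ])
  expect_equal(nrow(records(filterKiba(empty))), 0L)
})

test_that("cross-validation folds partition the records deterministically", {
  s <- makeCvFolds(10L, k = 5L, seed = 1L)
  expect_equal(unname(tabulate(foldOf(s) + 1L, 5L)), rep(2L, 5L))
  expect_identical(foldOf(makeCvFolds(10L, 5L, seed = 1L)), foldOf(s))
  expect_true(any(foldOf(makeCvFolds(100L, 5L, 1L)) !=
                    foldOf(makeCvFolds(100L, 5L, 2L))))
  expect_error(makeCvFolds(3L, k = 5L), "at least k")
  # partition property for all n <= 50
  for (n in 5:50) {
    f <- foldOf(makeCvFolds(n, 5L, seed = n))
    expect_equal(length(f), n)
    sizes <- tabulate(f + 1L, 5L)
    expect_lte(diff(range(sizes)), 1L)
  }
  # JSON round trip
  p <- tempfile(fileext = ".json")
  writeDatasetSplit(s, p)
  s2 <- readDatasetSplit(p)
  expect_identical(foldOf(s2), foldOf(s))
  expect_identical(s2@k, s@k)
})

test_that("C-alpha extraction handles missing atoms and altlocs", {
  coords <- rbind(c(0, 0, 0), c(3.8, 0, 0), c(7.6, 0, 0))
  pdb <- tempfile(fileext = ".pdb")
  writeFixturePdb(coords, "MKV", pdb)
  ca <- extractCaCoordinates(pdb)
  expect_equal(nrow(ca), 3L)
  expect_equal(as.matrix(ca[, c("x", "y", "z")]), coords,
               ignore_attr = TRUE, tolerance = 1e-3)
  expect_equal(ca$resid, c("MET", "LYS", "VAL"))

  # residue 2 has no CA at all -> skipped with a warning
  lines <- readLines(pdb)
  writeLines(c(lines[1L], sub("  CA  ", "  CB  ", lines[2L]), lines[3:4]), pdb)
  expect_warning(ca2 <- extractCaCoordinates(pdb), "skipped")
  expect_equal(nrow(ca2), 2L)

  # altloc A (occupancy 0.4) vs B (0.6): highest occupancy wins
  alt <- c(
    "ATOM      1  CA  ALA A   1       0.000   0.000   0.000  1.00  0.00           C",
    "ATOM      2  CA AVAL A   2       3.800   0.000   0.000  0.40  0.00           C",
    "ATOM      3  CA BVAL A   2       3.900   0.000   0.000  0.60  0.00           C",
    "ATOM      4  CA  GLY A   3       7.600   0.000   0.000  1.00  0.00           C",
    "END")
  writeLines(alt, pdb)
  ca3 <- extractCaCoordinates(pdb)
  expect_equal(ca3$x[2L], 3.9, tolerance = 1e-6)
  # occupancy tie -> altloc 'A'
  tie <- sub("  0.40  ", "  0.60  ", alt)
  writeLines(tie, pdb)
  expect_equal(extractCaCoordinates(pdb)$x[2L], 3.8, tolerance = 1e-6)

  writeLines(c(sub("  CA  ", "  CB  ", alt[1L]), "END"), pdb)
  expect_error(extractCaCoordinates(pdb), "C-alpha")
})
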