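test_that("generated molecules are valid, deterministic and span aromaticity", {
  m1 <- generateMolecules(10L, seed = 1L)
  expect_length(m1, 10L)
  expect_identical(m1, generateMolecules(10L, seed = 1L))
  for (s in m1) expect_gte(nrow(moleculeTopology(s)$atoms), 1L)
  fr <- vapply(generateMolecules(200L, seed = 2L), aromaticFraction, 0)
  decile <- findInterval(fr, seq(0, 1, 0.1), rightmost.closed = TRUE)
  expect_true(all(tabulate(decile, 10L) >= 5L))
})

test_that("protein sequences vary in hydrophobic content", {
  s1 <- generateProteinSequences(20L, c(40L, 80L), seed = 1L)
  expect_identical(s1, generateProteinSequences(20L, c(40L, 80L), seed = 1L))
  expect_true(all(nchar(s1) >= 40L & nchar(s1) <= 80L))
  hf <- vapply(s1, hydrophobicFraction, 0)
  expect_gt(max(hf) - min(hf), 0.3)
})

test_that("chain geometries respect the C-alpha virtual bond", {
  for (mode in c("ideal_chain", "helix", "random_walk")) {
    cc <- generateChainCoords(25L, mode, seed = 3L)
    steps <- sqrt(rowSums((cc[-1L, ] - cc[-25L, ])^2))
    expect_equal(steps, rep(3.8, 24L), tolerance = 1e-6)
  }
  ic <- generateChainCoords(5L, "ideal_chain")
  D <- computeDistanceMatrix(ic)
  expect_equal(D[1L, 3L], 7.6, tolerance = 1e-9)
  expect_equal(D[1L, 4L], 11.4, tolerance = 1e-9)
  # helix i,i+3 distance from the closed-form chord of the parameterization:
  # rise 1.5/residue, 100 deg twist, radius solved for a 3.8 A bond
  hx <- generateChainCoords(10L, "helix")
  radius <- sqrt(3.8^2 - 1.5^2) / (2 * sin(50 * pi / 180))
  chord3 <- sqrt((2 * radius * sin(3 * 50 * pi / 180))^2 + (3 * 1.5)^2)
  Dh <- computeDistanceMatrix(hx)
  expect_equal(Dh[1L, 4L], chord3, tolerance = 1e-9)
  expect_gt(chord3, 5.0); expect_lt(chord3, 5.4)
  # self-avoidance of the random walk
  rw <- generateChainCoords(40L, "random_walk", seed = 7L)
  Drw <- computeDistanceMatrix(rw)
  expect_gte(min(Drw[upper.tri(Drw)]), 3.0)
  expect_identical(rw, generateChainCoords(40L, "random_walk", seed = 7L))
  expect_error(generateChainCoords(1L), "at least 2")
})

test_that("planted affinity follows its closed form and is recoverable", {
  # deterministic linear form
  y <- plantAffinity("c1ccccc1C", "AAKR", weights = c(1, 2, 0), noiseSd = 0)
  expect_equal(y, 1 * (6 / 7) + 2 * 0.5)
  # benzene + poly-alanine: both fractions are 1
  expect_equal(plantAffinity("c1ccccc1", "AAAA", weights = c(1, 1, 0),
                             noiseSd = 0), 2.0)
  # least-squares recovery of the planted weights at n = 1000
  set.seed(8)
  mols <- generateMolecules(60L, seed = 21L)
  seqs <- generateProteinSequences(40L, c(30L, 60L), seed = 22L)
  af <- vapply(mols, aromaticFraction, 0)
  hf <- vapply(seqs, hydrophobicFraction, 0)
  di <- sample(60L, 1000L, TRUE); pj <- sample(40L, 1000L, TRUE)
  yy <- vapply(seq_len(1000L), function(r)
    plantAffinity(mols[di[r]], seqs[pj[r]], weights = c(2, 2, 2),
                  noiseSd = 0.1, seed = r), 0)
  fit <- stats::lm(yy ~ af[di] + hf[pj] + I(af[di] * hf[pj]))
  expect_equal(unname(stats::coef(fit)[2:4]), c(2, 2, 2), tolerance = 0.05)
})

test_that("mock providers produce distinct, unit-scale embeddings", {
  p <- mockAtomProvider(dim = 512L, seed = 1L)
  e <- embedAtoms(p, "c1ccccc1CCN")
  expect_equal(ncol(e), 512L)
  expect_equal(mean(apply(e, 1L, stats::sd)), 1, tolerance = 0.15)
  r <- mockResidueProvider(dim = 2560L, seed = 1L)
  er <- embedResidues(r, "MKVLAW")
  expect_equal(dim(er), c(6L, 2560L))
  expect_identical(er, embedResidues(r, "MKVLAW"))
  # 1000 random identity tuples: no near-duplicate embeddings
  set.seed(9)
  keys <- unique(replicate(1000L, paste(sample(letters, 4L), collapse = "|")))
  X <- vapply(keys, dualDTA:::.hashVector, numeric(512L), dim = 512L, seed = 1L)
  Xn <- sweep(X, 2L, sqrt(colSums(X^2)), "/")
  cs <- crossprod(Xn)
  diag(cs) <- 0
  expect_lt(max(cs), 0.99)
})

test_that("PDB fixtures round-trip and synthetic datasets are reproducible", {
  cc <- generateChainCoords(5L, "random_walk", seed = 2L)
  f <- tempfile(fileext = ".pdb")
  writeFixturePdb(cc, "MKVLA", f)
  ca <- extractCaCoordinates(f)
  expect_equal(as.matrix(ca[, c("x", "y", "z")]), cc, ignore_attr = TRUE,
               tolerance = 1e-3)
  expect_equal(ca$resid, c("MET", "LYS", "VAL", "LEU", "ALA"))

  d1 <- suppressWarnings(generateSyntheticDataset(nPairs = 40L, nDrugs = 10L,
                                                  nProteins = 5L, seed = 4L))
  d2 <- suppressWarnings(generateSyntheticDataset(nPairs = 40L, nDrugs = 10L,
                                                  nProteins = 5L, seed = 4L))
  expect_identical(records(d1), records(d2))
  expect_identical(d1@metadata$coords, d2@metadata$coords)
  rec <- records(d1)
  expect_equal(nrow(rec), 40L)
  expect_false(any(duplicated(paste(rec$drugId, rec$proteinId))))
  # labels sit on the pKd-like scale
  expect_true(all(rec$labelValue > 2 & rec$labelValue < 12))
  # pairs as sampled exceeding the grid are rejected
  expect_error(generateSyntheticDataset(nPairs = 100L, nDrugs = 5L,
                                        nProteins = 5L), "exceeds")
})
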