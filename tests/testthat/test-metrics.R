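# Brute-force oracles for every metric, written as plain double loops /
# direct formula transcriptions, independent of the implementations.

bruteCI <- function(y, p) {
  num <- 0; den <- 0
  for (i in seq_along(y)) for (j in seq_along(y)) {
    if (y[i] > y[j]) {
      den <- den + 1
      if (p[i] > p[j]) num <- num + 1
      else if (p[i] == p[j]) num <- num + 0.5
    }
  }
  num / den
}

bruteRm2 <- function(y, p) {
  r2 <- cor(y, p)^2
  k <- sum(y * p) / sum(p^2)
  r02 <- 1 - sum((y - k * p)^2) / sum((y - mean(y))^2)
  r2 * (1 - sqrt(abs(r2 - r02)))
}

bruteAUC <- function(y, p) {
  pos <- p[y == 1]; neg <- p[y == 0]
  s <- 0
  for (a in pos) for (b in neg)
    s <- s + (a > b) + 0.5 * (a == b)
  s / (length(pos) * length(neg))
}

test_that("concordance index matches its definition and the brute force", {
  y <- c(1, 2, 3, 4)
  expect_equal(concordanceIndex(y, y), 1)
  expect_equal(concordanceIndex(y, -y), 0)
  expect_equal(concordanceIndex(y, rep(1, 4L)), 0.5)  # all ties
  expect_error(concordanceIndex(rep(2, 4L), y), "all labels equal")
  set.seed(1)
  for (rep in 1:5) {
    yy <- sample(rnorm(100L))
    pp <- rnorm(100L) + 0.3 * yy
    pp[sample(100L, 10L)] <- pp[1L]         # inject prediction ties
    expect_identical(concordanceIndex(yy, pp), bruteCI(yy, pp))
  }
})

test_that("rm-squared follows the through-origin penalty formula", {
  y <- c(1, 2, 3, 4, 5)
  expect_equal(rmSquared(y, y), 1)
  set.seed(2)
  for (rep in 1:10) {
    yy <- rnorm(50L, mean = 6)
    pp <- 0.8 * yy + rnorm(50L, sd = 0.5)
    expect_equal(rmSquared(yy, pp), bruteRm2(yy, pp), tolerance = 1e-10)
  }
  # a constant shift moves predictions off the origin line: penalized
  expect_lt(rmSquared(y, y + 1), 1)
  # pure positive rescaling leaves the through-origin fit exact, so the
  # penalty term vanishes under this (standard) convention
  expect_equal(rmSquared(y, 2 * y), 1, tolerance = 1e-12)
  # symmetrized variant averages both through-origin directions
  yy <- rnorm(30L, 5); pp <- yy + rnorm(30L, sd = 1)
  r2 <- cor(yy, pp)^2
  expect_lte(rmSquared(yy, pp, "average"), r2 + 1e-12)
  expect_error(rmSquared(y, rep(1, 5L)), "zero variance")
})

test_that("regression panel agrees with textbook formulas", {
  y <- c(5, 6, 7, 8, 9)
  m <- regressionMetrics(y, y)
  expect_equal(unlist(m), c(mse = 0, mae = 0, pearson_r = 1, ci = 1, rm2 = 1))
  m2 <- regressionMetrics(y, y + 1)
  expect_equal(m2$mse, 1); expect_equal(m2$mae, 1)
  expect_equal(m2$pearson_r, 1)
  set.seed(3)
  yy <- rnorm(100L); pp <- 0.5 * yy + rnorm(100L)
  m3 <- regressionMetrics(yy, pp)
  expect_equal(m3$mse, mean((yy - pp)^2), tolerance = 1e-12)
  expect_equal(m3$mae, mean(abs(yy - pp)), tolerance = 1e-12)
  expect_equal(m3$pearson_r, cor(yy, pp), tolerance = 1e-12)
  expect_identical(m3$ci, bruteCI(yy, pp))
  expect_equal(m3$rm2, bruteRm2(yy, pp), tolerance = 1e-10)
})

test_that("classification panel matches confusion-matrix and rank oracles", {
  y <- c(0, 0, 1, 1)
  sep <- c(0.1, 0.2, 0.8, 0.9)
  m <- classificationMetrics(y, sep)
  expect_equal(unlist(m), c(acc = 1, auc = 1, ba = 1, mcc = 1, f1 = 1))
  # degenerate constant predictor on a balanced set
  md <- classificationMetrics(y, rep(1, 4L))
  expect_equal(md$acc, 0.5); expect_equal(md$mcc, 0)
  expect_error(classificationMetrics(c(1, 1), c(0.2, 0.4)), "one class")
  set.seed(4)
  yy <- rbinom(200L, 1L, 0.4)
  pp <- round(plogis(rnorm(200L) + yy), 2L)   # rounding creates ties
  m2 <- classificationMetrics(yy, pp)
  pred <- as.integer(pp > 0.5)
  tp <- sum(pred & yy); tn <- sum(!pred & !yy)
  fp <- sum(pred & !yy); fn <- sum(!pred & yy)
  expect_equal(m2$acc, (tp + tn) / 200)
  expect_equal(m2$ba, (tp / (tp + fn) + tn / (tn + fp)) / 2)
  expect_equal(m2$f1, 2 * tp / (2 * tp + fp + fn))
  expect_equal(m2$mcc, (tp * tn - fp * fn) /
                 sqrt(prod(c(tp + fp, tp + fn, tn + fp, tn + fn))))
  expect_identical(m2$auc, bruteAUC(yy, pp))
  if (requireNamespace("pROC", quietly = TRUE))
    expect_equal(m2$auc,
                 as.numeric(pROC::auc(pROC::roc(yy, pp, quiet = TRUE))),
                 tolerance = 1e-12)
})

test_that("metrics are invariant to joint permutations and calibrated at chance", {
  set.seed(5)
  y <- rnorm(60L); p <- rnorm(60L)
  perm <- sample(60L)
  m1 <- regressionMetrics(y, p)
  m2 <- regressionMetrics(y[perm], p[perm])
  expect_equal(m1, m2, tolerance = 1e-12)
  # a random predictor's CI concentrates at 0.5
  cis <- vapply(1:100, function(i)
    concordanceIndex(rnorm(50L), rnorm(50L)), 0)
  expect_gt(mean(cis), 0.45); expect_lt(mean(cis), 0.55)
})

test_that("evaluation report writes consistent artifacts", {
  set.seed(6)
  y <- rnorm(300L, 7); p <- y + rnorm(300L, sd = 0.5)
  out <- tempfile()
  files <- evaluationReport(y, p, out)
  met <- jsonlite::read_json(files$metrics, simplifyVector = TRUE)
  ref <- regressionMetrics(y, p)
  expect_equal(met$mse, ref$mse, tolerance = 1e-9)
  expect_equal(met$ci, ref$ci, tolerance = 1e-9)
  kde <- utils::read.csv(files$kde)
  for (s in unique(kde$series)) {
    cur <- kde[kde$series == s, ]
    area <- sum(diff(cur$x) * (head(cur$density, -1L) + tail(cur$density, -1L)) / 2)
    expect_equal(area, 1, tolerance = 1e-3)
  }
  sc <- utils::read.csv(files$scatter)
  expect_equal(nrow(sc), 300L)
  # KDE recovers a known density
  z <- rnorm(5000L)
  d <- stats::density(z, bw = stats::bw.nrd(z))
  expect_lt(max(abs(d$y - dnorm(d$x))), 0.05)
})
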