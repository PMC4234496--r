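test_that("a perfectly separating gene scores accuracy 1 with every classifier", {
  d <- makeSignalData(c("g1", "g2"), "g1", n = 40)
  for (cl in c("svm", "knn", "rf")) {
    cfg <- scorerConfig(cl, seed = 4, ntree = 50)
    expect_equal(scoreGeneSet(d, "g1", cfg), 1, info = cl)
  }
})

test_that("scores are deterministic, order-invariant and rescale-invariant", {
  set.seed(8)
  d <- makeData(paste0("g", 1:6), halfHalf(30), seed = 8)
  for (cl in c("svm", "rf")) {
    cfg <- scorerConfig(cl, seed = 99, ntree = 50)
    s1 <- scoreGeneSet(d, c("g1", "g3", "g5"), cfg)
    expect_identical(s1, scoreGeneSet(d, c("g1", "g3", "g5"), cfg))
    expect_identical(s1, scoreGeneSet(d, c("g5", "g1", "g3"), cfg))
  }
  # per-fold standardization absorbs an affine rescale of one gene (svm)
  cfg <- scorerConfig("svm", seed = 99)
  s1 <- scoreGeneSet(d, c("g1", "g3"), cfg)
  m <- exprsValues(d)
  m["g3", ] <- 7 * m["g3", ] - 2
  d2 <- LabeledExpression(m, phenoLabels(d))
  expect_equal(scoreGeneSet(d2, c("g1", "g3"), cfg), s1, tolerance = 1e-10)
})

test_that("null-data accuracy centers on 0.5", {
  # Monte-Carlo null: labels independent of expression
  set.seed(1234)
  accs <- vapply(1:30, function(i) {
    d <- makeData(paste0("g", 1:3), halfHalf(40), seed = 1000 + i)
    scoreGeneSet(d, paste0("g", 1:3), scorerConfig("svm", seed = i))
  }, numeric(1))
  expect_gt(mean(accs), 0.4)
  expect_lt(mean(accs), 0.6)
})

test_that("scoring rejects unknown genes and oversized fold counts", {
  d <- makeData(c("a", "b"), halfHalf(10))
  expect_error(scoreGeneSet(d, c("a", "zz"), scorerConfig("svm")),
               "absent")
  expect_error(scoreGeneSet(d, "a", scorerConfig("svm", folds = 6)),
               "smaller class")
})

test_that("chuangScore reproduces closed-form mutual information", {
  n <- 40
  labels <- halfHalf(n)
  # activity identical for every sample -> MI 0 (flat gene, logged)
  d0 <- makeData("g1", labels,
                 values = matrix(1, 1, n))
  expect_equal(suppressMessages(chuangScore(d0, "g1")), 0)
  # activity = label exactly, balanced -> 1 bit
  d1 <- makeData("g1", labels,
                 values = matrix(as.numeric(labels), 1, n))
  expect_equal(chuangScore(d1, "g1"), 1)
})

test_that("chuangScore matches a histogram MI oracle on random draws", {
  set.seed(77)
  for (rep in 1:10) {
    n <- 100
    labels <- sample(rep(c(0L, 1L), each = 50))
    vals <- matrix(rnorm(3 * n), 3, n)
    d <- makeData(paste0("g", 1:3), labels, values = vals)
    got <- chuangScore(d, paste0("g", 1:3), bins = 8)
    # oracle: recompute activity, bin, and use H(A) + H(Y) - H(A,Y)
    z <- t(scale(t(vals)))
    act <- colMeans(z)
    cuts <- seq(min(act), max(act), length.out = 9)
    b <- findInterval(act, cuts, rightmost.closed = TRUE, all.inside = TRUE)
    H <- function(x) {
      p <- table(x) / length(x)
      -sum(p * log2(p))
    }
    oracle <- H(b) + H(labels) - H(paste(b, labels))
    expect_equal(got, oracle, tolerance = 1e-12)
    expect_gte(got, 0)
    expect_lte(got, H(labels) + 1e-12)
  }
})

test_that("zero-variance genes contribute zero z-scores", {
  n <- 40
  labels <- halfHalf(n)
  set.seed(2)
  vals <- rbind(rnorm(n), rep(3, n))
  d <- makeData(c("sig", "flat"), labels, values = vals)
  expect_message(s2 <- chuangScore(d, c("sig", "flat")), "zero-variance")
  # equivalent to halving the informative gene's activity: same bins
  dHalf <- makeData("sig", labels, values = vals[1, , drop = FALSE] / 2)
  expect_equal(s2, chuangScore(dHalf, "sig"))
})

test_that("greedy MI search stops when no neighbor improves", {
  n <- 60
  labels <- halfHalf(n)
  set.seed(42)
  # star: seed S with neighbors that are pure noise -> singleton
  g <- makeGraph(rbind(c("S", "a"), c("S", "b")))
  vals <- rbind(as.numeric(labels) + rnorm(n, sd = 0.1),
                rnorm(n), rnorm(n))
  d <- makeData(c("S", "a", "b"), labels, values = vals)
  expect_equal(greedyChuangSearch(g, d, "S"), "S")
})

test_that("greedy MI search adds exactly the helpful neighbor on a chain", {
  n <- 80
  labels <- halfHalf(n)
  set.seed(43)
  # chain a - S - c: S and c share the signal, a is noise
  g <- makeGraph(rbind(c("a", "S"), c("S", "c"), c("c", "d")))
  sig <- as.numeric(labels) * 2 - 1
  vals <- rbind(rnorm(n),                      # a
                sig + rnorm(n, sd = 0.8),      # S
                sig + rnorm(n, sd = 0.8),      # c
                rnorm(n))                      # d
  d <- makeData(c("a", "S", "c", "d"), labels, values = vals)
  res <- greedyChuangSearch(g, d, "S")
  # exhaustive check of the first step: adding c must beat adding a
  s0 <- chuangScore(d, "S")
  sa <- chuangScore(d, c("S", "a"))
  sc <- chuangScore(d, c("S", "c"))
  expect_gt(sc, sa)
  if (sc > s0) expect_true(all(c("S", "c") %in% res))
})

test_that("scorer config round-trips through the key=value file", {
  cfg <- scorerConfig("rf", folds = 4, repeats = 2, seed = 123, ntree = 50)
  f <- withr::local_tempfile()
  writeScorerConfig(cfg, f)
  cfg2 <- readScorerConfig(f)
  expect_equal(cfg2@classifier, "rf")
  expect_equal(cfg2@folds, 4L)
  expect_equal(cfg2@repeats, 2L)
  expect_equal(cfg2@seed, 123L)
  expect_equal(cfg2@params$ntree, 50)
  d <- makeSignalData(paste0("g", 1:3), "g1", n = 20)
  expect_identical(scoreGeneSet(d, paste0("g", 1:3), cfg),
                   scoreGeneSet(d, paste0("g", 1:3), cfg2))
})

test_that("cross-validated AUC separates signal from noise", {
  d <- makeSignalData(c("s", "n1", "n2"), "s", n = 40, seed = 12)
  cfg <- scorerConfig("svm", seed = 5)
  expect_gt(scoreGeneSetAUC(d, "s", cfg), 0.95)
  dn <- makeData(c("n1", "n2"), halfHalf(40), seed = 99)
  aucNull <- scoreGeneSetAUC(dn, c("n1", "n2"), cfg)
  expect_lt(abs(aucNull - 0.5), 0.35)
})

test_that("a planted nonlinear gene set scores well above the null with svm", {
  cfg <- simulationConfig(nNodes = 60L, nSamples = 100L,
                          outcomeModel = "nonlinear", seed = 9L)
  inst <- generateInstance(cfg)
  s <- scoreGeneSet(inst$data, inst$truth$members,
                    scorerConfig("svm", seed = 2L))
  expect_gt(s, 0.65)
})
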