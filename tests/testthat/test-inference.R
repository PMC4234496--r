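test_that("permutation p-value follows the add-one formula", {
  # separable data: observed accuracy 1.0 beats every permuted score
  d <- makeSignalData(c("g1", "g2"), "g1", n = 20, seed = 3)
  cfg <- scorerConfig("knn", folds = 2, seed = 5, k = 1)
  obs <- scoreGeneSet(d, c("g1", "g2"), cfg)
  expect_equal(obs, 1)
  p <- permutationPvalue(d, c("g1", "g2"), obs, cfg, B = 19, seed = 1)
  expect_gte(p, 1 / 20)
  expect_lte(p, 1)
  # observed at the floor of the null: every null score >= observed
  p1 <- permutationPvalue(d, c("g1", "g2"), 0, cfg, B = 19, seed = 1)
  expect_equal(p1, 1)
  # deterministic given seeds
  expect_identical(p, permutationPvalue(d, c("g1", "g2"), obs, cfg,
                                        B = 19, seed = 1))
})

test_that("node importance ranks a decisive gene above pure noise", {
  d <- makeSignalData(paste0("g", 1:3), "g2", n = 50, seed = 21)
  vi <- nodeImportance(d, paste0("g", 1:3), T = 50, seed = 9)
  expect_named(vi, paste0("g", 1:3))
  expect_gt(vi[["g2"]], vi[["g1"]])
  expect_gt(vi[["g2"]], vi[["g3"]])
  expect_gt(vi[["g2"]], 0.1)
  # deterministic given seed
  expect_identical(vi, nodeImportance(d, paste0("g", 1:3), T = 50,
                                      seed = 9))
})

test_that("importance of a label-independent gene is near zero on average", {
  set.seed(99)
  vis <- vapply(1:15, function(i) {
    d <- makeSignalData(c("sig", "noise"), "sig", n = 40, seed = 300 + i)
    nodeImportance(d, c("noise", "sig"), T = 40,
                   seed = 500 + i)[["noise"]]
  }, numeric(1))
  expect_lt(abs(mean(vis)), 0.03)
})

test_that("per-tree OOB bookkeeping agrees with randomForest's own importance", {
  # independent oracle: randomForest's unscaled MeanDecreaseAccuracy is the
  # same mean over trees of (permuted OOB error - OOB error), computed in C
  # with its own permutations
  set.seed(12)
  labels <- halfHalf(60)
  sig <- (as.numeric(labels) * 2 - 1)
  vals <- rbind(sig + rnorm(60, sd = 0.7),
                sig + rnorm(60, sd = 1.5),
                rnorm(60), rnorm(60))
  d <- makeData(paste0("g", 1:4), labels, values = vals)
  vi <- nodeImportance(d, paste0("g", 1:4), T = 300, seed = 8)
  rf <- randomForest::randomForest(t(exprsValues(d)),
                                   factor(phenoLabels(d)),
                                   ntree = 300, importance = TRUE)
  oracle <- randomForest::importance(rf, type = 1, scale = FALSE)[, 1]
  expect_lt(max(abs(vi[paste0("g", 1:4)] - oracle[paste0("g", 1:4)])),
            0.05)
  expect_identical(names(which.max(vi)), names(which.max(oracle)))
})

makeScoredModule <- function(ego, mem, s, vi) {
  new("EgoModule", ego = ego, level = 1L, members = mem, score = s,
      scoreTrace = data.frame(level = 1L, score = s),
      importance = vi)
}

test_that("gene ranking sums score times importance over modules", {
  m1 <- makeScoredModule("a", c("a", "b"), 0.9, c(a = 0.5, b = 0.2))
  m2 <- makeScoredModule("b", c("b", "c"), 0.8, c(b = 0.1, c = 0.3))
  r <- rankGenes(EgoModuleList(list(m1, m2)), genes = c("a", "b", "c", "z"))
  M <- setNames(r$M, r$gene)
  expect_equal(M[["a"]], 0.45)            # one module: 0.9 * 0.5
  expect_equal(M[["b"]], 0.9 * 0.2 + 0.8 * 0.1)  # 0.26 across two modules
  expect_equal(M[["z"]], 0)               # in no module
  expect_identical(r$gene[1], "a")        # sorted by M descending
})

test_that("gene ranking matches a direct-summation oracle and is linear", {
  set.seed(64)
  genes <- paste0("g", 1:12)
  mods <- lapply(1:6, function(i) {
    mem <- sample(genes, sample(3:6, 1))
    vi <- setNames(rnorm(length(mem)), mem)
    makeScoredModule(mem[1], mem, runif(1, 0.05, 0.5), vi)
  })
  ml <- EgoModuleList(mods)
  r <- rankGenes(ml, genes = genes)
  M <- setNames(r$M, r$gene)
  # oracle: naive double loop
  for (g in genes) {
    expected <- 0
    for (m in mods)
      if (g %in% members(m))
        expected <- expected + moduleScore(m) * importanceValues(m)[[g]]
    expect_equal(M[[g]], expected, tolerance = 1e-15)
  }
  # linearity: doubling every S doubles every M
  mods2 <- lapply(mods, function(m) {
    m@score <- m@score * 2  # scores drawn in (0, 0.5] so this stays valid
    m
  })
  r2 <- rankGenes(EgoModuleList(mods2), genes = genes)
  expect_equal(r2$M[match(r$gene, r2$gene)], 2 * r$M, tolerance = 1e-12)
  # hub-enrichment: with equal per-module importances, a gene in more
  # modules gets a weakly higher M
  viEq <- lapply(mods, function(m) {
    m@importance <- setNames(rep(0.2, length(members(m))), members(m))
    m@score <- 0.9
    m
  })
  rEq <- rankGenes(EgoModuleList(viEq), genes = genes)
  counts <- vapply(genes, function(g)
    sum(vapply(viEq, function(m) g %in% members(m), logical(1))),
    numeric(1))
  MEq <- setNames(rEq$M, rEq$gene)[genes]
  ord <- order(counts)
  expect_true(all(diff(MEq[ord]) >= -1e-12))
})

test_that("DE flags: Welch t-test with BH control", {
  set.seed(55)
  n <- 60
  labels <- halfHalf(n)
  vals <- matrix(rnorm(20 * n), 20, n)
  vals[1, ] <- rnorm(n, mean = ifelse(labels == 1, 2, -2))  # strong effect
  d <- makeData(paste0("g", sprintf("%02d", 1:20)), labels, values = vals)
  de <- deFlags(d, fdr = 0.05)
  expect_true(de$de_flag[de$gene == "g01"])
  expect_equal(de$de_fdr, p.adjust(de$p, "BH"))
  # identical class distributions stay unflagged
  same <- makeData(c("x", "y"), labels,
                   values = matrix(rep(rnorm(n), 2), 2, n, byrow = TRUE))
  deSame <- deFlags(same, fdr = 0.05)
  expect_false(any(deSame$de_flag))
  # constant-in-both-classes genes get p = 1 with a message
  cst <- rbind(rnorm(n), rep(1, n))
  dcst <- makeData(c("ok", "flat"), labels, values = cst)
  expect_message(deC <- deFlags(dcst), "constant")
  expect_equal(deC$p[deC$gene == "flat"], 1)
  # pooled-variance option agrees with the classic t-test
  dePooled <- deFlags(d, pooled = TRUE)
  ref <- t.test(vals[2, labels == 0], vals[2, labels == 1],
                var.equal = TRUE)$p.value
  expect_equal(dePooled$p[dePooled$gene == "g02"], ref)
})

test_that("annotateModules filters by cutoff and attaches p and V", {
  d <- makeSignalData(c("A", "B", "C", "D"), "A", n = 24, seed = 2)
  g <- makeGraph(rbind(c("A", "B"), c("A", "C"), c("B", "C"), c("C", "D")))
  cfg <- scorerConfig("knn", folds = 2, seed = 7, k = 1)
  mods <- enumerateModules(g, d, cfg)
  ann <- annotateModules(mods, d, cfg, cutoff = 0.6, B = 9, T = 25,
                         seed = 10)
  expect_true(all(vapply(ann, moduleScore, numeric(1)) >= 0.6))
  for (m in as.list(ann)) {
    expect_gte(pValue(m), 1 / 10)
    expect_lte(pValue(m), 1)
    expect_setequal(names(importanceValues(m)), members(m))
  }
})
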