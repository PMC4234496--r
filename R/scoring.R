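#' @importFrom stats sd predict setNames
NULL

# stratified fold assignment: within each class, shuffle then deal
# round-robin so every fold holds both classes
.stratifiedFolds <- function(y, k) {
  fold <- integer(length(y))
  for (cl in unique(y)) {
    idx <- sample(which(y == cl))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

# column-standardize train, apply train moments to test; sd 0 -> 1
.standardize <- function(Xtr, Xte) {
  n <- nrow(Xtr)
  mu <- colMeans(Xtr)
  s <- sqrt(pmax(colSums(Xtr * Xtr) - n * mu * mu, 0) / (n - 1))
  s[s == 0 | is.na(s)] <- 1
  list(train = t((t(Xtr) - mu) / s), test = t((t(Xte) - mu) / s))
}

# fit on (Xtr, ytr), predict labels for Xte; features already standardized
.fitPredict <- function(classifier, Xtr, ytr, Xte, params) {
  switch(classifier,
    svm = {
      fit <- e1071::svm(Xtr, ytr, kernel = "radial",
                        cost = params$cost %||% 1,
                        gamma = params$gamma %||% (1 / ncol(Xtr)),
                        scale = FALSE)
      predict(fit, Xte)
    },
    knn = class::knn(Xtr, Xte, ytr, k = params$k %||% 5L, use.all = TRUE),
    rf = {
      fit <- ranger::ranger(x = Xtr, y = ytr,
                            num.trees = params$ntree %||% 500L,
                            num.threads = 1L,
                            seed = sample.int(.Machine$integer.max, 1L))
      predict(fit, Xte, num.threads = 1L)$predictions
    },
    stop("unknown classifier: ", classifier))
}

# shared CV loop over a prepared samples x genes matrix
.cvLoop <- function(data, genes, cfg, decision = FALSE) {
  genes <- sort(unique(genes))
  miss <- setdiff(genes, rownames(data))
  if (length(miss))
    stop("gene(s) absent from the expression data: ",
         paste(miss, collapse = ", "))
  X <- t(exprsValues(data)[genes, , drop = FALSE])
  y <- factor(phenoLabels(data), levels = c(0L, 1L))
  .cvLoopMatrix(X, y, cfg, decision)
}

.cvLoopMatrix <- function(X, y, cfg, decision = FALSE) {
  k <- cfg@folds
  if (k > min(table(y)))
    stop("folds (", k, ") exceeds the smaller class size (",
         min(table(y)), ")")
  withSeed(cfg@seed, {
    accs <- numeric(0)
    dec <- matrix(NA_real_, cfg@repeats, length(y))
    for (r in seq_len(cfg@repeats)) {
      fold <- .stratifiedFolds(y, k)
      for (f in seq_len(k)) {
        te <- fold == f
        std <- .standardize(X[!te, , drop = FALSE], X[te, , drop = FALSE])
        if (decision) {
          dec[r, te] <- .svmDecision(std$train, y[!te], std$test,
                                     cfg@params)
        } else {
          pred <- .fitPredict(cfg@classifier, std$train, y[!te], std$test,
                              cfg@params)
          accs <- c(accs, mean(pred == y[te]))
        }
      }
    }
    if (decision) list(decision = dec, y = y) else mean(accs)
  })
}

# RBF-SVM decision values oriented so that larger means class "1"
.svmDecision <- function(Xtr, ytr, Xte, params) {
  fit <- e1071::svm(Xtr, ytr, kernel = "radial",
                    cost = params$cost %||% 1,
                    gamma = params$gamma %||% (1 / ncol(Xtr)),
                    scale = FALSE)
  dv <- attr(predict(fit, Xte, decision.values = TRUE), "decision.values")
  # e1071 orients the decision value toward the first factor level it saw
  if (grepl("^1", colnames(dv)[1])) drop(dv) else -drop(dv)
}

#' Score a gene set by cross-validated classification accuracy
#'
#' The module score S: mean accuracy over stratified k-fold
#' cross-validation (averaged over repeats) of a classifier predicting the
#' binary phenotype from the expression of the given genes. Each gene is
#' standardized per fold using training-fold mean and standard deviation.
#' The score is invariant to gene order (genes are canonicalized
#' internally) and, because of the standardization, to affine rescaling of
#' any single gene. Identical \code{cfg} (including seed) gives
#' bit-identical scores.
#'
#' @param data a \linkS4class{LabeledExpression}.
#' @param genes gene identifiers, all present in \code{data}.
#' @param cfg a \linkS4class{ScorerConfig}.
#' @return accuracy in [0, 1].
#' @examples
#' m <- matrix(rnorm(200), 2, 100,
#'             dimnames = list(c("g1", "g2"), paste0("s", 1:100)))
#' y <- rep(c(0, 1), each = 50)
#' m[1, ] <- ifelse(y == 1, 1, -1)      # perfectly separating gene
#' d <- LabeledExpression(m, y)
#' scoreGeneSet(d, "g1", scorerConfig("svm", seed = 1))  # 1
#' @export
scoreGeneSet <- function(data, genes, cfg) {
  .cvLoop(data, genes, cfg, decision = FALSE)
}

#' Cross-validated AUC of a gene set
#'
#' Held-out evaluation used in the method-comparison study: RBF-SVM
#' decision values are collected over stratified CV folds and the area
#' under the ROC curve is computed from the pooled held-out values by the
#' rank (Mann-Whitney) formula.
#'
#' @inheritParams scoreGeneSet
#' @return AUC in [0, 1].
#' @export
scoreGeneSetAUC <- function(data, genes, cfg) {
  res <- .cvLoop(data, genes, cfg, decision = TRUE)
  pos <- res$y == "1"
  n1 <- sum(pos)
  n0 <- sum(!pos)
  aucs <- apply(res$decision, 1L, function(dv) {
    r <- rank(dv)
    (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  })
  mean(aucs)
}

#' Mutual-information subnetwork activity score
#'
#' The aggregated-Z baseline score: each member gene is z-normalized across
#' samples, the subnetwork activity is the per-sample mean of member
#' z-scores, the activity is discretized into \code{bins} equal-width bins,
#' and the score is the mutual information (in bits) between the binned
#' activity and the class labels. Zero-variance genes contribute zero
#' z-scores (with a message).
#'
#' @param data a \linkS4class{LabeledExpression}.
#' @param genes one or more gene identifiers present in \code{data}.
#' @param bins number of equal-width discretization bins (default 8).
#' @return mutual information in bits; always >= 0 and at most the entropy
#'   of the label distribution.
#' @export
chuangScore <- function(data, genes, bins = 8L) {
  genes <- unique(genes)
  miss <- setdiff(genes, rownames(data))
  if (length(miss))
    stop("gene(s) absent from the expression data: ",
         paste(miss, collapse = ", "))
  X <- exprsValues(data)[genes, , drop = FALSE]
  Z <- .zScoreRows(X)
  flat <- rowSums(Z != 0) == 0L
  if (any(flat))
    msg("zero-variance gene(s) contribute zero z-scores: ",
        paste(genes[flat], collapse = ", "))
  activity <- colMeans(Z)
  y <- phenoLabels(data)
  .miActivity(activity, y, bins)
}

# equal-width binning of the activity, then plug-in MI against 0/1 labels
.miActivity <- function(activity, y01, bins) {
  rng <- range(activity)
  if (rng[1] == rng[2]) return(0)
  cuts <- seq(rng[1], rng[2], length.out = bins + 1L)
  b <- findInterval(activity, cuts, rightmost.closed = TRUE,
                    all.inside = TRUE)
  .mutualInformationBits(b, y01, bins)
}

# plug-in MI (bits) of binned activity vs binary labels, via one joint
# tabulation
.mutualInformationBits <- function(b, y01, bins) {
  n <- length(b)
  counts <- tabulate(b + bins * y01, nbins = 2L * bins) / n
  j0 <- counts[seq_len(bins)]
  j1 <- counts[bins + seq_len(bins)]
  pa <- j0 + j1
  p0 <- sum(j0)
  p1 <- 1 - p0
  s <- 0
  nz <- j0 > 0
  if (any(nz)) s <- s + sum(j0[nz] * log2(j0[nz] / (pa[nz] * p0)))
  nz <- j1 > 0
  if (any(nz)) s <- s + sum(j1[nz] * log2(j1[nz] / (pa[nz] * p1)))
  s
}

#' Greedy subnetwork search maximizing mutual information
#'
#' Baseline search in the style of aggregated-Z subnetwork scoring: starting
#' from a seed gene, repeatedly add the neighboring gene (a network
#' neighbor of any current member) whose inclusion maximally increases
#' \code{\link{chuangScore}}; stop when no neighbor strictly improves the
#' score.
#'
#' @param net undirected \code{igraph} graph aligned to \code{data}.
#' @param data a \linkS4class{LabeledExpression}.
#' @param seedGene starting gene, present in both network and data.
#' @param bins passed to \code{\link{chuangScore}}.
#' @return sorted character vector: the selected gene set (always contains
#'   the seed).
#' @export
#' @importFrom igraph neighbors
greedyChuangSearch <- function(net, data, seedGene, bins = 8L) {
  nodes <- igraph::V(net)$name
  if (!seedGene %in% nodes) stop("seed '", seedGene, "' not in network")
  if (!seedGene %in% rownames(data))
    stop("seed '", seedGene, "' not in expression data")
  adj <- .adjacencyList(net)
  # per-gene z-scores computed once; the activity of a candidate set is an
  # incremental update of the running z-score sum
  Z <- .zScoreRows(exprsValues(data))
  y <- phenoLabels(data)
  inData <- nodes %in% rownames(data)
  current <- match(seedGene, nodes)
  sumZ <- Z[seedGene, ]
  score <- .miActivity(sumZ, y, bins)
  repeat {
    cand <- setdiff(unique(unlist(adj[current], use.names = FALSE)),
                    current)
    cand <- cand[inData[cand]]
    if (!length(cand)) break
    k <- length(current) + 1L
    candScores <- vapply(cand, function(v)
      .miActivity((sumZ + Z[nodes[v], ]) / k, y, bins), numeric(1))
    best <- which.max(candScores)
    if (candScores[best] <= score) break
    score <- candScores[best]
    sumZ <- sumZ + Z[nodes[cand[best]], ]
    current <- c(current, cand[best])
  }
  sort(nodes[current])
}

# row-wise z-scores; zero-variance rows become all-zero
.zScoreRows <- function(X) {
  mu <- rowMeans(X)
  s <- sqrt(pmax(rowSums((X - mu)^2), 0) / (ncol(X) - 1))
  s[s == 0 | is.na(s)] <- Inf
  (X - mu) / s
}

#' Write / read a ScorerConfig as a flat key=value file
#'
#' Plain-text serialization so a scoring setup can be stored beside
#' results; identical config + seed implies identical scores.
#'
#' @param cfg a \linkS4class{ScorerConfig}.
#' @param path file path.
#' @return \code{writeScorerConfig}: \code{path} invisibly;
#'   \code{readScorerConfig}: a \linkS4class{ScorerConfig}.
#' @export
writeScorerConfig <- function(cfg, path) {
  base <- c(classifier = cfg@classifier, folds = cfg@folds,
            repeats = cfg@repeats, seed = cfg@seed)
  extra <- unlist(cfg@params)
  kv <- c(base, extra)
  writeLines(paste0(names(kv), "=", kv), path)
  invisible(path)
}

#' @rdname writeScorerConfig
#' @export
readScorerConfig <- function(path) {
  kv <- strsplit(readLines(path), "=", fixed = TRUE)
  vals <- stats::setNames(vapply(kv, `[`, character(1), 2L),
                          vapply(kv, `[`, character(1), 1L))
  known <- c("classifier", "folds", "repeats", "seed")
  params <- lapply(vals[setdiff(names(vals), known)], function(v) {
    num <- suppressWarnings(as.numeric(v))
    if (is.na(num)) v else num
  })
  do.call(scorerConfig,
          c(list(classifier = vals[["classifier"]],
                 folds = as.integer(vals[["folds"]]),
                 repeats = as.integer(vals[["repeats"]]),
                 seed = as.integer(vals[["seed"]])),
            params))
}
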