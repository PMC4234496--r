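#' Label-permutation significance of a module score
#'
#' The null distribution of the classification accuracy is obtained by
#' permuting the phenotype labels \code{B} times and re-scoring the same
#' gene set with the same scorer configuration each time. The p-value uses
#' the add-one estimator p = (1 + #\{null >= observed\}) / (B + 1), which
#' never returns 0 and is valid for any finite \code{B}.
#'
#' @param data a \linkS4class{LabeledExpression}.
#' @param genes the module's gene set.
#' @param observed the module score produced by \code{\link{scoreGeneSet}}
#'   with the same \code{scorer}.
#' @param scorer the \linkS4class{ScorerConfig} used for \code{observed}.
#' @param B number of permutations (>= 1; 1000 for a full analysis).
#' @param seed seed for the permutation stream.
#' @return p-value in [1/(B+1), 1].
#' @export
permutationPvalue <- function(data, genes, observed, scorer, B = 1000L,
                              seed = 1L) {
  stopifnot(B >= 1L)
  genes <- sort(unique(genes))
  miss <- setdiff(genes, rownames(data))
  if (length(miss))
    stop("gene(s) absent from the expression data: ",
         paste(miss, collapse = ", "))
  X <- t(exprsValues(data)[genes, , drop = FALSE])
  y <- phenoLabels(data)
  perms <- withSeed(seed, {
    replicate(B, sample(y), simplify = FALSE)
  })
  nullScores <- vapply(perms, function(py) {
    .cvLoopMatrix(X, factor(py, levels = c(0L, 1L)), scorer)
  }, numeric(1))
  (1 + sum(nullScores >= observed)) / (B + 1)
}

#' Out-of-bag permutation importance of module genes
#'
#' Fits a random forest of \code{T} trees on the module's genes and, for
#' each gene j and each tree t, compares the tree's error on its out-of-bag
#' samples before and after permuting gene j's values within that OOB set.
#' The importance V of gene j is the mean over trees of (permuted OOB error
#' - OOB error); the labels are binary, so the error is the OOB
#' misclassification rate (which equals the mean squared error for 0/1
#' encoding under majority-vote prediction). Values can be negative for
#' uninformative genes.
#'
#' @param data a \linkS4class{LabeledExpression}.
#' @param genes two or more gene identifiers present in \code{data}.
#' @param T number of trees (default 100).
#' @param seed seed controlling the forest and the permutations.
#' @return named numeric vector of importances, one per gene.
#' @export
#' @importFrom randomForest randomForest
nodeImportance <- function(data, genes, T = 100L, seed = 1L) {
  genes <- sort(unique(genes))
  if (length(genes) < 2L) stop("need at least 2 genes")
  miss <- setdiff(genes, rownames(data))
  if (length(miss))
    stop("gene(s) absent from the expression data: ",
         paste(miss, collapse = ", "))
  X <- t(exprsValues(data)[genes, , drop = FALSE])
  y <- factor(phenoLabels(data), levels = c(0L, 1L))
  withSeed(seed, {
    rf <- randomForest::randomForest(X, y, ntree = as.integer(T),
                                     keep.inbag = TRUE,
                                     keep.forest = TRUE)
    allPred <- predict(rf, X, predict.all = TRUE)$individual
    vi <- matrix(NA_real_, as.integer(T), length(genes),
                 dimnames = list(NULL, genes))
    for (t in seq_len(as.integer(T))) {
      oob <- which(rf$inbag[, t] == 0L)
      if (!length(oob))
        stop("tree ", t, " has no out-of-bag samples; use more samples")
      errT <- mean(allPred[oob, t] != y[oob])
      Xoob <- X[oob, , drop = FALSE]
      for (j in seq_along(genes)) {
        Xp <- Xoob
        Xp[, j] <- Xoob[sample(length(oob)), j]
        predP <- predict(rf, Xp, predict.all = TRUE)$individual[, t]
        vi[t, j] <- mean(predP != y[oob]) - errT
      }
    }
    colMeans(vi)
  })
}

#' Rank genes by summed module contribution
#'
#' The global ranking metric M for gene j is the sum over the considered
#' modules of the module score S times the gene's importance V in that
#' module (V = 0 when the gene is not a member). Genes belonging to no
#' considered module get M = 0. The result is sorted by M descending, ties
#' broken lexicographically by gene.
#'
#' @param modules an \linkS4class{EgoModuleList} whose elements carry
#'   scores and importances (see \code{\link{nodeImportance}}).
#' @param genes the gene universe to report; defaults to the union of
#'   member genes over \code{modules}.
#' @return data.frame with columns \code{gene} and \code{M}.
#' @export
rankGenes <- function(modules, genes = NULL) {
  if (is.null(genes)) {
    genes <- sort(unique(unlist(lapply(modules, members))))
  } else genes <- sort(unique(genes))
  M <- stats::setNames(numeric(length(genes)), genes)
  for (m in as.list(modules)) {
    vi <- importanceValues(m)
    if (!length(vi))
      stop("module with ego '", ego(m), "' has no importances; run ",
           "nodeImportance first")
    common <- intersect(names(vi), genes)
    M[common] <- M[common] + moduleScore(m) * vi[common]
  }
  out <- data.frame(gene = genes, M = unname(M), stringsAsFactors = FALSE)
  out[order(-out$M, out$gene), , drop = FALSE]
}

#' Flag differentially expressed genes
#'
#' Per-gene two-sample two-tailed t-test (Welch by default) between the
#' two phenotype classes, with Benjamini-Hochberg adjustment across all
#' tested genes; a gene is flagged when its adjusted p-value is below
#' \code{fdr}. Genes constant within both classes get p = 1 (with a
#' message).
#'
#' @param data a \linkS4class{LabeledExpression} with >= 2 samples per
#'   class.
#' @param fdr adjusted-p threshold (default 0.05).
#' @param pooled use the pooled-variance (classic) t-test instead of
#'   Welch.
#' @return data.frame with columns \code{gene}, \code{p}, \code{de_fdr}
#'   (BH-adjusted p) and logical \code{de_flag}, in input gene order.
#' @export
#' @importFrom stats t.test p.adjust
deFlags <- function(data, fdr = 0.05, pooled = FALSE) {
  X <- exprsValues(data)
  y <- phenoLabels(data)
  g0 <- y == 0L
  p <- vapply(seq_len(nrow(X)), function(i) {
    x0 <- X[i, g0]
    x1 <- X[i, !g0]
    if (stats::sd(x0) == 0 && stats::sd(x1) == 0) return(NA_real_)
    stats::t.test(x0, x1, var.equal = pooled)$p.value
  }, numeric(1))
  if (anyNA(p)) {
    msg(sum(is.na(p)), " gene(s) constant in both classes; p set to 1")
    p[is.na(p)] <- 1
  }
  adj <- stats::p.adjust(p, method = "BH")
  data.frame(gene = rownames(X), p = p, de_fdr = adj,
             de_flag = adj < fdr, stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Annotate top modules with significance and importances
#'
#' Convenience wrapper over the inference steps of the full workflow:
#' selects modules with score >= \code{cutoff}, attaches a
#' label-permutation p-value and per-gene OOB permutation importances to
#' each, and returns them sorted by score.
#'
#' @param modules an \linkS4class{EgoModuleList} from
#'   \code{\link{enumerateModules}}.
#' @param data the \linkS4class{LabeledExpression} the modules were grown
#'   on.
#' @param scorer the \linkS4class{ScorerConfig} used to grow them.
#' @param cutoff accuracy cutoff selecting the discriminative modules
#'   (0.9 for a full analysis; use 0 to keep everything).
#' @param B permutations per module.
#' @param T trees for the importance forest.
#' @param seed base seed; each module uses a derived sub-seed.
#' @param verbose report progress.
#' @return an \linkS4class{EgoModuleList} of the annotated passing modules.
#' @export
annotateModules <- function(modules, data, scorer, cutoff = 0.9, B = 1000L,
                            T = 100L, seed = 1L, verbose = FALSE) {
  keep <- Filter(function(m) moduleScore(m) >= cutoff, as.list(modules))
  keep <- as.list(sortModules(EgoModuleList(keep)))
  out <- vector("list", length(keep))
  for (i in seq_along(keep)) {
    m <- keep[[i]]
    m@pValue <- permutationPvalue(data, members(m), moduleScore(m), scorer,
                                  B = B, seed = deriveSeed(seed, 2L * i))
    m@importance <- nodeImportance(data, members(m), T = T,
                                   seed = deriveSeed(seed, 2L * i + 1L))
    out[[i]] <- m
    if (verbose) msg("annotated module ", i, "/", length(keep), " (ego ",
                     ego(m), ")")
  }
  EgoModuleList(out)
}
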