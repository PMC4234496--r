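#' Run the full ego-network discovery workflow
#'
#' End-to-end pipeline: read the network and expression data, align them,
#' grow and score a module for every eligible ego, keep modules with score
#' at or above the accuracy cutoff, attach permutation p-values and OOB
#' permutation importances, rank all genes by the summed score-times-
#' importance metric M, flag differential expression, and write the module
#' and ranking tables. Identical configuration and seed produce
#' byte-identical output files.
#'
#' @param networkPath edge-list file (see \code{\link{readNetwork}}).
#' @param exprPath expression matrix TSV (see \code{\link{readExpression}}).
#' @param labelPath two-column sample/label TSV.
#' @param outDir output directory, created if needed. Files written:
#'   \code{modules.tsv}, \code{ranking.tsv}, \code{run.log}.
#' @param classifier scorer classifier (\code{"svm"}, \code{"knn"},
#'   \code{"rf"}).
#' @param folds stratified CV folds.
#' @param cutoff accuracy cutoff for discriminative modules (default 0.9).
#' @param B label permutations per passing module (default 1000).
#' @param T trees for the importance forest.
#' @param maxLevel,nodeCap growth bounds, see \code{\link{growModule}}.
#' @param fdr DE flag threshold (BH-adjusted p).
#' @param seed master seed.
#' @param verbose log stage counts to stderr.
#' @param ... extra classifier hyperparameters for
#'   \code{\link{scorerConfig}}.
#' @return invisibly, \code{list(modules = annotated EgoModuleList,
#'   ranking = data.frame, allModules = EgoModuleList)}.
#' @export
runEgoNet <- function(networkPath, exprPath, labelPath, outDir,
                      classifier = "svm", folds = 5L, cutoff = 0.9,
                      B = 1000L, T = 100L, maxLevel = 3L, nodeCap = 300L,
                      fdr = 0.05, seed = 1L, verbose = TRUE, ...) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  logLines <- character()
  log <- function(...) {
    line <- paste0(...)
    logLines <<- c(logLines, line)
    msg(line, verbose = verbose)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  cfgKv <- c(classifier = classifier, folds = folds, cutoff = cutoff,
             B = B, T = T, max_level = maxLevel, node_cap = nodeCap,
             fdr = fdr, seed = seed)
  log("config: ", paste(names(cfgKv), cfgKv, sep = "=", collapse = " "))

  net <- stage("read_network", readNetwork(networkPath))
  log("network: ", igraph::vcount(net), " genes, ", igraph::ecount(net),
      " interactions")
  data <- stage("read_expression", readExpression(exprPath, labelPath))
  log("expression: ", nrow(data), " genes x ", ncol(data), " samples (",
      sum(phenoLabels(data) == 1L), " cases)")
  al <- stage("align", alignNetworkExpression(net, data,
                                              verbose = verbose))
  log("aligned: ", igraph::vcount(al$network), " genes")

  scorer <- scorerConfig(classifier, folds = folds,
                         seed = deriveSeed(seed, 1L), ...)
  mods <- stage("enumerate_modules",
                enumerateModules(al$network, al$data, scorer,
                                 maxLevel = maxLevel, nodeCap = nodeCap,
                                 verbose = verbose))
  log("modules grown: ", length(mods), " (eligible egos: ",
      length(eligibleEgos(al$network)), ")")
  top <- stage("annotate_modules",
               annotateModules(mods, al$data, scorer, cutoff = cutoff,
                               B = B, T = T, seed = deriveSeed(seed, 2L),
                               verbose = verbose))
  log("modules with score >= ", cutoff, ": ", length(top))

  ranking <- stage("rank_genes", {
    r <- if (length(top)) rankGenes(top, genes = rownames(al$data))
         else data.frame(gene = sort(rownames(al$data)),
                         M = 0, stringsAsFactors = FALSE)
    de <- deFlags(al$data, fdr = fdr)
    merged <- merge(r, de[, c("gene", "de_flag", "de_fdr")], by = "gene",
                    sort = FALSE)
    merged[order(-merged$M, merged$gene), , drop = FALSE]
  })
  log("ranked genes: ", nrow(ranking), " (", sum(ranking$de_flag),
      " DE-flagged at FDR < ", fdr, ")")

  writeModuleTable(top, file.path(outDir, "modules.tsv"))
  writeRankingTable(ranking, file.path(outDir, "ranking.tsv"))
  writeLines(logLines, file.path(outDir, "run.log"))
  invisible(list(modules = top, ranking = ranking, allModules = mods))
}
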