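#' Read an undirected interaction network from an edge list
#'
#' Parses two-column (or SIF-style three-column, where the middle
#' interaction-type column is ignored) delimited text, one interaction per
#' line, into an undirected simple graph. Self-loops are dropped with a
#' warning and duplicate edges (in either orientation) are collapsed.
#'
#' @param path path to the edge-list file; fields separated by tabs or
#'   whitespace.
#' @param header logical; skip the first line.
#' @return an undirected simple \code{\link[igraph]{igraph}} graph whose
#'   vertex names are the gene identifiers.
#' @examples
#' f <- tempfile()
#' writeLines(c("A\tB", "B\tC", "B\tA"), f)
#' g <- readNetwork(f)
#' igraph::vcount(g)  # 3
#' igraph::ecount(g)  # 2
#' @seealso \code{\link{writeNetwork}}, \code{\link{alignNetworkExpression}}
#' @export
#' @importFrom igraph graph_from_edgelist simplify vcount ecount
readNetwork <- function(path, header = FALSE) {
  lines <- readLines(path)
  if (header) lines <- lines[-1L]
  keep <- nzchar(trimws(lines))
  lineno <- which(keep) + if (header) 1L else 0L
  lines <- lines[keep]
  if (!length(lines)) stop("no edges in ", path)
  toks <- strsplit(lines, "[ \t]+")
  nf <- lengths(toks)
  bad <- which(nf != 2L & nf != 3L)
  if (length(bad))
    stop("malformed edge line ", lineno[bad[1]], " in ", path, ": expected ",
         "2 columns (or 3, SIF-style), found ", nf[bad[1]])
  from <- vapply(toks, `[`, character(1), 1L)
  to <- vapply(toks, function(x) x[length(x)], character(1))
  loops <- from == to
  if (any(loops)) {
    warning(sum(loops), " self-loop(s) dropped")
    from <- from[!loops]
    to <- to[!loops]
  }
  if (!length(from)) stop("no edges left after dropping self-loops")
  g <- igraph::simplify(
    igraph::graph_from_edgelist(cbind(from, to), directed = FALSE),
    remove.multiple = TRUE, remove.loops = TRUE)
  g
}

#' Write a network as a two-column edge list
#'
#' Inverse of \code{\link{readNetwork}}: one tab-separated edge per line,
#' no header. Reading the file back reproduces the node and edge sets
#' exactly.
#'
#' @param net an undirected \code{igraph} graph.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
#' @importFrom igraph as_edgelist
writeNetwork <- function(net, path) {
  el <- igraph::as_edgelist(net, names = TRUE)
  writeLines(paste(el[, 1], el[, 2], sep = "\t"), path)
  invisible(path)
}

#' Read an expression matrix and binary phenotype labels
#'
#' The expression file is tab-delimited with gene identifiers in the first
#' column and sample identifiers in the header row. The label file is
#' two-column tab-delimited text (sample identifier, then 0 or 1) with no
#' header. Every sample in the matrix must be labeled; every labeled sample
#' must exist in the matrix; each class needs at least two samples.
#'
#' @param path expression matrix file.
#' @param labelPath label file.
#' @return a \linkS4class{LabeledExpression}.
#' @export
readExpression <- function(path, labelPath) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, colClasses = "character",
                           row.names = NULL)
  genes <- tab[[1L]]
  dup <- genes[duplicated(genes)]
  if (length(dup))
    stop("duplicate gene row(s) in ", path, ": ",
         paste(unique(dup), collapse = ", "))
  vals <- as.matrix(tab[, -1L, drop = FALSE])
  rownames(vals) <- genes
  suppressWarnings(num <- matrix(as.numeric(vals), nrow(vals), ncol(vals),
                                 dimnames = dimnames(vals)))
  if (anyNA(num)) {
    idx <- which(is.na(num), arr.ind = TRUE)[1L, ]
    stop("non-numeric expression value for gene '", rownames(num)[idx[1]],
         "', sample '", colnames(num)[idx[2]], "'")
  }
  lab <- readPhenotypeLabels(labelPath)
  unknown <- setdiff(names(lab), colnames(num))
  if (length(unknown))
    stop("label file has unknown sample(s): ",
         paste(unknown, collapse = ", "))
  unlabeled <- setdiff(colnames(num), names(lab))
  if (length(unlabeled))
    stop("samples without a label: ", paste(unlabeled, collapse = ", "))
  LabeledExpression(num, lab)
}

# two-column TSV: sample id, 0/1. No header.
readPhenotypeLabels <- function(path) {
  tab <- utils::read.delim(path, header = FALSE, sep = "\t",
                           colClasses = "character")
  if (ncol(tab) != 2L)
    stop("label file must have exactly 2 columns (sample, 0/1)")
  if (anyDuplicated(tab[[1L]]))
    stop("duplicate sample identifier(s) in label file")
  val <- suppressWarnings(as.integer(tab[[2L]]))
  bad <- is.na(val) | !(val %in% c(0L, 1L))
  if (any(bad))
    stop("labels must be 0 or 1; offending sample(s): ",
         paste(tab[[1L]][bad], collapse = ", "))
  stats::setNames(val, tab[[1L]])
}

#' Restrict a network and an expression dataset to their shared genes
#'
#' The ego scan only makes sense over genes that have both interactions and
#' measurements, so the network is induced on the genes present in the
#' expression matrix and the matrix is subset to genes present in the
#' network. Counts of dropped genes are reported. Applying the function to
#' already-aligned inputs returns them unchanged (idempotence).
#'
#' @param net undirected \code{igraph} graph.
#' @param data a \linkS4class{LabeledExpression}.
#' @param verbose report dropped-gene counts.
#' @return \code{list(network = , data = )} over the common gene set.
#' @export
#' @importFrom igraph V induced_subgraph
alignNetworkExpression <- function(net, data, verbose = TRUE) {
  netGenes <- igraph::V(net)$name
  common <- intersect(netGenes, rownames(data))
  if (!length(common))
    stop("network and expression data share no genes")
  dropNet <- length(netGenes) - length(common)
  dropExpr <- nrow(data) - length(common)
  if (dropNet || dropExpr)
    msg("alignment dropped ", dropNet, " network gene(s) and ", dropExpr,
        " expression gene(s); ", length(common), " genes remain",
        verbose = verbose)
  net2 <- igraph::induced_subgraph(net, common)
  data2 <- data[common, ]
  list(network = net2, data = data2)
}

#' Summarize modules as a data.frame
#'
#' @param modules an \linkS4class{EgoModuleList}.
#' @param adjustP add a \code{p_adj} column with Benjamini-Hochberg
#'   adjustment of the permutation p-values across modules (off by
#'   default: raw per-module permutation p-values are the primary
#'   report).
#' @return data.frame with columns \code{ego}, \code{level}, \code{n_genes},
#'   \code{score}, \code{p_value}, \code{members} (comma-joined), one row
#'   per module.
#' @export
moduleTable <- function(modules, adjustP = FALSE) {
  tab <- data.frame(
    ego = vapply(modules, ego, character(1)),
    level = vapply(modules, moduleLevel, integer(1)),
    n_genes = vapply(modules, function(m) length(members(m)), integer(1)),
    score = vapply(modules, moduleScore, numeric(1)),
    p_value = vapply(modules, pValue, numeric(1)),
    members = vapply(modules, function(m)
      paste(sort(members(m)), collapse = ","), character(1)),
    stringsAsFactors = FALSE, row.names = NULL)
  if (adjustP)
    tab$p_adj <- stats::p.adjust(tab$p_value, method = "BH")
  tab
}

#' Write the module report table
#'
#' Tab-separated module summary (see \code{\link{moduleTable}}), one row
#' per module.
#'
#' @param modules an \linkS4class{EgoModuleList}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeModuleTable <- function(modules, path) {
  utils::write.table(moduleTable(modules), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write the gene-ranking table
#'
#' Tab-separated output of \code{\link{rankGenes}} (gene, M value, DE flag,
#' DE FDR).
#'
#' @param ranking data.frame from \code{\link{rankGenes}}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeRankingTable <- function(ranking, path) {
  utils::write.table(ranking, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
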