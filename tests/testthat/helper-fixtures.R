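# in-code fixtures shared across test files

# small undirected graph from an edge matrix
makeGraph <- function(edges) {
  igraph::simplify(igraph::graph_from_edgelist(edges, directed = FALSE))
}

# expression dataset with given genes and a label vector; values ~ N(0,1)
# unless a signal matrix is supplied
makeData <- function(genes, labels, values = NULL, seed = 1) {
  set.seed(seed)
  n <- length(labels)
  if (is.null(values))
    values <- matrix(rnorm(length(genes) * n), length(genes), n)
  dimnames(values) <- list(genes, sprintf("s%02d", seq_len(n)))
  LabeledExpression(values, labels)
}

# balanced labels
halfHalf <- function(n) rep(c(0L, 1L), each = n / 2)

# dataset where `signalGene` equals the label (+/-1) and the rest are noise
makeSignalData <- function(genes, signalGene, n = 40, seed = 1) {
  labels <- halfHalf(n)
  d <- makeData(genes, labels, seed = seed)
  m <- exprsValues(d)
  m[signalGene, ] <- ifelse(labels == 1L, 1, -1)
  LabeledExpression(m, labels)
}

# write a toy 6-node two-star fixture (egos A and D) + matching expression;
# gene A carries the phenotype signal
writeToyFixture <- function(dir, n = 40, seed = 7) {
  set.seed(seed)
  edge <- file.path(dir, "net.tsv")
  writeLines(c("A\tB", "A\tC", "D\tE", "D\tF"), edge)
  genes <- c("A", "B", "C", "D", "E", "F")
  labels <- halfHalf(n)
  vals <- matrix(rnorm(length(genes) * n), length(genes), n,
                 dimnames = list(genes, sprintf("s%02d", seq_len(n))))
  vals["A", ] <- ifelse(labels == 1L, 1.5, -1.5) + rnorm(n, sd = 0.3)
  expr <- file.path(dir, "expr.tsv")
  write.table(data.frame(gene = genes, vals, check.names = FALSE),
              expr, sep = "\t", quote = FALSE, row.names = FALSE)
  lab <- file.path(dir, "labels.tsv")
  write.table(data.frame(sample = colnames(vals), label = labels),
              lab, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  list(network = edge, expr = expr, labels = lab)
}
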