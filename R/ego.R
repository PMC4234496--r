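#' @importFrom igraph V degree as_adj_list
NULL

# adjacency as a list of integer vectors, 1-based vertex indices
.adjacencyList <- function(net) {
  lapply(igraph::as_adj_list(net, mode = "all"), as.integer)
}

# closed BFS neighborhood of radius `level` around vertex index `egoIdx`;
# returns sorted vertex indices. Plain frontier expansion, independent of
# igraph's shortest-path machinery (which serves as the test oracle).
.bfsNeighborhood <- function(adj, egoIdx, level) {
  seen <- logical(length(adj))
  seen[egoIdx] <- TRUE
  frontier <- egoIdx
  d <- 0L
  while (d < level && length(frontier)) {
    nxt <- unique(unlist(adj[frontier], use.names = FALSE))
    nxt <- nxt[!seen[nxt]]
    seen[nxt] <- TRUE
    frontier <- nxt
    d <- d + 1L
  }
  which(seen)
}

#' Level-k ego neighborhood
#'
#' All genes at graph distance at most \code{level} from the ego (the ego
#' included), computed by breadth-first expansion. Level 0 is the ego
#' alone; level 1 adds its direct interaction partners (alters); growth
#' never crosses connected components.
#'
#' @param net undirected \code{igraph} graph.
#' @param ego a gene identifier present in the network.
#' @param level neighborhood radius, >= 0.
#' @return sorted character vector of member genes.
#' @examples
#' g <- igraph::make_graph(~ A - B, B - C, C - D)
#' egoNeighborhood(g, "B", 1)  # A B C
#' @export
egoNeighborhood <- function(net, ego, level) {
  nodes <- igraph::V(net)$name
  idx <- match(ego, nodes)
  if (is.na(idx)) stop("ego '", ego, "' is not in the network")
  if (level < 0) stop("level must be >= 0")
  adj <- .adjacencyList(net)
  sort(nodes[.bfsNeighborhood(adj, idx, as.integer(level))])
}

#' Genes eligible to serve as egos
#'
#' Only nodes with two or more interaction partners are scanned as egos; a
#' degree-1 node's level-1 neighborhood is just a single edge. Returned in
#' sorted order for reproducibility.
#'
#' @param net undirected \code{igraph} graph.
#' @return sorted character vector of gene identifiers with degree >= 2.
#' @export
eligibleEgos <- function(net) {
  deg <- igraph::degree(net)
  sort(igraph::V(net)$name[deg >= 2])
}

#' Grow one ego-network module by snowball sampling
#'
#' Starting from the ego's level-1 neighborhood, the module spreads outward
#' one level at a time; each level's member genes are scored as a set by
#' cross-validated classification accuracy against the phenotype. Growth
#' stops at the first level whose score is strictly lower than the previous
#' level's ("the accuracy drops"; ties continue growth), when a level adds
#' no new genes, when the member count would exceed \code{nodeCap}, or at
#' \code{maxLevel}. The returned module is the level with the maximal score
#' (the earliest such level on ties).
#'
#' @param net undirected \code{igraph} graph, aligned to \code{data}.
#' @param data a \linkS4class{LabeledExpression} aligned to \code{net}.
#' @param ego an eligible ego (degree >= 2).
#' @param scorer a \linkS4class{ScorerConfig}, or a function
#'   \code{function(data, genes)} returning a score in [0, 1] (useful for
#'   testing and custom metrics).
#' @param maxLevel maximum neighborhood radius (default 3; empirically
#'   almost all chosen levels are 1 or 2).
#' @param nodeCap levels whose member set would exceed this many genes are
#'   not explored (default 300); hub-centered level-2+ sets in scale-free
#'   networks can otherwise engulf the graph.
#' @return an \linkS4class{EgoModule}, or \code{NULL} (with a message) if
#'   the ego's neighborhood has fewer than 2 genes in the data.
#' @export
growModule <- function(net, data, ego, scorer, maxLevel = 3L,
                       nodeCap = 300L) {
  nodes <- igraph::V(net)$name
  idx <- match(ego, nodes)
  if (is.na(idx)) stop("ego '", ego, "' is not in the network")
  adj <- .adjacencyList(net)
  scoreFun <- if (is.function(scorer)) scorer
              else function(d, g) scoreGeneSet(d, g, scorer)
  .growModuleImpl(adj, nodes, data, idx, scoreFun, as.integer(maxLevel),
                  as.integer(nodeCap))
}

.growModuleImpl <- function(adj, nodes, data, egoIdx, scoreFun, maxLevel,
                            nodeCap) {
  ego <- nodes[egoIdx]
  memberIdx <- .bfsNeighborhood(adj, egoIdx, 1L)
  genes <- sort(nodes[memberIdx])
  genes <- genes[genes %in% rownames(data)]
  if (length(genes) < 2L) {
    msg("skipping ego '", ego, "': fewer than 2 genes with expression at ",
        "level 1")
    return(NULL)
  }
  levels <- 1L
  traces <- scoreFun(data, genes)
  memberSets <- list(genes)
  k <- 1L
  while (k < maxLevel) {
    nextIdx <- .bfsNeighborhood(adj, egoIdx, k + 1L)
    if (length(nextIdx) <= length(memberIdx)) break     # nothing new
    if (length(nextIdx) > nodeCap) break                # hub guard
    nextGenes <- sort(nodes[nextIdx])
    nextGenes <- nextGenes[nextGenes %in% rownames(data)]
    s <- scoreFun(data, nextGenes)
    levels <- c(levels, k + 1L)
    traces <- c(traces, s)
    memberSets <- c(memberSets, list(nextGenes))
    memberIdx <- nextIdx
    if (s < traces[length(traces) - 1L]) break          # accuracy dropped
    k <- k + 1L
  }
  best <- which.max(traces)  # earliest maximum on ties
  new("EgoModule", ego = ego, level = levels[best],
      members = memberSets[[best]], score = traces[best],
      scoreTrace = data.frame(level = levels, score = traces))
}

#' Enumerate grown modules for every eligible ego
#'
#' Scans all genes with two or more interaction partners in sorted order
#' and grows one module per ego (see \code{\link{growModule}}). Egos whose
#' neighborhood cannot be scored are skipped with a message. Deterministic
#' for a fixed scorer seed.
#'
#' @inheritParams growModule
#' @param verbose report progress and skips.
#' @return an \linkS4class{EgoModuleList}.
#' @export
enumerateModules <- function(net, data, scorer, maxLevel = 3L,
                             nodeCap = 300L, verbose = FALSE) {
  nodes <- igraph::V(net)$name
  adj <- .adjacencyList(net)
  egos <- eligibleEgos(net)
  # neighboring egos often share member sets at level >= 2, and the score
  # depends only on the gene set for a fixed config, so scores are memoized
  # by member set within one scan
  cache <- new.env(parent = emptyenv(), hash = TRUE)
  scoreFun <- if (is.function(scorer)) {
    inner <- scorer
    function(d, g) {
      key <- paste(g, collapse = "\r")
      if (is.null(cache[[key]])) cache[[key]] <- inner(d, g)
      cache[[key]]
    }
  } else {
    Xall <- t(exprsValues(data))
    yall <- factor(phenoLabels(data), levels = c(0L, 1L))
    function(d, g) {
      key <- paste(g, collapse = "\r")
      if (is.null(cache[[key]]))
        cache[[key]] <- .cvLoopMatrix(Xall[, g, drop = FALSE], yall, scorer)
      cache[[key]]
    }
  }
  mods <- vector("list", length(egos))
  for (i in seq_along(egos)) {
    m <- .growModuleImpl(adj, nodes, data, match(egos[i], nodes), scoreFun,
                         as.integer(maxLevel), as.integer(nodeCap))
    mods[[i]] <- m
    if (verbose && i %% 100L == 0L)
      msg("scored ", i, "/", length(egos), " egos")
  }
  EgoModuleList(Filter(Negate(is.null), mods))
}

#' Order modules by score
#'
#' Sorts a module list by score (descending), breaking ties by smaller
#' module size and then lexicographic ego, the order used to pick "top"
#' modules in the simulation studies.
#'
#' @param modules an \linkS4class{EgoModuleList}.
#' @return the sorted \linkS4class{EgoModuleList}.
#' @export
sortModules <- function(modules) {
  if (!length(modules)) return(modules)
  s <- vapply(modules, moduleScore, numeric(1))
  sz <- vapply(modules, function(m) length(members(m)), integer(1))
  eg <- vapply(modules, ego, character(1))
  EgoModuleList(as.list(modules)[order(-s, sz, eg)])
}
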