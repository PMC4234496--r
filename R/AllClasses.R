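#' @import methods
#' @importFrom S4Vectors SimpleList DataFrame metadata metadata<-
#' @importClassesFrom S4Vectors SimpleList
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData
NULL

#' Expression matrix with a binary phenotype
#'
#' A \linkS4class{SummarizedExperiment} carrying one assay \code{"exprs"}
#' (genes in rows, samples in columns) and an integer \code{label} column
#' (0/1) in \code{colData}. Both phenotype classes must be present, with at
#' least two samples each, so that stratified cross-validation and
#' two-sample tests are defined.
#'
#' @export
setClass("LabeledExpression", contains = "SummarizedExperiment")

setValidity("LabeledExpression", function(object) {
  msg <- character()
  if (!"exprs" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'exprs' is required")
  else {
    m <- SummarizedExperiment::assay(object, "exprs")
    if (!is.numeric(m)) msg <- c(msg, "assay 'exprs' must be numeric")
    if (anyNA(m)) msg <- c(msg, "assay 'exprs' must not contain NA values")
  }
  if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
    msg <- c(msg, "gene identifiers (rownames) must be present and unique")
  if (is.null(colnames(object)) || anyDuplicated(colnames(object)))
    msg <- c(msg, "sample identifiers (colnames) must be present and unique")
  if (!"label" %in% colnames(colData(object)))
    msg <- c(msg, "colData must have a 'label' column")
  else {
    lab <- colData(object)$label
    if (!all(lab %in% c(0L, 1L)))
      msg <- c(msg, "labels must be 0 or 1")
    else if (any(table(factor(lab, levels = c(0L, 1L))) < 2L))
      msg <- c(msg, "each phenotype class needs at least 2 samples")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a LabeledExpression object
#'
#' @param values numeric matrix, genes in rows (rownames = gene identifiers),
#'   samples in columns (colnames = sample identifiers).
#' @param labels binary phenotype, one value in \code{c(0, 1)} per sample.
#'   If named, names are matched against \code{colnames(values)}; otherwise
#'   positional order is assumed.
#' @return A \linkS4class{LabeledExpression} object.
#' @examples
#' m <- matrix(rnorm(40), 4, 10,
#'             dimnames = list(paste0("g", 1:4), paste0("s", 1:10)))
#' le <- LabeledExpression(m, rep(c(0, 1), each = 5))
#' @export
LabeledExpression <- function(values, labels) {
  values <- as.matrix(values)
  if (!is.null(names(labels))) {
    missing <- setdiff(colnames(values), names(labels))
    if (length(missing))
      stop("samples without a label: ", paste(missing, collapse = ", "))
    labels <- labels[colnames(values)]
  } else if (length(labels) != ncol(values)) {
    stop("need one label per sample (", ncol(values), "), got ",
         length(labels))
  }
  se <- SummarizedExperiment(
    assays = list(exprs = values),
    colData = DataFrame(label = as.integer(labels),
                        row.names = colnames(values)))
  new("LabeledExpression", se)
}

#' @describeIn LabeledExpression-class the expression matrix (genes x samples)
#' @param x a \code{LabeledExpression}
#' @export
exprsValues <- function(x) SummarizedExperiment::assay(x, "exprs")

#' @describeIn LabeledExpression-class integer 0/1 phenotype labels, named by
#'   sample
#' @export
phenoLabels <- function(x) {
  lab <- colData(x)$label
  names(lab) <- colnames(x)
  lab
}

#' A grown ego-network module
#'
#' The result of snowball growth from one ego: the chosen level (maximum
#' graph distance from the ego), the member gene set at that level, the
#' module score S (cross-validated classification accuracy), the full
#' level-by-level score trace, and optionally a permutation p-value and
#' per-gene out-of-bag permutation importances V.
#'
#' @slot ego the focal gene.
#' @slot level chosen neighborhood radius.
#' @slot members gene identifiers at graph distance <= level from the ego.
#' @slot score cross-validated accuracy of \code{members} against the
#'   phenotype, in [0, 1].
#' @slot scoreTrace data.frame with columns \code{level}, \code{score},
#'   one row per level actually evaluated during growth.
#' @slot pValue label-permutation p-value (NA until computed).
#' @slot importance named numeric of per-gene importances (empty until
#'   computed).
#' @export
setClass("EgoModule",
         representation(ego = "character", level = "integer",
                        members = "character", score = "numeric",
                        scoreTrace = "data.frame", pValue = "numeric",
                        importance = "numeric"),
         prototype(pValue = NA_real_, importance = numeric()))

setValidity("EgoModule", function(object) {
  msg <- character()
  if (length(object@ego) != 1L) msg <- c(msg, "ego must be a single gene")
  if (!object@ego %in% object@members) msg <- c(msg, "ego must be a member")
  if (length(object@level) != 1L || object@level < 0L)
    msg <- c(msg, "level must be a single non-negative integer")
  if (length(object@score) != 1L ||
      (!is.na(object@score) && (object@score < 0 || object@score > 1)))
    msg <- c(msg, "score must be in [0, 1]")
  if (!all(c("level", "score") %in% names(object@scoreTrace)))
    msg <- c(msg, "scoreTrace needs 'level' and 'score' columns")
  if (!is.na(object@pValue) && (object@pValue <= 0 || object@pValue > 1))
    msg <- c(msg, "pValue must be in (0, 1]")
  if (length(msg)) msg else TRUE
})

#' @describeIn EgoModule-class the ego gene
#' @param x an \code{EgoModule}
#' @export
ego <- function(x) x@ego

#' @describeIn EgoModule-class the chosen level
#' @export
moduleLevel <- function(x) x@level

#' @describeIn EgoModule-class member gene identifiers
#' @export
members <- function(x) x@members

#' @describeIn EgoModule-class the module score S (CV accuracy)
#' @export
moduleScore <- function(x) x@score

#' @describeIn EgoModule-class permutation p-value (NA if not computed)
#' @export
pValue <- function(x) x@pValue

#' @describeIn EgoModule-class named per-gene importances V (empty if not
#'   computed)
#' @export
importanceValues <- function(x) x@importance

setMethod("show", "EgoModule", function(object) {
  cat("EgoModule: ego ", object@ego, ", level ", object@level, ", ",
      length(object@members), " genes, score ",
      format(object@score, digits = 3), sep = "")
  if (!is.na(object@pValue))
    cat(", p ", format(object@pValue, digits = 3), sep = "")
  cat("\n")
})

#' List of EgoModule objects
#'
#' A \linkS4class{SimpleList} whose elements are \linkS4class{EgoModule}
#' objects, as returned by \code{\link{enumerateModules}}. Convert to a
#' tabular summary with \code{\link{moduleTable}}.
#'
#' @export
setClass("EgoModuleList", contains = "SimpleList",
         prototype = prototype(elementType = "EgoModule"))

#' @rdname EgoModuleList-class
#' @param modules a list of \code{EgoModule} objects
#' @export
EgoModuleList <- function(modules = list()) {
  new("EgoModuleList", SimpleList(modules))
}

setMethod("show", "EgoModuleList", function(object) {
  n <- length(object)
  cat("EgoModuleList with", n, "modules\n")
  if (n) {
    s <- vapply(object, moduleScore, numeric(1))
    sz <- vapply(object, function(m) length(members(m)), integer(1))
    cat("  score range: ", format(min(s), digits = 3), " - ",
        format(max(s), digits = 3),
        "; module size range: ", min(sz), " - ", max(sz), "\n", sep = "")
  }
})

#' Scoring configuration for gene-set classification
#'
#' Bundles the classifier choice, the stratified cross-validation layout
#' and the RNG seed that together define how a gene set is scored against
#' the phenotype.
#'
#' @slot classifier one of \code{"svm"} (RBF kernel), \code{"knn"},
#'   \code{"rf"}.
#' @slot folds number of stratified CV folds (>= 2).
#' @slot repeats number of CV repetitions averaged over.
#' @slot seed integer seed; identical config + seed gives bit-identical
#'   scores.
#' @slot params classifier hyperparameters: \code{cost}, \code{gamma} (svm;
#'   gamma defaults to 1/ngenes on standardized features), \code{k} (knn,
#'   default 5), \code{ntree} (rf, default 500).
#' @export
setClass("ScorerConfig",
         representation(classifier = "character", folds = "integer",
                        repeats = "integer", seed = "integer",
                        params = "list"))

setValidity("ScorerConfig", function(object) {
  msg <- character()
  if (!object@classifier %in% c("svm", "knn", "rf"))
    msg <- c(msg, "classifier must be one of svm, knn, rf")
  if (object@folds < 2L) msg <- c(msg, "folds must be >= 2")
  if (object@repeats < 1L) msg <- c(msg, "repeats must be >= 1")
  if (length(msg)) msg else TRUE
})

#' @rdname ScorerConfig-class
#' @param classifier,folds,repeats,seed see slots
#' @param ... classifier hyperparameters (\code{cost}, \code{gamma},
#'   \code{k}, \code{ntree})
#' @return a \code{ScorerConfig}
#' @examples
#' scorerConfig("svm", seed = 7)
#' @export
scorerConfig <- function(classifier = c("svm", "knn", "rf"), folds = 5L,
                         repeats = 1L, seed = 1L, ...) {
  classifier <- match.arg(classifier)
  new("ScorerConfig", classifier = classifier, folds = as.integer(folds),
      repeats = as.integer(repeats), seed = as.integer(seed),
      params = list(...))
}

setMethod("show", "ScorerConfig", function(object) {
  cat("ScorerConfig:", object@classifier, "|", object@folds, "folds x",
      object@repeats, "repeat(s) | seed", object@seed, "\n")
  if (length(object@params))
    cat("  params:", paste(names(object@params), unlist(object@params),
                           sep = "=", collapse = ", "), "\n")
})

#' Simulation study configuration
#'
#' Parameters of one synthetic instance family: a scale-free
#' (preferential-attachment) interaction network, i.i.d. standard-normal
#' expression, and a binary outcome driven by the disease genes of one
#' planted level-1 ego-network.
#'
#' @slot nNodes network size (genes).
#' @slot nSamples number of samples.
#' @slot nSims number of simulated instances in a study.
#' @slot egoDegreeRange the planted ego is drawn uniformly among nodes with
#'   degree in this closed range.
#' @slot diseaseFraction fraction of planted-module members marked as
#'   disease genes (count = round(fraction * module size)).
#' @slot outcomeModel \code{"linear"} (Y = sum of disease-gene values) or
#'   \code{"nonlinear"} (Y = sum of cubed values); the label is 1 iff
#'   Y >= 0.
#' @slot scenario \code{"ego_associated"} forces the ego into the disease
#'   set; \code{"ego_excluded"} forces it out.
#' @slot attachment edges added per node by preferential attachment.
#' @slot seed master seed; instance i uses seed + i.
#' @export
setClass("SimulationConfig",
         representation(nNodes = "integer", nSamples = "integer",
                        nSims = "integer", egoDegreeRange = "integer",
                        diseaseFraction = "numeric",
                        outcomeModel = "character", scenario = "character",
                        attachment = "integer", seed = "integer"))

setValidity("SimulationConfig", function(object) {
  msg <- character()
  if (object@diseaseFraction <= 0 || object@diseaseFraction > 1)
    msg <- c(msg, "diseaseFraction must be in (0, 1]")
  if (length(object@egoDegreeRange) != 2L ||
      diff(object@egoDegreeRange) < 0L)
    msg <- c(msg, "egoDegreeRange must be a non-empty [low, high] range")
  if (!object@outcomeModel %in% c("linear", "nonlinear"))
    msg <- c(msg, "outcomeModel must be 'linear' or 'nonlinear'")
  if (!object@scenario %in% c("ego_associated", "ego_excluded"))
    msg <- c(msg, "scenario must be 'ego_associated' or 'ego_excluded'")
  if (object@nSims < 1L) msg <- c(msg, "nSims must be >= 1")
  if (object@attachment < 1L) msg <- c(msg, "attachment must be >= 1")
  if (length(msg)) msg else TRUE
})

#' @rdname SimulationConfig-class
#' @param nNodes,nSamples,nSims,egoDegreeRange,diseaseFraction see slots
#' @param outcomeModel,scenario,attachment,seed see slots
#' @return a \code{SimulationConfig}
#' @examples
#' simulationConfig(nNodes = 200, nSims = 30, outcomeModel = "nonlinear")
#' @export
simulationConfig <- function(nNodes = 500L, nSamples = 100L, nSims = 100L,
                             egoDegreeRange = c(5L, 20L),
                             diseaseFraction = 0.8,
                             outcomeModel = c("linear", "nonlinear"),
                             scenario = c("ego_associated", "ego_excluded"),
                             attachment = 3L, seed = 1L) {
  new("SimulationConfig", nNodes = as.integer(nNodes),
      nSamples = as.integer(nSamples), nSims = as.integer(nSims),
      egoDegreeRange = as.integer(egoDegreeRange),
      diseaseFraction = diseaseFraction,
      outcomeModel = match.arg(outcomeModel),
      scenario = match.arg(scenario),
      attachment = as.integer(attachment), seed = as.integer(seed))
}

setMethod("show", "SimulationConfig", function(object) {
  cat("SimulationConfig: ", object@nNodes, " nodes, ", object@nSamples,
      " samples, ", object@nSims, " sims | ego degree [",
      object@egoDegreeRange[1], ", ", object@egoDegreeRange[2],
      "] | disease fraction ", object@diseaseFraction, "\n  outcome ",
      object@outcomeModel, " | scenario ", object@scenario,
      " | attachment m=", object@attachment, " | seed ", object@seed,
      "\n", sep = "")
})
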