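#' @import methods
#' @importFrom stats cor complete.cases lm coef pt rbinom rnorm runif sd
#'   setNames wilcox.test fisher.test
#' @importFrom utils write.table head
NULL

#' InteractionNetwork: a simple undirected protein-protein interaction graph
#'
#' Thin S4 wrapper around an undirected [igraph::igraph] object holding one
#' vertex per protein.  The constructor enforces the network contract used
#' throughout the package: no self-interactions, no duplicated (or
#' reverse-duplicated) edges, and every edge endpoint present in the protein
#' set.  Counts of rows dropped during normalisation are kept in the
#' `dropped` slot.
#'
#' @slot graph an undirected, simple `igraph` object with named vertices.
#' @slot dropped named integer vector of normalisation counts
#'   (`rows_read`, `self_loops`, `duplicates`, `filtered`).
#'
#' @seealso [interactionNetwork()], [readEdgeList()], [proteinDegree()],
#'   [clusteringCoefficient()]
#' @exportClass InteractionNetwork
setClass("InteractionNetwork",
         representation(graph = "ANY", dropped = "integer"))

setValidity("InteractionNetwork", function(object) {
  g <- object@graph
  if (!igraph::is_igraph(g))
    return("'graph' slot must contain an igraph object")
  if (igraph::is_directed(g))
    return("network must be undirected")
  if (igraph::any_loop(g))
    return("network must not contain self-interactions")
  if (igraph::any_multiple(g))
    return("network must not contain duplicated edges")
  if (is.null(igraph::V(g)$name))
    return("vertices must carry protein identifiers")
  TRUE
})

#' FunctionalAnnotation: protein functional-class assignments
#'
#' Maps protein identifiers to non-empty sets of functional-class labels
#' drawn from a fixed vocabulary (by default the 17 MIPS functional
#' catalogue classes, [mipsClasses()]).  Proteins absent from the mapping
#' are unannotated.
#'
#' @slot classes named list; each element a character vector of class labels
#'   for one protein.
#' @slot vocabulary character vector of admissible class labels.
#'
#' @seealso [readAnnotations()], [functionalityCoefficient()]
#' @exportClass FunctionalAnnotation
setClass("FunctionalAnnotation",
         representation(classes = "list", vocabulary = "character"))

setValidity("FunctionalAnnotation", function(object) {
  if (length(object@classes)) {
    if (is.null(names(object@classes)) || any(!nzchar(names(object@classes))))
      return("'classes' must be named by protein identifier")
    if (any(vapply(object@classes, length, 1L) == 0L))
      return("annotated proteins must carry at least one class label")
    bad <- setdiff(unique(unlist(object@classes)), object@vocabulary)
    if (length(bad))
      return(paste0("class labels outside the vocabulary: ",
                    paste(bad, collapse = ", ")))
  }
  TRUE
})

#' ComplexCatalog: protein-complex membership
#'
#' Maps complex identifiers to non-empty sets of member proteins.  A protein
#' may be a subunit of many complexes; proteins absent from every complex
#' are non-complex-forming.
#'
#' @slot members named list of character vectors (complex id -> member ids).
#'
#' @seealso [readComplexCatalog()], [complexNumber()], [isComplexForming()]
#' @exportClass ComplexCatalog
setClass("ComplexCatalog", representation(members = "list"))

setValidity("ComplexCatalog", function(object) {
  if (length(object@members)) {
    if (is.null(names(object@members)) || any(!nzchar(names(object@members))))
      return("'members' must be named by complex identifier")
    if (any(vapply(object@members, length, 1L) == 0L))
      return("complexes must have at least one member")
  }
  TRUE
})

#' SyntheticDataset: a generated study with planted structure
#'
#' Container for one synthetic study: an interaction network, functional
#' annotation, complex catalog, expression levels, one aligned ortholog
#' sequence pair per protein, and the generating ground truth (per-protein
#' latent constraint, planted distance and complex propensity).
#'
#' @slot network an [InteractionNetwork-class].
#' @slot annotation a [FunctionalAnnotation-class].
#' @slot complexes a [ComplexCatalog-class].
#' @slot expression named numeric vector of expression levels.
#' @slot alignments a [Biostrings::AAStringSet] with two gapped records per
#'   protein (focal sequence then ortholog), consecutive.
#' @slot truth data.frame of ground-truth values, one row per protein.
#' @slot config the [syntheticConfig()] list used.
#' @slot seed integer seed that fully determined the draw.
#'
#' @seealso [generateDataset()], [writeDataset()]
#' @importClassesFrom Biostrings AAStringSet
#' @exportClass SyntheticDataset
setClass("SyntheticDataset",
         representation(network = "InteractionNetwork",
                        annotation = "FunctionalAnnotation",
                        complexes = "ComplexCatalog",
                        expression = "numeric",
                        alignments = "AAStringSet",
                        truth = "data.frame",
                        config = "list",
                        seed = "integer"))

#' AnalysisReport: results of the evolutionary-rate inference chain
#'
#' Holds the statistical output of [analyzeFeatures()] /
#' [runPipeline()]: Spearman correlations of protein distance with
#' expression, degree and complex number; partial correlations controlling
#' the other two factors; the multivariate regression table; correlation-
#' matrix PCA (eigenvalues, loadings, retained components, PC1-distance
#' correlation); Mann-Whitney group comparisons; and Fisher-exact
#' contingency tests.
#'
#' @slot correlations data.frame of pairwise Spearman results.
#' @slot partials data.frame of partial Spearman results.
#' @slot regression data.frame of per-predictor OLS results.
#' @slot pca list with `eigenvalues`, `loadings`, `retained`,
#'   `variance_fraction`, `scores`, and `pc1_distance` correlation.
#' @slot groupTests data.frame of Mann-Whitney comparisons.
#' @slot contingency data.frame of Fisher-exact tests.
#' @slot settings list of cutoffs and options the run used.
#'
#' @seealso [analyzeFeatures()], [reportTables()], [writeReport()]
#' @exportClass AnalysisReport
setClass("AnalysisReport",
         representation(correlations = "data.frame",
                        partials = "data.frame",
                        regression = "data.frame",
                        pca = "list",
                        groupTests = "data.frame",
                        contingency = "data.frame",
                        settings = "list"))
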