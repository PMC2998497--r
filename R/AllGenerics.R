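#' Accessors for package containers
#'
#' `proteins()` returns the protein identifiers known to an object;
#' `complexIds()` the complex identifiers of a catalog; `vocabulary()` the
#' admissible class labels of an annotation; `droppedCounts()` the edge-list
#' normalisation counts of a network.
#'
#' @param x an [InteractionNetwork-class], [FunctionalAnnotation-class],
#'   [ComplexCatalog-class] or [SyntheticDataset-class] object.
#' @return `proteins()`: character vector of protein ids. `complexIds()`:
#'   character vector of complex ids. `vocabulary()`: character vector of
#'   class labels. `droppedCounts()`: named integer vector.
#' @name accessors
#' @examples
#' net <- interactionNetwork(data.frame(a = c("A", "B"), b = c("B", "C")))
#' proteins(net)
NULL

#' @rdname accessors
#' @export
setGeneric("proteins", function(x) standardGeneric("proteins"))

#' @rdname accessors
#' @export
setGeneric("complexIds", function(x) standardGeneric("complexIds"))

#' @rdname accessors
#' @export
setGeneric("vocabulary", function(x) standardGeneric("vocabulary"))

#' @rdname accessors
#' @export
setGeneric("droppedCounts", function(x) standardGeneric("droppedCounts"))

#' @rdname accessors
#' @export
setMethod("proteins", "InteractionNetwork",
          function(x) igraph::V(x@graph)$name)

#' @rdname accessors
#' @export
setMethod("proteins", "FunctionalAnnotation", function(x) names(x@classes))

#' @rdname accessors
#' @export
setMethod("proteins", "ComplexCatalog",
          function(x) sort(unique(unlist(x@members, use.names = FALSE))))

#' @rdname accessors
#' @export
setMethod("proteins", "SyntheticDataset", function(x) x@truth$protein_id)

#' @rdname accessors
#' @export
setMethod("complexIds", "ComplexCatalog", function(x) names(x@members))

#' @rdname accessors
#' @export
setMethod("vocabulary", "FunctionalAnnotation", function(x) x@vocabulary)

#' @rdname accessors
#' @export
setMethod("droppedCounts", "InteractionNetwork", function(x) x@dropped)

setMethod("show", "InteractionNetwork", function(object) {
  cat("InteractionNetwork with", igraph::vcount(object@graph),
      "proteins and", igraph::ecount(object@graph), "interactions\n")
  d <- object@dropped
  if (length(d) && any(d[c("self_loops", "duplicates")] > 0, na.rm = TRUE))
    cat("  (dropped", d[["self_loops"]], "self-interactions,",
        d[["duplicates"]], "duplicate edges)\n")
  invisible(object)
})

setMethod("show", "FunctionalAnnotation", function(object) {
  cat("FunctionalAnnotation:", length(object@classes), "proteins,",
      length(object@vocabulary), "classes in vocabulary\n")
  invisible(object)
})

setMethod("show", "ComplexCatalog", function(object) {
  sizes <- vapply(object@members, length, 1L)
  cat("ComplexCatalog:", length(object@members), "complexes,",
      length(proteins(object)), "distinct subunit proteins\n")
  if (length(sizes))
    cat("  member counts: min", min(sizes), "/ median", stats::median(sizes),
        "/ max", max(sizes), "\n")
  invisible(object)
})

setMethod("show", "SyntheticDataset", function(object) {
  cat("SyntheticDataset (seed ", object@seed, "): ",
      nrow(object@truth), " proteins\n", sep = "")
  show(object@network)
  show(object@complexes)
  invisible(object)
})

setMethod("show", "AnalysisReport", function(object) {
  cat("AnalysisReport\n")
  if (nrow(object@correlations)) {
    cat(" Spearman correlations with protein distance:\n")
    co <- object@correlations
    for (i in seq_len(nrow(co)))
      cat(sprintf("   %-15s rho = %+.3f  (p = %.3g, n = %d)\n",
                  co$variable[i], co$rho[i], co$p_value[i], co$n[i]))
  }
  if (length(object@pca)) {
    pc <- object@pca
    cat(sprintf(" PCA: PC1 carries %.1f%% of variance (eigenvalue %.2f%s)\n",
                100 * pc$variance_fraction[1], pc$eigenvalues[1],
                if (pc$retained[1]) ", retained" else ""))
  }
  if (nrow(object@groupTests))
    cat(" Group comparisons:", nrow(object@groupTests),
        "Mann-Whitney tests\n")
  invisible(object)
})
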