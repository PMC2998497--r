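#' Read a protein expression table
#'
#' Expects rows of `protein_id <TAB> expression_level`.
#'
#' @param path path to the TSV file.
#' @return named numeric vector.
#' @export
readExpression <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  lineNo <- which(keep)
  lines <- lines[keep]
  if (!length(lines)) return(setNames(numeric(), character()))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(vapply(fields, length, 1L) < 2L)
  if (length(short))
    stop("malformed expression row at line ", lineNo[short[1L]],
         " of '", path, "'")
  p <- vapply(fields, function(f) trimws(f[[1L]]), "")
  v <- vapply(fields, function(f) trimws(f[[2L]]), "")
  if (tolower(p[1L]) %in% c("protein_id", "protein", "id", "orf")) {
    p <- p[-1L]; v <- v[-1L]
  }
  x <- suppressWarnings(as.numeric(v))
  if (anyNA(x)) stop("non-numeric expression value for protein ",
                     p[which(is.na(x))[1L]])
  if (anyDuplicated(p)) stop("duplicated protein id in expression table")
  setNames(x, p)
}

#' Assemble the per-protein feature table
#'
#' Joins, on protein identifier, every feature the analysis uses: degree
#' and clustering coefficient with the SP/DP density label, the
#' functionality coefficient with its assigned class and SF/DF label,
#' complex number and complex-forming flag, expression level, and the
#' Kimura protein distance.  Classification cutoffs default to the dataset
#' mean of the defining coefficient (ties at the cutoff go to DP / SF).
#' Annotation, complex, expression and distance inputs are optional;
#' absent inputs leave their columns `NA` and downstream analyses that
#' need them are skipped.
#'
#' @param net an [InteractionNetwork-class].
#' @param annotation optional [FunctionalAnnotation-class].
#' @param complexes optional [ComplexCatalog-class].
#' @param expression optional named numeric vector.
#' @param distances optional data.frame from [batchDistances()] (or any
#'   data.frame with `protein_id` and `kimura_distance` columns).
#' @param funcCutoff SF/DF cutoff: `"mean"` or numeric.
#' @param clustCutoff SP/DP cutoff: `"mean"` or numeric.
#' @param partnerCount passed to [functionalityCoefficient()].
#' @return data.frame, one row per network protein; the cutoffs actually
#'   used are stored in `attr(, "cutoffs")`.
#' @examples
#' ds <- generateDataset(syntheticConfig(nProteins = 50), seed = 3)
#' ft <- buildFeatureTable(ds@network, ds@annotation, ds@complexes,
#'                         ds@expression, batchDistances(ds@alignments))
#' head(ft)
#' @export
buildFeatureTable <- function(net, annotation = NULL, complexes = NULL,
                              expression = NULL, distances = NULL,
                              funcCutoff = "mean", clustCutoff = "mean",
                              partnerCount = "all") {
  stopifnot(is(net, "InteractionNetwork"))
  ids <- proteins(net)
  ft <- data.frame(protein_id = ids,
                   degree = unname(proteinDegree(net, ids)),
                   stringsAsFactors = FALSE)
  cc <- clusteringCoefficient(net, ids)
  dens <- classifyDensity(cc, clustCutoff)
  ft$clustering_coefficient <- dens$clustering_coefficient
  ft$density_label <- dens$density_label
  cutoffs <- list(density = attr(dens, "cutoff"))

  if (!is.null(annotation)) {
    fc <- functionalityCoefficient(net, annotation, ids,
                                   partnerCount = partnerCount)
    fc <- classifyFunctionality(fc, funcCutoff)
    ft$functionality_coefficient <- fc$functionality_coefficient
    ft$assigned_class <- fc$assigned_class
    ft$m <- fc$m
    ft$n <- fc$n
    ft$functionality_label <- fc$functionality_label
    cutoffs$functionality <- attr(fc, "cutoff")
  } else {
    ft$functionality_coefficient <- NA_real_
    ft$assigned_class <- NA_character_
    ft$m <- NA_integer_; ft$n <- NA_integer_
    ft$functionality_label <- NA_character_
  }

  if (!is.null(complexes)) {
    ft$complex_number <- unname(complexNumber(complexes, ids))
    ft$complex_forming <- ft$complex_number >= 1L
  } else {
    ft$complex_number <- NA_integer_
    ft$complex_forming <- NA
  }

  ft$expression <- if (!is.null(expression))
    unname(expression[match(ids, names(expression))]) else NA_real_

  ft$kimura_distance <- if (!is.null(distances))
    distances$kimura_distance[match(ids, distances$protein_id)] else
    NA_real_

  attr(ft, "cutoffs") <- cutoffs
  ft
}

.spearRow <- function(variable, x, y, controls = NULL, pFloor = NULL) {
  res <- tryCatch({
    if (is.null(controls)) spearmanCor(x, y, pFloor = pFloor)
    else partialSpearman(x, y, controls, pFloor = pFloor)
  }, error = function(e) NULL)
  if (is.null(res)) return(NULL)
  data.frame(variable = variable, rho = res$rho, p_value = res$p_value,
             n = res$n, stringsAsFactors = FALSE)
}

.groupRow <- function(comparison, subset, a, b, labels) {
  if (sum(!is.na(a)) < 2L || sum(!is.na(b)) < 2L) return(NULL)
  mw <- mannWhitney(a, b)
  data.frame(comparison = comparison, subset = subset,
             group1 = labels[1L], group2 = labels[2L],
             n1 = mw$n1, n2 = mw$n2,
             mean1 = mw$mean1, mean2 = mw$mean2,
             U = mw$U, p_value = mw$p_value, stringsAsFactors = FALSE)
}

#' Run the evolutionary-rate inference chain on a feature table
#'
#' Executes the full statistical analysis on a [buildFeatureTable()]
#' output, each statistic restricted to the complete cases of its own
#' variables: Spearman correlations of the Kimura distance with expression
#' level, degree and complex number; partial Spearman correlations of each
#' factor controlling the other two; multivariate regression of distance
#' on all three factors; correlation-matrix PCA of (complex number,
#' expression, degree) with eigenvalue-1 retention and the correlation of
#' PC1 scores with distance; Mann-Whitney comparisons of distance between
#' SF/DF, SP/DP and complex/non-complex groups (the partner-feature splits
#' also within the complex-forming and non-complex-forming subsets, and
#' the complex/non-complex split also for expression and degree); and
#' Fisher exact tests of the association between complex-forming status
#' and the SF/DF and SP/DP labels.  Analyses whose inputs are absent are
#' skipped with a message.
#'
#' @param features data.frame from [buildFeatureTable()].
#' @param pFloor optional display floor for correlation p-values (e.g.
#'   `1e-6`); `NULL` reports computed values.
#' @param quiet suppress skip messages.
#' @return an [AnalysisReport-class].
#' @export
analyzeFeatures <- function(features, pFloor = NULL, quiet = FALSE) {
  ft <- features
  dist <- ft$kimura_distance
  skip <- function(what) if (!quiet) message("analyzeFeatures: ", what,
                                             " unavailable; skipping")
  haveDist <- any(!is.na(dist))
  haveExpr <- any(!is.na(ft$expression))
  haveCx <- any(!is.na(ft$complex_number))

  correlations <- data.frame()
  partials <- data.frame()
  regression <- data.frame()
  pca <- list()
  if (haveDist) {
    rows <- list(
      if (haveExpr) .spearRow("expression", dist, ft$expression,
                              pFloor = pFloor) else skip("expression"),
      .spearRow("degree", dist, ft$degree, pFloor = pFloor),
      if (haveCx) .spearRow("complex_number", dist, ft$complex_number,
                            pFloor = pFloor) else skip("complex data"))
    correlations <- do.call(rbind, Filter(is.data.frame, rows))
    if (haveExpr && haveCx) {
      partials <- do.call(rbind, Filter(is.data.frame, list(
        .spearRow("expression", dist, ft$expression,
                  cbind(ft$degree, ft$complex_number), pFloor),
        .spearRow("degree", dist, ft$degree,
                  cbind(ft$expression, ft$complex_number), pFloor),
        .spearRow("complex_number", dist, ft$complex_number,
                  cbind(ft$expression, ft$degree), pFloor))))
      regression <- tryCatch(
        multivariateRegression(dist,
          data.frame(expression = ft$expression, degree = ft$degree,
                     complex_number = ft$complex_number)),
        error = function(e) { skip("regression (degenerate)"); data.frame() })
    }
  } else skip("protein distances")
  if (haveExpr && haveCx) {
    pca <- tryCatch(
      pcaDeterminants(data.frame(complex_number = ft$complex_number,
                                 expression = ft$expression,
                                 degree = ft$degree)),
      error = function(e) { skip("PCA (degenerate)"); list() })
    if (length(pca) && haveDist) {
      idx <- complete.cases(ft$complex_number, ft$expression, ft$degree)
      pc1 <- tryCatch(
        spearmanCor(pca$scores[, 1L], dist[idx], pFloor = pFloor),
        error = function(e) NULL)
      pca$pc1_distance <- pc1
      pca$scores <- NULL  # bulky; scores retrievable via pcaDeterminants
    }
  }

  groups <- list()
  if (haveDist) {
    splitBy <- function(label, g1, g2, values, comparison, subset) {
      .groupRow(comparison, subset,
                values[ft[[label]] %in% g1], values[ft[[label]] %in% g2],
                c(g1, g2))
    }
    subsets <- list(all = rep(TRUE, nrow(ft)))
    if (haveCx) {
      subsets$complex <- ft$complex_forming %in% TRUE
      subsets$`non-complex` <- ft$complex_forming %in% FALSE
    }
    for (sub in names(subsets)) {
      sel <- subsets[[sub]]
      if (any(!is.na(ft$functionality_label)))
        groups[[paste0("fd_", sub)]] <- .groupRow(
          "distance: SF vs DF", sub,
          dist[sel & ft$functionality_label %in% "SF"],
          dist[sel & ft$functionality_label %in% "DF"], c("SF", "DF"))
      groups[[paste0("pd_", sub)]] <- .groupRow(
        "distance: SP vs DP", sub,
        dist[sel & ft$density_label %in% "SP"],
        dist[sel & ft$density_label %in% "DP"], c("SP", "DP"))
    }
    if (haveCx) {
      cx <- ft$complex_forming %in% TRUE
      ncx <- ft$complex_forming %in% FALSE
      groups$cx_dist <- .groupRow("distance: complex vs non-complex",
                                  "all", dist[cx], dist[ncx],
                                  c("complex", "non-complex"))
      if (haveExpr)
        groups$cx_expr <- .groupRow("expression: complex vs non-complex",
                                    "all", ft$expression[cx],
                                    ft$expression[ncx],
                                    c("complex", "non-complex"))
      groups$cx_deg <- .groupRow("degree: complex vs non-complex", "all",
                                 ft$degree[cx], ft$degree[ncx],
                                 c("complex", "non-complex"))
    }
  }
  groupTests <- do.call(rbind, Filter(is.data.frame, groups))
  if (is.null(groupTests)) groupTests <- data.frame()
  rownames(groupTests) <- NULL

  contingency <- data.frame()
  if (haveCx) {
    ctRow <- function(label, what) {
      lab <- ft[[what]]
      keep <- !is.na(lab) & lab != "unclassified" & !is.na(ft$complex_forming)
      if (!any(keep)) return(NULL)
      tab <- table(factor(lab[keep]), factor(ft$complex_forming[keep],
                                             levels = c(TRUE, FALSE)))
      if (any(dim(tab) != 2L) || any(rowSums(tab) == 0) ||
          any(colSums(tab) == 0)) return(NULL)
      data.frame(classification = label,
                 p_value = fisherExact(tab), n = sum(tab),
                 stringsAsFactors = FALSE)
    }
    contingency <- do.call(rbind, Filter(is.data.frame, list(
      ctRow("SF/DF vs complex-forming", "functionality_label"),
      ctRow("SP/DP vs complex-forming", "density_label"))))
    if (is.null(contingency)) contingency <- data.frame()
  }

  if (is.null(correlations)) correlations <- data.frame()
  new("AnalysisReport",
      correlations = correlations, partials = partials,
      regression = regression, pca = pca, groupTests = groupTests,
      contingency = contingency,
      settings = c(attr(features, "cutoffs"),
                   list(pFloor = pFloor,
                        n_proteins = nrow(ft))))
}

#' Run the full pipeline from input files
#'
#' Ingests the edge list (required) and whatever optional inputs are
#' supplied — functional annotations, complex catalog, expression table,
#' aligned ortholog FASTA — joins everything on protein identifier, and
#' runs [analyzeFeatures()].  With `outDir` set, writes `features.tsv`,
#' `report.json` and the rendered `tables/*.tsv`.
#'
#' @param edges path to the edge-list TSV.
#' @param annotations,complexes,expression,alignments optional input file
#'   paths (see [readAnnotations()], [readComplexCatalog()],
#'   [readExpression()], [readAlignedPairs()]).
#' @param outDir optional output directory.
#' @param funcCutoff,clustCutoff classification cutoffs (`"mean"` or
#'   numeric).
#' @param dialect edge-list dialect, see [readEdgeList()].
#' @param idFilter optional endpoint-identifier filter regex.
#' @param pFloor optional correlation p-value display floor.
#' @param quiet suppress progress messages.
#' @return list with elements `features` (data.frame) and `report`
#'   ([AnalysisReport-class]).
#' @examples
#' ds <- generateDataset(syntheticConfig(nProteins = 60), seed = 4)
#' files <- writeDataset(ds, tempfile())
#' res <- runPipeline(files["edges"], files["annotations"],
#'                    files["complexes"], files["expression"],
#'                    files["alignments"], quiet = TRUE)
#' res$report
#' @export
runPipeline <- function(edges, annotations = NULL, complexes = NULL,
                        expression = NULL, alignments = NULL,
                        outDir = NULL, funcCutoff = "mean",
                        clustCutoff = "mean", dialect = "tsv",
                        idFilter = NULL, pFloor = NULL, quiet = FALSE) {
  net <- readEdgeList(edges, dialect = dialect, idFilter = idFilter,
                      quiet = quiet)
  ann <- if (!is.null(annotations)) readAnnotations(annotations)
  cat_ <- if (!is.null(complexes)) readComplexCatalog(complexes)
  expr <- if (!is.null(expression)) readExpression(expression)
  dists <- if (!is.null(alignments))
    batchDistances(alignments, quiet = quiet)
  ids <- proteins(net)
  if (!is.null(expr) && length(expr) && !any(names(expr) %in% ids))
    stop("empty join: no expression-table protein occurs in the network")
  if (!is.null(dists) && nrow(dists) && !any(dists$protein_id %in% ids))
    stop("empty join: no aligned-pair protein occurs in the network")
  ft <- buildFeatureTable(net, ann, cat_, expr, dists,
                          funcCutoff = funcCutoff,
                          clustCutoff = clustCutoff)
  report <- analyzeFeatures(ft, pFloor = pFloor, quiet = quiet)
  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    write.table(ft, file.path(outDir, "features.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    writeReport(report, outDir)
  }
  list(features = ft, report = report)
}

#' Render an analysis report as flat tables
#'
#' @param report an [AnalysisReport-class].
#' @return named list of data.frames: `correlations`, `partials`,
#'   `regression`, `pca_loadings`, `group_tests`, `contingency`.  Sections
#'   that were not computed come back as empty data.frames.
#' @export
reportTables <- function(report) {
  stopifnot(is(report, "AnalysisReport"))
  pcaTab <- data.frame()
  if (length(report@pca)) {
    pc <- report@pca
    pcaTab <- data.frame(variable = rownames(pc$loadings),
                         pc$loadings, check.names = FALSE)
    attr(pcaTab, "eigenvalues") <- pc$eigenvalues
    attr(pcaTab, "variance_fraction") <- pc$variance_fraction
  }
  list(correlations = report@correlations,
       partials = report@partials,
       regression = report@regression,
       pca_loadings = pcaTab,
       group_tests = report@groupTests,
       contingency = report@contingency)
}

.reportAsList <- function(report) {
  pca <- report@pca
  if (length(pca) && !is.null(pca$loadings)) {
    pca$loadings <- as.data.frame(pca$loadings)
    pca$loadings$variable <- rownames(report@pca$loadings)
  }
  list(settings = report@settings,
       correlations = report@correlations,
       partial_correlations = report@partials,
       regression = c(list(n = attr(report@regression, "n"),
                           r_squared = attr(report@regression, "r_squared")),
                      list(coefficients = report@regression)),
       pca = pca,
       group_tests = report@groupTests,
       contingency = report@contingency)
}

#' Write an analysis report to disk
#'
#' Writes `report.json` (the full structured report) and one TSV per
#' rendered table under `tables/`.
#'
#' @param report an [AnalysisReport-class].
#' @param dir target directory.
#' @return invisibly, the paths written.
#' @export
writeReport <- function(report, dir) {
  stopifnot(is(report, "AnalysisReport"))
  dir.create(file.path(dir, "tables"), recursive = TRUE,
             showWarnings = FALSE)
  jsonPath <- file.path(dir, "report.json")
  jsonlite::write_json(.reportAsList(report), jsonPath,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  tabs <- reportTables(report)
  paths <- jsonPath
  for (nm in names(tabs)) {
    if (!nrow(tabs[[nm]])) next
    p <- file.path(dir, "tables", paste0(nm, ".tsv"))
    write.table(tabs[[nm]], p, sep = "\t", quote = FALSE,
                row.names = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}
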