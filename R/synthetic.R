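#' Configuration for the synthetic study generator
#'
#' Assembles and validates the parameters of [generateDataset()].  The
#' generator plants a single per-protein latent "constraint" value that
#' jointly raises expression, complex-membership propensity and
#' connectivity while lowering the planted evolutionary distance — the
#' simplest mechanism that reproduces the negative correlation pattern of
#' distance with expression, degree and complex number while leaving each
#' observable its own independent noise channel (so partial correlations
#' stay nonzero).
#'
#' @param nProteins number of proteins (default 2000).
#' @param nClasses number of functional classes (default 17; must not
#'   exceed the vocabulary size).
#' @param nComplexes number of complexes drawn (default 491; empty draws
#'   are discarded, so the realised catalog may be slightly smaller).
#' @param meanDegree target mean degree of the network at baseline
#'   constraint (default 4, as in curated yeast PPI sets); the baseline
#'   edge log-odds are derived from it so density is comparable at any
#'   `nProteins`.
#' @param aDegree weight of the latent constraint on connectivity
#'   (default 0.3).
#' @param complexBaseLogit baseline log-odds that a protein joins any one
#'   complex (default -6.5).
#' @param aComplex weight of the latent constraint on complex propensity
#'   (default 1.2).
#' @param aExpr weight of the latent constraint on log expression
#'   (default 0.5).
#' @param exprNoiseSd independent noise SD on log expression (default 0.4).
#' @param exprScale multiplicative expression scale (default 2, putting
#'   typical values in the low single digits, as for transcripts per
#'   cell).
#' @param bDistance weight of the latent constraint lowering distance
#'   (default 0.5).
#' @param distanceIntercept intercept of the distance linear predictor on
#'   the softplus scale (default -2.6, putting typical planted distances
#'   near 0.07 substitutions per site).
#' @param distanceNoiseSd independent noise SD on the distance predictor
#'   (default 0.25).
#' @param seqLength ungapped alignment length L in residues (default 500).
#' @param annotatedFraction fraction of proteins carrying functional
#'   annotation (default 0.92).
#' @param secondClassProb probability an annotated protein carries a
#'   second class (default 0.3).
#' @param complexHomogeneity probability that an annotated complex member
#'   additionally carries its complex's theme class (default 0.7).
#' @param gapRate per-column probability of injecting a gap into one
#'   sequence of a pair (default 0; used to exercise gap handling).
#' @param vocab functional-class vocabulary (default [mipsClasses()]).
#' @return a validated list of class `"GeneratorConfig"`.
#' @examples
#' cfg <- syntheticConfig(nProteins = 100)
#' cfg$nComplexes
#' @export
syntheticConfig <- function(nProteins = 2000L, nClasses = 17L,
                            nComplexes = 491L,
                            meanDegree = 4, aDegree = 0.3,
                            complexBaseLogit = -6.5, aComplex = 1.2,
                            aExpr = 0.5, exprNoiseSd = 0.4, exprScale = 2,
                            bDistance = 0.5, distanceIntercept = -2.6,
                            distanceNoiseSd = 0.25,
                            seqLength = 500L,
                            annotatedFraction = 0.92,
                            secondClassProb = 0.3,
                            complexHomogeneity = 0.7,
                            gapRate = 0,
                            vocab = mipsClasses()) {
  cfg <- list(nProteins = as.integer(nProteins),
              nClasses = as.integer(nClasses),
              nComplexes = as.integer(nComplexes),
              meanDegree = meanDegree, aDegree = aDegree,
              complexBaseLogit = complexBaseLogit, aComplex = aComplex,
              aExpr = aExpr, exprNoiseSd = exprNoiseSd,
              exprScale = exprScale,
              bDistance = bDistance,
              distanceIntercept = distanceIntercept,
              distanceNoiseSd = distanceNoiseSd,
              seqLength = as.integer(seqLength),
              annotatedFraction = annotatedFraction,
              secondClassProb = secondClassProb,
              complexHomogeneity = complexHomogeneity,
              gapRate = gapRate, vocab = vocab)
  with(cfg, {
    if (nProteins < 1L) stop("'nProteins' must be positive")
    if (nClasses < 1L || nClasses > length(vocab))
      stop("'nClasses' must be between 1 and the vocabulary size")
    if (nComplexes < 1L) stop("'nComplexes' must be positive")
    if (meanDegree <= 0 || meanDegree > nProteins - 1L && nProteins > 1L)
      stop("'meanDegree' must be positive and below 'nProteins'")
    if (seqLength < 1L) stop("'seqLength' must be positive")
    for (pr in c(annotatedFraction, secondClassProb, complexHomogeneity,
                 gapRate))
      if (pr < 0 || pr > 1) stop("probabilities must lie in [0, 1]")
    if (exprNoiseSd < 0 || distanceNoiseSd < 0)
      stop("noise scales must be non-negative")
  })
  class(cfg) <- "GeneratorConfig"
  cfg
}

.softplus <- function(x) ifelse(x > 30, x, log1p(exp(x)))

#' Simulate one aligned ortholog pair at a planted distance
#'
#' Inverts the Kimura correction to the difference proportion
#' `p* = kimuraInverse(d)`, draws the number of differing sites
#' `k ~ Binomial(L, p*)`, builds a random ancestral amino-acid sequence of
#' length `L` and substitutes `k` sites with different residues in the
#' copy.  Site-independent substitution without rate heterogeneity is
#' deliberate: only the p-to-d correction is under study.  With
#' `gapRate > 0`, columns are gapped at random in one of the two sequences
#' (extending the alignment), which exercises pairwise gap exclusion.
#'
#' @param d planted Kimura distance (non-negative, finite).
#' @param L ungapped sequence length.
#' @param ids character vector of two record names.
#' @param gapRate per-column gap injection probability.
#' @return a [Biostrings::AAStringSet] of two aligned records.
#' @examples
#' set.seed(1)
#' evolvePair(0.1, 100)
#' @export
evolvePair <- function(d, L, ids = c("anc", "der"), gapRate = 0) {
  if (!is.finite(d) || d < 0) stop("'d' must be finite and non-negative")
  pstar <- kimuraInverse(d)
  anc <- sample(.AA20, L, replace = TRUE)
  der <- anc
  k <- rbinom(1L, L, pstar)
  if (k > 0L) {
    sites <- sample.int(L, k)
    der[sites] <- vapply(anc[sites],
                         function(r) sample(setdiff(.AA20, r), 1L), "")
  }
  if (gapRate > 0) {
    gapped <- runif(L) < gapRate
    if (any(gapped)) {
      which1 <- runif(sum(gapped)) < 0.5
      anc[gapped][which1] <- "-"
      der[gapped][!which1] <- "-"
    }
  }
  Biostrings::AAStringSet(setNames(c(paste(anc, collapse = ""),
                                     paste(der, collapse = "")), ids))
}

#' Generate a complete synthetic study
#'
#' Draws a full set of pipeline inputs — interaction network, functional
#' annotation, complex catalog, expression levels and one aligned ortholog
#' pair per protein — with the planted latent-constraint structure
#' described in [syntheticConfig()].  Per protein `i` with latent
#' constraint `c_i ~ N(0, 1)`:
#' expression is `exprScale * exp(aExpr c_i + noise)`; each complex
#' includes the protein with probability `plogis(complexBaseLogit +
#' aComplex c_i)`; an edge joins proteins `i` and `j` with probability
#' `plogis(logit(meanDegree/(n-1)) + aDegree (c_i + c_j))`; the planted distance is
#' `softplus(distanceIntercept - bDistance c_i + noise)`, realised as a
#' sequence pair by [evolvePair()].  Functional classes are drawn per
#' protein, with complex members preferentially sharing their complex's
#' theme class.  The seed fully determines the output.
#'
#' @param config a [syntheticConfig()] object.
#' @param seed integer seed.
#' @return a [SyntheticDataset-class]; the `truth` slot records per
#'   protein the latent constraint, planted distance and complex
#'   propensity.
#' @examples
#' ds <- generateDataset(syntheticConfig(nProteins = 60), seed = 7)
#' ds
#' @export
generateDataset <- function(config = syntheticConfig(), seed = 1L) {
  stopifnot(inherits(config, "GeneratorConfig"))
  set.seed(as.integer(seed))
  n <- config$nProteins
  ids <- sprintf("P%05d", seq_len(n))
  constraint <- rnorm(n)

  expression <- config$exprScale *
    exp(config$aExpr * constraint + rnorm(n, 0, config$exprNoiseSd))
  names(expression) <- ids

  # complex membership: per-protein inclusion probability shared by all
  # complexes; empty complexes are discarded
  pComplex <- stats::plogis(config$complexBaseLogit +
                            config$aComplex * constraint)
  members <- vector("list", config$nComplexes)
  for (j in seq_len(config$nComplexes))
    members[[j]] <- ids[runif(n) < pComplex]
  names(members) <- sprintf("CPX%04d", seq_len(config$nComplexes))
  members <- members[vapply(members, length, 1L) > 0L]
  complexes <- new("ComplexCatalog", members = members)

  # network: independent edges, inclusion probability increasing in the
  # summed constraints of the endpoints
  edgeBaseLogit <- stats::qlogis(min(config$meanDegree / max(n - 1L, 1L),
                                     0.99))
  pairIdx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  pe <- stats::plogis(edgeBaseLogit +
                      config$aDegree * (constraint[pairIdx[, 1L]] +
                                        constraint[pairIdx[, 2L]]))
  keep <- runif(nrow(pairIdx)) < pe
  net <- interactionNetwork(
    data.frame(a = ids[pairIdx[keep, 1L]], b = ids[pairIdx[keep, 2L]],
               stringsAsFactors = FALSE),
    extraProteins = ids, quiet = TRUE)

  # functional classes: per-protein draws plus complex theme classes
  classVocab <- config$vocab[seq_len(config$nClasses)]
  annotated <- runif(n) < config$annotatedFraction
  classes <- vector("list", n)
  names(classes) <- ids
  primary <- sample(classVocab, n, replace = TRUE)
  second <- sample(classVocab, n, replace = TRUE)
  hasSecond <- runif(n) < config$secondClassProb
  for (i in which(annotated))
    classes[[i]] <- unique(c(primary[i], if (hasSecond[i]) second[i]))
  themes <- sample(classVocab, length(members), replace = TRUE)
  for (j in seq_along(members)) {
    mem <- members[[j]]
    add <- mem[annotated[match(mem, ids)] &
               runif(length(mem)) < config$complexHomogeneity]
    for (p in add) classes[[p]] <- unique(c(classes[[p]], themes[j]))
  }
  annotation <- new("FunctionalAnnotation",
                    classes = classes[!vapply(classes, is.null, TRUE)],
                    vocabulary = config$vocab)

  # planted distances and sequence pairs
  distance <- .softplus(config$distanceIntercept -
                        config$bDistance * constraint +
                        rnorm(n, 0, config$distanceNoiseSd))
  pairList <- vector("list", n)
  for (i in seq_len(n))
    pairList[[i]] <- evolvePair(distance[i], config$seqLength,
                                ids = c(ids[i], paste0(ids[i], "_ortho")),
                                gapRate = config$gapRate)
  alignments <- do.call(c, pairList)

  truth <- data.frame(protein_id = ids, constraint = constraint,
                      planted_distance = distance,
                      complex_propensity = pComplex,
                      expression = unname(expression),
                      stringsAsFactors = FALSE)

  new("SyntheticDataset", network = net, annotation = annotation,
      complexes = complexes, expression = expression,
      alignments = alignments, truth = truth,
      config = unclass(config), seed = as.integer(seed))
}

#' Write a synthetic study to pipeline input files
#'
#' Emits the dataset in exactly the formats [runPipeline()] consumes:
#' `edges.tsv`, `annotations.tsv`, `complexes.tsv`, `expression.tsv`,
#' `alignments.fasta`, plus `truth.tsv` and a `manifest.json` echoing the
#' seed and configuration.
#'
#' @param ds a [SyntheticDataset-class].
#' @param dir target directory (created if needed).
#' @return named character vector of the files written (the manifest).
#' @examples
#' ds <- generateDataset(syntheticConfig(nProteins = 30), seed = 2)
#' files <- writeDataset(ds, tempfile())
#' names(files)
#' @export
writeDataset <- function(ds, dir) {
  stopifnot(is(ds, "SyntheticDataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  path <- function(f) file.path(dir, f)
  eg <- igraph::as_edgelist(ds@network@graph)
  writeLines(paste(eg[, 1L], eg[, 2L], sep = "\t"), path("edges.tsv"))
  annDf <- do.call(rbind, lapply(names(ds@annotation@classes), function(p)
    data.frame(p = p, cl = ds@annotation@classes[[p]])))
  writeLines(if (is.null(annDf)) character() else
             paste(annDf$p, annDf$cl, sep = "\t"), path("annotations.tsv"))
  cxDf <- do.call(rbind, lapply(names(ds@complexes@members), function(cx)
    data.frame(cx = cx, p = ds@complexes@members[[cx]])))
  writeLines(if (is.null(cxDf)) character() else
             paste(cxDf$cx, cxDf$p, sep = "\t"), path("complexes.tsv"))
  writeLines(paste(names(ds@expression),
                   format(ds@expression, digits = 15, trim = TRUE,
                          scientific = FALSE), sep = "\t"),
             path("expression.tsv"))
  Biostrings::writeXStringSet(ds@alignments, path("alignments.fasta"))
  write.table(ds@truth, path("truth.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  manifest <- list(seed = ds@seed,
                   files = list(edges = "edges.tsv",
                                annotations = "annotations.tsv",
                                complexes = "complexes.tsv",
                                expression = "expression.tsv",
                                alignments = "alignments.fasta",
                                truth = "truth.tsv"),
                   config = ds@config[setdiff(names(ds@config), "vocab")])
  jsonlite::write_json(manifest, path("manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  files <- c(edges = path("edges.tsv"),
             annotations = path("annotations.tsv"),
             complexes = path("complexes.tsv"),
             expression = path("expression.tsv"),
             alignments = path("alignments.fasta"),
             truth = path("truth.tsv"),
             manifest = path("manifest.json"))
  invisible(files)
}
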