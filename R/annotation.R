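#' The 17 MIPS functional catalogue classes
#'
#' Top-level functional classes of the Munich Information Center for
#' Protein Sequences (MIPS) catalogue, the default vocabulary for protein
#' functional annotation in this package.
#'
#' @return character vector of 17 class names.
#' @examples
#' length(mipsClasses())
#' @export
mipsClasses <- function() {
  c("Metabolism",
    "Energy",
    "Cell cycle and DNA processing",
    "Transcription",
    "Protein synthesis",
    "Protein fate (folding, modification, destination)",
    "Protein with binding function or cofactor requirement (structural or catalytic)",
    "Regulation of metabolism and protein function",
    "Cellular transport, Transport facilities and transport routes",
    "Cellular communication/signal transduction mechanism",
    "Cell rescue, defense and virulence",
    "Interaction with the environment",
    "Transposable elements, viral and plasmid proteins",
    "Cell fate",
    "Development",
    "Biogenesis of cellular components",
    "Cell type differentiation")
}

#' Construct a functional annotation
#'
#' @param classes named list mapping protein id to a character vector of
#'   class labels, or a two-column data.frame of (protein id, class label)
#'   rows.
#' @param vocab character vector of admissible labels
#'   (default [mipsClasses()]).
#' @return a [FunctionalAnnotation-class].
#' @examples
#' ann <- functionalAnnotation(list(A = c("Energy", "Transcription")))
#' vocabulary(ann)[1:3]
#' @export
functionalAnnotation <- function(classes, vocab = mipsClasses()) {
  if (is.data.frame(classes)) {
    classes <- lapply(split(as.character(classes[[2L]]),
                            as.character(classes[[1L]])), unique)
  }
  classes <- lapply(classes, function(x) unique(as.character(x)))
  new("FunctionalAnnotation", classes = classes, vocabulary = vocab)
}

#' Read functional annotations from a TSV file
#'
#' Expects rows of `protein_id <TAB> class_label`; a protein may appear on
#' several rows (multi-class membership).  Labels outside the vocabulary
#' raise an error naming the offending line.
#'
#' @param path path to the annotation file.
#' @param vocab admissible class labels (default [mipsClasses()]).
#' @return a [FunctionalAnnotation-class].
#' @examples
#' f <- tempfile()
#' writeLines(c("A\tEnergy", "A\tTranscription", "B\tEnergy"), f)
#' readAnnotations(f)
#' @export
readAnnotations <- function(path, vocab = mipsClasses()) {
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  lineNo <- which(keep)
  lines <- lines[keep]
  if (!length(lines))
    return(functionalAnnotation(list(), vocab))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(vapply(fields, length, 1L) < 2L)
  if (length(short))
    stop("malformed annotation row at line ", lineNo[short[1L]],
         " of '", path, "'")
  p <- vapply(fields, function(f) trimws(f[[1L]]), "")
  cl <- vapply(fields, function(f) trimws(f[[2L]]), "")
  if (tolower(p[1L]) %in% c("protein_id", "protein", "id") &&
      !(cl[1L] %in% vocab)) {
    p <- p[-1L]; cl <- cl[-1L]; lineNo <- lineNo[-1L]
  }
  bad <- which(!(cl %in% vocab))
  if (length(bad))
    stop("unknown functional class '", cl[bad[1L]], "' at line ",
         lineNo[bad[1L]], " of '", path, "'")
  functionalAnnotation(data.frame(p, cl, stringsAsFactors = FALSE), vocab)
}

#' Classes annotated for given proteins
#'
#' @param ann a [FunctionalAnnotation-class].
#' @param ids protein identifiers.
#' @return named list of class-label vectors; `NULL` entries for
#'   unannotated proteins.
#' @export
annotationClasses <- function(ann, ids = proteins(ann)) {
  stopifnot(is(ann, "FunctionalAnnotation"))
  setNames(ann@classes[match(ids, names(ann@classes))], ids)
}

#' Coefficient of functionality
#'
#' For a protein with `m` interaction partners of which `n` share one of
#' its functional classes, the coefficient of functionality is `n / m`.
#' For a multi-class protein the coefficient is computed for each of its
#' own classes and the class with the largest value is assigned (ties are
#' broken towards the lexicographically smallest label).  The coefficient
#' is missing when the protein is unannotated or has no partner.
#'
#' @param net an [InteractionNetwork-class].
#' @param ann a [FunctionalAnnotation-class].
#' @param ids protein identifiers (default: all network proteins).
#' @param partnerCount `"all"` (default): `m` counts every partner,
#'   annotated or not; `"annotated"`: `m` counts annotated partners only.
#'   Unannotated partners can never contribute to `n` either way.
#' @return data.frame with columns `protein_id`,
#'   `functionality_coefficient`, `assigned_class`, `m`, `n`.
#' @examples
#' net <- interactionNetwork(data.frame(a = rep("P", 3), b = c("Q", "R", "S")))
#' ann <- functionalAnnotation(list(P = "Energy", Q = "Energy", R = "Energy",
#'                                  S = "Transcription"))
#' functionalityCoefficient(net, ann, "P")
#' @export
functionalityCoefficient <- function(net, ann, ids = proteins(net),
                                     partnerCount = c("all", "annotated")) {
  stopifnot(is(net, "InteractionNetwork"), is(ann, "FunctionalAnnotation"))
  partnerCount <- match.arg(partnerCount)
  .checkKnown(net, ids)
  adj <- igraph::adjacent_vertices(net@graph, v = ids)
  out <- data.frame(protein_id = ids,
                    functionality_coefficient = NA_real_,
                    assigned_class = NA_character_,
                    m = 0L, n = NA_integer_,
                    stringsAsFactors = FALSE)
  for (i in seq_along(ids)) {
    partners <- adj[[i]]$name
    own <- ann@classes[[ids[i]]]
    partnerClasses <- ann@classes[match(partners, names(ann@classes))]
    annotated <- !vapply(partnerClasses, is.null, TRUE)
    m <- if (partnerCount == "all") length(partners) else sum(annotated)
    out$m[i] <- m
    if (is.null(own) || m == 0L) next
    nByClass <- vapply(own, function(cl) {
      sum(vapply(partnerClasses[annotated],
                 function(pc) cl %in% pc, TRUE))
    }, 1L)
    best <- which(nByClass == max(nByClass))
    pick <- best[order(own[best])][1L]
    out$functionality_coefficient[i] <- nByClass[pick] / m
    out$assigned_class[i] <- own[pick]
    out$n[i] <- nByClass[pick]
  }
  out
}

#' Classify proteins into same-functional (SF) and different-functional (DF)
#'
#' Thresholds the coefficient of functionality at a cutoff: proteins whose
#' coefficient is at or above the cutoff are same-functional (SF), the rest
#' different-functional (DF).  With `cutoff = "mean"` the cutoff is the
#' mean over proteins with a defined coefficient.  Missing coefficients
#' (unannotated or partnerless proteins) give `unclassified`.
#'
#' @param results data.frame from [functionalityCoefficient()], or a named
#'   numeric vector of coefficients.
#' @param cutoff `"mean"` or a numeric threshold.
#' @return the input data.frame with a `functionality_label` column added
#'   (`"SF"`, `"DF"`, `"unclassified"`); cutoff in `attr(, "cutoff")`.
#' @export
classifyFunctionality <- function(results, cutoff = "mean") {
  if (is.numeric(results)) {
    results <- data.frame(protein_id = names(results),
                          functionality_coefficient = unname(results),
                          stringsAsFactors = FALSE)
  }
  co <- results$functionality_coefficient
  cut <- .resolveCutoff(co, cutoff, "functionality coefficient")
  results$functionality_label <-
    ifelse(is.na(co), "unclassified", ifelse(co >= cut, "SF", "DF"))
  attr(results, "cutoff") <- cut
  results
}
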