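#' Construct a protein-complex catalog
#'
#' @param members named list mapping complex id to member protein ids, or a
#'   two-column data.frame of (complex id, protein id) rows.  Duplicate
#'   memberships collapse; complexes left with no members are dropped with
#'   a warning.
#' @return a [ComplexCatalog-class].
#' @examples
#' cat <- complexCatalog(list(C1 = c("A", "B"), C2 = "A"))
#' complexNumber(cat, c("A", "B", "Z"))
#' @export
complexCatalog <- function(members) {
  if (is.data.frame(members)) {
    members <- lapply(split(as.character(members[[2L]]),
                            as.character(members[[1L]])), unique)
  }
  members <- lapply(members, function(x) unique(as.character(x)))
  empty <- vapply(members, length, 1L) == 0L
  if (any(empty)) {
    warning("dropping ", sum(empty), " complex(es) with empty member sets")
    members <- members[!empty]
  }
  new("ComplexCatalog", members = members)
}

#' Read a protein-complex catalog from a TSV file
#'
#' Expects rows of `complex_id <TAB> protein_id`.
#'
#' @param path path to the membership file.
#' @return a [ComplexCatalog-class].
#' @examples
#' f <- tempfile()
#' writeLines(c("C1\tA", "C1\tB", "C2\tA"), f)
#' readComplexCatalog(f)
#' @export
readComplexCatalog <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  lineNo <- which(keep)
  lines <- lines[keep]
  if (!length(lines)) return(complexCatalog(list()))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(vapply(fields, length, 1L) < 2L)
  if (length(short))
    stop("malformed complex row at line ", lineNo[short[1L]],
         " of '", path, "'")
  cx <- vapply(fields, function(f) trimws(f[[1L]]), "")
  p <- vapply(fields, function(f) trimws(f[[2L]]), "")
  if (tolower(cx[1L]) %in% c("complex_id", "complex")) {
    cx <- cx[-1L]; p <- p[-1L]
  }
  complexCatalog(data.frame(cx, p, stringsAsFactors = FALSE))
}

#' Members of one or all complexes
#'
#' @param cat a [ComplexCatalog-class].
#' @param id optional complex identifier; if omitted the full named list is
#'   returned.
#' @return character vector of member ids, or the named list of all member
#'   sets.
#' @export
complexMembers <- function(cat, id = NULL) {
  stopifnot(is(cat, "ComplexCatalog"))
  if (is.null(id)) return(cat@members)
  if (!id %in% names(cat@members)) stop("unknown complex: ", id)
  cat@members[[id]]
}

#' Complex number of a protein
#'
#' Number of protein complexes in which a protein takes part as a subunit.
#' Proteins absent from the catalog have complex number 0.
#'
#' @param cat a [ComplexCatalog-class].
#' @param ids protein identifiers.
#' @return named integer vector.
#' @export
complexNumber <- function(cat, ids) {
  stopifnot(is(cat, "ComplexCatalog"))
  counts <- table(unlist(cat@members, use.names = FALSE))
  n <- as.integer(counts[match(ids, names(counts))])
  n[is.na(n)] <- 0L
  setNames(n, ids)
}

#' Is a protein complex-forming?
#'
#' `TRUE` for proteins that are a subunit of at least one complex.
#'
#' @inheritParams complexNumber
#' @return named logical vector.
#' @export
isComplexForming <- function(cat, ids) complexNumber(cat, ids) >= 1L
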