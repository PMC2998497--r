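#' Build an interaction network from an edge table
#'
#' Normalises a two-column table of binary interactions into a simple
#' undirected [InteractionNetwork-class]: self-interactions are removed and
#' duplicated edges (in either orientation) are collapsed, mirroring the
#' standard cleaning applied to curated PPI downloads.
#'
#' @param edges data.frame or matrix whose first two columns are protein
#'   identifiers, one interaction per row.
#' @param extraProteins optional character vector of proteins to include as
#'   vertices even if they take part in no interaction.
#' @param quiet suppress the message reporting dropped rows.
#' @return an [InteractionNetwork-class].
#' @examples
#' net <- interactionNetwork(
#'   data.frame(a = c("A", "B", "A", "A"), b = c("B", "A", "A", "C")))
#' proteins(net)
#' droppedCounts(net)
#' @export
interactionNetwork <- function(edges, extraProteins = NULL, quiet = FALSE) {
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (ncol(edges) < 2L)
    stop("'edges' must have at least two columns of protein identifiers")
  a <- as.character(edges[[1L]])
  b <- as.character(edges[[2L]])
  if (anyNA(a) || anyNA(b) || any(!nzchar(a)) || any(!nzchar(b)))
    stop("edge endpoints must be non-empty protein identifiers")
  rows <- length(a)
  self <- a == b
  a <- a[!self]; b <- b[!self]
  lo <- pmin(a, b); hi <- pmax(a, b)
  dup <- duplicated(paste(lo, hi, sep = "\r"))
  lo <- lo[!dup]; hi <- hi[!dup]
  dropped <- c(rows_read = rows, self_loops = sum(self),
               duplicates = sum(dup), filtered = 0L)
  verts <- unique(c(lo, hi, as.character(extraProteins)))
  g <- igraph::graph_from_data_frame(
    data.frame(from = lo, to = hi, stringsAsFactors = FALSE),
    directed = FALSE, vertices = verts)
  if (!quiet && (dropped[["self_loops"]] || dropped[["duplicates"]]))
    message("interactionNetwork: dropped ", dropped[["self_loops"]],
            " self-interaction(s) and ", dropped[["duplicates"]],
            " duplicate edge(s)")
  new("InteractionNetwork", graph = g,
      dropped = vapply(dropped, as.integer, 1L))
}

#' Read a PPI edge list from a file
#'
#' Reads binary interactions from a tab-separated file and returns a
#' normalised [InteractionNetwork-class] (self-interactions dropped,
#' duplicate and reversed-duplicate edges collapsed).  Two dialects are
#' supported: a plain two-column TSV (header optional, auto-detected) and a
#' "mitab-lite" dialect where the first two columns carry interactor
#' identifiers, possibly `db:accession` prefixed and `|`-separated, followed
#' by any number of ignored metadata columns.
#'
#' @param path path to the edge-list file.
#' @param dialect `"tsv"` (default) or `"mitab"`.
#' @param idFilter optional regular expression; edges are kept only when
#'   both endpoint identifiers match (e.g. to restrict interactions to one
#'   species when identifiers are species-prefixed).
#' @param quiet suppress the dropped-row message.
#' @return an [InteractionNetwork-class]; `droppedCounts()` reports rows
#'   read and rows dropped as self-loops, duplicates, or by `idFilter`.
#' @examples
#' f <- tempfile()
#' writeLines(c("A\tB", "B\tA", "A\tA", "B\tC"), f)
#' net <- readEdgeList(f)
#' droppedCounts(net)
#' @export
readEdgeList <- function(path, dialect = c("tsv", "mitab"),
                         idFilter = NULL, quiet = FALSE) {
  dialect <- match.arg(dialect)
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  lineNo <- which(keep)
  lines <- lines[keep]
  if (!length(lines))
    return(interactionNetwork(data.frame(a = character(), b = character()),
                              quiet = quiet))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(vapply(fields, length, 1L) < 2L)
  if (length(short))
    stop("malformed edge row (fewer than two fields) at line ",
         lineNo[short[1L]], " of '", path, "'")
  a <- vapply(fields, function(f) trimws(f[[1L]]), "")
  b <- vapply(fields, function(f) trimws(f[[2L]]), "")
  headerNames <- c("id_a", "id_b", "protein_a", "protein_b", "source",
                   "target", "interactor_a", "interactor_b", "ida", "idb")
  if (tolower(a[1L]) %in% headerNames || tolower(b[1L]) %in% headerNames ||
      grepl("^#?ID( |\\()", a[1L])) {
    a <- a[-1L]; b <- b[-1L]
  }
  if (dialect == "mitab") {
    stripMitab <- function(x) {
      x <- vapply(strsplit(x, "|", fixed = TRUE), `[[`, "", 1L)
      sub("^[A-Za-z][A-Za-z0-9_.-]*:", "", x)
    }
    a <- stripMitab(a); b <- stripMitab(b)
  }
  filtered <- 0L
  if (!is.null(idFilter)) {
    ok <- grepl(idFilter, a) & grepl(idFilter, b)
    filtered <- sum(!ok)
    a <- a[ok]; b <- b[ok]
  }
  net <- interactionNetwork(data.frame(a = a, b = b,
                                       stringsAsFactors = FALSE),
                            quiet = quiet)
  net@dropped[["filtered"]] <- filtered
  validObject(net)
  net
}

.checkKnown <- function(net, ids) {
  unknown <- setdiff(ids, proteins(net))
  if (length(unknown))
    stop("unknown protein(s): ", paste(head(unknown, 5L), collapse = ", "))
}

#' Protein degree (connectivity)
#'
#' Number of distinct interaction partners of each protein.
#'
#' @param net an [InteractionNetwork-class].
#' @param ids protein identifiers; default all proteins in the network.
#' @return named integer vector of degrees.
#' @examples
#' net <- interactionNetwork(data.frame(a = c("A", "A"), b = c("B", "C")))
#' proteinDegree(net)
#' @export
proteinDegree <- function(net, ids = proteins(net)) {
  stopifnot(is(net, "InteractionNetwork"))
  .checkKnown(net, ids)
  d <- igraph::degree(net@graph, v = ids)
  setNames(as.integer(d), ids)
}

#' Local clustering coefficient
#'
#' For a protein with `v` partners among which `l` pairs interact, the
#' clustering coefficient is `2 l / (v (v - 1))` — the fraction of possible
#' partner pairs that themselves interact.  Proteins with fewer than two
#' partners have no defined coefficient and get `NA`; they are excluded
#' from the sparse/dense classification (see [classifyDensity()]).
#'
#' @inheritParams proteinDegree
#' @return named numeric vector in `[0, 1]`, `NA` where degree < 2.
#' @examples
#' tri <- interactionNetwork(
#'   data.frame(a = c("A", "B", "C"), b = c("B", "C", "A")))
#' clusteringCoefficient(tri)  # all 1
#' @export
clusteringCoefficient <- function(net, ids = proteins(net)) {
  stopifnot(is(net, "InteractionNetwork"))
  .checkKnown(net, ids)
  v <- as.numeric(igraph::degree(net@graph, v = ids))
  # number of interacting neighbour pairs == triangles through the vertex
  l <- as.numeric(igraph::count_triangles(net@graph, vids = ids))
  cc <- ifelse(v < 2, NA_real_, 2 * l / (v * (v - 1)))
  setNames(cc, ids)
}

#' Classify proteins into sparse-part (SP) and dense-part (DP)
#'
#' Thresholds clustering coefficients at a cutoff: proteins at or above the
#' cutoff sit in the dense part (DP) of the network, the rest in the sparse
#' part (SP).  With `cutoff = "mean"` (the default) the cutoff is the
#' arithmetic mean of the defined coefficients, so ties at the cutoff go to
#' DP.  Proteins with missing coefficients (degree < 2) are `unclassified`
#' and excluded from the mean.
#'
#' @param coefficients named numeric vector as returned by
#'   [clusteringCoefficient()]; may contain `NA`.
#' @param cutoff `"mean"` or a numeric threshold.
#' @return data.frame with columns `protein_id`, `clustering_coefficient`,
#'   `density_label` (`"SP"`, `"DP"`, `"unclassified"`); the cutoff used is
#'   stored in `attr(, "cutoff")`.
#' @examples
#' classifyDensity(c(A = 0.2, B = 0.8, C = 1.0))
#' @export
classifyDensity <- function(coefficients, cutoff = "mean") {
  if (is.null(names(coefficients)))
    stop("'coefficients' must be named by protein identifier")
  cut <- .resolveCutoff(coefficients, cutoff, "clustering coefficient")
  label <- ifelse(is.na(coefficients), "unclassified",
                  ifelse(coefficients >= cut, "DP", "SP"))
  out <- data.frame(protein_id = names(coefficients),
                    clustering_coefficient = unname(coefficients),
                    density_label = label,
                    stringsAsFactors = FALSE)
  attr(out, "cutoff") <- cut
  out
}

.resolveCutoff <- function(values, cutoff, what) {
  if (identical(cutoff, "mean")) {
    if (all(is.na(values)))
      stop("cannot take the mean ", what, " cutoff: no defined values")
    mean(values, na.rm = TRUE)
  } else if (is.numeric(cutoff) && length(cutoff) == 1L && is.finite(cutoff)) {
    cutoff
  } else stop("'cutoff' must be \"mean\" or a single finite number")
}
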