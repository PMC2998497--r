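#' Screen ortholog alignment summaries by acceptance thresholds
#'
#' Applies the ortholog acceptance rule to BLAST-style alignment summary
#' records: a pair is accepted when the expectation value is at most
#' `eValueMax`, percent similarity at least `minSimilarity`, percent
#' alignment overlap at least `minOverlap`, and percent gaps strictly below
#' `maxGapPercent`.  A rejected record carries the first failing criterion
#' (checked in that order).
#'
#' @param records data.frame with columns `query_id`, `subject_id`,
#'   `e_value`, `percent_similarity`, `percent_overlap`, `percent_gaps`.
#' @param eValueMax expectation-value ceiling (default `1e-5`).
#' @param minSimilarity minimum percent similarity (default 75).
#' @param minOverlap minimum percent alignment overlap (default 80).
#' @param maxGapPercent strict upper bound on percent gaps (default 3).
#' @return the input with logical `accepted` and character `reject_reason`
#'   (`NA` for accepted rows) columns appended.
#' @examples
#' rec <- data.frame(query_id = "P1", subject_id = "O1", e_value = 1e-6,
#'                   percent_similarity = 80, percent_overlap = 85,
#'                   percent_gaps = 1)
#' orthologFilter(rec)$accepted
#' @export
orthologFilter <- function(records, eValueMax = 1e-5, minSimilarity = 75,
                           minOverlap = 80, maxGapPercent = 3) {
  needed <- c("e_value", "percent_similarity", "percent_overlap",
              "percent_gaps")
  missing <- setdiff(needed, names(records))
  if (length(missing))
    stop("records lack column(s): ", paste(missing, collapse = ", "))
  pct <- as.matrix(records[needed[-1L]])
  if (any(pct < 0 | pct > 100, na.rm = TRUE))
    stop("percentage fields must lie in [0, 100]")
  if (any(records$e_value < 0, na.rm = TRUE))
    stop("e-values must be non-negative")
  reason <- rep(NA_character_, nrow(records))
  reason[is.na(reason) & records$percent_gaps >= maxGapPercent] <- "gaps"
  reason[records$percent_overlap < minOverlap] <- "overlap"
  reason[records$percent_similarity < minSimilarity] <- "similarity"
  reason[records$e_value > eValueMax] <- "e_value"
  records$accepted <- is.na(reason)
  records$reject_reason <- reason
  records
}

.AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
           "M", "F", "P", "S", "T", "W", "Y", "V")

#' Observed proportion of differing sites (p-distance)
#'
#' Compares two equal-length gapped amino-acid sequences column by column.
#' Columns holding a gap (`-`) in either sequence are excluded; `p` is the
#' fraction of the remaining columns at which the residues differ.
#'
#' @param a,b aligned sequences: character strings or
#'   [Biostrings::AAString] objects of equal length.
#' @return list with elements `p` and `ungapped_columns`.
#' @examples
#' pDistance("ACDEF", "ACDEY")
#' pDistance("AC-EF", "ACDEF")
#' @export
pDistance <- function(a, b) {
  a <- toupper(as.character(a)); b <- toupper(as.character(b))
  ca <- strsplit(a, "", fixed = TRUE)[[1L]]
  cb <- strsplit(b, "", fixed = TRUE)[[1L]]
  if (length(ca) != length(cb))
    stop("aligned sequences must have equal length (",
         length(ca), " vs ", length(cb), ")")
  ok <- c(.AA20, "-")
  if (!all(ca %in% ok) || !all(cb %in% ok))
    stop("sequences may contain only the 20 amino acids and '-'")
  ungapped <- ca != "-" & cb != "-"
  ncols <- sum(ungapped)
  if (ncols == 0L)
    stop("undefined distance: no column free of gaps in both sequences")
  list(p = sum(ca[ungapped] != cb[ungapped]) / ncols,
       ungapped_columns = ncols)
}

# Root of 0.2 p^2 + p - 1 = 0: the saturation boundary of the correction.
.kimuraPMax <- (sqrt(1.8) - 1) / 0.4

#' Kimura-corrected amino-acid distance
#'
#' Corrects the observed difference proportion `p` for multiple hits with
#' Kimura's empirical approximation `d = -ln(1 - p - 0.2 p^2)`.  The
#' correction is defined for `p < (sqrt(1.8) - 1)/0.4 ~ 0.8541`; at or
#' beyond that boundary the pair is saturated and an error is raised so
#' that saturated pairs are excluded (not silently capped) from downstream
#' statistics.
#'
#' @param p numeric vector of observed difference proportions in `[0, 1)`.
#' @return numeric vector of corrected distances (`d >= p`, with equality
#'   only at `p = 0`).
#' @examples
#' kimuraDistance(0.1)
#' @seealso [kimuraInverse()] for the exact inverse map.
#' @export
kimuraDistance <- function(p) {
  if (!is.numeric(p) || any(is.na(p)) || any(p < 0) || any(p >= 1))
    stop("'p' must be numeric in [0, 1)")
  q <- 1 - p - 0.2 * p^2
  if (any(q <= 0))
    stop("saturated distance: p = ",
         format(max(p[q <= 0])), " is at or beyond the domain boundary ",
         format(.kimuraPMax))
  -log(q)
}

#' Difference proportion implied by a Kimura distance
#'
#' Exact inverse of [kimuraDistance()]:
#' `p* = (-1 + sqrt(1 + 0.8 (1 - exp(-d)))) / 0.4`.  Used by the sequence
#' simulator to plant a target corrected distance.
#'
#' @param d numeric vector of non-negative corrected distances.
#' @return numeric vector of difference proportions in `[0, 0.8541)`.
#' @examples
#' kimuraInverse(kimuraDistance(0.25))
#' @export
kimuraInverse <- function(d) {
  if (!is.numeric(d) || any(is.na(d)) || any(d < 0))
    stop("'d' must be numeric and non-negative")
  (-1 + sqrt(1 + 0.8 * (1 - exp(-d)))) / 0.4
}

#' Read consecutive aligned ortholog pairs from FASTA
#'
#' Reads a gapped FASTA file in which records come in pairs: the focal
#' protein followed by its aligned ortholog.
#'
#' @param path path to the aligned FASTA file.
#' @return a [Biostrings::AAStringSet] with an even number of records.
#' @export
readAlignedPairs <- function(path) {
  seqs <- Biostrings::readAAStringSet(path)
  if (length(seqs) %% 2L != 0L)
    stop("aligned pair file '", path, "' holds an odd number of records (",
         length(seqs), ")")
  seqs
}

#' Kimura distances for a batch of aligned ortholog pairs
#'
#' Computes the p-distance and Kimura-corrected distance for each
#' consecutive record pair.  Pairs whose corrected distance is saturated,
#' or that have no gap-free column, are excluded from the result and
#' reported via a message and the `excluded` attribute.
#'
#' @param pairs a [Biostrings::AAStringSet] with two records per pair
#'   (focal protein first), or the path of an aligned FASTA file.
#' @param quiet suppress the exclusion message.
#' @return data.frame with columns `protein_id`, `ortholog_id`,
#'   `p_distance`, `kimura_distance`, `ungapped_columns`; excluded pairs
#'   (with reasons) in `attr(, "excluded")`.
#' @examples
#' seqs <- Biostrings::AAStringSet(c(P1 = "ACDEF", O1 = "ACDEY"))
#' batchDistances(seqs)
#' @export
batchDistances <- function(pairs, quiet = FALSE) {
  if (is.character(pairs) && length(pairs) == 1L)
    pairs <- readAlignedPairs(pairs)
  if (length(pairs) %% 2L != 0L)
    stop("'pairs' must hold an even number of records")
  npair <- length(pairs) %/% 2L
  ids <- sub("\\s.*$", "", names(pairs))
  rows <- vector("list", npair)
  excluded <- list()
  for (k in seq_len(npair)) {
    i <- 2L * k - 1L
    res <- tryCatch({
      pd <- pDistance(pairs[[i]], pairs[[i + 1L]])
      data.frame(protein_id = ids[i], ortholog_id = ids[i + 1L],
                 p_distance = pd$p,
                 kimura_distance = kimuraDistance(pd$p),
                 ungapped_columns = pd$ungapped_columns,
                 stringsAsFactors = FALSE)
    }, error = function(e) {
      excluded[[length(excluded) + 1L]] <<-
        data.frame(protein_id = ids[i], ortholog_id = ids[i + 1L],
                   reason = conditionMessage(e), stringsAsFactors = FALSE)
      NULL
    })
    rows[[k]] <- res
  }
  out <- do.call(rbind, c(rows, list(
    data.frame(protein_id = character(), ortholog_id = character(),
               p_distance = numeric(), kimura_distance = numeric(),
               ungapped_columns = integer(), stringsAsFactors = FALSE))))
  rownames(out) <- NULL
  excluded <- if (length(excluded)) do.call(rbind, excluded) else NULL
  if (!quiet && !is.null(excluded))
    message("batchDistances: excluded ", nrow(excluded),
            " pair(s) (saturated or gap-only)")
  attr(out, "excluded") <- excluded
  out
}
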