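# A ten-protein study small enough that every feature was computed by
# hand.  The expected values frozen here come from direct counting on the
# drawn graph and from the Kimura closed form evaluated at the hand-counted
# difference proportions (high-precision reference values).

KIMURA_P01 <- 0.1075852106799374   # -ln(1 - 0.1 - 0.2*0.01)
KIMURA_P02 <- 0.2331938871677111
KIMURA_P03 <- 0.3827256211386750
KIMURA_P05 <- 0.7985076962177716

tenProteinFixture <- function(dir = tempfile("fixture")) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(dir, f)

  writeLines(c("A\tB", "A\tC", "B\tC", "A\tD", "D\tE", "E\tF", "E\tG",
               "F\tG", "C\tH", "H\tI", "I\tJ"), p("edges.tsv"))
  writeLines(c("A\tTranscription", "B\tTranscription", "C\tTranscription",
               "C\tEnergy", "D\tEnergy", "E\tEnergy", "F\tMetabolism",
               "G\tEnergy", "G\tMetabolism", "H\tEnergy",
               "J\tMetabolism"), p("annotations.tsv"))
  writeLines(c("C1\tA", "C1\tB", "C1\tC", "C2\tE", "C2\tF", "C2\tG",
               "C3\tA", "C3\tE"), p("complexes.tsv"))
  writeLines(c("A\t5.0", "B\t4.0", "C\t3.5", "D\t1.0", "E\t2.8", "F\t2.0",
               "G\t1.5", "H\t0.8", "I\t0.6", "J\t0.4"), p("expression.tsv"))

  base <- "ACDEFGHIKL"
  pairs <- c(
    A = base,          A_orth = base,                 # p = 0
    B = base,          B_orth = "ACDEFGHIKV",         # p = 0.1
    C = "AC-DEFGHIKL", C_orth = "ACWDEFGHIKV",        # gap col; p = 0.1 of 10
    D = base,          D_orth = "ACDEFGHIVV",         # p = 0.2
    E = base,          E_orth = base,                 # p = 0
    F = base,          F_orth = "ACDEFMNPQR",         # p = 0.5
    G = base,          G_orth = "ACDEFGHMNP",         # p = 0.3
    H = base,          H_orth = "ACDEFGHIKV",         # p = 0.1
    I = base,          I_orth = "CDEFGHIKLL",         # p = 0.9: saturated
    J = base,          J_orth = "ACDEFGHIKV")         # p = 0.1
  writeLines(paste0(">", names(pairs), "\n", pairs), p("alignments.fasta"))

  expected <- data.frame(
    protein_id = LETTERS[1:10],
    degree = c(3L, 2L, 3L, 2L, 3L, 2L, 2L, 2L, 2L, 1L),
    clustering_coefficient = c(1/3, 1, 1/3, 0, 1/3, 1, 1, 0, 0, NA),
    density_label = c("SP", "DP", "SP", "SP", "SP", "DP", "DP", "SP",
                      "SP", "unclassified"),
    functionality_coefficient = c(2/3, 1, 2/3, 1/2, 2/3, 1/2, 1/2, 1/2,
                                  NA, 0),
    assigned_class = c("Transcription", "Transcription", "Transcription",
                       "Energy", "Energy", "Metabolism", "Energy",
                       "Energy", NA, "Metabolism"),
    m = c(3L, 2L, 3L, 2L, 3L, 2L, 2L, 2L, 2L, 1L),
    n = c(2L, 2L, 2L, 1L, 2L, 1L, 1L, 1L, NA, 0L),
    functionality_label = c("SF", "SF", "SF", "DF", "SF", "DF", "DF",
                            "DF", "unclassified", "DF"),
    complex_number = c(2L, 1L, 1L, 0L, 2L, 1L, 1L, 0L, 0L, 0L),
    complex_forming = c(TRUE, TRUE, TRUE, FALSE, TRUE, TRUE, TRUE, FALSE,
                        FALSE, FALSE),
    expression = c(5, 4, 3.5, 1, 2.8, 2, 1.5, 0.8, 0.6, 0.4),
    kimura_distance = c(0, KIMURA_P01, KIMURA_P01, KIMURA_P02, 0,
                        KIMURA_P05, KIMURA_P03, KIMURA_P01, NA,
                        KIMURA_P01),
    stringsAsFactors = FALSE)

  list(dir = dir,
       paths = c(edges = p("edges.tsv"), annotations = p("annotations.tsv"),
                 complexes = p("complexes.tsv"),
                 expression = p("expression.tsv"),
                 alignments = p("alignments.fasta")),
       expected = expected,
       densityCutoff = 4 / 9,        # mean of the nine defined coefficients
       functionalityCutoff = 5 / 9)  # mean of the nine defined coefficients
}
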