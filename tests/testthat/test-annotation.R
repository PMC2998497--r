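test_that("annotation files parse into class sets with validation", {
  f <- withr::local_tempfile()
  writeLines(c("A\tTranscription", "A\tEnergy", "B\tEnergy",
               "B\tEnergy"), f)
  ann <- readAnnotations(f)
  expect_setequal(annotationClasses(ann, "A")$A,
                  c("Transcription", "Energy"))
  expect_equal(annotationClasses(ann, "B")$B, "Energy")  # duplicate row

  bad <- withr::local_tempfile()
  writeLines(c("A\tEnergy", "B\tNotAClass"), bad)
  expect_error(readAnnotations(bad), "NotAClass.*line 2")

  empty <- withr::local_tempfile()
  writeLines(character(), empty)
  expect_length(proteins(readAnnotations(empty)), 0)

  expect_length(mipsClasses(), 17L)
})

test_that("functionality coefficient follows the n/m largest-value rule", {
  # 4 partners, 3 sharing the sole class -> 3/4
  net <- interactionNetwork(data.frame(a = rep("p", 4),
                                       b = c("q", "r", "s", "t")))
  ann <- functionalAnnotation(list(p = "Transcription",
                                   q = "Transcription",
                                   r = "Transcription",
                                   s = "Transcription", t = "Energy"))
  res <- functionalityCoefficient(net, ann, "p")
  expect_equal(res$functionality_coefficient, 0.75)
  expect_equal(res$m, 4L)
  expect_equal(res$n, 3L)

  # two own classes: 2/5 vs 3/5 -> the larger wins and names the class
  net2 <- interactionNetwork(data.frame(a = rep("p", 5),
                                        b = paste0("q", 1:5)))
  ann2 <- functionalAnnotation(list(
    p = c("Metabolism", "Energy"),
    q1 = "Metabolism", q2 = "Metabolism",
    q3 = "Energy", q4 = "Energy", q5 = "Energy"))
  res2 <- functionalityCoefficient(net2, ann2, "p")
  expect_equal(res2$functionality_coefficient, 0.6)
  expect_equal(res2$assigned_class, "Energy")

  # single partner sharing the sole class -> 1
  net3 <- interactionNetwork(data.frame(a = "p", b = "q"))
  ann3 <- functionalAnnotation(list(p = "Energy", q = "Energy"))
  expect_equal(functionalityCoefficient(net3, ann3,
                                        "p")$functionality_coefficient, 1)

  # tie between classes breaks to the lexicographically smallest
  ann4 <- functionalAnnotation(list(p = c("Metabolism", "Energy"),
                                    q1 = "Metabolism", q2 = "Energy",
                                    q3 = "Transcription"))
  net4 <- interactionNetwork(data.frame(a = rep("p", 3),
                                        b = paste0("q", 1:3)))
  expect_equal(functionalityCoefficient(net4, ann4, "p")$assigned_class,
               "Energy")
})

test_that("unannotated partners count toward m but never n (switchable)", {
  net <- interactionNetwork(data.frame(a = rep("p", 4),
                                       b = c("q", "r", "s", "t")))
  ann <- functionalAnnotation(list(p = "Energy", q = "Energy",
                                   r = "Energy"))  # s, t unannotated
  full <- functionalityCoefficient(net, ann, "p", partnerCount = "all")
  expect_equal(full$m, 4L)
  expect_equal(full$functionality_coefficient, 0.5)
  annOnly <- functionalityCoefficient(net, ann, "p",
                                      partnerCount = "annotated")
  expect_equal(annOnly$m, 2L)
  expect_equal(annOnly$functionality_coefficient, 1)

  # unannotated protein and partnerless protein -> missing coefficient
  net2 <- interactionNetwork(data.frame(a = "x", b = "y"),
                             extraProteins = "z")
  ann2 <- functionalAnnotation(list(z = "Energy"))
  res <- functionalityCoefficient(net2, ann2)
  expect_true(is.na(res$functionality_coefficient[res$protein_id == "x"]))
  expect_true(is.na(res$functionality_coefficient[res$protein_id == "z"]))
})

test_that("coefficient is invariant under class relabelling and monotone in partners", {
  set.seed(3)
  vocabA <- mipsClasses()
  vocabB <- sample(vocabA)  # a permutation used as the relabelling map
  ed <- randomEdgeTable(20, 0.25)
  net <- interactionNetwork(ed, quiet = TRUE)
  ids <- proteins(net)
  classesA <- setNames(lapply(ids, function(i)
    sample(vocabA, sample(1:2, 1))), ids)
  relabel <- setNames(vocabB, vocabA)
  classesB <- lapply(classesA, function(cl) unname(relabel[cl]))
  resA <- functionalityCoefficient(net, functionalAnnotation(classesA))
  resB <- functionalityCoefficient(net, functionalAnnotation(classesB))
  expect_equal(resA$functionality_coefficient,
               resB$functionality_coefficient)

  # adding a same-class partner cannot decrease n/m for a single-class
  # protein; adding a no-shared-class partner cannot increase it
  base <- data.frame(a = rep("p", 3), b = c("q1", "q2", "q3"))
  ann <- functionalAnnotation(list(p = "Energy", q1 = "Energy",
                                   q2 = "Transcription", q3 = "Energy",
                                   plus = "Energy", minus = "Cell fate"))
  f0 <- functionalityCoefficient(
    interactionNetwork(base), ann, "p")$functionality_coefficient
  fPlus <- functionalityCoefficient(
    interactionNetwork(rbind(base, data.frame(a = "p", b = "plus"))),
    ann, "p")$functionality_coefficient
  fMinus <- functionalityCoefficient(
    interactionNetwork(rbind(base, data.frame(a = "p", b = "minus"))),
    ann, "p")$functionality_coefficient
  expect_gte(fPlus, f0)
  expect_lte(fMinus, f0)
})

test_that("SF/DF classification partitions defined coefficients at >= mean", {
  res <- classifyFunctionality(c(a = 1, b = 0.5, c = 0))
  expect_equal(attr(res, "cutoff"), 0.5)
  expect_equal(res$functionality_label, c("SF", "SF", "DF"))

  atCut <- classifyFunctionality(c(a = 0.4, b = 0.8), cutoff = 0.8)
  expect_equal(atCut$functionality_label, c("DF", "SF"))

  withNA <- classifyFunctionality(c(a = 0.2, b = NA))
  expect_equal(withNA$functionality_label, c("SF", "unclassified"))
  expect_error(classifyFunctionality(c(a = NA_real_)), "no defined values")
})
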