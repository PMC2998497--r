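test_that("edge-list normalisation drops self-loops and collapses duplicates", {
  f <- withr::local_tempfile()
  writeLines(c("A\tB", "B\tA", "A\tA", "A\tB"), f)
  net <- suppressMessages(readEdgeList(f))
  expect_setequal(proteins(net), c("A", "B"))
  expect_equal(igraph::ecount(net@graph), 1)
  d <- droppedCounts(net)
  expect_equal(unname(d[c("rows_read", "self_loops", "duplicates")]),
               c(4L, 1L, 2L))

  empty <- withr::local_tempfile()
  writeLines(character(), empty)
  net0 <- readEdgeList(empty)
  expect_length(proteins(net0), 0)

  tri <- withr::local_tempfile()
  writeLines(c("id_a\tid_b", "A\tB", "B\tC", "C\tA"), tri)
  net3 <- readEdgeList(tri)
  expect_length(proteins(net3), 3)
  expect_equal(igraph::ecount(net3@graph), 3)
})

test_that("malformed rows, mitab identifiers and id filters are handled", {
  bad <- withr::local_tempfile()
  writeLines(c("A\tB", "loneField"), bad)
  expect_error(readEdgeList(bad), "line 2")

  mitab <- withr::local_tempfile()
  writeLines(c("uniprotkb:P1|dip:DIP-1\tuniprotkb:P2\ttaxid:4932\tscore:0.9",
               "uniprotkb:P2\tuniprotkb:P3\tx\ty"), mitab)
  net <- readEdgeList(mitab, dialect = "mitab")
  expect_setequal(proteins(net), c("P1", "P2", "P3"))

  mixed <- withr::local_tempfile()
  writeLines(c("SC_A\tSC_B", "SC_A\tSP_X"), mixed)
  net2 <- readEdgeList(mixed, idFilter = "^SC_")
  expect_setequal(proteins(net2), c("SC_A", "SC_B"))
  expect_equal(unname(droppedCounts(net2)["filtered"]), 1L)
})

test_that("degree obeys the handshake lemma and rejects unknown proteins", {
  set.seed(11)
  for (rep in 1:5) {
    ed <- randomEdgeTable(25, 0.15)
    net <- interactionNetwork(ed, quiet = TRUE)
    expect_equal(sum(proteinDegree(net)), 2L * nrow(unique(ed)))
  }
  star <- interactionNetwork(data.frame(a = rep("hub", 5),
                                        b = paste0("leaf", 1:5)))
  expect_equal(unname(proteinDegree(star, "hub")), 5L)
  iso <- interactionNetwork(data.frame(a = "A", b = "B"),
                            extraProteins = "Z")
  expect_equal(unname(proteinDegree(iso, "Z")), 0L)
  expect_error(proteinDegree(star, "nope"), "unknown protein")
  expect_error(clusteringCoefficient(star, "nope"), "unknown protein")
})

test_that("clustering coefficient matches brute-force neighbour-pair enumeration", {
  set.seed(42)
  for (rep in 1:20) {
    ed <- randomEdgeTable(30, 0.2)
    net <- interactionNetwork(ed, quiet = TRUE)
    ids <- proteins(net)
    got <- clusteringCoefficient(net, ids)
    want <- vapply(ids, function(p) bruteClustering(ed, p), 0)
    expect_identical(got, want)
    defined <- got[!is.na(got)]
    expect_true(all(defined >= 0 & defined <= 1))
  }
})

test_that("clustering coefficient hits its boundary values", {
  # clique neighbourhood -> 1; star centre -> 0; half-connected -> 1/3
  k4 <- interactionNetwork(data.frame(
    a = c("p", "p", "p", "x", "x", "y"),
    b = c("x", "y", "z", "y", "z", "z")))
  expect_equal(unname(clusteringCoefficient(k4, "p")), 1)
  star <- interactionNetwork(data.frame(a = rep("hub", 5),
                                        b = paste0("l", 1:5)))
  expect_equal(unname(clusteringCoefficient(star, "hub")), 0)
  half <- interactionNetwork(data.frame(
    a = c("p", "p", "p", "p", "a", "c"),
    b = c("a", "b", "c", "d", "b", "d")))
  expect_equal(unname(clusteringCoefficient(half, "p")), 1 / 3)
  # degree < 2 -> missing
  path2 <- interactionNetwork(data.frame(a = "A", b = "B"),
                              extraProteins = "Z")
  expect_true(all(is.na(clusteringCoefficient(path2))))
})

test_that("density classification uses the >= mean rule and skips missing", {
  lab <- classifyDensity(c(p1 = 0.2, p2 = 0.8, p3 = 1.0))
  expect_equal(attr(lab, "cutoff"), 2 / 3)
  expect_equal(lab$density_label, c("SP", "DP", "DP"))

  tied <- classifyDensity(c(a = 0.5, b = 0.5, c = 0.5))
  expect_true(all(tied$density_label == "DP"))

  withNA <- classifyDensity(c(a = 0.4, b = NA, c = 0.8))
  expect_equal(attr(withNA, "cutoff"), 0.6)  # NA excluded from the mean
  expect_equal(withNA$density_label[2], "unclassified")

  expect_error(classifyDensity(c(a = NA_real_)), "no defined values")
})

test_that("moving the cutoff relabels proteins monotonically", {
  set.seed(7)
  cc <- setNames(runif(40), paste0("p", 1:40))
  cuts <- sort(runif(8, min(cc), max(cc)))
  prevDP <- NULL
  for (ct in rev(cuts)) {  # decreasing cutoff: DP set can only grow
    dp <- with(classifyDensity(cc, ct), protein_id[density_label == "DP"])
    if (!is.null(prevDP)) expect_true(all(prevDP %in% dp))
    prevDP <- dp
  }
})
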