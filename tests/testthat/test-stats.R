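test_that("Spearman rho matches the rank-then-Pearson route and rank invariance", {
  expect_equal(spearmanCor(c(1, 2, 3), c(3, 2, 1))$rho, -1)
  set.seed(21)
  x <- rnorm(100); y <- rnorm(100)
  got <- spearmanCor(x, y)
  # independent route: the classical 1 - 6*sum(d^2)/(n(n^2-1)) formula
  d2 <- sum((rank(x) - rank(y))^2)
  expect_equal(got$rho, 1 - 6 * d2 / (100 * (100^2 - 1)),
               tolerance = 1e-12)
  # invariance under strictly increasing transforms
  expect_equal(spearmanCor(exp(x), y)$rho, got$rho)
  expect_equal(spearmanCor(x, qnorm(pnorm(y)))$rho, got$rho)
  expect_error(spearmanCor(rep(1, 10), rnorm(10)), "constant")
  expect_error(spearmanCor(1:2, 2:1), "at least 3")
})

test_that("Spearman p-values: exact enumeration small-n, t transform large-n", {
  set.seed(8)
  for (rep in 1:5) {
    x <- sample(100, 6); y <- sample(100, 6)
    got <- spearmanCor(x, y)
    expect_equal(got$method, "exact permutation")
    expect_equal(got$p_value, enumSpearmanP(x, y), tolerance = 1e-12)
    # cross-check against the independent exact tail in stats::cor.test
    expect_equal(got$p_value,
                 cor.test(x, y, method = "spearman",
                          exact = TRUE)$p.value, tolerance = 1e-10)
  }
  x <- rnorm(50); y <- rnorm(50)
  got <- spearmanCor(x, y)
  expect_equal(got$method, "t approximation")
  expect_equal(got$p_value,
               cor.test(x, y, method = "spearman",
                        exact = FALSE)$p.value, tolerance = 1e-10)
  expect_equal(spearmanCor(x, y, pFloor = 0.9)$p_value, 0.9)
})

test_that("partial Spearman: the two routes agree and reduce correctly", {
  set.seed(13)
  for (rep in 1:10) {
    n <- 60
    z1 <- rnorm(n); z2 <- rnorm(n)
    x <- z1 + rnorm(n); y <- -z1 + 0.5 * z2 + rnorm(n)
    inv <- partialSpearman(x, y, cbind(z1, z2), method = "inversion")
    res <- partialSpearman(x, y, cbind(z1, z2),
                           method = "residualization")
    expect_equal(inv$rho, res$rho, tolerance = 1e-10)
    expect_equal(inv$df, n - 4L)
    # single control matches the recursion formula on measured rank
    # correlations
    r <- cor(cbind(rank(x), rank(y), rank(z1)))
    expect_equal(partialSpearman(x, y, z1)$rho,
                 partialRecursion(r[1, 2], r[1, 3], r[2, 3]),
                 tolerance = 1e-12)
  }
  # an empty control set degrades to the plain Spearman correlation
  set.seed(14)
  x <- rnorm(30); y <- rnorm(30)
  expect_equal(partialSpearman(x, y, matrix(numeric(0), 30, 0))$rho,
               spearmanCor(x, y)$rho)
  # controlling y by itself is degenerate
  expect_error(partialSpearman(x, y, y), "degenerate")
})

test_that("multivariate regression recovers exact fits and known identities", {
  set.seed(17)
  X <- data.frame(a = rnorm(40), b = rnorm(40))
  yExact <- 2 * X$a - 3 * X$b
  fit <- suppressWarnings(  # summary.lm flags the perfect fit
    multivariateRegression(yExact, X, standardize = FALSE))
  expect_equal(attr(fit, "r_squared"), 1, tolerance = 1e-12)
  expect_equal(fit$estimate[fit$term == "a"], 2, tolerance = 1e-10)
  expect_equal(fit$estimate[fit$term == "b"], -3, tolerance = 1e-10)

  # single predictor: squared t equals the F statistic of the model
  y <- X$a + rnorm(40)
  one <- multivariateRegression(y, X["a"])
  f <- summary(lm(scale(y) ~ scale(X$a)))$fstatistic[["value"]]
  expect_equal(one$t_value[one$term == "a"]^2, f, tolerance = 1e-10)

  # collinear designs are refused rather than silently dropped
  X2 <- data.frame(a = X$a, b = 2 * X$a)
  expect_error(multivariateRegression(y, X2), "collinear")
  expect_error(multivariateRegression(y, data.frame(a = rep(1, 40))),
               "constant")
})

test_that("correlation-matrix PCA matches an independent SVD route", {
  set.seed(19)
  X <- matrix(rnorm(600), 200, 3,
              dimnames = list(NULL, c("u", "v", "w")))
  X[, 2] <- X[, 1] * 0.5 + X[, 2]
  got <- pcaDeterminants(X)
  expect_equal(sum(got$eigenvalues), 3, tolerance = 1e-10)
  ref <- prcomp(X, center = TRUE, scale. = TRUE)  # SVD, not eigen
  expect_equal(got$eigenvalues, ref$sdev^2, tolerance = 1e-10)
  for (j in 1:3)
    expect_equal(abs(got$loadings[, j]), abs(ref$rotation[, j]),
                 tolerance = 1e-8)
  # sign orientation: largest-magnitude loading positive
  for (j in 1:3)
    expect_gt(got$loadings[which.max(abs(got$loadings[, j])), j], 0)
  # correlation matrix reconstruction from all components is exact
  R <- got$loadings %*% diag(got$eigenvalues) %*% t(got$loadings)
  expect_equal(R, cor(X), tolerance = 1e-10,
               ignore_attr = TRUE)
  # two perfectly correlated variables -> eigenvalues {2, 0}
  Y <- cbind(a = X[, 1], b = 2 * X[, 1] + 3)
  expect_equal(pcaDeterminants(Y)$eigenvalues, c(2, 0),
               tolerance = 1e-10)
  expect_error(pcaDeterminants(cbind(X, k = 1)), "constant")
})

test_that("Mann-Whitney matches exact enumeration and permutation", {
  got <- mannWhitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(got$U, 0)
  expect_equal(got$p_value, 0.1)
  expect_equal(got$method, "exact")
  set.seed(23)
  for (rep in 1:8) {
    a <- sample(1000, sample(3:5, 1)); b <- sample(2000, sample(3:6, 1))
    while (anyDuplicated(c(a, b))) b <- sample(2000, length(b))
    expect_equal(mannWhitney(a, b)$p_value, enumMannWhitneyP(a, b),
                 tolerance = 1e-12)
  }
  # identical samples: two-sided p == 1 up to the approximation
  a <- rep(1:5, 4)
  expect_gt(mannWhitney(a, a)$p_value, 0.95)
  # large tie-free samples: normal approximation vs permutation
  x <- rnorm(40); y <- rnorm(45, mean = 0.5)
  approx <- mannWhitney(x, y)
  expect_equal(approx$method, "normal approximation")
  pooled <- c(x, y)
  uPerm <- replicate(10000, {
    idx <- sample(85, 40)
    sum(rank(pooled)[idx]) - 40 * 41 / 2
  })
  pPerm <- min(1, 2 * min(mean(uPerm <= approx$U), mean(uPerm >= approx$U)))
  expect_lt(abs(approx$p_value - pPerm), 0.02)
  expect_error(mannWhitney(numeric(), 1:3), "non-empty")
})

test_that("Fisher exact two-sided p sums hypergeometric probabilities", {
  expect_equal(fisherExact(matrix(c(2, 0, 0, 2), 2)), 1 / 3,
               tolerance = 1e-12)
  expect_equal(fisherExact(matrix(1, 2, 2)), 1)
  set.seed(29)
  for (rep in 1:25) {
    tab <- matrix(rpois(4, 3), 2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    expect_equal(fisherExact(tab), enumFisherP(tab), tolerance = 1e-12)
  }
  expect_error(fisherExact(matrix(c(0, 0, 1, 2), 2)), "margins")
  expect_error(fisherExact(matrix(c(1.5, 1, 1, 1), 2)), "integers")
})
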