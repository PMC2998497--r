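# Statistical machinery of the inference chain: Spearman and partial
# Spearman correlation, OLS regression, correlation-matrix PCA,
# Mann-Whitney U and Fisher's exact test.

.completePairs <- function(...) {
  m <- cbind(...)
  m[complete.cases(m), , drop = FALSE]
}

# all permutations of 1..n as an (n! x n) matrix; used for exact Spearman p
.allPerms <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- .allPerms(n - 1L)
  out <- matrix(0L, nrow(sub) * n, n)
  r <- 0L
  for (k in seq_len(n)) {
    rows <- seq_len(nrow(sub)) + r
    out[rows, 1L] <- k
    out[rows, -1L] <- ifelse(sub >= k, sub + 1L, sub)
    r <- r + nrow(sub)
  }
  out
}

#' Spearman rank correlation
#'
#' Rank correlation from average-ranked data (ties receive average ranks).
#' The two-sided p-value comes from exact enumeration of the permutation
#' null when `n <= 7` and the data are tie-free, and otherwise from the
#' t transform of rho with `n - 2` degrees of freedom.
#'
#' @param x,y numeric vectors of equal length; incomplete pairs are
#'   dropped.
#' @param pFloor optional lower display floor for the p-value (e.g.
#'   `1e-6`); `NULL` (default) reports the computed value.
#' @return list with `rho`, `p_value`, `n` and `method`.
#' @examples
#' spearmanCor(1:10, c(2, 1, 4, 3, 6, 5, 8, 7, 10, 9))
#' @export
spearmanCor <- function(x, y, pFloor = NULL) {
  m <- .completePairs(x = x, y = y)
  n <- nrow(m)
  if (n < 3L) stop("need at least 3 complete observation pairs")
  if (sd(m[, 1L]) == 0 || sd(m[, 2L]) == 0)
    stop("undefined correlation: constant input vector")
  rx <- rank(m[, 1L]); ry <- rank(m[, 2L])
  rho <- cor(rx, ry)
  ties <- anyDuplicated(rx) > 0L || anyDuplicated(ry) > 0L
  if (n <= 7L && !ties) {
    perms <- .allPerms(n)
    rhoNull <- apply(perms, 1L, function(pm) cor(rx, ry[pm]))
    p <- mean(abs(rhoNull) >= abs(rho) - 1e-12)
    method <- "exact permutation"
  } else {
    tstat <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
    p <- 2 * pt(-abs(tstat), df = n - 2)
    p <- min(max(p, .Machine$double.xmin), 1)
    method <- "t approximation"
  }
  if (!is.null(pFloor)) p <- max(p, pFloor)
  list(rho = rho, p_value = p, n = n, method = method)
}

.rankMatrix <- function(m) apply(m, 2L, rank)

#' Partial Spearman correlation
#'
#' Correlation between `x` and `y` after removing the rank-linear effect of
#' one or more control variables: all vectors are rank-transformed, then a
#' partial Pearson correlation of the ranks is taken given the control
#' ranks.  Two algebraically equivalent routes are provided — inversion of
#' the joint correlation matrix (default) and double residualization via
#' least squares — which agree to numerical precision.  The two-sided
#' p-value uses the t transform with `n - 2 - k` degrees of freedom for
#' `k` controls.
#'
#' @param x,y numeric vectors.
#' @param controls control variables: a numeric vector, matrix, data.frame
#'   or list of vectors.  An empty control set reduces to [spearmanCor()].
#' @param method `"inversion"` or `"residualization"`.
#' @param rankFirst rank-transform the inputs first (default `TRUE`, the
#'   partial Spearman); `FALSE` gives the partial Pearson correlation.
#' @param pFloor optional lower display floor for the p-value.
#' @return list with `rho`, `p_value`, `n`, `df` and `method`.
#' @examples
#' set.seed(1)
#' z <- rnorm(50); x <- z + rnorm(50); y <- -z + rnorm(50)
#' partialSpearman(x, y, z)$rho
#' @export
partialSpearman <- function(x, y, controls,
                            method = c("inversion", "residualization"),
                            rankFirst = TRUE, pFloor = NULL) {
  method <- match.arg(method)
  if (is.list(controls) && !is.data.frame(controls))
    controls <- do.call(cbind, controls)
  controls <- as.matrix(controls)
  if (ncol(controls) == 0L) return(spearmanCor(x, y, pFloor = pFloor))
  k <- ncol(controls)
  m <- .completePairs(x = x, y = y, controls)
  n <- nrow(m)
  if (n < k + 3L) stop("need at least ", k + 3L, " complete observations")
  if (any(apply(m, 2L, sd) == 0))
    stop("degenerate input: constant variable")
  rm_ <- if (rankFirst) .rankMatrix(m) else m
  if (method == "inversion") {
    R <- cor(rm_)
    P <- tryCatch(solve(R), error = function(e)
      stop("degenerate control correlation structure: ",
           conditionMessage(e)))
    pr <- -P[1L, 2L] / sqrt(P[1L, 1L] * P[2L, 2L])
  } else {
    Z <- cbind(1, rm_[, -(1:2), drop = FALSE])
    rx <- stats::lm.fit(Z, rm_[, 1L])$residuals
    ry <- stats::lm.fit(Z, rm_[, 2L])$residuals
    if (sd(rx) == 0 || sd(ry) == 0)
      stop("degenerate control correlation structure: ",
           "a variable is fully explained by the controls")
    pr <- cor(rx, ry)
  }
  if (!is.finite(pr))
    stop("degenerate control correlation structure")
  df <- n - 2L - k
  tstat <- pr * sqrt(df / max(1 - pr^2, .Machine$double.eps))
  p <- min(max(2 * pt(-abs(tstat), df = df), .Machine$double.xmin), 1)
  if (!is.null(pFloor)) p <- max(p, pFloor)
  list(rho = pr, p_value = p, n = n, df = df, method = method)
}

#' Multivariate ordinary least-squares regression
#'
#' Regresses a response on several predictors jointly and reports a
#' per-predictor coefficient table with two-sided t-test p-values, used to
#' ask whether each factor retains an independent effect on evolutionary
#' rate once the others are held in the model.  By default all variables
#' are z-standardized so coefficients are comparable across scales; the
#' p-values are unaffected by standardization.
#'
#' @param response numeric vector.
#' @param predictors named data.frame (or matrix) of numeric predictors.
#' @param standardize z-score response and predictors first (default
#'   `TRUE`).
#' @return data.frame with columns `term`, `estimate`, `std_error`,
#'   `t_value`, `p_value` (intercept row first); attributes `n`,
#'   `r_squared`, `adj_r_squared`.
#' @examples
#' set.seed(1)
#' d <- data.frame(a = rnorm(50), b = rnorm(50))
#' multivariateRegression(d$a + rnorm(50), d)
#' @export
multivariateRegression <- function(response, predictors,
                                   standardize = TRUE) {
  predictors <- as.data.frame(predictors)
  if (is.null(names(predictors)) || any(!nzchar(names(predictors))))
    stop("'predictors' must be named")
  m <- cbind(.response = response, predictors)
  m <- m[complete.cases(m), , drop = FALSE]
  n <- nrow(m)
  if (n <= ncol(predictors) + 1L)
    stop("need more observations than predictors plus one")
  if (any(vapply(m, sd, 1) == 0))
    stop("constant variable in the regression")
  if (standardize) m[] <- lapply(m, function(v) as.numeric(scale(v)))
  fit <- lm(.response ~ ., data = m)
  if (any(is.na(coef(fit))))
    stop("rank-deficient design: predictors are exactly collinear")
  s <- summary(fit)
  tab <- s$coefficients
  out <- data.frame(term = rownames(tab), estimate = tab[, 1L],
                    std_error = tab[, 2L], t_value = tab[, 3L],
                    p_value = tab[, 4L], stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "n") <- n
  attr(out, "r_squared") <- s$r.squared
  attr(out, "adj_r_squared") <- s$adj.r.squared
  out
}

#' Principal component analysis of evolutionary-rate covariates
#'
#' PCA on the correlation matrix (i.e. of z-scored columns) of a feature
#' matrix, as appropriate when the variables — complex number, expression
#' level, degree — live on very different scales.  Components with
#' eigenvalue at or above `retainAt` (default 1, the Kaiser rule) are
#' flagged as retained.  Each component is sign-oriented so that its
#' largest-magnitude loading is positive, making downstream correlations
#' of PC scores deterministic.
#'
#' @param features numeric matrix or data.frame (proteins x variables);
#'   incomplete rows are dropped.
#' @param retainAt eigenvalue retention threshold (default 1).
#' @return list with `eigenvalues` (descending), `loadings` (variables x
#'   components, orthonormal), `retained` (logical), `variance_fraction`,
#'   `scores` (complete rows x components) and `n`.
#' @examples
#' set.seed(1)
#' pcaDeterminants(matrix(rnorm(300), 100, 3))$eigenvalues
#' @export
pcaDeterminants <- function(features, retainAt = 1) {
  features <- as.matrix(features)
  features <- features[complete.cases(features), , drop = FALSE]
  n <- nrow(features)
  if (n < 3L) stop("need at least 3 complete rows")
  if (ncol(features) < 2L) stop("need at least 2 variables")
  if (any(apply(features, 2L, sd) == 0))
    stop("degenerate input: constant column")
  R <- cor(features)
  e <- eigen(R, symmetric = TRUE)
  load <- e$vectors
  for (j in seq_len(ncol(load))) {
    i <- which.max(abs(load[, j]))
    if (load[i, j] < 0) load[, j] <- -load[, j]
  }
  dimnames(load) <- list(colnames(features),
                         paste0("PC", seq_len(ncol(load))))
  scores <- scale(features) %*% load
  list(eigenvalues = e$values, loadings = load,
       retained = e$values >= retainAt,
       variance_fraction = e$values / ncol(features),
       scores = scores, n = n)
}

#' Mann-Whitney U comparison of two groups
#'
#' Two-sided Mann-Whitney (Wilcoxon rank-sum) test with the U statistic
#' counted for the first group.  The p-value is computed by exact
#' enumeration when the pooled sample size is at most 12 and tie-free, and
#' by the tie-corrected normal approximation (with continuity correction)
#' otherwise.  Group means are reported alongside, as in tables comparing
#' average rates/expression/connectivity between protein groups.
#'
#' @param a,b numeric vectors (NAs dropped); both must be non-empty.
#' @return list with `U`, `p_value`, `n1`, `n2`, `mean1`, `mean2`,
#'   `method`.
#' @examples
#' mannWhitney(c(1, 2, 3), c(4, 5, 6))
#' @export
mannWhitney <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (!length(a) || !length(b)) stop("both groups must be non-empty")
  ties <- anyDuplicated(c(a, b)) > 0L
  exact <- (length(a) + length(b)) <= 12L && !ties
  w <- suppressWarnings(wilcox.test(a, b, exact = exact, correct = TRUE))
  list(U = unname(w$statistic), p_value = w$p.value,
       n1 = length(a), n2 = length(b),
       mean1 = mean(a), mean2 = mean(b),
       method = if (exact) "exact" else "normal approximation")
}

#' Two-sided Fisher exact test for a 2 x 2 table
#'
#' Sum of hypergeometric probabilities of all tables with the observed
#' margins whose probability does not exceed that of the observed table.
#'
#' @param tab 2 x 2 matrix of non-negative integer counts with positive
#'   margins.
#' @return two-sided p-value.
#' @examples
#' fisherExact(matrix(c(2, 0, 0, 2), 2))
#' @export
fisherExact <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == 2L)) stop("'tab' must be a 2 x 2 table")
  if (any(tab < 0) || any(tab != round(tab)))
    stop("counts must be non-negative integers")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("all margins must be positive")
  fisher.test(tab)$p.value
}
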