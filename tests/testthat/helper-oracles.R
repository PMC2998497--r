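# Independent brute-force oracles used to validate the implementation
# routes.  These deliberately share no code with the package internals.

# clustering coefficient by direct enumeration of neighbour pairs
bruteClustering <- function(edgeDf, id) {
  key <- function(u, v) paste(pmin(u, v), pmax(u, v))
  edgeKeys <- unique(key(edgeDf[[1]], edgeDf[[2]]))
  nb <- unique(c(edgeDf[[2]][edgeDf[[1]] == id],
                 edgeDf[[1]][edgeDf[[2]] == id]))
  nb <- setdiff(nb, id)
  v <- length(nb)
  if (v < 2) return(NA_real_)
  l <- 0
  for (i in seq_len(v - 1))
    for (j in (i + 1):v)
      if (key(nb[i], nb[j]) %in% edgeKeys) l <- l + 1
  2 * l / (v * (v - 1))
}

# random Erdos-Renyi edge table (n nodes, edge probability p)
randomEdgeTable <- function(n, p) {
  ids <- sprintf("n%02d", seq_len(n))
  pairs <- t(combn(ids, 2))
  keep <- runif(nrow(pairs)) < p
  data.frame(a = pairs[keep, 1], b = pairs[keep, 2],
             stringsAsFactors = FALSE)
}

# exact two-sided Mann-Whitney p by enumerating all group assignments
enumMannWhitneyP <- function(a, b) {
  n1 <- length(a); pooled <- c(a, b); N <- length(pooled)
  uOf <- function(idx) {
    sum(rank(pooled)[idx]) - n1 * (n1 + 1) / 2
  }
  uObs <- uOf(seq_len(n1))
  us <- apply(combn(N, n1), 2, uOf)
  min(1, 2 * min(mean(us <= uObs), mean(us >= uObs)))
}

# two-sided Fisher exact p by hypergeometric enumeration
enumFisherP <- function(tab) {
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ]); c1 <- sum(tab[, 1])
  a <- max(0, c1 - r2):min(r1, c1)
  probs <- dhyper(a, r1, r2, c1)
  pObs <- dhyper(tab[1, 1], r1, r2, c1)
  sum(probs[probs <= pObs * (1 + 1e-7)])
}

# all permutations of a vector, recursively (small n only)
allPermsOracle <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v))
    out <- c(out, lapply(allPermsOracle(v[-i]), function(p) c(v[i], p)))
  out
}

# exact two-sided Spearman p by full permutation enumeration (tie-free)
enumSpearmanP <- function(x, y) {
  n <- length(x)
  rx <- rank(x); ry <- rank(y)
  rhoOf <- function(r2) 1 - 6 * sum((rx - r2)^2) / (n * (n^2 - 1))
  rhoObs <- rhoOf(ry)
  rhos <- vapply(allPermsOracle(ry), rhoOf, 0)
  mean(abs(rhos) >= abs(rhoObs) - 1e-12)
}

# single-control partial correlation recursion
partialRecursion <- function(rxy, rxz, ryz)
  (rxy - rxz * ryz) / sqrt((1 - rxz^2) * (1 - ryz^2))
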