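# Shared fixtures and independent oracles for the test suite.

# small mosaic panel; defaults keep module tests fast
testPanel <- function(n = 100, m_per_chr = 100, n_chr = 2, seed = 1,
                      missing_rate = 0, ...) {
  simulateGenotypes(simConfig(n_individuals = n,
                              markers_per_chromosome = m_per_chr,
                              n_chromosomes = n_chr, seed = seed,
                              missing_rate = missing_rate, ...))
}

# id of a well-polymorphic marker to plant a QTL on (max MAF, optionally
# restricted to one chromosome)
causalId <- function(panel, chrom = NULL, rank = 1) {
  info <- markerInfo(panel)
  X <- dosageMatrix(panel)
  p <- colMeans(X, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  keep <- if (is.null(chrom)) rep(TRUE, nrow(info)) else info$chrom == chrom
  info$id[keep][order(maf[keep], decreasing = TRUE)][rank]
}

# named phenotype vector from a single-record TraitTable
phenoFromTrait <- function(trait) {
  rec <- traitRecords(trait)
  setNames(rec$value, rec$variety)
}

# Explicit-inverse GLS oracle: for each marker, directly invert
# V* = K + delta I and compute the Wald/F test of y on [covs, x_j].
# Independent of the scan's rotation/residualization path.
oracleGLS <- function(panel, y, K, delta, covariates = NULL) {
  X0 <- matrix(1, length(y), 1)
  if (!is.null(covariates)) X0 <- cbind(X0, covariates)
  G <- dosageMatrix(panel)[names(y), , drop = FALSE]
  Vi <- solve(K[names(y), names(y)] + delta * diag(length(y)))
  m <- ncol(G)
  out <- data.frame(beta = rep(NA_real_, m), se = NA_real_, p = NA_real_)
  for (j in seq_len(m)) {
    if (var(G[, j]) == 0) next    # monomorphic: untestable, scan excludes
    X <- cbind(X0, G[, j])
    q <- ncol(X)
    XtVi <- t(X) %*% Vi
    A <- solve(XtVi %*% X)
    b <- A %*% (XtVi %*% y)
    r <- y - X %*% b
    s2 <- drop(t(r) %*% Vi %*% r) / (length(y) - q)
    se <- sqrt(s2 * A[q, q])
    Fst <- (b[q] / se)^2
    out$beta[j] <- b[q]
    out$se[j] <- se
    out$p[j] <- pf(Fst, 1, length(y) - q, lower.tail = FALSE)
  }
  out
}

# Tukey-Kramer oracle from first principles: group means, pooled MSE,
# studentized-range p via ptukey (unequal-n Kramer adjustment).
oracleTukey <- function(values, group) {
  group <- factor(group)
  ni <- tapply(values, group, length)
  mi <- tapply(values, group, mean)
  k <- nlevels(group)
  dfe <- length(values) - k
  mse <- sum(tapply(values, group, function(v) sum((v - mean(v))^2))) / dfe
  combs <- utils::combn(levels(group), 2)
  data.frame(
    g1 = combs[2, ], g2 = combs[1, ],   # match TukeyHSD's "b-a" order
    diff = mi[combs[2, ]] - mi[combs[1, ]],
    p_adj = vapply(seq_len(ncol(combs)), function(i) {
      a <- combs[1, i]; b <- combs[2, i]
      se <- sqrt(mse / 2 * (1 / ni[a] + 1 / ni[b]))
      ptukey(abs(mi[b] - mi[a]) / se, k, dfe, lower.tail = FALSE)
    }, numeric(1)), row.names = NULL)
}

# one-way ANOVA F oracle
oracleAnovaF <- function(values, group) {
  group <- factor(group)
  k <- nlevels(group)
  n <- length(values)
  ssb <- sum(tapply(values, group, function(v)
    length(v) * (mean(v) - mean(values))^2))
  ssw <- sum(tapply(values, group, function(v) sum((v - mean(v))^2)))
  (ssb / (k - 1)) / (ssw / (n - k))
}

# panel whose dosage columns are exactly mutually uncorrelated:
# products of +/-1 factor columns from a 2^6 full factorial, mapped to
# dosages {0, 2}; distinct subset-products are orthogonal and balanced.
orthogonalPanel <- function(n_markers, chrom = "1", duplicate_pairs = FALSE) {
  stopifnot(n_markers <= 63)
  fac <- as.matrix(expand.grid(rep(list(c(-1, 1)), 6)))
  subsets <- utils::combn(6, 1, simplify = FALSE)
  for (k in 2:6) subsets <- c(subsets, utils::combn(6, k, simplify = FALSE))
  cols <- vapply(subsets[seq_len(n_markers)],
                 function(s) apply(fac[, s, drop = FALSE], 1, prod),
                 numeric(nrow(fac)))
  dos <- cols + 1                       # {0, 2}
  if (duplicate_pairs) dos <- cbind(dos, dos)
  m <- ncol(dos)
  mk <- data.frame(id = sprintf("o%03d", seq_len(m)), chrom = chrom,
                   pos = 1000L * seq_len(m), ref = "A", alt = "G")
  GenotypePanel(mk, sprintf("V%03d", seq_len(nrow(dos))), dos)
}

# y drawn from the polygenic model g ~ N(0, h2 K), e ~ N(0, 1 - h2)
polygenicTrait <- function(K, h2, seed) {
  set.seed(seed)
  n <- nrow(K)
  eg <- eigen(K, symmetric = TRUE)
  d <- pmax(eg$values, 0)
  g <- eg$vectors %*% (sqrt(d) * rnorm(n))
  g <- g / sd(g) * sqrt(h2)
  y <- drop(g) + rnorm(n, 0, sqrt(1 - h2))
  setNames(y, rownames(K))
}
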