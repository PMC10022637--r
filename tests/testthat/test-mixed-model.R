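test_that("kinship matrix has VanRaden structure", {
  p <- imputeMissing(testPanel(n = 40, m_per_chr = 60, n_chr = 2,
                               seed = 1))
  K <- computeKinship(p)
  expect_equal(K, t(K))
  expect_gte(min(eigen(K, symmetric = TRUE, only.values = TRUE)$values),
             -1e-8 * sum(diag(K)) / nrow(K))
  # duplicated genotype rows: off-diagonal equals diagonal
  X <- dosageMatrix(p)
  X2 <- rbind(X, X[1, , drop = FALSE])
  p2 <- GenotypePanel(markerInfo(p), c(varieties(p), "dup"), X2)
  K2 <- computeKinship(p2)
  expect_equal(K2["dup", varieties(p)[1]], K2["dup", "dup"])
  # invariant to marker order
  ord <- sample(ncol(X))
  p3 <- GenotypePanel(markerInfo(p)[ord, ], varieties(p),
                      X[, ord, drop = FALSE])
  expect_equal(computeKinship(p3), K, tolerance = 1e-12)
})

test_that("kinship off-diagonals vanish for unrelated individuals", {
  p <- imputeMissing(testPanel(n = 60, m_per_chr = 500, n_chr = 1,
                               seed = 2, n_founders = 60,
                               switch_rate = 0.9))
  K <- computeKinship(p)
  expect_lt(abs(mean(K[upper.tri(K)])), 0.05)
})

test_that("REML null fit recovers variance component ratios", {
  p <- imputeMissing(testPanel(n = 400, m_per_chr = 150, n_chr = 2,
                               seed = 3))
  K <- computeKinship(p)
  # polygenic h2 = 0.5
  h2_hat <- vapply(1:5, function(s) {
    y <- polygenicTrait(K, 0.5, seed = 50 + s)
    f <- fitNull(y, K = K)
    f$sigma2_g / (f$sigma2_g + f$sigma2_e)
  }, numeric(1))
  expect_lt(abs(median(h2_hat) - 0.5), 0.15)
  # pure noise: estimated genetic fraction small
  h2_null <- vapply(1:5, function(s) {
    set.seed(80 + s)
    y <- setNames(rnorm(nrow(K)), rownames(K))
    f <- fitNull(y, K = K)
    f$sigma2_g / (f$sigma2_g + f$sigma2_e)
  }, numeric(1))
  expect_lt(median(h2_null), 0.1)
  # refit reproducibility
  y <- polygenicTrait(K, 0.5, seed = 1)
  expect_equal(fitNull(y, K = K)$loglik_reml,
               fitNull(y, K = K)$loglik_reml, tolerance = 1e-8)
})

test_that("variance ratio estimate is stable under subsampling", {
  p <- imputeMissing(testPanel(n = 300, m_per_chr = 100, n_chr = 2,
                               seed = 4))
  K <- computeKinship(p)
  y <- polygenicTrait(K, 0.5, seed = 7)
  ratio <- function(f) f$sigma2_g / (f$sigma2_g + f$sigma2_e)
  r_full <- ratio(fitNull(y, K = K))
  set.seed(8)
  keep <- sample(names(y), 250)
  r_sub <- ratio(fitNull(y[keep], K = K[keep, keep]))
  expect_lt(abs(r_full - r_sub), 0.2)
})


test_that("P3D scan matches the explicit-inverse GLS oracle", {
  p <- imputeMissing(testPanel(n = 100, m_per_chr = 10, n_chr = 2,
                               seed = 5))
  K <- computeKinship(p)
  y <- phenoFromTrait(simulateTraitQuantitative(
    p, list(list(marker_id = causalId(p), effect = 1, trait_name = "t")),
    0.4, seed = 5)$trait)
  fit <- fitNull(y, K = K)
  sc <- scanTable(scanQuantitative(p, y, K = K))
  orc <- oracleGLS(p, y, K, fit$delta)
  ok <- !sc$excluded
  expect_lt(max(abs(sc$p[ok] - orc$p[ok]) / orc$p[ok]), 1e-6)
  expect_lt(max(abs(sc$beta[ok] - orc$beta[ok]) /
                  pmax(abs(orc$beta[ok]), 1e-8)), 1e-6)
})

test_that("GLS reduces to OLS when the kinship contribution is zero", {
  p <- imputeMissing(testPanel(n = 60, m_per_chr = 15, n_chr = 1,
                               seed = 6))
  set.seed(6)
  y <- setNames(rnorm(60), varieties(p))
  K <- diag(60); dimnames(K) <- list(varieties(p), varieties(p))
  sc <- scanTable(scanQuantitative(p, y, K = K))
  X <- dosageMatrix(p)
  ok <- !sc$excluded
  p_ols <- vapply(which(ok), function(j) {
    f <- summary(lm(y ~ X[, j]))
    f$coefficients[2, 4]
  }, numeric(1))
  expect_equal(sc$p[ok], p_ols, tolerance = 1e-8)
})

test_that("per-marker REML (p3d = FALSE) agrees closely with P3D", {
  p <- imputeMissing(testPanel(n = 60, m_per_chr = 10, n_chr = 1,
                               seed = 7))
  K <- computeKinship(p)
  set.seed(7)
  y <- setNames(rnorm(60), varieties(p))   # no dominant marker effect
  s1 <- scanTable(scanQuantitative(p, y, K = K, p3d = TRUE))
  s2 <- scanTable(scanQuantitative(p, y, K = K, p3d = FALSE))
  ok <- !s1$excluded & !s2$excluded
  expect_equal(-log10(s1$p[ok]), -log10(s2$p[ok]), tolerance = 0.2)
})


test_that("a noiseless monogenic trait puts the causal marker on top", {
  p <- imputeMissing(testPanel(n = 120, m_per_chr = 80, n_chr = 2,
                               seed = 8))
  info <- markerInfo(p)
  causal <- causalId(p)
  y <- phenoFromTrait(simulateTraitQuantitative(
    p, list(list(marker_id = causal, effect = 1, trait_name = "t")),
    1, seed = 8)$trait)
  sc <- scanTable(scanQuantitative(p, y))
  ok <- !sc$excluded
  top <- sc$id[ok][which.max(sc$minus_log10_p[ok])]
  # top is the causal marker or a perfect proxy of it
  X <- dosageMatrix(p)
  r <- cor(X[, match(top, info$id)], X[, match(causal, info$id)])
  expect_gte(abs(r), 1 - 1e-10)
})

test_that("scans are invariant to phenotype scaling and sample permutation", {
  p <- imputeMissing(testPanel(n = 70, m_per_chr = 20, n_chr = 1,
                               seed = 9))
  K <- computeKinship(p)
  info <- markerInfo(p)
  y <- phenoFromTrait(simulateTraitQuantitative(
    p, list(list(marker_id = causalId(p), effect = 1, trait_name = "t")),
    0.5, seed = 9)$trait)
  s0 <- scanTable(scanQuantitative(p, y, K = K))
  s_scaled <- scanTable(scanQuantitative(p, 3.7 * y, K = K))
  expect_equal(s0$p, s_scaled$p, tolerance = 1e-10)
  perm <- sample(length(y))
  yp <- y[perm]
  pp <- GenotypePanel(info, varieties(p)[perm],
                      dosageMatrix(p)[perm, , drop = FALSE])
  Kp <- K[perm, perm]
  s_perm <- scanTable(scanQuantitative(pp, yp, K = Kp))
  expect_equal(s0$p, s_perm$p, tolerance = 1e-10)
})

test_that("conditional scan absorbs, excludes and localizes correctly", {
  p <- imputeMissing(testPanel(n = 150, m_per_chr = 80, n_chr = 2,
                               seed = 10))
  info <- markerInfo(p)
  causal <- causalId(p)
  y <- phenoFromTrait(simulateTraitQuantitative(
    p, list(list(marker_id = causal, effect = 1, trait_name = "t")),
    1, seed = 10)$trait)
  K <- computeKinship(p)
  cs <- scanTable(conditionalScan(p, y, K = K,
                                  conditioning_markers = causal))
  # conditioning marker excluded with the right reason
  expect_true(cs$excluded[cs$id == causal])
  expect_equal(cs$excluded_reason[cs$id == causal], "conditioning/proxy")
  # signal fully absorbed in the causal region
  region <- abs(cs$pos - info$pos[info$id == causal]) < 2e6 &
    cs$chrom == info$chrom[info$id == causal]
  ok <- region & !cs$excluded & !is.na(cs$minus_log10_p)
  expect_true(all(cs$minus_log10_p[ok] < 2))
  # conditioning on an uncorrelated other-chromosome marker barely moves
  # the causal-region minimum p
  other <- info$id[info$chrom != info$chrom[info$id == causal]][5]
  cs2 <- scanTable(conditionalScan(p, y, K = K,
                                   conditioning_markers = other))
  us <- scanTable(scanQuantitative(p, y, K = K))
  reg_max <- function(tab) {
    i <- tab$chrom == info$chrom[info$id == causal] & !tab$excluded &
      !is.na(tab$minus_log10_p)
    max(tab$minus_log10_p[i])
  }
  expect_lt(abs(reg_max(cs2) - reg_max(us)), 1)
  expect_error(conditionalScan(p, y, K = K,
                               conditioning_markers = "nope"),
               "not shared")
})

test_that("binary score scan finds a strong causal SNP and rejects bad input", {
  p <- imputeMissing(testPanel(n = 400, m_per_chr = 100, n_chr = 2,
                               seed = 11))
  info <- markerInfo(p)
  causal <- causalId(p)
  b <- simulateTraitBinary(p, list(list(marker_id = causal, effect = 1,
                                        trait_name = "b")),
                           h2_liability = 0.6, prevalence = 0.4, seed = 11)
  y <- phenoFromTrait(b$trait)
  sc <- scanTable(scanBinary(p, y))
  ok <- !sc$excluded
  top <- sc$id[ok][which.max(sc$minus_log10_p[ok])]
  X <- dosageMatrix(p)
  r <- cor(X[, match(top, info$id)], X[, match(causal, info$id)])
  expect_gt(abs(r), 0.8)
  expect_error(scanBinary(p, setNames(rep(1, 400), varieties(p))),
               "degenerate")
  yw <- y; yw[] <- 0; yw[1:3] <- 1
  expect_warning(scanBinary(p, yw), "fewer than 5")
})

test_that("PCA separates diverged founder groups and orders variance", {
  # two diverged pools: allele frequencies 0.2 vs 0.8 at every marker
  set.seed(12)
  m <- 150
  XA <- matrix(rbinom(40 * m, 2, 0.2), 40, m)
  XB <- matrix(rbinom(40 * m, 2, 0.8), 40, m)
  mk <- data.frame(id = sprintf("m%03d", 1:m), chrom = "1",
                   pos = 1000L * (1:m), ref = "A", alt = "G")
  joint <- GenotypePanel(mk, c(sprintf("A%02d", 1:40),
                               sprintf("B%02d", 1:40)), rbind(XA, XB))
  pc <- pcaStructure(joint, 4)
  grpA <- pc$scores[1:40, 1]
  grpB <- pc$scores[41:80, 1]
  expect_true(max(grpA) < min(grpB) || max(grpB) < min(grpA))
  expect_true(all(diff(pc$variance_explained) <= 1e-12))
  # duplicated individual: identical scores
  X <- dosageMatrix(joint)
  jd <- GenotypePanel(markerInfo(joint), c(varieties(joint), "dup"),
                      rbind(X, X[1, , drop = FALSE]))
  pcd <- pcaStructure(jd, 2)
  expect_equal(unname(pcd$scores["dup", ]), unname(pcd$scores[1, ]))
  expect_error(pcaStructure(joint, 500), "n_components")
})

test_that("inflation statistics behave under null and distorted p-values", {
  p <- imputeMissing(testPanel(n = 200, m_per_chr = 150, n_chr = 2,
                               seed = 13))
  set.seed(13)
  y <- setNames(rnorm(200), varieties(p))
  sc <- scanQuantitative(p, y)
  inf <- inflation(sc)
  expect_gt(inf$lambda_gc, 0.8)
  expect_lt(inf$lambda_gc, 1.2)
  expect_equal(nrow(inf$qq), sum(!scanTable(sc)$excluded))
  # squaring p-values inflates lambda above 1
  tab <- scanTable(sc)
  tab$p <- tab$p^2
  tab$minus_log10_p <- -log10(tab$p)
  sc2 <- crossGWAS:::ScanResult(tab, scanMeta(sc))
  expect_gt(inflation(sc2)$lambda_gc, inf$lambda_gc)
})
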