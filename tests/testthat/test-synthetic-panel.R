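test_that("simulateGenotypes is deterministic and dimensionally correct", {
  cfg <- simConfig(n_individuals = 200, n_chromosomes = 4,
                   markers_per_chromosome = 500, seed = 11)
  p1 <- simulateGenotypes(cfg)
  p2 <- simulateGenotypes(cfg)
  expect_identical(dosageMatrix(p1), dosageMatrix(p2))
  expect_identical(markerInfo(p1), markerInfo(p2))
  X <- dosageMatrix(p1)
  expect_equal(dim(X), c(200, 2000))
  expect_true(all(X[!is.na(X)] %in% 0:2))
  info <- markerInfo(p1)
  expect_false(is.unsorted(order(info$chrom, info$pos)))
  expect_error(simulateGenotypes(simConfig(markers_per_chromosome = 1)),
               "degenerate chromosome")
})

test_that("zero switch rate with two founders gives perfectly correlated differing markers", {
  p <- simulateGenotypes(simConfig(n_founders = 2, n_individuals = 60,
                                   n_chromosomes = 1,
                                   markers_per_chromosome = 40,
                                   switch_rate = 0, missing_rate = 0,
                                   seed = 5))
  X <- dosageMatrix(p)
  # markers where the two founders differ are those with any variation
  varying <- which(apply(X, 2, var) > 0)
  expect_gt(length(varying), 5)
  r <- cor(X[, varying])
  expect_true(all(abs(abs(r) - 1) < 1e-12))
})

test_that("mosaic model produces monotone LD decay", {
  p <- simulateGenotypes(simConfig(switch_rate = 0.02, n_founders = 8,
                                   n_individuals = 200, n_chromosomes = 1,
                                   markers_per_chromosome = 200,
                                   missing_rate = 0, seed = 1))
  X <- dosageMatrix(p)
  keep <- apply(X, 2, var) > 0
  X <- X[, keep]
  m <- ncol(X)
  r2 <- cor(X)^2
  adj <- mean(r2[cbind(1:(m - 1), 2:m)])
  far_pairs <- which(abs(row(r2) - col(r2)) >= 50 & upper.tri(r2))
  expect_gt(adj, mean(r2[far_pairs]))
})

test_that("quantitative trait simulator realizes the requested architecture", {
  p <- testPanel(n = 2000, m_per_chr = 60, n_chr = 1, seed = 7)
  spec <- list(list(marker_id = causalId(p), effect = 1.5,
                    trait_name = "CL"))
  # h2 = 1: phenotype equals genetic value
  r1 <- simulateTraitQuantitative(p, spec, h2_total = 1, seed = 7)
  expect_equal(unname(phenoFromTrait(r1$trait)),
               unname(r1$truth$genetic_values))
  # h2 = 0.5: realized variance ratio within 0.05
  r2 <- simulateTraitQuantitative(p, spec, h2_total = 0.5, seed = 7)
  g <- r2$truth$genetic_values
  y <- phenoFromTrait(r2$trait)[names(g)]
  expect_lt(abs(var(g) / var(y) - 0.5), 0.05)
  # two causal SNPs on distinct chromosomes: variances nearly additive
  p2 <- imputeMissing(testPanel(n = 1000, m_per_chr = 40, n_chr = 2,
                                seed = 8))
  info2 <- markerInfo(p2)
  j1 <- match(causalId(p2, chrom = "1"), info2$id)
  j2 <- match(causalId(p2, chrom = "2"), info2$id)
  sp2 <- list(list(marker_id = info2$id[j1], effect = 1, trait_name = "t"),
              list(marker_id = info2$id[j2], effect = -1, trait_name = "t"))
  r3 <- simulateTraitQuantitative(p2, sp2, h2_total = 1, seed = 9)
  X <- dosageMatrix(p2)
  # exact decomposition Var(g) = Var(x1) + Var(x2) - 2 Cov(x1, x2), with
  # the cross-chromosome covariance itself near zero
  cv <- cov(X[, j1], X[, j2])
  expect_equal(var(r3$truth$genetic_values),
               var(X[, j1]) + var(X[, j2]) - 2 * cv, tolerance = 1e-10)
  expect_lt(abs(cv), 0.05)
  expect_error(simulateTraitQuantitative(p, list(), 0, 1),
               "no causal specs")
})

test_that("liability-threshold binary traits have exact prevalence and causal enrichment", {
  p <- testPanel(n = 1000, m_per_chr = 50, n_chr = 1, seed = 3)
  spec <- list(list(marker_id = causalId(p), effect = 1,
                    trait_name = "WC"))
  b <- simulateTraitBinary(p, spec, h2_liability = 0.4, prevalence = 0.5,
                           seed = 3)
  y <- phenoFromTrait(b$trait)
  expect_equal(sum(y), 500)
  x <- dosageMatrix(imputeMissing(p))[, match(spec[[1]]$marker_id,
                                              markerInfo(p)$id)]
  expect_gt(mean(x[y == 1]), mean(x[y == 0]))
  expect_error(simulateTraitBinary(p, spec, 0.4, 0, 1), "prevalence")
})

test_that("legacy replicates carry environment offsets and bookkeeping", {
  p <- testPanel(n = 80, m_per_chr = 30, n_chr = 1, seed = 2)
  base <- simulateTraitQuantitative(
    p, list(list(marker_id = causalId(p), effect = 1,
                 trait_name = "CL")),
    h2_total = 0.8, seed = 2)
  # zero environment variance, zero residual: replicates equal input
  r0 <- simulateLegacyReplicates(base$trait, env_sd = 0, n_locations = 2,
                                 n_years = 2, seed = 4, residual_sd = 0,
                                 keep_prob = 1)
  rec <- traitRecords(r0$trait)
  bv <- phenoFromTrait(base$trait)
  expect_equal(rec$value, unname(bv[rec$variety]))
  expect_true(all(r0$truth$env_effects$offset == 0))
  # 12 locations x 3 years: at most 36 records per variety
  r1 <- simulateLegacyReplicates(base$trait, env_sd = 5, n_locations = 12,
                                 n_years = 3, seed = 4)
  cnt <- table(traitRecords(r1$trait)$variety)
  expect_true(all(cnt <= 36))
  # env variance dominates residual: between-env > within-env variance
  r2 <- simulateLegacyReplicates(base$trait, env_sd = 5, n_locations = 6,
                                 n_years = 2, seed = 5, residual_sd = 1)
  rc <- traitRecords(r2$trait)
  rc$dev <- rc$value - unname(bv[rc$variety])
  env <- paste(rc$location, rc$year)
  between <- var(tapply(rc$dev, env, mean))
  within <- mean(tapply(rc$dev, env, var))
  expect_gt(between, within)
  expect_error(simulateLegacyReplicates(base$trait, 1, 0, 0, 1),
               "environment")
})

test_that("two-panel generator honors overlap, scenarios and forced causal markers", {
  cfg <- simConfig(n_individuals = 80, n_chromosomes = 2,
                   markers_per_chromosome = 60, seed = 6)
  # full overlap + same phenotype seed: panels and traits identical
  s1 <- simulateTwoPanels(cfg, "shared_qtl", overlap_varieties = 1,
                          overlap_markers = 1, seed = 6,
                          trait_seeds = c(99L, 99L))
  expect_identical(dosageMatrix(s1$panel_A), dosageMatrix(s1$panel_B))
  expect_identical(phenoFromTrait(s1$trait_A),
                   setNames(phenoFromTrait(s1$trait_B),
                            names(phenoFromTrait(s1$trait_A))))
  # distinct_qtl: causal markers on different chromosomes, in both panels
  s2 <- simulateTwoPanels(cfg, "distinct_qtl", seed = 7)
  infoA <- markerInfo(s2$panel_A)
  infoB <- markerInfo(s2$panel_B)
  chrA <- infoA$chrom[infoA$id == s2$truth$causal_A]
  chrB <- infoB$chrom[infoB$id == s2$truth$causal_B]
  expect_false(chrA == chrB)
  expect_true(all(c(s2$truth$causal_A, s2$truth$causal_B) %in% infoA$id))
  expect_true(all(c(s2$truth$causal_A, s2$truth$causal_B) %in% infoB$id))
  # partial marker overlap close to the requested fraction
  s3 <- simulateTwoPanels(cfg, "shared_qtl", overlap_markers = 0.7,
                          seed = 8)
  shared <- length(intersect(markerInfo(s3$panel_A)$id,
                             markerInfo(s3$panel_B)$id))
  expect_equal(shared / nrow(s3$panel_A), 0.7, tolerance = 0.05)
  # null: no causal markers recorded
  s4 <- simulateTwoPanels(cfg, "null", seed = 9)
  expect_null(s4$truth$causal_A)
})

test_that("epistatic ordinal trait follows the switch/tone rules", {
  p <- testPanel(n = 150, m_per_chr = 40, n_chr = 2, seed = 10,
                 inbred = TRUE)
  X <- round(dosageMatrix(imputeMissing(p)))
  info <- markerInfo(p)
  # pick clearly polymorphic markers on different chromosomes
  mafs <- pmin(colMeans(X) / 2, 1 - colMeans(X) / 2)
  sw <- info$id[info$chrom == "1"][which.max(mafs[info$chrom == "1"])]
  tn <- info$id[info$chrom == "2"][which.max(mafs[info$chrom == "2"])]
  r <- simulateEpistaticOrdinal(p, sw, tn, seed = 12)
  y <- phenoFromTrait(r$trait)
  cls <- r$truth$classes[names(y)]
  expect_true(all(y[cls == "switch_null"] == 1))
  expect_true(all(y[cls == "light"] %in% 2:4))
  expect_true(all(y[cls == "dark"] %in% 5:9))
  expect_true(mean(y[cls == "switch_null"]) < mean(y[cls == "light"]))
  expect_true(mean(y[cls == "light"]) < mean(y[cls == "dark"]))
})

test_that("heritability recovery: realized Var(g)/Var(y) is unbiased", {
  p <- testPanel(n = 1000, m_per_chr = 50, n_chr = 2, seed = 20)
  spec <- list(list(marker_id = causalId(p), effect = 1,
                    trait_name = "t"))
  ratios <- vapply(1:50, function(s) {
    r <- simulateTraitQuantitative(p, spec, h2_total = 0.4, seed = 100 + s)
    g <- r$truth$genetic_values
    y <- phenoFromTrait(r$trait)[names(g)]
    var(g) / var(y)
  }, numeric(1))
  expect_lt(abs(mean(ratios) - 0.4), 0.02)
})
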