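#' Simulation configuration for founder-mosaic genotype panels
#'
#' Bundles and validates the parameters of the founder-mosaic genotype
#' simulator (\code{\link{simulateGenotypes}}). Each individual chromosome
#' copy is a mosaic of founder haplotypes with switches between founders
#' occurring independently at each marker interval, which yields the
#' block-wise linkage disequilibrium the downstream mixed-model machinery
#' assumes.
#'
#' @param n_founders number of founder haplotypes in the pool.
#' @param n_individuals number of (diploid) varieties to emit.
#' @param n_chromosomes number of chromosomes.
#' @param markers_per_chromosome markers per chromosome (>= 2).
#' @param chromosome_length_bp chromosome length in bp.
#' @param switch_rate probability, per marker interval, that a chromosome
#'   copy switches to a founder drawn uniformly from the pool.
#' @param maf_floor founder allele frequencies are drawn uniformly from
#'   [maf_floor, 1 - maf_floor]; must satisfy 0 <= maf_floor < 0.5.
#' @param missing_rate fraction of dosage entries set missing uniformly at
#'   random, to exercise QC and imputation.
#' @param inbred if TRUE a single haplotype mosaic is simulated per
#'   individual and doubled (fully homozygous lines, as in a selfing
#'   species); default FALSE (two independent mosaics).
#' @param seed integer seed; identical configs (including seed) give
#'   bit-identical panels.
#' @return A list of class \code{"SimConfig"}.
#' @examples
#' cfg <- simConfig(n_individuals = 50, n_chromosomes = 2,
#'                  markers_per_chromosome = 100, seed = 1)
#' @export
simConfig <- function(n_founders = 8, n_individuals = 200,
                      n_chromosomes = 4, markers_per_chromosome = 200,
                      chromosome_length_bp = 30e6, switch_rate = 0.02,
                      maf_floor = 0.1, missing_rate = 0.02,
                      inbred = FALSE, seed = 1) {
  counts <- c(n_founders, n_individuals, n_chromosomes,
              markers_per_chromosome)
  if (any(counts < 1)) stop("all counts must be >= 1")
  if (switch_rate < 0 || switch_rate > 1)
    stop("switch_rate must lie in [0, 1]")
  if (maf_floor < 0 || maf_floor >= 0.5)
    stop("maf_floor must lie in [0, 0.5)")
  if (missing_rate < 0 || missing_rate >= 1)
    stop("missing_rate must lie in [0, 1)")
  structure(list(n_founders = as.integer(n_founders),
                 n_individuals = as.integer(n_individuals),
                 n_chromosomes = as.integer(n_chromosomes),
                 markers_per_chromosome = as.integer(markers_per_chromosome),
                 chromosome_length_bp = as.integer(chromosome_length_bp),
                 switch_rate = switch_rate, maf_floor = maf_floor,
                 missing_rate = missing_rate, inbred = inbred,
                 seed = as.integer(seed)),
            class = "SimConfig")
}

# one haplotype mosaic over m markers: founder index per marker
.mosaicPath <- function(m, n_founders, switch_rate) {
  sw <- if (m > 1) rbinom(m - 1L, 1L, switch_rate) else integer(0)
  seg <- cumsum(c(1L, sw))        # segment id per marker
  founders <- sample.int(n_founders, max(seg), replace = TRUE)
  founders[seg]
}

#' Simulate a genotype panel under a founder-mosaic model
#'
#' Founder haplotypes are drawn per marker with allele frequencies uniform
#' on [maf_floor, 1 - maf_floor]; each individual's chromosome copies are
#' mosaics of founders with switch probability \code{switch_rate} per
#' marker interval (a Li-Stephens-style copying model). Dosage is the
#' count of alternate alleles; a \code{missing_rate} fraction of entries
#' is masked. The model produces monotonically decaying linkage
#' disequilibrium with distance, sufficient to exercise kinship
#' estimation, SimpleM and peak calling.
#'
#' @param config A \code{\link{simConfig}} object.
#' @return A \linkS4class{GenotypePanel}, markers sorted by (chrom, pos),
#'   deterministic given the config seed.
#' @examples
#' gp <- simulateGenotypes(simConfig(n_individuals = 20,
#'   n_chromosomes = 1, markers_per_chromosome = 50, seed = 3))
#' gp
#' @export
simulateGenotypes <- function(config) {
  stopifnot(inherits(config, "SimConfig"))
  if (config$markers_per_chromosome < 2) stop("degenerate chromosome")
  set.seed(config$seed)
  n <- config$n_individuals
  mpc <- config$markers_per_chromosome
  mk_list <- vector("list", config$n_chromosomes)
  dos_list <- vector("list", config$n_chromosomes)
  bases <- c("A", "C", "G", "T")
  for (chrom in seq_len(config$n_chromosomes)) {
    pos <- sort(sample.int(config$chromosome_length_bp, mpc))
    p <- runif(mpc, config$maf_floor, 1 - config$maf_floor)
    founders <- matrix(rbinom(config$n_founders * mpc, 1L, rep(p, each = config$n_founders)),
                       nrow = config$n_founders, ncol = mpc)
    dos <- matrix(0L, n, mpc)
    for (i in seq_len(n)) {
      path1 <- .mosaicPath(mpc, config$n_founders, config$switch_rate)
      h1 <- founders[cbind(path1, seq_len(mpc))]
      if (config$inbred) {
        dos[i, ] <- 2L * h1
      } else {
        path2 <- .mosaicPath(mpc, config$n_founders, config$switch_rate)
        dos[i, ] <- h1 + founders[cbind(path2, seq_len(mpc))]
      }
    }
    ra <- t(vapply(seq_len(mpc), function(j) sample(bases, 2), character(2)))
    mk_list[[chrom]] <- data.frame(
      id = sprintf("c%d_%d", chrom, pos), chrom = as.character(chrom),
      pos = pos, ref = ra[, 1], alt = ra[, 2], stringsAsFactors = FALSE)
    dos_list[[chrom]] <- dos
  }
  dosages <- do.call(cbind, dos_list)
  if (config$missing_rate > 0) {
    mask <- runif(length(dosages)) < config$missing_rate
    dosages[mask] <- NA
  }
  GenotypePanel(do.call(rbind, mk_list),
                sprintf("V%03d", seq_len(n)), dosages)
}

# variance of e matching Var(g)/Var(y) = h2 in expectation
.noiseSD <- function(var_g, h2) {
  if (h2 >= 1) return(0)
  if (h2 <= 0) return(sqrt(var_g))   # pure-noise trait on the g scale
  sqrt(var_g * (1 - h2) / h2)
}

.geneticValue <- function(panel, specs) {
  info <- markerInfo(panel)
  X <- dosageMatrix(panel)
  g <- numeric(nrow(X))
  for (sp in specs) {
    j <- match(sp$marker_id, info$id)
    if (is.na(j)) stop("causal marker not in panel: ", sp$marker_id)
    x <- X[, j]
    x[is.na(x)] <- mean(x, na.rm = TRUE)
    if (var(x) == 0) stop("no genetic variance")
    g <- g + sp$effect * x
  }
  names(g) <- varieties(panel)
  g
}

#' Simulate a quantitative trait from causal marker effects
#'
#' The genetic value of individual i is \eqn{g_i = \sum_j \beta_j x_{ij}}
#' over the causal specs; Gaussian noise is added with variance chosen so
#' that Var(g)/Var(y) equals \code{h2_total} in expectation.
#'
#' @param panel A \linkS4class{GenotypePanel}.
#' @param specs list of causal specs, each
#'   \code{list(marker_id=, effect=, trait_name=)}.
#' @param h2_total narrow-sense heritability in [0, 1]. With
#'   \code{h2_total = 0} the phenotype is pure noise (genetic value
#'   suppressed).
#' @param seed integer seed for the noise.
#' @param trait_name trait label (defaults to the first spec's).
#' @return list with elements \code{trait} (a \linkS4class{TraitTable}
#'   with one record per variety) and \code{truth} (a TruthRecord list:
#'   causal_specs, h2_total, env_effects).
#' @export
simulateTraitQuantitative <- function(panel, specs, h2_total, seed,
                                      trait_name = NULL) {
  if (length(specs) == 0 && h2_total == 0)
    stop("h2_total = 0 with no causal specs")
  if (h2_total < 0 || h2_total > 1) stop("h2_total must lie in [0, 1]")
  if (is.null(trait_name)) trait_name <- specs[[1]]$trait_name
  set.seed(seed)
  g <- .geneticValue(panel, specs)
  e <- rnorm(length(g), 0, .noiseSD(var(g), h2_total))
  y <- if (h2_total > 0) g + e else e + mean(g)
  rec <- data.frame(variety = names(g), trait = trait_name,
                    location = "SIM", year = 1L, value = as.numeric(y))
  list(trait = TraitTable(rec, setNames("quantitative", trait_name)),
       truth = list(causal_specs = specs, h2_total = h2_total,
                    liability_threshold = NULL, env_effects = NULL,
                    genetic_values = g))
}

#' Simulate a binary trait under the liability-threshold model
#'
#' A latent liability (genetic value plus Gaussian noise at
#' \code{h2_liability}) is thresholded at its empirical
#' (1 - prevalence)-quantile, so the realized prevalence is exact in
#' every sample.
#'
#' @inheritParams simulateTraitQuantitative
#' @param h2_liability heritability of the latent liability.
#' @param prevalence case fraction in (0, 1).
#' @return list(trait =, truth =) as in
#'   \code{\link{simulateTraitQuantitative}}; values coded 0/1 and the
#'   threshold recorded as \code{truth$liability_threshold}.
#' @export
simulateTraitBinary <- function(panel, specs, h2_liability, prevalence,
                                seed, trait_name = NULL) {
  if (prevalence <= 0 || prevalence >= 1)
    stop("prevalence must lie in (0, 1)")
  if (is.null(trait_name)) trait_name <- specs[[1]]$trait_name
  set.seed(seed)
  g <- .geneticValue(panel, specs)
  liab <- if (h2_liability > 0)
    g + rnorm(length(g), 0, .noiseSD(var(g), h2_liability))
  else rnorm(length(g), 0, sqrt(max(var(g), 1)))
  tau <- quantile(liab, 1 - prevalence, type = 1, names = FALSE)
  y <- as.integer(liab > tau)
  if (all(y == 0) || all(y == 1)) stop("degenerate binary trait")
  rec <- data.frame(variety = names(g), trait = trait_name,
                    location = "SIM", year = 1L, value = y)
  list(trait = TraitTable(rec, setNames("binary", trait_name)),
       truth = list(causal_specs = specs, h2_total = h2_liability,
                    liability_threshold = tau, env_effects = NULL,
                    genetic_values = g))
}

#' Expand a single-record trait into replicated legacy-style measurements
#'
#' Emulates genebank legacy data: each variety is measured in several
#' (location, year) environments; each environment contributes a common
#' Gaussian offset (sd \code{env_sd}) and each record an independent
#' residual. Records are randomly thinned to mimic incomplete coverage.
#'
#' @param trait A \linkS4class{TraitTable} with one record per variety
#'   (single trait).
#' @param env_sd standard deviation of the location-by-year offsets, in
#'   trait units.
#' @param n_locations,n_years numbers of locations and years.
#' @param seed integer seed.
#' @param residual_sd per-record residual sd (trait units).
#' @param keep_prob probability that a (variety, location, year) record is
#'   retained.
#' @return list(trait = replicated \linkS4class{TraitTable}, truth = list
#'   with \code{env_effects}, a data.frame (location, year, offset)).
#' @export
simulateLegacyReplicates <- function(trait, env_sd, n_locations, n_years,
                                     seed, residual_sd = 1,
                                     keep_prob = 0.8) {
  if (n_locations * n_years == 0) stop("need at least one environment")
  rec <- traitRecords(trait)
  tr <- unique(rec$trait)
  stopifnot(length(tr) == 1, !anyDuplicated(rec$variety))
  set.seed(seed)
  envs <- expand.grid(location = sprintf("L%02d", seq_len(n_locations)),
                      year = seq_len(n_years), stringsAsFactors = FALSE)
  envs$offset <- rnorm(nrow(envs), 0, env_sd)
  out <- do.call(rbind, lapply(seq_len(nrow(envs)), function(k) {
    keep <- runif(nrow(rec)) < keep_prob
    if (!any(keep)) return(NULL)
    data.frame(variety = rec$variety[keep], trait = tr,
               location = envs$location[k], year = envs$year[k],
               value = rec$value[keep] + envs$offset[k] +
                 rnorm(sum(keep), 0, residual_sd))
  }))
  list(trait = TraitTable(out, traitTypes(trait)),
       truth = list(env_effects = envs, residual_sd = residual_sd,
                    base_values = setNames(rec$value, rec$variety)))
}

#' Simulate two partially overlapping panels for cross-cohort analysis
#'
#' Draws two panels from one founder pool: a fraction
#' \code{overlap_varieties} of individuals appears in both panels with
#' identical genotypes; each panel genotypes a random marker subset such
#' that a fraction \code{overlap_markers} of its markers is shared with
#' the other panel. Causal markers are force-retained in both panels'
#' marker sets so that cross-panel conditioning is always possible.
#'
#' Scenarios: \code{"shared_qtl"} plants one causal marker with the same
#' effect in both panels' traits; \code{"distinct_qtl"} plants causal
#' markers on different chromosomes; \code{"null"} plants none (traits
#' are pure noise).
#'
#' @param config A \code{\link{simConfig}} for one panel's size; the
#'   founder pool and marker pool are shared between panels.
#' @param scenario one of \code{"shared_qtl"}, \code{"distinct_qtl"},
#'   \code{"null"}.
#' @param overlap_varieties fraction of each panel's individuals present
#'   in both panels.
#' @param overlap_markers fraction of each panel's markers shared with
#'   the other panel.
#' @param seed integer seed.
#' @param h2_qtl heritability attributable to the planted QTL.
#' @param trait_seeds length-2 integer vector of phenotype noise seeds
#'   for panels A and B (set equal to reproduce identical traits on
#'   fully overlapping panels).
#' @return list with elements \code{panel_A}, \code{trait_A},
#'   \code{panel_B}, \code{trait_B}, \code{truth}.
#' @export
simulateTwoPanels <- function(config, scenario = c("shared_qtl",
                                                   "distinct_qtl", "null"),
                              overlap_varieties = 0.5,
                              overlap_markers = 0.7, seed = 1,
                              h2_qtl = 0.3,
                              trait_seeds = seed + c(1L, 2L)) {
  scenario <- match.arg(scenario)
  stopifnot(overlap_varieties >= 0, overlap_varieties <= 1,
            overlap_markers >= 0, overlap_markers <= 1)
  n <- config$n_individuals
  n_shared <- round(overlap_varieties * n)
  total <- 2L * n - n_shared
  big_cfg <- config
  big_cfg$n_individuals <- as.integer(total)
  big_cfg$seed <- as.integer(seed)
  big <- simulateGenotypes(big_cfg)
  idx_A <- seq_len(n)
  idx_B <- c(seq_len(n_shared), n + seq_len(n - n_shared))
  info <- markerInfo(big)
  M <- nrow(info)

  set.seed(seed + 997L)
  # choose causal markers first so they can be force-retained
  maf_ok <- which(apply(dosageMatrix(big), 2, function(x) {
    p <- mean(x, na.rm = TRUE) / 2; min(p, 1 - p) >= 0.2
  }))
  causal_A <- causal_B <- NULL
  if (scenario == "shared_qtl") {
    causal_A <- causal_B <- sample(maf_ok, 1)
  } else if (scenario == "distinct_qtl") {
    chrA <- info$chrom[maf_ok[1]]
    onA <- maf_ok[info$chrom[maf_ok] == chrA]
    offA <- maf_ok[info$chrom[maf_ok] != chrA]
    if (!length(offA)) stop("need >= 2 chromosomes for distinct_qtl")
    causal_A <- sample(onA, 1)
    causal_B <- sample(offA, 1)
  }
  forced <- unique(c(causal_A, causal_B))

  m_p <- floor(M / (2 - overlap_markers))
  s <- round(overlap_markers * m_p)
  u <- m_p - s
  pool <- setdiff(sample.int(M), forced)       # random order, causal out
  shared_idx <- sort(c(forced, pool[seq_len(max(0, s - length(forced)))]))
  rest <- setdiff(pool, shared_idx)
  uA <- min(u, length(rest))
  only_A <- sort(rest[seq_len(uA)])
  remaining <- setdiff(rest, only_A)
  only_B <- sort(remaining[seq_len(min(u, length(remaining)))])
  mk_A <- sort(union(shared_idx, only_A))
  mk_B <- sort(union(shared_idx, only_B))

  subPanel <- function(rows, cols) {
    GenotypePanel(info[cols, , drop = FALSE],
                  varieties(big)[rows],
                  dosageMatrix(big)[rows, cols, drop = FALSE])
  }
  panel_A <- subPanel(idx_A, mk_A)
  panel_B <- subPanel(idx_B, mk_B)

  mkTrait <- function(panel, causal, tseed, label) {
    if (is.null(causal)) {
      set.seed(tseed)
      y <- rnorm(length(varieties(panel)))
      rec <- data.frame(variety = varieties(panel), trait = label,
                        location = "SIM", year = 1L, value = y)
      return(list(trait = TraitTable(rec, setNames("quantitative", label)),
                  truth = list(causal_specs = list(), h2_total = 0)))
    }
    spec <- list(list(marker_id = info$id[causal], effect = 1,
                      trait_name = label))
    simulateTraitQuantitative(panel, spec, h2_qtl, tseed)
  }
  tA <- mkTrait(panel_A, causal_A, trait_seeds[1], "trait_A")
  tB <- mkTrait(panel_B, causal_B, trait_seeds[2], "trait_B")

  list(panel_A = panel_A, trait_A = tA$trait,
       panel_B = panel_B, trait_B = tB$trait,
       truth = list(scenario = scenario,
                    causal_A = if (!is.null(causal_A)) info$id[causal_A],
                    causal_B = if (!is.null(causal_B)) info$id[causal_B],
                    h2_qtl = if (scenario == "null") 0 else h2_qtl,
                    shared_varieties = varieties(big)[seq_len(n_shared)],
                    truth_A = tA$truth, truth_B = tB$truth))
}

#' Simulate an ordinal color-like trait controlled by two epistatic loci
#'
#' A switch locus gates expression: varieties with dosage 0 (the null
#' allele homozygote) score 1 regardless of the tone locus. Among
#' functional-switch carriers, tone-null varieties draw a light score in
#' 2..4 and tone-functional varieties a dark score in 5..9, mirroring a
#' 1-9 ordinal color scale.
#'
#' @param panel A \linkS4class{GenotypePanel}.
#' @param switch_marker,tone_marker marker ids of the two loci.
#' @param seed integer seed.
#' @param trait_name trait label.
#' @return list(trait =, truth =); truth records the two marker ids and
#'   per-variety class labels.
#' @export
simulateEpistaticOrdinal <- function(panel, switch_marker, tone_marker,
                                     seed, trait_name = "ApC_like") {
  info <- markerInfo(panel)
  js <- match(switch_marker, info$id)
  jt <- match(tone_marker, info$id)
  if (is.na(js) || is.na(jt)) stop("marker not in panel")
  X <- dosageMatrix(panel)
  sw <- round(X[, js]); tn <- round(X[, jt])
  sw[is.na(sw)] <- round(mean(sw, na.rm = TRUE))
  tn[is.na(tn)] <- round(mean(tn, na.rm = TRUE))
  if (var(sw) == 0) stop("monomorphic switch marker")
  set.seed(seed)
  n <- nrow(X)
  score <- integer(n)
  cls <- character(n)
  for (i in seq_len(n)) {
    if (sw[i] == 0) { score[i] <- 1L; cls[i] <- "switch_null" }
    else if (tn[i] == 0) { score[i] <- sample(2:4, 1); cls[i] <- "light" }
    else { score[i] <- sample(5:9, 1); cls[i] <- "dark" }
  }
  rec <- data.frame(variety = varieties(panel), trait = trait_name,
                    location = "SIM", year = 1L, value = score)
  list(trait = TraitTable(rec, setNames("quantitative", trait_name)),
       truth = list(switch_marker = switch_marker,
                    tone_marker = tone_marker,
                    classes = setNames(cls, varieties(panel))))
}
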