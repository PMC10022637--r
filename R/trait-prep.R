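#' Convert a heading date to days after July 1
#'
#' Heading dates recorded as (month, day) within one growing season
#' (May through December of the same year) are mapped to an integer
#' offset from July 1: July 1 -> 0, later dates positive, earlier dates
#' (May, June) negative.
#'
#' @param month calendar month, 5-12.
#' @param day day of month.
#' @return integer days after July 1 (vectorized).
#' @examples
#' headingDays(7, 1)    # 0
#' headingDays(8, 10)   # 40
#' @export
headingDays <- function(month, day) {
  if (any(month < 5 | month > 12))
    stop("month outside the May-December growing season")
  # fixed non-leap reference year; validity checked via Date round-trip
  d <- as.Date(sprintf("2001-%02d-%02d", month, day), format = "%Y-%m-%d")
  if (anyNA(d)) stop("invalid calendar date")
  as.integer(d - as.Date("2001-07-01"))
}

#' Classify a trait as binary or quantitative from its value distribution
#'
#' A trait is designated binary when its most frequent level holds at
#' least \code{modal_fraction_cutoff} of the observations (an "extremely
#' unidirectional" distribution) or when it takes exactly two distinct
#' levels; otherwise it is quantitative. Invariant to relabeling of
#' levels.
#'
#' @param values numeric vector (missing values dropped); at least 10
#'   non-missing values required.
#' @param modal_fraction_cutoff modal-share cutoff, default 0.8.
#' @return \code{"binary"} or \code{"quantitative"}.
#' @export
classifyTraitType <- function(values, modal_fraction_cutoff = 0.8) {
  v <- values[!is.na(values)]
  if (length(v) < 10) stop("need >= 10 non-missing values")
  lev <- table(v)
  if (length(lev) < 2) stop("no variation")
  if (length(lev) == 2) return("binary")
  if (max(lev) / length(v) >= modal_fraction_cutoff) return("binary")
  "quantitative"
}

#' Binarize an ordinal or continuous trait
#'
#' Two splits are supported: \code{threshold(t)} codes values <= t as 0
#' and values > t as 1 (e.g. a 1-9 color scale split at 1 into
#' non-colored vs colored, or the colored subset split at 4 into light
#' vs dark); \code{modal_vs_rest} codes the modal level as 0 and all
#' other levels as 1.
#'
#' @param values named numeric vector (names are variety labels).
#' @param split either \code{list(type = "threshold", t = <value>)} or
#'   \code{list(type = "modal_vs_rest")}.
#' @param traitName label for the returned vector.
#' @return A \linkS4class{PhenotypeVector} with provenance
#'   \code{"binarized"}.
#' @export
binarize <- function(values, split, traitName = "binarized") {
  v <- values[!is.na(values)]
  if (split$type == "threshold") {
    y <- as.numeric(v > split$t)
  } else if (split$type == "modal_vs_rest") {
    tab <- table(v)
    modal <- as.numeric(names(tab)[which.max(tab)])
    y <- as.numeric(v != modal)
  } else stop("unknown split type")
  if (all(y == 0) || all(y == 1)) stop("split yields an empty class")
  PhenotypeVector(setNames(y, names(v)), traitName, type = "binary",
                  provenance = "binarized")
}

#' Adjust multi-environment trait records for location-by-year effects
#'
#' Fits, by REML, the linear mixed model
#' \deqn{value = \mu + variety + u_{(location, year)} + residual}
#' with variety as a fixed effect and the location-by-year combination as
#' an iid Gaussian random effect, and returns the per-variety BLUEs
#' (intercept plus fixed variety effects). With a single environment the
#' environment effect is unidentifiable and the raw values are returned
#' unchanged. Setting \code{variety_as = "random"} instead returns BLUPs
#' (shrunken predictions).
#'
#' @param records data.frame slice of \code{\link{traitRecords}} for one
#'   trait (columns variety, location, year, value), or a
#'   \linkS4class{TraitTable} holding a single trait.
#' @param variety_as \code{"fixed"} (BLUEs, default) or \code{"random"}
#'   (BLUPs).
#' @return A \linkS4class{PhenotypeVector} with provenance
#'   \code{"env_adjusted"}.
#' @export
adjustEnv <- function(records, variety_as = c("fixed", "random")) {
  variety_as <- match.arg(variety_as)
  if (is(records, "TraitTable")) {
    stopifnot(length(unique(records@records$trait)) == 1)
    records <- traitRecords(records)
  }
  rec <- records[!is.na(records$value), , drop = FALSE]
  if (nrow(rec) < 2) stop("trait has fewer than two records")
  tr <- if ("trait" %in% names(rec)) unique(rec$trait)[1] else "trait"
  rec$env <- paste(rec$location, rec$year, sep = ":")
  n_env <- length(unique(rec$env))
  if (n_env == 1) {
    vals <- tapply(rec$value, rec$variety, mean)
    return(PhenotypeVector(setNames(as.numeric(vals), names(vals)), tr,
                           provenance = "env_adjusted"))
  }
  rec$variety <- factor(rec$variety)
  fit <- if (variety_as == "fixed")
    suppressWarnings(suppressMessages(
      lme4::lmer(value ~ 0 + variety + (1 | env), data = rec, REML = TRUE,
                 control = lme4::lmerControl(check.conv.singular =
                   lme4::.makeCC(action = "ignore", tol = 1e-4)))))
  else
    suppressWarnings(suppressMessages(
      lme4::lmer(value ~ 1 + (1 | variety) + (1 | env), data = rec,
                 REML = TRUE,
                 control = lme4::lmerControl(check.conv.singular =
                   lme4::.makeCC(action = "ignore", tol = 1e-4)))))
  if (variety_as == "fixed") {
    be <- lme4::fixef(fit)
    vals <- setNames(as.numeric(be), sub("^variety", "", names(be)))
  } else {
    blup <- lme4::ranef(fit)$variety
    vals <- setNames(lme4::fixef(fit)[["(Intercept)"]] + blup[, 1],
                     rownames(blup))
  }
  PhenotypeVector(vals[levels(rec$variety)], tr,
                  provenance = "env_adjusted")
}

#' Standardize a phenotype to mean 0, standard deviation 1
#'
#' Plain z-scoring. Mixed-model Wald p-values are invariant under this
#' affine transformation of the phenotype; effect estimates are rescaled
#' by 1/SD, which makes SNP effects directly comparable across traits.
#' Idempotent.
#'
#' @param vector A \linkS4class{PhenotypeVector} (non-constant).
#' @return A \linkS4class{PhenotypeVector} with provenance
#'   \code{"standardized"}.
#' @export
standardize <- function(vector) {
  stopifnot(is(vector, "PhenotypeVector"))
  v <- phenoValues(vector)
  ok <- !is.na(v)
  if (sd(v[ok]) == 0) stop("constant phenotype")
  z <- v
  z[ok] <- (v[ok] - mean(v[ok])) / sd(v[ok])
  PhenotypeVector(z, vector@traitName, type = vector@type,
                  provenance = "standardized")
}

#' Pairwise Pearson correlations between traits
#'
#' Values are first aggregated to one value per variety per trait
#' (mean over environments); correlations use pairwise-complete
#' observations. Cells with fewer than 3 complete pairs are set NA.
#'
#' @param table A \linkS4class{TraitTable}.
#' @param traits character vector of trait names (default: all).
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
traitCorrelations <- function(table, traits = NULL) {
  rec <- traitRecords(table)
  if (is.null(traits)) traits <- unique(rec$trait)
  vars <- sort(unique(rec$variety))
  M <- matrix(NA_real_, length(vars), length(traits),
              dimnames = list(vars, traits))
  for (tr in traits) {
    sl <- rec[rec$trait == tr & !is.na(rec$value), ]
    if (!nrow(sl)) next
    mu <- tapply(sl$value, sl$variety, mean)
    M[names(mu), tr] <- mu
  }
  R <- suppressWarnings(cor(M, use = "pairwise.complete.obs"))
  npair <- crossprod(!is.na(M))
  R[npair < 3] <- NA
  diag(R) <- 1
  R
}
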