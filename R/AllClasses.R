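#' @import methods
#' @importClassesFrom SummarizedExperiment RangedSummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#'   rowRanges
#' @importFrom GenomicRanges GRanges seqnames
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors mcols DataFrame
#' @importFrom stats var sd cor median quantile rnorm rbinom runif optimize
#'   pf pchisq qchisq ppoints prcomp aov TukeyHSD anova ptukey complete.cases
#'   setNames aggregate
#' @importFrom utils read.table write.table head
NULL

#' GenotypePanel: a marker-by-variety dosage matrix with marker coordinates
#'
#' The central genotype container. It extends
#' \linkS4class{RangedSummarizedExperiment}: rows are biallelic markers
#' (SNPs or INDELs) carried as a \link[GenomicRanges]{GRanges} with
#' \code{id}, \code{ref} and \code{alt} metadata columns, columns are
#' varieties, and the single assay \code{"dosage"} holds alternate-allele
#' dosages. Raw panels hold dosages in \{0, 1, 2, NA\}; after
#' \code{\link{imputeMissing}} entries are real numbers in [0, 2].
#'
#' Markers are always sorted by (chromosome, position) and variety labels
#' are unique; both are enforced by the validity method.
#'
#' @seealso \code{\link{GenotypePanel}} (constructor),
#'   \code{\link{dosageMatrix}}, \code{\link{markerInfo}},
#'   \code{\link{readVCF}}, \code{\link{qcFilter}}
#' @export
setClass("GenotypePanel", contains = "RangedSummarizedExperiment")

setValidity("GenotypePanel", function(object) {
  msg <- character()
  if (!"dosage" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'dosage' is required")
  rr <- SummarizedExperiment::rowRanges(object)
  need <- c("id", "ref", "alt")
  if (!all(need %in% colnames(S4Vectors::mcols(rr))))
    msg <- c(msg, "rowRanges must carry mcols id, ref, alt")
  else {
    if (anyDuplicated(S4Vectors::mcols(rr)$id))
      msg <- c(msg, "marker ids must be unique")
    if (any(S4Vectors::mcols(rr)$ref == S4Vectors::mcols(rr)$alt))
      msg <- c(msg, "ref and alt alleles must differ")
  }
  if (anyDuplicated(colnames(object)))
    msg <- c(msg, "variety labels must be unique")
  if (length(rr) > 1L) {
    ord <- order(as.character(GenomicRanges::seqnames(rr)),
                 GenomicRanges::start(rr))
    if (!identical(ord, seq_along(rr)))
      msg <- c(msg, "markers must be sorted by (chrom, pos)")
  }
  d <- SummarizedExperiment::assay(object, "dosage")
  dn <- d[!is.na(d)]
  if (length(dn) && (min(dn) < 0 || max(dn) > 2))
    msg <- c(msg, "dosages must lie in [0, 2]")
  if (length(msg)) msg else TRUE
})

#' Construct a GenotypePanel
#'
#' @param markers data.frame with columns \code{id}, \code{chrom},
#'   \code{pos} (1-based bp), \code{ref}, \code{alt}.
#' @param varieties character vector of unique variety labels.
#' @param dosages numeric matrix, varieties x markers, entries in
#'   \{0, 1, 2, NA\} (or reals in [0, 2] for an imputed panel).
#' @return A \linkS4class{GenotypePanel}. Markers are re-sorted by
#'   (chrom, pos) if needed.
#' @examples
#' mk <- data.frame(id = c("c1_10", "c1_20"), chrom = "1", pos = c(10, 20),
#'                  ref = "A", alt = "G")
#' gp <- GenotypePanel(mk, c("v1", "v2"), matrix(c(0, 2, 1, NA), 2, 2))
#' dim(gp)
#' @export
GenotypePanel <- function(markers, varieties, dosages) {
  stopifnot(is.data.frame(markers),
            all(c("id", "chrom", "pos", "ref", "alt") %in% names(markers)))
  dosages <- as.matrix(dosages)
  if (nrow(dosages) != length(varieties) || ncol(dosages) != nrow(markers))
    stop("dosage matrix must be varieties x markers")
  ord <- order(as.character(markers$chrom), markers$pos)
  markers <- markers[ord, , drop = FALSE]
  dosages <- dosages[, ord, drop = FALSE]
  dimnames(dosages) <- NULL
  rr <- GenomicRanges::GRanges(
    seqnames = as.character(markers$chrom),
    ranges = IRanges::IRanges(start = markers$pos,
                              width = pmax(nchar(markers$ref), 1L)),
    id = as.character(markers$id),
    ref = as.character(markers$ref),
    alt = as.character(markers$alt))
  names(rr) <- as.character(markers$id)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(dosage = t(dosages)),
    rowRanges = rr,
    colData = S4Vectors::DataFrame(row.names = varieties))
  new("GenotypePanel", se)
}

#' @describeIn GenotypePanel Varieties-by-markers dosage matrix (transposed
#'   from the internal markers-by-varieties assay).
#' @param panel A GenotypePanel.
#' @export
dosageMatrix <- function(panel) {
  stopifnot(is(panel, "GenotypePanel"))
  t(SummarizedExperiment::assay(panel, "dosage"))
}

#' @describeIn GenotypePanel Marker metadata as a data.frame with columns
#'   id, chrom, pos, ref, alt.
#' @export
markerInfo <- function(panel) {
  rr <- SummarizedExperiment::rowRanges(panel)
  data.frame(id = S4Vectors::mcols(rr)$id,
             chrom = as.character(GenomicRanges::seqnames(rr)),
             pos = GenomicRanges::start(rr),
             ref = S4Vectors::mcols(rr)$ref,
             alt = S4Vectors::mcols(rr)$alt,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' @describeIn GenotypePanel Variety labels.
#' @export
varieties <- function(panel) colnames(panel)

setMethod("show", "GenotypePanel", function(object) {
  d <- SummarizedExperiment::assay(object, "dosage")
  miss <- mean(is.na(d))
  cat(sprintf("GenotypePanel: %d markers x %d varieties (%.1f%% missing)\n",
              nrow(object), ncol(object), 100 * miss))
  chr <- table(as.character(GenomicRanges::seqnames(
    SummarizedExperiment::rowRanges(object))))
  cat("  chromosomes:", paste(names(chr), collapse = ", "), "\n")
})

#' TraitTable: long-format phenotype records
#'
#' Holds one record per (variety, trait, location, year) with a numeric
#' value, plus a per-trait type designation (\code{"quantitative"} or
#' \code{"binary"}). Binary traits must be coded 0/1. Keys must be unique.
#'
#' @seealso \code{\link{TraitTable}} (constructor),
#'   \code{\link{traitRecords}}, \code{\link{traitTypes}},
#'   \code{\link{readTraitTable}}
#' @export
setClass("TraitTable",
         representation(records = "data.frame", traitTypes = "character"))

setValidity("TraitTable", function(object) {
  msg <- character()
  rec <- object@records
  need <- c("variety", "trait", "location", "year", "value")
  if (!all(need %in% names(rec)))
    return("records must have columns variety, trait, location, year, value")
  key <- paste(rec$variety, rec$trait, rec$location, rec$year, sep = "\r")
  if (anyDuplicated(key))
    msg <- c(msg, "duplicate (variety, trait, location, year) keys")
  tt <- object@traitTypes
  if (!all(tt %in% c("quantitative", "binary")))
    msg <- c(msg, "trait types must be 'quantitative' or 'binary'")
  if (!all(unique(rec$trait) %in% names(tt)))
    msg <- c(msg, "every trait needs a type designation")
  for (tr in names(tt)[tt == "binary"]) {
    v <- rec$value[rec$trait == tr]
    if (!all(v[!is.na(v)] %in% c(0, 1)))
      msg <- c(msg, sprintf("binary trait '%s' has values outside {0,1}", tr))
  }
  if (length(msg)) msg else TRUE
})

#' Construct a TraitTable
#'
#' @param records data.frame with columns variety, trait, location, year,
#'   value.
#' @param traitTypes named character vector mapping each trait to
#'   \code{"quantitative"} or \code{"binary"}.
#' @return A \linkS4class{TraitTable}.
#' @export
TraitTable <- function(records, traitTypes) {
  records <- as.data.frame(records)
  records$variety <- as.character(records$variety)
  records$trait <- as.character(records$trait)
  records$location <- as.character(records$location)
  new("TraitTable", records = records, traitTypes = traitTypes)
}

#' @describeIn TraitTable The record data.frame, optionally restricted to
#'   one trait.
#' @param x A TraitTable.
#' @param trait Optional trait name to subset to.
#' @export
traitRecords <- function(x, trait = NULL) {
  rec <- x@records
  if (!is.null(trait)) {
    if (!trait %in% rec$trait) stop("unknown trait: ", trait)
    rec <- rec[rec$trait == trait, , drop = FALSE]
  }
  rec
}

#' @describeIn TraitTable Named character vector of trait type
#'   designations.
#' @export
traitTypes <- function(x) x@traitTypes

setMethod("show", "TraitTable", function(object) {
  cat(sprintf("TraitTable: %d records, %d traits, %d varieties\n",
              nrow(object@records), length(unique(object@records$trait)),
              length(unique(object@records$variety))))
  for (tr in names(object@traitTypes))
    cat(sprintf("  %s (%s): n=%d\n", tr, object@traitTypes[[tr]],
                sum(object@records$trait == tr)))
})

#' PhenotypeVector: one analysis-ready phenotype per variety
#'
#' A named numeric vector of per-variety values for a single trait,
#' together with the trait name, its type and a provenance tag recording
#' how the values were produced (\code{"raw"}, \code{"env_adjusted"},
#' \code{"standardized"} or \code{"binarized"}).
#'
#' @seealso \code{\link{adjustEnv}}, \code{\link{standardize}},
#'   \code{\link{binarize}}
#' @export
setClass("PhenotypeVector",
         representation(values = "numeric", traitName = "character",
                        type = "character", provenance = "character"))

setValidity("PhenotypeVector", function(object) {
  msg <- character()
  if (is.null(names(object@values)) || anyDuplicated(names(object@values)))
    msg <- c(msg, "values must be named by unique varieties")
  if (!object@type %in% c("quantitative", "binary"))
    msg <- c(msg, "type must be 'quantitative' or 'binary'")
  if (!object@provenance %in% c("raw", "env_adjusted", "standardized",
                                "binarized"))
    msg <- c(msg, "unknown provenance")
  v <- object@values[!is.na(object@values)]
  if (object@type == "binary" && object@provenance != "standardized" &&
      !all(v %in% c(0, 1)))
    msg <- c(msg, "binary phenotype must be coded 0/1")
  if (object@provenance == "standardized" && length(v) > 1) {
    if (abs(mean(v)) > 1e-8 || abs(sd(v) - 1) > 1e-6)
      msg <- c(msg, "standardized phenotype must have mean 0, sd 1")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a PhenotypeVector
#'
#' @param values named numeric vector (names are variety labels).
#' @param traitName trait label.
#' @param type \code{"quantitative"} or \code{"binary"}.
#' @param provenance one of \code{"raw"}, \code{"env_adjusted"},
#'   \code{"standardized"}, \code{"binarized"}.
#' @return A \linkS4class{PhenotypeVector}.
#' @export
PhenotypeVector <- function(values, traitName, type = "quantitative",
                            provenance = "raw") {
  new("PhenotypeVector", values = values, traitName = traitName,
      type = type, provenance = provenance)
}

#' @describeIn PhenotypeVector The named value vector.
#' @param x A PhenotypeVector.
#' @export
phenoValues <- function(x) x@values

#' @describeIn PhenotypeVector The provenance tag.
#' @export
provenance <- function(x) x@provenance

setMethod("show", "PhenotypeVector", function(object) {
  cat(sprintf("PhenotypeVector '%s' (%s, %s): n=%d, mean=%.3g\n",
              object@traitName, object@type, object@provenance,
              length(object@values), mean(object@values, na.rm = TRUE)))
})

#' ScanResult: per-marker association output
#'
#' One row per marker of the scanned panel: effect estimate \code{beta}
#' (trait units per alternate allele), standard error, test statistic,
#' p-value, \code{minus_log10_p}, the number of varieties used, and an
#' exclusion flag with reason for markers not tested (collinear with
#' covariates, used for conditioning, or a perfect proxy of a
#' conditioning marker).
#'
#' @seealso \code{\link{scanQuantitative}}, \code{\link{scanBinary}},
#'   \code{\link{conditionalScan}}, \code{\link{scanTable}}
#' @export
setClass("ScanResult",
         representation(table = "data.frame", meta = "list"))

setValidity("ScanResult", function(object) {
  tab <- object@table
  need <- c("id", "chrom", "pos", "beta", "se", "stat", "p",
            "minus_log10_p", "n_used", "excluded", "excluded_reason")
  if (!all(need %in% names(tab)))
    return(paste("missing columns:", paste(setdiff(need, names(tab)),
                                           collapse = ", ")))
  ok <- !tab$excluded & !is.na(tab$p)
  msg <- character()
  if (any(tab$p[ok] <= 0 | tab$p[ok] > 1))
    msg <- c(msg, "p-values must lie in (0, 1]")
  if (any(abs(tab$minus_log10_p[ok] + log10(tab$p[ok])) > 1e-12))
    msg <- c(msg, "minus_log10_p must equal -log10(p)")
  if (any(!is.na(tab$p[tab$excluded])))
    msg <- c(msg, "excluded markers must carry no p-value")
  if (length(msg)) msg else TRUE
})

ScanResult <- function(table, meta = list()) {
  new("ScanResult", table = table, meta = meta)
}

#' Extract the per-marker table from a ScanResult
#'
#' @param x A \linkS4class{ScanResult}.
#' @return data.frame with columns id, chrom, pos, beta, se, stat, p,
#'   minus_log10_p, n_used, excluded, excluded_reason.
#' @export
scanTable <- function(x) x@table

#' @describeIn scanTable Scan metadata (model, covariate labels, p3d flag,
#'   null-model variance components).
#' @export
scanMeta <- function(x) x@meta

setMethod("show", "ScanResult", function(object) {
  tab <- object@table
  ok <- !tab$excluded
  cat(sprintf("ScanResult: %d markers (%d tested), n=%d\n",
              nrow(tab), sum(ok), tab$n_used[1]))
  if (any(ok)) {
    top <- tab[ok, ][which.max(tab$minus_log10_p[ok]), ]
    cat(sprintf("  top: %s (chr %s pos %d)  -log10 p = %.2f\n",
                top$id, top$chrom, top$pos, top$minus_log10_p))
  }
})
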