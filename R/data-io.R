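#' Read a VCF file into a GenotypePanel
#'
#' Loads biallelic records from a VCF (v4.x) with per-sample GT fields.
#' Genotypes are converted to alternate-allele dosages: 0/0 -> 0, 0/1 or
#' 1/0 -> 1, 1/1 -> 2, ./. -> missing; phased separators are accepted.
#' Multi-allelic records (ALT containing a comma) are skipped with one
#' warning reporting the count.
#'
#' @param path path to a VCF file (plain or bgzipped).
#' @return A \linkS4class{GenotypePanel}.
#' @seealso \code{\link{writeVCF}}, \code{\link{qcFilter}}
#' @export
readVCF <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  if (nrow(fix) == 0) stop("no variant records in ", path)
  gt <- v@gt
  if (is.null(gt) || ncol(gt) < 2) stop("VCF has no sample genotypes")
  multi <- grepl(",", fix[, "ALT"], fixed = TRUE)
  if (any(multi)) {
    warning(sum(multi), " multi-allelic record(s) skipped")
    fix <- fix[!multi, , drop = FALSE]
    gt <- gt[!multi, , drop = FALSE]
  }
  if (nrow(fix) == 0) stop("no biallelic records in ", path)
  samples <- colnames(gt)[-1]
  gtf <- sub(":.*", "", gt[, -1, drop = FALSE])
  gtf <- gsub("|", "/", gtf, fixed = TRUE)
  code <- c("0/0" = 0, "0/1" = 1, "1/0" = 1, "1/1" = 2)
  dos <- matrix(unname(code[gtf]), nrow = nrow(fix))  # others -> NA
  ids <- fix[, "ID"]
  bad <- is.na(ids) | ids == "."
  ids[bad] <- paste0(fix[bad, "CHROM"], "_", fix[bad, "POS"])
  mk <- data.frame(id = ids, chrom = fix[, "CHROM"],
                   pos = as.integer(fix[, "POS"]), ref = fix[, "REF"],
                   alt = fix[, "ALT"], stringsAsFactors = FALSE)
  message("readVCF: ", nrow(mk), " biallelic markers, ",
          length(samples), " samples")
  GenotypePanel(mk, samples, t(dos))
}

#' Write a GenotypePanel as minimal VCFv4.2
#'
#' Emits CHROM, POS, ID, REF, ALT and per-sample GT only. Dosages must be
#' integer-coded (0/1/2/NA); an imputed panel with fractional dosages
#' cannot be encoded as genotypes and raises an error.
#'
#' @param panel A \linkS4class{GenotypePanel}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeVCF <- function(panel, path) {
  X <- dosageMatrix(panel)                 # varieties x markers
  if (any(!is.na(X) & X != round(X)))
    stop("panel contains non-integer dosages; write before imputation")
  info <- markerInfo(panel)
  gt_code <- c("0/0", "0/1", "1/1")
  enc <- function(j) {
    g <- X[, j]
    out <- ifelse(is.na(g), "./.", gt_code[g + 1L])
    paste(out, collapse = "\t")
  }
  body <- vapply(seq_len(nrow(info)), function(j)
    paste(info$chrom[j], info$pos[j], info$id[j], info$ref[j], info$alt[j],
          ".", "PASS", ".", "GT", enc(j), sep = "\t"), character(1))
  header <- c("##fileformat=VCFv4.2",
              '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                      "FILTER", "INFO", "FORMAT", varieties(panel)),
                    collapse = "\t"))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Marker quality control: missingness and minor allele frequency
#'
#' Drops markers whose missing rate is greater than or equal to
#' \code{max_missing} (inclusive boundary) or whose minor allele
#' frequency is strictly below \code{min_maf}. MAF is computed from
#' non-missing dosages as min(p, 1 - p) with p = mean(dosage) / 2.
#' Idempotent: a second application removes nothing.
#'
#' @param panel A \linkS4class{GenotypePanel}.
#' @param max_missing missing-rate cutoff (default 0.1); markers with
#'   missing rate >= this value are removed.
#' @param min_maf MAF cutoff (default 0.05); markers with MAF < this
#'   value are removed (MAF exactly at the cutoff is retained).
#' @return The filtered \linkS4class{GenotypePanel}.
#' @export
qcFilter <- function(panel, max_missing = 0.1, min_maf = 0.05) {
  X <- dosageMatrix(panel)
  miss <- colMeans(is.na(X))
  p <- colMeans(X, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  maf[is.nan(maf)] <- 0                 # all-missing marker
  keep <- miss < max_missing & maf >= min_maf
  if (!any(keep)) stop("empty panel after QC")
  message("qcFilter: kept ", sum(keep), " of ", length(keep), " markers")
  info <- markerInfo(panel)
  GenotypePanel(info[keep, , drop = FALSE], varieties(panel),
                X[, keep, drop = FALSE])
}

#' Replace missing dosages by per-marker means
#'
#' Mean imputation keeps the scan sample and kinship estimate fixed
#' across markers; imputed entries are real numbers in [0, 2], which all
#' downstream model fits accept.
#'
#' @param panel A \linkS4class{GenotypePanel} (normally post-QC).
#' @return The panel with no missing entries.
#' @export
imputeMissing <- function(panel) {
  X <- dosageMatrix(panel)
  if (!anyNA(X)) return(panel)
  mu <- colMeans(X, na.rm = TRUE)
  if (anyNA(mu)) stop("marker with all entries missing")
  idx <- which(is.na(X), arr.ind = TRUE)
  X[idx] <- mu[idx[, 2]]
  GenotypePanel(markerInfo(panel), varieties(panel), X)
}

#' Intersect the marker sets of two panels
#'
#' Markers are matched on (chrom, pos); alleles must agree as sets.
#' Sites whose ref and alt are swapped between panels are matched with
#' \code{strand_flip = TRUE}: panel-B dosage at such a site is to be read
#' as \code{2 - dosage}. Same-position sites with irreconcilable alleles
#' are dropped and counted in a message.
#'
#' @param panelA,panelB Two \linkS4class{GenotypePanel}s.
#' @return A data.frame (class \code{"SharedMarkerMap"}) with columns
#'   \code{index_A}, \code{index_B}, \code{id_A}, \code{id_B},
#'   \code{chrom}, \code{pos}, \code{strand_flip}.
#' @export
intersectMarkers <- function(panelA, panelB) {
  a <- markerInfo(panelA)
  b <- markerInfo(panelB)
  key_a <- paste(a$chrom, a$pos)
  key_b <- paste(b$chrom, b$pos)
  j <- match(key_a, key_b)
  hit <- which(!is.na(j))
  same <- a$ref[hit] == b$ref[j[hit]] & a$alt[hit] == b$alt[j[hit]]
  flip <- a$ref[hit] == b$alt[j[hit]] & a$alt[hit] == b$ref[j[hit]]
  ok <- same | flip
  if (any(!ok))
    message("intersectMarkers: ", sum(!ok),
            " same-position site(s) with mismatched alleles dropped")
  hit <- hit[ok]
  out <- data.frame(index_A = hit, index_B = j[hit],
                    id_A = a$id[hit], id_B = b$id[j[hit]],
                    chrom = a$chrom[hit], pos = a$pos[hit],
                    strand_flip = flip[ok], stringsAsFactors = FALSE)
  class(out) <- c("SharedMarkerMap", "data.frame")
  out
}

#' Read or write a long-format trait table TSV
#'
#' The TSV has a header line \code{variety  trait  location  year  value}.
#' On read, trait types are taken from \code{traitTypes} if supplied and
#' otherwise inferred per trait with \code{\link{classifyTraitType}}
#' (falling back to \code{"quantitative"} for traits with too few
#' records to classify).
#'
#' @param path file path.
#' @param traitTypes optional named character vector of designations.
#' @return \code{readTraitTable}: a \linkS4class{TraitTable}.
#' @export
readTraitTable <- function(path, traitTypes = NULL) {
  rec <- read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
  if (is.null(traitTypes)) {
    traitTypes <- vapply(unique(rec$trait), function(tr) {
      v <- rec$value[rec$trait == tr]
      v <- v[!is.na(v)]
      if (length(v) < 10 || length(unique(v)) < 2) "quantitative"
      else classifyTraitType(v)
    }, character(1))
  }
  message("readTraitTable: ", nrow(rec), " records")
  TraitTable(rec, traitTypes)
}

#' @rdname readTraitTable
#' @param x A \linkS4class{TraitTable}.
#' @return \code{writeTraitTable}: \code{path}, invisibly.
#' @export
writeTraitTable <- function(x, path) {
  write.table(traitRecords(x), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
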