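#' Build and validate a pipeline run configuration
#'
#' @param scenario simulation scenario for the two-panel demo:
#'   \code{"shared_qtl"}, \code{"distinct_qtl"} or \code{"null"}.
#' @param seed global seed.
#' @param out_dir output directory (created if absent).
#' @param sim named list of \code{\link{simConfig}} overrides.
#' @param qc named list: \code{max_missing}, \code{min_maf}.
#' @param scan named list: \code{p3d}.
#' @param meff named list: \code{window_size}, \code{variance_fraction}.
#' @param peaks named list: \code{merge_gap}, \code{pad},
#'   \code{call_alpha}.
#' @param identity named list: \code{r2_min},
#'   \code{attenuation_fraction}, \code{overlap_varieties},
#'   \code{overlap_markers}, \code{h2_qtl}.
#' @return validated list of class \code{"RunConfig"}; unknown keys in
#'   any section are rejected.
#' @export
runConfig <- function(scenario = "shared_qtl", seed = 1,
                      out_dir = tempfile("gwasrun"), sim = list(),
                      qc = list(), scan = list(), meff = list(),
                      peaks = list(), identity = list()) {
  chk <- function(x, allowed, what) {
    bad <- setdiff(names(x), allowed)
    if (length(bad)) stop("unknown ", what, " key(s): ",
                          paste(bad, collapse = ", "))
    x
  }
  defaults <- list(
    scenario = match.arg(scenario, c("shared_qtl", "distinct_qtl", "null")),
    seed = as.integer(seed), out_dir = out_dir,
    sim = chk(sim, names(formals(simConfig)), "sim"),
    qc = utils::modifyList(list(max_missing = 0.1, min_maf = 0.05),
                           chk(qc, c("max_missing", "min_maf"), "qc")),
    scan = utils::modifyList(list(p3d = TRUE), chk(scan, "p3d", "scan")),
    meff = utils::modifyList(list(window_size = 200,
                                  variance_fraction = 0.995),
                             chk(meff, c("window_size",
                                         "variance_fraction"), "meff")),
    peaks = utils::modifyList(list(merge_gap = 300000, pad = 100000,
                                   call_alpha = 0.1),
                              chk(peaks, c("merge_gap", "pad",
                                           "call_alpha"), "peaks")),
    identity = utils::modifyList(list(r2_min = 0.4,
                                      attenuation_fraction = 0.5,
                                      overlap_varieties = 0.5,
                                      overlap_markers = 0.7,
                                      h2_qtl = 0.3),
                                 chk(identity, c("r2_min",
                                                 "attenuation_fraction",
                                                 "overlap_varieties",
                                                 "overlap_markers",
                                                 "h2_qtl"), "identity")))
  structure(defaults, class = "RunConfig")
}

#' Manhattan-plot-ready table from a scan
#'
#' Rows are tested markers sorted by a cumulative genome coordinate
#' (each chromosome offset by the preceding chromosomes' maximum
#' position); threshold lines are appended as metadata rows with
#' \code{type = "threshold"}.
#'
#' @param scan A \linkS4class{ScanResult}.
#' @param thresholds A \code{"ThresholdSet"} (optional).
#' @return data.frame with columns type, chrom, pos, cum_pos, id,
#'   minus_log10_p, alpha; attribute \code{"n_excluded"} counts markers
#'   left out.
#' @export
manhattanData <- function(scan, thresholds = NULL) {
  tab <- scanTable(scan)
  keep <- !tab$excluded & !is.na(tab$minus_log10_p)
  tab <- tab[keep, , drop = FALSE]
  tab <- tab[order(tab$chrom, tab$pos), ]
  offs <- 0
  tab$cum_pos <- NA_real_
  for (ch in unique(tab$chrom)) {
    i <- tab$chrom == ch
    tab$cum_pos[i] <- tab$pos[i] + offs
    offs <- offs + max(tab$pos[i])
  }
  out <- data.frame(type = "marker", chrom = tab$chrom, pos = tab$pos,
                    cum_pos = tab$cum_pos, id = tab$id,
                    minus_log10_p = tab$minus_log10_p, alpha = NA_real_,
                    stringsAsFactors = FALSE)
  if (!is.null(thresholds)) {
    out <- rbind(out, data.frame(
      type = "threshold", chrom = NA, pos = NA, cum_pos = NA,
      id = NA, minus_log10_p = as.numeric(thresholds$cutoffs),
      alpha = thresholds$alpha_levels, stringsAsFactors = FALSE))
  }
  attr(out, "n_excluded") <- sum(!keep)
  out
}

.writeScanTSV <- function(scan, path) {
  tab <- scanTable(scan)
  num <- vapply(tab, is.numeric, logical(1))
  tab[num] <- lapply(tab[num], signif, digits = 12)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Run the full cross-cohort identity-test pipeline on simulated panels
#'
#' Orchestrates simulate -> QC -> impute -> kinship -> scans ->
#' SimpleM thresholds -> peak calling -> identity test for the
#' configured two-panel scenario, writing per-stage outputs (scan TSVs,
#' Manhattan and Q-Q tables, M_eff JSON, peak BED, verdict JSON, run
#' manifest) under \code{config$out_dir}. Output is deterministic given
#' the config (no timestamps are written).
#'
#' @param config A \code{\link{runConfig}}.
#' @return the run directory path, invisibly; the primary verdict (or
#'   NULL when no peak was called) is attached as attribute
#'   \code{"verdict"}.
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "RunConfig"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  od <- function(...) file.path(config$out_dir, ...)
  scfg <- do.call(simConfig, utils::modifyList(config$sim,
                                               list(seed = config$seed)))
  sim <- simulateTwoPanels(scfg, scenario = config$scenario,
                           overlap_varieties =
                             config$identity$overlap_varieties,
                           overlap_markers =
                             config$identity$overlap_markers,
                           seed = config$seed,
                           h2_qtl = config$identity$h2_qtl)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      writeLines(paste0("FAILED at stage ", name, ": ",
                        conditionMessage(e)), od("FAILED"))
      stop("[", name, "] ", conditionMessage(e), call. = FALSE)
    })
  }
  panels <- stage("qc", lapply(list(A = sim$panel_A, B = sim$panel_B),
    function(p) imputeMissing(qcFilter(p, config$qc$max_missing,
                                       config$qc$min_maf))))
  yA <- setNames(traitRecords(sim$trait_A)$value,
                 traitRecords(sim$trait_A)$variety)
  yB <- setNames(traitRecords(sim$trait_B)$value,
                 traitRecords(sim$trait_B)$variety)
  KA <- stage("kinship", computeKinship(panels$A))
  KB <- stage("kinship", computeKinship(panels$B))
  scanA <- stage("scan", scanQuantitative(panels$A, yA, K = KA,
                                          p3d = config$scan$p3d))
  scanB <- stage("scan", scanQuantitative(panels$B, yB, K = KB,
                                          p3d = config$scan$p3d))
  meffA <- stage("meff", simpleM(panels$A, config$meff$window_size,
                                 config$meff$variance_fraction))
  thrA <- gwasThresholds(meffA)
  pk <- stage("peaks", callPeaks(scanA,
                                 .cutoffAt(thrA, config$peaks$call_alpha),
                                 config$peaks$merge_gap, config$peaks$pad))
  for (lab in c("A", "B")) {
    sc <- if (lab == "A") scanA else scanB
    .writeScanTSV(sc, od(paste0("scan_", lab, ".tsv")))
    md <- manhattanData(sc, thrA)
    write.table(md, od(paste0("manhattan_", lab, ".tsv")), sep = "\t",
                quote = FALSE, row.names = FALSE)
    qq <- inflation(sc)
    write.table(data.frame(lapply(qq$qq, signif, 12)),
                od(paste0("qq_", lab, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  jsonlite::write_json(list(M_eff = meffA$M_eff,
                            per_chromosome = as.list(meffA$per_chromosome),
                            window_size = meffA$window_size,
                            variance_fraction = meffA$variance_fraction,
                            thresholds = as.list(thrA$cutoffs)),
                       od("meff_A.json"), auto_unbox = TRUE, digits = NA)
  writePeaksBED(pk, od("peaks_A.bed"))
  verdict <- NULL
  if (nrow(pk)) {
    region <- pk[which.max(pk$top_minus_log10_p), ]
    smap <- intersectMarkers(panels$A, panels$B)
    tb <- scanTable(scanB)
    tb <- tb[!tb$excluded & !is.na(tb$minus_log10_p), ]
    top_B <- tb$id[which.max(tb$minus_log10_p)]
    verdict <- stage("identity", tryCatch({
      m1 <- method1(panels$A, yA, KA, region, top_B, smap, thrA,
                    panel_B = panels$B, scan_A = scanA,
                    attenuation_fraction =
                      config$identity$attenuation_fraction)
      m2 <- method2(scanA, scanB, region, smap)
      combineVerdict(m1, m2, config$identity$r2_min)
    }, error = function(e) {
      message("identity test not evaluable: ", conditionMessage(e))
      NULL
    }))
    if (!is.null(verdict)) writeVerdictJSON(verdict, od("verdict.json"))
  }
  cfg_path <- od("config.json")
  jsonlite::write_json(unclass(config), cfg_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  # hash the config minus the output path, so identical analyses hash
  # identically regardless of where they are written
  cfg_core <- unclass(config)
  cfg_core$out_dir <- NULL
  core_path <- tempfile(fileext = ".json")
  jsonlite::write_json(cfg_core, core_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  jsonlite::write_json(
    list(package = "crossGWAS",
         version = as.character(utils::packageVersion("crossGWAS")),
         seed = config$seed, scenario = config$scenario,
         config_md5 = unname(tools::md5sum(core_path)),
         n_markers_A = nrow(panels$A), n_markers_B = nrow(panels$B),
         n_varieties = ncol(panels$A), n_peaks = nrow(pk),
         verdict = if (is.null(verdict)) NA else verdict$verdict),
    od("manifest.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
  structure(invisible(config$out_dir), verdict = verdict)
}
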