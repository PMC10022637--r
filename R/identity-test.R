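#' Method 1 of the peak identity test: conditional peak disappearance
#'
#' Re-runs the association scan of panel A with the other study's top
#' marker included as a fixed effect. If the panel-A peak is driven by
#' the same QTL, including that marker removes its explainability and
#' the peak disappears. Status is judged against the lenient genome-wide
#' cutoff (alpha = 0.2): \code{disappeared} if the conditional maximum
#' over the region falls below it, \code{attenuated} if it stays above
#' but drops by at least \code{attenuation_fraction} of the
#' unconditional maximum, else \code{persisted}.
#'
#' When \code{top_marker_B} itself is absent from panel A, the shared
#' marker with the highest |r| to it in panel B is substituted
#' (requiring |r| >= \code{proxy_r_min}); this needs \code{panel_B}.
#'
#' @param panel_A imputed \linkS4class{GenotypePanel} of the study being
#'   re-scanned.
#' @param y_A phenotype for panel A (named vector or
#'   \linkS4class{PhenotypeVector}).
#' @param K_A kinship for panel A (computed when NULL).
#' @param region one row of \code{\link{callPeaks}} output (chrom,
#'   start, end in panel coordinates).
#' @param top_marker_B id of the top marker in the other study's scan.
#' @param shared_map \code{\link{intersectMarkers}} output for
#'   (panel_A, panel_B).
#' @param thresholds A \code{"ThresholdSet"}.
#' @param panel_B the other panel, needed only for the proxy fallback.
#' @param scan_A optional precomputed unconditional
#'   \linkS4class{ScanResult} for panel A (recomputed when NULL).
#' @param attenuation_fraction drop fraction separating attenuated from
#'   persisted (default 0.5).
#' @param proxy_r_min minimum |r| for the fallback proxy (default 0.8).
#' @return list of class \code{"Method1Outcome"}: region,
#'   conditioning_marker, unconditional_max, conditional_max, status.
#' @export
method1 <- function(panel_A, y_A, K_A = NULL, region, top_marker_B,
                    shared_map, thresholds, panel_B = NULL,
                    scan_A = NULL, attenuation_fraction = 0.5,
                    proxy_r_min = 0.8) {
  hit <- match(top_marker_B, shared_map$id_B)
  if (is.na(hit)) {
    if (is.null(panel_B))
      stop("conditioning marker not shared (no panel_B for proxy fallback)")
    GB <- dosageMatrix(imputeMissing(panel_B))
    jb <- match(top_marker_B, markerInfo(panel_B)$id)
    if (is.na(jb)) stop("conditioning marker not shared")
    r <- suppressWarnings(cor(GB[, shared_map$id_B, drop = FALSE],
                              GB[, jb]))
    best <- which.max(abs(r))
    if (!length(best) || is.na(r[best]) || abs(r[best]) < proxy_r_min)
      stop("conditioning marker not shared (no proxy with |r| >= ",
           proxy_r_min, ")")
    message("method1: substituting shared proxy ",
            shared_map$id_B[best], " (|r| = ", round(abs(r[best]), 3), ")")
    hit <- best
  }
  cond_id <- shared_map$id_A[hit]
  if (is.null(scan_A))
    scan_A <- scanQuantitative(panel_A, y_A, K = K_A)
  cscan <- conditionalScan(panel_A, y_A, K = K_A,
                           conditioning_markers = cond_id)
  inRegion <- function(tab)
    tab$chrom == region$chrom & tab$pos >= region$start &
      tab$pos < region$end
  ut <- scanTable(scan_A)
  ct <- scanTable(cscan)
  u_reg <- ut[inRegion(ut) & !ut$excluded & !is.na(ut$minus_log10_p), ]
  c_reg <- ct[inRegion(ct) & !ct$excluded & !is.na(ct$minus_log10_p), ]
  if (!nrow(c_reg)) stop("empty region after exclusions")
  u_max <- max(u_reg$minus_log10_p)
  c_max <- max(c_reg$minus_log10_p)
  lenient <- .cutoffAt(thresholds, 0.2)
  status <- if (c_max < lenient) "disappeared"
  else if (u_max - c_max >= attenuation_fraction * u_max) "attenuated"
  else "persisted"
  structure(list(region = region, conditioning_marker = cond_id,
                 unconditional_max = u_max, conditional_max = c_max,
                 status = status, lenient_cutoff = lenient),
            class = "Method1Outcome")
}

#' Method 2 of the peak identity test: correlation of -log10 P
#'
#' Over the markers inside the peak region that were tested in both
#' scans (matched through the shared-marker map), computes the squared
#' Pearson correlation of the paired -log10 p-values. Two scans of the
#' same underlying QTL produce strongly correlated local signal shapes.
#'
#' @param scan_A,scan_B \linkS4class{ScanResult}s for the two panels.
#' @param region one row of \code{\link{callPeaks}} output, on the
#'   shared coordinate system.
#' @param shared_map \code{\link{intersectMarkers}} output for
#'   (panel_A, panel_B).
#' @return list of class \code{"Method2Outcome"}: region, n_shared,
#'   r_squared, pairs (data.frame id_A, id_B, mlp_A, mlp_B).
#' @export
method2 <- function(scan_A, scan_B, region, shared_map) {
  ta <- scanTable(scan_A)
  tb <- scanTable(scan_B)
  sm <- shared_map[shared_map$chrom == region$chrom &
                     shared_map$pos >= region$start &
                     shared_map$pos < region$end, , drop = FALSE]
  ia <- match(sm$id_A, ta$id)
  ib <- match(sm$id_B, tb$id)
  ok <- !is.na(ia) & !is.na(ib) &
    !ta$excluded[ia] & !tb$excluded[ib] &
    !is.na(ta$minus_log10_p[ia]) & !is.na(tb$minus_log10_p[ib])
  pairs <- data.frame(id_A = sm$id_A[ok], id_B = sm$id_B[ok],
                      pos = sm$pos[ok],
                      mlp_A = ta$minus_log10_p[ia[ok]],
                      mlp_B = tb$minus_log10_p[ib[ok]],
                      stringsAsFactors = FALSE)
  if (nrow(pairs) < 3)
    stop("insufficient shared markers in region (n_shared = ",
         nrow(pairs), ")")
  r2 <- if (sd(pairs$mlp_A) == 0 || sd(pairs$mlp_B) == 0) 0
  else cor(pairs$mlp_A, pairs$mlp_B)^2
  structure(list(region = region, n_shared = nrow(pairs),
                 r_squared = r2, pairs = pairs),
            class = "Method2Outcome")
}

#' Combine Method 1 and Method 2 into an identity verdict
#'
#' Decision rule: \code{identical} when the peak disappeared and the
#' -log10 P correlation is high (R^2 >= r2_min); \code{partially_shared}
#' when the peak only attenuated but correlation is high (a peak shared
#' with an additional linked QTL); \code{distinct} when the peak
#' persisted and correlation is low; \code{inconclusive} otherwise.
#'
#' @param m1 A \code{"Method1Outcome"}.
#' @param m2 A \code{"Method2Outcome"} for the same region.
#' @param r2_min minimum R^2 accepted as a high correlation (default
#'   0.4).
#' @return list of class \code{"IdentityVerdict"}: method1, method2,
#'   verdict.
#' @export
combineVerdict <- function(m1, m2, r2_min = 0.4) {
  r1 <- m1$region; r2reg <- m2$region
  if (!identical(as.character(r1$chrom), as.character(r2reg$chrom)) ||
      r1$start != r2reg$start || r1$end != r2reg$end)
    stop("method 1 and method 2 outcomes refer to different regions")
  high <- m2$r_squared >= r2_min
  verdict <- if (m1$status == "disappeared" && high) "identical"
  else if (m1$status == "attenuated" && high) "partially_shared"
  else if (m1$status == "persisted" && !high) "distinct"
  else "inconclusive"
  structure(list(method1 = m1, method2 = m2, verdict = verdict,
                 r2_min = r2_min),
            class = "IdentityVerdict")
}

#' Serialize an identity verdict as a JSON record
#'
#' @param verdict An \code{"IdentityVerdict"}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeVerdictJSON <- function(verdict, path) {
  m1 <- verdict$method1; m2 <- verdict$method2
  obj <- list(region = list(chrom = as.character(m1$region$chrom),
                            start = m1$region$start, end = m1$region$end),
              conditioning_marker = m1$conditioning_marker,
              unconditional_max = m1$unconditional_max,
              conditional_max = m1$conditional_max,
              method1_status = m1$status,
              n_shared = m2$n_shared, r_squared = m2$r_squared,
              verdict = verdict$verdict)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
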