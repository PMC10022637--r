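#' SimpleM effective number of independent markers
#'
#' Addresses marker dependency when setting genome-wide thresholds.
#' Per chromosome, markers are processed in consecutive non-overlapping
#' windows of at most \code{window_size}; in each window the marker-by-
#' marker Pearson correlation matrix of dosages is eigendecomposed, and
#' the window's effective count is the smallest k such that the top-k
#' eigenvalues sum to at least \code{variance_fraction} of the total.
#' Chromosome counts are the sums over windows and \eqn{M_{eff}} is the
#' sum over chromosomes.
#'
#' @param panel An imputed \linkS4class{GenotypePanel}.
#' @param window_size markers per eigendecomposition window (default
#'   200); windows with a single marker contribute 1 directly.
#' @param variance_fraction fraction C of correlation variance the
#'   retained components must explain (default 0.995, following the
#'   original SimpleM recommendation).
#' @return list of class \code{"MeffResult"}: \code{M_eff},
#'   \code{per_chromosome} (named vector), \code{window_size},
#'   \code{variance_fraction}, \code{n_markers}.
#' @export
simpleM <- function(panel, window_size = 200, variance_fraction = 0.995) {
  X <- dosageMatrix(panel)
  if (anyNA(X)) stop("panel must be imputed")
  info <- markerInfo(panel)
  chroms <- unique(info$chrom)
  per <- setNames(numeric(length(chroms)), chroms)
  for (ch in chroms) {
    cols <- which(info$chrom == ch)
    starts <- seq(1, length(cols), by = window_size)
    eff <- 0L
    for (s in starts) {
      w <- cols[s:min(s + window_size - 1, length(cols))]
      if (length(w) < 2) { eff <- eff + length(w); next }
      Xi <- X[, w, drop = FALSE]
      sds <- apply(Xi, 2, sd)
      const <- sds == 0
      eff <- eff + sum(const)     # constant markers carry no correlation
      Xi <- Xi[, !const, drop = FALSE]
      if (ncol(Xi) == 0) next
      if (ncol(Xi) == 1) { eff <- eff + 1L; next }
      ev <- eigen(cor(Xi), symmetric = TRUE, only.values = TRUE)$values
      ev <- pmax(ev, 0)
      k <- which(cumsum(ev) >= variance_fraction * sum(ev))[1]
      eff <- eff + k
    }
    per[ch] <- eff
  }
  structure(list(M_eff = sum(per), per_chromosome = per,
                 window_size = window_size,
                 variance_fraction = variance_fraction,
                 n_markers = nrow(info)),
            class = "MeffResult")
}

#' Genome-wide significance thresholds from the effective marker number
#'
#' The -log10 p cutoff at level alpha is \eqn{-\log_{10}(\alpha /
#' M_{eff})}. The defaults 0.1 and 0.2 give the stringent and lenient
#' genome-wide thresholds used for peak calling and for judging peak
#' disappearance, respectively.
#'
#' @param meff A \code{"MeffResult"} (or a bare M_eff count).
#' @param alpha_levels significance levels in (0, 1); default
#'   \code{c(0.1, 0.2)}.
#' @return list of class \code{"ThresholdSet"}: \code{cutoffs} (named
#'   -log10 p values), \code{alpha_levels}, \code{M_eff}.
#' @examples
#' gwasThresholds(list(M_eff = 1000))   # 4.0 and ~3.699
#' @export
gwasThresholds <- function(meff, alpha_levels = c(0.1, 0.2)) {
  M <- if (is.list(meff)) meff$M_eff else meff
  if (M < 1) stop("M_eff must be >= 1")
  if (any(alpha_levels <= 0 | alpha_levels >= 1))
    stop("alpha levels must lie in (0, 1)")
  cut <- -log10(alpha_levels / M)
  structure(list(cutoffs = setNames(cut, format(alpha_levels)),
                 alpha_levels = alpha_levels, M_eff = M),
            class = "ThresholdSet")
}

.cutoffAt <- function(thresholds, alpha) {
  i <- match(alpha, thresholds$alpha_levels)
  if (is.na(i)) -log10(alpha / thresholds$M_eff)
  else thresholds$cutoffs[[i]]
}

#' Call peak regions from a scan
#'
#' Markers at or above the cutoff are clustered per chromosome:
#' consecutive significant markers at most \code{merge_gap} bp apart
#' join one region. Region bounds are half-open [start, end) in bp,
#' padded by \code{pad} on each side and clipped at 0. Output regions
#' are disjoint, sorted, and every significant marker belongs to
#' exactly one.
#'
#' @param scan A \linkS4class{ScanResult}.
#' @param cutoff -log10 p calling threshold (e.g.
#'   \code{gwasThresholds(m)$cutoffs[["0.1"]]}).
#' @param merge_gap maximum bp gap between significant markers in one
#'   region (default 300 kb).
#' @param pad bp added on each side of the significant span (default
#'   100 kb).
#' @return data.frame of peak regions: chrom, start, end, top_marker,
#'   top_minus_log10_p, n_significant (empty if no marker passes).
#' @export
callPeaks <- function(scan, cutoff, merge_gap = 300000, pad = 100000) {
  tab <- scanTable(scan)
  sig <- tab[!tab$excluded & !is.na(tab$minus_log10_p) &
               tab$minus_log10_p >= cutoff, , drop = FALSE]
  out <- data.frame(chrom = character(), start = numeric(),
                    end = numeric(), top_marker = character(),
                    top_minus_log10_p = numeric(),
                    n_significant = integer(), stringsAsFactors = FALSE)
  if (!nrow(sig)) return(out)
  sig <- sig[order(sig$chrom, sig$pos), ]
  for (ch in unique(sig$chrom)) {
    s <- sig[sig$chrom == ch, ]
    grp <- cumsum(c(1, diff(s$pos) > merge_gap))
    for (g in unique(grp)) {
      r <- s[grp == g, ]
      top <- r[which.max(r$minus_log10_p), ]
      out <- rbind(out, data.frame(
        chrom = ch, start = max(0, min(r$pos) - pad),
        end = max(r$pos) + pad, top_marker = top$id,
        top_minus_log10_p = top$minus_log10_p,
        n_significant = nrow(r), stringsAsFactors = FALSE))
    }
  }
  out[order(out$chrom, out$start), , drop = FALSE]
}

#' Write peak regions as BED
#'
#' BED is 0-based half-open; name = top marker, score = round(10 x top
#' -log10 p).
#'
#' @param peaks data.frame from \code{\link{callPeaks}}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writePeaksBED <- function(peaks, path) {
  bed <- data.frame(chrom = peaks$chrom, start = as.integer(peaks$start),
                    end = as.integer(peaks$end), name = peaks$top_marker,
                    score = as.integer(round(10 * peaks$top_minus_log10_p)))
  write.table(bed, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
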