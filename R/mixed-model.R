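#' Realized genomic relationship (kinship) matrix
#'
#' VanRaden-type estimator: with W the column-centered dosage matrix and
#' \eqn{c = 2 \sum_k p_k (1 - p_k)} over markers,
#' \eqn{K = W W^T / c}. The diagonal averages near 1 for an outbred
#' panel (near 2 for fully inbred lines). Invariant to marker order.
#'
#' @param panel An imputed \linkS4class{GenotypePanel} with >= 2 markers.
#' @return Symmetric n x n matrix with variety dimnames.
#' @export
computeKinship <- function(panel) {
  X <- dosageMatrix(panel)
  if (ncol(X) < 2) stop("need >= 2 markers")
  if (anyNA(X)) stop("panel must be imputed (no missing dosages)")
  p <- colMeans(X) / 2
  poly <- p > 0 & p < 1
  if (!any(poly)) stop("no polymorphic markers")
  W <- sweep(X[, poly, drop = FALSE], 2, 2 * p[poly])
  cc <- 2 * sum(p[poly] * (1 - p[poly]))
  K <- tcrossprod(W) / cc
  dimnames(K) <- list(varieties(panel), varieties(panel))
  K
}

# REML log-likelihood profile over delta = sigma2_e / sigma2_g for the
# rotated model (EMMA). Returns the pieces needed by the caller.
.remlProfile <- function(log_delta, d, yt, Xt, xtx_logdet) {
  delta <- exp(log_delta)
  n <- length(yt); q <- ncol(Xt)
  w <- 1 / (d + delta)
  sw <- sqrt(w)
  Xw <- Xt * sw
  yw <- yt * sw
  XtX <- crossprod(Xw)
  ch <- tryCatch(chol(XtX), error = function(e) NULL)
  if (is.null(ch)) return(list(ll = -Inf))
  beta <- backsolve(ch, forwardsolve(t(ch), crossprod(Xw, yw)))
  r <- yw - Xw %*% beta
  R <- sum(r^2)
  sigma2 <- R / (n - q)
  ll <- -0.5 * ((n - q) * log(2 * pi * sigma2) + sum(log(d + delta)) +
                  (n - q) + 2 * sum(log(diag(ch))) - xtx_logdet)
  list(ll = ll, sigma2 = sigma2, beta = beta, delta = delta)
}

#' Fit the null linear mixed model by REML
#'
#' Fits \eqn{y = X\alpha + g + e}, \eqn{g \sim N(0, \sigma^2_g K)},
#' \eqn{e \sim N(0, \sigma^2_e I)} via a single spectral decomposition of
#' K and EMMA-style one-dimensional REML optimization over
#' \eqn{\delta = \sigma^2_e / \sigma^2_g} (grid search plus golden-section
#' refinement on log delta in [-10, 10]). The decomposition is cached in
#' the returned fit and reused by the P3D scans.
#'
#' @param y named numeric phenotype vector, or a
#'   \linkS4class{PhenotypeVector}; missing values must have been
#'   dropped and names must be a subset of K's varieties.
#' @param covariates optional n x c matrix of fixed covariates with
#'   variety rownames; an intercept is always prepended.
#' @param K kinship matrix from \code{\link{computeKinship}}.
#' @return list of class \code{"NullModelFit"}: \code{sigma2_g},
#'   \code{sigma2_e}, \code{delta}, \code{loglik_reml}, \code{beta}
#'   (covariate effects), and the cached rotation (\code{U}, \code{d},
#'   \code{yt}, \code{Xt}, sample names).
#' @export
fitNull <- function(y, covariates = NULL, K) {
  if (is(y, "PhenotypeVector")) y <- phenoValues(y)
  y <- y[!is.na(y)]
  if (!all(names(y) %in% rownames(K)))
    stop("phenotype varieties missing from kinship matrix")
  K <- K[names(y), names(y)]
  n <- length(y)
  X <- cbind(intercept = rep(1, n))
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    if (is.null(rownames(covariates)))
      stop("covariates must have variety rownames")
    X <- cbind(X, covariates[names(y), , drop = FALSE])
  }
  # drop collinear covariate columns (intercept always kept)
  qrX <- qr(X)
  if (qrX$rank < ncol(X))
    X <- X[, qrX$pivot[seq_len(qrX$rank)], drop = FALSE]
  q <- ncol(X)
  if (n <= q + 1) stop("too few individuals for the covariate set")
  eg <- eigen(K, symmetric = TRUE)
  if (min(eg$values) < -1e-8 * sum(diag(K)) / n)
    stop("kinship matrix is not positive semidefinite")
  d <- pmax(eg$values, 0)
  U <- eg$vectors
  yt <- drop(crossprod(U, y))
  Xt <- crossprod(U, X)
  xtx_logdet <- as.numeric(determinant(crossprod(X), log = TRUE)$modulus)
  grid <- seq(-10, 10, length.out = 41)
  lls <- vapply(grid, function(ld)
    .remlProfile(ld, d, yt, Xt, xtx_logdet)$ll, numeric(1))
  i <- which.max(lls)
  lo <- grid[max(1, i - 1)]; hi <- grid[min(length(grid), i + 1)]
  opt <- optimize(function(ld)
    .remlProfile(ld, d, yt, Xt, xtx_logdet)$ll, c(lo, hi), maximum = TRUE,
    tol = 1e-6)
  best <- .remlProfile(opt$maximum, d, yt, Xt, xtx_logdet)
  structure(list(sigma2_g = best$sigma2, sigma2_e = best$delta * best$sigma2,
                 delta = best$delta, loglik_reml = best$ll,
                 beta = setNames(drop(best$beta), colnames(X)),
                 U = U, d = d, yt = yt, Xt = Xt, X = X, y = y,
                 samples = names(y), n = n, q = q),
            class = "NullModelFit")
}

# Align phenotype, panel, kinship and covariates to the common variety
# set; returns rotated, weighted design pieces ready for the scan.
.scanSetup <- function(panel, y, covariates, K, fit = NULL) {
  if (is(y, "PhenotypeVector")) y <- phenoValues(y)
  y <- y[!is.na(y)]
  common <- intersect(names(y), varieties(panel))
  if (length(common) < 3) stop("too few varieties shared by y and panel")
  y <- y[common]
  if (is.null(K)) {
    sub <- GenotypePanel(markerInfo(panel), common,
                         dosageMatrix(panel)[common, , drop = FALSE])
    K <- computeKinship(imputeMissing(sub))
  }
  if (is.null(fit)) fit <- fitNull(y, covariates, K)
  G <- dosageMatrix(panel)[fit$samples, , drop = FALSE]
  if (anyNA(G)) {
    mu <- colMeans(G, na.rm = TRUE)
    idx <- which(is.na(G), arr.ind = TRUE)
    G[idx] <- mu[idx[, 2]]
  }
  list(fit = fit, G = G, y = y)
}

# Weighted rotation + residualization against the covariates.
.rotate <- function(fit, G) {
  w <- 1 / (fit$d + fit$delta)
  sw <- sqrt(w)
  yw <- fit$yt * sw
  Xw <- fit$Xt * sw
  Gw <- crossprod(fit$U, G) * sw
  qrx <- qr(Xw)
  ry <- qr.resid(qrx, yw)
  RG <- qr.resid(qrx, Gw)
  list(yw = yw, ry = ry, RG = RG, Gw = Gw, ryy = sum(ry^2))
}

.emptyScanRow <- function(info, n_used) {
  data.frame(id = info$id, chrom = info$chrom, pos = info$pos,
             beta = NA_real_, se = NA_real_, stat = NA_real_,
             p = NA_real_, minus_log10_p = NA_real_, n_used = n_used,
             excluded = FALSE, excluded_reason = NA_character_,
             stringsAsFactors = FALSE)
}

#' Genome-wide mixed-model scan for a quantitative trait
#'
#' For every marker j, generalized least squares of y on
#' [covariates, x_j] under \eqn{\hat V = \hat\sigma^2_g K +
#' \hat\sigma^2_e I}. With \code{p3d = TRUE} (the default, the
#' P3D/EMMAX approximation) the variance components are estimated once
#' under the null and reused for every marker; with \code{p3d = FALSE}
#' they are re-estimated by REML per marker. The Wald statistic is
#' referred to the F distribution with (n - rank) denominator degrees of
#' freedom. Markers collinear with the covariate set (including
#' monomorphic markers) are excluded with reason \code{"collinear"}.
#'
#' @param panel A \linkS4class{GenotypePanel} (imputed, or residual
#'   missing dosages are mean-imputed on the aligned sample).
#' @param y named phenotype vector or \linkS4class{PhenotypeVector};
#'   varieties with missing y are dropped and \code{n_used} reports the
#'   sample actually scanned.
#' @param covariates optional covariate matrix with variety rownames
#'   (intercept added automatically).
#' @param K kinship matrix; computed from the panel when NULL.
#' @param p3d reuse null variance components (default TRUE).
#' @param .exclude_ids,.exclude_reason internal: marker ids to exclude
#'   (used by \code{\link{conditionalScan}}).
#' @return A \linkS4class{ScanResult}.
#' @export
scanQuantitative <- function(panel, y, covariates = NULL, K = NULL,
                             p3d = TRUE, .exclude_ids = NULL,
                             .exclude_reason = "conditioning/proxy") {
  st <- .scanSetup(panel, y, covariates, K)
  fit <- st$fit
  info <- markerInfo(panel)
  tab <- .emptyScanRow(info, fit$n)
  rot <- .rotate(fit, st$G)
  gg <- colSums(rot$RG^2)
  tg <- colSums(rot$Gw^2)
  collinear <- gg <= 1e-10 * pmax(tg, 1e-12)
  test <- !collinear
  if (!is.null(.exclude_ids)) {
    hard <- info$id %in% .exclude_ids
    tab$excluded[hard] <- TRUE
    tab$excluded_reason[hard] <- .exclude_reason
    test <- test & !hard
  }
  tab$excluded[collinear & !tab$excluded] <- TRUE
  tab$excluded_reason[collinear & is.na(tab$excluded_reason)] <- "collinear"
  df <- fit$n - fit$q - 1
  # covariates already explain y exactly: nothing left for any marker
  saturated <- rot$ryy <= 1e-12 * sum(rot$yw^2)
  if (p3d) {
    gy <- colSums(rot$RG * rot$ry)
    beta <- gy / gg
    rss <- pmax(rot$ryy - gy^2 / gg, 0)   # guard tiny negative rounding
    sigma2 <- rss / df
    se <- sqrt(sigma2 / gg)
    Fstat <- ifelse(se > 0, (beta / se)^2, Inf)
    if (saturated) { beta[] <- 0; se[] <- NA; Fstat[] <- 0 }
    idx <- which(test)
    tab$beta[idx] <- beta[idx]
    tab$se[idx] <- se[idx]
    tab$stat[idx] <- Fstat[idx]
    p <- pmax(pf(Fstat[idx], 1, df, lower.tail = FALSE), 1e-300)
    tab$p[idx] <- p
    tab$minus_log10_p[idx] <- -log10(p)
  } else {
    for (j in which(test)) {
      Xj <- cbind(fit$X, marker = st$G[, j])
      fj <- fitNullWithRotation(fit, Xj)
      b <- fj$beta[["marker"]]
      se <- fj$se_marker
      Fs <- (b / se)^2
      pj <- max(pf(Fs, 1, fj$df, lower.tail = FALSE), 1e-300)
      tab$beta[j] <- b; tab$se[j] <- se; tab$stat[j] <- Fs
      tab$p[j] <- pj; tab$minus_log10_p[j] <- -log10(pj)
    }
  }
  ScanResult(tab, meta = list(model = "quantitative", p3d = p3d,
                              sigma2_g = fit$sigma2_g,
                              sigma2_e = fit$sigma2_e,
                              covariates = colnames(fit$X),
                              n_used = fit$n))
}

# exact per-marker REML refit reusing the cached spectral decomposition
fitNullWithRotation <- function(fit, X) {
  yt <- fit$yt
  Xt <- crossprod(fit$U, X)
  xtx_logdet <- as.numeric(determinant(crossprod(X), log = TRUE)$modulus)
  grid <- seq(-10, 10, length.out = 21)
  lls <- vapply(grid, function(ld)
    .remlProfile(ld, fit$d, yt, Xt, xtx_logdet)$ll, numeric(1))
  i <- which.max(lls)
  opt <- optimize(function(ld)
    .remlProfile(ld, fit$d, yt, Xt, xtx_logdet)$ll,
    c(grid[max(1, i - 1)], grid[min(length(grid), i + 1)]),
    maximum = TRUE, tol = 1e-6)
  best <- .remlProfile(opt$maximum, fit$d, yt, Xt, xtx_logdet)
  w <- 1 / (fit$d + best$delta)
  Xw <- Xt * sqrt(w)
  XtXi <- solve(crossprod(Xw))
  j <- which(colnames(X) == "marker")
  list(beta = setNames(drop(best$beta), colnames(X)),
       se_marker = sqrt(best$sigma2 * XtXi[j, j]),
       df = length(yt) - ncol(X))
}

#' Mixed-model score test scan for a binary (0/1) trait
#'
#' The 0/1 phenotype is analyzed with the linear mixed model (not
#' logistic): the null LMM is fitted once, and each marker is tested
#' with the score statistic \eqn{U^2 / Var(U)} where
#' \eqn{U = x_j^T \hat V^{-1} (y - \hat y_{null})}, referred to
#' chi-squared with 1 df.
#'
#' @inheritParams scanQuantitative
#' @param y01 named 0/1 phenotype vector or binary
#'   \linkS4class{PhenotypeVector}; both classes must be present. A
#'   class with fewer than 5 members triggers a warning but the scan
#'   proceeds.
#' @return A \linkS4class{ScanResult}.
#' @export
scanBinary <- function(panel, y01, covariates = NULL, K = NULL) {
  yv <- if (is(y01, "PhenotypeVector")) phenoValues(y01) else y01
  yv <- yv[!is.na(yv)]
  if (!all(yv %in% c(0, 1))) stop("binary phenotype must be coded 0/1")
  if (length(unique(yv)) < 2) stop("degenerate binary trait")
  if (min(table(yv)) < 5)
    warning("a phenotype class has fewer than 5 members")
  st <- .scanSetup(panel, yv, covariates, K)
  fit <- st$fit
  info <- markerInfo(panel)
  tab <- .emptyScanRow(info, fit$n)
  rot <- .rotate(fit, st$G)
  gg <- colSums(rot$RG^2)
  tg <- colSums(rot$Gw^2)
  collinear <- gg <= 1e-10 * pmax(tg, 1e-12)
  gy <- colSums(rot$RG * rot$ry)
  stat <- gy^2 / (gg * fit$sigma2_g)
  idx <- which(!collinear)
  tab$excluded[collinear] <- TRUE
  tab$excluded_reason[collinear] <- "collinear"
  tab$beta[idx] <- (gy / gg)[idx]
  tab$se[idx] <- sqrt(fit$sigma2_g / gg[idx])
  tab$stat[idx] <- stat[idx]
  p <- pmax(pchisq(stat[idx], 1, lower.tail = FALSE), 1e-300)
  tab$p[idx] <- p
  tab$minus_log10_p[idx] <- -log10(p)
  ScanResult(tab, meta = list(model = "binary_score",
                              sigma2_g = fit$sigma2_g,
                              sigma2_e = fit$sigma2_e,
                              covariates = colnames(fit$X),
                              n_used = fit$n))
}

#' Conditional scan: re-scan with marker dosages as fixed covariates
#'
#' Appends the dosages of the conditioning markers to the covariate set
#' and reruns the quantitative scan. The conditioning markers themselves
#' and any marker in perfect LD with one (|r| >= 1 - 1e-10 on the
#' analysis sample) are excluded from testing with reason
#' \code{"conditioning/proxy"}. This is the engine behind Method 1 of
#' the peak identity test: if a peak is explained by the conditioning
#' marker, its signal disappears.
#'
#' @inheritParams scanQuantitative
#' @param conditioning_markers character vector of marker ids present in
#'   \code{panel}.
#' @return A \linkS4class{ScanResult}.
#' @export
conditionalScan <- function(panel, y, K = NULL, conditioning_markers,
                            p3d = TRUE, covariates = NULL) {
  info <- markerInfo(panel)
  j <- match(conditioning_markers, info$id)
  if (anyNA(j)) stop("conditioning marker not shared: ",
                     paste(conditioning_markers[is.na(j)], collapse = ", "))
  G <- dosageMatrix(panel)
  if (anyNA(G)) {
    mu <- colMeans(G, na.rm = TRUE)
    idx <- which(is.na(G), arr.ind = TRUE)
    G[idx] <- mu[idx[, 2]]
  }
  cond <- G[, j, drop = FALSE]
  colnames(cond) <- paste0("cond:", conditioning_markers)
  covs <- if (is.null(covariates)) cond else cbind(covariates, cond)
  # perfect proxies of a conditioning marker are untestable
  r <- suppressWarnings(cor(G, cond))
  proxy <- apply(abs(r) >= 1 - 1e-10, 1, any, na.rm = TRUE)
  excl <- unique(c(conditioning_markers, info$id[which(proxy)]))
  scanQuantitative(panel, y, covariates = covs, K = K, p3d = p3d,
                   .exclude_ids = excl,
                   .exclude_reason = "conditioning/proxy")
}

#' Principal component analysis of population structure
#'
#' PCA of the column-centered (optionally scaled) dosage matrix.
#'
#' @param panel An imputed \linkS4class{GenotypePanel}.
#' @param n_components number of components to return; must not exceed
#'   min(n - 1, number of markers).
#' @param scale. scale markers to unit variance (default FALSE).
#' @return list with \code{scores} (n x k, dimnames kept) and
#'   \code{variance_explained} (fractions of total variance,
#'   non-increasing).
#' @export
pcaStructure <- function(panel, n_components = 2, scale. = FALSE) {
  X <- dosageMatrix(panel)
  if (anyNA(X)) stop("panel must be imputed")
  if (n_components > min(nrow(X) - 1, ncol(X)))
    stop("n_components exceeds min(n - 1, markers)")
  keep <- apply(X, 2, var) > 0
  pc <- prcomp(X[, keep, drop = FALSE], center = TRUE, scale. = scale.)
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  list(scores = pc$x[, seq_len(n_components), drop = FALSE],
       variance_explained = ve[seq_len(n_components)])
}

#' Genomic-control inflation factor and Q-Q table
#'
#' \eqn{\lambda_{GC}} is the median of the per-marker 1-df chi-squared
#' statistics (derived from the p-values) divided by the null median
#' 0.4549; values near 1 indicate well-calibrated tests.
#'
#' @param scan A \linkS4class{ScanResult} with >= 100 tested markers.
#' @return list with \code{lambda_gc} and \code{qq}, a data.frame of
#'   expected vs observed -log10 p (both ascending).
#' @export
inflation <- function(scan) {
  tab <- scanTable(scan)
  p <- tab$p[!tab$excluded & !is.na(tab$p)]
  if (length(p) < 100) stop("need >= 100 tested markers")
  chi <- qchisq(p, 1, lower.tail = FALSE)
  lambda <- median(chi) / qchisq(0.5, 1, lower.tail = FALSE)
  qq <- data.frame(expected = -log10(rev(ppoints(length(p)))),
                   observed = sort(-log10(p)))
  list(lambda_gc = lambda, qq = qq)
}
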