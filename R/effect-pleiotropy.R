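#' Standardized SNP effect sizes across traits
#'
#' For each (peak marker, trait) pair, refits the mixed-model GLS used
#' by the scan on the standardized phenotype and tabulates the absolute
#' effect estimate |beta|. Because every trait has unit variance, the
#' entries are directly comparable across traits and quantify a peak's
#' pleiotropic footprint.
#'
#' @param panel An imputed \linkS4class{GenotypePanel}.
#' @param traits list of \linkS4class{PhenotypeVector}s with provenance
#'   \code{"standardized"} (see \code{\link{standardize}}).
#' @param peak_markers character vector of marker ids.
#' @param K kinship matrix (computed per trait sample when NULL).
#' @return numeric matrix, rows = peak markers, columns = trait names,
#'   entries = |beta| on the standardized scale.
#' @export
standardizedEffects <- function(panel, traits, peak_markers, K = NULL) {
  info <- markerInfo(panel)
  j <- match(peak_markers, info$id)
  if (anyNA(j)) stop("marker not in panel: ",
                     paste(peak_markers[is.na(j)], collapse = ", "))
  out <- matrix(NA_real_, length(peak_markers), length(traits),
                dimnames = list(peak_markers,
                                vapply(traits, function(t) t@traitName,
                                       character(1))))
  for (k in seq_along(traits)) {
    tr <- traits[[k]]
    if (!is(tr, "PhenotypeVector") || provenance(tr) != "standardized")
      stop("trait ", k, " is not a standardized PhenotypeVector")
    sc <- scanQuantitative(panel, tr, K = K)
    tab <- scanTable(sc)
    out[, k] <- abs(tab$beta[match(peak_markers, tab$id)])
  }
  out
}

#' Assign varieties to gene haplotypes from defining polymorphisms
#'
#' A gene haplotype definition lists, per haplotype, the expected
#' (rounded) dosage at each defining marker and whether the haplotype is
#' functional or null (e.g. carries a frameshift). Each variety is
#' matched to the haplotype whose defining alleles it carries exactly;
#' heterozygous calls at a defining marker (unexpected in an inbred
#' panel) and non-matching combinations yield \code{"unassigned"}.
#'
#' @param panel A \linkS4class{GenotypePanel}.
#' @param gene_def list with elements \code{gene_label} and
#'   \code{haplotypes}, the latter a named list of
#'   \code{list(alleles = c(<marker_id> = <dosage 0 or 2>, ...),
#'   functional = TRUE/FALSE)}.
#' @return data.frame (variety, haplotype, functional); functional is NA
#'   for unassigned varieties.
#' @export
assignHaplotypes <- function(panel, gene_def) {
  info <- markerInfo(panel)
  mk <- unique(unlist(lapply(gene_def$haplotypes,
                             function(h) names(h$alleles))))
  j <- match(mk, info$id)
  if (anyNA(j)) stop("defining marker not in panel: ",
                     paste(mk[is.na(j)], collapse = ", "))
  D <- round(dosageMatrix(panel)[, j, drop = FALSE])
  colnames(D) <- mk
  n_het <- 0L
  res <- lapply(seq_len(nrow(D)), function(i) {
    g <- setNames(D[i, ], colnames(D))
    if (anyNA(g) || any(g == 1)) {
      if (any(g == 1, na.rm = TRUE)) n_het <<- n_het + 1L
      return(c("unassigned", NA))
    }
    for (h in names(gene_def$haplotypes)) {
      al <- gene_def$haplotypes[[h]]$alleles
      if (all(g[names(al)] == al))
        return(c(h, gene_def$haplotypes[[h]]$functional))
    }
    c("unassigned", NA)
  })
  if (n_het > 0)
    message("assignHaplotypes[", gene_def$gene_label, "]: ", n_het,
            " heterozygous variety(ies) left unassigned")
  data.frame(variety = varieties(panel),
             haplotype = vapply(res, `[`, character(1), 1),
             functional = as.logical(vapply(res, `[`, character(1), 2)),
             stringsAsFactors = FALSE)
}

# Compact letter display via the insertion-absorption algorithm:
# start from one letter covering all groups; for each significantly
# different pair, split every letter set containing both; absorb sets
# contained in others. Groups share a letter iff adjusted p >= alpha.
.compactLetters <- function(groups, sig_pairs) {
  sets <- list(groups)
  for (k in seq_len(nrow(sig_pairs))) {
    a <- sig_pairs$g1[k]; b <- sig_pairs$g2[k]
    new_sets <- list()
    for (s in sets) {
      if (a %in% s && b %in% s) {
        new_sets <- c(new_sets, list(setdiff(s, a)), list(setdiff(s, b)))
      } else new_sets <- c(new_sets, list(s))
    }
    # absorb: drop sets that are subsets of another
    keep <- rep(TRUE, length(new_sets))
    for (i in seq_along(new_sets)) for (jj in seq_along(new_sets)) {
      if (i != jj && keep[i] && keep[jj] &&
          all(new_sets[[i]] %in% new_sets[[jj]]) &&
          !(all(new_sets[[jj]] %in% new_sets[[i]]) && i > jj))
        keep[i] <- FALSE
    }
    sets <- new_sets[keep]
    sets <- sets[vapply(sets, length, integer(1)) > 0]
  }
  # stable letter order: by first group appearance
  ord <- order(vapply(sets, function(s) min(match(s, groups)), numeric(1)))
  sets <- sets[ord]
  letters_out <- setNames(rep("", length(groups)), groups)
  for (i in seq_along(sets))
    for (g in sets[[i]])
      letters_out[g] <- paste0(letters_out[g], letters[i])
  letters_out
}

#' Compare trait values across variety groups (ANOVA + Tukey-Kramer HSD)
#'
#' One-way ANOVA across the groups; when the F-test is significant at
#' \code{alpha}, all-pairs Tukey-Kramer HSD (honestly significant
#' difference, valid for unequal group sizes) is run and summarized as a
#' compact letter display: two groups share a letter iff their adjusted
#' p-value is >= alpha. When ANOVA is not significant the comparison is
#' flagged NS and all groups share one letter.
#'
#' @param trait A \linkS4class{PhenotypeVector} (or named numeric
#'   vector).
#' @param groups named list mapping group label -> variety labels;
#'   groups must be disjoint. Groups with fewer than 2 phenotyped
#'   members are dropped with a warning.
#' @param alpha significance level (default 0.05).
#' @return list of class \code{"GroupComparison"}: groups, anova_p,
#'   ns (logical), tukey (data.frame of pairwise diffs and adjusted p,
#'   NULL when NS), tukey_letters, group_stats (n, mean, quartiles).
#' @export
groupCompare <- function(trait, groups, alpha = 0.05) {
  v <- if (is(trait, "PhenotypeVector")) phenoValues(trait) else trait
  if (anyDuplicated(unlist(groups))) stop("groups must be disjoint")
  dat <- do.call(rbind, lapply(names(groups), function(g) {
    y <- v[intersect(groups[[g]], names(v))]
    y <- y[!is.na(y)]
    if (!length(y)) return(NULL)
    data.frame(group = g, value = as.numeric(y))
  }))
  cnt <- vapply(names(groups), function(g) sum(dat$group == g), integer(1))
  small <- names(cnt)[cnt < 2]
  if (length(small)) {
    warning("dropping group(s) with n < 2: ", paste(small, collapse = ", "))
    dat <- dat[!dat$group %in% small, ]
  }
  dropped <- setdiff(names(groups), unique(dat$group))
  if (length(unique(dat$group)) < 2) stop("fewer than 2 usable groups")
  dat$group <- factor(dat$group, levels = intersect(names(groups),
                                                    unique(dat$group)))
  fit <- aov(value ~ group, data = dat)
  atab <- anova(fit)
  anova_p <- atab[["Pr(>F)"]][1]
  stats_by <- do.call(rbind, lapply(levels(dat$group), function(g) {
    y <- dat$value[dat$group == g]
    data.frame(group = g, n = length(y), mean = mean(y),
               q25 = quantile(y, 0.25, names = FALSE),
               median = median(y),
               q75 = quantile(y, 0.75, names = FALSE))
  }))
  if (anova_p < alpha) {
    tk <- TukeyHSD(fit, "group")$group
    pairs_df <- data.frame(
      g1 = sub("-.*", "", rownames(tk)),
      g2 = sub(".*-", "", rownames(tk)),
      diff = tk[, "diff"], p_adj = tk[, "p adj"],
      stringsAsFactors = FALSE, row.names = NULL)
    sig <- pairs_df[pairs_df$p_adj < alpha, , drop = FALSE]
    let <- .compactLetters(levels(dat$group), sig)
    ns <- FALSE
  } else {
    pairs_df <- NULL
    let <- setNames(rep("a", nlevels(dat$group)), levels(dat$group))
    ns <- TRUE
  }
  structure(list(groups = groups[setdiff(names(groups), dropped)],
                 anova_p = anova_p, anova_F = atab[["F value"]][1],
                 ns = ns, tukey = pairs_df, tukey_letters = let,
                 group_stats = stats_by, alpha = alpha),
            class = "GroupComparison")
}

#' Haplotype-group pleiotropy panel across traits
#'
#' Cross-classifies varieties by the functionality of each gene (e.g.
#' the four classes of a switch x tone gene pair, labeled
#' \code{Gene}/\code{gene} for functional/null) and runs
#' \code{\link{groupCompare}} for every trait. Unassigned varieties and
#' empty cross-classes are omitted.
#'
#' @param panel A \linkS4class{GenotypePanel}.
#' @param gene_defs list of gene definitions
#'   (see \code{\link{assignHaplotypes}}).
#' @param traits list of \linkS4class{PhenotypeVector}s (or named
#'   numeric vectors named in the list).
#' @param alpha significance level passed to \code{\link{groupCompare}}.
#' @return named list of \code{"GroupComparison"} objects, one per
#'   trait.
#' @export
pleiotropyPanel <- function(panel, gene_defs, traits, alpha = 0.05) {
  stopifnot(length(gene_defs) >= 1, length(traits) >= 1)
  assigns <- lapply(gene_defs, function(gd) assignHaplotypes(panel, gd))
  lab <- rep("", length(varieties(panel)))
  ok <- rep(TRUE, length(varieties(panel)))
  for (k in seq_along(assigns)) {
    a <- assigns[[k]]
    gl <- gene_defs[[k]]$gene_label
    part <- ifelse(is.na(a$functional), NA,
                   ifelse(a$functional, gl, tolower(gl)))
    ok <- ok & !is.na(part)
    lab <- paste(lab, part, sep = if (k == 1) "" else "/")
  }
  lab[!ok] <- NA
  groups <- split(varieties(panel)[ok], lab[ok])
  groups <- groups[vapply(groups, length, integer(1)) > 0]
  res <- lapply(traits, function(tr) groupCompare(tr, groups, alpha))
  nm <- vapply(seq_along(traits), function(i) {
    tr <- traits[[i]]
    if (is(tr, "PhenotypeVector")) tr@traitName
    else if (!is.null(names(traits)[i])) names(traits)[i] else paste0("trait", i)
  }, character(1))
  setNames(res, nm)
}
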