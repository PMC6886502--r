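#' PCA of the standardized TF expression matrix
#'
#' Each TF's profile is standardized to zero mean and unit variance
#' across the 10 domains, then PCA is run with domains as observations
#' and TFs as variables. PCs are ordered by decreasing variance and each
#' is oriented so its largest-magnitude domain score is positive, making
#' the sign convention reproducible across linear-algebra backends.
#'
#' @param profiles Gene x domain RPM matrix.
#' @param tf_genes Identifiers of the TF genes to use (>= 3 non-constant).
#' @param npcs Number of PCs to retain (default 3).
#' @return List of class `tf_pca`: `scores` (domain x PC), `loadings`
#'   (TF x PC), `variance_explained` (all PCs), `standardized` (TF x
#'   domain standardized matrix), `npcs`.
#' @export
tf_pca <- function(profiles, tf_genes, npcs = 3) {
  tf_genes <- intersect(tf_genes, rownames(profiles))
  X <- profiles[tf_genes, , drop = FALSE]
  sds <- apply(X, 1, stats::sd)
  if (any(sds == 0)) {
    warning(sum(sds == 0), " constant TF profile(s) dropped")
    X <- X[sds > 0, , drop = FALSE]
  }
  if (nrow(X) < 3) stop("need at least 3 non-constant expressed TFs")
  Z <- t(scale(t(X)))                       # TF x domain, row-standardized
  pr <- stats::prcomp(t(Z), center = FALSE, scale. = FALSE)
  ve <- pr$sdev^2 / sum(pr$sdev^2)
  npcs <- min(npcs, ncol(pr$x))
  scores <- pr$x
  loadings <- pr$rotation
  for (k in seq_len(ncol(scores))) {
    i <- which.max(abs(scores[, k]))
    if (scores[i, k] < 0) {
      scores[, k] <- -scores[, k]
      loadings[, k] <- -loadings[, k]
    }
  }
  res <- list(scores = scores[, seq_len(npcs), drop = FALSE],
              loadings = loadings[, seq_len(npcs), drop = FALSE],
              variance_explained = ve,
              scores_full = scores, loadings_full = loadings,
              standardized = Z, npcs = npcs)
  class(res) <- "tf_pca"
  res
}

#' TF-family correlation to principal components
#'
#' A family's profile is the per-domain mean of its members' standardized
#' expression (so large families with one dominant member do not swamp
#' the mean), correlated (Pearson) with each retained PC's domain scores.
#' Families with |r| >= `threshold` on a PC are flagged as correlated,
#' with the sign recorded. Singleton families are reported but flagged.
#'
#' @param pca A [tf_pca()] result.
#' @param annotation Data frame (`gene`, `family`).
#' @param threshold Correlation cutoff (default 0.6).
#' @param raw_profiles Optional gene x domain RPM matrix; when supplied
#'   the family mean is computed on raw RPM instead of standardized
#'   expression.
#' @return Data frame: family, pc, r, correlated, sign, n_members,
#'   singleton.
#' @export
family_pc_correlation <- function(pca, annotation, threshold = 0.6,
                                  raw_profiles = NULL) {
  Z <- if (is.null(raw_profiles)) pca$standardized else
    raw_profiles[, colnames(pca$standardized), drop = FALSE]
  fams <- sort(unique(annotation$family))
  out <- list()
  for (f in fams) {
    members <- intersect(annotation$gene[annotation$family == f],
                         rownames(Z))
    if (!length(members)) {
      warning("family '", f, "' has no expressed members; omitted")
      next
    }
    fm <- colMeans(Z[members, , drop = FALSE])
    for (k in seq_len(pca$npcs)) {
      r <- stats::cor(fm, pca$scores[, k])
      out[[length(out) + 1L]] <- data.frame(
        family = f, pc = colnames(pca$scores)[k], r = r,
        correlated = is.finite(r) && abs(r) >= threshold,
        sign = ifelse(is.na(r), NA_character_,
                      ifelse(r >= 0, "positive", "negative")),
        n_members = length(members),
        singleton = length(members) == 1, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Cumulative expression of signed TF sets
#'
#' Per-domain sum of member RPM, separately for the TFs of positively and
#' negatively correlated families. Sums are additive over any split of
#' the family lists.
#'
#' @param profiles Gene x domain RPM matrix.
#' @param annotation Data frame (`gene`, `family`).
#' @param positive_families,negative_families Family label vectors.
#' @return Matrix with rows `positive` and `negative`, one column per
#'   domain.
#' @export
cumulative_signed_expression <- function(profiles, annotation,
                                         positive_families,
                                         negative_families) {
  sum_of <- function(fams) {
    g <- intersect(annotation$gene[annotation$family %in% fams],
                   rownames(profiles))
    if (!length(g)) return(rep(0, ncol(profiles)))
    colSums(profiles[g, , drop = FALSE])
  }
  out <- rbind(positive = sum_of(positive_families),
               negative = sum_of(negative_families))
  colnames(out) <- colnames(profiles)
  out
}

#' TF-family enrichment in a gene set (Fisher exact, BH)
#'
#' For each family with background members, a 2x2 table of set membership
#' against family membership is tested with the two-sided Fisher exact
#' test; p-values are BH-adjusted across families.
#'
#' @param gene_set Character vector, subset of `background`.
#' @param annotation Data frame (`gene`, `family`).
#' @param background Universe of gene identifiers.
#' @return Data frame: family, n_set, n_set_family, n_bg_family,
#'   odds_ratio, p, q.
#' @export
family_enrichment <- function(gene_set, annotation, background) {
  if (!length(gene_set)) stop("empty gene set")
  if (!all(gene_set %in% background))
    stop("gene_set must be a subset of background")
  ann <- annotation[annotation$gene %in% background, , drop = FALSE]
  fams <- sort(unique(ann$family))
  out <- lapply(fams, function(f) {
    fg <- ann$gene[ann$family == f]
    a <- sum(gene_set %in% fg)
    b <- length(gene_set) - a
    cc <- length(fg) - a
    d <- length(background) - length(gene_set) - cc
    ft <- stats::fisher.test(matrix(c(a, b, cc, d), 2, byrow = TRUE))
    data.frame(family = f, n_set = length(gene_set), n_set_family = a,
               n_bg_family = length(fg),
               odds_ratio = unname(ft$estimate), p = ft$p.value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out$q <- stats::p.adjust(out$p, method = "BH")
  out
}
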