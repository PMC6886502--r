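#' Reads-per-million normalization and domain profiles
#'
#' Normalizes a gene x library count matrix to reads per million (RPM):
#' `RPM[g, j] = 1e6 * count[g, j] / sum_g count[g, j]`. RPM rather than a
#' length-normalized unit is appropriate for 3'-anchored, linearly
#' amplified libraries where read counts do not scale with transcript
#' length. Domain profiles are the per-domain means of replicate RPM
#' columns, in the canonical domain order.
#'
#' @param counts Nonnegative integer matrix, genes x libraries, with
#'   library column names.
#' @param design Data frame with columns `library`, `domain`, `replicate`.
#' @return List with `rpm` (per-library matrix), `profiles` (gene x domain
#'   replicate-mean matrix) and the reordered `design`.
#' @export
normalize_rpm <- function(counts, design) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be nonnegative")
  if (!all(design$library %in% colnames(counts)))
    stop("design libraries missing from counts matrix")
  counts <- counts[, design$library, drop = FALSE]
  tot <- colSums(counts)
  if (any(tot == 0))
    stop("library with zero total counts: ",
         paste(design$library[tot == 0], collapse = ", "))
  rpm <- sweep(counts, 2, 1e6 / tot, `*`)
  domains <- unique(design$domain)
  keep <- domains %in% apex_domains()
  if (all(domains %in% apex_domains()))
    domains <- apex_domains()[apex_domains() %in% domains]
  profiles <- vapply(domains, function(d) {
    rowMeans(rpm[, design$library[design$domain == d], drop = FALSE])
  }, numeric(nrow(rpm)))
  dimnames(profiles) <- list(rownames(counts), domains)
  list(rpm = rpm, profiles = profiles, design = design)
}

#' Expressed-gene filter
#'
#' A gene is called expressed when its replicate-mean RPM reaches
#' `min_rpm` in at least one domain (inclusive threshold).
#'
#' @param profiles Gene x domain replicate-mean RPM matrix.
#' @param min_rpm Threshold in RPM (default 2).
#' @return Character vector of expressed gene identifiers.
#' @export
filter_expressed <- function(profiles, min_rpm = 2) {
  rownames(profiles)[apply(profiles, 1, max) >= min_rpm]
}

#' Pairwise expression correlation between libraries or domains
#'
#' For every pair of columns the correlation is computed over the genes
#' expressed in that pair (value >= `min_rpm` in at least one of the two
#' columns), so lowly/never expressed genes do not inflate relatedness.
#'
#' @param mat Gene x column (library or domain) RPM matrix.
#' @param min_rpm Per-pair expression threshold.
#' @param method Correlation method (default Pearson).
#' @return Symmetric correlation matrix with unit diagonal; undefined
#'   entries (constant columns) are `NA` with a warning.
#' @export
pairwise_correlation <- function(mat, min_rpm = 2, method = "pearson") {
  if (ncol(mat) < 2) stop("need at least two columns")
  k <- ncol(mat)
  r <- diag(1, k)
  dimnames(r) <- list(colnames(mat), colnames(mat))
  warned <- FALSE
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      keep <- mat[, i] >= min_rpm | mat[, j] >= min_rpm
      x <- mat[keep, i]; y <- mat[keep, j]
      if (sum(keep) < 2 || stats::sd(x) == 0 || stats::sd(y) == 0) {
        r[i, j] <- r[j, i] <- NA_real_
        warned <- TRUE
      } else {
        r[i, j] <- r[j, i] <- stats::cor(x, y, method = method)
      }
    }
  }
  if (warned) warning("constant column(s): correlation undefined, set NA")
  r
}

#' Shannon entropy of an expression profile
#'
#' Converts a nonnegative profile to relative fractions
#' `p_t = x_t / sum(x)` and returns `H = -sum p_t log2 p_t` (bits), with
#' `0 * log 0 = 0`. Low entropy means domain-specific expression; the
#' maximum over T domains is `log2(T)` for a uniform profile.
#'
#' @param x Nonnegative numeric vector, or a gene x domain matrix (one
#'   entropy per row).
#' @return Entropy in bits (scalar or named per-gene vector).
#' @export
shannon_entropy <- function(x) {
  if (is.matrix(x)) {
    if (any(x < 0)) stop("negative expression values")
    s <- rowSums(x)
    if (any(s == 0)) stop("all-zero profile; filter before scoring")
    p <- x / s
    pl <- ifelse(p > 0, p * log2(p), 0)
    return(-rowSums(pl))
  }
  if (any(x < 0)) stop("negative expression values")
  s <- sum(x)
  if (s == 0) stop("all-zero profile; filter before scoring")
  p <- x / s
  -sum(ifelse(p > 0, p * log2(p), 0))
}

#' Classify domain-specific genes by entropy score
#'
#' Scores every expressed gene's replicate-mean domain profile with
#' [shannon_entropy()] and assigns the argmax domain. Genes with score
#' below `cutoff` (default 2.33 bits, chosen to tolerate the partial
#' physical overlap of captured domains) are flagged domain-specific.
#' Argmax ties go to the first domain in canonical order and are flagged.
#'
#' @param profiles Gene x domain RPM matrix.
#' @param expressed Optional gene subset (e.g. from [filter_expressed()]).
#' @param cutoff Specificity cutoff in bits.
#' @return Data frame: gene, H, p-fraction matrix attribute dropped,
#'   assigned_domain, specific, tie.
#' @export
classify_specific <- function(profiles, expressed = NULL, cutoff = 2.33) {
  if (!is.null(expressed))
    profiles <- profiles[rownames(profiles) %in% expressed, , drop = FALSE]
  H <- shannon_entropy(profiles)
  amax <- apply(profiles, 1, which.max)
  tie <- apply(profiles, 1, function(z) sum(z == max(z)) > 1)
  data.frame(gene = rownames(profiles), H = as.numeric(H),
             assigned_domain = colnames(profiles)[amax],
             specific = as.numeric(H) < cutoff, tie = tie,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Chi-square fit of the entropy-score distribution
#'
#' Fits a chi-square distribution (gamma, shape df/2, scale 2) to a set of
#' entropy scores by moment matching (df = mean) and reports a Pearson
#' chi-square goodness-of-fit p-value over equal-probability bins. Used to
#' check that the score distribution has the expected unimodal shape
#' before trusting a fixed specificity cutoff; the cutoff itself is
#' returned unchanged.
#'
#' @param H Numeric vector of entropy scores (>= 100 values).
#' @param cutoff Configured specificity cutoff, passed through.
#' @param bins Number of equal-probability bins (>= 20).
#' @return List: `df` (fitted degrees of freedom), `gof_stat`, `gof_p`,
#'   `cutoff`, `n`.
#' @export
calibrate_se_cutoff <- function(H, cutoff = 2.33, bins = 20) {
  H <- H[is.finite(H)]
  if (length(H) < 100) stop("need at least 100 scores")
  if (stats::sd(H) == 0) stop("degenerate (constant) scores")
  if (bins < 20) stop("use at least 20 bins")
  df_hat <- mean(H)
  edges <- stats::qchisq(seq(0, 1, length.out = bins + 1), df = df_hat)
  edges[1] <- -Inf; edges[bins + 1] <- Inf
  obs <- table(cut(H, edges))
  expd <- length(H) / bins
  stat <- sum((as.numeric(obs) - expd)^2 / expd)
  # one moment-fitted parameter -> df = bins - 2
  p <- stats::pchisq(stat, df = bins - 2, lower.tail = FALSE)
  list(df = df_hat, gof_stat = stat, gof_p = p, cutoff = cutoff,
       n = length(H))
}
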