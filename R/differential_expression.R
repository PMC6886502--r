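#' Median-of-ratios size factors
#'
#' For each library j, `s_j` is the median over genes of
#' `count[g, j] / geomean_g`, where the geometric mean is taken across
#' libraries and only genes with nonzero counts in every library enter
#' the median. Size factors absorb sequencing-depth differences without
#' being dominated by a few highly expressed genes.
#'
#' @param counts Gene x library count matrix.
#' @return Named positive numeric vector of size factors.
#' @export
estimate_size_factors <- function(counts) {
  counts <- as.matrix(counts)
  ok <- rowSums(counts == 0) == 0
  if (!any(ok)) stop("no gene has nonzero counts in all libraries")
  lg <- log(counts[ok, , drop = FALSE])
  geo <- rowMeans(lg)
  s <- apply(lg, 2, function(col) exp(stats::median(col - geo)))
  if (any(!is.finite(s)) || any(s <= 0))
    stop("degenerate size factors")
  s
}

#' Negative-binomial exact-test differential expression
#'
#' Two-group differential expression in the style of the classic NB
#' exact-conditional RNA-seq test: median-of-ratios size factors,
#' method-of-moments per-gene dispersion pooled within groups and floored
#' at a fitted log-linear mean-dispersion trend (conservative for few
#' replicates), then a two-sided exact conditional test on the split of
#' the two group sums given their total, summing the probabilities of all
#' splits no more likely than the observed one. P-values are BH-adjusted.
#'
#' @param counts Gene x library count matrix.
#' @param design Design data frame (`library`, `domain`, `replicate`).
#' @param groupA,groupB Domain label(s) defining the two groups; each
#'   group needs >= 2 libraries.
#' @param alpha Significance threshold on the BH-adjusted p-value.
#' @return Data frame (sorted by gene id): gene, baseMeanA, baseMeanB,
#'   log2fc, dispersion, pvalue, qvalue, significant; the size factors
#'   are attached as attribute `size_factors`.
#' @export
differential_expression <- function(counts, design, groupA, groupB,
                                    alpha = 0.01) {
  libsA <- design$library[design$domain %in% groupA]
  libsB <- design$library[design$domain %in% groupB]
  if (length(libsA) < 2 || length(libsB) < 2)
    stop("each group needs at least 2 libraries")
  counts <- as.matrix(counts)[, c(libsA, libsB), drop = FALSE]
  s <- estimate_size_factors(counts)
  z <- sweep(counts, 2, s, `/`)              # normalized counts
  grp <- rep(c("A", "B"), c(length(libsA), length(libsB)))

  q0 <- rowMeans(z)
  qA <- rowMeans(z[, grp == "A", drop = FALSE])
  qB <- rowMeans(z[, grp == "B", drop = FALSE])
  disp <- fit_dispersions(z, grp, s, q0)

  SA <- sum(s[grp == "A"]); SB <- sum(s[grp == "B"])
  kA <- rowSums(counts[, grp == "A", drop = FALSE])
  kB <- rowSums(counts[, grp == "B", drop = FALSE])
  sA <- s[grp == "A"]; sB <- s[grp == "B"]
  pv <- vapply(seq_len(nrow(counts)), function(g) {
    nb_exact_test(kA[g], kB[g], sA, sB, q0[g], disp[g])
  }, numeric(1))
  res <- data.frame(gene = rownames(counts), baseMeanA = qA,
                    baseMeanB = qB,
                    log2fc = log2(qB / qA),
                    dispersion = disp, pvalue = pv,
                    row.names = NULL, stringsAsFactors = FALSE)
  res <- res[order(res$gene), ]
  res$qvalue <- stats::p.adjust(res$pvalue, method = "BH")
  res$significant <- res$qvalue < alpha
  attr(res, "size_factors") <- s
  res
}

# Method-of-moments dispersion pooled within groups, floored at a fitted
# log-linear mean-dispersion trend. alpha in Var = mu + alpha mu^2.
fit_dispersions <- function(z, grp, s, q0) {
  groups <- unique(grp)
  ss <- 0
  for (g in groups) {
    zz <- z[, grp == g, drop = FALSE]
    ss <- ss + rowSums((zz - rowMeans(zz))^2)
  }
  v <- ss / (ncol(z) - length(groups))
  xim <- mean(1 / s)
  raw <- (v - q0 * xim) / q0^2
  raw[!is.finite(raw)] <- NA
  fit_ok <- which(!is.na(raw) & raw > 0 & q0 > 0)
  if (length(fit_ok) >= 10) {
    co <- stats::coef(stats::lm(log(raw[fit_ok]) ~ log(q0[fit_ok])))
    trend <- exp(co[1] + co[2] * log(pmax(q0, 1e-8)))
  } else if (length(fit_ok) >= 1) {
    trend <- rep(mean(raw[fit_ok]), length(q0))
  } else {
    trend <- rep(0, length(q0))
  }
  pmax(ifelse(is.na(raw), 0, raw), trend, 0)
}

# Exact conditional two-sided NB test on the split (kA, kB) of kA + kB.
# Group-sum distributions are NB with moment-matched size parameters; with
# alpha = 0 they reduce to Poisson and the test to the binomial
# conditional test.
nb_exact_test <- function(kA, kB, sA, sB, q0, alpha) {
  kS <- kA + kB
  if (kS == 0 || q0 <= 0) return(1)
  muA <- q0 * sum(sA); muB <- q0 * sum(sB)
  varA <- sum(q0 * sA + alpha * (q0 * sA)^2)
  varB <- sum(q0 * sB + alpha * (q0 * sB)^2)
  a <- 0:kS
  pa <- .nb_dens(a, muA, varA)
  pb <- .nb_dens(kS - a, muB, varB)
  pr <- pa * pb
  tot <- sum(pr)
  if (tot <= 0) return(1)
  pobs <- pr[kA + 1]
  min(1, sum(pr[pr <= pobs * (1 + 1e-7)]) / tot)
}

.nb_dens <- function(x, mu, v) {
  if (v > mu * (1 + 1e-12)) {
    size <- mu^2 / (v - mu)
    stats::dnbinom(x, mu = mu, size = size)
  } else {
    stats::dpois(x, mu)
  }
}
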