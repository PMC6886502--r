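#' Divergence from expectation
#'
#' The enrichment summary `D = (O - E) / sqrt(E)` used throughout the
#' gene-set analyses: positive for over-representation, zero when the
#' observed count equals expectation.
#'
#' @param O Observed count(s).
#' @param E Expected count(s), strictly positive.
#' @return Numeric divergence value(s).
#' @export
divergence_from_expectation <- function(O, E) {
  if (any(E <= 0)) stop("expected count must be > 0")
  (O - E) / sqrt(E)
}

#' Chi-square test with Yates' continuity correction
#'
#' 2x2 chi-square statistic with the per-cell correction
#' `(|O - E| - min(0.5, |O - E|))^2 / E` (the correction never overshoots
#' past zero), df = 1, upper-tail p-value.
#'
#' @param tab 2x2 count matrix with positive margins.
#' @return List: `statistic`, `p`.
#' @export
yates_chi2 <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == 2)) stop("need a 2x2 table")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("zero margin in 2x2 table")
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  dev <- abs(tab - E)
  stat <- sum((dev - pmin(0.5, dev))^2 / E)
  list(statistic = stat, p = stats::pchisq(stat, df = 1,
                                           lower.tail = FALSE))
}

# O/E/D/Yates record for one labelled subset vs a universe partition.
.enrich_record <- function(label, O, n_label, n_target, n_total) {
  E <- n_target * n_label / n_total
  D <- if (E > 0) divergence_from_expectation(O, E) else NA_real_
  tab <- matrix(c(O, n_target - O,
                  n_label - O, (n_total - n_target) - (n_label - O)),
                2, byrow = TRUE)
  ok <- all(rowSums(tab) > 0) && all(colSums(tab) > 0)
  yc <- if (ok) yates_chi2(tab) else list(statistic = NA_real_,
                                          p = NA_real_)
  data.frame(label = label, n = n_label, observed = O, expected = E,
             divergence = D, chi2 = yc$statistic, p = yc$p,
             stringsAsFactors = FALSE)
}

#' Entropy-binned target enrichment
#'
#' Partitions the expressed genes into `n_bins` bins of the entropy score
#' (equal-width on `[0, log2(10)]` by default, or equal-count) and
#' reports, per bin, the observed and expected number of target genes,
#' the divergence from expectation and a Yates-corrected chi-square
#' p-value on the in-bin/out-bin x target/non-target table.
#'
#' @param se_scores Named numeric vector of entropy scores for the
#'   expressed genes.
#' @param target_set Gene identifiers, subset of the expressed genes.
#' @param n_bins Number of score bins (default 20).
#' @param scheme "width" (equal-width bins) or "count" (equal-count).
#' @param max_score Upper end of the score range (default `log2(10)`).
#' @return Data frame with one row per bin: bin, lo, hi, n, observed,
#'   expected, divergence, chi2, p.
#' @export
binned_target_enrichment <- function(se_scores, target_set, n_bins = 20,
                                     scheme = c("width", "count"),
                                     max_score = log2(10)) {
  scheme <- match.arg(scheme)
  genes <- names(se_scores)
  if (!all(target_set %in% genes))
    stop("target_set must be a subset of the scored genes")
  if (scheme == "width") {
    edges <- seq(0, max_score, length.out = n_bins + 1)
  } else {
    edges <- stats::quantile(se_scores, probs = seq(0, 1,
                                                    length.out = n_bins + 1))
    edges <- unique(edges)
  }
  nb <- length(edges) - 1
  bin <- cut(pmin(pmax(se_scores, edges[1]), edges[nb + 1]), edges,
             include.lowest = TRUE, labels = FALSE)
  is_t <- genes %in% target_set
  out <- do.call(rbind, lapply(seq_len(nb), function(b) {
    inb <- bin == b
    r <- .enrich_record(sprintf("bin%02d", b), sum(is_t & inb),
                        sum(inb), length(target_set), length(genes))
    cbind(data.frame(bin = b, lo = edges[b], hi = edges[b + 1]),
          r[, -1, drop = FALSE])
  }))
  rownames(out) <- NULL
  out
}

#' Target enrichment across a partition of genes into classes
#'
#' Same observed/expected/divergence/Yates machinery as the binned
#' analysis, over an arbitrary disjoint partition (e.g. expression
#' pattern classes).
#'
#' @param classes Named list of gene-id vectors (disjoint), or a data
#'   frame (`gene`, `class`).
#' @param target_set Gene identifiers, subset of the class union.
#' @return Data frame: class, n, observed, expected, divergence, chi2, p.
#' @export
class_target_enrichment <- function(classes, target_set) {
  if (is.data.frame(classes))
    classes <- split(classes$gene, classes$class)
  all_g <- unlist(classes, use.names = FALSE)
  if (anyDuplicated(all_g)) stop("classes must be disjoint")
  if (!all(target_set %in% all_g))
    stop("target_set must lie within the class union")
  out <- do.call(rbind, lapply(names(classes), function(cl) {
    g <- classes[[cl]]
    .enrich_record(cl, sum(target_set %in% g), length(g),
                   length(target_set), length(all_g))
  }))
  names(out)[1] <- "class"
  rownames(out) <- NULL
  out
}

#' Genes near trait-associated SNPs
#'
#' A gene is near a SNP when the distance from the SNP position to the
#' gene body interval `[start, end]` is at most `window` bp (0 when the
#' SNP lies inside the gene). Redundancy is removed in two ordered
#' steps: (1) a gene with several SNPs for one trait counts once for
#' that trait; (2) for category-level sets, a gene associated with
#' several traits of the same category counts once.
#'
#' @param gene_models Data frame: gene, chrom, start, end.
#' @param snps SNP table: snp_id, chrom, pos, trait, category.
#' @param window Distance cutoff in bp (default 10,000).
#' @return List: `pairs` (snp-gene pairs with distance), `by_trait`
#'   (gene sets after rule 1), `by_category` (gene sets after rules 1-2).
#' @export
genes_near_snps <- function(gene_models, snps, window = 10000) {
  known <- snps$chrom %in% unique(gene_models$chrom)
  if (any(!known)) {
    warning(sum(!known), " SNP(s) on unknown chromosome skipped")
    snps <- snps[known, , drop = FALSE]
  }
  ggr <- GenomicRanges::GRanges(gene_models$chrom,
                                IRanges::IRanges(gene_models$start,
                                                 gene_models$end))
  sgr <- GenomicRanges::GRanges(snps$chrom,
                                IRanges::IRanges(snps$pos, snps$pos))
  ov <- GenomicRanges::findOverlaps(sgr, ggr, maxgap = window)
  si <- S4Vectors::queryHits(ov); gi <- S4Vectors::subjectHits(ov)
  # exact arithmetic distance from point to interval (the overlap search
  # above is a superset: its gap convention differs by 1)
  d <- pmax(0, gene_models$start[gi] - snps$pos[si],
            snps$pos[si] - gene_models$end[gi])
  keep <- d <= window
  pairs <- data.frame(snp_id = snps$snp_id[si][keep],
                      trait = snps$trait[si][keep],
                      category = snps$category[si][keep],
                      gene = gene_models$gene[gi][keep],
                      distance = d[keep], stringsAsFactors = FALSE)
  by_trait <- lapply(split(pairs$gene, pairs$trait), unique)
  by_category <- lapply(split(pairs$gene, pairs$category), unique)
  list(pairs = pairs, by_trait = by_trait, by_category = by_category)
}

#' Trait-associated-SNP proximity enrichment
#'
#' Tests whether a gene set is over-represented among the expressed
#' genes near trait-associated SNPs: `O` is the overlap of the set with
#' the near-TAS genes, `E = |nearTAS| * |set| / |expressed|`, summarized
#' as divergence from expectation with a Yates-corrected chi-square on
#' the near/not-near x in-set/out-of-set table.
#'
#' @param gene_set Gene identifiers, subset of `expressed`.
#' @param expressed Universe of expressed genes.
#' @param near_sets Named list of near-TAS gene sets (per trait or
#'   category), e.g. from [genes_near_snps()].
#' @return Data frame: set, n_near, observed, expected, divergence,
#'   chi2, p.
#' @export
tas_proximity_enrichment <- function(gene_set, expressed, near_sets) {
  if (!length(expressed)) stop("empty expressed set")
  if (!all(gene_set %in% expressed))
    stop("gene_set must be a subset of expressed")
  out <- do.call(rbind, lapply(names(near_sets), function(nm) {
    near <- intersect(near_sets[[nm]], expressed)
    r <- .enrich_record(nm, length(intersect(gene_set, near)),
                        length(near), length(gene_set), length(expressed))
    r
  }))
  names(out)[1:2] <- c("set", "n_near")
  rownames(out) <- NULL
  out
}

#' Hypergeometric annotation-term enrichment
#'
#' Upper-tail hypergeometric p-value for the overlap of a gene set with
#' each annotation term, BH-adjusted across terms. Terms without
#' background members are omitted.
#'
#' @param gene_set Gene identifiers, subset of `background`.
#' @param annotation Named list term -> gene-id vector.
#' @param background Universe of gene identifiers.
#' @return Data frame: term, n_term, overlap, expected, p, q.
#' @export
hypergeometric_enrichment <- function(gene_set, annotation, background) {
  if (!all(gene_set %in% background))
    stop("gene_set must be a subset of background")
  N <- length(background); k <- length(gene_set)
  out <- list()
  for (term in names(annotation)) {
    m <- length(intersect(annotation[[term]], background))
    if (m == 0) next
    x <- length(intersect(annotation[[term]], gene_set))
    p <- stats::phyper(x - 1, m, N - m, k, lower.tail = FALSE)
    out[[length(out) + 1L]] <- data.frame(
      term = term, n_term = m, overlap = x, expected = k * m / N,
      p = p, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, out)
  if (!is.null(out)) out$q <- stats::p.adjust(out$p, method = "BH")
  out
}
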