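test_that("divergence from expectation is exact arithmetic", {
  expect_equal(divergence_from_expectation(4, 4), 0)
  expect_equal(divergence_from_expectation(16, 4), 6)
  expect_equal(divergence_from_expectation(0, 9), -3)
  expect_error(divergence_from_expectation(1, 0), "> 0")
})

test_that("Yates chi-square matches the hand-evaluated formula", {
  prop <- matrix(c(10, 40, 20, 80), 2)      # perfectly proportional
  y0 <- yates_chi2(prop)
  expect_equal(y0$statistic, 0)
  expect_equal(y0$p, 1)
  # [[20, 80], [10, 90]]: E = 15/85, |O-E| = 5, corrected 4.5,
  # stat = 4.5^2 * 2 * (1/15 + 1/85) = 3.17647059
  y <- yates_chi2(matrix(c(20, 10, 80, 90), 2))
  expect_equal(y$statistic, 3.17647059, tolerance = 1e-8)
  expect_equal(y$p, pchisq(3.17647059, 1, lower.tail = FALSE),
               tolerance = 1e-8)
  expect_error(yates_chi2(matrix(c(0, 0, 3, 4), 2)), "margin")
})

test_that("Yates chi-square matches the reference implementation on
           random tables", {
  set.seed(14)
  for (i in 1:500) {
    tab <- matrix(rpois(4, sample(c(5, 20, 80), 1)) + 1L, 2)
    ours <- yates_chi2(tab)
    ref <- suppressWarnings(chisq.test(tab, correct = TRUE))
    expect_equal(ours$statistic, unname(ref$statistic),
                 tolerance = 1e-8)
    expect_equal(ours$p, unname(ref$p.value), tolerance = 1e-8)
    raw <- suppressWarnings(chisq.test(tab, correct = FALSE))
    expect_gte(unname(raw$statistic), ours$statistic)
  }
})

test_that("binned target enrichment conserves counts and instantiates
           the divergence formula", {
  set.seed(15)
  H <- runif(800, 0, log2(10))
  names(H) <- sprintf("g%03d", 1:800)
  tg <- sample(names(H), 120)
  out <- binned_target_enrichment(H, tg)
  expect_equal(nrow(out), 20)
  expect_equal(sum(out$observed), 120)
  expect_equal(sum(out$expected), 120)
  expect_equal(sum(out$n), 800)
  # all targets concentrated in one bin
  H2 <- c(rep(0.1, 50), runif(450, 1, 3.3))
  names(H2) <- sprintf("h%03d", 1:500)
  tg2 <- names(H2)[1:30]
  out2 <- binned_target_enrichment(H2, tg2)
  b1 <- out2[out2$bin == 1, ]
  E0 <- 30 * 50 / 500
  expect_equal(b1$observed, 30)
  expect_equal(b1$divergence, (30 - E0) / sqrt(E0))
  empty <- out2[out2$n == 0, ]
  expect_true(all(is.na(empty$divergence)))
  expect_error(binned_target_enrichment(H, "nope"), "subset")
})

test_that("class enrichment is permutation-symmetric and catches
           planted concentration", {
  genes <- sprintf("g%04d", 1:2000)
  classes <- split(genes, rep(c("a", "b", "c", "d"), each = 500))
  out1 <- class_target_enrichment(list(all = genes), genes[1:100])
  expect_equal(out1$divergence, 0)
  set.seed(16)
  tg <- sample(genes, 200, prob = rep(c(3, 1, 1, 1), each = 500))
  out <- class_target_enrichment(classes, tg)
  expect_lt(out$p[out$class == "a"], 0.01)
  expect_gt(out$divergence[out$class == "a"], 0)
  # permuting class labels permutes, never changes, the divergences
  perm <- classes[c(3, 1, 4, 2)]
  names(perm) <- names(classes)
  out_p <- class_target_enrichment(perm, tg)
  expect_setequal(round(out_p$divergence, 10), round(out$divergence, 10))
  expect_error(class_target_enrichment(list(a = genes[1:10],
                                            b = genes[5:20]),
                                       genes[1]), "disjoint")
})

test_that("SNP-gene proximity follows the arithmetic distance rule and
           dedup rules", {
  gm <- data.frame(gene = c("gA", "gB"), chrom = "chr1",
                   start = c(20000, 100000), end = c(25000, 103000))
  snps <- data.frame(
    snp_id = sprintf("s%d", 1:6), chrom = c(rep("chr1", 5), "chrX"),
    pos = c(12000, 9999, 26000, 35001, 22000, 5),
    trait = c("ph", "ph", "ph", "ph", "la", "ph"),
    category = c(rep("architectural", 5), "nonarchitectural"))
  expect_warning(near <- genes_near_snps(gm, snps), "unknown")
  p <- near$pairs
  expect_true("s1" %in% p$snp_id[p$gene == "gA"])    # distance 8000
  expect_false("s2" %in% p$snp_id)                   # distance 10001
  expect_true("s3" %in% p$snp_id[p$gene == "gA"])    # downstream 1000
  expect_false("s4" %in% p$snp_id)                   # downstream 10001
  expect_equal(p$distance[p$snp_id == "s5"], 0)      # inside gene body
  # rule 1: gA flanked by several "ph" SNPs counts once for "ph"
  expect_equal(sum(near$by_trait$ph == "gA"), 1)
  # rule 2: gA with "ph" and "la" SNPs counts once for the category
  expect_equal(sum(near$by_category$architectural == "gA"), 1)
  # dedup is idempotent
  expect_identical(lapply(near$by_trait, unique), near$by_trait)
})

test_that("TAS proximity enrichment contracts: identity set and window
           monotonicity", {
  a <- small_atlas()
  nr <- small_norm()
  ex <- filter_expressed(nr$profiles)
  near10 <- genes_near_snps(a$gene_models, a$snp_table, window = 10000)
  near5 <- genes_near_snps(a$gene_models, a$snp_table, window = 5000)
  for (cl in names(near10$by_category)) {
    expect_true(all(near5$by_category[[cl]] %in%
                      near10$by_category[[cl]]))
  }
  out <- tas_proximity_enrichment(ex, ex, near10$by_category)
  expect_equal(out$divergence, rep(0, nrow(out)))
  expect_error(tas_proximity_enrichment("g", character(0), list()),
               "empty")
})

test_that("hypergeometric enrichment matches a tail-sum oracle", {
  tail_oracle <- function(x, m, N, k) {
    xs <- x:min(m, k)
    sum(vapply(xs, function(v) {
      choose(m, v) * choose(N - m, k - v) / choose(N, k)
    }, numeric(1)))
  }
  bg <- sprintf("g%03d", 1:60)
  set.seed(17)
  for (i in 1:200) {
    m <- sample(5:30, 1); k <- sample(5:30, 1)
    term <- sample(bg, m); gs <- sample(bg, k)
    out <- hypergeometric_enrichment(gs, list(t = term), bg)
    x <- length(intersect(term, gs))
    expect_equal(out$p, tail_oracle(x, m, 60, k), tolerance = 1e-9)
  }
  expect_equal(hypergeometric_enrichment(bg[1:10], list(t = bg), bg)$p, 1)
  disj <- hypergeometric_enrichment(bg[1:10], list(t = bg[11:20]), bg)
  expect_equal(disj$p, 1)
  expect_null(hypergeometric_enrichment(bg[1:10], list(t = "zz"), bg))
})

test_that("conservation classification applies strict thresholds,
           exclusions and paralog fallback", {
  doms <- c("AtHB8", "S17shoot", "WUS", "CLV3", "FIL", "HDG4", "HMG",
            "KAN1", "LAS")
  prof <- function(...) {
    v <- c(...)
    names(v) <- doms
    v / sum(v)
  }
  ref <- rbind(
    # after excluding AtHB8/S17shoot: WUS 0.30, all rule domains <= 0.19
    oc_good = c(0.20, 0.20, 0.18, 0.066, 0.066, 0.066, 0.066, 0.066,
                0.07),
    vasc_boundary = prof(0.25, 0.05, 0.10, 0.10, 0.10, 0.10, 0.10,
                         0.10, 0.10),
    vasc_good = prof(0.40, 0.05, 0.08, 0.08, 0.08, 0.08, 0.08, 0.08,
                     0.07))
  colnames(ref) <- doms
  ref["oc_good", ] <- ref["oc_good", ] / sum(ref["oc_good", ])
  # sanity: renormalized WUS share clears the strict 25% rule
  expect_gt(unname(ref["oc_good", "WUS"] /
                     sum(ref["oc_good", !(doms %in%
                                            c("AtHB8", "S17shoot"))])),
            0.25)
  map <- data.frame(
    maize_gene = c("mz1", "mz2", "mz2", "mz3", "mz4"),
    at_gene = c("oc_good", "vasc_boundary", "vasc_good",
                "vasc_boundary", "missing_at"),
    relation = c("ortholog", "ortholog", "paralog", "ortholog",
                 "ortholog"))
  expect_equal(unname(conservation_classify("mz1", map, ref, "OC")),
               "ortholog-conserved")
  # exactly 25% in the defining domain is NOT conserved (strict >)
  expect_equal(unname(conservation_classify("mz3", map, ref,
                                            "vasculature")),
               "not-conserved")
  # ortholog fails, paralog passes
  expect_equal(unname(conservation_classify("mz2", map, ref,
                                            "vasculature")),
               "paralog-conserved")
  expect_equal(unname(conservation_classify("mz9", map, ref, "CZ")),
               "no-ortholog")
  expect_equal(unname(conservation_classify("mz4", map, ref, "CZ")),
               "not-conserved")
  # order independence over shuffled map rows
  expect_equal(conservation_classify(c("mz1", "mz2", "mz3"),
                                     map[sample(5), ], ref, "OC"),
               conservation_classify(c("mz1", "mz2", "mz3"), map, ref,
                                     "OC"))
  expect_error(conservation_classify("mz1", map, ref, "stem"), "unknown")
  expect_error(conservation_rules(define_gt = 1.2), "0, 1")
})
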