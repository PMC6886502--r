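test_that("identical config and seed give a bitwise-identical atlas", {
  cfg <- small_sim_config(seed = 7)
  a <- simulate_atlas(cfg)
  b <- simulate_atlas(cfg)
  expect_identical(a$counts, b$counts)
  expect_identical(a$truth, b$truth)
  expect_identical(as.character(a$genome), as.character(b$genome))
  expect_identical(a$snp_table, b$snp_table)
  expect_identical(a$planted_sites, b$planted_sites)
})

test_that("a config without planted genes yields an unlabeled truth table", {
  cfg <- small_sim_config(seed = 8, n_specific_per_domain = 0,
                          archetype_counts = c(CZ = 0, PZ = 0, OC = 0,
                                               core = 0, leaf_up = 0,
                                               leaf_down = 0),
                          n_tf = 0)
  a <- simulate_atlas(cfg, genome = FALSE, snps = FALSE)
  expect_true(all(is.na(a$truth$specific_domain)))
  expect_true(all(is.na(a$truth$archetype)))
  expect_true(all(is.na(a$truth$tf_family)))
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(n_genes = 0), "positive")
  expect_error(sim_config(lib_size = 1e4), "1e5")
  expect_error(sim_config(nb_dispersion = -0.1), ">= 0")
  expect_error(sim_config(motif_fg_rate = 1.2), "\\[0, 1\\]")
  expect_error(sim_config(n_genes = 100), "exceed")
})

test_that("library totals match the configured library size", {
  a <- small_atlas()
  tot <- colSums(a$counts)
  se <- stats::sd(tot) / sqrt(length(tot))
  expect_lt(abs(mean(tot) - a$config$lib_size), 3 * se)
})

test_that("zero dispersion gives Poisson counts (variance ~ mean)", {
  cfg <- small_sim_config(seed = 9, nb_dispersion = 0,
                          domain_noise_sd = 0)
  a <- simulate_atlas(cfg, genome = FALSE, snps = FALSE)
  d1 <- a$counts[, seq(1, 20, 2)]
  d2 <- a$counts[, seq(2, 20, 2)]
  # (x1 - x2)^2 / 2 is an unbiased variance estimate per replicate pair
  ratio <- mean((d1 - d2)^2 / 2) / mean((d1 + d2) / 2)
  expect_lt(abs(ratio - 1), 0.05)
})

test_that("truth labels and tables round-trip through disk unchanged", {
  a <- fixture("io_atlas", function() {
    simulate_atlas(small_sim_config(seed = 11))
  })
  dir <- withr::local_tempdir()
  write_atlas(a, dir)
  b <- read_atlas(dir)
  expect_identical(a$truth, b$truth)
  expect_identical(a$counts, b$counts)
  expect_identical(a$design$library, b$design$library)
  expect_identical(a$snp_table, b$snp_table)
  expect_equal(a$gene_models, b$gene_models)
  expect_identical(lapply(a$target_sets, sort), b$target_sets)
  expect_identical(as.character(a$genome), as.character(b$genome))
  expect_equal(a$pwms$pwm_planted$mat, b$pwms$pwm_planted$mat,
               tolerance = 1e-6)
})

test_that("deterministic motif planting honours rates and strands", {
  # long motif so chance occurrences of the consensus are negligible
  cfg <- small_sim_config(seed = 12, motif_fg_rate = 1,
                          motif_bg_rate = 0, motif_width = 12)
  a <- simulate_atlas(cfg, snps = FALSE)
  cons <- paste(c("A", "C", "G", "T")[apply(a$pwms$pwm_planted$mat, 1,
                                            which.max)], collapse = "")
  prom <- extract_promoters(a$gene_models, a$genome)
  fg <- a$truth$gene[!is.na(a$truth$archetype) & a$truth$archetype == "CZ"]
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(cons)))
  has <- grepl(cons, prom$sequence, fixed = TRUE) |
    grepl(rc, prom$sequence, fixed = TRUE)
  expect_true(all(has[prom$gene %in% fg]))
  expect_false(any(has[!prom$gene %in% fg]))
  # planted offsets must point at the site in transcribed orientation,
  # including minus-strand genes (reverse-complemented insertion)
  ps <- a$planted_sites
  minus <- a$gene_models$gene[a$gene_models$strand == "-"]
  expect_gt(sum(ps$gene %in% minus), 0)
  for (i in seq_len(nrow(ps))) {
    s <- prom$sequence[prom$gene == ps$gene[i]]
    frag <- substr(s, ps$offset[i], ps$offset[i] + 11)
    expect_true(frag == if (ps$strand[i] == "+") cons else rc)
  }
})

test_that("calibrated scanning recovers planted motif sites", {
  a <- fixture("io_atlas", function() {
    simulate_atlas(small_sim_config(seed = 11))
  })
  prom <- extract_promoters(a$gene_models, a$genome)
  pwm <- calibrate_threshold(a$pwms$pwm_planted)
  ps <- a$planted_sites
  hit <- vapply(seq_len(nrow(ps)), function(i) {
    m <- scan_promoter(pwm, prom$sequence[prom$gene == ps$gene[i]])
    any(m$position == ps$offset[i])
  }, logical(1))
  expect_gte(mean(hit), 0.99)
})

test_that("SNP proximity signal is planted as configured", {
  a1 <- simulate_atlas(small_sim_config(seed = 13, snp_window_signal = 1),
                       genome = FALSE)
  dyn <- a1$truth$gene[!is.na(a1$truth$archetype)]
  near <- genes_near_snps(a1$gene_models, a1$snp_table)
  arch_snps <- a1$snp_table$snp_id[a1$snp_table$category ==
                                     "architectural"]
  near_dyn <- unique(near$pairs$snp_id[near$pairs$gene %in% dyn])
  expect_true(all(arch_snps %in% near_dyn))

  a0 <- simulate_atlas(small_sim_config(seed = 13, n_snps = 400,
                                        snp_window_signal = 0),
                       genome = FALSE)
  near0 <- genes_near_snps(a0$gene_models, a0$snp_table)
  frac <- vapply(c("architectural", "nonarchitectural"), function(cl) {
    ids <- a0$snp_table$snp_id[a0$snp_table$category == cl]
    mean(ids %in% near0$pairs$snp_id[near0$pairs$gene %in% dyn])
  }, numeric(1))
  expect_lt(abs(frac[1] - frac[2]), 0.15)
})
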