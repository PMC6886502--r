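#' Archetype expression templates
#'
#' Domain-multiplier templates for the planted cluster archetypes over the
#' 10 apex domains. CZ genes peak in the stem-cell Tip with elevated
#' meristem expression; OC genes mark the organizing centre (whole-meristem
#' capture without the Tip); PZ genes peak at the incipient leaf P0; core
#' meristem genes are high in both meristem and Tip; leaf_up/leaf_down are
#' monotone over the Tip->P3 ontogeny.
#'
#' @param domains Domain labels (default canonical order).
#' @return Named list of multiplier vectors, one per archetype.
#' @export
archetype_templates <- function(domains = apex_domains()) {
  # Values over (meristem, Tip, P0, P1, P2, P3) are strictly graded so
  # that within-archetype rank order is stable under noise, and the six
  # rank vectors are mutually well separated (max pairwise Spearman 0.43)
  # so that rank-based clustering can tell the archetypes apart.
  base <- stats::setNames(rep(1, length(domains)), domains)
  ont <- ontogeny_tissues()
  mk <- function(v) { t <- base; t[ont] <- v; t }
  list(CZ        = mk(c(5,    10,   1.6,  1.1, 0.8, 0.55)),
       PZ        = mk(c(0.7,  1.0,  10,   3,   1.9, 1.4)),
       OC        = mk(c(10,   0.9,  2.2,  1.5, 1.1, 0.6)),
       core      = mk(c(10,   8.9,  0.55, 0.8, 1.1, 1.6)),
       leaf_up   = mk(c(0.9,  0.75, 1.6,  3,   6,   10)),
       leaf_down = mk(c(0.55, 10,   7,    4.5, 2.5, 1.2)))
}

#' Simulate a synthetic shoot-apex expression atlas
#'
#' Generates a complete atlas with known ground truth: an NB count matrix
#' over 10 domains x replicates, planted domain-specific genes, planted
#' archetype clusters, tissue-biased TF families, gene models on
#' pseudo-chromosomes, a random genome with planted promoter motifs, a
#' trait-associated SNP table with proximity signal, and a planted
#' binding-target gene set. Identical configs (including seed) give
#' identical atlases.
#'
#' Counts are drawn NB with mean `lib_size * relative_abundance` and
#' Var = mu + alpha * mu^2. Domain structure enters through multiplicative
#' domain multipliers: planted specific genes are on/off (defining domain
#' `specific_fold`, elsewhere `specific_leak`); archetype genes follow
#' [archetype_templates()]; the first three TF families are biased high in
#' meristem+Tip and the next three low there; every gene additionally gets
#' log-normal per-domain wobble of log2 SD `domain_noise_sd`.
#'
#' @param config A [sim_config()].
#' @param genome Generate the random genome sequence and planted motifs
#'   (the expensive part; disable when only counts are needed).
#' @param snps Generate the SNP table.
#' @return A list of class `synthetic_atlas` with elements `counts`,
#'   `design`, `truth`, `gene_models`, `genome`, `pwms`, `planted_sites`,
#'   `snp_table`, `target_sets`, `tf_annotation`, `config`.
#' @export
simulate_atlas <- function(config = sim_config(), genome = TRUE,
                           snps = TRUE) {
  validate_sim_config(config)
  nd <- length(config$domains)
  genes <- sprintf("gene%05d", seq_len(config$n_genes))

  ## --- truth labels -------------------------------------------------
  truth <- data.frame(gene = genes,
                      specific_domain = NA_character_,
                      archetype = NA_character_,
                      tf_family = NA_character_,
                      stringsAsFactors = FALSE)
  idx <- 1L
  if (config$n_specific_per_domain > 0) {
    for (d in config$domains) {
      take <- idx:(idx + config$n_specific_per_domain - 1L)
      truth$specific_domain[take] <- d
      idx <- idx + config$n_specific_per_domain
    }
  }
  arch <- config$archetype_counts[config$archetype_counts > 0]
  for (a in names(arch)) {
    take <- idx:(idx + arch[[a]] - 1L)
    truth$archetype[take] <- a
    idx <- idx + arch[[a]]
  }
  if (config$n_tf > 0) {
    take <- idx:(idx + config$n_tf - 1L)
    fam <- sprintf("fam%02d", rep_len(seq_len(config$n_families),
                                      config$n_tf))
    truth$tf_family[take] <- sort(fam)
  }

  ## --- domain multipliers ------------------------------------------
  set.seed(sub_seed(config$seed, "counts"))
  mult <- matrix(1, config$n_genes, nd,
                 dimnames = list(genes, config$domains))
  sp <- !is.na(truth$specific_domain)
  if (any(sp)) {
    mult[sp, ] <- config$specific_leak
    mult[cbind(which(sp),
               match(truth$specific_domain[sp], config$domains))] <-
      config$specific_fold
  }
  tmpl <- archetype_templates(config$domains)
  for (a in names(arch)) {
    rows <- which(!is.na(truth$archetype) & truth$archetype == a)
    mult[rows, ] <- matrix(tmpl[[a]], length(rows), nd, byrow = TRUE)
  }
  # TF family tissue biases: fam01-03 meristem/Tip-high, fam04-06 -low
  fam_bias <- stats::setNames(rep("none", config$n_families),
                              sprintf("fam%02d", seq_len(config$n_families)))
  fam_bias[seq_len(min(3, config$n_families))] <- "positive"
  if (config$n_families >= 6) fam_bias[4:6] <- "negative"
  mt <- match(c("meristem", "Tip"), config$domains)
  for (f in names(fam_bias)) {
    rows <- which(!is.na(truth$tf_family) & truth$tf_family == f)
    if (!length(rows)) next
    if (fam_bias[[f]] == "positive") mult[rows, mt] <- mult[rows, mt] * 5
    if (fam_bias[[f]] == "negative") mult[rows, mt] <- mult[rows, mt] * 0.2
  }
  if (config$domain_noise_sd > 0) {
    mult <- mult * 2^matrix(stats::rnorm(config$n_genes * nd, 0,
                                         config$domain_noise_sd),
                            config$n_genes, nd)
  }

  ## --- counts -------------------------------------------------------
  base <- 2^stats::rnorm(config$n_genes, config$base_log2_mean,
                         config$base_log2_sd)
  abun <- base * mult                      # genes x domains
  design <- expand.grid(replicate = seq_len(config$n_reps),
                        domain = config$domains, stringsAsFactors = FALSE)
  design <- design[, c("domain", "replicate")]
  design$library <- paste(design$domain, design$replicate, sep = "_")
  design <- design[, c("library", "domain", "replicate")]
  counts <- matrix(0L, config$n_genes, nrow(design),
                   dimnames = list(genes, design$library))
  for (j in seq_len(nrow(design))) {
    a <- abun[, design$domain[j]]
    mu <- config$lib_size * a / sum(a)
    counts[, j] <- as.integer(if (config$nb_dispersion > 0) {
      stats::rnbinom(config$n_genes, mu = mu,
                     size = 1 / config$nb_dispersion)
    } else {
      stats::rpois(config$n_genes, mu)
    })
  }

  ## --- gene models, genome, SNPs, targets ---------------------------
  gene_models <- layout_gene_models(config, genes)
  atlas <- list(counts = counts, design = design, truth = truth,
                gene_models = gene_models, config = config,
                tf_annotation = truth[!is.na(truth$tf_family),
                                      c("gene", "tf_family")],
                tf_family_bias = fam_bias)
  names(atlas$tf_annotation) <- c("gene", "family")

  if (genome) {
    gm <- simulate_genome_and_promoters(config, truth,
                                        gene_models = gene_models)
    atlas$genome <- gm$genome
    atlas$pwms <- gm$pwms
    atlas$planted_sites <- gm$planted_sites
  }
  if (snps) {
    atlas$snp_table <- simulate_snp_table(config, gene_models, truth)
  }
  atlas$target_sets <- simulate_target_set(config, truth)
  class(atlas) <- "synthetic_atlas"
  atlas
}

# Deterministic gene layout: genes_per_chrom genes per pseudo-chromosome,
# fixed spacing, alternating assignment kept reproducible via genome subseed.
layout_gene_models <- function(config, genes) {
  set.seed(sub_seed(config$seed, "genome"))
  n <- length(genes)
  chrom_i <- (seq_len(n) - 1L) %/% config$genes_per_chrom + 1L
  within <- (seq_len(n) - 1L) %% config$genes_per_chrom
  start <- 10001L + within * config$gene_spacing
  end <- start + config$gene_length - 1L
  strand <- sample(c("+", "-"), n, replace = TRUE)
  if (any(start - 1000 < 1))
    stop("gene layout would place a promoter past the chromosome start")
  data.frame(gene = genes,
             chrom = sprintf("chr%02d", chrom_i),
             start = start, end = end, strand = strand,
             tss = ifelse(strand == "+", start, end),
             stringsAsFactors = FALSE)
}

chrom_lengths <- function(config, gene_models) {
  lens <- tapply(gene_models$end, gene_models$chrom, max) + 11000L
  stats::setNames(as.integer(lens), names(lens))
}

# Planted binding-target set: biased 4:1 toward planted dynamic/specific
# genes so the target set concentrates in low-entropy score bins.
simulate_target_set <- function(config, truth) {
  set.seed(sub_seed(config$seed, "targets"))
  n <- min(config$n_targets, nrow(truth))
  w <- ifelse(!is.na(truth$specific_domain) | !is.na(truth$archetype), 4, 1)
  list(planted_targets = sort(sample(truth$gene, n, prob = w)))
}
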