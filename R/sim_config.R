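#' Configuration for the synthetic shoot-apex atlas generator
#'
#' Assembles and validates every knob of the synthetic-data generator. The
#' defaults define the reference simulation used throughout the package's
#' tests: 5,000 genes over the 10 apex domains with 2 replicates each,
#' negative-binomial counts at dispersion 0.05, 25 planted domain-specific
#' genes per domain (5% of the transcriptome, the proportion typical of
#' tissue-specificity screens at this scale), six planted cluster
#' archetypes, tissue-biased TF families, promoter motif planting and
#' trait-associated SNPs biased toward dynamic genes.
#'
#' @param n_genes Number of genes.
#' @param domains Ordered domain labels (default [apex_domains()]).
#' @param n_reps Replicates per domain.
#' @param lib_size Expected reads per library (>= 1e5).
#' @param nb_dispersion NB dispersion alpha in Var = mu + alpha * mu^2;
#'   0 gives Poisson counts.
#' @param n_specific_per_domain Planted domain-specific genes per domain.
#' @param specific_fold Fold elevation of a specific gene in its defining
#'   domain relative to a background gene's baseline.
#' @param specific_leak Residual off-domain multiplier for specific genes
#'   (specificity is planted as on/off with leakage, so the defining-domain
#'   fold over off domains is `specific_fold / specific_leak`).
#' @param archetype_counts Named counts of planted archetype genes
#'   (CZ, PZ, OC, core, leaf_up, leaf_down).
#' @param n_tf Number of genes annotated as transcription factors.
#' @param n_families Number of TF families.
#' @param domain_noise_sd log2 SD of per-gene per-domain biological wobble
#'   applied to every gene (0 disables cross-domain variation entirely,
#'   giving a pure null for differential expression).
#' @param base_log2_mean,base_log2_sd Log-normal baseline abundance model
#'   (log2 scale) giving a realistic expression dynamic range.
#' @param motif_fg_rate,motif_bg_rate Probability that a foreground
#'   (CZ-archetype) or background promoter receives a planted motif site.
#' @param motif_width Width of the generated PWMs.
#' @param n_snps Number of simulated trait-associated SNPs.
#' @param snp_window_signal Fraction of architectural SNPs placed within
#'   10 kb of a dynamic (archetype) gene; the rest fall uniformly.
#' @param n_targets Size of the planted binding-target gene set.
#' @param genes_per_chrom Genes per pseudo-chromosome.
#' @param gene_spacing Distance between gene starts (bp).
#' @param gene_length Gene body length (bp).
#' @param base_composition Nucleotide probabilities (A, C, G, T) of the
#'   random genome background.
#' @param seed Integer seed; sub-seeds for counts, genome and SNP placement
#'   are derived deterministically from it.
#'
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 5000,
                       domains = apex_domains(),
                       n_reps = 2,
                       lib_size = 1e6,
                       nb_dispersion = 0.05,
                       n_specific_per_domain = 25,
                       specific_fold = 10,
                       specific_leak = 0.2,
                       archetype_counts = c(CZ = 40, PZ = 40, OC = 40,
                                            core = 40, leaf_up = 40,
                                            leaf_down = 40),
                       n_tf = 300,
                       n_families = 20,
                       domain_noise_sd = 0.25,
                       base_log2_mean = 5,
                       base_log2_sd = 2,
                       motif_fg_rate = 0.5,
                       motif_bg_rate = 0.05,
                       motif_width = 9,
                       n_snps = 400,
                       snp_window_signal = 0.8,
                       n_targets = 400,
                       genes_per_chrom = 500,
                       gene_spacing = 20000,
                       gene_length = 3000,
                       base_composition = c(A = 0.25, C = 0.25,
                                            G = 0.25, T = 0.25),
                       seed = 1L) {
  cfg <- list(
    n_genes = as.integer(n_genes), domains = as.character(domains),
    n_reps = as.integer(n_reps), lib_size = lib_size,
    nb_dispersion = nb_dispersion,
    n_specific_per_domain = as.integer(n_specific_per_domain),
    specific_fold = specific_fold, specific_leak = specific_leak,
    archetype_counts = archetype_counts,
    n_tf = as.integer(n_tf), n_families = as.integer(n_families),
    domain_noise_sd = domain_noise_sd,
    base_log2_mean = base_log2_mean, base_log2_sd = base_log2_sd,
    motif_fg_rate = motif_fg_rate, motif_bg_rate = motif_bg_rate,
    motif_width = as.integer(motif_width),
    n_snps = as.integer(n_snps), snp_window_signal = snp_window_signal,
    n_targets = as.integer(n_targets),
    genes_per_chrom = as.integer(genes_per_chrom),
    gene_spacing = as.integer(gene_spacing),
    gene_length = as.integer(gene_length),
    base_composition = base_composition,
    seed = as.integer(seed))
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  pos <- c("n_genes", "n_reps", "lib_size", "motif_width",
           "genes_per_chrom", "gene_spacing", "gene_length")
  for (f in pos) {
    if (!is.numeric(cfg[[f]]) || length(cfg[[f]]) != 1 || cfg[[f]] <= 0)
      stop("sim_config: '", f, "' must be a single positive number",
           call. = FALSE)
  }
  if (cfg$lib_size < 1e5)
    stop("sim_config: lib_size must be >= 1e5", call. = FALSE)
  if (cfg$nb_dispersion < 0)
    stop("sim_config: nb_dispersion must be >= 0", call. = FALSE)
  rates <- c("motif_fg_rate", "motif_bg_rate", "snp_window_signal")
  for (f in rates) {
    if (cfg[[f]] < 0 || cfg[[f]] > 1)
      stop("sim_config: '", f, "' must lie in [0, 1]", call. = FALSE)
  }
  if (cfg$n_specific_per_domain < 0 || any(cfg$archetype_counts < 0))
    stop("sim_config: planted gene counts must be >= 0", call. = FALSE)
  if (length(cfg$domains) != length(unique(cfg$domains)))
    stop("sim_config: duplicate domain labels", call. = FALSE)
  needed <- length(cfg$domains) * cfg$n_specific_per_domain +
    sum(cfg$archetype_counts) + cfg$n_tf
  if (needed > cfg$n_genes)
    stop("sim_config: planted labels exceed n_genes", call. = FALSE)
  if (abs(sum(cfg$base_composition) - 1) > 1e-8 ||
      length(cfg$base_composition) != 4)
    stop("sim_config: base_composition must be 4 probabilities summing to 1",
         call. = FALSE)
  invisible(cfg)
}

# deterministic per-component sub-seed, kept below 2^31
sub_seed <- function(seed, component) {
  offs <- c(counts = 101L, genome = 211L, motifs = 307L,
            snps = 401L, targets = 503L)
  as.integer((as.numeric(seed) * 7919 + offs[[component]]) %% 2147483647)
}
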