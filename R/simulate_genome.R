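#' Simulate genome sequence, promoters and planted motif sites
#'
#' Builds one random pseudo-chromosome per block of genes (i.i.d.
#' nucleotides at the configured composition), generates a strongly
#' informative planted PWM plus a decoy PWM, and plants the planted PWM's
#' consensus into promoter windows (`[TSS-1000, TSS+499]` in transcribed
#' orientation): foreground promoters (planted CZ-archetype genes) receive
#' a site with probability `motif_fg_rate`, all others with
#' `motif_bg_rate`. Sites are inserted on a random strand of the
#' transcribed-orientation window; for minus-strand genes the genomic
#' insertion is reverse-complemented accordingly.
#'
#' @param config A [sim_config()].
#' @param truth Truth label table from [simulate_atlas()] (only the
#'   `gene` and `archetype` columns are used).
#' @param gene_models Optional precomputed gene layout; regenerated
#'   deterministically from the config when missing.
#' @return List with `gene_models`, `genome` (a
#'   [Biostrings::DNAStringSet]), `pwms` (see [read_pwms()] for the model
#'   structure) and `planted_sites` (gene, pwm, offset, strand).
#' @export
simulate_genome_and_promoters <- function(config, truth,
                                          gene_models = NULL) {
  if (is.null(gene_models))
    gene_models <- layout_gene_models(
      config, sprintf("gene%05d", seq_len(config$n_genes)))
  lens <- chrom_lengths(config, gene_models)
  if (any(gene_models$start - 1000 < 1))
    stop("promoter window extends past chromosome start")

  set.seed(sub_seed(config$seed, "motifs"))
  bases <- c("A", "C", "G", "T")
  uni <- all(abs(config$base_composition - 0.25) < 1e-12)
  codes <- lapply(lens, function(L) {
    if (uni) sample.int(4L, L, replace = TRUE)
    else sample.int(4L, L, replace = TRUE,
                    prob = config$base_composition)
  })

  w <- config$motif_width
  cons_planted <- paste(sample(bases, w, replace = TRUE), collapse = "")
  cons_decoy <- paste(sample(bases, w, replace = TRUE), collapse = "")
  pwms <- list(
    consensus_pwm(cons_planted, id = "pwm_planted", family = "fam01",
                  background = config$base_composition),
    consensus_pwm(cons_decoy, id = "pwm_decoy", family = "fam04",
                  background = config$base_composition))
  names(pwms) <- vapply(pwms, `[[`, "", "id")

  fg <- !is.na(truth$archetype) & truth$archetype == "CZ"
  rate <- ifelse(fg, config$motif_fg_rate, config$motif_bg_rate)
  plant <- stats::runif(nrow(gene_models)) < rate
  win <- 1500L
  sites <- NULL
  if (any(plant)) {
    rows <- which(plant)
    offs <- sample.int(win - w + 1L, length(rows), replace = TRUE)
    site_strand <- sample(c("+", "-"), length(rows), replace = TRUE)
    code_of <- function(s) match(strsplit(s, "")[[1]], bases)
    # sites are patched into the integer-coded sequence (cheap) before
    # the one-off string conversion below
    for (k in seq_along(rows)) {
      g <- gene_models[rows[k], ]
      p <- offs[k]
      ins <- if (site_strand[k] == "+") cons_planted else
        revcomp_chr(cons_planted)
      if (g$strand == "+") {
        gstart <- g$tss - 1000L + p - 1L
      } else {
        gstart <- g$tss + 1000L - (p + w - 2L)
        ins <- revcomp_chr(ins)
      }
      codes[[g$chrom]][gstart:(gstart + w - 1L)] <- code_of(ins)
    }
    sites <- data.frame(gene = gene_models$gene[rows],
                        pwm = "pwm_planted", offset = offs,
                        strand = site_strand, stringsAsFactors = FALSE)
  }
  genome <- Biostrings::DNAStringSet(vapply(codes, function(cd) {
    rawToChar(as.raw(c(65L, 67L, 71L, 84L))[cd])
  }, character(1)))
  names(genome) <- names(lens)
  list(gene_models = gene_models, genome = genome, pwms = pwms,
       planted_sites = sites)
}

# PWM with the given consensus at probability `major`, remainder spread
# evenly; log-odds against `background`.
consensus_pwm <- function(consensus, id, family = NA_character_,
                          major = 0.85, background = c(A = 0.25, C = 0.25,
                                                       G = 0.25, T = 0.25)) {
  bases <- c("A", "C", "G", "T")
  cc <- strsplit(consensus, "")[[1]]
  w <- length(cc)
  mat <- matrix((1 - major) / 3, w, 4, dimnames = list(NULL, bases))
  mat[cbind(seq_len(w), match(cc, bases))] <- major
  new_pwm(id = id, family = family, mat = mat, background = background)
}

revcomp_chr <- function(x) {
  vapply(x, function(s) {
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  }, character(1), USE.NAMES = FALSE)
}

#' Simulate a trait-associated SNP table
#'
#' Architectural-trait SNPs are placed within 10 kb of a random dynamic
#' (archetype-labelled) gene with probability `snp_window_signal` and
#' uniformly along the genome otherwise; non-architectural SNPs are always
#' uniform. Traits are drawn within each category.
#'
#' @param config A [sim_config()].
#' @param gene_models Gene layout table.
#' @param truth Truth label table (archetype column defines dynamic genes).
#' @return Data frame: snp_id, chrom, pos (1-based), trait, category.
#' @export
simulate_snp_table <- function(config, gene_models, truth) {
  set.seed(sub_seed(config$seed, "snps"))
  lens <- chrom_lengths(config, gene_models)
  n <- config$n_snps
  category <- sample(c("architectural", "nonarchitectural"), n,
                     replace = TRUE)
  traits <- list(
    architectural = c("plant_height", "leaf_angle", "node_number",
                      "ear_height"),
    nonarchitectural = c("flowering_time", "kernel_oil",
                         "disease_resistance"))
  trait <- vapply(category, function(cl) sample(traits[[cl]], 1), "")
  dyn <- gene_models[gene_models$gene %in%
                       truth$gene[!is.na(truth$archetype)], , drop = FALSE]
  chrom <- character(n)
  pos <- integer(n)
  near_dyn <- category == "architectural" &
    stats::runif(n) < config$snp_window_signal & nrow(dyn) > 0
  for (i in seq_len(n)) {
    if (near_dyn[i]) {
      g <- dyn[sample.int(nrow(dyn), 1), ]
      chrom[i] <- g$chrom
      lo <- max(1L, g$start - 10000L)
      hi <- min(lens[[g$chrom]], g$end + 10000L)
      pos[i] <- sample(seq.int(lo, hi), 1)
    } else {
      chrom[i] <- sample(names(lens), 1,
                         prob = as.numeric(lens) / sum(as.numeric(lens)))
      pos[i] <- sample.int(lens[[chrom[i]]], 1)
    }
  }
  data.frame(snp_id = sprintf("snp%04d", seq_len(n)), chrom = chrom,
             pos = pos, trait = trait, category = category,
             stringsAsFactors = FALSE)
}
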