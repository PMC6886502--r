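#' Write a synthetic atlas to plain-text files
#'
#' Emits the atlas as the pipeline's external interchange formats:
#' `counts.tsv` (genes x libraries), `design.tsv`, `genes.gff3`,
#' `genome.fa`, `motifs.meme`, `snps.tsv`, `tf_annotation.tsv`,
#' `targets.tsv` and `truth.json`.
#'
#' @param atlas A [simulate_atlas()] result.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the directory path.
#' @export
write_atlas <- function(atlas, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(df, f) utils::write.table(
    df, file.path(dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  cnt <- data.frame(gene = rownames(atlas$counts), atlas$counts,
                    check.names = FALSE)
  w(cnt, "counts.tsv")
  w(atlas$design, "design.tsv")
  gm <- atlas$gene_models
  gr <- GenomicRanges::GRanges(gm$chrom,
                               IRanges::IRanges(gm$start, gm$end),
                               strand = gm$strand)
  S4Vectors::mcols(gr)$source <- "apexatlas"
  S4Vectors::mcols(gr)$type <- "gene"
  S4Vectors::mcols(gr)$ID <- gm$gene
  rtracklayer::export(gr, file.path(dir, "genes.gff3"), format = "gff3")
  if (!is.null(atlas$genome))
    Biostrings::writeXStringSet(atlas$genome, file.path(dir, "genome.fa"))
  if (!is.null(atlas$pwms))
    write_pwms(atlas$pwms, file.path(dir, "motifs.meme"))
  if (!is.null(atlas$snp_table)) w(atlas$snp_table, "snps.tsv")
  w(atlas$tf_annotation, "tf_annotation.tsv")
  tg <- data.frame(
    set = rep(names(atlas$target_sets), lengths(atlas$target_sets)),
    gene = unlist(atlas$target_sets, use.names = FALSE))
  w(tg, "targets.tsv")
  fam_map <- data.frame(
    pwm = names(atlas$pwms %||% list()),
    family = vapply(atlas$pwms %||% list(), function(p) p$family,
                    character(1)))
  if (nrow(fam_map)) w(fam_map, "pwm_families.tsv")
  jsonlite::write_json(
    list(truth = atlas$truth,
         planted_sites = atlas$planted_sites,
         tf_family_bias = as.list(atlas$tf_family_bias)),
    file.path(dir, "truth.json"), dataframe = "columns", na = "null",
    null = "null", digits = NA)
  invisible(dir)
}

#' Read an atlas directory back into memory
#'
#' Inverse of [write_atlas()]; PWMs are re-read without an extra
#' pseudocount so matrices round-trip.
#'
#' @param dir Atlas directory.
#' @return A list of class `synthetic_atlas`.
#' @export
read_atlas <- function(dir) {
  r <- function(f, ...) utils::read.table(
    file.path(dir, f), sep = "\t", header = TRUE, check.names = FALSE,
    stringsAsFactors = FALSE, ...)
  cnt <- r("counts.tsv")
  counts <- as.matrix(cnt[, -1, drop = FALSE])
  rownames(counts) <- cnt$gene
  storage.mode(counts) <- "integer"
  design <- r("design.tsv")
  gr <- rtracklayer::import(file.path(dir, "genes.gff3"))
  gene_models <- data.frame(
    gene = S4Vectors::mcols(gr)$ID,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr), end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    stringsAsFactors = FALSE)
  gene_models$tss <- ifelse(gene_models$strand == "+",
                            gene_models$start, gene_models$end)
  o <- order(gene_models$gene)
  gene_models <- gene_models[o, , drop = FALSE]
  rownames(gene_models) <- NULL
  tj <- jsonlite::read_json(file.path(dir, "truth.json"),
                            simplifyVector = TRUE)
  truth <- as.data.frame(tj$truth, stringsAsFactors = FALSE)
  atlas <- list(counts = counts, design = design, truth = truth,
                gene_models = gene_models,
                tf_annotation = r("tf_annotation.tsv"),
                tf_family_bias = unlist(tj$tf_family_bias))
  if (!is.null(tj$planted_sites))
    atlas$planted_sites <- as.data.frame(tj$planted_sites,
                                         stringsAsFactors = FALSE)
  fa <- file.path(dir, "genome.fa")
  if (file.exists(fa)) atlas$genome <- Biostrings::readDNAStringSet(fa)
  meme <- file.path(dir, "motifs.meme")
  if (file.exists(meme)) {
    fam <- file.path(dir, "pwm_families.tsv")
    fm <- if (file.exists(fam)) r("pwm_families.tsv") else NULL
    atlas$pwms <- read_pwms(meme, pseudocount = 0, family_map = fm)
  }
  snp <- file.path(dir, "snps.tsv")
  if (file.exists(snp)) atlas$snp_table <- r("snps.tsv")
  tg <- r("targets.tsv")
  atlas$target_sets <- lapply(split(tg$gene, tg$set), sort)
  class(atlas) <- "synthetic_atlas"
  atlas
}
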