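#' Extract promoter sequences around transcription start sites
#'
#' Returns the window from `up` bp upstream of the TSS to `down` bp
#' downstream, in transcribed orientation, a total of `up + down` bases
#' with the TSS as the first downstream base. On the plus strand this is
#' genomic `[TSS - up, TSS + down - 1]` (1-based inclusive); on the minus
#' strand it is the reverse complement of `[TSS - down + 1, TSS + up]`.
#' Windows running past a chromosome end are truncated and flagged.
#'
#' @param gene_models Data frame: gene, chrom, start, end, strand, tss
#'   (1-based).
#' @param genome A [Biostrings::DNAStringSet] keyed by chromosome.
#' @param up,down Window extents in bp (defaults 1000 and 500).
#' @return Data frame: gene, chrom, strand, start, end (genomic, 1-based),
#'   truncated, sequence (transcribed orientation).
#' @export
extract_promoters <- function(gene_models, genome, up = 1000, down = 500) {
  if (!all(gene_models$chrom %in% names(genome)))
    stop("chromosome(s) missing from genome: ",
         paste(setdiff(unique(gene_models$chrom), names(genome)),
               collapse = ", "))
  plus <- gene_models$strand == "+"
  s <- ifelse(plus, gene_models$tss - up, gene_models$tss - down + 1)
  e <- ifelse(plus, gene_models$tss + down - 1, gene_models$tss + up)
  lens <- stats::setNames(Biostrings::width(genome), names(genome))
  cl <- lens[gene_models$chrom]
  trunc <- s < 1 | e > cl
  s2 <- pmax(s, 1)
  e2 <- pmin(e, cl)
  seqs <- character(nrow(gene_models))
  for (ch in unique(gene_models$chrom)) {
    i <- which(gene_models$chrom == ch)
    ext <- Biostrings::extractAt(genome[[ch]],
                                 IRanges::IRanges(s2[i], e2[i]))
    minus <- which(!plus[i])
    if (length(minus))
      ext[minus] <- Biostrings::reverseComplement(ext[minus])
    seqs[i] <- as.character(ext)
  }
  data.frame(gene = gene_models$gene, chrom = gene_models$chrom,
             strand = gene_models$strand, start = as.integer(s2),
             end = as.integer(e2), truncated = trunc, sequence = seqs,
             stringsAsFactors = FALSE)
}
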