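#' Scan a promoter set against a PWM collection
#'
#' Calibrates each PWM's match threshold (unless already set) and scans
#' every promoter on both strands, recording per-gene match counts.
#'
#' @param pwms Named list of `pwm_model` objects.
#' @param promoters Promoter table from [extract_promoters()].
#' @param p_value Per-window match probability for threshold calibration.
#' @return List: `counts` (gene x PWM match-count matrix), `hits`
#'   (logical gene x PWM, >= 1 match), `pwms` (calibrated models).
#' @export
scan_promoter_set <- function(pwms, promoters, p_value = 1e-4) {
  pwms <- lapply(pwms, function(p) {
    if (is.na(p$threshold)) calibrate_threshold(p, p_value) else p
  })
  codes <- lapply(promoters$sequence, .encode_seq)
  cnt <- matrix(0L, nrow(promoters), length(pwms),
                dimnames = list(promoters$gene, names(pwms)))
  for (k in seq_along(pwms)) {
    p <- pwms[[k]]
    lo <- p$logodds
    lo_rc <- lo[p$width:1, c("T", "G", "C", "A"), drop = FALSE]
    cnt[, k] <- vapply(codes, .count_matches, integer(1), lo = lo,
                       lo_rc = lo_rc, w = p$width, theta = p$threshold)
  }
  list(counts = cnt, hits = cnt > 0, pwms = pwms)
}

#' Motif enrichment of a foreground gene set over a background
#'
#' Per PWM, genes with at least one promoter match are counted in the
#' foreground and background sets; enrichment is the hit-rate fold
#' change with a two-sided Fisher exact p-value, BH-adjusted across
#' PWMs. A per-family summary takes the union of member-PWM hits.
#'
#' @param scan A [scan_promoter_set()] result (or its `hits` matrix).
#' @param foreground,background Gene identifier vectors
#'   (foreground must be a subset of background).
#' @param pwm_families Optional named family vector (defaults to the
#'   models' family fields).
#' @return List of data frames `per_pwm` and `per_family`, each with
#'   n_fg_hit, n_fg, n_bg_hit, n_bg, fold, p, q.
#' @export
motif_enrichment <- function(scan, foreground, background,
                             pwm_families = NULL) {
  hits <- if (is.list(scan) && !is.null(scan$hits)) scan$hits else scan
  if (is.null(pwm_families) && is.list(scan) && !is.null(scan$pwms))
    pwm_families <- vapply(scan$pwms, function(p) p$family %||% NA_character_,
                           character(1))
  if (!all(foreground %in% background))
    stop("foreground must be a subset of background")
  miss <- setdiff(background, rownames(hits))
  if (length(miss)) {
    warning(length(miss), " gene(s) lack promoter records; excluded")
    background <- setdiff(background, miss)
    foreground <- setdiff(foreground, miss)
  }
  fg <- hits[foreground, , drop = FALSE]
  bg <- hits[background, , drop = FALSE]
  tab_one <- function(label, fgh, bgh) {
    n_fg <- length(foreground); n_bg <- length(background)
    fold <- (fgh / n_fg) / (bgh / n_bg)
    p <- stats::fisher.test(matrix(c(fgh, n_fg - fgh,
                                     bgh - fgh,
                                     (n_bg - n_fg) - (bgh - fgh)),
                                   2, byrow = TRUE))$p.value
    data.frame(label = label, n_fg_hit = fgh, n_fg = n_fg,
               n_bg_hit = bgh, n_bg = n_bg, fold = fold, p = p,
               stringsAsFactors = FALSE)
  }
  per_pwm <- do.call(rbind, lapply(colnames(hits), function(m) {
    tab_one(m, sum(fg[, m]), sum(bg[, m]))
  }))
  names(per_pwm)[1] <- "pwm"
  per_pwm$q <- stats::p.adjust(per_pwm$p, method = "BH")
  per_family <- NULL
  if (!is.null(pwm_families) && any(!is.na(pwm_families))) {
    fams <- sort(unique(stats::na.omit(pwm_families)))
    per_family <- do.call(rbind, lapply(fams, function(f) {
      mm <- names(pwm_families)[!is.na(pwm_families) & pwm_families == f]
      mm <- intersect(mm, colnames(hits))
      fgh <- sum(rowSums(fg[, mm, drop = FALSE]) > 0)
      bgh <- sum(rowSums(bg[, mm, drop = FALSE]) > 0)
      tab_one(f, fgh, bgh)
    }))
    names(per_family)[1] <- "family"
    per_family$q <- stats::p.adjust(per_family$p, method = "BH")
  }
  list(per_pwm = per_pwm, per_family = per_family)
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0) b else a

#' Build a motif-based gene regulatory network edge table
#'
#' Directed family -> gene edges for every promoter with at least one
#' match to a family's PWMs, plus TF -> gene edges for CZ-specific TFs
#' whose family PWMs match. Node attributes record CZ-specificity and
#' TF status; the per-gene count of distinct matched families summarises
#' combinatorial regulation.
#'
#' @param scan A [scan_promoter_set()] result.
#' @param family_sign Optional named sign per family (e.g. PC1
#'   correlation sign).
#' @param cz_genes Genes to include as network targets (e.g. the
#'   CZ-specific set); defaults to all scanned genes.
#' @param cz_tfs Optional data frame (`gene`, `family`) of CZ-specific
#'   TFs generating individual TF -> gene edges.
#' @return List: `edges` (regulator, regulator_type, gene, family, sign,
#'   n_matches), `nodes`, `family_counts` (gene, n_families).
#' @export
build_grn <- function(scan, family_sign = NULL, cz_genes = NULL,
                      cz_tfs = NULL) {
  fams <- vapply(scan$pwms, function(p) p$family %||% NA_character_,
                 character(1))
  genes <- if (is.null(cz_genes)) rownames(scan$counts) else
    intersect(cz_genes, rownames(scan$counts))
  cnt <- scan$counts[genes, , drop = FALSE]
  edges <- list()
  ufam <- sort(unique(stats::na.omit(fams)))
  fam_hit <- matrix(0L, length(genes), length(ufam),
                    dimnames = list(genes, ufam))
  for (f in ufam) {
    mm <- names(fams)[!is.na(fams) & fams == f]
    nm <- rowSums(cnt[, mm, drop = FALSE])
    fam_hit[, f] <- as.integer(nm > 0)
    hit_genes <- genes[nm > 0]
    if (length(hit_genes)) {
      edges[[length(edges) + 1L]] <- data.frame(
        regulator = f, regulator_type = "family", gene = hit_genes,
        family = f,
        sign = if (!is.null(family_sign))
          unname(family_sign[f] %||% NA_character_) else NA_character_,
        n_matches = unname(nm[nm > 0]), stringsAsFactors = FALSE)
    }
    if (!is.null(cz_tfs)) {
      tfs <- cz_tfs$gene[cz_tfs$family == f]
      for (tf in tfs) {
        if (length(hit_genes)) {
          edges[[length(edges) + 1L]] <- data.frame(
            regulator = tf, regulator_type = "TF", gene = hit_genes,
            family = f,
            sign = if (!is.null(family_sign))
              unname(family_sign[f] %||% NA_character_) else NA_character_,
            n_matches = unname(nm[nm > 0]), stringsAsFactors = FALSE)
        }
      }
    }
  }
  edges <- if (length(edges)) do.call(rbind, edges) else
    data.frame(regulator = character(0), regulator_type = character(0),
               gene = character(0), family = character(0),
               sign = character(0), n_matches = integer(0))
  family_counts <- data.frame(gene = genes,
                              n_families = rowSums(fam_hit),
                              stringsAsFactors = FALSE)
  nodes <- data.frame(
    node = unique(c(genes, ufam,
                    if (!is.null(cz_tfs)) cz_tfs$gene)),
    stringsAsFactors = FALSE)
  nodes$type <- ifelse(nodes$node %in% ufam, "family",
                       ifelse(!is.null(cz_tfs) &
                                nodes$node %in% cz_tfs$gene, "TF", "gene"))
  nodes$cz_specific <- nodes$node %in% genes |
    (!is.null(cz_tfs) & nodes$node %in% cz_tfs$gene)
  list(edges = edges, nodes = nodes, family_counts = family_counts)
}
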