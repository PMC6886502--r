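#' Pipeline run configuration
#'
#' Collects every input path, stage toggle and threshold of the
#' end-to-end pipeline with the standard defaults: expression filter 2
#' RPM, specificity cutoff 2.33 bits, DE significance q < 0.01, dynamic
#' fold 2, CAST affinity 0.8, family-PC correlation cutoff 0.6, promoter
#' window -1000/+500, PWM match p-value 1e-4, 20 entropy bins, 10 kb SNP
#' window and 25%/20% conservation thresholds.
#'
#' @param atlas_dir Directory holding the atlas interchange files (see
#'   [write_atlas()]).
#' @param out_dir Output directory for stage tables and `report.json`.
#' @param stages Named logical vector toggling pipeline stages.
#' @param min_rpm,se_cutoff,de_q,fold,floor_rpm,cast_t,pc_r,npcs
#'   Stage thresholds (see module docs).
#' @param de_group_a,de_group_b Domains compared in the DE stage.
#' @param promoter_up,promoter_down,pwm_p Promoter/PWM settings.
#' @param bins,tas_window Enrichment settings.
#' @param conservation_define,conservation_low Conservation thresholds.
#' @param seed Seed for any stage with sampling (none by default; kept
#'   for reproducibility of future stochastic stages).
#' @return List of class `run_config`.
#' @export
run_config <- function(atlas_dir, out_dir,
                       stages = c(normalize = TRUE, specificity = TRUE,
                                  de = TRUE, cluster = TRUE,
                                  tfpca = TRUE, motif = TRUE,
                                  enrich = TRUE),
                       min_rpm = 2, se_cutoff = 2.33, de_q = 0.01,
                       de_group_a = "Tip", de_group_b = "P0",
                       fold = 2, floor_rpm = 1, cast_t = 0.8,
                       pc_r = 0.6, npcs = 3,
                       promoter_up = 1000, promoter_down = 500,
                       pwm_p = 1e-4, bins = 20, tas_window = 10000,
                       conservation_define = 0.25,
                       conservation_low = 0.20, seed = 1L) {
  cfg <- as.list(environment())
  if (cfg$cast_t <= 0 || cfg$cast_t > 1) stop("cast_t must be in (0, 1]")
  if (cfg$pwm_p <= 0 || cfg$pwm_p >= 0.5) stop("pwm_p must be in (0, 0.5)")
  class(cfg) <- "run_config"
  cfg
}

#' Read a run configuration from YAML
#'
#' @param path YAML file whose keys match [run_config()] arguments.
#' @return List of class `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$stages)) y$stages <- unlist(y$stages)
  do.call(run_config, y)
}

#' Run the full atlas pipeline
#'
#' Executes normalize -> specificity -> DE -> cluster -> TF PCA ->
#' motif/GRN -> enrichments in dependency order, writing each stage's
#' tables under `out_dir` plus a machine-readable `report.json` with
#' per-stage row counts, output md5 hashes, parameters and wall time.
#' Reruns on identical inputs reproduce identical outputs. Disabled
#' stages are marked skipped; a stage whose upstream output is missing
#' fails naming that stage.
#'
#' @param config A [run_config()] (or path to a YAML file for
#'   [read_run_config()]).
#' @return The run report, invisibly (also written as JSON).
#' @export
run_all <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  atlas <- read_atlas(config$atlas_dir)
  report <- list(parameters = config[!(names(config) %in%
                                         c("stages"))],
                 stages = list())
  report$parameters$stages <- NULL
  env <- new.env(parent = emptyenv())

  need <- function(what, stage) {
    if (!exists(what, envir = env))
      stop("stage '", stage, "': missing upstream output '", what, "'",
           call. = FALSE)
    get(what, envir = env)
  }
  out_tsv <- function(df, f) {
    p <- file.path(config$out_dir, f)
    utils::write.table(df, p, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    p
  }
  run_stage <- function(name, fun) {
    if (!isTRUE(config$stages[[name]])) {
      report$stages[[name]] <<- list(status = "skipped")
      return(invisible(NULL))
    }
    t0 <- proc.time()[["elapsed"]]
    info <- fun()
    info$status <- "ok"
    info$wall_s <- round(proc.time()[["elapsed"]] - t0, 3)
    if (!is.null(info$files))
      info$md5 <- as.list(tools::md5sum(unlist(info$files)))
    report$stages[[name]] <<- info
  }

  run_stage("normalize", function() {
    nr <- normalize_rpm(atlas$counts, atlas$design)
    assign("rpm", nr$rpm, envir = env)
    assign("profiles", nr$profiles, envir = env)
    corr <- pairwise_correlation(nr$profiles, min_rpm = config$min_rpm)
    f <- c(out_tsv(data.frame(gene = rownames(nr$rpm), nr$rpm,
                              check.names = FALSE), "rpm.tsv"),
           out_tsv(data.frame(gene = rownames(nr$profiles), nr$profiles,
                              check.names = FALSE), "profiles.tsv"),
           out_tsv(data.frame(domain = rownames(corr), corr,
                              check.names = FALSE), "correlation.tsv"))
    list(rows = nrow(nr$rpm), files = f)
  })

  run_stage("specificity", function() {
    profiles <- need("profiles", "specificity")
    expressed <- filter_expressed(profiles, config$min_rpm)
    assign("expressed", expressed, envir = env)
    se <- classify_specific(profiles, expressed, config$se_cutoff)
    assign("se", se, envir = env)
    fit <- calibrate_se_cutoff(se$H, cutoff = config$se_cutoff)
    list(rows = nrow(se), n_expressed = length(expressed),
         n_specific = sum(se$specific),
         se_fit_df = fit$df, se_fit_gof_p = fit$gof_p,
         files = out_tsv(se, "se_results.tsv"))
  })

  run_stage("de", function() {
    de <- differential_expression(atlas$counts, atlas$design,
                                  config$de_group_a, config$de_group_b,
                                  alpha = config$de_q)
    expressed <- need("expressed", "de")
    de <- de[de$gene %in% expressed, , drop = FALSE]
    assign("de", de, envir = env)
    f <- out_tsv(de, sprintf("de_%s_vs_%s.tsv", config$de_group_a,
                             config$de_group_b))
    list(rows = nrow(de), n_significant = sum(de$significant),
         files = f)
  })

  run_stage("cluster", function() {
    profiles <- need("profiles", "cluster")
    expressed <- need("expressed", "cluster")
    dyn <- select_dynamic_genes(
      profiles[expressed, , drop = FALSE],
      tissues = ontogeny_tissues(), fold = config$fold,
      floor_rpm = config$floor_rpm)
    assign("dynamic", dyn, envir = env)
    cast <- cast_cluster(profiles[dyn, ontogeny_tissues(), drop = FALSE],
                         t = config$cast_t)
    arch <- cluster_archetypes(cast, profiles)
    assign("cast", cast, envir = env)
    assign("archetypes", arch, envir = env)
    asg <- merge(cast$assignments, arch[, c("cluster", "archetype")],
                 by = "cluster")[, c("gene", "cluster", "archetype")]
    asg <- asg[order(asg$gene), ]
    f <- c(out_tsv(asg, "clusters.tsv"),
           out_tsv(arch, "cluster_profiles.tsv"))
    list(rows = length(dyn), n_clusters = length(cast$clusters),
         files = f)
  })

  run_stage("tfpca", function() {
    profiles <- need("profiles", "tfpca")
    expressed <- need("expressed", "tfpca")
    tfg <- intersect(atlas$tf_annotation$gene, expressed)
    pca <- tf_pca(profiles, tfg, npcs = config$npcs)
    corr <- family_pc_correlation(pca, atlas$tf_annotation,
                                  threshold = config$pc_r)
    assign("tf_corr", corr, envir = env)
    pc1 <- corr[corr$pc == "PC1" & corr$correlated, , drop = FALSE]
    cum <- cumulative_signed_expression(
      profiles, atlas$tf_annotation,
      pc1$family[pc1$sign == "positive"],
      pc1$family[pc1$sign == "negative"])
    f <- c(out_tsv(data.frame(domain = rownames(pca$scores), pca$scores,
                              check.names = FALSE), "pca_scores.tsv"),
           out_tsv(corr, "family_pc_corr.tsv"),
           out_tsv(data.frame(sign = rownames(cum), cum,
                              check.names = FALSE),
                   "cumulative_profiles.tsv"))
    list(rows = nrow(corr), n_tf = length(tfg),
         variance_explained_pc1 = pca$variance_explained[1], files = f)
  })

  run_stage("motif", function() {
    if (is.null(atlas$genome) || is.null(atlas$pwms))
      stop("stage 'motif': atlas lacks genome or motif files",
           call. = FALSE)
    expressed <- need("expressed", "motif")
    arch <- need("archetypes", "motif")
    cast <- need("cast", "motif")
    cz_clusters <- arch$cluster[arch$archetype == "CZ"]
    fg <- unique(unlist(cast$clusters[cz_clusters], use.names = FALSE))
    prom <- extract_promoters(atlas$gene_models, atlas$genome,
                              up = config$promoter_up,
                              down = config$promoter_down)
    prom <- prom[prom$gene %in% expressed, , drop = FALSE]
    fg <- intersect(fg, prom$gene)
    sc <- scan_promoter_set(atlas$pwms, prom, p_value = config$pwm_p)
    enr <- motif_enrichment(sc, foreground = fg,
                            background = prom$gene)
    sign_map <- NULL
    if (exists("tf_corr", envir = env)) {
      tc <- get("tf_corr", envir = env)
      tc <- tc[tc$pc == "PC1", , drop = FALSE]
      sign_map <- stats::setNames(tc$sign, tc$family)
    }
    grn <- build_grn(sc, family_sign = sign_map, cz_genes = fg)
    ps <- Biostrings::DNAStringSet(prom$sequence)
    names(ps) <- prom$gene
    fa <- file.path(config$out_dir, "promoters.fa")
    Biostrings::writeXStringSet(ps, fa)
    f <- c(fa,
           out_tsv(enr$per_pwm, "motif_enrichment.tsv"),
           out_tsv(grn$edges, "grn_edges.tsv"),
           out_tsv(grn$family_counts, "grn_family_counts.tsv"))
    list(rows = nrow(enr$per_pwm), n_foreground = length(fg),
         mean_families_per_fg_gene = mean(grn$family_counts$n_families),
         files = f)
  })

  run_stage("enrich", function() {
    se <- need("se", "enrich")
    expressed <- need("expressed", "enrich")
    targets <- intersect(atlas$target_sets[[1]], expressed)
    H <- stats::setNames(se$H, se$gene)
    binned <- binned_target_enrichment(H, targets, n_bins = config$bins)
    classes <- split(se$gene, se$assigned_domain)
    cls <- class_target_enrichment(classes, targets)
    f <- c(out_tsv(binned, "binned_enrichment.tsv"),
           out_tsv(cls, "class_enrichment.tsv"))
    rows <- nrow(binned)
    if (!is.null(atlas$snp_table)) {
      near <- genes_near_snps(atlas$gene_models, atlas$snp_table,
                              window = config$tas_window)
      dyn <- intersect(need("dynamic", "enrich"), expressed)
      tas <- tas_proximity_enrichment(dyn, expressed, near$by_category)
      f <- c(f, out_tsv(tas, "tas_enrichment.tsv"))
      rows <- rows + nrow(tas)
    }
    list(rows = rows, files = f)
  })

  report$generated <- "report.json"
  jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, na = "null",
                       null = "null")
  invisible(report)
}
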