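#' Default pipeline configuration
#'
#' A single list controls the whole run: simulation parameters (see
#' [sim_config()]), normalization settings (TMM trims, log offset),
#' differential-analysis settings (alpha, blocking per species), enrichment
#' settings (tissue atlas size, classification threshold/fold, Jaccard
#' collapse threshold), the reference window for Z-trajectories, the top-level
#' seed, and the output directory. Stage seeds are fanned out from the
#' top-level seed by fixed offsets so every stage is independently
#' reproducible.
#'
#' @param ... named overrides
#' @return pipeline configuration list
#' @export
default_pipeline_config <- function(...) {
  cfg <- list(
    seed = 1L,
    outdir = "gestprot_run",
    sim = list(),                  # sim_config() overrides
    trim_M = 0.30, trim_A = 0.05, offset = 2,
    alpha = 0.05,
    block_rhesus = TRUE, block_human = FALSE,
    reference_window = "G85eq",
    atlas = list(n_tissues = 8, planted_per_tissue = 40, fold = 10),
    expr_threshold = 1, tissue_fold = 5,
    collapse_threshold = 0.7
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) stop("unknown pipeline config field(s): ",
                            paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  cfg
}

#' Read a pipeline configuration from YAML
#' @param path YAML file
#' @return pipeline configuration list
#' @export
read_pipeline_config <- function(path) {
  do.call(default_pipeline_config, yaml::read_yaml(path))
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Run the full synthetic-data analysis pipeline
#'
#' Simulate -> IRS -> TMM + log normalization -> QC -> per-species
#' differential abundance (with consensus-correlation blocking for the
#' longitudinal species) -> ortholog join, concordance and overlap
#' enrichment -> tissue classification and direction-stratified ORA ->
#' PCA, clustering, and tissue Z-trajectories. All stage outputs are written
#' as TSV under `config$outdir` together with the echoed configuration and a
#' JSON run summary. Deterministic given `config$seed`. A failure in any
#' stage writes a `FAILED` marker naming the stage and re-raises the error.
#'
#' @param config a pipeline configuration ([default_pipeline_config()]) or a
#'   YAML path
#' @return the run summary (invisibly also written to
#'   `outdir/run_summary.json`)
#' @export
run_pipeline <- function(config = default_pipeline_config()) {
  if (is.character(config)) config <- read_pipeline_config(config)
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  cfg_path <- file.path(config$outdir, "config_echo.yaml")
  yaml::write_yaml(config, cfg_path)

  stage <- "setup"
  summary <- list(config_hash = unname(tools::md5sum(cfg_path)),
                  version = as.character(utils::packageVersion("gestprot")),
                  stages = list())
  t_stage <- function(expr, name) {
    stage <<- name
    t0 <- proc.time()[["elapsed"]]
    val <- expr
    summary$stages[[name]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    val
  }
  on_fail <- function(e) {
    writeLines(paste("stage:", stage, "-", conditionMessage(e)),
               file.path(config$outdir, "FAILED"))
    stop("pipeline failed in stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  }

  tryCatch({
    ## simulate -----------------------------------------------------------
    exp <- t_stage({
      scfg <- do.call(sim_config, c(config$sim, list(seed = config$seed)))
      generate_experiment(scfg)
    }, "simulate")
    write_quant_table(exp$rhesus, file.path(config$outdir, "quant_rhesus.tsv"))
    write_quant_table(exp$human, file.path(config$outdir, "quant_human.tsv"))
    write_sample_meta(exp$meta, file.path(config$outdir, "sample_meta.tsv"))
    write_ortholog_map(exp$ortholog_map, file.path(config$outdir, "orthologs.tsv"))
    write_tsv(exp$truth$rhesus, file.path(config$outdir, "truth_rhesus.tsv"))
    write_tsv(exp$truth$human, file.path(config$outdir, "truth_human.tsv"))

    ## per-species normalization + differential ---------------------------
    species_run <- function(tbl, species, block) {
      meta_s <- exp$meta[exp$meta$species == species, ]
      tbl <- filter_immunoglobulins(tbl)
      irs <- irs_scale(tbl, meta_s)
      qc <- median_cv(irs$table, meta_s)
      bio <- meta_s$sample_id[!meta_s$is_reference_pool]
      bt <- subset_quant(irs$table, samples = bio)
      nf <- tmm_factors(bt, config$trim_M, config$trim_A)
      logmat <- log_normalize(bt, nf, config$offset)
      gs <- stats::setNames(bt$gene_symbol, bt$protein_id)
      diff <- run_differential(logmat, meta_s, alpha = config$alpha,
                               block = block, gene_symbols = gs)
      list(irs = irs, qc = qc, factors = nf, logmat = logmat, diff = diff,
           meta = meta_s)
    }
    rh <- t_stage(species_run(exp$rhesus, "rhesus", config$block_rhesus),
                  "normalize_diff_rhesus")
    hu <- t_stage(species_run(exp$human, "human", config$block_human),
                  "normalize_diff_human")
    for (s in list(list(r = rh, n = "rhesus"), list(r = hu, n = "human"))) {
      write_tsv(s$r$diff[, setdiff(names(s$r$diff), "genes")],
                file.path(config$outdir, paste0("diff_", s$n, ".tsv")))
      write_tsv(s$r$qc$group_cv, file.path(config$outdir, paste0("cv_", s$n, ".tsv")))
      write_tsv(s$r$factors, file.path(config$outdir, paste0("tmm_", s$n, ".tsv")))
      write_tsv(volcano_table(s$r$diff),
                file.path(config$outdir, paste0("volcano_", s$n, ".tsv")))
    }

    ## cross-species ------------------------------------------------------
    cross <- t_stage({
      joined <- map_orthologs(rh$diff, hu$diff, exp$ortholog_map)
      conc <- concordance_classify(joined, alpha = config$alpha)
      ab <- abundance_correlation(joined$AveExpr_rhesus, joined$AveExpr_human)
      sig_both <- joined$adj_p_rhesus < config$alpha &
        joined$adj_p_human < config$alpha
      eff <- if (sum(sig_both, na.rm = TRUE) >= 3) {
        effect_correlation(joined$logFC_human[which(sig_both)],
                           joined$logFC_rhesus[which(sig_both)])
      } else NULL
      n_sig_r <- sum(joined$adj_p_rhesus < config$alpha, na.rm = TRUE)
      n_sig_h <- sum(joined$adj_p_human < config$alpha, na.rm = TRUE)
      ov <- overlap_enrichment(n_A = n_sig_h, n_B = n_sig_r,
                               k = sum(sig_both, na.rm = TRUE),
                               N = nrow(joined))
      list(joined = joined, conc = conc, ab = ab, eff = eff, ov = ov)
    }, "cross_species")
    write_tsv(cross$conc$records, file.path(config$outdir, "concordance.tsv"))

    ## enrichment ---------------------------------------------------------
    enr <- t_stage({
      atlas <- generate_tissue_reference(
        n_genes = scfg$n_proteins, tissues = sprintf("tissue%02d", seq_len(config$atlas$n_tissues)),
        planted_per_tissue = config$atlas$planted_per_tissue,
        fold = config$atlas$fold, seed = config$seed + 101L,
        gene_symbols = exp$human$gene_symbol)
      write_tissue_reference(atlas$reference,
                             file.path(config$outdir, "tissue_atlas.tsv"))
      sets <- classify_tissue_specific(atlas$reference, config$expr_threshold,
                                       config$tissue_fold)
      shared_dir <- cross$conc$records
      up_both <- shared_dir$ortholog[shared_dir$category == "both_same_direction" &
                                       shared_dir$logFC_human > 0]
      down_both <- shared_dir$ortholog[shared_dir$category == "both_same_direction" &
                                         shared_dir$logFC_human < 0]
      universe <- unique(toupper(hu$diff$gene_symbol))
      ora <- list(
        up = if (length(up_both)) collapse_redundant(
          hypergeom_ora(up_both, sets, universe), config$collapse_threshold) else NULL,
        down = if (length(down_both)) collapse_redundant(
          hypergeom_ora(down_both, sets, universe), config$collapse_threshold) else NULL)
      list(sets = sets, ora = ora)
    }, "enrichment")
    for (d in c("up", "down")) {
      if (!is.null(enr$ora[[d]]))
        write_tsv(enr$ora[[d]][, setdiff(names(enr$ora[[d]]), "genes")],
                  file.path(config$outdir, paste0("ora_tissue_", d, ".tsv")))
    }

    ## summaries ----------------------------------------------------------
    summ <- t_stage({
      pcas <- lapply(list(rhesus = rh, human = hu), function(s) pca(s$logmat))
      zs <- lapply(list(rhesus = rh, human = hu), function(s) {
        Z <- reference_zscores(s$logmat, s$meta, config$reference_window)
        gs <- stats::setNames(
          s$diff$gene_symbol[match(rownames(Z), s$diff$protein_id)], rownames(Z))
        traj <- tissue_trajectory(Z, enr$sets, s$meta, gene_symbols = gs)
        list(Z = Z, traj = traj)
      })
      list(pcas = pcas, zs = zs)
    }, "summaries")
    for (s in c("rhesus", "human")) {
      sc <- summ$pcas[[s]]$scores[, 1:2, drop = FALSE]
      write_tsv(data.frame(sample_id = rownames(sc), sc,
                           pct_var1 = summ$pcas[[s]]$pct_var[1],
                           pct_var2 = summ$pcas[[s]]$pct_var[2]),
                file.path(config$outdir, paste0("pca_", s, ".tsv")))
      if (!is.null(summ$zs[[s]]$traj))
        write_tsv(summ$zs[[s]]$traj,
                  file.path(config$outdir, paste0("trajectories_", s, ".tsv")))
    }

    counts <- list(
      n_proteins_rhesus = nrow(rh$diff), n_proteins_human = nrow(hu$diff),
      n_sig_up_rhesus = sum(rh$diff$direction == "up"),
      n_sig_down_rhesus = sum(rh$diff$direction == "down"),
      n_sig_up_human = sum(hu$diff$direction == "up"),
      n_sig_down_human = sum(hu$diff$direction == "down"),
      n_orthologs_joined = nrow(cross$joined),
      concordance_fractions = as.list(cross$conc$fractions),
      abundance_r = cross$ab$r,
      effect_r = if (!is.null(cross$eff)) cross$eff$r else NA_real_,
      overlap_p = cross$ov$p_value,
      consensus_rho_rhesus = attr(rh$diff, "moderation")$rho,
      median_cv = stats::setNames(
        c(rh$qc$group_cv$median_cv_pct, hu$qc$group_cv$median_cv_pct),
        c(rh$qc$group_cv$group, hu$qc$group_cv$group)),
      pc1_pct_var = vapply(summ$pcas, function(p) p$pct_var[1], numeric(1)),
      n_enriched_tissues_up = if (!is.null(enr$ora$up))
        sum(enr$ora$up$adj_p < config$alpha) else 0L,
      n_enriched_tissues_down = if (!is.null(enr$ora$down))
        sum(enr$ora$down$adj_p < config$alpha) else 0L)
    summary$counts <- counts
    jsonlite::write_json(summary, file.path(config$outdir, "run_summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    invisible(summary)
  }, error = on_fail)
}
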