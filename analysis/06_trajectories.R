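#!/usr/bin/env Rscript
# Sample-level summaries: PCA of each species' log matrix, hierarchical
# clustering of the ortholog-joined matrix, and longitudinal tissue Z-score
# trajectories anchored at the earliest gestational window.

source(file.path(dirname(sub("--file=", "", grep("--file=", commandArgs(FALSE),
                                                 value = TRUE))), "00_config.R"))
out <- dir_for("summaries")

meta <- read_sample_meta(file.path(RESULTS, "sim", "sample_meta.tsv"))
enr <- utils::read.delim(file.path(RESULTS, "enrichment",
                                   "tissue_enriched_genes.tsv"))
sets <- split(enr$gene_symbol, enr$tissue)

read_logmat <- function(species) {
  df <- utils::read.delim(
    file.path(RESULTS, "normalized", paste0("logmat_", species, ".tsv")),
    check.names = FALSE)
  m <- as.matrix(df[, -(1:2)])
  rownames(m) <- df$protein_id
  attr(m, "gene_symbol") <- df$gene_symbol
  m
}

for (species in c("rhesus", "human")) {
  m <- read_logmat(species)
  ms <- meta[meta$species == species, ]

  p <- pca(m)
  age <- ms$gestational_age_days[match(rownames(p$scores), ms$sample_id)]
  tsv(data.frame(sample_id = rownames(p$scores), p$scores[, 1:3],
                 age_days = age),
      file.path(out, paste0("pca_", species, ".tsv")))
  message(sprintf("%s: PC1 explains %.0f%% of variance; cor(PC1, age) = %.2f",
                  species, p$pct_var[1], cor(p$scores[, 1], age)))

  Z <- reference_zscores(m, ms, reference_window = "G85eq")
  gs <- attr(m, "gene_symbol")[match(rownames(Z), rownames(m))]
  traj <- tissue_trajectory(Z, sets, ms, gene_symbols = gs)
  tsv(traj, file.path(out, paste0("trajectories_", species, ".tsv")))

  hc <- hierarchical_cluster(m)
  tsv(data.frame(order = seq_along(hc$leaf_order), sample = hc$leaf_order),
      file.path(out, paste0("cluster_leaves_", species, ".tsv")))

  if (requireNamespace("ggplot2", quietly = TRUE)) {
    traj$window <- factor(traj$window, c("G85eq", "G110eq", "G135eq"))
    g <- ggplot2::ggplot(traj, ggplot2::aes(window, mean_z, group = tissue,
                                            colour = tissue)) +
      ggplot2::geom_line() + ggplot2::geom_point() +
      ggplot2::labs(y = "mean tissue Z-score",
                    title = sprintf("Tissue trajectories (%s)", species)) +
      ggplot2::theme_minimal()
    ggplot2::ggsave(file.path(out, paste0("trajectories_", species, ".pdf")),
                    g, width = 6, height = 4)
  }
}
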