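#!/usr/bin/env Rscript
# Per-protein linear models of log2 abundance on gestational age (days) with
# empirical-Bayes moderation; consensus-correlation blocking for the
# longitudinal rhesus cohort. Emits ranked tables, volcano tables and, when
# ggplot2 is available, volcano plots.

source(file.path(dirname(sub("--file=", "", grep("--file=", commandArgs(FALSE),
                                                 value = TRUE))), "00_config.R"))
normd <- file.path(RESULTS, "normalized")
out <- dir_for("differential")

meta <- read_sample_meta(file.path(RESULTS, "sim", "sample_meta.tsv"))

read_logmat <- function(species) {
  df <- utils::read.delim(file.path(normd, paste0("logmat_", species, ".tsv")),
                          check.names = FALSE)
  m <- as.matrix(df[, -(1:2)])
  rownames(m) <- df$protein_id
  list(m = m, gs = stats::setNames(df$gene_symbol, df$protein_id))
}

for (species in c("rhesus", "human")) {
  lg <- read_logmat(species)
  ms <- meta[meta$species == species, ]
  block <- species == "rhesus"        # humans are cross-sectional
  d <- run_differential(lg$m, ms, alpha = ALPHA, block = block,
                        gene_symbols = lg$gs)
  mod <- attr(d, "moderation")
  tsv(d, file.path(out, paste0("diff_", species, ".tsv")))
  tsv(volcano_table(d), file.path(out, paste0("volcano_", species, ".tsv")))
  message(sprintf(
    "%s: %d/%d proteins FDR-significant (%d up, %d down); d0 = %.1f, s0^2 = %.4f%s",
    species, sum(d$direction != "ns"), nrow(d),
    sum(d$direction == "up"), sum(d$direction == "down"),
    mod$d0, mod$s0_sq,
    if (block) sprintf(", consensus rho = %.2f", mod$rho) else ""))

  if (requireNamespace("ggplot2", quietly = TRUE)) {
    v <- volcano_table(d)
    p <- ggplot2::ggplot(v, ggplot2::aes(logFC, neg_log10_p, colour = color)) +
      ggplot2::geom_point(size = 0.6, alpha = 0.7) +
      ggplot2::scale_colour_identity() +
      ggplot2::labs(x = "log2 fold change per day", y = "-log10 p",
                    title = sprintf("Gestational-age association (%s)", species)) +
      ggplot2::theme_minimal()
    ggplot2::ggsave(file.path(out, paste0("volcano_", species, ".pdf")), p,
                    width = 5, height = 4)
  }
}
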