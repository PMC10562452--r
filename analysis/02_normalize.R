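#!/usr/bin/env Rscript
# Harmonize and normalize each species: immunoglobulin filtering, internal
# reference scaling across the 3 plexes, TMM + library scaling + log2
# transform, and per-window median CV QC.

source(file.path(dirname(sub("--file=", "", grep("--file=", commandArgs(FALSE),
                                                 value = TRUE))), "00_config.R"))
simd <- file.path(RESULTS, "sim")
out <- dir_for("normalized")

meta <- read_sample_meta(file.path(simd, "sample_meta.tsv"))

for (species in c("rhesus", "human")) {
  ms <- meta[meta$species == species, ]
  tbl <- read_quant_table(file.path(simd, paste0("quant_", species, ".tsv")), ms)
  tbl <- filter_immunoglobulins(tbl)
  irs <- irs_scale(tbl, ms)
  qc <- median_cv(irs$table, ms)
  bio <- ms$sample_id[!ms$is_reference_pool]
  bt <- subset_quant(irs$table, samples = bio)
  nf <- tmm_factors(bt)
  logmat <- log_normalize(bt, nf)

  tsv(data.frame(protein_id = rownames(logmat),
                 gene_symbol = bt$gene_symbol, logmat, check.names = FALSE),
      file.path(out, paste0("logmat_", species, ".tsv")))
  tsv(nf, file.path(out, paste0("tmm_factors_", species, ".tsv")))
  tsv(qc$group_cv, file.path(out, paste0("cv_", species, ".tsv")))
  tsv(qc$sample_stats, file.path(out, paste0("sample_stats_", species, ".tsv")))
  message(sprintf("%s: %d proteins normalized over %d biological channels; median CV by window: %s",
                  species, nrow(logmat), length(bio),
                  paste(sprintf("%s %.1f%%", qc$group_cv$group,
                                qc$group_cv$median_cv_pct), collapse = ", ")))
}
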