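#!/usr/bin/env Rscript
# Tissue-signature enrichment: classify tissue-enriched genes from the atlas
# with the >1 TPM / five-fold rule, then run direction-stratified
# hypergeometric over-representation of the shared-direction
# gestational-age-associated orthologs, with Jaccard redundancy collapse.

source(file.path(dirname(sub("--file=", "", grep("--file=", commandArgs(FALSE),
                                                 value = TRUE))), "00_config.R"))
out <- dir_for("enrichment")

atlas <- read_tissue_reference(file.path(RESULTS, "sim", "tissue_atlas.tsv"))
sets <- classify_tissue_specific(atlas, expr_threshold = 1, fold = 5)
tsv(data.frame(tissue = rep(names(sets), lengths(sets)),
               gene_symbol = unlist(sets)),
    file.path(out, "tissue_enriched_genes.tsv"))
message(sprintf("classified %d tissue-enriched genes across %d tissues",
                sum(lengths(sets)), sum(lengths(sets) > 0)))

conc <- utils::read.delim(file.path(RESULTS, "cross_species", "concordance.tsv"))
hd <- utils::read.delim(file.path(RESULTS, "differential", "diff_human.tsv"))
universe <- unique(toupper(hd$gene_symbol))

for (dir in c("up", "down")) {
  genes <- conc$ortholog[conc$category == "both_same_direction" &
                           sign(conc$logFC_human) == ifelse(dir == "up", 1, -1)]
  if (!length(genes)) { message("no shared ", dir, " genes"); next }
  ora <- hypergeom_ora(genes, sets, universe)
  ora <- collapse_redundant(ora, threshold = 0.7)
  flat <- ora
  flat$genes <- vapply(ora$genes, paste, "", collapse = ",")
  tsv(flat, file.path(out, paste0("ora_tissue_", dir, ".tsv")))
  top <- ora[ora$adj_p < ALPHA, ]
  message(sprintf("%s (%d genes): %d tissue(s) enriched at adj p < %.2f%s",
                  dir, length(genes), nrow(top), ALPHA,
                  if (nrow(top)) paste0(": ", paste(top$term, collapse = ", "))
                  else ""))
}
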