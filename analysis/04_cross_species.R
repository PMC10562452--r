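#!/usr/bin/env Rscript
# Join the two species on 1:1 orthologs: abundance correlation, concordance
# of gestational-age associations, and hypergeometric enrichment of the
# overlap of significant sets.

source(file.path(dirname(sub("--file=", "", grep("--file=", commandArgs(FALSE),
                                                 value = TRUE))), "00_config.R"))
out <- dir_for("cross_species")

rd <- utils::read.delim(file.path(RESULTS, "differential", "diff_rhesus.tsv"))
hd <- utils::read.delim(file.path(RESULTS, "differential", "diff_human.tsv"))
map <- read_ortholog_map(file.path(RESULTS, "sim", "orthologs.tsv"))

j <- map_orthologs(rd, hd, map)
tsv(j, file.path(out, "joined_orthologs.tsv"))

ab <- abundance_correlation(j$AveExpr_rhesus, j$AveExpr_human)
conc <- concordance_classify(j, alpha = ALPHA)
tsv(conc$records, file.path(out, "concordance.tsv"))

sig_r <- sum(j$adj_p_rhesus < ALPHA, na.rm = TRUE)
sig_h <- sum(j$adj_p_human < ALPHA, na.rm = TRUE)
k <- sum(j$adj_p_rhesus < ALPHA & j$adj_p_human < ALPHA, na.rm = TRUE)
ov <- overlap_enrichment(n_A = sig_h, n_B = sig_r, k = k, N = nrow(j))

both <- which(j$adj_p_rhesus < ALPHA & j$adj_p_human < ALPHA)
eff <- effect_correlation(j$logFC_human[both], j$logFC_rhesus[both])

tsv(data.frame(
  n_orthologs = nrow(j), abundance_r = ab$r,
  abundance_ci_lo = ab$ci[1], abundance_ci_hi = ab$ci[2],
  sig_rhesus = sig_r, sig_human = sig_h, sig_both = k,
  overlap_p = ov$p_value, effect_r = eff$r, effect_slope = eff$slope,
  t(as.matrix(conc$fractions))), file.path(out, "summary.tsv"))

message(sprintf(
  "%d orthologs joined; mean-abundance r = %.2f; effect-size r = %.2f over %d shared-significant; overlap p = %.2e",
  nrow(j), ab$r, eff$r, k, ov$p_value))
message(paste(sprintf("%s: %.1f%%", names(conc$fractions),
                      100 * conc$fractions), collapse = "; "))
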