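#!/usr/bin/env Rscript
# Simulate the two-species longitudinal amniotic-fluid experiment: 7 rhesus
# subjects sampled at gestational days 85/110/135 across 3 plexes, 24
# cross-sectional human subjects at the percent-gestation-matched ages, ~1300
# proteins per species with ~95% shared orthologs, plus a tissue atlas with
# planted tissue-enriched gene sets.

source(file.path(dirname(sub("--file=", "", grep("--file=", commandArgs(FALSE),
                                                 value = TRUE))), "00_config.R"))
out <- dir_for("sim")

cfg <- sim_config(seed = SEED)
exp <- generate_experiment(cfg)
write_quant_table(exp$rhesus, file.path(out, "quant_rhesus.tsv"))
write_quant_table(exp$human, file.path(out, "quant_human.tsv"))
write_sample_meta(exp$meta, file.path(out, "sample_meta.tsv"))
write_ortholog_map(exp$ortholog_map, file.path(out, "orthologs.tsv"))
tsv(exp$truth$rhesus, file.path(out, "truth_rhesus.tsv"))
tsv(exp$truth$human, file.path(out, "truth_human.tsv"))
yaml::write_yaml(unclass(cfg), file.path(out, "sim_config.yaml"))

# plant two tissue signatures on gestationally drifting shared orthologs —
# a lung-like tissue whose proteins rise with gestation and a placenta-like
# tissue whose proteins fall — plus six background tissues
tr <- exp$truth$human
shared_up <- tr$gene_symbol[tr$direction == "up" & tr$is_shared][1:40]
shared_down <- tr$gene_symbol[tr$direction == "down" & tr$is_shared][1:40]
atlas <- generate_tissue_reference(
  n_genes = cfg$n_proteins,
  tissues = c("lung_like", "placenta_like", sprintf("tissue%02d", 3:8)),
  planted_per_tissue = 40, fold = 10, seed = SEED + 101L,
  gene_symbols = exp$human$gene_symbol,
  planted_genes = list(lung_like = shared_up, placenta_like = shared_down))
write_tissue_reference(atlas$reference, file.path(out, "tissue_atlas.tsv"))
tsv(data.frame(tissue = rep(names(atlas$truth_sets),
                            lengths(atlas$truth_sets)),
               gene_symbol = unlist(atlas$truth_sets)),
    file.path(out, "tissue_truth_sets.tsv"))

message(sprintf("simulated %d rhesus and %d human proteins over %d channels; %d 1:1 orthologs",
                nrow(exp$rhesus$intensity), nrow(exp$human$intensity),
                nrow(exp$meta), sum(exp$ortholog_map$is_unique)))
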