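# Shared settings for the analysis scripts. Each numbered script can be run
# on its own (it reads the previous stage's TSVs from results/) provided the
# earlier stages have been run once.

library(gestprot)

SEED <- 1L
RESULTS <- "results"
ALPHA <- 0.05

dir_for <- function(stage) {
  d <- file.path(RESULTS, stage)
  dir.create(d, recursive = TRUE, showWarnings = FALSE)
  d
}

tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}
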