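#' Term lengths (days) used for gestational-window matching
#'
#' Rhesus macaque gestation is taken as 168 days and human gestation as 280
#' days; gestational windows are matched across species by percent completed
#' gestation against the rhesus sampling anchors (days 85, 110, 135).
#' @keywords internal
TERM_DAYS <- c(rhesus = 168, human = 280)

#' Rhesus anchor gestational days defining the three sampling windows
#' @keywords internal
WINDOW_ANCHORS <- c(G85eq = 85, G110eq = 110, G135eq = 135)

#' Construct a quantification table
#'
#' A `quant_table` is the pipeline's central object: a proteins x channels
#' matrix of non-negative reporter-ion intensities (arbitrary units) with a
#' protein accession per row and an optional gene symbol annotation.
#'
#' @param intensity numeric matrix, rows = proteins (rownames = accessions),
#'   columns = sample ids. Missing values are `NA`, never 0.
#' @param gene_symbol character vector of gene symbols, one per row (uppercased
#'   on construction for cross-species joins). Defaults to the rownames.
#' @return An object of class `quant_table`: a list with elements
#'   `protein_id`, `gene_symbol` and `intensity`.
#' @export
quant_table <- function(intensity, gene_symbol = rownames(intensity)) {
  if (!is.matrix(intensity) || !is.numeric(intensity))
    stop("intensity must be a numeric matrix")
  if (is.null(rownames(intensity)))
    stop("intensity must have protein ids as rownames")
  if (anyDuplicated(rownames(intensity)))
    stop("protein_id must be unique per table")
  if (is.null(colnames(intensity)))
    stop("intensity must have sample ids as colnames")
  neg <- which(intensity < 0, arr.ind = TRUE)
  if (nrow(neg)) {
    stop(sprintf("negative intensity for protein '%s' in channel '%s'",
                 rownames(intensity)[neg[1, 1]], colnames(intensity)[neg[1, 2]]))
  }
  structure(list(protein_id = rownames(intensity),
                 gene_symbol = toupper(as.character(gene_symbol)),
                 intensity = intensity),
            class = "quant_table")
}

#' @export
print.quant_table <- function(x, ...) {
  cat(sprintf("quant_table: %d proteins x %d channels\n",
              nrow(x$intensity), ncol(x$intensity)))
  invisible(x)
}

#' @export
dim.quant_table <- function(x) dim(x$intensity)

#' Subset a quant_table by protein and/or channel
#' @param table a `quant_table`
#' @param proteins,samples index vectors (logical, integer or names)
#' @return a `quant_table`
#' @export
subset_quant <- function(table, proteins = NULL, samples = NULL) {
  stopifnot(inherits(table, "quant_table"))
  ip <- if (is.null(proteins)) seq_len(nrow(table$intensity)) else proteins
  is_ <- if (is.null(samples)) seq_len(ncol(table$intensity)) else samples
  m <- table$intensity[ip, is_, drop = FALSE]
  gs <- table$gene_symbol[match(rownames(m), table$protein_id)]
  quant_table(m, gs)
}

#' Validate per-channel sample metadata
#'
#' Sample metadata carries one row per channel: `sample_id`, `species`
#' ("human" or "rhesus"), `subject_id`, `gestational_age_days`, `window`,
#' `plex_id`, `channel_label` and `is_reference_pool`. Reference-pool channels
#' (pooled aliquots shared across plexes) have `NA` age and window.
#'
#' @param meta data.frame of sample metadata
#' @return `meta`, invisibly, with `window` recomputed where missing
#' @export
validate_sample_meta <- function(meta) {
  need <- c("sample_id", "species", "subject_id", "gestational_age_days",
            "window", "plex_id", "channel_label", "is_reference_pool")
  miss <- setdiff(need, names(meta))
  if (length(miss)) stop("sample metadata missing column(s): ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(meta$sample_id))
    stop("sample_id values must be unique")
  if (!all(meta$species %in% names(TERM_DAYS)))
    stop("species must be one of: ", paste(names(TERM_DAYS), collapse = ", "))
  bio <- !meta$is_reference_pool
  age <- meta$gestational_age_days[bio]
  term <- TERM_DAYS[meta$species[bio]]
  bad <- which(!is.finite(age) | age <= 0 | age >= term)
  if (length(bad))
    stop(sprintf("gestational_age_days out of (0, term) for sample '%s'",
                 meta$sample_id[bio][bad[1]]))
  if (anyDuplicated(meta[, c("plex_id", "channel_label")]))
    stop("(plex_id, channel_label) pairs must be unique")
  no_ref <- setdiff(unique(meta$plex_id),
                    unique(meta$plex_id[meta$is_reference_pool]))
  if (length(no_ref))
    stop("plex without any reference-pool channel: ",
         paste(no_ref, collapse = ", "))
  invisible(meta)
}

#' Map a gestational age to its rhesus-equivalent window
#'
#' Windows are anchored at rhesus gestational days 85, 110 and 135; an age of
#' either species is assigned to the window whose anchor fraction of term
#' (85/168, 110/168, 135/168) is nearest to `age_days / term(species)`.
#'
#' @param age_days gestational age in days (vectorized)
#' @param species "rhesus" or "human" (recycled)
#' @return character vector among "G85eq", "G110eq", "G135eq"
#' @examples
#' rhesus_equivalent_window(85, "rhesus")   # "G85eq"
#' rhesus_equivalent_window(140, "human")   # "G85eq" (140/280 nearest 85/168)
#' @export
rhesus_equivalent_window <- function(age_days, species) {
  species <- rep_len(species, length(age_days))
  if (!all(species %in% names(TERM_DAYS)))
    stop("unknown species")
  term <- TERM_DAYS[species]
  if (any(!is.finite(age_days) | age_days <= 0 | age_days >= term))
    stop("age_days must lie strictly within (0, term length)")
  frac <- age_days / term
  anchors <- WINDOW_ANCHORS / TERM_DAYS["rhesus"]
  idx <- apply(abs(outer(frac, anchors, "-")), 1, which.min)
  names(WINDOW_ANCHORS)[idx]
}

#' Read / write sample metadata TSV
#' @param path file path
#' @return data.frame of validated sample metadata
#' @export
read_sample_meta <- function(path) {
  meta <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                            na.strings = c("NA", ""))
  meta$is_reference_pool <- as.logical(meta$is_reference_pool)
  validate_sample_meta(meta)
  meta
}

#' @rdname read_sample_meta
#' @param meta data.frame of sample metadata
#' @export
write_sample_meta <- function(meta, path) {
  validate_sample_meta(meta)
  utils::write.table(meta, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Read a protein quantification TSV
#'
#' Expects a header row with `protein_id`, `gene_symbol` and then one column
#' per sample id; empty cells are missing values (never zero). Columns are
#' validated against the sample metadata.
#'
#' @param path TSV path
#' @param meta validated sample metadata (or `NULL` to skip the check)
#' @return a `quant_table`
#' @export
read_quant_table <- function(path, meta = NULL) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          na.strings = c("NA", ""), check.names = FALSE)
  if (!all(c("protein_id", "gene_symbol") %in% names(df)[1:2]))
    stop("first columns must be protein_id, gene_symbol")
  samp <- setdiff(names(df), c("protein_id", "gene_symbol"))
  if (!is.null(meta)) {
    unknown <- setdiff(samp, meta$sample_id)
    if (length(unknown))
      stop("unknown sample_id column(s): ", paste(unknown, collapse = ", "))
  }
  m <- as.matrix(df[, samp, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- df$protein_id
  neg <- which(m < 0, arr.ind = TRUE)
  if (nrow(neg))
    stop(sprintf("negative intensity for protein '%s' in channel '%s'",
                 rownames(m)[neg[1, 1]], colnames(m)[neg[1, 2]]))
  quant_table(m, df$gene_symbol)
}

#' @rdname read_quant_table
#' @param table a `quant_table`
#' @export
write_quant_table <- function(table, path) {
  stopifnot(inherits(table, "quant_table"))
  df <- data.frame(protein_id = table$protein_id,
                   gene_symbol = table$gene_symbol,
                   table$intensity, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Remove immunoglobulin-family proteins
#'
#' Drops rows whose gene symbol matches the immunoglobulin heavy/kappa/lambda
#' locus prefixes (IGH*, IGK*, IGL* — variable, joining and constant segments)
#' or JCHAIN. IG*-prefixed genes that are not immunoglobulins (IGSF*, IGF*,
#' IGFBP*) do not match the prefix rule; an explicit whitelist guards the few
#' IGH-prefixed non-immunoglobulins.
#'
#' @param table a `quant_table`
#' @param whitelist gene symbols never removed despite matching the prefixes
#' @return a `quant_table` with immunoglobulin rows removed; retained rows are
#'   byte-identical to the input rows
#' @export
filter_immunoglobulins <- function(table, whitelist = c("IGHMBP2")) {
  stopifnot(inherits(table, "quant_table"))
  sym <- table$gene_symbol
  ig <- (grepl("^IG[HKL]", sym) | sym == "JCHAIN") & !(sym %in% whitelist)
  if (!any(ig)) return(table)
  subset_quant(table, proteins = which(!ig))
}

#' Read / write an ortholog map TSV
#'
#' Columns `rhesus_id`, `human_gene_symbol`, `is_unique`. Rows flagged
#' `is_unique` must form a one-to-one mapping in both directions.
#'
#' @param path TSV path
#' @return data.frame ortholog map
#' @export
read_ortholog_map <- function(path) {
  m <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  m$is_unique <- as.logical(m$is_unique)
  m$human_gene_symbol <- toupper(m$human_gene_symbol)
  validate_ortholog_map(m)
  m
}

#' @rdname read_ortholog_map
#' @param map ortholog map data.frame
#' @export
write_ortholog_map <- function(map, path) {
  validate_ortholog_map(map)
  utils::write.table(map, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname read_ortholog_map
#' @export
validate_ortholog_map <- function(map) {
  need <- c("rhesus_id", "human_gene_symbol", "is_unique")
  if (!all(need %in% names(map)))
    stop("ortholog map must have columns: ", paste(need, collapse = ", "))
  u <- map[map$is_unique, ]
  if (anyDuplicated(u$rhesus_id) || anyDuplicated(u$human_gene_symbol))
    stop("is_unique rows must form a one-to-one mapping in both directions")
  invisible(map)
}

#' Read / write a tissue reference expression matrix
#'
#' Genes x tissues matrix of TPM-like non-negative expression values, TSV with
#' a `gene_symbol` first column and one column per tissue.
#'
#' @param path TSV path
#' @return numeric matrix, rownames = gene symbols, colnames = tissues
#' @export
read_tissue_reference <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          check.names = FALSE)
  if (names(df)[1] != "gene_symbol") stop("first column must be gene_symbol")
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- toupper(df$gene_symbol)
  if (anyDuplicated(colnames(m))) stop("tissue names must be unique")
  if (any(m < 0, na.rm = TRUE)) stop("tissue expression must be non-negative")
  m
}

#' @rdname read_tissue_reference
#' @param ref genes x tissues matrix
#' @export
write_tissue_reference <- function(ref, path) {
  df <- data.frame(gene_symbol = rownames(ref), ref, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a GMT gene-set collection
#'
#' Standard GMT dialect: one set per line, tab-separated
#' `set_id<TAB>description<TAB>member1<TAB>member2...`. Members are
#' deduplicated preserving first-occurrence order.
#'
#' @param path GMT path
#' @return a `gene_sets` object: named list of member vectors with a
#'   `set_name` attribute (descriptions)
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  sets <- list(); nm <- character(0)
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3)
      stop(sprintf("GMT line %d has fewer than 3 fields", i))
    members <- unique(f[-(1:2)])
    members <- members[nzchar(members)]
    if (!length(members)) stop(sprintf("GMT line %d has no members", i))
    sets[[f[1]]] <- members
    nm[f[1]] <- f[2]
  }
  if (anyDuplicated(names(sets))) stop("duplicate set_id in GMT")
  gene_sets(sets, nm)
}

#' @rdname read_gmt
#' @param sets named list of character vectors
#' @param set_name named character vector of descriptions
#' @export
gene_sets <- function(sets, set_name = NULL) {
  if (is.null(set_name)) set_name <- stats::setNames(names(sets), names(sets))
  structure(lapply(sets, unique), set_name = set_name, class = "gene_sets")
}

#' @rdname read_gmt
#' @param collection a `gene_sets` object
#' @export
write_gmt <- function(collection, path) {
  nm <- attr(collection, "set_name")
  lines <- vapply(names(collection), function(id) {
    paste(c(id, nm[[id]], collection[[id]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @export
print.gene_sets <- function(x, ...) {
  cat(sprintf("gene_sets: %d sets, %d distinct genes\n",
              length(x), length(unique(unlist(x)))))
  invisible(x)
}
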