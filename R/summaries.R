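#' Principal component analysis of a log expression matrix
#'
#' Samples are observations, proteins features. Each protein (row) is
#' centered, the centered matrix decomposed by SVD; scores are the sample
#' projections and the percent variance explained per component is the
#' squared singular value over the total. Rows with missing values are
#' excluded with a warning.
#'
#' @param logmat proteins x samples matrix
#' @return list with `scores` (samples x components), `loadings` (proteins x
#'   components, orthonormal), `pct_var` and `sdev`
#' @export
pca <- function(logmat) {
  if (nrow(logmat) < 2 || ncol(logmat) < 2)
    stop("PCA requires at least 2 proteins and 2 samples")
  ok <- stats::complete.cases(logmat)
  if (!all(ok)) {
    warning(sum(!ok), " protein(s) with missing values excluded from PCA")
    logmat <- logmat[ok, , drop = FALSE]
  }
  Xc <- logmat - rowMeans(logmat)
  if (all(abs(Xc) < 1e-12)) stop("constant matrix: no variance to decompose")
  sv <- svd(t(Xc))
  scores <- sv$u %*% diag(sv$d, length(sv$d))
  rownames(scores) <- colnames(logmat)
  colnames(scores) <- paste0("PC", seq_along(sv$d))
  loadings <- sv$v
  rownames(loadings) <- rownames(logmat)
  colnames(loadings) <- colnames(scores)
  list(scores = scores, loadings = loadings,
       pct_var = 100 * sv$d^2 / sum(sv$d^2), sdev = sv$d / sqrt(ncol(logmat) - 1))
}

#' Hierarchical clustering of samples
#'
#' Agglomerative clustering of sample columns with correlation distance
#' (1 - Pearson, pairwise-complete) or Euclidean distance, and a configurable
#' linkage (default average). Deterministic given the input ordering.
#'
#' @param logmat proteins x samples matrix
#' @param distance "pearson" (1 - correlation) or "euclidean"
#' @param linkage an `stats::hclust` method (default "average")
#' @return list with `hclust` (the tree), `leaf_order`, `distance`, `linkage`
#' @export
hierarchical_cluster <- function(logmat, distance = c("pearson", "euclidean"),
                                 linkage = "average") {
  distance <- match.arg(distance)
  if (ncol(logmat) < 2) stop("at least 2 samples are required")
  allna <- colSums(!is.na(logmat)) == 0
  if (any(allna)) {
    warning("sample(s) with no observed values excluded: ",
            paste(colnames(logmat)[allna], collapse = ", "))
    logmat <- logmat[, !allna, drop = FALSE]
  }
  d <- if (distance == "pearson") {
    stats::as.dist(1 - stats::cor(logmat, use = "pairwise.complete.obs"))
  } else {
    stats::dist(t(logmat))
  }
  hc <- stats::hclust(d, method = linkage)
  list(hclust = hc, leaf_order = hc$labels[hc$order],
       distance = distance, linkage = linkage)
}

#' Reference-anchored Z-scores
#'
#' Standardizes each protein against the samples of a reference gestational
#' window: `Z = (x - mean_ref) / sd_ref` with the sample (n-1) standard
#' deviation. Proteins with zero or undefined reference SD are excluded and
#' reported in the `excluded` attribute.
#'
#' @param logmat proteins x samples log2 matrix (biological channels)
#' @param meta sample metadata
#' @param reference_window window defining the reference group (default
#'   "G85eq")
#' @return Z-score matrix (possibly fewer rows than input)
#' @export
reference_zscores <- function(logmat, meta, reference_window = "G85eq") {
  meta <- meta[match(colnames(logmat), meta$sample_id), ]
  ref_cols <- which(!meta$is_reference_pool & meta$window == reference_window)
  if (length(ref_cols) < 2)
    stop("reference window '", reference_window, "' needs >= 2 samples")
  mu <- rowMeans(logmat[, ref_cols, drop = FALSE], na.rm = TRUE)
  sd_ref <- apply(logmat[, ref_cols, drop = FALSE], 1, stats::sd, na.rm = TRUE)
  bad <- !is.finite(sd_ref) | sd_ref == 0
  Z <- (logmat[!bad, , drop = FALSE] - mu[!bad]) / sd_ref[!bad]
  attr(Z, "excluded") <- rownames(logmat)[bad]
  attr(Z, "reference_window") <- reference_window
  Z
}

#' Tissue-level longitudinal Z-score trajectories
#'
#' For each tissue-enriched gene set intersecting the matrix: per window, the
#' per-protein mean Z over that window's samples is averaged across member
#' proteins (SD and member count reported), giving one longitudinal
#' trajectory per tissue.
#'
#' @param Z Z-score matrix from [reference_zscores()] (rows named by gene
#'   symbol, or supply `gene_symbols`)
#' @param sets a `tissue_sets` object (or named list tissue -> genes)
#' @param meta sample metadata
#' @param gene_symbols optional gene symbols for the rows of `Z`
#' @return data.frame with columns `tissue`, `window`, `mean_z`, `sd_z`, `n`
#' @export
tissue_trajectory <- function(Z, sets, meta, gene_symbols = rownames(Z)) {
  meta <- meta[match(colnames(Z), meta$sample_id), ]
  bio <- !meta$is_reference_pool & !is.na(meta$window)
  windows <- names(WINDOW_ANCHORS)[names(WINDOW_ANCHORS) %in% meta$window[bio]]
  gene_symbols <- toupper(gene_symbols)
  rows <- lapply(names(sets), function(tis) {
    idx <- which(gene_symbols %in% toupper(sets[[tis]]))
    if (!length(idx)) {
      warning("tissue '", tis, "' has no member proteins in the matrix; omitted")
      return(NULL)
    }
    do.call(rbind, lapply(windows, function(w) {
      cols <- which(bio & meta$window == w)
      per_protein <- rowMeans(Z[idx, cols, drop = FALSE], na.rm = TRUE)
      data.frame(tissue = tis, window = w,
                 mean_z = mean(per_protein, na.rm = TRUE),
                 sd_z = stats::sd(per_protein, na.rm = TRUE),
                 n = sum(is.finite(per_protein)),
                 stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Volcano-plot-ready table
#'
#' @param diff a differential result table
#' @param cap cap on -log10(p) to avoid infinities at numeric underflow
#' @return data.frame with `protein_id`, `gene_symbol`, `logFC`,
#'   `neg_log10_p` and `color` (up = red, down = blue, ns = grey)
#' @export
volcano_table <- function(diff, cap = 320) {
  data.frame(protein_id = diff$protein_id, gene_symbol = diff$gene_symbol,
             logFC = diff$logFC,
             neg_log10_p = pmin(-log10(diff$p_value), cap),
             color = c(up = "red", down = "blue", ns = "grey")[diff$direction],
             stringsAsFactors = FALSE)
}
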