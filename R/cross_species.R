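#' Join two species' results on 1:1 orthologs
#'
#' Inner join restricted to ortholog pairs flagged unique; many-to-one and
#' one-to-many pairs are excluded. The rhesus side is keyed by protein
#' accession (`rhesus_id`), the human side by gene symbol.
#'
#' @param rhesus,human data.frames carrying a key column (`protein_id` for
#'   rhesus, `gene_symbol` — falling back to `protein_id` — for human)
#' @param map ortholog map with `rhesus_id`, `human_gene_symbol`, `is_unique`
#' @return joined data.frame with columns suffixed `_rhesus` / `_human` and an
#'   `ortholog` key column; attribute `cardinality` reports map and join sizes
#' @export
map_orthologs <- function(rhesus, human, map) {
  validate_ortholog_map(map)
  u <- map[map$is_unique, c("rhesus_id", "human_gene_symbol")]
  hkey <- if ("gene_symbol" %in% names(human)) human$gene_symbol else human$protein_id
  ir <- match(u$rhesus_id, rhesus$protein_id)
  ih <- match(u$human_gene_symbol, toupper(hkey))
  keep <- !is.na(ir) & !is.na(ih)
  if (!any(keep)) stop("no orthologs shared between the two tables")
  r <- rhesus[ir[keep], , drop = FALSE]
  h <- human[ih[keep], , drop = FALSE]
  names(r) <- paste0(names(r), "_rhesus")
  names(h) <- paste0(names(h), "_human")
  out <- cbind(ortholog = u$human_gene_symbol[keep], r, h,
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "cardinality") <- c(map_pairs = nrow(map),
                                unique_pairs = nrow(u),
                                joined = nrow(out))
  out
}

fisher_ci <- function(r, n, level = 0.95) {
  if (n <= 3) return(c(NA_real_, NA_real_))
  z <- atanh(r) + c(-1, 1) * stats::qnorm(1 - (1 - level) / 2) / sqrt(n - 3)
  tanh(z)
}

#' Pearson correlation of per-protein mean abundances across species
#'
#' @param x,y per-ortholog mean log intensities in the two species
#' @return list with `r`, `ci` (95% Fisher-z interval, omitted for n <= 3),
#'   `p_value` and `n`
#' @export
abundance_correlation <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("at least 3 ortholog pairs are required")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance in one of the vectors")
  r <- stats::cor(x, y)
  n <- length(x)
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, ci = fisher_ci(r, n),
       p_value = 2 * stats::pt(-abs(tstat), n - 2), n = n)
}

#' Classify cross-species concordance of gestational-age associations
#'
#' Each joined ortholog is assigned one of four categories:
#' `both_same_direction` / `both_opposite` (FDR-significant in both species,
#' matching / opposing slope signs), `one_species_only`, or `neither`.
#' Orthologs with missing statistics in either species are excluded and
#' counted separately.
#'
#' @param joined output of [map_orthologs()] over two differential tables
#'   (columns `logFC_*`, `adj_p_*`)
#' @param alpha FDR significance threshold
#' @return list with `records` (per-ortholog category table), `fractions`
#'   (named category fractions summing to 1) and `n_excluded`
#' @export
concordance_classify <- function(joined, alpha = 0.05) {
  need <- c("logFC_rhesus", "adj_p_rhesus", "logFC_human", "adj_p_human")
  if (!all(need %in% names(joined)))
    stop("joined table must carry logFC and adj_p for both species")
  ok <- stats::complete.cases(joined[, need])
  d <- joined[ok, ]
  sig_r <- d$adj_p_rhesus < alpha
  sig_h <- d$adj_p_human < alpha
  same <- sign(d$logFC_rhesus) == sign(d$logFC_human)
  category <- ifelse(sig_r & sig_h & same, "both_same_direction",
              ifelse(sig_r & sig_h, "both_opposite",
              ifelse(sig_r | sig_h, "one_species_only", "neither")))
  levs <- c("both_same_direction", "both_opposite", "one_species_only", "neither")
  frac <- table(factor(category, levels = levs)) / length(category)
  records <- data.frame(ortholog = d$ortholog, category = category,
                        logFC_rhesus = d$logFC_rhesus, adj_p_rhesus = d$adj_p_rhesus,
                        logFC_human = d$logFC_human, adj_p_human = d$adj_p_human,
                        stringsAsFactors = FALSE)
  list(records = records, fractions = c(frac), n_excluded = sum(!ok))
}

#' Exact hypergeometric enrichment of an overlap
#'
#' Upper-tail probability of observing at least `k` shared elements between
#' two sets of sizes `n_A` and `n_B` drawn from a universe of size `N`:
#' `p = P(X >= k)` with `X ~ Hypergeometric(N, K = n_B, n = n_A)`. Exact, and
#' symmetric in the two set sizes.
#'
#' @param n_A,n_B sizes of the two sets
#' @param k observed overlap
#' @param N universe size
#' @return list with `counts` (N, K, n, k) and `p_value`
#' @export
overlap_enrichment <- function(n_A, n_B, k, N) {
  if (any(c(n_A, n_B, k, N) < 0) || n_A > N || n_B > N ||
      k > min(n_A, n_B))
    stop("inconsistent overlap counts")
  p <- stats::phyper(k - 1, n_B, N - n_B, n_A, lower.tail = FALSE)
  list(counts = list(N = N, K = n_B, n = n_A, k = k), p_value = p)
}

#' Correlation of effect sizes between species
#'
#' Pearson correlation of per-day log2 slopes over a restricted ortholog set
#' (typically those FDR-significant in both species), with the least-squares
#' line for plotting.
#'
#' @param logFC_A,logFC_B effect sizes in the two species
#' @return list with `r`, `ci`, `p_value`, `n`, `slope` and `intercept`
#' @export
effect_correlation <- function(logFC_A, logFC_B) {
  res <- abundance_correlation(logFC_A, logFC_B)
  ok <- is.finite(logFC_A) & is.finite(logFC_B)
  fit <- stats::lm.fit(cbind(1, logFC_A[ok]), logFC_B[ok])
  res$intercept <- unname(fit$coefficients[1])
  res$slope <- unname(fit$coefficients[2])
  res
}

#' Compare internal results with an external protein list
#'
#' Counts how many externally reported gestational-age-associated proteins
#' were identified internally, how many overlap the internal significant set
#' (with an exact hypergeometric enrichment p over the internally quantified
#' universe), how many agree in direction, and — when the external list
#' carries effect sizes — the Pearson correlation of logFC over shared
#' proteins.
#'
#' @param internal a differential result table (with `gene_symbol`, `logFC`,
#'   `direction`)
#' @param external data.frame with `gene` and `direction` and/or `logFC`
#' @param alpha FDR threshold defining the internal significant set
#' @return list of counts, the hypergeometric `OverlapTest`, and `r` (NA when
#'   the external list has no effect sizes)
#' @export
compare_to_external <- function(internal, external, alpha = 0.05) {
  gene_int <- toupper(internal$gene_symbol)
  gene_ext <- unique(toupper(external$gene))
  identified <- intersect(gene_ext, gene_int)
  sig <- gene_int[internal$adj_p < alpha & !is.na(internal$adj_p)]
  overlapping <- intersect(identified, sig)

  consistent <- NA_integer_
  ext_dir <- NULL
  if ("direction" %in% names(external)) {
    ext_dir <- external$direction
  } else if ("logFC" %in% names(external)) {
    ext_dir <- ifelse(external$logFC > 0, "up", "down")
  }
  if (!is.null(ext_dir)) {
    ed <- ext_dir[match(overlapping, toupper(external$gene))]
    id <- internal$direction[match(overlapping, gene_int)]
    consistent <- sum(ed == id, na.rm = TRUE)
  }
  ov <- overlap_enrichment(n_A = length(identified), n_B = length(sig),
                           k = length(overlapping), N = length(gene_int))
  r <- NA_real_
  if ("logFC" %in% names(external) && length(overlapping) >= 3) {
    r <- stats::cor(external$logFC[match(overlapping, toupper(external$gene))],
                    internal$logFC[match(overlapping, gene_int)])
  }
  list(n_external = length(gene_ext), n_identified = length(identified),
       n_overlapping = length(overlapping), n_consistent = consistent,
       overlap_test = ov, r = r)
}
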