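#' Classify tissue-enriched genes from a reference expression atlas
#'
#' A gene is enriched in tissue t iff its expression there exceeds
#' `expr_threshold` (TPM-like units) AND is at least `fold` times the maximum
#' expression over all other tissues — the Human Protein Atlas
#' "tissue enriched" convention. Under the max-fold rule a gene can be
#' enriched in at most one tissue.
#'
#' @param ref genes x tissues non-negative expression matrix
#' @param expr_threshold minimum expression in the enriched tissue (default 1)
#' @param fold minimum fold over the highest other tissue (default 5)
#' @return a `tissue_sets` object: named list tissue -> enriched gene
#'   symbols, with the parameters as attributes
#' @export
classify_tissue_specific <- function(ref, expr_threshold = 1, fold = 5) {
  if (ncol(ref) < 2) stop("at least two tissues are required")
  top_idx <- max.col(ref, ties.method = "first")
  top <- ref[cbind(seq_len(nrow(ref)), top_idx)]
  second <- vapply(seq_len(nrow(ref)),
                   function(i) max(ref[i, -top_idx[i]]), numeric(1))
  enriched <- top > expr_threshold & top >= fold * second
  sets <- lapply(seq_len(ncol(ref)), function(j) {
    rownames(ref)[enriched & top_idx == j]
  })
  names(sets) <- colnames(ref)
  structure(sets, expr_threshold = expr_threshold, fold = fold,
            class = c("tissue_sets", "list"))
}

#' Hypergeometric over-representation analysis
#'
#' Tests each term of a collection for over-representation in a query gene
#' set within a finite universe. Counts follow the standard (N, K, n, k)
#' convention: N = universe size, K = term size within the universe, n =
#' query size, k = overlap. p-values are exact upper-tail hypergeometric
#' probabilities; BH adjustment is applied across the tested terms. Terms
#' with no members in the universe are skipped.
#'
#' @param query character vector of gene symbols (members outside the
#'   universe are dropped with a warning)
#' @param collection a `gene_sets` or `tissue_sets` object (named list of
#'   member vectors)
#' @param universe character vector of gene symbols
#' @return data.frame sorted by p-value with columns `term`, `N`, `K`, `n`,
#'   `k`, `gene_ratio` ("k/n"), `p_value`, `adj_p` and a list-column `genes`
#'   of overlap members
#' @export
hypergeom_ora <- function(query, collection, universe) {
  universe <- unique(toupper(universe))
  query <- unique(toupper(query))
  if (!length(universe)) stop("empty universe")
  if (!length(query)) stop("empty query")
  outside <- setdiff(query, universe)
  if (length(outside)) {
    warning(length(outside), " query gene(s) outside the universe dropped")
    query <- setdiff(query, outside)
    if (!length(query)) stop("no query genes inside the universe")
  }
  N <- length(universe); n <- length(query)
  rows <- lapply(names(collection), function(id) {
    members <- intersect(toupper(collection[[id]]), universe)
    K <- length(members)
    if (K == 0) return(NULL)
    hit <- intersect(members, query)
    k <- length(hit)
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term = id, N = N, K = K, n = n, k = k,
               gene_ratio = sprintf("%d/%d", k, n), p_value = p,
               genes = I(list(hit)), stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) {
    return(data.frame(term = character(), N = integer(), K = integer(),
                      n = integer(), k = integer(), gene_ratio = character(),
                      p_value = numeric(), adj_p = numeric(),
                      genes = I(list()), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out$adj_p <- bh_adjust(out$p_value)
  out <- out[order(out$p_value), c("term", "N", "K", "n", "k", "gene_ratio",
                                   "p_value", "adj_p", "genes")]
  rownames(out) <- NULL
  out
}

jaccard <- function(a, b) {
  u <- length(union(a, b))
  if (u == 0) return(0)
  length(intersect(a, b)) / u
}

#' Collapse redundant enriched terms
#'
#' Greedy simplification in ascending p-value order: a term is dropped when
#' the Jaccard index of its overlap gene set with an already-kept term
#' exceeds `threshold`. The smallest-p term is always kept. Dropped terms are
#' reported with the term that absorbed them.
#'
#' @param results an ORA result table (from [hypergeom_ora()]) carrying the
#'   `genes` list-column
#' @param threshold Jaccard cutoff above which a term is considered redundant
#'   (default 0.7)
#' @return the kept subset of `results`; attribute `dropped` maps dropped
#'   terms to the kept term that absorbed them
#' @export
collapse_redundant <- function(results, threshold = 0.7) {
  if (!nrow(results)) return(results)
  ord <- order(results$p_value)
  kept <- integer(0)
  dropped_by <- character(0)
  for (i in ord) {
    sim <- vapply(kept, function(j) jaccard(results$genes[[i]],
                                            results$genes[[j]]), numeric(1))
    if (length(sim) && any(sim > threshold)) {
      dropped_by[results$term[i]] <- results$term[kept[which.max(sim)]]
    } else {
      kept <- c(kept, i)
    }
  }
  out <- results[sort(kept), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "dropped") <- dropped_by
  out
}

#' Direction-stratified over-representation analysis
#'
#' Runs [hypergeom_ora()] separately on the significantly up- and
#' down-regulated gene sets of a differential result against the same
#' universe (by default all genes tested in the differential analysis), with
#' BH adjustment within each direction.
#'
#' @param diff a differential result table (with `gene_symbol`, `direction`)
#' @param collection a `gene_sets` or `tissue_sets` object
#' @param universe gene universe (default: all gene symbols in `diff`)
#' @return list with ORA tables `up` and `down` (empty tables when a
#'   direction has no significant genes)
#' @export
enrich_by_direction <- function(diff, collection,
                                universe = unique(toupper(diff$gene_symbol))) {
  one <- function(dir) {
    q <- unique(toupper(diff$gene_symbol[diff$direction == dir]))
    if (!length(q)) {
      return(data.frame(term = character(), N = integer(), K = integer(),
                        n = integer(), k = integer(), gene_ratio = character(),
                        p_value = numeric(), adj_p = numeric(),
                        genes = I(list()), stringsAsFactors = FALSE))
    }
    hypergeom_ora(q, collection, universe)
  }
  list(up = one("up"), down = one("down"))
}
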