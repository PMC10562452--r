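geomean <- function(x) {
  x <- x[is.finite(x) & x > 0]
  if (!length(x)) return(NA_real_)
  exp(mean(log(x)))
}

#' Internal reference scaling (IRS) across plexes
#'
#' Puts reporter-ion intensities from several plexes on a common per-protein
#' abundance scale using the pooled-reference channels present in every plex.
#' For protein g and plex p, `R_gp` is the geometric mean of g's
#' reference-pool intensities in p (zeros and missing values are ignored);
#' `G_g` is the geometric mean of the `R_gp` over plexes where defined; every
#' channel of plex p is multiplied by `f_gp = G_g / R_gp`. After scaling, the
#' per-plex reference geometric means are identical across plexes for
#' proteins observed in all plex reference pools. Proteins missing from a
#' plex's reference pools have no defined scale in that plex: their values in
#' that plex are set to missing rather than left on an unknown scale.
#'
#' @param table a `quant_table` (one species)
#' @param meta sample metadata covering the table's channels
#' @return list with `table` (IRS-scaled `quant_table`) and `factors` (a list
#'   with matrices `R` (proteins x plexes), `G` (global geometric means) and
#'   `f` (scale factors))
#' @export
irs_scale <- function(table, meta) {
  stopifnot(inherits(table, "quant_table"))
  meta <- meta[match(colnames(table$intensity), meta$sample_id), ]
  if (anyNA(meta$sample_id))
    stop("metadata missing for some table channels")
  plexes <- unique(meta$plex_id)
  for (p in plexes) {
    if (!any(meta$is_reference_pool & meta$plex_id == p))
      stop("plex '", p, "' has no reference-pool channel")
  }
  x <- table$intensity
  R <- sapply(plexes, function(p) {
    cols <- meta$sample_id[meta$plex_id == p & meta$is_reference_pool]
    apply(x[, cols, drop = FALSE], 1, geomean)
  })
  R <- matrix(R, nrow = nrow(x), dimnames = list(rownames(x), plexes))
  G <- apply(R, 1, geomean)
  f <- G / R                     # NA where protein absent from plex refs
  if (length(plexes) == 1L) f[] <- 1   # no cross-plex scale to reconcile

  scaled <- x
  for (p in plexes) {
    cols <- meta$sample_id[meta$plex_id == p]
    scaled[, cols] <- x[, cols, drop = FALSE] * f[, p]
  }
  out <- quant_table(scaled, table$gene_symbol)
  list(table = out, factors = list(R = R, G = G, f = f))
}

#' Trimmed mean of M-values (TMM) normalization factors
#'
#' Canonical TMM sample scaling factors: the reference sample is the column
#' whose upper-quartile/library-size ratio is closest to the mean such ratio;
#' per sample, log-ratios `M = log2((x_i/L_i)/(x_r/L_r))` and average
#' log-abundances `A` are computed over proteins positive in both, doubly
#' trimmed (`trim_M` on M, `trim_A` on A), and combined by a precision-
#' weighted mean with weights from the binomial variance approximation.
#' Factors are rescaled to geometric mean 1. `rel_scale` is the combined
#' per-sample scaling `L_i * t_i` rescaled to geometric mean 1 — the quantity
#' by which samples are effectively divided after TMM plus library scaling.
#'
#' @param table a `quant_table` or numeric matrix (proteins x samples)
#' @param trim_M fraction of M-values trimmed from each tail (default 0.30)
#' @param trim_A fraction of A-values trimmed from each tail (default 0.05)
#' @return data.frame with columns `sample_id`, `lib_size`, `tmm`,
#'   `effective` (= lib_size * tmm) and `rel_scale`
#' @export
tmm_factors <- function(table, trim_M = 0.30, trim_A = 0.05) {
  x <- if (inherits(table, "quant_table")) table$intensity else table
  if (ncol(x) < 2) stop("TMM requires at least 2 samples")
  if (any(x < 0, na.rm = TRUE)) stop("intensities must be non-negative")
  L <- colSums(x, na.rm = TRUE)
  if (any(L <= 0)) stop("zero library size")
  q <- apply(x, 2, stats::quantile, probs = 0.75, na.rm = TRUE) / L
  ref <- which.min(abs(q - mean(q)))

  one_factor <- function(i) {
    obs <- x[, i]; rf <- x[, ref]
    ok <- !is.na(obs) & !is.na(rf) & obs > 0 & rf > 0
    if (!any(ok)) {
      warning("no common positive proteins for sample ", colnames(x)[i],
              "; factor set to 1")
      return(1)
    }
    obs <- obs[ok]; rf <- rf[ok]
    M <- log2((obs / L[i]) / (rf / L[ref]))
    A <- 0.5 * log2((obs / L[i]) * (rf / L[ref]))
    v <- (L[i] - obs) / (L[i] * obs) + (L[ref] - rf) / (L[ref] * rf)
    if (max(abs(M)) < 1e-6) return(1)
    n <- length(M)
    loM <- floor(n * trim_M) + 1; hiM <- n + 1 - loM
    loA <- floor(n * trim_A) + 1; hiA <- n + 1 - loA
    keep <- rank(M) >= loM & rank(M) <= hiM & rank(A) >= loA & rank(A) <= hiA
    f <- sum(M[keep] / v[keep], na.rm = TRUE) / sum(1 / v[keep], na.rm = TRUE)
    if (!is.finite(f)) f <- 0
    2^f
  }
  t_i <- vapply(seq_len(ncol(x)), one_factor, numeric(1))
  t_i <- t_i / exp(mean(log(t_i)))
  eff <- L * t_i
  data.frame(sample_id = colnames(x), lib_size = unname(L), tmm = unname(t_i),
             effective = unname(eff),
             rel_scale = unname(eff / exp(mean(log(eff)))),
             stringsAsFactors = FALSE)
}

#' Log2 scaled-per-million transformation
#'
#' `value = log2(x * 1e6 / (L_i * t_i) + offset)`, i.e. log2 intensity per
#' million effective library units with an additive per-million offset so
#' zeros map to `log2(offset)` and the transform is finite everywhere.
#'
#' @param table a `quant_table` or matrix
#' @param factors output of [tmm_factors()] covering all samples
#' @param offset per-million offset (default 2), stabilizes variance at low
#'   intensity
#' @return numeric matrix (the log-scale expression matrix used by all
#'   downstream modelling)
#' @export
log_normalize <- function(table, factors, offset = 2) {
  x <- if (inherits(table, "quant_table")) table$intensity else table
  i <- match(colnames(x), factors$sample_id)
  if (anyNA(i)) stop("factors missing for sample(s): ",
                     paste(colnames(x)[is.na(i)], collapse = ", "))
  eff <- factors$effective[i]
  if (any(!is.finite(eff) | eff <= 0)) stop("zero effective library size")
  log2(sweep(x, 2, eff / 1e6, "/") + offset)
}

#' Median coefficient of variation per group
#'
#' The CV of each protein is its sample standard deviation divided by its
#' mean, computed on IRS-scaled raw-scale intensities within each
#' (species, window) group over biological channels; the group summary is the
#' median CV across proteins with at least two observed values, reported in
#' percent.
#'
#' @param table a `quant_table` of IRS-scaled intensities
#' @param meta sample metadata
#' @param grouping metadata columns defining groups (default species and
#'   window)
#' @return list with `group_cv` (data.frame group, median_cv_pct, n_samples,
#'   n_proteins) and `sample_stats` (per-sample total intensity and missing
#'   count)
#' @export
median_cv <- function(table, meta, grouping = c("species", "window")) {
  x <- if (inherits(table, "quant_table")) table$intensity else table
  meta <- meta[match(colnames(x), meta$sample_id), ]
  bio <- !meta$is_reference_pool
  key <- interaction(meta[bio, grouping, drop = FALSE], drop = TRUE, sep = ".")
  groups <- split(meta$sample_id[bio], key)

  rows <- lapply(names(groups), function(g) {
    cols <- groups[[g]]
    if (length(cols) < 2) {
      warning("group '", g, "' has a single sample; excluded from CV summary")
      return(NULL)
    }
    sub <- x[, cols, drop = FALSE]
    nobs <- rowSums(!is.na(sub))
    mu <- rowMeans(sub, na.rm = TRUE)
    s <- apply(sub, 1, stats::sd, na.rm = TRUE)
    cv <- (s / mu)[nobs >= 2]
    data.frame(group = g, median_cv_pct = 100 * stats::median(cv, na.rm = TRUE),
               n_samples = length(cols), n_proteins = sum(nobs >= 2),
               stringsAsFactors = FALSE)
  })
  sample_stats <- data.frame(
    sample_id = colnames(x),
    total_intensity = colSums(x, na.rm = TRUE),
    n_missing = as.integer(colSums(is.na(x))),
    stringsAsFactors = FALSE)
  list(group_cv = do.call(rbind, rows), sample_stats = sample_stats)
}
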