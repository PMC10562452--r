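# Compound-symmetry whitening: for a subject block of size m with intra-
# subject correlation rho, Sigma = (1-rho) I + rho J has inverse square root
# a*I + b*J with a = 1/sqrt(1-rho), b = (1/sqrt(1+(m-1)rho) - a)/m.
cs_whiten <- function(M, subject, rho) {
  if (is.null(rho) || rho == 0) return(M)
  for (s in unique(subject)) {
    idx <- which(subject == s)
    m <- length(idx)
    if (m == 1) {
      next
    }
    a <- 1 / sqrt(1 - rho)
    b <- (1 / sqrt(1 + (m - 1) * rho) - a) / m
    blk <- M[idx, , drop = FALSE]
    M[idx, ] <- a * blk + b * matrix(colSums(blk), m, ncol(M), byrow = TRUE)
  }
  M
}

#' Fit per-protein linear models of log2 abundance on gestational age
#'
#' Design: intercept + gestational age in days. With `rho = NULL` ordinary
#' least squares is used; with a consensus intra-subject correlation `rho`,
#' generalized least squares under block compound symmetry within subject
#' (each subject's samples share correlation `rho`), implemented by whitening
#' both response and design with the block inverse square root and fitting
#' OLS on the transformed data. The coefficient is the per-day log2 slope.
#'
#' @param logmat proteins x samples log2 expression matrix
#' @param meta sample metadata (biological channels of the matrix)
#' @param rho consensus intra-subject correlation in (-1, 1), or `NULL` for
#'   OLS
#' @return data.frame with per-protein `beta` (log2/day), `se`, `sigma2`
#'   (residual variance), `df` (residual degrees of freedom), `stdev_unscaled`
#'   (the design-dependent SE multiplier), `ave_expr` and `n_obs`. Proteins
#'   with fewer than 3 observed values carry `NA` statistics and are flagged
#'   in `fit_ok`.
#' @export
fit_gestational_model <- function(logmat, meta, rho = NULL) {
  meta <- meta[match(colnames(logmat), meta$sample_id), ]
  if (anyNA(meta$sample_id)) stop("metadata missing for some samples")
  if (any(meta$is_reference_pool))
    stop("reference-pool channels must be excluded before model fitting")
  age <- meta$gestational_age_days
  if (ncol(logmat) < 3) stop("at least 3 samples are required")
  if (length(unique(age)) < 2) stop("ages must not all be equal")
  if (!is.null(rho) && abs(rho) >= 1) stop("|rho| must be < 1")

  X <- cbind(intercept = 1, age = age)
  subject <- meta$subject_id
  ave_expr <- rowMeans(logmat, na.rm = TRUE)

  fit_rows <- function(Y, X, subject) {
    # Y: proteins x n complete block sharing design X
    Xw <- cs_whiten(X, subject, rho)
    Yw <- t(cs_whiten(t(Y), subject, rho))
    XtX <- crossprod(Xw)
    if (abs(det(XtX)) < 1e-10 * nrow(Xw)^2)
      stop("rank-deficient design (ages collinear with intercept)")
    XtXinv <- solve(XtX)
    B <- Yw %*% Xw %*% XtXinv            # proteins x 2 coefficients
    res <- Yw - B %*% t(Xw)
    df <- ncol(Y) - 2
    sigma2 <- rowSums(res^2) / df
    list(beta = B[, 2], sigma2 = sigma2, df = rep(df, nrow(Y)),
         unscaled = sqrt(XtXinv[2, 2]))
  }

  n_obs <- rowSums(!is.na(logmat))
  out <- data.frame(protein_id = rownames(logmat), beta = NA_real_,
                    se = NA_real_, sigma2 = NA_real_, df = NA_real_,
                    stdev_unscaled = NA_real_, ave_expr = ave_expr,
                    n_obs = n_obs, fit_ok = FALSE, stringsAsFactors = FALSE)

  complete <- which(n_obs == ncol(logmat))
  if (length(complete)) {
    f <- fit_rows(logmat[complete, , drop = FALSE], X, subject)
    out$beta[complete] <- f$beta
    out$sigma2[complete] <- f$sigma2
    out$df[complete] <- f$df
    out$stdev_unscaled[complete] <- f$unscaled
    out$fit_ok[complete] <- TRUE
  }
  partial <- which(n_obs < ncol(logmat) & n_obs >= 3)
  for (i in partial) {
    ok <- !is.na(logmat[i, ])
    if (length(unique(age[ok])) < 2) next
    f <- tryCatch(fit_rows(logmat[i, ok, drop = FALSE],
                           X[ok, , drop = FALSE], subject[ok]),
                  error = function(e) NULL)
    if (is.null(f)) next
    out$beta[i] <- f$beta; out$sigma2[i] <- f$sigma2; out$df[i] <- f$df
    out$stdev_unscaled[i] <- f$unscaled; out$fit_ok[i] <- TRUE
  }
  out$se <- sqrt(out$sigma2) * out$stdev_unscaled
  out
}

#' Estimate the consensus intra-subject correlation
#'
#' For each protein, residuals from the ordinary least-squares age fit give a
#' moment estimate of the intra-subject correlation: the mean cross-product
#' over within-subject sample pairs divided by the mean squared residual.
#' The consensus value is the hyperbolic tangent of the 30%-trimmed mean of
#' `atanh(rho_g)`, clipped to (-0.99, 0.99) — a single correlation shared by
#' all proteins, as used by consensus-correlation blocking.
#'
#' @inheritParams fit_gestational_model
#' @return the consensus correlation (scalar)
#' @export
estimate_consensus_correlation <- function(logmat, meta) {
  meta <- meta[match(colnames(logmat), meta$sample_id), ]
  subject <- meta$subject_id
  tab <- table(subject)
  rep_sub <- names(tab)[tab >= 2]
  if (length(rep_sub) < 2)
    stop("no repeated subjects: fit without blocking (rho = NULL)")
  fit <- fit_gestational_model(logmat, meta, rho = NULL)
  ok <- which(fit$fit_ok & rowSums(!is.na(logmat)) == ncol(logmat))
  X <- cbind(1, meta$gestational_age_days)
  H <- X %*% solve(crossprod(X)) %*% t(X)
  R <- logmat[ok, , drop = FALSE] %*% (diag(ncol(logmat)) - H)

  pair_idx <- do.call(rbind, lapply(rep_sub, function(s) {
    idx <- which(subject == s)
    t(utils::combn(idx, 2))
  }))
  cross <- R[, pair_idx[, 1], drop = FALSE] * R[, pair_idx[, 2], drop = FALSE]
  num <- rowMeans(cross)
  den <- rowMeans(R^2)
  rho_g <- pmin(pmax(num / den, -0.99), 0.99)
  rho_g <- rho_g[is.finite(rho_g)]
  tanh(mean(atanh(rho_g), trim = 0.3))
}

# Inverse of the trigamma function by Newton iteration (monotone decreasing).
trigamma_inverse <- function(x, tol = 1e-8, maxit = 50) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in seq_len(maxit)) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2)
    y <- y + dif
    if (abs(dif / y) < tol) break
  }
  y
}

#' Empirical-Bayes moderation of residual variances
#'
#' Fits the scaled-F variance prior `s^2_g ~ s0^2 F(df_g, d0)` by matching
#' the mean and variance of `log s^2` through the digamma/trigamma moment
#' equations (Newton inversion of the trigamma function, tolerance 1e-8),
#' then shrinks each variance to its posterior
#' `s~^2_g = (d0 s0^2 + df_g s^2_g) / (d0 + df_g)`. If the observed
#' log-variance dispersion is no larger than expected from chi-square
#' sampling alone, `d0 = Inf` and all posterior variances equal `s0^2`.
#'
#' @param s_sq per-protein residual variances (non-negative)
#' @param df per-protein residual degrees of freedom (>= 1)
#' @return list with `d0`, `s0_sq`, `s2_post` (posterior variances) and
#'   `df_total` (= df + d0, capped at 1e6 when d0 is infinite)
#' @export
moderate_variances <- function(s_sq, df) {
  ok <- is.finite(s_sq) & is.finite(df) & df >= 1
  if (!any(ok)) stop("no usable variances")
  if (any(s_sq[ok] < 0)) stop("variances must be non-negative")
  s <- pmax(s_sq[ok], 1e-300)
  d <- df[ok]
  z <- log(s)
  e <- z - digamma(d / 2) + log(d / 2)
  ebar <- mean(e)
  ev <- mean((e - ebar)^2) * length(e) / (length(e) - 1) -
    mean(trigamma(d / 2))
  if (is.na(ev) || ev <= 0) {
    # no excess dispersion beyond chi-square sampling: complete pooling
    d0 <- Inf
    s0 <- mean(s)
  } else {
    d0 <- 2 * trigamma_inverse(ev)
    s0 <- exp(ebar + digamma(d0 / 2) - log(d0 / 2))
  }
  post <- rep(NA_real_, length(s_sq))
  if (is.infinite(d0)) {
    post[ok] <- s0
  } else {
    post[ok] <- (d0 * s0 + df[ok] * s_sq[ok]) / (d0 + df[ok])
  }
  dft <- rep(NA_real_, length(s_sq))
  dft[ok] <- pmin(df[ok] + d0, 1e6)
  list(d0 = d0, s0_sq = s0, s2_post = post, df_total = dft)
}

#' Benjamini-Hochberg step-up adjusted p-values
#'
#' Sort ascending, form `p_(j) * m / j`, take the suffix minimum from the
#' largest rank down, cap at 1 and restore the input order. NAs are excluded
#' from the adjustment (m counts non-missing values) and propagated.
#'
#' @param p vector of p-values in \[0, 1\]
#' @return adjusted p-values in the input order
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  out <- rep(NA_real_, length(p))
  ok <- which(!is.na(p))
  m <- length(ok)
  if (!m) return(out)
  ord <- ok[order(p[ok])]
  v <- p[ord] * m / seq_len(m)
  out[ord] <- pmin(1, rev(cummin(rev(v))))
  out
}

#' Per-protein differential abundance with gestational age
#'
#' Composes model fitting, optional consensus-correlation blocking,
#' empirical-Bayes variance moderation and BH FDR control. The reported
#' `logFC` is the model coefficient for age: the log2 abundance change per
#' day of gestation. `AveExpr` is the mean log2 intensity across samples.
#'
#' @inheritParams fit_gestational_model
#' @param alpha FDR threshold for calling direction (default 0.05)
#' @param block use within-subject blocking (consensus-correlation GLS);
#'   requires repeated subjects
#' @param rho optional known consensus correlation; estimated when `block`
#'   and `NULL`
#' @param gene_symbols optional gene symbols named by protein id
#' @return data.frame sorted by p-value with columns `protein_id`,
#'   `gene_symbol`, `logFC`, `AveExpr`, `t_mod`, `p_value`, `adj_p`,
#'   `df_residual`, `df_total`, `direction`; attribute `moderation` carries
#'   (d0, s0_sq, rho)
#' @export
run_differential <- function(logmat, meta, alpha = 0.05, block = FALSE,
                             rho = NULL, gene_symbols = NULL) {
  if (block && is.null(rho))
    rho <- estimate_consensus_correlation(logmat, meta)
  if (!block) rho <- NULL
  fit <- fit_gestational_model(logmat, meta, rho = rho)
  mod <- moderate_variances(fit$sigma2, fit$df)
  t_mod <- fit$beta / (sqrt(mod$s2_post) * fit$stdev_unscaled)
  p <- 2 * stats::pt(-abs(t_mod), df = mod$df_total)
  adj <- bh_adjust(p)
  direction <- ifelse(is.na(adj) | adj >= alpha, "ns",
                      ifelse(fit$beta > 0, "up", "down"))
  gs <- if (is.null(gene_symbols)) fit$protein_id else
    unname(gene_symbols[fit$protein_id])
  out <- data.frame(protein_id = fit$protein_id, gene_symbol = gs,
                    logFC = fit$beta, AveExpr = fit$ave_expr, t_mod = t_mod,
                    p_value = p, adj_p = adj, df_residual = fit$df,
                    df_total = mod$df_total, direction = direction,
                    stringsAsFactors = FALSE)
  out <- out[order(out$p_value), ]
  rownames(out) <- NULL
  attr(out, "moderation") <- list(d0 = mod$d0, s0_sq = mod$s0_sq,
                                  rho = if (is.null(rho)) NA_real_ else rho)
  out
}
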