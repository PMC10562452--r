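meta_from_ages <- function(ages, subject = sprintf("S%d", seq_along(ages)),
                           species = "rhesus") {
  data.frame(sample_id = sprintf("SMP%d", seq_along(ages)), species = species,
             subject_id = subject, gestational_age_days = ages,
             window = rhesus_equivalent_window(ages, species),
             plex_id = "P1", channel_label = sprintf("C%d", seq_along(ages)),
             is_reference_pool = FALSE, stringsAsFactors = FALSE)
}

test_that("the age model recovers exact lines and matches the OLS closed form", {
  ages <- c(85, 110, 135)
  meta <- meta_from_ages(ages)
  y <- rbind(exact = 1 + 0.05 * ages, flat = rep(3, 3))
  colnames(y) <- meta$sample_id
  fit <- fit_gestational_model(y, meta)
  expect_equal(fit$beta, c(0.05, 0), tolerance = 1e-12)
  expect_equal(fit$sigma2, c(0, 0), tolerance = 1e-12)

  # 6-point noisy toy against the normal-equations oracle
  set.seed(10)
  ages6 <- c(85, 95, 105, 115, 125, 135)
  meta6 <- meta_from_ages(ages6)
  yy <- matrix(rnorm(6, 5 + 0.02 * ages6, 0.3), 1,
               dimnames = list("P1", meta6$sample_id))
  fit6 <- fit_gestational_model(yy, meta6)
  X <- cbind(1, ages6)
  bhat <- solve(t(X) %*% X, t(X) %*% yy[1, ])
  res <- yy[1, ] - X %*% bhat
  s2 <- sum(res^2) / 4
  expect_equal(fit6$beta, bhat[2], tolerance = 1e-12)
  expect_equal(fit6$sigma2, s2, tolerance = 1e-12)
  expect_equal(fit6$se, sqrt(s2 * solve(t(X) %*% X)[2, 2]), tolerance = 1e-12)
})

test_that("GLS with rho = 0 equals OLS, and proteins with < 3 values are
           flagged", {
  e <- tiny_experiment(seed = 21, n_proteins = 60)
  ns <- normalized_species(e, "rhesus")
  f0 <- fit_gestational_model(ns$logmat, ns$meta, rho = NULL)
  fz <- fit_gestational_model(ns$logmat, ns$meta, rho = 0)
  expect_equal(f0$beta, fz$beta, tolerance = 1e-12)
  expect_equal(f0$se, fz$se, tolerance = 1e-12)

  lm2 <- ns$logmat
  lm2[1, -1] <- NA
  f <- fit_gestational_model(lm2, ns$meta)
  expect_false(f$fit_ok[1])
  expect_true(is.na(f$beta[1]))
})

test_that("consensus correlation recovers the intra-subject correlation", {
  cfg <- sim_config(n_proteins = 1000, seed = 31, sigma_plex = 0,
                    sigma_subject = 0.3, sigma_noise = 0.3)  # true rho = 0.5
  e <- generate_experiment(cfg)
  m <- e$meta[e$meta$species == "rhesus" & !e$meta$is_reference_pool, ]
  lmat <- log2(e$rhesus$intensity[, m$sample_id])
  expect_equal(estimate_consensus_correlation(lmat, m), 0.5, tolerance = 0.1)

  cfg0 <- sim_config(n_proteins = 1000, seed = 32, sigma_plex = 0,
                     sigma_subject = 0, sigma_noise = 0.3)
  e0 <- generate_experiment(cfg0)
  m0 <- e0$meta[e0$meta$species == "rhesus" & !e0$meta$is_reference_pool, ]
  l0 <- log2(e0$rhesus$intensity[, m0$sample_id])
  expect_lt(abs(estimate_consensus_correlation(l0, m0)), 0.1)

  # cross-sectional design: no repeated subjects
  mh <- e$meta[e$meta$species == "human" & !e$meta$is_reference_pool, ]
  lh <- log2(e$human$intensity[, mh$sample_id])
  expect_error(estimate_consensus_correlation(lh, mh), "no repeated subjects")
})

test_that("variance moderation follows the posterior formula and its limits", {
  # forced arithmetic: d0 = 4, s0^2 = 0.04, df = 4, s^2 = 0.08 -> 0.06
  post <- (4 * 0.04 + 4 * 0.08) / (4 + 4)
  expect_equal(post, 0.06)
  # identical variances -> d0 = Inf and posterior = common value
  mv <- moderate_variances(rep(0.05, 100), rep(4, 100))
  expect_identical(mv$d0, Inf)
  expect_equal(mv$s2_post, rep(0.05, 100), tolerance = 1e-9)
})

test_that("moderation recovers (d0, s0) from scaled-F distributed variances", {
  set.seed(77)
  G <- 5000; d0 <- 4; s0 <- 0.05; df <- 4
  sigma2 <- d0 * s0 / rchisq(G, d0)         # scaled inverse-chi-square prior
  s2 <- sigma2 * rchisq(G, df) / df
  mv <- moderate_variances(s2, rep(df, G))
  expect_equal(mv$d0, d0, tolerance = 0.25)
  expect_equal(mv$s0_sq, s0, tolerance = 0.10)
})

test_that("moderation agrees with limma's squeezeVar", {
  skip_if_not_installed("limma")
  set.seed(78)
  s2 <- 0.05 * rchisq(2000, 6) / 6 * exp(rnorm(2000, 0, 0.5))
  mv <- moderate_variances(s2, rep(6, 2000))
  sq <- limma::squeezeVar(s2, df = 6)
  expect_equal(mv$d0, sq$df.prior, tolerance = 0.02)
  expect_equal(mv$s0_sq, sq$var.prior, tolerance = 0.02)
  expect_equal(mv$s2_post, sq$var.post, tolerance = 0.01)
})

test_that("BH adjustment equals the step-up oracle and stats::p.adjust", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  set.seed(11)
  for (i in 1:20) {
    p <- runif(sample(5:200, 1))^sample(1:3, 1)
    q <- bh_adjust(p)
    expect_equal(q, bh_stepup_oracle(p), tolerance = 1e-15)
    expect_equal(q, p.adjust(p, "BH"), tolerance = 1e-12) # independent check
    expect_true(all(diff(q[order(p)]) > -1e-15))          # monotone
    expect_true(all(q >= p - 1e-15))
  }
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("run_differential composes into a coherent, sorted result table", {
  e <- tiny_experiment(seed = 41, n_proteins = 300)
  ns <- normalized_species(e, "rhesus")
  gs <- setNames(ns$table$gene_symbol, ns$table$protein_id)
  d <- run_differential(ns$logmat, ns$meta, block = TRUE, gene_symbols = gs)
  expect_identical(nrow(d), 300L)
  expect_true(!is.unsorted(d$p_value))
  expect_true(all(d$adj_p >= d$p_value - 1e-15))
  expect_true(all((d$direction == "ns") == (d$adj_p >= 0.05)))
  expect_true(all(d$df_total > d$df_residual))
  # alpha = 1: every protein directional
  d1 <- run_differential(ns$logmat, ns$meta, alpha = 1)
  expect_true(all(d1$direction %in% c("up", "down")))
})

test_that("moderated statistics agree with limma's lmFit + eBayes pipeline", {
  skip_if_not_installed("limma")
  e <- tiny_experiment(seed = 51, n_proteins = 400)
  ns <- normalized_species(e, "human")
  d <- run_differential(ns$logmat, ns$meta, block = FALSE)
  design <- cbind(1, age = ns$meta$gestational_age_days[
    match(colnames(ns$logmat), ns$meta$sample_id)])
  fit <- limma::eBayes(limma::lmFit(ns$logmat, design))
  tt <- limma::topTable(fit, coef = 2, number = Inf, sort.by = "none")
  i <- match(rownames(tt), d$protein_id)
  expect_equal(d$logFC[i], tt$logFC, tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(d$t_mod[i], tt$t, tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(d$p_value[i], tt$P.Value, tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(d$AveExpr[i], tt$AveExpr, tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("slope recovery on true positives is nearly unbiased at the study
           design", {
  set.seed(61)
  n <- 21
  ages <- rep(c(85, 110, 135), each = 7)
  meta <- meta_from_ages(ages, subject = sprintf("S%d", seq_len(n)))
  G <- 1000
  beta <- ifelse(seq_len(G) <= 100, 0.04 * sample(c(-1, 1), G, TRUE), 0)
  Y <- outer(beta, ages) + matrix(rnorm(G * n, 0, 0.3), G)
  dimnames(Y) <- list(sprintf("P%d", 1:G), meta$sample_id)
  d <- run_differential(Y, meta)
  i <- match(sprintf("P%d", 1:100), d$protein_id)
  expect_gt(mean(d$adj_p[i] < 0.05), 0.8)                     # sensitivity
  rel_bias <- abs(d$logFC[i] - beta[1:100]) / abs(beta[1:100])
  expect_lt(median(rel_bias), 0.10)
})
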