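test_that("IRS factors follow the geometric-mean definition on a worked case", {
  # protein with reference geomeans 100 (plex A) and 400 (plex B):
  # global mean 200, factors 2.0 and 0.5
  m <- matrix(c(100, 100, 50, 400, 400, 80), nrow = 1,
              dimnames = list("P1", c("A_REF1", "A_REF2", "A_S1",
                                      "B_REF1", "B_REF2", "B_S1")))
  meta <- data.frame(
    sample_id = colnames(m), species = "rhesus",
    subject_id = c("pool", "pool", "X", "pool", "pool", "Y"),
    gestational_age_days = c(NA, NA, 85, NA, NA, 110),
    window = c(NA, NA, "G85eq", NA, NA, "G110eq"),
    plex_id = rep(c("A", "B"), each = 3),
    channel_label = sprintf("C%d", 1:6),
    is_reference_pool = rep(c(TRUE, TRUE, FALSE), 2),
    stringsAsFactors = FALSE)
  res <- irs_scale(quant_table(m), meta)
  expect_equal(unname(res$factors$G["P1"]), 200)
  expect_equal(unname(res$factors$f["P1", ]), c(2.0, 0.5))
  expect_equal(unname(res$table$intensity["P1", "A_S1"]), 100)
  expect_equal(unname(res$table$intensity["P1", "B_S1"]), 40)
})

test_that("IRS is the identity for single-plex data and exact across plexes", {
  e <- tiny_experiment(seed = 8)
  meta <- e$meta[e$meta$species == "rhesus", ]
  one <- meta[meta$plex_id == meta$plex_id[1], ]
  tbl <- subset_quant(e$rhesus, samples = one$sample_id)
  expect_equal(irs_scale(tbl, one)$table$intensity, tbl$intensity)

  res <- irs_scale(e$rhesus, meta)
  Rpost <- sapply(unique(meta$plex_id), function(p) {
    cols <- meta$sample_id[meta$plex_id == p & meta$is_reference_pool]
    apply(res$table$intensity[, cols, drop = FALSE], 1,
          function(z) exp(mean(log(z))))
  })
  rel <- apply(Rpost, 1, function(z) diff(range(z)) / mean(z))
  expect_lt(max(rel), 1e-9)
})

test_that("IRS shrinks cross-plex reference disagreement by >= 10x", {
  e <- tiny_experiment(seed = 12, sigma_plex = 0.5)
  meta <- e$meta[e$meta$species == "rhesus", ]
  ref_spread <- function(x) {
    R <- sapply(unique(meta$plex_id), function(p) {
      cols <- meta$sample_id[meta$plex_id == p & meta$is_reference_pool]
      apply(x[, cols, drop = FALSE], 1, function(z) exp(mean(log(z))))
    })
    L <- log2(R)
    mean(abs(L - rowMeans(L)))
  }
  before <- ref_spread(e$rhesus$intensity)
  after <- ref_spread(irs_scale(e$rhesus, meta)$table$intensity)
  expect_gt(before / after, 10)
})

test_that("TMM factors are 1 for identical columns and scale-invariant", {
  set.seed(1)
  x <- matrix(rexp(300, 1 / 50), 100, 3,
              dimnames = list(sprintf("P%d", 1:100), sprintf("S%d", 1:3)))
  x[, 2] <- x[, 1]; x[, 3] <- x[, 1]
  f <- tmm_factors(x)
  expect_equal(f$tmm, rep(1, 3), tolerance = 1e-12)
  expect_equal(f$rel_scale, rep(1, 3), tolerance = 1e-12)

  set.seed(2)
  y <- matrix(rexp(400, 1 / 50), 100, 4,
              dimnames = list(sprintf("P%d", 1:100), sprintf("S%d", 1:4)))
  f1 <- tmm_factors(y)
  f2 <- tmm_factors(y * 7)
  expect_equal(f1$tmm, f2$tmm, tolerance = 1e-12)
  expect_equal(f1$rel_scale, f2$rel_scale, tolerance = 1e-12)
})

test_that("a globally doubled column moves the combined sample scaling, not
           the TMM factor", {
  set.seed(3)
  x <- matrix(rexp(200, 1 / 50), 100, 2,
              dimnames = list(sprintf("P%d", 1:100), c("a", "b")))
  x[, 2] <- 2 * x[, 1]
  f <- tmm_factors(x)
  expect_equal(f$tmm, c(1, 1), tolerance = 1e-6)
  expect_equal(f$rel_scale, c(2^(-0.5), 2^(0.5)), tolerance = 0.01)
})

test_that("TMM matches edgeR's implementation on positive data", {
  skip_if_not_installed("edgeR")
  set.seed(4)
  x <- matrix(rpois(600, 200) * exp(rnorm(600, 0, 0.3)), 100, 6,
              dimnames = list(sprintf("P%d", 1:100), sprintf("S%d", 1:6)))
  x <- sweep(x, 2, c(1, 2, 0.5, 1.5, 1, 0.8), "*")
  mine <- tmm_factors(x)$tmm
  theirs <- unname(edgeR::calcNormFactors(x, method = "TMM"))
  expect_equal(mine, theirs, tolerance = 1e-6)
})

test_that("TMM recovers pure scalar column differences up to the geomean
           constraint", {
  set.seed(5)
  base <- rexp(200, 1 / 100)
  scal <- c(1, 2, 4, 0.5)
  x <- outer(base, scal)
  dimnames(x) <- list(sprintf("P%d", 1:200), sprintf("S%d", 1:4))
  f <- tmm_factors(x)
  expect_equal(f$rel_scale, scal / exp(mean(log(scal))), tolerance = 0.01)
})

test_that("log normalization matches its closed form and is monotone", {
  x <- matrix(c(0, 10, 250, 1000), 2, 2, byrow = TRUE,
              dimnames = list(c("P1", "P2"), c("S1", "S2")))
  f <- data.frame(sample_id = c("S1", "S2"), lib_size = c(1e6, 2e6),
                  tmm = c(1, 1), effective = c(1e6, 2e6),
                  rel_scale = c(1 / sqrt(2), sqrt(2)))
  lm2 <- log_normalize(x, f, offset = 2)
  expect_equal(lm2["P1", "S1"], log2(2))            # x = 0, L*t = 1e6
  expect_equal(lm2["P2", "S1"], log2(250 + 2))
  expect_equal(lm2["P1", "S2"], log2(10 * 1e6 / 2e6 + 2))
  # doubling x and effective size leaves the value unchanged
  f2 <- f; f2$effective <- f$effective * 2
  expect_equal(log_normalize(x * 2, f2), lm2)
  # monotone in x for a fixed sample
  xs <- matrix(seq(0, 100, by = 10), ncol = 1,
               dimnames = list(NULL, "S1"))
  expect_true(all(diff(log_normalize(xs, f)[, 1]) > 0))
})

test_that("median CV follows the SD/mean definition per group", {
  m <- matrix(c(90, 110, 100, 100,   # CV 14.14%, then 0%
                50, 50, 40, 60), 2, 4, byrow = TRUE,
              dimnames = list(c("P1", "P2"), sprintf("S%d", 1:4)))
  meta <- data.frame(
    sample_id = c(sprintf("S%d", 1:4), "POOLX"),
    species = "human",
    subject_id = c(sprintf("H%d", 1:4), "pool"),
    gestational_age_days = c(140, 140, 178.5, 178.5, NA),
    window = c("G85eq", "G85eq", "G110eq", "G110eq", NA),
    plex_id = "H1", channel_label = sprintf("C%d", 1:5),
    is_reference_pool = c(rep(FALSE, 4), TRUE), stringsAsFactors = FALSE)
  qc <- median_cv(m, meta)
  g85 <- qc$group_cv[qc$group_cv$group == "human.G85eq", ]
  # P1: sd(90,110)/100 = 14.142%; P2: sd(50,50)/50 = 0% -> median 7.07%
  expect_equal(g85$median_cv_pct, 100 * mean(c(sd(c(90, 110)) / 100, 0)))
  g110 <- qc$group_cv[qc$group_cv$group == "human.G110eq", ]
  expect_equal(g110$median_cv_pct,
               100 * mean(c(0, sd(c(40, 60)) / 50)))
  expect_identical(qc$sample_stats$n_missing, rep(0L, 4))
})
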