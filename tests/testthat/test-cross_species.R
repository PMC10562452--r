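test_that("ortholog join keeps only 1:1 pairs and reports cardinality", {
  rdiff <- data.frame(protein_id = c("r1", "r2", "r3"), logFC = 1:3 / 10,
                      stringsAsFactors = FALSE)
  hdiff <- data.frame(protein_id = c("h1", "h2"), gene_symbol = c("A", "B"),
                      logFC = c(0.5, -0.5), stringsAsFactors = FALSE)
  map <- data.frame(rhesus_id = c("r1", "r2", "r3"),
                    human_gene_symbol = c("A", "B", "B"),
                    is_unique = c(TRUE, FALSE, FALSE), stringsAsFactors = FALSE)
  j <- map_orthologs(rdiff, hdiff, map)
  expect_identical(nrow(j), 1L)
  expect_identical(j$ortholog, "A")
  expect_identical(unname(attr(j, "cardinality")["joined"]), 1L)
  bad <- data.frame(rhesus_id = "rX", human_gene_symbol = "ZZZ",
                    is_unique = TRUE, stringsAsFactors = FALSE)
  expect_error(map_orthologs(rdiff, hdiff, bad), "no orthologs")
})

test_that("joined size on synthetic maps equals the generator truth", {
  e <- tiny_experiment(seed = 13, n_proteins = 400)
  rdiff <- data.frame(protein_id = e$rhesus$protein_id,
                      gene_symbol = e$rhesus$gene_symbol,
                      stringsAsFactors = FALSE)
  hdiff <- data.frame(protein_id = e$human$protein_id,
                      gene_symbol = e$human$gene_symbol,
                      stringsAsFactors = FALSE)
  j <- map_orthologs(rdiff, hdiff, e$ortholog_map)
  expect_identical(nrow(j), sum(e$ortholog_map$is_unique))
})

test_that("correlations match closed forms, with Fisher-z intervals", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(abundance_correlation(x, x)$r, 1)
  expect_equal(abundance_correlation(x, -x)$r, -1)
  set.seed(14)
  a <- rnorm(5); b <- rnorm(5)
  r_hand <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  res <- abundance_correlation(a, b)
  expect_equal(res$r, r_hand, tolerance = 1e-12)
  expect_equal(res$ci, tanh(atanh(r_hand) + c(-1, 1) * qnorm(0.975) / sqrt(2)),
               tolerance = 1e-12)
  expect_error(abundance_correlation(a, rep(1, 5)), "zero variance")
  expect_error(abundance_correlation(a[1:2], b[1:2]), "at least 3")
  eff <- effect_correlation(a, b)
  expect_equal(eff$slope, unname(coef(lm(b ~ a))[2]), tolerance = 1e-12)
})

test_that("concordance categories partition joined orthologs", {
  joined <- data.frame(
    ortholog = sprintf("G%d", 1:5),
    logFC_rhesus = c(0.1, 0.1, 0.1, 0.1, NA),
    adj_p_rhesus = c(0.01, 0.01, 0.01, 0.50, 0.01),
    logFC_human = c(0.2, -0.2, 0.2, 0.2, 0.2),
    adj_p_human = c(0.01, 0.01, 0.50, 0.50, 0.01),
    stringsAsFactors = FALSE)
  res <- concordance_classify(joined)
  expect_identical(res$records$category,
                   c("both_same_direction", "both_opposite",
                     "one_species_only", "neither"))
  expect_equal(sum(res$fractions), 1)
  expect_identical(res$n_excluded, 1L)
  # invariant to row order
  res2 <- concordance_classify(joined[c(3, 1, 4, 2, 5), ])
  expect_equal(res2$fractions, res$fractions)
})

test_that("hypergeometric overlap p is exact, symmetric and monotone in k", {
  # printed case: N = 10, n = K = k = 5 -> 1 / C(10, 5)
  expect_equal(overlap_enrichment(5, 5, 5, 10)$p_value, 1 / choose(10, 5),
               tolerance = 1e-12)
  expect_equal(overlap_enrichment(5, 5, 0, 10)$p_value, 1)
  expect_equal(overlap_enrichment(4, 7, 2, 20)$p_value,
               overlap_enrichment(7, 4, 2, 20)$p_value, tolerance = 1e-15)
  p_seq <- sapply(0:4, function(k) overlap_enrichment(4, 7, k, 20)$p_value)
  expect_true(all(diff(p_seq) < 0))
  expect_error(overlap_enrichment(5, 5, 6, 10), "inconsistent")
  # oracle sweep on small universes
  for (N in c(6, 9, 12)) {
    for (K in 1:(N - 1)) for (n in 1:(N - 1)) for (k in 0:min(n, K)) {
      expect_equal(overlap_enrichment(n, K, k, N)$p_value,
                   hyper_upper_oracle(k, K, N, n), tolerance = 1e-12)
    }
  }
})

test_that("concordance recovery on shared-direction synthetic truth", {
  # 60% of orthologs DE in both species, same direction, at high power; a
  # single replicate carries some seed-to-seed compositional drift, so this
  # mechanics check is looser than the multi-replicate acceptance bound
  e <- tiny_experiment(seed = 15, n_proteins = 500, frac_up = 0.3,
                       frac_down = 0.3)
  rn <- normalized_species(e, "rhesus")
  hn <- normalized_species(e, "human")
  rd <- run_differential(rn$logmat, rn$meta, block = TRUE,
                         gene_symbols = setNames(rn$table$gene_symbol,
                                                 rn$table$protein_id))
  hd <- run_differential(hn$logmat, hn$meta,
                         gene_symbols = setNames(hn$table$gene_symbol,
                                                 hn$table$protein_id))
  j <- map_orthologs(rd, hd, e$ortholog_map)
  res <- concordance_classify(j)
  expect_equal(unname(res$fractions["both_same_direction"]), 0.6,
               tolerance = 0.15)
  ov <- overlap_enrichment(
    n_A = sum(j$adj_p_human < 0.05), n_B = sum(j$adj_p_rhesus < 0.05),
    k = sum(j$adj_p_human < 0.05 & j$adj_p_rhesus < 0.05), N = nrow(j))
  # overlap enrichment weakens when most of the universe is significant in
  # both species (little headroom above the expected overlap), so this only
  # asserts clear enrichment; the sharper bound lives in the acceptance suite
  expect_lt(ov$p_value, 0.05)
})

test_that("external-list comparison counts identification, overlap and
           direction", {
  internal <- data.frame(
    protein_id = sprintf("p%d", 1:6),
    gene_symbol = c("A", "B", "C", "D", "E", "F"),
    logFC = c(0.5, -0.5, 0.3, 0.2, -0.1, 0.4),
    adj_p = c(0.01, 0.01, 0.01, 0.5, 0.5, 0.5),
    direction = c("up", "down", "up", "ns", "ns", "ns"),
    stringsAsFactors = FALSE)
  ext_same <- data.frame(gene = c("A", "B", "C"),
                         logFC = c(1, -1, 0.6), stringsAsFactors = FALSE)
  res <- compare_to_external(internal, ext_same)
  expect_identical(res$n_identified, 3L)
  expect_identical(res$n_overlapping, 3L)
  expect_identical(res$n_consistent, 3L)
  expect_equal(res$r, 1, tolerance = 1e-12)

  ext_disjoint <- data.frame(gene = c("X", "Y"), direction = "up",
                             stringsAsFactors = FALSE)
  res2 <- compare_to_external(internal, ext_disjoint)
  expect_identical(res2$n_overlapping, 0L)
  expect_equal(res2$overlap_test$p_value, 1)
})
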