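# Independent oracles used across tests.

# Benjamini-Hochberg step-up from the definition: sort ascending,
# q_i = min over j >= i of p_(j) * m / j, capped at 1, back in input order.
bh_stepup_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  q <- vapply(seq_len(m), function(i) {
    j <- i:m
    min(1, min(ps[j] * m / j))
  }, numeric(1))
  out <- numeric(m)
  out[ord] <- q
  out
}

# Upper-tail hypergeometric probability as the combinatorial sum
# sum_{i >= k} C(K, i) C(N - K, n - i) / C(N, n).
hyper_upper_oracle <- function(k, K, N, n) {
  i <- k:min(n, K)
  i <- i[(n - i) <= (N - K)]
  if (!length(i)) return(0)
  sum(exp(lchoose(K, i) + lchoose(N - K, n - i) - lchoose(N, n)))
}

# Small two-species experiment for fast integration tests.
tiny_experiment <- function(seed = 42, n_proteins = 250, ...) {
  generate_experiment(sim_config(n_proteins = n_proteins, seed = seed, ...))
}

# Normalized per-species log matrix + metadata for downstream tests.
normalized_species <- function(exp, species, trim_M = 0.3, trim_A = 0.05) {
  meta <- exp$meta[exp$meta$species == species, ]
  irs <- irs_scale(exp[[species]], meta)
  bio <- meta$sample_id[!meta$is_reference_pool]
  bt <- subset_quant(irs$table, samples = bio)
  nf <- tmm_factors(bt, trim_M, trim_A)
  list(logmat = log_normalize(bt, nf), meta = meta, table = bt,
       irs = irs, factors = nf)
}
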