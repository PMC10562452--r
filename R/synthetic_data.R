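#' Default simulation configuration
#'
#' The defaults emulate the study design the pipeline targets: 7 rhesus
#' subjects sampled longitudinally at gestational days 85/110/135, human
#' subjects sampled cross-sectionally (7/10/7 per window at the matched ages
#' 140/178.5/220.5 days), ~1300 proteins per species of which ~95% are shared
#' orthologs and ~95% of those map 1:1, three plexes per species each carrying
#' two pooled-reference channels, multiplicative plex batch effects
#' (sigma_plex, log2 SD), subject random effects (sigma_subject) and
#' log-normal measurement noise (sigma_noise). A configurable fraction of
#' proteins drift up or down with gestational age with per-day log2 slopes
#' centred on `slope_magnitude`.
#'
#' @param ... named overrides of any default field
#' @return a list of class `sim_config`
#' @export
sim_config <- function(...) {
  cfg <- list(
    n_proteins = 1300,
    frac_up = 0.2,
    frac_down = 0.2,
    slope_magnitude = 0.04,      # log2 units / day
    n_subjects_rhesus = 7,
    rhesus_ages = c(85, 110, 135),
    n_humans_per_window = c(7, 10, 7),
    human_ages = c(140, 178.5, 220.5),
    ortholog_fraction = 0.95,
    unique_fraction = 0.95,
    sigma_subject = 0.3,         # log2 SD
    sigma_plex = 0.5,            # log2 SD
    sigma_noise = 0.3,           # log2 SD
    sigma_species = 0.7,         # log2 SD of species baseline offset
    baseline_log2_mean = 20,
    baseline_log2_sd = 2,
    n_plexes = 3,
    ref_pools_per_plex = 2,
    seed = 1L
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) stop("unknown sim_config field(s): ",
                            paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  cfg$n_humans_per_window <- rep_len(cfg$n_humans_per_window,
                                     length(cfg$human_ages))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  if (cfg$frac_up + cfg$frac_down > 1)
    stop("frac_up + frac_down must be <= 1")
  sds <- c(cfg$sigma_subject, cfg$sigma_plex, cfg$sigma_noise,
           cfg$sigma_species, cfg$baseline_log2_sd)
  if (any(sds < 0)) stop("all SDs must be >= 0")
  if (cfg$n_plexes < 1) stop("n_plexes must be >= 1")
  if (cfg$ref_pools_per_plex < 1) stop("ref_pools_per_plex must be >= 1")
  if (cfg$n_proteins < 1) stop("n_proteins must be >= 1")
  if (length(cfg$rhesus_ages) < 1 || length(cfg$human_ages) < 1)
    stop("at least one sampling age per species is required")
  if (any(cfg$rhesus_ages <= 0 | cfg$rhesus_ages >= TERM_DAYS["rhesus"]))
    stop("rhesus_ages must lie in (0, 168)")
  if (any(cfg$human_ages <= 0 | cfg$human_ages >= TERM_DAYS["human"]))
    stop("human_ages must lie in (0, 280)")
  invisible(cfg)
}

# exact per-config DE flag assignment: round(frac * n) up, round(frac * n) down
assign_de_flags <- function(n, frac_up, frac_down) {
  n_up <- round(frac_up * n)
  n_down <- round(frac_down * n)
  dir <- rep("ns", n)
  idx <- sample.int(n, n_up + n_down)
  dir[idx[seq_len(n_up)]] <- "up"
  if (n_down) dir[idx[n_up + seq_len(n_down)]] <- "down"
  dir
}

draw_slopes <- function(direction, magnitude) {
  b <- abs(stats::rnorm(length(direction), magnitude, magnitude / 4))
  ifelse(direction == "up", b, ifelse(direction == "down", -b, 0))
}

#' Generate a two-species multi-plex longitudinal experiment
#'
#' Simulates log2 reporter intensities under the additive model
#' `log2(x_gi) = baseline_g + beta_g * age_i + u_g,subject(i) + b_g,plex(i) + eps`
#' with `eps ~ N(0, sigma_noise^2)`. Subject and plex effects are
#' protein-specific random effects (drawn with SDs `sigma_subject` and
#' `sigma_plex`): per-protein subject intercepts induce the within-subject
#' correlation that blocking models, and per-protein plex effects are the
#' batch structure internal reference scaling corrects. Intensities are
#' emitted on the raw scale
#' (`2^log2`). Reference-pool channels carry, per plex, the arithmetic mean on
#' the log2 scale of all biological channel means of that species (a pooled
#' aliquot common to every plex) plus the plex effect and noise. Ortholog
#' pairs share their differential-abundance flag and direction across species;
#' slope magnitudes are drawn independently per species.
#'
#' @param config a `sim_config`
#' @return list with elements `rhesus` and `human` (each a `quant_table`),
#'   `meta` (combined sample metadata), `ortholog_map`, and `truth` (a list of
#'   ground-truth tables: per-species protein truth, subject effects, plex
#'   effects, and the config used)
#' @export
generate_experiment <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_proteins
  n_shared <- round(config$ortholog_fraction * n)
  n_unique <- round(config$unique_fraction * n_shared)

  human_gene <- sprintf("GENE%04d", seq_len(n))
  shared_gene <- human_gene[seq_len(n_shared)]
  rhesus_only_gene <- sprintf("RGENE%04d", seq_len(n - n_shared))
  rhesus_gene <- c(shared_gene, rhesus_only_gene)
  human_id <- sprintf("HP%04d_HUMAN", seq_len(n))
  rhesus_id <- sprintf("RP%04d_MACMU", seq_len(n))

  # ortholog map: first n_unique shared pairs are 1:1; the remainder are made
  # ambiguous by adding a second rhesus protein mapping to the same symbol
  map <- data.frame(rhesus_id = rhesus_id[seq_len(n_shared)],
                    human_gene_symbol = shared_gene,
                    is_unique = seq_len(n_shared) <= n_unique,
                    stringsAsFactors = FALSE)
  amb <- which(!map$is_unique)
  if (length(amb)) {
    extra <- data.frame(rhesus_id = paste0(map$rhesus_id[amb], "B"),
                        human_gene_symbol = map$human_gene_symbol[amb],
                        is_unique = FALSE, stringsAsFactors = FALSE)
    map <- rbind(map, extra)
  }

  # shared latent truth on the human gene universe
  dir_univ <- assign_de_flags(n, config$frac_up, config$frac_down)
  base_univ <- stats::rnorm(n, config$baseline_log2_mean, config$baseline_log2_sd)

  dir_rhesus <- c(dir_univ[seq_len(n_shared)],
                  assign_de_flags(n - n_shared, config$frac_up, config$frac_down))
  beta_h <- draw_slopes(dir_univ, config$slope_magnitude)
  beta_r <- draw_slopes(dir_rhesus, config$slope_magnitude)
  base_h <- base_univ + stats::rnorm(n, 0, config$sigma_species)
  base_r <- c(base_univ[seq_len(n_shared)],
              stats::rnorm(n - n_shared, config$baseline_log2_mean,
                           config$baseline_log2_sd)) +
            stats::rnorm(n, 0, config$sigma_species)

  # sample layouts
  r_sub <- sprintf("RSUB%02d", seq_len(config$n_subjects_rhesus))
  r_samples <- expand.grid(subject_id = r_sub, age = config$rhesus_ages,
                           stringsAsFactors = FALSE)
  r_samples$sample_id <- sprintf("R_%s_G%03d", r_samples$subject_id,
                                 round(r_samples$age))
  h_age <- rep(config$human_ages, config$n_humans_per_window)
  h_sub <- sprintf("HSUB%02d", seq_along(h_age))
  h_samples <- data.frame(subject_id = h_sub, age = h_age,
                          sample_id = sprintf("H_%s", h_sub),
                          stringsAsFactors = FALSE)

  sim_species <- function(species, samples, base, beta, ids, genes) {
    np <- config$n_plexes
    n_g <- length(base)
    subjects <- unique(samples$subject_id)
    plex_ids <- sprintf("%s%d", toupper(substr(species, 1, 1)), seq_len(np))
    plex_of <- sample(rep_len(plex_ids, nrow(samples)))
    # protein-specific random effects: subject (repeated-measures correlation)
    # and plex (the multiplicative batch structure IRS corrects)
    u <- matrix(stats::rnorm(n_g * length(subjects), 0, config$sigma_subject),
                n_g, dimnames = list(ids, subjects))
    b <- matrix(stats::rnorm(n_g * np, 0, config$sigma_plex),
                n_g, dimnames = list(ids, plex_ids))

    mu <- outer(base, rep(1, nrow(samples))) +
      outer(beta, samples$age) +
      u[, samples$subject_id, drop = FALSE]
    pool <- rowMeans(mu)

    bio <- mu + b[, plex_of, drop = FALSE] +
      matrix(stats::rnorm(length(mu), 0, config$sigma_noise), nrow(mu))
    colnames(bio) <- samples$sample_id

    ref_meta <- expand.grid(plex = plex_ids,
                            k = seq_len(config$ref_pools_per_plex),
                            stringsAsFactors = FALSE)
    ref_id <- sprintf("%s_POOL%d", ref_meta$plex, ref_meta$k)
    ref <- outer(pool, rep(1, nrow(ref_meta))) +
      b[, ref_meta$plex, drop = FALSE] +
      matrix(stats::rnorm(length(pool) * nrow(ref_meta), 0, config$sigma_noise),
             length(pool))
    colnames(ref) <- ref_id

    m <- 2^cbind(bio, ref)
    rownames(m) <- ids

    meta <- data.frame(
      sample_id = c(samples$sample_id, ref_id),
      species = species,
      subject_id = c(samples$subject_id, rep("pool", length(ref_id))),
      gestational_age_days = c(samples$age, rep(NA_real_, length(ref_id))),
      window = c(rhesus_equivalent_window(samples$age, species),
                 rep(NA_character_, length(ref_id))),
      plex_id = c(plex_of, ref_meta$plex),
      channel_label = NA_character_,
      is_reference_pool = c(rep(FALSE, nrow(samples)),
                            rep(TRUE, length(ref_id))),
      stringsAsFactors = FALSE)
    meta$channel_label <- stats::ave(meta$sample_id, meta$plex_id,
                                     FUN = function(x) sprintf("C%02d", seq_along(x)))
    list(table = quant_table(m, genes), meta = meta,
         subject_effects = u, plex_effects = b)
  }

  rh <- sim_species("rhesus", r_samples, base_r, beta_r, rhesus_id, rhesus_gene)
  hu <- sim_species("human", h_samples, base_h, beta_h, human_id, human_gene)

  meta <- rbind(rh$meta, hu$meta)
  validate_sample_meta(meta)

  truth <- list(
    rhesus = data.frame(protein_id = rhesus_id, gene_symbol = rhesus_gene,
                        beta = beta_r, direction = dir_rhesus,
                        baseline = base_r, is_shared = rhesus_gene %in% shared_gene,
                        stringsAsFactors = FALSE),
    human = data.frame(protein_id = human_id, gene_symbol = human_gene,
                       beta = beta_h, direction = dir_univ,
                       baseline = base_h, is_shared = human_gene %in% shared_gene,
                       stringsAsFactors = FALSE),
    subject_effects = list(rhesus = rh$subject_effects,
                           human = hu$subject_effects),
    plex_effects = list(rhesus = rh$plex_effects, human = hu$plex_effects),
    config = config)

  list(rhesus = rh$table, human = hu$table, meta = meta,
       ortholog_map = map, truth = truth)
}

#' Generate a tissue reference atlas with planted tissue-enriched genes
#'
#' Plants `planted_per_tissue` genes per tissue whose expression in that
#' tissue exceeds the expression threshold and is at least `fold`-fold higher
#' than in every other tissue, so the five-fold classification rule recovers
#' the planted sets exactly. Background genes either sit below the expression
#' threshold everywhere or are broadly expressed with fold-changes < 5.
#'
#' @param n_genes total genes in the atlas
#' @param tissues character vector of tissue names (>= 2)
#' @param planted_per_tissue planted genes per tissue
#' @param fold enrichment fold of planted genes; must be >= 5 or the
#'   classification rule cannot recover them
#' @param seed integer RNG seed
#' @param gene_symbols optional gene names (length `n_genes`); defaults to
#'   GENE0001, ... so atlases align with generated experiments
#' @param planted_genes optional named list (tissue -> gene symbols) fixing
#'   which genes are planted for those tissues — e.g. to make a tissue's
#'   signature coincide with gestationally drifting proteins; remaining
#'   tissues are planted from the leftover genes at `planted_per_tissue`
#' @return list with `reference` (genes x tissues matrix) and `truth_sets`
#'   (named list tissue -> planted gene symbols)
#' @export
generate_tissue_reference <- function(n_genes, tissues, planted_per_tissue,
                                      fold = 10, seed = 1L,
                                      gene_symbols = sprintf("GENE%04d", seq_len(n_genes)),
                                      planted_genes = NULL) {
  if (length(tissues) < 2) stop("at least two tissues are required")
  if (fold < 5) stop("fold must be >= 5 to satisfy the classification rule")
  stopifnot(length(gene_symbols) == n_genes)
  set.seed(seed)
  gene_symbols <- toupper(gene_symbols)
  if (!is.null(planted_genes)) {
    if (!all(names(planted_genes) %in% tissues))
      stop("planted_genes names must be tissues")
    if (!all(unlist(planted_genes) %in% gene_symbols))
      stop("planted_genes must be drawn from gene_symbols")
  }
  free_tissues <- setdiff(tissues, names(planted_genes))
  n_planted <- planted_per_tissue * length(free_tissues)
  if (n_planted + length(unlist(planted_genes)) > n_genes)
    stop("planted_per_tissue x number of tissues must be <= n_genes")

  m <- matrix(0, n_genes, length(tissues),
              dimnames = list(gene_symbols, tissues))
  fixed_idx <- match(unlist(planted_genes), gene_symbols)
  free_pool <- setdiff(seq_len(n_genes), fixed_idx)
  planted_idx <- c(fixed_idx, sample(free_pool, n_planted))
  tissue_of <- c(rep(names(planted_genes), lengths(planted_genes)),
                 rep(free_tissues, each = planted_per_tissue))
  for (j in seq_along(planted_idx)) {
    i <- planted_idx[j]
    pos <- match(tissue_of[j], tissues)
    own <- stats::runif(1, 10, 100)
    m[i, -pos] <- own / fold / stats::runif(length(tissues) - 1, 1.25, 3)
    m[i, pos] <- own
  }
  bg <- setdiff(seq_len(n_genes), planted_idx)
  low <- bg[seq_len(floor(length(bg) / 2))]
  broad <- setdiff(bg, low)
  m[low, ] <- matrix(stats::runif(length(low) * length(tissues), 0, 0.9),
                     length(low))
  base <- stats::runif(length(broad), 2, 10)
  m[broad, ] <- base * matrix(stats::runif(length(broad) * length(tissues), 0.5, 2),
                              length(broad))

  truth <- split(gene_symbols[planted_idx], tissue_of)[tissues]
  list(reference = m, truth_sets = truth)
}
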