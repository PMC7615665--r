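# End-to-end study pipeline: per-cohort estimation, cross-cohort replication,
# sensitivity analyses, and the output bundle.

#' Run configuration for the full pipeline
#'
#' @param cohort_paths optional named list/vector with CSV paths for
#'   `cohort_A` and `cohort_B`; when NULL the synthetic presets are used.
#' @param scenario planted-network scenario for synthetic runs.
#' @param n_a,n_b synthetic sample sizes (defaults mirror the study: 4,407
#'   and 10,351; use small values for smoke runs).
#' @param m imputations (study default 50).
#' @param max_iter chained-equation sweeps.
#' @param prior_scale prior SD on partial correlations (study default 0.2).
#' @param n_draws pooled posterior draws per model (study default 10,000).
#' @param burn_in per-chain burn-in.
#' @param bf_threshold Bayes-factor cut (study default 3).
#' @param n_spinglass spinglass iterations (study default 5,000).
#' @param completers_min_frac trait-completeness cut for the completers
#'   sensitivity condition.
#' @param sensitivity character subset of `prior_0.1`, `prior_0.4`,
#'   `completers_70`, `residualize_age_sex`.
#' @param seed global integer seed.
#' @param out_dir optional output directory; when non-NULL all tables,
#'   figures and the manifest are written there.
#' @return list of class `run_config`.
#' @export
run_config <- function(cohort_paths = NULL, scenario = "paper_like",
                       n_a = 4407L, n_b = 10351L,
                       m = 50L, max_iter = 5L, prior_scale = 0.2,
                       n_draws = 10000L, burn_in = 1000L, bf_threshold = 3,
                       n_spinglass = 5000L, completers_min_frac = 0.70,
                       sensitivity = c("prior_0.1", "prior_0.4",
                                       "completers_70", "residualize_age_sex"),
                       seed = 1L, out_dir = NULL) {
  structure(list(cohort_paths = cohort_paths, scenario = scenario,
                 n_a = as.integer(n_a), n_b = as.integer(n_b),
                 m = as.integer(m), max_iter = as.integer(max_iter),
                 prior_scale = prior_scale, n_draws = as.integer(n_draws),
                 burn_in = as.integer(burn_in), bf_threshold = bf_threshold,
                 n_spinglass = as.integer(n_spinglass),
                 completers_min_frac = completers_min_frac,
                 sensitivity = sensitivity, seed = as.integer(seed),
                 out_dir = out_dir),
            class = "run_config")
}

#' Read a run configuration from YAML
#' @param path YAML file whose keys match [run_config()] arguments.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  do.call(run_config, yaml::read_yaml(path))
}

stage <- function(label, expr) {
  t0 <- Sys.time()
  out <- tryCatch(expr, error = function(e)
    stop("pipeline stage '", label, "' failed: ", conditionMessage(e),
         call. = FALSE))
  message(sprintf("[%s] %.1fs", label, as.numeric(Sys.time() - t0, units = "secs")))
  out
}

analyze_cohort <- function(tbl, cfg, variant = "primary") {
  cohort <- tbl$cohort_id
  prior_scale <- switch(variant, prior_0.1 = 0.1, prior_0.4 = 0.4,
                        cfg$prior_scale)
  tbl <- stage(paste(cohort, "exclusions"), apply_exclusions(tbl, seed = cfg$seed))
  if (variant == "completers_70")
    tbl <- completers_filter(tbl, cfg$completers_min_frac)
  imp <- stage(paste(cohort, "imputation"),
               impute(tbl, imputation_config(cfg$m, cfg$max_iter,
                                             substream_seed(cfg$seed, cohort))))
  residualize_flag <- variant == "residualize_age_sex"
  screen <- stage(paste(cohort, "zero-order screen"), zero_order_screen(imp))
  fit_seed <- substream_seed(cfg$seed, paste0(cohort, "_ggm"))
  draws_traits <- stage(paste(cohort, "GGM traits"),
                        fit_ggm(imp, vars = trait_vars(),
                                prior_scale = prior_scale,
                                n_draws = cfg$n_draws, burn_in = cfg$burn_in,
                                seed = fit_seed,
                                residualize_covariates = residualize_flag))
  draws_full <- stage(paste(cohort, "GGM full"),
                      fit_ggm(imp, prior_scale = prior_scale,
                              n_draws = cfg$n_draws, burn_in = cfg$burn_in,
                              seed = fit_seed + 1L,
                              residualize_covariates = residualize_flag))
  dec_traits <- classify_edges(draws_traits, threshold = cfg$bf_threshold)
  dec_full <- classify_edges(draws_full, threshold = cfg$bf_threshold)
  if (any(dec_full$bf01 %in% c(1e-4, 1e4)))
    message(cohort, ": some Bayes factors hit the reporting floor/ceiling")
  beta <- beta_from_draws(draws_full)
  mediation <- list(
    hyper_dysreg_dep = mediation_index(beta, "hyperactive_impulsive",
                                       "dysregulation", "dep_12"),
    autistic_peer_dep = mediation_index(beta, "autistic", "peer_problems",
                                        "dep_12"))
  r2 <- lapply(stats::setNames(nm = depression_vars()),
               function(v) bayesian_r2(draws_full, v))
  community <- stage(paste(cohort, "spinglass"),
                     spinglass_consensus(
                       supported_adjacency(dec_full, draws_full$labels),
                       n_iter = cfg$n_spinglass,
                       seed = substream_seed(cfg$seed, paste0(cohort, "_sg"))))
  list(cohort_id = cohort, n = nrow(tbl$values), table = tbl, imputed = imp,
       screen = screen, rho_mean_full = apply(draws_full$rho, c(2, 3), mean),
       decisions_traits = dec_traits, decisions_full = dec_full,
       mediation = mediation, r2 = r2, community = community,
       prior_scale = prior_scale)
}

#' Run the primary two-cohort analysis
#'
#' Per cohort: exclusions, multiple imputation, nonparanormal transform, a
#' 7-node traits-only GGM and the full 13-node GGM, Bayes-factor edge
#' classification, zero-order screen, mediation indices, Bayesian R2 and
#' spinglass communities; then cross-cohort replication, per-block network
#' densities, adjacency similarity, and (optionally) figures and tables under
#' `cfg$out_dir`.
#'
#' @param cfg a `run_config`.
#' @param tables optional named list of two `cohort_table`s (overrides both
#'   `cfg$cohort_paths` and the synthetic presets; used by sensitivity runs).
#' @param variant internal variant label for sensitivity conditions.
#' @return a result bundle (list).
#' @export
run_primary <- function(cfg, tables = NULL, variant = "primary") {
  stopifnot(inherits(cfg, "run_config"))
  if (is.null(tables)) {
    tables <- if (!is.null(cfg$cohort_paths)) {
      list(cohort_A = load_cohort(cfg$cohort_paths[["cohort_A"]],
                                  ndnet_schema("cohort_A"), "cohort_A"),
           cohort_B = load_cohort(cfg$cohort_paths[["cohort_B"]],
                                  ndnet_schema("cohort_B"), "cohort_B"))
    } else {
      list(cohort_A = simulate_cohort_preset("cohort_A", cfg$seed,
                                             cfg$scenario, n = cfg$n_a),
           cohort_B = simulate_cohort_preset("cohort_B", cfg$seed,
                                             cfg$scenario, n = cfg$n_b))
    }
  }
  res <- lapply(tables, analyze_cohort, cfg = cfg, variant = variant)
  a <- res[[1]]; b <- res[[2]]

  repl_full <- replicate_edges(a$decisions_full, b$decisions_full)
  repl_traits <- replicate_edges(a$decisions_traits, b$decisions_traits)
  ps <- pair_sets()
  densities <- list(
    trait_trait = network_density(repl_full, ps$trait_trait),
    trait_stressor = network_density(repl_full, ps$trait_stressor),
    trait_depression = network_density(repl_full, ps$trait_depression),
    stressor_depression = network_density(repl_full, ps$stressor_depression))
  independence <- list(
    trait_depression = network_density(repl_full, ps$trait_depression,
                                       count = "replicated_independence"))
  similarity <- tryCatch(
    adjacency_similarity(a$decisions_full, b$decisions_full),
    error = function(e) NA_real_)

  bundle <- list(config = cfg, variant = variant, cohorts = res,
                 replication = repl_full, replication_traits = repl_traits,
                 densities = densities, independence = independence,
                 adjacency_similarity = similarity)
  if (!is.null(cfg$out_dir)) write_bundle(bundle, cfg)
  bundle
}

write_bundle <- function(bundle, cfg) {
  dir <- file.path(cfg$out_dir, bundle$variant)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  a <- bundle$cohorts[[1]]; b <- bundle$cohorts[[2]]
  write_edges_tsv(a$decisions_full, file.path(dir, "edges_cohort_A.tsv"))
  write_edges_tsv(b$decisions_full, file.path(dir, "edges_cohort_B.tsv"))
  write_edges_tsv(bundle$replication, file.path(dir, "replication.tsv"))
  utils::write.table(a$screen, file.path(dir, "zero_order_cohort_A.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  labels <- ndnet_variables()
  wa <- supported_adjacency(a$decisions_full, labels)
  wb <- supported_adjacency(b$decisions_full, labels)
  utils::write.csv(wa, file.path(dir, "adjacency_cohort_A.csv"))
  utils::write.csv(wb, file.path(dir, "adjacency_cohort_B.csv"))
  spec <- figure_spec(layout_seed = cfg$seed)
  avg <- (abs(wa) + abs(wb)) / 2
  la <- plot_network(wa, file.path(dir, "network_cohort_A.png"), spec,
                     schema = a$table$schema, layout_adjacency = avg)
  plot_network(wb, file.path(dir, "network_cohort_B.png"), spec,
               schema = b$table$schema, coords = la$coords)
  triangular_matrix(bundle$replication, a$decisions_full, b$decisions_full,
                    labels, file_tsv = file.path(dir, "triangular_matrix.tsv"),
                    file_png = file.path(dir, "triangular_matrix.png"))
  write_community_json(a$community, file.path(dir, "community_cohort_A.json"))
  write_community_json(b$community, file.path(dir, "community_cohort_B.json"))
  manifest <- list(
    package_version = as.character(utils::packageVersion("ndnet")),
    r_version = R.version.string,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    variant = bundle$variant,
    seed = cfg$seed,
    prior_scale = c(a$prior_scale, b$prior_scale)[1],
    n_draws = cfg$n_draws, m = cfg$m, bf_threshold = cfg$bf_threshold,
    n = list(cohort_A = a$n, cohort_B = b$n),
    densities = lapply(bundle$densities, function(d) d$density_pct),
    adjacency_similarity = bundle$adjacency_similarity)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Run the sensitivity analyses
#'
#' One bundle per condition, each varying a single element of the primary
#' run (prior scale 0.1 / 0.4; completers-only filter; age/sex
#' residualization) while reusing the primary run's data and seeds, plus a
#' per-pair comparison table of replication statuses across conditions.
#'
#' @param cfg a `run_config` (its `sensitivity` field selects conditions).
#' @param primary the primary bundle from [run_primary()]; rerun if NULL.
#' @return list: `bundles` (named by condition) and `comparison` (data.frame
#'   pair x condition with `changed` flags).
#' @export
run_sensitivity <- function(cfg, primary = NULL) {
  if (is.null(primary)) primary <- run_primary(cfg)
  tables <- lapply(primary$cohorts, function(cc) cc$table)
  names(tables) <- names(primary$cohorts) %||% c("cohort_A", "cohort_B")
  bundles <- lapply(stats::setNames(nm = cfg$sensitivity), function(cond)
    run_primary(cfg, tables = tables, variant = cond))
  comparison <- do.call(rbind, lapply(names(bundles), function(cond) {
    data.frame(condition = cond,
               pair = primary$replication$pair,
               primary = primary$replication$replication,
               sensitivity = bundles[[cond]]$replication$replication,
               stringsAsFactors = FALSE)
  }))
  comparison$changed <- comparison$primary != comparison$sensitivity
  if (!is.null(cfg$out_dir))
    utils::write.table(comparison,
                       file.path(cfg$out_dir, "sensitivity_comparison.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  list(bundles = bundles, comparison = comparison)
}
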