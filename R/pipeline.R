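#' Run the full analysis workflow on simulated traits
#'
#' Orchestrates every stage of the cross-trait analysis on a set of
#' simulated traits with known truth: simulation and QC, LD scores,
#' per-trait heritability (full, locus-excluded and liability-scale),
#' the pairwise genetic-correlation matrix with a Bonferroni threshold,
#' a local covariance scan, a directional screen, stratified enrichment,
#' and a random-effects meta-analysis of enrichment across traits.  One
#' TSV is written per stage plus a JSON run manifest; given the same
#' configuration and seed the stage TSVs are byte-identical across runs.
#'
#' @param config either a YAML file path or a list with elements:
#'   `seed` (root seed for all randomness); `out_dir`; `simulation`, a
#'   list accepting [sim_config()] fields plus `n_traits` (traits are
#'   simulated as consecutive pairs sharing one reference panel, with the
#'   configured within-pair genetic correlation) and optionally
#'   `enriched_frac`/`enriched_multiplier` for a functional category
#'   carrying concentrated heritability; `thresholds`, a list with any of
#'   `p_gwas` (5e-8), `window_bp` (5e5), `alpha` (0.05), `ppa` (0.9),
#'   `lr` (0.05); and `n_jackknife_blocks`.
#' @param out_dir output directory (overrides `config$out_dir`).
#' @return Invisibly, a list with the per-stage file paths and in-memory
#'   results.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  seed <- as.integer(config$seed %||% 1L)
  out_dir <- out_dir %||% config$out_dir %||% stop("no output directory")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  thr <- config$thresholds %||% list()
  p_gwas <- thr$p_gwas %||% 5e-8
  window_bp <- thr$window_bp %||% 5e5
  alpha <- thr$alpha %||% 0.05
  ppa_min <- thr$ppa %||% 0.9
  lr_threshold <- thr$lr %||% 0.05

  simc <- config$simulation %||% list()
  n_traits <- simc$n_traits %||% 2L
  stopifnot(n_traits >= 2)
  m_snps <- simc$m_snps %||% 4000
  n_blocks_ld <- simc$n_blocks %||% 40
  block_size <- simc$block_size %||% 100
  n_jk <- config$n_jackknife_blocks %||% min(n_blocks_ld, 200)
  t0 <- Sys.time()
  timings <- list()
  paths <- list()

  # --- panel, annotations, simulation -----------------------------------
  base_cfg <- sim_config(
    m_snps = m_snps, n_blocks = n_blocks_ld, block_size = block_size,
    ld_rho = simc$ld_rho %||% c(0.1, 0.8),
    h2_1 = (simc$h2 %||% rep(0.2, n_traits))[1],
    h2_2 = (simc$h2 %||% rep(0.2, n_traits))[2],
    n1 = simc$n %||% 50000, n2 = simc$n %||% 50000,
    seed = seed
  )
  panel <- build_reference_panel(base_cfg)
  map <- panel_snp_map(panel)

  enriched_frac <- simc$enriched_frac %||% 0.1
  enriched_mult <- simc$enriched_multiplier %||% 9
  n_enr_blocks <- max(1, round(enriched_frac * n_blocks_ld))
  enr_blocks <- with_seed(seed + 11,
                          sample(n_blocks_ld, n_enr_blocks))
  annot <- annot_matrix(
    map$snp_id,
    cbind(enriched = as.numeric(map$block %in% enr_blocks))
  )

  h2_vec <- simc$h2 %||% rep(0.2, n_traits)
  rg_pair <- simc$rg %||% 0.5
  trait_names <- simc$trait_names %||% paste0("trait", seq_len(n_traits))
  n_pairs_sim <- ceiling(n_traits / 2)
  ss_list <- vector("list", n_traits)
  truths <- vector("list", n_pairs_sim)
  for (k in seq_len(n_pairs_sim)) {
    i <- 2 * k - 1
    j <- min(2 * k, n_traits)
    cfg_k <- sim_config(
      m_snps = m_snps, n_blocks = n_blocks_ld, block_size = block_size,
      ld_rho = simc$ld_rho %||% c(0.1, 0.8),
      h2_1 = h2_vec[i], h2_2 = h2_vec[j], rg = rg_pair,
      n1 = simc$n %||% 50000, n2 = simc$n %||% 50000,
      annotations = annot,
      annotation_effects = c(enriched = enriched_mult),
      trait_names = c(trait_names[i], trait_names[j]),
      seed = seed
    )
    sim <- simulate_sumstats_pair(cfg_k, panel = panel,
                                  effects = simulate_joint_effects(
                                    cfg_k, panel, seed = seed + 100 + k),
                                  seed = seed + 200 + k)
    ss_list[[i]] <- sim$ss1
    if (j > i) ss_list[[j]] <- sim$ss2
    truths[[k]] <- sim$truth
  }
  names(ss_list) <- trait_names
  for (t in seq_len(n_traits)) {
    pth <- file.path(out_dir, paste0("sumstats_", trait_names[t], ".tsv"))
    write_sumstats(ss_list[[t]], pth)
    paths[[paste0("sumstats_", trait_names[t])]] <- pth
  }
  write_truth_manifest(truths[[1]], file.path(out_dir, "truth_pair1.json"))
  timings$simulate <- as.numeric(Sys.time() - t0, units = "secs")

  # --- QC ----------------------------------------------------------------
  ss_list <- lapply(ss_list, apply_qc_filters)
  snp_counts <- vapply(ss_list, function(s) nrow(s$snps), integer(1))

  # --- LD scores ---------------------------------------------------------
  t1 <- Sys.time()
  ld_strat <- compute_stratified_ld_scores(panel, annot)
  paths$ldscores <- file.path(out_dir, "ldscores.tsv")
  write_ld_scores(ld_strat, paths$ldscores)
  timings$ldscores <- as.numeric(Sys.time() - t1, units = "secs")

  # --- per-trait h2: full, locus-excluded, liability ---------------------
  t1 <- Sys.time()
  h2_rows <- vector("list", n_traits)
  h2_fits <- vector("list", n_traits)
  for (t in seq_len(n_traits)) {
    fit <- estimate_h2(ss_list[[t]], ld_strat, m_total = m_snps,
                       n_blocks = n_jk)
    loci <- clump_loci(ss_list[[t]], p_threshold = p_gwas,
                       window_bp = window_bp)
    prop <- if (nrow(loci) > 0) {
      pe <- proportion_explained(ss_list[[t]], ld_strat, loci,
                                 m_total = m_snps, n_blocks = n_jk)
      pe$proportion
    } else {
      0
    }
    h2_fits[[t]] <- fit
    h2_rows[[t]] <- data.frame(
      trait = trait_names[t],
      h2_obs = fit$h2_observed$value, h2_obs_se = fit$h2_observed$se,
      h2_liab = if (is.null(fit$h2_liability)) NA
                else fit$h2_liability$value,
      intercept = fit$intercept$value, intercept_se = fit$intercept$se,
      mean_chi2 = fit$mean_chi2, m_used = fit$m_snps_used,
      n_loci = nrow(loci), prop_h2_top_loci = prop
    )
  }
  paths$h2 <- file.path(out_dir, "h2.tsv")
  utils::write.table(do.call(rbind, h2_rows), paths$h2, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  timings$h2 <- as.numeric(Sys.time() - t1, units = "secs")

  # --- pairwise genetic correlations -------------------------------------
  t1 <- Sys.time()
  rg_tab <- rg_matrix(ss_list, ld_strat, m_total = m_snps,
                      n_blocks = n_jk, alpha = alpha)
  paths$rg <- file.path(out_dir, "rg.tsv")
  utils::write.table(rg_tab, paths$rg, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  timings$rg <- as.numeric(Sys.time() - t1, units = "secs")

  # --- local covariance scan for the first pair --------------------------
  t1 <- Sys.time()
  gcov12 <- attr(rg_tab, "fits")[[1]]
  scan <- local_scan(ss_list[[1]], ss_list[[2]], panel,
                     gcov_intercept = gcov12$gcov_intercept$value,
                     intercept1 = h2_fits[[1]]$intercept$value,
                     intercept2 = h2_fits[[2]]$intercept$value,
                     alpha = alpha)
  paths$local <- file.path(out_dir, "local.tsv")
  utils::write.table(as.data.frame(scan), paths$local, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  timings$local <- as.numeric(Sys.time() - t1, units = "secs")

  # --- directional screen over pairs -------------------------------------
  t1 <- Sys.time()
  dir_rows <- list()
  pairs <- utils::combn(n_traits, 2)
  for (kk in seq_len(ncol(pairs))) {
    i <- pairs[1, kk]; j <- pairs[2, kk]
    ids_x <- select_pruned(ss_list[[i]], panel, p_threshold = p_gwas)
    ids_y <- select_pruned(ss_list[[j]], panel, p_threshold = p_gwas)
    set_x <- ascertain_effects(ss_list[[i]], ss_list[[j]], ids_x,
                               trait = trait_names[i])
    set_y_raw <- ascertain_effects(ss_list[[j]], ss_list[[i]], ids_y,
                                   trait = trait_names[j])
    # orient columns as (x, y) for the model fitter
    set_y <- set_y_raw
    set_y$beta_x <- set_y_raw$beta_y; set_y$se_x <- set_y_raw$se_y
    set_y$beta_y <- set_y_raw$beta_x; set_y$se_y <- set_y_raw$se_x
    fit <- suppressMessages(
      fit_directional_models(set_x, set_y, lr_threshold = lr_threshold)
    )
    dir_rows[[kk]] <- data.frame(
      trait_x = trait_names[i], trait_y = trait_names[j],
      n_snps_x = fit$n_x, n_snps_y = fit$n_y,
      ll_causal_xy = fit$loglik[["causal_xy"]],
      ll_causal_yx = fit$loglik[["causal_yx"]],
      ll_noncausal_indep = fit$loglik[["noncausal_indep"]],
      ll_noncausal_pleio = fit$loglik[["noncausal_pleio"]],
      relative_lr = fit$relative_lr,
      hetero_flag = fit$hetero_flag, verdict = fit$verdict
    )
  }
  paths$direction <- file.path(out_dir, "direction.tsv")
  utils::write.table(do.call(rbind, dir_rows), paths$direction, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  timings$direction <- as.numeric(Sys.time() - t1, units = "secs")

  # --- stratified enrichment + meta-analysis -----------------------------
  t1 <- Sys.time()
  strat_fits <- lapply(ss_list, function(s) {
    stratified_h2(s, ld_strat, annot, m_total = m_snps, n_blocks = n_jk)
  })
  enr_rows <- do.call(rbind, lapply(seq_len(n_traits), function(t) {
    cbind(trait = trait_names[t], strat_fits[[t]]$enrichment)
  }))
  paths$enrichment <- file.path(out_dir, "enrichment.tsv")
  utils::write.table(enr_rows, paths$enrichment, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  meta_tab <- meta_analyze_enrichment(strat_fits, alpha = alpha)
  paths$meta <- file.path(out_dir, "meta.tsv")
  utils::write.table(meta_tab, paths$meta, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  timings$enrichment <- as.numeric(Sys.time() - t1, units = "secs")

  # --- manifest ----------------------------------------------------------
  manifest <- list(
    seed = seed,
    package_version = as.character(utils::packageVersion("ldscreg")),
    r_version = R.version.string,
    n_traits = n_traits, m_snps = m_snps,
    snp_counts_after_qc = as.list(snp_counts),
    thresholds = list(p_gwas = p_gwas, window_bp = window_bp,
                      alpha = alpha, ppa = ppa_min, lr = lr_threshold),
    timings_sec = lapply(timings, function(x) round(x, 3)),
    files = lapply(paths, basename)
  )
  paths$manifest <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       pretty = TRUE)

  invisible(list(paths = paths, sumstats = ss_list, panel = panel,
                 h2 = h2_fits, rg = rg_tab, local = scan,
                 stratified = strat_fits, meta = meta_tab,
                 truths = truths))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
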