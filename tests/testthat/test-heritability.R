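test_that("noiseless chi2 recovers the slope and intercept exactly", {
  # chi2_j = 1 + N h2 l_j / M with h2 = 0.5: exact linear recovery under
  # any regression weights (a SNP with l_j = 2 at N = 1e4, M = 1e3 has
  # chi2 = 11)
  cfg <- small_config(ld_rho = c(0.2, 0.8))
  panel <- build_reference_panel(cfg)
  ld <- compute_ld_scores(panel)
  map <- panel_snp_map(panel)
  h2 <- 0.5; n_obs <- 10000; m <- 1000
  chi2 <- 1 + n_obs * h2 * ld$L2 / m
  df <- data.frame(snp_id = map$snp_id, chrom = map$chrom, pos = map$pos,
                   a1 = "A", a2 = "G", z = sqrt(chi2), n = n_obs,
                   eaf = 0.3)
  ss <- sumstats(df, trait_name = "exact")
  fit <- estimate_h2(ss, ld, m_total = m, n_blocks = 20)
  expect_equal(fit$h2_observed$value, 0.5, tolerance = 1e-10)
  expect_equal(fit$intercept$value, 1, tolerance = 1e-10)
  expect_equal(max(abs(fit$h2_observed$delete_values - 0.5)), 0,
               tolerance = 1e-9)

  # constant LD scores leave the slope unidentified
  cfg_c <- small_config(ld_rho = 0)
  ld_c <- compute_ld_scores(build_reference_panel(cfg_c))
  df_c <- df
  df_c$z <- 1
  expect_error(estimate_h2(sumstats(df_c), ld_c, n_blocks = 20),
               "constant LD scores")
})

test_that("null simulations are covered by jackknife intervals", {
  cfg <- small_config(h2_1 = 0, h2_2 = 0)
  panel <- build_reference_panel(cfg)
  ld <- compute_ld_scores(panel)
  inside <- 0
  n_rep <- 60
  for (r in seq_len(n_rep)) {
    sim <- simulate_sumstats_pair(cfg, panel = panel,
                                  effects = simulate_joint_effects(
                                    cfg, panel, seed = 300 + r),
                                  seed = 800 + r)
    fit <- estimate_h2(sim$ss1, ld, n_blocks = 20)
    inside <- inside + (abs(fit$h2_observed$value) <=
                          2 * fit$h2_observed$se)
  }
  expect_gte(inside, round(0.85 * n_rep))
})

test_that("estimates are invariant to input row order", {
  cfg <- small_config(h2_1 = 0.3, h2_2 = 0.2)
  sim <- simulate_sumstats_pair(cfg)
  ld <- compute_ld_scores(sim$panel)
  fit1 <- estimate_h2(sim$ss1, ld, n_blocks = 20)
  shuffled <- sim$ss1
  perm <- sample(nrow(shuffled$snps))
  shuffled$snps <- shuffled$snps[perm, ]
  shuffled <- sumstats(shuffled$snps, trait_name = "shuffled")
  ld_shuf <- ld[rev(seq_len(nrow(ld))), ]
  class(ld_shuf) <- class(ld)
  fit2 <- estimate_h2(shuffled, ld_shuf, n_blocks = 20)
  expect_equal(fit1$h2_observed$value, fit2$h2_observed$value,
               tolerance = 1e-12)
  expect_equal(fit1$h2_observed$se, fit2$h2_observed$se, tolerance = 1e-12)
})

test_that("liability conversion matches high-precision constants", {
  # P = F = 0.5: phi(0)^2 = 1/(2 pi), factor is exactly pi/2
  expect_equal(liability_scale_factor(0.5, 0.5), pi / 2, tolerance = 1e-12)
  expect_equal(observed_to_liability(0.1, 0.5, 0.5), 0.1 * pi / 2,
               tolerance = 1e-12)
  # frozen values from a 30-digit independent evaluation of the closed form
  expect_equal(liability_scale_factor(0.1, 0.1), 2.9221098,
               tolerance = 1e-7)
  expect_equal(liability_scale_factor(0.5, 0.01), 0.55190730,
               tolerance = 1e-7)
  expect_error(liability_scale_factor(0, 0.5))
  expect_error(liability_scale_factor(0.5, 1))

  # strictly increasing in the observed-scale value, and exact on
  # estimate objects
  e <- estimate_with_error(0.1, c(0.09, 0.1, 0.11))
  el <- observed_to_liability(e, 0.5, 0.1)
  expect_equal(el$value, 0.1 * liability_scale_factor(0.5, 0.1))
  expect_equal(el$se, e$se * liability_scale_factor(0.5, 0.1))
  expect_gt(observed_to_liability(0.2, 0.3, 0.05),
            observed_to_liability(0.1, 0.3, 0.05))
})

test_that("binary-trait simulation inverts the liability conversion", {
  cfg <- small_config(h2_1 = 0.3, h2_2 = 0.3,
                      trait_types = c("binary", "binary"),
                      sample_prev = c(0.5, 0.4),
                      population_prev = c(0.1, 0.02))
  sim <- simulate_sumstats_pair(cfg)
  # observed-scale truth times the factor returns the liability input
  expect_equal(observed_to_liability(sim$truth$h2_obs[1], 0.5, 0.1), 0.3,
               tolerance = 1e-12)
  expect_equal(observed_to_liability(sim$truth$h2_obs[2], 0.4, 0.02), 0.3,
               tolerance = 1e-12)
  # the fitted object carries a liability-scale estimate
  ld <- compute_ld_scores(sim$panel)
  fit <- estimate_h2(sim$ss1, ld, n_blocks = 20)
  expect_equal(fit$h2_liability$value,
               fit$h2_observed$value * liability_scale_factor(0.5, 0.1))
})

test_that("greedy clumping reproduces hand-traced loci", {
  mk <- function(pos, p) {
    z <- qnorm(p / 2) * -1
    data.frame(snp_id = paste0("s", seq_along(pos)), chrom = 1L,
               pos = pos, a1 = "A", a2 = "G", z = z, n = 1e5,
               eaf = 0.3, p = p)
  }
  # no significant SNP: empty region set
  ss0 <- sumstats(mk(c(1e6, 2e6), c(1e-4, 0.3)))
  expect_equal(nrow(clump_loci(ss0)), 0)

  # 1.0 Mb (1e-10) absorbs 1.3 Mb (1e-9): a single +/- 500 kb region
  ss1 <- sumstats(mk(c(1.0e6, 1.3e6), c(1e-10, 1e-9)))
  r1 <- clump_loci(ss1)
  expect_equal(nrow(r1), 1)
  expect_equal(r1$start, 1.0e6 - 1 - 5e5)
  expect_equal(r1$end, 1.0e6 + 5e5)

  # adding 2.5 Mb (3e-9) and a non-significant 10 Mb SNP: exactly 2 regions
  ss2 <- sumstats(mk(c(1.0e6, 1.3e6, 2.5e6, 10e6),
                     c(1e-10, 1e-9, 3e-9, 0.01)))
  r2 <- clump_loci(ss2)
  expect_equal(nrow(r2), 2)
  expect_equal(r2$start[2], 2.5e6 - 1 - 5e5)
})

test_that("locus exclusion changes the estimate as the truth dictates", {
  cfg <- small_config(h2_1 = 0.3, h2_2 = 0.3)
  sim <- simulate_sumstats_pair(cfg)
  ld <- compute_ld_scores(sim$panel)
  full <- estimate_h2(sim$ss1, ld, n_blocks = 20)

  # empty exclusion is the identity
  same <- h2_excluding_regions(sim$ss1, ld, region_set(), n_blocks = 20)
  expect_equal(same$h2_observed$value, full$h2_observed$value)

  # excluding everything is fatal
  all_of_it <- region_set(1:22, rep(0, 22), rep(3e8, 22))
  expect_error(h2_excluding_regions(sim$ss1, ld, all_of_it, n_blocks = 20),
               "too few")

  # a block holding half the heritability roughly halves the estimate
  lel <- data.frame(block = 10, share = 0.5)
  cfg_l <- small_config(h2_1 = 0.3, h2_2 = 0.3, large_effect_loci = lel,
                        n1 = 50000, n2 = 50000)
  panel <- build_reference_panel(cfg_l)
  ld_l <- compute_ld_scores(panel)
  drop10 <- panel_block_regions(panel)[10, ]
  class(drop10) <- c("region_set", "data.frame")
  h2_full <- h2_excl <- numeric(12)
  for (r in seq_along(h2_full)) {
    siml <- simulate_sumstats_pair(cfg_l, panel = panel,
                                   effects = simulate_joint_effects(
                                     cfg_l, panel, seed = 40 + r),
                                   seed = 90 + r)
    f_full <- estimate_h2(siml$ss1, ld_l, n_blocks = 20, chisq_max = Inf)
    f_excl <- h2_excluding_regions(siml$ss1, ld_l, drop10, n_blocks = 20,
                                   m_total = f_full$m_total,
                                   chisq_max = Inf)
    h2_full[r] <- f_full$h2_observed$value
    h2_excl[r] <- f_excl$h2_observed$value
  }
  expect_lt(abs(mean(h2_excl) / mean(h2_full) - 0.5), 0.25)
})

test_that("proportion explained is zero without regions and errors on
           non-positive heritability", {
  cfg <- small_config(h2_1 = 0.3, h2_2 = 0.3)
  sim <- simulate_sumstats_pair(cfg)
  ld <- compute_ld_scores(sim$panel)
  pe <- proportion_explained(sim$ss1, ld, region_set(), n_blocks = 20)
  expect_equal(pe$proportion, 0)
})
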