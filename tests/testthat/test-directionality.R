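test_that("Wakefield log Bayes factors match direct evaluation", {
  # z = 0: pure shrinkage term sqrt(se^2 / (se^2 + W))
  expect_equal(wakefield_log_bf(0, 0.1, 0.04), log(sqrt(0.01 / 0.05)),
               tolerance = 1e-12)
  # z = 5 at the same scales: shrinkage times exp(z^2/2 * W/(se^2+W))
  expect_equal(wakefield_log_bf(0.5, 0.1, 0.04),
               log(sqrt(0.2)) + 12.5 * 0.8, tolerance = 1e-12)
  # strictly increasing in |z| at fixed se and W
  zs <- seq(0, 6, by = 0.5)
  bfs <- wakefield_log_bf(zs * 0.1, 0.1, 0.04)
  expect_true(all(diff(bfs) > 0))
  expect_error(wakefield_log_bf(1, 0, 0.04))
})

test_that("block PPA concentrates on truly associated blocks", {
  # all-null input: the prior collapses and nothing passes
  cfg0 <- small_config(h2_1 = 0, h2_2 = 0)
  sim0 <- simulate_sumstats_pair(cfg0)
  bp0 <- block_ppa(sim0$ss1, sim0$panel)
  expect_lt(attr(bp0, "pi"), 1e-4)
  expect_length(attr(bp0, "lead_snps"), 0)

  # one strong association: that block attains PPA >= 0.9 and its lead
  # SNP is the injected one
  ss <- sim0$ss1
  hit <- 550  # inside block 6
  ss$snps$z[hit] <- 8
  ss$snps$p[hit] <- 2 * pnorm(-8)
  bp <- block_ppa(ss, sim0$panel)
  expect_gt(bp$ppa[6], 0.9)
  expect_equal(bp$lead_snp[6], ss$snps$snp_id[hit])
  expect_true(ss$snps$snp_id[hit] %in% attr(bp, "lead_snps"))
})

test_that("greedy pruning keeps the significance-ordered independent set", {
  # hand-built 4-SNP panel with known pairwise correlations
  R <- matrix(c(1, 0.95, 0.2, 0.1,
                0.95, 1, 0.25, 0.1,
                0.2, 0.25, 1, 0.6,
                0.1, 0.1, 0.6, 1), 4, 4)
  panel <- manual_panel(R)
  p <- c(1e-10, 1e-9, 1e-12, 1e-8)
  z <- -qnorm(p / 2)
  ss <- sumstats(data.frame(snp_id = sprintf("rs%07d", 1:4), chrom = 1L,
                            pos = 1:4 * 1000, a1 = "A", a2 = "G",
                            z = z, n = 1e5, eaf = 0.3, p = p))
  kept <- select_pruned(ss, panel, r2_max = 0.1)

  # brute-force trace of the greedy rule
  ord <- order(p)
  brute <- integer(0)
  for (i in ord) {
    if (all(R[i, brute]^2 <= 0.1)) brute <- c(brute, i)
  }
  expect_setequal(kept, sprintf("rs%07d", brute))
  # SNP 3 is most significant; SNP 4 (r2 = 0.36 with 3) must be pruned,
  # SNP 1 beats SNP 2 (r2 ~ 0.9)
  expect_true("rs0000003" %in% kept)
  expect_false("rs0000004" %in% kept)
  expect_false("rs0000002" %in% kept)

  # SNPs in distinct independent blocks are all kept
  cfg <- small_config(h2_1 = 0, h2_2 = 0)
  sim <- simulate_sumstats_pair(cfg)
  ss2 <- sim$ss1
  hits <- c(150, 750, 1350)
  ss2$snps$z[hits] <- 9
  ss2$snps$p[hits] <- 2 * pnorm(-9)
  expect_setequal(select_pruned(ss2, sim$panel),
                  ss2$snps$snp_id[hits])
})

test_that("directional verdicts follow the generating mechanism", {
  d <- make_xy_data(n = 30, alpha = 0.3, seed = 11)
  fit <- fit_directional_models(d$set_x, d$set_y)
  expect_equal(fit$verdict, "xy")
  expect_lt(fit$relative_lr, 0.05)
  expect_equal(fit$alpha_xy, 0.3, tolerance = 0.05)
  expect_false(fit$hetero_flag)

  # swapping trait roles flips the verdict
  swap <- function(s) {
    t <- s
    t$beta_x <- s$beta_y; t$se_x <- s$se_y
    t$beta_y <- s$beta_x; t$se_y <- s$se_x
    t
  }
  fit_sw <- fit_directional_models(swap(d$set_y), swap(d$set_x))
  expect_equal(fit_sw$verdict, "yx")
  expect_equal(fit_sw$loglik[["causal_yx"]], fit$loglik[["causal_xy"]],
               tolerance = 1e-6)

  # independent effects: no directional verdict
  se <- 1 / sqrt(5e4)
  set.seed(3)
  ind_x <- make_aset(runif(30, 0.03, 0.06) * sample(c(-1, 1), 30, TRUE),
                     rnorm(30, 0, se), se, se)
  ind_y <- make_aset(rnorm(30, 0, se),
                     runif(30, 0.03, 0.06) * sample(c(-1, 1), 30, TRUE),
                     se, se)
  fit_ind <- fit_directional_models(ind_x, ind_y)
  expect_equal(fit_ind$verdict, "none")
  expect_gt(fit_ind$relative_lr, 0.05)

  # a shared factor (same ratio in both sets) defeats the causal models
  set.seed(4)
  u1 <- runif(30, 0.03, 0.06) * sample(c(-1, 1), 30, TRUE)
  u2 <- runif(30, 0.03, 0.06) * sample(c(-1, 1), 30, TRUE)
  pl_x <- make_aset(u1 + rnorm(30, 0, se), 0.5 * u1 + rnorm(30, 0, se),
                    se, se)
  pl_y <- make_aset(2 * u2 + rnorm(30, 0, se), u2 + rnorm(30, 0, se),
                    se, se)
  fit_pl <- fit_directional_models(pl_x, pl_y)
  expect_equal(fit_pl$verdict, "none")
  expect_gt(fit_pl$loglik[["noncausal_pleio"]],
            max(fit_pl$loglik[["causal_xy"]], fit_pl$loglik[["causal_yx"]]))

  # empty ascertained sets skip the test with a notice
  expect_message(fit_e <- fit_directional_models(d$set_x, d$set_y[0, ]),
                 "skipped")
  expect_equal(fit_e$verdict, "none")
})

test_that("the heteroscedasticity check flags set-dependent slopes", {
  se_tight <- 0.001
  u1 <- seq(0.03, 0.06, length.out = 20) * rep(c(-1, 1), 10)
  u2 <- seq(0.03, 0.06, length.out = 20) * rep(c(1, -1), 10)
  # identical transmission slopes in both sets: not flagged
  s_x <- make_aset(u1, 2 * u1, se_tight, se_tight)
  s_y <- make_aset(u2, 2 * u2, se_tight, se_tight)
  expect_false(heteroscedasticity_check(s_x, s_y, "xy"))
  # slope 2.0 against slope 0.0 with tight SEs: flagged
  s_y0 <- make_aset(u2, 0 * u2, se_tight, se_tight)
  expect_true(heteroscedasticity_check(s_x, s_y0, "xy"))
  # a degenerate set withholds the verdict
  expect_true(is.na(heteroscedasticity_check(s_x, s_y[0, ], "xy")))
})
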