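test_that("a base-only stratified model reproduces the plain regression", {
  cfg <- small_config(h2_1 = 0.3, h2_2 = 0.3)
  sim <- simulate_sumstats_pair(cfg)
  map <- panel_snp_map(sim$panel)
  ann <- annot_matrix(map$snp_id,
                      matrix(1, nrow(map), 1,
                             dimnames = list(NULL, "base")))
  lds <- compute_stratified_ld_scores(sim$panel, ann)
  plain <- estimate_h2(sim$ss1, lds, n_blocks = 20)
  strat <- stratified_h2(sim$ss1, lds, ann, n_blocks = 20)
  expect_equal(strat$h2_observed$value, plain$h2_observed$value,
               tolerance = 1e-10)
  expect_equal(strat$intercept$value, plain$intercept$value,
               tolerance = 1e-10)
  base_row <- strat$enrichment[strat$enrichment$category == "base", ]
  expect_equal(base_row$enrichment, 1)
  expect_equal(base_row$prop_h2, 1)
})

test_that("collinear annotation columns are rejected with names", {
  cfg <- small_config(h2_1 = 0.3, h2_2 = 0.3)
  sim <- simulate_sumstats_pair(cfg)
  map <- panel_snp_map(sim$panel)
  half <- as.numeric(map$block <= 10)
  dup <- annot_matrix(map$snp_id,
                      cbind(coding = half, coding_copy = half))
  lds <- compute_stratified_ld_scores(sim$panel, dup)
  expect_error(stratified_h2(sim$ss1, lds, dup, n_blocks = 20),
               "collinear")

  # a lone category equal to base is tolerated: the redundant base column
  # is dropped and the category's enrichment is one
  allsnps <- annot_matrix(map$snp_id,
                          cbind(everything = rep(1, nrow(map))))
  ld_all <- compute_stratified_ld_scores(sim$panel, allsnps)
  sf <- suppressMessages(
    stratified_h2(sim$ss1, ld_all, allsnps, n_blocks = 20))
  row <- sf$enrichment[sf$enrichment$category == "everything", ]
  expect_equal(row$enrichment, 1, tolerance = 1e-9)
})

test_that("enriched categories are recovered with calibrated enrichment", {
  # 10% of SNPs carrying ~50% of h2: enrichment ~ 5
  cfg0 <- small_config()
  panel <- build_reference_panel(cfg0)
  map <- panel_snp_map(panel)
  ann <- annot_matrix(map$snp_id,
                      cbind(enriched = as.numeric(map$block <= 2)))
  cfg <- small_config(h2_1 = 0.3, h2_2 = 0.3,
                      annotations = ann,
                      annotation_effects = c(enriched = 9))
  lds <- compute_stratified_ld_scores(panel, ann)
  vals <- ses <- props <- numeric(5)
  for (r in seq_along(vals)) {
    sim <- simulate_sumstats_pair(cfg, panel = panel,
                                  effects = simulate_joint_effects(
                                    cfg, panel, seed = 600 + r),
                                  seed = 700 + r)
    sf <- stratified_h2(sim$ss1, lds, ann, n_blocks = 20)
    row <- sf$enrichment[sf$enrichment$category == "enriched", ]
    vals[r] <- row$enrichment; ses[r] <- row$enrichment_se
    props[r] <- row$prop_h2
  }
  expect_lt(abs(mean(vals) - 5), 2 * mean(ses))
  expect_gt(mean(props), 0.3)
})

test_that("disjoint partitions conserve the heritability shares", {
  cfg0 <- small_config()
  panel <- build_reference_panel(cfg0)
  map <- panel_snp_map(panel)
  part <- cbind(a = as.numeric(map$block <= 7),
                b = as.numeric(map$block > 7 & map$block <= 14),
                c = as.numeric(map$block > 14))
  ann <- annot_matrix(map$snp_id, part)
  cfg <- small_config(h2_1 = 0.25, h2_2 = 0.25)
  sim <- simulate_sumstats_pair(cfg, panel = panel)
  lds <- compute_stratified_ld_scores(panel, ann)
  sf <- suppressMessages(stratified_h2(sim$ss1, lds, ann, n_blocks = 20))
  shares <- sf$enrichment$prop_h2[sf$enrichment$category %in%
                                    c("a", "b", "c")]
  expect_equal(sum(shares), 1, tolerance = 1e-9)
})

test_that("union annotations behave as set unions", {
  am <- annot_matrix(paste0("rs", 1:100),
                     cbind(a = rep(c(1, 0), 50),
                           b = rep(c(0, 1), 50),
                           c = c(rep(1, 30), rep(0, 70))))
  # disjoint union equals the elementwise sum
  u <- union_annotations(am, list(ab = c("a", "b")))
  expect_equal(u$values[, "ab"], am$values[, "a"] + am$values[, "b"])
  # idempotence
  u2 <- union_annotations(am, list(aa = c("a", "a")))
  expect_equal(u2$values[, "aa"], am$values[, "a"])
  # overlapping union matches brute-force set cardinality
  u3 <- union_annotations(am, list(ac = c("a", "c")))
  brute <- as.numeric(am$values[, "a"] > 0 | am$values[, "c"] > 0)
  expect_equal(u3$values[, "ac"], brute)
  expect_equal(sum(u3$values[, "ac"]),
               length(union(which(am$values[, "a"] > 0),
                            which(am$values[, "c"] > 0))))
  expect_error(union_annotations(am, list(bad = "missing")), "unknown")
})

test_that("the cell-type scan ranks the truly enriched candidate first", {
  cfg0 <- small_config()
  panel <- build_reference_panel(cfg0)
  map <- panel_snp_map(panel)
  set.seed(8)
  cand_values <- sapply(1:6, function(i) {
    if (i == 1) as.numeric(map$block <= 2)
    else as.numeric(sample(c(0, 1), nrow(map), TRUE, prob = c(0.9, 0.1)))
  })
  colnames(cand_values) <- paste0("cand_", 1:6)
  ann_cand <- annot_matrix(map$snp_id, cand_values)
  ann_base <- annot_matrix(map$snp_id,
                           cbind(coding = as.numeric(map$block >= 18)))
  cfg <- small_config(h2_1 = 0.3, h2_2 = 0.3,
                      annotations = ann_cand,
                      annotation_effects = c(cand_1 = 9))
  sim <- simulate_sumstats_pair(cfg, panel = panel)
  ld_base <- compute_stratified_ld_scores(panel, ann_base)
  ld_cand <- compute_stratified_ld_scores(panel, ann_cand)
  scan <- cell_type_scan(sim$ss1, ld_base, ann_base, ld_cand, ann_cand,
                         n_blocks = 20)
  expect_equal(attr(scan, "threshold"), 0.05 / 6)
  expect_equal(scan$category[1], "cand_1")

  # candidate duplicating a baseline category hits the collinearity path
  clash <- annot_matrix(map$snp_id,
                        cbind(coding_dup = as.numeric(map$block >= 18)))
  ld_clash <- compute_stratified_ld_scores(panel, clash)
  expect_error(cell_type_scan(sim$ss1, ld_base, ann_base, ld_clash, clash,
                              n_blocks = 20), "collinear")
})

test_that("DerSimonian-Laird pooling matches hand-computed values", {
  # estimates (1, 2) with SEs (0.5, 0.5): Q = 2, tau2 = 0.25,
  # pooled 1.5 with SE 0.5
  mr <- meta_analyze(c(1, 2), c(0.5, 0.5))
  expect_equal(mr$tau2_meta, 0.25, tolerance = 1e-10)
  expect_equal(mr$pooled, 1.5, tolerance = 1e-10)
  expect_equal(mr$se, 0.5, tolerance = 1e-10)
  expect_equal(mr$ci_lower, 1.5 - qnorm(0.975) * 0.5, tolerance = 1e-6)

  # identical estimates: no heterogeneity, pooled equals the input
  mr0 <- meta_analyze(c(1.3, 1.3, 1.3), c(0.2, 0.2, 0.2))
  expect_equal(mr0$tau2_meta, 0)
  expect_equal(mr0$pooled, 1.3)
  # with tau2 = 0 the pooling is fixed-effect inverse variance
  mr_fe <- meta_analyze(c(1.0, 1.1), c(0.2, 0.4))
  if (mr_fe$tau2_meta == 0) {
    w <- c(1 / 0.04, 1 / 0.16)
    expect_equal(mr_fe$pooled, sum(w * c(1.0, 1.1)) / sum(w),
                 tolerance = 1e-10)
  }

  # an imprecise study barely moves the pooled value
  mr_big <- suppressWarnings(meta_analyze(c(1.0, 50), c(0.01, 1e4)))
  expect_equal(mr_big$pooled, 1.0, tolerance = 1e-3)
  expect_error(meta_analyze(1, 0.5), "at least 2")
})
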