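#' Simulation configuration for paired GWAS summary statistics
#'
#' Describes a synthetic study design: a block-structured LD reference panel
#' and two polygenic traits measured in partially overlapping samples.
#' Within each LD block the SNP-SNP correlation is AR(1),
#' `r(i, j) = rho_b^|i-j|`, with the block coefficient `rho_b` drawn
#' uniformly from `ld_rho` (a fixed scalar is also accepted), mimicking the
#' variation of LD strength across the genome.  Blocks are mutually
#' independent and separated by well over 1 Mb in synthetic coordinates so
#' that window-based logic (locus exclusion, LD windows) behaves as it would
#' on real data.
#'
#' For binary traits, `h2_1`/`h2_2` are interpreted on the liability scale
#' and the simulator targets the corresponding observed-scale heritability
#' `h2 / liability_scale_factor(P, F)`, which makes the liability conversion
#' exactly invertible.
#'
#' @param m_snps total number of SNPs M (`n_blocks * block_size`).
#' @param n_blocks,block_size LD block count and SNPs per block.
#' @param ld_rho AR(1) adjacent-SNP correlation: either a single value in
#'   `[0, 1)` used for every block, or a range `c(lo, hi)` from which
#'   per-block coefficients are drawn.
#' @param maf_range range for uniform minor-allele-frequency draws.
#' @param h2_1,h2_2 true SNP-heritabilities in `[0, 1)` (liability scale for
#'   binary traits).
#' @param rg true genetic correlation in `[-1, 1]`.
#' @param n1,n2 study sample sizes.
#' @param n_shared number of overlapping samples (`<= min(n1, n2)`).
#' @param pheno_corr phenotypic correlation among overlapping samples.
#' @param trait_types character vector of length 2, each `"quantitative"`
#'   or `"binary"`.
#' @param sample_prev,population_prev length-2 prevalences (binary traits
#'   only; `NA` for quantitative traits).
#' @param annotations optional [annot_matrix()] aligned to the panel SNPs,
#'   used together with `annotation_effects` to concentrate per-SNP effect
#'   variance in functional categories.
#' @param annotation_effects named numeric vector of per-SNP variance
#'   multipliers for annotation categories (a SNP in a category with
#'   multiplier `m` has `m`-fold the background per-SNP effect variance;
#'   multipliers for overlapping categories act multiplicatively).
#' @param large_effect_loci optional data frame with columns `block` and
#'   `share`: each listed block has the given fraction of every trait's
#'   heritability concentrated on the central SNP of the block, producing a
#'   clumpable genome-wide significant locus.
#' @param trait_names length-2 character labels.
#' @param seed integer root seed; all randomness in the simulator derives
#'   from it.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(m_snps = 20000, n_blocks = 100, block_size = 200,
                       ld_rho = c(0.1, 0.8), maf_range = c(0.05, 0.5),
                       h2_1 = 0.2, h2_2 = 0.2, rg = 0,
                       n1 = 50000, n2 = 50000,
                       n_shared = 0, pheno_corr = 0,
                       trait_types = c("quantitative", "quantitative"),
                       sample_prev = c(NA, NA),
                       population_prev = c(NA, NA),
                       annotations = NULL, annotation_effects = NULL,
                       large_effect_loci = NULL,
                       trait_names = c("trait1", "trait2"),
                       seed = 1) {
  stopifnot(m_snps == n_blocks * block_size)
  if (length(ld_rho) == 1) ld_rho <- c(ld_rho, ld_rho)
  stopifnot(length(ld_rho) == 2, all(ld_rho >= 0))
  if (any(ld_rho >= 1)) stop("ld_rho must be < 1")
  stopifnot(h2_1 >= 0, h2_1 < 1, h2_2 >= 0, h2_2 < 1, abs(rg) <= 1)
  stopifnot(n1 > 0, n2 > 0, n_shared >= 0, n_shared <= min(n1, n2))
  stopifnot(abs(pheno_corr) <= 1)
  stopifnot(length(trait_types) == 2,
            all(trait_types %in% c("quantitative", "binary")))
  for (t in 1:2) {
    if (trait_types[t] == "binary" &&
        (is.na(sample_prev[t]) || is.na(population_prev[t]))) {
      stop("binary trait ", t, " requires sample_prev and population_prev")
    }
  }
  if (!is.null(large_effect_loci)) {
    stopifnot(is.data.frame(large_effect_loci),
              all(c("block", "share") %in% names(large_effect_loci)),
              all(large_effect_loci$block >= 1),
              all(large_effect_loci$block <= n_blocks),
              all(large_effect_loci$share > 0),
              sum(large_effect_loci$share) < 1)
  }
  structure(
    list(m_snps = m_snps, n_blocks = n_blocks, block_size = block_size,
         ld_rho = ld_rho, maf_range = maf_range,
         h2_1 = h2_1, h2_2 = h2_2, rg = rg,
         n1 = n1, n2 = n2, n_shared = n_shared, pheno_corr = pheno_corr,
         trait_types = trait_types, sample_prev = sample_prev,
         population_prev = population_prev,
         annotations = annotations, annotation_effects = annotation_effects,
         large_effect_loci = large_effect_loci,
         trait_names = trait_names, seed = as.integer(seed)),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Simulation config:", x$m_snps, "SNPs in", x$n_blocks,
      "blocks of", x$block_size, "\n")
  cat("  h2 =", x$h2_1, "/", x$h2_2, " rg =", x$rg,
      " N =", x$n1, "/", x$n2, " overlap =", x$n_shared, "\n")
  invisible(x)
}

# Run expr with a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

#' Build a synthetic block-correlation reference panel
#'
#' Creates per-block AR(1) SNP-SNP correlation matrices with SNP ids,
#' chromosome/position coordinates and minor allele frequencies.  Blocks
#' are laid out contiguously across autosomes with large inter-block gaps
#' (> 1 Mb) so that blocks are independent both statistically and spatially.
#'
#' @param config a [sim_config()].
#' @return An object of class `ref_panel`: a list with element `blocks`
#'   (each holding `snp_id`, `chrom`, `pos`, `maf`, `rho`, the correlation
#'   matrix `R` and its lower Cholesky factor `L`) plus layout metadata.
#' @export
build_reference_panel <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  nb <- config$n_blocks
  bs <- config$block_size
  blocks_per_chrom <- ceiling(nb / 22)
  stride <- max(2e6, bs * 1000 + 1.2e6)

  with_seed(config$seed, {
    rhos <- stats::runif(nb, config$ld_rho[1], config$ld_rho[2])
    mafs <- stats::runif(nb * bs, config$maf_range[1], config$maf_range[2])
  })

  blocks <- vector("list", nb)
  for (b in seq_len(nb)) {
    chrom <- as.integer((b - 1) %/% blocks_per_chrom + 1L)
    j <- (b - 1) %% blocks_per_chrom  # block index within chromosome
    pos <- j * stride + 5e5 + (seq_len(bs) - 1) * 1000 + 1
    rho <- rhos[b]
    R <- rho^abs(outer(seq_len(bs), seq_len(bs), "-"))
    L <- if (rho == 0) diag(bs) else t(chol(R))
    idx <- (b - 1) * bs + seq_len(bs)
    blocks[[b]] <- list(
      snp_id = sprintf("rs%07d", idx),
      chrom = chrom, pos = pos,
      maf = mafs[idx], rho = rho, R = R, L = L
    )
  }
  structure(list(blocks = blocks, m_snps = config$m_snps,
                 n_blocks = nb, block_size = bs, seed = config$seed),
            class = "ref_panel")
}

#' @export
print.ref_panel <- function(x, ...) {
  rhos <- vapply(x$blocks, function(b) b$rho, numeric(1))
  cat("Reference panel:", x$m_snps, "SNPs in", x$n_blocks,
      "independent blocks of", x$block_size, "\n")
  cat("  AR(1) coefficients in [", round(min(rhos), 3), ",",
      round(max(rhos), 3), "]\n")
  invisible(x)
}

#' SNP map of a reference panel
#'
#' @param panel a [build_reference_panel()] result.
#' @return Data frame with `snp_id`, `chrom`, `pos`, `maf` and `block`.
#' @export
panel_snp_map <- function(panel) {
  stopifnot(inherits(panel, "ref_panel"))
  out <- lapply(seq_along(panel$blocks), function(b) {
    blk <- panel$blocks[[b]]
    data.frame(snp_id = blk$snp_id, chrom = blk$chrom, pos = blk$pos,
               maf = blk$maf, block = b)
  })
  do.call(rbind, out)
}

#' Region set corresponding to the panel's LD blocks
#'
#' @param panel a [build_reference_panel()] result.
#' @return A [region_set()] with one interval per block.
#' @export
panel_block_regions <- function(panel) {
  stopifnot(inherits(panel, "ref_panel"))
  chrom <- vapply(panel$blocks, function(b) b$chrom, integer(1))
  start <- vapply(panel$blocks, function(b) min(b$pos) - 1, numeric(1))
  end <- vapply(panel$blocks, function(b) max(b$pos), numeric(1))
  region_set(chrom, start, end)
}

# Per-SNP effect-variance weights from annotations and multipliers.
effect_weights <- function(config) {
  m <- config$m_snps
  w <- rep(1, m)
  if (!is.null(config$annotations) && !is.null(config$annotation_effects)) {
    ann <- config$annotations
    eff <- config$annotation_effects
    unknown <- setdiff(names(eff), colnames(ann$values))
    if (length(unknown) > 0) {
      stop("annotation_effects for unknown categories: ",
           paste(unknown, collapse = ", "))
    }
    if (length(ann$snp_id) != m) {
      stop("annotations must cover every panel SNP")
    }
    for (cat in names(eff)) {
      w <- w * eff[[cat]]^ann$values[, cat]
    }
  }
  w
}

# Observed-scale heritability targets (inverts the liability conversion
# for binary traits).
observed_h2_targets <- function(config) {
  h2 <- c(config$h2_1, config$h2_2)
  for (t in 1:2) {
    if (config$trait_types[t] == "binary") {
      h2[t] <- h2[t] / liability_scale_factor(config$sample_prev[t],
                                              config$population_prev[t])
    }
  }
  h2
}

#' Simulate true standardized effect sizes for a trait pair
#'
#' Draws per-SNP standardized effects `(alpha_j, beta_j)` from a bivariate
#' normal with per-SNP variances allocated so that the expected sums equal
#' the observed-scale heritability targets, and cross-trait correlation
#' equal to the true genetic correlation.  Blocks listed in
#' `large_effect_loci` have their stated heritability share placed as a
#' fixed-magnitude effect on the central SNP of the block (random sign,
#' with signs coupled across traits according to `rg`).
#'
#' @param config a [sim_config()].
#' @param panel a matching [build_reference_panel()] (used for layout
#'   checks only).
#' @param seed RNG seed; defaults to `config$seed + 1`.
#' @return A list with per-SNP effect vectors `alpha`, `beta`, variance
#'   vectors `v1`, `v2`, the observed-scale targets `h2_obs`, and
#'   `large_idx` (indices of large-effect SNPs, possibly empty).
#' @export
simulate_joint_effects <- function(config, panel, seed = config$seed + 1) {
  stopifnot(inherits(config, "sim_config"), inherits(panel, "ref_panel"))
  stopifnot(panel$m_snps == config$m_snps)
  m <- config$m_snps
  h2_obs <- observed_h2_targets(config)
  rg <- config$rg

  w <- effect_weights(config)
  large_idx <- integer(0)
  large_share <- numeric(0)
  if (!is.null(config$large_effect_loci)) {
    lel <- config$large_effect_loci
    # random position within the block: concentrated effects then sit at
    # typical LD-score positions on average, so their heritability is
    # attributed without placement-driven leverage bias
    offs <- with_seed(seed + 7919L,
                      sample.int(config$block_size, nrow(lel),
                                 replace = TRUE))
    large_idx <- (lel$block - 1) * config$block_size + offs
    large_share <- lel$share
  }
  bg <- setdiff(seq_len(m), large_idx)
  bg_share <- 1 - sum(large_share)
  v1 <- v2 <- numeric(m)
  v1[bg] <- bg_share * h2_obs[1] * w[bg] / sum(w[bg])
  v2[bg] <- bg_share * h2_obs[2] * w[bg] / sum(w[bg])

  with_seed(seed, {
    a <- stats::rnorm(m)
    b <- stats::rnorm(m)
    alpha <- sqrt(v1) * a
    beta <- sqrt(v2) * (rg * a + sqrt(max(0, 1 - rg^2)) * b)
    if (length(large_idx) > 0) {
      s1 <- sample(c(-1, 1), length(large_idx), replace = TRUE)
      flip <- stats::runif(length(large_idx)) < (1 - rg) / 2
      s2 <- ifelse(flip, -s1, s1)
      alpha[large_idx] <- s1 * sqrt(large_share * h2_obs[1])
      beta[large_idx] <- s2 * sqrt(large_share * h2_obs[2])
      v1[large_idx] <- large_share * h2_obs[1]
      v2[large_idx] <- large_share * h2_obs[2]
    }
  })
  list(alpha = alpha, beta = beta, v1 = v1, v2 = v2,
       h2_obs = h2_obs, large_idx = large_idx)
}

#' Simulate a pair of GWAS summary-statistic tables
#'
#' Generates Z-scores directly at the summary level: within each LD block,
#' `z = sqrt(N) * R alpha + e` with `e ~ N(0, R)`, and the noise of the two
#' studies correlated per SNP by `n_shared * pheno_corr / sqrt(n1 * n2)`
#' (the cross-trait regression intercept).  Alleles are drawn from
#' strand-unambiguous pairs and effect-allele frequencies from the panel
#' MAFs, so the tables pass all package validators unchanged.
#'
#' @param config a [sim_config()].
#' @param panel optional pre-built [build_reference_panel()].
#' @param effects optional pre-drawn [simulate_joint_effects()] result.
#' @param seed RNG seed for the noise and allele draws; defaults to
#'   `config$seed + 2`.
#' @return A list with elements `ss1`, `ss2` (two [sumstats()] objects),
#'   `truth` (a manifest of every true quantity the estimators aim to
#'   recover), `effects`, and `panel`.
#' @export
simulate_sumstats_pair <- function(config, panel = NULL, effects = NULL,
                                   seed = config$seed + 2) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(panel)) panel <- build_reference_panel(config)
  if (is.null(effects)) effects <- simulate_joint_effects(config, panel)
  m <- config$m_snps
  bs <- config$block_size
  rho_ov <- config$n_shared * config$pheno_corr / sqrt(config$n1 * config$n2)

  z1 <- z2 <- numeric(m)
  with_seed(seed, {
    for (b in seq_len(config$n_blocks)) {
      blk <- panel$blocks[[b]]
      idx <- (b - 1) * bs + seq_len(bs)
      mu1 <- sqrt(config$n1) * drop(blk$R %*% effects$alpha[idx])
      mu2 <- sqrt(config$n2) * drop(blk$R %*% effects$beta[idx])
      eta1 <- stats::rnorm(bs)
      eta2 <- stats::rnorm(bs)
      e1 <- drop(blk$L %*% eta1)
      e2 <- drop(blk$L %*% (rho_ov * eta1 + sqrt(1 - rho_ov^2) * eta2))
      z1[idx] <- mu1 + e1
      z2[idx] <- mu2 + e2
    }
    # strand-unambiguous allele pairs and effect-allele orientation
    pairs <- rbind(c("A", "G"), c("A", "C"), c("T", "G"), c("T", "C"),
                   c("G", "A"), c("C", "A"), c("G", "T"), c("C", "T"))
    pick <- sample(nrow(pairs), m, replace = TRUE)
    flip_eaf <- stats::runif(m) < 0.5
  })

  map <- panel_snp_map(panel)
  eaf <- ifelse(flip_eaf, 1 - map$maf, map$maf)

  make_ss <- function(z, n, t) {
    df <- data.frame(snp_id = map$snp_id, chrom = map$chrom, pos = map$pos,
                     a1 = pairs[pick, 1], a2 = pairs[pick, 2],
                     z = z, n = n, eaf = eaf,
                     p = 2 * stats::pnorm(-abs(z)))
    sumstats(df, trait_name = config$trait_names[t],
             trait_type = config$trait_types[t],
             sample_prev = if (config$trait_types[t] == "binary")
               config$sample_prev[t] else NULL,
             population_prev = if (config$trait_types[t] == "binary")
               config$population_prev[t] else NULL)
  }
  ss1 <- make_ss(z1, config$n1, 1)
  ss2 <- make_ss(z2, config$n2, 2)

  block_id <- rep(seq_len(config$n_blocks), each = bs)
  truth <- list(
    h2_input = c(config$h2_1, config$h2_2),
    h2_obs = effects$h2_obs,
    trait_types = config$trait_types,
    sample_prev = config$sample_prev,
    population_prev = config$population_prev,
    rg = config$rg,
    rho_obs = config$rg * sqrt(effects$h2_obs[1] * effects$h2_obs[2]),
    gcov_intercept = rho_ov,
    realized_h2_1 = sum(effects$alpha^2),
    realized_h2_2 = sum(effects$beta^2),
    block_h2_1 = as.numeric(tapply(effects$alpha^2, block_id, sum)),
    block_h2_2 = as.numeric(tapply(effects$beta^2, block_id, sum)),
    large_idx = effects$large_idx,
    large_share = if (is.null(config$large_effect_loci)) numeric(0)
                  else config$large_effect_loci$share,
    seed = seed
  )
  list(ss1 = ss1, ss2 = ss2, truth = truth, effects = effects, panel = panel)
}

#' Write a simulation truth manifest as JSON
#'
#' @param truth the `truth` element of [simulate_sumstats_pair()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_truth_manifest <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(path)
}
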