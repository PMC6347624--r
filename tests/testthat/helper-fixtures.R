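# Shared fixtures: built in code at test time, cached per session.

withr_tempfile <- function() tempfile(fileext = ".tsv")

# Small hand-written summary-statistic table.
toy_snps <- function() {
  data.frame(
    snp_id = paste0("rs", 1:6),
    chrom = c(1L, 1L, 1L, 2L, 2L, 6L),
    pos = c(1000, 2000, 3000, 1000, 2000, 26e6),
    a1 = c("A", "G", "A", "C", "T", "A"),
    a2 = c("G", "A", "C", "A", "G", "C"),
    z = c(1.2, -0.5, 2.0, 0.3, -1.1, 0.8),
    n = rep(10000, 6),
    eaf = c(0.3, 0.6, 0.45, 0.2, 0.8, 0.5)
  )
}

toy_sumstats <- function(...) {
  sumstats(toy_snps(), trait_name = "toy", ...)
}

# Small simulation scale used by most tests (fast: ~0.1 s per replicate).
small_config <- function(...) {
  args <- utils::modifyList(
    list(m_snps = 2000, n_blocks = 20, block_size = 100,
         n1 = 20000, n2 = 20000, seed = 101),
    list(...)
  )
  do.call(sim_config, args)
}

# Default-scale panel and LD scores, built once per test session.
.fixture_cache <- new.env(parent = emptyenv())

default_panel <- function() {
  if (is.null(.fixture_cache$panel)) {
    cfg <- sim_config(seed = 99)
    .fixture_cache$cfg <- cfg
    .fixture_cache$panel <- build_reference_panel(cfg)
    .fixture_cache$ld <- compute_ld_scores(.fixture_cache$panel)
  }
  .fixture_cache$panel
}

default_ld <- function() {
  default_panel()
  .fixture_cache$ld
}

default_cfg <- function(...) {
  args <- utils::modifyList(list(seed = 99), list(...))
  do.call(sim_config, args)
}

# Hand-built single-block reference panel from an explicit correlation
# matrix (used for brute-force oracles).
manual_panel <- function(R, pos = NULL, chrom = 1L, maf = NULL) {
  n <- nrow(R)
  if (is.null(pos)) pos <- seq_len(n) * 1000
  if (is.null(maf)) maf <- rep(0.3, n)
  blk <- list(snp_id = sprintf("rs%07d", seq_len(n)), chrom = chrom,
              pos = pos, maf = maf, rho = NA_real_, R = R,
              L = t(chol(R)))
  structure(list(blocks = list(blk), m_snps = n, n_blocks = 1L,
                 block_size = n, seed = 0L),
            class = "ref_panel")
}

# Ascertained-set builder for directionality tests.
make_aset <- function(beta_x, beta_y, se_x, se_y, trait = "X") {
  out <- data.frame(snp_id = paste0("s", seq_along(beta_x)),
                    beta_x = beta_x, se_x = se_x,
                    beta_y = beta_y, se_y = se_y)
  attr(out, "trait") <- trait
  attr(out, "method") <- "pruned"
  class(out) <- c("ascertained_set", "data.frame")
  out
}

# Canonical X->Y directional data: transmitted effects with slope `alpha`
# among X-ascertained SNPs, Y-specific effects among Y-ascertained SNPs.
make_xy_data <- function(n = 30, alpha = 0.3, n_obs = 5e4, seed = 1) {
  se <- 1 / sqrt(n_obs)
  withr_seed <- function(expr) {
    old <- if (exists(".Random.seed", envir = .GlobalEnv)) {
      get(".Random.seed", envir = .GlobalEnv)
    } else {
      NULL
    }
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    set.seed(seed)
    expr
  }
  withr_seed({
    bx <- sample(c(-1, 1), n, TRUE) * runif(n, 0.03, 0.06)
    by_spec <- sample(c(-1, 1), n, TRUE) * runif(n, 0.03, 0.06)
    list(
      set_x = make_aset(bx + rnorm(n, 0, se), alpha * bx + rnorm(n, 0, se),
                        se, se, trait = "X"),
      set_y = make_aset(rnorm(n, 0, se), by_spec + rnorm(n, 0, se),
                        se, se, trait = "Y")
    )
  })
}
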