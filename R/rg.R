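#' Cross-trait LD score regression (genetic covariance)
#'
#' Fits the cross-trait regression
#' `E[z1_j z2_j] = (sqrt(N1 N2) rho_g / M) l_j + Ns r / sqrt(N1 N2)`
#' by weighted least squares of the Z-score products on
#' `sqrt(N1_j N2_j) l_j / M` with a free intercept.  The slope estimates
#' the genetic covariance `rho_g`; the intercept estimates the
#' sample-overlap term `Ns r / sqrt(N1 N2)` (Ns overlapping samples with
#' phenotypic correlation r) and is zero for disjoint studies without
#' confounding.  Per-trait heritabilities are fitted first on the same SNP
#' intersection and block scheme, both to build the product-regression
#' weights and to normalize the covariance into a correlation.  When the
#' two tables are the same study, the product regression is exactly the
#' chi-square regression and the single-trait fit is returned as the slope
#' and intercept.
#'
#' @param ss1,ss2 [sumstats()] objects harmonized to a shared reference.
#' @param ld an `ldscore_table`.
#' @param m_total regression denominator M; defaults to `nrow(ld)`.
#' @param n_blocks jackknife blocks (default 200).
#' @param n_iter weight-update iterations.
#' @return An object of class `ldsc_gcov` with [estimate_with_error()]
#'   elements `rho_g` and `gcov_intercept`, the two single-trait fits
#'   `h2_fit1`, `h2_fit2`, and bookkeeping fields.
#' @export
estimate_genetic_covariance <- function(ss1, ss2, ld, m_total = NULL,
                                        n_blocks = 200, n_iter = 2,
                                        chisq_max = NULL) {
  stopifnot(inherits(ss1, "sumstats"), inherits(ss2, "sumstats"))
  if (is.null(m_total)) m_total <- nrow(ld)
  common <- intersect(intersect(ss1$snps$snp_id, ss2$snps$snp_id),
                      ld$snp_id)
  if (length(common) == 0) {
    stop("no SNPs shared between the two studies and the LD scores")
  }
  # outlier cap applied jointly so both traits share one SNP set
  i1 <- match(common, ss1$snps$snp_id)
  i2 <- match(common, ss2$snps$snp_id)
  if (is.null(chisq_max)) {
    chisq_max <- max(80, 0.001 * mean(c(ss1$snps$n[i1], ss2$snps$n[i2])))
  }
  ok <- ss1$snps$z[i1]^2 <= chisq_max & ss2$snps$z[i2]^2 <= chisq_max
  common <- common[ok]
  ld_sub <- ld[ld$snp_id %in% common, , drop = FALSE]
  class(ld_sub) <- class(ld)
  fit1 <- estimate_h2(ss1, ld_sub, m_total = m_total, n_blocks = n_blocks,
                      n_iter = n_iter, chisq_max = Inf)
  fit2 <- estimate_h2(ss2, ld_sub, m_total = m_total, n_blocks = n_blocks,
                      n_iter = n_iter, chisq_max = Inf)
  d1 <- fit1$data
  d2 <- fit2$data
  stopifnot(identical(d1$snp_id, d2$snp_id))

  self_pair <- isTRUE(all.equal(d1$z, d2$z)) && isTRUE(all.equal(d1$n, d2$n))
  if (self_pair) {
    rho <- fit1$h2_observed
    icpt <- fit1$intercept
  } else {
    y <- d1$z * d2$z
    x <- sqrt(d1$n * d2$n) * d1$l / m_total
    X <- cbind(slope = x, intercept = 1)
    block_id <- fit1$block_id
    w <- rep(1, length(y))
    fit <- wls_jackknife(y, X, w, block_id)
    for (i in seq_len(n_iter)) {
      w <- ldsc_weights_gcov(d1$l, mean(d1$n), mean(d2$n), m_total,
                             fit1$h2_observed$value, fit2$h2_observed$value,
                             fit$coef[["slope"]], fit$coef[["intercept"]])
      fit <- wls_jackknife(y, X, w, block_id)
    }
    rho <- estimate_with_error(fit$coef[["slope"]], fit$delete[, "slope"])
    icpt <- estimate_with_error(fit$coef[["intercept"]],
                                fit$delete[, "intercept"])
  }
  structure(
    list(rho_g = rho, gcov_intercept = icpt,
         h2_fit1 = fit1, h2_fit2 = fit2,
         trait_names = c(ss1$trait_name, ss2$trait_name),
         m_snps_used = length(common), m_total = m_total,
         n_blocks = n_blocks, self_pair = self_pair),
    class = "ldsc_gcov"
  )
}

#' @export
print.ldsc_gcov <- function(x, digits = 4, ...) {
  cat("Cross-trait LD score regression: ",
      paste(x$trait_names, collapse = " ~ "), "\n", sep = "")
  cat("  genetic covariance rho_g: ", signif(x$rho_g$value, digits),
      " (se ", signif(x$rho_g$se, digits), ")\n", sep = "")
  cat("  overlap intercept:        ", signif(x$gcov_intercept$value, digits),
      " (se ", signif(x$gcov_intercept$se, digits), ")\n", sep = "")
  invisible(x)
}

#' Genetic correlation from a covariance fit
#'
#' Normalizes the genetic covariance by the two heritabilities,
#' `rg = rho_g / sqrt(h2_1 * h2_2)`, with a jackknife standard error on the
#' ratio (the delete-block ratio is formed from the paired delete values of
#' the covariance and both heritabilities, which share a block scheme by
#' construction).  A trait regressed on itself gives `rg = 1` with zero
#' jackknife spread.  Estimates outside `[-1, 1]` are not clipped but are
#' flagged.
#'
#' @param gcov an `ldsc_gcov` from [estimate_genetic_covariance()].
#' @return An object of class `ldsc_rg` with `rg`, `rho_g`,
#'   `gcov_intercept`, the per-trait h2 estimates, and an `out_of_range`
#'   flag.
#' @export
genetic_correlation <- function(gcov) {
  stopifnot(inherits(gcov, "ldsc_gcov"))
  h1 <- gcov$h2_fit1$h2_observed
  h2 <- gcov$h2_fit2$h2_observed
  if (h1$value <= 0 || h2$value <= 0) {
    stop("non-positive heritability estimate (",
         signif(h1$value, 3), ", ", signif(h2$value, 3),
         "): genetic correlation is undefined")
  }
  rg_value <- gcov$rho_g$value / sqrt(h1$value * h2$value)
  d_h1 <- h1$delete_values
  d_h2 <- h2$delete_values
  if (any(d_h1 <= 0) || any(d_h2 <= 0)) {
    warning("non-positive delete-block heritability values; ",
            "jackknife ratios use a small positive floor")
    d_h1 <- pmax(d_h1, 1e-12)
    d_h2 <- pmax(d_h2, 1e-12)
  }
  d_rg <- gcov$rho_g$delete_values / sqrt(d_h1 * d_h2)
  rg <- estimate_with_error(rg_value, d_rg)
  out_of_range <- abs(rg_value) > 1
  if (out_of_range) {
    warning("genetic correlation estimate outside [-1, 1]: ",
            signif(rg_value, 4))
  }
  structure(
    list(rg = rg, rho_g = gcov$rho_g, gcov_intercept = gcov$gcov_intercept,
         h2_1 = h1, h2_2 = h2, trait_names = gcov$trait_names,
         n_blocks = gcov$n_blocks, m_snps_used = gcov$m_snps_used,
         out_of_range = out_of_range),
    class = "ldsc_rg"
  )
}

#' @export
print.ldsc_rg <- function(x, digits = 4, ...) {
  cat("Genetic correlation: ", paste(x$trait_names, collapse = " ~ "),
      "\n", sep = "")
  cat("  rg = ", signif(x$rg$value, digits),
      " (se ", signif(x$rg$se, digits),
      ", p ", signif(x$rg$p, 3), ")",
      if (x$out_of_range) "  [outside [-1, 1]]" else "", "\n", sep = "")
  cat("  rho_g = ", signif(x$rho_g$value, digits),
      ", intercept = ", signif(x$gcov_intercept$value, digits), "\n",
      sep = "")
  invisible(x)
}

#' @export
coef.ldsc_rg <- function(object, ...) {
  c(rg = object$rg$value, rho_g = object$rho_g$value,
    gcov_intercept = object$gcov_intercept$value)
}

#' Test whether two genetic correlations differ
#'
#' Two-sided normal test of `rg_a - rg_b`,
#' `z = (rg_a - rg_b) / sqrt(se_a^2 + se_b^2 - 2 cov_ab)`, used for
#' subtype comparisons (e.g. whether a cancer is more strongly correlated
#' with one disease subtype than another).  When both results share a
#' jackknife block scheme the covariance of the two estimates is taken
#' from their paired delete-block values; otherwise it is set to zero with
#' a warning.
#'
#' @param res_a,res_b `ldsc_rg` objects.
#' @return List with `estimate` (the difference), `se`, `z`, `p_difference`
#'   and the covariance used.
#' @export
rg_difference_test <- function(res_a, res_b) {
  stopifnot(inherits(res_a, "ldsc_rg"), inherits(res_b, "ldsc_rg"))
  se_a <- res_a$rg$se
  se_b <- res_b$rg$se
  stopifnot(se_a > 0 || res_a$rg$value == res_b$rg$value,
            se_b > 0 || res_a$rg$value == res_b$rg$value)
  d_a <- res_a$rg$delete_values
  d_b <- res_b$rg$delete_values
  if (length(d_a) == length(d_b)) {
    cov_ab <- jackknife_cov(d_a, d_b)
  } else {
    warning("mismatched jackknife block schemes; assuming zero covariance")
    cov_ab <- 0
  }
  diff <- res_a$rg$value - res_b$rg$value
  v <- se_a^2 + se_b^2 - 2 * cov_ab
  if (diff == 0) {
    return(list(estimate = 0, se = sqrt(max(v, 0)), z = 0,
                p_difference = 1, cov_ab = cov_ab))
  }
  if (v <= 0) stop("non-positive variance of the rg difference")
  z <- diff / sqrt(v)
  list(estimate = diff, se = sqrt(v), z = z,
       p_difference = 2 * stats::pnorm(-abs(z)), cov_ab = cov_ab)
}

#' Bonferroni significance threshold
#'
#' @param n_tests number of tests (>= 1).
#' @param alpha family-wise error rate (default 0.05).
#' @return `alpha / n_tests` (e.g. 0.05/15 for 15 trait pairs,
#'   0.05/1703 for a 1703-region local scan).
#' @export
significance_threshold <- function(n_tests, alpha = 0.05) {
  if (!is.numeric(n_tests) || length(n_tests) != 1 || n_tests < 1 ||
      n_tests != round(n_tests)) {
    stop("n_tests must be a positive integer")
  }
  alpha / n_tests
}

#' Pairwise genetic-correlation matrix
#'
#' Runs [estimate_genetic_covariance()] and [genetic_correlation()] for
#' every unordered pair of traits and flags Bonferroni-significant pairs at
#' `alpha / n_pairs`.
#'
#' @param ss_list named list of [sumstats()] objects.
#' @param ld an `ldscore_table`.
#' @param m_total,n_blocks passed to the pair fits.
#' @param alpha family-wise error rate for the Bonferroni flag.
#' @return Data frame with one row per pair (trait_a, trait_b, rho_g, se,
#'   rg, se, p, intercept, significant); the fitted `ldsc_rg` objects are
#'   attached as attribute `fits`.
#' @export
rg_matrix <- function(ss_list, ld, m_total = NULL, n_blocks = 200,
                      alpha = 0.05) {
  stopifnot(length(ss_list) >= 2)
  nm <- names(ss_list)
  if (is.null(nm)) nm <- vapply(ss_list, function(s) s$trait_name, "")
  pairs <- utils::combn(length(ss_list), 2)
  thr <- significance_threshold(ncol(pairs), alpha)
  fits <- vector("list", ncol(pairs))
  rows <- vector("list", ncol(pairs))
  for (k in seq_len(ncol(pairs))) {
    i <- pairs[1, k]; j <- pairs[2, k]
    gc <- estimate_genetic_covariance(ss_list[[i]], ss_list[[j]], ld,
                                      m_total = m_total,
                                      n_blocks = n_blocks)
    rg <- genetic_correlation(gc)
    fits[[k]] <- rg
    rows[[k]] <- data.frame(
      trait_a = nm[i], trait_b = nm[j],
      rho_g = rg$rho_g$value, rho_g_se = rg$rho_g$se,
      rg = rg$rg$value, rg_se = rg$rg$se, p = rg$rg$p,
      intercept = rg$gcov_intercept$value,
      significant = !is.na(rg$rg$p) & rg$rg$p < thr
    )
  }
  out <- do.call(rbind, rows)
  attr(out, "threshold") <- thr
  attr(out, "fits") <- fits
  out
}
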