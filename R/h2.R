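#' Estimate SNP-heritability by LD score regression
#'
#' Fits the LD score regression `E[chi2_j] = (N_j h2 / M) l_j + 1` by
#' weighted least squares of the per-SNP chi-square statistics on
#' `x_j = N_j l_j / M` with a free intercept: the slope estimates the
#' observed-scale SNP-heritability and the intercept captures confounding
#' inflation (its null value is 1).  Weights combine the heteroscedasticity
#' and LD-overcounting corrections
#' `w_j = 1 / (max(l_j, 1) * (1 + N h2 l_j / M)^2)` and are refined over
#' `n_iter` iterations from an unweighted start.  Standard errors come from
#' a delete-one-block jackknife over `n_blocks` contiguous equal-count SNP
#' blocks.
#'
#' For binary traits carrying prevalences, the liability-scale estimate is
#' attached via [observed_to_liability()].
#'
#' @param ss a [sumstats()] object.
#' @param ld an `ldscore_table` from [compute_ld_scores()].
#' @param m_total total SNP count M used as the regression denominator;
#'   defaults to the number of SNPs in `ld`.
#' @param n_blocks number of jackknife blocks (default 200).
#' @param n_iter weight-update iterations (default 2).
#' @param chisq_max SNPs with chi-square above this are excluded from the
#'   regression (outlying hits violate the polygenic regression model and
#'   inflate the slope).  Default `max(80, 0.001 * mean(N))`, the cap used
#'   by standard LD score regression software; set `Inf` to disable.
#' @return An object of class `ldsc_h2` with elements `h2_observed`,
#'   `intercept` (both [estimate_with_error()] objects), `h2_liability`
#'   (binary traits only), `mean_chi2`, `m_snps_used`, `m_total`, the
#'   final `weights`, and the merged per-SNP `data` with its jackknife
#'   `block_id`.
#' @examples
#' cfg <- sim_config(m_snps = 2000, n_blocks = 20, block_size = 100,
#'                   h2_1 = 0.3, n1 = 20000, seed = 7)
#' sim <- simulate_sumstats_pair(cfg)
#' ld <- compute_ld_scores(sim$panel)
#' fit <- estimate_h2(sim$ss1, ld, n_blocks = 20)
#' coef(fit)
#' @export
estimate_h2 <- function(ss, ld, m_total = NULL, n_blocks = 200, n_iter = 2,
                        chisq_max = NULL) {
  stopifnot(inherits(ss, "sumstats"))
  dat <- merge_ss_ld(ss, ld)
  if (is.null(m_total)) m_total <- nrow(ld)
  if (is.null(chisq_max)) chisq_max <- max(80, 0.001 * mean(dat$n))
  dat <- dat[dat$z^2 <= chisq_max, , drop = FALSE]
  n <- nrow(dat)
  if (n < 2 * n_blocks) {
    stop("need at least ", 2 * n_blocks, " SNPs for ", n_blocks,
         " jackknife blocks; have ", n)
  }
  if (stats::sd(dat$l) < 1e-12) {
    stop("constant LD scores: heritability slope is not identifiable")
  }
  chi2 <- dat$z^2
  x <- dat$n * dat$l / m_total
  X <- cbind(slope = x, intercept = 1)
  block_id <- assign_blocks(n, n_blocks)
  n_bar <- mean(dat$n)

  w <- rep(1, n)
  fit <- wls_jackknife(chi2, X, w, block_id)
  for (i in seq_len(n_iter)) {
    w <- ldsc_weights_h2(dat$l, n_bar, m_total, fit$coef["slope"])
    fit <- wls_jackknife(chi2, X, w, block_id)
  }

  h2_obs <- estimate_with_error(fit$coef[["slope"]], fit$delete[, "slope"])
  icpt <- estimate_with_error(fit$coef[["intercept"]],
                              fit$delete[, "intercept"])
  h2_liab <- NULL
  if (ss$trait_type == "binary") {
    h2_liab <- observed_to_liability(h2_obs, ss$sample_prev,
                                     ss$population_prev)
  }
  structure(
    list(h2_observed = h2_obs, intercept = icpt, h2_liability = h2_liab,
         mean_chi2 = mean(chi2), m_snps_used = n, m_total = m_total,
         n_blocks = n_blocks, trait_name = ss$trait_name,
         trait_type = ss$trait_type, weights = w, data = dat,
         block_id = block_id, n_bar = n_bar, chisq_max = chisq_max),
    class = "ldsc_h2"
  )
}

# Inner join of a sumstats table with an LD score table, preserving
# (chromosome, position) order.
merge_ss_ld <- function(ss, ld) {
  stopifnot(inherits(ld, "ldscore_table") || is.data.frame(ld))
  idx <- match(ss$snps$snp_id, ld$snp_id)
  keep <- !is.na(idx)
  if (!any(keep)) stop("no SNPs shared between summary statistics and LD scores")
  dat <- ss$snps[keep, c("snp_id", "chrom", "pos", "z", "n")]
  dat$l <- ld_total(ld)[idx[keep]]
  dat <- dat[order(dat$chrom, dat$pos), ]
  rownames(dat) <- NULL
  dat
}

#' @export
print.ldsc_h2 <- function(x, digits = 4, ...) {
  cat("LD score regression heritability (", x$trait_name, ")\n", sep = "")
  cat("  h2 (observed):  ", signif(x$h2_observed$value, digits),
      " (se ", signif(x$h2_observed$se, digits), ")\n", sep = "")
  if (!is.null(x$h2_liability)) {
    cat("  h2 (liability): ", signif(x$h2_liability$value, digits),
        " (se ", signif(x$h2_liability$se, digits), ")\n", sep = "")
  }
  cat("  intercept:      ", signif(x$intercept$value, digits),
      " (se ", signif(x$intercept$se, digits), ")\n", sep = "")
  cat("  mean chi2 ", signif(x$mean_chi2, digits),
      ", SNPs used ", x$m_snps_used, " of M = ", x$m_total, "\n", sep = "")
  invisible(x)
}

#' @export
coef.ldsc_h2 <- function(object, ...) {
  c(h2_observed = object$h2_observed$value,
    intercept = object$intercept$value)
}

#' @export
summary.ldsc_h2 <- function(object, ...) {
  rows <- list(h2_observed = object$h2_observed,
               intercept = object$intercept)
  if (!is.null(object$h2_liability)) rows$h2_liability <- object$h2_liability
  tab <- do.call(rbind, lapply(rows, function(e) {
    data.frame(estimate = e$value, se = e$se, z = e$z, p = e$p)
  }))
  structure(list(table = tab, trait = object$trait_name,
                 mean_chi2 = object$mean_chi2,
                 m_snps_used = object$m_snps_used,
                 m_total = object$m_total),
            class = "summary.ldsc_h2")
}

#' @export
print.summary.ldsc_h2 <- function(x, ...) {
  cat("Trait:", x$trait, "  SNPs:", x$m_snps_used, "of M =", x$m_total,
      "  mean chi2:", round(x$mean_chi2, 4), "\n")
  print(signif(x$table, 4))
  invisible(x)
}

#' @export
confint.ldsc_h2 <- function(object, parm = "h2_observed", level = 0.95, ...) {
  e <- object[[parm]]
  zq <- stats::qnorm(1 - (1 - level) / 2)
  out <- matrix(c(e$value - zq * e$se, e$value + zq * e$se), 1, 2,
                dimnames = list(parm, sprintf("%.1f %%",
                                              c((1 - level) / 2,
                                                1 - (1 - level) / 2) * 100)))
  out
}

#' Liability-scale conversion factor
#'
#' Multiplier taking observed-scale (0/1 disease indicator) heritability to
#' the liability scale for a case-control study with sample prevalence `P`
#' and population prevalence `F`:
#' `c = [F(1-F) / phi(Phi^-1(F))^2] * [F(1-F) / (P(1-P))]`,
#' where `phi` and `Phi^-1` are the standard normal density and quantile.
#'
#' @param P sample prevalence in (0, 1).
#' @param F_pop population prevalence in (0, 1).
#' @return The scalar conversion factor (equals `pi/2` when `P = F = 0.5`).
#' @export
liability_scale_factor <- function(P, F_pop) {
  if (!(P > 0 && P < 1 && F_pop > 0 && F_pop < 1)) {
    stop("prevalences must lie in (0, 1)")
  }
  num <- F_pop * (1 - F_pop)
  num / stats::dnorm(stats::qnorm(F_pop))^2 * num / (P * (1 - P))
}

#' Convert an observed-scale heritability estimate to the liability scale
#'
#' Multiplies the estimate, its standard error and every jackknife
#' delete-block value by [liability_scale_factor()]; the conversion is
#' strictly increasing in the observed-scale value.
#'
#' @param h2_obs an [estimate_with_error()] (or a bare numeric value).
#' @param P sample prevalence in (0, 1).
#' @param F_pop population prevalence in (0, 1).
#' @return An `ldsc_est` on the liability scale (or a numeric value if the
#'   input was numeric).
#' @export
observed_to_liability <- function(h2_obs, P, F_pop) {
  fac <- liability_scale_factor(P, F_pop)
  if (is.numeric(h2_obs)) return(h2_obs * fac)
  stopifnot(inherits(h2_obs, "ldsc_est"))
  estimate_with_error(h2_obs$value * fac, h2_obs$delete_values * fac)
}

#' Greedy clumping of genome-wide significant loci
#'
#' Repeatedly takes the most significant remaining SNP with
#' `p < p_threshold`, emits the interval `pos +/- window_bp` (clipped at
#' zero), removes all SNPs inside it, and continues until no significant
#' SNP remains.  P-values are taken from the table or derived from Z as
#' `2 * (1 - Phi(|z|))`.
#'
#' @param ss a [sumstats()] object.
#' @param p_threshold genome-wide significance threshold (default 5e-8).
#' @param window_bp exclusion radius around each index SNP (default 500 kb).
#' @return A merged, sorted [region_set()] (possibly empty).
#' @export
clump_loci <- function(ss, p_threshold = 5e-8, window_bp = 5e5) {
  stopifnot(inherits(ss, "sumstats"))
  s <- ss$snps
  p <- ifelse(is.na(s$p), 2 * stats::pnorm(-abs(s$z)), s$p)
  cand <- which(p < p_threshold)
  if (length(cand) == 0) return(region_set())
  cand <- cand[order(p[cand])]
  chrom <- integer(0); start <- numeric(0); end <- numeric(0)
  alive <- rep(TRUE, nrow(s))
  for (i in cand) {
    if (!alive[i]) next
    lo <- max(0, s$pos[i] - 1 - window_bp)
    hi <- s$pos[i] + window_bp
    chrom <- c(chrom, s$chrom[i]); start <- c(start, lo); end <- c(end, hi)
    alive <- alive & !(s$chrom == s$chrom[i] &
                         (s$pos - 1) >= lo & (s$pos - 1) < hi)
  }
  region_set(chrom, start, end)
}

#' Heritability excluding genomic regions
#'
#' Re-runs [estimate_h2()] on the SNPs outside the given regions.  The
#' full-analysis M is kept as the regression denominator so that the change
#' in the estimate reflects heritability removed with the excluded loci
#' rather than a change of denominator.
#'
#' @inheritParams estimate_h2
#' @param regions a [region_set()] to exclude (e.g. from [clump_loci()]).
#' @return An `ldsc_h2` fit on the remaining SNPs.
#' @export
h2_excluding_regions <- function(ss, ld, regions, m_total = NULL,
                                 n_blocks = 200, n_iter = 2,
                                 chisq_max = NULL) {
  stopifnot(inherits(ss, "sumstats"), inherits(regions, "region_set"))
  if (is.null(m_total)) m_total <- nrow(ld)
  if (nrow(regions) > 0) {
    s <- ss$snps
    keep <- !in_regions(regions, s$chrom, s$pos)
    if (sum(keep) < 2 * n_blocks) {
      stop("locus exclusion leaves too few SNPs (", sum(keep), ")")
    }
    ss <- replace_snps(ss, s[keep, , drop = FALSE])
  }
  estimate_h2(ss, ld, m_total = m_total, n_blocks = n_blocks,
              n_iter = n_iter, chisq_max = chisq_max)
}

#' Proportion of heritability explained by top loci
#'
#' Compares the heritability estimated from all SNPs with the estimate after
#' excluding a set of regions (typically genome-wide significant loci plus
#' a +/- 500 kb window) and returns `1 - h2_excluded / h2_full`.  The
#' regions may come from the same trait's clumped loci (own attribution) or
#' from another trait's (cross-trait attribution).
#'
#' @inheritParams estimate_h2
#' @param regions_source either a [region_set()] or a [sumstats()] object
#'   whose genome-wide significant loci are clumped with [clump_loci()].
#' @param p_threshold,window_bp clumping parameters used when
#'   `regions_source` is a summary-statistics table.
#' @return List with the `proportion` explained, the excluded `regions`,
#'   and the two `ldsc_h2` fits (`fit_full`, `fit_excluded`).
#' @export
proportion_explained <- function(ss, ld, regions_source, m_total = NULL,
                                 n_blocks = 200, p_threshold = 5e-8,
                                 window_bp = 5e5, chisq_max = NULL) {
  regions <- if (inherits(regions_source, "sumstats")) {
    clump_loci(regions_source, p_threshold, window_bp)
  } else {
    regions_source
  }
  stopifnot(inherits(regions, "region_set"))
  fit_full <- estimate_h2(ss, ld, m_total = m_total, n_blocks = n_blocks,
                          chisq_max = chisq_max)
  if (fit_full$h2_observed$value <= 0) {
    stop("full-data heritability estimate is non-positive; ",
         "proportion explained is undefined")
  }
  if (nrow(regions) == 0) {
    return(list(proportion = 0, regions = regions,
                fit_full = fit_full, fit_excluded = fit_full))
  }
  fit_excl <- h2_excluding_regions(ss, ld, regions,
                                   m_total = fit_full$m_total,
                                   n_blocks = n_blocks,
                                   chisq_max = chisq_max)
  list(proportion = 1 - fit_excl$h2_observed$value /
         fit_full$h2_observed$value,
       regions = regions, fit_full = fit_full, fit_excluded = fit_excl)
}

#' Write heritability results as TSV
#'
#' @param fits list of `ldsc_h2` objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_h2_results <- function(fits, path) {
  rows <- lapply(fits, function(f) {
    data.frame(trait = f$trait_name,
               h2_obs = f$h2_observed$value, h2_obs_se = f$h2_observed$se,
               h2_liab = if (is.null(f$h2_liability)) NA
                         else f$h2_liability$value,
               h2_liab_se = if (is.null(f$h2_liability)) NA
                            else f$h2_liability$se,
               intercept = f$intercept$value,
               intercept_se = f$intercept$se,
               mean_chi2 = f$mean_chi2, m_used = f$m_snps_used)
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
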