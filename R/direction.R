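#' Wakefield approximate log Bayes factor
#'
#' Log Bayes factor for association at one SNP given an effect estimate
#' and its standard error, under a normal prior with variance `W` on the
#' true effect:
#' `log BF = 0.5 log(se^2 / (se^2 + W)) + (z^2 / 2) * W / (se^2 + W)`,
#' with `z = beta / se`.  The BF favours association and is strictly
#' increasing in `|z|` at fixed `se` and `W`.
#'
#' @param beta effect estimate(s).
#' @param se standard error(s), `> 0`.
#' @param prior_var prior variance `W > 0` on the standardized-effect
#'   scale (default 0.04).
#' @return Log Bayes factor(s), vectorized.
#' @export
wakefield_log_bf <- function(beta, se, prior_var = 0.04) {
  stopifnot(all(se > 0), prior_var > 0)
  z2 <- (beta / se)^2
  shrink <- se^2 / (se^2 + prior_var)
  0.5 * log(shrink) + (z2 / 2) * prior_var / (se^2 + prior_var)
}

log_sum_exp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Regional posterior probabilities of association
#'
#' Empirical-Bayes model over genome blocks: each block's regional Bayes
#' factor is the average of its per-SNP Wakefield Bayes factors, and the
#' prior probability `pi` that any block contains an association is
#' estimated by EM on the marginal likelihood
#' `sum_b log((1 - pi) + pi * RBF_b)`.  Blocks with posterior probability
#' of association (PPA) of at least `ppa_min` contribute their lead SNP
#' (largest per-SNP BF) to the ascertained set.
#'
#' @param ss a [sumstats()] object.
#' @param partition a partition input for [partition_for_scan()] tiling
#'   the SNPs.
#' @param prior_var Wakefield prior variance `W`.
#' @param ppa_min PPA cutoff for reporting lead SNPs (default 0.9).
#' @param max_iter,tol EM iteration controls.
#' @return A data frame (class `block_ppa`) with one row per block:
#'   `chrom`, `start`, `end`, `n_snps`, `log_rbf`, `ppa`, `lead_snp`,
#'   `lead_log_bf`; the fitted prior is attached as attribute `pi`, and
#'   `attr(, "lead_snps")` holds the ids of lead SNPs passing `ppa_min`.
#' @export
block_ppa <- function(ss, partition, prior_var = 0.04, ppa_min = 0.9,
                      max_iter = 100, tol = 1e-8) {
  stopifnot(inherits(ss, "sumstats"))
  partition <- partition_for_scan(partition)
  s <- ss$snps
  beta <- s$z / sqrt(s$n)
  se <- 1 / sqrt(s$n)
  log_bf <- wakefield_log_bf(beta, se, prior_var)

  n_blocks <- nrow(partition)
  rows <- vector("list", n_blocks)
  log_rbf <- numeric(n_blocks)
  for (b in seq_len(n_blocks)) {
    inside <- which(in_regions(partition[b, , drop = FALSE], s$chrom, s$pos))
    if (length(inside) == 0) {
      log_rbf[b] <- NA_real_
      rows[[b]] <- data.frame(chrom = partition$chrom[b],
                              start = partition$start[b],
                              end = partition$end[b], n_snps = 0L,
                              lead_snp = NA_character_,
                              lead_log_bf = NA_real_)
      next
    }
    log_rbf[b] <- log_sum_exp(log_bf[inside]) - log(length(inside))
    lead <- inside[which.max(log_bf[inside])]
    rows[[b]] <- data.frame(chrom = partition$chrom[b],
                            start = partition$start[b],
                            end = partition$end[b],
                            n_snps = length(inside),
                            lead_snp = s$snp_id[lead],
                            lead_log_bf = log_bf[lead])
  }
  use <- which(!is.na(log_rbf))

  # EM for the block prior pi
  pi_hat <- 0.1
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    log_odds <- log(pi_hat) - log1p(-pi_hat) + log_rbf[use]
    ppa <- stats::plogis(log_odds)
    pi_new <- mean(ppa)
    pi_new <- min(max(pi_new, 1e-12), 1 - 1e-12)
    if (abs(pi_new - pi_hat) < tol) {
      pi_hat <- pi_new
      converged <- TRUE
      break
    }
    pi_hat <- pi_new
  }
  if (!converged) {
    warning("block-prior EM did not converge after ", max_iter,
            " iterations; using last iterate")
  }
  ppa_all <- rep(NA_real_, n_blocks)
  ppa_all[use] <- stats::plogis(log(pi_hat) - log1p(-pi_hat) + log_rbf[use])

  out <- do.call(rbind, rows)
  out$log_rbf <- log_rbf
  out$ppa <- ppa_all
  out <- out[, c("chrom", "start", "end", "n_snps", "log_rbf", "ppa",
                 "lead_snp", "lead_log_bf")]
  attr(out, "pi") <- pi_hat
  attr(out, "lead_snps") <- out$lead_snp[!is.na(out$ppa) &
                                           out$ppa >= ppa_min]
  class(out) <- c("block_ppa", "data.frame")
  out
}

#' LD-pruned genome-wide significant SNPs
#'
#' Greedy ascertainment: SNPs with `p < p_threshold` are visited in order
#' of increasing p-value, and a SNP is kept unless it has squared
#' correlation above `r2_max` with an already kept SNP (SNPs in different
#' panel blocks are uncorrelated).
#'
#' @param ss a [sumstats()] object.
#' @param panel a `ref_panel` covering the SNPs.
#' @param p_threshold significance threshold (default 5e-8).
#' @param r2_max pruning threshold on squared correlation (default 0.1).
#' @return Character vector of kept SNP ids (possibly empty).
#' @export
select_pruned <- function(ss, panel, p_threshold = 5e-8, r2_max = 0.1) {
  stopifnot(inherits(ss, "sumstats"), inherits(panel, "ref_panel"))
  s <- ss$snps
  p <- ifelse(is.na(s$p), 2 * stats::pnorm(-abs(s$z)), s$p)
  cand <- which(p < p_threshold)
  if (length(cand) == 0) return(character(0))
  cand <- cand[order(p[cand])]
  map <- panel_snp_map(panel)
  midx <- match(s$snp_id, map$snp_id)
  bs <- panel$block_size
  kept <- integer(0)
  for (i in cand) {
    if (is.na(midx[i])) next
    blk_i <- map$block[midx[i]]
    pos_i <- midx[i] - (blk_i - 1) * bs
    ok <- TRUE
    for (j in kept) {
      blk_j <- map$block[midx[j]]
      if (blk_j != blk_i) next
      pos_j <- midx[j] - (blk_j - 1) * bs
      if (panel$blocks[[blk_i]]$R[pos_i, pos_j]^2 > r2_max) {
        ok <- FALSE
        break
      }
    }
    if (ok) kept <- c(kept, i)
  }
  s$snp_id[kept]
}

#' Paired effect sizes for an ascertained SNP set
#'
#' Extracts standardized effects (`beta = z / sqrt(N)`, `se = 1 / sqrt(N)`)
#' on both traits for a set of SNPs ascertained on one trait.
#'
#' @param ss_x,ss_y [sumstats()] objects for the two traits.
#' @param snp_ids SNPs ascertained (on either trait); must be present in
#'   both tables.
#' @param trait label of the ascertainment trait.
#' @param method `"pruned"` or `"ppa"`.
#' @return A data frame (class `ascertained_set`) with columns `snp_id`,
#'   `beta_x`, `se_x`, `beta_y`, `se_y`.
#' @export
ascertain_effects <- function(ss_x, ss_y, snp_ids, trait = ss_x$trait_name,
                              method = c("pruned", "ppa")) {
  method <- match.arg(method)
  i_x <- match(snp_ids, ss_x$snps$snp_id)
  i_y <- match(snp_ids, ss_y$snps$snp_id)
  keep <- !is.na(i_x) & !is.na(i_y)
  out <- data.frame(
    snp_id = snp_ids[keep],
    beta_x = ss_x$snps$z[i_x[keep]] / sqrt(ss_x$snps$n[i_x[keep]]),
    se_x = 1 / sqrt(ss_x$snps$n[i_x[keep]]),
    beta_y = ss_y$snps$z[i_y[keep]] / sqrt(ss_y$snps$n[i_y[keep]]),
    se_y = 1 / sqrt(ss_y$snps$n[i_y[keep]])
  )
  attr(out, "trait") <- trait
  attr(out, "method") <- method
  class(out) <- c("ascertained_set", "data.frame")
  out
}

# Log-likelihood of "downstream ~ slope * upstream" with measurement error
# on both coordinates: contrast d - slope * u ~ N(0, sd_d^2 + slope^2 sd_u^2).
ll_slope <- function(d, sd_d, u, sd_u, slope) {
  v <- sd_d^2 + slope^2 * sd_u^2
  sum(stats::dnorm(d - slope * u, 0, sqrt(v), log = TRUE))
}

# Maximize ll_slope over the slope (1-D, bounded search).
fit_slope <- function(d, sd_d, u, sd_u, lower = -50, upper = 50) {
  opt <- stats::optimize(function(s) ll_slope(d, sd_d, u, sd_u, s),
                         lower = lower, upper = upper, maximum = TRUE)
  list(slope = opt$maximum, loglik = opt$objective)
}

#' Directional model comparison for a trait pair
#'
#' Compares two causal and two non-causal effect-size models on SNP sets
#' ascertained separately on the two traits, using Gaussian
#' measurement-error likelihoods on the observed standardized effect
#' pairs.  Each X-ascertained SNP contributes the density of its effect on
#' Y, and each Y-ascertained SNP the density of its effect on X, so all
#' four models are likelihoods over the same data components:
#'
#' * `causal_xy` (X causes Y): X-ascertained SNPs transmit to Y with a free
#'   slope, `beta_y ~ N(alpha beta_x, se_y^2 + alpha^2 se_x^2)`;
#'   Y-ascertained SNPs act on Y independently of X,
#'   `beta_x ~ N(0, se_x^2)`.
#' * `causal_yx`: the mirror image.
#' * `noncausal_indep`: no cross-trait relation in either set.
#' * `noncausal_pleio`: a shared factor drives both traits, so both sets
#'   show the same effect ratio `lambda` (`beta_y = lambda beta_x` among
#'   X-ascertained SNPs and `beta_x = beta_y / lambda` among Y-ascertained
#'   ones).
#'
#' The relative likelihood ratio is
#' `LR = max L(non-causal) / max L(causal)`; a directional verdict (`xy`
#' or `yx`, whichever causal model fits better) is returned only when
#' `LR < lr_threshold` and the heteroscedasticity check does not flag
#' set-dependent transmission slopes.
#'
#' @param set_x an [ascertain_effects()] set ascertained on trait X.
#' @param set_y an [ascertain_effects()] set ascertained on trait Y.
#' @param lr_threshold decision threshold on the relative likelihood ratio
#'   (default 0.05).
#' @return An object of class `directional_fit`: log-likelihoods per
#'   model, fitted slopes, `relative_lr`, `hetero_flag` and `verdict`
#'   (`"xy"`, `"yx"` or `"none"`).
#' @export
fit_directional_models <- function(set_x, set_y, lr_threshold = 0.05) {
  if (is.null(set_x) || nrow(set_x) == 0 ||
      is.null(set_y) || nrow(set_y) == 0) {
    message("empty ascertained set; directional test skipped")
    return(structure(
      list(loglik = c(causal_xy = NA, causal_yx = NA,
                      noncausal_indep = NA, noncausal_pleio = NA),
           alpha_xy = NA, alpha_yx = NA, lambda = NA,
           relative_lr = NA, hetero_flag = NA, verdict = "none",
           n_x = if (is.null(set_x)) 0L else nrow(set_x),
           n_y = if (is.null(set_y)) 0L else nrow(set_y)),
      class = "directional_fit"
    ))
  }
  if (any(c(set_x$se_x, set_x$se_y, set_y$se_x, set_y$se_y) <= 0)) {
    stop("degenerate (non-positive) standard errors in ascertained sets")
  }

  # null cross-trait components
  ll_null_x <- sum(stats::dnorm(set_x$beta_y, 0, set_x$se_y, log = TRUE))
  ll_null_y <- sum(stats::dnorm(set_y$beta_x, 0, set_y$se_x, log = TRUE))

  fit_xy <- fit_slope(set_x$beta_y, set_x$se_y, set_x$beta_x, set_x$se_x)
  fit_yx <- fit_slope(set_y$beta_x, set_y$se_x, set_y$beta_y, set_y$se_y)

  ll <- c(causal_xy = fit_xy$loglik + ll_null_y,
          causal_yx = ll_null_x + fit_yx$loglik,
          noncausal_indep = ll_null_x + ll_null_y,
          noncausal_pleio = NA)

  pleio_ll <- function(lam) {
    ll_slope(set_x$beta_y, set_x$se_y, set_x$beta_x, set_x$se_x, lam) +
      ll_slope(set_y$beta_x, set_y$se_x, set_y$beta_y, set_y$se_y, 1 / lam)
  }
  opt_pos <- stats::optimize(pleio_ll, lower = 1e-4, upper = 50,
                             maximum = TRUE)
  opt_neg <- stats::optimize(pleio_ll, lower = -50, upper = -1e-4,
                             maximum = TRUE)
  if (opt_pos$objective >= opt_neg$objective) {
    lambda <- opt_pos$maximum
    ll["noncausal_pleio"] <- opt_pos$objective
  } else {
    lambda <- opt_neg$maximum
    ll["noncausal_pleio"] <- opt_neg$objective
  }

  best_causal <- max(ll["causal_xy"], ll["causal_yx"])
  best_noncausal <- max(ll["noncausal_indep"], ll["noncausal_pleio"])
  relative_lr <- exp(best_noncausal - best_causal)
  direction <- if (ll["causal_xy"] >= ll["causal_yx"]) "xy" else "yx"

  hetero <- heteroscedasticity_check(set_x, set_y, direction = direction)
  verdict <- if (!is.na(relative_lr) && relative_lr < lr_threshold &&
                 isFALSE(hetero)) direction else "none"

  structure(
    list(loglik = ll, alpha_xy = fit_xy$slope, alpha_yx = fit_yx$slope,
         lambda = lambda, relative_lr = relative_lr,
         hetero_flag = hetero, verdict = verdict,
         n_x = nrow(set_x), n_y = nrow(set_y)),
    class = "directional_fit"
  )
}

#' @export
print.directional_fit <- function(x, digits = 4, ...) {
  cat("Directional model comparison (", x$n_x, " X-ascertained, ",
      x$n_y, " Y-ascertained SNPs)\n", sep = "")
  print(signif(x$loglik, 6))
  cat("  relative LR (best non-causal / best causal): ",
      signif(x$relative_lr, digits), "\n", sep = "")
  cat("  heteroscedasticity flag: ", x$hetero_flag,
      "   verdict: ", x$verdict, "\n", sep = "")
  invisible(x)
}

# Transmission slope of the downstream trait on the upstream one within
# one set, with a leverage-corrected (HC3) robust standard error.
set_slope <- function(u, d, sd_d) {
  w <- 1 / sd_d^2
  denom <- sum(w * u^2)
  if (denom <= 0 || length(u) < 2) {
    return(list(slope = NA_real_, se = NA_real_))
  }
  slope <- sum(w * u * d) / denom
  h <- w * u^2 / denom
  resid <- (d - slope * u) / pmax(1 - h, 0.1)
  se <- sqrt(sum(w^2 * u^2 * resid^2)) / denom
  list(slope = slope, se = se, n = length(u))
}

#' Check for set-dependent transmission slopes
#'
#' Under genuine mediated causation the slope relating the downstream
#' trait's effects to the upstream trait's effects should be the same in
#' both ascertainment sets; a significant difference suggests pleiotropy.
#' The slope is estimated separately in each set by weighted regression
#' through the origin with heteroscedasticity-robust standard errors and
#' compared by a two-sided z-test at the 0.05 level.  A set without
#' leverage on the upstream effect yields a large slope standard error and
#' therefore cannot trigger the flag, as intended.
#'
#' @param set_x,set_y [ascertain_effects()] sets.
#' @param direction `"xy"` (slope of beta_y on beta_x) or `"yx"`.
#' @param alpha significance level for the slope-difference test.
#' @return `TRUE` (flagged), `FALSE`, or `NA` when a slope is inestimable
#'   (verdicts are withheld in that case).
#' @export
heteroscedasticity_check <- function(set_x, set_y, direction = "xy",
                                     alpha = 0.05) {
  if (is.null(set_x) || is.null(set_y) ||
      nrow(set_x) < 2 || nrow(set_y) < 2) {
    return(NA)
  }
  if (direction == "xy") {
    s1 <- set_slope(set_x$beta_x, set_x$beta_y, set_x$se_y)
    s2 <- set_slope(set_y$beta_x, set_y$beta_y, set_y$se_y)
  } else {
    s1 <- set_slope(set_y$beta_y, set_y$beta_x, set_y$se_x)
    s2 <- set_slope(set_x$beta_y, set_x$beta_x, set_x$se_x)
  }
  if (is.na(s1$slope) || is.na(s2$slope)) return(NA)
  v <- s1$se^2 + s2$se^2
  if (v <= 0) {
    return(s1$slope != s2$slope)
  }
  z <- (s1$slope - s2$slope) / sqrt(v)
  # t reference: slope variances are estimated from few SNPs
  p <- 2 * stats::pt(-abs(z), df = s1$n + s2$n - 2)
  p < alpha
}
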