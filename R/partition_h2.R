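#' Stratified LD score regression
#'
#' Partitions SNP-heritability across functional annotation categories by
#' multivariate weighted regression of the per-SNP chi-square statistics
#' on the per-category LD scores,
#' `E[chi2_j] = N_j sum_c tau_c l_{j,c} + 1` with a free intercept.  The
#' per-category coefficients `tau_c` give each SNP a modelled effect
#' variance `v_j = sum_c a_{j,c} tau_c`; the heritability share of a
#' category is `prop_h2(C) = sum_{j in C} v_j / sum_j v_j`, and its
#' enrichment is `prop_h2(C) / prop_snps(C)`.  All derived quantities
#' carry delete-one-block jackknife errors.  Regression weights and block
#' assignment are taken from the total-LD fit, so a base-only model
#' reproduces [estimate_h2()] exactly.  Continuous-valued annotation
#' columns (e.g. MAF bins expressed as weights, or LD-related adjusters)
#' enter the regression but are excluded from enrichment reporting, which
#' is defined only for membership categories.
#'
#' @param ss a [sumstats()] object.
#' @param ld a stratified `ldscore_table` from
#'   [compute_stratified_ld_scores()] (must include the base category).
#' @param annotations the matching [annot_matrix()].
#' @param m_total regression denominator M; defaults to `nrow(ld)`.
#' @param n_blocks jackknife blocks (default 200).
#' @return An object of class `ldsc_strat`: per-category `enrichment`
#'   table (category, prop_snps, prop_h2, se, enrichment, se,
#'   p_enrichment, tau, tau_se, tau_p), the total `h2_observed`, the
#'   intercept, and bookkeeping fields.
#' @export
stratified_h2 <- function(ss, ld, annotations, m_total = NULL,
                          n_blocks = 200) {
  stopifnot(inherits(ss, "sumstats"), inherits(annotations, "annot_matrix"))
  cats <- attr(ld, "categories")
  if (is.null(cats)) stop("ld must be a stratified LD score table")
  if (!"base" %in% cats) stop("stratified LD scores must include base")
  missing_ann <- setdiff(cats, colnames(annotations$values))
  if (length(missing_ann) > 0) {
    stop("annotations lack categories: ", paste(missing_ann, collapse = ", "))
  }
  if (is.null(m_total)) m_total <- nrow(ld)

  base_fit <- estimate_h2(ss, ld, m_total = m_total, n_blocks = n_blocks)
  dat <- base_fit$data
  idx_ld <- match(dat$snp_id, ld$snp_id)
  L <- as.matrix(ld[idx_ld, paste0("L2_", cats), drop = FALSE])
  colnames(L) <- cats
  idx_ann <- match(dat$snp_id, annotations$snp_id)
  if (anyNA(idx_ann)) stop("annotations do not cover the analyzed SNPs")
  A <- annotations$values[idx_ann, cats, drop = FALSE]

  n <- nrow(dat)
  X <- cbind(dat$n * L, intercept = 1)
  colnames(X) <- c(cats, "intercept")
  fit_cats <- cats
  qrX <- qr(X * sqrt(base_fit$weights))
  if (qrX$rank < ncol(X)) {
    # an exact disjoint covering of the SNPs spans the base category;
    # in that case the base column is redundant and is dropped from the
    # regression (its heritability is still the total by construction)
    X_nb <- X[, setdiff(colnames(X), "base"), drop = FALSE]
    qr_nb <- qr(X_nb * sqrt(base_fit$weights))
    if (qr_nb$rank == ncol(X_nb)) {
      message("base column spanned by the other categories; ",
              "fitting without it")
      X <- X_nb
      fit_cats <- setdiff(cats, "base")
    } else {
      aliased <- colnames(X_nb)[qr_nb$pivot[(qr_nb$rank + 1):ncol(X_nb)]]
      stop("collinear annotation columns: ",
           paste(aliased, collapse = ", "))
    }
  }
  fit <- wls_jackknife(dat$z^2, X, base_fit$weights, base_fit$block_id)

  tau <- structure(numeric(length(cats)), names = cats)
  tau[fit_cats] <- fit$coef[fit_cats]
  tau_del <- matrix(0, nrow(fit$delete), length(cats),
                    dimnames = list(NULL, cats))
  tau_del[, fit_cats] <- fit$delete[, fit_cats]
  # category heritabilities: h2_C = (A' A tau)_C, total = (colSums(A))' tau
  G <- crossprod(A)                       # C x C
  s_tot <- colSums(A)
  scale <- m_total / n
  h2_cat <- drop(G %*% tau) * scale
  h2_tot <- sum(s_tot * tau) * scale
  h2_cat_del <- tau_del %*% t(G) * scale  # B x C
  h2_tot_del <- drop(tau_del %*% s_tot) * scale

  is_binary <- apply(A, 2, function(col) all(col %in% c(0, 1)))
  m_c <- colSums(A > 0)
  prop_snps <- m_c / n

  rows <- vector("list", length(cats))
  ests <- list()
  for (i in seq_along(cats)) {
    cat_name <- cats[i]
    tau_est <- estimate_with_error(tau[[cat_name]], tau_del[, cat_name])
    if (is_binary[[cat_name]]) {
      prop <- h2_cat[i] / h2_tot
      prop_del <- h2_cat_del[, i] / h2_tot_del
      prop_est <- estimate_with_error(prop, prop_del)
      enr <- prop / prop_snps[[cat_name]]
      enr_est <- estimate_with_error(enr, prop_del / prop_snps[[cat_name]])
      # test of enrichment != 1 via the h2 share against the SNP share
      z_enr <- if (isTRUE(prop_est$se > 0)) {
        (prop - prop_snps[[cat_name]]) / prop_est$se
      } else {
        NA_real_
      }
      p_enr <- if (is.na(z_enr)) NA_real_ else 2 * stats::pnorm(-abs(z_enr))
    } else {
      prop_est <- NULL
      enr_est <- NULL
      p_enr <- NA_real_
    }
    ests[[cat_name]] <- list(tau = tau_est, prop_h2 = prop_est,
                             enrichment = enr_est)
    rows[[i]] <- data.frame(
      category = cat_name,
      binary = is_binary[[cat_name]],
      prop_snps = prop_snps[[cat_name]],
      prop_h2 = if (is_binary[[cat_name]]) prop_est$value else NA,
      prop_h2_se = if (is_binary[[cat_name]]) prop_est$se else NA,
      enrichment = if (is_binary[[cat_name]]) enr_est$value else NA,
      enrichment_se = if (is_binary[[cat_name]]) enr_est$se else NA,
      p_enrichment = p_enr,
      tau = tau_est$value, tau_se = tau_est$se, tau_p = tau_est$p
    )
  }
  enrichment <- do.call(rbind, rows)
  h2_observed <- estimate_with_error(h2_tot, h2_tot_del)
  negative <- enrichment$binary & !is.na(enrichment$prop_h2) &
    enrichment$prop_h2 < 0
  if (any(negative)) {
    message("negative category heritability estimate(s): ",
            paste(enrichment$category[negative], collapse = ", "))
  }

  structure(
    list(enrichment = enrichment, estimates = ests,
         h2_observed = h2_observed,
         intercept = estimate_with_error(fit$coef[["intercept"]],
                                         fit$delete[, "intercept"]),
         tau = tau, tau_delete = tau_del,
         trait_name = ss$trait_name, m_snps_used = n, m_total = m_total,
         n_blocks = n_blocks, categories = cats),
    class = "ldsc_strat"
  )
}

#' @export
print.ldsc_strat <- function(x, digits = 3, ...) {
  cat("Stratified LD score regression (", x$trait_name, ")\n", sep = "")
  cat("  total h2 (observed): ", signif(x$h2_observed$value, 4),
      " (se ", signif(x$h2_observed$se, 4), ")\n", sep = "")
  tab <- x$enrichment[x$enrichment$binary,
                      c("category", "prop_snps", "prop_h2", "enrichment",
                        "enrichment_se", "p_enrichment")]
  print(format(tab, digits = digits), row.names = FALSE)
  invisible(x)
}

#' @export
coef.ldsc_strat <- function(object, ...) {
  object$tau
}

#' One-at-a-time cell-type annotation scan
#'
#' Adds each candidate annotation individually to the baseline model
#' (creating one stratified regression per candidate, mirroring scans over
#' cell-type-specific histone-mark tracks) and reports the candidate's
#' coefficient test and enrichment, with a Bonferroni threshold of
#' `alpha / n_candidates`.
#'
#' @param ss a [sumstats()] object.
#' @param ld_baseline,annotations_baseline baseline stratified LD scores
#'   and annotations.
#' @param ld_candidates,annotations_candidates stratified LD scores and
#'   annotations for the candidate categories (names must be disjoint from
#'   the baseline's).
#' @param m_total,n_blocks passed to [stratified_h2()].
#' @param alpha family-wise error rate (default 0.05).
#' @return Data frame with one row per candidate (category, tau, tau_se,
#'   p, enrichment, enrichment_se, significant), ordered by p; threshold
#'   attached as attribute `threshold`.
#' @export
cell_type_scan <- function(ss, ld_baseline, annotations_baseline,
                           ld_candidates, annotations_candidates,
                           m_total = NULL, n_blocks = 200, alpha = 0.05) {
  base_cats <- attr(ld_baseline, "categories")
  cand_cats <- setdiff(attr(ld_candidates, "categories"), "base")
  if (length(cand_cats) == 0) stop("no candidate categories")
  clash <- intersect(cand_cats, base_cats)
  if (length(clash) > 0) {
    stop("candidate categories already in baseline: ",
         paste(clash, collapse = ", "))
  }
  stopifnot(identical(ld_baseline$snp_id, ld_candidates$snp_id))
  thr <- significance_threshold(length(cand_cats), alpha)

  rows <- vector("list", length(cand_cats))
  for (i in seq_along(cand_cats)) {
    cc <- cand_cats[i]
    ld_one <- ld_baseline
    ld_one[[paste0("L2_", cc)]] <- ld_candidates[[paste0("L2_", cc)]]
    attr(ld_one, "categories") <- c(base_cats, cc)
    ann_one <- annot_matrix(
      annotations_baseline$snp_id,
      cbind(annotations_baseline$values,
            annotations_candidates$values[, cc, drop = FALSE])
    )
    fit <- stratified_h2(ss, ld_one, ann_one, m_total = m_total,
                         n_blocks = n_blocks)
    row <- fit$enrichment[fit$enrichment$category == cc, ]
    rows[[i]] <- data.frame(category = cc, tau = row$tau,
                            tau_se = row$tau_se, p = row$tau_p,
                            enrichment = row$enrichment,
                            enrichment_se = row$enrichment_se,
                            p_enrichment = row$p_enrichment)
  }
  out <- do.call(rbind, rows)
  out$significant <- !is.na(out$p) & out$p < thr
  out <- out[order(out$p), ]
  rownames(out) <- NULL
  attr(out, "threshold") <- thr
  out
}

#' Random-effects meta-analysis of one category across traits
#'
#' DerSimonian-Laird random-effects pooling of per-trait estimates (for
#' example the enrichment, or proportion of heritability, of one
#' functional category across several cancers): fixed weights
#' `w_i = 1/se_i^2`, heterogeneity `Q = sum w_i (theta_i - theta_FE)^2`,
#' between-trait variance
#' `tau2 = max(0, (Q - df) / (sum w - sum w^2 / sum w))`, and pooling with
#' weights `1 / (se_i^2 + tau2)`.
#'
#' @param values per-trait estimates (length >= 2).
#' @param ses their standard errors (> 0).
#' @param category optional category label.
#' @param conf_level confidence level for the pooled interval.
#' @return An object of class `meta_row`: `pooled`, `se`, `ci_lower`,
#'   `ci_upper`, `p`, `tau2_meta`, `n_traits`.
#' @export
meta_analyze <- function(values, ses, category = NULL, conf_level = 0.95) {
  stopifnot(length(values) == length(ses))
  if (length(values) < 2) stop("meta-analysis needs at least 2 traits")
  stopifnot(all(ses > 0))
  fit <- metafor::rma.uni(yi = values, sei = ses, method = "DL",
                          level = conf_level * 100)
  structure(
    list(category = category, pooled = as.numeric(fit$b), se = fit$se,
         ci_lower = fit$ci.lb, ci_upper = fit$ci.ub, p = fit$pval,
         tau2_meta = fit$tau2, n_traits = length(values)),
    class = "meta_row"
  )
}

#' @export
print.meta_row <- function(x, digits = 4, ...) {
  cat("Random-effects meta-analysis",
      if (!is.null(x$category)) paste0("(", x$category, ")"), "\n")
  cat("  pooled ", signif(x$pooled, digits), " (se ", signif(x$se, digits),
      "), 95% CI [", signif(x$ci_lower, digits), ", ",
      signif(x$ci_upper, digits), "], p ", signif(x$p, 3),
      ", tau2 ", signif(x$tau2_meta, digits),
      " over ", x$n_traits, " traits\n", sep = "")
  invisible(x)
}

#' Meta-analyze enrichment across a list of stratified fits
#'
#' @param fits list of `ldsc_strat` objects (one per trait).
#' @param field `"enrichment"` (default) or `"prop_h2"`.
#' @param alpha family-wise error rate for the Bonferroni flag across
#'   categories.
#' @return Data frame with one row per binary category: pooled estimate,
#'   se, CI, p, tau2_meta, n_traits, significant.
#' @export
meta_analyze_enrichment <- function(fits, field = c("enrichment", "prop_h2"),
                                    alpha = 0.05) {
  field <- match.arg(field)
  stopifnot(length(fits) >= 2)
  cats <- fits[[1]]$enrichment$category[fits[[1]]$enrichment$binary]
  cats <- setdiff(cats, "base")
  thr <- significance_threshold(length(cats), alpha)
  rows <- lapply(cats, function(cc) {
    vals <- vapply(fits, function(f) {
      f$enrichment[[field]][f$enrichment$category == cc]
    }, numeric(1))
    ses <- vapply(fits, function(f) {
      f$enrichment[[paste0(field, "_se")]][f$enrichment$category == cc]
    }, numeric(1))
    mr <- meta_analyze(vals, ses, category = cc)
    data.frame(category = cc, pooled = mr$pooled, se = mr$se,
               ci_lower = mr$ci_lower, ci_upper = mr$ci_upper,
               p = mr$p, tau2_meta = mr$tau2_meta, n_traits = mr$n_traits,
               significant = !is.na(mr$p) & mr$p < thr)
  })
  out <- do.call(rbind, rows)
  attr(out, "threshold") <- thr
  out
}
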