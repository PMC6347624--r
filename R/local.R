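#' Genome partition for a local covariance scan
#'
#' Returns the fixed genome partition over which region-level genetic
#' covariance is scanned: either an externally supplied partition of
#' LD-independent regions, or, for a synthetic panel, the panel's block
#' boundaries (blocks are mutually independent by construction).
#'
#' @param x a `ref_panel`, a [region_set()], or a data frame with columns
#'   `chrom`, `start`, `end`.  Data-frame input with overlapping intervals
#'   is rejected rather than silently merged, since a partition must tile
#'   the SNPs without double counting.
#' @return A [region_set()].
#' @export
partition_for_scan <- function(x) {
  if (inherits(x, "ref_panel")) {
    return(panel_block_regions(x))
  }
  if (inherits(x, "region_set")) {
    return(x)
  }
  if (is.data.frame(x)) {
    rs <- region_set(x$chrom, x$start, x$end)
    if (nrow(rs) != nrow(x)) {
      stop("partition intervals overlap after merging (",
           nrow(x), " -> ", nrow(rs), ")")
    }
    return(rs)
  }
  stop("cannot derive a partition from class ", paste(class(x), collapse = "/"))
}

# Eigen-decompositions of the panel LD restricted to each region.
# Returns, per region, the region's SNP ids and the eigensystem of the
# (block-diagonal) correlation matrix over those SNPs.
region_spectra <- function(panel, partition) {
  stopifnot(inherits(panel, "ref_panel"))
  partition <- partition_for_scan(partition)
  map <- panel_snp_map(panel)
  bs <- panel$block_size
  lapply(seq_len(nrow(partition)), function(r) {
    inside <- in_regions(partition[r, , drop = FALSE] |>
                           structure(class = c("region_set", "data.frame")),
                         map$chrom, map$pos)
    idx <- which(inside)
    if (length(idx) == 0) {
      return(list(snp_id = character(0)))
    }
    blocks <- unique(map$block[idx])
    n <- length(idx)
    R <- matrix(0, n, n)
    offset <- 0
    ids <- character(0)
    for (b in blocks) {
      within <- idx[map$block[idx] == b] - (b - 1) * bs
      nb <- length(within)
      R[offset + seq_len(nb), offset + seq_len(nb)] <-
        panel$blocks[[b]]$R[within, within, drop = FALSE]
      ids <- c(ids, panel$blocks[[b]]$snp_id[within])
      offset <- offset + nb
    }
    list(snp_id = ids, eig = eigen(R, symmetric = TRUE))
  })
}

# Rank truncation: eigenvalues capturing `trace_frac` of the trace, with
# near-null directions dropped; optionally user-capped.
choose_rank <- function(values, k = NULL, trace_frac = 0.999) {
  pos <- values > max(values) * 1e-10
  k_max <- sum(pos)
  k_trace <- which(cumsum(values[seq_len(k_max)]) >=
                     trace_frac * sum(values[pos]))[1]
  k_auto <- min(k_max, k_trace)
  if (is.null(k)) return(k_auto)
  if (k > k_max) {
    warning("requested rank ", k, " exceeds positive-eigenvalue count ",
            k_max, "; reduced")
    k <- k_max
  }
  k
}

# Exact null tail of q = a*U - b*V with U, V iid chi-square(k):
# P(q > c), by integrating over V.
pq_chisq_diff <- function(c, a, b, k) {
  if (b <= 1e-14) return(stats::pchisq(c / a, k, lower.tail = FALSE))
  if (a <= 1e-14) return(stats::pchisq(-c / b, k))
  f <- function(v) {
    stats::dchisq(v, k) * stats::pchisq((c + b * v) / a, k,
                                        lower.tail = FALSE)
  }
  stats::integrate(f, 0, Inf, rel.tol = 1e-9, abs.tol = 1e-300)$value
}

#' Local genetic covariance in one region
#'
#' Estimates the genetic covariance attributable to a single genomic
#' region from the two Z-score vectors restricted to it.  With the region
#' LD matrix eigendecomposed as `R = U L U'` and truncated at rank k, the
#' estimator is
#' `local_cov = (z1' Uk Lk^-1 Uk' z2 - k * c) / sqrt(N1 N2)`, where `c` is
#' the genome-wide cross-trait regression intercept (sample-overlap term);
#' local per-trait heritabilities subtract the analogous `k * intercept`
#' chi-square bias and divide by N.  The reported standard error comes from
#' the asymptotic quadratic-form variance; the p-value is computed from the
#' exact null law of the bilinear form, a scaled difference of two
#' independent chi-square(k) variables, which is noticeably heavier-tailed
#' than its normal approximation at scan-level significance thresholds.
#'
#' @param ss1,ss2 [sumstats()] objects.
#' @param panel a `ref_panel` covering the region.
#' @param region a single-interval [region_set()] (or one row of one).
#' @param gcov_intercept genome-wide cross-trait intercept estimate
#'   (default 0: disjoint studies).
#' @param intercept1,intercept2 genome-wide single-trait LD score
#'   regression intercepts (default 1).
#' @param k eigen-truncation rank; `NULL` keeps the directions carrying
#'   99.9% of the LD-matrix trace.
#' @param spectrum optional precomputed element of `region_spectra()`.
#' @return An object of class `local_result`: list with `local_h2_1`,
#'   `local_h2_2`, `local_cov`, `se`, `p`, `k_eigen`, `n_snps` and the
#'   region.
#' @export
local_genetic_covariance <- function(ss1, ss2, panel, region,
                                     gcov_intercept = 0,
                                     intercept1 = 1, intercept2 = 1,
                                     k = NULL, spectrum = NULL) {
  stopifnot(inherits(ss1, "sumstats"), inherits(ss2, "sumstats"))
  if (is.null(spectrum)) {
    spectrum <- region_spectra(panel, region)[[1]]
  }
  ids <- spectrum$snp_id
  i1 <- match(ids, ss1$snps$snp_id)
  i2 <- match(ids, ss2$snps$snp_id)
  ok <- !is.na(i1) & !is.na(i2)
  if (sum(ok) < 2) stop("region has fewer than 2 SNPs present in both traits")
  if (!all(ok)) {
    # restrict the spectrum to the SNPs available in both tables
    keep_ids <- ids[ok]
    sub <- region_spectra_subset(panel, keep_ids)
    spectrum <- sub
    ids <- spectrum$snp_id
    i1 <- match(ids, ss1$snps$snp_id)
    i2 <- match(ids, ss2$snps$snp_id)
  }
  z1 <- ss1$snps$z[i1]
  z2 <- ss2$snps$z[i2]
  n1 <- mean(ss1$snps$n[i1])
  n2 <- mean(ss2$snps$n[i2])

  lam <- spectrum$eig$values
  k_use <- choose_rank(lam, k)
  U <- spectrum$eig$vectors[, seq_len(k_use), drop = FALSE]
  w1 <- drop(crossprod(U, z1)) / sqrt(lam[seq_len(k_use)])
  w2 <- drop(crossprod(U, z2)) / sqrt(lam[seq_len(k_use)])
  q11 <- sum(w1^2)
  q22 <- sum(w2^2)
  q12 <- sum(w1 * w2)

  local_h2_1 <- (q11 - k_use * intercept1) / n1
  local_h2_2 <- (q22 - k_use * intercept2) / n2
  t_obs <- q12 - k_use * gcov_intercept
  local_cov <- t_obs / sqrt(n1 * n2)

  # asymptotic quadratic-form variance with plug-in signal terms
  s1 <- max(q11 - k_use * intercept1, 0)
  s2 <- max(q22 - k_use * intercept2, 0)
  var_q <- intercept2 * s1 + intercept1 * s2 +
    2 * gcov_intercept * t_obs +
    k_use * (intercept1 * intercept2 + gcov_intercept^2)
  se <- sqrt(max(var_q, 0)) / sqrt(n1 * n2)

  # Exact null of q12 as a scaled difference of two independent chi2_k
  # variables.  The null scales are the regions' own marginal signal
  # levels (floored at the genome-wide intercepts), so that polygenic
  # background heritability without excess local sharing is part of the
  # null rather than a source of false positives.
  s1n <- max(intercept1, q11 / k_use)
  s2n <- max(intercept2, q22 / k_use)
  s12 <- sqrt(s1n * s2n)
  r <- gcov_intercept / s12
  r <- max(min(r, 1), -1)
  a <- s12 * (1 + r) / 2
  b <- s12 * (1 - r) / 2
  t_abs <- abs(t_obs)
  mu0 <- k_use * gcov_intercept
  p_hi <- pq_chisq_diff(mu0 + t_abs, a, b, k_use)
  p_lo <- 1 - pq_chisq_diff(mu0 - t_abs, a, b, k_use)
  p <- min(1, max(p_hi + p_lo, .Machine$double.xmin))

  structure(
    list(region = region, n_snps = length(ids), k_eigen = k_use,
         local_h2_1 = local_h2_1, local_h2_2 = local_h2_2,
         local_cov = local_cov, se = se, p = p),
    class = "local_result"
  )
}

# Spectrum for an arbitrary SNP id subset (block-diagonal LD submatrix).
region_spectra_subset <- function(panel, keep_ids) {
  map <- panel_snp_map(panel)
  idx <- match(keep_ids, map$snp_id)
  stopifnot(!anyNA(idx))
  bs <- panel$block_size
  n <- length(idx)
  R <- matrix(0, n, n)
  for (b in unique(map$block[idx])) {
    sel <- which(map$block[idx] == b)
    within <- idx[sel] - (b - 1) * bs
    R[sel, sel] <- panel$blocks[[b]]$R[within, within, drop = FALSE]
  }
  list(snp_id = keep_ids, eig = eigen(R, symmetric = TRUE))
}

#' @export
print.local_result <- function(x, digits = 4, ...) {
  cat("Local genetic covariance: ", signif(x$local_cov, digits),
      " (se ", signif(x$se, digits), ", p ", signif(x$p, 3), ")\n", sep = "")
  cat("  local h2: ", signif(x$local_h2_1, digits), " / ",
      signif(x$local_h2_2, digits),
      "  [", x$n_snps, " SNPs, rank ", x$k_eigen, "]\n", sep = "")
  invisible(x)
}

#' Genome-wide local covariance scan
#'
#' Runs [local_genetic_covariance()] over every region of a partition and
#' flags regions significant at the Bonferroni threshold
#' `alpha / n_regions` (e.g. 0.05/1703 = 2.9e-5 for a 1703-region
#' European-LD partition).
#'
#' @param ss1,ss2 [sumstats()] objects.
#' @param panel a `ref_panel`.
#' @param partition partition input for [partition_for_scan()]; defaults
#'   to the panel blocks.
#' @param gcov_intercept,intercept1,intercept2 genome-wide intercepts,
#'   estimated once and reused for all regions (see
#'   [estimate_genetic_covariance()]).
#' @param alpha family-wise error rate (default 0.05).
#' @param k eigen-truncation rank passed to each region.
#' @param spectra optional precomputed [region_spectra()] list for repeated
#'   scans over the same panel/partition.
#' @return A data frame (class `local_scan`) with one row per region:
#'   `chrom`, `start`, `end`, `n_snps`, `k_eigen`, `local_h2_1`,
#'   `local_h2_2`, `local_cov`, `se`, `p`, `significant`; the Bonferroni
#'   threshold is attached as attribute `threshold`.
#' @export
local_scan <- function(ss1, ss2, panel, partition = NULL,
                       gcov_intercept = 0, intercept1 = 1, intercept2 = 1,
                       alpha = 0.05, k = NULL, spectra = NULL) {
  partition <- partition_for_scan(if (is.null(partition)) panel
                                  else partition)
  if (is.null(spectra)) spectra <- region_spectra(panel, partition)
  n_regions <- nrow(partition)
  thr <- significance_threshold(n_regions, alpha)
  rows <- vector("list", n_regions)
  for (r in seq_len(n_regions)) {
    res <- local_genetic_covariance(
      ss1, ss2, panel, partition[r, , drop = FALSE],
      gcov_intercept = gcov_intercept,
      intercept1 = intercept1, intercept2 = intercept2,
      k = k, spectrum = spectra[[r]]
    )
    rows[[r]] <- data.frame(
      chrom = partition$chrom[r], start = partition$start[r],
      end = partition$end[r], n_snps = res$n_snps, k_eigen = res$k_eigen,
      local_h2_1 = res$local_h2_1, local_h2_2 = res$local_h2_2,
      local_cov = res$local_cov, se = res$se, p = res$p,
      significant = res$p < thr
    )
  }
  out <- do.call(rbind, rows)
  attr(out, "threshold") <- thr
  class(out) <- c("local_scan", "data.frame")
  out
}

#' @export
print.local_scan <- function(x, ...) {
  cat("Local covariance scan:", nrow(x), "regions, threshold",
      signif(attr(x, "threshold"), 3), "\n")
  cat("  significant regions:", sum(x$significant), "\n")
  cat("  sum of local h2:", signif(sum(x$local_h2_1), 4), "/",
      signif(sum(x$local_h2_2), 4), "\n")
  invisible(x)
}
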