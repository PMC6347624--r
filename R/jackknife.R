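#' Estimates with delete-one-block jackknife errors
#'
#' Container used for every regression-derived quantity in the package
#' (heritability, intercepts, genetic covariance and correlation,
#' per-category coefficients, enrichments).  The standard error is the
#' delete-one-block jackknife estimate over `n_blocks` contiguous genome
#' blocks, `se^2 = (n-1)/n * sum((d_i - mean(d))^2)`, and the p-value is
#' two-sided normal on `value / se`.
#'
#' @param value point estimate from the full data.
#' @param delete_values numeric vector of delete-one-block estimates.
#' @return An object of class `ldsc_est` with fields `value`, `se`,
#'   `delete_values`, `z` and `p`.
#' @export
estimate_with_error <- function(value, delete_values) {
  n <- length(delete_values)
  se <- if (n >= 2) {
    sqrt((n - 1) / n * sum((delete_values - mean(delete_values))^2))
  } else {
    NA_real_
  }
  z <- if (isTRUE(se > 0)) value / se else NA_real_
  p <- if (is.na(z)) NA_real_ else 2 * stats::pnorm(-abs(z))
  structure(list(value = value, se = se, delete_values = delete_values,
                 z = z, p = p),
            class = "ldsc_est")
}

#' @export
print.ldsc_est <- function(x, digits = 4, ...) {
  cat(format(signif(x$value, digits)), " (se ",
      format(signif(x$se, digits)), ", p ",
      format(signif(x$p, 3)), ")\n", sep = "")
  invisible(x)
}

# Jackknife covariance of two estimates sharing a block scheme.
jackknife_cov <- function(d1, d2) {
  n <- length(d1)
  stopifnot(length(d2) == n, n >= 2)
  (n - 1) / n * sum((d1 - mean(d1)) * (d2 - mean(d2)))
}

# Contiguous equal-count block assignment for n ordered SNPs.
assign_blocks <- function(n, n_blocks) {
  stopifnot(n >= n_blocks)
  ceiling(seq_len(n) * n_blocks / n)
}

# Weighted least squares with delete-one-block coefficient paths.
# X: n x p design (including intercept column), w: weights, block_id in
# 1..n_blocks.  Returns full coefficients and an n_blocks x p matrix of
# delete-block coefficients, computed from per-block cross-product sums.
wls_jackknife <- function(y, X, w, block_id) {
  X <- as.matrix(X)
  n <- nrow(X)
  p <- ncol(X)
  n_blocks <- max(block_id)
  Xw <- X * w
  # per-block X'WX (as p*p columns) and X'Wy
  cross_cols <- matrix(0, n, p * p)
  for (i in seq_len(p)) {
    for (j in seq_len(p)) {
      cross_cols[, (i - 1) * p + j] <- Xw[, i] * X[, j]
    }
  }
  A_blocks <- rowsum(cross_cols, block_id)
  b_blocks <- rowsum(Xw * y, block_id)
  A_tot <- colSums(A_blocks)
  b_tot <- colSums(b_blocks)
  A_full <- matrix(A_tot, p, p)
  qrA <- qr(A_full)
  if (qrA$rank < p) {
    stop("singular regression design (rank ", qrA$rank, " < ", p, ")")
  }
  coef_full <- drop(solve(qrA, b_tot))
  delete <- matrix(NA_real_, n_blocks, p)
  for (b in seq_len(n_blocks)) {
    A_b <- A_full - matrix(A_blocks[b, ], p, p)
    delete[b, ] <- drop(solve(A_b, b_tot - b_blocks[b, ]))
  }
  colnames(delete) <- colnames(X)
  names(coef_full) <- colnames(X)
  list(coef = coef_full, delete = delete, n_blocks = n_blocks)
}

# Heteroscedasticity/overcounting regression weights for the chi^2
# regression: w_j = 1 / (max(l_j, 1) * (1 + N h2 l_j / M)^2).
ldsc_weights_h2 <- function(l, n_bar, m_total, h2) {
  het <- pmax(1 + n_bar * max(h2, 0) * l / m_total, 0.05)
  1 / (pmax(l, 1) * het^2)
}

# Weights for the z1*z2 product regression; reduces to twice the single-trait
# weight when the two traits coincide.
ldsc_weights_gcov <- function(l, n1_bar, n2_bar, m_total, h2_1, h2_2,
                              rho, icpt) {
  t1 <- pmax(1 + n1_bar * max(h2_1, 0) * l / m_total, 0.05)
  t2 <- pmax(1 + n2_bar * max(h2_2, 0) * l / m_total, 0.05)
  cross <- sqrt(n1_bar * n2_bar) * rho * l / m_total + icpt
  1 / (pmax(l, 1) * (t1 * t2 + cross^2))
}
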