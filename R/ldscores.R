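#' LD scores from a reference panel
#'
#' The LD score of SNP j is `l_j = sum_k r^2(j, k)` over SNPs k within a
#' base-pair window of j (including j itself).  With the panel's exact
#' correlations no bias correction is needed; when the panel correlations
#' were estimated from `n_ref` genotype samples the unbiased adjustment
#' `r2_adj = r2 - (1 - r2) / (n_ref - 2)` removes finite-sample inflation.
#'
#' @param panel a [build_reference_panel()] result.
#' @param window_bp window radius in base pairs (default 1 Mb, a common
#'   1 cM surrogate).
#' @param n_ref optional reference-sample count for the unbiased r^2
#'   adjustment; `NULL` (default) treats correlations as exact.
#' @return An object of class `ldscore_table`: a data frame with columns
#'   `snp_id`, `chrom`, `pos` and `L2` (total LD score), with the window
#'   radius stored as attribute `window_bp`.
#' @export
compute_ld_scores <- function(panel, window_bp = 1e6, n_ref = NULL) {
  stopifnot(inherits(panel, "ref_panel"))
  if (length(panel$blocks) == 0) stop("empty reference panel")
  stopifnot(window_bp > 0)
  out <- lapply(panel$blocks, function(blk) {
    r2 <- block_r2(blk, window_bp, n_ref)
    data.frame(snp_id = blk$snp_id, chrom = blk$chrom, pos = blk$pos,
               L2 = rowSums(r2))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "window_bp") <- window_bp
  class(res) <- c("ldscore_table", "data.frame")
  res
}

# Windowed (and optionally bias-adjusted) squared-correlation matrix of a
# block; entries outside the window are zero.
block_r2 <- function(blk, window_bp, n_ref = NULL) {
  r2 <- blk$R^2
  if (!is.null(n_ref)) {
    stopifnot(n_ref > 2)
    r2 <- r2 - (1 - r2) / (n_ref - 2)
  }
  mask <- abs(outer(blk$pos, blk$pos, "-")) <= window_bp
  r2 * mask
}

#' Stratified (per-annotation) LD scores
#'
#' Computes `l_{j,c} = sum_k a_{k,c} r^2(j, k)` for every annotation
#' category c, within the same window as [compute_ld_scores()].  The `base`
#' column reproduces the total LD score, and scores are additive over any
#' disjoint covering of SNPs.
#'
#' @inheritParams compute_ld_scores
#' @param annotations an [annot_matrix()] aligned to the panel SNPs (same
#'   ids, same order).
#' @return An `ldscore_table` with one `L2_<category>` column per category;
#'   attribute `categories` lists the category names.
#' @export
compute_stratified_ld_scores <- function(panel, annotations,
                                         window_bp = 1e6, n_ref = NULL) {
  stopifnot(inherits(panel, "ref_panel"), inherits(annotations, "annot_matrix"))
  map_ids <- unlist(lapply(panel$blocks, function(b) b$snp_id))
  if (!identical(annotations$snp_id, map_ids)) {
    stop("annotation SNP ids are not aligned to the panel")
  }
  bs <- panel$block_size
  cats <- colnames(annotations$values)
  out <- lapply(seq_along(panel$blocks), function(b) {
    blk <- panel$blocks[[b]]
    idx <- (b - 1) * bs + seq_len(bs)
    r2 <- block_r2(blk, window_bp, n_ref)
    sc <- r2 %*% annotations$values[idx, , drop = FALSE]
    df <- data.frame(snp_id = blk$snp_id, chrom = blk$chrom, pos = blk$pos)
    cbind(df, as.data.frame(sc))
  })
  res <- do.call(rbind, out)
  names(res) <- c("snp_id", "chrom", "pos", paste0("L2_", cats))
  rownames(res) <- NULL
  attr(res, "window_bp") <- window_bp
  attr(res, "categories") <- cats
  class(res) <- c("ldscore_table", "data.frame")
  res
}

# Total LD score column of an ldscore_table (L2 or L2_base).
ld_total <- function(ld) {
  if ("L2" %in% names(ld)) return(ld$L2)
  if ("L2_base" %in% names(ld)) return(ld$L2_base)
  stop("LD score table lacks a total (L2 or L2_base) column")
}

#' MAF-bin annotations for a panel
#'
#' Indicator categories by minor-allele-frequency quantile bin, usable as
#' extra stratified-regression columns to adjust for frequency-dependent
#' architecture.
#'
#' @param panel a [build_reference_panel()] result.
#' @param n_bins number of MAF quantile bins.
#' @return An [annot_matrix()] with columns `mafbin_1` ... `mafbin_n`.
#' @export
maf_bin_annotations <- function(panel, n_bins = 5) {
  map <- panel_snp_map(panel)
  brks <- stats::quantile(map$maf, probs = seq(0, 1, length.out = n_bins + 1))
  brks[1] <- -Inf
  brks[n_bins + 1] <- Inf
  bin <- cut(map$maf, breaks = brks, labels = FALSE)
  values <- sapply(seq_len(n_bins), function(b) as.numeric(bin == b))
  colnames(values) <- paste0("mafbin_", seq_len(n_bins))
  annot_matrix(map$snp_id, values)
}

#' Write an LD score table as TSV
#'
#' @param ld an `ldscore_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ld_scores <- function(ld, path) {
  utils::write.table(as.data.frame(ld), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
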