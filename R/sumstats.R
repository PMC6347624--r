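#' GWAS summary-statistic tables
#'
#' A `sumstats` object holds per-SNP association summary records for one
#' trait: SNP identifier, chromosome (autosomes 1-22), 1-based position,
#' effect and other allele, signed Z-score, per-SNP sample size and
#' effect-allele frequency, plus trait metadata.  For binary (case-control)
#' traits the sample prevalence `P` and population prevalence `F` are carried
#' for liability-scale conversion.  Records are kept sorted by
#' (chromosome, position) with unique SNP ids.
#'
#' The standardized-effect convention used throughout is
#' `beta_j = z_j / sqrt(N_j)` with standard error `1/sqrt(N_j)`.
#'
#' @param snps data frame with columns `snp_id`, `chrom`, `pos`, `a1`
#'   (effect allele), `a2` (other allele), `z`, `n`, `eaf` and optionally `p`.
#' @param trait_name label for the trait.
#' @param trait_type `"quantitative"` or `"binary"`.
#' @param sample_prev,population_prev prevalences in (0,1); required iff
#'   `trait_type == "binary"`.
#' @param n_cases,n_controls optional case/control counts.
#' @param drop_invalid drop rows violating record invariants (with a message)
#'   instead of failing.
#' @return An object of class `sumstats`.
#' @export
sumstats <- function(snps, trait_name = "trait",
                     trait_type = c("quantitative", "binary"),
                     sample_prev = NULL, population_prev = NULL,
                     n_cases = NULL, n_controls = NULL,
                     drop_invalid = TRUE) {
  trait_type <- match.arg(trait_type)
  required <- c("snp_id", "chrom", "pos", "a1", "a2", "z", "n", "eaf")
  missing_cols <- setdiff(required, names(snps))
  if (length(missing_cols) > 0) {
    stop("missing summary-statistic columns: ",
         paste(missing_cols, collapse = ", "))
  }
  snps$snp_id <- as.character(snps$snp_id)
  snps$chrom <- suppressWarnings(as.integer(sub("^chr", "", snps$chrom)))
  snps$pos <- suppressWarnings(as.numeric(snps$pos))
  snps$a1 <- toupper(as.character(snps$a1))
  snps$a2 <- toupper(as.character(snps$a2))
  snps$z <- suppressWarnings(as.numeric(snps$z))
  snps$n <- suppressWarnings(as.numeric(snps$n))
  snps$eaf <- suppressWarnings(as.numeric(snps$eaf))
  if (!"p" %in% names(snps)) snps$p <- NA_real_
  snps$p <- suppressWarnings(as.numeric(snps$p))

  ok <- valid_snp_records(snps)
  if (any(!ok)) {
    if (!drop_invalid) stop(sum(!ok), " invalid summary-statistic rows")
    message("dropping ", sum(!ok), " row(s) failing record validation")
    snps <- snps[ok, , drop = FALSE]
  }
  if (nrow(snps) == 0) stop("no valid summary-statistic rows remain")
  if (anyDuplicated(snps$snp_id)) {
    stop("duplicated snp_id in summary statistics")
  }
  snps <- snps[order(snps$chrom, snps$pos), , drop = FALSE]
  rownames(snps) <- NULL

  if (trait_type == "binary") {
    if (is.null(sample_prev) || is.null(population_prev)) {
      stop("binary traits require sample_prev and population_prev")
    }
    stopifnot(sample_prev > 0, sample_prev < 1,
              population_prev > 0, population_prev < 1)
  } else {
    sample_prev <- NULL
    population_prev <- NULL
  }

  structure(
    list(snps = snps[, c(required, "p")],
         trait_name = trait_name,
         trait_type = trait_type,
         sample_prev = sample_prev,
         population_prev = population_prev,
         n_cases = n_cases,
         n_controls = n_controls),
    class = "sumstats"
  )
}

# Per-record invariants: autosome, valid distinct alleles, finite z, N > 0,
# eaf in (0,1), and p (when present) consistent with z to 1e-6.
valid_snp_records <- function(snps) {
  bases <- c("A", "C", "G", "T")
  ok <- !is.na(snps$chrom) & snps$chrom >= 1L & snps$chrom <= 22L &
    !is.na(snps$pos) & snps$pos >= 1 &
    snps$a1 %in% bases & snps$a2 %in% bases & snps$a1 != snps$a2 &
    is.finite(snps$z) & is.finite(snps$n) & snps$n > 0 &
    is.finite(snps$eaf) & snps$eaf > 0 & snps$eaf < 1
  has_p <- !is.na(snps$p)
  p_from_z <- 2 * stats::pnorm(-abs(snps$z))
  ok[has_p] <- ok[has_p] & abs(snps$p[has_p] - p_from_z[has_p]) <= 1e-6
  ok & !is.na(ok)
}

#' @export
print.sumstats <- function(x, ...) {
  cat("GWAS summary statistics: ", x$trait_name,
      " (", x$trait_type, "), ", nrow(x$snps), " SNPs\n", sep = "")
  if (x$trait_type == "binary") {
    cat("  sample prevalence P =", x$sample_prev,
        "; population prevalence F =", x$population_prev, "\n")
  }
  cat("  mean chi^2 =", round(mean(x$snps$z^2), 4), "\n")
  invisible(x)
}

#' @export
summary.sumstats <- function(object, ...) {
  s <- object$snps
  out <- list(trait_name = object$trait_name,
              trait_type = object$trait_type,
              n_snps = nrow(s),
              mean_chi2 = mean(s$z^2),
              lambda_gc = stats::median(s$z^2) / stats::qchisq(0.5, 1),
              maf_range = range(pmin(s$eaf, 1 - s$eaf)))
  class(out) <- "summary.sumstats"
  out
}

#' @export
print.summary.sumstats <- function(x, ...) {
  cat("Trait:", x$trait_name, "(", x$trait_type, ")\n")
  cat("SNPs:", x$n_snps, "\n")
  cat("Mean chi^2:", round(x$mean_chi2, 4),
      " lambda_GC:", round(x$lambda_gc, 4), "\n")
  cat("MAF range:", paste(signif(x$maf_range, 3), collapse = " - "), "\n")
  invisible(x)
}

# Canonical column dialect: SNP CHR BP A1 A2 Z N EAF [P]
canonical_dialect <- function() {
  c(snp_id = "SNP", chrom = "CHR", pos = "BP", a1 = "A1", a2 = "A2",
    z = "Z", n = "N", eaf = "EAF", p = "P")
}

#' Read GWAS summary statistics from a delimited text file
#'
#' Reads the canonical tab-separated dialect `SNP CHR BP A1 A2 Z N EAF [P]`
#' (A1 = effect allele) or any column naming described by `dialect`.  Rows
#' failing record validation (non-autosomal, bad alleles, missing Z,
#' out-of-range frequency, or a p-value inconsistent with Z) are dropped with
#' a message; a row with a p-value but no Z-score is dropped rather than
#' reconstructing a sign-unknown Z.
#'
#' @param path file path.
#' @param dialect named character vector mapping canonical field names
#'   (`snp_id`, `chrom`, `pos`, `a1`, `a2`, `z`, `n`, `eaf`, optionally `p`)
#'   to the file's column names.  Defaults to the canonical dialect.
#' @inheritParams sumstats
#' @return A [sumstats()] object.
#' @export
read_sumstats <- function(path, dialect = canonical_dialect(),
                          trait_name = basename(path),
                          trait_type = "quantitative",
                          sample_prev = NULL, population_prev = NULL) {
  if (!file.exists(path)) stop("summary-statistics file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = "",
                          stringsAsFactors = FALSE, check.names = FALSE)
  mandatory <- c("snp_id", "chrom", "pos", "a1", "a2", "z", "n", "eaf")
  miss <- setdiff(mandatory, names(dialect))
  if (length(miss) > 0) stop("dialect lacks mappings for: ",
                             paste(miss, collapse = ", "))
  unresolved <- setdiff(dialect[mandatory], names(df))
  if (length(unresolved) > 0) {
    stop("columns not found in file: ", paste(unresolved, collapse = ", "))
  }
  out <- data.frame(row.names = seq_len(nrow(df)))
  for (field in names(dialect)) {
    col <- dialect[[field]]
    if (col %in% names(df)) out[[field]] <- df[[col]]
  }
  sumstats(out, trait_name = trait_name, trait_type = trait_type,
           sample_prev = sample_prev, population_prev = population_prev)
}

#' Write summary statistics in the canonical dialect
#'
#' @param ss a [sumstats()] object.
#' @param path output path.
#' @param digits significant digits for numeric columns.
#' @return `path`, invisibly.
#' @export
write_sumstats <- function(ss, path, digits = 10) {
  stopifnot(inherits(ss, "sumstats"))
  s <- ss$snps
  out <- data.frame(SNP = s$snp_id, CHR = s$chrom, BP = s$pos,
                    A1 = s$a1, A2 = s$a2,
                    Z = signif(s$z, digits), N = s$n,
                    EAF = signif(s$eaf, digits))
  if (any(!is.na(s$p))) out$P <- signif(s$p, digits)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Harmonize summary statistics to reference alleles
#'
#' Aligns each record's effect allele to a reference allele map.  Records
#' whose alleles match the reference reversed get their Z-score and
#' effect-allele frequency flipped (`z -> -z`, `eaf -> 1 - eaf`);
#' strand-ambiguous records (A/T or C/G) and records absent from, or
#' inconsistent with, the reference are removed.  Applying the flip twice
#' restores the input, so harmonization is an involution on flipped records.
#'
#' @param ss a [sumstats()] object.
#' @param ref_alleles data frame with columns `snp_id`, `a1`, `a2` giving the
#'   reference effect/other alleles.
#' @return A harmonized [sumstats()] object.
#' @export
harmonize_to_reference <- function(ss, ref_alleles) {
  stopifnot(inherits(ss, "sumstats"))
  stopifnot(all(c("snp_id", "a1", "a2") %in% names(ref_alleles)))
  s <- ss$snps
  idx <- match(s$snp_id, ref_alleles$snp_id)
  ra1 <- toupper(ref_alleles$a1[idx])
  ra2 <- toupper(ref_alleles$a2[idx])

  comp <- c(A = "T", C = "G", G = "C", T = "A")
  ambiguous <- s$a1 == comp[s$a2]
  same <- !is.na(idx) & s$a1 == ra1 & s$a2 == ra2
  flipped <- !is.na(idx) & s$a1 == ra2 & s$a2 == ra1
  keep <- (same | flipped) & !ambiguous

  dropped <- sum(!keep)
  if (dropped > 0) {
    message("harmonization removed ", dropped,
            " SNP(s) (ambiguous or unmatched)")
  }
  s <- s[keep, , drop = FALSE]
  fl <- flipped[keep]
  s$z[fl] <- -s$z[fl]
  s$eaf[fl] <- 1 - s$eaf[fl]
  tmp <- s$a1[fl]
  s$a1[fl] <- s$a2[fl]
  s$a2[fl] <- tmp
  replace_snps(ss, s)
}

# Internal: swap in a new SNP table, preserving trait metadata.
replace_snps <- function(ss, snps) {
  if (nrow(snps) == 0) stop("no SNPs remain for trait ", ss$trait_name)
  ss$snps <- snps[order(snps$chrom, snps$pos), , drop = FALSE]
  rownames(ss$snps) <- NULL
  ss
}

#' Apply quality-control filters to summary statistics
#'
#' Retains autosomal SNPs with minor allele frequency above `maf_min`
#' (default 1%), restricted to an optional keep-list (a HapMap3-like SNP
#' panel in typical use), and outside all excluded intervals (the MHC region
#' by default).  Filtering is idempotent.
#'
#' @param ss a [sumstats()] object.
#' @param maf_min minimum minor allele frequency (exclusive bound).
#' @param keep_list optional character vector of SNP ids to retain.
#' @param exclude a [region_set()] of intervals to remove; defaults to the
#'   MHC interval from [mhc_region()].  Use `region_set()` for no exclusion.
#' @return The filtered [sumstats()] object.
#' @export
apply_qc_filters <- function(ss, maf_min = 0.01, keep_list = NULL,
                             exclude = mhc_region()) {
  stopifnot(inherits(ss, "sumstats"))
  s <- ss$snps
  maf <- pmin(s$eaf, 1 - s$eaf)
  keep <- maf > maf_min
  if (!is.null(keep_list)) keep <- keep & s$snp_id %in% keep_list
  if (!is.null(exclude) && nrow(exclude) > 0) {
    keep <- keep & !in_regions(exclude, s$chrom, s$pos)
  }
  if (!any(keep)) {
    stop("QC removed every SNP for trait ", ss$trait_name,
         " (maf_min = ", maf_min, ", keep_list = ",
         if (is.null(keep_list)) "none" else length(keep_list), " ids)")
  }
  n_removed <- sum(!keep)
  if (n_removed > 0) message("QC removed ", n_removed, " SNP(s)")
  replace_snps(ss, s[keep, , drop = FALSE])
}
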