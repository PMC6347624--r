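#' SNP-by-category annotation matrices
#'
#' An `annot_matrix` holds per-SNP functional-category memberships used by
#' the stratified regression: binary indicators or non-negative continuous
#' values, one named column per category.  A `base` column equal to 1 for
#' every SNP is always present (added if missing) so the stratified model
#' nests the single-component model.
#'
#' @param snp_id character vector of SNP ids.
#' @param values numeric matrix (or data frame) with one named column per
#'   category; rows aligned to `snp_id`.
#' @return An object of class `annot_matrix` with elements `snp_id` and
#'   `values` (a numeric matrix including a `base` column).
#' @export
annot_matrix <- function(snp_id, values) {
  snp_id <- as.character(snp_id)
  values <- as.matrix(values)
  if (is.null(colnames(values)) || any(colnames(values) == "")) {
    stop("annotation columns must be named")
  }
  if (anyDuplicated(colnames(values))) stop("duplicated category names")
  if (nrow(values) != length(snp_id)) {
    stop("annotation rows must align with snp_id")
  }
  storage.mode(values) <- "double"
  if (any(!is.finite(values)) || any(values < 0)) {
    stop("annotation values must be finite and non-negative")
  }
  if (!"base" %in% colnames(values)) {
    values <- cbind(base = rep(1, length(snp_id)), values)
  } else if (any(values[, "base"] != 1)) {
    stop("base column must equal 1 for all SNPs")
  }
  structure(list(snp_id = snp_id, values = values), class = "annot_matrix")
}

#' @export
print.annot_matrix <- function(x, ...) {
  cat("Annotation matrix:", length(x$snp_id), "SNPs x",
      ncol(x$values), "categories\n")
  cat("  categories:", paste(utils::head(colnames(x$values), 8),
                             collapse = ", "),
      if (ncol(x$values) > 8) "..." else "", "\n")
  invisible(x)
}

#' Read an annotation matrix from TSV
#'
#' Expects a header with a `SNP` column followed by one column per category.
#'
#' @param path file path.
#' @return An [annot_matrix()].
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = "",
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (!"SNP" %in% names(df)) stop("annotation file needs a SNP column")
  annot_matrix(df$SNP, as.matrix(df[, setdiff(names(df), "SNP"),
                                    drop = FALSE]))
}

#' Write an annotation matrix as TSV
#'
#' @param annot an [annot_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(annot, path) {
  stopifnot(inherits(annot, "annot_matrix"))
  df <- data.frame(SNP = annot$snp_id, annot$values, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Union annotation categories into groups
#'
#' Builds one annotation column per group as the union of its member
#' categories: for binary memberships the indicator that any member is 1,
#' and in general the elementwise maximum (so continuous memberships are
#' handled consistently and the union is idempotent).
#'
#' @param annot an [annot_matrix()].
#' @param groups named list mapping group names to character vectors of
#'   existing category names.
#' @return An [annot_matrix()] with a `base` column plus one column per
#'   group.
#' @export
union_annotations <- function(annot, groups) {
  stopifnot(inherits(annot, "annot_matrix"))
  stopifnot(is.list(groups), length(groups) > 0, !is.null(names(groups)))
  unknown <- setdiff(unique(unlist(groups)), colnames(annot$values))
  if (length(unknown) > 0) {
    stop("unknown annotation categories: ", paste(unknown, collapse = ", "))
  }
  cols <- lapply(groups, function(members) {
    do.call(pmax, lapply(members,
                         function(m) annot$values[, m]))
  })
  values <- do.call(cbind, cols)
  colnames(values) <- names(groups)
  annot_matrix(annot$snp_id, values)
}

#' Build annotations from genomic region tracks
#'
#' Converts BED-like interval tracks into binary SNP membership columns.
#'
#' @param snp_id,chrom,pos SNP ids with their coordinates (1-based `pos`).
#' @param tracks named list of [region_set()] objects, one per category.
#' @return An [annot_matrix()].
#' @export
annotations_from_regions <- function(snp_id, chrom, pos, tracks) {
  stopifnot(is.list(tracks), !is.null(names(tracks)))
  cols <- lapply(tracks, function(rs) as.numeric(in_regions(rs, chrom, pos)))
  values <- do.call(cbind, cols)
  colnames(values) <- names(tracks)
  annot_matrix(snp_id, values)
}
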