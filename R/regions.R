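#' Genomic region sets
#'
#' A `region_set` is a set of genomic intervals in 0-based half-open
#' coordinates `[start, end)`, normalized so that intervals are sorted by
#' (chromosome, start) and non-overlapping within a chromosome (overlapping
#' or book-ended input intervals are merged).  SNP positions throughout the
#' package are 1-based, so a SNP at position `pos` falls inside an interval
#' when `start <= pos - 1 < end`.
#'
#' @param chrom integer chromosome codes (1-22).
#' @param start,end interval bounds, `start < end`, 0-based half-open.
#' @return An object of class `region_set`: a data frame with columns
#'   `chrom`, `start`, `end`.
#' @examples
#' rs <- region_set(c(1, 1), c(100, 150), c(200, 300))
#' nrow(rs)  # merged into one interval [100, 300)
#' @export
region_set <- function(chrom = integer(), start = numeric(), end = numeric()) {
  chrom <- as.integer(chrom)
  start <- as.numeric(start)
  end <- as.numeric(end)
  if (length(chrom) != length(start) || length(start) != length(end)) {
    stop("chrom, start and end must have equal length")
  }
  if (any(start < 0) || any(start >= end)) {
    stop("regions require 0 <= start < end")
  }
  df <- data.frame(chrom = chrom, start = start, end = end)
  df <- merge_regions(df)
  class(df) <- c("region_set", "data.frame")
  df
}

# Merge overlapping/book-ended intervals within chromosome; sort output.
merge_regions <- function(df) {
  if (nrow(df) == 0) {
    return(df[0, c("chrom", "start", "end")])
  }
  df <- df[order(df$chrom, df$start, df$end), , drop = FALSE]
  out <- vector("list", nrow(df))
  n_out <- 0L
  cur <- df[1, ]
  for (i in seq_len(nrow(df))[-1]) {
    row <- df[i, ]
    if (row$chrom == cur$chrom && row$start <= cur$end) {
      cur$end <- max(cur$end, row$end)
    } else {
      n_out <- n_out + 1L
      out[[n_out]] <- cur
      cur <- row
    }
  }
  out[[n_out + 1L]] <- cur
  res <- do.call(rbind, out[seq_len(n_out + 1L)])
  rownames(res) <- NULL
  res
}

#' Test SNP membership in a region set
#'
#' @param regions a [region_set()].
#' @param chrom,pos integer chromosome and 1-based position vectors.
#' @return Logical vector, `TRUE` where the SNP lies inside some interval.
#' @export
in_regions <- function(regions, chrom, pos) {
  stopifnot(inherits(regions, "region_set"))
  inside <- logical(length(pos))
  if (nrow(regions) == 0 || length(pos) == 0) {
    return(inside)
  }
  p0 <- pos - 1  # 0-based
  for (i in seq_len(nrow(regions))) {
    inside <- inside |
      (chrom == regions$chrom[i] & p0 >= regions$start[i] & p0 < regions$end[i])
  }
  inside
}

#' Default MHC exclusion interval
#'
#' The major histocompatibility complex on chromosome 6 has atypically
#' long-range LD and is conventionally removed from LD score regression
#' analyses.  Bounds are configurable; the default covers
#' chr6:25,000,000-34,000,000.
#'
#' @param start,end interval bounds (0-based half-open).
#' @return A [region_set()] with the single MHC interval.
#' @export
mhc_region <- function(start = 25e6, end = 34e6) {
  region_set(6L, start, end)
}

#' Read a BED-like region file
#'
#' Expects whitespace/tab-delimited columns `chrom start end [name]`, with or
#' without a header line; `chr` prefixes on the chromosome are tolerated.
#'
#' @param path file path.
#' @return A [region_set()].
#' @export
read_regions <- function(path) {
  if (!file.exists(path)) stop("region file not found: ", path)
  first <- readLines(path, n = 1)
  has_header <- grepl("start|chrom", tolower(first))
  df <- utils::read.table(path, header = has_header, sep = "",
                          stringsAsFactors = FALSE)
  chrom <- as.integer(sub("^chr", "", as.character(df[[1]])))
  region_set(chrom, as.numeric(df[[2]]), as.numeric(df[[3]]))
}

#' Write a region set as BED-like TSV
#'
#' @param regions a [region_set()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_regions <- function(regions, path) {
  stopifnot(inherits(regions, "region_set"))
  utils::write.table(as.data.frame(regions), path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' @export
print.region_set <- function(x, ...) {
  cat("Region set:", nrow(x), "interval(s) on",
      length(unique(x$chrom)), "chromosome(s)\n")
  if (nrow(x) > 0) print(utils::head(as.data.frame(x), 10))
  invisible(x)
}
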