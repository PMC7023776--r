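# Readers and writers for the on-disk formats: tab-separated beta matrices,
# Bismark coverage files, BED capture regions, signature / annotation /
# sample-sheet tables. Coordinates are 1-based inclusive internally
# (Bismark convention); BED output is converted to 0-based half-open.

#' Read a beta-value matrix from a tab-separated file
#'
#' Expected layout: header line, first three columns `id`, `chrom`, `pos`,
#' remaining columns one per sample. Values must be in `[0, 1]` or `NA`.
#'
#' @param path file path.
#' @param channel assay channel, see [beta_matrix()].
#' @return a `beta_matrix`.
#' @export
read_beta_matrix <- function(path, channel = c("standard", "tab", "mc_specific")) {
  channel <- match.arg(channel)
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                          colClasses = NA, na.strings = c("NA", ""))
  if (ncol(df) < 4) stopf("%s: expected id/chrom/pos plus >=1 sample column", path)
  if (nrow(df) == 0) stopf("%s: no CpG rows", path)
  samp <- names(df)[-(1:3)]
  for (j in seq_along(samp)) {
    col <- df[[j + 3]]
    if (!is.numeric(col)) {
      bad <- which(!is.na(col) & is.na(suppressWarnings(as.numeric(col))))
      stopf("%s: non-numeric value '%s' at data row %d, column '%s'",
            path, col[bad[1]], bad[1], samp[j])
    }
  }
  vals <- as.matrix(df[, -(1:3), drop = FALSE])
  storage.mode(vals) <- "double"
  colnames(vals) <- samp
  bad <- which(!is.na(vals) & (vals < 0 | vals > 1))
  if (length(bad)) {
    rc <- arrayInd(bad[1], dim(vals))
    stopf("%s: beta value %g outside [0,1] at data row %d, column '%s'",
          path, vals[bad[1]], rc[1], samp[rc[2]])
  }
  sites <- data.frame(id = as.character(df[[1]]), chrom = as.character(df[[2]]),
                      pos = as.integer(df[[3]]))
  beta_matrix(vals, sites, channel = channel)
}

#' Write a beta matrix as a tab-separated file
#'
#' Round-trips with [read_beta_matrix()] to 6 decimals.
#'
#' @param x a `beta_matrix`.
#' @param path destination.
#' @param digits decimal digits for beta values.
#' @return `path`, invisibly.
#' @export
write_beta_matrix <- function(x, path, digits = 6) {
  stopifnot(inherits(x, "beta_matrix"))
  out <- data.frame(id = x$sites$id, chrom = x$sites$chrom, pos = x$sites$pos,
                    round(x$values, digits), check.names = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a Bismark coverage file
#'
#' Six tab-separated columns: chrom, start, end (1-based inclusive),
#' percent methylation, methylated read count, unmethylated read count.
#' The percent column is recomputed from the counts; a discrepancy beyond
#' 0.5 percentage points raises a warning (rounding tolerance). Records
#' with zero depth are retained and flagged `no_coverage`.
#'
#' @param path file path.
#' @return data.frame with columns `chrom, start, end, pct_meth, count_meth,
#'   count_unmeth, depth, no_coverage`, in file order.
#' @export
read_bismark_cov <- function(path) {
  df <- utils::read.delim(path, header = FALSE, sep = "\t",
                          colClasses = c("character", "integer", "integer",
                                         "numeric", "integer", "integer"))
  if (ncol(df) != 6) stopf("%s: expected 6 columns, found %d", path, ncol(df))
  names(df) <- c("chrom", "start", "end", "pct_meth", "count_meth", "count_unmeth")
  if (any(df$count_meth < 0 | df$count_unmeth < 0))
    stopf("%s: negative read counts", path)
  df$depth <- df$count_meth + df$count_unmeth
  df$no_coverage <- df$depth == 0
  recomputed <- ifelse(df$depth > 0, 100 * df$count_meth / df$depth, NA_real_)
  off <- which(!is.na(recomputed) & abs(recomputed - df$pct_meth) > 0.5)
  if (length(off))
    warnf("%s: %d record(s) where the stated %% methylation disagrees with the counts (first at line %d: stated %.4g, recomputed %.4g)",
          path, length(off), off[1], df$pct_meth[off[1]], recomputed[off[1]])
  df
}

#' Write Bismark-style coverage records
#'
#' @param cov data.frame as returned by [read_bismark_cov()] (extra columns
#'   are dropped).
#' @param path destination.
#' @return `path`, invisibly.
#' @export
write_bismark_cov <- function(cov, path) {
  need <- c("chrom", "start", "end", "pct_meth", "count_meth", "count_unmeth")
  stopifnot(all(need %in% names(cov)))
  out <- cov[, need]
  out$pct_meth <- formatC(out$pct_meth, format = "f", digits = 6)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read the EMT signature table
#'
#' Two tab-separated columns with header: `gene`, `klass` (one of
#' `epithelial`, `mesenchymal`).
#'
#' @param path file path.
#' @return data.frame with columns `gene`, `klass`.
#' @export
read_signature <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character")
  if (!all(c("gene", "klass") %in% names(df)))
    stopf("%s: expected columns gene, klass", path)
  if (anyDuplicated(df$gene)) stopf("%s: duplicate genes in signature", path)
  bad <- setdiff(unique(df$klass), c("epithelial", "mesenchymal"))
  if (length(bad)) stopf("%s: unknown class '%s'", path, bad[1])
  if (length(unique(df$klass)) < 2)
    stopf("%s: both epithelial and mesenchymal classes required", path)
  df[, c("gene", "klass")]
}

#' Read gene/TSS annotation
#'
#' Four tab-separated columns with header: `gene`, `chrom`, `tss`
#' (1-based), `strand` (`+` or `-`).
#'
#' @param path file path.
#' @return data.frame with one record per gene.
#' @export
read_gene_annotation <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = c("character", "character",
                                         "integer", "character"))
  if (!all(c("gene", "chrom", "tss", "strand") %in% names(df)))
    stopf("%s: expected columns gene, chrom, tss, strand", path)
  if (anyDuplicated(df$gene)) stopf("%s: duplicate gene records", path)
  bad <- setdiff(unique(df$strand), c("+", "-"))
  if (length(bad)) stopf("%s: unknown strand value '%s'", path, bad[1])
  df[, c("gene", "chrom", "tss", "strand")]
}

#' Read a longitudinal sample sheet
#'
#' Tab-separated with header; columns `patient, sample, day, status,
#' outcome`. Days must be non-negative and strictly increasing within a
#' patient.
#'
#' @param path file path.
#' @return data.frame of sample records.
#' @export
read_sample_sheet <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = c(day = "integer"))
  need <- c("patient", "sample", "day", "status", "outcome")
  if (!all(need %in% names(df)))
    stopf("%s: expected columns %s", path, paste(need, collapse = ", "))
  if (any(df$day < 0)) stopf("%s: negative treatment days", path)
  for (p in unique(df$patient)) {
    d <- df$day[df$patient == p]
    if (any(diff(d) <= 0))
      stopf("%s: days not strictly increasing for patient %s", path, p)
  }
  df[, need]
}

#' Write regions as BED (0-based half-open)
#'
#' Internal coordinates are 1-based inclusive; on export `start` becomes
#' `start - 1`.
#'
#' @param regions data.frame with columns `chrom, start, end` (1-based
#'   inclusive) and optionally `name`.
#' @param path destination.
#' @return `path`, invisibly.
#' @export
write_bed <- function(regions, path) {
  stopifnot(all(c("chrom", "start", "end") %in% names(regions)))
  out <- data.frame(chrom = regions$chrom,
                    start = regions$start - 1L,
                    end = regions$end,
                    name = regions$name %||% sprintf("region_%05d", seq_len(nrow(regions))))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED file into 1-based inclusive regions
#'
#' @param path file path.
#' @return data.frame with columns `chrom, start, end, name` (1-based
#'   inclusive coordinates).
#' @export
read_bed <- function(path) {
  df <- utils::read.delim(path, header = FALSE, sep = "\t")
  names(df)[1:3] <- c("chrom", "start", "end")
  df$start <- as.integer(df$start) + 1L
  df$end <- as.integer(df$end)
  df$name <- if (ncol(df) >= 4) as.character(df[[4]]) else NA_character_
  df[, c("chrom", "start", "end", "name")]
}
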