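#' Construct a CpG-by-sample beta-value matrix
#'
#' The central container of the package: per-CpG methylation fractions
#' (beta values in `[0, 1]`) with genomic coordinates, as produced by
#' Illumina 450K/EPIC arrays or derived channels. Three channels are
#' distinguished: `standard` (total 5mC + 5hmC signal of a conventional
#' bisulfite array), `tab` (TET-assisted bisulfite readout, reflecting
#' 5hmC only), and `mc_specific` (standard minus TAB, i.e. true 5mC).
#'
#' @param values numeric matrix, CpGs in rows, samples in columns. `NA`
#'   encodes missing values and is excluded pairwise downstream.
#' @param sites data.frame with columns `id`, `chrom`, `pos` (1-based
#'   position of the CpG cytosine), one row per row of `values`.
#' @param channel one of `"standard"`, `"tab"`, `"mc_specific"`.
#' @return an object of class `beta_matrix`: a list with elements
#'   `values`, `sites`, `samples`, `channel`.
#' @examples
#' bm <- beta_matrix(matrix(c(0.1, 0.9), 1, 2,
#'                          dimnames = list("cpg1", c("A", "B"))),
#'                   data.frame(id = "cpg1", chrom = "chr1", pos = 100L))
#' @export
beta_matrix <- function(values, sites, channel = c("standard", "tab", "mc_specific")) {
  channel <- match.arg(channel)
  values <- as.matrix(values)
  if (!is.numeric(values)) stopf("beta values must be numeric")
  sites <- as.data.frame(sites)
  need <- c("id", "chrom", "pos")
  if (!all(need %in% names(sites)))
    stopf("sites must have columns %s", paste(need, collapse = ", "))
  if (nrow(sites) != nrow(values))
    stopf("sites (%d rows) do not match values (%d rows)", nrow(sites), nrow(values))
  if (anyDuplicated(sites$id)) stopf("duplicate CpG ids in sites")
  if (any(sites$pos < 1)) stopf("CpG positions must be >= 1")
  bad <- which(!is.na(values) & (values < 0 | values > 1))
  if (length(bad)) {
    rc <- arrayInd(bad[1], dim(values))
    stopf("beta value outside [0,1] at row %d (%s), column %d (%s): %g",
          rc[1], sites$id[rc[1]], rc[2], colnames(values)[rc[2]] %||% rc[2],
          values[bad[1]])
  }
  rownames(values) <- sites$id
  structure(list(values = values, sites = sites,
                 samples = colnames(values), channel = channel),
            class = "beta_matrix")
}

#' @export
print.beta_matrix <- function(x, ...) {
  cat(sprintf("<beta_matrix> %d CpGs x %d samples, channel '%s', %d missing\n",
              nrow(x$values), ncol(x$values), x$channel, sum(is.na(x$values))))
  invisible(x)
}

#' @export
dim.beta_matrix <- function(x) dim(x$values)

#' Subset a beta matrix by CpG ids and/or samples
#'
#' @param x a `beta_matrix`.
#' @param sites character vector of CpG ids (default: all).
#' @param samples character vector of sample ids (default: all).
#' @return a `beta_matrix`.
#' @export
subset_beta <- function(x, sites = NULL, samples = NULL) {
  stopifnot(inherits(x, "beta_matrix"))
  ri <- if (is.null(sites)) seq_len(nrow(x$values)) else match(sites, x$sites$id)
  if (anyNA(ri)) stopf("unknown CpG id(s): %s",
                       paste(utils::head(sites[is.na(ri)], 3), collapse = ", "))
  ci <- if (is.null(samples)) seq_len(ncol(x$values)) else match(samples, x$samples)
  if (anyNA(ci)) stopf("unknown sample(s): %s",
                       paste(utils::head(samples[is.na(ci)], 3), collapse = ", "))
  beta_matrix(x$values[ri, ci, drop = FALSE], x$sites[ri, , drop = FALSE],
              channel = x$channel)
}

#' Per-CpG cohort means of a beta matrix
#'
#' Unweighted mean across samples, pairwise-complete (NAs dropped per CpG).
#'
#' @param x a `beta_matrix`.
#' @return named numeric vector, one mean per CpG id.
#' @export
cohort_means <- function(x) {
  stopifnot(inherits(x, "beta_matrix"))
  rowMeans(x$values, na.rm = TRUE)
}
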