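#' Map CpGs to gene promoter windows
#'
#' The promoter of a gene is the window from `upstream` bp upstream to
#' `downstream` bp downstream of its transcription start site, both
#' endpoints inclusive in 1-based coordinates. "Upstream" is
#' strand-relative: for a `+` gene the window is
#' `[tss - upstream, tss + downstream]`, for a `-` gene
#' `[tss - downstream, tss + upstream]`. A CpG lying in overlapping
#' promoters is assigned to every overlapping gene.
#'
#' @param sites data.frame of CpGs with columns `id, chrom, pos`.
#' @param genes data.frame with columns `gene, chrom, tss, strand`.
#' @param upstream bp upstream of the TSS (default 2000).
#' @param downstream bp downstream of the TSS (default 500).
#' @return named list mapping each gene to a character vector of CpG ids
#'   (possibly empty).
#' @export
annotate_promoters <- function(sites, genes, upstream = 2000, downstream = 500) {
  stopifnot(upstream >= 0, downstream >= 0)
  bad <- setdiff(unique(genes$strand), c("+", "-"))
  if (length(bad)) stopf("unknown strand value '%s'", bad[1])
  win_lo <- ifelse(genes$strand == "+", genes$tss - upstream, genes$tss - downstream)
  win_hi <- ifelse(genes$strand == "+", genes$tss + downstream, genes$tss + upstream)
  out <- vector("list", nrow(genes))
  names(out) <- genes$gene
  # group CpGs by chromosome once; per gene a vectorized interval test
  by_chrom <- split(seq_len(nrow(sites)), sites$chrom)
  for (i in seq_len(nrow(genes))) {
    idx <- by_chrom[[genes$chrom[i]]]
    if (is.null(idx)) { out[[i]] <- character(0); next }
    p <- sites$pos[idx]
    out[[i]] <- sites$id[idx[p >= win_lo[i] & p <= win_hi[i]]]
  }
  out
}
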