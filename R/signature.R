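#' The packaged 50-gene EMT signature (synthetic stand-in)
#'
#' A 50-gene epithelial/mesenchymal marker signature: 16 epithelial and 34
#' mesenchymal genes. The gene list is a *synthetic stand-in*: it contains
#' the canonical EMT markers (CDH1, EPCAM, VIM, CDH2, ZEB1/2, the
#' miR-200-regulated mesenchymal effectors, the 13 markers known to be
#' unreliable in healthy cfDNA, ...) padded with standard EMT genes, with
#' class labels constrained so that the documented class totals hold both
#' before (16/34) and after (9/28) cfDNA marker exclusion. It is not a
#' published supplementary table.
#'
#' @return data.frame with columns `gene`, `klass`.
#' @seealso [cfdna_excluded_markers()], [read_signature()]
#' @export
emt_signature <- function() {
  read_signature(system.file("extdata", "emt_signature_synthetic.tsv",
                             package = "methylEMT", mustWork = TRUE))
}

#' EMT markers excluded from cfDNA analysis
#'
#' Thirteen signature genes whose promoters show variable or high
#' methylation in the cell-free DNA of healthy individuals, violating the
#' `M_cfDNA ~ 0` assumption of tumor-methylome reconstruction; they are
#' dropped from all liquid-biopsy EMT scoring.
#'
#' @return character vector of 13 gene symbols.
#' @export
cfdna_excluded_markers <- function() {
  c("WNT5A", "VCAM1", "SPARC", "MMP9", "GRHL2", "CTNNB1", "CTNNA1",
    "COL8A2", "COL5A2", "COL4A2", "COL3A1", "COL1A2", "AXL")
}

#' The five candidate housekeeping genes for RT-qPCR normalization
#'
#' @return character vector of 5 gene symbols.
#' @export
housekeeper_candidates <- function() {
  c("ACTB", "B2M", "GAPDH", "UBC", "YWHAZ")
}
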