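# Differential methylation: delta-beta computation, promoter-level EMT
# methylation scoring, hyper/hypo CpG calling, the shared-overlap binomial
# test, quadrant enrichment, and TAB-based 5mC separation.

#' Separate true 5mC from a standard/TAB array pair
#'
#' The standard bisulfite array reads 5mC + 5hmC; the TET-assisted
#' bisulfite (TAB) array reads 5hmC. The 5mC-specific signal is the
#' difference, floored at zero.
#'
#' @param standard `beta_matrix`, channel `standard`.
#' @param tab `beta_matrix`, channel `tab`, same sites and samples.
#' @return `beta_matrix` with channel `mc_specific`; attribute
#'   `n_floored` counts negative differences floored at 0.
#' @export
split_5mc <- function(standard, tab) {
  stopifnot(inherits(standard, "beta_matrix"), inherits(tab, "beta_matrix"))
  if (!identical(standard$sites$id, tab$sites$id))
    stopf("site sets differ between standard and TAB matrices")
  if (!identical(standard$samples, tab$samples))
    stopf("sample sets differ between standard and TAB matrices")
  d <- standard$values - tab$values
  n_floor <- sum(d < 0, na.rm = TRUE)
  d[d < 0] <- 0
  out <- beta_matrix(d, standard$sites, channel = "mc_specific")
  attr(out, "n_floored") <- n_floor
  out
}

#' Call hyper-/hypomethylated CpGs between a parental and resistant line
#'
#' A CpG is hypermethylated when `beta_parental < lo` and
#' `beta_resistant > hi` (strict inequalities), hypomethylated in the
#' mirrored case, otherwise stable. CpGs missing in either sample are
#' excluded (counted in attribute `n_missing`).
#'
#' @param parental,resistant numeric beta vectors (equal length; names
#'   taken as CpG ids, else `ids`).
#' @param lo,hi thresholds, `lo < hi` (defaults 0.3 and 0.7).
#' @param ids optional CpG ids.
#' @return data.frame `id, beta_parental, beta_resistant, dbeta, call`
#'   with `call` in `{hyper, hypo, stable}`; rows with missing values are
#'   dropped.
#' @export
classify_dmcs <- function(parental, resistant, lo = 0.3, hi = 0.7, ids = NULL) {
  if (lo >= hi) stopf("lo (%g) must be below hi (%g)", lo, hi)
  if (length(parental) != length(resistant))
    stopf("parental and resistant vectors differ in length")
  ids <- ids %||% names(parental) %||% sprintf("cpg_%06d", seq_along(parental))
  keep <- is.finite(parental) & is.finite(resistant)
  n_missing <- sum(!keep)
  p <- parental[keep]; r <- resistant[keep]
  call <- rep("stable", length(p))
  call[p < lo & r > hi] <- "hyper"
  call[p > hi & r < lo] <- "hypo"
  structure(data.frame(id = ids[keep], beta_parental = unname(p),
                       beta_resistant = unname(r), dbeta = unname(r - p),
                       call = call, stringsAsFactors = FALSE),
            n_missing = n_missing)
}

#' Promoter-level EMT methylation score
#'
#' Pools per-CpG delta-beta (resistant minus parental) by signature class
#' over all promoter CpGs, reporting class means with SEM and a one-sided
#' Mann-Whitney test of the EMT expectation (mesenchymal promoter
#' delta-beta below epithelial). Per-gene promoter methylation is the
#' unweighted mean over the gene's promoter CpGs, per sample.
#'
#' @param beta `beta_matrix` holding the two samples.
#' @param promoters gene-to-CpG-id mapping, e.g. from
#'   [annotate_promoters()].
#' @param signature data.frame `gene, klass`.
#' @param parental,resistant sample ids in `beta`.
#' @return list with `class_summary` (data.frame: class, n_cpgs,
#'   mean_dbeta, sem), `per_gene` (data.frame: gene, klass, n_cpgs,
#'   mean_parental, mean_resistant, dbeta), `p` (one-sided), `U`,
#'   `genes_without_cpgs`.
#' @export
promoter_emt_methylation <- function(beta, promoters, signature,
                                     parental, resistant) {
  stopifnot(inherits(beta, "beta_matrix"))
  idx <- function(ids) match(ids, beta$sites$id)
  per_gene <- NULL; dbeta_by_class <- list(epithelial = numeric(0),
                                           mesenchymal = numeric(0))
  missing_genes <- character(0)
  sig <- signature[signature$gene %in% names(promoters), , drop = FALSE]
  for (i in seq_len(nrow(sig))) {
    g <- sig$gene[i]
    ids <- intersect(promoters[[g]], beta$sites$id)
    if (!length(ids)) { missing_genes <- c(missing_genes, g); next }
    ri <- idx(ids)
    bp <- beta$values[ri, parental]; br <- beta$values[ri, resistant]
    ok <- is.finite(bp) & is.finite(br)
    if (!any(ok)) { missing_genes <- c(missing_genes, g); next }
    db <- br[ok] - bp[ok]
    dbeta_by_class[[sig$klass[i]]] <- c(dbeta_by_class[[sig$klass[i]]], db)
    per_gene <- rbind(per_gene, data.frame(
      gene = g, klass = sig$klass[i], n_cpgs = sum(ok),
      mean_parental = mean(bp[ok]), mean_resistant = mean(br[ok]),
      dbeta = mean(db), stringsAsFactors = FALSE))
  }
  summ <- do.call(rbind, lapply(names(dbeta_by_class), function(k) {
    v <- dbeta_by_class[[k]]
    data.frame(klass = k, n_cpgs = length(v),
               mean_dbeta = if (length(v)) mean(v) else NA_real_,
               sem = if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else NA_real_)
  }))
  tst <- if (all(lengths(dbeta_by_class) >= 1))
    mann_whitney(dbeta_by_class$mesenchymal, dbeta_by_class$epithelial,
                 alternative = "less")
  else list(U = NA_real_, p = NA_real_)
  list(class_summary = summ, per_gene = per_gene, p = tst$p, U = tst$U,
       genes_without_cpgs = missing_genes)
}

#' Expression-vs-methylation quadrant enrichment
#'
#' Each signature gene is placed in a quadrant by the signs of its
#' promoter delta-beta (x) and expression log2 fold change (y). Upon EMT,
#' mesenchymal genes are expected in the upper-left quadrant
#' (hypomethylated, upregulated) and epithelial genes in the lower-right
#' (hypermethylated, downregulated); the chance expectation per quadrant
#' is 0.25. Genes with an exact zero on either axis join no quadrant and
#' leave the denominator.
#'
#' @param fc data.frame `gene, log2fc`.
#' @param gene_dbeta data.frame `gene, dbeta` (promoter methylation
#'   change), e.g. `per_gene` from [promoter_emt_methylation()].
#' @param signature data.frame `gene, klass`.
#' @return data.frame per class: `klass, n, n_expected_quadrant,
#'   fraction, expected_fraction, enriched`, plus attribute `quadrants`
#'   (per-gene table).
#' @export
quadrant_enrichment <- function(fc, gene_dbeta, signature) {
  m <- merge(merge(fc, gene_dbeta[, c("gene", "dbeta")], by = "gene"),
             signature, by = "gene")
  quad <- ifelse(m$dbeta == 0 | m$log2fc == 0, NA_character_,
                 paste0(ifelse(m$log2fc > 0, "up", "down"), "_",
                        ifelse(m$dbeta > 0, "hyper", "hypo")))
  m$quadrant <- quad
  expected <- c(epithelial = "down_hyper", mesenchymal = "up_hypo")
  out <- do.call(rbind, lapply(names(expected), function(k) {
    q <- quad[m$klass == k & !is.na(quad)]
    frac <- if (length(q)) mean(q == expected[[k]]) else NA_real_
    data.frame(klass = k, n = length(q),
               n_expected_quadrant = sum(q == expected[[k]]),
               fraction = frac, expected_fraction = 0.25,
               enriched = !is.na(frac) && frac > 0.25)
  }))
  attr(out, "quadrants") <- m
  out
}

# upper binomial tail P(X >= k), X ~ Bin(n, p), by log-space summation
binom_upper_tail <- function(k, n, p) {
  if (k <= 0) return(1)
  if (k > n) return(0)
  if (p <= 0) return(0)
  if (p >= 1) return(1)
  ks <- k:n
  lg <- lchoose(n, ks) + ks * log(p) + (n - ks) * log1p(-p)
  min(1, exp(logsumexp(lg)))
}

#' Shared differentially methylated CpGs: overlap binomial test
#'
#' Tests whether two resistance models share more hyper- (or hypo-)
#' methylated CpGs than expected by chance. On the `N` CpGs assayed in
#' both models, with `n_A` and `n_B` differential CpGs and `k` shared,
#' the expected overlap is `n_A * n_B / N` and the one-sided p-value is
#' `P(X >= k)` with `X ~ Binomial(n_small, n_large / N)` — conditioning
#' on the smaller count by default so the test is symmetric in its
#' arguments. A hypergeometric null is available for sensitivity
#' analysis.
#'
#' @param callsA,callsB data.frames from [classify_dmcs()].
#' @param direction `"hyper"` or `"hypo"`.
#' @param condition_on `"smaller"` (default), `"A"` or `"B"`: which count
#'   plays the number-of-trials role.
#' @param null `"binomial"` (default) or `"hypergeometric"`.
#' @return list with `N`, `n_A`, `n_B`, `k`, `expected`, `p`,
#'   `direction`, `null`.
#' @export
overlap_binomial <- function(callsA, callsB, direction = c("hyper", "hypo"),
                             condition_on = c("smaller", "A", "B"),
                             null = c("binomial", "hypergeometric")) {
  direction <- match.arg(direction)
  condition_on <- match.arg(condition_on)
  null <- match.arg(null)
  common <- intersect(callsA$id, callsB$id)
  N <- length(common)
  if (N == 0) stopf("no CpGs assayed in both models")
  a <- callsA$call[match(common, callsA$id)] == direction
  b <- callsB$call[match(common, callsB$id)] == direction
  n_A <- sum(a); n_B <- sum(b); k <- sum(a & b)
  if (n_A > N || n_B > N) stopf("differential count exceeds common set size")
  expected <- n_A * n_B / N
  nn <- switch(condition_on, smaller = min(n_A, n_B), A = n_A, B = n_B)
  other <- switch(condition_on, smaller = max(n_A, n_B), A = n_B, B = n_A)
  p <- if (null == "binomial") {
    binom_upper_tail(k, nn, other / N)
  } else {
    stats::phyper(k - 1, other, N - other, nn, lower.tail = FALSE)
  }
  list(N = N, n_A = n_A, n_B = n_B, k = k, expected = expected,
       p = p, direction = direction, null = null)
}
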