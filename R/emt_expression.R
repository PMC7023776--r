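# EMT scoring from expression: CPM log2 fold changes, delta-delta-Ct with
# housekeeper selection, and the epithelial-vs-mesenchymal rank test.

#' Mann-Whitney U test (exact for small samples)
#'
#' The U statistic is computed for `x` relative to `y` from midranks.
#' When both groups have at most 8 observations, or `n + m <= 10`, the
#' null distribution is obtained by exact enumeration of all
#' `choose(n + m, n)` rank assignments (ties handled via midranks);
#' otherwise a normal approximation with tie-corrected variance is used,
#' without continuity correction. Two-sided p-values are
#' `P(|U - nm/2| >= |u - nm/2|)`.
#'
#' @param x,y numeric vectors.
#' @param alternative `"two.sided"`, `"greater"` (x tends larger) or
#'   `"less"`.
#' @param exact force (`TRUE`) or forbid (`FALSE`) enumeration; default
#'   `NULL` picks automatically.
#' @return list with `U`, `p`, `method`, `alternative`.
#' @export
mann_whitney <- function(x, y, alternative = c("two.sided", "greater", "less"),
                         exact = NULL) {
  alternative <- match.arg(alternative)
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  nx <- length(x); ny <- length(y)
  if (nx < 1 || ny < 1) stopf("both groups must be non-empty")
  r <- rank(c(x, y))
  u <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  mu <- nx * ny / 2
  use_exact <- exact %||% ((nx <= 8 && ny <= 8) || (nx + ny <= 10))
  eps <- 1e-9
  if (use_exact) {
    cmb <- utils::combn(nx + ny, nx)
    u_all <- colSums(matrix(r[cmb], nrow = nx)) - nx * (nx + 1) / 2
    p <- switch(alternative,
                greater = mean(u_all >= u - eps),
                less = mean(u_all <= u + eps),
                two.sided = mean(abs(u_all - mu) >= abs(u - mu) - eps))
    method <- "exact enumeration"
  } else {
    n <- nx + ny
    t <- table(r)
    v <- nx * ny / 12 * ((n + 1) - sum(t^3 - t) / (n * (n - 1)))
    if (v <= 0) return(list(U = u, p = 1, method = "normal approximation",
                            alternative = alternative))
    z <- (u - mu) / sqrt(v)
    p <- switch(alternative,
                greater = stats::pnorm(z, lower.tail = FALSE),
                less = stats::pnorm(z),
                two.sided = 2 * stats::pnorm(-abs(z)))
    p <- min(1, p)
    method <- "normal approximation"
  }
  list(U = u, p = p, method = method, alternative = alternative)
}

#' Log2 fold changes from RNA-seq counts via CPM
#'
#' Counts are normalized to counts per million within each sample;
#' `log2fc = log2((CPM_resistant + pc) / (CPM_parental + pc))`, so positive
#' values mean upregulation in the resistant line.
#'
#' @param counts data.frame with a `gene` column and one count column per
#'   sample.
#' @param parental,resistant sample column names.
#' @param pseudocount CPM pseudocount (> 0, default 1).
#' @return data.frame `gene, log2fc`.
#' @export
cpm_log2fc <- function(counts, parental, resistant, pseudocount = 1) {
  stopifnot(pseudocount > 0)
  for (s in c(parental, resistant))
    if (!s %in% names(counts)) stopf("sample '%s' not in count table", s)
  tot_p <- sum(counts[[parental]]); tot_r <- sum(counts[[resistant]])
  if (tot_p == 0 || tot_r == 0) stopf("zero total counts in a sample")
  cpm_p <- 1e6 * counts[[parental]] / tot_p
  cpm_r <- 1e6 * counts[[resistant]] / tot_r
  data.frame(gene = counts$gene,
             log2fc = log2((cpm_r + pseudocount) / (cpm_p + pseudocount)),
             stringsAsFactors = FALSE)
}

#' Log2 fold changes from Ct values via delta-delta-Ct
#'
#' Technical duplicate columns (if `dup_of` given) are averaged first.
#' The `n_select` housekeeper candidates with the lowest Ct standard
#' deviation across all samples are used for normalization:
#' `dCt = Ct_gene - mean(Ct_housekeepers)` per sample, and
#' `log2fc = -(dCt_resistant - dCt_parental)`.
#'
#' @param ct data.frame with a `gene` column and one Ct column per sample.
#' @param parental,resistant sample column names.
#' @param housekeepers candidate housekeeping genes present in `ct`
#'   (default [housekeeper_candidates()]).
#' @param n_select number of housekeepers to select (default 2).
#' @return data.frame `gene, log2fc` (housekeepers excluded), with
#'   attribute `housekeepers` naming the selected pair.
#' @export
ddct_log2fc <- function(ct, parental, resistant,
                        housekeepers = housekeeper_candidates(), n_select = 2) {
  for (s in c(parental, resistant))
    if (!s %in% names(ct)) stopf("sample '%s' not in Ct table", s)
  samp_cols <- setdiff(names(ct), "gene")
  hk <- ct[ct$gene %in% housekeepers, , drop = FALSE]
  complete <- hk$gene[apply(is.finite(as.matrix(hk[, samp_cols, drop = FALSE])), 1, all)]
  if (length(complete) < n_select)
    stopf("fewer than %d housekeeper candidates with complete Ct", n_select)
  hk <- hk[hk$gene %in% complete, , drop = FALSE]
  sds <- apply(as.matrix(hk[, samp_cols, drop = FALSE]), 1, stats::sd)
  sel <- hk$gene[order(sds)][seq_len(n_select)]
  hk_mean <- colMeans(as.matrix(hk[hk$gene %in% sel, samp_cols, drop = FALSE]))
  targets <- ct[!ct$gene %in% housekeepers, , drop = FALSE]
  dct_p <- targets[[parental]] - hk_mean[[parental]]
  dct_r <- targets[[resistant]] - hk_mean[[resistant]]
  structure(data.frame(gene = targets$gene, log2fc = -(dct_r - dct_p),
                       stringsAsFactors = FALSE),
            housekeepers = sel)
}

#' Score EMT from signature log2 fold changes
#'
#' Partitions fold changes into epithelial and mesenchymal signature
#' genes, reports per-class medians, and compares the classes with a
#' Mann-Whitney U test ([mann_whitney()]; U is computed for the
#' epithelial class). The "full EMT" call requires mesenchymal
#' upregulation (median > 0), epithelial downregulation (median < 0) and
#' significance at `alpha`.
#'
#' @param fc data.frame `gene, log2fc`.
#' @param signature data.frame `gene, klass` (default [emt_signature()]).
#' @param sided `"two.sided"` (default, main-figure convention) or a
#'   one-sided alternative for the epithelial-vs-mesenchymal contrast.
#' @param alpha significance level for the full-EMT call (default 0.05).
#' @return list with `epithelial`, `mesenchymal` (fold-change vectors),
#'   `medians`, `U`, `p`, `sided`, `full_emt`.
#' @export
emt_expression_score <- function(fc, signature = emt_signature(),
                                 sided = c("two.sided", "greater", "less"),
                                 alpha = 0.05) {
  sided <- match.arg(sided)
  m <- merge(fc, signature, by = "gene")
  epi <- m$log2fc[m$klass == "epithelial"]
  mes <- m$log2fc[m$klass == "mesenchymal"]
  if (length(epi) < 2 || length(mes) < 2)
    stopf("need >=2 signature genes per class in the fold-change table (have %d epithelial, %d mesenchymal)",
          length(epi), length(mes))
  tst <- mann_whitney(epi, mes, alternative = sided)
  med <- c(epithelial = stats::median(epi), mesenchymal = stats::median(mes))
  list(epithelial = epi, mesenchymal = mes, medians = med,
       U = tst$U, p = tst$p, sided = sided,
       full_emt = unname(med["mesenchymal"] > 0 & med["epithelial"] < 0 &
                           tst$p < alpha))
}
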