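# Liquid-biopsy mixture model. Measured cfDNA methylation is
# M_meas = M_tumor * f_ctDNA + M_cfDNA * (1 - f_ctDNA); on capture-panel
# CpGs chosen for M_cfDNA ~ 0, the ctDNA fraction is the through-origin
# regression slope of M_meas on the tumor-reference methylation, and the
# tumor methylome is reconstructed as M_meas / f_ctDNA.

#' Build a cfDNA methylome from coverage records
#'
#' Collapses Bismark coverage records into per-CpG methylation fractions,
#' masking CpGs below the depth floor. CpGs are keyed `chrom:pos` to
#' match array coordinates.
#'
#' @param cov data.frame from [read_bismark_cov()] (or equivalent).
#' @param sample sample id to attach.
#' @param min_depth minimal read depth per CpG (default 10); shallower
#'   CpGs are masked (`m = NA`).
#' @return data.frame `sample, key, chrom, pos, depth, m, masked`.
#' @export
cfdna_methylome <- function(cov, sample = "sample", min_depth = 10) {
  depth <- cov$count_meth + cov$count_unmeth
  m <- ifelse(depth > 0, cov$count_meth / depth, NA_real_)
  masked <- depth < min_depth
  m[masked] <- NA_real_
  data.frame(sample = sample, key = paste0(cov$chrom, ":", cov$start),
             chrom = cov$chrom, pos = cov$start, depth = depth, m = m,
             masked = masked, stringsAsFactors = FALSE)
}

#' Tumor reference methylation from a tumor cohort
#'
#' Per-CpG unweighted cohort mean, keyed `chrom:pos`.
#'
#' @param tumor `beta_matrix` of the tumor cohort.
#' @param sites optional CpG id subset (e.g. panel targets).
#' @return data.frame `key, id, chrom, pos, m_tumor, n_samples`.
#' @export
tumor_reference <- function(tumor, sites = NULL) {
  stopifnot(inherits(tumor, "beta_matrix"))
  x <- if (is.null(sites)) tumor else subset_beta(tumor, sites = sites)
  mu <- cohort_means(x)
  data.frame(key = paste0(x$sites$chrom, ":", x$sites$pos),
             id = x$sites$id, chrom = x$sites$chrom, pos = x$sites$pos,
             m_tumor = unname(mu), n_samples = ncol(x$values),
             stringsAsFactors = FALSE)
}

#' Estimate the ctDNA fraction of a cfDNA sample
#'
#' Least-squares slope of measured methylation on tumor-reference
#' methylation with the intercept fixed at 0 (the `M_cfDNA ~ 0`
#' assumption of the capture design), over unmasked panel CpGs, clamped
#' to `[0, 1]`. A CpG-resampling bootstrap gives a 95% interval. The
#' reliability flag is false when the estimate falls below `f_floor` or
#' fewer than `min_cpgs` CpGs enter the fit; downstream reconstruction
#' refuses unreliable estimates. A free-intercept fit is available for
#' diagnostics.
#'
#' @param meas data.frame from [cfdna_methylome()].
#' @param tumor_ref data.frame from [tumor_reference()].
#' @param min_cpgs minimal number of usable CpGs (default 50).
#' @param f_floor reliability floor on the estimate (default 0.01).
#' @param nboot bootstrap replicates (default 200; 0 disables).
#' @param seed integer seed for the bootstrap.
#' @param intercept fit a free intercept instead (diagnostic only).
#' @return list of class `deconv_result`: `sample, f_ctdna, f_cfdna,
#'   n_cpgs, ci` (2-vector or NULL), `residual_sd, rank_cor, reliable,
#'   intercept`.
#' @export
estimate_f_ctdna <- function(meas, tumor_ref, min_cpgs = 50, f_floor = 0.01,
                             nboot = 200, seed = 1L, intercept = FALSE) {
  m <- merge(meas[!meas$masked, c("key", "m", "depth")],
             tumor_ref[, c("key", "m_tumor")], by = "key")
  m <- m[is.finite(m$m) & is.finite(m$m_tumor), ]
  if (nrow(m) < min_cpgs)
    stopf("only %d usable CpGs (need >= %d)", nrow(m), min_cpgs)
  if (all(m$m_tumor == 0)) stopf("all-zero tumor reference on the common CpG set")
  x <- m$m_tumor; y <- m$m
  slope <- function(x, y) {
    if (intercept) {
      cf <- stats::coef(stats::lm.fit(cbind(1, x), y)); cf[2]
    } else sum(x * y) / sum(x * x)
  }
  f_raw <- slope(x, y)
  f <- min(1, max(0, f_raw))
  ci <- NULL
  if (nboot > 0) {
    boot <- with_seed(seed, {
      n <- length(x)
      vapply(seq_len(nboot), function(i) {
        idx <- sample.int(n, n, replace = TRUE)
        min(1, max(0, slope(x[idx], y[idx])))
      }, numeric(1))
    })
    ci <- unname(stats::quantile(boot, c(0.025, 0.975)))
  }
  res <- structure(list(sample = meas$sample[1], f_ctdna = f, f_cfdna = 1 - f,
                        n_cpgs = nrow(m), ci = ci,
                        residual_sd = stats::sd(y - f_raw * x),
                        rank_cor = suppressWarnings(stats::cor(x, y, method = "spearman")),
                        reliable = f >= f_floor && nrow(m) >= min_cpgs,
                        intercept = intercept),
                   class = "deconv_result")
  res
}

#' @export
print.deconv_result <- function(x, ...) {
  cat(sprintf("<deconv_result> %s: f_ctDNA = %.4f (%d CpGs%s)%s\n",
              x$sample, x$f_ctdna, x$n_cpgs,
              if (!is.null(x$ci)) sprintf(", 95%% CI %.3f-%.3f", x$ci[1], x$ci[2]) else "",
              if (x$reliable) "" else " [unreliable]"))
  invisible(x)
}

#' Reconstruct the tumor methylome from a cfDNA sample
#'
#' Inverts the mixture under `M_cfDNA ~ 0`:
#' `M_tumor_hat = min(1, M_meas / f_ctDNA)` per unmasked CpG. Refuses
#' unreliable ctDNA fraction estimates rather than dividing by a noisy
#' near-zero value.
#'
#' @param meas data.frame from [cfdna_methylome()].
#' @param deconv `deconv_result` for the same sample.
#' @param keys optional key subset to reconstruct.
#' @return data.frame `key, m_hat, clipped` (unmasked CpGs only).
#' @export
reconstruct_tumor_methylation <- function(meas, deconv, keys = NULL) {
  stopifnot(inherits(deconv, "deconv_result"))
  if (!isTRUE(deconv$reliable))
    stopf("refusing to reconstruct: f_ctDNA estimate for '%s' is unreliable (f = %.4g, %d CpGs)",
          deconv$sample, deconv$f_ctdna, deconv$n_cpgs)
  m <- meas[!meas$masked & is.finite(meas$m), ]
  if (!is.null(keys)) m <- m[m$key %in% keys, ]
  raw <- m$m / deconv$f_ctdna
  data.frame(key = m$key, m_hat = pmin(1, raw), clipped = raw > 1,
             stringsAsFactors = FALSE)
}

#' Exclude EMT markers unreliable in healthy cfDNA
#'
#' Tumor-methylome reconstruction assumes near-zero cfDNA background; EMT
#' markers whose promoters are methylated, or variably methylated, in the
#' cfDNA of healthy controls violate it and are dropped. Per gene, the
#' promoter methylation (mean over its panel CpGs) is computed in every
#' control; a gene is excluded when the across-control mean exceeds
#' `mean_cap`, the across-control standard deviation exceeds `var_cap`,
#' or no panel CpG falls in its promoter.
#'
#' @param controls list of control methylomes ([cfdna_methylome()]),
#'   length >= 2.
#' @param signature data.frame `gene, klass`.
#' @param promoters gene-to-CpG-id map.
#' @param sites data.frame `id, chrom, pos` translating CpG ids to keys.
#' @param mean_cap maximal allowed control promoter mean (default 0.05).
#' @param var_cap maximal allowed across-control sd (default 0.05).
#' @return list with `retained` (signature data.frame), `report`
#'   (data.frame `gene, klass, control_mean, control_sd, excluded,
#'   reason`), `retained_counts` (table by class).
#' @export
exclude_unreliable_markers <- function(controls, signature, promoters, sites,
                                       mean_cap = 0.05, var_cap = 0.05) {
  if (length(controls) < 2) stopf("need >= 2 control samples")
  key_of <- setNames(paste0(sites$chrom, ":", sites$pos), sites$id)
  report <- NULL
  for (i in seq_len(nrow(signature))) {
    g <- signature$gene[i]
    keys <- unname(key_of[intersect(promoters[[g]] %||% character(0), sites$id)])
    means <- vapply(controls, function(ctl) {
      v <- ctl$m[match(keys, ctl$key)]
      if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
    }, numeric(1))
    if (!length(keys) || all(is.na(means))) {
      report <- rbind(report, data.frame(
        gene = g, klass = signature$klass[i], control_mean = NA_real_,
        control_sd = NA_real_, excluded = TRUE, reason = "no_cpgs"))
      next
    }
    mu <- mean(means, na.rm = TRUE); sdv <- stats::sd(means[!is.na(means)])
    reason <- if (mu > mean_cap) "high"
      else if (is.finite(sdv) && sdv > var_cap) "variable"
      else "retained"
    report <- rbind(report, data.frame(
      gene = g, klass = signature$klass[i], control_mean = mu,
      control_sd = sdv, excluded = reason != "retained", reason = reason))
  }
  retained <- signature[signature$gene %in% report$gene[!report$excluded], ]
  list(retained = retained, report = report,
       retained_counts = table(retained$klass))
}

#' Longitudinal EMT trajectory from serial liquid biopsies
#'
#' Per timepoint, the tumor methylome is reconstructed and the retained
#' EMT signature promoters summarized per class (mean over promoter CpGs,
#' with SEM). The EMT score is the epithelial minus the mesenchymal class
#' mean — rising as a tumor undergoes EMT (epithelial promoters gain,
#' mesenchymal promoters lose methylation) — and is reported relative to
#' the first reliable timepoint (t0, relative score 0 by construction).
#' The trend call at the last timepoint is `emt_shift` when the relative
#' score exceeds `tau`, `reverse_shift` below `-tau`, else `no_shift`.
#'
#' @param series list of per-timepoint lists with elements `meas`
#'   ([cfdna_methylome()]), `deconv` ([estimate_f_ctdna()]), `day`.
#' @param signature retained signature data.frame `gene, klass`.
#' @param promoters gene-to-CpG-id map.
#' @param sites data.frame `id, chrom, pos`.
#' @param tau trend threshold in absolute methylation units (default
#'   0.05).
#' @param patient patient id for the output.
#' @return list of class `emt_trajectory`: `patient`, `table`
#'   (data.frame `day, epithelial, epithelial_sem, mesenchymal,
#'   mesenchymal_sem, score, rel_score, reliable`), `trend`,
#'   `anchor_day`.
#' @export
emt_trajectory <- function(series, signature, promoters, sites, tau = 0.05,
                           patient = "P01") {
  if (length(series) < 2) stopf("need >= 2 timepoints")
  key_of <- setNames(paste0(sites$chrom, ":", sites$pos), sites$id)
  cls_keys <- lapply(split(signature$gene, signature$klass), function(gs)
    unname(key_of[intersect(unlist(promoters[gs], use.names = FALSE), sites$id)]))
  rows <- NULL
  for (tp in series) {
    reliable <- isTRUE(tp$deconv$reliable)
    epi <- mes <- c(NA_real_, NA_real_)
    if (reliable) {
      rec <- reconstruct_tumor_methylation(tp$meas, tp$deconv)
      stat <- function(keys) {
        v <- rec$m_hat[match(keys, rec$key)]
        v <- v[is.finite(v)]
        c(mean(v), stats::sd(v) / sqrt(length(v)))
      }
      epi <- stat(cls_keys$epithelial); mes <- stat(cls_keys$mesenchymal)
    }
    rows <- rbind(rows, data.frame(
      day = tp$day, epithelial = epi[1], epithelial_sem = epi[2],
      mesenchymal = mes[1], mesenchymal_sem = mes[2],
      score = epi[1] - mes[1], reliable = reliable))
  }
  anchor <- which(rows$reliable)[1]
  if (is.na(anchor)) stopf("no reliable timepoint to anchor the trajectory")
  if (anchor > 1)
    message(sprintf("emt_trajectory: t0 unreliable; anchoring at day %d", rows$day[anchor]))
  rows$rel_score <- rows$score - rows$score[anchor]
  last <- rev(which(rows$reliable))[1]
  trend <- if (rows$rel_score[last] > tau) "emt_shift"
    else if (rows$rel_score[last] < -tau) "reverse_shift"
    else "no_shift"
  structure(list(patient = patient, table = rows, trend = trend,
                 anchor_day = rows$day[anchor], tau = tau),
            class = "emt_trajectory")
}

#' @export
print.emt_trajectory <- function(x, ...) {
  cat(sprintf("<emt_trajectory> %s: %d timepoints, trend '%s' (tau = %g)\n",
              x$patient, nrow(x$table), x$trend, x$tau))
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Correlate a tissue biopsy with reconstructed liquid-biopsy methylomes
#'
#' Spearman rank correlation between tissue beta values and each liquid
#' sample's reconstructed tumor methylation (the ctDNA-fraction
#' correction), over the common panel CpGs. The liquid sample with the
#' highest coefficient is flagged.
#'
#' @param tissue one-sample `beta_matrix` (or data.frame `key, beta`).
#' @param liquids list of lists with `meas` and `deconv`.
#' @param min_cpgs minimal common CpG count (default 50).
#' @return data.frame `sample, rho, n_cpgs, best`.
#' @export
correlate_tissue_liquid <- function(tissue, liquids, min_cpgs = 50) {
  if (inherits(tissue, "beta_matrix")) {
    tis <- data.frame(key = paste0(tissue$sites$chrom, ":", tissue$sites$pos),
                      beta = tissue$values[, 1], stringsAsFactors = FALSE)
  } else tis <- tissue
  out <- NULL
  for (lq in liquids) {
    rec <- reconstruct_tumor_methylation(lq$meas, lq$deconv)
    m <- merge(tis, rec, by = "key")
    m <- m[is.finite(m$beta) & is.finite(m$m_hat), ]
    if (nrow(m) < min_cpgs) stopf("fewer than %d common CpGs for sample '%s'",
                                  min_cpgs, lq$meas$sample[1])
    out <- rbind(out, data.frame(
      sample = lq$meas$sample[1],
      rho = stats::cor(m$beta, m$m_hat, method = "spearman"),
      n_cpgs = nrow(m)))
  }
  out$best <- seq_len(nrow(out)) == which.max(out$rho)
  out
}
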