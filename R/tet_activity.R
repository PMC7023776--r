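# 5mC-decile 5hmC bin analysis: infers TET-activity differences between
# parental and resistant lines from the coupling of 5mC and 5hmC. At CpGs
# with constant turnover, 5hmC tracks 5mC; locally reduced TET activity
# shows as hypermethylating CpGs with high 5hmC while still lowly
# methylated (parental) and depressed 5hmC once methylated (resistant).

#' Assign CpGs to methylation-level bins
#'
#' Bin i covers `[(i-1)/n, i/n)`; the last bin is closed at 1. Binning is
#' per sample: each sample's CpGs are binned by that sample's 5mC level.
#'
#' @param mc numeric 5mC beta vector for one sample.
#' @param n_bins number of bins (default 10).
#' @return integer bin index per CpG (NA propagated).
#' @export
bin_by_methylation <- function(mc, n_bins = 10) {
  ok <- is.finite(mc)
  if (any(mc[ok] < 0 | mc[ok] > 1)) stopf("5mC values outside [0,1]")
  b <- floor(mc * n_bins) + 1L
  b[ok & mc >= 1] <- n_bins  # closed top bin
  b
}

#' Compare 5hmC of variable vs stable CpGs within 5mC bins
#'
#' For one sample, CpGs are binned by their 5mC level; within each
#' requested bin, the mean 5hmC of hyper- or hypomethylated ("variable")
#' CpGs is compared to the mean 5hmC of stable CpGs via a two-sided
#' Mann-Whitney test. The middle bins (4-7 by default) contain only
#' stable CpGs by construction of the 0.3/0.7 calling thresholds and are
#' excluded. Bins with fewer than 2 CpGs in either group are reported as
#' non-comparable (no p-value).
#'
#' @param mc `beta_matrix`, channel `mc_specific` (5mC).
#' @param hmc `beta_matrix`, channel `tab` (5hmC), same sites.
#' @param calls data.frame from [classify_dmcs()] on the 5mC channel.
#' @param sample sample id to analyze.
#' @param bins bin indices to analyze (default `c(1:3, 8:10)`).
#' @param n_bins total number of bins (default 10).
#' @return data.frame with one row per (bin, variable-group present):
#'   `sample, bin, group, n_variable, n_stable, mean_variable,
#'   mean_stable, delta` (stable minus variable), `p`, `comparable`.
#' @export
compare_variable_vs_stable <- function(mc, hmc, calls, sample,
                                       bins = c(1:3, 8:10), n_bins = 10) {
  stopifnot(inherits(mc, "beta_matrix"), inherits(hmc, "beta_matrix"))
  if (!identical(mc$sites$id, hmc$sites$id))
    stopf("site sets differ between 5mC and 5hmC matrices")
  if (!sample %in% mc$samples || !sample %in% hmc$samples)
    stopf("sample '%s' absent from a matrix", sample)
  mvec <- mc$values[, sample]
  hvec <- hmc$values[, sample]
  grp <- setNames(calls$call, calls$id)[mc$sites$id]
  bin <- bin_by_methylation(mvec, n_bins)
  out <- NULL
  for (b in bins) {
    inb <- which(bin == b & is.finite(hvec) & !is.na(grp))
    st <- inb[grp[inb] == "stable"]
    for (g in c("hyper", "hypo")) {
      vg <- inb[grp[inb] == g]
      if (!length(vg)) next
      comparable <- length(vg) >= 2 && length(st) >= 2
      p <- delta <- NA_real_
      if (comparable) {
        delta <- mean(hvec[st]) - mean(hvec[vg])
        p <- mann_whitney(hvec[vg], hvec[st], alternative = "two.sided")$p
      }
      out <- rbind(out, data.frame(
        sample = sample, bin = b, group = g,
        n_variable = length(vg), n_stable = length(st),
        mean_variable = mean(hvec[vg]),
        mean_stable = if (length(st)) mean(hvec[st]) else NA_real_,
        delta = delta, p = p, comparable = comparable,
        stringsAsFactors = FALSE))
    }
  }
  out %||% data.frame(sample = character(0), bin = integer(0),
                      group = character(0), n_variable = integer(0),
                      n_stable = integer(0), mean_variable = numeric(0),
                      mean_stable = numeric(0), delta = numeric(0),
                      p = numeric(0), comparable = logical(0))
}

# Stouffer combination of one-sided Mann-Whitney p-values across bins
stouffer <- function(p) {
  p <- p[is.finite(p)]
  if (!length(p)) return(NA_real_)
  p <- pmin(pmax(p, 1e-300), 1 - 1e-16)
  stats::pnorm(sum(stats::qnorm(1 - p)) / sqrt(length(p)), lower.tail = FALSE)
}

#' TET-activity signature across a parental/resistant pair
#'
#' Evaluates the two directional conditions of the TET interpretation:
#' variable CpGs carry *more* 5hmC than stable CpGs of the same bin while
#' lowly methylated (hypermethylating CpGs in bins 1-3 of the parental
#' line; hypomethylating CpGs in bins 1-3 of the resistant line), and
#' *less* 5hmC once highly methylated (bins 8-10, samples swapped).
#' Within each comparable bin a one-sided Mann-Whitney test is run;
#' per-side evidence is Stouffer-combined, and the signature flag fires
#' when both combined p-values fall below `alpha`.
#'
#' @param mc,hmc `beta_matrix` objects (5mC / 5hmC), samples including
#'   both lines.
#' @param calls data.frame from [classify_dmcs()].
#' @param parental,resistant sample ids.
#' @param low_bins,high_bins bin index sets (defaults 1:3 and 8:10).
#' @param n_bins total bins (default 10).
#' @param alpha significance level for the flag (default 0.05).
#' @return list with `flag`, `p_low`, `p_high`, and `bins` (the combined
#'   per-sample bin tables from [compare_variable_vs_stable()]).
#' @export
tet_activity_signature <- function(mc, hmc, calls, parental, resistant,
                                   low_bins = 1:3, high_bins = 8:10,
                                   n_bins = 10, alpha = 0.05) {
  one_sided <- function(sample, bins, group, alternative) {
    mvec <- mc$values[, sample]; hvec <- hmc$values[, sample]
    grp <- setNames(calls$call, calls$id)[mc$sites$id]
    bin <- bin_by_methylation(mvec, n_bins)
    ps <- numeric(0)
    for (b in bins) {
      inb <- which(bin == b & is.finite(hvec) & !is.na(grp))
      vg <- inb[grp[inb] == group]; st <- inb[grp[inb] == "stable"]
      if (length(vg) >= 2 && length(st) >= 2)
        ps <- c(ps, mann_whitney(hvec[vg], hvec[st], alternative = alternative)$p)
    }
    ps
  }
  # low-methylation side: variable group expected above stable
  p_low <- stouffer(c(one_sided(parental, low_bins, "hyper", "greater"),
                      one_sided(resistant, low_bins, "hypo", "greater")))
  # high-methylation side: variable group expected below stable
  p_high <- stouffer(c(one_sided(resistant, high_bins, "hyper", "less"),
                       one_sided(parental, high_bins, "hypo", "less")))
  bins <- rbind(compare_variable_vs_stable(mc, hmc, calls, parental,
                                           bins = c(low_bins, high_bins), n_bins = n_bins),
                compare_variable_vs_stable(mc, hmc, calls, resistant,
                                           bins = c(low_bins, high_bins), n_bins = n_bins))
  list(flag = isTRUE(p_low < alpha) && isTRUE(p_high < alpha),
       p_low = p_low, p_high = p_high, bins = bins)
}
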