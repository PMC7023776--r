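# Capture-panel design: select CpGs unmethylated in healthy blood and
# tile them into capture regions.

#' Select capture-target CpGs from a healthy-blood cohort
#'
#' Targets are CpGs whose unweighted, pairwise-complete mean beta across
#' blood samples lies strictly below `threshold`.
#'
#' @param blood `beta_matrix` of the healthy-blood cohort (>= 1 sample).
#' @param threshold strict upper bound on the cohort mean (default 0.03).
#' @return data.frame `id, chrom, pos, blood_mean` of selected CpGs, in
#'   input order.
#' @export
select_target_cpgs <- function(blood, threshold = 0.03) {
  stopifnot(inherits(blood, "beta_matrix"))
  if (ncol(blood$values) < 1) stopf("empty blood cohort")
  mu <- cohort_means(blood)
  keep <- which(is.finite(mu) & mu < threshold)
  data.frame(id = blood$sites$id[keep], chrom = blood$sites$chrom[keep],
             pos = blood$sites$pos[keep], blood_mean = unname(mu[keep]),
             stringsAsFactors = FALSE)
}

#' Tile target CpGs into capture regions
#'
#' Adjacent targets on the same chromosome within `merge_gap` bp are
#' merged into one region; regions shorter than `min_len` are padded
#' symmetrically. This is a reproducible stand-in for vendor probe
#' tiling. Coordinates are 1-based inclusive; use [write_bed()] for BED
#' export.
#'
#' @param targets data.frame with columns `chrom, pos` (e.g. from
#'   [select_target_cpgs()]); sorted internally if needed (with a
#'   message).
#' @param merge_gap maximal distance between merged targets (default 200).
#' @param min_len minimal region length in bp (default 60).
#' @return data.frame `chrom, start, end, n_cpgs, length`, with a summary
#'   attribute (`n_regions`, `median_length`, `range_length`).
#' @export
build_capture_regions <- function(targets, merge_gap = 200, min_len = 60) {
  stopifnot(all(c("chrom", "pos") %in% names(targets)))
  if (nrow(targets) == 0)
    return(structure(data.frame(chrom = character(0), start = integer(0),
                                end = integer(0), n_cpgs = integer(0),
                                length = integer(0)),
                     summary = list(n_regions = 0L)))
  ord <- order(targets$chrom, targets$pos)
  if (!identical(ord, seq_len(nrow(targets)))) {
    message("build_capture_regions: input not sorted; sorting by (chrom, pos)")
    targets <- targets[ord, ]
  }
  out <- NULL
  for (ch in unique(targets$chrom)) {
    p <- targets$pos[targets$chrom == ch]
    new_run <- c(TRUE, diff(p) > merge_gap)
    run <- cumsum(new_run)
    for (r in unique(run)) {
      pp <- p[run == r]
      start <- min(pp); end <- max(pp)
      len <- end - start + 1L
      if (len < min_len) {
        pad <- min_len - len
        start <- start - ceiling(pad / 2)
        end <- end + floor(pad / 2)
        start <- max(1L, start)
        len <- end - start + 1L
      }
      out <- rbind(out, data.frame(chrom = ch, start = as.integer(start),
                                   end = as.integer(end),
                                   n_cpgs = length(pp),
                                   length = as.integer(len)))
    }
  }
  structure(out, summary = list(n_regions = nrow(out),
                                median_length = stats::median(out$length),
                                range_length = range(out$length)))
}
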