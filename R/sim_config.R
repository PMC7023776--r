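#' Simulation configuration
#'
#' Bundles every tunable of the synthetic-data generators. Defaults encode
#' the study design the generators emulate: a 50-gene EMT signature
#' (16 epithelial / 34 mesenchymal), a healthy-blood reference cohort of
#' 656 subjects and a tumor reference cohort of 370 patients, capture
#' targets selected for blood methylation below 0.03, and liquid biopsies
#' read-sampled at ~100x. CpG counts are scaled down from array scale
#' (10,000 CpGs, 5,000 panel targets) so that desk-scale runs finish in
#' seconds.
#'
#' @param seed integer master seed; all generators derive their streams
#'   from it (see [derive_seed()]).
#' @param n_cpgs total number of CpGs in the synthetic genome.
#' @param n_target_cpgs number of CpGs designated as capture-panel targets
#'   (low blood methylation); must not exceed `n_cpgs`.
#' @param n_genes number of annotated genes; the first 50 carry the EMT
#'   signature, the remainder are unrelated background genes.
#' @param cpgs_per_promoter CpGs placed in each gene promoter (>= 3).
#' @param emt_delta promoter beta shift (delta-beta magnitude) acquired by
#'   signature promoters upon resistance, in (0, 1); 0 disables all
#'   differential structure (null simulation).
#' @param background_sd Gaussian beta noise added per CpG and sample.
#' @param blood_mean mean blood beta over designated target CpGs (the
#'   generator draws a 96%/4% clean/contaminated mixture with this overall
#'   mean).
#' @param blood_conc Beta concentration of per-sample blood draws.
#' @param blood_dirty_prop,blood_dirty_mean fraction and mean of
#'   contaminated (residually methylated) background target CpGs.
#' @param tumor_mean mean tumor-reference beta over target CpGs; realized
#'   as a bimodal mixture (`tumor_hi_prop` of CpGs near `tumor_hi_mean`).
#' @param tumor_hi_mean,tumor_hi_prop high mode of the tumor target
#'   mixture and its weight.
#' @param tumor_conc Beta concentration of per-CpG tumor mean draws.
#' @param tumor_sample_conc Beta concentration of per-sample tumor draws
#'   around the per-CpG mean.
#' @param patient_dev_conc concentration of patient-specific tumor
#'   profiles around the cohort mean (smaller = more patient-specific).
#' @param cfdna_offset extra cfDNA methylation at promoters of the 13
#'   designated unreliable EMT markers (present in every subject's cfDNA,
#'   absent from the blood-array reference).
#' @param emt_lo,emt_hi promoter methylation extremes used to map a
#'   patient's EMT state in `[0, 1]` onto signature-promoter methylation.
#' @param coverage_mean mean sequencing depth per CpG (Poisson).
#' @param f_ctdna default per-sample ctDNA fractions for ad hoc series.
#' @param tet_kappa length-2 numeric `(parental, resistant)` 5mC-to-5hmC
#'   turnover rates applied to hypermethylating CpGs (reversed for
#'   hypomethylating CpGs).
#' @param kappa_stable turnover rate of CpGs with stable methylation.
#' @param expression_effect absolute log2 fold change of signature genes
#'   in the resistant sample (+ for mesenchymal, - for epithelial).
#' @param dispersion negative-binomial dispersion of expression counts
#'   (0 = Poisson).
#' @param base_expression mean baseline expression count.
#' @param n_blood,n_tumor reference cohort sizes.
#' @param n_hyper,n_hypo numbers of designated background CpGs crossing
#'   the 0.3/0.7 thresholds between parental and resistant lines.
#' @return a `sim_config` list, validated.
#' @export
sim_config <- function(seed = 1L,
                       n_cpgs = 10000L,
                       n_target_cpgs = 5000L,
                       n_genes = 60L,
                       cpgs_per_promoter = 8L,
                       emt_delta = 0.4,
                       background_sd = 0.05,
                       blood_mean = 0.01,
                       blood_conc = 300,
                       blood_dirty_prop = 0.04,
                       blood_dirty_mean = 0.125,
                       tumor_mean = 0.4,
                       tumor_hi_mean = 0.8,
                       tumor_hi_prop = 0.45,
                       tumor_conc = 8,
                       tumor_sample_conc = 30,
                       patient_dev_conc = 10,
                       cfdna_offset = 0.10,
                       emt_lo = 0.1,
                       emt_hi = 0.8,
                       coverage_mean = 100,
                       f_ctdna = c(0.2, 0.1, 0.3),
                       tet_kappa = c(parental = 0.4, resistant = 0.1),
                       kappa_stable = 0.25,
                       expression_effect = 2,
                       dispersion = 0.3,
                       base_expression = 500,
                       n_blood = 656L,
                       n_tumor = 370L,
                       n_hyper = 500L,
                       n_hypo = 500L) {
  cfg <- list(seed = as.integer(seed), n_cpgs = as.integer(n_cpgs),
              n_target_cpgs = as.integer(n_target_cpgs),
              n_genes = as.integer(n_genes),
              cpgs_per_promoter = as.integer(cpgs_per_promoter),
              emt_delta = emt_delta, background_sd = background_sd,
              blood_mean = blood_mean, blood_conc = blood_conc,
              blood_dirty_prop = blood_dirty_prop,
              blood_dirty_mean = blood_dirty_mean,
              tumor_mean = tumor_mean, tumor_hi_mean = tumor_hi_mean,
              tumor_hi_prop = tumor_hi_prop, tumor_conc = tumor_conc,
              tumor_sample_conc = tumor_sample_conc,
              patient_dev_conc = patient_dev_conc,
              cfdna_offset = cfdna_offset, emt_lo = emt_lo, emt_hi = emt_hi,
              coverage_mean = coverage_mean, f_ctdna = f_ctdna,
              tet_kappa = tet_kappa, kappa_stable = kappa_stable,
              expression_effect = expression_effect, dispersion = dispersion,
              base_expression = base_expression,
              n_blood = as.integer(n_blood), n_tumor = as.integer(n_tumor),
              n_hyper = as.integer(n_hyper), n_hypo = as.integer(n_hypo))
  frac <- c(cfg$emt_delta, cfg$background_sd, cfg$blood_mean,
            cfg$blood_dirty_prop, cfg$blood_dirty_mean, cfg$tumor_mean,
            cfg$tumor_hi_mean, cfg$tumor_hi_prop, cfg$cfdna_offset,
            cfg$emt_lo, cfg$emt_hi, cfg$f_ctdna)
  if (any(frac < 0 | frac > 1)) stopf("all fraction parameters must lie in [0, 1]")
  if (cfg$emt_delta < 0 || cfg$emt_delta >= 1) stopf("emt_delta must lie in [0, 1)")
  cnts <- c(cfg$n_cpgs, cfg$n_target_cpgs, cfg$n_genes, cfg$cpgs_per_promoter,
            cfg$n_blood, cfg$n_tumor)
  if (any(cnts <= 0)) stopf("counts must be positive")
  if (cfg$n_target_cpgs > cfg$n_cpgs) stopf("n_target_cpgs exceeds n_cpgs")
  if (cfg$cpgs_per_promoter < 3) stopf("cpgs_per_promoter must be >= 3")
  if (cfg$n_genes < 50) stopf("n_genes must cover the 50 signature genes")
  if (length(cfg$tet_kappa) != 2) stopf("tet_kappa must have length 2 (parental, resistant)")
  structure(cfg, class = "sim_config")
}
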