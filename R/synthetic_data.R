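# Seeded generators for every input the pipeline consumes, with ground
# truth exposed for recovery tests. One deterministic genomic layout is
# shared by all generators: gene promoters carry a fixed number of CpGs,
# background CpGs fill the remainder of the synthetic genome.

# Deterministic layout: genes round-robin over 5 chromosomes, 300 kb
# apart; promoter CpGs spread across the strand-aware promoter window;
# background CpGs parked far downstream. No RNG involved.
sim_layout <- function(config) {
  sig <- emt_signature()
  n_extra <- config$n_genes - nrow(sig)
  genes <- data.frame(
    gene = c(sig$gene, if (n_extra > 0) sprintf("BGGENE%02d", seq_len(n_extra))),
    stringsAsFactors = FALSE)
  ng <- nrow(genes)
  genes$chrom <- paste0("chr", ((seq_len(ng) - 1L) %% 5L) + 1L)
  genes$tss <- 300000L * (((seq_len(ng) - 1L) %/% 5L) + 1L)
  genes$strand <- ifelse(seq_len(ng) %% 2L == 1L, "+", "-")

  k <- config$cpgs_per_promoter
  off <- as.integer(round(seq(-1800, 400, length.out = k)))
  prom <- do.call(rbind, lapply(seq_len(ng), function(i) {
    sgn <- if (genes$strand[i] == "+") 1L else -1L
    data.frame(chrom = genes$chrom[i], pos = genes$tss[i] + sgn * off,
               gene = genes$gene[i], stringsAsFactors = FALSE)
  }))
  n_bg <- config$n_cpgs - nrow(prom)
  if (n_bg < config$n_hyper + config$n_hypo)
    stopf("n_cpgs too small: %d background CpGs for %d designated hyper/hypo",
          n_bg, config$n_hyper + config$n_hypo)
  bg <- data.frame(chrom = paste0("chr", ((seq_len(n_bg) - 1L) %% 5L) + 1L),
                   pos = 50000000L + 1000L * (((seq_len(n_bg) - 1L) %/% 5L) + 1L),
                   gene = NA_character_, stringsAsFactors = FALSE)
  sites <- rbind(prom[, c("chrom", "pos")], bg[, c("chrom", "pos")])
  sites <- data.frame(id = sprintf("cpg_%06d", seq_len(nrow(sites))), sites,
                      stringsAsFactors = FALSE)
  gene_of <- c(prom$gene, bg$gene)
  promoters <- split(sites$id[!is.na(gene_of)], gene_of[!is.na(gene_of)])
  promoters <- promoters[genes$gene]  # gene order, all present

  sig_class <- setNames(sig$klass, sig$gene)
  epi_cpgs <- unlist(promoters[names(promoters) %in% sig$gene[sig$klass == "epithelial"]],
                     use.names = FALSE)
  mes_cpgs <- unlist(promoters[names(promoters) %in% sig$gene[sig$klass == "mesenchymal"]],
                     use.names = FALSE)
  bg_ids <- sites$id[is.na(gene_of)]
  list(genes = genes, sites = sites, promoters = promoters, signature = sig,
       epi_cpgs = epi_cpgs, mes_cpgs = mes_cpgs, bg_ids = bg_ids)
}

#' Simulate a parental/resistant cell-line pair
#'
#' Emits the array-like data of an EMT-mediated resistance model: a
#' standard beta matrix (5mC + 5hmC), a TAB beta matrix (5hmC), an
#' expression count table, and the ground truth. Epithelial signature
#' promoters gain `emt_delta` methylation in the resistant line,
#' mesenchymal promoters lose it; designated background CpG sets cross the
#' 0.3/0.7 hyper/hypo thresholds (shift `2 * emt_delta`); 5hmC follows the
#' turnover model `h = kappa * m * (1 - m)` with `kappa` switched between
#' parental and resistant for the designated sets; expression counts are
#' negative-binomial with signature-structured log2 fold changes. With
#' `emt_delta = 0` the simulation is null: no designated sets, identical
#' expectations in both lines.
#'
#' @param config a [sim_config()].
#' @return list with elements `standard`, `tab` (both `beta_matrix` with
#'   samples `parental`, `resistant`), `expression` (data.frame
#'   `gene, parental, resistant`, including the 5 housekeepers), `truth`
#'   (list: `hyper`, `hypo` designated CpG id sets, `kappa` data.frame,
#'   `n_clipped`), plus `genes`, `sites`, `promoters`, `signature`.
#' @export
simulate_cellline_pair <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  lay <- sim_layout(config)
  with_seed(derive_seed(config$seed, "cellline"), {
    n <- config$n_cpgs
    id <- lay$sites$id
    delta <- config$emt_delta
    null_sim <- delta == 0

    hyper_ids <- if (null_sim) character(0) else lay$bg_ids[seq_len(config$n_hyper)]
    hypo_ids <- if (null_sim) character(0) else
      lay$bg_ids[config$n_hyper + seq_len(config$n_hypo)]
    stable_bg <- setdiff(lay$bg_ids, c(hyper_ids, hypo_ids))

    m_par <- numeric(n); names(m_par) <- id
    # stable background: bimodal, identical base in both lines
    mode_hi <- stats::runif(length(stable_bg)) < 0.5
    m_par[stable_bg] <- rbeta_mu(length(stable_bg), ifelse(mode_hi, 0.85, 0.15), 6)
    # unrelated gene promoters behave like stable background
    extra_cpgs <- setdiff(unlist(lay$promoters, use.names = FALSE),
                          c(lay$epi_cpgs, lay$mes_cpgs))
    if (length(extra_cpgs)) {
      hi <- stats::runif(length(extra_cpgs)) < 0.5
      m_par[extra_cpgs] <- rbeta_mu(length(extra_cpgs), ifelse(hi, 0.85, 0.15), 6)
    }
    m_par[lay$epi_cpgs] <- 0.2
    m_par[lay$mes_cpgs] <- 0.6
    m_par[hyper_ids] <- 0.1
    m_par[hypo_ids] <- 0.9

    m_res <- m_par
    m_res[lay$epi_cpgs] <- m_par[lay$epi_cpgs] + delta
    m_res[lay$mes_cpgs] <- m_par[lay$mes_cpgs] - delta
    m_res[hyper_ids] <- m_par[hyper_ids] + 2 * delta
    m_res[hypo_ids] <- m_par[hypo_ids] - 2 * delta

    sd <- config$background_sd
    noisy <- function(x) clip01(x + if (sd > 0) stats::rnorm(n, 0, sd) else 0)
    m_par_n <- noisy(m_par); m_res_n <- noisy(m_res)
    n_clip <- attr(m_par_n, "n_clipped") + attr(m_res_n, "n_clipped")
    if (n_clip > 0.10 * 2 * n)
      stopf("emt_delta/noise clip %d of %d beta values (>10%%)", n_clip, 2L * n)

    kap_par <- rep(config$kappa_stable, n); names(kap_par) <- id
    kap_res <- kap_par
    kap_par[hyper_ids] <- config$tet_kappa[[1]]
    kap_res[hyper_ids] <- config$tet_kappa[[2]]
    kap_par[hypo_ids] <- config$tet_kappa[[2]]   # hypo: turnover increases
    kap_res[hypo_ids] <- config$tet_kappa[[1]]

    h_noise <- function(len) if (sd > 0) stats::rnorm(len, 0, sd / 5) else 0
    h_par <- clip01(kap_par * m_par_n * (1 - m_par_n) + h_noise(n))
    h_res <- clip01(kap_res * m_res_n * (1 - m_res_n) + h_noise(n))

    std <- cbind(parental = as.numeric(clip01(m_par_n + h_par)),
                 resistant = as.numeric(clip01(m_res_n + h_res)))
    tab <- cbind(parental = as.numeric(h_par), resistant = as.numeric(h_res))

    sig_class <- setNames(lay$signature$klass, lay$signature$gene)
    all_genes <- c(lay$genes$gene, housekeeper_candidates())
    lfc <- setNames(numeric(length(all_genes)), all_genes)
    lfc[names(sig_class)[sig_class == "mesenchymal"]] <- config$expression_effect
    lfc[names(sig_class)[sig_class == "epithelial"]] <- -config$expression_effect
    if (null_sim) lfc[] <- 0
    mu <- stats::rlnorm(length(all_genes), log(config$base_expression), 0.8)
    draw <- function(mu) {
      if (config$dispersion > 0)
        stats::rnbinom(length(mu), size = 1 / config$dispersion, mu = mu)
      else stats::rpois(length(mu), mu)
    }
    expr <- data.frame(gene = all_genes,
                       parental = draw(mu),
                       resistant = draw(mu * 2^lfc),
                       stringsAsFactors = FALSE)

    # ground truth from the pre-noise values: any CpG whose true betas
    # cross the 0.3/0.7 thresholds is truly differential (at large delta
    # this includes signature promoter CpGs, not only the designated sets)
    true_hyper <- id[m_par < 0.3 & m_res > 0.7]
    true_hypo <- id[m_par > 0.7 & m_res < 0.3]

    list(standard = beta_matrix(std, lay$sites, channel = "standard"),
         tab = beta_matrix(tab, lay$sites, channel = "tab"),
         expression = expr,
         truth = list(hyper = true_hyper, hypo = true_hypo,
                      designated_hyper = hyper_ids, designated_hypo = hypo_ids,
                      kappa = data.frame(id = id, parental = kap_par,
                                         resistant = kap_res),
                      m_parental = as.numeric(m_par_n),
                      m_resistant = as.numeric(m_res_n),
                      n_clipped = n_clip),
         genes = lay$genes, sites = lay$sites, promoters = lay$promoters,
         signature = lay$signature)
  })
}

#' Simulate healthy-blood and tumor reference cohorts
#'
#' Emulates a large healthy-blood 450K cohort (capture-panel design input)
#' and a tumor reference cohort (deconvolution input). Designated target
#' CpGs — all signature promoter CpGs plus background CpGs up to
#' `n_target_cpgs` — draw low blood betas (a clean/contaminated mixture
#' with overall mean `blood_mean`); non-target CpGs draw from a bimodal
#' mixture. Tumor reference betas over target CpGs are bimodal with
#' overall mean `tumor_mean`. The cfDNA of every subject additionally
#' carries `cfdna_offset` methylation at the promoters of the 13
#' designated unreliable EMT markers; this offset is invisible to the
#' blood-array reference and is what forces their exclusion downstream.
#'
#' @param config a [sim_config()].
#' @return list with `blood`, `tumor` (`beta_matrix`), `truth` (list:
#'   `target_ids`, `dirty_blood_ids`, `blood_mean`, `tumor_mean` — named
#'   per-CpG true means — `cfdna_offset` named vector, `excluded_genes`),
#'   plus `genes`, `sites`, `promoters`, `signature`.
#' @export
simulate_reference_cohorts <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  lay <- sim_layout(config)
  with_seed(derive_seed(config$seed, "reference"), {
    id <- lay$sites$id
    n <- config$n_cpgs
    sig_cpgs <- c(lay$epi_cpgs, lay$mes_cpgs)
    if (config$n_target_cpgs < length(sig_cpgs))
      stopf("n_target_cpgs (%d) below the %d signature promoter CpGs",
            config$n_target_cpgs, length(sig_cpgs))
    n_bg_target <- config$n_target_cpgs - length(sig_cpgs)
    bg_targets <- lay$bg_ids[seq_len(n_bg_target)]
    target_ids <- c(sig_cpgs, bg_targets)
    nontarget <- setdiff(id, target_ids)

    mu_clean <- (config$blood_mean -
                   config$blood_dirty_prop * config$blood_dirty_mean) /
      (1 - config$blood_dirty_prop)
    if (mu_clean <= 0) stopf("blood_dirty_mean/prop incompatible with blood_mean")

    b <- setNames(numeric(n), id)
    dirty <- bg_targets[stats::runif(length(bg_targets)) < config$blood_dirty_prop]
    b[target_ids] <- mu_clean
    b[dirty] <- config$blood_dirty_mean
    hi <- stats::runif(length(nontarget)) < 0.5
    b[nontarget] <- rbeta_mu(length(nontarget), ifelse(hi, 0.8, 0.2), 30)

    t_lo <- (config$tumor_mean - config$tumor_hi_prop * config$tumor_hi_mean) /
      (1 - config$tumor_hi_prop)
    if (t_lo <= 0) stopf("tumor_hi_mean/prop incompatible with tumor_mean")
    tm <- setNames(numeric(n), id)
    z <- stats::runif(length(target_ids)) < config$tumor_hi_prop
    tm[target_ids] <- rbeta_mu(length(target_ids),
                               ifelse(z, config$tumor_hi_mean, t_lo),
                               config$tumor_conc)
    hi2 <- stats::runif(length(nontarget)) < 0.5
    tm[nontarget] <- rbeta_mu(length(nontarget), ifelse(hi2, 0.8, 0.2), 6)

    blood_vals <- matrix(rbeta_mu(n * config$n_blood,
                                  rep(b, times = config$n_blood),
                                  config$blood_conc),
                         nrow = n, ncol = config$n_blood,
                         dimnames = list(id, sprintf("blood_%03d", seq_len(config$n_blood))))
    tumor_vals <- matrix(rbeta_mu(n * config$n_tumor,
                                  rep(tm, times = config$n_tumor),
                                  config$tumor_sample_conc),
                         nrow = n, ncol = config$n_tumor,
                         dimnames = list(id, sprintf("tumor_%03d", seq_len(config$n_tumor))))

    excluded <- intersect(cfdna_excluded_markers(), lay$signature$gene)
    offset <- setNames(numeric(n), id)
    offset[unlist(lay$promoters[excluded], use.names = FALSE)] <- config$cfdna_offset

    list(blood = beta_matrix(blood_vals, lay$sites, channel = "standard"),
         tumor = beta_matrix(tumor_vals, lay$sites, channel = "standard"),
         truth = list(target_ids = target_ids, dirty_blood_ids = dirty,
                      blood_mean = b, tumor_mean = tm, cfdna_offset = offset,
                      excluded_genes = excluded),
         genes = lay$genes, sites = lay$sites, promoters = lay$promoters,
         signature = lay$signature)
  })
}

# patient-specific true tumor methylome at one EMT state
patient_tumor_profile <- function(config, ref, base_dev, state) {
  tm <- base_dev  # per-patient deviated copy of the cohort mean
  lay_epi <- unlist(ref$promoters[ref$signature$gene[ref$signature$klass == "epithelial"]],
                    use.names = FALSE)
  lay_mes <- unlist(ref$promoters[ref$signature$gene[ref$signature$klass == "mesenchymal"]],
                    use.names = FALSE)
  span <- config$emt_hi - config$emt_lo
  tm[lay_epi] <- config$emt_lo + state * span
  tm[lay_mes] <- config$emt_hi - state * span
  tm
}

#' Simulate a longitudinal cfDNA series for one patient
#'
#' At each timepoint the measured methylome is the two-component mixture
#' `M = f * M_tumor + (1 - f) * M_cfDNA`, where `M_tumor` is a
#' patient-specific tumor profile (cohort mean plus patient deviation,
#' with signature promoters interpolated between epithelial and
#' mesenchymal extremes according to the EMT state) and `M_cfDNA` is the
#' healthy blood profile plus the unreliable-marker offset. Depth is
#' Poisson(`coverage_mean`); methylated counts are Binomial(depth, M).
#' Output is one Bismark-style coverage table per timepoint over all
#' designated target CpGs.
#'
#' @param config a [sim_config()].
#' @param ref output of [simulate_reference_cohorts()] (same config
#'   layout).
#' @param trajectory data.frame with one row per timepoint: `day`
#'   (non-negative, strictly increasing), `f` (true ctDNA fraction in
#'   `[0,1]`), `state` (true EMT state in `[0,1]`, 0 = epithelial).
#' @param patient patient id.
#' @param outcome one of `acquired_resistance`, `intrinsic_resistance`,
#'   `response`, `control`.
#' @return list with `coverages` (named list of coverage data.frames),
#'   `sheet` (sample-sheet rows), `truth` (list: `f`, `state`,
#'   `tumor_profile` per-CpG matrix (CpG x timepoint), `mixture` matrix).
#' @export
simulate_patient_series <- function(config, ref, trajectory,
                                    patient = "P01",
                                    outcome = c("acquired_resistance",
                                                "intrinsic_resistance",
                                                "response", "control")) {
  stopifnot(inherits(config, "sim_config"))
  outcome <- match.arg(outcome)
  need <- c("day", "f", "state")
  if (!all(need %in% names(trajectory)))
    stopf("trajectory needs columns %s", paste(need, collapse = ", "))
  if (nrow(trajectory) < 1) stopf("empty trajectory")
  if (any(diff(trajectory$day) <= 0)) stopf("days must be strictly increasing")
  if (any(trajectory$f < 0 | trajectory$f > 1)) stopf("f outside [0,1]")

  with_seed(derive_seed(config$seed, paste0("patient:", patient)), {
    tid <- ref$truth$target_ids
    ord <- match(tid, ref$sites$id)
    sites <- ref$sites[ord, ]
    nt <- nrow(trajectory)

    # patient-specific deviation from the tumor cohort mean (fixed in time)
    base_dev <- ref$truth$tumor_mean
    base_dev[] <- rbeta_mu(length(base_dev), base_dev, config$patient_dev_conc)

    blood <- ref$truth$blood_mean + ref$truth$cfdna_offset
    blood[blood > 1] <- 1
    status <- trajectory$status %||% c("start",
      if (nt > 2) rep("on_treatment", nt - 2),
      if (nt > 1) switch(outcome, response = "end_of_study",
                         control = "end_of_study", "progression"))

    covs <- list(); profs <- mix <- matrix(NA_real_, length(tid), nt,
                                           dimnames = list(tid, NULL))
    sheet <- data.frame(patient = character(0), sample = character(0),
                        day = integer(0), status = character(0),
                        outcome = character(0))
    for (j in seq_len(nt)) {
      f <- trajectory$f[j]
      prof <- patient_tumor_profile(config, ref, base_dev, trajectory$state[j])
      m <- f * prof[tid] + (1 - f) * blood[tid]
      depth <- stats::rpois(length(tid), config$coverage_mean)
      meth <- stats::rbinom(length(tid), depth, m)
      smp <- sprintf("%s_t%d", patient, j)
      covs[[smp]] <- data.frame(
        chrom = sites$chrom, start = sites$pos, end = sites$pos,
        pct_meth = ifelse(depth > 0, 100 * meth / depth, 0),
        count_meth = meth, count_unmeth = depth - meth,
        stringsAsFactors = FALSE)
      profs[, j] <- prof[tid]; mix[, j] <- m
      sheet <- rbind(sheet, data.frame(patient = patient, sample = smp,
                                       day = as.integer(trajectory$day[j]),
                                       status = status[j], outcome = outcome))
    }
    list(coverages = covs, sheet = sheet,
         truth = list(f = trajectory$f, state = trajectory$state,
                      tumor_profile = profs, mixture = mix))
  })
}

#' Simulate a tumor tissue biopsy for a simulated patient
#'
#' Array-style betas drawn around the patient's true tumor profile at one
#' timepoint; used to test tissue-liquid correlation.
#'
#' @param config a [sim_config()].
#' @param ref reference cohorts object.
#' @param series output of [simulate_patient_series()] for the patient.
#' @param patient patient id (seeds the draw).
#' @param timepoint which timepoint's profile to sample (default 1).
#' @return a one-sample `beta_matrix` over the target CpGs.
#' @export
simulate_tissue_biopsy <- function(config, ref, series, patient = "P01",
                                   timepoint = 1) {
  prof <- series$truth$tumor_profile[, timepoint]
  tid <- rownames(series$truth$tumor_profile)
  sites <- ref$sites[match(tid, ref$sites$id), ]
  with_seed(derive_seed(config$seed, paste0("tissue:", patient)), {
    vals <- matrix(rbeta_mu(length(prof), prof, 50), ncol = 1,
                   dimnames = list(tid, paste0(patient, "_tissue")))
    beta_matrix(vals, sites, channel = "standard")
  })
}

#' Study-design trajectories for a 12-patient cohort
#'
#' Six acquired-resistance patients (samples at onset, on treatment, and
#' progression; EMT state rising to mesenchymal at progression), three
#' durable responders (onset and end of study; state drifting epithelial,
#' ctDNA fraction falling), and three intrinsically resistant patients
#' (onset and first follow-up; state static).
#'
#' @return named list of per-patient lists with elements `trajectory`
#'   (data.frame `day, f, state`) and `outcome`.
#' @export
default_cohort_trajectories <- function() {
  acq <- list(trajectory = data.frame(day = c(0L, 90L, 180L),
                                      f = c(0.25, 0.08, 0.35),
                                      state = c(0.10, 0.30, 0.85)),
              outcome = "acquired_resistance")
  rsp <- list(trajectory = data.frame(day = c(0L, 270L),
                                      f = c(0.20, 0.08),
                                      state = c(0.15, 0.02)),
              outcome = "response")
  intr <- list(trajectory = data.frame(day = c(0L, 60L),
                                       f = c(0.25, 0.40),
                                       state = c(0.60, 0.60)),
               outcome = "intrinsic_resistance")
  out <- c(rep(list(acq), 6), rep(list(rsp), 3), rep(list(intr), 3))
  names(out) <- sprintf("P%02d", seq_along(out))
  out
}
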