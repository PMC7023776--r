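# direct methylome constructor (bypasses read sampling) for exact cases
make_meas <- function(m, keys = sprintf("chr1:%d", seq_along(m) * 100),
                      depth = 100, sample = "S") {
  data.frame(sample = sample, key = keys, chrom = "chr1",
             pos = seq_along(m) * 100L, depth = depth, m = m,
             masked = rep(FALSE, length(m)), stringsAsFactors = FALSE)
}

make_tref <- function(m_tumor, keys = sprintf("chr1:%d", seq_along(m_tumor) * 100)) {
  data.frame(key = keys, id = sprintf("cpg_%06d", seq_along(m_tumor)),
             chrom = "chr1", pos = seq_along(m_tumor) * 100L,
             m_tumor = m_tumor, n_samples = 100L, stringsAsFactors = FALSE)
}

test_that("estimate_f_ctdna recovers a noiseless slope and flags degenerate inputs", {
  set.seed(1)
  x <- runif(200, 0.05, 0.95)
  dc <- estimate_f_ctdna(make_meas(0.1 * x), make_tref(x), nboot = 50)
  expect_equal(dc$f_ctdna, 0.1, tolerance = 1e-12)
  expect_true(dc$reliable)
  expect_true(dc$ci[1] <= 0.1 && dc$ci[2] >= 0.1)

  dc0 <- estimate_f_ctdna(make_meas(rep(0, 200)), make_tref(x), nboot = 0)
  expect_equal(dc0$f_ctdna, 0)
  expect_false(dc0$reliable)

  expect_error(estimate_f_ctdna(make_meas(0.1 * x[1:10]), make_tref(x[1:10]),
                                nboot = 0), "usable CpGs")
  expect_error(estimate_f_ctdna(make_meas(x), make_tref(rep(0, 200)), nboot = 0),
               "all-zero")
})

test_that("cfdna_methylome masks shallow CpGs", {
  cov <- data.frame(chrom = "chr1", start = c(100L, 200L), end = c(100L, 200L),
                    pct_meth = c(50, 50), count_meth = c(2L, 50L),
                    count_unmeth = c(2L, 50L))
  meas <- cfdna_methylome(cov, min_depth = 10)
  expect_true(meas$masked[1])
  expect_true(is.na(meas$m[1]))
  expect_equal(meas$m[2], 0.5)
  expect_equal(meas$key, c("chr1:100", "chr1:200"))
})

test_that("reconstruction divides by f, clips at 1, and refuses unreliable fits", {
  set.seed(2)
  x <- runif(100, 0.1, 0.9)
  dc <- estimate_f_ctdna(make_meas(0.1 * x), make_tref(x), nboot = 0)
  rec <- reconstruct_tumor_methylation(make_meas(c(0.05, 0.5)), dc)
  expect_equal(rec$m_hat, c(0.5, 1.0), tolerance = 1e-9)
  expect_equal(rec$clipped, c(FALSE, TRUE))

  dc$reliable <- FALSE
  expect_error(reconstruct_tumor_methylation(make_meas(0.1), dc), "unreliable")
})

test_that("reconstruction exactly inverts a noise-free mixture", {
  set.seed(3)
  prof <- runif(500, 0.02, 0.98)
  f <- 0.23
  meas <- make_meas(f * prof)
  dc <- estimate_f_ctdna(meas, make_tref(prof), nboot = 0)
  expect_equal(dc$f_ctdna, f, tolerance = 1e-12)
  rec <- reconstruct_tumor_methylation(meas, dc)
  expect_equal(rec$m_hat, prof, tolerance = 1e-9)
})

test_that("f_ctdna estimates separate patients from controls on synthetic data", {
  cfg <- small_cfg(seed = 51)
  ref <- simulate_reference_cohorts(cfg)
  panel <- select_target_cpgs(ref$blood)
  tref <- tumor_reference(ref$tumor, sites = panel$id)
  f_of <- function(f, pn) {
    s <- simulate_patient_series(cfg, ref, data.frame(day = 0, f = f, state = 0.3),
                                 patient = pn)
    estimate_f_ctdna(cfdna_methylome(s$coverages[[1]]), tref, nboot = 0)$f_ctdna
  }
  controls <- vapply(sprintf("C%d", 1:3), function(pn) f_of(0, pn), numeric(1))
  patients <- vapply(sprintf("P%d", 1:3), function(pn) f_of(0.05, pn), numeric(1))
  expect_true(max(controls) < min(patients))
})

test_that("exclude_unreliable_markers drops high, variable, and CpG-less genes", {
  sig <- data.frame(gene = c("GOOD", "HIGH", "WOBBLY", "EMPTY"),
                    klass = c("epithelial", "mesenchymal", "mesenchymal", "epithelial"))
  sites <- data.frame(id = paste0("c", 1:3), chrom = "chr1",
                      pos = c(100L, 200L, 300L))
  prom <- list(GOOD = "c1", HIGH = "c2", WOBBLY = "c3", EMPTY = character(0))
  ctl <- function(m) data.frame(sample = "ctl", key = sprintf("chr1:%d", 1:3 * 100),
                                chrom = "chr1", pos = 1:3 * 100L, depth = 100,
                                m = m, masked = FALSE)
  controls <- list(ctl(c(0.00, 0.40, 0.00)), ctl(c(0.00, 0.42, 0.09)))
  res <- exclude_unreliable_markers(controls, sig, prom, sites)
  rep <- res$report
  expect_equal(rep$reason[rep$gene == "GOOD"], "retained")
  expect_equal(rep$reason[rep$gene == "HIGH"], "high")
  expect_equal(rep$reason[rep$gene == "WOBBLY"], "variable")
  expect_equal(rep$reason[rep$gene == "EMPTY"], "no_cpgs")
  expect_equal(res$retained$gene, "GOOD")
  expect_error(exclude_unreliable_markers(controls[1], sig, prom, sites), ">= 2")
})

test_that("the 13 planted unreliable markers are excluded on synthetic controls", {
  cfg <- small_cfg(seed = 52)
  ref <- simulate_reference_cohorts(cfg)
  controls <- lapply(1:3, function(i) {
    s <- simulate_patient_series(cfg, ref, data.frame(day = 0, f = 0, state = 0),
                                 patient = sprintf("C%02d", i), outcome = "control")
    cfdna_methylome(s$coverages[[1]])
  })
  res <- exclude_unreliable_markers(controls, ref$signature, ref$promoters,
                                    ref$sites)
  expect_setequal(res$report$gene[res$report$excluded], cfdna_excluded_markers())
  expect_equal(unname(res$retained_counts["epithelial"]), 9L)
  expect_equal(unname(res$retained_counts["mesenchymal"]), 28L)
})

test_that("emt_trajectory anchors at t0, scores class means, and calls trends", {
  sites <- data.frame(id = paste0("c", 1:4), chrom = "chr1", pos = 1:4 * 100L)
  prom <- list(E = c("c1", "c2"), M = c("c3", "c4"))
  sig <- data.frame(gene = c("E", "M"), klass = c("epithelial", "mesenchymal"))
  keys <- sprintf("chr1:%d", 1:4 * 100)
  tp <- function(m, f, day) {
    meas <- make_meas(f * m, keys = keys)
    dc <- estimate_f_ctdna(meas, make_tref(m, keys = keys), nboot = 0, min_cpgs = 4)
    list(meas = meas, deconv = dc, day = day)
  }
  # constant methylation: relative scores 0, no shift
  tr0 <- emt_trajectory(list(tp(c(0.2, 0.2, 0.8, 0.8), 0.2, 0),
                             tp(c(0.2, 0.2, 0.8, 0.8), 0.3, 30)),
                        sig, prom, sites)
  expect_equal(tr0$table$rel_score, c(0, 0), tolerance = 1e-9)
  expect_equal(tr0$trend, "no_shift")
  expect_equal(tr0$table$rel_score[1], 0)  # t0 anchored at exactly 0

  # mesenchymal promoters drop 0.8 -> 0.4, epithelial constant: +0.4 shift
  tr1 <- emt_trajectory(list(tp(c(0.2, 0.2, 0.8, 0.8), 0.2, 0),
                             tp(c(0.2, 0.2, 0.4, 0.4), 0.2, 60)),
                        sig, prom, sites)
  expect_equal(tr1$table$rel_score[2], 0.4, tolerance = 1e-9)
  expect_equal(tr1$trend, "emt_shift")

  # unreliable first timepoint: anchored later, with a notice
  bad <- tp(c(0.2, 0.2, 0.8, 0.8), 0.2, 0)
  bad$deconv$reliable <- FALSE
  expect_message(tr2 <- emt_trajectory(list(bad,
                                            tp(c(0.2, 0.2, 0.8, 0.8), 0.2, 30),
                                            tp(c(0.2, 0.2, 0.6, 0.6), 0.2, 60)),
                                       sig, prom, sites),
                 "anchoring")
  expect_equal(tr2$anchor_day, 30)
  expect_error(emt_trajectory(list(tp(c(0.2, 0.2, 0.8, 0.8), 0.2, 0)),
                              sig, prom, sites), ">= 2 timepoints")
})

test_that("tissue-liquid correlation is maximal for the matched patient", {
  cfg <- small_cfg(seed = 53, patient_dev_conc = 4)
  ref <- simulate_reference_cohorts(cfg)
  panel <- select_target_cpgs(ref$blood)
  tref <- tumor_reference(ref$tumor, sites = panel$id)
  sers <- lapply(sprintf("P%d", 1:3), function(pn)
    simulate_patient_series(cfg, ref, data.frame(day = 0, f = 0.3, state = 0.4),
                            patient = pn))
  liquids <- lapply(sers, function(s) {
    meas <- cfdna_methylome(s$coverages[[1]], names(s$coverages)[1])
    list(meas = meas, deconv = estimate_f_ctdna(meas, tref, nboot = 0))
  })
  tissue <- simulate_tissue_biopsy(cfg, ref, sers[[1]], patient = "P1")
  out <- correlate_tissue_liquid(tissue, liquids)
  expect_equal(which(out$best), 1L)
  expect_gt(out$rho[1], max(out$rho[-1]))

  # identical reconstruction: coefficient 1
  rec1 <- reconstruct_tumor_methylation(liquids[[1]]$meas, liquids[[1]]$deconv)
  tis <- data.frame(key = rec1$key, beta = rec1$m_hat)
  self <- correlate_tissue_liquid(tis, liquids[1])
  expect_equal(self$rho, 1, tolerance = 1e-12)
})
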