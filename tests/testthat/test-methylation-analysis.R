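test_that("split_5mc subtracts TAB from standard with a floor at zero", {
  std <- make_beta(matrix(c(0.8, 0.05, 0.6), 3, 1), channel = "standard")
  tab <- make_beta(matrix(c(0.1, 0.10, 0.0), 3, 1), channel = "tab")
  mc <- split_5mc(std, tab)
  expect_equal(unname(mc$values[, 1]), c(0.7, 0, 0.6))
  expect_equal(attr(mc, "n_floored"), 1L)
  expect_equal(mc$channel, "mc_specific")

  tab0 <- make_beta(matrix(0, 3, 1), channel = "tab")
  expect_equal(split_5mc(std, tab0)$values, std$values)

  tab_bad <- make_beta(matrix(0, 2, 1), channel = "tab")
  expect_error(split_5mc(std, tab_bad), "site sets differ")
})

test_that("classify_dmcs applies strict 0.3/0.7 thresholds", {
  p <- c(0.1, 0.9, 0.5, 0.29, 0.7, 0.31)
  r <- c(0.9, 0.1, 0.5, 0.71, 0.3, 0.9)
  calls <- classify_dmcs(p, r)
  expect_equal(calls$call, c("hyper", "hypo", "stable", "hyper", "stable", "stable"))
  expect_equal(calls$dbeta, r - p)

  expect_equal(classify_dmcs(0.2, 0.8)$call, "hyper")
  expect_equal(classify_dmcs(0.3, 0.8)$call, "stable")  # boundary is strict
  expect_error(classify_dmcs(0.2, 0.8, lo = 0.7, hi = 0.3), "lo")

  # missing values are excluded and counted
  cm <- classify_dmcs(c(0.1, NA, 0.2), c(0.9, 0.5, NA))
  expect_equal(nrow(cm), 1)
  expect_equal(attr(cm, "n_missing"), 2L)
})

test_that("classify_dmcs swaps hyper and hypo under argument exchange", {
  set.seed(13)
  p <- runif(500); r <- runif(500)
  a <- classify_dmcs(p, r); b <- classify_dmcs(r, p)
  expect_equal(a$call == "hyper", b$call == "hypo")
  expect_equal(a$call == "stable", b$call == "stable")
})

test_that("promoter_emt_methylation pools class delta-beta and averages per gene", {
  # 2 epithelial genes x 3 CpGs (+0.3), 2 mesenchymal x 3 CpGs (-0.3)
  sig <- data.frame(gene = c("E1", "E2", "M1", "M2"),
                    klass = rep(c("epithelial", "mesenchymal"), each = 2))
  prom <- list(E1 = paste0("cpg_00000", 1:3), E2 = paste0("cpg_00000", 4:6),
               M1 = paste0("cpg_00000", 7:9),
               M2 = c("cpg_000010", "cpg_000011", "cpg_000012"))
  par <- c(rep(0.2, 6), rep(0.8, 6))
  res <- c(rep(0.5, 6), rep(0.5, 6))
  bm <- make_beta(cbind(parental = par, resistant = res))
  out <- promoter_emt_methylation(bm, prom, sig, "parental", "resistant")
  cs <- out$class_summary
  expect_equal(cs$mean_dbeta[cs$klass == "epithelial"], 0.3)
  expect_equal(cs$mean_dbeta[cs$klass == "mesenchymal"], -0.3)
  expect_lt(out$p, 0.05)  # one-sided: mesenchymal < epithelial
  expect_equal(out$per_gene$dbeta, c(0.3, 0.3, -0.3, -0.3))

  # per-gene promoter mean is the unweighted CpG mean, order-invariant
  bm2 <- make_beta(cbind(parental = c(0.2, 0.4, 0.9), resistant = c(0.2, 0.4, 0.9)))
  p2 <- list(G = c("cpg_000003", "cpg_000001", "cpg_000002"))
  s2 <- data.frame(gene = c("G", "H"), klass = c("epithelial", "mesenchymal"))
  o2 <- promoter_emt_methylation(bm2, c(p2, list(H = "cpg_000001")), s2,
                                 "parental", "resistant")
  expect_equal(o2$per_gene$mean_parental[o2$per_gene$gene == "G"], 0.5)

  # all delta-beta zero: means 0, p = 1
  bm3 <- make_beta(cbind(parental = par, resistant = par))
  o3 <- promoter_emt_methylation(bm3, prom, sig, "parental", "resistant")
  expect_equal(o3$class_summary$mean_dbeta, c(0, 0))
  expect_equal(o3$p, 1)

  # signature gene with no promoter CpGs is reported, not scored
  o4 <- promoter_emt_methylation(bm, c(prom, list(X = character(0))),
                                 rbind(sig, data.frame(gene = "X", klass = "epithelial")),
                                 "parental", "resistant")
  expect_true("X" %in% o4$genes_without_cpgs)
})

test_that("quadrant_enrichment counts expected quadrants and drops axis genes", {
  sig <- data.frame(gene = paste0("M", 1:4), klass = "mesenchymal")
  fc <- data.frame(gene = sig$gene, log2fc = c(1, 2, 0.5, -1))
  db <- data.frame(gene = sig$gene, dbeta = c(-0.2, -0.1, -0.3, -0.2))
  q <- quadrant_enrichment(fc, db, sig)
  mes <- q[q$klass == "mesenchymal", ]
  expect_equal(mes$fraction, 0.75)
  expect_true(mes$enriched)
  expect_equal(mes$expected_fraction, 0.25)

  # exact zeros leave the denominator
  fc0 <- transform(fc, log2fc = 0)
  q0 <- quadrant_enrichment(fc0, db, sig)
  expect_true(is.na(q0$fraction[q0$klass == "mesenchymal"]))
  expect_equal(q0$n[q0$klass == "mesenchymal"], 0)
})

test_that("overlap_binomial matches the exact binomial tail and validates inputs", {
  oc <- make_overlap_calls(100, 10, 10, 0)
  r0 <- overlap_binomial(oc$A, oc$B)
  expect_equal(r0$expected, 1.0)
  expect_equal(r0$p, 1)

  oc5 <- make_overlap_calls(100, 10, 10, 5)
  r5 <- overlap_binomial(oc5$A, oc5$B)
  # oracle: upper tail of Binomial(10, 0.1)
  expect_equal(r5$p, sum(dbinom(5:10, 10, 0.1)), tolerance = 1e-12)
  expect_equal(r5$p, 1.63e-3, tolerance = 0.01)
  expect_equal(r5$k, 5)

  expect_error(overlap_binomial(oc5$A[0, ], oc5$B[0, ]), "no CpGs")

  # hypergeometric alternative available
  rh <- overlap_binomial(oc5$A, oc5$B, null = "hypergeometric")
  expect_equal(rh$p, phyper(4, 10, 90, 10, lower.tail = FALSE), tolerance = 1e-12)
})

test_that("overlap_binomial conditions symmetrically on the smaller count", {
  oc <- make_overlap_calls(200, 12, 40, 6)
  ab <- overlap_binomial(oc$A, oc$B)
  ba <- overlap_binomial(oc$B, oc$A)
  expect_equal(ab$p, ba$p)
  expect_equal(ab$expected, ba$expected)
  # conditioning choice is exposed
  rA <- overlap_binomial(oc$A, oc$B, condition_on = "A")
  expect_equal(rA$p, sum(dbinom(6:12, 12, 40 / 200)), tolerance = 1e-12)
})

test_that("overlap p-values agree with a permutation null within Monte Carlo error", {
  set.seed(77)
  # sampling fractions kept small so the binomial null tracks the
  # (hypergeometric) permutation null within Monte Carlo error
  N <- 1000; nA <- 30; nB <- 40; nperm <- 2000
  for (k_obs in c(3, 4)) {
    oc <- make_overlap_calls(N, nA, nB, k_obs)
    p_fit <- overlap_binomial(oc$A, oc$B)$p
    shared <- replicate(nperm, {
      a <- sample.int(N, nA); b <- sample.int(N, nB)
      length(intersect(a, b))
    })
    p_perm <- mean(shared >= k_obs)
    se <- sqrt(p_perm * (1 - p_perm) / nperm)
    expect_lt(abs(p_fit - p_perm), 3 * se + 1e-3)
  }
})
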