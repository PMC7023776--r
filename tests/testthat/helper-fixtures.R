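# In-code fixtures: everything is generated at test time.

# quick beta_matrix: values as vector/matrix, sites autogenerated on chr1
make_beta <- function(values, samples = NULL, channel = "standard",
                      pos = NULL, chrom = NULL) {
  v <- as.matrix(values)
  if (!is.null(samples)) colnames(v) <- samples
  if (is.null(colnames(v))) colnames(v) <- paste0("S", seq_len(ncol(v)))
  n <- nrow(v)
  sites <- data.frame(id = sprintf("cpg_%06d", seq_len(n)),
                      chrom = chrom %||% rep("chr1", n),
                      pos = pos %||% (seq_len(n) * 100L))
  beta_matrix(v, sites, channel = channel)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# small, fast config used across module tests
small_cfg <- function(seed = 1, ...) {
  sim_config(seed = seed, n_cpgs = 2000, n_target_cpgs = 800,
             n_blood = 40, n_tumor = 30, n_hyper = 150, n_hypo = 150, ...)
}

# calls data.frame realizing exact overlap-test counts on N common CpGs;
# feasible only when k >= n_A + n_B - N
make_overlap_calls <- function(N, n_A, n_B, k, direction = "hyper") {
  stopifnot(k >= max(0, n_A + n_B - N), k <= min(n_A, n_B))
  ids <- sprintf("s%04d", seq_len(N))
  callA <- rep("stable", N); callA[seq_len(n_A)] <- direction
  callB <- rep("stable", N)
  callB[seq_len(k)] <- direction                      # shared
  if (n_B > k) callB[n_A + seq_len(n_B - k)] <- direction
  list(A = data.frame(id = ids, call = callA, stringsAsFactors = FALSE),
       B = data.frame(id = ids, call = callB, stringsAsFactors = FALSE))
}
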