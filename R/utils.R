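#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run code with a reproducible, platform-stable RNG state
#'
#' Fixes the RNG kinds (Mersenne-Twister / Inversion / Rejection) so that a
#' given seed yields identical streams on every platform, and restores the
#' caller's RNG state on exit.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed), kind = "Mersenne-Twister",
           normal.kind = "Inversion", sample.kind = "Rejection")
  expr
}

#' Derive a stage-specific seed from a global run seed
#'
#' A single run seed is fanned out to independent per-stage streams so that
#' stages can be re-run standalone yet reproducibly. The derivation hashes
#' the stage tag into a 31-bit integer.
#'
#' @param seed integer global seed.
#' @param tag character stage label, e.g. `"blood"` or `"patient:P03"`.
#' @return an integer in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, tag) {
  h <- 0
  for (ch in utf8ToInt(as.character(tag))) h <- (h * 31 + ch) %% 2147483647
  as.integer((as.numeric(seed) %% 2147483647 * 2654435 + h) %% 2147483646 + 1)
}

# log(sum(exp(x))) without overflow; used by the binomial tail sum
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Draw Beta variates parameterized by mean and concentration
#'
#' `shape1 = mu * conc`, `shape2 = (1 - mu) * conc`; `conc` plays the role of
#' a precision (larger = tighter around `mu`).
#'
#' @param n number of draws.
#' @param mu mean(s) in (0, 1).
#' @param conc concentration(s) > 0.
#' @return numeric vector of draws in (0, 1).
#' @export
rbeta_mu <- function(n, mu, conc) {
  mu <- pmin(pmax(mu, 1e-6), 1 - 1e-6)
  stats::rbeta(n, shape1 = mu * conc, shape2 = (1 - mu) * conc)
}

# clip to [0,1], returning the clipped vector with attribute n_clipped
clip01 <- function(x) {
  n <- sum(x < 0 | x > 1, na.rm = TRUE)
  structure(pmin(pmax(x, 0), 1), n_clipped = n)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
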