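# Internal numeric and RNG helpers shared across modules.

#' Names of the perfusion (PWI) features
#'
#' Normalized perfusion parameters measured by dynamic susceptibility
#' contrast imaging: regional cerebral blood volume, mean transit time,
#' regional cerebral blood flow, contrast arrival time and time to peak,
#' each normalized by a contralateral normal region.
#'
#' @return Character vector of feature (column) names.
#' @export
perfusion_features <- function() c("nrCBV", "nMTT", "nrCBF", "nT0", "nTTP")

#' Names of the MR spectroscopic imaging (MRSI) features
#'
#' Metabolite ratios relative to creatine: choline, N-acetyl aspartate,
#' lactate and lipid at 1.3 ppm.
#'
#' @return Character vector of feature (column) names.
#' @export
mrsi_features <- function() c("Cho_Cr", "NAA_Cr", "Lac_Cr", "Lip13_Cr")

grade_states <- function() c("high", "low")
t1wc_states <- function() c("negative", "slight", "apparent")

all_feature_columns <- function() c(perfusion_features(), mrsi_features())

`%||%` <- function(a, b) if (is.null(a)) b else a

# Deterministic 31-bit sub-seed derived from a master seed and a label, so
# that adding or reordering features does not disturb other features' draws.
derive_seed <- function(seed, label) {
  h <- as.numeric(seed) %% 2147483647
  for (ch in utf8ToInt(label)) h <- (h * 31 + ch) %% 2147483647
  as.integer(h)
}

log_sum_exp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Log-density of a multivariate normal via Cholesky; `sigma` must be
# symmetric positive definite (per-node variance floors guarantee this).
log_dmvnorm <- function(x, mean, sigma) {
  d <- length(x)
  if (d == 1L) return(stats::dnorm(x, mean, sqrt(sigma[1L, 1L]), log = TRUE))
  ch <- chol(sigma)
  z <- backsolve(ch, x - mean, transpose = TRUE)
  -0.5 * d * log(2 * pi) - sum(log(diag(ch))) - 0.5 * sum(z^2)
}

is_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x)

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
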