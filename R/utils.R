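#' @importFrom rlang %||% abort warn inform
#' @importFrom stats pnorm pt pbeta qnorm rnorm runif rbinom rnbinom sd cor var
#'   coef cov rexp lm lm.fit optim prcomp smooth.spline predict median quantile
#'   complete.cases p.adjust cor.test t.test ks.test setNames
#' @importFrom utils head tail
NULL

# numerically stable log(sum(exp(x)))
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# log(exp(a) - exp(b)) for a >= b; returns -Inf when the difference underflows
logdiff <- function(a, b) {
  if (b >= a) return(-Inf)
  a + log1p(-exp(b - a))
}

# deterministic child seed from a master seed and a stage/gene offset,
# kept inside 32-bit integer range
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(offset) * 16807) %% 2147483629L) + 1L
}

# minor-allele frequency folded at 0.5
fold_maf <- function(freq) pmin(freq, 1 - freq)

empirical_maf <- function(dosage) fold_maf(colMeans(dosage) / 2)

stopifnot_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number", name))
  }
}

# two-sided p from a t statistic
t_pvalue <- function(tstat, df) 2 * pt(-abs(tstat), df)
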