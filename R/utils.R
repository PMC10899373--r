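#' @useDynLib rdmjoint, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats rnorm runif rgamma rbinom pnorm dnorm quantile cov var
#'   median sd rWishart setNames aggregate
#' @importFrom MASS mvrnorm
NULL

## Numerically stable log(sum(exp(x))).
logsumexp <- function(x) {
  x <- x[!is.na(x)]
  if (!length(x)) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

logmeanexp <- function(x) logsumexp(x) - log(length(x))

## Evaluate `code` under a temporary RNG state seeded with `seed`; the caller's
## RNG stream is untouched. All exported stochastic entry points funnel through
## this so that a seed argument gives full reproducibility.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

## Deterministic child-seed spawning: child i of master seed s.
## Kept strictly below 2^31 so set.seed() always accepts the result.
spawn_seed <- function(seed, i) {
  as.integer((as.double(seed) * 48271 + 7919 * as.double(i)) %% 2147483587)
}

## Multivariate normal log-density (vectorised over rows of x).
dmvnorm_log <- function(x, mean, sigma_chol = NULL, sigma = NULL) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  p <- ncol(x)
  if (is.null(sigma_chol)) sigma_chol <- chol(sigma)
  z <- backsolve(sigma_chol, t(x) - mean, transpose = TRUE)
  -0.5 * p * log(2 * pi) - sum(log(diag(sigma_chol))) - 0.5 * colSums(z^2)
}

## Multivariate t log-density (df nu), vectorised over rows of x.
dmvt_log <- function(x, mean, sigma_chol, nu) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  p <- ncol(x)
  z <- backsolve(sigma_chol, t(x) - mean, transpose = TRUE)
  q <- colSums(z^2)
  lgamma((nu + p) / 2) - lgamma(nu / 2) - 0.5 * p * log(nu * pi) -
    sum(log(diag(sigma_chol))) - 0.5 * (nu + p) * log1p(q / nu)
}

rmvnorm_chol <- function(n, mean, sigma_chol) {
  p <- length(mean)
  z <- matrix(rnorm(n * p), n, p) %*% sigma_chol
  sweep(z, 2, mean, "+")
}

## Inverse-gamma helpers (shape/rate parameterisation: IG(a, b) has mean
## b / (a - 1)).
rinvgamma <- function(n, shape, rate) 1 / rgamma(n, shape = shape, rate = rate)
dinvgamma_log <- function(x, shape, rate) {
  shape * log(rate) - lgamma(shape) - (shape + 1) * log(x) - rate / x
}

## Inverse-Wishart draw: X ~ IW(df, S) via Wishart on the inverse scale.
rinvwishart <- function(df, S) {
  W <- rWishart(1, df, solve(S))[, , 1]
  solve(W)
}

lmvgamma <- function(a, p) {
  0.25 * p * (p - 1) * log(pi) + sum(lgamma(a + (1 - seq_len(p)) / 2))
}

## Inverse-Wishart log-density of Sigma under IW(df, S).
dinvwishart_log <- function(Sigma, df, S) {
  p <- nrow(Sigma)
  ldS <- determinant(S, logarithm = TRUE)$modulus
  ldSig <- determinant(Sigma, logarithm = TRUE)$modulus
  as.numeric(0.5 * df * ldS - 0.5 * df * p * log(2) - lmvgamma(df / 2, p) -
    0.5 * (df + p + 1) * ldSig - 0.5 * sum(diag(S %*% solve(Sigma))))
}

## Symmetrise + ridge, for covariance estimates fed to chol().
make_pd <- function(S, ridge = 1e-6) {
  S <- (S + t(S)) / 2
  S + diag(ridge, nrow(S))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
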