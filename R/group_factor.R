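## Factor-analytic group level: alpha_i = mu + Lambda eta_i + e_i with
## diagonal uniquenesses, identification by fixed zeros above the diagonal of
## the loading matrix (in the declared parameter ordering), and blocked Gibbs
## full conditionals.

#' Construct a factor-analytic group state
#'
#' @param mu group mean vector (sampling scale).
#' @param Lambda p x k loading matrix; entries above the diagonal in the first
#'   k rows must be zero, and the diagonal entries must be nonnegative
#'   (identification constraints: the zeros pin the factor rotation, the
#'   sign constraint removes the reflection modes).
#' @param eps length-p positive uniquenesses (residual variances).
#' @param eta n x k factor scores (may be `NULL` until subjects are attached).
#' @export
factor_group <- function(mu, Lambda, eps, eta = NULL) {
  p <- length(mu)
  Lambda <- as.matrix(Lambda)
  k <- ncol(Lambda)
  if (k >= p) stop("number of factors must be smaller than the parameter count")
  stopifnot(nrow(Lambda) == p, length(eps) == p)
  if (any(eps <= 0)) stop("uniquenesses must be positive")
  free <- factor_free_mask(p, k)
  if (any(abs(Lambda[!free]) > 0))
    stop("constrained loadings (above the diagonal) must be exactly 0")
  if (any(diag(as.matrix(Lambda[seq_len(k), , drop = FALSE])) < 0))
    stop("diagonal loadings must be nonnegative (sign identification)")
  structure(list(mu = mu, Lambda = Lambda, eps = eps, eta = eta,
                 free = free, kind = "factor"),
            class = "group_state")
}

## TRUE where a loading is free; Lambda[j, m] with m > j is fixed to zero.
factor_free_mask <- function(p, k) {
  outer(seq_len(p), seq_len(k), ">=")
}

#' Blocked Gibbs update of the factor-analytic group level
#'
#' Draws, in order: factor scores given loadings and uniquenesses
#' (ridge-regression normal), loading rows given scores (normal, honouring
#' the fixed zeros), uniquenesses (inverse gamma), and the mean (normal).
#'
#' @param group a [factor_group()].
#' @param alpha n x p matrix of subject vectors (sampling scale).
#' @param prior a [group_prior()].
#' @param seed optional seed.
#' @export
gibbs_update_factor <- function(group, alpha, prior, seed = NULL) {
  n <- nrow(alpha); p <- ncol(alpha); k <- ncol(group$Lambda)
  with_seed(seed, {
    mu <- group$mu; L <- group$Lambda; eps <- group$eps
    ctr <- sweep(alpha, 2, mu)
    ## eta_i | rest
    prec <- diag(k) + t(L) %*% (L / eps)
    U <- chol(make_pd(prec, 0))
    mean_eta <- t(backsolve(U, backsolve(U, t(ctr %*% (L / eps)),
                                         transpose = TRUE)))
    eta <- mean_eta + t(backsolve(U, matrix(rnorm(n * k), k, n)))
    ## Lambda rows | rest (free entries only; normal prior with the
    ## configured scale; the diagonal entry of rows 1..k is half-normal,
    ## drawn by single-site truncated Gibbs within the row)
    lprec <- 1 / (prior$lambda_sd %||% 1)^2
    for (j in seq_len(p)) {
      fr <- which(group$free[j, ])
      if (!length(fr)) next
      H <- eta[, fr, drop = FALSE]
      prj <- diag(lprec, length(fr)) + crossprod(H) / eps[j]
      bj <- crossprod(H, ctr[, j]) / eps[j]
      if (j > k) {
        Uj <- chol(make_pd(prj, 0))
        mj <- backsolve(Uj, backsolve(Uj, bj, transpose = TRUE))
        L[j, ] <- 0
        L[j, fr] <- as.numeric(mj + backsolve(Uj, rnorm(length(fr))))
      } else {
        x <- L[j, fr]
        for (ci in seq_along(fr)) {
          v <- 1 / prj[ci, ci]
          m <- v * (bj[ci] - sum(prj[ci, -ci] * x[-ci]))
          x[ci] <- if (fr[ci] == j) rtruncnorm_pos(m, sqrt(v))
                   else rnorm(1, m, sqrt(v))
        }
        L[j, ] <- 0
        L[j, fr] <- x
      }
    }
    ## eps | rest
    resid <- ctr - eta %*% t(L)
    eps <- rinvgamma(p, prior$eps_shape + n / 2,
                     prior$eps_rate + colSums(resid^2) / 2)
    ## mu | rest
    fitted <- eta %*% t(L)
    prec_mu <- 1 + n / eps
    mean_mu <- (prior$mu0 + colSums(alpha - fitted) / eps) / prec_mu
    mu <- setNames(rnorm(p, mean_mu, sqrt(1 / prec_mu)), names(group$mu))
    factor_group(mu, L, eps, eta)
  })
}

## One draw from N(m, s^2) truncated to [0, Inf).
rtruncnorm_pos <- function(m, s) {
  p0 <- pnorm(0, m, s)
  u <- runif(1, min(p0, 1 - 1e-12), 1)
  max(qnorm(u, m, s), 0)
}

#' Align the signs of factor-loading draws
#'
#' The factor likelihood is invariant to flipping the sign of a whole column
#' of loadings together with its factor scores; for interpretable summaries,
#' each column of each draw is flipped so that its largest-magnitude median
#' loading is positive.
#'
#' @param Lambda_draws p x k x n_draws array of loading draws.
#' @return the array with column signs aligned.
#' @export
align_loadings <- function(Lambda_draws) {
  k <- dim(Lambda_draws)[2]
  med <- apply(Lambda_draws, c(1, 2), median)
  for (m in seq_len(k)) {
    lead <- which.max(abs(med[, m])) # reference loading for this column
    flip <- Lambda_draws[lead, m, ] < 0
    Lambda_draws[, m, flip] <- -Lambda_draws[, m, flip]
  }
  Lambda_draws
}
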