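## Multivariate-normal group level with the marginally noninformative
## hierarchical inverse-Wishart (Huang-Wand) covariance prior, and its
## conjugate Gibbs full conditionals.

#' Construct a multivariate-normal group state
#'
#' @param mu group mean vector (sampling scale).
#' @param Sigma group covariance (symmetric positive definite).
#' @param a auxiliary scale vector of the hierarchical covariance prior.
#' @export
mvn_group <- function(mu, Sigma, a = rep(1, length(mu))) {
  p <- length(mu)
  Sigma <- as.matrix(Sigma)
  stopifnot(nrow(Sigma) == p, ncol(Sigma) == p, length(a) == p)
  structure(list(mu = mu, Sigma = Sigma, a = a, kind = "mvn"),
            class = "group_state")
}

#' Group-level prior specification
#'
#' Means have independent normal priors with unit variance; the prior
#' locations are set on the natural scale by parameter kind (2 for thresholds,
#' 2 for difference/processing-ability parameters, 1 for urgency, 0.2 for
#' non-decision time, 0 otherwise) and mapped through each parameter's
#' sampling transform. The covariance prior is the hierarchical
#' inverse-Wishart with degrees `nu` and half-t scales `A` (marginally
#' noninformative); factor-model priors are standard-normal free loadings,
#' inverse-gamma uniquenesses and standard-normal factor scores.
#'
#' @param param_names names of the concatenated parameter vector.
#' @param transforms sampling transforms (from [param_layout()]); identity
#'   assumed if omitted.
#' @param nu,A hierarchical inverse-Wishart hyperparameters.
#' @param eps_shape,eps_rate inverse-gamma prior on factor uniquenesses.
#' @param lambda_sd prior standard deviation of free factor loadings. The
#'   default matches the scale of sampling-scale subject variability in these
#'   models; a unit-scale prior would place almost all its mass on loadings
#'   larger than any attainable value and correspondingly distort
#'   factor-count comparison through the prior's Occam penalty.
#' @export
group_prior <- function(param_names, transforms = NULL, nu = 2, A = 1,
                        eps_shape = 2, eps_rate = 0.3, lambda_sd = 0.5) {
  p <- length(param_names)
  transforms <- transforms %||% setNames(rep("identity", p), param_names)
  base <- sub(".*\\.", "", param_names)
  nat <- numeric(p)
  nat[grepl("^B", base)] <- 2
  nat[grepl("^delta", base)] <- 2
  nat[grepl("^V0", base)] <- 1
  nat[base == "t0"] <- 0.2
  mu0 <- nat
  mu0[transforms == "log"] <- log(pmax(nat[transforms == "log"], 1e-8))
  mu0[transforms == "logit"] <- 0 # midpoint on the natural scale
  structure(list(param_names = param_names, mu0 = setNames(mu0, param_names),
                 nu = nu, A = rep(A, length.out = p),
                 eps_shape = eps_shape, eps_rate = eps_rate,
                 lambda_sd = lambda_sd),
            class = "group_prior_spec")
}

#' Log prior density of a group state
#'
#' For the multivariate-normal state: normal prior on the mean, conditional
#' inverse-Wishart on the covariance given the auxiliary scales, and
#' inverse-gamma on the scales. For the factor state: normal prior on the
#' mean and the free loadings, inverse-gamma on the uniquenesses, and
#' standard normal on the factor scores; constraint violations (fixed-zero
#' loadings perturbed, nonpositive uniquenesses) give `-Inf`.
#'
#' @param group a group state ([mvn_group()] or [factor_group()]).
#' @param prior a [group_prior()].
#' @export
log_prior <- function(group, prior) {
  p <- length(group$mu)
  stopifnot(length(prior$mu0) == p)
  lp_mu <- sum(dnorm(group$mu, prior$mu0, 1, log = TRUE))
  if (group$kind == "mvn") {
    nu <- prior$nu
    df <- nu + p - 1
    S <- 2 * nu * diag(1 / group$a, p)
    lp_mu + dinvwishart_log(group$Sigma, df, S) +
      sum(dinvgamma_log(group$a, 1 / 2, 1 / prior$A^2))
  } else {
    if (any(group$eps <= 0)) return(-Inf)
    free <- group$free
    if (any(abs(group$Lambda[!free]) > 0)) return(-Inf)
    k <- ncol(group$Lambda)
    dg <- diag(as.matrix(group$Lambda[seq_len(k), , drop = FALSE]))
    if (any(dg < 0)) return(-Inf)
    ## free loadings normal; diagonal entries half-normal (the sign
    ## constraint folds the two reflection modes together)
    lsd <- prior$lambda_sd %||% 1
    lp_mu + sum(dnorm(group$Lambda[free], 0, lsd, log = TRUE)) + k * log(2) +
      sum(dinvgamma_log(group$eps, prior$eps_shape, prior$eps_rate)) +
      sum(dnorm(group$eta, 0, 1, log = TRUE))
  }
}

#' Gibbs update of the multivariate-normal group level
#'
#' Conjugate draws of `mu | Sigma, alpha`, `Sigma | mu, alpha, a` (inverse
#' Wishart) and the auxiliary scales `a | Sigma` (inverse gamma) under the
#' hierarchical inverse-Wishart prior.
#'
#' @param group an [mvn_group()].
#' @param alpha n x p matrix of subject vectors (sampling scale).
#' @param prior a [group_prior()].
#' @param seed optional seed.
#' @param Sigma_fixed if `TRUE`, the covariance (and auxiliaries) are held
#'   fixed and only the mean is updated; used for conjugate validation models.
#' @export
gibbs_update_mvn <- function(group, alpha, prior, seed = NULL,
                             Sigma_fixed = FALSE) {
  n <- nrow(alpha); p <- ncol(alpha)
  if (n < 2) stop("the group update needs at least 2 subjects")
  if (any(!is.finite(alpha))) stop("non-finite subject vectors")
  with_seed(seed, {
    Sig_inv <- chol2inv(chol(make_pd(group$Sigma, 0)))
    prec <- diag(p) + n * Sig_inv
    b <- prior$mu0 + Sig_inv %*% colSums(alpha)
    U <- chol(prec)
    mean_mu <- backsolve(U, backsolve(U, b, transpose = TRUE))
    mu <- as.numeric(mean_mu + backsolve(U, rnorm(p)))
    if (!Sigma_fixed) {
      ctr <- sweep(alpha, 2, mu)
      S <- crossprod(ctr)
      nu <- prior$nu
      df <- nu + p - 1 + n
      scale <- 2 * nu * diag(1 / group$a, p) + S
      Sigma <- rinvwishart(df, scale)
      Sig_inv2 <- chol2inv(chol(make_pd(Sigma, 0)))
      a <- rinvgamma(p, (nu + p) / 2, nu * diag(Sig_inv2) + 1 / prior$A^2)
    } else {
      Sigma <- group$Sigma; a <- group$a
    }
    mvn_group(setNames(mu, names(group$mu)), Sigma, a)
  })
}

#' Correlation matrix implied by a group state
#'
#' Normalises the group covariance (or the factor model's implied covariance
#' \eqn{\Lambda\Lambda^T + diag(\epsilon)}) to unit diagonal.
#'
#' @param group a group state.
#' @export
implied_correlations <- function(group) {
  S <- implied_cov(group)
  v <- diag(S)
  if (any(v <= 0)) stop("zero or negative variance; correlations undefined")
  stats::cov2cor(S)
}

#' Covariance matrix implied by a group state
#' @param group a group state.
#' @export
implied_cov <- function(group) {
  if (group$kind == "mvn") group$Sigma
  else group$Lambda %*% t(group$Lambda) + diag(group$eps, length(group$eps))
}
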