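## Importance-sampling-squared (IS2) estimation of the log marginal
## likelihood of a fitted hierarchical model. Outer level: a multivariate-t
## proposal moment-matched to the posterior draws of the (unconstrained)
## group-parameter vector. Inner level: per subject, an importance estimate of
## p(y_s | group) using a Gaussian proposal fitted to that subject's
## posterior draws. Ratios of two estimates give Bayes factors, with
## bootstrap standard errors from resampling the importance weights.

#' IS2 estimate of the log marginal likelihood
#'
#' @param fit a `pmwg_fit` with a completed sampling stage.
#' @param n_is number of outer importance samples.
#' @param n_particles inner importance samples per subject per outer draw.
#' @param df degrees of freedom of the outer multivariate-t proposal.
#' @param inflate variance inflation of the outer proposal covariance.
#' @param shrink diagonal shrinkage weight of the outer proposal covariance
#'   (guards against rank deficiency when draws are few relative to the
#'   group-parameter dimension).
#' @param n_boot bootstrap replicates for the standard error.
#' @param kernel_weight mixture weight of the kernel component of the outer
#'   proposal: with this probability an outer sample is a posterior draw
#'   perturbed by Gaussian noise (bandwidth `kernel_h` times the posterior
#'   scale), which keeps the proposal close to the posterior when the
#'   group-parameter dimension is large relative to the number of draws; the
#'   remaining mass is the heavy-tailed moment-matched t component.
#' @param kernel_h kernel bandwidth factor.
#' @param n_eta factor models only: number of factor-score draws per subject
#'   per outer sample in the factorized inner estimator (conditional on the
#'   factor scores the task components are independent, so the subject
#'   integral is estimated component-wise in low dimension).
#' @param seed integer seed.
#' @return an `evidence_result`: `logml`, `se`, per-sample `log_weights`,
#'   effective sample size, `reliable` flag (ESS >= 5% of `n_is`), and config.
#' @export
is2_marglik <- function(fit, n_is = 1000, n_particles = 250, df = 5,
                        inflate = 1.2, shrink = 0.2, n_boot = 200,
                        kernel_weight = 0.5, kernel_h = 0.5, n_eta = 16,
                        seed = 1L) {
  stopifnot(inherits(fit, "pmwg_fit"))
  dr <- stage_draws(fit)
  n <- dim(dr$alpha)[2]; p <- dim(dr$alpha)[3]
  fixed <- isTRUE(fit$Sigma_fixed)
  ## outer proposal from group-vector draws (mean only when the covariance is
  ## held fixed, as in conjugate validation models)
  theta <- if (fixed) dr$mu else
    t(vapply(seq_along(dr$idx), function(i)
      group_to_vec(draw_group(fit, dr, i)), numeric(group_vec_len(fit))))
  m <- colMeans(theta)
  S <- cov(theta)
  S <- (1 - shrink) * S + shrink * diag(diag(S) + 1e-8, ncol(S))
  S <- make_pd(S * inflate, 1e-8)
  Sch <- chol(S)
  ## inner proposals per subject
  subj_prop <- lapply(seq_len(n), function(s) {
    X <- matrix(dr$alpha[, s, ], ncol = p)
    Sp <- make_pd(cov(X) * 1.2, 1e-8)
    list(m = colMeans(X), chol = chol(Sp))
  })
  ## factorized route (factor group + component model): conditional on the
  ## factor scores the components are independent with diagonal residuals, so
  ## the subject-level integral splits into low-dimensional pieces
  factorized <- fit$group_kind == "factor" && is.null(fit$model$loglik)
  template <- draw_group(fit, dr, 1)
  Kch <- Sch * kernel_h # kernel component: posterior draw + N(0, h^2 S)
  M <- nrow(theta)
  with_seed(seed, {
    ## For the factorized route all inner randomness is drawn up front from
    ## theta-independent proposals; each outer draw then only reweights the
    ## cached particles (their likelihoods are computed once).
    if (factorized)
      cache <- build_factorized_cache(fit, dr, n, n_particles, n_eta)
    d <- ncol(S)
    from_kern <- runif(n_is) < kernel_weight
    z <- matrix(rnorm(n_is * d), n_is)
    g <- sqrt(df / stats::rchisq(n_is, df))
    thetas <- sweep(z %*% Sch * g, 2, m, "+")
    nk <- sum(from_kern)
    if (nk) {
      ctr <- theta[sample.int(M, nk, replace = TRUE), , drop = FALSE]
      thetas[from_kern, ] <- ctr + matrix(rnorm(nk * d), nk) %*% Kch
    }
    lt <- dmvt_log(thetas, m, Sch, df)
    lkern <- vapply(seq_len(n_is), function(i) {
      zz <- backsolve(Kch, t(theta) - thetas[i, ], transpose = TRUE)
      -0.5 * d * log(2 * pi) - sum(log(diag(Kch))) +
        logmeanexp(-0.5 * colSums(zz^2))
    }, numeric(1))
    lq <- apply(cbind(log(1 - kernel_weight) + lt,
                      log(kernel_weight + 1e-300) + lkern), 1, logsumexp)
    lw <- vapply(seq_len(n_is), function(i) {
      gi <- if (fixed)
        mvn_group(setNames(thetas[i, ], fit$param_names), template$Sigma)
      else try(vec_to_group(thetas[i, ], template), silent = TRUE)
      if (inherits(gi, "try-error")) return(-Inf)
      lp <- if (fixed) sum(dnorm(gi$mu, fit$prior$mu0, 1, log = TRUE))
            else log_prior_theta(gi, fit$prior, thetas[i, ])
      if (!is.finite(lp)) return(-Inf)
      Sg_chol <- try(chol(make_pd(implied_cov(gi), 1e-10)), silent = TRUE)
      if (inherits(Sg_chol, "try-error")) return(-Inf)
      lly <- 0
      for (s in seq_len(n)) {
        ps <- if (factorized)
          subject_loglik_factorized(gi, cache[[s]])
        else {
          ## defensive inner proposal: subject-fitted Gaussian mixed equally
          ## with the group distribution under theta*
          prop <- subj_prop[[s]]
          n1 <- ceiling(n_particles / 2)
          a <- rbind(rmvnorm_chol(n1, prop$m, prop$chol),
                     rmvnorm_chol(n_particles - n1, gi$mu, Sg_chol))
          lg <- dmvnorm_log(a, gi$mu, Sg_chol)
          d1 <- dmvnorm_log(a, prop$m, prop$chol)
          lqs <- apply(cbind(d1, lg), 1, logsumexp) - log(2)
          logmeanexp(model_loglik(fit$model, a, s) + lg - lqs)
        }
        lly <- lly + ps
        if (!is.finite(lly)) return(-Inf)
      }
      lly + lp - lq[i]
    }, numeric(1))
    logml <- logmeanexp(lw)
    wn <- exp(lw - max(lw[is.finite(lw)]))
    ess <- sum(wn)^2 / sum(wn^2)
    boots <- vapply(seq_len(n_boot), function(b)
      logmeanexp(lw[sample.int(n_is, replace = TRUE)]), numeric(1))
    structure(list(logml = logml, se = sd(boots), log_weights = lw,
                   n_is = n_is, ess = ess, reliable = ess >= 0.05 * n_is,
                   fingerprint = fit$model$fingerprint,
                   config = list(df = df, n_particles = n_particles,
                                 inflate = inflate, shrink = shrink,
                                 kernel_weight = kernel_weight,
                                 kernel_h = kernel_h, n_eta = n_eta)),
              class = "evidence_result")
  })
}

## Precompute, per subject: factor-score draws (with prior-vs-proposal log
## weights) and, per component, particle draws from the subject's fitted
## marginal together with their log-likelihoods and proposal densities. All
## proposals are independent of the group parameters, so the expensive
## likelihood evaluations are shared by every outer draw.
build_factorized_cache <- function(fit, dr, n, n_particles, n_eta) {
  k <- fit$k
  np <- max(32L, n_particles)
  lapply(seq_len(n), function(s) {
    E <- matrix(dr$eta[, s, ], ncol = k)
    em <- colMeans(E); ech <- chol(make_pd(cov(E) * 1.2, 1e-8))
    n1 <- ceiling(n_eta / 2) # defensive: fitted Gaussian + standard-normal prior
    etas <- rbind(rmvnorm_chol(n1, em, ech),
                  matrix(rnorm((n_eta - n1) * k), n_eta - n1, k))
    lq_eta <- apply(cbind(dmvnorm_log(etas, em, ech),
                          rowSums(dnorm(etas, log = TRUE))), 1,
                    logsumexp) - log(2)
    lw_eta <- rowSums(dnorm(etas, log = TRUE)) - lq_eta
    comps <- lapply(fit$model$data[[s]], function(comp) {
      cols <- comp$cols
      X <- matrix(dr$alpha[, s, cols], ncol = length(cols))
      qm <- colMeans(X)
      ## defensive marginal proposal: snug fit + a 2.5x-widened component
      qch1 <- chol(make_pd(cov(X) * 1.2, 1e-8))
      qch2 <- qch1 * 2.5
      n2 <- ceiling(np * 0.75)
      A <- rbind(rmvnorm_chol(n2, qm, qch1), rmvnorm_chol(np - n2, qm, qch2))
      lq <- apply(cbind(log(0.75) + dmvnorm_log(A, qm, qch1),
                        log(0.25) + dmvnorm_log(A, qm, qch2)), 1, logsumexp)
      nat <- to_natural(A, fit$model$transforms[cols])
      colnames(nat) <- fit$model$layout$map$base[cols]
      ll <- task_loglik(nat, comp$enc)
      list(cols = cols, A = A, base = ll - lq)
    })
    list(etas = etas, lw_eta = lw_eta, comps = comps)
  })
}

## Estimate log p(y_s | mu, Lambda, eps) from the cached particles: for each
## factor-score draw, each component integral is a reweighting of the cached
## particles against the conditional model density N(mu_c + Lambda_c eta,
## diag(eps_c)). Conditional on eta the components are independent, so the
## estimates multiply; unbiased on the likelihood scale.
subject_loglik_factorized <- function(gi, cache) {
  J <- nrow(cache$etas)
  comp_sum <- numeric(J)
  for (comp in cache$comps) {
    cols <- comp$cols
    centers <- cache$etas %*% t(gi$Lambda[cols, , drop = FALSE]) +
      rep(gi$mu[cols], each = J) # J x pc
    sdc <- sqrt(gi$eps[cols])
    As <- sweep(comp$A, 2, sdc, "/")
    Cs <- sweep(centers, 2, sdc, "/")
    ## np x J matrix of log N(A_i; center_j, diag(eps)) via one BLAS product
    qf <- -0.5 * (outer(rowSums(As^2), rowSums(Cs^2), "+") - 2 * As %*% t(Cs))
    ld <- qf - 0.5 * length(cols) * log(2 * pi) - sum(log(sdc))
    w <- ld + comp$base
    mx <- apply(w, 2, max)
    ok <- is.finite(mx)
    out <- rep(-Inf, J)
    out[ok] <- mx[ok] +
      log(colMeans(exp(sweep(w[, ok, drop = FALSE], 2, mx[ok]))))
    comp_sum <- comp_sum + out
  }
  logmeanexp(comp_sum + cache$lw_eta)
}

group_vec_len <- function(fit) {
  p <- length(fit$param_names)
  if (fit$group_kind == "mvn") p + p * (p + 1) / 2
  else p + sum(factor_free_mask(p, fit$k)) + p
}

## Materialise the group state of sampling-stage draw i.
draw_group <- function(fit, dr, i) {
  if (fit$group_kind == "mvn") {
    mvn_group(setNames(dr$mu[i, ], fit$param_names), dr$Sigma[, , i])
  } else {
    factor_group(setNames(dr$mu[i, ], fit$param_names), dr$Lambda[, , i],
                 dr$eps[i, ])
  }
}

## Log prior density on the unconstrained group-vector scale: the model's
## prior on (mu, Sigma) or (mu, Lambda, eps) plus the log-Jacobian of the
## reparameterisation. For the multivariate-normal group the covariance prior
## is the closed-form marginal of the hierarchical inverse-Wishart (auxiliary
## scales integrated out); eta is integrated out of the factor model.
log_prior_theta <- function(group, prior, theta) {
  p <- length(group$mu)
  lp_mu <- sum(dnorm(group$mu, prior$mu0, 1, log = TRUE))
  if (group$kind == "mvn") {
    lpS <- log_hw_marginal(group$Sigma, prior$nu, prior$A)
    ## Jacobian of Sigma -> (log-diag Cholesky): |J| = 2^p prod L_jj^(p-j+2)
    L <- t(chol(group$Sigma))
    lj <- p * log(2) + sum((p - seq_len(p) + 2) * log(diag(L)))
    lp_mu + lpS + lj
  } else {
    free <- group$free
    k <- ncol(group$Lambda)
    dg <- diag(as.matrix(group$Lambda[seq_len(k), , drop = FALSE]))
    if (any(dg < 0)) return(-Inf)
    lsd <- prior$lambda_sd %||% 1
    lp_mu + sum(dnorm(group$Lambda[free], 0, lsd, log = TRUE)) + k * log(2) +
      sum(dinvgamma_log(group$eps, prior$eps_shape, prior$eps_rate)) +
      sum(log(group$eps)) # Jacobian of log-eps
  }
}

## Closed-form marginal density of the hierarchical inverse-Wishart prior
## (half-t scales integrated out analytically).
log_hw_marginal <- function(Sigma, nu, A) {
  p <- nrow(Sigma)
  d <- nu + p - 1
  beta <- 1 / A^2
  Sinv <- chol2inv(chol(Sigma))
  ldSig <- as.numeric(determinant(Sigma, logarithm = TRUE)$modulus)
  terms <- (d / 2) * log(2 * nu) + 0.5 * log(beta) - lgamma(0.5) +
    lgamma((d + 1) / 2) - ((d + 1) / 2) * log(nu * diag(Sinv) + beta)
  sum(terms) - (d * p / 2) * log(2) - lmvgamma(d / 2, p) -
    ((d + p + 1) / 2) * ldSig
}

#' Bayes factor between two evidence estimates
#'
#' `BF = exp(logml_a - logml_b)`, with a bootstrap standard error obtained by
#' resampling each result's importance weights. Refuses to compare results
#' computed on different data.
#'
#' @param a,b `evidence_result`s for the same data.
#' @param n_boot bootstrap replicates.
#' @param seed integer seed.
#' @return list with `bf`, `log_bf`, and bootstrap `se` of the Bayes factor.
#' @export
bayes_factor <- function(a, b, n_boot = 500, seed = 1L) {
  stopifnot(inherits(a, "evidence_result"), inherits(b, "evidence_result"))
  if (!isTRUE(all.equal(a$fingerprint, b$fingerprint)))
    stop("evidence results were computed on different data")
  log_bf <- a$logml - b$logml
  with_seed(seed, {
    bfs <- vapply(seq_len(n_boot), function(i) {
      la <- logmeanexp(a$log_weights[sample.int(a$n_is, replace = TRUE)])
      lb <- logmeanexp(b$log_weights[sample.int(b$n_is, replace = TRUE)])
      exp(la - lb)
    }, numeric(1))
    list(bf = exp(log_bf), log_bf = log_bf, se = sd(bfs))
  })
}
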