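## Particle Metropolis-within-Gibbs: alternate conjugate Gibbs updates of the
## group level with conditional-importance-sampling updates of each subject's
## parameter vector, in three stages (burn-in, adaptation, sampling). During
## adaptation, per-subject joint Gaussian approximations over (subject vector,
## group parameters) are accumulated; the sampling stage adds their
## conditional distribution as an efficient proposal component.

#' Sampler configuration
#'
#' Stage lengths, particle counts and proposal-mixture weights of the
#' three-stage sampler. Defaults suit full analyses; validation studies in the
#' test suite use reduced settings.
#'
#' @param burn,adapt,sample iterations per stage.
#' @param particles particles per stage (named or positional:
#'   burn/adapt/sample).
#' @param mix_burn,mix_sample proposal mixture weights
#'   (group-level, local, conditional); the conditional weight must be 0
#'   before the sampling stage.
#' @param scale local-proposal scaling factor; the local component has
#'   covariance `scale^2 * Sigma_group`. Scaling down by the parameter
#'   dimension (random-walk style) makes the local kernel's peak density so
#'   high that the retained particle is heavily penalised in the importance
#'   weights, which destabilises high-dimensional joint fits, so the factor is
#'   dimension-free.
#' @param adapt_extend maximum number of times the adaptation stage is
#'   extended (by `adapt` iterations) if the conditional-proposal fit fails.
#' @param thin keep every `thin`-th sampling-stage draw.
#' @export
sampler_config <- function(burn = 500, adapt = 500, sample = 1000,
                           particles = c(100, 100, 50),
                           mix_burn = c(0.5, 0.5, 0),
                           mix_sample = c(0.1, 0.3, 0.6),
                           scale = 0.5, adapt_extend = 2, thin = 1) {
  stopifnot(burn > 0, adapt > 0, sample > 0, all(particles >= 2),
            abs(sum(mix_burn) - 1) < 1e-8, abs(sum(mix_sample) - 1) < 1e-8,
            mix_burn[3] == 0)
  list(burn = burn, adapt = adapt, sample = sample,
       particles = setNames(rep_len(particles, 3),
                            c("burn", "adapt", "sample")),
       mix_burn = mix_burn, mix_sample = mix_sample, scale = scale,
       adapt_extend = adapt_extend, thin = thin)
}

## Flatten group state to an unconstrained vector (used for conditional
## proposals and the IS2 outer proposal): mvn -> (mu, vech of the Cholesky
## factor with logged diagonal); factor -> (mu, free loadings, log eps).
group_to_vec <- function(group) {
  if (group$kind == "mvn") {
    L <- t(chol(group$Sigma))
    diag(L) <- log(diag(L))
    c(group$mu, L[lower.tri(L, diag = TRUE)])
  } else {
    c(group$mu, group$Lambda[group$free], log(group$eps))
  }
}

vec_to_group <- function(v, template) {
  p <- length(template$mu)
  mu <- setNames(v[seq_len(p)], names(template$mu))
  rest <- v[-seq_len(p)]
  if (template$kind == "mvn") {
    L <- matrix(0, p, p)
    L[lower.tri(L, diag = TRUE)] <- rest
    diag(L) <- exp(diag(L))
    mvn_group(mu, L %*% t(L), template$a)
  } else {
    k <- ncol(template$Lambda)
    nfree <- sum(template$free)
    Lam <- matrix(0, p, k)
    Lam[template$free] <- rest[seq_len(nfree)]
    eps <- exp(rest[nfree + seq_len(p)])
    factor_group(mu, Lam, eps, template$eta)
  }
}

#' Conditional-importance-sampling update of one subject's parameter vector
#'
#' Draws `n_particles - 1` fresh particles from a mixture of (i) the
#' group-level distribution, (ii) a local Gaussian centred on the subject's
#' current vector, and optionally (iii) a fitted conditional proposal; the
#' current vector is always retained as a particle. Particles are weighted by
#' `likelihood x group density / mixture density` and one is selected with
#' probability proportional to its weight, which leaves the subject's
#' conditional posterior invariant.
#'
#' @param ll_fn function: matrix of sampling-scale parameter rows -> vector
#'   of log-likelihoods.
#' @param current current subject vector.
#' @param group_mu,group_chol group-level mean and upper-triangular Cholesky
#'   factor of the group covariance.
#' @param n_particles total particle count (including the current value).
#' @param mix mixture weights (group, local, conditional).
#' @param local_chol Cholesky factor of the local proposal covariance.
#' @param cond optional list with `mean` and `chol` of the conditional
#'   proposal.
#' @param seed optional seed.
#' @return list with the selected `value`, its log-likelihood `ll`, its group
#'   log-density `lp`, and `new` (whether a fresh particle replaced the
#'   current one).
#' @export
particle_update <- function(ll_fn, current, group_mu, group_chol,
                            n_particles, mix, local_chol, cond = NULL,
                            seed = NULL) {
  with_seed(seed, {
    p <- length(current)
    if (n_particles == 1) {
      return(list(value = current, ll = ll_fn(matrix(current, 1))[1],
                  lp = dmvnorm_log(matrix(current, 1), group_mu, group_chol),
                  new = FALSE))
    }
    if (is.null(cond)) mix <- c(mix[1:2] / sum(mix[1:2]), 0)
    n_new <- n_particles - 1
    comp <- sample.int(3, n_new, replace = TRUE, prob = mix)
    parts <- matrix(0, n_new, p)
    ng <- sum(comp == 1); nl <- sum(comp == 2); nc <- sum(comp == 3)
    if (ng) parts[comp == 1, ] <- rmvnorm_chol(ng, group_mu, group_chol)
    if (nl) parts[comp == 2, ] <- rmvnorm_chol(nl, current, local_chol)
    if (nc) parts[comp == 3, ] <- rmvnorm_chol(nc, cond$mean, cond$chol)
    parts <- rbind(matrix(current, 1), parts)
    lp <- dmvnorm_log(parts, group_mu, group_chol)
    d1 <- lp + log(mix[1] + 1e-300)
    d2 <- dmvnorm_log(parts, current, local_chol) + log(mix[2] + 1e-300)
    d3 <- if (!is.null(cond))
      dmvnorm_log(parts, cond$mean, cond$chol) + log(mix[3] + 1e-300)
    else rep(-Inf, nrow(parts))
    mx <- pmax(d1, d2, d3)
    lw_mix <- ifelse(is.finite(mx),
                     mx + log(exp(d1 - mx) + exp(d2 - mx) + exp(d3 - mx)),
                     -Inf)
    ll <- ll_fn(parts)
    lw <- ll + lp - lw_mix
    if (all(!is.finite(lw))) {
      warning("all particle weights are zero; keeping current value")
      return(list(value = current, ll = ll[1], lp = lp[1], new = FALSE))
    }
    w <- exp(lw - max(lw, na.rm = TRUE))
    w[!is.finite(w)] <- 0
    idx <- sample.int(nrow(parts), 1, prob = w)
    list(value = parts[idx, ], ll = ll[idx], lp = lp[idx], new = idx > 1)
  })
}

#' Fit a hierarchical model by particle Metropolis-within-Gibbs
#'
#' Runs the three sampler stages on a model built with [eam_model()] /
#' [fit_joint()] or [custom_model()], with either a full multivariate-normal
#' group level or a factor-analytic one.
#'
#' @param model an `rdm_model`.
#' @param group `"mvn"` or `"factor"`.
#' @param k number of factors (factor group only).
#' @param prior a [group_prior()]; defaults to the package prior for the
#'   model's parameter names.
#' @param config a [sampler_config()].
#' @param seed integer seed (drives all stages).
#' @param Sigma_fixed optional fixed group covariance (validation models):
#'   the covariance is never updated.
#' @param init optional list with starting `mu` and `alpha`.
#' @param verbose print stage progress.
#' @return a `pmwg_fit` object: stage-labelled draws of the group state and
#'   subject vectors, log-likelihood bookkeeping, fitted conditional
#'   proposals, the model, prior, config and seed.
#' @export
fit_pmwg <- function(model, group = c("mvn", "factor"), k = 2, prior = NULL,
                     config = sampler_config(), seed = 1L,
                     Sigma_fixed = NULL, init = NULL, verbose = FALSE) {
  group_kind <- match.arg(group)
  p <- length(model$param_names)
  n <- length(model$data)
  prior <- prior %||% group_prior(model$param_names, model$transforms)
  with_seed(seed, {
    ## initial group state
    if (group_kind == "mvn") {
      Sigma0 <- Sigma_fixed %||% diag(0.3^2, p)
      gs <- mvn_group(setNames(init$mu %||% prior$mu0, model$param_names),
                      Sigma0)
    } else {
      if (k >= p) stop("k must be smaller than the parameter count")
      free <- factor_free_mask(p, k)
      Lam0 <- matrix(0, p, k); Lam0[free] <- 0.1
      gs <- factor_group(setNames(init$mu %||% prior$mu0, model$param_names),
                         Lam0, rep(0.09, p), matrix(0, n, k))
    }
    ## initial subject vectors: jitter around the group mean until finite.
    ## Non-decision-time coordinates start below each subject's fastest
    ## response, otherwise the likelihood can vanish for every jitter.
    alpha <- matrix(NA_real_, n, p, dimnames = list(NULL, model$param_names))
    if (!is.null(init$alpha)) alpha <- init$alpha
    for (s in seq_len(n)) {
      if (all(is.finite(alpha[s, ])) &&
          is.finite(model_loglik(model, alpha[s, ], s))) next
      centre <- gs$mu
      if (is.null(model$loglik)) {
        for (comp in model$data[[s]]) {
          t0_cols <- comp$cols[model$layout$map$base[comp$cols] == "t0"]
          if (length(t0_cols)) {
            min_rt <- min(comp$enc[, "rt"])
            centre[t0_cols] <- pmin(centre[t0_cols], log(0.7 * min_rt))
          }
        }
      }
      ## crude per-subject search: evaluate a cloud of candidates around the
      ## centre at the between-subject scale and start from the best one, so
      ## burn-in polishes rather than travels
      best <- -Inf
      for (sdj in c(0.4, 0.25, 0.15, 0.05)) {
        cand <- sweep(matrix(rnorm(40 * p, 0, sdj), 40, p), 2, centre, "+")
        ll <- model_loglik(model, cand, s)
        if (any(is.finite(ll)) && max(ll) > best) {
          best <- max(ll)
          alpha[s, ] <- cand[which.max(ll), ]
        }
      }
      if (!is.finite(best))
        stop("could not initialise subject ", s,
             ": likelihood is zero everywhere near the prior mean")
    }
    stages <- c(rep("burn", config$burn), rep("adapt", config$adapt),
                rep("sample", config$sample))
    run_chain(model, gs, alpha, prior, config, stages, group_kind,
              Sigma_fixed = !is.null(Sigma_fixed), seed = seed,
              verbose = verbose)
  })
}

run_chain <- function(model, gs, alpha, prior, config, stages, group_kind,
                      Sigma_fixed, seed, verbose) {
  p <- ncol(alpha); n <- nrow(alpha)
  ## Component models update each component's slice of the subject vector
  ## separately (blocked Gibbs over the subject vector): under the factor
  ## group, conditioning on the factor scores makes the components
  ## independent with diagonal prior covariance; under the multivariate
  ## normal group, the conditional prior of a block given the others is the
  ## Schur-complement normal. Each particle update then runs in the
  ## component's low dimension, which mixes far better than one joint
  ## high-dimensional update.
  comp_model <- is.null(model$loglik)
  total <- length(stages)
  k <- if (group_kind == "factor") ncol(gs$Lambda) else 0L
  mu_d <- matrix(NA_real_, total, p, dimnames = list(NULL, names(gs$mu)))
  Sigma_d <- if (group_kind == "mvn") array(NA_real_, c(p, p, total))
  Lambda_d <- if (group_kind == "factor") array(NA_real_, c(p, k, total))
  eps_d <- if (group_kind == "factor") matrix(NA_real_, total, p)
  eta_d <- if (group_kind == "factor") array(NA_real_, c(total, n, k))
  alpha_d <- array(NA_real_, c(total, n, p))
  ll_d <- matrix(NA_real_, total, n)
  new_d <- matrix(FALSE, total, n)
  cond_props <- NULL
  adapt_store <- NULL
  extend_left <- config$adapt_extend
  i <- 1L
  while (i <= length(stages)) {
    st <- stages[i]
    np <- config$particles[[st]]
    mix <- if (st == "sample" && !is.null(cond_props)) config$mix_sample
           else config$mix_burn
    if (comp_model) {
      if (group_kind == "factor") {
        centers_base <- gs$eta %*% t(gs$Lambda) + rep(gs$mu, each = n)
      } else {
        comp_cond <- lapply(model$data[[1]], function(comp) {
          cc <- comp$cols
          bb <- setdiff(seq_len(p), cc)
          if (length(bb)) {
            CB <- gs$Sigma[cc, bb, drop = FALSE] %*% solve(gs$Sigma[bb, bb])
            Vc <- make_pd(gs$Sigma[cc, cc] -
                            CB %*% gs$Sigma[bb, cc, drop = FALSE], 1e-10)
          } else {
            CB <- NULL
            Vc <- make_pd(gs$Sigma[cc, cc, drop = FALSE], 1e-10)
          }
          list(cc = cc, bb = bb, CB = CB, chol = chol(Vc))
        })
      }
      centers_i <- matrix(NA_real_, n, p)
      for (s in seq_len(n)) {
        lls <- 0; moved <- FALSE
        for (ci in seq_along(model$data[[s]])) {
          comp <- model$data[[s]][[ci]]
          cols <- comp$cols
          if (group_kind == "factor") {
            ctr <- centers_base[s, cols]
            pr_chol <- diag(sqrt(gs$eps[cols]), length(cols))
          } else {
            cnd <- comp_cond[[ci]]
            ctr <- gs$mu[cols]
            if (length(cnd$bb))
              ctr <- ctr +
                as.numeric(cnd$CB %*% (alpha[s, cnd$bb] - gs$mu[cnd$bb]))
            pr_chol <- cnd$chol
          }
          centers_i[s, cols] <- ctr
          cond <- NULL
          if (!is.null(cond_props) && st == "sample")
            cond <- conditional_proposal(cond_props[[s]][[ci]], ctr)
          up <- particle_update(
            make_comp_ll(model, comp), alpha[s, cols], ctr, pr_chol,
            np, mix, pr_chol * config$scale, cond)
          alpha[s, cols] <- up$value
          lls <- lls + up$ll
          moved <- moved || up$new
        }
        ll_d[i, s] <- lls
        new_d[i, s] <- moved
      }
    } else {
      Sg <- implied_cov(gs)
      Sg_chol <- chol(make_pd(Sg, 1e-10))
      local_chol <- Sg_chol * config$scale
      gvec <- if (!is.null(cond_props)) group_to_vec(gs)
      for (s in seq_len(n)) {
        cond <- NULL
        if (!is.null(cond_props) && st == "sample")
          cond <- conditional_proposal(cond_props[[s]], gvec)
        up <- particle_update(function(th) model_loglik(model, th, s),
                              alpha[s, ], gs$mu, Sg_chol, np, mix,
                              local_chol, cond)
        alpha[s, ] <- up$value
        ll_d[i, s] <- up$ll
        new_d[i, s] <- up$new
      }
    }
    gs <- if (group_kind == "mvn")
      gibbs_update_mvn(gs, alpha, prior, Sigma_fixed = Sigma_fixed)
    else gibbs_update_factor(gs, alpha, prior)
    mu_d[i, ] <- gs$mu
    if (group_kind == "mvn") Sigma_d[, , i] <- gs$Sigma
    else { Lambda_d[, , i] <- gs$Lambda; eps_d[i, ] <- gs$eps
           eta_d[i, , ] <- gs$eta }
    alpha_d[i, , ] <- alpha
    ## collect adaptation draws and fit conditional proposals at stage end
    if (st == "adapt") {
      if (comp_model) {
        adapt_store$centers <- abind_iter(adapt_store$centers, centers_i)
      } else {
        adapt_store$theta <- rbind(adapt_store$theta, group_to_vec(gs))
      }
      adapt_store$alpha <- abind_iter(adapt_store$alpha, alpha)
      if (i == max(which(stages == "adapt"))) {
        fit <- try(
          if (comp_model)
            fit_conditional_proposals_comp(adapt_store, model, n)
          else fit_conditional_proposals(adapt_store, n, p),
          silent = TRUE)
        if (inherits(fit, "try-error")) {
          if (extend_left > 0) {
            extend_left <- extend_left - 1
            add <- sum(stages == "adapt")
            stages <- append(stages, rep("adapt", add),
                             after = max(which(stages == "adapt")))
            warning("conditional-proposal fit failed; extending adaptation")
            grow <- function(m, extra) rbind(m, matrix(NA, extra, ncol(m)))
            total2 <- length(stages)
            mu_d <- rbind(mu_d, matrix(NA, add, p))
            if (group_kind == "mvn") {
              S2 <- array(NA_real_, c(p, p, total2)); S2[, , 1:total] <- Sigma_d
              Sigma_d <- S2
            } else {
              L2 <- array(NA_real_, c(p, k, total2)); L2[, , 1:total] <- Lambda_d
              Lambda_d <- L2
              eps_d <- rbind(eps_d, matrix(NA, add, p))
              e2 <- array(NA_real_, c(total2, n, k)); e2[1:total, , ] <- eta_d
              eta_d <- e2
            }
            a2 <- array(NA_real_, c(total2, n, p)); a2[1:total, , ] <- alpha_d
            alpha_d <- a2
            ll_d <- rbind(ll_d, matrix(NA, add, n))
            new_d <- rbind(new_d, matrix(FALSE, add, n))
            total <- total2
          } else stop("conditional-proposal fit failed after extensions: ",
                      attr(fit, "condition")$message)
        } else cond_props <- fit
      }
    }
    if (verbose && i %% 100 == 0)
      message(st, " iteration ", i, "/", length(stages))
    i <- i + 1L
  }
  structure(list(stage = stages, mu = mu_d, Sigma = Sigma_d,
                 Lambda = Lambda_d, eps = eps_d, eta = eta_d,
                 alpha = alpha_d, ll = ll_d,
                 new_particle = new_d, group_kind = group_kind, k = k,
                 Sigma_fixed = Sigma_fixed,
                 cond_props = cond_props, model = model, prior = prior,
                 config = config, seed = seed,
                 param_names = model$param_names),
            class = "pmwg_fit")
}

abind_iter <- function(store, alpha) {
  if (is.null(store)) array(alpha, c(1, dim(alpha)))
  else {
    out <- array(NA_real_, c(dim(store)[1] + 1, dim(alpha)))
    out[seq_len(dim(store)[1]), , ] <- store
    out[dim(out)[1], , ] <- alpha
    out
  }
}

## Fit per-subject joint Gaussians over (alpha_s, group vector) from the
## adaptation draws; stored as partitioned moments for fast conditioning.
fit_conditional_proposals <- function(adapt_store, n, p) {
  theta <- adapt_store$theta
  lapply(seq_len(n), function(s) {
    X <- cbind(adapt_store$alpha[, s, ], theta)
    m <- colMeans(X)
    S <- make_pd(cov(X), 1e-6)
    ia <- seq_len(p); ig <- (p + 1):ncol(X)
    C <- S[ia, ig] %*% solve(S[ig, ig])
    ccov <- make_pd(S[ia, ia] - C %*% S[ig, ia], 1e-6)
    list(m_a = m[ia], m_g = m[ig], C = C, chol = chol(ccov))
  })
}

conditional_proposal <- function(cp, gvec) {
  list(mean = as.numeric(cp$m_a + cp$C %*% (gvec - cp$m_g)), chol = cp$chol)
}

## Componentwise likelihood closure for factor fits.
make_comp_ll <- function(model, comp) {
  cols <- comp$cols
  tr <- model$transforms[cols]
  base <- model$layout$map$base[cols]
  force(comp)
  function(th) {
    nat <- to_natural(th, tr)
    colnames(nat) <- base
    task_loglik(nat, comp$enc)
  }
}

## Conditional proposals per subject and component: joint Gaussian of the
## component slice of the subject vector and its conditional-prior centre
## (mu_c + Lambda_c eta_s) over the adaptation draws.
fit_conditional_proposals_comp <- function(adapt_store, model, n) {
  lapply(seq_len(n), function(s) {
    lapply(model$data[[s]], function(comp) {
      cols <- comp$cols
      pc <- length(cols)
      X <- cbind(adapt_store$alpha[, s, cols],
                 adapt_store$centers[, s, cols])
      m <- colMeans(X)
      S <- make_pd(cov(X), 1e-6)
      ia <- seq_len(pc); ig <- pc + seq_len(pc)
      C <- S[ia, ig] %*% solve(S[ig, ig])
      ccov <- make_pd(S[ia, ia] - C %*% S[ig, ia], 1e-6)
      list(m_a = m[ia], m_g = m[ig], C = C, chol = chol(ccov))
    })
  })
}

#' Fit a joint model over several components
#'
#' Convenience wrapper: builds the joint model from the trial table (one
#' component per task, or per task-session when `pool_sessions = FALSE`) and
#' fits it with [fit_pmwg()]. A single-component call is identical to a
#' standard hierarchical fit.
#'
#' @inheritParams eam_model
#' @inheritParams fit_pmwg
#' @param ... passed to [fit_pmwg()].
#' @export
fit_joint <- function(trials, tasks = NULL, pool_sessions = TRUE,
                      group = "mvn", k = 2, ...) {
  model <- eam_model(trials, tasks = tasks, pool_sessions = pool_sessions)
  fit_pmwg(model, group = group, k = k, ...)
}

#' Extract sampling-stage draws from a fit
#'
#' @param fit a `pmwg_fit`.
#' @param stage stage label (default `"sample"`).
#' @export
stage_draws <- function(fit, stage = "sample") {
  idx <- which(fit$stage == stage)
  if (fit$config$thin > 1 && stage == "sample")
    idx <- idx[seq(1, length(idx), by = fit$config$thin)]
  list(idx = idx, mu = fit$mu[idx, , drop = FALSE],
       Sigma = if (!is.null(fit$Sigma)) fit$Sigma[, , idx, drop = FALSE],
       Lambda = if (!is.null(fit$Lambda)) fit$Lambda[, , idx, drop = FALSE],
       eps = if (!is.null(fit$eps)) fit$eps[idx, , drop = FALSE],
       eta = if (!is.null(fit$eta)) fit$eta[idx, , , drop = FALSE],
       alpha = fit$alpha[idx, , , drop = FALSE],
       ll = fit$ll[idx, , drop = FALSE])
}
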